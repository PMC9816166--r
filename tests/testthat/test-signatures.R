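# two synthetic signatures with disjoint channel support
disjoint_catalog <- function() {
  ch <- sbs_channels()
  a <- c(rep(1 / 48, 48), rep(0, 48))
  b <- c(rep(0, 48), rep(1 / 48, 48))
  mat <- cbind(SIGA = a, SIGB = b)
  rownames(mat) <- ch
  mat
}

test_that("context counting hits the right channel on either strand", {
  s <- snv_records("1", 1, "C", "T", 5, 10, 0, 10, context = "ACG")
  v <- count_contexts(s)
  expect_equal(sum(v), 1)
  expect_equal(unname(v["A[C>T]G"]), 1)
  # purine-strand record lands on the reverse-complement channel
  s2 <- snv_records("1", 2, "G", "A", 5, 10, 0, 10, context = "CGT")
  v2 <- count_contexts(s2)
  expect_equal(unname(v2["A[C>T]G"]), 1)
  s3 <- snv_records("1", 3, "C", "T", 5, 10, 0, 10)
  expect_error(count_contexts(s3), "context")
})

test_that("simulated context counts follow the planted mixture", {
  set.seed(21)
  catalog <- synthetic_catalog()
  e <- c(SBS1 = 0.2, SBS5 = 0.5, APOBEC = 0.3)
  sim <- simulate_tumor(sim_params(n_mutations = 5000, exposures = e),
                        seed = 3)
  counts <- count_contexts(sim$snvs)
  expect_equal(sum(counts), 5000)
  p_mix <- as.vector(catalog %*% e)
  gof <- suppressWarnings(chisq.test(counts, p = p_mix))
  expect_gt(gof$p.value, 0.001)
})

test_that("EM refit recovers degenerate and mixed exposures", {
  catalog <- synthetic_catalog()
  # single-signature catalog -> exposure 1
  f1 <- fit_exposures(round(catalog[, "SBS5"] * 1000),
                      catalog[, "SBS5", drop = FALSE])
  expect_equal(unname(f1$exposures), 1)
  # counts equal to one catalog column -> vertex MLE
  f2 <- fit_exposures(round(disjoint_catalog()[, 1] * 4800),
                      disjoint_catalog())
  expect_gt(f2$exposures["SIGA"], 0.999)
  # 0.5/0.5 mixture of disjoint-support signatures
  set.seed(8)
  draw <- sample(sbs_channels(), 5000, replace = TRUE,
                 prob = rowSums(disjoint_catalog()) / 2)
  counts <- table(factor(draw, levels = sbs_channels()))
  f3 <- fit_exposures(as.integer(counts)[seq_len(96)] |>
                        setNames(sbs_channels()), disjoint_catalog())
  expect_equal(unname(f3$exposures["SIGA"]), 0.5, tolerance = 0.02)
  expect_equal(sum(f3$exposures), 1, tolerance = 1e-9)
  expect_error(fit_exposures(rep(0, 96), catalog), "all-zero")
})

test_that("EM log-likelihood is monotone and matches a grid search", {
  set.seed(13)
  catalog <- synthetic_catalog()[, c("SBS1", "APOBEC")]
  draw <- sample(sbs_channels(), 3000, replace = TRUE,
                 prob = as.vector(catalog %*% c(0.3, 0.7)))
  counts <- setNames(as.integer(table(factor(draw,
                                             levels = sbs_channels()))),
                     sbs_channels())
  fit <- fit_exposures(counts, catalog)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  # brute-force 1-D grid over the 2-signature simplex
  grid <- seq(0, 1, by = 1e-4)
  ll <- vapply(grid, function(e1) {
    mix <- catalog %*% c(e1, 1 - e1)
    sum(counts[counts > 0] * log(mix[counts > 0]))
  }, numeric(1))
  expect_lt(abs(fit$exposures[1] - grid[which.max(ll)]), 1e-3)
})

test_that("duplicate signatures trigger the identifiability warning", {
  cat2 <- synthetic_catalog()[, c("SBS5", "SBS5")]
  colnames(cat2) <- c("A", "B")
  expect_warning(f <- fit_exposures(rep(10, 96) |>
                                      setNames(sbs_channels()), cat2),
                 "non-identifiable")
  expect_true(f$non_identifiable)
})

test_that("mutation posterior is Bayes rule, normalized on all channels", {
  catalog <- synthetic_catalog()
  e <- c(SBS1 = 0.2, SBS5 = 0.5, APOBEC = 0.3)
  post <- mutation_posterior(sbs_channels(), e, catalog)
  expect_equal(unname(rowSums(post)), rep(1, 96), tolerance = 1e-12)
  # brute-force normalization, channel by channel
  brute <- t(apply(catalog, 1, function(p) e * p / sum(e * p)))
  expect_equal(unname(post), unname(brute), tolerance = 1e-12)
  # degenerate exposure -> certainty wherever the signature has mass
  p1 <- mutation_posterior("A[C>T]G", c(SBS1 = 1, SBS5 = 0, APOBEC = 0),
                           catalog)
  expect_equal(unname(p1[1, "SBS1"]), 1)
  # hand arithmetic: e = (0.8, 0.2), P(c|s) = (0.01, 0.04)
  # -> P(s1|c) = 0.008 / 0.016 = 0.5
  ch <- sbs_channels()
  toy <- cbind(S1 = c(0.01, rep(0.99 / 95, 95)),
               S2 = c(0.04, rep(0.96 / 95, 95)))
  rownames(toy) <- ch
  pp <- mutation_posterior(ch[1], c(S1 = 0.8, S2 = 0.2), toy)
  expect_equal(unname(pp[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  # a channel with zero total mass under the model is fatal
  toy0 <- toy
  toy0[2, ] <- 0
  toy0 <- sweep(toy0, 2, colSums(toy0), "/")
  expect_error(mutation_posterior(ch[2], c(S1 = 0.8, S2 = 0.2), toy0),
               "zero probability")
})

test_that("clock-mutation rule: CpG C>T always; otherwise strict >50%
           SBS1+SBS5 posterior", {
  catalog <- synthetic_catalog()
  snvs <- snv_records(rep("1", 3), 1:3, c("C", "C", "C"),
                      c("T", "A", "A"), 5, 10, 0, 10,
                      context = c("ACG", "ACA", "ACA"))
  post <- rbind(c(SBS1 = 0.0, SBS5 = 0.0, APOBEC = 1.0),
                c(SBS1 = 0.3, SBS5 = 0.3, APOBEC = 0.4),
                c(SBS1 = 0.2, SBS5 = 0.2, APOBEC = 0.6))
  expect_equal(is_clock_mutation(snvs, post), c(TRUE, TRUE, FALSE))
  # a posterior of exactly 0.5 is NOT clock-like
  post_tie <- rbind(c(SBS1 = 0.25, SBS5 = 0.25, APOBEC = 0.5))
  s1 <- snvs[2, , drop = FALSE]
  expect_false(is_clock_mutation(s1, post_tie))
})

test_that("synthetic catalog has the advertised shape and samples from
           it concentrate on CpG for the SBS1-like column", {
  catalog <- synthetic_catalog()
  expect_equal(colSums(catalog), c(SBS1 = 1, SBS5 = 1, APOBEC = 1),
               tolerance = 1e-12)
  cpg <- grepl("\\[C>T\\]G$", rownames(catalog))
  expect_gte(sum(catalog[cpg, "SBS1"]), 0.8)
  set.seed(4)
  draw <- sample(rownames(catalog), 10000, replace = TRUE,
                 prob = catalog[, "SBS1"])
  expect_gte(mean(grepl("\\[C>T\\]G$", draw)), 0.8)
})

test_that("catalog TSV round-trips through read_catalog", {
  d <- withr::local_tempdir()
  path <- file.path(d, "catalog.tsv")
  write_catalog(synthetic_catalog(), path)
  back <- read_catalog(path)
  expect_equal(back, synthetic_catalog(), tolerance = 1e-12)
})
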