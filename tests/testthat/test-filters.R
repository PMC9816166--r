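mk_snvs <- function(n, tumor_depth = 40, normal_depth = 40,
                    normal_alt = 0) {
  snv_records(chrom = rep("1", n), pos = seq_len(n) * 100,
              ref = rep("C", n), alt = rep("T", n),
              tumor_alt = rep(10, n), tumor_depth = tumor_depth,
              normal_alt = normal_alt, normal_depth = normal_depth)
}

test_that("depth and normal-support cutoffs act at their boundaries", {
  s <- mk_snvs(4)
  s$tumor_depth <- c(9L, 10L, 40L, 40L)
  s$normal_depth <- c(40L, 10L, 9L, 40L)
  s$normal_alt <- c(0L, 0L, 0L, 2L)
  kept <- depth_normal_filter(s)
  expect_equal(kept$pos, 200)          # 10X boundary kept, others out
  # the stricter zero-normal-reads pipeline variant
  s2 <- mk_snvs(2)
  s2$normal_alt <- c(0L, 1L)
  expect_equal(nrow(depth_normal_filter(s2, max_normal_alt = 0)), 1)
  expect_equal(nrow(depth_normal_filter(s2, max_normal_alt = 1)), 2)
})

test_that("mapping filter removes only records failing >= 2 of 4 cutoffs", {
  s <- mk_snvs(4)
  ann <- data.frame(chrom = "1", pos = c(100, 200, 300, 400),
                    nonunique_map_frac = c(0.95, 0.95, 0.50, 0.50),
                    multimap_cluster = c(FALSE, FALSE, FALSE, TRUE),
                    excessive_depth = c(FALSE, FALSE, FALSE, TRUE),
                    dust_score = c(10, 65, 65, 65))
  kept <- mapping_filter(s, ann)
  expect_equal(kept$pos, c(100, 200))  # 1-of-4 kept, 2-of-4 removed
  removed <- attr(kept, "removed")
  expect_equal(removed$pos, c(300, 400))
  expect_match(removed$flags[1], "nonunique\\+dust")
})

test_that("missing mapping annotation is fatal and names the site", {
  s <- mk_snvs(2)
  ann <- data.frame(chrom = "1", pos = 100, nonunique_map_frac = 1,
                    multimap_cluster = FALSE, excessive_depth = FALSE,
                    dust_score = 0)
  expect_error(mapping_filter(s, ann), "1:200")
})

test_that("panel of normals removes exact matches only", {
  s <- mk_snvs(3)
  pon <- data.frame(chrom = "1", pos = c(100, 200), ref = c("C", "C"),
                    alt = c("T", "G"))
  kept <- panel_of_normals_filter(s, pon)
  # pos 200 has alt T but PON lists alt G there -> kept
  expect_equal(kept$pos, c(200, 300))
  expect_equal(panel_of_normals_filter(s, pon[0, , drop = FALSE]), s)
})

test_that("mutation burden divides by the 2800 Mb genome", {
  expect_equal(mutation_burden(14000), 5.0)
  expect_equal(mutation_burden(2800), 1.0)
  expect_equal(mutation_burden(0), 0.0)
  expect_error(mutation_burden(-1), "non-negative")
})

test_that("filter cascade is order-invariant", {
  set.seed(11)
  n <- 60
  s <- snv_records(chrom = rep("1", n), pos = seq_len(n) * 10,
                   ref = "C", alt = "T",
                   tumor_alt = rbinom(n, 5, 0.4),
                   tumor_depth = sample(5:60, n, TRUE),
                   normal_alt = sample(0:3, n, TRUE),
                   normal_depth = sample(5:60, n, TRUE))
  ann <- data.frame(chrom = "1", pos = s$pos,
                    nonunique_map_frac = runif(n, 0.4, 1),
                    multimap_cluster = runif(n) < 0.2,
                    excessive_depth = runif(n) < 0.2,
                    dust_score = sample(c(10, 70), n, TRUE))
  pon <- data.frame(chrom = "1", pos = sample(s$pos, 10),
                    ref = "C", alt = "T")
  f1 <- function(x) depth_normal_filter(x)
  f2 <- function(x) mapping_filter(x, ann)
  f3 <- function(x) panel_of_normals_filter(x, pon)
  orders <- list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))
  surv <- lapply(orders, function(o) {
    out <- s
    for (i in o) out <- list(f1, f2, f3)[[i]](out)
    sort(out$pos)
  })
  expect_equal(surv[[1]], surv[[2]])
  expect_equal(surv[[1]], surv[[3]])
})

test_that("excessive-depth helper flags against the chromosome median", {
  s <- mk_snvs(5)
  s$normal_depth <- c(30L, 30L, 30L, 30L, 100L)
  expect_equal(annotate_excessive_depth(s, k = 3),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
})
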