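#' Count mutations over the 96 substitution channels
#'
#' @param snvs SNV data.frame with pyrimidine-normalized `ref`, `alt`,
#'   `context` columns (see [snv_records()]).
#' @return named integer vector of length 96 in [sbs_channels()] order;
#'   the counts sum to `nrow(snvs)`.
#' @export
count_contexts <- function(snvs) {
  ch <- sbs_channel(snvs$ref, snvs$alt, snvs$context)
  if (anyNA(ch)) {
    bad <- which(is.na(ch))[1]
    stop("malformed or missing context at record ", bad, " (",
         snvs$chrom[bad], ":", snvs$pos[bad], ")")
  }
  tab <- table(factor(ch, levels = sbs_channels()))
  stats::setNames(as.integer(tab), sbs_channels())
}

#' Validate a 96-channel signature catalog
#'
#' @param probs numeric matrix, 96 rows (rownames = channel labels) by one
#'   column per signature; each column sums to 1.
#' @return the matrix, rows reordered to canonical channel order.
#' @export
signature_catalog <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 96L) stop("catalog must have 96 rows")
  if (is.null(rownames(probs)) ||
      !all(sort(rownames(probs)) == sort(sbs_channels())))
    stop("catalog rownames must be the 96 channel labels")
  probs <- probs[sbs_channels(), , drop = FALSE]
  if (any(probs < 0)) stop("catalog probabilities must be non-negative")
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-9))
    stop("catalog column(s) do not sum to 1: ",
         paste(colnames(probs)[abs(cs - 1) > 1e-9], collapse = ", "))
  probs
}

#' Read a signature catalog from TSV
#'
#' First column holds channel labels (`"A[C>A]A"` style, any row order);
#' remaining columns are signatures. COSMIC-format catalogs load directly.
#'
#' @param path TSV path.
#' @return validated 96 x S probability matrix.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  signature_catalog(mat)
}

#' Write a signature catalog to TSV
#'
#' @param catalog 96 x S probability matrix.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(Type = rownames(catalog), catalog,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fit signature exposures by maximum likelihood (EM)
#'
#' Models the 96-channel mutation counts as a multinomial mixture of the
#' catalog signatures and fits the mixture weights (exposures) by
#' expectation-maximization:
#' \deqn{e_s \leftarrow \frac{1}{N}\sum_c n_c P(s \mid c)}
#' iterated until the log-likelihood improves by less than `tol`. The EM
#' log-likelihood is non-decreasing by construction; the trace is
#' returned for inspection.
#'
#' @param counts 96-channel count vector (see [count_contexts()]).
#' @param catalog 96 x S probability matrix (see [signature_catalog()]).
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter iteration cap (default 10000).
#' @return object of class `signature_fit`: list with `exposures` (named,
#'   summing to 1), `loglik`, `loglik_trace`, `n_mutations`, `iterations`,
#'   `catalog`, and `non_identifiable` flag.
#' @export
fit_exposures <- function(counts, catalog, tol = 1e-8, max_iter = 10000) {
  catalog <- signature_catalog(catalog)
  if (length(counts) != 96L) stop("counts must have length 96")
  if (!is.null(names(counts))) counts <- counts[sbs_channels()]
  if (any(counts < 0)) stop("counts must be non-negative")
  n_tot <- sum(counts)
  if (n_tot == 0) stop("all-zero count vector: nothing to fit")

  S <- ncol(catalog)
  non_ident <- FALSE
  if (S > 1L) {
    dup <- duplicated(t(round(catalog, 12)))
    if (any(dup)) {
      warning("duplicate identical signatures in catalog; exposures are ",
              "non-identifiable")
      non_ident <- TRUE
    }
  }

  e <- rep(1 / S, S)
  trace <- numeric(0)
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    mix <- as.vector(catalog %*% e)              # P(c) under current e
    obs <- counts > 0
    ll <- sum(counts[obs] * log(mix[obs]))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    if (it >= max_iter) break
    # responsibilities P(s|c), then weighted average over observed counts
    resp <- catalog * rep(e, each = 96L)
    denom <- rowSums(resp)
    denom[denom == 0] <- 1
    resp <- resp / denom
    e <- as.vector(crossprod(resp, counts)) / n_tot
    ll_old <- ll
  }
  exposures <- stats::setNames(e, colnames(catalog))
  structure(list(exposures = exposures, loglik = trace[length(trace)],
                 loglik_trace = trace, n_mutations = n_tot,
                 iterations = it, catalog = catalog,
                 non_identifiable = non_ident),
            class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Signature refit (multinomial mixture, EM):",
      x$n_mutations, "mutations,", x$iterations, "iterations\n")
  print(round(x$exposures, 4))
  cat("log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' Per-mutation signature posterior
#'
#' Bayes' rule over signatures for each channel:
#' `P(s | c) = e_s P(c | s) / sum_s' e_s' P(c | s')`.
#'
#' @param channels character vector of channel labels (or a `signature_fit`
#'   can be queried via its catalog and exposures directly).
#' @param exposures named exposure vector summing to 1.
#' @param catalog 96 x S probability matrix.
#' @return matrix, one row per element of `channels`, one column per
#'   signature; rows sum to 1.
#' @export
mutation_posterior <- function(channels, exposures, catalog) {
  catalog <- signature_catalog(catalog)
  joint <- catalog * rep(exposures, each = 96L)  # e_s * P(c|s)
  mass <- rowSums(joint)
  idx <- match(channels, sbs_channels())
  if (anyNA(idx)) stop("unknown channel label(s): ",
                       paste(unique(channels[is.na(idx)]), collapse = ", "))
  zero <- mass[idx] == 0
  if (any(zero))
    stop("channel(s) with zero probability under the fitted model: ",
         paste(unique(channels[zero]), collapse = ", "))
  post <- joint[idx, , drop = FALSE] / mass[idx]
  rownames(post) <- channels
  post
}

#' Identify clock-like (aging-associated) mutations
#'
#' A mutation is counted as clock-like when it is a C>T substitution at a
#' CpG site (context `N[C>T]G`), or when its posterior probability of
#' arising from the clock signatures (SBS1 + SBS5 by default) exceeds
#' 0.5. The comparison is strict: a posterior of exactly 0.5 is not
#' clock-like.
#'
#' @param snvs SNV data.frame (pyrimidine-normalized).
#' @param posterior per-mutation posterior matrix from
#'   [mutation_posterior()], rows aligned with `snvs`.
#' @param clock_signatures column names counted as clock processes
#'   (default `c("SBS1", "SBS5")`).
#' @return logical vector, one element per mutation.
#' @export
is_clock_mutation <- function(snvs, posterior,
                              clock_signatures = c("SBS1", "SBS5")) {
  cpg <- snvs$ref == "C" & snvs$alt == "T" &
    substr(snvs$context, 3, 3) == "G"
  sigs <- intersect(clock_signatures, colnames(posterior))
  p_clock <- if (length(sigs))
    rowSums(posterior[, sigs, drop = FALSE]) else rep(0, nrow(snvs))
  (cpg %in% TRUE) | p_clock > 0.5
}

#' Synthetic three-signature catalog for testing and simulation
#'
#' A small stand-in catalog (not COSMIC data): an SBS1-like signature
#' with 85% of its mass on the four `N[C>T]G` CpG channels, a flat
#' SBS5-like signature, and an APOBEC-like signature concentrated on
#' `T[C>T]A/T` and `T[C>G]A/T`. Column names are `SBS1`, `SBS5`,
#' `APOBEC` so the clock rule applies directly. Real COSMIC v3.2
#' catalogs are read at run time with [read_catalog()].
#'
#' @return validated 96 x 3 probability matrix.
#' @export
synthetic_catalog <- function() {
  ch <- sbs_channels()
  flat <- rep(1 / 96, 96)
  cpg <- grepl("^\\w\\[C>T\\]G$", ch)
  sbs1 <- ifelse(cpg, 0.85 / 4, 0.15 / 92)
  apo_ch <- c("T[C>T]A", "T[C>T]T", "T[C>G]A", "T[C>G]T")
  apo <- ifelse(ch %in% apo_ch, 0.90 / 4, 0.10 / 92)
  mat <- cbind(SBS1 = sbs1, SBS5 = flat, APOBEC = apo)
  rownames(mat) <- ch
  signature_catalog(mat)
}
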