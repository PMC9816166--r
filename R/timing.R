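#' Count clonal mutations before and after a copy-number gain
#'
#' On a gained segment, clonal mutations with multiplicity >= 2 arose on
#' the ancestral copy before its duplication (`n_pre`, also written n2);
#' clonal mutations at multiplicity 1 arose after (`n_post`, n1).
#' Subclonal mutations are tallied separately and excluded from both.
#' When `clock` is supplied, only clock-like mutations are counted.
#'
#' @param calls multiplicity table from [assign_multiplicity()].
#' @param major major copy number of the segment (must be >= 2).
#' @param clock optional logical vector (see [is_clock_mutation()]).
#' @return list with `n_pre`, `n_post`, `n_subclonal`.
#' @export
count_pre_post <- function(calls, major, clock = NULL) {
  if (major < 2) stop("segment is not gained (major < 2); cannot time it")
  if (!is.null(clock)) {
    stopifnot(length(clock) == nrow(calls))
    calls <- calls[clock, , drop = FALSE]
  }
  list(n_pre = sum(calls$clonal & calls$m >= 2),
       n_post = sum(calls$clonal & calls$m == 1),
       n_subclonal = sum(!calls$clonal))
}

#' Molecular time of a copy-number gain (closed form)
#'
#' Assuming a constant per-copy mutation rate and a single synchronous
#' gain at molecular time pi (fraction of the segment's clonal mutation
#' history), the expected pre/post counts give:
#'
#' * `(2,0)` copy-neutral LOH: one ancestral copy for `pi`, two after, so
#'   `pi = 2 n2 / (2 n2 + n1)`;
#' * `(2,1)` single-copy gain: two ancestral copies (one duplicates),
#'   three after: `pi = 3 n2 / (2 n2 + n1)`;
#' * `(2,2)` synchronous double gain: `pi = 2 n2 / (2 n2 + n1)`.
#'
#' Estimates above 1 (possible for `(2,1)` when `n2 > n1`) are capped at
#' 1 with an `overflow` flag. Totals below `min_count` set a
#' `low_confidence` flag.
#'
#' @param n2 clonal mutations at multiplicity >= 2 (pre-gain).
#' @param n1 clonal mutations at multiplicity 1 (post-gain).
#' @param major,minor copy-number state; supported states are (2,0),
#'   (2,1) and (2,2).
#' @param min_count minimum informative count (default 20).
#' @return list with `pi`, `n_pre`, `n_post`, `cn_state`, `flags`.
#' @export
molecular_time <- function(n2, n1, major, minor, min_count = 20) {
  state <- paste0(major, "+", minor)
  mult <- switch(state, "2+0" = 2, "2+1" = 3, "2+2" = 2,
                 stop("unsupported copy-number state ", state,
                      "; closed-form timing covers (2,0), (2,1), (2,2) ",
                      "only - higher gains need a maximum-likelihood ",
                      "multi-gain extension"))
  flags <- character(0)
  if (n2 + n1 < min_count) flags <- c(flags, "low_confidence")
  if (n2 + n1 == 0) {
    pi <- NA_real_
    flags <- c(flags, "no_informative_mutations")
  } else {
    pi <- mult * n2 / (2 * n2 + n1)
    if (pi > 1) {
      pi <- 1
      flags <- c(flags, "overflow")
    }
  }
  list(pi = pi, n_pre = n2, n_post = n1, cn_state = c(major, minor),
       flags = flags)
}

#' Bootstrap confidence interval for molecular time
#'
#' Resamples mutations with replacement `B` times, recomputes pi on each
#' replicate, and returns empirical percentiles.
#'
#' @param calls multiplicity table of the segment's mutations.
#' @param major,minor copy-number state.
#' @param B bootstrap replicates (default 200; 10 reproduces the
#'   MutationTimeR default).
#' @param seed optional RNG seed for reproducibility.
#' @param clock optional logical clock filter, resampled with the calls.
#' @param conf confidence level (default 0.95).
#' @return list with `ci_low`, `ci_high`, `pi_boot` (replicates), and
#'   `flags`.
#' @export
bootstrap_ci <- function(calls, major, minor, B = 200, seed = NULL,
                         clock = NULL, conf = 0.95) {
  if (B < 2) stop("B must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(calls)
  counts <- count_pre_post(calls, major, clock)
  if (counts$n_pre + counts$n_post < 2)
    return(list(ci_low = NA_real_, ci_high = NA_real_,
                pi_boot = numeric(0), flags = "undefined_ci"))
  pis <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    cb <- count_pre_post(calls[idx, , drop = FALSE], major,
                         if (!is.null(clock)) clock[idx])
    if (cb$n_pre + cb$n_post == 0) return(NA_real_)
    molecular_time(cb$n_pre, cb$n_post, major, minor, min_count = 0)$pi
  }, numeric(1))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(pis, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(ci_low = qs[1], ci_high = qs[2], pi_boot = pis,
       flags = character(0))
}

#' Time a gained segment: point estimate plus bootstrap interval
#'
#' Estimates the molecular time of the gain from the segment's clonal
#' mutations and attaches a bootstrap confidence interval. Two
#' estimators are available:
#'
#' * `method = "ml"` (default, used when `tumor_alt`/`tumor_depth` and
#'   `purity` are supplied): the fraction `q` of clonal mutations at
#'   multiplicity 2 is fitted by maximum likelihood on the binomial
#'   mixture of the two expected VAFs, without hard per-mutation
#'   assignment, and mapped to time through the closed-form lineage
#'   relations of [molecular_time()] via the effective counts
#'   `(qN, (1-q)N)`. This removes the misassignment bias that hard
#'   argmax classification introduces when the two VAF distributions
#'   overlap (small pre-gain counts are otherwise swamped by binomial
#'   tails).
#' * `method = "counts"`: hard counts from [count_pre_post()] plugged
#'   directly into [molecular_time()].
#'
#' Hard pre/post counts are always reported alongside the estimate.
#'
#' @inheritParams bootstrap_ci
#' @param min_count passed to [molecular_time()].
#' @param method `"ml"` or `"counts"` (see Details).
#' @param tumor_alt,tumor_depth observed allele counts aligned with
#'   `calls` (required for `method = "ml"`).
#' @param purity tumor purity (required for `method = "ml"`).
#' @return object of class `gain_timing`: list with `pi`, `ci_low`,
#'   `ci_high`, `n_pre`, `n_post`, `n_subclonal`, `cn_state`, `n_boot`,
#'   `method`, `flags`.
#' @export
time_gain <- function(calls, major, minor, B = 200, seed = NULL,
                      clock = NULL, min_count = 20, conf = 0.95,
                      method = c("ml", "counts"), tumor_alt = NULL,
                      tumor_depth = NULL, purity = NULL) {
  method <- match.arg(method)
  if (method == "ml" && (is.null(tumor_alt) || is.null(purity)))
    method <- "counts"
  counts <- count_pre_post(calls, major, clock)

  if (method == "counts") {
    mt <- molecular_time(counts$n_pre, counts$n_post, major, minor,
                         min_count = min_count)
    ci <- bootstrap_ci(calls, major, minor, B = B, seed = seed,
                       clock = clock, conf = conf)
    return(structure(list(pi = mt$pi, ci_low = ci$ci_low,
                          ci_high = ci$ci_high, n_pre = counts$n_pre,
                          n_post = counts$n_post,
                          n_subclonal = counts$n_subclonal,
                          cn_state = c(major = major, minor = minor),
                          n_boot = B, method = method,
                          flags = union(mt$flags, ci$flags)),
                     class = "gain_timing"))
  }

  if (!is.null(seed)) set.seed(seed)
  keep <- calls$clonal %in% TRUE
  if (!is.null(clock)) keep <- keep & clock
  k <- tumor_alt[keep]
  n <- tumor_depth[keep]
  cn_tot <- major + minor
  l1 <- stats::dbinom(k, n, expected_vaf(1, purity, cn_tot))
  l2 <- stats::dbinom(k, n, expected_vaf(2, purity, cn_tot))
  nc <- length(k)

  fit_q <- function(w) {
    if (sum(w) == 0) return(NA_real_)
    nll <- function(q) -sum(w * log(q * l2 + (1 - q) * l1 + 1e-300))
    stats::optimize(nll, c(0, 1), tol = 1e-7)$minimum
  }
  q_to_pi <- function(q) {
    if (is.na(q)) return(NA_real_)
    molecular_time(q * nc, (1 - q) * nc, major, minor,
                   min_count = 0)$pi
  }
  pi_hat <- q_to_pi(fit_q(rep(1, nc)))
  flags <- character(0)
  if (nc < min_count) flags <- c(flags, "low_confidence")
  if (nc == 0) flags <- c(flags, "no_informative_mutations")

  if (nc >= 2) {
    pis <- vapply(seq_len(B), function(b) {
      w <- stats::rmultinom(1, nc, rep(1 / nc, nc))[, 1]
      q_to_pi(fit_q(w))
    }, numeric(1))
    alpha <- (1 - conf) / 2
    qs <- stats::quantile(pis, c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
    ci_low <- qs[1]; ci_high <- qs[2]
  } else {
    ci_low <- ci_high <- NA_real_
    flags <- c(flags, "undefined_ci")
  }
  structure(list(pi = pi_hat, ci_low = ci_low, ci_high = ci_high,
                 n_pre = counts$n_pre, n_post = counts$n_post,
                 n_subclonal = counts$n_subclonal,
                 cn_state = c(major = major, minor = minor),
                 n_boot = B, method = method, flags = flags),
            class = "gain_timing")
}

#' @export
print.gain_timing <- function(x, ...) {
  cat(sprintf("Molecular time of gain (%d+%d): pi = %.3f [%.3f, %.3f]\n",
              x$cn_state[1], x$cn_state[2], x$pi, x$ci_low, x$ci_high))
  cat(sprintf("  pre-gain (m>=2): %d   post-gain (m=1): %d   subclonal: %d   bootstrap B=%d\n",
              x$n_pre, x$n_post, x$n_subclonal, x$n_boot))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Earliest gain overlapping a locus
#'
#' Among timed gained segments overlapping the locus, returns the one
#' with the smallest molecular time (the first gain); `NULL` with a
#' message when no gain overlaps.
#'
#' @param timed_segments list of lists, each with `segment` (one row of a
#'   segment table) and `timing` (a `gain_timing` object).
#' @param locus list with `chrom`, `start`, `end` (1-based inclusive).
#' @return the selected element of `timed_segments`, or `NULL`.
#' @export
first_gain_time_over_locus <- function(timed_segments, locus) {
  l0 <- locus$start - 1
  hits <- Filter(function(ts) {
    s <- ts$segment
    s$chrom == locus$chrom && s$start < locus$end && l0 < s$end &&
      s$major >= 2 && !is.na(ts$timing$pi)
  }, timed_segments)
  if (!length(hits)) {
    message("no timed gain overlaps ", locus$chrom, ":", locus$start,
            "-", locus$end)
    return(NULL)
  }
  pis <- vapply(hits, function(ts) ts$timing$pi, numeric(1))
  hits[[which.min(pis)]]
}

#' Compare molecular times between two tumor groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test; exact for small
#' untied samples, normal approximation with tie correction otherwise
#' (the default behaviour of [stats::wilcox.test()]).
#'
#' @param times_a,times_b numeric vectors of molecular times.
#' @return list with `p_value`, `statistic`, `method`.
#' @export
compare_timing_groups <- function(times_a, times_b) {
  if (!length(times_a) || !length(times_b))
    stop("both groups must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(times_a, times_b,
                                            alternative = "two.sided"))
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       method = ht$method)
}

#' Correlate molecular times with age at diagnosis
#'
#' Pearson correlation with the usual t-distributed p-value.
#'
#' @param times,ages equal-length numeric vectors, n >= 3.
#' @return list with `r`, `p_value`, `n`, and a `flag` when undefined
#'   (zero variance).
#' @export
correlate_age <- function(times, ages) {
  if (length(times) != length(ages)) stop("unequal vector lengths")
  if (length(times) < 3) stop("need at least 3 pairs")
  if (stats::sd(times) == 0 || stats::sd(ages) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(times),
                flag = "zero_variance"))
  ht <- stats::cor.test(times, ages, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(times),
       flag = NULL)
}

#' Chronological bound on the age at gain from clock-like mutations
#'
#' Clock-like (SBS1/SBS5) mutations accumulate roughly linearly with age,
#' so the clock-based molecular time of the gain multiplied by the age at
#' diagnosis bounds the patient age at which the gain occurred. This is a
#' model-based extrapolation under the linear-clock assumption, not a
#' measurement, and is labelled as such.
#'
#' @param n_pre_clock,n_post_clock clock-mutation counts from
#'   [count_pre_post()] with the clock filter on.
#' @param major,minor copy-number state of the gain.
#' @param age_at_dx age at diagnosis in years (> 0).
#' @return list with `age_at_gain_years`, `pi_clock`, `assumption`; or
#'   `NULL` (with a message) when there are no clock mutations.
#' @export
chronological_bound <- function(n_pre_clock, n_post_clock, major, minor,
                                age_at_dx) {
  if (age_at_dx <= 0) stop("age_at_dx must be > 0")
  if (n_pre_clock + n_post_clock == 0) {
    message("no clock-like mutations; chronological bound undefined")
    return(NULL)
  }
  mt <- molecular_time(n_pre_clock, n_post_clock, major, minor,
                       min_count = 0)
  list(age_at_gain_years = mt$pi * age_at_dx, pi_clock = mt$pi,
       assumption = "linear-clock")
}
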