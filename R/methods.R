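#' @export
print.tumor_timing <- function(x, ...) {
  cat("LOH timing fit:", x$sample_id, "\n")
  cat(sprintf("  %d SNVs, burden %.3f /Mb, purity %.2f\n", x$n_snvs,
              x$burden, x$profile$purity))
  cat("  LOH state: ", x$loh$state,
      if (!is.na(x$loh$extent)) paste0(" (", x$loh$extent, ")"), "\n",
      sep = "")
  if (!is.null(x$timing))
    cat(sprintf("  molecular time of gain: pi = %.3f [%.3f, %.3f]\n",
                x$timing$pi, x$timing$ci_low, x$timing$ci_high))
  invisible(x)
}

#' @export
summary.tumor_timing <- function(object, ...) {
  structure(list(fit = object), class = "summary.tumor_timing")
}

#' @export
print.summary.tumor_timing <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$allele))
    cat(sprintf("  mutant allele on %s allele (expected VAF %.3f vs %.3f); VAF-shift p = %.3g\n",
                f$allele$call, f$allele$expected_vaf["MAJOR"],
                f$allele$expected_vaf["MINOR"], f$vaf_shift_p))
  cat("  exposures: ",
      paste(sprintf("%s=%.3f", names(f$signature_fit$exposures),
                    f$signature_fit$exposures), collapse = ", "), "\n")
  if (!is.null(f$timing))
    cat(sprintf("  pre/post-gain: %d / %d (all), %d / %d (clock-like)\n",
                f$timing$n_pre, f$timing$n_post, f$clock_counts$n_pre,
                f$clock_counts$n_post))
  if (!is.null(f$chronological))
    cat(sprintf("  clock-based bound: gain at ~%.1f years (pi_clock %.3f x age %.0f; linear-clock assumption)\n",
                f$chronological$age_at_gain_years,
                f$chronological$pi_clock, f$profile$age_at_dx))
  if (length(f$flags)) cat("  flags:", paste(f$flags, collapse = ", "),
                           "\n")
  invisible(x)
}

#' @export
coef.tumor_timing <- function(object, ...) {
  c(pi = if (!is.null(object$timing)) object$timing$pi else NA_real_)
}

#' @export
confint.tumor_timing <- function(object, parm = "pi", level = 0.95,
                                 ...) {
  if (is.null(object$timing))
    return(matrix(NA_real_, 1, 2,
                  dimnames = list("pi", c("2.5 %", "97.5 %"))))
  matrix(c(object$timing$ci_low, object$timing$ci_high), 1, 2,
         dimnames = list("pi", c("2.5 %", "97.5 %")))
}

#' Plot multiplicity along the locus chromosome
#'
#' Draws the continuous mutation copy number of each SNV on the locus
#' chromosome (clock-like mutations highlighted), the segment
#' major/minor copy-number bars, and the locus position — the standard
#' per-tumor view of a timed gain.
#'
#' @param x a `tumor_timing` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tumor_timing <- function(x, ...) {
  chrom <- x$params$locus$chrom
  on_chr <- x$snvs$chrom == chrom
  pos <- x$snvs$pos[on_chr] / 1e6
  mc <- x$multiplicity$m_continuous[on_chr]
  clk <- x$clock[on_chr]
  graphics::plot(pos, mc, pch = 16, cex = 0.5,
                 col = ifelse(clk, "#D55E00", "grey50"),
                 xlab = paste0("chr", chrom, " position (Mb)"),
                 ylab = "mutation copy number",
                 ylim = c(0, max(2.5, mc, na.rm = TRUE)), ...)
  segs <- x$segments[x$segments$chrom == chrom, , drop = FALSE]
  graphics::segments(segs$start / 1e6, segs$major, segs$end / 1e6,
                     segs$major, col = "red", lwd = 2)
  graphics::segments(segs$start / 1e6, segs$minor, segs$end / 1e6,
                     segs$minor, col = "darkgreen", lwd = 2)
  graphics::abline(v = c(x$params$locus$start, x$params$locus$end) / 1e6,
                   lty = 3)
  if (!is.null(x$timing))
    graphics::mtext(sprintf("pi = %.2f [%.2f, %.2f]  (%s)", x$timing$pi,
                            x$timing$ci_low, x$timing$ci_high,
                            x$loh$state), side = 3, line = 0.2,
                    cex = 0.9)
  invisible(x)
}

#' Simulate a tumor from a fitted model
#'
#' Generates synthetic tumors at the fitted purity, exposures and
#' molecular time — useful for parametric-bootstrap style checks of the
#' whole pipeline.
#'
#' @param object a `tumor_timing` fit.
#' @param nsim number of tumors.
#' @param seed RNG seed.
#' @param ... overrides passed to [sim_params()].
#' @export
simulate.tumor_timing <- function(object, nsim = 1, seed = 1, ...) {
  segs <- object$segments
  segs$pi_true <- NA_real_
  if (!is.null(object$timing)) {
    first_seg <- object$timed_segments[[1]]$segment
    hit <- segs$chrom == first_seg$chrom & segs$start == first_seg$start
    segs$pi_true[hit] <- object$timing$pi
  }
  p <- sim_params(purity = object$profile$purity,
                  n_mutations = object$n_snvs,
                  exposures = object$signature_fit$exposures,
                  segments = cbind(segs[, c("chrom", "start", "end",
                                            "major", "minor",
                                            "clonal_fraction")],
                                   pi_true = segs$pi_true),
                  ...)
  sims <- lapply(seq_len(nsim), function(i)
    simulate_tumor(p, seed = seed + i - 1))
  if (nsim == 1) sims[[1]] else sims
}
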