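#' Classify the LOH state of a locus from allele-specific copy number
#'
#' Maps the (major, minor) copy-number state of the clonal segment
#' containing the locus midpoint to an LOH state:
#'
#' * `(0,0)` homozygous deletion -> `HOM_DEL`
#' * `(1,0)` loss without gain -> `LOH_LOSS`
#' * `(2,0)` copy-neutral LOH -> `CN_LOH`
#' * `(>=3,0)` copy-gain LOH -> `CG_LOH`
#' * `(>=2,>=1)` gain without LOH -> `GAIN_NO_LOH`
#' * `(1,1)` diploid heterozygous -> `NO_LOH`
#'
#' Extent is `WHOLE_CHROMOSOME` when the run of abutting segments sharing
#' the locus state spans at least `whole_frac` of the chromosome,
#' `SEGMENTAL` otherwise, and `NA` for `NO_LOH`.
#'
#' @param segments internal segment data.frame (see [load_segments()]).
#' @param locus list with `chrom`, `start`, `end` (1-based inclusive, as
#'   in a config/BED-derived interval).
#' @param chrom_length chromosome length in bp.
#' @param whole_frac fraction of the chromosome the state must span to
#'   count as whole-chromosome (default 0.95).
#' @param clonal_min clonal fraction below which the call is flagged
#'   low-confidence (default 0.5).
#' @return object of class `loh_call`: list with `state`, `extent`,
#'   `major`, `minor`, `mutant_copies`, `wildtype_copies`,
#'   `span_fraction`, `clonal_fraction`, `low_confidence`, `locus`.
#' @export
classify_locus <- function(segments, locus, chrom_length,
                           whole_frac = 0.95, clonal_min = 0.5) {
  mid <- floor(((locus$start - 1) + locus$end) / 2)
  on_chr <- segments[segments$chrom == locus$chrom, , drop = FALSE]
  hit <- which(on_chr$start <= mid & mid < on_chr$end)
  if (!length(hit))
    stop("no copy-number segment overlaps ", locus$chrom, ":", mid + 1)
  seg <- on_chr[hit[1], ]
  state <- loh_state(seg$major, seg$minor)

  # extend the run of abutting same-state segments around the hit
  i0 <- i1 <- hit[1]
  same <- on_chr$major == seg$major & on_chr$minor == seg$minor
  while (i0 > 1L && same[i0 - 1L] && on_chr$end[i0 - 1L] == on_chr$start[i0])
    i0 <- i0 - 1L
  while (i1 < nrow(on_chr) && same[i1 + 1L] &&
         on_chr$start[i1 + 1L] == on_chr$end[i1])
    i1 <- i1 + 1L
  span <- on_chr$end[i1] - on_chr$start[i0]
  span_frac <- span / chrom_length
  extent <- if (state == "NO_LOH") NA_character_
            else if (span_frac >= whole_frac) "WHOLE_CHROMOSOME"
            else "SEGMENTAL"

  structure(list(
    locus = locus, state = state, extent = extent,
    major = seg$major, minor = seg$minor,
    mutant_copies = seg$major, wildtype_copies = seg$minor,
    span_fraction = span_frac, clonal_fraction = seg$clonal_fraction,
    low_confidence = seg$clonal_fraction < clonal_min
  ), class = "loh_call")
}

#' LOH state of a (major, minor) copy-number pair
#'
#' Total function on all states with `0 <= minor <= major`; vectorized.
#'
#' @param major,minor allele-specific copy numbers.
#' @return character vector of states (see [classify_locus()]).
#' @export
loh_state <- function(major, minor) {
  if (any(minor > major | minor < 0)) stop("need 0 <= minor <= major")
  ifelse(minor == 0,
         ifelse(major == 0, "HOM_DEL",
                ifelse(major == 1, "LOH_LOSS",
                       ifelse(major == 2, "CN_LOH", "CG_LOH"))),
         ifelse(major >= 2, "GAIN_NO_LOH", "NO_LOH"))
}

#' @export
print.loh_call <- function(x, ...) {
  cat("LOH call at ", x$locus$chrom, ":", x$locus$start, "-",
      x$locus$end, "\n", sep = "")
  cat("  state: ", x$state,
      if (!is.na(x$extent)) paste0(" (", x$extent, ")"), "\n", sep = "")
  cat(sprintf("  copy number: major %d / minor %d; state spans %.1f%% of chromosome\n",
              x$major, x$minor, 100 * x$span_fraction))
  if (isTRUE(x$low_confidence))
    cat("  [low confidence: clonal fraction ", x$clonal_fraction, "]\n",
        sep = "")
  invisible(x)
}

#' Assign the gained allele (mutant vs wildtype) from the tumor VAF
#'
#' A heterozygous germline variant sits on one of the two parental
#' copies. Under "mutant on the major allele" the tumor carries `major`
#' mutant copies; under "mutant on minor", `minor` copies. Contaminating
#' normal cells contribute one mutant copy each. The hypothesis with the
#' higher binomial likelihood of the observed tumor alt count wins.
#'
#' @param germline_vaf germline VAF of the variant (heterozygous,
#'   near 0.5; used for a sanity warning only).
#' @param tumor_alt,tumor_depth observed tumor allele counts at the
#'   germline variant.
#' @param purity tumor purity.
#' @param major,minor allele-specific copy number at the locus.
#' @return list with `call` (`"MAJOR"`, `"MINOR"`, or `"TIE"`), `tie`
#'   flag, `expected_vaf` (named vector for the two hypotheses) and
#'   `loglik`.
#' @export
assign_mutant_allele <- function(germline_vaf, tumor_alt, tumor_depth,
                                 purity, major, minor) {
  if (!is.na(germline_vaf) && abs(germline_vaf - 0.5) > 0.2)
    warning("germline VAF ", germline_vaf,
            " far from 0.5; variant may not be a clean heterozygote")
  cn_tot <- major + minor
  ev <- c(MAJOR = expected_vaf(major, purity, cn_tot,
                               normal_mutant_copies = 1),
          MINOR = expected_vaf(minor, purity, cn_tot,
                               normal_mutant_copies = 1))
  ll <- stats::dbinom(tumor_alt, tumor_depth, ev, log = TRUE)
  names(ll) <- names(ev)
  tie <- major == minor || abs(ll["MAJOR"] - ll["MINOR"]) < 1e-9
  call <- if (tie) "TIE" else names(which.max(ll))
  list(call = call, tie = tie, expected_vaf = ev, loglik = ll)
}

#' Test for a tumor-vs-germline VAF shift
#'
#' Two-sided Fisher's exact test on the 2x2 table of alt/ref read counts
#' in germline and tumor; a significant shift with higher tumor VAF
#' supports gain of the mutant allele.
#'
#' @param germ_alt,germ_depth germline alt and total read counts.
#' @param tum_alt,tum_depth tumor alt and total read counts.
#' @return two-sided p-value.
#' @export
vaf_shift_test <- function(germ_alt, germ_depth, tum_alt, tum_depth) {
  if (germ_depth <= 0 || tum_depth <= 0)
    stop("zero-depth sample in VAF shift test")
  tab <- matrix(c(germ_alt, germ_depth - germ_alt,
                  tum_alt, tum_depth - tum_alt),
                nrow = 2, byrow = TRUE)
  stats::fisher.test(tab)$p.value
}
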