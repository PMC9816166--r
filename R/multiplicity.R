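#' Expected variant allele fraction of a mutation
#'
#' Two-population accounting: a mutation present on `m` of the tumor's
#' `cn_tot` copies, in a sample of purity `purity`, with
#' `normal_mutant_copies` mutant copies in contaminating normal cells
#' (0 for somatic mutations, 1 for a heterozygous germline variant), has
#' expected VAF
#' \deqn{(m\rho + m_N(1-\rho)) / (\rho\,CN_{tot} + 2(1-\rho)).}
#' The value is capped at `1 - error_cap` so that a fully mutant locus
#' retains nonzero likelihood under rare reference-supporting error reads.
#'
#' @param m mutation multiplicity (copies carrying the mutation).
#' @param purity tumor purity in (0, 1].
#' @param cn_tot total tumor copy number at the locus (>= 1).
#' @param normal_mutant_copies mutant copies per normal cell (default 0).
#' @param error_cap sequencing-error allowance (default 0.01).
#' @return expected VAF in (0, `1 - error_cap`].
#' @export
expected_vaf <- function(m, purity, cn_tot, normal_mutant_copies = 0,
                         error_cap = 0.01) {
  if (any(cn_tot == 0)) stop("cn_tot must be >= 1")
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  if (any(m < 0)) stop("m must be >= 0")
  v <- (m * purity + normal_mutant_copies * (1 - purity)) /
    (purity * cn_tot + 2 * (1 - purity))
  pmin(v, 1 - error_cap)
}

#' Continuous mutation copy number from observed allele counts
#'
#' Inverts the expected-VAF relation for a clonal somatic mutation:
#' `VAF * (purity * cn_tot + 2 * (1 - purity)) / purity`.
#'
#' @param tumor_alt,tumor_depth observed alt and total read counts.
#' @param purity tumor purity in (0, 1].
#' @param cn_tot total tumor copy number at the locus.
#' @return continuous multiplicity estimate (vectorized).
#' @export
mutation_copy_number <- function(tumor_alt, tumor_depth, purity, cn_tot) {
  if (any(purity <= 0)) stop("purity must be > 0")
  if (any(tumor_depth <= 0)) stop("tumor_depth must be > 0")
  vaf <- tumor_alt / tumor_depth
  vaf * (purity * cn_tot + 2 * (1 - purity)) / purity
}

#' Assign integer multiplicity, CCF and clonality to mutations
#'
#' For each mutation, candidate hypotheses are clonal multiplicities
#' `m = 1..max_m` (cancer cell fraction 1) plus one subclonal branch
#' (`m = 1` at the plug-in CCF estimate, constrained to
#' `subclonal_ccf_range`). Binomial likelihoods of the observed alt count
#' at the hypothesis' expected VAF are combined under a flat prior; the
#' posterior over integer multiplicities (subclonal mass folded into
#' `m = 1`) is returned, with `m` its argmax.
#'
#' CCF is the continuous multiplicity divided by `m`, clipped to
#' `[0, 1.2]`. A mutation is called clonal when its CCF reaches
#' `clonal_threshold` or when the CCF confidence interval (a Jeffreys
#' binomial interval on VAF at level `ccf_conf`, propagated to CCF)
#' covers 1.
#'
#' @param tumor_alt,tumor_depth observed counts (vectorized).
#' @param purity tumor purity.
#' @param cn_tot total copy number of the containing segment.
#' @param max_m maximum candidate multiplicity (the segment's major copy
#'   number).
#' @param clonal_threshold CCF above which a mutation is clonal
#'   (default 0.8).
#' @param subclonal_ccf_range allowed CCF range of the subclonal branch
#'   (default `c(0.05, 0.95)`).
#' @param ccf_conf confidence level of the CCF interval used in the
#'   clonality rule (default 0.99).
#' @return data.frame with columns `m`, `m_continuous`, `ccf`, `clonal`,
#'   `p_subclonal`, and attribute `"posterior"` (matrix, one row per
#'   mutation, columns `m1..m<max_m>`, each row summing to 1).
#' @export
assign_multiplicity <- function(tumor_alt, tumor_depth, purity, cn_tot,
                                max_m, clonal_threshold = 0.8,
                                subclonal_ccf_range = c(0.05, 0.95),
                                ccf_conf = 0.99) {
  if (max_m < 1) stop("max_m must be >= 1")
  if (any(tumor_depth <= 0)) stop("tumor_depth must be > 0")
  n <- length(tumor_alt)
  m_cont <- mutation_copy_number(tumor_alt, tumor_depth, purity, cn_tot)

  # likelihood per clonal multiplicity hypothesis
  lik <- vapply(seq_len(max_m), function(m) {
    stats::dbinom(tumor_alt, tumor_depth,
                  expected_vaf(m, purity, cn_tot))
  }, numeric(n))
  lik <- matrix(lik, nrow = n)
  # subclonal branch: m = 1 at the plug-in CCF
  ccf_sub <- pmin(pmax(m_cont, subclonal_ccf_range[1]),
                  subclonal_ccf_range[2])
  vaf_sub <- expected_vaf(1, purity, cn_tot) * ccf_sub
  lik_sub <- stats::dbinom(tumor_alt, tumor_depth, vaf_sub)

  all_lik <- cbind(lik, lik_sub)
  tot <- rowSums(all_lik)
  tot[tot == 0] <- NA_real_
  post_all <- all_lik / tot
  p_sub <- post_all[, max_m + 1L]
  post_m <- post_all[, seq_len(max_m), drop = FALSE]
  post_m[, 1L] <- post_m[, 1L] + p_sub
  colnames(post_m) <- paste0("m", seq_len(max_m))

  m <- max.col(post_m, ties.method = "first")
  ccf <- pmin(pmax(m_cont / m, 0), 1.2)

  # Jeffreys upper bound on VAF, propagated to CCF
  alpha <- (1 - ccf_conf) / 2
  vaf_hi <- stats::qbeta(1 - alpha, tumor_alt + 0.5,
                         tumor_depth - tumor_alt + 0.5)
  ccf_hi <- vaf_hi * (purity * cn_tot + 2 * (1 - purity)) / (purity * m)
  clonal <- ccf >= clonal_threshold | ccf_hi >= 1

  out <- data.frame(m = m, m_continuous = m_cont, ccf = ccf,
                    clonal = clonal, p_subclonal = p_sub)
  attr(out, "posterior") <- post_m
  out
}
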