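#' Default parameters for the tumor simulator
#'
#' The defaults describe a typical high-purity pediatric tumor genome as
#' the package's analyses assume it: purity 0.7, 60x mean coverage, 2000
#' clonal-lineage somatic SNVs, a whole-chromosome-17 copy-neutral LOH
#' (2+0) segment gained at molecular time 0.3 plus a diploid background
#' chromosome, exposures over the synthetic three-signature catalog, and
#' a 15% subclonal fraction at cancer cell fraction 0.4.
#'
#' @param ... overrides for any default (names as in the returned list).
#' @return parameter list for [simulate_tumor()].
#' @export
sim_params <- function(...) {
  p <- list(
    sample_id = "SIM1",
    purity = 0.7,
    depth = 60,
    n_mutations = 2000,
    segments = data.frame(
      chrom = c("17", "1"),
      start = c(0, 0),
      end = c(81195210, 249250621),
      major = c(2L, 1L),
      minor = c(0L, 1L),
      clonal_fraction = c(1, 1),
      pi_true = c(0.3, NA),
      stringsAsFactors = FALSE),
    exposures = c(SBS1 = 0.2, SBS5 = 0.5, APOBEC = 0.3),
    catalog = NULL,           # NULL -> synthetic_catalog()
    subclonal_frac = 0.15,
    subclonal_ccf = 0.4,
    sex = "XX",
    age_at_dx = 10,
    germline_tp53 = list(chrom = "17", pos = 7577120, ref = "C",
                         alt = "T", germline_vaf = 0.5)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(p))
  if (length(bad)) stop("unknown simulator parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(overrides)] <- overrides
  p
}

#' Pre/post-gain lineage branches of a copy-number state
#'
#' For a segment with allele-specific state (major, minor) gained at
#' molecular time `pi`, returns the mutation lineage branches with their
#' relative mutational opportunity (copies x time at constant per-copy
#' rate) and resulting multiplicity. Supported gained states are (2,0),
#' (2,1) and (2,2); ungained states place all mutations at multiplicity 1
#' with opportunity equal to the total copy number.
#'
#' @param major,minor copy-number state.
#' @param pi molecular time of the gain (ignored for ungained states).
#' @return data.frame with columns `m` and `weight`.
#' @export
lineage_branches <- function(major, minor, pi = NA) {
  state <- paste0(major, "+", minor)
  if (major >= 2 && !is.na(pi)) {
    switch(state,
      "2+0" = data.frame(m = c(2L, 1L), weight = c(pi, 2 * (1 - pi))),
      "2+1" = data.frame(m = c(2L, 1L),
                         weight = c(pi, pi + 3 * (1 - pi))),
      "2+2" = data.frame(m = c(2L, 1L),
                         weight = c(2 * pi, 4 * (1 - pi))),
      stop("unsupported gained state ", state, " in simulator"))
  } else {
    data.frame(m = 1L, weight = major + minor)
  }
}

#' Simulate a tumor with known ground truth
#'
#' Generates somatic SNVs whose multiplicities follow the lineage
#' structure implied by each gained segment's planted molecular time,
#' trinucleotide contexts drawn from a signature mixture, Poisson read
#' depths, and binomial alt counts at the purity- and copy-number-scaled
#' expected VAF. Deterministic for a fixed seed. Optionally writes the
#' observed data (VCF + segment TSV) and the truth (JSON) to `dir`.
#'
#' @param params parameter list from [sim_params()].
#' @param seed RNG seed.
#' @param dir optional output directory; when given, writes
#'   `snvs.vcf.gz`, `segments.tsv`, `truth.json`, `profile.yaml`.
#' @return list with `snvs` (observed SNV table), `segments` (internal
#'   coordinates), `profile` (sample metadata incl. the germline TP53
#'   variant with simulated read counts), and `truth` (per-mutation
#'   multiplicity/clonality/signature, per-segment `pi_true`, exposures).
#' @export
simulate_tumor <- function(params = sim_params(), seed = 1, dir = NULL) {
  p <- params
  if (is.null(p$catalog)) p$catalog <- synthetic_catalog()
  catalog <- signature_catalog(p$catalog)
  e <- p$exposures
  if (any(e < 0) || abs(sum(e) - 1) > 1e-9)
    stop("invalid exposure vector: must be non-negative and sum to 1")
  if (!all(names(e) %in% colnames(catalog)))
    stop("exposure names must match catalog signatures")
  set.seed(seed)

  segs <- cn_segments(p$segments$chrom, p$segments$start, p$segments$end,
                      p$segments$major, p$segments$minor,
                      p$segments$clonal_fraction)
  # cn_segments sorts; carry pi_true along by matching keys
  key_in <- paste(p$segments$chrom, p$segments$start)
  segs$pi_true <- p$segments$pi_true[match(paste(segs$chrom, segs$start),
                                           key_in)]

  n <- p$n_mutations
  # mutational opportunity per segment: length x lineage weight
  branches <- lapply(seq_len(nrow(segs)), function(i)
    lineage_branches(segs$major[i], segs$minor[i], segs$pi_true[i]))
  seg_w <- vapply(seq_len(nrow(segs)), function(i)
    (segs$end[i] - segs$start[i]) * sum(branches[[i]]$weight), numeric(1))
  seg_of <- sample.int(nrow(segs), n, replace = TRUE,
                       prob = seg_w / sum(seg_w))

  # multiplicity via lineage branch within segment
  m <- integer(n)
  for (i in seq_len(nrow(segs))) {
    idx <- which(seg_of == i)
    if (!length(idx)) next
    br <- branches[[i]]
    m[idx] <- br$m[sample.int(nrow(br), length(idx), replace = TRUE,
                              prob = br$weight / sum(br$weight))]
  }

  # subclonal mutations ride a single later clone at m = 1
  clonal <- stats::runif(n) >= p$subclonal_frac
  m[!clonal] <- 1L
  ccf <- ifelse(clonal, 1, p$subclonal_ccf)

  # positions: uniform within segment, unique per chromosome
  pos <- segs$start[seg_of] +
    vapply(seg_of, function(i)
      sample.int(segs$end[i] - segs$start[i], 1), integer(1))
  while (anyDuplicated(paste(segs$chrom[seg_of], pos))) {
    dup <- which(duplicated(paste(segs$chrom[seg_of], pos)))
    pos[dup] <- segs$start[seg_of[dup]] +
      vapply(seg_of[dup], function(i)
        sample.int(segs$end[i] - segs$start[i], 1), integer(1))
  }

  # contexts from the signature mixture
  sig_of <- sample(names(e), n, replace = TRUE, prob = e)
  channel <- character(n)
  for (s in names(e)) {
    idx <- which(sig_of == s)
    if (length(idx))
      channel[idx] <- sample(sbs_channels(), length(idx), replace = TRUE,
                             prob = catalog[, s])
  }
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  context <- paste0(substr(channel, 1, 1), ref, substr(channel, 7, 7))

  cn_tot <- segs$major[seg_of] + segs$minor[seg_of]
  vaf <- expected_vaf(m, p$purity, cn_tot) * ccf
  tumor_depth <- pmax(1L, stats::rpois(n, p$depth))
  tumor_alt <- stats::rbinom(n, tumor_depth, vaf)
  normal_depth <- pmax(1L, stats::rpois(n, p$depth))

  snvs <- snv_records(segs$chrom[seg_of], pos, ref, alt, tumor_alt,
                      tumor_depth, integer(n), normal_depth, context)

  # germline TP53 variant read counts in tumor and normal
  g <- p$germline_tp53
  g_seg <- which(segs$chrom == g$chrom & segs$start <= g$pos - 1 &
                   g$pos - 1 < segs$end)
  gt_cn <- if (length(g_seg)) c(segs$major[g_seg[1]], segs$minor[g_seg[1]])
           else c(1L, 1L)
  g$tumor_depth <- max(1L, stats::rpois(1, p$depth))
  g$tumor_alt <- stats::rbinom(1, g$tumor_depth,
                               expected_vaf(gt_cn[1], p$purity,
                                            sum(gt_cn),
                                            normal_mutant_copies = 1))
  g$germ_depth <- max(1L, stats::rpois(1, p$depth))
  g$germ_alt <- stats::rbinom(1, g$germ_depth, g$germline_vaf)

  profile <- sample_profile(p$sample_id, p$purity, sex = p$sex,
                            age_at_dx = p$age_at_dx, germline_tp53 = g)

  truth <- list(
    purity = p$purity, depth = p$depth, exposures = as.list(e),
    segments = data.frame(chrom = segs$chrom, start = segs$start,
                          end = segs$end, major = segs$major,
                          minor = segs$minor, pi_true = segs$pi_true,
                          stringsAsFactors = FALSE),
    mutations = data.frame(chrom = segs$chrom[seg_of], pos = pos,
                           segment = seg_of, m = m, clonal = clonal,
                           ccf = ccf, signature = sig_of,
                           channel = channel, stringsAsFactors = FALSE))

  sim <- list(snvs = snvs, segments = segs, profile = profile,
              truth = truth)
  if (!is.null(dir)) write_simulation(sim, dir)
  sim
}

#' Construct a sample profile
#'
#' @param sample_id sample identifier.
#' @param purity tumor purity in (0, 1].
#' @param sex `"XX"` or `"XY"`.
#' @param age_at_dx age at diagnosis in years (optional).
#' @param germline_tp53 list describing the germline TP53 variant
#'   (`chrom`, `pos`, `ref`, `alt`, `germline_vaf`, and read counts when
#'   available).
#' @return list of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, purity, sex = NA,
                           age_at_dx = NA, germline_tp53 = NULL) {
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  structure(list(sample_id = sample_id, purity = purity, sex = sex,
                 age_at_dx = age_at_dx, germline_tp53 = germline_tp53),
            class = "sample_profile")
}

#' Write a simulated tumor to disk
#'
#' Emits the observed data in the dialects the pipeline reads
#' (`snvs.vcf.gz`, `segments.tsv` 1-based inclusive, `profile.yaml`) plus
#' the ground truth (`truth.json`).
#'
#' @param sim result of [simulate_tumor()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_snvs_vcf(sim$snvs, file.path(dir, "snvs.vcf"))
  write_segments(sim$segments[, c("chrom", "start", "end", "major",
                                  "minor", "clonal_fraction")],
                 file.path(dir, "segments.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  prof <- sim$profile
  yaml::write_yaml(list(sample_id = prof$sample_id,
                        purity = prof$purity, sex = prof$sex,
                        age_at_dx = prof$age_at_dx,
                        germline_tp53 = prof$germline_tp53),
                   file.path(dir, "profile.yaml"))
  invisible(dir)
}
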