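#' Map SNVs to their containing copy-number segment
#'
#' @param snvs SNV data.frame.
#' @param segments internal segment data.frame.
#' @return integer vector of row indices into `segments` (NA when a
#'   mutation falls outside every segment).
#' @export
map_to_segments <- function(snvs, segments) {
  idx <- rep(NA_integer_, nrow(snvs))
  for (i in seq_len(nrow(segments))) {
    hit <- snvs$chrom == segments$chrom[i] &
      snvs$pos - 1 >= segments$start[i] & snvs$pos - 1 < segments$end[i]
    idx[hit] <- i
  }
  idx
}

#' Fit the LOH-timing model to one tumor
#'
#' The central fitting function: composes the mutation-burden summary,
#' LOH state classification at the locus, mutant-allele assignment and
#' VAF-shift support, signature refitting with per-mutation posteriors,
#' purity-aware multiplicity assignment, and molecular-time estimation
#' (all mutations and clock-like mutations separately) with a bootstrap
#' confidence interval, for the first gain overlapping the locus.
#'
#' @param snvs filtered somatic SNV table (see [load_snvs()]).
#' @param segments allele-specific copy-number segments (see
#'   [load_segments()]).
#' @param profile [sample_profile()] with purity and, optionally, the
#'   germline variant read counts and age at diagnosis.
#' @param catalog signature catalog (default [synthetic_catalog()]).
#' @param locus locus of interest, 1-based inclusive (default
#'   [tp53_locus()]).
#' @param chrom_length length of the locus chromosome in bp (default
#'   hg19 chr17).
#' @param B bootstrap replicates (default 200).
#' @param seed RNG seed governing the bootstrap (default 1).
#' @param min_count minimum informative mutations for a confident time
#'   (default 20).
#' @param clock_signatures signatures counted as clock-like.
#' @return object of class `tumor_timing`.
#' @export
time_tumor <- function(snvs, segments, profile,
                       catalog = synthetic_catalog(),
                       locus = tp53_locus(), chrom_length = 81195210,
                       B = 200, seed = 1, min_count = 20,
                       clock_signatures = c("SBS1", "SBS5")) {
  if (is.null(profile$purity)) stop("profile is missing 'purity'")
  set.seed(seed)
  purity <- profile$purity

  burden <- mutation_burden(nrow(snvs))
  loh <- classify_locus(segments, locus, chrom_length)

  # mutant-allele assignment + VAF-shift support from the germline variant
  allele <- NULL
  vaf_shift_p <- NA_real_
  g <- profile$germline_tp53
  if (!is.null(g) && !is.null(g$tumor_alt)) {
    allele <- assign_mutant_allele(g$germline_vaf, g$tumor_alt,
                                   g$tumor_depth, purity, loh$major,
                                   loh$minor)
    if (!is.null(g$germ_alt))
      vaf_shift_p <- vaf_shift_test(g$germ_alt, g$germ_depth,
                                    g$tumor_alt, g$tumor_depth)
  }

  # signature refit and per-mutation clock posteriors
  counts <- count_contexts(snvs)
  sig_fit <- fit_exposures(counts, catalog)
  channels <- sbs_channel(snvs$ref, snvs$alt, snvs$context)
  posterior <- mutation_posterior(channels, sig_fit$exposures,
                                  sig_fit$catalog)
  clock <- is_clock_mutation(snvs, posterior, clock_signatures)

  # multiplicity per containing segment
  seg_of <- map_to_segments(snvs, segments)
  calls <- data.frame(m = rep(NA_integer_, nrow(snvs)),
                      m_continuous = NA_real_, ccf = NA_real_,
                      clonal = NA, p_subclonal = NA_real_)
  for (i in unique(seg_of[!is.na(seg_of)])) {
    idx <- which(seg_of == i)
    cn_tot <- segments$major[i] + segments$minor[i]
    if (cn_tot == 0 || segments$major[i] == 0) next
    calls[idx, ] <- assign_multiplicity(snvs$tumor_alt[idx],
                                        snvs$tumor_depth[idx], purity,
                                        cn_tot, segments$major[i])
  }

  # time every supported gained segment
  timed <- list()
  flags <- character(0)
  for (i in which(segments$major >= 2)) {
    if (segments$major[i] > 2) {
      flags <- c(flags, paste0("gain_", segments$chrom[i], ":",
                               segments$start[i] + 1,
                               "_excluded_major>2"))
      next
    }
    idx <- which(seg_of == i & !is.na(calls$m))
    if (!length(idx)) next
    timed[[length(timed) + 1L]] <- list(
      segment = segments[i, ],
      timing = time_gain(calls[idx, , drop = FALSE], segments$major[i],
                         segments$minor[i], B = B, min_count = min_count,
                         tumor_alt = snvs$tumor_alt[idx],
                         tumor_depth = snvs$tumor_depth[idx],
                         purity = purity),
      timing_clock = time_gain(calls[idx, , drop = FALSE],
                               segments$major[i], segments$minor[i],
                               B = B, clock = clock[idx],
                               min_count = min_count,
                               tumor_alt = snvs$tumor_alt[idx],
                               tumor_depth = snvs$tumor_depth[idx],
                               purity = purity),
      snv_idx = idx)
  }
  first <- first_gain_time_over_locus(timed, locus)

  chrono <- NULL
  clock_counts <- list(n_pre = NA_integer_, n_post = NA_integer_)
  if (!is.null(first)) {
    clock_counts <- list(n_pre = first$timing_clock$n_pre,
                         n_post = first$timing_clock$n_post)
    if (!is.na(profile$age_at_dx %||% NA))
      chrono <- chronological_bound(first$timing_clock$n_pre,
                                    first$timing_clock$n_post,
                                    first$segment$major,
                                    first$segment$minor,
                                    profile$age_at_dx)
  } else {
    flags <- c(flags, "no_timed_gain_over_locus")
  }

  structure(list(
    sample_id = profile$sample_id, profile = profile,
    n_snvs = nrow(snvs), burden = burden, loh = loh, allele = allele,
    vaf_shift_p = vaf_shift_p, signature_fit = sig_fit,
    clock_fraction = mean(clock), timing = first$timing,
    timing_clock = first$timing_clock, clock_counts = clock_counts,
    chronological = chrono, timed_segments = timed,
    multiplicity = calls, clock = clock, snvs = snvs,
    segments = segments, flags = flags,
    params = list(B = B, seed = seed, min_count = min_count,
                  locus = locus, chrom_length = chrom_length,
                  clock_signatures = clock_signatures)
  ), class = "tumor_timing")
}

#' Run the per-tumor pipeline from a configuration
#'
#' Loads inputs named in a configuration (a YAML path or an equivalent
#' list), optionally applies the somatic filter cascade, and fits
#' [time_tumor()]. Required fields: `vcf`, `segments`, `purity`,
#' `tumor_sample`, `normal_sample`. Optional: `sample_id`, `catalog`
#' (TSV path; default the synthetic catalog), `locus`
#' (`chrom`/`start`/`end`), `chrom_length`, `annotations`, `pon`,
#' `germline` (`chrom`, `pos`, `ref`, `alt`, `germline_vaf`,
#' `germ_alt`, `germ_depth`, `tumor_alt`, `tumor_depth`), `age_at_dx`,
#' `sex`, `seed`, `B`, `max_normal_alt`.
#'
#' @param config YAML file path or list.
#' @return a `tumor_timing` object (the configuration is echoed in
#'   `$config`).
#' @export
run_tumor <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (f in c("vcf", "segments", "purity", "tumor_sample",
              "normal_sample")) {
    if (is.null(cfg[[f]])) stop("config missing field '", f, "'")
  }
  snvs <- load_snvs(cfg$vcf, cfg$tumor_sample, cfg$normal_sample)
  snvs <- apply_filter_cascade(
    snvs,
    annotations = if (!is.null(cfg$annotations))
      load_annotations(cfg$annotations),
    pon_sites = if (!is.null(cfg$pon)) load_pon(cfg$pon),
    max_normal_alt = cfg$max_normal_alt %||% 1)
  filter_log <- attr(snvs, "filter_log")
  segments <- load_segments(cfg$segments)
  catalog <- if (!is.null(cfg$catalog)) read_catalog(cfg$catalog)
             else synthetic_catalog()
  profile <- sample_profile(cfg$sample_id %||% "tumor", cfg$purity,
                            sex = cfg$sex %||% NA,
                            age_at_dx = cfg$age_at_dx %||% NA,
                            germline_tp53 = cfg$germline)
  locus <- cfg$locus %||% tp53_locus()
  fit <- time_tumor(snvs, segments, profile, catalog = catalog,
                    locus = locus,
                    chrom_length = cfg$chrom_length %||% 81195210,
                    B = cfg$B %||% 200, seed = cfg$seed %||% 1)
  fit$config <- cfg
  fit$filter_log <- filter_log
  fit
}

#' Summarize a cohort of fitted tumors and compare groups
#'
#' Builds a one-row-per-tumor table, compares molecular times between
#' two labelled groups with a two-sided Wilcoxon rank-sum test, and,
#' when ages are available, correlates time with age at diagnosis
#' (Pearson).
#'
#' @param fits list of `tumor_timing` objects.
#' @param groups optional character vector of group labels, one per fit.
#' @param ages optional numeric ages; defaults to each profile's
#'   `age_at_dx`.
#' @return object of class `cohort_timing` with `table`, `comparison`,
#'   `age_correlation`.
#' @export
run_cohort <- function(fits, groups = NULL, ages = NULL) {
  ids <- vapply(fits, function(f) f$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicated sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tab <- do.call(rbind, lapply(fits, as_report_row))
  if (!is.null(groups)) tab$group <- groups
  if (is.null(ages))
    ages <- vapply(fits, function(f) as.numeric(f$profile$age_at_dx %||%
                                                  NA), numeric(1))
  tab$age_at_dx <- ages

  comparison <- NULL
  if (!is.null(groups) && length(unique(groups)) == 2) {
    gs <- unique(groups)
    comparison <- compare_timing_groups(tab$pi[groups == gs[1]],
                                        tab$pi[groups == gs[2]])
    comparison$groups <- gs
  } else if (!is.null(groups)) {
    message("group comparison needs exactly two groups; skipped")
  }
  age_cor <- NULL
  ok <- !is.na(tab$pi) & !is.na(ages)
  if (sum(ok) >= 3) age_cor <- correlate_age(tab$pi[ok], ages[ok])

  structure(list(table = tab, comparison = comparison,
                 age_correlation = age_cor), class = "cohort_timing")
}

#' @export
print.cohort_timing <- function(x, ...) {
  cat("Cohort of", nrow(x$table), "tumors\n")
  print(x$table[, intersect(c("sample_id", "group", "loh_state", "pi",
                              "ci_low", "ci_high", "age_at_dx"),
                            names(x$table))], row.names = FALSE)
  if (!is.null(x$comparison))
    cat(sprintf("Wilcoxon rank-sum (%s vs %s), two-sided: p = %.4g\n",
                x$comparison$groups[1], x$comparison$groups[2],
                x$comparison$p_value))
  if (!is.null(x$age_correlation))
    cat(sprintf("Pearson r(time, age) = %.3f, p = %.4g (n = %d)\n",
                x$age_correlation$r, x$age_correlation$p_value,
                x$age_correlation$n))
  invisible(x)
}

as_report_row <- function(f) {
  ex <- f$signature_fit$exposures
  data.frame(
    sample_id = f$sample_id, n_snvs = f$n_snvs,
    burden_per_mb = f$burden, loh_state = f$loh$state,
    loh_extent = f$loh$extent %||% NA_character_,
    major = f$loh$major, minor = f$loh$minor,
    mutant_allele = if (!is.null(f$allele)) f$allele$call
                    else NA_character_,
    vaf_shift_p = f$vaf_shift_p,
    exposure_sbs1 = unname(ex["SBS1"]), exposure_sbs5 = unname(ex["SBS5"]),
    clock_fraction = f$clock_fraction,
    n_pre = if (!is.null(f$timing)) f$timing$n_pre else NA_integer_,
    n_post = if (!is.null(f$timing)) f$timing$n_post else NA_integer_,
    n_subclonal = if (!is.null(f$timing)) f$timing$n_subclonal
                  else NA_integer_,
    n_pre_clock = f$clock_counts$n_pre,
    n_post_clock = f$clock_counts$n_post,
    pi = if (!is.null(f$timing)) f$timing$pi else NA_real_,
    ci_low = if (!is.null(f$timing)) f$timing$ci_low else NA_real_,
    ci_high = if (!is.null(f$timing)) f$timing$ci_high else NA_real_,
    pi_clock = if (!is.null(f$timing_clock)) f$timing_clock$pi
               else NA_real_,
    age_at_gain_years = if (!is.null(f$chronological))
      f$chronological$age_at_gain_years else NA_real_,
    flags = paste(f$flags, collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Write machine-readable per-tumor reports
#'
#' Emits `<prefix>.tsv` (one row per tumor) and `<prefix>.json`
#' (versioned schema with the same fields plus exposures and parameter
#' echo) for one or more fitted tumors.
#'
#' @param fits a `tumor_timing` object or list of them.
#' @param prefix output path prefix.
#' @return named character vector of the files written, invisibly.
#' @export
emit_report <- function(fits, prefix) {
  if (inherits(fits, "tumor_timing")) fits <- list(fits)
  tab <- if (length(fits)) do.call(rbind, lapply(fits, as_report_row))
         else as_report_row_empty()
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json <- paste0(prefix, ".json")
  payload <- list(
    schema_version = "1.0",
    tumors = lapply(fits, function(f) {
      row <- as.list(as_report_row(f))
      row$exposures <- as.list(f$signature_fit$exposures)
      row$params <- f$params[c("B", "seed", "min_count",
                               "chrom_length")]
      row
    }))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(tsv = tsv, json = json))
}

as_report_row_empty <- function() {
  proto <- utils::read.table(text = "", col.names = c(
    "sample_id", "n_snvs", "burden_per_mb", "loh_state", "loh_extent",
    "major", "minor", "mutant_allele", "vaf_shift_p", "exposure_sbs1",
    "exposure_sbs5", "clock_fraction", "n_pre", "n_post", "n_subclonal",
    "n_pre_clock", "n_post_clock", "pi", "ci_low", "ci_high",
    "pi_clock", "age_at_gain_years", "flags"))
  proto
}

#' Read a JSON report back
#'
#' @param path path to a `.json` report written by [emit_report()].
#' @return list with `schema_version` and `tumors`.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
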