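#' Depth and matched-normal support filter
#'
#' Keeps somatic calls with at least `min_depth` reads in both tumor and
#' normal and at most `max_normal_alt` reads supporting the variant in the
#' matched normal. Both pipeline variants in common use (normal alt reads
#' <= 1, or strictly 0) are available via `max_normal_alt`.
#'
#' @param snvs SNV data.frame (see [snv_records()]).
#' @param min_depth minimum depth required in tumor and normal (default 10).
#' @param max_normal_alt maximum variant-supporting reads tolerated in the
#'   normal (default 1).
#' @return the surviving rows of `snvs`.
#' @export
depth_normal_filter <- function(snvs, min_depth = 10, max_normal_alt = 1) {
  keep <- snvs$tumor_depth >= min_depth &
    snvs$normal_depth >= min_depth &
    snvs$normal_alt <= max_normal_alt
  snvs[keep, , drop = FALSE]
}

#' Mapping-quality filter (2-of-4 rule)
#'
#' A call is removed iff at least two of four mappability cutoffs fire:
#' fewer than `map_frac_min` of reads at the locus map uniquely; the locus
#' lies in a multi-mapping cluster seen in tumor and normal; mapping depth
#' is excessively high relative to the normal chromosome average; the site
#' lies in a low-complexity region (DUST score above `dust_max`).
#'
#' @param snvs SNV data.frame.
#' @param annotations per-site annotation data.frame (see
#'   [load_annotations()]); every SNV site must be annotated.
#' @param map_frac_min unique-mapping fraction cutoff (default 0.70).
#' @param dust_max DUST score cutoff (default 60).
#' @return surviving rows, with attribute `"removed"` logging the removed
#'   sites and which flags fired.
#' @export
mapping_filter <- function(snvs, annotations, map_frac_min = 0.70,
                           dust_max = 60) {
  key_s <- paste(snvs$chrom, snvs$pos)
  key_a <- paste(annotations$chrom, annotations$pos)
  idx <- match(key_s, key_a)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop("no filter annotation for site ", snvs$chrom[miss], ":",
         snvs$pos[miss])
  }
  a <- annotations[idx, , drop = FALSE]
  fired <- cbind(nonunique = a$nonunique_map_frac < map_frac_min,
                 multimap = a$multimap_cluster,
                 excessive_depth = a$excessive_depth,
                 dust = a$dust_score > dust_max)
  n_fired <- rowSums(fired)
  removed <- snvs[n_fired >= 2, , drop = FALSE]
  if (nrow(removed)) {
    removed$flags <- apply(fired[n_fired >= 2, , drop = FALSE], 1,
                           function(z) paste(colnames(fired)[z],
                                             collapse = "+"))
  }
  out <- snvs[n_fired < 2, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Panel-of-normals filter
#'
#' Removes calls whose exact (chrom, pos, ref, alt) tuple appears in a
#' panel of normal, non-neoplastic samples. Matching is exact: a different
#' alternate allele at a PON position is kept.
#'
#' @param snvs SNV data.frame.
#' @param pon_sites data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return surviving rows.
#' @export
panel_of_normals_filter <- function(snvs, pon_sites) {
  if (is.null(pon_sites) || nrow(pon_sites) == 0L) return(snvs)
  key_s <- paste(snvs$chrom, snvs$pos, snvs$ref, snvs$alt)
  key_p <- paste(pon_sites$chrom, pon_sites$pos, pon_sites$ref,
                 pon_sites$alt)
  snvs[!key_s %in% key_p, , drop = FALSE]
}

#' Mutation burden per megabase
#'
#' Count of passing coding and non-coding variants divided by a 2800 Mb
#' genome size.
#'
#' @param n_passing number of QC-passing variants.
#' @param genome_mb genome size in megabases (default 2800).
#' @return mutations per Mb.
#' @export
mutation_burden <- function(n_passing, genome_mb = 2800) {
  if (n_passing < 0) stop("n_passing must be non-negative")
  n_passing / genome_mb
}

#' Flag sites with excessively high mapping depth
#'
#' The cascade's "excessive depth" cutoff compares local depth to the
#' chromosome-wide average in the matched normal; here a site fires when
#' its normal depth exceeds `k` times the per-chromosome median normal
#' depth. The flag may instead be supplied precomputed in the annotation
#' table.
#'
#' @param snvs SNV data.frame.
#' @param k fold-change over the chromosome median (default 3).
#' @return logical vector, one element per SNV.
#' @export
annotate_excessive_depth <- function(snvs, k = 3) {
  med <- stats::ave(snvs$normal_depth, snvs$chrom,
                    FUN = function(x) stats::median(x))
  snvs$normal_depth > k * med
}

#' Apply the full somatic filter cascade
#'
#' Composes [depth_normal_filter()], [mapping_filter()] and
#' [panel_of_normals_filter()]. Each stage is a pure predicate on a
#' record, so the composition is order-invariant; the stage order here
#' only affects the bookkeeping of per-stage removal counts.
#'
#' @param snvs SNV data.frame.
#' @param annotations per-site annotations, or NULL to skip the mapping
#'   filter.
#' @param pon_sites PON site table, or NULL to skip.
#' @param min_depth,max_normal_alt,map_frac_min,dust_max cutoffs passed to
#'   the component filters.
#' @return surviving rows with attribute `"filter_log"` (named integer
#'   vector of records removed per stage).
#' @export
apply_filter_cascade <- function(snvs, annotations = NULL,
                                 pon_sites = NULL, min_depth = 10,
                                 max_normal_alt = 1, map_frac_min = 0.70,
                                 dust_max = 60) {
  log <- c(input = nrow(snvs))
  out <- depth_normal_filter(snvs, min_depth, max_normal_alt)
  log <- c(log, depth_normal = nrow(snvs) - nrow(out))
  if (!is.null(annotations)) {
    n0 <- nrow(out)
    out <- mapping_filter(out, annotations, map_frac_min, dust_max)
    log <- c(log, mapping = n0 - nrow(out))
  }
  if (!is.null(pon_sites)) {
    n0 <- nrow(out)
    out <- panel_of_normals_filter(out, pon_sites)
    log <- c(log, panel_of_normals = n0 - nrow(out))
  }
  log <- c(log, passing = nrow(out))
  attr(out, "filter_log") <- log
  out
}
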