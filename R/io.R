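#' Construct a validated somatic SNV table
#'
#' The package represents somatic SNVs as a plain data.frame with one row
#' per biallelic substitution and columns `chrom`, `pos` (1-based), `ref`,
#' `alt`, `tumor_alt`, `tumor_depth`, `normal_alt`, `normal_depth`,
#' `context` (pyrimidine-centered trinucleotide, may be NA). This
#' constructor validates the count invariants and normalizes contexts to
#' the pyrimidine strand.
#'
#' @param chrom,pos,ref,alt,tumor_alt,tumor_depth,normal_alt,normal_depth
#'   vectors of equal length.
#' @param context trinucleotide contexts (middle base = ref before
#'   normalization), or NA.
#' @return data.frame of somatic SNVs.
#' @export
snv_records <- function(chrom, pos, ref, alt, tumor_alt, tumor_depth,
                        normal_alt, normal_depth, context = NA_character_) {
  n <- length(pos)
  context <- rep_len(context, n)
  if (any(ref == alt)) stop("ref must differ from alt")
  if (any(tumor_alt < 0 | tumor_alt > tumor_depth))
    stop("tumor_alt must lie in [0, tumor_depth]")
  if (any(normal_alt < 0 | normal_alt > normal_depth))
    stop("normal_alt must lie in [0, normal_depth]")
  has_ctx <- !is.na(context)
  if (any(has_ctx)) {
    z <- pyrimidine_normalize(ref[has_ctx], alt[has_ctx], context[has_ctx])
    ref[has_ctx] <- z$ref
    alt[has_ctx] <- z$alt
    context[has_ctx] <- z$context
  }
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             ref = ref, alt = alt,
             tumor_alt = as.integer(tumor_alt),
             tumor_depth = as.integer(tumor_depth),
             normal_alt = as.integer(normal_alt),
             normal_depth = as.integer(normal_depth),
             context = context, stringsAsFactors = FALSE)
}

#' Load somatic SNVs from a VCF
#'
#' Reads a MuTect2-style somatic VCF with per-sample `FORMAT/AD` allele
#' depths and an optional `INFO/TNC` trinucleotide-context tag.
#' Multiallelic records are split into one row per alternate allele;
#' indels are skipped and their count reported via a message and the
#' `"skipped_indels"` attribute.
#'
#' @param vcf_path path to a VCF (plain or gzipped).
#' @param tumor_sample,normal_sample sample column names in the VCF.
#' @return data.frame of SNVs (see [snv_records()]) with attribute
#'   `skipped_indels`.
#' @export
load_snvs <- function(vcf_path, tumor_sample, normal_sample) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  for (s in c(tumor_sample, normal_sample)) {
    if (!s %in% samples)
      stop("sample '", s, "' not found in VCF (has: ",
           paste(samples, collapse = ", "), ")")
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  tnc <- suppressWarnings(vcfR::extract.info(vcf, "TNC"))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  ad_t <- ad[, tumor_sample]
  ad_n <- ad[, normal_sample]

  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ref <- fix[i, "REF"]
    ad_ti <- strsplit(ad_t[i], ",", fixed = TRUE)[[1]]
    ad_ni <- strsplit(ad_n[i], ",", fixed = TRUE)[[1]]
    if (anyNA(ad_t[i]) || anyNA(ad_n[i]) || length(ad_ti) < 2)
      stop("missing FORMAT/AD at ", fix[i, "CHROM"], ":", fix[i, "POS"])
    for (j in seq_along(alts)) {
      if (nchar(ref) != 1L || nchar(alts[j]) != 1L) {
        skipped <- skipped + 1L
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alts[j],
        tumor_alt = as.integer(ad_ti[j + 1L]),
        tumor_depth = sum(as.integer(ad_ti)),
        normal_alt = as.integer(ad_ni[j + 1L]),
        normal_depth = sum(as.integer(ad_ni)),
        context = if (length(tnc)) tnc[i] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L) message(skipped, " indel allele(s) skipped")
  if (!length(out)) {
    res <- snv_records(character(), integer(), character(), character(),
                       integer(), integer(), integer(), integer())
  } else {
    df <- do.call(rbind, out)
    res <- snv_records(df$chrom, df$pos, df$ref, df$alt, df$tumor_alt,
                       df$tumor_depth, df$normal_alt, df$normal_depth,
                       df$context)
  }
  attr(res, "skipped_indels") <- skipped
  res
}

#' Write somatic SNVs to a VCF
#'
#' Emits a minimal VCF 4.2 with `INFO/TNC` contexts and `GT:AD:DP` fields
#' for a TUMOR and NORMAL sample. Output is gzipped (`.vcf.gz`), the
#' standard on-disk form; [load_snvs()] reads it back.
#'
#' @param snvs SNV data.frame (see [snv_records()]).
#' @param path output path (a `.gz` suffix is appended if absent).
#' @param tumor_sample,normal_sample sample column names to write.
#' @return the path written, invisibly.
#' @export
write_snvs_vcf <- function(snvs, path, tumor_sample = "TUMOR",
                           normal_sample = "NORMAL") {
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=TNC,Number=1,Type=String,Description=\"Pyrimidine-centered trinucleotide context\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">")
  o <- order(snvs$chrom, snvs$pos)
  snvs <- snvs[o, , drop = FALSE]
  info <- ifelse(is.na(snvs$context), ".", paste0("TNC=", snvs$context))
  fix <- cbind(CHROM = snvs$chrom, POS = as.character(snvs$pos),
               ID = ".", REF = snvs$ref, ALT = snvs$alt, QUAL = ".",
               FILTER = "PASS", INFO = info)
  gt_t <- paste0("0/1:", snvs$tumor_depth - snvs$tumor_alt, ",",
                 snvs$tumor_alt, ":", snvs$tumor_depth)
  gt_n <- paste0("0/0:", snvs$normal_depth - snvs$normal_alt, ",",
                 snvs$normal_alt, ":", snvs$normal_depth)
  gt <- cbind(FORMAT = "GT:AD:DP", gt_t, gt_n)
  colnames(gt) <- c("FORMAT", tumor_sample, normal_sample)
  # instantiating the S4 class attaches vcfR; keep its banner quiet
  obj <- suppressPackageStartupMessages(
    methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                 meta = meta, fix = fix, gt = gt))
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Load allele-specific copy-number segments
#'
#' Reads a Battenberg-like tab-separated table with columns `chrom`,
#' `start`, `end`, `major`, `minor`, `clonal_fraction`. On disk the
#' coordinates are 1-based inclusive; internally the package uses 0-based
#' half-open intervals, converted here. Segments are sorted per chromosome
#' and must not overlap.
#'
#' @param tsv_path path to the segment table.
#' @return data.frame of segments (internal coordinates).
#' @export
load_segments <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "major", "minor", "clonal_fraction")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("segment table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  cn_segments(chrom = df$chrom, start = df$start - 1, end = df$end,
              major = df$major, minor = df$minor,
              clonal_fraction = df$clonal_fraction)
}

#' Construct a validated segment table (internal coordinates)
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates.
#' @param major,minor integer allele-specific copy numbers, major >= minor.
#' @param clonal_fraction fraction of tumor cells carrying the segment
#'   state, in `[0, 1]`.
#' @return sorted, overlap-checked data.frame of segments.
#' @export
cn_segments <- function(chrom, start, end, major, minor,
                        clonal_fraction = 1) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), major = as.integer(major),
                   minor = as.integer(minor),
                   clonal_fraction = rep_len(clonal_fraction, length(start)),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("segment start must be < end")
  bad <- which(df$major < df$minor | df$minor < 0)
  if (length(bad))
    stop("major < minor (or minor < 0) at row(s): ",
         paste(bad, collapse = ", "))
  if (any(df$clonal_fraction < 0 | df$clonal_fraction > 1))
    stop("clonal_fraction must lie in [0, 1]")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(s) > 1L) {
      ov <- which(s$start[-1] < s$end[-nrow(s)])
      if (length(ov))
        stop("overlapping segments on ", ch, ": rows ", ov[1], " and ",
             ov[1] + 1, " (", s$start[ov[1]] + 1, "-", s$end[ov[1]], " vs ",
             s$start[ov[1] + 1] + 1, "-", s$end[ov[1] + 1], ")")
    }
  }
  df
}

#' Write a segment table in the on-disk (1-based inclusive) dialect
#'
#' @param segments internal segment data.frame (see [load_segments()]).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- segments
  out$start <- out$start + 1
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default TP53 locus interval (hg19)
#'
#' Convenience configuration value; any locus can be supplied in its place.
#' Coordinates are 1-based inclusive.
#'
#' @return list with `chrom`, `start`, `end`.
#' @export
tp53_locus <- function() {
  list(chrom = "17", start = 7565097, end = 7590856)
}

#' Load mapping-quality annotations for the filter cascade
#'
#' TSV with columns `chrom`, `pos`, `nonunique_map_frac`,
#' `multimap_cluster`, `excessive_depth`, `dust_score`.
#'
#' @param path annotation TSV path.
#' @return data.frame of per-site annotations.
#' @export
load_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "nonunique_map_frac", "multimap_cluster",
           "excessive_depth", "dust_score")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df$multimap_cluster <- as.logical(df$multimap_cluster)
  df$excessive_depth <- as.logical(df$excessive_depth)
  df
}

#' Load a panel-of-normals site list
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`.
#'
#' @param path PON TSV path.
#' @return data.frame of PON sites.
#' @export
load_pon <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  req <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("PON table lacks column(s): ", paste(missing_cols, collapse = ", "))
  df
}
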