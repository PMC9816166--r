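#' Count reads containing telomeric repeats
#'
#' A read counts as telomeric when it contains at least `min_repeats`
#' non-overlapping occurrences of the telomere motif on either strand:
#' the forward motif (`TTAGGG`) and its reverse complement (`CCCTAA`) are
#' counted separately and the larger count is compared to the threshold.
#'
#' @param reads character vector of read sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param repeat_motif telomere repeat unit (default `"TTAGGG"`).
#' @param min_repeats minimum repeats per read (default 12, the
#'   HiSeqX/150 bp operating point).
#' @return number of telomeric reads.
#' @export
count_telomeric_reads <- function(reads, repeat_motif = "TTAGGG",
                                  min_repeats = 12) {
  if (!length(reads)) return(0L)
  dss <- if (methods::is(reads, "DNAStringSet")) reads
         else Biostrings::DNAStringSet(reads)
  fwd <- Biostrings::vcountPattern(repeat_motif, dss)
  rev <- Biostrings::vcountPattern(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(repeat_motif))),
    dss)
  sum(pmax(fwd, rev) >= min_repeats)
}

#' GC fraction of read sequences
#'
#' @param reads character vector or `DNAStringSet`.
#' @return numeric vector of G+C fractions.
#' @export
gc_fraction <- function(reads) {
  dss <- if (methods::is(reads, "DNAStringSet")) reads
         else Biostrings::DNAStringSet(reads)
  freq <- Biostrings::alphabetFrequency(dss, baseOnly = TRUE)
  (freq[, "G"] + freq[, "C"]) / Biostrings::width(dss)
}

#' Mean telomere length from telomeric read counts
#'
#' TelSeq-style normalization: telomeric read count is converted to
#' sequence mass (`k_tel * read_length`), divided by the GC-adjusted
#' coverage `c_gc = n_gc * read_length / g_gc` estimated from reads in a
#' GC-matched bin, and shared over the `n_ends` chromosome ends.
#'
#' @param k_tel telomeric read count.
#' @param n_gc read count in the GC-matched (48-52% GC) bin.
#' @param g_gc genome span of the GC-matched bin in bp.
#' @param n_ends number of chromosome ends (default 46).
#' @param read_length read length in bp (default 150).
#' @return mean telomere length per end, in kb.
#' @export
estimate_telomere_length <- function(k_tel, n_gc, g_gc, n_ends = 46,
                                     read_length = 150) {
  if (n_gc <= 0) stop("n_gc must be > 0")
  if (g_gc <= 0) stop("g_gc must be > 0")
  c_gc <- n_gc * read_length / g_gc
  per_end_bp <- (k_tel * read_length / c_gc) / n_ends
  per_end_bp / 1000
}

#' Tumor/normal telomere length ratio
#'
#' @param tumor_kb,normal_kb estimated telomere lengths in kb.
#' @return T/N ratio; values well above 1 suggest telomere lengthening.
#' @export
tn_ratio <- function(tumor_kb, normal_kb) {
  if (normal_kb <= 0) stop("normal telomere length must be > 0")
  tumor_kb / normal_kb
}

#' Telomere content profile of a read set
#'
#' Counts telomeric reads and GC-bin background reads (telomeric reads
#' are excluded from the background bin: they are signal, not coverage),
#' then applies [estimate_telomere_length()].
#'
#' @param reads character vector or `DNAStringSet` of read sequences.
#' @param g_gc genome span of the GC bin in bp (supplied by
#'   configuration).
#' @param gc_range GC bin bounds (default `c(0.48, 0.52)`).
#' @param min_repeats,read_length,n_ends see
#'   [count_telomeric_reads()] / [estimate_telomere_length()].
#' @return list with `k_tel`, `n_gc`, `g_gc`, `length_kb`.
#' @export
telomere_profile <- function(reads, g_gc, gc_range = c(0.48, 0.52),
                             min_repeats = 12, read_length = 150,
                             n_ends = 46) {
  dss <- if (methods::is(reads, "DNAStringSet")) reads
         else Biostrings::DNAStringSet(reads)
  fwd <- Biostrings::vcountPattern("TTAGGG", dss)
  rev <- Biostrings::vcountPattern("CCCTAA", dss)
  is_tel <- pmax(fwd, rev) >= min_repeats
  gc <- gc_fraction(dss)
  n_gc <- sum(!is_tel & gc >= gc_range[1] & gc <= gc_range[2])
  k_tel <- sum(is_tel)
  len <- if (n_gc > 0)
    estimate_telomere_length(k_tel, n_gc, g_gc, n_ends, read_length)
  else NA_real_
  list(k_tel = k_tel, n_gc = n_gc, g_gc = g_gc, length_kb = len)
}

#' Simulate tumor/normal read sets with planted telomere content
#'
#' Emits telomeric reads (tandem TTAGGG runs at a random phase, half
#' reverse-complemented, with optional per-read mismatches) and
#' GC-matched background reads (exactly 50% GC, telomere-motif free), for
#' a tumor and a matched normal. Deterministic for a fixed seed.
#'
#' @param params list with `n_tel_tumor`, `n_tel_normal`, `n_gc`
#'   (background reads per sample), `read_length` (default 150),
#'   `mismatches_per_read` (default 0).
#' @param seed RNG seed.
#' @return list with `tumor` and `normal` character vectors of reads.
#' @export
simulate_telomere_reads <- function(params, seed = 1) {
  p <- utils::modifyList(list(read_length = 150, mismatches_per_read = 0),
                         params)
  set.seed(seed)
  list(tumor = c(sim_tel_reads(p$n_tel_tumor, p$read_length,
                               p$mismatches_per_read),
                 sim_gc_reads(p$n_gc, p$read_length)),
       normal = c(sim_tel_reads(p$n_tel_normal, p$read_length,
                                p$mismatches_per_read),
                  sim_gc_reads(p$n_gc, p$read_length)))
}

sim_tel_reads <- function(n, read_length, mismatches) {
  if (n == 0) return(character(0))
  unit <- "TTAGGG"
  tandem <- strrep(unit, ceiling(read_length / nchar(unit)) + 1L)
  reads <- vapply(seq_len(n), function(i) {
    phase <- sample.int(nchar(unit), 1)
    r <- substr(tandem, phase, phase + read_length - 1L)
    if (mismatches > 0) {
      pos <- sample.int(read_length, mismatches)
      for (q in pos) {
        cur <- substr(r, q, q)
        substr(r, q, q) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      }
    }
    r
  }, character(1))
  flip <- seq_len(n) %% 2L == 0L
  reads[flip] <- revcomp(reads[flip])
  reads
}

sim_gc_reads <- function(n, read_length) {
  if (n == 0) return(character(0))
  n_gc_bases <- floor(read_length / 2)
  vapply(seq_len(n), function(i) {
    repeat {
      gc <- sample(c("G", "C"), n_gc_bases, replace = TRUE)
      at <- sample(c("A", "T"), read_length - n_gc_bases, replace = TRUE)
      r <- paste(sample(c(gc, at)), collapse = "")
      # background reads must not look telomeric
      if (!grepl("TTAGGG", r, fixed = TRUE) &&
          !grepl("CCCTAA", r, fixed = TRUE)) return(r)
    }
  }, character(1))
}

#' Write reads to FASTQ
#'
#' @param reads character vector of sequences.
#' @param path output FASTQ path.
#' @param id_prefix read-name prefix.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path, id_prefix = "read") {
  dss <- Biostrings::DNAStringSet(reads)
  names(dss) <- paste0(id_prefix, seq_along(reads))
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(dss, path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Read sequences from FASTQ
#'
#' @param path FASTQ path.
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}
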