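#' The 96 single-base-substitution channels
#'
#' Returns the standard 96 pyrimidine-centered trinucleotide substitution
#' channels, ordered by substitution class (`C>A`, `C>G`, `C>T`, `T>A`,
#' `T>C`, `T>G`) and, within each class, by 5' then 3' flanking base in
#' alphabetical order. Labels follow the `"A[C>A]A"` convention.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(f, t3) {
      paste0(f, "[", s, "]", t3)
    })))
  }), use.names = FALSE)
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector, reverse-complemented.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Normalize a substitution call to the pyrimidine strand
#'
#' Somatic substitutions are conventionally reported with the mutated base
#' as a pyrimidine (C or T). Calls recorded on the purine strand are
#' reverse-complemented (ref, alt, and trinucleotide context together) so
#' that a `G>A` at context `CGA` maps to the same channel as its `C>T`
#' reverse complement.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @param context trinucleotide contexts (3 characters, middle base = ref).
#' @return data.frame with columns `ref`, `alt`, `context` on the
#'   pyrimidine strand.
#' @export
pyrimidine_normalize <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(ref) == length(context))
  flip <- ref %in% c("A", "G")
  if (any(flip, na.rm = TRUE)) {
    idx <- which(flip)
    ref[idx] <- chartr("AG", "TC", ref[idx])
    alt[idx] <- chartr("ACGT", "TGCA", alt[idx])
    context[idx] <- revcomp(context[idx])
  }
  bad <- !is.na(context) & substr(context, 2, 2) != ref
  if (any(bad)) {
    stop("context middle base disagrees with REF at record(s): ",
         paste(which(bad)[seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  data.frame(ref = ref, alt = alt, context = context,
             stringsAsFactors = FALSE)
}

#' Map substitutions to their 96-channel label
#'
#' @param ref,alt single bases (pyrimidine-normalized or not; purine-strand
#'   calls are normalized first).
#' @param context trinucleotide context strings.
#' @return character vector of channel labels, e.g. `"A[C>T]G"`.
#' @export
sbs_channel <- function(ref, alt, context) {
  z <- pyrimidine_normalize(ref, alt, context)
  lab <- paste0(substr(z$context, 1, 1), "[", z$ref, ">", z$alt, "]",
                substr(z$context, 3, 3))
  ok <- lab %in% sbs_channels()
  ok[is.na(z$context)] <- NA
  lab[!ok %in% TRUE] <- NA_character_
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
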