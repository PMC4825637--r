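# Small DNA helpers shared across modules. Sequences travel as plain
# uppercase character strings restricted to A/C/G/T/N; tibbles carry them
# in a `seq` column keyed by `id`.

#' Reverse complement of a DNA string
#'
#' N is its own complement; the input must already be normalized to ACGTN.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' kp_revcomp("ACGTN")
kp_revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Normalize raw sequence text to the package alphabet: uppercase, U -> T,
# anything outside ACGT -> N.
normalize_dna <- function(x) {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("[^ACGTN]", "N", x)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside A/C/G/T/N", what))
  }
  invisible(x)
}

# Validate a sequence tibble (columns id, seq).
assert_seq_tbl <- function(seqs, what = "seqs") {
  if (!is.data.frame(seqs) || !all(c("id", "seq") %in% names(seqs))) {
    abort(sprintf("`%s` must be a data frame with columns `id` and `seq`", what))
  }
  if (anyDuplicated(seqs$id)) {
    abort(sprintf("duplicate sequence id in `%s`: %s", what,
                  seqs$id[duplicated(seqs$id)][1]))
  }
  invisible(seqs)
}

seq_as_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Intensity scale used throughout the karyotype module.
INTENSITY_LEVELS <- c("none", "weak", "medium", "strong")

intensity_ord <- function(x) {
  match(x, INTENSITY_LEVELS) - 1L
}
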