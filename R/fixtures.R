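#' Reference BAC clones of the common bean karyotyping system
#'
#' The eleven chromosome-specific single/low-copy BAC clones with their
#' anchored pseudo-chromosome coordinates (1-based inclusive), insert
#' lengths, physical positions and total repeat content, read from the
#' package's extdata.
#'
#' @return a tibble, one row per chromosome.
#' @export
kp_bac_reference <- function() {
  path <- system.file("extdata", "table2_bacs.tsv", package = "karyoprobe")
  readr::read_tsv(path, comment = "#", col_types = readr::cols(), na = "NA",
                  progress = FALSE)
}
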