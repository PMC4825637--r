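# File formats: FASTA sequences, 12/13-column tabular alignment hits, BED.
#
# Coordinate convention: every interval inside the package is 1-based and
# inclusive on both ends (so length == end - start + 1, matching how BAC
# insert lengths are tabulated from first/last base). Conversion to BED's
# 0-based half-open convention happens only when a BED file is written or
# read.

#' Read a FASTA file into a sequence tibble
#'
#' Sequences are uppercased, U is mapped to T, and any character outside
#' A/C/G/T is collapsed to N. Downstream k-mer and probe operations skip
#' N-containing windows, so ambiguity codes are deliberately not preserved.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `seq`.
#' @export
kp_read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1]))
  }
  seqs <- normalize_dna(as.character(set))
  if (any(nchar(seqs) == 0)) {
    abort(sprintf("zero-length sequence for id: %s", ids[nchar(seqs) == 0][1]))
  }
  tibble(id = ids, seq = unname(seqs))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs tibble with columns `id`, `seq`.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
kp_write_fasta <- function(seqs, path, width = 70L) {
  assert_seq_tbl(seqs)
  set <- Biostrings::BStringSet(stats::setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a tabular alignment table (BLAST outfmt-6 dialect)
#'
#' Expects 12 tab-separated columns (query, subject, identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, bitscore) with an optional 13th column carrying the query
#' length. Strand is derived from the subject coordinate order and subject
#' coordinates are normalized so `subject_start <= subject_end`.
#'
#' Query lengths are required to compute coverage; supply them via the 13th
#' column or the `query_lengths` argument (a named vector or a tibble with
#' columns `id`, `length`), e.g. derived from the query FASTA.
#'
#' @param path path to the tab-separated hit table (no header).
#' @param query_lengths optional query lengths (named vector or tibble).
#' @return a tibble of hits with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`, `strand`,
#'   `evalue`, `bitscore`, `query_length` (NA when unknown).
#' @export
kp_read_hits <- function(path, query_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort(sprintf("empty alignment table: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 12)) {
    abort(sprintf("line %d: expected >= 12 tab-separated columns, got %d",
                  which(n_col < 12)[1], n_col[which(n_col < 12)[1]]))
  }
  num_cols <- c(3:10, 11, 12)
  parse_row <- function(f, i) {
    vals <- suppressWarnings(as.numeric(f[num_cols]))
    if (anyNA(vals)) {
      bad <- num_cols[which(is.na(vals))[1]]
      abort(sprintf("line %d: non-numeric value '%s' in column %d", i, f[bad], bad))
    }
    qlen <- if (length(f) >= 13) {
      v <- suppressWarnings(as.numeric(f[13]))
      if (is.na(v)) abort(sprintf("line %d: non-numeric query length '%s'", i, f[13]))
      v
    } else NA_real_
    tibble(
      query_id = f[1], subject_id = f[2],
      percent_identity = vals[1], alignment_length = as.integer(vals[2]),
      mismatches = as.integer(vals[3]), gap_opens = as.integer(vals[4]),
      query_start = as.integer(vals[5]), query_end = as.integer(vals[6]),
      sstart = as.integer(vals[7]), send = as.integer(vals[8]),
      evalue = vals[9], bitscore = vals[10], query_length = qlen
    )
  }
  hits <- bind_rows(imap(fields, parse_row))
  hits <- hits |>
    mutate(
      strand = if_else(.data$sstart <= .data$send, "+", "-"),
      subject_start = pmin(.data$sstart, .data$send),
      subject_end = pmax(.data$sstart, .data$send)
    ) |>
    select(-"sstart", -"send") |>
    relocate("subject_start", "subject_end", "strand", .after = "query_end")
  if (!is.null(query_lengths)) {
    if (is.data.frame(query_lengths)) {
      query_lengths <- stats::setNames(query_lengths$length, query_lengths$id)
    }
    hits$query_length <- unname(query_lengths[hits$query_id])
  }
  hits
}

#' Write genomic intervals to a BED file
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention (`start - 1`, `end`).
#'
#' @param intervals tibble with columns `chrom`, `start`, `end` and
#'   optionally `label` (fourth BED column; falls back to `class`, then ".").
#' @param path output path.
#' @return `path`, invisibly.
#' @export
kp_write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) > 0 && any(intervals$start < 1 | intervals$start > intervals$end)) {
    abort("invalid interval: need 1 <= start <= end")
  }
  label <- intervals[["label"]] %||% intervals[["class"]] %||% rep(".", nrow(intervals))
  out <- sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                 as.integer(intervals$start) - 1L, as.integer(intervals$end), label)
  writeLines(out, path)
  invisible(path)
}

#' Read a BED3+1 file into a 1-based inclusive interval tibble
#'
#' @param path path to a BED file.
#' @return tibble with columns `chrom`, `start`, `end`, `label`.
#' @export
kp_read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE)
  if (ncol(raw) < 3) abort("BED file needs at least 3 columns")
  tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]) + 1L,
    end = as.integer(raw[[3]]),
    label = if (ncol(raw) >= 4) as.character(raw[[4]]) else "."
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
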