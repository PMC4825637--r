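# Oligo probe design: candidate enumeration over polymorphic windows,
# genome-wide mismatch-tolerant hit counting on both strands (the
# in-silico proxy for hybridization specificity), accept/reject decisions,
# and multi-fluorophore cocktail assembly with channel-conflict checks.

FLUOROPHORE_CHANNEL <- c(
  "FAM" = "green", "fluorescein" = "green",
  "TEX615" = "red", "TexasRed" = "red", "Texas Red" = "red",
  "Cy5" = "blue", "cyanine5" = "blue"
)

PROBE_TARGETS <- c("centromere", "subtelomere", "rDNA_locus", "arm_locus")

#' Imaging channel of a fluorophore label
#'
#' FAM/fluorescein image as green, TEX615/Texas Red as red, Cy5 as blue.
#'
#' @param fluorophore character vector of fluorophore names.
#' @return character vector of channels (green/red/blue).
#' @export
#' @examples
#' kp_channel_for(c("Cy5", "FAM", "TEX615"))
kp_channel_for <- function(fluorophore) {
  ch <- FLUOROPHORE_CHANNEL[fluorophore]
  if (anyNA(ch)) {
    abort(sprintf("unknown fluorophore: %s (known: %s)",
                  fluorophore[is.na(ch)][1],
                  paste(names(FLUOROPHORE_CHANNEL), collapse = ", ")))
  }
  unname(ch)
}

#' Enumerate candidate oligo windows from a source sequence
#'
#' All windows of `probe_length`; when `required_positions` (0-based
#' offsets into the source, e.g. polymorphic sites) are given, only
#' windows covering all of them are returned, ranked by the centrality of
#' those positions within the window (mean distance to the window centre,
#' ascending; ties by start). N-containing windows are excluded.
#'
#' @param source_seq source sequence (character scalar).
#' @param probe_length window length, nt.
#' @param required_positions optional integer vector of 0-based offsets
#'   that every candidate must cover.
#' @return tibble with `start` (0-based window offset), `sequence`,
#'   `n_covered` (number of required positions covered), `centrality`.
#' @export
kp_enumerate_oligos <- function(source_seq, probe_length = 25,
                                required_positions = NULL) {
  stopifnot(is.character(source_seq), length(source_seq) == 1)
  L <- nchar(source_seq)
  if (probe_length > L) abort("probe_length exceeds source length")
  if (!is.null(required_positions)) {
    if (any(required_positions < 0 | required_positions >= L)) {
      abort("required_positions outside the source sequence")
    }
  }
  start <- 0:(L - probe_length)
  cand <- tibble(start = start,
                 sequence = str_sub(source_seq, start + 1, start + probe_length)) |>
    filter(!str_detect(.data$sequence, "N"))
  if (is.null(required_positions) || length(required_positions) == 0) {
    return(mutate(cand, n_covered = 0L, centrality = NA_real_))
  }
  rp <- sort(unique(as.integer(required_positions)))
  cand <- cand |>
    mutate(
      n_covered = map_int(.data$start, function(s) {
        sum(rp >= s & rp <= s + probe_length - 1L)
      })
    ) |>
    filter(.data$n_covered == length(rp)) |>
    mutate(
      centrality = map_dbl(.data$start, function(s) {
        centre <- s + (probe_length - 1) / 2
        mean(abs(rp - centre))
      })
    ) |>
    arrange(desc(.data$n_covered), .data$centrality, .data$start)
  cand
}

#' Genome-wide hit counts of an oligo with mismatch tolerance
#'
#' Counts occurrences of the oligo and of its reverse complement at every
#' offset of every chromosome within Hamming distance `d` (substitutions
#' only, no indels). Overlapping occurrences are counted individually:
#' signal intensity is modelled as proportional to the number of binding
#' sites. An oligo equal to its own reverse complement is counted once per
#' strand, i.e. twice per site, on both the implementation and the naive
#' oracle path.
#'
#' @param oligo probe sequence (character scalar, N-free).
#' @param genome sequence tibble of chromosomes.
#' @param d maximum Hamming distance (must be < oligo length).
#' @return named integer vector: per-chromosome hit counts (both strands).
#' @export
kp_oligo_hits <- function(oligo, genome, d = 2) {
  assert_seq_tbl(genome, "genome")
  stopifnot(is.character(oligo), length(oligo) == 1)
  if (grepl("N", oligo, fixed = TRUE)) abort("oligo must be N-free")
  if (d >= nchar(oligo)) abort("d must be smaller than the oligo length")
  pat_f <- Biostrings::DNAString(oligo)
  pat_r <- Biostrings::DNAString(kp_revcomp(oligo))
  counts <- vapply(genome$seq, function(s) {
    subj <- Biostrings::DNAString(s)
    Biostrings::countPattern(pat_f, subj, max.mismatch = d, fixed = TRUE) +
      Biostrings::countPattern(pat_r, subj, max.mismatch = d, fixed = TRUE)
  }, integer(1), USE.NAMES = FALSE)
  stats::setNames(counts, genome$id)
}

#' Accept or reject an oligo on its genome-wide hit distribution
#'
#' Accepts when the summed on-target hits reach `min_hits` and the
#' on-target fraction of all hits reaches `threshold`.
#'
#' @param counts named per-chromosome hit counts from [kp_oligo_hits()].
#' @param target_chroms chromosomes the probe is meant to mark.
#' @param threshold minimum on-target fraction.
#' @param min_hits minimum on-target hit count.
#' @return a one-row tibble: `on_target`, `off_target`,
#'   `on_target_fraction` (NA when there are no hits), `decision`, plus
#'   the counts as attribute `"per_chrom_counts"`.
#' @export
kp_specificity <- function(counts, target_chroms, threshold = 0.95, min_hits = 5) {
  if (length(target_chroms) == 0) abort("target_chroms must be non-empty")
  unknown <- setdiff(target_chroms, names(counts))
  if (length(unknown) > 0) abort(sprintf("target chromosome not in counts: %s", unknown[1]))
  on <- sum(counts[target_chroms])
  tot <- sum(counts)
  frac <- if (tot > 0) on / tot else NA_real_
  res <- tibble(on_target = as.integer(on),
                off_target = as.integer(tot - on),
                on_target_fraction = frac,
                decision = if (!is.na(frac) && on >= min_hits && frac >= threshold)
                  "accept" else "reject")
  attr(res, "per_chrom_counts") <- counts
  res
}

#' Assemble a multi-fluorophore probe cocktail
#'
#' Validates the probe table and reports conflicts: two probes imaging in
#' the same channel whose target class and target chromosomes overlap are
#' indistinguishable under the microscope (co-located same-colour
#' signals), so each such pair triggers a warning.
#'
#' @param probes tibble with columns `name`, `channel` (or `fluorophore`),
#'   `target` (centromere/subtelomere/rDNA_locus/arm_locus) and
#'   `target_chroms` (list column of chromosome ids); `sequence` optional.
#' @return the cocktail tibble (class `kp_cocktail`) with a `conflicts`
#'   tibble attached as an attribute.
#' @export
kp_cocktail <- function(probes) {
  stopifnot(is.data.frame(probes))
  if (nrow(probes) == 0) {
    out <- tibble(name = character(), channel = character(),
                  target = character(), target_chroms = list())
    attr(out, "conflicts") <- tibble(probe_a = character(), probe_b = character(),
                                     channel = character(), target = character())
    class(out) <- c("kp_cocktail", class(out))
    return(out)
  }
  if (!"channel" %in% names(probes)) {
    probes$channel <- kp_channel_for(probes$fluorophore)
  }
  stopifnot(all(c("name", "channel", "target", "target_chroms") %in% names(probes)))
  if (anyDuplicated(probes$name)) {
    abort(sprintf("duplicate probe name: %s", probes$name[duplicated(probes$name)][1]))
  }
  bad_target <- setdiff(unique(probes$target), PROBE_TARGETS)
  if (length(bad_target) > 0) abort(sprintf("unknown probe target class: %s", bad_target[1]))
  conflicts <- list()
  n <- nrow(probes)
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      if (probes$channel[i] == probes$channel[j] &&
          probes$target[i] == probes$target[j] &&
          length(intersect(probes$target_chroms[[i]], probes$target_chroms[[j]])) > 0) {
        conflicts[[length(conflicts) + 1L]] <-
          tibble(probe_a = probes$name[i], probe_b = probes$name[j],
                 channel = probes$channel[i], target = probes$target[i])
      }
    }
  }
  conflicts <- if (length(conflicts) > 0) bind_rows(conflicts) else
    tibble(probe_a = character(), probe_b = character(),
           channel = character(), target = character())
  if (nrow(conflicts) > 0) {
    warn(sprintf("cocktail has %d same-channel co-located probe pair(s): %s",
                 nrow(conflicts),
                 paste(sprintf("%s/%s", conflicts$probe_a, conflicts$probe_b),
                       collapse = "; ")))
  }
  out <- probes
  attr(out, "conflicts") <- conflicts
  class(out) <- c("kp_cocktail", class(out))
  out
}

#' Conflicts recorded in a cocktail
#'
#' @param cocktail a [kp_cocktail()] object.
#' @return the conflicts tibble.
#' @export
kp_cocktail_conflicts <- function(cocktail) {
  attr(cocktail, "conflicts")
}

#' Bundled oligo probe set of the common bean karyotyping system
#'
#' The published fluorochrome-labelled oligos (24-26 nt) with their
#' fluorophores and imaging channels, read from the package's extdata.
#'
#' @return tibble with `name`, `sequence`, `fluorophore`, `channel`,
#'   `target`.
#' @export
kp_probe_set <- function() {
  path <- system.file("extdata", "oligo_probes.tsv", package = "karyoprobe")
  readr::read_tsv(path, comment = "#", col_types = readr::cols(), progress = FALSE) |>
    mutate(channel = kp_channel_for(.data$fluorophore))
}
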