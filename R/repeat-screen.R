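# Repeat screening: an internal library masker (seed-and-extend, mismatch
# tolerant, both strands), a windowed-entropy low-complexity mask, and the
# repeat-content percent used to screen BAC candidates.

REPEAT_CLASSES <- c("transposon", "low_complexity", "simple",
                    "tandem:rDNA", "tandem:CentPv1", "tandem:CentPv2",
                    "tandem:khipu")

assert_library <- function(library) {
  if (!is.data.frame(library) || !all(c("id", "seq", "class") %in% names(library))) {
    abort("`library` must be a data frame with columns id, seq, class")
  }
  bad <- setdiff(unique(library$class), REPEAT_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("unknown repeat class: %s (allowed: %s)",
                  bad[1], paste(REPEAT_CLASSES, collapse = ", ")))
  }
  invisible(library)
}

#' Mask sequences against a repeat library
#'
#' A library-driven masker standing in for a full repeat annotation run:
#' for every library entry, exact seed k-mers anchor candidate ungapped
#' alignments on both strands, which are then scanned for maximal segments
#' of length at least `min_match` whose mismatch fraction stays at or below
#' `max_mismatch_rate`. Matching is ungapped (substitutions only), and a
#' match never extends beyond the library entry's own footprint.
#' Overlapping or adjacent intervals of the same class are merged.
#'
#' @param seqs sequence tibble (`id`, `seq`) to mask.
#' @param library repeat library tibble with columns `id`, `seq`, `class`;
#'   classes must be one of transposon, low_complexity, simple,
#'   tandem:rDNA, tandem:CentPv1, tandem:CentPv2, tandem:khipu.
#' @param min_match minimum reported match length, bp.
#' @param max_mismatch_rate maximum mismatch fraction within a match.
#' @param seed_k exact seed length used to anchor candidate matches.
#' @return interval tibble (`chrom`, `start`, `end`, `class`), 1-based
#'   inclusive, merged per class.
#' @export
kp_mask_with_library <- function(seqs, library, min_match = 30,
                                 max_mismatch_rate = 0.1, seed_k = 12) {
  assert_seq_tbl(seqs)
  assert_library(library)
  stopifnot(min_match >= 1, max_mismatch_rate >= 0, max_mismatch_rate < 1)
  short <- nchar(library$seq) < min_match
  if (any(short)) {
    warn(sprintf("skipping %d library entr%s shorter than min_match (%d bp): %s",
                 sum(short), if (sum(short) == 1) "y" else "ies", min_match,
                 paste(library$id[short], collapse = ", ")))
    library <- library[!short, , drop = FALSE]
  }
  out <- list()
  for (si in seq_len(nrow(seqs))) {
    target <- seqs$seq[si]
    tchars <- seq_as_chars(target)
    tlen <- length(tchars)
    for (li in seq_len(nrow(library))) {
      for (entry in unique(c(library$seq[li], kp_revcomp(library$seq[li])))) {
        ivs <- scan_entry(entry, target, tchars, tlen, min_match,
                          max_mismatch_rate, seed_k)
        if (!is.null(ivs)) {
          ivs$chrom <- seqs$id[si]
          ivs$class <- library$class[li]
          out[[length(out) + 1L]] <- ivs
        }
      }
    }
  }
  merge_mask_intervals(bind_rows(out))
}

# Seed-and-extend scan of one library entry (one strand) against a target.
scan_entry <- function(entry, target, tchars, tlen, min_match,
                       max_mismatch_rate, seed_k) {
  elen <- nchar(entry)
  if (elen > 0 && tlen < min_match) return(NULL)
  k <- min(seed_k, elen)
  seed_starts <- unique(c(seq(1L, elen - k + 1L, by = k), elen - k + 1L))
  offsets <- integer(0)
  for (ss in seed_starts) {
    seed <- substr(entry, ss, ss + k - 1L)
    if (grepl("N", seed, fixed = TRUE)) next
    m <- gregexpr(seed, target, fixed = TRUE)[[1]]
    if (m[1] == -1) next
    offsets <- c(offsets, as.integer(m) - ss + 1L)
  }
  offsets <- unique(offsets)
  if (length(offsets) == 0) return(NULL)
  echars <- seq_as_chars(entry)
  res <- list()
  for (off in offsets) {
    # columns of the entry footprint that land inside the target
    c1 <- max(1L, 2L - off)             # entry column aligned to target pos >= 1
    c2 <- min(elen, tlen - off + 1L)
    if (c2 - c1 + 1L < min_match) next
    tpos <- off + (c1:c2) - 1L
    mism <- tchars[tpos] != echars[c1:c2]
    seg <- maximal_segments(mism, min_match, max_mismatch_rate)
    if (is.null(seg)) next
    res[[length(res) + 1L]] <- tibble(start = tpos[1] + seg$start - 1L,
                                      end = tpos[1] + seg$end - 1L)
  }
  if (length(res) == 0) NULL else bind_rows(res)
}

# For a logical mismatch vector, the union of all segments with length >=
# min_match and mismatch fraction <= rate, returned as covering intervals.
maximal_segments <- function(mism, min_match, rate) {
  n <- length(mism)
  csum <- c(0L, cumsum(mism))
  starts <- integer(0); ends <- integer(0)
  for (s in seq_len(n - min_match + 1L)) {
    e <- s + (min_match - 1L):(n - s)
    mm <- csum[e + 1L] - csum[s]
    ok <- mm <= floor(rate * (e - s + 1L))
    if (any(ok)) {
      starts <- c(starts, s)
      ends <- c(ends, max(e[ok]))
    }
  }
  if (length(starts) == 0) return(NULL)
  ir <- IRanges::reduce(IRanges::IRanges(starts, ends))
  tibble(start = IRanges::start(ir), end = IRanges::end(ir))
}

merge_mask_intervals <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), class = character()))
  }
  intervals |>
    group_by(.data$chrom, .data$class) |>
    reframe({
      ir <- IRanges::reduce(IRanges::IRanges(start, end))
      tibble(start = IRanges::start(ir), end = IRanges::end(ir))
    }) |>
    select("chrom", "start", "end", "class") |>
    arrange(.data$chrom, .data$start, .data$class)
}

#' Low-complexity mask by windowed base-composition entropy
#'
#' Tiles each sequence with non-overlapping windows (plus a final window
#' anchored at the sequence end) and masks windows whose Shannon entropy
#' over A/C/G/T composition is strictly below the threshold; N positions
#' are excluded from the composition. Adjacent masked windows are merged.
#'
#' @param seqs sequence tibble (`id`, `seq`).
#' @param window window size, bp; must not exceed the sequence length.
#' @param entropy_threshold bits; windows with entropy `<` this are masked.
#' @return interval tibble (`chrom`, `start`, `end`, `class`
#'   = "low_complexity").
#' @export
kp_low_complexity_mask <- function(seqs, window = 64, entropy_threshold = 1.0) {
  assert_seq_tbl(seqs)
  out <- list()
  for (si in seq_len(nrow(seqs))) {
    s <- seqs$seq[si]
    n <- nchar(s)
    if (window > n) abort(sprintf("window (%d) exceeds sequence length (%d) for %s",
                                  window, n, seqs$id[si]))
    starts <- unique(c(seq(1L, n, by = window), n - window + 1L))
    starts <- starts[starts >= 1L]
    ends <- pmin(starts + window - 1L, n)
    ent <- vapply(seq_along(starts), function(i) {
      shannon_entropy(substr(s, starts[i], ends[i]))
    }, numeric(1))
    masked <- ent < entropy_threshold
    if (any(masked)) {
      ir <- IRanges::reduce(IRanges::IRanges(starts[masked], ends[masked]))
      out[[length(out) + 1L]] <- tibble(chrom = seqs$id[si],
                                        start = IRanges::start(ir),
                                        end = IRanges::end(ir),
                                        class = "low_complexity")
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), class = character()))
  }
  bind_rows(out)
}

shannon_entropy <- function(s) {
  counts <- table(factor(seq_as_chars(s), levels = c("A", "C", "G", "T")))
  tot <- sum(counts)
  if (tot == 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

#' Repeat-content percent of masked sequences
#'
#' The percent of positions covered by the union of all mask intervals,
#' across classes: `100 * |union of masked positions| / target_length`.
#'
#' @param intervals interval tibble (`chrom`, `start`, `end`, any classes).
#' @param target_lengths named vector of sequence lengths, or a tibble with
#'   columns `id` and `length`.
#' @return tibble with `chrom`, `length`, `masked_bp`, `repeat_content`
#'   (percent), one row per target (zero content for targets without
#'   intervals).
#' @export
kp_repeat_content <- function(intervals, target_lengths) {
  if (is.data.frame(target_lengths)) {
    target_lengths <- stats::setNames(target_lengths$length, target_lengths$id)
  }
  if (nrow(intervals) > 0) {
    unknown <- setdiff(unique(intervals$chrom), names(target_lengths))
    if (length(unknown) > 0) abort(sprintf("interval on unknown target: %s", unknown[1]))
    lens <- target_lengths[intervals$chrom]
    if (any(intervals$start < 1 | intervals$end > lens | intervals$start > intervals$end)) {
      abort("mask interval out of target range")
    }
  }
  masked <- vapply(names(target_lengths), function(ch) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0) return(0L)
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(iv$start, iv$end))))
  }, integer(1))
  tibble(chrom = names(target_lengths),
         length = as.integer(unname(target_lengths)),
         masked_bp = as.integer(unname(masked)),
         repeat_content = 100 * unname(masked) / unname(target_lengths))
}

#' Does a mask annotation contain any tandem-repeat interval?
#'
#' @param intervals interval tibble with a `class` column.
#' @return tibble (`chrom`, `tandem_hit`); use [kp_repeat_screen()] for a
#'   per-sequence summary including sequences with no intervals.
#' @export
kp_has_tandem_hit <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), tandem_hit = logical()))
  }
  intervals |>
    group_by(.data$chrom) |>
    summarise(tandem_hit = any(startsWith(.data$class, "tandem:")), .groups = "drop")
}

#' Screen sequences: library mask + low-complexity mask + content summary
#'
#' Convenience wrapper chaining [kp_mask_with_library()] and
#' [kp_low_complexity_mask()], then summarising per sequence.
#'
#' @param seqs sequence tibble (`id`, `seq`).
#' @param library repeat library tibble.
#' @param min_match,max_mismatch_rate,seed_k see [kp_mask_with_library()].
#' @param window,entropy_threshold see [kp_low_complexity_mask()].
#' @param low_complexity apply the entropy mask (skipped for sequences
#'   shorter than `window`).
#' @return tibble (`id`, `length`, `masked_bp`, `repeat_content`,
#'   `tandem_hit`) with the interval tibble attached as attribute
#'   `"intervals"`.
#' @export
kp_repeat_screen <- function(seqs, library, min_match = 30,
                             max_mismatch_rate = 0.1, seed_k = 12,
                             window = 64, entropy_threshold = 1.0,
                             low_complexity = TRUE) {
  assert_seq_tbl(seqs)
  iv <- kp_mask_with_library(seqs, library, min_match = min_match,
                             max_mismatch_rate = max_mismatch_rate,
                             seed_k = seed_k)
  if (low_complexity) {
    long_enough <- seqs[nchar(seqs$seq) >= window, , drop = FALSE]
    if (nrow(long_enough) > 0) {
      iv <- bind_rows(iv, kp_low_complexity_mask(long_enough, window = window,
                                                 entropy_threshold = entropy_threshold))
    }
  }
  lens <- stats::setNames(nchar(seqs$seq), seqs$id)
  content <- kp_repeat_content(iv, lens)
  tand <- kp_has_tandem_hit(iv)
  res <- content |>
    rename(id = "chrom") |>
    left_join(rename(tand, id = "chrom"), by = "id") |>
    mutate(tandem_hit = !is.na(.data$tandem_hit) & .data$tandem_hit)
  attr(res, "intervals") <- iv
  res
}
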