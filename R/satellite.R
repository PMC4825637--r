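# Satellite tools: consensus building, monomer decomposition of tandem
# arrays, per-chromosome k-mer window profiling, and detection of
# chromosome-specific monomer variants (the route by which a variant such
# as a centromeric satellite confined to one chromosome is found and
# turned into a discriminating probe).

#' Majority-rule consensus of aligned sequences
#'
#' Per column, the most frequent non-gap symbol wins; ties are broken by
#' the fixed base order A < C < G < T < N. Columns with more than 50% gaps
#' are dropped.
#'
#' @param aligned character vector of equal-length sequences; `-` marks a
#'   gap.
#' @return a single consensus string.
#' @export
#' @examples
#' kp_consensus(c("ACGT", "ACGA", "ACG-"))
kp_consensus <- function(aligned) {
  if (length(aligned) < 2) abort("need at least 2 sequences")
  lens <- unique(nchar(aligned))
  if (length(lens) != 1) abort("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  cols <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    gap_frac <- mean(col == "-")
    if (gap_frac > 0.5) return("")
    col <- col[col != "-"]
    counts <- table(factor(col, levels = c("A", "C", "G", "T", "N")))
    names(counts)[which.max(counts)]   # which.max takes the first maximum: A<C<G<T<N
  }, character(1))
  paste(cols[cols != ""], collapse = "")
}

#' Decompose a tandem array into monomers by greedy consensus tiling
#'
#' Scans left to right: at each position the consensus is compared
#' (ungapped, substitutions only) against the window of its own length; a
#' window with identity at or above `min_identity` is accepted as a
#' monomer and the scan advances by the monomer length, otherwise by one.
#'
#' @param array_seq a single array sequence (character scalar).
#' @param consensus the monomer consensus (character scalar, length >= 10).
#' @param min_identity acceptance identity, fraction.
#' @return tibble with 0-based `offset` into the array and the `monomer`
#'   sequence; empty when the array is shorter than the consensus.
#' @export
kp_extract_monomers <- function(array_seq, consensus, min_identity = 0.7) {
  stopifnot(is.character(array_seq), length(array_seq) == 1,
            is.character(consensus), length(consensus) == 1)
  m <- nchar(consensus)
  if (m < 10) abort("consensus must be at least 10 bp")
  n <- nchar(array_seq)
  empty <- tibble(offset = integer(), monomer = character())
  if (n < m) return(empty)
  cons <- seq_as_chars(consensus)
  arr <- seq_as_chars(array_seq)
  offsets <- integer(0); monomers <- character(0)
  pos <- 1L
  min_matches <- ceiling(min_identity * m)
  while (pos + m - 1L <= n) {
    window <- arr[pos:(pos + m - 1L)]
    if (sum(window == cons) >= min_matches) {
      offsets <- c(offsets, pos - 1L)
      monomers <- c(monomers, paste(window, collapse = ""))
      pos <- pos + m
    } else {
      pos <- pos + 1L
    }
  }
  tibble(offset = offsets, monomer = monomers)
}

#' Decompose per-chromosome arrays into a monomer table
#'
#' @param arrays sequence tibble (`id` = chromosome, `seq` = array).
#' @param consensus monomer consensus string.
#' @param min_identity acceptance identity, fraction.
#' @return tibble (`chrom`, `offset`, `monomer`).
#' @export
kp_monomer_sets <- function(arrays, consensus, min_identity = 0.7) {
  assert_seq_tbl(arrays, "arrays")
  bind_rows(map2(arrays$id, arrays$seq, function(ch, s) {
    mutate(kp_extract_monomers(s, consensus, min_identity), chrom = ch,
           .before = 1)
  }))
}

#' Build a per-chromosome k-mer window profile of satellite monomers
#'
#' Every N-free length-`k` window of every monomer is counted under its
#' chromosome. The profile's consensus is the majority consensus over all
#' monomers of the modal length (monomers produced by
#' [kp_extract_monomers()] all share the consensus length). Each distinct
#' window is assigned the modal 0-based offset at which it was observed,
#' used to compare it against the consensus.
#'
#' @param monomers tibble (`chrom`, `monomer`) from [kp_monomer_sets()].
#' @param k window length, bp.
#' @return an object of class `kp_variant_profile`: list with `k`,
#'   `counts` (tibble `chrom`, `window`, `offset`, `count`) and
#'   `consensus`.
#' @export
kp_variant_profile <- function(monomers, k = 25) {
  stopifnot(is.data.frame(monomers), all(c("chrom", "monomer") %in% names(monomers)))
  if (nrow(monomers) == 0) abort("no monomers supplied")
  min_len <- min(nchar(monomers$monomer))
  if (k > min_len) {
    abort(sprintf("k (%d) exceeds the shortest monomer length (%d)", k, min_len))
  }
  windows <- bind_rows(map2(monomers$chrom, monomers$monomer, function(ch, mono) {
    L <- nchar(mono)
    off <- 0:(L - k)
    w <- str_sub(mono, off + 1, off + k)
    tibble(chrom = ch, window = w, offset = off)
  })) |>
    filter(!str_detect(.data$window, "N"))
  # modal offset per distinct window (ties -> smallest offset)
  modal <- windows |>
    count(.data$window, .data$offset, name = "n_at") |>
    arrange(.data$window, desc(.data$n_at), .data$offset) |>
    distinct(.data$window, .keep_all = TRUE) |>
    select("window", "offset")
  counts <- windows |>
    count(.data$chrom, .data$window, name = "count") |>
    left_join(modal, by = "window") |>
    select("chrom", "window", "offset", "count") |>
    arrange(.data$chrom, .data$offset, .data$window)
  modal_len <- as.integer(names(sort(table(nchar(monomers$monomer)),
                                     decreasing = TRUE))[1])
  aligned <- monomers$monomer[nchar(monomers$monomer) == modal_len]
  consensus <- if (length(aligned) >= 2) kp_consensus(aligned) else aligned[1]
  structure(list(k = as.integer(k), counts = counts, consensus = consensus),
            class = "kp_variant_profile")
}

#' @export
print.kp_variant_profile <- function(x, ...) {
  cat(sprintf("<kp_variant_profile> k=%d, %d distinct windows on %d chromosome(s), consensus %d bp\n",
              x$k, length(unique(x$counts$window)),
              length(unique(x$counts$chrom)), nchar(x$consensus)))
  invisible(x)
}

#' Detect chromosome-specific satellite variants
#'
#' A window is called `specific` for a chromosome when its count there
#' reaches `min_on_target`, its on-target fraction of total counts reaches
#' `specificity_threshold`, and it differs from the consensus window at
#' its offset in at least one position (those positions are recorded).
#' Windows reaching `min_on_target` on two or more chromosomes are called
#' `multi_target`; windows identical to the consensus are
#' `consensus_like` and never specific. Windows meeting none of these are
#' omitted.
#'
#' @param profile a [kp_variant_profile()] object.
#' @param min_on_target minimum count on the best chromosome.
#' @param specificity_threshold minimum on-target fraction of total counts.
#' @return tibble of variant calls: `window`, `offset`, `target_chrom`,
#'   `on_target_count`, `off_target_count`, `polymorphic_positions`
#'   (list column of 0-based offsets within the window), `status`.
#' @export
kp_detect_variants <- function(profile, min_on_target = 5,
                               specificity_threshold = 0.95) {
  stopifnot(inherits(profile, "kp_variant_profile"))
  cons <- profile$consensus
  k <- profile$k
  per_window <- profile$counts |>
    group_by(.data$window, .data$offset) |>
    summarise(total = sum(.data$count),
              best = max(.data$count),
              target_chrom = .data$chrom[order(-.data$count, .data$chrom)][1],
              n_abundant = sum(.data$count >= min_on_target),
              .groups = "drop")
  calls <- per_window |>
    filter(.data$offset + k <= nchar(cons)) |>
    mutate(
      cons_window = str_sub(cons, .data$offset + 1, .data$offset + k),
      consensus_like = .data$window == .data$cons_window,
      status = case_when(
        consensus_like ~ "consensus_like",
        n_abundant >= 2 ~ "multi_target",
        best >= min_on_target & best / total >= specificity_threshold ~ "specific",
        TRUE ~ NA_character_
      )
    ) |>
    filter(!is.na(.data$status))
  if (nrow(calls) == 0) {
    return(tibble(window = character(), offset = integer(),
                  target_chrom = character(), on_target_count = integer(),
                  off_target_count = integer(),
                  polymorphic_positions = list(), status = character()))
  }
  calls |>
    mutate(
      polymorphic_positions = map2(.data$window, .data$cons_window, function(w, cw) {
        which(seq_as_chars(w) != seq_as_chars(cw)) - 1L
      }),
      on_target_count = as.integer(.data$best),
      off_target_count = as.integer(.data$total - .data$best)
    ) |>
    select("window", "offset", "target_chrom", "on_target_count",
           "off_target_count", "polymorphic_positions", "status") |>
    arrange(.data$status, .data$target_chrom, .data$offset, .data$window)
}
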