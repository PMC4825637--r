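# BAC anchoring: turn filtered end-sequence hits into anchored clone
# intervals and select chromosome-specific single/low-copy FISH candidates.

#' Anchoring and selection criteria for BAC clones
#'
#' Defaults follow the published in-silico selection: identity strictly
#' above 99%, query coverage strictly above 90%, end pairs in opposite
#' orientations separated by 50-200 kb (inclusive), and candidates with
#' repeat content strictly below 20%.
#'
#' @param min_identity percent identity threshold (strict `>`).
#' @param min_query_coverage percent query coverage threshold (strict `>`).
#' @param span_min,span_max allowed outer span of the anchored insert, bp
#'   (inclusive bounds).
#' @param max_repeat_content repeat-content ceiling for candidates, percent
#'   (strict `<`).
#' @return a named list of class `kp_criteria`.
#' @export
kp_anchor_criteria <- function(min_identity = 99, min_query_coverage = 90,
                               span_min = 50000, span_max = 200000,
                               max_repeat_content = 20) {
  stopifnot(span_min > 0, span_min < span_max,
            min_identity >= 0, min_identity <= 100,
            min_query_coverage >= 0, min_query_coverage <= 100,
            max_repeat_content >= 0, max_repeat_content <= 100)
  structure(list(min_identity = min_identity,
                 min_query_coverage = min_query_coverage,
                 span_min = span_min, span_max = span_max,
                 max_repeat_content = max_repeat_content),
            class = "kp_criteria")
}

#' Filter alignment hits on identity and query coverage
#'
#' Keeps hits with `percent_identity > min_identity` and coverage
#' (`alignment_length / query_length`, as percent) `> min_query_coverage`.
#' Both inequalities are strict. Input order is preserved.
#'
#' @param hits hit tibble from [kp_read_hits()]; `query_length` must be set.
#' @param criteria a [kp_anchor_criteria()] list.
#' @return the filtered hit tibble with an added `query_coverage` column.
#' @export
kp_filter_hits <- function(hits, criteria = kp_anchor_criteria()) {
  if (nrow(hits) > 0 && anyNA(hits$query_length)) {
    abort(sprintf("hit without query_length for query: %s",
                  hits$query_id[is.na(hits$query_length)][1]))
  }
  hits |>
    mutate(query_coverage = 100 * .data$alignment_length / .data$query_length) |>
    filter(.data$percent_identity > criteria$min_identity,
           .data$query_coverage > criteria$min_query_coverage)
}

#' Insert length of an anchored clone
#'
#' Coordinates are 1-based inclusive, so the length is
#' `last_base - first_base + 1`.
#'
#' @param first_base,last_base 1-based inclusive coordinates.
#' @return integer insert length in bp (vectorized).
#' @export
#' @examples
#' kp_insert_length(51533991, 51677621) # 143631
kp_insert_length <- function(first_base, last_base) {
  if (any(first_base > last_base)) abort("first_base > last_base")
  as.integer(last_base - first_base + 1)
}

#' Physical position of a clone along its pseudo-chromosome
#'
#' The midpoint of first and last base as a percent of the total
#' pseudo-chromosome length: `100 * ((first + last) / 2) / chrom_length`.
#'
#' @param first_base,last_base 1-based inclusive coordinates.
#' @param chrom_length pseudo-chromosome length, bp.
#' @return percent position (vectorized).
#' @export
kp_physical_position <- function(first_base, last_base, chrom_length) {
  if (any(chrom_length <= 0)) abort("chrom_length must be positive")
  if (any(first_base < 1 | first_base > last_base | last_base > chrom_length)) {
    abort("need 1 <= first_base <= last_base <= chrom_length")
  }
  100 * ((first_base + last_base) / 2) / chrom_length
}

#' Anchor BAC clones from filtered end-sequence hits
#'
#' For each clone, every pair of one hit per end on the same chromosome is
#' accepted when the two hits are on opposite strands, the plus-strand hit
#' lies upstream of the minus-strand hit (the two ends face inward, as a
#' cloned insert requires), and the outer span
#' `max(subject_end) - min(subject_start) + 1` falls inside
#' `[span_min, span_max]` (inclusive). The anchored interval is the outer
#' span. Clones with more than one qualifying placement are kept but
#' flagged `ambiguous`; chromosome specificity requires a unique placement,
#' so [kp_select_candidates()] drops them.
#'
#' @param hits filtered hit tibble (see [kp_filter_hits()]).
#' @param pairs tibble with columns `clone_id`, `forward_end_id`,
#'   `reverse_end_id` mapping clones to their two end-sequence ids.
#' @param criteria a [kp_anchor_criteria()] list.
#' @return tibble of anchors with columns `clone_id`, `chrom`,
#'   `first_base`, `last_base`, `insert_length`, `ambiguous`, ordered by
#'   (chrom, first_base, clone_id).
#' @export
kp_pair_bac_ends <- function(hits, pairs, criteria = kp_anchor_criteria()) {
  stopifnot(all(c("clone_id", "forward_end_id", "reverse_end_id") %in% names(pairs)))
  if (any(pairs$forward_end_id == pairs$reverse_end_id)) {
    abort("a clone's two end ids must differ")
  }
  one_clone <- function(clone_id, forward_end_id, reverse_end_id) {
    hf <- hits[hits$query_id == forward_end_id, , drop = FALSE]
    hr <- hits[hits$query_id == reverse_end_id, , drop = FALSE]
    if (nrow(hf) == 0 || nrow(hr) == 0) return(NULL)
    grid <- tidyr::expand_grid(i = seq_len(nrow(hf)), j = seq_len(nrow(hr)))
    f <- hf[grid$i, ]
    r <- hr[grid$j, ]
    same_chrom <- f$subject_id == r$subject_id
    opposite <- f$strand != r$strand
    # coordinates of the plus / minus member of each putative pair
    plus_start <- if_else(f$strand == "+", f$subject_start, r$subject_start)
    minus_start <- if_else(f$strand == "-", f$subject_start, r$subject_start)
    inward <- plus_start <= minus_start
    first_base <- pmin(f$subject_start, r$subject_start)
    last_base <- pmax(f$subject_end, r$subject_end)
    span <- last_base - first_base + 1
    ok <- same_chrom & opposite & inward &
      span >= criteria$span_min & span <= criteria$span_max
    if (!any(ok)) return(NULL)
    tibble(clone_id = clone_id, chrom = f$subject_id[ok],
           first_base = as.integer(first_base[ok]),
           last_base = as.integer(last_base[ok]),
           insert_length = as.integer(span[ok]))
  }
  anchors <- bind_rows(pmap(pairs[c("clone_id", "forward_end_id", "reverse_end_id")],
                            one_clone))
  if (nrow(anchors) == 0) {
    return(tibble(clone_id = character(), chrom = character(),
                  first_base = integer(), last_base = integer(),
                  insert_length = integer(), ambiguous = logical()))
  }
  anchors |>
    distinct() |>
    group_by(.data$clone_id) |>
    mutate(ambiguous = n() > 1) |>
    ungroup() |>
    arrange(.data$chrom, .data$first_base, .data$clone_id)
}

#' Select chromosome-specific FISH candidate clones
#'
#' Drops anchors that are ambiguous (multiple placements), have repeat
#' content at or above the ceiling, or overlap any tandem repeat; the
#' survivors are ranked by how close their physical position lies to the
#' nearer chromosome end (`min(p, 100 - p)`, ascending). Proximity to the
#' end is a ranking preference, not a hard filter.
#'
#' @param anchors anchor tibble with `repeat_content`, `tandem_hit` and
#'   `physical_position_percent` populated (see [kp_annotate_anchors()]).
#' @param criteria a [kp_anchor_criteria()] list.
#' @return the retained anchors, ranked, with an `end_distance` column.
#' @export
kp_select_candidates <- function(anchors, criteria = kp_anchor_criteria()) {
  needed <- c("repeat_content", "tandem_hit", "physical_position_percent")
  missing_col <- setdiff(needed, names(anchors))
  if (length(missing_col) > 0) {
    abort(sprintf("anchors missing column(s): %s", paste(missing_col, collapse = ", ")))
  }
  if (anyNA(anchors$repeat_content)) {
    abort(sprintf("anchor missing repeat_content: %s",
                  anchors$clone_id[is.na(anchors$repeat_content)][1]))
  }
  ambiguous <- anchors[["ambiguous"]] %||% rep(FALSE, nrow(anchors))
  anchors |>
    filter(!ambiguous,
           .data$repeat_content < criteria$max_repeat_content,
           !.data$tandem_hit) |>
    mutate(end_distance = pmin(.data$physical_position_percent,
                               100 - .data$physical_position_percent)) |>
    arrange(.data$end_distance, .data$clone_id)
}

#' Annotate anchors with repeat content, tandem overlap and position
#'
#' Extracts each anchored interval from the genome, screens it against the
#' repeat library plus the low-complexity mask, and fills in
#' `repeat_content`, `tandem_hit` and `physical_position_percent`.
#'
#' @param anchors anchor tibble from [kp_pair_bac_ends()].
#' @param genome sequence tibble of pseudo-chromosomes.
#' @param library repeat library tibble (`id`, `seq`, `class`); see
#'   [kp_mask_with_library()].
#' @param ... passed to [kp_repeat_screen()].
#' @return the anchor tibble with the three columns added.
#' @export
kp_annotate_anchors <- function(anchors, genome, library, ...) {
  assert_seq_tbl(genome, "genome")
  chrom_len <- stats::setNames(nchar(genome$seq), genome$id)
  unknown <- setdiff(anchors$chrom, genome$id)
  if (length(unknown) > 0) {
    abort(sprintf("anchor on unknown chromosome: %s", unknown[1]))
  }
  if (nrow(anchors) == 0) {
    return(mutate(anchors, repeat_content = numeric(), tandem_hit = logical(),
                  physical_position_percent = numeric()))
  }
  inserts <- tibble(
    id = paste0(anchors$clone_id, "#", seq_len(nrow(anchors))),
    seq = str_sub(stats::setNames(genome$seq, genome$id)[anchors$chrom],
                  anchors$first_base, anchors$last_base)
  )
  screen <- kp_repeat_screen(inserts, library, ...)
  ord <- match(inserts$id, screen$id)
  anchors |>
    mutate(repeat_content = screen$repeat_content[ord],
           tandem_hit = screen$tandem_hit[ord],
           physical_position_percent = kp_physical_position(
             .data$first_base, .data$last_base, chrom_len[.data$chrom]))
}
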