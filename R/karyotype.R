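# Karyotype signal model: per-chromosome, per-position-class, per-channel
# intensity records. A chromosome's signature is the set of
# (position_class, channel, intensity) triples it shows — probes sharing a
# fluorophore at the same locus are physically confounded in imaging, so
# signatures are built from channels, never probe identities.

POSITION_CLASSES <- c("centromere", "subtelomere_S", "subtelomere_L",
                      "arm_S", "arm_L")
CHANNELS <- c("green", "red", "blue")

#' Construct a karyotype map from per-probe signal assignments
#'
#' Assignments record, per probe, which chromosome and position class it
#' marks and at what intensity. Records with intensity "none" are dropped;
#' same-channel signals at the same locus merge to the maximum intensity,
#' with provenance (contributing probe names) retained.
#'
#' @param genotype accession/species label.
#' @param chromosomes character vector of chromosome ids (display order).
#' @param assignments tibble with columns `probe`, `channel`, `chrom`,
#'   `position_class` (centromere, subtelomere_S, subtelomere_L, arm_S,
#'   arm_L), `intensity` (none/weak/medium/strong).
#' @param assumptions,annotations optional character vectors of free-text
#'   notes (e.g. fixture assumptions, heterozygosity observations).
#' @return an object of class `kp_karyotype`.
#' @export
kp_karyotype <- function(genotype, chromosomes, assignments,
                         assumptions = character(), annotations = character()) {
  stopifnot(is.character(genotype), length(genotype) == 1,
            is.character(chromosomes), length(chromosomes) >= 1)
  need <- c("probe", "channel", "chrom", "position_class", "intensity")
  stopifnot(is.data.frame(assignments), all(need %in% names(assignments)))
  unknown <- setdiff(unique(assignments$chrom), chromosomes)
  if (length(unknown) > 0) {
    abort(sprintf("assignment to unknown chromosome: %s", unknown[1]))
  }
  bad_pc <- setdiff(unique(assignments$position_class), POSITION_CLASSES)
  if (length(bad_pc) > 0) abort(sprintf("unknown position class: %s", bad_pc[1]))
  bad_in <- setdiff(unique(assignments$intensity), INTENSITY_LEVELS)
  if (length(bad_in) > 0) abort(sprintf("unknown intensity: %s", bad_in[1]))
  bad_ch <- setdiff(unique(assignments$channel), CHANNELS)
  if (length(bad_ch) > 0) abort(sprintf("unknown channel: %s", bad_ch[1]))
  assignments <- filter(as_tibble(assignments), .data$intensity != "none")
  obj <- structure(
    list(genotype = genotype, chromosomes = chromosomes,
         assignments = assignments,
         records = merge_signals(assignments),
         assumptions = assumptions, annotations = annotations),
    class = "kp_karyotype")
  obj
}

merge_signals <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(tibble(chrom = character(), position_class = character(),
                  channel = character(), intensity = character(),
                  probes = list()))
  }
  assignments |>
    group_by(.data$chrom, .data$position_class, .data$channel) |>
    summarise(
      intensity = INTENSITY_LEVELS[max(intensity_ord(.data$intensity)) + 1L],
      probes = list(sort(unique(.data$probe))),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$position_class, .data$channel)
}

#' @export
print.kp_karyotype <- function(x, ...) {
  cat(sprintf("<kp_karyotype> %s: %d chromosomes, %d signal records from %d probe(s)\n",
              x$genotype, length(x$chromosomes), nrow(x$records),
              length(unique(x$assignments$probe))))
  invisible(x)
}

#' Project a probe cocktail onto a karyotype map
#'
#' @param cocktail a [kp_cocktail()] (provides each probe's channel).
#' @param locus_assignments tibble with `probe`, `chrom`,
#'   `position_class`, `intensity`.
#' @param genotype accession label for the resulting map.
#' @param chromosomes chromosome id vector; defaults to the ids seen in
#'   the assignments, sorted.
#' @param ... passed on to [kp_karyotype()].
#' @return a `kp_karyotype`.
#' @export
kp_project_cocktail <- function(cocktail, locus_assignments, genotype = "map",
                                chromosomes = NULL, ...) {
  stopifnot(inherits(cocktail, "kp_cocktail"))
  unknown <- setdiff(unique(locus_assignments$probe), cocktail$name)
  if (length(unknown) > 0) abort(sprintf("assignment for unknown probe: %s", unknown[1]))
  channel <- stats::setNames(cocktail$channel, cocktail$name)
  assignments <- locus_assignments |>
    mutate(channel = unname(channel[.data$probe])) |>
    select("probe", "channel", "chrom", "position_class", "intensity")
  if (is.null(chromosomes)) chromosomes <- sort(unique(assignments$chrom))
  kp_karyotype(genotype, chromosomes, assignments, ...)
}

#' How many chromosomes does a probe subset distinguish?
#'
#' Restricts the map to signals contributed by `probes` (all probes when
#' NULL), re-merges channel signals, and partitions chromosomes by
#' identical signature (the set of position-class/channel/intensity
#' triples). A chromosome is distinguishable when its signature is unique.
#' Chromosomes with no signal share the empty signature.
#'
#' @param map a `kp_karyotype`.
#' @param probes optional character vector of probe names.
#' @return list with `count` (number of uniquely identifiable
#'   chromosomes), `groups` (partition of chromosomes by signature, in map
#'   chromosome order), and `signatures` (tibble `chrom`, `signature`).
#' @export
kp_distinguishable <- function(map, probes = NULL) {
  stopifnot(inherits(map, "kp_karyotype"))
  asn <- map$assignments
  if (!is.null(probes)) {
    unknown <- setdiff(probes, unique(asn$probe))
    if (length(unknown) > 0) abort(sprintf("unknown probe in subset: %s", unknown[1]))
    asn <- filter(asn, .data$probe %in% probes)
  }
  records <- merge_signals(asn)
  sig_of <- vapply(map$chromosomes, function(ch) {
    r <- records[records$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0) return("")
    paste(sort(sprintf("%s|%s|%s", r$position_class, r$channel, r$intensity)),
          collapse = ";")
  }, character(1))
  groups <- split(map$chromosomes, factor(sig_of, levels = unique(sig_of[map$chromosomes])))
  groups <- unname(groups[order(vapply(groups, function(g)
    match(g[1], map$chromosomes), integer(1)))])
  unique_chroms <- unlist(groups[lengths(groups) == 1])
  list(count = length(unique_chroms),
       groups = groups,
       signatures = tibble(chrom = map$chromosomes, signature = unname(sig_of)))
}

#' Diff two karyotype maps
#'
#' Compares merged signal records keyed by (chromosome, position class,
#' channel). A record present only in `b` is a `gain`, only in `a` a
#' `loss`, present in both at different intensities an
#' `intensity_change`.
#'
#' @param a,b `kp_karyotype` objects.
#' @param correspondence optional named character vector mapping `b`
#'   chromosome ids onto `a` ids when the id spaces differ.
#' @return tibble with `chrom`, `position_class`, `channel`,
#'   `intensity_a`, `intensity_b`, `kind`.
#' @export
kp_compare_karyotypes <- function(a, b, correspondence = NULL) {
  stopifnot(inherits(a, "kp_karyotype"), inherits(b, "kp_karyotype"))
  rb <- b$records
  if (!is.null(correspondence)) {
    unmapped <- setdiff(unique(rb$chrom), names(correspondence))
    if (length(unmapped) > 0) abort(sprintf("no correspondence for chromosome: %s", unmapped[1]))
    rb$chrom <- unname(correspondence[rb$chrom])
  } else if (!setequal(a$chromosomes, b$chromosomes)) {
    abort("chromosome sets differ; supply a `correspondence`")
  }
  key <- c("chrom", "position_class", "channel")
  full_join(
    select(a$records, all_of(key), intensity_a = "intensity"),
    select(rb, all_of(key), intensity_b = "intensity"),
    by = key
  ) |>
    filter(is.na(.data$intensity_a) | is.na(.data$intensity_b) |
             .data$intensity_a != .data$intensity_b) |>
    mutate(kind = case_when(
      is.na(intensity_a) ~ "gain",
      is.na(intensity_b) ~ "loss",
      TRUE ~ "intensity_change"
    )) |>
    arrange(.data$chrom, .data$position_class, .data$channel)
}

#' Write a karyotype map to JSON
#'
#' @param map a `kp_karyotype`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
kp_write_karyotype <- function(map, path) {
  stopifnot(inherits(map, "kp_karyotype"))
  payload <- list(
    genotype = map$genotype,
    chromosomes = map$chromosomes,
    assignments = map$assignments,
    assumptions = map$assumptions,
    annotations = map$annotations
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a karyotype map from JSON
#'
#' @param path path to a karyotype JSON written by [kp_write_karyotype()]
#'   (or a bundled fixture file).
#' @return a `kp_karyotype`.
#' @export
kp_read_karyotype <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kp_karyotype(
    genotype = x$genotype,
    chromosomes = as.character(x$chromosomes),
    assignments = as_tibble(x$assignments),
    assumptions = as.character(x$assumptions %||% character()),
    annotations = as.character(x$annotations %||% character())
  )
}

#' Bundled karyotype fixtures
#'
#' Encoded signal tables for the seven genotypes of the common bean
#' karyotyping study: landraces G19833 (Andean) and BAT93 (Mesoamerican),
#' wild accessions G23580 (Andean) and PI535416 (Mesoamerican), and
#' P. coccineus, P. dumosus and P. acutifolius. `g19833_fig1` is a variant
#' of G19833 encoding the occasionally ambiguous appearance in which the
#' subtelomeric/rDNA signals do not discriminate chromosomes 1, 3 and 7.
#' Signal placements not stated in prose are fixture assumptions, listed
#' in each map's `assumptions` field.
#'
#' @param name fixture name; call with no argument to list the available
#'   names.
#' @return a `kp_karyotype`, or a character vector of names.
#' @export
kp_karyotype_fixture <- function(name = NULL) {
  dir <- system.file("extdata", "karyotypes", package = "karyoprobe")
  avail <- sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
  if (is.null(name)) return(avail)
  if (!name %in% avail) {
    abort(sprintf("unknown fixture '%s' (available: %s)", name,
                  paste(avail, collapse = ", ")))
  }
  kp_read_karyotype(file.path(dir, paste0(name, ".json")))
}
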