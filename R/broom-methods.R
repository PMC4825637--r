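# tidy()/glance() methods for the package's fitted/constructed objects,
# following the broom convention: tidy() returns the per-record table,
# glance() a one-row summary.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn kp_karyotype tidy(): the merged signal records, one row per
#'   (chromosome, position class, channel), with a `genotype` column.
#' @param x a `kp_karyotype`.
#' @param ... unused.
#' @export
tidy.kp_karyotype <- function(x, ...) {
  mutate(x$records, genotype = x$genotype, .before = 1)
}

#' @describeIn kp_karyotype glance(): one-row summary with the number of
#'   chromosomes, probes, signal records and distinguishable chromosomes
#'   under the full probe set.
#' @export
glance.kp_karyotype <- function(x, ...) {
  d <- kp_distinguishable(x)
  tibble(genotype = x$genotype,
         n_chromosomes = length(x$chromosomes),
         n_probes = length(unique(x$assignments$probe)),
         n_records = nrow(x$records),
         n_distinguishable = d$count)
}

#' @describeIn kp_variant_profile tidy(): the per-chromosome window count
#'   table.
#' @param x a `kp_variant_profile`.
#' @param ... unused.
#' @export
tidy.kp_variant_profile <- function(x, ...) {
  x$counts
}

#' @describeIn kp_variant_profile glance(): one-row summary of the
#'   profile.
#' @export
glance.kp_variant_profile <- function(x, ...) {
  tibble(k = x$k,
         n_windows = length(unique(x$counts$window)),
         n_chromosomes = length(unique(x$counts$chrom)),
         total_count = sum(x$counts$count),
         consensus_length = nchar(x$consensus))
}

#' @describeIn kp_cocktail glance(): probe, channel and conflict counts.
#' @param x a `kp_cocktail`.
#' @param ... unused.
#' @export
glance.kp_cocktail <- function(x, ...) {
  tibble(n_probes = nrow(x),
         n_channels = length(unique(x$channel)),
         n_conflicts = nrow(kp_cocktail_conflicts(x)))
}
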