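test_that("projecting a cocktail merges same-channel co-located signals to the max", {
  mix <- kp_cocktail(tibble::tibble(
    name = c("CentPv1", "CentPv1_A", "redA", "redB"),
    channel = c("blue", "green", "red", "red"),
    target = "centromere",
    target_chroms = list(paste0("chr", c(1:4, 7:10)), "chr8", "chr5", "chr6")))
  asn <- dplyr::bind_rows(
    tibble::tibble(probe = "CentPv1",
                   chrom = paste0("chr", c(1, 3, 4, 7)),
                   position_class = "centromere", intensity = "strong"),
    tibble::tibble(probe = "CentPv1",
                   chrom = paste0("chr", c(2, 8, 9, 10)),
                   position_class = "centromere", intensity = "medium"),
    tibble::tibble(probe = "CentPv1_A", chrom = "chr8",
                   position_class = "centromere", intensity = "medium"),
    tibble::tibble(probe = c("redA", "redB"), chrom = "chr5",
                   position_class = "centromere",
                   intensity = c("weak", "strong")))
  map <- kp_project_cocktail(mix, asn, genotype = "toy",
                             chromosomes = paste0("chr", 1:10))
  # chr8 carries blue medium + green medium at the centromere
  chr8 <- map$records[map$records$chrom == "chr8", ]
  expect_setequal(paste(chr8$channel, chr8$intensity),
                  c("blue medium", "green medium"))
  # two red probes at cen5 (weak + strong) merge to one strong record
  chr5 <- map$records[map$records$chrom == "chr5", ]
  expect_equal(nrow(chr5), 1)
  expect_equal(chr5$intensity, "strong")
  expect_setequal(chr5$probes[[1]], c("redA", "redB"))

  # empty cocktail -> empty map
  empty_mix <- kp_cocktail(tibble::tibble(name = character(),
                                          channel = character(),
                                          target = character(),
                                          target_chroms = list()))
  empty <- kp_project_cocktail(empty_mix, asn[0, ], chromosomes = "chr1")
  expect_equal(nrow(empty$records), 0)

  expect_error(
    kp_project_cocktail(mix, dplyr::mutate(asn, chrom = "chrX"),
                        chromosomes = paste0("chr", 1:10)),
    "unknown chromosome")
})

test_that("the reference karyotype distinguishes 4 chromosomes with four probes and 11 with six", {
  map <- kp_karyotype_fixture("g19833")
  four <- kp_distinguishable(map, four_probe_mix)
  expect_equal(four$count, 4)
  expect_setequal(unlist(four$groups[lengths(four$groups) == 1]),
                  paste0("chr", c(5, 6, 8, 11)))
  six <- kp_distinguishable(map, six_probe_mix)
  expect_equal(six$count, 11)

  none <- kp_distinguishable(map, character(0))
  expect_equal(none$count, 0)
  expect_equal(none$groups, list(paste0("chr", 1:11)))
  expect_error(kp_distinguishable(map, "nonexistent_probe"), "unknown probe")
})

test_that("distinguishability grows monotonically as probes are added", {
  map <- kp_karyotype_fixture("g19833")
  probes <- c("CentPv1", "CentPv2", "CentPv1_A", "CentPv2_A", "khipu",
              "5S_rDNA", "CentPv1_B", "BAC_0100C06")
  counts <- vapply(seq_along(probes), function(i)
    kp_distinguishable(map, probes[1:i])$count, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("distinguishability is invariant under chromosome relabelling", {
  map <- kp_karyotype_fixture("g19833")
  relabel <- stats::setNames(paste0("K", 11:1), paste0("chr", 1:11))
  asn <- dplyr::mutate(map$assignments, chrom = unname(relabel[chrom]))
  map2 <- kp_karyotype("relabelled", unname(relabel[map$chromosomes]), asn)
  d1 <- kp_distinguishable(map, six_probe_mix)
  d2 <- kp_distinguishable(map2, six_probe_mix)
  expect_equal(d2$count, d1$count)
  # group structure maps through the relabelling
  g1 <- lapply(d1$groups, function(g) sort(unname(relabel[g])))
  g2 <- lapply(d2$groups, sort)
  expect_setequal(vapply(g1, paste, "", collapse = ","),
                  vapply(g2, paste, "", collapse = ","))
})

test_that("without the chr3 variant and chr7 BAC probes the ambiguous fixture confuses 1, 3 and 7", {
  map <- kp_karyotype_fixture("g19833_fig1")
  six <- kp_distinguishable(map, six_probe_mix)   # no CentPv1_B, no BAC
  confusable <- six$groups[lengths(six$groups) > 1]
  expect_equal(length(confusable), 1)
  expect_setequal(confusable[[1]], paste0("chr", c(1, 3, 7)))
  # the full final cocktail resolves them
  expect_equal(kp_distinguishable(map)$count, 11)
})

test_that("wild accessions are fully distinguished except chromosomes 1 and 4", {
  for (name in c("g23580", "pi535416")) {
    d <- kp_distinguishable(kp_karyotype_fixture(name))
    expect_equal(d$count, 9)
    confusable <- d$groups[lengths(d$groups) > 1]
    expect_equal(length(confusable), 1)
    expect_setequal(confusable[[1]], c("chr1", "chr4"))
  }
})

test_that("encoded centromere counts match the published distributions", {
  cen_count <- function(map, probe) {
    asn <- map$assignments
    length(unique(asn$chrom[asn$probe == probe &
                              asn$position_class == "centromere"]))
  }
  g <- kp_karyotype_fixture("g19833")
  expect_equal(cen_count(g, "CentPv1"), 8)
  expect_equal(cen_count(g, "CentPv2"), 3)
  expect_equal(cen_count(g, "CentPv1_A"), 1)
  expect_equal(cen_count(g, "CentPv1_B"), 1)
  cocc <- kp_karyotype_fixture("coccineus")
  expect_equal(cen_count(cocc, "CentPv1"), 5)
  expect_equal(cen_count(cocc, "CentPv2"), 1)
  acut <- kp_karyotype_fixture("acutifolius")
  expect_equal(cen_count(acut, "CentPv1"), 2)
  expect_equal(cen_count(acut, "CentPv2"), 0)
})

test_that("karyotype diffs report gains, losses and intensity changes", {
  g19833 <- kp_karyotype_fixture("g19833")
  pi <- kp_karyotype_fixture("pi535416")
  d <- kp_compare_karyotypes(g19833, pi)
  cen5 <- d[d$chrom == "chr5" & d$position_class == "centromere" &
              d$channel == "red", ]
  expect_equal(cen5$kind, "intensity_change")
  expect_equal(c(cen5$intensity_a, cen5$intensity_b), c("medium", "strong"))

  g23580 <- kp_karyotype_fixture("g23580")
  d2 <- kp_compare_karyotypes(g19833, g23580)
  k4 <- d2[d2$chrom == "chr4" & d2$position_class == "subtelomere_S", ]
  expect_equal(k4$kind, "intensity_change")
  expect_equal(c(k4$intensity_a, k4$intensity_b), c("strong", "weak"))

  # a record present on only one side is a loss/gain
  expect_true(any(d2$kind %in% c("gain", "loss")))
  # self-diff is empty
  expect_equal(nrow(kp_compare_karyotypes(g19833, g19833)), 0)
  # incomparable chromosome sets need a correspondence
  cocc <- kp_karyotype_fixture("coccineus")
  expect_error(kp_compare_karyotypes(g19833, cocc), "correspondence")
  corr <- stats::setNames(paste0("chr", 1:11), paste0("pc", 1:11))
  expect_s3_class(kp_compare_karyotypes(g19833, cocc, corr), "tbl_df")
})

test_that("karyotype maps round-trip through JSON", {
  map <- kp_karyotype_fixture("g19833")
  path <- tempfile(fileext = ".json")
  kp_write_karyotype(map, path)
  back <- kp_read_karyotype(path)
  expect_equal(back$genotype, map$genotype)
  expect_equal(back$chromosomes, map$chromosomes)
  expect_equal(back$records, map$records)
  expect_equal(back$assumptions, map$assumptions)
})

test_that("tidy/glance/autoplot surfaces work on karyotype objects", {
  map <- kp_karyotype_fixture("g19833")
  td <- generics::tidy(map)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$genotype[1], "G19833")
  gl <- generics::glance(map)
  expect_equal(gl$n_chromosomes, 11)
  expect_equal(gl$n_distinguishable, 11)
  p <- ggplot2::autoplot(map)
  expect_s3_class(p, "ggplot")
})
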