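# Small genomes keep these structural checks fast; the full-size
# parameter-recovery runs live in the acceptance suite.
small_spec <- function(...) {
  kp_genome_spec(n_chroms = 3, chrom_length = 60000,
                 monomers_per_centromere = 40,
                 subtelomeric_copies = c("chr2:S" = 0),
                 subtelomeric_default = 10, ...)
}

test_that("genome generation is byte-deterministic for a fixed seed", {
  g1 <- kp_generate_genome(small_spec(seed = 5))
  g2 <- kp_generate_genome(small_spec(seed = 5))
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth$arrays, g2$truth$arrays)
  p1 <- write_fasta_tmp(g1$genome); p2 <- write_fasta_tmp(g2$genome)
  expect_identical(readLines(p1), readLines(p2))
  g3 <- kp_generate_genome(small_spec(seed = 6))
  expect_false(identical(g1$genome$seq, g3$genome$seq))
})

test_that("planted arrays and variants appear where the truth table says", {
  spec <- small_spec(seed = 7, planted_variants = tibble::tibble(
    chrom = "chr3", offsets = list(c(10L, 20L)), fraction = 1.0))
  gen <- kp_generate_genome(spec)
  tr <- gen$truth
  # arrays sit mid-chromosome / within 5% of the ends
  cen <- tr$arrays[tr$arrays$class == "centromere", ]
  expect_true(all(abs((cen$start + cen$end) / 2 - 30000) < 3000))
  sub <- tr$arrays[startsWith(tr$arrays$class, "subtelomere"), ]
  edge <- 0.05 * 60000
  expect_true(all(sub$end <= edge | sub$start >= 60000 - edge))
  # no subtelomeric array was planted on chr2's short arm
  expect_false(any(sub$chrom == "chr2" & sub$class == "subtelomere_S"))
  chr2 <- gen$genome$seq[gen$genome$id == "chr2"]
  first_half <- substr(chr2, 1, 30000)
  expect_false(grepl(tr$subtelomeric_consensus, first_half, fixed = TRUE))

  # fraction 1.0: every chr3 monomer carries the variant
  cen3 <- cen[cen$chrom == "chr3", ]
  arr3 <- substr(gen$genome$seq[gen$genome$id == "chr3"], cen3$start, cen3$end)
  monos <- kp_extract_monomers(arr3, tr$satellite_consensus)
  expect_equal(nrow(monos), 40)
  expect_true(all(monos$monomer == tr$variants$variant_monomer))
})

test_that("generated BAC libraries respect the insert range and record truth", {
  spec <- kp_genome_spec(n_chroms = 2, chrom_length = 150000,
                         subtelomeric_default = 5, seed = 8)
  gen <- kp_generate_genome(spec)
  lib <- kp_generate_bac_library(gen$genome, n_clones = 30,
                                 insert_range = c(20000, 60000),
                                 end_length = 300, seed = 9)
  expect_equal(nrow(lib$truth), 30)
  expect_true(all(lib$truth$insert_length >= 20000 &
                    lib$truth$insert_length <= 60000))
  expect_equal(lib$truth$insert_length,
               lib$truth$last_base - lib$truth$first_base + 1L)
  # end reads match the recorded placement
  i <- 1
  chrom_seq <- gen$genome$seq[gen$genome$id == lib$truth$chrom[i]]
  expect_equal(lib$ends$seq[lib$ends$id == paste0(lib$truth$clone_id[i], "_F")],
               substr(chrom_seq, lib$truth$first_base[i],
                      lib$truth$first_base[i] + 299))
  expect_equal(lib$ends$seq[lib$ends$id == paste0(lib$truth$clone_id[i], "_R")],
               kp_revcomp(substr(chrom_seq, lib$truth$last_base[i] - 299,
                                 lib$truth$last_base[i])))
})

test_that("anchoring exact end alignments recovers the planted placements", {
  spec <- kp_genome_spec(n_chroms = 2, chrom_length = 150000,
                         subtelomeric_default = 5, seed = 10)
  gen <- kp_generate_genome(spec)
  lib <- kp_generate_bac_library(gen$genome, n_clones = 25,
                                 insert_range = c(20000, 60000),
                                 end_length = 300, seed = 11)
  hits <- kp_align_ends(lib$ends, gen$genome)
  crit <- kp_anchor_criteria(span_min = 20000, span_max = 60000)
  anchors <- kp_pair_bac_ends(kp_filter_hits(hits, crit), lib$pairs, crit)
  rec <- kp_evaluate_recovery(anchors, lib$truth,
                              keys = c("clone_id", "chrom", "first_base", "last_base"))
  expect_gte(rec$recall, 0.95)
  # clones whose ends land inside a satellite array match at many shifted
  # offsets; they are flagged ambiguous, and the unambiguous anchors are
  # exactly right
  clean <- anchors[!anchors$ambiguous, ]
  expect_equal(kp_evaluate_recovery(clean, lib$truth,
                                    keys = c("clone_id", "chrom", "first_base",
                                             "last_base"))$precision, 1)
})

test_that("a clone spanning the centromeric array is flagged by the repeat screen", {
  spec <- kp_genome_spec(n_chroms = 1, chrom_length = 100000,
                         monomers_per_centromere = 60,
                         subtelomeric_default = 5, seed = 12,
                         planted_variants = tibble::tibble(
                           chrom = character(), offsets = list(),
                           fraction = numeric()))
  gen <- kp_generate_genome(spec)
  cen <- gen$truth$arrays[gen$truth$arrays$class == "centromere", ]
  anchors <- tibble::tibble(clone_id = c("over_cen", "clear"),
                            chrom = "chr1",
                            first_base = c(cen$start - 2000L, 1000L),
                            last_base = c(cen$end + 2000L, 15000L),
                            insert_length = NA_integer_, ambiguous = FALSE)
  library <- tibble::tibble(id = "sat", seq = gen$truth$satellite_consensus,
                            class = "tandem:CentPv1")
  ann <- kp_annotate_anchors(anchors, gen$genome, library,
                             low_complexity = FALSE)
  expect_true(ann$tandem_hit[ann$clone_id == "over_cen"])
  expect_false(ann$tandem_hit[ann$clone_id == "clear"])
  expect_gt(ann$repeat_content[ann$clone_id == "over_cen"], 0)
})

test_that("recovery scoring counts exact matches", {
  truth <- tibble::tibble(id = paste0("t", 1:9), chrom = "chr1")
  calls <- truth
  r <- kp_evaluate_recovery(calls, truth)
  expect_equal(c(r$precision, r$recall), c(1, 1))
  r2 <- kp_evaluate_recovery(calls[0, ], truth)
  expect_equal(r2$recall, 0)
  r3 <- kp_evaluate_recovery(
    dplyr::bind_rows(truth, tibble::tibble(id = "bogus", chrom = "chr9")), truth)
  expect_equal(r3$precision, 0.9)
  expect_equal(r3$recall, 1)
})

test_that("anchoring recall degrades monotonically with end-read error", {
  spec <- kp_genome_spec(n_chroms = 2, chrom_length = 120000,
                         subtelomeric_default = 5, seed = 13)
  gen <- kp_generate_genome(spec)
  recall_at <- vapply(c(0, 0.01, 0.05), function(err) {
    lib <- kp_generate_bac_library(gen$genome, n_clones = 15,
                                   insert_range = c(20000, 50000),
                                   end_length = 200, error_rate = err, seed = 14)
    hits <- kp_align_ends(lib$ends, gen$genome, max_mismatch = 1)
    crit <- kp_anchor_criteria(span_min = 20000, span_max = 50000)
    anchors <- kp_pair_bac_ends(kp_filter_hits(hits, crit), lib$pairs, crit)
    kp_evaluate_recovery(anchors, lib$truth,
                         keys = c("clone_id", "chrom", "first_base", "last_base"))$recall
  }, numeric(1))
  expect_true(all(diff(recall_at) <= 0))
  expect_equal(recall_at[1], 1)
})
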