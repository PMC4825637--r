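# Seeded synthetic genomes with planted satellite arrays,
# chromosome-specific monomer variants, subtelomeric arrays with varying
# copy number, and BAC libraries with known truth. Every pipeline stage is
# testable against construction-time ground truth, with no external data.

#' Specification of a synthetic toy genome
#'
#' Defaults emulate the genome structure the karyotyping methods assume:
#' 11 chromosomes, a centromeric satellite array mid-chromosome on each, a
#' subtelomeric repeat array near each end with copy number elevated on
#' chromosome 4's short arm and chromosome 11's long arm (the two loci
#' that dominate subtelomeric signal in common bean landraces), i.i.d.
#' background at legume-like 38% GC, and one variant satellite planted on
#' chromosome 3 in 30% of its monomers — mirroring the one
#' chromosome-specific centromeric variant that a window-count screen is
#' expected to recover.
#'
#' @param n_chroms number of chromosomes (ids chr1..chrN).
#' @param chrom_length chromosome length, bp.
#' @param satellite_period centromeric satellite monomer length, bp.
#' @param monomers_per_centromere monomer copies per centromere; scalar or
#'   named per-chromosome vector.
#' @param planted_variants tibble with columns `chrom`, `offsets` (list of
#'   0-based polymorphic offsets within the monomer) and `fraction` of
#'   monomers carrying the variant, in (0, 1]. NULL (the default) plants
#'   one variant on chr3 at offsets 20/27/34 in 30% of monomers when the
#'   genome is large enough, else nothing.
#' @param subtelomeric_period subtelomeric repeat monomer length, bp.
#' @param subtelomeric_copies named vector of copies keyed "chrom:S" /
#'   "chrom:L" (unlisted arms fall back to `subtelomeric_default`).
#' @param subtelomeric_default default subtelomeric copies per arm.
#' @param background_gc GC fraction of the background sequence.
#' @param satellite_consensus,subtelomeric_consensus optional explicit
#'   consensus sequences; drawn from the seed when NULL.
#' @param seed integer seed controlling all randomness.
#' @return a list of class `kp_genome_spec`.
#' @export
kp_genome_spec <- function(n_chroms = 11, chrom_length = 400000,
                           satellite_period = 50,
                           monomers_per_centromere = 40,
                           planted_variants = NULL,
                           subtelomeric_period = 32,
                           subtelomeric_copies = c("chr4:S" = 60, "chr11:L" = 40),
                           subtelomeric_default = 15,
                           background_gc = 0.38,
                           satellite_consensus = NULL,
                           subtelomeric_consensus = NULL,
                           seed = 42) {
  stopifnot(n_chroms >= 1, chrom_length >= 1000, satellite_period >= 10,
            background_gc > 0, background_gc < 1)
  chroms <- paste0("chr", seq_len(n_chroms))
  if (is.null(planted_variants)) {
    # default study condition: one variant on chr3 at 30% of monomers,
    # polymorphic at three offsets close enough for one window to span
    planted_variants <- if (n_chroms >= 3 && satellite_period > 34) {
      tibble(chrom = "chr3", offsets = list(c(20L, 27L, 34L)), fraction = 0.3)
    } else {
      tibble(chrom = character(), offsets = list(), fraction = numeric())
    }
  }
  mpc <- if (length(monomers_per_centromere) == 1 && is.null(names(monomers_per_centromere))) {
    stats::setNames(rep(monomers_per_centromere, n_chroms), chroms)
  } else monomers_per_centromere
  if (nrow(planted_variants) > 0) {
    stopifnot(all(planted_variants$fraction > 0), all(planted_variants$fraction <= 1),
              all(planted_variants$chrom %in% chroms))
    for (o in planted_variants$offsets) {
      stopifnot(all(o >= 0), all(o < satellite_period))
    }
  }
  structure(list(
    n_chroms = n_chroms, chroms = chroms, chrom_length = chrom_length,
    satellite_period = satellite_period, monomers_per_centromere = mpc,
    planted_variants = planted_variants,
    subtelomeric_period = subtelomeric_period,
    subtelomeric_copies = subtelomeric_copies,
    subtelomeric_default = subtelomeric_default,
    background_gc = background_gc,
    satellite_consensus = satellite_consensus,
    subtelomeric_consensus = subtelomeric_consensus,
    seed = as.integer(seed)
  ), class = "kp_genome_spec")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute bases at 0-based offsets with a fixed transition map, so a
# variant monomer differs from the consensus at exactly those offsets
mutate_at_offsets <- function(s, offsets) {
  ch <- seq_as_chars(s)
  ch[offsets + 1L] <- chartr("ACGT", "GTAC", ch[offsets + 1L])
  paste(ch, collapse = "")
}

#' Generate a synthetic genome with planted arrays and known truth
#'
#' Deterministic for a fixed spec (the spec's seed drives all draws).
#' Centromeric arrays are placed mid-chromosome; subtelomeric arrays start
#' within the outer 5% of each chromosome end. Variant monomers carry
#' substitutions at the planted offsets in the specified fraction of
#' monomer copies (rounded), at seeded random positions within the array.
#'
#' @param spec a [kp_genome_spec()].
#' @return list with `genome` (sequence tibble) and `truth`, a list of:
#'   `satellite_consensus`, `subtelomeric_consensus`, `arrays` (tibble
#'   `chrom`, `class`, `start`, `end`), `variants` (tibble `chrom`,
#'   `offsets`, `fraction`, `n_variant`, `variant_monomer`).
#' @export
kp_generate_genome <- function(spec) {
  stopifnot(inherits(spec, "kp_genome_spec"))
  withr::with_seed(spec$seed, {
    sat_cons <- spec$satellite_consensus %||% random_dna(spec$satellite_period, 0.5)
    sub_cons <- spec$subtelomeric_consensus %||% random_dna(spec$subtelomeric_period, 0.5)
    L <- spec$chrom_length
    edge <- floor(0.05 * L)
    arrays <- list(); variants <- list()
    seqs <- character(spec$n_chroms)
    for (ci in seq_along(spec$chroms)) {
      ch <- spec$chroms[ci]
      chars <- seq_as_chars(random_dna(L, spec$background_gc))
      # subtelomeric arrays
      for (arm in c("S", "L")) {
        copies <- spec$subtelomeric_copies[paste0(ch, ":", arm)]
        if (is.na(copies)) copies <- spec$subtelomeric_default
        if (copies > 0) {
          alen <- copies * nchar(sub_cons)
          pad <- max(1L, floor(edge / 2))
          if (pad + alen > edge) {
            abort(sprintf("subtelomeric array exceeds the terminal region on %s arm %s", ch, arm))
          }
          start <- if (arm == "S") pad else L - pad - alen + 1L
          chars[start:(start + alen - 1L)] <-
            seq_as_chars(strrep(sub_cons, copies))
          arrays[[length(arrays) + 1L]] <-
            tibble(chrom = ch, class = paste0("subtelomere_", arm),
                   start = as.integer(start), end = as.integer(start + alen - 1L))
        }
      }
      # centromeric array
      n_mono <- spec$monomers_per_centromere[ch]
      if (is.na(n_mono)) n_mono <- 0
      if (n_mono > 0) {
        monos <- rep(sat_cons, n_mono)
        pv <- spec$planted_variants
        pv <- pv[pv$chrom == ch, , drop = FALSE]
        for (vi in seq_len(nrow(pv))) {
          n_var <- max(1L, round(pv$fraction[vi] * n_mono))
          idx <- sort(sample(n_mono, n_var))
          vm <- mutate_at_offsets(sat_cons, pv$offsets[[vi]])
          monos[idx] <- vm
          variants[[length(variants) + 1L]] <-
            tibble(chrom = ch, offsets = list(as.integer(pv$offsets[[vi]])),
                   fraction = pv$fraction[vi], n_variant = n_var,
                   variant_monomer = vm)
        }
        alen <- n_mono * nchar(sat_cons)
        start <- floor((L - alen) / 2) + 1L
        if (start <= edge || start + alen - 1L > L - edge) {
          abort(sprintf("centromeric array does not fit mid-chromosome on %s", ch))
        }
        chars[start:(start + alen - 1L)] <- seq_as_chars(paste(monos, collapse = ""))
        arrays[[length(arrays) + 1L]] <-
          tibble(chrom = ch, class = "centromere",
                 start = as.integer(start), end = as.integer(start + alen - 1L))
      }
      seqs[ci] <- paste(chars, collapse = "")
    }
    list(
      genome = tibble(id = spec$chroms, seq = seqs),
      truth = list(
        satellite_consensus = sat_cons,
        subtelomeric_consensus = sub_cons,
        arrays = bind_rows(arrays) |> arrange(.data$chrom, .data$start),
        variants = if (length(variants) > 0) bind_rows(variants) else
          tibble(chrom = character(), offsets = list(), fraction = numeric(),
                 n_variant = integer(), variant_monomer = character())
      )
    )
  })
}

#' Diagnostic truth windows of the planted variants
#'
#' All length-`k` windows of each planted variant monomer that cover at
#' least one planted polymorphic offset — exactly the windows a
#' chromosome-specific variant screen should call `specific`. The
#' `canonical` column marks, per variant, the window covering all planted
#' offsets with those offsets most central (the natural probe candidate).
#'
#' @param truth the `truth` element returned by [kp_generate_genome()].
#' @param k window length, bp.
#' @return tibble with `chrom`, `offset` (0-based, within the monomer),
#'   `window`, `canonical`.
#' @export
kp_truth_windows <- function(truth, k = 25) {
  v <- truth$variants
  bind_rows(pmap(list(v$chrom, v$offsets, v$variant_monomer),
                 function(ch, offs, vm) {
    L <- nchar(vm)
    if (k > L) abort("k exceeds the monomer length")
    start <- 0:(L - k)
    covered <- map_int(start, function(s) sum(offs >= s & offs <= s + k - 1L))
    keep <- covered > 0
    tb <- tibble(chrom = ch, offset = start[keep],
                 window = str_sub(vm, start[keep] + 1, start[keep] + k),
                 n_covered = covered[keep])
    all_cov <- tb$n_covered == length(offs)
    centr <- abs((tb$offset + (k - 1) / 2) - mean(offs))
    canon_idx <- if (any(all_cov)) which(all_cov)[which.min(centr[all_cov])] else
      which.max(tb$n_covered)
    tb$canonical <- seq_len(nrow(tb)) == canon_idx
    select(tb, -"n_covered")
  }))
}

#' Generate a BAC library with known placements from a genome
#'
#' Clones are placed uniformly at random; the forward end read is the
#' first `end_length` bases of the insert and the reverse end read is the
#' reverse complement of the last `end_length` bases. End reads are
#' error-free by default; `error_rate` adds i.i.d. substitutions for
#' robustness experiments.
#'
#' @param genome sequence tibble of chromosomes.
#' @param n_clones number of clones.
#' @param insert_range numeric length-2: insert length bounds, bp.
#' @param end_length end-read length, bp.
#' @param error_rate per-base substitution probability on end reads.
#' @param seed integer seed.
#' @return list with `ends` (sequence tibble, ids `<clone>_F`/`<clone>_R`),
#'   `pairs` (tibble `clone_id`, `forward_end_id`, `reverse_end_id`) and
#'   `truth` (tibble `clone_id`, `chrom`, `first_base`, `last_base`,
#'   `insert_length`).
#' @export
kp_generate_bac_library <- function(genome, n_clones = 100,
                                    insert_range = c(50000, 200000),
                                    end_length = 700, error_rate = 0,
                                    seed = 1) {
  assert_seq_tbl(genome, "genome")
  stopifnot(length(insert_range) == 2, insert_range[1] <= insert_range[2],
            end_length >= 1, error_rate >= 0, error_rate < 1)
  lens <- nchar(genome$seq)
  if (insert_range[1] > max(lens)) abort("insert_range exceeds every chromosome length")
  withr::with_seed(as.integer(seed), {
    rows <- vector("list", n_clones)
    ends <- vector("list", n_clones)
    for (i in seq_len(n_clones)) {
      repeat {
        ci <- sample(length(lens), 1)
        hi <- min(insert_range[2], lens[ci])
        if (hi >= insert_range[1]) break
      }
      ins <- sample(seq(insert_range[1], hi), 1)
      first <- sample(lens[ci] - ins + 1L, 1)
      last <- first + ins - 1L
      clone <- sprintf("clone%04d", i)
      fwd <- str_sub(genome$seq[ci], first, first + end_length - 1L)
      rev <- kp_revcomp(str_sub(genome$seq[ci], last - end_length + 1L, last))
      if (error_rate > 0) {
        fwd <- add_errors(fwd, error_rate)
        rev <- add_errors(rev, error_rate)
      }
      rows[[i]] <- tibble(clone_id = clone, chrom = genome$id[ci],
                          first_base = as.integer(first), last_base = as.integer(last),
                          insert_length = as.integer(ins))
      ends[[i]] <- tibble(id = paste0(clone, c("_F", "_R")), seq = c(fwd, rev))
    }
    list(
      ends = bind_rows(ends),
      pairs = tibble(clone_id = sprintf("clone%04d", seq_len(n_clones)),
                     forward_end_id = sprintf("clone%04d_F", seq_len(n_clones)),
                     reverse_end_id = sprintf("clone%04d_R", seq_len(n_clones))),
      truth = bind_rows(rows)
    )
  })
}

add_errors <- function(s, rate) {
  ch <- seq_as_chars(s)
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit) > 0) ch[hit] <- chartr("ACGT", "GTAC", ch[hit])
  paste(ch, collapse = "")
}

#' Align end reads to a genome by exact/near-exact matching
#'
#' Finds occurrences of each end read (and its reverse complement) in the
#' genome with at most `max_mismatch` substitutions and reports them in
#' the same tabular hit layout as [kp_read_hits()], so the anchoring
#' pipeline can run end to end on synthetic data without an external
#' aligner.
#'
#' @param ends sequence tibble of end reads.
#' @param genome sequence tibble of chromosomes.
#' @param max_mismatch maximum substitutions per hit.
#' @return a hit tibble compatible with [kp_filter_hits()].
#' @export
kp_align_ends <- function(ends, genome, max_mismatch = 0) {
  assert_seq_tbl(ends, "ends")
  assert_seq_tbl(genome, "genome")
  subjects <- Biostrings::DNAStringSet(stats::setNames(genome$seq, genome$id))
  out <- list()
  for (i in seq_len(nrow(ends))) {
    qlen <- nchar(ends$seq[i])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") ends$seq[i] else kp_revcomp(ends$seq[i])
      m <- Biostrings::vmatchPattern(pat, subjects, max.mismatch = max_mismatch,
                                     fixed = TRUE)
      for (ci in seq_along(m)) {
        ir <- m[[ci]]
        if (length(ir) == 0) next
        st <- Biostrings::start(ir); en <- Biostrings::end(ir)
        nmm <- vapply(seq_along(ir), function(j) {
          sum(seq_as_chars(as.character(Biostrings::subseq(subjects[[ci]], st[j], en[j]))) !=
                seq_as_chars(pat))
        }, integer(1))
        out[[length(out) + 1L]] <- tibble(
          query_id = ends$id[i], subject_id = genome$id[ci],
          percent_identity = 100 * (1 - nmm / qlen),
          alignment_length = qlen, mismatches = nmm, gap_opens = 0L,
          query_start = 1L, query_end = as.integer(qlen),
          subject_start = as.integer(st), subject_end = as.integer(en),
          strand = strand, evalue = 0, bitscore = 2 * qlen,
          query_length = qlen
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  percent_identity = numeric(), alignment_length = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  query_start = integer(), query_end = integer(),
                  subject_start = integer(), subject_end = integer(),
                  strand = character(), evalue = numeric(), bitscore = numeric(),
                  query_length = numeric()))
  }
  bind_rows(out) |> arrange(.data$query_id, .data$subject_id, .data$subject_start)
}

#' Exact-match precision and recall of calls against truth
#'
#' Rows are compared on `keys` (defaulting to all shared columns); a call
#' is a true positive when an identical key combination exists in the
#' truth table.
#'
#' @param calls tibble of calls.
#' @param truth tibble of truth records.
#' @param keys columns to compare on.
#' @return one-row tibble: `n_calls`, `n_truth`, `tp`, `precision`
#'   (NA when there are no calls), `recall`.
#' @export
kp_evaluate_recovery <- function(calls, truth,
                                 keys = intersect(names(calls), names(truth))) {
  if (length(keys) == 0) abort("no shared key columns between calls and truth")
  ck <- distinct(select(as_tibble(calls), all_of(keys)))
  tk <- distinct(select(as_tibble(truth), all_of(keys)))
  tp <- nrow(inner_join(ck, tk, by = keys))
  tibble(
    n_calls = nrow(ck), n_truth = nrow(tk), tp = tp,
    precision = if (nrow(ck) > 0) tp / nrow(ck) else NA_real_,
    recall = if (nrow(tk) > 0) tp / nrow(tk) else NA_real_
  )
}
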