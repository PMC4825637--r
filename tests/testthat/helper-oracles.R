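# Independent oracles and small generators used across the suite. Each
# oracle is a direct, brute-force restatement of the operation's
# definition, kept free of the implementation code paths it checks.

rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# naive two-strand Hamming scan: count offsets of `oligo` and its reverse
# complement within distance d, per chromosome
oracle_oligo_hits <- function(oligo, genome, d) {
  hamming_hits <- function(pat, subject) {
    k <- nchar(pat)
    n <- nchar(subject)
    if (n < k) return(0L)
    pc <- strsplit(pat, "")[[1]]
    sc <- strsplit(subject, "")[[1]]
    mism <- integer(n - k + 1)
    for (j in seq_len(k)) {
      mism <- mism + (sc[j:(n - k + j)] != pc[j])
    }
    sum(mism <= d)
  }
  rc <- karyoprobe::kp_revcomp(oligo)
  counts <- vapply(genome$seq, function(s) {
    hamming_hits(oligo, s) + hamming_hits(rc, s)
  }, numeric(1), USE.NAMES = FALSE)
  stats::setNames(as.integer(counts), genome$id)
}

# O(n^2) all-pairs restatement of the BAC end-pairing rule
oracle_pair_bac_ends <- function(hits, pairs, criteria) {
  res <- list()
  for (p in seq_len(nrow(pairs))) {
    hf <- hits[hits$query_id == pairs$forward_end_id[p], , drop = FALSE]
    hr <- hits[hits$query_id == pairs$reverse_end_id[p], , drop = FALSE]
    for (i in seq_len(nrow(hf))) for (j in seq_len(nrow(hr))) {
      a <- hf[i, ]; b <- hr[j, ]
      if (a$subject_id != b$subject_id) next
      if (a$strand == b$strand) next
      plus <- if (a$strand == "+") a else b
      minus <- if (a$strand == "-") a else b
      if (plus$subject_start > minus$subject_start) next
      first <- min(a$subject_start, b$subject_start)
      last <- max(a$subject_end, b$subject_end)
      span <- last - first + 1
      if (span < criteria$span_min || span > criteria$span_max) next
      res[[length(res) + 1]] <- data.frame(
        clone_id = pairs$clone_id[p], chrom = a$subject_id,
        first_base = first, last_base = last, insert_length = span)
    }
  }
  if (length(res) == 0) {
    return(data.frame(clone_id = character(), chrom = character(),
                      first_base = integer(), last_base = integer(),
                      insert_length = integer()))
  }
  out <- unique(do.call(rbind, res))
  out[order(out$chrom, out$first_base, out$clone_id), , drop = FALSE]
}

# position-set union restatement of repeat content
oracle_repeat_content <- function(intervals, target_length) {
  pos <- unique(unlist(mapply(seq, intervals$start, intervals$end,
                              SIMPLIFY = FALSE)))
  100 * length(pos) / target_length
}

# column-count restatement of the majority consensus
oracle_consensus <- function(aligned) {
  mat <- do.call(rbind, strsplit(aligned, ""))
  out <- character(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    if (mean(col == "-") > 0.5) next
    col <- col[col != "-"]
    best <- NULL; best_n <- -1
    for (sym in c("A", "C", "G", "T", "N")) {
      n <- sum(col == sym)
      if (n > best_n) { best <- sym; best_n <- n }
    }
    out <- c(out, best)
  }
  paste(out, collapse = "")
}

# random synthetic hit set for pairing property tests: n hits spread over
# a handful of end ids and chromosomes
random_hit_set <- function(seed, n_clones = 6, n_hits = 40) {
  withr::with_seed(seed, {
    pairs <- data.frame(
      clone_id = paste0("c", seq_len(n_clones)),
      forward_end_id = paste0("c", seq_len(n_clones), "_F"),
      reverse_end_id = paste0("c", seq_len(n_clones), "_R"))
    ends <- c(pairs$forward_end_id, pairs$reverse_end_id)
    start <- sample.int(900000, n_hits)
    hits <- tibble::tibble(
      query_id = sample(ends, n_hits, replace = TRUE),
      subject_id = sample(paste0("chr", 1:3), n_hits, replace = TRUE),
      percent_identity = 100, alignment_length = 700L,
      query_start = 1L, query_end = 700L,
      subject_start = start,
      subject_end = start + 699L,
      strand = sample(c("+", "-"), n_hits, replace = TRUE),
      evalue = 0, bitscore = 1400, query_length = 700)
    list(hits = hits, pairs = pairs)
  })
}

write_fasta_tmp <- function(seqs, dir = tempdir()) {
  path <- tempfile(fileext = ".fasta", tmpdir = dir)
  karyoprobe::kp_write_fasta(seqs, path)
  path
}

six_probe_mix <- c("CentPv1", "CentPv2", "CentPv1_A", "CentPv2_A",
                   "khipu", "5S_rDNA")
four_probe_mix <- c("CentPv1", "CentPv2", "CentPv1_A", "CentPv2_A")
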