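# Shared fixture builders and independent oracles.

bg_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")

rc_chr <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

# substitute at randomly chosen positions
mutate_at_rate <- function(s, d) {
  ch <- strsplit(s, "")[[1]]
  idx <- which(stats::runif(length(ch)) < d)
  for (p in idx) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# substitute at exactly n_mut evenly spaced interior positions, leaving both
# terminal bases intact, so every window has near-uniform identity
mutate_periodic <- function(s, n_mut) {
  ch <- strsplit(s, "")[[1]]
  pos <- unique(round(seq(2, length(ch) - 1, length.out = n_mut)))
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# --- Independent local-alignment oracle -------------------------------------
# Biostrings Smith-Waterman under the same scoring (match +1, mismatch -1,
# linear gap -2, N never matches), extracting non-overlapping alignments by
# N-masking the subject after each extraction. A separate code path from the
# package's compiled scan.
oracle_submat <- local({
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
})

oracle_hits_one_strand <- function(query, subject, min_score, max_iter = 50) {
  out <- list()
  s <- subject
  for (i in seq_len(max_iter)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(s), type = "local",
      substitutionMatrix = oracle_submat, gapOpening = 0, gapExtension = 2)
    if (Biostrings::score(pa) < min_score) break
    pr <- pa@pattern@range
    sr <- pa@subject@range
    alen <- nchar(as.character(Biostrings::pattern(pa)))
    out[[i]] <- tibble::tibble(
      score = Biostrings::score(pa),
      q_start = IRanges::start(pr), q_end = IRanges::end(pr),
      s_start = IRanges::start(sr), s_end = IRanges::end(sr),
      matches = Biostrings::nmatch(pa), aln_len = alen,
      identity = 100 * Biostrings::nmatch(pa) / alen)
    w <- IRanges::width(sr)
    substr(s, IRanges::start(sr), IRanges::end(sr)) <- strrep("N", w)
  }
  dplyr::bind_rows(out)
}

# both-strand oracle matching local_align_all's output conventions
oracle_align_all <- function(consensus, subject, min_identity = 80,
                             min_len = 80) {
  qlen <- nchar(consensus)
  min_score <- max(16L, as.integer(floor(min_len * (2 * min_identity / 100 - 1) / 2)))
  fw <- oracle_hits_one_strand(consensus, subject, min_score)
  if (nrow(fw)) fw$strand <- "+"
  rv <- oracle_hits_one_strand(rc_chr(consensus), subject, min_score)
  if (nrow(rv)) {
    rv$strand <- "-"
    qs <- rv$q_start
    rv$q_start <- qlen - rv$q_end + 1L
    rv$q_end <- qlen - qs + 1L
  }
  dplyr::bind_rows(fw, rv) |>
    dplyr::filter(identity >= min_identity, aln_len >= min_len) |>
    dplyr::transmute(start = s_start - 1L, end = s_end, strand,
                     q_start, q_end, identity, aln_len) |>
    dplyr::arrange(start)
}

# --- Textbook Pearson chi-squared oracle ------------------------------------
pearson_oracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       contributions = (m - E)^2 / E)
}

# --- Brute-force 80-80-80 clustering oracle ---------------------------------
# pairwise relation via the Biostrings aligner, transitive closure by
# repeated boolean propagation
cluster_oracle <- function(seqs, min_identity = 80, min_frac = 0.8,
                           min_len = 80) {
  n <- length(seqs)
  rel <- diag(TRUE, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ok_any <- FALSE
      for (b in c(seqs[[j]], rc_chr(seqs[[j]]))) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(b),
          type = "local", substitutionMatrix = oracle_submat,
          gapOpening = 0, gapExtension = 2)
        alen <- nchar(as.character(Biostrings::pattern(pa)))
        idt <- 100 * Biostrings::nmatch(pa) / alen
        ok_any <- ok_any || (idt >= min_identity && alen >= min_len &&
          alen >= min_frac * min(nchar(seqs[[i]]), nchar(seqs[[j]])))
      }
      rel[i, j] <- rel[j, i] <- ok_any
    }
  }
  repeat {
    rel2 <- (rel %*% rel) > 0
    if (identical(rel2, rel > 0)) break
    rel <- rel2
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[which(rel[i, ] > 0)] <- cid
    }
  }
  comp
}

# small synthetic bundle used by several test files
small_bundle <- function(seed = 101, divergence = 0.05) {
  simulate_mite_genome(synthetic_spec(
    genome_length = 4e5, n_contigs = 1,
    families = default_family_blueprints()[c(1, 3, 5, 8), ],
    copies_per_family = 8, divergence = divergence, n_genes = 12,
    libraries = c(libA = 2e6, libB = 2e6), seed = seed))
}
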