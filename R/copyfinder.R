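#' Find all local alignments of a consensus against a genome
#'
#' Exhaustive Smith-Waterman scan (match +1, mismatch -1, linear gap -2) of a
#' MITE consensus against every contig on both strands. The scan first
#' computes, in compiled code, the best local score ending at every subject
#' position; candidate regions are then re-aligned with full traceback and
#' non-overlapping alignments are extracted greedily by score. Minus-strand
#' hits are reported on forward-genome coordinates with query positions mapped
#' back to the original consensus orientation.
#'
#' @param consensus A single consensus sequence (character or DNAString(Set)).
#' @param genome Genome sequences (named character or DNAStringSet).
#' @param min_identity Minimum percent identity of reported alignments.
#' @param min_len Minimum alignment length (columns, incl. gaps).
#' @param family Family name attached to each hit.
#' @return A tibble of alignment hits: `family`, `contig`, `start`, `end`
#'   (0-based half-open on the forward strand), `strand`, `q_start`, `q_end`
#'   (1-based inclusive on the consensus), `identity`, `aln_len`, `score`,
#'   `consensus_len`.
#' @export
local_align_all <- function(consensus, genome, min_identity = 80,
                            min_len = 80, family = "family") {
  consensus <- unname(as_seq_chr(consensus)[1])
  if (nchar(consensus) == 0) abort("empty consensus", class = "mitescape_parameter_error")
  if (nchar(consensus) < 50) abort("consensus shorter than 50 bp", class = "mitescape_parameter_error")
  genome <- as_seq_chr(genome)
  if (is.null(names(genome))) names(genome) <- paste0("contig_", seq_along(genome))
  qlen <- nchar(consensus)
  s0 <- min_extract_score(min_identity, min_len)

  scan_one <- function(qseq, subject, contig, strand) {
    colmax <- cpp_colmax(qseq, subject, 1L, -1L, -2L)
    cand <- which(colmax >= s0)
    if (length(cand) == 0) return(NULL)
    # merge candidate end-positions into windows
    brk <- which(diff(cand) > qlen)
    grp <- rep(seq_len(length(brk) + 1), diff(c(0, brk, length(cand))))
    res <- lapply(split(cand, grp), function(pos) {
      ws <- max(1L, min(pos) - qlen - 50L)
      we <- min(nchar(subject), max(pos) + 50L)
      hits <- as_tibble(cpp_sw_hits(qseq, substr(subject, ws, we),
                                    1L, -1L, -2L, s0))
      if (nrow(hits) == 0) return(NULL)
      hits$s_start <- hits$s_start + ws - 1L
      hits$s_end <- hits$s_end + ws - 1L
      hits
    })
    res <- bind_rows(res)
    if (is.null(res) || nrow(res) == 0) return(NULL)
    res$contig <- contig
    res$strand <- strand
    res
  }

  rc <- revcomp(consensus)
  hits <- bind_rows(purrr::imap(genome, function(subject, contig) {
    bind_rows(scan_one(consensus, subject, contig, "+"),
              scan_one(rc, subject, contig, "-"))
  }))
  if (nrow(hits) == 0) {
    return(tibble(family = character(), contig = character(),
                  start = integer(), end = integer(), strand = character(),
                  q_start = integer(), q_end = integer(),
                  identity = double(), aln_len = integer(), score = integer(),
                  consensus_len = integer()))
  }
  hits <- hits |>
    mutate(
      identity = 100 * .data$matches / .data$aln_len,
      # map minus-strand query coordinates back onto the consensus
      qs = ifelse(.data$strand == "-", qlen - .data$q_end + 1L, .data$q_start),
      qe = ifelse(.data$strand == "-", qlen - .data$q_start + 1L, .data$q_end)
    ) |>
    filter(.data$identity >= min_identity, .data$aln_len >= min_len) |>
    transmute(
      family = family, contig = .data$contig,
      start = .data$s_start - 1L, end = .data$s_end,
      strand = .data$strand,
      q_start = .data$qs, q_end = .data$qe,
      identity = .data$identity, aln_len = .data$aln_len,
      score = .data$score, consensus_len = qlen
    ) |>
    arrange(.data$contig, .data$start)
  hits
}

#' Best local alignment between two sequences
#'
#' Single best Smith-Waterman alignment under a configurable scoring scheme,
#' optionally also checking the reverse-complement orientation of the second
#' sequence (the better-scoring orientation is returned).
#'
#' @param a,b Sequences (character or DNAString(Set)).
#' @param match,mismatch,gap Scoring parameters (linear gap penalty).
#' @param both_strands Also try `a` vs reverse-complement of `b`.
#' @return One-row tibble: `score`, `q_start`, `q_end`, `s_start`, `s_end`
#'   (1-based inclusive; subject coordinates always on the forward `b`),
#'   `matches`, `aln_len`, `identity`, `strand`; zero rows if no positive-score
#'   alignment exists.
#' @export
align_best_local <- function(a, b, match = 1, mismatch = -1, gap = -2,
                             both_strands = FALSE) {
  a <- unname(as_seq_chr(a)[1]); b <- unname(as_seq_chr(b)[1])
  one <- function(bb, strand) {
    h <- as_tibble(cpp_sw_hits(a, bb, as.integer(match), as.integer(mismatch),
                               as.integer(gap), 1L, max_hits = 1L))
    if (nrow(h) == 0) return(NULL)
    if (strand == "-") {
      n <- nchar(b)
      tmp <- h$s_start
      h$s_start <- n - h$s_end + 1L
      h$s_end <- n - tmp + 1L
    }
    h$strand <- strand
    h
  }
  out <- one(b, "+")
  if (both_strands) out <- bind_rows(out, one(revcomp(b), "-"))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(score = integer(), q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(), matches = integer(),
                  aln_len = integer(), identity = double(), strand = character()))
  }
  out |>
    mutate(identity = 100 * .data$matches / .data$aln_len) |>
    arrange(desc(.data$score)) |>
    slice(1)
}

#' Apply the 80-80-80 + end-anchoring acceptance rules
#'
#' A hit is accepted as a full-length copy when identity >= 80%, alignment
#' length >= 80 bp, the alignment covers >= 80% of the consensus, and the
#' alignment reaches to within 10 nt of BOTH consensus ends (offsets counted
#' 1-based: offset 1 means the terminal base is aligned). Rejected hits are
#' kept with `accepted = FALSE` and the first failed rule as `reason`.
#'
#' @param hits Tibble from [local_align_all()] (one family).
#' @param consensus_len Consensus length; taken from the hits if present.
#' @param min_identity,min_len,min_coverage,max_offset Acceptance thresholds.
#' @return The hits tibble with `left_offset`, `right_offset`, `accepted`,
#'   `reason` columns added.
#' @export
filter_full_length <- function(hits, consensus_len = NULL, min_identity = 80,
                               min_len = 80, min_coverage = 0.8,
                               max_offset = 10) {
  if (is.null(consensus_len)) {
    if (!"consensus_len" %in% names(hits)) abort("consensus_len required")
    consensus_len <- hits$consensus_len
  }
  cl <- consensus_len
  hits |>
    mutate(
      consensus_len = cl,
      left_offset = .data$q_start,
      right_offset = cl - .data$q_end + 1L,
      reason = dplyr::case_when(
        .data$identity < min_identity ~ "identity",
        .data$aln_len < min_len ~ "min_len",
        .data$aln_len < min_coverage * cl ~ "coverage",
        .data$left_offset > max_offset | .data$right_offset > max_offset ~ "end_anchor",
        TRUE ~ "ok"
      ),
      accepted = .data$reason == "ok"
    )
}

#' Resolve overlapping accepted copies across families
#'
#' Among copies whose genomic spans overlap by more than 50% of the shorter
#' span, the copy with the highest identity x (alignment length / consensus
#' length) is kept; ties go to the lexicographically smaller family name.
#'
#' @param copies Accepted copies (tibble with `contig`, `start`, `end`,
#'   `identity`, `aln_len`, `consensus_len`, `family`).
#' @return The retained copies, sorted by (contig, start).
#' @export
resolve_overlaps <- function(copies) {
  if (nrow(copies) == 0) return(copies)
  copies <- copies |>
    mutate(.priority = .data$identity * .data$aln_len / .data$consensus_len) |>
    arrange(desc(.data$.priority), .data$family, .data$contig, .data$start)
  keep <- logical(nrow(copies))
  for (ctg in unique(copies$contig)) {
    idx <- which(copies$contig == ctg)
    kept_s <- integer(0); kept_e <- integer(0)
    for (i in idx) {
      s <- copies$start[i]; e <- copies$end[i]
      if (length(kept_s)) {
        ov <- pmin(kept_e, e) - pmax(kept_s, s)
        shorter <- pmin(kept_e - kept_s, e - s)
        if (any(ov > 0.5 * shorter)) next
      }
      keep[i] <- TRUE
      kept_s <- c(kept_s, s); kept_e <- c(kept_e, e)
    }
  }
  copies[keep, ] |>
    select(-".priority") |>
    arrange(.data$contig, .data$start)
}

#' Find accepted full-length copies of every family in a genome
#'
#' Convenience wrapper: runs [local_align_all()] per consensus, applies
#' [filter_full_length()], and resolves cross-family overlaps.
#'
#' @param consensi Named consensus set (DNAStringSet or named character).
#' @param genome Genome sequences.
#' @param min_identity,min_len,min_coverage,max_offset Acceptance thresholds.
#' @return Tibble of accepted copies with a `copy_id` column.
#' @export
find_copies <- function(consensi, genome, min_identity = 80, min_len = 80,
                        min_coverage = 0.8, max_offset = 10) {
  consensi <- as_seq_chr(consensi)
  if (is.null(names(consensi))) names(consensi) <- paste0("fam", seq_along(consensi))
  all <- purrr::imap(consensi, function(seq, fam) {
    local_align_all(seq, genome, min_identity = min_identity,
                    min_len = min_len, family = fam) |>
      filter_full_length(min_identity = min_identity, min_len = min_len,
                         min_coverage = min_coverage, max_offset = max_offset) |>
      filter(.data$accepted)
  }) |> bind_rows()
  out <- resolve_overlaps(all)
  if (nrow(out)) {
    # project the aligned span to the full consensus extent: accepted copies
    # anchor within 10 nt of both consensus ends, so unaligned overhangs are
    # diverged terminal bases, not missing sequence. The projection restores
    # element boundaries (and hence the flanking TSD position) when the
    # aligner trims mismatched ends.
    lens <- stats::setNames(nchar(as_seq_chr(as_dna_set(genome))),
                            names(as_dna_set(genome)))
    out <- out |>
      mutate(
        aln_start = .data$start, aln_end = .data$end,
        start = pmax(0L, ifelse(.data$strand == "+",
                                .data$start - (.data$q_start - 1L),
                                .data$start - (.data$consensus_len - .data$q_end))),
        end = pmin(unname(lens[.data$contig]),
                   ifelse(.data$strand == "+",
                          .data$end + (.data$consensus_len - .data$q_end),
                          .data$end + (.data$q_start - 1L)))
      )
    out$copy_id <- sprintf("%s_%s_%d", out$family, out$contig, out$start)
  }
  out
}
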