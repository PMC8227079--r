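#' Extract element and flank sequences for copies
#'
#' Pulls each copy's sequence plus up to `flank` nt of genomic sequence on
#' each side (shorter when clipped at a contig edge). Flanks are reported on
#' the forward genome strand, so the TSD appears as a direct repeat.
#'
#' @param genome Genome sequences.
#' @param copies Tibble with `contig`, `start`, `end` (0-based half-open).
#' @param flank Flank length in nt.
#' @return `copies` with `left_flank`, `right_flank`, `element_seq` columns.
#' @export
extract_flanks <- function(genome, copies, flank = 50) {
  genome <- as_seq_chr(as_dna_set(genome))
  if (!all(copies$contig %in% names(genome))) {
    abort("copy on unknown contig", class = "mitescape_reference_error")
  }
  seqs <- genome[copies$contig]
  copies |>
    mutate(
      left_flank = unname(substr(seqs, pmax(1L, .data$start - flank + 1L),
                                 .data$start)),
      right_flank = unname(substr(seqs, .data$end + 1L,
                                  pmin(nchar(seqs), .data$end + flank))),
      element_seq = unname(substr(seqs, .data$start + 1L, .data$end))
    )
}

hamming <- function(a, b) {
  mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
         a, b, USE.NAMES = FALSE)
}

#' Call target site duplications from flanking sequence
#'
#' For k in (10, 9, 8, 3, 2) the k-mer immediately left of the element is
#' compared with the k-mer immediately right; the first match wins. Short
#' TSDs (k = 2, 3) must match exactly; for k >= 8 one mismatch is tolerated
#' (reported with `exact = FALSE`). `ta_stretch` flags elements whose
#' element-adjacent 6-mer on either side is a (TA)3 run, the hallmark of
#' MITEs inserted in microsatellites.
#'
#' @param flanked Tibble with `left_flank` and `right_flank` columns (from
#'   [extract_flanks()]), or two character vectors via `left`/`right`.
#' @param left,right Alternative character-vector interface.
#' @return Tibble columns `tsd`, `tsd_k`, `tsd_exact`, `ta_stretch` (bound to
#'   `flanked` when given). `tsd_k = 0` means no call.
#' @export
detect_tsd <- function(flanked = NULL, left = NULL, right = NULL) {
  if (!is.null(flanked)) {
    left <- flanked$left_flank; right <- flanked$right_flank
  }
  left <- unname(toupper(left)); right <- unname(toupper(right))
  one <- function(l, r) {
    for (k in c(10L, 9L, 8L, 3L, 2L)) {
      if (nchar(l) < k || nchar(r) < k) next
      lk <- substr(l, nchar(l) - k + 1, nchar(l))
      rk <- substr(r, 1, k)
      if (lk == rk) return(list(tsd = lk, tsd_k = k, tsd_exact = TRUE))
      if (k >= 8 && hamming(lk, rk) <= 1) {
        return(list(tsd = lk, tsd_k = k, tsd_exact = FALSE))
      }
    }
    list(tsd = "", tsd_k = 0L, tsd_exact = NA)
  }
  calls <- purrr::map2(left, right, one)
  is_ta6 <- function(x) x %in% c("TATATA", "ATATAT")
  res <- tibble(
    tsd = purrr::map_chr(calls, "tsd"),
    tsd_k = purrr::map_int(calls, "tsd_k"),
    tsd_exact = purrr::map_lgl(calls, "tsd_exact"),
    ta_stretch = is_ta6(substr(left, pmax(1, nchar(left) - 5), nchar(left))) |
      is_ta6(substr(right, 1, 6))
  )
  if (!is.null(flanked)) {
    flanked <- flanked[, setdiff(names(flanked), names(res)), drop = FALSE]
    bind_cols(flanked, res)
  } else res
}

#' Call terminal inverted repeats
#'
#' Scans arm lengths from 8 up to `max_arm`, scoring the ungapped identity
#' between the leading arm and the reverse complement of the trailing arm,
#' and returns the arm maximizing identity (ties go to the longer arm). A TIR
#' is `tir_recognized` when identity >= 80% and the arm is >= 10 nt. Elements
#' shorter than 16 nt yield no call (`tir_arm = 0`).
#'
#' @param elements Character vector of element sequences (or a tibble with an
#'   `element_seq` column, to which results are bound).
#' @param max_arm Longest arm length scanned.
#' @param min_identity,min_arm Recognition thresholds (percent, nt).
#' @return Tibble columns `tir_arm`, `tir_identity`, `tir_recognized`.
#' @export
detect_tir <- function(elements, max_arm = 50, min_identity = 80,
                       min_arm = 10) {
  tb <- NULL
  if (is.data.frame(elements)) {
    tb <- elements; elements <- elements$element_seq
  }
  elements <- toupper(elements)
  one <- function(s) {
    n <- nchar(s)
    if (n < 16) return(list(tir_arm = 0L, tir_identity = NA_real_))
    arms <- 8:min(max_arm, floor(n / 2))
    lead <- strsplit(substr(s, 1, max(arms)), "")[[1]]
    trail <- strsplit(revcomp(substr(s, n - max(arms) + 1, n)), "")[[1]]
    eq <- lead == trail & lead != "N"
    ident <- vapply(arms, function(a) 100 * mean(eq[seq_len(a)]), numeric(1))
    best <- max(ident)
    arm <- arms[max(which(ident == best))]
    list(tir_arm = arm, tir_identity = best)
  }
  calls <- purrr::map(elements, one)
  res <- tibble(
    tir_arm = purrr::map_int(calls, "tir_arm"),
    tir_identity = purrr::map_dbl(calls, "tir_identity")
  ) |>
    mutate(tir_recognized = !is.na(.data$tir_identity) &
             .data$tir_identity >= min_identity & .data$tir_arm >= min_arm)
  if (!is.null(tb)) {
    tb <- tb[, setdiff(names(tb), names(res)), drop = FALSE]
    bind_cols(tb, res)
  } else res
}

#' Classify copies into Class II superfamily groups
#'
#' Canonical TSD-to-superfamily mapping: TA (k = 2) -> Stowaway; TAA or TTA
#' (k = 3) -> Tourist; k = 8 -> hAT-like; k = 9 or 10 -> Mutator-like.
#' Elements sitting in a (TA)n stretch whose TIR is weak or absent (identity
#' < 80%) are MiMs; since MiMs in (TA)n necessarily show a TA duplication,
#' the MiM rule is tested first. Everything else is Unclassified. The
#' `group` column pools MiMs with the Mutator-like group for summary tables.
#'
#' @param calls Tibble with `tsd`, `tsd_k`, `ta_stretch`, `tir_identity`
#'   columns (e.g. from [detect_tsd()] + [detect_tir()]).
#' @param weak_tir Identity threshold below which a TIR counts as weak.
#' @return `calls` with `superfamily` and `group` columns added.
#' @export
classify_superfamily <- function(calls, weak_tir = 80) {
  calls <- calls[, setdiff(names(calls), c("superfamily", "group")), drop = FALSE]
  calls |>
    mutate(
      superfamily = dplyr::case_when(
        .data$ta_stretch & (is.na(.data$tir_identity) |
                              .data$tir_identity < weak_tir) ~ "MiM",
        .data$tsd_k == 2 & .data$tsd == "TA" ~ "Stowaway",
        .data$tsd_k == 3 & .data$tsd %in% c("TAA", "TTA") ~ "Tourist",
        .data$tsd_k == 8 ~ "hAT-like",
        .data$tsd_k %in% c(9, 10) ~ "Mutator-like",
        TRUE ~ "Unclassified"
      ),
      group = ifelse(.data$superfamily == "MiM", "Mutator-like",
                     .data$superfamily)
    )
}

#' Call structure (TSD, TIR, superfamily) for a set of copies
#'
#' Convenience wrapper chaining [extract_flanks()], [detect_tsd()],
#' [detect_tir()] and [classify_superfamily()].
#'
#' @param genome Genome sequences.
#' @param copies Copy tibble (`contig`, `start`, `end`).
#' @param flank Flank length used for TSD detection.
#' @return `copies` with flank, TSD, TIR and superfamily columns.
#' @export
call_structure <- function(genome, copies, flank = 50) {
  extract_flanks(genome, copies, flank = flank) |>
    detect_tsd() |>
    detect_tir() |>
    classify_superfamily() |>
    select(-"left_flank", -"right_flank", -"element_seq")
}

#' Cluster consensus sequences into families (80-80-80 rule)
#'
#' Two consensi are linked when they share a local alignment (either strand)
#' with identity >= 80% spanning >= 80% of the shorter sequence and >= 80 bp.
#' Families are the single-linkage connected components of that graph; the
#' representative is each family's longest member (ties broken by name). The
#' partition is order-invariant and idempotent.
#'
#' @param consensi Named sequence set (DNAStringSet or named character).
#' @param min_identity,min_frac,min_len The three 80s, configurable.
#' @return Tibble: `name`, `length`, `family`, `representative`, sorted by
#'   family then name.
#' @export
cluster_families <- function(consensi, min_identity = 80, min_frac = 0.8,
                             min_len = 80) {
  consensi <- as_seq_chr(consensi)
  if (is.null(names(consensi))) names(consensi) <- paste0("seq", seq_along(consensi))
  nm <- names(consensi)
  n <- length(nm)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    linked <- apply(pairs, 2, function(ij) {
      a <- consensi[[ij[1]]]; b <- consensi[[ij[2]]]
      h <- align_best_local(a, b, both_strands = TRUE)
      nrow(h) > 0 && h$identity >= min_identity && h$aln_len >= min_len &&
        h$aln_len >= min_frac * min(nchar(a), nchar(b))
    })
    edges <- t(pairs[, linked, drop = FALSE])
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  tibble(name = nm, length = nchar(unname(consensi)), component = comp) |>
    group_by(.data$component) |>
    mutate(representative = .data$name[order(-.data$length, .data$name)][1]) |>
    ungroup() |>
    mutate(family = .data$representative) |>
    select("name", "length", "family", "representative") |>
    arrange(.data$family, .data$name)
}

# Six-frame translations of a contig with nt coordinate mapping.
six_frames <- function(seq) {
  n <- nchar(seq)
  dna <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(dna)
  out <- list()
  for (f in 0:2) {
    len <- n - f; len <- len - len %% 3
    if (len < 3) next
    out[[length(out) + 1]] <- list(
      aa = as.character(suppressWarnings(
        Biostrings::translate(Biostrings::subseq(dna, f + 1, f + len),
                              if.fuzzy.codon = "X"))),
      strand = "+", offset = f)
    out[[length(out) + 1]] <- list(
      aa = as.character(suppressWarnings(
        Biostrings::translate(Biostrings::subseq(rc, f + 1, f + len),
                              if.fuzzy.codon = "X"))),
      strand = "-", offset = f)
  }
  out
}

# aa positions (1-based, inclusive) in a frame -> 0-based half-open nt span
# on the forward strand.
aa_to_nt <- function(aa_start, aa_end, strand, offset, n) {
  nt1 <- offset + 3 * (aa_start - 1)        # 0-based start on frame strand
  nt2 <- offset + 3 * aa_end                # 0-based end (half-open)
  if (strand == "+") c(nt1, nt2) else c(n - nt2, n - nt1)
}

#' Mine putative autonomous Mutator elements
#'
#' Searches the genome for transposase similarity by aligning protein queries
#' against all six translation frames (local alignment under BLOSUM62), then
#' extracts each hit region with 4-kb flanks and looks for an inverted-repeat
#' arm pair: one arm on each flank of the transposase span, in complementary
#' orientation, with identity >= 50% over >= 20 bp. Element boundaries are
#' the outermost coordinates of the arm pair; regions without an acceptable
#' arm pair are reported as candidates without boundaries.
#'
#' @param genome Genome sequences.
#' @param proteins Protein queries (AAStringSet or named character).
#' @param flank Flank length around transposase hits (bp).
#' @param min_prot_score Minimum BLOSUM62 local-alignment score.
#' @param min_arm_identity,min_arm_len Inverted-repeat acceptance thresholds.
#' @param min_arm_score Minimum ungapped alignment score of the arm pair
#'   (matches minus mismatches), a significance floor that keeps chance
#'   similarities in long flanks from defining spurious boundaries.
#' @return Tibble: `contig`, `tp_start`, `tp_end` (transposase span, 0-based
#'   half-open), `region_start`, `region_end`, `bound_start`, `bound_end`
#'   (NA when no arm pair), `tir_identity`, `tir_arm_len`, `has_boundaries`.
#' @export
mine_autonomous <- function(genome, proteins, flank = 4000,
                            min_prot_score = 100, min_arm_identity = 50,
                            min_arm_len = 20, min_arm_score = 20) {
  genome <- as_seq_chr(as_dna_set(genome))
  if (methods::is(proteins, "XStringSet")) proteins <- as.character(proteins)
  if (length(proteins) == 0) abort("no protein queries",
                                   class = "mitescape_parameter_error")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  hits <- list()
  for (ctg in names(genome)) {
    n <- nchar(genome[[ctg]])
    frames <- six_frames(genome[[ctg]])
    for (fr in frames) {
      aa <- gsub("[*]", "X", fr$aa)
      for (p in proteins) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(p), Biostrings::AAString(aa), type = "local",
          substitutionMatrix = B62, gapOpening = 11, gapExtension = 1)
        if (Biostrings::score(pa) < min_prot_score) next
        sub <- pa@subject@range
        span <- aa_to_nt(IRanges::start(sub), IRanges::end(sub),
                         fr$strand, fr$offset, n)
        hits[[length(hits) + 1]] <- tibble(contig = ctg, tp_start = span[1],
                                           tp_end = span[2])
      }
    }
  }
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) {
    return(tibble(contig = character(), tp_start = integer(),
                  tp_end = integer(), region_start = integer(),
                  region_end = integer(), bound_start = integer(),
                  bound_end = integer(), tir_identity = double(),
                  tir_arm_len = integer(), has_boundaries = logical()))
  }
  # merge overlapping transposase hits across proteins/frames
  merged <- hits |>
    group_by(.data$contig) |>
    group_modify(function(df, key) {
      ir <- IRanges::reduce(IRanges::IRanges(df$tp_start + 1L, df$tp_end))
      tibble(tp_start = IRanges::start(ir) - 1L, tp_end = IRanges::end(ir))
    }) |>
    ungroup()
  merged |>
    rowwise() |>
    mutate(found = list({
      n <- nchar(genome[[.data$contig]])
      rs <- max(0L, .data$tp_start - as.integer(flank))
      re <- min(n, .data$tp_end + as.integer(flank))
      left <- substr(genome[[.data$contig]], rs + 1L, .data$tp_start)
      right <- substr(genome[[.data$contig]], .data$tp_end + 1L, re)
      res <- list(region_start = rs, region_end = re,
                  bound_start = NA_integer_, bound_end = NA_integer_,
                  tir_identity = NA_real_, tir_arm_len = NA_integer_)
      if (nchar(left) >= min_arm_len && nchar(right) >= min_arm_len) {
        # arm on each flank in complementary orientation: ungapped local
        # alignment of the left flank against the reverse complement of the
        # right flank (TIR arms are compared ungapped throughout)
        h <- align_best_local(left, revcomp(right), match = 1, mismatch = -1,
                              gap = -10000)
        if (nrow(h) && h$identity >= min_arm_identity &&
            h$aln_len >= min_arm_len && h$score >= min_arm_score) {
          res$bound_start <- rs + h$q_start - 1L
          # subject coords are on RC(right); map back to forward genome
          res$bound_end <- re - h$s_start + 1L
          res$tir_identity <- h$identity
          res$tir_arm_len <- h$aln_len
        }
      }
      res
    })) |>
    ungroup() |>
    tidyr::unnest_wider("found") |>
    mutate(has_boundaries = !is.na(.data$bound_start))
}

#' Link MiM consensi to mined autonomous elements
#'
#' Both 50-bp terminal segments of each MiM consensus are locally aligned
#' (either strand) against each autonomous element sequence; a link is
#' reported when either end matches with identity >= 80% over >= 30 bp.
#'
#' @param mim_consensi Named MiM consensus set.
#' @param autonomous Tibble from [mine_autonomous()] (rows with boundaries).
#' @param genome Genome sequences (to extract element sequences).
#' @param min_identity,min_len Link thresholds.
#' @return Tibble: `mim`, `element` (contig:bounds), `end` (`"5p"`/`"3p"` of
#'   the best-matching end), `identity`, `aln_len`, `linked`, `note`.
#' @export
link_mim_to_autonomous <- function(mim_consensi, autonomous, genome,
                                   min_identity = 80, min_len = 30) {
  mim_consensi <- as_seq_chr(mim_consensi)
  genome <- as_seq_chr(as_dna_set(genome))
  auto <- autonomous |> filter(.data$has_boundaries)
  out <- list()
  for (i in seq_along(mim_consensi)) {
    nm <- names(mim_consensi)[i]
    s <- mim_consensi[[i]]
    if (nchar(s) < 50) {
      out[[length(out) + 1]] <- tibble(mim = nm, element = NA_character_,
                                       end = NA_character_, identity = NA_real_,
                                       aln_len = NA_integer_, linked = NA,
                                       note = "consensus shorter than 50 bp")
      next
    }
    ends <- c(`5p` = substr(s, 1, 50), `3p` = substr(s, nchar(s) - 49, nchar(s)))
    for (j in seq_len(nrow(auto))) {
      el <- substr(genome[[auto$contig[j]]], auto$bound_start[j] + 1L,
                   auto$bound_end[j])
      elname <- sprintf("%s:%d-%d", auto$contig[j], auto$bound_start[j],
                        auto$bound_end[j])
      best <- purrr::imap(ends, function(e, lab) {
        h <- align_best_local(e, el, both_strands = TRUE)
        if (nrow(h)) mutate(h, end = lab) else NULL
      }) |> bind_rows()
      if (nrow(best) == 0) {
        out[[length(out) + 1]] <- tibble(mim = nm, element = elname,
                                         end = NA_character_,
                                         identity = NA_real_,
                                         aln_len = NA_integer_, linked = FALSE,
                                         note = NA_character_)
        next
      }
      best <- best |>
        mutate(ok = .data$identity >= min_identity & .data$aln_len >= min_len) |>
        arrange(desc(.data$ok), desc(.data$score)) |>
        slice(1)
      out[[length(out) + 1]] <- tibble(mim = nm, element = elname,
                                       end = best$end, identity = best$identity,
                                       aln_len = best$aln_len,
                                       linked = best$ok, note = NA_character_)
    }
  }
  bind_rows(out)
}
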