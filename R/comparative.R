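#' Compare two family consensi under the 60/60 criterion
#'
#' Best local alignment between the pair (either strand); coverage is the
#' aligned span as a fraction of each sequence's own length. The pair is
#' related when either direction satisfies identity >= 60% and coverage
#' >= 60% — a disjunction that makes the relation symmetric.
#'
#' @param fam_a,fam_b Consensus sequences.
#' @param min_identity Percent identity threshold (inclusive).
#' @param min_coverage Coverage fraction threshold (inclusive).
#' @return One-row tibble: `identity`, `coverage_a`, `coverage_b`,
#'   `coverage` (max of the two), `aln_len`, `related`.
#' @export
family_match <- function(fam_a, fam_b, min_identity = 60,
                         min_coverage = 0.60) {
  a <- unname(as_seq_chr(fam_a)[1]); b <- unname(as_seq_chr(fam_b)[1])
  h <- align_best_local(a, b, both_strands = TRUE)
  if (nrow(h) == 0) {
    return(tibble(identity = 0, coverage_a = 0, coverage_b = 0, coverage = 0,
                  aln_len = 0L, related = FALSE))
  }
  cov_a <- (h$q_end - h$q_start + 1) / nchar(a)
  cov_b <- (h$s_end - h$s_start + 1) / nchar(b)
  tibble(identity = h$identity, coverage_a = cov_a, coverage_b = cov_b,
         coverage = max(cov_a, cov_b), aln_len = h$aln_len,
         related = h$identity >= min_identity &
           (cov_a >= min_coverage | cov_b >= min_coverage))
}

#' Pairwise family comparison across species libraries
#'
#' Runs [family_match()] for every cross-species family pair and bins the
#' identity-times-coverage score ratio at 0.25/0.50/0.75 (the conventional
#' four-color similarity bins for ribbon plots).
#'
#' @param libraries Named list: species -> named consensus set.
#' @param min_identity,min_coverage Relatedness thresholds.
#' @return Tibble: `species_a`, `family_a`, `species_b`, `family_b`,
#'   `identity`, `coverage`, `related`, `score_ratio`, `bin`.
#' @export
compare_family_libraries <- function(libraries, min_identity = 60,
                                     min_coverage = 0.60) {
  stopifnot(length(libraries) >= 2)
  libraries <- lapply(libraries, as_seq_chr)
  species <- names(libraries)
  out <- list()
  for (i in seq_along(species)) {
    for (j in seq_along(species)) {
      if (i >= j) next
      for (fa in names(libraries[[i]])) {
        for (fb in names(libraries[[j]])) {
          m <- family_match(libraries[[i]][[fa]], libraries[[j]][[fb]],
                            min_identity, min_coverage)
          out[[length(out) + 1]] <- m |>
            mutate(species_a = species[i], family_a = fa,
                   species_b = species[j], family_b = fb)
        }
      }
    }
  }
  bind_rows(out) |>
    mutate(score_ratio = (.data$identity / 100) * .data$coverage,
           bin = cut(.data$score_ratio, c(-Inf, 0.25, 0.50, 0.75, Inf),
                     labels = c("blue", "green", "orange", "red"))) |>
    select("species_a", "family_a", "species_b", "family_b", "identity",
           "coverage", "related", "score_ratio", "bin")
}

#' Summarize family sharing across species
#'
#' From a pairwise match table, reports (i) for each focal family the set of
#' other species containing a related family, (ii) per species-pair counts
#' of related families, and (iii) per focal species, how many families are
#' shared with exactly 1, 2, ... other species. No transitive closure is
#' applied: sharing requires a direct match.
#'
#' @param matches Output of [compare_family_libraries()].
#' @return List of tibbles `per_family`, `per_pair`, `sharing_degree`.
#' @export
shared_family_network <- function(matches) {
  rel <- matches |> filter(.data$related)
  # symmetric long form: each related pair seen from both sides
  long <- bind_rows(
    rel |> select(species = "species_a", family = "family_a",
                  other_species = "species_b"),
    rel |> select(species = "species_b", family = "family_b",
                  other_species = "species_a")
  ) |> distinct()
  per_family <- long |>
    group_by(.data$species, .data$family) |>
    summarise(shared_with = paste(sort(unique(.data$other_species)),
                                  collapse = ","),
              n_species = dplyr::n_distinct(.data$other_species),
              .groups = "drop")
  per_pair <- rel |>
    distinct(.data$species_a, .data$family_a, .data$species_b, .data$family_b) |>
    count(.data$species_a, .data$species_b, name = "n_related_pairs")
  sharing_degree <- per_family |>
    count(.data$species, .data$n_species, name = "n_families") |>
    rename(shared_with_n_species = "n_species")
  list(per_family = per_family, per_pair = per_pair,
       sharing_degree = sharing_degree)
}
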