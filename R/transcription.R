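#' Match reads against MITE copy sequences
#'
#' Computes the best local alignment of every read against every MITE
#' sequence and keeps evidence for matches longer than 20 bp with identity
#' above 80% (strict inequalities). Each read contributes at most one match
#' per MITE copy (its best hit, either strand).
#'
#' @param reads Read sequences (DNAStringSet or named character), each
#'   at least 20 bp.
#' @param mite_seqs Named MITE copy sequences.
#' @param min_len Match length that must be exceeded.
#' @param min_identity Percent identity that must be exceeded.
#' @return Tibble: `read`, `mite`, `aln_len`, `identity`, `counted`.
#' @export
match_reads_to_mites <- function(reads, mite_seqs, min_len = 20,
                                 min_identity = 80) {
  reads <- as_seq_chr(reads)
  mite_seqs <- as_seq_chr(mite_seqs)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  if (is.null(names(mite_seqs))) names(mite_seqs) <- paste0("mite", seq_along(mite_seqs))
  grid <- tidyr::expand_grid(read = names(reads), mite = names(mite_seqs))
  res <- purrr::pmap(grid, function(read, mite) {
    h <- align_best_local(reads[[read]], mite_seqs[[mite]], both_strands = TRUE)
    if (nrow(h) == 0) return(NULL)
    tibble(read = read, mite = mite, aln_len = h$aln_len, identity = h$identity)
  }) |> bind_rows()
  if (nrow(res) == 0) {
    return(tibble(read = character(), mite = character(), aln_len = integer(),
                  identity = double(), counted = logical()))
  }
  res |> mutate(counted = .data$aln_len > min_len & .data$identity > min_identity)
}

#' Select co-transcribed MITE copies
#'
#' Copies whose total matched-read count (summed over libraries unless
#' `per_library = TRUE`) reaches `min_reads` are retained and joined to
#' their host/nearby gene via the genomic-context category; intergenic
#' copies carry no gene and are excluded from the gene join.
#'
#' @param evidence Tibble with `mite` (copy id) and either `counted` rows
#'   from [match_reads_to_mites()] or a `count` column (optionally per
#'   `library`).
#' @param categorized Categorized copies (`copy_id`, `category`,
#'   `nearest_gene`).
#' @param min_reads Minimum read support (default 10).
#' @param per_library Apply the threshold within single libraries instead of
#'   to the pooled count.
#' @return Tibble of retained copies: `copy_id`, `reads`, `category`,
#'   `gene_id` (NA for intergenic copies).
#' @export
cotranscribed_mites <- function(evidence, categorized, min_reads = 10,
                                per_library = FALSE) {
  if ("counted" %in% names(evidence)) {
    counts <- evidence |>
      filter(.data$counted) |>
      count(.data$mite, name = "reads") |>
      rename(copy_id = "mite")
  } else {
    by <- if (per_library && "library" %in% names(evidence)) {
      c("copy_id", "library")
    } else "copy_id"
    id_col <- if ("copy_id" %in% names(evidence)) "copy_id" else "mite"
    counts <- evidence |>
      rename(copy_id = dplyr::all_of(id_col)) |>
      group_by(dplyr::across(dplyr::all_of(by))) |>
      summarise(reads = sum(.data$count), .groups = "drop")
    if (per_library) {
      counts <- counts |>
        group_by(.data$copy_id) |>
        summarise(reads = max(.data$reads), .groups = "drop")
    }
  }
  counts |>
    filter(.data$reads >= min_reads) |>
    inner_join(categorized |>
                 select("copy_id", "category", "nearest_gene"),
               by = "copy_id") |>
    mutate(gene_id = ifelse(as.character(.data$category) == "intergenic",
                            NA_character_, .data$nearest_gene))
}

#' Normalized reads per kilobase
#'
#' `RPK = count / (length/1000)`; normalized RPK divides by the library size
#' in millions: `RPK / (library_size/1e6)`. Scale-invariant: doubling both
#' the count and the library size leaves the value unchanged.
#'
#' @param count Read count(s).
#' @param length_bp Feature length(s) in bp (> 0).
#' @param library_size Total reads in the library (> 0).
#' @return Normalized RPK value(s).
#' @export
normalized_rpk <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0) || any(library_size <= 0)) {
    abort("length and library size must be positive",
          class = "mitescape_parameter_error")
  }
  (count / (length_bp / 1000)) / (library_size / 1e6)
}

#' Expression table with RPK and normalized RPK
#'
#' @param counts Tibble (`feature_id`, `feature_type`, `library`, `count`,
#'   `length_bp`).
#' @param library_sizes Tibble (`library`, `size`).
#' @return `counts` with `rpk` and `nrpk` columns.
#' @export
expression_table <- function(counts, library_sizes) {
  counts |>
    inner_join(library_sizes, by = "library") |>
    mutate(rpk = .data$count / (.data$length_bp / 1000),
           nrpk = normalized_rpk(.data$count, .data$length_bp, .data$size)) |>
    select(-"size")
}

#' MITE/gene expression ratio records
#'
#' For each (gene, MITE copy, library) the M/g ratio is the MITE segment's
#' normalized RPK over the gene's normalized RPK. A record is selected when
#' the gene's (normalized) RPK exceeds 1 and M/g exceeds 1.9, both strict.
#' Records with zero gene expression have an undefined ratio and are never
#' selected.
#'
#' @param expr Expression table from [expression_table()].
#' @param pairs Tibble (`gene_id`, `copy_id`) linking copies to host genes.
#' @param min_gene_rpk,min_mg Selection thresholds (strict inequalities).
#' @param use_normalized Apply the gene RPK filter to normalized RPK
#'   (default) or to raw RPK.
#' @return Tibble: `gene_id`, `copy_id`, `library`, `gene_nrpk`,
#'   `mite_nrpk`, `mg`, `selected`.
#' @export
mg_ratio <- function(expr, pairs, min_gene_rpk = 1, min_mg = 1.9,
                     use_normalized = TRUE) {
  gene_expr <- expr |>
    filter(.data$feature_type == "gene") |>
    select(gene_id = "feature_id", "library", gene_rpk = "rpk",
           gene_nrpk = "nrpk")
  mite_expr <- expr |>
    filter(.data$feature_type == "mite_segment") |>
    select(copy_id = "feature_id", "library", mite_nrpk = "nrpk")
  pairs |>
    select("gene_id", "copy_id") |>
    inner_join(gene_expr, by = "gene_id", relationship = "many-to-many") |>
    inner_join(mite_expr, by = c("copy_id", "library")) |>
    mutate(
      mg = ifelse(.data$gene_nrpk > 0, .data$mite_nrpk / .data$gene_nrpk, NA_real_),
      gene_filter = if (use_normalized) .data$gene_nrpk else .data$gene_rpk,
      selected = !is.na(.data$mg) & .data$gene_filter > min_gene_rpk &
        .data$mg > min_mg
    ) |>
    select("gene_id", "copy_id", "library", "gene_nrpk", "mite_nrpk", "mg",
           "selected")
}

#' Genes with tissue-differential M/g
#'
#' Retains genes whose M/g range across libraries (max minus min) exceeds
#' `min_range`. Genes observed in a single library are not evaluable and are
#' excluded.
#'
#' @param mg_records Output of [mg_ratio()].
#' @param min_range Required M/g range (strict; default 1.5).
#' @return Tibble: `gene_id`, `mg_max`, `mg_min`, `mg_range`, `retained`.
#' @export
differential_mg <- function(mg_records, min_range = 1.5) {
  mg_records |>
    filter(!is.na(.data$mg)) |>
    group_by(.data$gene_id) |>
    summarise(n_libraries = dplyr::n_distinct(.data$library),
              mg_max = max(.data$mg), mg_min = min(.data$mg),
              .groups = "drop") |>
    filter(.data$n_libraries >= 2) |>
    mutate(mg_range = .data$mg_max - .data$mg_min,
           retained = .data$mg_range > min_range) |>
    select("gene_id", "mg_max", "mg_min", "mg_range", "retained")
}

#' Heatmap of per-library M/g ratios
#'
#' @param mg_records Output of [mg_ratio()].
#' @return A ggplot tile plot (genes x libraries, fill = M/g).
#' @export
plot_mg_heatmap <- function(mg_records) {
  ggplot2::ggplot(mg_records,
                  ggplot2::aes(.data$library, .data$gene_id,
                               fill = .data$mg)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "M/g", na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
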