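#' Group-level summary table
#'
#' The classic per-group summary of a genome-wide MITE annotation: number of
#' families, number of copies, occupied bp (and Mbp), percent of the genome,
#' mean copy number per family, mean element length, size of the largest
#' family, and per-category localization counts, plus a Total row. Mean
#' fields are reported both rounded to the nearest integer (the conventional
#' presentation) and unrounded.
#'
#' @param copies Categorized, classified copies (`family`, `group`, `start`,
#'   `end`, `category`).
#' @param genome_size Genome size in bp (> 0).
#' @return A tibble, one row per group plus `Total`.
#' @export
summarize_groups <- function(copies, genome_size) {
  if (is.null(genome_size) || genome_size <= 0) {
    abort("genome_size must be positive", class = "mitescape_parameter_error")
  }
  one <- function(df, label) {
    occupied <- sum(df$end - df$start)
    nfam <- dplyr::n_distinct(df$family)
    ncopy <- nrow(df)
    fam_sizes <- if (ncopy) table(df$family) else integer(0)
    cats <- table(factor(df$category, levels = CONTEXT_LEVELS))
    tibble(
      group = label, n_families = nfam, n_copies = ncopy,
      mbp = occupied / 1e6,
      pct_genome = 100 * occupied / genome_size,
      mean_copies_per_family = if (nfam) ncopy / nfam else NA_real_,
      mean_copies_per_family_int = if (nfam) round(ncopy / nfam) else NA_integer_,
      mean_length_bp = if (ncopy) occupied / ncopy else NA_real_,
      mean_length_bp_int = if (ncopy) round(occupied / ncopy) else NA_integer_,
      largest_family = if (ncopy) max(fam_sizes) else NA_integer_
    ) |> bind_cols(as_tibble(as.list(cats)))
  }
  groups <- sort(unique(copies$group))
  rows <- lapply(groups, function(g) one(copies[copies$group == g, ], g))
  bind_rows(rows, one(copies, "Total"))
}

#' Summary statistics from a published-style summary table
#'
#' Recomputes the derived columns of a per-group genome-wide summary (mean
#' copies per family, mean element length, percent of genome) from its
#' primary columns, for consistency checks against printed tables.
#'
#' @param summary Tibble with `n_families`, `n_copies`, `mbp` and optionally
#'   `genome_size_mbp` columns.
#' @return `summary` with `mean_copies_per_family`, `mean_length_bp` (both
#'   with `_int` rounded versions) and, when genome size is present,
#'   `pct_genome` columns recomputed.
#' @export
recompute_summary <- function(summary) {
  out <- summary |>
    mutate(mean_copies_per_family = .data$n_copies / .data$n_families,
           mean_copies_per_family_int = round(.data$mean_copies_per_family),
           mean_length_bp = .data$mbp * 1e6 / .data$n_copies,
           mean_length_bp_int = round(.data$mean_length_bp))
  if ("genome_size_mbp" %in% names(summary)) {
    out <- out |> mutate(pct_genome = 100 * .data$mbp / .data$genome_size_mbp)
  }
  out
}

#' Run the full MITE annotation pipeline
#'
#' Orchestrates copy finding, structural classification, genomic-context
#' categorization with chi-squared enrichment, expression (M/g) analysis and
#' cross-species comparison from a single configuration, writing the
#' standard outputs (MITE GFF3 and BED, per-copy TSV, group summary,
#' enrichment report, M/g tables, sharing report) plus a run log with every
#' threshold.
#'
#' @param config A list (or path to a YAML file) with elements: `genome`
#'   (path or DNAStringSet), `library` (consensus FASTA path or sequence
#'   set), optional `gff3` (path or tidy gene tibble), optional `counts` /
#'   `library_sizes` (paths or tibbles), optional `pairs` (gene-copy table),
#'   optional `proteins`, optional `species_libraries` (named list), optional
#'   `thresholds` (overrides), `seed`, `out_dir`.
#' @return A list of result tables (`copies`, `summary`, `chisq`,
#'   `mg_records`, `selected_genes`, `comparison`, `log`), invisibly written
#'   to `out_dir` when given.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  th <- utils::modifyList(list(
    min_identity = 80, min_len = 80, min_coverage = 0.8, max_offset = 10,
    context_window = 1000, min_reads = 10, min_gene_rpk = 1, min_mg = 1.9,
    min_mg_range = 1.5, cross_identity = 60, cross_coverage = 0.60
  ), config$thresholds %||% list())
  if (!is.null(config$seed)) set.seed(config$seed)
  log <- character()
  note <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...))
  }
  note("thresholds: %s", paste(names(th), unlist(th), sep = "=", collapse = " "))
  note("seed: %s", config$seed %||% "none")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "mitescape_stage_error")
    })
  }

  as_path_or_seqs <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) read_fasta(x)
    else as_dna_set(x)
  }
  genome <- stage("genome", as_path_or_seqs(config$genome))
  consensi <- stage("library", as_path_or_seqs(config$library))
  note("genome: %d contigs, %d bp", length(genome), sum(Biostrings::width(genome)))
  note("library: %d consensi", length(consensi))

  copies <- stage("find_copies", find_copies(
    consensi, genome, min_identity = th$min_identity, min_len = th$min_len,
    min_coverage = th$min_coverage, max_offset = th$max_offset))
  note("find_copies: %d accepted copies", nrow(copies))

  copies <- stage("classify", call_structure(genome, copies))
  note("classify: %s", paste(names(table(copies$group)),
                             table(copies$group), sep = "=", collapse = " "))

  genes <- NULL; chisq <- NULL; loc <- NULL
  if (!is.null(config$gff3)) {
    genes <- stage("gff3", {
      if (is.character(config$gff3) && length(config$gff3) == 1) {
        read_gff3(config$gff3)
      } else config$gff3
    })
    copies <- stage("context", categorize_copies(copies, genes,
                                                 window = th$context_window))
    loc <- localization_table(copies)
    chisq <- tryCatch(enrichment_chisq(loc), error = function(e) NULL)
    note("context: genic fraction %.1f%%", genic_fraction(loc)$percent)
  } else {
    warning("no GFF3 given: genomic-context stage skipped")
    note("context: skipped (no gff3)")
    copies$category <- factor(rep(NA_character_, nrow(copies)),
                              levels = CONTEXT_LEVELS)
    copies$nearest_gene <- NA_character_
  }

  summary <- stage("summary", summarize_groups(
    copies, genome_size = sum(Biostrings::width(genome))))

  mg_records <- NULL; selected <- NULL
  if (!is.null(config$counts) && !is.null(config$library_sizes)) {
    counts <- if (is.character(config$counts)) {
      readr::read_tsv(config$counts, show_col_types = FALSE)
    } else config$counts
    lib_sizes <- if (is.character(config$library_sizes)) {
      readr::read_tsv(config$library_sizes, show_col_types = FALSE)
    } else config$library_sizes
    expr <- stage("expression", expression_table(counts, lib_sizes))
    pairs <- config$pairs
    if (is.null(pairs) && !is.null(genes)) {
      cot <- cotranscribed_mites(
        counts |> filter(.data$feature_type == "mite_segment") |>
          rename(copy_id = "feature_id"),
        copies, min_reads = th$min_reads)
      pairs <- cot |> filter(!is.na(.data$gene_id)) |>
        select("gene_id", "copy_id")
    }
    if (!is.null(pairs) && nrow(pairs)) {
      mg_records <- stage("mg", mg_ratio(expr, pairs,
                                         min_gene_rpk = th$min_gene_rpk,
                                         min_mg = th$min_mg))
      selected <- differential_mg(mg_records, min_range = th$min_mg_range)
      note("expression: %d M/g records, %d genes with differential M/g",
           nrow(mg_records), sum(selected$retained))
    }
  }

  comparison <- NULL
  if (!is.null(config$species_libraries) &&
      length(config$species_libraries) >= 2) {
    libs <- lapply(config$species_libraries, function(x) {
      if (is.character(x) && length(x) == 1 && file.exists(x)) read_fasta(x) else as_dna_set(x)
    })
    comparison <- stage("compare", compare_family_libraries(
      libs, min_identity = th$cross_identity, min_coverage = th$cross_coverage))
    note("compare: %d related cross-species pairs", sum(comparison$related))
  }

  out <- list(copies = copies, summary = summary, localization = loc,
              chisq = chisq, mg_records = mg_records,
              selected_genes = selected, comparison = comparison,
              thresholds = th, log = log)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) if (!is.null(df)) readr::write_tsv(as_tibble(df), file.path(config$out_dir, f))
    write_mite_gff3(copies, file.path(config$out_dir, "mites.gff3"))
    write_bed(copies, file.path(config$out_dir, "mites.bed"))
    w(copies, "copies.tsv")
    w(summary, "summary.tsv")
    if (!is.null(chisq)) w(tidy(chisq), "chisq_contributions.tsv")
    w(mg_records, "mg_records.tsv")
    w(selected, "selected_genes.tsv")
    w(comparison, "comparison.tsv")
    writeLines(log, file.path(config$out_dir, "run.log"))
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Published carrot MITE summary table
#'
#' Loads the packaged genome-wide carrot MITE summary (groups by family
#' count, copy count, occupied Mbp, largest family, and localization
#' counts), shipped as a plain TSV for arithmetic consistency checks.
#'
#' @param which `"carrot"` (per-group summary with localization counts) or
#'   `"asterids"` (nine-species summary with genome sizes).
#' @return A tibble.
#' @export
published_summary <- function(which = c("carrot", "asterids")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0(which, "_mite_summary.tsv"),
                   package = "mitescape")
  readr::read_tsv(f, show_col_types = FALSE)
}
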