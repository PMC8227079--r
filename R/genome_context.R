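CONTEXT_LEVELS <- c("five_prime_utr", "three_prime_utr", "cds", "intron",
                    "upstream", "downstream", "intergenic")

#' Assign genomic-context categories to MITE copies
#'
#' Each copy receives exactly one category, evaluated in priority order:
#' overlaps an annotated 5' UTR; overlaps a 3' UTR; overlaps a CDS; fully
#' contained in an intron; within 1 kb upstream of a gene start
#' (strand-aware, inclusive distance); within 1 kb downstream of a gene end;
#' otherwise intergenic. UTR/CDS require any overlap, intron requires full
#' containment, so boundary-straddling copies fall through to the next rule.
#'
#' @param copies Tibble with `contig`, `start`, `end` (0-based half-open).
#' @param genes Tidy gene models (as from [read_gff3()]).
#' @param window Upstream/downstream distance in bp (inclusive).
#' @return `copies` with `category` (factor over the seven levels) and
#'   `nearest_gene` columns.
#' @export
categorize_copies <- function(copies, genes, window = 1000) {
  if (nrow(copies) == 0) {
    copies$category <- factor(character(), levels = CONTEXT_LEVELS)
    copies$nearest_gene <- character()
    return(copies)
  }
  n <- nrow(copies)
  cat <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  if (!is.null(genes) && nrow(genes) > 0) {
    cr <- GenomicRanges::GRanges(copies$contig,
                                 IRanges::IRanges(copies$start + 1L, copies$end))
    feat_hit <- function(type, contained = FALSE) {
      f <- genes |> filter(.data$type == .env$type)
      if (nrow(f) == 0) return(list(hit = rep(FALSE, n), gene = rep(NA_character_, n)))
      fr <- GenomicRanges::GRanges(f$contig, IRanges::IRanges(f$start + 1L, f$end))
      ov <- GenomicRanges::findOverlaps(cr, fr,
                                        type = if (contained) "within" else "any")
      hit <- rep(FALSE, n); gn <- rep(NA_character_, n)
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      hit[qh] <- TRUE
      gn[qh[!duplicated(qh)]] <- f$gene_id[sh[!duplicated(qh)]]
      list(hit = hit, gene = gn)
    }
    assign_cat <- function(res, label) {
      sel <- is.na(cat) & res$hit
      cat[sel] <<- label
      gene[sel] <<- res$gene[sel]
    }
    assign_cat(feat_hit("five_prime_utr"), "five_prime_utr")
    assign_cat(feat_hit("three_prime_utr"), "three_prime_utr")
    assign_cat(feat_hit("cds"), "cds")
    assign_cat(feat_hit("intron", contained = TRUE), "intron")
    # strand-aware 1-kb windows; distance inclusive, straddle clamps to 0
    spans <- gene_spans(genes)
    side_hit <- function(side) {
      hit <- rep(FALSE, n); gn <- rep(NA_character_, n); bd <- rep(Inf, n)
      for (k in seq_len(nrow(spans))) {
        gs <- spans$start[k]; ge <- spans$end[k]
        five_side_low <- (spans$strand[k] != "-")  # 5' edge at lower coord?
        at_low <- (side == "upstream") == five_side_low
        on <- copies$contig == spans$contig[k]
        if (at_low) {
          d <- pmax(0L, gs - copies$end)
          ok <- on & copies$start < gs & d <= window
        } else {
          d <- pmax(0L, copies$start - ge)
          ok <- on & copies$end > ge & d <= window
        }
        upd <- ok & d < bd
        gn[upd] <- spans$gene_id[k]; bd[upd] <- d[upd]; hit <- hit | ok
      }
      list(hit = hit, gene = gn)
    }
    assign_cat(side_hit("upstream"), "upstream")
    assign_cat(side_hit("downstream"), "downstream")
  }
  cat[is.na(cat)] <- "intergenic"
  copies$category <- factor(cat, levels = CONTEXT_LEVELS)
  copies$nearest_gene <- gene
  copies
}

#' Build the group-by-category localization table
#'
#' Counts categorized copies per (superfamily group, context category), with
#' margins carried as attributes. Returns a `localization_table`: a tibble in
#' the classic summary layout (one row per group, one column per category).
#'
#' @param copies Categorized copies (needs `category` and a grouping column).
#' @param group Name of the grouping column (default `"group"`).
#' @return A `localization_table` tibble.
#' @export
localization_table <- function(copies, group = "group") {
  if (!group %in% names(copies)) {
    abort(sprintf("grouping column '%s' not found", group))
  }
  cats <- factor(copies$category, levels = CONTEXT_LEVELS)
  grp <- copies[[group]]
  tab <- as.data.frame.matrix(table(grp, cats))
  out <- tibble(group = rownames(tab)) |> bind_cols(as_tibble(tab))
  for (cl in CONTEXT_LEVELS) if (!cl %in% names(out)) out[[cl]] <- 0L
  out <- out[, c("group", CONTEXT_LEVELS)]
  structure(out, class = c("localization_table", class(out)))
}

loc_matrix <- function(table) {
  m <- as.matrix(as.data.frame(table)[, CONTEXT_LEVELS])
  rownames(m) <- table$group
  m
}

#' Pearson chi-squared enrichment over a localization table
#'
#' Classic Pearson test of independence on the group x category count table:
#' expected counts are outer products of the margins over the grand total;
#' the statistic is the sum of per-cell contributions (O-E)^2/E, with the
#' sign of O-E recording the direction of each deviation (the balloon-plot
#' summary of group-by-region enrichment).
#'
#' @param table A `localization_table` or a count matrix.
#' @return A `mite_chisq` object: `statistic`, `df`, `p_value`, `observed`,
#'   `expected`, `contributions`, `signs`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
enrichment_chisq <- function(table) {
  m <- if (is.matrix(table)) table else loc_matrix(table)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (any(rowSums(m) == 0) || any(colSums(m) == 0) || nrow(m) < 2 || ncol(m) < 2) {
    abort("degenerate table: need at least two non-empty rows and columns",
          class = "mitescape_degenerate_table_error")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  contrib <- (ct$observed - ct$expected)^2 / ct$expected
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), observed = ct$observed,
                 expected = ct$expected, contributions = contrib,
                 signs = sign(ct$observed - ct$expected)),
            class = "mite_chisq")
}

#' @export
print.mite_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-squared: X^2 = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mite_chisq <- function(x, ...) {
  as_tibble(as.data.frame.table(x$observed, responseName = "observed")) |>
    rename(group = 1, category = 2) |>
    mutate(expected = as.vector(x$expected),
           contribution = as.vector(x$contributions),
           sign = as.vector(x$signs)) |>
    mutate(across(c("group", "category"), as.character))
}

#' @export
glance.mite_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Balloon plot of chi-squared contributions
#'
#' Circle size is each cell's contribution to the Pearson statistic; color
#' shows the direction of the deviation from expectation.
#'
#' @param object A `mite_chisq`.
#' @param ... Unused.
#' @export
autoplot.mite_chisq <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$category, .data$group)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$contribution,
                                     color = factor(.data$sign))) +
    ggplot2::scale_color_manual(values = c(`-1` = "#2166ac", `0` = "grey70",
                                           `1` = "#b2182b"),
                                name = "deviation") +
    ggplot2::labs(x = NULL, y = NULL, size = "(O-E)²/E") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Fraction of copies in genic regions
#'
#' Genic = gene body plus the 1-kb upstream/downstream windows, i.e.
#' everything but intergenic: `100 * (total - intergenic) / total`.
#'
#' @param table A `localization_table`, or any tibble with the seven category
#'   count columns.
#' @return A list with `percent` (exact) and `percent_rounded` (nearest
#'   integer, the conventional summary figure).
#' @export
genic_fraction <- function(table) {
  df <- as.data.frame(table)
  total <- sum(df[, CONTEXT_LEVELS])
  if (total == 0) abort("empty table: genic fraction undefined",
                        class = "mitescape_undefined_fraction_error")
  pct <- 100 * (total - sum(df$intergenic)) / total
  list(percent = pct, percent_rounded = round(pct))
}
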