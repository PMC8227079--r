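#' Read a FASTA file
#'
#' Sequences are uppercased and any letter outside ACGT is replaced by N
#' (N never matches in downstream alignments).
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_dna_set(as_seq_chr(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or DNAStringSet.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(as_dna_set(seqs), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS/UTR features (1-based closed GFF3 coordinates)
#' into tidy gene models on 0-based half-open coordinates. Genes with several
#' mRNA isoforms are collapsed to the union model: exon union, CDS union, UTR
#' unions over isoforms; intron space is the gene's exon-union gaps.
#'
#' @param path GFF3 file.
#' @return A tibble of gene features: `gene_id`, `contig`, `strand`, `type`
#'   (`exon`, `cds`, `five_prime_utr`, `three_prime_utr`, `intron`), `start`,
#'   `end` (0-based half-open).
#' @export
read_gff3 <- function(path) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  g$type <- tolower(as.character(g$type))
  g$type[g$type %in% c("five_prime_utr", "5'utr", "five_prime_utr")] <- "five_prime_utr"
  g$type[g$type %in% c("three_prime_utr", "3'utr")] <- "three_prime_utr"
  if (!"ID" %in% names(g)) g$ID <- NA_character_
  if (!"Parent" %in% names(g)) g$Parent <- replicate(nrow(g), character(0), simplify = FALSE)
  ids <- ifelse(is.na(g$ID), sprintf(".row%d", seq_len(nrow(g))), g$ID)
  parent <- vapply(g$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  # map every feature to its gene via the parent chain (feature -> mRNA -> gene)
  gene_of <- stats::setNames(rep(NA_character_, nrow(g)), ids)
  gene_of[g$type == "gene"] <- ids[g$type == "gene"]
  for (pass in 1:3) {
    unresolved <- is.na(gene_of)
    hit <- unresolved & !is.na(parent) & !is.na(gene_of[parent])
    gene_of[hit] <- gene_of[parent[hit]]
  }
  child <- g$type %in% c("exon", "cds", "five_prime_utr", "three_prime_utr")
  if (any(child & !is.na(parent) & !(parent %in% ids))) {
    abort("GFF3 child feature with unknown Parent", class = "mitescape_structure_error")
  }
  if (any(child & is.na(gene_of[ids]))) {
    abort("GFF3 child feature not linked to a gene", class = "mitescape_structure_error")
  }
  feats <- tibble(
    gene_id = unname(gene_of[ids]), contig = as.character(g$seqid),
    strand = as.character(g$strand), type = g$type,
    start = g$start - 1L, end = g$end
  ) |> filter(.data$type %in% c("exon", "cds", "five_prime_utr", "three_prime_utr"))

  build_gene_models(feats)
}

# Collapse per-isoform features to union gene models and derive introns.
build_gene_models <- function(feats) {
  union_iv <- function(df) {
    if (nrow(df) == 0) return(df)
    ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
    tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }
  out <- feats |>
    group_by(.data$gene_id, .data$contig, .data$strand, .data$type) |>
    group_modify(~ union_iv(.x)) |>
    ungroup()
  # validate CDS within exon union, derive introns per gene
  per_gene <- split(out, out$gene_id)
  introns <- purrr::map(per_gene, function(gf) {
    ex <- gf[gf$type == "exon", ]
    cds <- gf[gf$type == "cds", ]
    if (nrow(ex)) {
      exr <- IRanges::IRanges(ex$start + 1L, ex$end)
      if (nrow(cds)) {
        cdr <- IRanges::IRanges(cds$start + 1L, cds$end)
        if (sum(IRanges::width(IRanges::intersect(cdr, exr))) < sum(IRanges::width(IRanges::reduce(cdr))))
          abort(sprintf("CDS outside exon union for gene %s", gf$gene_id[1]),
                class = "mitescape_structure_error")
      }
      gaps <- IRanges::gaps(exr)
      if (length(gaps)) {
        return(tibble(gene_id = gf$gene_id[1], contig = gf$contig[1],
                      strand = gf$strand[1], type = "intron",
                      start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps)))
      }
    }
    NULL
  })
  bind_rows(out, bind_rows(introns)) |>
    arrange(.data$gene_id, .data$type, .data$start)
}

#' Gene spans from a gene-model table
#'
#' @param genes Gene features as returned by [read_gff3()].
#' @return One row per gene: `gene_id`, `contig`, `strand`, `start`, `end`
#'   (0-based half-open span over all features).
#' @export
gene_spans <- function(genes) {
  genes |>
    group_by(.data$gene_id, .data$contig, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
}

#' Write MITE copies as GFF3
#'
#' Internal 0-based half-open spans are emitted as 1-based closed GFF3
#' coordinates, one `MITE` feature per copy, with family, superfamily,
#' identity and TSD carried as attributes.
#'
#' @param copies Tibble of copies (`contig`, `start`, `end`, `strand`,
#'   `family`; optionally `superfamily`, `identity`, `tsd`, `copy_id`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mite_gff3 <- function(copies, path) {
  n <- nrow(copies)
  get <- function(col, default) {
    if (col %in% names(copies)) return(copies[[col]])
    if (length(default) == n) default else rep(default, n)
  }
  attrs <- sprintf(
    "ID=%s;family=%s;superfamily=%s;identity=%s;tsd=%s",
    get("copy_id", sprintf("MITE%05d", seq_len(n))),
    copies$family, get("superfamily", "Unclassified"),
    formatC(get("identity", NA_real_), format = "f", digits = 1),
    get("tsd", ".")
  )
  lines <- sprintf("%s\tmitescape\tMITE\t%d\t%d\t.\t%s\t.\t%s",
                   copies$contig, copies$start + 1L, copies$end,
                   copies$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' BED is 0-based half-open, matching the internal convention directly.
#'
#' @param intervals Tibble with `contig`, `start`, `end`; optional `name`
#'   (or `family`), `score` (or `identity`, rounded to integer), `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  n <- nrow(intervals)
  name <- if ("name" %in% names(intervals)) intervals$name
          else if ("family" %in% names(intervals)) intervals$family else rep(".", n)
  score <- if ("score" %in% names(intervals)) intervals$score
           else if ("identity" %in% names(intervals)) round(intervals$identity) else rep(0, n)
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep(".", n)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", intervals$contig,
                     intervals$start, intervals$end, name, as.integer(score),
                     strand), path)
  invisible(path)
}

#' Extend intervals symmetrically, clipped to contig bounds
#'
#' Grows each interval by `pad` bp on both sides (the flank-extraction step
#' uses 50 nt), clipping at 0 and at the contig length.
#'
#' @param intervals Tibble with `contig`, `start`, `end` (0-based half-open).
#' @param pad Non-negative padding in bp.
#' @param contig_lengths Named vector of contig lengths (or a DNAStringSet).
#' @return The intervals tibble with padded, clipped `start`/`end`.
#' @export
extend_intervals <- function(intervals, pad, contig_lengths) {
  stopifnot(pad >= 0)
  if (methods::is(contig_lengths, "XStringSet")) {
    contig_lengths <- stats::setNames(Biostrings::width(contig_lengths),
                                      names(contig_lengths))
  }
  if (!all(intervals$contig %in% names(contig_lengths))) {
    abort("interval on unknown contig", class = "mitescape_reference_error")
  }
  len <- unname(contig_lengths[intervals$contig])
  intervals |>
    mutate(start = pmax(0L, .data$start - as.integer(pad)),
           end = pmin(len, .data$end + as.integer(pad)))
}

#' Write union gene models as GFF3
#'
#' Emits gene, mRNA, exon, CDS and UTR lines (1-based closed coordinates) for
#' gene models in the tidy representation of [read_gff3()]. Each gene gets a
#' single mRNA covering the union model, which round-trips through
#' [read_gff3()].
#'
#' @param genes Tidy gene feature tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  spans <- gene_spans(genes) |> arrange(.data$contig, .data$start)
  type_out <- c(exon = "exon", cds = "CDS", five_prime_utr = "five_prime_UTR",
                three_prime_utr = "three_prime_UTR")
  lines <- unlist(lapply(seq_len(nrow(spans)), function(i) {
    gid <- spans$gene_id[i]
    gf <- genes |>
      filter(.data$gene_id == gid, .data$type != "intron") |>
      arrange(.data$type, .data$start)
    c(
      sprintf("%s\tmitescape\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              spans$contig[i], spans$start[i] + 1L, spans$end[i],
              spans$strand[i], gid),
      sprintf("%s\tmitescape\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              spans$contig[i], spans$start[i] + 1L, spans$end[i],
              spans$strand[i], gid, gid),
      sprintf("%s\tmitescape\t%s\t%d\t%d\t.\t%s\t%s\tID=%s.%s%d;Parent=%s.t1",
              gf$contig, type_out[gf$type], gf$start + 1L, gf$end,
              gf$strand, ifelse(gf$type == "cds", "0", "."),
              gid, gf$type, seq_len(nrow(gf)), gid)
    )
  }))
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
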