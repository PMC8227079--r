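#' Build a synthetic MITE family consensus
#'
#' The consensus carries perfect terminal inverted repeats (the trailing
#' `tir_arm` bases are the reverse complement of the leading `tir_arm` bases)
#' around a random internal core. MiM families are built with degraded
#' (poorly conserved) TIRs, as observed for microsatellite-associated MITEs.
#' Consensi are capped at 700 bp, the conventional MITE size bound.
#'
#' @param superfamily One of `"Stowaway"`, `"Tourist"`, `"hAT-like"`,
#'   `"Mutator-like"`, `"MiM"`.
#' @param length Consensus length in bp (at least `2 * tir_arm + 20`, at most
#'   700).
#' @param tir_arm TIR arm length in bp.
#' @param seed Optional integer seed.
#' @param name Family name (default derived from the superfamily).
#' @return One-row tibble: `name`, `superfamily`, `length`, `tir_arm`,
#'   `tsd_len`, `consensus`.
#' @export
make_family <- function(superfamily, length, tir_arm, seed = NULL,
                        name = NULL) {
  if (length < 2 * tir_arm + 20 || length > 700) {
    abort("consensus length must satisfy 2*tir_arm + 20 <= length <= 700",
          class = "mitescape_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(name)) name <- sprintf("%s_fam%04d", gsub("-like", "", superfamily),
                                     sample.int(9999, 1))
  arm <- random_dna(tir_arm)
  core <- random_dna(length - 2 * tir_arm)
  tail_arm <- revcomp(arm)
  if (superfamily == "MiM") {
    # degrade the trailing arm to ~50% identity, evenly spread so no short
    # window looks conserved: distinguishable but weak TIR
    pos <- seq(1, tir_arm, by = 2)
    ch <- strsplit(tail_arm, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    tail_arm <- paste(ch, collapse = "")
  }
  tsd_len <- switch(superfamily,
    "Stowaway" = 2L, "Tourist" = 3L, "hAT-like" = 8L,
    "Mutator-like" = sample(9:10, 1), "MiM" = 2L,
    abort("unknown superfamily", class = "mitescape_parameter_error"))
  tibble(name = name, superfamily = superfamily, length = as.integer(length),
         tir_arm = as.integer(tir_arm), tsd_len = tsd_len,
         consensus = paste0(arm, core, tail_arm))
}

mutate_seq <- function(seq, divergence) {
  n <- nchar(seq)
  idx <- which(stats::runif(n) < divergence)
  if (length(idx)) {
    ch <- strsplit(seq, "")[[1]]
    for (p in idx) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    seq <- paste(ch, collapse = "")
  }
  list(seq = seq, divergence = length(idx) / n)
}

# Shift 0-based half-open intervals in a tibble after inserting L bases at
# point p on `contig`: intervals at/after p move right; intervals spanning p
# grow.
shift_intervals <- function(df, contig, p, L) {
  if (is.null(df) || nrow(df) == 0) return(df)
  on <- df$contig == contig
  grow <- on & df$start < p & df$end > p
  move <- on & df$start >= p
  df$end[grow] <- df$end[grow] + L
  df$start[move] <- df$start[move] + L
  df$end[move] <- df$end[move] + L
  df
}

# Allowed insertion-point regions (0-based points, inclusive ends) for a
# target genomic-context category, given current gene models.
allowed_regions <- function(category, genes, contig_lengths, window = 1000) {
  lens <- tibble(contig = names(contig_lengths),
                 clen = unname(as.integer(contig_lengths)))
  if (is.null(category) || is.na(category)) {
    return(lens |> transmute(.data$contig, start = 50L,
                             end = .data$clen - 800L, gene_id = NA_character_))
  }
  if (is.null(genes) || nrow(genes) == 0) {
    abort("gene models required for category-directed planting",
          class = "mitescape_parameter_error")
  }
  spans <- gene_spans(genes)
  inside <- function(type) {
    genes |>
      filter(.data$type == .env$type, .data$end - .data$start >= 40) |>
      transmute(.data$contig, start = .data$start + 5L, end = .data$end - 5L,
                .data$gene_id)
  }
  out <- switch(category,
    intron = inside("intron"),
    five_prime_utr = inside("five_prime_utr"),
    three_prime_utr = inside("three_prime_utr"),
    cds = inside("cds"),
    upstream = spans |>
      mutate(start2 = ifelse(.data$strand == "+", .data$start - window + 120L, .data$end + 20L),
             end2 = ifelse(.data$strand == "+", .data$start - 20L, .data$end + window - 120L)) |>
      transmute(.data$contig, start = pmax(50, .data$start2),
                end = .data$end2, .data$gene_id),
    downstream = spans |>
      mutate(start2 = ifelse(.data$strand == "+", .data$end + 20L, .data$start - window + 120L),
             end2 = ifelse(.data$strand == "+", .data$end + window - 120L, .data$start - 20L)) |>
      transmute(.data$contig, start = pmax(50, .data$start2),
                end = .data$end2, .data$gene_id),
    intergenic = {
      res <- lapply(lens$contig, function(ctg) {
        clen <- lens$clen[lens$contig == ctg]
        sp <- spans |> filter(.data$contig == ctg)
        occ <- IRanges::reduce(IRanges::IRanges(pmax(1L, sp$start - window - 800L),
                                                pmin(clen, sp$end + window + 800L)))
        free <- IRanges::gaps(occ, start = 1L, end = clen)
        tibble(contig = ctg, start = IRanges::start(free) + 49L,
               end = IRanges::end(free) - 850L, gene_id = NA_character_)
      })
      bind_rows(res)
    },
    abort(sprintf("unknown category '%s'", category),
          class = "mitescape_parameter_error"))
  out |> filter(.data$end > .data$start)
}

#' Plant diverged copies of a family into a genome
#'
#' Each copy is the consensus with i.i.d. substitutions at the requested
#' divergence, inserted together with a superfamily-appropriate target site
#' duplication (TSD): Stowaway/Tourist copies carry their canonical TA /
#' TAA|TTA duplication, hAT-like and Mutator-like copies duplicate the host
#' k-mer at the insertion site (k = 8 or 9-10), and MiM copies are planted
#' inside a generated (TA)n, n >= 5 stretch. Insertion points are sampled
#' uniformly outside previously planted elements; insertions are non-nested.
#' Existing truth records and gene-model coordinates are shifted accordingly.
#'
#' @param genome Genome sequences (DNAStringSet or named character).
#' @param family One-row family tibble from [make_family()].
#' @param n Number of copies to plant.
#' @param divergence Per-base substitution probability in `[0, 0.3]`.
#' @param seed Optional integer seed.
#' @param truth Existing planted-copy truth tibble to extend (coordinates are
#'   shifted as new insertions land upstream of them).
#' @param genes Optional tidy gene models; shifted in the same way and used
#'   for category-directed planting.
#' @param target_category Optional context category (or vector of length `n`)
#'   each copy should realize (`intron`, `upstream`, ..., `intergenic`).
#' @param p_minus Probability of planting on the minus strand.
#' @return A list with elements `genome` (DNAStringSet), `truth` (tibble:
#'   `family`, `superfamily`, `contig`, `start`, `end`, `strand`, `tsd`,
#'   `realized_divergence`, `context_truth`, `host_gene`), and `genes`.
#' @export
plant_copies <- function(genome, family, n, divergence, seed = NULL,
                         truth = NULL, genes = NULL, target_category = NULL,
                         p_minus = 0.5) {
  stopifnot(n >= 0, divergence >= 0, divergence <= 0.3)
  if (!is.null(seed)) set.seed(seed)
  genome <- as_seq_chr(as_dna_set(genome))
  if (n == 0) {
    return(list(genome = Biostrings::DNAStringSet(genome),
                truth = if (is.null(truth)) empty_truth() else truth,
                genes = genes))
  }
  if (!is.null(target_category) && length(target_category) == 1) {
    target_category <- rep(target_category, n)
  }
  truth <- if (is.null(truth)) empty_truth() else truth
  cons <- family$consensus
  for (i in seq_len(n)) {
    cat_i <- if (is.null(target_category)) NA_character_ else target_category[i]
    placed <- FALSE
    for (try in 1:300) {
      regions <- allowed_regions(cat_i, genes,
                                 stats::setNames(nchar(genome), names(genome)))
      if (nrow(regions) == 0) break
      r <- regions[sample.int(nrow(regions), 1,
                              prob = regions$end - regions$start), ]
      p <- sample(seq.int(r$start, r$end), 1)
      ctg <- r$contig
      # keep clear of previously planted elements (incl. their TSDs)
      tr <- truth |> filter(.data$contig == ctg)
      if (nrow(tr) && any(p > tr$start - 15 & p < tr$end + 15)) next
      # one copy per upstream/downstream window: a later insertion between an
      # earlier copy and the gene edge would push the earlier copy out of the
      # 1-kb window and silently change its true category
      if (!is.na(cat_i) && cat_i %in% c("upstream", "downstream") &&
          nrow(tr) && any(tr$start < r$end + 25 & tr$end > r$start - 25)) next
      mut <- mutate_seq(cons, divergence)
      strand <- if (stats::runif(1) < p_minus) "-" else "+"
      elem <- if (strand == "-") revcomp(mut$seq) else mut$seq
      sf <- family$superfamily
      host <- genome[[ctg]]
      if (sf %in% c("Stowaway", "Tourist")) {
        tsd <- if (sf == "Stowaway") "TA" else sample(c("TAA", "TTA"), 1)
        block <- paste0(tsd, elem, tsd)
        off <- nchar(tsd)
      } else if (sf == "MiM") {
        tsd <- "TA"
        block <- paste0(strrep("TA", 5), elem, strrep("TA", 5))
        off <- 10L
      } else {
        k <- family$tsd_len
        if (p + k > nchar(host)) next
        tsd <- substr(host, p + 1, p + k)
        if (grepl("N", tsd)) next
        block <- paste0(elem, tsd)  # host k-mer right of p becomes the left copy
        off <- 0L
        p <- p + k  # insert after the existing host k-mer
      }
      genome[[ctg]] <- paste0(substr(host, 1, p), block,
                              substr(host, p + 1, nchar(host)))
      L <- nchar(block)
      truth <- shift_intervals(truth, ctg, p, L)
      genes <- shift_intervals(genes, ctg, p, L)
      truth <- bind_rows(truth, tibble(
        family = family$name, superfamily = sf, contig = ctg,
        start = p + off, end = p + off + nchar(elem), strand = strand,
        tsd = tsd, realized_divergence = mut$divergence,
        context_truth = cat_i, host_gene = r$gene_id))
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(sprintf("no remaining insertion space (category %s)",
                    ifelse(is.na(cat_i), "any", cat_i)),
            class = "mitescape_capacity_error")
    }
  }
  list(genome = Biostrings::DNAStringSet(genome), truth = truth, genes = genes)
}

empty_truth <- function() {
  tibble(family = character(), superfamily = character(), contig = character(),
         start = integer(), end = integer(), strand = character(),
         tsd = character(), realized_divergence = double(),
         context_truth = character(), host_gene = character())
}

#' Generate non-overlapping synthetic gene models
#'
#' Genes are laid out left to right on each contig with intergenic gaps large
#' enough that 1-kb upstream/downstream windows never collide. Each gene has
#' 2-4 exons separated by introns, a CDS, and 5'/3' UTRs at the ends of the
#' terminal exons (strand-aware: the 5' UTR of a minus-strand gene sits on
#' its higher-coordinate side).
#'
#' @param genome Genome sequences (lengths are what matters).
#' @param n_genes Number of genes to place.
#' @param seed Optional integer seed.
#' @param exon_range Range of exon counts per gene.
#' @param exon_len Range of exon lengths (bp).
#' @param intron_len Range of intron lengths (bp).
#' @param utr_len Range of UTR lengths (bp; must fit in the terminal exons).
#' @param gap Minimum intergenic gap (bp).
#' @return Tidy gene feature tibble (`gene_id`, `contig`, `strand`, `type`,
#'   `start`, `end`), including derived introns.
#' @export
make_gene_annotation <- function(genome, n_genes, seed = NULL,
                                 exon_range = c(2, 4), exon_len = c(300, 600),
                                 intron_len = c(800, 1600),
                                 utr_len = c(120, 250), gap = 3000) {
  stopifnot(n_genes >= 0)
  if (!is.null(seed)) set.seed(seed)
  lens <- if (methods::is(genome, "XStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else stats::setNames(nchar(genome), names(genome))
  feats <- list(); made <- 0L
  ctg_i <- 1L
  pos <- gap + round(stats::runif(1, 0, 500))
  while (made < n_genes) {
    if (ctg_i > length(lens)) {
      abort("insufficient space for requested gene count",
            class = "mitescape_capacity_error")
    }
    k <- sample(seq(exon_range[1], exon_range[2]), 1)
    ex_w <- sample(seq(exon_len[1], exon_len[2]), k, replace = TRUE)
    in_w <- if (k > 1) sample(seq(intron_len[1], intron_len[2]), k - 1, replace = TRUE) else integer(0)
    glen <- sum(ex_w) + sum(in_w)
    if (pos + glen + gap > lens[ctg_i]) {
      ctg_i <- ctg_i + 1L
      pos <- gap + round(stats::runif(1, 0, 500))
      next
    }
    made <- made + 1L
    gid <- sprintf("gene%03d", made)
    strand <- sample(c("+", "-"), 1)
    starts <- pos + cumsum(c(0, head(ex_w, -1) + in_w))
    ex <- tibble(gene_id = gid, contig = names(lens)[ctg_i], strand = strand,
                 type = "exon", start = as.integer(starts),
                 end = as.integer(starts + ex_w))
    u5 <- sample(seq(utr_len[1], utr_len[2]), 1)
    u3 <- sample(seq(utr_len[1], utr_len[2]), 1)
    gs <- min(ex$start); ge <- max(ex$end)
    if (strand == "+") {
      utr5 <- tibble(start = gs, end = gs + u5)
      utr3 <- tibble(start = ge - u3, end = ge)
    } else {
      utr5 <- tibble(start = ge - u5, end = ge)
      utr3 <- tibble(start = gs, end = gs + u3)
    }
    cds_rng <- IRanges::setdiff(
      IRanges::IRanges(ex$start + 1L, ex$end),
      IRanges::IRanges(c(utr5$start, utr3$start) + 1L, c(utr5$end, utr3$end)))
    add <- function(type, df) tibble(gene_id = gid, contig = names(lens)[ctg_i],
                                     strand = strand, type = type,
                                     start = as.integer(df$start),
                                     end = as.integer(df$end))
    feats[[length(feats) + 1]] <- bind_rows(
      ex,
      add("five_prime_utr", utr5), add("three_prime_utr", utr3),
      add("cds", tibble(start = IRanges::start(cds_rng) - 1L,
                        end = IRanges::end(cds_rng))),
      if (k > 1) add("intron", tibble(start = head(ex$end, -1),
                                      end = ex$start[-1]))
    )
    pos <- pos + glen + gap + round(stats::runif(1, 0, 1000))
  }
  if (length(feats) == 0) return(empty_gene_features())
  bind_rows(feats) |> arrange(.data$contig, .data$start)
}

empty_gene_features <- function() {
  tibble(gene_id = character(), contig = character(), strand = character(),
         type = character(), start = integer(), end = integer())
}

#' Simulate per-library read counts over genes and MITE segments
#'
#' Counts are Poisson draws whose expectations realize the requested M/g
#' ratio per (gene, MITE copy) pair: the gene's expected normalized RPK is
#' `gene_nrpk`, the MITE segment's is `target_mg * gene_nrpk`, and expected
#' counts follow from `count = nRPK * (library_size/1e6) * (length/1000)`.
#'
#' @param planted Truth tibble from [plant_copies()] (needs `copy_id` or
#'   family/contig/start to build one, plus spans for segment lengths).
#' @param genes Tidy gene models.
#' @param libraries Tibble (`library`, `size`) or named numeric vector of
#'   library sizes (total reads).
#' @param target_mg Either a single M/g value applied to every pair, or a
#'   tibble (`gene_id`, `copy_id`, `target_mg`).
#' @param seed Optional integer seed.
#' @param gene_nrpk Expected normalized RPK of each gene.
#' @return List of `counts` (tibble: `feature_id`, `feature_type`, `library`,
#'   `count`, `length_bp`), `library_sizes` (tibble: `library`, `size`), and
#'   `pairs` (the gene-copy-target table used).
#' @export
simulate_read_counts <- function(planted, genes, libraries, target_mg,
                                 seed = NULL, gene_nrpk = 50) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.data.frame(libraries)) {
    libraries <- tibble(library = names(libraries), size = unname(libraries))
  }
  planted <- add_copy_ids(planted)
  spans <- gene_spans(genes)
  if (is.data.frame(target_mg)) {
    pairs <- target_mg
  } else {
    pairs <- planted |>
      filter(!is.na(.data$host_gene)) |>
      transmute(gene_id = .data$host_gene, copy_id = .data$copy_id,
                target_mg = target_mg)
  }
  if (!all(pairs$gene_id %in% spans$gene_id)) {
    abort("unknown gene id in target_mg", class = "mitescape_reference_error")
  }
  if (!all(pairs$copy_id %in% planted$copy_id)) {
    abort("unknown MITE copy id in target_mg", class = "mitescape_reference_error")
  }
  stopifnot(all(pairs$target_mg >= 0))
  gene_len <- spans |> transmute(.data$gene_id, len = .data$end - .data$start)
  mite_len <- planted |> transmute(.data$copy_id, len = .data$end - .data$start)
  feats <- bind_rows(
    spans |> transmute(feature_id = .data$gene_id, feature_type = "gene",
                       length_bp = .data$end - .data$start,
                       nrpk = gene_nrpk),
    pairs |>
      left_join(mite_len, by = "copy_id") |>
      transmute(feature_id = .data$copy_id, feature_type = "mite_segment",
                length_bp = .data$len, nrpk = .data$target_mg * gene_nrpk)
  )
  counts <- tidyr::crossing(feats, libraries) |>
    mutate(mu = .data$nrpk * (.data$size / 1e6) * (.data$length_bp / 1000),
           count = stats::rpois(dplyr::n(), .data$mu)) |>
    select("feature_id", "feature_type", "library", "count", "length_bp")
  list(counts = counts, library_sizes = libraries, pairs = pairs)
}

add_copy_ids <- function(truth) {
  if (!"copy_id" %in% names(truth)) {
    truth$copy_id <- sprintf("%s_%s_%d", truth$family, truth$contig, truth$start)
  }
  truth
}

#' Specification for a synthetic MITE study
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe the
#' standard test-bed: a 2-Mb two-contig genome, eight families spanning the
#' five superfamily groups, 25 copies per family at 10% divergence, 40 genes,
#' and four read libraries of two million reads.
#'
#' @param genome_length Total genome length (bp).
#' @param n_contigs Number of contigs.
#' @param families Tibble of family blueprints (`superfamily`, `length`,
#'   `tir_arm`).
#' @param copies_per_family Copies planted per family.
#' @param divergence Substitution probability per base, in `[0, 0.3]`.
#' @param n_genes Number of gene models.
#' @param libraries Named numeric vector of library sizes.
#' @param target_mg Target M/g ratio for genic copies.
#' @param category_mix Named probabilities over context categories used to
#'   direct planting.
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(genome_length = 2e6, n_contigs = 2,
                           families = default_family_blueprints(),
                           copies_per_family = 25, divergence = 0.10,
                           n_genes = 40,
                           libraries = c(lib1 = 2e6, lib2 = 2e6,
                                         lib3 = 2e6, lib4 = 2e6),
                           target_mg = 2.5,
                           category_mix = c(intergenic = 0.40, intron = 0.20,
                                            upstream = 0.15, downstream = 0.10,
                                            five_prime_utr = 0.05,
                                            three_prime_utr = 0.05, cds = 0.05),
                           seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 0.3)
  planted_bp <- copies_per_family * nrow(families) * mean(families$length)
  stopifnot(genome_length > planted_bp)
  structure(list(genome_length = genome_length, n_contigs = n_contigs,
                 families = families, copies_per_family = copies_per_family,
                 divergence = divergence, n_genes = n_genes,
                 libraries = libraries, target_mg = target_mg,
                 category_mix = category_mix, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_family_blueprints <- function() {
  tibble(
    superfamily = c("Stowaway", "Stowaway", "Tourist", "Tourist",
                    "hAT-like", "hAT-like", "Mutator-like", "MiM"),
    length = c(254L, 230L, 319L, 300L, 454L, 420L, 429L, 380L),
    tir_arm = c(12L, 11L, 14L, 13L, 14L, 15L, 16L, 12L)
  )
}

#' Simulate a full synthetic MITE study with ground truth
#'
#' Generates a random genome, gene models, family consensi, planted copies
#' directed across genomic-context categories (MiM copies are planted
#' intergenic inside (TA)n stretches), and Poisson read counts realizing the
#' requested M/g ratio for genic copies.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `genome`, `families` (tibble incl. consensus), `truth`,
#'   `genes`, `counts`, `library_sizes`, `pairs`, `spec`.
#' @export
simulate_mite_genome <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  genome <- random_genome(spec$genome_length, spec$n_contigs)
  genes <- make_gene_annotation(genome, spec$n_genes)
  fams <- purrr::pmap(spec$families, function(superfamily, length, tir_arm) {
    make_family(superfamily, length, tir_arm,
                name = sprintf("%s_%03d", gsub("-like", "", superfamily),
                               sample.int(999, 1)))
  }) |> bind_rows()
  truth <- NULL
  mix <- spec$category_mix
  for (i in seq_len(nrow(fams))) {
    fam <- fams[i, ]
    n <- spec$copies_per_family
    cats <- if (fam$superfamily == "MiM") rep("intergenic", n) else {
      sample(names(mix), n, replace = TRUE, prob = mix)
    }
    res <- plant_copies(genome, fam, n, spec$divergence, truth = truth,
                        genes = genes, target_category = cats)
    genome <- res$genome; truth <- res$truth; genes <- res$genes
  }
  truth <- add_copy_ids(truth)
  rc <- simulate_read_counts(truth, genes, spec$libraries, spec$target_mg)
  list(genome = genome, families = fams, truth = truth, genes = genes,
       counts = rc$counts, library_sizes = rc$library_sizes, pairs = rc$pairs,
       spec = spec)
}

#' Write a synthetic bundle to disk
#'
#' Emits the genome FASTA, the planted-copy truth TSV, the gene GFF3, the
#' counts TSV and the library-size TSV into `dir`.
#'
#' @param bundle Result of [simulate_mite_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$genome, file.path(dir, "genome.fa"))
  write_fasta(stats::setNames(bundle$families$consensus, bundle$families$name),
              file.path(dir, "families.fa"))
  readr::write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  write_gff3(bundle$genes, file.path(dir, "genes.gff3"))
  readr::write_tsv(bundle$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(bundle$library_sizes, file.path(dir, "library_sizes.tsv"))
  invisible(dir)
}
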