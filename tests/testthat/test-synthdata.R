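test_that("make_family builds consensi with perfect TIRs, deterministically", {
  f <- make_family("Stowaway", 254, 12, seed = 1)
  expect_equal(nchar(f$consensus), 254)
  lead <- substr(f$consensus, 1, 12)
  trail <- substr(f$consensus, 254 - 11, 254)
  expect_identical(trail, rc_chr(lead))
  expect_identical(f$superfamily, "Stowaway")

  a <- make_family("hAT-like", 454, 14, seed = 2)
  b <- make_family("hAT-like", 454, 14, seed = 2)
  expect_identical(a$consensus, b$consensus)

  expect_error(make_family("Stowaway", 30, 20, seed = 1),
               class = "mitescape_parameter_error")
  expect_error(make_family("Stowaway", 701, 12, seed = 1),
               class = "mitescape_parameter_error")

  # MiM consensi carry deliberately weak TIRs
  m <- make_family("MiM", 380, 12, seed = 3)
  expect_lt(detect_tir(m$consensus)$tir_identity, 80)
})

test_that("plant_copies inserts exact copies with conserved TSDs at divergence 0", {
  g <- random_genome(60000, 1, seed = 10)
  fam <- make_family("hAT-like", 454, 14, seed = 11)
  res <- plant_copies(g, fam, 20, 0, seed = 12)
  expect_equal(nrow(res$truth), 20)
  gseq <- as.character(res$genome[[1]])
  for (i in seq_len(20)) {
    tr <- res$truth[i, ]
    planted <- substr(gseq, tr$start + 1, tr$end)
    expected <- if (tr$strand == "-") rc_chr(fam$consensus) else fam$consensus
    expect_identical(planted, expected)
    # TSD duplicated immediately on both sides
    k <- nchar(tr$tsd)
    expect_identical(substr(gseq, tr$start - k + 1, tr$start), tr$tsd)
    expect_identical(substr(gseq, tr$end + 1, tr$end + k), tr$tsd)
  }
})

test_that("plant_copies with n = 0 leaves the genome unchanged", {
  g <- random_genome(10000, 1, seed = 13)
  fam <- make_family("Stowaway", 254, 12, seed = 14)
  res <- plant_copies(g, fam, 0, 0.1, seed = 15)
  expect_identical(as.character(res$genome[[1]]), as.character(g[[1]]))
  expect_equal(nrow(res$truth), 0)
})

test_that("realized divergence concentrates on the requested rate", {
  g <- random_genome(200000, 1, seed = 16)
  fam <- make_family("Tourist", 319, 14, seed = 17)
  res <- plant_copies(g, fam, 50, 0.10, seed = 18)
  # binomial oracle: mean realized divergence ~ Binomial(L, 0.1)/L averaged
  # over 50 copies; 3-sigma bound on the mean
  sigma <- sqrt(0.1 * 0.9 / (319 * 50))
  expect_lt(abs(mean(res$truth$realized_divergence) - 0.10), 3 * sigma)
})

test_that("planting fails cleanly when no insertion space remains", {
  g <- Biostrings::DNAStringSet(c(tiny = bg_dna(900)))
  fam <- make_family("Stowaway", 254, 12, seed = 19)
  expect_error(plant_copies(g, fam, 40, 0, seed = 20),
               class = "mitescape_capacity_error")
})

test_that("MiM copies are planted inside (TA)n stretches", {
  g <- random_genome(60000, 1, seed = 21)
  fam <- make_family("MiM", 380, 12, seed = 22)
  res <- plant_copies(g, fam, 10, 0, seed = 23)
  fl <- extract_flanks(res$genome, res$truth)
  calls <- detect_tsd(fl)
  expect_true(all(calls$ta_stretch))
})

test_that("gene models are non-overlapping with CDS inside the exon union", {
  g <- random_genome(300000, 1, seed = 24)
  genes <- make_gene_annotation(g, 10, seed = 25)
  spans <- gene_spans(genes)
  expect_equal(nrow(spans), 10)
  sp <- dplyr::arrange(spans, start)
  expect_true(all(sp$start[-1] >= sp$end[-nrow(sp)]))
  for (gid in spans$gene_id) {
    gf <- genes[genes$gene_id == gid, ]
    ex <- IRanges::reduce(IRanges::IRanges(gf$start[gf$type == "exon"] + 1L,
                                           gf$end[gf$type == "exon"]))
    cds <- IRanges::IRanges(gf$start[gf$type == "cds"] + 1L,
                            gf$end[gf$type == "cds"])
    expect_equal(sum(IRanges::width(IRanges::intersect(cds, ex))),
                 sum(IRanges::width(IRanges::reduce(cds))))
  }
})

test_that("minus-strand genes carry their 5' UTR on the higher-coordinate side", {
  g <- random_genome(400000, 1, seed = 26)
  genes <- make_gene_annotation(g, 12, seed = 27)
  spans <- gene_spans(genes)
  minus <- spans$gene_id[spans$strand == "-"]
  expect_gt(length(minus), 0)
  for (gid in minus) {
    gf <- genes[genes$gene_id == gid, ]
    u5 <- gf[gf$type == "five_prime_utr", ]
    expect_equal(max(u5$end), max(gf$end))
  }
})

test_that("identical seeds give byte-identical GFF3 and bundles", {
  g <- random_genome(300000, 1, seed = 28)
  f1 <- tempfile(); f2 <- tempfile()
  write_gff3(make_gene_annotation(g, 8, seed = 29), f1)
  write_gff3(make_gene_annotation(g, 8, seed = 29), f2)
  expect_identical(readLines(f1), readLines(f2))

  spec <- synthetic_spec(genome_length = 2e5, n_contigs = 1,
                         families = default_family_blueprints()[c(1, 5), ],
                         copies_per_family = 4, n_genes = 5, seed = 30)
  b1 <- simulate_mite_genome(spec)
  b2 <- simulate_mite_genome(spec)
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$counts, b2$counts)
})

test_that("simulated read counts realize the requested M/g ratio", {
  b <- small_bundle(seed = 105)
  expr <- expression_table(b$counts, b$library_sizes)
  # pooled estimate across libraries: large expectations, Poisson oracle
  pooled <- dplyr::summarise(
    dplyr::group_by(expr, feature_id, feature_type, length_bp),
    count = sum(count), .groups = "drop")
  pooled$nrpk <- normalized_rpk(pooled$count, pooled$length_bp,
                                sum(b$library_sizes$size))
  genes <- pooled[pooled$feature_type == "gene", ]
  mites <- pooled[pooled$feature_type == "mite_segment", ]
  est <- dplyr::inner_join(
    dplyr::transmute(b$pairs, gene_id, copy_id, target_mg),
    dplyr::transmute(genes, gene_id = feature_id, g = nrpk), by = "gene_id")
  est <- dplyr::inner_join(
    est, dplyr::transmute(mites, copy_id = feature_id, m = nrpk),
    by = "copy_id")
  expect_gt(nrow(est), 5)
  expect_lt(abs(mean(est$m / est$g) - 2.5) / 2.5, 0.10)
})

test_that("zero target M/g yields zero MITE-segment reads", {
  b <- small_bundle(seed = 106)
  pairs <- dplyr::mutate(b$pairs, target_mg = 0)
  rc <- simulate_read_counts(b$truth, b$genes, b$library_sizes, pairs,
                             seed = 107)
  m <- rc$counts[rc$counts$feature_type == "mite_segment", ]
  expect_true(all(m$count == 0))
})

test_that("unknown ids in the M/g targets raise reference errors", {
  b <- small_bundle(seed = 108)
  bad <- tibble::tibble(gene_id = "nope", copy_id = b$truth$copy_id[1],
                        target_mg = 1)
  expect_error(simulate_read_counts(b$truth, b$genes, b$library_sizes, bad),
               class = "mitescape_reference_error")
})
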