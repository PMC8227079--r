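# A hand-built two-gene annotation used across the categorization tests.
# gene_plus: + strand, span [10000, 13000): exon1 [10000,10500) with 5'UTR
# [10000,10200), CDS [10200,10500); intron [10500,12000); exon2 [12000,13000)
# with CDS [12000,12700) and 3'UTR [12700,13000).
# gene_minus: - strand, span [20000, 22000): single exon; 5'UTR at the
# higher-coordinate side [21800,22000); CDS [20200,21800); 3'UTR [20000,20200).
toy_genes <- function() {
  tibble::tribble(
    ~gene_id, ~contig, ~strand, ~type, ~start, ~end,
    "gene_plus", "chr", "+", "exon", 10000L, 10500L,
    "gene_plus", "chr", "+", "five_prime_utr", 10000L, 10200L,
    "gene_plus", "chr", "+", "cds", 10200L, 10500L,
    "gene_plus", "chr", "+", "intron", 10500L, 12000L,
    "gene_plus", "chr", "+", "exon", 12000L, 13000L,
    "gene_plus", "chr", "+", "cds", 12000L, 12700L,
    "gene_plus", "chr", "+", "three_prime_utr", 12700L, 13000L,
    "gene_minus", "chr", "-", "exon", 20000L, 22000L,
    "gene_minus", "chr", "-", "five_prime_utr", 21800L, 22000L,
    "gene_minus", "chr", "-", "cds", 20200L, 21800L,
    "gene_minus", "chr", "-", "three_prime_utr", 20000L, 20200L
  )
}

cat_of <- function(start, end) {
  copies <- tibble::tibble(contig = "chr", start = as.integer(start),
                           end = as.integer(end))
  as.character(categorize_copies(copies, toy_genes())$category)
}

test_that("categories follow the stated priority order", {
  expect_identical(cat_of(10199, 10400), "five_prime_utr")  # 1-bp UTR overlap
  expect_identical(cat_of(12650, 12900), "three_prime_utr") # straddles cds+3'UTR
  expect_identical(cat_of(10300, 10400), "cds")
  expect_identical(cat_of(10600, 11000), "intron")          # fully contained
  expect_identical(cat_of(10400, 10700), "cds")             # straddle -> overlap rule
  expect_identical(cat_of(14500, 14800), "intergenic")      # 1.5 kb away
  expect_identical(cat_of(9500, 9700), "upstream")
  expect_identical(cat_of(13100, 13300), "downstream")
})

test_that("upstream/downstream windows are strand-aware and inclusive at 1 kb", {
  # minus-strand gene: upstream is the higher-coordinate side
  expect_identical(cat_of(22100, 22300), "upstream")
  expect_identical(cat_of(19500, 19700), "downstream")
  # distance exactly 1000: inclusive
  expect_identical(cat_of(8800, 9000), "upstream")    # gap = 10000-9000 = 1000
  expect_identical(cat_of(8700, 8999), "intergenic")  # gap = 1001
})

test_that("categorization is a partition and degrades monotonically", {
  set.seed(401)
  copies <- tibble::tibble(
    contig = "chr",
    start = as.integer(round(stats::runif(200, 8000, 24000))))
  copies$end <- copies$start + 150L
  full <- categorize_copies(copies, toy_genes())
  expect_false(any(is.na(full$category)))
  # dropping UTR/CDS annotations can only move copies DOWN the priority list
  stripped <- toy_genes() |>
    dplyr::filter(!type %in% c("five_prime_utr", "three_prime_utr", "cds"))
  reduced <- categorize_copies(copies, stripped)
  expect_true(all(as.integer(reduced$category) >= as.integer(full$category)))
})

test_that("localization tables match planted truth counts exactly", {
  b <- small_bundle(seed = 402, divergence = 0)
  truth <- dplyr::mutate(b$truth,
                         group = ifelse(superfamily == "MiM", "Mutator-like",
                                        superfamily))
  ctx <- categorize_copies(truth, b$genes)
  tab <- localization_table(ctx)
  truth_counts <- table(truth$group, factor(truth$context_truth,
                                            levels = levels(ctx$category)))
  m <- as.matrix(as.data.frame(tab)[, levels(ctx$category)])
  expect_equal(unname(m), unname(as.matrix(as.data.frame.matrix(truth_counts))))
  # margins: total equals number of categorized copies
  expect_equal(sum(m), nrow(truth))

  empty <- localization_table(ctx[0, ])
  expect_equal(sum(as.matrix(as.data.frame(empty)[, -1])), 0)
})

test_that("chi-squared matches the hand-computed Pearson example", {
  m <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y")))
  r <- enrichment_chisq(m)
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(r$df, 1)
  expect_equal(unname(as.vector(r$contributions)), rep(5 / 3, 4),
               tolerance = 1e-10)
  expect_equal(sum(r$contributions), r$statistic)
  # proportional rows: statistic 0
  p <- matrix(c(10, 20, 30, 60), 2, byrow = TRUE)
  expect_lt(enrichment_chisq(p)$statistic, 1e-10)
  # zero margin: degenerate
  z <- matrix(c(5, 0, 7, 0), 2, byrow = TRUE)
  expect_error(enrichment_chisq(z), class = "mitescape_degenerate_table_error")
})

test_that("chi-squared equals the textbook computation on random tables", {
  set.seed(403)
  for (i in 1:20) {
    nr <- sample(2:3, 1); nc <- sample(2:4, 1)
    m <- matrix(rpois(nr * nc, 30) + 1, nr, nc)
    r <- enrichment_chisq(m)
    o <- pearson_oracle(m)
    expect_equal(r$statistic, o$statistic, tolerance = 1e-10)
    expect_equal(r$df, o$df)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-10)
    expect_equal(unname(r$contributions), unname(o$contributions),
                 tolerance = 1e-10)
    expect_identical(r$signs, sign(r$observed - r$expected))
  }
})

test_that("the chi-squared test is calibrated under the null", {
  set.seed(404)
  rej <- vapply(1:400, function(i) {
    rp <- c(0.1, 0.2, 0.3, 0.4)
    cp <- c(0.3, 0.3, 0.2, 0.2)
    m <- matrix(stats::rmultinom(1, 2000, outer(rp, cp)), 4, 4)
    enrichment_chisq(m)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("genic fraction arithmetic matches the published totals", {
  pub <- published_summary("carrot")
  tab <- dplyr::transmute(pub, group,
                          five_prime_utr, three_prime_utr, cds, intron,
                          upstream, downstream, intergenic)
  gf <- genic_fraction(tab)
  expect_equal(gf$percent, 100 * (31025 - 14332) / 31025, tolerance = 1e-10)
  expect_equal(gf$percent_rounded, 54)
  # degenerate directions
  all_inter <- tab; all_inter[, 2:7] <- 0
  expect_equal(genic_fraction(all_inter)$percent, 0)
  no_inter <- tab; no_inter$intergenic <- 0
  expect_equal(genic_fraction(no_inter)$percent, 100)
  none <- tab; none[, -1] <- 0
  expect_error(genic_fraction(none),
               class = "mitescape_undefined_fraction_error")
})

test_that("tidy/glance/autoplot work on chi-squared results", {
  m <- matrix(c(12, 20, 25, 9), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y")))
  r <- enrichment_chisq(m)
  td <- generics::tidy(r)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$contribution), r$statistic)
  gl <- generics::glance(r)
  expect_named(gl, c("statistic", "df", "p_value"))
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
})
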