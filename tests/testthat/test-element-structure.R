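test_that("TSD detection follows the k-cascade with mismatch tolerance", {
  # dinucleotide duplication
  r <- detect_tsd(left = "GGGGCTA", right = "TAGGCC")
  expect_identical(r$tsd, "TA")
  expect_equal(r$tsd_k, 2L)
  expect_true(r$tsd_exact)
  # 8-mer duplication
  r8 <- detect_tsd(left = paste0(bg_dna(10), "ACGTTGCA"),
                   right = paste0("ACGTTGCA", bg_dna(10)))
  expect_equal(r8$tsd_k, 8L)
  expect_identical(r8$tsd, "ACGTTGCA")
  # one mismatch tolerated only for k >= 8
  set.seed(301)
  r8m <- detect_tsd(left = "CCCCCCCCGGACGTTGCA", right = "ACGTTGGACCCCCCCCGG")
  expect_equal(r8m$tsd_k, 8L)
  expect_false(r8m$tsd_exact)
  # short flanks: no call
  r0 <- detect_tsd(left = "G", right = "C")
  expect_equal(r0$tsd_k, 0L)
  # TA-stretch flag
  rta <- detect_tsd(left = "GGCTATATA", right = "TATATAGGC")
  expect_true(rta$ta_stretch)
  expect_false(detect_tsd(left = "GGGGGGGG", right = "CCCCCCCC")$ta_stretch)
})

test_that("TIR detection maximizes ungapped arm identity", {
  set.seed(302)
  # perfect 8-bp TIR
  core <- bg_dna(120)
  el <- paste0("CACTACAA", core, "TTGTAGTG")
  r <- detect_tir(el)
  expect_equal(r$tir_identity, 100)
  expect_gte(r$tir_arm, 8L)
  # 14-bp arm with one mismatch near the start: identity 13/14
  arm <- "GGCATCGGTTCAGA"
  rc_arm <- rc_chr(arm)
  arm_mut <- paste0(substr(arm, 1, 1), "T", substr(arm, 3, 14))  # pos 2 G->T
  el2 <- paste0(arm_mut, bg_dna(150), rc_arm)
  r2 <- detect_tir(el2)
  expect_equal(r2$tir_arm, 14L)
  expect_equal(r2$tir_identity, 100 * 13 / 14, tolerance = 1e-8)
  # too-short element: no call
  r3 <- detect_tir("ACGTACGTACGT")
  expect_equal(r3$tir_arm, 0L)
})

test_that("random sequences essentially never show a recognized TIR", {
  set.seed(303)
  nulls <- vapply(1:300, function(i) detect_tir(bg_dna(300))$tir_recognized,
                  logical(1))
  expect_lt(mean(nulls), 0.02)
})

test_that("superfamily classification follows the canonical TSD table", {
  mk <- function(tsd, k, ta = FALSE, tir = 95) {
    tibble::tibble(tsd = tsd, tsd_k = k, tsd_exact = TRUE, ta_stretch = ta,
                   tir_arm = 12L, tir_identity = tir, tir_recognized = tir >= 80)
  }
  expect_identical(classify_superfamily(mk("TA", 2L))$superfamily, "Stowaway")
  expect_identical(classify_superfamily(mk("TAA", 3L))$superfamily, "Tourist")
  expect_identical(classify_superfamily(mk("TTA", 3L))$superfamily, "Tourist")
  expect_identical(classify_superfamily(mk("CGA", 3L))$superfamily, "Unclassified")
  expect_identical(classify_superfamily(mk("ACGTTGCA", 8L))$superfamily, "hAT-like")
  expect_identical(classify_superfamily(mk("ACGTTGCAA", 9L))$superfamily, "Mutator-like")
  expect_identical(classify_superfamily(mk("ACGTTGCAAT", 10L))$superfamily, "Mutator-like")
  expect_identical(classify_superfamily(mk("", 0L))$superfamily, "Unclassified")
  # TA-stretch with weak TIR: MiM, pooled with Mutator-like as a group
  mim <- classify_superfamily(mk("TA", 2L, ta = TRUE, tir = 60))
  expect_identical(mim$superfamily, "MiM")
  expect_identical(mim$group, "Mutator-like")
  # TA-stretch with a strong TIR stays Stowaway
  sto <- classify_superfamily(mk("TA", 2L, ta = TRUE, tir = 95))
  expect_identical(sto$superfamily, "Stowaway")
})

test_that("structure calls recover every planted superfamily and TSD", {
  b <- small_bundle(seed = 304, divergence = 0)
  st <- call_structure(b$genome, b$truth)
  expect_identical(st$superfamily, b$truth$superfamily)
  fl <- detect_tsd(extract_flanks(b$genome, b$truth))
  # inside a (TA)n stretch the duplication length is ambiguous (any even k
  # matches), so exact-TSD recovery is asserted for non-MiM copies and the
  # TA-stretch flag for MiMs
  mim <- b$truth$superfamily == "MiM"
  expect_identical(fl$tsd[!mim], b$truth$tsd[!mim])
  expect_true(all(fl$ta_stretch[mim]))
})

test_that("family clustering is single-linkage and matches a brute-force oracle", {
  set.seed(305)
  a <- bg_dna(300)
  b <- mutate_at_rate(a, 0.10)       # a~b above threshold
  c2 <- mutate_at_rate(b, 0.10)      # b~c above, a~c likely below
  d <- bg_dna(300)                   # unrelated
  e <- rc_chr(a)                     # related to a on the minus strand
  seqs <- c(A = a, B = b, C = c2, D = d, E = e)
  cl <- cluster_families(seqs)
  oracle <- cluster_oracle(as.list(seqs))
  # identical partitions (compare as label co-membership)
  co_impl <- outer(cl$family[match(names(seqs), cl$name)],
                   cl$family[match(names(seqs), cl$name)], "==")
  co_orac <- outer(oracle, oracle, "==")
  expect_identical(co_impl, co_orac)
  # single linkage pulls A,B,C together with E; D stays alone
  expect_equal(dplyr::n_distinct(cl$family), 2)
  expect_equal(sum(cl$family == cl$family[cl$name == "D"]), 1)
})

test_that("clustering is order-invariant and splits dissimilar pairs", {
  set.seed(306)
  a <- bg_dna(250)
  seqs <- c(x = a, y = mutate_at_rate(a, 0.05), z = bg_dna(250))
  cl1 <- cluster_families(seqs)
  cl2 <- cluster_families(rev(seqs))
  expect_identical(dplyr::arrange(cl1, name), dplyr::arrange(cl2, name))
  # two identical consensi: one family
  cl3 <- cluster_families(c(p = a, q = a))
  expect_equal(dplyr::n_distinct(cl3$family), 1)
  # ~50% identical pair: two families
  half <- mutate_periodic(a, 125)
  cl4 <- cluster_families(c(p = a, q = half))
  expect_equal(dplyr::n_distinct(cl4$family), 2)
})

codon_table <- c(M = "ATG", A = "GCT", R = "CGT", N = "AAT", D = "GAT",
                 C = "TGT", E = "GAA", Q = "CAA", G = "GGT", H = "CAT",
                 I = "ATT", L = "CTT", K = "AAA", F = "TTT", P = "CCT",
                 S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

make_transposase_plant <- function(arm_len = 25, arm_identity = 1,
                                   flank_bp = 2975, seed = 307) {
  set.seed(seed)
  prot <- paste(sample(names(codon_table), 250, replace = TRUE), collapse = "")
  orf <- paste(codon_table[strsplit(prot, "")[[1]]], collapse = "")
  arm <- bg_dna(arm_len)
  arm_right <- rc_chr(arm)
  if (arm_identity < 1) {
    n_mut <- round((1 - arm_identity) * arm_len)
    arm_right <- rc_chr(mutate_periodic(arm, n_mut))
  }
  # non-complementary spacers right at the arm ends keep chance extension out
  contig <- paste0(bg_dna(1000 - 4), "AAAA", arm, bg_dna(flank_bp), orf,
                   bg_dna(flank_bp), arm_right, "AAAA", bg_dna(1000 - 4))
  list(contig = contig, prot = prot,
       bound_start = 1000, bound_end = 1000 + arm_len + flank_bp +
         nchar(orf) + flank_bp + arm_len)
}

test_that("autonomous-element boundaries are exact on constructed plants", {
  pl <- make_transposase_plant()
  res <- mine_autonomous(c(chr = pl$contig), c(tp = pl$prot))
  expect_equal(nrow(res), 1)
  expect_true(res$has_boundaries)
  expect_equal(res$bound_start, pl$bound_start)
  expect_equal(res$bound_end, pl$bound_end)
  expect_gte(res$tir_identity, 99)
})

test_that("weak or absent inverted repeats yield candidates without boundaries", {
  pl40 <- make_transposase_plant(arm_identity = 0.40, seed = 308)
  res40 <- mine_autonomous(c(chr = pl40$contig), c(tp = pl40$prot))
  expect_false(res40$has_boundaries)

  set.seed(309)
  prot <- paste(sample(names(codon_table), 250, replace = TRUE), collapse = "")
  orf <- paste(codon_table[strsplit(prot, "")[[1]]], collapse = "")
  contig <- paste0(bg_dna(4000), orf, bg_dna(4000))
  res0 <- mine_autonomous(c(chr = contig), c(tp = prot))
  expect_equal(nrow(res0), 1)   # transposase region still reported
  expect_false(res0$has_boundaries)
})

test_that("MiM ends copied from a mined element are linked; random ends are not", {
  pl <- make_transposase_plant(seed = 310)
  res <- mine_autonomous(c(chr = pl$contig), c(tp = pl$prot))
  el <- substr(pl$contig, res$bound_start + 1, res$bound_end)
  set.seed(311)
  mim_related <- paste0(substr(el, 1, 50), bg_dna(200),
                        substr(el, nchar(el) - 49, nchar(el)))
  mim_random <- bg_dna(300)
  links <- link_mim_to_autonomous(
    c(rel = mim_related, rnd = mim_random), res, c(chr = pl$contig))
  expect_true(links$linked[links$mim == "rel"])
  expect_false(links$linked[links$mim == "rnd"])
  # too-short consensus flagged per record
  short <- link_mim_to_autonomous(c(tiny = bg_dna(40)), res,
                                  c(chr = pl$contig))
  expect_true(is.na(short$linked))
  expect_match(short$note, "shorter")
})
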