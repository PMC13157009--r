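test_that("expansion ratios follow the clade-mean pseudo-count rule", {
  cl <- six_clades()
  rnase <- expansion_ratio(
    "RNaseA",
    c(celegans = 0, dmelanogaster = 0, drerio = 3, xtropicalis = 1,
      mmusculus = 20, hsapiens = 15), cl)
  expect_equal(rnase$invert_mean, 0)
  expect_equal(rnase$vert_mean, 9.75)
  expect_equal(rnase$ratio, 19.5)
  expect_true(rnase$pseudocount_applied)

  plain <- expansion_ratio(
    "X", c(celegans = 1, dmelanogaster = 1, drerio = 5, xtropicalis = 5,
           mmusculus = 5, hsapiens = 5), cl)
  expect_equal(plain$ratio, 5.0)
  expect_false(plain$pseudocount_applied)

  zero <- expansion_ratio(
    "Y", c(celegans = 0, dmelanogaster = 0, drerio = 0, xtropicalis = 0,
           mmusculus = 0, hsapiens = 0), cl)
  expect_equal(zero$ratio, 0)
  expect_true(zero$pseudocount_applied)

  expect_error(expansion_ratio("Z", c(a = 1), c(a = "invertebrate")),
               "vertebrate clade empty")
})

test_that("expansion ratio is order-invariant and scales linearly", {
  cl <- six_clades()
  counts <- c(celegans = 2, dmelanogaster = 4, drerio = 6,
              xtropicalis = 8, mmusculus = 10, hsapiens = 12)
  r1 <- expansion_ratio("D", counts, cl)$ratio
  r2 <- expansion_ratio("D", counts[sample(names(counts))], cl)$ratio
  expect_equal(r1, r2)
  scaled <- counts
  vert <- names(cl)[cl == "vertebrate"]
  scaled[vert] <- 3 * scaled[vert]
  expect_equal(expansion_ratio("D", scaled, cl)$ratio, 3 * r1)
})

test_that("percentile ranks use the inclusive convention", {
  sc <- stats::setNames(1:100, paste0("p", 1:100))
  pr <- percentile_ranks(sc)
  expect_equal(unname(pr["p100"]), 100)
  expect_equal(unname(pr["p1"]), 1)

  tied <- stats::setNames(rep(5, 10), paste0("t", 1:10))
  expect_true(all(percentile_ranks(tied) == 100))

  # hand-enumerated tie fixture
  v <- stats::setNames(c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7),
                       paste0("x", 1:10))
  pr2 <- percentile_ranks(v)
  expect_equal(unname(pr2["x2"]), 100 * 3 / 10)  # two 2s, one 1 below
  expect_equal(unname(pr2["x7"]), 100 * 7 / 10)  # three 4s, four below
  expect_error(percentile_ranks(numeric(0)), "empty")
})

test_that("percentile + top-decile fraction matches a brute-force count", {
  set.seed(31)
  for (n in c(57, 400, 1000)) {
    sc <- stats::setNames(round(rlnorm(n), 2), paste0("g", seq_len(n)))
    pr <- percentile_ranks(sc)
    frac <- high_fraction(names(sc), pr, threshold_pct = 90)
    brute <- mean(sapply(sc, function(s) {
      100 * sum(sc <= s) / n >= 90
    }))
    expect_equal(frac, brute)
    # inclusive ties only inflate the top bucket
    expect_gte(frac, 0.10 - 1e-9)
  }
})

test_that("high_fraction handles subsets and errors", {
  sc <- stats::setNames(1:100, paste0("p", 1:100))
  pr <- percentile_ranks(sc)
  expect_equal(high_fraction(paste0("p", 91:100), pr), 1.0)
  # a synthetic repertoire tuned to 17.5% top-decile membership
  subset <- c(paste0("p", 94:100), paste0("p", 1:33))
  expect_equal(high_fraction(subset, pr), 0.175)
  expect_error(high_fraction(character(0), pr), "empty")
  expect_error(high_fraction("nope", pr), "missing")
})

test_that("disorder summaries merge intervals before measuring", {
  s <- summarize_disorder("p1", 100, 1, 10)
  expect_equal(s$idr_content_pct, 10)
  expect_equal(s$longest_idr, 10)
  expect_equal(s$total_disordered, 10)
  expect_false(s$high_idr)

  ov <- summarize_disorder("p2", 100, c(1, 5), c(10, 20))
  expect_equal(ov$total_disordered, 20)
  expect_equal(ov$longest_idr, 20)

  # adjacent intervals merge; 30% exactly is NOT high-IDR, 31% is
  adj <- summarize_disorder("p3", 100, c(1, 11), c(10, 20))
  expect_equal(adj$longest_idr, 20)
  expect_false(summarize_disorder("p4", 100, 1, 30)$high_idr)
  expect_true(summarize_disorder("p5", 100, 1, 31)$high_idr)

  expect_error(summarize_disorder("p6", 50, 10, 60), "outside")
})

test_that("re-splitting an interval into adjacent halves changes nothing", {
  set.seed(17)
  for (i in 1:10) {
    L <- sample(50:300, 1)
    st <- sort(sample(seq_len(L - 20), 2))
    en <- pmin(st + sample(5:15, 2), L)
    whole <- summarize_disorder("p", L, st, en)
    cut <- st[1] + 3
    split_s <- c(st[1], cut + 1, st[2])
    split_e <- c(cut, en[1], en[2])
    halves <- summarize_disorder("p", L, split_s, split_e)
    expect_equal(halves$total_disordered, whole$total_disordered)
    expect_equal(halves$longest_idr, whole$longest_idr)
  }
})

test_that("species disorder means average per protein", {
  tracks <- data.frame(
    protein_id = c("a", "b"), protein_length = c(100, 200),
    start = c(1, 1), end = c(40, 60))
  sm <- disorder_summaries(tracks)
  m <- species_disorder_means(sm)
  expect_equal(m$mean_longest_idr, 50)
  expect_equal(m$mean_content_pct, mean(c(40, 30)))
  expect_equal(m$high_idr_fraction, 0.5)

  roster <- data.frame(protein_id = c("a", "b", "c"),
                       protein_length = c(100, 200, 50))
  sm2 <- disorder_summaries(tracks, all_proteins = roster)
  expect_equal(nrow(sm2), 3)
  expect_equal(sm2$total_disordered[sm2$protein_id == "c"], 0)
})

test_that("representative transcript selection cascades its tie-breaks", {
  tt <- data.frame(
    gene_id = "g", transcript_id = c("t1", "t2", "t3"),
    utr5_len = c(10, 10, 10), cds_len = c(300, 300, 300),
    utr3_len = c(100, 200, 150))
  expect_equal(select_representative_transcript(tt)$transcript_id, "t2")

  tie <- data.frame(
    gene_id = "g", transcript_id = c("tA", "tB"),
    utr5_len = c(100, 200), cds_len = c(600, 600),
    utr3_len = c(200, 200))
  expect_equal(select_representative_transcript(tie)$transcript_id, "tB")

  tie2 <- data.frame(
    gene_id = "g", transcript_id = c("tB", "tA"),
    utr5_len = c(100, 100), cds_len = c(600, 600),
    utr3_len = c(200, 200))
  expect_equal(select_representative_transcript(tie2)$transcript_id, "tA")

  single <- tt[1, ]
  expect_equal(select_representative_transcript(single)$transcript_id,
               "t1")
})

test_that("region medians exclude absent annotations and fold change rounds", {
  reps <- data.frame(
    gene_id = paste0("g", 1:4), transcript_id = paste0("t", 1:4),
    utr5_len = c(50, 60, 70, 0), cds_len = c(900, 1000, 1100, 1200),
    utr3_len = c(0, 100, 200, 300))
  rm <- region_medians(reps, "sp1")
  expect_equal(rm$median_utr3, 200)  # the 0 gene is excluded
  expect_equal(rm$median_cds, 1050)  # but contributes to CDS
  expect_equal(rm$median_utr5, 60)
  expect_equal(rm$n_genes, 4)

  expect_equal(fold_change(1444, 163), 8.9)
  expect_equal(fold_change(10, 4, digits = NULL), 2.5)
  expect_error(fold_change(1, 0), "> 0")

  none <- reps
  none$utr3_len <- 0L
  expect_error(region_medians(none, "sp1"), "3'UTR")
})

test_that("orthogroup classification follows the species/copy bands", {
  og <- data.frame(
    og_id = c(rep("OG1", 6), rep("OG2", 4), rep("OG3", 1)),
    species_id = c(paste0("s", 1:6), "s1", "s1", "s2", "s2", "s3"),
    gene_id = paste0("g", 1:11))
  cls <- classify_orthogroups(og, n_study_species = 6)
  expect_equal(cls$conservation, c("universal", "moderate",
                                   "species_specific"))
  expect_equal(cls$copy_class, c("single_copy", "small", "single_copy"))
  expect_equal(cls$max_copies, c(1L, 2L, 1L))

  sm <- summarize_orthogroups(cls)
  expect_equal(sum(sm$conservation$n), nrow(cls))
  expect_equal(sum(sm$copy_class$n), nrow(cls))
})

test_that("the 527-orthogroup fixture reports 72.1% strict single copy", {
  og <- sim_orthogroups(seed = 99)
  cls <- classify_orthogroups(og$orthogroups)
  sm <- summarize_orthogroups(cls)
  single <- sm$copy_class[sm$copy_class$category == "single_copy", ]
  expect_equal(sm$total, 527)
  expect_equal(single$n, 380)
  expect_equal(single$pct, 72.1)
  small <- sm$copy_class[sm$copy_class$category == "small", ]
  expect_equal(small$n, 96)
  expect_equal(small$pct, 18.2)
  large <- sm$copy_class[sm$copy_class$category == "large", ]
  expect_equal(large$n, 8)
  expect_equal(large$pct, 1.5)
  # percentages sum to 100 up to rounding
  expect_lt(abs(sum(sm$copy_class$pct) - 100), 0.3)
})

test_that("evidence fractions reproduce the per-domain percentages", {
  five <- stats::setNames(c("established", "established", "limited",
                            "limited", "limited"), paste0("g", 1:5))
  expect_equal(round(100 * evidence_fraction(five)), 40)
  seven <- stats::setNames(c("established", rep("limited", 6)),
                           paste0("g", 1:7))
  expect_equal(round(100 * evidence_fraction(seven)), 14)
  expect_equal(evidence_fraction(c(a = "established")), 1)
  expect_error(evidence_fraction(c(a = "unknown")), "label")
  expect_error(evidence_fraction(character(0)), "no labeled")
})
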