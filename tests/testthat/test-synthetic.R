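test_that("realizable rho values are the discrete n-point spectrum", {
  r6 <- realizable_rhos(6)
  expect_length(r6, 36)  # Sum d^2 ranges over even values 0..70
  expect_true(all(diff(r6) > 0))
  expect_true(any(abs(r6 - 0.8857143) < 1e-6))
  expect_equal(range(r6), c(-1, 1))
})

test_that("the panel generator hits the target rho through the pipeline", {
  sim <- sim_species_panel(seed = 11)  # defaults: the study conditions
  divs <- vapply(names(sim$genes), function(sp) {
    family_diversity(assign_families(sim$genes[[sp]], sim$catalog))
  }, integer(1))
  expect_equal(unname(divs), unname(sim$diversity))
  r <- spearman_cor(divs, sim$species$neuron_count)
  expect_equal(round(r$rho, 3), 0.886)
})

test_that("target rho 1 yields diversity increasing with the covariate", {
  sim <- sim_species_panel(target_rho = 1, seed = 4)
  o <- order(sim$species$neuron_count)
  expect_true(all(diff(sim$diversity[o]) > 0))
})

test_that("unrealizable targets fail with nearest alternatives listed", {
  expect_error(sim_species_panel(target_rho = 0.87, seed = 1),
               "nearest realizable")
})

test_that("generation is a pure function of config and seed", {
  s1 <- sim_species_panel(seed = 5)
  s2 <- sim_species_panel(seed = 5)
  expect_identical(s1, s2)
  s3 <- sim_species_panel(seed = 6)
  expect_false(identical(s1$genes, s3$genes))

  o1 <- sim_orthogroups(seed = 3)
  o2 <- sim_orthogroups(seed = 3)
  expect_identical(o1, o2)
})

test_that("BM traits respect sigma2 = 0 and reproduce under a seed", {
  tr <- read_newick_text("((A:1,B:1):1,(C:1.5,D:0.5):0.5);")
  z <- sim_bm_traits(tr, sigma2 = 0, lambda = 1, n_replicates = 3,
                     seed = 1, mean = 2)
  expect_true(all(z == 2))
  y1 <- sim_bm_traits(tr, 1, 0.5, n_replicates = 2, seed = 9)
  y2 <- sim_bm_traits(tr, 1, 0.5, n_replicates = 2, seed = 9)
  expect_identical(y1, y2)
  expect_equal(rownames(y1), tr$tip.label)
})

test_that("lambda = 0 traits have near-diagonal sample covariance", {
  set.seed(2)
  tr <- ape::rcoal(6)
  Y <- sim_bm_traits(tr, sigma2 = 1, lambda = 0, n_replicates = 4000,
                     seed = 12)
  S <- stats::cov(t(Y))
  off <- S[upper.tri(S)]
  expect_lt(max(abs(off)), 0.12)  # Monte-Carlo zero
  expect_gt(min(diag(S)), 0.5)    # variances track the tip depths
})

test_that("orthogroup mixtures are realized exactly and recovered", {
  og <- sim_orthogroups(n = 100,
                        copy_mixture = c(single_copy = 60, small = 25,
                                         medium = 10, large = 5),
                        conservation_mixture = c(species_specific = 10,
                                                 moderate = 40,
                                                 conserved = 30,
                                                 universal = 20),
                        seed = 5)
  cls <- classify_orthogroups(og$orthogroups)
  # the classifier recovers every stored truth label
  m <- merge(cls, og$truth, by = "og_id")
  expect_equal(m$conservation.x, m$conservation.y)
  expect_equal(m$copy_class.x, m$copy_class.y)
  sm <- summarize_orthogroups(cls)
  expect_equal(sm$copy_class$n, c(60L, 25L, 10L, 5L))
  expect_equal(sm$conservation$n, c(10L, 40L, 30L, 20L))
})

test_that("orthogroup class counts are invariant to gene-name shuffling", {
  o1 <- sim_orthogroups(n = 60, seed = 1)
  shuffled <- o1$orthogroups
  set.seed(99)
  shuffled$gene_id <- sample(sprintf("anon%04d", seq_len(nrow(shuffled))))
  s1 <- summarize_orthogroups(classify_orthogroups(o1$orthogroups))
  s2 <- summarize_orthogroups(classify_orthogroups(shuffled))
  expect_equal(s1, s2)
})

test_that("proportion-style mixtures allocate deterministically", {
  og <- sim_orthogroups(n = 10,
                        copy_mixture = c(single_copy = 0.72,
                                         small = 0.18, medium = 0.08,
                                         large = 0.02),
                        conservation_mixture = c(species_specific = 0.25,
                                                 moderate = 0.25,
                                                 conserved = 0.25,
                                                 universal = 0.25),
                        seed = 2)
  sm <- summarize_orthogroups(classify_orthogroups(og$orthogroups))
  expect_equal(sum(sm$copy_class$n), 10L)
  # floors 7/1/0/0 leave 2; the remainder goes to the largest classes
  expect_equal(sm$copy_class$n, c(8L, 2L, 0L, 0L))
})

test_that("score and transcript generators recover their scale targets", {
  sc <- sim_score_table(5000, meanlog = 1, sdlog = 0.5, seed = 7)
  expect_equal(stats::median(sc$score), exp(1), tolerance = 0.05)

  tt <- sim_transcript_table(800, utr3_median = 400, seed = 8)
  reps <- representative_transcripts(tt)
  m <- region_medians(reps, "sp")
  # longest-3'UTR selection biases the realized median upward
  expect_gt(m$median_utr3, 400 * 0.9)
  expect_lt(m$median_utr3, 400 * 1.8)
})

test_that("disorder generator approaches its target content", {
  tr <- sim_disorder_tracks(600, target_content_pct = 18, seed = 9)
  sm <- species_disorder_means(disorder_summaries(tr))
  expect_equal(sm$mean_content_pct, 18, tolerance = 0.15)
  expect_true(all(tr$end <= tr$protein_length))
})
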