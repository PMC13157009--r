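test_that("single-family matches and non-canonical fallback work", {
  cat <- tiny_catalog()
  a <- assign_families(make_gene("g1", "RRM_1"), cat)
  expect_equal(a$family_id, "famA")
  expect_equal(a$matched_domains[[1]], "RRM_1")

  none <- assign_families(make_gene("g2", character(0)), cat)
  expect_equal(none$family_id, NON_CANONICAL)

  unknown <- assign_families(make_gene("g3", "PF99999"), cat)
  expect_equal(unknown$family_id, NON_CANONICAL)
})

test_that("multi-family genes go to the highest reference gene count", {
  cat <- tiny_catalog()
  # famA count 500 beats famB count 100
  a <- assign_families(make_gene("g1", c("KH_1", "RRM_1")), cat)
  expect_equal(a$family_id, "famA")
  # matched domains are restricted to the winning family's domains
  expect_equal(a$matched_domains[[1]], "RRM_1")
})

test_that("count ties break lexicographically, independent of domain order", {
  cat <- tiny_catalog()  # famB and famC both count 100
  a1 <- assign_families(make_gene("g1", c("KH_1", "YTH")), cat)
  a2 <- assign_families(make_gene("g1", c("YTH", "KH_1")), cat)
  expect_equal(a1$family_id, "famB")
  expect_equal(a2$family_id, "famB")
})

test_that("assignment is invariant under domain-set shuffling", {
  cat <- tiny_catalog()
  doms <- c("RRM_1", "KH_1", "YTH", "PFX")
  set.seed(1)
  fams <- replicate(20, {
    assign_families(make_gene("g", sample(doms)), cat)$family_id
  })
  expect_length(unique(fams), 1)
})

test_that("domain matching is case-insensitive", {
  cat <- tiny_catalog()
  expect_equal(assign_families(make_gene("g", "rrm_1"), cat)$family_id,
               "famA")
  expect_equal(assign_families(make_gene("g", "Yth"), cat)$family_id,
               "famC")
})

test_that("family diversity counts distinct families, not genes", {
  a <- data.frame(
    gene_id = paste0("g", 1:4), species_id = "sp1",
    family_id = c("famA", "famA", "famB", NON_CANONICAL),
    stringsAsFactors = FALSE)
  a$matched_domains <- list("RRM_1", "RRM_2", "KH_1", character(0))
  expect_equal(family_diversity(a), 2)
  expect_equal(family_diversity(a[a$family_id == NON_CANONICAL, ]), 0)
  expect_equal(family_diversity(a[0, ]), 0)
})

test_that("adding genes never decreases diversity (monotonicity)", {
  cat <- tiny_catalog()
  genes <- rbind(make_gene("g1", "RRM_1"), make_gene("g2", "KH_1"))
  base <- family_diversity(assign_families(genes, cat))
  for (extra in list("YTH", "RRM_2", character(0))) {
    grown <- rbind(genes, make_gene("gX", extra))
    expect_gte(family_diversity(assign_families(grown, cat)), base)
  }
})

test_that("diversity is bounded by the catalog size", {
  sim <- sim_species_panel(n_species = 4, target_rho = 1,
                           family_pool_size = 50,
                           diversity_range = c(10, 40), seed = 3)
  for (sp in names(sim$genes)) {
    d <- family_diversity(assign_families(sim$genes[[sp]], sim$catalog))
    expect_lte(d, 50)
  }
})

test_that("clan rollup counts clans, with singleton fallback", {
  cat <- tiny_catalog(with_clans = TRUE)
  genes <- rbind(make_gene("g1", "KH_1"), make_gene("g2", "YTH"))
  a <- assign_families(genes, cat)
  # KH_1 and YTH share clan CL1
  expect_equal(clan_diversity(a, cat), 1)

  cat_nc <- tiny_catalog(with_clans = FALSE)
  a2 <- assign_families(genes, cat_nc)
  # no clan map: every matched domain is its own pseudo-clan
  expect_equal(clan_diversity(a2, cat_nc), 2)

  # mixed: RRM_1 unmapped -> pseudo-clan adds 1
  a3 <- assign_families(rbind(genes, make_gene("g3", "RRM_1")), cat)
  expect_equal(clan_diversity(a3, cat), 2)
})

test_that("overlap report computes count, percentage and domain carve-out", {
  r <- overlap_report(c("a", "b", "c", "d"), c("c", "d", "e"))
  expect_equal(r$overlap, 2)
  expect_equal(r$percentage, 50.0)

  # repertoire-scale fixture: 2961 RBPs, 194 shared, 86 carrying zf-C2H2
  rbp <- sprintf("r%04d", 1:2961)
  tf <- c(rbp[1:194], sprintf("t%04d", 1:500))
  gd <- c(lapply(1:86, function(i) c("zf-C2H2", "KH_1")),
          lapply(87:194, function(i) "RRM_1"))
  names(gd) <- rbp[1:194]
  r2 <- overlap_report(rbp, tf, exclude_domains = "zf-C2H2",
                       gene_domains = gd)
  expect_equal(r2$overlap, 194)
  expect_equal(r2$percentage, 6.6)
  expect_equal(r2$excluded_domain_overlap, 86)

  expect_error(overlap_report(character(0), "x"), "empty")
})

test_that("a catalog merged from classified species classifies a held-out one", {
  sim <- sim_species_panel(n_species = 6, target_rho = 1,
                           family_pool_size = 60,
                           diversity_range = c(20, 50), seed = 8)
  held_out <- names(sim$genes)[1]
  sources <- do.call(rbind, lapply(names(sim$genes)[-1], function(sp) {
    assign_families(sim$genes[[sp]], sim$catalog)
  }))
  merged <- catalog_from_assignments(sources)
  a <- assign_families(sim$genes[[held_out]], merged)
  # the five source species jointly realize every family of the held-out
  # species, so classification under the merged catalog is lossless
  expect_equal(family_diversity(a), unname(sim$diversity[held_out]))
})
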