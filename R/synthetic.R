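#' Spearman correlations realizable for a given sample size
#'
#' With n distinct ranks Spearman's rho takes only the discrete values
#' `1 - 6 * S / (n * (n^2 - 1))` where S is an achievable sum of squared
#' rank differences; for n = 6 there are just 36 of them. The generator
#' therefore constructs a rank permutation with the required S rather
#' than sampling noise and hoping to land on the target.
#'
#' @param n number of observations (2..8; the permutation space is
#'   enumerated).
#' @return Sorted numeric vector of realizable rho values.
#' @export
realizable_rhos <- function(n) {
  if (n < 2 || n > 8) stop("realizable_rhos supports 2 <= n <= 8",
                           call. = FALSE)
  perms <- .permutations(n)
  S <- apply(perms, 1, function(p) sum((p - seq_len(n))^2))
  sort(unique(1 - 6 * S / (n * (n^2 - 1))))
}

# first (lexicographic) permutation of 1..n achieving the target rho;
# the tolerance accepts 3-decimal printed roundings of the exact
# discrete values (e.g. 0.886 for 0.885714... at n = 6)
.rho_permutation <- function(n, target_rho, tol = 5e-4) {
  perms <- .permutations(n)
  rho <- 1 - 6 * apply(perms, 1, function(p) sum((p - seq_len(n))^2)) /
    (n * (n^2 - 1))
  hit <- which(abs(rho - target_rho) < tol)
  if (length(hit) == 0) {
    vals <- realizable_rhos(n)
    near <- vals[order(abs(vals - target_rho))][1:min(3, length(vals))]
    stop("target_rho = ", target_rho, " is not realizable for n = ", n,
         "; nearest realizable values: ",
         paste(round(near, 4), collapse = ", "), call. = FALSE)
  }
  perms[hit[1], ]
}

#' Generate a synthetic species panel with known diversity ground truth
#'
#' Builds species metadata, per-species gene tables and a reference
#' family catalog such that the family diversity vector recovered by the
#' classify-count pipeline achieves a REQUESTED Spearman correlation
#' against the complexity covariate exactly. The diversity ranks are
#' constructed combinatorially (a permutation with the required sum of
#' squared rank differences); gene tables then realize each species'
#' diversity by drawing genes only from its allotted families.
#'
#' Defaults reproduce the six-species study conditions: neuron counts
#' spanning 302 to 8.6e10, two invertebrates and four vertebrates, a
#' 686-family reference catalog, diversity between 397 and 472 distinct
#' families, and roughly 3.6 genes per family as in curated RBP lists.
#'
#' @param n_species number of species (default 6).
#' @param target_rho requested Spearman between diversity and covariate
#'   (default 0.886; must be realizable for `n_species`, see
#'   [realizable_rhos()]). Ignored when `diversity` is supplied.
#' @param neuron_counts complexity covariate (defaults to the bundled
#'   six-species counts when `n_species` is 6, else a geometric ladder).
#' @param clades clade labels per species (default: first third
#'   invertebrate, rest vertebrate, matching the 2 + 4 study split).
#' @param family_pool_size catalog size (default 686).
#' @param diversity_range min/max distinct families per species
#'   (default c(397, 472)).
#' @param diversity optional explicit diversity vector (one count per
#'   species) overriding the target-rho construction.
#' @param genes_per_family mean paralog count per represented family
#'   (default 2 to keep fixture tables small; rank structure, not table
#'   size, is what downstream statistics consume).
#' @param noncanonical_fraction fraction of extra domain-less genes
#'   appended per species (default 0.1).
#' @param seed mandatory integer seed; generation is a pure function of
#'   the configuration and seed.
#' @return List: `species` (metadata data frame), `genes` (named list of
#'   gene tables), `catalog` ([family_catalog]), `diversity` (named
#'   ground-truth vector).
#' @export
sim_species_panel <- function(n_species = 6, target_rho = 0.886,
                              neuron_counts = NULL, clades = NULL,
                              family_pool_size = 686,
                              diversity_range = c(397, 472),
                              diversity = NULL,
                              genes_per_family = 2,
                              noncanonical_fraction = 0.1,
                              seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(neuron_counts)) {
    neuron_counts <- if (n_species == 6) {
      c(302, 2e5, 1e7, 1.6e7, 7.1e7, 8.6e10)
    } else {
      302 * 10^(seq(0, 8, length.out = n_species))
    }
  }
  stopifnot(length(neuron_counts) == n_species)
  if (is.null(clades)) {
    n_inv <- max(1, floor(n_species / 3))
    clades <- c(rep("invertebrate", n_inv),
                rep("vertebrate", n_species - n_inv))
  }
  species_id <- if (n_species == 6) {
    c("celegans", "dmelanogaster", "drerio", "xtropicalis", "mmusculus",
      "hsapiens")
  } else {
    sprintf("sp%02d", seq_len(n_species))
  }

  if (is.null(diversity)) {
    # species are in increasing covariate order here, so covariate ranks
    # are 1..n and the permutation directly gives the diversity ranks
    o <- order(neuron_counts)
    perm <- .rho_permutation(n_species, target_rho)
    levels <- round(seq(diversity_range[1], diversity_range[2],
                        length.out = n_species))
    diversity <- numeric(n_species)
    diversity[o] <- levels[perm]
  }
  stopifnot(length(diversity) == n_species,
            max(diversity) <= family_pool_size)
  names(diversity) <- species_id

  catalog_df <- data.frame(
    family_id = sprintf("FAM%04d", seq_len(family_pool_size)),
    # strictly decreasing reference counts make the priority rule
    # deterministic for multi-family genes
    reference_gene_count = family_pool_size + 1 - seq_len(family_pool_size),
    stringsAsFactors = FALSE
  )
  catalog_df$domains <- lapply(seq_len(family_pool_size),
                               function(i) sprintf("PF%05d", i))
  catalog <- family_catalog(catalog_df)

  genes <- stats::setNames(vector("list", n_species), species_id)
  for (s in seq_len(n_species)) {
    d <- diversity[s]
    fams <- seq_len(d)  # species s realizes families 1..d
    copies <- 1L + stats::rpois(d, max(genes_per_family - 1, 0))
    fam_of_gene <- rep(fams, copies)
    n_extra <- round(noncanonical_fraction * length(fam_of_gene))
    gene_id <- sprintf("%s_g%05d", species_id[s],
                       seq_len(length(fam_of_gene) + n_extra))
    tbl <- data.frame(gene_id = gene_id, species_id = species_id[s],
                      stringsAsFactors = FALSE)
    tbl$accessions <- as.list(sprintf("ACC_%s", gene_id))
    tbl$pfam_domains <- c(
      lapply(fam_of_gene, function(f) catalog$domains[[f]]),
      rep(list(character(0)), n_extra)
    )
    tbl$protein_length <- stats::rpois(nrow(tbl), 450)
    genes[[s]] <- tbl
  }

  species <- data.frame(species_id = species_id,
                        display_name = species_id,
                        clade = clades,
                        neuron_count = neuron_counts,
                        stringsAsFactors = FALSE)
  list(species = species, genes = genes, catalog = catalog,
       diversity = diversity)
}

#' Simulate Brownian-motion traits on a tree with known lambda
#'
#' Draws replicate trait vectors from a multivariate normal with
#' covariance `sigma2 * lambda_transform(C, lambda)`, the generating
#' model under which [optimize_lambda()] should recover the phylogenetic
#' signal strength.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length);
#'   `sigma2 = 0` yields constant traits.
#' @param lambda true Pagel's lambda in \[0, 1\].
#' @param n_replicates number of independent trait vectors.
#' @param seed mandatory integer seed.
#' @param mean trait mean (default 0).
#' @return Matrix taxa x replicates with taxa rownames.
#' @export
sim_bm_traits <- function(tree, sigma2 = 1, lambda = 1, n_replicates = 1,
                          seed, mean = 0) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]",
                                     call. = FALSE)
  C <- phylo_cov(tree)
  n <- nrow(C)
  set.seed(as.integer(seed))
  if (sigma2 == 0) {
    out <- matrix(mean, n, n_replicates)
  } else {
    V <- sigma2 * lambda_transform(C, lambda)
    L <- tryCatch(chol(V), error = function(e) {
      stop("transformed covariance is not positive definite",
           call. = FALSE)
    })
    Z <- matrix(stats::rnorm(n * n_replicates), n, n_replicates)
    out <- mean + crossprod(L, Z)
  }
  rownames(out) <- rownames(C)
  out
}

# deterministic largest-remainder allocation of n items to mixture weights
.allocate_mixture <- function(n, mixture) {
  w <- mixture / sum(mixture)
  base <- floor(n * w)
  rem <- n - sum(base)
  if (rem > 0) {
    # remainder goes to the largest class(es), largest first
    o <- order(-w, seq_along(w))
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(mixture))
}

#' Generate orthogroups with labeled ground-truth classes
#'
#' Builds an orthogroup membership table whose realized copy-number and
#' conservation class counts match the requested mixtures exactly
#' (deterministic largest-remainder allocation, never sampling), so the
#' classifier can be cross-checked against stored truth labels. Defaults
#' reproduce the study's 527-orthogroup composition: 380 strict
#' single-copy, 96 small, 43 medium, 8 large expansions, with the
#' conservation mixture 13 species-specific / 366 moderate / 122
#' conserved / 26 universal.
#'
#' @param n total orthogroups (default 527).
#' @param copy_mixture counts or proportions for
#'   single_copy/small/medium/large.
#' @param conservation_mixture counts or proportions for
#'   species_specific/moderate/conserved/universal.
#' @param species species ids (default the six-species panel).
#' @param seed mandatory seed (drives which species host each group and
#'   the within-band copy numbers; class counts are unaffected).
#' @return List: `orthogroups` (long-format table as from
#'   [read_orthogroups()]), `truth` (data frame `og_id`, `conservation`,
#'   `copy_class`).
#' @export
sim_orthogroups <- function(n = 527,
                            copy_mixture = c(single_copy = 380,
                                             small = 96, medium = 43,
                                             large = 8),
                            conservation_mixture = c(species_specific = 13,
                                                     moderate = 366,
                                                     conserved = 122,
                                                     universal = 26),
                            species = c("celegans", "dmelanogaster",
                                        "drerio", "xtropicalis",
                                        "mmusculus", "hsapiens"),
                            seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  n_sp <- length(species)
  copy_n <- .allocate_mixture(n, copy_mixture)
  cons_n <- .allocate_mixture(n, conservation_mixture)
  copy_lab <- rep(names(copy_n), copy_n)
  cons_lab <- rep(names(cons_n), cons_n)
  # pair the two label sequences after one seeded shuffle of each; every
  # (conservation, copy) combination is constructible
  copy_lab <- sample(copy_lab)
  cons_lab <- sample(cons_lab)

  n_species_for <- function(lab) {
    switch(lab,
           species_specific = 1L,
           moderate = sample(2:3, 1),
           conserved = sample(seq(4L, max(4L, n_sp - 1L)), 1),
           universal = n_sp)
  }
  max_copies_for <- function(lab) {
    switch(lab,
           single_copy = 1L,
           small = 2L,
           medium = sample(3:5, 1),
           large = sample(6:8, 1))
  }

  rows <- vector("list", n)
  truth <- data.frame(og_id = sprintf("OG%07d", seq_len(n)),
                      conservation = cons_lab, copy_class = copy_lab,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    k <- n_species_for(cons_lab[i])
    present <- sort(sample.int(n_sp, k))
    maxc <- max_copies_for(copy_lab[i])
    copies <- rep(1L, k)
    copies[sample.int(k, 1)] <- maxc  # one species carries the maximum
    if (k > 1 && maxc > 1) {
      # others vary freely below the class maximum
      others <- setdiff(seq_len(k), which(copies == maxc)[1])
      copies[others] <- sample.int(maxc, length(others), replace = TRUE)
    }
    sp <- rep(species[present], copies)
    rows[[i]] <- data.frame(
      og_id = truth$og_id[i], species_id = sp,
      gene_id = sprintf("%s_%s_c%d", truth$og_id[i], sp,
                        unlist(lapply(copies, seq_len))),
      stringsAsFactors = FALSE)
  }
  og <- do.call(rbind, rows)
  rownames(og) <- NULL
  attr(og, "og_order") <- truth$og_id
  list(orthogroups = og, truth = truth)
}

#' Simulate a log-normal proteome score table
#'
#' Stand-in for per-protein propensity score exports. Only the rank
#' structure matters downstream (scores are percentile-normalized within
#' proteome), so the log-normal family choice is cosmetic.
#'
#' @param n proteome size.
#' @param meanlog,sdlog log-normal parameters (defaults 0, 1).
#' @param seed mandatory seed.
#' @param prefix id prefix.
#' @return Gene-level score table (columns `id`, `score`).
#' @export
sim_score_table <- function(n, meanlog = 0, sdlog = 1, seed,
                            prefix = "prot") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  out <- data.frame(id = sprintf("%s%05d", prefix, seq_len(n)),
                    score = stats::rlnorm(n, meanlog, sdlog),
                    stringsAsFactors = FALSE)
  attr(out, "level") <- "gene"
  out
}

#' Simulate disorder-interval tracks with a target mean content
#'
#' Each protein receives one or two disordered intervals sized so the
#' per-protein content scatters around `target_content_pct`; the
#' realized species mean converges to the target as n grows.
#'
#' @param n number of proteins.
#' @param target_content_pct mean disorder content to emulate
#'   (default 18, inside the 15-20% band typical of RBP repertoires).
#' @param len_meanlog,len_sdlog log-normal protein-length parameters
#'   (defaults give median ~400 aa).
#' @param seed mandatory seed.
#' @param prefix id prefix.
#' @return Disorder-interval data frame (`protein_id`, `protein_length`,
#'   `start`, `end`).
#' @export
sim_disorder_tracks <- function(n, target_content_pct = 18,
                                len_meanlog = log(400), len_sdlog = 0.4,
                                seed, prefix = "prot") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    L <- max(30L, as.integer(round(stats::rlnorm(1, len_meanlog,
                                                 len_sdlog))))
    content <- min(95, max(0, stats::rnorm(1, target_content_pct, 8)))
    total <- as.integer(round(content / 100 * L))
    id <- sprintf("%s%05d", prefix, i)
    if (total < 1) next  # fully ordered protein: no interval row
    two <- total >= 10 && stats::runif(1) < 0.5
    lens <- if (two) {
      a <- sample.int(total - 1, 1)
      c(a, total - a)
    } else total
    # place intervals left to right with >= 2 aa gaps so they stay disjoint
    gap <- 2L
    starts <- integer(length(lens))
    pos <- 1L
    ok <- TRUE
    for (j in seq_along(lens)) {
      room <- L - (sum(lens[j:length(lens)]) +
                   gap * (length(lens) - j)) - pos + 1L
      if (room < 0) { ok <- FALSE; break }
      starts[j] <- pos + sample.int(room + 1L, 1) - 1L
      pos <- starts[j] + lens[j] + gap
    }
    if (!ok) { lens <- min(total, L); starts <- 1L }
    rows[[i]] <- data.frame(protein_id = id, protein_length = L,
                            start = starts,
                            end = starts + lens - 1L,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a transcript-region length table
#'
#' Per gene, one to three transcripts with log-normal region lengths;
#' the 3'UTR scale parameter is the target MEDIAN 3'UTR of the species'
#' representative transcripts (up to selection bias from picking the
#' longest-3'UTR isoform, which inflates the realized median slightly).
#'
#' @param n_genes number of genes.
#' @param utr3_median target 3'UTR median scale in nucleotides.
#' @param cds_median,utr5_median scales for the other regions
#'   (defaults 1300 and 170 nt).
#' @param seed mandatory seed.
#' @param prefix gene id prefix.
#' @return Transcript table (`gene_id`, `transcript_id`, `utr5_len`,
#'   `cds_len`, `utr3_len`).
#' @export
sim_transcript_table <- function(n_genes, utr3_median, cds_median = 1300,
                                 utr5_median = 170, seed,
                                 prefix = "gene") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    k <- sample.int(3, 1)
    gid <- sprintf("%s%05d", prefix, i)
    rows[[i]] <- data.frame(
      gene_id = gid,
      transcript_id = sprintf("%s.t%d", gid, seq_len(k)),
      utr5_len = as.integer(round(stats::rlnorm(k, log(utr5_median), 0.5))),
      cds_len = as.integer(round(stats::rlnorm(k, log(cds_median), 0.3))),
      utr3_len = as.integer(round(stats::rlnorm(k, log(utr3_median), 0.5))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
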