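# shared fixtures and independent oracles

# the six-species study data (printed family counts and neuron counts)
study_pairs <- function() {
  p <- six_species_panel()
  list(x = p$rbp_family_count, y = p$neuron_count, ids = p$species_id,
       clades = stats::setNames(p$clade, p$species_id))
}

# brute-force Spearman via the classic no-ties formula 1 - 6*S/(n(n^2-1))
spearman_oracle <- function(x, y) {
  n <- length(x)
  S <- sum((rank(x) - rank(y))^2)
  1 - 6 * S / (n * (n^2 - 1))
}

# independent MRCA-depth covariance: walk root-to-tip paths explicitly
brute_force_cov <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  # edges to parents
  parent_of <- integer(max(tree$edge))
  elen_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  elen_of[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(tip) {
    nodes <- tip
    while (nodes[length(nodes)] != root) {
      nodes <- c(nodes, parent_of[nodes[length(nodes)]])
    }
    nodes
  }
  depth_of <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + elen_of[node]
      node <- parent_of[node]
    }
    d
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    pi <- path_to_root(i)
    for (j in seq_len(n)) {
      common <- intersect(pi, path_to_root(j))
      mrca <- common[1]  # paths are tip->root ordered, first shared = MRCA
      C[i, j] <- depth_of(mrca)
    }
  }
  C
}

# tiny catalog: famA (2 domains, big), famB, famC sharing a clan with famB
tiny_catalog <- function(with_clans = FALSE) {
  fams <- data.frame(
    family_id = c("famA", "famB", "famC"),
    reference_gene_count = c(500, 100, 100),
    stringsAsFactors = FALSE)
  fams$domains <- list(c("RRM_1", "RRM_2"), "KH_1", "YTH")
  clan_map <- if (with_clans) {
    data.frame(domain = c("KH_1", "YTH"), clan_id = c("CL1", "CL1"),
               stringsAsFactors = FALSE)
  }
  family_catalog(fams, clan_map)
}

make_gene <- function(id, domains, species = "sp1") {
  g <- data.frame(gene_id = id, species_id = species,
                  stringsAsFactors = FALSE)
  g$pfam_domains <- list(domains)
  g
}

six_clades <- function() {
  p <- six_species_panel()
  stats::setNames(p$clade, p$species_id)
}
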