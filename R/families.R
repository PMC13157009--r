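#' Construct a reference RNA-binding-domain family catalog
#'
#' The catalog maps each family to the Pfam domains that define it and to
#' the family's reference gene count, the key used to prioritize among
#' multiple matching families. Domains are matched case-insensitively on
#' both Pfam accession and short name to tolerate annotation-dialect
#' drift. An optional clan map lifts domains one level up the Pfam
#' hierarchy for clan-level robustness counting.
#'
#' @param families data frame with columns `family_id`, `domains`
#'   (';'-separated string or list column of character vectors), and
#'   `reference_gene_count`.
#' @param clan_map optional data frame with columns `domain`, `clan_id`.
#' @return An object of class `family_catalog`.
#' @export
family_catalog <- function(families, clan_map = NULL) {
  stopifnot(all(c("family_id", "domains", "reference_gene_count") %in%
                names(families)))
  if (anyDuplicated(families$family_id)) {
    stop("duplicate family_id in catalog", call. = FALSE)
  }
  doms <- families$domains
  if (!is.list(doms)) doms <- lapply(as.character(doms), .split_field)
  if (any(lengths(doms) == 0)) {
    stop("every family needs >= 1 member domain", call. = FALSE)
  }
  counts <- as.numeric(families$reference_gene_count)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("reference_gene_count must be >= 0", call. = FALSE)
  }

  # flat lookup: lower-cased domain -> family rows it belongs to
  flat <- data.frame(
    domain = tolower(unlist(doms)),
    family_idx = rep(seq_along(doms), lengths(doms)),
    stringsAsFactors = FALSE
  )
  domain_index <- split(flat$family_idx, flat$domain)

  clans <- NULL
  if (!is.null(clan_map)) {
    stopifnot(all(c("domain", "clan_id") %in% names(clan_map)))
    clans <- stats::setNames(as.character(clan_map$clan_id),
                             tolower(as.character(clan_map$domain)))
  }
  structure(
    list(family_id = as.character(families$family_id),
         domains = doms,
         reference_gene_count = counts,
         domain_index = domain_index,
         clan_map = clans),
    class = "family_catalog"
  )
}

#' @export
print.family_catalog <- function(x, ...) {
  cat("<family_catalog> ", length(x$family_id), " families, ",
      length(x$domain_index), " member domains",
      if (!is.null(x$clan_map)) paste0(", clan map (",
                                       length(unique(x$clan_map)),
                                       " clans)") else "", "\n", sep = "")
  invisible(x)
}

#' @rdname family_catalog
#' @param path catalog TSV: `family_id`, `domains` (';'-separated),
#'   `reference_gene_count`.
#' @param clan_path optional clan map TSV: `domain`, `clan_id`.
#' @export
read_family_catalog <- function(path, clan_path = NULL) {
  df <- .read_tsv(path)
  .require_columns(df, c("family_id", "domains", "reference_gene_count"),
                   path)
  clan_map <- NULL
  if (!is.null(clan_path)) {
    clan_map <- .read_tsv(clan_path)
    .require_columns(clan_map, c("domain", "clan_id"), clan_path)
  }
  family_catalog(df, clan_map)
}

# family assignment of one domain set; returns list(family_id, matched)
.assign_one <- function(domains, catalog) {
  hits <- unlist(catalog$domain_index[tolower(domains)], use.names = FALSE)
  if (length(hits) == 0) {
    return(list(family_id = NON_CANONICAL, matched = character(0)))
  }
  cand <- unique(hits)
  counts <- catalog$reference_gene_count[cand]
  best <- cand[counts == max(counts)]
  # ties beyond the reference count are broken lexicographically so the
  # assignment is a pure function of the domain SET, not its order
  fam_ids <- catalog$family_id[best]
  pick <- best[order(fam_ids)[1]]
  fam_domains <- tolower(catalog$domains[[pick]])
  list(family_id = catalog$family_id[pick],
       matched = sort(domains[tolower(domains) %in% fam_domains]))
}

#' Assign genes to RNA-binding-domain families
#'
#' Each gene is matched by intersecting its Pfam domain set with the
#' catalog's family definitions. When domains of one gene match several
#' families, the family with the highest reference gene count wins;
#' remaining ties are broken lexicographically by family id so the result
#' is deterministic and independent of domain order. Genes matching no
#' family are classified [NON_CANONICAL].
#'
#' @param genes gene table from [read_gene_table()] (needs `gene_id`,
#'   `species_id`, `pfam_domains`).
#' @param catalog a [family_catalog].
#' @return Data frame with columns `gene_id`, `species_id`, `family_id`,
#'   `matched_domains` (list column).
#' @export
assign_families <- function(genes, catalog) {
  stopifnot(inherits(catalog, "family_catalog"))
  res <- lapply(genes$pfam_domains, .assign_one, catalog = catalog)
  out <- data.frame(
    gene_id = genes$gene_id,
    species_id = genes$species_id,
    family_id = vapply(res, `[[`, character(1), "family_id"),
    stringsAsFactors = FALSE
  )
  out$matched_domains <- lapply(res, `[[`, "matched")
  out
}

#' @rdname assign_families
#' @param gene single-row gene record (or list with `gene_id`,
#'   `species_id`, `pfam_domains`).
#' @export
assign_family <- function(gene, catalog) {
  genes <- data.frame(gene_id = gene$gene_id,
                      species_id = gene$species_id,
                      stringsAsFactors = FALSE)
  genes$pfam_domains <- list(unlist(gene$pfam_domains))
  assign_families(genes, catalog)
}

#' Family diversity of a repertoire
#'
#' The study's central diversity metric: the number of DISTINCT
#' RNA-binding-domain families represented in one species' assignments.
#' Non-canonical genes do not contribute; paralog counts within a family
#' do not either.
#'
#' @param assignments assignment table from [assign_families()] for one
#'   species.
#' @return Integer count (0 for an empty repertoire).
#' @export
family_diversity <- function(assignments) {
  fams <- assignments$family_id
  length(unique(fams[fams != NON_CANONICAL]))
}

#' Clan-level diversity of a repertoire
#'
#' Rolls matched domains up to Pfam clans and counts distinct clans, the
#' coarser classification granularity used to confirm that the
#' diversity-complexity correlation is not an artifact of family-level
#' resolution. Domains without a clan mapping count as their own
#' singleton pseudo-clans.
#'
#' @param assignments assignment table from [assign_families()].
#' @param catalog the [family_catalog] holding the clan map (may be
#'   absent, in which case every domain is its own pseudo-clan).
#' @return Integer count of distinct clans covered by canonical
#'   assignments.
#' @export
clan_diversity <- function(assignments, catalog) {
  canon <- assignments$family_id != NON_CANONICAL
  doms <- tolower(unique(unlist(assignments$matched_domains[canon])))
  if (length(doms) == 0) return(0L)
  if (is.null(catalog$clan_map)) return(length(doms))
  clans <- catalog$clan_map[doms]
  # unmapped domains fall back to themselves as singleton pseudo-clans
  clans[is.na(clans)] <- doms[is.na(clans)]
  length(unique(clans))
}

#' Overlap between an RBP repertoire and another protein class
#'
#' Reports how many genes of an RBP set are also annotated in a second
#' class (typically transcription factors), as a count and as a
#' percentage of the RBP set, plus the number of shared genes carrying
#' any domain from an exclusion set (used to quantify how much of the
#' overlap is attributable to promiscuous domains such as zf-C2H2).
#'
#' @param rbp_genes,tf_genes character vectors of gene symbols from the
#'   same species namespace.
#' @param exclude_domains optional character vector of domain names.
#' @param gene_domains named list mapping gene id to its domain vector
#'   (required when `exclude_domains` is given).
#' @return List with `overlap`, `percentage` (one decimal),
#'   `excluded_domain_overlap` (NA when no exclusion set given).
#' @export
overlap_report <- function(rbp_genes, tf_genes, exclude_domains = NULL,
                           gene_domains = NULL) {
  rbp_genes <- unique(rbp_genes)
  if (length(rbp_genes) == 0) {
    stop("empty RBP gene set: overlap percentage undefined", call. = FALSE)
  }
  shared <- intersect(rbp_genes, unique(tf_genes))
  excluded <- NA_integer_
  if (!is.null(exclude_domains)) {
    if (is.null(gene_domains)) {
      stop("gene_domains mapping required with exclude_domains",
           call. = FALSE)
    }
    ex <- tolower(exclude_domains)
    excluded <- sum(vapply(shared, function(g) {
      any(tolower(unlist(gene_domains[[g]])) %in% ex)
    }, logical(1)))
  }
  list(overlap = length(shared),
       percentage = round(100 * length(shared) / length(rbp_genes), 1),
       excluded_domain_overlap = excluded)
}

#' Build a family catalog from classified species
#'
#' Generic catalog-merge: pools the domain-to-family evidence of several
#' already-classified species into a new catalog that can classify a
#' held-out species. Each family's domain set is the union of the matched
#' domains observed across the source species and its reference gene
#' count is the number of source genes assigned to it (used as fallback
#' when the original catalog carries no count for a species' dialect).
#'
#' @param assignments assignment table covering the source species
#'   (non-canonical rows are ignored).
#' @param reference_counts optional named vector overriding the pooled
#'   gene counts per family.
#' @return A [family_catalog].
#' @export
catalog_from_assignments <- function(assignments, reference_counts = NULL) {
  canon <- assignments[assignments$family_id != NON_CANONICAL, ,
                       drop = FALSE]
  if (nrow(canon) == 0) stop("no canonical assignments to pool",
                             call. = FALSE)
  fams <- sort(unique(canon$family_id))
  doms <- lapply(fams, function(f) {
    sort(unique(unlist(canon$matched_domains[canon$family_id == f])))
  })
  counts <- as.numeric(table(factor(canon$family_id, levels = fams)))
  if (!is.null(reference_counts)) {
    hit <- fams %in% names(reference_counts)
    counts[hit] <- as.numeric(reference_counts[fams[hit]])
  }
  fam_df <- data.frame(family_id = fams,
                       reference_gene_count = counts,
                       stringsAsFactors = FALSE)
  fam_df$domains <- doms
  family_catalog(fam_df)
}

#' Write a family assignment table as TSV
#' @param assignments table from [assign_families()].
#' @param path output path.
#' @export
write_assignments <- function(assignments, path) {
  out <- assignments
  out$matched_domains <- vapply(out$matched_domains, .join_field,
                                character(1))
  .write_tsv(out, path)
}
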