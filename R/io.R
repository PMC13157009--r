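#' Read a species metadata table
#'
#' The table defines the study panel: one row per organism with its clade
#' label and neuron count, the complexity covariate used throughout the
#' correlation analyses. Neuron counts are stored as doubles because the
#' human count (8.6e10) exceeds the 32-bit integer range; downstream
#' statistics use only ranks or log10 values, so no precision is lost.
#'
#' @param path TSV with columns `species_id`, `display_name`, `clade`
#'   (one of `"invertebrate"`/`"vertebrate"`), `neuron_count`, and
#'   optionally `rbp_family_count`.
#' @return A data frame, one row per species, in file order.
#' @export
read_species_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("species_id", "clade", "neuron_count"), path)
  if (anyDuplicated(df$species_id)) {
    stop("duplicate species_id in '", path, "'", call. = FALSE)
  }
  bad <- setdiff(unique(df$clade), c("invertebrate", "vertebrate"))
  if (length(bad) > 0) {
    stop("unknown clade label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$neuron_count <- as.numeric(df$neuron_count)
  if (any(!is.finite(df$neuron_count)) || any(df$neuron_count < 1)) {
    stop("neuron_count must be finite and >= 1", call. = FALSE)
  }
  df
}

#' The bundled six-species metazoan panel
#'
#' Metadata for the six model organisms spanning 302 (nematode) to 8.6e10
#' (human) neurons, together with the distinct RNA-binding-domain family
#' count of each species' repertoire. This is the reference input for the
#' diversity-complexity correlation.
#'
#' @return Data frame with columns `species_id`, `display_name`, `clade`,
#'   `neuron_count`, `rbp_family_count`.
#' @examples
#' panel <- six_species_panel()
#' spearman_cor(panel$rbp_family_count, panel$neuron_count)
#' @export
six_species_panel <- function() {
  read_species_table(system.file("extdata", "species_metadata.tsv",
                                 package = "rbpdiversity", mustWork = TRUE))
}

#' Read a per-species gene annotation table
#'
#' Parses a TSV of gene records with their protein accessions and Pfam
#' domain annotations. Public annotation exports routinely repeat a gene
#' once per isoform, so duplicate `gene_id` rows are merged: accessions and
#' domain sets are unioned and the maximum protein length is kept.
#'
#' @param path TSV with columns `gene_id`, `accessions` (';'-separated),
#'   `pfam_domains` (';'-separated; empty cell means no annotated domain),
#'   and optionally `protein_length` (amino acids, 0 = unknown).
#' @param species_id label attached to every record.
#' @return Data frame with columns `gene_id`, `species_id`, `accessions`
#'   and `pfam_domains` (list columns of character vectors), and
#'   `protein_length`.
#' @export
read_gene_table <- function(path, species_id) {
  df <- .read_tsv(path)
  .require_columns(df, c("gene_id", "accessions", "pfam_domains"), path)
  if (is.null(df$protein_length)) df$protein_length <- 0L
  df$gene_id <- trimws(as.character(df$gene_id))
  if (any(!nzchar(df$gene_id))) {
    stop("empty gene_id in '", path, "'", call. = FALSE)
  }
  acc <- lapply(as.character(df$accessions), .split_field)
  dom <- lapply(as.character(df$pfam_domains), .split_field)
  len <- as.integer(df$protein_length)

  ids <- unique(df$gene_id)
  idx <- split(seq_len(nrow(df)), factor(df$gene_id, levels = ids))
  genes <- data.frame(gene_id = ids, species_id = species_id,
                      stringsAsFactors = FALSE)
  genes$accessions <- lapply(idx, function(i) unique(unlist(acc[i])))
  genes$pfam_domains <- lapply(idx, function(i) unique(unlist(dom[i])))
  genes$protein_length <- vapply(idx, function(i) max(len[i], 0L),
                                 integer(1))
  rownames(genes) <- NULL
  genes
}

#' Write a gene table in the format accepted by [read_gene_table()]
#' @param genes data frame as returned by [read_gene_table()].
#' @param path output TSV path.
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(
    gene_id = genes$gene_id,
    accessions = vapply(genes$accessions, .join_field, character(1)),
    pfam_domains = vapply(genes$pfam_domains, .join_field, character(1)),
    protein_length = genes$protein_length,
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}

#' Read a per-proteome score table
#'
#' Score tables hold one dimensionless propensity score (for example a
#' phase-separation propensity) per protein or per gene. Isoform-level
#' tables carry a `gene_id` column mapping each isoform to its gene so
#' that [aggregate_isoform_scores()] can collapse them.
#'
#' @param path TSV with columns `id`, `score`, and (for isoform-level
#'   tables) `gene_id`.
#' @param species_id label stored as an attribute.
#' @param level `"gene"` or `"isoform"`.
#' @return Data frame with attributes `species_id` and `level`.
#' @export
read_score_table <- function(path, species_id, level = c("gene", "isoform")) {
  level <- match.arg(level)
  df <- .read_tsv(path)
  .require_columns(df, c("id", "score"), path)
  if (level == "isoform") .require_columns(df, "gene_id", path)
  df$score <- as.numeric(df$score)
  if (any(!is.finite(df$score))) {
    stop("non-finite score in '", path, "'", call. = FALSE)
  }
  if (level == "gene" && anyDuplicated(df$id)) {
    stop("gene-level score table has duplicate ids: '", path, "'",
         call. = FALSE)
  }
  attr(df, "species_id") <- species_id
  attr(df, "level") <- level
  df
}

#' Collapse isoform scores to gene level by maximum
#'
#' Within-gene aggregation takes the maximum score across isoforms, the
#' convention under which a gene is as phase-separation-prone as its most
#' prone isoform.
#'
#' @param scores isoform-level score table from [read_score_table()].
#' @return Gene-level score table (columns `id`, `score`), one row per gene.
#' @export
aggregate_isoform_scores <- function(scores) {
  if (!identical(attr(scores, "level"), "isoform")) {
    stop("scores are not isoform-level", call. = FALSE)
  }
  agg <- stats::aggregate(score ~ gene_id, data = scores, FUN = max)
  out <- data.frame(id = agg$gene_id, score = agg$score,
                    stringsAsFactors = FALSE)
  attr(out, "species_id") <- attr(scores, "species_id")
  attr(out, "level") <- "gene"
  out
}

#' Read a disorder-interval table
#'
#' One row per predicted disordered interval, in 1-based inclusive
#' amino-acid coordinates (position 1 is the first residue; an interval
#' `(5, 7)` covers residues 5, 6 and 7). Intervals for a protein may
#' overlap or touch; [summarize_disorder()] merges them before measuring.
#'
#' @param path TSV with columns `protein_id`, `protein_length`, `start`,
#'   `end`.
#' @return Data frame with the same columns, validated.
#' @export
read_disorder_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("protein_id", "protein_length", "start", "end"),
                   path)
  df$protein_length <- as.integer(df$protein_length)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- df$start < 1 | df$end < df$start | df$end > df$protein_length
  if (any(bad)) {
    stop("invalid disorder interval(s) in '", path, "' (rows ",
         paste(utils::head(which(bad), 5), collapse = ", "),
         "): need 1 <= start <= end <= protein_length", call. = FALSE)
  }
  df
}

#' Read a transcript-region length table
#'
#' BioMart-export-like table of per-transcript region lengths in
#' nucleotides; 0 means the annotation is absent. Every transcript must
#' have at least one positive region length.
#'
#' @param path TSV with columns `gene_id`, `transcript_id`, `utr5_len`,
#'   `cds_len`, `utr3_len`.
#' @return Validated data frame.
#' @export
read_transcript_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("gene_id", "transcript_id", "utr5_len",
                         "cds_len", "utr3_len"), path)
  for (col in c("utr5_len", "cds_len", "utr3_len")) {
    df[[col]] <- as.integer(df[[col]])
    if (any(df[[col]] < 0)) stop("negative ", col, " in '", path, "'",
                                 call. = FALSE)
  }
  if (any(df$utr5_len + df$cds_len + df$utr3_len == 0)) {
    stop("transcript with all region lengths 0 in '", path, "'",
         call. = FALSE)
  }
  df
}

#' Read an orthogroup membership table
#'
#' Consumes the Orthogroups.tsv dialect produced by orthology inference
#' tools: first column the orthogroup id, one column per species, each
#' cell a comma-separated gene list (whitespace around ids is stripped,
#' empty cell = species absent from the group).
#'
#' @param path TSV in the dialect above.
#' @param species optional character vector of expected species ids; any
#'   header species outside this set triggers a warning but the column is
#'   retained under its raw name.
#' @return Long-format data frame with columns `og_id`, `species_id`,
#'   `gene_id`, one row per member gene. Orthogroups appear in file order
#'   (factor-free; use `unique(out$og_id)` for the order).
#' @export
read_orthogroups <- function(path, species = NULL) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) {
    stop("orthogroup table '", path, "' needs an id column plus >= 1 ",
         "species column", call. = FALSE)
  }
  og_col <- names(df)[1]
  sp_cols <- names(df)[-1]
  if (!is.null(species)) {
    unknown <- setdiff(sp_cols, species)
    if (length(unknown) > 0) {
      warning("orthogroup table has species column(s) not in the study ",
              "registry: ", paste(unknown, collapse = ", "),
              " (retained under raw names)", call. = FALSE)
    }
  }
  rows <- lapply(sp_cols, function(sp) {
    genes <- lapply(as.character(df[[sp]]), .split_field, sep = ",")
    n <- lengths(genes)
    data.frame(og_id = rep(as.character(df[[og_col]]), n),
               species_id = rep(sp, sum(n)),
               gene_id = unlist(genes, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  empty <- setdiff(as.character(df[[og_col]]), out$og_id)
  if (length(empty) > 0) {
    stop("orthogroup(s) with no member in any species: ",
         paste(utils::head(empty, 5), collapse = ", "), call. = FALSE)
  }
  # preserve file order of orthogroups
  out <- out[order(match(out$og_id, as.character(df[[og_col]]))), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "og_order") <- as.character(df[[og_col]])
  out
}

#' Write orthogroups in the Orthogroups.tsv dialect
#' @param og long-format orthogroup data frame (`og_id`, `species_id`,
#'   `gene_id`).
#' @param path output path.
#' @param species column order; defaults to order of appearance.
#' @export
write_orthogroups <- function(og, path, species = NULL) {
  if (is.null(species)) species <- unique(og$species_id)
  og_ids <- if (!is.null(attr(og, "og_order"))) attr(og, "og_order")
            else unique(og$og_id)
  wide <- data.frame(Orthogroup = og_ids, stringsAsFactors = FALSE)
  for (sp in species) {
    sub <- og[og$species_id == sp, , drop = FALSE]
    cells <- vapply(og_ids, function(id) {
      paste(sub$gene_id[sub$og_id == id], collapse = ", ")
    }, character(1))
    wide[[sp]] <- unname(cells)
  }
  .write_tsv(wide, path)
}
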