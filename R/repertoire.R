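#' Vertebrate/invertebrate expansion ratio of a domain family
#'
#' Computes the mean gene count of a domain family per clade and their
#' ratio, the metric used to rank domain families by vertebrate
#' enrichment. When the invertebrate mean is exactly zero (a domain
#' absent from all invertebrates) a pseudo-count replaces the divisor so
#' vertebrate-specific emergences still receive a finite, comparable
#' ratio; the pseudo-count is never applied to the numerator.
#'
#' @param domain_id label carried through to the record.
#' @param counts named numeric vector of per-species gene counts.
#' @param clades named character vector mapping each species in `counts`
#'   to `"invertebrate"` or `"vertebrate"`.
#' @param pseudocount divisor substitute when the invertebrate mean is 0
#'   (default 0.5).
#' @return Object of class `expansion_record`: `domain_id`,
#'   `per_species_counts`, `invert_mean`, `vert_mean`, `ratio` (full
#'   precision; report to one decimal), `pseudocount_applied`.
#' @examples
#' expansion_ratio("RNaseA",
#'                 c(celegans = 0, dmelanogaster = 0, drerio = 3,
#'                   xtropicalis = 1, mmusculus = 20, hsapiens = 15),
#'                 c(celegans = "invertebrate",
#'                   dmelanogaster = "invertebrate", drerio = "vertebrate",
#'                   xtropicalis = "vertebrate", mmusculus = "vertebrate",
#'                   hsapiens = "vertebrate"))  # ratio 19.5
#' @export
expansion_ratio <- function(domain_id, counts, clades, pseudocount = 0.5) {
  if (any(counts < 0)) stop("gene counts must be >= 0", call. = FALSE)
  miss <- setdiff(names(counts), names(clades))
  if (length(miss) > 0) {
    stop("species without clade label: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cl <- clades[names(counts)]
  inv <- counts[cl == "invertebrate"]
  ver <- counts[cl == "vertebrate"]
  if (length(ver) == 0) stop("vertebrate clade empty", call. = FALSE)
  if (length(inv) == 0) stop("invertebrate clade empty", call. = FALSE)
  invert_mean <- mean(inv)
  vert_mean <- mean(ver)
  pseudo <- invert_mean == 0
  ratio <- vert_mean / if (pseudo) pseudocount else invert_mean
  structure(list(domain_id = domain_id, per_species_counts = counts,
                 invert_mean = invert_mean, vert_mean = vert_mean,
                 ratio = ratio, pseudocount_applied = pseudo),
            class = "expansion_record")
}

#' @export
print.expansion_record <- function(x, ...) {
  cat(sprintf("%s: vertebrate mean %.2f / invertebrate mean %.2f%s -> %.1fx\n",
              x$domain_id, x$vert_mean, x$invert_mean,
              if (x$pseudocount_applied) " (pseudo-count)" else "",
              x$ratio))
  invisible(x)
}

#' Within-proteome percentile ranks
#'
#' Converts raw propensity scores to percentiles within one proteome so
#' that species scored by a predictor trained on a single reference
#' proteome become comparable. The percentile of a score is
#' `100 * (number of proteome scores <= it) / proteome size`; the
#' inclusive convention means ties share the same percentile and every
#' maximum scores 100.
#'
#' @param scores gene-level score table (columns `id`, `score`) or a
#'   named numeric vector.
#' @return Named numeric vector of percentiles in (0, 100].
#' @export
percentile_ranks <- function(scores) {
  if (is.data.frame(scores)) {
    v <- stats::setNames(scores$score, scores$id)
  } else {
    v <- scores
  }
  if (length(v) == 0) stop("empty proteome", call. = FALSE)
  100 * rank(v, ties.method = "max") / length(v)
}

#' Fraction of a gene subset above a percentile threshold
#'
#' The top-decile membership metric: which share of (say) the RBP
#' repertoire sits in the top 10% of its own proteome's score
#' distribution. Because the percentile convention is inclusive, tie
#' mass at the threshold inflates rather than deflates the fraction.
#'
#' @param subset_ids ids of the subset of interest; must all be ranked.
#' @param ranks percentile vector from [percentile_ranks()].
#' @param threshold_pct percentile cutoff (default 90, i.e. top 10%).
#' @return Proportion in \[0, 1\] (multiply by 100 and round to one
#'   decimal for report output).
#' @export
high_fraction <- function(subset_ids, ranks, threshold_pct = 90) {
  if (length(subset_ids) == 0) stop("empty subset", call. = FALSE)
  miss <- setdiff(subset_ids, names(ranks))
  if (length(miss) > 0) {
    stop("subset ids missing from ranks: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  mean(ranks[subset_ids] >= threshold_pct)
}

# merge 1-based inclusive intervals; adjacent (end + 1 == start) merge too
.merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- c()
  out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Summarize the disorder annotation of one protein
#'
#' Merges overlapping and adjacent disordered intervals, then reports the
#' disorder content (% of residues), the length of the longest contiguous
#' intrinsically disordered region, the total number of disordered
#' residues, and whether the protein is high-IDR (content strictly above
#' 30%).
#'
#' @param protein_id label.
#' @param protein_length protein length in amino acids.
#' @param start,end interval bounds, 1-based inclusive.
#' @return Object of class `disorder_summary` (also a one-row list):
#'   `protein_id`, `protein_length`, `idr_content_pct`, `longest_idr`,
#'   `total_disordered`, `high_idr`.
#' @export
summarize_disorder <- function(protein_id, protein_length, start, end) {
  if (length(start) != length(end)) stop("start/end length mismatch",
                                         call. = FALSE)
  if (length(start) == 0) {
    return(structure(list(protein_id = protein_id,
                          protein_length = protein_length,
                          idr_content_pct = 0, longest_idr = 0L,
                          total_disordered = 0L, high_idr = FALSE),
                     class = "disorder_summary"))
  }
  if (any(start < 1) || any(end < start) || any(end > protein_length)) {
    stop("interval outside [1, protein_length] for ", protein_id,
         call. = FALSE)
  }
  m <- .merge_intervals(as.integer(start), as.integer(end))
  lens <- m[, "end"] - m[, "start"] + 1L
  total <- sum(lens)
  content <- 100 * total / protein_length
  structure(list(protein_id = protein_id,
                 protein_length = as.integer(protein_length),
                 idr_content_pct = content,
                 longest_idr = max(lens),
                 total_disordered = total,
                 high_idr = content > 30),
            class = "disorder_summary")
}

#' Summarize a whole disorder-interval table
#'
#' @param tracks data frame from [read_disorder_table()]. Proteins with
#'   zero intervals are absent from such tables; include them by listing
#'   them in `all_proteins` (a data frame `protein_id`, `protein_length`)
#'   to count them as fully ordered.
#' @param all_proteins optional roster of proteins (with lengths) that
#'   should appear even without intervals.
#' @return Data frame, one row per protein, with the
#'   [summarize_disorder()] fields.
#' @export
disorder_summaries <- function(tracks, all_proteins = NULL) {
  ids <- unique(tracks$protein_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$protein_id == id, , drop = FALSE]
    s <- summarize_disorder(id, tr$protein_length[1], tr$start, tr$end)
    as.data.frame(unclass(s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(all_proteins)) {
    extra <- all_proteins[!all_proteins$protein_id %in% ids, ,
                          drop = FALSE]
    if (nrow(extra) > 0) {
      zero <- do.call(rbind, lapply(seq_len(nrow(extra)), function(i) {
        s <- summarize_disorder(extra$protein_id[i],
                                extra$protein_length[i],
                                integer(0), integer(0))
        as.data.frame(unclass(s), stringsAsFactors = FALSE)
      }))
      out <- rbind(out, zero)
    }
  }
  rownames(out) <- NULL
  out
}

#' Species-level means of per-protein disorder summaries
#'
#' Arithmetic means across proteins (each protein weighted equally);
#' these species-level vectors are what feed the rank-correlation
#' against the complexity covariate.
#'
#' @param summaries data frame from [disorder_summaries()].
#' @return List: `mean_content_pct`, `mean_longest_idr`,
#'   `mean_total_disordered`, `high_idr_fraction`, `n_proteins`.
#' @export
species_disorder_means <- function(summaries) {
  if (nrow(summaries) == 0) stop("no disorder summaries", call. = FALSE)
  list(mean_content_pct = mean(summaries$idr_content_pct),
       mean_longest_idr = mean(summaries$longest_idr),
       mean_total_disordered = mean(summaries$total_disordered),
       high_idr_fraction = mean(summaries$high_idr),
       n_proteins = nrow(summaries))
}

#' Pick the representative transcript of a gene
#'
#' The transcript with the longest 3'UTR represents its gene, the
#' convention that favors the isoform with the richest post-
#' transcriptional regulatory tail. Ties cascade to the longest total
#' mRNA, then to the lexicographically smallest transcript id.
#'
#' @param records data frame of transcripts of ONE gene (columns
#'   `transcript_id`, `utr5_len`, `cds_len`, `utr3_len`).
#' @return The selected row.
#' @export
select_representative_transcript <- function(records) {
  if (nrow(records) == 0) stop("no transcripts", call. = FALSE)
  total <- records$utr5_len + records$cds_len + records$utr3_len
  o <- order(-records$utr3_len, -total, records$transcript_id)
  records[o[1], , drop = FALSE]
}

#' Representative transcripts for every gene in a table
#' @param transcripts data frame from [read_transcript_table()].
#' @return One row per gene.
#' @export
representative_transcripts <- function(transcripts) {
  parts <- split(transcripts, transcripts$gene_id)
  out <- do.call(rbind, lapply(parts, select_representative_transcript))
  rownames(out) <- NULL
  out
}

#' Median transcript-region lengths of a species
#'
#' Medians over per-gene representative transcripts; standard median
#' (even n: mean of the two middle values). A zero region length encodes
#' an absent annotation and is excluded from that region's median while
#' the gene still contributes to the other regions.
#'
#' @param reps per-gene representative transcripts
#'   (from [representative_transcripts()]).
#' @param species_id label.
#' @return Object of class `region_lengths`: `species_id`,
#'   `median_utr5`, `median_cds`, `median_utr3`, `n_genes`. 5'UTR/CDS
#'   medians are NA when no gene has that annotation; a fully absent
#'   3'UTR annotation is an error because the 3'UTR median is the
#'   analysis's primary quantity.
#' @export
region_medians <- function(reps, species_id) {
  if (nrow(reps) == 0) stop("no genes", call. = FALSE)
  med <- function(v) if (any(v > 0)) stats::median(v[v > 0]) else NA_real_
  m3 <- med(reps$utr3_len)
  if (is.na(m3)) {
    stop("all 3'UTR annotations absent: median_utr3 undefined",
         call. = FALSE)
  }
  structure(list(species_id = species_id,
                 median_utr5 = med(reps$utr5_len),
                 median_cds = med(reps$cds_len),
                 median_utr3 = m3,
                 n_genes = nrow(reps)),
            class = "region_lengths")
}

#' Fold change between two values
#' @param a,b numerator and denominator; `b > 0`.
#' @param digits rounding (default 1, the report convention); `NULL`
#'   for full precision.
#' @return `a / b`, rounded.
#' @examples
#' fold_change(1444, 163)  # 8.9
#' @export
fold_change <- function(a, b, digits = 1) {
  if (b <= 0) stop("denominator must be > 0", call. = FALSE)
  fc <- a / b
  if (is.null(digits)) fc else round(fc, digits)
}

#' Classify orthogroups by conservation level and copy number
#'
#' Conservation is determined solely by the number of species
#' represented: species-specific (1), moderate (2-3), conserved (4-5),
#' universal (all study species). The copy class is set by the maximum
#' per-species copy number among represented species: single-copy
#' (strict 1:1 in every represented species), small expansion (max 2),
#' medium (3-5), large (> 5).
#'
#' @param og long-format orthogroup table from [read_orthogroups()]
#'   (columns `og_id`, `species_id`, `gene_id`).
#' @param n_study_species total species in the study (default 6);
#'   defines the universal category.
#' @return Data frame: `og_id`, `n_species_present`, `max_copies`,
#'   `conservation`, `copy_class`.
#' @export
classify_orthogroups <- function(og, n_study_species = 6) {
  counts <- table(og$og_id, og$species_id)
  og_ids <- if (!is.null(attr(og, "og_order"))) attr(og, "og_order")
            else unique(og$og_id)
  counts <- counts[og_ids, , drop = FALSE]
  n_present <- rowSums(counts > 0)
  max_copies <- apply(counts, 1, max)
  conservation <- cut(n_present,
                      breaks = c(0, 1, 3, n_study_species - 1,
                                 n_study_species),
                      labels = c("species_specific", "moderate",
                                 "conserved", "universal"))
  copy_class <- cut(max_copies, breaks = c(0, 1, 2, 5, Inf),
                    labels = c("single_copy", "small", "medium", "large"))
  data.frame(og_id = og_ids,
             n_species_present = as.integer(n_present),
             max_copies = as.integer(max_copies),
             conservation = as.character(conservation),
             copy_class = as.character(copy_class),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Category counts and percentages over classified orthogroups
#'
#' @param classes data frame from [classify_orthogroups()].
#' @return List of two data frames (`conservation`, `copy_class`), each
#'   with `category`, `n`, `pct` (one decimal, of the orthogroup total).
#' @export
summarize_orthogroups <- function(classes) {
  total <- nrow(classes)
  tab <- function(col, levels) {
    n <- as.integer(table(factor(classes[[col]], levels = levels)))
    data.frame(category = levels, n = n,
               pct = round(100 * n / total, 1),
               stringsAsFactors = FALSE)
  }
  list(conservation = tab("conservation",
                          c("species_specific", "moderate", "conserved",
                            "universal")),
       copy_class = tab("copy_class",
                        c("single_copy", "small", "medium", "large")),
       total = total)
}

#' Fraction of genes with established RNA-binding evidence
#'
#' @param labels named character vector, one label per gene, each
#'   `"established"` or `"limited"`.
#' @return Proportion established (round `100 * x` to 0 decimals for
#'   report output).
#' @export
evidence_fraction <- function(labels) {
  if (length(labels) == 0) stop("no labeled genes", call. = FALSE)
  bad <- setdiff(unique(labels), c("established", "limited"))
  if (length(bad) > 0 || anyNA(labels)) {
    stop("unlabeled or unknown evidence label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mean(labels == "established")
}
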