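#' Write a complete six-species input bundle
#'
#' Materializes, into one directory, every input table the full analysis
#' consumes, built from the bundled study metadata plus the synthetic
#' generators: species metadata with neuron counts, per-species gene
#' tables and a family catalog realizing the printed diversity vector
#' (397, 419, 455, 446, 472, 469), the control-class correlations, the
#' RNase A expansion counts, a 527-orthogroup table with the study's
#' class mixture, and score/disorder/transcript tables per species.
#' All stochastic pieces derive from one root seed via fixed per-stage
#' offsets, so regenerating the bundle is byte-identical.
#'
#' @param dir output directory (created if absent).
#' @param seed root integer seed.
#' @return Invisibly, a named list of the file paths written (a valid
#'   `config` for [run_report()]).
#' @export
write_six_species_bundle <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "genes"), showWarnings = FALSE)
  dir.create(file.path(dir, "scores"), showWarnings = FALSE)
  dir.create(file.path(dir, "disorder"), showWarnings = FALSE)
  dir.create(file.path(dir, "transcripts"), showWarnings = FALSE)
  seed <- as.integer(seed)

  panel <- six_species_panel()
  species_path <- file.path(dir, "species_metadata.tsv")
  .write_tsv(panel, species_path)

  file.copy(system.file("extdata", "control_correlations.tsv",
                        package = "rbpdiversity", mustWork = TRUE),
            file.path(dir, "control_correlations.tsv"), overwrite = TRUE)
  file.copy(system.file("extdata", "expansion_domain_counts.tsv",
                        package = "rbpdiversity", mustWork = TRUE),
            file.path(dir, "expansion_domain_counts.tsv"),
            overwrite = TRUE)

  sim <- sim_species_panel(diversity = panel$rbp_family_count,
                           seed = seed + 101L)
  gene_paths <- character(0)
  for (sp in names(sim$genes)) {
    p <- file.path(dir, "genes", paste0(sp, ".tsv"))
    write_gene_table(sim$genes[[sp]], p)
    gene_paths[sp] <- p
  }
  catalog_path <- file.path(dir, "family_catalog.tsv")
  cat_df <- data.frame(
    family_id = sim$catalog$family_id,
    domains = vapply(sim$catalog$domains, .join_field, character(1)),
    reference_gene_count = sim$catalog$reference_gene_count,
    stringsAsFactors = FALSE)
  .write_tsv(cat_df, catalog_path)

  og <- sim_orthogroups(seed = seed + 202L)
  og_path <- file.path(dir, "orthogroups.tsv")
  write_orthogroups(og$orthogroups, og_path,
                    species = panel$species_id)

  # per-species proteome scores; the RBP subset is the species' gene list
  score_paths <- character(0)
  subset_paths <- character(0)
  for (i in seq_len(nrow(panel))) {
    sp <- panel$species_id[i]
    scores <- sim_score_table(2000, seed = seed + 300L + i,
                              prefix = paste0(sp, "_p"))
    rbp_ids <- scores$id[seq_len(400)]
    p <- file.path(dir, "scores", paste0(sp, ".tsv"))
    .write_tsv(scores, p)
    ps <- file.path(dir, "scores", paste0(sp, "_rbp_ids.txt"))
    writeLines(rbp_ids, ps)
    score_paths[sp] <- p
    subset_paths[sp] <- ps
  }

  # disorder content ramps over the study's 15.3-20.0% band
  disorder_paths <- character(0)
  contents <- seq(15.3, 20.0, length.out = nrow(panel))
  for (i in seq_len(nrow(panel))) {
    sp <- panel$species_id[i]
    tr <- sim_disorder_tracks(400, target_content_pct = contents[i],
                              seed = seed + 400L + i,
                              prefix = paste0(sp, "_p"))
    p <- file.path(dir, "disorder", paste0(sp, ".tsv"))
    .write_tsv(tr, p)
    disorder_paths[sp] <- p
  }

  # 3'UTR medians anchored at the printed endpoints (worm 163 nt, human
  # 1444 nt); intermediate species interpolate on a log scale
  transcript_paths <- character(0)
  utr3 <- round(exp(seq(log(163), log(1444), length.out = nrow(panel))))
  for (i in seq_len(nrow(panel))) {
    sp <- panel$species_id[i]
    tt <- sim_transcript_table(300, utr3_median = utr3[i],
                               seed = seed + 500L + i,
                               prefix = paste0(sp, "_g"))
    p <- file.path(dir, "transcripts", paste0(sp, ".tsv"))
    .write_tsv(tt, p)
    transcript_paths[sp] <- p
  }

  config <- list(species = species_path,
                 genes = as.list(gene_paths),
                 catalog = catalog_path,
                 control_correlations = file.path(dir,
                                                  "control_correlations.tsv"),
                 expansion_counts = file.path(dir,
                                              "expansion_domain_counts.tsv"),
                 orthogroups = og_path,
                 scores = as.list(score_paths),
                 score_subsets = as.list(subset_paths),
                 disorder = as.list(disorder_paths),
                 transcripts = as.list(transcript_paths),
                 seed = seed)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(config)
}

.report_row <- function(stage, metric, value) {
  data.frame(stage = stage, metric = metric, value = value,
             stringsAsFactors = FALSE)
}

#' Run the full repertoire analysis and emit a report
#'
#' Orchestrates every analysis stage over an input bundle: family
#' classification and diversity counting, the diversity-complexity
#' correlation with bootstrap and leave-one-out robustness, Fisher-z
#' effect sizes against control protein classes, clade expansion ratios,
#' orthogroup conservation classes, within-proteome percentile
#' normalization, disorder summaries and transcript-region medians.
#' Only stages whose inputs are present in the config (and listed in
#' `stages`) run; the result is deterministic given the config and seed.
#'
#' @param config named list of input paths as produced by
#'   [write_six_species_bundle()], or the path to a YAML file with the
#'   same structure. Must contain `seed` when a stochastic stage
#'   (bootstrap) is enabled.
#' @param stages character vector of stages to run; default all
#'   available. Known stages: `"diversity"`, `"bootstrap"`, `"loo"`,
#'   `"effect_size"`, `"expansion"`, `"orthogroups"`, `"llps"`, `"idr"`,
#'   `"utr"`.
#' @param outdir optional directory; when given, each stage writes its
#'   TSV there plus a combined `summary.tsv`.
#' @param B bootstrap iterations (default 10000).
#' @return List with one element per executed stage plus `summary`
#'   (long-format data frame of stage/metric/value rows).
#' @export
run_report <- function(config, stages = NULL, outdir = NULL, B = 10000) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  all_stages <- c("diversity", "bootstrap", "loo", "effect_size",
                  "expansion", "orthogroups", "llps", "idr", "utr")
  if (is.null(stages)) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown) > 0) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  has <- function(key) !is.null(config[[key]])
  emit <- function(df, name) {
    if (!is.null(outdir)) .write_tsv(df, file.path(outdir,
                                                   paste0(name, ".tsv")))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  out <- list()
  summary <- list()
  species <- if (has("species")) read_species_table(config$species)

  diversity <- NULL
  if ("diversity" %in% stages && has("genes") && has("catalog")) {
    run_stage("diversity", {
      catalog <- read_family_catalog(config$catalog)
      div <- vapply(names(config$genes), function(sp) {
        genes <- read_gene_table(config$genes[[sp]], sp)
        family_diversity(assign_families(genes, catalog))
      }, integer(1))
      div <- div[species$species_id]
      diversity <- div
      cor_res <- spearman_cor(div, species$neuron_count)
      df <- data.frame(species_id = names(div), family_diversity = div,
                       neuron_count = species$neuron_count,
                       row.names = NULL)
      out$diversity <- list(table = df, correlation = cor_res)
      emit(df, "diversity")
      summary <- c(summary, list(
        .report_row("diversity", "spearman_rho", round(cor_res$rho, 3)),
        .report_row("diversity", "p_value", signif(cor_res$p_value, 3))))
    })
  }

  # the correlation stages fall back to the family counts stored in the
  # species metadata when gene tables are not part of the bundle
  div_vec <- function() {
    if (!is.null(diversity)) return(diversity)
    if (!is.null(species$rbp_family_count)) {
      return(stats::setNames(species$rbp_family_count,
                             species$species_id))
    }
    stop("no diversity source: need gene tables or rbp_family_count")
  }

  if ("bootstrap" %in% stages && !is.null(species)) {
    run_stage("bootstrap", {
      if (is.null(config$seed)) stop("seed required for bootstrap")
      bt <- bootstrap_correlation(div_vec(), species$neuron_count, B = B,
                                  seed = config$seed)
      out$bootstrap <- bt
      summary <- c(summary, list(
        .report_row("bootstrap", "median_rho", round(bt$median_rho, 3)),
        .report_row("bootstrap", "ci_low", round(bt$ci_low, 3)),
        .report_row("bootstrap", "ci_high", round(bt$ci_high, 3)),
        .report_row("bootstrap", "pct_negative",
                    round(100 * bt$frac_negative, 1))))
    })
  }

  if ("loo" %in% stages && !is.null(species)) {
    run_stage("loo", {
      loo <- leave_one_out_rho(div_vec(), species$neuron_count,
                               ids = species$species_id)
      out$loo <- loo
      df <- data.frame(excluded = names(loo), rho = round(loo, 3),
                       row.names = NULL)
      emit(df, "leave_one_out")
      summary <- c(summary, list(
        .report_row("loo", "min_rho", round(min(loo, na.rm = TRUE), 3)),
        .report_row("loo", "max_rho", round(max(loo, na.rm = TRUE), 3))))
    })
  }

  if ("effect_size" %in% stages && has("control_correlations") &&
      !is.null(species)) {
    run_stage("effect_size", {
      ctrl <- .read_tsv(config$control_correlations)
      rbp_rho <- round(spearman_cor(div_vec(),
                                    species$neuron_count)$rho, 3)
      others <- ctrl[ctrl$protein_class != "RBP", , drop = FALSE]
      rows <- lapply(seq_len(nrow(others)), function(i) {
        es <- cohens_d_fisher(rbp_rho, others$rho[i],
                              nrow(species))
        .report_row("effect_size",
                    paste0("d_RBP_vs_", others$protein_class[i]),
                    round(es$d, 3))
      })
      out$effect_size <- do.call(rbind, rows)
      emit(out$effect_size, "effect_size")
      summary <- c(summary, rows)
    })
  }

  if ("expansion" %in% stages && has("expansion_counts") &&
      !is.null(species)) {
    run_stage("expansion", {
      cnt <- .read_tsv(config$expansion_counts)
      clades <- stats::setNames(species$clade, species$species_id)
      rows <- lapply(seq_len(nrow(cnt)), function(i) {
        counts <- unlist(cnt[i, species$species_id])
        er <- expansion_ratio(cnt$domain_id[i], counts, clades)
        data.frame(domain_id = er$domain_id,
                   invert_mean = er$invert_mean,
                   vert_mean = er$vert_mean,
                   ratio = round(er$ratio, 1),
                   pseudocount_applied = er$pseudocount_applied,
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      out$expansion <- df
      emit(df, "expansion")
      summary <- c(summary, lapply(seq_len(nrow(df)), function(i) {
        .report_row("expansion", paste0("ratio_", df$domain_id[i]),
                    df$ratio[i])
      }))
    })
  }

  if ("orthogroups" %in% stages && has("orthogroups")) {
    run_stage("orthogroups", {
      og <- read_orthogroups(config$orthogroups,
                             species = species$species_id)
      cls <- classify_orthogroups(og,
                                  n_study_species = nrow(species))
      sm <- summarize_orthogroups(cls)
      out$orthogroups <- list(classes = cls, summary = sm)
      emit(cls, "orthogroup_classes")
      single <- sm$copy_class[sm$copy_class$category == "single_copy", ]
      summary <- c(summary, list(
        .report_row("orthogroups", "n_total", sm$total),
        .report_row("orthogroups", "n_single_copy", single$n),
        .report_row("orthogroups", "pct_single_copy", single$pct)))
    })
  }

  if ("llps" %in% stages && has("scores") && !is.null(species)) {
    run_stage("llps", {
      fracs <- vapply(species$species_id, function(sp) {
        scores <- read_score_table(config$scores[[sp]], sp)
        ranks <- percentile_ranks(scores)
        subset <- if (has("score_subsets"))
          readLines(config$score_subsets[[sp]]) else scores$id
        high_fraction(subset, ranks, threshold_pct = 90)
      }, numeric(1))
      df <- data.frame(species_id = species$species_id,
                       top10_pct = round(100 * fracs, 1),
                       row.names = NULL)
      out$llps <- df
      emit(df, "llps")
      cr <- spearman_cor(fracs, species$neuron_count)
      summary <- c(summary, list(
        .report_row("llps", "top10_rho", round(cr$rho, 3))))
    })
  }

  if ("idr" %in% stages && has("disorder") && !is.null(species)) {
    run_stage("idr", {
      means <- lapply(species$species_id, function(sp) {
        tracks <- read_disorder_table(config$disorder[[sp]])
        species_disorder_means(disorder_summaries(tracks))
      })
      df <- data.frame(
        species_id = species$species_id,
        mean_content_pct = vapply(means, `[[`, 1, "mean_content_pct"),
        mean_longest_idr = vapply(means, `[[`, 1, "mean_longest_idr"),
        mean_total_disordered = vapply(means, `[[`, 1,
                                       "mean_total_disordered"),
        high_idr_fraction = vapply(means, `[[`, 1, "high_idr_fraction"),
        row.names = NULL)
      out$idr <- df
      emit(df, "idr")
      cr <- spearman_cor(df$mean_content_pct, species$neuron_count)
      summary <- c(summary, list(
        .report_row("idr", "content_rho", round(cr$rho, 3))))
    })
  }

  if ("utr" %in% stages && has("transcripts") && !is.null(species)) {
    run_stage("utr", {
      med <- lapply(species$species_id, function(sp) {
        tt <- read_transcript_table(config$transcripts[[sp]])
        region_medians(representative_transcripts(tt), sp)
      })
      df <- data.frame(
        species_id = species$species_id,
        median_utr5 = vapply(med, `[[`, 1, "median_utr5"),
        median_cds = vapply(med, `[[`, 1, "median_cds"),
        median_utr3 = vapply(med, `[[`, 1, "median_utr3"),
        row.names = NULL)
      out$utr <- df
      emit(df, "utr")
      fc <- fold_change(df$median_utr3[nrow(df)], df$median_utr3[1])
      cr <- spearman_cor(df$median_utr3, species$neuron_count)
      summary <- c(summary, list(
        .report_row("utr", "utr3_fold_first_to_last", fc),
        .report_row("utr", "utr3_rho", round(cr$rho, 3))))
    })
  }

  summary_df <- if (length(summary) > 0) {
    do.call(rbind, summary)
  } else {
    data.frame(stage = character(0), metric = character(0),
               value = numeric(0))
  }
  if (!is.null(outdir)) .write_tsv(summary_df, file.path(outdir,
                                                         "summary.tsv"))
  out$summary <- summary_df
  out
}
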