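# rbpdiversity

Comparative analysis of RNA-binding protein (RBP) family repertoires
across species, and of how repertoire diversity tracks neural
complexity.

## The problem

RBPs control mRNA processing, localization, stability and translation,
and neurons lean on them unusually hard. A natural comparative question
is whether the *diversity* of RBP families — the number of distinct
RNA-binding Pfam domain families a species' proteome realizes, not the
paralog count — scales with the complexity of its nervous system.
`rbpdiversity` implements the full analysis chain for a six-species
metazoan panel (*C. elegans*, *D. melanogaster*, *D. rerio*,
*X. tropicalis*, *M. musculus*, *H. sapiens*) whose neuron counts span
302 to 8.6 × 10¹⁰:

* **Family classification** — match each gene's Pfam domains against a
  reference catalog of RNA-binding-domain families; multi-family hits
  resolve to the family with the highest reference gene count (ties:
  lexicographic); unmatched genes are non-canonical. Clan-level rollup
  and catalog merging for held-out species included.
* **Association statistics** — Spearman's ρ (average ranks) with the
  two-sided t-approximation p = 2·P(T₍ₙ₋₂₎ ≤ −|ρ√((n−2)/(1−ρ²))|), an
  exact-permutation alternative for n ≤ 8, bootstrap resampling with
  degenerate-resample redraw, leave-one-out validation, and Cohen's
  d = |atanh(ρ₁) − atanh(ρ₂)|/√(2/(n−3)) on the Fisher-z scale.
* **Phylogenetic control** — PGLS with Pagel's λ scaling of the
  Brownian-motion covariance (off-diagonal × λ), maximum-likelihood λ
  on a grid with golden-section refinement.
* **Repertoire summaries** — vertebrate/invertebrate expansion ratios
  (clade means, pseudo-count 0.5 when the invertebrate mean is 0),
  within-proteome percentile ranks and top-decile fractions,
  disordered-region summaries (merged intervals; content %, longest
  IDR, total disordered), longest-3′UTR transcript selection and
  region medians, orthogroup conservation/copy-number classification.
* **Synthetic data** — generators for every input table with exact
  ground truth (rank permutations constructed combinatorially, class
  mixtures allocated deterministically), so the whole pipeline is
  testable offline.

## Worked example

```r
library(rbpdiversity)

panel <- six_species_panel()
spearman_cor(panel$rbp_family_count, panel$neuron_count)
#> Spearman rho = 0.886, p = 0.0188 (n = 6, t_approx)

bootstrap_correlation(panel$rbp_family_count, panel$neuron_count, seed = 42)
#> Bootstrap (B = 10000, seed = 42): median rho = 0.882, 95% CI [0.200, 1.000],
#> 0.2% negative, 0 degenerate redraws

round(leave_one_out_rho(panel$rbp_family_count, panel$neuron_count,
                        panel$species_id), 3)
#>      celegans dmelanogaster        drerio   xtropicalis     mmusculus
#>           0.8           0.8           0.9           0.9           0.9
#>      hsapiens
#>           0.9

cohens_d_fisher(0.886, 0.429, 6)   # RBP correlation vs the kinase control
#> Cohen's d = 1.157 (rho 0.886 vs 0.429, n = 6, se = 0.816)

clades <- setNames(panel$clade, panel$species_id)
expansion_ratio("RNaseA",
                c(celegans = 0, dmelanogaster = 0, drerio = 3,
                  xtropicalis = 1, mmusculus = 20, hsapiens = 15), clades)
#> RNaseA: vertebrate mean 9.75 / invertebrate mean 0.00 (pseudo-count) -> 19.5x

og <- sim_orthogroups(seed = 7)   # 527 groups, study-composition mixture
summarize_orthogroups(classify_orthogroups(og$orthogroups))$copy_class
#>      category   n  pct
#> 1 single_copy 380 72.1
#> 2       small  96 18.2
#> 3      medium  43  8.2
#> 4       large   8  1.5
```

Reading the output: family diversity and neuron count are strongly rank
correlated (ρ = 0.886, p < 0.05 under the t-approximation), and the
association is stable under resampling (median bootstrap ρ 0.882, 0.2%
of resamples negative) and under excluding any single species
(ρ ∈ [0.80, 0.90]). The effect size against the kinase control is large
(d = 1.157). The RNase A domain family illustrates a
vertebrate-specific expansion: absent from both invertebrates, so the
0.5 pseudo-count divisor yields a 19.5-fold ratio. Of the 527
RBP-containing orthogroups, 72.1% are strict single-copy across their
represented species.

A full end-to-end run over a generated input bundle:

```r
config <- write_six_species_bundle("bundle_dir", seed = 1)
rep <- run_report(config, outdir = "report_dir")
rep$summary   # stage / metric / value rows for every analysis
```

See `vignettes/rbp-diversity-methods.Rmd` for the model conventions,
tunable parameters, generator design and known limitations.

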