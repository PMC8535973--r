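# pyropattern

Pyroptosis — inflammatory, gasdermin-driven programmed cell death — shapes
the tumor microenvironment (TME). Across tumor expression cohorts, the
joint expression of a curated panel of ~33 pyroptosis regulators
(gasdermins, inflammatory caspases, inflammasome sensors, interleukins)
stratifies patients into *pyroptosis patterns* with distinct immune
landscapes and survival. `pyropattern` is an R package for transcriptomics
analysts who want that entire analysis as tested, reusable code:

* **pattern discovery** — subsampled consensus clustering of the regulator
  panel; the number of patterns is selected by minimizing PAC (the
  proportion of ambiguous clustering, the CDF mass of consensus values in
  (0.1, 0.9]);
* **TME scoring** — single-sample gene set enrichment (ssGSEA): per sample,
  genes are ranked by decreasing expression and the score is
  `sum_j [ P_in(j) - P_out(j) ]` with hit weight `|rank|^alpha`; plus
  ESTIMATE-style immune/stromal scores with purity
  `cos(0.6049872018 + 0.0001467884 * score)`, and hypergeometric
  over-representation with BH correction;
* **signature genes** — empirical-Bayes moderated t per gene
  (`s2_post = (d0*s0^2 + d*s2) / (d0 + d)`, hyperparameters by
  digamma/trigamma moment matching); pattern-related signature genes are
  those with FDR < 0.01 in *every* pairwise pattern contrast;
* **pyroptosis score (PS)** — univariate Cox screen (p < 0.05) of the
  signature genes, centering-only PCA, `PS = PC1 + PC2` coordinates per
  sample, and a maximally selected log-rank cutpoint defining high/low
  groups;
* **survival & landscape** — Kaplan–Meier, log-rank, Newton–Raphson Cox
  (Breslow/Efron), IPCW time-dependent ROC, Wilcoxon/Kruskal–Wallis,
  Spearman; mutation frequency, Fisher co-mutation, CNV gain/loss
  frequency and tumor mutation burden (TMB);
* **synthetic data** — a generator that plants K patterns, batch effects,
  a latent prognostic score and a burden–score coupling, so every stage of
  the pipeline has recoverable ground truth.

## Worked example

A complete run on a simulated two-cohort study (150 samples, 3 planted
patterns, 2000 genes):

```r
library(pyropattern)

sim  <- simulate_study(sim_config(seed = 7))
expr <- correct_batch(sim$expression)

cc <- consensus_cluster(expr, panel = sim$sets$regulator_panel,
                        k_range = 2:5, reps = 200, seed = 7)
cc
#> consensus_result over k = {2, 3, 4, 5}, 200 reps, p_item = 0.80
#> PAC: k=2: 0.4474  k=3: 0.0000  k=4: 0.2157  k=5: 0.2963
k <- select_k(cc)                      # 3: PAC is minimized at the truth
clusters <- cc$per_k[[as.character(k)]]$assignments

de   <- moderated_de(expr, clusters)
degs <- overlap_degs(de, fdr_threshold = 0.01)
degs
#> overlap_deg_set: 133 gene(s) below fdr 0.01 in all 3 contrast(s)

prog  <- screen_prognostic(expr, sim$clinical, degs)
model <- fit_ps_model(expr, prog)
model
#> ps_model: 133 gene(s); PC1/PC2 variance explained 72.8% / 0.8%
ps  <- compute_ps(model, expr)
res <- find_cutpoint(ps, sim$clinical)
res
#> ps_result: cutpoint -0.2588 (max |z| = 7.454); 76 high / 74 low

cox_fit(as.numeric(res$group == "high"), sim$clinical$time, sim$clinical$event)
#> cox_fit (breslow ties, 150 samples, 99 events)
#>        beta        se       HR           ci95        p
#> x1 1.647388 0.2404527 5.193395 [3.242, 8.320] 7.32e-12

burden <- tmb(sim$mutations, sample_ids = names(ps))
spearman_assoc(as.numeric(burden), ps[names(burden)])$rho
#> 0.844
adjusted_rand_index(sim$truth$pattern, clusters[names(sim$truth$pattern)])
#> 1
```

Reading the output: the consensus CDF is unambiguous exactly at k = 3
(PAC = 0) and the recovered clusters match the planted patterns perfectly
(adjusted Rand index 1). 133 genes separate all three patterns at
FDR < 0.01; their two-component PCA score splits the cohort at the
maximally selected cutpoint −0.259. In this simulation the latent score
carries a *positive* log-hazard (β = 0.5), so the high-PS group has HR ≈
5.2 (worse survival) — the orientation of PS against outcome is a
reported property of each dataset, never silently flipped. TMB tracks PS
(ρ = 0.84) because the generator couples mutation burden to the same
latent score.

## Command-line interface

A thin CLI over the same functions ships in `inst/cli/pyropattern.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/pyropattern.R", package = "pyropattern"))')
Rscript $CLI simulate  --seed 5 --out sim/
Rscript $CLI prepare   --expr sim/expression.tsv --clinical sim/clinical.tsv \
                       --cohorts sim/cohorts.tsv --scale log2 --out prep.rds
Rscript $CLI cluster   --prepared prep.rds --panel sim/regulators.gmt \
                       --kmin 2 --kmax 6 --reps 1000 --seed 17 --out clusters.tsv
Rscript $CLI de        --prepared prep.rds --clusters clusters.tsv --out degs.tsv
Rscript $CLI ps        --prepared prep.rds --degs degs.tsv --out ps.tsv
Rscript $CLI survival  --ps ps.tsv --prepared prep.rds --out survstats.json
Rscript $CLI landscape --maf sim/mutations.tsv --cnv sim/cnv.tsv \
                       --panel sim/regulators.gmt --ps ps.tsv --out landscape.json
```

## Scope notes

The package computes; it does not plot, and it does not download — GEO/TCGA
retrieval, probe collapsing, GSVA's kernel statistic, drug-sensitivity
prediction and immunotherapy-cohort assembly are out of scope. See
`vignettes/pyropattern-methods.Rmd` for the models, the synthetic world's
assumptions, and the design decisions.
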