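# omicwalk

Multi-omic aberration integration and network propagation for cancer gene
prioritization, with survival-based validation of the resulting gene
signatures.

## The problem

Tumors accumulate regulatory damage on several layers at once: somatic
mutations, copy-number gains and losses, and promoter methylation changes,
all of which can push a gene's expression up or down. Studies built on
paired tumor/adjacent-normal designs (TCGA-style colorectal cohorts are the
motivating case) ask which genes carry *concordant* damage — e.g.
over-expression together with amplification, or under-expression together
with promoter hypermethylation — and which genes sit at the focus of that
damage within a gene regulatory network. `omicwalk` implements that whole
analysis as a tested, reusable pipeline:

1. **Per-layer aberration calling** on paired matrices. Differential
   expression from raw counts (paired test on log2(CPM+1) differences,
   FDR < 0.01 and fold change ≥ 2), gene-level copy number from SEG
   segment tables (length-weighted means over the gene body; paired test on
   the linear copy ratio 2^segmean, FDR < 0.001, FC ≥ 1.2), promoter
   methylation from probe-level β values (strand-aware promoter window
   TSS−1000 bp to TSS+300 bp, multi-probe mean; paired test on β,
   FDR < 0.001, FC ≥ 1.5), and recurrently mutated genes (patient-level
   mutation rate strictly above 5%). SGOL gain/loss profiles and 500-kb
   methylation bins are available for genome-wide summaries.
2. **Candidate group formation and overlap testing.** Group A
   (expression–copy-number consistent), Group B (expression–methylation
   consistent), Group C (differentially expressed and mutated). Pairwise
   overlaps are tested with the upper-tail hypergeometric probability

   P(X ≥ x), X ~ Hypergeometric(N, K, M),

   where N is the number of all differentially expressed genes, K and M the
   two group sizes and x the observed overlap; the same statistic powers a
   generic GMT-based over-representation test.
3. **Random walk with restart (RWR).** Edge lists are merged into one
   simple undirected graph; the walk runs on the biggest connected
   component with the column-normalized adjacency W:

   p(t+1) = (1 − r) · W · p(t) + r · p0,   r = 0.7,

   iterated until the L1 change drops below 1e-10. Seed genes from groups
   B and C score 1, genes in both score 2; p0 is the normalized score
   vector. Significance comes from a node-label permutation null (default
   10,000 permutations): the score multiset is re-placed at random node
   positions, and each gene's steady-state probability is compared with its
   own null distribution (strict p < 0.01 cut).
4. **Survival evaluation.** Cox-derived linear risk scores
   r_j = Σ_i β_i·x_ij from a training cohort, median-split Kaplan–Meier with
   log-rank tests (overall and within stage I/II vs III/IV strata),
   stratified k-fold cross-validation, Harrell's C-index, and fixed-effect /
   DerSimonian–Laird random-effect pooling of per-cohort hazard ratios.

A synthetic-data module generates paired multi-omic cohorts, scale-free
networks with a planted propagation-proximal module, and proportional-
hazards survival cohorts — all with known ground truth — so every stage of
the pipeline is testable without access to controlled data.

## Worked example

```r
library(omicwalk)

# paired tumor/normal cohort with known implants (2000 genes, 32 pairs)
cohort <- simulate_cohort(sim_config(seed = 1))

deg  <- call_deg(cohort$expression)
cnv  <- call_cnv(gene_level_cnv(cohort$seg, cohort$annotation))
meth <- call_methylation(promoter_methylation(cohort$probes, cohort$annotation))
mut  <- call_mutated(cohort$mutations, n_patients = 32)

groups <- form_groups(deg, cnv, meth, mut)
groups
#> <gene_groups> A: 50, B: 50, C: 25 (background: 100 DEGs)
overlap_tests(groups)
#> # A tibble: 3 × 7
#>   group1 group2     N     K     M overlap p_value
#> 1 A      B        100    50    50      26   0.421
#> 2 A      C        100    50    25      10   0.917
#> 3 B      C        100    50    25      14   0.322
```

All 350 implanted aberrations are recovered at the published gates, and the
groups contain exactly the sign-consistent implants. On the published
worked example the overlap statistic reproduces the printed probability:

```r
hypergeometric_tail(4041, 568, 397, 107)
#> [1] 6.309559e-13
```

Propagation over a network with a planted module (genes carrying both
aberration classes in a dense seed-adjacent neighbourhood):

```r
sim  <- simulate_network(300, planted_module_size = 10, n_seeds = 40, seed = 1)
walk <- rwr_significance(sim$network, sim$truth$group_b, sim$truth$group_c,
                         B = 1000, seed = 1)
glance(walk)
#> # A tibble: 1 × 7
#>   n_nodes n_seeds iterations converged     B p_mode      n_significant
#> 1     300      50         16 TRUE       1000 pseudocount            10
head(select_significant(walk), 3)
#> # A tibble: 3 × 6
#>   gene_id raw_score steady_prob   perm_p significant  rank
#> 1 v0008           2      0.0355 0.00200  TRUE            1
#> 2 v0189           2      0.0344 0.000999 TRUE            2
#> 3 v0119           2      0.0343 0.000999 TRUE            3
```

The 10 significant genes are exactly the planted module. Finally, a 10-gene
signature evaluated on simulated survival cohorts (train n = 300, four test
cohorts of 150, 30% censoring), late-stage strata:

```r
genes <- sprintf("sig%02d", 1:10)
sim_s <- simulate_survival_cohorts(genes, rep(c(0.7, -0.7), 5),
                                   n_per_cohort = c(300, 150, 150, 150, 150),
                                   censoring = 0.3, seed = 1)
model  <- fit_risk_model(sim_s$cohorts[[1]], genes)
splits <- purrr::map_dfr(sim_s$cohorts[-1], function(co)
  median_split_logrank(risk_scores(model, co), co,
                       stage_filter = c("III", "IV")))
meta_analyze(splits, model = "fixed")
#> <meta_result> fixed-effect pooling of 4 cohorts: HR 40.049 (20.480-78.314),
#>   p = 4.07e-27, tau^2 = 0
```

High-risk patients (scores above the cohort median) fail markedly earlier
in every late-stage stratum, and the pooled hazard ratio recovers the
implanted direction. `plot_km()`, `autoplot()` on walk results, call tables
and meta-analyses, plus `tidy()`/`glance()` methods, cover reporting.

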