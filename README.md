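# metadeg

Discovery of metastasis-associated genes from multi-site tumor RNA-seq, with
tissue-of-origin control filtering, transcription-factor binding-site
enrichment, and prognostic survival screening.

## The problem

Autopsy cohorts of metastatic castration-resistant prostate cancer (mCRPC)
pair a handful of primary tumors with metastases spread across liver,
adrenal gland, bone, subdural and lymph-node sites. Two confounders dominate
any naive primary-vs-metastasis comparison:

* **Tissue of origin** — a gene highly expressed in liver looks
  "metastasis-up" simply because some metastases grow in liver.
* **Patient identity** — patient-to-patient variance exceeds the
  primary/metastasis difference, so unmatched comparisons are noisy.

`metadeg` implements the full discovery cascade that addresses both, for
analysts who want the pipeline's logic on their own count matrices, and a
synthetic cohort generator that makes every stage testable without access to
controlled patient data.

## The method

1. **Differential expression.** Per gene, a negative-binomial log-link model
   with median-of-ratios size factors `s_j`:

   `K_gj ~ NB(mu_gj, alpha_g)`, `mu_gj = s_j exp(b0 + b1 x_j)`,
   `Var = mu + alpha_g mu^2`

   where `x_j` indicates metastasis. `alpha_g` comes from a pooled
   within-group method of moments; `b1` is tested with a Wald z test and
   Benjamini–Hochberg adjustment. Genes with adjusted p <= 0.1 enter the
   cascade (a deliberately permissive first gate).
2. **Tissue-control filters** (adjusted p < 0.01, each oriented
   prostate-side over control-side). A candidate with metastasis direction
   `d` is removed when a control contrast is significant with sign `-d`:
   (a) primaries vs each non-prostate normal tissue, (b) primaries vs all
   non-prostate normals pooled, (c) BPH prostate controls vs pooled normals.
3. **Pairwise concordance.** For each patient with a matched primary, the
   sign of (mean normalized expression over that patient's metastases) minus
   (their primary). Genes divergent from the cohort-level direction in more
   than two patients are removed; a two-primary patient is divergent if
   either comparison diverges.
4. **Regulome.** Strand-aware regulatory windows (-15 kb/+2 kb around the
   TSS), >= 1 bp peak overlap, one-tailed Fisher enrichment of TF binding
   sites in DEG windows vs background gene windows (BH across TFs, adjusted
   p < 0.15), plus tumor/normal AR binding-site annotation with peak-level
   FOXA1/HOXB13 co-occupancy.
5. **Prognosis.** Third-quartile expression stratification, Kaplan–Meier
   log-rank screening (p < 0.05), then multivariate Cox proportional-hazards
   regression (Efron ties) with the standard clinical covariate codings
   (age <=62/>62; PSA <=10 / 10–19.9 / >=20; Gleason <7 / =7 / >7;
   pT2a-b / pT3a-b). A gene is an independent predictor when its expression
   term stays significant in the multivariate model.

## Worked example

```r
library(metadeg)

cfg    <- sim_config(n_genes = 2000, seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> <sim_cohort> 2000 genes x 129 samples (bph 7, metastasis 82, normal 33, primary 7)
#>   planted: 300 metastasis gene(s), 200 tissue gene(s), 5 prognostic gene(s)

report <- run_discovery(cohort$counts, cohort$samples, pipeline_config())
report
#> <discovery_report> 2000 genes, 6 matched patient(s)
#>          stage n_in n_kept n_up n_down
#>             de  397    397  224    173
#>     tissue_per  397    326  159    167
#>  tissue_pooled  326    326  159    167
#>            bph  326    326  159    167
#>       pairwise  326    323  157    166
#> final: 323 metastasis-associated gene(s) (157 up, 166 down)
```

397 genes pass the permissive DE gate; the per-tissue filter removes 71 of
them (the planted liver/adrenal/bone signatures that leaked into the call),
and the pairwise filter drops 3 more genes whose within-patient changes
contradict the cohort-level direction.

```r
windows <- regulatory_windows(cohort$annotation)
peaks   <- simulate_peaks(cohort$annotation,
  list(EZH2 = list(targets = cohort$truth$met_deg$gene_id, p1 = 0.6, p0 = 0.05),
       TP63 = list(targets = character(), p1 = 0.05, p0 = 0.05)), seed = 43)
tf_enrichment(report$final$gene_id, windows, peaks, alpha = 0.15)
#> <tf_enrichment> 2 TF(s), 323 DEG windows, exclusive background; 1 enriched at adj p < 0.15
#>  tf_name   a   b  c    d odds_ratio             p         adj_p enriched
#>     EZH2 191 132 99 1578 23.0638200 3.846685e-103 7.693370e-103     TRUE
#>     TP63  16 307 90 1587  0.9190011  6.614003e-01  6.614003e-01    FALSE
```

The planted factor (60% of metastasis genes carry a binding site vs 5% of
background) is recovered; the null factor is not. `a`–`d` are the 2x2 table
cells: DEG windows with/without a site, background windows with/without.

```r
prog   <- simulate_prognostic_cohort(report$final$gene_id,
                                     cohort$truth$prognostic, n = 200, seed = 44)
screen <- prognostic_screen(union(report$final$gene_id,
                                  cohort$truth$prognostic$gene_id),
                            prog$expression, prog$records)
screen
#> <prognostic_screen> 328 gene(s) screened, 23 with log-rank p < 0.05, 16 independent predictor(s)
```

`run_pipeline()` chains all stages and writes every table (counts, design,
annotation, peaks as BED, DE results, per-gene filter decisions, enrichment,
ARBS flags, survival screens) into an output directory; two runs with the
same seeds are byte-identical.

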