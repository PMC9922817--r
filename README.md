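# mitopulse

Pulse-SILAC (pSILAC) analysis of mitochondrial translation and OXPHOS
complex assembly, for proteomics researchers who want the full
computational path — from protein sequence to moderated statistics —
as tested, reusable R functions.

Chloramphenicol (CAP) blocks the mitochondrial ribosome but not the
cytosolic one. In a pSILAC experiment, cells switch to medium-heavy (M) or
heavy (H) labeled amino acids, so the per-peptide H/M intensity ratio
compares newly synthesized protein between CAP- and vehicle-treated
cultures; in a pulse-chase experiment, loss of the pulse-labeled H cohort
(read out as H/L under CAP relative to DMSO) measures degradation of newly
made protein. When mitochondrial translation stops, nuclear-encoded OXPHOS
subunits that normally assemble with mitochondrial-encoded partners become
orphans and are degraded. `mitopulse` implements:

* **In-silico digestion** — trypsin / lysC / chymotrypsin and their
  combinations, missed cleavages, the proline rule, theoretically
  observable peptides (6–30 residues) and iBAQ divisors.
* **A generative turnover model** — first-order kinetics
  ($\dot X = s(t) - k(t)X$) with per-protein synthesis rate $s$,
  degradation rate $k_d$, and two drug knobs: $f$ (synthesis multiplier)
  and $g$ (degradation multiplier of newly made cohorts). It produces
  three-channel SILAC evidence with peptide ionization factors, channel
  noise, mixing bias, intensity-dependent dropout, and known ground truth.
* **Quantification** — peptide log-ratio medians per protein and
  replicate, label-swap reconciliation, median-centering normalization,
  the all-replicates filter, and a one-sample empirical-Bayes moderated
  t-test ($\tilde s^2 = (d_0 s_0^2 + d_i s_i^2)/(d_0+d_i)$, $t = \bar x
  \sqrt n/\tilde s$ on $d_0 + d_i$ df) with Benjamini–Hochberg FDR.
* **Pulse-chase scoring** — synthesis and degradation scores
  ($\log_2$ ratio-of-ratios vs the DMSO reference), CAP-sensitivity
  classification at $\log_2 H/M = -0.5$ (boundary inclusive on
  "unchanged"), and one-sided Wilcoxon rank-sum group comparisons.
* **OXPHOS annotation** — a packaged human subunit table (CI 45, CII 4,
  CIII 11, CIV 21, CV 17; 13 mitochondrial-encoded) with CI's seven
  assembly modules and CIII/CIV/CV subcomplexes, per-category and
  per-module summaries, and cross-experiment Pearson correlation.
* **Enrichment** — one-sided hypergeometric (Fisher) term tests with BH
  correction.

## Worked example

```r
library(mitopulse)

# the classic observable-peptide argument: human MT-ND4L has one arginine
# and no lysine, so lysC+trypsin yields peptides of 23 and 75 residues,
# only the 23-mer observable
nd4l <- read_fasta(system.file("extdata", "mt_nd4l.fasta", package = "mitopulse"))
digest(nd4l, digest_spec(c("lysc", "trypsin")))$length
#> [1] 23 75

# simulate a pSILAC + pulse-chase study: 300 proteins, 13 mitochondrial-
# encoded (f = 0.05), 20 nuclear orphans (g = 3), label-swapped duplicates
sc <- sim_scenario(n_proteins = 300, n_mt = 13, n_orphan = 20, seed = 42)
fit <- quantify_psilac(sc$psilac_evidence)
fit
#> pSILAC quantification: 300 of 300 proteins quantified in all 2 replicates
#> empirical-Bayes variance prior: d0 = 1.561 , s0^2 = 0.007521  (fit on 300 proteins)
#> proteins at FDR < 0.05: 22

head(volcano_table(fit)[, c("protein_id", "mean_log2_fc", "p_value", "fdr")], 3)
#>   protein_id mean_log2_fc      p_value        fdr
#> 1     MTP006    -1.961003 0.0001157765 0.01252686
#> 2     MTP003    -1.831979 0.0001335757 0.01252686
#> 3     MTP012    -1.837020 0.0001875964 0.01252686

cs <- chase_scores(sc$chase_evidence, fit$table)
chase_group_comparison(cs)
#>         score n_unchanged n_sensitive      p_value
#> 1 degradation         270          30 1.510076e-05
#> 2   synthesis         270          30 7.802332e-11
```

The top of the volcano table is dominated by the planted
mitochondrial-encoded proteins with strongly negative log2 fold changes
(CAP/DMSO), as expected for direct targets of mitochondrial translation
inhibition. The chase comparison shows the CAP-sensitive group — the
orphaned nuclear subunits plus the MT-proteins — losing its newly
synthesized H cohort significantly faster than the unchanged group
(degradation p ≈ 1.5e-5), with synthesis inhibition even clearer.

`plot(fit, highlight = sc$mt_ids)` draws the volcano plot;
`summarize_by_module(volcano_table(fit), load_annotation(), "CIII")`
summarizes fold changes per assembly subcomplex; `run_pipeline()` chains
all stages from a single config and writes reproducible TSVs.

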