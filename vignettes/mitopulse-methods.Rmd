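---
title: "Models and methods behind mitopulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitopulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopulse)
```

## The scientific problem

The 13 proteins encoded in the mitochondrial genome (MT-proteins) are
translated by mitoribosomes and assemble, together with nuclear-encoded
subunits, into the five OXPHOS complexes. Pulse SILAC (pSILAC) with isolated
mitochondria makes these hydrophobic, low-abundance proteins quantifiable:
newly synthesized protein incorporates medium-heavy (M) or heavy (H)
arginine/lysine, so the H/M intensity ratio of a peptide compares new-protein
production between two conditions — here chloramphenicol (CAP), an inhibitor
of the mitochondrial but not the cytosolic ribosome, against vehicle (DMSO).
When mitochondrial translation is blocked, nuclear-encoded subunits that
normally partner MT-proteins in assembly subcomplexes are left "orphaned" and
degraded by the proteasome. `mitopulse` implements the computational side of
this experimental programme end to end, driven by a synthetic evidence
generator with known ground truth so that every stage can be verified
without raw mass-spectrometry data.

## In-silico digestion and observable peptides

Cleavage rules are positional: trypsin cuts after K or R, lysC after K,
chymotrypsin after the aromatic residues F, W, Y (the specificity that
matters for SILAC labeling with essential amino acids; no L/M cleavage is
modeled). Trypsin and chymotrypsin obey the classical proline rule — a cut
is suppressed when the next residue is proline — while lysC cleaves
regardless; the rule can be disabled per `digest_spec()`. A protease
combination cuts at the union of the individual site sets. With
`missed_cleavages = 0` the peptides partition the sequence; with `m` missed
cleavages every run of up to `m + 1` adjacent fragments is also produced.

"Theoretically observable" peptides are fully cleaved products of 6–30
residues, the standard detectability window in shotgun MS, and their count
is the iBAQ divisor (`ibaq()` = protein intensity / observable-peptide
count). We use 0 missed cleavages for observable counts: the worked
MT-ND4L example — a 98-residue protein with a single arginine and no
lysine, so lysC+trypsin yields only a 23-mer and a 75-mer, of which only
the 23-mer is observable — pins this convention, and the count remains a
parameter for users who prefer the search engine's tolerance of 2.
Initiator methionine is retained; coordinates are 1-based inclusive;
non-canonical residues (B/J/O/U/X/Z) are rejected outright rather than
silently skipped, because their cleavage behaviour is undefined.

```{r nd4l}
nd4l <- read_fasta(system.file("extdata", "mt_nd4l.fasta",
                               package = "mitopulse"))
digest(nd4l, digest_spec(c("lysc", "trypsin")))[, c("start", "end", "length")]
```

## The turnover model behind the simulator

Each protein carries a synthesis rate $s$ (intensity units/h) and a
first-order degradation rate $k_d$ (/h), at steady state $A_0 = s/k_d$
before labeling. Drug action is split into two orthogonal knobs:

* $f \ge 0$ multiplies synthesis (the direct effect of a translation
  inhibitor on its targets),
* $g \ge 1$ multiplies the degradation rate of *newly made and
  pulse-labeled cohorts only* — the orphan-subunit effect. In the chase
  design the pre-existing (L) pool always decays at baseline $k_d$:
  already-assembled complexes are not orphaned by a translation block.
  (In the pSILAC closed form the residual pre-existing pool does share the
  drug-window degradation rate; the H/M readout never uses the L channel
  there, so this asymmetry of the model is inconsequential.)

For the pSILAC design (label from $t = 0$, preincubation $t_1 = 8$ h, drug
window $t_2 = 16$ h, $f' = f$, $k_d' = g k_d$ under drug):

$$\mathrm{New} = \frac{s}{k_d}\left(1 - e^{-k_d t_1}\right)e^{-k_d' t_2}
  + \frac{s f'}{k_d'}\left(1 - e^{-k_d' t_2}\right),$$

and for the 4 h pulse / 4 h chase design,
$H = \frac{s}{k_d}(1 - e^{-k_d t_p})\,e^{-k_d' t_c}$,
$M = \frac{s f'}{k_d'}(1 - e^{-k_d' t_c})$,
$L = A_0 e^{-k_d (t_p + t_c)}$. Both closed forms are verified against an
independent ODE integration of $\dot X = s(t) - k(t) X$ to better than
$10^{-6}$ relative error in the test suite.

## What the evidence generator emulates — and what it does not

Per observable peptide and replicate, intensity = channel amount ×
peptide ionization factor (log-normal, `peptide_factor_sigma = 0.5`,
shared across channels so noiseless ratios are exact — SILAC's
within-peptide ratio principle) × independent log-normal channel noise
(`channel_noise_sigma = 0.2`) × a global per-channel mixing bias, followed
by channel-wise logistic dropout on log10 intensity. The dropout defaults
(`midpoint = 1.5`, `slope = 1.2`) drop roughly 10% of channel measurements
at the default intensity scale, giving intensity-dependent (MNAR)
missingness. Degradation rates are log-normal with median 0.03/h (half-life
about 23 h) and synthesis rates log-normal with median 100, a realistic
mammalian range spanning the dropout regime. The packaged scenario plants
13 mitochondrial-encoded proteins at $f = 0.05$ (strong direct inhibition),
optional nuclear sets with partial synthesis effects or with $g = 3$
orphan destabilization, and label-swapped duplicate replicates.

Not emulated: spectrum-level artifacts (isotope envelopes, co-elution
interference), peptide identification errors, protein-group ambiguity,
growth dilution, and any drug effect on global growth. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generative model, not robustness to those real-data pathologies.

## Quantification and moderated statistics

Per replicate, each peptide row with both ratio channels present
contributes $\log_2(\mathrm{CAP\ channel}/\mathrm{control\ channel})$,
with label-swapped replicates sign-corrected through their recorded CAP
channel; the protein ratio is the peptide median. Ratios are normalized by
per-replicate median-centering — the mixing error the cited
variance-stabilizing step corrects is a location shift on the log-ratio
scale, which centering removes exactly (the global median is 0 after the
operation, and it is idempotent). An affine-arcsinh mode
(`normalization = "arcsinh"`) is available as a documented approximation
of intensity-level variance stabilization; its scale anchors at the 5th
percentile of the replicate's intensities so the transform is
logarithmic for the bulk of measurements. Proteins must be quantified in
**all** replicates (no imputation), with at least one peptide each.

The one-sample moderated test shrinks each protein's replicate variance
toward a prior estimated from all proteins: with $s_i^2$ on $d_i = n - 1$
df, the prior $(d_0, s_0^2)$ solves the digamma/trigamma moment equations
of the scaled inverse-chi-square model, with the trigamma inverted by
Newton iteration; when the spread of log-variances does not exceed what
sampling alone explains, $d_0 = \infty$ and the prior collapses to the
bias-corrected geometric-mean pooled variance. Then
$\tilde s^2 = (d_0 s_0^2 + d_i s_i^2)/(d_0 + d_i)$,
$t = \bar x / (\tilde s/\sqrt n)$ on $d_0 + d_i$ df, two-sided p, and
Benjamini–Hochberg FDR across all tested proteins. The implementation is
authored here from these formulas and cross-checked against an independent
reference implementation in the test suite; at $d_0 = 0$ it reproduces the
ordinary one-sample t exactly.

## Pulse-chase scoring and classification

The degradation score is $\log_2\frac{(H/L)_\mathrm{CAP}}{(H/L)_\mathrm{DMSO}}$
(negative = the new cohort was lost faster under CAP) and the synthesis
score the same with M/L. Scores are invariant to common rescaling of all
four channels. Classification into "unchanged" ($\log_2 H/M \ge -0.5$,
boundary inclusive) versus "CAP-sensitive" ($< -0.5$) uses the *pSILAC*
experiment's mean log2 H/M, not the chase experiment's own M channel —
matching the two-experiment design. Group scores are compared with a
one-sided Wilcoxon rank-sum test: exact when the combined n is at most 12
with no ties, otherwise the normal approximation with tie and continuity
correction. Whether chase ratios should themselves be normalized is not
settled; `chase_scores(normalize = TRUE)` median-centers each condition's
log-ratios by default and records the choice in the output attributes —
the group comparison is invariant to this location shift. The MG132 arm of
the simulator sets $g = 1$ under CAP+MG132, emulating proteasome rescue,
and the identical comparison on that arm is expected non-significant.

## Complexes, modules, and enrichment

The packaged annotation pins the per-complex totals CI 45, CII 4, CIII 11,
CIV 21, CV 17 and exactly 13 mitochondrial-encoded entries, with CI's
seven-module architecture (N, Q, ND1, ND2, ND4, ND5, NDUFAB1), CIII/CIV
assembly subcomplexes and CV assembly steps; members whose placement is
not firmly established (tissue isoforms, the UQCRFS1 presequence entry,
historically reassigned subunits) carry an `uncertain` flag rather than a
silent guess. Category summaries use the four-way split (MT-encoded
OXPHOS / nuclear OXPHOS / nuclear mito / nuclear non-mito), with
non-OXPHOS mitochondrial membership supplied as an id list;
cross-experiment agreement uses Pearson correlation per category.
Enrichment is the plain one-sided hypergeometric test with BH correction —
a deliberate, documented substitution for web-service GO tooling — with
the background convention "proteins quantified in all protocols under
comparison".

## Numerical and design choices

* Exact-vs-approximate Wilcoxon switch at combined n = 12; ties force the
  approximation.
* Zero moderated variance yields the smallest representable p with a flag,
  never 0.
* Undefined iBAQ (0 observable peptides) is missing, not an error.
* Evidence cells that are empty are missing; 0 is treated as missing only
  under the external (MaxQuant-style) column dialect, matching that tool's
  convention.
* All simulator randomness flows from the single seed in `noise_model()`;
  identical seeds give byte-identical evidence tables.
* File writes are atomic (temp file + rename); every pipeline output
  carries version, seed and stage in a comment header.

## Problem sizes used in the packaged checks

The end-to-end recovery scenario uses 1000 proteins, two label-swapped
replicates, channel noise 0.2, and 50 planted $f = 0.25$ effects; the
digestion oracle runs 100 random proteins (length ≤ 400) across all seven
protease subsets and 0–2 missed cleavages; the kinetic closed forms are
checked on a 100-point random parameter grid; the null calibration of the
chase comparison uses 200 simulated datasets of 60 proteins. These sizes
give stable Monte-Carlo estimates (binomial SE of the type-I rate
≈ 0.015 at 200 replicates) while keeping the whole suite fast.

## Known limitations

* The arcsinh mode approximates, but is not, the full calibrated
  variance-stabilizing normalization of the intensity literature.
* Absolute half-lives and per-protein $k_d$ fits are out of scope: the
  chase design here is single-timepoint.
* The annotation's uncertain-flagged memberships should be reviewed before
  biological interpretation of module-level summaries at those entries.
* With two replicates the per-protein variance has a single degree of
  freedom; the moderated test leans heavily on the prior, which is exactly
  the regime it is designed for, but outlier proteins with correlated
  peptide errors can still escape it.
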