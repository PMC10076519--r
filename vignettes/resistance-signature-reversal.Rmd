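---
title: "From drug-sensitivity cohorts to signature-reversing drugs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From drug-sensitivity cohorts to signature-reversal: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigconnect)
```

## The problem this package addresses

A recurring design in translational transcriptomics starts from a cohort of
patient samples profiled twice: bulk RNA-seq, and an ex vivo drug screen
summarized as the area under the dose-viability curve (AUC) per drug. Samples
with high AUC are resistant, samples with low AUC sensitive. The analytical
chain is then:

1. stratify the cohort per drug into sensitive (S) and resistant (R) AUC
   tertiles;
2. rank every gene by a signal-to-noise score between R and S, per drug, and
   combine the per-drug rankings into one average-rank resistance signature;
3. screen transcription-factor (TF) target sets against the per-drug rankings
   with weighted Kolmogorov–Smirnov (KS) gene-set enrichment to find the TF
   program that is consistently activated in resistant samples;
4. turn the TF program into signed query gene lists and score them against a
   compendium of drug-perturbation signatures (connectivity mapping:
   two-tailed enrichment → WTCS → NCS → tau → median summary) to find
   compounds whose transcriptional effect *reverses* the resistance program —
   candidates for combination therapy.

`sigconnect` implements every statistical step of that chain as tested
package code, and pairs it with a synthetic-cohort generator whose planted
ground truth (which genes form the TF program, which compendium entry is the
reverser) makes the whole chain verifiable end to end without any external
data.

## The synthetic study conditions

`sim_config()` fixes the study conditions; its defaults are the conditions
used throughout the tests and the analysis scripts: 2,000 genes, 120
samples, 4 drugs, a 100-gene TF target program, and a 100-perturbagen × 2
cell-line compendium.

Expression is simulated directly on the log2 scale,

$$x_{gs} = \mu_g + \beta \, a_s \, \mathbf{1}[g \in T] + \varepsilon_{gs},
\qquad a_s \sim N(0,1),\ \varepsilon_{gs} \sim N(0, \sigma^2),$$

with latent TF activity $a_s$, target set $T$, effect $\beta$ (`tf_effect`,
default 1 log2 unit per activity SD) and noise SD $\sigma$ (`noise_sd`,
default 1). There is no count model: every downstream statistic
(signal-to-noise, rank combination, KS enrichment) is mean- or rank-based,
so negative-binomial fidelity would add cost without changing what the tests
can detect. For the same reason no library-size, batch, or mutation
co-occurrence structure is simulated — passing tests show the *statistical
machinery* recovers planted structure at realistic effect sizes, not that
the generator reproduces any real cohort's covariance.

AUC is linear in the latent activity plus clinical covariates:

$$\mathrm{AUC}_{ds} = \alpha_d + \gamma\, a_s + \delta\, b_s +
\eta\, \mathbf{1}[\mathrm{NPM1}_s] + e_{ds},$$

with blast percentage $b_s \sim U(5, 95)$, slopes
$\gamma = 8$ AUC units per activity SD (resistance), $\delta = -0.25$ per
blast point and $\eta = -10$ for NPM1-mutant samples (both sensitizing; 41%
of samples carry the flag, matching the mutation frequency typical of the
cohorts this emulates), intercept $\alpha_d = 80$ and residual SD 6. These
values were chosen once so that each association is comfortably but not
trivially detectable at $n = 120$ (the blast correlation lands near
$\rho \approx -0.4$, the NPM1 contrast near one residual SD), and are not
revisited.

The perturbation experiments (TF overexpression, knockdown, dominant-negative
p30) are emulated as per-gene score tables: responsive targets score
$\pm 4 \pm 0.3$, background genes $N(0,1)$, and direction sets are called at
$|score| \ge 2.5$. The margin between 4 and 2.5 makes target calls
essentially deterministic while background false calls across all three
tables are negligible, so the common intersection equals the planted program
at full overlap. An `overlap` parameter thins each experiment's responsive
subset independently to emulate partial concordance across experiments.

The compendium's planted reverser blends, at weight `reverser_strength`
(default 0.9), the negated target-direction vector with a permuted copy of a
fixed symmetric score profile; all other perturbagens are independent
permutations of that profile, hence exchangeable noise. Perturbagen classes
are assigned round-robin from ten pharmacological labels; they only matter
for NCS stratification and for the class-composition report.

All randomness derives from one integer seed; each generator stage uses a
fixed offset of it, so any stage can be rerun in isolation and still
reproduce its slice of a full-pipeline run.

## Statistical choices worth spelling out

**Tertile remainder rule.** For $n$ not divisible by 3, the sensitive group
takes $\lceil n/3 \rceil$ samples and the resistant group
$\lfloor n/3 \rfloor$; ties in AUC are broken by stable sample-id order. Any
fixed rule would do; this one is pinned and documented, and the same rule is
reused when the non-resistant two-thirds are subdivided into MS/LS.

**Signal-to-noise floor.** The ranking metric is
$(\mu_R - \mu_S)/(s_R + s_S)$ with each group SD floored at
$\max(s, 0.2|\mu|, 0.2)$, the convention established by the GSEA desktop
tool. The floor is mean-dependent, so the metric is not invariant to adding
a constant to a gene — an accepted property of the convention, not a bug.

**Differential expression.** Welch's t on log2 values with
Benjamini–Hochberg FDR, filtered at two-fold change and FDR ≤ 0.05. This is
a declared surrogate for a count-model DE test: the synthetic data are
Gaussian on the log2 scale and the pipeline consumes only the pass/fail
filter, never dispersion estimates. On real count data a dedicated DE
package should replace this step.

**GSEA null and FDR.** Significance uses gene-set permutation (size-matched
random sets), not phenotype permutation: the cohorts here are small and the
gene-set null is exactly calibrated by construction (the nominal p of a
random set is uniform, which the test suite verifies by a KS test).
Across-set correction is plain BH on the nominal p, reported as `q_bh` to
distinguish it from the NES-binned FDR of the desktop tool. NES divides ES
by the mean |null ES| of matching sign. The TF screen gates at
`q_bh` ≤ 0.25 (the conventional exploratory threshold) in *all* drugs and
ranks the survivors by median NES; the cross-drug aggregation rule is a
package choice, as is the `weight_p = 1` default (classic weighted GSEA;
`weight_p = 0` gives the unweighted KS statistic and is used in
cross-checks).

**ES extremum ties.** When the maximal positive and negative running-sum
deviations tie in magnitude (common at `weight_p = 0`, where deviations are
rational multiples of common steps), the positive one is reported; the
comparison carries a 1e-9 tolerance so that algebraically equal quantities
computed in different summation orders resolve the same way.

**Connectivity conventions.** WTCS is $(ES_{up} - ES_{down})/2$ when the
tails disagree in sign and 0 otherwise; queries with an empty down list are
scored one-tailed as $ES_{up}$ — the reversal screen queries an up-gene
program and looks for negative connectivity. NCS normalizes WTCS within
(query, cell line, class) strata by the signed within-stratum means,
self-inclusive, so a score alone of its sign normalizes to ±1. Tau is the
signed percentile of |NCS| against the other perturbagens of the same cell
line with a *strict* inequality — with that convention a score exceeding 19
of 20 references lands exactly at ±95, and ±100 is attained when it exceeds
all of them. Per perturbagen, the cell line with the largest |NCS| is kept,
and the median across query lists (midpoint convention for even counts) is
the summary score. Reversers are summary tau ≤ −90; the class composition
of the lowest 2% is reported alongside.

## What the tests and scripts actually compute

The analysis scripts under `analysis/` run the chain once at seed 101 under
the default conditions above and print what they find at each stage (cohort
statistics, DEG counts, decile occupancy of the planted program, the
common-top TF, and the reverser's rank and summary tau). The test suite
re-runs the full pipeline across 20 seeds and requires the planted TF and
reverser to be recovered in at least 18; cohort-direction checks (negative
AUC-blast correlation, NPM1 sensitization) must hold in at least 19. Problem
sizes in the tests (universes of a few hundred to 2,000 genes, 499-999
permutations, 20-seed replicates) were chosen as the smallest at which the
planted effects are unambiguous.

## Known limitations

* The generator's simplicity is deliberate; conclusions about real cohorts
  require real data, and the DE step in particular should be swapped for a
  count-aware test there.
* Gene-set permutation calibrates exactly under the synthetic null but does
  not model inter-gene correlation within real signatures; on real data,
  phenotype permutation (not implemented) is the conservative alternative.
* The compendium emulates ranked full-universe signatures; landmark-gene
  inference and the scale of real perturbation compendia are out of scope.
* Tau is computed against the scored compendium itself (self excluded); with
  very small compendia the percentile grid is coarse, which is why
  construction refuses fewer than 10 perturbagens.
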