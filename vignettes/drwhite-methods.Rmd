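---
title: "Quantifying DSB repair pathway choice with drwhite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DSB repair pathway choice with drwhite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drwhite)
```

## The assay and its two readouts

The DR-*white* reporter carries two non-functional direct repeats of the
*Drosophila* *white* gene. The upstream copy, Sce.*white*, is inactivated
by an insertion carrying the 18-bp I-SceI recognition sequence; the
downstream copy is a truncated donor. Expressing I-SceI cuts once at the
recognition site, and the repair outcome is read out in two ways:

* **Molecular (trace decomposition).** The locus is PCR-amplified and
  Sanger-sequenced. Homologous recombination (HR) with the donor deletes
  the full insertion and restores a SacI site (`GAGCTC`), producing a net
  **−23 bp** shift relative to the uncut Sce.*white* amplicon.
  Non-homologous end joining (NHEJ) leaves indels of other sizes (scored up
  to ±35 bp), and a net shift of 0 is scored "no DSB" — a class that also
  absorbs precise NHEJ and intersister HR, which are molecularly
  indistinguishable from no cutting.
* **Phenotypic (germline).** Single premeiotic germline events are revealed
  in the next generation's phenotype: red eyes = HR; white eyes with brown
  body = no DSB/NHEJ (the reporter's starting phenotype); white eyes with
  yellow body = single-strand annealing (SSA), which deletes the *yellow*
  marker between the repeats. The trace readout cannot see SSA; only the
  phenotypic readout scores it.

## The decomposition model

Let $c(p)$ be the four-channel control-trace signal at position $p$ (the
uncut Sce.*white* amplicon) and $s(p)$ the sample signal after registration.
Over a window strictly downstream of the break, a sample that is a mixture
of molecules carrying net indels $k$ satisfies

$$ s(p) \;\approx\; \sum_{k=-K}^{K} w_k \, c(p - k), \qquad w_k \ge 0, $$

because every molecule with a net indel of $k$ bases simply displaces the
downstream sequence by $k$. `decompose()` solves for $w$ by non-negative
least squares (Lawson–Hanson, via `pracma::lsqnonneg`) on the stacked
four-channel signal, truncates weights below `nonneg_tol` ($10^{-9}$) and
renormalises to sum to one. $R^2 = 1 - SS_{res}/SS_{tot}$ over the window
summarises fit quality; a per-component $t$ statistic from the active-set
covariance is attached for reporting but never used to gate the spectrum —
the assay's statistics are proportions, not component significances.

### Window geometry

Two windows matter, both configurable in `decomposition_config()`:

* `align_window`, default $[b-100, b-20]$ for break position $b$: upstream
  of the cut, where control and sample must agree. It drives registration
  (exhaustive integer-offset search maximising cross-channel correlation;
  below 0.8 the sample is rejected as unusable) and the background QC
  statistic.
* `decomp_window`, default $[b+K+5,\; L-K-10]$ for trace length $L$:
  shifted models are only distinguishable downstream of the break, and by
  starting after $b+K$ no modelled position ever overlaps unknown inserted
  bases, so pure shifting of the control is exact for every $k$. The window
  ends $K$ positions short of the trace so that every shifted copy stays
  inside the control; a window that violates these bounds is a
  configuration error, not a silent truncation.

### Quality screen

`background_qc()` measures the mean fraction of intensity carried by
non-dominant channels over the pre-break window. Samples above
`background_threshold` (default 0.15) are flagged `qc_pass = FALSE`;
`classify_spectrum()` refuses them and `aggregate_group()` reports the
exclusion count. All-zero positions are dropped from the mean; an all-zero
window is an error.

### Degenerate inputs and tie-breaks

Base calls tie-break to `N` (deterministic, flags low quality). A sample
with an all-zero decomposition window, or whose NNLS fit retains no
component, is a hard error rather than a zero spectrum. If the active model
columns are rank-deficient (a repetitive control), the solver's vertex
solution is kept and a warning notes that the decomposition may be
non-unique; the synthetic generator's random constructs never trigger this.

## Classification and aggregation

For HR shift $h$ (−23 canonically): $p_{HR} = w_h$, $p_{noDSB} = w_0$,
$p_{NHEJ} = 1 - p_{HR} - p_{noDSB}$. Relative proportions condition on
detectable events, $rel_{HR} = 100\,p_{HR}/(p_{HR}+p_{NHEJ})$; absolute
proportions are of all events, $abs_{HR} = 100\,p_{HR}$ and
$abs_{total} = 100\,(p_{HR}+p_{NHEJ})$. A sample with no detectable repair
has *undefined* relative proportions and is excluded from group means with
a logged count — imputing 0 would bias the conditional statistic. Group
summaries are arithmetic means with SEM $= sd/\sqrt{n}$ across samples.

The germline readout mirrors this at the vial level: per-vial outcome
percentages always sum to 100, and the per-sex statistic is the
**unweighted mean of per-vial percentages** (the vial is the sampling
unit; a vial with 10 flies counts as much as one with 90). The pooled
per-fly proportion is reported alongside for reference.

## The synthetic-data generator

Every input the pipeline consumes can be generated with full seed control,
so each stage is testable against known truth without raw chromatograms:

* `make_reference()` draws a random amplicon (default 600 bp) containing
  `GAGCTC` exactly once and inserts, inside the SacI site, a 23-bp cassette
  (18-bp recognition sequence + 5 duplicated SacI bases) whose removal
  restores the wild type — so the HR shift is −23 by construction.
* `simulate_trace_pair()` renders the control from the Sce amplicon and the
  sample as a truth-weighted sum of indel-bearing variants, each with
  independent noise: called channel $\sim N(\mu\,\delta^{p}, \sigma_s)$
  truncated at 0 with $\mu = 1$, $\sigma_s = 0.05$, optional per-position
  decay $\delta$; other channels folded $N(0, 0.02)$. This is deliberately
  the simplest model with the mixture-of-shifts structure the decomposition
  assumes; real chromatogram noise is autocorrelated and
  amplitude-dependent, so passing recovery tests demonstrate correctness of
  the estimator under its model, not robustness to every real-world
  artefact.
* `simulate_cohort()` draws per-sample outcome fractions around a profile
  by a Dirichlet perturbation (concentration 200, so cohort SEMs are
  non-degenerate), places the HR mass at −23, the no-DSB mass at 0, and
  spreads the NHEJ mass over `nhej_shift_spectrum()` — a geometric decay in
  $|k|$ (ratio 0.6) with a 2:1 deletion bias. The true NHEJ size spectrum
  of the assayed system is unreported; this shape is a modelling choice,
  config-exposed and recorded in every manifest.
* `tissue_profiles()` presets encode each assayed group's HR share of
  detectable events (e.g. larval brain 80.4%, adult head 28.1%, salivary
  gland 14.1%, whole fly 47.3%) and its cohort size. The detectable
  fraction is unreported for several tissues; those presets use 0.5 (and
  0.725 for 3–6 h embryos, between the reported flanking ages) — chosen
  once; the relative HR/NHEJ split the cohorts are scored on does not
  depend on it.
* `simulate_germline_cohort()` draws per-vial progeny counts from a
  truncated Poisson and outcomes from a multinomial, then renders
  phenotypes by inverting the scoring rule. Real vials are overdispersed
  relative to a multinomial (between-vial biology adds variance), so
  simulated ANOVA $F$ statistics run larger than observed ones even though
  the outcome means and their recovery are unbiased; comparisons of means
  are meaningful, absolute $F$ magnitudes are not.

## The statistics layer

* `welch_t_test()` — unpaired comparisons of one variable (unequal
  variances, Satterthwaite df), with explicit conventions when both groups
  are constant.
* `wilcoxon_signed_rank()` — paired HR-vs-NHEJ comparisons; zero
  differences are dropped, the p value is exact for ≤ 25 non-zero untied
  pairs and a continuity-corrected normal approximation otherwise.
* `factorial_anova()` — 1–3 crossed factors. Balanced designs use the
  conventional sequential decomposition; unbalanced designs (the assayed
  cohorts differ in size) use marginal Type-III sums of squares with
  sum-to-zero contrasts, and the choice is recorded in the output.
  Proportions are analysed untransformed. p values below $10^{-15}$ are
  labelled `"< 1e-15"`.
* `tukey_hsd()` — all pairwise comparisons via the studentized range
  (Tukey–Kramer for unequal group sizes), reporting the adjusted p, 95%
  family-wise CIs and the $q$ statistic recomputed from the fit's error
  mean square.

For pathway comparisons the package supports the complementary-rows design
(each sample contributes its HR and NHEJ relative percentages as two rows
of a `pathway` factor — this reproduces the error degrees of freedom of
grouped two-way analyses of such data) as well as a single-response design;
the complementary rows are statistically redundant (they sum to 100), so
single-response models are preferable when not matching an existing
analysis.

## A worked example

```{r example}
ref <- make_reference(seed = 1)
prof <- preset_profile("larval_brain_male")
co <- simulate_cohort(prof, n_samples = 6, seed = 42, ref = ref)

calls <- do.call(rbind, lapply(seq_along(co$pairs), function(i) {
  sp <- decompose(co$pairs[[i]]$control, co$pairs[[i]]$sample, ref)
  classify_spectrum(sp, sample_id = co$manifest$sample_id[i],
                    tissue = prof$tissue, sex = prof$sex)
}))
aggregate_group(calls, keys = c("tissue", "sex"))
```

```{r germline}
prog <- simulate_germline_cohort(p = c(0.33, 0.621, 0.049), n_vials = 20,
                                 mean_progeny = 89, seed = 7)
aggregate_germline(tally_progeny(prog))
```

## Problem sizes and numerical choices

The shipped tests decompose traces of ~600 bp with $K = 35$ (a 71-column
NNLS on a ~950-row stacked signal, a few tens of milliseconds each); oracle
equivalence against an exhaustive active-set enumeration is checked at
$K = 5$ on 50-position windows, where the $2^{11}$ subset enumeration is
tractable. Monte-Carlo checks use 500 germline replicates at the assayed
cohort size and 2000-replicate null calibrations for the tests. Weight
truncation at $10^{-9}$, the 0.8 registration floor and the 0.15 background
threshold are all config-exposed defaults.

## Limitations

* The decomposition assumes a single dominant break site and integer net
  shifts; it does not infer inserted base identity, model knock-in
  two-reference designs, or handle reverse-strand reads.
* Shift-0 weight conflates no cutting, precise NHEJ and intersister HR;
  the package reports it as "no DSB" without attempting to split them.
* SSA is invisible to the molecular readout; only the phenotypic module
  scores it, and SSA is itself indistinguishable from mitotic crossover
  there.
* The synthetic noise and NHEJ-spectrum models are idealisations (see
  above); conclusions about real traces require the QC screen and judgment
  about chromatogram quality.
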