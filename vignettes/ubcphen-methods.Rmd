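---
title: "Deriving bladder-cancer prognostic phenotypes from procedure codes and replicating candidate SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving bladder-cancer prognostic phenotypes from procedure codes and replicating candidate SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubcphen)
```

## The problem

Recurrence and progression of urinary bladder cancer (UBC) are not part of
routinely collected cancer-registry data. Hospital episode records, however,
carry dated OPCS4 procedure codes, and the clinical management of UBC is
stereotyped enough that tumour events can be inferred from the interventions
they trigger: a transurethral resection of a bladder tumour (TURBT, `M42`)
is performed *because* a tumour was found; a fresh course of intravesical
chemotherapy (`M494`/`M495`) after a long pause implies a new tumour; a
cystoscopic examination (`M45`) promptly followed by treatment implies the
examination found something. `ubcphen` implements this rule engine, derives
death and age outcomes from registry data, and runs a candidate-SNP
replication analysis (allele-dosage regression under an additive model,
sex-adjusted, with approximate Bayes factors and per-outcome Bonferroni
correction) over the derived phenotypes.

Because the cohort this design targets lives behind controlled access, the
package ships a synthetic-cohort generator with embedded ground truth. Every
stage of the pipeline is tested against that ground truth or against
brute-force oracles; nothing in the test suite requires any download.

## The event rules

Episodes are classified by OPCS4 code: 3-character map entries match any
4-character extension by prefix (`M421` is a TURBT), 4-character entries
match exactly (`M494` is intravesical chemotherapy; `M493` is not).
Candidate tumour events then arise from three rules:

1. **TURBT rule** — every TURBT episode is an event at its date.
2. **Instillation-gap rule** — within a patient's intravesical-chemotherapy
   sequence, a gap of more than `ivc_gap_days` (default 120, "longer than
   4 months") between consecutive instillations starts a new event, dated at
   the first instillation of the new block. The first block is treatment of
   the preceding event (or of the index tumour) and never spawns an event.
3. **Examination rule** — a bladder examination followed by intravesical
   chemotherapy, cystectomy, radiotherapy or systemic chemotherapy within
   `followup_window_days` (default 183, "within 6 months"; day 0 and the
   boundary day inclusive) is an event at the examination date. The
   direction is examination-then-intervention.

Candidate events closer than `independence_days` (default 91, ">3 months")
are registration duplicates: a greedy left-to-right pass keeps an event only
if it is more than 91 days after the previously *kept* one, retaining the
earliest date of each merged cluster. Same-day candidates from different
rules collapse to one event with priority TURBT > examination >
instillation-gap (a same-day resection is the more direct evidence).

Events within `baseline_window_days` (default 91) of the index diagnosis are
the primary-treatment block and are not recurrences; the recurrence count is
the number of independent events after that block. Progression is called
when a post-baseline TURBT- or examination-rule event is followed by
cystectomy or radiotherapy within the 6-month window — so every progression
is also a recurrence, an invariant the code asserts. Baseline invasiveness
(MIBC vs NMIBC) is separate: a cystectomy or radiotherapy within
`invasiveness_window_days` (default 183) of the index diagnosis marks the
cancer as muscle-invasive at presentation, which is radical *primary*
therapy, not progression — this is why the baseline block exists at all.

### Window arithmetic and boundaries

Month lengths are nowhere defined in routine data, so the package fixes
"4 months" = 120 days, "6 months" = 183 days and "3 months" = 91 days, all
configurable in `window_config()`. Comparisons are: instillation gap strictly
`> 120`; independence strictly `> 91`; look-forward windows inclusive of both
day 0 and the boundary day. These conventions make every boundary testable
to the day, and the test suite pins each one.

### Monotonicity is not what intuition says

One would expect growing `followup_window_days` to only add progressions and
growing `independence_days` to only remove recurrences. Neither holds once
the rules interact through deduplication. Two frozen counterexamples (in
`test-phenotyping.R`): events at days 0/80/130/230 yield *more*
post-baseline recurrences at gap 85 than at gap 60, because the greedy merge
re-anchors; and enlarging the follow-up window can convert an in-baseline
examination into an event that absorbs the post-baseline TURBT, *losing* a
progression. What does hold, and is property-tested, is that the total
number of kept independent events is non-increasing in the independence gap.
Users tuning windows should therefore compare whole configurations, not
reason one window at a time.

## Cohort selection and outcomes

Eligibility requires a bladder-cancer diagnosis code (ICD10 `C67.0`–`C67.9`,
`D09.0`, with bare `C67` accepted as unspecified-site; ICD9 `1880`, `1882`,
`1884`, `1886`, `1888`, `1889`, `2337`) and a urothelial-compatible ICD-O
histology (8000, 8001, 8010, 8020, 8050, 8120, 8130) on any record of the
same patient, plus (by default) a precomputed White-British ancestry flag.
The index diagnosis is the earliest code-matching record; all windows hang
off it. Death is overall (any death-registry record) or disease-specific
(primary cause `C67*`/`188*`); age at diagnosis is dichotomised at the
cut-offs 50/55/60/65/70 with the case group `age >= cutoff`.

## The statistics core

All estimators are implemented in the package (reference implementations
appear only as test oracles):

* **Dosage logistic regression** by iteratively reweighted least squares;
  Wald standard errors from the inverse observed information; quasi-separated
  or non-converged fits are flagged (`converged = FALSE`) and still reported
  with a warning — small MIBC subgroups with empty genotype cells are shown,
  not silently penalised or dropped. A constant adjustment covariate (sex in
  a single-sex subgroup) is dropped rather than allowed to break the fit.
* **Linear regression** (age as a continuous outcome) by OLS with t-based
  p-values.
* **Approximate Bayes factor** (alternative vs null) in Wakefield's closed
  form with prior sd `W = 0.2` on the log-odds scale — a 95% prior that the
  per-allele OR lies in about (0.68, 1.48). The original analyses used an
  unstated SNPTEST Bayesian model, so Bayes factors are comparable in
  spirit, not digit-for-digit; they are deliberately not acceptance-tested
  against printed values.
* **INFO score** from genotype-probability triples,
  `1 - sum(f_i - e_i^2) / (2N theta (1-theta))`, clamped into [0, 1]:
  posteriors more dispersed than the binomial reference cannot arise from a
  consistent imputation model, but can be constructed, so the clamp keeps
  the advertised range.
* **MAF** as `min(p, 1-p)` from (possibly fractional) genotype-count
  triples — this reproduces every printed whole-percent value checked, which
  settles that the published "MAF" columns are minor-allele, not
  effect-allele, frequencies.
* **LD r²** as squared Pearson correlation of dosages (the original used an
  external web tool; dosage correlation is the in-data equivalent).
* **Bonferroni thresholds** `alpha/m` with `m` taken from the loaded
  catalog's per-family sizes (69/53/20/23 with the shipped-style lists),
  never hard-coded.

A note on a worked identity: the per-allele logistic MLE on dosages does
*not* equal the 2×2 allele-table odds ratio in general (they differ in the
fourth decimal for the shipped worked example); expanding each subject into
two Bernoulli allele trials makes the equality exact, and that identity is
what the acceptance suite verifies at 1e-6.

## The synthetic cohort

`sim_config()` defaults state the cohort profile the pipeline targets:
1,500 patients, 78% male, age ~ N(61, 9²) years, 40.3% recurrence, 3.8%
progression, 7.4% MIBC at baseline, 13.6% deaths (6.9% disease-specific),
index dates uniform over 1997–2010 (the coverage window of admitted
in-patient episode data). Episode streams are written through the *inverse*
of the rules — a true recurrence at day *t* emits a TURBT (or a new
instillation block, or an examination plus systemic chemotherapy) at *t*;
a progression appends a cystectomy/radiotherapy 60 days after the final
event; MIBC emits radical therapy at day 30 — with spacings chosen so no
rule fires accidentally (events 250 ± 40 days apart, all gaps clear of the
91/120/183-day boundaries). Consequently phenotyping must recover the
ground-truth labels *exactly*, and the 50-seed round-trip test treats any
disagreement as a rule-engine defect. Genotypes use exact retrospective
tilting: control allele frequency `maf`, case allele frequency
`logit(maf) + log(OR)` on the logit scale, Hardy–Weinberg within group;
probability triples are Dirichlet perturbations concentrated on the true
genotype (`prob_noise` = 0 gives hard calls and INFO = 1), and the dosage is
always the triple's expectation. For age-linked variants the generator tilts
on the dichotomised age indicator (for `age_continuous`, on age above the
median) — adequate for pipeline testing, not a faithful quantitative-trait
model.

What the generator does **not** emulate: realistic code-frequency mixtures,
registration noise near window boundaries, informative censoring, linkage
disequilibrium between variants, imputation error correlated with frequency.
A green round-trip therefore establishes that the engine implements its
stated rules exactly — not that the rules recover true clinical events in
real registry data, where the original design itself expects undercounting.

## Degenerate inputs and numerical choices

IRLS starts at the empirical logit intercept, tolerance 1e-8 on the maximum
coefficient change, 25 iterations; weights floored at 1e-10; |beta| > 12
flags quasi-separation. Readers are total: malformed rows fail loudly with
row numbers, never silently dropped. Monomorphic variants, all-case
outcomes, constant dosages and empty-count MAFs raise errors; missing
dosages exclude a patient from that variant's test only. Strand-ambiguous
(A/T, C/G) variants are flagged, never auto-flipped; an allele swap between
catalog and file flips the sign of the reported effect.

## Known limitations

The rule engine sees only in-patient procedure codes: out-patient
surveillance and chemotherapy coded elsewhere are invisible, so derived
event rates underestimate truth by design. Tumour stage/grade are not
integrated. Time-to-event structure is deliberately out of scope — outcomes
are overall risk indicators. The per-outcome Bonferroni treats the two
survival labels as one family, matching the published accounting (53
survival tests), which slightly over-corrects if both labels are tested for
the same variant.
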