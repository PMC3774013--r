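---
title: "Methods and design notes for va2012"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for va2012}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(va2012)
```

This vignette records the scientific model behind each module, the
parameters that matter, and the design decisions taken where the standard
itself leaves the design open. It states no empirical result that the test
suite or the acceptance script does not itself compute.

## The standard as data

The 2012 WHO VA standard reduced the 2007 physician-oriented standard from
106 assignable causes to 62 cause categories (a 41.5% reduction; 60 causes
plus fresh and macerated stillbirth, added for their public-health
importance despite not strictly being causes of death) and from 408 to 221
CoD-related indicators (45.8%; 164 retained, 57 newly introduced, 244
excluded). The package ships this as four JSON artifacts under
`inst/extdata/` — cause list, indicator registry, subsumption map,
structural constants — validated on load and audited against each other by
`registry_consistency_report()`.

Two transcription decisions deserve note:

- **VA-99.** The cause table has 63 leaf rows: the 62 cause categories and
  a "cause of death unknown" row (VA-99, an explicit rule for ICD-10 R99
  and the fallback for indeterminate assignments). We keep all 63 rows and
  flag VA-99 with `is_cause = FALSE`, so cause counts report 62 while the
  R99 rule and the indeterminacy fallback still resolve.
- **Neonatal sepsis.** The printed certification code (P63) conflicts with
  the category's source range (P36, the ICD-10 bacterial sepsis of newborn
  block). We store the printed value verbatim with a note; mapping logic
  uses source ranges only, so behaviour is unaffected, and the round-trip
  audit lists this cause (with anaemia of pregnancy, whose certification
  code O99 is broader than its O99.0 source rule) as a documented
  exception.

### Indicator stubs

The published standard prints indicator *counts* — by age group, by skip
level, and in total — but not the 221 item texts or the gating topology
(those are distributed by WHO). The registry therefore ships stubs: stable
ids with short labels drawn from the symptom domains, arranged in a
topology whose counts reproduce every printed number. Distinct items per
skip level are 93/87/31/10; per-age-group CoD-related items are 130
(adult), 101 (child), 104 (neonate); each group adds 26 personal, 3
respondent and 10 context items (gate-free). The sharing structure across
age groups (e.g. 15 level-1 items common to all three groups, 10 level-4
items common to all) is one concrete solution of the printed marginal
counts; any other solution would serve, and the registry file is swappable
for the official item list without code change. A green count test
establishes that the *engine* honours the printed structure — not that the
stub items resemble real interview questions.

### The maternal block

The published maxima are 104 questions for a neonatal death and 130 for a
maternal death, and 130 equals the adult CoD-related total. We therefore
realize the maternal profile as the all-gates-open adult path, and model a
maternal block — one level-1 screening gate plus 12 gated descendants, all
adult-only — that a generic (non-maternal) adult interview skips, giving a
generic adult maximum of 118. The standard prints no generic-adult
maximum; 118 is a property of the packaged topology, not a published
constant. Record validation flags endorsed maternal items on male records.

## ICD-10 mapping precedence

The cause table's from-ICD column overlaps deliberately: residual
categories claim wide ranges (C60–D48 "other neoplasms", K40–K93 and
R00–R69 under "other NCD") from which specific causes carve out
sub-ranges (C60–C63, K70–K76, R10, D57). The table states no resolution
rule; only a *most-specific-wins* precedence reproduces the evident
intent, so the mapper orders candidate rules by:

1. code-set size (an exact subcoded rule such as O75.3 or O99.0 outranks
   any category range; a single category outranks a multi-category range);
2. residual status (`VAs-98`, `VA-99`, `*.99` lose ties to specific
   causes);
3. table order.

Consequences the tests pin down: O75.3 → pregnancy-related sepsis while
O75 → other maternal; A33 → neonatal tetanus (ICD-10 A33 *is* neonatal
tetanus, so no age input is needed) while A34–A35 → tetanus; P95 maps to
both stillbirth categories at equal precedence and is returned ambiguous.
Codes matched by no rule — notably the Z and U chapters, and gaps such as
A10–A14, O17–O19 or R70–R98 — return *unmapped* rather than VA-99:
coercing them would hide data errors, since VA-99 is an explicit rule for
R99 only. The whole mapper is checked against a brute-force oracle that
enumerates every rule's member codes over the full A00–Y98 universe.

## Skip logic

Applicability is the fixpoint of the gating relation: level-1 items of the
record's age group are always applicable; a level-k item is applicable iff
its parent is applicable and answered "yes". `dont_know` and missing
answers close a gate — the conservative interviewing convention (no
follow-ups to an unconfirmed screen). Personal, respondent and context
blocks are gate-free. Because levels are topologically ordered, one sweep
per level computes the fixpoint; the property tests verify idempotence and
monotonicity (adding a "yes" never removes applicability).

## Interpretation engines

**Bayesian (InterVA-style).** Given a conditional-probability matrix
`P(i|j)` and a prior over causes,
`posterior_j ∝ prior_j · Π_{i: yes} P(i|j)`, computed in log space, with
`× Π_{i: no} (1 − P(i|j))` added in `full_bernoulli` mode. The default
`positive_only` mode ignores "no" answers, matching the InterVA family's
documented behaviour; the full-Bernoulli mode is kept for synthetic
studies where negatives are informative. Matrix entries are floored into
`[1e-6, 1 − 1e-6]`: they are expert or synthetic estimates, and a literal
zero must not veto an entire posterior on one item. The indeterminacy
threshold `tau` (default 0, always assign) sends records whose top
posterior falls below it to VA-99. Exact ties break by cause-list order
and are recorded.

**Tariff.** Endorsement rates `x(i,j)` per cause are centred on their
across-cause median and scaled by the across-cause IQR (quantile type 7,
linear interpolation — stated because tariff values depend on it). A zero
IQR falls back to 1.4826·MAD; if that is also zero the row is
uninformative and carries zero tariffs. (With type-7 quantiles a zero IQR
forces a zero MAD in all but pathological cases, so the fallback chain
effectively ends in the zero row — the tests pin this.) Scoring is purely
additive over endorsed items. No probability values or tariffs shipped or
fitted here are claimed as WHO-endorsed; the standard aligns with such
engines but does not print their parameters.

## Evaluation metrics

The VA validation literature names its measures without printing formulas;
we adopt the standard definitions so results are comparable across
implementations: one-vs-rest sensitivity/specificity/PPV/NPV; Cohen's
kappa `(p_o − p_e)/(1 − p_e)` with marginal-product expectation; CSMF
accuracy `1 − Σ_j|pred_j − true_j| / (2(1 − min_j true_j))`; per-cause
chance-corrected concordance `(P(assigned=j|true=j) − 1/N)/(1 − 1/N)`
averaged over causes with at least one true death; Lin's concordance
correlation with population moments; trapezoid/midrank AUC. Degenerate
inputs (a never-assigned cause's PPV, a point-mass truth's CSMF accuracy)
return `NA` flagged `undefined`, never a silent zero. One convention is
ours to declare: the `min_j true_j` in CSMF accuracy runs over the cause
list *as given*, so appending a cause with `true = pred = 0` changes the
normalizer; the tests assert this behaviour explicitly.

## Synthetic cohorts

The generator emulates the generative assumption behind matrix-based
interpretation: a cause drawn from a known CSMF, then conditionally
independent Bernoulli endorsements `P(i|cause)`. Records are built level
by level so skip consistency holds by construction (items behind closed
gates are `not_applicable`), `dont_know` is injected at `missing_rate` on
answered non-gate items, and gates outside the matrix open with a
cause-independent probability (default 0.5) to keep the endorsement model
identifiable. Defaults chosen once: `missing_rate = 0.05` (a realistic
don't-know rate for symptom items), background endorsement 0.3 for
non-matrix items, all-adult age mix unless overridden (cause–age
independence keeps the model simple; the packaged-registry tests override
it with a 0.2/0.3/0.5 neonate/child/adult mix).

**Separability.** Each indicator gets a shared baseline rate
`base_i ~ U(0.1, 0.9)` and one random signature cause; with weight
`w = 1 − 1/separability` the matrix entry is
`(1−w)·base_i + w·s_ij`, `s_ij = 0.95` on the signature cause and 0.02
elsewhere. Separability 1 gives identical, cause-uninformative columns
(posterior = prior for every record, so average chance-corrected
concordance sits exactly at its chance level of 0); the infinite limit is
one near-1 entry per indicator. Column overlap is measured by the mean
pairwise Bhattacharyya coefficient and decreases monotonically in the
exponent (verified over 20 seeds).

**Reproducibility.** A root seed draws the cause/age assignments and a
vector of per-record substream seeds, so cohorts are reproducible record
by record.

**What a green recovery test establishes — and what it does not.** At
separability 5 with the true matrix, 10 causes, 60 indicators and n =
2000, the Bayesian engine recovers the cause distribution with CSMF
accuracy ≥ 0.9 at the frozen pilot seeds; stochastic thresholds are set
from pilot runs and frozen with their seeds, never tuned afterwards.
Recovery difficulty varies across seeds with the minimum number of
signature indicators a cause happens to receive under the random
allocation (a cause with only two signature items is intrinsically harder
to identify), so the acceptance script's value at other seeds scatters
around that level. None of this says anything about real-world accuracy:
real symptom data violate conditional independence, real matrices are
estimated rather than true, and the cohorts emulate no actual population's
epidemiology.

## Known limitations

- Indicator stubs carry no semantic content; engines that exploit item
  meaning (text, duration structure) cannot be studied with the packaged
  registry.
- The mapper implements the code syntax of the cause table only (letter +
  two digits + one optional decimal); full ICD-10 four-character
  subclassifications and clinical modifications are out of scope.
- The intended handling of Z- and U-chapter codes is not specified by the
  standard; we report them unmapped.
- Tariff ranking refinements used in production systems (significance
  filtering of tariffs, rank-based normalization against a training pool)
  are not implemented; the scorer is the plain additive form.
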