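# va2012

Verbal autopsy (VA) infers probable causes of death (CoD) from structured
interviews with caregivers or witnesses, for the large share of deaths in
low- and middle-income countries that are never medically certified. The
2012 WHO VA standard made that workflow feasible at civil-registration
scale: a simplified list of 62 cause categories onto which every ICD-10
cause code maps, and 221 CoD-related interview indicators organised in four
skip levels so that no interview asks more than 130 questions (adult
maternal death) or fewer than 104 (neonatal death).

`va2012` ships that standard as validated, machine-readable data and
implements the computation that makes it usable:

- **Standard registry** — the 62-category cause list with certification
  (to-ICD) and source (from-ICD) codes, the indicator registry with skip
  structure, the 27-entry 2007→2012 cause subsumption map, and a
  consistency audit that recomputes every published count
  (`load_cause_list()`, `load_indicator_registry()`,
  `registry_consistency_report()`).
- **ICD-10 mapping** — code/range algebra and precedence-resolved
  bidirectional mapping. Overlapping rules (specific causes carved out of
  residual ranges such as C60–D48 or R00–R69) resolve by
  *most-specific-wins*: exact subcode < single category < wider range,
  residual categories lose ties, remaining ties break by table order
  (`map_from_icd()`, `map_to_icd()`, `coverage_audit()`).
- **Questionnaire engine** — skip-pattern applicability as the fixpoint of
  the gating relation, record validation, and open-gate question-count
  maxima (`applicable_indicators()`, `validate_record()`,
  `max_question_count()`).
- **Interpretation** — automated, physician-free cause assignment: an
  InterVA-style Bayesian posterior
  `P(cause j | record) ∝ prior_j · Π_{i endorsed} P(i | j)`
  (optionally × Π over "no" answers of `1 − P(i|j)`), and a Tariff-style
  additive scorer with robust-scaled endorsement deviations
  `tariff(i,j) = (x_ij − median_j x_i·) / IQR_j x_i·`
  (`bayes_posterior()`, `fit_tariff()`, `assign_cause()`,
  `csmf_from_assignments()`).
- **Evaluation metrics** — the validity measures used across the VA
  validation literature: one-vs-rest sensitivity/specificity/PPV/NPV,
  Cohen's kappa, CSMF accuracy
  `1 − Σ|pred−true| / (2(1−min_j true_j))`, per-cause and average
  chance-corrected concordance `(P(correct|j) − 1/N)/(1 − 1/N)`, Lin's
  concordance correlation of CSMFs, and rank-based AUC.
- **Synthetic cohorts** — skip-consistent record generation from a known
  cause-specific mortality fraction (CSMF) vector and cause-conditional
  endorsement probabilities, with a separability dial and
  parameter-recovery experiments (`generate_matrix()`,
  `generate_cohort()`, `recovery_experiment()`).

## Worked example

```r
library(va2012)

cl <- load_cause_list()
cl
#> 2012 WHO VA cause list: 62 cause categories (+ 1 unknown-cause
#> pseudo-category), 104 mapping rules

# C61 (prostate cancer) sits in both C60-C63 and the residual C60-D48;
# the 4-category range wins on specificity
map_from_icd("C61", cl)
#> C61 -> VAs-02.06

# P95 belongs to both stillbirth categories: a deliberate ambiguity,
# fresh vs macerated is an interview distinction, not an ICD one
map_from_icd("P95", cl)
#> P95 -> VAs-11.01 | VAs-11.02 [ambiguous]

# certification code depends on clinical context
map_to_icd("VAs-09.04", "postpartum", cl)
#> "O72"

reg <- load_indicator_registry()
max_question_count("adult", "maternal", reg)   # 130
max_question_count("neonate", "generic", reg)  # 104

# parameter recovery on a synthetic cohort: 5 causes, 30 indicators,
# separability 4, 5% dont_know injection
causes <- sprintf("C%02d", 1:5)
m <- generate_matrix(causes, sprintf("i%02d", 1:30), separability = 4,
                     seed = 11)
cfg <- generator_config(800, setNames(rep(0.2, 5), causes), m,
                        missing_rate = 0.05, seed = 12)
recovery_experiment(cfg)
#> recovery: CSMF accuracy 0.980 | avg chance-corrected concordance 0.973 |
#> top-1 0.979
```

CSMF accuracy 0.98 means the estimated population cause distribution is
within 2% of the worst-case-normalized total variation of the truth; a
chance-corrected concordance of 0.97 means individual assignments are 97%
of the way from random (0) to perfect (1) agreement.

## Command line

The installed package ships an executable at `inst/cli/va2012`:

```sh
va2012 standard audit                       # consistency report, exit != 0 on violation
va2012 map --from-icd B22                   # -> VAs-01.03 HIV/AIDS related death
va2012 map --to-icd VAs-09.04 --context postpartum
va2012 map audit --universe A00-Y98
va2012 validate records.csv
va2012 interpret records.csv --engine bayes --matrix m.csv --out out.csv
```

## What the data files are

`inst/extdata/causes.json`, `subsumption.json` and `constants.json` are
transcriptions of the published 2012 standard. `indicators.json` ships
*indicator stubs*: stable ids with short domain labels whose per-age-group,
per-skip-level and distinct counts exactly reproduce the published pattern
(93/87/31/10 by level; 130/101/104 CoD-related items by age group). The
official WHO item texts are distributed by WHO, not reprinted here; the
registry file is data and can be swapped for them without code change.
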