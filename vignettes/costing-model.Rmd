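---
title: "The entocost costing model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The entocost costing model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entocost)
```

## The problem

National malaria control programmes process tens of thousands of
mosquitoes a year through laboratory pipelines that answer three
questions per specimen: which species is it, does it carry *Plasmodium*
sporozoites, and (for blood-fed females) what did it feed on. The
conventional pipeline answers these with PCR, CSP-ELISA and blood-meal
ELISA, escalating ambiguous results to Sanger sequencing or a repeat
confirmatory assay. MALDI-TOF MS protein profiling can answer all three
questions from one spectral acquisition. Whether switching saves money
and time is a budgeting question, and `entocost` is the calculator: a
deterministic decision-tree model of assay pipelines with per-sample
payoffs in four dimensions — bench time (minutes), materials (USD),
labour (USD) and their sum, direct cost.

## The decision-tree model

A workflow is a rooted tree (`chance_node()`, `terminal_node()`,
`branch()`). Branches carry probabilities; any node can carry assays
applied to every sample that reaches it. The model is an expected-value
(cohort) evaluation, not a per-individual simulation: a cohort of $n$
samples sends $n\prod_j p_j$ *fractional* samples down each terminal
path, and each payoff dimension accumulates

$$\mathrm{total}_d \;=\; \sum_{\text{paths }k} n\,P_k
  \sum_{a \in \text{assays}(k)} \pi_{a,d},$$

where $\pi_{a,d}$ is assay $a$'s per-sample payoff in dimension $d$.
Fractional expected counts are deliberate — they are what makes the
totals exact rational multiples of the unit payoffs — and counts are
never rounded. Direct cost is defined as materials + labour and is
computed from the accumulated totals, so additivity holds to machine
precision.

Probabilities at a chance node must sum to 1 within $10^{-9}$;
`validate_tree()` reports violations as diagnostics and the package
refuses to renormalize silently, because a probability mismatch in a
config is almost always a transcription error the user should see.

### Dimension masks

Each assay occurrence carries a *dimension mask* (`assay_use(id, dims)`),
defaulting to all dimensions. The mask exists because cost and time do
not always travel together: in the bundled proposed workflow the
confirmatory repeat heated CSP-ELISA on quality-assurance positives
consumes reagents and technician minutes but adds no elapsed
time-to-results, since it runs on the already-prepared lysate alongside
the QA plate. Its occurrence is therefore masked to
`{materials, labour}`. This single mechanism reconciles the time and
cost tables of the case study simultaneously; without it one of the two
would be off (time by 318.375 min, or labour by 9 USD, at the default
parameters).

## Micro-costing conventions

Per-sample payoffs can be supplied directly (`assay_profile()`) or built
from primitives:

* **Materials** (`per_sample_material_cost()`): sum of
  `unit_price × quantity_per_batch` over an item table, divided by the
  plate size — 90 samples/plate for PCR, ELISA and sequencing, 47 for
  MALDI target plates. Costs are USD throughout; no currency-conversion
  layer exists.
* **Time** (`per_sample_time()`): total per-plate assay time divided by
  the same plate size. MALDI plate-cleaning time is treated as part of
  the per-plate total.
* **Adjusted time** (`adjusted_time()`): labour is priced on hands-on
  time only, excluding incubation steps *strictly* longer than 60
  minutes (a 60-minute incubation is retained — the rule is a literal
  "above 60"), on the assumption that staff do other work during long
  incubations.
* **Labour** (`labour_cost()`): a per-minute rate times adjusted time.
  `labour_rate()` derives the rate as
  `annual_salary / (weeks_per_year × hours_per_week × 60)`; for the
  bundled case-study salary of 6,289.82 USD/yr at 40 h/wk this gives
  0.0504 USD/min.

The bundled profiles (`reference_profiles()`) are the *measured*
per-sample values of the case study, shipped as data rather than
recomputed, because the measured labour costs are not all consistent
with any single per-minute rate (implied per-assay rates vary several
fold, as is common when different assays are staffed differently). The
recomputation path exists for users bringing their own item tables and
timings; the shipped profiles take precedence for the reference
scenario.

## The bundled workflows and their parameters

`workflow_params()` holds the scenario knobs, all validated:

| parameter | default | meaning |
|---|---|---|
| `p_bloodfed` | 0.20 | blood-fed fraction of the collection |
| `p_unsat` | 0.10 | unsatisfactory primary results (PCR/ELISA and MALDI alike) |
| `p_positive` | 0.05 | CSP-ELISA positives needing confirmation |
| `cohort_size` | 15,000 | annual samples |
| `include_parity_dissection` | FALSE | add per-sample parity-dissection payoffs to the current workflow |
| `qa_include_pcr` | FALSE | charge a separate PCR in the proposed QA path |

Three builders produce the trees. **Current**: every sample gets
species-ID PCR and CSP-ELISA; `p_unsat` adds Sanger sequencing;
`p_positive` adds the repeat heated CSP-ELISA; `p_bloodfed` adds a
blood-meal ELISA, whose undetected results are not pursued further.
**Proposed**: every sample gets one MALDI head/thorax acquisition;
the unsatisfactory fraction gets Sanger sequencing plus a QA CSP-ELISA
(and, within it, the masked confirmatory repeat on positives); blood-fed
samples get a MALDI blood-meal acquisition, escalating to blood-meal
ELISA for the unsatisfactory fraction of those. **Ideal**: MALDI only,
no supplementary assays.

Two deliberate modelling choices in the proposed tree:

1. **No separate QA PCR by default.** The QA path's sequencing payoff
   (23.23 USD, 15.958 min) is treated as inclusive of amplification;
   charging PCR on top would double-count sample preparation and
   overshoots every reference total. Users who cost PCR separately can
   set `qa_include_pcr = TRUE`.
2. **Parity dissection as parameters.** The current workflow's
   all-endpoints variant adds a parity-dissection payoff to every
   sample. Its defaults (0.012 USD materials, 0.104 USD labour, 0 min)
   are back-computed by subtracting the three-endpoint totals from the
   all-endpoints totals over 15,000 samples; they are a reconciliation,
   not a measurement, and should be replaced by users who have dissection
   cost data.

## Reporting conventions

`compare_workflows()` differences two evaluations of equal cohort size;
percentage savings are always computed from full-precision totals, never
from rounded displays. `render_tables()` rounds half-even — 2 decimals
for USD, 4 for per-sample minutes — only at rendering, and its CSV
output is byte-stable. `minutes_to_display()` converts minutes to exact
hours and to *calendar* days rounded up (`ceiling(min/1440)`); the
ceiling-calendar rule is the only convention that reproduces all four
published day figures of the case study (99, 47, 26, 74), whereas an
8-hour working-day conversion reproduces none.

## Sensitivity analysis

The reference model is deterministic. The sensitivity module is the
package's stochastic extension of it, following standard
decision-modelling practice:

* `one_way_sweep()` re-evaluates the comparison over a grid on one
  parameter, everything else held at base values. Because every payoff
  enters the totals affinely, savings along an evenly spaced grid on a
  unit cost are evenly spaced — a property the tests exploit as a
  finite-difference check.
* `probabilistic_sa()` draws jointly independent parameter sets — beta
  distributions for probabilities, gamma for costs and times, point
  masses for fixed values — evaluates the deterministic model at each
  draw, and summarises savings (mean, SD, 2.5/97.5 percentiles,
  probability of positive saving). A single integer seed makes runs
  bit-reproducible, and the caller's RNG state is saved and restored.
  Correlated parameter draws are out of scope; correlation between
  *branch* events can instead be expressed structurally by explicit
  nesting in the tree.

## The synthetic-data generators and what tests show

`random_cost_table()`, `random_profiles()` and `random_tree()` generate
valid inputs (uniform prices/quantities/times within configured ranges,
normalized branch probabilities, bounded depth) so that engine
invariants can be property-tested on structures no fixture anticipated.
`simulate_cohort()` routes an integer cohort through the tree by
multinomial splitting at every chance node — equivalent in law to
independent per-sample categorical draws — and is the package's
independent stochastic oracle: by the law of large numbers its replicate
mean must converge to `evaluate_cohort()`'s expectation.

Test tolerances for stochastic checks are 4 Monte-Carlo standard errors,
keeping the suite's false-failure rate well under 1%; replicate counts
(1,000 for random-tree agreement at cohort 200, 5,000 for the reference
workflow at cohort 15,000, 2,000 PSA draws) were chosen so the standard
error is a small fraction of the checked quantity while the whole suite
runs in about a minute.

What the generators deliberately do **not** emulate: mosquito biology,
assay error processes, batching and queueing effects, price correlation
across reagents, or calendar scheduling. Passing tests therefore show
that the *arithmetic* of expected-value costing is right and that the
bundled trees encode the stated pipelines — not that the cost estimates
generalise to a differently organised laboratory.

## Numerical choices and degenerate inputs

* All arithmetic is double precision end to end; displays round
  half-even.
* `cohort_size = 0` evaluates to all-zero totals; per-sample averages on
  an empty cohort raise a division error rather than returning NaN.
* Empty item tables cost 0; a zero or missing plate size is an
  invalid-batch error, not an Inf.
* Config files serialize currency as decimal strings, so fixtures stay
  free of binary-float drift; probabilities written by `write_config()`
  may differ from their source by one ulp after parsing, which is why
  round-trip equality is checked numerically rather than bitwise.
* Probability tolerance at chance nodes is absolute $10^{-9}$.

## Known limitations

* Capital, start-up and maintenance costs are excluded by design; the
  comparison assumes instruments are already available.
* The deterministic cohort model has no variance on its own — uncertainty
  statements require the PSA module, whose distribution families are an
  analyst choice, not an estimate from data.
* The bundled labour payoffs are measured values that cannot be
  regenerated from a single salary figure; cross-laboratory transfer of
  the labour dimension requires re-timing the assays.
* Time totals are bench-time sums, not makespans: the model ignores
  parallelism between plates, so "calendar days" figures are workload
  equivalents, not turnaround predictions.
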