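---
title: "Modelling methods: decision-tree cost-effectiveness of preservative-free glaucoma therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling methods: decision-tree cost-effectiveness of preservative-free glaucoma therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poagcea)
```

## The decision problem

Topical glaucoma therapy preserved with benzalkonium chloride and related
agents is ocular-surface toxic; in eyes that have already developed
dry-eye disease the prescriber chooses between preservative-free
formulations (roughly double the pack price) and preservative-containing
ones. `poagcea` models this as a two-strategy decision analysis over a
1-year horizon from the combined payer + patient perspective, with the
affected **eye** as the unit of analysis. `patient_id` is provenance
only; the two eyes of one patient are treated as statistically
independent, because the modelled cohort reports per-eye tallies without
within-patient pairing (a known simplification, revisited under
Limitations).

## Outcomes and disease control

Effectiveness is dichotomised disease control on three tear-film tests:
Schirmer test (ST, mm; aqueous phase), total meiboscore (TMS, 0–6 summed
over both eyelids; meibomian-gland morphology) and non-invasive tear
break-up time (NIBUT, s; lipid-phase function). Defaults in
`control_thresholds()`:

| test | good control | default threshold |
|------|--------------|-------------------|
| ST | above threshold | 10 mm |
| TMS | **below** threshold | 3 |
| NIBUT | above threshold | 14 s |

Two conventions needed a decision:

* **TMS direction.** Clinical sources describing this scale are not
  uniformly worded; we classify *low* meiboscores as good control (low
  gland loss is the healthy state), which is also the direction implied
  by the reported control tallies (23/64 good at scores below 3).
* **Boundary values.** A value exactly on a threshold (ST = 10, TMS = 3,
  NIBUT = 14) is classified **poor**: the clinical definitions say only
  "above"/"below", so we take the conservative strict-inequality reading.
  `control_thresholds(boundary = "good")` switches to inclusive
  comparisons; nothing downstream depends on the choice except the
  classification itself.

Overall therapeutic success requires good control on *all three* tests
(`overall_good` is the conjunction).

## Costing

Yearly cost of a therapy line is `doses_per_day x year_days /
doses_per_pack x pack_price`, rounded to 0.01 BGN. Notable choices:

* **365-day year**, no leap handling.
* **Continuous proration** of partial packs by default, matching the
  multiplicative formula; `dispensing = "whole_packs"` charges every
  started pack, which is how real dispensing behaves. The default keeps
  costs exactly homogeneous of degree 1 in pack prices (a tested
  invariant).
* **Pack sizes are inputs.** Public price registers list pack prices, not
  drops per bottle, so the price-list schema requires `doses_per_pack`
  explicitly. The bundled `example_price_list()` documents its pack sizes
  as illustrative fixtures; only the two latanoprost pack prices
  (23.5 / 50.4 BGN) are register values.
* **Payment split.** The payer reimburses a configurable share
  (default 0.5) of glaucoma cost; artificial-tears (dry-eye) cost is
  never reimbursed. Monetary rounding uses largest-remainder
  reconciliation in integer cents so `reimbursed + copay` always equals
  the rounded total exactly; a half-cent tie goes to the reimbursed
  share.
* All computation is in BGN; the 1 BGN = €0.51 conversion is display
  only.

Cost summaries report medians (midpoint mean for even samples) and n−1
standard deviations per preservative arm; an empty arm is reported absent
(`NA`), never as zero.

## The decision tree and its roll-back

The tree has two strategy branches (preservative-free, preservative
non-free); within each, a chance level for mono vs combination therapy,
then a level for the therapeutic class (monotherapy) or combination
composition. Probabilities are plain maximum-likelihood proportions
`n(A)/n` with **no smoothing**: a stratum with zero eyes simply never
appears, so sibling probabilities sum to one by construction and no
continuity correction is introduced.

Terminal payoffs from a cohort: the **arithmetic mean** of member eyes'
total yearly cost (glaucoma + dry-eye) and the good-control
**proportion** on the chosen measure. Mean (not median) cost is
deliberate: it makes the rolled-back expected cost equal the
cohort-weighted average cost exactly, which is the property the tests
check. With proportions as effects, the expected effect unit is
"probability of a controlled eye", so ICERs read as BGN per additional
controlled eye-year. When reproducing published strategy-level tables
whose effect unit is not re-derivable from leaf data, printed
per-strategy values and printed deltas are taken as direct inputs instead
(`reference_strategy_values()`, `reference_deltas()`,
`ce_compare(..., deltas = )`); the two modes are kept strictly separate.

`rollback()` computes expected values by leaf-to-root recursion;
`path_enumeration_oracle()` recomputes them by exhaustively enumerating
root-to-leaf paths. The two are independent implementations and agree to
1e-9 on randomised trees (a property-based test over 200 trees of depth
up to 4). Chance-node probability sums are validated to 1e-9.

## ICER, dominance and verdicts

Deltas are comparator minus reference, with preservative non-free
(current practice) as reference. The ICER is undefined when the effect
delta is zero (reported absent, verdict `not_applicable`, no division).
Quadrants follow the signs: NE (costlier, more effective — ICER is a
price), SE (dominant), NW (dominated), SW (cheaper, less effective). A
negative ICER is therefore always reported *with its quadrant*: the same
number means opposite things in SE and NW.

The WHO GDP-multiple verdict (default GDP per capita 15,226 BGN) grades
NE ICERs: `< 1x` GDP highly cost-effective, up to and including `3x` GDP
cost-effective (the upper bound is closed — an ICER exactly at 3x GDP
passes), above that not cost-effective. For SW comparisons, which the
modelled data never produce, we apply the threshold to the reversed
comparison: accepting the cheaper, less effective strategy is judged
acceptable iff the savings per unit of effect forgone exceed 3x GDP.

One published inconsistency is left unreproduced by design: the source
table's NIBUT ICER cell does not equal its own printed deltas
(59.29 / 0.52 = 114.02, not 93.48), and the corresponding abstract values
(744, 131) match neither. We compute ratios from printed deltas and make
none of those three numbers a target.

## One-way deterministic sensitivity analysis

`one_way_dsa()` re-evaluates the ICER with one parameter at
`base x (1 ± 0.30)` and all others at base, never mutating the input tree
(verified by a serialisation snapshot test). Parameters are addressed by
path (`strategy/.../leaf@cost`); the default tornado set is **all leaf
costs and effects, probabilities excluded** — the published analysis
varied "cost and effect" only — but `@prob` parameters are supported: a
perturbed branch probability is clamped to [0, 1] and its siblings
rescaled proportionally so the node still sums to one. Tornado entries
are sorted by descending width, ties broken by parameter id.
`sign_flip_scan()` walks a grid (default 61 points, 1 % steps over
±30 %) in order of increasing magnitude and reports the smallest
perturbation whose ICER sign differs from base; grid points with an
undefined ICER are skipped with a warning.

## The synthetic cohort generator

`generate_cohort()` exists because the modelled study deposits no
accession — its data live only in printed tables — so the pipeline needs
a statistically faithful stand-in. Defaults (`default_config()`) are the
published study conditions: 64 eyes; P(preservative-free) = 20/64;
P(mono | free) = 14/20 and P(mono | non-free) = 20/44; monotherapy class
weights 25:9:0:0 (CAI and A2A monotherapy weights are zero exactly as
observed); combination weights 6:8:5:2:9; marginal good-control
probabilities 15/64, 23/64, 2/64; demographic weights 25:39 (sex),
10:28:21:5 (age bands), 30:34 (side), 27:27:10 (duration). Every eye
receives artificial tears, as observed.

* **Measurements** are drawn uniformly from config-exposed intervals
  strictly on the sampled side of each threshold (e.g. ST good →
  U(10.5, 20), poor → U(0, 9.5)), because only dichotomised counts are
  published. Classification therefore reproduces the sampled flags
  exactly — a tested invariant.
* **Costs** are log-normal: yearly therapy costs are positive and
  right-skewed (the combination tail). Given target median m and SD s,
  `mu = log(m)` and `sigma^2 = log(x)` with
  `x = (1 + sqrt(1 + 4 s^2/m^2))/2`, the exact closed-form root of the
  log-normal variance equation — no numeric solver. Arm targets:
  median 320.97 / SD 133.18 BGN (free), 322.14 / 203.76 (non-free),
  179.93 / 9.36 (artificial tears).
* **Prices follow draws.** Because each eye's yearly cost is drawn, the
  generator emits the per-line synthetic price list that reproduces those
  draws through the costing module (equal split across an eye's glaucoma
  lines, 100-dose packs); the cohort and price list are returned
  together as a `ce_study`.
* The three tests are sampled **independently** (only marginals are
  published); per-arm control probabilities are supported via the list
  form of `control_probs`. Within-patient eye pairing and any
  test-to-test correlation are *not* emulated, so passing tests show the
  pipeline's arithmetic is right under the published marginal structure —
  not that real ocular-surface data behave this way.
* Generation is deterministic given `seed` (default 2019, an arbitrary
  fixed value) and restores the caller's RNG state.

## Numerical and testing choices

* Money is rounded to 0.01 BGN at line level and reconciled at split
  level; probabilities validated to 1e-9; roll-back vs oracle compared at
  1e-9.
* Percentages in summaries are reported both as raw fractions and
  one-decimal roundings; published tables that disagree with their own
  arithmetic (a 55 %/45 % print for a 53.1 %/46.9 % split) are *not*
  replicated — exact values win.
* Test problem sizes: property tests use 50–200 random trees (depth ≤ 4);
  generator-recovery tests use 20,000 eyes in the routine suite and
  100,000 in the end-to-end checks, where binomial standard errors
  (~0.001–0.003) make the ±0.01 and 4-SE bands meaningful; cost-median
  recovery is checked within 5 %.
* The fixture `reference_cohort()` matches all published *marginal*
  tallies deterministically; its joint assignments (which eyes are good
  on which test, arm-by-composition fill) are arbitrary, so only marginal
  quantities should ever be asserted against it.

## Known limitations

No intraocular-pressure modelling (IOP was not an outcome here); no
QALYs or indirect costs; no discounting (1-year horizon); no
Markov/state-transition extension and no probabilistic sensitivity
analysis — the deterministic ±30 % design is the implemented scope.
Dry-eye *incidence* under preservative exposure is not modelled, only
control of established disease; extending the tree with incidence
probabilities is the natural next step.
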