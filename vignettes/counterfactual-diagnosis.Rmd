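---
title: "Counterfactual diagnosis on noisy-OR disease networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual diagnosis on noisy-OR disease networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfdiag)
```

## The model

`cfdiag` works on three-layer Bayesian networks over binary nodes: risk
factors $R_i$ (demographics, exposures, history), diseases $D_j$ and
symptoms $S_k$, with edges only $R \to D$ and $D \to S$. Every disease and
symptom follows a noisy-OR mechanism: each parent that is on tries to
activate the child and fails independently with probability
$\lambda_{\text{parent},\text{child}}$, and an always-on *leak* parent —
standing for all causes outside the model — fails with probability
$\lambda_0$ (the `leak_failure`). A child is off exactly when every
attempt fails, so

$$P(S = 0 \mid \mathbf{d}) \;=\; \lambda_{0,S} \prod_{j:\, d_j = 1} \lambda_{D_j,S}.$$

Read as a structural causal model, every edge and every leak carries an
explicit binary exogenous failure variable $u$ with $P(u = 1) = \lambda$
($u = 1$ means the activation fails). Given a complete exogenous state the
network is deterministic (`structural_eval()`), which is what gives
interventions and counterfactuals a precise meaning: `do(X = x)` severs
$X$'s mechanism and forces its value, and a counterfactual query holds the
exogenous state fixed between the factual and hypothetical worlds.

Two modelling choices deserve note. First, disease-layer CPTs are
noisy-OR over risk-factor parents with a leak encoding baseline
prevalence; a disease with no risk parents is parameterised purely by its
leak, prevalence $1 - \lambda_0$. This subsumes a bare prior and keeps one
CPT family throughout; other dependence structures are an extension point,
not supported here. Second, the leak is modelled as an explicit always-on
parent of the SCM rather than folded into the noise, so that the
sufficiency measure's intervention can switch it off (targets of the form
`"leak:<child>"`).

## Associative and counterfactual scores

The associative benchmark is the exact posterior $P(D = 1 \mid \mathcal{E})$
(`posterior_disease()`), where evidence $\mathcal{E}$ comprises observed
risk factors $\mathcal{R}$, present symptoms $\mathcal{S}_+$ and absent
symptoms $\mathcal{S}_-$. Unobserved symptoms are marginalised, never
treated as absent: clinical vignettes list a non-exhaustive subset of what
is true of the patient, and coding silence as absence would bias every
query. Partial risk evidence is marginalised under the risk priors.

The counterfactual scores ask a causal question instead:

* **expected disablement** — how many present symptoms would switch off,
  in expectation, under $do(D = 0)$ ("cure the disease");
* **expected sufficiency** — how many present symptoms would persist under
  $do(\mathsf{Pa}(\mathcal{S}_+) \setminus D = 0)$, switching off every
  *other* direct cause of the present symptoms, their leak parents
  included.

Both expectations count only the factually present symptoms: a symptom
that was absent or unobserved but activates in the hypothetical world is
not part of the patient's presentation and is not counted. In the
sufficiency intervention only the present symptoms' mechanisms are
touched; negative-evidence symptoms keep their mechanisms and are
re-evaluated in the counterfactual world. These two conventions are the
package's resolution of genuinely open design points; both are validated
by the closed form below, which is the ground truth the defining
expectations must reproduce.

## Three computation routes

The same quantity is computed by three independent routes, which is the
package's main correctness instrument:

1. **Closed form** (`method = "closed_form"`, the default). For
   three-layer noisy-OR networks both measures equal
   $$\frac{\sum_{\mathcal{Z} \subseteq \mathcal{S}_+} (-1)^{|\mathcal{Z}|}
   \, P(\mathcal{S}_- = 0, \mathcal{Z} = 0, D = 1 \mid \mathcal{R}) \,
   \tau(D, \mathcal{Z})}{P(\mathcal{S}_\pm \mid \mathcal{R})},$$
   with $\tau = \sum_{S \in \mathcal{S}_+ \setminus \mathcal{Z}}
   (1 - \lambda_{D,S})$ for sufficiency and
   $\tau = \sum_{S \in \mathcal{Z}} (1 - 1/\lambda_{D,S})$ for
   disablement. The all-off joints factorise over diseases given the risk
   layer (`negated_subset_likelihood()`), so each term is cheap; the
   subset sum is exponential in $|\mathcal{S}_+|$ and is capped at 16
   present symptoms with a clear error.
2. **Twin network** (`"twin_def"`). The defining expectation, evaluated by
   exact inference on the twin network: factual and counterfactual copies
   of each affected node share their exogenous noise, the engine
   enumerates risk and disease configurations, and the symptom layer is
   handled analytically through two-world joints such as
   $P(S = 0, S' = 0) = \prod_{\text{attempts active in either world}}
   \lambda$ (shared noise counted once). No inclusion–exclusion, no noise
   enumeration.
3. **Abduction–action–prediction** (`"abduction"`). The textbook recipe,
   exhaustively: enumerate all exogenous states, condition on the factual
   evidence, apply the intervention, re-evaluate, average. Exponential in
   the number of noise terms (refused above $2^{22}$ states), and kept
   deliberately naive so it is an independent oracle for the other two.

On 200 random networks the three routes agree to about $10^{-14}$
(tolerance asserted: $10^{-9}$); the worked single-link example
(prevalence 0.2, $\lambda = 0.4$, leak failure 0.9, $S$ present) gives
posterior $0.128/0.208$, sufficiency $0.120/0.208$ and disablement
$0.108/0.208$ on all routes, matching hand algebra.

### Numerical choices

A $\lambda_{D,S} = 0$ edge (deterministic activation) makes $1/\lambda$
infinite in the disablement $\tau$, but the joint it multiplies contains
the event $\{S = 0, D = 1\}$ and hence the matching factor $\lambda$. The
implementation divides that factor out analytically inside the joint
(`drop_lambda_child` in the all-off primitive), so the $0 \cdot \infty$
limit evaluates exactly; agreement with the twin route at $\lambda = 0$
and $\lambda = 10^{-6}$ is asserted in the tests. Probabilities are
clamped to $[0, 1]$ only at the public boundary (guarding against
$10^{-16}$-scale inclusion–exclusion residue); intermediate sums are never
clamped. Zero-probability evidence raises a typed condition
(`cfdiag_domain_error`) rather than returning `NaN`, so cohort evaluation
can catch, report and skip the offending vignette.

## Rankings and evaluation metrics

`rank_diseases()` returns a full ranking of all modelled diseases under
one measure. Ties are broken by higher posterior, then lexicographic id —
the delivered order is therefore deterministic. Because the tie policy
inside mean-rank statistics is a genuine free choice, each entry carries
two positions: the tie-broken order position (used by top-$k$ and
matched-$k$ accuracy) and the tie-min position, where equal scores share
the best place (used for mean ranks and win/draw/loss counts). Cohort
summaries record this in `tie_note`.

`evaluate_cohort()` computes per-measure top-$k$ accuracy curves, mean
ranks, win/draw/loss counts against the posterior, the relative error
reduction $1 - e_c/e_a$, rarity strata and matched differential-size
accuracy (each vignette scored at its own $k$, mirroring clinicians who
size a differential to their uncertainty). Rarity bands cut on the
patient-specific prior $P(D = 1 \mid \mathcal{R})$; the default edges
$(10^{-4}, 10^{-3}, 10^{-2}, 0.05, 0.2)$ are conventional configuration
values, labelled as such in the output, not published thresholds.

## The synthetic-data generator

Everything is testable offline because the package generates its own study
material. `generate_network()` draws layered DAGs with configurable
densities and uniform parameter ranges; `generate_vignette()` simulates a
patient by choosing a true disease (among diseases with symptom children),
forcing it on (an intervention, not rejection on $D = 1$ — cheaper and
faithful to "simulate a typical presentation of this disease"), sampling
the exogenous state, rejecting worlds where no child symptom of the true
disease is present (cap $10^4$), and then revealing a non-exhaustive
evidence subset.

Defaults, chosen once as a plausible small-clinic regime and not tuned:
risk priors $U(0.05, 0.5)$; edge failures $U(0.1, 0.9)$; disease leak
failures $U(0.7, 0.99)$ (baseline prevalence 1–30%); symptom leak failures
$U(0.85, 0.99)$ (symptoms rarely appear without a modelled cause); reveal
probabilities 0.9 for present symptoms, 0.3 for absent symptoms, 0.75 for
risk factors; differential sizes $k \sim 1 + \mathrm{Poisson}(1.58)$, mean
2.58. One present child symptom of the true disease is always revealed so
every vignette carries positive evidence, as the vignette contract
requires. Reveal probabilities are honest free parameters of the
simulator — real case-writing behaviour is unknown and not estimated.

What the generator emulates is the generative *structure* of diagnostic
case material: a layered causal world, disease-conditioned presentations,
partial observation. What it does not emulate: realistic medical
ontologies, correlated reveal behaviour, free-text case notes,
doctor-authored differential sizes, or a professionally parameterised
disease model with hundreds of nodes. Green tests therefore certify the
inference machinery and the metric pipeline, not clinical performance;
headline accuracies on real vignette sets are outside what this package
can reproduce.

## Problem sizes

The verification suite fixes sizes where all three routes stay exact and
fast: agreement sweeps use networks of 2 risk factors, 3 diseases and 2–3
symptoms at density 0.4–0.5 (keeping the exogenous space enumerable for
the abduction oracle) with up to 3 present symptoms; inference is checked
against full-joint enumeration on 200 such networks; the evaluation
pipeline runs on a 500-vignette cohort over a 3/5/6 network. The exact
inference contract targets models up to roughly 20 diseases relevant to a
query; quickscore-style factorisation keeps the cost linear in diseases
but exponential in $|\mathcal{S}_+|$ and in unobserved risk parents.

## Known limitations

* Binary nodes and noisy-OR CPTs only; no multi-valued states, no other
  CPT families, no learning of parameters from data.
* Exact inference only — no variational or sampling approximations — so
  very large positive-evidence sets or risk layers are refused rather than
  approximated.
* The two implemented measures are the only ones; probabilities of
  necessity/sufficiency and related attribution indices are not provided.
* Expected disablement and expected sufficiency often order diseases
  similarly in practice, but no such property is asserted or relied on;
  the package treats them as distinct measures throughout.
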