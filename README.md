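# cfdiag — counterfactual diagnosis over noisy-OR disease networks

Model-based diagnostic systems traditionally rank candidate diseases by
their posterior probability given the patient's findings,
*P(D = 1 | ℰ)*. That associative ranking confuses correlation with
causation: a disease can be strongly correlated with a symptom through a
shared risk factor while being unable to have *caused* it, and such a
disease is not a reasonable diagnosis. `cfdiag` implements diagnosis as a
counterfactual inference task on three-layer noisy-OR Bayesian networks
(risk factors → diseases → symptoms) read as structural causal models, and
is aimed at researchers studying causal inference in diagnostic decision
support.

## The measures

For evidence ℰ with positively evidenced symptoms 𝒮₊, two scores quantify
how well a candidate disease *D* explains the present symptoms:

* **Expected disablement** — the expected number of present symptoms that
  would switch off had we intervened to cure the disease:
  𝔼_dis(D, ℰ) = Σ_{𝒮′} |𝒮₊ \ 𝒮₊′| · P(𝒮′ | ℰ, do(D = 0)).
* **Expected sufficiency** — the expected number of present symptoms that
  would persist had we switched off every *other* possible cause (all other
  disease parents of 𝒮₊ and their leak terms):
  𝔼_suff(D, ℰ) = Σ_{𝒮′} |𝒮₊′| · P(𝒮′ | ℰ, do(Pa(𝒮₊) \ D = 0)).

For three-layer noisy-OR networks both have an exact closed form,

    Σ_{𝒵 ⊆ 𝒮₊} (−1)^|𝒵| P(𝒮₋ = 0, 𝒵 = 0, D = 1 | ℛ) · τ(D, 𝒵)  /  P(𝒮± | ℛ),

with τ(D, 𝒵) = Σ_{S ∈ 𝒮₊∖𝒵} (1 − λ_{D,S}) for sufficiency and
τ(D, 𝒵) = Σ_{S ∈ 𝒵} (1 − 1/λ_{D,S}) for disablement, where λ_{D,S} is the
noisy-OR failure probability of the D → S activation. The package computes
the measures three independent ways — the closed form, exact inference on
the twin network (factual and counterfactual worlds sharing exogenous
noise), and abduction–action–prediction by exhaustive noise enumeration —
and the routes agree to ~1e-14 on test-sized networks.

Both measures satisfy three diagnostic desiderata the posterior violates:
they are bounded by |𝒮₊| · P(D = 1 | ℰ) (consistency), they are exactly
zero for a disease with no causal path to any present symptom (causality),
and they prefer diseases that explain more of the presentation
(simplicity).

## Worked example

The smallest interesting network: one disease with prevalence 0.2, one
symptom with activation failure λ = 0.4 and leak failure 0.9.

```r
library(cfdiag)

net <- single_link_network(prior = 0.2, lambda = 0.4, leak = 0.9)
ev  <- evidence(positive = "S")

evidence_likelihood(net, ev)        # 0.208      = 1 - 0.9 (1 - 0.2 * 0.6)
posterior_disease(net, ev, "D")     # 0.6153846  = 0.128 / 0.208
expected_sufficiency(net, ev, "D")  # 0.5769231  = 0.120 / 0.208
expected_disablement(net, ev, "D")  # 0.5192308  = 0.108 / 0.208

counterfactual_probability(net,
  counterfactual_query(ev, c(D = 0L), "S", 0L))
# 0.5192308: the probability the symptom would vanish if D were cured,
# which for a single present symptom equals the expected disablement
```

Cohort-level evaluation against synthetic clinical vignettes:

```r
cfg <- generator_config(n_risk = 3, n_disease = 5, n_symptom = 6, seed = 424)
net <- generate_network(cfg)
cohort <- generate_cohort(net, cfg, 500)
evaluate_cohort(net, cohort)
#> <cohort_result> 500 vignette(s), 0 failed, 5 disease(s)
#>   posterior              top-1 0.3520  top-5 1.0000  mean rank 2.336
#>   expected_sufficiency   top-1 0.4140  top-5 1.0000  mean rank 2.156
#>   expected_disablement   top-1 0.4100  top-5 1.0000  mean rank 2.140
```

Each vignette masks a true disease; the summary reports, per ranking
measure, how often the true disease is ranked first (top-1), the mean rank
of the true disease (lower is better; 3.0 would be random for 5 diseases),
plus error-reduction curves, win/draw/loss counts against the posterior and
rarity-stratified results.

A command-line interface wrapping the same functions ships at
`inst/cli/cfdiag` (subcommands `validate`, `diagnose`, `evaluate`,
`simulate-model`, `simulate-cohort`).

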