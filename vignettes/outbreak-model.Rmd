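---
title: "Modelling phage outbreaks against CRISPR-Cas immunity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling phage outbreaks against CRISPR-Cas immunity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprout)
```

## The model

`crisprout` simulates the early phase of a virulent-phage outbreak in a
bacterial population whose only defence is a naive CRISPR-Cas system. The
state tracks, per bacterial strain, the sensitive cells $S$ (no spacer) and
resistant cells $R_i$ carrying spacer $i$ against one of the $n_s$
protospacers of the phage genome, together with the wild-type phage $P$ and
escape phage $P_i$ mutated in protospacer $i$. All counts are integers and
every process is a stochastic jump channel:

* **Logistic growth.** Every bacterial genotype divides at rate $g B$ and
  dies at the density-dependent rate $g B T / K$, where $T$ is the total
  bacterial population across strains and $K$ the shared carrying capacity.
* **Infection of sensitive cells.** Wild-type phage meet sensitive cells at
  rate $\beta S P$. Each infection has exactly one of three outcomes: with
  probability $(1-\alpha)(1-n_s\mu)$ the cell lyses and releases $b_{WT}$
  wild-type virions; with probability $(1-\alpha)\mu$ *per protospacer* the
  burst carries an escape mutation in that protospacer and the progeny is
  split half/half between the parental and the mutant genotype
  ($\mathrm{round}(b_{WT}/2)$ plus $\mathrm{round}(b_m/2)$ virions); with
  probability $\alpha$ the cell acquires one spacer, chosen uniformly among
  the $n_s$ protospacers, killing the infecting virion. The three branch
  probabilities sum to one, so the total infection flux is exactly
  $\beta S P$.
* **Interference.** Wild-type phage entering any resistant cell are degraded
  (the phage dies, the cell is unharmed). Escape phage $P_i$ burst on
  sensitive cells and on matching hosts $R_i$ (releasing $b_m < b_{WT}$
  virions, the escape fitness cost), and are degraded by every non-matching
  host $R_{j \ne i}$. A strain flagged *type III* is escape-proof: its
  resistant cells degrade every phage genotype including matching mutants.
* **Autoimmunity.** Self-targeting spacer acquisition is modelled as an
  extra per-capita death rate $\alpha \times \mathrm{propensity}$ applied to
  every cell of the strain.

Successful bursts do not remove the infecting virion; the loss of one phage
per burst is negligible against burst sizes of order $10^2$, and the
mean-field limit of the network then reproduces the model's differential
equations term by term (this is checked in the test suite against an
independent symbolic evaluation of each term).

Two simplifications keep the state space finite and the biology within the
one-round regime the model targets: each cell acquires at most one spacer
and each phage escapes at most one spacer. Priming, biased protospacer
choice, multiple simultaneous mutations and free-phage decay are outside the
model's scope.

## Parameters

Defaults (the `crispr_params()` arguments) describe the *Streptococcus
thermophilus* DGCC7710 / phage 2972 reference system:

| parameter | meaning | default |
|---|---|---|
| `alpha` | spacer-acquisition probability per infection | variable (1e-5) |
| `mu` | escape probability per protospacer per replication | 3.4e-7 (type I/II), 0 (type III) |
| `g` | bacterial growth rate (per h) | 0.44 |
| `K` | carrying capacity (cells) | 1e11 |
| `n_s` | protospacers on the phage genome | 100 |
| `beta` | infectivity rate constant (per h per phage per cell) | 1e-6 |
| `b_wt` | wild-type burst size (virions) | 190 |
| `b_m` | escape burst size (virions) | 179 |
| `propensity` | autoimmunity multiplier | 0 |

The growth rate comes from two exponential-phase optical-density readings,
`growth_rate_from_od(0.4, 5.5, 0.5, 6)` = `r round(growth_rate_from_od(0.4,
5.5, 0.5, 6), 3)` per hour (tabulated as 0.44). The protospacer count of a
real phage genome can be estimated with `count_pam_sites()` (each occurrence
of the acquisition motif, e.g. the CR1 PAM `AGAA`, flags one candidate
protospacer; overlapping occurrences count, and both strands are scanned by
default — the forward-plus-reverse-complement decomposition is tested
against a brute-force scan). `n_s = 100` is a computational reduction of the
several hundred candidates a real genome carries, large enough that spacer
diversity, not spacer identity, governs the dynamics. Standard initial
conditions are $S = 6\times10^6$, $P = 10^5$ (`outbreak_init()`), or
$S_1 = S_2 = 3\times10^6$ for two-strain competitions
(`competition_init()`), simulated to `t_max = 150` hours.

## Simulation engine

`simulate_outbreak()` realizes the network as a continuous-time Markov
chain. Two methods are provided:

* `method = "exact"` — the Gillespie stochastic simulation algorithm,
  implemented in interpreted R. Practical for the miniature systems used in
  testing (`make_fixture("mini-system")`: $K = 10^4$, 5 protospacers,
  amplified infectivity).
* `method = "tau_leap"` — the production path, compiled. Adaptive
  tau-leaping with species-relative error control $\varepsilon = 0.03$,
  a critical-reaction partition (any channel within 10 firings of exhausting
  a reactant is fired one event at a time), an exact-step fallback when a
  leap would advance fewer than a handful of events, and roll-back with a
  halved step whenever a leap would drive a count negative. Extinction tests
  use exact integer zero, never a threshold. Poisson firing counts switch to
  a rounded normal approximation above $\lambda = 10^9$, far beyond the
  regime where the discreteness matters.

The two methods are independent implementations sharing only the network
definition; the test suite checks them against each other in distribution on
the miniature system, and checks the stochastic ensemble mean against the
mean-field solution (`ode_reference()`, integrated with `deSolve`) in a
scaled large-population regime. Identical seed, method and inputs give
bit-identical trajectories.

States are sampled every 0.5 h (zero-order hold) plus at termination and at
the instant each strain's sensitive population first hits zero — the
"beginning of the outbreak" snapshot used by the diversity metrics. Full
event logs are not retained. Runs stop early once every phage count or every
bacterial count is zero: the model has no free-phage decay, so a phage
population without hosts is frozen and nothing of interest can follow.

## Metrics and experiments

Spacer diversity is summarized as the Simpson index in its effective-number
(Hill order 2) form, $1/\sum_i p_i^2$, over resistant genotypes only —
newly generated spacers, excluding the sensitive pool
(`simpson_diversity()`, `diversity_at_s_extinction()`; replicates whose
bacterial population is extinct at the snapshot score 0). Competition
outcomes use the relative fitness
$p_f(1-p_i) / \big(p_i(1-p_f)\big)$, which reduces to $p_f/(1-p_f)$ for the
standard 50/50 seeding; both strains extinct scores 0 and extinction of the
control strain scores `Inf` (`relative_fitness()`). The "size" of an
outbreak is reported as the running peak of total free phage
(`outbreak_size()`); a cumulative-virion count would be the natural
alternative but the peak is the quantity a plaque or titer assay would see.

The experiment runners replicate these measurements over seeded Monte-Carlo
grids: `extinction_probability()`, `resistant_emergence_probability()`,
`acquisition_sweep()`, `threshold_estimate()` (bisection on a geometric
acquisition grid for the smallest value whose extinction fraction reaches
0.5), `initial_diversity_experiment()` (50% naive plus 50% pre-existing
resistance split over a chosen number of genotypes, with acquisition turned
off), `competition()`, `propensity_scan()` and `type_competition_grid()`.
Replicate $r$ of grid cell $c$ runs at seed `replicate_seed(master, c, r)`,
a multiplicative hash into the 32-bit range, so every summary is exactly
reproducible and cells are independent. Default replicate counts are 100;
desk-scale runs use 20–40 with binomial standard errors reported.

## Model behaviour at the reference parameters

Three regimes are worth knowing when interpreting output (each is exercised
by the test suite):

* **Escape-proof defence (`mu = 0`).** The outbreak outcome is governed
  entirely by whether at least one cell acquires a spacer before the
  sensitive pool is destroyed: expected acquisitions are
  $\alpha S_0$, so extinction probability saturates to 1 once
  $\alpha \gtrsim 10^{-6}$ at the reference $S_0 = 6\times10^6$. Any
  resistant lineage, once present, grows logistically and adsorbs the entire
  phage population well before 150 h.
* **Escapable defence (`mu > 0`).** A resistant lineage survives only if no
  escape mutant against its spacer ever arises. Mutation-burst events number
  about $n_s \mu S_0$ (roughly 200 at the type I/II defaults), spread
  uniformly over the protospacers, so each acquired lineage remains
  unmatched with probability about $e^{-\mu S_0}$. The phage-extinction
  probability therefore rises smoothly with $\alpha$ (approximately
  $1 - \exp(-\alpha S_0 e^{-\mu S_0})$ in the sub-saturation range) rather
  than jumping at a single sharp value; the `threshold_estimate()` statistic
  reports where the rise crosses one half. Higher escape rates shift the
  rise to higher acquisition probabilities.
* **Autoimmunity.** The per-capita autoimmune death rate
  $\alpha \times \mathrm{propensity}$ is phage-independent, so without phage
  the lowest acquisition probability always wins a competition, while during
  an outbreak the product of epidemiological benefit and autoimmune cost
  selects intermediate acquisition; the higher the propensity, the lower the
  optimum.

## Numerical choices and limitations

* Half-bursts of a mutation event are rounded to the nearest integer (95
  and 90 virions at the default burst sizes); the bias is below 0.6% of a
  burst. The split can be overridden (`half_wt`, `half_m`), and the
  `all_mutant_progeny` switch makes mutation bursts release only escape
  virions.
* The two written growth rates of the mean-field equations share the single
  measured value `g`; sensitive and resistant cells grow identically.
* Channels whose state change does not depend on which resistant genotype
  participates (wild-type adsorption, cross adsorption of an escape phage on
  its non-matching hosts) are aggregated over that index; the rate sums are
  unchanged and the jump distribution is identical.
* In two-strain competitions the strains share one protospacer coordinate
  system (spacers are phage-sequence-defined), and escape mutants arise on
  any sensitive host at that strain's own `mu`. A type III strain is
  modelled with `mu = 0` *and* escape-proof interference; whether phage
  mutation "occurs but is irrelevant" or simply does not occur is
  indistinguishable in this model.
* Tie-breaking in `type_competition_grid()` is conservative: an exact tie in
  outcome counts, or equal final strain sizes, classifies as extinction.
* The acceptance script and the test suite run the reference scale with
  reduced replicate counts (20–40 per cell) and geometric acquisition grids
  of half-decade resolution; production figures would use 100 replicates and
  finer grids, which changes error bars, not structure.
* The synthetic experiments emulate a well-mixed batch culture with constant
  rate parameters. Real outbreaks add spatial structure, latent periods,
  nutrient depletion, biased protospacer choice and multi-spacer acquisition
  — passing tests here say nothing about those effects.

## A worked example

```{r example, eval = FALSE}
params <- crispr_params(alpha = 1e-5, mu = 0)   # type III defence
res <- extinction_probability(params, reps = 40, seed = 1)
res$fraction    # 1: every replicate clears the phage
res$se          # binomial standard error (0 at a degenerate fraction)

# the same acquisition probability with a type I/II escape rate: the
# extinction fraction now depends on whether some acquired spacer stays
# un-escaped, so it is governed by the smooth rise described above
params2 <- crispr_params(alpha = 1e-5, mu = 3.4e-7, type_iii = FALSE)
res2 <- extinction_probability(params2, reps = 40, seed = 1)
res2$fraction
```
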