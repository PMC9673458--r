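---
title: "Probabilistic linguistic fuzzy cognitive maps: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic linguistic fuzzy cognitive maps: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plfcm)
```

## The problem this package addresses

Expert-elicited causal maps (fuzzy cognitive maps, FCMs) model a complex
system as a signed directed graph of concepts whose activations are iterated
through weighted influence plus a squashing function. Classical FCMs force
every judgment into a single crisp number, which throws away two things real
elicitation produces in abundance: *hesitation* between neighbouring
linguistic grades and *disagreement* between experts. A probabilistic
linguistic term set (PLTS) keeps both — it is a set of linguistic terms, each
carrying a probability, e.g. `{s-3:0.5, s-2:0.1, s-1:0.1, s0:0.3}` for "half
the weight on *very strong negative*, a tenth each on *strong* and *weak
negative*, the rest undecided".

This package implements fuzzy cognitive maps whose concept states **and**
edge weights are PLTSs, runs them to a terminal state with a two-channel
update rule, and ranks the factor concepts by the similarity of their settled
behaviour to the settled behaviour of a designated outcome concept. The
motivating application, shipped as a fixture, is a 13-node map of the health
determinants of rural older adults (12 factors in four groups, plus
self-rated health as the outcome).

## Scales, transformations, and PLTS operations

A linguistic scale has terms $s_{-\tau},\dots,s_0,\dots,s_\tau$. Two scales
coexist in one model: states live on an 11-term scale ($\tau = 5$) and edge
weights on a 7-term scale ($\tau = 3$, "very strong negative impact" to
"very strong positive impact"). The *equivalent transformation*

$$g(\gamma) = \frac{\gamma + \tau}{2\tau} \in [0, 1], \qquad
  g^{-1}(\eta) = (2\eta - 1)\,\tau,$$

is the affine bijection between term indices and membership degrees: all
arithmetic happens in $g$-space. On the state scale the triple
$(s_{-3}, s_0, s_3)$ maps to $(0.2, 0.5, 0.8)$. Note a consequence that
shapes everything downstream: a "negative" term does not become a negative
number — it becomes a membership *below 0.5*. The engine therefore never
produces negative activations; antagonistic influence manifests as pulling a
position towards the low end of $[0,1]$.

PLTS arithmetic ($\oplus$, $\otimes$, scalar multiple, power) combines
entries over the Cartesian product in $g$-space — probabilistic sum
$\eta_1 + \eta_2 - \eta_1\eta_2$ for $\oplus$, product for $\otimes$, pair
probability $p_1 p_2$ — and maps back through $g^{-1}$. Two numerical
conventions bound the combinatorics:

* duplicate resulting memberships (within $10^{-12}$) are merged by summing
  their probabilities, keeping results in ascending membership order;
* results of $g^{-1}$ may carry non-integer term values (e.g. $s_{0.9}$);
  only *user-supplied* PLTSs are required to use whole terms.

The *score* of a PLTS is the probability-weighted expectation of its term
indices on the normalized form; its $g$-image is the usual crisp
defuzzification. Expert pooling is a per-term weighted average of
probability mass over the union of supports, normalized afterwards.

## Distance, Z-mapping similarity, and a documented convention

The probabilistic linguistic Euclidean distance is

$$d(L_1(P), L_2(P)) = \sqrt{\tfrac{1}{l}\sum_{\theta=1}^{l}
  \bigl(v_1^\theta - v_2^\theta\bigr)^2},\qquad l = \max(\#L_1, \#L_2),$$

after normalization and zero-probability padding. The literature often
leaves the position scalar $v^\theta$ implicit; this package fixes it as a
**documented convention**: $v^\theta$ = $g$-transformed membership times
probability, with entries aligned by ascending term index. The padding
convention is equally explicit: the shorter operand repeats its smallest
term with probability zero. Both choices are deterministic and
order-preserving; swapping in another convention would change similarity
*values* but, being monotone recalibrations of the same geometry, rarely
the induced *order*.

A similarity degree is obtained through a decreasing Z-mapping
$Z : [0,1] \to [0,1]$:

$$S(L_1, L_2) = \frac{Z(d) - Z(1)}{Z(0) - Z(1)},$$

with four standard forms: $1-t$, $(1-t)/(1+t)$, $1-t e^{t-1}$, $1-t^2$
(`linear`, `rational`, `exponential`, `quadratic`; `rational` is the
default). Every form satisfies the similarity axioms — range $[0,1]$,
symmetry, $S = 1$ iff equal, $S = 0$ iff at maximal distance (complements at
the scale endpoints) — and, because each is strictly decreasing, the factor
*ranking* is invariant to the choice of form. The test suite exercises the
axioms over 1,000 seeded random PLTS pairs per form.

## The two-channel inference engine

Rather than iterating whole PLTS objects (whose supports would grow
combinatorially under $\oplus$/$\otimes$), the engine separates each PLTS
into a membership vector and a probability vector over a common *position
template* and iterates the two channels in parallel.

**Alignment.** The template is the ascending union of the term indices
appearing in any node state (the case study yields $(s_{-3}, s_0, s_3)$,
hence the 3-component vectors in all printed trajectories). States are
expanded onto it by term matching: position $k$ carries
$g(\text{template}_k)$ on the state scale and the node's probability for
that term (zero when absent). Edge weights are aligned *positionally*:
entries sorted ascending, padded to the template length by the
zero-probability rule, memberships taken from their **own** terms under $g$
on the weight scale. This asymmetry is deliberate. Term-matching the weights
onto the state template would force every edge's lowest position to
membership $g(-\tau_w) = 0$, which freezes that position of the entire map
at its autonomous decay — a degenerate dynamic that contradicts the intended
behaviour of the model. Positional alignment lets a weight concentrated on,
say, $\{s_1, s_2\}$ exert its (moderately positive) influence at every
position.

**Update.** For node $i$, position $k$, with incoming edges $j \to i$:

$$a_i^k = 1 - \prod_{j \ne i}\bigl(1 - \eta_j^k\, w_{ji}^k\bigr),\qquad
  \eta_i^k \leftarrow f\!\bigl(\eta_i^k + a_i^k - \eta_i^k a_i^k\bigr),$$

i.e. the incoming influences and the node's own state combine by the
probabilistic sum, then pass through the threshold
$f(x) = \tanh(\lambda x)$, $\lambda > 0$. The probability channel updates
analogously with the edge-weight probabilities and is then renormalised so
every node's probability row sums to 1 — the renormalisation is what keeps
the probability channel a probability distribution at every recorded step.
Three consequences are guaranteed by construction and enforced as tested
invariants:

* after the first step every membership lies in $[0, \tanh\lambda]$ (the
  threshold input is a probabilistic sum of $[0,1]$ quantities);
* probability rows sum to 1 at every step (within $10^{-9}$);
* the membership channel never reads a probability, so two models that
  differ only in probabilities have bit-identical membership histories —
  this is exactly why the hesitant-baseline comparison below shares the
  full model's membership trajectory.

**Termination.** The run stops at a *fixed point* when the max-norm change
across both channels drops to `tol` ($10^{-6}$ by default), at a *limit
cycle* when the current state recurs (within `tol`) among the last
`cycle_window` states (50), or is classified *chaotic* when `max_iter`
(500) is exhausted. Two honest caveats about this taxonomy:

* Under the tanh threshold the update map is monotone with positive
  diagonal on $[0,1]^n$, and a brute-force search over small random weight
  settings found no genuine limit cycle — consistent with the theory of
  monotone discrete-time maps. The detection code path is therefore
  exercised through the *pluggable threshold hook* (`threshold` in
  `plfcm_settings()`): any decreasing hook produces a clean period-2 cycle.
* "Chaotic" means "did not settle within the budget". Positions whose
  incoming influence decays to zero approach their fixed point 0 only
  algebraically ($x \mapsto \tanh x$ contracts with slope 1 at the
  origin), which can legitimately exceed a 500-iteration budget at
  `tol = 1e-6`. This is a property of the dynamics, not an artifact; maps
  whose every node receives some positive-membership inflow (as in the
  case study's printed trajectories, which saturate towards
  $\tanh 1 \approx 0.7616$) converge in tens of iterations.

**Back-transformation.** At a fixed point, each node's final membership
vector is mapped through $g^{-1}$ on the state scale and paired with the
final probability row, giving the steady-state PLTS per node.

## Ranking, sensitivity analyses, and baselines

`rank_factors()` computes the similarity of every factor's steady PLTS to
the outcome's steady PLTS and ranks descending (rank 1 = most similar = most
closely coupled to the outcome). Ties receive the mean of the tied
positions. First-level group scores are arithmetic means of member ranks, so
lower scores mark more influential categories.

`sensitivity_z()` recomputes the similarity table under all four Z forms
from a single run (the steady state does not depend on Z) and flags whether
the rank vectors agree — they must, for strictly decreasing forms.
`sensitivity_lambda()` reruns the whole pipeline over a steepness grid
(default $\{2, 3, 4, 6, 8, 10\}$) and reports the similarity spread
(max − min) per $\lambda$: steeper thresholds saturate harder, steady states
crowd together, and the spread shrinks — discrimination between factors is
sharpest at small $\lambda$.

Two degenerate baselines isolate what the probabilistic component adds:

* **Hesitant baseline** (`hflcm_run()`): probabilities disregarded. The
  iteration *is* the membership channel (identical bit-for-bit); similarity
  is computed on bare membership vectors. Because every node's membership
  saturates into the same narrow band, the resulting similarities bunch
  near 1 and discriminate factors poorly — the probability channel is what
  separates them.
* **Crisp baseline** (`fcm_run()`): every PLTS collapsed by score. States
  become $g(\text{score})$ on the state scale (unsigned, $[0,1]$); weights
  become score divided by $\tau_w$ (signed, $[-1,1]$, preserving negative
  influences). The classical update
  $x_i \leftarrow f(x_i + \sum_{j\ne i} x_j w_{ji})$ uses the **plain** sum,
  so activations can exceed $\tanh\lambda$ (inputs are unbounded) — visible
  in the crisp trajectories approaching 1. Similarity uses $|x_i - x_R|$
  as the distance fed to the Z-mapping.

## The case-study fixture and the synthetic stand-in matrix

`load_case_study()` ships the 13 nodes with their initial PLTSs over
$\{s_{-3}, s_0, s_3\}$, exactly as tabulated from the underlying national
surveys (CLHLS, CHARLS, CGSS); the finer 11-grade refinement behind those
triples is collapsed to the three working terms, and the package records the
triples verbatim rather than re-deriving them from microdata. Score
defuzzification of the fixture reproduces the published crisp initial vector
$(0.65, 0.65, 0.35, \dots, 0.59)$ exactly, which pins down the
state-defuzzification convention.

The expert-elicited connection matrices themselves are supplementary
material of the original study and are not redistributable here, so the
fixture is states-only. `write_matrix_template()` emits a CSV skeleton with
the correct row/column ids for transcribing such a matrix, and
`attach_matrix()` validates and attaches it. For end-to-end demonstrations
and tests the package bundles `synthetic_connection_matrix.csv` — *synthetic
by construction and named accordingly*: its edge directions follow the
qualitative causal structure described for the rural-health system
(socio-economic status driving lifestyle and environment, lifestyle driving
health management, all factors feeding the outcome, selected feedback from
health to factors), but every strength is invented. Rankings computed from
it are illustrative of the machinery, not of the published findings.

## The synthetic model generator

`generate_synthetic()` draws seeded random models for property testing:
states on a given term template with symmetric-Dirichlet probabilities,
edges as independent coin flips at the requested density, and weights as one
to three adjacent terms from the negative- or positive-leaning half of the
weight scale according to `sign_mix`. The defaults — 13 nodes, density 0.3,
30% negative-leaning edges, states on $\{s_{-3}, s_0, s_3\}$ with
concentration 1 — mirror the case-study geometry and the sparsity typical of
expert-drawn causal maps.

What the generator deliberately does *not* emulate: correlated expert
judgments (each edge is independent), hub structure (real causal maps
concentrate in- and out-degree on a few concepts), and the survey-derived
coupling between a state's support and its probabilities. Passing property
tests on generated models therefore certifies the *algebraic and dynamical
invariants* of the implementation — probability conservation, threshold
bounds, channel independence, oracle equivalence, determinism — not the
epidemiological plausibility of any particular random map.

## Numerical choices and problem sizes

* Probability-sum checks at $10^{-9}$; transformation round trips and
  oracle comparisons at $10^{-12}$.
* Convergence metric: max-norm over both channels; defaults
  `tol = 1e-6`, `max_iter = 500`, `cycle_window = 50` are desk-scale safe.
* Degenerate inputs fail loudly: all-zero probability vectors, scale
  mismatches, self-edges, unknown matrix ids, and malformed PLTS cells
  (reported with their row/column context) are errors, not warnings.
* The test suite runs at deliberately moderate sizes — 1,000 seeded PLTS
  pairs per similarity axiom, 60 generated models for structural
  invariants, engine oracles on models of up to 6 nodes over multiple
  steps — chosen so the whole suite completes in well under a minute while
  still covering every code path.

## Known limitations

* Only explicit `term:probability` sets are supported; comparative
  linguistic expressions ("at least medium") and context-free-grammar
  elicitation are out of scope.
* One distance family (the Euclidean form above) is implemented; Hamming
  or Hausdorff variants are not.
* The connection matrix is taken as given: no learning algorithms
  (Hebbian, particle-swarm, genetic) are provided.
* The per-position scalar inside the distance and the placement of the
  threshold in the probability channel are documented conventions where the
  source formulation is ambiguous; both are configurable or isolated enough
  to swap, and the probability-channel flag (`apply_f_prob`) is exposed in
  the settings.
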