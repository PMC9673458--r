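# plfcm — probabilistic linguistic fuzzy cognitive maps

Expert-elicited causal maps (fuzzy cognitive maps) force every judgment
into one crisp number, discarding the hesitation and disagreement real
elicitation produces. `plfcm` implements fuzzy cognitive maps whose concept
states and edge weights are **probabilistic linguistic term sets** (PLTSs)
— sets of linguistic terms each carrying a probability, e.g.
`{s-3:0.5, s-2:0.1, s-1:0.1, s0:0.3}` — and ranks the factor concepts of
such a map by how closely their settled behaviour tracks a designated
outcome concept. It is aimed at health-services and policy researchers who
model "what drives this outcome?" systems from expert knowledge plus survey
marginals; the packaged case study is a 13-node map of the health
determinants of rural older adults.

## The method in brief

Terms live on a symmetric scale $s_{-\tau},\dots,s_{\tau}$ ($\tau = 5$ for
states, $\tau = 3$ for weights) and move to the unit interval through the
equivalent transformation $g(\gamma) = (\gamma + \tau)/(2\tau)$. Each PLTS
is split into a membership vector and a probability vector over a common
position template, and the two channels iterate in parallel: for node $i$,
position $k$,

$$a_i^k = 1 - \prod_{j \ne i} \bigl(1 - \eta_j^k w_{ji}^k\bigr), \qquad
  \eta_i^k \leftarrow \tanh\!\lambda\bigl(\eta_i^k + a_i^k - \eta_i^k a_i^k\bigr),$$

with the probability channel updated analogously and renormalised per node.
The run terminates at a fixed point, a limit cycle, or a chaotic
classification at the iteration cap. At a fixed point each node's state is
mapped back through $g^{-1}$, and every factor $C_i$ is scored against the
outcome $R$ by a Z-mapping similarity on the probabilistic linguistic
Euclidean distance,

$$S(C_i, R) = \frac{Z(d) - Z(1)}{Z(0) - Z(1)}, \qquad
  Z(t) = \tfrac{1-t}{1+t} \text{ (default)},$$

rank 1 being the factor most strongly coupled to the outcome. Sensitivity
analyses over the four standard Z forms and the threshold steepness
$\lambda$, plus two degenerate baselines (a hesitant fuzzy linguistic map
that ignores probabilities, and a crisp classical map built from PLTS
scores), complete the pipeline. The methods vignette
(`vignettes/plfcm-methods.Rmd`) documents every convention and its
rationale.

## Worked example

The fixture ships the 13 node states; the expert connection matrix is
supplementary material of the original study, so the package bundles a
clearly-labelled **synthetic** stand-in matrix (same causal skeleton,
invented strengths) for demonstration:

```r
library(plfcm)

m  <- load_case_study(synthetic_matrix_path())
tr <- plfcm_run(m)
tr
#> <plfcm_trace> fixed_point after 107 iteration(s); 13 nodes, 3 positions

rank_factors(m)
#> <similarity_ranking> mode = plfcm, Z = rational, lambda = 1
#>   id                                  label                 group similarity rank
#>   C5                              Mentality             lifestyle     0.9936    1
#>   C6 Preventive medical service utilization     health management     0.9832    2
#>   C3                      Physical exercise             lifestyle     0.9795    3
#>   ...
#>   C4                    Unhealthy lifestyle             lifestyle     0.8451   12
#> group scores (mean member rank; lower = more influential):
#>                  group    score
#>      health management 4.000000
#>              lifestyle 5.600000
#>     living environment 7.000000
#>  socio-economic status 9.333333
```

The map reaches a fixed point in 107 iterations; with this synthetic
matrix, mentality is the factor whose steady state tracks self-rated health
most closely (similarity 0.9936), and health management is the most
influential first-level group (best mean rank 4.0). Because the matrix is
synthetic, these numbers illustrate the machinery, not the published
epidemiology. Three anchor computations are exact regardless of any
matrix: `g_transform(c(-3, 0, 3), 5)` returns `0.2 0.5 0.8`; score
defuzzification of the fixture states returns the crisp initial vector
`0.65 0.65 0.35 0.62 0.71 0.56 0.62 0.395 0.515 0.335 0.47 0.62 0.59`; and
pooling the three worked expert opinions returns
`{s-3:0.5, s-2:0.1, s-1:0.1, s0:0.3}`.

To use a real elicited matrix, write a template and transcribe into it:

```r
write_matrix_template(load_case_study(), "matrix.csv")  # fill in the cells
m <- load_case_study("matrix.csv")
```

A shell entry point is installed at `exec/plfcm`
(`plfcm simulate|rank|sensitivity|compare|synth`; exit code 0 = fixed
point, 2 = limit cycle, 3 = chaotic).

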