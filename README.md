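# qpcog

Quantum-probability engine for predictive cognition models in which
top-down **predictions** and bottom-up **evidence** are *complementary*
measurement contexts over one shared state space.

## The problem and the model

Classical predictive-coding accounts of the brain assume that predictions
and sensory evidence live in a single Boolean sample space, so that
updating on evidence is Bayesian conditioning. `qpcog` implements the
quantum-probability alternative: the cognitive state is a unit vector
|S⟩ in an N-dimensional Hilbert space, and predictions and evidence are
two ordered orthonormal bases {|P₁⟩,…,|Pₙ⟩} and {|E₁⟩,…,|Eₙ⟩} of that
space. The machinery is standard quantum measurement theory:

- **Born rule** — the probability of an outcome event is the squared
  length of the projection of |S⟩ onto the event's subspace:
  p(Pᵢ) = |⟨Pᵢ|S⟩|²; for a union of rays of one context the probabilities
  add, and over a complete context they sum to 1.
- **Collapse (Lüders rule)** — observing an event projects the state onto
  the event's subspace and renormalizes. Within a single context this *is*
  Bayes' rule; `bayes_equivalence_check()` verifies the identity
  P(ray j | union U) = P(ray j)/P(U).
- **Basis change** — the two contexts are linked by a unitary transition
  matrix U with entries ⟨Pᵢ|Eⱼ⟩; ψ = U·φ re-expresses the same state, and
  |U|² is doubly stochastic.
- **Sequential paths and order effects** — the probability of a path
  |S⟩→|E₂⟩→|P₁⟩ is the product of the step probabilities (the
  multiplicative chain rule); when the contexts do not commute,
  P(A then B) ≠ P(B then A).
- **Interference** — for incompatible contexts the law of total
  probability fails: the direct probability of an event differs from the
  sum of its mediated paths through an intermediate context, and can even
  be smaller than a *single* mediated path.

When the two contexts commute (`compatibility_report()`), order effects
and interference vanish identically and the engine reduces to a classical
Bayesian model — the Bayesian account is the compatible special case.

Real and complex amplitudes are supported throughout; models serialize to
JSON (canonical) or YAML, and a seeded generator (`random_model()`)
produces synthetic models for property testing.

## Worked example

The packaged fixture is a 2-D model: prediction context `P` (the
reference frame), evidence context `E` with basis vectors
(−0.4372, 0.8994) and (0.8994, 0.4372) in the `P` frame, and state
(0.2269, 0.9739) in `P` coordinates.

```r
library(qpcog)
m <- fixture_model(quiet = TRUE)

probability_table(m$state, m$contexts$P)
#>   context outcome probability
#> 1       P      P1  0.05148542
#> 2       P      P2  0.94851458

change_frame(m$state, m$contexts$E)
#> <pure state in frame 'E'>
#>   E1: 0.7767
#>   E2: 0.6299

path_probability(m$state, list(event_subspace(m$contexts$E, "E2"),
                               event_subspace(m$contexts$P, "P1")))
#> <sequential measurement path>
#>   steps: E:E2 -> P:P1
#>   step probabilities: 0.3968, 0.8089
#>   path probability (product of steps): 0.3209

total_probability_decomposition(m$state, m$contexts$E,
                                event_subspace(m$contexts$P, "P1"))
#> <total-probability decomposition of P:P1 via context E>
#>   direct probability:  0.0515
#>   mediated paths:      E1: 0.1153, E2: 0.3209
#>   classical sum:       0.4362
#>   interference term:   -0.3847
```

Reading the numbers: the direct probability of prediction `P1` is 0.0515,
but the path that first registers evidence `E2` and then asks about `P1`
has probability 0.3209 — conditioning *raised* the probability above its
unconditional value, which no classical model allows. The interference
term −0.3847 quantifies the violation of the law of total probability.

## Command line

```sh
inst/cli/qpcog prob --model fixture --event P:P1
inst/cli/qpcog path --model fixture --steps E:E2,P:P1 --json
inst/cli/qpcog interference --model fixture --via E --final P:P1
inst/cli/qpcog random --dim 3 --n-contexts 2 --seed 7 --out model.json
```

Exit status 0 on success, 1 on domain errors (impossible outcome, invalid
model), 2 on usage errors. `--json` gives lossless machine output;
`--out FILE` writes CSV or JSON by extension.

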