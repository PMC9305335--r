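---
title: "A quantum-probability engine for complementary prediction and evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quantum-probability engine for complementary prediction and evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcog)
```

## The model

`qpcog` implements projective quantum measurement as a model of predictive
cognition. The cognitive state is a unit vector $|S\rangle$ in an
$N$-dimensional Hilbert space. A *measurement context* is an ordered
orthonormal basis of that space whose rays are the elementary outcomes:
here, a top-down prediction context $\{|P_1\rangle,\dots,|P_N\rangle\}$
and a bottom-up evidence context $\{|E_1\rangle,\dots,|E_N\rangle\}$. The
assumptions are exactly those of finite-dimensional quantum probability:

1. **Born rule.** The probability of an event (a ray, or a union of rays
   of one context) is the squared length of the projection of the state
   onto the event's subspace. Orthogonality of the rays makes union
   probabilities additive and the complete-context probabilities sum to 1.
2. **Lüders collapse.** Observing an event projects the state onto the
   event's subspace and rescales the projection to unit length. Within a
   single context this reproduces classical conditioning exactly —
   `bayes_equivalence_check()` computes both sides of
   $P(j \mid U) = P(j)/P(U)$ and reports their largest discrepancy.
3. **Complementarity.** The two contexts need not share rays. When their
   ray projectors fail to commute, sequential measurements acquire order
   effects and the law of total probability gains an interference term;
   when they all commute (`compatibility_report()`), both vanish
   identically and the engine *is* a classical Bayesian model. The
   classical account is thus recovered as the compatible special case
   rather than contradicted.

Both real and complex amplitudes are supported everywhere. The packaged
worked example (`fixture_model()`) is real-valued: a 2-D model whose
evidence basis is a reflection of the prediction basis, with state
$(0.2269, 0.9739)$ in prediction coordinates.

## Sequential paths: why the product rule

The probability of a measurement path such as
$|S\rangle \to |E_2\rangle \to |P_1\rangle$ is computed by iterating
Born-rule measurement and collapse, which for single-ray steps equals the
product of squared transition amplitudes,
$|\langle P_1|E_2\rangle|^2 \cdot |\langle E_2|S\rangle|^2$. This
multiplicative chain rule is the only coherent composition: step
probabilities are conditional probabilities, and a *sum* of conditional
probabilities is not the probability of anything — it can exceed 1.
`path_probability()` therefore always multiplies, records the rule in the
result (`rule = "product"`), and its tests assert that the reversed path
of the worked example comes out at $0.0515 \times 0.8089 \approx 0.0416$,
the value the product rule dictates.

Paths through events that span several outcomes ("coarse" steps) are
accepted and handled by the same project-and-renormalize rule, but flagged
`coarse = TRUE`: for coarse events the squared-amplitude product form is
no longer available, the law of reciprocity does not apply, and sequential
coarse measurement of *mixed* states is outside this package's scope
(pure states only).

## Tunable parameters

All tolerances are dimensionless (amplitudes and probabilities are
dimensionless).

| parameter | default | role |
|---|---|---|
| state/basis norm tolerance | 1e-6 | validation bound on norm and Gram deviations |
| printed-value slack | 1e-3 | how far amplitudes quoted at 4 decimals may deviate before renormalization is refused |
| collapse threshold | 1e-12 | outcomes at or below this probability cannot be conditioned on (`impossible_outcome`) |
| commutator tolerance | 1e-9 | projector-commutator norm at or below which two contexts count as compatible |

The collapse threshold errs rather than returning a direction dominated by
rounding noise. The compatibility verdict uses the *maximum entrywise
magnitude* over all pairwise ray-projector commutators, a conservative and
basis-independent-enough summary for the verdict it feeds.

## Numerical and design choices

- **Renormalization policy.** Orthonormality violations are rejected, not
  repaired: silently re-orthogonalizing a basis would move the user's
  probabilities. The one sanctioned repair (`normalize = TRUE`, used by
  the fixture and by `load_model()`) rescales vector *lengths* only, never
  directions, and only within the 1e-3 printed-value slack, with a
  message. The fixture's amplitudes are stored exactly as printed at four
  decimals (squared norms off by about 3–6 × 10⁻⁵), so fidelity to the
  quoted values wins over silent precision; after rescaling, derived
  probabilities match the quoted 4-decimal values to within 0.001.
- **Phase convention.** After collapse the state is rotated by a global
  phase so its largest-magnitude coordinate is real and nonnegative.
  Probabilities are phase-blind; this only fixes a deterministic
  representative (after a ray collapse the state is literally that basis
  vector).
- **Reflections allowed.** The worked example's change of basis has
  determinant −1. Any unitary (or real orthogonal) transition is physical;
  probabilities do not see the determinant, so no rotation-only
  restriction is imposed.
- **Ordered contexts.** Outcome labels carry meaning, so a permuted basis
  is *not* ray-equivalent to the original (`ray_equivalent()` compares
  index by index, up to a per-ray phase). Permuted or sign-flipped bases
  do, however, share rays and are therefore *compatible* — the two notions
  are deliberately distinct.
- **Reciprocity vs double stochasticity.** Two related symmetries are
  checked separately and not conflated: $|\langle a|b\rangle|^2 =
  |\langle b|a\rangle|^2$ for any ray pair (reciprocity), and row/column
  sums of the squared-magnitude transition matrix equal to 1 (double
  stochasticity of any unitary). In two dimensions the latter implies the
  cross-outcome equality $|\langle E_2|P_1\rangle|^2 = |\langle
  E_1|P_2\rangle|^2$; `reciprocity_matrix()` reports both.
- **Generator reproducibility.** `random_model()` orthonormalizes seeded
  standard-normal matrices by QR with the sign convention that the R
  factor's diagonal is nonnegative, making the factorization unique and
  the model identical across platforms for a given seed. The first context
  is the canonical reference frame; the state is a normalized
  standard-normal vector. The generator draws real amplitudes: the
  geometry under study (order effects, interference) already appears in
  real models, and complex support is exercised separately.
- **Degenerate inputs.** Empty coordinate vectors, dimension mismatches,
  unknown labels, duplicate outcomes, conditioning on
  probability-zero events, and malformed model files all raise classed
  errors (`malformed_state`, `incompatible_model`, `invalid_context`,
  `impossible_outcome`, `invalid_model`, `parse_error`, `usage_error`), so
  callers and the CLI can distinguish domain errors (exit 1) from usage
  errors (exit 2).
- **Indexing.** Outcome indices are 1-based, matching both R convention
  and the outcome labels (`P1` is outcome 1).

## What the synthetic generator does and does not emulate

`random_model()` produces uniformly scrambled orthonormal contexts and a
random state. That is the right stress test for the *mathematical* claims
— completeness, unitarity, double stochasticity, the product-rule/collapse
equivalence, antisymmetry of order effects — because those must hold for
every model. It does not emulate anything about real cognition: no
behavioral data are fitted, the dimensions carry no neural interpretation,
and nothing constrains the angle between contexts to realistic
"precision" trade-offs. Passing property tests therefore certifies the
probability engine, not any empirical claim about brains. The 2-D rotated
family (`rotation_context_2d()`), with its closed-form
$\cos^2(\alpha-\theta)$ law, covers the geometrically interpretable slice
in between.

## Problem sizes and test budget

The test suite runs entirely on desk-scale problems: the 2-D worked
example, random models of dimension 2–5, 200 seeded models for the
product-rule/collapse equivalence check, a 9 × 9 grid of state and context
angles for the cosine law, and Monte-Carlo draws of $n = 10^4$ per context
compared to Born probabilities at a 3-standard-error binomial bound. The
full suite completes in a few seconds.

## Known limitations

- Pure states only: no density matrices, POVMs, or mixed-state sequential
  coarse measurement.
- Finite dimensions and orthonormal (complete, non-overcomplete) contexts
  only.
- Contextuality analysis (e.g. separating direct influences from genuine
  contextuality across measurement conditions) is out of scope.
- No fitting of model parameters to empirical judgment or questionnaire
  data; the package is an engine for specified models, not an estimator.
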