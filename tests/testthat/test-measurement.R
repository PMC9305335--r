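test_that("sequential path probabilities follow the multiplicative chain rule", {
  m <- fix()
  res <- path_probability(m$state, list(ev(m, "E:E2"), ev(m, "P:P1")))
  expect_equal(res$path_probability, 0.3209, tolerance = PRINT_TOL)
  expect_equal(res$step_probabilities, c(0.3968, 0.8089), tolerance = PRINT_TOL)
  expect_equal(res$path_probability, prod(res$step_probabilities),
               tolerance = 1e-12)
  expect_identical(res$rule, "product")
  expect_false(res$coarse)
  # post state is |P1>
  expect_equal(change_frame(res$post_state, m$contexts$P)$coords, c(1, 0),
               tolerance = 1e-12)

  # reversed order: the product rule gives 0.0416 (= 0.0515 * 0.8089)
  rev <- path_probability(m$state, list(ev(m, "P:P1"), ev(m, "E:E2")))
  expect_within(rev$path_probability, 0.0416)

  # repeating a step is idempotent
  twice <- path_probability(m$state, list(ev(m, "P:P1"), ev(m, "P:P1")))
  expect_equal(twice$path_probability,
               born_probability(m$state, ev(m, "P:P1")), tolerance = 1e-12)
})

test_that("an impossible step flags the path and zeroes its probability", {
  m <- fix()
  res <- path_probability(m$state, list(ev(m, "P:P1"), ev(m, "P:P2")))
  expect_true(res$impossible)
  expect_identical(res$path_probability, 0)
  expect_null(res$post_state)
})

test_that("iterated collapse equals the squared-amplitude product oracle for ray paths", {
  n_checked <- 0
  for (seed in 1:200) {
    dim <- 2 + (seed %% 4)
    mod <- random_model(dim, 3, seed)
    idx <- 1 + (c(seed, seed + 1, seed + 2) %% dim)
    steps <- list(event_subspace(mod$contexts$C2, idx[1]),
                  event_subspace(mod$contexts$C3, idx[2]),
                  event_subspace(mod$contexts$C1, idx[3]))
    got <- path_probability(mod$state, steps)$path_probability
    want <- oracle_ray_path(state_ref_coords(mod),
                            list(ray_vec(mod$contexts$C2, idx[1]),
                                 ray_vec(mod$contexts$C3, idx[2]),
                                 ray_vec(mod$contexts$C1, idx[3])))
    expect_equal(got, want, tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 200)
})

test_that("order effects are antisymmetric and match the path oracle on the example", {
  m <- fix()
  a <- ev(m, "E:E2"); b <- ev(m, "P:P1")
  d <- order_effect(m$state, a, b)
  expect_equal(d, 0.2793, tolerance = PRINT_TOL)
  expect_equal(order_effect(m$state, b, a), -d, tolerance = 1e-12)

  # events of one context commute: both orders, zero effect
  expect_equal(order_effect(m$state, ev(m, "P:P1"), ev(m, "P:P2")), 0)
  expect_equal(order_effect(m$state, ev(m, "E:E1"), ev(m, "E:E1+E2")), 0,
               tolerance = 1e-12)

  for (seed in 1:5) {
    mod <- random_model(3, 2, seed)
    ea <- event_subspace(mod$contexts$C1, 1)
    eb <- event_subspace(mod$contexts$C2, 2)
    expect_equal(order_effect(mod$state, ea, eb),
                 -order_effect(mod$state, eb, ea), tolerance = 1e-12)
  }
})

test_that("reciprocity holds for rays and squared magnitudes are doubly stochastic", {
  m <- fix()
  r <- reciprocity_matrix(m$contexts$P, m$contexts$E)
  expect_equal(r$matrix["P1", "E2"], 0.8089, tolerance = PRINT_TOL)
  # same probability in the reverse direction, and the 2-D cross symmetry
  expect_lt(r$reciprocity_max_error, 1e-12)
  expect_equal(r$matrix["P1", "E2"], r$matrix["P2", "E1"], tolerance = 1e-12)

  ident <- reciprocity_matrix(m$contexts$P, m$contexts$P)
  expect_equal(unname(ident$matrix), diag(2), tolerance = 1e-12)

  mod <- random_model(3, 2, 13)
  r3 <- reciprocity_matrix(mod$contexts$C1, mod$contexts$C2)
  expect_equal(unname(r3$row_sums), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(r3$col_sums), rep(1, 3), tolerance = 1e-9)
  expect_true(r3$doubly_stochastic)
})

test_that("compatibility diagnoses commuting versus complementary contexts", {
  m <- fix()
  rep_pe <- compatibility_report(m$contexts$P, m$contexts$E, state = m$state)
  expect_false(rep_pe$compatible)
  expect_gt(rep_pe$max_projector_commutator_norm, 0.1)
  expect_gt(rep_pe$max_order_effect, 0.1)

  self <- compatibility_report(m$contexts$P, m$contexts$P, state = m$state)
  expect_true(self$compatible)
  expect_equal(self$max_order_effect, 0, tolerance = 1e-12)

  # rotation by zero is the canonical basis: compatible
  r0 <- compatibility_report(m$contexts$P, rotation_context_2d(0))
  expect_true(r0$compatible)

  # permuted and sign-flipped bases share rays: still compatible
  perm <- build_context("Q", rbind(c(0, -1), c(1, 0)))
  expect_true(compatibility_report(m$contexts$P, perm)$compatible)
})

test_that("incompatible contexts break the law of total probability; compatible ones do not", {
  m <- fix()
  rep1 <- total_probability_decomposition(m$state, m$contexts$E, ev(m, "P:P1"))
  expect_equal(rep1$direct_probability, 0.0515, tolerance = PRINT_TOL)
  expect_equal(unname(rep1$mediated_probabilities), c(0.1153, 0.3209),
               tolerance = PRINT_TOL)
  expect_equal(rep1$classical_sum, 0.4362, tolerance = PRINT_TOL)
  expect_equal(rep1$interference_term, -0.3848, tolerance = PRINT_TOL)
  expect_equal(rep1$classical_sum, sum(rep1$mediated_probabilities),
               tolerance = 1e-12)
  # the direct probability is even smaller than one single mediated path
  expect_lt(rep1$direct_probability, rep1$mediated_probabilities[["E2"]])

  # amplitudes, unlike probabilities, do decompose exactly
  expect_lt(rep1$amplitude_identity_error, 1e-9)

  # compatible intermediate context: interference vanishes
  rep2 <- total_probability_decomposition(m$state, m$contexts$P, ev(m, "P:P1"))
  expect_equal(rep2$interference_term, 0, tolerance = 1e-9)
  perm <- build_context("Q", rbind(c(0, 1), c(1, 0)))
  rep3 <- total_probability_decomposition(m$state, perm, ev(m, "P:P1"))
  expect_equal(rep3$interference_term, 0, tolerance = 1e-9)
})

test_that("within one context, collapse reproduces classical Bayesian conditioning", {
  mod <- random_model(3, 1, 21)
  ctx <- mod$contexts$C1

  chk <- bayes_equivalence_check(mod$state, ctx, outcomes = c(1, 2))
  expect_true(chk$pass)
  p <- probability_table(mod$state, ctx)$probability
  expect_equal(unname(chk$conditional),
               c(p[1:2] / sum(p[1:2]), 0), tolerance = 1e-12)

  # conditioning on the sure event changes nothing
  full <- bayes_equivalence_check(mod$state, ctx)
  expect_true(full$pass)
  expect_equal(unname(full$conditional), p, tolerance = 1e-12)

  # conditioning on a single ray makes it certain
  one <- bayes_equivalence_check(mod$state, ctx, outcomes = 2)
  expect_equal(unname(one$conditional), c(0, 1, 0), tolerance = 1e-12)

  expect_error(
    bayes_equivalence_check(pure_state(c(1, 0, 0), ctx), ctx, outcomes = 2),
    class = "impossible_outcome")
})

test_that("rotated-context probabilities follow the cos^2 law", {
  for (alpha in seq(0, pi, length.out = 7)) {
    s <- pure_state(c(cos(alpha), sin(alpha)),
                    build_context("P", diag(2), reference = TRUE))
    for (theta in seq(-pi / 2, pi / 2, length.out = 7)) {
      ctx <- rotation_context_2d(theta)
      expect_equal(born_probability(s, event_subspace(ctx, 1)),
                   cos(alpha - theta)^2, tolerance = 1e-12)
    }
  }
})
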