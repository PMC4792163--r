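test_that("PD matrix has the weak-dilemma structure T = b, R = 1, P = S = 0", {
  M <- pd_matrix(game_spec(1.5))
  expect_equal(unclass(M), matrix(c(1, 0, 1.5, 0), 2, byrow = TRUE,
                                  dimnames = list(c("C", "D"), c("C", "D"))))
  # boundary b = 1: C and D earn equally against a cooperator
  M1 <- pd_matrix(game_spec(1))
  expect_equal(M1["D", "C"], M1["C", "C"])
  # defection dominance: the advantage of defecting on a cooperator is b - 1
  for (b in c(1.1, 1.5, 2)) {
    M <- pd_matrix(game_spec(b))
    expect_gt(M["D", "C"] - M["C", "C"], 0)
    expect_equal(M["D", "C"] - M["C", "C"], b - 1)
  }
})

test_that("parameter domains are enforced", {
  expect_error(game_spec(0.9), "b")
  expect_error(game_spec(2.1), "b")
  expect_error(game_spec(1.5, -0.1), "gamma")
  expect_error(game_spec(1.5, pi), "gamma")
  expect_silent(game_spec(1))   # endpoints are simulated in the sweeps
  expect_silent(game_spec(2, pi / 2))
})

test_that("QPD matrix matches the trig formulas and collapses to PD at gamma = 0", {
  # gamma = 0: Q row and column identical to C row and column
  M0 <- qpd_matrix(game_spec(1.7, 0))
  expect_equal(M0["Q", ], M0["C", ], ignore_attr = TRUE)
  expect_equal(M0[, "Q"], M0[, "C"], ignore_attr = TRUE)
  expect_equal(unclass(M0)[c("C", "D"), c("C", "D")],
               unclass(pd_matrix(game_spec(1.7))))
  # gamma = pi/2, b = 2: substitute sin^2 = 1, cos^2 = 0
  M <- qpd_matrix(game_spec(2, pi / 2))
  expect_equal(M["Q", "D"], 2)
  expect_equal(M["D", "Q"], 0)
  expect_equal(M["Q", "C"], 0)
  # gamma = pi/4, b = 2: cos^2 = sin^2 = 1/2
  M4 <- qpd_matrix(game_spec(2, pi / 4))
  expect_equal(M4["C", "Q"], 0.5)
  expect_equal(M4["Q", "C"], 0.5)
  expect_equal(M4["D", "Q"], 1)
  expect_equal(M4["Q", "D"], 1)
})

test_that("QPD matrix identities hold across the (b, gamma) grid", {
  for (b in seq(1, 2, length.out = 7)) {
    for (g in seq(0, pi / 2, length.out = 7)) {
      M <- qpd_matrix(game_spec(b, g))
      expect_true(all(is.finite(M)) && all(M >= 0))
      # C-Q equal status
      expect_equal(M["C", "Q"], M["Q", "C"])
      # complementary D-Q payoffs: sin^2 + cos^2 = 1
      expect_equal(M["Q", "D"] + M["D", "Q"], b)
    }
  }
  # monotonicity in gamma: D earns less, Q earns more against each other
  gs <- seq(0, pi / 2, length.out = 25)
  dq <- vapply(gs, function(g) qpd_matrix(game_spec(1.8, g))["D", "Q"],
               numeric(1))
  qd <- vapply(gs, function(g) qpd_matrix(game_spec(1.8, g))["Q", "D"],
               numeric(1))
  expect_true(all(diff(dq) <= 1e-12))
  expect_true(all(diff(qd) >= -1e-12))
})

test_that("pairwise subgames reproduce the G_CD, G_CQ, G_DQ decomposition", {
  spec <- game_spec(1.6, pi / 3)
  Q <- qpd_matrix(spec)
  # G_CD is the classical PD at the same b
  expect_equal(unclass(pairwise_subgame(Q, "C", "D")),
               unclass(pd_matrix(spec)))
  # G_CQ: equal off-diagonal payoffs cos^2(gamma), diagonal 1
  cq <- pairwise_subgame(Q, "C", "Q")
  expect_equal(cq["C", "Q"], cos(pi / 3)^2)
  expect_equal(cq["Q", "C"], cos(pi / 3)^2)
  expect_equal(diag(unclass(cq)), c(C = 1, Q = 1))
  # G_DQ at gamma = pi/2: D earns 0 against Q, Q earns b against D
  dq <- pairwise_subgame(qpd_matrix(game_spec(1.6, pi / 2)), "D", "Q")
  expect_equal(dq["D", "Q"], 0)
  expect_equal(dq["Q", "D"], 1.6)
  expect_error(pairwise_subgame(Q, "C", "C"), "differ")
  expect_error(pairwise_subgame(pd_matrix(spec), "C", "Q"), "not in matrix")
})

test_that("Q equilibrium analysis matches brute-force best-response enumeration", {
  # oracle: Q is a strict NE iff Q is the unique best response to Q
  brute_strict_ne <- function(M) {
    against_q <- unclass(M)[, "Q"]
    all(against_q["Q"] > against_q[c("C", "D")])
  }
  for (b in seq(1.05, 2, length.out = 20)) {
    for (g in seq(0, pi / 2, length.out = 20)) {
      rep <- q_equilibrium_analysis(game_spec(b, g))
      expect_identical(rep$q_strict_ne,
                       brute_strict_ne(qpd_matrix(game_spec(b, g))))
    }
  }
  # gamma = 0: Q is C, D is the PD equilibrium
  expect_false(q_equilibrium_analysis(game_spec(1.3, 0))$q_strict_ne)
  # exact boundary b cos^2 gamma = 1 is not strict
  expect_false(q_equilibrium_analysis(game_spec(2, pi / 4))$q_strict_ne)
  # above threshold: strict NE with closed-form threshold
  rep <- q_equilibrium_analysis(game_spec(1.5, pi / 2))
  expect_true(rep$q_strict_ne)
  expect_true(rep$q_dominates_d_in_subgame)
  expect_equal(rep$gamma_threshold, acos(1 / sqrt(1.5)), tolerance = 1e-12)
  expect_equal(rep$gamma_threshold, 0.6155, tolerance = 1e-4)
})

test_that("payoff matrices round-trip through labelled CSV", {
  M <- qpd_matrix(game_spec(1.9, 0.7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_payoff_csv(M, path)
  expect_equal(unclass(read_payoff_csv(path)), unclass(M))
})
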