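# Traveling-wave reduction, residual assembly and constraint derivation.

test_that("the wave ODE residual vanishes on constant steady states", {
  p <- generic_params()
  ode <- reduce_to_wave_ode(p, wave_frame(0.7))
  ss <- boundary_steady_states(p)
  for (i in seq_len(nrow(ss))) {
    r <- ode(ss$u[i], 0, 0, ss$v[i], 0, 0, ss$w[i], 0, 0)
    expect_lt(max(abs(unlist(r))), 1e-12)
  }
})

test_that("balancing forces N = 2 for quadratic kinetics and flags linear ones", {
  for (eq in 1:3) {
    b <- balance_exponents(eq)
    expect_identical(b$N, 2L)
    expect_true(b$balanced)
  }
  b <- balance_exponents(1, reaction_degree = 1L)
  expect_identical(b$N, Inf)
  expect_false(b$balanced)
})

test_that("assembled residual polynomials match direct ODE evaluation", {
  # random numeric amplitudes and parameters (no constraints imposed):
  # the polynomial route and brute-force evaluation at omega = atanh(Y)
  # must agree because the assembly is an identity, not a solution
  set.seed(11)
  res <- assemble_residual(tanh_ansatz("1-general"))
  for (k in 1:5) {
    vals <- stats::runif(14, 0.2, 2)
    names(vals) <- c("mu", "d1", "d3", "beta1", "beta3", "alpha1", "alpha2",
                     "alpha3", "alpha4", "kappa1", "kappa2", "sigma1",
                     "sigma2", "sigma3")
    p <- dimensionless_params(vals[["d1"]], vals[["d3"]], vals[["beta1"]],
                              vals[["beta3"]], vals[["alpha1"]], vals[["alpha2"]],
                              vals[["alpha3"]], vals[["alpha4"]],
                              vals[["kappa1"]], vals[["kappa2"]])
    ode <- reduce_to_wave_ode(p, wave_frame(vals[["mu"]]))
    Y <- stats::runif(50, -0.99, 0.99)
    direct <- vapply(Y, function(yy) {
      om <- atanh(yy)
      s1 <- vals[["sigma1"]]; s2 <- vals[["sigma2"]]
      u <- function(o) s1 * (1 - tanh(o))^2
      v <- function(o) s2 * (1 - tanh(o))
      w <- function(o) 1 - (1 - tanh(o)) / 2
      r <- ode(u(om), fd_d1(u, om), fd_d2(u, om),
               v(om), fd_d1(v, om), fd_d2(v, om),
               w(om), fd_d1(w, om), fd_d2(w, om))
      unlist(r)
    }, numeric(3))
    poly <- langfronts:::residual_eval(res, vals, z = 1 - Y)
    scale <- max(1, abs(direct))
    expect_lt(max(abs(t(direct) - do.call(cbind, poly))) / scale, 1e-9)
  }
})

test_that("non-integer or unbalanced ansatz exponents are rejected", {
  a <- tanh_ansatz("1-general")
  a$exponents <- c(2.5, 1, 1)
  expect_error(assemble_residual(a), "positive integers")
  a$exponents <- c(3L, 1L, 1L)
  expect_error(assemble_residual(a), "balanced maximum")
})

test_that("zero-amplitude ansatz yields zero residual polynomials", {
  res <- assemble_residual(tanh_ansatz("2"))
  vals <- c(mu = 0.7, d1 = 1, d3 = 1, beta1 = 0, beta3 = 0, alpha1 = 1,
            alpha2 = 1, alpha3 = 1, alpha4 = 1, kappa1 = 1, kappa2 = 1,
            sigma1 = 0, sigma2 = 0, sigma3 = 0)
  out <- langfronts:::residual_eval(res, vals, z = 1 - seq(-0.9, 0.9, by = 0.3))
  expect_lt(max(abs(unlist(out))), 1e-14)
})

test_that("every derived branch drives all residual coefficients to zero", {
  set.seed(4)
  for (case in c("1-general", "1-fixed", "2", "3")) {
    cs <- derive_case_constraints(case)
    expect_true(cs$verification$ok)
    expect_lt(cs$verification$max_residual, 1e-10)
    # fresh random instantiations, full coefficient list
    res <- assemble_residual(tanh_ansatz(case))
    eqs <- c(unlist(res$z_coeffs, recursive = FALSE), res$ansatz$extra_eqs)
    for (k in 1:10) {
      fv <- stats::runif(length(cs$free), 0.3, 2.5); names(fv) <- cs$free
      vals <- instantiate_constraints(cs, fv)
      worst <- max(vapply(eqs, function(e) {
        abs(langfronts:::mp_eval(e, vals)) /
          max(1, langfronts:::mp_eval_abs(e, vals))
      }, 0))
      expect_lt(worst, 1e-10)
    }
  }
})

test_that("the fixed-exponent branch forces speed 10, unit diffusivities and alpha1 = beta1 - 24", {
  cs <- derive_case_constraints("1-fixed")
  v <- instantiate_constraints(cs, c(beta1 = 31, alpha2 = 1.4, alpha3 = 35,
                                     alpha4 = 0.8, kappa2 = 0.3))
  expect_equal(v[["mu"]], 10)
  expect_equal(v[["d1"]], 1)
  expect_equal(v[["d3"]], 1)
  expect_equal(v[["beta1"]] - v[["alpha1"]], 24)
})

test_that("the pulse-w branch forces speed 17/4, beta1 + 16 d1 = 17 and 2 beta3 + 8 d3 = 17", {
  cs <- derive_case_constraints("2")
  set.seed(8)
  for (k in 1:5) {
    fv <- stats::runif(length(cs$free), 0.3, 2); names(fv) <- cs$free
    v <- instantiate_constraints(cs, fv)
    expect_equal(4 * v[["mu"]], 17)
    expect_equal(v[["beta1"]] + 16 * v[["d1"]], 17, tolerance = 1e-12)
    expect_equal(2 * v[["beta3"]] + 8 * v[["d3"]], 17, tolerance = 1e-10)
    expect_equal(v[["sigma3"]], (17 - 40 * v[["d1"]]) / (4 * v[["alpha1"]]),
                 tolerance = 1e-12)
  }
})

test_that("the corner-connecting branch forces alpha2 = 0 and mu = alpha3/4", {
  cs <- derive_case_constraints("3")
  v <- instantiate_constraints(cs, c(d1 = 0.25, alpha1 = 1.5, alpha3 = 28,
                                     alpha4 = 11.5))
  expect_equal(v[["alpha2"]], 0)
  expect_equal(v[["mu"]], v[["alpha3"]] / 4)
  expect_equal(v[["beta1"]], v[["alpha3"]] - 16 * v[["d1"]])
  expect_equal(v[["sigma2"]], (24 - 28) / (2 * (28 - 8)))
})

test_that("derived amplitudes reconcile with the steady-state formulas", {
  for (case in c("1-general", "1-fixed")) {
    cs <- derive_case_constraints(case)
    expect_true(cs$sigma_reconciliation$sigma1_matches)
    expect_true(cs$sigma_reconciliation$sigma2_matches)
  }
})

test_that("the variable-speed branch reproduces the printed coefficient relations", {
  cs <- derive_case_constraints("1-general")
  rfv <- function(s) if (s %in% names(cs$determined)) cs$determined[[s]] else
    langfronts:::rf_new(langfronts:::mp_var(s))
  rzero <- function(a, b) langfronts:::rf_is_zero(langfronts:::rf_sub(a, b))
  c16 <- langfronts:::as_ratfun(16); c4 <- langfronts:::as_ratfun(4)
  c5 <- langfronts:::as_ratfun(5); c2 <- langfronts:::as_ratfun(2)
  c3 <- langfronts:::as_ratfun(3); c6 <- langfronts:::as_ratfun(6)
  # alpha1 = 16 d1 - 4 mu + beta1
  expect_true(rzero(rfv("alpha1"), c16 * rfv("d1") - c4 * rfv("mu") + rfv("beta1")))
  # alpha3 = d3 beta1 / (3 d1)
  expect_true(rzero(rfv("alpha3"), rfv("d3") * rfv("beta1") / (c3 * rfv("d1"))))
  # kappa1 = (5 - 2 mu)/alpha4
  expect_true(rzero(rfv("kappa1"), (c5 - c2 * rfv("mu")) / rfv("alpha4")))
  # sigma1 = 6 d1 / beta1
  expect_true(rzero(rfv("sigma1"), c6 * rfv("d1") / rfv("beta1")))
})

test_that("constraint sets serialize to JSON and back losslessly", {
  for (case in c("1-general", "2")) {
    cs <- derive_case_constraints(case)
    js <- constraints_to_json(cs)
    cs2 <- constraints_from_json(js)
    expect_identical(sort(names(cs2$determined)), sort(names(cs$determined)))
    for (v in names(cs$determined)) {
      d <- langfronts:::rf_sub(cs$determined[[v]], cs2$determined[[v]])
      expect_true(langfronts:::rf_is_zero(d))
    }
  }
})
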