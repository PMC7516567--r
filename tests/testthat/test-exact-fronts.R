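# Closed-form fronts: evaluation, asymptotics, certification.

test_that("the variable-speed front passes through w = 1/2 at omega = 0", {
  f <- build_known_front("1-general")
  expect_equal(evaluate_front(f, 0, 0)$w, 0.5)
  expect_equal(evaluate_front(f, 2, 2 * f$mu)$w, 0.5)
})

test_that("fronts translate exactly: f(t, x) = f(0, x - mu t)", {
  for (case in c("1-general", "2", "3")) {
    f <- build_known_front(case)
    x <- seq(-6, 6, by = 0.37)
    a <- evaluate_front(f, 1.3, x)
    b <- evaluate_front(f, 0, x - f$mu * 1.3)
    expect_equal(a[c("u", "v", "w")], b[c("u", "v", "w")], tolerance = 1e-14)
  }
})

test_that("the variable-speed front is monotone and bounded, without overflow", {
  f <- build_known_front("1-general")
  x <- seq(-12, 12, length.out = 100)
  ev <- evaluate_front(f, 0, x)
  expect_true(all(diff(ev$u) < 0))
  expect_true(all(diff(ev$v) < 0))
  expect_true(all(diff(ev$w) > 0))
  far <- evaluate_front(f, 0, c(-700, 700))
  expect_true(all(is.finite(unlist(far[c("u", "v", "w")]))))
  a <- asymptotic_states(f)
  expect_equal(max(ev$u), a$left[["u"]], tolerance = 1e-6)
})

test_that("asymptotic states match the designated steady-state pairs", {
  # variable-speed family: left = mixed uv state, right = (0,0,1)
  f <- build_known_front("1-general")
  a <- asymptotic_states(f)
  expect_equal(unname(a$right), c(0, 0, 1))
  p <- f$params
  den <- p$beta1 + p$kappa2 * p$alpha2^2
  expect_equal(a$left[["u"]], (p$beta1 + p$alpha2) / den, tolerance = 1e-12)
  expect_equal(a$left[["u"]], 24 * p$d1 / p$beta1, tolerance = 1e-12)
  expect_equal(a$left[["v"]], p$beta1 * (1 - p$kappa2 * p$alpha2) / den,
               tolerance = 1e-12)
  expect_equal(a$left[["w"]], 0)
  # pulse family: right limit is full extinction
  f2 <- build_known_front("2")
  expect_equal(unname(asymptotic_states(f2)$right), c(0, 0, 0))
  # corner-connecting family: (1,1,0) -> (0,1,0)
  f3 <- build_known_front("3")
  expect_equal(unname(asymptotic_states(f3)$left), c(1, 1, 0))
  expect_equal(unname(asymptotic_states(f3)$right), c(0, 1, 0))
  # profile values at omega = +-30 sit on those states to 1e-10
  for (f in list(build_known_front("1-general"), f2, f3)) {
    a <- asymptotic_states(f)
    ev <- evaluate_front(f, 0, c(-30, 30))
    expect_lt(max(abs(unlist(ev[1, c("u", "v", "w")]) - a$left)), 1e-10)
    expect_lt(max(abs(unlist(ev[2, c("u", "v", "w")]) - a$right)), 1e-10)
  }
})

test_that("certification: valid fronts at rounding level, perturbations detected", {
  for (case in c("1-general", "1-fixed", "2", "3")) {
    f <- build_known_front(case)
    expect_lt(certify_residual(f), 1e-10)
  }
  # a constant steady-state profile is a trivial exact solution
  f <- build_known_front("1-general")
  fc <- f
  fc$coeffs <- list(u = 0, v = 0, w = 1)
  expect_lt(certify_residual(fc), 1e-14)
  # a 1% perturbation of beta1 must be flagged
  fp <- f
  fp$params$beta1 <- fp$params$beta1 * 1.01
  expect_gt(certify_residual(fp), 1e-4)
})

test_that("certification agrees with brute-force finite differencing", {
  set.seed(21)
  for (case in c("1-general", "1-fixed", "2", "3")) {
    f <- build_known_front(case)
    omega <- stats::runif(100, -8, 8)
    expect_lt(fd_wave_residual(f, omega), 1e-8)
  }
})

test_that("inadmissible inputs are rejected with the violated condition named", {
  # beta1 >= 24 d1 makes the v amplitude negative in the variable-speed
  # family; mu = 2.6 gives beta1 > 24 d1 through the derived relations
  expect_error(build_front("1-general", mu = 2.6, d1 = 0.3, d3 = 2,
                           alpha2 = 1, alpha4 = 1),
               "inadmissible|positive")
  # missing parameter
  expect_error(build_front("1-general", mu = 1.5), "requires free parameters")
  # unknown parameter
  expect_error(build_front("3", d1 = .25, alpha1 = 1, alpha3 = 28,
                           alpha4 = 12, mu = 3), "unknown parameters")
})

test_that("the v-correction of the corner-connecting family vanishes at alpha3 = 24", {
  cs <- derive_case_constraints("3")
  v <- instantiate_constraints(cs, c(d1 = 0.25, alpha1 = 1.5, alpha3 = 24,
                                     alpha4 = 10))
  expect_equal(v[["sigma2"]], 0)
})

test_that("random admissible fronts certify across all families", {
  set.seed(31)
  for (case in c("1-general", "1-fixed", "2", "3")) {
    for (fp in sample_front_params(case, n = 5)) {
      f <- do.call(build_front, c(list(case = case), as.list(fp)))
      expect_lt(certify_residual(f), 1e-10)
      a <- asymptotic_states(f)
      for (s in a) {
        r <- reaction_terms(s[["u"]], s[["v"]], s[["w"]], f$params)
        expect_lt(max(abs(unlist(r))), 1e-10)
      }
    }
  }
})

test_that("front CSV export writes the t,x,u,v,w table and metadata sidecar", {
  f <- build_known_front("1-general")
  path <- file.path(tempdir(), "front.csv")
  export_front_csv(f, path, t = c(0, 1), x = seq(-4, 8, length.out = 25))
  tab <- utils::read.csv(path)
  expect_identical(names(tab), c("t", "x", "u", "v", "w"))
  expect_identical(nrow(tab), 50L)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_identical(meta$case, "1-general")
  expect_equal(meta$mu, f$mu)
})
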