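# Positivity-oriented parameter selection.

test_that("the forward selection reproduces the illustrative parameter set", {
  p <- select_remark4(mu = 3/2, epsilon = 1, d = 2)
  expect_equal(attr(p, "alpha"), 5)      # (5 - 2 mu) d + epsilon = 2*2 + 1
  expect_equal(p$alpha2, 5); expect_equal(p$alpha4, 5)
  expect_equal(attr(p, "G"), 1)          # G = epsilon by construction
  expect_true(attr(p, "report")$pass)
  # minimal admissible d at mu = 3/2, epsilon = 1 is (3+1)/(3-1) = 2
  expect_error(select_remark4(mu = 3/2, epsilon = 1, d = 1.99), "d3-bound")
  expect_silent(suppressWarnings(select_remark4(mu = 3/2, epsilon = 1, d = 2)))
})

test_that("forward-selection preconditions carry named diagnostics", {
  expect_error(select_case_i(mu = 0.4, epsilon = 0.5, d3 = 5, d1 = 5), "mu-range")
  expect_error(select_case_i(mu = 2.6, epsilon = 0.5, d3 = 5, d1 = 5), "mu-range")
  expect_error(select_case_i(mu = 1.5, epsilon = -1, d3 = 5, d1 = 5),
               "epsilon-range")
  expect_error(select_case_i(mu = 1.5, epsilon = 0.5, d3 = 1, d1 = 5), "d3-bound")
  expect_error(select_case_i(mu = 1.5, epsilon = 0.5, d3 = 3, d1 = 0.1), "d1-bound")
  expect_warning(select_case_i(mu = 2, epsilon = 1.5, d3 = 4, d1 = 2), "not small")
})

test_that("a mid-range forward selection passes the full positivity check", {
  p <- select_remark4(mu = 2, epsilon = 0.5, d = 2)
  expect_equal(attr(p, "alpha"), 2.5)
  rep <- attr(p, "report")
  expect_true(rep$pass)
  expect_true(all(rep$checks$ok))
})

test_that("the backward selection fixes alpha2 = 24 d1 and its defaults match the illustration", {
  p <- select_case_ii(d1 = 1/2, d3 = 1/2, mu = -5)
  expect_equal(p$alpha2, 12)
  expect_equal(p$alpha4, 12)   # 1.6 x lower threshold (5 - 2 mu) d3 = 7.5
  expect_equal(p$kappa1, (5 - 2 * (-5)) / 12)
  expect_true(attr(p, "report")$pass)
  expect_error(select_case_ii(d1 = 1/2, d3 = 1.2, mu = -5), "d3-range")
  expect_error(select_case_ii(d1 = 1/2, d3 = 1/2, mu = -0.3), "mu-bound")
  expect_error(select_case_ii(d1 = 1/2, d3 = 1/2, mu = -5, alpha4 = 7),
               "alpha4-bound")
})

test_that("the admissible alpha4 interval has the exact beta1 lower threshold", {
  iv <- admissible_alpha4_interval(1/2, 1/2, -5)
  expect_equal(iv$lower, (5 - 2 * (-5)) * 0.5, tolerance = 1e-6)
  expect_true(iv$upper > iv$lower)
  # beta3 changes sign at the upper end
  cs <- derive_case_constraints("1-general")
  eps <- 1e-4
  if (is.finite(iv$upper)) {
    lo <- instantiate_constraints(cs, c(mu = -5, d1 = .5, d3 = .5, alpha2 = 12,
                                        alpha4 = iv$upper * (1 - eps)))
    hi <- instantiate_constraints(cs, c(mu = -5, d1 = .5, d3 = .5, alpha2 = 12,
                                        alpha4 = iv$upper * (1 + eps)))
    expect_gt(lo[["beta3"]], 0)
    expect_lt(hi[["beta3"]], 0)
  }
})

test_that("validate_positivity reports DLVS degeneracy and negative-v violations", {
  p0 <- dimensionless_params(d1 = 1, d3 = 1, beta1 = 1, beta3 = 1,
                             alpha1 = 0, alpha2 = 1, alpha3 = 0, alpha4 = 1,
                             kappa1 = 1, kappa2 = 1, check_degeneracy = FALSE)
  rep <- validate_positivity(p0, case = "1-general", mu = 1.5)
  expect_false(rep$pass)
  expect_true(any(grepl("alpha1 \\+ alpha3", rep$violations)))
  # beta1 >= 24 d1: negative-v diagnostic
  p1 <- select_remark4(mu = 3/2, epsilon = 1, d = 2)
  p1$beta1 <- 24 * p1$d1 + 1
  rep1 <- validate_positivity(p1, case = "1-general", mu = 3/2)
  expect_false(rep1$pass)
  expect_true(any(grepl("v >= 0", rep1$violations)))
})

test_that("G = epsilon holds exactly and boundary sharpness bites below the d3 bound", {
  set.seed(5)
  for (k in 1:20) {
    mu <- stats::runif(1, 0.6, 2.4); eps <- stats::runif(1, 0.1, 0.95)
    d3 <- (2 * mu + eps) / (2 * mu - 1) * stats::runif(1, 1, 2)
    al <- (5 - 2 * mu) * d3 + eps
    d1 <- max((4 * mu + al) / 40, al / 24) * stats::runif(1, 1.05, 2)
    p <- select_case_i(mu, eps, d3, d1)
    expect_equal(attr(p, "G"), eps, tolerance = 1e-12)
    expect_true(attr(p, "report")$pass)
  }
  # taking d3 just below the bound violates a precondition for some mu:
  # asserted as an existence statement over a scan
  violated <- FALSE
  for (mu in seq(0.6, 2.4, by = 0.2)) {
    eps <- 0.5
    d3 <- 0.99 * (2 * mu + eps) / (2 * mu - 1)
    got <- tryCatch({ select_case_i(mu, eps, d3, d1 = 100); FALSE },
                    error = function(e) TRUE)
    violated <- violated || got
  }
  expect_true(violated)
})

test_that("random selections in both regimes produce certified fronts", {
  set.seed(6)
  for (k in 1:10) {
    mu <- stats::runif(1, 0.6, 2.4); eps <- stats::runif(1, 0.1, 0.95)
    d3 <- (2 * mu + eps) / (2 * mu - 1) * stats::runif(1, 1, 2.5)
    al <- (5 - 2 * mu) * d3 + eps
    d1 <- max((4 * mu + al) / 40, al / 24) * stats::runif(1, 1.05, 2.5)
    p <- select_case_i(mu, eps, d3, d1)
    f <- build_front("1-general", mu = mu, d1 = p$d1, d3 = p$d3,
                     alpha2 = p$alpha2, alpha4 = p$alpha4)
    expect_lt(certify_residual(f), 1e-10)
  }
  done <- 0L
  while (done < 5L) {
    d1 <- stats::runif(1, 0.1, 0.9); d3 <- stats::runif(1, 0.1, 0.9)
    mu <- d3 / (2 * (d3 - 1)) * stats::runif(1, 1.2, 6)
    p <- tryCatch(select_case_ii(d1, d3, mu),
                  selection_error = function(e) NULL)
    if (is.null(p)) next   # infeasible (d1, d3, mu) triple: reported upstream
    done <- done + 1L
    f <- build_front("1-general", mu = mu, d1 = d1, d3 = d3,
                     alpha2 = p$alpha2, alpha4 = p$alpha4)
    expect_lt(certify_residual(f), 1e-10)
  }
})
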