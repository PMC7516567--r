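# Parameter spaces, nondimensionalization, reaction terms, steady states.

test_that("nondimensionalize reproduces the defining coefficient ratios", {
  # identity scaling
  p <- dimensional_params(1, 1, 1, 1, 1, 1, 1, 1, 1,
                          c31 = 1, c12 = 0, c13 = 1, c32 = 0)
  q <- nondimensionalize(p)
  expect_equal(unclass(q)[c("d1", "d3", "beta1", "beta3", "kappa1", "kappa2",
                            "alpha1", "alpha3", "alpha2", "alpha4")],
               list(d1 = 1, d3 = 1, beta1 = 1, beta3 = 1, kappa1 = 1,
                    kappa2 = 1, alpha1 = 1, alpha3 = 1, alpha2 = 0, alpha4 = 0))
  # diffusivity ratios d1 = lambda1/lambda2, d3 = lambda3/lambda2
  p <- dimensional_params(2, 1, 3, 1, 1, 1, 1, 1, 1, c31 = 1, c13 = 1)
  q <- nondimensionalize(p)
  expect_equal(q$d1, 2); expect_equal(q$d3, 3)
  # growth and conversion ratios: beta1 = a1/a2, alpha2 = c12 K2/a2
  p <- dimensional_params(1, 1, 1, a1 = 2, a2 = 4, a3 = 1, K1 = 1, K2 = 8,
                          K3 = 1, c31 = 1, c12 = 1, c13 = 1)
  q <- nondimensionalize(p)
  expect_equal(q$beta1, 0.5); expect_equal(q$alpha2, 2)
  expect_equal(attr(q, "time_scale"), 1 / 4)
  expect_equal(attr(q, "length_scale"), sqrt(1 / 4))
})

test_that("degenerate DLVS inputs are rejected with a specific diagnostic", {
  expect_error(dimensional_params(1, 1, 1, 1, 1, 1, 1, 1, 1,
                                  c31 = 0, c13 = 0, c12 = 1),
               "Lotka-Volterra")
  expect_error(dimensionless_params(1, 1, 1, 1, alpha1 = 0, alpha2 = 1,
                                    alpha3 = 0, alpha4 = 1, kappa1 = 1,
                                    kappa2 = 1),
               "DLVS")
  expect_error(dimensional_params(1, -1, 1, 1, 1, 1, 1, 1, 1, c13 = 1),
               "positive")
})

test_that("reaction terms vanish at the designated states", {
  p <- generic_params()
  z <- reaction_terms(0, 0, 0, p)
  expect_identical(unlist(z), c(du = 0, dv = 0, dw = 0))
  z <- reaction_terms(0, 0, 1, p)
  expect_identical(unlist(z), c(du = 0, dv = 0, dw = 0))
  # (1,1,0) is steady exactly when alpha2 = 0
  p0 <- dimensionless_params(d1 = 1, d3 = 1, beta1 = 1, beta3 = 1,
                             alpha1 = 0.4, alpha2 = 0, alpha3 = 0.6,
                             alpha4 = 0.2, kappa1 = 1, kappa2 = 1)
  z <- reaction_terms(1, 1, 0, p0)
  expect_equal(max(abs(unlist(z))), 0)
  z <- reaction_terms(1, 1, 0, p)  # alpha2 > 0: not steady
  expect_gt(max(abs(unlist(z))), 1e-3)
})

test_that("the six boundary steady states zero the kinetics to 1e-12", {
  for (p in list(generic_params(),
                 select_remark4(mu = 3/2, epsilon = 1, d = 2),
                 select_case_ii(1/2, 1/2, -5))) {
    ss <- boundary_steady_states(p)
    expect_identical(nrow(ss), 6L)
    expect_lt(max(ss$max_residual), 1e-12)
    expect_true(all(c("origin", "center", "w_corner", "u_corner",
                      "uv_mixed", "vw_mixed") %in% ss$role))
    expect_true(all(ss[ss$role == "center", c("u", "v", "w")] == c(0, 1, 0)))
    expect_true(all(ss[ss$role == "u_corner", c("u", "v", "w")] == c(1, 0, 0)))
  }
})

test_that("states with negative components are flagged, not dropped", {
  # kappa2 * alpha2 > 1 makes the mixed uv state dip negative in v
  p <- dimensionless_params(d1 = 1, d3 = 1, beta1 = 1, beta3 = 1,
                            alpha1 = 1, alpha2 = 2, alpha3 = 1, alpha4 = 0.1,
                            kappa1 = 1, kappa2 = 1)
  ss <- boundary_steady_states(p)
  expect_identical(nrow(ss), 6L)
  expect_false(ss$admissible[ss$role == "uv_mixed"])
  expect_lt(max(ss$max_residual), 1e-12)
})

test_that("the u/w swap groups the six states into four classes", {
  ss <- boundary_steady_states(generic_params())
  cls <- equivalence_classes(ss)
  expect_identical(cls$n_classes, 4L)
  expect_length(cls$duplicates, 0L)
  sizes <- sort(lengths(cls$classes))
  expect_identical(sizes, c(1L, 1L, 2L, 2L))
  # restricted to the four corner states: three classes
  cls4 <- equivalence_classes(ss[1:4, ])
  expect_identical(cls4$n_classes, 3L)
  # degenerate parameters collapse the mixed uv state onto (1,0,0):
  # the coincidence is reported
  pd <- dimensionless_params(d1 = 1, d3 = 1, beta1 = 2, beta3 = 1,
                             alpha1 = 1, alpha2 = 1, alpha3 = 1, alpha4 = 0,
                             kappa1 = 1, kappa2 = 1)
  ssd <- boundary_steady_states(pd)
  clsd <- equivalence_classes(ssd)
  expect_true(any(grepl("uv_mixed", clsd$duplicates)))
})

test_that("parameter configs round-trip through YAML and JSON", {
  p <- generic_params()
  attr(p, "mu") <- 1.25
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("params.", ext))
    write_params(p, path)
    q <- read_params(path)
    expect_s3_class(q, "dimensionless_params")
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
    expect_equal(attr(q, "mu"), 1.25)
  }
  pd <- dimensional_params(2, 1, 3, 1, 2, 1, 4, 8, 5,
                           c31 = .5, c12 = .25, c13 = .3, c32 = .4)
  path <- file.path(tempdir(), "dim.yaml")
  write_params(pd, path)
  expect_equal(unclass(read_params(path)), unclass(pd), tolerance = 1e-12)
})

test_that("simulating the dimensional and rescaled systems agrees after mapping", {
  pd <- dimensional_params(lambda1 = 2, lambda2 = 1.5, lambda3 = 3,
                           a1 = 2, a2 = 4, a3 = 1, K1 = 2, K2 = 8, K3 = 5,
                           c31 = 0.5, c12 = 0.25, c13 = 0.3, c32 = 0.4)
  q <- nondimensionalize(pd)
  Ts <- attr(q, "time_scale"); Ls <- attr(q, "length_scale")
  gq <- spatial_grid(-8, 8, 161)
  u0 <- exp(-gq$x^2 / 4); v0 <- 0.4 + 0.2 * tanh(gq$x); w0 <- 1 / (1 + exp(gq$x))
  tq <- c(0, 0.2, 0.4)
  trq <- rd_integrate(q, list(u = u0, v = v0, w = w0), gq, tq)
  # dimensional run on the mapped grid/times with scaled fields
  gd <- spatial_grid(-8 * Ls, 8 * Ls, 161)
  trd <- rd_integrate(pd, list(u = pd$K1 * u0, v = pd$K2 * v0, w = pd$K3 * w0),
                      gd, tq * Ts)
  dev <- max(abs(trd$u / pd$K1 - trq$u), abs(trd$v / pd$K2 - trq$v),
             abs(trd$w / pd$K3 - trq$w))
  expect_lt(dev, 1e-6)
})
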