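# Positivity-oriented parameter selection for the variable-speed front
# family ("1-general").
#
# The derived coefficients beta1, beta3, alpha1, alpha3, kappa1, kappa2 of
# that family are rational functions of the free inputs (mu, d1, d3,
# alpha2, alpha4); a usable front needs every one of them positive along
# with the profile itself.  With the simplification alpha2 = alpha4 = alpha
# the sign analysis runs through the auxiliaries
#   F = 10 d1 - mu + 2 alpha,   G = 2 mu d3 - 5 d3 + alpha,
# in terms of which beta1 = 24 d1 - alpha (1 - 2 G/F).  Admissible forward
# fronts need F > 0, G > 0 and G/F < 1/2.

#' Validate positivity of a parameter set for a front family
#'
#' Checks that a fully instantiated parameter set satisfies its family's
#' constraint set and that every derived coefficient and profile component
#' is admissible: positive `d1, d3, beta1, beta3, kappa1, kappa2`,
#' nonnegative `alpha` coefficients with `alpha1 + alpha3 > 0` (otherwise
#' the DLVS degeneracy is flagged), positive amplitudes, and the
#' family-specific component conditions (`beta1 < 24 d1`, i.e. `v >= 0`,
#' and `kappa2 alpha2 <= 1`, i.e. `V0 >= 0`, for the Case-1 families;
#' `alpha2 = 0` for family "3").  When `alpha2 = alpha4` and a speed is
#' available, the auxiliaries `F`, `G` and the bound `G/F < 1/2` are
#' reported as well.
#'
#' @param p a [dimensionless_params()] object (created with
#'   `check_degeneracy = FALSE` if you want the DLVS case reported rather
#'   than refused at construction).
#' @param case front family label.
#' @param mu wave speed; defaults to the `mu` attribute of `p`.
#' @param values optional full symbol instantiation (as produced by
#'   [instantiate_constraints()]); reconstructed from `p` when missing.
#' @param tol consistency tolerance between `p` and the constraint set.
#' @return An object of class `positivity_report` with elements `pass`,
#'   `violations` (character), and `checks` (data frame of item, value,
#'   requirement, ok).
#' @export
validate_positivity <- function(p, case = "1-general", mu = attr(p, "mu"),
                                values = NULL, tol = 1e-8) {
  stopifnot(inherits(p, "dimensionless_params"))
  case <- match.arg(case, .case_labels)
  checks <- list()
  add <- function(item, value, req, ok) {
    checks[[length(checks) + 1L]] <<- data.frame(item = item, value = value,
                                                 requirement = req, ok = ok)
  }
  if (p$alpha1 + p$alpha3 <= 1e-12)
    add("alpha1 + alpha3", p$alpha1 + p$alpha3,
        "> 0 (DLVS degeneracy: alpha1 = alpha3 = 0 reduces the model to the diffusive Lotka-Volterra system)",
        FALSE)
  else
    add("alpha1 + alpha3", p$alpha1 + p$alpha3, "> 0", TRUE)
  for (nm in c("d1", "d3", "beta1", "beta3", "kappa1", "kappa2"))
    add(nm, p[[nm]], "> 0", p[[nm]] > 0)
  for (nm in c("alpha1", "alpha3", "alpha4"))
    add(nm, p[[nm]], ">= 0", p[[nm]] >= 0)
  if (case == "3")
    add("alpha2", p$alpha2, "= 0 (required by family 3)", abs(p$alpha2) <= 1e-10)
  else
    add("alpha2", p$alpha2, ">= 0", p$alpha2 >= 0)
  if (is.null(values)) {
    cs <- derive_case_constraints(case)
    fv <- vapply(cs$free, function(s) if (s == "mu") {
      if (is.null(mu)) NA_real_ else mu
    } else p[[s]], 0)
    names(fv) <- cs$free
    if (anyNA(fv))
      stop("validate_positivity needs the wave speed mu for case ", case)
    values <- instantiate_constraints(cs, fv)
    # consistency of p with the derived constraint set
    for (nm in .DIMENSIONLESS_KEYS) {
      if (!(nm %in% names(values))) next
      dev <- abs(values[[nm]] - p[[nm]]) / max(1, abs(p[[nm]]))
      add(paste0(nm, " (constraint consistency)"), dev, paste("<", tol), dev < tol)
    }
  }
  sig <- intersect(c("sigma1", "sigma2", "sigma3"), names(values))
  for (nm in sig) {
    if (case == "3" && nm == "sigma2")
      add("1 + sigma2 (v >= 0)", 1 + values[[nm]], ">= 0", 1 + values[[nm]] >= 0)
    else
      add(nm, values[[nm]], "> 0", values[[nm]] > 0)
  }
  if (case == "1-general")
    add("24 d1 - beta1 (v >= 0)", 24 * p$d1 - p$beta1, "> 0 (negative-v otherwise)",
        24 * p$d1 - p$beta1 > 0)
  if (case %in% c("1-general", "1-fixed", "2"))
    add("1 - kappa2 alpha2 (V0 >= 0)", 1 - p$kappa2 * p$alpha2, ">= 0",
        1 - p$kappa2 * p$alpha2 >= 0)
  if (case == "1-general" && !is.null(mu) &&
      isTRUE(abs(p$alpha2 - p$alpha4) < 1e-12)) {
    al <- p$alpha2
    FF <- 10 * p$d1 - mu + 2 * al
    GG <- 2 * mu * p$d3 - 5 * p$d3 + al
    add("F = 10 d1 - mu + 2 alpha", FF, "> 0", FF > 0)
    add("G = 2 mu d3 - 5 d3 + alpha", GG, "> 0", GG > 0)
    add("G/F", GG / FF, "< 1/2", GG / FF < 1/2)
  }
  checks <- do.call(rbind, checks)
  viol <- checks$item[!checks$ok]
  structure(list(pass = !length(viol),
                 violations = as.character(viol),
                 checks = checks, case = case, mu = mu),
            class = "positivity_report")
}

#' @export
print.positivity_report <- function(x, ...) {
  cat("Positivity report, case ", x$case,
      if (!is.null(x$mu)) paste0(", mu = ", format(x$mu)), ": ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  if (!x$pass)
    cat(" violated:", paste(x$violations, collapse = "; "), "\n")
  invisible(x)
}

.sel_err <- function(code, msg) stop(structure(
  class = c("selection_error", "error", "condition"),
  list(message = paste0("[", code, "] ", msg), call = sys.call(-1))))

#' Select admissible forward-front parameters (Case i: mu > 0)
#'
#' Implements the positivity algorithm for rightward fronts of the
#' variable-speed family: fix a speed `mu` in `(1/2, 5/2)` and a small
#' slack `epsilon > 0`; take any `d3` with
#' `d3 >= (2 mu + epsilon)/(2 mu - 1)`; set
#' `alpha2 = alpha4 = alpha = (5 - 2 mu) d3 + epsilon` (equivalently
#' `G = epsilon`); finally take `d1` large enough that
#' `40 d1 > 4 mu + (5 - 2 mu) d3 + epsilon` and
#' `24 d1 > (5 - 2 mu) d3 + epsilon`.  Every derived coefficient of the
#' constraint set is then positive.
#'
#' @param mu wave speed, in `(1/2, 5/2)`.
#' @param epsilon positive slack; values below 1 keep the construction in
#'   its "sufficiently small" regime (larger values are allowed with a
#'   warning).
#' @param d3,d1 diffusivity ratios satisfying the bounds above.
#' @return A [dimensionless_params()] object with attributes `mu`,
#'   `epsilon`, `alpha`, `F`, `G` and `report` (the positivity report).
#' @export
select_case_i <- function(mu, epsilon, d3, d1) {
  if (!(mu > 1/2 && mu < 5/2))
    .sel_err("mu-range", sprintf("mu = %g outside (1/2, 5/2)", mu))
  if (epsilon <= 0)
    .sel_err("epsilon-range", sprintf("epsilon = %g must be positive", epsilon))
  if (epsilon > 1)
    warning("epsilon = ", epsilon,
            " is not small; the construction still applies but check the report")
  d3min <- (2 * mu + epsilon) / (2 * mu - 1)
  if (d3 < d3min)
    .sel_err("d3-bound", sprintf("d3 = %g below (2 mu + epsilon)/(2 mu - 1) = %g",
                                 d3, d3min))
  alpha <- (5 - 2 * mu) * d3 + epsilon
  if (!(40 * d1 > 4 * mu + alpha && 24 * d1 > alpha))
    .sel_err("d1-bound", sprintf(
      "d1 = %g too small: need 40 d1 > %g and 24 d1 > %g",
      d1, 4 * mu + alpha, alpha))
  .finish_selection(mu, d1, d3, alpha2 = alpha, alpha4 = alpha,
                    epsilon = epsilon)
}

#' Simplified selection with equal diffusivities
#'
#' The special case `alpha2 = alpha4 = alpha`, `d1 = d3 = d` of
#' [select_case_i()]: the algorithm reduces to
#' `d >= (2 mu + epsilon)/(2 mu - 1)` and `alpha = (5 - 2 mu) d + epsilon`.
#'
#' @param mu wave speed in `(1/2, 5/2)`.
#' @param epsilon positive slack.
#' @param d common diffusivity ratio.
#' @return As [select_case_i()].
#' @export
select_remark4 <- function(mu, epsilon, d) {
  if (epsilon > 0 && mu > 1/2 && mu < 5/2 &&
      d < (2 * mu + epsilon) / (2 * mu - 1))
    .sel_err("d3-bound", sprintf("d = %g below (2 mu + epsilon)/(2 mu - 1) = %g",
                                 d, (2 * mu + epsilon) / (2 * mu - 1)))
  select_case_i(mu, epsilon, d3 = d, d1 = d)
}

#' Admissible `alpha4` interval for backward fronts (Case ii: mu < 0)
#'
#' With `alpha2 = 24 d1` fixed, positivity of every derived coefficient of
#' the variable-speed family holds on an interval of `alpha4` values whose
#' lower end is determined by `beta1 > 0` (exactly
#' `alpha4 > (5 - 2 mu) d3`) and `beta3 > 0`.  The interval is determined
#' numerically from the positivity report by root-finding on the
#' minimum-margin function; an infinite upper end means no positivity
#' failure was found up to `cap`.
#'
#' @param d1,d3 diffusivity ratios in `(0, 1)`.
#' @param mu negative wave speed with `mu < d3/(2 (d3 - 1))`.
#' @param cap numeric search cap for the upper end.
#' @return A list with `lower`, `upper`.
#' @export
admissible_alpha4_interval <- function(d1, d3, mu, cap = 1e8) {
  margin <- function(a4) {
    cs <- derive_case_constraints("1-general")
    v <- instantiate_constraints(cs, c(mu = mu, d1 = d1, d3 = d3,
                                       alpha2 = 24 * d1, alpha4 = a4))
    min(v[["beta1"]], v[["beta3"]], v[["alpha1"]], v[["alpha3"]],
        v[["kappa1"]], v[["kappa2"]], v[["sigma1"]], v[["sigma2"]],
        1 - v[["kappa2"]] * v[["alpha2"]])
  }
  lo0 <- (5 - 2 * mu) * d3
  hi <- lo0 * 2
  while (margin(hi) <= 0 && hi < cap) hi <- hi * 2
  if (margin(hi) <= 0)
    .sel_err("alpha4-infeasible", sprintf(
      "no alpha4 below %g makes every derived coefficient positive for d1 = %g, d3 = %g, mu = %g",
      cap, d1, d3, mu))
  lower <- stats::uniroot(margin, c(lo0 * 0.5, hi), tol = 1e-12)$root
  upper <- if (margin(cap) > 0) Inf else
    stats::uniroot(margin, c(hi, cap), tol = 1e-10)$root
  list(lower = lower, upper = upper)
}

#' Select admissible backward-front parameters (Case ii: mu < 0)
#'
#' For leftward fronts the analysis fixes `alpha2 = 24 d1` and requires
#' `d3 < 1` and `mu < d3/(2 (d3 - 1))` (a negative bound); `alpha4` is then
#' chosen inside the admissible interval of
#' [admissible_alpha4_interval()], whose lower end is `(5 - 2 mu) d3` when
#' `beta1` is the binding coefficient.
#'
#' @param d1,d3 diffusivity ratios in `(0, 1)`.
#' @param mu negative wave speed with `mu < d3/(2 (d3 - 1))`.
#' @param alpha4 conversion coefficient; when `NULL`, 1.6 times the lower
#'   threshold is used (comfortably interior to the admissible interval;
#'   with `d1 = d3 = 1/2`, `mu = -5` this reproduces the illustrative
#'   backward-front set `alpha2 = alpha4 = 12`).
#' @return As [select_case_i()].
#' @export
select_case_ii <- function(d1, d3, mu, alpha4 = NULL) {
  if (!(d1 > 0 && d1 < 1))
    .sel_err("d1-range", sprintf("d1 = %g outside (0, 1)", d1))
  if (!(d3 > 0 && d3 < 1))
    .sel_err("d3-range", sprintf("d3 = %g outside (0, 1); d3 < 1 required", d3))
  mubound <- d3 / (2 * (d3 - 1))
  if (!(mu < mubound))
    .sel_err("mu-bound", sprintf("mu = %g must lie below d3/(2(d3-1)) = %g",
                                 mu, mubound))
  iv <- admissible_alpha4_interval(d1, d3, mu)
  if (is.null(alpha4)) alpha4 <- 1.6 * iv$lower
  if (alpha4 <= iv$lower || alpha4 >= iv$upper)
    .sel_err("alpha4-bound", sprintf(
      "alpha4 = %g outside the admissible interval (%g, %g)",
      alpha4, iv$lower, iv$upper))
  .finish_selection(mu, d1, d3, alpha2 = 24 * d1, alpha4 = alpha4,
                    epsilon = NULL)
}

.finish_selection <- function(mu, d1, d3, alpha2, alpha4, epsilon) {
  cs <- derive_case_constraints("1-general")
  vals <- instantiate_constraints(cs, c(mu = mu, d1 = d1, d3 = d3,
                                        alpha2 = alpha2, alpha4 = alpha4))
  p <- dimensionless_params(d1 = vals[["d1"]], d3 = vals[["d3"]],
                            beta1 = vals[["beta1"]], beta3 = vals[["beta3"]],
                            alpha1 = vals[["alpha1"]], alpha2 = vals[["alpha2"]],
                            alpha3 = vals[["alpha3"]], alpha4 = vals[["alpha4"]],
                            kappa1 = vals[["kappa1"]], kappa2 = vals[["kappa2"]])
  attr(p, "mu") <- mu
  if (!is.null(epsilon)) {
    attr(p, "epsilon") <- epsilon
    attr(p, "alpha") <- alpha2
    attr(p, "F") <- 10 * d1 - mu + 2 * alpha2
    attr(p, "G") <- 2 * mu * d3 - 5 * d3 + alpha2
  }
  rep <- validate_positivity(p, case = "1-general", mu = mu, values = vals)
  attr(p, "report") <- rep
  if (!rep$pass)
    stop("internal error: selected parameter set fails positivity: ",
         paste(rep$violations, collapse = "; "))
  p
}
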