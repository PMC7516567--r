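# Model parameter spaces and the reaction kinetics.
#
# The dimensional model tracks three interacting communities of speakers:
# u and w are the two monolingual communities, v the bilingual one.  Each
# component diffuses, grows logistically towards its own carrying capacity,
# and exchanges speakers through bilinear conversion terms: c31*u*w and
# c13*u*w move monolinguals into the bilingual pool, while c12*u*v and
# c32*v*w describe bilinguals reverting to a monolingual community.

.DIMENSIONAL_KEYS <- c("lambda1", "lambda2", "lambda3", "a1", "a2", "a3",
                       "K1", "K2", "K3", "c31", "c12", "c13", "c32")
.DIMENSIONLESS_KEYS <- c("d1", "d3", "beta1", "beta3",
                         "alpha1", "alpha2", "alpha3", "alpha4",
                         "kappa1", "kappa2")
.DEGENERACY_TOL <- 1e-12

#' Dimensional model parameters
#'
#' Bundles the coefficients of the dimensional three-component model:
#' diffusivities `lambda1..lambda3` (area/time), intrinsic growth rates
#' `a1..a3` (1/time), carrying capacities `K1..K3` (frequency units) and
#' nonnegative conversion coefficients `c31, c12, c13, c32`
#' (1/(frequency*time)).  The conversion coefficients `c13` and `c31`
#' must not both vanish: with `c13 = c31 = 0` the model degenerates to the
#' diffusive Lotka-Volterra system (DLVS), which is outside the model class.
#'
#' @param lambda1,lambda2,lambda3 positive diffusivities.
#' @param a1,a2,a3 positive intrinsic growth rates.
#' @param K1,K2,K3 positive carrying capacities.
#' @param c31,c12,c13,c32 nonnegative conversion coefficients.
#' @return An object of class `dimensional_params`.
#' @seealso [nondimensionalize()], [dimensionless_params()]
#' @export
dimensional_params <- function(lambda1, lambda2, lambda3, a1, a2, a3,
                               K1, K2, K3, c31 = 0, c12 = 0, c13 = 0, c32 = 0) {
  p <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
            a1 = a1, a2 = a2, a3 = a3, K1 = K1, K2 = K2, K3 = K3,
            c31 = c31, c12 = c12, c13 = c13, c32 = c32)
  vapply(p, function(x) {
    stopifnot(is.numeric(x), length(x) == 1L, is.finite(x)); 0
  }, 0)
  pos <- c("lambda1", "lambda2", "lambda3", "a1", "a2", "a3", "K1", "K2", "K3")
  bad <- pos[unlist(p[pos]) <= 0]
  if (length(bad))
    stop("dimensional parameters must be positive: ", paste(bad, collapse = ", "))
  nn <- c("c31", "c12", "c13", "c32")
  bad <- nn[unlist(p[nn]) < 0]
  if (length(bad))
    stop("conversion coefficients must be nonnegative: ", paste(bad, collapse = ", "))
  if (p$c13^2 + p$c31^2 <= .DEGENERACY_TOL^2)
    stop("c13 and c31 are both zero: the model degenerates to the diffusive ",
         "Lotka-Volterra system (DLVS), which is excluded")
  structure(p, class = "dimensional_params")
}

#' Dimensionless model parameters
#'
#' The rescaled system measures each component against its own carrying
#' capacity, time against `1/a2` and length against `sqrt(lambda2/a2)`,
#' leaving ten coefficients: diffusivity ratios `d1, d3`, growth-rate
#' ratios `beta1, beta3`, scaled conversion coefficients `alpha1..alpha4`
#' and capacity ratios `kappa1, kappa2`.
#'
#' @param d1,d3 positive diffusivity ratios.
#' @param beta1,beta3 positive growth-rate ratios.
#' @param alpha1,alpha2,alpha3,alpha4 nonnegative scaled conversion
#'   coefficients with `alpha1 + alpha3 > 0` (DLVS degeneracy excluded).
#' @param kappa1,kappa2 positive carrying-capacity ratios.
#' @param check_degeneracy set to `FALSE` to allow `alpha1 = alpha3 = 0`;
#'   such parameter sets reproduce a three-component Lotka-Volterra form and
#'   are accepted only as a regression reference - every validator in the
#'   package rejects them.
#' @return An object of class `dimensionless_params`.
#' @export
dimensionless_params <- function(d1, d3, beta1, beta3,
                                 alpha1, alpha2, alpha3, alpha4,
                                 kappa1, kappa2, check_degeneracy = TRUE) {
  p <- list(d1 = d1, d3 = d3, beta1 = beta1, beta3 = beta3,
            alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3, alpha4 = alpha4,
            kappa1 = kappa1, kappa2 = kappa2)
  vapply(p, function(x) {
    stopifnot(is.numeric(x), length(x) == 1L, is.finite(x)); 0
  }, 0)
  pos <- c("d1", "d3", "beta1", "beta3", "kappa1", "kappa2")
  bad <- pos[unlist(p[pos]) <= 0]
  if (length(bad))
    stop("dimensionless parameters must be positive: ", paste(bad, collapse = ", "))
  al <- c("alpha1", "alpha2", "alpha3", "alpha4")
  bad <- al[unlist(p[al]) < 0]
  if (length(bad))
    stop("alpha coefficients must be nonnegative: ", paste(bad, collapse = ", "))
  if (check_degeneracy && (p$alpha1 + p$alpha3) <= .DEGENERACY_TOL)
    stop("alpha1 + alpha3 vanishes: the system degenerates to the diffusive ",
         "Lotka-Volterra system (DLVS), which is excluded from the model class")
  structure(p, class = "dimensionless_params")
}

#' @export
print.dimensional_params <- function(x, ...) {
  cat("Dimensional three-component RD parameters\n")
  print(round(unlist(x), 6))
  invisible(x)
}

#' @export
print.dimensionless_params <- function(x, ...) {
  cat("Dimensionless three-component RD parameters\n")
  print(round(unlist(x), 6))
  mu <- attr(x, "mu")
  if (!is.null(mu)) cat("wave speed mu =", mu, "\n")
  invisible(x)
}

#' Rescale dimensional parameters to the dimensionless system
#'
#' Applies the rescaling `u -> K1 u`, `v -> K2 v`, `w -> K3 w`,
#' `t -> t/a2`, `x -> sqrt(lambda2/a2) x` and returns the ten coefficients
#' of the dimensionless system, together with the time scale `1/a2` and
#' length scale `sqrt(lambda2/a2)` (as attributes `time_scale` and
#' `length_scale`) needed to convert solver output back to dimensional
#' units.
#'
#' @param p a [dimensional_params()] object.
#' @return A [dimensionless_params()] object with `time_scale` and
#'   `length_scale` attributes.
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "dimensional_params"))
  if (p$a2 <= 0 || p$lambda2 <= 0)
    stop("nondimensionalization requires positive a2 and lambda2")
  out <- dimensionless_params(
    d1 = p$lambda1 / p$lambda2,
    d3 = p$lambda3 / p$lambda2,
    beta1 = p$a1 / p$a2,
    beta3 = p$a3 / p$a2,
    alpha1 = p$c31 * p$K3 / p$a2,
    alpha2 = p$c12 * p$K2 / p$a2,
    alpha3 = p$c13 * p$K1 / p$a2,
    alpha4 = p$c32 * p$K2 / p$a2,
    kappa1 = p$K3 / p$K2,
    kappa2 = p$K1 / p$K2)
  attr(out, "time_scale") <- 1 / p$a2
  attr(out, "length_scale") <- sqrt(p$lambda2 / p$a2)
  out
}

#' Reaction terms of the dimensionless system
#'
#' Evaluates the kinetic part of the dimensionless model at frequencies
#' `(u, v, w)`:
#' \deqn{f_1 = \beta_1 u(1-u) - \alpha_1 u w + \alpha_2 u v}
#' \deqn{f_2 = v(1-v) + (\kappa_1\alpha_3 + \kappa_2\alpha_1) u w -
#'             (\kappa_2\alpha_2 u + \kappa_1\alpha_4 w) v}
#' \deqn{f_3 = \beta_3 w(1-w) - \alpha_3 u w + \alpha_4 v w}
#' Frequencies are not clamped to `[0, 1]`: the components are scaled by
#' different carrying capacities, and valid fronts can exceed 1.
#'
#' @param u,v,w finite numeric vectors (recycled to a common length).
#' @param p a [dimensionless_params()] object.
#' @return A list with components `du`, `dv`, `dw`.
#' @export
reaction_terms <- function(u, v, w, p) {
  stopifnot(inherits(p, "dimensionless_params"),
            all(is.finite(u)), all(is.finite(v)), all(is.finite(w)))
  list(du = p$beta1 * u * (1 - u) - p$alpha1 * u * w + p$alpha2 * u * v,
       dv = v * (1 - v) + (p$kappa1 * p$alpha3 + p$kappa2 * p$alpha1) * u * w -
         (p$kappa2 * p$alpha2 * u + p$kappa1 * p$alpha4 * w) * v,
       dw = p$beta3 * w * (1 - w) - p$alpha3 * u * w + p$alpha4 * v * w)
}

# reaction terms of the dimensional system (2); used by the solver for the
# rescaling round-trip check
reaction_terms_dimensional <- function(u, v, w, p) {
  stopifnot(inherits(p, "dimensional_params"))
  list(du = p$a1 * u * (1 - u / p$K1) - p$c31 * u * w + p$c12 * u * v,
       dv = p$a2 * v * (1 - v / p$K2) + (p$c13 + p$c31) * u * w -
         (p$c12 * u + p$c32 * w) * v,
       dw = p$a3 * w * (1 - w / p$K3) - p$c13 * u * w + p$c32 * v * w)
}

#' Boundary steady states of the dimensionless system
#'
#' Enumerates the six spatially homogeneous equilibria with
#' `u0 * v0 * w0 = 0`: the extinction state, the three single-community
#' corner states, and the two mixed states in which one monolingual
#' community coexists with the bilingual one.  Interior equilibria (all
#' three components positive) are outside the scope of this enumeration.
#'
#' Each returned state is verified against [reaction_terms()]; a state with
#' a negative component (possible when `kappa2*alpha2 > 1` or
#' `kappa1*alpha4 > 1`) is flagged in the `admissible` column rather than
#' dropped.
#'
#' @param p a [dimensionless_params()] object.
#' @param tol verification tolerance for the reaction terms (pure
#'   arithmetic, no discretization: default `1e-12`).
#' @return A data frame with columns `role`, `u`, `v`, `w`, `admissible`,
#'   `max_residual`.
#' @export
boundary_steady_states <- function(p, tol = 1e-12) {
  stopifnot(inherits(p, "dimensionless_params"))
  den5 <- p$beta1 + p$kappa2 * p$alpha2^2
  den6 <- p$beta3 + p$kappa1 * p$alpha4^2
  states <- rbind(
    origin   = c(0, 0, 0),
    center   = c(0, 1, 0),
    w_corner = c(0, 0, 1),
    u_corner = c(1, 0, 0),
    uv_mixed = c((p$beta1 + p$alpha2) / den5,
                 p$beta1 * (1 - p$kappa2 * p$alpha2) / den5, 0),
    vw_mixed = c(0, p$beta3 * (1 - p$kappa1 * p$alpha4) / den6,
                 (p$beta3 + p$alpha4) / den6))
  res <- reaction_terms(states[, 1], states[, 2], states[, 3], p)
  maxres <- pmax(abs(res$du), abs(res$dv), abs(res$dw))
  if (any(maxres > tol))
    stop("internal error: steady state fails verification (max residual ",
         format(max(maxres)), ")")
  data.frame(role = rownames(states),
             u = states[, 1], v = states[, 2], w = states[, 3],
             admissible = apply(states >= 0, 1L, all),
             max_residual = maxres,
             row.names = NULL)
}

#' Group steady states under the u/w structural swap
#'
#' The first and third equations of the model have the same structure, so
#' the relabelling `u <-> w` (together with the coefficient swap
#' `d1 <-> d3`, `beta1 <-> beta3`, `alpha1 <-> alpha3`, `alpha2 <-> alpha4`,
#' `kappa1 <-> kappa2`) maps the model family onto itself.  Under this swap
#' the six boundary steady states fall into four essentially different
#' classes: the extinction state, the pure-bilingual state, the pair of
#' monolingual corner states, and the pair of mixed states.
#'
#' @param states a data frame as returned by [boundary_steady_states()], or
#'   any data frame with columns `u`, `v`, `w` (a `role` column is used
#'   when present).
#' @param tol tolerance for detecting numerically coincident states.
#' @return A list with `classes` (list of integer row indices), `n_classes`,
#'   and `duplicates` (character notes on states that numerically coincide
#'   across classes, e.g. a degenerate mixed state equal to a corner).
#' @export
equivalence_classes <- function(states, tol = 1e-12) {
  stopifnot(is.data.frame(states), all(c("u", "v", "w") %in% names(states)))
  sig <- function(i) {
    s <- c(states$u[i], states$v[i], states$w[i])
    nz <- abs(s) > tol
    # swap-invariant support signature: (sorted u/w support, v support)
    paste(paste(sort(nz[c(1, 3)]), collapse = ""), nz[2], sep = "|")
  }
  keys <- vapply(seq_len(nrow(states)), sig, "")
  classes <- split(seq_len(nrow(states)), keys)
  names(classes) <- NULL
  # numerically coincident states across different classes are impossible
  # (same coordinates imply the same support); within-tolerance duplicates
  # anywhere in the list are worth reporting
  dup <- character()
  n <- nrow(states)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (abs(states$u[i] - states$u[j]) < tol &&
          abs(states$v[i] - states$v[j]) < tol &&
          abs(states$w[i] - states$w[j]) < tol) {
        lab <- if ("role" %in% names(states))
          paste(states$role[i], states$role[j], sep = " == ") else
            paste(i, j, sep = " == ")
        dup <- c(dup, lab)
      }
    }
  }
  list(classes = classes, n_classes = length(classes), duplicates = dup)
}

# ---- flat key-value config I/O ------------------------------------------

#' Read a parameter set from a YAML or JSON config file
#'
#' The config is a flat key-value mapping using exactly the keys
#' `lambda1..lambda3, a1..a3, K1..K3, c31, c12, c13, c32` (dimensional) or
#' `d1, d3, beta1, beta3, alpha1..alpha4, kappa1, kappa2` (dimensionless).
#' The dialect is chosen from the file extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path path to the config file.
#' @return A [dimensional_params()] or [dimensionless_params()] object; an
#'   optional `mu` key is attached as the `mu` attribute.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  vals <- lapply(vals, as.numeric)
  mu <- vals[["mu"]]
  vals[["mu"]] <- NULL
  keys <- names(vals)
  out <- if (all(.DIMENSIONAL_KEYS %in% keys)) {
    do.call(dimensional_params, vals[.DIMENSIONAL_KEYS])
  } else if (all(.DIMENSIONLESS_KEYS %in% keys)) {
    do.call(dimensionless_params, vals[.DIMENSIONLESS_KEYS])
  } else {
    stop("config must contain either the dimensional keys (",
         paste(.DIMENSIONAL_KEYS, collapse = ", "), ") or the dimensionless keys (",
         paste(.DIMENSIONLESS_KEYS, collapse = ", "), ")")
  }
  if (!is.null(mu)) attr(out, "mu") <- mu
  out
}

#' Write a parameter set to a YAML or JSON config file
#'
#' @param p a parameter object from [dimensional_params()] or
#'   [dimensionless_params()].
#' @param path destination; the extension selects the dialect.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "dimensional_params") || inherits(p, "dimensionless_params"))
  vals <- lapply(unclass(p), as.numeric)
  if (!is.null(attr(p, "mu"))) vals$mu <- as.numeric(attr(p, "mu"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path, precision = 17L)
  }
  invisible(path)
}
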