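# Method-of-lines integration of the reaction-diffusion system on a
# bounded interval with no-flux (zero Neumann) boundaries.
#
# Space is discretized with second-order central differences on a uniform
# grid; the no-flux condition is imposed through mirror ghost nodes, which
# keeps the boundary treatment second-order accurate.  The resulting ODE
# system is moderately stiff for realistic conversion coefficients, so a
# stiff-capable adaptive integrator (deSolve) is used at tight tolerances.

#' Uniform spatial grid
#'
#' @param A,B domain endpoints, `A < B`.
#' @param M number of nodes (`>= 3`).
#' @return An object of class `spatial_grid` with nodes `x` and spacing `h`.
#' @export
spatial_grid <- function(A, B, M) {
  stopifnot(is.numeric(A), is.numeric(B), A < B, M >= 3, M == round(M))
  M <- as.integer(M)
  x <- seq(A, B, length.out = M)
  structure(list(A = A, B = B, M = M, h = (B - A) / (M - 1), x = x),
            class = "spatial_grid")
}

.init_fields <- function(init, M) {
  if (is.data.frame(init)) init <- as.list(init)
  if (is.matrix(init)) init <- list(u = init[, 1], v = init[, 2], w = init[, 3])
  stopifnot(is.list(init), all(c("u", "v", "w") %in% names(init)))
  for (nm in c("u", "v", "w")) {
    if (length(init[[nm]]) != M) stop("initial field '", nm,
                                      "' must have one value per grid node")
    if (!all(is.finite(init[[nm]]))) stop("initial field '", nm, "' not finite")
  }
  init
}

#' Integrate the reaction-diffusion system
#'
#' Method-of-lines solution of the dimensionless system (or, given
#' [dimensional_params()], of the dimensional one) with second-order
#' central differences, mirror-node no-flux boundaries and adaptive stiff
#' time integration.
#'
#' @param p a [dimensionless_params()] or [dimensional_params()] object.
#' @param init initial fields: list/data frame/matrix with components
#'   `u`, `v`, `w` on the grid nodes.
#' @param grid a [spatial_grid()].
#' @param times output times (strictly increasing; the first is the
#'   initial time).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param method deSolve integrator (default `"lsodes"`, sparse-stiff).
#' @param reaction set `FALSE` to switch the reaction terms off
#'   (diffusion-only; used to check discrete mass conservation under
#'   no-flux boundaries).
#' @return An object of class `rd_trajectory`: time stamps, grid, and
#'   `u`, `v`, `w` matrices (time by node), plus solver metadata.
#' @export
rd_integrate <- function(p, init, grid, times, rtol = 1e-8, atol = 1e-10,
                         method = "lsodes", reaction = TRUE) {
  stopifnot(inherits(grid, "spatial_grid"), length(times) >= 1L,
            all(diff(times) > 0))
  dimensional <- inherits(p, "dimensional_params")
  if (!dimensional) stopifnot(inherits(p, "dimensionless_params"))
  init <- .init_fields(init, grid$M)
  M <- grid$M; h <- grid$h
  diff_coef <- if (dimensional) c(p$lambda1, p$lambda2, p$lambda3) else
    c(p$d1, 1, p$d3)
  lap <- function(f) c(2 * (f[2L] - f[1L]),
                       f[3:M] + f[1:(M - 2L)] - 2 * f[2:(M - 1L)],
                       2 * (f[M - 1L] - f[M])) / h^2
  rhs <- function(t, y, parms) {
    u <- y[1:M]; v <- y[M + 1:M]; w <- y[2L * M + 1:M]
    if (reaction) {
      f <- if (dimensional) reaction_terms_dimensional(u, v, w, p) else
        reaction_terms(u, v, w, p)
    } else f <- list(du = 0, dv = 0, dw = 0)
    list(c(diff_coef[1L] * lap(u) + f$du,
           diff_coef[2L] * lap(v) + f$dv,
           diff_coef[3L] * lap(w) + f$dw))
  }
  y0 <- c(init$u, init$v, init$w)
  out <- deSolve::ode.1D(y = y0, times = times, func = rhs, parms = NULL,
                         nspec = 3L, dimens = M, method = method,
                         rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("integration failure (step-size collapse) near t = ",
         max(out[, 1L]), "; solver state ", attr(out, "istate")[1L])
  vals <- out[, -1L, drop = FALSE]
  if (anyNA(vals) || !all(is.finite(vals)))
    stop("non-finite values in the solution: the integration diverged")
  structure(list(times = out[, 1L],
                 grid = grid,
                 u = vals[, 1:M, drop = FALSE],
                 v = vals[, M + 1:M, drop = FALSE],
                 w = vals[, 2L * M + 1:M, drop = FALSE],
                 params = p,
                 meta = list(rtol = rtol, atol = atol, method = method,
                             scheme = "central-2nd-order, mirror-node Neumann",
                             reaction = reaction, dimensional = dimensional)),
            class = "rd_trajectory")
}

#' @export
print.rd_trajectory <- function(x, ...) {
  cat("RD trajectory:", length(x$times), "times on [",
      x$grid$A, ",", x$grid$B, "] with", x$grid$M, "nodes\n")
  cat(" t in [", min(x$times), ",", max(x$times), "], scheme:",
      x$meta$scheme, ", method:", x$meta$method, "\n")
  invisible(x)
}

#' Build a trajectory from a closed-form front (no integration)
#'
#' Evaluates an exact front on a grid at the requested times and packs the
#' result as an `rd_trajectory`; useful for testing the measurement
#' utilities against a profile whose speed is known exactly.
#'
#' @param front a [build_front()] object.
#' @param grid a [spatial_grid()].
#' @param times time stamps.
#' @return An `rd_trajectory`.
#' @export
front_trajectory <- function(front, grid, times) {
  stopifnot(inherits(front, "traveling_front"), inherits(grid, "spatial_grid"))
  ev <- lapply(times, function(ti) evaluate_front(front, ti, grid$x))
  structure(list(times = times, grid = grid,
                 u = do.call(rbind, lapply(ev, `[[`, "u")),
                 v = do.call(rbind, lapply(ev, `[[`, "v")),
                 w = do.call(rbind, lapply(ev, `[[`, "w")),
                 params = front$params,
                 meta = list(method = "exact", scheme = "closed form",
                             reaction = TRUE, dimensional = FALSE)),
            class = "rd_trajectory")
}

#' Measure the front speed from a trajectory
#'
#' Locates, at each stored time, the position where the chosen component
#' crosses a level (by linear interpolation along a monotone profile), and
#' fits position against time by least squares over the final half of the
#' record; the slope is the speed estimate.
#'
#' @param traj an `rd_trajectory`.
#' @param component `"u"`, `"v"` or `"w"`.
#' @param level crossing level; sensible defaults are `1/2` for the `w`
#'   component of Case-1 fronts (which spans 0 to 1) and half the left
#'   plateau of `u` for the pulse families.
#' @param fit_fraction fraction of the record (from the end) used in the
#'   fit.
#' @return An object of class `front_speed`: `speed`, per-time crossing
#'   `positions`, and the `lm` fit.
#' @export
measure_front_speed <- function(traj, component = "w", level = 0.5,
                                fit_fraction = 0.5) {
  stopifnot(inherits(traj, "rd_trajectory"),
            component %in% c("u", "v", "w"))
  prof <- traj[[component]]
  x <- traj$grid$x
  pos <- vapply(seq_along(traj$times), function(i) {
    y <- prof[i, ]
    s <- y - level
    cross <- c(x[s == 0],                       # level hit exactly on a node
               vapply(which(s[-length(s)] * s[-1L] < 0), function(i0)
                 x[i0] + (level - y[i0]) * (x[i0 + 1L] - x[i0]) /
                   (y[i0 + 1L] - y[i0]), 0))
    cross <- sort(unique(cross))
    # collapse crossings closer than one grid cell (an exact node hit sits
    # inside its bracketing interval)
    if (length(cross) > 1L)
      cross <- cross[c(TRUE, diff(cross) > traj$grid$h)]
    if (!length(cross))
      stop("no crossing of level ", level, " for component '", component,
           "' at time ", traj$times[i])
    if (length(cross) > 1L)
      stop("non-monotone profile for component '", component,
           "' at time ", traj$times[i], " (", length(cross), " crossings)")
    cross
  }, 0)
  n <- length(traj$times)
  use <- seq.int(max(1L, ceiling(n * (1 - fit_fraction))), n)
  if (length(use) < 2L) use <- seq_len(n)
  fit <- stats::lm(pos ~ t, data = data.frame(t = traj$times[use], pos = pos[use]))
  structure(list(speed = unname(stats::coef(fit)[2L]), positions = pos,
                 times = traj$times, fit = fit, component = component,
                 level = level),
            class = "front_speed")
}

#' @export
print.front_speed <- function(x, ...) {
  cat("Front speed estimate:", format(x$speed, digits = 8),
      "(component", x$component, "at level", x$level, ")\n")
  invisible(x)
}

#' Compare a trajectory with a closed-form front
#'
#' @param traj an `rd_trajectory`.
#' @param front a [build_front()] object sharing the trajectory's
#'   parameter set (checked; mismatches are rejected).
#' @param tol parameter-agreement tolerance.
#' @return Maximum absolute deviation over components, nodes and stored
#'   times, with a per-time breakdown in attribute `by_time`.
#' @export
compare_to_exact <- function(traj, front, tol = 1e-10) {
  stopifnot(inherits(traj, "rd_trajectory"), inherits(front, "traveling_front"))
  pa <- unlist(unclass(traj$params)); pb <- unlist(unclass(front$params))
  if (length(pa) != length(pb) || max(abs(pa - pb[names(pa)])) > tol)
    stop("trajectory and front parameter sets differ; refusing to compare")
  devs <- vapply(seq_along(traj$times), function(i) {
    ex <- evaluate_front(front, traj$times[i], traj$grid$x)
    max(abs(traj$u[i, ] - ex$u), abs(traj$v[i, ] - ex$v), abs(traj$w[i, ] - ex$w))
  }, 0)
  out <- max(devs)
  attr(out, "by_time") <- devs
  out
}

#' Write a trajectory to CSV (+ JSON metadata sidecar)
#'
#' Long format with columns `t, x, u, v, w`; the sidecar stores the grid,
#' tolerances and parameter set so that [read_trajectory()] can
#' reconstruct the object bit-for-bit.
#'
#' @param traj an `rd_trajectory`.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "rd_trajectory"))
  tab <- do.call(rbind, lapply(seq_along(traj$times), function(i)
    data.frame(t = traj$times[i], x = traj$grid$x,
               u = traj$u[i, ], v = traj$v[i, ], w = traj$w[i, ])))
  # %.17g round-trips doubles exactly through text
  tab[] <- lapply(tab, function(col) sprintf("%.17g", col))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  meta <- list(grid = list(A = traj$grid$A, B = traj$grid$B, M = traj$grid$M),
               params = lapply(unclass(traj$params), as.numeric),
               dimensional = isTRUE(traj$meta$dimensional),
               meta = traj$meta[c("rtol", "atol", "method", "scheme", "reaction")])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path (the `.json` sidecar must sit next to it).
#' @return An `rd_trajectory`.
#' @export
read_trajectory <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  grid <- spatial_grid(meta$grid$A, meta$grid$B, meta$grid$M)
  pl <- as.list(meta$params)
  p <- if (isTRUE(meta$dimensional)) do.call(dimensional_params, pl) else
    do.call(dimensionless_params, c(pl, list(check_degeneracy = FALSE)))
  times <- unique(tab$t)
  shape <- function(nm) do.call(rbind, lapply(times, function(ti)
    tab[[nm]][tab$t == ti]))
  structure(list(times = times, grid = grid,
                 u = shape("u"), v = shape("v"), w = shape("w"),
                 params = p,
                 meta = c(meta$meta, list(dimensional = isTRUE(meta$dimensional)))),
            class = "rd_trajectory")
}
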