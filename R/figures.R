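# Reproduction of the three illustrative front plots.
#
# All three figures show the variable-speed front family on x in [-4, 8]:
# figures 1-2 the forward set (mu = 3/2, d1 = d3 = 2, alpha2 = alpha4 = 5,
# obtained from the simplified selection rule with epsilon = 1), figure 3
# the backward set (mu = -5, d1 = d3 = 1/2, alpha2 = alpha4 = 12, from the
# Case (ii) rule).  Plots are a convenience; the CSVs carry the data.

.figure_spec <- function(figure) {
  switch(as.character(figure),
         "1" = list(sel = function() select_remark4(mu = 3/2, epsilon = 1, d = 2),
                    mu = 3/2, times = c(0.01, 4)),
         "2" = list(sel = function() select_remark4(mu = 3/2, epsilon = 1, d = 2),
                    mu = 3/2, times = 6),
         "3" = list(sel = function() select_case_ii(d1 = 1/2, d3 = 1/2, mu = -5),
                    mu = -5, times = c(0.01, 3)),
         stop("unknown figure id: ", figure, " (use 1, 2 or 3)"))
}

#' Regenerate an illustrative front figure
#'
#' Evaluates the variable-speed exact front at the figure's parameter set
#' and times on `x` in `[-4, 8]`, writes one CSV per panel
#' (`figure<id>_t<time>.csv`, columns `t, x, u, v, w`) plus a metadata
#' sidecar, and draws the three-curve panels into a PNG.
#'
#' @param figure 1, 2 or 3.
#' @param outdir output directory (created if missing).
#' @param n_points nodes on the x-grid.
#' @return Invisibly, a list with the front, the written `csv` paths and
#'   the `png` path.
#' @export
run_figures <- function(figure, outdir = ".", n_points = 601L) {
  spec <- .figure_spec(figure)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p <- spec$sel()
  front <- build_front("1-general", mu = spec$mu, d1 = p$d1, d3 = p$d3,
                       alpha2 = p$alpha2, alpha4 = p$alpha4)
  x <- seq(-4, 8, length.out = n_points)
  csvs <- character()
  for (ti in spec$times) {
    path <- file.path(outdir, sprintf("figure%s_t%s.csv", figure, ti))
    export_front_csv(front, path, t = ti, x = x)
    csvs <- c(csvs, path)
  }
  png <- file.path(outdir, sprintf("figure%s.png", figure))
  grDevices::png(png, width = 480 * length(spec$times), height = 420)
  op <- graphics::par(mfrow = c(1, length(spec$times)), mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  for (ti in spec$times) {
    ev <- evaluate_front(front, ti, x)
    graphics::matplot(x, as.matrix(ev[, c("u", "v", "w")]), type = "l",
                      lty = 1, lwd = 2, col = c("blue", "red", "green3"),
                      xlab = "x", ylab = "frequency",
                      main = sprintf("t = %g (mu = %g)", ti, front$mu))
    graphics::legend("topright", c("u", "v", "w"), lty = 1, lwd = 2,
                     col = c("blue", "red", "green3"), bty = "n")
  }
  invisible(list(front = front, csv = csvs, png = png))
}
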