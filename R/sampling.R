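# Random admissible parameter draws for each front family.
#
# Used by the verification suite: draws are taken from the documented
# admissible regions (rejection-sampled against the positivity report
# where the region is not a box), so that every draw yields a genuine
# nonnegative bounded front.

#' Draw random admissible free parameters for a front family
#'
#' @param case front family label.
#' @param n number of draws.
#' @param max_tries rejection-sampling cap per draw.
#' @return A list of `n` named numeric vectors, each a valid `...`
#'   argument set for [build_front()].
#' @export
sample_front_params <- function(case = .case_labels, n = 1L, max_tries = 500L) {
  case <- match.arg(case)
  draw1 <- switch(case,
    "1-general" = function() {
      if (stats::runif(1) < 0.5) {  # forward front via the Case (i) rules
        mu <- stats::runif(1, 0.6, 2.4)
        eps <- stats::runif(1, 0.2, 0.95)
        d3 <- (2 * mu + eps) / (2 * mu - 1) * stats::runif(1, 1.0, 2.5)
        alpha <- (5 - 2 * mu) * d3 + eps
        d1 <- max((4 * mu + alpha) / 40, alpha / 24) * stats::runif(1, 1.05, 2.5)
        c(mu = mu, d1 = d1, d3 = d3, alpha2 = alpha, alpha4 = alpha)
      } else {                      # backward front via the Case (ii) rules
        d1 <- stats::runif(1, 0.1, 0.9)
        d3 <- stats::runif(1, 0.1, 0.9)
        mu <- d3 / (2 * (d3 - 1)) * stats::runif(1, 1.2, 8)
        iv <- admissible_alpha4_interval(d1, d3, mu)
        hi <- if (is.finite(iv$upper)) iv$upper else 4 * iv$lower
        a4 <- iv$lower + (hi - iv$lower) * stats::runif(1, 0.1, 0.9)
        c(mu = mu, d1 = d1, d3 = d3, alpha2 = 24 * d1, alpha4 = a4)
      }
    },
    "1-fixed" = function()
      c(beta1 = stats::runif(1, 24.5, 50),
        alpha2 = stats::runif(1, 0.3, 2.5),
        alpha3 = stats::runif(1, 26, 80),
        alpha4 = stats::runif(1, 0.2, 2.5),
        kappa2 = stats::runif(1, 0.05, 0.9) / stats::runif(1, 1, 3)),
    "2" = function() {
      d1 <- stats::runif(1, 0.05, 0.38)
      sig <- stats::runif(1, 0.08, 0.45)
      alpha1 <- (17 - 40 * d1) / (4 * sig)
      alpha2 <- stats::runif(1, 0.3, 2.5)
      kappa2 <- stats::runif(1, 0.05, 0.9) / alpha2
      b1 <- 17 - 16 * d1
      S1 <- (b1 + alpha2) / (4 * (b1 + kappa2 * alpha2^2))
      alpha3 <- 17 / (4 * S1) * stats::runif(1, 1.05, 2.5)
      c(d1 = d1, alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
        kappa2 = kappa2)
    },
    "3" = function() {
      alpha3 <- stats::runif(1, 24.5, 34)
      d1 <- stats::runif(1, 0.02, 0.85 * alpha3 / 40)
      alpha4 <- (alpha3 - 6) / 2 * stats::runif(1, 1.05, 2.2)
      sig3 <- stats::runif(1, 2.2, 6)
      alpha1 <- (alpha3 - 40 * d1) / (4 * sig3)
      c(d1 = d1, alpha1 = alpha1, alpha3 = alpha3, alpha4 = alpha4)
    })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      fp <- tryCatch(draw1(), error = function(e) NULL)
      if (is.null(fp)) next
      f <- tryCatch(do.call(build_front, c(list(case = case), as.list(fp))),
                    error = function(e) NULL)
      if (!is.null(f)) { out[[i]] <- fp; ok <- TRUE; break }
    }
    if (!ok) stop("could not draw admissible parameters for case ", case,
                  " within ", max_tries, " tries")
  }
  out
}
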