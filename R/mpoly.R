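# Exact multivariate polynomial arithmetic over the rationals.
#
# The tanh expansion reduces the traveling-wave ODE system to polynomial
# identities in Y = tanh(omega) whose coefficients are polynomials in the
# model parameters and the ansatz amplitudes.  Deriving the constraint sets
# means solving "every coefficient vanishes" exactly, so the engine keeps
# rational coefficients exact (numerator/denominator pairs of integers held
# in doubles, always gcd-reduced; an error is raised long before the 2^53
# exact-integer limit of double precision could be crossed).

.INT_LIMIT <- 2^52

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

.gcdv <- function(a, b) {
  if (length(a) == 0L) return(numeric())
  mapply(.gcd2, a, b)
}

.chk_int <- function(x) {
  if (any(abs(x) > .INT_LIMIT))
    stop("exact rational arithmetic overflow (coefficient beyond 2^52)")
  x
}

.rat_norm <- function(num, den) {
  if (any(den == 0)) stop("zero denominator in rational coefficient")
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- .gcdv(num, den)
  g[g == 0] <- 1
  list(num = .chk_int(num / g), den = .chk_int(den / g))
}

# ---- mpoly: canonical sparse multivariate polynomial --------------------

.mp_new <- function(vars, pow, num, den) {
  keep <- num != 0
  pow <- pow[keep, , drop = FALSE]; num <- num[keep]; den <- den[keep]
  if (length(num) > 1L && ncol(pow) == 0L) {
    # all terms share the empty monomial: fold into a single constant
    n <- 0; d <- 1
    for (j in seq_along(num)) {
      r <- .rat_norm(n * den[j] + num[j] * d, d * den[j])
      n <- r$num; d <- r$den
    }
    num <- n; den <- d
    pow <- matrix(0L, 1L, 0L)
    keep <- num != 0
    pow <- pow[keep, , drop = FALSE]; num <- num[keep]; den <- den[keep]
  }
  if (length(num) && ncol(pow)) {
    key <- apply(pow, 1L, paste, collapse = ",")
    if (anyDuplicated(key)) {
      ord <- split(seq_along(key), key)
      num2 <- den2 <- numeric(length(ord))
      pow2 <- matrix(0L, length(ord), ncol(pow), dimnames = list(NULL, vars))
      for (i in seq_along(ord)) {
        idx <- ord[[i]]
        n <- 0; d <- 1
        for (j in idx) {
          r <- .rat_norm(n * den[j] + num[j] * d, d * den[j])
          n <- r$num; d <- r$den
        }
        num2[i] <- n; den2[i] <- d
        pow2[i, ] <- pow[idx[1L], ]
      }
      pow <- pow2; num <- num2; den <- den2
      keep <- num != 0
      pow <- pow[keep, , drop = FALSE]; num <- num[keep]; den <- den[keep]
    }
  }
  if (length(num) && ncol(pow)) {
    used <- colSums(pow) > 0L
    pow <- pow[, used, drop = FALSE]; vars <- vars[used]
    if (ncol(pow)) {
      o <- order(colnames(pow))
      pow <- pow[, o, drop = FALSE]; vars <- vars[o]
      key <- apply(pow, 1L, paste, collapse = ",")
      o <- order(key)
      pow <- pow[o, , drop = FALSE]; num <- num[o]; den <- den[o]
    }
  } else if (length(num) == 0L) {
    vars <- character(); pow <- matrix(0L, 0L, 0L)
  } else {
    vars <- character(); pow <- matrix(0L, length(num), 0L)
  }
  structure(list(vars = vars, pow = pow, num = num, den = den), class = "mpoly")
}

mp_zero <- function() .mp_new(character(), matrix(0L, 0L, 0L), numeric(), numeric())

mp_const <- function(num, den = 1) {
  r <- .rat_norm(num, den)
  if (r$num == 0) return(mp_zero())
  .mp_new(character(), matrix(0L, 1L, 0L), r$num, r$den)
}

mp_var <- function(name, pow = 1L) {
  m <- matrix(as.integer(pow), 1L, 1L, dimnames = list(NULL, name))
  .mp_new(name, m, 1, 1)
}

mp_is_zero <- function(a) length(a$num) == 0L

mp_is_const <- function(a) length(a$vars) == 0L

# exact rational reconstruction of a double (continued fractions); only
# values that reproduce the double exactly are accepted
.dbl_to_rat <- function(x, maxden = 2^40) {
  if (!is.finite(x)) stop("non-finite numeric cannot enter exact arithmetic")
  if (x == round(x)) return(c(x, 1))
  a <- x; p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  for (i in 1:64) {
    ai <- floor(a)
    p <- ai * p1 + p0; q <- ai * q1 + q0
    if (q > maxden) break
    if (p / q == x) return(c(p, q))
    p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
    fr <- a - ai
    if (fr == 0) break
    a <- 1 / fr
  }
  stop("cannot represent ", x, " as an exact rational")
}

as_mpoly <- function(x) {
  if (inherits(x, "mpoly")) return(x)
  if (is.character(x) && length(x) == 1L) return(mp_var(x))
  if (is.numeric(x) && length(x) == 1L) {
    r <- .dbl_to_rat(x)
    return(mp_const(r[1L], r[2L]))
  }
  stop("cannot coerce to mpoly")
}

.mp_align <- function(a, b) {
  vars <- sort(union(a$vars, b$vars))
  expand <- function(p, nterm) {
    m <- matrix(0L, nterm, length(vars), dimnames = list(NULL, vars))
    if (length(p$vars)) m[, p$vars] <- p$pow
    m
  }
  list(vars = vars,
       pa = expand(a, length(a$num)),
       pb = expand(b, length(b$num)))
}

mp_add <- function(a, b) {
  al <- .mp_align(a, b)
  .mp_new(al$vars, rbind(al$pa, al$pb), c(a$num, b$num), c(a$den, b$den))
}

mp_neg <- function(a) { a$num <- -a$num; a }

mp_sub <- function(a, b) mp_add(a, mp_neg(b))

mp_scale <- function(a, num, den = 1) {
  if (num == 0) return(mp_zero())
  r <- .rat_norm(a$num * num, a$den * den)
  .mp_new(a$vars, a$pow, r$num, r$den)
}

mp_mul <- function(a, b) {
  if (mp_is_zero(a) || mp_is_zero(b)) return(mp_zero())
  al <- .mp_align(a, b)
  na <- length(a$num); nb <- length(b$num)
  ia <- rep(seq_len(na), each = nb); ib <- rep(seq_len(nb), times = na)
  pow <- al$pa[ia, , drop = FALSE] + al$pb[ib, , drop = FALSE]
  r <- .rat_norm(a$num[ia] * b$num[ib], a$den[ia] * b$den[ib])
  .mp_new(al$vars, pow, r$num, r$den)
}

mp_pow <- function(a, n) {
  n <- as.integer(n)
  if (n < 0L) stop("negative power of mpoly")
  out <- mp_const(1)
  while (n > 0L) { out <- mp_mul(out, a); n <- n - 1L }
  out
}

mp_deg <- function(a, var) {
  if (!(var %in% a$vars)) return(0L)
  if (mp_is_zero(a)) return(0L)
  max(a$pow[, var])
}

# coefficients of var^0 .. var^deg as mpoly list
mp_coef_list <- function(a, var) {
  d <- mp_deg(a, var)
  out <- vector("list", d + 1L)
  for (k in 0:d) {
    if (var %in% a$vars) {
      sel <- a$pow[, var] == k
      pow <- a$pow[sel, setdiff(a$vars, var), drop = FALSE]
      out[[k + 1L]] <- .mp_new(setdiff(a$vars, var), pow, a$num[sel], a$den[sel])
    } else {
      out[[k + 1L]] <- if (k == 0L) a else mp_zero()
    }
  }
  out
}

mp_deriv <- function(a, var) {
  if (!(var %in% a$vars)) return(mp_zero())
  k <- a$pow[, var]
  sel <- k > 0L
  pow <- a$pow[sel, , drop = FALSE]
  num <- a$num[sel] * k[sel]; den <- a$den[sel]
  pow[, var] <- pow[, var] - 1L
  r <- .rat_norm(num, den)
  .mp_new(a$vars, pow, r$num, r$den)
}

# substitute an mpoly for a variable (Horner)
mp_subst <- function(a, var, b) {
  if (!(var %in% a$vars)) return(a)
  cf <- mp_coef_list(a, var)
  out <- cf[[length(cf)]]
  for (k in rev(seq_len(length(cf) - 1L))) out <- mp_add(mp_mul(out, b), cf[[k]])
  out
}

mp_eval <- function(a, vals) {
  if (mp_is_zero(a)) return(0)
  term <- a$num / a$den
  for (v in a$vars) {
    if (is.na(vals[v])) stop("missing value for symbol '", v, "'")
    term <- term * vals[[v]]^a$pow[, v]
  }
  sum(term)
}

# sum of absolute term values: scale for relative residual checks
mp_eval_abs <- function(a, vals) {
  if (mp_is_zero(a)) return(0)
  term <- abs(a$num / a$den)
  for (v in a$vars) term <- term * abs(vals[[v]])^a$pow[, v]
  sum(term)
}

# integer-primitive part; attributes content num/den such that
# a = (cnum/cden) * primitive(a); leading (first canonical) coefficient > 0
mp_primitive <- function(a) {
  if (mp_is_zero(a)) return(structure(a, cnum = 0, cden = 1))
  L <- Reduce(function(x, y) .chk_int(x / .gcd2(x, y) * y), a$den, accumulate = FALSE)
  ints <- .chk_int(a$num * (L / a$den))
  g <- Reduce(.gcd2, abs(ints))
  s <- sign(ints[1L])
  prim <- .mp_new(a$vars, a$pow, ints / g * s, rep(1, length(ints)))
  structure(prim, cnum = g * s, cden = L)
}

# common monomial divisor: named minimum exponent per var
mp_mono_content <- function(a) {
  if (mp_is_zero(a) || !length(a$vars)) return(integer())
  m <- apply(a$pow, 2L, min)
  m[m > 0L]
}

mp_div_mono <- function(a, mono) {
  if (!length(mono)) return(a)
  pow <- a$pow
  for (v in names(mono)) pow[, v] <- pow[, v] - mono[[v]]
  .mp_new(a$vars, pow, a$num, a$den)
}

# exact multivariate division: returns quotient or NULL
mp_divexact <- function(a, b) {
  if (mp_is_zero(b)) stop("division by zero polynomial")
  if (mp_is_zero(a)) return(mp_zero())
  if (mp_is_const(b)) return(mp_scale(a, b$den[1L], b$num[1L]))
  vars <- sort(union(a$vars, b$vars))
  lead <- function(p) {  # lex-largest term w.r.t. the shared variable order
    pw <- matrix(0L, length(p$num), length(vars), dimnames = list(NULL, vars))
    if (length(p$vars)) pw[, p$vars] <- p$pow
    i <- do.call(order, c(lapply(seq_along(vars), function(j) -pw[, j]),
                          list(decreasing = FALSE)))[1L]
    list(pow = pw[i, ], num = p$num[i], den = p$den[i])
  }
  q <- mp_zero(); r <- a
  maxit <- 2000L
  while (!mp_is_zero(r)) {
    maxit <- maxit - 1L
    if (maxit < 0L) return(NULL)
    lr <- lead(r); lb <- lead(b)
    dp <- lr$pow - lb$pow
    if (any(dp < 0L)) return(NULL)
    cf <- .rat_norm(lr$num * lb$den, lr$den * lb$num)
    mono <- .mp_new(vars, matrix(dp, 1L, length(vars), dimnames = list(NULL, vars)),
                    cf$num, cf$den)
    q <- mp_add(q, mono)
    r <- mp_sub(r, mp_mul(mono, b))
  }
  q
}

mp_to_str <- function(a) {
  if (mp_is_zero(a)) return("0")
  terms <- character(length(a$num))
  for (i in seq_along(a$num)) {
    parts <- character()
    cf <- if (a$den[i] == 1) sprintf("%.0f", a$num[i]) else
      sprintf("%.0f/%.0f", a$num[i], a$den[i])
    vs <- character()
    if (length(a$vars)) {
      for (v in a$vars) {
        p <- a$pow[i, v]
        if (p == 1L) vs <- c(vs, v) else if (p > 1L) vs <- c(vs, sprintf("%s^%d", v, p))
      }
    }
    if (!length(vs)) parts <- cf
    else if (a$num[i] == 1 && a$den[i] == 1) parts <- paste(vs, collapse = "*")
    else if (a$num[i] == -1 && a$den[i] == 1) parts <- paste0("-", paste(vs, collapse = "*"))
    else parts <- paste(c(cf, vs), collapse = "*")
    terms[i] <- parts
  }
  out <- terms[1L]
  for (t in terms[-1L]) {
    out <- if (startsWith(t, "-")) paste0(out, " - ", substring(t, 2L)) else
      paste0(out, " + ", t)
  }
  out
}

#' @export
print.mpoly <- function(x, ...) {
  cat("<mpoly> ", mp_to_str(x), "\n", sep = "")
  invisible(x)
}

# ---- ratfun: ratio of two mpolys ----------------------------------------

rf_new <- function(num, den = mp_const(1)) {
  num <- as_mpoly(num); den <- as_mpoly(den)
  if (mp_is_zero(den)) stop("ratfun with zero denominator")
  if (mp_is_zero(num))
    return(structure(list(num = mp_zero(), den = mp_const(1)), class = "ratfun"))
  pn <- mp_primitive(num); pd <- mp_primitive(den)
  cf <- .rat_norm(attr(pn, "cnum") * attr(pd, "cden"),
                  attr(pn, "cden") * attr(pd, "cnum"))
  n <- pn; d <- pd
  # cancel common monomial factors (all model symbols are nonzero on the
  # admissible parameter sets; assumptions are tracked by the solver)
  cn <- mp_mono_content(n); cd <- mp_mono_content(d)
  common <- intersect(names(cn), names(cd))
  if (length(common)) {
    mono <- pmin(cn[common], cd[common])
    n <- mp_div_mono(n, mono); d <- mp_div_mono(d, mono)
  }
  q <- mp_divexact(n, d)
  if (!is.null(q)) { n <- q; d <- mp_const(1) }
  n <- mp_scale(n, cf$num, cf$den)
  structure(list(num = n, den = d), class = "ratfun")
}

as_ratfun <- function(x) {
  if (inherits(x, "ratfun")) return(x)
  rf_new(as_mpoly(x))
}

rf_is_zero <- function(a) mp_is_zero(a$num)

rf_add <- function(a, b) rf_new(mp_add(mp_mul(a$num, b$den), mp_mul(b$num, a$den)),
                                mp_mul(a$den, b$den))
rf_mul <- function(a, b) rf_new(mp_mul(a$num, b$num), mp_mul(a$den, b$den))
rf_div <- function(a, b) {
  if (rf_is_zero(b)) stop("division by zero ratfun")
  rf_new(mp_mul(a$num, b$den), mp_mul(a$den, b$num))
}
rf_neg <- function(a) { a$num <- mp_neg(a$num); a }
rf_sub <- function(a, b) rf_add(a, rf_neg(b))
rf_pow <- function(a, n) {
  n <- as.integer(n)
  if (n < 0L) return(rf_pow(rf_div(as_ratfun(1), a), -n))
  out <- as_ratfun(1)
  while (n > 0L) { out <- rf_mul(out, a); n <- n - 1L }
  out
}

rf_eval <- function(a, vals) mp_eval(a$num, vals) / mp_eval(a$den, vals)

rf_vars <- function(a) union(a$num$vars, a$den$vars)

rf_to_str <- function(a) {
  if (mp_is_const(a$den)) {
    if (a$den$num[1] == 1 && a$den$den[1] == 1) return(mp_to_str(a$num))
    return(sprintf("(%s) / (%s)", mp_to_str(a$num), mp_to_str(a$den)))
  }
  sprintf("(%s) / (%s)", mp_to_str(a$num), mp_to_str(a$den))
}

#' @export
print.ratfun <- function(x, ...) {
  cat("<ratfun> ", rf_to_str(x), "\n", sep = "")
  invisible(x)
}

#' @export
Ops.ratfun <- function(e1, e2) {
  if (.Generic == "-" && missing(e2)) return(rf_neg(as_ratfun(e1)))
  if (.Generic == "+" && missing(e2)) return(as_ratfun(e1))
  if (.Generic == "^") return(rf_pow(as_ratfun(e1), e2))
  a <- as_ratfun(e1); b <- as_ratfun(e2)
  switch(.Generic,
         "+" = rf_add(a, b),
         "-" = rf_sub(a, b),
         "*" = rf_mul(a, b),
         "/" = rf_div(a, b),
         stop("unsupported operation for ratfun: ", .Generic))
}

#' @export
Ops.mpoly <- function(e1, e2) {
  if (.Generic == "-" && missing(e2)) return(mp_neg(e1))
  if (.Generic == "+" && missing(e2)) return(e1)
  if (.Generic == "^") {
    if (e2 >= 0 && e2 == round(e2)) return(mp_pow(e1, e2))
    return(rf_pow(as_ratfun(e1), e2))
  }
  if (inherits(e1, "ratfun") || inherits(e2, "ratfun"))
    return(Ops.ratfun(e1, e2))
  if (.Generic == "/") return(rf_div(as_ratfun(e1), as_ratfun(e2)))
  a <- as_mpoly(e1); b <- as_mpoly(e2)
  switch(.Generic,
         "+" = mp_add(a, b),
         "-" = mp_sub(a, b),
         "*" = mp_mul(a, b),
         stop("unsupported operation for mpoly: ", .Generic))
}

# substitute a ratfun for a variable in an mpoly -> ratfun
mp_subst_rf <- function(a, var, rf) {
  if (!(var %in% a$vars)) return(as_ratfun(a))
  cf <- mp_coef_list(a, var)
  K <- length(cf) - 1L
  num <- mp_zero()
  npow <- mp_const(1)               # rf$num^k, built up
  dpows <- vector("list", K + 1L)   # rf$den^(K-k)
  dpows[[K + 1L]] <- mp_const(1)
  for (k in K:1) dpows[[k]] <- mp_mul(dpows[[k + 1L]], rf$den)
  for (k in 0:K) {
    if (!mp_is_zero(cf[[k + 1L]]))
      num <- mp_add(num, mp_mul(cf[[k + 1L]], mp_mul(npow, dpows[[k + 1L]])))
    if (k < K) npow <- mp_mul(npow, rf$num)
  }
  rf_new(num, mp_pow(rf$den, K))
}

rf_subst <- function(a, var, rf) {
  rf_div(mp_subst_rf(a$num, var, rf), mp_subst_rf(a$den, var, rf))
}

# parse an expression string (arithmetic on known symbols) back to a ratfun
rf_parse <- function(s, symbols) {
  expr <- parse(text = s)[[1L]]
  used <- all.names(expr)
  ok <- c("+", "-", "*", "/", "^", "(", symbols)
  bad <- setdiff(used, ok)
  if (length(bad)) stop("unknown symbols in expression: ", paste(bad, collapse = ", "))
  env <- new.env(parent = environment(rf_parse))
  for (v in symbols) assign(v, rf_new(mp_var(v)), envir = env)
  out <- eval(expr, envir = env)
  as_ratfun(out)
}
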