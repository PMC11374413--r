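# Real branches of the Lambert W function (w * exp(w) = x), by Halley
# iteration from asymptotic starting values. Written in-package because the
# intrinsic-growth closed form needs the principal branch of arguments whose
# *logarithm* is the natural input (tau * (d_A - d_J) reaches 1e5 near the
# niche edges, far beyond double range), and the delayed characteristic
# equation needs complex branches.

w_halley <- function(w, lnx_minus_w_target = NULL, x = NULL, max_iter = 100L) {
  # iterate on f(w) = w + log(w) - log(x) when log-form requested (w > 0),
  # else on f(w) = w * exp(w) - x
  for (i in seq_len(max_iter)) {
    if (!is.null(lnx_minus_w_target)) {
      f <- w + log(w) - lnx_minus_w_target
      fp <- 1 + 1 / w
      fpp <- -1 / w^2
    } else {
      ew <- exp(w)
      f <- w * ew - x
      fp <- ew * (w + 1)
      fpp <- ew * (w + 2)
    }
    step <- f / (fp - f * fpp / (2 * fp))
    w <- w - step
    if (abs(step) < 1e-15 * (1 + abs(w))) break
  }
  w
}

#' Principal-branch Lambert W, overflow-safe
#'
#' Evaluates the principal real branch of the Lambert W function (the
#' solution `w >= -1` of `w * exp(w) = x`) by Halley iteration. Arguments too
#' large for double precision are passed as logarithms via `log_x`, in which
#' case the equivalent equation `w + log(w) = log(x)` is solved; the
#' intrinsic-growth closed form requires this deep in the thermal tails.
#'
#' @param x argument, `>= -1/e`; ignored when `log_x` is given.
#' @param log_x optional log of a positive argument.
#' @return the value `w` with `w * exp(w) = x`.
#' @export
#' @examples
#' lambert_w0(1)                  # 0.5671433
#' lambert_w0(log_x = 1e5)        # W(exp(1e5)) without overflow
lambert_w0 <- function(x = NULL, log_x = NULL) {
  if (is.null(log_x)) {
    stopifnot(is.numeric(x), length(x) == 1)
    if (x < -exp(-1) - 1e-12)
      abort("lambert_w0: argument below -1/e", class = "thermalniche_domain_error")
    if (x == 0) return(0)
    if (x > exp(1)) return(w_halley(log(x) - log(log(x)), lnx_minus_w_target = log(x)))
    if (x < -0.25) {
      # near the branch point: series in sqrt(2 (e x + 1))
      p <- sqrt(2 * (exp(1) * max(x, -exp(-1)) + 1))
      return(w_halley(-1 + p - p^2 / 3, x = x))
    }
    w_halley(x / (1 + x * exp(1) / (1 + exp(1))), x = x)
  } else {
    stopifnot(is.numeric(log_x), length(log_x) == 1)
    if (log_x < 2) return(lambert_w0(exp(log_x)))
    w_halley(log_x - log(log_x), lnx_minus_w_target = log_x)
  }
}

#' Lower real branch of the Lambert W function
#'
#' The branch `w <= -1` of `w * exp(w) = x`, defined for `x` in `[-1/e, 0)`.
#'
#' @param x argument in `[-1/e, 0)`.
#' @return the value `w <= -1` with `w * exp(w) = x`.
#' @export
lambert_wm1 <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1)
  if (x < -exp(-1) - 1e-12 || x >= 0)
    abort("lambert_wm1: argument must lie in [-1/e, 0)", class = "thermalniche_domain_error")
  if (x > -1e-300) return(-Inf)
  w <- if (x < -0.25) {
    p <- sqrt(2 * (exp(1) * max(x, -exp(-1)) + 1))
    -1 - p - p^2 / 3
  } else {
    l1 <- log(-x)
    l1 - log(-l1)
  }
  w_halley(w, x = x)
}

# Complex roots of the scalar delayed characteristic equation
#   lambda = -a + c * exp(-lambda * tau)
# via lambda = -a + u/tau where u e^u = z, z = c * tau * exp(a * tau).
# Each solution satisfies u + Log(u) = log|z| + i*arg(z) + 2*pi*i*k for some
# integer k; Newton on that equation per branch k yields the branch roots
# without ever forming z (only log z is needed, so large a*tau is safe).
# Returns complex roots with Im >= 0 (conjugates implied), dominant first.
char_roots <- function(a, c, tau, k_max = 6) {
  stopifnot(tau > 0)
  if (c == 0) return(complex(real = -a, imaginary = 0))
  logz <- log(abs(c) + 0i) + log(tau) + a * tau + (if (c < 0) 1i * pi else 0i)
  roots <- complex(0)
  starts_for <- function(k) {
    L <- logz + 2i * pi * k
    s <- c(L - log(L + (abs(L) < 1e-8)))  # asymptotic start
    if (k == 0) {
      z <- c * tau * exp(a * tau)  # may overflow; guard
      if (is.finite(z) && z >= -exp(-1)) {
        s <- c(s, complex(real = lambert_w0(z)))
        if (z < 0) s <- c(s, complex(real = lambert_wm1(z)))
      }
      s <- c(s, 0.5 + 0i, -0.5 + 2i)
    }
    s
  }
  for (k in 0:k_max) {
    L <- logz + 2i * pi * k
    for (u in starts_for(k)) {
      if (!is.finite(Re(u)) || !is.finite(Im(u))) next
      conv <- FALSE
      for (i in 1:200) {
        if (Mod(u) < 1e-300) break
        f <- u + log(u) - L
        step <- f / (1 + 1 / u)
        u <- u - step
        if (Mod(step) < 1e-13 * (1 + Mod(u))) { conv <- TRUE; break }
      }
      if (!conv) next
      # verify against the unwound equation for the nearest integer k'
      kk <- round(Im(u + log(u) - logz) / (2 * pi))
      res <- Mod(u + log(u) - (logz + 2i * pi * kk))
      if (res > 1e-8 * (1 + Mod(u))) next
      u <- if (Im(u) < 0) Conj(u) else u
      if (!any(Mod(roots - u) < 1e-8 * (1 + Mod(u)))) roots <- c(roots, u)
    }
  }
  lam <- -a + roots / tau
  lam[order(-Re(lam))]
}

# Argument-principle count of characteristic roots inside a rectangle
# [re_lo, re_hi] x [im_lo, im_hi] of the complex plane: winding number of
# g(lambda) = lambda + a - c * exp(-lambda * tau) along the boundary.
# Used as an independent check that char_roots() found every dominant root.
count_char_roots <- function(a, c, tau, re_lo, re_hi, im_lo, im_hi, n = 4000) {
  corner <- c(complex(real = re_lo, imaginary = im_lo),
              complex(real = re_hi, imaginary = im_lo),
              complex(real = re_hi, imaginary = im_hi),
              complex(real = re_lo, imaginary = im_hi))
  pts <- unlist(lapply(1:4, function(i) {
    p <- corner[i]; q <- corner[if (i == 4) 1 else i + 1]
    p + (q - p) * (0:(n - 1)) / n
  }))
  g <- pts + a - c * exp(-pts * tau)
  ph <- Arg(g)
  dph <- diff(c(ph, ph[1]))
  dph <- ((dph + pi) %% (2 * pi)) - pi
  round(sum(dph) / (2 * pi))
}
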