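# Distribution-pair construction: two skewed distributions (gamma or
# lognormal) sharing mean and coefficient of skewness but differing in
# standard deviation by a prescribed ratio.  X is always the wider member,
# Y the reference member normalized to SD 1.

DIST_FAMILIES <- c("gamma", "lognormal")

check_family <- function(family) {
  if (!(is.character(family) && length(family) == 1L && family %in% DIST_FAMILIES)) {
    stop("`family` must be one of: ", paste(DIST_FAMILIES, collapse = ", "),
         call. = FALSE)
  }
  family
}

#' Gamma shape parameter for a target coefficient of skewness
#'
#' A gamma distribution with shape \eqn{k} has coefficient of skewness
#' (standardized third central moment) \eqn{\gamma_1 = 2/\sqrt{k}}, so the
#' shape matching a target skewness is available in closed form,
#' \eqn{k = (2/\gamma_1)^2}.
#'
#' @param skewness Target coefficient of skewness, a positive scalar.
#' @return The gamma shape parameter \eqn{k > 0}.
#' @examples
#' solve_gamma_shape(2)   # 1: the exponential distribution
#' solve_gamma_shape(1)   # 4
#' @seealso [solve_lognormal_sigma()], [make_pair()]
#' @export
solve_gamma_shape <- function(skewness) {
  if (!is.numeric(skewness) || length(skewness) != 1L || !is.finite(skewness) ||
      skewness <= 0) {
    stop("`skewness` must be a single positive finite number", call. = FALSE)
  }
  (2 / skewness)^2
}

#' Lognormal log-scale parameter for a target coefficient of skewness
#'
#' A lognormal distribution with log-scale \eqn{\sigma} has skewness
#' \eqn{\gamma_1 = (w + 2)\sqrt{w - 1}} with \eqn{w = e^{\sigma^2}}.  The
#' equation is solved for \eqn{w} on \eqn{(1, \infty)} by bracketed root
#' finding (the left side is strictly increasing in \eqn{w}), then
#' \eqn{\sigma = \sqrt{\log w}}.
#'
#' @param skewness Target coefficient of skewness, a positive scalar
#'   (supported up to 100).
#' @return The lognormal \eqn{\sigma > 0}.
#' @examples
#' solve_lognormal_sigma(4)  # sqrt(log(2)): w = 2 solves (w+2)^2 (w-1) = 16
#' @export
solve_lognormal_sigma <- function(skewness) {
  if (!is.numeric(skewness) || length(skewness) != 1L || !is.finite(skewness) ||
      skewness <= 0) {
    stop("`skewness` must be a single positive finite number", call. = FALSE)
  }
  g <- function(w) (w + 2) * sqrt(w - 1) - skewness
  lo <- 1 + 1e-12
  hi <- 1e6
  if (g(hi) < 0) stop("failed to bracket the lognormal skewness root", call. = FALSE)
  w <- stats::uniroot(g, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  # polish with one round at tighter tolerance in case the bracket was wide
  w <- stats::uniroot(g, c(max(lo, w * (1 - 1e-6)), w * (1 + 1e-6) + 1e-12),
                      tol = .Machine$double.eps)$root
  sqrt(log(w))
}

#' Construct one member distribution of a pair
#'
#' A member is a shifted, scaled standard form: for the gamma family a
#' `gamma(shape, scale)` variate plus `shift`; for the lognormal family
#' `scale * exp(sigma * Z) + shift` with `Z` standard normal (so `shape`
#' stores \eqn{\sigma}).
#'
#' @param family `"gamma"` or `"lognormal"`.
#' @param shape Gamma shape \eqn{k}, or lognormal \eqn{\sigma}; positive.
#' @param scale Positive scale multiplier.
#' @param shift Location offset added to every draw.
#' @return An object of class `skewsim_member`.
#' @export
dist_member <- function(family, shape, scale, shift = 0) {
  check_family(family)
  stopifnot(is.numeric(shape), length(shape) == 1L, is.finite(shape), shape > 0,
            is.numeric(scale), length(scale) == 1L, is.finite(scale), scale > 0,
            is.numeric(shift), length(shift) == 1L, is.finite(shift))
  structure(list(family = family, shape = shape, scale = scale, shift = shift),
            class = "skewsim_member")
}

# Moments of the unshifted, unit-scale standard form.
member_base_moments <- function(member) {
  if (member$family == "gamma") {
    k <- member$shape
    list(mean = k, sd = sqrt(k), skewness = 2 / sqrt(k))
  } else {
    w <- exp(member$shape^2)
    list(mean = sqrt(w), sd = sqrt(w * (w - 1)), skewness = (w + 2) * sqrt(w - 1))
  }
}

#' Analytic moments of a member distribution
#'
#' @param member A `skewsim_member`.
#' @return `member_mean()` and `member_sd()` return scalars;
#'   `member_skewness()` the coefficient of skewness (scale/shift free).
#' @export
member_mean <- function(member) {
  m <- member_base_moments(member)
  m$mean * member$scale + member$shift
}

#' @rdname member_mean
#' @export
member_sd <- function(member) {
  member_base_moments(member)$sd * member$scale
}

#' @rdname member_mean
#' @export
member_skewness <- function(member) {
  member_base_moments(member)$skewness
}

#' Density, distribution, and quantile functions of a member
#'
#' These account for the member's scale and shift.
#'
#' @param member A `skewsim_member`.
#' @param t Numeric vector of evaluation points.
#' @param p Numeric vector of probabilities.
#' @return Densities, cumulative probabilities, or quantiles.
#' @export
member_pdf <- function(member, t) {
  z <- (t - member$shift) / member$scale
  if (member$family == "gamma") {
    stats::dgamma(z, shape = member$shape) / member$scale
  } else {
    stats::dlnorm(z, meanlog = 0, sdlog = member$shape) / member$scale
  }
}

#' @rdname member_pdf
#' @export
member_cdf <- function(member, t) {
  z <- (t - member$shift) / member$scale
  if (member$family == "gamma") {
    stats::pgamma(z, shape = member$shape)
  } else {
    stats::plnorm(z, meanlog = 0, sdlog = member$shape)
  }
}

#' @rdname member_pdf
#' @export
member_quantile <- function(member, p) {
  q <- if (member$family == "gamma") {
    stats::qgamma(p, shape = member$shape)
  } else {
    stats::qlnorm(p, meanlog = 0, sdlog = member$shape)
  }
  q * member$scale + member$shift
}

#' Build a mean- and skewness-matched distribution pair
#'
#' Constructs the two distributions compared throughout the package: both
#' members share the family and the shape parameter (hence exactly equal
#' skewness), Y is the unshifted reference with SD normalized to 1, and X
#' shares Y's shape with its scale chosen so that SD(X) = `sd_ratio` and its
#' shift chosen so that mean(X) = mean(Y) exactly.  With a common shape
#' parameter, equal means and equal medians cannot hold simultaneously when
#' the SDs differ; this constructor equalizes the means (see the package
#' vignette for the rationale).
#'
#' @param family `"gamma"` or `"lognormal"`.
#' @param skewness Common coefficient of skewness, positive.
#' @param sd_ratio \eqn{\rho =} SD(X)/SD(Y), at least 1 (X is by convention
#'   the member with the larger SD).
#' @return An object of class `skewsim_pair` with elements `x`, `y`
#'   (both `skewsim_member`), `skewness`, `sd_ratio`, `common_mean`.
#' @examples
#' p <- make_pair("gamma", skewness = 3, sd_ratio = 1.10)
#' member_mean(p$x) - member_mean(p$y)   # 0
#' member_sd(p$x) / member_sd(p$y)       # 1.10
#' @export
make_pair <- function(family, skewness, sd_ratio) {
  check_family(family)
  if (!is.numeric(sd_ratio) || length(sd_ratio) != 1L || !is.finite(sd_ratio) ||
      sd_ratio < 1) {
    stop("`sd_ratio` must be >= 1 (X is the larger-SD member)", call. = FALSE)
  }
  shape <- if (family == "gamma") {
    solve_gamma_shape(skewness)
  } else {
    solve_lognormal_sigma(skewness)
  }
  base <- member_base_moments(dist_member(family, shape, 1))
  scale_y <- 1 / base$sd
  scale_x <- sd_ratio * scale_y
  # equal means: shift X down by the mean excess its larger scale induces
  shift_x <- base$mean * (scale_y - scale_x)
  pair <- structure(
    list(x = dist_member(family, shape, scale_x, shift_x),
         y = dist_member(family, shape, scale_y, 0),
         skewness = skewness, sd_ratio = sd_ratio,
         common_mean = base$mean * scale_y),
    class = "skewsim_pair")
  stopifnot(abs(member_mean(pair$x) - member_mean(pair$y)) <=
              1e-10 * max(1, abs(pair$common_mean)),
            abs(member_sd(pair$x) / member_sd(pair$y) - sd_ratio) <= 1e-10)
  pair
}

#' @export
print.skewsim_pair <- function(x, ...) {
  cat(sprintf(
    "Distribution pair (%s): skewness %.4g, SD ratio %.4g, common mean %.6g\n",
    x$x$family, x$skewness, x$sd_ratio, x$common_mean))
  cat(sprintf("  X: shape %.6g, scale %.6g, shift %.6g\n",
              x$x$shape, x$x$scale, x$x$shift))
  cat(sprintf("  Y: shape %.6g, scale %.6g, shift %.6g\n",
              x$y$shape, x$y$scale, x$y$shift))
  invisible(x)
}

# Base (standard-form) draws shared by sample_pair() and the block sampler,
# so a blocked simulation consumes the RNG stream in the same order as a
# one-replicate-at-a-time run: n draws for X, then n draws for Y.
draw_base <- function(pair, m) {
  if (pair$x$family == "gamma") {
    stats::rgamma(m, shape = pair$x$shape)
  } else {
    stats::rlnorm(m, meanlog = 0, sdlog = pair$x$shape)
  }
}

#' Draw one pair of samples
#'
#' Draws `n` i.i.d. values from X followed by `n` from Y, using R's global
#' random number generator: call `set.seed()` first for reproducibility.
#'
#' @param pair A `skewsim_pair`.
#' @param n Per-group sample size, at least 1.
#' @return A list with numeric vectors `x` and `y` of length `n`.
#' @export
sample_pair <- function(pair, n) {
  stopifnot(inherits(pair, "skewsim_pair"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  base <- draw_base(pair, 2L * n)
  list(x = base[seq_len(n)] * pair$x$scale + pair$x$shift,
       y = base[n + seq_len(n)] * pair$y$scale)
}

# n x b matrices for a block of b replicates; replicate j occupies column j
# and consumes the stream exactly as b sequential sample_pair(pair, n) calls.
sample_pair_block <- function(pair, n, b) {
  base <- matrix(draw_base(pair, 2L * n * b), nrow = 2L * n)
  list(x = base[seq_len(n), , drop = FALSE] * pair$x$scale + pair$x$shift,
       y = base[n + seq_len(n), , drop = FALSE] * pair$y$scale)
}

#' Stochastic-superiority probability P(X < Y)
#'
#' Computes \eqn{P(X < Y) = \int f_X(t)\,\{1 - F_Y(t)\}\,dt} by adaptive
#' quadrature.  The integral is evaluated after the probability substitution
#' \eqn{u = F_X(t)}, i.e. \eqn{\int_0^1 \{1 - F_Y(Q_X(u))\}\,du}, whose
#' integrand is bounded and smooth on \[0, 1\] even when the gamma density
#' is singular at its support endpoint (shape < 1); the quadrature is run
#' piecewise between fixed u-breakpoints and the summed absolute error must
#' not exceed `abs.tol`.
#'
#' This is the quantity whose departure from 1/2 the Wilcoxon-Mann-Whitney
#' test detects: its general null hypothesis is P(X < Y) = 1/2, not equality
#' of means or medians.
#'
#' @param pair A `skewsim_pair`.
#' @param abs.tol Absolute error budget for the quadrature (default 1e-8).
#' @return A probability in \[0, 1\].
#' @examples
#' prob_x_less_y(make_pair("gamma", 3, 1.10))  # about 0.56
#' @export
prob_x_less_y <- function(pair, abs.tol = 1e-8) {
  stopifnot(inherits(pair, "skewsim_pair"))
  integrand <- function(u) {
    1 - member_cdf(pair$y, member_quantile(pair$x, u))
  }
  cuts <- c(0, 1e-4, 1e-2, 0.1, 0.3, 0.5, 0.7, 0.9, 0.99, 0.9999, 1)
  total <- 0
  err <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    piece <- stats::integrate(integrand, cuts[i], cuts[i + 1L],
                              rel.tol = 1e-10, abs.tol = abs.tol / 20,
                              subdivisions = 500L, stop.on.error = FALSE)
    if (!piece$message %in% c("OK", "roundoff error was detected")) {
      stop(sprintf(
        "quadrature failed on u in [%.6g, %.6g]: %s (family %s, skewness %g, ratio %g)",
        cuts[i], cuts[i + 1L], piece$message, pair$x$family, pair$skewness,
        pair$sd_ratio), call. = FALSE)
    }
    total <- total + piece$value
    err <- err + piece$abs.error
  }
  if (err > abs.tol) {
    stop(sprintf("quadrature error estimate %.3g exceeds tolerance %.3g",
                 err, abs.tol), call. = FALSE)
  }
  min(max(total, 0), 1)
}
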