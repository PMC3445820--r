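# From-scratch implementations of the two tests under comparison: the Welch
# unequal-variance two-sample t-test and the Wilcoxon-Mann-Whitney rank-sum
# test (normal approximation with continuity and tie corrections, plus an
# exact-enumeration mode for small samples).

check_sample <- function(v, name, min_len) {
  if (!is.numeric(v) || length(v) < min_len || anyNA(v) || any(!is.finite(v))) {
    stop(sprintf("`%s` must be a finite numeric vector of length >= %d",
                 name, min_len), call. = FALSE)
  }
}

new_test_result <- function(statistic, df, p, method, test, degenerate,
                            data.name) {
  structure(
    list(statistic = statistic,
         parameter = if (is.null(df)) NULL else c(df = df),
         p.value = p,
         method = method,
         data.name = data.name,
         test = test,
         degenerate = degenerate),
    class = c("skewsim_htest", "htest"))
}

#' Welch unequal-variance two-sample t-test
#'
#' Tests equality of means without assuming equal variances:
#' \deqn{t = \frac{\bar x - \bar y}{\sqrt{s_1^2/n_1 + s_2^2/n_2}}}
#' with unbiased sample variances, and p-value from Student's t with the
#' (non-integer) Welch-Satterthwaite degrees of freedom
#' \deqn{\nu = \frac{(s_1^2/n_1 + s_2^2/n_2)^2}
#'   {(s_1^2/n_1)^2/(n_1-1) + (s_2^2/n_2)^2/(n_2-1)}.}
#'
#' Degenerate inputs (both sample variances zero) return p = 1 when the
#' means are equal and p = 0 otherwise, with `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @return An object of classes `skewsim_htest` and `htest` with elements
#'   `statistic`, `parameter` (the df), `p.value`, `test` (`"welch_t"`),
#'   and `degenerate`.
#' @examples
#' welch_t(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
#' @export
welch_t <- function(x, y) {
  check_sample(x, "x", 2L)
  check_sample(y, "y", 2L)
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  dname <- paste(deparse1(substitute(x)), "and", deparse1(substitute(y)))
  if (v1 == 0 && v2 == 0) {
    equal <- mean(x) == mean(y)
    return(new_test_result(c(t = if (equal) 0 else sign(mean(x) - mean(y)) * Inf),
                           NULL, if (equal) 1 else 0,
                           "Welch two-sample t-test (degenerate)", "welch_t",
                           TRUE, dname))
  }
  se2 <- v1 / n1 + v2 / n2
  stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  new_test_result(c(t = stat), df, p, "Welch two-sample t-test", "welch_t",
                  FALSE, dname)
}

# Mann-Whitney U (pairs with y_j < x_i, ties counted half) from midranks,
# together with tie counts of the pooled sample.
wmw_u_stat <- function(x, y) {
  n1 <- as.numeric(length(x))  # doubles: n1 * n2 can exceed integer range
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  nties <- if (anyDuplicated(pooled)) as.numeric(table(pooled)) else numeric(0)
  list(u = u, nties = nties)
}

wmw_normal_p <- function(u, n1, n2, nties) {
  mu <- n1 * n2 / 2
  N <- n1 + n2
  tie_term <- if (length(nties)) sum(nties^3 - nties) / (N * (N - 1)) else 0
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(z = 0, p = 1, degenerate = TRUE))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  list(z = z, p = p, degenerate = FALSE)
}

# Exact two-sided p by enumeration of all choose(n1+n2, n1) assignments of
# the pooled observations to the first group (handles ties via midranks).
wmw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  N <- n1 + n2
  if (N > 16L) {
    stop("exact enumeration is limited to n1 + n2 <= 16", call. = FALSE)
  }
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(N, n1)
  us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Computes the Mann-Whitney U statistic from midranks of the pooled sample
#' and a two-sided p-value.  The default mode is the normal approximation
#' with a 0.5 continuity correction and the tie-corrected variance
#' \deqn{\sigma_U^2 = \frac{n_1 n_2}{12}\Big\{(N+1) -
#'   \frac{\sum_j (t_j^3 - t_j)}{N(N-1)}\Big\}}
#' (\eqn{t_j} the tie-group sizes, \eqn{N = n_1 + n_2}).  `method = "exact"`
#' enumerates all \eqn{\binom{N}{n_1}} group assignments of the pooled
#' observations (available for \eqn{N \le 16}; intended as a small-sample
#' oracle).  The general null hypothesis is P(X < Y) = 1/2.
#'
#' If every pooled value is tied the result is degenerate with p = 1.
#'
#' @param x,y Numeric vectors, each of length at least 1.
#' @param method `"normal"` (default) or `"exact"`.
#' @return An object of classes `skewsim_htest` and `htest`; `statistic`
#'   holds U and, for the normal mode, the standardized z is in
#'   `statistic["z"]`.
#' @examples
#' wmw_test(c(1, 2, 3), c(4, 5, 6), method = "exact")  # p = 0.1
#' @export
wmw_test <- function(x, y, method = c("normal", "exact")) {
  method <- match.arg(method)
  check_sample(x, "x", 1L)
  check_sample(y, "y", 1L)
  dname <- paste(deparse1(substitute(x)), "and", deparse1(substitute(y)))
  st <- wmw_u_stat(x, y)
  n1 <- length(x); n2 <- length(y)
  if (method == "exact") {
    p <- wmw_exact_p(x, y)
    degen <- length(st$nties) == 1L  # all pooled values tied
    return(new_test_result(c(U = st$u), NULL, if (degen) 1 else p,
                           "Wilcoxon-Mann-Whitney rank-sum test (exact enumeration)",
                           "wmw", degen, dname))
  }
  np <- wmw_normal_p(st$u, as.numeric(n1), as.numeric(n2), st$nties)
  new_test_result(c(U = st$u, z = np$z), NULL, np$p,
                  "Wilcoxon-Mann-Whitney rank-sum test (normal approximation, continuity-corrected)",
                  "wmw", np$degenerate, dname)
}

#' Is the WMW p-value strictly smaller than the t-test p-value?
#'
#' Strict comparison; ties count as "not smaller".
#'
#' @param p_wmw,p_t Probabilities in \[0, 1\].
#' @return A logical scalar.
#' @export
compare_p <- function(p_wmw, p_t) {
  stopifnot(is.numeric(p_wmw), is.numeric(p_t),
            all(p_wmw >= 0 & p_wmw <= 1), all(p_t >= 0 & p_t <= 1))
  p_wmw < p_t
}
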