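#' Discrete size distributions
#'
#' Light container used throughout the package for clone-size laws: a vector
#' of non-negative values indexed by integer size (cells `k` or reads `q`)
#' from 0 up to a truncation bound, together with the mass beyond the bound.
#'
#' @param size integer sizes, `0:k_max`.
#' @param value expected clone counts or probabilities at each size.
#' @param log_value `log(value)`, kept to avoid underflow at large sizes.
#' @param tail_mass mass beyond the truncation bound.
#' @param kind label for printing ("progenitor", "peripheral", "sampled", ...).
#' @return An object of class `"size_distribution"`.
#' @keywords internal
size_distribution <- function(size, value, log_value = log(value),
                              tail_mass = 0, kind = "size") {
  stopifnot(length(size) == length(value), all(value >= -1e-15))
  structure(list(size = size, value = value, log_value = log_value,
                 tail_mass = tail_mass, kind = kind),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("%s size distribution on 0..%d (truncated mass %.3g, total %.6g)\n",
              x$kind, max(x$size), x$tail_mass, sum(x$value)))
  invisible(x)
}

#' @export
as.data.frame.size_distribution <- function(x, ...) {
  data.frame(size = x$size, value = x$value)
}

#' Stationary clone-size distribution in the progenitor pool
#'
#' The per-clone stationary law of the birth-death-immigration process that
#' each HSC lineage performs in the progenitor compartment: immigration at
#' the HSC differentiation rate `alpha`, per-cell birth at the stationary
#' growth rate `r`, per-cell removal at `mu`.  One-step detailed balance
#' `(alpha + r*k) P_k = mu*(k + 1) P_{k+1}` gives a negative binomial,
#' `P_k = (1 - rbar)^a * Gamma(a + k)/(Gamma(a) k!) * rbar^k` with
#' `a = alpha/r` and `rbar = r/mu`; for `a < 1` the head behaves like the
#' log-series `rbar^k k^(a-1)` (gamma-distribution approximation).  The
#' expected number of clones of size `k` is `c_k = C * P_k`.
#'
#' @param a normalized differentiation rate `alpha/r`, `> 0`.
#' @param rbar stationary growth-to-removal ratio `r/mu`, in `(0, 1)`.
#'   Supply `delta = 1 - rbar` instead when `rbar` is within rounding of 1.
#' @param delta alternative to `rbar` (`delta = 1 - rbar`), kept exact for
#'   the near-capacity regime where `delta ~ 1e-7`.
#' @param k_max truncation bound; if `NULL`, the smallest bound with tail
#'   mass below `tail_tol` (computed in log space; sizes up to 1e7 work).
#' @param tail_tol tail-mass tolerance for the automatic bound.
#' @return A [size_distribution] over `k = 0..k_max` with `value` the
#'   per-clone probabilities `P_k`.
#' @examples
#' pd <- progenitor_clone_dist(a = 1, rbar = 0.5)  # geometric: P_k = 0.5^(k+1)
#' pd$value[1:3]
#' @export
progenitor_clone_dist <- function(a, rbar = NULL, delta = NULL, k_max = NULL,
                                  tail_tol = 1e-12) {
  delta <- resolve_delta(rbar, delta)
  stopifnot(a > 0)
  if (is.null(k_max)) {
    k_max <- qnbinom(tail_tol, size = a, prob = delta, lower.tail = FALSE) + 1L
    while (pnbinom(k_max, size = a, prob = delta, lower.tail = FALSE) > tail_tol)
      k_max <- k_max * 2L
  }
  if (k_max > 1e7) stop("k_max beyond supported range (1e7)")
  k <- 0:k_max
  lp <- dnbinom(k, size = a, prob = delta, log = TRUE)
  size_distribution(k, exp(lp), lp,
                    tail_mass = pnbinom(k_max, size = a, prob = delta,
                                        lower.tail = FALSE),
                    kind = "progenitor")
}

# accept either rbar or delta, preferring the explicitly supplied one
resolve_delta <- function(rbar, delta) {
  if (is.null(delta)) {
    stopifnot(!is.null(rbar), rbar > 0, rbar < 1)
    delta <- 1 - rbar
  }
  stopifnot(delta > 0, delta < 1)
  delta
}

#' Stationary clone sizes in the peripheral (differentiated) pool
#'
#' Conditional on a lineage holding `k` progenitor cells, its differentiated
#' cell count receives constant influx `(1 + eta)*omega*k` and per-cell
#' clearance `mu_d`, so the stationary conditional law is Poisson with mean
#' `w*k`, `w = (1 + eta)*omega/mu_d`.  The marginal over the progenitor law
#' is the Poisson mixture `y_n/C = sum_k P_k Poisson(n; w*k)`.
#'
#' @param pk a [size_distribution] of progenitor clone sizes (e.g. from
#'   [progenitor_clone_dist()]).
#' @param w amplification ratio `(1 + eta)*omega/mu_d`, `> 0`.
#' @param n_max truncation bound for the marginal; automatic if `NULL`.
#' @param tail_tol tail tolerance for the automatic bound.
#' @return A [size_distribution] over differentiated cell counts `n` with the
#'   mixture weights; the conditional means `w*k` are in attribute
#'   `"conditional_mean"`.
#' @export
peripheral_clone_dist <- function(pk, w, n_max = NULL, tail_tol = 1e-10) {
  stopifnot(inherits(pk, "size_distribution"), w > 0)
  k <- pk$size
  lam <- w * k
  if (is.null(n_max)) {
    n_max <- max(qpois(tail_tol / 10, max(lam), lower.tail = FALSE) + 5L, 10L)
  }
  n <- 0:n_max
  # log y_n = logsumexp_k [ log P_k + log Poisson(n; w k) ]
  ly <- vapply(n, function(nn) {
    logsumexp(pk$log_value + dpois(nn, lam, log = TRUE))
  }, numeric(1))
  out <- size_distribution(n, exp(ly), ly,
                           tail_mass = max(0, 1 - pk$tail_mass - sum(exp(ly))),
                           kind = "peripheral")
  attr(out, "conditional_mean") <- lam
  out
}

#' Expected sampled clone-size distribution
#'
#' When `S` marked reads are drawn from a marked differentiated pool of size
#' `Nd` (`epsilon = S/Nd << 1`), a lineage with `k` progenitor cells yields
#' `q` reads with probability `Poisson(q; eps_w*k)` where `eps_w =
#' epsilon*w`.  The expected fraction of clones seen with exactly `q` reads
#' is the negative-binomial/Poisson mixture
#' `<m_q>/C = sum_k P_k exp(-eps_w k)(eps_w k)^q / q!`.
#'
#' The default `method = "transform"` evaluates the mixture exactly via the
#' factorial-moment expansion of the negative-binomial generating function
#' (a finite sum of positive terms over Stirling numbers of the second kind,
#' assembled in log space), which is fast and carries no truncation error in
#' `k`.  `method = "ksum"` performs the literal sum over `k` with an
#' adaptive truncation bound (neglected mixing mass below `tail_tol`); it is
#' slower and retained as an independent cross-check.
#'
#' @inheritParams progenitor_clone_dist
#' @param eps_w combined sampling/turnover parameter `epsilon*w`, `>= 0`.
#' @param q_max largest read count to tabulate; if `NULL`, extended until the
#'   undetected tail mass is below `tail_tol`.
#' @param method `"transform"` (exact generating-function route, default) or
#'   `"ksum"` (brute-force summation over progenitor sizes).
#' @param tail_tol tolerance governing automatic truncation.
#' @return A [size_distribution] over reads `q = 0..q_max`; `value` holds
#'   `<m_q>/C` (multiply by `C` for expected clone counts).
#' @examples
#' m <- sampled_clone_dist(a = 0.1, delta = 1e-3, eps_w = 5e-5, q_max = 50)
#' sum(m$value[-1])  # detected fraction, cf. sampled_clone_fraction()
#' @export
sampled_clone_dist <- function(a, rbar = NULL, delta = NULL, eps_w,
                               q_max = NULL, method = c("transform", "ksum"),
                               tail_tol = 1e-10) {
  method <- match.arg(method)
  delta <- resolve_delta(rbar, delta)
  stopifnot(a > 0, eps_w >= 0)
  if (eps_w == 0) {
    q_max <- if (is.null(q_max)) 1L else q_max
    v <- c(1, rep(0, q_max))
    return(size_distribution(0:q_max, v, c(0, rep(-Inf, q_max)),
                             tail_mass = 0, kind = "sampled"))
  }
  detected <- sampled_clone_fraction(a, delta = delta, eps_w = eps_w)
  if (is.null(q_max)) {
    # grow until the not-yet-tabulated detected mass falls below tail_tol
    q_max <- 32L
    repeat {
      lv <- log_sampled_pmf(1:q_max, a, delta, eps_w, method)
      if (detected - sum(exp(lv)) < tail_tol || q_max >= 20000L) break
      q_max <- q_max * 2L
    }
  } else {
    lv <- log_sampled_pmf(1:q_max, a, delta, eps_w, method)
  }
  if (q_max > 20000L) stop("q_max beyond the supported range of the log-factorial tables")
  l0 <- log_sampled_p0(a, delta, eps_w)
  lv <- c(l0, lv)
  size_distribution(0:q_max, exp(lv), lv,
                    tail_mass = max(0, detected - sum(exp(lv[-1]))),
                    kind = "sampled")
}

# log <m_0>/C = a * (log delta - log(1 - rbar e^-eps_w)), the NB pgf at e^-eps_w
log_sampled_p0 <- function(a, delta, eps_w) {
  a * (log(delta) - log_one_minus_rbar_z(delta, eps_w))
}

# log(1 - (1-delta) e^-eps_w), stable when both delta and eps_w are tiny
log_one_minus_rbar_z <- function(delta, eps_w) {
  log(-expm1(log1p(-delta) - eps_w))
}

# log <m_q>/C at integer q >= 1, vectorized over q
log_sampled_pmf <- function(q, a, delta, eps_w, method = "transform") {
  if (method == "transform") {
    vapply(q, log_sampled_pmf_transform1, numeric(1),
           a = a, delta = delta, eps_w = eps_w)
  } else {
    log_sampled_pmf_ksum(q, a, delta, eps_w)
  }
}

# Exact factorial-moment route:
#   sum_k P_k e^{-l k} (l k)^q / q!  with  z = e^{-l}
#     = (l^q/q!) sum_n S(q,n) z^n G^(n)(z)
#     = (l^q/q!) delta^a sum_{n=1}^{q} S(q,n) (a)_n (rbar z)^n (1 - rbar z)^{-(a+n)}
# All summands are positive; assembled by log-sum-exp.
log_sampled_pmf_transform1 <- function(q, a, delta, eps_w) {
  if (q == 0) return(log_sampled_p0(a, delta, eps_w))
  lrz <- log1p(-delta) - eps_w            # log(rbar * z)
  lom <- log_one_minus_rbar_z(delta, eps_w)
  n <- 1:q
  terms <- stirling2_log_row(q) +
    lgamma(a + n) - lgamma(a) +
    n * lrz - (a + n) * lom
  q * log(eps_w) - lgamma(q + 1) + a * log(delta) + logsumexp(terms)
}

# Brute-force oracle: literal truncated sum over progenitor sizes k.
log_sampled_pmf_ksum <- function(q, a, delta, eps_w, tail_eps = 1e-16) {
  # the summand P_k Poisson(q; eps_w k) is proportional to the pmf of
  # NB(a + q, delta') in k, delta' = 1 - rbar e^{-eps_w}; bound k by its tail
  delta_p <- -expm1(log1p(-delta) - eps_w)
  vapply(q, function(qq) {
    k_hi <- qnbinom(tail_eps, size = a + qq, prob = delta_p,
                    lower.tail = FALSE) + 10
    k <- 0:k_hi
    logsumexp(dnbinom(k, size = a, prob = delta, log = TRUE) +
                dpois(qq, eps_w * k, log = TRUE))
  }, numeric(1))
}

#' Two-stage sampling sum (validation form)
#'
#' The collapsed law above treats reads as `Poisson(eps_w * k)` directly.
#' The exact two-stage construction first mixes the peripheral Poisson law,
#' `l ~ Poisson(w k)`, then samples reads as `Poisson(epsilon * l)`:
#' `<m_q>/C = sum_k P_k sum_l Poisson(l; w k) Poisson(q; epsilon l)`.
#' The two agree to `O(epsilon)`; this slower exact form is kept for
#' validating the collapse and is only practical at moderate `w*k`.
#'
#' @inheritParams sampled_clone_dist
#' @param eps sampling fraction `S/Nd`.
#' @param w amplification `(1 + eta)*omega/mu_d`.
#' @return A [size_distribution] over `q = 0..q_max`.
#' @export
sampled_clone_dist_two_stage <- function(a, rbar = NULL, delta = NULL,
                                         eps, w, q_max, tail_tol = 1e-12) {
  delta <- resolve_delta(rbar, delta)
  stopifnot(a > 0, eps > 0, eps <= 1, w > 0)
  k_hi <- qnbinom(tail_tol, size = a, prob = delta, lower.tail = FALSE) + 5
  lv <- rep(-Inf, q_max + 1)
  for (k in 0:k_hi) {
    lpk <- dnbinom(k, size = a, prob = delta, log = TRUE)
    lam <- w * k
    l_hi <- qpois(tail_tol, lam, lower.tail = FALSE) + 5
    l <- 0:l_hi
    lpl <- dpois(l, lam, log = TRUE)
    for (q in 0:q_max) {
      lv[q + 1] <- logaddexp(lv[q + 1],
                             lpk + logsumexp(lpl + dpois(q, eps * l, log = TRUE)))
    }
  }
  v <- exp(lv)
  size_distribution(0:q_max, v, lv, tail_mass = max(0, 1 - sum(v)),
                    kind = "sampled (two-stage)")
}

#' Cumulative sampled-clone fraction Q(q)
#'
#' From the expected sampled clone counts `<m_q>` (any positive scaling),
#' forms the cumulative `F(q) = sum_{k <= q} <m_k>` and the fraction of
#' detected clones represented by `q` or fewer reads,
#' `Q(q) = (F(q) - F(0)) / (F(S) - F(0))`, for `q = 1..S`.  `Q` is
#' nondecreasing with `Q(S) = 1` and is invariant under rescaling of `m`.
#'
#' @param m a [size_distribution] over reads including `q = 0` (e.g. from
#'   [sampled_clone_dist()]), or a numeric vector of `<m_q>` for `q = 0, 1, ...`.
#' @param S total sequenced reads: the upper limit of the support. If the
#'   tabulated support is shorter, the last tabulated value is used for
#'   `F(S)` (tail mass beyond it is assumed negligible).
#' @return A data frame with columns `q`, `F`, `Q` for `q = 1..min(S, q_max)`.
#' @export
cumulative_F_and_Q <- function(m, S) {
  stopifnot(S >= 1)
  v <- if (inherits(m, "size_distribution")) m$value else as.numeric(m)
  stopifnot(length(v) >= 2, all(v >= 0))
  q_hi <- min(S, length(v) - 1)
  Fq <- cumsum(v)                      # F(0), F(1), ..., F(q_max)
  FS <- Fq[q_hi + 1]
  if (FS == Fq[1]) stop("no sampled clones: F(S) = F(0), Q is undefined")
  q <- 1:q_hi
  data.frame(q = q, F = Fq[q + 1], Q = (Fq[q + 1] - Fq[1]) / (FS - Fq[1]))
}

#' Expected fraction of clones detected in a sample
#'
#' The chance that an active HSC clone appears with at least one read,
#' `C_s/C`.  The exact form follows from the negative-binomial generating
#' function, `C_s/C = 1 - (delta / (1 - (1 - delta) e^{-eps_w}))^a`; for
#' `eps_w << 1` and small detected fractions it reduces to the logarithmic
#' approximation `a * log(eps_w/delta + 1)`.
#'
#' @inheritParams sampled_clone_dist
#' @param form `"exact"` or `"log_approx"`.
#' @return The detected fraction.  For `form = "log_approx"` the attribute
#'   `"valid"` flags the regime (`eps_w < 0.01` and result `< 0.1`) in which
#'   the approximation is trustworthy.
#' @examples
#' sampled_clone_fraction(a = 0.01, delta = 5e-5/70, eps_w = 5e-5,
#'                        form = "log_approx")  # ~ 0.01 * log(71)
#' @export
sampled_clone_fraction <- function(a, rbar = NULL, delta = NULL, eps_w,
                                   form = c("exact", "log_approx")) {
  form <- match.arg(form)
  delta <- resolve_delta(rbar, delta)
  stopifnot(a > 0, eps_w >= 0)
  if (form == "exact") {
    if (eps_w == 0) return(0)
    # 1 - exp(a * (log delta - log(1 - rbar e^-eps_w))), all in log space
    -expm1(a * (log(delta) - log_one_minus_rbar_z(delta, eps_w)))
  } else {
    out <- a * log1p(eps_w / delta)
    attr(out, "valid") <- (eps_w < 0.01) && (out < 0.1)
    out
  }
}
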