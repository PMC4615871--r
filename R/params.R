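#' Mechanistic model parameters
#'
#' Bundles the full parameter set of the three-pool model of clonal
#' hematopoiesis: `C` labeled and `U` unlabeled active HSCs feed a
#' transit-amplifying progenitor pool by asymmetric differentiation at rate
#' `alpha` per HSC; progenitors replicate at the carrying-capacity-regulated
#' Hill rate `r(Np) = p*K/(Np + K)`, die at rate `mu_p`, and terminally
#' differentiate at rate `omega` (symmetrically with probability `eta`);
#' differentiated peripheral cells turn over at rate `mu_d`.  All rates are
#' per month.
#'
#' Two derived combinations recur throughout the model: the combined
#' progenitor removal rate `mu = mu_p + eta*omega` and the
#' progenitor-to-peripheral amplification `w = (1 + eta)*omega/mu_d`.
#'
#' @param alpha HSC asymmetric differentiation rate (per month).
#' @param p free (low-density) progenitor replication rate (per month).
#' @param mu_p progenitor death rate (per month).
#' @param mu_d differentiated-cell death rate (per month).
#' @param eta probability that a terminal differentiation event is symmetric
#'   (both daughters differentiated), in `[0, 1]`.
#' @param omega terminal differentiation rate (per month).
#' @param K progenitor carrying capacity (cells); the pool size at which the
#'   effective growth rate falls to `p/2`.
#' @param U number of active unlabeled HSCs.
#' @param C number of active labeled (vector-marked) HSC clones.
#' @param S optional number of sequenced marked reads per sample; used to
#'   derive the sampling fraction `epsilon = S/Nd` where needed.
#' @return An object of class `"model_params"`: a list of the arguments plus
#'   derived `mu` and `w`.
#' @examples
#' pars <- model_params(alpha = 0.2, p = 2, mu_p = 0.6, mu_d = 1,
#'                      eta = 0.5, omega = 0.8, K = 100, U = 0, C = 100)
#' pars$mu  # 1.0
#' @export
model_params <- function(alpha, p, mu_p, mu_d, eta, omega, K, U, C, S = NULL) {
  stopifnot(alpha >= 0, p >= 0, mu_p >= 0, mu_d >= 0, omega >= 0,
            eta >= 0, eta <= 1, K >= 1, U >= 0, C >= 1)
  mu <- mu_p + eta * omega
  if (!(p > mu))
    stop("low-density progenitor growth must be net positive: require p > mu_p + eta*omega")
  out <- list(alpha = alpha, p = p, mu_p = mu_p, mu_d = mu_d, eta = eta,
              omega = omega, K = K, U = U, C = C, S = S,
              mu = mu, w = (1 + eta) * omega / mu_d)
  class(out) <- "model_params"
  out
}

#' @export
print.model_params <- function(x, ...) {
  cat("Three-pool clonal hematopoiesis parameters (rates per month)\n")
  cat(sprintf("  HSCs: alpha = %g, U = %g unlabeled, C = %g labeled clones\n",
              x$alpha, x$U, x$C))
  cat(sprintf("  progenitors: p = %g, mu_p = %g, omega = %g, eta = %g, K = %g\n",
              x$p, x$mu_p, x$omega, x$eta, x$K))
  cat(sprintf("  peripheral: mu_d = %g;  derived mu = %g, w = %g\n",
              x$mu_d, x$mu, x$w))
  invisible(x)
}

#' Hill-regulated progenitor growth rate
#'
#' The effective per-cell replication rate of transit-amplifying progenitors,
#' `r(Np) = p*K/(Np + K)`: equal to the free rate `p` for an empty pool,
#' half-maximal at the carrying capacity `Np = K`, and monotonically
#' decreasing to zero as the pool grows.
#'
#' @param Np total progenitor population (cells), `>= 0`.
#' @param p free replication rate (per month).
#' @param K carrying capacity (cells), `> 0`.
#' @return The growth rate (per month), vectorized over `Np`.
#' @export
growth_rate <- function(Np, p, K) {
  stopifnot(all(Np >= 0), K > 0, p >= 0)
  p * K / (Np + K)
}

#' Steady state of the progenitor and peripheral pools
#'
#' Solves the stationary balance `alpha*(U + C) + (r(Np) - mu)*Np = 0`
#' (a quadratic in `Np`, positive root) for the total progenitor population,
#' and reports the stationary growth rate `r(Np*)`, its ratio
#' `rbar = r/mu`, the shortfall `delta = 1 - rbar` (computed stably from the
#' exact balance `delta = alpha*(U + C)/(mu*Np*)`), and the peripheral pool
#' `Nd* = w*Np*`.
#'
#' @param params a [model_params()] object with `p > mu` (regulated regime).
#' @return A list with elements `Np`, `Nd`, `r`, `rbar`, `delta`.
#' @examples
#' pars <- model_params(alpha = 0.2, p = 2, mu_p = 0.6, mu_d = 1,
#'                      eta = 0.5, omega = 0.8, K = 100, U = 0, C = 100)
#' steady_state_pools(pars)$delta
#' @export
steady_state_pools <- function(params) {
  stopifnot(inherits(params, "model_params"))
  A <- params$U + params$C
  mu <- params$mu
  aA <- params$alpha * A
  if (aA == 0 && params$p <= mu)
    stop("no positive steady state: p <= mu with no HSC influx")
  # mu*Np^2 - (alpha*A + (p - mu)*K)*Np - alpha*A*K = 0
  B <- aA + (params$p - mu) * params$K
  Np <- (B + sqrt(B^2 + 4 * mu * aA * params$K)) / (2 * mu)
  r <- growth_rate(Np, params$p, params$K)
  # exact balance (r - mu)*Np = -alpha*A  =>  delta = alpha*A/(mu*Np)
  delta <- if (aA > 0) aA / (mu * Np) else 1 - r / mu
  list(Np = Np, Nd = params$w * Np, r = r, rbar = 1 - delta, delta = delta)
}

#' Small-delta approximation for the growth-rate shortfall
#'
#' In the regulated regime near carrying capacity the stationary growth rate
#' sits just below the removal rate, `rbar = r/mu = 1 - delta` with
#' `delta ~ alpha*(U + C) / ((p - mu)*K)`, i.e. inversely proportional to the
#' carrying capacity.  Accurate to relative order `delta` compared with the
#' exact root of [steady_state_pools()].
#'
#' @inheritParams steady_state_pools
#' @return the dimensionless shortfall `delta`.
#' @export
delta_approx <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$alpha * (params$U + params$C) / ((params$p - params$mu) * params$K)
}

#' Effective (fit-identifiable) parameters
#'
#' The steady-state clone-size distribution depends on the mechanistic
#' parameters essentially only through two combinations: the normalized HSC
#' differentiation rate `a = alpha/r` and the composite parameter
#' `R = eps_w/log(1/rbar)` (approximately `eps_w/delta` when `delta << 1`),
#' where `eps_w = epsilon*w` couples read sampling depth to peripheral
#' turnover.  This constructor validates the triple and derives
#' `delta = 1 - rbar` from the exact consistency relation
#' `R*log(1/(1 - delta)) = eps_w`.
#'
#' @param a normalized HSC differentiation rate `alpha/r`, `> 0`.
#' @param R composite sampling-by-regulation parameter, `> 0`.
#' @param eps_w product of the sampling fraction `epsilon = S/Nd` and the
#'   amplification `w = (1 + eta)*omega/mu_d`, `> 0`.
#' @return An object of class `"effective_params"`: list with `a`, `R`,
#'   `eps_w`, `delta`, `rbar`.
#' @examples
#' effective_params(a = 0.01, R = 70, eps_w = 5e-5)
#' @export
effective_params <- function(a, R, eps_w) {
  stopifnot(a > 0, R > 0, eps_w > 0)
  # rbar = exp(-eps_w/R); delta via expm1 for precision at small eps_w/R
  delta <- -expm1(-eps_w / R)
  out <- list(a = a, R = R, eps_w = eps_w, delta = delta, rbar = 1 - delta)
  class(out) <- "effective_params"
  out
}

#' @export
print.effective_params <- function(x, ...) {
  cat(sprintf(
    "Effective clone-size parameters: a = %g, R = %g (eps_w = %g, delta = %g)\n",
    x$a, x$R, x$eps_w, x$delta))
  invisible(x)
}

#' Map mechanistic parameters to the effective pair (a, R)
#'
#' Solves the pool steady state and returns `a = alpha/r(Np*)` and
#' `R = eps_w / log(1/rbar)` together with `delta` and `eps_w`.  The sampling
#' fraction is `epsilon = S/Nd*` with `S` taken from `params$S` unless given
#' explicitly.
#'
#' @inheritParams steady_state_pools
#' @param S number of sequenced marked reads (defaults to `params$S`).
#' @return An [effective_params()] object.
#' @export
effective_from_mechanistic <- function(params, S = params$S) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(S)) stop("S (reads per sample) is required to form eps_w = (S/Nd)*w")
  ss <- steady_state_pools(params)
  eps_w <- (S / ss$Nd) * params$w
  eff <- effective_params(a = params$alpha / ss$r,
                          R = eps_w / (-log1p(-ss$delta)),
                          eps_w = eps_w)
  # keep the exact mechanistic delta (identical to -expm1(-eps_w/R) by construction)
  eff$delta <- ss$delta
  eff$rbar <- ss$rbar
  eff
}
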