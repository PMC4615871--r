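#' Negative log-likelihood of a read histogram under the stationary model
#'
#' Detected clones are treated as i.i.d. draws from the stationary sampled
#' clone-size law conditioned on detection: with `rbar = exp(-eps_w/R)`,
#' `p_q = (<m_q>/C) / (1 - <m_0>/C)` for `q >= 1`, and the histogram
#' contributes `-sum_q n_q log p_q` (a multinomial likelihood conditional on
#' detection; Poisson sampling of many small clones decouples their counts).
#' Evaluated wholly in log space, so `p_q` never underflows at observed `q`.
#'
#' When the total number of marked clones `C_total` is known (synthetic
#' data; or experiments where the transplanted clone count is measured), the
#' detected-clone count adds a binomial factor
#' `C_s ~ Binomial(C_total, C_s/C(a, R))` that sharpens `a` considerably: in
#' the small-`a` regime the conditional shape approaches a log-series limit
#' that depends on `a` only at first order, so the detection probability
#' carries most of the information about `a`.
#'
#' @param hist a `clone_histogram` (columns `q`, `n_q`).
#' @param a,R effective parameters (both `> 0`).
#' @param eps_w fixed sampling/turnover parameter (`> 0`).
#' @param C_total optional known total number of marked clones; adds the
#'   detected-count binomial term.
#' @return Negative log-likelihood in nats.
#' @export
clone_negloglik <- function(hist, a, R, eps_w, C_total = NULL) {
  stopifnot(nrow(hist) >= 1, a > 0, R > 0, eps_w > 0)
  delta <- -expm1(-eps_w / R)
  lq <- log_sampled_pmf(hist$q, a, delta, eps_w)
  lp0 <- log_sampled_p0(a, delta, eps_w)
  ldetect <- log1mexp(lp0)
  nll <- -sum(hist$n_q * (lq - ldetect))
  if (!is.null(C_total)) {
    Cs <- sum(hist$n_q)
    stopifnot(C_total >= Cs)
    nll <- nll - (Cs * ldetect + (C_total - Cs) * lp0)
  }
  nll
}

#' Maximum-likelihood fit of the effective parameters (a, R)
#'
#' Coarse grid search over `(log a, log R)` followed by derivative-free
#' (Nelder-Mead) refinement of [clone_negloglik()], with `eps_w` held fixed
#' (the likelihood is nearly flat in `eps_w` at fixed `(a, R)`, so it is not
#' estimable from shape; supply it from estimates of the sampling fraction
#' and peripheral turnover).
#'
#' @inheritParams clone_negloglik
#' @param eps_w fixed value of `epsilon*w`.  The default `5e-5` is a
#'   representative deep-sequencing operating point; override per sample
#'   from `S/Nd * w` when those are known.
#' @param a_range,R_range search box (natural scale).
#' @param grid_n coarse grid resolution per axis.
#' @param reltol relative parameter tolerance of the refinement.
#' @return An object of class `"clone_fit"`: list with `a_star`, `R_star`,
#'   `eps_w_fixed`, `loglik`, `converged`, `boundary_flag` (optimum within
#'   one grid step of the box edge), `UC_estimate` (= `S/(R* a*)` when the
#'   histogram carries its total read count), `S_used`,
#'   `n_clones_observed`, and the coarse `grid` (for diagnostics).
#' @examples
#' h <- sample_steady_state_reads(effective_params(0.05, 30, 5e-5),
#'                                C = 5e4, seed = 3)
#' fit <- fit_clone_mle(h, eps_w = 5e-5, grid_n = 15)
#' c(fit$a_star, fit$R_star)
#' @export
fit_clone_mle <- function(hist, eps_w = 5e-5,
                          a_range = c(1e-4, 1), R_range = c(1, 1e4),
                          grid_n = 21, reltol = 1e-10, C_total = NULL) {
  stopifnot(nrow(hist) >= 1, eps_w > 0)
  la <- seq(log(a_range[1]), log(a_range[2]), length.out = grid_n)
  lR <- seq(log(R_range[1]), log(R_range[2]), length.out = grid_n)
  nll_grid <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n))
    for (j in seq_len(grid_n))
      nll_grid[i, j] <- clone_negloglik(hist, exp(la[i]), exp(lR[j]), eps_w, C_total)
  ij <- which(nll_grid == min(nll_grid), arr.ind = TRUE)[1, ]
  start <- c(la[ij[1]], lR[ij[2]])
  obj <- function(th) {
    if (th[1] < log(a_range[1]) - 1e-9 || th[1] > log(a_range[2]) + 1e-9 ||
        th[2] < log(R_range[1]) - 1e-9 || th[2] > log(R_range[2]) + 1e-9)
      return(Inf)
    clone_negloglik(hist, exp(th[1]), exp(th[2]), eps_w, C_total)
  }
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = reltol, maxit = 2000))
  step_a <- diff(la)[1]; step_R <- diff(lR)[1]
  boundary <- opt$par[1] < log(a_range[1]) + step_a ||
    opt$par[1] > log(a_range[2]) - step_a ||
    opt$par[2] < log(R_range[1]) + step_R ||
    opt$par[2] > log(R_range[2]) - step_R
  S_used <- attr(hist, "S")
  a_star <- exp(opt$par[1]); R_star <- exp(opt$par[2])
  out <- list(a_star = a_star, R_star = R_star, eps_w_fixed = eps_w,
              loglik = -opt$value, converged = opt$convergence == 0,
              boundary_flag = boundary,
              UC_estimate = if (!is.null(S_used) && is.finite(S_used))
                S_used / (R_star * a_star) else NA_real_,
              S_used = if (is.null(S_used)) NA_real_ else S_used,
              n_clones_observed = attr(hist, "n_clones"),
              a_range = a_range, R_range = R_range,
              grid = list(log_a = la, log_R = lR, nll = nll_grid))
  class(out) <- "clone_fit"
  out
}

#' @export
print.clone_fit <- function(x, ...) {
  cat(sprintf("MLE of the stationary clone-size law (eps_w fixed at %g)\n",
              x$eps_w_fixed))
  cat(sprintf("  a* = %.4g, R* = %.4g, logLik = %.2f (%s%s)\n",
              x$a_star, x$R_star, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              if (x$boundary_flag) ", at search-box boundary" else ""))
  if (is.finite(x$UC_estimate))
    cat(sprintf("  active HSCs U+C ~ S/(R* a*) = %.0f (S = %g, %d clones observed)\n",
                x$UC_estimate, x$S_used, x$n_clones_observed))
  invisible(x)
}

#' Estimate the number of actively contributing HSCs
#'
#' In the small-sample limit `S << R*K` the number of active stem cells
#' (labeled plus unlabeled) satisfies `U + C ~ S / (R* a*)`: the expected
#' reads per active clone is `a*R*`, so the read budget divided by it counts
#' the clones feeding the blood.
#'
#' @param S total sequenced marked reads of the sample.
#' @param fit a `"clone_fit"` object.
#' @param K optionally, the carrying capacity; when supplied, the validity
#'   flag checks `S < 0.01 * R* * K`.
#' @return The estimate, with attribute `"small_sample_ok"` when `K` given.
#' @examples
#' \dontrun{estimate_UC(10026, fit)}
#' @export
estimate_UC <- function(S, fit, K = NULL) {
  stopifnot(inherits(fit, "clone_fit"), S >= 1)
  if (!fit$converged) warning("fit did not converge; estimate unreliable")
  out <- S / (fit$R_star * fit$a_star)
  if (!is.null(K)) attr(out, "small_sample_ok") <- S < 0.01 * fit$R_star * K
  out
}

#' Profile likelihood over one effective parameter
#'
#' Profiles the negative log-likelihood over `a` or `R` (re-optimizing the
#' other parameter at each grid point) and reports the interval where the
#' profile lies within 1.92 nats of its minimum (the asymptotic 95% level
#' for one parameter).
#'
#' @inheritParams fit_clone_mle
#' @param param `"a"` or `"R"`.
#' @param grid vector of parameter values to profile over; by default, 61
#'   log-spaced points centered on the fitted value and spanning a factor
#'   `e^3` around it (clipped to the search box).
#' @param fit optional `"clone_fit"` (refitted if missing).
#' @param C_total passed through to the likelihood (see [clone_negloglik()]).
#' @return A list with `param`, `grid`, `profile_nll`, `ci` (the 1.92-unit
#'   interval, endpoints log-interpolated between grid points; ends that run
#'   off the grid are `-Inf`/`Inf` and flagged by `monotone`), and the
#'   minimizing value.
#' @export
profile_loglik <- function(hist, eps_w = 5e-5, param = c("a", "R"),
                           grid = NULL, fit = NULL, C_total = NULL) {
  param <- match.arg(param)
  if (is.null(fit)) fit <- fit_clone_mle(hist, eps_w, C_total = C_total)
  box <- if (param == "a") fit$a_range else fit$R_range
  other_box <- if (param == "a") fit$R_range else fit$a_range
  if (is.null(grid)) {
    center <- log(if (param == "a") fit$a_star else fit$R_star)
    grid <- exp(seq(max(log(box[1]), center - 1.5),
                    min(log(box[2]), center + 1.5), length.out = 61))
  }
  prof <- vapply(grid, function(v) {
    optimize(function(lo) {
      if (param == "a") clone_negloglik(hist, v, exp(lo), eps_w, C_total)
      else clone_negloglik(hist, exp(lo), v, eps_w, C_total)
    }, interval = log(other_box), tol = 1e-8)$objective
  }, numeric(1))
  nll_min <- min(prof, -fit$loglik)
  thr <- nll_min + 1.92
  inside <- prof <= thr
  lg <- log(grid)
  cross <- function(i, j) {  # log-interpolated crossing between grid points
    exp(lg[i] + (thr - prof[i]) * (lg[j] - lg[i]) / (prof[j] - prof[i]))
  }
  lo <- hi <- NA_real_
  if (!any(inside)) {
    lo <- hi <- grid[which.min(prof)]
  } else {
    i1 <- min(which(inside)); i2 <- max(which(inside))
    lo <- if (i1 == 1) -Inf else cross(i1 - 1, i1)
    hi <- if (i2 == length(grid)) Inf else cross(i2 + 1, i2)
  }
  list(param = param, grid = grid, profile_nll = prof,
       ci = c(lower = lo, upper = hi),
       monotone = is.infinite(lo) || is.infinite(hi),
       minimum = grid[which.min(prof)])
}

#' Goodness of fit of a stationary-model fit
#'
#' Reports the multinomial deviance against the saturated model, the
#' sup-norm distance between the empirical and fitted cumulative fraction
#' `Q(q)`, and a parametric-bootstrap Monte Carlo p-value for the latter
#' (histograms resimulated from the fitted conditional law).
#'
#' @inheritParams fit_clone_mle
#' @param fit a `"clone_fit"`.
#' @param n_boot bootstrap replicates.
#' @param seed seed for the bootstrap, or `NULL`.
#' @return A list with `deviance`, `sup_Q`, `p_value`, `n_boot`.
#' @export
goodness_of_fit <- function(hist, fit, n_boot = 200, seed = NULL) {
  stopifnot(inherits(fit, "clone_fit"))
  if (!is.null(seed)) set.seed(seed)
  n <- sum(hist$n_q)
  model <- conditional_read_pmf(fit$a_star, fit$R_star, fit$eps_w_fixed,
                                q_hi = max(hist$q))
  sup_and_dev <- function(h) {
    lp <- model$logp_at(h$q)
    dev <- 2 * sum(h$n_q * (log(h$n_q / sum(h$n_q)) - lp))
    Qemp <- cumsum(h$n_q) / sum(h$n_q)   # h is sorted by q
    Qmod <- model$cdf_at(h$q)
    list(dev = dev, sup = max(abs(Qemp - Qmod)))
  }
  obs <- sup_and_dev(hist)
  sups <- vapply(seq_len(n_boot), function(b) {
    qb <- sample(model$support, n, replace = TRUE, prob = model$p)
    tb <- table(qb)
    hb <- data.frame(q = as.integer(names(tb)), n_q = as.integer(tb))
    hb <- hb[order(hb$q), ]
    sup_and_dev(hb)$sup
  }, numeric(1))
  list(deviance = obs$dev, sup_Q = obs$sup,
       p_value = (1 + sum(sups >= obs$sup)) / (n_boot + 1),
       boot_sup = sups, n_boot = n_boot)
}

# Conditional-on-detection read pmf on a finite support with tail folded
# into the last point (for simulation and cdf evaluation).
conditional_read_pmf <- function(a, R, eps_w, q_hi, tail_tol = 1e-9) {
  delta <- -expm1(-eps_w / R)
  m <- sampled_clone_dist(a, delta = delta, eps_w = eps_w, tail_tol = tail_tol)
  q_hi <- max(q_hi, max(m$size))
  support <- 1:max(m$size)
  detected <- sum(m$value[-1]) + m$tail_mass
  p <- m$value[-1] / detected
  p[length(p)] <- p[length(p)] + m$tail_mass / detected
  ldetect <- log1mexp(log_sampled_p0(a, delta, eps_w))
  cdfv <- cumsum(p)
  list(support = support, p = p,
       logp_at = function(q) log_sampled_pmf(q, a, delta, eps_w) - ldetect,
       cdf_at = function(q) cdfv[pmin(q, length(cdfv))])
}
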