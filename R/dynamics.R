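#' Right-hand side of the truncated clone-count master equations
#'
#' Mean-field evolution of the expected number of clones `c_k` of size `k`
#' in the progenitor pool,
#' `dc_k/dt = alpha*(c_{k-1} - c_k) + r*((k-1)c_{k-1} - k c_k)
#'           + mu*((k+1)c_{k+1} - k c_k)`,
#' with `c_0 = C - sum_k c_k`, coupled to the unlabeled progenitors
#' `du/dt = (r - mu)u + alpha*U` and the peripheral pool
#' `dNd/dt = (1 + eta)*omega*Np - mu_d*Nd`.  The growth rate
#' `r(Np)` is evaluated from the instantaneous total
#' `Np = u + sum_k k c_k` (plus tracked tail cells), which makes moment
#' closure exact: summing `k * dc_k/dt` recovers the scalar `Np` equation.
#'
#' The ladder is truncated at `k_max`; clone flux crossing the boundary,
#' `(alpha + r*k_max)*c_kmax`, is absorbed into a tail accumulator whose
#' clone and cell content is tracked so that a too-small `k_max` is
#' detectable rather than silently distorting the solution.
#'
#' @param state named list or numeric state: `c` (vector, `k = 1..k_max`),
#'   `u`, `Nd`, `tail_clones`, `tail_cells`.
#' @param params a [model_params()] object.
#' @return A list with the derivatives (`dc`, `du`, `dNd`, `dtail_clones`,
#'   `dtail_cells`) and the current `r`, `Np`, `c0`.
#' @export
clone_master_rhs <- function(state, params) {
  c_k <- state$c
  k_max <- length(c_k)
  k <- seq_len(k_max)
  c0 <- params$C - sum(c_k) - state$tail_clones
  Np <- state$u + sum(k * c_k) + state$tail_cells
  r <- growth_rate(Np, params$p, params$K)
  mu <- params$mu
  alpha <- params$alpha
  cm1 <- c(c0, c_k[-k_max])            # c_{k-1}
  cp1 <- c(c_k[-1], 0)                 # c_{k+1}, zero above the boundary
  dc <- alpha * (cm1 - c_k) +
    r * ((k - 1) * cm1 - k * c_k) +
    mu * ((k + 1) * cp1 - k * c_k)
  flux_up <- (alpha + r * k_max) * c_k[k_max]
  list(dc = dc,
       du = (r - mu) * state$u + alpha * params$U,
       dNd = (1 + params$eta) * params$omega * Np - params$mu_d * state$Nd,
       dtail_clones = flux_up,
       dtail_cells = (k_max + 1) * flux_up,
       r = r, Np = Np, c0 = c0)
}

#' Integrate the truncated clone-count master equations
#'
#' Stiff adaptive integration (via [deSolve::ode()], `lsoda`) of the system
#' defined by [clone_master_rhs()], starting by default from the
#' post-transplant initial condition: every lineage is a single HSC, the
#' progenitor and differentiated pools are empty (`c_k = 0`, `u = 0`,
#' `Nd = 0`).
#'
#' @param params a [model_params()] object.
#' @param times increasing vector of output times (months); must include the
#'   initial time as its first element.
#' @param k_max ladder truncation.  Default: the smallest size with
#'   stationary negative-binomial tail mass below `1e-12`, times a safety
#'   factor of 4 (transient fronts are broader than the stationary law).
#' @param state0 optional initial state list (`c`, `u`, `Nd`,
#'   `tail_clones`, `tail_cells`); default empty pools.
#' @param rtol,atol integration tolerances.
#' @param tail_tol error if the absorbed tail clone mass exceeds this
#'   fraction of `C` at any output time (signals `k_max` too small).
#' @return An object of class `"clone_trajectory"`: list with `times`,
#'   matrix `c` (rows = output times, columns `k = 1..k_max`), vectors
#'   `c0`, `u`, `Np`, `Nd`, `tail_clones`, `tail_cells`, and `params`.
#' @examples
#' pars <- model_params(alpha = 0.2, p = 2, mu_p = 0.6, mu_d = 1,
#'                      eta = 0.5, omega = 0.8, K = 100, U = 0, C = 100)
#' tr <- integrate_clone_dynamics(pars, times = c(0, 5, 50), k_max = 120)
#' tr$Np
#' @export
integrate_clone_dynamics <- function(params, times, k_max = NULL, state0 = NULL,
                                     rtol = 1e-8, atol = NULL, tail_tol = 1e-6) {
  stopifnot(inherits(params, "model_params"), all(diff(times) > 0))
  ss <- steady_state_pools(params)
  if (is.null(k_max)) {
    a <- params$alpha / ss$r
    k_tail <- qnbinom(1e-12, size = a, prob = ss$delta, lower.tail = FALSE) + 1
    k_max <- as.integer(4 * k_tail)
  }
  if (is.null(atol)) atol <- 1e-12 * params$C
  if (is.null(state0))
    state0 <- list(c = rep(0, k_max), u = 0, Nd = 0,
                   tail_clones = 0, tail_cells = 0)
  stopifnot(length(state0$c) == k_max)
  y0 <- c(state0$c, state0$u, state0$Nd, state0$tail_clones, state0$tail_cells)
  deriv <- function(t, y, parms) {
    st <- list(c = y[seq_len(k_max)], u = y[k_max + 1], Nd = y[k_max + 2],
               tail_clones = y[k_max + 3], tail_cells = y[k_max + 4])
    d <- clone_master_rhs(st, params)
    list(c(d$dc, d$du, d$dNd, d$dtail_clones, d$dtail_cells))
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("integration failed at t = %g", sol[nrow(sol), 1]))
  cmat <- sol[, 1 + seq_len(k_max), drop = FALSE]
  u <- sol[, k_max + 2]
  Nd <- sol[, k_max + 3]
  tail_clones <- sol[, k_max + 4]
  tail_cells <- sol[, k_max + 5]
  if (max(tail_clones) > tail_tol * params$C)
    stop(sprintf("tail accumulator reached %.3g clones: k_max = %d too small",
                 max(tail_clones), k_max))
  Np <- u + cmat %*% seq_len(k_max) + tail_cells
  structure(list(times = sol[, 1], c = cmat,
                 c0 = params$C - rowSums(cmat) - tail_clones,
                 u = u, Np = as.numeric(Np), Nd = Nd,
                 tail_clones = tail_clones, tail_cells = tail_cells,
                 k_max = k_max, params = params),
            class = "clone_trajectory")
}

#' @export
print.clone_trajectory <- function(x, ...) {
  cat(sprintf(
    "Clone-count trajectory: %d times in [%g, %g], k_max = %d, final Np = %.4g, Nd = %.4g\n",
    length(x$times), min(x$times), max(x$times), x$k_max,
    tail(x$Np, 1), tail(x$Nd, 1)))
  invisible(x)
}

#' Integrate the scalar mean pool sizes
#'
#' The closed two-dimensional system for the total progenitor and
#' differentiated populations,
#' `dNp/dt = alpha*(U + C) + (r(Np) - mu)*Np` and
#' `dNd/dt = (1 + eta)*omega*Np - mu_d*Nd`, from empty pools.  Because the
#' clone-resolved master equations close exactly under the first moment,
#' this must coincide with `Np` from [integrate_clone_dynamics()].
#'
#' @inheritParams integrate_clone_dynamics
#' @return A data frame with columns `time`, `Np`, `Nd`.
#' @export
integrate_mean_pools <- function(params, times, rtol = 1e-10, atol = 1e-10) {
  stopifnot(inherits(params, "model_params"))
  deriv <- function(t, y, parms) {
    r <- growth_rate(y[1], params$p, params$K)
    list(c(params$alpha * (params$U + params$C) + (r - params$mu) * y[1],
           (1 + params$eta) * params$omega * y[1] - params$mu_d * y[2]))
  }
  sol <- deSolve::ode(y = c(0, 0), times = times, func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
  data.frame(time = sol[, 1], Np = sol[, 2], Nd = sol[, 3])
}

#' Export a clone trajectory as long-format tables
#'
#' Writes `(t, k, c_k)` in long TSV form plus a `(t, Np, Nd, u)` summary.
#'
#' @param traj a `"clone_trajectory"` from [integrate_clone_dynamics()].
#' @param path_long,path_summary output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_trajectory <- function(traj, path_long, path_summary) {
  stopifnot(inherits(traj, "clone_trajectory"))
  long <- data.frame(
    t = rep(traj$times, each = traj$k_max),
    k = rep(seq_len(traj$k_max), times = length(traj$times)),
    c_k = as.numeric(t(traj$c)))
  write.table(long, path_long, sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- data.frame(t = traj$times, Np = traj$Np, Nd = traj$Nd, u = traj$u)
  write.table(summ, path_summary, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path_long, path_summary))
}
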