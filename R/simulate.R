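#' Simulation configuration
#'
#' Parameters and run settings for the stochastic three-pool simulator.
#' Extends [model_params()] with sampling times, sequencing depth, marked
#' fraction, seed and method.
#'
#' @inheritParams model_params
#' @param sample_times increasing vector of observation times (months).
#' @param S_per_sample intended sequencing depth (marked reads) per sample.
#' @param f marked fraction of sampled blood, in `(0, 1]`.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param method `"exact-event"` (Gillespie, every reaction simulated) or
#'   `"tau-leap"` (fixed-step Poisson leaping; use for carrying capacities
#'   where event-by-event simulation is infeasible).
#' @param max_events hard cap on simulated events in exact mode; exceeding
#'   it signals runaway growth (a `K` inconsistent with the method).
#' @param tau tau-leap step (months). Default: chosen so that the largest
#'   per-cell rate times the step is at most 0.05.
#' @return An object of class `"sim_config"` (also a `"model_params"`).
#' @examples
#' cfg <- sim_config(alpha = 1, p = 10, mu_p = 6, mu_d = 2, eta = 0.5,
#'                   omega = 4, K = 1e4, U = 0, C = 200,
#'                   sample_times = c(10, 20), seed = 1)
#' @export
sim_config <- function(alpha, p, mu_p, mu_d, eta, omega, K, U, C,
                       sample_times, S_per_sample = NULL, f = 1,
                       seed = NULL, method = c("exact-event", "tau-leap"),
                       max_events = 5e8, tau = NULL) {
  method <- match.arg(method)
  out <- model_params(alpha, p, mu_p, mu_d, eta, omega, K, U, C, S = S_per_sample)
  stopifnot(all(sample_times >= 0), all(diff(sample_times) > 0),
            f > 0, f <= 1)
  if (is.null(tau)) tau <- 0.05 / max(p + mu_p + omega, mu_d, alpha)
  out$sample_times <- sample_times
  out$S_per_sample <- S_per_sample
  out$f <- f
  out$seed <- seed
  out$method <- method
  out$max_events <- max_events
  out$tau <- tau
  class(out) <- c("sim_config", "model_params")
  out
}

#' Stochastic simulation of clonal repopulation
#'
#' Realizes the continuous-time Markov process underlying the mean-field
#' model.  Initial condition: each labeled clone and each unlabeled HSC is a
#' single HSC; the progenitor and differentiated pools are empty
#' (transplanted progenitor cells are ignored, as their clones die out).
#' HSCs never die or replicate; each fires asymmetric differentiations as an
#' independent rate-`alpha` Poisson process, adding progenitors to its own
#' lineage.  Progenitors replicate at the shared regulated rate
#' `r(Np) = p*K/(Np + K)`, die at `mu_p`, and terminally differentiate at
#' `omega` -- symmetrically (progenitor replaced by two differentiated
#' cells) with probability `eta`, else asymmetrically (progenitor kept, one
#' differentiated cell added).  Differentiated cells die at `mu_d`.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `"sim_trajectory"`: list with `t` (the sample
#'   times), integer matrices `n_prog`, `n_diff` (times x clones), vectors
#'   `u_prog`, `u_diff`, `Np`, `Nd`, the event count `n_events` (exact mode),
#'   the clamp counter `n_clamped` (tau-leap mode) and the `config`.
#' @export
simulate_clones <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- if (config$method == "exact-event") {
    z <- .ssa_simulate(config$alpha, config$p, config$mu_p, config$mu_d,
                       config$eta, config$omega, config$K,
                       config$U, config$C, config$sample_times,
                       config$max_events)
    z$n_clamped <- 0L
    z
  } else {
    tau_leap_simulate(config)
  }
  res$Np <- res$u_prog + rowSums(res$n_prog)
  res$Nd <- res$u_diff + rowSums(res$n_diff)
  res$config <- config
  class(res) <- "sim_trajectory"
  res
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf(
    "Stochastic clone trajectory (%s): %d clones, %d sample times, final Np = %g, Nd = %g\n",
    x$config$method, x$config$C, length(x$t),
    tail(x$Np, 1), tail(x$Nd, 1)))
  invisible(x)
}

# Fixed-step tau-leaping: per-clone Poisson event counts per step, with
# negative counts clamped to zero and counted (the clamp counter should stay
# at 0 in any sane configuration; it is reported, not hidden).
tau_leap_simulate <- function(config) {
  C <- config$C
  times <- config$sample_times
  tau <- config$tau
  nprog <- numeric(C); ndiff <- numeric(C)
  uprog <- 0; udiff <- 0
  out_prog <- matrix(0, length(times), C)
  out_diff <- matrix(0, length(times), C)
  out_up <- numeric(length(times)); out_ud <- numeric(length(times))
  t <- 0; ti <- 1; nclamp <- 0L
  t_end <- max(times)
  record <- function(tnew) {
    while (ti <= length(times) && times[ti] <= tnew) {
      out_prog[ti, ] <<- nprog; out_diff[ti, ] <<- ndiff
      out_up[ti] <<- uprog; out_ud[ti] <<- udiff
      ti <<- ti + 1
    }
  }
  record(t)
  while (ti <= length(times)) {
    step <- min(tau, t_end - t + tau / 2)
    Np <- uprog + sum(nprog)
    r <- growth_rate(Np, config$p, config$K)
    if (!is.finite(r)) stop("non-finite propensity in tau-leap step")
    imm <- rpois(C, config$alpha * step)
    births <- rpois(C, r * nprog * step)
    deaths <- rpois(C, config$mu_p * nprog * step)
    terms <- rpois(C, config$omega * nprog * step)
    sym <- rbinom(C, terms, config$eta)
    ddeaths <- rpois(C, config$mu_d * ndiff * step)
    nprog <- nprog + imm + births - deaths - sym
    neg <- nprog < 0
    nclamp <- nclamp + sum(neg)
    nprog[neg] <- 0
    ndiff <- ndiff + terms + sym - ddeaths
    neg <- ndiff < 0
    nclamp <- nclamp + sum(neg)
    ndiff[neg] <- 0
    # unlabeled pool, same channels in aggregate
    u_imm <- rpois(1, config$alpha * config$U * step)
    u_b <- rpois(1, r * uprog * step)
    u_d <- rpois(1, config$mu_p * uprog * step)
    u_t <- rpois(1, config$omega * uprog * step)
    u_s <- rbinom(1, u_t, config$eta)
    u_dd <- rpois(1, config$mu_d * udiff * step)
    uprog <- max(0, uprog + u_imm + u_b - u_d - u_s)
    udiff <- max(0, udiff + u_t + u_s - u_dd)
    t <- t + step
    record(t)
  }
  list(t = times, n_prog = out_prog, n_diff = out_diff,
       u_prog = out_up, u_diff = out_ud,
       n_events = NA_real_, n_clamped = nclamp)
}

#' Read sampling from a simulated state
#'
#' Emulates sequencing `S` marked reads from the differentiated pool at one
#' sample time.  With `mode = "binomial"` each clone's read count is a
#' binomial thinning of its differentiated cell count with success
#' probability `epsilon = S/Nd`; `mode = "poisson"` draws
#' `Poisson(epsilon * n_diff)` (the analytic model's approximation).  Clones
#' with zero reads are dropped.
#'
#' @param sim a `"sim_trajectory"` from [simulate_clones()].
#' @param time which sample time to use (must be one of `sim$t`).
#' @param S number of reads to draw (`epsilon = S/Nd <= 1` required).
#' @param mode `"binomial"` or `"poisson"`.
#' @param animal_id,cell_type labels copied into the output rows.
#' @return A list with `reads` (data frame: `animal_id`, `cell_type`,
#'   `months`, `clone_id`, `reads`) and `meta` (data frame: `animal_id`,
#'   `cell_type`, `months`, `S` realized, `f` realized marked fraction,
#'   `N_d_true`).
#' @export
sample_reads <- function(sim, time, S, mode = c("binomial", "poisson"),
                         animal_id = "sim", cell_type = "PBMC") {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "sim_trajectory"), S >= 1)
  ti <- match(time, sim$t)
  if (is.na(ti)) stop("time is not one of the recorded sample times")
  nd <- sim$n_diff[ti, ]
  Nd <- sim$Nd[ti]
  if (sum(nd) < 1) {
    reads <- data.frame(animal_id = character(), cell_type = character(),
                        months = numeric(), clone_id = character(),
                        reads = integer())
    meta <- data.frame(animal_id = animal_id, cell_type = cell_type,
                       months = time, S = 0L, f = 0, N_d_true = Nd)
    return(list(reads = reads, meta = meta))
  }
  eps <- S / Nd
  if (eps > 1) stop("S exceeds the differentiated pool: epsilon = S/Nd > 1")
  q <- if (mode == "binomial") rbinom(length(nd), nd, eps)
       else rpois(length(nd), eps * nd)
  keep <- q > 0
  reads <- data.frame(animal_id = animal_id, cell_type = cell_type,
                      months = time,
                      clone_id = sprintf("clone_%05d", which(keep)),
                      reads = q[keep])
  meta <- data.frame(animal_id = animal_id, cell_type = cell_type,
                     months = time, S = sum(q),
                     f = sum(nd) / Nd, N_d_true = Nd)
  list(reads = reads, meta = meta)
}

#' Draw a read histogram directly from the stationary law
#'
#' Fast fixture generator for inference: progenitor clone sizes are drawn
#' from the stationary negative binomial (`k ~ NB(a, delta)`), read counts
#' as `Poisson(eps_w * k)`, and zero-read clones are suppressed.  This is
#' sampling from [sampled_clone_dist()] without simulating dynamics.
#'
#' @param eff an [effective_params()] object (fields `a`, `delta`, `eps_w`).
#' @param C number of clones to draw.
#' @param seed integer seed, or `NULL`.
#' @return A `"clone_histogram"`: data frame with columns `q`, `n_q` and
#'   attributes `S` (total reads drawn), `n_clones` (detected clones) and
#'   `C_total`.
#' @examples
#' h <- sample_steady_state_reads(effective_params(0.01, 70, 5e-5),
#'                                C = 1e4, seed = 7)
#' head(h)
#' @export
sample_steady_state_reads <- function(eff, C, seed = NULL) {
  stopifnot(inherits(eff, "effective_params"), C >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- rnbinom(C, size = eff$a, prob = eff$delta)
  q <- rpois(C, eff$eps_w * k)
  q <- q[q > 0]
  tab <- table(q)
  out <- data.frame(q = as.integer(names(tab)), n_q = as.integer(tab))
  clone_histogram(out, S = sum(q))
}

# constructor shared by the samplers and vis_io
clone_histogram <- function(df, S = NA_real_, f = NA_real_, sample_id = NULL) {
  stopifnot(all(df$q >= 1), all(df$n_q >= 1), !anyDuplicated(df$q))
  df <- df[order(df$q), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("clone_histogram", "data.frame"),
            S = S, f = f, sample_id = sample_id,
            n_clones = sum(df$n_q))
}

#' @export
print.clone_histogram <- function(x, ...) {
  cat(sprintf("Clone read-count histogram: %d clones, %d distinct sizes, total reads %s\n",
              attr(x, "n_clones"), nrow(x),
              format(sum(as.numeric(x$q) * x$n_q))))
  NextMethod()
}
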