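test_that("progenitor stationary law is negative binomial with the right head", {
  # a = 1 collapses to a geometric law P_k = (1-rbar) rbar^k
  pd <- progenitor_clone_dist(a = 1, rbar = 0.5)
  expect_equal(pd$value[1:11], 0.5^(1:11), tolerance = 1e-12)
  # P_0 = delta^a in general
  pd2 <- progenitor_clone_dist(a = 0.3, delta = 0.2)
  expect_equal(pd2$value[1], 0.2^0.3)
  expect_lt(pd2$tail_mass, 1e-12)
  expect_equal(sum(pd2$value) + pd2$tail_mass, 1, tolerance = 1e-12)
})

test_that("small-a head follows the log-series form rbar^k k^(a-1)", {
  a <- 0.01; rbar <- 0.99
  pd <- progenitor_clone_dist(a = a, rbar = rbar, k_max = 200)
  k <- 1:100
  # log(P_k * k / P_1) should be linear in k with slope log(rbar), up to the
  # slowly varying k^a factor; check pointwise against the quoted gamma form
  quoted <- pd$value[2] * rbar^(k - 1) * k^(a - 1)
  expect_equal(pd$value[k + 1], quoted, tolerance = 0.01)
})

test_that("the stationary law satisfies one-step detailed balance", {
  a <- 0.23; delta <- 0.13
  rbar <- 1 - delta
  # (a + k) rbar P_k = (k+1) P_{k+1} in units of mu (alpha = a*r, r = rbar*mu)
  pd <- progenitor_clone_dist(a = a, delta = delta, k_max = 400)
  k <- 0:399
  lhs <- (a * rbar + rbar * k) * pd$value[k + 1]
  rhs <- (k + 1) * pd$value[k + 2]
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("peripheral law is the Poisson mixture of the progenitor law", {
  pd <- progenitor_clone_dist(a = 0.5, delta = 0.2)
  w <- 1.7
  yp <- peripheral_clone_dist(pd, w = w)
  # clone with no progenitors contributes a point mass at n = 0
  expect_equal(yp$value[1],
               sum(pd$value * dpois(0, w * pd$size)), tolerance = 1e-12)
  # law of total expectation: E n = w * E k
  expect_equal(sum(yp$size * yp$value),
               w * sum(pd$size * pd$value), tolerance = 1e-6)
  expect_equal(sum(yp$value) + yp$tail_mass, 1, tolerance = 1e-9)
})

test_that("sampled law: trivial eps_w = 0 and clone conservation", {
  m0 <- sampled_clone_dist(a = 0.1, delta = 0.01, eps_w = 0, q_max = 5)
  expect_equal(m0$value, c(1, rep(0, 5)))
  m <- sampled_clone_dist(a = 0.1, delta = 1e-3, eps_w = 5e-5, tail_tol = 1e-12)
  expect_equal(sum(m$value) + m$tail_mass, 1, tolerance = 1e-9)
})

test_that("transform method agrees with the brute-force k-sum oracle", {
  cases <- list(c(a = 0.1, delta = 1e-3, eps_w = 5e-5),
                c(a = 0.01, delta = 7.14e-7, eps_w = 5e-5),
                c(a = 0.5, delta = 0.05, eps_w = 1e-2))
  for (cs in cases) {
    q <- c(1, 2, 5, 10, 50, 200)
    lt <- hemaclone:::log_sampled_pmf(q, cs["a"], cs["delta"], cs["eps_w"],
                                      method = "transform")
    lk <- hemaclone:::log_sampled_pmf(q, cs["a"], cs["delta"], cs["eps_w"],
                                      method = "ksum")
    expect_equal(lt, lk, tolerance = 1e-10)
  }
})

test_that("detected mass matches the generating-function closed form", {
  # sum_{q>=1} <m_q>/C = 1 - (delta/(1 - (1-delta) e^-eps_w))^a
  for (a in c(0.01, 0.1)) for (delta in c(1e-4, 1e-2)) {
    m <- sampled_clone_dist(a = a, delta = delta, eps_w = 5e-5,
                            tail_tol = 1e-13)
    cs <- sampled_clone_fraction(a = a, delta = delta, eps_w = 5e-5)
    expect_equal(sum(m$value[-1]), cs, tolerance = 1e-8)
  }
})

test_that("two-stage sampling sum converges to the collapsed law as eps -> 0", {
  a <- 0.3; delta <- 0.1; w <- 2
  errs <- vapply(c(0.02, 0.005), function(eps) {
    ts <- sampled_clone_dist_two_stage(a, delta = delta, eps = eps, w = w,
                                       q_max = 12)
    cl <- sampled_clone_dist(a, delta = delta, eps_w = eps * w, q_max = 12)
    max(abs(ts$value - cl$value))
  }, numeric(1))
  expect_lt(errs[2], 1e-3)
  expect_lt(errs[2], errs[1] / 2)  # first-order in eps
})

test_that("sampled clone fraction: limits and the log approximation", {
  expect_equal(sampled_clone_fraction(a = 0.1, delta = 0.01, eps_w = 0), 0)
  la <- sampled_clone_fraction(a = 0.1, delta = 0.01, eps_w = 0,
                               form = "log_approx")
  expect_equal(as.numeric(la), 0)
  # eps_w -> infinity: probability the clone exists in the progenitor pool
  expect_equal(sampled_clone_fraction(a = 0.2, delta = 0.3, eps_w = 1e4),
               1 - 0.3^0.2, tolerance = 1e-10)
  # a = 0.01, eps_w/delta = 70: log form gives 0.01*log(71) ~ 0.0426 and the
  # exact form is within 2% of it at eps_w = 5e-5
  la2 <- sampled_clone_fraction(a = 0.01, delta = 5e-5 / 70, eps_w = 5e-5,
                                form = "log_approx")
  expect_equal(as.numeric(la2), 0.01 * log(71), tolerance = 1e-12)
  # the exact form sits below the log form by ~ result/2 (second-order term
  # of 1 - exp(-a log(...))), i.e. ~2% here
  ex2 <- sampled_clone_fraction(a = 0.01, delta = 5e-5 / 70, eps_w = 5e-5)
  rel <- (as.numeric(la2) - ex2) / as.numeric(la2)
  expect_equal(rel, as.numeric(la2) / 2, tolerance = 0.05)
  expect_lt(rel, 0.03)
  expect_true(attr(la2, "valid"))
})

test_that("cumulative Q: degenerate mass, rescale invariance, monotonicity", {
  # all detected mass at q = 1
  FQ <- cumulative_F_and_Q(c(0.7, 0.3), S = 1)
  expect_equal(FQ$Q, 1)
  m <- sampled_clone_dist(a = 0.1, delta = 1e-3, eps_w = 5e-5, q_max = 200)
  q1 <- cumulative_F_and_Q(m$value, S = 200)
  q2 <- cumulative_F_and_Q(17.3 * m$value, S = 200)
  expect_equal(q1$Q, q2$Q, tolerance = 1e-12)
  expect_true(all(diff(q1$Q) >= 0))
  expect_equal(q1$Q[nrow(q1)], 1)
  expect_error(cumulative_F_and_Q(c(1, 0, 0), S = 2), "undefined")
})

test_that("varying a at fixed R rescales the sampled law nearly uniformly", {
  # shape sensitivity: the a-dependence is mostly a multiplicative factor
  R <- 70; eps_w <- 5e-5
  avals <- c(0.0025, 0.01, 0.1)
  ms <- lapply(avals, function(a) {
    eff <- effective_params(a, R, eps_w)
    sampled_clone_dist(eff$a, delta = eff$delta, eps_w = eff$eps_w,
                       q_max = 1000)$value[-1]
  })
  q <- 1:1000
  # the residual shape change is the slowly varying factor q^(a1 - a2)
  # (from Gamma(a + q)/Gamma(q)); for nearby a it is within 10% of flat,
  # and for any pair it is captured by that power law to a few percent
  ratio <- ms[[1]] / ms[[2]]
  expect_lt(max(abs(ratio / median(ratio) - 1)), 0.10)
  for (i in 1:2) for (j in (i + 1):3) {
    ratio <- ms[[i]] / ms[[j]]
    shape <- ratio / q^(avals[i] - avals[j])
    expect_lt(max(abs(shape / median(shape) - 1)), 0.05)
  }
})

test_that("sampled law is strictly decreasing in q for a < 1", {
  eff <- op_point()
  m <- sampled_clone_dist(eff$a, delta = eff$delta, eps_w = eff$eps_w,
                          q_max = 1000)
  expect_true(all(diff(m$value[-1]) < 0))
})

test_that("matched effective parameters give identical Q curves from distinct mechanisms", {
  # two mechanistic sets tuned to the same (a, R, eps_w)
  p1 <- model_params(alpha = 0.2, p = 2, mu_p = 0.6, mu_d = 1, eta = 0.5,
                     omega = 0.8, K = 1e5, U = 0, C = 100, S = 50)
  mu <- p1$mu
  p2 <- model_params(alpha = 0.2, p = mu + (p1$p - mu) / 2, mu_p = 0.6,
                     mu_d = 1, eta = 0.5, omega = 0.8, K = 2e5, U = 0,
                     C = 100, S = 50)
  e1 <- effective_from_mechanistic(p1)
  e2 <- effective_from_mechanistic(p2)
  # matched up to O(delta) corrections of the exact steady-state root
  expect_equal(e1$a, e2$a, tolerance = 1e-6)
  expect_equal(e1$R, e2$R, tolerance = 1e-6)
  m1 <- sampled_clone_dist(e1$a, delta = e1$delta, eps_w = e1$eps_w, q_max = 300)
  m2 <- sampled_clone_dist(e2$a, delta = e2$delta, eps_w = e2$eps_w, q_max = 300)
  Q1 <- cumulative_F_and_Q(m1$value, S = 300)
  Q2 <- cumulative_F_and_Q(m2$value, S = 300)
  expect_lt(max(abs(Q1$Q - Q2$Q)), 1e-6)
  # alpha -> 0 sends a -> 0 and the detected fraction to 0
  p3 <- model_params(alpha = 1e-9, p = 2, mu_p = 0.6, mu_d = 1, eta = 0.5,
                     omega = 0.8, K = 1e5, U = 0, C = 100, S = 50)
  e3 <- effective_from_mechanistic(p3)
  expect_lt(e3$a, 1e-8)
  expect_lt(sampled_clone_fraction(e3$a, delta = e3$delta, eps_w = e3$eps_w),
            1e-6)
})
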