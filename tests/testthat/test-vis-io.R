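test_that("write + load round-trips a table and validates its shape", {
  paths <- write_tmp_table(toy_reads(), toy_meta())
  tab <- load_clone_table(paths["table"], paths["meta"])
  expect_equal(as.data.frame(tab)[names(toy_reads())], toy_reads())
  expect_equal(attr(tab, "meta")$S, 10)
  # simulated table round-trip
  cfg <- sim_config(alpha = 2, p = 4, mu_p = 1, mu_d = 0.5, eta = 0.5,
                    omega = 1, K = 300, U = 0, C = 40,
                    sample_times = c(8), seed = 11)
  s <- simulate_clones(cfg)
  rs <- sample_reads(s, 8, S = 50)
  paths2 <- write_tmp_table(rs$reads, rs$meta[c("animal_id", "cell_type",
                                               "months", "S", "f")])
  tab2 <- load_clone_table(paths2["table"], paths2["meta"])
  expect_equal(tab2$reads, rs$reads$reads)
  expect_equal(tab2$clone_id, rs$reads$clone_id)
})

test_that("malformed tables are rejected with line numbers", {
  p <- tempfile(fileext = ".tsv")
  writeLines("animal_id\tcell_type\tmonths\tclone_id\treads", p)
  expect_error(load_clone_table(p), "no data rows")
  reads <- toy_reads(); reads$reads[2] <- 0L
  paths <- write_tmp_table(reads, toy_meta())
  expect_error(load_clone_table(paths["table"], paths["meta"]),
               "line\\(s\\): 3")
  reads <- rbind(toy_reads(), toy_reads()[1, ])
  paths <- write_tmp_table(reads, toy_meta())
  expect_error(load_clone_table(paths["table"], paths["meta"]), "duplicate")
  paths <- write_tmp_table(toy_reads(), toy_meta()[0, ])
  expect_error(load_clone_table(paths["table"], paths["meta"]),
               "missing from metadata")
  paths <- write_tmp_table(toy_reads(), toy_meta(S = 3L))
  expect_error(load_clone_table(paths["table"], paths["meta"]),
               "exceed")
  expect_warning(load_clone_table(paths["table"]), "f = 0.065")
})

test_that("histograms count clones by exact read count", {
  paths <- write_tmp_table(toy_reads(), toy_meta())
  tab <- load_clone_table(paths["table"], paths["meta"])
  h <- clone_size_histogram(tab, "A1", "PBMC", 12)
  expect_equal(h$q, c(1L, 5L))
  expect_equal(h$n_q, c(2L, 1L))
  expect_equal(sum(h$q * h$n_q), sum(tab$reads))
  expect_equal(attr(h, "S"), 10)
  expect_error(clone_size_histogram(tab, "A1", "Grans", 12), "no such sample")
})

test_that("large simulated histograms match the generator's expectation", {
  eff <- effective_params(a = 0.2, R = 10, eps_w = 2e-3)
  C <- 1e5
  h <- sample_steady_state_reads(eff, C = C, seed = 8)
  m <- sampled_clone_dist(eff$a, delta = eff$delta, eps_w = eff$eps_w,
                          q_max = max(h$q))
  for (q in 1:8) {
    expected <- C * m$value[q + 1]
    observed <- if (q %in% h$q) h$n_q[h$q == q] else 0
    expect_lt(abs(observed - expected), 3 * sqrt(expected) + 1e-9)
  }
})

test_that("nu rescaling and its minimum are f*q/S and f/S", {
  expect_equal(rescale_nu(1e4, S = 1e4, f = 1), 1)
  expect_equal(rescale_nu(10, S = 1e4, f = 0.05), 5e-5)
  expect_equal(nu_min(S = 1e4, f = 0.05), 5e-6)
  q <- c(2, 5, 9)
  expect_true(all(diff(rescale_nu(q, 100, 0.1)) > 0))  # order preserved
})

test_that("empirical Q is a proper right-continuous step function", {
  h1 <- hemaclone:::clone_histogram(data.frame(q = 4L, n_q = 1L), S = 10, f = 0.1)
  Q1 <- empirical_Q(h1)
  expect_equal(Q1$Q, 1)           # single clone: unit step
  h <- hemaclone:::clone_histogram(data.frame(q = c(1L, 2L, 7L),
                                              n_q = c(5L, 3L, 2L)),
                                   S = 20, f = 0.05)
  Q <- empirical_Q(h)
  expect_true(all(diff(Q$Q) > 0))
  expect_equal(Q$Q[3], 1)
  expect_equal(Q$nu, 0.05 * c(1, 2, 7) / 20)
  expect_equal(Q$Q[1], 0.5)       # ties accumulate in one step
})

test_that("binomial reference has the stated mean and degenerate limit", {
  b <- binomial_reference(S = 50, mean_size = 8)
  expect_equal(sum(b$size * b$value), 8, tolerance = 1e-12)
  b2 <- binomial_reference(S = 20, mean_size = 20)
  expect_equal(b2$value[21], 1)   # point mass at q = S
  # the model's stationary law has more low-frequency clones than a
  # binomial of equal mean (conditional on detection)
  eff <- op_point()
  m <- sampled_clone_dist(eff$a, delta = eff$delta, eps_w = eff$eps_w,
                          q_max = 1000)
  pdet <- sum(m$value[-1])
  mean_q <- sum(m$size[-1] * m$value[-1]) / pdet
  bref <- binomial_reference(S = 1000, mean_size = mean_q)
  qlow <- seq_len(max(1, floor(mean_q)))   # below the binomial mode
  model_low <- sum(m$value[qlow + 1]) / pdet
  binom_low <- sum(bref$value[qlow + 1]) / sum(bref$value[-1])
  expect_gt(model_low, binom_low)
})

test_that("wide matrices convert to the long format with zeros dropped", {
  mat <- matrix(c(3, 0, 1, 0, 2, 5), nrow = 3,
                dimnames = list(c("a", "b", "c"), NULL))
  info <- data.frame(animal_id = c("A", "A"), cell_type = c("PBMC", "Grans"),
                     months = c(6, 6))
  long <- wide_to_long_clone_table(mat, info)
  expect_equal(nrow(long), 4)
  expect_equal(long$reads[long$clone_id == "a" & long$cell_type == "PBMC"], 3L)
  expect_false(any(long$reads == 0))
})

test_that("simulated Q(nu) curves at two post-relaxation times agree", {
  # the rescaled cumulative fraction is stationary once the pools relax
  cfg <- sim_config(alpha = 1, p = 10, mu_p = 6, mu_d = 2, eta = 0.5,
                    omega = 4, K = 2000, U = 0, C = 150,
                    sample_times = c(30, 40), seed = 314)
  s <- simulate_clones(cfg)
  S_fix <- 350   # identical depth at both times so the nu grids coincide
  get_nu <- function(ti) {
    set.seed(1000 + ti)
    rs <- sample_reads(s, s$t[ti], S = S_fix)
    rescale_nu(rs$reads$reads, S = S_fix, f = 1)
  }
  nu1 <- get_nu(1); nu2 <- get_nu(2)
  grid <- sort(unique(c(nu1, nu2)))
  Qof <- function(nu) ecdf(nu)(grid)
  obs_gap <- max(abs(Qof(nu1) - Qof(nu2)))
  # two-sample clone-resampling bootstrap band under stationarity: resample
  # both curves from the pooled reads and take the 95% quantile of the gap
  pooled <- c(nu1, nu2)
  set.seed(9)
  boot <- vapply(1:400, function(b) {
    max(abs(Qof(sample(pooled, length(nu1), replace = TRUE)) -
              Qof(sample(pooled, length(nu2), replace = TRUE))))
  }, numeric(1))
  expect_lt(obs_gap, quantile(boot, 0.95) + 1e-12)
})
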