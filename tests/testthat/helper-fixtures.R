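# Shared fixtures: a moderate-capacity parameter set whose steady state is
# reachable quickly (delta ~ 0.15, k_max a few hundred), and the reduced-K
# simulation configuration used for simulator-vs-theory comparisons.

moderate_params <- function(S = NULL) {
  model_params(alpha = 0.2, p = 2, mu_p = 0.6, mu_d = 1, eta = 0.5,
               omega = 0.8, K = 100, U = 0, C = 100, S = S)
}

# reduced-carrying-capacity simulation operating point (exact-event scale)
reduced_K_config <- function(sample_times, seed = 1, ...) {
  sim_config(alpha = 1, p = 10, mu_p = 6, mu_d = 2, eta = 0.5, omega = 4,
             K = 1e4, U = 0, C = 200, sample_times = sample_times,
             seed = seed, ...)
}

# deep-sequencing operating point of the fitted monkey samples
op_point <- function() effective_params(a = 0.01, R = 70, eps_w = 5e-5)

# build a read table + metadata in tempfiles, return the two paths
write_tmp_table <- function(reads, meta) {
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_clone_table(reads, meta, p1, p2)
  c(table = p1, meta = p2)
}

toy_reads <- function() {
  data.frame(animal_id = "A1", cell_type = "PBMC", months = 12,
             clone_id = c("c1", "c2", "c3"), reads = c(1L, 1L, 5L))
}

toy_meta <- function(S = 10L, f = 0.05) {
  data.frame(animal_id = "A1", cell_type = "PBMC", months = 12, S = S, f = f)
}
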