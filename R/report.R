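#' Read a pipeline run configuration
#'
#' Configurations are flat YAML files with a `mode` field
#' (`simulate`, `fit`, `recover` or `report`) plus the fields that mode
#' needs; see [run_pipeline()].  Rates are per month; `mu_d` may be given
#' as a string with a `/day` suffix (e.g. `"0.1/day"`) and is converted to
#' per month (30.44 days).
#'
#' @param path YAML file path.
#' @return A `"run_config"` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$mode) ||
      !cfg$mode %in% c("simulate", "fit", "recover", "report"))
    stop("config must set mode to one of simulate/fit/recover/report")
  if (!is.null(cfg$mu_d) && is.character(cfg$mu_d)) {
    if (grepl("/day$", cfg$mu_d))
      cfg$mu_d <- as.numeric(sub("/day$", "", cfg$mu_d)) * 30.44
    else cfg$mu_d <- as.numeric(cfg$mu_d)
  }
  structure(cfg, class = "run_config")
}

#' Run a configured analysis end to end
#'
#' Config-driven orchestration of the package's pipelines into a
#' deterministic artifact directory (`config.yaml` echo, `log.txt`, tables,
#' plots).  Modes:
#' \describe{
#'   \item{simulate}{stochastic replicates of the three-pool model; writes a
#'     clone read table + metadata per replicate (fields: the
#'     [sim_config()] parameters, `replicates`, `sample_S`,
#'     `read_mode`).}
#'   \item{fit}{loads a read table (`table`, `metadata` paths), builds the
#'     histogram of sample (`animal_id`, `cell_type`, `months`), fits
#'     `(a, R)` at fixed `eps_w`, writes `fit.json` and the
#'     fitted-vs-empirical `Q(q)` table.}
#'   \item{recover}{parameter-recovery experiment: draws histograms from the
#'     stationary law at known (`a`, `R`, `eps_w`, `C`) across `n_seeds`
#'     seeds, refits each, writes `recovery.tsv` and a deterministic
#'     `summary.txt`.}
#'   \item{report}{plots for a previous simulate/fit directory: `Q(nu)`
#'     overlays, clone-size sensitivity panels, fit summaries.}
#' }
#'
#' @param config a `"run_config"` (or path to one).
#' @param out output directory (created; must not exist unless
#'   `overwrite = TRUE`).
#' @param seed overrides the config seed.
#' @param overwrite replace an existing output directory.
#' @return The output directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out, seed = NULL, overwrite = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out) && !overwrite) stop("output directory exists: ", out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) config$seed <- seed
  yaml::write_yaml(unclass(config), file.path(out, "config.yaml"))
  logf <- file.path(out, "log.txt")
  logmsg <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = logf, append = TRUE)
    message(msg)
  }
  ok <- FALSE
  on.exit(if (!ok) writeLines("INCOMPLETE", file.path(out, "FAILED")))
  switch(config$mode,
         simulate = run_mode_simulate(config, out, logmsg),
         fit = run_mode_fit(config, out, logmsg),
         recover = run_mode_recover(config, out, logmsg),
         report = run_mode_report(config, out, logmsg))
  ok <- TRUE
  invisible(out)
}

run_mode_simulate <- function(cfg, out, logmsg) {
  need <- c("alpha", "p", "mu_p", "mu_d", "eta", "omega", "K", "U", "C",
            "sample_times")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("simulate config missing fields: ",
                         paste(miss, collapse = ", "))
  reps <- if (is.null(cfg$replicates)) 1L else cfg$replicates
  method <- if (is.null(cfg$method)) "exact-event" else cfg$method
  base_seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  for (rep in seq_len(reps)) {
    sc <- sim_config(cfg$alpha, cfg$p, cfg$mu_p, cfg$mu_d, cfg$eta,
                     cfg$omega, cfg$K, cfg$U, cfg$C,
                     sample_times = as.numeric(cfg$sample_times),
                     seed = base_seed + rep - 1L, method = method)
    sim <- simulate_clones(sc)
    all_reads <- list(); all_meta <- list()
    for (tm in sim$t) {
      S_target <- if (is.null(cfg$sample_S)) max(1, round(0.01 * sim$Nd[match(tm, sim$t)]))
                  else cfg$sample_S
      rs <- sample_reads(sim, tm, S_target,
                         mode = if (is.null(cfg$read_mode)) "binomial" else cfg$read_mode,
                         animal_id = sprintf("rep%02d", rep))
      all_reads[[length(all_reads) + 1]] <- rs$reads
      all_meta[[length(all_meta) + 1]] <- rs$meta
    }
    write_clone_table(do.call(rbind, all_reads), do.call(rbind, all_meta),
                      file.path(out, sprintf("reads_rep%02d.tsv", rep)),
                      file.path(out, sprintf("meta_rep%02d.tsv", rep)))
    logmsg("replicate %d: seed %d, %d sample times", rep, sc$seed, length(sim$t))
  }
}

run_mode_fit <- function(cfg, out, logmsg) {
  for (f in c("table", "animal_id", "cell_type", "months"))
    if (is.null(cfg[[f]])) stop("fit config missing field: ", f)
  tab <- load_clone_table(cfg$table, cfg$metadata)
  h <- clone_size_histogram(tab, cfg$animal_id, cfg$cell_type, cfg$months)
  eps_w <- if (is.null(cfg$eps_w)) 5e-5 else cfg$eps_w
  fit <- fit_clone_mle(h, eps_w = eps_w)
  res <- list(a_star = fit$a_star, R_star = fit$R_star,
              eps_w_fixed = fit$eps_w_fixed, loglik = fit$loglik,
              converged = fit$converged, boundary_flag = fit$boundary_flag,
              UC_estimate = fit$UC_estimate, S_used = fit$S_used,
              n_clones_observed = fit$n_clones_observed)
  jsonlite::write_json(res, file.path(out, "fit.json"),
                       auto_unbox = TRUE, digits = NA)
  # fitted vs empirical cumulative fraction
  delta <- -expm1(-eps_w / fit$R_star)
  m <- sampled_clone_dist(fit$a_star, delta = delta, eps_w = eps_w,
                          tail_tol = 1e-9)
  FQ <- cumulative_F_and_Q(m, S = max(m$size))
  emp <- empirical_Q(h)
  write.table(data.frame(q = FQ$q, Q_model = FQ$Q),
              file.path(out, "Q_model.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(emp, file.path(out, "Q_empirical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  logmsg("fit %s/%s/%s: a* = %.4g, R* = %.4g (%d clones)",
         cfg$animal_id, cfg$cell_type, cfg$months,
         fit$a_star, fit$R_star, fit$n_clones_observed)
}

run_mode_recover <- function(cfg, out, logmsg) {
  for (f in c("a", "R", "eps_w", "C"))
    if (is.null(cfg[[f]])) stop("recover config missing field: ", f)
  n_seeds <- if (is.null(cfg$n_seeds)) 5L else cfg$n_seeds
  base_seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  eff <- effective_params(cfg$a, cfg$R, cfg$eps_w)
  rows <- lapply(seq_len(n_seeds), function(i) {
    h <- sample_steady_state_reads(eff, C = cfg$C, seed = base_seed + i - 1L)
    fit <- fit_clone_mle(h, eps_w = cfg$eps_w, grid_n = 13, C_total = cfg$C)
    data.frame(seed = base_seed + i - 1L, a_hat = fit$a_star,
               R_hat = fit$R_star, UC_hat = fit$UC_estimate,
               n_clones = fit$n_clones_observed, S = fit$S_used)
  })
  rec <- do.call(rbind, rows)
  write.table(format(rec, digits = 12), file.path(out, "recovery.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- c(
    sprintf("truth\ta=%.*g\tR=%.*g\tC=%d", 12, cfg$a, 12, cfg$R, as.integer(cfg$C)),
    sprintf("median_a_hat\t%.12g", median(rec$a_hat)),
    sprintf("median_R_hat\t%.12g", median(rec$R_hat)),
    sprintf("median_UC_hat\t%.12g", median(rec$UC_hat)))
  writeLines(summ, file.path(out, "summary.txt"))
  logmsg("recovery over %d seeds: median a_hat %.4g, R_hat %.4g",
         n_seeds, median(rec$a_hat), median(rec$R_hat))
}

run_mode_report <- function(cfg, out, logmsg) {
  if (is.null(cfg$input)) stop("report config missing field: input")
  pdf_path <- file.path(out, "report.pdf")
  grDevices::pdf(pdf_path, width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  # Q(nu) overlays for any read tables found in the input directory
  tabs <- list.files(cfg$input, pattern = "^reads_.*\\.tsv$", full.names = TRUE)
  if (length(tabs)) {
    graphics::plot(NA, xlim = c(1e-6, 1), ylim = c(0, 1), log = "x",
                   xlab = expression(nu), ylab = expression(Q(nu)),
                   main = "Rescaled cumulative clone fractions")
    cols <- grDevices::hcl.colors(max(2, length(tabs)), "Dark 3")
    ci <- 1
    for (tb in tabs) {
      meta_path <- sub("reads_", "meta_", tb)
      tab <- load_clone_table(tb, if (file.exists(meta_path)) meta_path else NULL)
      meta <- attr(tab, "meta")
      for (i in seq_len(nrow(meta))) {
        h <- clone_size_histogram(tab, meta$animal_id[i], meta$cell_type[i],
                                  meta$months[i])
        qc <- empirical_Q(h, S = meta$S[i],
                          f = if ("f" %in% names(meta)) meta$f[i] else NA)
        graphics::lines(qc$nu, qc$Q, type = "s", col = cols[ci])
      }
      ci <- ci %% length(cols) + 1
    }
    logmsg("report: Q(nu) overlay from %d table(s)", length(tabs))
  }
  # clone-size sensitivity panel: a scales, R shapes
  eps_w <- if (is.null(cfg$eps_w)) 5e-5 else cfg$eps_w
  graphics::plot(NA, xlim = c(1, 1e3), ylim = c(1e-10, 1), log = "xy",
                 xlab = "reads q", ylab = expression(m[q] / C),
                 main = "Sampled clone-size distributions")
  cols <- grDevices::hcl.colors(6, "Zissou 1")
  i <- 0
  for (a in c(0.0025, 0.01, 0.1)) for (R in c(10, 70)) {
    i <- i + 1
    eff <- effective_params(a, R, eps_w)
    m <- sampled_clone_dist(eff$a, delta = eff$delta, eps_w = eff$eps_w,
                            q_max = 1000)
    graphics::lines(m$size[-1], m$value[-1], col = cols[i])
  }
  graphics::legend("bottomleft",
                   legend = sprintf("a=%g R=%g", rep(c(0.0025, 0.01, 0.1), each = 2),
                                    rep(c(10, 70), 3)),
                   col = cols, lty = 1, cex = 0.7)
  # fit summary if present
  fj <- file.path(cfg$input, "fit.json")
  if (file.exists(fj)) {
    fit <- jsonlite::read_json(fj)
    graphics::plot.new()
    graphics::text(0.5, 0.6, sprintf("a* = %.4g   R* = %.4g", fit$a_star, fit$R_star))
    graphics::text(0.5, 0.4, sprintf("U+C = %.0f  (S = %g)", fit$UC_estimate, fit$S_used))
  }
  logmsg("report written to %s", pdf_path)
}
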