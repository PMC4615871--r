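#' Load a clone read-count table with per-sample metadata
#'
#' Reads the long/tidy TSV format used throughout the package: one row per
#' detected clone per sample with columns exactly
#' `animal_id, cell_type, months, clone_id, reads`, plus a companion
#' metadata TSV with columns `animal_id, cell_type, months, S, f` (total
#' sequenced marked reads and marked fraction of sampled blood).
#'
#' Validation: read counts must be positive integers (detected clones have
#' at least one read), `(animal_id, cell_type, months, clone_id)` must be
#' unique, every sample present in the table must have metadata, and the
#' summed reads of a sample may not exceed its `S`.  Violations are
#' reported with the offending line numbers.
#'
#' @param path path to the read-count TSV.
#' @param metadata_path path to the metadata TSV; if `NULL`, missing `f` is
#'   filled with 0.065 (the midpoint of typical marked fractions 0.03-0.1)
#'   and `S` with the summed sample reads, with a loud warning.
#' @return A `"clone_read_table"`: data frame of reads with the metadata
#'   data frame in attribute `"meta"`.
#' @export
load_clone_table <- function(path, metadata_path = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("no data rows in ", path)
  need <- c("animal_id", "cell_type", "months", "clone_id", "reads")
  if (!identical(sort(names(tab)), sort(need)))
    stop("expected columns exactly {", paste(need, collapse = ", "), "}, got {",
         paste(names(tab), collapse = ", "), "}")
  tab <- tab[, need]
  bad_q <- which(!is.finite(tab$reads) | tab$reads < 1 |
                   tab$reads != round(tab$reads))
  if (length(bad_q))
    stop("invalid read counts (must be integers >= 1) at data line(s): ",
         paste(head(bad_q + 1L, 20), collapse = ", "))
  key <- interaction(tab$animal_id, tab$cell_type, tab$months, tab$clone_id,
                     drop = TRUE)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate clone rows at data line(s): ",
         paste(head(dup + 1L, 20), collapse = ", "))
  if (is.null(metadata_path)) {
    warning("no metadata supplied: assuming marked fraction f = 0.065 ",
            "(midpoint of the typical 0.03-0.1 range) and S = summed reads ",
            "per sample", call. = FALSE)
    agg <- stats::aggregate(reads ~ animal_id + cell_type + months, tab, sum)
    meta <- data.frame(agg[, 1:3], S = agg$reads, f = 0.065)
  } else {
    meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
    mneed <- c("animal_id", "cell_type", "months", "S", "f")
    if (!all(mneed %in% names(meta)))
      stop("metadata must have columns {", paste(mneed, collapse = ", "), "}")
    meta <- meta[, union(mneed, names(meta))]
  }
  skey <- function(d) paste(d$animal_id, d$cell_type, d$months, sep = "\r")
  missing_meta <- setdiff(unique(skey(tab)), skey(meta))
  if (length(missing_meta))
    stop("samples present in the table but missing from metadata: ",
         paste(gsub("\r", "/", missing_meta), collapse = "; "))
  sums <- tapply(tab$reads, skey(tab), sum)
  Sm <- setNames(meta$S, skey(meta))
  over <- names(sums)[sums > Sm[names(sums)] + 1e-9]
  if (length(over))
    stop("summed reads exceed the sample's total S for: ",
         paste(gsub("\r", "/", over), collapse = "; "))
  structure(tab, meta = meta, class = c("clone_read_table", "data.frame"))
}

#' Write a clone read-count table and its metadata
#'
#' @param reads data frame with the five read-table columns.
#' @param meta per-sample metadata data frame.
#' @param path,metadata_path output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_clone_table <- function(reads, meta, path, metadata_path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, metadata_path))
}

#' Convert a wide clone x sample matrix to the long table format
#'
#' Convenience for data shipped as a matrix of read counts (rows = clones,
#' columns = samples).  Zero entries are dropped (undetected clone-sample
#' pairs).
#'
#' @param mat numeric matrix; rownames are clone ids.
#' @param sample_info data frame with one row per column of `mat` and
#'   columns `animal_id`, `cell_type`, `months`.
#' @return A long-format data frame with the standard five columns.
#' @export
wide_to_long_clone_table <- function(mat, sample_info) {
  stopifnot(ncol(mat) == nrow(sample_info),
            all(c("animal_id", "cell_type", "months") %in% names(sample_info)))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("clone_%05d", seq_len(nrow(mat)))
  out <- do.call(rbind, lapply(seq_len(ncol(mat)), function(j) {
    nz <- which(mat[, j] > 0)
    data.frame(animal_id = sample_info$animal_id[j],
               cell_type = sample_info$cell_type[j],
               months = sample_info$months[j],
               clone_id = rownames(mat)[nz],
               reads = as.integer(mat[nz, j]))
  }))
  rownames(out) <- NULL
  out
}

#' Clone-size histogram of one sample
#'
#' Counts the number of detected clones represented by exactly `q` reads,
#' `n_q`, for the selected `(animal_id, cell_type, months)` sample.
#'
#' @param table a `"clone_read_table"` (or compatible data frame with a
#'   `"meta"` attribute).
#' @param animal_id,cell_type,months sample selector.
#' @return A `"clone_histogram"` (columns `q`, `n_q`) carrying the sample's
#'   `S` and `f` as attributes.
#' @export
clone_size_histogram <- function(table, animal_id, cell_type, months) {
  sel <- table$animal_id == animal_id & table$cell_type == cell_type &
    table$months == months
  if (!any(sel)) stop("no such sample in the table")
  q <- table$reads[sel]
  tab <- table(q)
  meta <- attr(table, "meta")
  S <- f <- NA_real_
  if (!is.null(meta)) {
    mi <- meta$animal_id == animal_id & meta$cell_type == cell_type &
      meta$months == months
    if (any(mi)) { S <- meta$S[mi][1]; f <- meta$f[mi][1] }
  }
  clone_histogram(data.frame(q = as.integer(names(tab)), n_q = as.integer(tab)),
                  S = S, f = f,
                  sample_id = paste(animal_id, cell_type, months, sep = "/"))
}

#' Rescaled relative clone frequency
#'
#' Converts a read count to the fraction of all peripheral blood it
#' represents: `nu = f * q / S`, where `f` is the marked fraction of
#' sampled blood and `S` the total marked reads.  The smallest detectable
#' frequency (one read) is `nu_min = f/S`.
#'
#' @param q read count(s), `1 <= q <= S`.
#' @param S total sequenced marked reads.
#' @param f marked fraction, in `(0, 1]`.
#' @return `nu`, vectorized over `q`.
#' @examples
#' rescale_nu(10, S = 1e4, f = 0.05)  # 5e-5
#' nu_min(S = 1e4, f = 0.05)          # 5e-6
#' @export
rescale_nu <- function(q, S, f) {
  stopifnot(all(q >= 1), all(q <= S), f > 0, f <= 1)
  f * q / S
}

#' @rdname rescale_nu
#' @export
nu_min <- function(S, f) {
  stopifnot(S >= 1, f > 0, f <= 1)
  f / S
}

#' Empirical cumulative clone fraction Q(nu)
#'
#' The fraction of detected clones whose rescaled frequency is at or below
#' `nu`: a right-continuous step function with ties (equal `q`) accumulated
#' into a single step; `Q` at the largest observed `nu` equals 1.
#'
#' @param hist a `"clone_histogram"` whose `S` and `f` attributes are set
#'   (or pass `S`, `f` explicitly).
#' @param S,f overrides for the sample depth and marked fraction.
#' @return A data frame with columns `nu`, `q`, `Q` (one row per distinct
#'   observed read count, increasing).
#' @export
empirical_Q <- function(hist, S = attr(hist, "S"), f = attr(hist, "f")) {
  stopifnot(nrow(hist) >= 1)
  if (is.null(S) || !is.finite(S)) stop("sample depth S is required")
  if (is.null(f) || !is.finite(f)) {
    warning("marked fraction f missing: using the 0.03-0.1 midpoint 0.065",
            call. = FALSE)
    f <- 0.065
  }
  data.frame(nu = rescale_nu(hist$q, S, f), q = hist$q,
             Q = cumsum(hist$n_q) / sum(hist$n_q))
}

#' Binomial reference clone-size distribution
#'
#' The null expectation if every detected clone had the same underlying
#' frequency: reads `q ~ Binomial(S, mean_size/S)`.  Overlaid on measured
#' `Q(nu)` curves, it shows the data's excess of low-population clones
#' (a binomial underestimates them).
#'
#' @param S total reads (trials).
#' @param mean_size mean clone size in reads, `<= S`.
#' @return A [size_distribution] over `q = 0..S`; its `Q(nu)` overlay can be
#'   formed with [cumulative_F_and_Q()] and [rescale_nu()].
#' @export
binomial_reference <- function(S, mean_size) {
  stopifnot(S >= 1, mean_size <= S, mean_size >= 0)
  q <- 0:S
  v <- stats::dbinom(q, S, mean_size / S)
  size_distribution(q, v, stats::dbinom(q, S, mean_size / S, log = TRUE),
                    tail_mass = 0, kind = "binomial reference")
}
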