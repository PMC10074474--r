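## Two-sided cluster-based sign-flip permutation test over participant-level
## frequency x time contrast maps (paired design, test against zero).

#' Per-cell paired t statistics
#'
#' @param x participants x frequency x time array (or participants x cells
#'   matrix) of paired differences.
#' @return Array of t values against zero (one fewer dimension than `x`).
#' @keywords internal
cell_t_map <- function(x) {
  d <- dim(x)
  n <- d[1]
  m <- matrix(x, nrow = n)
  mu <- colMeans(m)
  sd_ <- apply(m, 2, stats::sd)
  t_ <- mu / (sd_ / sqrt(n))
  t_[sd_ == 0 & mu == 0] <- 0
  t_[sd_ == 0 & mu != 0] <- sign(mu[sd_ == 0 & mu != 0]) * 1e12
  if (length(d) > 2) array(t_, d[-1], dimnames = dimnames(x)[-1]) else t_
}

#' Form candidate clusters from a t map
#'
#' Cells whose two-sided paired t test is significant at
#' `alpha_cluster_forming` (|t| at or above the critical value; ties at the
#' threshold are included) enter clustering. Maximal connected components of
#' same-sign cells under 4-neighbour adjacency on the frequency x time
#' lattice form the candidate clusters, each scored by the sum of its t
#' values.
#'
#' @param x participants x frequency x time array of paired differences
#'   (no undefined cells).
#' @param alpha_cluster_forming two-sided cluster-forming alpha.
#' @return List with `tmap` (frequency x time t matrix), `labels` (integer
#'   matrix of cluster ids, 0 = sub-threshold), `clusters` (data frame:
#'   `id, sign, n_cells, tsum`), `tcrit`, `n`.
#' @export
form_clusters <- function(x, alpha_cluster_forming = 0.05) {
  d <- dim(x)
  if (length(d) != 3) stop("x must be a participants x frequency x time array")
  n <- d[1]
  if (n < 2) stop("cluster statistics need at least 2 participants")
  if (anyNA(x)) stop("undefined cells inside the tested window; trim first")
  tcrit <- stats::qt(1 - alpha_cluster_forming / 2, df = n - 1)
  tmap <- cell_t_map(x)
  lab <- .cluster_label(as.numeric(tmap), d[2], d[3], tcrit)
  labels <- matrix(lab$labels, d[2], d[3], dimnames = dimnames(x)[-1])
  tsums <- lab$tsums
  clusters <- if (length(tsums)) {
    data.frame(id = seq_along(tsums), sign = ifelse(tsums >= 0, 1L, -1L),
               n_cells = as.integer(tabulate(labels[labels > 0],
                                             nbins = length(tsums))),
               tsum = tsums)
  } else {
    data.frame(id = integer(0), sign = integer(0), n_cells = integer(0),
               tsum = numeric(0))
  }
  list(tmap = matrix(tmap, d[2], d[3], dimnames = dimnames(x)[-1]),
       labels = labels, clusters = clusters, tcrit = tcrit, n = n)
}

#' Cluster-based sign-flip permutation test
#'
#' Tests a paired frequency x time contrast against zero across
#' participants. Candidate clusters are formed with [form_clusters()]; each
#' permutation flips the sign of every participant's whole difference map
#' independently with probability 1/2 (exchangeability of a paired design
#' under the null), and the maximum |t-sum| over that permutation's clusters
#' (pooled over both signs, controlling the two-sided family-wise error) is
#' recorded. A cluster's p value is the proportion of permutation maxima at
#' or above its |t-sum|; when no permutation reaches it the p value is
#' floored at `1/n_permutations` (optionally, `plus_one = TRUE` adds the
#' observed data as one permutation, the "+1" convention).
#'
#' @param x participants x frequency x time array of paired differences.
#' @param alpha_cluster_forming two-sided cluster-forming alpha (0.05).
#' @param n_permutations number of random sign-flip permutations (10,000).
#' @param seed RNG seed for the permutation draws (optional but recommended;
#'   fixed seed gives bit-identical results).
#' @param plus_one if `TRUE`, use `(b + 1) / (m + 1)` instead of the
#'   proportion with a `1/m` floor.
#' @return Object of class `cluster_test`: the [form_clusters()] fields plus
#'   `clusters$p`, `perm_max` (permutation max-|t-sum| distribution) and the
#'   settings.
#' @export
#' @examples
#' set.seed(1)
#' x <- array(rnorm(8 * 6 * 10), c(8, 6, 10))
#' ct <- cluster_test(x, n_permutations = 500, seed = 2)
#' ct
cluster_test <- function(x, alpha_cluster_forming = 0.05,
                         n_permutations = 10000, seed = NULL,
                         plus_one = FALSE) {
  if (n_permutations < 1) stop("n_permutations must be at least 1")
  fc <- form_clusters(x, alpha_cluster_forming)
  d <- dim(x)
  n <- d[1]
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  if (!is.null(seed)) set.seed(seed)
  signs <- matrix(sample(c(-1L, 1L), n_permutations * n, replace = TRUE),
                  n_permutations, n)
  perm_max <- .perm_max_tsums(matrix(x, nrow = n), d[2], d[3], signs, fc$tcrit)
  if (nrow(fc$clusters)) {
    b <- vapply(abs(fc$clusters$tsum),
                function(s) sum(perm_max >= s), numeric(1))
    fc$clusters$p <- if (plus_one) (b + 1) / (n_permutations + 1) else
      pmax(b, 1) / n_permutations
  } else {
    fc$clusters$p <- numeric(0)
  }
  fc$perm_max <- perm_max
  fc$settings <- list(alpha_cluster_forming = alpha_cluster_forming,
                      n_permutations = n_permutations, seed = seed,
                      plus_one = plus_one)
  class(fc) <- "cluster_test"
  fc
}

#' Exact sign-flip cluster test by enumeration
#'
#' Enumerates all `2^n` sign-flip patterns (feasible for small participant
#' counts) and reports exact p values: the proportion of patterns whose
#' maximum |t-sum| is at or above each observed cluster's |t-sum|. The
#' identity pattern is included, so exact p values are at least `2^-n`.
#'
#' @param x participants x frequency x time array of paired differences.
#' @param alpha_cluster_forming two-sided cluster-forming alpha.
#' @return A `cluster_test` object with exact `p` and the full enumeration
#'   in `perm_max`.
#' @export
cluster_test_exact <- function(x, alpha_cluster_forming = 0.05) {
  d <- dim(x)
  n <- d[1]
  if (n > 20) stop("exact enumeration limited to 20 participants (2^n patterns)")
  fc <- form_clusters(x, alpha_cluster_forming)
  patt <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
  storage.mode(patt) <- "integer"
  perm_max <- .perm_max_tsums(matrix(x, nrow = n), d[2], d[3], patt, fc$tcrit)
  if (nrow(fc$clusters)) {
    fc$clusters$p <- vapply(abs(fc$clusters$tsum),
                            function(s) mean(perm_max >= s), numeric(1))
  } else {
    fc$clusters$p <- numeric(0)
  }
  fc$perm_max <- perm_max
  fc$settings <- list(alpha_cluster_forming = alpha_cluster_forming,
                      n_permutations = nrow(patt), exact = TRUE)
  class(fc) <- "cluster_test"
  fc
}

#' Smallest cluster p value (1 when no cluster formed)
#' @param ct a `cluster_test` object.
#' @return Numeric scalar.
#' @export
min_cluster_p <- function(ct) {
  if (!nrow(ct$clusters)) return(1)
  min(ct$clusters$p)
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster-based sign-flip permutation test (n = %d, %d permutations)\n",
              x$n, x$settings$n_permutations))
  cat(sprintf("  cluster-forming |t| >= %.3f (two-sided alpha = %g)\n",
              x$tcrit, x$settings$alpha_cluster_forming))
  if (!nrow(x$clusters)) {
    cat("  no supra-threshold clusters\n")
  } else {
    cl <- x$clusters[order(x$clusters$p, -abs(x$clusters$tsum)), ]
    for (i in seq_len(min(5, nrow(cl)))) {
      cat(sprintf("  cluster %d: sign %+d, %d cells, t-sum %.1f, p %s\n",
                  cl$id[i], cl$sign[i], cl$n_cells[i], cl$tsum[i],
                  format.pval(cl$p[i], digits = 3)))
    }
    if (nrow(cl) > 5) cat(sprintf("  ... and %d more\n", nrow(cl) - 5))
  }
  invisible(x)
}

#' Trim a participants x frequency x time array to its defined region
#'
#' Drops leading/trailing time points (and frequencies) that are `NA` for
#' every participant, e.g. STFT edge windows.
#'
#' @param x participants x frequency x time array.
#' @param time_ms optional time axis to subset alongside.
#' @return List with `x` (trimmed array) and `time_ms`.
#' @export
trim_defined <- function(x, time_ms = NULL) {
  ok_t <- apply(x, 3, function(sl) !anyNA(sl))
  ok_f <- apply(x, 2, function(sl) !anyNA(sl[, ok_t, drop = FALSE]))
  out <- x[, ok_f, ok_t, drop = FALSE]
  list(x = out, time_ms = if (!is.null(time_ms)) time_ms[ok_t] else NULL,
       kept_freqs = which(ok_f), kept_times = which(ok_t))
}
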