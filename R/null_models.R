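# Permutation null models. Two null ensembles are used: the data-stream
# permutation, which shuffles individual identities within each
# observation sample before rebuilding the SRI network (preserving shoal
# sizes and each individual's sighting count), and the edge-weight
# permutation, which shuffles dyadic weights over dyad slots (preserving
# the weight multiset and hence the degree-free weight distribution).

#' Data-stream permutation of an observation table
#'
#' Independently for each sample, the identities of the individuals
#' observed in that sample are uniformly permuted among themselves
#' (equivalently: the node labels of the sample's binary association
#' matrix are permuted). Shoal sizes within every sample and each
#' individual's set of samples are preserved exactly; association patterns
#' are randomized.
#'
#' @param obs Observation table.
#' @param seed Integer seed.
#' @return Observation table of identical shape with permuted
#'   `individual_id` within samples.
#' @export
datastream_permute <- function(obs, seed = NULL) {
  with_seed(seed, {
    rows <- split(seq_len(nrow(obs)), as.character(obs$sample_id))
    ind <- as.character(obs$individual_id)
    for (r in rows) ind[r] <- resample(ind[r])
    out <- obs
    out$individual_id <- ind
    out
  })
}

#' Stream of SRI matrices under the data-stream null
#'
#' Applies [datastream_permute()] independently to every sample and
#' rebuilds the SRI matrix, `n_permutations` times, calling `fun` on each
#' null matrix as it is produced (matrices are never all held in memory).
#' Per-draw seeds are derived deterministically from `seed`.
#'
#' The node set of every null matrix equals the observed network's node
#' set, and each draw preserves the per-sample shoal-size multisets and
#' per-individual sighting counts by construction.
#'
#' @param obs Filtered observation table.
#' @param n_permutations Number of draws.
#' @param seed Integer master seed.
#' @param fun Function applied to each null `association_matrix`; defaults
#'   to identity, in which case a list of matrices is returned (only
#'   sensible for small ensembles).
#' @return List of `fun` results, length `n_permutations` (simplified to a
#'   vector when every result is a scalar).
#' @export
permuted_sri_ensemble <- function(obs, n_permutations, seed = 1L,
                                  fun = identity) {
  idx <- obs_index(obs)
  draw_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                           n_permutations))
  rows <- split(seq_along(idx$ind), idx$samp)
  out <- vector("list", n_permutations)
  for (i in seq_len(n_permutations)) {
    ind <- idx$ind
    with_seed(draw_seeds[i], {
      for (r in rows) ind[r] <- resample(ind[r])
    })
    cnt <- sri_counts(idx, ind)
    w <- cnt$together / cnt$either
    w[cnt$either == 0] <- 0
    diag(w) <- 0
    dimnames(w) <- list(idx$ids, idx$ids)
    w <- structure(w, class = c("association_matrix", "matrix"),
                   sightings = stats::setNames(cnt$sightings, idx$ids))
    out[[i]] <- fun(w)
  }
  if (all(vapply(out, function(x) is.numeric(x) && length(x) == 1L,
                 logical(1)))) {
    out <- unlist(out)
  }
  out
}

#' Edge-weight permutation of an association matrix
#'
#' Uniformly permutes the multiset of off-diagonal dyadic weights
#' (including zeros) over the dyad slots, preserving symmetry. The null
#' breaks any relationship between a dyad's identity and its weight while
#' keeping the weight distribution fixed.
#'
#' @param matrix Symmetric association matrix.
#' @param seed Integer seed.
#' @return Permuted symmetric matrix (same dimnames).
#' @export
edge_weight_permute <- function(matrix, seed = NULL) {
  with_seed(seed, {
    up <- upper.tri(matrix)
    w <- matrix
    w[up] <- resample(matrix[up])
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    w
  })
}

#' Two-tailed permutation test against an empirical null
#'
#' Compares an observed statistic to its permutation null distribution.
#' Two conventions are reported: the add-one-corrected two-tailed p-value
#' `2 * min((#\{null >= obs\} + 1)/(N + 1), (#\{null <= obs\} + 1)/(N + 1))`
#' capped at 1, and the raw-proportion analogue `p_raw`. The significance
#' decision is made directly on the empirical null: the result is
#' significant when the observed value lies strictly inside the
#' `alpha_tail` highest (tail `"high"`) or lowest (tail `"low"`) fraction
#' of null values; null values tying the observed count as equally extreme
#' in both tails (conservative). The null median is reported, matching the
#' convention of quoting permuted-network reference values.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null statistics.
#' @param alpha_tail Tail probability (default 0.025).
#' @param statistic_name Label for printing.
#' @param keep_null Keep the null values in the result (default TRUE).
#' @return An object of class `perm_test`.
#' @examples
#' two_tailed_test(5, rnorm(999), statistic_name = "toy")
#' @export
two_tailed_test <- function(observed, null_values, alpha_tail = 0.025,
                            statistic_name = "statistic",
                            keep_null = TRUE) {
  null_values <- null_values[!is.na(null_values)]
  n <- length(null_values)
  if (n < 1L) stop("need at least one null value", call. = FALSE)
  b_ge <- sum(null_values >= observed)
  b_le <- sum(null_values <= observed)
  p <- min(1, 2 * min((b_ge + 1) / (n + 1), (b_le + 1) / (n + 1)))
  p_raw <- min(1, 2 * min(b_ge / n, b_le / n))
  prop_ge <- b_ge / n
  prop_le <- b_le / n
  tail <- if (prop_ge < alpha_tail) "high"
          else if (prop_le < alpha_tail) "low"
          else "none"
  structure(
    list(statistic_name = statistic_name,
         observed = observed,
         null_median = median(null_values),
         p_two_tailed = p, p_raw = p_raw,
         significant = tail != "none", tail = tail,
         alpha_tail = alpha_tail, n_permutations = n,
         null_values = if (keep_null) null_values),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Two-tailed permutation test of %s (N = %d)\n  observed = %.4g, null median = %.4g, p = %.4g%s\n",
    x$statistic_name, x$n_permutations, x$observed, x$null_median,
    x$p_two_tailed,
    if (x$significant) sprintf("  [significant, %s tail]", x$tail) else ""))
  invisible(x)
}

#' Histogram of a permutation null with the observed value marked
#'
#' @param x A `perm_test` object (with retained null values).
#' @param ... Passed to [graphics::hist()].
#' @export
plot.perm_test <- function(x, ...) {
  if (is.null(x$null_values)) {
    stop("null values were not retained (keep_null = FALSE)", call. = FALSE)
  }
  hist(x$null_values, main = x$statistic_name,
       xlab = "null statistic",
       xlim = range(c(x$null_values, x$observed)), ...)
  abline(v = x$observed, col = "red", lwd = 2)
  legend("topright", legend = sprintf("observed (p = %.3g)", x$p_two_tailed),
         col = "red", lwd = 2, bty = "n")
  invisible(x)
}
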