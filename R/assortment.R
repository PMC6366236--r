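# Assortativity coefficients and the permutation tests built on them.
# Positive assortativity: like associates with like.

#' Weighted assortativity coefficient for a continuous trait
#'
#' Weighted Pearson correlation of the trait across edge endpoints, taken
#' over all ordered node pairs (i, j), i != j, with weights `w_ij`:
#' `r = (E_w[x_i x_j] - E_w[x_i] E_w[x_j]) / (sd_w[x_i] sd_w[x_j])`
#' where `E_w` denotes the `w`-weighted mean over ordered pairs. On a
#' symmetric matrix the two endpoint marginals coincide. Setting
#' `weighted = FALSE` replaces every positive weight by 1, giving the
#' unweighted coefficient computed on edge presence/absence.
#'
#' The coefficient is invariant to affine transformation of the trait and
#' to uniform rescaling of the weights; it is 1 for perfect assortment
#' (edges only within trait-constant blocks) and undefined (NA, with a
#' warning) when the trait has zero weighted variance over endpoints.
#'
#' @param matrix Symmetric non-negative weight matrix (zero diagonal).
#' @param values Numeric trait vector aligned with the matrix rows (or
#'   named by node id).
#' @param weighted Use edge weights (default) or presence/absence.
#' @return Scalar coefficient in `[-1, 1]`, or `NA` when undefined.
#' @examples
#' w <- rbind(c(0, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 0, 1), c(0, 0, 1, 0))
#' assortativity_continuous(w, c(1, 1, 9, 9))  # 1: perfect assortment
#' @export
assortativity_continuous <- function(matrix, values, weighted = TRUE) {
  w <- unclass_matrix(matrix, weighted)
  x <- align_values(values, matrix)
  W <- sum(w)
  if (W <= 0) {
    warning("no positive edge weights; assortativity undefined",
            call. = FALSE)
    return(NA_real_)
  }
  s <- rowSums(w)            # symmetric: row and column strengths equal
  m1 <- sum(s * x) / W
  m2 <- sum(s * x^2) / W
  v <- m2 - m1^2
  if (v <= .Machine$double.eps * max(1, m2)) {
    warning("zero trait variance over weighted endpoints; assortativity undefined",
            call. = FALSE)
    return(NA_real_)
  }
  cross <- drop(crossprod(x, w %*% x)) / W
  (cross - m1^2) / v
}

#' Weighted assortativity coefficient for a categorical trait
#'
#' Newman-style discrete assortativity on the weight-normalized mixing
#' matrix `e` (entry `e_cd` = fraction of total edge weight joining class
#' `c` to class `d` over ordered pairs):
#' `r = (sum_c e_cc - sum_c a_c b_c) / (1 - sum_c a_c b_c)` with `a`, `b`
#' the marginals of `e`. 1 means all weight within classes; maximally
#' disassorted mixing gives negative values (-1 for balanced two-class
#' bipartite mixing).
#'
#' @inheritParams assortativity_continuous
#' @param labels Class labels aligned with the matrix rows.
#' @return Scalar coefficient, or `NA` when only one class is present.
#' @examples
#' w <- matrix(0.5, 4, 4); diag(w) <- 0
#' assortativity_discrete(w, c("F", "F", "M", "M"))
#' @export
assortativity_discrete <- function(matrix, labels, weighted = TRUE) {
  w <- unclass_matrix(matrix, weighted)
  labels <- align_values(labels, matrix)
  f <- factor(labels)
  if (nlevels(f) < 2L) {
    warning("only one class present; assortativity undefined", call. = FALSE)
    return(NA_real_)
  }
  W <- sum(w)
  if (W <= 0) {
    warning("no positive edge weights; assortativity undefined",
            call. = FALSE)
    return(NA_real_)
  }
  M <- stats::model.matrix(~ f - 1)
  e <- crossprod(M, w %*% M) / W
  ab <- sum(rowSums(e) * colSums(e))
  if (1 - ab <= .Machine$double.eps) {
    warning("degenerate mixing matrix; assortativity undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (sum(diag(e)) - ab) / (1 - ab)
}

#' Assortativity for a continuous or categorical trait
#'
#' Dispatch wrapper: numeric trait vectors go to
#' [assortativity_continuous()], anything else to
#' [assortativity_discrete()].
#'
#' @inheritParams assortativity_continuous
#' @export
assortativity <- function(matrix, values, weighted = TRUE) {
  if (is.numeric(values)) {
    assortativity_continuous(matrix, values, weighted)
  } else {
    assortativity_discrete(matrix, values, weighted)
  }
}

unclass_matrix <- function(matrix, weighted) {
  w <- unclass(matrix)
  attributes(w)[setdiff(names(attributes(w)), "dim")] <- NULL
  if (any(w < 0)) stop("negative edge weights", call. = FALSE)
  if (!weighted) w <- (w > 0) * 1
  diag(w) <- 0
  w
}

align_values <- function(values, matrix) {
  ids <- rownames(matrix)
  if (!is.null(names(values)) && !is.null(ids)) {
    if (!all(ids %in% names(values))) {
      stop("trait undefined for node(s): ",
           paste(head(setdiff(ids, names(values)), 5L), collapse = ", "),
           call. = FALSE)
    }
    values <- values[ids]
  }
  if (length(values) != nrow(matrix)) {
    stop("trait vector length does not match node count", call. = FALSE)
  }
  if (anyNA(values)) stop("missing trait value", call. = FALSE)
  values
}

#' Permutation test of trait assortment in an observed network
#'
#' Fits the observed assortativity coefficient (weighted or unweighted;
#' continuous or categorical trait) on the SRI network built from filtered
#' observations, then compares it to coefficients from
#' `config$n_permutations` data-stream-permuted networks via
#' [two_tailed_test()]. For `subset = "females"`/`"males"` both the
#' observed network and every null network are restricted to that sex
#' *after* permutation, preserving the null's group-size structure.
#'
#' @param obs Observation table (filtered by [filter_individuals()]; the
#'   filter is applied here with `config$min_sightings` if not already).
#' @param individuals Individual-attribute table supplying the trait and
#'   sex columns.
#' @param trait Column of `individuals` to test (e.g.
#'   `"overall_cooperativeness"`, `"body_length_mm"`, `"sex"`).
#' @param weighted Use edge weights (TRUE) or presence/absence (FALSE).
#' @param subset `"all"`, `"females"` or `"males"`.
#' @param config A [run_config()].
#' @param prefilter Apply the sighting filter inside the function
#'   (default TRUE; set FALSE if `obs` is already filtered).
#' @return An object of class `assort_test` (extends `perm_test`) with the
#'   observed coefficient, null median, two-tailed p and significance. If
#'   the coefficient is undefined in more than 1% of null draws the test
#'   aborts with diagnostics.
#' @export
assortment_test <- function(obs, individuals, trait, weighted = TRUE,
                            subset = c("all", "females", "males"),
                            config = run_config(), prefilter = TRUE) {
  subset <- match.arg(subset)
  stopifnot(inherits(config, "run_config"))
  if (prefilter) obs <- filter_individuals(obs, config$min_sightings)
  vals <- stats::setNames(individuals[[trait]],
                          as.character(individuals$individual_id))
  if (is.null(individuals[[trait]])) {
    stop("individuals table lacks trait '", trait, "'", call. = FALSE)
  }
  sex <- stats::setNames(as.character(individuals$sex),
                         as.character(individuals$individual_id))
  sex_value <- c(females = "F", males = "M")[subset]
  net_ids <- sort(unique(as.character(obs$individual_id)))
  missing_trait <- net_ids[is.na(vals[net_ids]) | !net_ids %in% names(vals)]
  if (length(missing_trait)) {
    coop_log("dropping ", length(missing_trait),
             " node(s) without trait '", trait, "'")
    obs <- obs[!as.character(obs$individual_id) %in% missing_trait, ,
               drop = FALSE]
  }
  coef_of <- function(m) {
    if (subset != "all") {
      keep <- which(sex[rownames(m)] == sex_value)
      if (length(keep) < 3L) return(NA_real_)
      m <- m[keep, keep, drop = FALSE]
    }
    suppressWarnings(assortativity(m, vals[rownames(m)], weighted))
  }
  observed_net <- sri_matrix(obs)
  observed <- coef_of(observed_net)
  if (is.na(observed)) {
    stop("observed assortativity undefined (constant trait or empty subset)",
         call. = FALSE)
  }
  null_vals <- permuted_sri_ensemble(obs, config$n_permutations,
                                     seed = config$seed, fun = coef_of)
  n_undef <- sum(is.na(null_vals))
  if (n_undef > 0.01 * config$n_permutations) {
    stop(sprintf(
      "assortativity undefined in %d of %d null draws (trait '%s', subset %s)",
      n_undef, config$n_permutations, trait, subset), call. = FALSE)
  }
  res <- two_tailed_test(observed, null_vals, config$alpha_tail,
                         statistic_name = sprintf(
                           "%s assortativity (%s, %s)",
                           if (weighted) "weighted" else "unweighted",
                           trait, subset))
  res$trait <- trait
  res$weighted <- weighted
  res$subset <- subset
  res$coefficient <- observed
  res$n_nodes <- nrow(observed_net)
  class(res) <- c("assort_test", class(res))
  res
}

#' @export
print.assort_test <- function(x, ...) {
  sym <- if (x$weighted) "r^w" else "r^u"
  cat(sprintf(
    "Assortment by %s (%s, %s individuals, n = %d):\n  %s = %.3f, %s_perm = %.3f, p = %.3g%s\n",
    x$trait, if (x$weighted) "weighted" else "unweighted", x$subset,
    x$n_nodes, sym, x$observed, sym, x$null_median, x$p_two_tailed,
    if (x$significant) sprintf("  [significant, %s tail]", x$tail) else ""))
  invisible(x)
}

#' Dyad table of an association network
#'
#' One row per unordered dyad: edge weight, summed cooperativeness of the
#' pair, and (optionally) their relatedness.
#'
#' @param matrix Association matrix.
#' @param cooperativeness Named vector of overall cooperativeness scores.
#' @param relatedness Optional relatedness matrix (id dimnames).
#' @return Data frame `id_a, id_b, weight, summed_cooperativeness[,
#'   relatedness]` with `dyad_count(n)` rows.
#' @export
dyad_table <- function(matrix, cooperativeness = NULL, relatedness = NULL) {
  ids <- rownames(matrix)
  up <- which(upper.tri(matrix), arr.ind = TRUE)
  out <- data.frame(id_a = ids[up[, 1L]], id_b = ids[up[, 2L]],
                    weight = matrix[up], stringsAsFactors = FALSE)
  if (!is.null(cooperativeness)) {
    cvals <- cooperativeness[ids]
    if (anyNA(cvals)) stop("cooperativeness missing for network node",
                           call. = FALSE)
    out$summed_cooperativeness <- cvals[up[, 1L]] + cvals[up[, 2L]]
  }
  if (!is.null(relatedness)) {
    miss <- setdiff(ids, rownames(relatedness))
    if (length(miss)) {
      stop("relatedness missing for node(s): ",
           paste(head(miss, 5L), collapse = ", "), call. = FALSE)
    }
    r <- relatedness[ids, ids]
    out$relatedness <- r[up]
  }
  out
}

#' Dyadic correlation test of edge weight against a pair statistic
#'
#' Pearson correlation over *all* unordered dyads (zero-weight dyads
#' included) between SRI edge weights and either the dyad's summed
#' cooperativeness or its relatedness, with the matching permutation null:
#'
#' * `statistic = "summed_cooperativeness"`: nulls are networks with
#'   randomly permuted edge weights ([edge_weight_permute()]), asking
#'   whether strong ties concentrate among cooperative pairs;
#' * `statistic = "relatedness"`: nulls are data-stream permuted networks
#'   ([permuted_sri_ensemble()]), asking whether association strength
#'   follows kinship.
#'
#' @param obs Filtered observation table (needed for the data-stream null
#'   and to build the observed network).
#' @param individuals Individual table (for cooperativeness values).
#' @param statistic `"summed_cooperativeness"` or `"relatedness"`.
#' @param relatedness Relatedness matrix (required for the relatedness
#'   test).
#' @param config A [run_config()].
#' @param prefilter Apply the sighting filter (default TRUE).
#' @return A `perm_test` object with extra fields `statistic`, `n_dyads`.
#' @export
dyadic_correlation_test <- function(obs, individuals,
                                    statistic = c("summed_cooperativeness",
                                                  "relatedness"),
                                    relatedness = NULL,
                                    config = run_config(),
                                    prefilter = TRUE) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(config, "run_config"))
  if (prefilter) obs <- filter_individuals(obs, config$min_sightings)
  net <- sri_matrix(obs)
  ids <- rownames(net)
  up <- upper.tri(net)
  w_obs <- net[up]
  if (statistic == "summed_cooperativeness") {
    coop <- stats::setNames(individuals$overall_cooperativeness,
                            as.character(individuals$individual_id))
    y <- dyad_table(net, cooperativeness = coop)$summed_cooperativeness
  } else {
    if (is.null(relatedness)) stop("relatedness matrix required",
                                   call. = FALSE)
    y <- dyad_table(net, relatedness = relatedness)$relatedness
  }
  if (sd(w_obs) == 0 || sd(y) == 0) {
    stop("zero variance in dyadic vectors; correlation undefined",
         call. = FALSE)
  }
  observed <- cor(w_obs, y)
  null_vals <- if (statistic == "summed_cooperativeness") {
    seeds <- with_seed(config$seed,
                       sample.int(.Machine$integer.max - 1L,
                                  config$n_permutations))
    vapply(seeds, function(s) {
      with_seed(s, cor(resample(w_obs), y))
    }, numeric(1))
  } else {
    permuted_sri_ensemble(obs, config$n_permutations, seed = config$seed,
                          fun = function(m) cor(m[up], y))
  }
  res <- two_tailed_test(observed, null_vals, config$alpha_tail,
                         statistic_name = sprintf(
                           "dyadic correlation: edge weight vs %s",
                           statistic))
  res$statistic <- statistic
  res$n_dyads <- dyad_count(length(ids))
  res
}

#' Spearman rank correlation test
#'
#' Rank correlation of two paired vectors (midranks for ties) with the
#' standard asymptotic two-sided p-value; used for body length vs
#' cooperativeness.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return List with `r_s`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  list(r_s = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups; used for sex differences
#' in cooperativeness. The reported `W` is the U statistic of the first
#' group (the number of pairs where a first-group value exceeds a
#' second-group value, ties counting 1/2), matching
#' [stats::wilcox.test()].
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @return List with `W`, `p`, `n_a`, `n_b`.
#' @export
mann_whitney_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  if (sd(c(group_a, group_b)) == 0) {
    return(list(W = length(group_a) * length(group_b) / 2, p = 1,
                n_a = length(group_a), n_b = length(group_b)))
  }
  wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = FALSE,
                                     correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value,
       n_a = length(group_a), n_b = length(group_b))
}
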