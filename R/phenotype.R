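# Cooperativeness scoring and repeatability: the phenotype arm of the
# analysis. Cooperativeness is scored as mean distance from the refuge
# during a standardized inspection trial; a cooperative phenotype is a
# significantly repeatable score across trials, estimated from the one-way
# ANOVA intraclass correlation with a Monte-Carlo permutation p-value and
# Benjamini-Hochberg FDR control across population batches.

#' Cooperativeness score of one trial
#'
#' Arithmetic mean over frames of the Euclidean distance of the fish from
#' the refuge. Larger scores mean more time spent away from the refuge,
#' towards the predator: more cooperative.
#'
#' @param track Positions: a numeric vector of 1-D positions, or a matrix /
#'   data frame with one row per frame and coordinate columns.
#' @param refuge_point Refuge coordinate (scalar or vector matching the
#'   track's dimensionality; default 0).
#' @return Non-negative scalar score.
#' @examples
#' trial_score(c(0, 10, 20), refuge_point = 0)  # 10
#' @export
trial_score <- function(track, refuge_point = 0) {
  if (is.data.frame(track)) track <- as.matrix(track)
  if (is.matrix(track)) {
    if (nrow(track) == 0L) stop("empty track", call. = FALSE)
    if (length(refuge_point) != ncol(track)) {
      stop("refuge_point must have one coordinate per track column",
           call. = FALSE)
    }
    d <- sqrt(rowSums(sweep(track, 2L, refuge_point)^2))
  } else {
    if (length(track) == 0L) stop("empty track", call. = FALSE)
    d <- abs(track - refuge_point)
  }
  mean(d)
}

#' Overall cooperativeness of an individual
#'
#' Mean of the per-trial scores; requires exactly `n0` scores (individuals
#' with missing trials are excluded upstream).
#'
#' @param scores Numeric vector of per-trial scores.
#' @param n0 Expected number of trials (default 2).
#' @return Scalar mean score.
#' @export
overall_cooperativeness <- function(scores, n0 = 2L) {
  if (length(scores) != n0) {
    stop(sprintf("expected %d trial scores, got %d", n0, length(scores)),
         call. = FALSE)
  }
  if (anyNA(scores)) stop("missing trial score", call. = FALSE)
  mean(scores)
}

# Balanced score matrix (individuals x trials) from a long trial table.
score_matrix <- function(trials) {
  ids <- unique(as.character(trials$individual_id))
  counts <- table(as.character(trials$individual_id))
  n0 <- unique(as.integer(counts))
  if (length(n0) != 1L) {
    stop("unbalanced design: individuals have differing trial counts (",
         paste(range(counts), collapse = "-"), ")", call. = FALSE)
  }
  y <- matrix(NA_real_, length(ids), n0, dimnames = list(ids, NULL))
  y[cbind(match(as.character(trials$individual_id), ids),
          as.integer(trials$trial_number))] <- trials$score
  if (anyNA(y)) {
    stop("trial numbers must be 1..n0 for every individual", call. = FALSE)
  }
  y
}

anova_from_matrix <- function(y) {
  n <- nrow(y); k <- ncol(y); N <- n * k
  G <- sum(y)
  ss_total <- sum(y^2) - G^2 / N
  ss_a <- sum(rowSums(y)^2) / k - G^2 / N
  ss_w <- ss_total - ss_a
  df_a <- n - 1L
  df_w <- N - n
  ms_a <- ss_a / df_a
  ms_w <- ss_w / df_w
  list(MS_A = ms_a, MS_W = ms_w, F = ms_a / ms_w,
       df_A = df_a, df_W = df_w, n0 = k,
       SS_A = ss_a, SS_W = ss_w, SS_total = ss_total)
}

#' One-way ANOVA decomposition of repeated scores by individual
#'
#' Standard balanced one-way decomposition with individual identity as the
#' grouping factor: mean squares among (`MS_A`) and within (`MS_W`)
#' individuals, their ratio `F`, and degrees of freedom. The design must be
#' balanced (`n0 >= 2` trials for each of `>= 2` individuals).
#'
#' @param trials Long trial table (`individual_id`, `trial_number`,
#'   `score`).
#' @return An object of class `coop_anova`. When all scores are identical
#'   the F ratio is 0/0; the object carries `degenerate = TRUE` and
#'   `F = NaN`.
#' @examples
#' tr <- data.frame(individual_id = rep(c("a", "b", "c"), each = 2),
#'                  trial_number = rep(1:2, 3),
#'                  score = c(1, 2, 5, 6, 9, 10))
#' anova_oneway(tr)
#' @export
anova_oneway <- function(trials) {
  y <- score_matrix(trials)
  if (nrow(y) < 2L) stop("need >= 2 individuals", call. = FALSE)
  if (ncol(y) < 2L) stop("need >= 2 trials per individual", call. = FALSE)
  a <- anova_from_matrix(y)
  a$degenerate <- a$MS_A == 0 && a$MS_W == 0
  if (a$degenerate) a$F <- NaN
  structure(a, class = "coop_anova")
}

#' @export
print.coop_anova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA by individual: MS_A = %.4g (df %d), MS_W = %.4g (df %d), F = %.4g\n",
    x$MS_A, x$df_A, x$MS_W, x$df_W, x$F))
  if (isTRUE(x$degenerate)) cat("  (degenerate: all scores identical)\n")
  invisible(x)
}

#' Repeatability from ANOVA mean squares
#'
#' Intraclass-correlation repeatability
#' `R = ((MS_A - MS_W)/n0) / (MS_W + (MS_A - MS_W)/n0)`, where `n0` is the
#' number of measures per individual. Algebraically `R = (F - 1)/(F - 1 +
#' n0)`, which for `n0 = 2` is `(F - 1)/(F + 1)`. `R` reaches 1 only with
#' no within-individual variation and is negative when `F < 1`.
#'
#' @param anova A `coop_anova` object (or anything with elements `MS_A`,
#'   `MS_W`, `n0`), or `NULL` when `F` is supplied directly.
#' @param F_value,n0 Alternative direct parameterization via the F ratio.
#' @return Scalar repeatability `R <= 1`. When `MS_W = 0` (perfect
#'   repeatability) returns 1 with attribute `degenerate = TRUE`.
#' @examples
#' repeatability(F_value = 2.48)  # 0.4253
#' @export
repeatability <- function(anova = NULL, F_value = NULL, n0 = 2L) {
  if (is.null(anova)) {
    stopifnot(is.numeric(F_value))
    f <- F_value
  } else {
    if (isTRUE(anova$degenerate) || (is.nan(anova$F))) {
      stop("repeatability undefined: degenerate ANOVA (all scores equal)",
           call. = FALSE)
    }
    if (anova$MS_W == 0) {
      return(structure(1, degenerate = TRUE))
    }
    f <- anova$F
    n0 <- anova$n0
  }
  if (is.infinite(f)) return(structure(1, degenerate = TRUE))
  (f - 1) / (f - 1 + n0)
}

#' Monte-Carlo permutation p-value for the one-way ANOVA F ratio
#'
#' Under the null of no individual effect all scores are exchangeable
#' across every individual-by-trial slot. Scores are re-shuffled uniformly
#' across all slots `n_permutations` times and the p-value is the
#' add-one-corrected proportion `(b + 1)/(N + 1)` of permutations with
#' `F >= F_observed`.
#'
#' @param trials Long trial table.
#' @param n_permutations Number of shuffles (default 10000).
#' @param seed Integer seed.
#' @return Scalar p-value in `(0, 1]`.
#' @export
permutation_anova_p <- function(trials, n_permutations = 10000L, seed = 1L) {
  y <- score_matrix(trials)
  n <- nrow(y); k <- ncol(y)
  obs <- anova_from_matrix(y)$F
  if (is.nan(obs)) return(1)
  v <- as.vector(y)
  with_seed(seed, {
    b <- 0L
    for (i in seq_len(n_permutations)) {
      ym <- matrix(v[sample.int(length(v))], n, k)
      f <- anova_from_matrix(ym)$F
      if (!is.nan(f) && f >= obs) b <- b + 1L
    }
    (b + 1) / (n_permutations + 1)
  })
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up FDR control at level `alpha` over one batch of p-values: sort
#' ascending, find the largest `k` with `p_(k) <= k * alpha / m`, flag
#' those `k` tests. Flags are invariant to the input order.
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha FDR level (default 0.05).
#' @return Logical vector of significance flags, aligned with the input.
#' @examples
#' fdr_control(c(0.001, 0.04, 0.3))
#' @export
fdr_control <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value batch", call. = FALSE)
  p.adjust(p_values, method = "BH") <= alpha
}

#' Repeatability analysis across populations and sex subsets
#'
#' The batch driver for cooperative-phenotype testing: for every
#' population, and within it for all individuals / females / males, fits
#' the one-way ANOVA, computes repeatability and a Monte-Carlo permutation
#' p-value, then applies Benjamini-Hochberg FDR control separately within
#' each of the three subset batches (all, females, males) across
#' populations. Individuals lacking a complete set of trials are excluded
#' with a log message; subsets with fewer than 2 individuals are skipped
#' with a warning.
#'
#' @param individuals Individual-attribute table.
#' @param trials Long trial table.
#' @param config A [run_config()].
#' @return An object of class `repeatability_analysis`: a data frame with
#'   columns `subset`, `population_id`, `n`, `F`, `p_perm`, `R`,
#'   `significant_fdr`, plus the config as an attribute.
#' @export
repeatability_analysis <- function(individuals, trials,
                                   config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  trials$individual_id <- as.character(trials$individual_id)
  individuals$individual_id <- as.character(individuals$individual_id)
  # require the modal trial count; drop incomplete individuals
  counts <- table(trials$individual_id)
  n0 <- as.integer(names(sort(table(as.integer(counts)),
                              decreasing = TRUE))[1L])
  incomplete <- names(counts)[counts != n0]
  if (length(incomplete)) {
    coop_log("excluding ", length(incomplete),
             " individual(s) without exactly ", n0, " trials")
    trials <- trials[!trials$individual_id %in% incomplete, ]
  }
  pops <- unique(individuals$population_id)
  subsets <- c(all = "all", females = "F", males = "M")
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max - 1L,
                                length(pops) * length(subsets)))
  rows <- list(); si <- 0L
  for (subset in names(subsets)) {
    for (pop in pops) {
      si <- si + 1L
      ind <- individuals[individuals$population_id == pop, ]
      if (subsets[[subset]] != "all") {
        ind <- ind[ind$sex == subsets[[subset]], ]
      }
      tr <- trials[trials$individual_id %in% ind$individual_id, ]
      n_ind <- length(unique(tr$individual_id))
      if (n_ind < 2L) {
        warning(sprintf("skipping %s/%s: fewer than 2 individuals",
                        pop, subset), call. = FALSE)
        next
      }
      an <- anova_oneway(tr)
      r <- if (isTRUE(an$degenerate)) NA_real_ else repeatability(an)
      p <- permutation_anova_p(tr, config$n_permutations, seeds[si])
      rows[[length(rows) + 1L]] <- data.frame(
        subset = subset, population_id = pop, n = n_ind,
        F = as.numeric(an$F), p_perm = p, R = as.numeric(r),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  res$significant_fdr <- FALSE
  for (subset in names(subsets)) {
    idx <- which(res$subset == subset)
    if (length(idx)) {
      res$significant_fdr[idx] <- fdr_control(res$p_perm[idx],
                                              config$fdr_alpha)
    }
  }
  rownames(res) <- NULL
  structure(res, class = c("repeatability_analysis", "data.frame"),
            config = config, n0 = n0)
}

#' @export
print.repeatability_analysis <- function(x, digits = 3, ...) {
  cat(sprintf("Repeatability of cooperativeness (%d tests, n0 = %d, %d permutations)\n",
              nrow(x), attr(x, "n0"), attr(x, "config")$n_permutations))
  df <- as.data.frame(x)
  df$F <- round(df$F, digits)
  df$R <- round(df$R, digits)
  df$p_perm <- signif(df$p_perm, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.repeatability_analysis <- function(object, ...) {
  df <- as.data.frame(object)
  agg <- stats::aggregate(significant_fdr ~ subset, data = df, FUN = sum)
  names(agg)[2L] <- "n_significant"
  agg$n_tests <- as.vector(table(df$subset)[agg$subset])
  agg
}
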