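# Shared fixtures and independent oracles. Oracles are deliberately naive
# (explicit loops over dyads / ordered pairs) so they stay independent of
# the vectorized implementation they check.

make_obs <- function(sample_id, shoal_id, individual_id) {
  data.frame(sample_id = sample_id, shoal_id = shoal_id,
             individual_id = individual_id, stringsAsFactors = FALSE)
}

make_individuals <- function(ids, sex = NULL, body = NULL, coop = NULL,
                             population = "P", regime = "HP") {
  n <- length(ids)
  data.frame(
    individual_id = ids, population_id = population,
    predation_regime = regime,
    sex = if (is.null(sex)) rep(c("F", "M"), length.out = n) else sex,
    body_length_mm = if (is.null(body)) seq(20, 30, length.out = n) else body,
    overall_cooperativeness = if (is.null(coop)) seq_len(n) else coop,
    stringsAsFactors = FALSE
  )
}

# random small observation table: n_ind individuals, n_samp samples,
# random presence and random shoal assignment
random_obs <- function(n_ind, n_samp, p = 0.7) {
  ids <- LETTERS[seq_len(n_ind)]
  rows <- list()
  for (s in seq_len(n_samp)) {
    seen <- ids[runif(n_ind) < p]
    if (!length(seen)) next
    shoal <- sample.int(max(1L, ceiling(length(seen) / 2)),
                        length(seen), replace = TRUE)
    rows[[s]] <- make_obs(sprintf("s%02d", s), sprintf("g%d", shoal), seen)
  }
  do.call(rbind, rows)
}

# SRI by exhaustive per-dyad counting over samples
sri_oracle <- function(obs) {
  ids <- sort(unique(obs$individual_id))
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  samples <- unique(obs$sample_id)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      x <- 0L; den <- 0L
      for (s in samples) {
        sub <- obs[obs$sample_id == s, ]
        in_i <- ids[i] %in% sub$individual_id
        in_j <- ids[j] %in% sub$individual_id
        if (in_i || in_j) den <- den + 1L
        if (in_i && in_j &&
            sub$shoal_id[sub$individual_id == ids[i]] ==
            sub$shoal_id[sub$individual_id == ids[j]]) {
          x <- x + 1L
        }
      }
      w[i, j] <- w[j, i] <- if (den > 0) x / den else 0
    }
  }
  w
}

# continuous-trait weighted assortativity by explicit ordered-pair sums
assort_cont_oracle <- function(w, x, weighted = TRUE) {
  if (!weighted) w <- (w > 0) * 1
  n <- nrow(w)
  W <- 0; sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    wij <- w[i, j]
    W <- W + wij
    sx <- sx + wij * x[i];  sy <- sy + wij * x[j]
    sxx <- sxx + wij * x[i]^2; syy <- syy + wij * x[j]^2
    sxy <- sxy + wij * x[i] * x[j]
  }
  (sxy / W - (sx / W) * (sy / W)) /
    sqrt((sxx / W - (sx / W)^2) * (syy / W - (sy / W)^2))
}

# discrete-trait assortativity from an explicitly accumulated mixing matrix
assort_disc_oracle <- function(w, labels, weighted = TRUE) {
  if (!weighted) w <- (w > 0) * 1
  lev <- sort(unique(labels))
  e <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  n <- nrow(w)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) e[labels[i], labels[j]] <- e[labels[i], labels[j]] + w[i, j]
  }
  e <- e / sum(e)
  ab <- sum(rowSums(e) * colSums(e))
  (sum(diag(e)) - ab) / (1 - ab)
}

# balanced trial table from a score matrix
trials_from_matrix <- function(y) {
  data.frame(
    individual_id = rep(rownames(y), times = ncol(y)),
    trial_number = rep(seq_len(ncol(y)), each = nrow(y)),
    score = as.vector(y), stringsAsFactors = FALSE
  )
}
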