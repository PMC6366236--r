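test_that("trial_score averages Euclidean distance from the refuge", {
  expect_equal(trial_score(rep(5, 10), refuge_point = 5), 0)
  expect_equal(trial_score(c(0, 0, 8, 8), refuge_point = 0), 4)
  # 5-frame 2-D toy track against a hand-computed mean
  track <- rbind(c(0, 0), c(3, 4), c(6, 8), c(0, 1), c(1, 0))
  hand <- mean(c(0, 5, 10, 1, 1))
  expect_equal(trial_score(track, refuge_point = c(0, 0)), hand)
  expect_error(trial_score(numeric(0)), "empty")
})

test_that("overall cooperativeness is the mean of exactly n0 trial scores", {
  expect_equal(overall_cooperativeness(c(10, 20)), 15)
  expect_equal(overall_cooperativeness(c(7, 7)), 7)
  expect_error(overall_cooperativeness(c(1, 2, 3)), "expected 2")
  set.seed(1)
  y <- matrix(runif(8, 0, 50), 4, 2)
  expect_equal(vapply(1:4, function(i) overall_cooperativeness(y[i, ]),
                      numeric(1)),
               (y[, 1] + y[, 2]) / 2)
})

test_that("one-way ANOVA matches the independent lm decomposition", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:8, 1); k <- sample(2:4, 1)
    y <- matrix(rnorm(n * k, 30, 5), n, k,
                dimnames = list(paste0("i", 1:n), NULL))
    tr <- trials_from_matrix(y)
    a <- anova_oneway(tr)
    ref <- anova(lm(score ~ factor(individual_id), data = tr))
    expect_equal(a$MS_A, ref$`Mean Sq`[1])
    expect_equal(a$MS_W, ref$`Mean Sq`[2])
    expect_equal(a$F, ref$`F value`[1])
    expect_equal(a$df_A, ref$Df[1])
    expect_equal(a$df_W, ref$Df[2])
    expect_equal(a$SS_A + a$SS_W, a$SS_total, tolerance = 1e-9)
  }
})

test_that("degenerate ANOVA inputs are flagged", {
  tr <- trials_from_matrix(matrix(5, 3, 2, dimnames = list(c("a","b","c"), NULL)))
  a <- anova_oneway(tr)
  expect_true(a$degenerate)
  expect_true(is.nan(a$F))
  expect_error(repeatability(a), "degenerate")
  # perfect repeatability: zero within-individual variance
  y <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  a2 <- anova_oneway(trials_from_matrix(y))
  expect_equal(a2$MS_W, 0)
  r <- repeatability(a2)
  expect_equal(as.numeric(r), 1)
  expect_true(attr(r, "degenerate"))
  expect_error(anova_oneway(trials_from_matrix(y)[1:3, ]), "unbalanced")
})

test_that("repeatability follows the (F-1)/(F+1) identity for n0 = 2", {
  expect_equal(repeatability(F_value = 1), 0)
  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    y <- matrix(rnorm(2 * n, 30, sample(1:10, 1)), n, 2,
                dimnames = list(paste0("i", 1:n), NULL))
    a <- anova_oneway(trials_from_matrix(y))
    expect_equal(repeatability(a), (a$F - 1) / (a$F + 1))
  }
  # monotone in F; general n0 formula
  fs <- seq(0.2, 10, by = 0.2)
  rs <- vapply(fs, function(f) repeatability(F_value = f), numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_equal(repeatability(F_value = 3, n0 = 4), (3 - 1) / (3 - 1 + 4))
})

test_that("every reference F ratio reproduces the published repeatability", {
  tab <- reference_repeatability_table()
  r_hat <- vapply(tab$F, function(f) repeatability(F_value = f, n0 = 2),
                  numeric(1))
  # printed precision: half-ULP of the 2 d.p. repeatability plus the
  # propagated rounding of the printed 2 d.p. F ratio
  tol <- 0.005 + 2 * 0.005 / (tab$F + 1)^2
  expect_true(all(abs(r_hat - tab$repeatability) <= tol))
  # and most rows round exactly
  expect_gte(sum(round(r_hat, 2) == tab$repeatability), 22)
})

test_that("permutation ANOVA p-value matches exhaustive enumeration on a tiny design", {
  y <- matrix(c(1.0, 1.2, 3.1, 3.3, 5.0, 4.7), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  tr <- trials_from_matrix(y)
  # exhaustive: all 6! assignments of the scores to slots
  v <- as.vector(y)
  perms <- NULL
  permute_all <- function(x) {
    if (length(x) == 1L) return(list(x))
    out <- list()
    for (i in seq_along(x)) {
      for (p in permute_all(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
    }
    out
  }
  f_of <- function(vv) {
    ym <- matrix(vv, 3, 2)
    anova(lm(as.vector(ym) ~ factor(rep(1:3, 2))))$`F value`[1]
  }
  obs <- f_of(v)
  fs <- vapply(permute_all(v), f_of, numeric(1))
  p_exact <- mean(fs >= obs - 1e-12)
  p_mc <- permutation_anova_p(tr, n_permutations = 2000, seed = 3)
  # Monte-Carlo estimate within 3 binomial SDs of the exhaustive value
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(p_mc - p_exact), 3 * se + 1 / 2000)
})

test_that("permutation p is small for repeatable data, uniform under the null", {
  y <- matrix(c(1, 1.1, 10, 10.2, 20, 19.8, 30, 30.3), 4, 2, byrow = TRUE,
              dimnames = list(letters[1:4], NULL))
  expect_lte(permutation_anova_p(trials_from_matrix(y), 999, seed = 1), 0.01)
  ps <- vapply(1:200, function(i) {
    s <- simulate_phenotypes(phenotype_model(n_individuals = 15,
                                             sigma2_A = 0, sigma2_W = 25),
                             seed = 700 + i)
    permutation_anova_p(s$trials, 99, seed = i)
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.06)
})

test_that("BH control reproduces the published significance pattern", {
  tab <- reference_repeatability_table()
  for (batch in c("all", "females", "males")) {
    sub <- tab[tab$subset == batch, ]
    flags <- fdr_control(sub$p_value, alpha = 0.05)
    expect_identical(flags, sub$significant,
                     info = paste("batch", batch))
  }
  expect_equal(sum(fdr_control(tab$p_value[tab$subset == "all"])), 7)
  expect_equal(sum(fdr_control(tab$p_value[tab$subset == "females"])), 6)
  expect_equal(sum(fdr_control(tab$p_value[tab$subset == "males"])), 2)
  # flags invariant to input order; degenerate batches
  p <- c(0.001, 0.02, 0.04, 0.9)
  ord <- c(3, 1, 4, 2)
  expect_identical(fdr_control(p)[ord], fdr_control(p[ord]))
  expect_false(any(fdr_control(rep(1, 5))))
  expect_error(fdr_control(numeric(0)), "empty")
})

test_that("repeatability_analysis assembles per-population, per-sex results", {
  sim_f <- simulate_phenotypes(phenotype_model(n_individuals = 40,
                                               sigma2_A = 40, sigma2_W = 30,
                                               sex_ratio = 1),
                               seed = 21, population_id = "p1f")
  sim_m <- simulate_phenotypes(phenotype_model(n_individuals = 40,
                                               sigma2_A = 0.01,
                                               sigma2_W = 70, sex_ratio = 0),
                               seed = 22, population_id = "p1m")
  ind <- rbind(sim_f$individuals, sim_m$individuals)
  ind$population_id <- "p1"
  tr <- rbind(sim_f$trials, sim_m$trials)
  res <- repeatability_analysis(ind, tr, run_config(seed = 1,
                                                    n_permutations = 500))
  expect_setequal(res$subset, c("all", "females", "males"))
  rf <- res[res$subset == "females", ]
  rm_ <- res[res$subset == "males", ]
  expect_gt(rf$R, rm_$R)  # females repeatable by construction, males not
  expect_lt(rf$p_perm, 0.05)
  # incomplete individuals are dropped, not fatal
  tr_broken <- tr[-1, ]
  res2 <- repeatability_analysis(ind, tr_broken,
                                 run_config(seed = 1, n_permutations = 99))
  expect_equal(res2[res2$subset == "all", "n"], 79)
})
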