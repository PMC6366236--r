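test_that("continuous assortativity matches the brute-force ordered-pair oracle", {
  set.seed(91)
  for (i in 1:15) {
    n <- sample(4:6, 1)
    w <- matrix(runif(n * n), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    x <- rnorm(n)
    expect_equal(assortativity_continuous(w, x),
                 assort_cont_oracle(w, x), tolerance = 1e-12)
    expect_equal(assortativity_continuous(w, x, weighted = FALSE),
                 assort_cont_oracle(w, x, weighted = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("discrete assortativity matches the mixing-matrix oracle", {
  set.seed(92)
  for (i in 1:15) {
    n <- sample(4:6, 1)
    w <- matrix(runif(n * n), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    labels <- sample(c("F", "M"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1] <- setdiff(c("F", "M"),
                                                         labels[1])
    expect_equal(assortativity_discrete(w, labels),
                 assort_disc_oracle(w, labels), tolerance = 1e-12)
    expect_equal(assortativity_discrete(w, labels, weighted = FALSE),
                 assort_disc_oracle(w, labels, weighted = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("assortativity hits its closed-form landmark values", {
  # two disconnected cliques, trait constant within cliques -> 1
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 0.7; w[4:6, 4:6] <- 0.2
  diag(w) <- 0
  x <- c(1, 1, 1, 5, 5, 5)
  expect_equal(assortativity_continuous(w, x), 1, tolerance = 1e-12)
  expect_equal(assortativity_continuous(w, x, weighted = FALSE), 1,
               tolerance = 1e-12)
  # complete graph with equal weights: exactly the finite-size baseline
  # -1/(n-1) for any trait (pairs drawn without replacement decorrelate
  # only asymptotically)
  for (n in c(5, 9)) {
    w2 <- matrix(0.4, n, n); diag(w2) <- 0
    expect_equal(assortativity_continuous(w2, rnorm(n)), -1 / (n - 1),
                 tolerance = 1e-10)
  }
  # all edges within class -> 1
  labs <- c("a", "a", "a", "b", "b", "b")
  expect_equal(assortativity_discrete(w, labs), 1, tolerance = 1e-12)
  # perfect balanced bipartite mixing -> -1
  w3 <- matrix(0, 4, 4)
  w3[1:2, 3:4] <- 1; w3[3:4, 1:2] <- 1
  expect_equal(assortativity_discrete(w3, c("a", "a", "b", "b")), -1,
               tolerance = 1e-12)
  # hand-computed 2-class mixing matrix e = [[.3,.2],[.2,.3]] -> r = 0.2
  # realized as a 4-node weighted graph with the matching weight pattern
  w4 <- matrix(0, 4, 4)
  w4[1, 2] <- w4[2, 1] <- 0.3   # within class a
  w4[3, 4] <- w4[4, 3] <- 0.3   # within class b
  w4[1, 3] <- w4[3, 1] <- 0.2   # between
  w4[2, 4] <- w4[4, 2] <- 0.2   # between
  expect_equal(assortativity_discrete(w4, c("a", "a", "b", "b")), 0.2,
               tolerance = 1e-12)
})

test_that("coefficients are invariant to trait affine maps and weight scaling", {
  set.seed(93)
  w <- matrix(runif(36), 6, 6); w <- (w + t(w)) / 2; diag(w) <- 0
  x <- rnorm(6)
  r0 <- assortativity_continuous(w, x)
  expect_equal(assortativity_continuous(w, 3 * x - 10), r0,
               tolerance = 1e-12)
  expect_equal(assortativity_continuous(5 * w, x), r0, tolerance = 1e-12)
  # unweighted equals weighted when all positive weights are equal
  wb <- (w > 0.5) * 0.37
  if (sum(wb) > 0) {
    expect_equal(assortativity_continuous(wb, x),
                 assortativity_continuous(wb, x, weighted = FALSE),
                 tolerance = 1e-12)
  }
  # degenerate inputs are flagged undefined
  expect_warning(r <- assortativity_continuous(w, rep(2, 6)), "variance")
  expect_true(is.na(r))
  expect_warning(r2 <- assortativity_discrete(w, rep("F", 6)), "one class")
  expect_true(is.na(r2))
})

test_that("unweighted coefficient agrees with igraph on binary graphs", {
  skip_if_not_installed("igraph")
  set.seed(94)
  for (i in 1:5) {
    n <- 8
    w <- matrix(rbinom(n * n, 1, 0.4), n, n)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    diag(w) <- 0
    if (sum(w) == 0) next
    x <- rnorm(n)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected")
    expect_equal(assortativity_continuous(w, x, weighted = FALSE),
                 igraph::assortativity(g, values = x, directed = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("weak cross-group edges lower the unweighted coefficient below the weighted", {
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 0.9; w[4:6, 4:6] <- 0.9
  w[3, 4] <- w[4, 3] <- 0.01   # one weak bridge
  diag(w) <- 0
  x <- c(0, 0, 0, 1, 1, 1)
  expect_lt(assortativity_continuous(w, x, weighted = FALSE),
            assortativity_continuous(w, x))
})

test_that("assortment_test detects synthetic assortment and stays null otherwise", {
  sim <- simulate_population(
    phenotype_model(n_individuals = 40),
    observation_model(assort_strength = 3,
                      traits = "overall_cooperativeness"),
    kin = NULL, seed = 61)
  cfg <- run_config(seed = 8, n_permutations = 200)
  strong <- assortment_test(sim$observations, sim$individuals,
                            "overall_cooperativeness", config = cfg)
  expect_true(strong$significant)
  expect_equal(strong$tail, "high")
  expect_gt(strong$coefficient, 0)
  # same data, a trait with no structure: coefficient near null median
  set.seed(62)
  sim$individuals$noise_trait <- rnorm(nrow(sim$individuals))
  null_t <- assortment_test(sim$observations, sim$individuals,
                            "noise_trait", config = cfg)
  expect_gt(null_t$p_two_tailed, 0.025)
  # constant trait aborts
  sim$individuals$flat <- 1
  expect_error(assortment_test(sim$observations, sim$individuals, "flat",
                               config = cfg), "undefined")
  # within-sex subset runs and restricts the node set
  fem <- assortment_test(sim$observations, sim$individuals,
                         "overall_cooperativeness", subset = "females",
                         config = cfg)
  expect_lt(fem$n_nodes, strong$n_nodes + 1)
  expect_identical(fem$subset, "females")
})

test_that("dyadic correlation test wires the right null to each statistic", {
  sim <- simulate_population(
    phenotype_model(n_individuals = 30),
    observation_model(),
    kin = kin_model(family_size_mean = 3), seed = 63)
  cfg <- run_config(seed = 9, n_permutations = 200)
  dc <- dyadic_correlation_test(sim$observations, sim$individuals,
                                "summed_cooperativeness", config = cfg)
  n_net <- length(unique(filter_individuals(sim$observations,
                                            cfg$min_sightings)$individual_id))
  expect_equal(dc$n_dyads, dyad_count(n_net))
  expect_true(is.finite(dc$observed))
  dr <- dyadic_correlation_test(sim$observations, sim$individuals,
                                "relatedness",
                                relatedness = sim$relatedness, config = cfg)
  expect_true(is.finite(dr$observed))
  expect_error(dyadic_correlation_test(sim$observations, sim$individuals,
                                       "relatedness", config = cfg),
               "required")
  # kin-free grouping: relatedness test should not reject (single draw)
  expect_gt(dr$p_two_tailed, 0.01)
})

test_that("perfect linear dyadic relationship gives r = 1 and significance", {
  # construct a network whose weights are an exact linear function of
  # summed cooperativeness
  n <- 8
  coop <- seq(1, 8)
  names(coop) <- LETTERS[1:n]
  s <- outer(coop, coop, "+")
  w <- (s - min(s)) / (max(s) - min(s)) * 0.9 + 0.05
  diag(w) <- 0
  dimnames(w) <- list(LETTERS[1:n], LETTERS[1:n])
  dt <- dyad_table(w, cooperativeness = coop)
  expect_equal(cor(dt$weight, dt$summed_cooperativeness), 1,
               tolerance = 1e-12)
  expect_equal(nrow(dt), dyad_count(n))
})

test_that("scalar trait tests wrap the standard nonparametric machinery", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_test(x, x)$r_s, 1)
  expect_equal(spearman_test(x, -x)$r_s, -1)
  # 6-pair toy with a tie, against hand-computed midranks
  y <- c(10, 20, 20, 30, 40, 50)
  hand <- cor(rank(x), rank(y))
  expect_equal(spearman_test(x, y)$r_s, hand, tolerance = 1e-12)
  expect_error(spearman_test(x, rep(1, 6)), "constant")

  # disjoint supports: U = 0 for the lower group
  mw <- mann_whitney_test(c(1, 2, 3, 4), c(10, 11, 12))
  expect_equal(mw$W, 0)
  # identical groups: p ~ 1
  expect_gt(mann_whitney_test(c(5, 6, 7), c(5, 6, 7))$p, 0.9)
  # all tied across both groups: defined, p = 1
  expect_equal(mann_whitney_test(rep(3, 4), rep(3, 3))$p, 1)
  # 4-vs-3 toy: W matches exhaustive enumeration of the U statistic
  a <- c(1.2, 3.4, 2.2, 5.0); b <- c(0.8, 2.9, 4.1)
  u_hand <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(mann_whitney_test(a, b)$W, u_hand)
})
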