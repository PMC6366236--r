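# Synthetic-data generators. The generators provide populations with known
# ground truth (true repeatability, assortment strength, kin blocks) so
# every analysis stage can be validated end to end without field data.

#' Phenotype generating model
#'
#' Variance-component model for repeated cooperativeness scores. Each
#' individual carries a latent cooperativeness value
#' `a_i ~ N(mu, sigma2_A)`; each trial score is `y_it = a_i + e_it` with
#' `e_it ~ N(0, sigma2_W)`. The implied true repeatability is
#' `R_true = sigma2_A / (sigma2_A + sigma2_W)`. Body length (mm) is drawn
#' jointly normal with `a_i` at correlation `bodylength_coop_corr`.
#'
#' Defaults are on the scale of wild guppy assays: scores are distances in
#' cm with mean 30, variance components 30 (among) and 40 (within) give
#' `R_true ~ 0.43`; body length is N(25, 3^2) mm.
#'
#' @param n_individuals Number of individuals.
#' @param sex_ratio Proportion of females in `[0, 1]`.
#' @param mu Mean cooperativeness score (distance units).
#' @param sigma2_A Among-individual variance (>= 0).
#' @param sigma2_W Within-individual variance (>= 0).
#' @param n_trials Repeated measures per individual (default 2).
#' @param bodylength_coop_corr Correlation in `[-1, 1]` between body length
#'   and latent cooperativeness.
#' @param bodylength_mean,bodylength_sd Body length distribution (mm).
#' @return An object of class `phenotype_model`.
#' @export
phenotype_model <- function(n_individuals = 100L, sex_ratio = 0.5,
                            mu = 30, sigma2_A = 30, sigma2_W = 40,
                            n_trials = 2L, bodylength_coop_corr = 0,
                            bodylength_mean = 25, bodylength_sd = 3) {
  stopifnot(n_individuals >= 2L, sex_ratio >= 0, sex_ratio <= 1,
            sigma2_A >= 0, sigma2_W >= 0, n_trials >= 1L,
            abs(bodylength_coop_corr) <= 1, bodylength_sd >= 0)
  if (sigma2_A == 0 && sigma2_W == 0) {
    stop("degenerate model: sigma2_A and sigma2_W cannot both be 0",
         call. = FALSE)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 sex_ratio = sex_ratio, mu = mu,
                 sigma2_A = sigma2_A, sigma2_W = sigma2_W,
                 n_trials = as.integer(n_trials),
                 bodylength_coop_corr = bodylength_coop_corr,
                 bodylength_mean = bodylength_mean,
                 bodylength_sd = bodylength_sd,
                 R_true = sigma2_A / (sigma2_A + sigma2_W)),
            class = "phenotype_model")
}

#' Shoal-observation sampling model
#'
#' Repeated partial observation of a population: on each of
#' `n_days * samples_per_day` samples every individual is seen
#' independently with probability `p_observe`; the observed individuals are
#' placed at a latent position `z_i = sum_t strength_t *
#' standardized(trait_t, i) + N(0, 1)`, sorted by `z`, and cut into
#' consecutive shoals whose sizes are 1 + Poisson(`mean_shoal_size` - 1).
#' With all strengths 0 the grouping is exchangeable (no trait structure);
#' increasing a strength produces monotonically stronger assortment by that
#' trait.
#'
#' @param n_days Sampling days (default 6).
#' @param samples_per_day Samples per day (default 5).
#' @param p_observe Per-sample detection probability in (0, 1].
#' @param mean_shoal_size Mean shoal size (> 1).
#' @param assort_strength Named numeric vector of per-trait latent weights
#'   (names among the `traits`), or a single number applied to all
#'   `traits`. 0 means random grouping.
#' @param traits Character vector of individual-table columns the latent
#'   position may load on (e.g. `"overall_cooperativeness"`,
#'   `"body_length_mm"`, `"sex"`).
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(n_days = 6L, samples_per_day = 5L,
                              p_observe = 0.8, mean_shoal_size = 4,
                              assort_strength = 0, traits = character()) {
  stopifnot(n_days >= 1L, samples_per_day >= 1L,
            p_observe > 0, p_observe <= 1, mean_shoal_size > 1)
  if (length(assort_strength) > 1L || any(assort_strength != 0)) {
    if (length(traits) == 0L) {
      stop("assort_strength > 0 requires at least one trait", call. = FALSE)
    }
  }
  if (is.null(names(assort_strength)) && length(traits)) {
    assort_strength <- stats::setNames(rep_len(assort_strength,
                                               length(traits)), traits)
  }
  if (any(assort_strength < 0)) stop("assort_strength must be >= 0",
                                     call. = FALSE)
  structure(list(n_days = as.integer(n_days),
                 samples_per_day = as.integer(samples_per_day),
                 p_observe = p_observe, mean_shoal_size = mean_shoal_size,
                 assort_strength = assort_strength, traits = traits),
            class = "observation_model")
}

#' Block-structured kin model
#'
#' Individuals are partitioned into families; pairwise relatedness is
#' `within_family_r` inside a family and zero-mean noise
#' (sd `background_r_sd`) between families.
#'
#' @param family_size_mean Mean family size (>= 1); sizes are
#'   1 + Poisson(`family_size_mean` - 1).
#' @param within_family_r Relatedness within families (default 0.5, full
#'   sibs).
#' @param background_r_sd SD of the off-family noise (default 0, so
#'   off-family pairs are exactly 0).
#' @return An object of class `kin_model`.
#' @export
kin_model <- function(family_size_mean = 1, within_family_r = 0.5,
                      background_r_sd = 0) {
  stopifnot(family_size_mean >= 1, background_r_sd >= 0)
  structure(list(family_size_mean = family_size_mean,
                 within_family_r = within_family_r,
                 background_r_sd = background_r_sd),
            class = "kin_model")
}

#' Simulate individual attributes and repeated trial scores
#'
#' Draws a population from a [phenotype_model()]: latent cooperativeness
#' values, `n_trials` noisy trial scores per individual (truncated at 0,
#' scores are distances), correlated body lengths and sexes. The overall
#' cooperativeness column is the mean of the trial scores.
#'
#' @param model A [phenotype_model()].
#' @param seed Integer seed.
#' @param population_id,predation_regime Labels stamped on the individual
#'   table.
#' @return A list with elements `individuals` (individual-attribute table
#'   including `overall_cooperativeness` and the ground-truth latent value
#'   `true_value`) and `trials` (long trial table).
#' @examples
#' sim <- simulate_phenotypes(phenotype_model(n_individuals = 20), seed = 1)
#' head(sim$trials)
#' @export
simulate_phenotypes <- function(model, seed,
                                population_id = "sim",
                                predation_regime = "HP") {
  stopifnot(inherits(model, "phenotype_model"))
  with_seed(seed, {
    n <- model$n_individuals
    ids <- sprintf("%s_%03d", population_id, seq_len(n))
    a <- rnorm(n, 0, sqrt(model$sigma2_A))
    rho <- model$bodylength_coop_corr
    a_std <- if (model$sigma2_A > 0) a / sqrt(model$sigma2_A) else rnorm(n)
    bl <- model$bodylength_mean + model$bodylength_sd *
      (rho * a_std + sqrt(1 - rho^2) * rnorm(n))
    bl <- pmax(bl, 1)
    sex <- ifelse(runif(n) < model$sex_ratio, "F", "M")
    scores <- matrix(model$mu + a, n, model$n_trials) +
      matrix(rnorm(n * model$n_trials, 0, sqrt(model$sigma2_W)),
             n, model$n_trials)
    scores <- pmax(scores, 0)
    trials <- data.frame(
      individual_id = rep(ids, times = model$n_trials),
      trial_number = rep(seq_len(model$n_trials), each = n),
      score = as.vector(scores),
      stringsAsFactors = FALSE
    )
    trials <- trials[order(trials$individual_id, trials$trial_number), ]
    rownames(trials) <- NULL
    individuals <- data.frame(
      individual_id = ids,
      population_id = population_id,
      predation_regime = predation_regime,
      sex = sex,
      body_length_mm = bl,
      overall_cooperativeness = rowMeans(scores),
      true_value = model$mu + a,
      stringsAsFactors = FALSE
    )
    list(individuals = individuals, trials = trials)
  })
}

# Latent social position for one sample: weighted sum of standardized
# traits plus unit noise. Categorical traits are coded by their factor
# levels before standardization.
latent_position <- function(individuals, model) {
  n <- nrow(individuals)
  z <- rnorm(n)
  for (tr in model$traits) {
    s <- model$assort_strength[[tr]]
    if (is.null(s) || s == 0) next
    v <- individuals[[tr]]
    if (is.null(v)) {
      stop("individuals table lacks trait '", tr, "'", call. = FALSE)
    }
    if (!is.numeric(v)) v <- as.numeric(factor(v))
    sdv <- sd(v)
    v <- if (sdv > 0) (v - mean(v)) / sdv else rep(0, n)
    z <- z + s * v
  }
  z
}

#' Simulate a shoal-observation stream
#'
#' Generates `n_days * samples_per_day` independent samples from an
#' [observation_model()]. Each sample observes a random subset of the
#' population and partitions it into shoals; trait assortment is induced by
#' grouping individuals adjacent in a trait-loaded latent dimension.
#'
#' @param individuals Individual-attribute table carrying every trait the
#'   model loads on.
#' @param model An [observation_model()].
#' @param seed Integer seed.
#' @return A long observation table (`sample_id`, `shoal_id`,
#'   `individual_id`). Sample ids encode day and sample index
#'   (`d01_s03`) and sort lexicographically in time order.
#' @export
simulate_observations <- function(individuals, model, seed) {
  stopifnot(inherits(model, "observation_model"))
  with_seed(seed, {
    ids <- as.character(individuals$individual_id)
    n <- length(ids)
    out <- vector("list", model$n_days * model$samples_per_day)
    k <- 0L
    for (day in seq_len(model$n_days)) {
      for (s in seq_len(model$samples_per_day)) {
        k <- k + 1L
        seen <- which(runif(n) < model$p_observe)
        if (length(seen) == 0L) next
        z <- latent_position(individuals[seen, , drop = FALSE], model)
        ord <- seen[order(z)]
        m <- length(ord)
        sizes <- integer(0)
        while (sum(sizes) < m) {
          sizes <- c(sizes, 1L + rpois(1L, model$mean_shoal_size - 1))
        }
        shoal <- rep(seq_along(sizes), times = sizes)[seq_len(m)]
        out[[k]] <- data.frame(
          sample_id = sprintf("d%02d_s%02d", day, s),
          shoal_id = sprintf("g%02d", shoal),
          individual_id = ids[ord],
          stringsAsFactors = FALSE
        )
      }
    }
    obs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    rownames(obs) <- NULL
    obs
  })
}

#' Simulate a block-structured relatedness matrix
#'
#' @param individuals Individual-attribute table (ids define matrix order).
#' @param model A [kin_model()].
#' @param seed Integer seed.
#' @return A symmetric relatedness matrix with a `families` attribute
#'   giving the ground-truth family assignment.
#' @export
simulate_relatedness <- function(individuals, model, seed) {
  stopifnot(inherits(model, "kin_model"))
  with_seed(seed, {
    ids <- as.character(individuals$individual_id)
    n <- length(ids)
    sizes <- integer(0)
    while (sum(sizes) < n) {
      sizes <- c(sizes, 1L + rpois(1L, model$family_size_mean - 1))
    }
    fam <- rep(seq_along(sizes), times = sizes)[seq_len(n)]
    fam <- resample(fam)  # families not confounded with id order
    same <- outer(fam, fam, "==")
    r <- matrix(0, n, n)
    if (model$background_r_sd > 0) {
      noise <- matrix(rnorm(n * n, 0, model$background_r_sd), n, n)
      noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
      r <- noise
    }
    r[same] <- model$within_family_r
    diag(r) <- 1
    dimnames(r) <- list(ids, ids)
    attr(r, "families") <- stats::setNames(fam, ids)
    r
  })
}

#' Simulate a single predator-inspection position track
#'
#' Bounded mean-reverting random walk on the inspection lane `[0,
#' arena_length]` whose stationary mean distance from the refuge (at 0)
#' equals the cooperativeness parameter, clamped to the arena. Defaults
#' mirror a standard assay: 5-minute trials sampled at 30.1 frames/s give
#' 9030 frames.
#'
#' @param overall_cooperativeness Target mean distance from the refuge.
#' @param arena_length Lane length, same units as the target (default 60).
#' @param n_frames Track length in frames (default `round(5 * 60 * 30.1)`).
#' @param seed Integer seed.
#' @param reversion Mean-reversion rate per frame in (0, 1].
#' @param step_sd Innovation SD per frame.
#' @return Numeric vector of distances from the refuge, length `n_frames`.
#' @examples
#' tr <- simulate_track(30, seed = 1, n_frames = 500)
#' trial_score(tr, refuge_point = 0)
#' @export
simulate_track <- function(overall_cooperativeness, arena_length = 60,
                           n_frames = round(5 * 60 * 30.1), seed = NULL,
                           reversion = 0.05, step_sd = 1) {
  stopifnot(arena_length > 0, n_frames >= 1, reversion > 0, reversion <= 1)
  target <- min(max(overall_cooperativeness, 0), arena_length)
  with_seed(seed, {
    if (target <= 0) return(rep(0, n_frames))
    if (target >= arena_length) return(rep(arena_length, n_frames))
    x <- numeric(n_frames)
    x[1L] <- target
    eps <- rnorm(n_frames, 0, step_sd)
    for (t in seq_len(n_frames - 1L)) {
      nxt <- x[t] + reversion * (target - x[t]) + eps[t]
      # reflect at the refuge wall and the predator enclosure
      if (nxt < 0) nxt <- -nxt
      if (nxt > arena_length) nxt <- 2 * arena_length - nxt
      x[t + 1L] <- min(max(nxt, 0), arena_length)
    }
    x
  })
}

#' Simulate a complete population bundle
#'
#' Convenience wrapper producing all four analysis inputs plus a
#' ground-truth sidecar, optionally written as CSVs (plus `truth.json`).
#'
#' @param phenotype A [phenotype_model()].
#' @param observation An [observation_model()].
#' @param kin A [kin_model()] or `NULL` to skip relatedness.
#' @param seed Integer seed (sub-seeds for each stage are derived from it).
#' @param population_id,predation_regime Labels for the individual table.
#' @param out_dir If non-`NULL`, directory to write `individuals.csv`,
#'   `trials.csv`, `observations.csv`, `relatedness.csv` and `truth.json`.
#' @return A list `individuals`, `trials`, `observations`, `relatedness`,
#'   `truth`.
#' @export
simulate_population <- function(phenotype = phenotype_model(),
                                observation = observation_model(),
                                kin = kin_model(),
                                seed = 1L,
                                population_id = "sim",
                                predation_regime = "HP",
                                out_dir = NULL) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  ph <- simulate_phenotypes(phenotype, seeds[1L], population_id,
                            predation_regime)
  obs <- simulate_observations(ph$individuals, observation, seeds[2L])
  rel <- if (!is.null(kin)) {
    simulate_relatedness(ph$individuals, kin, seeds[3L])
  }
  truth <- list(
    R_true = phenotype$R_true,
    assort_strength = as.list(observation$assort_strength),
    families = if (!is.null(rel)) as.list(attr(rel, "families"))
  )
  bundle <- list(individuals = ph$individuals, trials = ph$trials,
                 observations = obs, relatedness = rel, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(ph$individuals, file.path(out_dir, "individuals.csv"),
                "individuals")
    write_table(ph$trials, file.path(out_dir, "trials.csv"), "trials")
    write_table(obs, file.path(out_dir, "observations.csv"), "observations")
    if (!is.null(rel)) {
      write_table(rel, file.path(out_dir, "relatedness.csv"), "relatedness")
    }
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    coop_log("simulated bundle written to ", out_dir, " (seed ", seed, ")")
  }
  bundle
}
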