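# End-to-end orchestration: phenotype -> network -> assortment -> report.

derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Run the full cooperative-phenotype / social-assortment analysis
#'
#' Composes every stage on one population's data: repeatability of trial
#' scores (across all populations present in the individual table), the
#' filtered SRI network, the full battery of assortment tests
#' (cooperativeness weighted and unweighted for all/females/males; body
#' length and sex weighted), the dyadic summed-cooperativeness and
#' relatedness correlation tests, and the scalar trait tests (Spearman
#' body length vs cooperativeness; Mann-Whitney sex difference, both over
#' the network's individuals). Each test draws its permutations from a
#' seed derived deterministically from `config$seed`, so a rerun with the
#' same config, seed and inputs is bit-identical.
#'
#' @param config A [run_config()].
#' @param individuals,trials,observations,relatedness Input tables (see
#'   [read_table()]), or `NULL` to skip the corresponding stage
#'   (`relatedness` only). Character scalars are treated as CSV paths.
#' @param out_dir Optional directory for CSV/JSON reports (values rounded
#'   to 6 significant digits for byte-stable comparison).
#' @return An object of class `coop_report`: list with elements
#'   `repeatability`, `network`, `assortment` (list of `assort_test`),
#'   `dyadic` (list of `perm_test`), `trait_tests`, `manifest`.
#' @export
run_full_analysis <- function(config, individuals, trials, observations,
                              relatedness = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (is.character(individuals)) individuals <- read_table(individuals, "individuals")
  if (is.character(trials)) trials <- read_table(trials, "trials")
  if (is.character(observations)) observations <- read_table(observations, "observations")
  if (is.character(relatedness)) relatedness <- read_table(relatedness, "relatedness")
  xl <- validate_crosslinks(individuals, trials, observations, relatedness)
  if (!xl$consistent) {
    print(xl)
    stop("cross-link inconsistent inputs; fix tables or subset them first",
         call. = FALSE)
  }
  seeds <- derive_seeds(config$seed, 16L)
  cfg_i <- function(i) {
    c2 <- config; c2$seed <- seeds[i]; c2
  }

  rep_res <- tryCatch(
    repeatability_analysis(individuals, trials, cfg_i(1L)),
    error = function(e) stop("stage repeatability: ", conditionMessage(e),
                             call. = FALSE))

  obs_f <- tryCatch(
    filter_individuals(observations, config$min_sightings),
    error = function(e) stop("stage network: ", conditionMessage(e),
                             call. = FALSE))
  # overall cooperativeness from trials if not already on the table
  if (is.null(individuals$overall_cooperativeness) ||
      anyNA(individuals$overall_cooperativeness)) {
    sc <- tapply(trials$score, as.character(trials$individual_id), mean)
    individuals$overall_cooperativeness <-
      as.numeric(sc[as.character(individuals$individual_id)])
  }
  net <- sri_matrix(obs_f)

  grid <- list(
    list(trait = "overall_cooperativeness", weighted = TRUE,  subset = "all"),
    list(trait = "overall_cooperativeness", weighted = TRUE,  subset = "females"),
    list(trait = "overall_cooperativeness", weighted = TRUE,  subset = "males"),
    list(trait = "overall_cooperativeness", weighted = FALSE, subset = "all"),
    list(trait = "overall_cooperativeness", weighted = FALSE, subset = "females"),
    list(trait = "overall_cooperativeness", weighted = FALSE, subset = "males"),
    list(trait = "body_length_mm",          weighted = TRUE,  subset = "all"),
    list(trait = "sex",                     weighted = TRUE,  subset = "all")
  )
  assort <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    g <- grid[[i]]
    assort[[i]] <- tryCatch(
      assortment_test(obs_f, individuals, g$trait, g$weighted, g$subset,
                      cfg_i(1L + i), prefilter = FALSE),
      error = function(e) stop("stage assortment (", g$trait, ", ",
                               g$subset, "): ", conditionMessage(e),
                               call. = FALSE))
  }
  names(assort) <- vapply(grid, function(g) {
    sprintf("%s_%s_%s", g$trait, if (g$weighted) "w" else "u", g$subset)
  }, character(1))

  dyadic <- list()
  dyadic$summed_cooperativeness <- tryCatch(
    dyadic_correlation_test(obs_f, individuals, "summed_cooperativeness",
                            config = cfg_i(10L), prefilter = FALSE),
    error = function(e) stop("stage dyadic (summed cooperativeness): ",
                             conditionMessage(e), call. = FALSE))
  if (!is.null(relatedness)) {
    dyadic$relatedness <- tryCatch(
      dyadic_correlation_test(obs_f, individuals, "relatedness",
                              relatedness = relatedness,
                              config = cfg_i(11L), prefilter = FALSE),
      error = function(e) stop("stage dyadic (relatedness): ",
                               conditionMessage(e), call. = FALSE))
  }

  ids <- rownames(net)
  ind_net <- individuals[match(ids, as.character(individuals$individual_id)), ]
  trait_tests <- list(
    bodylength_vs_cooperativeness = spearman_test(
      ind_net$body_length_mm, ind_net$overall_cooperativeness),
    sex_difference_cooperativeness = mann_whitney_test(
      ind_net$overall_cooperativeness[ind_net$sex == "F"],
      ind_net$overall_cooperativeness[ind_net$sex == "M"])
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("coopassort")),
    config = unclass(config),
    n_individuals = nrow(individuals),
    n_trial_rows = nrow(trials),
    n_observation_rows = nrow(observations),
    network_nodes = nrow(net),
    network_dyads = dyad_count(nrow(net)),
    has_relatedness = !is.null(relatedness),
    runtime_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  report <- structure(
    list(repeatability = rep_res, network = net, assortment = assort,
         dyadic = dyadic, trait_tests = trait_tests, manifest = manifest),
    class = "coop_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

perm_test_row <- function(name, x) {
  data.frame(test = name,
             observed = signif(x$observed, 6),
             null_median = signif(x$null_median, 6),
             p = signif(x$p_two_tailed, 6),
             significant = x$significant,
             tail = x$tail,
             stringsAsFactors = FALSE)
}

#' Tabular summary of a full-analysis report
#'
#' @param object A `coop_report`.
#' @param ... Unused.
#' @return Data frame with one row per permutation test (assortment and
#'   dyadic), columns `test, observed, null_median, p, significant, tail`.
#' @export
summary.coop_report <- function(object, ...) {
  rows <- c(
    lapply(names(object$assortment), function(nm) {
      perm_test_row(nm, object$assortment[[nm]])
    }),
    lapply(names(object$dyadic), function(nm) {
      perm_test_row(paste0("dyadic_", nm), object$dyadic[[nm]])
    })
  )
  do.call(rbind, rows)
}

#' @export
print.coop_report <- function(x, ...) {
  cat("== Cooperative phenotype / social assortment report ==\n\n")
  print(x$repeatability)
  cat("\n")
  print(x$network)
  cat("\nPermutation tests:\n")
  print.data.frame(summary(x), row.names = FALSE)
  tt <- x$trait_tests
  cat(sprintf("\nBody length vs cooperativeness: r_s = %.3f, p = %.3g (n = %d)\n",
              tt$bodylength_vs_cooperativeness$r_s,
              tt$bodylength_vs_cooperativeness$p,
              tt$bodylength_vs_cooperativeness$n))
  cat(sprintf("Sex difference in cooperativeness: W = %.1f, p = %.3g (%d F, %d M)\n",
              tt$sex_difference_cooperativeness$W,
              tt$sex_difference_cooperativeness$p,
              tt$sex_difference_cooperativeness$n_a,
              tt$sex_difference_cooperativeness$n_b))
  invisible(x)
}

#' Write a full-analysis report to disk
#'
#' Writes `repeatability.csv`, `association_matrix.csv`, `edge_list.csv`,
#' `permutation_tests.csv`, `trait_tests.csv`, `report.json` and
#' `manifest.json` under `out_dir`. Numeric report fields are rounded to 6
#' significant digits so reruns with the same seed are byte-identical.
#'
#' @param report A `coop_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rep_df <- as.data.frame(report$repeatability)
  for (col in c("F", "p_perm", "R")) rep_df[[col]] <- signif(rep_df[[col]], 6)
  write.csv(rep_df, file.path(out_dir, "repeatability.csv"),
            row.names = FALSE, quote = FALSE)
  net <- signif(unclass(report$network), 6)
  write_table(net, file.path(out_dir, "association_matrix.csv"),
              "relatedness")  # same square-CSV layout
  el <- edge_list(report$network)
  el$sri <- signif(el$sri, 6)
  write.csv(el, file.path(out_dir, "edge_list.csv"), row.names = FALSE,
            quote = FALSE)
  pt <- summary(report)
  write.csv(pt, file.path(out_dir, "permutation_tests.csv"),
            row.names = FALSE, quote = FALSE)
  tt <- report$trait_tests
  tt_df <- data.frame(
    test = c("spearman_bodylength_cooperativeness",
             "mannwhitney_sex_cooperativeness"),
    statistic = signif(c(tt$bodylength_vs_cooperativeness$r_s,
                         tt$sex_difference_cooperativeness$W), 6),
    p = signif(c(tt$bodylength_vs_cooperativeness$p,
                 tt$sex_difference_cooperativeness$p), 6))
  write.csv(tt_df, file.path(out_dir, "trait_tests.csv"),
            row.names = FALSE, quote = FALSE)
  json <- list(
    repeatability = rep_df,
    permutation_tests = pt,
    trait_tests = tt_df,
    manifest = report$manifest
  )
  json$manifest$runtime_seconds <- NULL  # not reproducible across runs
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  coop_log("report written to ", out_dir)
  invisible(out_dir)
}

#' Contrast two full-analysis reports
#'
#' Side-by-side comparison of every permutation test shared by two report
#' bundles (e.g. a high- and a low-predation population). Emits a warning
#' when the analysis settings (permutation count, tail level, filter)
#' differ.
#'
#' @param report_a,report_b `coop_report` objects.
#' @param labels Character vector of two column labels.
#' @return Data frame with observed coefficients, p-values and
#'   significance flags for both reports plus their difference.
#' @export
compare_populations <- function(report_a, report_b,
                                labels = c("a", "b")) {
  stopifnot(inherits(report_a, "coop_report"),
            inherits(report_b, "coop_report"))
  ca <- report_a$manifest$config; cb <- report_b$manifest$config
  for (k in c("n_permutations", "alpha_tail", "min_sightings")) {
    if (!identical(ca[[k]], cb[[k]])) {
      warning("reports differ in setting '", k, "' (", ca[[k]], " vs ",
              cb[[k]], "); contrasts may not be comparable", call. = FALSE)
    }
  }
  sa <- summary(report_a); sb <- summary(report_b)
  common <- intersect(sa$test, sb$test)
  sa <- sa[match(common, sa$test), ]; sb <- sb[match(common, sb$test), ]
  out <- data.frame(
    test = common,
    observed_a = sa$observed, observed_b = sb$observed,
    delta = signif(sa$observed - sb$observed, 6),
    p_a = sa$p, p_b = sb$p,
    significant_a = sa$significant, significant_b = sb$significant,
    agreement = sa$significant == sb$significant,
    stringsAsFactors = FALSE
  )
  names(out) <- sub("_a$", paste0("_", labels[1L]), names(out))
  names(out) <- sub("_b$", paste0("_", labels[2L]), names(out))
  out
}
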