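#' Analysis run configuration
#'
#' Bundles the knobs shared by every stochastic stage: the master seed, the
#' permutation count, the two-tailed significance quantile, the FDR level
#' and the minimum-sightings network filter.
#'
#' @param seed Integer master seed for all randomness in a run.
#' @param n_permutations Number of permutations per null distribution
#'   (default 10000, the conventional count for data-stream nulls).
#' @param alpha_tail Tail probability of the two-tailed significance rule:
#'   a test is significant when the observed statistic lies among the
#'   `alpha_tail` highest or lowest null values (default 0.025, i.e. a 5%
#'   two-tailed test).
#' @param fdr_alpha Level of Benjamini-Hochberg FDR control applied to each
#'   batch of repeatability tests (default 0.05).
#' @param min_sightings Minimum number of distinct samples an individual
#'   must be observed in to enter the association network (default 4,
#'   i.e. "observed more than three times").
#'
#' @return An object of class `run_config` (a validated list).
#' @examples
#' run_config(seed = 1, n_permutations = 200)
#' @export
run_config <- function(seed = 1L, n_permutations = 10000L,
                       alpha_tail = 0.025, fdr_alpha = 0.05,
                       min_sightings = 4L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L) {
    stop("n_permutations must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(alpha_tail) || alpha_tail <= 0 || alpha_tail >= 0.5) {
    stop("alpha_tail must lie strictly between 0 and 0.5", call. = FALSE)
  }
  if (!is.numeric(fdr_alpha) || fdr_alpha <= 0 || fdr_alpha > 1) {
    stop("fdr_alpha must lie in (0, 1]", call. = FALSE)
  }
  min_sightings <- as.integer(min_sightings)
  if (is.na(min_sightings) || min_sightings < 1L) {
    stop("min_sightings must be >= 1", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_permutations = n_permutations,
         alpha_tail = alpha_tail, fdr_alpha = fdr_alpha,
         min_sightings = min_sightings),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (k in names(x)) cat(sprintf("  %-15s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read a run configuration from a flat key-value file
#'
#' The file holds one `key = value` (or `key: value`, or whitespace
#' separated) pair per line; `#` starts a comment. Unknown keys are an
#' error. Missing keys take the [run_config()] defaults.
#'
#' @param path Path to the configuration file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[=:[:space:]]+")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) != 2L) {
      stop("cannot parse config line: '", ln, "'", call. = FALSE)
    }
    kv[[parts[1L]]] <- parts[2L]
  }
  allowed <- c("seed", "n_permutations", "alpha_tail", "fdr_alpha",
               "min_sightings")
  bad <- setdiff(names(kv), allowed)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  kv <- lapply(kv, as.numeric)
  do.call(run_config, kv)
}
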