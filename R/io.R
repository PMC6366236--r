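# CSV schemas. All interchange files are comma-separated UTF-8 with a
# mandatory header row, "." decimal separator and empty fields for missing
# values.

.schemas <- list(
  individuals  = c("individual_id", "population_id", "predation_regime",
                   "sex", "body_length_mm"),
  trials       = c("individual_id", "trial_number", "score"),
  observations = c("sample_id", "shoal_id", "individual_id")
)

schema_error <- function(kind, msg) {
  stop(sprintf("[%s] schema error: %s", kind, msg), call. = FALSE)
}

#' Read a typed analysis table from CSV
#'
#' Reads and validates one of the four table kinds the analysis consumes:
#'
#' * `"individuals"`: columns `individual_id, population_id,
#'   predation_regime, sex, body_length_mm` (an optional
#'   `overall_cooperativeness` column is kept if present);
#' * `"trials"`: columns `individual_id, trial_number, score`;
#' * `"observations"`: long group-by-individual format with columns
#'   `sample_id, shoal_id, individual_id`;
#' * `"relatedness"`: a square matrix with individual ids as header row and
#'   first column; asymmetry beyond `1e-9` is an error.
#'
#' Validation failures (missing columns, duplicate keys, unparseable or
#' out-of-range numerics) raise an error naming the offending row and
#' column. Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"individuals"`, `"trials"`, `"observations"`,
#'   `"relatedness"`.
#' @return A validated `data.frame`, or a symmetric numeric matrix for
#'   `schema = "relatedness"`.
#' @seealso [write_table()], [validate_crosslinks()]
#' @export
read_table <- function(path, schema = c("individuals", "trials",
                                        "observations", "relatedness")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (schema == "relatedness") return(read_relatedness(path))
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  validate_table(df, schema)
}

#' Validate an in-memory analysis table
#'
#' Applies the same checks as [read_table()] to a data frame built in code.
#'
#' @param df A data frame.
#' @param schema Table kind, as in [read_table()].
#' @return The validated data frame with typed columns.
#' @export
validate_table <- function(df, schema = c("individuals", "trials",
                                          "observations")) {
  schema <- match.arg(schema)
  need <- .schemas[[schema]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    schema_error(schema, paste("missing column(s):",
                               paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  num_col <- function(col, positive = FALSE, nonneg = FALSE) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(as.character(df[[col]]))))
    if (length(bad) == 0L) bad <- which(is.na(v))
    if (length(bad)) {
      schema_error(schema, sprintf("unparseable numeric in column '%s', row %d",
                                   col, bad[1L]))
    }
    if (positive && any(v <= 0)) {
      schema_error(schema, sprintf("column '%s' must be > 0 (row %d)",
                                   col, which(v <= 0)[1L]))
    }
    if (nonneg && any(v < 0)) {
      schema_error(schema, sprintf("column '%s' must be >= 0 (row %d)",
                                   col, which(v < 0)[1L]))
    }
    v
  }
  if (schema == "individuals") {
    df$body_length_mm <- num_col("body_length_mm", positive = TRUE)
    if ("overall_cooperativeness" %in% names(df)) {
      df$overall_cooperativeness <-
        suppressWarnings(as.numeric(df$overall_cooperativeness))
    }
    bad <- which(!df$predation_regime %in% c("HP", "LP"))
    if (length(bad)) {
      schema_error(schema, sprintf(
        "predation_regime must be HP or LP (row %d: '%s')",
        bad[1L], df$predation_regime[bad[1L]]))
    }
    bad <- which(!df$sex %in% c("F", "M"))
    if (length(bad)) {
      schema_error(schema, sprintf("sex must be F or M (row %d: '%s')",
                                   bad[1L], df$sex[bad[1L]]))
    }
    key <- paste(df$population_id, df$individual_id, sep = "\r")
    if (anyDuplicated(key)) {
      schema_error(schema, sprintf(
        "duplicate individual_id within population (row %d: '%s')",
        which(duplicated(key))[1L],
        df$individual_id[which(duplicated(key))[1L]]))
    }
  } else if (schema == "trials") {
    df$trial_number <- num_col("trial_number", positive = TRUE)
    if (any(df$trial_number != round(df$trial_number))) {
      schema_error(schema, "trial_number must be integer")
    }
    df$trial_number <- as.integer(df$trial_number)
    df$score <- num_col("score", nonneg = TRUE)
    key <- paste(df$individual_id, df$trial_number, sep = "\r")
    if (anyDuplicated(key)) {
      schema_error(schema, sprintf(
        "duplicate (individual_id, trial_number) at row %d",
        which(duplicated(key))[1L]))
    }
  } else if (schema == "observations") {
    key <- paste(df$sample_id, df$individual_id, sep = "\r")
    if (anyDuplicated(key)) {
      schema_error(schema, sprintf(
        "individual '%s' appears more than once in sample '%s' (row %d)",
        df$individual_id[which(duplicated(key))[1L]],
        df$sample_id[which(duplicated(key))[1L]],
        which(duplicated(key))[1L]))
    }
  }
  rownames(df) <- NULL
  df
}

read_relatedness <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) {
    schema_error("relatedness", sprintf("matrix not square (%d x %d)",
                                        nrow(m), ncol(m)))
  }
  if (!identical(ids, colnames(m))) {
    schema_error("relatedness", "row ids do not match column ids")
  }
  if (anyDuplicated(ids)) {
    schema_error("relatedness", "duplicate individual ids")
  }
  dimnames(m) <- list(ids, ids)
  off <- m; diag(off) <- 0
  if (any(is.na(off))) {
    schema_error("relatedness", "missing off-diagonal value")
  }
  if (max(abs(off - t(off))) > 1e-9) {
    schema_error("relatedness", "matrix asymmetric beyond 1e-9 tolerance")
  }
  m
}

#' Write an analysis table to CSV
#'
#' Inverse of [read_table()]: numeric columns are formatted with up to 15
#' significant digits so that a write-then-read round trip reproduces the
#' records exactly.
#'
#' @param x A data frame (or, for `schema = "relatedness"`, a symmetric
#'   matrix with id dimnames).
#' @param path Output path.
#' @param schema Table kind, as in [read_table()].
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, schema = c("individuals", "trials",
                                            "observations", "relatedness")) {
  schema <- match.arg(schema)
  if (schema == "relatedness") {
    df <- data.frame(individual_id = rownames(x),
                     as.data.frame(x, check.names = FALSE),
                     check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-link consistency report across analysis tables
#'
#' Checks that every individual referenced by the trial table, the
#' observation table and the (optional) relatedness matrix is present in
#' the individual-attribute table, and reports individuals lacking trial
#' records. Purely diagnostic: inputs are never modified.
#'
#' @param individuals Individual-attribute table.
#' @param trials Trial-score table (optional).
#' @param observations Shoal-observation table (optional).
#' @param relatedness Relatedness matrix (optional).
#' @return An object of class `crosslink_report`: a named list of character
#'   vectors of offending ids, with a logical `consistent` flag.
#' @examples
#' ind <- data.frame(individual_id = c("a", "b"), population_id = "P",
#'                   predation_regime = "HP", sex = c("F", "M"),
#'                   body_length_mm = c(20, 22))
#' tr <- data.frame(individual_id = rep(c("a", "c"), each = 2),
#'                  trial_number = rep(1:2, 2), score = 1:4)
#' validate_crosslinks(ind, trials = tr)
#' @export
validate_crosslinks <- function(individuals, trials = NULL,
                                observations = NULL, relatedness = NULL) {
  known <- unique(as.character(individuals$individual_id))
  rep <- list(
    trials_not_in_individuals = character(),
    individuals_without_trials = character(),
    observations_not_in_individuals = character(),
    relatedness_missing_ids = character()
  )
  if (!is.null(trials)) {
    tid <- unique(as.character(trials$individual_id))
    rep$trials_not_in_individuals <- setdiff(tid, known)
    rep$individuals_without_trials <- setdiff(known, tid)
  }
  if (!is.null(observations)) {
    oid <- unique(as.character(observations$individual_id))
    rep$observations_not_in_individuals <- setdiff(oid, known)
  }
  if (!is.null(relatedness)) {
    net_ids <- if (!is.null(observations)) {
      unique(as.character(observations$individual_id))
    } else {
      known
    }
    rep$relatedness_missing_ids <- setdiff(net_ids, rownames(relatedness))
  }
  rep$consistent <- all(lengths(rep[names(rep) != "individuals_without_trials"]) == 0L)
  class(rep) <- "crosslink_report"
  rep
}

#' @export
print.crosslink_report <- function(x, ...) {
  cat("Cross-link report:",
      if (x$consistent) "consistent\n" else "INCONSISTENT\n")
  for (k in setdiff(names(x), "consistent")) {
    if (length(x[[k]])) {
      cat(sprintf("  %s: %s\n", k, paste(x[[k]], collapse = ", ")))
    }
  }
  invisible(x)
}
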