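# Simple-ratio-index association networks from group-by-individual shoal
# observations.

#' Drop rarely sighted individuals from an observation table
#'
#' Removes every observation row of individuals seen in fewer than
#' `min_sightings` distinct samples. The default 4 encodes the standard
#' "observed more than three times" inclusion rule, which trades network
#' size for precision of the association estimates. Shoal membership of
#' retained individuals is unchanged.
#'
#' @param obs Observation table (`sample_id`, `shoal_id`, `individual_id`).
#' @param min_sightings Minimum distinct samples (default 4).
#' @return Filtered observation table.
#' @export
filter_individuals <- function(obs, min_sightings = 4L) {
  stopifnot(min_sightings >= 1L)
  seen <- tapply(as.character(obs$sample_id),
                 as.character(obs$individual_id),
                 function(s) length(unique(s)))
  keep <- names(seen)[seen >= min_sightings]
  out <- obs[as.character(obs$individual_id) %in% keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no individuals meet the sighting threshold", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Binary association matrix of one sample
#'
#' Entry 1 iff the two individuals shared a shoal in the sample, else 0;
#' block-diagonal under the shoal partition.
#'
#' @param sample Observation rows of a single sample.
#' @return Symmetric 0/1 matrix over the individuals observed in the
#'   sample (zero diagonal).
#' @export
binary_sample_matrix <- function(sample) {
  ids <- as.character(sample$individual_id)
  if (anyDuplicated(ids)) {
    stop("individual appears more than once in the sample", call. = FALSE)
  }
  shoal <- as.character(sample$shoal_id)
  m <- outer(shoal, shoal, "==") * 1
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  m
}

# Internal index used by sri_matrix and the permutation ensemble: integer
# codes for individuals, samples and (sample, shoal) groups.
obs_index <- function(obs, ids = NULL) {
  ind_chr <- as.character(obs$individual_id)
  if (is.null(ids)) ids <- sort(unique(ind_chr))
  ind <- match(ind_chr, ids)
  if (anyNA(ind)) stop("observation of unknown individual", call. = FALSE)
  samp_chr <- as.character(obs$sample_id)
  samples <- sort(unique(samp_chr))
  samp <- match(samp_chr, samples)
  key <- paste(samp_chr, as.character(obs$shoal_id), sep = "\r")
  shoal <- match(key, unique(key))
  if (anyDuplicated(paste(samp, ind))) {
    stop("individual appears more than once in a sample", call. = FALSE)
  }
  list(ids = ids, samples = samples, ind = ind, samp = samp, shoal = shoal)
}

# Dyadic together / either-seen counts from an index; the ensemble reuses
# this with permuted `ind`.
sri_counts <- function(idx, ind = idx$ind) {
  n <- length(idx$ids)
  A <- matrix(0, n, max(idx$shoal))
  A[cbind(ind, idx$shoal)] <- 1
  together <- tcrossprod(A)
  O <- matrix(0, n, length(idx$samples))
  O[cbind(ind, idx$samp)] <- 1
  both <- tcrossprod(O)
  n_i <- diag(both)
  either <- outer(n_i, n_i, "+") - both
  list(together = together, either = either, sightings = n_i)
}

#' Simple ratio index association matrix
#'
#' For each dyad the SRI edge weight is `x / n`: the number of samples
#' where the two were observed in the same shoal, out of all samples where
#' at least one of them was observed (including samples where both were
#' seen but in different shoals). Weights range from 0 (never together) to
#' 1 (together whenever either was seen).
#'
#' Apply [filter_individuals()] first; a dyad whose denominator is 0
#' (neither individual ever observed) is defined as weight 0 and counted in
#' the `zero_denominator` attribute — impossible after filtering.
#'
#' @param obs Observation table.
#' @param ids Optional character vector fixing node order (defaults to the
#'   sorted observed ids).
#' @return An object of class `association_matrix`: the symmetric weight
#'   matrix with attributes `x` (together counts), `n` (either-seen
#'   counts) and `sightings` (per-node sample counts).
#' @examples
#' obs <- data.frame(sample_id = c("s1", "s1", "s2", "s2", "s3"),
#'                   shoal_id = c("a", "a", "a", "b", "a"),
#'                   individual_id = c("A", "B", "A", "B", "A"))
#' sri_matrix(obs)  # A-B: together 1 of 3
#' @export
sri_matrix <- function(obs, ids = NULL) {
  idx <- obs_index(obs, ids)
  cnt <- sri_counts(idx)
  w <- cnt$together / cnt$either
  zero_den <- sum(cnt$either[upper.tri(cnt$either)] == 0)
  w[cnt$either == 0] <- 0
  diag(w) <- 0
  diag(cnt$together) <- 0
  dimnames(w) <- list(idx$ids, idx$ids)
  dimnames(cnt$together) <- dimnames(w)
  dimnames(cnt$either) <- dimnames(w)
  structure(w, class = c("association_matrix", "matrix"),
            x = cnt$together, n = cnt$either,
            sightings = stats::setNames(cnt$sightings, idx$ids),
            zero_denominator = zero_den)
}

#' @export
print.association_matrix <- function(x, ...) {
  n <- nrow(x)
  up <- x[upper.tri(x)]
  cat(sprintf(
    "SRI association network: %d nodes, %d dyads, %d non-zero edges\n",
    n, dyad_count(n), sum(up > 0)))
  cat(sprintf("  mean edge weight %.4f (non-zero mean %.4f, max %.4f)\n",
              mean(up), if (any(up > 0)) mean(up[up > 0]) else NA_real_,
              max(up)))
  invisible(x)
}

#' Attribute-restricted subnetwork
#'
#' Restriction of an association matrix to the nodes taking a given value
#' of a node attribute (e.g. one sex); edge weights are unchanged.
#'
#' @param matrix An `association_matrix` (or plain symmetric matrix with id
#'   dimnames).
#' @param attributes Named vector (names = node ids) or an individual table
#'   with `individual_id` plus the attribute column.
#' @param attribute Attribute column name when `attributes` is a table.
#' @param value Attribute value selecting the nodes.
#' @return The restricted matrix (class preserved). Fewer than 3 remaining
#'   nodes triggers a warning; zero is an error.
#' @export
subnetwork <- function(matrix, attributes, value, attribute = NULL) {
  if (is.data.frame(attributes)) {
    stopifnot(!is.null(attribute))
    attributes <- stats::setNames(attributes[[attribute]],
                                  as.character(attributes$individual_id))
  }
  ids <- rownames(matrix)
  vals <- attributes[ids]
  if (anyNA(vals)) {
    stop("attribute undefined for node(s): ",
         paste(head(ids[is.na(vals)], 5L), collapse = ", "), call. = FALSE)
  }
  keep <- which(vals == value)
  if (length(keep) == 0L) stop("no node has attribute value '", value, "'",
                               call. = FALSE)
  if (length(keep) < 3L) {
    warning("subnetwork has fewer than 3 nodes; assortativity unstable",
            call. = FALSE)
  }
  out <- matrix[keep, keep, drop = FALSE]
  for (a in c("x", "n")) {
    if (!is.null(attr(matrix, a))) {
      attr(out, a) <- attr(matrix, a)[keep, keep, drop = FALSE]
    }
  }
  if (!is.null(attr(matrix, "sightings"))) {
    attr(out, "sightings") <- attr(matrix, "sightings")[keep]
  }
  class(out) <- class(matrix)
  out
}

#' Number of unordered dyads
#'
#' @param n Node count (>= 2).
#' @return `n * (n - 1) / 2`.
#' @examples
#' dyad_count(61)   # 1830
#' dyad_count(102)  # 5151
#' @export
dyad_count <- function(n) {
  if (any(n < 2L)) stop("need n >= 2", call. = FALSE)
  n * (n - 1) / 2
}

#' Edge list of an association matrix
#'
#' @param matrix An `association_matrix`.
#' @return Data frame `id_a, id_b, x_together, n_either, sri` over all
#'   unordered dyads.
#' @export
edge_list <- function(matrix) {
  ids <- rownames(matrix)
  up <- which(upper.tri(matrix), arr.ind = TRUE)
  x <- attr(matrix, "x"); nn <- attr(matrix, "n")
  data.frame(
    id_a = ids[up[, 1L]], id_b = ids[up[, 2L]],
    x_together = if (!is.null(x)) x[up] else NA_real_,
    n_either = if (!is.null(nn)) nn[up] else NA_real_,
    sri = matrix[up],
    stringsAsFactors = FALSE
  )
}
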