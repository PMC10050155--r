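## ---------------------------------------------------------------------------
## Single-sample gene-set enrichment (ssGSEA).
##
## One sample at a time, genes are ranked by expression (average ranks for
## ties) and walked in decreasing-rank order; the enrichment score of a set is
## the sum over all positions of the difference between the cumulative
## rank-weight mass of in-set genes (|rank|^alpha, normalised to 1) and the
## cumulative uniform mass of out-of-set genes. Because only ranks enter the
## statistic, scores are invariant to any strictly increasing per-sample
## transform of expression -- the property that makes pathway-level
## classification robust to normalisation differences between cohorts.
## ---------------------------------------------------------------------------

#' Rank a sample's expression values
#'
#' Ranks 1..N with N for the highest expression; ties receive average ranks.
#' An all-constant vector cannot be ranked meaningfully and is an error.
#'
#' @param column numeric vector of finite values.
#' @return numeric rank vector.
#' @export
rank_within_sample <- function(column) {
  if (!all(is.finite(column))) stop("non-finite expression value", call. = FALSE)
  if (length(unique(column)) == 1L)
    stop("degenerate sample: all expression values identical", call. = FALSE)
  rank(column, ties.method = "average")
}

#' Scoring parameters for ssGSEA
#'
#' @param alpha rank-weight exponent (>= 0). 0.25 is the conventional default
#'   of the reference implementations of this statistic.
#' @param normalise divide the whole score matrix by its global max - min
#'   (the conventional ssGSEA normalisation), putting scores on a common,
#'   comparable scale.
#' @param min_coverage,warn_coverage a set whose surviving fraction of members
#'   (after dropping genes absent from the matrix) falls below `warn_coverage`
#'   triggers a warning; below `min_coverage` it is an error. Cross-species
#'   translation of sets loses members, so some slack is routine.
#' @return list of class `scoring_params`.
#' @export
scoring_params <- function(alpha = 0.25, normalise = TRUE,
                           min_coverage = 0.3, warn_coverage = 0.8) {
  stopifnot(alpha >= 0, min_coverage >= 0, warn_coverage >= min_coverage)
  structure(list(alpha = alpha, normalise = normalise,
                 min_coverage = min_coverage, warn_coverage = warn_coverage,
                 tie_method = "average"),
            class = "scoring_params")
}

#' Single-sample gene-set enrichment scores
#'
#' Converts a genes x samples matrix into a sets x samples score matrix.
#'
#' For sample ranks \eqn{r_i} ordered decreasingly, in-set weight
#' \eqn{w_i = |r_i|^\alpha}, the enrichment score of set S is
#' \deqn{ES = \sum_{i=1}^{N} \left[ P_{in}(i) - P_{out}(i) \right]}
#' with \eqn{P_{in}} the cumulative normalised in-set weight and
#' \eqn{P_{out}} the cumulative uniform mass over out-of-set genes.
#'
#' Genes listed in a set but absent from the matrix are dropped (with the
#' coverage policy of [scoring_params()]); a set with zero overlap is an
#' error naming the set.
#'
#' @param x expression matrix (genes x samples), normalised log scale.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param params [scoring_params()].
#' @return numeric matrix, sets x samples.
#' @export
ssgsea_score <- function(x, sets, params = scoring_params()) {
  validate_expression_matrix(x)
  stopifnot(inherits(params, "scoring_params"))
  if (!is.list(sets) || is.null(names(sets)) || length(sets) == 0L)
    stop("sets must be a non-empty named list", call. = FALSE)
  genes <- rownames(x)
  filtered <- lapply(sets, intersect, y = genes)
  overlap <- lengths(filtered)
  if (any(overlap == 0L))
    stop("gene set(s) with zero overlap with the matrix: ",
         paste(names(sets)[overlap == 0L], collapse = ", "), call. = FALSE)
  coverage <- overlap / lengths(sets)
  if (any(coverage < params$min_coverage))
    stop("gene set(s) below minimum coverage ", params$min_coverage, ": ",
         paste(names(sets)[coverage < params$min_coverage], collapse = ", "),
         call. = FALSE)
  if (any(coverage < params$warn_coverage))
    warning("gene set(s) below ", params$warn_coverage * 100, "% coverage: ",
            paste(names(sets)[coverage < params$warn_coverage],
                  collapse = ", "), call. = FALSE)

  n <- nrow(x)
  idx_by_set <- lapply(filtered, match, table = genes)
  es <- matrix(0, nrow = length(sets), ncol = ncol(x),
               dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    r <- rank_within_sample(x[, j])
    ord <- order(r, decreasing = TRUE)
    w <- abs(r[ord])^params$alpha
    # membership of each ordered position, per set
    pos_of_gene <- integer(n)
    pos_of_gene[ord] <- seq_len(n)
    for (s in seq_along(idx_by_set)) {
      inset <- logical(n)
      inset[pos_of_gene[idx_by_set[[s]]]] <- TRUE
      win <- w * inset
      p_in <- cumsum(win) / sum(win)
      n_out <- n - sum(inset)
      if (n_out == 0L)
        stop("gene set '", names(sets)[s],
             "' covers every matrix gene; enrichment undefined", call. = FALSE)
      p_out <- cumsum(!inset) / n_out
      es[s, j] <- sum(p_in - p_out)
    }
  }
  if (params$normalise) {
    rng <- max(es) - min(es)
    if (rng == 0)
      stop("all enrichment scores identical; cannot range-normalise",
           call. = FALSE)
    es <- es / rng
  }
  es
}

#' Average scores per gene set within each class
#'
#' @param scores sets x samples matrix (e.g. from [ssgsea_score()]).
#' @param labels named character vector or factor, one class per sample
#'   (names = sample ids), or unnamed in column order.
#' @return matrix, sets x classes, of arithmetic means.
#' @export
mean_scores_by_class <- function(scores, labels) {
  validate_expression_matrix(scores, what = "score matrix")
  labels <- align_labels(labels, colnames(scores))
  classes <- if (is.factor(labels)) levels(droplevels(labels)) else
    unique(as.character(labels))
  out <- vapply(classes, function(k)
    rowMeans(scores[, labels == k, drop = FALSE]),
    numeric(nrow(scores)))
  out <- matrix(out, nrow = nrow(scores),
                dimnames = list(rownames(scores), classes))
  out
}

# Align a label vector to sample ids; every sample must be labelled.
align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing))
      stop("unlabelled sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("labels length (", length(labels), ") != number of samples (",
         length(sample_ids), ")", call. = FALSE)
  }
  if (anyNA(labels)) stop("NA class label", call. = FALSE)
  labels
}
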