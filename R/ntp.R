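## ---------------------------------------------------------------------------
## Nearest-template prediction (NTP).
##
## Each class is encoded as a binary indicator over the template's feature
## universe; a sample is assigned the class whose indicator is nearest in
## cosine correlation distance, computed on feature-centered data (cosine
## distance on uncentered, all-positive data degenerates toward the largest
## class). Significance comes from a feature-permutation null: the sample's
## own centered values are shuffled across the template universe, preserving
## the sample's value distribution, and the distance to the assigned class is
## recomputed. Benjamini-Hochberg FDR across samples gates the final call;
## samples failing the cutoff are "unclassified".
## ---------------------------------------------------------------------------

#' Parameters for nearest-template prediction
#'
#' @param n_perm permutation count B (>= 19; default 1000).
#' @param fdr_threshold q cutoff in (0,1); samples at or above it are called
#'   `"unclassified"` (default 0.05).
#' @param seed integer RNG seed. Each sample's permutation stream is derived
#'   from this seed and a hash of the sample's name, so p-values do not
#'   depend on sample order.
#' @param center `"feature_mean"` or `"feature_median"` centering across the
#'   classified cohort.
#' @param scale also divide each centered feature by its SD (off by default).
#' @return list of class `ntp_params`.
#' @export
ntp_params <- function(n_perm = 1000L, fdr_threshold = 0.05, seed = 1L,
                       center = c("feature_mean", "feature_median"),
                       scale = FALSE) {
  center <- match.arg(center)
  stopifnot(n_perm >= 19L, fdr_threshold > 0, fdr_threshold < 1)
  structure(list(n_perm = as.integer(n_perm), fdr_threshold = fdr_threshold,
                 seed = as.integer(seed), center = center, scale = scale),
            class = "ntp_params")
}

#' Binary class-indicator matrix for a template
#'
#' Rows are the template features found in `feature_universe` (template
#' order: class by class), columns the classes; entry 1 marks membership.
#' Features absent from the universe are dropped with a warning naming them;
#' a class losing all its features is an error.
#'
#' @param template [subtype_template()].
#' @param feature_universe character vector of available feature ids.
#' @return numeric matrix (features x classes).
#' @export
build_indicator <- function(template, feature_universe) {
  stopifnot(inherits(template, "subtype_template"))
  kept <- lapply(template$features_by_class, intersect, y = feature_universe)
  missing <- setdiff(unlist(template$features_by_class, use.names = FALSE),
                     feature_universe)
  if (length(missing))
    warning("template feature(s) absent from data: ",
            paste(missing, collapse = ", "), call. = FALSE)
  empty <- names(kept)[lengths(kept) == 0L]
  if (length(empty))
    stop("class(es) with zero features present in the data: ",
         paste(empty, collapse = ", "), call. = FALSE)
  feats <- unlist(kept, use.names = FALSE)
  ind <- matrix(0, nrow = length(feats), ncol = length(kept),
                dimnames = list(feats, names(kept)))
  for (k in names(kept)) ind[kept[[k]], k] <- 1
  ind
}

#' Center features across samples
#'
#' Subtracts each feature's mean (or median) across the cohort so cosine
#' distance measures profile shape rather than overall magnitude. Requires
#' at least 2 samples.
#'
#' @param x expression matrix.
#' @param method `"feature_mean"` or `"feature_median"`.
#' @param scale also divide by the feature SD.
#' @return centered matrix.
#' @export
center_features <- function(x, method = c("feature_mean", "feature_median"),
                            scale = FALSE) {
  method <- match.arg(method)
  validate_expression_matrix(x)
  if (ncol(x) < 2L)
    stop("cohort centering requires >= 2 samples", call. = FALSE)
  ctr <- if (method == "feature_mean") rowMeans(x) else
    apply(x, 1L, stats::median)
  out <- x - ctr
  if (scale) {
    s <- apply(x, 1L, stats::sd)
    if (any(s == 0))
      stop("constant feature(s) cannot be scaled: ",
           paste(rownames(x)[s == 0], collapse = ", "), call. = FALSE)
    out <- out / s
  }
  out
}

#' Cosine correlation distance
#'
#' \eqn{d = 1 - x \cdot t / (\|x\| \|t\|)}, in [0, 2].
#'
#' @param x,t non-zero numeric vectors of equal length.
#' @return distance d.
#' @export
cosine_distance <- function(x, t) {
  if (length(x) != length(t)) stop("length mismatch", call. = FALSE)
  nx <- sqrt(sum(x^2)); nt <- sqrt(sum(t^2))
  if (nx == 0 || nt == 0) stop("zero vector", call. = FALSE)
  1 - sum(x * t) / (nx * nt)
}

#' Permutation p-value of a sample's distance to one class indicator
#'
#' The null is built by shuffling the sample's centered values across the
#' template feature universe B times and recomputing the cosine distance to
#' the given indicator column; \eqn{p = (1 + \#\{d^* \le d_{obs}\})/(B + 1)}.
#' This is the calibration engine behind [ntp_classify()]; exposed so the
#' permutation test itself can be checked against exhaustive enumeration and
#' uniform-null expectations.
#'
#' @param x centered feature vector of one sample (template universe order).
#' @param indicator_col binary indicator vector of one class.
#' @param n_perm permutation count B.
#' @param seed integer seed for this sample's stream.
#' @param d_obs observed distance; recomputed when `NULL`.
#' @return p-value in [1/(B+1), 1].
#' @export
ntp_pvalue <- function(x, indicator_col, n_perm = 1000L, seed = 1L,
                       d_obs = NULL) {
  if (is.null(d_obs)) d_obs <- cosine_distance(x, indicator_col)
  nx <- sqrt(sum(x^2))
  nt <- sqrt(sum(indicator_col^2))
  # cosine distance to a permuted x only needs the permuted in-class sum:
  # d* = 1 - sum(x_perm[in]) / (||x|| ||t||); ||x_perm|| == ||x||.
  inset <- which(indicator_col != 0)
  hits <- with_local_seed(seed, {
    h <- 0L
    for (b in seq_len(n_perm)) {
      xp <- x[sample.int(length(x))]
      dstar <- 1 - sum(xp[inset]) / (nx * nt)
      if (dstar <= d_obs) h <- h + 1L
    }
    h
  })
  (1 + hits) / (n_perm + 1)
}

# Evaluate expr under its own seed, leaving the caller's RNG state untouched.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable 32-bit string hash (djb2) for order-invariant per-sample seeds.
string_seed <- function(seed, name) {
  h <- 5381
  for (code in utf8ToInt(name)) h <- (h * 33 + code) %% 2147483647
  as.integer((seed + h) %% 2147483647)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up q-values via [stats::p.adjust()]; inputs must lie in
#' (0, 1].
#'
#' @param p_values numeric vector of p-values.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] <= 0 | p_values[ok] > 1))
    stop("p-value outside (0, 1]", call. = FALSE)
  out <- p_values
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Classify samples by nearest-template prediction
#'
#' Works on a gene matrix with a gene-space template (option A) or on an
#' ssGSEA score matrix with a gene_set-space template (options B/C). Data are
#' restricted to the template universe, feature-centered across the cohort,
#' and each sample is assigned the class at minimum cosine distance. The
#' assignment's permutation p-value ([ntp_pvalue()]) is BH-adjusted across
#' samples; calls with q at or above `params$fdr_threshold` become
#' `"unclassified"`. A sample tied between classes (distance difference
#' below 1e-12) is flagged ambiguous and left unclassified; an all-zero
#' centered sample cannot be scored and is likewise unclassified, with NA
#' distances.
#'
#' @param x expression or score matrix (features x samples).
#' @param template [subtype_template()] whose feature space matches `x`.
#' @param params [ntp_params()].
#' @return data.frame with columns `sample`, `predicted_class`, `d.<class>`
#'   per class, `p_value`, `FDR`, plus a `reason` attribute column `flag`
#'   (`""`, `"ambiguous"` or `"degenerate"`).
#' @export
ntp_classify <- function(x, template, params = ntp_params()) {
  stopifnot(inherits(params, "ntp_params"))
  ind <- build_indicator(template, rownames(x))
  xr <- x[rownames(ind), , drop = FALSE]
  xc <- center_features(xr, method = params$center, scale = params$scale)
  classes <- colnames(ind)
  n_s <- ncol(xc)
  d <- matrix(NA_real_, nrow = n_s, ncol = length(classes),
              dimnames = list(colnames(xc), classes))
  pred <- character(n_s)
  flag <- character(n_s)
  p <- rep(NA_real_, n_s)
  for (j in seq_len(n_s)) {
    xj <- xc[, j]
    if (all(xj == 0)) {
      pred[j] <- "unclassified"; flag[j] <- "degenerate"
      next
    }
    dj <- vapply(classes, function(k) cosine_distance(xj, ind[, k]), 0)
    d[j, ] <- dj
    best <- which.min(dj)
    if (sum(dj - dj[best] < 1e-12) > 1L) {
      pred[j] <- "unclassified"; flag[j] <- "ambiguous"
      next
    }
    pred[j] <- classes[best]
    flag[j] <- ""
    p[j] <- ntp_pvalue(xj, ind[, best], n_perm = params$n_perm,
                       seed = string_seed(params$seed, colnames(xc)[j]),
                       d_obs = dj[best])
  }
  q <- bh_adjust(p)
  pred[!is.na(q) & q >= params$fdr_threshold] <- "unclassified"
  out <- data.frame(sample = colnames(xc), predicted_class = pred,
                    stringsAsFactors = FALSE)
  dd <- as.data.frame(d)
  colnames(dd) <- paste0("d.", classes)
  out <- cbind(out, dd)
  out$p_value <- p
  out$FDR <- q
  out$flag <- flag
  rownames(out) <- NULL
  out
}

#' One-call pipeline: classify a cohort with a chosen template option
#'
#' Option A applies the gene-space template directly to the expression
#' matrix; options B and C first convert the matrix to ssGSEA scores over the
#' template's gene sets, then run NTP on the score matrix.
#'
#' @param x genes x samples expression matrix.
#' @param template [subtype_template()].
#' @param option `"A"`, `"B"` or `"C"`.
#' @param sets gene-set collection supplying members for the template's set
#'   names (options B/C; defaults to the template's `sets` attribute).
#' @param scoring [scoring_params()] for options B/C.
#' @param params [ntp_params()].
#' @return classification data.frame as from [ntp_classify()].
#' @export
classify_cohort <- function(x, template, option = c("A", "B", "C"),
                            sets = attr(template, "sets"),
                            scoring = scoring_params(),
                            params = ntp_params()) {
  option <- match.arg(option)
  if (option == "A") {
    if (template$feature_space != "gene")
      stop("option A requires a gene-space template", call. = FALSE)
    return(ntp_classify(x, template, params))
  }
  if (template$feature_space != "gene_set")
    stop("options B/C require a gene_set-space template", call. = FALSE)
  wanted <- unlist(template$features_by_class, use.names = FALSE)
  if (is.null(sets) || !all(wanted %in% names(sets)))
    stop("gene-set collection missing template set(s): ",
         paste(setdiff(wanted, names(sets)), collapse = ", "), call. = FALSE)
  scores <- ssgsea_score(x, sets[wanted], scoring)
  ntp_classify(scores, template, params)
}
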