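## ---------------------------------------------------------------------------
## Template derivation from a labelled reference cohort.
##
## Three routes build the class -> feature templates that NTP consumes:
##   option A: ortholog translation of an existing gene-space template;
##   option B: GO-style selection -- per-set class means of ssGSEA scores are
##             z-scored across classes and a set is class-specific when its z
##             is positive in exactly one class and negative in all others;
##   option C: four collections (curated signatures, hallmarks,
##             microenvironment cell-population markers, an immune gene panel
##             grouped by multinomial LASSO) each filtered by pairwise Welch
##             t-tests, then unioned.
## Plus the reverse-translation meta-signature check and cross-cohort
## mean-score concordance.
## ---------------------------------------------------------------------------

#' Derivation parameters
#'
#' @param p_threshold pairwise Welch t-test cutoff for set retention
#'   (default 0.01).
#' @param lasso_folds cross-validation folds (default 10).
#' @param lasso_rule lambda selection rule, `"lambda.1se"` (largest penalty
#'   within one SE of the CV minimum) or `"lambda.min"`.
#' @param lasso_seed seed for the CV fold assignment.
#' @param fc_threshold linear-scale fold-change cutoff for meta-signature
#'   genes (default 4).
#' @param meta_p p cutoff for meta-signature genes (default 0.05).
#' @param meta_top_n maximum genes per class meta-signature (default 20).
#' @return list of class `derive_params`.
#' @export
derive_params <- function(p_threshold = 0.01, lasso_folds = 10L,
                          lasso_rule = c("lambda.1se", "lambda.min"),
                          lasso_seed = 1L, fc_threshold = 4,
                          meta_p = 0.05, meta_top_n = 20L) {
  lasso_rule <- match.arg(lasso_rule)
  stopifnot(p_threshold > 0, p_threshold < 1, lasso_folds >= 2L,
            fc_threshold > 1)
  structure(list(p_threshold = p_threshold, lasso_folds = as.integer(lasso_folds),
                 lasso_rule = lasso_rule, lasso_seed = as.integer(lasso_seed),
                 fc_threshold = fc_threshold, meta_p = meta_p,
                 meta_top_n = as.integer(meta_top_n)),
            class = "derive_params")
}

#' Z-score per-set class means across classes
#'
#' Each set's row of class means is standardised to
#' (mean_k - row mean) / row SD, using the sample SD over the class means.
#' Rows with zero SD carry no between-class signal; they are excluded and
#' recorded in the `degenerate` attribute.
#'
#' @param class_means sets x classes matrix (see [mean_scores_by_class()]).
#' @return z-score matrix over non-degenerate sets, attribute `degenerate`
#'   naming the excluded sets.
#' @export
zscore_class_means <- function(class_means) {
  stopifnot(is.matrix(class_means), ncol(class_means) >= 2L)
  mu <- rowMeans(class_means)
  sdv <- apply(class_means, 1L, stats::sd)
  degenerate <- rownames(class_means)[sdv == 0]
  keep <- sdv > 0
  z <- (class_means[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  attr(z, "degenerate") <- degenerate
  z
}

#' Select class-specific sets by the one-positive z-score rule
#'
#' A set is assigned to class k iff its z-score is strictly above 0 in k and
#' strictly below 0 in every other class; all other sets are discarded.
#'
#' @param z sets x classes z-score matrix from [zscore_class_means()].
#' @return gene_set-space [subtype_template()]; per-class counts in the
#'   `counts` attribute. A class ending up with zero sets is an error.
#' @export
select_class_specific_sets <- function(z) {
  stopifnot(is.matrix(z), ncol(z) >= 2L)
  classes <- colnames(z)
  assign_of <- apply(z, 1L, function(row) {
    pos <- row > 0
    if (sum(pos) == 1L && all(row[!pos] < 0)) classes[which(pos)] else NA_character_
  })
  fbc <- lapply(classes, function(k) rownames(z)[!is.na(assign_of) & assign_of == k])
  names(fbc) <- classes
  empty <- classes[lengths(fbc) == 0L]
  if (length(empty))
    stop("no class-specific sets for class(es): ",
         paste(empty, collapse = ", "), call. = FALSE)
  tpl <- subtype_template(fbc, "gene_set")
  attr(tpl, "counts") <- lengths(fbc)
  tpl
}

#' Filter sets by pairwise Welch t-tests against every other class
#'
#' A set is kept for class k iff, for each other class j, a two-sided Welch
#' two-sample t-test of k versus j has p below `p_threshold` AND the class-k
#' mean exceeds the class-j mean ("significantly higher than each other
#' subtype in turn"). At most one class can satisfy the rule per set.
#'
#' @param scores sets x samples score matrix.
#' @param labels class label per sample (named by sample id, or in column
#'   order). Every class needs at least 3 samples.
#' @param params [derive_params()].
#' @param allow_empty_classes permit classes with zero surviving sets (used
#'   when several collections are later unioned).
#' @return gene_set-space [subtype_template()] with a `counts` attribute.
#' @export
ttest_filter <- function(scores, labels, params = derive_params(),
                         allow_empty_classes = FALSE) {
  validate_expression_matrix(scores, what = "score matrix")
  labels <- as.character(align_labels(labels, colnames(scores)))
  classes <- sort(unique(labels))
  n_k <- table(labels)
  if (any(n_k < 3L))
    stop("class(es) with fewer than 3 samples: ",
         paste(names(n_k)[n_k < 3L], collapse = ", "), call. = FALSE)
  idx <- lapply(classes, function(k) which(labels == k))
  names(idx) <- classes
  assign_of <- rep(NA_character_, nrow(scores))
  for (s in seq_len(nrow(scores))) {
    v <- scores[s, ]
    for (k in classes) {
      ok <- TRUE
      for (j in setdiff(classes, k)) {
        a <- v[idx[[k]]]; b <- v[idx[[j]]]
        if (mean(a) <= mean(b)) { ok <- FALSE; break }
        p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
        if (!is.finite(p) || p >= params$p_threshold) { ok <- FALSE; break }
      }
      if (ok) { assign_of[s] <- k; break }
    }
  }
  fbc <- lapply(classes, function(k)
    rownames(scores)[!is.na(assign_of) & assign_of == k])
  names(fbc) <- classes
  tpl <- subtype_template(fbc, "gene_set",
                          allow_empty_classes = allow_empty_classes)
  attr(tpl, "counts") <- lengths(fbc)
  tpl
}

#' Group candidate genes by class with multinomial LASSO
#'
#' Fits an L1-penalised multinomial logistic model over a lambda path
#' (features standardised), chooses lambda by stratified K-fold
#' cross-validation at the `lasso_rule` point, and assigns a gene to class k
#' iff its class-k coefficient at that lambda is positive. A gene positive in
#' several classes goes to the class with the largest coefficient, and the
#' event is logged in the `multi_positive` attribute. Constant genes cannot
#' be standardised and are excluded before fitting, with a warning.
#'
#' @param expr_subset candidate genes x samples matrix.
#' @param labels class per sample (>= 2 per class; every fold must contain
#'   every class, so each class needs at least `lasso_folds` samples).
#' @param params [derive_params()].
#' @return named list class -> gene character vector, with attributes
#'   `lambda` (chosen value) and `multi_positive`.
#' @export
lasso_group_genes <- function(expr_subset, labels, params = derive_params()) {
  validate_expression_matrix(expr_subset, what = "candidate gene matrix")
  labels <- as.character(align_labels(labels, colnames(expr_subset)))
  classes <- sort(unique(labels))
  n_k <- table(labels)
  if (any(n_k < 2L))
    stop("class(es) with fewer than 2 samples", call. = FALSE)
  if (any(n_k < params$lasso_folds))
    stop("class(es) with fewer samples than CV folds (a fold would miss a ",
         "class): ", paste(names(n_k)[n_k < params$lasso_folds], collapse = ", "),
         call. = FALSE)
  sds <- apply(expr_subset, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant gene(s): ",
            paste(rownames(expr_subset)[sds == 0], collapse = ", "),
            call. = FALSE)
    expr_subset <- expr_subset[sds > 0, , drop = FALSE]
  }
  if (nrow(expr_subset) < 2L)
    stop("fewer than 2 variable candidate genes", call. = FALSE)
  X <- t(expr_subset)
  y <- factor(labels, levels = classes)
  foldid <- integer(length(y))
  with_local_seed(params$lasso_seed, {
    for (k in classes) {
      ik <- which(labels == k)
      foldid[ik] <- sample(rep_len(seq_len(params$lasso_folds), length(ik)))
    }
  })
  cv <- tryCatch(
    glmnet::cv.glmnet(X, y, family = "multinomial", foldid = foldid,
                      standardize = TRUE, type.measure = "deviance"),
    error = function(e) stop("LASSO fit failed: ", conditionMessage(e),
                             call. = FALSE))
  lam <- cv[[params$lasso_rule]]
  cf <- stats::coef(cv, s = lam)
  # one coefficient vector per class; drop the intercept row
  beta <- vapply(classes, function(k) as.matrix(cf[[k]])[-1L, 1L],
                 numeric(nrow(expr_subset)))
  rownames(beta) <- rownames(expr_subset)
  pos <- beta > 0
  n_pos <- rowSums(pos)
  multi <- rownames(beta)[n_pos > 1L]
  assign_of <- rep(NA_character_, nrow(beta))
  sel <- n_pos >= 1L
  assign_of[sel] <- classes[apply(beta[sel, , drop = FALSE], 1L, which.max)]
  out <- lapply(classes, function(k)
    rownames(beta)[!is.na(assign_of) & assign_of == k])
  names(out) <- classes
  attr(out, "lambda") <- lam
  attr(out, "multi_positive") <- multi
  out
}

#' Assemble an option-C template from four signature collections
#'
#' The four steps: (1) curated signatures and (2) hallmark sets are
#' ssGSEA-scored and kept when one class is significantly higher than each of
#' the others ([ttest_filter()]); (3) microenvironment cell-population (MCP)
#' marker sets are scored and filtered the same way; (4) the immune gene
#' panel is grouped into one candidate set per class by [lasso_group_genes()],
#' each group is scored as a set, and retained only if the t-test filter
#' assigns it to its own class. The surviving sets are unioned into one
#' gene_set-space template.
#'
#' @param curated,hallmarks,mcp gene-set collections (named lists).
#' @param immune_genes character vector of candidate immune genes.
#' @param expr genes x samples reference expression matrix.
#' @param labels class per sample.
#' @param params [derive_params()].
#' @param scoring [scoring_params()] used for all ssGSEA steps.
#' @return list with `template` (the union), `sets` (member genes for every
#'   template set, including the LASSO-derived immune groups), and `report`
#'   (per-step, per-class counts plus the provenance step of every set).
#' @export
assemble_option_c <- function(curated, hallmarks, mcp, immune_genes,
                              expr, labels, params = derive_params(),
                              scoring = scoring_params()) {
  stopifnot(length(curated) > 0, length(hallmarks) > 0, length(mcp) > 0,
            length(immune_genes) > 0)
  labels <- align_labels(labels, colnames(expr))
  step_tpl <- list()
  collections <- list(curated = curated, hallmarks = hallmarks, mcp = mcp)
  for (nm in names(collections)) {
    sc <- ssgsea_score(expr, collections[[nm]], scoring)
    step_tpl[[nm]] <- ttest_filter(sc, labels, params,
                                   allow_empty_classes = TRUE)
  }
  immune_present <- intersect(immune_genes, rownames(expr))
  if (length(immune_present) < 2L)
    stop("fewer than 2 immune panel genes present in the matrix",
         call. = FALSE)
  groups <- lasso_group_genes(expr[immune_present, , drop = FALSE], labels,
                              params)
  groups <- groups[lengths(groups) > 0L]
  immune_sets <- list()
  immune_kept <- character(0)
  if (length(groups)) {
    names(groups) <- paste0("IMMUNE_", names(groups))
    sc <- ssgsea_score(expr, groups, scoring)
    imm_tpl <- ttest_filter(sc, labels, params, allow_empty_classes = TRUE)
    # keep a group only when the filter assigns it to its own class
    for (k in imm_tpl$classes) {
      own <- intersect(imm_tpl$features_by_class[[k]], paste0("IMMUNE_", k))
      immune_kept <- c(immune_kept, own)
    }
    immune_sets <- groups[immune_kept]
  }
  classes <- sort(unique(as.character(labels)))
  fbc <- lapply(classes, function(k) unique(c(
    step_tpl$curated$features_by_class[[k]],
    step_tpl$hallmarks$features_by_class[[k]],
    step_tpl$mcp$features_by_class[[k]],
    intersect(immune_kept, paste0("IMMUNE_", k)))))
  names(fbc) <- classes
  empty <- classes[lengths(fbc) == 0L]
  if (length(empty))
    stop("no sets survived for class(es): ", paste(empty, collapse = ", "),
         call. = FALSE)
  template <- subtype_template(fbc, "gene_set")
  members <- c(collections$curated, collections$hallmarks, collections$mcp,
               immune_sets)
  all_sets <- unlist(fbc, use.names = FALSE)
  attr(template, "sets") <- members[all_sets]
  step_of <- c(
    setNames(rep("curated", length(unlist(step_tpl$curated$features_by_class))),
             unlist(step_tpl$curated$features_by_class)),
    setNames(rep("hallmarks", length(unlist(step_tpl$hallmarks$features_by_class))),
             unlist(step_tpl$hallmarks$features_by_class)),
    setNames(rep("mcp", length(unlist(step_tpl$mcp$features_by_class))),
             unlist(step_tpl$mcp$features_by_class)),
    setNames(rep("immune_lasso", length(immune_kept)), immune_kept))
  report <- list(
    counts_by_step = vapply(c("curated", "hallmarks", "mcp", "immune_lasso"),
                            function(s) sum(step_of == s), 0L),
    counts_by_class = lengths(fbc),
    step_of = step_of[all_sets],
    lasso_lambda = attr(groups, "lambda"))
  list(template = template, sets = attr(template, "sets"), report = report)
}

#' Build an option-A template by ortholog conversion
#'
#' Thin wrapper over [translate_template()]: converts an existing gene-space
#' template (e.g. the 529-gene human CMS marker template) to the target
#' species, reporting dropouts (sources without an ortholog) and expansions
#' (sources with several), which typically leave the translated template a
#' slightly different size.
#'
#' @param human_template gene-space [subtype_template()].
#' @param map [ortholog_map()].
#' @return as [translate_template()].
#' @export
build_option_a <- function(human_template, map)
  translate_template(human_template, map)

#' Reverse-translation meta-signature check
#'
#' For each called class, takes the (up to) `meta_top_n` most discriminatory
#' genes -- linear fold change above `fc_threshold` (class vs rest, computed
#' as 2^(difference of log2 class means)) with Welch p below `meta_p`,
#' ranked by fold change -- scores every sample by the median expression of
#' that gene list, and returns the class-by-class matrix of median scores.
#' A clean gene-level signal shows as a diagonal-dominant matrix; classes
#' with no qualifying genes yield an NA row and are listed in the `flagged`
#' attribute.
#'
#' @param expr genes x samples log2-scale expression matrix.
#' @param calls classification data.frame (columns `sample`,
#'   `predicted_class`) or a named label vector; `"unclassified"` samples are
#'   ignored.
#' @param params [derive_params()].
#' @return matrix, signature class x sample class, of median meta-signature
#'   scores; attributes `signatures` (gene lists) and `flagged`.
#' @export
meta_signature_check <- function(expr, calls, params = derive_params()) {
  validate_expression_matrix(expr)
  if (is.data.frame(calls))
    calls <- setNames(calls$predicted_class, calls$sample)
  calls <- calls[names(calls) %in% colnames(expr)]
  calls <- calls[calls != "unclassified"]
  classes <- sort(unique(as.character(calls)))
  if (length(classes) < 2L)
    stop("need calls from at least 2 classes", call. = FALSE)
  expr <- expr[, names(calls), drop = FALSE]
  sigs <- list()
  flagged <- character(0)
  for (k in classes) {
    ink <- calls == k
    fc <- 2^(rowMeans(expr[, ink, drop = FALSE]) -
               rowMeans(expr[, !ink, drop = FALSE]))
    cand <- which(fc > params$fc_threshold)
    if (length(cand)) {
      pv <- vapply(cand, function(g)
        stats::t.test(expr[g, ink], expr[g, !ink])$p.value, 0)
      cand <- cand[pv < params$meta_p]
    }
    if (length(cand) == 0L) {
      sigs[[k]] <- character(0)
      flagged <- c(flagged, k)
    } else {
      ord <- cand[order(fc[cand], decreasing = TRUE)]
      sigs[[k]] <- rownames(expr)[utils::head(ord, params$meta_top_n)]
    }
  }
  out <- matrix(NA_real_, length(classes), length(classes),
                dimnames = list(signature = classes, cohort = classes))
  for (k in classes) {
    if (length(sigs[[k]]) == 0L) next
    sample_score <- apply(expr[sigs[[k]], , drop = FALSE], 2L, stats::median)
    for (j in classes)
      out[k, j] <- stats::median(sample_score[calls == j])
  }
  attr(out, "signatures") <- sigs
  attr(out, "flagged") <- flagged
  out
}

#' Cross-cohort concordance of class mean-score profiles
#'
#' Pearson correlation, per class, between two cohorts' mean ssGSEA score
#' vectors over a shared set universe -- the check that a mouse cohort's
#' class-level pathway profile mirrors the human one.
#'
#' @param scores_a,scores_b sets x classes matrices with matching class
#'   columns; row universes are intersected (at least 3 shared sets).
#' @return named numeric vector, Pearson r per class.
#' @export
cross_cohort_concordance <- function(scores_a, scores_b) {
  shared <- intersect(rownames(scores_a), rownames(scores_b))
  if (length(shared) < 3L)
    stop("fewer than 3 shared sets between cohorts", call. = FALSE)
  if (!identical(colnames(scores_a), colnames(scores_b)))
    stop("class labels differ between cohorts", call. = FALSE)
  vapply(colnames(scores_a), function(k)
    stats::cor(scores_a[shared, k], scores_b[shared, k], method = "pearson"),
    0)
}
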