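## ---------------------------------------------------------------------------
## Synthetic dual-species cohorts with planted subtype structure.
##
## Log-scale expression is drawn as Gaussian noise around gene-level
## baselines, with each class's planted gene sets shifted upward by delta in
## that class's samples. A Gaussian marginal (rather than negative-binomial
## counts) is deliberate: the classifier consumes normalised data and its
## pathway-level scoring is rank-based, so the marginal family is immaterial
## to what the simulation exercises. A paired second-species gene namespace
## with dropouts and one-to-many expansions emulates the ortholog map.
## ---------------------------------------------------------------------------

#' Simulation parameters
#'
#' @param n_classes number of subtype classes (default 4, labelled CMS1..).
#' @param n_per_class labelled samples per class.
#' @param n_genes total genes.
#' @param sets_per_class planted gene sets per class (disjoint across sets).
#' @param genes_per_set genes per planted set.
#' @param delta class effect size, log2-expression units, added to a class's
#'   planted genes in its own samples.
#' @param sigma noise SD in log2 units.
#' @param frac_null fraction (of the labelled cohort size) of additional
#'   signal-free samples with truth label `"unclassified"`.
#' @param ortholog_dropout probability a gene has no second-species
#'   counterpart.
#' @param ortholog_expand probability a gene has two counterparts.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_classes = 4L, n_per_class = 25L, n_genes = 2000L,
                       sets_per_class = 5L, genes_per_set = 20L,
                       delta = 1.5, sigma = 1, frac_null = 0,
                       ortholog_dropout = 0.05, ortholog_expand = 0.05,
                       seed = 1L) {
  stopifnot(delta >= 0, sigma > 0,
            ortholog_dropout >= 0, ortholog_dropout <= 1,
            ortholog_expand >= 0, ortholog_expand <= 1,
            frac_null >= 0, frac_null <= 1,
            n_classes >= 2L, n_per_class >= 1L, n_genes >= 1L,
            sets_per_class >= 1L, genes_per_set >= 1L)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a labelled cohort with planted subtype structure
#'
#' Baseline expression of gene g in every sample is Normal(mu_g, sigma) with
#' mu_g ~ Uniform(4, 10); each class's planted sets are shifted by +delta in
#' that class's samples. Signal-free samples (if `frac_null > 0`) receive no
#' shift and carry the truth label `"unclassified"`. The ortholog map assigns
#' each human-style symbol a mouse-style counterpart, drops one with
#' probability `ortholog_dropout`, and doubles one with probability
#' `ortholog_expand`.
#'
#' @param params [sim_params()].
#' @return list with `expr` (genes x samples matrix), `labels` (named truth
#'   vector incl. `"unclassified"` nulls), `sets` (planted collection, class
#'   truth in attribute `class_of`), `map` ([ortholog_map()],
#'   human -> mouse), and `truth` (record of all planted structure).
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  need <- p$n_classes * p$sets_per_class * p$genes_per_set
  if (need > p$n_genes)
    stop("planted sets need ", need, " genes but n_genes = ", p$n_genes,
         call. = FALSE)
  with_local_seed(p$seed, {
    genes <- sprintf("GENE%05d", seq_len(p$n_genes))
    classes <- paste0("CMS", seq_len(p$n_classes))
    n_sig <- p$n_classes * p$n_per_class
    n_null <- round(p$frac_null * n_sig)
    samples <- sprintf("S%04d", seq_len(n_sig + n_null))
    labels <- c(rep(classes, each = p$n_per_class),
                rep("unclassified", n_null))
    names(labels) <- samples

    mu <- stats::runif(p$n_genes, 4, 10)
    expr <- matrix(stats::rnorm(p$n_genes * length(samples), mean = mu,
                                sd = p$sigma),
                   nrow = p$n_genes, ncol = length(samples),
                   dimnames = list(genes, samples))

    # planted sets: disjoint consecutive gene blocks, class by class
    sets <- list()
    class_of <- character(0)
    gi <- 0L
    for (k in seq_along(classes)) {
      for (s in seq_len(p$sets_per_class)) {
        members <- genes[gi + seq_len(p$genes_per_set)]
        gi <- gi + p$genes_per_set
        nm <- sprintf("SET_%s_%02d", classes[k], s)
        sets[[nm]] <- members
        class_of[nm] <- classes[k]
        expr[members, labels == classes[k]] <-
          expr[members, labels == classes[k]] + p$delta
      }
    }
    attr(sets, "class_of") <- class_of

    # second-species namespace
    src <- character(0); tgt <- character(0)
    mouse_name <- function(g) paste0("m", tolower(g))
    for (g in genes) {
      u <- stats::runif(1)
      if (u < p$ortholog_dropout) next
      src <- c(src, g); tgt <- c(tgt, mouse_name(g))
      if (u < p$ortholog_dropout + p$ortholog_expand) {
        src <- c(src, g); tgt <- c(tgt, paste0(mouse_name(g), "b"))
      }
    }
    map <- ortholog_map(src, tgt, direction = "human->mouse")

    list(expr = expr, labels = labels, sets = sets, map = map,
         truth = list(params = p, classes = classes, class_of_set = class_of,
                      n_signal_samples = n_sig, n_null_samples = n_null))
  })
}

#' Simulate a pure-noise collection of gene sets
#'
#' Random sets drawn from genes outside any planted block, for testing that
#' derivation filters select nothing from noise.
#'
#' @param cohort output of [simulate_cohort()].
#' @param n_sets number of noise sets.
#' @param genes_per_set members per set.
#' @param seed RNG seed.
#' @return named list of character vectors.
#' @export
noise_sets <- function(cohort, n_sets = 20L, genes_per_set = 20L, seed = 1L) {
  planted <- unique(unlist(cohort$sets, use.names = FALSE))
  pool <- setdiff(rownames(cohort$expr), planted)
  if (length(pool) < genes_per_set)
    stop("not enough non-planted genes for noise sets", call. = FALSE)
  with_local_seed(seed, {
    out <- lapply(seq_len(n_sets), function(i) sample(pool, genes_per_set))
    names(out) <- sprintf("NOISE_%02d", seq_len(n_sets))
    out
  })
}

#' Agreement between two classification runs
#'
#' Fraction of samples assigned the same class among those classified
#' (non-`"unclassified"`) by both runs; swapped and unclassified counts are
#' reported alongside. With zero co-classified samples the fraction is
#' undefined (`NA`) and the result is flagged.
#'
#' @param calls_a,calls_b classification data.frames over the same samples
#'   (columns `sample`, `predicted_class`).
#' @return list with `fraction`, `n_co_classified`, `n_agree`, `n_disagree`,
#'   `n_unclassified_either`, `flagged`.
#' @export
concordance <- function(calls_a, calls_b) {
  a <- setNames(calls_a$predicted_class, calls_a$sample)
  b <- setNames(calls_b$predicted_class, calls_b$sample)
  if (!setequal(names(a), names(b)))
    stop("calls cover different sample universes", call. = FALSE)
  b <- b[names(a)]
  co <- a != "unclassified" & b != "unclassified"
  n_co <- sum(co)
  n_agree <- sum(a[co] == b[co])
  list(fraction = if (n_co == 0L) NA_real_ else n_agree / n_co,
       n_co_classified = n_co,
       n_agree = n_agree,
       n_disagree = n_co - n_agree,
       n_unclassified_either = sum(!co),
       flagged = n_co == 0L)
}
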