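test_that("z-scoring class means matches hand arithmetic and flags flat rows", {
  cm <- rbind(S1 = c(10, 0, 0, 0),
              S2 = c(5, 5, 0, 0),
              S3 = c(3, 3, 3, 3))
  colnames(cm) <- paste0("CMS", 1:4)
  z <- zscore_class_means(cm)
  expect_equal(unname(z["S1", ]), c(1.5, -0.5, -0.5, -0.5))
  # (5,5,0,0): mean 2.5, sample SD sqrt(25/3) -> z = +/- sqrt(3)/2
  expect_equal(unname(z["S2", ]), c(1, 1, -1, -1) * sqrt(3) / 2)
  expect_identical(attr(z, "degenerate"), "S3")
  expect_false("S3" %in% rownames(z))
  # rows sum to 0 with unit sample SD
  expect_equal(unname(rowSums(z)), rep(0, 2), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 2), tolerance = 1e-12)
})

test_that("the one-positive z rule assigns and discards correctly", {
  z <- rbind(A = c(1.5, -0.5, -0.5, -0.5),
             B = c(-0.5, 1.5, -0.5, -0.5),
             C = c(0.9, 0.9, -0.9, -0.9),   # two positives -> discarded
             D = c(-0.5, -0.5, 1.5, -0.5),
             E = c(-0.2, -0.6, -0.7, 1.5))
  colnames(z) <- paste0("CMS", 1:4)
  tpl <- select_class_specific_sets(z)
  expect_equal(tpl$features_by_class,
               list(CMS1 = "A", CMS2 = "B", CMS3 = "D", CMS4 = "E"))
  expect_false("C" %in% unlist(tpl$features_by_class))
  z_empty <- z[c("A", "B", "D"), ]
  expect_error(select_class_specific_sets(z_empty), "CMS4")
})

test_that("z-score selection recovers planted set-class assignments", {
  sim <- simulate_cohort(sim_params(delta = 2, sigma = 1, n_per_class = 25,
                                    n_genes = 1200, sets_per_class = 10,
                                    genes_per_set = 10, seed = 77))
  scores <- ssgsea_score(sim$expr, sim$sets)
  z <- zscore_class_means(mean_scores_by_class(scores, sim$labels))
  tpl <- select_class_specific_sets(z)
  truth <- attr(sim$sets, "class_of")
  hits <- 0
  for (k in tpl$classes)
    hits <- hits + sum(truth[tpl$features_by_class[[k]]] == k)
  expect_gte(hits / length(truth), 0.9)
})

test_that("pairwise t-test filtering keeps only one-class-high sets", {
  set.seed(5)
  n <- 8
  labels <- setNames(rep(paste0("CMS", 1:4), each = n),
                     sprintf("s%02d", 1:(4 * n)))
  base <- function(sd = 0.1) rnorm(4 * n, sd = sd)
  up_in <- function(k, amount = 2) {
    v <- base()
    v[labels == paste0("CMS", k)] <- v[labels == paste0("CMS", k)] + amount
    v
  }
  scores <- rbind(HI1 = up_in(1), HI3 = up_in(3),
                  FLAT = base(),
                  TWO = up_in(1) + up_in(2))  # high in both 1 and 2
  colnames(scores) <- names(labels)
  tpl <- ttest_filter(scores, labels, derive_params(),
                      allow_empty_classes = TRUE)
  expect_identical(tpl$features_by_class$CMS1, "HI1")
  expect_identical(tpl$features_by_class$CMS3, "HI3")
  expect_false("FLAT" %in% unlist(tpl$features_by_class))
  expect_false("TWO" %in% unlist(tpl$features_by_class))

  expect_error(ttest_filter(scores[, 1:9, drop = FALSE],
                            setNames(c(rep("CMS1", 8), "CMS2"), colnames(scores)[1:9]),
                            derive_params()), "fewer than 3")
})

test_that("LASSO grouping recovers planted class markers and drops constants", {
  sim <- simulate_cohort(sim_params(delta = 3, sigma = 0.5, n_per_class = 20,
                                    n_genes = 300, sets_per_class = 1,
                                    genes_per_set = 3, seed = 4))
  planted <- unlist(sim$sets, use.names = FALSE)
  cand <- c(planted, setdiff(rownames(sim$expr), planted)[1:28])
  groups <- lasso_group_genes(sim$expr[cand, ], sim$labels,
                              derive_params(lasso_seed = 3))
  truth <- attr(sim$sets, "class_of")
  hits <- 0
  for (k in names(groups)) {
    want <- sim$sets[[paste0("SET_", k, "_01")]]
    hits <- hits + length(intersect(groups[[k]], want))
  }
  expect_gte(hits / length(planted), 0.8)

  # constant gene excluded with a warning
  x <- sim$expr[cand[1:10], ]
  x["GENE00001", ] <- 5
  expect_warning(lasso_group_genes(x, sim$labels,
                                   derive_params(lasso_seed = 3)),
                 "constant")

  # folds exceeding class size is an error (a fold would miss a class)
  expect_error(lasso_group_genes(sim$expr[cand, , drop = FALSE],
                                 sim$labels,
                                 derive_params(lasso_folds = 40)),
               "fold")
})

test_that("LASSO on pure noise selects (almost) nothing at lambda.1se", {
  sim <- simulate_cohort(sim_params(delta = 0, sigma = 1, n_per_class = 20,
                                    n_genes = 300, sets_per_class = 1,
                                    genes_per_set = 2, seed = 8))
  cand <- rownames(sim$expr)[1:60]
  groups <- lasso_group_genes(sim$expr[cand, ], sim$labels,
                              derive_params(lasso_seed = 12))
  expect_lte(length(unlist(groups)) / length(cand), 0.05)
})

test_that("option-C assembly recovers planted sets with clean bookkeeping", {
  sim <- simulate_cohort(sim_params(delta = 2, sigma = 1, n_per_class = 20,
                                    n_genes = 1200, sets_per_class = 9,
                                    genes_per_set = 10, seed = 13))
  curated <- sim$sets[grepl("_0[1-3]$", names(sim$sets))]
  hallmarks <- sim$sets[grepl("_0[4-6]$", names(sim$sets))]
  mcp <- sim$sets[grepl("_0[7-8]$", names(sim$sets))]
  immune <- unlist(lapply(sim$sets[grepl("_09$", names(sim$sets))], head, 5),
                   use.names = FALSE)
  res <- assemble_option_c(curated, hallmarks, mcp, immune,
                           sim$expr, sim$labels,
                           derive_params(lasso_seed = 2))
  truth <- attr(sim$sets, "class_of")
  # every recovered curated/hallmark/mcp set belongs to its planted class
  for (k in res$template$classes) {
    feats <- res$template$features_by_class[[k]]
    named_sets <- feats[!startsWith(feats, "IMMUNE_")]
    expect_true(all(truth[named_sets] == k))
  }
  # step counts sum to template size; classes disjoint by construction
  expect_equal(sum(res$report$counts_by_step),
               length(unlist(res$template$features_by_class)))
  expect_equal(sum(res$report$counts_by_class),
               length(unlist(res$template$features_by_class)))
  expect_setequal(names(res$report$step_of),
                  unlist(res$template$features_by_class))
  # every template set has member genes available for scoring
  expect_true(all(unlist(res$template$features_by_class) %in%
                    names(res$sets)))

  # all-noise collections leave classes empty -> deterministic error
  noise <- noise_sets(sim, n_sets = 9, genes_per_set = 10, seed = 3)
  expect_error(
    assemble_option_c(noise[1:3], noise[4:6], noise[7:9],
                      unlist(noise[1:2], use.names = FALSE)[1:10],
                      sim$expr, sim$labels, derive_params(lasso_seed = 2)),
    "no sets survived")
})

test_that("option A delegates to template translation with full reporting", {
  tpl <- subtype_template(list(CMS1 = c("A", "B"), CMS2 = c("C", "D")), "gene")
  m <- ortholog_map(c("A", "A", "B", "C"), c("a1", "a2", "b", "c"))
  res <- build_option_a(tpl, m)
  expect_equal(lengths(res$template$features_by_class),
               c(CMS1 = 3L, CMS2 = 1L))
  expect_identical(res$reports$CMS2$dropped_symbols, "D")
  expect_equal(res$reports$CMS1$n_expanded, 1L)
})

test_that("meta-signatures are diagonal-dominant for planted 8-fold markers", {
  sim <- simulate_cohort(sim_params(delta = 3, sigma = 1, n_per_class = 15,
                                    n_genes = 400, sets_per_class = 2,
                                    genes_per_set = 10, seed = 19))
  calls <- setNames(sim$labels, names(sim$labels))
  ms <- meta_signature_check(sim$expr, calls)
  expect_equal(unname(apply(ms, 1, which.max)), seq_len(nrow(ms)))
  expect_length(attr(ms, "flagged"), 0)
  sigs <- attr(ms, "signatures")
  expect_true(all(lengths(sigs) <= 20))

  # no qualifying genes -> flagged NA rows, no error
  null_sim <- simulate_cohort(sim_params(delta = 0, n_per_class = 10,
                                         n_genes = 100, sets_per_class = 1,
                                         genes_per_set = 2, seed = 20))
  ms0 <- meta_signature_check(null_sim$expr, null_sim$labels)
  expect_setequal(attr(ms0, "flagged"), paste0("CMS", 1:4))
  expect_true(all(is.na(ms0)))
})

test_that("cross-cohort concordance is per-class Pearson correlation", {
  a <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("S", 1:5), paste0("CMS", 1:4)))
  expect_equal(unname(cross_cohort_concordance(a, a)), rep(1, 4))
  expect_equal(unname(cross_cohort_concordance(a, -a)), rep(-1, 4))
  b <- matrix(c(1, 2, 3, 1, 2, 4), 3, 2,
              dimnames = list(paste0("S", 1:3), c("CMS1", "CMS2")))
  r <- cross_cohort_concordance(b, b[, c(1, 2)])
  expect_equal(unname(r), c(1, 1))
  x <- cbind(CMS1 = c(1, 2, 3)); rownames(x) <- paste0("S", 1:3)
  y <- cbind(CMS1 = c(1, 2, 4)); rownames(y) <- paste0("S", 1:3)
  expect_equal(unname(cross_cohort_concordance(x, y)), 0.98198,
               tolerance = 1e-5)
  expect_error(cross_cohort_concordance(x[1:2, , drop = FALSE], y), "3 shared")
})
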