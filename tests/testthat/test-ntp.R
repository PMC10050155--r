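test_that("indicator matrices encode templates over the feature universe", {
  tpl <- two_class_template()
  ind <- build_indicator(tpl, paste0("f", 1:4))
  expect_equal(dim(ind), c(4L, 2L))
  expect_equal(unname(colSums(ind)), c(2, 2))
  expect_warning(ind3 <- build_indicator(tpl, c("f1", "f2", "f3")), "f4")
  expect_equal(dim(ind3), c(3L, 2L))
  expect_error(suppressWarnings(build_indicator(tpl, c("f1", "f2"))), "CMS2")
})

test_that("feature centering is idempotent, medians supported", {
  x <- matrix(c(2, 0), 1, 2, dimnames = list("f", c("a", "b")))
  expect_equal(unname(center_features(x)["f", ]), c(1, -1))
  y <- random_expression(10, 5, seed = 3)
  yc <- center_features(y)
  expect_equal(center_features(yc), yc)
  m <- matrix(c(0, 0, 3), 1, 3, dimnames = list("f", c("a", "b", "c")))
  expect_equal(unname(center_features(m, "feature_median")["f", ]), c(0, 0, 3))
  expect_error(center_features(y[, 1, drop = FALSE]), "2 samples")
})

test_that("cosine distance matches direct arithmetic", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 1, 0)), 1 - 3 / sqrt(28),
               tolerance = 1e-12)
  expect_equal(cosine_distance(c(1, 1), c(-1, -1)), 2)
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero vector")
})

test_that("BH adjustment matches hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 0)), "outside")
  expect_error(bh_adjust(c(1.2)), "outside")
})

test_that("the worked two-class example classifies with exact distances", {
  res <- ntp_classify(two_class_matrix(), two_class_template(),
                      ntp_params(n_perm = 2000, seed = 5, fdr_threshold = 0.5))
  expect_equal(res$predicted_class, c("CMS1", "CMS2"))
  expect_equal(res$d.CMS1, c(1 - 1 / sqrt(2), 1 + 1 / sqrt(2)),
               tolerance = 1e-12)
  expect_equal(res$d.CMS2, c(1 + 1 / sqrt(2), 1 - 1 / sqrt(2)),
               tolerance = 1e-12)
})

test_that("sampled permutation p converges to exhaustive enumeration", {
  B <- 2000
  # the worked example: exact p = 4/24 on the centered sample
  xc <- c(1, 1, -1, -1)
  ind <- c(1, 1, 0, 0)
  p_exact <- exact_perm_p(xc, ind)
  expect_equal(p_exact, 4 / 24)
  p_hat <- ntp_pvalue(xc, ind, n_perm = B, seed = 17)
  se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(p_hat - p_exact), 3 * se + 1 / (B + 1))

  # random 6-feature instances against full 720-permutation enumeration
  set.seed(23)
  for (i in 1:5) {
    x <- rnorm(6)
    ind6 <- c(1, 1, 1, 0, 0, 0)[sample(6)]
    p_exact <- exact_perm_p(x, ind6)
    p_hat <- ntp_pvalue(x, ind6, n_perm = B, seed = 40 + i)
    se <- sqrt(p_exact * (1 - p_exact) / B)
    expect_lt(abs(p_hat - p_exact), 3 * se + 1 / (B + 1))
  }
})

test_that("p-values are bounded and monotone in the observed distance", {
  x <- rnorm(12, sd = 1)
  ind <- rep(c(1, 0), each = 6)
  ds <- seq(0.2, 1.8, by = 0.2)
  ps <- vapply(ds, function(d)
    ntp_pvalue(x, ind, n_perm = 500, seed = 9, d_obs = d), 0)
  expect_true(all(ps >= 1 / 501 & ps <= 1))
  expect_true(all(diff(ps) >= 0))
})

test_that("calls and p-values are invariant to sample and feature order", {
  sim <- simulate_cohort(sim_params(n_per_class = 5, n_genes = 200,
                                    sets_per_class = 2, genes_per_set = 8,
                                    delta = 2, seed = 31))
  tpl <- planted_template(sim)
  scores <- ssgsea_score(sim$expr, sim$sets)
  res1 <- ntp_classify(scores, tpl, ntp_params(n_perm = 200, seed = 4))
  perm_s <- sample(ncol(scores))
  perm_f <- sample(nrow(scores))
  res2 <- ntp_classify(scores[perm_f, perm_s], tpl,
                       ntp_params(n_perm = 200, seed = 4))
  res2 <- res2[match(res1$sample, res2$sample), ]
  expect_equal(res1$predicted_class, res2$predicted_class)
  expect_equal(res1$p_value, res2$p_value)
  expect_equal(res1$d.CMS1, res2$d.CMS1)
})

test_that("distance ties and degenerate samples end up unclassified", {
  # sA equals the feature means -> centered to zero -> degenerate;
  # sB/sC center to (+1,-1,+1,-1)/(-1,+1,-1,+1), equidistant (d = 1) from
  # both class indicators -> ambiguous tie
  x <- cbind(sA = c(1, 1, 1, 1), sB = c(2, 0, 2, 0), sC = c(0, 2, 0, 2))
  rownames(x) <- paste0("f", 1:4)
  tpl <- two_class_template()
  res <- ntp_classify(x, tpl, ntp_params(n_perm = 100, seed = 2,
                                         fdr_threshold = 0.999))
  expect_equal(res$flag, c("degenerate", "ambiguous", "ambiguous"))
  expect_equal(res$predicted_class, rep("unclassified", 3))
  expect_true(all(is.na(unlist(res[res$sample == "sA",
                                   c("d.CMS1", "d.CMS2")]))))
  expect_equal(res$d.CMS1[2:3], c(1, 1))
})

test_that("an uncentered sample equal to a class indicator has distance 0", {
  ind <- c(1, 1, 0, 0)
  expect_equal(cosine_distance(ind, ind), 0)
})
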