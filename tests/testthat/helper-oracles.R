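# Independent oracles and tiny fixture builders shared across the suite.
# Everything here is deliberately naive (explicit loops, enumeration) so it
# stays independent of the package's vectorised code paths.

random_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n_genes * n_samples, mean = 6, sd = 2),
         nrow = n_genes,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

# naive per-position running-sum ssGSEA: one gene at a time, membership
# re-checked at every step
naive_ssgsea <- function(x, sets, alpha = 0.25, normalise = TRUE) {
  es <- matrix(NA_real_, length(sets), ncol(x),
               dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    ord <- rownames(x)[order(r, decreasing = TRUE)]
    r_ord <- sort(r, decreasing = TRUE)
    for (s in seq_along(sets)) {
      members <- intersect(sets[[s]], rownames(x))
      w_total <- 0
      for (g in seq_along(ord))
        if (ord[g] %in% members) w_total <- w_total + abs(r_ord[g])^alpha
      n_out <- nrow(x) - length(members)
      p_in <- 0; p_out <- 0; acc <- 0
      for (g in seq_along(ord)) {
        if (ord[g] %in% members) p_in <- p_in + abs(r_ord[g])^alpha / w_total
        else p_out <- p_out + 1 / n_out
        acc <- acc + (p_in - p_out)
      }
      es[s, j] <- acc
    }
  }
  if (normalise) es <- es / (max(es) - min(es))
  es
}

# all permutations of 1..n, as a list (n <= 7)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# exact enumeration p: fraction of permutations of x whose cosine distance to
# the indicator column is <= d_obs
exact_perm_p <- function(x, ind_col) {
  d_obs <- 1 - sum(x * ind_col) / (sqrt(sum(x^2)) * sqrt(sum(ind_col^2)))
  ps <- all_perms(length(x))
  hits <- 0L
  for (p in ps) {
    xp <- x[p]
    d <- 1 - sum(xp * ind_col) / (sqrt(sum(xp^2)) * sqrt(sum(ind_col^2)))
    if (d <= d_obs + 1e-12) hits <- hits + 1L
  }
  hits / length(ps)
}

# hand enumeration of translated per-class template sizes: union of targets
# per class, then cross-class collisions removed everywhere
enumerate_translated_sizes <- function(features_by_class, src, tgt) {
  targets_of <- function(g) tgt[src == g]
  per_class <- lapply(features_by_class, function(genes) {
    out <- character(0)
    for (g in genes) out <- c(out, targets_of(g))
    unique(out)
  })
  everything <- unlist(per_class, use.names = FALSE)
  dup <- unique(everything[duplicated(everything)])
  vapply(per_class, function(v) length(setdiff(v, dup)), 0L)
}

# tiny 2-class fixture used across NTP tests
two_class_matrix <- function() {
  matrix(c(2, 2, 0, 0,
           0, 0, 2, 2), nrow = 4,
         dimnames = list(paste0("f", 1:4), c("s1", "s2")))
}

two_class_template <- function()
  subtype_template(list(CMS1 = c("f1", "f2"), CMS2 = c("f3", "f4")), "gene")

# planted cohort + its truth-derived gene_set template
planted_template <- function(sim) {
  co <- attr(sim$sets, "class_of")
  tpl <- subtype_template(split(names(co), co), "gene_set")
  attr(tpl, "sets") <- sim$sets
  tpl
}
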