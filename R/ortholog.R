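## ---------------------------------------------------------------------------
## Ortholog translation of gene lists, templates and matrices.
##
## Symbol mapping between species is rarely one-to-one: a human gene may have
## no recognised mouse ortholog (dropout) or several (expansion). Gene lists
## keep ALL targets of an expanded source -- a translated template may grow --
## while unmapped sources are dropped and reported. No alias or synonym
## resolution is attempted: the supplied map is authoritative.
## ---------------------------------------------------------------------------

#' Translate an ordered gene list through an ortholog map
#'
#' @param genes character vector of source-species symbols (non-empty).
#' @param map [ortholog_map()] object.
#' @return list with `genes` (ordered union of all targets of mappable
#'   inputs, de-duplicated, input order preserved) and `report`, a list with
#'   `n_input`, `n_mapped` (distinct sources with at least one target),
#'   `n_dropped`, `dropped_symbols` and `n_expanded` (sources with more than
#'   one target).
#' @export
map_genes <- function(genes, map) {
  stopifnot(inherits(map, "ortholog_map"))
  if (length(genes) == 0L) stop("empty input gene list", call. = FALSE)
  genes <- as.character(genes)
  tgt_by_src <- split(map$target, map$source)
  hits <- tgt_by_src[genes]
  mapped <- !vapply(hits, is.null, TRUE)
  out <- unique(unlist(hits[mapped], use.names = FALSE))
  report <- list(n_input = length(genes),
                 n_mapped = sum(mapped),
                 n_dropped = sum(!mapped),
                 dropped_symbols = genes[!mapped],
                 n_expanded = sum(vapply(hits[mapped], length, 1L) > 1L))
  list(genes = out, report = report)
}

#' Translate a gene-space subtype template between species
#'
#' Each class's marker list is translated independently with [map_genes()].
#' If a target symbol lands in more than one class (two different source
#' markers converging on one ortholog), it is removed from every class and
#' logged: a marker shared by two class templates is uninformative for
#' nearest-template prediction.
#'
#' @param template gene-space [subtype_template()].
#' @param map [ortholog_map()].
#' @return list with `template` (translated), `reports` (per-class
#'   [map_genes()] reports) and `conflicts` (symbols removed for landing in
#'   multiple classes).
#' @export
translate_template <- function(template, map) {
  stopifnot(inherits(template, "subtype_template"))
  if (template$feature_space != "gene")
    stop("translate_template requires a gene-space template", call. = FALSE)
  trans <- lapply(template$features_by_class, map_genes, map = map)
  lists <- lapply(trans, `[[`, "genes")
  reports <- lapply(trans, `[[`, "report")
  all_tgt <- unlist(lists, use.names = FALSE)
  conflicts <- unique(all_tgt[duplicated(all_tgt)])
  if (length(conflicts))
    lists <- lapply(lists, setdiff, y = conflicts)
  empty <- names(lists)[lengths(lists) == 0L]
  if (length(empty))
    stop("class(es) left empty after translation: ",
         paste(empty, collapse = ", "), call. = FALSE)
  list(template = subtype_template(lists, "gene"),
       reports = reports,
       conflicts = conflicts)
}

#' Re-key an expression matrix to the target species' symbols
#'
#' Rows are re-labelled through the map; a source row with several targets is
#' replicated under each, several source rows converging on one target are
#' collapsed by `collapse`. Unmapped rows are dropped and counted.
#'
#' @param x expression matrix (source-species gene symbols in rows).
#' @param map [ortholog_map()].
#' @param collapse `"max_variance"` (keep the most variable source row, the
#'   most informative one; default), `"mean"` (element-wise mean) or
#'   `"first"` (first source row in matrix order).
#' @return matrix re-keyed to target symbols, with attribute `n_unmapped`.
#' @export
translate_matrix <- function(x, map,
                             collapse = c("max_variance", "mean", "first")) {
  collapse <- match.arg(collapse)
  validate_expression_matrix(x)
  stopifnot(inherits(map, "ortholog_map"))
  pairs <- map[map$source %in% rownames(x), , drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("no matrix rows are mappable through the supplied ortholog map",
         call. = FALSE)
  n_unmapped <- sum(!rownames(x) %in% map$source)
  rows_by_target <- split(pairs$source, pairs$target)
  out <- matrix(NA_real_, nrow = length(rows_by_target), ncol = ncol(x),
                dimnames = list(names(rows_by_target), colnames(x)))
  for (i in seq_along(rows_by_target)) {
    src <- rows_by_target[[i]]
    if (length(src) == 1L) {
      out[i, ] <- x[src, ]
    } else {
      sub <- x[src, , drop = FALSE]
      out[i, ] <- switch(collapse,
        mean = colMeans(sub),
        first = sub[which.min(match(src, rownames(x))), ],
        max_variance = sub[which.max(apply(sub, 1L, stats::var)), ])
    }
  }
  attr(out, "n_unmapped") <- n_unmapped
  out
}
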