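#' @keywords internal
"_PACKAGE"

## ---------------------------------------------------------------------------
## Domain containers
##
## An expression matrix is a plain numeric matrix, features (genes or gene
## sets) in rows, samples in columns, with unique dimnames and finite values.
## Gene-set collections are named lists of character vectors. Feature
## identifiers are opaque case-sensitive strings throughout: human upper-case
## vs mouse title-case conventions are the business of the ortholog map, never
## of a parser, because silent case-folding manufactures false ortholog hits.
## ---------------------------------------------------------------------------

#' Validate (and return) an expression matrix
#'
#' Checks the invariants every function in the package relies on: a numeric
#' matrix with at least one row and one column, unique non-empty row and
#' column names, and all values finite.
#'
#' @param x numeric matrix, features in rows, samples in columns.
#' @param what label used in error messages.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop(what, " must have at least 1 feature and 1 sample", call. = FALSE)
  rn <- rownames(x); cn <- colnames(x)
  if (is.null(rn) || is.null(cn) || any(!nzchar(rn)) || any(!nzchar(cn)))
    stop(what, " must have non-empty row and column names", call. = FALSE)
  if (anyDuplicated(rn))
    stop(what, ": duplicate feature identifier(s): ",
         paste(unique(rn[duplicated(rn)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(cn))
    stop(what, ": duplicate sample identifier(s): ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "), call. = FALSE)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(what, ": non-finite value at feature '", rn[bad[1L]],
         "', sample '", cn[bad[2L]], "'", call. = FALSE)
  }
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' Expected layout: first column feature identifiers, header row sample
#' identifiers, genes in rows and samples in columns. Values must be numeric
#' and finite; duplicate feature rows and missing cells are rejected rather
#' than silently resolved or imputed.
#'
#' Input is assumed already normalised (e.g. vst or quantile normalised,
#' log scale); a warning is emitted if the maximum value exceeds 50, which
#' usually means raw counts were supplied.
#'
#' @param path path to a TSV file.
#' @return numeric matrix (features x samples).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or malformed expression file: ", path, call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric value '", vals[bad[1L], bad[2L]], "' at feature '",
         ids[bad[1L]], "', sample '", colnames(vals)[bad[2L]], "'",
         call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(vals))
  validate_expression_matrix(num)
  if (max(num) > 50)
    warning("maximum value ", format(max(num)),
            " > 50; input looks like raw counts, not normalised log-scale ",
            "expression", call. = FALSE)
  num
}

#' Write an expression matrix as TSV
#'
#' @param x numeric matrix with dimnames.
#' @param path output path.
#' @param id_column header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "feature") {
  validate_expression_matrix(x)
  df <- data.frame(rownames(x), formatC(x, format = "g", digits = 12),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then members. Lines with fewer than three fields are an error (never
#' guessed at), duplicate set names are an error, duplicate members within a
#' set are collapsed keeping first occurrence.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors with a `descriptions` attribute
#'   (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields",
         call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  if (any(lengths(sets) == 0L))
    stop("gene set(s) with no members: ",
         paste(nm[lengths(sets) == 0L], collapse = ", "), call. = FALSE)
  desc <- vapply(fields, `[[`, "", 2L)
  names(desc) <- nm
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors; an optional `descriptions`
#'   attribute supplies the second GMT field (default `"na"`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ortholog map
#'
#' A TSV of (source symbol, target symbol) pairs, optionally with a header
#' row (detected when the first line is repeated nowhere and matches common
#' header words, or via `header`). Duplicated pairs are stored once; blank
#' symbols and one-column lines are errors. One source may map to many
#' targets and vice versa.
#'
#' @param path path to TSV.
#' @param direction free-text label, e.g. `"human->mouse"`.
#' @param header `NA` to auto-detect, otherwise logical.
#' @return object of class `ortholog_map`: data.frame with columns `source`,
#'   `target`, a `direction` attribute and a multiplicity summary available
#'   through [summary()].
#' @export
read_ortholog_map <- function(path, direction = "source->target",
                              header = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty ortholog map: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("ortholog map line ", which(lengths(fields) < 2L)[1L],
         " has fewer than 2 columns", call. = FALSE)
  if (is.na(header)) {
    h1 <- tolower(fields[[1L]][1L])
    header <- h1 %in% c("source", "from", "human", "gene", "symbol",
                        "human_symbol", "hgnc")
  }
  if (header) fields <- fields[-1L]
  src <- vapply(fields, `[[`, "", 1L)
  tgt <- vapply(fields, `[[`, "", 2L)
  ortholog_map(src, tgt, direction = direction)
}

#' Construct an ortholog map from symbol vectors
#'
#' @param source,target character vectors of equal length.
#' @param direction free-text direction label.
#' @return `ortholog_map` object.
#' @export
ortholog_map <- function(source, target, direction = "source->target") {
  stopifnot(length(source) == length(target))
  if (any(!nzchar(source)) || any(!nzchar(target)))
    stop("blank symbol in ortholog map", call. = FALSE)
  keep <- !duplicated(paste0(source, "\r", target))
  out <- data.frame(source = source[keep], target = target[keep],
                    stringsAsFactors = FALSE)
  attr(out, "direction") <- direction
  class(out) <- c("ortholog_map", "data.frame")
  out
}

#' @export
summary.ortholog_map <- function(object, ...) {
  st <- table(object$source)
  ts <- table(object$target)
  list(n_pairs = nrow(object),
       n_sources = length(st),
       n_targets = length(ts),
       n_one_to_many = sum(st > 1L),
       n_many_to_one = sum(ts > 1L),
       direction = attr(object, "direction"))
}

#' Write an ortholog map as two-column TSV
#'
#' @param map `ortholog_map` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(map[, c("source", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Subtype templates
## ---------------------------------------------------------------------------

#' Construct a subtype template
#'
#' A template maps each class (by default CMS1-CMS4) to its feature list;
#' features are genes (`feature_space = "gene"`, used by the gene-level
#' option A) or gene-set names (`"gene_set"`, options B and C). A feature may
#' belong to at most one class: a marker listed under two classes carries no
#' information for nearest-template prediction, so cross-class duplicates are
#' an error here (and are removed with a log entry by [translate_template()]).
#'
#' @param features_by_class named list, class -> character vector of features.
#' @param feature_space `"gene"` or `"gene_set"`.
#' @param allow_empty_classes internal: permit classes with zero features
#'   (used by derivation steps whose per-collection output is later unioned).
#' @return object of class `subtype_template`.
#' @export
subtype_template <- function(features_by_class, feature_space = c("gene", "gene_set"),
                             allow_empty_classes = FALSE) {
  feature_space <- match.arg(feature_space)
  if (!is.list(features_by_class) || is.null(names(features_by_class)) ||
      any(!nzchar(names(features_by_class))))
    stop("features_by_class must be a named list", call. = FALSE)
  features_by_class <- lapply(features_by_class, function(f) unique(as.character(f)))
  if (!allow_empty_classes && any(lengths(features_by_class) == 0L))
    stop("class(es) with zero features: ",
         paste(names(features_by_class)[lengths(features_by_class) == 0L],
               collapse = ", "), call. = FALSE)
  all_feat <- unlist(features_by_class, use.names = FALSE)
  if (anyDuplicated(all_feat))
    stop("feature(s) assigned to more than one class: ",
         paste(unique(all_feat[duplicated(all_feat)]), collapse = ", "),
         call. = FALSE)
  structure(list(classes = names(features_by_class),
                 features_by_class = features_by_class,
                 feature_space = feature_space),
            class = "subtype_template")
}

#' @export
print.subtype_template <- function(x, ...) {
  cat("subtype_template (", x$feature_space, " space)\n", sep = "")
  for (k in x$classes)
    cat("  ", k, ": ", length(x$features_by_class[[k]]), " features\n",
        sep = "")
  invisible(x)
}

#' Read a subtype template from a class-prefixed GMT file
#'
#' Each GMT set name must be `CLASS|name` (e.g. `CMS4|TGFB_SIGNALING`); for
#' gene-space templates a single set per class named `CLASS|genes` (or just
#' `CLASS`) holds the class's marker genes.
#'
#' @param path GMT path.
#' @param feature_space `"gene"` or `"gene_set"`.
#' @return `subtype_template`. For `"gene_set"` templates the member genes of
#'   each set are attached as attribute `sets` (a gene-set collection).
#' @export
read_template <- function(path, feature_space = c("gene", "gene_set")) {
  feature_space <- match.arg(feature_space)
  gmt <- read_gmt(path)
  nm <- names(gmt)
  cls <- sub("\\|.*$", "", nm)
  if (feature_space == "gene") {
    fbc <- lapply(split(gmt, cls), function(s) unique(unlist(s, use.names = FALSE)))
    fbc <- fbc[unique(cls)]
    subtype_template(fbc, "gene")
  } else {
    setname <- sub("^[^|]*\\|", "", nm)
    if (any(setname == nm))
      stop("gene_set template requires 'CLASS|set_name' GMT names",
           call. = FALSE)
    fbc <- split(setname, cls)[unique(cls)]
    tpl <- subtype_template(fbc, "gene_set")
    members <- gmt
    names(members) <- setname
    attr(members, "descriptions") <- NULL
    attr(tpl, "sets") <- members
    tpl
  }
}

#' Write a subtype template as class-prefixed GMT
#'
#' @param template `subtype_template`.
#' @param path output path.
#' @param sets for gene_set templates, the collection supplying each set's
#'   member genes (defaults to the template's `sets` attribute).
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path, sets = attr(template, "sets")) {
  stopifnot(inherits(template, "subtype_template"))
  lines <- character(0)
  for (k in template$classes) {
    feats <- template$features_by_class[[k]]
    if (template$feature_space == "gene") {
      lines <- c(lines, paste(c(paste0(k, "|genes"), "gene-space template",
                                feats), collapse = "\t"))
    } else {
      for (s in feats) {
        members <- if (!is.null(sets) && s %in% names(sets)) sets[[s]] else s
        lines <- c(lines, paste(c(paste0(k, "|", s), "gene_set-space template",
                                  members), collapse = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Classification results
## ---------------------------------------------------------------------------

#' Write a classification result as TSV
#'
#' Columns: `sample`, `predicted_class`, one `d.<class>` column per class,
#' `p_value`, `FDR`. Distances are printed with 12 significant digits so a
#' written file re-reads to within 1e-9.
#'
#' @param result data.frame as returned by [ntp_classify()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(is.data.frame(result),
            all(c("sample", "predicted_class", "p_value", "FDR") %in%
                  colnames(result)))
  out <- result
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), "NA", formatC(v, format = "g", digits = 12)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a classification result written by [write_results()]
#'
#' @param path TSV path.
#' @return data.frame with the same columns.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  df$sample <- as.character(df$sample)
  df$predicted_class <- as.character(df$predicted_class)
  df
}
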