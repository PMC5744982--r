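# Delimited-text readers/writers for expression matrices, labels and fit
# reports. Samples-in-rows is the canonical orientation; genes-in-rows
# input (the microarray convention) is supported via `transpose`.

#' Read an expression matrix and sample labels from delimited text
#'
#' The matrix file must be TSV/CSV with an identifier header row and
#' identifier first column; the body must be fully numeric. The labels file
#' maps sample id to class (two columns `sample_id`, `label`, header
#' optional-free); exactly two distinct labels are allowed and are remapped
#' to `+1/-1`. Labels already coded `-1/1` or `0/1` keep their canonical
#' meaning; any other pair maps alphabetically (first label -> `+1`). The
#' mapping is returned and recorded by downstream report writers.
#'
#' @param path Path to the matrix file.
#' @param labels_path Path to the labels file.
#' @param transpose Set `TRUE` when the matrix is genes-in-rows.
#' @param sep Field separator (default tab).
#' @return A list: `x` (samples x features, dimnames set), `y` in
#'   `{-1, +1}`, `label_mapping` (named vector label -> code).
#' @export
read_expression_matrix <- function(path, labels_path, transpose = FALSE,
                                   sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(raw)
  if (!is.numeric(x)) {
    bad <- which(!vapply(raw, is.numeric, TRUE))[1L]
    stop(sprintf("matrix column '%s' is not numeric", names(raw)[bad]),
         call. = FALSE)
  }
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value in matrix at row '%s', column '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]), call. = FALSE)
  }
  if (transpose) x <- t(x)
  if (anyDuplicated(rownames(x))) {
    stop("duplicate sample identifiers in matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate feature identifiers in matrix", call. = FALSE)
  }
  lab <- utils::read.table(labels_path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2L) {
    stop("labels file needs two columns: sample_id, label", call. = FALSE)
  }
  if (identical(tolower(as.character(lab[1, 1])), "sample_id")) {
    lab <- lab[-1, , drop = FALSE]
  }
  ids <- as.character(lab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample identifiers in labels file", call. = FALSE)
  }
  missing <- setdiff(rownames(x), ids)
  if (length(missing)) {
    stop("samples without labels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cls <- as.character(lab[[2]])[match(rownames(x), ids)]
  lev <- sort(unique(cls))
  if (length(lev) != 2L) {
    stop(sprintf("expected exactly 2 classes, found %d (%s)", length(lev),
                 paste(lev, collapse = ", ")), call. = FALSE)
  }
  mapping <- if (setequal(lev, c("-1", "1"))) {
    c(`1` = 1, `-1` = -1)               # already canonically coded
  } else if (setequal(lev, c("0", "1"))) {
    c(`1` = 1, `0` = -1)
  } else {
    stats::setNames(c(1, -1), lev)
  }
  list(x = x, y = unname(mapping[cls]), label_mapping = mapping)
}

#' Write an expression matrix (and optional labels) as TSV
#'
#' Inverse of [read_expression_matrix()]: samples in rows, identifier
#' header and first column.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path for the matrix.
#' @param y Optional labels; written next to `path` with suffix
#'   `_labels.tsv` unless `labels_path` is given.
#' @param labels_path Optional explicit labels path.
#' @return Invisibly, the matrix path.
#' @export
write_expression_matrix <- function(x, path, y = NULL, labels_path = NULL) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(y)) {
    if (is.null(labels_path)) {
      labels_path <- sub("(\\.[a-zA-Z]+)?$", "_labels.tsv", path)
    }
    utils::write.table(
      data.frame(sample_id = rownames(x), label = y),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(path)
}

#' Write a fit report (weights table + run metadata)
#'
#' Writes `<prefix>_weights.tsv` (feature id, weight, prior variance where
#' available, selected flag; sorted by `|weight|` descending) and
#' `<prefix>_meta.json` (method, dimensions, iterations, convergence flag,
#' support size, and any extras such as the seed or label mapping), enough
#' to reproduce and audit the run.
#'
#' @param fit An `sbfit` object.
#' @param prefix Output path prefix.
#' @param extra Optional named list merged into the metadata JSON.
#' @return Invisibly, the two paths written.
#' @export
write_fit_report <- function(fit, prefix, extra = list()) {
  stopifnot(inherits(fit, "sbfit"))
  beta <- fit$coefficients
  tab <- data.frame(
    feature_id = fit$feature_names,
    weight = unname(beta),
    gamma = if (!is.null(fit$gamma)) unname(fit$gamma) else NA_real_,
    selected = seq_along(beta) %in% fit$support)
  tab <- tab[order(-abs(tab$weight), seq_len(nrow(tab))), ]
  wpath <- paste0(prefix, "_weights.tsv")
  mpath <- paste0(prefix, "_meta.json")
  utils::write.table(tab, wpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- c(list(method = fit$method, n_samples = fit$n,
                 n_features = fit$m, iterations = fit$iterations,
                 converged = fit$converged,
                 support_size = length(fit$support),
                 intercept = fit$intercept), extra)
  jsonlite::write_json(meta, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(weights = wpath, metadata = mpath))
}
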