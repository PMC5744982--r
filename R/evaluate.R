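# Evaluation protocol: stratified CV accuracy, selection error rates
# against simulation truth, feature ranking, the stability/accuracy score,
# and the optimal feature-set-size search.

# Stratified fold assignment: within each class, fold labels are dealt out
# in random order as evenly as possible. Returns an integer vector 1..k.
stratified_folds <- function(y, k) {
  stopifnot(k >= 2)
  if (min(table(y)) < k) {
    stop("each class needs at least `k` samples for stratified ", k,
         "-fold CV", call. = FALSE)
  }
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# Resolve a method name or function to fitter(x, y) -> sbfit.
resolve_method <- function(method) {
  if (is.function(method)) return(method)
  switch(match.arg(method, c("sblogit", "rlr", "sbl")),
         sblogit = function(x, y) sblogit(x, y, keep_data = FALSE),
         rlr = function(x, y) l1logit(x, y, keep_data = FALSE),
         sbl = function(x, y) rvmlogit(x, y, keep_data = FALSE))
}

#' Feature ranking from a fitted model
#'
#' Orders feature indices by decreasing `|coefficient|`; ties broken toward
#' the smaller index, so the ranking is deterministic and invariant to a
#' global sign flip.
#'
#' @param fit An `sbfit` object, or a numeric coefficient vector.
#' @return Integer vector of feature indices, best first.
#' @export
rank_features <- function(fit) {
  beta <- if (is.numeric(fit)) fit else stats::coef(fit)
  order(-abs(beta), seq_along(beta))
}

#' Selection error rates against the simulation truth
#'
#' False-negative rate = missed true-support features / true-support size;
#' false-positive rate = spurious selections / number of true-zero features
#' (`n_features - support size`). With these denominators
#' `fn * s` and `fp * (M - s)` are the integer miss and false-alarm counts.
#'
#' @param selected Integer vector of selected feature indices.
#' @param truth A `truth` list from [simulate_correlated_design()] (or a
#'   `sim_design`), or an integer vector of true-support indices.
#' @param n_features Total feature count `M` (taken from `truth$beta_true`
#'   when available).
#' @return A list with `fp_rate` and `fn_rate`.
#' @export
selection_metrics <- function(selected, truth, n_features = NULL) {
  if (inherits(truth, "sim_design")) truth <- truth$truth
  if (is.list(truth)) {
    if (is.null(n_features)) n_features <- length(truth$beta_true)
    truth <- truth$support
  }
  truth <- as.integer(truth)
  if (length(truth) == 0L) {
    stop("true support is empty; selection rates are undefined",
         call. = FALSE)
  }
  if (is.null(n_features)) {
    stop("`n_features` is required when `truth` is a plain index vector",
         call. = FALSE)
  }
  s <- length(truth)
  if (s >= n_features) {
    stop("true support must leave at least one null feature", call. = FALSE)
  }
  selected <- as.integer(selected)
  if (length(selected) && (min(selected) < 1L || max(selected) > n_features)) {
    stop("`selected` contains indices outside 1..n_features", call. = FALSE)
  }
  list(fp_rate = length(setdiff(selected, truth)) / (n_features - s),
       fn_rate = length(setdiff(truth, selected)) / s)
}

#' Pooled cross-validated classification accuracy
#'
#' Stratified k-fold CV following the embedded-selection protocol: per
#' fold, fit on the training portion, select features on that same
#' training portion, refit a restricted model on the selected features,
#' and predict the held-out samples. Returns the pooled accuracy over all
#' held-out samples.
#'
#' The per-fold selection is controlled by `q`:
#' * `q = "support"` (default): the fold model's own selected support
#'   (features with non-zero weights) — the restricted refit removes the
#'   residual small-weight features and is what keeps the protocol honest
#'   at small sample sizes;
#' * an integer: the top-`q` ranked features ([rank_features()]);
#' * `NULL`: no restriction, predict straight from the full fold fit.
#'
#' @param x,y Design matrix and binary labels.
#' @param method `"sblogit"`, `"rlr"`, `"sbl"`, or a function
#'   `function(x, y)` returning an `sbfit`.
#' @param folds Number of CV folds.
#' @param q Per-fold feature selection rule; see Details.
#' @param seed Optional seed for the fold assignment.
#' @param y_eval Optional reference labels to score the held-out
#'   predictions against (training always uses `y`). In simulations with
#'   label noise, passing the noiseless true class here measures recovery
#'   of the underlying class rather than agreement with the corrupted
#'   labels, whose Bayes rate is below 1.
#' @return Scalar accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(x, y, method = "sblogit", folds = 10L,
                        q = "support", seed = NULL, y_eval = NULL) {
  d <- validate_xy(x, y)
  x <- d$x; y <- d$y
  if (is.null(y_eval)) y_eval <- y
  else y_eval <- validate_xy(x, y_eval)$y
  fitter <- resolve_method(method)
  with_seed(seed, {
    fold <- stratified_folds(y, folds)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- fitter(x[tr, , drop = FALSE], y[tr])
      sel <- if (is.null(q)) {
        NULL
      } else if (identical(q, "support")) {
        if (length(fit$support)) fit$support else rank_features(fit)[1L]
      } else {
        rank_features(fit)[seq_len(min(q, ncol(x)))]
      }
      if (is.null(sel)) {
        pred <- predict(fit, x[!tr, , drop = FALSE], type = "class")
      } else {
        rfit <- fitter(x[tr, sel, drop = FALSE], y[tr])
        pred <- predict(rfit, x[!tr, sel, drop = FALSE], type = "class")
      }
      correct <- correct + sum(pred == y_eval[!tr])
    }
    correct / length(y)
  })
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Combined stability/accuracy score for a candidate feature-set size
#'
#' Scores a feature-set size by how stable the selected sets are across CV
#' folds *and* how well the restricted models predict: with
#' `S` = mean pairwise Jaccard similarity of the per-fold selected sets and
#' `A` = mean per-fold held-out accuracy, the score is the harmonic-style
#' combination `2*S*A / (S + A)` (0 when `S + A = 0`). This concrete
#' formula is this package's documented choice of accuracy-plus-stability
#' summary; pairs involving an empty union contribute 0 to `S`.
#'
#' @param per_fold_sets List of integer index vectors, one per fold.
#' @param per_fold_accuracy Numeric vector of per-fold accuracies.
#' @return Scalar score in `[0, 1]`.
#' @export
stability_score <- function(per_fold_sets, per_fold_accuracy) {
  stopifnot(length(per_fold_sets) == length(per_fold_accuracy),
            length(per_fold_sets) >= 1)
  k <- length(per_fold_sets)
  S <- if (k < 2) 1 else {
    pr <- utils::combn(k, 2)
    mean(apply(pr, 2, function(ij) {
      jaccard(per_fold_sets[[ij[1]]], per_fold_sets[[ij[2]]])
    }))
  }
  A <- mean(per_fold_accuracy)
  if (S + A == 0) 0 else 2 * S * A / (S + A)
}

#' Optimal feature-set-size search
#'
#' For each candidate size `q`: in every CV fold, fit on the training
#' portion, take the top-`q` ranked features (capped at the fold model's
#' non-zero count — a sparse fit cannot vouch for features it assigned
#' exactly zero weight), refit restricted to them and record the held-out
#' accuracy; score `q` by [stability_score()] of the per-fold sets and
#' accuracies. The optimal `q` maximises the score (ties toward the
#' smaller `q`). The reported optimal set is the most frequent
#' per-fold set at that `q`; if no set repeats, features are ranked by
#' selection frequency across folds (then by mean `|coefficient|`) and the
#' top `q` are taken.
#'
#' @inheritParams cv_accuracy
#' @param q_range Integer vector of candidate sizes (within `1..M`).
#' @return A list of class `q_selection`: `q` (optimal size), `selected`
#'   (optimal set, sorted), `score`, `score_table` (per-q scores),
#'   `per_fold_sets` and `per_fold_accuracy` at the optimum.
#' @export
select_q <- function(x, y, method = "sblogit", q_range = 1:10, folds = 10L,
                     seed = NULL) {
  d <- validate_xy(x, y)
  x <- d$x; y <- d$y
  M <- ncol(x)
  q_range <- sort(unique(as.integer(q_range)))
  stopifnot(all(q_range >= 1), all(q_range <= M))
  fitter <- resolve_method(method)
  with_seed(seed, {
    fold <- stratified_folds(y, folds)
    ranks <- vector("list", folds)
    nnz <- integer(folds)
    abs_beta <- matrix(0, folds, M)
    test_sets <- vector("list", folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- fitter(x[tr, , drop = FALSE], y[tr])
      ranks[[f]] <- rank_features(fit)
      nnz[f] <- sum(stats::coef(fit) != 0)
      abs_beta[f, ] <- abs(stats::coef(fit))
      test_sets[[f]] <- which(!tr)
    }
    sets_q <- acc_q <- vector("list", length(q_range))
    scores <- numeric(length(q_range))
    for (iq in seq_along(q_range)) {
      q <- q_range[iq]
      sets <- vector("list", folds)
      accs <- numeric(folds)
      for (f in seq_len(folds)) {
        tr <- fold != f
        # a fold model can rank no more features than it retained:
        # sets are capped at the fold's non-zero count, never padded
        top <- ranks[[f]][seq_len(max(1L, min(q, nnz[f])))]
        rfit <- fitter(x[tr, top, drop = FALSE], y[tr])
        pred <- predict(rfit, x[test_sets[[f]], top, drop = FALSE],
                        type = "class")
        sets[[f]] <- sort(top)
        accs[f] <- mean(pred == y[test_sets[[f]]])
      }
      sets_q[[iq]] <- sets
      acc_q[[iq]] <- accs
      scores[iq] <- stability_score(sets, accs)
    }
    best <- which.max(scores)    # ties -> smallest q (q_range sorted)
    q_opt <- q_range[best]
    sets <- sets_q[[best]]
    keys <- vapply(sets, paste, "", collapse = ",")
    tab <- table(keys)
    top_keys <- names(tab)[tab == max(tab)]
    if (max(tab) > 1 && length(top_keys) == 1L) {
      selected <- as.integer(strsplit(top_keys, ",")[[1]])
    } else {
      freq <- tabulate(unlist(sets), nbins = M)
      pool <- which(freq > 0)
      pool <- pool[order(-freq[pool], -colMeans(abs_beta)[pool], pool)]
      selected <- sort(pool[seq_len(min(q_opt, length(pool)))])
    }
    structure(list(q = q_opt, selected = sort(selected),
                   score = scores[best],
                   score_table = data.frame(q = q_range, score = scores),
                   per_fold_sets = sets, per_fold_accuracy = acc_q[[best]]),
              class = "q_selection")
  })
}

#' @export
print.q_selection <- function(x, ...) {
  cat("Optimal feature-set size search\n")
  cat(sprintf("  optimal q: %d (score %.3f)\n", x$q, x$score))
  cat("  selected features:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Benchmark methods over a simulation grid
#'
#' For every row of a [simulation_grid()]-style data frame, generates the
#' dataset, and for every method records the pooled CV accuracy plus the
#' FP/FN selection rates of the full-data fit against the simulation truth.
#' Per-setting means over replicates are returned alongside the raw
#' per-replicate table. A replicate/method combination that errors is
#' recorded as `NA` with a warning and excluded from the means.
#'
#' @param grid Data frame with columns `n_samples`, `n_features`,
#'   `sparsity`, `correlated_fraction`, `replicate`, `seed`.
#' @param methods Character vector from `c("sblogit", "rlr", "sbl")`.
#' @param folds CV folds for the accuracy estimate.
#' @param verbose Print one progress line per grid row.
#' @return A list with `raw` (per replicate) and `summary` (per setting,
#'   means over replicates) data frames.
#' @export
run_benchmark <- function(grid, methods = c("sblogit", "rlr", "sbl"),
                          folds = 10L, verbose = FALSE) {
  need <- c("n_samples", "n_features", "sparsity", "correlated_fraction",
            "replicate", "seed")
  stopifnot(all(need %in% names(grid)))
  rows <- list()
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    sim <- simulate_correlated_design(
      n_samples = g$n_samples, n_features = g$n_features,
      sparsity = g$sparsity, correlated_fraction = g$correlated_fraction,
      seed = g$seed)
    for (m in methods) {
      res <- tryCatch({
        fit <- suppressWarnings(resolve_method(m)(sim$x, sim$y))
        met <- selection_metrics(fit$support, sim$truth)
        acc <- suppressWarnings(
          cv_accuracy(sim$x, sim$y, method = m, folds = folds,
                      seed = g$seed + 1L))
        c(accuracy = acc, fp_rate = met$fp_rate, fn_rate = met$fn_rate)
      }, error = function(e) {
        warning(sprintf("replicate %d method %s failed: %s",
                        g$replicate, m, conditionMessage(e)), call. = FALSE)
        c(accuracy = NA_real_, fp_rate = NA_real_, fn_rate = NA_real_)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        n_samples = g$n_samples, n_features = g$n_features,
        sparsity = g$sparsity, correlated_fraction = g$correlated_fraction,
        replicate = g$replicate, method = m,
        accuracy = res[["accuracy"]], fp_rate = res[["fp_rate"]],
        fn_rate = res[["fn_rate"]])
    }
    if (verbose) {
      message(sprintf("grid row %d/%d done", r, nrow(grid)))
    }
  }
  raw <- do.call(rbind, rows)
  summary <- stats::aggregate(
    raw[, c("accuracy", "fp_rate", "fn_rate")],
    by = raw[, c("n_samples", "n_features", "sparsity",
                 "correlated_fraction", "method")],
    FUN = mean, na.rm = TRUE)
  summary <- summary[order(summary$correlated_fraction, summary$n_samples,
                           summary$n_features, summary$method), ]
  rownames(summary) <- NULL
  list(raw = raw, summary = summary)
}
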