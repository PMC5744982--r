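# Shared S3 methods for fitted classifiers (class "sbfit": the main
# reweighted-ridge model and both comparator baselines).

method_label <- function(object) {
  switch(object$method,
         sblogit = "sparse Bayesian logistic regression (reweighted ridge)",
         rlr = "l1-regularised logistic regression (ADMM)",
         sbl = "relevance-vector logistic regression (EM)",
         object$method)
}

#' @export
print.sbfit <- function(x, ...) {
  cat(method_label(x), "\n")
  cat(sprintf("  %d samples, %d features; %d selected (non-zero weights)\n",
              x$n, x$m, length(x$support)))
  cat(sprintf("  %d iterations, %s\n", x$iterations,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.sbfit <- function(object, ...) object$coefficients

#' Summarise a fitted sparse classifier
#'
#' @param object An `sbfit` object.
#' @param ... Unused.
#' @return A `summary.sbfit` list with the selected-feature table (weights
#'   sorted by magnitude) and fit diagnostics.
#' @export
summary.sbfit <- function(object, ...) {
  beta <- object$coefficients
  sel <- object$support
  tab <- data.frame(feature = object$feature_names[sel],
                    index = sel, weight = beta[sel],
                    row.names = NULL)
  tab <- tab[order(-abs(tab$weight)), ]
  rownames(tab) <- NULL
  structure(list(method = method_label(object), n = object$n, m = object$m,
                 support_size = length(sel), selected = tab,
                 iterations = object$iterations,
                 converged = object$converged,
                 intercept = object$intercept,
                 final_objective =
                   if (length(object$objective_trace))
                     utils::tail(object$objective_trace, 1) else NA_real_),
            class = "summary.sbfit")
}

#' @export
print.summary.sbfit <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  %d samples, %d features\n", x$n, x$m))
  cat(sprintf("  support size: %d; iterations: %d (%s)\n",
              x$support_size, x$iterations,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  if (!is.na(x$final_objective)) {
    cat(sprintf("  final joint objective (Laplace scale): %.4f\n",
                x$final_objective))
  }
  if (nrow(x$selected)) {
    cat("  selected features (by |weight|):\n")
    print(utils::head(x$selected, 20), digits = 4)
    if (nrow(x$selected) > 20) {
      cat("  ... and", nrow(x$selected) - 20, "more\n")
    }
  } else {
    cat("  no features selected\n")
  }
  invisible(x)
}

#' Predict class probabilities or labels
#'
#' Applies the logistic link to the fitted linear margins: probability
#' `sigmoid(x' beta + b0)`, label `+1` when the probability is `>= 0.5`,
#' else `-1`.
#'
#' @param object An `sbfit` object.
#' @param newdata Numeric matrix with `ncol` matching the training features.
#' @param type `"class"` (default), `"prob"`, or `"link"` (raw margin).
#' @param ... Unused.
#' @return Numeric vector of labels, probabilities, or margins.
#' @export
predict.sbfit <- function(object, newdata,
                          type = c("class", "prob", "link"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$m) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(newdata), object$m), call. = FALSE)
  }
  m <- drop(newdata %*% object$coefficients) + object$intercept
  switch(type,
         link = m,
         prob = sigmoid(m),
         class = ifelse(sigmoid(m) >= 0.5, 1, -1))
}

#' Residuals of a fitted sparse classifier
#'
#' @param object An `sbfit` fitted with `keep_data = TRUE`.
#' @param type `"deviance"` (signed square-root of twice the per-sample
#'   negative log-likelihood) or `"response"` (`y01 - fitted probability`).
#' @param ... Unused.
#' @export
residuals.sbfit <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  if (is.null(object$x)) {
    stop("fit was created with keep_data = FALSE; no residuals available",
         call. = FALSE)
  }
  m <- drop(object$x %*% object$coefficients) + object$intercept
  y <- object$y
  if (type == "response") {
    (y + 1) / 2 - sigmoid(m)
  } else {
    y * sqrt(2 * log1pexp(-y * m))
  }
}

#' Plot fitted feature weights
#'
#' Stem plot of the coefficient vector; selected (non-zero) features are
#' drawn filled.
#'
#' @param x An `sbfit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sbfit <- function(x, ...) {
  beta <- x$coefficients
  idx <- seq_along(beta)
  graphics::plot(idx, beta, type = "h", xlab = "feature index",
                 ylab = "weight", main = method_label(x), ...)
  graphics::points(idx, beta, pch = ifelse(idx %in% x$support, 19, 1),
                   cex = 0.6)
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}

#' Simulate labels from a fitted classifier
#'
#' Draws Bernoulli labels at the training design points from the fitted
#' class probabilities.
#'
#' @param object An `sbfit` fitted with `keep_data = TRUE`.
#' @param nsim Number of label vectors to draw.
#' @param seed Optional seed (RNG state restored afterwards).
#' @param ... Unused.
#' @return A data frame with `nsim` columns of `-1/+1` labels.
#' @export
simulate.sbfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$x)) {
    stop("fit was created with keep_data = FALSE; cannot simulate",
         call. = FALSE)
  }
  p <- predict(object, object$x, type = "prob")
  with_seed(seed, {
    out <- replicate(nsim, ifelse(stats::runif(length(p)) < p, 1, -1))
    as.data.frame(out)
  })
}
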