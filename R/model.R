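# Probabilistic model layer: prior, likelihood, MAP objective and its
# derivatives. Everything here is a pure function of (beta, gamma, x, y);
# the iterative solver lives in sblogit.R.
#
# Conventions: x is the N x M design matrix (samples in rows, linear
# feature basis), y is coded -1/+1, gamma is the vector of per-feature
# prior variances, Gamma = diag(gamma).

# Numerically stable log(1 + exp(t)).
log1pexp <- function(t) pmax(t, 0) + log1p(exp(-abs(t)))

#' Logistic sigmoid
#'
#' `sigmoid(f)` returns `1 / (1 + exp(-f))`, the inverse-logit link used to
#' turn decision margins into class probabilities. Stable over the whole
#' double range (saturates to 0/1 rather than overflowing).
#'
#' @param f Numeric vector of finite values.
#' @return Numeric vector of the same length with entries in `[0, 1]`.
#' @examples
#' sigmoid(0)        # 0.5
#' sigmoid(log(3))   # 0.75
#' @export
sigmoid <- function(f) {
  if (!is.numeric(f)) stop("`f` must be numeric", call. = FALSE)
  if (anyNA(f) || any(!is.finite(f))) {
    stop("`f` contains non-finite values", call. = FALSE)
  }
  1 / (1 + exp(-f))
}

# Coerce/validate a design matrix and -1/+1 labels. Accepts labels coded
# -1/+1, 0/1, logical, or a two-level factor/character (levels mapped
# alphabetically: first level -> +1). Returns list(x, y, map).
validate_xy <- function(x, y, require_both_classes = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix (samples in rows)", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("`x` contains a non-finite value at row %d, column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (ncol(x) < 1L) stop("need at least 1 feature", call. = FALSE)
  map <- NULL
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) > 2L) {
      stop("labels have more than 2 classes: ", paste(lev, collapse = ", "),
           call. = FALSE)
    }
    map <- stats::setNames(c(1, -1)[seq_along(lev)], lev)
    y <- unname(map[as.character(y)])
  }
  y <- as.numeric(y)
  if (length(y) != nrow(x)) {
    stop("length(y) must equal nrow(x)", call. = FALSE)
  }
  if (anyNA(y)) stop("labels contain missing values", call. = FALSE)
  if (all(y %in% c(0, 1)) && any(y == 0)) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) {
    stop("labels must be codable as -1/+1 (accepted: -1/+1, 0/1, logical, ",
         "two-level factor)", call. = FALSE)
  }
  if (require_both_classes && length(unique(y)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  list(x = x, y = y, map = map)
}

check_model_args <- function(beta, gamma, x, y) {
  if (length(beta) != ncol(x)) {
    stop("length(beta) must equal ncol(x)", call. = FALSE)
  }
  if (!is.null(gamma) && length(gamma) != ncol(x)) {
    stop("length(gamma) must equal ncol(x)", call. = FALSE)
  }
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)", call. = FALSE)
  invisible(TRUE)
}

#' Negative log-likelihood of the logistic model
#'
#' Computes `sum_n log(1 + exp(-y_n * x_n' beta))`, the negated Bernoulli
#' log-likelihood under the logistic link, with a `log1p`-stable form so
#' large negative margins do not overflow.
#'
#' @param beta Coefficient vector, length `ncol(x)`.
#' @param x Design matrix, samples in rows.
#' @param y Labels in `{-1, +1}` (other codings are remapped).
#' @return Nonnegative scalar.
#' @export
logistic_nll <- function(beta, x, y) {
  d <- validate_xy(x, y, require_both_classes = FALSE)
  check_model_args(beta, NULL, d$x, d$y)
  sum(log1pexp(-d$y * drop(d$x %*% beta)))
}

#' Penalised (MAP) objective for fixed prior variances
#'
#' The maximum-a-posteriori objective in `beta` for fixed `gamma`:
#' `logistic_nll(beta) + 0.5 * sum(beta_i^2 / gamma_i)` over features with
#' `gamma_i > 0`. Features with `gamma_i = 0` are pruned and must carry
#' `beta_i = 0`; their penalty contribution is zero. Additive terms constant
#' in `beta` (the `log|Gamma|` normaliser) are excluded.
#'
#' @inheritParams logistic_nll
#' @param gamma Nonnegative prior variances, length `ncol(x)`.
#' @return Scalar objective value.
#' @export
map_objective <- function(beta, gamma, x, y) {
  d <- validate_xy(x, y, require_both_classes = FALSE)
  check_model_args(beta, gamma, d$x, d$y)
  if (any(gamma < 0)) stop("gamma must be nonnegative", call. = FALSE)
  if (any(gamma == 0 & beta != 0)) {
    stop("beta must be 0 wherever gamma is 0 (pruned feature)", call. = FALSE)
  }
  act <- gamma > 0
  logistic_nll(beta, d$x, d$y) + 0.5 * sum(beta[act]^2 / gamma[act])
}

#' Gradient of the MAP objective
#'
#' `-sum_n y_n x_n (1 - S(y_n x_n' beta)) + Gamma^-1 beta`, with the prior
#' term taken as 0 on pruned (`gamma = 0`, `beta = 0`) coordinates.
#'
#' @inheritParams map_objective
#' @return Numeric vector of length `ncol(x)`.
#' @export
map_gradient <- function(beta, gamma, x, y) {
  d <- validate_xy(x, y, require_both_classes = FALSE)
  check_model_args(beta, gamma, d$x, d$y)
  if (any(gamma == 0 & beta != 0)) {
    stop("beta must be 0 wherever gamma is 0 (pruned feature)", call. = FALSE)
  }
  m <- drop(d$x %*% beta)
  g <- -drop(crossprod(d$x, d$y * sigmoid(-d$y * m)))
  prior <- numeric(length(beta))
  act <- gamma > 0
  prior[act] <- beta[act] / gamma[act]
  g + prior
}

#' Hessian of the MAP objective
#'
#' `X' diag(z) X + Gamma^-1` with `z_n = S(m_n) (1 - S(m_n))`,
#' `m_n = y_n x_n' beta` (the `diag(y)` factors cancel since `y_n^2 = 1`).
#' Symmetric positive definite whenever all `gamma_i > 0`.
#'
#' @inheritParams map_objective
#' @param gamma Strictly positive prior variances.
#' @return `M x M` symmetric matrix.
#' @export
map_hessian <- function(beta, gamma, x, y) {
  d <- validate_xy(x, y, require_both_classes = FALSE)
  check_model_args(beta, gamma, d$x, d$y)
  if (any(gamma <= 0)) {
    stop("map_hessian requires all gamma > 0", call. = FALSE)
  }
  s <- sigmoid(d$y * drop(d$x %*% beta))
  z <- s * (1 - s)
  H <- crossprod(d$x, d$x * z) + diag(1 / gamma, nrow = length(gamma))
  (H + t(H)) / 2
}

#' Joint objective in (beta, gamma)
#'
#' The marginal-likelihood-based objective that the alternating solver
#' descends, combining data fit, the Gaussian prior, and the Laplace
#' log-determinant term. Two equivalent-up-to-scaling forms are offered:
#'
#' * `laplace_scale = FALSE` (default):
#'   `nll + beta' Gamma^-1 beta + log|Gamma| + 0.5 log|H(beta)|`
#' * `laplace_scale = TRUE`: the Laplace-approximate negative log marginal
#'   posterior `nll + 0.5 beta' Gamma^-1 beta + 0.5 log|Gamma| +
#'   0.5 log|H(beta)|`, which is the quantity the convex-concave iteration
#'   is guaranteed to decrease (and the one recorded in
#'   `objective_trace` by [sblogit()]).
#'
#' Both log-determinants come from a Cholesky factorisation; a
#' non-positive-definite Hessian is an error.
#'
#' @inheritParams map_hessian
#' @param laplace_scale Logical; see Details.
#' @return Scalar.
#' @export
joint_objective <- function(beta, gamma, x, y, laplace_scale = FALSE) {
  H <- map_hessian(beta, gamma, x, y)
  R <- tryCatch(chol(H), error = function(e) {
    stop("Hessian is not positive definite", call. = FALSE)
  })
  ld_H <- 2 * sum(log(diag(R)))
  ld_G <- sum(log(gamma))
  quad <- sum(beta^2 / gamma)
  nll <- logistic_nll(beta, x, y)
  if (laplace_scale) {
    nll + 0.5 * quad + 0.5 * ld_G + 0.5 * ld_H
  } else {
    nll + quad + ld_G + 0.5 * ld_H
  }
}
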