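# Comparator methods: l1-regularised logistic regression solved by ADMM
# ("RLR") and an EM-style relevance-vector classifier ("SBL"). Both share
# the sbfit interface (coef/predict/support) with the main solver.

soft_threshold <- function(v, k) sign(v) * pmax(abs(v) - k, 0)

#' Control parameters for the ADMM l1-logistic baseline
#'
#' @param rho ADMM augmented-Lagrangian penalty.
#' @param max_iter Maximum ADMM iterations.
#' @param abs_tol,rel_tol Absolute/relative tolerances for the standard
#'   primal/dual residual stopping rule.
#' @param cv_folds Folds for the internal lambda-selection cross-validation.
#' @param nlambda,lambda_min_ratio Log-spaced lambda grid: `nlambda` values
#'   from `lambda_max` (smallest lambda giving the all-zero solution) down
#'   to `lambda_min_ratio * lambda_max`.
#' @return A named list of class `l1logit_control`.
#' @export
l1logit_control <- function(rho = 1, max_iter = 2000L, abs_tol = 1e-5,
                            rel_tol = 1e-4, cv_folds = 5L, nlambda = 6L,
                            lambda_min_ratio = 1e-3) {
  stopifnot(rho > 0, max_iter >= 1, abs_tol > 0, rel_tol > 0,
            cv_folds >= 2, nlambda >= 1, lambda_min_ratio > 0)
  structure(list(rho = rho, max_iter = as.integer(max_iter),
                 abs_tol = abs_tol, rel_tol = rel_tol,
                 cv_folds = as.integer(cv_folds),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio),
            class = "l1logit_control")
}

# One ADMM solve of min_b NLL(b) + lambda * |b|_1 at fixed lambda.
# Splitting: x-update = smooth NLL + (rho/2)|b - z + u|^2 (L-BFGS, warm
# started), z-update = soft threshold, u-update = dual ascent. An optional
# unpenalised intercept rides along in the smooth block and is not
# thresholded. Returns the consensus variable z (exact zeros).
admm_l1_logistic <- function(x, y, lambda, rho = 1, max_iter = 200L,
                             abs_tol = 1e-4, rel_tol = 1e-3,
                             intercept = FALSE, init = NULL) {
  M <- ncol(x)
  xa <- if (intercept) cbind(x, 1) else x
  P <- ncol(xa)
  pen <- c(rep(TRUE, M), if (intercept) FALSE)
  b <- if (is.null(init)) numeric(P) else init$b
  z <- if (is.null(init)) numeric(P) else init$z
  u <- if (is.null(init)) numeric(P) else init$u
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    v <- z - u
    fn <- function(p) {
      sum(log1pexp(-y * drop(xa %*% p))) + 0.5 * rho * sum((p - v)^2)
    }
    gr <- function(p) {
      -drop(crossprod(xa, y * sigmoid(-y * drop(xa %*% p)))) + rho * (p - v)
    }
    b <- stats::optim(b, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = 100L, pgtol = 1e-7,
                                     factr = 1e7))$par
    z_old <- z
    z <- b + u
    z[pen] <- soft_threshold(z[pen], lambda / rho)
    u <- u + b - z
    r_norm <- sqrt(sum((b - z)^2))
    s_norm <- rho * sqrt(sum((z - z_old)^2))
    eps_pri <- sqrt(P) * abs_tol +
      rel_tol * max(sqrt(sum(b^2)), sqrt(sum(z^2)))
    eps_dual <- sqrt(P) * abs_tol + rel_tol * rho * sqrt(sum(u^2))
    if (r_norm < eps_pri && s_norm < eps_dual) { converged <- TRUE; break }
  }
  list(beta = z[seq_len(M)],
       intercept = if (intercept) z[P] else 0,
       iterations = it, converged = converged,
       state = list(b = b, z = z, u = u))
}

# Largest lambda with all-zero solution: sup-norm of the NLL gradient at 0.
lambda_max_l1 <- function(x, y) max(abs(0.5 * drop(crossprod(x, y))))

#' l1-regularised logistic regression via ADMM
#'
#' Comparator classifier: `min_b sum_n log(1 + exp(-y_n x_n' b)) +
#' lambda |b|_1`, solved by the alternating direction method of multipliers
#' with a soft-threshold consensus update.
#'
#' By default `lambda = 0.3 * lambda_max`, where `lambda_max` is the
#' smallest penalty giving the all-zero solution — a fixed fraction in the
#' sparse regime of the path, where the fit keeps roughly one
#' representative of each correlated informative group and essentially no
#' null features (the selection behaviour this comparator exists to
#' exhibit). `lambda = "cv"` instead picks the penalty by internal
#' stratified cross-validated accuracy over a log-spaced grid (ties toward
#' the larger, sparser value); accuracy-driven selection prefers weaker
#' penalties and correspondingly denser supports.
#'
#' @inheritParams sblogit
#' @param lambda Penalty level: a number, `NULL` (0.3 of `lambda_max`), or
#'   `"cv"`.
#' @param control An [l1logit_control()] list.
#' @return An object of class `c("l1logit", "sbfit")`; `support` holds the
#'   indices with exactly non-zero consensus coefficients, `lambda` the
#'   penalty used, `cv_table` the internal selection table (if CV ran).
#' @export
l1logit <- function(x, y, lambda = NULL, intercept = FALSE,
                    control = l1logit_control(), keep_data = TRUE) {
  cl <- match.call()
  d <- validate_xy(x, y)
  x <- d$x; y <- d$y
  M <- ncol(x)
  fnames <- colnames(x)
  if (is.null(fnames)) fnames <- paste0("f", seq_len(M))

  cv_table <- NULL
  if (is.null(lambda)) {
    lambda <- 0.3 * lambda_max_l1(x, y)
  } else if (identical(lambda, "cv")) {
    lmax <- lambda_max_l1(x, y)
    grid <- lmax * exp(seq(0, log(control$lambda_min_ratio),
                           length.out = control$nlambda))
    folds <- stratified_folds(y, control$cv_folds)
    acc <- matrix(NA_real_, control$cv_folds, length(grid))
    for (f in seq_len(control$cv_folds)) {
      tr <- folds != f
      init <- NULL
      for (j in seq_along(grid)) {      # warm start down the path
        res <- admm_l1_logistic(x[tr, , drop = FALSE], y[tr], grid[j],
                                rho = control$rho,
                                max_iter = control$max_iter,
                                abs_tol = control$abs_tol,
                                rel_tol = control$rel_tol,
                                intercept = intercept, init = init)
        init <- res$state
        m_te <- drop(x[!tr, , drop = FALSE] %*% res$beta) + res$intercept
        acc[f, j] <- mean(ifelse(m_te >= 0, 1, -1) == y[!tr])
      }
    }
    mean_acc <- colMeans(acc)
    lambda <- grid[which.max(mean_acc)]   # grid is decreasing: ties -> larger
    cv_table <- data.frame(lambda = grid, accuracy = mean_acc)
  }

  fit <- admm_l1_logistic(x, y, lambda, rho = control$rho,
                          max_iter = control$max_iter,
                          abs_tol = control$abs_tol,
                          rel_tol = control$rel_tol, intercept = intercept)
  if (!fit$converged) {
    warning("ADMM did not converge within max_iter; returning best iterate",
            call. = FALSE)
  }
  beta <- fit$beta
  names(beta) <- fnames
  structure(list(
    coefficients = beta, intercept = fit$intercept,
    gamma = NULL, support = which(beta != 0),
    iterations = fit$iterations, converged = fit$converged,
    objective_trace = numeric(0),
    lambda = lambda, cv_table = cv_table,
    method = "rlr", feature_names = fnames,
    n = nrow(x), m = M, control = control, has_intercept = intercept,
    call = cl,
    x = if (keep_data) x else NULL, y = if (keep_data) y else NULL
  ), class = c("l1logit", "sbfit"))
}

#' Control parameters for the relevance-vector baseline
#'
#' @param max_iter Maximum outer (model-update) rounds.
#' @param tol Convergence threshold on the largest relative change of the
#'   log relevance precisions with no pending add/delete move.
#' @param alpha_prune Relevance-precision cap; a basis function whose
#'   re-estimated precision exceeds it is removed (weight exactly 0).
#' @param theta_tol Numerical slack on the evidence statistic
#'   `q^2 - s` when deciding whether a feature supports inclusion.
#' @return A named list of class `rvmlogit_control`.
#' @export
rvmlogit_control <- function(max_iter = 200L, tol = 1e-3,
                             alpha_prune = 1e9, theta_tol = 1e-8) {
  stopifnot(max_iter >= 1, tol > 0, alpha_prune > 0, theta_tol >= 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 alpha_prune = alpha_prune, theta_tol = theta_tol),
            class = "rvmlogit_control")
}

#' Sparse Bayesian (relevance-vector) logistic classifier
#'
#' Classical sparse Bayesian learning over a linear feature basis: each
#' coefficient carries an independent zero-mean Gaussian prior with
#' relevance precision `alpha_i`, estimated by maximising the Laplace
#' approximation of the marginal likelihood. The model is built
#' constructively (fast marginal-likelihood maximisation): starting from
#' the single most aligned feature, each round refits the posterior mode,
#' then uses the per-feature sparsity/quality statistics `s_i`, `q_i` to
#' add the feature with the largest positive evidence gain
#' (`theta_i = q_i^2 - s_i > 0`), delete members whose evidence turns
#' negative, and re-estimate member precisions `alpha_i = s_i^2 / theta_i`.
#' Because a near-duplicate of a feature already in the model contributes
#' essentially no additional evidence, this classifier characteristically
#' keeps only one member of each highly correlated pair — the comparator
#' behaviour it exists to exhibit.
#'
#' @inheritParams sblogit
#' @param control An [rvmlogit_control()] list.
#' @return An object of class `c("rvmlogit", "sbfit")`; `alpha` holds the
#'   final relevance precisions (`Inf` for excluded features).
#' @export
rvmlogit <- function(x, y, intercept = FALSE,
                     control = rvmlogit_control(), keep_data = TRUE) {
  cl <- match.call()
  d <- validate_xy(x, y)
  x <- d$x; y <- d$y
  N <- nrow(x); M <- ncol(x)
  fnames <- colnames(x)
  if (is.null(fnames)) fnames <- paste0("f", seq_len(M))
  t01 <- (y + 1) / 2

  # seed the model with the feature most aligned with the centred labels
  # (posterior statistics at beta = 0: B = I/4, working response 2*y)
  Q0 <- drop(crossprod(x, y / 2))
  S0 <- colSums(x^2) / 4
  i0 <- which.max(Q0^2 / S0)
  A <- i0
  alpha <- rep(Inf, M)
  alpha[i0] <- if (Q0[i0]^2 > S0[i0] + control$theta_tol) {
    S0[i0]^2 / (Q0[i0]^2 - S0[i0])
  } else 1
  mu <- 0
  converged <- FALSE
  it <- 0L
  for (it in seq_len(control$max_iter)) {
    xa <- x[, A, drop = FALSE]
    if (intercept) xa <- cbind(xa, 1)
    wa <- if (intercept) c(alpha[A], 0) else alpha[A]
    par0 <- c(mu, if (intercept) 0)
    bs <- beta_step(xa, y, wa, par0, inner_max_iter = 200L,
                    inner_grad_tol = 1e-6)
    mu_full <- bs$par
    mu <- mu_full[seq_along(A)]
    b0 <- if (intercept) mu_full[length(mu_full)] else 0
    p <- sigmoid(drop(xa %*% mu_full))
    Bv <- pmax(p * (1 - p), 1e-10)
    # Laplace posterior covariance on the active set
    Ha <- crossprod(xa, xa * Bv) +
      diag(if (intercept) c(alpha[A], 0) else alpha[A],
           nrow = length(mu_full))
    Sig <- chol2inv(chol(Ha))
    # linearised targets and full-sample statistics S, Q for every feature
    that <- drop(xa %*% mu_full) + (t01 - p) / Bv
    Bt <- Bv * that
    BX <- x * Bv                        # N x M
    G <- crossprod(xa, BX)              # |A'| x M,  Phi_A' B phi_i
    SG <- Sig %*% G
    Smat <- colSums(BX * x) - colSums(G * SG)
    Qvec <- drop(crossprod(x, Bt)) - drop(crossprod(SG, crossprod(xa, Bt)))
    s <- Smat; q <- Qvec
    den <- alpha[A] - Smat[A]
    den[abs(den) < 1e-12] <- 1e-12
    s[A] <- alpha[A] * Smat[A] / den
    q[A] <- alpha[A] * Qvec[A] / den
    theta <- q^2 - s

    # delete members with non-positive evidence, re-estimate the rest
    drop_i <- A[theta[A] <= control$theta_tol]
    alpha_old <- alpha
    keep <- setdiff(A, drop_i)
    alpha[drop_i] <- Inf
    alpha[keep] <- pmin(s[keep]^2 / theta[keep], control$alpha_prune)
    # strongest candidate addition
    cand <- setdiff(which(theta > control$theta_tol), A)
    add_i <- integer(0)
    if (length(cand) && length(drop_i) == 0L) {
      gain <- (q[cand]^2 - s[cand]) / s[cand] + log(s[cand] / q[cand]^2)
      add_i <- cand[which.max(gain)]
      alpha[add_i] <- s[add_i]^2 / theta[add_i]
    }
    A_new <- sort(c(keep, add_i))
    moved <- length(drop_i) > 0L || length(add_i) > 0L
    if (!moved && length(keep)) {
      dl <- max(abs(log(alpha[keep]) - log(alpha_old[keep])))
      if (dl < control$tol) { A <- A_new; converged <- TRUE }
    }
    mu <- numeric(length(A_new))
    mu[match(intersect(A_new, A), A_new)] <-
      bs$par[match(intersect(A_new, A), A)]
    A <- A_new
    if (converged || length(A) == 0L) break
  }
  if (!converged && length(A)) {
    warning("relevance-vector update did not converge within max_iter",
            call. = FALSE)
  }
  # final posterior mode on the converged active set
  beta <- numeric(M)
  b0 <- 0
  if (length(A)) {
    xa <- x[, A, drop = FALSE]
    if (intercept) xa <- cbind(xa, 1)
    wa <- if (intercept) c(alpha[A], 0) else alpha[A]
    bs <- beta_step(xa, y, wa, c(mu, if (intercept) 0),
                    inner_max_iter = 200L, inner_grad_tol = 1e-6)
    beta[A] <- bs$par[seq_along(A)]
    if (intercept) b0 <- bs$par[length(bs$par)]
  }
  names(beta) <- fnames
  structure(list(
    coefficients = beta, intercept = b0, gamma = NULL,
    alpha = alpha, support = which(beta != 0),
    iterations = it, converged = converged, objective_trace = numeric(0),
    method = "sbl", feature_names = fnames,
    n = N, m = M, control = control, has_intercept = intercept,
    call = cl,
    x = if (keep_data) x else NULL, y = if (keep_data) y else NULL
  ), class = c("rvmlogit", "sbfit"))
}
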