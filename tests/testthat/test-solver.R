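bench_fit <- function(sim, ...) sblogit(sim$x, sim$y, keep_data = FALSE, ...)

test_that("coefficient step solves the weighted-ridge subproblem", {
  inst <- random_instance(30, 5, seed = 71)
  # overwhelming penalty forces the solution to zero
  bs <- sblogit:::beta_step(inst$x, inst$y, rep(1e12, 5), numeric(5))
  expect_lt(max(abs(bs$par)), 1e-5)
  # objective value matches an independent generic solver
  for (s in 1:3) {
    set.seed(300 + s)
    w <- rexp(5) + 0.2
    bs <- sblogit:::beta_step(inst$x, inst$y, w, numeric(5),
                              inner_max_iter = 500L, inner_grad_tol = 1e-9)
    oracle <- ridge_logit_oracle(inst$x, inst$y, w)
    obj <- function(b) sum(log1p(exp(-inst$y * drop(inst$x %*% b)))) +
      0.5 * sum(w * b^2)
    expect_equal(obj(bs$par), oracle$objective, tolerance = 1e-6)
  }
  # unit weights = ridge-penalised logistic fit
  bs <- sblogit:::beta_step(inst$x, inst$y, rep(1, 5), numeric(5),
                            inner_max_iter = 500L, inner_grad_tol = 1e-9)
  oracle <- ridge_logit_oracle(inst$x, inst$y, rep(1, 5))
  expect_equal(bs$par, oracle$par, tolerance = 1e-4)
})

test_that("exact inverse-Hessian diagonal matches dense inversion and its
           spectral bound", {
  # identity design at beta = 0: H_ii = 1/4 + 1/gamma
  n <- 6
  x <- diag(n)
  y <- rep(c(1, -1), 3)
  d <- sblogit:::exact_inv_hessian(x, y, numeric(n), rep(1, n))$diag
  expect_equal(d, rep(0.8, n), tolerance = 1e-12)
  inst <- random_instance(25, 6, seed = 81)
  set.seed(82)
  beta <- rnorm(6); gamma <- rexp(6) + 0.2
  d <- sblogit:::exact_inv_hessian(inst$x, inst$y, beta, 1 / gamma)$diag
  Hfull <- map_hessian(beta, gamma, inst$x, inst$y)
  expect_equal(d, diag(solve(Hfull)), tolerance = 1e-8)
  # H >= Gamma^-1 in Loewner order implies H^-1 diagonal <= gamma
  expect_true(all(d <= gamma + 1e-10))
  expect_true(all(d > 0))
})

test_that("L-BFGS-approximate inverse-Hessian diagonal is positive and
           tracks the exact one", {
  inst <- random_instance(200, 4, seed = 83)
  set.seed(84)
  beta <- rnorm(4, sd = 0.3); gamma <- rep(1, 4)
  d_apx <- sblogit:::lbfgs_inv_hessian_diag(inst$x, inst$y, beta, 1 / gamma)
  d_ex <- sblogit:::exact_inv_hessian(inst$x, inst$y, beta, 1 / gamma)$diag
  expect_true(all(d_apx > 0))
  expect_equal(d_apx, d_ex, tolerance = 0.5)
})

test_that("hyperparameter updates follow their closed forms", {
  expect_equal(sblogit:::alpha_update(1, 2), 0.25)
  # boundary case clamps to alpha_min
  expect_equal(sblogit:::alpha_update(1, 1, alpha_min = 1e-12), 1e-12)
  expect_equal(sblogit:::gamma_update(2, 4), 1)
  expect_identical(sblogit:::gamma_update(0, 4), 0)
  # raw alpha is nonnegative whenever the spectral bound holds
  inst <- random_instance(20, 5, seed = 91)
  for (s in 1:5) {
    set.seed(400 + s)
    beta <- rnorm(5); gamma <- rexp(5) + 0.2
    d <- sblogit:::exact_inv_hessian(inst$x, inst$y, beta, 1 / gamma)$diag
    expect_true(all(1 / gamma - d / gamma^2 >= -1e-10))
  }
})

test_that("variance update minimises beta^2/gamma + alpha*gamma", {
  set.seed(92)
  for (rep in 1:10) {
    b <- rnorm(1, sd = 2); a <- rexp(1) + 0.05
    grid <- seq(1e-3, 100, length.out = 200000)
    g_grid <- grid[which.min(b^2 / grid + a * grid)]
    expect_equal(sblogit:::gamma_update(b, a), g_grid, tolerance = 1e-3)
  }
})

test_that("fit recovers the correlated-pair support on the benchmark
           design", {
  sim <- simulate_correlated_design(seed = 1001)
  fit <- bench_fit(sim)
  expect_setequal(fit$support, sim$truth$support)
  # both members of each pair carry weights of the same sign
  b <- coef(fit)
  expect_true(all(sign(b[sim$truth$pairs[, 1]]) ==
                    sign(b[sim$truth$pairs[, 2]])))
})

test_that("duplicated informative columns are co-selected", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(500 + s)
    x <- matrix(rnorm(200 * 10), 200, 10)
    x[, 2] <- x[, 1] + rnorm(200, sd = 0.1)   # near-exact duplicate
    beta_true <- c(1, 1, 1.2, rep(0, 7))
    y <- ifelse(drop(x %*% beta_true) >= 0, 1, -1)
    fit <- sblogit(x, y, keep_data = FALSE)
    b <- coef(fit)
    both <- all(c(1, 2) %in% fit$support) &&
      sign(b[1]) == sign(b[2])
    neither <- !any(c(1, 2) %in% fit$support)
    hits <- hits + (both || neither)
  }
  expect_gte(hits, 9L)
})

test_that("labels carrying no signal leave the support near-empty", {
  sizes <- integer(10)
  for (s in 1:10) {
    sim <- simulate_correlated_design(seed = 3000 + s)
    set.seed(s)
    y_perm <- sample(sim$y)
    fit <- suppressWarnings(sblogit(sim$x, y_perm, keep_data = FALSE))
    sizes[s] <- length(fit$support)
  }
  expect_lte(median(sizes), 2)
})

test_that("every reweighting round decreases the joint objective", {
  for (s in c(1001, 1002, 1003)) {
    sim <- simulate_correlated_design(
      label_noise_sd = c(0, 0.5, 1)[(s %% 3) + 1], seed = s)
    fit <- bench_fit(sim)
    expect_true(all(is.finite(fit$objective_trace)))
    expect_true(all(fit$descent_margin >=
                      -1e-6 * (1 + abs(fit$objective_trace))))
  }
})

test_that("negating the labels mirrors the fitted weights", {
  sim <- simulate_correlated_design(n_samples = 200, n_features = 20,
                                    support_size = 4, seed = 1005)
  f1 <- bench_fit(sim)
  f2 <- sblogit(sim$x, -sim$y, keep_data = FALSE)
  expect_setequal(f1$support, f2$support)
  expect_equal(coef(f1), -coef(f2), tolerance = 1e-4)
})

test_that("rescaling a feature column rescales its weight inversely", {
  sim <- simulate_correlated_design(n_samples = 300, n_features = 10,
                                    support_size = 3,
                                    correlated_fraction = 0, seed = 1006)
  j <- sim$truth$support[1]
  f1 <- bench_fit(sim)
  x2 <- sim$x
  x2[, j] <- 2 * x2[, j]
  f2 <- sblogit(x2, sim$y, keep_data = FALSE)
  expect_equal(coef(f2)[j], coef(f1)[j] / 2, tolerance = 0.05 *
                 abs(coef(f1)[j]))
})

test_that("solver matches a from-scratch reimplementation of the update
           equations on a small instance", {
  sim <- simulate_correlated_design(n_samples = 40, n_features = 6,
                                    support_size = 2, label_noise_sd = 0.5,
                                    seed = 1007)
  x <- sim$x; y <- sim$y
  ctl <- sblogit_control(inner_grad_tol = 1e-10, inner_max_iter = 1000L)
  fit <- sblogit(x, y, control = ctl, keep_data = FALSE)
  # brute force: same update equations, written independently (nlminb for
  # the convex step, dense solve() for the Hessian inverse)
  M <- 6
  active <- rep(TRUE, M); gamma <- rep(1, M); beta <- numeric(M)
  for (k in 1:ctl$k_max) {
    idx <- which(active)
    ora <- ridge_logit_oracle(x[, idx, drop = FALSE], y, 1 / gamma[idx],
                              start = beta[idx])
    bnew <- numeric(M); bnew[idx] <- ora$par
    p <- stats::plogis(y * drop(x[, idx, drop = FALSE] %*% ora$par))
    H <- crossprod(x[, idx, drop = FALSE],
                   x[, idx, drop = FALSE] * (p * (1 - p))) +
      diag(1 / gamma[idx], nrow = length(idx))
    hi <- diag(solve(H))
    al <- pmax(1 / gamma[idx] - hi / gamma[idx]^2, ctl$alpha_min)
    gn <- abs(bnew[idx]) / sqrt(al)
    thr <- max(ctl$gamma_prune * max(gn), ctl$gamma_min)
    keep <- gn > thr
    active[idx[!keep]] <- FALSE; bnew[idx[!keep]] <- 0
    gamma[idx] <- ifelse(keep, gn, 0)
    delta <- max(abs(bnew - beta)) / (1 + max(abs(beta)))
    beta <- bnew
    if (delta < ctl$beta_tol) break
  }
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-4)
  expect_setequal(fit$support, which(beta != 0))
})

test_that("a non-separable instance reaches a coefficient fixed point", {
  sim <- simulate_correlated_design(n_samples = 200, n_features = 10,
                                    support_size = 3,
                                    correlated_fraction = 0,
                                    label_noise_sd = 1, seed = 99)
  ctl <- sblogit_control(k_max = 60)
  fit <- sblogit(sim$x, sim$y, control = ctl, keep_data = FALSE)
  expect_true(fit$fixed_point)
  expect_lt(fit$iterations, ctl$k_max)
  # the final round moved the coefficients less than the tolerance
  expect_lt(fit$outer_delta, ctl$beta_tol)
})

test_that("fit validates its inputs", {
  sim <- simulate_correlated_design(n_samples = 50, n_features = 5,
                                    support_size = 2, seed = 1008)
  expect_error(sblogit(sim$x, rep(1, 50)), "both classes")
  expect_error(sblogit(sim$x, sim$y[-1]), "length")
})

test_that("prediction applies the logistic link to the fitted margins", {
  sim <- simulate_correlated_design(n_samples = 100, n_features = 8,
                                    support_size = 3, seed = 1009)
  fit <- bench_fit(sim)
  newx <- sim$x[1:7, ]
  p <- unname(predict(fit, newx, type = "prob"))
  expect_true(all(p > 0 & p < 1))
  expect_equal(p + predict(fit, -newx, type = "prob"), rep(1, 7),
               ignore_attr = TRUE)
  expect_equal(predict(fit, newx, type = "class"),
               ifelse(p >= 0.5, 1, -1), ignore_attr = TRUE)
  # an all-zero model is maximally uncertain and defaults to +1
  null_fit <- fit
  null_fit$coefficients[] <- 0
  expect_equal(predict(null_fit, newx, type = "prob"), rep(0.5, 7),
               ignore_attr = TRUE)
  expect_equal(predict(null_fit, newx, type = "class"), rep(1, 7),
               ignore_attr = TRUE)
  expect_error(predict(fit, newx[, 1:3]), "columns")
})
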