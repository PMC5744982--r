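test_that("selection error rates use the documented denominators", {
  truth <- list(beta_true = numeric(50), support = 1:8)
  truth$beta_true[1:8] <- 1
  # four of eight true features missed, nothing spurious
  m <- selection_metrics(c(1, 3, 5, 7), truth)
  expect_equal(m$fn_rate, 0.5)
  expect_equal(m$fp_rate, 0)
  # one spurious selection among the 42 null features
  m <- selection_metrics(c(1:8, 20), truth)
  expect_equal(m$fp_rate, 1 / 42)
  expect_equal(m$fn_rate, 0)
  m <- selection_metrics(1:8, truth)
  expect_equal(unlist(m), c(fp_rate = 0, fn_rate = 0))
  expect_error(selection_metrics(1:3, list(beta_true = numeric(10),
                                           support = integer(0))),
               "empty")
  expect_error(selection_metrics(60, truth), "outside")
})

test_that("rates times their denominators are integer counts", {
  set.seed(11)
  for (rep in 1:20) {
    M <- sample(10:60, 1)
    s <- sample(2:(M - 2), 1)
    truth <- list(beta_true = numeric(M), support = sample(M, s))
    truth$beta_true[truth$support] <- 1
    sel <- sample(M, sample(0:M, 1))
    m <- selection_metrics(sel, truth)
    expect_equal(m$fp_rate * (M - s), round(m$fp_rate * (M - s)))
    expect_equal(m$fn_rate * s, round(m$fn_rate * s))
  }
})

test_that("feature ranking is by |weight| with deterministic ties", {
  expect_equal(rank_features(c(0.1, -3, 0)), c(2, 1, 3))
  expect_equal(rank_features(c(2, 0.5, 1, -2)), c(1, 4, 3, 2))
  set.seed(12)
  b <- rnorm(8)
  expect_equal(rank_features(b), rank_features(-b))
})

test_that("stability score combines Jaccard stability and accuracy
           harmonically", {
  sets <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(stability_score(sets, rep(1, 3)), 1)
  expect_equal(stability_score(list(1:3, 4:6, 7:9), rep(1, 3)), 0)
  s <- stability_score(list(1:4, c(1, 2, 5, 6)), c(0.9, 0.9))
  expect_equal(s, 2 * (1 / 3) * 0.9 / (1 / 3 + 0.9), tolerance = 1e-12)
  # empty sets contribute zero stability, not an error
  expect_equal(stability_score(list(integer(0), integer(0)), c(1, 1)), 0)
  expect_error(stability_score(list(1:2), c(1, 1)), "length")
})

test_that("cross-validated accuracy is perfect on a margin-separated
           design and near chance on permuted labels", {
  set.seed(21)
  x <- matrix(rnorm(100 * 4), 100, 4)
  x[, 1] <- sample(c(-1, 1), 100, TRUE) * runif(100, 0.5, 2)
  y <- sign(x[, 1])   # unit margin gap around the boundary
  expect_equal(cv_accuracy(x, y, "sblogit", folds = 5, seed = 1), 1)
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    y_perm <- sample(y)
    suppressWarnings(cv_accuracy(x, y_perm, "sblogit", folds = 5,
                                 seed = s))
  }, numeric(1))
  expect_gt(median(accs), 0.3)
  expect_lt(median(accs), 0.7)
})

test_that("cv folds are stratified and reproducible", {
  y <- rep(c(1, -1), c(30, 10))
  set.seed(3)
  f <- sblogit:::stratified_folds(y, 5)
  expect_equal(unname(table(f)), rep(8L, 5), ignore_attr = TRUE)
  for (k in 1:5) expect_equal(sum(y[f == k] == -1), 2)
  expect_error(sblogit:::stratified_folds(rep(c(1, -1), c(38, 2)), 5),
               "at least")
  sim <- simulate_correlated_design(n_samples = 80, n_features = 5,
                                    support_size = 2, seed = 22)
  a1 <- cv_accuracy(sim$x, sim$y, "sblogit", folds = 5, seed = 9)
  a2 <- cv_accuracy(sim$x, sim$y, "sblogit", folds = 5, seed = 9)
  expect_identical(a1, a2)
})

test_that("scoring against reference labels isolates class recovery", {
  sim <- simulate_correlated_design(n_samples = 300, n_features = 10,
                                    support_size = 3, beta_scale = 3,
                                    correlated_fraction = 0,
                                    label_noise_sd = 1, seed = 23)
  acc_noisy <- cv_accuracy(sim$x, sim$y, "sblogit", folds = 5, seed = 4)
  acc_clean <- cv_accuracy(sim$x, sim$y, "sblogit", folds = 5, seed = 4,
                           y_eval = sim$y_true)
  expect_gt(acc_clean, acc_noisy)
})

test_that("the optimal-q search finds the support size of a clean
           two-feature signal", {
  sim <- simulate_correlated_design(n_samples = 120, n_features = 8,
                                    support_size = 2, beta_scale = 4,
                                    correlated_fraction = 0, seed = 24)
  qs <- select_q(sim$x, sim$y, "sblogit", q_range = 1:4, folds = 5,
                 seed = 5)
  expect_equal(qs$q, 2)
  expect_setequal(qs$selected, sim$truth$support)
  expect_equal(length(qs$per_fold_sets), 5)
  expect_true(all(qs$score_table$score >= 0 & qs$score_table$score <= 1))
  # a single-candidate range is returned as-is
  qs1 <- select_q(sim$x, sim$y, "sblogit", q_range = 8, folds = 5,
                  seed = 5)
  expect_equal(qs1$q, 8)
})

test_that("run_benchmark aggregates replicates deterministically", {
  grid <- simulation_grid(base_seed = 3, n_samples = 60, n_features = 10,
                          sparsity = 0.2, correlated_fraction = 0,
                          n_replicates = 2)
  b1 <- suppressWarnings(run_benchmark(grid, methods = "sblogit",
                                       folds = 5))
  b2 <- suppressWarnings(run_benchmark(grid, methods = "sblogit",
                                       folds = 5))
  expect_identical(b1, b2)
  expect_equal(nrow(b1$raw), 2)
  expect_equal(nrow(b1$summary), 1)
  expect_true(all(c("accuracy", "fp_rate", "fn_rate") %in%
                    names(b1$summary)))
  expect_true(all(b1$summary$accuracy >= 0 & b1$summary$accuracy <= 1))
})
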