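# Synthetic expression data with correlated informative feature pairs.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a sparse-signal design with correlated feature pairs
#'
#' Generates the benchmark data-generating process used throughout the
#' package: a standard-normal `n_samples x n_features` design matrix, a
#' sparse true coefficient vector with `support_size` non-zero entries
#' drawn from `{-beta_scale, +beta_scale}` (members of a correlated pair
#' share their sign, so each pair carries a coherent, recoverable signal),
#' and binary labels
#' `y = sign(x %*% beta_true + eps)`, `eps ~ N(0, label_noise_sd^2)`
#' (`sign(0)` taken as `+1`). A fraction `correlated_fraction` of the true
#' support is arranged into correlated pairs: the second member of each pair
#' is a copy of the first plus `N(0, pair_noise_sd^2)` noise (sample
#' correlation about `1/sqrt(1 + pair_noise_sd^2)`, i.e. ~0.995 at the
#' default 0.1). These near-duplicate informative columns are what separate
#' selection methods that keep correlated biomarkers from those that drop
#' one member of each pair.
#'
#' The number of paired features is `2 * round(correlated_fraction *
#' support_size / 2)` (pairs must be whole; R's round-half-to-even applies),
#' recorded in the returned truth metadata.
#'
#' @param n_samples,n_features Dimensions of the design matrix.
#' @param support_size Number of non-zero true coefficients. Ignored when
#'   `sparsity` is given, in which case `support_size =
#'   round(sparsity * n_features)`.
#' @param sparsity Optional fraction of non-zero coefficients.
#' @param correlated_fraction Fraction of the true support arranged in
#'   correlated pairs, in `[0, 1]`.
#' @param pair_noise_sd Standard deviation of the within-pair perturbation.
#' @param label_noise_sd Standard deviation of the additive label noise.
#' @param beta_scale Magnitude of the non-zero true coefficients
#'   (default 1, i.e. weights in `{-1, +1}`).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A list of class `sim_design`: `x` (with `f1..fM` column names and
#'   `s1..sN` row names), `y` in `{-1, +1}` (the observed, noise-corrupted
#'   labels), `y_true` (the noiseless true class `sign(x %*% beta_true)`,
#'   the reference against which classification of noisy data is scored),
#'   and `truth` with `beta_true`, `support` (sorted indices), `pairs`
#'   (2-column matrix, first/second member), `n_paired`, and
#'   `label_noise_sd`.
#' @examples
#' sim <- simulate_correlated_design(seed = 1)
#' dim(sim$x)                 # 500 x 50
#' length(sim$truth$support)  # 8
#' @export
simulate_correlated_design <- function(n_samples = 500L, n_features = 50L,
                                       support_size = 8L, sparsity = NULL,
                                       correlated_fraction = 1,
                                       pair_noise_sd = 0.1,
                                       label_noise_sd = 0,
                                       beta_scale = 1,
                                       seed = NULL) {
  stopifnot(n_samples >= 2, n_features >= 1,
            correlated_fraction >= 0, correlated_fraction <= 1,
            pair_noise_sd > 0, label_noise_sd >= 0, beta_scale > 0)
  if (!is.null(sparsity)) {
    stopifnot(sparsity > 0, sparsity < 1)
    support_size <- max(1L, round(sparsity * n_features))
  }
  support_size <- as.integer(support_size)
  if (support_size > n_features) {
    stop("support_size cannot exceed n_features", call. = FALSE)
  }
  n_paired <- 2L * as.integer(round(correlated_fraction * support_size / 2))
  if (n_paired > support_size) n_paired <- n_paired - 2L

  with_seed(seed, {
    x <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    support <- sample.int(n_features, support_size)
    pairs <- NULL
    if (n_paired > 0L) {
      np <- n_paired %/% 2L
      s1 <- support[seq_len(np)]
      s2 <- support[np + seq_len(np)]
      x[, s2] <- x[, s1, drop = FALSE] +
        matrix(stats::rnorm(n_samples * np, sd = pair_noise_sd),
               n_samples, np)
      pairs <- cbind(first = s1, second = s2)
    }
    beta_true <- numeric(n_features)
    beta_true[support] <- beta_scale *
      sample(c(-1, 1), support_size, replace = TRUE)
    if (n_paired > 0L) {
      # members of a pair share the sign: near-duplicate columns with
      # opposite true effects would cancel in x %*% beta_true, erasing the
      # pair's signal from the labels and making it unrecoverable by design
      beta_true[pairs[, "second"]] <- beta_true[pairs[, "first"]]
    }
    eta <- drop(x %*% beta_true)
    y_true <- ifelse(eta >= 0, 1, -1)
    eta_noisy <- eta +
      if (label_noise_sd > 0) stats::rnorm(n_samples, sd = label_noise_sd)
      else 0
    y <- ifelse(eta_noisy >= 0, 1, -1)
    dimnames(x) <- list(paste0("s", seq_len(n_samples)),
                        paste0("f", seq_len(n_features)))
    structure(list(
      x = x, y = y, y_true = y_true,
      truth = list(beta_true = beta_true, support = sort(support),
                   pairs = pairs, n_paired = n_paired,
                   label_noise_sd = label_noise_sd,
                   correlated_fraction = correlated_fraction,
                   pair_noise_sd = pair_noise_sd, seed = seed)
    ), class = "sim_design")
  })
}

#' Factorial simulation grid
#'
#' Enumerates the full benchmark grid: sample and feature sizes from
#' `{50, 100, 500}`, sparsity `{0.1, 0.2}`, correlated fraction `{0, 0.5}`,
#' with `n_replicates` seeded replicates per setting (720 rows at the
#' defaults). Replicate seeds are a deterministic function of `base_seed`,
#' so the whole grid regenerates bit-identically.
#'
#' @param base_seed Integer; master seed for the grid.
#' @param n_samples,n_features,sparsity,correlated_fraction Vectors of
#'   levels to cross.
#' @param n_replicates Replicates per setting.
#' @return A data frame with one row per (setting, replicate) and a derived
#'   `seed` column, suitable for [run_benchmark()].
#' @export
simulation_grid <- function(base_seed = 1L,
                            n_samples = c(50L, 100L, 500L),
                            n_features = c(50L, 100L, 500L),
                            sparsity = c(0.1, 0.2),
                            correlated_fraction = c(0, 0.5),
                            n_replicates = 20L) {
  g <- expand.grid(replicate = seq_len(n_replicates),
                   correlated_fraction = correlated_fraction,
                   sparsity = sparsity,
                   n_features = as.integer(n_features),
                   n_samples = as.integer(n_samples),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("n_samples", "n_features", "sparsity",
             "correlated_fraction", "replicate")]
  g$seed <- as.integer((as.numeric(base_seed) + 104729 * seq_len(nrow(g))) %%
                         2147483647)
  rownames(g) <- NULL
  g
}
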