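# Independent numerical oracles used across the test files. These
# re-derive quantities from first principles (finite differences, direct
# probability products, generic optimisers, grid search) and never call
# the code paths they check.

# central finite-difference gradient of a scalar function
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# negative log-likelihood as a direct product of Bernoulli probabilities
nll_bernoulli_oracle <- function(beta, x, y) {
  p <- stats::plogis(drop(x %*% beta))        # P(y = +1 | x)
  -sum(log(ifelse(y > 0, p, 1 - p)))
}

# weighted-ridge logistic optimum via an unrelated optimiser (PORT/nlminb)
# with an independently written objective
ridge_logit_oracle <- function(x, y, w, start = NULL) {
  obj <- function(b) {
    eta <- drop(x %*% b)
    sum(log(1 + exp(-y * eta))) + 0.5 * sum(w * b^2)
  }
  if (is.null(start)) start <- numeric(ncol(x))
  stats::nlminb(start, obj, control = list(iter.max = 1000,
                                           rel.tol = 1e-14))
}

# proximal-gradient (ISTA) solver for l1-penalised logistic regression
ista_l1_oracle <- function(x, y, lambda, iters = 20000, step = NULL) {
  if (is.null(step)) step <- 4 / max(colSums(x^2)) / ncol(x) * 2
  L <- 0.25 * norm(x, "2")^2
  step <- 1 / L
  b <- numeric(ncol(x))
  for (k in seq_len(iters)) {
    g <- -drop(crossprod(x, y * stats::plogis(-y * drop(x %*% b))))
    b <- b - step * g
    b <- sign(b) * pmax(abs(b) - step * lambda, 0)
  }
  b
}

l1_objective <- function(b, x, y, lambda) {
  sum(log(1 + exp(-y * drop(x %*% b)))) + lambda * sum(abs(b))
}

# small random logistic instance with both classes guaranteed
random_instance <- function(n, m, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  b <- rnorm(m)
  y <- ifelse(drop(x %*% b) + rnorm(n) >= 0, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  list(x = x, y = y)
}
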