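# Smoothed-hinge machinery shared by the binary and ordinal trainers.
#
# The training objective is the regularized hinge risk
#   (1/n) sum_i max(0, 1 - m_i) + (lambda/2) ||w||^2
# with margins m_i = y_i (w.x_i + b) (binary) or the all-threshold sum over
# K-1 ordered thresholds (ordinal); bias and thresholds are unregularized.
# The hinge is smoothed by Huber rounding of the kink over a width delta and
# minimized by L-BFGS-B with analytic gradients under delta-continuation
# (1e-3 -> 1e-6), which is deterministic from a zero (or warm) start. The
# smoothing changes the objective by at most delta/2 per term, far below the
# convergence tolerance.

huber_hinge <- function(m, delta) {
  u <- 1 - m
  ifelse(u <= 0, 0, ifelse(u >= delta, u - delta / 2, u^2 / (2 * delta)))
}

# derivative of huber_hinge wrt the margin m
huber_hinge_dm <- function(m, delta) {
  u <- 1 - m
  ifelse(u <= 0, 0, ifelse(u >= delta, -1, -u / delta))
}

hinge_loss <- function(m) {
  r <- pmax(0, 1 - m)
  dim(r) <- dim(m)
  r
}

# exact (unsmoothed) binary objective; X is cells x genes
binary_objective <- function(X, y, w, b, lambda) {
  m <- y * (drop(X %*% w) + b)
  mean(hinge_loss(m)) + lambda / 2 * sum(w^2)
}

# exact all-threshold ordinal objective; cat_idx in 1..K, theta length K-1
ordinal_objective <- function(X, cat_idx, w, theta, lambda) {
  f <- drop(X %*% w)
  s <- outer(cat_idx, seq_along(theta), function(ci, k) ifelse(ci > k, 1, -1))
  m <- s * outer(f, theta, "-")
  mean(rowSums(hinge_loss(m))) + lambda / 2 * sum(w^2)
}

solver_deltas <- c(1e-3, 1e-6)

# L-BFGS-B stops when the objective improvement falls below factr * eps;
# objectives here are O(1), so factr = tol / eps enforces ~tol accuracy
solver_factr <- function(tol) max(tol / .Machine$double.eps, 10)

# minimize the smoothed binary objective; returns list(w, b, objective)
solve_hinge_binary <- function(X, y, lambda, tol = 1e-6, max_iter = 10000,
                               init = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  par <- if (is.null(init)) numeric(p + 1) else init
  delta <- NA_real_
  fn <- function(par) {
    w <- par[seq_len(p)]
    m <- y * (drop(X %*% w) + par[p + 1])
    mean(huber_hinge(m, delta)) + lambda / 2 * sum(w^2)
  }
  gr <- function(par) {
    w <- par[seq_len(p)]
    m <- y * (drop(X %*% w) + par[p + 1])
    g <- huber_hinge_dm(m, delta) * y / n
    c(drop(crossprod(X, g)) + lambda * w, sum(g))
  }
  conv <- 0L
  for (delta in solver_deltas) {
    opt <- optim(par, fn, gr,
      method = "L-BFGS-B",
      control = list(maxit = max_iter, factr = solver_factr(tol))
    )
    par <- opt$par
    conv <- opt$convergence
  }
  if (conv == 1L) {
    abort(sprintf("hinge solver failed to converge within %d iterations", max_iter))
  }
  w <- par[seq_len(p)]
  b <- par[p + 1]
  list(w = w, b = b, objective = binary_objective(X, y, w, b, lambda))
}

# minimize the smoothed all-threshold ordinal objective
solve_hinge_ordinal <- function(X, cat_idx, n_thresholds, lambda, tol = 1e-6,
                                max_iter = 10000, init = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  K1 <- n_thresholds
  s <- outer(cat_idx, seq_len(K1), function(ci, k) ifelse(ci > k, 1, -1))
  par <- if (is.null(init)) {
    # spread initial thresholds so categories start separated
    c(numeric(p), seq(-0.5, 0.5, length.out = K1))
  } else {
    init
  }
  delta <- NA_real_
  fn <- function(par) {
    w <- par[seq_len(p)]
    theta <- par[p + seq_len(K1)]
    m <- s * outer(drop(X %*% w), theta, "-")
    mean(rowSums(huber_hinge(m, delta))) + lambda / 2 * sum(w^2)
  }
  gr <- function(par) {
    w <- par[seq_len(p)]
    theta <- par[p + seq_len(K1)]
    m <- s * outer(drop(X %*% w), theta, "-")
    g <- huber_hinge_dm(m, delta) * s / n
    c(drop(crossprod(X, rowSums(g))) + lambda * w, -colSums(g))
  }
  conv <- 0L
  for (delta in solver_deltas) {
    opt <- optim(par, fn, gr,
      method = "L-BFGS-B",
      control = list(maxit = max_iter, factr = solver_factr(tol))
    )
    par <- opt$par
    conv <- opt$convergence
  }
  if (conv == 1L) {
    abort(sprintf("ordinal solver failed to converge within %d iterations", max_iter))
  }
  w <- par[seq_len(p)]
  theta <- par[p + seq_len(K1)]
  # the all-threshold loss yields ordered thresholds at the optimum; enforce
  # strict increase against numerically tied solutions
  theta <- sort(theta)
  tied <- which(diff(theta) <= 0)
  for (k in tied) theta[k + 1] <- theta[k] + 1e-8
  list(
    w = w, theta = theta,
    objective = ordinal_objective(X, cat_idx, w, theta, lambda)
  )
}

standardize_train <- function(Xt) {
  mu <- colMeans(Xt)
  sdv <- apply(Xt, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(x = sweep(sweep(Xt, 2, mu), 2, sdv, "/"), mean = mu, sd = sdv)
}
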