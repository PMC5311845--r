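# Primal linear L2-SVM (squared hinge loss) with per-example weights.
#
# Minimizes 0.5*||w||^2 + C * sum_i c_i * max(0, 1 - y_i*(x_i.w + b))^2
# by BFGS with analytic gradients. The squared hinge is once-differentiable,
# so quasi-Newton minimization is exact for this convex objective; this is
# the same primal formulation Percolator's internal solver optimizes, and at
# the low dimensionality of PSM feature sets each fit costs milliseconds.
#
# x: numeric matrix (n x d); y: +1/-1; weights: per-example costs c_i.
# Returns list(w, b, converged).
fit_linear_svm <- function(x, y, cost = 1, weights = NULL, w0 = NULL, b0 = 0) {
  n <- nrow(x); d <- ncol(x)
  if (is.null(weights)) weights <- rep(1, n)
  cy <- cost * weights
  obj <- function(par) {
    w <- par[1:d]; b <- par[d + 1L]
    m <- 1 - y * (drop(x %*% w) + b)
    xi <- pmax(m, 0)
    0.5 * sum(w * w) + sum(cy * xi * xi)
  }
  grad <- function(par) {
    w <- par[1:d]; b <- par[d + 1L]
    m <- 1 - y * (drop(x %*% w) + b)
    act <- m > 0
    g <- -2 * cy[act] * y[act] * m[act]
    c(w + drop(crossprod(x[act, , drop = FALSE], g)), sum(g))
  }
  start <- c(w0 %||% rep(0, d), b0)
  fit <- stats::optim(start, obj, grad, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  list(w = fit$par[1:d], b = fit$par[d + 1L], converged = fit$convergence == 0L)
}
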