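#' One-dimensional Bayesian optimization by expected improvement
#'
#' Maximizes a (possibly noisy) scalar objective over an interval using
#' a Gaussian-process surrogate with a squared-exponential kernel and
#' the expected-improvement acquisition, evaluated on a dense grid.
#' Intended for tuning a single hyperparameter such as the SVM cost on
#' an internal cross-validation objective.
#'
#' @param fn objective function of one numeric argument, maximized.
#' @param lower,upper search interval.
#' @param n_init number of initial evenly spread evaluations.
#' @param n_iter number of acquisition-driven evaluations.
#' @param noise_sd assumed observation noise sd of the objective.
#' @param seed RNG seed (jitters the initial design).
#' @return list: `x_best`, `y_best`, and the evaluation history
#'   data.frame `history`.
#' @export
bayes_opt_1d <- function(fn, lower, upper, n_init = 6, n_iter = 24,
                         noise_sd = 0.01, seed = 1L) {
  stopifnot(upper > lower, n_init >= 2, n_iter >= 0)
  with_seed(seed, {
    span <- upper - lower
    xs <- lower + span * (seq_len(n_init) - 0.5) / n_init +
      runif(n_init, -0.5, 0.5) * span / (2 * n_init)
    xs <- pmin(pmax(xs, lower), upper)
    ys <- vapply(xs, fn, numeric(1))
    ell <- span / 5
    grid <- seq(lower, upper, length.out = 201)
    kern <- function(a, b) exp(-outer(a, b, `-`)^2 / (2 * ell^2))
    for (it in seq_len(n_iter)) {
      sf2 <- max(var(ys), 1e-8)
      K <- sf2 * kern(xs, xs) + diag(noise_sd^2 + 1e-8, length(xs))
      Ks <- sf2 * kern(grid, xs)
      L <- chol(K)
      alpha <- backsolve(L, forwardsolve(t(L), ys - mean(ys)))
      mu <- mean(ys) + drop(Ks %*% alpha)
      v <- forwardsolve(t(L), t(Ks))
      s2 <- pmax(sf2 - colSums(v^2), 1e-12)
      s <- sqrt(s2)
      best <- max(ys)
      zimp <- (mu - best) / s
      ei <- (mu - best) * pnorm(zimp) + s * dnorm(zimp)
      ei[vapply(grid, function(g) any(abs(g - xs) < span / 400), logical(1))] <- 0
      x_new <- grid[which.max(ei)]
      xs <- c(xs, x_new)
      ys <- c(ys, fn(x_new))
    }
    i <- which.max(ys)
    list(x_best = xs[i], y_best = ys[i],
         history = data.frame(x = xs, y = ys))
  })
}
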