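# Independent oracles, deliberately separate from the package's fitting
# path: a simultaneous all-parameter least-squares optimizer (general
# purpose bounded quasi-Newton, PORT routines, with analytic gradient) and
# a grid-refined projection of one series onto a known true curve.

oracle_rss <- function(series, x_bounds = c(-15, 15)) {
  df <- series[!series$excluded, , drop = FALSE]
  ids <- unique(df$series_id)
  si <- match(df$series_id, ids)
  y <- df$y
  d <- df$d
  n_series <- length(ids)

  obj <- function(p) {
    pr <- plogis(p[3L] * (p[3L + si] + d))
    sum((y - (p[1L] + p[2L] * pr))^2)
  }
  grad <- function(p) {
    xx <- p[3L + si] + d
    pr <- plogis(p[3L] * xx)
    r <- y - (p[1L] + p[2L] * pr)
    core <- p[2L] * pr * (1 - pr)
    gx <- -2 * tapply(r * core * p[3L], si, sum)
    c(-2 * sum(r), -2 * sum(r * pr), -2 * sum(r * core * xx),
      as.numeric(gx[as.character(seq_len(n_series))]))
  }
  # same deterministic initialization convention as the fitter, derived here
  # from scratch
  a0 <- unname(quantile(y, 0.05))
  b0 <- max(unname(quantile(y, 0.95)) - a0, 1e-6)
  ybar <- tapply(y, si, mean)[as.character(seq_len(n_series))]
  x0 <- qlogis(pmin(pmax((as.numeric(ybar) - a0) / b0, 0.01), 0.99))
  lower <- c(-Inf, 1e-8, 1e-8, rep(x_bounds[1L], n_series))
  upper <- c(Inf, Inf, Inf, rep(x_bounds[2L], n_series))
  par <- c(a0, b0, 1, x0)
  value <- obj(par)
  # cycle two independent general-purpose optimizers until neither improves;
  # a single run of either can stall short of the optimum on this surface
  for (round in 1:20) {
    before <- value
    o1 <- nlminb(par, obj, gradient = grad, lower = lower, upper = upper,
                 control = list(iter.max = 5000, eval.max = 10000,
                                rel.tol = 1e-14))
    if (o1$objective < value) {
      par <- o1$par
      value <- o1$objective
    }
    o2 <- optim(par, obj, grad, method = "L-BFGS-B", lower = lower,
                upper = upper, control = list(maxit = 5000, factr = 10))
    if (o2$value < value) {
      par <- o2$par
      value <- o2$value
    }
    if (before - value <= 1e-12 * value) break
  }
  value
}

# least-squares position of one series against a known curve, by coarse
# grid search refined with optimize
project_on_true_curve <- function(y, d, alpha, beta, gamma,
                                  x_bounds = c(-15, 15)) {
  f <- function(x) {
    vapply(x, function(xx)
      sum((y - (alpha + beta * plogis(gamma * (xx + d))))^2), numeric(1))
  }
  grid <- seq(x_bounds[1L], x_bounds[2L], length.out = 601L)
  x0 <- grid[which.min(f(grid))]
  lo <- max(x_bounds[1L], x0 - 0.1)
  hi <- min(x_bounds[2L], x0 + 0.1)
  optimize(f, c(lo, hi), tol = 1e-10)$minimum
}
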