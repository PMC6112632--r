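# two-stage grid search over the profiled joint likelihood: for each
# centred item parameter d (delta = c(d, -d) for two dichotomous
# items), every person's theta is maximised on its own grid, and the
# grids are refined down to 0.001-logit resolution.
grid_jmle_oracle <- function(x0) {
  ll_person <- function(th, d1, d2, x) {
    # log-likelihood of one person over a theta grid
    l1 <- x[1] * (th - d1) - log(1 + exp(th - d1))
    l2 <- x[2] * (th - d2) - log(1 + exp(th - d2))
    l1 + l2
  }
  profile_ll <- function(d, th_grid) {
    tot <- 0
    th_hat <- numeric(nrow(x0))
    for (n in seq_len(nrow(x0))) {
      ll <- ll_person(th_grid, d, -d, x0[n, ])
      k <- which.max(ll)
      tot <- tot + ll[k]
      th_hat[n] <- th_grid[k]
    }
    list(ll = tot, theta = th_hat)
  }
  d_grid <- seq(-3, 3, by = 0.05)
  th_grid <- seq(-5, 5, by = 0.05)
  best <- d_grid[which.max(vapply(d_grid, function(d)
    profile_ll(d, th_grid)$ll, 0))]
  d_grid <- seq(best - 0.1, best + 0.1, by = 0.001)
  prof <- lapply(d_grid, function(d) {
    th_c <- profile_ll(d, th_grid)$theta
    fine <- lapply(seq_len(nrow(x0)), function(n)
      seq(th_c[n] - 0.1, th_c[n] + 0.1, by = 0.001))
    tot <- 0; th_hat <- numeric(nrow(x0))
    for (n in seq_len(nrow(x0))) {
      ll <- ll_person(fine[[n]], d, -d, x0[n, ])
      tot <- tot + max(ll)
      th_hat[n] <- fine[[n]][which.max(ll)]
    }
    list(ll = tot, theta = th_hat)
  })
  k <- which.max(vapply(prof, `[[`, 0, "ll"))
  list(delta = c(d_grid[k], -d_grid[k]), theta = prof[[k]]$theta)
}
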