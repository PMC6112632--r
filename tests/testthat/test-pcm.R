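test_that("category probabilities normalise and obey logistic symmetry", {
  # dichotomous item at theta = delta -> P(1) = 0.5
  p <- pcm_probabilities(0.7, 0.7)
  expect_equal(p[1, 2], 0.5)

  # normalisation at machine precision over random parameter draws
  set.seed(11)
  for (r in 1:20) {
    th <- stats::rnorm(7, sd = 2)
    d <- stats::rnorm(sample(1:4, 1), sd = 1.5)
    pm <- pcm_probabilities(th, d)
    expect_equal(rowSums(pm), rep(1, 7), tolerance = 1e-12)
    expect_true(all(pm >= 0))
  }
})

test_that("JMLE matches a grid-search maximiser of the joint likelihood", {
  spec <- dicho_spec(2L)
  m <- rbind(c(2L, 1L), c(1L, 2L), c(2L, 1L))   # codes 1/2
  rm <- rm_from(m, spec)
  fit <- fit_pcm(rm, tol = 1e-7, score_tol = 1e-7, max_iter = 5000L)
  oracle <- grid_jmle_oracle(m - 1L)
  expect_equal(unname(unlist(fit$thresholds)), oracle$delta,
               tolerance = 0.0015)
  expect_equal(unname(fit$theta), oracle$theta, tolerance = 0.0015)
})

test_that("score-to-measure table is monotone and inverts the TCC", {
  sim <- shared_sim()
  fit <- fit_pcm(sim$responses)
  tab <- score_to_measure(fit)

  expect_true(all(diff(tab$measure) > 0))
  expect_true(all(tab$se > 0))
  expect_equal(nrow(tab), 53 - 17 + 1)
  expect_equal(range(tab$score), c(17, 53))

  # round-trip: expected score at theta(s) equals s for interior scores
  for (i in seq(2, nrow(tab) - 1, by = 7)) {
    e <- sum(vapply(fit$thresholds, function(d) {
      p <- pcm_probabilities(tab$measure[i], d)
      sum(p * (seq_along(p) - 1))
    }, 0))
    expect_equal(e + 17, tab$score[i], tolerance = 1e-6)
  }
})

test_that("two-item symmetric test has measure zero at the middle score", {
  # delta = (-1, +1): at raw score 1 of 2 the TCC crosses at theta = 0
  spec <- dicho_spec(2L)
  set.seed(3)
  m <- matrix(sample(1:2, 120, replace = TRUE), 60, 2)
  rm <- rm_from(m, spec)
  fit <- fit_pcm(rm, on_nonconverge = "warn")
  fit$thresholds <- list(d1 = -1, d2 = 1)
  tab <- score_to_measure(fit)
  expect_equal(tab$measure[tab$score == 3], 0, tolerance = 1e-8)

  # bisection oracle on the test characteristic curve, including the
  # 0.3-unit adjusted extreme scores
  tcc <- function(th) sum(vapply(fit$thresholds, function(d)
    1 / (1 + exp(-(th - d))), 0))
  targets <- c(0.3, 1, 1.7)
  for (k in 1:3) {
    root <- stats::uniroot(function(th) tcc(th) - targets[k], c(-30, 30),
                           tol = 1e-12)$root
    expect_equal(tab$measure[k], root, tolerance = 1e-6)
  }
})

test_that("fit statistics equal hand arithmetic on a known-parameter fit", {
  spec <- dicho_spec(2L)
  x0 <- rbind(c(1L, 0L), c(0L, 1L))
  theta <- c(0.5, -0.5)
  thr <- list(d1 = 0.2, d2 = -0.3)
  fit <- fake_fit(theta, thr, x0, spec)

  pr <- function(th, d) 1 / (1 + exp(-(th - d)))
  E <- rbind(c(pr(0.5, 0.2), pr(0.5, -0.3)),
             c(pr(-0.5, 0.2), pr(-0.5, -0.3)))
  V <- E * (1 - E)
  y <- x0 - E
  fs <- fit_statistics(fit)
  expect_equal(fs$person$outfit, rowMeans(y^2 / V), tolerance = 1e-12)
  expect_equal(fs$person$infit, rowSums(y^2) / rowSums(V), tolerance = 1e-12)
  expect_equal(fs$item$outfit, unname(colMeans(y^2 / V)), tolerance = 1e-12)
  expect_equal(fs$item$infit, unname(colSums(y^2) / colSums(V)),
               tolerance = 1e-12)
})

test_that("item infit is near 1 on model-conforming data", {
  sim <- simulate_responses(sim_config(n_persons = 1000, missing_rate = 0),
                            seed = 99)
  fit <- fit_pcm(sim$responses)
  fs <- fit_statistics(fit)
  expect_gt(mean(fs$item$infit), 0.9)
  expect_lt(mean(fs$item$infit), 1.1)
})

test_that("separation obeys the PSI-reliability identity and degenerates", {
  sim <- shared_sim()
  fit <- fit_pcm(sim$responses)
  ps <- person_separation(fit)
  expect_equal(ps$reliability, ps$psi^2 / (1 + ps$psi^2), tolerance = 1e-12)

  # identical measures -> no true variance -> PSI 0
  fit2 <- fit
  act <- fit2$answered > 0 & !fit2$extreme
  fit2$theta[act] <- 0.3
  expect_equal(person_separation(fit2)$psi, 0)
})

test_that("targeting is zero for a sample centred on the items", {
  sim <- shared_sim()
  fit <- fit_pcm(sim$responses)
  act <- fit$answered > 0 & !fit$extreme
  fit$theta[act] <- fit$theta[act] - mean(fit$theta[act]) +
    mean(fit$item_difficulty)
  expect_equal(targeting(fit), 0, tolerance = 1e-12)
})

test_that("residual PCA eigenvalues sum to the item count", {
  sim <- shared_sim()
  fit <- fit_pcm(sim$responses)
  d <- residual_pca(fit)
  expect_equal(sum(d$eigenvalues), length(fit$items), tolerance = 1e-8)
  expect_gte(d$raw_variance_explained, 0)
  expect_lte(d$raw_variance_explained, 100)
  expect_gt(d$first_contrast_eigenvalue, 0)
})

test_that("a unidimensional subscale shows a weak first contrast", {
  set.seed(5)
  ok <- 0L
  for (r in 1:10) {
    sim <- simulate_responses(sim_config(n_persons = 400, missing_rate = 0))
    sub <- subscale_spec(sim$responses$spec, "ESF")
    rms <- response_matrix(sim$responses$responses[, sub$item_ids], sub)
    fit <- fit_pcm(rms, on_nonconverge = "warn")
    if (residual_pca(fit)$first_contrast_eigenvalue < 2.0) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("unobserved categories are collapsed with a warning", {
  spec <- toy_spec3()
  set.seed(8)
  m <- matrix(sample(c(1L, 3L), 90, replace = TRUE), 30, 3)  # code 2 absent
  m[1, 1] <- 1L; m[2, 1] <- 3L
  rm <- rm_from(m, spec)
  expect_warning(fit <- fit_pcm(rm, on_nonconverge = "warn"), "collapsed")
  expect_true(all(vapply(fit$thresholds, length, 0L) == 1L))
})
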