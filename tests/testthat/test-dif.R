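# simulate one data set, duplicate it across two groups, with an
# optional difficulty shift injected into one item for group "B"
two_group_sim <- function(n_per_group, shift_item = NULL, shift = 0,
                          seed = 1) {
  set.seed(seed)
  spec <- cvss17_spec()
  thr <- default_thresholds(spec)
  theta <- stats::rnorm(2 * n_per_group, 0.3, 1)
  grp <- rep(c("A", "B"), each = n_per_group)
  m <- matrix(NA_integer_, 2 * n_per_group, 17,
              dimnames = list(NULL, spec$item_ids))
  for (it in spec$item_ids) {
    d <- thr[[it]]
    x <- integer(2 * n_per_group)
    for (g in c("A", "B")) {
      dg <- d
      if (identical(it, shift_item) && g == "B") dg <- d + shift
      sel <- grp == g
      p <- pcm_probabilities(theta[sel], dg)
      cp <- t(apply(p, 1, cumsum))
      u <- stats::runif(sum(sel))
      x[sel] <- as.integer(rowSums(u > cp[, -ncol(cp), drop = FALSE]))
    }
    m[, it] <- x + 1L
  }
  list(rm = response_matrix(m, spec), group = factor(grp))
}

test_that("MH DIF size matches direct 2x2xK Mantel-Haenszel arithmetic", {
  # constructed dichotomous item over 3 strata; the scale raw score is
  # forced to define the strata via a highly informative second item
  spec <- dicho_spec(2L)
  # stratum k: persons with anchor item code k pattern; build by hand
  # counts per stratum: group A: a of 10 score 1; group B: c of 10
  a_k <- c(7, 5, 3); c_k <- c(5, 3, 1)
  rows <- list(); grp <- c()
  for (k in 1:3) {
    for (g in c("A", "B")) {
      n1 <- if (g == "A") a_k[k] else c_k[k]
      x <- c(rep(1L, n1), rep(0L, 10 - n1))
      anchor <- rep(k - 1L, 10)
      rows[[length(rows) + 1L]] <- cbind(x, anchor)
      grp <- c(grp, rep(g, 10))
    }
  }
  m0 <- do.call(rbind, rows)
  # anchor needs codes 1..3 -> 3-category second item
  sp <- scale_spec(c("tgt", "anchor"), c(2L, 3L), "S")
  rm <- rm_from(m0 + 1L, sp)
  fit <- fit_pcm(rm, on_nonconverge = "warn")
  out <- dif_mantel(fit, factor(grp), "tgt", min_per_cell = 3L,
                    strata = m0[, "anchor"])

  # oracle: classical MH common odds ratio over the three 2x2 tables,
  # reported on the difficulty metric (minus the log-odds)
  num <- 0; den <- 0
  for (k in 1:3) {
    a <- a_k[k]; b <- 10 - a_k[k]; cc <- c_k[k]; d <- 10 - c_k[k]
    nt <- 20
    num <- num + a * d / nt
    den <- den + b * cc / nt
  }
  expect_equal(out$size, -log(num / den), tolerance = 1e-10)
})

test_that("identical group distributions give zero DIF by both methods", {
  tg <- two_group_sim(150, seed = 31)
  # duplicate group A's responses into group B -> literally identical
  n <- 150
  m <- tg$rm$responses
  m[(n + 1):(2 * n), ] <- m[1:n, ]
  rm <- response_matrix(m, tg$rm$spec)
  fit <- fit_pcm(rm, on_nonconverge = "warn")
  mh <- dif_mantel(fit, tg$group, "A9")
  ld <- dif_logit_difference(fit, tg$group, "A9")
  expect_equal(mh$size, 0, tolerance = 1e-10)
  expect_equal(ld$size, 0, tolerance = 1e-10)
})

test_that("DIF size reverses sign when group labels swap", {
  tg <- two_group_sim(200, shift_item = "A21", shift = 0.6, seed = 37)
  fit <- fit_pcm(tg$rm, on_nonconverge = "warn")
  flip <- factor(tg$group, levels = c("B", "A"))
  mh1 <- dif_mantel(fit, tg$group, "A21")
  mh2 <- dif_mantel(fit, flip, "A21")
  expect_equal(mh1$size, -mh2$size, tolerance = 1e-10)
  ld1 <- dif_logit_difference(fit, tg$group, "A21")
  ld2 <- dif_logit_difference(fit, flip, "A21")
  expect_equal(ld1$size, -ld2$size, tolerance = 1e-10)
  # both methods agree in sign on the injected shift (harder for B)
  expect_equal(sign(mh1$size), sign(ld1$size))
  expect_lt(ld1$size, 0)
  expect_gt(abs(ld1$size), 0.2)
})

test_that("anchored logit-difference recovers an injected 0.6-logit shift", {
  tg <- two_group_sim(300, shift_item = "C16", shift = 0.6, seed = 41)
  fit <- fit_pcm(tg$rm, on_nonconverge = "warn")
  ld <- dif_logit_difference(fit, tg$group, "C16")
  # item is harder for group B; size is group A minus group B difficulty
  expect_lt(ld$size, -0.4)
  expect_gt(ld$size, -0.8)
  expect_lt(ld$p, 0.05)
  mh <- dif_mantel(fit, tg$group, "C16")
  expect_lt(mh$size, 0)  # easier for group A on the difficulty metric
})

test_that("null DIF is centred at zero over repeated simulations", {
  sizes <- numeric(20)
  for (r in 1:20) {
    tg <- two_group_sim(100, seed = 100 + r)
    fit <- fit_pcm(tg$rm, on_nonconverge = "warn")
    sizes[r] <- dif_logit_difference(fit, tg$group, "A17")$size
  }
  expect_lt(abs(mean(sizes)), 0.08)
})

test_that("the DIF report flags by threshold and undefined cases", {
  tg <- two_group_sim(150, shift_item = "A32", shift = 1.2, seed = 43)
  fit <- fit_pcm(tg$rm, on_nonconverge = "warn")
  rep <- dif_report(fit, list(grp = tg$group), threshold = 0.5)
  expect_true(all(c("MH", "logit_diff") %in% rep$method))
  expect_equal(nrow(rep), 17 * 2)
  a32 <- rep[rep$item == "A32" & rep$method == "logit_diff", ]
  expect_true(a32$flagged)
  expect_identical(rep$flagged, !is.na(rep$size) & abs(rep$size) > 0.5)
})

test_that("quality grades reproduce the published subscale panels", {
  g <- grade_quality(list(
    infit_items_outside = 0, outfit_items_outside = 0,
    variance_explained = 53.0, first_contrast = 1.71,
    psi = 2.61, level_reliability = 0.96, targeting = -0.41,
    dif_gender_flags = 0, dif_age_flags = 0))
  got <- stats::setNames(g$grade, g$property)
  expect_equal(unname(got[c("psi", "targeting", "variance_explained",
                            "first_contrast", "level_reliability")]),
               c("A", "A", "B", "B", "A"))

  g2 <- grade_quality(list(
    infit_items_outside = 0, outfit_items_outside = 2,
    variance_explained = 56.1, first_contrast = 1.78,
    psi = 1.63, level_reliability = 0.92, targeting = -1.27,
    dif_gender_flags = 0, dif_age_flags = 0))
  got2 <- stats::setNames(g2$grade, g2$property)
  expect_equal(unname(got2[c("psi", "targeting", "outfit_items_outside",
                             "variance_explained", "first_contrast")]),
               c("C", "B", "B", "B", "B"))

  # grading is total over supplied properties, missing -> not assessed
  g3 <- grade_quality(list(psi = 2.0))
  expect_equal(g3$grade[g3$property == "psi"], "B")
  expect_true(all(g3$grade[g3$property != "psi"] == "not assessed"))
})
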