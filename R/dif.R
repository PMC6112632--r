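# Pool adjacent raw-score strata until each stratum has at least
# min_per_cell persons in both groups. Returns an integer stratum id
# per person (NA when unusable).
pool_strata <- function(score, group, min_per_cell = 5L) {
  lv <- sort(unique(score))
  bins <- match(score, lv)
  repeat {
    tab <- table(factor(bins, levels = sort(unique(bins))), group)
    thin <- which(apply(tab, 1L, min) < min_per_cell)
    if (!length(thin) || nrow(tab) <= 1L) break
    ids <- as.integer(rownames(tab))
    j <- ids[thin[1L]]
    nb <- if (j == max(ids)) max(ids[ids < j]) else min(ids[ids > j])
    bins[bins == j] <- nb
  }
  bins
}

#' Mantel-Haenszel differential item functioning
#'
#' Persons are stratified by their raw scale score (thin strata pooled
#' until both groups have at least `min_per_cell` members per stratum).
#' The DIF size is the Mantel-Haenszel common log-odds ratio pooled
#' over all strata and cumulative category splits (a Liu-Agresti-style
#' cumulative common log-odds), expressed on the item-difficulty
#' metric: positive means the item is harder for the first group at a
#' matched score (the same convention as [dif_logit_difference()], so
#' the two methods agree in sign). Significance comes from the Mantel
#' chi-square for stratified ordinal tables (1 df).
#'
#' @param fit a [fit_pcm()] result.
#' @param grouping factor with exactly 2 levels per person (NAs dropped).
#' @param item item id to test.
#' @param min_per_cell minimum persons per group per stratum (default 5).
#' @param strata optional matching variable per person; defaults to the
#'   raw scale score.
#' @return list with `size` (logits), `chi2`, `p`, `n_strata`; all `NA`
#'   with `flagged_undefined = TRUE` when fewer than 2 usable strata
#'   remain.
#' @export
dif_mantel <- function(fit, grouping, item, min_per_cell = 5L,
                       strata = NULL) {
  j <- match(item, fit$items)
  if (is.na(j)) stop("unknown item: ", item)
  g <- factor(grouping)
  x <- fit$x0[, j]
  score <- if (is.null(strata)) rowSums(fit$x0, na.rm = TRUE)
           else as.numeric(strata)
  ok <- !is.na(x) & !is.na(g) & fit$answered > 0L
  g <- droplevels(g[ok]); x <- x[ok]; score <- score[ok]
  if (nlevels(g) != 2L) stop("grouping must have exactly 2 levels")

  bins <- pool_strata(score, g, min_per_cell)
  usable <- integer(0)
  for (b in sort(unique(bins))) {
    sel <- bins == b
    if (length(unique(g[sel])) == 2L && length(unique(x[sel])) > 1L)
      usable <- c(usable, b)
  }
  if (length(usable) < 2L)
    return(list(size = NA_real_, chi2 = NA_real_, p = NA_real_,
                n_strata = length(usable), flagged_undefined = TRUE))

  num <- 0; den <- 0          # MH pooled cumulative odds
  S <- 0; E <- 0; V <- 0      # Mantel statistic pieces
  gA <- levels(g)[1L]
  for (b in usable) {
    sel <- bins == b
    xa <- x[sel & g == gA]; xb <- x[sel & g != gA]
    for (cpt in seq_len(max(x[sel]))) {
      a <- sum(xa >= cpt); bb <- sum(xa < cpt)
      cc <- sum(xb >= cpt); dd <- sum(xb < cpt)
      nt <- a + bb + cc + dd
      if (nt > 0) { num <- num + a * dd / nt; den <- den + bb * cc / nt }
    }
    xs <- x[sel]; nA <- length(xa); nB <- length(xb); Nk <- nA + nB
    S <- S + sum(xa)
    E <- E + nA * mean(xs)
    V <- V + nA * nB / (Nk * (Nk - 1)) * sum((xs - mean(xs))^2)
  }
  # higher odds of high categories for group A = easier for A, so the
  # difficulty-metric size is minus the common log-odds
  size <- if (num > 0 && den > 0) -log(num / den) else NA_real_
  chi2 <- if (V > 0) (S - E)^2 / V else NA_real_
  list(size = size, chi2 = chi2,
       p = if (is.na(chi2)) NA_real_ else
         stats::pchisq(chi2, 1, lower.tail = FALSE),
       n_strata = length(usable), flagged_undefined = FALSE)
}

# Solve for a uniform shift d of one item's thresholds, holding person
# measures fixed, so that the item's expected scores match the observed
# total (anchored one-item estimation).
solve_item_shift <- function(theta, x, delta, tol = 1e-8, max_iter = 100L) {
  d <- 0
  for (it in seq_len(max_iter)) {
    mo <- item_moments(theta, delta + d)
    u <- sum(mo$e) - sum(x)           # expected minus observed
    v <- sum(mo$v)
    if (v < 1e-10) return(list(shift = NA_real_, se = NA_real_))
    step <- max(min(u / v, 1), -1)    # higher d lowers E, so move with u
    d <- d + step
    if (abs(step) < tol) break
  }
  mo <- item_moments(theta, delta + d)
  list(shift = d, se = 1 / sqrt(sum(mo$v)))
}

#' Logit-difference (anchored) differential item functioning
#'
#' Re-estimates the target item's difficulty separately in each group
#' while anchoring all person measures and every other item at the
#' overall estimates; the DIF size is the difficulty difference
#' (group 1 minus group 2) in logits, positive meaning the item is
#' harder for group 1. A Wald p-value combines the two anchored
#' standard errors.
#'
#' @inheritParams dif_mantel
#' @return list with `size` (logits), `se`, `z`, `p`; `NA` with
#'   `flagged_undefined = TRUE` when a group has no variance on the
#'   item.
#' @export
dif_logit_difference <- function(fit, grouping, item) {
  j <- match(item, fit$items)
  if (is.na(j)) stop("unknown item: ", item)
  g <- factor(grouping)
  x <- fit$x0[, j]
  ok <- !is.na(x) & !is.na(g) & fit$answered > 0L & !fit$extreme
  g <- droplevels(g[ok]); x <- x[ok]; th <- fit$theta[ok]
  if (nlevels(g) != 2L) stop("grouping must have exactly 2 levels")
  delta <- fit$thresholds[[j]]

  res <- lapply(levels(g), function(lv) {
    sel <- g == lv
    if (length(unique(x[sel])) < 2L) return(NULL)
    solve_item_shift(th[sel], x[sel], delta)
  })
  if (any(vapply(res, is.null, TRUE)) ||
      any(vapply(res, function(r) is.na(r$shift), TRUE)))
    return(list(size = NA_real_, se = NA_real_, z = NA_real_,
                p = NA_real_, flagged_undefined = TRUE))
  size <- res[[1L]]$shift - res[[2L]]$shift
  se <- sqrt(res[[1L]]$se^2 + res[[2L]]$se^2)
  z <- size / se
  list(size = size, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       flagged_undefined = FALSE)
}

#' DIF screen of every item by both methods
#'
#' @param fit a [fit_pcm()] result.
#' @param contrasts named list of 2-level groupings per person (e.g.
#'   `list(gender = ..., age_group = ...)`).
#' @param threshold absolute DIF size (logits) above which an item is
#'   flagged (default 0.5, the conventional screening level).
#' @return data.frame of class `dif_report`: `item`, `contrast`,
#'   `method` (`"MH"`/`"logit_diff"`), `size`, `p`, `flagged`.
#' @export
dif_report <- function(fit, contrasts, threshold = 0.5) {
  rows <- list()
  for (ct in names(contrasts)) {
    g <- contrasts[[ct]]
    for (it in fit$items) {
      mh <- dif_mantel(fit, g, it)
      ld <- dif_logit_difference(fit, g, it)
      rows[[length(rows) + 1L]] <- data.frame(
        item = it, contrast = ct,
        method = c("MH", "logit_diff"),
        size = c(mh$size, ld$size), p = c(mh$p, ld$p),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$flagged <- !is.na(out$size) & abs(out$size) > threshold
  class(out) <- c("dif_report", "data.frame")
  out
}

#' Default A/B/C quality-grade cut-points
#'
#' Boundaries for grading a subscale's psychometric report, in the
#' style of published quality-appraisal guidelines for ophthalmic
#' questionnaires. Each entry is a function value -> grade; all are
#' user-replaceable.
#'
#' @return named list of grading functions.
#' @export
quality_cutpoints <- function() {
  list(
    infit_items_outside = function(v) if (v == 0) "A" else if (v <= 2) "B" else "C",
    outfit_items_outside = function(v) if (v == 0) "A" else if (v <= 2) "B" else "C",
    variance_explained = function(v) if (v >= 60) "A" else if (v >= 40) "B" else "C",
    first_contrast = function(v) if (v < 1.5) "A" else if (v <= 2.0) "B" else "C",
    psi = function(v) if (v >= 2.5) "A" else if (v >= 2.0) "B" else "C",
    level_reliability = function(v) if (v >= 0.9) "A" else if (v >= 0.8) "B" else "C",
    targeting = function(v) if (abs(v) <= 1) "A" else if (abs(v) <= 2) "B" else "C",
    dif_gender_flags = function(v) if (v == 0) "A" else if (v <= 2) "B" else "C",
    dif_age_flags = function(v) if (v == 0) "A" else if (v <= 2) "B" else "C")
}

#' Grade a psychometric report on an A/B/C scale
#'
#' Maps each supplied property value to a grade through the configured
#' cut-points (A high, B medium, C low); properties without a supplied
#' value are reported as `"not assessed"`.
#'
#' @param values named list/vector of property values; recognised names
#'   are those of [quality_cutpoints()].
#' @param cutpoints grading functions, defaults to [quality_cutpoints()].
#' @return data.frame of class `quality_report`: `property`, `value`,
#'   `grade`.
#' @export
grade_quality <- function(values, cutpoints = quality_cutpoints()) {
  out <- data.frame(property = names(cutpoints),
                    value = NA_real_, grade = "not assessed",
                    stringsAsFactors = FALSE)
  for (i in seq_along(cutpoints)) {
    pr <- names(cutpoints)[i]
    if (!is.null(values[[pr]]) && !is.na(values[[pr]])) {
      out$value[i] <- as.numeric(values[[pr]])
      out$grade[i] <- cutpoints[[pr]](out$value[i])
    }
  }
  class(out) <- c("quality_report", "data.frame")
  out
}
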