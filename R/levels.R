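#' Number of statistically distinct levels of performance
#'
#' Wright's sample-independent strata count from a score-to-measure
#' table: the measure range of the scale divided by `multiplier` times
#' the root mean square of the score standard errors. With the default
#' multiplier of 3, adjacent level centres are three error units apart —
#' the conventional spacing for statistically different at p < .05.
#' The companion reliability is `L^2 / (1 + L^2)`.
#'
#' @param table a [score_to_measure()] table (columns `measure`, `se`).
#' @param multiplier error-unit spacing between distinguishable levels
#'   (default 3).
#' @param include_extremes include the extrapolated extreme-score rows
#'   in the RMSE pooling (default `FALSE`; the measure range always uses
#'   the full table).
#' @return list with `levels` (fractional count, floored at 1) and
#'   `reliability`.
#' @export
count_levels <- function(table, multiplier = 3, include_extremes = FALSE) {
  if (nrow(table) < 2L) stop("score table needs at least 2 rows")
  rng <- max(table$measure) - min(table$measure)
  keep <- if (!include_extremes && "extreme" %in% names(table))
    !table$extreme else rep(TRUE, nrow(table))
  se <- table$se[keep]
  if (any(!is.finite(se)) || any(se <= 0)) stop("positive finite SEs required")
  L <- max(1, rng / (multiplier * sqrt(mean(se^2))))
  list(levels = L, reliability = L^2 / (1 + L^2))
}

#' Derive raw-score cutoffs for the performance levels
#'
#' Divides the measure range into `ceiling(L)` equal-width bands and
#' maps each band edge back to the smallest raw score whose measure
#' reaches it, yielding half-open score intervals `[b_j, b_{j+1})` with
#' the top interval closed.
#'
#' @param table a [score_to_measure()] table.
#' @param L fractional level count from [count_levels()].
#' @return object of class `level_scheme`: `boundaries` (raw scores,
#'   first = scale minimum, last = scale maximum), `n_levels`,
#'   `n_levels_fractional`, `reliability`.
#' @export
derive_cutoffs <- function(table, L) {
  if (L < 1) stop("L must be >= 1")
  nlev <- max(1L, as.integer(ceiling(L - 1e-9)))
  th_min <- min(table$measure); th_max <- max(table$measure)
  edges <- th_min + (th_max - th_min) * seq(0, 1, length.out = nlev + 1L)
  ord <- order(table$score)
  sc <- table$score[ord]; ms <- table$measure[ord]
  bound <- integer(nlev + 1L)
  bound[1L] <- sc[1L]
  for (j in 2:nlev) bound[j] <- sc[which(ms >= edges[j])[1L]]
  bound[nlev + 1L] <- sc[length(sc)]
  if (any(diff(bound) <= 0))
    stop("degenerate cutoffs: too many levels for the score range")
  structure(
    list(boundaries = bound, n_levels = nlev, n_levels_fractional = L,
         reliability = L^2 / (1 + L^2), collapsed = rep(FALSE, nlev)),
    class = "level_scheme")
}

#' @export
print.level_scheme <- function(x, ...) {
  b <- x$boundaries; k <- x$n_levels
  iv <- paste0("[", b[-(k + 1L)], ",", b[-1L],
               c(rep(")", k - 1L), "]"))
  cat("<level_scheme> ", k, " levels (fractional ",
      round(x$n_levels_fractional, 1), ", reliability ",
      round(x$reliability, 2), ")\n  ", paste(iv, collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Merge sparsely occupied levels
#'
#' Any level holding less than `min_share` of the scored sample is
#' merged into its adjacent lower level (the bottom level, having no
#' lower neighbour, merges upward), repeating until stable.
#'
#' @param scheme a [derive_cutoffs()] scheme.
#' @param counts integer vector of persons per level (length
#'   `scheme$n_levels`).
#' @param min_share minimum occupancy share to keep a level (default 0.01).
#' @return a `level_scheme` with merged boundaries; `collapsed` flags
#'   the levels that absorbed a neighbour.
#' @export
collapse_sparse_levels <- function(scheme, counts, min_share = 0.01) {
  stopifnot(length(counts) == scheme$n_levels)
  b <- scheme$boundaries
  cnt <- as.numeric(counts)
  collapsed <- rep(FALSE, length(cnt))
  repeat {
    share <- cnt / sum(cnt)
    sparse <- which(share < min_share)
    if (!length(sparse)) break
    if (length(cnt) <= 2L)
      stop("cannot collapse below 2 levels")
    j <- sparse[length(sparse)]        # merge from the top down
    into <- if (j == 1L) 2L else j - 1L
    lo <- min(j, into); hi <- max(j, into)
    cnt[lo] <- cnt[lo] + cnt[hi]
    cnt <- cnt[-hi]
    b <- b[-hi]                        # drop the internal boundary
    collapsed <- collapsed[-hi]
    collapsed[lo] <- TRUE
  }
  structure(
    list(boundaries = b, n_levels = length(cnt),
         n_levels_fractional = scheme$n_levels_fractional,
         reliability = scheme$reliability, collapsed = collapsed),
    class = "level_scheme")
}

#' Assign a raw score to its performance level
#'
#' @param scheme a `level_scheme`.
#' @param score integer raw score(s) within the scale range.
#' @return integer level index (1-based); intervals are half-open
#'   `[b_j, b_{j+1})` with the top interval closed.
#' @export
assign_level <- function(scheme, score) {
  b <- scheme$boundaries
  if (any(score < b[1L] | score > b[length(b)], na.rm = TRUE))
    stop("score out of scale range [", b[1L], ",", b[length(b)], "]")
  idx <- findInterval(score, b, rightmost.closed = TRUE)
  idx[is.na(score)] <- NA_integer_
  idx
}

#' Tabulate level occupancy for a scored sample
#'
#' @param scheme a `level_scheme`.
#' @param scores integer raw scores (NAs dropped).
#' @return integer vector of counts per level.
#' @export
level_counts <- function(scheme, scores) {
  lv <- assign_level(scheme, scores[!is.na(scores)])
  tabulate(lv, nbins = scheme$n_levels)
}
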