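#' Linear discriminant classification of persons into levels
#'
#' Fisher linear discriminant functions on the factor scores, with
#' classification by maximum posterior under configurable priors
#' (equal by default, as SPSS's "all groups equal"). Reports the
#' resubstitution confusion matrix and accuracy — the "% of cases
#' correctly classified" figure of classical DA output — plus Wilks'
#' lambda and its chi-square test for each successive set of functions,
#' and optionally leave-one-out cross-validated accuracy.
#'
#' @param scores numeric matrix persons x features (e.g. two factor
#'   scores).
#' @param levels integer or factor group label per person.
#' @param prior `"equal"` (default) or `"proportional"`.
#' @param cv also compute leave-one-out accuracy (default `TRUE`).
#' @return object of class `da_result`: `confusion`, `accuracy`
#'   (percent), `cv_accuracy`, `wilks` (data.frame per function set),
#'   `centroids`, `scaling`, and the underlying [MASS::lda] fit.
#' @export
fit_lda <- function(scores, levels, prior = c("equal", "proportional"),
                    cv = TRUE) {
  prior <- match.arg(prior)
  scores <- as.matrix(scores)
  g <- factor(levels)
  ok <- stats::complete.cases(scores) & !is.na(g)
  scores <- scores[ok, , drop = FALSE]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("each group needs at least 2 members")
  pr <- if (prior == "equal") rep(1 / k, k) else as.vector(table(g) / length(g))

  fit <- MASS::lda(scores, grouping = g, prior = pr)
  pred <- stats::predict(fit)$class
  confusion <- table(true = g, predicted = pred)
  accuracy <- 100 * sum(diag(confusion)) / sum(confusion)

  cv_accuracy <- NA_real_
  if (cv) {
    cvfit <- MASS::lda(scores, grouping = g, prior = pr, CV = TRUE)
    cv_accuracy <- 100 * mean(cvfit$class == g)
  }

  # Wilks' lambda from the eigenvalues of W^{-1} B
  n <- nrow(scores); p <- ncol(scores)
  gm <- colMeans(scores)
  B <- matrix(0, p, p); W <- matrix(0, p, p)
  for (lv in levels(g)) {
    Xg <- scores[g == lv, , drop = FALSE]
    mg <- colMeans(Xg)
    B <- B + nrow(Xg) * tcrossprod(mg - gm)
    W <- W + crossprod(sweep(Xg, 2L, mg))
  }
  ev <- sort(Re(eigen(solve(W, B), only.values = TRUE)$values),
             decreasing = TRUE)
  ev <- pmax(ev, 0)[seq_len(min(p, k - 1L))]
  wilks <- data.frame(functions = character(0), lambda = numeric(0),
                      chi2 = numeric(0), df = numeric(0), p = numeric(0))
  for (s in seq_along(ev)) {
    lam <- prod(1 / (1 + ev[s:length(ev)]))
    chi2 <- -(n - 1 - (p + k) / 2) * log(lam)
    df <- (p - s + 1) * (k - s)
    wilks <- rbind(wilks, data.frame(
      functions = paste0(s, "..", length(ev)), lambda = lam, chi2 = chi2,
      df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE)))
  }

  structure(
    list(confusion = confusion, accuracy = accuracy,
         cv_accuracy = cv_accuracy, wilks = wilks,
         centroids = fit$means, scaling = fit$scaling, prior = pr,
         lda = fit),
    class = "da_result")
}

#' @export
print.da_result <- function(x, ...) {
  cat("<da_result> resubstitution accuracy ",
      round(x$accuracy, 1), "%", sep = "")
  if (!is.na(x$cv_accuracy))
    cat(" (leave-one-out ", round(x$cv_accuracy, 1), "%)", sep = "")
  cat("\n")
  print(x$confusion)
  invisible(x)
}

#' Kruskal-Wallis comparison of scores across groups
#'
#' Tie-corrected rank-based H statistic with a chi-square p-value on
#' `groups - 1` degrees of freedom (delegates to [stats::kruskal.test]).
#'
#' @param values numeric scores per person.
#' @param groups group label per person (NAs dropped pairwise).
#' @return list with `H`, `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  ok <- !is.na(values) & !is.na(g)
  g <- droplevels(g[ok]); v <- values[ok]
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (length(unique(v)) == 1L)
    return(list(H = 0, df = nlevels(g) - 1L, p = 1, n = length(v)))
  kt <- stats::kruskal.test(v, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = length(v))
}

#' Dunn's post hoc pairwise comparisons
#'
#' For each group pair, the z statistic compares mean ranks with the
#' tie-corrected standard error
#' `sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))`, where
#' `T = sum(t^3 - t) / (12(N - 1))` over tie groups. Two-sided p-values
#' are Bonferroni-adjusted over the number of pairs and capped at 1.
#'
#' @param values numeric scores per person.
#' @param groups group label per person.
#' @param adjustment `"bonferroni"` (default) or `"none"`.
#' @return data.frame with `group1`, `group2`, `z`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups, adjustment = c("bonferroni", "none")) {
  adjustment <- match.arg(adjustment)
  g <- factor(groups)
  ok <- !is.na(values) & !is.na(g)
  g <- droplevels(g[ok]); v <- values[ok]
  lv <- levels(g)
  if (length(lv) < 2L) stop("need at least 2 groups")
  N <- length(v)
  rk <- rank(v)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(rk, g, mean)
  n_g <- tabulate(g)
  pairs <- utils::combn(seq_along(lv), 2L)
  m <- ncol(pairs)
  out <- data.frame(group1 = lv[pairs[1L, ]], group2 = lv[pairs[2L, ]],
                    z = NA_real_, p_unadjusted = NA_real_,
                    p_adjusted = NA_real_, stringsAsFactors = FALSE)
  for (c_ in seq_len(m)) {
    i <- pairs[1L, c_]; j <- pairs[2L, c_]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[i] + 1 / n_g[j]))
    z <- (mean_rank[[i]] - mean_rank[[j]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    out$z[c_] <- z
    out$p_unadjusted[c_] <- p
    out$p_adjusted[c_] <- if (adjustment == "bonferroni") min(1, p * m) else p
  }
  out
}
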