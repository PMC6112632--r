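#' Sampling adequacy and sphericity checks for factor analysis
#'
#' Kaiser-Meyer-Olkin index from squared correlations versus squared
#' anti-image partial correlations, and Bartlett's sphericity test
#' `chi^2 = -(n - 1 - (2p + 5)/6) * ln|R|` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param corr item correlation matrix (positive definite).
#' @param n sample size behind the correlations.
#' @return list with `kmo`, `bartlett_chi2`, `bartlett_df`, `bartlett_p`.
#' @export
fa_suitability <- function(corr, n) {
  p <- ncol(corr)
  inv <- tryCatch(solve(corr), error = function(e)
    stop("correlation matrix is singular; consider removing items"))
  d <- 1 / sqrt(diag(inv))
  partial <- -inv * outer(d, d)     # anti-image partial correlations
  off <- upper.tri(corr)
  kmo <- sum(corr[off]^2) / (sum(corr[off]^2) + sum(partial[off]^2))

  det_r <- det(corr)
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(det_r)
  df <- p * (p - 1) / 2
  list(kmo = kmo, bartlett_chi2 = chi2, bartlett_df = df,
       bartlett_p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# flip factor columns so the majority of loadings are positive
fix_signs <- function(L) {
  s <- ifelse(colSums(L > 0) >= colSums(L < 0), 1, -1)
  sweep(L, 2L, s, "*")
}

#' Principal-component extraction with varimax rotation
#'
#' Retains components with eigenvalue over `cutoff` (Kaiser rule),
#' forms loadings `V * sqrt(lambda)` and rotates them by varimax with
#' Kaiser normalisation. Columns are ordered by explained variance and
#' signed so most loadings are positive. Total variance explained is
#' `100 * sum(retained eigenvalues) / p`, invariant under rotation.
#'
#' @param corr item correlation matrix.
#' @param cutoff eigenvalue retention rule (default 1).
#' @return object of class `factor_solution`: `eigenvalues`,
#'   `n_factors`, `loadings` (rotated), `unrotated`,
#'   `variance_explained_total` (percent), `rotation`, `corr`.
#' @export
extract_and_rotate <- function(corr, cutoff = 1) {
  p <- ncol(corr)
  eig <- eigen(corr, symmetric = TRUE)
  keep <- which(eig$values > cutoff)
  if (!length(keep)) stop("no component has eigenvalue over ", cutoff)
  L <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), length(keep))
  rownames(L) <- colnames(corr)

  if (length(keep) > 1L) {
    rot <- stats::varimax(L, normalize = TRUE)
    L <- unclass(rot$loadings)
    ss <- colSums(L^2)
    L <- L[, order(ss, decreasing = TRUE), drop = FALSE]
  }
  L <- fix_signs(L)
  colnames(L) <- paste0("F", seq_len(ncol(L)))

  structure(
    list(eigenvalues = eig$values, n_factors = length(keep),
         loadings = L,
         variance_explained_total = 100 * sum(eig$values[keep]) / p,
         rotation = if (length(keep) > 1L) "varimax" else "none",
         corr = corr),
    class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("<factor_solution> ", x$n_factors, " factors, ",
      round(x$variance_explained_total, 2), "% total variance (",
      x$rotation, ")\n", sep = "")
  print(round(x$loadings, 2))
  invisible(x)
}

#' Assign items to factors by loading threshold
#'
#' Each item goes to the factor on which its absolute loading exceeds
#' `threshold`. Items whose top two absolute loadings both exceed the
#' threshold, or lie within `cross_margin` of each other, are flagged
#' `cross`; items with no loading over the threshold are flagged
#' `none`. Either way the item is provisionally assigned to its largest
#' loading, and an `override` table (item -> factor column name)
#' resolves flagged items to a published grouping.
#'
#' @param solution a [extract_and_rotate()] result.
#' @param threshold absolute loading cutoff (default 0.5).
#' @param cross_margin top-two loading gap below which an item counts
#'   as cross-loading (default 0.1).
#' @param override optional named character vector, item -> factor.
#' @return data.frame with `item`, `factor`, `flag` (`""`, `"cross"`,
#'   `"none"`).
#' @export
assign_items <- function(solution, threshold = 0.5, cross_margin = 0.1,
                         override = NULL) {
  L <- abs(solution$loadings)
  out <- data.frame(item = rownames(L), factor = NA_character_,
                    flag = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(L))) {
    v <- sort(L[i, ], decreasing = TRUE)
    hits <- sum(L[i, ] > threshold)
    out$factor[i] <- colnames(L)[which.max(L[i, ])]
    if (hits == 0L) {
      out$flag[i] <- "none"
    } else if (hits > 1L ||
               (ncol(L) > 1L && v[1L] - v[2L] < cross_margin)) {
      out$flag[i] <- "cross"
    }
    it <- out$item[i]
    if (!is.null(override) && it %in% names(override))
      out$factor[i] <- override[[it]]
  }
  out
}

#' Regression-method factor scores
#'
#' Scores are `Z R^{-1} Lambda` with `Z` the standardised complete-case
#' responses and `Lambda` the rotated loadings, then standardised per
#' factor to mean 0 and SD 1 over the sample (SPSS-style recoded
#' scores).
#'
#' @param solution a [extract_and_rotate()] result.
#' @param responses numeric matrix of complete-case responses, columns
#'   matching the loading rows (raw category codes are fine; they are
#'   standardised internally).
#' @return matrix persons x factors of standardised scores.
#' @export
factor_scores <- function(solution, responses) {
  responses <- as.matrix(responses)
  if (anyNA(responses)) stop("factor scores require complete cases")
  responses <- responses[, rownames(solution$loadings), drop = FALSE]
  Z <- scale(responses)
  S <- Z %*% solve(solution$corr) %*% solution$loadings
  scale(S)[, , drop = FALSE]
}

#' Classical factor analysis of a response matrix
#'
#' Convenience wrapper running the complete-case Pearson-correlation
#' workflow: listwise deletion, suitability checks, eigenvalue-over-one
#' extraction, varimax rotation, item assignment and regression factor
#' scores.
#'
#' @param rm a [response_matrix()].
#' @param threshold loading threshold for item assignment.
#' @param override optional item -> factor override table.
#' @param cutoff eigenvalue retention rule.
#' @return list with `n_complete`, `suitability`, `solution`,
#'   `assignment`, `scores` (rownames = complete-case person ids).
#' @export
factor_structure <- function(rm, threshold = 0.5, override = NULL,
                             cutoff = 1) {
  complete <- stats::complete.cases(rm$responses)
  X <- rm$responses[complete, , drop = FALSE]
  if (nrow(X) < ncol(X) + 1L) stop("too few complete cases")
  R <- stats::cor(X)
  suit <- fa_suitability(R, nrow(X))
  sol <- extract_and_rotate(R, cutoff = cutoff)
  list(n_complete = nrow(X),
       complete = stats::setNames(complete, rm$persons),
       suitability = suit,
       solution = sol,
       assignment = assign_items(sol, threshold = threshold,
                                 override = override),
       scores = factor_scores(sol, X))
}
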