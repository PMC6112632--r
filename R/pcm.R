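#' Partial credit model category probabilities
#'
#' For a person at `theta` and an item with step thresholds `delta`
#' (length m, in logits), the probability of responding in category
#' `x` (0-based, 0..m) is
#' `P(X = x) = exp(sum_{k<=x}(theta - delta_k)) / sum_h exp(sum_{k<=h}(theta - delta_k))`
#' with the empty sum for x = 0 equal to zero.
#'
#' @param theta numeric vector of person measures (logits).
#' @param delta numeric vector of step thresholds for one item (logits).
#' @return matrix `length(theta)` x `(length(delta) + 1)` of category
#'   probabilities; rows sum to one.
#' @export
pcm_probabilities <- function(theta, delta) {
  m <- length(delta)
  d_cum <- c(0, cumsum(delta))
  eta <- outer(theta, 0:m) - matrix(d_cum, length(theta), m + 1L, byrow = TRUE)
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta)
  p / rowSums(p)
}

item_moments <- function(theta, delta) {
  m <- length(delta)
  p <- pcm_probabilities(theta, delta)
  e <- drop(p %*% (0:m))
  v <- drop(p %*% ((0:m)^2)) - e^2
  list(p = p, e = e, v = pmax(v, 1e-10))
}

# Expected total score and information over a set of items at one theta.
tcc_at <- function(theta, deltas) {
  e <- 0; v <- 0
  for (d in deltas) {
    mo <- item_moments(theta, d)
    e <- e + mo$e; v <- v + mo$v
  }
  c(e = e, v = v)
}

# Solve sum_i E[X_i | theta] = target by Newton iteration on the test
# characteristic curve (strictly increasing, so the root is unique).
solve_theta <- function(target, deltas, tol = 1e-10, max_iter = 100L) {
  theta <- 0
  for (it in seq_len(max_iter)) {
    mo <- tcc_at(theta, deltas)
    step <- (target - mo["e"]) / max(mo["v"], 1e-8)
    step <- max(min(step, 2), -2)
    theta <- theta + step
    if (abs(step) < tol) break
  }
  unname(theta)
}

#' Fit the partial credit model by joint maximum likelihood
#'
#' Alternating Newton-Raphson over person measures and item step
#' thresholds (the JMLE scheme of WINSTEPS-style Rasch software), with
#' item difficulties centred at zero. Missing cells contribute nothing
#' to the likelihood. Categories never observed in the data are
#' collapsed out (with a warning) so each item's codes are contiguous.
#' Persons with extreme (minimum or maximum) raw scores carry no
#' information about item parameters; they are dropped from estimation
#' and afterwards receive finite measures by shifting their raw score
#' `extreme_adjust` score units towards the interior before inverting
#' the test characteristic curve.
#'
#' @param rm a [response_matrix()].
#' @param tol convergence tolerance on the largest parameter change
#'   between sweeps (logits; default 0.005).
#' @param score_tol tolerance on the largest person raw-score residual
#'   (default 0.01).
#' @param max_iter maximum alternating sweeps (default 200).
#' @param extreme_adjust fractional score-unit adjustment used to give
#'   extreme scores finite measures (default 0.3).
#' @param on_nonconverge `"error"` (default) or `"warn"`.
#' @return an object of class `pcm_fit` with components `theta`,
#'   `se` (person measures and model standard errors, logits),
#'   `thresholds` (list of step thresholds per item), `item_difficulty`
#'   (mean threshold per item), `extreme` (logical per person),
#'   `converged`, `iterations`, plus the collapsed 0-based response
#'   matrix `x0` used for fitting.
#' @export
fit_pcm <- function(rm, tol = 0.005, score_tol = 0.01, max_iter = 200L,
                    extreme_adjust = 0.3, on_nonconverge = c("error", "warn")) {
  on_nonconverge <- match.arg(on_nonconverge)
  spec <- rm$spec
  items <- spec$item_ids
  x0 <- rm$responses - 1L   # 0-based categories
  n <- nrow(x0); p <- ncol(x0)
  if (p < 2L) stop("need at least 2 items")

  # collapse never-observed categories to contiguous 0..m codes
  cat_map <- vector("list", p); names(cat_map) <- items
  n_collapsed <- 0L
  for (j in seq_len(p)) {
    obs <- sort(unique(x0[!is.na(x0[, j]), j]))
    if (length(obs) < 2L)
      stop("item ", items[j], " has no observed variance")
    full <- 0:(spec$n_categories[[j]] - 1L)
    if (!identical(obs, full)) {
      n_collapsed <- n_collapsed + 1L
      x0[, j] <- match(x0[, j], obs) - 1L
    }
    cat_map[[j]] <- obs
  }
  if (n_collapsed > 0L)
    warning(n_collapsed, " item(s) had unobserved categories collapsed")
  m <- vapply(seq_len(p), function(j) max(x0[, j], na.rm = TRUE), 0L)
  names(m) <- items

  obs_mask <- !is.na(x0)
  r <- rowSums(x0, na.rm = TRUE)                 # raw 0-based person scores
  r_max <- as.vector(obs_mask %*% m)             # per-person maximum
  answered <- rowSums(obs_mask)
  extreme <- answered > 0L & (r == 0L | r == r_max)
  active <- answered > 0L & !extreme
  if (sum(active) < 2L) stop("need at least 2 non-extreme persons")

  # PROX-flavoured start values
  frac <- pmin(pmax((r + 0.5) / (r_max + 1), 0.01), 0.99)
  theta <- ifelse(answered > 0L, log(frac / (1 - frac)), NA_real_)
  delta <- lapply(seq_len(p), function(j) rep(0, m[j]))
  names(delta) <- items

  converged <- FALSE
  max_change <- Inf; max_resid <- Inf
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # --- person sweep (non-extreme persons only)
    e_tot <- numeric(n); v_tot <- numeric(n)
    for (j in seq_len(p)) {
      mo <- item_moments(theta[active], delta[[j]])
      ok <- obs_mask[active, j]
      e <- numeric(sum(active)); v <- numeric(sum(active))
      e[ok] <- mo$e[ok]; v[ok] <- mo$v[ok]
      e_tot[active] <- e_tot[active] + e
      v_tot[active] <- v_tot[active] + v
    }
    d_theta <- (r[active] - e_tot[active]) / pmax(v_tot[active], 0.05)
    d_theta <- pmax(pmin(d_theta, 1), -1)
    theta[active] <- pmin(pmax(theta[active] + d_theta, -10), 10)

    # --- item sweep
    d_delta_max <- 0
    for (j in seq_len(p)) {
      ok <- active & obs_mask[, j]
      th <- theta[ok]; x <- x0[ok, j]
      for (k in seq_len(m[j])) {
        pmat <- pcm_probabilities(th, delta[[j]])
        p_ge <- rowSums(pmat[, (k + 1L):(m[j] + 1L), drop = FALSE])
        u <- sum(p_ge) - sum(x >= k)
        h <- sum(p_ge * (1 - p_ge))
        step <- if (h > 1e-10) u / h else 0
        step <- max(min(step, 1), -1)
        delta[[j]][k] <- min(max(delta[[j]][k] + step, -10), 10)
        d_delta_max <- max(d_delta_max, abs(step))
      }
    }

    # --- centre item difficulties at zero (likelihood-invariant shift)
    mu <- mean(vapply(delta, mean, 0))
    delta <- lapply(delta, function(d) d - mu)
    theta[answered > 0L] <- theta[answered > 0L] - mu

    # --- convergence: parameter change and score residual
    e_chk <- numeric(n)
    for (j in seq_len(p)) {
      mo <- item_moments(theta[active], delta[[j]])
      ok <- obs_mask[active, j]
      e <- numeric(sum(active)); e[ok] <- mo$e[ok]
      e_chk[active] <- e_chk[active] + e
    }
    max_change <- max(max(abs(d_theta)), d_delta_max)
    max_resid <- max(abs(r[active] - e_chk[active]))
    if (max_change < tol && max_resid < score_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    msg <- sprintf(
      "PCM JMLE did not converge in %d iterations (max change %.4f, max score residual %.4f)",
      max_iter, max_change, max_resid)
    if (on_nonconverge == "error") stop(msg) else warning(msg)
  }

  # finite measures for extreme persons via fractional-score adjustment
  for (i in which(extreme)) {
    its <- which(obs_mask[i, ])
    tgt <- if (r[i] == 0L) extreme_adjust else r_max[i] - extreme_adjust
    theta[i] <- solve_theta(tgt, delta[its])
  }

  # model standard errors = 1/sqrt(information at theta)
  se <- rep(NA_real_, n)
  info <- numeric(n)
  for (j in seq_len(p)) {
    has <- answered > 0L
    mo <- item_moments(theta[has], delta[[j]])
    ok <- obs_mask[has, j]
    v <- numeric(sum(has)); v[ok] <- mo$v[ok]
    info[has] <- info[has] + v
  }
  se[answered > 0L] <- 1 / sqrt(info[answered > 0L])

  structure(
    list(theta = stats::setNames(theta, rm$persons),
         se = stats::setNames(se, rm$persons),
         thresholds = delta,
         item_difficulty = vapply(delta, mean, 0),
         extreme = stats::setNames(extreme, rm$persons),
         answered = answered, x0 = x0, m = m, cat_map = cat_map,
         items = items, spec = spec,
         converged = converged, iterations = iter,
         max_change = max_change, max_score_residual = max_resid),
    class = "pcm_fit")
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat("<pcm_fit> ", length(x$items), " items, ",
      sum(x$answered > 0), " persons (", sum(x$extreme), " extreme), ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " sweeps\n", sep = "")
  invisible(x)
}

# Expected scores and variances for every observed cell at the fitted
# parameters; NA elsewhere.
fitted_moments <- function(fit) {
  n <- nrow(fit$x0); p <- ncol(fit$x0)
  E <- matrix(NA_real_, n, p, dimnames = dimnames(fit$x0))
  V <- E
  has <- fit$answered > 0L
  for (j in seq_len(p)) {
    mo <- item_moments(fit$theta[has], fit$thresholds[[j]])
    E[has, j] <- mo$e; V[has, j] <- mo$v
  }
  E[is.na(fit$x0)] <- NA; V[is.na(fit$x0)] <- NA
  list(E = E, V = V)
}

#' Score-to-measure conversion table
#'
#' Maps every achievable raw score of the fitted scale to a latent
#' measure (logits) and its model standard error, by inverting the test
#' characteristic curve with Newton iteration. Extreme scores (minimum
#' and maximum) are shifted `extreme_adjust` score units inward before
#' inversion so they receive finite measures. The `score` column is on
#' the chart scale (e.g. 17..53 for the default CVSS17 chart).
#'
#' @param fit a [fit_pcm()] result.
#' @param extreme_adjust fractional score-unit adjustment (default 0.3).
#' @return a data.frame of class `score_table` with columns `score`,
#'   `measure`, `se` and a logical `extreme` marker.
#' @export
score_to_measure <- function(fit, extreme_adjust = 0.3) {
  deltas <- fit$thresholds
  M <- sum(fit$m)
  s0 <- 0:M
  target <- s0
  target[1L] <- extreme_adjust
  target[M + 1L] <- M - extreme_adjust
  theta <- vapply(target, solve_theta, 0, deltas = deltas)
  info <- vapply(theta, function(th) tcc_at(th, deltas)[["v"]], 0)

  ch <- chart_for(fit$spec, "total")
  steps <- vapply(ch, function(v) length(v) - 1L, 0L)
  unit <- all(vapply(ch, function(v) all(diff(v) == 1), TRUE))
  if (!unit)
    warning("score chart is not unit-increment; chart scores approximate")
  chart_min <- sum(vapply(ch, min, 0))

  out <- data.frame(score = s0 + chart_min, measure = theta,
                    se = 1 / sqrt(info),
                    extreme = s0 %in% c(0L, M))
  class(out) <- c("score_table", "data.frame")
  out
}

#' Infit and outfit mean square fit statistics
#'
#' Residual-based fit of persons and items to the Rasch model. With
#' score residual `y = x - E[X]` and model variance `W = Var(X)` per
#' observed cell, outfit is the unweighted mean of `y^2/W` and infit the
#' information-weighted `sum(y^2)/sum(W)` — per person across items and
#' per item across persons. Both have expectation near 1 under the
#' model. Statistics are undefined (`NA`) for extreme persons, and items
#' are assessed over non-extreme persons only.
#'
#' @param fit a [fit_pcm()] result.
#' @return list of class `fit_statistics` with data.frames `person` and
#'   `item`, each holding `infit` and `outfit` columns.
#' @export
fit_statistics <- function(fit) {
  mo <- fitted_moments(fit)
  y <- fit$x0 - mo$E
  z2 <- y^2 / mo$V
  act <- fit$answered > 0L & !fit$extreme

  person <- data.frame(
    infit = rowSums(y^2, na.rm = TRUE) / rowSums(mo$V, na.rm = TRUE),
    outfit = rowMeans(z2, na.rm = TRUE),
    row.names = names(fit$theta))
  person[!act, ] <- NA_real_

  ya <- y[act, , drop = FALSE]; va <- mo$V[act, , drop = FALSE]
  z2a <- z2[act, , drop = FALSE]
  item <- data.frame(
    infit = colSums(ya^2, na.rm = TRUE) / colSums(va, na.rm = TRUE),
    outfit = colMeans(z2a, na.rm = TRUE),
    row.names = fit$items)

  structure(list(person = person, item = item), class = "fit_statistics")
}

#' Person separation index and reliability
#'
#' PSI is the ratio of the noise-adjusted true person standard deviation
#' to the root mean square model error of the person measures, computed
#' over non-extreme persons; reliability is `PSI^2 / (1 + PSI^2)`,
#' analogous to Cronbach's alpha.
#'
#' @param fit a [fit_pcm()] result.
#' @return list with `psi`, `reliability`, `rmse`, `sd_true`.
#' @export
person_separation <- function(fit) {
  act <- fit$answered > 0L & !fit$extreme
  th <- fit$theta[act]; se <- fit$se[act]
  if (length(th) < 2L) stop("need at least 2 non-extreme persons")
  rmse <- sqrt(mean(se^2))
  v_obs <- stats::var(th)
  sd_true <- sqrt(max(0, v_obs - rmse^2))
  psi <- sd_true / rmse
  list(psi = psi, reliability = psi^2 / (1 + psi^2),
       rmse = rmse, sd_true = sd_true)
}

#' Item-person targeting
#'
#' Difference between the average item difficulty (zero by the centring
#' convention) and the mean person measure, in logits. Negative values
#' mean persons sit above the items (a "mildly easy" instrument for the
#' sample); zero is perfect targeting.
#'
#' @param fit a [fit_pcm()] result.
#' @param include_extreme include extreme persons' (adjusted, finite)
#'   measures in the person mean (default `FALSE`).
#' @return targeting offset in logits.
#' @export
targeting <- function(fit, include_extreme = FALSE) {
  keep <- fit$answered > 0L & (include_extreme | !fit$extreme)
  mean(fit$item_difficulty) - mean(fit$theta[keep])
}

#' Dimensionality summary from a PCA of standardised residuals
#'
#' Standardised residuals `z = (x - E)/sqrt(W)` are correlated across
#' items and eigen-decomposed; the largest eigenvalue is the strength of
#' the first residual contrast (in item units). Raw variance explained
#' by the measures is the modelled-expectation variance as a share of
#' modelled plus residual variance, in percent.
#'
#' @param fit a [fit_pcm()] result.
#' @return list of class `dimensionality` with
#'   `raw_variance_explained` (percent), `first_contrast_eigenvalue`,
#'   and the full `eigenvalues` vector.
#' @export
residual_pca <- function(fit) {
  mo <- fitted_moments(fit)
  act <- fit$answered > 0L & !fit$extreme
  y <- (fit$x0 - mo$E)[act, , drop = FALSE]
  z <- y / sqrt(mo$V[act, , drop = FALSE])
  cc <- stats::cor(z, use = "pairwise.complete.obs")
  cc[is.na(cc)] <- 0; diag(cc) <- 1
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values

  e_obs <- mo$E[act, , drop = FALSE]
  v_model <- stats::var(as.vector(e_obs), na.rm = TRUE)
  v_resid <- mean(y^2, na.rm = TRUE)
  structure(
    list(raw_variance_explained = 100 * v_model / (v_model + v_resid),
         first_contrast_eigenvalue = ev[1L],
         eigenvalues = ev),
    class = "dimensionality")
}
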