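#' Default simulation thresholds for a scale
#'
#' Item step thresholds (logits): item difficulty offsets evenly spaced
#' in `[-0.8, 0.8]`, dealt to the subscales in round-robin order so each
#' subscale spans the same difficulty range; each item's steps spread
#' from -1 to +1 logits around its offset. A mildly easy test relative
#' to the simulated person distribution, giving targeting around -0.4.
#'
#' @param spec a [scale_spec()].
#' @return named list, item -> numeric threshold vector.
#' @export
default_thresholds <- function(spec) {
  p <- length(spec$item_ids)
  offs <- seq(-0.8, 0.8, length.out = p)
  by_sub <- split(spec$item_ids, spec$subscale[spec$item_ids])
  dealt <- character(0)          # round-robin over subscales
  idx <- rep(1L, length(by_sub))
  while (length(dealt) < p) {
    for (s in seq_along(by_sub)) {
      if (idx[s] <= length(by_sub[[s]])) {
        dealt <- c(dealt, by_sub[[s]][idx[s]])
        idx[s] <- idx[s] + 1L
      }
    }
  }
  out <- lapply(seq_len(p), function(i) {
    it <- dealt[i]
    m <- spec$n_categories[[it]] - 1L
    offs[i] + seq(-1, 1, length.out = m)
  })
  names(out) <- dealt
  out[spec$item_ids]
}

#' Simulation configuration
#'
#' Conditions of the emulated study: two correlated latent symptom
#' traits (external/internal), four gender-by-presbyopia groups with
#' presbyope women shifted upward, partial-credit category responses
#' and completely-at-random missingness.
#'
#' @param n_persons sample size (default 796, the analysed sample).
#' @param rho latent correlation between the ESF and ISF traits
#'   (default 0.6).
#' @param group_probs sampling probabilities for the NPW/NPM/PW/PM
#'   groups (default proportional to the study's 135/64/219/182).
#' @param latent_mean baseline latent mean, logits (default 0.3, placing
#'   persons slightly above the items).
#' @param group_shift additive latent shift per group, logits (default
#'   +0.4 for presbyope women only).
#' @param latent_sd latent standard deviation, logits (default 1.3,
#'   which reproduces the dispersion of the study sample's total scores
#'   and its sampling adequacy under the default thresholds).
#' @param missing_rate per-cell missingness probability (default 0.017,
#'   leaving roughly three quarters of persons with complete forms).
#' @param thresholds item step thresholds; `NULL` for
#'   [default_thresholds()].
#' @param cross_loading optional `list(item =, weight =)`: that item's
#'   governing trait becomes `weight * ESF + (1 - weight) * ISF`,
#'   emulating a cross-loading item.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 796L, rho = 0.6,
                       group_probs = c(NPW = 135, NPM = 64, PW = 219, PM = 182),
                       latent_mean = 0.3,
                       group_shift = c(NPW = 0, NPM = 0, PW = 0.4, PM = 0),
                       latent_sd = 1.3, missing_rate = 0.017,
                       thresholds = NULL, cross_loading = NULL) {
  stopifnot(abs(rho) < 1, missing_rate >= 0, missing_rate <= 0.3,
            n_persons >= 2)
  structure(
    list(n_persons = as.integer(n_persons), rho = rho,
         group_probs = group_probs / sum(group_probs),
         latent_mean = latent_mean, group_shift = group_shift,
         latent_sd = latent_sd, missing_rate = missing_rate,
         thresholds = thresholds, cross_loading = cross_loading),
    class = "sim_config")
}

sample_pcm_item <- function(theta, delta) {
  p <- pcm_probabilities(theta, delta)
  cp <- t(apply(p, 1L, cumsum))
  u <- stats::runif(length(theta))
  as.integer(rowSums(u > cp[, -ncol(cp), drop = FALSE]))
}

#' Simulate a response matrix with known truth
#'
#' Draws per-person latent trait pairs (bivariate normal with
#' correlation `rho` and a group-specific mean shift), samples each
#' item's category from partial credit model probabilities under the
#' trait of the item's subscale, and applies completely-at-random
#' missingness. Gender and age follow from the sampled group (women in
#' the `*W` groups; presbyopes aged 40-65, non-presbyopes 18-39).
#'
#' @param config a [sim_config()].
#' @param spec a [scale_spec()] (default [cvss17_spec()]).
#' @param seed integer seed for bit-for-bit reproducibility (optional).
#' @return list of class `sim_result`: `responses` (a
#'   [response_matrix()]), `truth` (list with `theta` persons x 2
#'   trait matrix, `thresholds`, `group` factor, `config`).
#' @export
simulate_responses <- function(config = sim_config(), spec = cvss17_spec(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_persons
  thr <- config$thresholds
  if (is.null(thr)) thr <- default_thresholds(spec)
  stopifnot(setequal(names(thr), spec$item_ids))

  grp <- factor(sample(names(config$group_probs), n, replace = TRUE,
                       prob = config$group_probs),
                levels = names(config$group_probs))
  gender <- ifelse(grepl("W$", as.character(grp)), "F", "M")
  presby <- grepl("^P", as.character(grp))
  age <- ifelse(presby, sample(40:65, n, replace = TRUE),
                sample(18:39, n, replace = TRUE))

  mu <- config$latent_mean + config$group_shift[as.character(grp)]
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  th1 <- mu + config$latent_sd * z1
  th2 <- mu + config$latent_sd * (config$rho * z1 +
                                    sqrt(1 - config$rho^2) * z2)
  subs <- unique(spec$subscale)
  if (length(subs) > 2L) stop("simulator supports at most 2 subscales")
  theta <- cbind(th1, th2)[, seq_along(subs), drop = FALSE]
  colnames(theta) <- subs

  subsc <- spec$subscale
  m <- matrix(NA_integer_, n, length(spec$item_ids),
              dimnames = list(paste0("P", seq_len(n)), spec$item_ids))
  for (it in spec$item_ids) {
    tr <- theta[, subsc[[it]]]
    cl <- config$cross_loading
    if (!is.null(cl) && identical(cl$item, it) && ncol(theta) == 2L)
      tr <- cl$weight * theta[, 1L] + (1 - cl$weight) * theta[, 2L]
    m[, it] <- sample_pcm_item(tr, thr[[it]]) + 1L
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(m)) < config$missing_rate,
                   nrow(m), ncol(m))
    m[drop] <- NA_integer_
  }

  rm <- response_matrix(m, spec, gender = gender, age = age)
  structure(
    list(responses = rm,
         truth = list(theta = theta, thresholds = thr, group = grp,
                      config = config)),
    class = "sim_result")
}

#' Rand index between two partitions
#'
#' Share of object pairs on which two partitions agree (together in
#' both or apart in both); 1 means identical partitions.
#'
#' @param a,b cluster labels of equal length.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  s_cells <- sum(comb2(tab))
  s_a <- sum(comb2(rowSums(tab)))
  s_b <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  (total + 2 * s_cells - s_a - s_b) / total
}

#' Parameter-recovery summary for a simulated data set
#'
#' Fits the full pipeline pieces needed to compare estimates with the
#' generating truth: correlation between true and estimated person
#' measures (the estimated measure from the total-scale fit is compared
#' to the step-count-weighted composite of the two true traits),
#' threshold recovery correlation and RMSE, and the Rand index between
#' the factor-analysis item partition and the true subscale partition.
#'
#' @param sim a [simulate_responses()] result.
#' @param fit optional precomputed total-scale [fit_pcm()].
#' @param fa optional precomputed [factor_structure()].
#' @return list with `theta_cor`, `threshold_cor`, `threshold_rmse`,
#'   `partition_rand`, `n_factors`.
#' @export
recovery_report <- function(sim, fit = NULL, fa = NULL) {
  rm <- sim$responses
  if (is.null(fit)) fit <- fit_pcm(rm)
  spec <- rm$spec
  w <- vapply(spec$item_ids,
              function(it) spec$n_categories[[it]] - 1L, 0L)
  subs <- colnames(sim$truth$theta)
  w_by <- vapply(subs, function(s) sum(w[spec$subscale == s]), 0)
  composite <- drop(sim$truth$theta %*% w_by) / sum(w_by)
  act <- fit$answered > 0L & !fit$extreme
  theta_cor <- stats::cor(composite[act], fit$theta[act])

  tr <- c(); es <- c()
  for (it in fit$items) {
    t_true <- sim$truth$thresholds[[it]]
    t_est <- fit$thresholds[[it]]
    if (length(t_true) == length(t_est)) {
      tr <- c(tr, t_true); es <- c(es, t_est)
    }
  }
  threshold_cor <- stats::cor(tr, es)
  threshold_rmse <- sqrt(mean((tr - es)^2))

  if (is.null(fa)) fa <- factor_structure(rm)
  part <- if (fa$solution$n_factors >= 2L)
    rand_index(fa$assignment$factor[match(spec$item_ids, fa$assignment$item)],
               spec$subscale[spec$item_ids]) else 0

  list(theta_cor = theta_cor, threshold_cor = threshold_cor,
       threshold_rmse = threshold_rmse, partition_rand = part,
       n_factors = fa$solution$n_factors)
}
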