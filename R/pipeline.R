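stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full scale-validation pipeline
#'
#' Orchestrates the whole analysis chain on a response matrix:
#' person exclusions (answered-count rule, then a preliminary partial
#' credit fit, then the outfit rule, then one refit), the total-scale
#' Rasch analysis with score-to-measure table and Wright levels of
#' performance (with sparse-level collapsing), classical factor
#' analysis of complete cases, discriminant classification of persons
#' into levels from their factor scores, Kruskal-Wallis/Dunn group
#' comparisons across the gender-by-presbyopia groups, and per-subscale
#' Rasch panels with DIF screens and A/B/C quality grades. The run is
#' deterministic given its inputs.
#'
#' @param rm a [response_matrix()] with gender and age covariates.
#' @param min_answered,outfit_cap person inclusion rules (defaults 12
#'   items and outfit 2.5).
#' @param presbyopia_age presbyopia proxy threshold (default 39).
#' @param min_share occupancy share below which levels merge
#'   (default 0.01).
#' @param loading_threshold factor-assignment loading cutoff (0.5).
#' @param override optional item -> factor override for flagged items.
#' @param dif_threshold DIF flag size in logits (0.5).
#' @param prior discriminant priors, `"equal"` or `"proportional"`.
#' @return list of class `pipeline_report` with sections `exclusions`,
#'   `fit`, `score_table`, `levels` (scheme, occupancy, collapsed
#'   scheme, per-person assignment), `descriptives`, `comparisons`
#'   (Kruskal-Wallis + Dunn per scale), `factors`, `discriminant`, and
#'   `subscales` (per-subscale fit summaries, DIF and quality grades).
#' @export
run_full_validation <- function(rm,
                                min_answered = 12L, outfit_cap = 2.5,
                                presbyopia_age = 39,
                                min_share = 0.01,
                                loading_threshold = 0.5, override = NULL,
                                dif_threshold = 0.5,
                                prior = "equal") {
  spec <- rm$spec

  # -- exclusions: answered rule, preliminary fit, outfit rule, refit
  rm1 <- stage("answered-filter",
               filter_persons(rm, min_answered = min_answered,
                              outfit_cap = outfit_cap))
  prelim <- stage("preliminary-fit", fit_pcm(rm1, on_nonconverge = "warn"))
  outfit0 <- fit_statistics(prelim)$person$outfit
  names(outfit0) <- rm1$persons
  rm2 <- stage("outfit-filter",
               filter_persons(rm1, person_outfit = outfit0,
                              min_answered = min_answered,
                              outfit_cap = outfit_cap))
  exclusions <- list(
    n_submitted = length(rm$persons),
    answered_rule = attr(rm1, "exclusions"),
    outfit_rule = attr(rm2, "exclusions"),
    n_retained = length(rm2$persons))

  # -- total-scale Rasch analysis
  fit <- stage("total-fit", fit_pcm(rm2))
  tab <- stage("score-table", score_to_measure(fit))
  lv <- stage("levels", count_levels(tab))
  scheme <- stage("cutoffs", derive_cutoffs(tab, lv$levels))
  scores_total <- raw_score(rm2, "total")
  occupancy <- level_counts(scheme, scores_total)
  collapsed <- stage("collapse",
                     collapse_sparse_levels(scheme, occupancy, min_share))
  person_level <- assign_level(collapsed, scores_total)
  names(person_level) <- rm2$persons

  # -- groups and nonparametric comparisons
  groups <- stage("groups", assign_groups(rm2, presbyopia_age))
  scales <- names(spec$chart)
  comparisons <- lapply(stats::setNames(scales, scales), function(sc) {
    v <- raw_score(rm2, sc)
    keep <- !is.na(v) & stats::complete.cases(rm2$responses)
    list(kruskal = kruskal_wallis(v[keep], groups[keep]),
         dunn = dunn_posthoc(v[keep], groups[keep]))
  })
  descriptives <- list(
    group_n = table(groups[stats::complete.cases(rm2$responses)]),
    total_mean = mean(scores_total, na.rm = TRUE),
    total_sd = stats::sd(scores_total, na.rm = TRUE),
    total_median = stats::median(scores_total, na.rm = TRUE),
    total_range = range(scores_total, na.rm = TRUE))

  # -- factor structure on complete cases
  fa <- stage("factor-analysis",
              factor_structure(rm2, threshold = loading_threshold,
                               override = override))

  # -- discriminant classification: factor scores vs collapsed levels
  complete_ids <- rm2$persons[fa$complete]
  da <- stage("discriminant",
              fit_lda(fa$scores, person_level[complete_ids], prior = prior))
  factor_means_by_level <- stats::aggregate(
    fa$scores, by = list(level = person_level[complete_ids]),
    function(v) c(mean = mean(v), sd = stats::sd(v)))

  # -- per-subscale Rasch panels with DIF and quality grades
  subscales <- lapply(stats::setNames(unique(spec$subscale),
                                      unique(spec$subscale)), function(sc) {
    sp <- subscale_spec(spec, sc)
    rms <- response_matrix(rm2$responses[, sp$item_ids, drop = FALSE], sp,
                           gender = rm2$gender, age = rm2$age,
                           person_ids = rm2$persons)
    f <- stage(paste0("subscale-fit-", sc), fit_pcm(rms))
    fs <- fit_statistics(f)
    ps <- person_separation(f)
    dim_ <- residual_pca(f)
    stab <- score_to_measure(f)
    slv <- count_levels(stab)
    contrasts <- list(
      gender = rm2$gender,
      age_group = factor(ifelse(rm2$age > presbyopia_age, "P", "NP")))
    dif <- dif_report(f, contrasts, threshold = dif_threshold)
    grades <- grade_quality(list(
      infit_items_outside = sum(fs$item$infit < 0.7 | fs$item$infit > 1.3),
      outfit_items_outside = sum(fs$item$outfit < 0.7 | fs$item$outfit > 1.3),
      variance_explained = dim_$raw_variance_explained,
      first_contrast = dim_$first_contrast_eigenvalue,
      psi = ps$psi,
      level_reliability = slv$reliability,
      targeting = targeting(f),
      dif_gender_flags = sum(dif$flagged[dif$contrast == "gender"]),
      dif_age_flags = sum(dif$flagged[dif$contrast == "age_group"])))
    list(fit = f, fit_statistics = fs, separation = ps,
         dimensionality = dim_, score_table = stab, levels = slv,
         targeting = targeting(f), dif = dif, quality = grades)
  })

  structure(
    list(exclusions = exclusions, fit = fit, score_table = tab,
         levels = list(fractional = lv$levels,
                       reliability = lv$reliability,
                       scheme = scheme, occupancy = occupancy,
                       collapsed = collapsed,
                       assignment = person_level),
         descriptives = descriptives, comparisons = comparisons,
         factors = fa, discriminant = da,
         factor_means_by_level = factor_means_by_level,
         subscales = subscales),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  retained ", x$exclusions$n_retained, " of ",
      x$exclusions$n_submitted, " persons\n", sep = "")
  cat("  levels: ", round(x$levels$fractional, 1), " (reliability ",
      round(x$levels$reliability, 2), "), ", x$levels$collapsed$n_levels,
      " after collapsing\n", sep = "")
  cat("  factors: ", x$factors$solution$n_factors, " retained, ",
      round(x$factors$solution$variance_explained_total, 2),
      "% variance, KMO ", round(x$factors$suitability$kmo, 2),
      "\n", sep = "")
  cat("  discriminant accuracy: ", round(x$discriminant$accuracy, 1),
      "%\n", sep = "")
  for (sc in names(x$subscales)) {
    s <- x$subscales[[sc]]
    cat("  ", sc, ": PSI ", round(s$separation$psi, 2),
        ", targeting ", round(s$targeting, 2), " logits, ",
        round(s$levels$levels, 1), " levels\n", sep = "")
  }
  invisible(x)
}
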