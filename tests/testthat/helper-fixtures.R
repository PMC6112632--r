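# Small in-code fixtures shared across test files.

# 3-item toy scale, one subscale, 3 categories each
toy_spec3 <- function() {
  scale_spec(c("i1", "i2", "i3"), 3L, "S")
}

# two dichotomous items (2 categories), used for analytic checks
dicho_spec <- function(n_items = 2L) {
  scale_spec(paste0("d", seq_len(n_items)), 2L, "S")
}

# response_matrix from a plain matrix of category codes
rm_from <- function(m, spec, gender = NULL, age = NULL) {
  colnames(m) <- spec$item_ids
  response_matrix(m, spec, gender = gender, age = age)
}

# the published severity scheme used in worked examples:
# boundaries 17/23/29/36/43/49/53, six levels before collapsing
published_scheme <- function() {
  structure(
    list(boundaries = c(17L, 23L, 29L, 36L, 43L, 49L, 53L),
         n_levels = 6L, n_levels_fractional = 5.8,
         reliability = 5.8^2 / (1 + 5.8^2), collapsed = rep(FALSE, 6L)),
    class = "level_scheme")
}

# a fake pcm_fit with known parameters, for oracle arithmetic on the
# downstream statistics (fit_statistics, residual_pca, targeting)
fake_fit <- function(theta, thresholds, x0, spec) {
  n <- length(theta)
  structure(
    list(theta = stats::setNames(theta, paste0("P", seq_len(n))),
         se = stats::setNames(rep(0.5, n), paste0("P", seq_len(n))),
         thresholds = thresholds,
         item_difficulty = vapply(thresholds, mean, 0),
         extreme = stats::setNames(rep(FALSE, n), paste0("P", seq_len(n))),
         answered = rowSums(!is.na(x0)),
         x0 = x0, m = vapply(thresholds, length, 0L),
         cat_map = NULL, items = spec$item_ids, spec = spec,
         converged = TRUE, iterations = 0L),
    class = "pcm_fit")
}

# deterministic simulated data set reused by several files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_responses(sim_config(n_persons = 600),
                                   seed = 1234)
    cache
  }
})
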