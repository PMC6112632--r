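#' Define a polytomous scale specification
#'
#' A `scale_spec` describes a fixed-form questionnaire: the ordered item
#' labels, the number of ordered response categories per item (category
#' codes run `1..n_cat`), the subscale each item belongs to, and a score
#' chart giving the integer score contribution of every category of every
#' item, separately for the total scale and each subscale.
#'
#' The default chart scores each category by its own code (a plain sum),
#' so the scale minimum is the item count and the maximum is the sum of
#' top category codes. Published scoring charts that deviate from a plain
#' sum (subscale charts need not be additive with the total chart) can be
#' supplied via `chart` or loaded with [read_score_chart()].
#'
#' @param item_ids character vector of unique item labels, in form order.
#' @param n_categories integer vector, number of response categories per
#'   item (>= 2); recycled if length 1.
#' @param subscale character vector assigning each item to a subscale
#'   (e.g. `"ESF"` / `"ISF"`).
#' @param chart optional named list `scale -> item -> numeric vector` of
#'   per-category score contributions; scales default to `"total"` plus
#'   one per subscale, each a plain category-code sum over its items.
#' @return an object of class `scale_spec`.
#' @seealso [cvss17_spec()] for the CVSS17 default.
#' @export
scale_spec <- function(item_ids, n_categories, subscale, chart = NULL) {
  item_ids <- as.character(item_ids)
  if (anyDuplicated(item_ids)) stop("duplicate item ids")
  p <- length(item_ids)
  n_categories <- as.integer(rep_len(n_categories, p))
  if (any(n_categories < 2L)) stop("items need at least 2 categories")
  subscale <- as.character(rep_len(subscale, p))
  names(n_categories) <- names(subscale) <- item_ids

  scales <- c("total", unique(subscale))
  if (is.null(chart)) {
    chart <- lapply(scales, function(sc) {
      its <- if (sc == "total") item_ids else item_ids[subscale == sc]
      stats::setNames(lapply(its, function(it) seq_len(n_categories[[it]])), its)
    })
    names(chart) <- scales
  } else {
    for (sc in names(chart)) {
      for (it in names(chart[[sc]])) {
        if (!it %in% item_ids) stop("chart names unknown item: ", it)
        if (length(chart[[sc]][[it]]) != n_categories[[it]])
          stop("chart for item ", it, " has wrong category count")
      }
    }
  }

  structure(
    list(item_ids = item_ids, n_categories = n_categories,
         subscale = subscale, chart = chart),
    class = "scale_spec")
}

#' The CVSS17 scale specification
#'
#' Seventeen items measuring computer-related visual and ocular symptoms:
#' 11 items form the external symptom factor (ESF, ocular-surface
#' symptoms such as stinging, burning or red eyes) and 6 the internal
#' symptom factor (ISF, visual symptoms such as blur and diplopia).
#' Fifteen items have 3 ordered categories and two have 4, so the plain
#' category-sum chart yields total scores from 17 to 53, higher meaning
#' more symptoms. Which two items carry the fourth category is a package
#' default (one per subscale); override `n_categories` or the chart to
#' match a printed scoring chart exactly.
#'
#' @param chart optional score chart as in [scale_spec()].
#' @return a `scale_spec` with 17 items.
#' @export
cvss17_spec <- function(chart = NULL) {
  esf <- c("A32", "A21", "A9", "A17", "A4", "C16", "B8", "A20", "C23",
           "B7", "A33")
  isf <- c("C21", "A2", "A22", "A30", "C24", "A28")
  items <- c(esf, isf)
  ncat <- rep(3L, 17L)
  names(ncat) <- items
  ncat[c("A4", "A22")] <- 4L
  scale_spec(items, ncat,
             subscale = c(rep("ESF", length(esf)), rep("ISF", length(isf))),
             chart = chart)
}

#' @export
print.scale_spec <- function(x, ...) {
  cat("<scale_spec> ", length(x$item_ids), " items, subscales: ",
      paste(sprintf("%s (%d)", unique(x$subscale),
                    tabulate(factor(x$subscale, unique(x$subscale)))),
            collapse = ", "), "\n", sep = "")
  rng <- score_range(x, "total")
  cat("  total score range ", rng[1], "-", rng[2], "\n", sep = "")
  invisible(x)
}

#' Achievable score range of a scale
#'
#' @param spec a `scale_spec`.
#' @param scale `"total"` or a subscale name.
#' @return integer vector `c(min, max)` of the chart's score range.
#' @export
score_range <- function(spec, scale = "total") {
  ch <- chart_for(spec, scale)
  c(sum(vapply(ch, min, 0)), sum(vapply(ch, max, 0)))
}

chart_for <- function(spec, scale) {
  ch <- spec$chart[[scale]]
  if (is.null(ch)) stop("no score chart for scale '", scale, "'")
  ch
}

#' Restrict a scale specification to one subscale
#'
#' Returns a `scale_spec` containing only the items of `scale`, with that
#' subscale's chart installed as the new total chart. Used to run the
#' Rasch pipeline on a subscale as an isolated instrument.
#'
#' @inheritParams score_range
#' @return a `scale_spec`.
#' @export
subscale_spec <- function(spec, scale) {
  keep <- spec$item_ids[spec$subscale == scale]
  if (!length(keep)) stop("unknown subscale: ", scale)
  ch <- chart_for(spec, scale)
  scale_spec(keep, spec$n_categories[keep], spec$subscale[keep],
             chart = stats::setNames(list(ch[keep], ch[keep]), c("total", scale)))
}

#' Load a score chart from JSON
#'
#' The JSON maps scale name -> item id -> array of per-category integer
#' scores, mirroring a printed scoring chart.
#'
#' @param path JSON file path.
#' @return a chart list suitable for [scale_spec()]'s `chart` argument.
#' @export
read_score_chart <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(sc) lapply(sc, as.numeric))
}
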