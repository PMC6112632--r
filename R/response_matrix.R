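#' Construct a response matrix
#'
#' Persons x items ordinal category codes with optional missing cells,
#' plus per-person gender and age covariates. Category codes are checked
#' against the scale specification (`1..n_cat` per item).
#'
#' @param responses integer matrix or data.frame, persons in rows, items
#'   in columns (column names must match `spec$item_ids`); `NA` = missing.
#' @param spec a [scale_spec()].
#' @param gender character/factor of `"F"`/`"M"` per person (optional).
#' @param age numeric age in years per person (optional).
#' @param person_ids character ids; defaults to rownames or `P1..Pn`.
#' @return an object of class `response_matrix`.
#' @export
response_matrix <- function(responses, spec, gender = NULL, age = NULL,
                            person_ids = NULL) {
  m <- as.matrix(responses)
  storage.mode(m) <- "integer"
  if (is.null(colnames(m))) colnames(m) <- spec$item_ids
  missing_items <- setdiff(spec$item_ids, colnames(m))
  if (length(missing_items))
    stop("responses lack item columns: ", paste(missing_items, collapse = ", "))
  unknown <- setdiff(colnames(m), spec$item_ids)
  if (length(unknown))
    stop("unknown item column: ", paste(unknown, collapse = ", "))
  m <- m[, spec$item_ids, drop = FALSE]

  if (is.null(person_ids)) {
    person_ids <- rownames(m)
    if (is.null(person_ids)) person_ids <- paste0("P", seq_len(nrow(m)))
  }
  person_ids <- as.character(person_ids)
  if (anyDuplicated(person_ids)) stop("duplicate person id")
  rownames(m) <- person_ids

  for (it in spec$item_ids) {
    v <- m[, it]
    bad <- !is.na(v) & (v < 1L | v > spec$n_categories[[it]])
    if (any(bad))
      stop("invalid category code for item ", it, ": ",
           paste(unique(v[bad]), collapse = ", "))
  }

  if (!is.null(gender)) {
    gender <- factor(as.character(gender), levels = c("F", "M"))
    stopifnot(length(gender) == nrow(m))
  }
  if (!is.null(age)) {
    age <- as.numeric(age)
    stopifnot(length(age) == nrow(m))
  }

  structure(
    list(responses = m, persons = person_ids, items = spec$item_ids,
         gender = gender, age = age, spec = spec),
    class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> ", nrow(x$responses), " persons x ",
      ncol(x$responses), " items, ",
      sum(is.na(x$responses)), " missing cells\n", sep = "")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

subset_persons <- function(rm, keep) {
  structure(
    list(responses = rm$responses[keep, , drop = FALSE],
         persons = rm$persons[keep], items = rm$items,
         gender = if (!is.null(rm$gender)) rm$gender[keep],
         age = if (!is.null(rm$age)) rm$age[keep],
         spec = rm$spec),
    class = "response_matrix")
}

#' Read questionnaire responses from CSV
#'
#' Canonical layout: first column person id, one column per item id,
#' then optional `gender` (F/M) and `age` (integer years). Blank cells
#' are missing; cells that do not parse as a valid category code are
#' converted to missing with a single warning giving the count.
#' Spreadsheet submissions should be exported to CSV first.
#'
#' @param path CSV file path.
#' @param spec a [scale_spec()].
#' @return a [response_matrix()].
#' @export
read_responses <- function(path, spec) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("", "NA"))
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate person id in ", path)
  covar <- intersect(c("gender", "age"), names(df))
  item_cols <- setdiff(names(df)[-1L], covar)
  unknown <- setdiff(item_cols, spec$item_ids)
  if (length(unknown))
    stop("unknown item column: ", paste(unknown, collapse = ", "))
  missing_items <- setdiff(spec$item_ids, item_cols)
  if (length(missing_items))
    stop("missing item columns: ", paste(missing_items, collapse = ", "))

  m <- matrix(NA_integer_, nrow(df), length(spec$item_ids),
              dimnames = list(ids, spec$item_ids))
  n_bad <- 0L
  for (it in spec$item_ids) {
    v <- suppressWarnings(as.integer(df[[it]]))
    bad <- (!is.na(df[[it]])) & (is.na(v) | v < 1L | v > spec$n_categories[[it]])
    n_bad <- n_bad + sum(bad)
    v[bad] <- NA_integer_
    m[, it] <- v
  }
  if (n_bad > 0L)
    warning(n_bad, " unparseable or out-of-range cells set to missing")

  response_matrix(
    m, spec,
    gender = if ("gender" %in% covar) df[["gender"]],
    age = if ("age" %in% covar) suppressWarnings(as.numeric(df[["age"]])),
    person_ids = ids)
}

#' Write responses to CSV in the canonical layout
#'
#' @param rm a [response_matrix()].
#' @param path output file path.
#' @export
write_responses <- function(rm, path) {
  df <- data.frame(person = rm$persons, rm$responses, check.names = FALSE)
  if (!is.null(rm$gender)) df$gender <- as.character(rm$gender)
  if (!is.null(rm$age)) df$age <- rm$age
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Compute raw scale or subscale scores
#'
#' Sums the score-chart contribution of each observed category over the
#' requested scale's items. By default the score is undefined (`NA`) for
#' a person missing any item of the scale; with `prorate = TRUE` the
#' observed mean contribution is rescaled to the full item count.
#'
#' @param rm a [response_matrix()].
#' @param scale `"total"` (default) or a subscale name.
#' @param prorate logical; prorate incomplete persons instead of `NA`.
#' @return named numeric vector of scores per person.
#' @export
raw_score <- function(rm, scale = "total", prorate = FALSE) {
  spec <- rm$spec
  ch <- chart_for(spec, scale)
  items <- names(ch)
  contrib <- matrix(NA_real_, nrow(rm$responses), length(items),
                    dimnames = list(rm$persons, items))
  for (it in items) {
    v <- rm$responses[, it]
    contrib[, it] <- ifelse(is.na(v), NA_real_, ch[[it]][v])
  }
  if (prorate) {
    k <- rowSums(!is.na(contrib))
    s <- rowMeans(contrib, na.rm = TRUE) * length(items)
    s[k == 0L] <- NA_real_
    s
  } else {
    rowSums(contrib)
  }
}

#' Apply the study's person inclusion filters
#'
#' Retains persons who answered at least `min_answered` items AND whose
#' person outfit mean square does not exceed `outfit_cap` (the rule is
#' strictly "over", so outfit exactly at the cap is retained; persons
#' with undefined outfit, e.g. extreme scorers, pass the outfit rule).
#' Exclusion counts per reason are attached as attribute `"exclusions"`.
#'
#' @param rm a [response_matrix()].
#' @param person_outfit named numeric vector of outfit mean squares (from
#'   [fit_statistics()] on a preliminary fit); `NULL` skips the rule.
#' @param min_answered minimum items answered (default 12).
#' @param outfit_cap outfit exclusion threshold (default 2.5).
#' @return filtered [response_matrix()] with an `"exclusions"` attribute.
#' @export
filter_persons <- function(rm, person_outfit = NULL, min_answered = 12L,
                           outfit_cap = 2.5) {
  if (min_answered > length(rm$items))
    stop("min_answered exceeds the item count")
  answered <- rowSums(!is.na(rm$responses))
  few <- answered < min_answered
  misfit <- rep(FALSE, length(rm$persons))
  if (!is.null(person_outfit)) {
    of <- person_outfit[rm$persons]
    misfit <- !is.na(of) & of > outfit_cap
  }
  out <- subset_persons(rm, !(few | misfit))
  attr(out, "exclusions") <- c(
    too_few_answered = sum(few),
    outfit_over_cap = sum(misfit & !few),
    retained = sum(!(few | misfit)))
  out
}

#' Assign gender x presbyopia groups
#'
#' Partition persons into non-presbyope women (NPW), non-presbyope men
#' (NPM), presbyope women (PW) and presbyope men (PM). Presbyopia is
#' proxied by age strictly over `presbyopia_age` (default 39 years).
#' Persons with missing gender or age get `NA` and are counted in the
#' `"n_ungrouped"` attribute.
#'
#' @param rm a [response_matrix()] with gender and age.
#' @param presbyopia_age age threshold; presbyope means age > threshold.
#' @return factor of group labels (`NPW`, `NPM`, `PW`, `PM`) per person.
#' @export
assign_groups <- function(rm, presbyopia_age = 39) {
  if (is.null(rm$gender) || is.null(rm$age))
    stop("gender and age covariates required")
  presby <- rm$age > presbyopia_age
  lab <- ifelse(is.na(rm$gender) | is.na(presby), NA_character_,
                paste0(ifelse(presby, "P", "NP"),
                       ifelse(rm$gender == "F", "W", "M")))
  g <- factor(lab, levels = c("NPW", "NPM", "PW", "PM"))
  names(g) <- rm$persons
  attr(g, "n_ungrouped") <- sum(is.na(g))
  g
}
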