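#' Median imputation of missing ordinal responses
#'
#' Replaces each missing cell with the median of the observed responses to
#' that item, pooled over all respondents in the supplied data. With an
#' even number of observations the default convention is the lower median,
#' so the imputed value is always an attained (valid ordinal) category
#' code; `even = "midpoint"` instead rounds the midpoint of the two
#' central values to the nearest integer.
#'
#' @param data Data frame of responses (item columns; optional
#'   `respondent_id`). Missing responses are `NA`.
#' @param items Item columns to impute; default every non-identifier column.
#' @param even Even-count median convention: `"lower"` (default) or
#'   `"midpoint"`.
#' @return The completed tibble. The imputation audit record is attached as
#'   attribute `"imputation_report"` and can be read with
#'   [imputation_report()].
#' @examples
#' x <- data.frame(a = c(1, 2, NA, 4), b = c(2, 2, 3, 3))
#' imputation_report(impute_median(x))
#' @export
impute_median <- function(data, items = NULL, even = c("lower", "midpoint")) {
  even <- match.arg(even)
  m <- response_matrix(data, items)
  items <- colnames(m)
  n_cells <- length(m)
  n_missing <- sum(is.na(m))
  medians <- setNames(rep(NA_real_, length(items)), items)
  for (j in seq_along(items)) {
    v <- m[, j]
    obs <- v[!is.na(v)]
    if (length(obs) == 0L) {
      abort(paste0("Item '", items[j], "' has no observed values to impute from."))
    }
    s <- sort(obs)
    n <- length(s)
    med <- if (n %% 2L == 1L) {
      s[(n + 1L) %/% 2L]
    } else if (even == "lower") {
      s[n %/% 2L]
    } else {
      round((s[n %/% 2L] + s[n %/% 2L + 1L]) / 2)
    }
    medians[j] <- med
    m[is.na(v), j] <- med
  }
  out <- as_tibble(data)
  out[items] <- as.data.frame(m)
  report <- tibble(
    n_cells = n_cells,
    n_missing = n_missing,
    fraction_missing = n_missing / n_cells
  )
  report$per_item_medians <- list(tibble(item = items, median = unname(medians)))
  attr(out, "imputation_report") <- report
  out
}

#' Retrieve the imputation audit record
#'
#' @param data A tibble returned by [impute_median()].
#' @return A one-row tibble with `n_cells`, `n_missing`, `fraction_missing`
#'   and a `per_item_medians` list-column.
#' @export
imputation_report <- function(data) {
  rep <- attr(data, "imputation_report")
  if (is.null(rep)) abort("No imputation report attached; run impute_median() first.")
  rep
}

#' Scaled mean rating per item
#'
#' The mean observed code for an item divided by its number of response
#' options, placing 4- and 5-point items on a common (0, 1] scale for
#' side-by-side reporting.
#'
#' @inheritParams sum_score
#' @return A tibble with columns `item` and `scaled_mean_rating`.
#' @examples
#' inst <- new_instrument(data.frame(id = "a", n_categories = 5))
#' scaled_mean_rating(data.frame(a = c(1, 2)), inst)
#' @export
scaled_mean_rating <- function(data, instrument, items = NULL) {
  inst <- instrument_subset(instrument, items)
  m <- response_matrix(data, inst$id)
  if (anyNA(m)) {
    abort("Missing values present; impute first (impute_median()).")
  }
  tibble(
    item = inst$id,
    scaled_mean_rating = unname(colMeans(m) / inst$n_categories)
  )
}
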