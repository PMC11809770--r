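#' Read an instrument definition
#'
#' An instrument definition lists the items of a questionnaire in
#' administration order, one record per item, with the fields `id` (unique
#' string), `text`, `domain`, `n_categories` (number of response options,
#' at least 2), `core` (locked into every candidate subset during item
#' selection), `min_code` (lowest score a response contributes, usually 1)
#' and optionally `reverse` (reverse-keyed before summation; default
#' `FALSE`). Definitions are stored either as CSV (comment lines starting
#' with `#` allowed) or as YAML with an `items` list.
#'
#' @param path Path to a CSV or YAML instrument definition.
#' @param name Instrument name; defaults to the file name.
#' @return A tibble of class `instrument`, one row per item.
#' @examples
#' clcf_sf()
#' @export
read_instrument <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("No such instrument file: ", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    doc <- yaml::read_yaml(path)
    if (is.null(doc$items)) abort("YAML instrument definition needs an `items` list.")
    items <- dplyr::bind_rows(lapply(doc$items, as_tibble))
    if (is.null(name)) name <- doc$name
  } else {
    items <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                             progress = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  new_instrument(items, name = name)
}

#' Construct an instrument from an item table
#'
#' @param items Data frame with columns `id`, `n_categories` and optionally
#'   `text`, `domain`, `core`, `min_code`, `reverse`.
#' @param name Instrument name.
#' @return A tibble of class `instrument`.
#' @export
new_instrument <- function(items, name = "instrument") {
  items <- as_tibble(items)
  required <- c("id", "n_categories")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0L) {
    abort(paste0("Instrument definition lacks fields: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(items) == 0L) abort("An instrument needs at least one item.")
  if (!"text" %in% names(items)) items$text <- items$id
  if (!"domain" %in% names(items)) items$domain <- NA_character_
  if (!"core" %in% names(items)) items$core <- FALSE
  if (!"min_code" %in% names(items)) items$min_code <- 1L
  if (!"reverse" %in% names(items)) items$reverse <- FALSE
  known <- c("id", "text", "domain", "n_categories", "core", "min_code", "reverse")
  unknown <- setdiff(names(items), known)
  if (length(unknown) > 0L) {
    abort(paste0("Unknown instrument fields: ", paste(unknown, collapse = ", ")))
  }
  items$id <- as.character(items$id)
  items$core <- as.logical(items$core)
  items$reverse <- as.logical(items$reverse)
  items$n_categories <- as.integer(items$n_categories)
  items$min_code <- as.integer(items$min_code)
  dup <- unique(items$id[duplicated(items$id)])
  if (length(dup) > 0L) {
    abort(paste0("Duplicated item id(s): ", paste(dup, collapse = ", ")))
  }
  bad <- items$id[items$n_categories < 2L | is.na(items$n_categories)]
  if (length(bad) > 0L) {
    abort(paste0("n_categories must be >= 2; offending item(s): ",
                 paste(bad, collapse = ", ")))
  }
  items <- items[known]
  structure(items, name = name,
            class = c("instrument", class(items)))
}

#' The packaged CLCF-SF instrument definition
#'
#' The 15-item short form of the Challenge of Living with Cystic Fibrosis
#' questionnaire: five core items (three expert-chosen challenge items plus
#' two perceived-support items added to preserve content validity) and ten
#' items selected by the genetic algorithm. Thirteen items use a 5-point
#' Likert scale and two use a 4-point scale, all scored from 1, so totals
#' range from 15 to 73, higher totals indicating greater caregiving
#' challenge. Item wording in the packaged file is synthetic placeholder
#' text (see the file header in `inst/extdata/`); the structural fields
#' (counts, scale sizes, core flags, scoring) are the published ones.
#'
#' @return A tibble of class `instrument` with 15 rows.
#' @examples
#' score_range(clcf_sf())
#' @export
clcf_sf <- function() {
  read_instrument(
    system.file("extdata", "clcf_sf.csv", package = "shortscale"),
    name = "CLCF-SF"
  )
}

#' @export
print.instrument <- function(x, ...) {
  cat("<instrument> ", attr(x, "name"), ": ", nrow(x), " items (",
      sum(x$core), " core)\n", sep = "")
  NextMethod()
}

instrument_subset <- function(instrument, items = NULL) {
  if (is.null(items)) return(instrument)
  unknown <- setdiff(items, instrument$id)
  if (length(unknown) > 0L) {
    abort(paste0("Item(s) not in instrument: ", paste(unknown, collapse = ", ")))
  }
  instrument[match(items, instrument$id), , drop = FALSE]
}

#' Total (summative) scores over an item subset
#'
#' Sums raw category codes per respondent over the chosen items;
#' reverse-keyed items are reflected about their scale midpoint first.
#' Higher totals indicate greater challenge (the scoring direction of the
#' CLCF family of instruments). Missing values inside the subset are an
#' error: impute first (see [impute_median()]).
#'
#' @param data Data frame of responses, one row per respondent, one column
#'   per item (an optional `respondent_id` column is carried through).
#' @param instrument An `instrument`.
#' @param items Character vector of item ids to score; default all items.
#' @return A tibble with columns `respondent_id` and `total`.
#' @examples
#' inst <- clcf_sf()
#' resp <- as.data.frame(setNames(as.list(inst$min_code), inst$id))
#' sum_score(resp, inst)  # all-lowest responses give the minimum total
#' @export
sum_score <- function(data, instrument, items = NULL) {
  inst <- instrument_subset(instrument, items)
  m <- response_matrix(data, inst$id)
  if (anyNA(m)) {
    abort(paste0(
      "Missing values among the scored items (",
      sum(is.na(m)), " cell(s)). Impute first, e.g. with impute_median()."
    ))
  }
  validate_codes(m, inst)
  rev_idx <- which(inst$reverse)
  for (j in rev_idx) {
    lo <- inst$min_code[j]
    hi <- inst$min_code[j] + inst$n_categories[j] - 1L
    m[, j] <- lo + hi - m[, j]
  }
  tibble(respondent_id = respondent_ids(data), total = unname(rowSums(m)))
}

# Check observed codes against each item's admissible range.
validate_codes <- function(m, inst, context = "response") {
  for (j in seq_len(ncol(m))) {
    lo <- inst$min_code[j]
    hi <- lo + inst$n_categories[j] - 1L
    v <- m[, j]
    bad <- which(!is.na(v) & (v < lo | v > hi | v != round(v)))
    if (length(bad) > 0L) {
      abort(paste0(
        "Out-of-range ", context, " for item '", inst$id[j], "' (allowed ",
        lo, "..", hi, ") in row(s): ", paste(head(bad, 5L), collapse = ", ")
      ))
    }
  }
  invisible(m)
}

#' Attainable score range of an item subset
#'
#' The minimum total is the sum of the items' lowest codes and the maximum
#' the sum of their highest codes; these equal the extremes over all
#' response patterns. For the packaged CLCF-SF (13 five-point and 2
#' four-point items scored from 1) the range is 15 to 73.
#'
#' @inheritParams sum_score
#' @return A one-row tibble with columns `min_total` and `max_total`.
#' @examples
#' score_range(clcf_sf())
#' @export
score_range <- function(instrument, items = NULL) {
  inst <- instrument_subset(instrument, items)
  if (nrow(inst) == 0L) abort("Empty item subset has no score range.")
  tibble(
    min_total = sum(inst$min_code),
    max_total = sum(inst$min_code + inst$n_categories - 1L)
  )
}

#' Count of treatments in use per respondent
#'
#' Collapses a per-respondent treatment usage table (indicator or
#' frequency columns, one per treatment) into the number of distinct
#' treatments with nonzero usage — the simple treatment-burden sum score
#' used alongside the treatment-management scales.
#'
#' @param data Data frame with one column per treatment holding nonnegative
#'   indicators or frequencies (an optional `respondent_id` column is
#'   carried through). `NA` cells are treated as "not received".
#' @return A tibble with columns `respondent_id` and `n_treatments`.
#' @examples
#' treatment_count_score(data.frame(neb = c(1, 0), iv = c(2, 0), physio = c(1, 1)))
#' @export
treatment_count_score <- function(data) {
  m <- response_matrix(data)
  if (any(m < 0, na.rm = TRUE)) {
    abort("Treatment usage must be nonnegative indicators or frequencies.")
  }
  m[is.na(m)] <- 0
  tibble(
    respondent_id = respondent_ids(data),
    n_treatments = unname(as.integer(rowSums(m > 0)))
  )
}
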