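# Internal helpers shared across modules.

# Deterministically expand one global seed into `n` stage seeds.
# Kept below 2^31 so they remain valid R integers.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Evaluate `expr` under a seed without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  force(expr)
}

# Extract the numeric item-response columns of a data frame as a matrix,
# dropping known identifier columns.
response_matrix <- function(data, items = NULL) {
  stopifnot(is.data.frame(data))
  id_cols <- intersect(names(data), c("respondent_id", ".id"))
  if (is.null(items)) {
    items <- setdiff(names(data), id_cols)
  } else {
    missing_items <- setdiff(items, names(data))
    if (length(missing_items) > 0L) {
      abort(paste0(
        "Items not present in data: ",
        paste(missing_items, collapse = ", ")
      ))
    }
  }
  m <- as.matrix(data[items])
  if (!is.numeric(m)) {
    abort("Response columns must be numeric category codes.")
  }
  rownames(m) <- if ("respondent_id" %in% names(data)) {
    as.character(data$respondent_id)
  } else {
    as.character(seq_len(nrow(data)))
  }
  m
}

respondent_ids <- function(data) {
  if ("respondent_id" %in% names(data)) data$respondent_id else seq_len(nrow(data))
}
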