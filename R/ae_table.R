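#' Per-arm adverse-event frequency table for one randomized trial
#'
#' An `ae_table` holds, for a single parallel-group trial, the number of
#' participants in each arm who experienced at least one event of each
#' distinct adverse-event (AE) term, together with the per-arm
#' safety-population sizes. It is the complete, clinical-study-report-style
#' listing that selection criteria are applied to. Counts are always
#' participants with one or more events, never event counts.
#'
#' @param data A data frame in long format with columns `trial_id`, `arm`,
#'   `n` (safety-population size of the arm), `is_active` (logical or 0/1
#'   flag marking a test-intervention arm), `ae_term` and `count`
#'   (participants with >= 1 event of that term in that arm). One row per
#'   (arm, term) pair; rows for the same term across arms are merged into
#'   one record. Arms that appear only in the sizing rows (count columns
#'   all zero for a term) are allowed; missing (arm, term) pairs are
#'   treated as zero counts.
#' @param trial_id Optional trial identifier; defaults to the unique
#'   `trial_id` value found in `data`.
#'
#' @details
#' Validation enforces the invariants the downstream engine relies on:
#' at least two arms with at least one active and one non-active arm;
#' positive arm sizes; `count <= n` for every cell; AE terms unique after
#' trimming/case-folding (original casing is preserved for display); no
#' duplicate (arm, term) rows; and every stored term has at least one
#' affected participant somewhere in the trial (all-zero terms are
#' dropped silently on construction, mirroring that observed-event
#' listings only contain events that occurred).
#'
#' The per-arm denominator `n` is caller-supplied (conventionally the
#' safety population); no denominator is ever derived from the counts.
#'
#' @return An object of class `ae_table`.
#' @examples
#' df <- data.frame(
#'   trial_id = "T1",
#'   arm = rep(c("gabapentin", "placebo"), each = 2),
#'   n = 100, is_active = rep(c(TRUE, FALSE), each = 2),
#'   ae_term = rep(c("dizziness", "headache"), 2),
#'   count = c(20, 6, 5, 6)
#' )
#' ae_table(df)
#' @export
ae_table <- function(data, trial_id = NULL) {
  req <- c("trial_id", "arm", "n", "is_active", "ae_term", "count")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`data` is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "aeselect_schema_error")
  }
  data <- as.data.frame(data)[req]
  ids <- unique(as.character(data$trial_id))
  if (is.null(trial_id)) {
    if (length(ids) != 1L) {
      abort("`data` must describe exactly one trial (found multiple trial_id values); pass `trial_id` to select one.",
        class = "aeselect_schema_error")
    }
    trial_id <- ids
  } else {
    data <- data[as.character(data$trial_id) == trial_id, , drop = FALSE]
    if (nrow(data) == 0L) {
      abort(sprintf("no rows for trial_id '%s'", trial_id),
        class = "aeselect_schema_error")
    }
  }

  arm_info <- unique(data.frame(
    arm = as.character(data$arm),
    n = as.numeric(data$n),
    is_active = as.logical(data$is_active),
    stringsAsFactors = FALSE
  ))
  if (anyDuplicated(arm_info$arm)) {
    bad <- arm_info$arm[duplicated(arm_info$arm)]
    abort(sprintf(
      "inconsistent n/is_active for arm(s): %s", paste(unique(bad), collapse = ", ")
    ), class = "aeselect_validation_error")
  }
  new_ae_table(
    trial_id = trial_id,
    arms = tibble(
      arm = arm_info$arm, n = arm_info$n, is_active = arm_info$is_active
    ),
    long = data
  )
}

# Internal constructor from an arms tibble plus long (arm, term, count) rows.
new_ae_table <- function(trial_id, arms, long = NULL, counts = NULL) {
  if (nrow(arms) < 2L) {
    abort("an AE table needs at least two arms", class = "aeselect_validation_error")
  }
  if (any(is.na(arms$n)) || any(arms$n < 1) || any(arms$n != round(arms$n))) {
    abort("arm sizes `n` must be positive integers",
      class = "aeselect_validation_error")
  }
  if (any(is.na(arms$is_active))) {
    abort("`is_active` must be TRUE/FALSE (or 0/1) for every arm",
      class = "aeselect_validation_error")
  }
  if (!any(arms$is_active) || all(arms$is_active)) {
    abort("an AE table needs at least one active and one non-active arm",
      class = "aeselect_validation_error")
  }

  if (is.null(counts)) {
    counts <- counts_matrix_from_long(long, arms, trial_id)
  }
  validate_counts(counts, arms, trial_id)

  structure(
    list(
      trial_id = trial_id,
      arms = arms,
      counts = counts
    ),
    class = "ae_table"
  )
}

counts_matrix_from_long <- function(long, arms, trial_id) {
  long$arm <- as.character(long$arm)
  long$ae_term <- as.character(long$ae_term)
  # rows with a missing term are arm-sizing rows only (empty tables)
  long <- long[!is.na(long$ae_term) & trimws(long$ae_term) != "", , drop = FALSE]
  unknown <- setdiff(long$arm, arms$arm)
  if (length(unknown) > 0) {
    abort(sprintf("rows reference unknown arm(s): %s", paste(unknown, collapse = ", ")),
      class = "aeselect_schema_error")
  }
  key <- paste(long$arm, norm_term(long$ae_term), sep = "\r")
  if (anyDuplicated(key)) {
    d <- long[duplicated(key), , drop = FALSE]
    abort(sprintf(
      "trial '%s': duplicate (arm, term) row(s), e.g. arm '%s' term '%s'",
      trial_id, d$arm[1], d$ae_term[1]
    ), class = "aeselect_validation_error")
  }
  # first-seen original casing wins for display
  nt <- norm_term(long$ae_term)
  first <- !duplicated(nt)
  display <- setNames(long$ae_term[first], nt[first])
  terms <- unname(display[unique(nt)])
  m <- matrix(0, nrow = length(terms), ncol = nrow(arms),
    dimnames = list(terms, arms$arm))
  if (length(terms) > 0) {
    m[cbind(match(nt, norm_term(terms)), match(long$arm, arms$arm))] <-
      as.numeric(long$count)
  }
  keep <- rowSums(m) > 0
  m[keep, , drop = FALSE]
}

validate_counts <- function(counts, arms, trial_id) {
  if (!is.matrix(counts)) abort("internal: counts must be a matrix")
  if (ncol(counts) != nrow(arms) || !identical(colnames(counts), arms$arm)) {
    abort("internal: counts columns must match arms")
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort(sprintf("trial '%s': counts must be non-negative integers", trial_id),
      class = "aeselect_validation_error")
  }
  over <- which(t(t(counts) > arms$n), arr.ind = TRUE)
  if (nrow(over) > 0) {
    abort(sprintf(
      "trial '%s': count exceeds arm size for term '%s' in arm '%s' (%d > %d)",
      trial_id, rownames(counts)[over[1, 1]], arms$arm[over[1, 2]],
      as.integer(counts[over[1, , drop = FALSE]]),
      as.integer(arms$n[over[1, 2]])
    ), class = "aeselect_validation_error")
  }
  nt <- norm_term(rownames(counts))
  if (anyDuplicated(nt)) {
    abort(sprintf(
      "trial '%s': duplicate AE term after normalization: '%s'",
      trial_id, rownames(counts)[duplicated(nt)][1]
    ), class = "aeselect_validation_error")
  }
  if (nrow(counts) > 0 && any(rowSums(counts) == 0)) {
    abort(sprintf("trial '%s': terms with zero participants overall are not stored",
      trial_id), class = "aeselect_validation_error")
  }
  invisible(counts)
}

#' @export
print.ae_table <- function(x, ...) {
  cat(sprintf(
    "<ae_table> trial '%s': %d AE terms, %d arms (%s)\n",
    x$trial_id, nrow(x$counts), nrow(x$arms),
    paste0(x$arms$arm, ifelse(x$arms$is_active, "*", ""), "=n", x$arms$n,
      collapse = ", ")
  ))
  cat("  (* = active/test-intervention arm)\n")
  if (nrow(x$counts) > 0) {
    shown <- head(ae_terms(x), 8)
    cat("  terms:", paste(shown, collapse = ", "),
      if (nrow(x$counts) > 8) "...\n" else "\n")
  }
  invisible(x)
}

#' AE terms stored in a table
#'
#' @param table An [ae_table].
#' @param sorted Sort terms alphabetically (default) or keep storage order.
#' @return Character vector of AE term names (original casing).
#' @export
ae_terms <- function(table, sorted = TRUE) {
  stopifnot(inherits(table, "ae_table"))
  out <- rownames(table$counts)
  if (is.null(out)) out <- character(0)
  if (sorted) sort(out, method = "radix") else out
}

#' @exportS3Method tibble::as_tibble
as_tibble.ae_table <- function(x, ...) {
  if (nrow(x$counts) == 0) {
    # sizing rows only, so arm structure survives a round trip
    return(tibble(
      trial_id = x$trial_id, arm = x$arms$arm, n = as.integer(x$arms$n),
      is_active = x$arms$is_active, ae_term = NA_character_,
      count = NA_integer_
    ))
  }
  grid <- expand.grid(
    ae_term = rownames(x$counts), arm = x$arms$arm,
    stringsAsFactors = FALSE
  )
  i <- match(grid$arm, x$arms$arm)
  tibble(
    trial_id = x$trial_id,
    arm = grid$arm,
    n = as.integer(x$arms$n[i]),
    is_active = x$arms$is_active[i],
    ae_term = grid$ae_term,
    count = as.integer(x$counts[cbind(grid$ae_term, grid$arm)])
  )
}

#' @export
format.ae_table <- function(x, ...) {
  sprintf("<ae_table '%s': %d terms x %d arms>", x$trial_id,
    nrow(x$counts), nrow(x$arms))
}
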