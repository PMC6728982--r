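#' Read and write per-arm AE frequency tables
#'
#' Two plain-text serializations are supported:
#'
#' * `csv_long` — UTF-8 CSV with header
#'   `trial_id,arm,n,is_active,ae_term,count`, one row per (arm, term)
#'   pair, `is_active` in `{0,1}`. A table with no AE records is written
#'   as one sizing row per arm with an empty `ae_term`.
#' * `json` — one object per trial with fields `trial_id`, `arms`
#'   (list of `{name, n, is_active}`) and `records` (list of
#'   `{term, counts}` with `counts` a map arm name -> count).
#'
#' Both formats round-trip exactly: `read_ae_table(write_ae_table(t))`
#' reproduces `t` (terms, counts, arm sizes and active flags).
#'
#' @param path File path.
#' @param format `"csv_long"` or `"json"`; default is guessed from the
#'   file extension (`.json` vs anything else).
#' @return `read_ae_table()` returns a validated [ae_table];
#'   `write_ae_table()` returns `path` invisibly.
#' @examples
#' tab <- ae_table(data.frame(
#'   trial_id = "T1", arm = rep(c("drug", "placebo"), each = 2), n = 100,
#'   is_active = rep(c(1, 0), each = 2),
#'   ae_term = rep(c("dizziness", "nausea"), 2), count = c(20, 3, 5, 1)
#' ))
#' f <- tempfile(fileext = ".csv")
#' write_ae_table(tab, f)
#' identical(read_ae_table(f)$counts, tab$counts)
#' @export
read_ae_table <- function(path, format = c("auto", "csv_long", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv_long"
  }
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "aeselect_io_error")
  }
  if (format == "csv_long") {
    df <- readr::read_csv(path, col_types = readr::cols(
      trial_id = readr::col_character(),
      arm = readr::col_character(),
      n = readr::col_double(),
      is_active = readr::col_double(),
      ae_term = readr::col_character(),
      count = readr::col_double()
    ))
    req <- c("trial_id", "arm", "n", "is_active", "ae_term", "count")
    if (!all(req %in% names(df))) {
      abort(sprintf(
        "%s: csv_long requires columns %s", path, paste(req, collapse = ",")
      ), class = "aeselect_schema_error")
    }
    if (any(is.na(df$n))) {
      abort(sprintf("%s: missing arm-size (n) value", path),
        class = "aeselect_schema_error")
    }
    # sizing rows have an empty term and a missing count
    df$count[is.na(df$ae_term) | trimws(df$ae_term) == ""] <- 0
    ae_table(df)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    arms <- tibble(
      arm = vapply(obj$arms, function(a) as.character(a$name), character(1)),
      n = vapply(obj$arms, function(a) as.numeric(a$n), numeric(1)),
      is_active = vapply(obj$arms, function(a) as.logical(a$is_active), logical(1))
    )
    recs <- obj$records %||% list()
    long <- purrr::map_dfr(recs, function(r) {
      cts <- unlist(r$counts)
      tibble(arm = names(cts), ae_term = as.character(r$term),
        count = as.numeric(cts))
    })
    if (nrow(long) == 0) {
      long <- tibble(arm = character(), ae_term = character(), count = numeric())
    }
    new_ae_table(trial_id = as.character(obj$trial_id), arms = arms, long = long)
  }
}

#' @param table An [ae_table] to serialize.
#' @rdname read_ae_table
#' @export
write_ae_table <- function(table, path, format = c("auto", "csv_long", "json")) {
  stopifnot(inherits(table, "ae_table"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv_long"
  }
  if (format == "csv_long") {
    df <- as_tibble(table)
    df$is_active <- as.integer(df$is_active)
    readr::write_csv(df, path, na = "")
  } else {
    obj <- list(
      trial_id = table$trial_id,
      arms = purrr::pmap(table$arms, function(arm, n, is_active) {
        list(name = arm, n = as.integer(n), is_active = is_active)
      }),
      records = purrr::map(seq_len(nrow(table$counts)), function(i) {
        list(
          term = rownames(table$counts)[i],
          counts = as.list(setNames(
            as.integer(table$counts[i, ]), colnames(table$counts)
          ))
        )
      })
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
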