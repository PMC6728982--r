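#' Adverse-event selection criteria
#'
#' A selection criterion is the rule a trial report uses to decide which
#' AE terms it lists. It has three components:
#'
#' 1. a **numerical threshold** — a minimum proportion of participants
#'    experiencing the AE (inclusive, `>=`), e.g. "occurring in >= 2%";
#' 2. a **participant-group scope** — whose proportion is thresholded:
#'    `"any"` single arm, the pooled `"active"` (test-intervention)
#'    arm(s), or `"all"` arms combined; and
#' 3. an optional **difference-between-groups rule** — `"none"`,
#'    `"higher"` (strictly greater pooled-active than pooled-comparator
#'    proportion), or `"ratio"` (pooled-active at least `ratio` times the
#'    comparator proportion; a positive active proportion against a zero
#'    comparator passes, zero against zero fails).
#'
#' @param threshold Proportion in \[0, 1\] (0.02 means ">= 2%").
#' @param scope One of `"any"`, `"active"`, `"all"`.
#' @param diff One of `"none"`, `"higher"`, `"ratio"`.
#' @param ratio Ratio for `diff = "ratio"`; must be > 1. Default 2
#'   ("at least twice as frequent").
#'
#' @return An object of class `ae_criterion` with fields `threshold`
#'   (proportion), `pct` (the threshold as an exact percent value),
#'   `scope`, `diff`, `ratio` and `label` (the canonical DSL rendering).
#' @seealso [parse_criterion()], [build_grid()], [apply_criterion()]
#' @examples
#' criterion(0.05)                               # ">= 5% in any arm"
#' criterion(0.02, "active", "ratio", ratio = 2) # ">= 2% of active, twice placebo"
#' @export
criterion <- function(threshold, scope = c("any", "active", "all"),
                      diff = c("none", "higher", "ratio"), ratio = 2) {
  scope <- match.arg(scope)
  diff <- match.arg(diff)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
    threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single proportion in [0, 1]",
      class = "aeselect_criterion_error")
  }
  # exact percent value; round() strips binary representation dust so the
  # engine's integer cross-multiplication (count*100 >= pct*n) is exact
  pct <- round(threshold * 100, 9)
  if (diff == "ratio") {
    if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio <= 1) {
      abort("`ratio` must be a single number > 1",
        class = "aeselect_criterion_error")
    }
  } else {
    ratio <- NA_real_
  }
  out <- structure(
    list(threshold = pct / 100, pct = pct, scope = scope, diff = diff,
      ratio = ratio),
    class = "ae_criterion"
  )
  out$label <- render_criterion(out)
  out
}

#' Render a criterion to its canonical DSL string
#'
#' The grammar is `thr=<number>%;scope=<any|active|all>;diff=<none|higher|ratio>=<r>>`.
#' Rendering is canonical: `parse_criterion(render_criterion(x))` equals `x`.
#'
#' @param x An `ae_criterion`.
#' @return A single string.
#' @export
render_criterion <- function(x) {
  stopifnot(inherits(x, "ae_criterion"))
  diff <- if (x$diff == "ratio") {
    paste0("ratio>=", fmt_pct(x$ratio))
  } else {
    x$diff
  }
  sprintf("thr=%s%%;scope=%s;diff=%s", fmt_pct(x$pct), x$scope, diff)
}

#' Parse a criterion DSL string
#'
#' Accepts `thr=<number>%` optionally followed by `;scope=<any|active|all>`
#' and `;diff=<none|higher|ratio>=<r>>` in any order. Omitted scope
#' defaults to `"any"`, omitted diff to `"none"`. Parsing composed with
#' rendering is the identity on canonical strings.
#'
#' @param text A criterion string, e.g. `"thr=5%;scope=any;diff=none"` or
#'   `"thr=2%;scope=active;diff=ratio>=2"`.
#' @return An `ae_criterion`.
#' @examples
#' parse_criterion("thr=5%")
#' parse_criterion("thr=10%;scope=active;diff=ratio>=2")
#' @export
parse_criterion <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("`text` must be a single string", class = "aeselect_parse_error")
  }
  parts <- strsplit(trimws(text), ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  if (length(parts) == 0) {
    parse_fail(text, 1L, "empty criterion")
  }
  thr <- NULL
  scope <- "any"
  diff <- "none"
  ratio <- 2
  pos <- 1L
  seen <- character(0)
  for (p in parts) {
    pt <- trimws(p)
    key <- sub("=.*$", "", pt)
    if (key %in% seen) parse_fail(text, pos, sprintf("duplicate component '%s'", key))
    if (grepl("^thr=", pt)) {
      num <- sub("^thr=", "", pt)
      if (!grepl("%$", num)) parse_fail(text, pos, "threshold must end in '%'")
      num <- sub("%$", "", num)
      val <- suppressWarnings(as.numeric(num))
      if (is.na(val) || val < 0 || val > 100) {
        parse_fail(text, pos, sprintf("malformed threshold number '%s'", num))
      }
      thr <- val / 100
      seen <- c(seen, "thr")
    } else if (grepl("^scope=", pt)) {
      val <- sub("^scope=", "", pt)
      if (!val %in% c("any", "active", "all")) {
        parse_fail(text, pos, sprintf("unknown scope '%s' (expected any|active|all)", val))
      }
      scope <- val
      seen <- c(seen, "scope")
    } else if (grepl("^diff=", pt)) {
      val <- sub("^diff=", "", pt)
      if (val %in% c("none", "higher")) {
        diff <- val
      } else if (grepl("^ratio>=", val)) {
        r <- suppressWarnings(as.numeric(sub("^ratio>=", "", val)))
        if (is.na(r)) parse_fail(text, pos, "malformed ratio number")
        if (r <= 1) parse_fail(text, pos, sprintf("ratio must be > 1, got %s", fmt_pct(r)))
        diff <- "ratio"
        ratio <- r
      } else {
        parse_fail(text, pos,
          sprintf("unknown diff '%s' (expected none|higher|ratio>=<r>)", val))
      }
      seen <- c(seen, "diff")
    } else {
      parse_fail(text, pos, sprintf("unknown keyword '%s'", key))
    }
    pos <- pos + nchar(p) + 1L
  }
  if (is.null(thr)) parse_fail(text, 1L, "missing required component 'thr'")
  criterion(thr, scope = scope, diff = diff, ratio = ratio)
}

parse_fail <- function(text, pos, msg) {
  abort(sprintf("criterion parse error at position %d in \"%s\": %s",
    pos, text, msg), class = "aeselect_parse_error")
}

#' @export
print.ae_criterion <- function(x, ...) {
  cat("<ae_criterion>", x$label, "\n")
  invisible(x)
}

#' @export
format.ae_criterion <- function(x, ...) x$label

#' Build the crossed grid of selection criteria
#'
#' Forms the full cross-product of numerical thresholds, participant-group
#' scopes and difference rules, in deterministic threshold-major order
#' (then scope, then diff, each in the order given).
#'
#' @param thresholds Numeric vector of proportions in \[0, 1\].
#' @param scopes Character vector from `{"any", "active", "all"}`.
#' @param diffs Character vector of difference rules; `"none"`,
#'   `"higher"`, or `"ratio>=<r>"` (e.g. `"ratio>=2"`).
#' @return A tibble of class `ae_criterion_grid` with columns `label`,
#'   `threshold`, `scope`, `diff`, `ratio` and a list-column `criterion`
#'   of `ae_criterion` objects; one row per grid cell.
#' @examples
#' build_grid(c(0.01, 0.05), c("any", "active", "all"), "none")
#' nrow(build_grid(observed_components())) # 45
#' @export
build_grid <- function(thresholds, scopes = c("any", "active", "all"),
                       diffs = c("none", "higher", "ratio>=2")) {
  if (is.list(thresholds) && all(c("thresholds", "scopes", "diffs") %in% names(thresholds))) {
    comp <- thresholds
    thresholds <- comp$thresholds
    scopes <- comp$scopes
    diffs <- comp$diffs
  }
  check_components(thresholds, "thresholds")
  check_components(scopes, "scopes")
  check_components(diffs, "diffs")

  rows <- tidyr::expand_grid(
    threshold = thresholds, scope = scopes, diff_spec = diffs
  )
  crits <- purrr::pmap(rows, function(threshold, scope, diff_spec) {
    if (grepl("^ratio>=", diff_spec)) {
      criterion(threshold, scope, "ratio",
        ratio = as.numeric(sub("^ratio>=", "", diff_spec)))
    } else {
      criterion(threshold, scope, diff_spec)
    }
  })
  out <- tibble(
    label = vapply(crits, `[[`, character(1), "label"),
    threshold = vapply(crits, `[[`, numeric(1), "threshold"),
    scope = vapply(crits, `[[`, character(1), "scope"),
    diff = vapply(crits, `[[`, character(1), "diff"),
    ratio = vapply(crits, `[[`, numeric(1), "ratio"),
    criterion = crits
  )
  if (anyDuplicated(out$label)) {
    abort("duplicate criteria in grid", class = "aeselect_criterion_error")
  }
  class(out) <- c("ae_criterion_grid", class(out))
  out
}

check_components <- function(x, what) {
  if (length(x) == 0) {
    abort(sprintf("`%s` must be non-empty", what),
      class = "aeselect_criterion_error")
  }
  if (anyDuplicated(x)) {
    abort(sprintf("`%s` contains duplicates", what),
      class = "aeselect_criterion_error")
  }
  invisible(x)
}

#' Observed selection-criterion components
#'
#' The component sets observed across public sources of the gabapentin
#' (neuropathic pain) and quetiapine (bipolar depression) placebo-controlled
#' trials: five numerical thresholds (1%, 2%, 3%, 5%, 10%), all three
#' participant-group scopes, and three difference rules (none, higher in
#' the active group, at least twice the placebo frequency). Crossing them
#' with [build_grid()] gives the 45 combined selection criteria.
#'
#' @return A named list with elements `thresholds` (proportions), `scopes`
#'   and `diffs`, suitable as the first argument of [build_grid()].
#' @examples
#' nrow(build_grid(observed_components())) # 45
#' @export
observed_components <- function() {
  list(
    thresholds = c(0.01, 0.02, 0.03, 0.05, 0.10),
    scopes = c("any", "active", "all"),
    diffs = c("none", "higher", "ratio>=2")
  )
}
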