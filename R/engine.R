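#' Proportion of participants with an AE, by arm or pooled scope
#'
#' @param table An [ae_table].
#' @param term AE term (matched case-insensitively after whitespace
#'   normalization).
#' @param scope Either an arm name, or one of `"active"` (pooled
#'   test-intervention arms), `"all"` (all arms combined), or
#'   `"comparator"` (pooled non-active arms). The `"any"` scope of a
#'   criterion is not a single number; use per-arm calls for it.
#' @return The proportion (count / denominator) as a double.
#' @examples
#' tab <- example_ae_table()
#' ae_proportion(tab, "dizziness", "gabapentin") # 0.20
#' ae_proportion(tab, "dizziness", "all")        # 25/200
#' @export
ae_proportion <- function(table, term, scope) {
  stopifnot(inherits(table, "ae_table"))
  i <- match(norm_term(term), norm_term(rownames(table$counts)))
  if (is.na(i)) {
    abort(sprintf("unknown AE term '%s' in trial '%s'", term, table$trial_id),
      class = "aeselect_validation_error")
  }
  active <- table$arms$is_active
  cts <- table$counts[i, ]
  n <- table$arms$n
  if (scope %in% table$arms$arm) {
    j <- match(scope, table$arms$arm)
    return(unname(cts[j] / n[j]))
  }
  switch(scope,
    active = {
      if (!any(active)) {
        abort("no active arm in table", class = "aeselect_validation_error")
      }
      sum(cts[active]) / sum(n[active])
    },
    all = sum(cts) / sum(n),
    comparator = {
      if (!any(!active)) {
        abort("no comparator arm in table", class = "aeselect_validation_error")
      }
      sum(cts[!active]) / sum(n[!active])
    },
    abort(sprintf("unknown arm or scope '%s'", scope),
      class = "aeselect_validation_error")
  )
}

# Vectorized pass/fail over all stored terms of a table.
#
# All comparisons are exact: a count/n >= pct/100 test is evaluated as
# count*100 >= pct*n, and difference rules cross-multiply the pooled
# fractions, so no rounding happens before comparison. With
# rounded_percents = TRUE, per-scope percentages are first rounded to
# whole percents (round-half-up, as tables in reports are typically
# rounded) and the criterion is evaluated on those rounded values.
passing_mask <- function(counts, n, active, crit,
                         rounded_percents = FALSE, strict = FALSE) {
  if (nrow(counts) == 0) return(logical(0))
  if (!any(active)) {
    abort("criterion requires an active arm but the table has none",
      class = "aeselect_validation_error")
  }
  pct <- crit$pct
  a <- rowSums(counts[, active, drop = FALSE])
  n1 <- sum(n[active])
  cc <- rowSums(counts[, !active, drop = FALSE])
  n0 <- sum(n[!active])

  cmp <- if (strict) `>` else `>=`
  if (rounded_percents) {
    rp_arm <- round_half_up(sweep(counts * 100, 2, n, `/`))
    rp_a <- round_half_up(a * 100 / n1)
    rp_c <- round_half_up(cc * 100 / n0)
    rp_all <- round_half_up(rowSums(counts) * 100 / sum(n))
    thr_ok <- switch(crit$scope,
      any = apply(cmp(rp_arm, pct), 1, any),
      active = cmp(rp_a, pct),
      all = cmp(rp_all, pct)
    )
    diff_ok <- switch(crit$diff,
      none = rep(TRUE, nrow(counts)),
      higher = rp_a > rp_c,
      ratio = (rp_c == 0 & rp_a > 0) | (rp_c > 0 & rp_a >= crit$ratio * rp_c)
    )
  } else {
    thr_ok <- switch(crit$scope,
      any = rowSums(cmp(sweep(counts * 100, 2, pct * n, `-`), 0)) > 0,
      active = cmp(a * 100, pct * n1),
      all = cmp(rowSums(counts) * 100, pct * sum(n))
    )
    diff_ok <- switch(crit$diff,
      none = rep(TRUE, nrow(counts)),
      higher = a * n0 > cc * n1,
      ratio = (cc == 0 & a > 0) | (cc > 0 & a * n0 >= crit$ratio * cc * n1)
    )
  }
  unname(thr_ok & diff_ok)
}

round_half_up <- function(x) floor(x + 0.5)

#' Does a single AE term pass a selection criterion?
#'
#' @inheritParams ae_proportion
#' @param criterion An [criterion()] object or a DSL string.
#' @param rounded_percents Evaluate the criterion on percentages rounded
#'   to whole percents first (some report authors plausibly thresholded
#'   rounded table values). Default `FALSE`: exact fractions.
#' @param strict Use a strict `>` threshold instead of the inclusive `>=`
#'   every observed criterion states. Default `FALSE`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' passes_criterion(example_ae_table(), "dizziness", "thr=5%")
#' @export
passes_criterion <- function(table, term, criterion,
                             rounded_percents = FALSE, strict = FALSE) {
  stopifnot(inherits(table, "ae_table"))
  crit <- as_criterion(criterion)
  i <- match(norm_term(term), norm_term(rownames(table$counts)))
  if (is.na(i)) {
    abort(sprintf("unknown AE term '%s' in trial '%s'", term, table$trial_id),
      class = "aeselect_validation_error")
  }
  mask <- passing_mask(table$counts, table$arms$n, table$arms$is_active,
    crit, rounded_percents = rounded_percents, strict = strict)
  mask[i]
}

as_criterion <- function(x) {
  if (inherits(x, "ae_criterion")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_criterion(x))
  abort("`criterion` must be an ae_criterion or a DSL string",
    class = "aeselect_criterion_error")
}

#' Apply a selection criterion to a trial's AE table
#'
#' Evaluates the criterion for every stored AE term and returns the set
#' of terms that would be reported, together with the percent of the
#' table's distinct terms that set represents (one heat-map cell).
#'
#' @inheritParams passes_criterion
#' @return An object of class `ae_reported_set`: fields `trial_id`,
#'   `criterion`, `terms` (sorted passing term names), `n_total_terms`
#'   and `percent_reported` (100 * passing / total).
#' @examples
#' rs <- apply_criterion(example_ae_table(), "thr=5%;scope=any;diff=none")
#' rs$terms            # dizziness, headache
#' rs$percent_reported # 50
#' @export
apply_criterion <- function(table, criterion,
                            rounded_percents = FALSE, strict = FALSE) {
  stopifnot(inherits(table, "ae_table"))
  crit <- as_criterion(criterion)
  mask <- passing_mask(table$counts, table$arms$n, table$arms$is_active,
    crit, rounded_percents = rounded_percents, strict = strict)
  n_total <- nrow(table$counts)
  terms <- sort(rownames(table$counts)[mask], method = "radix")
  structure(
    list(
      trial_id = table$trial_id,
      criterion = crit,
      terms = terms,
      n_total_terms = n_total,
      percent_reported = if (n_total == 0) 0 else 100 * length(terms) / n_total
    ),
    class = "ae_reported_set"
  )
}

#' @export
print.ae_reported_set <- function(x, ...) {
  cat(sprintf(
    "<ae_reported_set> trial '%s', criterion %s\n  %d/%d terms reported (%.1f%%)\n",
    x$trial_id, x$criterion$label, length(x$terms), x$n_total_terms,
    x$percent_reported
  ))
  if (length(x$terms) > 0) {
    cat("  ", paste(head(x$terms, 10), collapse = ", "),
      if (length(x$terms) > 10) "..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ae_reported_set <- function(x, ...) {
  tibble(
    trial_id = x$trial_id, criterion = x$criterion$label,
    n_reported = length(x$terms), n_total_terms = x$n_total_terms,
    percent_reported = x$percent_reported
  )
}

#' Percent-of-AEs-reported matrix over a criterion grid
#'
#' Applies every criterion of a grid to every trial and collects the
#' percent of each trial's AE terms that would be reported — the data
#' behind a criteria-by-trials heat map. Optionally marks (criterion,
#' trial) pairs as used in at least one real source, which
#' [autoplot.ae_heatmap()] outlines.
#'
#' @param tables A list of [ae_table] objects (or a single table).
#' @param grid An [build_grid()] criterion grid.
#' @param annotations Optional data frame with columns `label` (criterion
#'   label) and `trial_id`, marking criteria actually used by a source.
#' @inheritParams passes_criterion
#' @return A tibble of class `ae_heatmap` in long form: `label`,
#'   `trial_id`, `percent_reported`, `annotated`, with criteria in grid
#'   order and trials in input order (both kept as factor levels).
#' @examples
#' grid <- build_grid(c(0, 0.05), "any", "none")
#' criteria_heatmap(example_ae_table(), grid)
#' @export
criteria_heatmap <- function(tables, grid, annotations = NULL,
                             rounded_percents = FALSE, strict = FALSE) {
  if (inherits(tables, "ae_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1, inherits(grid, "ae_criterion_grid"))
  ids <- vapply(tables, `[[`, character(1), "trial_id")
  if (anyDuplicated(ids)) {
    abort("trial ids must be unique across tables",
      class = "aeselect_validation_error")
  }
  cells <- purrr::map_dfr(seq_along(tables), function(t) {
    tab <- tables[[t]]
    if (!any(tab$arms$is_active)) {
      abort(sprintf("criterion grid inapplicable to trial '%s': no active arm",
        tab$trial_id), class = "aeselect_validation_error")
    }
    tibble(
      label = grid$label,
      trial_id = ids[t],
      percent_reported = vapply(grid$criterion, function(cr) {
        apply_criterion(tab, cr, rounded_percents = rounded_percents,
          strict = strict)$percent_reported
      }, numeric(1))
    )
  })
  cells$annotated <- FALSE
  if (!is.null(annotations)) {
    key <- paste(cells$label, cells$trial_id, sep = "\r")
    akey <- paste(annotations$label, annotations$trial_id, sep = "\r")
    cells$annotated <- key %in% akey
  }
  cells$label <- factor(cells$label, levels = grid$label)
  cells$trial_id <- factor(cells$trial_id, levels = ids)
  cells <- dplyr::arrange(cells, .data$label, .data$trial_id)
  class(cells) <- c("ae_heatmap", class(cells))
  cells
}

#' Heat map of percent of AEs reported per criterion and trial
#'
#' Green marks criteria under which most AE terms would be reported, red
#' the fewest; cells for criteria actually used by at least one source
#' are outlined in black.
#'
#' @param object An `ae_heatmap` from [criteria_heatmap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ae_heatmap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$trial_id, y = .data$label, fill = .data$percent_reported
  )) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::geom_tile(
      data = object[object$annotated, , drop = FALSE],
      fill = NA, color = "black", linewidth = 0.8
    ) +
    ggplot2::scale_fill_gradient(
      low = "firebrick", high = "forestgreen", limits = c(0, 100),
      name = "% AEs reported"
    ) +
    ggplot2::scale_y_discrete(limits = rev(levels(object$label))) +
    ggplot2::labs(x = "trial", y = "selection criterion") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ae_heatmap
#' @param x An `ae_heatmap`.
#' @export
plot_heatmap <- function(x, ...) autoplot.ae_heatmap(x, ...)

#' Wide criteria-by-trials matrix from a heat map
#'
#' @param x An `ae_heatmap`.
#' @param digits Decimal places for the percents (default 1, the scale
#'   report figures use).
#' @return A tibble with a `criterion` column and one column per trial.
#' @export
heatmap_matrix <- function(x, digits = 1) {
  stopifnot(inherits(x, "ae_heatmap"))
  wide <- tidyr::pivot_wider(
    dplyr::mutate(as_tibble(x),
      percent_reported = round(.data$percent_reported, digits)),
    id_cols = "label", names_from = "trial_id",
    values_from = "percent_reported"
  )
  dplyr::rename(wide, criterion = "label")
}

#' Check a source's reported AE list against its stated criterion
#'
#' Given the complete AE table (the clinical-study-report view), the list
#' of terms a public source actually reported, and the selection
#' criterion that source said it used, finds terms that met the criterion
#' but were not reported (`under_reported`) and terms reported despite
#' not meeting it (`over_included`). Reported terms absent from the full
#' table altogether land in `over_included` and are additionally listed
#' in `unknown`.
#'
#' @param table The complete [ae_table].
#' @param reported_terms Character vector of AE terms the source reported.
#' @param stated The criterion the source stated, as an [criterion()] or
#'   DSL string.
#' @inheritParams passes_criterion
#' @return An object of class `ae_discrepancies` with fields
#'   `under_reported`, `over_included`, `unknown` (all sorted character
#'   vectors; the first two are disjoint) plus `trial_id` and `criterion`.
#' @examples
#' check_discrepancies(example_ae_table(), c("headache"), "thr=5%")
#' @export
check_discrepancies <- function(table, reported_terms, stated,
                                rounded_percents = FALSE, strict = FALSE) {
  stopifnot(inherits(table, "ae_table"))
  crit <- as_criterion(stated)
  should <- apply_criterion(table, crit, rounded_percents = rounded_percents,
    strict = strict)$terms
  rep_norm <- unique(norm_term(reported_terms))
  reported_terms <- reported_terms[!duplicated(norm_term(reported_terms))]
  tab_norm <- norm_term(rownames(table$counts))
  unknown <- sort(reported_terms[!rep_norm %in% tab_norm], method = "radix")
  under <- sort(should[!norm_term(should) %in% rep_norm], method = "radix")
  over <- sort(reported_terms[!rep_norm %in% norm_term(should)],
    method = "radix")
  structure(
    list(
      trial_id = table$trial_id, criterion = crit,
      under_reported = under, over_included = over, unknown = unknown
    ),
    class = "ae_discrepancies"
  )
}

#' @export
print.ae_discrepancies <- function(x, ...) {
  cat(sprintf("<ae_discrepancies> trial '%s', stated criterion %s\n",
    x$trial_id, x$criterion$label))
  cat(sprintf("  under-reported (met criterion, not reported): %s\n",
    if (length(x$under_reported)) paste(x$under_reported, collapse = ", ") else "none"))
  cat(sprintf("  over-included (reported, did not meet criterion): %s\n",
    if (length(x$over_included)) paste(x$over_included, collapse = ", ") else "none"))
  if (length(x$unknown)) {
    cat(sprintf("  unknown terms (not in the full table): %s\n",
      paste(x$unknown, collapse = ", ")))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ae_discrepancies <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = x$under_reported, issue = "under_reported"),
    tibble(term = x$over_included, issue = "over_included")
  ) |>
    dplyr::mutate(
      trial_id = x$trial_id, criterion = x$criterion$label,
      unknown = .data$term %in% x$unknown,
      .before = 1
    )
}

#' Worked example AE table
#'
#' A small two-arm trial used throughout the documentation: four AE
#' terms with counts 20 vs 5 (dizziness), 6 vs 6 (headache), 1 vs 0
#' (nausea) and 3 vs 2 (fatigue) out of 100 participants per arm.
#'
#' @return An [ae_table].
#' @export
example_ae_table <- function() {
  ae_table(data.frame(
    trial_id = "example-1",
    arm = rep(c("gabapentin", "placebo"), each = 4),
    n = 100,
    is_active = rep(c(TRUE, FALSE), each = 4),
    ae_term = rep(c("dizziness", "headache", "nausea", "fatigue"), 2),
    count = c(20, 6, 1, 3, 5, 6, 0, 2)
  ))
}
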