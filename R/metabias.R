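#' Extract a pooled 2x2 table for one AE term
#'
#' Pools active arms against non-active arms: events and totals for the
#' term in each pooled group. A term absent from the table yields a
#' zero-event stratum (with the arm totals) flagged `absent`.
#'
#' @param table An [ae_table].
#' @param term AE term name.
#' @return A one-row tibble with columns `trial_id`, `term`, `a` (active
#'   events), `n1` (active total), `c` (comparator events), `n0`
#'   (comparator total), `absent`.
#' @examples
#' extract_two_by_two(example_ae_table(), "dizziness")
#' @export
extract_two_by_two <- function(table, term) {
  stopifnot(inherits(table, "ae_table"))
  active <- table$arms$is_active
  i <- match(norm_term(term), norm_term(rownames(table$counts)))
  absent <- is.na(i)
  cts <- if (absent) rep(0, nrow(table$arms)) else table$counts[i, ]
  tibble(
    trial_id = table$trial_id,
    term = term,
    a = sum(cts[active]),
    n1 = sum(table$arms$n[active]),
    c = sum(cts[!active]),
    n0 = sum(table$arms$n[!active]),
    absent = absent
  )
}

#' Mantel-Haenszel pooled risk ratio
#'
#' Fixed-effect pooled risk ratio over trial strata, computed directly
#' from the estimator
#' \deqn{RR_{MH} = \frac{\sum_i a_i n_{0i} / N_i}{\sum_i c_i n_{1i} / N_i},
#'   \quad N_i = n_{1i} + n_{0i}.}
#' No continuity corrections are applied: strata with zero events in a
#' group simply contribute zero to the corresponding sum, and when the
#' denominator sum is zero the estimate is undefined and returned as
#' `NA` (with `Inf` when only the numerator is positive).
#'
#' @param strata A data frame with columns `a`, `n1`, `c`, `n0`
#'   (active events/total, comparator events/total), one row per stratum,
#'   e.g. rows from [extract_two_by_two()].
#' @return A single number: the pooled risk ratio; `Inf` if events occur
#'   only in the active group, `NA` if no events occur in either group.
#' @examples
#' mh_pooled_rr(data.frame(a = 20, n1 = 100, c = 5, n0 = 100)) # 4
#' @export
mh_pooled_rr <- function(strata) {
  strata <- as.data.frame(strata)
  req <- c("a", "n1", "c", "n0")
  if (!all(req %in% names(strata))) {
    abort("`strata` needs columns a, n1, c, n0",
      class = "aeselect_validation_error")
  }
  if (nrow(strata) == 0) {
    abort("`strata` must contain at least one stratum",
      class = "aeselect_validation_error")
  }
  with(strata, {
    if (any(a < 0 | c < 0 | a > n1 | c > n0)) {
      abort("invalid 2x2 stratum: need 0 <= a <= n1 and 0 <= c <= n0",
        class = "aeselect_validation_error")
    }
    N <- n1 + n0
    num <- sum(a * n0 / N)
    den <- sum(c * n1 / N)
    if (den == 0) {
      if (num == 0) NA_real_ else Inf
    } else {
      num / den
    }
  })
}

#' Censor trial AE tables through a selection criterion
#'
#' Produces the "journal-article view" of each trial: only the AE terms
#' passing the criterion remain; arm sizes and the counts of the
#' surviving terms are untouched.
#'
#' @param tables A list of [ae_table]s (or a single table).
#' @param criterion An [criterion()] or DSL string.
#' @inheritParams passes_criterion
#' @return A list of censored [ae_table]s in the same order.
#' @examples
#' cens <- simulate_reporting(example_ae_table(), "thr=5%")
#' ae_terms(cens[[1]])
#' @export
simulate_reporting <- function(tables, criterion,
                               rounded_percents = FALSE, strict = FALSE) {
  if (inherits(tables, "ae_table")) tables <- list(tables)
  crit <- as_criterion(criterion)
  lapply(tables, function(tab) {
    mask <- passing_mask(tab$counts, tab$arms$n, tab$arms$is_active, crit,
      rounded_percents = rounded_percents, strict = strict)
    out <- new_ae_table(
      trial_id = tab$trial_id, arms = tab$arms,
      counts = tab$counts[mask, , drop = FALSE]
    )
    attr(out, "ground_truth") <- attr(tab, "ground_truth")
    attr(out, "elevated_terms") <- attr(tab, "elevated_terms")
    out
  })
}

#' Selective-reporting bias experiment
#'
#' Quantifies how criterion-based selective AE reporting distorts a
#' meta-analysis. Per Monte-Carlo replicate: simulate `k_trials` trials
#' of the same drug; for each criterion, censor every trial through it
#' ([simulate_reporting()]); then per AE term compute the
#' Mantel-Haenszel pooled risk ratio over *all* trials (the
#' complete-evidence estimate a reader of clinical study reports could
#' form) and over only the trials whose censored report includes the
#' term (the availability-biased estimate a reviewer of journal articles
#' could form). Terms reported by no trial are invisible to the
#' selective analysis.
#'
#' @param config A [synthetic_config()].
#' @param k_trials Trials per replicate.
#' @param criteria A list of [criterion()] objects, DSL strings, or an
#'   [build_grid()] grid.
#' @param reps Monte-Carlo replicates (>= 1). The latent truth is
#'   redrawn each replicate.
#' @param master_seed Integer seed; replicate r uses a stream derived
#'   from `(master_seed, r)`.
#' @inheritParams passes_criterion
#' @return An object of class `bias_result`: a list with
#' * `summary` — one row per criterion: `criterion`, `mean_bias`
#'   (mean over replicates of the within-replicate mean, over terms
#'   reported at least once with a finite estimate, of selective pooled
#'   log-RR minus true log-RR), `mean_selective_log_rr`,
#'   `frac_elevated_reported` (truly elevated terms reported in >= 1
#'   trial), `frac_never_reported` (terms invisible to the selective
#'   analysis), `max_discrepancy` (largest |selective - complete| pooled
#'   RR over terms reported at least once, maximized over replicates);
#' * `reps` — the same quantities per (criterion, replicate);
#' * `terms` — per (criterion, replicate, term) records: `true_log_rr`,
#'   `log_rr_complete`, `log_rr_selective`, `n_trials_reporting`,
#'   `elevated`.
#' @examples
#' res <- bias_experiment(
#'   synthetic_config(n_per_arm = c(100, 100), n_terms = 30),
#'   k_trials = 4, criteria = list("thr=0%", "thr=5%;diff=higher"),
#'   reps = 3, master_seed = 1
#' )
#' tidy(res)
#' @export
bias_experiment <- function(config, k_trials, criteria, reps, master_seed,
                            rounded_percents = FALSE, strict = FALSE) {
  stopifnot(inherits(config, "synthetic_config"), k_trials >= 1, reps >= 1)
  crits <- normalize_criteria(criteria)
  labels <- vapply(crits, `[[`, character(1), "label")

  term_rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    rep_seed <- derive_seed(master_seed, r)
    tables <- simulate_trials(config, k_trials, rep_seed)
    truth <- attr(tables[[1]], "ground_truth")
    n1 <- sum(config$n_per_arm[config$active])
    n0 <- sum(config$n_per_arm[!config$active])
    N <- n1 + n0

    # term-by-trial event matrices aligned to the full latent dictionary
    A <- vapply(tables, function(tab) {
      idx <- match(truth$term, rownames(tab$counts))
      av <- rowSums(tab$counts[, config$active, drop = FALSE])
      ifelse(is.na(idx), 0, av[idx])
    }, numeric(config$n_terms))
    C <- vapply(tables, function(tab) {
      idx <- match(truth$term, rownames(tab$counts))
      cv <- rowSums(tab$counts[, !config$active, drop = FALSE])
      ifelse(is.na(idx), 0, cv[idx])
    }, numeric(config$n_terms))
    A <- matrix(A, nrow = config$n_terms)
    C <- matrix(C, nrow = config$n_terms)

    # complete-evidence pooled RR per term (constant arm sizes, so the
    # MH weights reduce to constants times the event sums)
    rr_complete <- mh_rr_rows(A, C, n1, n0, N)

    per_crit <- purrr::map_dfr(seq_along(crits), function(ci) {
      cens <- simulate_reporting(tables, crits[[ci]],
        rounded_percents = rounded_percents, strict = strict)
      M <- vapply(cens, function(tab) {
        truth$term %in% rownames(tab$counts)
      }, logical(config$n_terms))
      M <- matrix(M, nrow = config$n_terms)
      rr_sel <- mh_rr_rows(A * M, C * M, n1, n0, N)
      tibble(
        criterion = labels[ci],
        rep = r,
        term = truth$term,
        elevated = truth$elevated,
        true_log_rr = log(truth$p_active / truth$p_comparator),
        log_rr_complete = log(rr_complete),
        log_rr_selective = log(rr_sel),
        n_trials_reporting = rowSums(M),
        rr_complete = rr_complete,
        rr_selective = rr_sel
      )
    })
    term_rows[[r]] <- per_crit
  }
  terms <- dplyr::bind_rows(term_rows)

  rep_summ <- terms |>
    dplyr::group_by(.data$criterion, .data$rep) |>
    dplyr::summarise(
      mean_bias = mean_or_na(
        (.data$log_rr_selective - .data$true_log_rr)[
          .data$n_trials_reporting >= 1 & is.finite(.data$log_rr_selective)
        ]
      ),
      mean_selective_log_rr = mean_or_na(
        .data$log_rr_selective[
          .data$n_trials_reporting >= 1 & is.finite(.data$log_rr_selective)
        ]
      ),
      frac_elevated_reported = mean_or_na(
        (.data$n_trials_reporting >= 1)[.data$elevated]
      ),
      frac_never_reported = mean(.data$n_trials_reporting == 0),
      max_discrepancy = max_discrepancy(
        .data$rr_selective[.data$n_trials_reporting >= 1],
        .data$rr_complete[.data$n_trials_reporting >= 1]
      ),
      .groups = "drop"
    )

  summ <- rep_summ |>
    dplyr::group_by(.data$criterion) |>
    dplyr::summarise(
      mean_bias = mean(.data$mean_bias, na.rm = TRUE),
      mean_selective_log_rr = mean(.data$mean_selective_log_rr, na.rm = TRUE),
      frac_elevated_reported = mean(.data$frac_elevated_reported, na.rm = TRUE),
      frac_never_reported = mean(.data$frac_never_reported),
      max_discrepancy = max(.data$max_discrepancy),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_trials = k_trials, reps = reps, .after = "criterion")
  # report criteria in input order
  summ <- summ[match(unique(labels), summ$criterion), , drop = FALSE]

  structure(
    list(summary = summ, reps = rep_summ, terms = terms,
      config = config, master_seed = master_seed),
    class = "bias_result"
  )
}

normalize_criteria <- function(criteria) {
  if (inherits(criteria, "ae_criterion_grid")) return(criteria$criterion)
  if (inherits(criteria, "ae_criterion")) return(list(criteria))
  if (is.character(criteria)) return(lapply(criteria, parse_criterion))
  stopifnot(is.list(criteria))
  lapply(criteria, as_criterion)
}

# Row-wise MH pooled RR when all strata share arm totals n1/n0:
# RR = (n0/N * sum_t a_t) / (n1/N * sum_t c_t); zero denominator -> NA/Inf.
mh_rr_rows <- function(A, C, n1, n0, N) {
  num <- rowSums(A) * (n0 / N)
  den <- rowSums(C) * (n1 / N)
  out <- num / den
  out[den == 0 & num == 0] <- NA_real_
  out
}

mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

max_discrepancy <- function(sel, comp) {
  ok <- !(is.na(sel) & is.na(comp))
  sel <- sel[ok]
  comp <- comp[ok]
  if (length(sel) == 0) return(0)
  same <- (sel == comp) | (is.infinite(sel) & is.infinite(comp) & sign(sel) == sign(comp))
  same[is.na(same)] <- FALSE
  d <- ifelse(same, 0, abs(sel - comp))
  d[is.na(d)] <- Inf # one side undefined, the other not
  max(d)
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf(
    "<bias_result> %d criteria, %d trials/replicate, %d replicates (seed %s)\n",
    nrow(x$summary), x$summary$n_trials[1], x$summary$reps[1],
    format(x$master_seed)
  ))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bias_result <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.bias_result <- function(x, ...) {
  tibble(
    n_criteria = nrow(x$summary),
    n_trials = x$summary$n_trials[1],
    reps = x$summary$reps[1],
    n_terms = x$config$n_terms,
    risk_ratio = x$config$risk_ratio,
    elevated_fraction = x$config$elevated_fraction,
    master_seed = x$master_seed
  )
}

#' Plot selective-reporting bias per criterion
#'
#' Mean bias of the selective pooled log risk ratio (against the true
#' log-RR) per criterion, with the fraction of AE terms never reported.
#'
#' @param object A `bias_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bias_result <- function(object, ...) {
  d <- tidyr::pivot_longer(object$summary,
    c("mean_bias", "frac_never_reported"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$criterion, levels = rev(object$summary$criterion)),
    y = .data$value
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = "selection criterion", y = NULL) +
    ggplot2::theme_minimal()
}
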