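#' Background incidence laws for simulated adverse events
#'
#' Spontaneously reported AEs in a trial form a long tail: a handful of
#' common terms and very many rare ones. Two families reproduce that
#' shape for the per-term comparator-arm incidence:
#'
#' * `log_uniform(lo, hi)` — incidence drawn uniformly on the log scale
#'   between `lo` and `hi`;
#' * `power_law(alpha, min_rate)` — Pareto tail
#'   `p = min_rate * U^(-1/(alpha - 1))`, truncated at 1; `alpha > 1`.
#'
#' @param lo,hi Incidence bounds, `0 <= lo <= hi <= 1` (`lo = hi` gives a
#'   degenerate point mass, useful for edge cases).
#' @param alpha Pareto shape (> 1); larger means a shorter tail.
#' @param min_rate Minimum incidence (> 0).
#' @return A rate-law object used by [synthetic_config()].
#' @export
log_uniform <- function(lo = 5e-4, hi = 0.2) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo >= 0, hi <= 1, lo <= hi)
  structure(list(kind = "log_uniform", lo = lo, hi = hi),
    class = "ae_rate_law")
}

#' @rdname log_uniform
#' @export
power_law <- function(alpha = 2, min_rate = 5e-4) {
  stopifnot(is.numeric(alpha), alpha > 1, is.numeric(min_rate), min_rate > 0)
  structure(list(kind = "power_law", alpha = alpha, min_rate = min_rate),
    class = "ae_rate_law")
}

draw_rates <- function(law, n) {
  switch(law$kind,
    log_uniform = {
      if (law$hi == 0) return(rep(0, n))
      lo <- max(law$lo, 1e-12) # guard log(0); lo = 0 collapses to hi-only mass
      if (law$lo == 0 && law$hi > 0) lo <- 1e-12
      exp(runif(n, log(lo), log(law$hi)))
    },
    power_law = pmin(1, law$min_rate * runif(n)^(-1 / (law$alpha - 1))),
    abort(sprintf("unknown rate law '%s'", law$kind))
  )
}

#' Configuration for simulated non-systematic AE data
#'
#' Describes one simulated drug: arm sizes, how many distinct AE terms
#' exist, the long-tailed background (comparator-arm) incidence law, and
#' which fraction of terms is truly elevated in the active arm(s) and by
#' what risk ratio. Per arm and per term, the number of affected
#' participants is an independent binomial draw; terms no participant
#' experienced are not stored, just as observed-event listings only
#' contain events that occurred.
#'
#' @param n_per_arm Integer vector of participants per arm. Names are
#'   used as arm names; unnamed two-arm configs get `active`/`placebo`,
#'   longer ones `active_1`, ..., `placebo`.
#' @param n_terms Number of distinct AE terms in the latent dictionary.
#' @param background_rate_law A [log_uniform()] or [power_law()] object.
#' @param elevated_fraction Fraction of terms with elevated active-arm
#'   risk; `ceiling(elevated_fraction * n_terms)` terms are elevated.
#' @param risk_ratio Active / comparator incidence ratio for elevated
#'   terms; active incidence is capped at 1.
#' @param active_arms Indices (or names) of the active arms; default all
#'   but the last arm.
#' @param seed Default seed used by [simulate_trial()] when none is given.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_arm = c(200, 200), n_terms = 300,
                             background_rate_law = log_uniform(5e-4, 0.2),
                             elevated_fraction = 0.1, risk_ratio = 2,
                             active_arms = NULL, seed = NULL) {
  stopifnot(
    is.numeric(n_per_arm), length(n_per_arm) >= 2, all(n_per_arm >= 1),
    all(n_per_arm == round(n_per_arm)),
    is.numeric(n_terms), n_terms >= 1, n_terms == round(n_terms),
    inherits(background_rate_law, "ae_rate_law"),
    is.numeric(elevated_fraction), elevated_fraction >= 0, elevated_fraction <= 1,
    is.numeric(risk_ratio), risk_ratio > 0
  )
  k <- length(n_per_arm)
  nms <- names(n_per_arm)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- if (k == 2) c("active", "placebo") else c(paste0("active_", seq_len(k - 1)), "placebo")
  }
  if (anyDuplicated(nms)) abort("arm names must be unique")
  if (is.null(active_arms)) {
    active <- c(rep(TRUE, k - 1), FALSE)
  } else {
    active <- rep(FALSE, k)
    idx <- if (is.character(active_arms)) match(active_arms, nms) else active_arms
    if (any(is.na(idx)) || any(idx < 1 | idx > k)) abort("invalid `active_arms`")
    active[idx] <- TRUE
    if (all(active) || !any(active)) {
      abort("need at least one active and one comparator arm")
    }
  }
  structure(
    list(
      n_per_arm = setNames(as.integer(n_per_arm), nms),
      n_terms = as.integer(n_terms),
      background_rate_law = background_rate_law,
      elevated_fraction = elevated_fraction,
      risk_ratio = risk_ratio,
      active = active,
      seed = seed
    ),
    class = "synthetic_config"
  )
}

# Latent truth shared by all trials of one simulated drug: per-term
# comparator incidence, elevated flags, and the implied active incidence.
draw_truth <- function(config) {
  p0 <- draw_rates(config$background_rate_law, config$n_terms)
  n_elev <- ceiling(config$elevated_fraction * config$n_terms)
  elevated <- rep(FALSE, config$n_terms)
  if (n_elev > 0) {
    elevated[sample.int(config$n_terms, n_elev)] <- TRUE
  }
  p1 <- ifelse(elevated, pmin(1, config$risk_ratio * p0), p0)
  tibble(
    term = sprintf("ae_%04d", seq_len(config$n_terms)),
    p_comparator = p0,
    p_active = p1,
    elevated = elevated
  )
}

#' Simulate one trial's AE table
#'
#' Draws the latent per-term incidences (unless a shared `truth` is
#' supplied) and then, independently per arm and term, the number of
#' affected participants as `Binomial(n_arm, incidence)`. Active arms use
#' the elevated incidence for elevated terms; all arms share the
#' comparator incidence otherwise. Terms with zero affected participants
#' across all arms are dropped. Fully reproducible given the seed.
#'
#' @param config A [synthetic_config()].
#' @param trial_id Trial label.
#' @param seed Integer seed; defaults to `config$seed`.
#' @param truth Optional truth tibble (from a shared drug-level draw);
#'   when `NULL` it is drawn from the seed's truth stream.
#' @return An [ae_table] with attributes `ground_truth` (tibble with
#'   `term`, `p_comparator`, `p_active`, `elevated`) and
#'   `elevated_terms` (character vector).
#' @examples
#' tab <- simulate_trial(synthetic_config(n_terms = 50), seed = 1)
#' head(attr(tab, "ground_truth"))
#' @export
simulate_trial <- function(config, trial_id = "trial_01", seed = config$seed,
                           truth = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(seed)) abort("a seed is required (argument or config$seed)")
  if (is.null(truth)) {
    truth <- with_local_seed(derive_seed(seed, 0), draw_truth(config))
  }
  counts <- with_local_seed(derive_seed(seed, 1), {
    draw_counts(config, truth)
  })
  build_sim_table(config, trial_id, counts, truth)
}

draw_counts <- function(config, truth) {
  n_arm <- config$n_per_arm
  vapply(seq_along(n_arm), function(j) {
    p <- if (config$active[j]) truth$p_active else truth$p_comparator
    rbinom(config$n_terms, n_arm[j], p)
  }, numeric(config$n_terms))
}

build_sim_table <- function(config, trial_id, counts, truth) {
  counts <- matrix(counts, nrow = config$n_terms,
    dimnames = list(truth$term, names(config$n_per_arm)))
  keep <- rowSums(counts) > 0
  tab <- new_ae_table(
    trial_id = trial_id,
    arms = tibble(
      arm = names(config$n_per_arm),
      n = as.numeric(config$n_per_arm),
      is_active = config$active
    ),
    counts = counts[keep, , drop = FALSE]
  )
  attr(tab, "ground_truth") <- truth
  attr(tab, "elevated_terms") <- truth$term[truth$elevated]
  tab
}

#' Simulate many trials of the same drug
#'
#' The "same drug, many trials" setting a meta-analysis needs: the latent
#' per-term incidences and elevated set are drawn once from
#' `master_seed`, then each trial's counts are resampled independently
#' on its own derived stream, so adding trials never perturbs earlier
#' ones and `simulate_trials(config, 1, s)[[1]]` equals
#' `simulate_trial(config, seed = s)`.
#'
#' @param config A [synthetic_config()].
#' @param k Number of trials (>= 1).
#' @param master_seed Integer seed for the whole corpus.
#' @return A list of `k` [ae_table]s named `trial_01`, ..., each carrying
#'   the shared `ground_truth` attribute.
#' @export
simulate_trials <- function(config, k, master_seed) {
  stopifnot(inherits(config, "synthetic_config"), k >= 1)
  truth <- with_local_seed(derive_seed(master_seed, 0), draw_truth(config))
  out <- lapply(seq_len(k), function(i) {
    counts <- with_local_seed(derive_seed(master_seed, i), {
      draw_counts(config, truth)
    })
    build_sim_table(config, sprintf("trial_%02d", i), counts, truth)
  })
  names(out) <- vapply(out, `[[`, character(1), "trial_id")
  out
}
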