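# Shared fixtures and the independent brute-force criterion oracle.

# The worked fixture trial: 2 arms of 100, four AE terms.
fixture_table <- function() {
  ae_table(data.frame(
    trial_id = "fix-1",
    arm = rep(c("drug", "placebo"), each = 4),
    n = 100,
    is_active = rep(c(TRUE, FALSE), each = 4),
    ae_term = rep(c("dizziness", "headache", "nausea", "fatigue"), 2),
    count = c(20, 6, 1, 3, 5, 6, 0, 2)
  ))
}

# Random valid AE table with <= max_terms terms and 2 or 3 arms.
random_table <- function(id = "rt", max_terms = 10) {
  n_arms <- sample(2:3, 1)
  n <- sample(c(20, 50, 100, 150), n_arms, replace = TRUE)
  is_active <- c(rep(TRUE, n_arms - 1), FALSE)
  n_terms <- sample(1:max_terms, 1)
  repeat {
    counts <- vapply(seq_len(n_arms), function(j) {
      rbinom(n_terms, n[j], runif(1, 0.005, 0.25))
    }, numeric(n_terms))
    counts <- matrix(counts, nrow = n_terms)
    if (any(rowSums(counts) > 0)) break
  }
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  arms <- paste0("arm", seq_len(n_arms))
  df <- do.call(rbind, lapply(seq_len(n_arms), function(j) {
    data.frame(
      trial_id = id, arm = arms[j], n = n[j], is_active = is_active[j],
      ae_term = paste0("term", seq_len(nrow(counts))), count = counts[, j]
    )
  }))
  ae_table(df)
}

# Brute-force oracle: evaluates one term against a criterion straight
# from the prose definition, using plain per-arm divisions on the long
# tibble form. Independent of the engine's vectorized integer-arithmetic
# path.
oracle_passes <- function(table, term, crit) {
  df <- tibble::as_tibble(table)
  df <- df[df$ae_term == term, ]
  stopifnot(nrow(df) >= 2)
  p_arm <- df$count / df$n
  p_active <- sum(df$count[df$is_active]) / sum(df$n[df$is_active])
  p_comp <- sum(df$count[!df$is_active]) / sum(df$n[!df$is_active])
  p_all <- sum(df$count) / sum(df$n)

  thr_ok <- switch(crit$scope,
    any = any(p_arm >= crit$threshold),
    active = p_active >= crit$threshold,
    all = p_all >= crit$threshold
  )
  diff_ok <- switch(crit$diff,
    none = TRUE,
    higher = p_active > p_comp,
    ratio = if (p_comp == 0) p_active > 0 else p_active >= crit$ratio * p_comp
  )
  thr_ok && diff_ok
}

oracle_reported_terms <- function(table, crit) {
  terms <- ae_terms(table)
  sort(terms[vapply(terms, oracle_passes, logical(1), table = table, crit = crit)])
}
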