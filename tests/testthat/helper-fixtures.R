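# Shared fixtures and independent oracles, all built in code.

# Brute-force AUC: loop over every (positive, negative) pair, ties count 1/2.
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Nested-loop rule-activation oracle using scalar evaluation only.
bf_rule_matrix <- function(rules, table) {
  m <- matrix(0L, nrow(table), length(rules))
  for (i in seq_len(nrow(table))) {
    for (j in seq_along(rules)) {
      m[i, j] <- evaluate_rule(rules[[j]], table[i, , drop = FALSE])
    }
  }
  colnames(m) <- vapply(rules, function(r) r$rule_id, character(1))
  m
}

# Small random flat table (no windowing) for rule-evaluation tests.
random_flat_table <- function(n, seed) {
  set.seed(seed)
  data.frame(
    age = round(stats::runif(n, 0, 18), 1),
    rr = round(stats::runif(n, 10, 60)),
    sbt = sample(c("Not assessed", "Failed", "Passed"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

random_rule <- function(id, seed) {
  set.seed(seed)
  conds <- list()
  if (stats::runif(1) < 0.7) {
    conds <- c(conds, list(rule_condition("age",
      sample(c("numeric_le", "numeric_gt"), 1), threshold = stats::runif(1, 2, 16))))
  }
  if (stats::runif(1) < 0.7) {
    conds <- c(conds, list(rule_condition("rr",
      sample(c("numeric_le", "numeric_gt"), 1), threshold = stats::runif(1, 15, 50))))
  }
  if (length(conds) == 0 || stats::runif(1) < 0.4) {
    conds <- c(conds, list(rule_condition("sbt", "categorical_in",
      levels = sample(c("Not assessed", "Failed", "Passed"),
                      sample(1:2, 1)))))
  }
  new_rule(id, conds)
}

# Small fast cohort for pipeline-level tests.
small_cohort_config <- function(seed = 1L, ...) {
  thr <- stats::qnorm(0.4)
  rules <- list(
    planted_rule(list(rule_condition("f1", "numeric_le", threshold = thr)),
                 effect_train = 1.5, effect_external = 1.5),
    planted_rule(list(rule_condition("f2", "numeric_gt", threshold = -thr)),
                 effect_train = -1.5, effect_external = -1.5))
  cohort_config(n_intubations = 80, n_external = 40, windows_min = 3,
                windows_max = 6, n_numeric = 3,
                categorical_levels = list(sbt = c("No", "Yes")),
                planted_rules = rules, base_logit = 0.5, seed = seed, ...)
}

# A deterministic simulated study: cohort + fitted rule ensemble, cached per
# session so several test files can share it.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(small_cohort_config(seed = 42))
      train <- cohort_split(cohort, "train")
      model <- fit_rulefit(train,
                           rulefit_hyperparams(num_leaves = 3, n_trees = 8),
                           n_folds = 3, seed = 42)
      cache <<- list(cohort = cohort, train = train,
                     test = cohort_split(cohort, "test"),
                     external = cohort_split(cohort, "external"),
                     model = model)
    }
    cache
  }
})
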