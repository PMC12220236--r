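# Hand-written tree table mirroring the boosting library's dump format:
# a depth-2 tree on (x, y) and a second tree duplicating one path.
toy_tree_table <- function() {
  data.frame(
    Tree = c(0, 0, 0, 0, 0, 0, 0, 1, 1, 1),
    Node = c(0, 1, 2, 3, 4, 5, 6, 0, 1, 2),
    ID = c("0-0", "0-1", "0-2", "0-3", "0-4", "0-5", "0-6",
           "1-0", "1-1", "1-2"),
    Feature = c("x", "y", "x", "Leaf", "Leaf", "Leaf", "Leaf",
                "x", "Leaf", "Leaf"),
    Split = c(5, 2, 8, NA, NA, NA, NA, 5, NA, NA),
    Yes = c("0-1", "0-3", "0-5", NA, NA, NA, NA, "1-1", NA, NA),
    No = c("0-2", "0-4", "0-6", NA, NA, NA, NA, "1-2", NA, NA),
    stringsAsFactors = FALSE)
}

toy_schema <- list(feature_cols = c("x", "y"), numeric_cols = c("x", "y"),
                   levels_map = list())

test_that("rule extraction enumerates every root-to-node path and dedups", {
  rules <- extract_rules(toy_tree_table(), schema = toy_schema)
  texts <- vapply(rules, render_rule, character(1))
  # tree 0 has 6 paths below the root (hand enumeration); tree 1 duplicates
  # {x <= 5} and {x > 5}; nested x-conditions collapse to the tighter interval
  expect_setequal(texts, c(
    "x <= 5", "x > 5",
    "x <= 5 & y <= 2", "x <= 5 & y > 2",
    "x > 5 & x <= 8", "x > 8"))
  expect_identical(vapply(rules, function(r) r$rule_id, character(1)),
                   sprintf("r%03d", seq_along(rules)))
})

test_that("leaves-only extraction keeps only leaf paths", {
  tt <- toy_tree_table()
  rules <- extract_rules(tt[tt$Tree == 0, ], schema = toy_schema,
                         leaves_only = TRUE)
  texts <- vapply(rules, render_rule, character(1))
  expect_false("x <= 5" %in% texts)     # internal node path of tree 0
  expect_setequal(texts, c("x <= 5 & y <= 2", "x <= 5 & y > 2",
                           "x > 5 & x <= 8", "x > 8"))
})

test_that("rules from a depth-1 tree partition the records", {
  tt <- data.frame(Tree = 0, Node = 0:2, ID = c("0-0", "0-1", "0-2"),
                   Feature = c("x", "Leaf", "Leaf"), Split = c(1.5, NA, NA),
                   Yes = c("0-1", NA, NA), No = c("0-2", NA, NA),
                   stringsAsFactors = FALSE)
  rules <- extract_rules(tt, schema = toy_schema)
  expect_length(rules, 2L)
  tab <- data.frame(x = seq(-3, 3, by = 0.5))
  m <- build_rule_matrix(rules, tab)
  expect_true(all(rowSums(m) == 1))
})

test_that("one-hot splits map back to categorical membership", {
  tt <- data.frame(Tree = 0, Node = 0:2, ID = c("0-0", "0-1", "0-2"),
                   Feature = c("sbt=Passed", "Leaf", "Leaf"),
                   Split = c(0.5, NA, NA),
                   Yes = c("0-1", NA, NA), No = c("0-2", NA, NA),
                   stringsAsFactors = FALSE)
  schema <- list(feature_cols = "sbt", numeric_cols = character(0),
                 levels_map = list(sbt = c("Failed", "Not assessed", "Passed")))
  rules <- extract_rules(tt, schema = schema)
  texts <- vapply(rules, render_rule, character(1))
  expect_setequal(texts, c("sbt in {Failed, Not assessed}", "sbt in {Passed}"))
})

test_that("boosting recovers a perfect single-feature separation", {
  set.seed(1)
  n <- 400
  tab <- tibble::tibble(intubation_id = seq_len(n), window_index = 0L,
                        window_end_time = 12, split = "train",
                        outcome = integer(n), f1 = rnorm(n))
  tab$outcome <- as.integer(tab$f1 <= 0)
  ens <- fit_boosted_trees(tab, rulefit_hyperparams(num_leaves = 2, n_trees = 2),
                           seed = 1)
  rules <- extract_rules(ens)
  thr <- rules[[1]]$conditions[[1]]$threshold
  gap <- sort(abs(tab$f1))[1:2]   # resolution of the observed grid around 0
  expect_lt(abs(thr), max(0.1, 3 * gap[2]))
  # the split reproduces the labels
  m <- build_rule_matrix(rules[1], tab)
  expect_gt(abs(cor(as.numeric(m[, 1]), tab$outcome)), 0.99)
})

test_that("boosting and the fitted pipeline are deterministic under a fixed seed", {
  st <- small_study()
  m2 <- fit_rulefit(st$train, rulefit_hyperparams(num_leaves = 3, n_trees = 8),
                    n_folds = 3, seed = 42)
  expect_identical(st$model$selected_ids, m2$selected_ids)
  expect_equal(st$model$coefficients, m2$coefficients, tolerance = 1e-12)
})

test_that("boosting refuses a single-class outcome", {
  tab <- tibble::tibble(intubation_id = 1:50, window_index = 0L,
                        window_end_time = 12, split = "train",
                        outcome = 1L, f1 = rnorm(50))
  expect_error(fit_boosted_trees(tab), "single class")
})

test_that("full shrinkage selects no rules and predicts the base rate", {
  st <- small_study()
  m <- build_rule_matrix(st$model$all_rules, st$train)
  fit <- fit_lasso_selection(m, st$train$outcome, rules = st$model$all_rules,
                             lambda = 5)
  expect_length(fit$selected_ids, 0L)
  p <- predict(fit, st$train)
  expect_equal(unique(round(p, 10)), round(mean(st$train$outcome), 10),
               tolerance = 1e-6)
})

test_that("lambda = 0 selection matches the unpenalized logistic fit", {
  set.seed(8)
  n <- 300
  m <- cbind(r1 = rbinom(n, 1, 0.4), r2 = rbinom(n, 1, 0.3),
             r3 = rbinom(n, 1, 0.5))
  eta <- -0.5 + 1.2 * m[, 1] - 0.8 * m[, 2]
  y <- rbinom(n, 1, plogis(eta))
  fit <- suppressWarnings(fit_lasso_selection(m, y, lambda = 0))
  oracle <- glm(y ~ m, family = binomial())
  expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-4)
  got <- rep(0, 3); names(got) <- colnames(m)
  got[fit$selected_ids] <- fit$coefficients
  expect_equal(unname(got), unname(coef(oracle)[-1]), tolerance = 1e-4)
})

test_that("selection grows from empty as the penalty relaxes", {
  # with correlated Boolean rule columns the LASSO active set is not globally
  # monotone in lambda; the dependable property is emptiness under full
  # shrinkage and growth over the sparse upper region of the path
  st <- small_study()
  m <- build_rule_matrix(st$model$all_rules, st$train)
  n_sel <- vapply(c(0.5, 0.05, 0.02), function(l) {
    length(suppressWarnings(
      fit_lasso_selection(m, st$train$outcome, lambda = l))$selected_ids)
  }, numeric(1))
  expect_identical(n_sel[1], 0)
  expect_gt(n_sel[2], 0)
  expect_gte(n_sel[3], n_sel[2])
})

test_that("duplicating a rule column leaves in-sample predictions unchanged", {
  set.seed(12)
  n <- 250
  m <- cbind(r1 = rbinom(n, 1, 0.5), r2 = rbinom(n, 1, 0.3))
  y <- rbinom(n, 1, plogis(-0.3 + m[, 1]))
  lam <- 0.02
  f1 <- suppressWarnings(fit_lasso_selection(m, y, lambda = lam))
  m2 <- cbind(m, r1dup = m[, 1])
  f2 <- suppressWarnings(fit_lasso_selection(m2, y, lambda = lam))
  coef_full <- function(f, cols) {
    b <- rep(0, length(cols)); names(b) <- cols
    b[f$selected_ids] <- f$coefficients; b
  }
  p1 <- plogis(f1$intercept + m %*% coef_full(f1, colnames(m)))
  p2 <- plogis(f2$intercept + m2 %*% coef_full(f2, colnames(m2)))
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-5)
})

test_that("a singleton grid is returned without cross-validation", {
  grid <- hyperparam_grid(learning_rates = 0.2, num_leaves = 4, n_trees = 8)
  hp <- tune_hyperparameters(small_study()$train, grid)
  expect_identical(hp$learning_rate, 0.2)
  expect_identical(hp$num_leaves, 4L)
  expect_null(attr(hp, "cv_table"))
})

test_that("grid tuning is deterministic and prefers the expressive setting", {
  # outcome driven by a strict two-feature interaction: stumps cannot express
  # it, two-level trees can
  set.seed(30)
  n <- 600
  tab <- tibble::tibble(intubation_id = seq_len(n), window_index = 0L,
                        window_end_time = 12, split = "train",
                        f1 = rnorm(n), f2 = rnorm(n))
  tab$outcome <- rbinom(n, 1, plogis(3 * ((tab$f1 > 0) == (tab$f2 > 0)) - 1.5))
  grid <- hyperparam_grid(learning_rates = 0.3, num_leaves = c(2, 4),
                          n_trees = 8, n_folds = 2, seed = 5)
  hp1 <- tune_hyperparameters(tab, grid)
  hp2 <- tune_hyperparameters(tab, grid)
  expect_identical(hp1$num_leaves, hp2$num_leaves)
  cv <- attr(hp1, "cv_table")
  auc2 <- cv$cv_auc[cv$num_leaves == 2]
  auc4 <- cv$cv_auc[cv$num_leaves == 4]
  expect_gt(auc4, auc2)
  expect_identical(hp1$num_leaves, 4L)
})

test_that("a fitted model round-trips through JSON", {
  st <- small_study()
  path <- tempfile(fileext = ".json")
  write_rulefit_model(st$model, path)
  back <- read_rulefit_model(path)
  expect_identical(back$selected_ids, st$model$selected_ids)
  expect_equal(back$coefficients, st$model$coefficients, tolerance = 1e-12)
  expect_equal(predict(back, st$test), predict(st$model, st$test),
               tolerance = 1e-12)
})
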