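#' Boosting / selection hyperparameters
#'
#' @param learning_rate Shrinkage of the gradient-boosting stage.
#' @param num_leaves Maximum leaves per tree (shallow trees; leaf-wise growth).
#' @param n_trees Number of boosting rounds (default 32, sized so the
#'   candidate-rule count lands near one hundred under default settings).
#' @param lasso_lambda Optional fixed L1 penalty; `NULL` selects lambda by
#'   cross-validation.
#' @return A `rulefit_hyperparams` list.
#' @export
rulefit_hyperparams <- function(learning_rate = 0.1, num_leaves = 4,
                                n_trees = 32, lasso_lambda = NULL) {
  stopifnot(learning_rate > 0, num_leaves >= 2, n_trees >= 1)
  structure(list(learning_rate = learning_rate,
                 num_leaves = as.integer(num_leaves),
                 n_trees = as.integer(n_trees),
                 lasso_lambda = lasso_lambda),
            class = "rulefit_hyperparams")
}

#' Hyperparameter grid for cross-validated tuning
#'
#' @param learning_rates,num_leaves Candidate values for the boosting stage.
#' @param n_trees Boosting rounds (fixed across the grid).
#' @param n_folds Cross-validation folds (>= 2), assigned at the intubation
#'   level so windows of one intubation never straddle folds.
#' @param seed Integer seed for fold assignment.
#' @return A `hyperparam_grid` list.
#' @export
hyperparam_grid <- function(learning_rates = c(0.1, 0.3),
                            num_leaves = c(4, 8),
                            n_trees = 32, n_folds = 3, seed = 1L) {
  stopifnot(length(learning_rates) >= 1, length(num_leaves) >= 1, n_folds >= 2)
  structure(list(learning_rates = learning_rates,
                 num_leaves = as.integer(num_leaves),
                 n_trees = as.integer(n_trees),
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "hyperparam_grid")
}

cohort_feature_cols <- function(table) {
  setdiff(names(table),
          c("intubation_id", "window_index", "window_end_time", "split", "outcome"))
}

# Feature schema: which columns are numeric vs categorical, and the level
# sets (from the data) used to one-hot encode and to complement level sets
# during rule extraction.
feature_schema <- function(table, feature_cols = cohort_feature_cols(table)) {
  is_cat <- vapply(feature_cols, function(f) {
    is.character(table[[f]]) || is.factor(table[[f]])
  }, logical(1))
  levels_map <- lapply(feature_cols[is_cat], function(f) {
    sort(unique(as.character(table[[f]])))
  })
  names(levels_map) <- feature_cols[is_cat]
  list(feature_cols = feature_cols,
       numeric_cols = feature_cols[!is_cat],
       levels_map = levels_map)
}

# One-hot design matrix for the boosting stage. Categorical feature f with
# level L becomes indicator column "f=L"; numeric features pass through.
design_matrix <- function(table, schema) {
  cols <- list()
  for (f in schema$numeric_cols) cols[[f]] <- as.numeric(table[[f]])
  for (f in names(schema$levels_map)) {
    for (lv in schema$levels_map[[f]]) {
      cols[[paste0(f, "=", lv)]] <- as.numeric(as.character(table[[f]]) == lv)
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  m
}

#' Fit the gradient-boosted tree stage
#'
#' Shallow leaf-wise trees fit to the training split only; categorical
#' features are one-hot encoded so every split is either a numeric threshold
#' or a single-level membership test.
#'
#' @param train Training cohort table (must contain both outcome classes).
#' @param hyperparams A [rulefit_hyperparams()].
#' @param seed Integer seed.
#' @return A `boosted_ensemble` holding the booster and the feature schema.
#' @export
fit_boosted_trees <- function(train, hyperparams = rulefit_hyperparams(),
                              seed = 1L) {
  stopifnot(inherits(hyperparams, "rulefit_hyperparams"),
            "outcome" %in% names(train))
  y <- as.integer(train$outcome)
  if (length(unique(y)) < 2L) {
    stop("training outcome has a single class; cannot fit boosted trees",
         call. = FALSE)
  }
  schema <- feature_schema(train)
  x <- design_matrix(train, schema)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  params <- list(objective = "binary:logistic",
                 eta = hyperparams$learning_rate,
                 max_leaves = hyperparams$num_leaves,
                 grow_policy = "lossguide",
                 max_depth = 0,
                 tree_method = "hist",
                 nthread = 1,
                 seed = seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hyperparams$n_trees, verbose = 0)
  structure(list(booster = booster, schema = schema,
                 hyperparams = hyperparams, seed = seed),
            class = "boosted_ensemble")
}

# Convert one split into the pair of child conditions (left: value < Split,
# right: value >= Split), mapping one-hot indicator splits back to
# categorical membership on the original feature.
split_conditions <- function(feature, threshold, schema) {
  if (grepl("=", feature, fixed = TRUE)) {
    parts <- regmatches(feature, regexpr("=", feature, fixed = TRUE),
                        invert = TRUE)[[1]]
    base <- parts[1]; lv <- parts[2]
    all_lv <- schema$levels_map[[base]]
    list(left = rule_condition(base, "categorical_in", levels = setdiff(all_lv, lv)),
         right = rule_condition(base, "categorical_in", levels = lv))
  } else {
    list(left = rule_condition(feature, "numeric_le", threshold = threshold),
         right = rule_condition(feature, "numeric_gt", threshold = threshold))
  }
}

# Merge a path's conditions per feature: numeric conditions collapse to the
# tightest interval; categorical level sets intersect. Returns NULL for an
# infeasible conjunction (empty level intersection).
merge_conditions <- function(conds) {
  feats <- vapply(conds, function(cn) cn$feature, character(1))
  out <- list()
  for (f in unique(feats)) {
    fc <- conds[feats == f]
    kinds <- vapply(fc, function(cn) cn$kind, character(1))
    if (all(kinds == "categorical_in")) {
      lv <- Reduce(intersect, lapply(fc, function(cn) cn$levels))
      if (length(lv) == 0L) return(NULL)
      out[[length(out) + 1L]] <- rule_condition(f, "categorical_in", levels = lv)
    } else {
      ub <- vapply(fc[kinds == "numeric_le"], function(cn) cn$threshold, numeric(1))
      lb <- vapply(fc[kinds == "numeric_gt"], function(cn) cn$threshold, numeric(1))
      if (length(lb)) out[[length(out) + 1L]] <-
          rule_condition(f, "numeric_gt", threshold = max(lb))
      if (length(ub)) out[[length(out) + 1L]] <-
          rule_condition(f, "numeric_le", threshold = min(ub))
    }
  }
  ord <- order(vapply(out, function(cn) cn$feature, character(1)))
  out[ord]
}

#' Extract conjunctive rules from a boosted ensemble
#'
#' One candidate rule per root-to-node path (every internal and leaf node
#' below the root; set `leaves_only = TRUE` for leaf paths only), with
#' conditions merged per feature and exact duplicates removed. Ordering is
#' deterministic by (tree index, node index).
#'
#' @param ensemble A fitted [fit_boosted_trees()] result, or a data frame in
#'   tree-table form (columns `Tree`, `Node`, `Feature`, `Split`, `Yes`,
#'   `No`, with `Feature == "Leaf"` on leaves) plus a `schema`.
#' @param leaves_only Extract only leaf paths.
#' @param schema Feature schema (required when `ensemble` is a raw tree
#'   table).
#' @return List of [new_rule()]s with ids `r001`, `r002`, ...
#' @export
extract_rules <- function(ensemble, leaves_only = FALSE, schema = NULL) {
  if (inherits(ensemble, "boosted_ensemble")) {
    tt <- as.data.frame(xgboost::xgb.model.dt.tree(model = ensemble$booster))
    schema <- ensemble$schema
  } else {
    tt <- as.data.frame(ensemble)
    if (is.null(schema)) stop("schema required for a raw tree table", call. = FALSE)
  }
  rules <- list()
  for (tree_id in sort(unique(tt$Tree))) {
    nodes <- tt[tt$Tree == tree_id, , drop = FALSE]
    if (nrow(nodes) <= 1L) next   # stump with a single leaf: no split, no rules
    rownames(nodes) <- nodes$ID
    root_id <- nodes$ID[nodes$Node == 0]
    # path conditions accumulated from the root; depth-first in node order
    conds_at <- list(); conds_at[[root_id]] <- list()
    for (i in order(nodes$Node)) {
      nd <- nodes[i, ]
      if (nd$Feature == "Leaf") next
      pair <- split_conditions(nd$Feature, nd$Split, schema)
      conds_at[[nd$Yes]] <- c(conds_at[[nd$ID]], list(pair$left))
      conds_at[[nd$No]] <- c(conds_at[[nd$ID]], list(pair$right))
    }
    keep <- nodes$Node[nodes$ID != root_id]
    if (leaves_only) keep <- nodes$Node[nodes$Feature == "Leaf"]
    for (node_id in sort(keep)) {
      id <- nodes$ID[nodes$Node == node_id]
      merged <- merge_conditions(conds_at[[id]])
      if (is.null(merged)) next
      rules[[length(rules) + 1L]] <- new_rule("pending", merged)
    }
  }
  sigs <- vapply(rules, rule_signature, character(1))
  rules <- rules[!duplicated(sigs)]
  for (j in seq_along(rules)) rules[[j]]$rule_id <- sprintf("r%03d", j)
  rules
}

# Fit a penalized logistic model at (a) fixed lambda value(s) with a warm
# path for numerical stability, mirroring glmnet's objective
# -(1/n) loglik + lambda * sum_j pf_j * (alpha|b_j| + (1-alpha) b_j^2 / 2)
# with penalty factors rescaled internally to mean 1.
glmnet_at <- function(x, y, lambda, alpha, penalty.factor = rep(1, ncol(x))) {
  path <- sort(unique(c(10^seq(1, log10(max(lambda, 1e-4)), length.out = 30),
                        lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                        lambda = path, standardize = FALSE,
                        penalty.factor = penalty.factor,
                        thresh = 1e-11, maxit = 1e6)
  k <- which(abs(fit$lambda - lambda) < 1e-12)[1]
  list(intercept = as.numeric(fit$a0[k]),
       beta = as.numeric(fit$beta[, k]),
       lambda = lambda, fit = fit)
}

deterministic_foldid <- function(n, n_folds, seed, cluster = NULL) {
  set.seed(seed)
  if (is.null(cluster)) return(sample(rep_len(seq_len(n_folds), n)))
  ids <- sort(unique(cluster))   # row-order invariant
  fold_of <- sample(rep_len(seq_len(n_folds), length(ids)))
  names(fold_of) <- as.character(ids)
  unname(fold_of[as.character(cluster)])
}

#' L1 rule selection on the Boolean activation matrix
#'
#' Penalized logistic regression on 0/1 rule columns (unstandardized, so the
#' penalty applies uniformly on the common rule scale); rules with
#' exactly-zero coefficients are dropped. The intercept is unpenalized.
#'
#' @param matrix Rule-activation matrix from [build_rule_matrix()].
#' @param outcomes 0/1 outcome vector, one per row.
#' @param rules The rule list behind the matrix columns (optional but needed
#'   to return selected `Rule` objects).
#' @param lambda Fixed L1 penalty; `NULL` chooses `lambda.min` by
#'   `n_folds`-fold cross-validation.
#' @param n_folds,seed Cross-validation folds and seed.
#' @param cluster Optional cluster id (e.g. intubation) per row for
#'   cluster-level fold assignment.
#' @return A `rulefit_model`: all rules, selected rules, intercept, nonzero
#'   coefficients, hyperparameters, and CV metadata.
#' @export
fit_lasso_selection <- function(matrix, outcomes, rules = NULL, lambda = NULL,
                                n_folds = 5, seed = 1L, cluster = NULL) {
  y <- as.integer(outcomes)
  stopifnot(nrow(matrix) == length(y))
  zero_cols <- colSums(matrix != 0) == 0
  if (any(zero_cols)) {
    warning(sprintf("%d all-zero rule column(s) retained (necessarily zero coefficient)",
                    sum(zero_cols)), call. = FALSE)
  }
  cvm <- NULL
  if (is.null(lambda)) {
    foldid <- deterministic_foldid(length(y), n_folds, seed, cluster)
    cv <- glmnet::cv.glmnet(matrix, y, family = "binomial", alpha = 1,
                            standardize = FALSE, foldid = foldid)
    lambda <- cv$lambda.min
    cvm <- list(lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
                n_folds = n_folds, seed = seed)
  }
  sol <- glmnet_at(matrix, y, lambda, alpha = 1)
  beta <- sol$beta
  names(beta) <- colnames(matrix)
  sel <- names(beta)[beta != 0]
  selected_rules <- NULL
  if (!is.null(rules)) {
    ids <- rule_ids(rules)
    selected_rules <- rules[match(sel, ids)]
  }
  structure(list(all_rules = rules,
                 selected_rules = selected_rules,
                 selected_ids = sel,
                 intercept = sol$intercept,
                 coefficients = beta[sel],
                 hyperparams = list(lasso_lambda = lambda),
                 cv_metadata = cvm),
            class = "rulefit_model")
}

#' Fit the full rule-ensemble (RuleFit) baseline
#'
#' Gradient-boosted shallow trees on the training split, conversion of every
#' tree path into a conjunctive rule, Boolean rule-activation matrix, and
#' L1-penalized logistic selection of a sparse rule subset.
#'
#' @param train Training cohort table.
#' @param hyperparams A [rulefit_hyperparams()].
#' @param leaves_only Extract rules from leaf paths only.
#' @param n_folds,seed CV folds / seed for lambda selection.
#' @return A `rulefit_model` with rule supports filled in.
#' @export
fit_rulefit <- function(train, hyperparams = rulefit_hyperparams(),
                        leaves_only = FALSE, n_folds = 5, seed = 1L) {
  ensemble <- fit_boosted_trees(train, hyperparams, seed = seed)
  rules <- extract_rules(ensemble, leaves_only = leaves_only)
  if (length(rules) == 0L) stop("no rules extracted from the ensemble", call. = FALSE)
  m <- build_rule_matrix(rules, train)
  supp <- colMeans(m)
  for (j in seq_along(rules)) rules[[j]]$support_train <- unname(supp[j])
  model <- fit_lasso_selection(m, train$outcome, rules = rules,
                               lambda = hyperparams$lasso_lambda,
                               n_folds = n_folds, seed = seed,
                               cluster = train$intubation_id)
  model$hyperparams <- c(hyperparams[c("learning_rate", "num_leaves", "n_trees")],
                         model$hyperparams)
  model$schema <- ensemble$schema
  model
}

#' @method print rulefit_model
#' @export
print.rulefit_model <- function(x, ...) {
  cat(sprintf("<rulefit_model> %d candidate rules, %d selected (lambda = %.5g)\n",
              length(x$all_rules), length(x$selected_ids),
              x$hyperparams$lasso_lambda))
  invisible(x)
}

#' Predict success probabilities from a rule model
#'
#' `logistic(intercept + sum of coefficient * rule activation)`.
#'
#' @param object A `rulefit_model`.
#' @param newdata Cohort table covering every feature the selected rules
#'   reference.
#' @param ... Unused.
#' @return Numeric vector of per-record scores in (0, 1).
#' @export
predict.rulefit_model <- function(object, newdata, ...) {
  eta <- rep(object$intercept, nrow(newdata))
  if (length(object$selected_rules) > 0) {
    m <- build_rule_matrix(object$selected_rules, newdata)
    eta <- eta + as.numeric(m %*% object$coefficients[colnames(m)])
  }
  stats::plogis(eta)
}

#' Cross-validated hyperparameter tuning
#'
#' Grid search over (learning rate, number of leaves) maximizing mean
#' cross-validated AUC of the full rule-ensemble pipeline; folds are
#' assigned at the intubation level. Ties break toward smaller `num_leaves`
#' then smaller `learning_rate`.
#'
#' @param train Training cohort table.
#' @param grid A [hyperparam_grid()].
#' @return A [rulefit_hyperparams()] for the winning grid point, with the CV
#'   table attached as attribute `cv_table`.
#' @export
tune_hyperparameters <- function(train, grid = hyperparam_grid()) {
  stopifnot(inherits(grid, "hyperparam_grid"))
  combos <- expand.grid(learning_rate = grid$learning_rates,
                        num_leaves = grid$num_leaves)
  if (nrow(combos) == 1L) {
    return(rulefit_hyperparams(combos$learning_rate[1], combos$num_leaves[1],
                               grid$n_trees))
  }
  foldid <- deterministic_foldid(nrow(train), grid$n_folds, grid$seed,
                                 cluster = train$intubation_id)
  combos$cv_auc <- NA_real_
  for (i in seq_len(nrow(combos))) {
    hp <- rulefit_hyperparams(combos$learning_rate[i], combos$num_leaves[i],
                              grid$n_trees)
    aucs <- vapply(seq_len(grid$n_folds), function(k) {
      tr <- train[foldid != k, , drop = FALSE]
      va <- train[foldid == k, , drop = FALSE]
      model <- fit_rulefit(tr, hp, n_folds = 3, seed = grid$seed)
      roc_auc(predict(model, va), va$outcome)
    }, numeric(1))
    combos$cv_auc[i] <- mean(aucs)
  }
  ord <- order(-combos$cv_auc, combos$num_leaves, combos$learning_rate)
  best <- combos[ord[1], ]
  out <- rulefit_hyperparams(best$learning_rate, best$num_leaves, grid$n_trees)
  attr(out, "cv_table") <- combos
  out
}

condition_to_list <- function(cn) {
  list(feature = cn$feature, kind = cn$kind,
       threshold = cn$threshold, levels = as.list(cn$levels))
}

condition_from_list <- function(l) {
  rule_condition(l$feature, l$kind,
                 threshold = if (!is.null(l$threshold)) as.numeric(l$threshold),
                 levels = if (length(l$levels)) unlist(l$levels))
}

rule_to_list <- function(r) {
  list(rule_id = r$rule_id,
       conditions = lapply(r$conditions, condition_to_list),
       support_train = r$support_train,
       text = render_rule(r))
}

rule_from_list <- function(l) {
  new_rule(l$rule_id, lapply(l$conditions, condition_from_list),
           support_train = if (is.null(l$support_train)) NA_real_ else
             as.numeric(l$support_train))
}

#' Serialize / restore a fitted rule model as JSON
#'
#' @param model A `rulefit_model`.
#' @param path Output file path.
#' @return `write_rulefit_model` returns `path` invisibly;
#'   `read_rulefit_model` the restored model.
#' @export
write_rulefit_model <- function(model, path) {
  obj <- list(type = "rulefit_model",
              all_rules = lapply(model$all_rules, rule_to_list),
              selected_ids = as.list(model$selected_ids),
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              hyperparams = model$hyperparams,
              cv_metadata = model$cv_metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_rulefit_model
#' @export
read_rulefit_model <- function(path) {
  obj <- jsonlite::read_json(path)
  all_rules <- lapply(obj$all_rules, rule_from_list)
  ids <- rule_ids(all_rules)
  sel <- unlist(obj$selected_ids)
  coefs <- vapply(obj$coefficients, as.numeric, numeric(1))
  structure(list(all_rules = all_rules,
                 selected_rules = all_rules[match(sel, ids)],
                 selected_ids = sel,
                 intercept = as.numeric(obj$intercept),
                 coefficients = coefs[sel],
                 hyperparams = obj$hyperparams,
                 cv_metadata = obj$cv_metadata),
            class = "rulefit_model")
}
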