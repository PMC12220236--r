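#' Expert-informed ridge refit with differential penalties (soft variant)
#'
#' Re-fits the selected rules' coefficients by L2-penalized logistic
#' regression where rule j's penalty contribution is scaled by
#' `p_j = |delta_rank_over_sd_j|` normalized to mean 1 over the included
#' rules. A rule on which model and experts agree perfectly (`p_j = 0`) is
#' left unpenalized; the intercept is never penalized. Scaling the penalty
#' is equivalent to dividing column j by `sqrt(p_j)` before a uniform ridge
#' fit and rescaling the coefficient by the same factor; the implementation
#' uses per-coefficient penalty factors directly.
#'
#' @param matrix Activation matrix over the selected rules (columns named by
#'   rule_id).
#' @param outcomes 0/1 outcome vector.
#' @param assessments `rule_assessment` tibble covering every column.
#' @param lambda Fixed ridge penalty; `NULL` selects it by `n_folds`-fold CV.
#' @param n_folds,seed CV folds and seed.
#' @param cluster Optional cluster id per row for fold assignment.
#' @param rules Optional rule list (stored for prediction).
#' @return An `eaml_model` (variant `"soft"`).
#' @export
soft_eaml <- function(matrix, outcomes, assessments, lambda = NULL,
                      n_folds = 5, seed = 1L, cluster = NULL, rules = NULL) {
  ids <- colnames(matrix)
  miss <- setdiff(ids, assessments$rule_id)
  if (length(miss)) {
    stop(sprintf("missing assessment for rule(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  a <- assessments[match(ids, assessments$rule_id), , drop = FALSE]
  pf <- abs(a$delta_rank_over_sd)
  if (mean(pf) > 0) pf <- pf / mean(pf)   # normalize to mean 1
  fit_eaml_ridge(matrix, outcomes, pf,
                 variant = list(kind = "soft", k_excluded = 0L),
                 lambda = lambda, n_folds = n_folds, seed = seed,
                 cluster = cluster, rules = rules, assessments = assessments)
}

# Exclusion order for the hard variant: largest |delta rank/SD| first,
# ties broken by larger |delta rank|, then rule_id.
hard_exclusion_order <- function(assessments) {
  ord <- order(-abs(assessments$delta_rank_over_sd),
               -abs(assessments$delta_rank),
               assessments$rule_id)
  assessments$rule_id[ord]
}

#' Expert-informed refit excluding the most discrepant rules (hard variant)
#'
#' Drops the `k` rules with the largest `|delta_rank_over_sd|` (ties: larger
#' `|delta_rank|` first, then rule id) and re-fits the remainder with a
#' uniform ridge logistic regression.
#'
#' @inheritParams soft_eaml
#' @param k Number of rules to exclude (0 <= k < number of rules; `k = 0` is
#'   the uniform-ridge baseline refit).
#' @return An `eaml_model` (variant `"hard"`, with `excluded_rules`).
#' @export
hard_eaml <- function(matrix, outcomes, assessments, k, lambda = NULL,
                      n_folds = 5, seed = 1L, cluster = NULL, rules = NULL) {
  ids <- colnames(matrix)
  if (k >= length(ids)) {
    stop(sprintf("k = %d must be smaller than the number of rules (%d)",
                 k, length(ids)), call. = FALSE)
  }
  a <- assessments[match(ids, assessments$rule_id), , drop = FALSE]
  excl <- utils::head(hard_exclusion_order(a), k)
  keep <- setdiff(ids, excl)
  m <- matrix[, keep, drop = FALSE]
  out <- fit_eaml_ridge(m, outcomes, rep(1, length(keep)),
                        variant = list(kind = "hard", k_excluded = as.integer(k)),
                        lambda = lambda, n_folds = n_folds, seed = seed,
                        cluster = cluster,
                        rules = if (is.null(rules)) NULL else {
                          pos <- match(keep, rule_ids(rules))
                          if (anyNA(pos)) stop("rules must cover every matrix column",
                                               call. = FALSE)
                          rules[pos]
                        },
                        assessments = assessments)
  out$excluded_rules <- excl
  out
}

# Penalized logistic fit for a single-column design (glmnet needs >= 2
# columns): direct BFGS on the penalized deviance, same objective as glmnet.
ridge_logistic_1d <- function(x, y, lambda, pf) {
  n <- length(y)
  obj <- function(par) {
    eta <- par[1] + par[2] * x
    -mean(y * eta - log1p(exp(eta))) + lambda * pf * par[2]^2 / 2
  }
  fit <- stats::optim(c(0, 0), obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

fit_eaml_ridge <- function(matrix, outcomes, penalty_factors, variant,
                           lambda, n_folds, seed, cluster, rules, assessments) {
  y <- as.integer(outcomes)
  stopifnot(nrow(matrix) == length(y))
  if (ncol(matrix) == 1L) {
    if (is.null(lambda)) lambda <- 0.01
    par <- ridge_logistic_1d(as.numeric(matrix[, 1]), y, lambda,
                             penalty_factors[1])
    return(structure(list(variant = variant,
                          included_rules = colnames(matrix),
                          intercept = par[1],
                          coefficients = stats::setNames(par[2], colnames(matrix)),
                          penalty_factors = stats::setNames(penalty_factors,
                                                            colnames(matrix)),
                          ridge_lambda = lambda,
                          cv_metadata = NULL,
                          rules = rules,
                          assessments = assessments),
                     class = "eaml_model"))
  }
  cvm <- NULL
  if (is.null(lambda)) {
    foldid <- deterministic_foldid(length(y), n_folds, seed, cluster)
    cv <- glmnet::cv.glmnet(matrix, y, family = "binomial", alpha = 0,
                            lambda = 10^seq(1, -5, length.out = 60),
                            standardize = FALSE,
                            penalty.factor = penalty_factors,
                            foldid = foldid)
    lambda <- cv$lambda.min
    cvm <- list(lambda_min = cv$lambda.min, n_folds = n_folds, seed = seed)
  }
  if (lambda == 0) {
    # unpenalized logistic refit
    fit <- stats::glm.fit(cbind(1, matrix), y,
                          family = stats::binomial())
    intercept <- fit$coefficients[1]
    beta <- fit$coefficients[-1]
  } else {
    sol <- glmnet_at(matrix, y, lambda, alpha = 0,
                     penalty.factor = penalty_factors)
    intercept <- sol$intercept
    beta <- sol$beta
  }
  beta <- stats::setNames(as.numeric(beta), colnames(matrix))
  structure(list(variant = variant,
                 included_rules = colnames(matrix),
                 intercept = unname(intercept),
                 coefficients = beta,
                 penalty_factors = stats::setNames(penalty_factors,
                                                   colnames(matrix)),
                 ridge_lambda = lambda,
                 cv_metadata = cvm,
                 rules = rules,
                 assessments = assessments),
            class = "eaml_model")
}

#' @method print eaml_model
#' @export
print.eaml_model <- function(x, ...) {
  lab <- if (x$variant$kind == "hard") {
    sprintf("hard (k = %d excluded)", x$variant$k_excluded)
  } else "soft (penalty factors |delta rank/SD|)"
  cat(sprintf("<eaml_model> %s; %d rules, ridge lambda = %.5g\n",
              lab, length(x$included_rules), x$ridge_lambda))
  invisible(x)
}

#' @rdname predict.rulefit_model
#' @export
predict.eaml_model <- function(object, newdata, ...) {
  eta <- rep(object$intercept, nrow(newdata))
  if (length(object$rules) > 0) {
    m <- build_rule_matrix(object$rules, newdata)
    eta <- eta + as.numeric(m %*% object$coefficients[colnames(m)])
  } else if (length(object$included_rules) > 0) {
    stop("model carries no rule definitions; supply rules at fit time",
         call. = FALSE)
  }
  stats::plogis(eta)
}

#' Fit the full set of expert-augmented variants
#'
#' The soft variant plus one hard variant per requested exclusion count,
#' all refit on the training activation matrix of the baseline model's
#' selected rules.
#'
#' @param model A `rulefit_model`.
#' @param train Training cohort table.
#' @param assessments `rule_assessment` tibble for the selected rules.
#' @param ks Exclusion counts for the hard variants (counts at or above the
#'   rule count are dropped with a warning).
#' @param include_soft Include the soft variant.
#' @param lambda,n_folds,seed Forwarded to the refits.
#' @return Named list of `eaml_model`s (`soft`, `hard_1`, `hard_3`, ...).
#' @export
fit_eaml_variants <- function(model, train, assessments,
                              ks = c(1, 3, 5, 7, 10, 11),
                              include_soft = TRUE, lambda = NULL,
                              n_folds = 5, seed = 1L) {
  rules <- model$selected_rules
  m <- build_rule_matrix(rules, train)
  cl <- train$intubation_id
  out <- list()
  if (include_soft) {
    out$soft <- soft_eaml(m, train$outcome, assessments, lambda = lambda,
                          n_folds = n_folds, seed = seed, cluster = cl,
                          rules = rules)
  }
  keep_ks <- ks[ks < ncol(m)]
  if (length(keep_ks) < length(ks)) {
    warning(sprintf("dropping exclusion count(s) >= rule count (%d): %s",
                    ncol(m), paste(setdiff(ks, keep_ks), collapse = ", ")),
            call. = FALSE)
  }
  for (k in keep_ks) {
    out[[sprintf("hard_%d", k)]] <-
      hard_eaml(m, train$outcome, assessments, k, lambda = lambda,
                n_folds = n_folds, seed = seed, cluster = cl, rules = rules)
  }
  out
}

#' Serialize / restore expert-augmented models as JSON
#'
#' @param models Named list of `eaml_model`s (as from [fit_eaml_variants()]).
#' @param path Output path.
#' @return `write_eaml_models` returns `path` invisibly; `read_eaml_models`
#'   the restored named list.
#' @export
write_eaml_models <- function(models, path) {
  obj <- lapply(models, function(m) {
    list(variant = m$variant,
         included_rules = as.list(m$included_rules),
         excluded_rules = as.list(m$excluded_rules),
         intercept = m$intercept,
         coefficients = as.list(m$coefficients),
         penalty_factors = as.list(m$penalty_factors),
         ridge_lambda = m$ridge_lambda,
         rules = lapply(m$rules, rule_to_list))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_eaml_models
#' @export
read_eaml_models <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj, function(l) {
    structure(list(variant = list(kind = l$variant$kind,
                                  k_excluded = as.integer(l$variant$k_excluded)),
                   included_rules = unlist(l$included_rules),
                   excluded_rules = unlist(l$excluded_rules),
                   intercept = as.numeric(l$intercept),
                   coefficients = vapply(l$coefficients, as.numeric, numeric(1)),
                   penalty_factors = vapply(l$penalty_factors, as.numeric,
                                            numeric(1)),
                   ridge_lambda = as.numeric(l$ridge_lambda),
                   rules = lapply(l$rules, rule_from_list)),
              class = "eaml_model")
  })
}
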