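#' Area under the ROC curve
#'
#' Mann-Whitney formulation with ties counted one half:
#' `P(score+ > score-) + 0.5 P(score+ = score-)`, computed from average
#' ranks.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both outcome classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve coordinates
#'
#' One row per distinct threshold (each observed score, descending, plus
#' sentinels), with false- and true-positive rates.
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.integer(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / n_neg, numeric(1))
  tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Bootstrap specification
#'
#' @param n_iterations Bootstrap replicates (default 2000).
#' @param resample_unit `"intubation"` (cluster bootstrap; windows within an
#'   intubation are dependent) or `"window"`.
#' @param seed Integer seed.
#' @param max_redraws Cap on redraws of single-class replicates.
#' @return A `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_iterations = 2000,
                           resample_unit = c("intubation", "window"),
                           seed = 1L, max_redraws = 100L) {
  stopifnot(n_iterations >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 resample_unit = match.arg(resample_unit),
                 ci_method = "percentile",
                 seed = as.integer(seed),
                 max_redraws = as.integer(max_redraws)),
            class = "bootstrap_spec")
}

# Row indices of one bootstrap resample of `table` under the spec's unit.
resample_indices <- function(table, unit) {
  if (unit == "window") return(sample.int(nrow(table), replace = TRUE))
  ids <- unique(table$intubation_id)
  take <- sample(ids, length(ids), replace = TRUE)
  idx_of <- split(seq_len(nrow(table)), table$intubation_id)
  unlist(idx_of[as.character(take)], use.names = FALSE)
}

# Draw a resample with both outcome classes present, redrawing up to the cap.
resample_two_class <- function(table, unit, max_redraws) {
  for (i in seq_len(max_redraws + 1L)) {
    idx <- resample_indices(table, unit)
    if (length(unique(table$outcome[idx])) == 2L) {
      if (i > 1L) warning(sprintf("redrew %d single-class bootstrap replicate(s)",
                                  i - 1L), call. = FALSE)
      return(idx)
    }
  }
  stop("exceeded bootstrap redraw cap without a two-class replicate",
       call. = FALSE)
}

#' Paired bootstrap difference of a performance statistic
#'
#' Resamples units with replacement and evaluates both models on each
#' replicate (paired), giving the point difference
#' `statistic_fn(a) - statistic_fn(b)` and its percentile 95% CI.
#' Deterministic given the spec's seed. Single-class replicates are redrawn
#' up to a cap.
#'
#' @param model_a,model_b Fitted models with a `predict` method (or numeric
#'   score vectors of length `nrow(table)`).
#' @param table Cohort table both models score.
#' @param spec A [bootstrap_spec()].
#' @param statistic_fn Function `(scores, labels) -> numeric` (default
#'   [roc_auc()]).
#' @return List with `point`, `ci` (percentile 2.5/97.5), and `draws`.
#' @export
bootstrap_paired_diff <- function(model_a, model_b, table,
                                  spec = bootstrap_spec(),
                                  statistic_fn = roc_auc) {
  sa <- model_scores(model_a, table)
  sb <- model_scores(model_b, table)
  y <- table$outcome
  point <- statistic_fn(sa, y) - statistic_fn(sb, y)
  set.seed(spec$seed)
  draws <- vapply(seq_len(spec$n_iterations), function(i) {
    idx <- resample_two_class(table, spec$resample_unit, spec$max_redraws)
    statistic_fn(sa[idx], y[idx]) - statistic_fn(sb[idx], y[idx])
  }, numeric(1))
  list(point = point,
       ci = unname(stats::quantile(draws, c(0.025, 0.975), type = 7)),
       draws = draws)
}

model_scores <- function(model, table) {
  if (is.numeric(model)) {
    stopifnot(length(model) == nrow(table))
    return(model)
  }
  stats::predict(model, table)
}

#' Generalization change score
#'
#' `AUC(external) - AUC(test)` for one model; negative values are the usual
#' performance drop on the shifted external cohort.
#'
#' @param model Fitted model.
#' @param test_table,external_table Cohort tables.
#' @return Numeric change score.
#' @export
change_score <- function(model, test_table, external_table) {
  roc_auc(model_scores(model, external_table), external_table$outcome) -
    roc_auc(model_scores(model, test_table), test_table$outcome)
}

#' Difference-in-differences of change scores against a baseline
#'
#' `did = change_score(model) - change_score(baseline)`; positive values
#' mean the model lost less performance externally than the baseline. The
#' CI comes from a paired bootstrap over joint resamples of both tables.
#'
#' @param model,baseline Fitted models.
#' @param test_table,external_table Cohort tables.
#' @param spec A [bootstrap_spec()].
#' @return List with `point`, `ci`, `draws`.
#' @export
did_vs_baseline <- function(model, baseline, test_table, external_table,
                            spec = bootstrap_spec()) {
  sm_t <- model_scores(model, test_table)
  sb_t <- model_scores(baseline, test_table)
  sm_e <- model_scores(model, external_table)
  sb_e <- model_scores(baseline, external_table)
  yt <- test_table$outcome; ye <- external_table$outcome
  cs <- function(mt, me, it, ie) {
    (roc_auc(me[ie], ye[ie]) - roc_auc(mt[it], yt[it]))
  }
  all_t <- seq_along(yt); all_e <- seq_along(ye)
  point <- cs(sm_t, sm_e, all_t, all_e) - cs(sb_t, sb_e, all_t, all_e)
  set.seed(spec$seed)
  draws <- vapply(seq_len(spec$n_iterations), function(i) {
    it <- resample_two_class(test_table, spec$resample_unit, spec$max_redraws)
    ie <- resample_two_class(external_table, spec$resample_unit, spec$max_redraws)
    cs(sm_t, sm_e, it, ie) - cs(sb_t, sb_e, it, ie)
  }, numeric(1))
  list(point = point,
       ci = unname(stats::quantile(draws, c(0.025, 0.975), type = 7)),
       draws = draws)
}

# Threshold maximizing the Youden index (sensitivity + specificity - 1) on
# the supplied (usually training) scores.
youden_threshold <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  j <- rc$tpr - rc$fpr
  rc$threshold[which.max(j)]
}

threshold_metrics <- function(scores, labels, threshold) {
  y <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  sens <- sum(pred == 1 & y == 1) / sum(y == 1)
  spec <- sum(pred == 0 & y == 0) / sum(y == 0)
  c(sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2)
}

#' Full internal / external evaluation report
#'
#' Scores every model on the internal test and external test sets and
#' reports, per model: both AUCs, the paired-bootstrap difference from the
#' baseline (first model) on each set with 95% CI, the change score
#' (external minus test AUC), the difference-in-differences against the
#' baseline with 95% CI, and secondary metrics (sensitivity, specificity,
#' balanced accuracy) at the threshold maximizing the training Youden
#' index. Also emits ROC coordinates per model and split.
#'
#' @param models Named list of fitted models; the first is the baseline
#'   (reference) model.
#' @param test_table,external_table,train_table Cohort tables.
#' @param spec A [bootstrap_spec()].
#' @return List with `report` (tibble, one row per model) and `roc` (tibble
#'   of ROC coordinates: `model`, `split`, `threshold`, `fpr`, `tpr`).
#' @export
full_report <- function(models, test_table, external_table, train_table,
                        spec = bootstrap_spec()) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  base_name <- names(models)[1]
  rows <- vector("list", length(models))
  roc_rows <- list()
  base <- models[[1]]
  for (i in seq_along(models)) {
    m <- models[[i]]
    st <- model_scores(m, test_table)
    se <- model_scores(m, external_table)
    str_ <- model_scores(m, train_table)
    thr <- youden_threshold(str_, train_table$outcome)
    mt <- threshold_metrics(st, test_table$outcome, thr)
    auc_t <- roc_auc(st, test_table$outcome)
    auc_e <- roc_auc(se, external_table$outcome)
    if (i == 1L) {
      dt <- de <- dd <- list(point = 0, ci = c(NA_real_, NA_real_))
    } else {
      dt <- bootstrap_paired_diff(m, base, test_table, spec)
      de <- bootstrap_paired_diff(m, base, external_table, spec)
      dd <- did_vs_baseline(m, base, test_table, external_table, spec)
    }
    rows[[i]] <- tibble::tibble(
      model = names(models)[i],
      auc_test = auc_t,
      diff_test = if (i == 1L) NA_real_ else dt$point,
      diff_test_lo = dt$ci[1], diff_test_hi = dt$ci[2],
      auc_external = auc_e,
      diff_external = if (i == 1L) NA_real_ else de$point,
      diff_external_lo = de$ci[1], diff_external_hi = de$ci[2],
      change_score = auc_e - auc_t,
      did = if (i == 1L) NA_real_ else dd$point,
      did_lo = dd$ci[1], did_hi = dd$ci[2],
      threshold = thr,
      sensitivity_test = unname(mt["sensitivity"]),
      specificity_test = unname(mt["specificity"]),
      balanced_accuracy_test = unname(mt["balanced_accuracy"]))
    for (sp in c("test", "external")) {
      sc <- if (sp == "test") st else se
      tb <- if (sp == "test") test_table else external_table
      rc <- roc_curve(sc, tb$outcome)
      rc$model <- names(models)[i]; rc$split <- sp
      roc_rows[[length(roc_rows) + 1L]] <- rc
    }
  }
  list(report = do.call(rbind, rows),
       roc = do.call(rbind, roc_rows),
       baseline = base_name)
}
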