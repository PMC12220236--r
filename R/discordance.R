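#' Empirical risk of a rule's subgroup
#'
#' Proportion of positive outcomes (successful extubation) among the
#' training records for which the rule fires.
#'
#' @param rule An [new_rule()].
#' @param train Training cohort table.
#' @return Proportion in \[0, 1\]; zero support is an error.
#' @export
empirical_risk <- function(rule, train) {
  fire <- rule_fires(rule, train) == 1L
  if (!any(fire)) {
    stop(sprintf("rule '%s' fires for no training record", rule$rule_id),
         call. = FALSE)
  }
  mean(train$outcome[fire])
}

#' Empirical risks for a rule list
#'
#' @param rules List of rules.
#' @param train Training cohort table.
#' @return Named numeric vector (rule_id -> risk).
#' @export
rule_risks <- function(rules, train) {
  out <- vapply(rules, empirical_risk, numeric(1), train = train)
  names(out) <- rule_ids(rules)
  out
}

#' Rank rules by model-estimated chance of success
#'
#' Ascending ranks on empirical risk (1 = lowest chance of success); ties
#' receive average (fractional) ranks.
#'
#' @param risks Named vector of empirical risks.
#' @return Named rank vector.
#' @export
rank_by_model <- function(risks) {
  stopifnot(length(risks) >= 2)
  r <- rank(risks, ties.method = "average")
  names(r) <- names(risks)
  r
}

#' Rank rules by expert-assessed chance of success
#'
#' Ascending rank on chance of success is a *descending* rank on the mean
#' Likert response, since 1 = "much higher" chance; ties receive average
#' ranks.
#'
#' @param aggregated Output of [aggregate_responses()] (columns `rule_id`,
#'   `expert_mean`).
#' @return Named rank vector (rule_id -> rank; 1 = lowest chance of success).
#' @export
rank_by_experts <- function(aggregated) {
  stopifnot(nrow(aggregated) >= 2)
  r <- rank(-aggregated$expert_mean, ties.method = "average")
  names(r) <- aggregated$rule_id
  r
}

#' Model-versus-expert rank discordance
#'
#' `delta_rank = model_rank - expert_rank`; negative values mean the model
#' rated the subgroup less likely to succeed than the experts did. Dividing
#' by the expert response SD (`delta_rank_over_sd`) penalizes disagreement
#' more strongly where the experts agreed most among themselves. A unanimous
#' panel (SD = 0) would make the ratio infinite, so SDs are floored at the
#' smallest positive observed SD (fallback 0.1 when all are zero), with a
#' warning.
#'
#' @param model_ranks,expert_ranks Named rank vectors over the same rule set.
#' @param expert_sds Named vector of per-rule expert response SDs.
#' @param expert_means,risks Optional named vectors carried into the table.
#' @param sd_floor Numeric floor for SDs, or `"auto"` for the rule above.
#' @return Tibble of `rule_assessment` rows: `rule_id`, `empirical_risk`,
#'   `model_rank`, `expert_mean`, `expert_sd`, `expert_rank`, `delta_rank`,
#'   `delta_rank_over_sd`.
#' @export
compute_discordance <- function(model_ranks, expert_ranks, expert_sds,
                                expert_means = NULL, risks = NULL,
                                sd_floor = "auto") {
  ids <- names(model_ranks)
  if (!setequal(ids, names(expert_ranks)) || !setequal(ids, names(expert_sds))) {
    stop("model_ranks, expert_ranks and expert_sds must cover the same rule ids",
         call. = FALSE)
  }
  expert_ranks <- expert_ranks[ids]
  expert_sds <- expert_sds[ids]
  if (identical(sd_floor, "auto")) {
    pos <- expert_sds[expert_sds > 0]
    sd_floor <- if (length(pos)) min(pos) else 0.1
  }
  if (any(expert_sds <= 0)) {
    warning(sprintf("%d rule(s) with zero expert SD floored at %.4g",
                    sum(expert_sds <= 0), sd_floor), call. = FALSE)
  }
  delta <- model_ranks - expert_ranks
  out <- tibble::tibble(
    rule_id = ids,
    empirical_risk = if (is.null(risks)) NA_real_ else unname(risks[ids]),
    model_rank = unname(model_ranks),
    expert_mean = if (is.null(expert_means)) NA_real_ else unname(expert_means[ids]),
    expert_sd = unname(expert_sds),
    expert_rank = unname(expert_ranks),
    delta_rank = unname(delta),
    delta_rank_over_sd = unname(delta / pmax(expert_sds, sd_floor)))
  class(out) <- c("rule_assessment", class(out))
  out
}

#' Assess all selected rules of a fitted model against an expert panel
#'
#' Convenience composition: empirical risks on the training split, the two
#' rankings, and the discordance table.
#'
#' @param model A `rulefit_model`.
#' @param train Training cohort table.
#' @param aggregated Output of [aggregate_responses()] covering every
#'   selected rule.
#' @param sd_floor See [compute_discordance()].
#' @return A `rule_assessment` tibble.
#' @export
assess_rules <- function(model, train, aggregated, sd_floor = "auto") {
  rules <- model$selected_rules
  ids <- rule_ids(rules)
  miss <- setdiff(ids, aggregated$rule_id)
  if (length(miss)) {
    stop(sprintf("no aggregated responses for rule(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  aggregated <- aggregated[match(ids, aggregated$rule_id), , drop = FALSE]
  risks <- rule_risks(rules, train)
  means <- stats::setNames(aggregated$expert_mean, ids)
  sds <- stats::setNames(aggregated$expert_sd, ids)
  compute_discordance(rank_by_model(risks), rank_by_experts(aggregated), sds,
                      expert_means = means, risks = risks, sd_floor = sd_floor)
}

#' Model-expert concordance summary
#'
#' Ordinary least-squares R-squared of the mean expert response regressed on
#' empirical risk, plus the per-rule scatter table behind it.
#'
#' @param assessments A `rule_assessment` tibble with at least 3 rules and
#'   non-missing `expert_mean` and `empirical_risk`.
#' @return List with `r_squared` (NA with a message when either variable has
#'   zero variance) and `scatter` (tibble `rule_id`, `empirical_risk`,
#'   `expert_mean`).
#' @export
concordance_summary <- function(assessments) {
  stopifnot(nrow(assessments) >= 3)
  scatter <- assessments[, c("rule_id", "empirical_risk", "expert_mean")]
  if (stats::var(assessments$empirical_risk) == 0 ||
      stats::var(assessments$expert_mean) == 0) {
    warning("zero variance in risk or expert mean; R-squared undefined",
            call. = FALSE)
    return(list(r_squared = NA_real_, scatter = scatter))
  }
  fit <- stats::lm(expert_mean ~ empirical_risk, data = assessments)
  list(r_squared = summary(fit)$r.squared, scatter = scatter)
}

#' Write the assessment table as CSV
#'
#' Columns mirror the discordance report: ranks, SD, delta rank, delta
#' rank/SD (full precision), plus the rendered rule text.
#'
#' @param assessments A `rule_assessment` tibble.
#' @param rules Rule list supplying rendered text (optional).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assessments_csv <- function(assessments, path, rules = NULL) {
  d <- as.data.frame(assessments)
  if (!is.null(rules)) {
    d$rule_text <- vapply(rules[match(d$rule_id, rule_ids(rules))],
                          render_rule, character(1))
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
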