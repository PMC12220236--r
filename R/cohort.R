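#' Planted rule for the synthetic cohort generator
#'
#' A subgroup-defining rule together with its log-odds contribution to the
#' outcome in the internal (train/test) and the external cohort. A rule is
#' spurious when its internal effect does not carry over to the external
#' cohort (opposite sign, or zero external effect with a nonzero internal
#' one) — the pattern that penalizes generalization.
#'
#' @param conditions List of [rule_condition()]s.
#' @param effect_train Log-odds contribution in the internal cohort.
#' @param effect_external Log-odds contribution in the external cohort.
#' @return A `planted_rule` object; its `spurious` flag is derived from the
#'   two effects, never set by hand.
#' @export
planted_rule <- function(conditions, effect_train, effect_external) {
  stopifnot(is.numeric(effect_train), is.numeric(effect_external))
  spurious <- (sign(effect_train) != sign(effect_external)) ||
    (effect_external == 0 && effect_train != 0)
  structure(list(conditions = conditions,
                 effect_train = as.numeric(effect_train),
                 effect_external = as.numeric(effect_external),
                 spurious = spurious),
            class = "planted_rule")
}

#' Configuration of the synthetic ICU cohort
#'
#' Describes a cohort of intubation episodes binned into 4-hour time windows
#' (the first window ending 12 h after intubation), with numeric and
#' categorical window-level features, lagged copies from the two prior
#' windows, a baseline (window-0) copy, and a per-window binary outcome drawn
#' from a logistic model over planted rules. The internal cohort is split
#' into train/test by intubation order (a stand-in for intubation date); a
#' separate external cohort uses each planted rule's external effect, so
#' spurious rules carry signal internally but not externally.
#'
#' @param n_intubations Internal-cohort intubation count (split train/test).
#' @param n_external External-cohort intubation count.
#' @param windows_min,windows_max Per-intubation window count is drawn
#'   uniformly from this range.
#' @param n_numeric Number of numeric window-level features (`f1`, `f2`, ...),
#'   marginally standard normal with AR(1) persistence `ar_rho` across windows.
#' @param categorical_levels Named list: categorical feature name -> character
#'   vector of levels. Levels persist across windows with probability
#'   `cat_persist`, else are redrawn uniformly.
#' @param n_lags Number of lagged copies of each feature (default 2; columns
#'   `<f>_lag1`, `<f>_lag2`). Missing early lags are backfilled with the
#'   earliest available value.
#' @param baseline_copy Add `<f>_base`, the window-0 value carried forward.
#' @param planted_rules List of [planted_rule()]s; conditions may reference
#'   base, lagged, or baseline columns.
#' @param base_logit Intercept of the outcome logit. Ignored when
#'   `target_rate` is given.
#' @param target_rate Optional overall positive-outcome rate; when set, the
#'   intercept is calibrated by root-finding on the realized internal-cohort
#'   linear predictor so that the expected window-level rate matches.
#' @param train_fraction Fraction of internal intubations (by order index)
#'   assigned to the training split.
#' @param ar_rho AR(1) coefficient of numeric features across windows.
#' @param cat_persist Probability a categorical level persists to the next
#'   window.
#' @param outcome_ar_sd,outcome_ar_rho Optional within-intubation AR(1)
#'   latent term added to the outcome logit (marginal SD `outcome_ar_sd`);
#'   default 0 (independent outcomes given features).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_intubations = 1000,
                          n_external = 250,
                          windows_min = 4,
                          windows_max = 12,
                          n_numeric = 8,
                          categorical_levels = list(
                            sbt = c("Not assessed", "Ineligible", "Failed", "Passed")),
                          n_lags = 2,
                          baseline_copy = TRUE,
                          planted_rules = list(),
                          base_logit = 0,
                          target_rate = NULL,
                          train_fraction = 0.8,
                          ar_rho = 0.6,
                          cat_persist = 0.8,
                          outcome_ar_sd = 0,
                          outcome_ar_rho = 0.5,
                          seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_lags >= 0,
            windows_min >= 1, windows_max >= windows_min,
            n_intubations >= 2, n_external >= 0, outcome_ar_sd >= 0)
  ok <- vapply(planted_rules, inherits, logical(1), "planted_rule")
  if (!all(ok)) stop("planted_rules must be planted_rule objects", call. = FALSE)
  structure(list(n_intubations = as.integer(n_intubations),
                 n_external = as.integer(n_external),
                 windows_min = as.integer(windows_min),
                 windows_max = as.integer(windows_max),
                 n_numeric = as.integer(n_numeric),
                 categorical_levels = categorical_levels,
                 n_lags = as.integer(n_lags),
                 baseline_copy = isTRUE(baseline_copy),
                 planted_rules = planted_rules,
                 base_logit = base_logit,
                 target_rate = target_rate,
                 train_fraction = train_fraction,
                 ar_rho = ar_rho,
                 cat_persist = cat_persist,
                 outcome_ar_sd = outcome_ar_sd,
                 outcome_ar_rho = outcome_ar_rho,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default study-emulation cohort configuration
#'
#' Eight planted single-condition rules on the numeric features: six stable
#' rules on common subgroups (~35% support; log-odds effects carried to the
#' external cohort) and two spurious rules on rare subgroups (~8% support;
#' internal effects of -2 and +2 that vanish externally, the niche-artifact
#' pattern expert review is meant to catch). The intercept is
#' calibrated so the overall positive rate lands near 0.76, and the internal
#' cohort of 1000 intubations splits 80/20 into 800 train / 200 test, with
#' 250 external intubations.
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [cohort_config()].
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(seed = 1L, ...) {
  thr <- stats::qnorm(0.35)    # ~35% support per planted subgroup
  stable_fx <- c(1, -1, 1, -1, 1.5, -1.5)
  stable <- lapply(1:6, function(j) {
    kind <- if (j %% 2 == 1) "numeric_le" else "numeric_gt"
    tt <- if (j %% 2 == 1) thr else -thr
    planted_rule(list(rule_condition(paste0("f", j), kind, threshold = tt)),
                 effect_train = stable_fx[j], effect_external = stable_fx[j])
  })
  # spurious subgroups are rare niches (~8% of windows): a strong
  # internal-only effect concentrated in a small subgroup, the pattern an
  # artifact rule typically takes
  thr_sp <- stats::qnorm(0.08)
  spurious <- list(
    planted_rule(list(rule_condition("f7", "numeric_le", threshold = thr_sp)),
                 effect_train = -2, effect_external = 0),
    planted_rule(list(rule_condition("f8", "numeric_gt", threshold = -thr_sp)),
                 effect_train = 2, effect_external = 0))
  cohort_config(planted_rules = c(stable, spurious),
                target_rate = 0.762, seed = seed, ...)
}

# AR(1) series with standard-normal marginals, one per (intubation, feature).
ar1_series <- function(n, rho) {
  z <- stats::rnorm(n)
  if (n == 1L || rho == 0) return(z)
  x <- numeric(n)
  x[1] <- z[1]
  for (t in 2:n) x[t] <- rho * x[t - 1] + sqrt(1 - rho^2) * z[t]
  x
}

markov_levels <- function(n, levels, persist) {
  x <- character(n)
  x[1] <- sample(levels, 1L)
  if (n > 1L) for (t in 2:n) {
    x[t] <- if (stats::runif(1) < persist) x[t - 1] else sample(levels, 1L)
  }
  x
}

lag_backfill <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  c(rep(x[1], min(k, n)), x[seq_len(max(n - k, 0L))])
}

generate_one_cohort <- function(config, n_intubations, id_offset, effect_field) {
  feat_names <- c(if (config$n_numeric > 0) paste0("f", seq_len(config$n_numeric)),
                  names(config$categorical_levels))
  blocks <- vector("list", n_intubations)
  for (i in seq_len(n_intubations)) {
    nw <- sample(config$windows_min:config$windows_max, 1L)
    d <- data.frame(intubation_id = id_offset + i,
                    window_index = 0:(nw - 1L),
                    window_end_time = 12 + 4 * (0:(nw - 1L)))
    for (j in seq_len(config$n_numeric)) {
      d[[paste0("f", j)]] <- ar1_series(nw, config$ar_rho)
    }
    for (cf in names(config$categorical_levels)) {
      d[[cf]] <- markov_levels(nw, config$categorical_levels[[cf]], config$cat_persist)
    }
    # lagged and baseline copies of every base feature
    for (f in feat_names) {
      if (config$n_lags > 0) for (k in seq_len(config$n_lags)) {
        d[[paste0(f, "_lag", k)]] <- lag_backfill(d[[f]], k)
      }
      if (config$baseline_copy) d[[paste0(f, "_base")]] <- d[[f]][1]
    }
    blocks[[i]] <- d
  }
  tab <- do.call(rbind, blocks)
  # per-window log-odds offset from the planted rules
  offset <- rep(0, nrow(tab))
  for (pr in config$planted_rules) {
    r <- new_rule("planted", pr$conditions)
    offset <- offset + pr[[effect_field]] * rule_fires(r, tab)
  }
  if (config$outcome_ar_sd > 0) {
    eps <- unlist(lapply(split(seq_len(nrow(tab)), tab$intubation_id), function(idx) {
      config$outcome_ar_sd * ar1_series(length(idx), config$outcome_ar_rho)
    }), use.names = FALSE)
    offset <- offset + eps
  }
  list(table = tab, offset = offset)
}

#' Generate a synthetic windowed cohort with internal and external splits
#'
#' Internal intubations are split by order index — the first `train_fraction`
#' into `train`, the remainder into `test` (mimicking a date-based split) —
#' and outcomes are drawn Bernoulli(logistic(intercept + sum of planted-rule
#' effects)), using each rule's internal effect for train/test and its
#' external effect for the external cohort.
#'
#' @param config A [cohort_config()]. Planted rules referencing undefined
#'   features are rejected.
#' @return A tibble (`cohort_table`): `intubation_id`, `window_index`,
#'   `window_end_time`, `split`, `outcome`, then feature columns. The
#'   calibrated intercept is attached as attribute `base_logit`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  internal <- generate_one_cohort(config, config$n_intubations, 0L, "effect_train")
  # validate planted-rule features against the generated schema (errors
  # surfaced during offset computation above would name the feature already,
  # but check explicitly for a clear contract)
  feat_cols <- setdiff(names(internal$table),
                       c("intubation_id", "window_index", "window_end_time"))
  for (pr in config$planted_rules) {
    miss <- setdiff(vapply(pr$conditions, function(cn) cn$feature, character(1)),
                    feat_cols)
    if (length(miss)) {
      stop(sprintf("planted rule references undefined feature(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  base_logit <- config$base_logit
  if (!is.null(config$target_rate)) {
    off <- internal$offset
    f <- function(b) mean(stats::plogis(b + off)) - config$target_rate
    base_logit <- stats::uniroot(f, interval = c(-20, 20), tol = 1e-10)$root
  }
  internal$table$outcome <-
    stats::rbinom(nrow(internal$table), 1L,
                  stats::plogis(base_logit + internal$offset))
  n_train <- floor(config$train_fraction * config$n_intubations)
  internal$table$split <-
    ifelse(internal$table$intubation_id <= n_train, "train", "test")

  tab <- internal$table
  if (config$n_external > 0) {
    external <- generate_one_cohort(config, config$n_external,
                                    config$n_intubations, "effect_external")
    external$table$outcome <-
      stats::rbinom(nrow(external$table), 1L,
                    stats::plogis(base_logit + external$offset))
    external$table$split <- "external"
    tab <- rbind(tab, external$table)
  }
  front <- c("intubation_id", "window_index", "window_end_time", "split", "outcome")
  tab <- tab[, c(front, setdiff(names(tab), front))]
  out <- tibble::as_tibble(tab)
  attr(out, "base_logit") <- base_logit
  class(out) <- c("cohort_table", class(out))
  out
}

#' Split a cohort table
#'
#' @param table A cohort table.
#' @param split One of `"train"`, `"test"`, `"external"`.
#' @return The subset of rows in that split.
#' @export
cohort_split <- function(table, split = c("train", "test", "external")) {
  split <- match.arg(split)
  table[table$split == split, , drop = FALSE]
}

#' Write / read a cohort table as CSV
#'
#' One row per window; columns `intubation_id`, `window_index`,
#' `window_end_time`, `split`, `outcome`, then features.
#'
#' @param table A cohort table.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort tibble.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  out <- tibble::as_tibble(tab)
  class(out) <- c("cohort_table", class(out))
  out
}

#' Configuration of the simulated expert panel
#'
#' Experts observe each rule's subgroup through a noisy latent score: the log
#' ratio of the subgroup's external-cohort outcome rate to the overall
#' external rate, plus a shared systematic bias and independent normal
#' perception noise. The latent score is cut into the five Likert anchors
#' (1 = much higher chance of success ... 5 = much lower), so a higher latent
#' relative risk maps to a *lower* Likert value.
#'
#' @param roles Data frame with columns `role`, `experience_band`, `n`
#'   (counts summing to the panel size). The default is a 25-member panel
#'   (12 attending physicians, 7 fellows, 4 nurses, 2 respiratory
#'   therapists) with experience bands <3 / 3-5 / 6-10 / >10 years.
#' @param perception_noise_sd SD of each expert's independent perception
#'   noise on the latent log-relative-risk scale (>= 0).
#' @param shared_bias Systematic shift applied to every expert's latent
#'   score (log relative-risk units).
#' @param likert_cutpoints Four strictly increasing thresholds on the latent
#'   scale; scores above the top cutpoint map to Likert 1.
#' @param seed Integer seed.
#' @return An `expert_panel_config`.
#' @export
expert_panel_config <- function(roles = default_panel_roles(),
                                perception_noise_sd = 0.25,
                                shared_bias = 0,
                                likert_cutpoints = c(-0.4, -0.1, 0.1, 0.4),
                                seed = 1L) {
  stopifnot(is.data.frame(roles),
            all(c("role", "experience_band", "n") %in% names(roles)),
            perception_noise_sd >= 0,
            length(likert_cutpoints) == 4L,
            all(diff(likert_cutpoints) > 0))
  structure(list(roles = roles,
                 n_experts = as.integer(sum(roles$n)),
                 perception_noise_sd = perception_noise_sd,
                 shared_bias = shared_bias,
                 likert_cutpoints = as.numeric(likert_cutpoints),
                 seed = as.integer(seed)),
            class = "expert_panel_config")
}

#' @rdname expert_panel_config
#' @export
default_panel_roles <- function() {
  data.frame(
    role = c("attending", "attending", "attending", "attending",
             "fellow", "fellow", "fellow",
             "nurse", "nurse", "respiratory_therapist"),
    experience_band = c(">10", "6-10", "3-5", "<3",
                        "6-10", "3-5", "<3",
                        ">10", "<3", "6-10"),
    n = c(5, 3, 2, 2, 2, 3, 2, 3, 1, 2),
    stringsAsFactors = FALSE)
}

#' Simulate a panel of expert Likert responses to rules
#'
#' Each expert's latent score for a rule is the log ratio of the rule
#' subgroup's empirical outcome rate in the external cohort to the overall
#' external rate, plus the panel's shared bias and the expert's own
#' N(0, `perception_noise_sd`) perception noise; the score is then mapped
#' through the Likert cutpoints (higher latent relative risk -> lower Likert
#' value, i.e. "1 = much higher"). Rules with no firing external record fall
#' back to the training-cohort rate and are flagged with a warning.
#'
#' @param rules List of [new_rule()]s; each must fire for at least one
#'   training record.
#' @param cohort A cohort table with `train` and (normally) `external` splits.
#' @param config An [expert_panel_config()].
#' @return Tibble (`expert_response_set`) with columns `expert_id`, `role`,
#'   `experience_band`, `rule_id`, `response` (integer 1-5), and
#'   `zero_external_support` flag.
#' @export
simulate_expert_panel <- function(rules, cohort, config) {
  stopifnot(inherits(config, "expert_panel_config"))
  train <- cohort_split(cohort, "train")
  ext <- cohort[cohort$split == "external", , drop = FALSE]
  set.seed(config$seed)

  experts <- config$roles[rep(seq_len(nrow(config$roles)), config$roles$n), ,
                          drop = FALSE]
  experts$expert_id <- sprintf("e%02d", seq_len(nrow(experts)))

  rate_floor <- function(k, n) max(k, 0.5) / n   # keep log finite at 0 successes
  overall_ext <- if (nrow(ext) > 0) rate_floor(sum(ext$outcome), nrow(ext)) else NA_real_

  per_rule <- lapply(rules, function(r) {
    tr_fire <- rule_fires(r, train) == 1L
    if (!any(tr_fire)) {
      stop(sprintf("rule '%s' fires for no training record", r$rule_id), call. = FALSE)
    }
    zero_ext <- TRUE
    if (nrow(ext) > 0) {
      ex_fire <- rule_fires(r, ext) == 1L
      zero_ext <- !any(ex_fire)
    }
    if (!zero_ext) {
      sub_rate <- rate_floor(sum(ext$outcome[ex_fire]), sum(ex_fire))
      latent0 <- log(sub_rate / overall_ext)
    } else {
      warning(sprintf(paste0("rule '%s' has zero external support; ",
                             "latent score taken from the training cohort"),
                      r$rule_id), call. = FALSE)
      sub_rate <- rate_floor(sum(train$outcome[tr_fire]), sum(tr_fire))
      all_rate <- rate_floor(sum(train$outcome), nrow(train))
      latent0 <- log(sub_rate / all_rate)
    }
    list(latent0 = latent0, zero_ext = zero_ext)
  })

  rows <- vector("list", length(rules))
  for (j in seq_along(rules)) {
    latent <- per_rule[[j]]$latent0 + config$shared_bias +
      stats::rnorm(nrow(experts), 0, config$perception_noise_sd)
    response <- 5L - findInterval(latent, config$likert_cutpoints)
    rows[[j]] <- data.frame(expert_id = experts$expert_id,
                            role = experts$role,
                            experience_band = experts$experience_band,
                            rule_id = rules[[j]]$rule_id,
                            response = as.integer(response),
                            zero_external_support = per_rule[[j]]$zero_ext,
                            stringsAsFactors = FALSE)
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  class(out) <- c("expert_response_set", class(out))
  out
}
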