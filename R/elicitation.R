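SURVEY_STEM <- paste("Do patients in the subgroup have a higher or lower chance",
                     "of successful extubation 12 hours from now compared with",
                     "patients in the population?")

LIKERT_ANCHORS <- c("1" = "much higher", "2" = "somewhat higher",
                    "3" = "no difference", "4" = "somewhat lower",
                    "5" = "much lower")

#' Summarize a rule's subgroup against the full training sample
#'
#' Only the variables referenced by the rule's conditions are summarized:
#' numeric variables by median (minimum, maximum), categorical variables by
#' mode plus all levels present, each for the firing subgroup and for the
#' full training sample.
#'
#' @param rule An [new_rule()] with at least one firing training record.
#' @param train Training cohort table.
#' @return A `subgroup_summary`: `rule_id`, `subgroup_n`, `population_n`,
#'   and a per-variable list of subgroup/population summaries.
#' @export
summarize_subgroup <- function(rule, train) {
  fire <- rule_fires(rule, train) == 1L
  if (!any(fire)) {
    stop(sprintf("rule '%s' fires for no training record", rule$rule_id),
         call. = FALSE)
  }
  vars <- rule_features(rule)
  sub <- train[fire, , drop = FALSE]
  summarize_var <- function(x) {
    if (is.numeric(x)) {
      list(type = "numeric", median = stats::median(x),
           min = min(x), max = max(x))
    } else {
      x <- as.character(x)
      tab <- sort(table(x), decreasing = TRUE)
      list(type = "categorical", mode = names(tab)[1],
           levels = sort(unique(x)))
    }
  }
  variables <- lapply(vars, function(v) {
    list(variable = v,
         subgroup = summarize_var(sub[[v]]),
         population = summarize_var(train[[v]]))
  })
  names(variables) <- vars
  structure(list(rule_id = rule$rule_id, subgroup_n = sum(fire),
                 population_n = nrow(train), variables = variables),
            class = "subgroup_summary")
}

format_var_summary <- function(s, digits = 1) {
  if (s$type == "numeric") {
    sprintf("%s (%s, %s)", round(s$median, digits), round(s$min, digits),
            round(s$max, digits))
  } else {
    sprintf("%s (%s)", s$mode, paste(s$levels, collapse = ", "))
  }
}

#' Render selected rules as a survey form
#'
#' One item per selected rule, in the subgroup-vs-population format: for each
#' referenced variable the subgroup and full-training-sample summaries, the
#' fixed question stem, and the five Likert anchors. Item order is
#' randomized once under a recorded seed.
#'
#' @param model A `rulefit_model` with selected rules.
#' @param summaries List of [summarize_subgroup()] results, one per selected
#'   rule (default: computed from `train`).
#' @param train Training cohort table (used when `summaries` is `NULL`).
#' @param seed Integer seed for item-order randomization (recorded in the
#'   form).
#' @param json_path,md_path Optional output paths for the machine-readable
#'   (JSON) and human-readable (markdown) forms.
#' @return A `survey_form`: `stem`, `anchors`, `seed`, and ordered `items`.
#'   Zero selected rules yield an empty form with a warning.
#' @export
render_survey <- function(model, summaries = NULL, train = NULL, seed = 1L,
                          json_path = NULL, md_path = NULL) {
  rules <- model$selected_rules
  if (length(rules) == 0L) {
    warning("no selected rules; emitting an empty survey form", call. = FALSE)
    items <- list()
  } else {
    if (is.null(summaries)) {
      if (is.null(train)) stop("either summaries or train must be supplied",
                               call. = FALSE)
      summaries <- lapply(rules, summarize_subgroup, train = train)
    }
    if (length(summaries) != length(rules)) {
      stop("one summary per selected rule is required", call. = FALSE)
    }
    set.seed(seed)
    ord <- sample(seq_along(rules))
    items <- lapply(ord, function(j) {
      list(rule_id = rules[[j]]$rule_id,
           rule_text = render_rule(rules[[j]]),
           summary = unclass(summaries[[j]]))
    })
  }
  form <- structure(list(stem = SURVEY_STEM,
                         anchors = as.list(LIKERT_ANCHORS),
                         seed = as.integer(seed),
                         items = items),
                    class = "survey_form")
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(form), json_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  if (!is.null(md_path)) writeLines(format_survey_md(form), md_path)
  form
}

format_survey_md <- function(form) {
  out <- c("# Expert survey", "",
           sprintf("Answer scale: %s.",
                   paste(sprintf("%s = %s", names(LIKERT_ANCHORS), LIKERT_ANCHORS),
                         collapse = ", ")), "")
  for (i in seq_along(form$items)) {
    it <- form$items[[i]]
    out <- c(out, sprintf("## Item %d (rule %s)", i, it$rule_id), "",
             form$stem, "",
             "| Variable | Subgroup | Population |",
             "|---|---|---|")
    for (v in it$summary$variables) {
      out <- c(out, sprintf("| %s | %s | %s |", v$variable,
                            format_var_summary(v$subgroup),
                            format_var_summary(v$population)))
    }
    out <- c(out, "")
  }
  out
}

#' Read a survey form back from JSON
#'
#' @param path Path written by [render_survey()].
#' @return A `survey_form`.
#' @export
read_survey_form <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(obj, class = "survey_form")
}

#' Write / ingest expert responses
#'
#' Responses travel as CSV with header
#' `expert_id,role,experience_band,rule_id,response`. Ingestion validates
#' that responses are integers 1-5 and rule ids belong to the form,
#' deduplicates exact duplicate rows, and rejects conflicting duplicates
#' (same expert and rule, different value).
#'
#' @param responses An expert response set (tibble).
#' @param path CSV path.
#' @param form The `survey_form` the responses answer (optional: when
#'   supplied, unknown rule ids are an error).
#' @return `write_responses_csv` returns `path` invisibly;
#'   `ingest_responses` the validated response tibble.
#' @export
write_responses_csv <- function(responses, path) {
  cols <- c("expert_id", "role", "experience_band", "rule_id", "response")
  utils::write.csv(as.data.frame(responses)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses_csv
#' @export
ingest_responses <- function(path, form = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", "role", "experience_band", "rule_id", "response")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop(sprintf("responses file lacks column(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  bad <- which(!(d$response %in% 1:5) | d$response != as.integer(d$response))
  if (length(bad)) {
    stop(sprintf("response out of range 1-5 at row(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(form)) {
    known <- vapply(form$items, function(it) it$rule_id, character(1))
    unknown <- setdiff(unique(d$rule_id), known)
    if (length(unknown)) {
      stop(sprintf("unknown rule_id(s) not in the survey form: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  d <- unique(d)
  key <- paste(d$expert_id, d$rule_id)
  if (anyDuplicated(key)) {
    conf <- unique(key[duplicated(key)])
    stop(sprintf("conflicting duplicate responses for (expert, rule): %s",
                 paste(utils::head(conf, 10), collapse = "; ")), call. = FALSE)
  }
  d$response <- as.integer(d$response)
  out <- tibble::as_tibble(d)
  class(out) <- c("expert_response_set", class(out))
  out
}

#' Aggregate expert responses per rule
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator; `sd_n`
#' switches to the n denominator) of the numeric Likert responses, overall
#' or restricted to a subpanel by role and/or experience band — e.g. the
#' attending-physician-only sensitivity analysis.
#'
#' @param responses An expert response set.
#' @param roles Optional character vector of roles to keep.
#' @param experience_bands Optional character vector of experience bands to
#'   keep.
#' @param sd_n Use the n (population) denominator for the SD.
#' @return Tibble with `rule_id`, `expert_mean`, `expert_sd`, `n_responses`.
#'   A rule left with zero responses after filtering is an error.
#' @export
aggregate_responses <- function(responses, roles = NULL,
                                experience_bands = NULL, sd_n = FALSE) {
  all_rules <- unique(responses$rule_id)
  d <- responses
  if (!is.null(roles)) d <- d[d$role %in% roles, , drop = FALSE]
  if (!is.null(experience_bands)) {
    d <- d[d$experience_band %in% experience_bands, , drop = FALSE]
  }
  empty <- setdiff(all_rules, unique(d$rule_id))
  if (length(empty)) {
    stop(sprintf("no responses after filtering for rule(s): %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  sd_fun <- function(x) {
    if (length(x) == 1L) return(0)
    s <- stats::sd(x)
    if (sd_n) s * sqrt((length(x) - 1) / length(x)) else s
  }
  agg <- do.call(rbind, lapply(split(d$response, d$rule_id), function(x) {
    data.frame(expert_mean = mean(x), expert_sd = sd_fun(x),
               n_responses = length(x))
  }))
  out <- tibble::tibble(rule_id = rownames(agg),
                        expert_mean = agg$expert_mean,
                        expert_sd = agg$expert_sd,
                        n_responses = as.integer(agg$n_responses))
  out[match(all_rules, out$rule_id), , drop = FALSE]
}
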