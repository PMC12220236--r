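test_that("subgroup summaries cover only referenced variables and obey containment", {
  st <- small_study()
  for (rule in st$model$selected_rules[1:min(5, length(st$model$selected_rules))]) {
    s <- summarize_subgroup(rule, st$train)
    expect_setequal(names(s$variables),
                    unique(vapply(rule$conditions, function(cn) cn$feature,
                                  character(1))))
    for (v in s$variables) {
      if (v$subgroup$type == "numeric") {
        expect_gte(v$subgroup$min, v$population$min)
        expect_lte(v$subgroup$max, v$population$max)
        expect_true(v$subgroup$median >= v$subgroup$min &&
                    v$subgroup$median <= v$subgroup$max)
      } else {
        expect_true(all(v$subgroup$levels %in% v$population$levels))
      }
    }
  }
})

test_that("the empty rule's subgroup summary equals the population summary", {
  st <- small_study()
  r <- new_rule("all", list(rule_condition("f1", "numeric_gt",
                                           threshold = min(st$train$f1) - 1)))
  s <- summarize_subgroup(r, st$train)
  expect_identical(s$subgroup_n, s$population_n)
  expect_equal(s$variables$f1$subgroup, s$variables$f1$population)
})

test_that("a degenerate subgroup has median = min = max", {
  train <- tibble::tibble(intubation_id = 1:6, window_index = 0L,
                          window_end_time = 12, split = "train",
                          outcome = c(0, 1, 0, 1, 1, 0),
                          hours = c(12, 12, 12, 132, 600, 3072))
  r <- new_rule("niche", list(rule_condition("hours", "numeric_le",
                                             threshold = 12)))
  s <- summarize_subgroup(r, train)
  expect_identical(c(s$variables$hours$subgroup$median,
                     s$variables$hours$subgroup$min,
                     s$variables$hours$subgroup$max), c(12, 12, 12))
  expect_identical(s$variables$hours$population$max, 3072)
})

test_that("a categorical subgroup can lack levels the population has", {
  train <- tibble::tibble(
    intubation_id = 1:8, window_index = 0L, window_end_time = 12,
    split = "train", outcome = rep(0:1, 4),
    sbt = c("Not assessed", "Not assessed", "Ineligible", "Passed",
            "Failed", "Not assessed", "Eligible but inconclusive", "Passed"))
  r <- new_rule("r1", list(rule_condition("sbt", "categorical_in",
    levels = c("Not assessed", "Eligible but inconclusive", "Failed", "Passed"))))
  s <- summarize_subgroup(r, train)
  expect_identical(s$variables$sbt$subgroup$mode, "Not assessed")
  expect_false("Ineligible" %in% s$variables$sbt$subgroup$levels)
  expect_true("Ineligible" %in% s$variables$sbt$population$levels)
})

test_that("zero-support rules are rejected by name", {
  st <- small_study()
  r <- new_rule("ghost", list(rule_condition("f1", "numeric_gt",
                                             threshold = max(st$train$f1) + 1)))
  expect_error(summarize_subgroup(r, st$train), "ghost")
})

test_that("the survey form has one item per rule, fixed stem, stable order", {
  st <- small_study()
  form <- render_survey(st$model, train = st$train, seed = 10)
  expect_length(form$items, length(st$model$selected_rules))
  expect_match(form$stem, "higher or lower chance of successful extubation")
  expect_identical(unlist(form$anchors),
                   c(`1` = "much higher", `2` = "somewhat higher",
                     `3` = "no difference", `4` = "somewhat lower",
                     `5` = "much lower"))
  form2 <- render_survey(st$model, train = st$train, seed = 10)
  expect_identical(vapply(form$items, `[[`, character(1), "rule_id"),
                   vapply(form2$items, `[[`, character(1), "rule_id"))
  form3 <- render_survey(st$model, train = st$train, seed = 11)
  expect_false(identical(vapply(form$items, `[[`, character(1), "rule_id"),
                         vapply(form3$items, `[[`, character(1), "rule_id")))
})

test_that("an empty model yields an empty form with a warning", {
  st <- small_study()
  m <- build_rule_matrix(st$model$all_rules, st$train)
  empty <- fit_lasso_selection(m, st$train$outcome,
                               rules = st$model$all_rules, lambda = 5)
  expect_warning(form <- render_survey(empty, train = st$train), "empty")
  expect_length(form$items, 0L)
})

test_that("survey JSON and markdown are written and readable", {
  st <- small_study()
  jp <- tempfile(fileext = ".json"); mp <- tempfile(fileext = ".md")
  form <- render_survey(st$model, train = st$train, seed = 1,
                        json_path = jp, md_path = mp)
  back <- read_survey_form(jp)
  expect_identical(vapply(back$items, `[[`, character(1), "rule_id"),
                   vapply(form$items, `[[`, character(1), "rule_id"))
  md <- readLines(mp)
  expect_true(any(grepl("\\| Variable \\| Subgroup \\| Population \\|", md)))
})

test_that("response ingestion validates range, membership, and duplicates", {
  st <- small_study()
  form <- render_survey(st$model, train = st$train, seed = 1)
  resp <- simulate_expert_panel(st$model$selected_rules, st$cohort,
                                expert_panel_config(seed = 2))
  path <- tempfile(fileext = ".csv")
  write_responses_csv(resp, path)
  ok <- ingest_responses(path, form)
  expect_identical(nrow(ok), nrow(resp))

  bad <- as.data.frame(resp)[, c("expert_id", "role", "experience_band",
                                 "rule_id", "response")]
  bad$response[3] <- 6L
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(ingest_responses(path, form), "out of range")

  bad$response[3] <- 2L
  bad$rule_id[5] <- "r999"
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(ingest_responses(path, form), "r999")

  # exact duplicate rows collapse; conflicting duplicates are an error
  good <- as.data.frame(resp)[, c("expert_id", "role", "experience_band",
                                  "rule_id", "response")]
  utils::write.csv(rbind(good, good[1, ]), path, row.names = FALSE)
  expect_identical(nrow(ingest_responses(path, form)), nrow(resp))
  conflict <- good[1, ]; conflict$response <- (conflict$response %% 5) + 1L
  utils::write.csv(rbind(good, conflict), path, row.names = FALSE)
  expect_error(ingest_responses(path, form), "conflicting")
})

test_that("aggregation uses the sample SD and carries full precision", {
  resp <- tibble::tibble(
    expert_id = sprintf("e%d", 1:4), role = "attending",
    experience_band = ">10", rule_id = "r1", response = c(1L, 2L, 2L, 3L))
  agg <- aggregate_responses(resp)
  expect_equal(agg$expert_mean, 2.0)
  expect_equal(agg$expert_sd, sd(c(1, 2, 2, 3)))
  expect_equal(round(agg$expert_sd, 4), 0.8165)
  # n-denominator option
  agg_n <- aggregate_responses(resp, sd_n = TRUE)
  expect_equal(agg_n$expert_sd, sd(c(1, 2, 2, 3)) * sqrt(3 / 4))
  # unanimous panel
  resp$response <- 3L
  agg3 <- aggregate_responses(resp)
  expect_identical(c(agg3$expert_mean, agg3$expert_sd), c(3, 0))
  # a fractional mean like 1.75 is representable exactly
  resp$response <- c(1L, 2L, 2L, 2L)
  expect_equal(aggregate_responses(resp)$expert_mean, 1.75)
})

test_that("filtering that keeps the whole panel changes nothing, and empty filters fail", {
  st <- small_study()
  resp <- simulate_expert_panel(st$model$selected_rules, st$cohort,
                                expert_panel_config(seed = 3))
  full <- aggregate_responses(resp)
  same <- aggregate_responses(resp, roles = unique(resp$role))
  expect_equal(full, same)
  attending <- aggregate_responses(resp, roles = "attending")
  expect_true(all(attending$n_responses == 12L))
  expect_error(aggregate_responses(resp, roles = "chaplain"),
               "no responses after filtering")
})

test_that("render -> complete -> ingest -> aggregate reproduces the panel exactly", {
  st <- small_study()
  form <- render_survey(st$model, train = st$train, seed = 6)
  resp <- simulate_expert_panel(st$model$selected_rules, st$cohort,
                                expert_panel_config(seed = 7))
  path <- tempfile(fileext = ".csv")
  write_responses_csv(resp, path)
  round_trip <- aggregate_responses(ingest_responses(path, form))
  direct <- aggregate_responses(resp)
  rt <- round_trip[match(direct$rule_id, round_trip$rule_id), ]
  expect_equal(rt$expert_mean, direct$expert_mean)
  expect_equal(rt$expert_sd, direct$expert_sd)
})
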