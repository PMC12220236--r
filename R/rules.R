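#' Atomic rule condition
#'
#' A single condition on one feature. Numeric conditions are closed-left
#' (`numeric_le` is `x <= threshold`, `numeric_gt` is `x > threshold`);
#' categorical conditions hold when the record's level is in `levels`.
#'
#' @param feature Feature (column) name the condition tests.
#' @param kind One of `"numeric_le"`, `"numeric_gt"`, `"categorical_in"`.
#' @param threshold Finite numeric threshold (numeric kinds only).
#' @param levels Non-empty character vector of levels (`categorical_in` only).
#' @return An object of class `rule_condition`.
#' @export
rule_condition <- function(feature, kind, threshold = NULL, levels = NULL) {
  kind <- match.arg(kind, c("numeric_le", "numeric_gt", "categorical_in"))
  stopifnot(is.character(feature), length(feature) == 1L, nzchar(feature))
  if (kind == "categorical_in") {
    if (is.null(levels) || length(levels) == 0L) {
      stop("categorical_in condition requires a non-empty level set", call. = FALSE)
    }
    levels <- unique(as.character(levels))
    threshold <- NULL
  } else {
    if (is.null(threshold) || !is.finite(threshold)) {
      stop("numeric condition requires a finite threshold", call. = FALSE)
    }
    threshold <- as.numeric(threshold)
    levels <- NULL
  }
  structure(list(feature = feature, kind = kind, threshold = threshold,
                 levels = levels),
            class = "rule_condition")
}

#' Conjunctive decision rule
#'
#' A rule is a conjunction of [rule_condition()]s defining a subgroup of
#' records; it takes the value 1 for a record when every condition holds.
#' An empty condition list is the trivially-true rule.
#'
#' @param rule_id Stable identifier string.
#' @param conditions List of [rule_condition()] objects (deduplicated).
#' @param support_train Optional training support (proportion firing).
#' @return An object of class `eaml_rule`.
#' @export
new_rule <- function(rule_id, conditions = list(), support_train = NA_real_) {
  stopifnot(is.character(rule_id), length(rule_id) == 1L)
  conditions <- unique(conditions)
  ok <- vapply(conditions, inherits, logical(1), "rule_condition")
  if (!all(ok)) stop("all conditions must be rule_condition objects", call. = FALSE)
  structure(list(rule_id = rule_id, conditions = conditions,
                 support_train = support_train),
            class = "eaml_rule")
}

rule_ids <- function(rules) vapply(rules, function(r) r$rule_id, character(1))

rule_features <- function(rule) {
  unique(vapply(rule$conditions, function(cn) cn$feature, character(1)))
}

#' @method format rule_condition
#' @export
format.rule_condition <- function(x, digits = 6, ...) {
  switch(x$kind,
    numeric_le = sprintf("%s <= %s", x$feature, format(x$threshold, digits = digits)),
    numeric_gt = sprintf("%s > %s", x$feature, format(x$threshold, digits = digits)),
    categorical_in = sprintf("%s in {%s}", x$feature, paste(x$levels, collapse = ", ")))
}

#' @method print rule_condition
#' @export
print.rule_condition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Render a rule as a human-readable conjunction
#'
#' @param rule An [new_rule()] object.
#' @param digits Display precision for thresholds.
#' @return A single string such as `"age <= 10 & rr <= 30"`.
#' @export
render_rule <- function(rule, digits = 6) {
  if (length(rule$conditions) == 0L) return("(always)")
  paste(vapply(rule$conditions, format, character(1), digits = digits),
        collapse = " & ")
}

#' @method print eaml_rule
#' @export
print.eaml_rule <- function(x, ...) {
  cat(sprintf("<rule %s> %s\n", x$rule_id, render_rule(x)))
  invisible(x)
}

# Vectorized evaluation of one condition over a data frame; errors on a
# missing referenced feature (never a silent 0).
condition_holds <- function(cond, table) {
  if (!cond$feature %in% names(table)) {
    stop(sprintf("feature '%s' referenced by a rule is absent from the data",
                 cond$feature), call. = FALSE)
  }
  x <- table[[cond$feature]]
  switch(cond$kind,
    numeric_le = as.numeric(x) <= cond$threshold,
    numeric_gt = as.numeric(x) > cond$threshold,
    categorical_in = as.character(x) %in% cond$levels)
}

#' Does a rule fire for each record?
#'
#' Vectorized evaluation: returns the rule's 0/1 activation over every row of
#' `table`. The empty conjunction fires for every record.
#'
#' @param rule An [new_rule()] object.
#' @param table Data frame of records carrying every feature the rule
#'   references (a missing feature is an error).
#' @return Integer vector of 0/1, one per row.
#' @export
rule_fires <- function(rule, table) {
  out <- rep(TRUE, nrow(table))
  for (cond in rule$conditions) out <- out & condition_holds(cond, table)
  as.integer(out)
}

#' Evaluate a rule for a single record
#'
#' @param rule An [new_rule()] object.
#' @param record A one-row data frame (or list coercible to one).
#' @return 1 if every condition holds, else 0.
#' @export
evaluate_rule <- function(rule, record) {
  if (!is.data.frame(record)) record <- as.data.frame(record, stringsAsFactors = FALSE)
  if (nrow(record) != 1L) stop("evaluate_rule expects a single record", call. = FALSE)
  rule_fires(rule, record)
}

#' Boolean rule-activation matrix
#'
#' Entry (i, j) is 1 iff rule j fires for record i; column means are the
#' rules' supports in `table`.
#'
#' @param rules Non-empty list of [new_rule()] objects.
#' @param table Data frame of records.
#' @return Integer 0/1 matrix with rownames from `table` rows and colnames
#'   the rule ids.
#' @export
build_rule_matrix <- function(rules, table) {
  if (length(rules) == 0L) stop("rules must be non-empty", call. = FALSE)
  cols <- lapply(seq_along(rules), function(j) {
    tryCatch(rule_fires(rules[[j]], table), error = function(e) {
      stop(sprintf("rule '%s' (column %d): %s",
                   rules[[j]]$rule_id, j, conditionMessage(e)), call. = FALSE)
    })
  })
  m <- do.call(cbind, cols)
  colnames(m) <- rule_ids(rules)
  rownames(m) <- rownames(table)
  storage.mode(m) <- "integer"
  m
}

# Canonical signature used to deduplicate rules: sorted rendered conditions
# at full precision.
rule_signature <- function(rule) {
  if (length(rule$conditions) == 0L) return("(always)")
  paste(sort(vapply(rule$conditions, format, character(1), digits = 17)),
        collapse = " & ")
}
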