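#' Validation rules for pre-import screening
#'
#' The EDC screens imports for incorrectly formatted values and numbers
#' beyond pre-defined bounds before committing them; `validate_flat()`
#' mirrors that screening locally so problems surface before an import is
#' attempted. A rule binds a field to a kind (`numeric`, `integer`, `text`,
#' `date_string`), optional inclusive bounds (numeric/integer only), and a
#' required flag.
#'
#' Numeric parsing accepts a decimal point only (`-?digits[.digits]`); comma
#' decimals or scientific notation count as incorrectly formatted.
#' `date_string` accepts the compact digit tokens instruments emit (YYMMDD
#' or YYYYMMDD) or ISO `YYYY-MM-DD`; no calendar arithmetic is done.
#'
#' @param field Field column name the rule applies to.
#' @param kind One of `"numeric"`, `"integer"`, `"text"`, `"date_string"`.
#' @param min,max Optional inclusive bounds; only allowed for numeric and
#'   integer kinds, and `min <= max` when both are given.
#' @param required If `TRUE`, an empty cell in this field is an issue.
#' @return An object of class `validation_rule`.
#' @export
validation_rule <- function(field, kind = c("numeric", "integer", "text", "date_string"),
                            min = NULL, max = NULL, required = FALSE) {
  kind <- match.arg(kind)
  if (!is.null(min) || !is.null(max)) {
    if (!kind %in% c("numeric", "integer")) {
      stop_eavflat("config_schema_error",
                   sprintf("bounds are only allowed for numeric/integer rules (field '%s')", field))
    }
    if (!is.null(min) && !is.null(max) && min > max) {
      stop_eavflat("config_schema_error",
                   sprintf("rule for '%s' has min > max", field))
    }
  }
  structure(list(field = as.character(field), kind = kind,
                 min = if (is.null(min)) NULL else as.numeric(min),
                 max = if (is.null(max)) NULL else as.numeric(max),
                 required = isTRUE(required)),
            class = "validation_rule")
}

#' Load validation rules from a YAML file or config section
#'
#' Rules live either in their own YAML file (a top-level `rules:` sequence
#' or a bare sequence) or inside the mapping-config file's `rules:` section.
#' Each entry has keys `field`, `kind`, and optionally `min`, `max`,
#' `required`.
#'
#' @param source Path to a YAML file.
#' @return A list of [validation_rule()] objects.
#' @export
load_rules <- function(source) {
  raw <- tryCatch(yaml::read_yaml(source),
                  error = function(e) stop_eavflat("config_schema_error",
                    paste0("cannot parse rules: ", conditionMessage(e))))
  if (is.list(raw) && !is.null(raw$rules)) raw <- raw$rules
  if (is.null(raw)) return(list())
  lapply(raw, function(r) {
    unknown <- setdiff(names(r), c("field", "kind", "min", "max", "required"))
    if (length(unknown) > 0L || is.null(r$field) || is.null(r$kind)) {
      stop_eavflat("config_schema_error",
                   "each rule needs 'field' and 'kind' and nothing beyond min/max/required")
    }
    validation_rule(r$field, r$kind, min = r$min, max = r$max,
                    required = isTRUE(r$required))
  })
}

num_re <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)$"
int_re <- "^[+-]?[0-9]+$"
date_re <- "^([0-9]{6}|[0-9]{8}|[0-9]{4}-[0-9]{2}-[0-9]{2})$"

check_cell <- function(value, rule) {
  # returns character vector of issue messages for one non-empty cell
  msgs <- character(0)
  if (rule$kind == "numeric" || rule$kind == "integer") {
    re <- if (rule$kind == "integer") int_re else num_re
    if (!grepl(re, value)) {
      return(sprintf("value '%s' is not a well-formed %s", value, rule$kind))
    }
    x <- as.numeric(value)
    if (!is.null(rule$min) && x < rule$min) {
      msgs <- c(msgs, sprintf("value %s below minimum %s", value, rule$min))
    }
    if (!is.null(rule$max) && x > rule$max) {
      msgs <- c(msgs, sprintf("value %s above maximum %s", value, rule$max))
    }
  } else if (rule$kind == "date_string") {
    if (!grepl(date_re, value)) {
      msgs <- sprintf("value '%s' is not a recognised date token", value)
    }
  }
  msgs
}

#' Screen a flat table against validation rules
#'
#' Checks every cell governed by a rule: non-empty cells are checked for
#' parseability per the rule's kind and (numeric/integer) inclusive bounds;
#' empty cells in `required` fields are flagged. The table is never
#' modified; screening is advisory — the caller (or the CLI `--strict`
#' switch) decides whether issues abort the run.
#'
#' @param table A [flat_table()].
#' @param rules List of [validation_rule()] objects; every rule's field must
#'   exist among the table's field columns.
#' @return A `validation_report`: list with `issues` (data frame with
#'   columns entity, event, field, kind, message), `n_checked` (screened
#'   cells: non-empty ruled cells plus empty required cells) and
#'   `n_rejected` (cells with at least one issue).
#' @export
validate_flat <- function(table, rules) {
  stopifnot(inherits(table, "flat_table"))
  if (inherits(rules, "validation_rule")) rules <- list(rules)
  fc <- field_columns(table)
  for (r in rules) {
    if (!r$field %in% fc) {
      stop_eavflat("unknown_field_error",
                   sprintf("rule references field '%s' absent from the table", r$field))
    }
  }
  issues <- list()
  n_checked <- 0L
  rejected <- character(0)
  for (r in rules) {
    col <- table[[r$field]]
    for (i in seq_along(col)) {
      v <- col[[i]]
      cell_id <- paste(i, r$field, sep = "\r")
      if (!nzchar(v)) {
        if (r$required) {
          n_checked <- n_checked + 1L
          issues[[length(issues) + 1L]] <- data.frame(
            entity = table[[1L]][[i]], event = table[[2L]][[i]],
            field = r$field, kind = r$kind,
            message = "required value is missing",
            stringsAsFactors = FALSE)
          rejected <- c(rejected, cell_id)
        }
        next
      }
      n_checked <- n_checked + 1L
      msgs <- check_cell(v, r)
      if (length(msgs) > 0L) {
        issues[[length(issues) + 1L]] <- data.frame(
          entity = table[[1L]][[i]], event = table[[2L]][[i]],
          field = r$field, kind = r$kind, message = msgs,
          stringsAsFactors = FALSE)
        rejected <- c(rejected, cell_id)
      }
    }
  }
  issues <- if (length(issues) == 0L) {
    data.frame(entity = character(0), event = character(0),
               field = character(0), kind = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
  structure(list(issues = issues,
                 n_checked = n_checked,
                 n_rejected = length(unique(rejected))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d cell(s) screened, %d rejected, %d issue(s)\n",
              x$n_checked, x$n_rejected, nrow(x$issues)))
  if (nrow(x$issues) > 0L) print.data.frame(utils::head(x$issues, 20L))
  invisible(x)
}

#' Write a validation report as CSV
#' @param report A `validation_report`.
#' @param sink Path or writable connection.
#' @return `sink`, invisibly.
#' @export
write_report <- function(report, sink) {
  stopifnot(inherits(report, "validation_report"))
  write_csv_lf(report$issues, sink)
  invisible(sink)
}
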