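#' Declarative mapping configuration
#'
#' A `mapping_config` binds the columns of an instrument EAV export to their
#' roles (entity, event, date, attribute, value), maps instrument attribute
#' names to EDC field names, optionally renames event tokens, and fixes the
#' policies applied when translation meets an unmapped attribute, a missing
#' template row, or a duplicate measurement.
#'
#' Attribute matching is case-sensitive and exact: silent case-folding could
#' merge distinct assays, so a mismatch surfaces as an unmapped attribute
#' instead. `event_map` defaults to the identity (instrument event tokens
#' equal EDC event names).
#'
#' @param study_id Label for the root of the hierarchical intermediate.
#' @param entity_column Name of the participant-id column in the EAV file.
#' @param event_columns Character vector of event columns in priority order;
#'   the first non-empty cell on a row becomes that row's event id. A file
#'   with a single combined event column binds just that one.
#' @param attribute_column,value_column Names of the attribute and value
#'   columns.
#' @param date_column Optional name of the date column; dates are carried as
#'   opaque strings and never parsed.
#' @param attribute_map Named character vector: names are instrument
#'   attribute identifiers, values are EDC field names. Targets must be
#'   unique (no many-to-one merging).
#' @param event_map Optional named character vector renaming instrument event
#'   tokens to EDC event names; tokens absent from it pass through unchanged.
#' @param unmapped_attribute_policy `"error"` or `"skip_with_warning"`.
#' @param missing_row_policy `"error"` or `"append"`.
#' @param duplicate_policy `"error"` or `"last_wins"`.
#' @return An object of class `mapping_config`.
#' @seealso [load_config()], [map_attribute()]
#' @examples
#' cfg <- mapping_config(
#'   study_id = "copd_study",
#'   entity_column = "pat_id",
#'   event_columns = c("visit_id", "exacerbation_id"),
#'   date_column = "Date",
#'   attribute_column = "Attribute",
#'   value_column = "Value",
#'   attribute_map = c(calcium = "Ncal", leukocytes = "leuco")
#' )
#' map_attribute(cfg, "calcium")
#' @export
mapping_config <- function(study_id,
                           entity_column,
                           event_columns,
                           attribute_column,
                           value_column,
                           date_column = NULL,
                           attribute_map = character(0),
                           event_map = character(0),
                           unmapped_attribute_policy = c("error", "skip_with_warning"),
                           missing_row_policy = c("error", "append"),
                           duplicate_policy = c("error", "last_wins")) {
  unmapped_attribute_policy <- match.arg(unmapped_attribute_policy)
  missing_row_policy <- match.arg(missing_row_policy)
  duplicate_policy <- match.arg(duplicate_policy)
  cfg <- structure(
    list(
      schema_version = 1L,
      study_id = as.character(study_id),
      entity_column = as.character(entity_column),
      event_columns = as.character(event_columns),
      date_column = if (is.null(date_column) || !nzchar(date_column)) NULL else as.character(date_column),
      attribute_column = as.character(attribute_column),
      value_column = as.character(value_column),
      attribute_map = as_named_chr(attribute_map),
      event_map = as_named_chr(event_map),
      unmapped_attribute_policy = unmapped_attribute_policy,
      missing_row_policy = missing_row_policy,
      duplicate_policy = duplicate_policy
    ),
    class = "mapping_config"
  )
  validate_mapping_config(cfg)
}

as_named_chr <- function(x) {
  if (is.null(x) || length(x) == 0L) return(structure(character(0), names = character(0)))
  if (is.list(x)) x <- unlist(x)
  storage.mode(x) <- "character"
  x
}

validate_mapping_config <- function(cfg) {
  if (length(cfg$event_columns) == 0L) {
    stop_eavflat("config_consistency_error", "event_columns must be non-empty")
  }
  core <- c(cfg$entity_column, cfg$attribute_column, cfg$value_column)
  if (anyDuplicated(core)) {
    stop_eavflat("config_consistency_error",
                 "entity, attribute and value columns must be distinct names")
  }
  amap <- cfg$attribute_map
  if (length(amap) > 0L) {
    if (is.null(names(amap)) || any(!nzchar(names(amap)))) {
      stop_eavflat("config_consistency_error", "attribute_map entries must be named")
    }
    if (anyDuplicated(names(amap))) {
      stop_eavflat("config_consistency_error",
                   sprintf("duplicate attribute in attribute_map: %s",
                           paste(unique(names(amap)[duplicated(names(amap))]), collapse = ", ")))
    }
    if (anyDuplicated(amap)) {
      stop_eavflat("config_consistency_error",
                   sprintf("two attributes map to the same field: %s",
                           paste(unique(amap[duplicated(amap)]), collapse = ", ")))
    }
  }
  cfg
}

config_keys <- c("schema_version", "study_id", "entity_column", "event_columns",
                 "date_column", "attribute_column", "value_column",
                 "attribute_map", "event_map", "unmapped_attribute_policy",
                 "missing_row_policy", "duplicate_policy")
required_config_keys <- c("study_id", "entity_column", "event_columns",
                          "attribute_column", "value_column")

#' Load a mapping configuration from a YAML file
#'
#' The file schema is versioned (`schema_version: 1`) and its keys match the
#' arguments of [mapping_config()] exactly; unknown keys are rejected so that
#' typos do not silently change behaviour. An optional `rules:` section (see
#' [load_rules()]) is permitted and ignored here.
#'
#' @param source Path to a YAML configuration file.
#' @return A validated `mapping_config`.
#' @export
load_config <- function(source) {
  raw <- tryCatch(yaml::read_yaml(source),
                  error = function(e) stop_eavflat("config_schema_error",
                    paste0("cannot parse config: ", conditionMessage(e))))
  if (!is.list(raw)) {
    stop_eavflat("config_schema_error", "config file must contain a YAML mapping")
  }
  raw$rules <- NULL
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown) > 0L) {
    stop_eavflat("config_schema_error",
                 sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(required_config_keys, names(raw))
  if (length(missing) > 0L) {
    stop_eavflat("config_schema_error",
                 sprintf("missing required config key(s): %s", paste(missing, collapse = ", ")))
  }
  if (!is.null(raw$schema_version) && as.integer(raw$schema_version) != 1L) {
    stop_eavflat("config_schema_error",
                 sprintf("unsupported schema_version %s (this build reads version 1)",
                         raw$schema_version))
  }
  mapping_config(
    study_id = raw$study_id,
    entity_column = raw$entity_column,
    event_columns = unlist(raw$event_columns),
    date_column = raw$date_column,
    attribute_column = raw$attribute_column,
    value_column = raw$value_column,
    attribute_map = as_named_chr(raw$attribute_map),
    event_map = as_named_chr(raw$event_map),
    unmapped_attribute_policy = raw$unmapped_attribute_policy %||% "error",
    missing_row_policy = raw$missing_row_policy %||% "error",
    duplicate_policy = raw$duplicate_policy %||% "error"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a mapping configuration to a YAML file
#'
#' `load_config(write_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config A `mapping_config`.
#' @param sink Path to write.
#' @return `sink`, invisibly.
#' @export
write_config <- function(config, sink) {
  stopifnot(inherits(config, "mapping_config"))
  out <- config[config_keys]
  names(out) <- config_keys
  out <- Filter(Negate(is.null), out)
  out$attribute_map <- as.list(out$attribute_map)
  out$event_map <- as.list(out$event_map)
  yaml::write_yaml(out, sink)
  invisible(sink)
}

#' Map an instrument attribute to its EDC field name
#'
#' Pure, case-sensitive exact lookup in the config's `attribute_map`.
#'
#' @param config A `mapping_config`.
#' @param attribute Instrument attribute identifier.
#' @return The mapped field name, or `NA_character_` when the attribute is
#'   unmapped and the policy is `"skip_with_warning"`.
#' @export
map_attribute <- function(config, attribute) {
  stopifnot(inherits(config, "mapping_config"))
  hit <- match(attribute, names(config$attribute_map))
  if (is.na(hit)) {
    if (config$unmapped_attribute_policy == "error") {
      stop_eavflat("unmapped_attribute_error",
                   sprintf("attribute '%s' has no mapping", attribute))
    }
    return(NA_character_)
  }
  unname(config$attribute_map[[hit]])
}

map_event <- function(config, event) {
  hit <- match(event, names(config$event_map))
  if (is.na(hit)) event else unname(config$event_map[[hit]])
}

#' @export
print.mapping_config <- function(x, ...) {
  cat("<mapping_config> study:", x$study_id, "\n")
  cat("  entity:", x$entity_column,
      "| events:", paste(x$event_columns, collapse = " > "),
      "| attribute:", x$attribute_column,
      "| value:", x$value_column, "\n")
  if (!is.null(x$date_column)) cat("  date column:", x$date_column, "\n")
  if (length(x$attribute_map)) {
    cat("  attribute map:",
        paste(sprintf("%s→%s", names(x$attribute_map), x$attribute_map),
              collapse = ", "), "\n")
  }
  cat("  policies: unmapped =", x$unmapped_attribute_policy,
      "| missing row =", x$missing_row_policy,
      "| duplicate =", x$duplicate_policy, "\n")
  invisible(x)
}
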