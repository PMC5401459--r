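#' Build the five-level hierarchical intermediate from EAV records
#'
#' The translation runs in two stages: EAV rows are first organised into a
#' hierarchy whose five levels are, top to bottom, the study id, the study
#' participants, their events (scheduled visits and exacerbations share one
#' level, distinguished only by event token), the biomarkers, and the value
#' each biomarker holds. The second stage ([flatten()]) writes that tree
#' into a flat-table template.
#'
#' Insertion order is the order of first appearance in the EAV table, so
#' traversal — and every downstream output — is deterministic. A duplicate
#' (entity, event, attribute) with an equal value is silently deduplicated
#' (and counted in the tree's `n_deduplicated` attribute); with differing
#' values the config's `duplicate_policy` decides: `"error"` raises
#' `eavflat_duplicate_measurement_error`, `"last_wins"` keeps the later
#' value in the original position.
#'
#' @param table An [eav_table()] read with the same config.
#' @param config A [mapping_config()].
#' @return A `hierarchy_tree`: nested named lists
#'   `$participants[[entity]]$events[[event]]$biomarkers[[attribute]]`, each
#'   biomarker holding `value` and `date`; plus `$study_id`.
#' @export
build_hierarchy <- function(table, config) {
  stopifnot(inherits(table, "eav_table"), inherits(config, "mapping_config"))
  participants <- list()
  n_dedup <- 0L
  for (i in seq_len(nrow(table))) {
    e <- table$entity_id[[i]]; v <- table$event_id[[i]]
    a <- table$attribute[[i]]; x <- table$value[[i]]; d <- table$date[[i]]
    if (is.null(participants[[e]])) participants[[e]] <- list(events = list())
    if (is.null(participants[[e]]$events[[v]])) {
      participants[[e]]$events[[v]] <- list(biomarkers = list())
    }
    node <- participants[[e]]$events[[v]]$biomarkers[[a]]
    if (!is.null(node)) {
      if (identical(node$value, x)) {
        n_dedup <- n_dedup + 1L
        next
      }
      if (config$duplicate_policy == "error") {
        stop_eavflat("duplicate_measurement_error",
                     sprintf("conflicting duplicate measurement (%s, %s, %s): '%s' vs '%s'",
                             e, v, a, node$value, x))
      }
      # last_wins: replace in place, keep first-appearance position
    }
    participants[[e]]$events[[v]]$biomarkers[[a]] <- list(value = x, date = d)
  }
  if (n_dedup > 0L) {
    message(sprintf("build_hierarchy: deduplicated %d repeated identical measurement(s)", n_dedup))
  }
  structure(list(study_id = config$study_id, participants = participants),
            n_deduplicated = n_dedup,
            class = "hierarchy_tree")
}

#' Depth of a hierarchy tree
#'
#' Counts levels from the study root down to the values: a tree holding at
#' least one measurement has depth 5 (study, participant, event, biomarker,
#' value); a root-only tree has depth 1.
#'
#' @param tree A `hierarchy_tree`.
#' @return Integer depth.
#' @export
hierarchy_depth <- function(tree) {
  stopifnot(inherits(tree, "hierarchy_tree"))
  if (length(tree$participants) == 0L) return(1L)
  d <- 2L
  for (p in tree$participants) {
    if (length(p$events) == 0L) next
    d <- max(d, 3L)
    for (ev in p$events) {
      if (length(ev$biomarkers) == 0L) next
      d <- max(d, 4L)
      for (b in ev$biomarkers) if (!is.null(b$value)) d <- max(d, 5L)
    }
  }
  d
}

#' Leaves of a hierarchy tree in traversal order
#' @param tree A `hierarchy_tree`.
#' @return Data frame with columns entity_id, event_id, attribute, value,
#'   date; one row per leaf, in first-appearance order.
#' @export
hierarchy_leaves <- function(tree) {
  stopifnot(inherits(tree, "hierarchy_tree"))
  rows <- list()
  for (e in names(tree$participants)) {
    evs <- tree$participants[[e]]$events
    for (v in names(evs)) {
      bms <- evs[[v]]$biomarkers
      for (a in names(bms)) {
        rows[[length(rows) + 1L]] <- data.frame(
          entity_id = e, event_id = v, attribute = a,
          value = bms[[a]]$value, date = bms[[a]]$date,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(entity_id = character(0), event_id = character(0),
                      attribute = character(0), value = character(0),
                      date = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @export
print.hierarchy_tree <- function(x, ...) {
  lv <- hierarchy_leaves(x)
  cat(sprintf("<hierarchy_tree> study '%s': %d participant(s), %d leaf value(s), depth %d\n",
              x$study_id, length(x$participants), nrow(lv), hierarchy_depth(x)))
  for (e in utils::head(names(x$participants), 5L)) {
    evs <- x$participants[[e]]$events
    cat(sprintf("  %s: %s\n", e,
                paste(sprintf("%s(%d)", names(evs),
                              vapply(evs, function(v) length(v$biomarkers), 0L)),
                      collapse = ", ")))
  }
  if (length(x$participants) > 5L) {
    cat("  ... and", length(x$participants) - 5L, "more participant(s)\n")
  }
  invisible(x)
}

#' Flatten a hierarchy into a flat-table template
#'
#' For each leaf (entity, event, attribute, value) whose attribute the
#' config maps to a field, the cell at row (entity, mapped event) and that
#' field's column is set to the value. Everything else — header order, row
#' order of pre-existing rows, every untargeted cell — is preserved exactly
#' as in the template; the template object itself is never modified.
#'
#' Unmapped attributes follow `unmapped_attribute_policy` (skipped leaves
#' are reported in one warning). A leaf whose (entity, event) row is absent
#' follows `missing_row_policy`: `"append"` adds rows at the end in
#' first-appearance order, all other cells blank. A target cell that already
#' holds a different value raises `eavflat_cell_conflict_error` — the output
#' is destined for an audited EDC import, so nothing is silently
#' overwritten; an equal pre-existing value is left untouched.
#'
#' @param tree A [build_hierarchy()] result.
#' @param config A [mapping_config()].
#' @param template A [flat_table()] whose field columns include every mapped
#'   target the tree's leaves need.
#' @return A new `flat_table` with the values filled in.
#' @export
flatten <- function(tree, config, template) {
  stopifnot(inherits(tree, "hierarchy_tree"), inherits(config, "mapping_config"),
            inherits(template, "flat_table"))
  leaves <- hierarchy_leaves(tree)
  out <- template
  skipped <- character(0)
  for (i in seq_len(nrow(leaves))) {
    a <- leaves$attribute[[i]]
    f <- map_attribute(config, a)   # errors here under policy "error"
    if (is.na(f)) {
      skipped <- c(skipped, a)
      next
    }
    if (!f %in% field_columns(out)) {
      stop_eavflat("missing_target_column_error",
                   sprintf("mapped target column '%s' (attribute '%s') is absent from the template",
                           f, a))
    }
    e <- leaves$entity_id[[i]]
    v <- map_event(config, leaves$event_id[[i]])
    ri <- row_key_index(out, e, v)
    if (length(ri) == 0L) {
      if (config$missing_row_policy == "error") {
        stop_eavflat("missing_row_error",
                     sprintf("no template row keyed (%s, %s)", e, v))
      }
      new_row <- as.data.frame(as.list(stats::setNames(rep("", ncol(out)), names(out))),
                               stringsAsFactors = FALSE, check.names = FALSE)
      new_row[[1L]] <- e
      new_row[[2L]] <- v
      out <- rbind_flat(out, new_row)
      ri <- nrow(out)
    }
    cur <- out[[f]][[ri]]
    x <- leaves$value[[i]]
    if (nzchar(cur) && !identical(cur, x)) {
      stop_eavflat("cell_conflict_error",
                   sprintf("cell (%s, %s, %s) already holds '%s'; refusing to overwrite with '%s'",
                           e, v, f, cur, x))
    }
    out[[f]][[ri]] <- x
  }
  if (length(skipped) > 0L) {
    warn_eavflat("unmapped_attribute_warning",
                 sprintf("skipped %d leaf value(s) with unmapped attribute(s): %s",
                         length(skipped), paste(unique(skipped), collapse = ", ")))
  }
  out
}

rbind_flat <- function(table, new_row) {
  df <- rbind(as.data.frame(table), as.data.frame(new_row))
  rownames(df) <- NULL
  structure(df,
            id_column_name = attr(table, "id_column_name"),
            event_column_name = attr(table, "event_column_name"),
            class = class(table))
}

#' Translate an instrument EAV export into an EDC import file
#'
#' The single entry point composing [read_eav()], [build_hierarchy()] and
#' [flatten()]: extracts the biomarker values from the instrument CSV,
#' reshapes them, and inserts them into the flat-table template exported
#' from the EDC. Inputs are never modified; the filled table is returned
#' (write it with [write_flat()]). Identical inputs always produce an
#' identical result.
#'
#' @param eav_source Path or connection to the instrument EAV CSV.
#' @param template_source Path, connection, or an already-read
#'   [flat_table()] template.
#' @param config A [mapping_config()].
#' @param strict Passed to [read_eav()].
#' @return The filled `flat_table`.
#' @export
translate <- function(eav_source, template_source, config, strict = TRUE) {
  eav <- if (inherits(eav_source, "eav_table")) eav_source else
    read_eav(eav_source, config, strict = strict)
  template <- if (inherits(template_source, "flat_table")) template_source else
    read_flat(template_source)
  flatten(build_hierarchy(eav, config), config, template)
}

#' Recover EAV records from a filled flat table
#'
#' The inverse transform used for round-trip checking: every non-empty data
#' cell whose column is a mapped target becomes one EAV record, with the
#' attribute recovered through the inverted `attribute_map` (invertible by
#' config invariant) and the event through the inverted `event_map`. Dates
#' are not recoverable from a flat table and come back empty. Cells in
#' columns no attribute maps to are ignored. Records are emitted row-major
#' (template row order, then field-column order).
#'
#' @param table A filled [flat_table()].
#' @param config The [mapping_config()] used to fill it.
#' @return An [eav_table()] with empty dates.
#' @export
unflatten <- function(table, config) {
  stopifnot(inherits(table, "flat_table"), inherits(config, "mapping_config"))
  inv_attr <- stats::setNames(names(config$attribute_map),
                              unname(config$attribute_map))
  inv_event <- stats::setNames(names(config$event_map), unname(config$event_map))
  ent <- character(0); ev <- character(0); att <- character(0); val <- character(0)
  for (i in seq_len(nrow(table))) {
    for (f in field_columns(table)) {
      x <- table[[f]][[i]]
      if (!nzchar(x) || !f %in% names(inv_attr)) next
      ent <- c(ent, table[[1L]][[i]])
      v <- table[[2L]][[i]]
      ev <- c(ev, if (v %in% names(inv_event)) unname(inv_event[[v]]) else v)
      att <- c(att, unname(inv_attr[[f]]))
      val <- c(val, x)
    }
  }
  eav_table(entity_id = ent, event_id = ev, date = rep("", length(ent)),
            attribute = att, value = val,
            source_columns = c(config$entity_column, config$event_columns,
                               config$date_column, config$attribute_column,
                               config$value_column))
}
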