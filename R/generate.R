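#' Specify a synthetic longitudinal biomarker study
#'
#' The generator emulates the structure of a longitudinal COPD biomarker
#' study: every participant attends a fixed schedule of visits, and after
#' each visit interval may additionally experience an exacerbation (an
#' unscheduled acute-worsening event), recorded alongside the visits under
#' its own event token. Each event yields one measurement per biomarker
#' attribute, drawn uniformly from that attribute's plausible range and
#' formatted with at most two decimals, matching instrument output style.
#'
#' The defaults describe a small but realistic study slice: 20 participants,
#' 4 scheduled visits each, a 0.15 per-interval exacerbation probability,
#' and four clinical-chemistry biomarkers with adult reference ranges
#' (calcium mmol/L 2.0–3.0, leukocytes 1e9/L 3.0–10.0, haemoglobin g/L
#' 115–170, monocytes 1e9/L 0.2–1.0).
#'
#' @param n_patients Number of participants (>= 0).
#' @param visits_per_patient Scheduled visits per participant (>= 0).
#' @param exacerbation_rate Probability of an exacerbation in each
#'   inter-visit interval, per participant.
#' @param attributes Data frame with columns `attribute` (instrument name),
#'   `field` (EDC field name), `min`, `max` (numeric range).
#' @param seed Integer; the same spec always generates byte-identical
#'   files.
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(n_patients = 20L,
                       visits_per_patient = 4L,
                       exacerbation_rate = 0.15,
                       attributes = default_attributes(),
                       seed = 20150321L) {
  stopifnot(n_patients >= 0L, visits_per_patient >= 0L,
            exacerbation_rate >= 0, exacerbation_rate <= 1,
            all(c("attribute", "field", "min", "max") %in% names(attributes)),
            all(attributes$min <= attributes$max))
  structure(list(n_patients = as.integer(n_patients),
                 visits_per_patient = as.integer(visits_per_patient),
                 exacerbation_rate = as.numeric(exacerbation_rate),
                 attributes = as.data.frame(attributes, stringsAsFactors = FALSE),
                 seed = as.integer(seed)),
            class = "study_spec")
}

default_attributes <- function() {
  data.frame(
    attribute = c("calcium", "leukocytes", "hemoglobin", "monocytes"),
    field = c("Ncal", "leuco", "hb", "mono"),
    min = c(2.0, 3.0, 115, 0.2),
    max = c(3.0, 10.0, 170, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Generate a coherent synthetic study: EAV file, template, config, rules
#'
#' Produces everything one translation run needs, mutually consistent:
#' an [eav_table()] with one row per (participant, event, attribute) in the
#' instrument dialect (visit tokens in a `visit_id` column, exacerbation
#' tokens in an `exacerbation_id` column, one of the two blank per row); a
#' blank flat-table template holding exactly the (participant, event) rows
#' of the schedule; a [mapping_config()] mapping every attribute; one
#' numeric bounds [validation_rule()] per attribute; and a `ledger` — the
#' ground-truth tuple set (entity, event, attribute, field, value) — for
#' oracle tests. Fully reproducible from `spec$seed`; the generator
#' restores the caller's RNG state.
#'
#' @param spec A [study_spec()].
#' @return List with elements `eav`, `template`, `config`, `rules`,
#'   `ledger`.
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  patients <- if (spec$n_patients > 0L)
    sprintf("%06d", 100000L + seq_len(spec$n_patients)) else character(0)
  base_date <- as.Date("2015-03-21")
  sched <- list()
  for (p in patients) {
    n_ex <- 0L
    day <- 0L
    for (k in seq_len(spec$visits_per_patient)) {
      sched[[length(sched) + 1L]] <- list(p = p, ev = paste0("visit_", k),
                                          kind = "visit", day = day)
      if (stats::runif(1) < spec$exacerbation_rate) {
        n_ex <- n_ex + 1L
        sched[[length(sched) + 1L]] <- list(
          p = p, ev = paste0("exacerbation_", n_ex), kind = "exacerbation",
          day = day + sample(30:150, 1L))
      }
      day <- day + 182L
    }
  }
  A <- nrow(spec$attributes)
  n_ev <- length(sched)
  rows <- vector("list", n_ev * A)
  r <- 0L
  for (s in sched) {
    date_tok <- format(base_date + s$day, "%y%m%d")
    for (j in seq_len(A)) {
      x <- stats::runif(1, spec$attributes$min[[j]], spec$attributes$max[[j]])
      r <- r + 1L
      rows[[r]] <- data.frame(
        pat_id = s$p,
        visit_id = if (s$kind == "visit") s$ev else "",
        exacerbation_id = if (s$kind == "exacerbation") s$ev else "",
        Date = date_tok,
        Attribute = spec$attributes$attribute[[j]],
        Value = as.character(round(x, 2L)),
        stringsAsFactors = FALSE)
    }
  }
  eav_df <- if (r == 0L) {
    data.frame(pat_id = character(0), visit_id = character(0),
               exacerbation_id = character(0), Date = character(0),
               Attribute = character(0), Value = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  config <- mapping_config(
    study_id = "synthetic_study",
    entity_column = "pat_id",
    event_columns = c("visit_id", "exacerbation_id"),
    date_column = "Date",
    attribute_column = "Attribute",
    value_column = "Value",
    attribute_map = stats::setNames(spec$attributes$field, spec$attributes$attribute),
    unmapped_attribute_policy = "error",
    missing_row_policy = "error",
    duplicate_policy = "error"
  )
  eav <- eav_table(
    entity_id = eav_df$pat_id,
    event_id = ifelse(nzchar(eav_df$visit_id), eav_df$visit_id, eav_df$exacerbation_id),
    date = eav_df$Date,
    attribute = eav_df$Attribute,
    value = eav_df$Value,
    source_columns = names(eav_df)
  )
  tmpl_fields <- as.data.frame(
    matrix("", nrow = n_ev, ncol = A,
           dimnames = list(NULL, spec$attributes$field)),
    stringsAsFactors = FALSE, check.names = FALSE)
  template <- flat_table(
    ids = vapply(sched, `[[`, character(1), "p"),
    events = vapply(sched, `[[`, character(1), "ev"),
    fields = tmpl_fields
  )
  rules <- lapply(seq_len(A), function(j) {
    validation_rule(spec$attributes$field[[j]], "numeric",
                    min = spec$attributes$min[[j]],
                    max = spec$attributes$max[[j]])
  })
  ledger <- if (r == 0L) {
    data.frame(entity_id = character(0), event_id = character(0),
               attribute = character(0), field = character(0),
               value = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(entity_id = eav$entity_id, event_id = eav$event_id,
               attribute = eav$attribute,
               field = unname(config$attribute_map[eav$attribute]),
               value = eav$value, stringsAsFactors = FALSE)
  }
  list(eav = eav, template = template, config = config, rules = rules,
       ledger = ledger)
}

#' Write a generated study to disk
#'
#' Writes `eav.csv`, `template.csv`, `config.yaml` (with an embedded
#' `rules:` section) and `ledger.csv` into a directory. Byte-identical
#' across runs with the same spec.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_eav(study$eav, file.path(dir, "eav.csv"), study$config)
  write_flat(study$template, file.path(dir, "template.csv"))
  write_config(study$config, file.path(dir, "config.yaml"))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$rules <- lapply(study$rules, function(r) {
    out <- list(field = r$field, kind = r$kind)
    if (!is.null(r$min)) out$min <- r$min
    if (!is.null(r$max)) out$max <- r$max
    if (r$required) out$required <- TRUE
    out
  })
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  write_csv_lf(study$ledger, file.path(dir, "ledger.csv"))
  invisible(dir)
}

#' The worked two-participant example study
#'
#' Returns, built in code, the canonical desk-scale example this package's
#' documentation and tests use throughout: an 8-record instrument EAV table
#' (participants 100001 and 100002; events visit_1, visit_2 and
#' exacerbation_1; attributes calcium and leukocytes), the matching blank
#' 4-row EDC template with field columns Ncal, leuco, hb and mono, and the
#' config mapping calcium to Ncal and leukocytes to leuco. Deterministic:
#' every call returns identical objects. The same files ship under
#' `inst/extdata/` for CLI use.
#'
#' @return List with elements `eav`, `template`, `config`.
#' @examples
#' ex <- example_study()
#' filled <- translate(ex$eav, ex$template, ex$config)
#' filled
#' @export
example_study <- function() {
  eav <- eav_table(
    entity_id = c("100001", "100001", "100002", "100002",
                  "100001", "100001", "100002", "100002"),
    event_id = c("visit_1", "visit_1", "visit_1", "visit_1",
                 "visit_2", "visit_2", "exacerbation_1", "exacerbation_1"),
    date = c("150321", "150321", "150321", "150321",
             "150917", "150917", "150613", "150613"),
    attribute = c("calcium", "leukocytes", "calcium", "leukocytes",
                  "calcium", "leukocytes", "calcium", "leukocytes"),
    value = c("6.2", "6.5", "2.45", "6.5", "2.51", "6.2", "2.44", "8.1"),
    source_columns = c("pat_id", "visit_id", "exacerbation_id",
                       "Date", "Attribute", "Value")
  )
  template <- flat_table(
    ids = c("100001", "100002", "100001", "100002"),
    events = c("visit_1", "visit_1", "visit_2", "exacerbation_1"),
    fields = data.frame(Ncal = character(4), leuco = character(4),
                        hb = character(4), mono = character(4),
                        stringsAsFactors = FALSE)
  )
  config <- mapping_config(
    study_id = "copd_biomarker_study",
    entity_column = "pat_id",
    event_columns = c("visit_id", "exacerbation_id"),
    date_column = "Date",
    attribute_column = "Attribute",
    value_column = "Value",
    attribute_map = c(calcium = "Ncal", leukocytes = "leuco"),
    unmapped_attribute_policy = "skip_with_warning"
  )
  list(eav = eav, template = template, config = config)
}
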