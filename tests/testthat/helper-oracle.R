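# Brute-force nested-map oracle: fills the template by direct lookup from the
# raw EAV rows, bypassing the hierarchy entirely. Independent of flatten().
oracle_fill <- function(eav, config, template) {
  out <- as.data.frame(template)
  for (i in seq_len(nrow(eav))) {
    a <- eav$attribute[[i]]
    hit <- match(a, names(config$attribute_map))
    if (is.na(hit)) next
    f <- unname(config$attribute_map[[hit]])
    ev <- eav$event_id[[i]]
    eh <- match(ev, names(config$event_map))
    if (!is.na(eh)) ev <- unname(config$event_map[[eh]])
    ri <- which(out[[1L]] == eav$entity_id[[i]] & out[[2L]] == ev)
    if (length(ri) == 0L) {
      nr <- as.data.frame(as.list(stats::setNames(rep("", ncol(out)), names(out))),
                          check.names = FALSE)
      nr[[1L]] <- eav$entity_id[[i]]; nr[[2L]] <- ev
      out <- rbind(out, nr); rownames(out) <- NULL
      ri <- nrow(out)
    }
    out[[f]][[ri]] <- eav$value[[i]]
  }
  out
}

# Random study specs for property-style tests; sizes kept small so a suite
# iteration of a few hundred studies stays well under a minute.
random_spec <- function(seed) {
  set.seed(seed)
  pool <- data.frame(
    attribute = c("calcium", "leukocytes", "hemoglobin", "monocytes", "crp", "albumin"),
    field = c("Ncal", "leuco", "hb", "mono", "crp", "alb"),
    min = c(2, 3, 115, 0.2, 0, 34),
    max = c(3, 10, 170, 1.0, 10, 45),
    stringsAsFactors = FALSE
  )
  study_spec(
    n_patients = sample(1:6, 1L),
    visits_per_patient = sample(1:4, 1L),
    exacerbation_rate = runif(1, 0, 0.4),
    attributes = pool[sort(sample(nrow(pool), sample(1:5, 1L))), , drop = FALSE],
    seed = sample.int(1e6, 1L)
  )
}

# Overwrite k cells of a filled flat table with out-of-bounds numbers; the
# rules generated alongside the study bound every field, so each planted
# cell is exactly one violation. Returns the table and the planted positions.
plant_violations <- function(filled, spec, k, seed) {
  set.seed(seed)
  fields <- spec$attributes$field
  cells <- expand.grid(row = seq_len(nrow(filled)), field = fields,
                       stringsAsFactors = FALSE)
  k <- min(k, nrow(cells))
  pick <- cells[sample(nrow(cells), k), , drop = FALSE]
  for (j in seq_len(k)) {
    f <- pick$field[[j]]
    mx <- spec$attributes$max[[match(f, spec$attributes$field)]]
    filled[[f]][[pick$row[[j]]]] <- as.character(mx + 1000)
  }
  list(table = filled, planted = pick)
}

expect_same_cells <- function(a, b) {
  expect_identical(dim(a), dim(b))
  expect_identical(names(a), names(b))
  for (cn in names(a)) expect_identical(as.character(a[[cn]]), as.character(b[[cn]]))
}
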