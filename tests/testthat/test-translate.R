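ex <- example_study()

test_that("the worked example builds a five-level hierarchy with the printed fan-out", {
  tree <- build_hierarchy(ex$eav, ex$config)
  expect_s3_class(tree, "hierarchy_tree")
  expect_equal(hierarchy_depth(tree), 5L)
  expect_equal(length(tree$participants), 2L)
  expect_identical(names(tree$participants[["100001"]]$events), c("visit_1", "visit_2"))
  expect_identical(names(tree$participants[["100002"]]$events), c("visit_1", "exacerbation_1"))
  for (p in tree$participants) {
    for (ev in p$events) expect_length(ev$biomarkers, 2L)
  }
  expect_equal(hierarchy_depth(build_hierarchy(eav_table(), ex$config)), 1L)
})

test_that("flatten fills exactly the eight example cells and leaves the rest blank", {
  filled <- translate(ex$eav, ex$template, ex$config)
  cell <- function(e, v, f) filled[[f]][[which(filled[[1]] == e & filled[[2]] == v)]]
  expect_equal(cell("100001", "visit_1", "Ncal"), "6.2")
  expect_equal(cell("100001", "visit_1", "leuco"), "6.5")
  expect_equal(cell("100002", "visit_1", "Ncal"), "2.45")
  expect_equal(cell("100002", "visit_1", "leuco"), "6.5")
  expect_equal(cell("100001", "visit_2", "Ncal"), "2.51")
  expect_equal(cell("100001", "visit_2", "leuco"), "6.2")
  expect_equal(cell("100002", "exacerbation_1", "Ncal"), "2.44")
  expect_equal(cell("100002", "exacerbation_1", "leuco"), "8.1")
  expect_true(all(filled$hb == ""))
  expect_true(all(filled$mono == ""))
  expect_equal(sum(nzchar(as.matrix(as.data.frame(filled)[-(1:2)]))), 8L)
})

test_that("an empty tree returns the template unchanged, byte-identical on write", {
  tree <- build_hierarchy(eav_table(), ex$config)
  out <- flatten(tree, ex$config, ex$template)
  expect_identical(as.data.frame(out), as.data.frame(ex$template))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_flat(ex$template, p1); write_flat(out, p2)
  expect_identical(read_file_bytes(p1), read_file_bytes(p2))
})

test_that("translate is deterministic: two runs give byte-identical files", {
  eav_p <- system.file("extdata", "example_eav.csv", package = "eavflat")
  tpl_p <- system.file("extdata", "example_template.csv", package = "eavflat")
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_flat(translate(eav_p, tpl_p, ex$config), p1)
  write_flat(translate(eav_p, tpl_p, ex$config), p2)
  expect_identical(read_file_bytes(p1), read_file_bytes(p2))
})

test_that("duplicate measurements follow the duplicate policy", {
  dup <- as.data.frame(ex$eav)[c(1:8, 1), ]
  same <- do.call(eav_table, c(as.list(dup), list(source_columns = attr(ex$eav, "source_columns"))))
  expect_message(tree <- build_hierarchy(same, ex$config), "deduplicated 1")
  expect_equal(nrow(hierarchy_leaves(tree)), 8L)

  dup$value[[9L]] <- "9.9"
  diff <- do.call(eav_table, c(as.list(dup), list(source_columns = attr(ex$eav, "source_columns"))))
  expect_error(build_hierarchy(diff, ex$config),
               class = "eavflat_duplicate_measurement_error")
  cfg_lw <- ex$config; cfg_lw$duplicate_policy <- "last_wins"
  tree_lw <- build_hierarchy(diff, cfg_lw)
  leaves <- hierarchy_leaves(tree_lw)
  expect_equal(nrow(leaves), 8L)
  # later value replaces, first-appearance position kept
  expect_equal(leaves$value[[1L]], "9.9")
  expect_equal(leaves$attribute[[1L]], "calcium")
})

test_that("missing rows, missing target columns and cell conflicts follow policy", {
  short_tpl <- flat_table(ids = c("100001", "100002", "100001"),
                          events = c("visit_1", "visit_1", "visit_2"),
                          fields = data.frame(Ncal = character(3), leuco = character(3),
                                              stringsAsFactors = FALSE))
  expect_error(flatten(build_hierarchy(ex$eav, ex$config), ex$config, short_tpl),
               class = "eavflat_missing_row_error")
  cfg_app <- ex$config; cfg_app$missing_row_policy <- "append"
  out <- flatten(build_hierarchy(ex$eav, cfg_app), cfg_app, short_tpl)
  expect_equal(nrow(out), 4L)
  expect_identical(unlist(out[4L, 1:2], use.names = FALSE), c("100002", "exacerbation_1"))
  expect_equal(out$Ncal[[4L]], "2.44")

  no_col <- flat_table(ids = ex$template[[1]], events = ex$template[[2]],
                       fields = data.frame(Ncal = character(4), stringsAsFactors = FALSE))
  expect_error(flatten(build_hierarchy(ex$eav, ex$config), ex$config, no_col),
               class = "eavflat_missing_target_column_error")

  pre <- ex$template; pre$Ncal[[1L]] <- "9.99"
  expect_error(flatten(build_hierarchy(ex$eav, ex$config), ex$config, pre),
               class = "eavflat_cell_conflict_error")
  pre2 <- ex$template; pre2$Ncal[[1L]] <- "6.2"  # equal value: no conflict
  out2 <- flatten(build_hierarchy(ex$eav, ex$config), ex$config, pre2)
  expect_equal(out2$Ncal[[1L]], "6.2")
})

test_that("event_map renames instrument event tokens into EDC event names", {
  cfg <- ex$config
  cfg$event_map <- c(visit_1 = "baseline_arm_1")
  tpl <- flat_table(ids = c("100001", "100002", "100001", "100002"),
                    events = c("baseline_arm_1", "baseline_arm_1", "visit_2", "exacerbation_1"),
                    fields = data.frame(Ncal = character(4), leuco = character(4),
                                        hb = character(4), mono = character(4),
                                        stringsAsFactors = FALSE))
  out <- flatten(build_hierarchy(ex$eav, cfg), cfg, tpl)
  expect_equal(out$Ncal[[1L]], "6.2")
  rt <- unflatten(out, cfg)
  expect_true(all(rt$event_id[rt$entity_id == "100001" & rt$value == "6.2" &
                                rt$attribute == "calcium"] == "visit_1"))
})

test_that("unflatten recovers the example EAV tuples exactly, dates excepted", {
  filled <- translate(ex$eav, ex$template, ex$config)
  back <- unflatten(filled, ex$config)
  expect_equal(nrow(back), 8L)
  key <- function(t) sort(paste(t$entity_id, t$event_id, t$attribute, t$value, sep = "|"))
  expect_identical(key(back), key(as.data.frame(ex$eav)))
  expect_true(all(back$date == ""))
  expect_equal(nrow(unflatten(ex$template, ex$config)), 0L)
})

test_that("flatten agrees cell-for-cell with the nested-map oracle on random studies", {
  for (s in 1:30) {
    study <- generate_study(random_spec(1000 + s))
    got <- flatten(build_hierarchy(study$eav, study$config), study$config, study$template)
    want <- oracle_fill(study$eav, study$config, study$template)
    expect_same_cells(as.data.frame(got), want)
    # conservation: filled cells == mapped leaves
    expect_equal(sum(nzchar(as.matrix(as.data.frame(got)[-(1:2)]))), nrow(study$ledger))
    # round trip through unflatten
    back <- unflatten(got, study$config)
    key <- function(t) sort(paste(t$entity_id, t$event_id, t$attribute, t$value, sep = "|"))
    expect_identical(key(as.data.frame(back)), key(as.data.frame(study$eav)))
  }
})
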