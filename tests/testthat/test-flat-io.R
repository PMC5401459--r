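test_that("the packaged template reads into 4 blank keyed rows", {
  tpl <- read_flat(system.file("extdata", "example_template.csv", package = "eavflat"))
  expect_s3_class(tpl, "flat_table")
  expect_equal(nrow(tpl), 4L)
  expect_identical(field_columns(tpl), c("Ncal", "leuco", "hb", "mono"))
  expect_identical(attr(tpl, "id_column_name"), "patient_id")
  expect_identical(attr(tpl, "event_column_name"), "redcap_event_name")
  keys <- paste(tpl[[1L]], tpl[[2L]])
  expect_identical(keys, c("100001 visit_1", "100002 visit_1",
                           "100001 visit_2", "100002 exacerbation_1"))
  expect_true(all(as.matrix(as.data.frame(tpl)[-(1:2)]) == ""))

  hdr_only <- withr::local_tempfile(lines = "patient_id,redcap_event_name,Ncal")
  expect_equal(nrow(read_flat(hdr_only)), 0L)
})

test_that("duplicate row keys are rejected", {
  p <- withr::local_tempfile(lines = c("patient_id,redcap_event_name,Ncal",
                                       "100001,visit_1,", "100001,visit_1,"))
  expect_error(read_flat(p), class = "eavflat_duplicate_row_key_error")
})

test_that("the filled example writes the expected exacerbation line", {
  ex <- example_study()
  filled <- translate(ex$eav, ex$template, ex$config)
  p <- withr::local_tempfile()
  write_flat(filled, p)
  lines <- readLines(p)
  expect_equal(lines[[1L]], "patient_id,redcap_event_name,Ncal,leuco,hb,mono")
  expect_equal(lines[[5L]], "100002,exacerbation_1,2.44,8.1,,")
})

test_that("flat tables round-trip through their CSV dialect", {
  set.seed(99)
  rand_cell <- function(n) {
    pool <- c("", "2.4", "x,y", 'quo"te', "multi\nline", "  pad  ", "0")
    sample(pool, n, replace = TRUE)
  }
  for (i in 1:40) {
    n <- sample(0:6, 1L)
    tbl <- flat_table(
      ids = as.character(sample(1e5, n)),
      events = sprintf("visit_%d", seq_len(n)),
      fields = data.frame(a = rand_cell(n), b = rand_cell(n),
                          stringsAsFactors = FALSE),
      id_column_name = "rec", event_column_name = "ev"
    )
    p <- withr::local_tempfile()
    write_flat(tbl, p)
    back <- read_flat(p)
    expect_identical(as.data.frame(back), as.data.frame(tbl))
    expect_identical(attr(back, "id_column_name"), "rec")
  }
})

test_that("a template read and rewritten unchanged is byte-identical to its source", {
  src <- system.file("extdata", "example_template.csv", package = "eavflat")
  p <- withr::local_tempfile()
  write_flat(read_flat(src), p)
  expect_identical(read_file_bytes(p), read_file_bytes(src))
})

test_that("screening flags out-of-bounds and malformed values without touching the table", {
  ex <- example_study()
  filled <- translate(ex$eav, ex$template, ex$config)
  before <- as.data.frame(filled)
  rep <- validate_flat(filled, validation_rule("Ncal", "numeric", min = 2.0, max = 3.0))
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$n_checked, 4L)     # four non-empty Ncal cells
  expect_equal(rep$n_rejected, 1L)    # only (100001, visit_1) = 6.2 breaches
  expect_identical(rep$issues$entity, "100001")
  expect_identical(rep$issues$event, "visit_1")
  expect_match(rep$issues$message, "above maximum")
  expect_identical(as.data.frame(filled), before)

  rep0 <- validate_flat(filled, list())
  expect_equal(rep0$n_checked, 0L)
  expect_equal(nrow(rep0$issues), 0L)

  bad <- filled
  bad$leuco[[1L]] <- "6,5"   # comma decimal: incorrectly formatted
  bad$hb[[2L]] <- "12.5"
  rep2 <- validate_flat(bad, list(
    validation_rule("leuco", "numeric", min = 3, max = 10),
    validation_rule("hb", "integer"),
    validation_rule("mono", "numeric", required = TRUE)))
  expect_true(any(grepl("not a well-formed numeric", rep2$issues$message)))
  expect_true(any(grepl("not a well-formed integer", rep2$issues$message)))
  expect_equal(sum(rep2$issues$message == "required value is missing"), 4L)
})

test_that("rule construction and unknown fields are validated", {
  expect_error(validation_rule("x", "text", min = 1),
               class = "eavflat_config_schema_error")
  expect_error(validation_rule("x", "numeric", min = 2, max = 1),
               class = "eavflat_config_schema_error")
  ex <- example_study()
  expect_error(validate_flat(ex$template, validation_rule("nope", "numeric")),
               class = "eavflat_unknown_field_error")
})

test_that("date_string screening accepts instrument and ISO tokens only", {
  tbl <- flat_table(ids = as.character(1:4), events = paste0("v", 1:4),
                    fields = data.frame(d = c("150321", "20150321", "2015-03-21", "21/03/2015"),
                                        stringsAsFactors = FALSE))
  rep <- validate_flat(tbl, validation_rule("d", "date_string"))
  expect_equal(rep$n_checked, 4L)
  expect_equal(rep$n_rejected, 1L)
  expect_identical(rep$issues$entity, "4")
})

test_that("exactly K planted violations are detected on generated studies", {
  for (s in 1:10) {
    sp <- random_spec(2000 + s)
    study <- generate_study(sp)
    filled <- flatten(build_hierarchy(study$eav, study$config),
                      study$config, study$template)
    clean <- validate_flat(filled, study$rules)
    expect_equal(clean$n_rejected, 0L)
    expect_equal(clean$n_checked, nrow(study$ledger))
    set.seed(s)
    k <- sample(0:5, 1L)
    planted <- plant_violations(filled, sp, k, seed = s)
    rep <- validate_flat(planted$table, study$rules)
    expect_equal(rep$n_rejected, nrow(planted$planted))
    expect_equal(nrow(rep$issues), nrow(planted$planted))
  }
})
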