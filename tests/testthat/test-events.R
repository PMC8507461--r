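csv_header <- paste("event_id,t_start,duration,event_type,kvp,filtration_cu,",
                    "filtration_al,ang_primary,ang_secondary,field_area,",
                    "p_ka,k_air_ref,table_height", sep = "")

test_that("CSV dialect rows parse into typed events", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(csv_header,
               "a1,100.5,12.4,fluoroscopy,79,0.3,0,0,0,835,4.1,17.6,"), f)
  log <- read_events(f, "csv")
  expect_s3_class(log, "irs_log")
  expect_equal(nrow(log), 1L)
  expect_equal(log$kvp, 79)
  expect_equal(log$filtration_cu, 0.3)
  expect_equal(log$field_area, 835)
  expect_equal(log$p_ka, 4.1)
  expect_equal(log$k_air_ref, 17.6)
  expect_true(is.na(log$table_height))
})

test_that("a file with zero event rows yields an empty log, not an error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(csv_header, f)
  log <- read_events(f, "csv")
  expect_equal(nrow(log), 0L)
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines("[]", f2)
  expect_equal(nrow(read_events(f2, "json")), 0L)
})

test_that("a 19-event log parses with all events retained", {
  df <- fix_log_df(19)
  log <- procedure_log(df)
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(log, f, "csv")
  expect_equal(nrow(read_events(f, "csv")), 19L)
})

test_that("round trips are field-for-field identical in both dialects", {
  df <- fix_log_df(8, p_ka = c(0, 0.5, 1.3, 0.004, 2, 7, 0.1, 0.06))
  df$event_type[c(2, 5)] <- "acquisition"
  df$ang_primary <- c(-35, 0, 15, 26, 38, -10, 5, 0)
  log <- procedure_log(df)
  for (dialect in c("csv", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_events(log, f, dialect)
    back <- read_events(f, dialect)
    for (col in names(log)) expect_equal(back[[col]], log[[col]], label = col)
  }
})

test_that("events sort by start time with stable id tie-break", {
  df <- fix_log_df(3)
  df$t_start <- c(50, 10, 10)
  df$event_id <- c("c", "b", "a")
  log <- procedure_log(df)
  expect_equal(log$event_id, c("a", "b", "c"))
})

test_that("validation names the offending event and field", {
  df <- fix_log_df(3)
  df$kvp[2] <- 200
  expect_error(procedure_log(df), "ev02.*kvp")
  df2 <- fix_log_df(2)
  df2$field_area[1] <- 0
  expect_error(procedure_log(df2), "ev01.*field_area")
  df3 <- fix_log_df(2)
  df3$event_type[2] <- "cine"
  expect_error(procedure_log(df3), "event_type")
  df4 <- fix_log_df(2)
  df4$event_id <- c("x", "x")
  expect_error(procedure_log(df4), "unique")
  expect_error(read_events("no/such/file.csv", "csv"), "cannot read")
  expect_error(read_events("whatever.dcm", "rdsr_dicom"), "dialect")
})

test_that("summaries match brute-force column reductions", {
  df <- fix_log_df(12, p_ka = runif(12, 0, 3))
  df$kvp <- sample(66:86, 12, replace = TRUE)
  df$event_type[1:4] <- "acquisition"
  log <- procedure_log(df)
  sm <- summarize_events(log)
  expect_equal(sm$total_pka, sum(df$p_ka))
  expect_equal(sm$total_kair, sum(df$k_air_ref))
  expect_equal(unname(sm$ranges$kvp), unname(range(df$kvp)))
  expect_equal(unname(sm$counts["acquisition"]), 4L)
  single <- summarize_events(procedure_log(fix_log_df(1)))
  expect_equal(single$ranges$kvp[["min"]], single$ranges$kvp[["max"]])
})
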