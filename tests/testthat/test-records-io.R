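# Trial-record IO, validation, the exclusion pipeline, sessionization.

test_that("read_trials keeps valid rows and reports row diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "user_id,seq_index,timestamp,stimulus_id,true_label,response",
    "u1,0,,s1,benign,benign",
    "u1,1,,s2,malignant,maybe",
    "u1,2,,s3,benign,malignant",
    "u2,0,,s1,benign,benign",
    "u2,1,,s4,malignant,malignant"
  ), path)
  expect_warning(tr <- read_trials(path), "invalid")
  expect_equal(nrow(tr), 4)
  diag <- attr(tr, "diagnostics")
  expect_equal(diag$row, 2)
  expect_match(diag$problem, "response")
})

test_that("an empty trial file yields an empty table with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("user_id,seq_index,timestamp,stimulus_id,true_label,response", path)
  expect_warning(tr <- read_trials(path), "no trial records")
  expect_equal(nrow(tr), 0)
})

test_that("a missing required column is a schema error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("user_id,seq_index,true_label", "u1,0,benign"), path)
  expect_error(read_trials(path), class = "serialdep_schema_error")
})

test_that("write -> read round-trip is the identity on simulated tables", {
  cfg <- sim_config(n_images = 100, n_users = 3, trials_per_user = 40, seed = 4)
  pool <- generate_stimuli(cfg)
  tr <- simulate_trials(pool, observer_params(), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  expect_equal(as.data.frame(read_trials(path)), as.data.frame(tr))
  spath <- withr::local_tempfile(fileext = ".csv")
  write_stimuli(pool, spath)
  back <- read_stimuli(spath)
  expect_equal(back$malignancy, pool$malignancy)
})

test_that("preprocess applies the ordered rules and the report balances", {
  base <- toy_trials()
  # a user with only 5 trials is removed entirely by the min-trials rule
  pp <- preprocess_trials(base[1:5, ], min_trials_per_user = 20)
  expect_equal(nrow(pp$trials), 0)
  expect_equal(pp$report$rules$min_trials_per_user, 5)

  # no rule fires -> identity with all counts zero
  pp2 <- preprocess_trials(base, min_trials_per_user = 1)
  expect_equal(as.data.frame(pp2$trials), as.data.frame(base))
  expect_true(all(unlist(pp2$report$rules) == 0))

  # 10 rows of which 2 are exact duplicates -> 8 kept under permissive rules
  extra <- base[1:2, ]
  extra$user_id <- "u02"
  ten <- dplyr::bind_rows(base, extra, base[1:2, ])
  ten <- ten[order(ten$user_id, ten$seq_index), ]
  pp3 <- preprocess_trials(ten, min_trials_per_user = 1)
  expect_equal(pp3$report$n_output, 8)
  expect_equal(pp3$report$rules$duplicate_user_seq, 2)
})

test_that("preprocess is idempotent and its arithmetic balances on random fixtures", {
  for (s in 1:5) {
    fx <- random_fixture(n_trials = 80, n_users = 4, seed = s)
    tr <- fx$trials
    # inject duplicates and missing fields
    tr <- dplyr::bind_rows(tr, tr[sample(nrow(tr), 5), ])
    tr$response[sample(nrow(tr), 3)] <- NA
    pp1 <- preprocess_trials(tr, min_trials_per_user = 10)
    expect_equal(pp1$report$n_output,
                 pp1$report$n_input - sum(unlist(pp1$report$rules)))
    pp2 <- preprocess_trials(pp1$trials, min_trials_per_user = 10)
    expect_equal(as.data.frame(pp2$trials), as.data.frame(pp1$trials))
    expect_true(all(unlist(pp2$report$rules) == 0))
  }
})

test_that("exclusion reports serialize to JSON", {
  pp <- preprocess_trials(toy_trials(), min_trials_per_user = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_exclusion_report(pp$report, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$n_input, 6)
  expect_named(j$rules, c("duplicate_user_seq", "missing_fields", "min_trials_per_user"))
})

test_that("sessionize splits on gaps, is identity at infinite threshold", {
  tr <- toy_trials()
  one <- sessionize(tr, gap_minutes = 30)
  expect_true(all(one$session_id == 0))

  tr2 <- tr
  tr2$timestamp[4:6] <- sprintf("2021-01-04T11:%02d:00Z", 3:5)  # 2 h gap
  two <- sessionize(tr2, gap_minutes = 30)
  expect_equal(unique(two$session_id), c(0L, 1L))
  expect_equal(two$session_id, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_true(all(sessionize(tr2, gap_minutes = Inf)$session_id == 0L))
})

test_that("non-monotone timestamps are an error naming the user", {
  tr <- toy_trials()
  tr$timestamp[3] <- "2021-01-04T08:00:00Z"
  expect_error(sessionize(tr, gap_minutes = 30), "u01",
               class = "serialdep_timestamp_error")
})
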