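test_that("reading and writing a trial table round-trips exactly", {
  ds <- small_trial()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(ds, path)
  back <- read_trial(path, control_arm = "Vehicle")
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ds),
               ignore_attr = TRUE)
  expect_identical(control_arm(back), "Vehicle")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_trial(ds, tsv)
  expect_equal(tibble::as_tibble(read_trial(tsv)),
               tibble::as_tibble(ds), ignore_attr = TRUE)
})

test_that("the nibr-pdxe dialect preset maps the published column names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    'Model,Tumor Type,Treatment,Days Post T0,Volume',
    'X-1004,CRC,untreated,0,180',
    'X-1004,CRC,untreated,7,420',
    'X-1004,CRC,BYL719,0,195',
    'X-1004,CRC,BYL719,7,210'), path)
  ds <- read_trial(path, dialect = "nibr-pdxe")
  expect_setequal(names(ds), c("tumor_id", "tumor_type", "arm", "animal_id",
                               "day", "volume"))
  expect_identical(unique(ds$tumor_id), "X-1004")
  expect_identical(unique(ds$tumor_type), "CRC")
  # one animal per model-by-treatment cell gets a synthesized id
  expect_identical(unique(ds$animal_id[ds$arm == "BYL719"]), "X-1004:BYL719")
  # "untreated" is auto-detected as the control arm
  expect_identical(control_arm(ds), "untreated")
  expect_equal(ds$volume[ds$arm == "BYL719" & ds$day == 7], 210)
})

test_that("read errors name the offending column or row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Model,Volume", "X,100"), path)
  expect_error(read_trial(path, dialect = "nibr-pdxe"),
               "Tumor Type|Treatment|Days Post T0")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tumor_id,arm,animal_id,day,volume",
               "T,Vehicle,m1,0,abc"), path2)
  expect_error(read_trial(path2), "non-numeric 'volume'")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tumor_id,arm,animal_id,day,volume",
               "T,Vehicle,m1,0,100",
               "T,Vehicle,m1,0,120"), path3)
  expect_error(read_trial(path3), "duplicate")
})

test_that("an empty file with a valid header yields 0 records and a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("tumor_id,arm,animal_id,day,volume", path)
  expect_warning(ds <- read_trial(path), "no records")
  expect_identical(nrow(ds), 0L)
  rep <- validate_trial(ds)
  expect_true(any(rep$issues$message == "no records"))
})

test_that("validation flags baselines, short series, and negative volumes", {
  ds <- trial_dataset(data.frame(
    tumor_id = "T", arm = c("Vehicle", "Vehicle", "Vehicle", "D", "D", "D"),
    animal_id = c("m1", "m1", "m2", "m3", "m3", "m4"),
    day = c(0, 7, 7, 0, 7, 0),
    volume = c(100, 150, 140, 100, -5, 90)),
    control_arm = "Vehicle")
  rep <- validate_trial(ds)
  expect_s3_class(rep, "validation_report")
  expect_false(is_valid(rep))  # negative volume is fatal
  msgs <- rep$issues$message
  expect_true(any(grepl("negative volume", msgs)))
  expect_true(any(grepl("missing baseline", msgs)))   # m2 starts at day 7
  expect_true(any(grepl("fewer than 2 timepoints", msgs)))  # m4
  expect_equal(rep$n_animals, 4L)
  expect_equal(rep$n_arms, 2L)

  clean <- validate_trial(small_trial())
  expect_true(is_valid(clean))
  expect_equal(clean$n_animals, 6L)
  expect_equal(clean$n_timepoints, 3L)
})

test_that("pattern inference matches the four design codes", {
  # 1 tumor, 5 treatments + vehicle, 8 animals each
  ds_1an <- simulate_trial(sim_config("1AN", n_arms = 5, n_animals = 8,
                                      seed = 1))
  expect_identical(infer_pattern(ds_1an)$code, "1AN")
  expect_false(infer_pattern(ds_1an)$degenerate)

  # 3 tumors, Vehicle + 1 drug, 5 animals per cell
  ds_t1n <- simulate_trial(sim_config("T1N", n_tumors = 3, n_animals = 5,
                                      seed = 2))
  expect_identical(infer_pattern(ds_t1n)$code, "T1N")

  # many tumors, many arms, 1 animal per arm
  ds_ta1 <- simulate_trial(sim_config("TA1", n_tumors = 6, n_arms = 4,
                                      seed = 3))
  expect_identical(infer_pattern(ds_ta1)$code, "TA1")

  ds_tan <- simulate_trial(sim_config("TAN", n_tumors = 3, n_arms = 3,
                                      n_animals = 4, seed = 4))
  expect_identical(infer_pattern(ds_tan)$code, "TAN")

  expect_error(infer_pattern(trial_dataset(small_trial()[0, ])), "empty")
})

test_that("pattern inference is invariant to row order and label renaming", {
  ds <- simulate_trial(sim_config("TAN", n_tumors = 3, n_arms = 3,
                                  n_animals = 4, seed = 5))
  ref <- infer_pattern(ds)
  shuffled <- trial_dataset(tibble::as_tibble(ds)[sample(nrow(ds)), ],
                            control_arm = control_arm(ds))
  expect_identical(infer_pattern(shuffled)$code, ref$code)

  renamed <- tibble::as_tibble(ds)
  renamed$arm <- paste0("arm.", renamed$arm)
  renamed$tumor_id <- paste0("line.", renamed$tumor_id)
  ds2 <- trial_dataset(renamed, control_arm = "arm.Vehicle")
  expect_identical(infer_pattern(ds2)$code, ref$code)
})

test_that("relative change is exact on hand-worked series and scale-free", {
  ds <- trial_dataset(data.frame(
    tumor_id = "T", arm = "D", animal_id = "m1",
    day = c(0, 7, 14), volume = c(100, 80, 60)))
  rc <- relative_change(ds)
  expect_equal(rc$pct_change, c(0, -20, -40))

  # multiplying one animal's series by a positive constant changes nothing
  ds2 <- trial_dataset(data.frame(
    tumor_id = "T", arm = "D", animal_id = "m1",
    day = c(0, 7, 14), volume = 7.3 * c(100, 80, 60)))
  expect_equal(relative_change(ds2)$pct_change, rc$pct_change)

  # constant series is identically zero
  ds3 <- trial_dataset(data.frame(
    tumor_id = "T", arm = "D", animal_id = "m1",
    day = c(0, 7, 14), volume = c(50, 50, 50)))
  expect_equal(relative_change(ds3)$pct_change, c(0, 0, 0))

  # an animal without a positive baseline is excluded with a warning
  ds4 <- trial_dataset(data.frame(
    tumor_id = "T", arm = "D", animal_id = c("m1", "m1", "m2", "m2"),
    day = c(0, 7, 0, 7), volume = c(100, 120, 0, 50)))
  expect_warning(rc4 <- relative_change(ds4), "excluded")
  expect_setequal(unique(rc4$animal_id), "m1")
})

test_that("arm summaries compute center and SEM per day", {
  ds <- trial_dataset(data.frame(
    tumor_id = "T", arm = "A", animal_id = c("m1", "m2"),
    day = 7, volume = c(100, 120)))
  s <- summarize_arms(ds)
  expect_equal(s$center, 110)
  expect_equal(s$sem, 10)  # sd = sqrt(200), sem = sqrt(200)/sqrt(2)

  # n = 1: center is the value, SEM absent
  ds1 <- trial_dataset(data.frame(tumor_id = "T", arm = "A",
                                  animal_id = "m1", day = 7, volume = 123))
  s1 <- summarize_arms(ds1)
  expect_equal(s1$center, 123)
  expect_true(is.na(s1$sem))

  # median resists the outlier
  ds2 <- trial_dataset(data.frame(
    tumor_id = "T", arm = "A", animal_id = c("m1", "m2", "m3"),
    day = 7, volume = c(100, 120, 500)))
  expect_equal(summarize_arms(ds2, center = "median")$center, 120)

  # k identical animals: common trajectory, SEM exactly 0
  ds3 <- trial_dataset(data.frame(
    tumor_id = "T", arm = "A", animal_id = rep(c("m1", "m2", "m3"), each = 2),
    day = rep(c(0, 7), 3), volume = rep(c(100, 150), 3)))
  s3 <- summarize_arms(ds3)
  expect_equal(s3$center, c(100, 150))
  expect_equal(s3$sem, c(0, 0))
})
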