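test_that("a clean CSV ingests with an empty rejection log", {
  cohort <- generate_cohort(synthetic_config(n_per_stratum = 3, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(cohort, path)
  res <- read_records(path)
  expect_s3_class(res, "ingest_result")
  expect_equal(nrow(res$records), 24)
  expect_equal(nrow(res$rejected), 0)
})

test_that("cohort CSVs round-trip at full stored precision", {
  cohort <- generate_cohort(synthetic_config(n_per_stratum = 4, seed = 15))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(cohort, path)
  back <- read_records(path)$records
  for (col in c("age_years", "weight_kg", "height_cm", "mac_cm", "ac_cm",
                "cc_cm", "hc_cm", "kh_cm", "sst_mm")) {
    expect_identical(back[[col]], cohort[[col]], label = col)
  }
  expect_identical(back$participant_id, cohort$participant_id)
  expect_identical(back$sex, cohort$sex)
})

make_csv <- function(rows) {
  header <- paste(c("participant_id", "sex", "age_years", "weight_kg",
                    "height_cm", "mac_cm", "ac_cm", "cc_cm", "hc_cm",
                    "kh_cm", "sst_mm"), collapse = ",")
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c(header, rows), path)
  path
}

test_that("rows violating validation rules are rejected with reasons, not coerced", {
  path <- make_csv(c(
    "P1,F,30,64.5,162.5,28.6,81.8,34.5,96.5,51.5,12",
    "P2,male,30,64.5,16.25,28.6,81.8,34.5,96.5,51.5,12",   # decimal-slip height
    "P3,male,30,-4,170,28.6,81.8,34.5,96.5,51.5,12",       # non-positive weight
    "P4,unknown,30,64.5,170,28.6,81.8,34.5,96.5,51.5,12",  # bad sex label
    "P5,male,30,sixty,170,28.6,81.8,34.5,96.5,51.5,12",    # non-numeric
    "P6,2,44,70,158,,,,,,"                                  # missing fields are fine
  ))
  res <- read_records(path)
  expect_equal(res$n_read, 6)
  expect_equal(res$records$participant_id, c("P1", "P6"))
  expect_identical(res$records$sex, c("female", "female"))
  expect_identical(sex_code(res$records$sex[1]), 2L)
  expect_true(any(res$rejected$row == 2 & grepl("plausible range", res$rejected$reason)))
  expect_true(any(res$rejected$row == 3 & grepl("non-positive", res$rejected$reason)))
  expect_true(any(res$rejected$row == 4 & grepl("sex", res$rejected$field)))
  expect_true(any(res$rejected$row == 5 & grepl("not a number", res$rejected$reason)))
})

test_that("duplicate participant ids abort the ingest", {
  path <- make_csv(c(
    "P1,m,30,64.5,162.5,28.6,81.8,34.5,96.5,51.5,12",
    "P1,f,28,55,158,26,75,33,98,49,14"
  ))
  expect_error(read_records(path), "duplicate participant_id")
})

test_that("column mapping absorbs nonstandard headers and missing columns error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,Gender,Age,Wt,Ht,MUAC,Abd,Calf,Hip,Knee,Skinfold",
               "A1,M,30,64.5,162.5,28.6,81.8,34.5,96.5,51.5,12"), path)
  schema <- ingest_schema(columns = c(
    id = "ID", sex = "Gender", age_years = "Age", weight_kg = "Wt",
    height_cm = "Ht", mac_cm = "MUAC", ac_cm = "Abd", cc_cm = "Calf",
    hc_cm = "Hip", kh_cm = "Knee", sst_mm = "Skinfold"
  ))
  res <- read_records(path, schema)
  expect_equal(res$records$weight_kg, 64.5)
  expect_error(read_records(path), "unmapped required column")
  expect_error(ingest_schema(columns = c(bogus = "x")), "unknown canonical field")
})

test_that("descriptives use median and linear-interpolation quartiles", {
  recs <- tibble::tibble(
    participant_id = as.character(1:4), sex = c("male", "male", "female", "female"),
    age_years = c(1, 2, 3, 4), weight_kg = c(60, 70, 50, 80), height_cm = 160
  )
  d <- describe_cohort(recs)
  age <- d[d$variable == "age_years" & d$group == "overall", ]
  expect_equal(age$median, 2.5)
  expect_equal(age$q1, 1.75)
  expect_equal(age$q3, 3.25)

  one <- describe_cohort(recs[1, ])
  w1 <- one[one$variable == "weight_kg" & one$group == "overall", ]
  expect_equal(c(w1$median, w1$q1, w1$q3), c(60, 60, 60))
  fem <- one[one$variable == "weight_kg" & one$group == "female", ]
  expect_equal(fem$n, 0L)
  expect_match(fem$note, "no observations")
})

test_that("the report bundle has the published tables' shape and is deterministic", {
  cohort <- generate_cohort(synthetic_config(n_per_stratum = 6, seed = 19))
  bundle <- run_validation(cohort)
  expect_equal(nrow(bundle$overall), 9)
  expect_equal(nrow(bundle$subgroup), 9 * 6)
  expect_setequal(unique(bundle$subgroup$axis), c("sex", "nutrition"))
  expect_equal(bundle$manifest$n_records, 48)
  expect_equal(bundle$manifest$synthetic_seed, 19)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  p1 <- write_validation_reports(bundle, dir1)
  p2 <- write_validation_reports(run_validation(cohort), dir2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]), label = f)
  }
  # display columns are half-up 2dp renderings of the machine columns
  overall_csv <- readr::read_csv(
    p1[["overall"]], show_col_types = FALSE,
    col_types = readr::cols(p10_display = readr::col_character())
  )
  expect_equal(overall_csv$p10_display,
               sprintf("%.2f", anthroweight:::round_half_up(overall_csv$p10, 2)))
})

test_that("the command-line entry point predicts from shell arguments", {
  cli <- system.file("cli", "anthroweight.R", package = "anthroweight")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(cli, "predict", "--equation", "R3", "--mac", "28.6",
               "--ac", "81.8", "--cc", "34.5", "--sex", "male"),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  expect_equal(utils::tail(out, 1), "64.69")
})

test_that("planted-truth provenance flows into the manifest", {
  cohort <- plant_equation_truth(
    synthetic_config(n_per_stratum = 4, seed = 23,
                     planted_equation = "R3", planted_noise_sd = 2)
  )
  bundle <- run_validation(cohort, c("R3", "KK"))
  expect_equal(bundle$manifest$planted_truth$equation, "R3")
  expect_equal(bundle$manifest$planted_truth$noise_sd, 2)
})

test_that("implausible non-positive predictions warn and are flagged, not masked", {
  recs <- tibble::tibble(
    participant_id = c("T1", "T2", "T3"), sex = "male", age_years = 30,
    weight_kg = c(40, 41, 42), height_cm = 150,
    mac_cm = c(10, 10.5, 11),  # tiny arm girth drives Cattermole negative
    ac_cm = 60, cc_cm = 28, hc_cm = 80, kh_cm = 45, sst_mm = 6
  )
  expect_lt(predict_weight(recs[1, ], "C"), 0)
  expect_warning(bundle <- run_validation(recs, "C"), "implausible")
  expect_equal(bundle$overall$n_implausible, 3L)
})

test_that("Bland-Altman plot data and ggplot helper line up with the report", {
  cohort <- generate_cohort(synthetic_config(n_per_stratum = 4, seed = 27))
  bundle <- run_validation(cohort, c("R3", "KK"))
  pts <- bundle$ba_points[bundle$ba_points$equation == "R3", ]
  expect_equal(nrow(pts), nrow(cohort))
  ba <- bland_altman(
    bundle$predictions$predicted_kg[bundle$predictions$equation == "R3"],
    bundle$predictions$actual_kg[bundle$predictions$equation == "R3"]
  )
  line <- bundle$ba_lines[bundle$ba_lines$equation == "R3", ]
  expect_equal(line$bias, ba$bias, tolerance = 1e-12)
  expect_equal(line$loa_lower, ba$loa_lower, tolerance = 1e-12)
  p <- plot_bland_altman(bundle, "R3")
  expect_s3_class(p, "ggplot")
})
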