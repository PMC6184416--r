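test_that("generator honours count and seed contracts", {
  cfg <- sim_config(n_records = 100, n_institutions = 10, seed = 1)
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  expect_equal(nrow(sim1$records), 100)
  expect_identical(sim1$records, sim2$records)
  expect_identical(sim1$ledgers, sim2$ledgers)
  sim3 <- simulate_dataset(sim_config(n_records = 100, n_institutions = 10,
                                      seed = 2))
  expect_false(identical(sim1$records, sim3$records))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(n_records = 0), "n_records",
               class = "cceann_config_error")
  expect_error(sim_config(noise_sd = -1), "noise_sd",
               class = "cceann_config_error")
  expect_error(sim_config(genitourinary_fraction = 1.2),
               "genitourinary_fraction", class = "cceann_config_error")
  expect_error(sim_config(effect_sizes = c(length_of_stay = 1)),
               "effect_sizes", class = "cceann_config_error")
  expect_error(sim_config(insurance_levels = c("a", "b")),
               "insurance_levels", class = "cceann_config_error")
})

test_that("zero noise and zero effects give identical inpatient income", {
  cfg <- sim_config(
    n_records = 400, n_institutions = 8, noise_sd = 0,
    effect_sizes = setNames(numeric(8), names(sim_config()$effect_sizes)),
    seed = 4
  )
  rec <- simulate_dataset(cfg)$records
  inpat <- rec[rec$setting == "inpatient", ]
  for (stratum in split(inpat, inpat$institution_type)) {
    expect_length(unique(stratum$curative_income), 1)
  }
})

test_that("records satisfy the discharge-record invariants", {
  rec <- simulate_dataset(sim_config(n_records = 2000, n_institutions = 20,
                                     seed = 5))$records
  expect_true(all(rec$length_of_stay[rec$setting == "outpatient"] == 0))
  expect_true(all(rec$length_of_stay[rec$setting == "inpatient"] >= 1))
  expect_true(all(rec$curative_income >= 0))
  expect_true(all(grepl("^[A-Z][0-9]{2}$", rec$icd10)))
  led <- simulate_dataset(sim_config(n_records = 2000, n_institutions = 20,
                                     seed = 5))$ledgers
  sampled <- dplyr::summarise(dplyr::group_by(rec, institution_id),
                              a = sum(curative_income))
  m <- dplyr::inner_join(led, sampled, by = "institution_id")
  expect_true(all(m$ST_INC >= m$a - 1e-9))
  expect_true(all(led$S_P_ALL >= 0 & led$S_P_ALL <= led$ST_ALL))
})

test_that("a dominant length-of-stay effect shows up as the top correlation", {
  cfg <- sim_config(
    n_records = 10000, n_institutions = 30,
    effect_sizes = c(length_of_stay = 0.8, institution_type = 0.2,
                     insurance_type = 0.2, surgery = 0.1, gender = 0.1,
                     institution_level = 0.1, age = 0.1,
                     admission_season = 0.1),
    seed = 7
  )
  rec <- simulate_dataset(cfg)$records
  inpat <- rec[rec$setting == "inpatient", ]
  ly <- log(inpat$curative_income)
  cors <- c(
    length_of_stay = cor(ly, inpat$length_of_stay),
    surgery = cor(ly, as.numeric(inpat$surgery)),
    gender = cor(ly, as.numeric(inpat$gender == "male")),
    age = cor(ly, inpat$age)
  )
  expect_equal(names(which.max(abs(cors))), "length_of_stay")
  expect_gt(abs(cors["length_of_stay"]), 0.5)
})

test_that("with noise 0 and a single LOS effect, income is monotone in stay", {
  cfg <- sim_config(
    n_records = 1000, n_institutions = 5, noise_sd = 0,
    effect_sizes = c(length_of_stay = 0.5, institution_type = 0,
                     insurance_type = 0, surgery = 0, gender = 0,
                     institution_level = 0, age = 0, admission_season = 0),
    seed = 8
  )
  rec <- simulate_dataset(cfg)$records
  inpat <- dplyr::arrange(rec[rec$setting == "inpatient", ], length_of_stay)
  agg <- dplyr::summarise(dplyr::group_by(inpat, length_of_stay),
                          income = unique(curative_income))
  expect_true(all(diff(agg$income) > 0))
})

test_that("realized genitourinary fraction sits inside binomial 99% bounds", {
  frac <- 0.05
  n <- 5000
  rec <- simulate_dataset(sim_config(n_records = n, n_institutions = 20,
                                     genitourinary_fraction = frac,
                                     seed = 9))$records
  k <- sum(startsWith(rec$icd10, "N"))
  bounds <- qbinom(c(0.005, 0.995), n, frac)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("records round-trip through CSV field for field", {
  rec <- tiny_records()[1:3, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, path)
  expect_equal(read_records(path), rec)

  # header-only file gives an empty collection
  empty <- rec[0, ]
  write_records(empty, path)
  expect_equal(nrow(read_records(path)), 0)
})

test_that("malformed record files are rejected with row numbers", {
  rec <- tiny_records()[1:3, ]
  path <- withr::local_tempfile(fileext = ".csv")
  rec$length_of_stay[2] <- NA
  readr::write_csv(rec, path)
  expect_error(read_records(path), "row\\(s\\) 2",
               class = "cceann_validation_error")

  rec2 <- tiny_records()[1:3, ]
  rec2$icd10[3] <- "banana"
  readr::write_csv(rec2, path)
  expect_error(read_records(path), "ICD-10",
               class = "cceann_validation_error")

  suppressWarnings(
    expect_error(read_records(
      {
        p2 <- withr::local_tempfile(fileext = ".csv")
        readr::write_csv(dplyr::select(tiny_records(), -length_of_stay), p2)
        p2
      }
    ), "length_of_stay", class = "cceann_format_error")
  )
})

test_that("simulated output serializes byte-identically under one seed", {
  cfg <- sim_config(n_records = 300, n_institutions = 8, seed = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in c("records.csv", "ledgers.csv", "population.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("YAML configuration round-trips into sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_records: 50",
    "n_institutions: 5",
    "seed: 3",
    "noise_sd: 0.2"
  ), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_records, 50L)
  expect_equal(cfg$noise_sd, 0.2)
})
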