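ref_spec <- function() reference_population()

test_that("individual realization applies log-normal effects to the right parameters", {
  spec <- ref_spec()

  # all eta zero: the typical individual
  ind <- realize_individual(spec, NULL)
  expect_equal(ind$pk$Ka, 9.57)
  expect_equal(ind$pk$V, 6.15)
  expect_equal(ind$pd$E0, 4.65)

  # exp-scaling on a random-effect parameter
  ind2 <- realize_individual(spec, c(Ka = log(2)))
  expect_equal(ind2$pk$Ka, 19.14)
  expect_equal(ind2$pk$V, 6.15)

  # the population constants admit no eta
  expect_error(realize_individual(spec, c(IC50 = 0.1)), "without a random effect")
  expect_error(realize_individual(spec, c(CL = 0.1)), "without a random effect")
  expect_error(realize_individual(spec, c(V2 = 0.1)), "without a random effect")
})

test_that("population spec validation enforces the random-effect structure", {
  tv <- ref_spec()$tv
  expect_error(population_spec(tv, c(IC50 = 0.1), 0.1, 0.15), "population constants")
  expect_error(population_spec(tv, c(Ka = -0.1), 0.1, 0.15), "non-negative")
  expect_error(population_spec(tv[-1], c(Ka = 0.1), 0.1, 0.15), "named")
  expect_error(population_spec(tv, c(Ka = 0.1), 0, 0.15), "positive")
})

test_that("CV <-> omega transform is the exact log-normal relation", {
  cv <- c(0.9195, 0.1761, 0.0435)
  expect_equal(omega_to_cv(cv_to_omega(cv)), cv)
  expect_equal(cv_to_omega(0.9195), log(1 + 0.9195^2))
})

test_that("sampled parameters reproduce the target CV and median", {
  spec <- ref_spec()
  inds <- sample_population(spec, 10000, seed = 1)
  ka <- vapply(inds, function(x) x$pk$Ka, numeric(1))

  # Monte-Carlo check of the CV <-> omega transform
  expect_lt(abs(stats::sd(ka) / mean(ka) - 0.9195), 0.03)
  # log-normal identity: median -> tv
  expect_lt(abs(stats::median(ka) / 9.57 - 1), 0.02)

  # constants stay constant
  expect_true(all(vapply(inds, function(x) x$pk$CL, numeric(1)) == 0.03))
  expect_true(all(vapply(inds, function(x) x$pd$IC50, numeric(1)) == 1.13))
})

test_that("sampling is reproducible and stable under cohort extension", {
  spec <- ref_spec()
  a <- sample_population(spec, 10, seed = 7)
  b <- sample_population(spec, 10, seed = 7)
  expect_identical(a, b)

  # adding subjects never perturbs earlier subjects' draws
  c5 <- sample_population(spec, 5, seed = 7)
  expect_identical(a[1:5], c5)

  # zero variability collapses to the typical individual
  spec0 <- spec
  spec0$omega[] <- 0
  inds <- sample_population(spec0, 3, seed = 1)
  expect_equal(inds[[1]]$pk$Ka, 9.57)
  expect_equal(inds[[2]]$pd$Gam, 1.66)
})

test_that("simulated studies have the designed shape and error structure", {
  spec <- ref_spec()
  des <- small_design(6)
  ds <- simulate_study(spec, des, seed = 3)

  expect_s3_class(ds, "study_dataset")
  expect_equal(sum(ds$obs$kind == "drug_conc"), 6 * 11)
  expect_equal(sum(ds$obs$kind == "glucose"), 6 * 11)
  expect_equal(nrow(ds$doses), 6)
  expect_true(all(ds$obs$value >= 0))

  # byte-identical reproducibility
  expect_identical(ds, simulate_study(spec, des, seed = 3))

  # noiseless, no-variability limit equals the typical profile
  spec0 <- spec
  spec0$omega[] <- 0
  spec0$sigma_pk <- 1e-12
  spec0$sigma_pd <- 1e-12
  ds0 <- simulate_study(spec0, des, seed = 3)
  prof <- simulate_profile(typical_pk(), typical_pd(), 10, study_times(),
                           method = "analytic")
  one <- ds0$obs[ds0$obs$subject == "S001", ]
  expect_equal(one$value[one$kind == "drug_conc"], prof$C, tolerance = 1e-8)
  expect_equal(one$value[one$kind == "glucose"], prof$E, tolerance = 1e-8)
})

test_that("baseline glucose averages to the typical value across many subjects", {
  spec <- ref_spec()
  des <- small_design(1000)
  ds <- simulate_study(spec, des, seed = 11)
  base <- ds$obs$value[ds$obs$kind == "glucose" & ds$obs$time == 0]
  expect_equal(length(base), 1000)
  expect_lt(abs(mean(base) / 4.65 - 1), 0.01)
})

test_that("dataset validation catches structural defects", {
  obs <- data.frame(subject = "S001", time = c(0, 0), kind = "glucose",
                    value = c(4.5, 4.6), blq = FALSE)
  expect_error(study_dataset(data.frame(subject = "S001", time = 0,
                                        amount = 10), obs),
               "duplicate")
  obs2 <- data.frame(subject = "S002", time = 1, kind = "glucose",
                     value = 4.5, blq = FALSE)
  expect_error(study_dataset(data.frame(subject = "S001", time = 0,
                                        amount = 10), obs2),
               "no dose event")
  expect_error(study_dataset(data.frame(subject = "S001", time = 0,
                                        amount = -1), obs2),
               "amount")
})
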