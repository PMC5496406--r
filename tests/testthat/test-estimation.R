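# The FOCE machinery: inner joint likelihood, approximate marginal -2LL,
# sequential fitting, shrinkage.

test_that("joint log-likelihood matches an independently written formula", {
  spec <- reference_population()
  spec$omega <- c(V = 0.04)
  times <- c(0.5, 1)
  dose <- 10
  eta <- 0.17

  # brute force: explicit normal densities around the tri-exponential
  # prediction with V scaled by exp(eta)
  pk <- pk_params(Ka = 9.57, V = 6.15 * exp(eta), V2 = 104.69, CL = 0.03,
                  CL2 = 9.85, Tlag = 0.09)
  f <- analytic_central_conc(pk, dose, times)
  y <- c(0.9, 0.5)
  sd <- 0.10 * f
  expected <- sum(-0.5 * log(2 * pi * sd^2) - (y - f)^2 / (2 * sd^2)) +
    (-0.5 * log(2 * pi * 0.04) - eta^2 / (2 * 0.04))

  got <- individual_joint_loglik(spec, list(dose = dose, times = times,
                                            values = y), eta, "pk")
  expect_equal(got, expected, tolerance = 1e-10)

  # eta dimension must match the active set
  expect_error(individual_joint_loglik(spec, list(dose = dose, times = times,
                                                  values = y),
                                       c(0, 0), "pk"),
               "length")
})

test_that("additive-error likelihood reduces to the plain normal density", {
  spec <- reference_population()
  spec$omega <- spec$omega[c("Ka")] # no PD random effects
  ind <- realize_individual(spec)
  sub <- list(dose = 10, times = 1.5, values = 4.0, pk = ind$pk)
  f <- inhibitory_effect(effect_site_conc(ind$pk, ind$pd, 10, 1.5), ind$pd)
  expected <- -0.5 * log(2 * pi * 0.15^2) - (4.0 - f)^2 / (2 * 0.15^2)
  expect_equal(individual_joint_loglik(spec, sub, numeric(0), "pd"), expected,
               tolerance = 1e-10)
})

test_that("FOCE objective collapses to the naive pooled -2LL without random effects", {
  spec <- reference_population()
  spec$omega[] <- 0
  ds <- simulate_study(reference_population(), small_design(4), seed = 2)
  fo <- foce_objective(spec, ds, "pk")

  fl <- mitipkpd:::flatten_stage(ds, "pk")
  manual <- 0
  for (i in seq_len(fl$n)) {
    idx <- (fl$starts[i] + 1):fl$starts[i + 1]
    f <- analytic_central_conc(typical_pk(), fl$doses[i], fl$times[idx])
    sd <- spec$sigma_pk * pmax(f, 1e-6)
    manual <- manual - 2 * sum(stats::dnorm(fl$ys[idx], f, sd, log = TRUE))
  }
  expect_equal(fo$objective, manual, tolerance = 1e-8)
})

test_that("FOCE -2LL agrees with exact marginalization on toy problems", {
  # one subject, one random effect, a handful of observations: the Laplace
  # approximation with a Gauss-Newton Hessian should be within 1% of exact
  # numeric quadrature for both error models
  des <- study_design(n_subjects = 1, dose = 10,
                      pk_times = c(0.25, 0.5, 1, 2, 3))

  spec <- reference_population()
  spec$omega <- c(V = 0.04)
  ds <- simulate_study(spec, des, seed = 9)
  fo <- foce_objective(spec, ds, "pk")
  o <- ds$obs[ds$obs$kind == "drug_conc" & ds$obs$value > 0 & !ds$obs$blq, ]
  sub <- list(dose = 10, times = o$time, values = o$value)
  marg <- stats::integrate(Vectorize(function(e)
    exp(individual_joint_loglik(spec, sub, e, "pk"))), -2, 2,
    rel.tol = 1e-10)
  expect_lt(abs(fo$objective - (-2 * log(marg$value))) /
              abs(-2 * log(marg$value)), 0.01)

  spec2 <- reference_population()
  spec2$omega <- c(E0 = 0.01)
  ds2 <- simulate_study(spec2, des, seed = 10)
  fo2 <- foce_objective(spec2, ds2, "pd")
  o2 <- ds2$obs[ds2$obs$kind == "glucose" & !ds2$obs$blq, ]
  sub2 <- list(dose = 10, times = o2$time, values = o2$value,
               pk = realize_individual(spec2)$pk)
  marg2 <- stats::integrate(Vectorize(function(e)
    exp(individual_joint_loglik(spec2, sub2, e, "pd"))), -1, 1,
    rel.tol = 1e-10)
  expect_lt(abs(fo2$objective - (-2 * log(marg2$value))) /
              abs(-2 * log(marg2$value)), 0.01)
})

test_that("independent subjects contribute additively to the objective", {
  spec <- reference_population()
  times <- c(0.25, 0.5, 1, 2, 3)
  prof <- analytic_central_conc(typical_pk(), 10, times)
  y <- prof * c(1.05, 0.92, 1.1, 0.97, 1.02)
  one <- toy_dataset(times, drug = y)
  two <- study_dataset(
    data.frame(subject = c("S001", "S002"), time = 0, amount = 10),
    rbind(data.frame(subject = "S001", time = times, kind = "drug_conc",
                     value = y, blq = FALSE),
          data.frame(subject = "S002", time = times, kind = "drug_conc",
                     value = y, blq = FALSE)))
  f1 <- foce_objective(spec, one, "pk")
  f2 <- foce_objective(spec, two, "pk")
  expect_equal(f2$objective, 2 * f1$objective, tolerance = 1e-8)
})

test_that("objective is invariant to subject relabeling and row order", {
  spec <- reference_population()
  ds <- simulate_study(spec, small_design(5), seed = 13)
  base <- foce_objective(spec, ds, "pk")$objective

  shuffled <- ds
  set.seed(1)
  perm <- sample(nrow(shuffled$obs))
  shuffled$obs <- shuffled$obs[perm, ]
  expect_equal(foce_objective(spec, shuffled, "pk")$objective, base,
               tolerance = 1e-10)

  relabeled <- ds
  map <- c(S001 = "Z9", S002 = "A1", S003 = "M5", S004 = "B2", S005 = "Q7")
  relabeled$obs$subject <- unname(map[relabeled$obs$subject])
  relabeled$doses$subject <- unname(map[relabeled$doses$subject])
  relabeled$subjects <- sort(unname(map))
  expect_equal(foce_objective(spec, relabeled, "pk")$objective, base,
               tolerance = 1e-8)
})

test_that("eta shrinkage follows its defining arithmetic", {
  omega <- c(Ka = 0.25)
  ebe_zero <- matrix(0, 10, 1, dimnames = list(NULL, "Ka"))
  expect_equal(unname(eta_shrinkage(ebe_zero, omega)["Ka"]), 1)

  # SD equal to sqrt(omega): no shrinkage
  v <- scale(stats::rnorm(50))[, 1] * sqrt(0.25)
  ebe_full <- matrix(v, ncol = 1, dimnames = list(NULL, "Ka"))
  expect_equal(unname(eta_shrinkage(ebe_full, omega)["Ka"]), 0,
               tolerance = 1e-10)

  # SD at 40% of sqrt(omega): shrinkage 0.6, above the 0.5 exclusion rule
  ebe_part <- matrix(v * 0.4, ncol = 1, dimnames = list(NULL, "Ka"))
  s <- eta_shrinkage(ebe_part, omega)
  expect_equal(unname(s["Ka"]), 0.6, tolerance = 1e-10)
  expect_identical(attr(s, "flagged"), "Ka")

  expect_error(eta_shrinkage(ebe_zero[1:2, , drop = FALSE], omega), "3 subjects")
  expect_error(eta_shrinkage(ebe_zero, c(Ka = 0)), "> 0")
})

test_that("typical values are recovered exactly from noiseless pooled data", {
  spec <- reference_population()
  spec$omega[] <- 0
  spec$sigma_pk <- 1e-4
  spec$sigma_pd <- 1e-4
  ds <- simulate_study(spec, small_design(4), seed = 6)

  init <- reference_population()
  init$tv[c("Ka", "V", "Tlag", "CL2")] <-
    init$tv[c("Ka", "V", "Tlag", "CL2")] * c(1.2, 0.85, 1.1, 0.9)
  init$sigma_pk <- 1e-4
  fit <- fit_population_pk(ds, init,
                           fixed = c("omega_Ka", "omega_V", "omega_Tlag",
                                     "omega_CL2", "sigma_pk", "CL", "V2"),
                           control = list(maxit = 2000, restarts = 4))
  for (p in c("Ka", "V", "Tlag", "CL2")) {
    expect_lt(abs(fit$estimates$tv[[p]] / spec$tv[[p]] - 1), 1e-3)
  }
})

test_that("the sequential PD stage refuses an unconverged PK fit", {
  spec <- reference_population()
  ds <- simulate_study(spec, small_design(4), seed = 2)
  fake <- evaluate_population(spec, ds, "pk")
  fake$converged <- FALSE
  expect_error(fit_population_pd(ds, fake, spec), "converge")
  expect_error(fit_population_pk(toy_dataset(c(0.5, 1), glucose = c(4, 4)),
                                 spec),
               "no usable drug_conc")
})
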