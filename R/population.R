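#' @title Random-effect parameterization
#' @description Parameters carrying inter-individual variability (log-normal,
#'   `param = tv * exp(eta)`). `V2`, `CL` and `IC50` are population constants
#'   with no random effect.
#' @keywords internal
#' @name random-effects
NULL

PARAM_NAMES <- c("Ka", "V", "V2", "CL", "CL2", "Tlag", "Ke0", "IC50", "Gam", "E0")
RE_NAMES <- c("Ka", "V", "Tlag", "CL2", "Ke0", "Gam", "E0")
RE_PK <- c("Ka", "V", "Tlag", "CL2")
RE_PD <- c("Ke0", "Gam", "E0")

#' Convert a coefficient of variation to a log-normal eta variance
#'
#' Uses the exact log-normal relation `omega = ln(1 + CV^2)` implied by the
#' `tv * exp(eta)` parameterization.
#'
#' @param cv coefficient of variation as a fraction (0.9195 for 91.95%)
#' @return variance of eta on the log scale
#' @export
cv_to_omega <- function(cv) {
  stopifnot(all(cv >= 0))
  log(1 + cv^2)
}

#' @rdname cv_to_omega
#' @param omega eta variance on the log scale
#' @export
omega_to_cv <- function(omega) {
  stopifnot(all(omega >= 0))
  sqrt(exp(omega) - 1)
}

#' Population parameter specification
#'
#' The estimand of the whole analysis: typical values for all ten structural
#' parameters, random-effect variances for the parameters with
#' inter-individual variability, and residual-error magnitudes (proportional
#' for drug concentration, additive for glucose).
#'
#' @param tv named numeric vector of typical values for
#'   `Ka, V, V2, CL, CL2, Tlag, Ke0, IC50, Gam, E0` (units as in
#'   [pk_params()] / [pd_params()])
#' @param omega named numeric vector of eta variances (log scale) for a
#'   subset of `Ka, V, Tlag, CL2, Ke0, Gam, E0`; parameters `V2`, `CL` and
#'   `IC50` admit no random effect
#' @param sigma_pk proportional residual SD for drug concentration
#'   (dimensionless fraction)
#' @param sigma_pd additive residual SD for glucose (mmol/L)
#' @return an object of class `population_spec`
#' @export
population_spec <- function(tv, omega, sigma_pk, sigma_pd) {
  tv <- unlist(tv)
  if (!setequal(names(tv), PARAM_NAMES)) {
    stop("tv must be named with exactly: ", paste(PARAM_NAMES, collapse = ", "),
         call. = FALSE)
  }
  tv <- tv[PARAM_NAMES]
  if (any(!is.finite(tv)) || any(tv[setdiff(PARAM_NAMES, "Tlag")] <= 0) ||
      tv[["Tlag"]] < 0) {
    stop("typical values must be positive (Tlag >= 0)", call. = FALSE)
  }
  omega <- unlist(omega)
  bad <- setdiff(names(omega), RE_NAMES)
  if (length(bad)) {
    stop("no random effect is defined for: ", paste(bad, collapse = ", "),
         " (V2, CL and IC50 are population constants)", call. = FALSE)
  }
  if (any(!is.finite(omega)) || any(omega < 0)) {
    stop("omega values must be non-negative variances", call. = FALSE)
  }
  if (!is.finite(sigma_pk) || sigma_pk <= 0 ||
      !is.finite(sigma_pd) || sigma_pd <= 0) {
    stop("sigma_pk and sigma_pd must be positive", call. = FALSE)
  }
  structure(list(tv = tv, omega = omega, sigma_pk = sigma_pk,
                 sigma_pd = sigma_pd),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Population PK-PD specification\n")
  cat("  typical values:\n")
  for (p in PARAM_NAMES) {
    om <- if (p %in% names(x$omega)) {
      sprintf("  CV %.1f%%", 100 * omega_to_cv(x$omega[[p]]))
    } else ""
    cat(sprintf("    %-4s %10.4g%s\n", p, x$tv[[p]], om))
  }
  cat(sprintf("  residual error: proportional %.3g (drug), additive %.3g mmol/L (glucose)\n",
              x$sigma_pk, x$sigma_pd))
  invisible(x)
}

#' Realize one individual's structural parameters
#'
#' Applies log-normal random effects to the typical values:
#' `param = tv * exp(eta)` for parameters with inter-individual variability;
#' `V2`, `CL` and `IC50` equal their typical values exactly.
#'
#' @param spec a [population_spec()]
#' @param eta named numeric vector of random effects (missing names treated
#'   as 0); supplying an eta for `V2`, `CL` or `IC50` is an error
#' @return list with elements `pk` ([pk_params()]) and `pd` ([pd_params()])
#' @export
realize_individual <- function(spec, eta = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(eta)) eta <- numeric(0)
  bad <- setdiff(names(eta), RE_NAMES)
  if (length(bad)) {
    stop("eta supplied for parameter(s) without a random effect: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  full <- stats::setNames(numeric(length(PARAM_NAMES)), PARAM_NAMES)
  full[names(eta)] <- eta
  v <- spec$tv * exp(full)
  list(pk = pk_params(Ka = v[["Ka"]], V = v[["V"]], V2 = v[["V2"]],
                      CL = v[["CL"]], CL2 = v[["CL2"]], Tlag = v[["Tlag"]]),
       pd = pd_params(Ke0 = v[["Ke0"]], IC50 = v[["IC50"]],
                      Gam = v[["Gam"]], E0 = v[["E0"]]))
}

# Deterministic per-subject RNG substream: adding subjects never perturbs the
# draws of earlier subjects.
subject_seed <- function(master, i) {
  (abs(as.integer(master)) %% 1000000L) * 2039L + as.integer(i)
}

# Draw the full eta vector (all RE_NAMES, zeros where omega is absent) plus
# residual-error normals for one subject from its substream.
draw_subject <- function(spec, master, i, n_pk, n_pd) {
  om <- stats::setNames(numeric(length(RE_NAMES)), RE_NAMES)
  om[names(spec$omega)] <- spec$omega
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subject_seed(master, i))
  eta <- stats::rnorm(length(RE_NAMES)) * sqrt(om)
  names(eta) <- RE_NAMES
  list(eta = eta,
       eps_pk = stats::rnorm(n_pk),
       eps_pd = stats::rnorm(n_pd))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Sample individual parameter sets from a population
#'
#' Draws each subject's eta vector independently from zero-mean normals with
#' the specified variances and realizes the structural parameters.
#' Reproducible: subject `i` uses a dedicated substream derived from the
#' master seed, so enlarging `n` never changes earlier subjects.
#'
#' @param spec a [population_spec()]
#' @param n number of subjects, >= 1
#' @param seed integer master seed
#' @return list of length `n`; each element has `pk`, `pd` and `eta`
#' @export
sample_population <- function(spec, n, seed) {
  stopifnot(inherits(spec, "population_spec"), n >= 1)
  lapply(seq_len(n), function(i) {
    d <- draw_subject(spec, seed, i, 0, 0)
    ind <- realize_individual(spec, d$eta[names(spec$omega)])
    ind$eta <- d$eta
    ind
  })
}

#' Study design
#'
#' @param n_subjects number of subjects
#' @param dose single oral dose (mg), > 0
#' @param pk_times drug-concentration sampling times (h), sorted from 0
#' @param pd_times glucose sampling times (h), sorted from 0
#' @return an object of class `study_design`
#' @export
study_design <- function(n_subjects, dose, pk_times, pd_times = pk_times) {
  stopifnot(n_subjects >= 1, dose > 0)
  for (tt in list(pk_times, pd_times)) {
    if (length(tt) < 1 || any(tt < 0) || is.unsorted(tt)) {
      stop("sampling times must be sorted and non-negative", call. = FALSE)
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), dose = dose,
                 pk_times = pk_times, pd_times = pd_times),
            class = "study_design")
}

subject_ids <- function(n) sprintf("S%03d", seq_len(n))

#' Simulate a full population study
#'
#' For each virtual subject: sample the eta vector, evaluate the individual
#' concentration and glucose trajectories at the design times, and add
#' residual error — proportional on concentration, additive on glucose.
#' Pre-lag and pre-dose concentrations are exactly zero before noise; values
#' driven negative by noise are truncated at zero and flagged, and drug
#' observations below the quantification limit are flagged.
#'
#' @param spec a [population_spec()]
#' @param design a [study_design()]
#' @param seed integer master seed
#' @param blq_limit lower limit of quantification for drug concentration
#'   (mg/L); default 2e-4 (0.2 ng/mL)
#' @return a `study_dataset`: list with `doses`, `obs` and `subjects`
#' @export
simulate_study <- function(spec, design, seed, blq_limit = 2e-4) {
  stopifnot(inherits(spec, "population_spec"), inherits(design, "study_design"))
  ids <- subject_ids(design$n_subjects)
  doses <- data.frame(subject = ids, time = 0, amount = design$dose,
                      stringsAsFactors = FALSE)
  obs_list <- vector("list", design$n_subjects)
  for (i in seq_len(design$n_subjects)) {
    d <- draw_subject(spec, seed, i, length(design$pk_times),
                      length(design$pd_times))
    ind <- realize_individual(spec, d$eta[names(spec$omega)])
    conc <- tryCatch(
      analytic_central_conc(ind$pk, design$dose, design$pk_times),
      error = function(e) simulate_profile(ind$pk, ind$pd, design$dose,
                                           design$pk_times)$C)
    ce <- tryCatch(
      effect_site_conc(ind$pk, ind$pd, design$dose, design$pd_times),
      error = function(e) simulate_profile(ind$pk, ind$pd, design$dose,
                                           design$pd_times)$Ce)
    gluc <- inhibitory_effect(ce, ind$pd)
    y_pk <- conc * (1 + spec$sigma_pk * d$eps_pk)
    y_pd <- gluc + spec$sigma_pd * d$eps_pd
    blq_pk <- y_pk < blq_limit
    trunc_pd <- y_pd < 0
    y_pk <- pmax(y_pk, 0)
    y_pd <- pmax(y_pd, 0)
    obs_list[[i]] <- rbind(
      data.frame(subject = ids[i], time = design$pk_times, kind = "drug_conc",
                 value = y_pk, blq = blq_pk, stringsAsFactors = FALSE),
      data.frame(subject = ids[i], time = design$pd_times, kind = "glucose",
                 value = y_pd, blq = trunc_pd, stringsAsFactors = FALSE))
  }
  obs <- do.call(rbind, obs_list)
  obs <- obs[order(obs$subject, obs$time, obs$kind), , drop = FALSE]
  rownames(obs) <- NULL
  study_dataset(doses, obs)
}

#' Construct and validate a study dataset
#'
#' @param doses data.frame with columns `subject`, `time`, `amount`
#' @param obs data.frame with columns `subject`, `time`, `kind`
#'   (`"drug_conc"` or `"glucose"`), `value`, `blq`
#' @return validated `study_dataset`
#' @export
study_dataset <- function(doses, obs) {
  stopifnot(all(c("subject", "time", "amount") %in% names(doses)),
            all(c("subject", "time", "kind", "value", "blq") %in% names(obs)))
  if (any(doses$amount <= 0) || any(doses$time < 0)) {
    stop("dose events need amount > 0 and time >= 0", call. = FALSE)
  }
  if (any(obs$time < 0)) stop("observation times must be >= 0", call. = FALSE)
  if (!all(obs$kind %in% c("drug_conc", "glucose"))) {
    stop("observation kind must be 'drug_conc' or 'glucose'", call. = FALSE)
  }
  if (any(obs$value < 0 & !obs$blq)) {
    stop("negative observation values must carry the below-limit flag",
         call. = FALSE)
  }
  key <- paste(obs$subject, obs$time, obs$kind)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, time, kind) observation: ",
         key[anyDuplicated(key)], call. = FALSE)
  }
  subjects <- sort(unique(c(doses$subject, obs$subject)))
  missing_dose <- setdiff(unique(obs$subject), doses$subject)
  if (length(missing_dose)) {
    stop("subjects with observations but no dose event: ",
         paste(missing_dose, collapse = ", "), call. = FALSE)
  }
  structure(list(doses = doses, obs = obs, subjects = subjects),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Study dataset: %d subjects, %d dose events, %d observations\n",
              length(x$subjects), nrow(x$doses), nrow(x$obs)))
  cat(sprintf("  drug_conc: %d rows, glucose: %d rows, flagged: %d\n",
              sum(x$obs$kind == "drug_conc"), sum(x$obs$kind == "glucose"),
              sum(x$obs$blq)))
  invisible(x)
}
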