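# Population estimation by FOCE maximum likelihood, run sequentially:
# PK stage first (proportional residual error, with interaction), then the
# PD stage conditional on each subject's empirical-Bayes PK parameters
# (IPP sequential strategy).

PK_PARAM_ORDER <- c("Ka", "V", "V2", "CL", "CL2", "Tlag")
PD_PARAM_ORDER <- c("Ke0", "IC50", "Gam", "E0")

stage_re_names <- function(stage) if (stage == "pk") RE_PK else RE_PD

# 0-based index of a random-effect parameter inside the stage's tv vector
stage_re_index <- function(stage, names) {
  ord <- if (stage == "pk") PK_PARAM_ORDER else PD_PARAM_ORDER
  as.integer(match(names, ord) - 1L)
}

# Filter and flatten one stage's observations into contiguous per-subject
# blocks (sorted by subject id).  Exclusions: flagged (below-limit/truncated)
# rows always; zero drug concentrations (pre-dose / pre-lag) from the PK
# likelihood.
flatten_stage <- function(dataset, stage) {
  stopifnot(inherits(dataset, "study_dataset"))
  kind <- if (stage == "pk") "drug_conc" else "glucose"
  keep <- dataset$obs$kind == kind & !dataset$obs$blq
  if (stage == "pk") keep <- keep & dataset$obs$value > 0
  rows <- which(keep)
  if (!length(rows)) {
    stop("no usable ", kind, " observations in the dataset", call. = FALSE)
  }
  o <- dataset$obs[rows, , drop = FALSE]
  ids <- sort(unique(o$subject))
  ord <- order(match(o$subject, ids), o$time)
  o <- o[ord, , drop = FALSE]
  rows <- rows[ord]
  starts <- cumsum(c(0L, as.integer(table(factor(o$subject, levels = ids)))))
  dose_map <- tapply(dataset$doses$amount, dataset$doses$subject, sum)
  doses <- as.numeric(dose_map[ids])
  if (any(is.na(doses))) {
    stop("subjects lacking a dose event: ",
         paste(ids[is.na(doses)], collapse = ", "), call. = FALSE)
  }
  list(ids = ids, n = length(ids), doses = doses, starts = starts,
       times = o$time, ys = o$value, rows = rows)
}

# individual PK parameter matrix (6 x n, column = subject) from a PK fit's
# empirical Bayes etas, aligned to `ids`
ipk_matrix <- function(pk_fit, ids) {
  miss <- setdiff(ids, rownames(pk_fit$ebe))
  if (length(miss)) {
    stop("subjects missing from the PK fit's empirical Bayes estimates: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tv <- pk_fit$estimates$tv[PK_PARAM_ORDER]
  m <- matrix(rep(tv, length(ids)), nrow = 6,
              dimnames = list(PK_PARAM_ORDER, ids))
  for (p in colnames(pk_fit$ebe)) {
    m[p, ] <- m[p, ] * exp(pk_fit$ebe[ids, p])
  }
  m
}

#' Joint log-likelihood of one subject's data and random effects
#'
#' The inner objective of FOCE: `log p(y | eta) + log p(eta)`.  The PK stage
#' uses the subject's drug concentrations with proportional residual error
#' (variance floored at a predicted concentration of 1e-6 mg/L); the PD
#' stage uses glucose with additive error and the subject's fixed PK
#' parameters.
#'
#' @param spec a [population_spec()]; its `omega` entries for the stage's
#'   random-effect parameters define the eta vector (in the order
#'   `Ka, V, Tlag, CL2` for PK and `Ke0, Gam, E0` for PD)
#' @param subject_data list with `dose` (mg), `times` (h), `values`
#'   (observations of the stage's kind) and, for the PD stage, `pk`
#'   (the subject's [pk_params()])
#' @param eta numeric vector of random effects matching the stage's active
#'   set
#' @param stage `"pk"` or `"pd"`
#' @return scalar log-likelihood
#' @export
individual_joint_loglik <- function(spec, subject_data, eta,
                                    stage = c("pk", "pd")) {
  stage <- match.arg(stage)
  stopifnot(inherits(spec, "population_spec"))
  active <- intersect(stage_re_names(stage), names(spec$omega)[spec$omega > 0])
  if (length(eta) != length(active)) {
    stop("eta must have length ", length(active), " (active effects: ",
         paste(active, collapse = ", "), ")", call. = FALSE)
  }
  omega <- spec$omega[active]
  t <- subject_data$times
  y <- subject_data$values
  if (stage == "pk") {
    tv <- spec$tv[PK_PARAM_ORDER]
    tv[active] <- tv[active] * exp(eta)
    pk <- do.call(pk_params, as.list(tv))
    f <- cpp_conc(as_numeric_pk(pk), subject_data$dose, t)
    sd <- spec$sigma_pk * pmax(f, 1e-6)
  } else {
    if (is.null(subject_data$pk)) {
      stop("PD stage requires the subject's pk params in subject_data$pk",
           call. = FALSE)
    }
    tv <- spec$tv[PD_PARAM_ORDER]
    tv[active] <- tv[active] * exp(eta)
    ce <- cpp_ce(as_numeric_pk(subject_data$pk), tv[["Ke0"]],
                 subject_data$dose, t)
    f <- cpp_effect(ce, tv[["IC50"]], tv[["Gam"]], tv[["E0"]])
    sd <- rep(spec$sigma_pd, length(t))
  }
  sum(stats::dnorm(y, f, sd, log = TRUE)) +
    sum(stats::dnorm(eta, 0, sqrt(omega), log = TRUE))
}

#' FOCE approximate -2 log-likelihood of a dataset
#'
#' For each subject, locates the conditional mode of the random effects
#' (maximizing [individual_joint_loglik()]), applies the Laplace-type
#' second-order approximation with a first-order (Gauss-Newton) Hessian —
#' with interaction for the proportional PK error — and sums `-2 log` of the
#' approximate marginal likelihood over subjects.
#'
#' @param spec a [population_spec()] at which to evaluate
#' @param dataset a `study_dataset`
#' @param stage `"pk"` or `"pd"`
#' @param ipk for the PD stage: a 6 x n matrix of individual PK parameters
#'   (rows `Ka, V, V2, CL, CL2, Tlag`, columns named by subject), e.g. from
#'   a PK fit via the empirical Bayes estimates; defaults to typical values
#'   for every subject
#' @param warm optional n x p matrix of starting values for the conditional
#'   modes
#' @return list with `objective` (-2LL), `per_subject` contributions, `eta`
#'   (matrix of conditional modes), `ids`
#' @export
foce_objective <- function(spec, dataset, stage = c("pk", "pd"), ipk = NULL,
                           warm = NULL) {
  stage <- match.arg(stage)
  fl <- flatten_stage(dataset, stage)
  active <- intersect(stage_re_names(stage), names(spec$omega)[spec$omega > 0])
  res <- foce_eval(spec, fl, stage, active, ipk = ipk, warm = warm)
  list(objective = res$objective, per_subject = as.numeric(res$per_subject),
       eta = res$eta, ids = fl$ids)
}

# low-level FOCE evaluation on flattened data
foce_eval <- function(spec, fl, stage, active, ipk = NULL, warm = NULL,
                      inner_ftol = 1e-11, inner_maxeval = 600) {
  p <- length(active)
  if (is.null(warm)) warm <- matrix(0, fl$n, p)
  if (stage == "pk") {
    tv <- spec$tv[PK_PARAM_ORDER]
    sigma <- spec$sigma_pk
    pkmat <- matrix(0, 0, 0)
    stage_i <- 1L
  } else {
    tv <- spec$tv[PD_PARAM_ORDER]
    sigma <- spec$sigma_pd
    if (is.null(ipk)) {
      pkmat <- matrix(rep(spec$tv[PK_PARAM_ORDER], fl$n), nrow = 6,
                      dimnames = list(PK_PARAM_ORDER, fl$ids))
    } else {
      pkmat <- ipk[PK_PARAM_ORDER, fl$ids, drop = FALSE]
    }
    stage_i <- 2L
  }
  out <- cpp_foce(stage_i, as.numeric(tv), stage_re_index(stage, active),
                  as.numeric(spec$omega[active]), sigma, fl$doses,
                  as.integer(fl$starts), fl$times, fl$ys, pkmat, warm,
                  inner_ftol, inner_maxeval)
  eta <- out$eta
  dimnames(eta) <- list(fl$ids, active)
  list(objective = out$objective, per_subject = out$per_subject, eta = eta)
}

#' Eta-shrinkage of empirical Bayes estimates
#'
#' `shrinkage = 1 - SD(EBE eta) / sqrt(omega)` per parameter.  Values above
#' 0.5 indicate that the individual data carry little information about that
#' random effect (the conventional exclusion threshold).
#'
#' @param ebe n x p matrix of empirical Bayes eta estimates (columns named
#'   by parameter)
#' @param omega named vector of eta variances, > 0, covering the columns
#' @return named vector of shrinkage fractions with attribute `flagged`
#'   naming parameters exceeding 0.5
#' @export
eta_shrinkage <- function(ebe, omega) {
  ebe <- as.matrix(ebe)
  if (nrow(ebe) < 3) {
    stop("shrinkage is undefined for fewer than 3 subjects", call. = FALSE)
  }
  pars <- colnames(ebe)
  if (is.null(pars) || !all(pars %in% names(omega))) {
    stop("ebe columns must be named and covered by omega", call. = FALSE)
  }
  if (any(omega[pars] <= 0)) {
    stop("omega must be > 0 for every reported parameter", call. = FALSE)
  }
  shr <- 1 - apply(ebe, 2, stats::sd) / sqrt(omega[pars])
  names(shr) <- pars
  attr(shr, "flagged") <- pars[shr > 0.5]
  shr
}

# ---- outer optimization ----------------------------------------------------

fit_free_names <- function(stage) {
  if (stage == "pk") {
    c(PK_PARAM_ORDER, paste0("omega_", RE_PK), "sigma_pk")
  } else {
    c(PD_PARAM_ORDER, paste0("omega_", RE_PD), "sigma_pd")
  }
}

# all fit parameters are positive: optimize on the log scale
spec_to_theta <- function(spec, stage) {
  re <- stage_re_names(stage)
  om <- stats::setNames(rep(0.09, length(re)), re)  # fallback 30% CV start
  present <- intersect(names(spec$omega), re)
  om[present] <- pmax(spec$omega[present], 1e-4)
  if (stage == "pk") {
    th <- c(spec$tv[PK_PARAM_ORDER], om, sigma_pk = spec$sigma_pk)
  } else {
    th <- c(spec$tv[PD_PARAM_ORDER], om, sigma_pd = spec$sigma_pd)
  }
  stats::setNames(log(as.numeric(th)), fit_free_names(stage))
}

theta_to_spec <- function(theta, base, stage) {
  v <- exp(theta)
  spec <- base
  re <- stage_re_names(stage)
  tv_names <- if (stage == "pk") PK_PARAM_ORDER else PD_PARAM_ORDER
  spec$tv[tv_names] <- v[tv_names]
  om <- spec$omega
  for (r in re) om[r] <- v[[paste0("omega_", r)]]
  spec$omega <- om[intersect(RE_NAMES, names(om))]
  if (stage == "pk") spec$sigma_pk <- v[["sigma_pk"]]
  else spec$sigma_pd <- v[["sigma_pd"]]
  spec
}

default_fit_control <- function(control) {
  defaults <- list(maxit = 500, reltol = 1e-8, restarts = 8,
                   pass_tol = 0.05, pooled_init = TRUE, n_starts = 1,
                   start_seed = 1, inner_ftol = 1e-10, inner_maxeval = 600,
                   trace = FALSE)
  defaults[names(control)] <- control
  defaults
}

# shared outer FOCE optimization for both stages
run_foce_fit <- function(dataset, init, stage, fixed, control, ipk = NULL) {
  ctl <- default_fit_control(control)
  fl <- flatten_stage(dataset, stage)
  free_all <- fit_free_names(stage)
  bad <- setdiff(fixed, free_all)
  if (length(bad)) {
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  re <- stage_re_names(stage)
  theta_full <- spec_to_theta(init, stage)

  # naive-pooled least-squares initializer for the typical values
  # (all etas at zero; no inner optimization, so it is cheap)
  if (isTRUE(ctl$pooled_init)) {
    pooled_free <- setdiff(if (stage == "pk") PK_PARAM_ORDER else
                           PD_PARAM_ORDER, fixed)
    if (length(pooled_free)) {
      pooled_obj <- function(th) {
        full <- theta_full
        full[pooled_free] <- th
        sp <- theta_to_spec(full, init, stage)
        sp$omega[] <- 0
        r <- try(foce_eval(sp, fl, stage, character(0), ipk = ipk),
                 silent = TRUE)
        if (inherits(r, "try-error") || !is.finite(r$objective)) 1e10
        else r$objective
      }
      ans <- stats::optim(theta_full[pooled_free], pooled_obj,
                          method = "Nelder-Mead",
                          control = list(maxit = 800, reltol = 1e-10))
      theta_full[pooled_free] <- ans$par
    }
  }

  free <- setdiff(free_all, fixed)
  env <- new.env()
  env$warm <- matrix(0, fl$n, length(re))
  env$best <- Inf
  env$best_theta <- theta_full
  env$trace <- numeric(0)
  env$neval <- 0L
  obj <- function(th) {
    full <- theta_full
    full[free] <- th
    sp <- theta_to_spec(full, init, stage)
    r <- try(foce_eval(sp, fl, stage, re, ipk = ipk, warm = env$warm,
                       inner_ftol = ctl$inner_ftol,
                       inner_maxeval = ctl$inner_maxeval),
             silent = TRUE)
    env$neval <- env$neval + 1L
    if (inherits(r, "try-error") || !is.finite(r$objective)) return(1e10)
    env$warm <- unname(r$eta)
    if (r$objective < env$best) {
      env$best <- r$objective
      env$best_theta <- full
      env$trace <- c(env$trace, r$objective)
      if (isTRUE(ctl$trace)) {
        message(sprintf("  FOCE %s: -2LL %.4f after %d evaluations",
                        stage, r$objective, env$neval))
      }
    }
    r$objective
  }

  # optional multi-start: additional starts at +/-30% log-perturbations,
  # winner by lowest objective (ties broken by start index)
  starts <- list(theta_full[free])
  if (ctl$n_starts > 1) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(ctl$start_seed)
    for (k in seq_len(ctl$n_starts - 1)) {
      starts[[k + 1]] <- theta_full[free] +
        stats::runif(length(free), -log(1.3), log(1.3))
    }
  }
  best_val <- Inf; best_par <- starts[[1]]; conv <- 1L
  for (s in seq_along(starts)) {
    par <- starts[[s]]
    if (!length(par)) { best_par <- par; best_val <- obj(par); conv <- 0L; break }
    prev <- Inf; val <- Inf; conv_here <- 1L
    for (pass in seq_len(ctl$restarts)) {
      ans <- stats::optim(par, obj, method = "Nelder-Mead",
                          control = list(maxit = ctl$maxit,
                                         reltol = ctl$reltol))
      par <- ans$par
      val <- ans$value
      conv_here <- ans$convergence
      if (conv_here == 0L) break # simplex met its relative tolerance
      # a full restart that improves -2LL by less than the pass tolerance
      # (absolute floor 0.05 -- far below the 3.84 chi-square unit of one
      # parameter -- or 1e-4 of the objective magnitude, whichever is
      # larger) is a statistically meaningless gain: declare convergence
      if (abs(prev - val) <= max(ctl$pass_tol, 1e-4 * abs(val))) {
        conv_here <- 0L
        break
      }
      prev <- val
    }
    if (val < best_val) { best_val <- val; best_par <- par; conv <- conv_here }
  }
  theta_hat <- theta_full
  theta_hat[free] <- best_par
  est <- theta_to_spec(theta_hat, init, stage)
  final <- foce_eval(est, fl, stage, re, ipk = ipk, warm = env$warm,
                     inner_ftol = ctl$inner_ftol,
                     inner_maxeval = ctl$inner_maxeval)
  shr <- eta_shrinkage(final$eta, est$omega)
  structure(list(estimates = est, stage = stage, ebe = final$eta,
                 objective = final$objective, converged = conv == 0L,
                 n_evaluations = env$neval, shrinkage = shr, se = NULL,
                 trace = env$trace, ids = fl$ids,
                 ipk = if (stage == "pd") ipk else NULL),
            class = "pkpd_fit")
}

#' Fit the population PK model by FOCE
#'
#' Estimates the typical values `Ka, V, V2, CL, CL2, Tlag`, the eta
#' variances of `Ka, V, Tlag, CL2` and the proportional residual SD by
#' minimizing the FOCE -2 log-likelihood on the log-transformed scale
#' (Nelder-Mead outer search with simplex restarts, preceded by a
#' naive-pooled least-squares refinement of the typical values).
#'
#' @param dataset a `study_dataset` with drug concentration observations
#' @param init a [population_spec()] of starting values
#' @param fixed character vector of parameters to hold at their `init`
#'   values (names from `Ka, V, V2, CL, CL2, Tlag, omega_Ka, omega_V,
#'   omega_Tlag, omega_CL2, sigma_pk`)
#' @param control list overriding defaults: `maxit` (500 outer iterations
#'   per pass), `reltol` (1e-8), `restarts`, `pooled_init`, `n_starts`,
#'   `start_seed`, `inner_ftol`, `inner_maxeval`, `trace`
#' @return a `pkpd_fit`: estimates, empirical Bayes etas, -2LL objective,
#'   convergence flag, per-parameter shrinkage
#' @export
fit_population_pk <- function(dataset, init, fixed = character(0),
                              control = list()) {
  stopifnot(inherits(init, "population_spec"))
  run_foce_fit(dataset, init, "pk", fixed, control)
}

#' Fit the population PD model by FOCE, sequentially after the PK fit
#'
#' Fixes each subject's PK parameters at their empirical Bayes individual
#' values from the PK fit (IPP sequential strategy), then estimates the
#' typical values `Ke0, IC50, Gam, E0`, the eta variances of
#' `Ke0, Gam, E0` and the additive residual SD from the glucose data.
#'
#' @param dataset a `study_dataset` with glucose observations
#' @param pk_fit a converged `pkpd_fit` from [fit_population_pk()]
#' @param init a [population_spec()] of starting values for the PD side
#' @inheritParams fit_population_pk
#' @return a `pkpd_fit` (PD stage); `estimates` carries the PK typical
#'   values of `pk_fit` together with the fitted PD values
#' @export
fit_population_pd <- function(dataset, pk_fit, init, fixed = character(0),
                              control = list()) {
  stopifnot(inherits(init, "population_spec"))
  if (!inherits(pk_fit, "pkpd_fit") || pk_fit$stage != "pk") {
    stop("pk_fit must be a PK-stage pkpd_fit", call. = FALSE)
  }
  if (!isTRUE(pk_fit$converged)) {
    stop("PK fit did not converge; refusing to run the sequential PD stage",
         call. = FALSE)
  }
  fl <- flatten_stage(dataset, "pd")
  ipk <- ipk_matrix(pk_fit, fl$ids)
  # carry the whole fitted PK side into the PD result's estimates
  base <- init
  base$tv[PK_PARAM_ORDER] <- pk_fit$estimates$tv[PK_PARAM_ORDER]
  om <- base$omega
  pk_om <- intersect(names(pk_fit$estimates$omega), RE_PK)
  om[pk_om] <- pk_fit$estimates$omega[pk_om]
  base$omega <- om[intersect(RE_NAMES, names(om))]
  base$sigma_pk <- pk_fit$estimates$sigma_pk
  fit <- run_foce_fit(dataset, base, "pd", fixed, control, ipk = ipk)
  fit$pk_fit_objective <- pk_fit$objective
  fit
}

#' Evaluate a population model on a dataset without fitting
#'
#' Computes the FOCE objective and the empirical Bayes etas at a fixed
#' specification — useful for diagnostics under a known (e.g. generating)
#' model and as the starting point of profile comparisons.
#'
#' @inheritParams foce_objective
#' @return a `pkpd_fit` with `converged = TRUE` and no optimization trace
#' @export
evaluate_population <- function(spec, dataset, stage = c("pk", "pd"),
                                ipk = NULL) {
  stage <- match.arg(stage)
  fl <- flatten_stage(dataset, stage)
  active <- intersect(stage_re_names(stage), names(spec$omega)[spec$omega > 0])
  res <- foce_eval(spec, fl, stage, active, ipk = ipk)
  shr <- if (length(active) && fl$n >= 3) {
    eta_shrinkage(res$eta, spec$omega)
  } else NULL
  structure(list(estimates = spec, stage = stage, ebe = res$eta,
                 objective = res$objective, converged = TRUE,
                 n_evaluations = 1L, shrinkage = shr, se = NULL,
                 trace = numeric(0), ids = fl$ids,
                 ipk = if (stage == "pd") ipk else NULL),
            class = "pkpd_fit")
}

#' @export
print.pkpd_fit <- function(x, ...) {
  cat(sprintf("Population %s fit (FOCE): -2LL = %.3f, %sconverged, %d evaluations\n",
              toupper(x$stage), x$objective,
              if (x$converged) "" else "NOT ", x$n_evaluations))
  est <- x$estimates
  pars <- if (x$stage == "pk") PK_PARAM_ORDER else PD_PARAM_ORDER
  for (p in pars) {
    om <- if (p %in% names(est$omega) && est$omega[[p]] > 0) {
      sprintf("  CV %.1f%%", 100 * omega_to_cv(est$omega[[p]]))
    } else ""
    cat(sprintf("  tv%-4s %10.4g%s\n", p, est$tv[[p]], om))
  }
  sig <- if (x$stage == "pk") est$sigma_pk else est$sigma_pd
  cat(sprintf("  sigma_%s %.4g\n", x$stage, sig))
  if (!is.null(x$shrinkage)) {
    cat("  eta-shrinkage:",
        paste(sprintf("%s %.2f", names(x$shrinkage), x$shrinkage),
              collapse = ", "), "\n")
    fl <- attr(x$shrinkage, "flagged")
    if (length(fl)) {
      cat("  (> 0.5, conventionally dropped:", paste(fl, collapse = ", "), ")\n")
    }
  }
  invisible(x)
}
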