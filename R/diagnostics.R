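# Model-evaluation quantities: population and individual predictions and
# conditional weighted residuals under the FOCE linearization.

# individual model prediction for one subject at a given eta
predict_subject <- function(stage, spec, active, eta, dose, times, pk = NULL) {
  if (stage == "pk") {
    tv <- spec$tv[PK_PARAM_ORDER]
    tv[active] <- tv[active] * exp(eta)
    cpp_conc(as.numeric(tv), dose, times)
  } else {
    tv <- spec$tv[PD_PARAM_ORDER]
    tv[active] <- tv[active] * exp(eta)
    ce <- cpp_ce(as.numeric(pk), tv[["Ke0"]], dose, times)
    cpp_effect(ce, tv[["IC50"]], tv[["Gam"]], tv[["E0"]])
  }
}

# observations retained by the stage's likelihood, per subject, plus the
# ingredients for linearization
diag_context <- function(fit, dataset) {
  stage <- fit$stage
  fl <- flatten_stage(dataset, stage)
  miss <- setdiff(fl$ids, rownames(fit$ebe))
  if (length(miss)) {
    stop("subjects missing from the fit's empirical Bayes estimates: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  spec <- fit$estimates
  active <- colnames(fit$ebe)
  list(stage = stage, fl = fl, spec = spec, active = active,
       sigma = if (stage == "pk") spec$sigma_pk else spec$sigma_pd)
}

subject_slice <- function(fl, i) {
  idx <- (fl$starts[i] + 1):fl$starts[i + 1]
  list(times = fl$times[idx], ys = fl$ys[idx], dose = fl$doses[i], idx = idx)
}

#' Population and individual predictions
#'
#' `PRED` is the model evaluated at the population typical values (all etas
#' zero — for the PD stage, typical PK as well); `IPRED` evaluates at the
#' subject's empirical Bayes etas (and, for the PD stage, the subject's
#' individual PK parameters).
#'
#' @param fit a `pkpd_fit`
#' @param dataset the `study_dataset` the fit was (or could be) run on
#' @return data.frame with one row per retained observation: `subject`,
#'   `IVAR` (time, h), `kind`, `DV`, `PRED`, `IPRED`
#' @export
population_predictions <- function(fit, dataset) {
  stopifnot(inherits(fit, "pkpd_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  cx <- diag_context(fit, dataset)
  out <- vector("list", cx$fl$n)
  for (i in seq_len(cx$fl$n)) {
    id <- cx$fl$ids[i]
    s <- subject_slice(cx$fl, i)
    eta <- fit$ebe[id, ]
    typ_pk <- as.numeric(cx$spec$tv[PK_PARAM_ORDER])
    pred <- predict_subject(cx$stage, cx$spec, cx$active,
                            numeric(length(cx$active)), s$dose, s$times,
                            pk = typ_pk)
    ipred <- predict_subject(cx$stage, cx$spec, cx$active, eta, s$dose,
                             s$times,
                             pk = if (cx$stage == "pd") fit$ipk[, id] else NULL)
    out[[i]] <- data.frame(subject = id, IVAR = s$times,
                           kind = if (cx$stage == "pk") "drug_conc" else "glucose",
                           DV = s$ys, PRED = pred, IPRED = ipred,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# symmetric inverse square root with eigenvalue clamping
inv_sqrt_spd <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  vals <- e$values
  floor_val <- max(vals) * 1e-10
  if (any(vals < floor_val)) {
    warning("near-singular marginal covariance regularized in CWRES")
    vals <- pmax(vals, floor_val)
  }
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Conditional weighted residuals (CWRES)
#'
#' FOCE-linearized residuals: the subject model is expanded to first order
#' around the empirical Bayes eta, giving the marginal approximation
#' `E[y] = f(eta_hat) - F eta_hat` and
#' `Cov[y] = F Omega F' + R(eta_hat)` (residual variance evaluated at the
#' conditional mode — interaction for the proportional PK error), and
#' `CWRES = Cov^{-1/2} (y - E[y])`.  Approximately standard normal when the
#' model is correct.
#'
#' @inheritParams population_predictions
#' @return data.frame with `subject`, `IVAR`, `kind`, `DV`, `CWRES`
#' @export
cwres <- function(fit, dataset) {
  stopifnot(inherits(fit, "pkpd_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  cx <- diag_context(fit, dataset)
  p <- length(cx$active)
  omega <- if (p) diag(cx$spec$omega[cx$active], p) else NULL
  out <- vector("list", cx$fl$n)
  h <- 1e-4
  for (i in seq_len(cx$fl$n)) {
    id <- cx$fl$ids[i]
    s <- subject_slice(cx$fl, i)
    eta <- as.numeric(fit$ebe[id, ])
    pkfix <- if (cx$stage == "pd") fit$ipk[, id] else NULL
    fhat <- predict_subject(cx$stage, cx$spec, cx$active, eta, s$dose,
                            s$times, pk = pkfix)
    m <- length(s$times)
    rvar <- if (cx$stage == "pk") {
      (cx$sigma * pmax(fhat, 1e-6))^2
    } else rep(cx$sigma^2, m)
    if (p) {
      F <- matrix(0, m, p)
      for (k in seq_len(p)) {
        ep <- eta; ep[k] <- eta[k] + h
        em <- eta; em[k] <- eta[k] - h
        F[, k] <- (predict_subject(cx$stage, cx$spec, cx$active, ep, s$dose,
                                   s$times, pk = pkfix) -
                   predict_subject(cx$stage, cx$spec, cx$active, em, s$dose,
                                   s$times, pk = pkfix)) / (2 * h)
      }
      Ey <- fhat - as.numeric(F %*% eta)
      V <- F %*% omega %*% t(F) + diag(rvar, m)
      w <- inv_sqrt_spd(V)
      cw <- as.numeric(w %*% (s$ys - Ey))
    } else {
      cw <- (s$ys - fhat) / sqrt(rvar)
    }
    out[[i]] <- data.frame(subject = id, IVAR = s$times,
                           kind = if (cx$stage == "pk") "drug_conc" else "glucose",
                           DV = s$ys, CWRES = cw, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' The four standard diagnostic tables
#'
#' Plot-ready tables for the canonical goodness-of-fit panels:
#' CWRES vs time (IVAR), CWRES vs PRED, DV vs IPRED, and DV vs PRED.
#' Each carries reference-line metadata (`zero` for residual panels,
#' `identity` for observed-vs-predicted panels) and explicit axis units.
#'
#' @inheritParams population_predictions
#' @return named list of four data.frames: `cwres_vs_ivar`,
#'   `cwres_vs_pred`, `dv_vs_ipred`, `dv_vs_pred`
#' @export
diagnostic_tables <- function(fit, dataset) {
  preds <- population_predictions(fit, dataset)
  cw <- cwres(fit, dataset)
  unit <- if (fit$stage == "pk") "mg/L" else "mmol/L"
  tabs <- list(
    cwres_vs_ivar = data.frame(subject = cw$subject, kind = cw$kind,
                               x = cw$IVAR, y = cw$CWRES),
    cwres_vs_pred = data.frame(subject = cw$subject, kind = cw$kind,
                               x = preds$PRED, y = cw$CWRES),
    dv_vs_ipred = data.frame(subject = preds$subject, kind = preds$kind,
                             x = preds$IPRED, y = preds$DV),
    dv_vs_pred = data.frame(subject = preds$subject, kind = preds$kind,
                            x = preds$PRED, y = preds$DV))
  attr(tabs$cwres_vs_ivar, "reference") <- "zero"
  attr(tabs$cwres_vs_ivar, "units") <- c(x = "h", y = "dimensionless")
  attr(tabs$cwres_vs_pred, "reference") <- "zero"
  attr(tabs$cwres_vs_pred, "units") <- c(x = unit, y = "dimensionless")
  attr(tabs$dv_vs_ipred, "reference") <- "identity"
  attr(tabs$dv_vs_ipred, "units") <- c(x = unit, y = unit)
  attr(tabs$dv_vs_pred, "reference") <- "identity"
  attr(tabs$dv_vs_pred, "units") <- c(x = unit, y = unit)
  tabs
}
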