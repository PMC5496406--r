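# Non-compartmental analysis of a single-dose concentration-time profile:
# terminal slope, half-life, Cmax/Tmax, trapezoidal AUC with extrapolation,
# apparent clearance and volume.

#' Terminal elimination slope by log-linear regression
#'
#' Fits `ln(C)` against time over candidate contiguous terminal windows of
#' at least `min_points` positive concentrations after (and excluding) the
#' peak, and keeps the window with the best adjusted R-squared — the common
#' automatic convention when the selection is not reported.
#'
#' @param times sampling times (h), sorted
#' @param concs concentrations (mg/L), same length
#' @param min_points minimum number of terminal points (default 3)
#' @return list with `lambda_z` (1/h), `r_squared` (adjusted), `n_points`
#' @export
terminal_slope <- function(times, concs, min_points = 3) {
  stopifnot(length(times) == length(concs), !is.unsorted(times))
  i_max <- which.max(concs)[1]
  cand <- which(seq_along(concs) > i_max & concs > 0)
  if (length(cand) < min_points) {
    stop("terminal slope not estimable: fewer than ", min_points,
         " positive post-peak concentrations", call. = FALSE)
  }
  best <- NULL
  for (start in cand[seq_len(length(cand) - min_points + 1)]) {
    idx <- cand[cand >= start]
    ly <- log(concs[idx])
    if (stats::sd(ly) == 0) next # flat tail: no decline
    fit <- stats::lm(ly ~ times[idx])
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || slope >= 0) next
    n <- length(idx)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
    r2adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
    if (!is.finite(r2adj)) next
    if (is.null(best) || r2adj > best$r_squared + 1e-12) {
      best <- list(lambda_z = -slope, r_squared = r2adj,
                   n_points = length(idx))
    }
  }
  if (is.null(best)) {
    stop("terminal slope not estimable: no declining terminal window",
         call. = FALSE)
  }
  best
}

#' Area under the curve to the last sampled concentration
#'
#' Trapezoidal accumulation over the whole sampled profile (a trailing
#' all-zero stretch adds no area).  Under the `linear-up-log-down` rule
#' (the assay standard), segments where the concentration declines between
#' two positive values use the log-trapezoid `(C1 - C2) * dt / ln(C1/C2)`;
#' all other segments — rises, flats and falls to zero — use the linear
#' trapezoid.
#'
#' @param times sampling times (h), sorted
#' @param concs concentrations (mg/L), >= 0
#' @param rule `"linear-up-log-down"` or `"linear"`
#' @return area (mg*h/L)
#' @export
auc_last <- function(times, concs, rule = c("linear-up-log-down", "linear")) {
  rule <- match.arg(rule)
  stopifnot(length(times) == length(concs), !is.unsorted(times),
            all(concs >= 0))
  if (length(times) < 2) stop("need at least 2 points", call. = FALSE)
  auc <- 0
  for (i in seq_len(length(times) - 1)) {
    dt <- times[i + 1] - times[i]
    c1 <- concs[i]; c2 <- concs[i + 1]
    auc <- auc + if (rule == "linear-up-log-down" && c1 > c2 && c2 > 0) {
      (c1 - c2) * dt / log(c1 / c2)
    } else {
      (c1 + c2) * dt / 2
    }
  }
  auc
}

#' Non-compartmental analysis of one subject's profile
#'
#' Computes the full NCA quantity set: `Cmax`/`Tmax` from the observed
#' maximum (earliest time on ties), `AUC_last` by trapezoid, the terminal
#' slope `lambda_z` with `t_half = ln2 / lambda_z`,
#' `AUC_inf = AUC_last + C_last / lambda_z`, the AUC extrapolation ratio,
#' `CL_F = dose / AUC_inf` and `Vd_F = CL_F / lambda_z`.  When the terminal
#' slope is not estimable, the extrapolated quantities are `NA` while
#' `Cmax`, `Tmax` and `AUC_last` are still reported.
#'
#' @param times sampling times (h), sorted
#' @param concs concentrations (mg/L)
#' @param dose administered dose (mg)
#' @param min_points,rule passed to [terminal_slope()] and [auc_last()]
#' @return an `nca_result` (named list)
#' @export
nca_subject <- function(times, concs, dose, min_points = 3,
                        rule = c("linear-up-log-down", "linear")) {
  rule <- match.arg(rule)
  stopifnot(dose > 0)
  i_max <- which.max(concs)[1]
  cmax <- concs[i_max]
  tmax <- times[i_max]
  auc_t <- auc_last(times, concs, rule)
  ts <- tryCatch(terminal_slope(times, concs, min_points),
                 error = function(e) NULL)
  if (is.null(ts)) {
    res <- list(lambda_z = NA_real_, t_half = NA_real_, Tmax = tmax,
                Cmax = cmax, AUC_last = auc_t, AUC_inf = NA_real_,
                pct_AUC_ratio = NA_real_, CL_F = NA_real_, Vd_F = NA_real_,
                n_lambda_points = NA_integer_, r_squared = NA_real_)
  } else {
    # extrapolate from the final observed concentration: a zero tail
    # leaves nothing to extrapolate
    c_last <- concs[length(concs)]
    auc_inf <- auc_t + c_last / ts$lambda_z
    cl_f <- dose / auc_inf
    res <- list(lambda_z = ts$lambda_z, t_half = log(2) / ts$lambda_z,
                Tmax = tmax, Cmax = cmax, AUC_last = auc_t,
                AUC_inf = auc_inf, pct_AUC_ratio = 100 * auc_t / auc_inf,
                CL_F = cl_f, Vd_F = cl_f / ts$lambda_z,
                n_lambda_points = ts$n_points, r_squared = ts$r_squared)
  }
  structure(res, class = "nca_result")
}

#' Per-subject NCA over a study dataset
#'
#' Applies [nca_subject()] to every subject's drug concentrations.  The
#' pre-dose zero concentration anchors the AUC at `(0, 0)`; below-limit
#' values are zero before the first positive concentration and missing
#' afterwards.
#'
#' @param dataset a `study_dataset`
#' @param min_points,rule passed through
#' @return named list of `nca_result`, one per subject
#' @export
nca_study <- function(dataset, min_points = 3,
                      rule = c("linear-up-log-down", "linear")) {
  rule <- match.arg(rule)
  stopifnot(inherits(dataset, "study_dataset"))
  obs <- dataset$obs[dataset$obs$kind == "drug_conc", , drop = FALSE]
  ids <- sort(unique(obs$subject))
  out <- list()
  for (id in ids) {
    o <- obs[obs$subject == id, , drop = FALSE]
    o <- o[order(o$time), , drop = FALSE]
    conc <- o$value
    first_pos <- which(conc > 0 & !o$blq)[1]
    keep <- rep(TRUE, nrow(o))
    if (!is.na(first_pos)) {
      conc[o$blq & seq_len(nrow(o)) < first_pos] <- 0
      keep[o$blq & seq_len(nrow(o)) >= first_pos] <- FALSE
    } else {
      conc[o$blq] <- 0
    }
    dose <- sum(dataset$doses$amount[dataset$doses$subject == id])
    out[[id]] <- nca_subject(o$time[keep], conc[keep], dose,
                             min_points = min_points, rule = rule)
  }
  out
}

#' Summarize NCA results across subjects
#'
#' Arithmetic mean and SD for every quantity except `Tmax`, which is
#' summarized as median (min-max) following the reporting convention for
#' that statistic.
#'
#' @param results list of `nca_result` objects
#' @return data.frame with columns `parameter`, `mean`, `sd`, `median`,
#'   `min`, `max`, `n`
#' @export
summarize_nca <- function(results) {
  stopifnot(length(results) >= 1)
  quantities <- c("t_half", "Tmax", "CL_F", "Vd_F", "Cmax", "AUC_last",
                  "AUC_inf", "pct_AUC_ratio")
  rows <- lapply(quantities, function(q) {
    v <- vapply(results, function(r) r[[q]], numeric(1))
    v <- v[is.finite(v)]
    data.frame(parameter = q,
               mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               median = stats::median(v),
               min = min(v), max = max(v), n = length(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.nca_result <- function(x, ...) {
  cat("Non-compartmental analysis\n")
  cat(sprintf("  Cmax %.4g mg/L (%.4g ng/mL) at Tmax %.3g h\n",
              x$Cmax, 1000 * x$Cmax, x$Tmax))
  cat(sprintf("  AUC_last %.4g mg*h/L, AUC_inf %.4g mg*h/L (%.4g%% covered)\n",
              x$AUC_last, x$AUC_inf, x$pct_AUC_ratio))
  cat(sprintf("  lambda_z %.4g 1/h (t1/2 %.4g h, n = %s, adj R2 %.4g)\n",
              x$lambda_z, x$t_half,
              ifelse(is.na(x$n_lambda_points), "NA", x$n_lambda_points),
              x$r_squared))
  cat(sprintf("  CL/F %.4g L/h, Vd/F %.4g L\n", x$CL_F, x$Vd_F))
  invisible(x)
}
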