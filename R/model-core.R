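#' Right-hand side of the PK-PD differential system
#'
#' Rates of change of the depot amount `Aa` (mg), central amount `A1` (mg),
#' peripheral amount `A2` (mg) and effect-site concentration `Ce` (mg/L):
#'
#' \deqn{dAa/dt = -Ka \cdot Aa}
#' \deqn{dA1/dt = Ka \cdot Aa - CL \cdot C - CL2 \cdot (C - C2)}
#' \deqn{dA2/dt = CL2 \cdot (C - C2)}
#' \deqn{dCe/dt = Ke0 \cdot (C - Ce)}
#'
#' with `C = A1/V` and `C2 = A2/V2`.  The effect compartment is driven by the
#' central concentration and carries negligible mass (standard biophase
#' assumption).
#'
#' @param state numeric vector `(Aa, A1, A2, Ce)` (named or positional)
#' @param pk a [pk_params()] object
#' @param pd a [pd_params()] object
#' @return named numeric vector `(dAa, dA1, dA2, dCe)` in mg/h (dCe in
#'   mg/L/h)
#' @export
pkpd_derivatives <- function(state, pk, pd) {
  stopifnot(inherits(pk, "pk_params"), inherits(pd, "pd_params"))
  if (length(state) != 4 || any(!is.finite(state))) {
    stop("state must be four finite numbers (Aa, A1, A2, Ce)", call. = FALSE)
  }
  Aa <- state[[1]]; A1 <- state[[2]]; A2 <- state[[3]]; Ce <- state[[4]]
  C <- A1 / pk$V
  C2 <- A2 / pk$V2
  c(dAa = -pk$Ka * Aa,
    dA1 = pk$Ka * Aa - pk$CL * C - pk$CL2 * (C - C2),
    dA2 = pk$CL2 * (C - C2),
    dCe = pd$Ke0 * (C - Ce))
}

#' Sigmoid inhibitory Emax glucose response
#'
#' Plasma glucose as a function of effect-site drug concentration:
#' \deqn{E = E0 (1 - Ce^{Gam} / (IC50^{Gam} + Ce^{Gam}))}
#' Maximal inhibition is complete suppression of `E0` (no separate Imax
#' parameter).  Strictly decreasing in `Ce`, bounded in `(0, E0]`.
#'
#' @param Ce effect-site concentration(s), mg/L, >= 0
#' @param pd a [pd_params()] object
#' @return plasma glucose (mmol/L), same length as `Ce`
#' @export
#' @examples
#' pd <- pd_params(Ke0 = 7.47, IC50 = 1.13, Gam = 1.66, E0 = 4.65)
#' inhibitory_effect(0, pd)     # baseline E0
#' inhibitory_effect(1.13, pd)  # half-maximal: E0/2
inhibitory_effect <- function(Ce, pd) {
  stopifnot(inherits(pd, "pd_params"))
  if (any(!is.finite(Ce)) || any(Ce < 0)) {
    stop("Ce must be non-negative and finite", call. = FALSE)
  }
  # log-scale ratio avoids overflow for large Ce^Gam
  r <- ifelse(Ce == 0, 0, exp(pd$Gam * (log(Ce) - log(pd$IC50))))
  pd$E0 * (1 - r / (1 + r))
}

# Disposition micro rate constants and eigenvalues (alpha >= beta).
pk_micro <- function(pk) {
  k10 <- pk$CL / pk$V
  k12 <- pk$CL2 / pk$V
  k21 <- pk$CL2 / pk$V2
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  list(k10 = k10, k12 = k12, k21 = k21,
       alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

# Exponential decomposition of the central amount A1 after the lag:
# A1(tau) = sum(a * exp(-lam * tau)).  Errors when Ka coincides with a
# disposition eigenvalue (the tri-exponential form degenerates).
a1_exponentials <- function(pk, dose) {
  mic <- pk_micro(pk)
  lam <- c(mic$alpha, mic$beta, pk$Ka)
  scale <- max(pk$Ka, mic$alpha)
  if (abs(pk$Ka - mic$alpha) < 1e-10 * scale ||
      abs(pk$Ka - mic$beta) < 1e-10 * scale ||
      abs(mic$alpha - mic$beta) < 1e-10 * max(mic$alpha, 1e-300)) {
    stop("degenerate rate constants: Ka coincides with a disposition ",
         "eigenvalue; use the numeric method", call. = FALSE)
  }
  kad <- pk$Ka * dose
  a <- kad * c((mic$k21 - mic$alpha) / ((pk$Ka - mic$alpha) * (mic$beta - mic$alpha)),
               (mic$k21 - mic$beta) / ((pk$Ka - mic$beta) * (mic$alpha - mic$beta)),
               (mic$k21 - pk$Ka) / ((mic$alpha - pk$Ka) * (mic$beta - pk$Ka)))
  list(lam = lam, a = a, micro = mic)
}

#' Closed-form central concentration of the two-compartment oral model
#'
#' The standard tri-exponential solution of the linear absorption-disposition
#' system, evaluated with micro rate constants `k10 = CL/V`, `k12 = CL2/V`,
#' `k21 = CL2/V2` and time-shifted by the absorption lag.  Used as the
#' independent oracle for the numeric integrator.
#'
#' @param pk a [pk_params()] object
#' @param dose oral dose (mg)
#' @param t time(s) since dosing (h), >= 0
#' @return central concentration(s) `C(t)` in mg/L; 0 for `t <= Tlag`
#' @export
analytic_central_conc <- function(pk, dose, t) {
  stopifnot(inherits(pk, "pk_params"), dose >= 0)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (dose == 0) return(numeric(length(t)))
  dec <- a1_exponentials(pk, dose)
  tau <- t - pk$Tlag
  out <- numeric(length(t))
  pos <- tau > 0
  if (any(pos)) {
    ee <- exp(-outer(tau[pos], dec$lam))       # |pos| x 3
    out[pos] <- pmax(as.vector(ee %*% dec$a) / pk$V, 0)
  }
  out
}

#' Closed-form effect-site concentration
#'
#' Solution of `dCe/dt = Ke0 (C - Ce)` with the tri-exponential central
#' concentration as input and `Ce = 0` at the lag time.
#'
#' @inheritParams analytic_central_conc
#' @param pd a [pd_params()] object (supplies `Ke0`)
#' @return effect-site concentration(s) in mg/L
#' @export
effect_site_conc <- function(pk, pd, dose, t) {
  stopifnot(inherits(pk, "pk_params"), inherits(pd, "pd_params"), dose >= 0)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (dose == 0) return(numeric(length(t)))
  dec <- a1_exponentials(pk, dose)
  ke0 <- pd$Ke0
  tau <- t - pk$Tlag
  out <- numeric(length(t))
  pos <- which(tau > 0)
  for (i in pos) {
    ce <- 0
    for (j in 1:3) {
      d <- ke0 - dec$lam[j]
      ce <- ce + if (abs(d) < 1e-9 * max(ke0, 1)) {
        dec$a[j] * ke0 * tau[i] * exp(-ke0 * tau[i])
      } else {
        dec$a[j] * ke0 * (exp(-dec$lam[j] * tau[i]) - exp(-ke0 * tau[i])) / d
      }
    }
    out[i] <- max(ce / pk$V, 0)
  }
  out
}

# Closed-form full state profile (amounts, eliminated mass, Ce, E).
analytic_profile_states <- function(pk, pd, dose, times) {
  n <- length(times)
  out <- data.frame(times = times, Aa = rep(dose, n), A1 = 0, A2 = 0,
                    C = 0, C2 = 0, Ce = 0, E = pd$E0, eliminated = 0)
  if (dose == 0) {
    out$Aa <- 0
    return(out)
  }
  dec <- a1_exponentials(pk, dose)
  mic <- dec$micro
  tau <- times - pk$Tlag
  pos <- tau > 0
  if (any(pos)) {
    tp <- tau[pos]
    ee <- exp(-outer(tp, dec$lam))             # m x 3
    out$Aa[pos] <- dose * exp(-pk$Ka * tp)
    out$A1[pos] <- pmax(as.vector(ee %*% dec$a), 0)
    # A2' = k12 A1 - k21 A2  =>  convolution of A1 exponentials with k21
    A2 <- numeric(sum(pos))
    for (j in 1:3) {
      d <- mic$k21 - dec$lam[j]
      A2 <- A2 + if (abs(d) < 1e-9 * max(mic$k21, 1)) {
        dec$a[j] * tp * exp(-mic$k21 * tp)
      } else {
        dec$a[j] * (ee[, j] - exp(-mic$k21 * tp)) / d
      }
    }
    out$A2[pos] <- pmax(mic$k12 * A2, 0)
    # eliminated(tau) = k10 * integral of A1
    elim <- numeric(sum(pos))
    for (j in 1:3) {
      elim <- elim + if (dec$lam[j] < 1e-12) {
        dec$a[j] * tp
      } else {
        dec$a[j] * (1 - ee[, j]) / dec$lam[j]
      }
    }
    out$eliminated[pos] <- mic$k10 * elim
    out$C[pos] <- out$A1[pos] / pk$V
    out$C2[pos] <- out$A2[pos] / pk$V2
    out$Ce[pos] <- effect_site_conc(pk, pd, dose, times[pos])
    out$E[pos] <- inhibitory_effect(out$Ce[pos], pd)
  }
  out
}

#' Simulate the full PK-PD profile of one individual
#'
#' Integrates (or evaluates in closed form) the depot, central, peripheral
#' and effect compartments after a single oral dose, together with the
#' cumulative eliminated amount, and maps the effect-site concentration to
#' plasma glucose.  The absorption lag is handled by starting the system at
#' `t = Tlag` with the whole dose in the depot; for `t < Tlag` the dose sits
#' unabsorbed in the depot (`C = 0`, `E = E0`).
#'
#' @param pk a [pk_params()] object
#' @param pd a [pd_params()] object
#' @param dose oral dose (mg), >= 0
#' @param times sorted non-negative time grid (h)
#' @param method `"numeric"` (adaptive stiff-capable `deSolve::lsoda`) or
#'   `"analytic"` (closed-form tri-exponential evaluation)
#' @param rtol,atol numeric-integrator tolerances
#' @return a `data.frame` of class `simulated_profile` with columns `times`,
#'   `Aa`, `A1`, `A2` (mg), `C`, `C2`, `Ce` (mg/L), `E` (mmol/L) and
#'   `eliminated` (mg)
#' @export
#' @examples
#' pk <- pk_params(Ka = 9.57, V = 6.15, V2 = 104.69, CL = 0.03, CL2 = 9.85,
#'                 Tlag = 0.09)
#' pd <- pd_params(Ke0 = 7.47, IC50 = 1.13, Gam = 1.66, E0 = 4.65)
#' prof <- simulate_profile(pk, pd, dose = 10, times = seq(0, 3, by = 0.25))
#' head(prof)
simulate_profile <- function(pk, pd, dose, times,
                             method = c("numeric", "analytic"),
                             rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  stopifnot(inherits(pk, "pk_params"), inherits(pd, "pd_params"))
  if (dose < 0) stop("dose must be non-negative", call. = FALSE)
  if (length(times) < 1 || any(!is.finite(times)) || any(times < 0) ||
      is.unsorted(times)) {
    stop("times must be a sorted grid of non-negative values", call. = FALSE)
  }
  if (method == "analytic") {
    out <- analytic_profile_states(pk, pd, dose, times)
  } else {
    n <- length(times)
    out <- data.frame(times = times, Aa = rep(dose, n), A1 = 0, A2 = 0,
                      C = 0, C2 = 0, Ce = 0, E = pd$E0, eliminated = 0)
    post <- times > pk$Tlag
    if (dose == 0) {
      out$Aa <- 0
    } else if (any(post)) {
      rhs <- function(t, y, p) {
        C <- y[2] / pk$V
        C2 <- y[3] / pk$V2
        list(c(-pk$Ka * y[1],
               pk$Ka * y[1] - pk$CL * C - pk$CL2 * (C - C2),
               pk$CL2 * (C - C2),
               pd$Ke0 * (C - y[4]),
               pk$CL * C))
      }
      tt <- c(pk$Tlag, times[post])
      sol <- deSolve::lsoda(y = c(dose, 0, 0, 0, 0), times = tt, func = rhs,
                            parms = NULL, rtol = rtol, atol = atol)
      if (attr(sol, "istate")[1] < 0) {
        stop("ODE integration failed (istate = ", attr(sol, "istate")[1],
             "); consider loosening tolerances", call. = FALSE)
      }
      sol <- sol[-1, , drop = FALSE]
      out$Aa[post] <- pmax(sol[, 2], 0)
      out$A1[post] <- pmax(sol[, 3], 0)
      out$A2[post] <- pmax(sol[, 4], 0)
      out$Ce[post] <- pmax(sol[, 5], 0)
      out$eliminated[post] <- pmax(sol[, 6], 0)
      out$C[post] <- out$A1[post] / pk$V
      out$C2[post] <- out$A2[post] / pk$V2
      out$E[post] <- inhibitory_effect(out$Ce[post], pd)
    }
  }
  attr(out, "dose") <- dose
  class(out) <- c("simulated_profile", "data.frame")
  out
}
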