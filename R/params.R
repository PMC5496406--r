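#' Structural pharmacokinetic parameters for one individual
#'
#' Constants of the two-compartment oral-absorption model with a lag time:
#' drug enters a depot at the end of the lag, is absorbed first-order into a
#' central compartment, distributes to a peripheral compartment, and is
#' cleared linearly from the central compartment.
#'
#' @param Ka first-order absorption rate constant (1/h), > 0
#' @param V central volume of distribution (L), > 0
#' @param V2 peripheral volume of distribution (L), > 0
#' @param CL central elimination clearance (L/h), >= 0
#' @param CL2 inter-compartmental clearance (L/h), >= 0
#' @param Tlag absorption lag time (h), >= 0
#' @return an object of class `pk_params`
#' @export
#' @examples
#' pk_params(Ka = 9.57, V = 6.15, V2 = 104.69, CL = 0.03, CL2 = 9.85,
#'           Tlag = 0.09)
pk_params <- function(Ka, V, V2, CL, CL2, Tlag = 0) {
  x <- c(Ka = Ka, V = V, V2 = V2, CL = CL, CL2 = CL2, Tlag = Tlag)
  if (any(!is.finite(x))) {
    stop("all PK parameters must be finite numbers", call. = FALSE)
  }
  if (Ka <= 0 || V <= 0 || V2 <= 0) {
    stop("Ka, V and V2 must be strictly positive", call. = FALSE)
  }
  if (CL < 0 || CL2 < 0 || Tlag < 0) {
    stop("CL, CL2 and Tlag must be non-negative", call. = FALSE)
  }
  structure(as.list(x), class = "pk_params")
}

#' Structural pharmacodynamic parameters for one individual
#'
#' Constants of the effect-compartment (biophase) sigmoid inhibitory Emax
#' model of plasma glucose: the effect-site concentration `Ce` equilibrates
#' with the central plasma concentration at rate `Ke0` and suppresses glucose
#' from its drug-free baseline `E0` through a Hill function with potency
#' `IC50` and steepness `Gam`.
#'
#' @param Ke0 effect-compartment equilibration rate constant (1/h), > 0
#' @param IC50 effect-site concentration at half-maximal glucose suppression
#'   (mg/L), > 0
#' @param Gam Hill (sigmoidicity) exponent, dimensionless, > 0
#' @param E0 baseline plasma glucose in the absence of drug (mmol/L), > 0
#' @return an object of class `pd_params`
#' @export
#' @examples
#' pd_params(Ke0 = 7.47, IC50 = 1.13, Gam = 1.66, E0 = 4.65)
pd_params <- function(Ke0, IC50, Gam, E0) {
  x <- c(Ke0 = Ke0, IC50 = IC50, Gam = Gam, E0 = E0)
  if (any(!is.finite(x))) {
    stop("all PD parameters must be finite numbers", call. = FALSE)
  }
  if (any(x <= 0)) {
    stop("Ke0, IC50, Gam and E0 must be strictly positive", call. = FALSE)
  }
  structure(as.list(x), class = "pd_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Structural PK parameters (two-compartment, oral, lag time)\n")
  cat(sprintf("  Ka   %8.4g 1/h    V    %8.4g L    V2  %8.4g L\n",
              x$Ka, x$V, x$V2))
  cat(sprintf("  CL   %8.4g L/h    CL2  %8.4g L/h  Tlag %7.4g h\n",
              x$CL, x$CL2, x$Tlag))
  invisible(x)
}

#' @export
print.pd_params <- function(x, ...) {
  cat("Structural PD parameters (effect compartment, sigmoid inhibition)\n")
  cat(sprintf("  Ke0 %8.4g 1/h   IC50 %8.4g mg/L   Gam %6.4g   E0 %6.4g mmol/L\n",
              x$Ke0, x$IC50, x$Gam, x$E0))
  invisible(x)
}

as_numeric_pk <- function(pk) {
  c(pk$Ka, pk$V, pk$V2, pk$CL, pk$CL2, pk$Tlag)
}
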