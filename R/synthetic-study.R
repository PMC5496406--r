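#' Reference population parameter set
#'
#' The published population estimates for oral mitiglinide after a single
#' 10 mg dose: typical values for all structural parameters and
#' inter-individual CVs for the parameters carrying random effects
#' (`Ka` 91.95%, `Tlag` 70.71%, `V` 17.61%, `CL2` 22.18%, `Ke0` 90.61%,
#' `Gam` 18.67%, `E0` 4.35%); `V2`, `CL` and `IC50` are population constants.
#' CVs are converted to eta variances by the exact log-normal relation
#' `omega = ln(1 + CV^2)`.  Residual-error magnitudes are this package's
#' defaults (the source analysis does not report an error model):
#' proportional 10% on concentration, additive 0.15 mmol/L on glucose.
#'
#' Note: the reference set carries `CL = 0.03` L/h as printed, which is far
#' smaller than the non-compartmental apparent clearance of the same study
#' (7.80 L/h); see [nca_consistent_population()] for a demonstration preset
#' with a clearance matched to the NCA value.
#'
#' @param sigma_pk proportional residual SD for drug concentration
#' @param sigma_pd additive residual SD for glucose (mmol/L)
#' @return a [population_spec()]
#' @export
reference_population <- function(sigma_pk = 0.10, sigma_pd = 0.15) {
  tv <- c(Ka = 9.57, V = 6.15, V2 = 104.69, CL = 0.03, CL2 = 9.85,
          Tlag = 0.09, Ke0 = 7.47, IC50 = 1.13, Gam = 1.66, E0 = 4.65)
  cv <- c(Ka = 0.9195, Tlag = 0.7071, V = 0.1761, CL2 = 0.2218,
          Ke0 = 0.9061, Gam = 0.1867, E0 = 0.0435)
  population_spec(tv = tv, omega = cv_to_omega(cv),
                  sigma_pk = sigma_pk, sigma_pd = sigma_pd)
}

#' Demonstration preset with NCA-consistent clearance
#'
#' SYNTHETIC variant of [reference_population()] — not a published parameter
#' set.  Replaces the printed population clearance (0.03 L/h) with the value
#' that makes the model's apparent clearance match the study's
#' non-compartmental CL/F of 7.80 L/h.  Useful for demonstrations in which
#' the terminal phase should resemble the observed 1.69 h half-life.
#'
#' @inheritParams reference_population
#' @return a [population_spec()]
#' @export
nca_consistent_population <- function(sigma_pk = 0.10, sigma_pd = 0.15) {
  spec <- reference_population(sigma_pk, sigma_pd)
  spec$tv[["CL"]] <- 7.80
  spec
}

#' Default study design
#'
#' The trial layout being emulated: 18 fasted subjects, one 10 mg oral dose,
#' blood sampling for both drug and glucose at 0, 0.08, 0.17, 0.25, 0.33,
#' 0.5, 0.75, 1, 1.5, 2 and 3 h post-dose.
#'
#' @return a [study_design()]
#' @export
default_design <- function() {
  times <- c(0, 0.08, 0.17, 0.25, 0.33, 0.5, 0.75, 1, 1.5, 2, 3)
  study_design(n_subjects = 18, dose = 10, pk_times = times, pd_times = times)
}

#' Generate a synthetic study dataset
#'
#' Composes [simulate_study()] with the published defaults: the reference
#' population and the 18-subject single-dose design.  Fully reproducible
#' from the seed.
#'
#' @param seed integer master seed
#' @param design a [study_design()]; defaults to [default_design()]
#' @param spec a [population_spec()]; defaults to [reference_population()]
#' @param blq_limit drug lower limit of quantification (mg/L)
#' @return a `study_dataset`
#' @export
#' @examples
#' ds <- generate_study(seed = 1)
#' ds
generate_study <- function(seed, design = default_design(),
                           spec = reference_population(), blq_limit = 2e-4) {
  simulate_study(spec, design, seed, blq_limit = blq_limit)
}
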