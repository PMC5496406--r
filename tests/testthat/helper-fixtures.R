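# shared fixtures: the published typical individual and small study designs

typical_pk <- function() {
  pk_params(Ka = 9.57, V = 6.15, V2 = 104.69, CL = 0.03, CL2 = 9.85,
            Tlag = 0.09)
}

typical_pd <- function() {
  pd_params(Ke0 = 7.47, IC50 = 1.13, Gam = 1.66, E0 = 4.65)
}

study_times <- function() c(0, 0.08, 0.17, 0.25, 0.33, 0.5, 0.75, 1, 1.5, 2, 3)

small_design <- function(n) {
  study_design(n_subjects = n, dose = 10, pk_times = study_times())
}

# random valid PK parameter sets log-uniformly spread over two decades
# around the published typical values
random_pk_sets <- function(n, seed) {
  tv <- c(Ka = 9.57, V = 6.15, V2 = 104.69, CL = 0.03, CL2 = 9.85,
          Tlag = 0.09)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- tv * 10^stats::runif(6, -1, 1)
    pk_params(Ka = v[["Ka"]], V = v[["V"]], V2 = v[["V2"]], CL = v[["CL"]],
              CL2 = v[["CL2"]], Tlag = v[["Tlag"]])
  })
}

# a minimal hand-built dataset with one subject
toy_dataset <- function(times, drug = NULL, glucose = NULL, dose = 10,
                        id = "S001") {
  obs <- NULL
  if (!is.null(drug)) {
    obs <- rbind(obs, data.frame(subject = id, time = times, kind = "drug_conc",
                                 value = drug, blq = FALSE))
  }
  if (!is.null(glucose)) {
    obs <- rbind(obs, data.frame(subject = id, time = times, kind = "glucose",
                                 value = glucose, blq = FALSE))
  }
  study_dataset(data.frame(subject = id, time = 0, amount = dose), obs)
}
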