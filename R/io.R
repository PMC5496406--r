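# Long-format CSV interchange in the NONMEM column convention:
# ID, TIME (h), DVID (1 drug mg/L, 2 glucose mmol/L), DV, AMT (mg),
# MDV (1 when DV missing), BLQ (0/1).  Dose rows carry AMT and empty DV;
# observation rows the reverse.

INTERCHANGE_COLS <- c("ID", "TIME", "DVID", "DV", "AMT", "MDV", "BLQ")
DVID_DRUG <- 1L
DVID_GLUCOSE <- 2L

fmt_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) sprintf("%.17g", v), ""))
}

#' Write a study dataset to the CSV interchange format
#'
#' Deterministic row order (ID, then TIME, with dose rows before
#' observations at the same time, then DVID) and full-precision numeric
#' rendering, so a write-read round trip reproduces the dataset exactly.
#'
#' @param dataset a `study_dataset`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  dose_rows <- data.frame(ID = dataset$doses$subject,
                          TIME = dataset$doses$time,
                          DVID = NA_integer_, DV = NA_real_,
                          AMT = dataset$doses$amount,
                          MDV = 1L, BLQ = 0L, stringsAsFactors = FALSE)
  obs_rows <- data.frame(ID = dataset$obs$subject,
                         TIME = dataset$obs$time,
                         DVID = ifelse(dataset$obs$kind == "drug_conc",
                                       DVID_DRUG, DVID_GLUCOSE),
                         DV = dataset$obs$value,
                         AMT = NA_real_, MDV = 0L,
                         BLQ = as.integer(dataset$obs$blq),
                         stringsAsFactors = FALSE)
  all_rows <- rbind(dose_rows, obs_rows)
  ord <- order(all_rows$ID, all_rows$TIME, !is.na(all_rows$DVID),
               all_rows$DVID)
  all_rows <- all_rows[ord, , drop = FALSE]
  lines <- c(paste(INTERCHANGE_COLS, collapse = ","),
             paste(all_rows$ID,
                   fmt_num(all_rows$TIME),
                   ifelse(is.na(all_rows$DVID), "", all_rows$DVID),
                   fmt_num(all_rows$DV),
                   fmt_num(all_rows$AMT),
                   all_rows$MDV, all_rows$BLQ, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a study dataset from the CSV interchange format
#'
#' Validates the header (case-insensitive), numeric parseability and the
#' dose-row/observation-row dichotomy, and rejects duplicated
#' `(ID, TIME, DVID)` observation rows naming the offending row.
#'
#' @param path CSV file path
#' @return a validated `study_dataset`
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse CSV: ", conditionMessage(e),
                             call. = FALSE))
  names(df) <- toupper(names(df))
  miss <- setdiff(INTERCHANGE_COLS, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) stop("no data rows in ", path, call. = FALSE)
  num <- function(col) {
    x <- df[[col]]
    x[x == ""] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      stop("unparseable ", col, " at data row ", bad[1], call. = FALSE)
    }
    v
  }
  time <- num("TIME"); dv <- num("DV"); amt <- num("AMT")
  dvid <- num("DVID"); mdv <- num("MDV"); blq <- num("BLQ")
  is_dose <- !is.na(amt)
  both <- which(is_dose & !is.na(dv))
  if (length(both)) {
    stop("row ", both[1], " has both AMT and DV set", call. = FALSE)
  }
  obs_rows <- which(!is_dose)
  obs_rows <- obs_rows[!(mdv[obs_rows] %in% 1) | !is.na(dv[obs_rows])]
  no_dv <- obs_rows[is.na(dv[obs_rows])]
  if (length(no_dv)) {
    stop("observation row ", no_dv[1], " lacks DV and is not MDV", call. = FALSE)
  }
  bad_dvid <- obs_rows[!(dvid[obs_rows] %in% c(DVID_DRUG, DVID_GLUCOSE))]
  if (length(bad_dvid)) {
    stop("observation row ", bad_dvid[1], " has DVID outside {1, 2}",
         call. = FALSE)
  }
  key <- paste(df$ID[obs_rows], time[obs_rows], dvid[obs_rows])
  dup <- anyDuplicated(key)
  if (dup) {
    stop("duplicate (ID, TIME, DVID) observation at data row ",
         obs_rows[dup], call. = FALSE)
  }
  doses <- data.frame(subject = df$ID[is_dose], time = time[is_dose],
                      amount = amt[is_dose], stringsAsFactors = FALSE)
  obs <- data.frame(subject = df$ID[obs_rows], time = time[obs_rows],
                    kind = ifelse(dvid[obs_rows] == DVID_DRUG, "drug_conc",
                                  "glucose"),
                    value = dv[obs_rows],
                    blq = blq[obs_rows] %in% 1,
                    stringsAsFactors = FALSE)
  obs <- obs[order(obs$subject, obs$time, obs$kind), , drop = FALSE]
  rownames(obs) <- NULL
  study_dataset(doses, obs)
}

#' Serialize a fit to machine-readable JSON and a plain-text report
#'
#' @param fit a `pkpd_fit`
#' @param path output path for the JSON file; a `.txt` report with the same
#'   stem is written alongside
#' @return `path`, invisibly
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "pkpd_fit"))
  est <- fit$estimates
  payload <- list(stage = fit$stage,
                  tv = as.list(est$tv),
                  omega = as.list(est$omega),
                  sigma_pk = est$sigma_pk, sigma_pd = est$sigma_pd,
                  objective = fit$objective, converged = fit$converged,
                  n_evaluations = fit$n_evaluations,
                  shrinkage = as.list(fit$shrinkage),
                  ebe = list(subjects = rownames(fit$ebe),
                             parameters = colnames(fit$ebe),
                             values = unname(as.data.frame(fit$ebe))),
                  ipk = if (!is.null(fit$ipk)) {
                    list(parameters = rownames(fit$ipk),
                         subjects = colnames(fit$ipk),
                         values = unname(as.data.frame(fit$ipk)))
                  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  report <- sub("\\.json$", ".txt", path)
  if (identical(report, path)) report <- paste0(path, ".txt")
  con <- file(report, "w")
  sink(con); print(fit); sink()
  close(con)
  invisible(path)
}

#' Read a fit written by [write_fit()]
#'
#' @param path JSON file path
#' @return a `pkpd_fit`
#' @export
read_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- population_spec(tv = unlist(p$tv), omega = unlist(p$omega),
                          sigma_pk = p$sigma_pk, sigma_pd = p$sigma_pd)
  ebe <- as.matrix(as.data.frame(p$ebe$values))
  dimnames(ebe) <- list(p$ebe$subjects, p$ebe$parameters)
  ipk <- NULL
  if (!is.null(p$ipk) && length(p$ipk)) {
    ipk <- as.matrix(as.data.frame(p$ipk$values))
    dimnames(ipk) <- list(p$ipk$parameters, p$ipk$subjects)
  }
  shr <- unlist(p$shrinkage)
  structure(list(estimates = spec, stage = p$stage, ebe = ebe,
                 objective = p$objective, converged = p$converged,
                 n_evaluations = p$n_evaluations, shrinkage = shr,
                 se = NULL, trace = numeric(0), ids = p$ebe$subjects,
                 ipk = ipk),
            class = "pkpd_fit")
}

#' Format a population estimates table
#'
#' Renders the fitted typical values with their implied inter-individual
#' CVs in the conventional `value (CV%)` layout; drug concentration scale
#' is reported both in mg/L and ng/mL.
#'
#' @param fit a `pkpd_fit`
#' @return character vector of report lines
#' @export
format_estimates <- function(fit) {
  est <- fit$estimates
  pars <- if (fit$stage == "pk") PK_PARAM_ORDER else PD_PARAM_ORDER
  lines <- c(sprintf("stage: %s   -2LL: %.4f   converged: %s",
                     fit$stage, fit$objective, fit$converged))
  for (p in pars) {
    cvtxt <- if (p %in% names(est$omega) && est$omega[[p]] > 0) {
      sprintf("%.2f", 100 * omega_to_cv(est$omega[[p]]))
    } else "-"
    lines <- c(lines, sprintf("%-5s %12.6g   CV%% %s", p, est$tv[[p]], cvtxt))
  }
  sig <- if (fit$stage == "pk") est$sigma_pk else est$sigma_pd
  c(lines, sprintf("sigma_%s %.6g", fit$stage, sig))
}
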