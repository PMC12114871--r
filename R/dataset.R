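#' Dosing regimen
#'
#' Describes a repeated oral dosing schedule for the modeled drug: the
#' per-administration dose (mg/kg), the dosing interval tau (hours), the
#' number of administrations, and the day on the study clock (t = 0 at tumor
#' inoculation) at which the first dose is given.
#'
#' @param dose_amount Dose per administration (mg/kg); must be >= 0.
#' @param tau_h Dosing interval (hours); must be > 0.
#' @param n_doses Number of administrations; integer >= 1.
#' @param start_day Day of the first dose on the study clock (days).
#' @return An object of class `dose_regimen`.
#' @examples
#' dose_regimen(10, 24, 30, start_day = 7)
#' @export
dose_regimen <- function(dose_amount, tau_h = 24, n_doses = 1, start_day = 0) {
  if (!is.numeric(dose_amount) || length(dose_amount) != 1 || dose_amount < 0)
    stopf("dose_amount must be a single non-negative number")
  if (!is.numeric(tau_h) || length(tau_h) != 1 || tau_h <= 0)
    stopf("tau_h must be a single positive number")
  if (!is.numeric(n_doses) || length(n_doses) != 1 || n_doses < 1 ||
      n_doses != round(n_doses))
    stopf("n_doses must be an integer >= 1")
  structure(
    list(dose_amount = dose_amount, tau_h = tau_h,
         n_doses = as.integer(n_doses), start_day = start_day),
    class = "dose_regimen"
  )
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("Dose regimen: %g mg/kg q%gh x %d, first dose day %g\n",
              x$dose_amount, x$tau_h, x$n_doses, x$start_day))
  invisible(x)
}

# Dose times on the study clock, in days.
dose_days <- function(reg) reg$start_day + (seq_len(reg$n_doses) - 1) * reg$tau_h / 24

STUDY_ARMS <- c("CONTROL", "AFT", "HADB1", "COMB")
# Arms that receive the modeled drug and therefore must carry a regimen.
DRUG_ARMS <- c("AFT", "COMB")

#' Study dataset
#'
#' Long-format container for a PK/PD xenograft study: observation records
#' (serum concentrations in ng/mL with time in hours post-dose, and tumor
#' volumes in mm^3 with time in days since inoculation) plus one dosing
#' regimen per drug-treated arm. This mirrors the NONMEM-style interchange
#' convention (ID/TIME/AMT/DV/EVID/MDV) used throughout pharmacometrics.
#'
#' @param records Data frame with columns `ID`, `TIME`, `DV`, `MDV`, `DVID`
#'   (1 = concentration, 2 = tumor volume), `ARM`.
#' @param regimens Named list mapping arm label to a [dose_regimen()].
#' @param metadata Optional list of units, provenance and simulation truth.
#' @return An object of class `study_dataset`.
#' @seealso [read_dataset()], [write_dataset()]
#' @export
study_dataset <- function(records, regimens = list(), metadata = list()) {
  ds <- structure(list(records = as.data.frame(records),
                       regimens = regimens, metadata = metadata),
                  class = "study_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a study dataset
#'
#' Checks the record schema and type invariants: non-negative times and
#' values, known arm labels, known observation types, strictly increasing
#' times per subject within an observation type, and presence of a dosing
#' regimen for every drug-treated arm (none for CONTROL). Errors name the
#' offending row.
#'
#' @param ds A `study_dataset`.
#' @return `ds`, invisibly, if valid.
#' @export
validate_dataset <- function(ds) {
  r <- ds$records
  need <- c("ID", "TIME", "DV", "MDV", "DVID", "ARM")
  miss <- setdiff(need, names(r))
  if (length(miss))
    stopf("dataset schema error: missing column(s) %s", paste(miss, collapse = ", "))
  if (nrow(r)) {
    bad <- which(r$TIME < 0)
    if (length(bad)) stopf("validation error: negative TIME at record row %d", bad[1])
    bad <- which(r$DV < 0)
    if (length(bad)) stopf("validation error: negative DV at record row %d", bad[1])
    bad <- which(!r$ARM %in% STUDY_ARMS)
    if (length(bad))
      stopf("validation error: unknown ARM '%s' at record row %d", r$ARM[bad[1]], bad[1])
    bad <- which(!r$DVID %in% c(1L, 2L))
    if (length(bad))
      stopf("validation error: unknown DVID %s at record row %d", r$DVID[bad[1]], bad[1])
    for (key in split(seq_len(nrow(r)), paste(r$ID, r$DVID))) {
      tt <- r$TIME[key]
      if (any(diff(tt) <= 0))
        stopf("validation error: times not strictly increasing for subject %s (row %d)",
              r$ID[key[1]], key[which(diff(tt) <= 0)[1] + 1])
    }
    for (arm in intersect(unique(r$ARM), DRUG_ARMS)) {
      if (is.null(ds$regimens[[arm]]))
        stopf("validation error: drug-treated arm %s has no dosing regimen", arm)
    }
  }
  if (!is.null(ds$regimens[["CONTROL"]]))
    stopf("validation error: CONTROL arm must not carry a dosing regimen")
  invisible(ds)
}

#' @export
print.study_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("Study dataset: %d observation records (%d concentration, %d tumor), arms: %s\n",
              nrow(r), sum(r$DVID == 1), sum(r$DVID == 2),
              paste(sort(unique(r$ARM)), collapse = ", ")))
  if (length(x$regimens))
    for (a in names(x$regimens))
      cat(" ", a, ": ", sprintf("%g mg/kg q%gh x %d from day %g",
          x$regimens[[a]]$dose_amount, x$regimens[[a]]$tau_h,
          x$regimens[[a]]$n_doses, x$regimens[[a]]$start_day), "\n", sep = "")
  invisible(x)
}

# Observation subset helpers used by the analysis stages.
obs_records <- function(ds, dvid, arms = NULL, observed_only = TRUE) {
  r <- ds$records
  keep <- r$DVID == dvid
  if (observed_only) keep <- keep & r$MDV == 0
  if (!is.null(arms)) keep <- keep & r$ARM %in% arms
  r[keep, , drop = FALSE]
}

DATASET_COLUMNS <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "DVID", "ARM")

#' Read a study dataset from a NONMEM-style CSV file
#'
#' Expects columns `ID, TIME, AMT, DV, EVID, MDV, DVID, ARM`. Rows with
#' `EVID = 1` are dose events and are collapsed into one [dose_regimen()]
#' per arm (doses are assumed evenly spaced and identical across subjects of
#' an arm); rows with `EVID = 0` become observation records. `DVID = 1`
#' marks serum concentration (ng/mL, TIME in hours); `DVID = 2` marks tumor
#' volume (mm^3, TIME in days since inoculation); missing observations carry
#' `MDV = 1` with `DV = 0`.
#'
#' @param path Path to a CSV file.
#' @return A [study_dataset()].
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(miss))
    stopf("dataset schema error: missing column(s) %s in %s",
          paste(miss, collapse = ", "), path)
  bad <- which(raw$TIME < 0)
  if (length(bad)) stopf("validation error: negative TIME at file row %d", bad[1])
  bad <- which(raw$DV < 0)
  if (length(bad)) stopf("validation error: negative DV at file row %d", bad[1])
  bad <- which(!raw$ARM %in% STUDY_ARMS)
  if (length(bad))
    stopf("validation error: unknown ARM '%s' at file row %d", raw$ARM[bad[1]], bad[1])

  doses <- raw[raw$EVID == 1, , drop = FALSE]
  regimens <- list()
  for (arm in unique(doses$ARM)) {
    d <- doses[doses$ARM == arm, , drop = FALSE]
    d1 <- d[d$ID == d$ID[1], , drop = FALSE]        # pattern of one subject
    tt <- sort(d1$TIME)
    tau_h <- if (length(tt) >= 2) stats::median(diff(tt)) * 24 else 24
    regimens[[arm]] <- dose_regimen(dose_amount = d1$AMT[1], tau_h = tau_h,
                                    n_doses = length(tt), start_day = tt[1])
  }
  obs <- raw[raw$EVID == 0, DATASET_COLUMNS, drop = FALSE]
  obs <- obs[order(obs$ARM, obs$ID, obs$DVID, obs$TIME), , drop = FALSE]
  records <- data.frame(ID = as.character(obs$ID), TIME = obs$TIME, DV = obs$DV,
                        MDV = as.integer(obs$MDV), DVID = as.integer(obs$DVID),
                        ARM = obs$ARM, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  meta <- list(source = path,
               units = list(concentration = "ng/mL (TIME h)",
                            tumor_volume = "mm3 (TIME days)"))
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar))
    meta <- utils::modifyList(meta, jsonlite::read_json(sidecar, simplifyVector = TRUE))
  study_dataset(records, regimens, metadata = meta)
}

#' Write a study dataset to a NONMEM-style CSV file
#'
#' Emits one `EVID = 1` row per administration per dosed subject (expanded
#' from the arm regimens; dose times in days on the study clock) followed by
#' the observation rows, in the canonical column order
#' `ID, TIME, AMT, DV, EVID, MDV, DVID, ARM`. Numbers are serialized with 15
#' significant digits so a write/read/write cycle is byte-stable and
#' round-trips are exact to better than 1e-12 relative.
#'
#' Dataset metadata (units, seed provenance, generator truth) is written to
#' a JSON sidecar `<path>.meta.json` when present and read back by
#' [read_dataset()].
#'
#' @param ds A [study_dataset()].
#' @param path Output file path.
#' @param sidecar Write the metadata sidecar (default `TRUE` when metadata
#'   is non-empty).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, sidecar = length(ds$metadata) > 0) {
  validate_dataset(ds)
  r <- ds$records
  rows <- list()
  for (arm in sort(unique(r$ARM))) {
    reg <- ds$regimens[[arm]]
    ids <- sort(unique(r$ID[r$ARM == arm]))
    for (id in ids) {
      if (!is.null(reg)) {
        td <- dose_days(reg)
        rows[[length(rows) + 1L]] <- data.frame(
          ID = id, TIME = td, AMT = reg$dose_amount, DV = 0, EVID = 1L,
          MDV = 1L, DVID = 0L, ARM = arm, stringsAsFactors = FALSE)
      }
      sub <- r[r$ARM == arm & r$ID == id, , drop = FALSE]
      sub <- sub[order(sub$DVID, sub$TIME), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        ID = id, TIME = sub$TIME, AMT = 0, DV = sub$DV, EVID = 0L,
        MDV = sub$MDV, DVID = sub$DVID, ARM = arm, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(DATASET_COLUMNS))),
                    DATASET_COLUMNS)
  num <- function(x) vapply(x, function(v) formatC(v, digits = 15, format = "g"), "")
  lines <- c(paste(DATASET_COLUMNS, collapse = ","),
             if (nrow(out)) paste(out$ID, num(out$TIME), num(out$AMT), num(out$DV),
                                  out$EVID, out$MDV, out$DVID, out$ARM, sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  if (isTRUE(sidecar))
    jsonlite::write_json(ds$metadata, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
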