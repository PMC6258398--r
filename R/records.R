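# Patient care record (PCR) data model.
#
# One PCR describes a single EMS patient encounter: a time-ordered series of
# vital-sign observations, the interventions performed, medication
# administrations, the disposition, and any exclusion flags that remove the
# record from the review pool (care-pathway cases, high-risk procedures or
# medications, infrequent procedures, inter-facility transports).

consciousness_levels <- c("alert", "voice", "pain", "unresponsive")
disposition_levels <- c("transported", "refusal_of_transport", "other")
intervention_kinds <- c("supplemental_oxygen", "assisted_ventilation",
                        "spinal_immobilisation", "other")
exclusion_flag_levels <- c("care_pathway", "high_risk_procedure",
                           "high_risk_medication", "infrequent_procedure",
                           "interfacility_transport")

#' Build a vital-sign observation table
#'
#' Each row is one timed observation; any vital may be absent (`NA`).
#'
#' @param time observation times (ISO-8601 strings or POSIXct); required.
#' @param spo2 oxygen saturation, percent 0-100.
#' @param sbp systolic blood pressure, mmHg (> 0).
#' @param temp temperature, degrees Celsius.
#' @param pain pain score, integer 0-10.
#' @param resp_rate respiratory rate, breaths/min.
#' @param heart_rate heart rate, beats/min.
#' @param consciousness one of `"alert"`, `"voice"`, `"pain"`, `"unresponsive"`.
#' @return a data frame of observations, not yet time-sorted (sorting happens
#'   in [pcr()]).
#' @export
observations <- function(time = character(), spo2 = NA_real_, sbp = NA_real_,
                         temp = NA_real_, pain = NA_real_,
                         resp_rate = NA_real_, heart_rate = NA_real_,
                         consciousness = NA_character_) {
  time <- parse_ts(time)
  n <- length(time)
  data.frame(
    time = time,
    spo2 = rep_len(as.numeric(spo2), n),
    sbp = rep_len(as.numeric(sbp), n),
    temp = rep_len(as.numeric(temp), n),
    pain = rep_len(as.numeric(pain), n),
    resp_rate = rep_len(as.numeric(resp_rate), n),
    heart_rate = rep_len(as.numeric(heart_rate), n),
    consciousness = rep_len(as.character(consciousness), n),
    stringsAsFactors = FALSE
  )
}

#' Build an intervention table
#'
#' @param kind intervention kind; one of `"supplemental_oxygen"`,
#'   `"assisted_ventilation"`, `"spinal_immobilisation"`, `"other"`.
#' @param time intervention times.
#' @param indicated logical; documented clinical indication. Meaningful only
#'   for spinal immobilisation; `NA` means the indication was not documented.
#' @param performed logical; whether the intervention was actually carried out
#'   (`NA` is treated as performed). A spinal-immobilisation row with
#'   `indicated = TRUE, performed = FALSE` records indicated care that was
#'   omitted.
#' @return a data frame of interventions.
#' @export
interventions <- function(kind = character(), time = character(),
                          indicated = NA, performed = NA) {
  time <- parse_ts(time)
  n <- length(kind)
  data.frame(
    kind = as.character(kind),
    time = rep_len(time, max(n, length(time))),
    indicated = rep_len(as.logical(indicated), n),
    performed = rep_len(as.logical(performed), n),
    stringsAsFactors = FALSE
  )
}

#' Build a medication administration table
#'
#' Names are normalised to lower case and trimmed; there is no ontology
#' mapping (the opioid/antagonist trigger matches against a configurable
#' name list).
#'
#' @param name medication names (free text).
#' @param time administration times.
#' @return a data frame of medication administrations.
#' @export
medications <- function(name = character(), time = character()) {
  data.frame(
    name = tolower(trimws(as.character(name))),
    time = parse_ts(time),
    stringsAsFactors = FALSE
  )
}

empty_observations <- function() observations()
empty_interventions <- function() interventions()
empty_medications <- function() medications()

#' Construct a patient care record
#'
#' @param record_id unique record identifier.
#' @param patient_id patient identifier, stable across encounters (drives the
#'   return-within-24-h trigger); defaults to `record_id`.
#' @param encounter_start,encounter_end encounter window (ISO-8601 or POSIXct).
#' @param observations observation table from [observations()]; sorted by time
#'   on construction.
#' @param interventions intervention table from [interventions()].
#' @param medications medication table from [medications()].
#' @param disposition `"transported"`, `"refusal_of_transport"` or `"other"`.
#' @param exclusion_flags character subset of the exclusion criteria:
#'   `r paste(exclusion_flag_levels, collapse = ", ")`.
#' @return an object of class `"pcr"`.
#' @seealso [validate_record()], [read_records()], [write_records()]
#' @export
pcr <- function(record_id, patient_id = record_id, encounter_start,
                encounter_end, observations = empty_observations(),
                interventions = empty_interventions(),
                medications = empty_medications(),
                disposition = "transported",
                exclusion_flags = character()) {
  obs <- observations
  if (nrow(obs) > 1) obs <- obs[order(obs$time), , drop = FALSE]
  rownames(obs) <- NULL
  meds <- medications
  meds$name <- tolower(trimws(meds$name))
  structure(
    list(
      record_id = as.character(record_id),
      patient_id = as.character(patient_id),
      encounter_start = parse_ts(encounter_start),
      encounter_end = parse_ts(encounter_end),
      observations = obs,
      interventions = interventions,
      medications = meds,
      disposition = as.character(disposition),
      exclusion_flags = as.character(exclusion_flags)
    ),
    class = "pcr"
  )
}

#' @export
print.pcr <- function(x, ...) {
  cat(sprintf(
    "<pcr %s> patient %s, %s .. %s\n  %d observation(s), %d intervention(s), %d medication(s); disposition: %s%s\n",
    x$record_id, x$patient_id, format_ts(x$encounter_start),
    format_ts(x$encounter_end), nrow(x$observations), nrow(x$interventions),
    nrow(x$medications), x$disposition,
    if (length(x$exclusion_flags))
      paste0("; excluded: ", paste(x$exclusion_flags, collapse = ", "))
    else ""
  ))
  invisible(x)
}

#' Validate a patient care record
#'
#' Checks every structural invariant of the record model and returns the
#' violations found. Validation is total: it reports rather than throws, and
#' never errors on a structurally parseable record.
#'
#' @param x a `"pcr"` object.
#' @return character vector of violation messages, each naming the offending
#'   field; `character(0)` if the record is valid.
#' @export
validate_record <- function(x) {
  v <- character()
  say <- function(...) v <<- c(v, sprintf(...))

  if (!is.character(x$record_id) || length(x$record_id) != 1 ||
      is.na(x$record_id) || !nzchar(x$record_id))
    say("record_id: missing or empty")
  id <- if (length(x$record_id) == 1 && !is.na(x$record_id)) x$record_id else "?"
  if (is.na(x$encounter_start)) say("encounter_start: missing")
  if (is.na(x$encounter_end)) say("encounter_end: missing")
  if (!is.na(x$encounter_start) && !is.na(x$encounter_end) &&
      x$encounter_start > x$encounter_end)
    say("encounter_start: after encounter_end")
  if (!x$disposition %in% disposition_levels)
    say("disposition: '%s' not one of %s", x$disposition,
        paste(disposition_levels, collapse = "/"))
  bad_flags <- setdiff(x$exclusion_flags, exclusion_flag_levels)
  if (length(bad_flags))
    say("exclusion_flags: unknown flag(s) %s", paste(bad_flags, collapse = ", "))

  obs <- x$observations
  if (nrow(obs)) {
    if (anyNA(obs$time)) say("observations: time missing in row(s) %s",
                             paste(which(is.na(obs$time)), collapse = ","))
    if (is.unsorted(obs$time, na.rm = TRUE))
      say("observations: not time-ordered")
    out <- !is.na(obs$time) &
      (obs$time < x$encounter_start | obs$time > x$encounter_end)
    if (any(out, na.rm = TRUE))
      say("observations: row(s) %s outside encounter window",
          paste(which(out), collapse = ","))
    bad <- !is.na(obs$pain) & (obs$pain < 0 | obs$pain > 10 |
                                 obs$pain != floor(obs$pain))
    if (any(bad)) say("pain: row(s) %s outside 0..10",
                      paste(which(bad), collapse = ","))
    bad <- !is.na(obs$spo2) & (obs$spo2 < 0 | obs$spo2 > 100)
    if (any(bad)) say("spo2: row(s) %s outside [0,100]",
                      paste(which(bad), collapse = ","))
    bad <- !is.na(obs$sbp) & obs$sbp <= 0
    if (any(bad)) say("sbp: row(s) %s not > 0", paste(which(bad), collapse = ","))
    bad <- !is.na(obs$consciousness) &
      !obs$consciousness %in% consciousness_levels
    if (any(bad)) say("consciousness: row(s) %s not in %s",
                      paste(which(bad), collapse = ","),
                      paste(consciousness_levels, collapse = "/"))
  }

  iv <- x$interventions
  if (nrow(iv)) {
    bad <- !iv$kind %in% intervention_kinds
    if (any(bad)) say("interventions.kind: row(s) %s unknown",
                      paste(which(bad), collapse = ","))
    if (anyNA(iv$time)) say("interventions.time: missing in row(s) %s",
                            paste(which(is.na(iv$time)), collapse = ","))
    out <- !is.na(iv$time) &
      (iv$time < x$encounter_start | iv$time > x$encounter_end)
    if (any(out, na.rm = TRUE))
      say("interventions.time: row(s) %s outside encounter window",
          paste(which(out), collapse = ","))
  }

  md <- x$medications
  if (nrow(md)) {
    bad <- is.na(md$name) | !nzchar(md$name)
    if (any(bad)) say("medications.name: empty in row(s) %s",
                      paste(which(bad), collapse = ","))
    out <- !is.na(md$time) &
      (md$time < x$encounter_start | md$time > x$encounter_end)
    if (any(out, na.rm = TRUE))
      say("medications.time: row(s) %s outside encounter window",
          paste(which(out), collapse = ","))
  }

  if (length(v)) sprintf("record %s: %s", id, v) else character(0)
}

# Validate a whole cohort (list of pcr), including record_id uniqueness.
validate_cohort <- function(records) {
  ids <- vapply(records, function(r) r$record_id, character(1))
  v <- unlist(lapply(records, validate_record))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    v <- c(v, sprintf("record_id: duplicate id(s) %s",
                      paste(dup, collapse = ", ")))
  v
}
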