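# The eight-item EMS trigger engine.
#
# Items, all evaluated deterministically per record:
#   C1  SpO2 < 94% without supplemental oxygen, or < 85% without assisted
#       ventilation
#   C2  change in systolic blood pressure > 20% from the first measurement
#   C3  pain score > 4/10 without subsequent reduction
#   C4  temperature > 38 C without subsequent reduction
#   C5  increase in early warning score > 1 point
#   M1  opioid analgesic and naloxone administered to the same patient
#   P1  inappropriate spinal immobilisation
#   R1  return to the same patient within 24 h of a refusal of transport
#
# Every threshold comparison is strict: a value exactly at a threshold never
# fires.

#' Trigger item codes
#'
#' @return the eight trigger item codes in canonical evaluation order.
#' @export
trigger_items <- function() c("C1", "C2", "C3", "C4", "C5", "M1", "P1", "R1")

#' Trigger engine configuration
#'
#' All rule constants are configurable; the defaults are the published tool
#' thresholds.
#'
#' @param spo2_low SpO2 threshold (percent) below which supplemental oxygen is
#'   expected (default 94).
#' @param spo2_critical SpO2 threshold below which assisted ventilation is
#'   expected (default 85; must be below `spo2_low`).
#' @param sbp_change_frac relative change in systolic blood pressure from the
#'   first measurement that fires C2 (default 0.20, strict).
#' @param pain_threshold pain score above which C3 arms (default 4).
#' @param temp_threshold temperature in Celsius above which C4 arms
#'   (default 38).
#' @param ews_increase early-warning-score increase that C5 must strictly
#'   exceed (default 1, i.e. an increase of 2 or more fires).
#' @param opioid_names lower-case opioid analgesic names matched by M1.
#' @param antagonist_name lower-case antagonist name matched by M1
#'   (default `"naloxone"`).
#' @param return_window_hours half-open return window (0, w] for R1
#'   (default 24).
#' @param p1_mode `"mismatch"` (default) fires P1 on immobilisation applied
#'   without indication *or* omitted despite indication;
#'   `"applied_without_indication"` fires only on the first.
#' @param c2_direction `"both"` (default) treats C2's "change" as absolute
#'   relative change (rise or fall); `"drop"` restricts to falls.
#' @param ews_table early warning score band table, see [default_ews_table()].
#' @return an object of class `"trigger_config"`.
#' @export
trigger_config <- function(spo2_low = 94, spo2_critical = 85,
                           sbp_change_frac = 0.20, pain_threshold = 4,
                           temp_threshold = 38, ews_increase = 1,
                           opioid_names = c("morphine", "fentanyl",
                                            "oxycodone", "pethidine",
                                            "tramadol"),
                           antagonist_name = "naloxone",
                           return_window_hours = 24,
                           p1_mode = c("mismatch",
                                       "applied_without_indication"),
                           c2_direction = c("both", "drop"),
                           ews_table = default_ews_table()) {
  stopifnot(spo2_low > 0, spo2_critical > 0, spo2_critical < spo2_low,
            sbp_change_frac > 0, sbp_change_frac < 1,
            pain_threshold > 0, temp_threshold > 0, ews_increase > 0,
            return_window_hours > 0)
  validate_ews_table(ews_table)
  structure(list(
    spo2_low = spo2_low, spo2_critical = spo2_critical,
    sbp_change_frac = sbp_change_frac, pain_threshold = pain_threshold,
    temp_threshold = temp_threshold, ews_increase = ews_increase,
    opioid_names = tolower(opioid_names),
    antagonist_name = tolower(antagonist_name),
    return_window_hours = return_window_hours,
    p1_mode = match.arg(p1_mode),
    c2_direction = match.arg(c2_direction),
    ews_table = ews_table
  ), class = "trigger_config")
}

ews_bands <- function(lo, hi, score) {
  stopifnot(length(lo) == length(hi), length(lo) == length(score))
  data.frame(lo = lo, hi = hi, score = score)
}

#' Default early warning score table
#'
#' The tool specifies an "increase in early warning score" trigger without
#' fixing a particular instrument, so the score table is configuration.  This
#' default is an implementer-supplied aggregate-weighted table over
#' respiratory rate, SpO2, systolic blood pressure, heart rate, temperature
#' and consciousness, with bands of the familiar national-early-warning-score
#' shape.  Each numeric parameter maps through half-open bands `[lo, hi)` to a
#' non-negative integer score; absent parameters contribute 0; consciousness
#' scores 0 when alert and 3 otherwise.
#'
#' @return a named list of band tables plus a `consciousness` score vector.
#' @export
default_ews_table <- function() {
  list(
    resp_rate = ews_bands(c(0, 9, 12, 21, 25), c(9, 12, 21, 25, Inf),
                          c(3, 1, 0, 2, 3)),
    spo2 = ews_bands(c(0, 92, 94, 96), c(92, 94, 96, 101), c(3, 2, 1, 0)),
    sbp = ews_bands(c(0, 91, 101, 111, 220), c(91, 101, 111, 220, Inf),
                    c(3, 2, 1, 0, 3)),
    heart_rate = ews_bands(c(0, 41, 51, 91, 111, 131),
                           c(41, 51, 91, 111, 131, Inf),
                           c(3, 1, 0, 1, 2, 3)),
    temp = ews_bands(c(25, 35.1, 36.1, 38.1, 39.1),
                     c(35.1, 36.1, 38.1, 39.1, 46), c(3, 1, 0, 1, 2)),
    consciousness = c(alert = 0, voice = 3, pain = 3, unresponsive = 3)
  )
}

validate_ews_table <- function(table) {
  for (p in setdiff(names(table), "consciousness")) {
    b <- table[[p]]
    stopifnot(is.data.frame(b), all(c("lo", "hi", "score") %in% names(b)))
    if (any(b$score < 0)) stop("ews table ", p, ": negative score")
    o <- order(b$lo)
    b <- b[o, ]
    if (any(b$lo >= b$hi)) stop("ews table ", p, ": empty band")
    if (nrow(b) > 1 && any(abs(b$hi[-nrow(b)] - b$lo[-1]) > 1e-9))
      stop("ews table ", p, ": bands not contiguous (gap or overlap)")
  }
  if (!is.null(table$consciousness)) {
    stopifnot(all(consciousness_levels %in% names(table$consciousness)),
              all(table$consciousness >= 0))
  }
  invisible(table)
}

#' Compute an early warning score for one observation
#'
#' Sums the band scores of every vital present in the observation; absent
#' vitals contribute 0. A value falling outside every band of its parameter
#' is a configuration error.
#'
#' @param obs a one-row observation data frame (or named list) as in the
#'   `observations` table of a [pcr()].
#' @param table an EWS table, see [default_ews_table()].
#' @return integer score.
#' @export
compute_ews <- function(obs, table = default_ews_table()) {
  score <- 0
  for (p in setdiff(names(table), "consciousness")) {
    v <- obs[[p]]
    if (is.null(v) || is.na(v)) next
    b <- table[[p]]
    j <- which(v >= b$lo & v < b$hi)
    if (!length(j))
      stop(sprintf("ews: value %s = %s outside all configured bands", p, v),
           call. = FALSE)
    score <- score + b$score[j[1]]
  }
  cl <- obs[["consciousness"]]
  if (!is.null(table$consciousness) && !is.null(cl) && !is.na(cl)) {
    if (!cl %in% names(table$consciousness))
      stop("ews: unknown consciousness level ", cl, call. = FALSE)
    score <- score + unname(table$consciousness[cl])
  }
  score
}

ev <- function(field, time, value) {
  list(field = field, time = if (is.null(time)) NA else format_ts(time),
       value = value)
}

trigger_hit <- function(record_id, item, evidence) {
  list(record_id = record_id, item = item, evidence = evidence)
}

#' @rdname screen
#' @param record a single `"pcr"` record.
#' @export
eval_c1 <- function(record, config = trigger_config()) {
  obs <- record$observations
  iv <- record$interventions
  evid <- list()
  low <- which(!is.na(obs$spo2) & obs$spo2 < config$spo2_low)
  if (length(low)) {
    t0 <- obs$time[low[1]]
    relieved <- any(iv$kind == "supplemental_oxygen" & !is.na(iv$time) &
                      iv$time >= t0)
    if (!relieved)
      evid <- c(evid, list(ev("spo2", t0, obs$spo2[low[1]])))
  }
  crit <- which(!is.na(obs$spo2) & obs$spo2 < config$spo2_critical)
  if (length(crit)) {
    t0 <- obs$time[crit[1]]
    relieved <- any(iv$kind == "assisted_ventilation" & !is.na(iv$time) &
                      iv$time >= t0)
    if (!relieved)
      evid <- c(evid, list(ev("spo2", t0, obs$spo2[crit[1]])))
  }
  if (!length(evid)) return(NULL)
  trigger_hit(record$record_id, "C1", evid)
}

#' @rdname screen
#' @export
eval_c2 <- function(record, config = trigger_config()) {
  obs <- record$observations
  idx <- which(!is.na(obs$sbp))
  if (length(idx) < 2) return(NULL)
  b <- obs$sbp[idx[1]]
  later <- idx[-1]
  rel <- (obs$sbp[later] - b) / b
  hit <- if (config$c2_direction == "both") abs(rel) > config$sbp_change_frac
         else -rel > config$sbp_change_frac
  if (!any(hit)) return(NULL)
  j <- later[which(hit)[1]]
  trigger_hit(record$record_id, "C2", list(
    ev("sbp", obs$time[idx[1]], b),
    ev("sbp", obs$time[j], obs$sbp[j])
  ))
}

#' @rdname screen
#' @param item for [eval_reduction_trigger()], `"C3"` (pain) or `"C4"`
#'   (temperature).
#' @export
eval_reduction_trigger <- function(record, item = c("C3", "C4"),
                                   config = trigger_config()) {
  item <- match.arg(item)
  field <- if (item == "C3") "pain" else "temp"
  thr <- if (item == "C3") config$pain_threshold else config$temp_threshold
  obs <- record$observations
  vals <- obs[[field]]
  qual <- which(!is.na(vals) & vals > thr)
  if (!length(qual)) return(NULL)
  m <- max(vals[qual])
  i_m <- qual[which.max(vals[qual])]  # first occurrence of the maximum
  reduced <- any(!is.na(vals) & obs$time > obs$time[i_m] & vals < m)
  if (reduced) return(NULL)
  trigger_hit(record$record_id, item, list(ev(field, obs$time[i_m], m)))
}

#' @rdname screen
#' @export
eval_c5 <- function(record, config = trigger_config()) {
  obs <- record$observations
  if (nrow(obs) < 2) return(NULL)
  scores <- vapply(seq_len(nrow(obs)), function(i)
    compute_ews(obs[i, ], config$ews_table), numeric(1))
  inc <- scores[-1] - scores[1]
  if (max(inc) <= config$ews_increase) return(NULL)
  j <- which.max(inc) + 1
  trigger_hit(record$record_id, "C5", list(
    ev("ews", obs$time[1], scores[1]),
    ev("ews", obs$time[j], scores[j])
  ))
}

#' @rdname screen
#' @export
eval_m1 <- function(record, config = trigger_config()) {
  md <- record$medications
  op <- which(md$name %in% config$opioid_names)
  ant <- which(md$name == config$antagonist_name)
  if (!length(op) || !length(ant)) return(NULL)
  trigger_hit(record$record_id, "M1", list(
    ev("medication", md$time[op[1]], md$name[op[1]]),
    ev("medication", md$time[ant[1]], md$name[ant[1]])
  ))
}

#' @rdname screen
#' @export
eval_p1 <- function(record, config = trigger_config()) {
  iv <- record$interventions
  sp <- iv[iv$kind == "spinal_immobilisation", , drop = FALSE]
  if (!nrow(sp)) return(NULL)
  undoc <- is.na(sp$indicated)
  if (any(undoc)) {
    warning(sprintf(
      "record %s: spinal immobilisation with undocumented indication; P1 indeterminate for that entry",
      record$record_id), call. = FALSE)
    sp <- sp[!undoc, , drop = FALSE]
  }
  if (!nrow(sp)) return(NULL)
  performed <- is.na(sp$performed) | sp$performed
  applied_wo <- !sp$indicated & performed
  omitted <- sp$indicated & !performed
  fire <- any(applied_wo) ||
    (config$p1_mode == "mismatch" && any(omitted))
  if (!fire) return(NULL)
  j <- if (any(applied_wo)) which(applied_wo)[1] else which(omitted)[1]
  trigger_hit(record$record_id, "P1", list(
    list(field = "spinal_immobilisation", time = format_ts(sp$time[j]),
         value = if (any(applied_wo)) "applied_without_indication"
                 else "omitted_when_indicated")
  ))
}

#' Build the cohort index used by the return-call trigger
#'
#' @param records list of `"pcr"` records.
#' @return a data frame mapping each record to its patient, encounter window
#'   and disposition.
#' @export
cohort_index <- function(records) {
  data.frame(
    record_id = vapply(records, function(r) r$record_id, character(1)),
    patient_id = vapply(records, function(r) r$patient_id, character(1)),
    start = as.POSIXct(vapply(records, function(r)
      as.numeric(r$encounter_start), numeric(1)), origin = "1970-01-01",
      tz = "UTC"),
    end = as.POSIXct(vapply(records, function(r)
      as.numeric(r$encounter_end), numeric(1)), origin = "1970-01-01",
      tz = "UTC"),
    disposition = vapply(records, function(r) r$disposition, character(1)),
    stringsAsFactors = FALSE
  )
}

#' @rdname screen
#' @param index cohort index from [cohort_index()] covering the full cohort.
#' @export
eval_r1 <- function(record, index, config = trigger_config()) {
  cand <- index[index$patient_id == record$patient_id &
                  index$record_id != record$record_id &
                  index$disposition == "refusal_of_transport", , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  gap_h <- as.numeric(difftime(record$encounter_start, cand$end,
                               units = "hours"))
  ok <- gap_h > 0 & gap_h <= config$return_window_hours
  if (!any(ok)) return(NULL)
  j <- which(ok)[1]
  trigger_hit(record$record_id, "R1", list(
    list(field = "companion_record_id", time = format_ts(cand$end[j]),
         value = cand$record_id[j]),
    ev("encounter_start", record$encounter_start, record$record_id)
  ))
}

eval_record <- function(record, index, config) {
  hits <- list(
    eval_c1(record, config),
    eval_c2(record, config),
    eval_reduction_trigger(record, "C3", config),
    eval_reduction_trigger(record, "C4", config),
    eval_c5(record, config),
    eval_m1(record, config),
    eval_p1(record, config),
    eval_r1(record, index, config)
  )
  hits[!vapply(hits, is.null, logical(1))]
}

#' Screen records for trigger items
#'
#' Evaluates all eight trigger items on every record (the return-call item
#' against the full cohort index) and returns one row per fired item per
#' record, in deterministic item order C1..C5, M1, P1, R1. Items are binary
#' per record: multiple qualifying observations yield a single hit.
#'
#' The per-item evaluators (`eval_c1()` .. `eval_r1()`,
#' [eval_reduction_trigger()]) are exported individually; each returns a hit
#' (record id, item, supporting evidence) or `NULL`.
#'
#' @param records list of `"pcr"` records (the cohort).
#' @param config a [trigger_config()].
#' @return a data frame with columns `record_id`, `item` and `evidence`
#'   (a list column of evidence tuples); zero rows when nothing fires.
#' @export
screen <- function(records, config = trigger_config()) {
  index <- cohort_index(records)
  hits <- unlist(lapply(records, eval_record, index = index, config = config),
                 recursive = FALSE)
  if (!length(hits)) {
    return(data.frame(record_id = character(), item = character(),
                      evidence = I(list()), stringsAsFactors = FALSE))
  }
  data.frame(
    record_id = vapply(hits, `[[`, character(1), "record_id"),
    item = vapply(hits, `[[`, character(1), "item"),
    evidence = I(lapply(hits, `[[`, "evidence")),
    stringsAsFactors = FALSE
  )
}
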