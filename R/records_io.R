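# Reading and writing cohorts of patient care records.
#
# JSON is the canonical, lossless format: one nested object per record, field
# names exactly as in the data model. The CSV dialect spreads each cohort over
# four flat files (records.csv, observations.csv, interventions.csv,
# medications.csv) joined on record_id, because CSV cannot nest.

record_to_list <- function(r) {
  strip <- function(row) row[!vapply(row, function(x) is.na(x), logical(1))]
  obs <- r$observations
  iv <- r$interventions
  md <- r$medications
  out <- list(
    record_id = r$record_id,
    patient_id = r$patient_id,
    encounter_start = format_ts(r$encounter_start),
    encounter_end = format_ts(r$encounter_end),
    observations = lapply(seq_len(nrow(obs)), function(i) {
      strip(list(time = format_ts(obs$time[i]), spo2 = obs$spo2[i],
                 sbp = obs$sbp[i], temp = obs$temp[i], pain = obs$pain[i],
                 resp_rate = obs$resp_rate[i], heart_rate = obs$heart_rate[i],
                 consciousness = obs$consciousness[i]))
    }),
    interventions = lapply(seq_len(nrow(iv)), function(i) {
      strip(list(kind = iv$kind[i], time = format_ts(iv$time[i]),
                 indicated = iv$indicated[i], performed = iv$performed[i]))
    }),
    medications = lapply(seq_len(nrow(md)), function(i) {
      list(name = md$name[i], time = format_ts(md$time[i]))
    }),
    disposition = r$disposition,
    exclusion_flags = as.list(r$exclusion_flags)
  )
  out
}

list_to_record <- function(o) {
  g <- function(x, f, default = NA) {
    v <- x[[f]]
    if (is.null(v)) default else v
  }
  obs_list <- o$observations %||% list()
  obs <- observations(
    time = vapply(obs_list, function(x) as.character(g(x, "time", NA_character_)), character(1)),
    spo2 = vapply(obs_list, function(x) as.numeric(g(x, "spo2")), numeric(1)),
    sbp = vapply(obs_list, function(x) as.numeric(g(x, "sbp")), numeric(1)),
    temp = vapply(obs_list, function(x) as.numeric(g(x, "temp")), numeric(1)),
    pain = vapply(obs_list, function(x) as.numeric(g(x, "pain")), numeric(1)),
    resp_rate = vapply(obs_list, function(x) as.numeric(g(x, "resp_rate")), numeric(1)),
    heart_rate = vapply(obs_list, function(x) as.numeric(g(x, "heart_rate")), numeric(1)),
    consciousness = vapply(obs_list, function(x) as.character(g(x, "consciousness", NA_character_)), character(1))
  )
  iv_list <- o$interventions %||% list()
  iv <- interventions(
    kind = vapply(iv_list, function(x) as.character(g(x, "kind", NA_character_)), character(1)),
    time = vapply(iv_list, function(x) as.character(g(x, "time", NA_character_)), character(1)),
    indicated = vapply(iv_list, function(x) as.logical(g(x, "indicated")), logical(1)),
    performed = vapply(iv_list, function(x) as.logical(g(x, "performed")), logical(1))
  )
  md_list <- o$medications %||% list()
  md <- medications(
    name = vapply(md_list, function(x) as.character(g(x, "name", NA_character_)), character(1)),
    time = vapply(md_list, function(x) as.character(g(x, "time", NA_character_)), character(1))
  )
  pcr(
    record_id = o$record_id,
    patient_id = o$patient_id %||% o$record_id,
    encounter_start = o$encounter_start,
    encounter_end = o$encounter_end,
    observations = obs, interventions = iv, medications = md,
    disposition = o$disposition %||% "transported",
    exclusion_flags = unlist(o$exclusion_flags %||% character())
  )
}

#' Write a cohort of patient care records
#'
#' @param records list of `"pcr"` objects.
#' @param dest for `format = "json"` a file path; for `format = "csv"` a
#'   directory (created if needed) receiving `records.csv`,
#'   `observations.csv`, `interventions.csv` and `medications.csv` joined on
#'   `record_id`.
#' @param format `"json"` (canonical, lossless) or `"csv"`.
#' @return `dest`, invisibly. The written file(s) round-trip through
#'   [read_records()] losslessly.
#' @export
write_records <- function(records, dest, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(lapply(records, record_to_list), dest,
                         auto_unbox = TRUE, null = "null", na = "null",
                         digits = NA)
    return(invisible(dest))
  }
  if (!dir.exists(dest)) dir.create(dest, recursive = TRUE)
  ids <- vapply(records, function(r) r$record_id, character(1))
  rec <- data.frame(
    record_id = ids,
    patient_id = vapply(records, function(r) r$patient_id, character(1)),
    encounter_start = vapply(records, function(r) format_ts(r$encounter_start), character(1)),
    encounter_end = vapply(records, function(r) format_ts(r$encounter_end), character(1)),
    disposition = vapply(records, function(r) r$disposition, character(1)),
    exclusion_flags = vapply(records, function(r)
      paste(r$exclusion_flags, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  bind_child <- function(field, fmt) {
    parts <- lapply(records, function(r) {
      d <- r[[field]]
      if (!nrow(d)) return(NULL)
      d <- fmt(d)
      cbind(data.frame(record_id = r$record_id, stringsAsFactors = FALSE), d)
    })
    parts <- Filter(Negate(is.null), parts)
    if (!length(parts)) return(NULL)
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
  }
  fmt_time <- function(d) { d$time <- format_ts(d$time); d }
  obs <- bind_child("observations", fmt_time)
  iv <- bind_child("interventions", fmt_time)
  md <- bind_child("medications", fmt_time)
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  if (is.null(obs)) obs <- empty(c("record_id", names(empty_observations())))
  if (is.null(iv)) iv <- empty(c("record_id", names(empty_interventions())))
  if (is.null(md)) md <- empty(c("record_id", names(empty_medications())))
  utils::write.csv(rec, file.path(dest, "records.csv"), row.names = FALSE)
  utils::write.csv(obs, file.path(dest, "observations.csv"), row.names = FALSE)
  utils::write.csv(iv, file.path(dest, "interventions.csv"), row.names = FALSE)
  utils::write.csv(md, file.path(dest, "medications.csv"), row.names = FALSE)
  invisible(dest)
}

#' Read a cohort of patient care records
#'
#' Records are validated on read: any invariant violation (e.g. a pain score
#' outside 0..10, an observation outside the encounter window) raises an
#' error naming the record and field, and duplicate `record_id`s are
#' rejected. Observations come back time-sorted and medication names
#' lower-cased regardless of how the file was written.
#'
#' @param source file path (JSON) or directory (CSV dialect), as written by
#'   [write_records()].
#' @param format `"json"` or `"csv"`.
#' @return list of validated `"pcr"` objects.
#' @export
read_records <- function(source, format = c("json", "csv")) {
  format <- match.arg(format)
  records <- if (format == "json") {
    objs <- jsonlite::read_json(source, simplifyVector = FALSE)
    lapply(objs, list_to_record)
  } else {
    read_records_csv(source)
  }
  v <- validate_cohort(records)
  if (length(v)) stop("invalid record(s) in ", source, ":\n  ",
                      paste(v, collapse = "\n  "), call. = FALSE)
  records
}

read_records_csv <- function(dir) {
  rd <- function(f, classes) {
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                    colClasses = classes)
  }
  rec <- rd("records.csv", c(
    record_id = "character", patient_id = "character",
    encounter_start = "character", encounter_end = "character",
    disposition = "character", exclusion_flags = "character"))
  obs <- rd("observations.csv", c(
    record_id = "character", time = "character", spo2 = "numeric",
    sbp = "numeric", temp = "numeric", pain = "numeric",
    resp_rate = "numeric", heart_rate = "numeric",
    consciousness = "character"))
  iv <- rd("interventions.csv", c(
    record_id = "character", kind = "character", time = "character",
    indicated = "logical", performed = "logical"))
  md <- rd("medications.csv", c(
    record_id = "character", name = "character", time = "character"))
  obs$consciousness[!is.na(obs$consciousness) & obs$consciousness == ""] <- NA
  lapply(seq_len(nrow(rec)), function(i) {
    id <- rec$record_id[i]
    o <- obs[obs$record_id == id, -1, drop = FALSE]
    v <- iv[iv$record_id == id, -1, drop = FALSE]
    m <- md[md$record_id == id, -1, drop = FALSE]
    flags <- rec$exclusion_flags[i]
    flags <- if (is.na(flags) || !nzchar(flags)) character()
             else strsplit(flags, ";", fixed = TRUE)[[1]]
    pcr(
      record_id = id, patient_id = rec$patient_id[i],
      encounter_start = rec$encounter_start[i],
      encounter_end = rec$encounter_end[i],
      observations = observations(
        time = o$time, spo2 = o$spo2, sbp = o$sbp, temp = o$temp,
        pain = o$pain, resp_rate = o$resp_rate, heart_rate = o$heart_rate,
        consciousness = o$consciousness),
      interventions = interventions(
        kind = v$kind, time = v$time, indicated = v$indicated,
        performed = v$performed),
      medications = medications(name = m$name, time = m$time),
      disposition = rec$disposition[i],
      exclusion_flags = flags
    )
  })
}
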