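# Builders for hand-specified and random test records.

t_base <- as.POSIXct("2016-01-01 10:00:00", tz = "UTC")

ts_min <- function(min) t_base + min * 60

# A record with vital series laid out at 10-minute intervals.
mk_rec <- function(id = "r1", spo2 = NA, sbp = NA, temp = NA, pain = NA,
                   resp = NA, hr = NA, cons = NA, n = NULL,
                   iv = emstt::interventions(), md = emstt::medications(),
                   disposition = "transported", flags = character(),
                   patient = id, start_min = 0, end_min = 120) {
  if (is.null(n))
    n <- max(1, length(spo2), length(sbp), length(temp), length(pain),
             length(resp), length(hr), length(cons))
  obs <- emstt::observations(
    time = ts_min(start_min + 10 * seq_len(n)),
    spo2 = rep_len(spo2, n), sbp = rep_len(sbp, n),
    temp = rep_len(temp, n), pain = rep_len(pain, n),
    resp_rate = rep_len(resp, n), heart_rate = rep_len(hr, n),
    consciousness = rep_len(cons, n))
  emstt::pcr(id, patient, ts_min(start_min), ts_min(end_min),
             observations = obs, interventions = iv, medications = md,
             disposition = disposition, exclusion_flags = flags)
}

fired_items <- function(record, config = emstt::trigger_config(),
                        cohort = list(record)) {
  hits <- emstt::screen(cohort, config)
  sort(hits$item[hits$record_id == record$record_id])
}

# Random but always-valid record exercising optional/absent fields, for
# round-trip property tests.
random_record <- function(id) {
  n <- sample(0:4, 1)
  maybe <- function(gen) if (stats::runif(1) < 0.3) rep(NA, n) else gen(n)
  obs <- emstt::observations(
    time = ts_min(sort(stats::runif(n, 1, 100))),
    spo2 = maybe(function(k) sample(80:100, k, replace = TRUE)),
    sbp = maybe(function(k) sample(80:200, k, replace = TRUE)),
    temp = maybe(function(k) round(stats::runif(k, 35, 40), 1)),
    pain = maybe(function(k) sample(0:10, k, replace = TRUE)),
    resp_rate = maybe(function(k) sample(8:30, k, replace = TRUE)),
    heart_rate = maybe(function(k) sample(40:140, k, replace = TRUE)),
    consciousness = maybe(function(k)
      sample(c("alert", "voice", "pain", "unresponsive"), k, replace = TRUE)))
  n_iv <- sample(0:2, 1)
  iv <- emstt::interventions(
    kind = sample(c("supplemental_oxygen", "assisted_ventilation",
                    "spinal_immobilisation", "other"), n_iv, replace = TRUE),
    time = ts_min(stats::runif(n_iv, 1, 100)),
    indicated = sample(c(TRUE, FALSE, NA), n_iv, replace = TRUE),
    performed = sample(c(TRUE, FALSE, NA), n_iv, replace = TRUE))
  n_md <- sample(0:2, 1)
  md <- emstt::medications(
    name = sample(c("Morphine", "paracetamol", "NALOXONE", "ondansetron"),
                  n_md, replace = TRUE),
    time = ts_min(stats::runif(n_md, 1, 100)))
  emstt::pcr(
    id, paste0("pt-", id), ts_min(0), ts_min(120),
    observations = obs, interventions = iv, medications = md,
    disposition = sample(c("transported", "refusal_of_transport", "other"), 1),
    exclusion_flags = if (stats::runif(1) < 0.2)
      sample(c("care_pathway", "interfacility_transport"), 1) else character())
}

random_cohort <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) random_record(sprintf("rec-%03d", i)))
}

expect_cohort_equal <- function(a, b) {
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    for (f in c("record_id", "patient_id", "disposition", "exclusion_flags"))
      expect_equal(a[[i]][[f]], b[[i]][[f]])
    expect_equal(as.numeric(a[[i]]$encounter_start),
                 as.numeric(b[[i]]$encounter_start))
    expect_equal(as.numeric(a[[i]]$encounter_end),
                 as.numeric(b[[i]]$encounter_end))
    for (f in c("observations", "interventions", "medications")) {
      x <- a[[i]][[f]]; y <- b[[i]][[f]]
      rownames(x) <- rownames(y) <- NULL
      x$time <- as.numeric(x$time); y$time <- as.numeric(y$time)
      expect_equal(x, y)
    }
  }
}
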