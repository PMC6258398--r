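# Synthetic cohort generator.
#
# Emulates a stream of prehospital patient care records with known
# ground-truth trigger/adverse-event/harm labels, so that every downstream
# stage (sampling, screening, review, classification, rates, control charts)
# is testable without access to any operational record system. Trigger
# positives are planted by running the trigger rules in reverse and verified
# against the engine itself; negatives carry constant in-encounter vitals in
# non-scoring bands so they provably fire nothing.

#' Synthetic cohort configuration
#'
#' Defaults emulate the published study conditions: 36 half-month sampling
#' periods over 18 months; a service answering 600-700 calls/day (about
#' 9,750 encounters per half-month); per-item trigger prevalences that pool
#' to 8.20 triggers per 10,000 encounters, split across items in the
#' observed proportions (C1 0.42, C2 4.56, C3 0.13, C4 0.30, C5 2.62,
#' P1 0.17, M1 and R1 0); an adverse-event probability of 0.30 per trigger
#' (2.48/8.20) and a harm probability of 0.14 per adverse event (0.34/2.48);
#' harm-category distributions matching the observed classification mix; and
#' a reviewer error rate of 0.05, under which two independent reviewers agree
#' on a fraction eps^2 + (1-eps)^2 = 0.905 of decisions.
#'
#' @param seed integer seed fixing all randomness. One master seed is split
#'   into independent sub-streams (cohort construction, trigger planting and
#'   labels, reviewer simulation, sampling) so that changing e.g. the
#'   reviewer error rate does not perturb the cohort.
#' @param n_periods number of half-month sampling periods.
#' @param encounters_per_period_mean Poisson mean of the per-period patient
#'   encounter denominator.
#' @param trigger_prevalence named vector, expected events per 10,000
#'   encounters per trigger item (values above 10,000 are a config error).
#' @param p_ae_given_trigger probability a trigger-positive record carries a
#'   true adverse event.
#' @param p_harm_given_ae probability an adverse event involves harm.
#' @param merp_distribution probability vector over the modified NCC MERP
#'   categories A..I (C replaced by C_EMS) assigned to trigger-positive
#'   records.
#' @param severity_distribution probability vector over severity codes 1..7
#'   assigned to trigger-positive records in the severity era.
#' @param reviewer_error_rate probability a reviewer flips any single true
#'   decision, independently per decision and reviewer (stands in for the
#'   record-legibility problems that drive real disagreement).
#' @param exclusion_rate probability a background record carries an exclusion
#'   flag.
#' @param background_per_period number of trigger-negative records
#'   materialised per period (the review pool). Trigger-positive records are
#'   materialised in full; the remaining encounters exist only in the
#'   denominators.
#' @param severity_start_period first period (sample) index carrying severity
#'   codes (the second classification system was introduced mid-study).
#' @param vitals_baselines per-parameter mean/sd for the constant
#'   in-encounter vitals of background records.
#' @param start_date first day of the first period (ISO date).
#' @return an object of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L, n_periods = 36,
                             encounters_per_period_mean = 9750,
                             trigger_prevalence = c(
                               C1 = 0.42, C2 = 4.56, C3 = 0.13, C4 = 0.30,
                               C5 = 2.62, M1 = 0, P1 = 0.17, R1 = 0),
                             p_ae_given_trigger = 0.30,
                             p_harm_given_ae = 0.14,
                             merp_distribution = c(
                               A = 147, B = 36, C_EMS = 11, D = 0, E = 0,
                               F = 0, G = 0, H = 0, I = 0) / 194,
                             severity_distribution = c(
                               `1` = 0, `2` = 3, `3` = 0, `4` = 11, `5` = 10,
                               `6` = 11, `7` = 67) / 102,
                             reviewer_error_rate = 0.05,
                             exclusion_rate = 0.05,
                             background_per_period = 40,
                             severity_start_period = 10,
                             vitals_baselines = list(
                               sbp = c(mean = 125, sd = 10),
                               spo2 = c(mean = 98, sd = 1.2),
                               temp = c(mean = 36.8, sd = 0.3),
                               pain = c(mean = 1, sd = 1),
                               resp_rate = c(mean = 16, sd = 2),
                               heart_rate = c(mean = 75, sd = 8)),
                             start_date = "2016-01-01") {
  stopifnot(length(seed) == 1, n_periods >= 1,
            encounters_per_period_mean > 0, background_per_period >= 0)
  if (!all(names(trigger_prevalence) %in% trigger_items()))
    stop("trigger_prevalence: unknown item name(s)", call. = FALSE)
  if (any(trigger_prevalence < 0) || any(trigger_prevalence > 10000))
    stop("trigger_prevalence: rates must lie in [0, 10000] per 10,000",
         call. = FALSE)
  probs <- c(p_ae_given_trigger, p_harm_given_ae, reviewer_error_rate,
             exclusion_rate)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  check_dist <- function(d, nm, what) {
    if (!identical(sort(names(d)), sort(nm)) ||
        any(d < 0) || abs(sum(d) - 1) > 1e-9)
      stop(what, ": must be a probability vector over {",
           paste(nm, collapse = ","), "} summing to 1", call. = FALSE)
  }
  check_dist(merp_distribution, c("A", "B", "C_EMS", "D", "E", "F", "G",
                                  "H", "I"), "merp_distribution")
  check_dist(severity_distribution, as.character(1:7),
             "severity_distribution")
  structure(list(
    seed = as.integer(seed), n_periods = as.integer(n_periods),
    encounters_per_period_mean = encounters_per_period_mean,
    trigger_prevalence = trigger_prevalence,
    p_ae_given_trigger = p_ae_given_trigger,
    p_harm_given_ae = p_harm_given_ae,
    merp_distribution = merp_distribution,
    severity_distribution = severity_distribution,
    reviewer_error_rate = reviewer_error_rate,
    exclusion_rate = exclusion_rate,
    background_per_period = as.integer(background_per_period),
    severity_start_period = as.integer(severity_start_period),
    vitals_baselines = vitals_baselines,
    start_date = start_date
  ), class = "generator_config")
}

# Half-month periods: H1 = days 1-15, H2 = day 16 to month end.
make_periods <- function(start_date, n_periods) {
  months <- seq(as.Date(start_date), by = "month",
                length.out = ceiling(n_periods / 2) + 1)
  out <- lapply(seq_len(n_periods), function(i) {
    m <- (i - 1) %/% 2 + 1
    half <- (i - 1) %% 2 + 1
    start <- if (half == 1) months[m] else months[m] + 15
    end <- if (half == 1) months[m] + 15 else months[m + 1]
    data.frame(
      index = i,
      period_id = sprintf("%s-H%d", format(months[m], "%Y-%m"), half),
      start = as.POSIXct(start, tz = "UTC"),
      end = as.POSIXct(end, tz = "UTC"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

rnorm_clamp <- function(n, ms, lo, hi, digits = 0) {
  round(pmin(pmax(stats::rnorm(n, ms[["mean"]], ms[["sd"]]), lo), hi), digits)
}

# Constant in-encounter vitals in non-scoring bands: SpO2 >= 95, SBP in
# 115-175 (0-band, and any +/-25% excursion would be planted, not sampled),
# temp <= 37.8, pain <= 4, resp 12-20, HR 55-90. A record built from these
# fires no trigger by construction.
draw_safe_vitals <- function(config) {
  vb <- config$vitals_baselines
  list(
    spo2 = rnorm_clamp(1, vb$spo2, 95, 100),
    sbp = rnorm_clamp(1, vb$sbp, 115, 175),
    temp = rnorm_clamp(1, vb$temp, 36.0, 37.8, digits = 1),
    pain = rnorm_clamp(1, vb$pain, 0, 4),
    resp_rate = rnorm_clamp(1, vb$resp_rate, 12, 20),
    heart_rate = rnorm_clamp(1, vb$heart_rate, 55, 90)
  )
}

make_background_record <- function(record_id, period_start, period_end,
                                   config, exclusion_flags = character(),
                                   patient_id = record_id,
                                   disposition = "transported",
                                   enc_start = NULL) {
  dur_s <- stats::runif(1, 45, 75) * 60
  if (is.null(enc_start)) {
    span <- as.numeric(difftime(period_end, period_start, units = "secs"))
    enc_start <- period_start + stats::runif(1, 0, max(span - dur_s, 1))
  }
  enc_start <- round(enc_start, "secs")
  enc_end <- enc_start + round(dur_s)
  n_obs <- sample(2:4, 1)
  t_obs <- enc_start + round(cumsum(stats::runif(n_obs, 5, 10)) * 60)
  v <- draw_safe_vitals(config)
  pcr(
    record_id = record_id, patient_id = patient_id,
    encounter_start = enc_start, encounter_end = enc_end,
    observations = observations(
      time = t_obs, spo2 = v$spo2, sbp = v$sbp, temp = v$temp,
      pain = v$pain, resp_rate = v$resp_rate, heart_rate = v$heart_rate,
      consciousness = "alert"),
    disposition = disposition,
    exclusion_flags = exclusion_flags
  )
}

#' Plant a trigger item on a record
#'
#' Edits a record that currently fires nothing so that it fires *exactly* the
#' requested item, and asserts this by re-evaluating the trigger engine on
#' the edited record (engine-as-oracle). Planting draws from the caller's
#' RNG state. The return-call item R1 cannot be planted on a single record
#' (it needs a refusal/return pair for the same patient); request it at
#' cohort level via [generate_cohort()].
#'
#' @param record a `"pcr"` record firing no trigger.
#' @param item one of `"C1".."C5"`, `"M1"`, `"P1"`.
#' @param config the [trigger_config()] used as the planting oracle.
#' @return the edited `"pcr"` record.
#' @export
plant_trigger <- function(record, item, config = trigger_config()) {
  if (item == "R1")
    stop("R1 cannot be planted on a single record; plant at cohort level ",
         "(refusal-of-transport record plus a return within the window)",
         call. = FALSE)
  stopifnot(item %in% trigger_items())
  obs <- record$observations
  mid <- record$encounter_start +
    as.numeric(difftime(record$encounter_end, record$encounter_start,
                        units = "secs")) / 2
  ensure_obs <- function(n_min) {
    while (nrow(obs) < n_min) {
      t_new <- if (nrow(obs)) obs$time[nrow(obs)] + 420 else mid
      obs <<- rbind(obs, observations(time = t_new))
    }
  }
  if (item == "C1") {
    # one observation only, so the EWS-increase item cannot co-fire
    ensure_obs(1)
    obs <- obs[1, , drop = FALSE]
    obs$spo2 <- sample(87:93, 1)
  } else if (item == "C2") {
    # rise of 25% between 0-scoring EWS pressure bands
    ensure_obs(2)
    b <- sample(115:140, 1)
    obs$sbp <- round(b * 1.25)
    obs$sbp[1] <- b
  } else if (item == "C3") {
    ensure_obs(1)
    obs$pain <- NA_real_
    obs$pain[nrow(obs)] <- sample(5:9, 1)
  } else if (item == "C4") {
    # supra-threshold temperature worth a single EWS point, on the last
    # observation so no later reading can count as a reduction
    ensure_obs(1)
    obs$temp <- NA_real_
    obs$temp[nrow(obs)] <- round(stats::runif(1, 38.2, 38.9), 1)
  } else if (item == "C5") {
    ensure_obs(2)
    obs$resp_rate <- sample(21:24, 1)  # 2-point band
    obs$resp_rate[1] <- sample(13:20, 1)  # 0-point band
  }
  iv <- record$interventions
  md <- record$medications
  if (item == "M1") {
    md <- rbind(md, medications(
      name = c(sample(config$opioid_names, 1), config$antagonist_name),
      time = c(record$encounter_start + 600, record$encounter_start + 1200)))
  } else if (item == "P1") {
    iv <- rbind(iv, interventions(
      kind = "spinal_immobilisation", time = record$encounter_start + 300,
      indicated = FALSE, performed = TRUE))
  }
  out <- pcr(record$record_id, record$patient_id, record$encounter_start,
             record$encounter_end, observations = obs, interventions = iv,
             medications = md, disposition = record$disposition,
             exclusion_flags = record$exclusion_flags)
  assert_fires_exactly(out, item, config)
  out
}

assert_fires_exactly <- function(record, items, config,
                                 index = cohort_index(list(record))) {
  fired <- vapply(eval_record(record, index, config), `[[`, character(1),
                  "item")
  if (!identical(sort(fired), sort(items)))
    stop(sprintf("plant failed on %s: wanted {%s}, engine fired {%s}",
                 record$record_id, paste(items, collapse = ","),
                 paste(fired, collapse = ",")), call. = FALSE)
  v <- validate_record(record)
  if (length(v)) stop("plant produced invalid record: ",
                      paste(v, collapse = "; "), call. = FALSE)
  invisible(record)
}

# Refusal-of-transport record plus a return encounter for the same patient a
# uniform 1-23 h later; the return record carries the R1 hit.
plant_return_pair <- function(id_refusal, id_return, patient_id,
                              period_start, period_end, config,
                              trig_config = trigger_config()) {
  refusal <- make_background_record(
    id_refusal, period_start, period_start + 0.4 *
      as.numeric(difftime(period_end, period_start, units = "secs")),
    config, patient_id = patient_id, disposition = "refusal_of_transport")
  gap_s <- round(stats::runif(1, 1, 23) * 3600)
  ret <- make_background_record(
    id_return, period_start, period_end, config, patient_id = patient_id,
    enc_start = refusal$encounter_end + gap_s)
  idx <- cohort_index(list(refusal, ret))
  assert_fires_exactly(ret, "R1", trig_config, index = idx)
  assert_fires_exactly(refusal, character(0), trig_config, index = idx)
  list(refusal = refusal, ret = ret)
}

#' Generate a synthetic cohort with ground truth
#'
#' Per period, the encounter denominator is Poisson with the configured mean,
#' and each encounter independently carries each trigger item with
#' probability `prevalence / 10,000`; equivalently (and as implemented), the
#' per-period planted count for each item is Binomial(encounters,
#' prevalence/10,000). Planted records are materialised in full and verified
#' to fire exactly the planted item; a configurable number of
#' trigger-negative background records per period forms the review pool; the
#' remaining encounters exist only in the denominators. Adverse-event, harm
#' and classification labels are drawn per the configuration. All output is
#' a pure function of the configuration (including its seed).
#'
#' @param config a [generator_config()].
#' @return a list with elements `records` (list of [pcr()] objects), `truth`
#'   (one row per record: planted items, adverse event, harm, MERP category,
#'   severity code, period), `denominators` (per-period encounter counts)
#'   and `periods` (period calendar).
#' @export
generate_cohort <- function(config = generator_config()) {
  seeds <- derive_seeds(config$seed, 4L)
  periods <- make_periods(config$start_date, config$n_periods)
  tc <- trigger_config()

  cohort <- with_seed(seeds[1], {
    enc <- pmax(stats::rpois(config$n_periods,
                             config$encounters_per_period_mean), 1L)
    recs <- list()
    pidx <- integer()
    for (p in seq_len(config$n_periods)) {
      for (k in seq_len(config$background_per_period)) {
        flags <- if (stats::runif(1) < config$exclusion_rate)
          sample(exclusion_flag_levels, 1) else character()
        recs[[length(recs) + 1]] <- make_background_record(
          sprintf("%s-B%03d", periods$period_id[p], k),
          periods$start[p], periods$end[p], config, flags)
        pidx <- c(pidx, p)
      }
    }
    list(enc = enc, recs = recs, pidx = pidx)
  })

  prev <- config$trigger_prevalence
  planted <- with_seed(seeds[2], {
    recs <- list()
    pidx <- integer()
    items <- character()
    for (p in seq_len(config$n_periods)) {
      for (item in names(prev)) {
        if (prev[[item]] <= 0) next
        k <- stats::rbinom(1, cohort$enc[p], prev[[item]] / 1e4)
        if (k == 0) next
        for (j in seq_len(k)) {
          if (item == "R1") {
            pair <- plant_return_pair(
              sprintf("%s-R1f%02d", periods$period_id[p], j),
              sprintf("%s-R1r%02d", periods$period_id[p], j),
              sprintf("PT-%s-%02d", periods$period_id[p], j),
              periods$start[p], periods$end[p], config, tc)
            recs <- c(recs, list(pair$refusal, pair$ret))
            pidx <- c(pidx, p, p)
            items <- c(items, "", "R1")
          } else {
            base <- make_background_record(
              sprintf("%s-%s%03d", periods$period_id[p], item, j),
              periods$start[p], periods$end[p], config)
            recs[[length(recs) + 1]] <- plant_trigger(base, item, tc)
            pidx <- c(pidx, p)
            items <- c(items, item)
          }
        }
      }
    }
    # ground-truth labels for trigger-positive records
    n <- length(recs)
    ae <- harm <- logical(n)
    merp <- rep(NA_character_, n)
    sev <- rep(NA_integer_, n)
    pos <- which(items != "")
    for (i in pos) {
      ae[i] <- stats::runif(1) < config$p_ae_given_trigger
      harm[i] <- ae[i] && stats::runif(1) < config$p_harm_given_ae
      merp[i] <- sample(names(config$merp_distribution), 1,
                        prob = config$merp_distribution)
      if (pidx[i] >= config$severity_start_period)
        sev[i] <- as.integer(sample(names(config$severity_distribution), 1,
                                    prob = config$severity_distribution))
    }
    list(recs = recs, pidx = pidx, items = items, ae = ae, harm = harm,
         merp = merp, sev = sev)
  })

  records <- c(cohort$recs, planted$recs)
  n_bg <- length(cohort$recs)
  n_pl <- length(planted$recs)
  truth <- data.frame(
    record_id = vapply(records, function(r) r$record_id, character(1)),
    period_id = periods$period_id[c(cohort$pidx, planted$pidx)],
    sample_index = c(cohort$pidx, planted$pidx),
    stringsAsFactors = FALSE
  )
  for (it in trigger_items())
    truth[[paste0("true_", it)]] <- c(rep(FALSE, n_bg),
                                      planted$items == it)
  truth$true_ae <- c(rep(FALSE, n_bg), planted$ae)
  truth$true_harm <- c(rep(FALSE, n_bg), planted$harm)
  truth$true_merp <- c(rep(NA_character_, n_bg), planted$merp)
  truth$true_severity <- c(rep(NA_integer_, n_bg), planted$sev)

  list(
    records = records,
    truth = truth,
    denominators = data.frame(period_id = periods$period_id,
                              encounters = cohort$enc,
                              stringsAsFactors = FALSE),
    periods = periods
  )
}

#' Simulate paired reviewer decisions from ground truth
#'
#' Each reviewer reports every decision equal to the truth with probability
#' `1 - reviewer_error_rate`, independently per decision and reviewer
#' (binary decisions flip; categorical classifications are replaced by a
#' uniformly chosen different category). Two such reviewers agree on any one
#' binary decision with probability `eps^2 + (1-eps)^2`. Deterministic given
#' the configuration seed, and on an RNG stream independent of the cohort's,
#' so changing the error rate does not change the cohort.
#'
#' @param truth the `truth` data frame from [generate_cohort()].
#' @param config the same [generator_config()].
#' @return list with decision data frames `r1` and `r2`, one row per case:
#'   per-item trigger calls, adverse-event and harm flags, MERP category and
#'   severity code.
#' @export
generate_reviews <- function(truth, config) {
  seeds <- derive_seeds(config$seed, 4L)
  eps <- config$reviewer_error_rate
  n <- nrow(truth)
  merp_levels <- names(config$merp_distribution)
  with_seed(seeds[3], {
    make <- function(rid) {
      d <- data.frame(case_id = truth$record_id, reviewer_id = rid,
                      sample_index = truth$sample_index,
                      stringsAsFactors = FALSE)
      for (it in trigger_items())
        d[[paste0("trigger_", it)]] <-
          xor(truth[[paste0("true_", it)]], stats::runif(n) < eps)
      d$ae <- xor(truth$true_ae, stats::runif(n) < eps)
      d$harm <- xor(truth$true_harm, stats::runif(n) < eps)
      d$merp <- truth$true_merp
      flip <- !is.na(d$merp) & stats::runif(n) < eps
      d$merp[flip] <- vapply(d$merp[flip], function(cur)
        sample(setdiff(merp_levels, cur), 1), character(1))
      d$severity <- truth$true_severity
      flip <- !is.na(d$severity) & stats::runif(n) < eps
      d$severity[flip] <- vapply(d$severity[flip], function(cur)
        sample(setdiff(1:7, cur), 1), integer(1))
      d
    }
    list(r1 = make("reviewer1"), r2 = make("reviewer2"))
  })
}
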