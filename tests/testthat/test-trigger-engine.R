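cfg <- trigger_config()

test_that("C1 fires on untreated desaturation and respects the two clauses", {
  expect_equal(fired_items(mk_rec("a", spo2 = 88)), "C1")
  # < 85 with oxygen given after but no assisted ventilation: the critical
  # clause still fires
  r <- mk_rec("b", spo2 = 84,
              iv = interventions("supplemental_oxygen", ts_min(20)))
  expect_equal(fired_items(r), "C1")
  # low (not critical) desaturation relieved by oxygen at-or-after: no hit
  r <- mk_rec("c", spo2 = 90,
              iv = interventions("supplemental_oxygen", ts_min(10)))
  expect_length(fired_items(r), 0)
  # oxygen documented only before the first low reading does not relieve
  r <- mk_rec("d", spo2 = c(90, 90),
              iv = interventions("supplemental_oxygen", ts_min(5)))
  expect_equal(fired_items(r), "C1")
})

test_that("C1 is monotone in supplemental oxygen", {
  set.seed(7)
  for (i in 1:30) {
    r <- mk_rec(paste0("m", i), spo2 = sample(85:99, 2))
    with_o2 <- r
    with_o2$interventions <- interventions("supplemental_oxygen", ts_min(15))
    before <- !is.null(eval_c1(r, cfg))
    after <- !is.null(eval_c1(with_o2, cfg))
    expect_false(!before && after)  # adding oxygen never creates a hit
  }
})

test_that("C2 uses relative change from the first measurement, both directions", {
  expect_false(is.null(eval_c2(mk_rec("a", sbp = c(120, 90)), cfg)))  # -25%
  expect_null(eval_c2(mk_rec("b", sbp = c(100, 80)), cfg))       # exactly 20%
  expect_equal(fired_items(mk_rec("c", sbp = c(120, 150))), "C2")  # +25%
  expect_length(fired_items(mk_rec("d", sbp = 120)), 0)          # single value
  # drop-only mode ignores rises
  drop_cfg <- trigger_config(c2_direction = "drop")
  expect_null(eval_c2(mk_rec("e", sbp = c(100, 125)), drop_cfg))
  expect_false(is.null(eval_c2(mk_rec("f", sbp = c(100, 75)), drop_cfg)))
})

test_that("C3/C4 fire on supra-threshold values without subsequent reduction", {
  expect_equal(fired_items(mk_rec("a", pain = 6)), "C3")        # no later reading
  expect_length(fired_items(mk_rec("b", pain = c(6, 5))), 0)    # any decrease
  expect_equal(fired_items(mk_rec("c", pain = c(3, 6))), "C3")  # max is last
  expect_length(fired_items(mk_rec("d", pain = 4)), 0)          # boundary, strict
  expect_length(fired_items(mk_rec("e", temp = 38.0)), 0)       # boundary, strict
  expect_equal(fired_items(mk_rec("f", temp = 38.4)), "C4")
  expect_length(fired_items(mk_rec("g", temp = c(38.9, 38.4))), 0)
  # a reading equal to the maximum is not a reduction
  expect_equal(fired_items(mk_rec("h", pain = c(6, 6))), "C3")
})

test_that("EWS sums band scores, ignores absent vitals, errors out of bands", {
  toy <- list(
    spo2 = data.frame(lo = c(0, 92, 94, 96), hi = c(92, 94, 96, 101),
                      score = c(3, 2, 1, 0)),
    sbp = data.frame(lo = c(0, 90, 101, 111, 220),
                     hi = c(90, 101, 111, 220, Inf),
                     score = c(3, 2, 1, 0, 3)))
  expect_equal(compute_ews(list(spo2 = 91, sbp = 105), toy), 4)
  expect_equal(compute_ews(list(spo2 = 98, sbp = 120), toy), 0)
  expect_equal(compute_ews(list(sbp = 105), toy), 1)  # absent spo2 scores 0
  expect_error(compute_ews(list(temp = 50), default_ews_table()),
               "outside all configured bands")
  # brute-force lookup oracle on random observations
  set.seed(11)
  tab <- default_ews_table()
  for (i in 1:50) {
    obs <- list(spo2 = sample(85:100, 1), sbp = sample(70:230, 1),
                resp_rate = sample(6:30, 1), heart_rate = sample(35:150, 1),
                temp = round(stats::runif(1, 34, 41), 1),
                consciousness = sample(c("alert", "voice", NA), 1))
    expect_equal(compute_ews(obs, tab), naive_ews(obs, tab))
  }
})

test_that("C5 fires on an EWS increase strictly above the threshold", {
  # resp 16 -> 0 points; resp 22 -> 2 points: increase 2 > 1 fires
  expect_equal(fired_items(mk_rec("a", resp = c(16, 22))), "C5")
  # spo2 95 -> 1 point from 0: increase exactly 1 does not fire
  expect_length(fired_items(mk_rec("b", spo2 = c(97, 95))), 0)
  # decrease never fires
  expect_length(fired_items(mk_rec("c", resp = c(22, 16), n = 2)), 0)
})

test_that("M1 requires an opioid and the antagonist, in any order", {
  m <- function(...) mk_rec("m", md = medications(c(...), ts_min(c(15, 25))))
  expect_equal(fired_items(m("morphine", "naloxone")), "M1")
  expect_equal(fired_items(m("naloxone", "fentanyl")), "M1")
  expect_length(fired_items(m("morphine", "paracetamol")), 0)
  expect_length(fired_items(mk_rec("m", md = medications("naloxone", ts_min(15)))), 0)
})

test_that("P1 fires on indication mismatch; undocumented indication warns", {
  p <- function(ind, perf) mk_rec("p", iv = interventions(
    "spinal_immobilisation", ts_min(15), indicated = ind, performed = perf))
  expect_equal(fired_items(p(FALSE, TRUE)), "P1")
  expect_length(fired_items(p(TRUE, TRUE)), 0)
  expect_equal(fired_items(p(TRUE, FALSE)), "P1")  # omitted when indicated
  expect_warning(hit <- eval_p1(p(NA, TRUE), cfg), "undocumented indication")
  expect_null(hit)
  # applied_without_indication mode ignores omissions
  narrow <- trigger_config(p1_mode = "applied_without_indication")
  expect_null(eval_p1(p(TRUE, FALSE), narrow))
  expect_false(is.null(eval_p1(p(FALSE, TRUE), narrow)))
})

test_that("R1 fires on the return record within the half-open 24 h window", {
  refusal <- mk_rec("ref", disposition = "refusal_of_transport",
                    start_min = 0, end_min = 60)
  ret_at <- function(h, id = "ret") mk_rec(
    id, patient = "ref", start_min = 60 + h * 60, end_min = 120 + h * 60)
  expect_equal(fired_items(ret_at(23), cohort = list(refusal, ret_at(23))), "R1")
  expect_equal(fired_items(ret_at(24), cohort = list(refusal, ret_at(24))), "R1")
  over <- ret_at(24 + 1 / 60)
  expect_length(fired_items(over, cohort = list(refusal, over)), 0)
  # hit attaches to the return record, names the refusal as companion
  hits <- screen(list(refusal, ret_at(5)))
  expect_equal(hits$record_id, "ret")
  expect_equal(hits$evidence[[1]][[1]]$value, "ref")
  # different patient, no trigger
  other <- mk_rec("oth", patient = "someone-else", start_min = 120,
                  end_min = 180)
  expect_length(fired_items(other, cohort = list(refusal, other)), 0)
})

test_that("screen agrees with an independent naive re-evaluation on random cohorts", {
  set.seed(23)
  cohort <- list()
  for (i in 1:120) {
    r <- random_record(sprintf("rr-%03d", i))
    cohort[[i]] <- r
  }
  got <- suppressWarnings(screen(cohort, cfg))
  want <- naive_screen(cohort, cfg)
  key <- function(d) sort(paste(d$record_id, d$item))
  expect_identical(key(got), key(want))
  expect_gt(nrow(got), 0)  # the random cohort does exercise the rules
})

test_that("screen is deterministic and evidence refers to the record", {
  cohort <- list(mk_rec("a", spo2 = 88), mk_rec("b", sbp = c(120, 90)))
  h1 <- screen(cohort, cfg)
  h2 <- screen(cohort, cfg)
  expect_identical(h1, h2)
  expect_true(all(vapply(h1$evidence, length, integer(1)) > 0))
})
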