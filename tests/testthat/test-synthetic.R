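small_cfg <- function(seed = 1, ...) {
  generator_config(seed = seed, n_periods = 4,
                   encounters_per_period_mean = 1500,
                   background_per_period = 15, ...)
}

test_that("cohorts are pure functions of the configuration", {
  a <- generate_cohort(small_cfg(seed = 5))
  b <- generate_cohort(small_cfg(seed = 5))
  expect_identical(a$truth, b$truth)
  expect_identical(a$denominators, b$denominators)
  expect_cohort_equal(a$records, b$records)
  # a different reviewer error rate must not perturb the cohort stream
  c_ <- generate_cohort(small_cfg(seed = 5, reviewer_error_rate = 0.5))
  expect_identical(a$truth, c_$truth)
})

test_that("zero prevalence yields a trigger-free cohort", {
  cfg <- small_cfg(trigger_prevalence = c(C1 = 0, C2 = 0, C3 = 0, C4 = 0,
                                          C5 = 0, M1 = 0, P1 = 0, R1 = 0))
  co <- generate_cohort(cfg)
  expect_equal(nrow(screen(co$records)), 0)
  expect_false(any(co$truth$true_ae))
})

test_that("prevalence above 10,000 per 10,000 is a config error", {
  expect_error(small_cfg(trigger_prevalence = c(C2 = 10001)), "10000")
})

test_that("planted counts follow the binomial sampling distribution", {
  # 50 per 10,000 over ~100,000 encounters: expect 500 +/- 3*sqrt(500)
  cfg <- generator_config(
    seed = 99, n_periods = 10, encounters_per_period_mean = 10000,
    background_per_period = 0, exclusion_rate = 0,
    trigger_prevalence = c(C2 = 50))
  co <- generate_cohort(cfg)
  n_pl <- sum(co$truth$true_C2)
  n_enc <- sum(co$denominators$encounters)
  expected <- n_enc * 50 / 1e4
  expect_lt(abs(n_pl - expected), 3 * sqrt(expected))
  # and the engine confirms every plant (engine-as-oracle, built in)
  hits <- screen(co$records)
  expect_equal(sort(hits$record_id),
               sort(co$truth$record_id[co$truth$true_C2]))
  expect_true(all(hits$item == "C2"))
})

test_that("plant_trigger fires exactly the requested item and keeps records valid", {
  set.seed(42)
  base <- function() mk_rec(paste0("bb", sample.int(1e6, 1)),
                            spo2 = 98, sbp = 125, temp = 36.8, pain = 1,
                            resp = 16, hr = 72, cons = "alert", n = 3)
  for (item in c("C1", "C2", "C3", "C4", "C5", "M1", "P1")) {
    for (rep in 1:5) {
      planted <- plant_trigger(base(), item)
      expect_identical(fired_items(planted), item)
      expect_identical(validate_record(planted), character(0))
    }
  }
  # planted C4 appends a supra-threshold temperature with no later lower one
  p <- plant_trigger(base(), "C4")
  expect_gt(max(p$observations$temp, na.rm = TRUE), 38)
  # planted C2 moves the pressure out of the 20% band around the baseline
  p <- plant_trigger(base(), "C2")
  s <- p$observations$sbp
  expect_gt(abs(s[length(s)] - s[1]) / s[1], 0.2)
  # planted M1 carries both the opioid and the antagonist
  p <- plant_trigger(base(), "M1")
  expect_true("naloxone" %in% p$medications$name)
  expect_error(plant_trigger(base(), "R1"), "cohort level")
})

test_that("for error-free reviews the screen output equals planted truth on every seed", {
  for (seed in 1:4) {
    cfg <- small_cfg(seed = seed, reviewer_error_rate = 0,
                     trigger_prevalence = c(C1 = 10, C2 = 20, C3 = 10,
                                            C4 = 10, C5 = 15, M1 = 5,
                                            P1 = 5, R1 = 10))
    co <- generate_cohort(cfg)
    hits <- screen(co$records)
    for (it in trigger_items()) {
      expect_setequal(hits$record_id[hits$item == it],
                      co$truth$record_id[co$truth[[paste0("true_", it)]]])
    }
    rev <- generate_reviews(co$truth, cfg)
    for (it in trigger_items())
      expect_identical(rev$r1[[paste0("trigger_", it)]],
                       co$truth[[paste0("true_", it)]])
    expect_identical(rev$r2$ae, co$truth$true_ae)
  }
})

test_that("reviewer agreement follows eps^2 + (1-eps)^2", {
  fake_truth <- data.frame(record_id = sprintf("c%04d", 1:4000),
                           sample_index = rep(12, 4000),
                           stringsAsFactors = FALSE)
  for (it in trigger_items()) fake_truth[[paste0("true_", it)]] <- FALSE
  fake_truth$true_ae <- rep(c(TRUE, FALSE), 2000)
  fake_truth$true_harm <- FALSE
  fake_truth$true_merp <- NA_character_
  fake_truth$true_severity <- NA_integer_

  for (eps in c(0.5, 0.05)) {
    cfg <- generator_config(seed = 3, reviewer_error_rate = eps)
    rev <- generate_reviews(fake_truth, cfg)
    p_agree <- mean(rev$r1$ae == rev$r2$ae)
    expected <- eps^2 + (1 - eps)^2
    se <- sqrt(expected * (1 - expected) / 4000)
    expect_lt(abs(p_agree - expected), 3 * se + 1e-9)
  }
  # eps = 0: both reviewers identical to truth, 100% agreement
  cfg0 <- generator_config(seed = 3, reviewer_error_rate = 0)
  rev0 <- generate_reviews(fake_truth, cfg0)
  expect_equal(percent_agreement(rev0$r1$ae, rev0$r2$ae), 100)
  expect_identical(rev0$r1$ae, fake_truth$true_ae)
})

test_that("review simulation is deterministic given the seed", {
  co <- generate_cohort(small_cfg(seed = 8))
  r_a <- generate_reviews(co$truth, small_cfg(seed = 8))
  r_b <- generate_reviews(co$truth, small_cfg(seed = 8))
  expect_identical(r_a, r_b)
})
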