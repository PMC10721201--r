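test_that("missing bout ends are imputed at start + 15 s and present ends kept", {
  ev <- make_events("M1", "O2", c("2012-06-01 10:00:00", "2012-06-01 11:00:00"),
                    "bout", end = c(NA, "2012-06-01 11:00:40"))
  out <- impute_bout_end(ev)
  expect_equal(out$end_time[1], ts("2012-06-01 10:00:15"))
  expect_equal(out$end_time[2], ts("2012-06-01 11:00:40"))
})

test_that("direct latencies anchor on the most recent receipt from the same partner", {
  mothers <- make_mothers(3)
  # M2 helps M1 (day 1), M1 helps M2 (day 20): one direct record of ~19 days
  ev <- make_events(
    female = c("M2", "M1"), offspring = c("O1", "O2"),
    start = c("2012-06-01 10:00:00", "2012-06-20 10:00:00"),
    outcome = "bout", end = c("2012-06-01 10:00:20", "2012-06-20 10:00:10")
  )
  rec <- direct_latencies(ev, mothers)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$mother_id, "M1")
  expect_equal(rec$latency_days, 19 - 20 / 86400, tolerance = 1e-9)

  # help given with no prior receipt from that partner: no record
  ev2 <- make_events("M1", "O2", "2012-06-01 10:00:00", "bout",
                     end = "2012-06-01 10:00:10")
  expect_equal(nrow(direct_latencies(ev2, mothers)), 0)
})

test_that("generalized latencies anchor on the most recent receipt from anyone", {
  mothers <- make_mothers(3)
  # M3 helps M1 on day 5; M1 helps M2 on day 6 -> generalized ~1 day, no direct
  ev <- make_events(
    female = c("M3", "M1"), offspring = c("O1", "O2"),
    start = c("2012-06-05 10:00:00", "2012-06-06 10:00:00"),
    outcome = "bout", end = c("2012-06-05 10:00:15", "2012-06-06 10:00:25")
  )
  gen <- generalized_latencies(ev, mothers)
  dir <- direct_latencies(ev, mothers)
  expect_equal(nrow(gen), 1)
  expect_equal(gen$latency_days, 1 - 15 / 86400, tolerance = 1e-9)
  expect_equal(nrow(dir), 0)
})

test_that("simulated streams match the brute-force latency oracle and obey the dominance property", {
  set.seed(31)
  sim <- simulate_group(sim_config(n_mothers = 6, observation_days = 15,
                                   group_id = "GL", seed = 31))
  dl <- direct_latencies(sim$events, sim$mothers, sim$relatedness, year = 2012L)
  gl <- generalized_latencies(sim$events, sim$mothers, sim$relatedness, year = 2012L)
  expect_equal(sort(dl$latency_days), oracle_latencies(sim$events, sim$mothers, "direct"),
               tolerance = 1e-12)
  expect_equal(sort(gl$latency_days), oracle_latencies(sim$events, sim$mothers, "generalized"),
               tolerance = 1e-12)
  # per given bout with both defined: generalized <= direct
  key_d <- paste(dl$mother_id, dl$given_start)
  key_g <- paste(gl$mother_id, gl$given_start)
  shared <- intersect(key_d, key_g)
  expect_gt(length(shared), 0)
  expect_true(all(gl$latency_days[match(shared, key_g)] <=
                    dl$latency_days[match(shared, key_d)] + 1e-12))
  # permutation invariance of the event log
  shuf <- sim$events[sample(nrow(sim$events)), ]
  dl2 <- direct_latencies(shuf, sim$mothers, sim$relatedness, year = 2012L)
  expect_equal(dplyr::arrange(dl2, mother_id, given_start),
               dplyr::arrange(dl, mother_id, given_start))
})

test_that("the rule comparison reports raw means and the printed-style difference", {
  set.seed(32)
  n <- 80
  rec <- dplyr::bind_rows(
    tibble::tibble(mother_id = rep(paste0("M", 1:8), 10), rule = "direct",
                   latency_days = rlnorm(n, log(19), 0.3),
                   age = rep(4:11, 10), offspring_sex = rep(c("M", "F"), 40),
                   r = rnorm(n, 0, 0.05), year = rep(c(2012L, 2013L), 40)),
    tibble::tibble(mother_id = rep(paste0("M", 1:8), 10), rule = "generalized",
                   latency_days = rlnorm(n, log(1.1), 0.3),
                   age = rep(4:11, 10), offspring_sex = rep(c("M", "F"), 40),
                   r = rnorm(n, 0, 0.05), year = rep(c(2012L, 2013L), 40))
  )
  cmp <- suppressMessages(compare_rules(rec))
  expect_equal(cmp$difference_days,
               mean(rec$latency_days[rec$rule == "direct"]) -
                 mean(rec$latency_days[rec$rule == "generalized"]))
  rc <- cmp$fit$coefficients
  b <- rc[rc$term == "rulegeneralized", ]
  expect_lt(b$estimate, 0)
  expect_lt(b$p, 0.001)

  # identical distributions: rule coefficient near zero
  rec0 <- rec
  rec0$latency_days <- rep(rlnorm(n, log(5), 0.3), 2)
  cmp0 <- suppressMessages(compare_rules(rec0))
  rc0 <- cmp0$fit$coefficients
  expect_lt(abs(rc0$estimate[rc0$term == "rulegeneralized"]), 0.1)

  expect_error(compare_rules(rec[rec$rule == "direct", ]), "both latency rules")
})

test_that("latency records round-trip through the exchange CSV", {
  rec <- tibble::tibble(mother_id = "M1", rule = "direct", latency_days = 2.5,
                        received_start = ts("2012-06-01 10:00:00"),
                        given_start = ts("2012-06-03 22:00:00"),
                        age = 7, offspring_sex = "F", r = 0.02, year = 2012L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_latencies(rec, f)
  back <- read_latencies(f)
  expect_equal(back$latency_days, 2.5)
  expect_equal(names(back), c("mother_id", "rule", "latency_days", "age",
                              "offspring_sex", "r", "year"))
})
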