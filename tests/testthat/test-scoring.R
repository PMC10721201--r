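test_that("solicitations are scored by the 5 s suckling cutoff", {
  expect_equal(classify_solicitation(5.0, FALSE), "bout")
  expect_equal(classify_solicitation(4.9, TRUE), "rejection")
  expect_equal(classify_solicitation(NA, TRUE), "attempt")   # female walks away
  expect_equal(classify_solicitation(0, TRUE), "attempt")
  expect_equal(classify_solicitation(c(12, 3, NA), c(FALSE, TRUE, TRUE)),
               c("bout", "rejection", "attempt"))
  expect_error(classify_solicitation(-1, TRUE), "negative")
  expect_error(classify_solicitation(5, TRUE, approached_within_head = FALSE))
})

test_that("suckling episodes merge across gaps shorter than 20 s and split at 20 s", {
  ep <- tibble::tibble(
    start_time = ts(c("2012-06-01 10:00:00", "2012-06-01 10:00:20")),
    end_time = ts(c("2012-06-01 10:00:10", "2012-06-01 10:00:30")),
    duration_s = c(10, 10)
  )
  merged <- merge_bout_fragments(ep)  # 10 s gap < 20 s: one bout
  expect_equal(nrow(merged), 1)
  expect_equal(merged$duration_s, 20)
  expect_equal(merged$end_time, ep$end_time[2])

  ep20 <- ep
  ep20$start_time[2] <- ep$end_time[1] + 20  # exactly 20 s terminates
  expect_equal(nrow(merge_bout_fragments(ep20)), 2)

  expect_identical(merge_bout_fragments(ep[1, ]), ep[1, ])  # single episode

  overlap <- ep
  overlap$start_time[2] <- ep$end_time[1] - 1
  expect_error(merge_bout_fragments(overlap), "overlap")
})

test_that("sex similarity is the stated indicator and symmetric", {
  expect_equal(sex_similarity("M", "M"), 1L)
  expect_equal(sex_similarity("F", "F"), 1L)
  expect_equal(sex_similarity("M", "F"), 0L)
  expect_equal(sex_similarity("F", "M"), 0L)
  expect_error(sex_similarity("m", "F"), "sex")
})

test_that("dyad table counts non-filial bouts within ordered pairs", {
  mothers <- make_mothers(3)
  rel <- make_relatedness(3)
  ev <- make_events(
    female = c("M1", "M1", "M1", "M2", "M1", "M3"),
    offspring = c("O2", "O2", "O2", "O1", "O1", "O2"),
    start = paste0("2012-06-01 10:0", 0:5, ":00"),
    outcome = c("bout", "bout", "bout", "bout", "bout", "rejection")
  )
  dy <- build_dyad_table(ev, mothers, rel)
  expect_equal(nrow(dy), 6)  # N(N-1) ordered pairs
  expect_equal(dy$a_ij[dy$giver_id == "M1" & dy$receiver_id == "M2"], 3L)
  expect_equal(dy$a_ij[dy$giver_id == "M2" & dy$receiver_id == "M1"], 1L)
  # the filial bout (M1 nursing its own O1) and the rejection are excluded
  expect_equal(sum(dy$a_ij), 4L)
  expect_equal(dy$rafi[dy$giver_id == "M1" & dy$receiver_id == "M2"], 0.5)
  expect_equal(dy$received[dy$giver_id == "M1" & dy$receiver_id == "M2"], 1L)
  # unknown offspring errors
  bad <- ev; bad$offspring_id[1] <- "OX"
  expect_error(build_dyad_table(bad, mothers, rel), "no known mother")
})

test_that("dyad table has no events -> all-zero counts, and conserves the bout total", {
  mothers <- make_mothers(4)
  rel <- make_relatedness(4)
  empty <- make_events(character(), character(), character(), character())[0, ]
  dy0 <- build_dyad_table(empty, mothers, rel)
  expect_equal(nrow(dy0), 12)
  expect_true(all(dy0$a_ij == 0))
  expect_true(all(is.na(dy0$rafi)))
})

test_that("dyad counts equal a brute-force tally and ignore event order", {
  set.seed(5)
  sim <- simulate_group(sim_config(n_mothers = 6, observation_days = 12,
                                   group_id = "GS", seed = 5))
  dy <- build_dyad_table(sim$events, sim$mothers, sim$relatedness)
  oracle <- oracle_dyad_counts(sim$events, sim$mothers)
  for (k in seq_len(nrow(dy))) {
    expect_equal(dy$a_ij[k], oracle[dy$giver_id[k], dy$receiver_id[k]])
  }
  expect_equal(sum(dy$a_ij), sum(sim$counters))
  # permutation invariance
  shuf <- sim$events[sample(nrow(sim$events)), ]
  dy2 <- build_dyad_table(shuf, sim$mothers, sim$relatedness)
  expect_equal(dplyr::arrange(dy2, giver_id, receiver_id),
               dplyr::arrange(dy, giver_id, receiver_id))
})

test_that("mother totals match the dyad margins and conserve the group bout count", {
  set.seed(6)
  sim <- simulate_group(sim_config(n_mothers = 5, observation_days = 10,
                                   group_id = "GT", seed = 6))
  tt <- mother_totals(sim$events, sim$mothers, 10)
  dy <- build_dyad_table(sim$events, sim$mothers, sim$relatedness)
  given <- tapply(dy$a_ij, dy$giver_id, sum)
  received <- tapply(dy$a_ij, dy$receiver_id, sum)
  expect_equal(tt$total_given, as.integer(given[tt$mother_id]),
               ignore_attr = TRUE)
  expect_equal(tt$total_received, as.integer(received[tt$mother_id]),
               ignore_attr = TRUE)
  expect_equal(sum(tt$total_given), sum(tt$total_received))
  expect_equal(sum(tt$total_given), sum(sim$counters))
  expect_true(all(tt$observation_days == 10))
})

test_that("the likelihood table has one row per non-filial solicitation with dyad covariates", {
  mothers <- make_mothers(3)
  rel <- make_relatedness(3, 0.2)
  ev <- make_events(
    female = c("M1", "M2", "M1", "M2"),
    offspring = c("O2", "O1", "O2", "O3"),
    start = paste0("2012-06-01 10:0", 0:3, ":00"),
    outcome = c("bout", "bout", "rejection", "attempt")
  )
  lik <- build_likelihood_table(ev, mothers, rel)
  expect_equal(nrow(lik), 4)
  expect_equal(lik$success, c(1L, 1L, 0L, 0L))
  expect_equal(lik$rafi[1], 1)       # M1<->M2 exchanged 1 and 1
  expect_equal(lik$r, rep(0.2, 4))
  expect_equal(lik$offspring_sex, c("F", "M", "F", "M"))
})
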