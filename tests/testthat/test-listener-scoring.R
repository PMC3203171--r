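test_that("trial lists are blocked by duration and seeded", {
  geom <- cluster_geometry()
  tl <- make_trial_list(geom$stimuli, seed = 3)
  expect_equal(tl$trial_id, seq_len(nrow(tl)))
  expect_true(!is.unsorted(tl$duration_ms))
  # within the shortest block the order is shuffled, not sorted by id
  first_block <- tl$stimulus_id[tl$duration_ms == 20]
  expect_false(identical(first_block, sort(first_block)))
  expect_identical(make_trial_list(geom$stimuli, seed = 3)$stimulus_id,
                   tl$stimulus_id)
  expect_false(identical(make_trial_list(geom$stimuli, seed = 4)$stimulus_id,
                         tl$stimulus_id))

  one_dur <- geom$stimuli[geom$stimuli$duration_ms == 20, ]
  tl1 <- make_trial_list(one_dur, seed = 3)
  expect_setequal(tl1$stimulus_id, one_dur$stimulus_id)
})

test_that("a 300-stimulus factorial design starts with sixty 20 ms trials", {
  stim <- tibble::tibble(
    stimulus_id = sprintf("S%03d", 1:300),
    label = rep(category_labels(), 100),
    duration_ms = rep(c(20, 30, 50, 100, 200), each = 60),
    normalization = "PEAK"
  )
  tl <- make_trial_list(stim, seed = 1)
  expect_true(all(tl$duration_ms[1:60] == 20))
  expect_true(all(tl$duration_ms[61:120] == 30))
})

test_that("zero sensitivity gives uniform guessing", {
  geom <- cluster_geometry(n_per = 40)
  model <- listener_model(sensitivity = 0, duration_gain = c("20" = 1), seed = 2)
  trials <- purrr::map_dfr(1:84, function(i) {
    m <- model
    m$seed <- i
    simulate_listener(m, make_trial_list(geom$stimuli, seed = i),
                      geom$scores, geom$summaries,
                      participant_id = sprintf("U%02d", i))
  })
  props <- table(trials$response_label) / nrow(trials)  # ~10,000 trials
  expect_true(all(abs(props - 1 / 3) < 0.015))
})

test_that("high sensitivity approaches the nearest-barycenter classifier", {
  geom <- cluster_geometry(n_per = 20, sep = 10, sd = 0.5)
  model <- listener_model(sensitivity = 200, duration_gain = c("20" = 1), seed = 6)
  trials <- simulate_listener(model, make_trial_list(geom$stimuli, seed = 6),
                              geom$scores, geom$summaries)
  bary <- rbind(
    VOICE = colMeans(geom$scores[geom$labels == "VOICE", ]),
    MUSIC = colMeans(geom$scores[geom$labels == "MUSIC", ]),
    ESOUND = colMeans(geom$scores[geom$labels == "ESOUND", ])
  )
  nearest <- vapply(trials$stimulus_id, function(id) {
    rownames(bary)[which.min(sqrt(rowSums((bary - matrix(geom$scores[id, ], 3, 2,
                                                         byrow = TRUE))^2)))]
  }, character(1))
  expect_identical(unname(trials$response_label), unname(nearest))
})

test_that("listener sensitivity is recoverable by maximum likelihood", {
  geom <- cluster_geometry(n_per = 50, sep = 4, sd = 1.5, seed = 19)
  truth <- 0.8
  model <- listener_model(sensitivity = truth,
                          duration_gain = c("20" = 0.5, "30" = 0.8, "50" = 1,
                                            "100" = 1.5, "200" = 2),
                          seed = 33)
  trials <- purrr::map_dfr(1:20, function(i) {   # 20 x 150 = 3,000 trials
    m <- model
    m$seed <- i
    simulate_listener(m, make_trial_list(geom$stimuli, seed = 100 + i),
                      geom$scores, geom$summaries,
                      participant_id = sprintf("R%02d", i))
  })
  est <- estimate_sensitivity(trials, geom$scores, geom$summaries,
                              duration_gain = model$duration_gain)
  expect_lt(abs(est$sensitivity - truth) / truth, 0.15)
})

test_that("confusion matrices count and percentage correctly", {
  perfect <- tibble::tibble(
    true_label = rep(category_labels(), each = 10),
    response_label = rep(category_labels(), each = 10)
  )
  cm <- confusion_matrix(perfect)
  expect_equal(diag(cm$counts), setNames(rep(10L, 3), category_labels()))
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0)
  expect_equal(diag(cm$percent), setNames(rep(100, 3), category_labels()))

  # a constructed environmental-sound row: 60% E / 24% M / 16% V
  esound_row <- tibble::tibble(
    true_label = rep("ESOUND", 100),
    response_label = rep(c("ESOUND", "MUSIC", "VOICE"), c(60, 24, 16))
  )
  other <- tibble::tibble(
    true_label = rep(c("VOICE", "MUSIC"), each = 100),
    response_label = rep(c("VOICE", "MUSIC"), each = 100)
  )
  cm2 <- confusion_matrix(dplyr::bind_rows(esound_row, other))
  expect_equal(unname(cm2$percent["ESOUND", c("ESOUND", "MUSIC", "VOICE")]),
               c(60, 24, 16))

  all_voice <- tibble::tibble(
    true_label = rep(category_labels(), each = 5),
    response_label = "VOICE"
  )
  cm3 <- confusion_matrix(all_voice)
  expect_equal(sum(cm3$counts[, "VOICE"]), 15)
  expect_equal(sum(cm3$counts[, c("MUSIC", "ESOUND")]), 0)
})

test_that("the accuracy index follows Hit/N - FA/(2N)", {
  perfect <- tibble::tibble(
    true_label = rep(category_labels(), each = 20),
    response_label = rep(category_labels(), each = 20)
  )
  expect_equal(accuracy_index(perfect, "VOICE")$index, 1.0)

  all_voice <- perfect
  all_voice$response_label <- "VOICE"
  expect_equal(accuracy_index(all_voice, "VOICE")$index, 0)  # 20/20 - 40/40

  # hand arithmetic: 14 hits, 8 false alarms, N = 20 -> 0.70 - 0.20
  mixed <- tibble::tibble(
    true_label = rep(category_labels(), each = 20),
    response_label = c(
      rep("VOICE", 14), rep("MUSIC", 6),
      rep("MUSIC", 15), rep("VOICE", 5),
      rep("ESOUND", 17), rep("VOICE", 3)
    )
  )
  rec <- accuracy_index(mixed, "VOICE")
  expect_equal(rec$hits, 14)
  expect_equal(rec$false_alarms, 8)
  expect_equal(rec$index, 0.50)

  unbalanced <- perfect[-1, ]
  expect_error(accuracy_index(unbalanced, "VOICE"),
               class = "soundgate_parameter_error")
})

test_that("the index is invariant to trial order and bounded", {
  set.seed(61)
  log <- tibble::tibble(
    true_label = rep(category_labels(), each = 20),
    response_label = sample(category_labels(), 60, replace = TRUE)
  )
  a <- accuracy_index(log, "MUSIC")
  b <- accuracy_index(log[sample(60), ], "MUSIC")
  expect_equal(a$index, b$index)
  for (lab in category_labels()) {
    idx <- accuracy_index(log, lab)$index
    expect_gte(idx, -0.5)
    expect_lte(idx, 1)
  }
  # hits + false alarms attributed across labels exhaust the trials
  tot <- sum(vapply(category_labels(), function(lab) {
    r <- accuracy_index(log, lab)
    r$hits + r$false_alarms
  }, numeric(1)))
  expect_equal(tot, nrow(log))
})

test_that("false-alarm rates use the non-label trial count", {
  perfect <- tibble::tibble(
    true_label = rep(category_labels(), each = 20),
    response_label = rep(category_labels(), each = 20)
  )
  for (lab in category_labels()) expect_equal(false_alarm_rate(perfect, lab), 0)

  set.seed(67)
  log <- tibble::tibble(
    true_label = rep(category_labels(), each = 30),
    response_label = sample(category_labels(), 90, replace = TRUE)
  )
  for (lab in category_labels()) {
    manual <- 0
    denom <- 0
    for (i in seq_len(nrow(log))) {
      if (log$true_label[i] != lab) {
        denom <- denom + 1
        if (log$response_label[i] == lab) manual <- manual + 1
      }
    }
    expect_equal(false_alarm_rate(log, lab), manual / denom)
  }
})

test_that("above-chance testing matches the textbook t statistic", {
  expect_true(above_chance_test(rep(0, 5))$degenerate)
  sym <- c(-0.2, -0.1, 0.1, 0.2)
  res <- above_chance_test(sym)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  set.seed(71)
  x <- rnorm(18, mean = 0.1, sd = 0.2)
  res18 <- above_chance_test(x)
  t_oracle <- mean(x) / (sd(x) / sqrt(18))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 17)
  expect_equal(res18$t, t_oracle, tolerance = 1e-9)
  expect_equal(res18$df, 17)
  expect_equal(res18$p_value, p_oracle, tolerance = 1e-9)
  expect_error(above_chance_test(0.3), class = "soundgate_parameter_error")
})

test_that("response logs round-trip through CSV", {
  geom <- cluster_geometry(n_per = 5)
  model <- listener_model(sensitivity = 1, seed = 5)
  trials <- simulate_listener(model, make_trial_list(geom$stimuli, seed = 5),
                              geom$scores, geom$summaries)
  f <- withr::local_tempfile(fileext = ".csv")
  write_response_log(trials, f)
  back <- read_response_log(f)
  expect_equal(as.data.frame(back), as.data.frame(trials))
})
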