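test_that("published configuration reproduces the printed trial counts", {
  sq <- build_trial_sequence(published_cfg, seed = 42)
  tr <- sq$trials
  expect_equal(nrow(tr), 474)
  expect_equal(sum(tr$trial_type == "stop"), 60)
  expect_equal(sum(tr$level == "green"), 234)
  counts <- table(tr$level, tr$trial_type)
  expect_equal(unname(counts["yellow", "stop"]), 6)
  expect_equal(unname(counts["amber", "stop"]), 12)
  expect_equal(unname(counts["orange", "stop"]), 18)
  expect_equal(unname(counts["red", "stop"]), 24)
  expect_equal(unname(counts["yellow", "go"]), 30)
  expect_equal(unname(counts["orange", "go"]), 54)
})

test_that("probability labels follow from the counts", {
  expect_identical(implied_stop_probability(30, 6), 17L)
  expect_identical(implied_stop_probability(48, 12), 20L)
  expect_identical(implied_stop_probability(54, 18), 25L)
  expect_identical(implied_stop_probability(48, 24), 33L)
  expect_identical(implied_stop_probability(10, 0), 0L)
  expect_error(implied_stop_probability(-1, 2), "non-negative")
  expect_error(implied_stop_probability(0, 0))
})

test_that("scheduled duration matches the trial pitch arithmetic", {
  expect_equal(scheduled_duration(published_cfg), 996)
  one <- task_config(levels = data.frame(label = "green", n_go = 1L,
                                         n_stop = 0L),
                     block_size_range = c(1, 1),
                     rest_blocks = data.frame(position = numeric(0),
                                              duration = numeric(0)))
  expect_equal(scheduled_duration(one), 2)
  empty <- task_config(levels = data.frame(label = "green", n_go = 0L,
                                           n_stop = 0L),
                       rest_blocks = data.frame(position = numeric(0),
                                                duration = numeric(0)))
  expect_equal(scheduled_duration(empty), 0)
})

test_that("a single baseline block yields evenly spaced go trials", {
  cfg <- task_config(levels = data.frame(label = "green", n_go = 12L,
                                         n_stop = 0L),
                     rest_blocks = data.frame(position = numeric(0),
                                              duration = numeric(0)))
  sq <- build_trial_sequence(cfg, seed = 1)
  expect_equal(nrow(sq$trials), 12)
  expect_true(all(sq$trials$trial_type == "go"))
  expect_equal(sq$trials$onset, seq(0, 22, by = 2))
})

test_that("onsets advance by the pitch except across rest blocks", {
  sq <- build_trial_sequence(published_cfg, seed = 3)
  d <- diff(sq$trials$onset)
  expect_true(all(d %in% c(2, 26)))
  expect_equal(sum(d == 26), 2)  # two 24 s rests
  expect_equal(nrow(sq$rests), 2)
  expect_true(all(sq$rests$duration == 24))
})

test_that("block structure and pseudorandomisation constraints hold", {
  for (seed in c(2, 9, 77)) {
    sq <- build_trial_sequence(published_cfg, seed = seed)
    tr <- sq$trials
    sizes <- table(tr$block_id)
    expect_true(all(sizes >= 12 & sizes <= 15))
    for (b in unique(tr$block_id)) {
      blk <- tr[tr$block_id == b, ]
      if (blk$block_type[1] == "baseline") {
        expect_true(all(blk$level == "green" & blk$trial_type == "go"))
      } else {
        expect_true(all(blk$level != "green"))
        expect_identical(blk$trial_type[1], "go")
        r <- rle(blk$trial_type)
        expect_true(all(r$lengths[r$values == "stop"] <= 2))
      }
    }
  }
})

test_that("count conservation and probability identity hold over many seeds", {
  for (seed in 1:60) {
    sq <- build_trial_sequence(published_cfg, seed = seed,
                               max_modulator_cor = Inf)
    tr <- sq$trials
    for (i in seq_len(nrow(published_cfg$levels))) {
      lvl <- published_cfg$levels[i, ]
      n_go <- sum(tr$level == lvl$label & tr$trial_type == "go")
      n_st <- sum(tr$level == lvl$label & tr$trial_type == "stop")
      expect_equal(n_go, lvl$n_go)
      expect_equal(n_st, lvl$n_stop)
      if (lvl$p_stop > 0)
        expect_equal(implied_stop_probability(n_go, n_st),
                     as.integer(round(100 * lvl$p_stop)))
    }
  }
})

test_that("sequences and events files are byte-identical per seed", {
  s1 <- build_trial_sequence(published_cfg, seed = 11)
  s2 <- build_trial_sequence(published_cfg, seed = 11)
  expect_identical(s1$trials, s2$trials)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_events(s1, f1); write_events(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  ev <- read_events(f1)
  expect_equal(nrow(ev), 474)
  expect_equal(ev$onset, s1$trials$onset)
})

test_that("inconsistent counts raise a configuration error naming the level", {
  bad <- data.frame(label = c("green", "red"), n_go = c(24L, 24L),
                    n_stop = c(0L, 12L), p_stop = c(0, 0.25))
  cfg <- task_config(levels = bad)
  expect_error(build_trial_sequence(cfg, seed = 1), "red")
})

test_that("config invariants are enforced", {
  expect_error(task_config(ssd_init = 900), "ssd_init")
  expect_error(task_config(staircase_step = 0), "staircase_step")
  expect_error(task_config(block_size_range = c(5, 3)), "block_size_range")
})
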