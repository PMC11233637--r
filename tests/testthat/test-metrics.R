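test_that("ingroup favoritism counts ingroup over non-self allocations", {
  pl <- default_roster()
  all_in <- build_events(data.frame(
    round = 1:6, allocator = "g1h1",
    recipient = c("g1h2", "g1h3", "g1h2", "g1h3", "g1h2", "g1a1")), pl)
  expect_equal(ingroup_favoritism(all_in, 1, 6), 1.0)

  mix <- build_events(data.frame(
    round = 1:6, allocator = "g1h1",
    recipient = c("g1h2", "g1h3", "g1h2", "g1h3", "g2h1", "g2h2")), pl)
  expect_equal(ingroup_favoritism(mix, 1, 6), 4 / 6)

  # self-giving is excluded from numerator and denominator
  selfy <- build_events(data.frame(
    round = 1:6, allocator = "g1h1",
    recipient = c("g1h2", "g1h3", "g1h2", "g1h1", "g1h1", "g1h1")), pl)
  expect_equal(ingroup_favoritism(selfy, 1, 6), 1.0)

  only_self <- build_events(data.frame(
    round = 1:3, allocator = "g1h1", recipient = rep("g1h1", 3)), pl)
  expect_true(is.na(ingroup_favoritism(only_self, 1, 6)))

  two <- build_events(data.frame(round = 1:2,
                                 allocator = c("g1h1", "g1h2"),
                                 recipient = c("g1h2", "g1h1")), pl)
  expect_error(ingroup_favoritism(two, 1, 6), "single allocator")
})

test_that("ingroup_favoritism equals the brute-force counter on random lists", {
  set.seed(14)
  for (i in 1:200) {
    ev <- random_toy_events(n_events = sample(1:30, 1))
    ws <- sample(1:25, 1); we <- ws + sample(0:5, 1)
    expect_identical(ingroup_favoritism(ev, ws, we), oracle_if(ev, ws, we))
    # invariant to injecting self-allocations into the wave
    selfers <- build_events(data.frame(round = rep(ws, 3),
                                       allocator = "g1h1",
                                       recipient = "g1h1"),
                            default_roster())
    expect_identical(ingroup_favoritism(rbind(ev, selfers), ws, we),
                     ingroup_favoritism(ev, ws, we))
  }
})

test_that("if_series yields the study wave structure and drops agents", {
  log1 <- run_game(cfg_s1(c(1, 1), seed = 8), ratings = FALSE)
  s1 <- if_series(log1)
  expect_equal(sort(unique(s1$wave)), 1:5)        # five 6-round waves
  expect_equal(nrow(s1), 6 * 5)                   # 6 humans x 5 waves
  expect_true(all(s1$player_id %in%
                    log1$players$id[log1$players$kind == "human"]))
  expect_true(all(s1$if_value >= 0 & s1$if_value <= 1, na.rm = TRUE))

  log2 <- run_game(cfg_s2(c(2, 0), seed = 8), ratings = FALSE)
  s2 <- if_series(log2)
  expect_equal(sort(unique(s2$wave)), 1:3)        # three 5-round waves
  expect_equal(nrow(s2), 6 * 3)

  expect_error(if_series(log1, wave_length = 7), "divisible")
})

test_that("normalization constants match the eligible-allocator rule for every composition", {
  # (agents in group, humans in group) -> N for each category, allocating group 1
  compositions <- list(c(1, 0), c(2, 0), c(1, 1), c(2, 1), c(2, 2))
  for (agents in compositions) {
    cfg <- cfg_s1(agents, seed = 3)
    log <- run_game(cfg, ratings = FALSE)
    for (g in 1:2) {
      n_h <- sum(log$players$group == g & log$players$kind == "human")
      n_a <- sum(log$players$group == g & log$players$kind == "agent")
      expect_equal(normalized_allocation(log, g, "ingroup_human")$N, n_h - 1L)
      expect_equal(normalized_allocation(log, g, "outgroup_human")$N, n_h)
      if (n_a > 0)
        expect_equal(normalized_allocation(log, g, "ingroup_agent")$N, n_h)
      else
        expect_error(normalized_allocation(log, g, "ingroup_agent"),
                     class = "nudgesim_absent_category")
    }
  }
})

test_that("uniform round-robin allocation gives equal ratios across categories", {
  cfg <- game_config("rr", "1:1", rounds = 7L, starting_tokens = 30L,
                     agents_per_group = c(1, 1), wave_length = 7L, seed = 1)
  pl <- make_players(cfg)
  # every player gives to each of the 7 others exactly once over 7 rounds
  rows <- do.call(rbind, lapply(pl$id, function(p) {
    others <- setdiff(pl$id, p)
    data.frame(round = 1:7, allocator = p, recipient = sample(others),
               stringsAsFactors = FALSE)
  }))
  log <- game_log(cfg, pl, build_events(rows, pl))
  ratios <- vapply(c("ingroup_human", "ingroup_agent", "outgroup_human",
                     "outgroup_agent"),
                   function(cat) normalized_allocation(log, 1, cat)$ratio,
                   numeric(1))
  expect_equal(unname(ratios), rep(1 / 7, 4), tolerance = 1e-12)
})

test_that("norm-enforcing humans withdraw cooperation from ingroup agents", {
  contrasts <- vapply(1:5, function(s) {
    log <- run_game(cfg_s1(c(2, 2), seed = 900 + s), ratings = FALSE)
    mean(withdrawal_contrast(log)$contrast)
  }, numeric(1))
  expect_gt(mean(contrasts), 0)

  log0 <- run_game(cfg_s2(c(0, 0), seed = 1), ratings = FALSE)
  expect_error(withdrawal_contrast(log0),
               class = "nudgesim_absent_category")
})

test_that("rating summaries compute per-cell means and sample SDs", {
  pl <- default_roster()
  rt <- data.frame(rater_id = c("g1h1", "g1h1", "g1h2", "g1h1"),
                   rater_group = c(1L, 1L, 1L, 1L),
                   target_id = c("g1h2", "g1h3", "g1h3", "g2a1"),
                   target_group = c(1L, 1L, 1L, 2L),
                   target_kind = c("human", "human", "human", "agent"),
                   rating_type = c("fairness", "fairness", "fairness",
                                   "humanness"),
                   value = c(3L, 5L, 4L, 4L), stringsAsFactors = FALSE)
  s <- rating_summary(rt)
  fair <- s[s$rating_type == "fairness" & s$relation == "ingroup" &
              s$target_kind == "human", ]
  expect_equal(fair$mean, 4.0)
  expect_equal(fair$n, 3L)
  hum <- s[s$rating_type == "humanness", ]
  expect_equal(hum$mean, 4.0)
  expect_equal(hum$sd, 0)
  expect_equal(hum$n, 1L)

  two <- rt[1:2, ]
  s2 <- rating_summary(two)
  expect_equal(s2$sd, stats::sd(c(3, 5)))   # sample SD, 1.414

  expect_error(rating_summary(rt[0, ]), "no ratings")

  # generated ratings always summarize to means within the scale
  log <- run_game(cfg_s1(c(1, 1), seed = 12))
  sg <- rating_summary(log$ratings)
  expect_true(all(sg$mean >= 1 & sg$mean <= 5))
  expect_equal(nrow(sg[sg$rating_type == "fairness", ]), 4L)
})
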