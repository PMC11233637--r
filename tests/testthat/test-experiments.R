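count_design <- function(design) {
  agents <- vapply(design$configs, function(c) sum(c$agents_per_group), 0L)
  humans <- vapply(design$configs,
                   function(c) 2L * c$group_size - sum(c$agents_per_group), 0L)
  list(games = length(design$configs), agents = sum(agents),
       humans = sum(humans))
}

test_that("the Study-1-style design reproduces the published layout exactly", {
  d <- build_study1_design(seed = 1)
  cnt <- count_design(d)
  expect_equal(cnt$games, 50L)
  expect_equal(cnt$humans, 280L)
  expect_equal(cnt$agents, 120L)
  conds <- vapply(d$configs, function(c) c$condition, "")
  expect_equal(as.integer(table(conds)), rep(10L, 5))
  for (cfg in d$configs) {
    expect_equal(cfg$rounds, 30L)
    expect_equal(cfg$starting_tokens, 30L)
    expect_equal(cfg$wave_length, 6L)
  }
  c21 <- d$configs[conds == "2:1"]
  for (cfg in c21) expect_equal(cfg$agents_per_group, c(2L, 1L))
})

test_that("the Study-2-style design reproduces the published layout exactly", {
  d <- build_study2_design(seed = 1)
  cnt <- count_design(d)
  expect_equal(cnt$games, 60L)
  expect_equal(cnt$humans, 360L)
  expect_equal(cnt$agents, 120L)
  conds <- vapply(d$configs, function(c) c$condition, "")
  expect_equal(as.integer(table(conds)), rep(20L, 3))
  for (cfg in d$configs) {
    expect_equal(cfg$rounds, 15L)
    expect_equal(cfg$starting_tokens, 40L)
    expect_equal(cfg$wave_length, 5L)
  }
  for (cfg in d$configs[conds == "null"])
    expect_equal(cfg$agents_per_group, c(0L, 0L))
})

test_that("per-game seeds are splittable: growing a design keeps earlier seeds", {
  small <- build_study2_design(seed = 9, replications = 3)
  big <- build_study2_design(seed = 9, replications = 5)
  ids_small <- vapply(small$configs, function(c) c$game_id, "")
  ids_big <- vapply(big$configs, function(c) c$game_id, "")
  for (id in ids_small) {
    a <- small$configs[[match(id, ids_small)]]
    b <- big$configs[[match(id, ids_big)]]
    expect_identical(a$seed, b$seed)
  }
  # different master seeds give different per-game seeds
  other <- build_study2_design(seed = 10, replications = 3)
  expect_false(any(vapply(seq_along(small$configs), function(i)
    identical(small$configs[[i]]$seed, other$configs[[i]]$seed), TRUE)))
})

test_that("run_batch simulates every game, logs failures, and writes tables", {
  d <- build_study2_design(seed = 4, replications = 2)
  dir <- withr::local_tempdir()
  b <- run_batch(d, ratings = FALSE, output_dir = dir)
  expect_equal(nrow(b$manifest), 6L)
  expect_true(all(b$manifest$status == "ok"))
  expect_equal(length(b$logs), 6L)
  for (log in b$logs) expect_equal(nrow(log$events), 120L)
  expect_equal(sort(unique(b$if_table$condition)), c("2:0", "2:2", "null"))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "if_table.csv")))
  expect_true(dir.exists(file.path(dir, "logs", d$configs[[1]]$game_id)))

  # a corrupted config is logged as failed; the batch continues
  d$configs[[2]]$seed <- "not a seed"
  b2 <- suppressWarnings(run_batch(d, ratings = FALSE))
  expect_equal(sum(b2$manifest$status == "failed"), 1L)
  expect_equal(sum(b2$manifest$status == "ok"), 5L)
  expect_equal(length(b2$logs), 5L)
})

test_that("identical master seeds reproduce batches exactly", {
  d <- build_study2_design(seed = 6, replications = 1)
  b1 <- run_batch(d)
  b2 <- run_batch(d)
  expect_identical(b1$if_table, b2$if_table)
  expect_identical(b1$alloc_table, b2$alloc_table)
  expect_identical(b1$rating_table, b2$rating_table)
  for (id in names(b1$logs))
    expect_identical(b1$logs[[id]]$events, b2$logs[[id]]$events)
})

test_that("bootstrap_ci is a percentile interval with nominal-ish coverage", {
  expect_equal(unname(bootstrap_ci(rep(3.5, 10), B = 50, seed = 1)),
               c(3.5, 3.5))
  expect_error(bootstrap_ci(numeric(0)), "empty")
  expect_error(bootstrap_ci(1:5, B = 0), "B must be")
  expect_error(bootstrap_ci(1:5, level = 1.2), "level")

  set.seed(8)
  covered <- vapply(1:200, function(i) {
    x <- stats::rnorm(50)
    ci <- bootstrap_ci(x, B = 400)
    ci["lower"] <= 0 && 0 <= ci["upper"]
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("the paired sign-flip permutation test behaves at its edges", {
  x <- c(0.8, 0.7, 0.9, 0.6)
  expect_equal(permutation_wave_test(x, x), 1.0)

  set.seed(2)
  a <- runif(10, 0.6, 0.9)
  b <- a - runif(10, 0.05, 0.2)       # all differences positive
  expect_equal(permutation_wave_test(a, b, permutations = 2000), 2 / 1024)

  expect_warning(p1 <- permutation_wave_test(0.5, 0.4), "one pair")
  expect_equal(p1, 1)
  expect_error(permutation_wave_test(1:3, 1:4), "paired")
  expect_error(permutation_wave_test(a, b, permutations = 10), ">= 100")

  # Monte Carlo branch agrees with enumeration within sampling error
  set.seed(3)
  d_a <- rnorm(25, 0.05, 0.1); d_b <- rep(0, 25)
  p_mc <- permutation_wave_test(d_a, d_b, permutations = 4000, seed = 5)
  expect_true(p_mc > 0 && p_mc < 1)
})
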