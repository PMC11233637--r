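test_that("detect_reciprocation follows the window definition", {
  pl <- default_roster()
  # g2h1 gives to g1h1 at round 1; g1h1 answers at round 2
  ev <- build_events(data.frame(round = c(1, 2),
                                allocator = c("g2h1", "g1h1"),
                                recipient = c("g1h1", "g2h1")), pl)
  expect_true(detect_reciprocation(ev, "g1h1", 2))
  # answer goes elsewhere -> no reciprocation
  ev2 <- build_events(data.frame(round = c(1, 2),
                                 allocator = c("g2h1", "g1h1"),
                                 recipient = c("g1h1", "g1h2")), pl)
  expect_false(detect_reciprocation(ev2, "g1h1", 2))
  # nobody gave to the player in the window -> undefined opportunity
  ev3 <- build_events(data.frame(round = c(1, 2),
                                 allocator = c("g2h1", "g1h1"),
                                 recipient = c("g2h2", "g2h1")), pl)
  expect_true(is.na(detect_reciprocation(ev3, "g1h1", 2)))
  expect_true(is.na(detect_reciprocation(ev, "g1h1", 1)))
  # wider window reaches back further
  ev4 <- build_events(data.frame(round = c(1, 3),
                                 allocator = c("g2h1", "g1h1"),
                                 recipient = c("g1h1", "g2h1")), pl)
  expect_true(is.na(detect_reciprocation(ev4, "g1h1", 3, window = 1)))
  expect_true(detect_reciprocation(ev4, "g1h1", 3, window = 2))
})

test_that("extract_features computes ties, wealth and tendency from the prefix", {
  cfg <- cfg_s2(c(2, 0))
  pl <- make_players(cfg)
  # cold start
  f1 <- extract_features(empty_ev <- build_events(
    data.frame(round = integer(), allocator = character(),
               recipient = character()), pl),
    "g2h1", 1, "g1a1", cfg, players = pl)
  expect_equal(unname(f1), c(0, 0, 0, 1, 0.5))

  # 2 ingroup + 1 outgroup allocations; received one token
  rows <- data.frame(round = 1:4,
                     allocator = c("g2h1", "g2h1", "g2h1", "g1h1"),
                     recipient = c("g2h2", "g2h3", "g1h1", "g2h1"))
  ev <- build_events(rows, pl)
  f <- extract_features(ev, "g2h1", 5, "g1a1", cfg, players = pl)
  expect_equal(f[["ingroup_tie"]], 2 / 3)
  expect_equal(f[["outgroup_tie"]], 1 / 3)
  expect_equal(f[["ingroup_tie"]] + f[["outgroup_tie"]], 1)
  # balance 40 - 3 + 1 = 38 -> wealth 0.95
  expect_equal(f[["wealth"]], 38 / 40)
  expect_equal(f[["group_alignment"]], 0)
  f_in <- extract_features(ev, "g1h1", 5, "g1a1", cfg, players = pl)
  expect_equal(f_in[["group_alignment"]], 1)
})

test_that("degenerate fits reduce K and keep stochastic rows", {
  feats <- list(matrix(rep(c(0, 0.5, 0.5, 1, 0.5), 4), 4, byrow = TRUE,
                       dimnames = list(NULL, c("group_alignment",
                                               "ingroup_tie", "outgroup_tie",
                                               "wealth",
                                               "reciprocation_tendency"))))
  labs <- list(c(NA, TRUE, TRUE, FALSE))
  m1 <- fit_motive_model(feats, labs, K = 1, seed = 1)
  expect_equal(m1$transitions, matrix(1, 1, 1))
  expect_equal(m1$emissions, (2 + 1) / (3 + 2))  # smoothed label mean

  expect_warning(m3 <- fit_motive_model(feats, labs, K = 3, seed = 1),
                 "reducing K")
  expect_equal(m3$K, 1L)

  two <- list(rbind(feats[[1]], feats[[1]] + 1))
  expect_warning(mk <- fit_motive_model(two, list(rep(NA, 8)), K = 3,
                                        seed = 1), "reducing K")
  expect_equal(mk$K, 2L)

  expect_error(fit_motive_model(list(), list(), K = 2), "empty")
})

test_that("fitted models recover a 2-motive generator's parameters", {
  truth <- structure(list(
    K = 2L,
    centers = rbind(c(0, 0.9, 0.1, 1, 0.8), c(1, 0.1, 0.9, 0.4, 0.2)),
    transitions = rbind(c(0.8, 0.2), c(0.3, 0.7)),
    emissions = c(0.8, 0.2), seed = NULL, n_obs = 0L),
    class = "motive_model")
  errs <- vapply(1:20, function(s) {
    sim <- simulate(truth, nsim = 1, seed = s, length = 500,
                    feature_sd = 0.05)
    fit <- suppressWarnings(fit_motive_model(sim$features,
                                             sim$observations, K = 2,
                                             seed = s))
    # align fitted states to truth by nearest center
    ord <- apply(fit$centers, 1, function(ctr)
      which.min(colSums((t(truth$centers) - ctr)^2)))
    max(abs(fit$emissions[order(ord)] - truth$emissions))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.1)

  sim <- simulate(truth, nsim = 1, seed = 99, length = 500)
  fit <- suppressWarnings(fit_motive_model(sim$features, sim$observations,
                                           K = 2, seed = 99))
  ord <- apply(fit$centers, 1, function(ctr)
    which.min(colSums((t(truth$centers) - ctr)^2)))
  perm <- order(ord)
  expect_true(all(abs(fit$transitions[perm, perm] - truth$transitions) < 0.1))
  expect_equal(rowSums(fit$transitions), c(1, 1), tolerance = 1e-9)
})

test_that("predict gives the transition-weighted emission probability", {
  m1 <- random_motive_model(1)
  m1$emissions <- 0.7
  expect_equal(predict(m1, runif(5)), 0.7)

  m2 <- random_motive_model(2)
  m2$transitions <- matrix(0.5, 2, 2)
  m2$emissions <- c(0.2, 0.8)
  # any point maps to a state; both rows mix to 0.5 * 0.2 + 0.5 * 0.8
  expect_equal(predict(m2, runif(5)), 0.5)

  bad <- random_motive_model(2)
  bad$transitions[1, ] <- c(0.4, 0.5)
  expect_error(predict(bad, runif(5)), "sum to 1")
  expect_error(forward_filter(bad, c(TRUE)), "sum to 1")
})

test_that("predictions are invariant to permuting the motive labels", {
  set.seed(3)
  m <- random_motive_model(3)
  perm <- c(3, 1, 2)
  mp <- m
  mp$centers <- m$centers[perm, ]
  mp$transitions <- m$transitions[perm, perm]
  mp$emissions <- m$emissions[perm]
  x <- matrix(runif(20 * 5), 20, 5)
  expect_equal(predict(m, x), predict(mp, x), tolerance = 1e-12)
})

test_that("forward_filter matches the exhaustive path-sum oracle", {
  m1 <- random_motive_model(1)
  expect_equal(forward_filter(m1, c(TRUE, FALSE, NA)), 1)

  set.seed(11)
  for (K in 1:3) for (len in c(1, 3, 6)) {
    m <- random_motive_model(K)
    obs <- sample(c(TRUE, FALSE, NA), len, replace = TRUE)
    expect_equal(forward_filter(m, obs), oracle_forward(m, obs),
                 tolerance = 1e-10)
  }
  expect_error(forward_filter(random_motive_model(2), logical(0)), "empty")

  degenerate <- random_motive_model(2)
  degenerate$emissions <- c(0, 0)
  expect_warning(post <- forward_filter(degenerate, TRUE), "zero likelihood")
  expect_equal(post, c(0.5, 0.5))
})

test_that("motive models survive a JSON round trip", {
  set.seed(21)
  m <- random_motive_model(3)
  m$n_obs <- 42L
  path <- withr::local_tempfile(fileext = ".json")
  write_motive_model(m, path)
  back <- read_motive_model(path)
  expect_equal(back$transitions, m$transitions, tolerance = 1e-12)
  expect_equal(back$emissions, m$emissions, tolerance = 1e-12)
  expect_equal(unname(back$centers), unname(m$centers), tolerance = 1e-12)
  expect_equal(back$K, m$K)
})
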