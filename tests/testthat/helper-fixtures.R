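# Shared fixtures and independent oracles, all built in code.

# standard Study-1-style (30 rounds, 30 tokens) and Study-2-style configs
cfg_s1 <- function(agents = c(1, 1), seed = 1, id = "t_s1",
                   cond = paste(agents, collapse = ":")) {
  game_config(id, cond, rounds = 30L, starting_tokens = 30L,
              agents_per_group = agents, wave_length = 6L, seed = seed)
}
cfg_s2 <- function(agents = c(2, 0), seed = 1, id = "t_s2",
                   cond = paste(agents, collapse = ":")) {
  game_config(id, cond, rounds = 15L, starting_tokens = 40L,
              agents_per_group = agents, wave_length = 5L, seed = seed)
}

# hand-build an event table from a compact spec: a data.frame with
# round, allocator, recipient ids; groups looked up from a roster
build_events <- function(rows, players) {
  ai <- match(rows$allocator, players$id)
  ri <- match(rows$recipient, players$id)
  data.frame(round = as.integer(rows$round),
             allocator_id = rows$allocator,
             allocator_group = players$group[ai],
             allocator_kind = players$kind[ai],
             recipient_id = rows$recipient,
             recipient_group = players$group[ri],
             recipient_kind = players$kind[ri],
             stringsAsFactors = FALSE)
}

default_roster <- function() {
  data.frame(id = c("g1a1", "g1h1", "g1h2", "g1h3",
                    "g2a1", "g2h1", "g2h2", "g2h3"),
             group = rep(1:2, each = 4),
             kind = rep(c("agent", "human", "human", "human"), 2),
             stringsAsFactors = FALSE)
}

# independent brute-force oracle for per-wave ingroup favoritism: a plain
# loop over event rows, counting indicator variables round by round
oracle_if <- function(events, wave_start, wave_end) {
  ia <- 0; oa <- 0
  for (i in seq_len(nrow(events))) {
    r <- events$round[i]
    if (r < wave_start || r > wave_end) next
    if (events$allocator_id[i] == events$recipient_id[i]) next
    if (events$allocator_group[i] == events$recipient_group[i]) ia <- ia + 1
    else oa <- oa + 1
  }
  if (ia + oa == 0) return(NA_real_)
  ia / (ia + oa)
}

# random toy event list for one allocator: recipients drawn over all eight
# players (self included), rounds drawn with replacement
random_toy_events <- function(n_events = 12, rounds = 30) {
  pl <- default_roster()
  who <- "g1h1"
  rec <- sample(pl$id, n_events, replace = TRUE)
  build_events(data.frame(round = sample.int(rounds, n_events, replace = TRUE),
                          allocator = who, recipient = rec,
                          stringsAsFactors = FALSE), pl)
}

# exhaustive path-sum oracle for the forward filter: enumerate all K^T state
# paths, multiply initial (uniform), transition and Bernoulli emission
# probabilities, and marginalize over the final state
oracle_forward <- function(model, obs) {
  K <- model$K; T_ <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  post <- numeric(K)
  for (p in seq_len(nrow(paths))) {
    path <- paths[p, ]
    pr <- 1 / K
    for (t in seq_len(T_)) {
      if (t > 1) pr <- pr * model$transitions[path[t - 1], path[t]]
      e <- model$emissions[path[t]]
      if (!is.na(obs[t])) pr <- pr * (if (obs[t]) e else 1 - e)
    }
    post[path[T_]] <- post[path[T_]] + pr
  }
  post / sum(post)
}

# random valid motive model (for oracle-equivalence property tests)
random_motive_model <- function(K, p = 5) {
  tr <- matrix(stats::runif(K * K, 0.05, 1), K, K)
  tr <- tr / rowSums(tr)
  structure(list(K = K,
                 centers = matrix(stats::runif(K * p), K, p),
                 transitions = tr,
                 emissions = stats::runif(K, 0.05, 0.95),
                 seed = NULL, n_obs = 0L),
            class = "motive_model")
}
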