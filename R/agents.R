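#' Configuration of the adaptive nudge agent
#'
#' @param reciprocation_threshold Probability cut-off strictly between 0 and
#'   1: outgroup participants with predicted reciprocation probability above
#'   it form the agent's candidate set (default 0.5, the natural reading of
#'   "likely to reciprocate").
#' @param warmup_rounds Rounds at the start of the game during which the
#'   agent allocates uniformly at random to the outgroup instead of
#'   predicting (default 1: no data to learn from in round 1).
#' @param motive_count Number of CHMM motive states `K` (default 4).
#' @param include_agent_targets If `TRUE`, outgroup agents may also enter the
#'   candidate set; default `FALSE` (candidates are outgroup humans).
#' @param recip_window Reciprocation window passed to the CHMM features and
#'   labels (default 1 round).
#' @return An object of class `adaptive_agent_config`.
#' @export
adaptive_agent_config <- function(reciprocation_threshold = 0.5,
                                  warmup_rounds = 1L, motive_count = 4L,
                                  include_agent_targets = FALSE,
                                  recip_window = 1L) {
  if (reciprocation_threshold <= 0 || reciprocation_threshold >= 1)
    stop("reciprocation_threshold must lie strictly between 0 and 1")
  if (warmup_rounds < 1L) stop("warmup_rounds must be >= 1")
  if (motive_count < 1L) stop("motive_count must be >= 1")
  structure(list(reciprocation_threshold = reciprocation_threshold,
                 warmup_rounds = as.integer(warmup_rounds),
                 motive_count = as.integer(motive_count),
                 include_agent_targets = include_agent_targets,
                 recip_window = as.integer(recip_window)),
            class = "adaptive_agent_config")
}

#' Nonadaptive outgroup-altruistic agent policy
#'
#' Allocates to a uniformly random member of the opposite group every round;
#' never to itself, never to the ingroup.
#'
#' @param state A `game_state`.
#' @param agent_id Id of the deciding agent.
#' @return The recipient's id.
#' @export
nonadaptive_policy <- function(state, agent_id) {
  pl <- state$players
  i <- match(agent_id, pl$id)
  if (is.na(i)) stop("unknown agent: ", agent_id)
  out <- pl$id[pl$group != pl$group[i]]
  if (!length(out)) stop("malformed game: no outgroup members")
  out[sample.int(length(out), 1L)]
}

# ---- adaptive agent internals -------------------------------------------

# Incrementally cache, per completed round r:
#   feat[[r]]  : 8 x 4 matrix (ingroup_tie, outgroup_tie, wealth, tendency)
#                computed from events strictly before r
#   labels[[p]]: reciprocation label of player p at each round (NA = no
#                opportunity)
# Features/labels never change retroactively, so the cache is append-only.
ensure_agent_cache <- function(env, state, recip_window) {
  pl <- state$players
  ev <- state$events
  t_now <- state$round
  if (is.null(env$feat)) {
    env$feat <- list()
    env$labels <- stats::setNames(
      rep(list(logical(0)), nrow(pl)), pl$id)
    env$labels_done <- 0L
  }
  # labels first: reciprocation at every completed round, so the tendency
  # column of this round's features sees all information available so far
  if (env$labels_done < t_now) {
    for (r in (env$labels_done + 1L):t_now)
      for (pid in pl$id)
        env$labels[[pid]][r] <- detect_reciprocation(ev, pid, r,
                                                     window = recip_window)
    env$labels_done <- t_now
  }
  # feature rows for rounds 1 .. t_now + 1 (round t_now + 1 uses all events
  # seen so far)
  if (length(env$feat) >= t_now + 1L) return(invisible(env))
  for (r in (length(env$feat) + 1L):(t_now + 1L)) {
    past <- ev[ev$round < r, , drop = FALSE]
    m <- matrix(0, nrow(pl), 4,
                dimnames = list(pl$id, c("ingroup_tie", "outgroup_tie",
                                         "wealth", "reciprocation_tendency")))
    for (i in seq_len(nrow(pl))) {
      pid <- pl$id[i]
      own <- past[past$allocator_id == pid & past$recipient_id != pid, ,
                  drop = FALSE]
      if (nrow(own)) {
        m[i, 1] <- mean(own$recipient_group == own$allocator_group)
        m[i, 2] <- 1 - m[i, 1]
      }
      given <- sum(past$allocator_id == pid)
      recv <- sum(past$recipient_id == pid)
      m[i, 3] <- (state$config$starting_tokens - given + recv) /
        state$config$starting_tokens
      lab <- env$labels[[pid]][seq_len(min(r - 1L, env$labels_done))]
      known <- lab[!is.na(lab)]
      m[i, 4] <- if (length(known)) mean(known) else 0.5
    }
    env$feat[[r]] <- m
  }
  invisible(env)
}

# Fit (once per round and agent group) a motive model from the cached
# feature/label sequences, with group alignment coded relative to `group`.
agent_group_model <- function(env, state, group, cfg) {
  key <- sprintf("g%d_r%d", group, state$round + 1L)
  if (!is.null(env$models[[key]])) return(env$models[[key]])
  pl <- state$players
  t_hist <- state$round                  # rounds with observed labels
  align <- as.numeric(pl$group == group)
  feature_seqs <- lapply(seq_len(nrow(pl)), function(i) {
    rows <- t(vapply(seq_len(t_hist), function(r) env$feat[[r]][i, ],
                     numeric(4)))
    cbind(group_alignment = align[i], rows)
  })
  label_seqs <- lapply(pl$id, function(pid) env$labels[[pid]][seq_len(t_hist)])
  model <- suppressWarnings(
    fit_motive_model(feature_seqs, label_seqs, K = cfg$motive_count))
  env$models[[key]] <- model
  model
}

#' Build an adaptive (CHMM-driven) agent policy
#'
#' Each round past the warm-up, the agent refits the motive model from the
#' full public history, predicts each outgroup participant's probability of
#' reciprocating, and allocates uniformly at random among those whose
#' probability exceeds `reciprocation_threshold`. When no outgroup
#' participant qualifies, it falls back to a uniformly random ingroup
#' participant. During warm-up (rounds `<= warmup_rounds`) it allocates
#' uniformly at random to the outgroup. Every decision is appended to the
#' shared decision trace (round, agent, candidate set, chosen recipient,
#' fallback and warm-up flags) for audit.
#'
#' @param cfg An [adaptive_agent_config()].
#' @param shared Environment shared by all adaptive agents of a game,
#'   holding the model cache and the decision trace (see
#'   [make_policy_assignment()]).
#' @return A policy function `f(state, agent_id)`.
#' @export
make_adaptive_policy <- function(cfg = adaptive_agent_config(),
                                 shared = new.env(parent = emptyenv())) {
  force(cfg)
  if (is.null(shared$trace)) reset_shared_env(shared)
  function(state, agent_id) {
    pl <- state$players
    i <- match(agent_id, pl$id)
    if (is.na(i)) stop("unknown agent: ", agent_id)
    g <- pl$group[i]
    r <- state$round + 1L
    outgroup <- pl$id[pl$group != g]
    if (!length(outgroup)) stop("malformed game: no outgroup members")

    if (r <= cfg$warmup_rounds) {
      chosen <- outgroup[sample.int(length(outgroup), 1L)]
      shared$trace <- rbind(shared$trace, data.frame(
        round = r, agent_id = agent_id, candidates = "", chosen = chosen,
        fallback = FALSE, warmup = TRUE, stringsAsFactors = FALSE))
      return(chosen)
    }

    ensure_agent_cache(shared, state, cfg$recip_window)
    model <- agent_group_model(shared, state, g, cfg)

    keep_kind <- if (cfg$include_agent_targets) c("human", "agent") else "human"
    targets <- pl$id[pl$group != g & pl$kind %in% keep_kind]
    if (!length(targets)) targets <- outgroup
    feats <- cbind(group_alignment = 0,
                   shared$feat[[r]][targets, , drop = FALSE])
    p <- predict(model, feats)
    L <- targets[p > cfg$reciprocation_threshold]

    if (length(L)) {
      chosen <- L[sample.int(length(L), 1L)]
      fallback <- FALSE
    } else {
      ingroup_h <- pl$id[pl$group == g & pl$kind == "human"]
      pool <- if (length(ingroup_h)) ingroup_h
              else setdiff(pl$id[pl$group == g], agent_id)
      chosen <- pool[sample.int(length(pool), 1L)]
      fallback <- TRUE
    }
    shared$trace <- rbind(shared$trace, data.frame(
      round = r, agent_id = agent_id,
      candidates = paste(L, collapse = ";"), chosen = chosen,
      fallback = fallback, warmup = FALSE, stringsAsFactors = FALSE))
    chosen
  }
}

#' Build the full policy assignment for a game
#'
#' Humans receive the synthetic participant policy with parameters `params`;
#' agents receive either the nonadaptive outgroup-altruism policy (Study-1
#' style) or the adaptive CHMM policy (Study-2 style). Adaptive agents in
#' the same game share one model cache and decision trace, attached to the
#' returned list as the `shared_env` attribute and collected by
#' [run_game()].
#'
#' @param config A [game_config()].
#' @param params A [policy_params()] for the humans.
#' @param agent_type `"nonadaptive"` or `"adaptive"`.
#' @param agent_cfg An [adaptive_agent_config()] (used when adaptive).
#' @return Named list of policy functions, one per player id.
#' @export
make_policy_assignment <- function(config, params = policy_params(),
                                   agent_type = c("nonadaptive", "adaptive"),
                                   agent_cfg = adaptive_agent_config()) {
  agent_type <- match.arg(agent_type)
  players <- make_players(config)
  shared <- NULL
  policies <- stats::setNames(vector("list", nrow(players)), players$id)
  for (i in seq_len(nrow(players))) {
    if (players$kind[i] == "human") {
      policies[[i]] <- make_human_policy(params)
    } else if (agent_type == "nonadaptive") {
      policies[[i]] <- nonadaptive_policy
    } else {
      if (is.null(shared)) shared <- new.env(parent = emptyenv())
      policies[[i]] <- make_adaptive_policy(agent_cfg, shared)
    }
  }
  attr(policies, "shared_env") <- shared
  policies
}
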