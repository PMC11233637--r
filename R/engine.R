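#' Initialize a game state
#'
#' Sets up the roster, starting balances and an empty history. Every player
#' must have a policy: a function `f(state, player_id)` returning the id of
#' the recipient of that player's token this round. Policies see only the
#' public end-of-round state (completed rounds), mirroring a platform that
#' reveals exchanges after each round.
#'
#' @param config A [game_config()].
#' @param policies Named list mapping every player id to a policy function.
#' @return A `game_state`: list with `config`, `players`, `round` (0),
#'   `balances`, `events` (empty), `policies`, and an empty `agent_trace`.
#' @seealso [play_round()], [run_game()]
#' @export
init_game <- function(config, policies) {
  players <- make_players(config)
  if (!setequal(names(policies), players$id))
    stop("policies must be supplied for exactly the ",
         nrow(players), " players: ",
         paste(players$id, collapse = ", "))
  if (!all(vapply(policies, is.function, logical(1))))
    stop("every policy must be a function")
  structure(
    list(config = config, players = players, round = 0L,
         balances = stats::setNames(rep(config$starting_tokens,
                                        nrow(players)), players$id),
         events = empty_events(), policies = policies),
    class = "game_state")
}

empty_events <- function() {
  data.frame(round = integer(), allocator_id = character(),
             allocator_group = integer(), allocator_kind = character(),
             recipient_id = character(), recipient_group = integer(),
             recipient_kind = character(), stringsAsFactors = FALSE)
}

empty_trace <- function() {
  data.frame(round = integer(), agent_id = character(),
             candidates = character(), chosen = character(),
             fallback = logical(), warmup = logical(),
             stringsAsFactors = FALSE)
}

#' Play one round of the game
#'
#' All players decide simultaneously from the previous round's public state:
#' the eight recipients are computed from the state as it stood at the end of
#' the last round (policies are called in fixed player-id order, so a seeded
#' RNG makes the round deterministic), then all eight allocations are applied
#' together. Each allocation moves exactly one token from allocator to
#' recipient, so the total balance is conserved.
#'
#' @param state A `game_state` with `state$round < config$rounds`.
#' @return The updated `game_state` with eight new events and `round`
#'   incremented.
#' @export
play_round <- function(state) {
  cfg <- state$config
  if (state$round >= cfg$rounds)
    stop("game is over: round ", state$round, " of ", cfg$rounds)
  pl <- state$players
  r <- state$round + 1L

  # decisions from the frozen pre-round state: no intra-round information leak
  recipients <- character(nrow(pl))
  for (i in seq_len(nrow(pl))) {
    pid <- pl$id[i]
    rec <- state$policies[[pid]](state, pid)
    if (!is.character(rec) || length(rec) != 1L || !(rec %in% pl$id))
      stop("policy for ", pid, " returned an invalid recipient")
    recipients[i] <- rec
  }

  idx <- match(recipients, pl$id)
  new_ev <- data.frame(round = r, allocator_id = pl$id,
                       allocator_group = pl$group, allocator_kind = pl$kind,
                       recipient_id = recipients,
                       recipient_group = pl$group[idx],
                       recipient_kind = pl$kind[idx],
                       stringsAsFactors = FALSE)
  bal <- state$balances
  bal <- bal - 1L                      # everyone gives one token
  recv <- table(factor(recipients, levels = pl$id))
  bal <- bal + as.integer(recv)
  names(bal) <- pl$id

  state$events <- rbind(state$events, new_ev)
  state$balances <- bal
  state$round <- r
  state
}

#' Run a complete game
#'
#' Seeds the RNG from `seed` (default: the config's seed), optionally plays
#' unscored warm-up trial rounds (discarded entirely, as a practice run), then
#' plays `config$rounds` scored rounds and, when `ratings = TRUE`, collects
#' post-game fairness and humanness ratings from the human players. The
#' result is reproducible bit-for-bit from `(config, policies, seed)`.
#'
#' @param config A [game_config()].
#' @param policies Named list of policy functions, one per player id; if
#'   `NULL`, a default assignment is built with [make_policy_assignment()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param trial_rounds Unscored practice rounds played and discarded before
#'   the scored game (default 0).
#' @param ratings Generate synthetic post-game ratings (default `TRUE`).
#' @param ... Passed to [make_policy_assignment()] when `policies` is `NULL`.
#' @return A validated [game_log()].
#' @examples
#' cfg <- game_config("ex", "1:1", 30, 30, c(1, 1), 6, seed = 42)
#' log <- run_game(cfg)
#' summary(log)
#' @export
run_game <- function(config, policies = NULL, seed = config$seed,
                     trial_rounds = 0L, ratings = TRUE, ...) {
  set.seed(seed)
  if (is.null(policies))
    policies <- make_policy_assignment(config, ...)
  shared <- attr(policies, "shared_env")
  if (trial_rounds > 0L) {
    trial <- init_game(config, policies)
    for (i in seq_len(trial_rounds)) trial <- play_round(trial)
  }
  # adaptive agents cache fitted models and a decision trace between calls;
  # clear both so the scored game starts clean (the trial run is discarded)
  if (!is.null(shared)) reset_shared_env(shared)
  state <- init_game(config, policies)
  for (r in seq_len(config$rounds)) state <- play_round(state)
  rt <- if (ratings) generate_ratings(state) else empty_ratings()
  trace <- NULL
  if (!is.null(shared) && nrow(shared$trace)) trace <- shared$trace
  game_log(config, state$players, state$events, rt, agent_trace = trace)
}

# internal: fresh model cache + trace for a policy assignment's shared state
reset_shared_env <- function(env) {
  env$trace <- empty_trace()
  env$models <- list()
  env$features <- list()
  invisible(env)
}
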