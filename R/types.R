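#' Game configuration
#'
#' Describes one token-exchange game: two groups of `group_size` players, a
#' fixed number of rounds, a per-player starting token balance, and how many
#' of each group's slots are filled by nudge agents rather than humans.
#'
#' @param game_id Unique string identifying the game.
#' @param condition Condition label, e.g. `"1:0"`, `"2:2"` or `"null"`.
#' @param rounds Number of scored rounds (30 for Study-1-style games, 15 for
#'   Study-2-style games).
#' @param starting_tokens Starting token balance per player. Must be at least
#'   `rounds` so no balance can go negative.
#' @param agents_per_group Integer pair: number of agents in group 1 and
#'   group 2. Each component must lie in `[0, group_size]`.
#' @param wave_length Number of rounds per wave used by the ingroup-favoritism
#'   metric (6 for 30-round games, 5 for 15-round games). `rounds` must be
#'   divisible by `wave_length`.
#' @param group_size Players per group (default 4; the study design).
#' @param seed Integer seed driving all randomness in this game.
#'
#' @return An object of class `game_config`.
#' @examples
#' cfg <- game_config("demo", "1:1", rounds = 30, starting_tokens = 30,
#'                    agents_per_group = c(1, 1), wave_length = 6, seed = 1)
#' @export
game_config <- function(game_id, condition, rounds, starting_tokens,
                        agents_per_group, wave_length, group_size = 4L,
                        seed = 1L) {
  rounds <- as.integer(rounds)
  starting_tokens <- as.integer(starting_tokens)
  agents_per_group <- as.integer(agents_per_group)
  wave_length <- as.integer(wave_length)
  group_size <- as.integer(group_size)
  seed <- as.integer(seed)
  stopifnot(is.character(game_id), length(game_id) == 1L,
            length(agents_per_group) == 2L,
            rounds >= 1L, wave_length >= 1L, group_size >= 1L)
  if (any(agents_per_group < 0L) || any(agents_per_group > group_size))
    stop("agents_per_group components must lie in [0, group_size]")
  if (rounds %% wave_length != 0L)
    stop("rounds (", rounds, ") must be divisible by wave_length (",
         wave_length, ")")
  if (starting_tokens < rounds)
    stop("starting_tokens must be >= rounds to guarantee non-negative balances")
  structure(
    list(game_id = game_id, condition = as.character(condition),
         group_size = group_size, rounds = rounds,
         starting_tokens = starting_tokens,
         agents_per_group = agents_per_group, wave_length = wave_length,
         seed = seed),
    class = "game_config")
}

#' @export
print.game_config <- function(x, ...) {
  cat("<game_config> ", x$game_id, " [", x$condition, "]\n", sep = "")
  cat("  rounds: ", x$rounds, " (waves of ", x$wave_length, ")",
      "   starting tokens: ", x$starting_tokens, "\n", sep = "")
  cat("  agents per group: ", x$agents_per_group[1], "/",
      x$agents_per_group[2], "   seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Build the player roster for a game
#'
#' Agents occupy the first `agents_per_group[g]` slots of each group; the
#' remaining slots are humans. Ids encode group and kind (`g1a1`, `g1h2`, ...)
#' and are unique within the game.
#'
#' @param config A [game_config()].
#' @return A data frame with columns `id`, `group` (1 or 2) and `kind`
#'   (`"human"` or `"agent"`), one row per player, ordered by id.
#' @export
make_players <- function(config) {
  rows <- lapply(1:2, function(g) {
    n_a <- config$agents_per_group[g]
    n_h <- config$group_size - n_a
    ids <- c(if (n_a > 0) sprintf("g%da%d", g, seq_len(n_a)),
             if (n_h > 0) sprintf("g%dh%d", g, seq_len(n_h)))
    data.frame(id = ids, group = g,
               kind = rep(c("agent", "human"), c(n_a, n_h)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# internal: canonical event ordering used everywhere (round, then allocator id)
order_events <- function(events) {
  events <- events[order(events$round, events$allocator_id), , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Construct a game log
#'
#' The complete record of one game: configuration, roster, the ordered
#' allocation events (exactly one per player per round), post-game ratings,
#' and final token balances. Normally produced by [run_game()] or
#' [read_game_log()]; this constructor validates and canonicalizes.
#'
#' @param config A [game_config()].
#' @param players Roster data frame as from [make_players()].
#' @param events Data frame with columns `round`, `allocator_id`,
#'   `allocator_group`, `allocator_kind`, `recipient_id`, `recipient_group`,
#'   `recipient_kind`.
#' @param ratings Data frame of 1-5 ratings (may have zero rows): columns
#'   `rater_id`, `rater_group`, `target_id`, `target_group`, `target_kind`,
#'   `rating_type` (`"fairness"` or `"humanness"`), `value`.
#' @param agent_trace Optional per-round adaptive-agent decision trace.
#' @param validate If `TRUE` (default), stop on the first invariant violation.
#' @return An object of class `game_log`.
#' @seealso [validate_log()], [write_game_log()], [read_game_log()]
#' @export
game_log <- function(config, players, events, ratings = empty_ratings(),
                     agent_trace = NULL, validate = TRUE) {
  events <- order_events(events)
  log <- structure(
    list(config = config, players = players, events = events,
         ratings = ratings,
         final_balances = final_balances(config, players, events),
         agent_trace = agent_trace),
    class = "game_log")
  if (validate) {
    v <- validate_log(log)
    if (length(v)) stop("invalid game log: ", v[1])
  }
  log
}

empty_ratings <- function() {
  data.frame(rater_id = character(), rater_group = integer(),
             target_id = character(), target_group = integer(),
             target_kind = character(), rating_type = character(),
             value = integer(), stringsAsFactors = FALSE)
}

# internal: balances implied by the event stream (each allocation moves 1 token)
final_balances <- function(config, players, events) {
  bal <- stats::setNames(rep(config$starting_tokens, nrow(players)),
                         players$id)
  if (nrow(events)) {
    given <- table(factor(events$allocator_id, levels = players$id))
    recv <- table(factor(events$recipient_id, levels = players$id))
    bal <- bal - as.integer(given) + as.integer(recv)
    names(bal) <- players$id
  }
  bal
}

#' @export
print.game_log <- function(x, ...) {
  cat("<game_log> ", x$config$game_id, " [", x$config$condition, "]: ",
      nrow(x$players), " players, ", x$config$rounds, " rounds, ",
      nrow(x$events), " events, ", nrow(x$ratings), " ratings\n", sep = "")
  invisible(x)
}

#' @export
summary.game_log <- function(object, ...) {
  hum <- object$players$id[object$players$kind == "human"]
  ev <- object$events[object$events$allocator_id %in% hum &
                        object$events$allocator_id != object$events$recipient_id, ]
  if_overall <- if (nrow(ev)) mean(ev$allocator_group == ev$recipient_group)
                else NA_real_
  out <- list(game_id = object$config$game_id,
              condition = object$config$condition,
              rounds = object$config$rounds,
              n_players = nrow(object$players),
              n_agents = sum(object$players$kind == "agent"),
              human_ingroup_share = if_overall,
              balances = object$final_balances)
  class(out) <- "summary.game_log"
  out
}

#' @export
print.summary.game_log <- function(x, ...) {
  cat("Game ", x$game_id, " [", x$condition, "], ", x$rounds, " rounds, ",
      x$n_agents, " agents\n", sep = "")
  cat(sprintf("Human ingroup allocation share (self excluded): %.3f\n",
              x$human_ingroup_share))
  cat("Final balances:\n")
  print(x$balances)
  invisible(x)
}

#' Validate a game log against its structural invariants
#'
#' Checks the roster (two groups of `group_size`, unique ids), the event
#' stream (exactly one allocation per player per round, `2 * group_size *
#' rounds` events in total, all references resolvable), token conservation
#' (balances sum to `n_players * starting_tokens`, none negative), and the
#' ratings (values in 1..5, human raters, no self-rating).
#'
#' @param log A [game_log()].
#' @return Character vector of violation descriptions; empty when the log
#'   conforms. Violations are returned, never raised.
#' @export
validate_log <- function(log) {
  v <- character()
  cfg <- log$config
  pl <- log$players
  ev <- log$events
  n_expected <- 2L * cfg$group_size

  if (anyDuplicated(pl$id))
    v <- c(v, "duplicate player ids")
  if (nrow(pl) != n_expected)
    v <- c(v, sprintf("expected %d players, found %d", n_expected, nrow(pl)))
  if (!setequal(unique(pl$group), 1:2) ||
      any(table(factor(pl$group, levels = 1:2)) != cfg$group_size))
    v <- c(v, sprintf("players must form 2 groups of %d", cfg$group_size))
  if (!all(pl$kind %in% c("human", "agent")))
    v <- c(v, "player kind outside {human, agent}")

  if (nrow(ev) != n_expected * cfg$rounds)
    v <- c(v, sprintf("expected %d events (%d players x %d rounds), found %d",
                      n_expected * cfg$rounds, n_expected, cfg$rounds,
                      nrow(ev)))
  if (nrow(ev)) {
    bad <- !(ev$allocator_id %in% pl$id) | !(ev$recipient_id %in% pl$id)
    if (any(bad))
      v <- c(v, sprintf("event row %d references an unknown player",
                        which(bad)[1]))
    dup <- duplicated(ev[, c("round", "allocator_id")])
    if (any(dup))
      v <- c(v, sprintf(
        "duplicate (player, round) event: allocator %s at round %d (row %d)",
        ev$allocator_id[dup][1], ev$round[dup][1], which(dup)[1]))
    if (any(ev$round < 1L | ev$round > cfg$rounds))
      v <- c(v, "event round outside [1, rounds]")
  }

  bal <- log$final_balances
  if (any(bal < 0))
    v <- c(v, sprintf("negative final balance for %s", names(bal)[bal < 0][1]))
  total <- n_expected * cfg$starting_tokens
  if (sum(bal) != total)
    v <- c(v, sprintf("token conservation violated: balances sum to %d, not %d",
                      sum(bal), total))

  rt <- log$ratings
  if (nrow(rt)) {
    if (any(rt$value < 1L | rt$value > 5L))
      v <- c(v, sprintf("rating value outside 1..5 at row %d",
                        which(rt$value < 1L | rt$value > 5L)[1]))
    if (!all(rt$rating_type %in% c("fairness", "humanness")))
      v <- c(v, "unknown rating_type")
    rater_kind <- pl$kind[match(rt$rater_id, pl$id)]
    if (any(is.na(rater_kind)) || any(rater_kind != "human"))
      v <- c(v, "ratings must come from human raters in the roster")
    if (any(rt$rater_id == rt$target_id))
      v <- c(v, "self-rating present")
  }
  v
}
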