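#' Ingroup favoritism of one player over a block of rounds
#'
#' The ratio of ingroup allocations to all non-self allocations in the round
#' block `[wave_start, wave_end]`:
#' \deqn{IF = \frac{\sum_i IA_i}{\sum_i (IA_i + OA_i)}}
#' where \eqn{IA_i} indicates an ingroup allocation at round i and
#' \eqn{OA_i} an outgroup allocation. Self-giving is a self-favoring rather
#' than group-favoring strategy and is excluded from both numerator and
#' denominator. When the player made no non-self allocation in the block the
#' ratio is undefined and `NA` is returned (a 0/0 has no convention).
#'
#' @param events Event rows of a single allocator (typically a human; agent
#'   rows are removed upstream by [if_series()]).
#' @param wave_start,wave_end First and last round of the wave (inclusive).
#' @return A value in `[0, 1]`, or `NA` when undefined.
#' @export
ingroup_favoritism <- function(events, wave_start, wave_end) {
  stopifnot(wave_start <= wave_end)
  if (nrow(events) && length(unique(events$allocator_id)) > 1L)
    stop("events must come from a single allocator")
  ev <- events[events$round >= wave_start & events$round <= wave_end &
                 events$allocator_id != events$recipient_id, , drop = FALSE]
  if (nrow(ev) == 0L) return(NA_real_)
  ia <- sum(ev$recipient_group == ev$allocator_group)
  ia / nrow(ev)
}

#' Per-wave ingroup favoritism series for every human in a game
#'
#' Splits the game's rounds into consecutive waves of `wave_length` rounds
#' (five 6-round waves for a 30-round game, three 5-round waves for a
#' 15-round game) and computes [ingroup_favoritism()] per human per wave.
#' Events produced by agents are removed: the metric describes human
#' behavior only.
#'
#' @param log A [game_log()].
#' @param wave_length Rounds per wave; defaults to the config's value. Must
#'   divide the number of rounds.
#' @return Data frame with columns `game_id`, `condition`, `player_id`,
#'   `group`, `wave`, `wave_start`, `wave_end`, `if_value` (`NA` where
#'   undefined).
#' @export
if_series <- function(log, wave_length = log$config$wave_length) {
  cfg <- log$config
  if (cfg$rounds %% wave_length != 0L)
    stop("rounds (", cfg$rounds, ") not divisible by wave_length (",
         wave_length, ")")
  n_waves <- cfg$rounds %/% wave_length
  humans <- log$players[log$players$kind == "human", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(humans))) {
    pid <- humans$id[i]
    ev <- log$events[log$events$allocator_id == pid, , drop = FALSE]
    for (w in seq_len(n_waves)) {
      ws <- (w - 1L) * wave_length + 1L
      we <- w * wave_length
      rows[[length(rows) + 1L]] <- data.frame(
        game_id = cfg$game_id, condition = cfg$condition, player_id = pid,
        group = humans$group[i], wave = w, wave_start = ws, wave_end = we,
        if_value = ingroup_favoritism(ev, ws, we),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

category_targets <- function(players, group, category) {
  switch(category,
         ingroup_human = players$id[players$group == group &
                                      players$kind == "human"],
         ingroup_agent = players$id[players$group == group &
                                      players$kind == "agent"],
         outgroup_human = players$id[players$group != group &
                                       players$kind == "human"],
         outgroup_agent = players$id[players$group != group &
                                       players$kind == "agent"],
         stop("unknown category: ", category))
}

#' Normalized human allocation to a target category
#'
#' Counts the allocations made by one group's humans to targets of one of
#' the four categories (ingroup human, ingroup agent, outgroup human,
#' outgroup agent) and normalizes by the number of eligible human allocators
#' per target, `N`. Self-allocations are removed, so for a group of 3 humans
#' and 1 agent `N = 3` for the ingroup-agent, outgroup-human and
#' outgroup-agent categories but `N = 2` for the ingroup-human category
#' (each human target cannot allocate to itself). The ratio is additionally
#' averaged per target and per round so it is comparable across categories
#' of different sizes and across 30- and 15-round games:
#' `ratio = n / (N * T * rounds)` with `T` the number of targets in the
#' category. Under uniform random allocation every category has the same
#' expected ratio.
#'
#' @param log A [game_log()].
#' @param group Allocating group (1 or 2).
#' @param category One of `"ingroup_human"`, `"ingroup_agent"`,
#'   `"outgroup_human"`, `"outgroup_agent"`.
#' @return An object of class `normalized_allocation`: list with `game_id`,
#'   `group`, `category`, `n` (allocation count), `N` (eligible human
#'   allocators per target), `targets` (category size) and `ratio`.
#'   An empty category (e.g. ingroup agents in an agentless group) raises a
#'   condition of class `nudgesim_absent_category`.
#' @export
normalized_allocation <- function(log, group, category) {
  pl <- log$players
  targets <- category_targets(pl, group, category)
  allocators <- pl$id[pl$group == group & pl$kind == "human"]
  if (!length(targets))
    stop(errorCondition(sprintf("category %s is absent in group %d",
                                category, group),
                        class = "nudgesim_absent_category"))
  if (!length(allocators))
    stop("group ", group, " has no human allocators")
  N <- if (category == "ingroup_human") length(allocators) - 1L
       else length(allocators)
  if (N < 1L) stop("no eligible allocators for category ", category)
  ev <- log$events
  n <- sum(ev$allocator_id %in% allocators &
             ev$recipient_id %in% targets &
             ev$allocator_id != ev$recipient_id)
  structure(list(game_id = log$config$game_id, group = group,
                 category = category, n = n, N = N,
                 targets = length(targets),
                 ratio = n / (N * length(targets) * log$config$rounds)),
            class = "normalized_allocation")
}

#' @export
print.normalized_allocation <- function(x, ...) {
  cat(sprintf(
    "<normalized_allocation> game %s, group %d, %s: n = %d, N = %d, T = %d, ratio = %.4f\n",
    x$game_id, x$group, x$category, x$n, x$N, x$targets, x$ratio))
  invisible(x)
}

#' Withdrawal-of-cooperation contrast
#'
#' For each group containing at least one agent and at least two humans,
#' the difference between the normalized allocation its humans direct at
#' ingroup humans and at ingroup agents. A positive value means the group's
#' humans withhold cooperation from their ingroup agents relative to their
#' ingroup human peers.
#'
#' @param log A [game_log()].
#' @return Data frame with columns `game_id`, `condition`, `group`,
#'   `ingroup_human_ratio`, `ingroup_agent_ratio`, `contrast`. Errors (with
#'   class `nudgesim_absent_category`) when no group qualifies.
#' @export
withdrawal_contrast <- function(log) {
  pl <- log$players
  rows <- list()
  for (g in 1:2) {
    n_agents <- sum(pl$group == g & pl$kind == "agent")
    n_humans <- sum(pl$group == g & pl$kind == "human")
    if (n_agents >= 1L && n_humans >= 2L) {
      ih <- normalized_allocation(log, g, "ingroup_human")
      ia <- normalized_allocation(log, g, "ingroup_agent")
      rows[[length(rows) + 1L]] <- data.frame(
        game_id = log$config$game_id, condition = log$config$condition,
        group = g, ingroup_human_ratio = ih$ratio,
        ingroup_agent_ratio = ia$ratio, contrast = ih$ratio - ia$ratio,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop(errorCondition(paste0(
      "no group with >= 1 agent and >= 2 humans in game ",
      log$config$game_id), class = "nudgesim_absent_category"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary statistics of fairness and humanness ratings
#'
#' Crosses each rating type with the rater-relative target group (ingroup:
#' same group as the rater; outgroup otherwise) and the target kind (human
#' vs agent), and reports mean, sample SD and n per cell.
#'
#' @param ratings Rating data frame (as in a `game_log`), nonempty.
#' @return Data frame with columns `rating_type`, `relation`, `target_kind`,
#'   `mean`, `sd`, `n`, one row per nonempty cell.
#' @export
rating_summary <- function(ratings) {
  if (is.null(ratings) || nrow(ratings) == 0L)
    stop("no ratings to summarize")
  relation <- ifelse(ratings$rater_group == ratings$target_group,
                     "ingroup", "outgroup")
  key <- interaction(ratings$rating_type, relation, ratings$target_kind,
                     drop = TRUE, sep = "|")
  cells <- split(ratings$value, key)
  parts <- strsplit(names(cells), "|", fixed = TRUE)
  out <- data.frame(
    rating_type = vapply(parts, `[`, "", 1L),
    relation = vapply(parts, `[`, "", 2L),
    target_kind = vapply(parts, `[`, "", 3L),
    mean = vapply(cells, mean, numeric(1)),
    sd = vapply(cells, function(v) if (length(v) > 1L) stats::sd(v) else 0,
                numeric(1)),
    n = vapply(cells, length, integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$rating_type, out$relation, out$target_kind), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
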