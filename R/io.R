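#' Write a game log to a directory of plain-text files
#'
#' Serializes one game as three (or four) files under `destination`:
#' `events.csv` (one row per allocation: game_id, condition, round,
#' allocator_id, allocator_group, allocator_kind, recipient_id,
#' recipient_group, recipient_kind), `ratings.csv`, a `config.json` sidecar
#' mirroring the [game_config()] fields, and `agent_trace.csv` when the log
#' carries an adaptive-agent decision trace. [read_game_log()] on the same
#' directory reproduces the log exactly.
#'
#' @param log A valid [game_log()].
#' @param destination Directory to write into (created if missing).
#' @return Invisibly, the destination path.
#' @export
write_game_log <- function(log, destination) {
  v <- validate_log(log)
  if (length(v)) stop("refusing to write invalid log: ", v[1])
  if (!dir.exists(destination))
    dir.create(destination, recursive = TRUE)
  if (!dir.exists(destination)) stop("unwritable destination: ", destination)

  ev <- log$events
  ev_out <- data.frame(game_id = log$config$game_id,
                       condition = log$config$condition,
                       ev[, c("round", "allocator_id", "allocator_group",
                              "allocator_kind", "recipient_id",
                              "recipient_group", "recipient_kind")],
                       stringsAsFactors = FALSE)
  utils::write.csv(ev_out, file.path(destination, "events.csv"),
                   row.names = FALSE, quote = TRUE)
  utils::write.csv(log$ratings, file.path(destination, "ratings.csv"),
                   row.names = FALSE, quote = TRUE)
  cfg <- unclass(log$config)
  jsonlite::write_json(cfg, file.path(destination, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(log$agent_trace))
    utils::write.csv(log$agent_trace, file.path(destination, "agent_trace.csv"),
                     row.names = FALSE, quote = TRUE)
  invisible(destination)
}

read_config_sidecar <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  game_config(game_id = raw$game_id, condition = raw$condition,
              rounds = raw$rounds, starting_tokens = raw$starting_tokens,
              agents_per_group = raw$agents_per_group,
              wave_length = raw$wave_length,
              group_size = raw$group_size, seed = raw$seed)
}

#' Read a game log written by [write_game_log()]
#'
#' Reconstructs a validated [game_log()] from `events.csv`, `ratings.csv` and
#' `config.json` (plus `agent_trace.csv` when present) in `source`. The
#' roster is recovered from the event table, which names every player each
#' round. Unknown extra columns are ignored with a warning; missing mandatory
#' columns, groups outside {1, 2} and rating values outside 1..5 are errors
#' that name the offending column or row.
#'
#' @param source Directory containing the files.
#' @return A validated [game_log()].
#' @export
read_game_log <- function(source) {
  ev_path <- file.path(source, "events.csv")
  rt_path <- file.path(source, "ratings.csv")
  cfg_path <- file.path(source, "config.json")
  for (p in c(ev_path, rt_path, cfg_path))
    if (!file.exists(p)) stop("missing file: ", p)

  config <- read_config_sidecar(cfg_path)
  ev <- utils::read.csv(ev_path, stringsAsFactors = FALSE)
  needed <- c("round", "allocator_id", "allocator_group", "allocator_kind",
              "recipient_id", "recipient_group", "recipient_kind")
  miss <- setdiff(needed, names(ev))
  if (length(miss)) stop("events.csv is missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(ev), c("game_id", "condition", needed))
  if (length(extra))
    warning("ignoring unknown event column(s): ", paste(extra, collapse = ", "))
  if (nrow(ev) == 0L) stop("no events in ", ev_path)
  bad_grp <- !(ev$allocator_group %in% 1:2) | !(ev$recipient_group %in% 1:2)
  if (any(bad_grp))
    stop("event row ", which(bad_grp)[1], ": group outside {1, 2}")
  ev <- ev[, needed]

  # roster from the events: every player allocates every round
  seen <- unique(ev[, c("allocator_id", "allocator_group", "allocator_kind")])
  players <- data.frame(id = seen$allocator_id, group = seen$allocator_group,
                        kind = seen$allocator_kind, stringsAsFactors = FALSE)
  players <- players[order(players$id), , drop = FALSE]
  rownames(players) <- NULL

  rt <- utils::read.csv(rt_path, stringsAsFactors = FALSE)
  rt_needed <- c("rater_id", "rater_group", "target_id", "target_group",
                 "target_kind", "rating_type", "value")
  if (nrow(rt) == 0L) {
    rt <- empty_ratings()
  } else {
    rmiss <- setdiff(rt_needed, names(rt))
    if (length(rmiss)) stop("ratings.csv is missing mandatory column(s): ",
                            paste(rmiss, collapse = ", "))
    bad_val <- rt$value < 1L | rt$value > 5L
    if (any(bad_val))
      stop("ratings.csv row ", which(bad_val)[1], ": value ",
           rt$value[bad_val][1], " outside 1..5")
    rt <- rt[, rt_needed]
  }

  trace <- NULL
  tr_path <- file.path(source, "agent_trace.csv")
  if (file.exists(tr_path))
    trace <- utils::read.csv(tr_path, stringsAsFactors = FALSE)

  game_log(config, players, ev, rt, agent_trace = trace)
}
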