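# Splittable master-seed -> per-game seed derivation. Index-based, so adding
# games to a design never perturbs the seeds of earlier games. Kept below
# 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master_seed, index) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m) * 48271 + as.numeric(index) * 1009
  as.integer(s %% m) + 1L
}

study_design <- function(study, configs, replications) {
  structure(list(study = study, configs = configs,
                 replications = replications),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  conds <- vapply(x$configs, function(cfg) cfg$condition, "")
  cat("<study_design> Study ", x$study, ": ", length(x$configs),
      " games, ", x$replications, " per condition\n", sep = "")
  print(table(condition = conds))
  invisible(x)
}

#' Study-1-style experiment design
#'
#' Five conditions varying the number of agents per group — 1:0, 2:0, 1:1,
#' 2:1, 2:2 — with 10 replicated games each: 50 games of 30 rounds, starting
#' balance 30 tokens, 6-round waves. Across the design this places 120
#' agents and 280 humans. Each game gets its own seed derived from the
#' master seed.
#'
#' @param seed Master seed.
#' @param replications Games per condition (default 10).
#' @return A `study_design` (study label 1).
#' @export
build_study1_design <- function(seed = 1L, replications = 10L) {
  layout <- list("1:0" = c(1L, 0L), "2:0" = c(2L, 0L), "1:1" = c(1L, 1L),
                 "2:1" = c(2L, 1L), "2:2" = c(2L, 2L))
  configs <- list()
  for (ci in seq_along(layout)) {
    cond <- names(layout)[ci]
    for (rep in seq_len(replications)) {
      # index is stable per (condition, replicate): growing the design never
      # perturbs the seeds of existing games
      configs[[length(configs) + 1L]] <- game_config(
        game_id = sprintf("s1_%s_g%02d", gsub(":", "", cond), rep),
        condition = cond, rounds = 30L, starting_tokens = 30L,
        agents_per_group = layout[[cond]], wave_length = 6L,
        seed = derive_seed(seed, ci * 100000L + rep))
    }
  }
  study_design(1L, configs, replications)
}

#' Study-2-style experiment design
#'
#' Three conditions — null (no agents), 2:0 (two agents in group 1), 2:2
#' (two agents per group) — with 20 replicated games each: 60 games of 15
#' rounds, starting balance 40 tokens, 5-round waves (120 agents and 360
#' humans across the design).
#'
#' @param seed Master seed.
#' @param replications Games per condition (default 20).
#' @return A `study_design` (study label 2).
#' @export
build_study2_design <- function(seed = 1L, replications = 20L) {
  layout <- list("null" = c(0L, 0L), "2:0" = c(2L, 0L), "2:2" = c(2L, 2L))
  configs <- list()
  for (ci in seq_along(layout)) {
    cond <- names(layout)[ci]
    for (rep in seq_len(replications)) {
      configs[[length(configs) + 1L]] <- game_config(
        game_id = sprintf("s2_%s_g%02d", gsub(":", "", cond), rep),
        condition = cond, rounds = 15L, starting_tokens = 40L,
        agents_per_group = layout[[cond]], wave_length = 5L,
        seed = derive_seed(seed, 1000000L + ci * 100000L + rep))
    }
  }
  study_design(2L, configs, replications)
}

#' Run every game of a design and collect the metric tables
#'
#' Simulates each game with its own config seed (so replays are bit-exact),
#' then assembles tidy tables of the dependent variables: the per-wave
#' ingroup-favoritism series, the normalized allocations per (game, group,
#' category), the withdrawal contrasts for qualifying groups, and the rating
#' summaries. A manifest records each game's condition, seed and outcome;
#' a failing game is logged there and the batch continues.
#'
#' @param design A `study_design` from [build_study1_design()] or
#'   [build_study2_design()].
#' @param params [policy_params()] for the synthetic humans.
#' @param agent_type `"nonadaptive"` (Study-1 style) or `"adaptive"`
#'   (Study-2 style); default chosen from the design's study label.
#' @param agent_cfg [adaptive_agent_config()] for adaptive agents.
#' @param output_dir Optional directory; when given, the metric tables and
#'   manifest are written there as CSV and each game log under
#'   `logs/<game_id>/`.
#' @param keep_logs Keep the `game_log` objects in the result (default
#'   `TRUE`; set `FALSE` to save memory in large batches).
#' @param ratings Generate post-game ratings (default `TRUE`).
#' @return List with elements `logs`, `if_table`, `alloc_table`,
#'   `withdrawal_table`, `rating_table`, `manifest`.
#' @export
run_batch <- function(design, params = policy_params(),
                      agent_type = NULL,
                      agent_cfg = adaptive_agent_config(),
                      output_dir = NULL, keep_logs = TRUE, ratings = TRUE) {
  if (is.null(agent_type))
    agent_type <- if (identical(design$study, 2L)) "adaptive" else "nonadaptive"
  logs <- list()
  if_rows <- list(); alloc_rows <- list(); wd_rows <- list(); rt_rows <- list()
  manifest <- data.frame(game_id = character(), condition = character(),
                         seed = integer(), status = character(),
                         message = character(), stringsAsFactors = FALSE)
  version <- as.character(utils::packageVersion("nudgesim"))

  for (cfg in design$configs) {
    res <- tryCatch({
      log <- run_game(cfg, policies = NULL, seed = cfg$seed,
                      ratings = ratings, params = params,
                      agent_type = agent_type, agent_cfg = agent_cfg)
      list(ok = TRUE, log = log)
    }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    manifest <- rbind(manifest, data.frame(
      game_id = cfg$game_id, condition = cfg$condition, seed = cfg$seed,
      status = if (res$ok) "ok" else "failed",
      message = if (res$ok) "" else res$msg, stringsAsFactors = FALSE))
    if (!res$ok) next
    log <- res$log
    if (keep_logs) logs[[cfg$game_id]] <- log

    if_rows[[cfg$game_id]] <- if_series(log)
    for (g in 1:2) for (cat in c("ingroup_human", "ingroup_agent",
                                 "outgroup_human", "outgroup_agent")) {
      na <- tryCatch(normalized_allocation(log, g, cat),
                     nudgesim_absent_category = function(e) NULL)
      if (!is.null(na))
        alloc_rows[[length(alloc_rows) + 1L]] <- data.frame(
          game_id = cfg$game_id, condition = cfg$condition, group = g,
          category = cat, n = na$n, N = na$N, targets = na$targets,
          ratio = na$ratio, stringsAsFactors = FALSE)
    }
    wd <- tryCatch(withdrawal_contrast(log),
                   nudgesim_absent_category = function(e) NULL)
    if (!is.null(wd)) wd_rows[[length(wd_rows) + 1L]] <- wd
    if (nrow(log$ratings)) {
      rs <- rating_summary(log$ratings)
      rs <- cbind(game_id = cfg$game_id, condition = cfg$condition, rs,
                  stringsAsFactors = FALSE)
      rt_rows[[length(rt_rows) + 1L]] <- rs
    }
    if (!is.null(output_dir))
      write_game_log(log, file.path(output_dir, "logs", cfg$game_id))
  }

  attr(manifest, "version") <- version
  bind <- function(x) if (length(x)) {
    out <- do.call(rbind, x); rownames(out) <- NULL; out
  } else NULL
  out <- list(logs = logs, if_table = bind(if_rows),
              alloc_table = bind(alloc_rows),
              withdrawal_table = bind(wd_rows),
              rating_table = bind(rt_rows), manifest = manifest)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    man_out <- cbind(manifest, version = version, stringsAsFactors = FALSE)
    utils::write.csv(man_out, file.path(output_dir, "manifest.csv"),
                     row.names = FALSE)
    for (nm in c("if_table", "alloc_table", "withdrawal_table",
                 "rating_table"))
      if (!is.null(out[[nm]]))
        utils::write.csv(out[[nm]], file.path(output_dir,
                                              paste0(nm, ".csv")),
                         row.names = FALSE)
  }
  out
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the game-level statistics with replacement `B` times and
#' returns the percentile interval of the resampled means. The game is the
#' replication unit, so resampling is at the game level.
#'
#' @param x Numeric vector of game-level statistics (nonempty; `NA` dropped).
#' @param B Bootstrap replicates (>= 1).
#' @param level Coverage level in (0, 1), default 0.95.
#' @param seed Optional seed.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(x, B = 2000L, level = 0.95, seed = NULL) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty input")
  if (B < 1L) stop("B must be >= 1")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  means <- vapply(seq_len(B),
                  function(b) mean(x[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  alpha <- (1 - level) / 2
  q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  stats::setNames(q, c("lower", "upper"))
}

#' Paired sign-flip permutation test between two waves
#'
#' Tests whether per-game mean ingroup favoritism differs between two waves
#' by randomly flipping the signs of the paired per-game differences. The
#' two-sided p-value is the fraction of sign assignments whose mean absolute
#' difference is at least as large as the observed one. When `2^n` does not
#' exceed `permutations` the full enumeration is used (the p-value is then
#' exact); otherwise `permutations` random flips are drawn and the observed
#' assignment is included (add-one correction).
#'
#' @param wave_a,wave_b Paired numeric vectors of per-game means.
#' @param permutations Number of random sign assignments (>= 100).
#' @param seed Optional seed.
#' @return Two-sided p-value.
#' @export
permutation_wave_test <- function(wave_a, wave_b, permutations = 2000L,
                                  seed = NULL) {
  if (length(wave_a) != length(wave_b))
    stop("wave_a and wave_b must be paired (equal length)")
  keep <- !(is.na(wave_a) | is.na(wave_b))
  d <- wave_a[keep] - wave_b[keep]
  n <- length(d)
  if (n == 0L) stop("no complete pairs")
  if (n == 1L) {
    warning("only one pair; p-value is uninformative")
    return(1)
  }
  if (permutations < 100L) stop("permutations must be >= 100")
  obs <- abs(mean(d))
  if (2^n <= permutations && n <= 20L) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- abs(as.numeric(signs %*% d)) / n
    return(mean(stat >= obs - 1e-12))
  }
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(permutations)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    if (abs(mean(s * d)) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (permutations + 1)
}
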