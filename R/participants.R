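#' Parameters of the synthetic human allocation policy
#'
#' The synthetic participants embody the behavioral structure the analysis
#' assumes: a baseline preference for the ingroup, short-horizon reciprocity
#' toward recent benefactors, and norm enforcement (withholding tokens from
#' ingroup members who visibly favor the outgroup). Utilities are combined
#' into choice probabilities by a softmax with temperature `temperature`.
#'
#' For focal player f, the utility of allocating to player j is
#' \deqn{u_j = b\,[j \in ingroup(f)] + r\,G_W(j \to f)
#'       - e\,[j \in ingroup(f),\ j \ne f,\ s_j > d]
#'       + \log(w_{self})\,[j = f] + m\,[j \in outgroup(f)]\,\bar{s}_{peers}}
#' where `b` = `ingroup_bias`, `r` = `reciprocity_weight`, \eqn{G_W} counts
#' j's gifts to f within the last `reciprocity_window` rounds, `e` =
#' `norm_enforcement` applied when j's historical outgroup share \eqn{s_j}
#' exceeds `defector_threshold`, and `m` = `imitation` (default 0: neither
#' study found imitation of the agents, so the term is off by default and
#' exists only for counterfactual experiments). Choice probabilities are
#' `softmax(u / temperature)`.
#'
#' The default calibration produces a stable null-condition ingroup
#' favoritism around 0.6-0.7, the direction the analysis assumes for
#' agentless populations; it is a documented choice, not a fit to any
#' empirical figure.
#'
#' @param ingroup_bias Utility bonus for same-group targets (including self).
#' @param reciprocity_weight Utility per token received from the target
#'   within the reciprocity window.
#' @param norm_enforcement Utility penalty for ingroup "defectors" whose
#'   outgroup share exceeds `defector_threshold`.
#' @param defector_threshold Outgroup-share level in `[0, 1]` above which an
#'   ingroup member is treated as a norm violator.
#' @param self_weight Multiplicative odds weight for self-allocation
#'   (enters utility as `log(self_weight)`); must be > 0.
#' @param temperature Softmax temperature (> 0); lower is more deterministic.
#' @param reciprocity_window Number of most recent completed rounds counted
#'   by the reciprocity term (default 3).
#' @param imitation Weight of the optional imitation term (default 0).
#' @return An object of class `policy_params`.
#' @export
policy_params <- function(ingroup_bias = 1.2, reciprocity_weight = 1.5,
                          norm_enforcement = 1.0, defector_threshold = 0.5,
                          self_weight = 0.3, temperature = 1.0,
                          reciprocity_window = 3L, imitation = 0) {
  p <- list(ingroup_bias = ingroup_bias,
            reciprocity_weight = reciprocity_weight,
            norm_enforcement = norm_enforcement,
            defector_threshold = defector_threshold,
            self_weight = self_weight, temperature = temperature,
            reciprocity_window = as.integer(reciprocity_window),
            imitation = imitation)
  num <- unlist(p[c("ingroup_bias", "reciprocity_weight", "norm_enforcement",
                    "defector_threshold", "self_weight", "temperature",
                    "imitation")])
  if (any(!is.finite(num))) stop("policy parameters must be finite")
  if (any(num[c("ingroup_bias", "reciprocity_weight", "norm_enforcement",
                "imitation")] < 0))
    stop("utility weights must be >= 0")
  if (p$defector_threshold < 0 || p$defector_threshold > 1)
    stop("defector_threshold must lie in [0, 1]")
  if (p$temperature <= 0) stop("temperature must be > 0")
  if (p$self_weight <= 0) stop("self_weight must be > 0")
  structure(p, class = "policy_params")
}

#' Fraction of a player's past allocations that went to the outgroup
#'
#' Counts the player's non-self allocations strictly before `upto_round` and
#' returns the fraction directed at the other group; 0 when the player has
#' made no non-self allocation yet. This is the quantity norm-enforcing
#' peers use to classify a player as an outgroup-favoring defector.
#'
#' @param events Event data frame (as in a `game_log`).
#' @param player_id Player whose giving record is summarized.
#' @param upto_round Only events with `round < upto_round` are counted.
#' @return A number in `[0, 1]`.
#' @export
outgroup_share <- function(events, player_id, upto_round) {
  stopifnot(upto_round >= 1)
  ev <- events[events$allocator_id == player_id &
                 events$round < upto_round &
                 events$recipient_id != player_id, , drop = FALSE]
  if (nrow(ev) == 0L) return(0)
  mean(ev$recipient_group != ev$allocator_group)
}

#' Choice probabilities of a synthetic human over the eight players
#'
#' Computes the softmax choice distribution described in [policy_params()]
#' from the public game state as of the end of the last completed round.
#'
#' @param state A `game_state` (see [init_game()]).
#' @param focal_id Id of the deciding human player.
#' @param params A [policy_params()].
#' @return Named probability vector over all players (sums to 1).
#' @export
recipient_weights <- function(state, focal_id, params) {
  pl <- state$players
  i <- match(focal_id, pl$id)
  if (is.na(i)) stop("unknown player: ", focal_id)
  if (pl$kind[i] != "human") stop(focal_id, " is not a human player")
  if (params$temperature <= 0) stop("temperature must be > 0")
  ev <- state$events
  next_round <- state$round + 1L

  same <- pl$group == pl$group[i]
  u <- params$ingroup_bias * as.numeric(same)

  if (params$reciprocity_weight > 0 && nrow(ev)) {
    recent <- ev[ev$round >= next_round - params$reciprocity_window &
                   ev$recipient_id == focal_id &
                   ev$allocator_id != focal_id, , drop = FALSE]
    if (nrow(recent)) {
      gifts <- table(factor(recent$allocator_id, levels = pl$id))
      u <- u + params$reciprocity_weight * as.numeric(gifts)
    }
  }

  if (params$norm_enforcement > 0) {
    shares <- vapply(pl$id, outgroup_share, numeric(1),
                     events = ev, upto_round = next_round)
    defector <- same & pl$id != focal_id & shares > params$defector_threshold
    u <- u - params$norm_enforcement * as.numeric(defector)
  }

  if (params$imitation > 0 && nrow(ev)) {
    peers <- pl$id[same & pl$id != focal_id]
    peer_share <- mean(vapply(peers, outgroup_share, numeric(1),
                              events = ev, upto_round = next_round))
    u <- u + params$imitation * peer_share * as.numeric(!same)
  }

  u[i] <- u[i] + log(params$self_weight)

  z <- u / params$temperature
  w <- exp(z - max(z))
  stats::setNames(w / sum(w), pl$id)
}

#' Draw one recipient from a choice distribution
#'
#' @param weights Named non-negative probability vector summing to 1 (within
#'   1e-9).
#' @return One name drawn from the categorical distribution; reproducible
#'   under a seeded RNG.
#' @export
sample_allocation <- function(weights) {
  if (any(weights < 0)) stop("negative weight")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(sum(weights)), ")")
  names(weights)[sample.int(length(weights), 1L, prob = weights)]
}

#' Build a synthetic human policy
#'
#' @param params A [policy_params()].
#' @return A policy function `f(state, player_id)` for [init_game()].
#' @export
make_human_policy <- function(params = policy_params()) {
  force(params)
  function(state, pid) sample_allocation(recipient_weights(state, pid, params))
}

# Synthetic post-game ratings. Fairness tracks how much of the target's
# giving favored the rater's group (ingroup-favoring targets look fair to
# their own group and unfair to the other); humanness is noise around the
# scale midpoint for every target, emulating the finding that agents went
# undetected. Plumbing for the rating metrics, not a fitted model.
generate_ratings <- function(state) {
  pl <- state$players
  ev <- state$events
  humans <- pl$id[pl$kind == "human"]
  if (!length(humans) || !nrow(ev)) return(empty_ratings())
  out <- vector("list", 2L * length(humans) * (nrow(pl) - 1L))
  k <- 0L
  clamp <- function(x) pmin(5L, pmax(1L, as.integer(round(x))))
  for (rater in humans) {
    rg <- pl$group[match(rater, pl$id)]
    for (j in seq_len(nrow(pl))) {
      target <- pl$id[j]
      if (target == rater) next
      giv <- ev[ev$allocator_id == target & ev$recipient_id != target, ,
                drop = FALSE]
      to_rater_grp <- if (nrow(giv)) mean(giv$recipient_group == rg) else 0.5
      fairness <- clamp(1 + 4 * to_rater_grp + stats::rnorm(1, 0, 0.6))
      humanness <- clamp(stats::rnorm(1, 3, 1.2))
      k <- k + 1L
      out[[k]] <- data.frame(rater_id = rater, rater_group = rg,
                             target_id = target, target_group = pl$group[j],
                             target_kind = pl$kind[j],
                             rating_type = c("fairness", "humanness"),
                             value = c(fairness, humanness),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}
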