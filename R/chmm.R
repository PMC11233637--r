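#' Did a player reciprocate at a given round?
#'
#' A player reciprocates at round `t` when their round-`t` allocation goes to
#' someone who allocated to them within the preceding `window` rounds
#' (`[t - window, t - 1]`). When nobody gave to the player in that window
#' there was no opportunity to reciprocate, and the result is `NA` — an
#' undefined-opportunity signal distinct from `FALSE`, excluded from
#' reciprocation-tendency denominators.
#'
#' @param events Event data frame.
#' @param player_id The focal player.
#' @param round Round at which reciprocation is assessed (must be >= 2).
#' @param window Look-back horizon in rounds (default 1: immediate response).
#' @return `TRUE`, `FALSE`, or `NA` (no opportunity).
#' @export
detect_reciprocation <- function(events, player_id, round, window = 1L) {
  if (round < 2L) return(NA)
  benefactors <- events$allocator_id[
    events$recipient_id == player_id &
      events$allocator_id != player_id &
      events$round >= round - window & events$round <= round - 1L]
  if (!length(benefactors)) return(NA)
  target <- events$recipient_id[events$allocator_id == player_id &
                                  events$round == round]
  if (!length(target)) return(NA)
  target[1] %in% benefactors
}

feature_names <- c("group_alignment", "ingroup_tie", "outgroup_tie",
                   "wealth", "reciprocation_tendency")

#' Behavioral feature vector of a player before a round
#'
#' Summarizes a player's observable behavior from all events strictly before
#' `round`, from the perspective of a focal agent: group alignment (same
#' group as the focal agent), ingroup and outgroup ties (shares of the
#' player's past non-self allocations to own vs other group; they sum to 1
#' once the player has allocated to a non-self target), wealth (current
#' balance over starting tokens), and reciprocation tendency (share of past
#' reciprocation opportunities taken). Cold start (round 1): ties are 0/0
#' (not yet allocated), wealth 1, tendency 0.5 (uninformative prior).
#'
#' @param events Event data frame.
#' @param player_id Player whose features are computed.
#' @param round Features describe behavior strictly before this round.
#' @param focal_agent_id Agent from whose perspective alignment is coded.
#' @param config The game's [game_config()].
#' @param players Roster data frame; recovered from `events` when omitted.
#' @param recip_window Window passed to [detect_reciprocation()].
#' @return Named numeric vector with components `group_alignment`,
#'   `ingroup_tie`, `outgroup_tie`, `wealth`, `reciprocation_tendency`.
#' @export
extract_features <- function(events, player_id, round, focal_agent_id,
                             config, players = NULL, recip_window = 1L) {
  if (is.null(players)) {
    players <- unique(data.frame(id = events$allocator_id,
                                 group = events$allocator_group,
                                 stringsAsFactors = FALSE))
  }
  i <- match(player_id, players$id)
  if (is.na(i)) stop("player ", player_id, " not in game")
  f <- match(focal_agent_id, players$id)
  if (is.na(f)) stop("focal agent ", focal_agent_id, " not in game")
  past <- events[events$round < round, , drop = FALSE]

  own <- past[past$allocator_id == player_id &
                past$recipient_id != player_id, , drop = FALSE]
  if (nrow(own)) {
    in_tie <- mean(own$recipient_group == own$allocator_group)
    out_tie <- 1 - in_tie
  } else {
    in_tie <- out_tie <- 0
  }

  given <- sum(past$allocator_id == player_id)
  recv <- sum(past$recipient_id == player_id)
  wealth <- (config$starting_tokens - given + recv) / config$starting_tokens

  if (round >= 3L) {
    opp <- vapply(2:(round - 1L), function(t)
      detect_reciprocation(past, player_id, t, window = recip_window),
      FUN.VALUE = NA)
    taken <- opp[!is.na(opp)]
    tendency <- if (length(taken)) mean(taken) else 0.5
  } else tendency <- 0.5

  c(group_alignment = as.numeric(players$group[i] == players$group[f]),
    ingroup_tie = in_tie, outgroup_tie = out_tie,
    wealth = wealth, reciprocation_tendency = tendency)
}

#' Fit a cluster hidden Markov model of allocation motives
#'
#' The CHMM treats each player-round as occupying one of `K` hidden "motive"
#' states, identified as clusters of behavioral feature vectors. Fitting is
#' count-based: (1) centers come from seeded k-means on the pooled feature
#' rows (with restarts); (2) each observation is assigned to its nearest
#' center, giving one state sequence per player; (3) the transition matrix is
#' the row-normalized bigram count matrix with add-one smoothing; (4) each
#' state's Bernoulli emission is the smoothed fraction of reciprocation
#' events among reciprocation opportunities observed in that state
#' (labels that are `NA` — no opportunity — are excluded).
#'
#' @param feature_seqs List of numeric matrices, one per player, rows =
#'   successive rounds, columns = the five features of [extract_features()].
#' @param label_seqs List of logical vectors aligned with `feature_seqs`
#'   rows: did the player reciprocate at that round (`NA` = no opportunity).
#' @param K Number of motive states (default 4). If the data contain fewer
#'   distinct feature points, `K` is reduced with a warning.
#' @param seed Optional integer seed for the clustering restarts.
#' @param nstart k-means restarts (default 10).
#' @return An object of class `motive_model`: list with `K`, `centers`
#'   (`K x 5`), `transitions` (`K x K`, rows sum to 1), `emissions`
#'   (per-state reciprocation probabilities), `seed`, `n_obs`.
#' @seealso [predict.motive_model()], [forward_filter()],
#'   [simulate.motive_model()]
#' @export
fit_motive_model <- function(feature_seqs, label_seqs, K = 4L, seed = NULL,
                             nstart = 10L) {
  if (!length(feature_seqs) || !sum(vapply(feature_seqs, nrow, 0L)))
    stop("empty input: no feature rows to fit")
  if (length(feature_seqs) != length(label_seqs) ||
      any(vapply(feature_seqs, nrow, 0L) !=
            vapply(label_seqs, length, 0L)))
    stop("feature sequences and label sequences must be aligned")
  pool <- do.call(rbind, feature_seqs)
  n_distinct <- nrow(unique(pool))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (n_distinct < K) {
    warning("only ", n_distinct, " distinct feature points; reducing K from ",
            K, " to ", n_distinct)
    K <- n_distinct
  }
  if (!is.null(seed)) set.seed(seed)
  ux <- unique(pool)
  if (K == 1L) {
    centers <- matrix(colMeans(pool), nrow = 1,
                      dimnames = list(NULL, colnames(pool)))
  } else if (nrow(ux) == K) {
    centers <- ux
  } else {
    # cluster the distinct points: duplicate rows otherwise break the random
    # center initialization
    km <- suppressWarnings(
      stats::kmeans(ux, centers = K, nstart = nstart, iter.max = 100L))
    centers <- km$centers
  }

  states <- lapply(feature_seqs, function(m) nearest_center(m, centers))

  trans_counts <- matrix(1, K, K)         # add-one smoothing
  for (s in states) {
    if (length(s) >= 2L)
      for (t in seq_len(length(s) - 1L))
        trans_counts[s[t], s[t + 1L]] <- trans_counts[s[t], s[t + 1L]] + 1
  }
  transitions <- trans_counts / rowSums(trans_counts)

  succ <- numeric(K); opp <- numeric(K)
  for (i in seq_along(states)) {
    lab <- label_seqs[[i]]
    st <- states[[i]]
    keep <- !is.na(lab)
    if (any(keep)) {
      tab_s <- tapply(as.numeric(lab[keep]), st[keep], sum)
      tab_n <- table(st[keep])
      succ[as.integer(names(tab_s))] <- succ[as.integer(names(tab_s))] + tab_s
      opp[as.integer(names(tab_n))] <- opp[as.integer(names(tab_n))] +
        as.numeric(tab_n)
    }
  }
  emissions <- (succ + 1) / (opp + 2)     # Laplace-smoothed Bernoulli rates

  structure(list(K = K, centers = centers, transitions = transitions,
                 emissions = emissions, seed = seed, n_obs = nrow(pool)),
            class = "motive_model")
}

# internal: row-wise nearest center (squared Euclidean)
nearest_center <- function(m, centers) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  d2 <- outer(rowSums(m^2), rowSums(centers^2), "+") -
    2 * m %*% t(centers)
  max.col(-d2, ties.method = "first")
}

check_motive_model <- function(model) {
  if (any(abs(rowSums(model$transitions) - 1) > 1e-9))
    stop("invalid motive model: a transition row does not sum to 1")
  if (any(model$emissions < 0 | model$emissions > 1))
    stop("invalid motive model: emission outside [0, 1]")
  invisible(model)
}

#' @export
print.motive_model <- function(x, ...) {
  cat("Cluster hidden Markov model of allocation motives\n")
  cat("  states (K):", x$K, "   observations:", x$n_obs, "\n")
  cat("  per-state reciprocation probabilities:\n   ",
      paste(sprintf("%.3f", x$emissions), collapse = "  "), "\n")
  cat("  transition matrix:\n")
  print(round(x$transitions, 3))
  invisible(x)
}

#' Predict one-step-ahead reciprocation probability
#'
#' Assigns the current feature vector to its nearest motive center `s` and
#' returns \eqn{\sum_k T[s, k]\, e_k}: the probability of reciprocation next
#' step after a motive transition.
#'
#' @param object A fitted `motive_model`.
#' @param newdata A feature vector, or a matrix of feature rows.
#' @param ... Unused.
#' @return Probability (vector) in `[0, 1]`.
#' @export
predict.motive_model <- function(object, newdata, ...) {
  check_motive_model(object)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  s <- nearest_center(newdata, object$centers)
  as.numeric(object$transitions[s, , drop = FALSE] %*% object$emissions)
}

#' Posterior over motive states given an observation sequence
#'
#' Standard forward recursion with a uniform initial state distribution and
#' Bernoulli emissions: observation `TRUE` has likelihood \eqn{e_k} in state
#' k, `FALSE` has \eqn{1 - e_k}, and `NA` (no reciprocation opportunity)
#' carries no information (likelihood 1). Returns the filtered posterior
#' over the `K` motives after the last observation.
#'
#' @param model A `motive_model`.
#' @param observations Logical vector (NA allowed), length >= 1.
#' @return Numeric vector of length `K` summing to 1.
#' @export
forward_filter <- function(model, observations) {
  check_motive_model(model)
  if (!length(observations)) stop("empty observation sequence")
  lik <- function(obs) {
    if (is.na(obs)) rep(1, model$K)
    else if (obs) model$emissions
    else 1 - model$emissions
  }
  alpha <- rep(1 / model$K, model$K) * lik(observations[1])
  if (length(observations) > 1L) {
    for (t in 2:length(observations)) {
      alpha <- as.numeric(t(model$transitions) %*% alpha) *
        lik(observations[t])
    }
  }
  total <- sum(alpha)
  if (total <= 0) {
    warning("zero likelihood for the observation sequence; uniform posterior")
    return(rep(1 / model$K, model$K))
  }
  alpha / total
}

#' Simulate motive-state paths and reciprocation observations
#'
#' Generates `nsim` sequences of `length` steps from the model: states follow
#' the transition matrix from a uniform initial state, observations are
#' Bernoulli draws from the state's emission probability, and feature rows
#' are the state centers plus Gaussian noise (`feature_sd`). Used for
#' parameter-recovery checks and synthetic training data.
#'
#' @param object A `motive_model`.
#' @param nsim Number of sequences.
#' @param seed Optional seed.
#' @param length Steps per sequence.
#' @param feature_sd Noise sd around the state centers.
#' @param ... Unused.
#' @return List with `states`, `observations`, `features` (parallel lists).
#' @export
simulate.motive_model <- function(object, nsim = 1, seed = NULL,
                                  length = 100L, feature_sd = 0.05, ...) {
  check_motive_model(object)
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(object$centers)
  sims <- lapply(seq_len(nsim), function(i) {
    st <- integer(length)
    st[1] <- sample.int(object$K, 1L)
    if (length > 1L)
      for (t in 2:length)
        st[t] <- sample.int(object$K, 1L, prob = object$transitions[st[t - 1L], ])
    obs <- stats::runif(length) < object$emissions[st]
    feat <- object$centers[st, , drop = FALSE] +
      matrix(stats::rnorm(length * p, 0, feature_sd), length, p)
    list(states = st, observations = obs, features = feat)
  })
  list(states = lapply(sims, `[[`, "states"),
       observations = lapply(sims, `[[`, "observations"),
       features = lapply(sims, `[[`, "features"))
}

#' Serialize / restore a motive model as JSON
#'
#' @param model A `motive_model`.
#' @param path File path.
#' @return `read_motive_model` returns the restored `motive_model`;
#'   `write_motive_model` returns the path invisibly.
#' @export
write_motive_model <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, centers = as.data.frame(model$centers),
         transitions = as.data.frame(model$transitions),
         emissions = model$emissions, seed = model$seed,
         n_obs = model$n_obs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_motive_model
#' @export
read_motive_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- structure(list(K = as.integer(raw$K),
                      centers = as.matrix(raw$centers),
                      transitions = as.matrix(raw$transitions),
                      emissions = as.numeric(raw$emissions),
                      seed = raw$seed, n_obs = raw$n_obs),
                 class = "motive_model")
  dimnames(m$transitions) <- NULL
  check_motive_model(m)
  m
}
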