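#' Configure the Q-learning classification agent
#'
#' Defaults are the published training hyperparameters of the
#' classification stage: learning rate `alpha = 0.1`, discount
#' `gamma = 0.6`, exploration `epsilon = 0.1`, 1000 episodes of 100 steps,
#' and a +1/-1 reward for correct/incorrect class predictions. With
#' `|r| <= 1` and `gamma = 0.6` every Q-value is confined to
#' `[-1/(1-gamma), +1/(1-gamma)] = [-2.5, 2.5]`.
#'
#' @param alpha learning rate in (0, 1].
#' @param gamma discount factor in \[0, 1).
#' @param epsilon exploration probability in \[0, 1\].
#' @param episodes number of training episodes.
#' @param max_steps images sampled per episode.
#' @param seed integer seed governing sampling, exploration and tie-free
#'   reproducibility.
#' @param reward_correct,reward_incorrect step rewards (+1 / -1).
#' @param replace sample images with replacement within an episode
#'   (default); set `FALSE` to sample without replacement when the training
#'   set has at least `max_steps` records.
#' @return A `q_config` list.
#' @export
q_config <- function(alpha = 0.1, gamma = 0.6, epsilon = 0.1,
                     episodes = 1000, max_steps = 100, seed = 0L,
                     reward_correct = 1, reward_incorrect = -1,
                     replace = TRUE) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  if (episodes < 0 || max_steps < 1) stop("invalid episode schedule")
  structure(list(alpha = alpha, gamma = gamma, epsilon = epsilon,
                 episodes = as.integer(episodes),
                 max_steps = as.integer(max_steps), seed = as.integer(seed),
                 reward_correct = reward_correct,
                 reward_incorrect = reward_incorrect, replace = replace),
            class = "q_config")
}

#' Fit the feature-state encoder
#'
#' Discretizes the continuous 64-d CNN embedding into a Q-table key: the
#' encoder stores the per-feature median of the training embeddings, and a
#' vector is encoded as the 64-bit pattern of median exceedances
#' (`feature > threshold`), serialized to a bit-string key. Encoding is
#' total and deterministic: any vector, seen or unseen, maps to a valid key.
#'
#' @param features numeric matrix (n x d, n >= 2) of training embeddings.
#' @return A `state_encoder` with per-feature `thresholds`.
#' @export
fit_state_encoder <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 feature vectors")
  structure(list(thresholds = apply(features, 2, stats::median),
                 dim = ncol(features)),
            class = "state_encoder")
}

#' Encode a feature vector to a state key
#'
#' @param encoder a [fit_state_encoder()] result.
#' @param f numeric feature vector (or matrix, one row per vector).
#' @return Character key(s): the bit pattern of `f > thresholds`.
#' @export
encode_state <- function(encoder, f) {
  stopifnot(inherits(encoder, "state_encoder"))
  if (is.matrix(f)) {
    stopifnot(ncol(f) == encoder$dim)
    apply(f, 1, function(r)
      paste(as.integer(r > encoder$thresholds), collapse = ""))
  } else {
    stopifnot(length(f) == encoder$dim)
    paste(as.integer(f > encoder$thresholds), collapse = "")
  }
}

#' Create an empty Q-table
#'
#' A hash-backed map from (state key, action) to a Q-value, with lazy zero
#' initialization: any unseen (state, action) pair reads as exactly 0.
#'
#' @param num_actions number of actions K (class count).
#' @return A `q_table` object.
#' @export
new_q_table <- function(num_actions) {
  stopifnot(num_actions >= 1)
  structure(list(table = new.env(parent = emptyenv(), hash = TRUE),
                 num_actions = as.integer(num_actions)),
            class = "q_table")
}

#' Look up the Q-value row of a state
#'
#' @param q a [new_q_table()].
#' @param s state key string.
#' @return Numeric vector of length `num_actions`; all zeros when unseen.
#' @export
q_lookup <- function(q, s) {
  v <- q$table[[s]]
  if (is.null(v)) numeric(q$num_actions) else v
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action is drawn from the
#' session RNG (seed it with `set.seed()` or `withr::with_seed()` for
#' reproducibility); otherwise the greedy action `argmax_a Q(s, a)`, with
#' ties broken toward the lowest action index.
#'
#' @param q a `q_table`.
#' @param s state key.
#' @param epsilon exploration probability in \[0, 1\].
#' @return Integer action in `[0, K-1]`.
#' @export
select_action <- function(q, s, epsilon) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  if (epsilon > 0 && runif(1) < epsilon)
    return(sample.int(q$num_actions, 1L) - 1L)
  row <- q_lookup(q, s)
  which.max(row) - 1L  # which.max returns the first (lowest-index) maximum
}

#' Classification reward
#'
#' +1 when the predicted class equals the true label, -1 otherwise
#' (configurable magnitudes).
#'
#' @param predicted predicted action (class index).
#' @param truth true label.
#' @param reward_correct,reward_incorrect reward values.
#' @return `reward_correct` or `reward_incorrect`.
#' @export
compute_reward <- function(predicted, truth, reward_correct = 1,
                           reward_incorrect = -1) {
  if (predicted == truth) reward_correct else reward_incorrect
}

#' One Bellman update of the Q-table
#'
#' Applies `Q(s,a) <- Q(s,a) + alpha * (r + gamma * max_a' Q(s',a') -
#' Q(s,a))`; at a terminal transition the bootstrap term is zero. The table
#' is updated in place (environment-backed) and the new value returned.
#'
#' @param q a `q_table`.
#' @param s,a current state key and action.
#' @param r observed reward.
#' @param s_next next state key (ignored when `terminal`).
#' @param terminal logical; `TRUE` zeroes the bootstrap term.
#' @param alpha,gamma learning rate and discount factor.
#' @return The updated Q(s, a), invisibly the same value stored.
#' @export
q_update <- function(q, s, a, r, s_next = NULL, terminal = FALSE,
                     alpha = 0.1, gamma = 0.6) {
  if (!is.finite(r) || !is.finite(alpha) || !is.finite(gamma))
    stop("non-finite inputs to q_update")
  row <- q_lookup(q, s)
  target <- r + if (terminal) 0 else gamma * max(q_lookup(q, s_next))
  row[a + 1L] <- row[a + 1L] + alpha * (target - row[a + 1L])
  q$table[[s]] <- row
  row[a + 1L]
}

#' Train the tabular Q-learning classifier
#'
#' Runs the episodic training protocol: each episode draws `max_steps`
#' training images from a seeded generator (with replacement by default);
#' at each step the current image's encoded feature state is observed, an
#' action chosen epsilon-greedily, the +1/-1 reward collected, and the
#' Bellman update applied with the next drawn image's state as `s'` (the
#' final step of an episode is terminal). Per-step traces and per-episode
#' reward totals are logged.
#'
#' @param features numeric matrix of training embeddings (n x 64).
#' @param labels integer labels in `[0, K-1]`, one per row.
#' @param cfg a [q_config()].
#' @param encoder optional pre-fitted [fit_state_encoder()]; fitted on
#'   `features` when omitted.
#' @param num_actions number of classes K; defaults to `max(labels) + 1`.
#' @return A `q_agent` with elements `q` (the table), `encoder`, `config`,
#'   `episodes` (tibble: `episode`, `total_reward`) and `steps` (tibble:
#'   `episode`, `step`, `state_key`, `action`, `reward`).
#' @export
train_agent <- function(features, labels, cfg = q_config(), encoder = NULL,
                        num_actions = NULL) {
  stopifnot(inherits(cfg, "q_config"))
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (!nrow(features)) stop("empty training features")
  if (length(labels) != nrow(features)) stop("one label per feature row")
  if (is.null(num_actions)) num_actions <- max(labels) + 1L
  if (is.null(encoder)) encoder <- fit_state_encoder(features)
  q <- new_q_table(num_actions)
  n <- nrow(features)
  keys <- encode_state(encoder, features)
  total_steps <- cfg$episodes * cfg$max_steps
  log_ep <- integer(total_steps)
  log_step <- integer(total_steps)
  log_key <- character(total_steps)
  log_act <- integer(total_steps)
  log_rew <- numeric(total_steps)
  pos <- 0L
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$episodes)) {
      replace <- cfg$replace || n < cfg$max_steps
      idx <- sample.int(n, cfg$max_steps, replace = replace)
      ep_keys <- keys[idx]
      for (t in seq_len(cfg$max_steps)) {
        s <- ep_keys[t]
        a <- select_action(q, s, cfg$epsilon)
        r <- compute_reward(a, labels[idx[t]], cfg$reward_correct,
                            cfg$reward_incorrect)
        terminal <- t == cfg$max_steps
        q_update(q, s, a, r,
                 s_next = if (terminal) NULL else ep_keys[t + 1L],
                 terminal = terminal, alpha = cfg$alpha, gamma = cfg$gamma)
        pos <- pos + 1L
        log_ep[pos] <- ep
        log_step[pos] <- t
        log_key[pos] <- s
        log_act[pos] <- a
        log_rew[pos] <- r
      }
    }
  })
  steps <- tibble::tibble(episode = log_ep, step = log_step,
                          state_key = log_key, action = log_act,
                          reward = log_rew)
  episodes <- if (cfg$episodes > 0)
    tibble::tibble(episode = seq_len(cfg$episodes),
                   total_reward = as.vector(tapply(steps$reward,
                                                   steps$episode, sum)))
  else tibble::tibble(episode = integer(), total_reward = numeric())
  structure(list(q = q, encoder = encoder, config = cfg,
                 episodes = episodes, steps = steps,
                 num_actions = num_actions),
            class = "q_agent")
}

#' Greedy class prediction from the Q-table
#'
#' Predicts `argmax_a Q(s, a)` for the encoded state of a feature vector,
#' with ties broken toward the lowest action index. A state never visited
#' during training has an all-zero Q row and therefore falls back to
#' action 0; the fraction of such states is reported.
#'
#' @param q a `q_table`.
#' @param encoder the fitted `state_encoder`.
#' @param f a feature vector or an n x 64 matrix.
#' @param warn_unseen warn when unseen states are encountered.
#' @return Integer action(s), with attribute `unseen_rate`.
#' @export
predict_action <- function(q, encoder, f, warn_unseen = FALSE) {
  keys <- encode_state(encoder, f)
  seen <- vapply(keys, function(k) !is.null(q$table[[k]]), logical(1))
  acts <- vapply(keys, function(k) which.max(q_lookup(q, k)) - 1L, integer(1))
  if (warn_unseen && any(!seen))
    warning(sum(!seen), " of ", length(keys),
            " states unseen during training; predicted class 0 fallback")
  structure(as.integer(acts), unseen_rate = mean(!seen))
}

#' @rdname predict_action
#' @param object a `q_agent`.
#' @param newdata feature vector or matrix.
#' @param ... unused.
#' @export
predict.q_agent <- function(object, newdata, ...) {
  predict_action(object$q, object$encoder, newdata)
}

#' Evaluate the agent on held-out features
#'
#' Greedy (learned-policy-only) prediction on every test record, scored as
#' `accuracy = correct / total * 100` together with the full confusion
#' matrix and per-class precision/recall/F1 report.
#'
#' @param agent a trained `q_agent`.
#' @param features test embedding matrix.
#' @param labels integer test labels.
#' @return List: `accuracy` (percent), `report` (a
#'   [classification_report()]), `unseen_rate`.
#' @export
evaluate_agent <- function(agent, features, labels) {
  if (!length(labels)) stop("empty test set")
  preds <- predict(agent, as.matrix(features))
  rep <- classification_report(as.integer(labels), as.integer(preds),
                               num_classes = agent$num_actions)
  list(accuracy = rep$overall_accuracy, report = rep,
       unseen_rate = attr(preds, "unseen_rate"))
}

#' Save / load a Q-table as JSON
#'
#' Serializes the state-key to Q-row map together with the training
#' configuration header as plain JSON text.
#'
#' @param agent a `q_agent`.
#' @param path output JSON path.
#' @return `save_qtable` the path invisibly; `load_qtable` a list with the
#'   rebuilt `q` table, `encoder` and `config`.
#' @export
save_qtable <- function(agent, path) {
  keys <- ls(agent$q$table)
  tab <- stats::setNames(lapply(keys, function(k) agent$q$table[[k]]), keys)
  jsonlite::write_json(
    list(config = unclass(agent$config), num_actions = agent$num_actions,
         thresholds = agent$encoder$thresholds, table = tab),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_qtable
#' @export
load_qtable <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  q <- new_q_table(obj$num_actions)
  for (k in names(obj$table)) q$table[[k]] <- as.numeric(obj$table[[k]])
  enc <- structure(list(thresholds = as.numeric(obj$thresholds),
                        dim = length(obj$thresholds)),
                   class = "state_encoder")
  list(q = q, encoder = enc, config = do.call(q_config, obj$config))
}

#' @export
print.q_agent <- function(x, ...) {
  cat("<q_agent> ", x$num_actions, " actions, ",
      length(ls(x$q$table)), " visited states, ",
      nrow(x$episodes), " episodes (mean reward ",
      round(mean(x$episodes$total_reward), 1), ")\n", sep = "")
  invisible(x)
}
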