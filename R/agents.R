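#' Construct decision agents
#'
#' An agent is a heuristic kind plus the knowledge it uses to search cues:
#' * a *take-the-best* agent holds a fixed cue search order (typically the
#'   descending order of cue validities) and a per-cue direction flag;
#' * a *minimalist* agent holds no order — it searches cues in a fresh
#'   uniformly random order for every pair decision.
#'
#' A `"reversed"` direction means the agent treats cue value 1 as signalling
#' the *smaller* criterion — the appropriate reading of a cue whose
#' estimated validity is below 0.5, whose effective validity is then
#' `1 - V`.
#'
#' @param cue_order Permutation of cue indices; the search order.
#' @param directions Character vector, `"normal"` or `"reversed"`, one per
#'   cue (indexed by cue, not by search position).
#' @param validities Optional `validity_estimate` the order was derived
#'   from; kept for audit.
#' @param n_cues Number of cues a minimalist agent searches over.
#' @return An object of class `decision_agent`.
#' @seealso [objective_agent()], [learn_from_sample()], [decide_pair()]
#' @export
ttb_agent <- function(cue_order, directions = NULL, validities = NULL) {
  cue_order <- as.integer(cue_order)
  k <- length(cue_order)
  if (!setequal(cue_order, seq_len(k))) {
    stop("cue_order must be a permutation of 1..k", call. = FALSE)
  }
  if (is.null(directions)) directions <- rep("normal", k)
  new_agent("ttb", cue_order, directions, validities)
}

#' @rdname ttb_agent
#' @export
minimalist_agent <- function(n_cues = 5, directions = NULL) {
  k <- as.integer(n_cues)
  if (k < 1) stop("n_cues must be positive", call. = FALSE)
  if (is.null(directions)) directions <- rep("normal", k)
  new_agent("minimalist", NULL, directions, NULL)
}

new_agent <- function(kind, cue_order, directions, validities) {
  if (!all(directions %in% c("normal", "reversed"))) {
    stop("directions must be 'normal' or 'reversed'", call. = FALSE)
  }
  k <- if (is.null(cue_order)) length(directions) else length(cue_order)
  if (length(directions) != k) {
    stop("one direction flag per cue is required", call. = FALSE)
  }
  structure(list(kind = kind, cue_order = cue_order,
                 directions = directions, validities = validities,
                 n_cues = k),
            class = "decision_agent")
}

#' @export
print.decision_agent <- function(x, ...) {
  cat("Agent:", if (x$kind == "ttb") "take-the-best" else "minimalist", "\n")
  if (!is.null(x$cue_order)) {
    cat("  cue order:", paste(x$cue_order, collapse = " > "), "\n")
  } else {
    cat("  cue order: random per decision\n")
  }
  if (any(x$directions == "reversed")) {
    cat("  reversed cues:", paste(which(x$directions == "reversed"),
                                  collapse = ", "), "\n")
  }
  if (!is.null(x$validities)) {
    cat("  learned validities:",
        paste(format(round(x$validities$validity, 3)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Take-the-best agent with the objective cue order
#'
#' Builds the deterministic take-the-best agent that searches cues in
#' descending order of their (objective) effective validities.  Ties are
#' broken by ascending cue index, so that every agent built from the same
#' validities is identical — the homogeneous-group assumption of the
#' group-size study.  Cues with validity below 0.5 are used in the reversed
#' direction (effective validity `1 - V`); all bundled environments have
#' every objective validity above 0.5, so their objective agents use all
#' cues in the normal direction.
#'
#' @param validities A `validity_estimate`, or a plain numeric vector of
#'   per-cue validities.
#' @return A `decision_agent` of kind take-the-best.
#' @export
objective_agent <- function(validities) {
  v <- as_validity_vector(validities)
  eff <- effective_validity(v$validity, v$defined)
  ord <- order(-eff, seq_along(eff))  # deterministic index tie-break
  dirs <- ifelse(v$defined & v$validity < 0.5, "reversed", "normal")
  ttb_agent(ord, dirs, validities = v$est)
}

#' Learn a cue order from a sample of options
#'
#' The validity-learning procedure of the individual-learning study: the
#' agent computes each cue's validity over all option pairs in its learning
#' sample, reads a cue with estimated validity below 0.5 in the reversed
#' direction (effective validity `1 - V`), treats a never-discriminating cue
#' as neutral (effective validity 0.5), and searches cues in descending
#' order of effective validity.  Ties — common in the flatter environments,
#' where sampling error dominates the small true differences — are broken
#' uniformly at random per agent, which is a source of between-agent
#' diversity.
#'
#' @param learning_options An `option_set` (the agent's learning sample,
#'   at least 2 options).
#' @return A `decision_agent` of kind take-the-best, with
#'   `learned_validities` attached as `$validities`.
#' @examples
#' set.seed(7)
#' agent <- learn_from_sample(generate_options(task_environment("LD"), 25))
#' agent$cue_order
#' @export
learn_from_sample <- function(learning_options) {
  v <- compute_validity(learning_options, pairs = "all")
  eff <- effective_validity(v$validity, v$defined)
  ord <- order(-eff, runif(length(eff)))  # random tie-break per agent
  dirs <- ifelse(v$defined & v$validity < 0.5, "reversed", "normal")
  ttb_agent(ord, dirs, validities = v)
}

effective_validity <- function(validity, defined) {
  ifelse(defined, pmax(validity, 1 - validity), 0.5)
}

as_validity_vector <- function(validities) {
  if (inherits(validities, "validity_estimate")) {
    list(validity = validities$validity, defined = validities$defined,
         est = validities)
  } else {
    v <- as.numeric(validities)
    if (anyNA(v) || any(v < 0 | v > 1)) {
      stop("validities must lie in [0, 1]", call. = FALSE)
    }
    list(validity = v, defined = rep(TRUE, length(v)), est = NULL)
  }
}

#' Serialize an agent to JSON (and back)
#'
#' Round-trips the agent's kind, cue order, direction flags and learned
#' validities, for audit and replay of simulation runs.
#'
#' @param agent A `decision_agent`.
#' @param txt JSON text produced by `agent_to_json`.
#' @return `agent_to_json` returns a JSON string; `agent_from_json` a
#'   `decision_agent`.
#' @export
agent_to_json <- function(agent) {
  stopifnot(inherits(agent, "decision_agent"))
  payload <- list(kind = agent$kind, cue_order = agent$cue_order,
                  directions = agent$directions)
  if (!is.null(agent$validities)) {
    payload$validities <- as.data.frame(agent$validities)
  }
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname agent_to_json
#' @export
agent_from_json <- function(txt) {
  p <- jsonlite::fromJSON(txt)
  validities <- NULL
  if (!is.null(p$validities)) {
    validities <- new_validity_estimate(p$validities$n_right,
                                        p$validities$n_wrong)
  }
  if (p$kind == "minimalist") {
    minimalist_agent(length(p$directions), p$directions)
  } else {
    ttb_agent(p$cue_order, p$directions, validities)
  }
}
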