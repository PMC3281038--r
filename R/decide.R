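#' Decide a single paired comparison
#'
#' The one-reason decision cycle shared by take-the-best and minimalist:
#' cues are inspected one at a time — in the agent's fixed order for
#' take-the-best, in a fresh uniformly random order for minimalist — and
#' search stops at the first cue on which the two options' (direction-
#' adjusted) binary values differ.  The option whose adjusted value is 1 on
#' that cue is chosen.  If no cue discriminates, the choice is a fair coin
#' flip and `stopping_cue` is `NA`.
#'
#' This is the literal sequential algorithm, convenient for single
#' decisions and worked examples; simulation runs use the vectorized
#' [decide_pairs()], which produces identical take-the-best decisions.
#'
#' @param agent A `decision_agent`.
#' @param cues_a,cues_b Binary cue vectors of the two options.
#' @return An object of class `pair_decision`: list with `choice` (`"A"` or
#'   `"B"`), `stopping_cue` (cue index or `NA`), `searched_cues` (cue
#'   indices in inspection order, up to and including the stopping cue) and
#'   `guessed` (logical).
#' @examples
#' agent <- ttb_agent(1:3)
#' decide_pair(agent, c(1, 0, 1), c(1, 1, 0))  # stops at cue 2, chooses B
#' @export
decide_pair <- function(agent, cues_a, cues_b) {
  stopifnot(inherits(agent, "decision_agent"))
  if (length(cues_a) != length(cues_b)) {
    stop("cue vectors must have equal length", call. = FALSE)
  }
  if (!all(c(cues_a, cues_b) %in% c(0, 1))) {
    stop("cue values must be binary", call. = FALSE)
  }
  k <- length(cues_a)
  if (k != agent$n_cues) {
    stop("cue vectors do not match the agent's cue count", call. = FALSE)
  }
  ord <- if (agent$kind == "minimalist") sample.int(k) else agent$cue_order
  searched <- integer(0)
  for (cue in ord) {
    searched <- c(searched, cue)
    a <- cues_a[cue]
    b <- cues_b[cue]
    if (agent$directions[cue] == "reversed") {
      a <- 1 - a
      b <- 1 - b
    }
    if (a != b) {
      choice <- if (a > b) "A" else "B"
      return(new_pair_decision(choice, cue, searched, FALSE))
    }
  }
  choice <- if (runif(1) < 0.5) "A" else "B"
  new_pair_decision(choice, NA_integer_, searched, TRUE)
}

new_pair_decision <- function(choice, stopping_cue, searched_cues, guessed) {
  structure(list(choice = choice, stopping_cue = stopping_cue,
                 searched_cues = searched_cues, guessed = guessed),
            class = "pair_decision")
}

#' @export
print.pair_decision <- function(x, ...) {
  cat("Choice:", x$choice,
      if (x$guessed) "(guess)" else paste0("(stopped at cue ", x$stopping_cue, ")"),
      "\n")
  cat("Searched cues:", paste(x$searched_cues, collapse = ", "), "\n")
  invisible(x)
}

#' Decide a batch of paired comparisons
#'
#' Vectorized decision core used by the study drivers.  For take-the-best,
#' the lexicographic decision over the agent's cue order is computed as the
#' sign of a base-2-weighted sum of per-cue differences; for minimalist, a
#' fresh random search order per pair is realized by per-(pair, cue) uniform
#' priorities — search stops at the discriminating cue with the smallest
#' priority, and the cues searched are exactly those with priority at most
#' the stopping cue's.  Guesses (no discriminating cue) are resolved by
#' independent fair coin flips.
#'
#' @param agent A `decision_agent`.
#' @param cues_a,cues_b Binary matrices (pairs x cues): row `p` holds the
#'   cue vectors of the two options of pair `p`.
#' @param collect_search If `TRUE`, also return the logical matrix of cues
#'   inspected per pair (needed for search-diversity summaries).
#' @return List with `choice` (integer, 1 = first option, 2 = second),
#'   `stopping_cue` (integer, `NA` on guesses), `guessed` (logical) and —
#'   when requested — `searched` (pairs x cues logical).
#' @export
decide_pairs <- function(agent, cues_a, cues_b, collect_search = FALSE) {
  stopifnot(inherits(agent, "decision_agent"))
  a <- as.matrix(cues_a)
  b <- as.matrix(cues_b)
  if (!all(dim(a) == dim(b))) {
    stop("cue matrices must have equal dimensions", call. = FALSE)
  }
  np <- nrow(a)
  k <- ncol(a)
  if (k != agent$n_cues) {
    stop("cue matrices do not match the agent's cue count", call. = FALSE)
  }
  sgn <- ifelse(agent$directions == "reversed", -1, 1)
  d <- (a - b) * rep(sgn, each = np)  # direction-adjusted differences
  searched <- NULL
  if (agent$kind == "ttb") {
    ord <- agent$cue_order
    dd <- d[, ord, drop = FALSE]
    # sign of sum(dd * 2^-position) == sign of first nonzero dd: lexicographic
    score <- drop(dd %*% 2^(k - seq_len(k)))
    disc <- dd != 0
    any_disc <- rowSums(disc) > 0
    pos <- max.col(disc, ties.method = "first")
    pos[!any_disc] <- k  # exhausted search
    stopping <- ifelse(any_disc, ord[pos], NA_integer_)
    choice <- integer(np)
    choice[score > 0] <- 1L
    choice[score < 0] <- 2L
    if (collect_search) {
      in_prefix <- matrix(seq_len(k), np, k, byrow = TRUE) <=
        matrix(pos, np, k)
      searched <- matrix(FALSE, np, k)
      searched[, ord] <- in_prefix
    }
  } else {
    u <- matrix(runif(np * k), np, k)  # search priorities, one order per pair
    disc <- d != 0
    any_disc <- rowSums(disc) > 0
    uu <- u
    uu[!disc] <- Inf
    stop_col <- max.col(-uu, ties.method = "first")
    u_stop <- uu[cbind(seq_len(np), stop_col)]
    stopping <- ifelse(any_disc, stop_col, NA_integer_)
    d_stop <- d[cbind(seq_len(np), stop_col)]
    choice <- integer(np)
    choice[any_disc & d_stop > 0] <- 1L
    choice[any_disc & d_stop < 0] <- 2L
    if (collect_search) searched <- u <= u_stop  # u_stop = Inf => all cues
  }
  guessed <- choice == 0L
  if (any(guessed)) {
    choice[guessed] <- 1L + (runif(sum(guessed)) < 0.5)
  }
  out <- list(choice = choice, stopping_cue = stopping, guessed = guessed)
  if (collect_search) out$searched <- searched
  out
}
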