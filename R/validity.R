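#' Estimate cue validities from a sample of options
#'
#' A cue's validity is `V = R / (R + W)`, where `R` and `W` count the
#' correct and incorrect decisions the cue makes on option pairs where its
#' binary values differ (the discriminating pairs): a decision is correct
#' when the option carrying cue value 1 has the larger criterion.  Pairs
#' with exactly equal criterion values are excluded from both counts (their
#' number is recorded in the `n_tied_pairs` attribute).  A cue that never
#' discriminates has no defined validity; it is flagged `defined = FALSE`
#' and reported at the neutral value 0.5.
#'
#' @param options An `option_set`.
#' @param pairs `"all"` enumerates all `n(n-1)/2` option pairs (the rule
#'   agents use when learning from a sample); `"sampled"` draws `n_pairs`
#'   random pairs with replacement, for Monte-Carlo estimation on large
#'   sets.
#' @param n_pairs Number of pairs to draw when `pairs = "sampled"`.
#' @return A `validity_estimate`: data frame with one row per cue and
#'   columns `cue`, `n_right`, `n_wrong`, `defined`, `validity`.
#' @examples
#' set.seed(1)
#' opts <- generate_options(task_environment("LD"), 25)
#' compute_validity(opts)
#' @export
compute_validity <- function(options, pairs = c("all", "sampled"),
                             n_pairs = NULL) {
  stopifnot(inherits(options, "option_set"))
  pairs <- match.arg(pairs)
  n <- length(options$criterion)
  if (n < 2) stop("need at least two options", call. = FALSE)
  if (pairs == "all") {
    idx <- pair_indices(n)
    i <- idx[1L, ]
    j <- idx[2L, ]
  } else {
    if (is.null(n_pairs) || n_pairs < 1) {
      stop("n_pairs must be given for sampled pairs", call. = FALSE)
    }
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n, n_pairs, replace = TRUE)
    keep <- i != j
    i <- i[keep]
    j <- j[keep]
  }
  validity_from_pairs(options$criterion[i], options$criterion[j],
                      options$cues_bin[i, , drop = FALSE],
                      options$cues_bin[j, , drop = FALSE])
}

# Core validity counts for pre-formed pairs: criterion and binary-cue
# matrices for the two sides of each pair.
validity_from_pairs <- function(crit_a, crit_b, bin_a, bin_b) {
  k <- ncol(bin_a)
  tie <- crit_a == crit_b
  a_larger <- crit_a > crit_b
  n_right <- integer(k)
  n_wrong <- integer(k)
  for (cue in seq_len(k)) {
    a <- bin_a[, cue]
    b <- bin_b[, cue]
    disc <- (a != b) & !tie
    right <- disc & ((a == 1L & a_larger) | (b == 1L & !a_larger))
    n_right[cue] <- sum(right)
    n_wrong[cue] <- sum(disc) - n_right[cue]
  }
  new_validity_estimate(n_right, n_wrong, n_tied = sum(tie))
}

new_validity_estimate <- function(n_right, n_wrong, n_tied = 0L) {
  stopifnot(all(n_right >= 0), all(n_wrong >= 0))
  defined <- (n_right + n_wrong) > 0L
  validity <- ifelse(defined, n_right / (n_right + n_wrong), 0.5)
  structure(
    data.frame(cue = seq_along(n_right), n_right = n_right,
               n_wrong = n_wrong, defined = defined, validity = validity),
    n_tied_pairs = as.integer(n_tied),
    class = c("validity_estimate", "data.frame"))
}

#' Monte-Carlo objective cue validities of an environment
#'
#' The objective validity of a cue is its validity in the population of
#' options.  It is approximated here by a large Monte-Carlo sample of
#' independent option pairs drawn directly from the environment's
#' generative model, under a dedicated seed so that the "population"
#' quantities are fixed, reproducible numbers independent of any simulation
#' run (the session random-number stream is left untouched).  Results are
#' cached per (environment, n_pairs, seed).
#'
#' @param env A [task_environment].
#' @param n_pairs Number of random option pairs (default 1e6; standard
#'   error of each validity about 0.0007).
#' @param seed Dedicated seed for the population draw.
#' @param cutoff Dichotomization cutoff.
#' @return A `validity_estimate` (see [compute_validity()]).
#' @examples
#' \donttest{
#' objective_validity(task_environment("LD"))$validity
#' }
#' @export
objective_validity <- function(env, n_pairs = 1e6, seed = 424242L,
                               cutoff = 0) {
  stopifnot(inherits(env, "task_environment"))
  if (n_pairs < 1) stop("n_pairs must be positive", call. = FALSE)
  key <- paste0("ov:", paste(c(env$betas, env$beta_e, n_pairs, seed, cutoff),
                             collapse = ","))
  hit <- .heurigroup_cache[[key]]
  if (!is.null(hit)) return(hit)
  est <- withr::with_seed(seed, mc_pair_validity(env, n_pairs, cutoff))
  .heurigroup_cache[[key]] <- est
  est
}

# chunked so that 1e6+ pairs stay modest in memory
mc_pair_validity <- function(env, n_pairs, cutoff = 0, chunk = 250000L) {
  k <- length(env$betas)
  n_right <- numeric(k)
  n_wrong <- numeric(k)
  n_tied <- 0L
  left <- as.numeric(n_pairs)
  while (left > 0) {
    m <- as.integer(min(chunk, left))
    left <- left - m
    xa <- matrix(rnorm(m * k), m, k)
    xb <- matrix(rnorm(m * k), m, k)
    ya <- drop(xa %*% env$betas) + env$beta_e * rnorm(m)
    yb <- drop(xb %*% env$betas) + env$beta_e * rnorm(m)
    est <- validity_from_pairs(ya, yb, dichotomize(xa, cutoff),
                               dichotomize(xb, cutoff))
    n_right <- n_right + est$n_right
    n_wrong <- n_wrong + est$n_wrong
    n_tied <- n_tied + attr(est, "n_tied_pairs")
  }
  new_validity_estimate(n_right, n_wrong, n_tied)
}

#' @export
print.validity_estimate <- function(x, ...) {
  cat("Cue validity estimate (", sum(x$n_right + x$n_wrong),
      " discriminating pair-decisions)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# cached all-pairs index table (2 x P, i < j in option-index order)
pair_indices <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  key <- paste0("pairs:", n)
  hit <- .heurigroup_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- combn(n, 2L)
  .heurigroup_cache[[key]] <- idx
  idx
}
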