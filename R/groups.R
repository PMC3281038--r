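#' Aggregate member choices by simple majority
#'
#' Returns the option with more votes.  An exact tie (possible for even
#' group sizes) is broken uniformly at random and flagged, so tie frequency
#' stays reportable.
#'
#' @param choices Integer vector of member choices (1 = first option,
#'   2 = second), one entry per group member, for a single paired
#'   comparison.
#' @return An object of class `group_decision`: list with `choice`,
#'   `tie_broken` and `member_choices`.
#' @examples
#' majority_vote(c(1, 1, 2, 2, 2))$choice  # 2
#' @export
majority_vote <- function(choices) {
  if (length(choices) == 0) stop("empty choice list", call. = FALSE)
  if (!all(choices %in% c(1L, 2L))) {
    stop("choices must be 1 or 2", call. = FALSE)
  }
  res <- majority_matrix(matrix(as.integer(choices), nrow = 1L))
  structure(list(choice = res$choice, tie_broken = res$tie_broken,
                 member_choices = as.integer(choices)),
            class = "group_decision")
}

# vectorized majority over a pairs x members vote matrix
majority_matrix <- function(votes) {
  m <- ncol(votes)
  votes1 <- rowSums(votes == 1L)
  choice <- integer(nrow(votes))
  choice[votes1 * 2L > m] <- 1L
  choice[votes1 * 2L < m] <- 2L
  tie <- choice == 0L
  if (any(tie)) choice[tie] <- 1L + (runif(sum(tie)) < 0.5)
  list(choice = choice, tie_broken = tie)
}

#' Score member and group choices against the true criterion
#'
#' A choice is correct when the chosen option has the strictly larger
#' criterion value.  Pairs with exactly equal criterion values carry no
#' correct answer and are excluded from scoring (their count is recorded in
#' the `n_excluded` attribute).  Accuracies are reported as percentages
#' (PC, percentage correct): `pc_individual` is the mean over all
#' member-decisions, `pc_group` the percentage of correct group decisions.
#'
#' @param member_choices Integer matrix (pairs x members) of member choices
#'   (1/2), or a vector for a single member.
#' @param group_choice Integer vector of group choices (1/2), one per pair.
#' @param criterion_a,criterion_b Criterion values of the two options of
#'   each pair.
#' @return An `accuracy_summary`: list with `pc_individual`, `pc_group` and
#'   `n_decisions` (scored pairs).
#' @export
score_decisions <- function(member_choices, group_choice,
                            criterion_a, criterion_b) {
  if (is.vector(member_choices)) {
    member_choices <- matrix(member_choices, ncol = 1L)
  }
  np <- nrow(member_choices)
  stopifnot(length(group_choice) == np, length(criterion_a) == np,
            length(criterion_b) == np)
  ok <- criterion_a != criterion_b
  a_larger <- criterion_a > criterion_b
  ind_correct <- (member_choices == 1L) == a_larger
  grp_correct <- (group_choice == 1L) == a_larger
  new_accuracy_summary(
    pc_individual = 100 * mean(ind_correct[ok, , drop = FALSE]),
    pc_group = 100 * mean(grp_correct[ok]),
    n_decisions = sum(ok),
    n_excluded = sum(!ok))
}

new_accuracy_summary <- function(pc_individual, pc_group, n_decisions,
                                 n_excluded = 0L) {
  structure(list(pc_individual = pc_individual, pc_group = pc_group,
                 n_decisions = as.integer(n_decisions),
                 n_excluded = as.integer(n_excluded)),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf("PC individual %.2f%%, PC group %.2f%% (%d decisions)\n",
              x$pc_individual, x$pc_group, x$n_decisions))
  invisible(x)
}

#' Summarize group diversity in decisions and search
#'
#' Two complementary diversity measures:
#' * `decision_diversity` — the mean, over pair decisions, of the fraction
#'   of member pairs that disagree on that decision (0 for a homogeneous
#'   deterministic group, 1 when every member pair disagrees); computed
#'   from the vote split as `v1 * (m - v1) / choose(m, 2)`.
#' * `search_diversity` — the mean number of distinct cues inspected by the
#'   group per pair decision (the size of the union of members' searched
#'   cue sets; between 1 and the cue count).
#'
#' These are this package's explicit operationalizations of group
#' diversity; they are qualitative summaries, defined here, not reproduced
#' from any external table.
#'
#' @param member_choices Integer matrix (pairs x members) of member
#'   choices.
#' @param searched List with one pairs-x-cues logical matrix per member
#'   (cues each member inspected on each pair), or `NULL` to skip the
#'   search measure.
#' @return A `diversity_summary`: list with `decision_diversity` and
#'   `search_diversity` (the latter `NA` when `searched` is `NULL`).
#' @export
diversity_summary <- function(member_choices, searched = NULL) {
  if (is.vector(member_choices)) {
    member_choices <- matrix(member_choices, ncol = 1L)
  }
  m <- ncol(member_choices)
  dd <- if (m < 2) {
    0
  } else {
    v1 <- rowSums(member_choices == 1L)
    mean(v1 * (m - v1) / choose(m, 2))
  }
  sd_ <- NA_real_
  if (!is.null(searched)) {
    union_mat <- Reduce(`|`, searched)
    sd_ <- mean(rowSums(union_mat))
  }
  structure(list(decision_diversity = dd, search_diversity = sd_),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("Decision diversity %.3f; search diversity %.2f cues/pair\n",
              x$decision_diversity, x$search_diversity))
  invisible(x)
}
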