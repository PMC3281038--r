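#' Bundled worked-example fixtures
#'
#' Small regression fixtures shipped with the package: the two-flower
#' take-the-best worked example (clean and misperceived cue variants), a
#' three-option validity hand enumeration, and the four bundled environment
#' definitions with their reference validities and variance fractions.
#' Each fixture carries a provenance `tag` (`"reference"` for values taken
#' from the task definition, `"derived"` for values obtained by hand
#' enumeration) so provenance can be machine-checked.
#'
#' @param path Optional path to an alternative fixture JSON file.
#' @return A named list of fixtures (class `heuristic_fixture` each).
#' @seealso [check_fixture()]
#' @export
builtin_fixtures <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fixtures.json", package = "heurigroup",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixtures <- lapply(seq_len(nrow(raw)), function(i) {
    f <- lapply(raw, function(col) {
      if (is.list(col)) col[[i]] else col[i]
    })
    f <- f[!vapply(f, function(x) all(is.na(x)) && !is.list(x), logical(1))]
    structure(f, class = "heuristic_fixture")
  })
  names(fixtures) <- raw$name
  fixtures
}

#' Evaluate a bundled fixture against the implementation
#'
#' Re-executes the fixture's scenario with the package's own functions and
#' compares against the fixture's expected values:
#' * `decision` fixtures run [decide_pair()] with the stated cue order and
#'   check the chosen option and stopping cue;
#' * `validity` fixtures run [compute_validity()] on the stated options and
#'   check validity and right/wrong counts;
#' * `environment` fixtures check the coefficient sum of squares and
#'   [variance_explained()] exactly (3 d.p.) and the Monte-Carlo
#'   [objective_validity()] within the stated tolerance.
#'
#' @param fixture A fixture from [builtin_fixtures()].
#' @param n_pairs Monte-Carlo pair count for environment fixtures.
#' @return `TRUE` when every check passes, otherwise a character vector of
#'   failure descriptions.
#' @export
check_fixture <- function(fixture, n_pairs = 1e6) {
  stopifnot(inherits(fixture, "heuristic_fixture"))
  fails <- character(0)
  note <- function(fmt, ...) fails <<- c(fails, sprintf(fmt, ...))
  if (fixture$type == "decision") {
    agent <- ttb_agent(fixture$cue_order)
    dec <- decide_pair(agent, fixture$cues_a, fixture$cues_b)
    if (!identical(dec$choice, fixture$expected_choice)) {
      note("choice %s != expected %s", dec$choice, fixture$expected_choice)
    }
    if (!isTRUE(dec$stopping_cue == fixture$expected_stopping_cue)) {
      note("stopping cue %s != expected %s", dec$stopping_cue,
           fixture$expected_stopping_cue)
    }
  } else if (fixture$type == "validity") {
    crit <- as.numeric(fixture$criterion)
    bin <- matrix(as.integer(fixture$cues_bin), ncol = 1)
    opts <- new_option_set(crit, bin, bin)
    v <- compute_validity(opts)
    if (!isTRUE(all.equal(v$validity, fixture$expected_validity))) {
      note("validity %.3f != expected %.3f", v$validity,
           fixture$expected_validity)
    }
    if (v$n_right != fixture$expected_n_right ||
        v$n_wrong != fixture$expected_n_wrong) {
      note("counts R=%d W=%d != expected R=%d W=%d", v$n_right, v$n_wrong,
           fixture$expected_n_right, fixture$expected_n_wrong)
    }
  } else if (fixture$type == "environment") {
    env <- task_environment(fixture$environment)
    ss <- sum(env$betas^2) + env$beta_e^2
    if (!isTRUE(all.equal(ss, fixture$expected_sum_sq, tolerance = 1e-8))) {
      note("coefficient sum of squares %.4f != expected %.4f", ss,
           fixture$expected_sum_sq)
    }
    ve <- round(variance_explained(env), 3)
    if (ve != fixture$expected_variance_explained) {
      note("variance explained %.3f != expected %.3f", ve,
           fixture$expected_variance_explained)
    }
    v <- objective_validity(env, n_pairs = n_pairs)$validity
    off <- abs(v - fixture$expected_validities) > fixture$validity_tolerance
    if (any(off)) {
      note("validities off for cue(s) %s", paste(which(off), collapse = ","))
    }
  } else {
    note("unknown fixture type '%s'", fixture$type)
  }
  if (length(fails) == 0) TRUE else fails
}

#' @export
print.heuristic_fixture <- function(x, ...) {
  cat("Fixture '", x$name, "' (", x$type, ", tag: ", x$tag, ")\n", sep = "")
  invisible(x)
}
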