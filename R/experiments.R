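#' Simulate one study condition
#'
#' Runs the full replicate cycle for one grid point: per replicate, draw a
#' testing sample of `n_options` options from the environment (and, where
#' applicable, per-agent learning samples or per-agent noisy cue
#' perceptions), have every member decide all `n(n-1)/2` option pairs,
#' aggregate member choices by simple majority, score against the true
#' criterion values, and average over `n_samples` replicates.
#'
#' Agent construction depends on the condition:
#' * take-the-best with `n_learn = NULL` or `"population"` — every member
#'   is the deterministic [objective_agent()] for the environment (cue
#'   order from the Monte-Carlo population validities);
#' * take-the-best with numeric `n_learn` — each member learns its own cue
#'   order from an independent fresh sample of `n_learn` options every
#'   replicate ([learn_from_sample()]);
#' * minimalist — members search in fresh random orders
#'   ([minimalist_agent()]); `n_learn` is ignored.
#'
#' When all members are identical deterministic take-the-best agents
#' perceiving the same error-free cues, the group is homogeneous: every
#' member makes the same decision, including the same guess resolution, so
#' group accuracy equals individual accuracy exactly and decision diversity
#' is zero.  The simulation shares one decision stream across members in
#' that case, which is what makes group accuracy exactly invariant in group
#' size there.
#'
#' @param env A [task_environment], or the name of a bundled one.
#' @param heuristic `"ttb"` (take-the-best) or `"minimalist"`.
#' @param m Group size (number of members).
#' @param n_options Options per testing sample (default 15, i.e. 105 pairs).
#' @param n_samples Number of replicate samples to average over.
#' @param sigma Standard deviation of per-agent cue-perception noise
#'   (see [perturb_cues()]); 0 disables the noise path entirely.
#' @param n_learn Learning-sample size: `NULL` (objective order, no
#'   learning), a number of options, or `"population"`.
#' @param seed Seed for the condition's random stream (optional; when
#'   `NULL` the current session stream is used).
#' @param score_guess_half If `TRUE`, a member's guessed decisions are
#'   scored 0.5 in `pc_individual` (variance reduction at the individual
#'   level); group aggregation always uses the coin-resolved votes.
#' @param minimalist_order `"per_decision"` (a fresh random order for every
#'   pair; the classic definition, and the default) or `"per_agent"` (one
#'   random order per member per replicate; sensitivity check).
#' @param population_pairs,population_seed Size and dedicated seed of the
#'   Monte-Carlo population used for objective validities
#'   (see [objective_validity()]).
#' @return One-row data frame: `environment`, `heuristic`, `m`, `n_learn`,
#'   `sigma`, `pc_individual`, `pc_group`, `decision_diversity`,
#'   `search_diversity`, `n_samples`, `seed`, `n_decisions`, `tie_rate`.
#' @examples
#' run_condition("LD", "minimalist", m = 5, n_samples = 50, seed = 1)
#' @export
run_condition <- function(env, heuristic = c("ttb", "minimalist"), m,
                          n_options = 15, n_samples = 2000, sigma = 0,
                          n_learn = NULL, seed = NULL,
                          score_guess_half = FALSE,
                          minimalist_order = c("per_decision", "per_agent"),
                          population_pairs = 1e6,
                          population_seed = 424242L) {
  if (is.character(env)) env <- task_environment(env)
  stopifnot(inherits(env, "task_environment"))
  heuristic <- match.arg(heuristic)
  minimalist_order <- match.arg(minimalist_order)
  if (m < 1) stop("group size m must be at least 1", call. = FALSE)
  if (n_options < 2) stop("n_options must be at least 2", call. = FALSE)
  if (n_samples < 1) stop("n_samples must be positive", call. = FALSE)
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  learn_pop <- identical(n_learn, "population")
  if (!is.null(n_learn) && !learn_pop &&
      (!is.numeric(n_learn) || n_learn < 2)) {
    stop("n_learn must be NULL, 'population', or a sample size >= 2",
         call. = FALSE)
  }
  m <- as.integer(m)
  n_samples <- as.integer(n_samples)

  # objective-order agent; RNG-neutral (dedicated seed, session stream kept)
  base_agent <- NULL
  if (heuristic == "ttb" && (is.null(n_learn) || learn_pop)) {
    base_agent <- objective_agent(
      objective_validity(env, n_pairs = population_pairs,
                         seed = population_seed))
  }
  learning <- heuristic == "ttb" && !is.null(n_learn) && !learn_pop
  homogeneous <- !is.null(base_agent) && sigma == 0

  if (!is.null(seed)) set.seed(seed)
  k <- length(env$betas)
  idx <- pair_indices(n_options)
  ia <- idx[1L, ]
  ib <- idx[2L, ]
  np <- ncol(idx)
  min_agent <- if (heuristic == "minimalist" &&
                   minimalist_order == "per_decision") minimalist_agent(k)

  ind_sum <- 0; ind_n <- 0      # member-decision correctness
  grp_sum <- 0; grp_n <- 0      # group-decision correctness
  dd_sum <- 0; sd_sum <- 0      # diversity accumulators (per pair)
  div_n <- 0
  tie_sum <- 0
  n_excluded <- 0

  for (r in seq_len(n_samples)) {
    opts <- generate_options(env, n_options)
    ca <- opts$criterion[ia]
    cb <- opts$criterion[ib]
    ok <- ca != cb
    a_larger <- ca > cb
    n_ok <- sum(ok)
    n_excluded <- n_excluded + (np - n_ok)

    if (homogeneous) {
      dec <- decide_pairs(base_agent,
                          opts$cues_bin[ia, , drop = FALSE],
                          opts$cues_bin[ib, , drop = FALSE],
                          collect_search = TRUE)
      correct <- (dec$choice == 1L) == a_larger
      ind_corr <- as.numeric(correct)
      if (score_guess_half) ind_corr[dec$guessed] <- 0.5
      ind_sum <- ind_sum + m * sum(ind_corr[ok])
      ind_n <- ind_n + m * n_ok
      grp_sum <- grp_sum + sum(correct[ok])
      grp_n <- grp_n + n_ok
      sd_sum <- sd_sum + sum(rowSums(dec$searched))
      div_n <- div_n + np
      next
    }

    bins <- if (sigma > 0) perturb_cues(opts, sigma, m)
    votes <- matrix(0L, np, m)
    guessed <- matrix(FALSE, np, m)
    search_union <- matrix(FALSE, np, k)
    for (a in seq_len(m)) {
      agent <- if (learning) {
        learn_from_sample(generate_options(env, n_learn))
      } else if (heuristic == "minimalist") {
        if (minimalist_order == "per_agent") {
          ttb_agent(sample.int(k))
        } else {
          min_agent
        }
      } else {
        base_agent
      }
      bin <- if (sigma > 0) bins[[a]] else opts$cues_bin
      dec <- decide_pairs(agent, bin[ia, , drop = FALSE],
                          bin[ib, , drop = FALSE], collect_search = TRUE)
      votes[, a] <- dec$choice
      guessed[, a] <- dec$guessed
      search_union <- search_union | dec$searched
    }
    grp <- majority_matrix(votes)
    ind_corr <- (votes == 1L) == matrix(a_larger, np, m)
    ind_corr <- ind_corr + 0
    if (score_guess_half) ind_corr[guessed] <- 0.5
    ind_sum <- ind_sum + sum(ind_corr[ok, , drop = FALSE])
    ind_n <- ind_n + m * n_ok
    grp_sum <- grp_sum + sum(((grp$choice == 1L) == a_larger)[ok])
    grp_n <- grp_n + n_ok
    tie_sum <- tie_sum + sum(grp$tie_broken)
    if (m >= 2) {
      v1 <- rowSums(votes == 1L)
      dd_sum <- dd_sum + sum(v1 * (m - v1) / choose(m, 2))
    }
    sd_sum <- sd_sum + sum(rowSums(search_union))
    div_n <- div_n + np
  }

  data.frame(
    environment = env$name,
    heuristic = heuristic,
    m = m,
    n_learn = if (is.null(n_learn)) NA_character_ else as.character(n_learn),
    sigma = sigma,
    pc_individual = 100 * ind_sum / ind_n,
    pc_group = 100 * grp_sum / grp_n,
    decision_diversity = dd_sum / div_n,
    search_diversity = sd_sum / div_n,
    n_samples = n_samples,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    n_decisions = grp_n,
    tie_rate = tie_sum / (np * n_samples),
    stringsAsFactors = FALSE)
}

#' Configure a simulation study
#'
#' Bundles the parameter grid of one of the three study designs with its
#' replicate count and root seed.  Defaults follow the study definitions:
#'
#' * **Study 1 (group size)** — error-free cues, objective-order
#'   take-the-best versus minimalist, `n = 15` options per sample, group
#'   sizes `m = 1, 5, 15, 100`.
#' * **Study 2 (individual learning)** — take-the-best agents learn cue
#'   orders from independent samples of `n_learn = 10, 15, 25, 50` options
#'   or know the population order; minimalist as the no-learning baseline;
#'   `m = 5`, testing samples of 15 options.
#' * **Study 3 (information errors)** — per-agent Gaussian cue noise with
#'   `sigma = 0, 0.2, 0.4, 0.6, 0.8`; both heuristics with objective
#'   orders; `m = 5`, `n = 15`.
#'
#' The full design uses `N = 10000` replicate samples per condition
#' (`full = TRUE`); the default reduced mode uses `N = 2000`, which leaves
#' every figure-level ordering statistically clear while keeping a full
#' sweep in minutes.
#'
#' @param study 1, 2 or 3.
#' @param environments Environment names to sweep.
#' @param heuristics Heuristics to run.
#' @param group_sizes,n_options,learning_sizes,sigmas Grid overrides; the
#'   study defaults apply when `NULL`.  `learning_sizes` may mix numbers
#'   and the string `"population"`.
#' @param n_samples Replicates per condition; default 2000 (reduced) or
#'   10000 (`full = TRUE`).
#' @param seed Root seed; per-condition substream seeds are derived from it
#'   so any subset of conditions reproduces identically.
#' @param full Use the full replicate count.
#' @return An object of class `study_config`.
#' @export
study_config <- function(study, environments = c("LD", "MD", "SD", "ND"),
                         heuristics = c("ttb", "minimalist"),
                         group_sizes = NULL, n_options = 15,
                         learning_sizes = NULL, sigmas = NULL,
                         n_samples = NULL, seed = 1L, full = FALSE) {
  if (!study %in% 1:3) stop("study must be 1, 2 or 3", call. = FALSE)
  if (is.null(n_samples)) n_samples <- if (full) 10000L else 2000L
  if (n_samples < 1) stop("n_samples must be positive", call. = FALSE)
  if (is.null(group_sizes)) {
    group_sizes <- if (study == 1) c(1L, 5L, 15L, 100L) else 5L
  }
  if (study == 2 && is.null(learning_sizes)) {
    learning_sizes <- list(10L, 15L, 25L, 50L, "population")
  }
  if (is.null(sigmas)) sigmas <- if (study == 3) c(0, 0.2, 0.4, 0.6, 0.8) else 0
  if (any(sigmas < 0)) stop("sigma must be nonnegative", call. = FALSE)
  if (any(group_sizes < 1) || n_options < 2) {
    stop("group sizes and n_options must be positive", call. = FALSE)
  }
  structure(list(study = study, environments = environments,
                 heuristics = heuristics, group_sizes = group_sizes,
                 n_options = n_options,
                 learning_sizes = if (is.null(learning_sizes)) NULL
                                  else as.list(learning_sizes),
                 sigmas = sigmas, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study", x$study, "configuration:",
      length(study_grid(x)), "conditions,",
      x$n_samples, "replicates each, seed", x$seed, "\n")
  invisible(x)
}

# expand a config into a list of run_condition argument lists
study_grid <- function(config) {
  grid <- list()
  add <- function(...) grid[[length(grid) + 1L]] <<- list(...)
  for (envname in config$environments) {
    if (config$study == 1) {
      # take-the-best groups are homogeneous here: accuracy is invariant
      # in m, so one row represents the take-the-best group
      if ("ttb" %in% config$heuristics) {
        add(env = envname, heuristic = "ttb", m = 1L)
      }
      if ("minimalist" %in% config$heuristics) {
        for (m in config$group_sizes) {
          add(env = envname, heuristic = "minimalist", m = as.integer(m))
        }
      }
    } else if (config$study == 2) {
      for (m in config$group_sizes) {
        if ("ttb" %in% config$heuristics) {
          for (nl in config$learning_sizes) {
            add(env = envname, heuristic = "ttb", m = as.integer(m),
                n_learn = if (identical(nl, "population")) "population"
                          else as.integer(nl))
          }
        }
        if ("minimalist" %in% config$heuristics) {
          add(env = envname, heuristic = "minimalist", m = as.integer(m))
        }
      }
    } else {
      for (h in config$heuristics) {
        for (m in config$group_sizes) {
          for (s in config$sigmas) {
            add(env = envname, heuristic = h, m = as.integer(m), sigma = s)
          }
        }
      }
    }
  }
  grid
}

#' Run a full study sweep
#'
#' Expands the configuration into its condition grid and runs
#' [run_condition()] on every grid point.  Each condition receives its own
#' substream seed derived deterministically from the root seed, so results
#' are bit-reproducible and independent of sweep order.
#'
#' @param config A [study_config()].
#' @param verbose Log one line per condition.
#' @param ... Further arguments passed to [run_condition()] (e.g.
#'   `minimalist_order`, `score_guess_half`).
#' @return Data frame with one row per condition (see [run_condition()]).
#' @examples
#' cfg <- study_config(1, environments = "LD", n_samples = 20)
#' run_study(cfg)
#' @export
run_study <- function(config, verbose = FALSE, ...) {
  stopifnot(inherits(config, "study_config"))
  grid <- study_grid(config)
  seeds <- withr::with_seed(
    config$seed, sample.int(.Machine$integer.max, length(grid)))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    args <- grid[[i]]
    args$n_options <- config$n_options
    args$n_samples <- config$n_samples
    args$seed <- seeds[i]
    if (verbose) {
      message(sprintf("[%d/%d] %s %s m=%s%s%s", i, length(grid), args$env,
                      args$heuristic, args$m,
                      if (!is.null(args$n_learn))
                        paste0(" n_learn=", args$n_learn) else "",
                      if (!is.null(args$sigma) && args$sigma > 0)
                        paste0(" sigma=", args$sigma) else ""))
    }
    rows[[i]] <- do.call(run_condition, c(args, list(...)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read/write study results as tidy CSV
#'
#' @param results Data frame returned by [run_study()] or
#'   [run_condition()].
#' @param path File path.
#' @return `read_results` returns the data frame; `write_results` returns
#'   `path` invisibly.
#' @export
write_results <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(n_learn = "character"))
}
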