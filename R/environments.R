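#' Define a cue task environment
#'
#' A task environment is the generative model for one decision task: options
#' carry a continuous criterion built as a linear combination of five
#' independent standard-normal cues plus an independent standard-normal error
#' term, `Y = sum(betas * X) + beta_e * Xe`.  The dispersion of the cue
#' coefficients controls how unequal the cues' validities are.
#'
#' Four named environments are bundled with the package, ranging from a
#' highly dispersed coefficient profile to a flat one:
#' `"LD"` (large difference), `"MD"` (medium), `"SD"` (small), `"ND"` (none).
#' Calling `task_environment("LD")` returns the bundled definition; passing
#' `betas`/`beta_e` defines a custom environment with the same structure.
#'
#' @param name Environment label.  One of the bundled names, or any label
#'   when `betas` is supplied.
#' @param betas Numeric vector of five nonnegative cue coefficients.
#' @param beta_e Nonnegative coefficient of the error term.
#' @return An object of class `task_environment`: a list with elements
#'   `name`, `betas` (length 5) and `beta_e`.
#' @examples
#' env <- task_environment("LD")
#' variance_explained(env)
#' @seealso [builtin_environments()], [generate_options()],
#'   [variance_explained()]
#' @export
task_environment <- function(name, betas = NULL, beta_e = NULL) {
  if (is.null(betas) && is.null(beta_e)) {
    envs <- builtin_environments()
    if (!name %in% names(envs)) {
      stop("unknown environment '", name, "'; bundled environments are ",
           paste(names(envs), collapse = ", "),
           " (supply betas/beta_e for a custom one)", call. = FALSE)
    }
    return(envs[[name]])
  }
  new_task_environment(name, betas, beta_e)
}

new_task_environment <- function(name, betas, beta_e) {
  betas <- as.numeric(betas)
  beta_e <- as.numeric(beta_e)
  if (length(betas) != 5L) {
    stop("a task environment has exactly five cue coefficients", call. = FALSE)
  }
  if (length(beta_e) != 1L) stop("beta_e must be a single number", call. = FALSE)
  if (anyNA(betas) || is.na(beta_e) || any(betas < 0) || beta_e < 0) {
    stop("coefficients must be nonnegative and finite", call. = FALSE)
  }
  structure(list(name = as.character(name), betas = betas, beta_e = beta_e),
            class = "task_environment")
}

#' Bundled task environments
#'
#' Reads the environment definitions shipped with the package (or any file
#' with the same JSON schema: an array of objects with fields `name`,
#' `betas`, `beta_e`).
#'
#' @param path Path to a JSON file of environment definitions; default the
#'   bundled set (LD, MD, SD, ND).
#' @return Named list of [task_environment] objects.
#' @export
builtin_environments <- function(path = NULL) {
  if (is.null(path)) {
    key <- "builtin_environments"
    if (!is.null(.heurigroup_cache[[key]])) return(.heurigroup_cache[[key]])
    path <- system.file("extdata", "environments.json", package = "heurigroup",
                        mustWork = TRUE)
  } else {
    key <- NULL
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  envs <- lapply(seq_len(nrow(raw)), function(i) {
    new_task_environment(raw$name[i], raw$betas[[i]], raw$beta_e[i])
  })
  names(envs) <- raw$name
  if (!is.null(key)) .heurigroup_cache[[key]] <- envs
  envs
}

#' @export
print.task_environment <- function(x, ...) {
  cat("Task environment '", x$name, "'\n", sep = "")
  cat("  cue coefficients:", paste(format(x$betas), collapse = ", "), "\n")
  cat("  error coefficient:", format(x$beta_e), "\n")
  cat("  variance explained by cues:",
      format(round(variance_explained(x), 3)), "\n")
  invisible(x)
}

#' Fraction of criterion variance attributable to the cues
#'
#' Closed form for the linear-Gaussian model: with independent
#' standard-normal cues and error term, the criterion variance is
#' `sum(betas^2) + beta_e^2`, of which the cues contribute `sum(betas^2)`.
#'
#' @param env A [task_environment].
#' @return A number in `[0, 1]`.
#' @examples
#' variance_explained(task_environment("SD"))  # 0.866 to 3 d.p.
#' @export
variance_explained <- function(env) {
  stopifnot(inherits(env, "task_environment"))
  ss <- sum(env$betas^2)
  if (ss == 0 && env$beta_e == 0) {
    stop("all coefficients are zero: the criterion is degenerate", call. = FALSE)
  }
  if (ss == 0) stop("no nonzero cue coefficient", call. = FALSE)
  ss / (ss + env$beta_e^2)
}

#' Dichotomize continuous cue values
#'
#' Converts continuous cue values to binary at a cutoff: 1 when the value is
#' strictly above the cutoff, 0 otherwise (values exactly at the cutoff code
#' as 0; for continuous cues this is a probability-zero convention).  The
#' default cutoff 0 is the distributional median of the standard-normal cues
#' (and of any mean-zero Gaussian perturbation of them), so the same cutoff
#' applies to learning samples, testing samples and noise-perturbed cues.
#'
#' @param values Numeric vector or matrix (options x cues) of cue values.
#' @param cutoff Cutoff; a single number, or one per column for a matrix.
#' @return Binary (0/1) object of the same shape as `values`.
#' @examples
#' dichotomize(c(-0.3, 0.2, 1.1))  # 0 1 1
#' @export
dichotomize <- function(values, cutoff = 0) {
  if (anyNA(values) || any(!is.finite(values))) {
    stop("cue values must be finite", call. = FALSE)
  }
  if (is.matrix(values)) {
    if (!length(cutoff) %in% c(1L, ncol(values))) {
      stop("cutoff must have length 1 or one entry per cue", call. = FALSE)
    }
    out <- (values > rep(cutoff, each = nrow(values))) + 0L
    dimnames(out) <- dimnames(values)
    return(out)
  }
  (values > cutoff) + 0L
}

#' Generate a sample of options from a task environment
#'
#' Draws `n_options` options: five independent standard-normal continuous
#' cues and an error term per option, a criterion formed as the
#' environment's linear combination, and binary cues obtained by
#' dichotomizing the continuous cues at the cutoff.
#'
#' Uses the R session random-number stream; call `set.seed()` (or use the
#' `seed` arguments of the study drivers) for reproducibility.
#'
#' @param env A [task_environment].
#' @param n_options Number of options to draw (at least 2).
#' @param cutoff Dichotomization cutoff, default 0 (the distributional
#'   median of the cues).
#' @return An object of class `option_set`: list with `criterion` (numeric
#'   vector), `cues_cont` and `cues_bin` (`n_options` x 5 matrices) and
#'   `cutoff`.
#' @examples
#' set.seed(1)
#' opts <- generate_options(task_environment("LD"), 15)
#' nrow(opts$cues_bin)
#' @export
generate_options <- function(env, n_options, cutoff = 0) {
  stopifnot(inherits(env, "task_environment"))
  if (length(n_options) != 1L || is.na(n_options) || n_options < 2) {
    stop("n_options must be a single integer >= 2", call. = FALSE)
  }
  n <- as.integer(n_options)
  k <- length(env$betas)
  cues <- matrix(rnorm(n * k), n, k,
                 dimnames = list(NULL, paste0("cue", seq_len(k))))
  err <- rnorm(n)
  criterion <- drop(cues %*% env$betas) + env$beta_e * err
  new_option_set(criterion, cues, dichotomize(cues, cutoff), cutoff)
}

#' Construct an option set from explicit components
#'
#' Builds an `option_set` from user-supplied values, e.g. for worked
#' examples or fixtures.  When `cues_bin` is omitted it is derived from
#' `cues_cont` by [dichotomize()] at `cutoff`.
#'
#' @param criterion Numeric criterion values, one per option.
#' @param cues_cont Options x cues matrix of continuous cue values.
#' @param cues_bin Optional binary cue matrix of the same shape.
#' @param cutoff Dichotomization cutoff.
#' @return An `option_set`.
#' @examples
#' option_set(c(3, 2, 1), matrix(c(1, -1, 1, -1, 1, -1), 3, 2))
#' @export
option_set <- function(criterion, cues_cont, cues_bin = NULL, cutoff = 0) {
  cues_cont <- as.matrix(cues_cont)
  if (is.null(cues_bin)) cues_bin <- dichotomize(cues_cont, cutoff)
  new_option_set(criterion, cues_cont, cues_bin, cutoff)
}

new_option_set <- function(criterion, cues_cont, cues_bin, cutoff = 0) {
  cues_cont <- as.matrix(cues_cont)
  cues_bin <- as.matrix(cues_bin)
  storage.mode(cues_bin) <- "integer"
  if (length(criterion) != nrow(cues_cont) ||
      !all(dim(cues_cont) == dim(cues_bin))) {
    stop("criterion, cues_cont and cues_bin sizes disagree", call. = FALSE)
  }
  if (!all(cues_bin %in% c(0L, 1L))) {
    stop("cues_bin entries must be 0 or 1", call. = FALSE)
  }
  structure(list(criterion = as.numeric(criterion), cues_cont = cues_cont,
                 cues_bin = cues_bin, cutoff = cutoff),
            class = "option_set")
}

#' @export
print.option_set <- function(x, ...) {
  cat("Option set:", length(x$criterion), "options,",
      ncol(x$cues_bin), "binary cues (cutoff ", x$cutoff, ")\n", sep = " ")
  invisible(x)
}

#' Read/write an option set as CSV
#'
#' Plain-text round trip of an [generate_options()] result: one row per
#' option with columns `criterion`, `cue1..cue5` (continuous) and
#' `cue1_bin..cue5_bin`.
#'
#' @param options An `option_set`.
#' @param path File path.
#' @param cutoff Cutoff recorded in the restored object.
#' @return `read_option_set` returns an `option_set`; `write_option_set`
#'   returns `path` invisibly.
#' @export
write_option_set <- function(options, path) {
  stopifnot(inherits(options, "option_set"))
  k <- ncol(options$cues_cont)
  df <- data.frame(criterion = options$criterion, options$cues_cont,
                   check.names = FALSE)
  bin <- options$cues_bin
  colnames(bin) <- paste0(colnames(options$cues_cont), "_bin")
  df <- cbind(df, bin)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_option_set
#' @export
read_option_set <- function(path, cutoff = 0) {
  df <- read.csv(path, check.names = FALSE)
  cont <- as.matrix(df[, grep("^cue[0-9]+$", names(df)), drop = FALSE])
  bin <- as.matrix(df[, grep("_bin$", names(df)), drop = FALSE])
  colnames(bin) <- sub("_bin$", "", colnames(bin))
  new_option_set(df$criterion, cont, bin, cutoff)
}

#' Per-agent noisy perception of binary cues
#'
#' Models information errors: each agent perceives each continuous cue value
#' with an independent additive Gaussian error of standard deviation
#' `sigma`, and dichotomizes the perturbed value at the same cutoff as the
#' clean cues.  Errors are drawn once per (agent, cue, option) and therefore
#' stay fixed across every pairwise comparison within the option set.  A
#' cue's perceived binary value flips relative to the error-free value with
#' probability `pnorm(-abs(x) / sigma)` for a continuous value `x`.
#'
#' @param options An `option_set`.
#' @param sigma Standard deviation of the perception error (>= 0).  With
#'   `sigma = 0` no random draws are made and every agent perceives the
#'   clean binary cues exactly.
#' @param n_agents Number of agents to draw independent error sets for.
#' @return List of `n_agents` binary matrices (options x cues).
#' @export
perturb_cues <- function(options, sigma, n_agents) {
  stopifnot(inherits(options, "option_set"))
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("sigma must be a single nonnegative number", call. = FALSE)
  }
  if (n_agents < 1) stop("n_agents must be positive", call. = FALSE)
  n_agents <- as.integer(n_agents)
  if (sigma == 0) {
    return(replicate(n_agents, options$cues_bin, simplify = FALSE))
  }
  n <- nrow(options$cues_cont)
  k <- ncol(options$cues_cont)
  lapply(seq_len(n_agents), function(a) {
    noisy <- options$cues_cont + matrix(rnorm(n * k, sd = sigma), n, k)
    dichotomize(noisy, options$cutoff)
  })
}
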