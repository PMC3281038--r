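test_that("bundled environments carry the reference coefficient sets", {
  envs <- builtin_environments()
  expect_named(envs, c("LD", "MD", "SD", "ND"))
  for (env in envs) {
    expect_s3_class(env, "task_environment")
    expect_length(env$betas, 5)
    expect_true(all(env$betas >= 0) && env$beta_e >= 0)
  }
  expect_equal(envs$LD$betas, c(0.37, 0.23, 0.11, 0.07, 0.04))
  expect_equal(envs$LD$beta_e, 0.18)
  expect_equal(envs$ND$betas, rep(0.17, 5))
  # total criterion variance (sum of squared coefficients), by hand
  expect_equal(sum(envs$LD$betas^2) + envs$LD$beta_e^2, 0.2408)
  expect_equal(sum(envs$SD$betas^2) + envs$SD$beta_e^2, 0.1680)
  expect_error(task_environment("XX"), "unknown environment")
  expect_error(task_environment("bad", betas = c(1, 2), beta_e = 0.1),
               "five cue coefficients")
  expect_error(task_environment("bad", betas = c(-1, 1, 1, 1, 1),
                                beta_e = 0.1), "nonnegative")
})

test_that("dichotomization follows the strict above-cutoff rule", {
  expect_equal(dichotomize(c(-0.3, 0.2, 1.1)), c(0L, 1L, 1L))
  # values exactly at the cutoff code as 0
  expect_equal(dichotomize(rep(0.7, 4), cutoff = 0.7), rep(0L, 4))
  m <- matrix(c(-1, 1, 2, -2), 2, 2)
  expect_equal(dichotomize(m, cutoff = c(0, -3)), matrix(c(0L, 1L, 1L, 1L), 2, 2))
  expect_error(dichotomize(c(1, NA)), "finite")
  # cutoff 0 splits standard-normal draws evenly
  set.seed(401)
  expect_equal(mean(dichotomize(rnorm(1e5))), 0.5, tolerance = 0.01)
})

test_that("generated option sets obey the linear-Gaussian model", {
  env <- ld_env()
  set.seed(402)
  opts <- generate_options(env, 15)
  expect_s3_class(opts, "option_set")
  expect_length(opts$criterion, 15)
  expect_equal(dim(opts$cues_bin), c(15L, 5L))
  expect_true(all(opts$cues_bin %in% c(0L, 1L)))
  expect_equal(opts$cues_bin, dichotomize(opts$cues_cont, opts$cutoff))
  expect_error(generate_options(env, 1), "n_options")
  # criterion variance equals the coefficient sum of squares (0.2408)
  set.seed(403)
  big <- generate_options(env, 1e5)
  expect_equal(var(big$criterion), 0.2408, tolerance = 0.005)
})

test_that("a signal-free environment yields chance-level validities", {
  v <- objective_validity(noise_only_env(), n_pairs = 1e5, seed = 404)
  expect_true(all(abs(v$validity - 0.5) < 0.01))
})

test_that("validity counts match hand enumeration over pairs", {
  # criteria 3 > 2 > 1; cue (1,0,1): pair (1,2) right, (2,3) wrong, (1,3) silent
  opts <- binary_option_set(c(3, 2, 1), cbind(c(1, 0, 1)))
  v <- compute_validity(opts)
  expect_equal(v$n_right, 1L)
  expect_equal(v$n_wrong, 1L)
  expect_equal(v$validity, 0.5)
  expect_true(v$defined)
  # a cue identical to the criterion rank order is perfectly valid
  opts2 <- binary_option_set(c(5, 4, 1), cbind(c(1, 1, 0), c(0, 0, 0)))
  v2 <- compute_validity(opts2)
  expect_equal(v2$validity[1], 1)
  # constant cue never discriminates: undefined, reported neutral
  expect_false(v2$defined[2])
  expect_equal(v2$validity[2], 0.5)
  # pairs with exactly equal criteria are excluded and counted
  opts3 <- binary_option_set(c(2, 2, 1), cbind(c(1, 0, 1)))
  v3 <- compute_validity(opts3)
  expect_equal(attr(v3, "n_tied_pairs"), 1L)
  expect_equal(v3$n_right + v3$n_wrong, 1L)  # only the (2,3) pair counts
})

test_that("sampled-pair validity converges to the all-pairs value", {
  set.seed(405)
  opts <- generate_options(ld_env(), 60)
  all_pairs <- compute_validity(opts, pairs = "all")
  sampled <- compute_validity(opts, pairs = "sampled", n_pairs = 2e5)
  expect_equal(sampled$validity, all_pairs$validity, tolerance = 0.01)
  expect_error(compute_validity(opts, pairs = "sampled"), "n_pairs")
})

test_that("variance_explained matches the closed form on all environments", {
  expected <- c(LD = 0.865, MD = 0.864, SD = 0.866, ND = 0.865)
  for (nm in names(expected)) {
    expect_equal(round(variance_explained(task_environment(nm)), 3),
                 unname(expected[nm]))
  }
  expect_equal(variance_explained(task_environment("pure", rep(1, 5), 0)), 1)
  expect_error(variance_explained(task_environment("void", rep(0, 5), 0)),
               "zero")
})

test_that("Monte-Carlo validities preserve the coefficient ordering", {
  for (nm in c("LD", "MD")) {
    v <- objective_validity(task_environment(nm), n_pairs = 2e5, seed = 406)
    expect_true(all(diff(v$validity) < 0))  # beta1 > ... > beta5 => V1 > ... > V5
    expect_true(all(v$validity > 0.5))
  }
})

test_that("cue perturbation flips binary values at the Gaussian tail rate", {
  set.seed(407)
  opts <- generate_options(sd_env(), 20)
  expect_error(perturb_cues(opts, -0.1, 2), "nonnegative")
  # zero noise: bit-exact identity for every agent, no randomness consumed
  clean <- perturb_cues(opts, 0, 3)
  for (b in clean) expect_identical(b, opts$cues_bin)
  # strong noise: two agents perceive different cue patterns
  noisy <- perturb_cues(opts, 0.8, 2)
  expect_false(identical(noisy[[1]], noisy[[2]]))
  # flip probability of a single value x is pnorm(-|x| / sigma)
  x <- 0.5
  sigma <- 0.4
  one <- option_set(criterion = rep(1, 2e4),
                    cues_cont = matrix(x, 2e4, 5))
  set.seed(408)
  flipped <- 1 - perturb_cues(one, sigma, 1)[[1]]
  expect_equal(mean(flipped), pnorm(-x / sigma), tolerance = 0.01)
})

test_that("option sets survive a CSV round trip", {
  set.seed(409)
  opts <- generate_options(ld_env(), 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_option_set(opts, path)
  back <- read_option_set(path)
  expect_equal(back$criterion, opts$criterion, tolerance = 1e-12)
  expect_identical(back$cues_bin, opts$cues_bin)
})
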