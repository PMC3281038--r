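test_that("take-the-best stops at the first discriminating cue", {
  agent <- ttb_agent(1:3)
  # two flowers on odor/color/shape: stop at the color cue, choose B
  clean <- decide_pair(agent, c(1, 0, 1), c(1, 1, 0))
  expect_equal(clean$choice, "B")
  expect_equal(clean$stopping_cue, 2L)
  expect_equal(clean$searched_cues, c(1L, 2L))
  expect_false(clean$guessed)
  # B's second cue misread as 0: search continues, stop at cue 3, choose A
  misread <- decide_pair(agent, c(1, 0, 1), c(1, 0, 0))
  expect_equal(misread$choice, "A")
  expect_equal(misread$stopping_cue, 3L)
  expect_equal(misread$searched_cues, 1:3)
  # a reversed cue points the decision the other way
  rev_agent <- ttb_agent(1:3, directions = c("normal", "reversed", "normal"))
  expect_equal(decide_pair(rev_agent, c(1, 0, 1), c(1, 1, 0))$choice, "A")
  expect_error(decide_pair(agent, c(1, 0), c(1, 1, 0)), "equal length")
  expect_error(decide_pair(agent, c(1, 2, 0), c(1, 1, 0)), "binary")
})

test_that("forced guesses are resolved by a fair coin", {
  agent <- ttb_agent(1:4)
  set.seed(501)
  picks <- replicate(4000, {
    d <- decide_pair(agent, c(1, 0, 1, 0), c(1, 0, 1, 0))
    expect_true(d$guessed)
    d$choice
  })
  expect_true(is.na(decide_pair(agent, rep(1, 4), rep(1, 4))$stopping_cue))
  expect_lt(abs(mean(picks == "A") - 0.5), 0.03)
})

test_that("vectorized decisions agree with the sequential algorithm", {
  set.seed(502)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    np <- 30
    a <- matrix(rbinom(np * k, 1, 0.5), np, k)
    b <- matrix(rbinom(np * k, 1, 0.5), np, k)
    dirs <- sample(c("normal", "reversed"), k, replace = TRUE)
    agent <- ttb_agent(sample.int(k), directions = dirs)
    batch <- decide_pairs(agent, a, b)
    for (p in seq_len(np)) {
      single <- decide_pair(agent, a[p, ], b[p, ])
      if (batch$guessed[p]) {
        expect_true(single$guessed)
      } else {
        expect_equal(batch$choice[p], if (single$choice == "A") 1L else 2L)
        expect_equal(batch$stopping_cue[p], single$stopping_cue)
      }
    }
  }
})

test_that("the winning option does not depend on presentation order", {
  set.seed(503)
  for (rep in 1:50) {
    a <- rbinom(5, 1, 0.5)
    b <- rbinom(5, 1, 0.5)
    agent <- ttb_agent(sample.int(5))
    d_ab <- decide_pair(agent, a, b)
    d_ba <- decide_pair(agent, b, a)
    if (!d_ab$guessed) {
      expect_equal(d_ab$choice, c(A = "B", B = "A")[[d_ba$choice]])
      expect_equal(d_ab$stopping_cue, d_ba$stopping_cue)
    }
    # minimalist: consistent under the same random search order
    min_agent <- minimalist_agent(5)
    set.seed(777 + rep); m_ab <- decide_pair(min_agent, a, b)
    set.seed(777 + rep); m_ba <- decide_pair(min_agent, b, a)
    if (!m_ab$guessed) {
      expect_equal(m_ab$choice, c(A = "B", B = "A")[[m_ba$choice]])
    }
  }
})

test_that("minimalist searched-cue sets are random prefixes ending at a discriminating cue", {
  set.seed(504)
  a <- matrix(rbinom(200 * 5, 1, 0.5), 200, 5)
  b <- matrix(rbinom(200 * 5, 1, 0.5), 200, 5)
  dec <- decide_pairs(minimalist_agent(5), a, b, collect_search = TRUE)
  disc <- a != b
  for (p in 1:200) {
    if (dec$guessed[p]) {
      expect_equal(sum(dec$searched[p, ]), 5)  # exhausted search
    } else {
      s <- dec$searched[p, ]
      expect_true(s[dec$stopping_cue[p]])
      expect_true(disc[p, dec$stopping_cue[p]])
      # search stops at the first discriminating cue, so exactly one of
      # the searched cues discriminates
      expect_equal(sum(disc[p, ] & s), 1)
    }
  }
})

test_that("learning orders cues by effective validity", {
  # cue 1 tracks the criterion perfectly (V = 1); the others err:
  # hand enumeration gives V = 2/3 for cue 2 and V = 1/3 for cue 3
  crit <- c(6, 5, 4, 3, 2, 1)
  bin <- cbind(c(1, 1, 1, 0, 0, 0),
               c(1, 0, 1, 0, 1, 0),
               c(0, 0, 1, 1, 1, 0),
               c(1, 0, 0, 1, 1, 0),
               c(0, 0, 1, 1, 0, 1))
  set.seed(505)
  agent <- learn_from_sample(binary_option_set(crit, bin))
  expect_equal(agent$validities$validity[1:3], c(1, 2 / 3, 1 / 3))
  expect_equal(agent$cue_order[1], 1L)
  expect_equal(agent$directions[1], "normal")
  # the below-0.5 cue is read in reverse at effective validity 2/3
  expect_equal(agent$directions[3], "reversed")
})

test_that("an anti-correlated cue is learned as a reversed first cue", {
  # single informative cue, perfectly wrong way round: V = 0, effective 1
  crit <- c(3, 2, 1)
  bin <- cbind(c(0, 0, 1), c(1, 1, 1))
  set.seed(510)
  agent <- learn_from_sample(binary_option_set(crit, bin))
  expect_equal(agent$validities$validity[1], 0)
  expect_false(agent$validities$defined[2])  # constant cue: neutral 0.5
  expect_equal(agent$cue_order[1], 1L)
  expect_equal(agent$directions, c("reversed", "normal"))
  # the reversed cue now decides correctly: option A has the larger
  # criterion and the smaller raw cue value
  expect_equal(decide_pair(agent, c(0, 1), c(1, 1))$choice, "A")
})

test_that("objective agents are deterministic with index tie-breaks", {
  ld <- objective_agent(c(0.86, 0.71, 0.60, 0.57, 0.54))
  expect_equal(ld$cue_order, 1:5)
  expect_equal(ld$directions, rep("normal", 5))
  flat <- objective_agent(rep(0.69, 5))
  expect_equal(flat$cue_order, 1:5)
  rev <- objective_agent(c(0.54, 0.57, 0.60, 0.71, 0.86))
  expect_equal(rev$cue_order, 5:1)
  # a below-0.5 objective validity is used reversed at effective 1 - V
  low <- objective_agent(c(0.9, 0.2, 0.6, 0.55, 0.52))
  expect_equal(low$directions[2], "reversed")
  expect_equal(low$cue_order, c(1L, 2L, 3L, 4L, 5L))  # effective 0.8 ranks 2nd
})

test_that("learning from a near-population sample recovers the objective order", {
  set.seed(506)
  big <- generate_options(ld_env(), 3000)
  agent <- learn_from_sample(big)
  objective <- objective_agent(objective_validity(ld_env(), n_pairs = 2e5,
                                                  seed = 507))
  expect_equal(agent$cue_order, objective$cue_order)
  expect_equal(objective$cue_order, 1:5)
})

test_that("minimalist matches take-the-best when validities are flat", {
  ttb <- run_condition(nd_env(), "ttb", m = 1, n_samples = 1000, seed = 508)
  min_ <- run_condition(nd_env(), "minimalist", m = 1, n_samples = 1000,
                        seed = 508)
  expect_lt(abs(ttb$pc_individual - min_$pc_individual), 1.0)
})

test_that("agents survive a JSON round trip", {
  set.seed(509)
  agent <- learn_from_sample(generate_options(sd_env(), 12))
  back <- agent_from_json(agent_to_json(agent))
  expect_equal(back$kind, agent$kind)
  expect_equal(back$cue_order, agent$cue_order)
  expect_equal(back$directions, agent$directions)
  expect_equal(back$validities$validity, agent$validities$validity)
  min_back <- agent_from_json(agent_to_json(minimalist_agent(5)))
  expect_equal(min_back$kind, "minimalist")
  expect_null(min_back$cue_order)
})
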