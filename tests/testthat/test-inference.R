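test_that("dynamic-programming MAP equals the enumeration oracle on random toys", {
  set.seed(81)
  for (r in 1:30) {
    m <- rand_model(K = 3, W = 2, N = 4)
    h <- rand_history(T_ = 3, N = 4)
    a <- map_trajectory(h, m)
    b <- brute_force_map(h, m)
    expect_identical(a$stage, b$stage)
    expect_identical(a$active, b$active)
    expect_equal(a$logp, b$logp, tolerance = 1e-9)
  }
})

test_that("MAP trajectories honor hard anchor evidence and reject impossible input", {
  anchors <- anchor_set(list(C1 = "F1"))
  m <- rand_model(K = 2, W = 2, N = 3, anchors = anchors)
  m$leak[1] <- 0
  h <- patient_history("p", 0:2, list(integer(0), 1L, integer(0)))
  tr <- map_trajectory(h, m)
  expect_true(all(tr$active[2:3, 1]))       # anchored onset from slice 2 on

  ## a positive finding no cause can produce
  m2 <- rand_model(K = 2, W = 1, N = 2)
  m2$A[] <- 0; m2$leak[] <- 0
  h2 <- patient_history("p", 0:1, list(integer(0), 2L))
  expect_error(map_trajectory(h2, m2), "slice 2")
  expect_error(brute_force_map(h2, m2), "zero-probability")
})

test_that("the enumeration oracle guards its search space and breaks ties lexicographically", {
  m <- rand_model(K = 5, W = 8, N = 9)
  h <- rand_history(T_ = 8, N = 9)
  expect_error(brute_force_map(h, m), "1e6")

  ## fully tied model: the lexicographically smallest assignment wins in
  ## both engines (earliest stages, then earliest onsets)
  flat <- rand_model(K = 2, W = 1, N = 2)
  flat$A[] <- 0; flat$leak[] <- 0.5; flat$pi_onset[] <- 0.5
  flat$h_onset[] <- 1; flat$Q <- matrix(0, 2, 2)
  h1 <- patient_history("p", c(0, 1), list(1L, 1L))
  a <- map_trajectory(h1, flat)
  b <- brute_force_map(h1, flat)
  expect_identical(a$stage, b$stage)
  expect_identical(a$active, b$active)
  expect_identical(b$stage, c(1L, 1L))      # earliest stages
  expect_true(all(b$active))                # earliest onsets
})

test_that("forecasts follow the closed forms and are monotone in the hazard", {
  m <- toy2_model()
  h <- patient_history("p", 0:1, list(1L, 1L))
  tr <- map_trajectory(h, m)

  ## absorbing last stage, zero hazards: nothing happens
  m0 <- toy2_model(); m0$h_onset[] <- 0
  tr0 <- map_trajectory(h, m0)
  tr0$stage <- c(2L, 2L)                   # force absorbing stage
  f0 <- forecast(tr0, m0, horizon_years = 5)
  expect_true(all(f0$forecast$stage == 2L))
  expect_true(all(is.na(f0$forecast$onset_year[!tr0$active[2, ]])))

  ## single complication at h = 0.5/yr: predicted onset in year 1
  m1 <- toy2_model(); m1$h_onset[] <- 0.5
  tr1 <- map_trajectory(patient_history("p", 0:1, list(integer(0), integer(0))), m1)
  tr1$stage <- c(2L, 2L); tr1$active[] <- FALSE
  f1 <- forecast(tr1, m1, horizon_years = 4)
  expect_identical(f1$forecast$onset_year[1], 1L)

  ## stage advance at rate ln 2: median crossing in year 1
  mq <- toy2_model()
  mq$Q <- matrix(c(-log(2), log(2), 0, 0), 2, 2, byrow = TRUE)
  trq <- map_trajectory(patient_history("p", 0:1, list(integer(0), integer(0))), mq)
  trq$stage <- c(1L, 1L)
  fq <- forecast(trq, mq, horizon_years = 5)
  expect_identical(fq$forecast$stage_entry[2], 1L)
  expect_true(!is.unsorted(fq$forecast$stage))

  ## predicted onset year nonincreasing in the hazard
  years <- vapply(c(0.15, 0.3, 0.6), function(hz) {
    mh <- toy2_model(); mh$h_onset[] <- hz
    trh <- trq; trh$stage <- c(1L, 1L); trh$active[] <- FALSE
    fh <- forecast(trh, mh, horizon_years = 30)
    fh$forecast$onset_year[1]
  }, 0L)
  expect_true(all(diff(years) <= 0))

  expect_error(forecast(tr, m, horizon_years = 0), "positive")
})

test_that("posterior complication marginals match logic and enumeration", {
  ## no evidence, zero hazards and initial probabilities: all zeros
  m <- toy2_model(); m$h_onset[] <- 0; m$pi_onset[] <- 0
  h <- patient_history("p", 0:1, list(integer(0), integer(0)))
  pp <- posterior_complication_probs(h, m, n_samples = 50, seed = 3, burn_in = 5)
  expect_true(all(pp == 0))

  ## anchored code with zero leak: marginal 1 at its slice
  anchors <- anchor_set(list(C1 = "F1"))
  ma <- rand_model(K = 2, W = 2, N = 3, anchors = anchors)
  ma$leak[1] <- 0
  ha <- patient_history("p", 0:1, list(integer(0), 1L))
  pa <- posterior_complication_probs(ha, ma, n_samples = 100, seed = 4, burn_in = 10)
  expect_equal(pa[2, 1], 1)

  ## enumeration on the two-slice toy
  m2 <- toy2_model()
  h2 <- patient_history("p", 0:1, list(1L, c(1L, 2L)))
  P <- stage_transition_matrix(m2$Q, 1)
  marg <- c(0, 0)
  norm <- 0
  for (s1 in 1:2) for (s2 in s1:2) for (tau in 1:3) {
    pr <- 0.5 * P[s1, s2] *
      switch(tau, m2$pi_onset[s1, 1],
             (1 - m2$pi_onset[s1, 1]) * m2$h_onset[s2, 1],
             (1 - m2$pi_onset[s1, 1]) * (1 - m2$h_onset[s2, 1]))
    for (t in 1:2) {
      act <- tau <= t
      p <- vapply(1:2, function(n) noisy_or_prob(act, n, m2), 0)
      pos <- c(TRUE, t == 2)
      pr <- pr * prod(ifelse(pos, p, 1 - p))
    }
    norm <- norm + pr
    marg <- marg + pr * c(tau <= 1, tau <= 2)
  }
  exact <- marg / norm
  pp2 <- posterior_complication_probs(h2, m2, n_samples = 8000, seed = 5, burn_in = 200)
  expect_lt(max(abs(pp2[, 1] - exact)), 0.025)
  ## monotone over slices
  expect_true(all(diff(pp2[, 1]) >= -0.02))

  ## invariance to patient relabeling
  h2b <- patient_history("someone_else", 0:1, list(1L, c(1L, 2L)))
  pp2b <- posterior_complication_probs(h2b, m2, n_samples = 500, seed = 7)
  pp2c <- posterior_complication_probs(h2, m2, n_samples = 500, seed = 7)
  expect_identical(pp2b, pp2c)
})
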