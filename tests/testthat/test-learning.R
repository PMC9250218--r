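test_that("model initialization is reproducible and binds the full anchor table", {
  ## synthetic 88-code vocabulary containing all 28 anchor codes
  anchors <- t2d_anchors()
  anchored <- unlist(anchors, use.names = FALSE)
  expect_length(anchored, 28)
  vocab <- sort(c(anchored, sprintf("X%02d.%d", 1:60, rep(1:9, length.out = 60))),
                method = "radix")
  expect_length(vocab, 88)
  m1 <- init_model(5, 12, vocab, anchors, seed = 7)
  m2 <- init_model(5, 12, vocab, anchors, seed = 7)
  expect_identical(m1$A, m2$A)
  expect_identical(m1$leak, m2$leak)
  expect_identical(m1$h_onset, m2$h_onset)
  cs <- colSums(m1$mask)
  expect_equal(sum(cs == 1), 28)
  expect_true(all(cs[cs != 1] == 12))
  expect_length(validate_model(m1), 0)
  ## anchored entries start at the anchor initialization value
  expect_equal(m1$A[1, code_index(m1$vocabulary, "E11.9")], 0.8)

  ## W = 1, no anchors: fully connected mask
  m3 <- init_model(2, 1, c("a", "b"), NULL, seed = 1)
  expect_true(all(m3$mask))
})

test_that("stage sampling matches exhaustive enumeration on a two-slice toy", {
  m <- toy2_model()
  h <- patient_history("p", 0:1, list(1L, c(1L, 2L)))
  act <- matrix(c(FALSE, TRUE), 2, 1)   # complication onsets at slice 2
  P <- stage_transition_matrix(m$Q, 1)
  lik <- function(s) {
    0.5 * P[s[1], s[2]] * (1 - m$pi_onset[s[1], 1]) * m$h_onset[s[2], 1]
  }
  seqs <- list(c(1, 1), c(1, 2), c(2, 2))
  exact <- vapply(seqs, lik, 0); exact <- exact / sum(exact)
  set.seed(31)
  draws <- replicate(8000, paste(sample_stages(h, act, m), collapse = ""))
  emp <- as.numeric(table(factor(draws, c("11", "12", "22")))) / 8000
  expect_lt(max(abs(emp - exact)), 0.025)
  ## every draw is nondecreasing
  expect_false(any(draws == "21"))
})

test_that("deterministic emissions pin the stage sequence", {
  m <- toy2_model()
  m$pi_onset[, 1] <- c(0, 1)   # active at slice 1 only possible in stage 2
  h <- patient_history("p", 0:1, list(integer(0), integer(0)))
  act <- matrix(c(TRUE, TRUE), 2, 1)
  set.seed(5)
  for (r in 1:20) expect_equal(sample_stages(h, act, m), c(2L, 2L))
})

test_that("onset-time sampling matches enumeration and honors hard evidence", {
  m <- toy2_model()
  h <- patient_history("p", 0:1, list(1L, c(1L, 2L)))
  stages <- c(1L, 2L)
  prior <- c(m$pi_onset[1, 1],
             (1 - m$pi_onset[1, 1]) * m$h_onset[2, 1],
             (1 - m$pi_onset[1, 1]) * (1 - m$h_onset[2, 1]))
  obs_l <- function(tau) {
    l <- 1
    for (t in 1:2) {
      act <- tau <= t
      p <- vapply(1:2, function(n) noisy_or_prob(act, n, m), 0)
      pos <- c(TRUE, t == 2)
      l <- l * prod(ifelse(pos, p, 1 - p))
    }
    l
  }
  exact <- prior * vapply(1:3, obs_l, 0); exact <- exact / sum(exact)
  set.seed(41)
  draws <- replicate(8000, {
    r <- sample_complications(h, stages, matrix(FALSE, 2, 1), m)
    if (is.na(r$onset_slice[1])) 3L else r$onset_slice[1]
  })
  emp <- as.numeric(table(factor(draws, 1:3))) / 8000
  expect_lt(max(abs(emp - exact)), 0.025)

  ## with no evidence coupling (A = 0, findings absent) the posterior is the prior chain
  m0 <- toy2_model(); m0$A[] <- 0
  h0 <- patient_history("p", 0:1, list(integer(0), integer(0)))
  pr0 <- c(m0$pi_onset[1, 1],
           (1 - m0$pi_onset[1, 1]) * m0$h_onset[2, 1],
           (1 - m0$pi_onset[1, 1]) * (1 - m0$h_onset[2, 1]))
  ## findings absent still informs through the leak; silence that too
  m0$leak[] <- 0
  draws0 <- replicate(8000, {
    r <- sample_complications(h0, stages, matrix(FALSE, 2, 1), m0)
    if (is.na(r$onset_slice[1])) 3L else r$onset_slice[1]
  })
  emp0 <- as.numeric(table(factor(draws0, 1:3))) / 8000
  expect_lt(max(abs(emp0 - pr0)), 0.025)

  ## an anchored code with zero leak forces its anchor complication on
  anchors <- anchor_set(list(C1 = "F1"))
  ma <- rand_model(K = 2, W = 2, N = 3, anchors = anchors)
  ma$leak[1] <- 0
  ha <- patient_history("p", 0:1, list(integer(0), 1L))
  set.seed(3)
  for (r in 1:10) {
    out <- sample_complications(ha, c(1L, 1L), matrix(FALSE, 2, 2), ma)
    expect_true(out$active[2, 1])
  }
})

test_that("attribution sampling is the exact noisy-or augmentation", {
  ## only the leak can explain the finding
  m <- rand_model(K = 2, W = 1, N = 2)
  h <- patient_history("p", 0:1, list(1L, integer(0)))
  at <- sample_attributions(h, matrix(FALSE, 2, 1), m)
  expect_identical(at[[1]][[1]]$fired, 0L)
  expect_identical(at[[1]][[1]]$attributed, 0L)

  ## two equal-strength parents, zero leak: symmetric single attribution
  m2 <- rand_model(K = 2, W = 2, N = 2)
  m2$A[, 1] <- 0.5; m2$leak[1] <- 0
  set.seed(51)
  att <- replicate(6000, {
    a <- sample_attributions(h, matrix(TRUE, 2, 2), m2)
    a[[1]][[1]]$attributed
  })
  expect_lt(abs(mean(att == 1) - 0.5), 0.03)
  expect_false(any(att == 0))

  ## firing-vector distribution matches enumeration for A=(0.6,0.3), leak 0.1
  m3 <- rand_model(K = 2, W = 2, N = 2)
  m3$A[, 1] <- c(0.6, 0.3); m3$leak[1] <- 0.1
  p <- c(0.6, 0.3, 0.1)
  pats <- as.matrix(expand.grid(0:1, 0:1, 0:1))[-1, ]
  exact <- apply(pats, 1, function(y) prod(ifelse(y == 1, p, 1 - p)))
  exact <- exact / sum(exact)
  lab <- apply(pats, 1, function(y)
    paste(sort(c(if (y[1]) 1L, if (y[2]) 2L, if (y[3]) 0L)), collapse = ","))
  set.seed(52)
  emp <- table(replicate(8000, {
    a <- sample_attributions(h, matrix(TRUE, 2, 2), m3)
    paste(sort(a[[1]][[1]]$fired), collapse = ",")
  })) / 8000
  expect_lt(max(abs(as.numeric(emp[lab]) - exact)), 0.03)

  ## impossible positive observation errors
  m4 <- rand_model(K = 2, W = 1, N = 2)
  m4$A[] <- 0; m4$leak[] <- 0
  expect_error(sample_attributions(h, matrix(FALSE, 2, 1), m4),
               "zero total activation")
})

test_that("the M-step reproduces parameters from their expected counts", {
  set.seed(61)
  m <- rand_model(K = 3, W = 2, N = 4)
  ctrl <- fit_control()
  big <- 1e6
  st <- prognet:::empty_stats(3, 2, 4)
  st$n_sweeps <- 1
  st$A_expose[] <- big; st$A_succ <- m$A * big
  st$leak_expose <- big; st$leak_succ <- m$leak * big
  st$pi_n[] <- big; st$pi_succ <- m$pi_onset * big
  st$h_succ <- m$h_onset * big
  st$h_years <- (1 - m$h_onset) * big
  st$Q_time[] <- big
  st$Q_jumps <- m$Q * big; st$Q_jumps[st$Q_jumps < 0] <- 0
  out <- m_step(st, m, ctrl)
  expect_equal(out$A, m$A, tolerance = 1e-4)
  expect_equal(out$leak, m$leak, tolerance = 1e-4)
  expect_equal(out$h_onset, m$h_onset, tolerance = 1e-4)
  expect_equal(out$Q, m$Q, tolerance = 1e-4)

  ## with no observations, Beta(1,1) smoothing returns the prior mean
  st0 <- prognet:::empty_stats(3, 2, 4); st0$n_sweeps <- 1
  out0 <- m_step(st0, m, ctrl)
  expect_true(all(out0$A[m$mask] == 0.5))
  expect_true(all(out0$leak == 0.5))
})

test_that("fitting is reproducible, monotone, and valid on degenerate input", {
  set.seed(71)
  fm <- make_fixture_model()
  co <- generate_cohort(fm, 25, seed = 5, horizon_years = 8, residence_years = Inf)
  hs <- cohort_histories(co, keep_empty = TRUE)
  ctrl <- fit_control(n_em_iterations = 4, n_gibbs_sweeps = 3, burn_in = 1,
                      seed = 9, initial_stage_prior = c(1, 0, 0))
  f1 <- fit_progression(hs, 3, 2, fm$vocabulary, anchors = fm$anchors, control = ctrl)
  f2 <- fit_progression(hs, 3, 2, fm$vocabulary, anchors = fm$anchors, control = ctrl)
  expect_identical(f1$diagnostics[c("iteration", "loglik", "loglik_se")],
                   f2$diagnostics[c("iteration", "loglik", "loglik_se")])
  expect_identical(f1$model$A, f2$model$A)
  expect_identical(f1$model$Q, f2$model$Q)
  expect_true(all(f1$diagnostics$monotone_ok))
  expect_length(validate_model(f1$model), 0)
  ## structural anchor invariant: mask untouched by fitting
  expect_identical(f1$model$mask, fm$mask)

  ## single patient, two slices
  single <- list(patient_history("solo", 0:1, list(1L, c(1L, 3L))))
  fs <- fit_progression(single, 3, 2, fm$vocabulary, anchors = fm$anchors,
                        control = fit_control(n_em_iterations = 2,
                                              n_gibbs_sweeps = 2, burn_in = 0,
                                              seed = 2))
  expect_length(validate_model(fs$model), 0)

  expect_error(fit_progression(list(), 3, 2, fm$vocabulary), "no patient histories")
})

test_that("the smoothed complete-data log-likelihood climbs during EM", {
  fm <- make_fixture_model()
  co <- generate_cohort(fm, 60, seed = 15, horizon_years = 8, residence_years = Inf)
  hs <- cohort_histories(co, keep_empty = TRUE)
  ctrl <- fit_control(n_em_iterations = 8, n_gibbs_sweeps = 4, burn_in = 1,
                      seed = 19, initial_stage_prior = c(1, 0, 0))
  f <- fit_progression(hs, 3, 2, fm$vocabulary, anchors = fm$anchors, control = ctrl)
  d <- f$diagnostics
  ## the trend is upward, and no single drop gives back more than a
  ## quarter of the total improvement (Monte Carlo EM jitters: the
  ## parameter update injects noise beyond the within-iteration sweep SE)
  climb <- d$loglik[nrow(d)] - d$loglik[1]
  expect_gt(climb, 0)
  expect_true(all(diff(d$loglik) > -0.25 * climb))
})
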