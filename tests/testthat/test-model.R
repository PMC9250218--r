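test_that("the parameter-counting formula matches its worked values", {
  expect_identical(count_parameters(5, 10, 1000, 0), 10125L)
  expect_identical(count_parameters(5, 12, 88, 0), 25L + 120L + 1056L)
  ## pruning removes W-1 links per anchored code
  expect_identical(count_parameters(2, 3, 5, anchored_codes = 4),
                   4L + 12L + 15L - 8L)
  expect_identical(count_parameters(3, 2, 6, 2),
                   count_parameters(3, 2, 6, 0) - 2L * (2L - 1L))
  ## forward-only free count replaces K^2 by K(K-1)/2
  expect_identical(count_parameters(5, 10, 1000, 0, free = TRUE),
                   10125L - 25L + 10L)
  expect_error(count_parameters(-1, 2, 3))
  expect_error(count_parameters(3, 2, 3, anchored_codes = 4))
})

test_that("anchor pruning keeps one parent per anchored code and all parents elsewhere", {
  vocab <- prognet:::new_vocabulary(paste0("F", 1:5))
  anchors <- anchor_set(list(C1 = "F2", C2 = c("F1", "F5"), C3 = "F3"))
  mask <- make_connectivity_mask(anchors, vocab, W = 3)
  expect_equal(unname(colSums(mask)), c(1, 1, 1, 3, 1))
  expect_equal(sum(mask), 7)              # 7 of 15 links survive
  expect_true(mask[2, 1] && mask[1, 2] && mask[3, 3] && mask[2, 5])

  ## no anchors: fully connected
  expect_true(all(make_connectivity_mask(anchor_set(list(character(0))), vocab, 3)))

  ## every finding anchored: exactly one link per column
  all_anch <- anchor_set(list(c("F1", "F2"), c("F3", "F4", "F5")))
  expect_equal(sum(make_connectivity_mask(all_anch, vocab, 2)), 5)

  ## a code may not anchor two complications
  expect_error(anchor_set(list("F1", "F1")), "at most one")
  ## more anchor groups than complications
  expect_error(make_connectivity_mask(anchors, vocab, W = 2), "more complications")
})

test_that("noisy-or activation probabilities follow the closed form and are monotone", {
  m <- rand_model(K = 2, W = 2, N = 3)
  m$leak <- c(0.1, 0, 0.3)
  m$A[, 1] <- c(0.5, 0.8)
  expect_equal(noisy_or_prob(c(FALSE, FALSE), 1, m), 0.1)
  expect_equal(noisy_or_prob(c(TRUE, FALSE), 1, m), 1 - 0.9 * 0.5)
  m$A[2, 1] <- 1
  expect_equal(noisy_or_prob(c(TRUE, TRUE), 1, m), 1)
  ## monotone in the active set and in activation probabilities
  set.seed(4)
  for (r in 1:20) {
    mm <- rand_model(K = 2, W = 3, N = 4)
    n <- sample(4, 1)
    act <- stats::runif(3) < 0.5
    act2 <- act | (stats::runif(3) < 0.5)
    expect_gte(noisy_or_prob(act2, n, mm) + 1e-12, noisy_or_prob(act, n, mm))
    mm2 <- mm; mm2$A <- pmin(mm$A + 0.1, 1)
    expect_gte(noisy_or_prob(act, n, mm2) + 1e-12, noisy_or_prob(act, n, mm))
  }
})

test_that("observation log-likelihood handles impossible and hand-computed cases", {
  m <- rand_model(K = 2, W = 1, N = 2)
  m$leak <- c(0, 0)
  expect_equal(observation_log_likelihood(integer(0), FALSE, m), 0)
  expect_identical(observation_log_likelihood(1L, FALSE, m), -Inf)
  ## two-finding toy against a direct product
  m$leak <- c(0.1, 0.2); m$A[1, ] <- c(0.6, 0.3)
  p <- c(1 - 0.9 * 0.4, 1 - 0.8 * 0.7)
  expect_equal(observation_log_likelihood(1L, TRUE, m),
               log(p[1]) + log(1 - p[2]))
})

test_that("interval transition matrices agree with series and Chapman-Kolmogorov", {
  ## zero generator: identity
  expect_equal(stage_transition_matrix(matrix(0, 3, 3), 2), diag(3))
  ## two-stage closed form 1 - exp(-lambda dt)
  Q <- matrix(c(-log(2), log(2), 0, 0), 2, 2, byrow = TRUE)
  P <- stage_transition_matrix(Q, 1)
  expect_equal(P[1, 2], 0.5, tolerance = 1e-12)
  ## independent truncated Taylor-series oracle
  set.seed(11)
  for (r in 1:10) {
    m <- rand_model(K = 4, W = 1, N = 2)
    dt <- stats::runif(1, 0.3, 3)
    S <- diag(4); term <- diag(4)
    for (n in 1:60) { term <- term %*% (m$Q * dt) / n; S <- S + term }
    P1 <- stage_transition_matrix(m$Q, dt)
    expect_equal(P1, S, tolerance = 1e-9)
    expect_equal(rowSums(P1), rep(1, 4), tolerance = 1e-10)
    expect_true(all(P1[lower.tri(P1)] == 0))
    ## Chapman-Kolmogorov
    dt2 <- stats::runif(1, 0.2, 2)
    expect_equal(stage_transition_matrix(m$Q, dt + dt2),
                 P1 %*% stage_transition_matrix(m$Q, dt2), tolerance = 1e-8)
  }
  expect_error(stage_transition_matrix(Q, 0), "positive")
})

test_that("interval onset probabilities follow the per-year hazard closed form", {
  m <- rand_model(K = 3, W = 2, N = 2)
  m$h_onset[2, 1] <- 0
  expect_equal(onset_prob(1, 2, 5, m), 0)
  m$h_onset[2, 1] <- 1
  expect_equal(onset_prob(1, 2, 3, m), 1)
  m$h_onset[3, 2] <- 0.19
  expect_equal(onset_prob(2, 3, 2, m), 1 - 0.81^2)
  m$pi_onset[1, 1] <- 0.37
  expect_equal(onset_prob(1, 1, 1, m, first = TRUE), 0.37)
  expect_error(onset_prob(1, 2, -1, m))
})

test_that("model validation reports each violated invariant by name", {
  m <- rand_model(K = 3, W = 2, N = 4)
  expect_length(validate_model(m), 0)
  bad <- m; bad$Q[1, 2] <- -0.1
  expect_true(any(grepl("Q", validate_model(bad))))
  bad2 <- unclass(m); bad2$mask[1, 2] <- FALSE; bad2$mask[2, 2] <- TRUE
  bad2$A[1, 2] <- 0.4; bad2$A[2, 2] <- 0
  viol <- validate_model(bad2)
  expect_true(any(grepl("A\\[1,2\\]", viol)))
})

test_that("model JSON serialization round-trips at full precision", {
  dir <- withr::local_tempdir()
  set.seed(21)
  anchors <- anchor_set(list(C1 = "F1", C2 = "F3"))
  m <- rand_model(K = 3, W = 2, N = 4, anchors = anchors)
  path <- file.path(dir, "model.json")
  write_model(m, path)
  m2 <- read_model(path)
  for (f in c("Q", "pi_onset", "h_onset", "A", "leak")) {
    expect_identical(unname(m[[f]]), unname(m2[[f]]))
  }
  expect_equal(as.character(m2$vocabulary), as.character(m$vocabulary))
  expect_equal(unname(m2$mask), unname(m$mask))
})
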