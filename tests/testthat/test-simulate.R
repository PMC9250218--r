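test_that("generation is reproducible and structurally sound", {
  fm <- make_fixture_model()
  set.seed(1); p1 <- generate_patient(fm)
  set.seed(1); p2 <- generate_patient(fm)
  expect_identical(p1, p2)

  co1 <- generate_cohort(fm, 20, seed = 3)
  co2 <- generate_cohort(fm, 20, seed = 3)
  expect_identical(co1, co2)

  for (p in co1) {
    ent <- p$entry_time[!is.na(p$entry_time)]
    expect_true(ent[1] == 0 && !is.unsorted(ent, strictly = TRUE))
    expect_true(all(p$stage == cummax(p$stage)))
    ## onsets fall inside the occupancy of their generating stage
    for (w in which(!is.na(p$onset_year))) {
      expect_lte(p$onset_year[w], p$end_time)
    }
    expect_true(all(p$year == seq_along(p$year) - 1))
  }
})

test_that("holding times follow the intensity matrix closed form", {
  fm <- make_fixture_model()
  co <- generate_cohort(fm, 3000, seed = 7, horizon_years = 200)
  hold1 <- vapply(co, function(p) {
    ex <- stage_interval(p, 1)
    if (is.null(ex)) NA_real_ else ex[2] - ex[1]
  }, 0)
  mu <- mean(hold1, na.rm = TRUE)
  truth <- 1 / 0.32
  se <- truth / sqrt(length(hold1))      # exponential: sd = mean
  expect_lt(abs(mu - truth), 3 * se)

  ## two disjoint seed streams are statistically indistinguishable
  co2 <- generate_cohort(fm, 1500, seed = 104729, horizon_years = 200)
  hold2 <- vapply(co2, function(p) stage_interval(p, 1)[2], 0)
  pval <- stats::t.test(hold1, hold2)$p.value
  expect_gt(pval, 0.01)
})

test_that("zero hazards and leaks give empty encounters but a progressing stage path", {
  fm <- make_fixture_model()
  fm$h_onset[] <- 0; fm$pi_onset[] <- 0; fm$leak[] <- 0
  set.seed(9)
  p <- generate_patient(fm, horizon_years = 50)
  expect_true(all(lengths(p$findings) == 0))
  expect_true(any(!is.na(p$entry_time[-1])))
})

test_that("observed finding frequencies match the noisy-or given the active set", {
  fm <- make_fixture_model()
  fm$pi_onset[1, ] <- 1                       # both complications active from year 0
  co <- generate_cohort(fm, 400, seed = 11, horizon_years = 6, residence_years = Inf)
  counts <- integer(fm$N); n_enc <- 0
  for (p in co) {
    for (t in seq_along(p$year)) {
      counts[p$findings[[t]]] <- counts[p$findings[[t]]] + 1L
      n_enc <- n_enc + 1
    }
  }
  expected <- prognet:::noisy_or_vec(c(TRUE, TRUE), fm)
  emp <- counts / n_enc
  se <- sqrt(expected * (1 - expected) / n_enc)
  expect_true(all(abs(emp - expected) < 4 * se + 1e-9))
})

test_that("the fixture model is valid, sparse like the study data, and serializable", {
  fm <- make_fixture_model()
  expect_length(validate_model(fm), 0)
  dir <- withr::local_tempdir()
  write_model(fm, file.path(dir, "fm.json"))
  fm2 <- read_model(file.path(dir, "fm.json"))
  expect_identical(unname(fm$A), unname(fm2$A))
  expect_identical(fm$Q, fm2$Q)

  co <- generate_cohort(fm, 300, seed = 13, horizon_years = 25)
  mpos <- mean(unlist(lapply(co, function(p) lengths(p$findings))))
  expect_gte(mpos, 1); expect_lte(mpos, 3)
})

test_that("cohorts round-trip through serialization and the ingest pipeline", {
  fm <- make_fixture_model()
  co <- generate_cohort(fm, 25, seed = 17, horizon_years = 15)
  dir <- withr::local_tempdir()

  cpath <- file.path(dir, "cohort.jsonl")
  write_cohort(co, cpath)
  co2 <- read_cohort(cpath)
  expect_equal(length(co2), length(co))
  expect_equal(co2[[5]]$entry_time, co[[5]]$entry_time)
  expect_equal(co2[[5]]$onset_year, co[[5]]$onset_year)
  expect_equal(co2[[5]]$findings, co[[5]]$findings)
  expect_equal(attr(co2, "K"), 3)

  ## encounters exported as raw events reproduce the preprocessed histories
  epath <- file.path(dir, "events.csv")
  write_cohort_events(co, fm, epath)
  ev <- read_events(epath)
  hs_file <- build_time_slices(ev, fm$vocabulary)
  hs_direct <- cohort_histories(co, keep_empty = FALSE)
  expect_equal(length(hs_file), length(hs_direct))
  for (i in seq_along(hs_file)) {
    expect_equal(hs_file[[i]]$year, hs_direct[[i]]$year)
    expect_equal(hs_file[[i]]$findings, hs_direct[[i]]$findings)
  }
})

test_that("simulate method on a fitted object delegates to the generator", {
  fm <- make_fixture_model()
  fake_fit <- structure(list(model = fm), class = "progression_fit")
  co <- simulate(fake_fit, nsim = 5, seed = 2)
  expect_s3_class(co, "synthetic_cohort")
  expect_length(co, 5)
  expect_identical(co, generate_cohort(fm, 5, seed = 2))
})
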