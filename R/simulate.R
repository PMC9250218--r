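## Synthetic-patient generation from a progression model, and the small
## fixture model used for parameter-recovery experiments.

#' Generate one synthetic patient
#'
#' Samples a full latent trajectory and yearly encounters from the
#' generative model.  The patient starts at time 0 in stage I.  Stage
#' holding times are exponential with rate \code{|Q[k,k]|} and the next
#' stage is drawn proportional to \code{Q[k, j]}; complication onsets
#' within a stage follow the continuous-time equivalent of the per-year
#' onset probability (hazard \code{-log(1 - h_onset[k, w])}); encounters
#' are observed at integer years through the noisy-or layer.  Generation
#' stops one residence year after entry into the absorbing stage \code{K}
#' (configurable) or at \code{horizon_years}, whichever is earlier.
#'
#' @param model a \code{progression_model}.
#' @param horizon_years maximum follow-up in years (default 60, generously
#'   beyond a typical complete path so truncation is negligible).
#' @param residence_years observation years after entering stage K
#'   (default 1).
#' @return object of class \code{synthetic_patient} with fields
#'   \code{entry_time} (length-K stage entry years, \code{NA} if a stage is
#'   never visited), \code{onset_year} (length-W complication onset years,
#'   \code{NA} if never), \code{end_time}, and yearly encounters
#'   (\code{year}, \code{stage}, \code{findings}).
#' @export
generate_patient <- function(model, horizon_years = 60, residence_years = 1) {
  stopifnot(horizon_years > 0)
  K <- model$K; W <- model$W
  ## stage path
  entry <- rep(NA_real_, K)
  entry[1] <- 0
  k <- 1L; t <- 0
  while (k < K) {
    rate <- -model$Q[k, k]
    if (rate <= 0) { t <- horizon_years; break }   # dead-end stage: truncate
    hold <- stats::rexp(1, rate)
    if (t + hold >= horizon_years) { t <- horizon_years; break }
    t <- t + hold
    rates <- model$Q[k, (k + 1):K]
    k <- k + if (length(rates) == 1) 1L else
      sample.int(length(rates), 1, prob = rates)
    entry[k] <- t
  }
  end_time <- if (k == K) min(entry[K] + residence_years, horizon_years)
              else horizon_years
  visited <- which(!is.na(entry))
  exit <- c(entry[visited][-1], end_time)

  ## complication onsets
  onset <- rep(NA_real_, W)
  for (w in seq_len(W)) {
    if (stats::runif(1) < model$pi_onset[1, w]) { onset[w] <- 0; next }
    for (i in seq_along(visited)) {
      kk <- visited[i]
      t0 <- entry[kk]; t1 <- exit[i]
      h <- model$h_onset[kk, w]
      if (h <= 0) next
      lam <- -log1p(-min(h, 1 - 1e-15))
      e <- stats::rexp(1, lam)
      if (t0 + e < t1) { onset[w] <- t0 + e; break }
    }
  }

  ## yearly encounters
  years <- 0:floor(end_time)
  stage_at <- vapply(years, function(y) max(which(!is.na(entry) & entry <= y)), 0L)
  findings <- vector("list", length(years))
  for (i in seq_along(years)) {
    active <- !is.na(onset) & onset <= years[i]
    p <- noisy_or_vec(active, model)
    findings[[i]] <- which(stats::runif(model$N) < p)
  }
  structure(list(entry_time = entry, onset_year = onset, end_time = end_time,
                 year = years, stage = stage_at, findings = findings),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  vis <- which(!is.na(x$entry_time))
  cat("Synthetic patient: stages",
      paste(sprintf("%d@%.1fy", vis, x$entry_time[vis]), collapse = " -> "),
      sprintf("(end %.1fy)\n", x$end_time))
  on <- which(!is.na(x$onset_year))
  if (length(on)) cat("  complication onsets:",
                      paste(sprintf("w%d@%.1fy", on, x$onset_year[on]),
                            collapse = ", "), "\n")
  cat(" ", length(x$year), "encounters,",
      sum(lengths(x$findings)), "positive observations\n")
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' @param model a \code{progression_model}.
#' @param n_patients cohort size (the study setting is 5000).
#' @param seed integer seed for the single random stream driving all
#'   patients.
#' @param horizon_years,residence_years passed to [generate_patient()].
#' @return list of \code{synthetic_patient} objects, class
#'   \code{synthetic_cohort}.
#' @export
generate_cohort <- function(model, n_patients, seed = 1, horizon_years = 60,
                            residence_years = 1) {
  stopifnot(n_patients >= 1)
  set.seed(seed)
  out <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    out[[i]] <- generate_patient(model, horizon_years, residence_years)
  }
  structure(out, class = "synthetic_cohort", K = model$K, W = model$W)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  K <- attr(x, "K")
  reached <- mean(vapply(x, function(p) !is.na(p$entry_time[K]), TRUE))
  cat("Synthetic cohort:", length(x), "patients;",
      sprintf("%.1f%% reach stage %d\n", 100 * reached, K))
  invisible(x)
}

#' Occupancy interval of a stage for one synthetic patient
#'
#' @param patient a \code{synthetic_patient}.
#' @param k stage index.
#' @return \code{c(entry, exit)} in years, or \code{NULL} if the stage is
#'   never occupied.
#' @export
stage_interval <- function(patient, k) {
  if (is.na(patient$entry_time[k])) return(NULL)
  visited <- which(!is.na(patient$entry_time))
  i <- match(k, visited)
  exit <- if (i < length(visited)) patient$entry_time[visited[i + 1]]
          else patient$end_time
  c(patient$entry_time[k], exit)
}

#' Convert synthetic encounters to fit-ready patient histories
#'
#' By default drops encounters with no positive finding, re-anchors year 0
#' at the first non-empty encounter, and excludes patients with fewer than
#' two retained encounters — exactly what preprocessing of real encounter
#' records produces.  With \code{keep_empty = TRUE} every yearly encounter
#' is kept (complete data, as only a simulator can provide), which avoids
#' the informative-missingness approximation when testing parameter
#' recovery.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param keep_empty keep encounters with no positive finding?
#' @return list of \code{patient_history} objects.
#' @export
cohort_histories <- function(cohort, keep_empty = FALSE) {
  out <- list()
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    keep <- if (keep_empty) rep(TRUE, length(p$year)) else lengths(p$findings) > 0
    if (sum(keep) < 2) next
    yr <- p$year[keep]
    out[[length(out) + 1]] <- patient_history(
      sprintf("S%05d", i), yr - yr[1], p$findings[keep])
  }
  out
}

#' Export synthetic encounters in the raw-event input format
#'
#' Writes one row per (patient, year, positive code), with dates laid out
#' from a fixed origin so the cohort round-trips through [read_events()]
#' and [build_time_slices()].
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param model the generating model (for the code vocabulary).
#' @param path output CSV path.
#' @param origin origin date for year 0.
#' @export
write_cohort_events <- function(cohort, model, path, origin = as.Date("2000-01-01")) {
  rows <- list()
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    for (j in seq_along(p$year)) {
      f <- p$findings[[j]]
      if (!length(f)) next
      ## 366-day spacing: exactly linear in the year index, so re-binning
      ## by floor(days/365.25) recovers the year offsets no matter which
      ## encounter anchors a patient's first event
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = sprintf("S%05d", i),
        event_date = format(origin + 366 * p$year[j], "%Y-%m-%d"),
        icd10 = as.character(model$vocabulary)[f],
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), event_date = character(),
               icd10 = character())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a synthetic cohort as line-delimited JSON
#'
#' One record per patient carrying the full latent trajectory (stage entry
#' times, complication onset years, end of follow-up) and the yearly
#' encounters.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(K = attr(cohort, "K"),
                                   W = attr(cohort, "W"),
                                   n = length(cohort)),
                              auto_unbox = TRUE), con)
  for (p in cohort) {
    writeLines(jsonlite::toJSON(unclass(p), auto_unbox = FALSE, digits = I(17),
                                na = "null", null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- jsonlite::fromJSON(lines[1])
  pats <- lapply(lines[-1], function(l) {
    r <- jsonlite::fromJSON(l, simplifyMatrix = FALSE)
    structure(list(entry_time = as.numeric(r$entry_time),
                   onset_year = as.numeric(r$onset_year),
                   end_time = as.numeric(r$end_time),
                   year = as.integer(r$year),
                   stage = as.integer(r$stage),
                   findings = lapply(r$findings, as.integer)),
              class = "synthetic_patient")
  })
  structure(pats, class = "synthetic_cohort", K = hdr$K, W = hdr$W)
}

#' Small ground-truth fixture model
#'
#' A known (K=3, W=2, N=6) model that emulates the shape of sparse yearly
#' encounter data: roughly two positive codes per encounter, forward-only
#' stages with mean holding times of a few years, and one anchored code per
#' complication.  Anchored activation probabilities and leaks are fixed;
#' the unanchored activation entries are drawn reproducibly from the given
#' seed.
#'
#' @param K,W,N dimensions (defaults 3, 2, 6).
#' @param seed seed for the reproducible unanchored activation draws.
#' @return a valid \code{progression_model} with attribute
#'   \code{"anchored_values"} listing the fixed anchored links.
#' @export
make_fixture_model <- function(K = 3, W = 2, N = 6, seed = 42) {
  stopifnot(K == 3, W == 2, N == 6)  # the fixture is this specific shape
  vocab <- c("E11.2", "E11.6", "H26.9", "I10", "I83", "N18")
  anchors <- anchor_set(list(Nephropathy = "E11.2", Ophthalmopathy = "H26.9"))
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- 0.30; Q[1, 3] <- 0.02; Q[2, 3] <- 0.25
  diag(Q) <- -rowSums(Q)
  pi_onset <- rbind(c(0.05, 0.04), c(0.35, 0.25), c(0.60, 0.50))
  h_onset  <- rbind(c(0.06, 0.05), c(0.22, 0.18), c(0.40, 0.30))
  mask <- make_connectivity_mask(anchors, new_vocabulary(vocab), W)
  set.seed(seed)
  A <- matrix(stats::runif(W * N, 0.25, 0.6), W, N)
  A[!mask] <- 0
  A[1, 1] <- 0.80   # anchored: nephropathy -> E11.2
  A[2, 3] <- 0.75   # anchored: ophthalmopathy -> H26.9
  leak <- c(0.05, 0.20, 0.05, 0.30, 0.15, 0.20)
  m <- progression_model(K, W, vocab, Q, pi_onset, h_onset, A, leak,
                         mask = mask, anchors = anchors)
  attr(m, "anchored_values") <- c("1->E11.2" = 0.80, "2->H26.9" = 0.75)
  m
}
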