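## Cohort-level summaries of generated trajectories: stage holding times,
## complication prevalence by stage, and the retrospective
## "later-to-earlier" complication statistics conditioned on the last
## stage.

#' Percentage rounded half-up to one decimal
#'
#' \code{100 * numerator / denominator}, rounded half-up to one decimal —
#' the printed precision of the retrospective tables.
#'
#' @param numerator,denominator counts; \code{denominator} must be > 0.
#' @return numeric percentage(s) with one decimal.
#' @export
round_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  p <- 100 * numerator / denominator
  floor(p * 10 + 0.5 + 1e-9) / 10
}

## Was complication w ever active while the patient occupied stage s?
## (Activity is irreversible, so this is: stage occupied, and onset before
## the stage's exit time.)
active_during <- function(patient, s) {
  iv <- stage_interval(patient, s)
  if (is.null(iv)) return(rep(FALSE, length(patient$onset_year)))
  !is.na(patient$onset_year) & patient$onset_year < iv[2]
}

#' Stage-level cohort summary
#'
#' Mean stage entry year, mean completed holding time, and per-complication
#' prevalence while in each stage, averaged over the patients that occupy
#' the stage.  Holding times are averaged over completed occupancies only
#' (the absorbing last stage, and stays truncated by the horizon, are
#' excluded).
#'
#' @param cohort a \code{synthetic_cohort}.
#' @return object of class \code{stage_summary}: data frame with one row
#'   per stage plus a \code{prevalence} attribute (K x W matrix).
#' @export
stage_summary <- function(cohort) {
  if (length(cohort) == 0) stop("empty cohort")
  K <- attr(cohort, "K"); W <- attr(cohort, "W")
  n_occ <- integer(K); entry_sum <- numeric(K)
  hold_sum <- numeric(K); hold_n <- integer(K)
  prev <- matrix(0, K, W)
  for (p in cohort) {
    visited <- which(!is.na(p$entry_time))
    for (i in seq_along(visited)) {
      s <- visited[i]
      n_occ[s] <- n_occ[s] + 1
      entry_sum[s] <- entry_sum[s] + p$entry_time[s]
      if (i < length(visited)) {   # completed occupancy
        hold_sum[s] <- hold_sum[s] + p$entry_time[visited[i + 1]] - p$entry_time[s]
        hold_n[s] <- hold_n[s] + 1
      }
      prev[s, ] <- prev[s, ] + active_during(p, s)
    }
  }
  out <- data.frame(
    stage = seq_len(K),
    n_patients = n_occ,
    mean_entry_year = ifelse(n_occ > 0, entry_sum / n_occ, NA_real_),
    mean_holding_years = ifelse(hold_n > 0, hold_sum / hold_n, NA_real_),
    n_completed = hold_n)
  attr(out, "prevalence") <- prev / pmax(n_occ, 1)
  class(out) <- c("stage_summary", "data.frame")
  out
}

#' @export
print.stage_summary <- function(x, ...) {
  cat("Stage summary over", max(x$n_patients), "patients\n")
  print.data.frame(cbind(x[, c("stage", "n_patients")],
                         round(x[, c("mean_entry_year", "mean_holding_years")], 2)),
                   row.names = FALSE)
  cat("\nComplication prevalence while in stage (rows = stages):\n")
  print(round(attr(x, "prevalence"), 3))
  invisible(x)
}

#' @export
plot.stage_summary <- function(x, ...) {
  prev <- attr(x, "prevalence")
  graphics::matplot(seq_len(nrow(prev)), prev, type = "b", pch = 16,
                    xlab = "stage", ylab = "complication prevalence",
                    ylim = c(0, 1), ...)
  invisible(x)
}

## Base group and retro percentages shared by both tables.  pattern is an
## integer vector of complication indices; a patient "has" the pattern at
## stage s iff all members are active while in s.
pattern_at_stage <- function(cohort, pattern, s) {
  vapply(cohort, function(p) all(active_during(p, s)[pattern]), TRUE)
}

#' Single-complication retrospective table
#'
#' For each complication: the number and percentage of generated patients
#' with the complication active while in the last stage (stage V for
#' K = 5), and — among that stage-V-positive group — the percentage already
#' active at each earlier stage.  Irreversible activity makes these
#' percentages nonincreasing toward earlier stages.  Percentages are
#' rounded half-up to one decimal; groups with no stage-V-positive patient
#' report \code{NA} retro percentages (undefined, not zero).
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param complication_indices which complications to tabulate (default
#'   all).
#' @return data frame of class \code{retro_table}: one row per
#'   complication with columns \code{n_V}, \code{pct_V}, and per earlier
#'   stage \code{n_to_<s>} / \code{pct_to_<s>}.
#' @export
single_complication_table <- function(cohort,
                                      complication_indices = seq_len(attr(cohort, "W"))) {
  if (length(cohort) == 0) stop("empty cohort")
  K <- attr(cohort, "K")
  rows <- lapply(complication_indices, function(w) {
    retro_row(cohort, w, K)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(complication = complication_indices), out)
  class(out) <- c("retro_table", "data.frame")
  attr(out, "n_cohort") <- length(cohort)
  out
}

retro_row <- function(cohort, pattern, K) {
  base <- pattern_at_stage(cohort, pattern, K)
  n_V <- sum(base)
  row <- data.frame(n_V = n_V, pct_V = round_percent(n_V, length(cohort)))
  for (s in (K - 1):1) {
    n_s <- if (n_V > 0) sum(pattern_at_stage(cohort[base], pattern, s)) else NA_integer_
    row[[paste0("n_to_", s)]] <- n_s
    row[[paste0("pct_to_", s)]] <-
      if (n_V > 0) round_percent(n_s, n_V) else NA_real_
  }
  row
}

#' @export
print.retro_table <- function(x, ...) {
  cat("Retrospective later-to-earlier statistics",
      sprintf("(base: last-stage positives of %d patients)\n", attr(x, "n_cohort")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Complication-pattern retrospective table
#'
#' For each pattern (a set of two or more complications considered jointly
#' active): the stage-V base group of patients carrying the full pattern in
#' the last stage, and — for every nonempty subset of the pattern — the
#' percentage of that base group already carrying the subset at each
#' earlier stage.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param patterns list of integer vectors (typically of length >= 2; a
#'   length-1 pattern reduces to the corresponding
#'   [single_complication_table()] row).
#' @return list of class \code{retro_pattern_table}: per pattern, a list
#'   with \code{pattern}, \code{n_V}, \code{pct_V} and \code{retro} (a
#'   stage-by-subset matrix of percentages, \code{NA} when the base group
#'   is empty).
#' @export
pattern_table <- function(cohort, patterns) {
  if (length(cohort) == 0) stop("empty cohort")
  K <- attr(cohort, "K"); W <- attr(cohort, "W")
  out <- lapply(patterns, function(pat) {
    pat <- as.integer(pat)
    if (length(pat) < 1) stop("empty pattern")
    if (any(pat < 1 | pat > W)) stop("pattern has unknown complication index")
    subsets <- all_subsets(pat)
    base <- pattern_at_stage(cohort, pat, K)
    n_V <- sum(base)
    retro <- matrix(NA_real_, K - 1, length(subsets),
                    dimnames = list(paste0("V_to_", (K - 1):1),
                                    vapply(subsets, function(s)
                                      paste0("[", paste(s, collapse = ","), "]"), "")))
    if (n_V > 0) {
      grp <- cohort[base]
      for (j in seq_along(subsets)) {
        for (i in seq_len(K - 1)) {
          s <- K - i
          retro[i, j] <- round_percent(sum(pattern_at_stage(grp, subsets[[j]], s)), n_V)
        }
      }
    }
    list(pattern = pat, n_V = n_V,
         pct_V = round_percent(n_V, length(cohort)), retro = retro)
  })
  structure(out, class = "retro_pattern_table", n_cohort = length(cohort))
}

## nonempty subsets ordered by size, then lexicographically.
all_subsets <- function(pat) {
  out <- list()
  for (size in seq_along(pat)) {
    cmb <- utils::combn(sort(pat), size)
    for (j in seq_len(ncol(cmb))) out[[length(out) + 1]] <- cmb[, j]
  }
  out
}

#' @export
print.retro_pattern_table <- function(x, ...) {
  for (el in x) {
    cat(sprintf("Pattern [%s]: %d of %d at last stage (%.1f%%)\n",
                paste(el$pattern, collapse = ","), el$n_V,
                attr(x, "n_cohort"), el$pct_V))
    print(el$retro)
    cat("\n")
  }
  invisible(x)
}

#' Write retrospective tables as CSV
#'
#' @param x a \code{retro_table} or \code{retro_pattern_table}.
#' @param path output file path (pattern tables write one file per pattern,
#'   suffixed \code{_1}, \code{_2}, ...).
#' @return invisibly, the paths actually written.
#' @export
write_retro_csv <- function(x, path) {
  if (inherits(x, "retro_table")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
    return(invisible(path))
  }
  stem <- sub("\\.csv$", "", path)
  paths <- character(0)
  for (i in seq_along(x)) {
    df <- data.frame(stage = rownames(x[[i]]$retro), x[[i]]$retro,
                     check.names = FALSE)
    paths[i] <- sprintf("%s_%d.csv", stem, i)
    utils::write.csv(df, paths[i], row.names = FALSE)
  }
  invisible(paths)
}
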