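## Ingestion of raw encounter-level diagnosis records into model-ready,
## time-sliced patient histories.

#' Read raw encounter events
#'
#' Reads event-level diagnosis records, one ICD-10 code per row, from either
#' a comma-separated file with header columns \code{patient_id, event_date,
#' icd10} or a line-delimited JSON file with the same fields.  Dates must be
#' ISO-8601 (\code{YYYY-MM-DD}); rows whose date does not parse are dropped
#' with a warning rather than aborting the run.
#'
#' @param path path to a \code{.csv} or line-delimited \code{.json}/\code{.jsonl} file.
#' @param format \code{"auto"} (by extension), \code{"csv"} or \code{"jsonl"}.
#' @return a data frame with columns \code{patient_id} (character),
#'   \code{event_date} (\code{Date}) and \code{code} (character).
#' @export
read_events <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    cols <- c("patient_id", "event_date", "icd10")
    if (!all(cols %in% names(raw))) {
      stop("event file must have header columns patient_id,event_date,icd10")
    }
    ev <- data.frame(patient_id = raw$patient_id,
                     event_date = raw$event_date,
                     code = raw$icd10,
                     stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    ev <- data.frame(
      patient_id = vapply(recs, function(r) as.character(r$patient_id), ""),
      event_date = vapply(recs, function(r) as.character(r$event_date), ""),
      code = vapply(recs, function(r) as.character(r$icd10), ""),
      stringsAsFactors = FALSE)
  }
  as_events(ev)
}

#' Coerce a data frame of raw events
#'
#' Validates and normalises event rows: non-empty codes, ISO-8601 dates.
#' Rows with unparseable dates or empty codes are dropped with a warning.
#'
#' @param df data frame with columns \code{patient_id}, \code{event_date}
#'   (character or \code{Date}) and \code{code}.
#' @return normalised event data frame.
#' @export
as_events <- function(df) {
  stopifnot(all(c("patient_id", "event_date", "code") %in% names(df)))
  pid <- as.character(df$patient_id)
  code <- as.character(df$code)
  if (inherits(df$event_date, "Date")) {
    date <- df$event_date
  } else {
    chr <- as.character(df$event_date)
    ok_iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", chr)
    date <- as.Date(rep(NA_character_, length(chr)))
    date[ok_iso] <- as.Date(chr[ok_iso], format = "%Y-%m-%d")
  }
  bad <- is.na(date) | is.na(code) | !nzchar(code) | is.na(pid) | !nzchar(pid)
  if (any(bad)) {
    warning(sum(bad), " event record(s) dropped (unparseable ISO-8601 date or empty field)")
  }
  data.frame(patient_id = pid[!bad], event_date = date[!bad],
             code = code[!bad], stringsAsFactors = FALSE)
}

#' Filter rare diagnosis codes and build the finding vocabulary
#'
#' Counts each code's total number of event occurrences across all patients
#' (before any patient-level exclusion) and retains codes occurring at least
#' \code{min_count} times.  The vocabulary is the sorted (C-locale
#' lexicographic) list of retained codes; its order defines the finding
#' index used everywhere else in the package.
#'
#' @param events event data frame as returned by [read_events()].
#' @param min_count minimum total occurrence count for a code to be kept
#'   (default 30: codes appearing fewer than 30 times are removed).
#' @return a list with elements \code{vocabulary} (character vector of codes,
#'   class \code{finding_vocabulary}) and \code{events} (the retained rows).
#' @export
filter_codes <- function(events, min_count = 30) {
  stopifnot(min_count >= 1)
  if (nrow(events) == 0) {
    return(list(vocabulary = new_vocabulary(character(0)), events = events))
  }
  tab <- table(events$code)
  keep <- sort(names(tab)[tab >= min_count], method = "radix")
  list(vocabulary = new_vocabulary(keep),
       events = events[events$code %in% keep, , drop = FALSE])
}

new_vocabulary <- function(codes) {
  codes <- as.character(codes)
  if (anyDuplicated(codes)) stop("vocabulary codes must be distinct")
  structure(codes, class = "finding_vocabulary")
}

#' @export
print.finding_vocabulary <- function(x, ...) {
  cat("Finding vocabulary:", length(x), "ICD-10 codes\n")
  if (length(x)) cat(" ", paste(utils::head(unclass(x), 10), collapse = ", "),
                     if (length(x) > 10) "..." else "", "\n")
  invisible(x)
}

#' Look up vocabulary indices for codes
#'
#' @param vocabulary a \code{finding_vocabulary}.
#' @param codes character vector of ICD-10 codes.
#' @return integer positions (1-based); \code{NA} for codes not in the
#'   vocabulary.
#' @export
code_index <- function(vocabulary, codes) match(codes, as.character(vocabulary))

#' Construct a time-sliced patient history
#'
#' @param patient_id identifier string.
#' @param year integer vector of slice indices, starting at 0 at the
#'   patient's first retained event and strictly increasing.
#' @param findings list (same length as \code{year}) of integer vectors of
#'   1-based vocabulary indices observed in each slice.
#' @return an object of class \code{patient_history}.
#' @export
patient_history <- function(patient_id, year, findings) {
  year <- as.integer(year)
  stopifnot(length(year) == length(findings),
            length(year) >= 1,
            all(diff(year) > 0), year[1] == 0L)
  findings <- unname(lapply(findings, function(f) sort(unique(as.integer(f)))))
  structure(list(patient_id = as.character(patient_id),
                 year = year, findings = findings),
            class = "patient_history")
}

#' @export
print.patient_history <- function(x, ...) {
  cat("Patient", x$patient_id, "-", length(x$year), "time slices\n")
  for (i in seq_along(x$year)) {
    cat(sprintf("  year %2d: {%s}\n", x$year[i],
                paste(x$findings[[i]], collapse = ",")))
  }
  invisible(x)
}

#' Aggregate events into yearly time slices per patient
#'
#' Events are binned per patient by \code{floor(days since first event /
#' (365.25 * granularity_years))}; duplicate codes within a slice collapse
#' to a single binary observation.  Patients with fewer than two non-empty
#' slices are excluded (the model needs at least one between-encounter
#' interval).
#'
#' @param events code-filtered event data frame.
#' @param vocabulary the \code{finding_vocabulary} from [filter_codes()].
#' @param granularity_years slice width in years (default 1).
#' @return list of \code{patient_history} objects, ordered by patient id.
#' @export
build_time_slices <- function(events, vocabulary, granularity_years = 1) {
  stopifnot(granularity_years > 0)
  if (nrow(events) == 0) return(list())
  idx <- code_index(vocabulary, events$code)
  if (anyNA(idx)) stop("events contain codes outside the vocabulary; run filter_codes first")
  out <- list()
  for (pid in sort(unique(events$patient_id), method = "radix")) {
    rows <- events$patient_id == pid
    dates <- events$event_date[rows]
    codes <- idx[rows]
    rel_days <- as.numeric(dates - min(dates))
    bin <- floor(rel_days / (365.25 * granularity_years))
    slices <- split(codes, factor(bin, levels = sort(unique(bin))))
    years <- as.integer(names(slices))
    if (length(years) < 2) next
    out[[pid]] <- patient_history(pid, years, slices)
  }
  unname(out)
}

#' Encounter-level summary counts
#'
#' @param histories list of \code{patient_history} objects.
#' @return list with \code{n_encounters} (total number of time slices) and
#'   \code{n_positive_observations} (total number of distinct positive codes
#'   summed over slices).
#' @export
encounter_stats <- function(histories) {
  n_enc <- sum(vapply(histories, function(h) length(h$year), 0L))
  n_pos <- sum(vapply(histories, function(h)
    sum(lengths(h$findings)), 0L))
  list(n_encounters = as.integer(n_enc),
       n_positive_observations = as.integer(n_pos))
}

#' Write / read a finding vocabulary as plain text
#'
#' One code per line; line order is the vocabulary index.
#' @param vocabulary a \code{finding_vocabulary}.
#' @param path file path.
#' @export
write_vocabulary <- function(vocabulary, path) {
  writeLines(as.character(vocabulary), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) new_vocabulary(readLines(path, warn = FALSE))

#' Write / read patient histories as line-delimited JSON
#'
#' One JSON object per line with fields \code{patient_id}, \code{year} and
#' \code{findings} (1-based vocabulary indices per slice).
#'
#' @param histories list of \code{patient_history} objects.
#' @param path file path.
#' @export
write_histories <- function(histories, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (h in histories) {
    writeLines(jsonlite::toJSON(list(
      patient_id = h$patient_id,
      year = h$year,
      findings = lapply(h$findings, as.integer)), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_histories
#' @export
read_histories <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    patient_history(r$patient_id,
                    vapply(r$year, as.integer, 0L),
                    lapply(r$findings, function(f) vapply(f, as.integer, 0L)))
  })
}
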