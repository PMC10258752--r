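#' Symptom classes used in the daily diary
#'
#' A-symptoms: fever, wheezing, wet cough, medically diagnosed pneumonia or
#' otitis media. B-symptoms: dry cough, chills, sore throat, runny or
#' blocked nose, increased need to sleep, loss of appetite, increased
#' attachment. One A-symptom, or two B-symptoms on the same day, qualifies
#' the day as part of an acute respiratory infection (ARI).
#'
#' @return Character vector of diary column names.
#' @export
a_symptoms <- function() {
  c("fever", "wheezing", "wet_cough", "pneumonia_dx", "otitis_media_dx")
}

#' @rdname a_symptoms
#' @export
b_symptoms <- function() {
  c("dry_cough", "chills", "sore_throat", "runny_blocked_nose",
    "increased_sleep", "appetite_loss", "increased_attachment")
}

#' Build a symptom diary
#'
#' A diary is a per-day grid of boolean symptom indicators for one subject.
#' Day 0 is the date of birth. Days absent from `days` are treated as
#' unrecorded; on unrecorded days all symptom columns must be `FALSE`.
#'
#' @param days data.frame with integer column `day` (strictly increasing),
#'   logical column `recorded`, and one logical column per symptom in
#'   [a_symptoms()] and [b_symptoms()] (missing symptom columns are filled
#'   with `FALSE`).
#' @param subject_id subject identifier.
#' @return Object of class `symptom_diary`.
#' @export
symptom_diary <- function(days, subject_id) {
  stopifnot(is.data.frame(days), "day" %in% names(days))
  days$day <- as.integer(days$day)
  if (is.unsorted(days$day, strictly = TRUE)) {
    stop("diary day indices must be strictly increasing", call. = FALSE)
  }
  if (any(days$day < 0L)) stop("day indices must be >= 0", call. = FALSE)
  if (is.null(days$recorded)) days$recorded <- TRUE
  for (s in c(a_symptoms(), b_symptoms())) {
    if (is.null(days[[s]])) days[[s]] <- FALSE
    days[[s]] <- as.logical(days[[s]])
  }
  sym_cols <- c(a_symptoms(), b_symptoms())
  unrec <- !days$recorded
  if (any(unrec & rowSums(days[, sym_cols, drop = FALSE]) > 0L)) {
    stop("symptom sets must be empty on unrecorded days", call. = FALSE)
  }
  rownames(days) <- NULL
  structure(list(subject_id = as.character(subject_id),
                 days = days[, c("day", "recorded", sym_cols)]),
            class = "symptom_diary")
}

#' @export
print.symptom_diary <- function(x, ...) {
  cat(sprintf("<symptom_diary> subject %s: %d days (%d recorded), days %d..%d\n",
              x$subject_id, nrow(x$days), sum(x$days$recorded),
              min(x$days$day), max(x$days$day)))
  invisible(x)
}

#' Does a diary day qualify as an ARI day?
#'
#' A recorded day qualifies when it has at least one A-symptom or at least
#' two B-symptoms.
#'
#' @param day_record one-row data.frame (or list) with the diary columns.
#' @return `TRUE`/`FALSE`.
#' @export
#' @examples
#' d <- data.frame(day = 1, recorded = TRUE, fever = TRUE)
#' is_ari_day(symptom_diary(d, "S1")$days[1, ])
is_ari_day <- function(day_record) {
  if (!isTRUE(as.logical(day_record[["recorded"]]))) {
    stop("is_ari_day requires a recorded day; handle missingness upstream",
         call. = FALSE)
  }
  n_a <- sum(vapply(a_symptoms(), function(s) isTRUE(day_record[[s]]),
                    logical(1)))
  n_b <- sum(vapply(b_symptoms(), function(s) isTRUE(day_record[[s]]),
                    logical(1)))
  n_a >= 1L || n_b >= 2L
}

# Vectorized qualification over the whole diary grid. Unrecorded days are
# never qualifying (their symptom sets are empty by construction).
qualifying_days <- function(diary) {
  d <- diary$days
  n_a <- rowSums(d[, a_symptoms(), drop = FALSE])
  n_b <- rowSums(d[, b_symptoms(), drop = FALSE])
  d$recorded & (n_a >= 1L | n_b >= 2L)
}

#' Call ARI episodes from a symptom diary
#'
#' Scans days in order. A qualifying day (>= 1 A-symptom or >= 2
#' B-symptoms) while no episode is open starts one; an open episode ends on
#' its last qualifying day once `gap_days` consecutive non-qualifying days
#' have passed. A single qualifying day therefore constitutes an episode.
#'
#' The start rule is fixed by the diary design; the termination gap is a
#' convention (default 3 days, configurable 1-14) and should be reported
#' with any downstream result. Under `missing_policy = "asymptomatic"`
#' unrecorded days count as non-qualifying (they can close an episode);
#' under `"censor"` they neither extend nor terminate an episode - the gap
#' counter pauses.
#'
#' @param diary a [symptom_diary()].
#' @param gap_days consecutive non-qualifying days that terminate an
#'   episode (integer in 1..14).
#' @param missing_policy `"asymptomatic"` or `"censor"`.
#' @return data.frame with columns `start_day`, `end_day`,
#'   `n_symptom_days`; episodes are sorted and non-overlapping.
#' @export
call_episodes <- function(diary, gap_days = 3L,
                          missing_policy = c("asymptomatic", "censor")) {
  stopifnot(inherits(diary, "symptom_diary"))
  missing_policy <- match.arg(missing_policy)
  if (!is_scalar_int(gap_days) || gap_days < 1 || gap_days > 14) {
    stop("gap_days must be an integer in 1..14", call. = FALSE)
  }
  d <- diary$days
  empty <- data.frame(start_day = integer(0), end_day = integer(0),
                      n_symptom_days = integer(0))
  if (nrow(d) == 0L) return(empty)

  # Expand to the full day range; days absent from the table are unrecorded.
  full_days <- seq(min(d$day), max(d$day))
  recorded <- rep(FALSE, length(full_days))
  qual <- rep(FALSE, length(full_days))
  idx <- match(d$day, full_days)
  recorded[idx] <- d$recorded
  qual[idx] <- qualifying_days(diary)

  episodes <- empty
  open <- FALSE
  start <- last_qual <- n_sympt <- 0L
  gap <- 0L
  for (i in seq_along(full_days)) {
    day <- full_days[i]
    if (qual[i]) {
      if (!open) {
        open <- TRUE
        start <- day
        n_sympt <- 0L
      }
      last_qual <- day
      n_sympt <- n_sympt + 1L
      gap <- 0L
    } else if (open) {
      counts_toward_gap <- recorded[i] || missing_policy == "asymptomatic"
      if (counts_toward_gap) {
        gap <- gap + 1L
        if (gap >= gap_days) {
          episodes <- rbind(episodes, data.frame(
            start_day = start, end_day = last_qual,
            n_symptom_days = n_sympt))
          open <- FALSE
          gap <- 0L
        }
      }
    }
  }
  if (open) {
    episodes <- rbind(episodes, data.frame(
      start_day = start, end_day = last_qual, n_symptom_days = n_sympt))
  }
  rownames(episodes) <- NULL
  episodes
}

#' Diary completeness over a window
#'
#' Fraction of days in `[window[1], window[2]]` with a recorded diary
#' entry. Days absent from the diary count as unrecorded. Subjects are
#' conventionally retained when completeness exceeds 0.8.
#'
#' @param diary a [symptom_diary()].
#' @param window integer vector `c(start_day, end_day)`, inclusive.
#' @return Fraction in \[0, 1\].
#' @export
completeness <- function(diary, window) {
  stopifnot(inherits(diary, "symptom_diary"), length(window) == 2L)
  if (window[2] < window[1]) stop("window must be non-empty", call. = FALSE)
  total <- window[2] - window[1] + 1
  d <- diary$days
  in_win <- d$day >= window[1] & d$day <= window[2]
  sum(d$recorded[in_win]) / total
}

#' Cumulative ARI counts at year boundaries
#'
#' Counts episodes whose start day falls on or before each year end. With
#' day 0 the date of birth, year n ends at day 365*n - 1 (leap days
#' ignored). An episode is attributed to the interval containing its start
#' day.
#'
#' @param episodes data.frame from [call_episodes()].
#' @param year_ends increasing vector of day indices (default the first
#'   four years of life).
#' @return Non-decreasing integer vector of counts, one per year end.
#' @export
cumulative_ari <- function(episodes, year_ends = year_end_days(1:4)) {
  stopifnot(is.data.frame(episodes))
  if (is.unsorted(year_ends, strictly = TRUE)) {
    stop("year_ends must be strictly increasing", call. = FALSE)
  }
  vapply(year_ends, function(e) sum(episodes$start_day <= e), integer(1))
}

#' Day index of the end of year n of life
#'
#' @param n year number(s), 1-based.
#' @return `365 * n - 1` (day 0 = birth; leap days ignored).
#' @export
year_end_days <- function(n) {
  as.integer(365L * n - 1L)
}

#' Read symptom diaries from a long-format TSV
#'
#' Expects columns `subject_id`, `day`, `recorded` and one boolean column
#' per symptom.
#'
#' @param path TSV path.
#' @return Named list of [symptom_diary()] objects, one per subject.
#' @export
read_diaries <- function(path) {
  df <- read_tsv(path)
  needed <- c("subject_id", "day", "recorded")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("diary table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  lapply(split(df, df$subject_id), function(g) {
    id <- g$subject_id[1]
    g <- g[order(g$day), setdiff(names(g), "subject_id"), drop = FALSE]
    symptom_diary(g, subject_id = id)
  })
}

#' Write symptom diaries as a long-format TSV
#'
#' @param diaries list of [symptom_diary()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diaries <- function(diaries, path) {
  rows <- lapply(diaries, function(d) {
    cbind(subject_id = d$subject_id, d$days, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}
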