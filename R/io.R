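#' Read a population from delimited text
#'
#' The on-disk layout is one UTF-8 tab-separated file with a header row and
#' one line per event:
#' `patient_id, birth_date, sex, event_kind, code, date, value, flags`.
#' Dates are ISO-8601 (`YYYY-MM-DD`). `event_kind` is one of `diagnosis`,
#' `antibiotic_prescription`, `lab_result`, `gp_visit`, or `none` for a
#' demographics-only line registering a patient without events. `value` is
#' only filled for `lab_result` lines (g/L). `flags` carries
#' semicolon-separated manual exclusion flags (usually empty). An optional
#' leading comment line `# extraction_date: YYYY-MM-DD` records the database
#' extraction date; without it the latest event date is used.
#'
#' @param path Path to the file.
#' @param extraction_date Optional override for the extraction date.
#' @param max_bad_fraction Maximum tolerated fraction of unparseable event
#'   rows (reported with their line numbers as warnings) before the read
#'   fails. Default 0: any bad row is an error.
#' @return A [population()].
#' @export
read_population <- function(path, extraction_date = NULL, max_bad_fraction = 0) {
  if (!file.exists(path)) stop("read_population: no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && grepl("^#\\s*extraction_date:", first)) {
    file_extraction <- as.Date(sub("^#\\s*extraction_date:\\s*", "", first))
  } else {
    file_extraction <- NULL
  }
  tab <- read.delim(path, comment.char = "#", colClasses = "character",
                    na.strings = c("NA", ""), stringsAsFactors = FALSE)
  required <- c("patient_id", "birth_date", "sex", "event_kind", "code", "date")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("read_population: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(tab$value)) tab$value <- rep(NA_character_, nrow(tab))
  if (is.null(tab$flags)) tab$flags <- rep(NA_character_, nrow(tab))

  n <- nrow(tab)
  bad <- rep(FALSE, n)
  dates <- as.Date(rep(NA, n))
  is_event <- !is.na(tab$event_kind) & tab$event_kind != "none"
  if (n > 0) {
    parsed <- suppressWarnings(as.Date(tab$date))
    dates <- parsed
    bad <- is_event & (is.na(parsed) |
                         !(tab$event_kind %in% EVENT_KINDS) |
                         (tab$event_kind != "gp_visit" &
                            (is.na(tab$code) | !nzchar(tab$code))))
  }
  if (any(bad)) {
    lines <- which(bad) + 1L  # header offset; comment line not counted by read.delim
    warning("read_population: unparseable row(s) at line(s): ",
            paste(head(lines, 20), collapse = ", "))
    if (mean(bad) > max_bad_fraction) {
      stop("read_population: ", sum(bad), "/", n,
           " rows unparseable, above the allowed fraction ", max_bad_fraction)
    }
    tab <- tab[!bad, , drop = FALSE]
    dates <- dates[!bad]
    is_event <- is_event[!bad]
  }

  ids <- unique(tab$patient_id)
  patients <- lapply(ids, function(id) {
    rows <- tab$patient_id == id
    sub <- tab[rows, , drop = FALSE]
    ev_rows <- is_event[rows]
    events <- if (any(ev_rows)) {
      data.frame(code = ifelse(is.na(sub$code[ev_rows]), "", sub$code[ev_rows]),
                 kind = sub$event_kind[ev_rows],
                 date = dates[rows][ev_rows],
                 value = suppressWarnings(as.numeric(sub$value[ev_rows])),
                 stringsAsFactors = FALSE)
    } else {
      empty_events()
    }
    flags <- sub$flags[!is.na(sub$flags)]
    flags <- unique(unlist(strsplit(flags, ";", fixed = TRUE)))
    bd <- suppressWarnings(as.Date(sub$birth_date[1]))
    if (is.na(bd)) stop("read_population: invalid birth_date for patient ", id)
    patient_record(patient_id = id, birth_date = bd,
                   sex = if (is.na(sub$sex[1])) "U" else sub$sex[1],
                   events = events,
                   manual_exclusion_flags = flags)
  })

  if (is.null(extraction_date)) extraction_date <- file_extraction
  if (is.null(extraction_date)) {
    all_dates <- do.call(c, lapply(patients, function(p) p$events$date))
    if (length(all_dates) == 0) stop("read_population: no events and no extraction date given")
    extraction_date <- max(all_dates)
  }
  population(patients, extraction_date)
}

#' Write a population to delimited text
#'
#' Inverse of [read_population()]; the round trip preserves patient count,
#' event count and all field values.
#'
#' @param pop A [population()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "population"))
  rows <- lapply(pop$patients, function(p) {
    flags <- paste(p$manual_exclusion_flags, collapse = ";")
    if (nrow(p$events) == 0) {
      data.frame(patient_id = p$patient_id, birth_date = format(p$birth_date),
                 sex = p$sex, event_kind = "none", code = NA_character_,
                 date = NA_character_, value = NA_real_, flags = flags,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = p$patient_id, birth_date = format(p$birth_date),
                 sex = p$sex, event_kind = p$events$kind,
                 code = p$events$code, date = format(p$events$date),
                 value = p$events$value, flags = flags,
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# extraction_date: ", format(pop$extraction_date)), con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = ""))
  invisible(path)
}
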