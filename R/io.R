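#' Read a cohort from disk
#'
#' Two plain-text dialects are supported. `"jsonl"`: one subject per line
#' with keys `subject_id`, `group`, `age_months`, `sex` and `segments`
#' (each with `procedure`, `frame_rate`, `segment_length`, `events`,
#' `frames`); an optional leading line `{"cohort_provenance": ...}` carries
#' metadata. `"csv-pair"`: a directory holding `subjects.csv`, `events.csv`
#' and `frames.csv` keyed by `(subject_id, procedure)`; per-segment
#' `frame_rate` and `segment_length` travel as repeated columns of
#' `events.csv`. All floats are serialized with full precision.
#'
#' @param path file (jsonl) or directory (csv-pair).
#' @param format "jsonl" or "csv-pair".
#' @param validate when TRUE (default) run [validateCohort()] and stop on
#'   the first rule violation, naming the subject and the rule.
#' @return A validated [Cohort-class].
#' @export
readCohort <- function(path, format = c("jsonl", "csv-pair"),
                       validate = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("path does not exist: ", path)
  cohort <- if (format == "jsonl") .readJsonl(path) else .readCsvPair(path)
  if (validate) {
    viol <- validateCohort(cohort)
    if (nrow(viol))
      stop(sprintf("validation error: subject '%s' (%s) violates rule '%s': %s",
                   viol$subject_id[1], viol$procedure[1], viol$rule[1],
                   viol$detail[1]))
  }
  cohort
}

#' Write a cohort to disk
#'
#' Inverse of [readCohort()]; lossless for all required fields including
#' optional yaw and 68-point landmark sets.
#'
#' @param cohort a [Cohort-class].
#' @param path output file (jsonl) or directory (csv-pair; created).
#' @param format "jsonl" or "csv-pair".
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path, format = c("jsonl", "csv-pair")) {
  stopifnot(is(cohort, "Cohort"))
  format <- match.arg(format)
  if (format == "jsonl") .writeJsonl(cohort, path) else .writeCsvPair(cohort, path)
  invisible(path)
}

.segmentToList <- function(seg) {
  evs <- lapply(seq_len(nrow(seg@events)), function(i)
    list(t_call = seg@events$t_call[i], caller = seg@events$caller[i],
         call_index = seg@events$call_index[i]))
  frs <- lapply(seq_len(nrow(seg@frames)), function(i) {
    f <- list(frame_index = seg@frames$frame_index[i],
              face_present = seg@frames$face_present[i],
              identity_match = seg@frames$identity_match[i])
    if (!is.na(seg@frames$yaw_deg[i])) f$yaw_deg <- seg@frames$yaw_deg[i]
    lm <- seg@frames$landmarks[[i]]
    if (!is.null(lm)) f$landmarks <- unname(lm)
    f
  })
  list(procedure = seg@procedure, frame_rate = seg@frameRate,
       segment_length = seg@segmentLength, events = evs, frames = frs)
}

.writeJsonl <- function(cohort, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(cohort@provenance)) {
    writeLines(as.character(jsonlite::toJSON(
      list(cohort_provenance = cohort@provenance), auto_unbox = TRUE,
      digits = NA, dataframe = "columns", null = "null")), con)
  }
  for (subj in cohort@subjects) {
    rec <- list(subject_id = subj@subjectId, group = subj@group,
                age_months = subj@ageMonths, sex = subj@sex,
                segments = lapply(unname(subj@segments), .segmentToList))
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                             digits = NA, null = "null",
                                             na = "null")), con)
  }
}

.num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

.segmentFromList <- function(sl, subjectId) {
  evs <- if (length(sl$events)) {
    data.frame(
      t_call = vapply(sl$events, function(e) as.numeric(e$t_call), 1),
      caller = vapply(sl$events, function(e) as.character(e$caller), ""),
      call_index = vapply(sl$events, function(e) as.integer(e$call_index), 1L),
      stringsAsFactors = FALSE)
  } else NULL
  frs <- if (length(sl$frames)) {
    df <- data.frame(
      frame_index = vapply(sl$frames, function(f) as.integer(f$frame_index), 1L),
      face_present = vapply(sl$frames, function(f) as.logical(f$face_present), NA),
      identity_match = vapply(sl$frames, function(f) as.logical(f$identity_match), NA),
      yaw_deg = vapply(sl$frames, function(f) .num(f$yaw_deg), 1),
      stringsAsFactors = FALSE)
    df$landmarks <- lapply(sl$frames, function(f) {
      if (is.null(f$landmarks)) return(NULL)
      m <- do.call(rbind, lapply(f$landmarks, as.numeric))
      dimnames(m) <- NULL
      m
    })
    df
  } else NULL
  ProcedureSegment(subjectId, sl$procedure, events = evs, frames = frs,
                   frameRate = as.numeric(sl$frame_rate),
                   segmentLength = as.numeric(sl$segment_length))
}

.readJsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  prov <- list()
  subjects <- list()
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) stop(sprintf("parse error at line %d of %s: %s",
                                       i, path, conditionMessage(e))))
    if (!is.null(rec$cohort_provenance)) {
      prov <- jsonlite::fromJSON(lines[i],
                                 simplifyVector = TRUE)$cohort_provenance
      if (!is.null(prov$truth)) prov$truth <- as.data.frame(prov$truth)
      next
    }
    if (is.null(rec$subject_id))
      stop(sprintf("parse error at line %d of %s: missing subject_id", i, path))
    segs <- lapply(rec$segments, .segmentFromList, subjectId = rec$subject_id)
    subjects[[length(subjects) + 1L]] <-
      SubjectRecord(rec$subject_id, rec$group, .num(rec$age_months),
                    rec$sex, segs)
  }
  Cohort(subjects, prov)
}

.packLandmarks <- function(lm) {
  if (is.null(lm)) return("")
  paste(sprintf("%.9g:%.9g", lm[, 1], lm[, 2]), collapse = ";")
}

.unpackLandmarks <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  pairs <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  m <- do.call(rbind, lapply(pairs, as.numeric))
  dimnames(m) <- NULL
  m
}

.writeCsvPair <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  subs <- do.call(rbind, lapply(cohort@subjects, function(s)
    data.frame(subject_id = s@subjectId, group = s@group,
               age_months = s@ageMonths, sex = s@sex,
               stringsAsFactors = FALSE)))
  if (is.null(subs))
    subs <- data.frame(subject_id = character(0), group = character(0),
                       age_months = numeric(0), sex = character(0))
  evl <- list(); frl <- list()
  for (s in cohort@subjects) for (seg in s@segments) {
    if (nrow(seg@events))
      evl[[length(evl) + 1L]] <- cbind(
        data.frame(subject_id = s@subjectId, procedure = seg@procedure,
                   frame_rate = seg@frameRate,
                   segment_length = seg@segmentLength,
                   stringsAsFactors = FALSE),
        seg@events)
    if (nrow(seg@frames)) {
      fr <- seg@frames
      frl[[length(frl) + 1L]] <- data.frame(
        subject_id = s@subjectId, procedure = seg@procedure,
        frame_index = fr$frame_index, face_present = fr$face_present,
        identity_match = fr$identity_match, yaw_deg = fr$yaw_deg,
        landmarks = vapply(fr$landmarks, .packLandmarks, ""),
        stringsAsFactors = FALSE)
    }
  }
  evs <- if (length(evl)) do.call(rbind, evl) else
    data.frame(subject_id = character(0), procedure = character(0),
               frame_rate = numeric(0), segment_length = numeric(0),
               t_call = numeric(0), caller = character(0),
               call_index = integer(0))
  frs <- if (length(frl)) do.call(rbind, frl) else
    data.frame(subject_id = character(0), procedure = character(0),
               frame_index = integer(0), face_present = logical(0),
               identity_match = logical(0), yaw_deg = numeric(0),
               landmarks = character(0))
  utils::write.csv(subs, file.path(path, "subjects.csv"), row.names = FALSE)
  utils::write.csv(evs, file.path(path, "events.csv"), row.names = FALSE)
  utils::write.csv(frs, file.path(path, "frames.csv"), row.names = FALSE)
}

.readCsvPair <- function(path) {
  need <- file.path(path, c("subjects.csv", "events.csv", "frames.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("csv-pair directory is missing: ", paste(missing, collapse = ", "))
  subs <- utils::read.csv(need[1], stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  evs <- utils::read.csv(need[2], stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  frs <- utils::read.csv(need[3], stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  if (!"landmarks" %in% names(frs)) frs$landmarks <- ""
  frs$landmarks[is.na(frs$landmarks)] <- ""
  subjects <- lapply(seq_len(nrow(subs)), function(i) {
    sid <- subs$subject_id[i]
    sev <- evs[evs$subject_id == sid, , drop = FALSE]
    sfr <- frs[frs$subject_id == sid, , drop = FALSE]
    segs <- lapply(unique(sev$procedure), function(proc) {
      pev <- sev[sev$procedure == proc, , drop = FALSE]
      pfr <- sfr[sfr$procedure == proc, , drop = FALSE]
      frames <- NULL
      if (nrow(pfr)) {
        frames <- data.frame(frame_index = pfr$frame_index,
                             face_present = pfr$face_present,
                             identity_match = pfr$identity_match,
                             yaw_deg = pfr$yaw_deg, stringsAsFactors = FALSE)
        frames$landmarks <- lapply(pfr$landmarks, .unpackLandmarks)
      }
      ProcedureSegment(sid, proc,
                       events = pev[, c("t_call", "caller", "call_index")],
                       frames = frames,
                       frameRate = pev$frame_rate[1],
                       segmentLength = pev$segment_length[1])
    })
    SubjectRecord(sid, subs$group[i], subs$age_months[i], subs$sex[i], segs)
  })
  Cohort(subjects, list(source = path))
}
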