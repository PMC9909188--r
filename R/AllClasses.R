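#' @import methods
NULL

.PROCEDURES <- c("evaluator", "caregiver")
.GROUPS <- c("ASD", "DD", "TD")

#' Empty name-call event table
#'
#' Canonical zero-row `data.frame` with the columns every event table
#' carries: `t_call` (seconds from segment start), `caller`
#' ("evaluator"/"caregiver") and `call_index` (1..3).
#'
#' @return A zero-row data.frame.
#' @export
emptyEvents <- function() {
  data.frame(t_call = numeric(0), caller = character(0),
             call_index = integer(0), stringsAsFactors = FALSE)
}

#' Empty frame-record table
#'
#' Canonical zero-row frame table: `frame_index`, `face_present`,
#' `identity_match`, `yaw_deg` (NA when no pose available) and a
#' `landmarks` list column holding 68x2 matrices or NULL.
#'
#' @return A zero-row data.frame with a `landmarks` list column.
#' @export
emptyFrames <- function() {
  df <- data.frame(frame_index = integer(0), face_present = logical(0),
                   identity_match = logical(0), yaw_deg = numeric(0),
                   stringsAsFactors = FALSE)
  df$landmarks <- list()
  df
}

.EVENT_COLS <- c("t_call", "caller", "call_index")
.FRAME_COLS <- c("frame_index", "face_present", "identity_match", "yaw_deg",
                 "landmarks")

#' ProcedureSegment: one name-call procedure for one subject
#'
#' Synchronized container for a single response-to-name trial: the
#' name-call events (at most three calls) and the per-frame face/identity/
#' pose stream at a fixed frame rate. Frame k spans
#' `[k/frameRate, (k+1)/frameRate)` seconds; frame-to-time conversion uses
#' the frame start time. Frame streams may be sparse: a frame index absent
#' from the table means no face was detected in that frame.
#'
#' @slot subjectId character scalar.
#' @slot procedure "evaluator" or "caregiver".
#' @slot frameRate frames per second (default 30).
#' @slot segmentLength segment duration in seconds.
#' @slot events data.frame of name-call events (see [emptyEvents()]).
#' @slot frames data.frame of frame records (see [emptyFrames()]).
#'
#' @seealso [ProcedureSegment()], [validateSegment()]
#' @export
setClass("ProcedureSegment",
  representation(subjectId = "character", procedure = "character",
                 frameRate = "numeric", segmentLength = "numeric",
                 events = "data.frame", frames = "data.frame"),
  prototype(subjectId = NA_character_, procedure = "evaluator",
            frameRate = 30, segmentLength = 0))

setValidity("ProcedureSegment", function(object) {
  msg <- character(0)
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (length(object@procedure) != 1L || !object@procedure %in% .PROCEDURES)
    msg <- c(msg, "procedure must be 'evaluator' or 'caregiver'")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a positive number")
  if (length(object@segmentLength) != 1L || !is.finite(object@segmentLength) ||
      object@segmentLength < 0)
    msg <- c(msg, "segmentLength must be a non-negative number")
  if (!all(.EVENT_COLS %in% names(object@events)))
    msg <- c(msg, "events must have columns t_call, caller, call_index")
  if (!all(.FRAME_COLS %in% names(object@frames)))
    msg <- c(msg, paste("frames must have columns",
                        paste(.FRAME_COLS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SubjectRecord: one toddler with group label and up to two segments
#'
#' @slot subjectId character scalar, unique within a cohort.
#' @slot group clinical group, one of "ASD", "DD", "TD".
#' @slot ageMonths chronological age in months.
#' @slot sex "M" or "F".
#' @slot segments named list of [ProcedureSegment-class] objects, at most
#'   one per procedure, named by procedure.
#'
#' @export
setClass("SubjectRecord",
  representation(subjectId = "character", group = "character",
                 ageMonths = "numeric", sex = "character",
                 segments = "list"),
  prototype(subjectId = NA_character_, group = "TD", ageMonths = NA_real_,
            sex = "M", segments = list()))

setValidity("SubjectRecord", function(object) {
  msg <- character(0)
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (length(object@group) != 1L || !object@group %in% .GROUPS)
    msg <- c(msg, "group must be one of ASD, DD, TD")
  if (length(object@sex) != 1L || !object@sex %in% c("M", "F"))
    msg <- c(msg, "sex must be 'M' or 'F'")
  if (length(object@segments) > 2L)
    msg <- c(msg, "at most two segments (one per procedure)")
  if (length(object@segments)) {
    if (!all(vapply(object@segments, is, logical(1), "ProcedureSegment")))
      msg <- c(msg, "segments must contain ProcedureSegment objects")
    else {
      procs <- vapply(object@segments, function(s) s@procedure, character(1))
      if (anyDuplicated(procs))
        msg <- c(msg, "duplicate procedure within subject")
      if (!identical(names(object@segments), unname(procs)))
        msg <- c(msg, "segments list must be named by procedure")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Cohort: a list of subjects plus provenance metadata
#'
#' @slot subjects list of [SubjectRecord-class] objects with unique ids.
#' @slot provenance free-form list (seed, generator version, file source,
#'   and — for simulated cohorts — the planted ground truth).
#'
#' @export
setClass("Cohort",
  representation(subjects = "list", provenance = "list"),
  prototype(subjects = list(), provenance = list()))

setValidity("Cohort", function(object) {
  msg <- character(0)
  if (length(object@subjects)) {
    if (!all(vapply(object@subjects, is, logical(1), "SubjectRecord")))
      msg <- c(msg, "subjects must contain SubjectRecord objects")
    else {
      ids <- vapply(object@subjects, function(s) s@subjectId, character(1))
      if (anyDuplicated(ids))
        msg <- c(msg, paste("duplicate subject_id:",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

.normalizeEvents <- function(events) {
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) return(emptyEvents())
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  stopifnot(all(.EVENT_COLS %in% names(events)))
  events <- events[, .EVENT_COLS, drop = FALSE]
  events$t_call <- as.numeric(events$t_call)
  events$caller <- as.character(events$caller)
  events$call_index <- as.integer(events$call_index)
  rownames(events) <- NULL
  events
}

.normalizeFrames <- function(frames) {
  if (is.null(frames)) return(emptyFrames())
  frames <- as.data.frame(frames, stringsAsFactors = FALSE)
  if (nrow(frames) == 0L) return(emptyFrames())
  if (!"yaw_deg" %in% names(frames)) frames$yaw_deg <- NA_real_
  if (!"landmarks" %in% names(frames)) frames$landmarks <- rep(list(NULL), nrow(frames))
  stopifnot(all(c("frame_index", "face_present", "identity_match") %in% names(frames)))
  frames <- frames[, .FRAME_COLS, drop = FALSE]
  frames$frame_index <- as.integer(frames$frame_index)
  frames$face_present <- as.logical(frames$face_present)
  frames$identity_match <- as.logical(frames$identity_match)
  frames$yaw_deg <- as.numeric(frames$yaw_deg)
  rownames(frames) <- NULL
  frames
}

#' Construct a ProcedureSegment
#'
#' @param subjectId subject identifier.
#' @param procedure "evaluator" or "caregiver".
#' @param events data.frame with columns `t_call`, `caller`, `call_index`.
#' @param frames data.frame with columns `frame_index`, `face_present`,
#'   `identity_match` and optionally `yaw_deg` and a `landmarks` list
#'   column (68x2 matrices).
#' @param frameRate frames per second; the protocol videos run at 30.
#' @param segmentLength segment duration (s). When `NULL`, defaults to
#'   first-call time + 13 s (covering the 10 s response window plus slack),
#'   extended to cover the last listed frame and call.
#'
#' @return A [ProcedureSegment-class] object. Structural typing is enforced
#'   here; protocol rules are checked by [validateSegment()].
#' @examples
#' seg <- ProcedureSegment("s1", "evaluator",
#'   events = data.frame(t_call = 3, caller = "evaluator", call_index = 1),
#'   frames = data.frame(frame_index = 120:150, face_present = TRUE,
#'                       identity_match = TRUE))
#' validateSegment(seg)
#' @export
ProcedureSegment <- function(subjectId, procedure, events = NULL,
                             frames = NULL, frameRate = 30,
                             segmentLength = NULL) {
  events <- .normalizeEvents(events)
  frames <- .normalizeFrames(frames)
  if (is.null(segmentLength)) {
    base <- if (nrow(events)) min(events$t_call) + 13 else 13
    frameEnd <- if (nrow(frames)) (max(frames$frame_index) + 1) / frameRate else 0
    callEnd <- if (nrow(events)) max(events$t_call) + 1 else 0
    segmentLength <- max(base, frameEnd, callEnd)
  }
  new("ProcedureSegment", subjectId = as.character(subjectId),
      procedure = as.character(procedure), frameRate = as.numeric(frameRate),
      segmentLength = as.numeric(segmentLength), events = events,
      frames = frames)
}

#' Construct a SubjectRecord
#'
#' @param subjectId subject identifier.
#' @param group "ASD", "DD" or "TD".
#' @param ageMonths chronological age in months.
#' @param sex "M" or "F".
#' @param segments list of [ProcedureSegment-class] (0-2, one per procedure).
#' @return A [SubjectRecord-class] object.
#' @export
SubjectRecord <- function(subjectId, group, ageMonths = NA_real_, sex = "M",
                          segments = list()) {
  if (length(segments))
    names(segments) <- vapply(segments, function(s) s@procedure, character(1))
  new("SubjectRecord", subjectId = as.character(subjectId),
      group = as.character(group), ageMonths = as.numeric(ageMonths),
      sex = as.character(sex), segments = segments)
}

#' Construct a Cohort
#'
#' @param subjects list of [SubjectRecord-class] objects (unique ids).
#' @param provenance free-form metadata list.
#' @return A [Cohort-class] object.
#' @export
Cohort <- function(subjects = list(), provenance = list()) {
  new("Cohort", subjects = subjects, provenance = provenance)
}
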