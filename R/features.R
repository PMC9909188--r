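#' Time of the first name call
#'
#' @param segment a [ProcedureSegment-class].
#' @return `t_call` of the event with `call_index == 1`, in seconds.
#' @export
firstCallTime <- function(segment) {
  ev <- segment@events
  if (nrow(ev) == 0L)
    stop("missing-call error: segment '", segment@subjectId,
         "' has no name-call events")
  i <- which(ev$call_index == 1L)
  if (!length(i))
    stop("missing-call error: segment '", segment@subjectId,
         "' has no event with call_index 1")
  ev$t_call[i[1]]
}

#' Per-frame qualification for a valid response
#'
#' A frame qualifies when a face is present, the identity matches the
#' child, and the head is facing the caller. Facing uses `yaw_deg` when
#' available (see [annotateFrames()] for filling it from landmarks); frames
#' with no pose information count as facing unless `strictPose = TRUE` — a
#' detected, identity-matched face with unknown pose is not assumed
#' averted.
#'
#' @param segment a [ProcedureSegment-class].
#' @param facingThreshold facing threshold in degrees.
#' @param strictPose if TRUE, frames without pose information do not
#'   qualify.
#' @return Logical vector along the frame table.
#' @keywords internal
.qualifyingFrames <- function(segment, facingThreshold = 30,
                              strictPose = FALSE) {
  fr <- segment@frames
  if (!nrow(fr)) return(logical(0))
  facing <- ifelse(is.na(fr$yaw_deg), !strictPose,
                   abs(fr$yaw_deg) <= facingThreshold)
  fr$face_present & fr$identity_match & facing
}

#' Time of the first valid face detection
#'
#' Start time of the earliest qualifying frame strictly after the first
#' name call and no later than 10 s after it (the response window; the
#' boundary is inclusive). Pre-call face detections never count: only a
#' response appearing after the name call is valid.
#'
#' @inheritParams .qualifyingFrames
#' @param windowS response window length in seconds after the first call.
#' @return Time in seconds, or `NA_real_` when no frame qualifies.
#' @export
firstFaceTime <- function(segment, facingThreshold = 30, windowS = 10,
                          strictPose = FALSE) {
  tc1 <- firstCallTime(segment)
  q <- .qualifyingFrames(segment, facingThreshold, strictPose)
  if (!any(q)) return(NA_real_)
  tt <- segment@frames$frame_index[q] / segment@frameRate
  tt <- tt[tt > tc1 & tt <= tc1 + windowS]
  if (!length(tt)) NA_real_ else min(tt)
}

#' Response latency in seconds
#'
#' `Latency = T_f - T_c1`: time from the onset of the first name call to
#' the first valid face detection. When no valid response occurs within
#' the 10 s window the latency is imputed at 10 s ("no response").
#'
#' @inheritParams firstFaceTime
#' @return Latency in `(0, 10]` seconds.
#' @export
responseLatency <- function(segment, facingThreshold = 30, windowS = 10,
                            strictPose = FALSE) {
  tf <- firstFaceTime(segment, facingThreshold, windowS, strictPose)
  if (is.na(tf)) return(windowS)
  tf - firstCallTime(segment)
}

#' Response duration in seconds
#'
#' `Duration = N_f / frame rate`, where `N_f` is the total number of
#' qualifying face frames after the first call (a sum, not the largest
#' contiguous run). When no valid response occurs the duration is 0.
#'
#' @inheritParams firstFaceTime
#' @return Duration in seconds (an integer multiple of the frame period).
#' @export
responseDuration <- function(segment, facingThreshold = 30, windowS = 10,
                             strictPose = FALSE) {
  tf <- firstFaceTime(segment, facingThreshold, windowS, strictPose)
  if (is.na(tf)) return(0)
  .nFaceFrames(segment, facingThreshold, strictPose) / segment@frameRate
}

.nFaceFrames <- function(segment, facingThreshold = 30, strictPose = FALSE) {
  tc1 <- firstCallTime(segment)
  q <- .qualifyingFrames(segment, facingThreshold, strictPose)
  if (!any(q)) return(0L)
  tt <- segment@frames$frame_index[q] / segment@frameRate
  sum(tt > tc1)
}

#' Response features for one segment
#'
#' @inheritParams firstFaceTime
#' @return One-row data.frame: `subject_id`, `procedure`, `responded`,
#'   `latency_s`, `duration_s`, `t_first_call`, `t_first_face`,
#'   `n_face_frames`.
#' @export
segmentFeatures <- function(segment, facingThreshold = 30, windowS = 10,
                            strictPose = FALSE) {
  tc1 <- firstCallTime(segment)
  tf <- firstFaceTime(segment, facingThreshold, windowS, strictPose)
  responded <- !is.na(tf)
  nf <- if (responded) .nFaceFrames(segment, facingThreshold, strictPose) else 0L
  data.frame(
    subject_id = segment@subjectId, procedure = segment@procedure,
    responded = responded,
    latency_s = if (responded) tf - tc1 else windowS,
    duration_s = nf / segment@frameRate,
    t_first_call = tc1, t_first_face = if (responded) tf else NA_real_,
    n_face_frames = as.integer(nf), stringsAsFactors = FALSE)
}

#' Response features for one subject
#'
#' One row per present procedure; a subject with no valid segment yields
#' zero rows (callers treat that as a skip, not an error).
#'
#' @param subject a [SubjectRecord-class].
#' @inheritParams firstFaceTime
#' @return data.frame as in [segmentFeatures()], plus a `group` column.
#' @export
extractFeatures <- function(subject, facingThreshold = 30, windowS = 10,
                            strictPose = FALSE) {
  rows <- list()
  for (seg in subject@segments) {
    if (nrow(validateSegment(seg))) next
    rows[[length(rows) + 1L]] <-
      segmentFeatures(seg, facingThreshold, windowS, strictPose)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    segmentFeatures(ProcedureSegment(subject@subjectId, "evaluator",
      events = data.frame(t_call = 0, caller = "evaluator",
                          call_index = 1L)))[0, ]
  if (nrow(out)) out$group <- subject@group else out$group <- character(0)
  out[, c("subject_id", "group", "procedure", "responded", "latency_s",
          "duration_s", "t_first_call", "t_first_face", "n_face_frames")]
}

#' Response features for every subject of a cohort
#'
#' @param cohort a [Cohort-class].
#' @inheritParams firstFaceTime
#' @return Long data.frame, one row per subject x present procedure.
#' @export
cohortFeatures <- function(cohort, facingThreshold = 30, windowS = 10,
                           strictPose = FALSE) {
  rows <- lapply(cohort@subjects, extractFeatures,
                 facingThreshold = facingThreshold, windowS = windowS,
                 strictPose = strictPose)
  skipped <- vapply(rows, nrow, 1L) == 0L
  if (any(skipped))
    message("skipping ", sum(skipped), " subject(s) with no valid segment")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pivot long features to one row per subject
#'
#' Columns `latency_evaluator`, `latency_caregiver`, `duration_evaluator`,
#' `duration_caregiver` (latency features first — this column order is the
#' tie-break order of the joint classifier), NA where a procedure is
#' absent.
#'
#' @param features long feature table from [cohortFeatures()].
#' @param requireBoth drop subjects lacking either procedure (the joint
#'   analysis default, giving the 123-subject analysis set under the
#'   default simulation design).
#' @return Wide data.frame keyed by `subject_id` with a `group` column.
#' @export
widenFeatures <- function(features, requireBoth = TRUE) {
  ids <- unique(features$subject_id)
  rows <- lapply(ids, function(sid) {
    ff <- features[features$subject_id == sid, , drop = FALSE]
    pick <- function(proc, col) {
      v <- ff[ff$procedure == proc, col]
      if (length(v)) v[1] else NA_real_
    }
    data.frame(subject_id = sid, group = ff$group[1],
               latency_evaluator = pick("evaluator", "latency_s"),
               latency_caregiver = pick("caregiver", "latency_s"),
               duration_evaluator = pick("evaluator", "duration_s"),
               duration_caregiver = pick("caregiver", "duration_s"),
               stringsAsFactors = FALSE)
  })
  wide <- do.call(rbind, rows)
  if (requireBoth)
    wide <- wide[stats::complete.cases(
      wide[, c("latency_evaluator", "latency_caregiver",
               "duration_evaluator", "duration_caregiver")]), , drop = FALSE]
  rownames(wide) <- NULL
  wide
}
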