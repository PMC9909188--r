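#' Check a segment against the call-protocol rules
#'
#' Protocol rules are checked as data, not exceptions: the function is
#' total and returns one row per violated rule. The rules encode the
#' name-call protocol (no more than three calls, calls sorted and at least
#' 1 s apart, call indices unique in 1..3) and the frame-stream contract
#' (strictly increasing non-negative frame indices, identity implies a
#' detected face, landmark sets have exactly 68 finite points, no frame
#' or call beyond the segment end).
#'
#' The 1 s minimum inter-call gap is deliberately permissive: the protocol
#' pauses roughly 3 s between calls but real timings jitter; the simulator
#' uses 3 s.
#'
#' @param segment a [ProcedureSegment-class] object.
#' @return A data.frame with columns `rule` and `detail`; zero rows iff the
#'   segment satisfies every invariant.
#' @examples
#' seg <- ProcedureSegment("s1", "evaluator",
#'   events = data.frame(t_call = c(3, 6, 9, 12), caller = "evaluator",
#'                       call_index = 1:4))
#' validateSegment(seg)$rule
#' @export
validateSegment <- function(segment) {
  stopifnot(is(segment, "ProcedureSegment"))
  v <- list()
  add <- function(rule, detail) v[[length(v) + 1L]] <<- c(rule, detail)
  ev <- segment@events
  fr <- segment@frames
  rate <- segment@frameRate
  len <- segment@segmentLength

  if (nrow(ev) == 0L)
    add("no-events", "a valid segment needs at least one name-call event")
  if (nrow(ev) > 3L)
    add("max-3-calls", sprintf("%d call events, protocol allows at most 3",
                               nrow(ev)))
  if (nrow(ev)) {
    if (any(!is.finite(ev$t_call) | ev$t_call < 0))
      add("negative-t-call", "t_call must be finite and non-negative")
    if (is.unsorted(ev$t_call, strictly = FALSE))
      add("events-unsorted", "events must be sorted ascending in t_call")
    if (any(!ev$call_index %in% 1:3))
      add("call-index-range", "call_index must lie in 1..3")
    if (anyDuplicated(ev$call_index))
      add("call-index-duplicate", "call_index must be unique within segment")
    if (nrow(ev) > 1L) {
      gaps <- diff(sort(ev$t_call))
      if (any(gaps < 1.0 - 1e-9))
        add("inter-call-gap",
            sprintf("minimum inter-call gap is 1.0 s, observed %.3f s",
                    min(gaps)))
    }
    if (any(ev$t_call >= len))
      add("call-beyond-segment", "all t_call must be < segment_length")
    if (any(!ev$caller %in% .PROCEDURES))
      add("caller-enum", "caller must be 'evaluator' or 'caregiver'")
  }
  if (nrow(fr)) {
    if (any(!is.finite(fr$frame_index) | fr$frame_index < 0))
      add("negative-frame-index", "frame_index must be non-negative")
    if (is.unsorted(fr$frame_index, strictly = TRUE))
      add("frames-not-increasing",
          "frame_index must be strictly increasing within segment")
    if (max(fr$frame_index) / rate > len + 1e-9)
      add("frame-beyond-segment",
          "max frame_index / frame_rate must be <= segment_length")
    if (any(fr$identity_match & !fr$face_present))
      add("identity-without-face", "identity_match implies face_present")
    bad <- vapply(fr$landmarks, function(lm) {
      if (is.null(lm)) return(FALSE)
      !(is.matrix(lm) && nrow(lm) == 68L && ncol(lm) == 2L &&
          all(is.finite(lm)))
    }, logical(1))
    if (any(bad))
      add("landmarks-shape",
          "landmarks, when present, must be a finite 68x2 matrix")
  }
  if (length(v)) {
    m <- do.call(rbind, v)
    data.frame(rule = m[, 1], detail = m[, 2], stringsAsFactors = FALSE)
  } else {
    data.frame(rule = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  }
}

#' Validate every segment of a cohort
#'
#' @param cohort a [Cohort-class] object.
#' @return data.frame with columns `subject_id`, `procedure`, `rule`,
#'   `detail`; zero rows iff all segments are clean.
#' @export
validateCohort <- function(cohort) {
  stopifnot(is(cohort, "Cohort"))
  out <- lapply(cohort@subjects, function(subj) {
    res <- lapply(subj@segments, function(seg) {
      vv <- validateSegment(seg)
      if (nrow(vv))
        cbind(subject_id = subj@subjectId, procedure = seg@procedure, vv,
              stringsAsFactors = FALSE)
      else NULL
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(subject_id = character(0), procedure = character(0),
                      rule = character(0), detail = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
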