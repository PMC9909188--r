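#' Accessors for RTN containers
#'
#' Small accessor layer over the S4 slots: `subjectId()`, `groupLabel()`,
#' `segments()`, `events()`, `frames()`, `frameRate()`, `segmentLength()`,
#' `subjects()`, `subjectIds()`, `provenance()` and `nSubjects()`.
#'
#' @param x a [ProcedureSegment-class], [SubjectRecord-class] or
#'   [Cohort-class] object, as appropriate.
#' @name accessors
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("segmentLength", function(x) standardGeneric("segmentLength"))
#' @rdname accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))
#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname accessors
#' @export
setMethod("subjectId", "ProcedureSegment", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "SubjectRecord", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("groupLabel", "SubjectRecord", function(x) x@group)
#' @rdname accessors
#' @export
setMethod("segments", "SubjectRecord", function(x) x@segments)
#' @rdname accessors
#' @export
setMethod("events", "ProcedureSegment", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("frames", "ProcedureSegment", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("frameRate", "ProcedureSegment", function(x) x@frameRate)
#' @rdname accessors
#' @export
setMethod("segmentLength", "ProcedureSegment", function(x) x@segmentLength)
#' @rdname accessors
#' @export
setMethod("subjects", "Cohort", function(x) x@subjects)
#' @rdname accessors
#' @export
setMethod("subjectIds", "Cohort",
          function(x) vapply(x@subjects, function(s) s@subjectId, character(1)))
#' @rdname accessors
#' @export
setMethod("provenance", "Cohort", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("nSubjects", "Cohort", function(x) length(x@subjects))

setMethod("show", "ProcedureSegment", function(object) {
  cat(sprintf("ProcedureSegment [%s / %s]\n", object@subjectId,
              object@procedure))
  cat(sprintf("  %d call event(s), %d frame record(s), %.5g fps, %.5g s\n",
              nrow(object@events), nrow(object@frames), object@frameRate,
              object@segmentLength))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord %s (%s, %s, %.3g mo): segments [%s]\n",
              object@subjectId, object@group, object@sex, object@ageMonths,
              paste(names(object@segments), collapse = ", ")))
})

setMethod("show", "Cohort", function(object) {
  grp <- vapply(object@subjects, function(s) s@group, character(1))
  cat(sprintf("Cohort with %d subject(s)", length(object@subjects)))
  if (length(grp))
    cat(": ", paste(sprintf("%s=%d", names(table(grp)), table(grp)),
                    collapse = ", "), sep = "")
  cat("\n")
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "),
        "\n")
})
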