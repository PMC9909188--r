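# Builders for small hand-specified segments used across the test files.

# A segment with calls at `callTimes` and face runs given as a list of
# c(first_frame, n_frames); every run frame is identity-matched and frontal
# unless yaw is supplied.
makeSegment <- function(callTimes = 3, faceRuns = list(), rate = 30,
                        yaw = 0, subject = "s1", proc = "evaluator",
                        segmentLength = NULL) {
  events <- data.frame(t_call = callTimes, caller = proc,
                       call_index = seq_along(callTimes))
  frames <- NULL
  if (length(faceRuns)) {
    idx <- unlist(lapply(faceRuns, function(r) r[1] + seq_len(r[2]) - 1L))
    frames <- data.frame(frame_index = as.integer(idx), face_present = TRUE,
                         identity_match = TRUE, yaw_deg = yaw)
  }
  ProcedureSegment(subject, proc, events = events, frames = frames,
                   frameRate = rate, segmentLength = segmentLength)
}

# A random (not necessarily rule-abiding) segment for totality fuzzing.
randomRawSegment <- function() {
  nEv <- sample(0:5, 1)
  events <- if (nEv) data.frame(
    t_call = round(runif(nEv, -1, 20), 2),
    caller = sample(c("evaluator", "caregiver"), nEv, replace = TRUE),
    call_index = sample(0:4, nEv, replace = TRUE)) else NULL
  nFr <- sample(0:30, 1)
  frames <- if (nFr) data.frame(
    frame_index = sample(0:900, nFr, replace = TRUE),
    face_present = sample(c(TRUE, FALSE), nFr, replace = TRUE),
    identity_match = sample(c(TRUE, FALSE), nFr, replace = TRUE),
    yaw_deg = ifelse(runif(nFr) < 0.5, NA_real_, runif(nFr, -90, 90))) else NULL
  ProcedureSegment("fz", sample(c("evaluator", "caregiver"), 1),
                   events = events, frames = frames,
                   segmentLength = runif(1, 0, 40))
}

# A rule-abiding random segment with planted latency/duration, for the
# feature round-trip property. Returns the segment plus the planted truth.
randomPlantedSegment <- function(rate = 30) {
  t0 <- round(runif(1, 0.5, 5), 2)
  responded <- runif(1) < 0.7
  if (responded) {
    latency <- runif(1, 0.05, 9.8)
    duration <- runif(1, 2 / rate, 6)
    nCalls <- min(3, floor(latency / 3) + 1)
    k0 <- ceiling((t0 + latency) * rate)
    n <- max(1, round(duration * rate))
    runs <- list(c(k0, n))
  } else {
    latency <- NA; duration <- 0; nCalls <- 3; runs <- list()
  }
  seg <- makeSegment(callTimes = t0 + 3 * (seq_len(nCalls) - 1),
                     faceRuns = runs, rate = rate)
  list(segment = seg, t0 = t0, responded = responded, latency = latency,
       duration = duration)
}

# Tiny cohort for I/O tests: a few subjects per group, optional landmarks.
smallCohort <- function(seed = 1, withLandmarks = FALSE) {
  generateCohort(cohortDesign(nASD = 3, nDD = 2, nTD = 2,
                              missingCaregiver = c(ASD = 1, DD = 0, TD = 0),
                              withLandmarks = withLandmarks, seed = seed))
}

expect_segment_equal <- function(a, b) {
  expect_equal(subjectId(a), subjectId(b))
  expect_equal(a@procedure, b@procedure)
  expect_equal(frameRate(a), frameRate(b))
  expect_equal(segmentLength(a), segmentLength(b))
  expect_equal(events(a), events(b))
  fa <- frames(a); fb <- frames(b)
  expect_equal(fa[, c("frame_index", "face_present", "identity_match")],
               fb[, c("frame_index", "face_present", "identity_match")])
  expect_equal(fa$yaw_deg, fb$yaw_deg, tolerance = 1e-6)
  expect_equal(length(fa$landmarks), length(fb$landmarks))
  for (i in seq_along(fa$landmarks)) {
    if (is.null(fa$landmarks[[i]])) expect_null(fb$landmarks[[i]])
    else expect_equal(fa$landmarks[[i]], fb$landmarks[[i]],
                      tolerance = 1e-6)
  }
}

expect_cohort_equal <- function(a, b) {
  expect_equal(subjectIds(a), subjectIds(b))
  for (i in seq_along(subjects(a))) {
    sa <- subjects(a)[[i]]; sb <- subjects(b)[[i]]
    expect_equal(groupLabel(sa), groupLabel(sb))
    expect_equal(sa@ageMonths, sb@ageMonths)
    expect_equal(sa@sex, sb@sex)
    expect_equal(names(segments(sa)), names(segments(sb)))
    for (p in names(segments(sa)))
      expect_segment_equal(segments(sa)[[p]], segments(sb)[[p]])
  }
}
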