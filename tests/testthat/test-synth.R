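test_that("default behavior parameters encode the observed score table", {
  p <- defaultBehaviorParams()
  expect_equal(p$ASD$evaluator$p_respond, 24 / 61)
  expect_equal(p$ASD$caregiver$p_respond, 30 / 60)
  expect_equal(p$TD$evaluator$p_respond, 27 / 33)
  expect_equal(p$ASD$evaluator$p_partial_response, 2 / 24)
  for (g in c("ASD", "DD", "TD")) for (proc in c("evaluator", "caregiver")) {
    e <- p[[g]][[proc]]
    expect_true(e$p_respond >= 0 && e$p_respond <= 1)
    expect_true(e$p_partial_response >= 0 && e$p_partial_response <= 1)
    expect_gt(e$latency_sdlog, 0)
    expect_gt(e$duration_shape, 0)
    expect_gt(e$duration_scale, 0)
    expect_true(is.finite(e$latency_meanlog))
  }
})

test_that("generation is bit-identical for identical seeds", {
  a <- generateCohort(cohortDesign(seed = 11))
  b <- generateCohort(cohortDesign(seed = 11))
  expect_cohort_equal(a, b)
  expect_equal(provenance(a)$truth, provenance(b)$truth)
  c_ <- generateCohort(cohortDesign(seed = 12))
  expect_false(isTRUE(all.equal(provenance(a)$truth, provenance(c_)$truth)))
})

test_that("the default design reproduces the cohort structure", {
  co <- generateCohort(cohortDesign(seed = 2))
  grp <- vapply(subjects(co), groupLabel, character(1))
  expect_equal(as.integer(table(grp)[c("ASD", "DD", "TD")]),
               c(61L, 31L, 33L))
  nseg <- vapply(subjects(co), function(s) length(segments(s)), 1L)
  # one ASD and one TD caregiver segment absent: 123 two-procedure subjects
  expect_equal(sum(nseg == 2L), 123L)
  f <- cohortFeatures(co)
  expect_equal(nrow(f), 248L)
})

test_that("quota mode plants exact non-responder counts", {
  co <- generateCohort(cohortDesign(seed = 31, quotaMode = TRUE))
  truth <- provenance(co)$truth
  grp <- vapply(subjects(co), groupLabel, character(1))
  names(grp) <- subjectIds(co)
  nonResp <- function(g, proc) {
    t <- truth[grp[truth$subject_id] == g & truth$procedure == proc, ]
    sum(!t$responded)
  }
  expect_equal(nonResp("ASD", "evaluator"), 37)
  expect_equal(nonResp("ASD", "caregiver"), 30)
  expect_equal(nonResp("DD", "evaluator"), 6)
  expect_equal(nonResp("DD", "caregiver"), 5)
  expect_equal(nonResp("TD", "evaluator"), 6)
  expect_equal(nonResp("TD", "caregiver"), 4)
})

test_that("human scores follow the planted truth and partial-response rates", {
  co <- generateCohort(cohortDesign(seed = 41))
  h <- generateHumanScores(co, seed = 41)
  truth <- provenance(co)$truth
  expect_equal(nrow(h), nrow(truth))
  expect_true(all(h$score[!truth$responded] == 0L))
  expect_true(all(h$score[truth$responded] %in% c(1L, 2L)))
  # TD has a zero partial-response rate: responders always score 2
  grp <- vapply(subjects(co), groupLabel, character(1))
  names(grp) <- subjectIds(co)
  tdResp <- truth$responded & grp[truth$subject_id] == "TD"
  expect_true(all(h$score[tdResp] == 2L))
  expect_equal(generateHumanScores(co, seed = 41), h)  # deterministic
  expect_error(generateHumanScores(Cohort()), "planted truth")

  # ASD evaluator score-1 count is binomial(~24, 1/12): mean about 2
  ones <- sapply(1:20, function(s) {
    coS <- generateCohort(cohortDesign(seed = 100 + s))
    hS <- generateHumanScores(coS, seed = s)
    tS <- provenance(coS)$truth
    gS <- vapply(subjects(coS), groupLabel, character(1))
    names(gS) <- subjectIds(coS)
    sum(hS$score == 1L & gS[hS$subject_id] == "ASD" &
          hS$procedure == "evaluator")
  })
  expect_gt(mean(ones), 0.8)
  expect_lt(mean(ones), 4)
})

test_that("perturbRater flips scores at the requested rate", {
  s <- rep(c(0L, 2L), 50)
  expect_equal(perturbRater(s, 0, seed = 1), s)
  all_flipped <- perturbRater(s, 1, seed = 1)
  expect_true(all(all_flipped != s))
  expect_true(all(all_flipped %in% 0:2))
  # 2% disagreement keeps two raters near-perfectly consistent
  co <- generateCohort(cohortDesign(seed = 5))
  h <- generateHumanScores(co, seed = 5)
  alphas <- sapply(1:20, function(s)
    cronbachAlpha(cbind(h$score, perturbRater(h$score, 0.02, seed = s))))
  expect_true(all(alphas >= 0.9 & alphas <= 1))
  expect_gt(mean(alphas), 0.95)
})

test_that("simulated overall medians are calibrated to the group targets", {
  meds <- t(sapply(1:12, function(s) {
    co <- generateCohort(cohortDesign(seed = 300 + s))
    f <- suppressMessages(cohortFeatures(co))
    med <- function(g, p, col) median(f[f$group == g & f$procedure == p, col])
    c(dd = med("DD", "evaluator", "latency_s"),
      td = med("TD", "evaluator", "latency_s"),
      dd_dur = med("DD", "evaluator", "duration_s"),
      td_dur = med("TD", "evaluator", "duration_s"))
  }))
  # across-seed medians of the per-seed group medians land on the targets
  expect_lt(abs(median(meds[, "dd"]) - 3), 1)
  expect_lt(abs(median(meds[, "td"]) - 2.17), 1)
  expect_lt(abs(median(meds[, "dd_dur"]) - 1.88), 1)
  expect_lt(abs(median(meds[, "td_dur"]) - 1.73), 1)
})

test_that("landmark cohorts recover planted yaw through the pose module", {
  co <- smallCohort(seed = 9, withLandmarks = TRUE)
  subj <- subjects(co)[[1]]
  seg <- segments(subj)[[1]]
  fr <- frames(seg)
  if (nrow(fr)) {
    expect_true(all(is.na(fr$yaw_deg)))
    ann <- annotateFrames(seg)
    expect_true(all(!is.na(frames(ann)$yaw_deg)))
    # simulated responders face the caller: recovered yaw within threshold
    expect_true(all(abs(frames(ann)$yaw_deg) <= 12))
  }
  # feature extraction equal whether pose comes from landmarks or yaw
  co2 <- smallCohort(seed = 9, withLandmarks = FALSE)
  annotated <- Cohort(lapply(subjects(co), function(s)
    SubjectRecord(subjectId(s), groupLabel(s), s@ageMonths, s@sex,
                  lapply(segments(s), annotateFrames))),
    provenance = provenance(co))
  f1 <- cohortFeatures(annotated, strictPose = TRUE)
  f2 <- cohortFeatures(co2, strictPose = TRUE)
  expect_equal(f1$latency_s, f2$latency_s)
  expect_equal(f1$n_face_frames, f2$n_face_frames)
})
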