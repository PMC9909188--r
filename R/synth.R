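.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit substream seed from a master seed and a string key,
# so cohort content is independent of generation order.
.deriveSeed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

.qlnormTrunc <- function(p, meanlog, sdlog, upper) {
  stats::qlnorm(p * stats::plnorm(upper, meanlog, sdlog), meanlog, sdlog)
}

# meanlog such that the truncated-lognormal quantile `prob` equals `target`
.calibrateLatency <- function(target, prob, sdlog, upper = 10) {
  f <- function(mu) stats::plnorm(target, mu, sdlog) /
    stats::plnorm(upper, mu, sdlog) - prob
  stats::uniroot(f, lower = log(0.005), upper = log(50), tol = 1e-10)$root
}

#' Default group-conditional behavior parameters
#'
#' Per (group, procedure) simulation parameters. Non-response
#' probabilities come from the observed human score-0 proportions
#' (ASD 37/61 and 30/60, DD 6/31 and 5/31, TD 6/33 and 4/32 for the
#' evaluator and caregiver procedures). Responder latency is truncated
#' log-normal and duration is gamma, with parameters solved so the
#' *overall* medians (non-responders imputed at 10 s latency and 0 s
#' duration) land on the published group medians where those are not
#' already forced by a majority of non-responders (DD/TD latencies
#' 3 / 2.17 / 2.00 / 1.80 s; durations 1.88 / 1.73 / 1.00 / 1.45 s).
#' ASD responder distributions are not identifiable from imputation-
#' dominated overall medians and are fixed at a plausible responder
#' median (4 s latency, 1.2 s duration). The partial-response
#' probability (head turn without eye contact, human score 1) comes from
#' the observed score-1 share among responders.
#'
#' @param latencySdlog log-sd of the responder latency distribution.
#' @param durationShape gamma shape of the responder duration.
#' @return Nested list `params[[group]][[procedure]]`, each entry holding
#'   `p_respond`, `latency_meanlog`, `latency_sdlog`, `duration_shape`,
#'   `duration_scale`, `p_partial_response`, `first_call_s`,
#'   `inter_call_gap_s`, `p_precall_face`, `precall_duration_s`.
#' @export
defaultBehaviorParams <- function(latencySdlog = 0.8, durationShape = 2) {
  pRespond <- list(
    ASD = c(evaluator = 24 / 61, caregiver = 30 / 60),
    DD  = c(evaluator = 25 / 31, caregiver = 26 / 31),
    TD  = c(evaluator = 27 / 33, caregiver = 28 / 32))
  pPartial <- list(
    ASD = c(evaluator = 2 / 24, caregiver = 3 / 30),
    DD  = c(evaluator = 2 / 25, caregiver = 1 / 26),
    TD  = c(evaluator = 0, caregiver = 0))
  latMedian <- list(ASD = c(evaluator = NA, caregiver = NA),
                    DD = c(evaluator = 3, caregiver = 2.00),
                    TD = c(evaluator = 2.17, caregiver = 1.80))
  durMedian <- list(ASD = c(evaluator = NA, caregiver = NA),
                    DD = c(evaluator = 1.88, caregiver = 1.00),
                    TD = c(evaluator = 1.73, caregiver = 1.45))
  out <- list()
  for (g in .GROUPS) {
    out[[g]] <- list()
    for (proc in .PROCEDURES) {
      p <- pRespond[[g]][[proc]]
      lm <- latMedian[[g]][[proc]]
      dm <- durMedian[[g]][[proc]]
      # overall latency median m solves p * F_trunc(m) = 0.5
      latProb <- if (is.na(lm)) 0.5 else 0.5 / p
      latTarget <- if (is.na(lm)) 4 else lm
      meanlog <- .calibrateLatency(latTarget, min(latProb, 0.98),
                                   latencySdlog)
      # overall duration median d solves (1 - p) + p * F(d) = 0.5
      durProb <- if (is.na(dm)) 0.5 else (0.5 - (1 - p)) / p
      durTarget <- if (is.na(dm) || durProb < 0.02) 1.2 else dm
      if (is.na(dm) || durProb < 0.02) durProb <- 0.5
      scale <- durTarget / stats::qgamma(durProb, shape = durationShape)
      out[[g]][[proc]] <- list(
        p_respond = p, latency_meanlog = meanlog,
        latency_sdlog = latencySdlog, duration_shape = durationShape,
        duration_scale = scale,
        p_partial_response = pPartial[[g]][[proc]],
        first_call_s = 3, inter_call_gap_s = 3,
        p_precall_face = 0.3, precall_duration_s = 0.5)
    }
  }
  out
}

#' Cohort simulation design
#'
#' Defaults reproduce the study conditions: 61 ASD, 31 DD, 33 TD toddlers,
#' two call procedures each, one ASD and one TD caregiver segment absent
#' (leaving 123 subjects with both procedures), 30 fps.
#'
#' @param nASD,nDD,nTD group sizes.
#' @param missingCaregiver named counts of subjects per group lacking the
#'   caregiver segment.
#' @param quotaMode plant exactly `round(n * (1 - p_respond))`
#'   non-responders per group x procedure instead of Bernoulli draws.
#' @param frameRate frames per second.
#' @param withLandmarks emit 68-point landmark streams (yaw left for
#'   [annotateFrames()] to fill) instead of precomputed `yaw_deg`.
#' @param seed master seed.
#' @return List of class `"CohortDesign"`.
#' @export
cohortDesign <- function(nASD = 61, nDD = 31, nTD = 33,
                         missingCaregiver = c(ASD = 1, DD = 0, TD = 1),
                         quotaMode = FALSE, frameRate = 30,
                         withLandmarks = FALSE, seed = 0) {
  n <- c(ASD = nASD, DD = nDD, TD = nTD)
  stopifnot(all(n >= 0), all(missingCaregiver[names(n)] <= n | n == 0))
  structure(list(n = n, missingCaregiver = missingCaregiver,
                 quotaMode = quotaMode, frameRate = frameRate,
                 withLandmarks = withLandmarks, seed = seed),
            class = "CohortDesign")
}

.simulateSegment <- function(sid, proc, p, responded, rate, withLandmarks,
                             template) {
  t0 <- p$first_call_s
  gap <- p$inter_call_gap_s
  if (responded) {
    latency <- .qlnormTrunc(stats::runif(1), p$latency_meanlog,
                            p$latency_sdlog, upper = 9.9)
    duration <- max(2 / rate, min(stats::rgamma(1, shape = p$duration_shape,
                                                scale = p$duration_scale), 12))
    nCalls <- min(3L, floor(latency / gap) + 1L)
  } else {
    latency <- NA_real_; duration <- 0; nCalls <- 3L
  }
  callTimes <- t0 + gap * (seq_len(nCalls) - 1)
  events <- data.frame(t_call = callTimes, caller = proc,
                       call_index = seq_len(nCalls))
  frames <- NULL
  if (stats::runif(1) < p$p_precall_face) {
    kEnd <- floor((t0 - 0.5) * rate)
    nPre <- max(1L, round(p$precall_duration_s * rate))
    kStart <- max(0L, kEnd - nPre + 1L)
    frames <- data.frame(frame_index = kStart:kEnd, face_present = TRUE,
                         identity_match = TRUE, yaw_deg = 0)
  }
  if (responded) {
    k0 <- ceiling((t0 + latency) * rate)
    nResp <- max(1L, round(duration * rate))
    yaw <- stats::runif(nResp, -10, 10)
    frames <- rbind(frames,
                    data.frame(frame_index = k0 + seq_len(nResp) - 1L,
                               face_present = TRUE, identity_match = TRUE,
                               yaw_deg = yaw))
  }
  if (!is.null(frames) && withLandmarks) {
    frames$landmarks <- lapply(frames$yaw_deg, function(y)
      projectLandmarks(template, yaw = y, scale = 2,
                       translation = c(320, 240)))
    frames$yaw_deg <- NA_real_
  }
  segLen <- max(t0 + 13,
                if (responded) t0 + latency + duration + 1 else 0,
                if (!is.null(frames)) (max(frames$frame_index) + 1) / rate else 0)
  list(segment = ProcedureSegment(sid, proc, events = events,
                                  frames = frames, frameRate = rate,
                                  segmentLength = segLen),
       truth = data.frame(subject_id = sid, procedure = proc,
                          responded = responded, latency_s = latency,
                          duration_s = duration, stringsAsFactors = FALSE))
}

#' Generate a synthetic response-to-name cohort
#'
#' Per subject and procedure: the first call at 3 s, further calls at 3 s
#' gaps (non-responders receive all three calls); responders get a
#' qualifying frontal, identity-matched face run starting one frame-grid
#' tick after first call + latency and lasting the drawn duration;
#' optional pre-call face noise exercises the validity rule that only
#' post-call detections count. Bit-identical output for identical
#' (design, seed); per-subject substreams make the content independent of
#' generation order. The planted per-segment ground truth is stored in
#' `provenance(cohort)$truth`.
#'
#' @param design a [cohortDesign()].
#' @param params parameter set from [defaultBehaviorParams()].
#' @param seed master seed (defaults to `design$seed`).
#' @return A [Cohort-class].
#' @export
generateCohort <- function(design = cohortDesign(),
                           params = defaultBehaviorParams(),
                           seed = design$seed) {
  stopifnot(inherits(design, "CohortDesign"))
  rate <- design$frameRate
  template <- if (design$withLandmarks) canonicalFaceTemplate() else NULL
  plan <- list()
  for (g in names(design$n)) {
    ng <- design$n[[g]]
    if (ng == 0) next
    nMiss <- design$missingCaregiver[[g]]
    for (i in seq_len(ng)) {
      sid <- sprintf("%s%03d", g, i)
      procs <- if (i <= nMiss) "evaluator" else .PROCEDURES
      plan[[sid]] <- list(sid = sid, group = g, procs = procs)
    }
  }
  # responder flags: quota mode plants exact counts per group x procedure
  flags <- list()
  for (g in names(design$n)) {
    for (proc in .PROCEDURES) {
      elig <- names(plan)[vapply(plan, function(s)
        s$group == g && proc %in% s$procs, TRUE)]
      if (!length(elig)) next
      p <- params[[g]][[proc]]$p_respond
      if (design$quotaMode) {
        nNon <- round(length(elig) * (1 - p))
        non <- .withSeed(.deriveSeed(seed, paste0("quota/", g, "/", proc)),
                         sample(elig, nNon))
        resp <- !(elig %in% non)
      } else {
        resp <- .withSeed(.deriveSeed(seed, paste0("bern/", g, "/", proc)),
                          stats::runif(length(elig)) < p)
      }
      for (j in seq_along(elig))
        flags[[paste0(elig[j], "/", proc)]] <- resp[j]
    }
  }
  subjects <- list(); truths <- list()
  for (s in plan) {
    sub <- .withSeed(.deriveSeed(seed, paste0("subj/", s$sid)), {
      age <- min(30, max(16, round(stats::rnorm(1, 25, 3.5), 1)))
      sex <- if (stats::runif(1) < 0.84) "M" else "F"
      segs <- list(); tr <- list()
      for (proc in s$procs) {
        sim <- .simulateSegment(s$sid, proc, params[[s$group]][[proc]],
                                flags[[paste0(s$sid, "/", proc)]], rate,
                                design$withLandmarks, template)
        segs[[proc]] <- sim$segment
        tr[[proc]] <- sim$truth
      }
      list(rec = SubjectRecord(s$sid, s$group, age, sex, segs),
           truth = do.call(rbind, tr))
    })
    subjects[[length(subjects) + 1L]] <- sub$rec
    truths[[length(truths) + 1L]] <- sub$truth
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  Cohort(subjects,
         provenance = list(generator = "rtnscreen", seed = seed,
                           quota_mode = design$quotaMode, truth = truth))
}

#' Simulated human rater scores
#'
#' Requires a cohort generated by [generateCohort()] (the planted truth in
#' its provenance). Non-responders score 0; responders score 2 except
#' with the group's partial-response probability they score 1 (head turn
#' without eye contact). Deterministic given the seed.
#'
#' @param cohort a generated [Cohort-class].
#' @param params parameter set from [defaultBehaviorParams()].
#' @param seed RNG seed.
#' @return data.frame `subject_id`, `procedure`, `score`, `source`.
#' @export
generateHumanScores <- function(cohort, params = defaultBehaviorParams(),
                                seed = 0) {
  truth <- provenance(cohort)$truth
  if (is.null(truth))
    stop("cohort carries no planted truth; generate it with generateCohort()")
  groups <- vapply(subjects(cohort), groupLabel, character(1))
  names(groups) <- subjectIds(cohort)
  pPart <- mapply(function(sid, proc)
    params[[groups[[sid]]]][[proc]]$p_partial_response,
    truth$subject_id, truth$procedure)
  partial <- .withSeed(.deriveSeed(seed, "human-scores"),
                       stats::runif(nrow(truth)) < pPart)
  data.frame(subject_id = truth$subject_id, procedure = truth$procedure,
             score = ifelse(!truth$responded, 0L, ifelse(partial, 1L, 2L)),
             source = "human", stringsAsFactors = FALSE)
}

#' Perturb a rater's scores to emulate a second rater
#'
#' Each score is independently replaced, with the given probability, by a
#' different score drawn uniformly from the remaining valid levels.
#'
#' @param scores integer scores.
#' @param disagreementRate probability of replacement in `[0, 1]`.
#' @param seed RNG seed.
#' @param levels valid score levels.
#' @return Perturbed score vector.
#' @export
perturbRater <- function(scores, disagreementRate, seed = 0,
                         levels = c(0L, 1L, 2L)) {
  stopifnot(disagreementRate >= 0, disagreementRate <= 1)
  .withSeed(.deriveSeed(seed, "rater-perturb"), {
    flip <- stats::runif(length(scores)) < disagreementRate
    out <- scores
    for (i in which(flip)) {
      alt <- setdiff(levels, scores[i])
      out[i] <- if (length(alt) == 1L) alt else sample(alt, 1)
    }
    out
  })
}
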