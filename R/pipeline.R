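#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run. All randomness derives
#' from `seed` (cohort generation, simulated raters) and `cvSeed` (fold
#' shuffle), so a run is a deterministic function of its configuration.
#'
#' @param seed master seed for simulation.
#' @param quotaMode plant exact non-responder counts (see
#'   [cohortDesign()]).
#' @param latThreshold,durThreshold machine-score thresholds (s), see
#'   [ruleScore()].
#' @param facingThreshold head-yaw facing threshold (degrees).
#' @param k,cvSeed cross-validation folds and fold-shuffle seed.
#' @param requireBoth restrict the joint analysis to subjects with both
#'   procedures.
#' @param method joint classifier method ("tree" or "or").
#' @param jointFeatures features fed to the joint classifier: `"raw"`
#'   (default; the four latency/duration features) or `"scores"` (the two
#'   per-procedure machine scores, which reproduces an OR-of-non-response
#'   operating point).
#' @param raterDisagreement second-rater perturbation rate for the
#'   reliability block.
#' @param durationCap duration saturation (s) in [riskScore()].
#' @param outDir when non-NULL, write `features.csv`, `predictions.csv`
#'   and `report.json` there.
#' @return List of class `"RunConfig"`.
#' @export
runConfig <- function(seed = 0, quotaMode = FALSE, latThreshold = 10,
                      durThreshold = 0.5, facingThreshold = 30, k = 10,
                      cvSeed = 0, requireBoth = TRUE, method = "tree",
                      jointFeatures = c("raw", "scores"),
                      raterDisagreement = 0.02, durationCap = 3,
                      outDir = NULL) {
  stopifnot(k >= 2, latThreshold > 0, durThreshold > 0, facingThreshold > 0)
  jointFeatures <- match.arg(jointFeatures)
  structure(list(seed = seed, quotaMode = quotaMode,
                 latThreshold = latThreshold, durThreshold = durThreshold,
                 facingThreshold = facingThreshold, k = k, cvSeed = cvSeed,
                 requireBoth = requireBoth, method = method,
                 jointFeatures = jointFeatures,
                 raterDisagreement = raterDisagreement,
                 durationCap = durationCap, outDir = outDir),
            class = "RunConfig")
}

.scoreWide <- function(scores, ids) {
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (proc in .PROCEDURES) {
    ss <- scores[scores$procedure == proc, , drop = FALSE]
    out[[paste0("score_", proc)]] <-
      ss$score[match(ids, ss$subject_id)]
  }
  out
}

#' Run the full response-to-name analysis pipeline
#'
#' simulate (or accept) a cohort -> extract latency/duration features ->
#' machine and simulated human scoring -> rating agreement and
#' reliability -> group comparisons -> joint cross-validated ASD
#' classification for both rating sources -> confusion metrics, ROC/AUC,
#' DeLong comparison of the two correlated ROC curves, and the chi-square
#' comparison of overall accuracies.
#'
#' @param config a [runConfig()].
#' @param cohort optional pre-built [Cohort-class]; when NULL a cohort is
#'   generated from the default design with `config$seed`.
#' @param params behavior parameters for simulation-derived blocks.
#' @param verbose emit progress messages.
#' @return The report as a nested list (invisibly written to
#'   `config$outDir` when set), with blocks `meta`, `agreement`,
#'   `reliability`, `group_comparisons`, `confusion`, `roc`, `delong`,
#'   `chi_square`.
#' @export
runPipeline <- function(config = runConfig(), cohort = NULL,
                        params = defaultBehaviorParams(), verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(...) if (verbose) message(...)
  if (is.null(cohort)) {
    say("simulating cohort (seed ", config$seed, ", quota_mode ",
        config$quotaMode, ")")
    cohort <- generateCohort(cohortDesign(quotaMode = config$quotaMode,
                                          seed = config$seed), params)
  }
  say("extracting features (facing threshold ", config$facingThreshold,
      " deg)")
  features <- cohortFeatures(cohort, facingThreshold = config$facingThreshold)
  mScores <- machineScores(features, config$latThreshold, config$durThreshold)
  hScores <- generateHumanScores(cohort, params, seed = config$seed)
  h2 <- perturbRater(hScores$score, config$raterDisagreement,
                     seed = config$seed)

  # agreement between machine and human scores, per group x procedure
  key <- function(d) paste(d$subject_id, d$procedure)
  hMatch <- hScores$score[match(key(mScores), key(hScores))]
  groups <- vapply(subjects(cohort), groupLabel, character(1))
  names(groups) <- subjectIds(cohort)
  mGroup <- groups[mScores$subject_id]
  agree <- list(); rates <- c(); ns <- c()
  for (g in .GROUPS) for (proc in .PROCEDURES) {
    sel <- mGroup == g & mScores$procedure == proc
    if (!any(sel)) next
    r <- agreementRate(mScores$score[sel], hMatch[sel])
    agree[[paste(g, proc, sep = "_")]] <- list(rate = r, n = sum(sel))
    rates <- c(rates, r); ns <- c(ns, sum(sel))
  }
  agreement <- list(by_group = agree,
                    pooled = pooledAgreement(rates, ns),
                    n_total = sum(ns))
  reliability <- list(
    cronbach_alpha = cronbachAlpha(cbind(hScores$score, h2)),
    disagreement_rate = config$raterDisagreement)

  say("group comparisons")
  comparisons <- lapply(stats::setNames(.PROCEDURES, .PROCEDURES),
                        function(proc)
    compareGroupsReport(features, proc, config$latThreshold,
                        config$durThreshold))

  say("joint classification (", config$k, "-fold CV, seed ",
      config$cvSeed, ")")
  wide <- widenFeatures(features, requireBoth = config$requireBoth)
  labels <- wide$group == "ASD"
  X <- if (identical(config$jointFeatures, "scores")) {
    mw <- .scoreWide(mScores, wide$subject_id)
    as.matrix(mw[, c("score_evaluator", "score_caregiver")])
  } else {
    as.matrix(wide[, c("latency_evaluator", "latency_caregiver",
                       "duration_evaluator", "duration_caregiver")])
  }
  cv <- crossvalPredict(X, labels, ids = wide$subject_id,
                        k = config$k, seed = config$cvSeed,
                        method = config$method)
  tabC <- diagnose(cv$predicted, cv$label)

  hWide <- .scoreWide(hScores, wide$subject_id)
  h2Wide <- .scoreWide(
    data.frame(hScores[, c("subject_id", "procedure")], score = h2),
    wide$subject_id)
  # human analysis uses the mean of the two simulated raters' scores
  hFeat <- cbind(score_evaluator =
                   (hWide$score_evaluator + h2Wide$score_evaluator) / 2,
                 score_caregiver =
                   (hWide$score_caregiver + h2Wide$score_caregiver) / 2)
  cvH <- crossvalPredict(hFeat, labels, ids = wide$subject_id,
                         k = config$k, seed = config$cvSeed,
                         method = config$method)
  tabH <- diagnose(cvH$predicted, cvH$label)

  say("ROC / DeLong / chi-square")
  riskC <- riskScore(wide, config$durationCap)
  riskH <- 1 - (hFeat[, 1] + hFeat[, 2]) / 4
  rocC <- aucMannWhitney(riskC, labels)
  rocH <- aucMannWhitney(riskH, labels)
  dl <- delongTest(riskH, riskC, labels)
  correct <- c(tabC$tp + tabC$tn, tabH$tp + tabH$tn)
  incorrect <- c(tabC$fp + tabC$fn, tabH$fp + tabH$fn)
  chi <- pearsonChi2(cbind(correct, incorrect))

  report <- list(
    meta = list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                seed = config$seed, cv_seed = config$cvSeed,
                k = config$k, lat_threshold_s = config$latThreshold,
                dur_threshold_s = config$durThreshold,
                facing_threshold_deg = config$facingThreshold,
                quota_mode = config$quotaMode,
                n_subjects = nSubjects(cohort),
                n_joint = nrow(wide)),
    agreement = agreement,
    reliability = reliability,
    group_comparisons = comparisons,
    confusion = list(
      computer = c(list(tp = tabC$tp, fn = tabC$fn, fp = tabC$fp,
                        tn = tabC$tn), confusionMetrics(tabC)),
      human = c(list(tp = tabH$tp, fn = tabH$fn, fp = tabH$fp,
                     tn = tabH$tn), confusionMetrics(tabH))),
    roc = list(computer = unclass(rocC), human = unclass(rocH)),
    delong = dl,
    chi_square = chi)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(features, file.path(config$outDir, "features.csv"),
                     row.names = FALSE)
    preds <- data.frame(cv[, c("subject_id", "fold")],
                        predicted_label = ifelse(cv$predicted, "ASD",
                                                 "non-ASD"),
                        risk_score = riskC[match(cv$subject_id,
                                                 wide$subject_id)])
    utils::write.csv(preds, file.path(config$outDir, "predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    say("wrote report to ", file.path(config$outDir, "report.json"))
  }
  invisible(report)
}

#' Bundled reference diagnosis outcomes
#'
#' 2x2 predicted-vs-clinical contingency counts (123 toddlers; 60 ASD, 63
#' non-ASD) from the original clinical deployment of this kind of
#' response-to-name screen, for the computer-rated and human-rated
#' classifiers. Packaged as plain-text regression fixtures so the
#' headline diagnostic metrics are testable without simulation.
#'
#' @param source "computer" or "human".
#' @return A [diagnosisTable()].
#' @export
referenceDiagnosisTable <- function(source = c("computer", "human")) {
  source <- match.arg(source)
  path <- system.file("extdata",
                      paste0("reference_diagnosis_", source, ".csv"),
                      package = "rtnscreen", mustWork = TRUE)
  d <- utils::read.csv(path)
  diagnosisTable(d$tp, d$fn, d$fp, d$tn)
}
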