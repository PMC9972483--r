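# End-to-end orchestration: simulate -> contrastive embedding -> patch
# graphs -> model training -> evaluation -> interpretability, plus the
# cross-validation and ablation protocols.

.GT_TARGET <- list(PMI1 = 3L, PMI2 = 3L, PF1 = 3L, PF2 = 3L,
                   CCI1 = 2L, CCI2 = 2L, NNI1 = c(2L, 3L))

#' Experiment configuration
#'
#' Bundles every knob of a synthetic-cohort experiment. Defaults are the
#' desk-scale settings used by the test suite; the full-scale cohort
#' (80 patients/type, 800 x 800 px) is obtained by raising `n_per_type`
#' and `image_size`.
#'
#' @param paradigm disease paradigm (see [applyParadigm()]).
#' @param n_per_type patients per type.
#' @param image_size (height, width) px.
#' @param train_fraction fraction of patients (stratified) used for
#'   training+validation; the rest is the test set.
#' @param n_runs independent train/test runs averaged in the report.
#' @param search_trials architecture-search trials on the training split
#'   (0 = train the supplied model config directly).
#' @param search_epochs training epochs per search trial.
#' @param pcl a [pclConfig()].
#' @param model a [modelConfig()].
#' @param interpret_images max test images used for the interpretability
#'   overlap (pixel pooling across images).
#' @param seed global seed; all stage seeds derive from it.
#' @param out_dir optional output directory for the report and figures.
#' @return classed list `"ExperimentConfig"`.
#' @export
experimentConfig <- function(paradigm = "CCI1", n_per_type = 20L,
                             image_size = c(300L, 300L),
                             train_fraction = 0.5, n_runs = 1L,
                             search_trials = 0L, search_epochs = 40L,
                             pcl = pclConfig(), model = modelConfig(),
                             interpret_images = 12L, seed = 1L,
                             out_dir = NULL) {
  structure(list(paradigm = paradigm, n_per_type = as.integer(n_per_type),
                 image_size = as.integer(image_size),
                 train_fraction = train_fraction, n_runs = as.integer(n_runs),
                 search_trials = as.integer(search_trials),
                 search_epochs = as.integer(search_epochs),
                 pcl = pcl, model = model,
                 interpret_images = as.integer(interpret_images),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "ExperimentConfig")
}

# stratified train/test split of patient indices
.splitCohort <- function(types, frac, seed) {
  .withSeed(seed, {
    tr <- integer(0)
    for (tp in unique(types)) {
      idx <- which(types == tp)
      tr <- c(tr, sample(idx, round(length(idx) * frac)))
    }
    sort(tr)
  })
}

.embedCohort <- function(cohort, encoder) {
  lapply(seq_along(cohort$tissues), function(i) {
    tt <- cohort$tissues[[i]]
    embedImage(tt$image, encoder, imageId = tt$patientId)
  })
}

.cohortGraphs <- function(embedded, cohort) {
  lapply(seq_along(embedded), function(i)
    buildPatchGraph(embedded[[i]], label = cohort$tissues[[i]]$patientType,
                    patientId = cohort$tissues[[i]]$patientId))
}

# pooled interpretability overlap of flagged neighborhood TMEs vs the
# paradigm-defining ground-truth neighborhood(s), over a set of images
.overlapOnImages <- function(model, embedded, cohort, idx, flaggedN, gtIds) {
  inter <- 0; gtTot <- 0
  S <- embedded[[1]]@patchSize
  for (i in idx) {
    emb <- embedded[[i]]
    gs <- gridShape(emb)
    gr <- buildPatchGraph(emb, label = cohort$tissues[[i]]$patientType,
                          patientId = cohort$tissues[[i]]$patientId)
    asg <- assignTMEs(model, gr)
    if (is.null(asg$SN)) next
    gt <- neighborhoodMask(cohort$tissues[[i]]$truth)
    gt <- gt[seq_len(gs[1] * S), seq_len(gs[2] * S)] %in% gtIds
    gt <- matrix(gt, gs[1] * S)
    if (length(flaggedN)) {
      masks <- lapply(flaggedN, function(t) mapTMEToImage(asg$SN, emb, t))
      u <- Reduce(`|`, masks)
      inter <- inter + sum(u & gt)
    }
    gtTot <- gtTot + sum(gt)
  }
  if (gtTot == 0) return(NA_real_)
  100 * inter / gtTot
}

#' Run a synthetic-cohort experiment end to end
#'
#' Simulates (or reuses) a cohort, then for each run: splits patients into
#' stratified train/test halves, trains the contrastive encoder on the
#' training images only, embeds all images, builds patch graphs, optionally
#' performs an architecture search on the training split, trains the model
#' and evaluates test accuracy. Interpretability is quantified as the
#' pooled pixel overlap between the union of differentially significant
#' learned neighborhoods and the paradigm-defining ground-truth
#' neighborhood, on test images. Results are averaged over `n_runs`
#' (95% CI = mean +/- 1.96 sd / sqrt(n)).
#'
#' @param cfg an [experimentConfig()].
#' @param cohort optional pre-simulated `SyntheticCohort` (reused across
#'   ablation arms so comparisons are paired).
#' @param verbose print stage progress.
#' @return report list: per-run and aggregate accuracy with CI,
#'   interpretability overlap, contrast accuracy, chosen configs, seeds.
#' @export
runSyntheticExperiment <- function(cfg, cohort = NULL, verbose = FALSE) {
  t0 <- proc.time()[3]
  if (is.null(cohort))
    cohort <- simulateCohort(cfg$paradigm, cfg$n_per_type, cfg$image_size,
                             seed = cfg$seed)
  types <- vapply(cohort$tissues, `[[`, "", "patientType")
  runs <- list()
  for (r in seq_len(cfg$n_runs)) {
    runSeed <- deriveSeed(cfg$seed, 5000L + r)
    tr <- .splitCohort(types, cfg$train_fraction, runSeed)
    te <- setdiff(seq_along(types), tr)
    if (verbose) message(sprintf("run %d: %d train / %d test", r,
                                 length(tr), length(te)))
    pclCfg <- cfg$pcl
    pclCfg$seed <- deriveSeed(runSeed, 1L)
    pclFit <- trainPCL(lapply(cohort$tissues[tr], `[[`, "image"), pclCfg)
    embedded <- .embedCohort(cohort, pclFit$encoder)
    graphs <- .cohortGraphs(embedded, cohort)

    mCfg <- cfg$model
    mCfg$seed <- deriveSeed(runSeed, 2L)
    if (cfg$search_trials > 0) {
      sr <- searchArchitecture(graphs[tr], nTrials = cfg$search_trials,
                               epochs = cfg$search_epochs,
                               seed = deriveSeed(runSeed, 3L),
                               baseConfig = mCfg)
      mCfg <- sr$best
      mCfg$epochs <- cfg$model$epochs
      mCfg$seed <- deriveSeed(runSeed, 4L)
    }
    model <- trainTMEModel(graphs[tr], mCfg, verbose = verbose)
    predAll <- predictTMEModel(model, graphs)
    acc <- mean(predAll$predicted[te] == types[te])

    interp <- NA_real_
    flaggedN <- integer(0)
    if (model@config$use_neighborhoods &&
        cfg$paradigm %in% names(.GT_TARGET)) {
      diffT <- differentialTMEAnalysis(model, predAll$abundance, types)
      flagged <- diffT$tme[diffT$flagged]
      flaggedN <- as.integer(sub("^N", "", grep("^N", flagged, value = TRUE)))
      evalIdx <- te[seq_len(min(cfg$interpret_images, length(te)))]
      interp <- .overlapOnImages(model, embedded, cohort, evalIdx, flaggedN,
                                 .GT_TARGET[[cfg$paradigm]])
    } else diffT <- NULL

    runs[[r]] <- list(accuracy = acc, interpretability = interp,
                      contrast_accuracy = pclFit$contrastAccuracy,
                      model = model, differential = diffT,
                      flagged_neighborhoods = flaggedN,
                      train_idx = tr, test_idx = te, seed = runSeed,
                      abundance = predAll$abundance, labels = types)
  }
  accs <- vapply(runs, `[[`, 0, "accuracy")
  interps <- vapply(runs, `[[`, 0, "interpretability")
  cas <- vapply(runs, `[[`, 0, "contrast_accuracy")
  ciHalf <- if (length(accs) > 1) 1.96 * stats::sd(accs) / sqrt(length(accs))
  else NA_real_
  report <- list(paradigm = cfg$paradigm,
                 accuracy = mean(accs), accuracy_runs = accs,
                 accuracy_ci95 = c(mean(accs) - ciHalf, mean(accs) + ciHalf),
                 interpretability = mean(interps, na.rm = TRUE),
                 interpretability_runs = interps,
                 contrast_accuracy = mean(cas),
                 n_runs = cfg$n_runs, seed = cfg$seed,
                 n_patients = length(types),
                 image_size = cfg$image_size,
                 elapsed_s = unname(proc.time()[3] - t0),
                 runs = runs)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    slim <- report[setdiff(names(report), "runs")]
    jsonlite::write_json(slim, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(config = unclass(cfg[setdiff(names(cfg), c("pcl", "model"))]),
                     pcl = unclass(cfg$pcl), model = unclass(cfg$model),
                     run_seeds = vapply(runs, `[[`, 0L, "seed"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    r1 <- runs[[1]]
    if (!is.null(r1$differential))
      renderReports(list(differential = r1$differential,
                         abundance = r1$abundance,
                         labels = r1$labels), cfg$out_dir)
  }
  report
}

#' Run an ablation arm
#'
#' Disables one learning module (its subnetwork, its losses, and its block
#' of the classifier input) and reruns the experiment protocol, reusing
#' the same simulated cohort so the comparison is paired.
#'
#' @param cfg an [experimentConfig()].
#' @param drop `"phenotype"`, `"neighborhood"` or `"area"`.
#' @param cohort optional pre-simulated cohort (paired comparisons).
#' @param verbose print progress.
#' @return the [runSyntheticExperiment()] report for the ablated model.
#' @export
runAblation <- function(cfg, drop = c("phenotype", "neighborhood", "area"),
                        cohort = NULL, verbose = FALSE) {
  drop <- match.arg(drop)
  m <- cfg$model
  if (drop == "phenotype") m$use_phenotypes <- FALSE
  if (drop == "neighborhood") m$use_neighborhoods <- FALSE
  if (drop == "area") m$use_areas <- FALSE
  m <- do.call(modelConfig, unclass(m))
  cfg$model <- m
  runSyntheticExperiment(cfg, cohort = cohort, verbose = verbose)
}

#' Stratified k-fold cross-validation (optionally nested)
#'
#' Splits patients into stratified outer folds. Per outer fold, an
#' optional inner architecture search (random search scored on inner
#' validation splits of the training patients only) selects the model
#' configuration, which is then trained on the outer-fold training set
#' and evaluated on the held-out fold. With multiple graphs per patient
#' (image-wise mode), patient-wise predictions are the mean of the
#' patient's image probabilities.
#'
#' @param graphs list of labeled [PatchGraph-class]; multiple graphs may
#'   share a patientId (image-wise input).
#' @param k number of outer folds.
#' @param searchTrials inner search trials (0 = use `baseConfig`).
#' @param baseConfig a [modelConfig()].
#' @param patientWise aggregate image probabilities per patient.
#' @param seed integer seed.
#' @return list: `fold_metrics` data.frame, `accuracy` (overall),
#'   `predictions` data.frame.
#' @export
runCrossValidation <- function(graphs, k = 5L, searchTrials = 0L,
                               baseConfig = modelConfig(),
                               patientWise = FALSE, seed = 1L) {
  labels <- vapply(graphs, patientLabel, "")
  pids <- vapply(graphs, patientId, "")
  units <- unique(pids)                        # fold by patient, never image
  uLab <- labels[match(units, pids)]
  folds <- .withSeed(seed, {
    f <- integer(length(units))
    for (cl in unique(uLab)) {
      idx <- sample(which(uLab == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  classes <- sort(unique(labels))
  preds <- list(); fm <- list()
  for (fold in seq_len(k)) {
    teU <- units[folds == fold]
    trIdx <- which(!(pids %in% teU))
    teIdx <- which(pids %in% teU)
    if (length(unique(labels[trIdx])) < 2 ||
        length(unique(labels[teIdx])) < 1)
      .stopf("fold %d is degenerate (single class); reduce k", fold)
    cfgF <- baseConfig
    cfgF$seed <- deriveSeed(seed, 10L + fold)
    if (searchTrials > 0) {
      sr <- searchArchitecture(graphs[trIdx], nTrials = searchTrials,
                               seed = deriveSeed(seed, 100L + fold),
                               baseConfig = baseConfig)
      cfgF <- sr$best
      cfgF$seed <- deriveSeed(seed, 10L + fold)
    }
    model <- trainTMEModel(graphs[trIdx], cfgF)
    pr <- predictTMEModel(model, graphs[teIdx])
    probs <- pr$probs
    if (patientWise) {
      agg <- rowsum(probs, pids[teIdx]) /
        as.vector(table(pids[teIdx])[unique(pids[teIdx])])
      agg <- agg[match(sort(unique(pids[teIdx])), rownames(agg)), ,
                 drop = FALSE]
      pLab <- labels[match(rownames(agg), pids)]
      pred <- classes[max.col(agg, ties.method = "first")]
      preds[[fold]] <- data.frame(fold = fold, unit = rownames(agg),
                                  label = pLab, predicted = pred)
      fm[[fold]] <- data.frame(fold = fold, n = nrow(agg),
                               accuracy = mean(pred == pLab))
    } else {
      pred <- pr$predicted
      preds[[fold]] <- data.frame(fold = fold, unit = pids[teIdx],
                                  label = labels[teIdx], predicted = pred)
      fm[[fold]] <- data.frame(fold = fold, n = length(teIdx),
                               accuracy = mean(pred == labels[teIdx]))
    }
  }
  allPred <- do.call(rbind, preds)
  list(fold_metrics = do.call(rbind, fm),
       accuracy = mean(allPred$predicted == allPred$label),
       predictions = allPred)
}
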