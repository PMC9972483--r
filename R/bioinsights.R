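# Interpretability: which learned TMEs drive the predictions.
#
# Cohort level: leave-one-TME-out re-evaluation of the trained classifier
# with a Kruskal-Wallis rank test on the true-class probabilities
# (Bonferroni-adjusted across TMEs). Patient level: the predictive
# influence ratio PIR = p_full / p_leave-one-out. "Extracting" a TME means
# zeroing its abundance entry: f2 is a fixed trained map and both passes
# evaluate the same model.

#' Differential TME analysis
#'
#' Identifies cohort-level predictive TMEs with a leave-one-out strategy:
#' for every TME t, its abundance entry is zeroed in all patients'
#' vectors and the fixed trained classifier is re-evaluated. A TME is
#' flagged predictive when (a) its removal actually shifts the model's
#' predictions (a label-free usage screen; TMEs the classifier ignores
#' can never be flagged) and (b) its abundance differs across outcome
#' classes by a Kruskal-Wallis rank test after multiple-testing
#' adjustment (Bonferroni by default). A rank test comparing the full vs
#' leave-one-out true-class probability distributions is reported
#' alongside (`loo_p_value`).
#'
#' @param model a trained [TMEModel-class].
#' @param abundance patients x TMEs matrix (from [predictTMEModel()]).
#' @param labels character vector of true labels (length = patients).
#' @param alpha significance level after adjustment (default 0.05).
#' @param adjust `"bonferroni"` (default, the correction used throughout)
#'   or `"BH"`.
#' @return data.frame, one row per TME: tme, p_value (abundance vs class),
#'   p_adjusted, used (leave-one-out screen), flagged, direction (class
#'   with highest mean abundance), loo_p_value, and per-class mean
#'   abundances; sorted by adjusted p-value.
#' @export
differentialTMEAnalysis <- function(model, abundance, labels, alpha = 0.05,
                                    adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  classes <- model@classes
  .assertThat(length(unique(labels)) >= 2, "need at least 2 classes")
  y <- match(labels, classes)
  probsFull <- classifyAbundance(model, abundance)
  pFull <- probsFull[cbind(seq_along(y), y)]
  tmes <- colnames(abundance)
  looP <- numeric(length(tmes))
  classP <- numeric(length(tmes))
  used <- logical(length(tmes))
  for (t in seq_along(tmes)) {
    ab <- abundance
    ab[, t] <- 0
    probsLoo <- classifyAbundance(model, ab)
    used[t] <- max(abs(probsFull - probsLoo)) > 1e-8
    pLoo <- probsLoo[cbind(seq_along(y), y)]
    if (max(abs(pFull - pLoo)) < 1e-12) {
      looP[t] <- 1
    } else {
      looP[t] <- stats::kruskal.test(list(pFull, pLoo))$p.value
      if (!is.finite(looP[t])) looP[t] <- 1
    }
    if (stats::sd(abundance[, t]) < 1e-12) {
      classP[t] <- 1                     # degenerate abundance, no contrast
    } else {
      classP[t] <- stats::kruskal.test(abundance[, t], factor(labels))$p.value
      if (!is.finite(classP[t])) classP[t] <- 1
    }
  }
  pv <- classP
  padj <- pmin(stats::p.adjust(pv, method = if (adjust == "bonferroni")
    "bonferroni" else "BH"), 1)
  classMeans <- t(vapply(seq_along(tmes), function(t)
    vapply(classes, function(cl) mean(abundance[labels == cl, t]), 0),
    numeric(length(classes))))
  colnames(classMeans) <- paste0("mean_", classes)
  out <- data.frame(tme = tmes, p_value = pv, p_adjusted = padj,
                    used = used, flagged = used & padj < alpha,
                    direction = classes[max.col(classMeans,
                                                ties.method = "first")],
                    loo_p_value = looP, stringsAsFactors = FALSE)
  out <- cbind(out, classMeans)
  out[order(out$p_adjusted, out$p_value), ]
}

#' Predictive influence ratio (PIR)
#'
#' The influence of TME t on one patient's prediction: the ratio of the
#' classifier's true-class probability with the full abundance vector to
#' the probability with TME t zeroed. PIR > 1 means the TME supported the
#' prediction. For unlabeled deployment pass the predicted class.
#'
#' @param model a trained [TMEModel-class].
#' @param abundance the patient's abundance vector (named by TME).
#' @param trueClass the patient's class label.
#' @param tme TME name or column index.
#' @return scalar PIR (> 0; `Inf` with a warning if the leave-one-out
#'   probability underflows to 0).
#' @export
predictiveInfluenceRatio <- function(model, abundance, trueClass, tme) {
  ci <- match(trueClass, model@classes)
  .assertThat(!is.na(ci), "unknown class '%s'", trueClass)
  if (is.character(tme)) tme <- match(tme, names(abundance))
  .assertThat(!is.na(tme) && tme >= 1 && tme <= length(abundance),
              "tme out of range")
  pFull <- unname(classifyAbundance(model, abundance)[ci])
  ab <- abundance; ab[tme] <- 0
  pLoo <- unname(classifyAbundance(model, ab)[ci])
  if (pLoo == 0) {
    warning("leave-one-out probability is 0; PIR reported as Inf")
    return(Inf)
  }
  pFull / pLoo
}

#' PIR table for a cohort
#'
#' @param model a trained [TMEModel-class].
#' @param abundance patients x TMEs matrix.
#' @param labels true class labels.
#' @return data.frame (patient x TME rows): patient_id, tme, pir,
#'   p_full, p_loo.
#' @export
pirTable <- function(model, abundance, labels) {
  y <- match(labels, model@classes)
  if (is.null(rownames(abundance)))
    rownames(abundance) <- paste0("patient", seq_len(nrow(abundance)))
  probs <- classifyAbundance(model, abundance)
  pFull <- probs[cbind(seq_along(y), y)]
  rows <- list()
  for (t in seq_len(ncol(abundance))) {
    ab <- abundance; ab[, t] <- 0
    pLoo <- classifyAbundance(model, ab)[cbind(seq_along(y), y)]
    rows[[t]] <- data.frame(patient_id = rownames(abundance),
                            tme = colnames(abundance)[t],
                            pir = ifelse(pLoo > 0, pFull / pLoo, Inf),
                            p_full = pFull, p_loo = pLoo)
  }
  do.call(rbind, rows)
}

#' Map a learned TME back onto the image
#'
#' A patch belongs to the mask iff the argmax of its assignment row equals
#' `tme`; the patch-resolution mask is upsampled to pixel resolution by
#' block replication (each patch becomes an S_L x S_L block).
#'
#' @param assignment L x C soft assignment matrix (e.g. `SN` from
#'   [assignTMEs()]), rows in row-major patch order.
#' @param embedded the [EmbeddedImage-class] the assignment belongs to.
#' @param tme TME column index (1-based).
#' @return logical pixel matrix of size `(rows*S_L) x (cols*S_L)`.
#' @export
mapTMEToImage <- function(assignment, embedded, tme) {
  .assertThat(tme >= 1 && tme <= ncol(assignment), "tme id out of range")
  gs <- gridShape(embedded)
  .assertThat(nrow(assignment) == prod(gs),
              "assignment rows do not match the patch grid")
  sel <- max.col(assignment, ties.method = "first") == tme
  patchMask <- matrix(sel, gs[1], gs[2], byrow = TRUE)  # row-major order
  S <- embedded@patchSize
  patchMask[rep(seq_len(gs[1]), each = S), rep(seq_len(gs[2]), each = S)]
}

#' Interpretability overlap with ground truth
#'
#' Percentage of the ground-truth region covered by the union of the
#' selected TME masks: `100 * |union(masks) ∩ GT| / |GT|`. Monotone
#' nondecreasing in the selected set.
#'
#' @param masks list of logical pixel masks (same size as `gtMask`), or a
#'   single mask.
#' @param gtMask logical (or 0/1) ground-truth mask.
#' @return overlap percentage in `[0, 100]`.
#' @export
interpretabilityOverlap <- function(masks, gtMask) {
  gt <- gtMask > 0
  .assertThat(sum(gt) > 0, "empty ground-truth mask")
  if (is.list(masks)) {
    u <- Reduce(`|`, masks)
  } else u <- masks > 0
  .assertThat(all(dim(u) == dim(gt)), "mask sizes differ")
  100 * sum(u & gt) / sum(gt)
}

#' Mean marker expression per learned TME
#'
#' For every learned TME, the mean raw marker intensity of the patches
#' whose argmax assignment is that TME -- the matrix behind the
#' TME-by-marker heatmaps.
#'
#' @param assignment L x C assignment matrix.
#' @param embedded the matching [EmbeddedImage-class].
#' @param image the source [MultiplexImage-class].
#' @return C x B matrix (TME x marker) of mean intensities (NA for TMEs
#'   with no assigned patch).
#' @export
tmeMarkerMatrix <- function(assignment, embedded, image) {
  a <- .asImageArray(image)
  S <- embedded@patchSize
  gs <- gridShape(embedded)
  rows <- gs[1]; cols <- gs[2]
  B <- dim(a)[3]
  a <- a[seq_len(rows * S), seq_len(cols * S), , drop = FALSE]
  arr <- array(a, c(S, rows, S, cols, B))
  pm <- apply(arr, c(2, 4, 5), mean)              # rows x cols x B
  patchMeans <- matrix(NA_real_, rows * cols, B)
  for (b in seq_len(B))
    patchMeans[, b] <- as.vector(t(pm[, , b]))    # row-major patch order
  amax <- max.col(assignment, ties.method = "first")
  out <- matrix(NA_real_, ncol(assignment), B)
  for (t in seq_len(ncol(assignment)))
    if (any(amax == t))
      out[t, ] <- colMeans(patchMeans[amax == t, , drop = FALSE])
  rownames(out) <- colnames(assignment)
  colnames(out) <- markerNames(image)
  out
}

#' Write interpretability report artifacts
#'
#' Writes (1) a z-scored TME-by-marker heatmap (pdf), (2) per-class
#' abundance boxplots for the top TMEs (pdf), (3) the differential-TME
#' table and the PIR table as CSV. TMEs are ordered by adjusted p-value.
#'
#' @param results list with elements `differential` (from
#'   [differentialTMEAnalysis()]), `pir` (from [pirTable()]), `abundance`,
#'   `labels`, and optionally `markerMatrix` (TME x marker).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
renderReports <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  dt <- results$differential
  dt <- dt[order(dt$p_adjusted, dt$p_value), ]
  f <- file.path(dir, "differential_tme.csv")
  utils::write.csv(dt, f, row.names = FALSE)
  paths <- c(paths, f)
  if (!is.null(results$pir)) {
    f <- file.path(dir, "pir.csv")
    utils::write.csv(results$pir, f, row.names = FALSE)
    paths <- c(paths, f)
  }
  if (!is.null(results$markerMatrix)) {
    mm <- results$markerMatrix
    keep <- rowSums(is.na(mm)) == 0 & apply(mm, 1, stats::sd) > 0
    mm <- mm[keep, , drop = FALSE]
    if (nrow(mm) >= 2) {
      z <- t(scale(t(mm)))
      f <- file.path(dir, "tme_marker_heatmap.pdf")
      grDevices::pdf(f, width = 6, height = 6)
      pheatmap::pheatmap(z, cluster_rows = FALSE, cluster_cols = FALSE,
                         main = "z-scored mean marker expression per TME")
      grDevices::dev.off()
      paths <- c(paths, f)
    }
  }
  if (!is.null(results$abundance)) {
    top <- utils::head(dt$tme[dt$flagged], 4)
    if (length(top)) {
      f <- file.path(dir, "abundance_by_class.pdf")
      grDevices::pdf(f, width = 2.5 * length(top), height = 3.5)
      op <- graphics::par(mfrow = c(1, length(top)))
      for (t in top)
        graphics::boxplot(results$abundance[, t] ~ factor(results$labels),
                          main = t, xlab = "class", ylab = "abundance")
      graphics::par(op)
      grDevices::dev.off()
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}
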