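# hand-built 2-class linear classifier over named TME abundances
linearModel <- function(W, classes = c("a", "b")) {
  cfg <- modelConfig(P = 2L, N = 2L, A = 2L)
  new("TMEModel",
      params = list(Wf = W, bf = matrix(0, 1, ncol(W)),
                    .featMu = rep(0, nrow(W)), .featSd = rep(1, nrow(W))),
      config = unclass(cfg), classes = classes,
      featureMean = 0, featureSd = 1, history = data.frame())
}

test_that("PIR is the exact full/leave-one-out probability ratio", {
  # TME 1 carries all discriminative weight; TMEs 2..4 are dead weight
  W <- rbind(c(2, -2), 0, 0, 0)
  rownames(W) <- paste0("T", 1:4)
  m <- linearModel(W)
  ab <- c(T1 = 1.5, T2 = 3, T3 = 0.5, T4 = 2)
  # zero-weight TME: removal changes nothing -> PIR exactly 1
  expect_identical(predictiveInfluenceRatio(m, ab, "a", "T2"), 1)
  expect_identical(predictiveInfluenceRatio(m, ab, "a", 4L), 1)
  # ratio equals independently computed probabilities
  pFull <- classifyAbundance(m, ab)["a"]
  ab0 <- ab; ab0["T1"] <- 0
  pLoo <- classifyAbundance(m, ab0)["a"]
  expect_equal(predictiveInfluenceRatio(m, ab, "a", "T1"),
               unname(pFull / pLoo), tolerance = 1e-12)
  # the loaded TME dominates every other TME for correct predictions
  set.seed(2)
  for (i in 1:10) {
    abr <- c(T1 = runif(1, 1, 3), T2 = runif(1), T3 = runif(1),
             T4 = runif(1))
    pirs <- vapply(paste0("T", 1:4), function(t)
      predictiveInfluenceRatio(m, abr, "a", t), 0)
    expect_identical(names(which.max(pirs)), "T1")
  }
})

test_that("PIR table reproduces p_full / p_loo and flags underflow", {
  W <- rbind(c(3, -3), c(-1, 1))
  rownames(W) <- c("T1", "T2")
  m <- linearModel(W)
  ab <- matrix(runif(10, 1, 2), 5, 2, dimnames = list(paste0("p", 1:5),
                                                      c("T1", "T2")))
  tab <- pirTable(m, ab, rep(c("a", "b"), length.out = 5))
  expect_equal(tab$pir, tab$p_full / tab$p_loo, tolerance = 1e-12)
  expect_identical(nrow(tab), 10L)
})

test_that("differential analysis flags constructed signal and skips dead TMEs", {
  set.seed(3)
  W <- rbind(c(1.5, -1.5), 0, 0, 0)
  rownames(W) <- paste0("T", 1:4)
  m <- linearModel(W)
  nPer <- 40
  labels <- rep(c("a", "b"), each = nPer)
  ab <- cbind(T1 = c(rnorm(nPer, 5), rnorm(nPer, 1)),
              T2 = c(rnorm(nPer, 5), rnorm(nPer, 1)),  # associated, unused
              T3 = rnorm(2 * nPer, 3),
              T4 = rnorm(2 * nPer, 3))
  dt <- differentialTMEAnalysis(m, ab, labels)
  row <- function(t) dt[dt$tme == t, ]
  expect_true(row("T1")$flagged)             # used and class-associated
  expect_false(row("T2")$flagged)            # class-associated but unused
  expect_false(row("T2")$used)
  expect_false(row("T3")$flagged)            # used? no weight -> not used
  expect_true(all(dt$p_adjusted >= dt$p_value - 1e-15))
  expect_identical(row("T1")$direction, "a")
  # degenerate constant abundance -> p = 1, never flagged
  abc <- ab; abc[, "T1"] <- 2
  dtc <- differentialTMEAnalysis(m, abc, labels)
  expect_equal(dtc[dtc$tme == "T1", ]$p_value, 1)
  expect_false(dtc[dtc$tme == "T1", ]$flagged)
})

test_that("type-I error of the differential flag is controlled under permutation", {
  set.seed(4)
  W <- rbind(c(1, -1), c(-0.5, 0.5), c(0.8, -0.8), c(0.2, -0.2))
  rownames(W) <- paste0("T", 1:4)
  m <- linearModel(W)
  ab <- matrix(rexp(60 * 4, rate = 0.5), 60, 4,
               dimnames = list(NULL, paste0("T", 1:4)))
  labels <- rep(c("a", "b"), each = 30)
  rate <- mean(replicate(60, {
    dt <- differentialTMEAnalysis(m, ab, sample(labels))
    mean(dt$flagged)
  }))
  expect_lte(rate, 0.05)
})

test_that("TME masks partition the patch grid and upsample by block", {
  emb <- new("EmbeddedImage", embeddings = matrix(0, 12, 2),
             gridShape = c(3L, 4L), patchSize = 5L, imageId = "x")
  set.seed(5)
  A <- multiplexTME:::.softmaxRows(matrix(rnorm(36, sd = 2), 12, 3))
  masks <- lapply(1:3, function(t) mapTMEToImage(A, emb, t))
  expect_identical(dim(masks[[1]]), c(15L, 20L))
  expect_true(all(Reduce(`+`, masks) == 1))        # argmax totality
  amax <- max.col(A, ties.method = "first")
  for (t in 1:3)
    expect_identical(sum(masks[[t]]), sum(amax == t) * 25L)
  # row-major correspondence: patch (r, c) maps to its pixel block
  r <- 2L; cc <- 3L
  expect_identical(unique(as.vector(masks[[amax[(r - 1) * 4 + cc]]][
    ((r - 1) * 5 + 1):(r * 5), ((cc - 1) * 5 + 1):(cc * 5)])), TRUE)
  expect_error(mapTMEToImage(A, emb, 9L), "out of range")
})

test_that("interpretability overlap follows |union ∩ GT| / |GT|", {
  gt <- matrix(FALSE, 20, 20); gt[1:10, 1:10] <- TRUE
  expect_equal(interpretabilityOverlap(gt, gt), 100)
  dj <- matrix(FALSE, 20, 20); dj[11:20, 11:20] <- TRUE
  expect_equal(interpretabilityOverlap(dj, gt), 0)
  # 50 of 100 GT pixels covered plus 500 outside -> still 50%
  half <- matrix(FALSE, 20, 20); half[1:5, 1:10] <- TRUE
  half[11:20, ] <- TRUE
  expect_equal(interpretabilityOverlap(half, gt), 50)
  # monotone nondecreasing in the selected set
  m1 <- list(half)
  m2 <- list(half, dj, gt)
  expect_lte(interpretabilityOverlap(m1, gt),
             interpretabilityOverlap(m2, gt))
  expect_error(interpretabilityOverlap(half, gt & FALSE), "empty")
})

test_that("marker matrix and report artifacts have the documented shape", {
  tt <- smallTissues("CCI1", 200L)[[1]]
  fitE <- tinyEncoder()
  emb <- embedImage(tt$image, fitE$encoder, "x")
  set.seed(8)
  A <- multiplexTME:::.softmaxRows(matrix(rnorm(nrow(embeddingMatrix(emb)) * 5),
                                          ncol = 5))
  mm <- tmeMarkerMatrix(A, emb, tt$image)
  expect_identical(dim(mm), c(5L, 6L))
  z <- t(scale(t(mm)))
  expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5), tolerance = 1e-12)

  W <- rbind(c(1, -1), 0, 0, 0, 0)
  rownames(W) <- paste0("N", 1:5)
  m <- linearModel(W)
  ab <- matrix(rexp(40 * 5), 40, 5, dimnames = list(NULL, paste0("N", 1:5)))
  ab[1:20, 1] <- ab[1:20, 1] + 4
  labels <- rep(c("a", "b"), each = 20)
  dt <- differentialTMEAnalysis(m, ab, labels)
  d <- withr::local_tempdir()
  paths <- renderReports(list(differential = dt, abundance = ab,
                              labels = labels, markerMatrix = mm,
                              pir = pirTable(m, ab, labels)), d)
  expect_true(file.exists(file.path(d, "differential_tme.csv")))
  got <- read.csv(file.path(d, "differential_tme.csv"))
  expect_true(!is.unsorted(got$p_adjusted))
  expect_true(file.exists(file.path(d, "pir.csv")))
})
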