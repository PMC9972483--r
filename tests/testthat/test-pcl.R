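test_that("crop sampling respects sizes, bounds and determinism", {
  tis <- smallTissues("none", 120L)
  imgs <- lapply(tis, `[[`, "image")
  cfg <- pclConfig(patch_size = 10L, crop_factor = 1.15, batch_crops = 12L,
                   images_per_batch = 2L)
  set.seed(1); b <- sampleCrops(imgs, cfg)
  expect_length(b$crops, 12)
  expect_identical(dim(b$crops[[1]]), c(11L, 11L, 6L))  # floor(10 * 1.15)
  expect_true(all(b$source$y >= 1 & b$source$y <= 120 - 11 + 1))
  expect_lte(length(unique(b$source$image)), 2)
  set.seed(1); b2 <- sampleCrops(imgs, cfg)
  expect_identical(b$source, b2$source)
  # alpha = 1 -> crop side = S_L
  cfg1 <- pclConfig(patch_size = 10L, crop_factor = 1, batch_crops = 2L)
  set.seed(2)
  expect_identical(dim(sampleCrops(imgs, cfg1)$crops[[1]])[1], 10L)
  tiny <- list(array(0, c(8, 8, 6)))
  expect_error(sampleCrops(tiny, cfg), "at least")
})

test_that("augmentation produces S_L views with the documented cutout", {
  crop <- array(runif(12 * 12 * 3, min = 0.2, max = 1), c(12, 12, 3))
  set.seed(4)
  v <- augmentCrop(crop, patch_size = 10L)
  expect_identical(dim(v[[1]]), c(10L, 10L, 3L))
  expect_identical(dim(v[[2]]), c(10L, 10L, 3L))
  # cutout side round(0.15 * 10) = 2: exactly 4 zeroed pixels per channel
  for (view in v) {
    zero <- which(view[, , 1] == 0, arr.ind = TRUE)
    expect_identical(nrow(zero), 4L)
    expect_lte(diff(range(zero[, 1])), 1)
    expect_lte(diff(range(zero[, 2])), 1)
    expect_true(all(view[, , 2][view[, , 1] == 0] == 0))
  }
  # alpha = 1: views are rotations/cutouts of the same pixels
  set.seed(5)
  v1 <- augmentCrop(crop[1:10, 1:10, , drop = FALSE], patch_size = 10L)
  expect_identical(dim(v1[[1]]), c(10L, 10L, 3L))
})

test_that("NT-Xent matches enumerated oracle values", {
  # single pair, no negatives -> -log(1) = 0
  set.seed(1)
  expect_equal(ntXentLoss(matrix(rnorm(8), 2, 4)), 0)
  # 3 identical pairs: each anchor sees 1 positive + 4 equal negatives
  z <- matrix(1, 6, 4)
  expect_equal(ntXentLoss(z), log(5), tolerance = 1e-12)
  # brute-force enumeration oracle on a random batch
  set.seed(2)
  zr <- matrix(rnorm(6 * 3), 6, 3)
  tau <- 0.5
  zn <- zr / sqrt(rowSums(zr^2))
  S <- zn %*% t(zn)
  partner <- c(2, 1, 4, 3, 6, 5)
  ref <- mean(vapply(1:6, function(i) {
    num <- exp(S[i, partner[i]] / tau)
    den <- sum(exp(S[i, setdiff(1:6, i)] / tau))
    -log(num / den)
  }, 0))
  expect_equal(ntXentLoss(zr, tau), ref, tolerance = 1e-12)
  expect_error(ntXentLoss(matrix(0, 2, 3)), "zero-norm")
})

test_that("contrast accuracy is top-1 positive retrieval with low-index ties", {
  set.seed(3)
  base <- matrix(rnorm(3 * 4, sd = 3), 3, 4)
  z <- base[rep(1:3, each = 2), ] + matrix(rnorm(24, sd = 0.01), 6, 4)
  expect_equal(contrastAccuracy(z), 1)
  # identical projections: all similarities tie; argmax is the lowest
  # other index, so only the anchor whose partner IS that index scores
  zi <- matrix(1, 6, 2)
  # anchors 1 and 2 retrieve each other (partner is the lowest other
  # index); anchors 3..6 fall back to index 1, which is not their partner
  expect_equal(contrastAccuracy(zi), 2 / 6)
  # random projections: expected accuracy ~ 1/(2 B_L - 1)
  set.seed(6)
  accs <- replicate(500, contrastAccuracy(matrix(rnorm(8 * 16), 8, 16)))
  expect_lt(abs(mean(accs) - 1 / 7), 0.025)
})

test_that("projection dimensions follow the configuration", {
  fit <- tinyEncoder()
  tis <- smallTissues("none", 120L)
  cfg <- pclConfig(patch_size = 8L, batch_crops = 10L, embedding_dim = 32L,
                   projection_dim = 16L)
  set.seed(8)
  b <- sampleCrops(lapply(tis, `[[`, "image"), cfg)
  views <- unlist(lapply(b$crops, augmentCrop, patch_size = 8L),
                  recursive = FALSE)
  pr <- pclProject(views, fit$encoder)
  expect_identical(dim(pr$h), c(length(views), 32L))
  expect_identical(dim(pr$z), c(length(views), 16L))
})

test_that("training reduces the contrastive loss and reports accuracy in [0,1]", {
  fit <- tinyEncoder()
  h <- fit$history
  expect_true(fit$contrastAccuracy >= 0 && fit$contrastAccuracy <= 1)
  first <- mean(head(h$loss, 10)); last <- mean(tail(h$loss, 10))
  expect_lt(last, first)
  # trivially distinguishable images: large constant one-hot blocks with
  # distinct intensities, no noise -> crops are identifiable by content
  # and separable positives dominate the softmax
  set.seed(11)
  imgs <- lapply(1:8, function(i) {
    a <- array(0, c(66, 66, 3))
    for (bl in 0:2) for (bc in 0:2) {
      ch <- sample.int(3, 1)
      a[bl * 22 + 1:22, bc * 22 + 1:22, ch] <- runif(1, 0.1, 1)
    }
    a
  })
  cfg <- pclConfig(patch_size = 8L, crop_factor = 1, batch_crops = 16L,
                   images_per_batch = 8L, embedding_dim = 32L,
                   projection_dim = 16L, max_iters = 400L,
                   plateau_window = 200L, learning_rate = 4e-3, seed = 12L)
  sep <- trainPCL(imgs, cfg)
  expect_gt(sep$contrastAccuracy, 0.9)
})

test_that("embedding tiles row-major, drops borders, and is deterministic", {
  fit <- tinyEncoder()
  img <- smallTissues("none", 120L)[[1]]$image
  emb <- embedImage(img, fit$encoder, "t1")
  expect_identical(gridShape(emb), c(15L, 15L))        # floor(120/8)
  expect_identical(nrow(embeddingMatrix(emb)), 225L)
  expect_identical(ncol(embeddingMatrix(emb)), 32L)
  emb2 <- embedImage(img, fit$encoder, "t1")
  expect_identical(embeddingMatrix(emb), embeddingMatrix(emb2))
  # row-major order: embedding of patch (r, c) equals encoding that block
  a <- imageArray(img)
  r <- 3L; cc <- 5L
  block <- a[((r - 1) * 8 + 1):(r * 8), ((cc - 1) * 8 + 1):(cc * 8), ,
             drop = FALSE]
  direct <- pclProject(list(block), fit$encoder)$h
  expect_equal(unname(embeddingMatrix(emb)[(r - 1) * 15 + cc, ]),
               unname(direct[1, ]), tolerance = 1e-10)
  untrained <- initPCLEncoder(pclConfig(patch_size = 8L), 6L)
  expect_error(embedImage(img, untrained), "not been trained")
})

test_that("batch order does not change the mean NT-Xent loss", {
  set.seed(14)
  z <- matrix(rnorm(12 * 5), 12, 5)
  l0 <- ntXentLoss(z)
  perm <- sample(6)                      # permute crops, keep pairs intact
  idx <- as.vector(rbind(2 * perm - 1, 2 * perm))
  expect_equal(ntXentLoss(z[idx, ]), l0, tolerance = 1e-12)
})
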