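# Patch Contrastive Learning: self-supervised patch embeddings.
#
# Two augmented views of the same image crop are pulled together and views
# of different crops pushed apart with a normalized-temperature
# cross-entropy (NT-Xent) over cosine similarities. The trained encoder
# then converts every image into an L x g list of patch embeddings.

#' Patch contrastive learning configuration
#'
#' @param patch_size patch side S_L in pixels (10 for the synthetic
#'   cohorts; 15 and 18 px in the real-tissue settings).
#' @param crop_factor crop scale alpha_L >= 1; crops have side
#'   `floor(patch_size * crop_factor)` so the two views of one crop can
#'   capture information from neighboring pixels. The pipeline accepts the
#'   sweep values 1, 1.15, 1.30.
#' @param batch_crops number of crops B_L per training batch.
#' @param images_per_batch number R of distinct images the crops of one
#'   batch are drawn from.
#' @param temperature NT-Xent temperature tau (default 0.5).
#' @param embedding_dim encoder output dimension g (default 256).
#' @param projection_dim projection-head output dimension (default 128).
#' @param cutout_fraction side of the square cutout as a fraction of
#'   patch_size (default 0.15).
#' @param encoder_depth `"small"` (2 residual blocks) or `"deep"`
#'   (33 residual blocks, a 101-layer-class residual network).
#' @param max_iters maximum training iterations.
#' @param plateau_window,plateau_tol convergence detection: stop when the
#'   moving-average loss over the last window improves by less than
#'   `plateau_tol` relative to the previous window.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed.
#' @return classed list `"PCLConfig"`.
#' @export
pclConfig <- function(patch_size = 10L, crop_factor = 1.15, batch_crops = 64L,
                      images_per_batch = 8L, temperature = 0.5,
                      embedding_dim = 256L, projection_dim = 128L,
                      cutout_fraction = 0.15, encoder_depth = c("small", "deep"),
                      max_iters = 400L, plateau_window = 100L,
                      plateau_tol = 1e-3, learning_rate = 1e-3, seed = 1L) {
  encoder_depth <- match.arg(encoder_depth)
  .assertThat(crop_factor >= 1, "crop_factor must be >= 1")
  .assertThat(temperature > 0, "temperature must be > 0")
  .assertThat(embedding_dim >= projection_dim,
              "embedding_dim must be >= projection_dim")
  structure(list(patch_size = as.integer(patch_size), crop_factor = crop_factor,
                 batch_crops = as.integer(batch_crops),
                 images_per_batch = as.integer(images_per_batch),
                 temperature = temperature,
                 embedding_dim = as.integer(embedding_dim),
                 projection_dim = as.integer(projection_dim),
                 cutout_fraction = cutout_fraction,
                 encoder_depth = encoder_depth,
                 max_iters = as.integer(max_iters),
                 plateau_window = as.integer(plateau_window),
                 plateau_tol = plateau_tol,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "PCLConfig")
}

.asImageArray <- function(x) {
  if (is(x, "MultiplexImage")) imageArray(x) else x
}

#' Sample a batch of image crops
#'
#' Draws `batch_crops` crops of side `floor(patch_size * crop_factor)` at
#' uniform positions from `images_per_batch` randomly chosen images.
#'
#' @param images list of [MultiplexImage-class] or H x W x B arrays.
#' @param cfg a [pclConfig()].
#' @return list with `crops` (list of side x side x B arrays) and `source`
#'   (data.frame image, y, x).
#' @export
sampleCrops <- function(images, cfg) {
  side <- floor(cfg$patch_size * cfg$crop_factor)
  n <- length(images)
  dims <- lapply(images, function(im) dim(.asImageArray(im)))
  ok <- vapply(dims, function(d) d[1] >= side && d[2] >= side, TRUE)
  if (!all(ok)) .stopf("all images must be at least %d px on each side", side)
  pick <- sample.int(n, min(cfg$images_per_batch, n))
  src <- pick[sample.int(length(pick), cfg$batch_crops, replace = TRUE)]
  crops <- vector("list", cfg$batch_crops)
  ys <- integer(cfg$batch_crops); xs <- integer(cfg$batch_crops)
  for (i in seq_len(cfg$batch_crops)) {
    a <- .asImageArray(images[[src[i]]])
    d <- dim(a)
    ys[i] <- sample.int(d[1] - side + 1L, 1L)
    xs[i] <- sample.int(d[2] - side + 1L, 1L)
    crops[[i]] <- a[ys[i]:(ys[i] + side - 1L), xs[i]:(xs[i] + side - 1L), ,
                    drop = FALSE]
  }
  list(crops = crops, source = data.frame(image = src, y = ys, x = xs))
}

.rotcw <- function(m) t(m[nrow(m):1, , drop = FALSE])

.rotArray <- function(a, k) {
  k <- k %% 4
  if (k == 0) return(a)
  for (i in seq_len(k)) {
    out <- array(0, c(dim(a)[2], dim(a)[1], dim(a)[3]))
    for (b in seq_len(dim(a)[3])) out[, , b] <- .rotcw(a[, , b])
    a <- out
  }
  a
}

#' Generate two augmented views of a crop
#'
#' Each view is an independent random S_L sub-crop, rotated by a random
#' multiple of 90 degrees (no interpolation artifacts on few-pixel patches),
#' with one random square cutout of side `max(1, round(0.15 * S_L))` zeroed
#' across all channels.
#'
#' @param crop side x side x B array (side >= S_L).
#' @param patch_size S_L.
#' @param cutout_fraction cutout side fraction.
#' @return list of two S_L x S_L x B arrays.
#' @export
augmentCrop <- function(crop, patch_size, cutout_fraction = 0.15) {
  side <- dim(crop)[1]
  .assertThat(side >= patch_size, "crop smaller than patch size")
  S <- patch_size
  one <- function() {
    oy <- sample.int(side - S + 1L, 1L)
    ox <- sample.int(side - S + 1L, 1L)
    v <- crop[oy:(oy + S - 1L), ox:(ox + S - 1L), , drop = FALSE]
    v <- .rotArray(v, sample.int(4L, 1L) - 1L)
    cs <- max(1L, as.integer(round(cutout_fraction * S)))
    cy <- sample.int(S - cs + 1L, 1L)
    cx <- sample.int(S - cs + 1L, 1L)
    v[cy:(cy + cs - 1L), cx:(cx + cs - 1L), ] <- 0
    v
  }
  list(one(), one())
}

# ---- encoder ----------------------------------------------------------------

.pclInitParams <- function(cfg, nChannels) {
  D <- cfg$patch_size^2 * nChannels
  g <- cfg$embedding_dim
  nblocks <- if (cfg$encoder_depth == "small") 2L else 33L
  p <- list(W0 = .initMat(D, g), b0 = matrix(0, 1, g))
  for (j in seq_len(nblocks)) {
    p[[paste0("Wr", j)]] <- .initMat(g, g) * 0.5
    p[[paste0("br", j)]] <- matrix(0, 1, g)
  }
  p$V1 <- .initMat(g, g); p$c1 <- matrix(0, 1, g)
  p$V2 <- .initMat(g, cfg$projection_dim)
  # nonzero bias: a fully dead encoder row still projects to a valid
  # (nonzero-norm) vector instead of crashing the cosine similarity
  p$c2 <- matrix(0.01, 1, cfg$projection_dim)
  attr(p, "nblocks") <- nblocks
  p
}

#' Initialize an untrained contrastive encoder
#'
#' @param cfg a [pclConfig()].
#' @param nChannels number of image channels B.
#' @return a [PCLEncoder-class] with random weights.
#' @export
initPCLEncoder <- function(cfg, nChannels) {
  params <- .withSeed(cfg$seed, .pclInitParams(cfg, nChannels))
  new("PCLEncoder", params = params, channelMean = rep(0, nChannels),
      channelSd = rep(1, nChannels), config = unclass(cfg), trained = FALSE)
}

# forward through encoder; returns cache for backprop
.encForward <- function(X, p) {
  nb <- attr(p, "nblocks")
  cache <- list(X = X)
  pre0 <- .addBias(X %*% p$W0, p$b0)
  h <- .relu(pre0)
  cache$pre0 <- pre0
  cache$hs <- vector("list", nb)
  for (j in seq_len(nb)) {
    pre <- .addBias(h %*% p[[paste0("Wr", j)]], p[[paste0("br", j)]])
    cache$hs[[j]] <- list(hin = h, pre = pre)
    h <- h + .relu(pre)
  }
  cache$h <- h
  pre1 <- .addBias(h %*% p$V1, p$c1)
  p1 <- .relu(pre1)
  z <- .addBias(p1 %*% p$V2, p$c2)
  cache$pre1 <- pre1; cache$p1 <- p1; cache$z <- z
  cache
}

.encBackward <- function(cache, p, dz, dh_extra = NULL) {
  nb <- attr(p, "nblocks")
  g <- list()
  g$V2 <- crossprod(cache$p1, dz)
  g$c2 <- matrix(colSums(dz), 1)
  dp1 <- dz %*% t(p$V2)
  dpre1 <- dp1 * (cache$pre1 > 0)
  g$V1 <- crossprod(cache$h, dpre1)
  g$c1 <- matrix(colSums(dpre1), 1)
  dh <- dpre1 %*% t(p$V1)
  if (!is.null(dh_extra)) dh <- dh + dh_extra
  for (j in rev(seq_len(nb))) {
    cc <- cache$hs[[j]]
    dpre <- dh * (cc$pre > 0)
    g[[paste0("Wr", j)]] <- crossprod(cc$hin, dpre)
    g[[paste0("br", j)]] <- matrix(colSums(dpre), 1)
    dh <- dh + dpre %*% t(p[[paste0("Wr", j)]])
  }
  dpre0 <- dh * (cache$pre0 > 0)
  g$W0 <- crossprod(cache$X, dpre0)
  g$b0 <- matrix(colSums(dpre0), 1)
  g
}

#' Embed and project augmented views
#'
#' Runs views through the encoder (length-g representations h) and the
#' projection MLP (length-`projection_dim` vectors z used by the
#' contrastive loss).
#'
#' @param views list of S_L x S_L x B arrays, or a pre-flattened matrix.
#' @param encoder a [PCLEncoder-class].
#' @return list with `h` (n x g) and `z` (n x projection_dim).
#' @export
pclProject <- function(views, encoder) {
  X <- if (is.matrix(views)) views else
    t(vapply(views, as.vector, numeric(length(views[[1]]))))
  X <- .normalizeChannels(X, encoder)
  cache <- .encForward(X, encoder@params)
  list(h = cache$h, z = cache$z)
}

.normalizeChannels <- function(X, encoder) {
  B <- length(encoder@channelMean)
  D <- ncol(X)
  per <- D / B
  mu <- rep(encoder@channelMean, each = per)
  sd <- rep(encoder@channelSd, each = per)
  sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
}

# ---- NT-Xent ----------------------------------------------------------------

# rows of z come in consecutive positive pairs (1,2), (3,4), ...
.ntxent <- function(z, tau, wantGrad = FALSE) {
  n <- nrow(z)
  .assertThat(n %% 2 == 0, "projections must come in pairs")
  nrm <- sqrt(rowSums(z * z))
  if (any(nrm < 1e-12)) .stopf("zero-norm projection encountered")
  zn <- z / nrm
  S <- tcrossprod(zn)
  partner <- seq_len(n) + c(1L, -1L)[(seq_len(n) - 1L) %% 2L + 1L]
  E <- exp(S / tau)
  diag(E) <- 0
  denom <- rowSums(E)
  pos <- S[cbind(seq_len(n), partner)] / tau
  loss <- mean(-pos + log(denom))
  acc <- {
    Sm <- S; diag(Sm) <- -Inf
    mean(max.col(Sm, ties.method = "first") == partner)
  }
  if (!wantGrad) return(list(loss = loss, acc = acc))
  G <- E / denom                      # softmax over j != i
  G[cbind(seq_len(n), partner)] <- G[cbind(seq_len(n), partner)] - 1
  G <- G / (tau * n)
  dzn <- (G + t(G)) %*% zn
  dz <- (dzn - zn * rowSums(zn * dzn)) / nrm
  list(loss = loss, acc = acc, dz = dz)
}

#' Normalized-temperature cross-entropy (NT-Xent) contrastive loss
#'
#' For each positive pair (two views of one crop), the loss is
#' `-log( exp(sim/tau) / sum_candidates exp(sim/tau) )` with cosine
#' similarity; candidates are the positive partner plus the `2*B_L - 2`
#' views of all other crops. The total is the mean over all `2*B_L`
#' anchors. With a single pair (no negatives) the loss is exactly 0.
#'
#' @param z n x d projection matrix, rows in consecutive positive pairs.
#' @param tau temperature (> 0).
#' @return scalar loss.
#' @export
ntXentLoss <- function(z, tau = 0.5) .ntxent(z, tau)$loss

#' Contrast accuracy: top-1 positive retrieval
#'
#' Fraction of anchors whose positive partner has the highest cosine
#' similarity among all other views in the batch (ties broken toward the
#' lowest index).
#'
#' @inheritParams ntXentLoss
#' @return fraction in `[0, 1]`.
#' @export
contrastAccuracy <- function(z) {
  nrm <- sqrt(rowSums(z * z))
  nrm[nrm < 1e-12] <- 1e-12
  zn <- z / nrm
  S <- tcrossprod(zn)
  diag(S) <- -Inf
  n <- nrow(z)
  partner <- seq_len(n) + c(1L, -1L)[(seq_len(n) - 1L) %% 2L + 1L]
  mean(max.col(S, ties.method = "first") == partner)
}

# ---- training ---------------------------------------------------------------

.viewsToMatrix <- function(viewList) {
  t(vapply(viewList, as.vector, numeric(length(viewList[[1]]))))
}

#' Train the patch contrastive encoder
#'
#' Iterates crop sampling, augmentation, projection and NT-Xent gradient
#' steps (Adam) until `max_iters` or a loss plateau. Per-channel z-score
#' normalization statistics are estimated from the training images and
#' stored with the encoder. The reported contrast accuracy is computed on
#' freshly sampled batches after training (no parameter updates).
#'
#' @param images list of [MultiplexImage-class]/arrays, or character paths
#'   to multi-page TIFFs.
#' @param cfg a [pclConfig()].
#' @param verbose print progress every 50 iterations.
#' @return list: `encoder` ([PCLEncoder-class]), `contrastAccuracy`
#'   (held-out), `history` (per-iteration loss and batch accuracy).
#' @export
trainPCL <- function(images, cfg, verbose = FALSE) {
  if (is.character(images)) images <- lapply(images, readMultiplexImage)
  .assertThat(length(images) >= 1, "no images provided")
  arrays <- lapply(images, .asImageArray)
  B <- dim(arrays[[1]])[3]
  .withSeed(cfg$seed, {
    # channel stats from a pixel subsample
    sub <- lapply(arrays[seq_len(min(10, length(arrays)))], function(a) {
      idx <- sample.int(prod(dim(a)[1:2]), min(5000, prod(dim(a)[1:2])))
      apply(a, 3, function(m) m[idx])
    })
    subm <- do.call(rbind, sub)
    chMean <- colMeans(subm)
    chSd <- pmax(apply(subm, 2, stats::sd), 1e-6)

    params <- .pclInitParams(cfg, B)
    enc <- new("PCLEncoder", params = params, channelMean = chMean,
               channelSd = chSd, config = unclass(cfg), trained = FALSE)
    opt <- .adamInit(params)
    losses <- numeric(cfg$max_iters)
    accs <- numeric(cfg$max_iters)
    it <- 0L
    while (it < cfg$max_iters) {
      it <- it + 1L
      batch <- sampleCrops(arrays, cfg)
      views <- unlist(lapply(batch$crops, augmentCrop,
                             patch_size = cfg$patch_size,
                             cutout_fraction = cfg$cutout_fraction),
                      recursive = FALSE)
      X <- .normalizeChannels(.viewsToMatrix(views), enc)
      cache <- .encForward(X, params)
      res <- .ntxent(cache$z, cfg$temperature, wantGrad = TRUE)
      if (!is.finite(res$loss)) .stopf("contrastive loss diverged (non-finite)")
      grads <- .encBackward(cache, params, res$dz)
      upd <- .adamStep(params, grads, opt, cfg$learning_rate)
      params <- upd$params; opt <- upd$state
      attr(params, "nblocks") <- attr(enc@params, "nblocks")
      losses[it] <- res$loss; accs[it] <- res$acc
      if (verbose && it %% 50 == 0)
        message(sprintf("pcl iter %d loss %.4f acc %.3f", it, res$loss, res$acc))
      w <- cfg$plateau_window
      if (it >= 2 * w) {
        recent <- mean(losses[(it - w + 1):it])
        prev <- mean(losses[(it - 2 * w + 1):(it - w)])
        if (prev - recent < cfg$plateau_tol * abs(prev)) break
      }
    }
    enc@params <- params
    enc@trained <- TRUE
    # held-out contrast accuracy on fresh batches
    ho <- vapply(1:5, function(i) {
      batch <- sampleCrops(arrays, cfg)
      views <- unlist(lapply(batch$crops, augmentCrop,
                             patch_size = cfg$patch_size,
                             cutout_fraction = cfg$cutout_fraction),
                      recursive = FALSE)
      contrastAccuracy(pclProject(.viewsToMatrix(views), enc)$z)
    }, 0)
    list(encoder = enc, contrastAccuracy = mean(ho),
         history = data.frame(iter = seq_len(it), loss = losses[seq_len(it)],
                              batch_acc = accs[seq_len(it)]))
  })
}

#' Embed an image as a grid of patch embeddings
#'
#' Tiles the image into non-overlapping S_L x S_L patches (row-major
#' order, partial border tiles dropped) and encodes each patch, yielding
#' `L = floor(H/S_L) * floor(W/S_L)` embeddings of length g.
#'
#' @param image a [MultiplexImage-class] or H x W x B array.
#' @param encoder a trained [PCLEncoder-class].
#' @param imageId identifier stored with the result.
#' @return an [EmbeddedImage-class].
#' @export
embedImage <- function(image, encoder, imageId = "img") {
  .assertThat(encoder@trained, "encoder has not been trained")
  a <- .asImageArray(image)
  S <- encoder@config$patch_size
  rows <- nrow(a) %/% S; cols <- ncol(a) %/% S
  B <- dim(a)[3]
  a <- a[seq_len(rows * S), seq_len(cols * S), , drop = FALSE]
  # (y, x, b) -> (row, col, sy, sx, b), row-major patch order
  arr <- array(a, c(S, rows, S, cols, B))
  arr <- aperm(arr, c(2, 4, 1, 3, 5))
  X <- matrix(arr, rows * cols, S * S * B)
  # row-major: patch (r, c) must be row (r-1)*cols + c; aperm gives
  # column-major over (row, col) i.e. (c-1)*rows + r, so reorder
  ord <- as.vector(t(matrix(seq_len(rows * cols), rows, cols)))
  X <- X[ord, , drop = FALSE]
  # flatten order within a patch after aperm is (sy, sx, b), matching
  # as.vector() of an S x S x B view
  X <- .normalizeChannels(X, encoder)
  h <- .encForward(X, encoder@params)$h
  new("EmbeddedImage", embeddings = h, gridShape = c(rows, cols),
      patchSize = as.integer(S), imageId = imageId)
}
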