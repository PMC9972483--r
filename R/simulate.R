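# Synthetic multiplex-tissue simulator.
#
# Pipeline per tissue: (1) partition the canvas into neighborhood
# territories with a quota-balanced multiplicatively-weighted Voronoi
# tessellation whose seeds respect neighborhood attraction/repulsion;
# (2) lay a jittered hexagonal lattice of cell sites inside each territory
# and draw phenotype labels from the neighborhood's abundance vector
# (multinomial, so realized frequencies are exact draws from the config);
# (3) realize pairwise phenotype attraction/repulsion by swapping labels
# between sites (attraction moves a partner label to contact range,
# repulsion moves it beyond a separation radius) -- swaps preserve the
# multinomial counts exactly; (4) render cells as oriented ellipses with
# per-cell truncated-Gaussian marker intensities plus background noise.

# ---- territory tessellation -------------------------------------------------

.territoryMap <- function(cfg, H, W) {
  prev <- vapply(cfg$neighborhoods, `[[`, 0, "tissue_prevalence")
  nN <- length(prev)
  bg <- 1 - sum(prev)
  targets <- c(prev, if (bg > 1e-6) bg)
  nReg <- length(targets)
  inter <- cfg$neighborhood_interactions

  nSeeds <- pmax(1L, round(targets * 8))
  seeds <- vector("list", nReg)
  for (k in seq_len(nReg)) {
    pk <- matrix(0, nSeeds[k], 2)
    for (s in seq_len(nSeeds[k])) {
      partners <- if (k <= nN) which(inter[k, ] != 0 & seq_len(nN) < k) else integer(0)
      placed <- FALSE
      if (length(partners)) {
        j <- partners[1]
        w <- inter[k, j]
        if (stats::runif(1) < abs(w) && nrow(seeds[[j]]) > 0) {
          ref <- seeds[[j]][sample.int(nrow(seeds[[j]]), 1), ]
          if (w > 0) {                       # attract: seed near partner seed
            pk[s, ] <- pmin(pmax(ref + stats::rnorm(2, 0, 0.10 * c(H, W)), 1), c(H, W))
          } else {                           # repel: farthest of 25 candidates
            cand <- cbind(stats::runif(25, 1, H), stats::runif(25, 1, W))
            dmin <- apply(cand, 1, function(p)
              min(sqrt(rowSums((seeds[[j]] - matrix(p, nrow(seeds[[j]]), 2,
                                                    byrow = TRUE))^2))))
            pk[s, ] <- cand[which.max(dmin), ]
          }
          placed <- TRUE
        }
      }
      if (!placed) pk[s, ] <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
    }
    seeds[[k]] <- pk
  }

  cf <- 4L                                   # coarse grid factor
  cy <- seq(1, H, by = cf) + (cf - 1) / 2
  cx <- seq(1, W, by = cf) + (cf - 1) / 2
  ch <- length(cy); cw <- length(cx)
  gy <- rep(cy, times = cw); gx <- rep(cx, each = ch)
  dmin <- matrix(0, ch * cw, nReg)
  for (k in seq_len(nReg)) {
    d2 <- Inf
    for (s in seq_len(nrow(seeds[[k]])))
      d2 <- pmin(d2, (gy - seeds[[k]][s, 1])^2 + (gx - seeds[[k]][s, 2])^2)
    dmin[, k] <- sqrt(d2)
  }
  logw <- rep(0, nReg)                       # quota balancing
  for (it in 1:40) {
    lab <- max.col(-(dmin / exp(logw)[col(dmin)]), ties.method = "first")
    frac <- tabulate(lab, nReg) / length(lab)
    logw <- logw + 0.4 * (targets - frac)
    logw <- logw - mean(logw)
  }
  lab <- max.col(-(dmin / exp(logw)[col(dmin)]), ties.method = "first")
  lab[lab > nN] <- 0L                        # background
  coarse <- matrix(as.integer(lab), ch, cw)
  full <- coarse[rep(seq_len(ch), each = cf)[seq_len(H)],
                 rep(seq_len(cw), each = cf)[seq_len(W)]]
  full
}

# ---- cell-site placement ----------------------------------------------------

.hexSites <- function(H, W, s, jitter) {
  dy <- s * sqrt(3) / 2
  rows <- seq(1, H, by = dy)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    xs <- seq(if (i %% 2 == 0) 1 + s / 2 else 1, W, by = s)
    out[[i]] <- cbind(rows[i], xs)
  }
  pts <- do.call(rbind, out)
  pts + matrix(stats::rnorm(length(pts), 0, s * jitter), nrow(pts), 2)
}

.minDistTo <- function(pts, refs) {
  # min distance from each row of pts to any row of refs
  if (nrow(refs) == 0) return(rep(Inf, nrow(pts)))
  d2 <- matrix(Inf, nrow(pts), 1)
  best <- rep(Inf, nrow(pts))
  for (j in seq_len(nrow(refs)))
    best <- pmin(best, (pts[, 1] - refs[j, 1])^2 + (pts[, 2] - refs[j, 2])^2)
  sqrt(best)
}

.placeCells <- function(cfg, territory) {
  H <- nrow(territory); W <- ncol(territory)
  radii <- vapply(cfg$phenotypes, `[[`, 0, "cell_radius_px")
  nN <- length(cfg$neighborhoods)
  inter <- cfg$phenotype_interactions
  cells <- list()
  for (k in seq_len(nN)) {
    ab <- cfg$neighborhoods[[k]]$phenotype_abundance
    rbar <- sum(ab * radii)
    s <- 2 * rbar * cfg$spacing_factor
    pts <- .hexSites(H, W, s, cfg$jitter_frac)
    ok <- pts[, 1] >= 1 & pts[, 1] <= H & pts[, 2] >= 1 & pts[, 2] <= W
    pts <- pts[ok, , drop = FALSE]
    # site and its 4 extreme points must fall inside the territory
    inReg <- function(y, x) {
      y <- pmin(pmax(round(y), 1), H); x <- pmin(pmax(round(x), 1), W)
      territory[cbind(y, x)] == k
    }
    keep <- inReg(pts[, 1], pts[, 2]) &
      inReg(pts[, 1] - rbar, pts[, 2]) & inReg(pts[, 1] + rbar, pts[, 2]) &
      inReg(pts[, 1], pts[, 2] - rbar) & inReg(pts[, 1], pts[, 2] + rbar)
    pts <- pts[keep, , drop = FALSE]
    n <- nrow(pts)
    if (n == 0) next
    counts <- as.vector(stats::rmultinom(1, n, ab))
    lab <- sample(rep.int(seq_along(ab), counts))

    # pairwise attraction/repulsion via label swaps
    pairs <- which(inter != 0 & upper.tri(inter), arr.ind = TRUE)
    if (nrow(pairs) && n > 3) {
      for (pp in seq_len(nrow(pairs))) {
        p <- pairs[pp, 1]; q <- pairs[pp, 2]
        w <- inter[p, q]
        # contact range: one lattice step (cells adjacent in the packing)
        dAtt <- max(cfg$attract_dist_factor * (radii[p] + radii[q]), 1.25 * s)
        dRep <- cfg$repel_dist_px
        iq <- which(lab == q)
        if (!length(iq) || !length(which(lab == p))) next
        for (i in iq) {
          if (stats::runif(1) > abs(w)) next
          ip <- which(lab == p)
          if (w > 0) {
            cand <- integer(0)
            for (try in seq_len(min(3L, length(ip)))) {
              j <- ip[sample.int(length(ip), 1)]
              d <- sqrt((pts[, 1] - pts[j, 1])^2 + (pts[, 2] - pts[j, 2])^2)
              cand <- which(d <= dAtt & !(lab %in% c(p, q)))
              if (length(cand)) break
            }
            if (length(cand)) {
              csel <- cand[sample.int(length(cand), 1)]
              tmp <- lab[csel]; lab[csel] <- lab[i]; lab[i] <- tmp
              # attraction is cell-cell contact: pull the moved cell to
              # touching distance from its partner
              dir <- pts[csel, ] - pts[j, ]
              nd <- sqrt(sum(dir^2))
              if (nd > 1e-9) {
                tgt <- pts[j, ] + dir / nd * (radii[p] + radii[q]) * 1.05
                tgt <- pmin(pmax(tgt, 1), c(H, W))
                pts[csel, ] <- tgt
              }
              next
            }
            cand <- integer(0)          # no contact site available
          } else {
            dmin <- .minDistTo(pts, pts[ip, , drop = FALSE])
            if (dmin[i] > dRep) next
            cand <- which(dmin > dRep & !(lab %in% c(p, q)))
          }
          if (length(cand)) {
            csel <- cand[sample.int(length(cand), 1)]
            tmp <- lab[csel]; lab[csel] <- lab[i]; lab[i] <- tmp
          }
        }
      }
    }
    cells[[k]] <- data.frame(phenotype = lab, neighborhood = k,
                             y = pts[, 1], x = pts[, 2])
  }
  out <- do.call(rbind, cells)
  if (is.null(out))
    out <- data.frame(phenotype = integer(0), neighborhood = integer(0),
                      y = numeric(0), x = numeric(0))
  out$cell <- seq_len(nrow(out))
  rad <- radii[out$phenotype] * stats::runif(nrow(out), 0.9, 1.1)
  out$radius <- if (nrow(out)) rad else numeric(0)
  out[, c("cell", "phenotype", "neighborhood", "y", "x", "radius")]
}

# ---- rendering --------------------------------------------------------------

.renderTissue <- function(cfg, cells, H, W) {
  B <- cfg$n_markers
  img <- array(0, c(H, W, B))
  pmask <- matrix(0L, H, W)
  ecc <- vapply(cfg$phenotypes, `[[`, 0, "eccentricity")
  plane <- H * W
  for (i in seq_len(nrow(cells))) {
    ph <- cells$phenotype[i]
    r <- cells$radius[i]
    e <- ecc[ph]
    sq <- (1 - e^2)^(1 / 4)
    a <- r / sq; b <- r * sq
    th <- stats::runif(1, 0, pi)
    y0 <- cells$y[i]; x0 <- cells$x[i]
    yy <- max(1, floor(y0 - a)):min(H, ceiling(y0 + a))
    xx <- max(1, floor(x0 - a)):min(W, ceiling(x0 + a))
    dy <- yy - y0; dx <- xx - x0
    u <- outer(dy * cos(th), dx * sin(th), "+")
    v <- outer(-dy * sin(th), dx * cos(th), "+")
    inside <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(inside)) next
    lin <- which(inside)
    ri <- (lin - 1) %% length(yy) + 1
    ci <- (lin - 1) %/% length(yy) + 1
    pix <- (xx[ci] - 1) * H + yy[ri]
    pmask[pix] <- ph
    mu <- cfg$phenotypes[[ph]]$marker_expression
    sdv <- cfg$phenotypes[[ph]]$expression_noise
    val <- pmin(pmax(stats::rnorm(B, mu, sdv), 0), 1)
    for (bb in seq_len(B)) img[pix + (bb - 1) * plane] <- val[bb]
  }
  img <- img + stats::rnorm(length(img), 0, cfg$background_noise_sd)
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img, phenotypeMask = pmask)
}

# ---- public operations ------------------------------------------------------

#' Simulate one multiplex tissue image
#'
#' Deterministically renders a multiplex tissue from a `CohortConfig`:
#' neighborhood territories, cells with phenotype labels drawn from each
#' neighborhood's abundance vector, pairwise attraction/repulsion, and
#' per-marker intensities. Reproducible bit-exactly from `(cfg, cfg$seed)`.
#'
#' @param cfg a `CohortConfig`.
#' @return list with elements `image` ([MultiplexImage-class]) and
#'   `truth` ([GroundTruth-class]).
#' @export
simulateTissue <- function(cfg) {
  validateCohortConfig(cfg)
  H <- cfg$image_size_px[1]; W <- cfg$image_size_px[2]
  .withSeed(cfg$seed, {
    territory <- .territoryMap(cfg, H, W)
    cells <- .placeCells(cfg, territory)
    if (nrow(cells) == 0)
      .stopf("cell density infeasible for image size %d x %d", H, W)
    rend <- .renderTissue(cfg, cells, H, W)
    truth <- new("GroundTruth", phenotypeMask = rend$phenotypeMask,
                 neighborhoodMask = territory, cellTable = cells)
    list(image = MultiplexImage(rend$image, cfg$markers), truth = truth)
  })
}

#' Simulate a synthetic patient cohort
#'
#' Emits `3 * nPerType` patients (types I, II, III) under one disease
#' paradigm. Each patient gets an independent child seed derived from the
#' global seed with [deriveSeed()], so cohorts are reproducible and any
#' patient can be regenerated in isolation.
#'
#' @param paradigm paradigm name (see [applyParadigm()]), or `"none"`.
#' @param nPerType patients per type (full-scale cohorts use 80).
#' @param imageSize (height, width) in pixels.
#' @param seed global integer seed.
#' @param outDir optional directory; when given, images, masks and a
#'   manifest CSV are written via [writeCohort()].
#' @return A `SyntheticCohort` list: `tissues` (per patient: image, truth,
#'   patientType), `manifest` data.frame, `paradigm`, `seed`.
#' @export
simulateCohort <- function(paradigm, nPerType, imageSize = c(800L, 800L),
                           seed = 1L, outDir = NULL) {
  .assertThat(nPerType >= 1, "nPerType must be >= 1")
  base <- defaultCohortConfig(imageSize = imageSize)
  tissues <- list()
  rows <- list()
  counter <- 0L
  for (ti in 1:3) {
    type <- .PATIENT_TYPES[ti]
    for (i in seq_len(nPerType)) {
      counter <- counter + 1L
      cfg <- if (paradigm == "none") base else applyParadigm(base, paradigm, type)
      cfg$seed <- deriveSeed(seed, counter)
      tt <- simulateTissue(cfg)
      pid <- sprintf("%s_%s_%03d", paradigm, type, i)
      tissues[[counter]] <- list(image = tt$image, truth = tt$truth,
                                 patientType = type, patientId = pid)
      rows[[counter]] <- data.frame(patient_id = pid,
                                    image_path = paste0(pid, ".ome.tiff"),
                                    mask_paths = paste0(pid, "_phmask.png;",
                                                        pid, "_nbmask.png"),
                                    patient_type = type, paradigm = paradigm,
                                    seed = cfg$seed)
    }
  }
  cohort <- structure(list(tissues = tissues, manifest = do.call(rbind, rows),
                           paradigm = paradigm, seed = seed),
                      class = "SyntheticCohort")
  if (!is.null(outDir)) writeCohort(cohort, outDir)
  cohort
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: paradigm %s, %d patients (%s), seed %d\n",
              x$paradigm, length(x$tissues),
              paste(table(x$manifest$patient_type), collapse = "/"), x$seed))
  invisible(x)
}

#' Write / read multiplex images and cohorts on disk
#'
#' Images are stored as multi-page TIFF (one float32 page per marker,
#' intensities in `[0, 1]`), masks as 16-bit PNG, and the cohort manifest as
#' CSV with columns patient_id, image_path, mask_paths, patient_type,
#' paradigm, seed.
#'
#' @param img a [MultiplexImage-class].
#' @param path file path (`.tiff`).
#' @export
writeMultiplexImage <- function(img, path) {
  a <- imageArray(img)
  pages <- lapply(seq_len(dim(a)[3]), function(b) a[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname writeMultiplexImage
#' @param markers optional marker names for the pages read back.
#' @export
readMultiplexImage <- function(path, markers = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- array(0, c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) a[, , b] <- pages[[b]]
  MultiplexImage(a, markers)
}

# label masks as grey PNG; 8-bit is lossless for label ids <= 255
.writeMask16 <- function(mask, path) {
  .assertThat(max(mask) <= 255, "mask labels exceed the PNG range")
  png::writePNG(mask / 255, path)
}

.readMask16 <- function(path) {
  m <- png::readPNG(path)
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' @rdname writeMultiplexImage
#' @param cohort a `SyntheticCohort`.
#' @param dir output directory (created if missing).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tt in cohort$tissues) {
    writeMultiplexImage(tt$image, file.path(dir, paste0(tt$patientId, ".ome.tiff")))
    .writeMask16(phenotypeMask(tt$truth),
                 file.path(dir, paste0(tt$patientId, "_phmask.png")))
    .writeMask16(neighborhoodMask(tt$truth),
                 file.path(dir, paste0(tt$patientId, "_nbmask.png")))
    utils::write.csv(cellTable(tt$truth),
                     file.path(dir, paste0(tt$patientId, "_cells.csv")),
                     row.names = FALSE)
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Mean nearest-neighbor distance between two phenotypes
#'
#' For every cell of phenotype `p`, the distance to the nearest cell of
#' phenotype `q`; averaged. Used to verify that simulated attraction
#' (smaller distances) and repulsion (larger) are realized.
#'
#' @param truth a [GroundTruth-class] (or its cell table).
#' @param p,q phenotype ids.
#' @return mean nearest-neighbor distance in pixels (NA if either empty).
#' @export
phenotypeNNDistance <- function(truth, p, q) {
  ct <- if (is(truth, "GroundTruth")) cellTable(truth) else truth
  A <- as.matrix(ct[ct$phenotype == p, c("y", "x")])
  Bm <- as.matrix(ct[ct$phenotype == q, c("y", "x")])
  if (nrow(A) == 0 || nrow(Bm) == 0) return(NA_real_)
  mean(.minDistTo(A, Bm))
}
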