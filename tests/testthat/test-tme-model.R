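test_that("max-sum pooling keeps row maxima and sums columns", {
  S <- rbind(c(0.7, 0.3), c(0.4, 0.6), c(0.9, 0.1))
  expect_equal(maxSumPool(S), c(1.6, 0.6))
  oneHot <- diag(3)[c(1, 1, 2, 3, 3, 3), ]
  expect_equal(maxSumPool(oneHot), c(2, 1, 3))
  # uniform rows, lowest-index tie-break: all mass lands in column 1
  expect_equal(maxSumPool(matrix(0.25, 8, 4)), c(2, 0, 0, 0))
  # conservation bound: column sums total within [L/C, L]
  set.seed(5)
  for (i in 1:20) {
    S <- multiplexTME:::.softmaxRows(matrix(rnorm(12 * 4, sd = 2), 12, 4))
    tot <- sum(maxSumPool(S))
    expect_gte(tot, 12 / 4); expect_lte(tot, 12)
  }
})

test_that("entropy losses have the documented ranges and oracle values", {
  expect_equal(patchEntropyLoss(diag(4)[c(1, 2, 3), ]), 0)
  expect_equal(patchEntropyLoss(matrix(1 / 5, 3, 5)), 1)
  # single row [0.9, 0.1]: -(0.9 ln 0.9 + 0.1 ln 0.1)/ln 2
  expect_equal(patchEntropyLoss(matrix(c(0.9, 0.1), 1)),
               -(0.9 * log(0.9) + 0.1 * log(0.1)) / log(2),
               tolerance = 1e-12)
  expect_equal(round(patchEntropyLoss(matrix(c(0.9, 0.1), 1)), 3), 0.469)

  expect_equal(patientEntropyLoss(c(0, 0, 5, 0)), 0)
  expect_equal(patientEntropyLoss(rep(3, 6)), -1)
  expect_equal(patientEntropyLoss(c(0.75, 0.25)),
               (0.75 * log(0.75) + 0.25 * log(0.25)) / log(2),
               tolerance = 1e-12)
  expect_equal(round(patientEntropyLoss(c(0.75, 0.25)), 3), -0.811)
  expect_error(patientEntropyLoss(c(0, 0)), "all-zero")
  set.seed(6)
  for (i in 1:10) {
    S <- multiplexTME:::.softmaxRows(matrix(rnorm(15), 5, 3))
    expect_true(patchEntropyLoss(S) >= 0 && patchEntropyLoss(S) <= 1)
    v <- runif(4)
    expect_true(patientEntropyLoss(v) >= -1 && patientEntropyLoss(v) <= 0)
  }
})

test_that("total loss composes from independently computed components", {
  cfg <- modelConfig(P = 3L, N = 3L, A = 2L, lambda_ep = 0.1,
                     lambda_en = 0.2, lambda_ea = 0.3, lambda_pp = 0.4,
                     lambda_pn = 0.5, lambda_pa = 0.6)
  set.seed(7)
  SP <- multiplexTME:::.softmaxRows(matrix(rnorm(12), 4, 3))
  SN <- multiplexTME:::.softmaxRows(matrix(rnorm(12), 4, 3))
  SA <- multiplexTME:::.softmaxRows(matrix(rnorm(6), 3, 2))
  ab <- list(P = maxSumPool(SP), N = maxSumPool(SN), A = maxSumPool(SA))
  logits <- c(1.2, -0.3, 0.4)
  ref <- -log(exp(logits[2]) / sum(exp(logits))) +
    (0.1 * patchEntropyLoss(SP) + 0.2 * patchEntropyLoss(SN) +
       0.3 * patchEntropyLoss(SA)) / 3 +
    (0.4 * patientEntropyLoss(ab$P) + 0.5 * patientEntropyLoss(ab$N) +
       0.6 * patientEntropyLoss(ab$A)) / 3
  expect_equal(totalLoss(logits, 2L, SP, SN, SA, ab, cfg), ref,
               tolerance = 1e-12)
  # all lambdas zero -> exactly cross-entropy
  cfg0 <- modelConfig(lambda_ep = 0, lambda_en = 0, lambda_ea = 0,
                      lambda_pp = 0, lambda_pn = 0, lambda_pa = 0)
  expect_equal(totalLoss(logits, 1L, SP, SN, SA, ab, cfg0),
               -log(exp(logits[1]) / sum(exp(logits))), tolerance = 1e-12)
})

test_that("assignment networks have the documented pointwise/graph behavior", {
  m <- toyTrainedModel()
  g <- toyGraph(2L, 3L, g = 6L, seed = 31L)
  Z <- embeddingMatrix(g)
  lp <- phenotypeAssign(Z, m)
  expect_identical(dim(lp), c(6L, 4L))
  # pointwise map: duplicated rows give duplicated logits
  lp2 <- phenotypeAssign(Z[c(1, 1, 3), ], m)
  expect_equal(lp2[1, ], lp2[2, ], tolerance = 1e-12)
  expect_equal(lp2[1, ], lp[1, ], tolerance = 1e-12)

  # no edges, K = 1: output equals the pointwise self-transform
  na <- neighborhoodAssign(Z, matrix(0L, 0, 2), m)
  p <- m@params
  selfOnly <- multiplexTME:::.relu(sweep(Z %*% p$Ns1, 2, p$Nb1, "+"))
  expect_equal(na$ZK, selfOnly, tolerance = 1e-12)
  # identical features on a regular (cycle) graph -> identical rows
  Zc <- matrix(1, 4, 6)
  cyc <- cbind(c(1, 2, 3, 4, 2, 3, 4, 1), c(2, 3, 4, 1, 1, 2, 3, 4))
  nac <- neighborhoodAssign(Zc, cyc, m)
  expect_lt(max(abs(sweep(nac$logits, 2, nac$logits[1, ]))), 1e-10)
})

test_that("two GNN hops extend the receptive field along a path", {
  cfg <- modelConfig(P = 2L, N = 2L, A = 2L, K = 2L, hidden = 4L, seed = 3L)
  set.seed(3)
  params <- multiplexTME:::.tmeInitParams(cfg, 3L, 2L)
  attr(params, "config") <- unclass(cfg)
  edges <- cbind(c(1, 2, 2, 3), c(2, 1, 3, 2))     # path a - b - c
  Z <- matrix(rnorm(9), 3, 3)
  base <- neighborhoodAssign(Z, edges, structure(params,
                                                 config = unclass(cfg)))
  Z2 <- Z; Z2[3, ] <- Z2[3, ] + 5                  # perturb node c
  pert <- neighborhoodAssign(Z2, edges, structure(params,
                                                  config = unclass(cfg)))
  expect_gt(max(abs(pert$ZK[1, ] - base$ZK[1, ])), 1e-8)  # a sees c in 2 hops
  # with K = 1 node a must NOT see c
  cfg1 <- modelConfig(P = 2L, N = 2L, A = 2L, K = 1L, hidden = 4L, seed = 3L)
  set.seed(3)
  params1 <- multiplexTME:::.tmeInitParams(cfg1, 3L, 2L)
  b1 <- neighborhoodAssign(Z, edges, structure(params1, config = unclass(cfg1)))
  p1 <- neighborhoodAssign(Z2, edges, structure(params1, config = unclass(cfg1)))
  expect_lt(max(abs(p1$ZK[1, ] - b1$ZK[1, ])), 1e-12)
})

test_that("coarse features and adjacency follow the matrix definitions", {
  m <- toyTrainedModel()
  # two disconnected 2-node components, one-hot assignment per component
  edges <- cbind(c(1, 2, 3, 4), c(2, 1, 4, 3))
  SN <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 1, 0, 0))
  ZK <- matrix(rnorm(4 * 8), 4, 8)
  C <- crossprod(SN, ZK)
  expect_equal(C[1, ], ZK[1, ] + ZK[2, ])
  A <- Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = 1,
                            dims = c(4, 4))
  Q <- crossprod(SN, as.matrix(A %*% SN))
  expect_equal(Q[1, 2], 0)               # disconnected -> zero off-diagonal
  expect_equal(Q[2, 1], 0)
  expect_equal(Q[1, 1], 2)               # within-block directed edges
  # all patches in one neighborhood -> single nonzero diagonal block
  S1 <- cbind(rep(1, 4), 0, 0, 0)
  Q1 <- crossprod(S1, as.matrix(A %*% S1))
  expect_equal(Q1[1, 1], 4)
  expect_equal(sum(Q1) - Q1[1, 1], 0)
  la <- areaAssign(SN, ZK, edges, m)
  expect_identical(dim(la), c(4L, 3L))
})

test_that("classifier probabilities are a softmaxed affine map", {
  m <- toyTrainedModel()
  ab <- maxSumPoolAll <- runif(nrow(m@params$Wf), 1, 5)
  pr <- classifyAbundance(m, ab)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_true(all(pr >= 0 & pr <= 1))
  # zero weights -> uniform over classes
  m0 <- m
  m0@params$Wf <- m@params$Wf * 0
  m0@params$bf <- m@params$bf * 0
  expect_equal(unname(classifyAbundance(m0, ab)), rep(0.5, 2))
  # affine: scaling abundances changes logits linearly (1-layer map)
  xs <- function(v) (v - m@params$.featMu) / m@params$.featSd
  l1 <- xs(ab) %*% m@params$Wf
  l2 <- xs(2 * ab) %*% m@params$Wf
  l3 <- xs(3 * ab) %*% m@params$Wf
  expect_equal(l3 - l2, l2 - l1, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences on a toy graph", {
  set.seed(11)
  mk <- function(pid, lab, seed) toyGraph(2L, 3L, g = 5L, pid = pid,
                                          label = lab, seed = seed)
  graphs <- list(mk("a", "x", 41L), mk("b", "y", 42L))
  cfg <- modelConfig(P = 3L, N = 3L, A = 2L, K = 2L, hidden = 4L,
                     lambda_ep = 0.05, lambda_en = 0.07, lambda_ea = 0.04,
                     lambda_pp = 0.3, lambda_pn = 0.2, lambda_pa = 0.25,
                     seed = 2L)
  d <- multiplexTME:::.buildModelData(graphs, rep(0, 5), rep(1, 5))
  set.seed(3)
  params <- multiplexTME:::.tmeInitParams(cfg, 5L, 2L)
  # evaluate at a generic point: exact-zero biases put dead ReLU units
  # precisely on the kink, where one-sided derivatives differ
  params <- lapply(params, function(w) w + rnorm(length(w), sd = 0.05))
  fs <- rep(1, nrow(params$Wf))
  y <- c(1L, 2L)
  fw <- multiplexTME:::.tmeForward(d, params, cfg, y = y, featSd = fs,
                                   wantGrad = TRUE)
  f <- function(p) multiplexTME:::.tmeForward(d, p, cfg, y = y,
                                              featSd = fs)$loss
  set.seed(4)
  for (nm in names(params)) {
    if (!is.matrix(params[[nm]])) next
    for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      h <- 1e-5
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h; up <- f(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h; dn <- f(pp)
      num <- (up - dn) / (2 * h)
      expect_lt(abs(num - fw$grads[[nm]][i]) / max(abs(num), 1e-6), 1e-4)
    }
  }
})

test_that("abundances and predictions are invariant to patch relabeling", {
  m <- toyTrainedModel()
  g <- toySeparableGraphs()[[1]]
  a1 <- assignTMEs(m, g)
  set.seed(9)
  perm <- sample(nrow(g@Z))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  edges <- cbind(inv[g@edges[, 1]], inv[g@edges[, 2]])
  gp <- new("PatchGraph", Z = g@Z[perm, ], edges = edges,
            patientId = g@patientId, label = g@label,
            coords = g@coords[perm, ], imageId = g@imageId,
            nodeImage = g@nodeImage[perm])
  a2 <- assignTMEs(m, gp)
  expect_equal(a2$abundance, a1$abundance, tolerance = 1e-8)
  expect_equal(a2$probs, a1$probs, tolerance = 1e-8)
  expect_equal(a2$SP[inv, ], a1$SP, tolerance = 1e-8)
})

test_that("training learns a linearly separable toy cohort deterministically", {
  m <- toyTrainedModel()
  graphs <- toySeparableGraphs()
  pr <- predictTMEModel(m, graphs)
  labs <- vapply(graphs, patientLabel, "")
  expect_gte(mean(pr$predicted == labs), 0.95)
  # abundance invariants
  ab <- pr$abundance
  L <- 36
  expect_true(all(rowSums(ab[, 1:4]) <= L + 1e-9))
  expect_true(all(rowSums(ab[, 1:4]) >= L / 4 - 1e-9))
  # determinism: same data + config + seed reproduces the weights
  cfg <- modelConfig(P = 4L, N = 4L, A = 3L, K = 1L, hidden = 8L,
                     epochs = 15L, patience = 15L, seed = 13L)
  m1 <- trainTMEModel(graphs, cfg)
  m2 <- trainTMEModel(graphs, cfg)
  expect_equal(m1@params$Wf, m2@params$Wf, tolerance = 1e-12)
  expect_error(trainTMEModel(graphs[1:3], cfg), "single class")
})

test_that("architecture search returns the argmax of its leaderboard", {
  graphs <- toySeparableGraphs()
  sr <- searchArchitecture(graphs, nTrials = 3L, epochs = 10L, seed = 5L,
                           baseConfig = modelConfig(P = 4L, N = 4L, A = 3L,
                                                    hidden = 8L))
  expect_identical(nrow(sr$leaderboard), 3L)
  expect_true(all(sr$leaderboard$score[1] >= sr$leaderboard$score))
  sr1 <- searchArchitecture(graphs, nTrials = 1L, epochs = 5L, seed = 6L)
  expect_identical(nrow(sr1$leaderboard), 1L)
  expect_error(searchArchitecture(graphs, nTrials = 1L, space = list()),
               "infeasible")
})

test_that("ablation flags shrink the classifier input accordingly", {
  cfgs <- list(
    full = modelConfig(P = 4L, N = 3L, A = 2L),
    noP = modelConfig(P = 4L, N = 3L, A = 2L, use_phenotypes = FALSE),
    noN = modelConfig(P = 4L, N = 3L, A = 2L, use_neighborhoods = FALSE),
    noA = modelConfig(P = 4L, N = 3L, A = 2L, use_areas = FALSE))
  widths <- vapply(cfgs, multiplexTME:::.f2Width, 0L)
  expect_identical(unname(widths), c(9L, 5L, 6L, 7L))
  expect_error(modelConfig(use_phenotypes = FALSE, use_neighborhoods = FALSE,
                           use_areas = FALSE), "at least one")
})
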