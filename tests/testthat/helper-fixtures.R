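# Shared fixtures, built once per test session and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small cohort of simulated tissues (one per patient type) for a paradigm
smallTissues <- function(paradigm = "CCI1", size = 160L, seedBase = 300L) {
  memo(paste0("tissues_", paradigm, "_", size), {
    base <- defaultCohortConfig(c(size, size))
    lapply(1:3, function(ti) {
      cfg <- applyParadigm(base, paradigm, ti)
      cfg$seed <- deriveSeed(seedBase, ti)
      simulateTissue(cfg)
    })
  })
}

# a tiny trained encoder shared across PCL tests
tinyEncoder <- function() {
  memo("tiny_encoder", {
    tis <- smallTissues("none", 120L)
    cfg <- pclConfig(patch_size = 8L, batch_crops = 16L, embedding_dim = 32L,
                     projection_dim = 16L, max_iters = 60L,
                     learning_rate = 2e-3, seed = 9L)
    trainPCL(lapply(tis, `[[`, "image"), cfg)
  })
}

# deterministic toy patch graph with random embeddings
toyGraph <- function(rows = 2L, cols = 3L, g = 5L, pid = "pt", label = "x",
                     seed = 7L) {
  set.seed(seed)
  emb <- new("EmbeddedImage", embeddings = matrix(rnorm(rows * cols * g),
                                                  rows * cols, g),
             gridShape = c(rows, cols), patchSize = 2L, imageId = pid)
  buildPatchGraph(emb, label = label, patientId = pid)
}

# a synthetic, linearly separable toy cohort of patch graphs: class is
# determined by the abundance of a marker-pure patch type
toySeparableGraphs <- function(nPerClass = 8L, L = 36L, g = 6L, seed = 21L) {
  memo(paste0("sep_graphs_", nPerClass, "_", L), {
    set.seed(seed)
    graphs <- list()
    k <- 0L
    for (cl in c("a", "b")) {
      for (i in seq_len(nPerClass)) {
        k <- k + 1L
        frac <- if (cl == "a") 0.65 else 0.15   # abundance of pure type
        n1 <- round(L * frac)
        Z <- rbind(matrix(rnorm(n1 * g, mean = 2), n1, g) *
                     rep(c(1, 0, 0, 1, 0, 0), each = n1),
                   matrix(rnorm((L - n1) * g, mean = 0.3), L - n1, g))
        Z <- Z[sample(L), ]
        emb <- new("EmbeddedImage", embeddings = Z,
                   gridShape = c(6L, 6L), patchSize = 2L,
                   imageId = sprintf("%s%02d", cl, i))
        graphs[[k]] <- buildPatchGraph(emb, label = cl,
                                       patientId = sprintf("%s%02d", cl, i))
      }
    }
    graphs
  })
}

# a tiny trained model on the separable cohort
toyTrainedModel <- function() {
  memo("toy_model", {
    graphs <- toySeparableGraphs()
    cfg <- modelConfig(P = 4L, N = 4L, A = 3L, K = 1L, hidden = 8L,
                       epochs = 60L, patience = 60L, learning_rate = 0.02,
                       seed = 13L)
    trainTMEModel(graphs, cfg)
  })
}
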