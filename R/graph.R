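# Sparse patch graphs: nodes are patch embeddings on the patch grid,
# edges connect adjacent patches; stored as a directed edge list with
# both orientations so memory grows linearly in L.

#' Build the sparse patch graph of an embedded image
#'
#' Connects each patch to its 4 adjacent grid neighbors (up/down/left/
#' right; border nodes have fewer). Coordinates are 0-based, row-major,
#' origin top-left. An 8-neighbor variant (diagonals included) exists for
#' sensitivity analysis and is off by default.
#'
#' @param embedded an [EmbeddedImage-class].
#' @param label patient-level label (character or factor level).
#' @param patientId patient identifier.
#' @param diagonal also connect the 4 diagonal neighbors.
#' @return a [PatchGraph-class].
#' @export
buildPatchGraph <- function(embedded, label = NA_character_,
                            patientId = embedded@imageId, diagonal = FALSE) {
  gs <- gridShape(embedded)
  rows <- gs[1]; cols <- gs[2]
  L <- rows * cols
  .assertThat(L == nrow(embeddingMatrix(embedded)),
              "grid shape inconsistent with embedding count")
  r <- rep(seq_len(rows), each = cols)
  cc <- rep(seq_len(cols), times = rows)
  id <- function(rr, ccc) (rr - 1L) * cols + ccc
  from <- integer(0); to <- integer(0)
  add <- function(dr, dc) {
    ok <- r + dr >= 1 & r + dr <= rows & cc + dc >= 1 & cc + dc <= cols
    from <<- c(from, id(r[ok], cc[ok]))
    to <<- c(to, id(r[ok] + dr, cc[ok] + dc))
  }
  add(-1L, 0L); add(1L, 0L); add(0L, -1L); add(0L, 1L)
  if (diagonal) { add(-1L, -1L); add(-1L, 1L); add(1L, -1L); add(1L, 1L) }
  new("PatchGraph", Z = embeddingMatrix(embedded),
      edges = cbind(from, to, deparse.level = 0),
      patientId = patientId, label = as.character(label),
      coords = cbind(r - 1L, cc - 1L), imageId = embedded@imageId,
      nodeImage = rep(1L, L))
}

#' Merge all images of one patient into a single disjoint graph
#'
#' Concatenates node blocks and reindexes edges; no edges are introduced
#' between images, so the merged graph has one connected component per
#' (connected) input image.
#'
#' @param graphs list of [PatchGraph-class] sharing patientId and label.
#' @return a single [PatchGraph-class].
#' @export
mergePatientGraphs <- function(graphs) {
  .assertThat(length(graphs) >= 1, "no graphs to merge")
  pid <- unique(vapply(graphs, patientId, ""))
  lab <- unique(vapply(graphs, patientLabel, ""))
  .assertThat(length(pid) == 1, "graphs belong to different patients: %s",
              paste(pid, collapse = ", "))
  .assertThat(length(lab) == 1, "graphs carry different labels")
  if (length(graphs) == 1) return(graphs[[1]])
  sizes <- vapply(graphs, function(g) nrow(g@Z), 0L)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  Z <- do.call(rbind, lapply(graphs, function(g) g@Z))
  edges <- do.call(rbind, Map(function(g, o) g@edges + o, graphs, offs))
  coords <- do.call(rbind, lapply(graphs, function(g) g@coords))
  nodeImage <- unlist(Map(function(g, i) rep(i, nrow(g@Z)),
                          graphs, seq_along(graphs)))
  new("PatchGraph", Z = Z, edges = edges, patientId = pid, label = lab,
      coords = coords,
      imageId = vapply(graphs, function(g) g@imageId[1], ""),
      nodeImage = as.integer(nodeImage))
}

#' Persist a patch graph
#'
#' Writes the node features, edge list and metadata as a compressed RDS
#' plus a JSON sidecar; `readPatchGraph` restores it losslessly.
#'
#' @param graph a [PatchGraph-class].
#' @param path file path (`.rds`).
#' @export
writePatchGraph <- function(graph, path) {
  saveRDS(list(Z = graph@Z, edges = graph@edges, patientId = graph@patientId,
               label = graph@label, coords = graph@coords,
               imageId = graph@imageId, nodeImage = graph@nodeImage), path)
  meta <- list(patient_id = graph@patientId, label = graph@label,
               n_nodes = nrow(graph@Z), n_edges = nrow(graph@edges),
               images = graph@imageId)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePatchGraph
#' @export
readPatchGraph <- function(path) {
  x <- readRDS(path)
  new("PatchGraph", Z = x$Z, edges = x$edges, patientId = x$patientId,
      label = x$label, coords = x$coords, imageId = x$imageId,
      nodeImage = x$nodeImage)
}
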