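# Generative specification of synthetic multiplex cohorts.
#
# Eight phenotypes expressing six markers: Ph1..Ph6 each dominated by one
# marker (near-orthogonal signatures), Ph7/Ph8 are two-marker mixtures.
# Four neighborhoods with abundance vectors concentrated on 2-3 phenotypes.
# Disease paradigms perturb exactly one of these knobs per patient type.

.PARADIGMS <- c("PMI1", "PMI2", "PF1", "PF2", "CCI1", "CCI2", "NNI1", "none")
.PATIENT_TYPES <- c("I", "II", "III")

#' Default synthetic-cohort configuration
#'
#' Returns the documented default generative model: 8 cell phenotypes
#' defined by probabilistic expression of 6 markers plus cell size and
#' eccentricity, and 4 cellular neighborhoods defined by phenotype
#' abundance vectors, pairwise phenotype attraction/repulsion rules and
#' tissue prevalences. Disease paradigms are applied on top of this default
#' with [applyParadigm()].
#'
#' @param imageSize integer (height, width) in pixels.
#' @param seed integer seed stored in the config; `simulateTissue()` is
#'   deterministic given the config.
#' @return A `CohortConfig` list (classed `"CohortConfig"`).
#' @export
defaultCohortConfig <- function(imageSize = c(800L, 800L), seed = 1L) {
  B <- 6L
  mk <- function(idx, val) { e <- rep(0.05, B); e[idx] <- val; e }
  phen <- function(id, expr, noise, radius, ecc)
    list(id = id, marker_expression = expr, expression_noise = rep(noise, B),
         cell_radius_px = radius, eccentricity = ecc)
  phenotypes <- list(
    phen("Ph1", mk(1L, 0.85), 0.06, 5.0, 0.20),
    phen("Ph2", mk(2L, 0.85), 0.06, 4.0, 0.50),
    phen("Ph3", mk(3L, 0.85), 0.06, 6.0, 0.10),
    phen("Ph4", mk(4L, 0.85), 0.06, 5.0, 0.30),
    phen("Ph5", mk(5L, 0.85), 0.06, 5.0, 0.30),
    phen("Ph6", mk(6L, 0.85), 0.06, 4.0, 0.60),
    phen("Ph7", mk(c(1L, 2L), 0.50), 0.06, 5.0, 0.40),
    phen("Ph8", mk(c(2L, 3L), 0.45), 0.06, 6.0, 0.20))
  nb <- function(id, ab, prev) {
    v <- rep(0, 8); v[ab[, 1]] <- ab[, 2]
    list(id = id, phenotype_abundance = v / sum(v), tissue_prevalence = prev)
  }
  neighborhoods <- list(
    nb("Nb1", cbind(c(1, 2, 7), c(0.55, 0.30, 0.15)), 0.35),
    nb("Nb2", cbind(c(3, 4, 5), c(0.90, 0.05, 0.05)), 0.25),
    nb("Nb3", cbind(c(1, 6, 8), c(0.45, 0.15, 0.40)), 0.25),
    nb("Nb4", cbind(c(2, 7, 8), c(0.35, 0.35, 0.30)), 0.15))
  cfg <- list(
    phenotypes = phenotypes,
    neighborhoods = neighborhoods,
    phenotype_interactions = matrix(0, 8, 8),
    neighborhood_interactions = matrix(0, 4, 4),
    image_size_px = as.integer(imageSize),
    n_markers = B,
    markers = paste0("Mk", seq_len(B)),
    # placement parameters: jittered hexagonal packing of cell sites,
    # attraction realized at contact range, repulsion at long range
    spacing_factor = 1.15,
    jitter_frac = 0.12,
    attract_dist_factor = 1.4,
    repel_dist_px = 45,
    background_noise_sd = 0.02,
    paradigm = "none",
    patient_type = NA_character_,
    seed = as.integer(seed))
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants of a `CohortConfig`: marker-expression
#' means and noise in `[0, 1]`, positive radii, eccentricity in `[0, 1)`,
#' abundance vectors summing to 1, symmetric interaction matrices and
#' tissue prevalences summing to at most 1.
#'
#' @param cfg a `CohortConfig`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validateCohortConfig <- function(cfg) {
  B <- cfg$n_markers
  nP <- length(cfg$phenotypes)
  for (ph in cfg$phenotypes) {
    .assertThat(length(ph$marker_expression) == B,
                "phenotype %s: expected %d marker means", ph$id, B)
    .assertThat(all(ph$marker_expression >= 0 & ph$marker_expression <= 1),
                "phenotype %s: marker expression outside [0,1]", ph$id)
    .assertThat(ph$cell_radius_px > 0, "phenotype %s: radius must be > 0", ph$id)
    .assertThat(ph$eccentricity >= 0 && ph$eccentricity < 1,
                "phenotype %s: eccentricity outside [0,1)", ph$id)
  }
  prev <- vapply(cfg$neighborhoods, `[[`, 0, "tissue_prevalence")
  .assertThat(sum(prev) <= 1 + 1e-9, "tissue prevalences sum to more than 1")
  for (nbh in cfg$neighborhoods) {
    ab <- nbh$phenotype_abundance
    .assertThat(length(ab) == nP, "neighborhood %s: bad abundance length", nbh$id)
    .assertThat(abs(sum(ab) - 1) < 1e-9,
                "neighborhood %s: abundance must sum to 1", nbh$id)
  }
  .assertThat(isTRUE(all.equal(cfg$phenotype_interactions,
                               t(cfg$phenotype_interactions))),
              "phenotype interaction matrix must be symmetric")
  .assertThat(isTRUE(all.equal(cfg$neighborhood_interactions,
                               t(cfg$neighborhood_interactions))),
              "neighborhood interaction matrix must be symmetric")
  invisible(cfg)
}

# Set the abundance of phenotypes `ph` (vector) in neighborhood `nb` to
# `value` (recycled), rescaling the remaining phenotypes to fill the rest.
.setAbundance <- function(cfg, nb, ph, value) {
  ab <- cfg$neighborhoods[[nb]]$phenotype_abundance
  value <- rep_len(value, length(ph))
  rest <- ab; rest[ph] <- 0
  if (sum(rest) == 0) rest[-ph] <- 1
  ab <- rest / sum(rest) * (1 - sum(value))
  ab[ph] <- value
  cfg$neighborhoods[[nb]]$phenotype_abundance <- ab
  cfg
}

#' Apply a disease paradigm to a cohort configuration
#'
#' Produces the patient-type-specific configuration for one of the seven
#' disease paradigms. Only the paradigm-defining parameters are modified:
#'
#' * `PMI1`/`PMI2` (phenotype marker intensity): Ph6 cells in Nb3 express
#'   Mk6 at 25/50/75% relative intensity for patient types I/II/III; Ph6
#'   abundance in Nb3 is 15% (PMI1) or 0.25% (PMI2).
#' * `PF1`/`PF2` (phenotype frequency): Ph6 abundance in Nb3 is 0/30/60%
#'   (PF1) or 0/0.12/0.25% (PF2) by patient type.
#' * `CCI1`/`CCI2` (cell-cell interaction): Ph4 and Ph5 abundance in Nb2 is
#'   5% each (CCI1) or 1% (CCI2); the Ph4-Ph5 interaction is repulsion /
#'   none / attraction for types I/II/III.
#' * `NNI1` (neighborhood-neighborhood interaction): Nb2 and Nb3 prevalence
#'   set to 15% each; their interaction is repulsion / none / attraction by
#'   patient type.
#'
#' @param cfg a `CohortConfig` (usually [defaultCohortConfig()]).
#' @param paradigm one of `"PMI1"`, `"PMI2"`, `"PF1"`, `"PF2"`, `"CCI1"`,
#'   `"CCI2"`, `"NNI1"`, `"none"`.
#' @param patientType `"I"`, `"II"` or `"III"` (or 1:3).
#' @return A modified copy of `cfg`.
#' @export
applyParadigm <- function(cfg, paradigm, patientType) {
  if (is.numeric(patientType)) patientType <- .PATIENT_TYPES[patientType]
  .assertThat(paradigm %in% .PARADIGMS, "unknown paradigm '%s'", paradigm)
  .assertThat(patientType %in% .PATIENT_TYPES,
              "unknown patient type '%s'", patientType)
  ti <- match(patientType, .PATIENT_TYPES)
  out <- cfg
  if (paradigm %in% c("PMI1", "PMI2")) {
    ab <- if (paradigm == "PMI1") 0.15 else 0.0025
    out <- .setAbundance(out, 3L, 6L, ab)
    rel <- c(0.25, 0.50, 0.75)[ti]
    out$phenotypes[[6]]$marker_expression[6] <-
      cfg$phenotypes[[6]]$marker_expression[6] * rel
  } else if (paradigm == "PF1") {
    out <- .setAbundance(out, 3L, 6L, c(0, 0.30, 0.60)[ti])
  } else if (paradigm == "PF2") {
    out <- .setAbundance(out, 3L, 6L, c(0, 0.0012, 0.0025)[ti])
  } else if (paradigm %in% c("CCI1", "CCI2")) {
    ab <- if (paradigm == "CCI1") 0.05 else 0.01
    out <- .setAbundance(out, 2L, c(4L, 5L), ab)
    w <- c(-1, 0, 1)[ti]
    out$phenotype_interactions[4, 5] <- w
    out$phenotype_interactions[5, 4] <- w
  } else if (paradigm == "NNI1") {
    w <- c(-1, 0, 1)[ti]
    out$neighborhood_interactions[2, 3] <- w
    out$neighborhood_interactions[3, 2] <- w
    prev <- vapply(out$neighborhoods, `[[`, 0, "tissue_prevalence")
    others <- setdiff(seq_along(prev), c(2L, 3L))
    rest <- prev[others] / sum(prev[others]) * (1 - 0.30)
    prev[c(2L, 3L)] <- 0.15
    prev[others] <- rest
    for (i in seq_along(prev))
      out$neighborhoods[[i]]$tissue_prevalence <- prev[i]
  }
  out$paradigm <- paradigm
  out$patient_type <- patientType
  validateCohortConfig(out)
  out
}

#' Write / read a cohort configuration as YAML
#'
#' Round-trips the full generative specification through YAML so cohorts
#' can be regenerated outside R sessions.
#'
#' @param cfg a `CohortConfig`.
#' @param path file path.
#' @return `readCohortConfig` returns the `CohortConfig`.
#' @export
writeCohortConfig <- function(cfg, path) {
  x <- unclass(cfg)
  x$phenotype_interactions <- as.vector(x$phenotype_interactions)
  x$neighborhood_interactions <- as.vector(x$neighborhood_interactions)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeCohortConfig
#' @export
readCohortConfig <- function(path) {
  x <- yaml::read_yaml(path)
  nP <- length(x$phenotypes)
  nN <- length(x$neighborhoods)
  x$phenotype_interactions <- matrix(unlist(x$phenotype_interactions), nP, nP)
  x$neighborhood_interactions <- matrix(unlist(x$neighborhood_interactions), nN, nN)
  for (i in seq_len(nN))
    x$neighborhoods[[i]]$phenotype_abundance <-
      unlist(x$neighborhoods[[i]]$phenotype_abundance)
  for (i in seq_len(nP)) {
    x$phenotypes[[i]]$marker_expression <- unlist(x$phenotypes[[i]]$marker_expression)
    x$phenotypes[[i]]$expression_noise <- unlist(x$phenotypes[[i]]$expression_noise)
  }
  x$image_size_px <- as.integer(unlist(x$image_size_px))
  class(x) <- "CohortConfig"
  validateCohortConfig(x)
  x
}
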