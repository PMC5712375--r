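#' Electrode layouts
#'
#' An `electrode_layout` holds named positions of scalp electrodes on a unit
#' sphere (head model with Cz at the vertex, x to the right, y to the nasion,
#' z up) together with the ordered subset of electrodes used for feature
#' extraction. Pairwise 3-D Euclidean (chord) distances between electrodes
#' feed the surface-Laplacian weights.
#'
#' @name electrode_layout
NULL

# unit vector from inclination alpha (deg from vertex) and azimuth beta
# (deg from the nasion direction, positive towards the right ear)
.sph <- function(alpha, beta) {
  a <- alpha * pi / 180
  b <- beta * pi / 180
  c(x = sin(a) * sin(b), y = sin(a) * cos(b), z = cos(a))
}

# spherical linear interpolation between two unit vectors
.slerp <- function(p, q, t) {
  omega <- acos(max(-1, min(1, sum(p * q))))
  if (omega < 1e-12) return(p)
  (sin((1 - t) * omega) * p + sin(t * omega) * q) / sin(omega)
}

#' Standard 31-channel 10/10 layout
#'
#' Builds a 31-electrode montage on the unit sphere from the 10/10
#' arc-construction: the outer 10% circle sits at 72 degrees inclination,
#' midline electrodes at 18-degree steps, and intermediate electrodes are
#' placed by spherical interpolation along their row arcs. The analysis
#' subset is the nine central electrodes surrounding Cz.
#'
#' The montage is a geometric idealisation (spherical head, no digitised
#' positions); it exists to supply inter-electrode distances for the
#' Laplacian filter, for which chord-length ratios are what matter.
#'
#' @return An `electrode_layout`: list with `positions` (tibble of
#'   `name`, `x`, `y`, `z`), and `feature_subset` (character vector of the
#'   9 analysis electrodes).
#' @examples
#' lay <- standard_1010_layout()
#' lay$positions
#' @export
standard_1010_layout <- function() {
  pos <- list(
    Fp1 = .sph(72, -18), Fp2 = .sph(72, 18),
    F7  = .sph(72, -54), F8  = .sph(72, 54),
    T7  = .sph(72, -90), T8  = .sph(72, 90),
    P7  = .sph(72, -126), P8 = .sph(72, 126),
    PO7 = .sph(72, -144), PO8 = .sph(72, 144),
    O1  = .sph(72, -162), O2 = .sph(72, 162),
    Oz  = .sph(72, 180),
    Fz  = .sph(36, 0), Cz = .sph(0, 0),
    Pz  = .sph(36, 180), POz = .sph(54, 180),
    C3  = .sph(36, -90), C4 = .sph(36, 90)
  )
  # intermediate electrodes: quarter points of the arc from the outer-circle
  # electrode of the row to the midline electrode of the row
  ft7 <- .sph(72, -72); fcz <- .sph(18, 0)
  tp7 <- .sph(72, -108); cpz <- .sph(18, 180)
  pos$F3  <- .slerp(pos$F7, pos$Fz, 0.5)
  pos$FC5 <- .slerp(ft7, fcz, 0.25)
  pos$FC1 <- .slerp(ft7, fcz, 0.75)
  pos$CP5 <- .slerp(tp7, cpz, 0.25)
  pos$CP1 <- .slerp(tp7, cpz, 0.75)
  pos$P3  <- .slerp(pos$P7, pos$Pz, 0.5)
  mirror <- function(v) c(-v[["x"]], v[["y"]], v[["z"]])
  pos$F4  <- mirror(pos$F3)
  pos$FC6 <- mirror(pos$FC5)
  pos$FC2 <- mirror(pos$FC1)
  pos$CP6 <- mirror(pos$CP5)
  pos$CP2 <- mirror(pos$CP1)
  pos$P4  <- mirror(pos$P3)

  order_names <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                   "FC5", "FC1", "FC2", "FC6",
                   "T7", "C3", "Cz", "C4", "T8",
                   "CP5", "CP1", "CP2", "CP6",
                   "P7", "P3", "Pz", "P4", "P8",
                   "PO7", "POz", "PO8", "O1", "Oz", "O2")
  m <- do.call(rbind, pos[order_names])
  positions <- tibble::tibble(name = order_names,
                              x = m[, 1], y = m[, 2], z = m[, 3])
  new_electrode_layout(
    positions,
    feature_subset = c("Fz", "FC1", "FC2", "C3", "Cz", "C4",
                       "CP1", "CP2", "Pz")
  )
}

#' Construct an electrode layout
#'
#' @param positions Tibble/data frame with columns `name`, `x`, `y`, `z`;
#'   coordinates must be unit vectors.
#' @param feature_subset Character vector of electrode names used for
#'   feature extraction; must be a subset of `positions$name`.
#' @return An `electrode_layout` object.
#' @export
new_electrode_layout <- function(positions, feature_subset = positions$name) {
  positions <- tibble::as_tibble(positions)
  stopifnot(all(c("name", "x", "y", "z") %in% names(positions)))
  if (anyDuplicated(positions$name)) {
    stop_gaitbci("electrode names must be unique", "gaitbci_validation_error")
  }
  nrm <- sqrt(positions$x^2 + positions$y^2 + positions$z^2)
  if (any(abs(nrm - 1) > 1e-9)) {
    stop_gaitbci("electrode coordinates must lie on the unit sphere",
                 "gaitbci_validation_error")
  }
  if (!all(feature_subset %in% positions$name)) {
    stop_gaitbci("feature_subset contains unknown electrode names",
                 "gaitbci_validation_error")
  }
  structure(list(positions = positions, feature_subset = feature_subset),
            class = "electrode_layout")
}

#' Pairwise electrode distances
#'
#' 3-D Euclidean (chord) distances between all electrodes of a layout.
#'
#' @param layout An `electrode_layout`.
#' @return A symmetric matrix with zero diagonal, dimnames set to electrode
#'   names.
#' @export
electrode_distances <- function(layout) {
  stopifnot(inherits(layout, "electrode_layout"))
  m <- as.matrix(layout$positions[, c("x", "y", "z")])
  rownames(m) <- layout$positions$name
  d <- as.matrix(stats::dist(m))
  if (any(d[upper.tri(d)] <= 0)) {
    stop_gaitbci("duplicate electrode coordinates (zero distance)",
                 "gaitbci_geometry_error")
  }
  d
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout: %d electrodes, %d in feature subset>\n",
              nrow(x$positions), length(x$feature_subset)))
  invisible(x)
}
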