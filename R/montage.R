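# Idealized spherical 10-10 electrode geometry, constructed from the
# proportional-arc definition of the extended international 10-20 system:
# the outer ring sits 72 degrees from the vertex with electrodes every 18
# degrees of azimuth, the below-ring row (FT9/TP9/PO9 etc.) 90 degrees from
# the vertex, and intermediate electrodes are spaced evenly along the
# great-circle arcs from the ring to the midline.

slerp <- function(u, v, f) {
  omega <- acos(pmin(1, pmax(-1, sum(u * v))))
  if (omega < 1e-12) return(u)
  (sin((1 - f) * omega) * u + sin(f * omega) * v) / sin(omega)
}

# unit vector from polar angle theta (deg, from vertex) and azimuth az
# (deg; 90 = front, 180 = left, 270 = back, 0 = right); x right, y front,
# z up
sph_vec <- function(theta, az) {
  th <- theta * pi / 180
  a <- az * pi / 180
  c(cos(a) * sin(th), sin(a) * sin(th), cos(th))
}

#' Standard 64-channel 10-10 montage positions
#'
#' Idealized positions of 64 standard 10-10 electrodes on a spherical head
#' of the given radius, suitable for neighbor-based channel adjacency and
#' spherical-spline interpolation.
#'
#' @param head_radius Head sphere radius in meters (default 0.09).
#' @return A data.frame with columns `label`, `x`, `y`, `z` (meters).
#' @export
standard_montage_64 <- function(head_radius = 0.09) {
  ring_az <- c(Fp1 = 108, AF7 = 126, F7 = 144, FT7 = 162, T7 = 180,
               TP7 = 198, P7 = 216, PO7 = 234, O1 = 252, Oz = 270,
               O2 = 288, PO8 = 306, P8 = 324, TP8 = 342, T8 = 0,
               FT8 = 18, F8 = 36, AF8 = 54, Fp2 = 72)
  pos <- list()
  for (l in names(ring_az)) pos[[l]] <- sph_vec(72, ring_az[[l]])
  below <- c(FT9 = 162, TP9 = 198, PO9 = 234, PO10 = 306, TP10 = 342, FT10 = 18)
  for (l in names(below)) pos[[l]] <- sph_vec(90, below[[l]])
  midline <- list(Fz = c(36, 90), Cz = c(0, 90), CPz = c(18, 270),
                  Pz = c(36, 270), POz = c(54, 270))
  for (l in names(midline)) pos[[l]] <- sph_vec(midline[[l]][1], midline[[l]][2])
  # midline anchors for rows whose midline electrode is not in the set
  anchors <- list(AFz = sph_vec(54, 90), FCz = sph_vec(18, 90))

  arc <- function(edge, mid, labels, fracs) {
    for (i in seq_along(labels)) pos[[labels[i]]] <<- slerp(edge, mid, fracs[i])
  }
  arc(pos$AF7, anchors$AFz, "AF3", 0.5)
  arc(pos$AF8, anchors$AFz, "AF4", 0.5)
  arc(pos$F7, pos$Fz, c("F5", "F3", "F1"), c(0.25, 0.5, 0.75))
  arc(pos$F8, pos$Fz, c("F6", "F4", "F2"), c(0.25, 0.5, 0.75))
  arc(pos$FT7, anchors$FCz, c("FC5", "FC3", "FC1"), c(0.25, 0.5, 0.75))
  arc(pos$FT8, anchors$FCz, c("FC6", "FC4", "FC2"), c(0.25, 0.5, 0.75))
  arc(pos$T7, pos$Cz, c("C5", "C3", "C1"), c(0.25, 0.5, 0.75))
  arc(pos$T8, pos$Cz, c("C6", "C4", "C2"), c(0.25, 0.5, 0.75))
  arc(pos$TP7, pos$CPz, c("CP5", "CP3", "CP1"), c(0.25, 0.5, 0.75))
  arc(pos$TP8, pos$CPz, c("CP6", "CP4", "CP2"), c(0.25, 0.5, 0.75))
  arc(pos$P7, pos$Pz, c("P5", "P3", "P1"), c(0.25, 0.5, 0.75))
  arc(pos$P8, pos$Pz, c("P6", "P4", "P2"), c(0.25, 0.5, 0.75))
  arc(pos$PO7, pos$POz, "PO3", 0.5)
  arc(pos$PO8, pos$POz, "PO4", 0.5)

  mat <- do.call(rbind, pos) * head_radius
  data.frame(label = rownames(mat), x = mat[, 1], y = mat[, 2], z = mat[, 3],
             row.names = NULL)
}

#' Build a channel adjacency structure from electrode positions
#'
#' Channels whose Euclidean distance is within `radius` are neighbors.
#' Temporal adjacency of consecutive samples is implicit in the cluster
#' test; for one-dimensional (e.g. pupil) data an empty adjacency over a
#' single channel is valid.
#'
#' @param positions A data.frame with columns `label`, `x`, `y`, `z` (see
#'   [standard_montage_64()]), or `NULL`/zero rows for purely temporal data.
#' @param radius Neighbor radius in the montage's units (default 0.04 m).
#' @return An object of class `channel_adjacency` with `labels`, `pairs`
#'   (two-column matrix of channel indices, i < j) and `neighbors` (list of
#'   integer vectors per channel).
#' @export
build_adjacency <- function(positions = NULL, radius = 0.04) {
  if (is.null(positions) || nrow(positions) == 0) {
    return(structure(list(labels = character(0),
                          pairs = matrix(integer(0), ncol = 2),
                          neighbors = list()), class = "channel_adjacency"))
  }
  labels <- as.character(positions$label)
  if (anyDuplicated(labels)) stop("duplicate channel labels in montage")
  p <- as.matrix(positions[, c("x", "y", "z")])
  n <- nrow(p)
  d <- as.matrix(stats::dist(p))
  adj <- d <= radius & upper.tri(d)
  pairs <- which(adj, arr.ind = TRUE)
  pairs <- cbind(pairs[, 1], pairs[, 2])
  neighbors <- lapply(seq_len(n), function(i) {
    sort(unique(c(pairs[pairs[, 1] == i, 2], pairs[pairs[, 2] == i, 1])))
  })
  structure(list(labels = labels, pairs = pairs, neighbors = neighbors),
            class = "channel_adjacency")
}

#' @export
print.channel_adjacency <- function(x, ...) {
  cat(sprintf("<channel_adjacency> %d channels, %d neighbor pairs\n",
              length(x$labels), nrow(x$pairs)))
  invisible(x)
}
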