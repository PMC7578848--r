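# Standard 10-10 montage geometry: channel labels, 2-D projected positions,
# Delaunay channel adjacency and the four scalp regions of interest.

#' The 64 standard 10-10 channel labels
#'
#' The montage used throughout the pipeline (a 64-channel cap in 10-10
#' nomenclature, A/B amplifier order).
#' @return character vector of 64 labels.
#' @export
standardChannelNames <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2")
}

# Spherical construction of the 10-10 positions: midline electrodes sit on
# the nasion-inion arc at 22.5 degree steps from the vertex; the outer 10%
# ring (inclination 90 degrees) holds Fp1/2, AF7/8, F7/8, FT7/8, T7/8,
# TP7/8, P7/8, PO7/8, O1/2 at 18 degree azimuth steps; intermediate
# electrodes interpolate along the great circle from the midline electrode
# of their row to the row's ring electrode. P9/P10 and Iz lie 22.5 degrees
# below the ring.
.montage3d <- function() {
  deg <- pi / 180
  vec <- function(theta, az) {  # theta from vertex, az from nose, + = left
    c(sin(theta * deg) * sin(az * deg),
      sin(theta * deg) * cos(az * deg),
      cos(theta * deg))
  }
  slerp <- function(u, v, t) {
    om <- acos(max(-1, min(1, sum(u * v))))
    if (om < 1e-9) return(u)
    (sin((1 - t) * om) * u + sin(t * om) * v) / sin(om)
  }
  rows <- list(
    Fp = list(mid = 90,  az = 0,   ring = 18),
    AF = list(mid = 67.5, az = 0,  ring = 36),
    F  = list(mid = 45,  az = 0,   ring = 54),
    FC = list(mid = 22.5, az = 0,  ring = 72),
    C  = list(mid = 0,   az = 0,   ring = 90),
    CP = list(mid = 22.5, az = 180, ring = 108),
    P  = list(mid = 45,  az = 180, ring = 126),
    PO = list(mid = 67.5, az = 180, ring = 144),
    O  = list(mid = 90,  az = 180, ring = 162)
  )
  pos <- list()
  for (rn in names(rows)) {
    r <- rows[[rn]]
    mid <- vec(r$mid, r$az)
    for (side in c(-1, 1)) {
      ring <- vec(90, side * r$ring)
      sfx <- if (side < 0) c(1, 3, 5, 7) else c(2, 4, 6, 8)
      # ring electrode label per row
      ringlab <- switch(rn,
        Fp = paste0("Fp", if (side < 0) 1 else 2),
        AF = paste0("AF", if (side < 0) 7 else 8),
        F  = paste0("F", if (side < 0) 7 else 8),
        FC = paste0("FT", if (side < 0) 7 else 8),
        C  = paste0("T", if (side < 0) 7 else 8),
        CP = paste0("TP", if (side < 0) 7 else 8),
        P  = paste0("P", if (side < 0) 7 else 8),
        PO = paste0("PO", if (side < 0) 7 else 8),
        O  = paste0("O", if (side < 0) 1 else 2))
      pos[[ringlab]] <- ring
      for (g in 1:3) {  # interior grades between midline and ring
        lab <- paste0(rn, sfx[g])
        pos[[lab]] <- slerp(mid, ring, g / 4)
      }
    }
    pos[[paste0(rn, "z")]] <- mid
  }
  pos[["Cz"]] <- vec(0, 0)
  pos[["P9"]] <- vec(112.5, -126)
  pos[["P10"]] <- vec(112.5, 126)
  pos[["Iz"]] <- vec(112.5, 180)
  pos
}

#' 2-D projected positions of the standard montage
#'
#' Azimuthal (polar) projection of the spherical 10-10 positions: radius is
#' the inclination from the vertex, angle is the azimuth, so the head is a
#' disc with the nose up.
#'
#' @param channels channel labels to return (default: the full 64-channel
#'   montage). Unknown labels raise an error.
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
standardMontage <- function(channels = standardChannelNames()) {
  pos <- .montage3d()
  unknown <- setdiff(channels, names(pos))
  if (length(unknown))
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  xy <- t(vapply(channels, function(ch) {
    v <- pos[[ch]]
    theta <- acos(max(-1, min(1, v[3])))
    r <- sqrt(v[1] ^ 2 + v[2] ^ 2)
    if (r < 1e-12) c(0, 0) else theta * c(v[1], v[2]) / r
  }, numeric(2)))
  data.frame(channel = channels, x = xy[, 1], y = xy[, 2],
             row.names = NULL)
}

# environment memoizing Delaunay adjacency per coordinate set
.adjCache <- new.env(parent = emptyenv())

#' Channel adjacency by Delaunay triangulation
#'
#' Builds the symmetric, irreflexive neighbor relation used to exclude
#' neighboring channel pairs from phase-connectivity: two channels are
#' neighbors when they share an edge in the Delaunay triangulation of the
#' 2-D projected montage.
#'
#' @param channels channel labels.
#' @param positions data.frame with `channel`, `x`, `y` (default: the
#'   standard montage positions for `channels`).
#' @return logical channels x channels matrix; `TRUE` marks neighbors.
#' @export
buildAdjacency <- function(channels = standardChannelNames(),
                           positions = standardMontage(channels)) {
  stopifnot(all(channels %in% positions$channel))
  positions <- positions[match(channels, positions$channel), ]
  key <- paste(c(channels, round(positions$x, 9), round(positions$y, 9)),
               collapse = "|")
  hit <- get0(key, envir = .adjCache)
  if (!is.null(hit)) return(hit)
  p <- cbind(positions$x, positions$y)
  n <- nrow(p)
  adj <- matrix(FALSE, n, n, dimnames = list(channels, channels))
  tri <- utils::combn(n, 3)
  ax <- p[tri[1, ], 1]; ay <- p[tri[1, ], 2]
  bx <- p[tri[2, ], 1]; by <- p[tri[2, ], 2]
  cx <- p[tri[3, ], 1]; cy <- p[tri[3, ], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ok <- abs(d) > 1e-12
  ux <- ((ax ^ 2 + ay ^ 2) * (by - cy) + (bx ^ 2 + by ^ 2) * (cy - ay) +
           (cx ^ 2 + cy ^ 2) * (ay - by)) / d
  uy <- ((ax ^ 2 + ay ^ 2) * (cx - bx) + (bx ^ 2 + by ^ 2) * (ax - cx) +
           (cx ^ 2 + cy ^ 2) * (bx - ax)) / d
  r2 <- (ux - ax) ^ 2 + (uy - ay) ^ 2
  # a triangle is Delaunay when its circumcircle holds no other point
  d2 <- outer(ux, p[, 1], function(a, b) (a - b) ^ 2) +
    outer(uy, p[, 2], function(a, b) (a - b) ^ 2)
  # strict containment: triangle vertices and cocircular points sit on the
  # circle itself and do not disqualify the triangle
  inside <- d2 < r2 - 1e-9
  keep <- which(ok & rowSums(inside) == 0)
  for (t in keep) {
    v <- tri[, t]
    adj[v[1], v[2]] <- adj[v[2], v[1]] <- TRUE
    adj[v[1], v[3]] <- adj[v[3], v[1]] <- TRUE
    adj[v[2], v[3]] <- adj[v[3], v[2]] <- TRUE
  }
  diag(adj) <- FALSE
  assign(key, adj, envir = .adjCache)
  adj
}

#' The four connectivity regions of interest
#'
#' Channel membership of the left frontal, right frontal, left
#' parieto-occipital and right parieto-occipital regions used to summarize
#' inter-site phase coherence (11, 10, 9 and 9 channels respectively).
#'
#' @return named list of four character vectors.
#' @export
defaultRoiMap <- function() {
  list(
    left_frontal = c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7",
                     "FC1", "FC3", "FC5", "FT7"),
    right_frontal = c("Fp2", "F4", "F8", "FC2", "FC6", "F2", "AF4",
                      "FC4", "F6", "AF8"),
    left_parieto_occipital = c("P1", "P3", "P5", "P7", "CP3", "CP5",
                               "PO3", "PO7", "O1"),
    right_parieto_occipital = c("P2", "P4", "P6", "P8", "CP4", "CP6",
                                "PO4", "PO8", "O2")
  )
}
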