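#' Default 24-channel EEG montage
#'
#' A standard 10-20 montage of 24 Ag/AgCl positions on the unit sphere,
#' matching a compact mobile-EEG cap: frontal, frontocentral, central,
#' temporal, centroparietal, parietal and occipital rows, including the two
#' mastoids (TP9/TP10) used for linked-mastoid re-referencing and the channel
#' sets used for N1 (Fz, FC1, FC2, Cz, C3, C4) and P3 (Pz, P3, P4, CPz, CP1,
#' CP2) quantification.
#'
#' Positions are unit-norm xyz coordinates with +x to the right ear, +y to the
#' nasion and +z to the vertex.
#'
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @export
#' @examples
#' m <- default_montage()
#' stopifnot(nrow(m) == 24, all(abs(sqrt(m$x^2 + m$y^2 + m$z^2) - 1) < 1e-12))
default_montage <- function() {
  # (label, inclination from vertex [deg], azimuth from nasion [deg, +right])
  tab <- rbind(
    c("Fp1", 90, -18), c("Fp2", 90, 18),
    c("F7", 90, -54),  c("F3", 60, -39), c("Fz", 45, 0),
    c("F4", 60, 39),   c("F8", 90, 54),
    c("FC1", 31, -23), c("FC2", 31, 23),
    c("T7", 90, -90),  c("C3", 45, -90), c("Cz", 0, 0),
    c("C4", 45, 90),   c("T8", 90, 90),
    c("TP9", 108, -108), c("TP10", 108, 108),
    c("CP1", 31, -157), c("CP2", 31, 157), c("CPz", 22.5, 180),
    c("P3", 60, -141), c("Pz", 45, 180), c("P4", 60, 141),
    c("O1", 90, -162), c("O2", 90, 162)
  )
  incl <- as.numeric(tab[, 2]) * pi / 180
  az <- as.numeric(tab[, 3]) * pi / 180
  data.frame(
    label = tab[, 1],
    x = sin(incl) * sin(az),
    y = sin(incl) * cos(az),
    z = cos(incl),
    stringsAsFactors = FALSE
  )
}

# Great-circle (angular) distance between unit vectors and one center.
angular_dist <- function(pos, center) {
  cosang <- pmin(1, pmax(-1, as.matrix(pos) %*% center))
  acos(drop(cosang))
}

# Smooth Gaussian field on the sphere centered at a montage location;
# used for source topographies (frontocentral N1/P2/TRF, parietal P3, blinks).
gaussian_topography <- function(montage, center_label, sigma_rad = 0.8) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  ic <- match(center_label, montage$label)
  if (is.na(ic)) stop_fmt("montage has no channel '%s'", center_label)
  d <- angular_dist(pos, pos[ic, ])
  w <- exp(-d^2 / (2 * sigma_rad^2))
  stats::setNames(as.numeric(w), montage$label)
}

# Topography centered between two electrodes (e.g. FCz between Fz and Cz).
midpoint_topography <- function(montage, labels = c("Fz", "Cz"), sigma_rad = 0.8) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  idx <- match(labels, montage$label)
  ctr <- colMeans(pos[idx, , drop = FALSE])
  ctr <- ctr / sqrt(sum(ctr^2))
  d <- angular_dist(pos, ctr)
  stats::setNames(as.numeric(exp(-d^2 / (2 * sigma_rad^2))), montage$label)
}
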