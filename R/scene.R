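#' Describe one thorax phantom configuration
#'
#' A scene places two circular lung regions and one circular heart region on
#' the unit-disk thorax section.  Conductivities follow the standard thorax
#' phantom convention: lungs at 0.5x, heart at 2x the unit background.
#'
#' @param lung_radius Common radius of both lungs, in \[0.3, 0.6\] (arbitrary
#'   length units on the unit-radius domain).
#' @param heart_radius Heart radius, in \[0.1, 0.3\].
#' @param lung_centers 2 x 2 matrix of lung centres (default `(+-0.5, 0)`).
#' @param heart_center Heart centre (default `(0, 0.15)`).
#' @param sigma_lung,sigma_heart,sigma_background Conductivities (must be
#'   positive).
#' @param organs_present Character subset of `c("lungs", "heart")`; organs
#'   not listed are omitted from the scene (used to generate the single-organ
#'   target variants).
#' @return A list of class `phantom_scene`.
#' @examples
#' sc <- phantom_scene(0.45, 0.2)
#' sc$organs_present
#' @export
phantom_scene <- function(lung_radius = 0.45, heart_radius = 0.2,
                          lung_centers = rbind(c(-0.5, 0), c(0.5, 0)),
                          heart_center = c(0, 0.15),
                          sigma_lung = 0.5, sigma_heart = 2,
                          sigma_background = 1,
                          organs_present = c("lungs", "heart")) {
  stopifnot(lung_radius >= 0.3, lung_radius <= 0.6,
            heart_radius >= 0.1, heart_radius <= 0.3,
            sigma_lung > 0, sigma_heart > 0, sigma_background > 0,
            all(organs_present %in% c("lungs", "heart")))
  structure(list(
    lung_radius = lung_radius, heart_radius = heart_radius,
    lung_centers = lung_centers, heart_center = heart_center,
    sigma_lung = sigma_lung, sigma_heart = sigma_heart,
    sigma_background = sigma_background,
    organs_present = unique(organs_present)
  ), class = "phantom_scene")
}

#' Per-element conductivity field for a scene
#'
#' Element membership is decided by the element centroid.  Where regions
#' overlap the precedence is heart > lung > background, so at extreme radii
#' an element inside both a lung and the heart takes the heart conductivity.
#'
#' @param mesh An `eit_mesh`.
#' @param scene A `phantom_scene`.
#' @return Numeric vector of conductivities, one per mesh element.
#' @export
assign_conductivity <- function(mesh, scene) {
  stopifnot(inherits(mesh, "eit_mesh"), inherits(scene, "phantom_scene"))
  cx <- mesh$centroids[, 1]; cy <- mesh$centroids[, 2]
  sigma <- rep(scene$sigma_background, nrow(mesh$elements))
  if ("lungs" %in% scene$organs_present) {
    for (i in seq_len(nrow(scene$lung_centers))) {
      inside <- (cx - scene$lung_centers[i, 1])^2 +
                (cy - scene$lung_centers[i, 2])^2 < scene$lung_radius^2
      sigma[inside] <- scene$sigma_lung
    }
  }
  if ("heart" %in% scene$organs_present) {
    inside <- (cx - scene$heart_center[1])^2 +
              (cy - scene$heart_center[2])^2 < scene$heart_radius^2
    sigma[inside] <- scene$sigma_heart
  }
  sigma
}
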