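#' Build a recording-probe geometry
#'
#' Defines the 3D coordinates (in micrometres) of the recording sites at which
#' the composite extracellular signal is rendered. Two presets are shipped: a
#' classic \code{tetrode} (4 sites on a regular tetrahedron, 25 um edge) and a
#' \code{polytrode_8x4} modelled on Buzsaki-style silicon arrays (4 shanks
#' spaced 200 um, 8 staggered sites per shank at 20 um vertical pitch, 32
#' sites in total). Arbitrary layouts are supported through
#' \code{preset = "custom"}.
#'
#' @param preset one of \code{"tetrode"}, \code{"polytrode_8x4"},
#'   \code{"custom"}.
#' @param coords for \code{"custom"}: an n x 3 numeric matrix (or data frame)
#'   of site positions in um.
#' @param site_diameter recording-site diameter in um (default 13).
#' @param name optional label; defaults to the preset name.
#' @return an object of class \code{probe_geometry}: a list with \code{name},
#'   \code{site_diameter} (um) and \code{sites} (n x 3 matrix, columns
#'   \code{x}, \code{y}, \code{z}, um).
#' @examples
#' build_probe("tetrode")
#' build_probe("custom", coords = matrix(0, 1, 3))
#' @export
build_probe <- function(preset = c("tetrode", "polytrode_8x4", "custom"),
                        coords = NULL, site_diameter = 13, name = NULL) {
  preset <- match.arg(preset)
  sites <- switch(preset,
    tetrode = {
      # regular tetrahedron, edge 25 um, centred at the origin
      a <- 25 / (2 * sqrt(2))
      a * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    },
    polytrode_8x4 = {
      shank_x <- rep(seq(0, 600, by = 200), each = 8)
      z <- rep(seq(0, 140, by = 20), times = 4)
      stagger <- rep(c(-10, 10), length.out = 8)
      cbind(shank_x + rep(stagger, times = 4), 0, z)
    },
    custom = {
      if (is.null(coords)) {
        stop_configuration("preset 'custom' requires 'coords'")
      }
      m <- as.matrix(coords)
      if (ncol(m) != 3L || !is.numeric(m)) {
        stop_validation("'coords' must be an n x 3 numeric matrix of um positions")
      }
      m
    })
  if (nrow(sites) < 1L) stop_validation("a probe needs at least one site")
  if (anyDuplicated(asplit(sites, 1))) {
    stop_validation("site positions must be unique")
  }
  if (!is_scalar_num(site_diameter) || site_diameter <= 0) {
    stop_validation("'site_diameter' must be a positive scalar (um)")
  }
  dimnames(sites) <- list(NULL, c("x", "y", "z"))
  structure(list(name = name %||% preset,
                 site_diameter = site_diameter,
                 sites = sites),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("<probe_geometry> %s: %d sites, %g um diameter\n",
              x$name, nrow(x$sites), x$site_diameter))
  ext <- apply(x$sites, 2, range)
  cat(sprintf("  extent x [%g, %g] y [%g, %g] z [%g, %g] um\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  invisible(x)
}

#' Translate a probe so its bounding-box centre sits at a target point
#'
#' Presets are defined in probe-local coordinates; this places them inside a
#' tissue volume (by default at the volume centre).
#'
#' @param probe a \code{\link{build_probe}} geometry.
#' @param volume a \code{\link{tissue_volume}}.
#' @param at target (x, y, z) in um for the probe centre; defaults to the
#'   volume centre.
#' @return the translated \code{probe_geometry}.
#' @export
position_probe <- function(probe, volume, at = NULL) {
  stopifnot(inherits(probe, "probe_geometry"), inherits(volume, "tissue_volume"))
  at <- at %||% (volume$dimensions / 2)
  ctr <- colMeans(apply(probe$sites, 2, range))
  probe$sites <- sweep(probe$sites, 2, ctr - at, "-")
  inside <- probe$sites >= 0 &
    sweep(probe$sites, 2, volume$dimensions, "<=")
  if (!all(inside)) {
    stop_validation("probe sites fall outside the tissue volume")
  }
  probe
}

#' Read / write a probe geometry as JSON
#'
#' File layout: \code{{"name", "site_diameter_um", "sites": [[x,y,z], ...]}}.
#'
#' @param probe a \code{probe_geometry}.
#' @param path file path.
#' @return \code{write_probe} returns \code{path} invisibly; \code{read_probe}
#'   returns a \code{probe_geometry}.
#' @export
write_probe <- function(probe, path) {
  stopifnot(inherits(probe, "probe_geometry"))
  jsonlite::write_json(
    list(name = probe$name, site_diameter_um = probe$site_diameter,
         sites = unname(apply(probe$sites, 1, as.numeric, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_probe
#' @export
read_probe <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  coords <- if (is.matrix(j$sites)) j$sites else
    matrix(unlist(j$sites), ncol = 3, byrow = TRUE)
  build_probe("custom", coords = coords,
              site_diameter = j$site_diameter_um, name = j$name)
}
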