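#' Firing-rate models
#'
#' Describes the distribution from which per-unit mean firing rates are drawn.
#' Supported kinds:
#' \describe{
#'   \item{uniform_bounds}{uniform between \code{min_rate} and \code{max_rate}
#'     (Hz), the default for the awake / anaesthetised presets.}
#'   \item{generalized_pareto}{GPD with \code{location}, \code{scale},
#'     \code{shape}; heavy-tailed ("exponential-like") rate distributions.}
#'   \item{logistic}{logistic with \code{location}, \code{scale}, truncated
#'     below at \code{lower_trunc} (default 0.01 Hz) so drawn rates stay
#'     strictly positive; used by the multilayer hippocampus preset.}
#'   \item{custom_table}{empirical resampling from \code{rates} with optional
#'     \code{weights}.}
#' }
#'
#' @param kind distribution family, see Details.
#' @param ... parameters of the chosen family (see above).
#' @return an object of class \code{firing_rate_model}.
#' @examples
#' firing_rate_model("uniform_bounds", min_rate = 0.5, max_rate = 12)
#' @export
firing_rate_model <- function(kind = c("uniform_bounds", "generalized_pareto",
                                       "logistic", "custom_table"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  switch(kind,
    uniform_bounds = {
      if (!is_scalar_num(p$min_rate) || !is_scalar_num(p$max_rate) ||
          p$min_rate <= 0 || p$max_rate < p$min_rate) {
        stop_validation("uniform_bounds needs 0 < min_rate <= max_rate")
      }
    },
    generalized_pareto = {
      p$location <- p$location %||% 0
      p$shape <- p$shape %||% 0.1
      if (!is_scalar_num(p$scale) || p$scale <= 0 || p$location < 0) {
        stop_validation("generalized_pareto needs scale > 0 and location >= 0")
      }
    },
    logistic = {
      p$lower_trunc <- p$lower_trunc %||% 0.01
      if (!is_scalar_num(p$location) || !is_scalar_num(p$scale) || p$scale <= 0) {
        stop_validation("logistic needs numeric location and scale > 0")
      }
    },
    custom_table = {
      if (is.null(p$rates) || any(p$rates <= 0)) {
        stop_validation("custom_table needs strictly positive 'rates'")
      }
    })
  structure(list(kind = kind, params = p), class = "firing_rate_model")
}

# Draw n rates; `factor` rescales the law (bounds, or location and scale) --
# used to give interneurons `interneuron_factor` times the pyramidal rates.
draw_rates <- function(model, n, factor = 1) {
  stopifnot(inherits(model, "firing_rate_model"))
  if (n == 0L) return(numeric(0))
  p <- model$params
  r <- switch(model$kind,
    uniform_bounds = stats::runif(n, p$min_rate * factor, p$max_rate * factor),
    generalized_pareto = {
      # inverse-CDF sampling; shape = 0 degenerates to exponential
      u <- stats::runif(n)
      xi <- p$shape
      tail <- if (abs(xi) < 1e-12) -log1p(-u) * p$scale else
        p$scale / xi * ((1 - u)^(-xi) - 1)
      (p$location + tail) * factor
    },
    logistic = {
      loc <- p$location * factor; sc <- p$scale * factor
      lo <- stats::plogis(p$lower_trunc, loc, sc)
      stats::qlogis(stats::runif(n, lo, 1), loc, sc)
    },
    custom_table = factor * sample(p$rates, n, replace = TRUE,
                                   prob = p$weights %||% NULL))
  pmax(r, .Machine$double.eps)
}

#' Describe one tissue layer
#'
#' @param name layer label (e.g. \code{"stratum pyramidale"}).
#' @param thickness slab thickness along z, um (> 0).
#' @param density neuron density, neurons per cubic millimetre (>= 0).
#' @param rate_model a \code{\link{firing_rate_model}} for units in this layer.
#' @param active_fraction proportion of units that fire (default 1).
#' @param pyramidal_fraction proportion of pyramidal cells (default 0.8,
#'   the hippocampal 80/20 pyramidal/interneuron split).
#' @return an object of class \code{layer_spec}.
#' @export
layer_spec <- function(name, thickness, density, rate_model,
                       active_fraction = 1, pyramidal_fraction = 0.8) {
  if (!is_scalar_num(thickness) || thickness <= 0) {
    stop_validation("'thickness' must be > 0 (um)")
  }
  if (!is_scalar_num(density) || density < 0) {
    stop_validation("'density' must be >= 0 (neurons/mm^3)")
  }
  check_fraction(active_fraction, "active_fraction")
  check_fraction(pyramidal_fraction, "pyramidal_fraction")
  stopifnot(inherits(rate_model, "firing_rate_model"))
  structure(list(name = name, thickness = thickness, density = density,
                 rate_model = rate_model, active_fraction = active_fraction,
                 pyramidal_fraction = pyramidal_fraction),
            class = "layer_spec")
}

#' Define a virtual tissue volume
#'
#' Layers are stacked along z as half-open slabs \code{[z0, z0 + thickness)}
#' starting at z = 0; coordinates are in um with the origin at a volume
#' corner. The layer footprint is the full x-y extent of the volume.
#'
#' @param dimensions numeric length-3, (x, y, z) extents in um.
#' @param layers list of \code{\link{layer_spec}} objects; their thicknesses
#'   must not exceed the z extent.
#' @return an object of class \code{tissue_volume}.
#' @seealso \code{\link{tissue_cube}} for the single-block convenience form.
#' @export
tissue_volume <- function(dimensions, layers) {
  dimensions <- as.numeric(dimensions)
  if (length(dimensions) != 3L || any(!is.finite(dimensions)) ||
      any(dimensions <= 0)) {
    stop_validation("'dimensions' must be three positive extents (um)")
  }
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "layer_spec"))) {
    stop_validation("'layers' must be a non-empty list of layer_spec objects")
  }
  if (sum(vapply(layers, `[[`, 0, "thickness")) > dimensions[3] + 1e-9) {
    stop_validation("sum of layer thicknesses exceeds the z extent")
  }
  names(dimensions) <- c("x", "y", "z")
  structure(list(dimensions = dimensions, layers = layers),
            class = "tissue_volume")
}

#' Single-block cubic tissue volume
#'
#' Convenience constructor for the homogeneous case: a cube of
#' \code{volume_mm3} cubic millimetres holding one layer. The default
#' reproduces the reference configuration of a 1.5 mm^3 cube at 300,000
#' neurons/mm^3 with an 80/20 pyramidal/interneuron split.
#'
#' @param volume_mm3 cube volume in mm^3 (default 1.5).
#' @param density neurons/mm^3 (default 300000).
#' @param rate_model a \code{\link{firing_rate_model}}.
#' @param active_fraction,pyramidal_fraction passed to
#'   \code{\link{layer_spec}}.
#' @return a \code{tissue_volume} with a single layer spanning the cube.
#' @export
tissue_cube <- function(volume_mm3 = 1.5, density = 3e5,
                        rate_model = firing_rate_model("uniform_bounds",
                                                       min_rate = 0.5,
                                                       max_rate = 12),
                        active_fraction = 1, pyramidal_fraction = 0.8) {
  side <- (volume_mm3 * 1e9)^(1 / 3)  # um
  tissue_volume(rep(side, 3),
                list(layer_spec("block", thickness = side, density = density,
                                rate_model = rate_model,
                                active_fraction = active_fraction,
                                pyramidal_fraction = pyramidal_fraction)))
}

#' @export
print.tissue_volume <- function(x, ...) {
  d <- x$dimensions
  cat(sprintf("<tissue_volume> %.0f x %.0f x %.0f um (%.3g mm^3), %d layer(s)\n",
              d[1], d[2], d[3], prod(d) / 1e9, length(x$layers)))
  for (l in x$layers) {
    cat(sprintf("  %-20s %6g um thick, %8g /mm^3, active %g%%\n",
                l$name, l$thickness, l$density, 100 * l$active_fraction))
  }
  invisible(x)
}

layer_count <- function(volume, layer) {
  sub_mm3 <- volume$dimensions[1] * volume$dimensions[2] * layer$thickness / 1e9
  as.integer(round_half_away(layer$density * sub_mm3))
}

#' Place neurons in a tissue volume
#'
#' Per layer, the unit count is deterministic:
#' \code{round(density x sub-volume in mm^3)} (half away from zero), and
#' positions are i.i.d. uniform inside the layer slab. The number of active
#' units is \code{round(active_fraction x count)}, chosen at random.
#'
#' @param volume a \code{\link{tissue_volume}}.
#' @param seed RNG seed for reproducible placement.
#' @return an object of class \code{neuron_population}: a data frame with
#'   columns \code{x}, \code{y}, \code{z} (um), \code{layer_id},
#'   \code{layer_name}, \code{active}; the volume is kept as attribute
#'   \code{volume}.
#' @examples
#' vol <- tissue_cube(volume_mm3 = 0.001, density = 1e5)
#' pop <- place_neurons(vol, seed = 1)
#' nrow(pop)  # round(1e5 * 0.001) = 100
#' @export
place_neurons <- function(volume, seed = NULL) {
  stopifnot(inherits(volume, "tissue_volume"))
  d <- volume$dimensions
  with_seed(seed, {
    z0 <- 0
    parts <- vector("list", length(volume$layers))
    for (i in seq_along(volume$layers)) {
      ly <- volume$layers[[i]]
      if (prod(d[1], d[2], ly$thickness) <= 0) {
        stop_validation(sprintf("layer '%s' has zero volume", ly$name))
      }
      n <- layer_count(volume, ly)
      active <- rep(FALSE, n)
      if (n > 0L) {
        active[sample.int(n, as.integer(round_half_away(ly$active_fraction * n)))] <- TRUE
      }
      parts[[i]] <- data.frame(
        x = stats::runif(n, 0, d[1]),
        y = stats::runif(n, 0, d[2]),
        z = z0 + stats::runif(n, 0, ly$thickness),
        layer_id = rep_len(i, n),
        layer_name = rep_len(ly$name, n),
        active = active)
      z0 <- z0 + ly$thickness
    }
    pop <- do.call(rbind, parts)
    rownames(pop) <- NULL
    structure(pop, volume = volume,
              class = c("neuron_population", "data.frame"))
  })
}

#' Assign cell types to a neuron population
#'
#' Exactly \code{round(pyramidal_fraction x n)} units per layer become
#' pyramidal (exact proportional rounding, so the 80/20 split holds
#' deterministically); which units is a seeded random choice.
#'
#' @param pop a \code{\link{place_neurons}} population.
#' @param pyramidal_fraction proportion in [0, 1]; \code{NULL} (default) uses
#'   each layer's configured fraction.
#' @param seed RNG seed.
#' @return the population with a \code{cell_type} column
#'   (\code{"pyramidal"} / \code{"interneuron"}).
#' @export
assign_types <- function(pop, pyramidal_fraction = NULL, seed = NULL) {
  stopifnot(inherits(pop, "neuron_population"))
  if (!is.null(pyramidal_fraction)) check_fraction(pyramidal_fraction, "pyramidal_fraction")
  volume <- attr(pop, "volume")
  with_seed(seed, {
    pop$cell_type <- "interneuron"
    for (i in seq_along(volume$layers)) {
      idx <- which(pop$layer_id == i)
      frac <- pyramidal_fraction %||% volume$layers[[i]]$pyramidal_fraction
      n_pyr <- as.integer(round_half_away(frac * length(idx)))
      if (n_pyr > 0L) {
        pop$cell_type[sample(idx, n_pyr)] <- "pyramidal"
      }
    }
    pop
  })
}

#' Assign firing rates to a neuron population
#'
#' Pyramidal rates are drawn from the layer's (or the supplied) rate model;
#' interneuron rates from the same model with its bounds (or location and
#' scale) multiplied by \code{interneuron_factor} — the convention that
#' interneurons fire about five times faster than pyramidal cells.
#'
#' @param pop a population with cell types (\code{\link{assign_types}}).
#' @param model a \code{\link{firing_rate_model}}, or \code{NULL} to use each
#'   layer's configured model.
#' @param interneuron_factor positive multiplier for interneuron rates
#'   (default 5).
#' @param seed RNG seed.
#' @return the population with a \code{rate} column (Hz, strictly positive).
#' @export
assign_rates <- function(pop, model = NULL, interneuron_factor = 5,
                         seed = NULL) {
  stopifnot(inherits(pop, "neuron_population"))
  if (is.null(pop$cell_type)) {
    stop_validation("assign cell types before rates (see assign_types())")
  }
  if (!is_scalar_num(interneuron_factor) || interneuron_factor <= 0) {
    stop_validation("'interneuron_factor' must be > 0")
  }
  volume <- attr(pop, "volume")
  with_seed(seed, {
    pop$rate <- NA_real_
    for (i in seq_along(volume$layers)) {
      m <- model %||% volume$layers[[i]]$rate_model
      for (ct in c("pyramidal", "interneuron")) {
        idx <- which(pop$layer_id == i & pop$cell_type == ct)
        f <- if (ct == "interneuron") interneuron_factor else 1
        pop$rate[idx] <- draw_rates(m, length(idx), factor = f)
      }
    }
    pop
  })
}

#' @export
print.neuron_population <- function(x, ...) {
  cat(sprintf("<neuron_population> %d units, %d active", nrow(x),
              sum(x$active)))
  if (!is.null(x$cell_type)) {
    cat(sprintf(", %.1f%% pyramidal", 100 * mean(x$cell_type == "pyramidal")))
  }
  cat("\n")
  invisible(x)
}
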