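#' Tissue layer description
#'
#' One layer of a layered phantom, modeled as a homogeneous slab of
#' discrete scatterers acting as a linear retarder.
#'
#' @param thickness_um layer thickness (um), > 0.
#' @param reflectivity_mean mean scatterer amplitude (dimensionless, >= 0).
#' @param attenuation_mm amplitude attenuation coefficient (mm^-1, >= 0).
#' @param birefringence refractive-index difference Delta-n between slow
#'   and fast axes (>= 0).
#' @param axis_deg in-plane optic-axis orientation in degrees, wrapped to
#'   \[-90, 90); ignored when `birefringence` is zero.
#' @param is_void marks a low-scattering space (e.g. the epidural target)
#'   entered through a strong refractive-index-mismatch interface.
#' @param scatter_spacing_scale multiplies the phantom's mean scatterer
#'   spacing inside this layer (void layers are sparser).
#' @param name optional label.
#' @return object of class `layer_spec`.
#' @export
layer_spec <- function(thickness_um, reflectivity_mean = 1,
                       attenuation_mm = 0.8, birefringence = 0,
                       axis_deg = 0, is_void = FALSE,
                       scatter_spacing_scale = if (is_void) 4 else 1,
                       name = NULL) {
  if (thickness_um <= 0) stop_field("thickness_um", "must be > 0")
  if (reflectivity_mean < 0) stop_field("reflectivity_mean", ">= 0")
  if (attenuation_mm < 0) stop_field("attenuation_mm", ">= 0")
  if (birefringence < 0) stop_field("birefringence", ">= 0")
  l <- list(thickness_um = thickness_um,
            reflectivity_mean = reflectivity_mean,
            attenuation_mm = attenuation_mm,
            birefringence = birefringence,
            axis_deg = wrap_axis_deg(axis_deg),
            is_void = isTRUE(is_void),
            scatter_spacing_scale = scatter_spacing_scale,
            name = name %||% "layer")
  class(l) <- "layer_spec"
  l
}

new_phantom <- function(layers, scatterer_spacing_um = 5, seed = 1L,
                        preset = "custom") {
  stopifnot(length(layers) >= 1)
  ph <- list(layers = layers,
             scatterer_spacing_um = scatterer_spacing_um,
             seed = as.integer(seed),
             preset = preset)
  class(ph) <- "phantom"
  ph
}

#' Total phantom depth
#' @param phantom a phantom.
#' @return depth from the tissue surface to the bottom of the last layer (um).
#' @export
phantom_depth <- function(phantom) {
  sum(vapply(phantom$layers, function(l) l$thickness_um, 0))
}

# depths (um) of the internal + terminal layer boundaries, surface excluded
layer_boundaries <- function(phantom) {
  cumsum(vapply(phantom$layers, function(l) l$thickness_um, 0))
}

# index of the layer containing depth z (um); boundaries belong to the
# deeper layer, z = total depth to the last
layer_at <- function(phantom, z) {
  b <- layer_boundaries(phantom)
  pmin(findInterval(z, c(0, b[-length(b)]), left.open = FALSE), length(b))
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> preset '%s', %d layers, %.0f um deep, spacing %.1f um, seed %d\n",
              x$preset, length(x$layers), phantom_depth(x),
              x$scatterer_spacing_um, x$seed))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  %2d %-11s %6.0f um  refl %.2f  att %.2f/mm  dn %.1e  axis %+.0f deg%s\n",
                i, l$name, l$thickness_um, l$reflectivity_mean,
                l$attenuation_mm, l$birefringence, l$axis_deg,
                if (l$is_void) "  [void]" else ""))
  }
  invisible(x)
}

#' Build a named phantom archetype
#'
#' Three archetypes mirror the standard layered-tissue test cases for
#' needle PS-OCT:
#' * `"salmon"` - nine alternating layers, five birefringent muscle
#'   (myomere) sheets separated by four non-birefringent fatty connective
#'   layers: retardation contrast.
#' * `"shrimp"` - three muscle layers of equal birefringence whose fiber
#'   orientations differ: optic-axis contrast.
#' * `"spine"` - skin, subcutaneous fat, three ligament layers, then a
#'   low-scattering void entered through a strong interface reflection
#'   (epidural-space archetype).
#' * `"custom"` - caller-supplied `layers`.
#'
#' @param preset_name one of `"salmon"`, `"shrimp"`, `"spine"`, `"custom"`.
#' @param seed integer seed controlling the scatterer realization.
#' @param layers list of [layer_spec()] (required for `"custom"`).
#' @param scatterer_spacing_um mean axial spacing of discrete scatterers.
#' @return object of class `phantom`.
#' @export
build_phantom <- function(preset_name, seed = 1L, layers = NULL,
                          scatterer_spacing_um = 5) {
  presets <- c("salmon", "shrimp", "spine", "custom")
  if (!is.character(preset_name) || length(preset_name) != 1 ||
      !(preset_name %in% presets))
    stop_field("preset_name",
               sprintf("unknown preset; must be one of %s",
                       paste(presets, collapse = ", ")))
  L <- switch(preset_name,
    salmon = {
      muscle <- function() layer_spec(450, 1.0, 0.6, 1.4e-3, 22, name = "muscle")
      conn   <- function() layer_spec(300, 0.65, 1.3, 0, 0, name = "connective")
      list(muscle(), conn(), muscle(), conn(), muscle(), conn(), muscle(),
           conn(), muscle())
    },
    shrimp = list(
      layer_spec(1100, 1.0, 0.5, 1.2e-3, -50, name = "muscle1"),
      layer_spec(1100, 1.0, 0.5, 1.2e-3,  10, name = "muscle2"),
      layer_spec(1100, 1.0, 0.5, 1.2e-3,  60, name = "muscle3")
    ),
    spine = list(
      layer_spec(700, 1.0, 1.2, 4e-4,  0, name = "skin"),
      layer_spec(800, 0.8, 1.5, 0,     0, name = "subcutaneous"),
      layer_spec(500, 1.1, 0.8, 1.8e-3, 15, name = "ligament1"),
      layer_spec(400, 1.1, 0.8, 1.8e-3, 20, name = "ligament2"),
      layer_spec(600, 1.1, 0.8, 1.8e-3, 25, name = "ligament3"),
      # epidural-space archetype: strong entry interface; residual fat
      # content keeps normal scatterer density at ~22 dB lower reflectivity
      layer_spec(1500, 0.08, 0.1, 0, 0, is_void = TRUE,
                 scatter_spacing_scale = 1, name = "void")
    ),
    custom = {
      if (is.null(layers)) stop_field("layers", "required for preset 'custom'")
      layers
    })
  new_phantom(L, scatterer_spacing_um = scatterer_spacing_um, seed = seed,
              preset = preset_name)
}

# cumulative amplitude-attenuation exponent integral_0^z mu(z') dz'
# evaluated at depths z (um); mu in mm^-1 -> per-um conversion
attenuation_cumulative <- function(phantom, z) {
  b <- c(0, layer_boundaries(phantom))
  mu <- vapply(phantom$layers, function(l) l$attenuation_mm, 0) / 1000
  cum <- c(0, cumsum(mu * diff(b)))
  i <- clamp(findInterval(z, b, rightmost.closed = TRUE), 1, length(mu))
  cum[i] + mu[i] * (z - b[i])
}

# Draw the discrete scatterer field of a phantom: positions (um from the
# surface), log-normal amplitudes, and per-scatterer layer index. Boundary
# interface reflectors model specular index-mismatch returns; the void
# entry interface is strong.
phantom_scatterers <- function(phantom) {
  with_seed(phantom$seed, {
    b <- c(0, layer_boundaries(phantom))
    zs <- numeric(0); amp <- numeric(0)
    for (i in seq_along(phantom$layers)) {
      l <- phantom$layers[[i]]
      sp <- phantom$scatterer_spacing_um * l$scatter_spacing_scale
      n <- max(1L, round(l$thickness_um / sp))
      # jittered grid keeps local density near 1/spacing while avoiding
      # periodicity artifacts
      z <- b[i] + (seq_len(n) - runif(n)) * (l$thickness_um / n)
      a <- rlnorm(n, meanlog = log(max(l$reflectivity_mean, 1e-12)) - 0.125,
                  sdlog = 0.5)
      zs <- c(zs, z); amp <- c(amp, a)
      # interface reflector at the top of each layer after the first
      if (i > 1) {
        prev <- phantom$layers[[i - 1]]
        ia <- if (l$is_void) 8 else
          0.4 * abs(l$reflectivity_mean - prev$reflectivity_mean) +
          0.2 * (l$reflectivity_mean + prev$reflectivity_mean)
        if (ia > 0) { zs <- c(zs, b[i]); amp <- c(amp, ia) }
      }
    }
    o <- order(zs)
    list(z = zs[o], amp = amp[o], layer = layer_at(phantom, zs[o]))
  })
}
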