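#' Define an original soil profile for the tillage-erosion mixing model
#'
#' A soil profile is an ordered, contiguous stack of layers starting at depth
#' 0, together with the plow depth `m` (the thickness of the cultivated
#' horizon that tillage homogenises every year) and the mean annual erosion
#' thickness `d`. Depths below the deepest declared layer may be used by the
#' simulator only when that layer is typed `"parent"`, in which case the
#' parent material is treated as extending indefinitely (it is the backfill
#' substrate).
#'
#' @param layers data.frame with columns `label` (character),
#'   `top_depth` (cm, numeric), `thickness` (cm, > 0) and `material`
#'   (one of `"cultivated"`, `"subsoil"`, `"parent"`). Layers must be
#'   contiguous from depth 0.
#' @param plow_depth Thickness of the cultivated horizon `m` in cm
#'   (default 20).
#' @param annual_erosion Mean annual erosion thickness `d` in cm per year
#'   (default 0.1, the basin-scale value used for plot design). Must satisfy
#'   `0 < d < m`.
#' @return An object of class `soil_profile`.
#' @examples
#' prof <- default_profile()
#' prof
#' @export
soil_profile <- function(layers, plow_depth = 20, annual_erosion = 0.1) {
  stopifnot(is.data.frame(layers))
  required <- c("label", "top_depth", "thickness", "material")
  if (!all(required %in% names(layers)))
    stop("`layers` needs columns: ", paste(required, collapse = ", "))
  layers <- layers[order(layers$top_depth), , drop = FALSE]
  if (any(layers$thickness <= 0)) stop("all layer thicknesses must be > 0")
  if (abs(layers$top_depth[1L]) > 1e-9) stop("layers must start at depth 0")
  bottoms <- layers$top_depth + layers$thickness
  if (nrow(layers) > 1L &&
      any(abs(layers$top_depth[-1L] - bottoms[-nrow(layers)]) > 1e-9))
    stop("layers must be contiguous and non-overlapping")
  if (anyDuplicated(layers$label)) stop("layer labels must be unique")
  mats <- c("cultivated", "subsoil", "parent")
  if (!all(layers$material %in% mats))
    stop("layer material must be one of: ", paste(mats, collapse = ", "))
  if (!is.numeric(plow_depth) || plow_depth <= 0)
    stop("`plow_depth` must be a positive number")
  if (!is.numeric(annual_erosion) || annual_erosion <= 0 ||
      annual_erosion >= plow_depth)
    stop("`annual_erosion` must satisfy 0 < d < plow depth m")
  structure(
    list(layers = layers, plow_depth = plow_depth,
         annual_erosion = annual_erosion),
    class = "soil_profile"
  )
}

#' Default sloping arable-land profile
#'
#' The reference profile of the simulated-erosion experiment: a 20 cm
#' cultivated horizon (`h0`), two 10 cm subsoil layers down to the 40 cm
#' effective soil depth, and parent material below 40 cm.
#'
#' @param annual_erosion Mean annual erosion thickness in cm/a (default 0.1).
#' @return A `soil_profile`.
#' @export
default_profile <- function(annual_erosion = 0.1) {
  soil_profile(
    data.frame(
      label = c("h0 (0-20 cm)", "20-30 cm", "30-40 cm", "parent (>40 cm)"),
      top_depth = c(0, 20, 30, 40),
      thickness = c(20, 10, 10, 10),
      material = c("cultivated", "subsoil", "subsoil", "parent"),
      stringsAsFactors = FALSE
    ),
    plow_depth = 20, annual_erosion = annual_erosion
  )
}

#' Read a soil profile from a YAML or JSON configuration file
#'
#' The file must contain `plow_depth`, `annual_erosion` and a `layers` list
#' of records with `label`, `top_depth`, `thickness` and `material`.
#'
#' @param path Path to a `.yaml`/`.yml` (or JSON; YAML is a superset) file.
#' @return A `soil_profile`.
#' @export
read_profile <- function(path) {
  cfg <- yaml::read_yaml(path)
  layers <- do.call(rbind, lapply(cfg$layers, function(l)
    data.frame(label = l$label, top_depth = l$top_depth,
               thickness = l$thickness, material = l$material,
               stringsAsFactors = FALSE)))
  soil_profile(layers, plow_depth = cfg$plow_depth,
               annual_erosion = cfg$annual_erosion)
}

#' @export
print.soil_profile <- function(x, ...) {
  cat("Soil profile: m =", x$plow_depth, "cm, d =", x$annual_erosion,
      "cm/a\n")
  print(x$layers, row.names = FALSE)
  invisible(x)
}

# Layer intervals [top, bottom); the deepest parent layer extends to Inf.
profile_intervals <- function(profile) {
  ly <- profile$layers
  top <- ly$top_depth
  bottom <- ly$top_depth + ly$thickness
  n <- length(top)
  if (ly$material[n] == "parent") bottom[n] <- Inf
  list(label = ly$label, top = top, bottom = bottom,
       extendable = ly$material[n] == "parent",
       declared_bottom = ly$top_depth[n] + ly$thickness[n])
}

# Overlap of [lo, hi) with every layer interval, as a named numeric vector.
layer_overlap <- function(iv, lo, hi) {
  pmax(0, pmin(iv$bottom, hi) - pmax(iv$top, lo))
}
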