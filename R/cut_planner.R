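#' Convert a thin equivalent layer into a constructible cut block
#'
#' Field construction cannot excavate a layer only a few centimetres thick,
#' so the thin equivalent layer (thickness `hi_prime` spread over the whole
#' plot) is re-expressed, by volume conservation, as a block of the *full*
#' source-layer thickness `hi` with a reduced footprint: with the cut length
#' fixed at `a_prime`, the cut width is
#' `b_prime = (hi_prime * a * b) / (hi * a_prime)`.
#' When the required width exceeds the plot width `b`, the block is split
#' into equal-width strips (with a warning); the summed strip volume is
#' unchanged.
#'
#' @param hi_prime Equivalent thickness of the layer in the new cultivated
#'   horizon (cm, > 0).
#' @param hi Full thickness of the source layer (cm, > 0).
#' @param a,b Plot length and width (m; both 2 m in the reference design).
#' @param a_prime Fixed cut length (m, default 2).
#' @param layer_label Optional label carried into the output.
#' @return A data.frame of class `cut_block` with one row per strip:
#'   `layer_label`, `strip`, `cut_thickness_cm` (= `hi`), `cut_length_m`,
#'   `cut_width_m` and `volume_m3`.
#' @examples
#' block_dimensions(12.1154, hi = 20, a = 2, b = 2)
#' @export
block_dimensions <- function(hi_prime, hi, a = 2, b = 2, a_prime = 2,
                             layer_label = NA_character_) {
  vals <- c(hi_prime = hi_prime, hi = hi, a = a, b = b, a_prime = a_prime)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all block inputs must be positive numbers")
  target_volume <- (hi_prime / 100) * a * b          # m^3
  b_prime <- (hi_prime * a * b) / (hi * a_prime)
  n_strips <- 1L
  if (b_prime > b + 1e-9) {
    n_strips <- as.integer(ceiling(b_prime / b - 1e-9))
    warning("required cut width ", format(round(b_prime, 3)),
            " m exceeds plot width ", b, " m; splitting into ", n_strips,
            " strips")
  }
  out <- data.frame(
    layer_label = layer_label,
    strip = seq_len(n_strips),
    cut_thickness_cm = hi,
    cut_length_m = a_prime,
    cut_width_m = b_prime / n_strips,
    volume_m3 = target_volume / n_strips,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cut_block", "data.frame")
  out
}

#' Construction plan for a set of simulated erosion plots
#'
#' For every plot design, computes the cultivated-horizon composition under
#' its treatment, converts each component into cut blocks, and records the
#' parent-material backfill (thickness equal to the treatment's erosion
#' depth) that keeps all plot surfaces level. Treatments are assigned to
#' plot positions at random when a seed is given.
#'
#' @param profile A [soil_profile].
#' @param treatments Erosion-thickness levels in cm (default
#'   `c(0, 10, 20, 30, 40)`).
#' @param replicates Replicate plots per treatment (default 10).
#' @param a,b Plot length and width in m (default 2 x 2).
#' @param a_prime Fixed cut length in m (default 2).
#' @param seed Optional integer; when given, treatment-to-position
#'   assignment is randomised reproducibly.
#' @return A data.frame with one row per (plot, layer component):
#'   `plot_id`, `position`, `treatment_cm`, `replicate`, `layer_label`,
#'   `equivalent_thickness_cm`, `cut_thickness_cm`, `cut_length_m`,
#'   `cut_width_m`, `n_strips`, `backfill_cm`. Control plots (D = 0) keep
#'   their horizon in place: a single row with no cut and no backfill.
#' @examples
#' plan <- construction_plan(default_profile(), seed = 1)
#' length(unique(plan$plot_id)) # 50 plots
#' @export
construction_plan <- function(profile, treatments = c(0, 10, 20, 30, 40),
                              replicates = 10, a = 2, b = 2, a_prime = 2,
                              seed = NULL) {
  stopifnot(inherits(profile, "soil_profile"))
  if (length(a) != 1L || length(b) != 1L || a <= 0 || b <= 0)
    stop("inconsistent plot dimensions: `a` and `b` must be single positive values")
  design <- expand.grid(replicate = seq_len(replicates),
                        treatment_cm = treatments)
  n_plots <- nrow(design)
  position <- seq_len(n_plots)
  if (!is.null(seed)) {
    set.seed(seed)
    position <- sample(position)
  }
  design$position <- position
  design$plot_id <- sprintf("P%02d", design$position)

  full_thickness <- stats::setNames(profile$layers$thickness,
                                    profile$layers$label)
  rows <- vector("list", n_plots)
  for (i in seq_len(n_plots)) {
    D <- design$treatment_cm[i]
    comp <- horizon_composition(profile, D = D)
    comp_df <- as.data.frame(comp)
    blocks <- lapply(seq_len(nrow(comp_df)), function(j) {
      lab <- comp_df$layer_label[j]
      hp <- comp_df$equivalent_thickness_cm[j]
      hi <- full_thickness[[lab]]
      if (D == 0) {
        # control: the horizon is left untouched, no cutting
        data.frame(layer_label = lab, strip = 1L, cut_thickness_cm = NA_real_,
                   cut_length_m = NA_real_, cut_width_m = NA_real_,
                   volume_m3 = NA_real_, stringsAsFactors = FALSE)
      } else {
        block_dimensions(hp, hi, a = a, b = b, a_prime = a_prime,
                         layer_label = lab)
      }
    })
    bl <- do.call(rbind, blocks)
    eq <- comp_df$equivalent_thickness_cm[
      match(bl$layer_label, comp_df$layer_label)]
    rows[[i]] <- data.frame(
      plot_id = design$plot_id[i],
      position = design$position[i],
      treatment_cm = D,
      replicate = design$replicate[i],
      layer_label = bl$layer_label,
      equivalent_thickness_cm = eq,
      cut_thickness_cm = bl$cut_thickness_cm,
      cut_length_m = bl$cut_length_m,
      cut_width_m = bl$cut_width_m,
      n_strips = ave(bl$strip, bl$layer_label, FUN = max),
      backfill_cm = D,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$layer_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
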