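#' Default path model for mineral-nitrogen drivers
#'
#' The structural model relating erosion thickness and season to mineral
#' nitrogen: erosion thickness acts on total nitrogen, carbon content
#' (SOC + DOC), the AMF community and the nifH (diazotroph) community;
#' season acts on both communities; AMF promotes nifH; mineral nitrogen
#' (NH4 + NO3) is the final endogenous block receiving all of these plus
#' direct erosion and season paths. Exogenous blocks are single-indicator
#' (erosion thickness in cm; season as a rainy = 1 / dry = 0 dummy); the
#' community blocks use a dominant-genus relative-abundance summary plus
#' Shannon diversity.
#'
#' @param scheme Inner weighting scheme (default `"centroid"`).
#' @return A [path_model_spec].
#' @export
mineral_n_path_spec <- function(scheme = "centroid") {
  blocks <- list(
    erosion  = "treatment_cm",
    season   = "season_rainy",
    tn       = "TN",
    carbon   = c("SOC", "DOC"),
    amf      = c("amf_dominance", "amf_shannon"),
    nifh     = c("nifh_dominance", "nifh_shannon"),
    mineraln = c("NH4", "NO3")
  )
  paths <- data.frame(
    from = c("erosion", "erosion", "erosion", "erosion", "season", "season",
             "amf", "tn", "carbon", "nifh", "amf", "erosion", "season"),
    to   = c("tn", "carbon", "amf", "nifh", "amf", "nifh",
             "nifh", "mineraln", "mineraln", "mineraln", "mineraln",
             "mineraln", "mineraln"),
    stringsAsFactors = FALSE)
  path_model_spec(blocks, paths, scheme = scheme)
}

#' Assemble the indicator matrix for the mineral-nitrogen path model
#'
#' Joins the plot-by-season soil variables (TN, SOC, DOC, NH4, NO3) with
#' per-sample community summaries (relative abundance of the most abundant
#' genus and Shannon diversity for each community), the numeric erosion
#' thickness and the season dummy, giving one row per plot x season.
#'
#' @param field Output of [generate_field()] (long format).
#' @param communities Output of [generate_communities()].
#' @return data.frame with the indicator columns used by
#'   [mineral_n_path_spec()].
#' @export
assemble_path_data <- function(field, communities) {
  need <- c("TN", "SOC", "DOC", "NH4", "NO3")
  wide <- stats::reshape(
    field[field$variable %in% need, ],
    idvar = c("plot_id", "treatment_cm", "replicate", "season"),
    timevar = "variable", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide$season_rainy <- as.numeric(wide$season == "rainy")
  wide$sample_id <- paste(wide$plot_id, wide$season, sep = "_")

  summarise_community <- function(tab, prefix) {
    rel <- tab$counts / rowSums(tab$counts)
    data.frame(
      sample_id = tab$metadata$sample_id,
      dominance = apply(rel, 1, max),
      shannon = unname(shannon_index(tab$counts)),
      stringsAsFactors = FALSE) |>
      stats::setNames(c("sample_id", paste0(prefix, "_dominance"),
                        paste0(prefix, "_shannon")))
  }
  out <- merge(wide, summarise_community(communities$AMF, "amf"),
               by = "sample_id")
  out <- merge(out, summarise_community(communities$nifH, "nifh"),
               by = "sample_id")
  out[order(out$sample_id), , drop = FALSE]
}
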