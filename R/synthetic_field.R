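#' Configuration for the synthetic study-shaped dataset
#'
#' Bundles every tunable of the synthetic generator emulating the
#' simulated-erosion experiment: 5 erosion-thickness treatments x 10
#' replicate plots, sampled in a rainy and a dry season. Mineral-nitrogen
#' group means are anchored to the study's reported season endpoints and
#' per-treatment reduction percentages; all other soil/plant variables
#' follow monotone treatment trends with plausible field magnitudes.
#' Plot-level noise is lognormal with a common coefficient of variation.
#'
#' @param seed Integer seed; the whole dataset is bit-reproducible given it.
#' @param treatments Erosion-thickness levels (cm).
#' @param replicates Plots per treatment.
#' @param cv Lognormal coefficient of variation of plot-level noise
#'   (default 0.15). `cv = 0` returns group means exactly.
#' @param concentration Dirichlet concentration of community profiles
#'   (total alpha; larger = less compositional overdispersion).
#' @param amf_tilt,nifh_tilt Rainy-season treatment-shift strength per 40 cm
#'   of erosion. The AMF tilt sharpens dominance with erosion (Shannon
#'   declines), the nifH tilt flattens it (Shannon rises); the dry season is
#'   treatment-independent, mirroring the seasonal contrast the analysis
#'   chain is meant to detect.
#' @param library_size_mean,library_size_disp Negative-binomial mean and
#'   dispersion (size) of per-sample read counts.
#' @return A list of class `field_config`.
#' @export
field_config <- function(seed = 1, treatments = c(0, 10, 20, 30, 40),
                         replicates = 10, cv = 0.15,
                         concentration = 200,
                         amf_tilt = 0.75, nifh_tilt = 0.5,
                         library_size_mean = 1e4,
                         library_size_disp = 10) {
  if (!is.numeric(cv) || cv < 0) stop("`cv` must be >= 0")
  if (concentration <= 0) stop("`concentration` must be > 0")
  if (length(treatments) < 2 || replicates < 1)
    stop("incomplete design: need >= 2 treatments and >= 1 replicate")
  structure(list(
    seed = as.integer(seed), treatments = treatments,
    replicates = as.integer(replicates), cv = cv,
    concentration = concentration,
    amf_tilt = amf_tilt, nifh_tilt = nifh_tilt,
    library_size_mean = library_size_mean,
    library_size_disp = library_size_disp
  ), class = "field_config")
}

# Reported no-erosion means and per-treatment reduction percentages for
# mineral nitrogen (mg/kg), by season; treatments 10..40 cm.
mineral_n_anchors <- function() {
  list(
    NH4 = list(
      rainy = list(control = 3.11, reduction = c(5.84, 8.89, 10.14, 27.19)),
      dry   = list(control = 2.68, reduction = c(10.51, 26.23, 29.18, 40.68))
    ),
    NO3 = list(
      rainy = list(control = 0.33, reduction = c(26.30, 53.40, 56.86, 72.17)),
      dry   = list(control = 0.27, reduction = c(17.68, 23.38, 68.52, 78.99))
    )
  )
}

# Endpoint means (control -> 40 cm) for the remaining variables, by season.
# Directions follow the observed treatment responses: silt, SOC, DOC, TN,
# TP, AP, AK and biomass decline with erosion thickness; sand and TK rise;
# pH, SM and clay carry no treatment trend.
field_variable_table <- function() {
  v <- function(variable, season, mean_0, mean_40)
    data.frame(variable = variable, season = season, mean_0 = mean_0,
               mean_40 = mean_40, stringsAsFactors = FALSE)
  rbind(
    v("sand",    "rainy", 45,   53),   v("sand",    "dry", 45,   53),
    v("silt",    "rainy", 35,   27),   v("silt",    "dry", 35,   27),
    v("pH",      "rainy", 6.5,  6.5),  v("pH",      "dry", 6.6,  6.6),
    v("SM",      "rainy", 15,   15),   v("SM",      "dry", 6,    6),
    v("SOC",     "rainy", 8.0,  5.0),  v("SOC",     "dry", 7.5,  5.2),
    v("DOC",     "rainy", 120,  70),   v("DOC",     "dry", 95,   60),
    v("TN",      "rainy", 0.90, 0.55), v("TN",      "dry", 0.85, 0.55),
    v("TP",      "rainy", 0.60, 0.45), v("TP",      "dry", 0.60, 0.45),
    v("TK",      "rainy", 14,   16.5), v("TK",      "dry", 14,   16.5),
    v("AP",      "rainy", 6.0,  3.0),  v("AP",      "dry", 5.5,  3.0),
    v("AK",      "rainy", 120,  75),   v("AK",      "dry", 110,  70),
    v("biomass", "rainy", 250,  80),   v("biomass", "dry", 160,  50)
  )
}

#' Treatment-level target means of a synthetic field variable
#'
#' NH4 and NO3 means come from the reported no-erosion means with the
#' reported percentage reductions applied at each treatment level; all other
#' variables interpolate linearly between their configured control and
#' 40 cm endpoint means.
#'
#' @param variable Variable name (e.g. `"NH4"`, `"SOC"`).
#' @param season `"rainy"` or `"dry"`.
#' @param treatments Erosion-thickness levels (cm).
#' @return Named numeric vector of target group means.
#' @export
treatment_means <- function(variable, season,
                            treatments = c(0, 10, 20, 30, 40)) {
  season <- match.arg(season, c("rainy", "dry"))
  anch <- mineral_n_anchors()
  if (variable %in% names(anch)) {
    a <- anch[[variable]][[season]]
    ref_treat <- c(10, 20, 30, 40)
    red <- stats::approx(ref_treat, a$reduction, xout = treatments,
                         rule = 2)$y
    red[treatments == 0] <- 0
    mu <- a$control * (1 - red / 100)
  } else {
    tab <- field_variable_table()
    row <- tab[tab$variable == variable & tab$season == season, ]
    if (nrow(row) != 1L) stop("unknown variable: ", variable)
    mu <- row$mean_0 + (row$mean_40 - row$mean_0) * treatments / 40
  }
  stats::setNames(mu, treatments)
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  mean * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate the synthetic plot-level field dataset
#'
#' Produces the long table of soil and plant variables for the full
#' treatments x replicates x seasons design. Mineral nitrogen follows the
#' reported season-by-treatment anchor means; other variables follow the
#' configured monotone trends; noise is lognormal around each group mean.
#' Soil texture satisfies sand + silt + clay = 100 within every plot-season
#' (clay is the remainder).
#'
#' @param config A [field_config].
#' @return data.frame with columns `plot_id`, `treatment_cm`, `replicate`,
#'   `season`, `variable`, `value`.
#' @examples
#' fd <- generate_field(field_config(seed = 1))
#' nrow(subset(fd, variable == "NH4")) # 100: 50 plots x 2 seasons
#' @export
generate_field <- function(config) {
  stopifnot(inherits(config, "field_config"))
  set.seed(config$seed)
  design <- expand.grid(replicate = seq_len(config$replicates),
                        treatment_cm = config$treatments)
  design$plot_id <- sprintf("P%02d", seq_len(nrow(design)))
  seasons <- c("rainy", "dry")
  vars <- c(unique(field_variable_table()$variable), "NH4", "NO3")
  vars <- setdiff(vars, "clay")  # clay derived from the texture closure

  out <- list()
  for (season in seasons) {
    block <- design
    block$season <- season
    vals <- list()
    for (v in vars) {
      mu <- treatment_means(v, season, config$treatments)
      m_i <- mu[as.character(block$treatment_cm)]
      vals[[v]] <- rlnorm_mean_cv(nrow(block), 1, config$cv) * m_i
    }
    # texture closure: redraw the rare plot where sand + silt leaves no clay
    bad <- which(vals$sand + vals$silt >= 99)
    while (length(bad) > 0) {
      mu_s <- treatment_means("sand", season, config$treatments)
      mu_si <- treatment_means("silt", season, config$treatments)
      tt <- as.character(block$treatment_cm[bad])
      vals$sand[bad] <- rlnorm_mean_cv(length(bad), 1, config$cv) * mu_s[tt]
      vals$silt[bad] <- rlnorm_mean_cv(length(bad), 1, config$cv) * mu_si[tt]
      bad <- which(vals$sand + vals$silt >= 99)
    }
    vals$clay <- 100 - vals$sand - vals$silt
    for (v in names(vals)) {
      out[[paste(season, v)]] <- data.frame(
        plot_id = block$plot_id, treatment_cm = block$treatment_cm,
        replicate = block$replicate, season = season, variable = v,
        value = vals[[v]], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write the field dataset as a tidy CSV
#' @param field Output of [generate_field()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  utils::write.csv(field, path, row.names = FALSE)
  invisible(path)
}
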