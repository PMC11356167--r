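#' Season-specific genus pools of the synthetic communities
#'
#' Mean relative-abundance profiles for the AMF and nifH communities in each
#' season. They encode the qualitative seasonal turnover the study design
#' targets: in the dry season all dominant AMF genera but *Diversispora*
#' collapse, while the nifH community keeps *Bradyrhizobium* dominant but
#' swaps its season-specific genera.
#'
#' @return Nested list `pools[[community]][[season]]`: named numeric vectors
#'   over the community's full genus set (zeros mark genera absent in that
#'   season), each summing to 1.
#' @export
community_pools <- function() {
  amf_rainy <- c(
    Glomus = 0.28, Diversispora = 0.18, Paraglomus = 0.12,
    Acaulospora = 0.10, Claroideoglomus = 0.09, Rhizophagus = 0.08,
    Funneliformis = 0.06, Gigaspora = 0.04, Scutellospora = 0.03,
    Archaeospora = 0.02)
  amf_dry <- c(
    Glomus = 0, Diversispora = 0.80, Paraglomus = 0,
    Acaulospora = 0, Claroideoglomus = 0, Rhizophagus = 0,
    Funneliformis = 0, Gigaspora = 0.06, Scutellospora = 0.08,
    Archaeospora = 0.06)
  shared <- c("Mesorhizobium", "Rhizobium", "Sinorhizobium", "Burkholderia",
              "Geobacter", "Desulfovibrio", "Frankia", "Nostoc",
              "Paenibacillus")
  rainy_only <- c("Azospirillum", "Methylosinus", "Agrobacterium",
                  "Rubrivivax", "Pseudomonas", "Anaeromyxobacter")
  dry_only <- c("Zohydromonas", "Skermanella", "Azotobacter", "Beijerinckia")
  genera <- c("Bradyrhizobium", rainy_only, dry_only, shared)
  nifh_rainy <- stats::setNames(numeric(length(genera)), genera)
  nifh_rainy["Bradyrhizobium"] <- 0.30
  nifh_rainy[rainy_only] <- 0.30 / length(rainy_only)
  nifh_rainy[shared] <- 0.40 / length(shared)
  nifh_dry <- stats::setNames(numeric(length(genera)), genera)
  nifh_dry["Bradyrhizobium"] <- 0.32
  nifh_dry[dry_only] <- 0.24 / length(dry_only)
  nifh_dry[shared] <- 0.44 / length(shared)
  list(AMF = list(rainy = amf_rainy, dry = amf_dry),
       nifH = list(rainy = nifh_rainy, dry = nifh_dry))
}

# Exponent tilt of a mean profile: power > 1 sharpens dominance (Shannon
# falls), power < 1 flattens it (Shannon rises). Zeros stay zero.
tilt_profile <- function(p, power) {
  q <- ifelse(p > 0, p^power, 0)
  q / sum(q)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate the pair of synthetic genus abundance tables
#'
#' Dirichlet-multinomial counts for the AMF and nifH communities across all
#' plots and both seasons. Rainy-season composition drifts with erosion
#' thickness (an exponent tilt of the mean profile whose strength is the
#' config's `amf_tilt`/`nifh_tilt` per 40 cm: dominance sharpens for AMF and
#' flattens for nifH), while dry-season composition is
#' treatment-independent — the seasonal contrast the ordination and
#' PERMANOVA stage is designed to detect. Genera absent from a season's
#' pool receive exactly zero counts in that season.
#'
#' @param config A [field_config].
#' @return Named list (`AMF`, `nifH`) of `abundance_table` objects: each has
#'   `$counts` (samples x genera integer matrix) and `$metadata`
#'   (`sample_id`, `plot_id`, `treatment_cm`, `replicate`, `season`).
#' @examples
#' com <- generate_communities(field_config(seed = 1))
#' dim(com$AMF$counts) # 100 samples x 10 genera
#' @export
generate_communities <- function(config) {
  stopifnot(inherits(config, "field_config"))
  if (config$concentration <= 0) stop("`concentration` must be > 0")
  set.seed(config$seed + 1L)
  pools <- community_pools()
  design <- expand.grid(replicate = seq_len(config$replicates),
                        treatment_cm = config$treatments)
  design$plot_id <- sprintf("P%02d", seq_len(nrow(design)))
  tilts <- c(AMF = config$amf_tilt, nifH = config$nifh_tilt)

  out <- list()
  for (com in names(pools)) {
    meta <- do.call(rbind, lapply(c("rainy", "dry"), function(s) {
      d <- design; d$season <- s; d
    }))
    meta$sample_id <- paste(meta$plot_id, meta$season, sep = "_")
    genera <- names(pools[[com]]$rainy)
    counts <- matrix(0L, nrow(meta), length(genera),
                     dimnames = list(meta$sample_id, genera))
    for (i in seq_len(nrow(meta))) {
      base <- pools[[com]][[meta$season[i]]]
      if (meta$season[i] == "rainy") {
        frac <- meta$treatment_cm[i] / 40
        power <- if (com == "AMF") 1 + tilts[[com]] * frac
                 else 1 / (1 + tilts[[com]] * frac)
        base <- tilt_profile(base, power)
      }
      nz <- base > 0
      p <- rdirichlet1(config$concentration * base[nz])
      size <- max(100, stats::rnbinom(1, mu = config$library_size_mean,
                                      size = config$library_size_disp))
      counts[i, nz] <- stats::rmultinom(1, size, p)[, 1]
    }
    out[[com]] <- structure(
      list(community = com, counts = counts,
           metadata = meta[, c("sample_id", "plot_id", "treatment_cm",
                               "replicate", "season")]),
      class = "abundance_table")
  }
  out
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table:", x$community, "-", nrow(x$counts), "samples x",
      ncol(x$counts), "genera\n")
  invisible(x)
}

#' Random rooted genus tree for phylogenetic beta diversity
#'
#' A pure-birth (Yule) tree over the given tip labels, for use with
#' [unweighted_unifrac()]. Purely synthetic: it carries no real phylogenetic
#' signal and exists so the phylogenetic distance path is exercisable
#' end-to-end.
#'
#' @param labels Tip labels (genus names).
#' @param seed Integer seed.
#' @param birth Speciation rate of the Yule process.
#' @return A rooted `phylo` object with branch lengths.
#' @export
community_tree <- function(labels, seed = 1, birth = 1) {
  set.seed(seed)
  tr <- ape::rphylo(length(labels), birth = birth, death = 0)
  tr$tip.label <- sample(labels)
  tr
}

#' Write an abundance table as genera x samples TSV plus metadata TSV
#' @param tab An `abundance_table`.
#' @param counts_path,metadata_path Output file paths.
#' @return `counts_path`, invisibly.
#' @export
write_abundance_tsv <- function(tab, counts_path, metadata_path) {
  m <- t(tab$counts)  # genera x samples
  df <- data.frame(genus = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(tab$metadata, metadata_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(counts_path)
}
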