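# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (naive loops, exhaustive enumeration)
# rather than calling the package's own implementation paths.

# Naive PERMANOVA pseudo-F straight from the distance decomposition.
oracle_permanova_f <- function(dmat, groups) {
  dmat <- as.matrix(dmat)
  groups <- as.character(groups)
  N <- nrow(dmat)
  lv <- unique(groups)
  sst <- 0
  for (i in seq_len(N - 1)) for (j in seq(i + 1, N))
    sst <- sst + dmat[i, j]^2
  sst <- sst / N
  ssw <- 0
  for (g in lv) {
    idx <- which(groups == g)
    acc <- 0
    if (length(idx) > 1)
      for (a in seq_len(length(idx) - 1)) for (b in seq(a + 1, length(idx)))
        acc <- acc + dmat[idx[a], idx[b]]^2
    ssw <- ssw + acc / length(idx)
  }
  ssb <- sst - ssw
  (ssb / (length(lv) - 1)) / (ssw / (N - length(lv)))
}

# Exhaustive-permutation PERMANOVA p-value by brute force (tiny N only).
oracle_permanova_exhaustive_p <- function(dmat, groups) {
  N <- nrow(as.matrix(dmat))
  perms <- expand_permutations(N)
  f_obs <- oracle_permanova_f(dmat, groups)
  fs <- apply(perms, 2, function(ix) oracle_permanova_f(dmat, groups[ix]))
  mean(fs >= f_obs - 1e-12)
}

expand_permutations <- function(n) {
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v))
    do.call(cbind, lapply(seq_along(v), function(i) rbind(v[i], rec(v[-i]))))
  }
  rec(seq_len(n))
}

# Unweighted UniFrac for one sample pair by explicit branch enumeration.
oracle_unifrac_pair <- function(tree, present_a, present_b) {
  ntip <- length(tree$tip.label)
  tips_under <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  shared_len <- unshared_len <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tips_under(tree$edge[e, 2])
    ina <- any(tips %in% present_a)
    inb <- any(tips %in% present_b)
    if (ina && inb) shared_len <- shared_len + tree$edge.length[e]
    else if (ina || inb) unshared_len <- unshared_len + tree$edge.length[e]
  }
  if (shared_len + unshared_len == 0) return(0)
  unshared_len / (shared_len + unshared_len)
}

# All directed simple paths from `from` to `to` in a coefficient matrix,
# summing the products of coefficients along each path.
oracle_total_effect <- function(P, from, to) {
  lat <- rownames(P)
  total <- 0
  walk <- function(node, prod) {
    for (nxt in lat[P[node, ] != 0]) {
      p2 <- prod * P[node, nxt]
      if (nxt == to) total <<- total + p2
      else walk(nxt, p2)
    }
  }
  walk(from, 1)
  total
}

# Latent-variable data generator for path-model recovery tests. Latents
# follow the DAG with the given standardized coefficients; disturbance
# variances are solved from the population covariance recursion so every
# latent has population variance exactly 1, making the nominal
# coefficients the exact population standardized path coefficients. Each
# block's indicators load on its latent with the given loading
# (single-indicator blocks observe the latent directly).
make_latent_data <- function(n, spec, coefs, loading = 0.95, seed = 1) {
  set.seed(seed)
  lat <- names(spec$blocks)
  adj <- spec$adjacency
  ord <- erodyn:::topological_order(adj)
  L <- length(lat)
  Sigma <- matrix(0, L, L, dimnames = list(lat, lat))
  psi <- stats::setNames(numeric(L), lat)
  scores <- matrix(NA_real_, n, L, dimnames = list(NULL, lat))
  done <- character(0)
  for (b in ord) {
    parents <- lat[adj[, b] == 1]
    if (!length(parents)) {
      psi[b] <- 1
      scores[, b] <- rnorm(n)
      Sigma[b, b] <- 1
    } else {
      beta <- vapply(parents, function(p) coefs[[paste(p, b)]], numeric(1))
      psi[b] <- 1 - drop(t(beta) %*% Sigma[parents, parents] %*% beta)
      stopifnot(psi[b] > 0)
      scores[, b] <- scores[, parents, drop = FALSE] %*% beta +
        rnorm(n, sd = sqrt(psi[b]))
      Sigma[b, b] <- 1
      for (a in done) Sigma[b, a] <- Sigma[a, b] <-
          drop(Sigma[a, parents, drop = FALSE] %*% beta)
    }
    done <- c(done, b)
  }
  dat <- list()
  for (b in lat) {
    inds <- spec$blocks[[b]]
    for (x in inds) {
      dat[[x]] <- if (length(inds) == 1) scores[, b] else
        loading * scores[, b] + rnorm(n, sd = sqrt(1 - loading^2))
    }
  }
  list(data = as.data.frame(dat), scores = scores)
}

# A small DAG shaped like the mineral-nitrogen structural model, with
# single-indicator blocks unless `indicators > 1`.
toy_mineral_spec <- function(indicators = 1) {
  lat <- c("erosion", "season", "tn", "carbon", "amf", "nifh", "mineraln")
  blocks <- lapply(lat, function(b) {
    if (indicators == 1) paste0(b, "_x1") else
      paste0(b, "_x", seq_len(indicators))
  })
  names(blocks) <- lat
  paths <- data.frame(
    from = c("erosion", "erosion", "erosion", "season", "season", "amf",
             "tn", "carbon", "nifh", "amf"),
    to   = c("tn", "carbon", "nifh", "amf", "nifh", "nifh",
             "mineraln", "mineraln", "mineraln", "mineraln"))
  path_model_spec(blocks, paths)
}

toy_mineral_coefs <- function() {
  c("erosion tn" = -0.6, "erosion carbon" = -0.55, "erosion nifh" = -0.3,
    "season amf" = 0.5, "season nifh" = 0.25, "amf nifh" = 0.35,
    "tn mineraln" = 0.3, "carbon mineraln" = 0.25, "nifh mineraln" = 0.3,
    "amf mineraln" = 0.2)
}
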