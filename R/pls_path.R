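#' Specify a PLS path model
#'
#' Defines the latent blocks (reflective indicators) and the directed
#' acyclic inner path structure of a partial-least-squares path model.
#'
#' @param blocks Named list: latent name -> character vector of indicator
#'   column names. Every indicator belongs to exactly one block.
#' @param paths Two-column data.frame (`from`, `to`) of directed paths
#'   among latent names; must be acyclic.
#' @param scheme Inner weighting scheme: `"centroid"` (default),
#'   `"factorial"` or `"path"`.
#' @return Object of class `path_model_spec`.
#' @export
path_model_spec <- function(blocks, paths,
                            scheme = c("centroid", "factorial", "path")) {
  scheme <- match.arg(scheme)
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop("`blocks` must be a named list")
  ind <- unlist(blocks)
  if (anyDuplicated(ind))
    stop("every indicator must belong to exactly one block")
  paths <- as.data.frame(paths)
  names(paths)[1:2] <- c("from", "to")
  lat <- names(blocks)
  if (!all(c(paths$from, paths$to) %in% lat))
    stop("paths refer to unknown latents")
  if (any(paths$from == paths$to)) stop("self-loops not allowed")
  adj <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
  adj[cbind(paths$from, paths$to)] <- 1
  if (is.null(topological_order(adj))) stop("path structure must be acyclic")
  structure(list(blocks = blocks, paths = paths, adjacency = adj,
                 scheme = scheme), class = "path_model_spec")
}

# Kahn topological sort; NULL when a cycle exists.
topological_order <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  order <- character(0)
  avail <- rownames(adj)[indeg == 0]
  indeg_work <- indeg
  remaining <- rownames(adj)
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
    for (w in colnames(adj)[adj[v, ] == 1]) {
      indeg_work[w] <- indeg_work[w] - 1
      if (indeg_work[w] == 0 && w %in% remaining) avail <- c(avail, w)
    }
  }
  if (length(order) < n) NULL else order
}

#' Read a path model specification from YAML
#'
#' Expected structure: a `blocks` mapping (latent -> list of indicators), a
#' `paths` list of `[from, to]` pairs, and optionally `scheme`.
#'
#' @param path YAML file path.
#' @return A [path_model_spec].
#' @export
read_path_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  paths <- do.call(rbind, lapply(cfg$paths, function(p)
    data.frame(from = p[[1]], to = p[[2]], stringsAsFactors = FALSE)))
  path_model_spec(cfg$blocks, paths,
                  scheme = if (is.null(cfg$scheme)) "centroid"
                           else cfg$scheme)
}

#' Fit a PLS path model
#'
#' Lohmoeller-style alternating estimation with reflective (mode A) outer
#' measurement: indicators are standardised; outer weights start at unity;
#' each round forms latent scores, derives inner weights under the chosen
#' scheme (centroid: sign of the score correlation between connected
#' latents; factorial: the correlation itself; path: regression
#' coefficients toward predecessors, correlations toward successors),
#' builds inner proxies, and regresses each indicator on its block proxy to
#' update the outer weights, until the largest outer-weight change falls
#' below `tol`. Path coefficients are then per-equation least squares of
#' each endogenous latent score on its parents; because scores are
#' standardised the coefficients are standardised. Each latent's sign is
#' aligned to its dominant indicator (the one with the largest absolute
#' loading) so bootstrap aggregation is sign-stable.
#'
#' @param data data.frame/matrix containing all indicator columns.
#' @param spec A [path_model_spec].
#' @param tol Outer-weight convergence tolerance (default 1e-6).
#' @param maxit Maximum iterations (default 300).
#' @return List of class `plspm_fit`: `weights`, `loadings`, `scores`,
#'   `path_coefficients` (from x to matrix), `paths` (tidy table), `r2`,
#'   `iterations`, `scheme`, `spec`.
#' @export
fit_plspm <- function(data, spec, tol = 1e-6, maxit = 300) {
  stopifnot(inherits(spec, "path_model_spec"))
  data <- as.data.frame(data)
  ind <- unlist(spec$blocks)
  miss <- setdiff(ind, names(data))
  if (length(miss)) stop("missing indicator columns: ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(data[, ind, drop = FALSE])
  if (!is.numeric(X)) stop("indicators must be numeric")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("singular predictor set: zero-variance indicator(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  X <- scale(X)
  n <- nrow(X)
  lat <- names(spec$blocks)
  L <- length(lat)
  adj <- spec$adjacency
  connected <- (adj + t(adj)) > 0

  std <- function(v) as.vector(scale(v))
  w <- lapply(spec$blocks, function(b) rep(1, length(b)))
  scores <- sapply(lat, function(b)
    std(X[, spec$blocks[[b]], drop = FALSE] %*% w[[b]]))
  it <- 0
  repeat {
    it <- it + 1
    R <- stats::cor(scores)
    # inner weights
    E <- matrix(0, L, L, dimnames = list(lat, lat))
    for (b in lat) {
      conn <- lat[connected[b, ]]
      if (!length(conn)) stop("latent '", b, "' is disconnected")
      if (spec$scheme == "centroid") {
        E[b, conn] <- sign(R[b, conn])
      } else if (spec$scheme == "factorial") {
        E[b, conn] <- R[b, conn]
      } else { # path scheme
        parents <- lat[adj[, b] == 1]
        children <- lat[adj[b, ] == 1]
        if (length(parents)) {
          cf <- solve(R[parents, parents, drop = FALSE],
                      R[parents, b, drop = FALSE])
          E[b, parents] <- cf
        }
        if (length(children)) E[b, children] <- R[b, children]
      }
    }
    Z <- scores %*% t(E)
    # outer update, mode A: weight = cor(indicator, inner proxy)
    w_new <- lapply(lat, function(b)
      as.vector(stats::cor(X[, spec$blocks[[b]], drop = FALSE], Z[, b])))
    names(w_new) <- lat
    delta <- max(mapply(function(a, b) max(abs(abs(a) - abs(b))), w, w_new))
    w <- w_new
    scores <- sapply(lat, function(b)
      std(X[, spec$blocks[[b]], drop = FALSE] %*% w[[b]]))
    if (delta < tol) break
    if (it >= maxit)
      stop("PLS outer estimation did not converge in ", maxit,
           " iterations (last weight change ", format(delta), ")")
  }

  # sign alignment: each latent positively loads on its dominant indicator
  for (b in lat) {
    ld <- stats::cor(X[, spec$blocks[[b]], drop = FALSE], scores[, b])
    dom <- which.max(abs(ld))
    if (ld[dom] < 0) {
      scores[, b] <- -scores[, b]
      w[[b]] <- -w[[b]]
    }
  }
  loadings <- lapply(lat, function(b)
    as.vector(stats::cor(X[, spec$blocks[[b]], drop = FALSE], scores[, b])))
  names(loadings) <- lat
  for (b in lat) names(loadings[[b]]) <- names(w[[b]]) <- spec$blocks[[b]]

  P <- matrix(0, L, L, dimnames = list(lat, lat))
  r2 <- stats::setNames(rep(NA_real_, L), lat)
  tidy <- list()
  for (b in lat) {
    parents <- lat[adj[, b] == 1]
    if (!length(parents)) next
    fit <- stats::lm.fit(cbind(1, scores[, parents, drop = FALSE]),
                         scores[, b])
    coefs <- fit$coefficients[-1]
    P[parents, b] <- coefs
    r2[b] <- 1 - sum(fit$residuals^2) / sum(scores[, b]^2)
    tidy[[b]] <- data.frame(from = parents, to = b,
                            coefficient = unname(coefs),
                            stringsAsFactors = FALSE)
  }
  structure(list(weights = w, loadings = loadings, scores = scores,
                 path_coefficients = P,
                 paths = do.call(rbind, tidy),
                 r2 = r2[!is.na(r2)], iterations = it,
                 scheme = spec$scheme, spec = spec),
            class = "plspm_fit")
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat("PLS path model (", x$scheme, " scheme, ", x$iterations,
      " iterations)\nPath coefficients:\n", sep = "")
  print(x$paths, row.names = FALSE)
  cat("R2:\n"); print(round(x$r2, 4))
  invisible(x)
}

#' Direct, indirect and total effects of a fitted path model
#'
#' Total effects are the sum over every directed path of the product of its
#' coefficients, computed by summing powers of the coefficient adjacency
#' matrix until it is nilpotent (guaranteed for a DAG).
#'
#' @param fit A `plspm_fit` (or a bare coefficient matrix `from x to`).
#' @return List with matrices `direct`, `indirect`, `total` (from x to).
#' @export
total_effects <- function(fit) {
  P <- if (inherits(fit, "plspm_fit")) fit$path_coefficients else as.matrix(fit)
  L <- nrow(P)
  total <- matrix(0, L, L, dimnames = dimnames(P))
  term <- P
  for (step in seq_len(L)) {
    total <- total + term
    term <- term %*% P
    if (all(abs(term) < 1e-14)) break
    if (step == L) stop("cycle detected: coefficient matrix is not nilpotent")
  }
  list(direct = P, indirect = total - P, total = total)
}

#' Nonparametric bootstrap confidence intervals for path coefficients
#'
#' Resamples rows with replacement, refits the model, and reports
#' percentile confidence intervals for every path coefficient; a path is
#' flagged significant when its interval excludes zero. Resamples in which
#' an indicator collapses to zero variance (or the fit fails) are skipped
#' and counted, with a warning when more than 1% are skipped.
#'
#' @param data Indicator data.frame.
#' @param spec A [path_model_spec].
#' @param B Number of bootstrap resamples (default 999, minimum 199).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List of class `plspm_boot`: `paths` (data.frame with `from`,
#'   `to`, `coefficient`, `lower`, `upper`, `significant`), `B_effective`,
#'   `skipped`, plus the original `fit`.
#' @export
bootstrap_paths <- function(data, spec, B = 999, seed = 1, conf = 0.95) {
  if (B < 199) stop("B must be at least 199")
  fit <- fit_plspm(data, spec)
  n <- nrow(data)
  set.seed(seed)
  draws <- matrix(NA_real_, B, nrow(fit$paths))
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, replace = TRUE)
    fb <- tryCatch(fit_plspm(data[idx, , drop = FALSE], spec),
                   error = function(e) NULL)
    if (is.null(fb)) { skipped <- skipped + 1L; next }
    draws[b, ] <- fb$paths$coefficient
  }
  if (skipped > 0.01 * B)
    warning(skipped, " of ", B, " bootstrap resamples were degenerate and skipped")
  ok <- stats::complete.cases(draws)
  a <- (1 - conf) / 2
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a), names = FALSE)
  out <- fit$paths
  out$lower <- qs[1, ]
  out$upper <- qs[2, ]
  out$significant <- out$lower > 0 | out$upper < 0
  structure(list(paths = out, B_effective = sum(ok), skipped = skipped,
                 conf = conf, fit = fit),
            class = "plspm_boot")
}

#' @export
print.plspm_boot <- function(x, ...) {
  cat(sprintf("PLS path bootstrap: %d effective resamples, %.0f%% CIs\n",
              x$B_effective, 100 * x$conf))
  print(x$paths, row.names = FALSE)
  invisible(x)
}
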