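#' Non-metric multidimensional scaling by stress majorization
#'
#' Minimises Kruskal stress-1 in `k` dimensions by alternating monotone
#' regression (pool-adjacent-violators, via `stats::isoreg`, on the
#' configuration distances ordered by the input dissimilarities) with a
#' Guttman-transform update of the configuration. A step-halving safeguard
#' keeps the recorded stress sequence non-increasing. The best of
#' `n_starts` random starts (plus a classical-scaling start) is returned;
#' results are deterministic given `seed`.
#'
#' @param d A `dist` object or symmetric dissimilarity matrix (>= 4
#'   samples, finite entries).
#' @param k Embedding dimension (default 2).
#' @param n_starts Number of random starts in addition to the
#'   classical-scaling start (default 20).
#' @param maxit Maximum iterations per start (default 300).
#' @param tol Convergence tolerance on the stress decrease (default 1e-7).
#' @param seed Integer seed for the random starts.
#' @return List of class `nmds` with `points` (samples x k), `stress`
#'   (final stress-1), `stress_trace` (per-iteration stress of the winning
#'   start), `converged`, `n_starts`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, maxit = 300, tol = 1e-7,
                 seed = 1) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("`d` must be symmetric")
  if (any(!is.finite(dm))) stop("non-finite distances")
  n <- nrow(dm)
  if (n < 4) stop("need at least 4 samples")
  labs <- rownames(dm)
  diss <- dm[lower.tri(dm)]
  o <- order(diss)

  set.seed(seed)
  starts <- vector("list", n_starts + 1)
  # classical-scaling start, then random ones
  cmd <- suppressWarnings(stats::cmdscale(dm, k = k))
  if (ncol(cmd) < k) cmd <- cbind(cmd, matrix(0, n, k - ncol(cmd)))
  starts[[1]] <- cmd
  for (s in seq_len(n_starts))
    starts[[s + 1]] <- matrix(stats::rnorm(n * k), n, k)

  best <- NULL
  for (X0 in starts) {
    res <- nmds_one_start(X0, diss, o, n, k, maxit, tol)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  pts <- scale(best$X, center = TRUE, scale = FALSE)
  # rotate to principal axes for a reproducible orientation
  pts <- pts %*% svd(pts)$v
  dimnames(pts) <- list(labs, paste0("NMDS", seq_len(k)))
  structure(list(points = pts, stress = best$stress,
                 stress_trace = best$trace, converged = best$converged,
                 n_starts = n_starts + 1),
            class = "nmds")
}

nmds_one_start <- function(X, diss, o, n, k, maxit, tol) {
  stress_of <- function(X) {
    dc <- as.vector(stats::dist(X))
    dhat <- numeric(length(dc))
    dhat[o] <- stats::isoreg(dc[o])$yf
    num <- sum((dc - dhat)^2)
    den <- sum(dc^2)
    list(stress = sqrt(num / den), dc = dc, dhat = dhat)
  }
  cur <- stress_of(X)
  trace <- cur$stress
  converged <- FALSE
  for (it in seq_len(maxit)) {
    Xnew <- guttman_update(X, cur$dhat, n, k)
    nxt <- stress_of(Xnew)
    halvings <- 0
    while (nxt$stress > cur$stress && halvings < 20) {
      Xnew <- (Xnew + X) / 2
      nxt <- stress_of(Xnew)
      halvings <- halvings + 1
    }
    if (nxt$stress > cur$stress) { converged <- TRUE; break }
    improvement <- cur$stress - nxt$stress
    X <- Xnew
    cur <- nxt
    trace <- c(trace, cur$stress)
    if (improvement < tol) { converged <- TRUE; break }
  }
  list(X = X, stress = cur$stress, trace = trace, converged = converged)
}

# One Guttman transform step toward target disparities `dhat`.
guttman_update <- function(X, dhat, n, k) {
  dc <- as.matrix(stats::dist(X))
  W <- matrix(0, n, n)
  W[lower.tri(W)] <- dhat
  W <- W + t(W)
  ratio <- ifelse(dc > 1e-12, W / dc, 0)
  B <- -ratio
  diag(B) <- rowSums(ratio)
  (B %*% X) / n
}

#' @export
print.nmds <- function(x, ...) {
  cat(sprintf("NMDS (%d samples, k = %d): stress-1 = %.5f over %d starts\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_starts))
  invisible(x)
}
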