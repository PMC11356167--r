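#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance for a single grouping
#' factor. Sums of squares come from the standard distance decomposition:
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, pseudo-F `= (SS_between / (g-1)) / (SS_within / (N-g))`,
#' `R^2 = SS_between / SS_total`. The p-value permutes group labels; with
#' `exhaustive = TRUE` every permutation of the samples is enumerated
#' (feasible for ~8 or fewer samples) and the p-value is the exact
#' permutation fraction, otherwise `n_perm` random permutations are drawn
#' and the observed statistic is counted (`(hits + 1) / (n_perm + 1)`).
#'
#' @param d `dist` or symmetric dissimilarity matrix.
#' @param groups Grouping vector (>= 2 groups, each n >= 2).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exhaustive Enumerate all permutations instead of sampling.
#' @return List of class `permanova` with `F`, `R2`, `p`, `df_between`,
#'   `df_within`, `n_permutations`, `exhaustive`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1,
                      exhaustive = FALSE) {
  D2 <- as.matrix(d)^2
  groups <- factor(groups)
  N <- nrow(D2)
  if (length(groups) != N) stop("length mismatch")
  ns <- table(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(ns < 2)) stop("every group needs n >= 2")
  g <- nlevels(groups)

  f_stat <- function(idx_groups) {
    ssw <- 0
    for (lv in levels(idx_groups)) {
      sel <- which(idx_groups == lv)
      ssw <- ssw + sum(D2[sel, sel]) / (2 * length(sel))
    }
    sst <- sum(D2) / (2 * N)
    ssb <- sst - ssw
    c(F = (ssb / (g - 1)) / (ssw / (N - g)), R2 = ssb / sst)
  }
  obs <- f_stat(groups)

  if (exhaustive) {
    perms <- all_permutations(N)
    fs <- vapply(seq_len(ncol(perms)),
                 function(i) f_stat(groups[perms[, i]])[["F"]], numeric(1))
    p <- mean(fs >= obs[["F"]] - 1e-12)
    n_used <- ncol(perms)
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      fp <- f_stat(groups[sample.int(N)])[["F"]]
      if (fp >= obs[["F"]] - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(F = unname(obs[["F"]]), R2 = unname(obs[["R2"]]), p = p,
                 df_between = g - 1, df_within = N - g,
                 n_permutations = n_used, exhaustive = exhaustive),
            class = "permanova")
}

# All permutations of 1..n as a matrix (n! columns); intended for tiny n.
all_permutations <- function(n) {
  if (n > 9) stop("exhaustive enumeration limited to n <= 9")
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v))
    do.call(cbind, lapply(seq_along(v), function(i)
      rbind(v[i], rec(v[-i]))))
  }
  rec(seq_len(n))
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F(%d, %d) = %.4f, R2 = %.4f, p = %.4g (%s%d perms)\n",
    x$df_between, x$df_within, x$F, x$R2, x$p,
    if (x$exhaustive) "exhaustive, " else "", x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA over all group pairs
#'
#' Runs [permanova()] on the sub-distance-matrix of every unordered pair of
#' groups (10 pairs for five erosion-thickness levels), mirroring the
#' pairwise community-composition comparisons reported for the study's
#' treatments.
#'
#' @inheritParams permanova
#' @return data.frame with one row per pair: `group1`, `group2`, `F`, `R2`,
#'   `p`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = 1) {
  dm <- as.matrix(d)
  groups <- factor(groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    sel <- groups %in% pairs[, i]
    res <- permanova(dm[sel, sel], droplevels(groups[sel]),
                     n_perm = n_perm, seed = seed + i)
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               F = res$F, R2 = res$R2, p = res$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
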