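#' Normality and homogeneity screens for grouped data
#'
#' Runs a Shapiro-Wilk normality test within each treatment group and a
#' Brown-Forsythe homogeneity-of-variance test (median-centred Levene test)
#' across groups — the screening step that precedes one-way ANOVA.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor/vector, same length as `values`.
#' @return List with `normality` (data.frame: `group`, `n`, `W`, `p`) and
#'   `homogeneity` (data.frame: `statistic`, `df1`, `df2`, `p`).
#' @export
screen_groups <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("length mismatch")
  split_vals <- split(values, groups)
  if (any(lengths(split_vals) < 3))
    stop("each group needs n >= 3 for the normality screen")
  if (any(vapply(split_vals, function(v) stats::sd(v) == 0, logical(1))))
    stop("degenerate input: a group has zero spread")
  norm <- do.call(rbind, lapply(names(split_vals), function(g) {
    sw <- stats::shapiro.test(split_vals[[g]])
    data.frame(group = g, n = length(split_vals[[g]]),
               W = unname(sw$statistic), p = sw$p.value,
               stringsAsFactors = FALSE)
  }))
  lev <- car::leveneTest(values ~ groups, center = stats::median)
  hom <- data.frame(statistic = lev$`F value`[1], df1 = lev$Df[1],
                    df2 = lev$Df[2], p = lev$`Pr(>F)`[1])
  list(normality = norm, homogeneity = hom)
}

#' One-way ANOVA with Fisher LSD compact letter display
#'
#' Classical one-way ANOVA followed by unprotected pairwise Fisher
#' least-significant-difference comparisons (t tests on the pooled residual
#' mean square with N - g degrees of freedom) and a compact letter display:
#' groups share a letter exactly when their LSD comparison is
#' non-significant at `alpha`. No multiplicity correction is applied to the
#' pairwise comparisons; with five treatment levels (10 pairs) the
#' per-family error rate is accordingly inflated.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor/vector (>= 2 levels, each n >= 2).
#' @param alpha Significance level for the letters (default 0.05).
#' @return List of class `anova_lsd` with elements `anova` (F, dfs, p, MSE),
#'   `means` (group means, n, letters, ordered by descending mean),
#'   `pairs` (per-pair difference, t, p, significance).
#' @examples
#' set.seed(1)
#' anova_lsd(rnorm(30, rep(c(0, 1, 3), each = 10)), rep(1:3, each = 10))
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("length mismatch")
  ns <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(ns < 2)) stop("each group needs at least 2 observations")
  fit <- stats::aov(values ~ groups)
  at <- stats::anova(fit)
  mse <- at$`Mean Sq`[2]
  df_w <- at$Df[2]
  res <- list(F = at$`F value`[1], df_between = at$Df[1], df_within = df_w,
              p = at$`Pr(>F)`[1], MSE = mse)

  means <- tapply(values, groups, mean)
  ord <- order(means, decreasing = TRUE)
  lv <- levels(groups)[ord]
  mu <- means[ord]
  nn <- as.numeric(ns[ord])

  g <- length(lv)
  pairs <- utils::combn(g, 2)
  ptab <- data.frame(
    group1 = lv[pairs[1, ]], group2 = lv[pairs[2, ]],
    difference = mu[pairs[1, ]] - mu[pairs[2, ]],
    stringsAsFactors = FALSE)
  se <- sqrt(mse * (1 / nn[pairs[1, ]] + 1 / nn[pairs[2, ]]))
  ptab$t <- ptab$difference / se
  ptab$p <- 2 * stats::pt(-abs(ptab$t), df_w)
  ptab$significant <- ptab$p < alpha

  sig <- matrix(FALSE, g, g)
  sig[t(pairs)] <- ptab$significant
  sig <- sig | t(sig)
  letters_vec <- cld_insert_absorb(sig)

  means_df <- data.frame(group = lv, n = nn, mean = as.numeric(mu),
                         letters = letters_vec, stringsAsFactors = FALSE)
  structure(list(anova = res, means = means_df, pairs = ptab,
                 alpha = alpha), class = "anova_lsd")
}

# Insert-and-absorb compact letter display. `sig` is a symmetric logical
# matrix over groups ordered by descending mean; TRUE = significantly
# different. Returns one letter string per group such that two groups share
# a letter iff their comparison is non-significant.
cld_insert_absorb <- function(sig) {
  g <- nrow(sig)
  cols <- list(rep(TRUE, g))          # each column = set of groups
  for (i in seq_len(g - 1)) for (j in seq(i + 1, g)) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1]] <- b
      }
    }
    # absorb columns that became subsets of another
    keep <- rep(TRUE, length(cols))
    for (u in seq_along(cols)) for (v in seq_along(cols)) {
      if (u != v && keep[u] && keep[v] && all(cols[[u]] <= cols[[v]]) &&
          any(cols[[v]] & !cols[[u]]))
        keep[u] <- FALSE
      else if (u < v && keep[u] && keep[v] &&
               all(cols[[u]] == cols[[v]]))
        keep[v] <- FALSE
    }
    cols <- cols[keep]
  }
  # order columns by their first member so the top mean gets "a"
  first <- vapply(cols, function(cl) which(cl)[1], numeric(1))
  cols <- cols[order(first)]
  vapply(seq_len(g), function(i)
    paste(letters[which(vapply(cols, `[`, logical(1), i))], collapse = ""),
    character(1))
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g, MSE = %.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p,
              x$anova$MSE))
  cat("Group means (Fisher LSD letters, alpha =", x$alpha, "):\n")
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Percentage reduction relative to a control mean
#'
#' `100 * (control - treatment) / control`, the convention used to report
#' mineral-nitrogen decline across erosion-thickness treatments.
#'
#' @param control_mean Control (no-erosion) group mean, > 0.
#' @param treatment_mean Treatment group mean (vectorised).
#' @return Percent reduction (positive when the treatment mean is lower).
#' @examples
#' reduction_rate(2.68, 1.59) # ~40.7% dry-season NH4 reduction at 40 cm
#' @export
reduction_rate <- function(control_mean, treatment_mean) {
  if (!is.numeric(control_mean) || any(control_mean <= 0))
    stop("`control_mean` must be > 0")
  100 * (control_mean - treatment_mean) / control_mean
}

#' Nitrate to ammonium ratio
#'
#' @param no3 Nitrate-N concentration(s), mg/kg.
#' @param nh4 Ammonium-N concentration(s), mg/kg; must be > 0.
#' @return `no3 / nh4`. Values below 1 indicate ammonium-dominated mineral
#'   nitrogen, a signature of nitrogen scarcity in these soils.
#' @export
mineral_ratio <- function(no3, nh4) {
  if (!is.numeric(nh4) || any(nh4 <= 0)) stop("`nh4` must be > 0")
  no3 / nh4
}
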