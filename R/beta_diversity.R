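#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum|x_i - x_j| / sum(x_i + x_j)` over genera, computed on
#' relative abundances by default (so differing library sizes do not inflate
#' the distance), or on raw counts with `relative = FALSE`.
#'
#' @param x Samples x genera numeric matrix (or an `abundance_table`).
#' @param relative Convert rows to relative abundances first (default TRUE).
#' @return A `dist` object with sample labels; entries in \[0, 1\].
#' @examples
#' bray_curtis(rbind(a = c(6, 4, 0), b = c(2, 4, 4))) # 0.4
#' @export
bray_curtis <- function(x, relative = TRUE) {
  x <- as_count_matrix(x)
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("all-zero sample(s): ",
         paste(rownames(x)[rs == 0], collapse = ", "))
  if (relative) x <- x / rs
  num <- as.matrix(stats::dist(x, method = "manhattan"))
  s <- rowSums(x)
  den <- outer(s, s, "+")
  stats::as.dist(num / den)
}

#' Shannon diversity per sample
#'
#' `H = -sum p log p` over genera with positive abundance (natural log).
#'
#' @param x Samples x genera numeric matrix, an `abundance_table`, or a
#'   single count vector.
#' @return Named numeric vector of Shannon indices.
#' @examples
#' shannon_index(c(3, 1)) # ~0.5623
#' @export
shannon_index <- function(x) {
  if (is.null(dim(x)) && !inherits(x, "abundance_table"))
    x <- matrix(x, nrow = 1)
  x <- as_count_matrix(x)
  if (any(x < 0)) stop("negative counts")
  if (any(rowSums(x) <= 0)) stop("sample sum must be > 0")
  apply(x, 1, function(v) {
    p <- v[v > 0] / sum(v)
    -sum(p * log(p))
  })
}

#' Unweighted UniFrac distance
#'
#' Presence/absence phylogenetic dissimilarity: for each pair of samples,
#' the branch length leading only to tips present in exactly one of the two
#' samples, divided by the branch length leading to tips present in either.
#'
#' @param x Samples x genera matrix (or `abundance_table`); column names
#'   must all be tips of `tree`.
#' @param tree Rooted `phylo` tree with branch lengths.
#' @return A `dist` object; entries in \[0, 1\].
#' @export
unweighted_unifrac <- function(x, tree) {
  x <- as_count_matrix(x)
  if (!inherits(tree, "phylo")) stop("`tree` must be a `phylo` object")
  missing <- setdiff(colnames(x), tree$tip.label)
  if (length(missing))
    stop("genera missing from tree tips: ", paste(missing, collapse = ", "))
  extra <- setdiff(tree$tip.label, colnames(x))
  if (length(extra)) tree <- ape::keep.tip(tree, colnames(x))
  if (any(rowSums(x > 0) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(x)[rowSums(x > 0) == 0], collapse = ", "))

  ntip <- length(tree$tip.label)
  edge <- tree$edge
  len <- tree$edge.length
  # tips descending from each edge's child, by postorder accumulation
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  # edge x sample presence: does any descendant tip occur in the sample?
  pres <- x[, tree$tip.label, drop = FALSE] > 0
  edge_pres <- matrix(FALSE, nrow(edge), nrow(x))
  for (e in seq_len(nrow(edge)))
    edge_pres[e, ] <- rowSums(pres[, desc[[edge[e, 2]]], drop = FALSE]) > 0
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ei <- edge_pres[, i]; ej <- edge_pres[, j]
    union_len <- sum(len[ei | ej])
    d[i, j] <- d[j, i] <- if (union_len == 0) 0 else
      sum(len[xor(ei, ej)]) / union_len
  }
  stats::as.dist(d)
}

as_count_matrix <- function(x) {
  if (inherits(x, "abundance_table")) x <- x$counts
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  storage.mode(x) <- "double"
  x
}
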