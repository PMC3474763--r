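#' Distance-based phylogenetics
#'
#' Pairwise distances from aligned sequences (p-distance with Kimura-style
#' corrections), neighbor-joining tree construction, bootstrap support, and
#' extraction of the terminal sister pairs used for ortholog/paralog
#' pairing.
#'
#' @name phylogeny
NULL

#' Proportion of differing sites between two aligned sequences
#'
#' @param aligned_a,aligned_b Aligned sequences of equal length (single
#'   strings; `-` marks a gap).
#' @param deletion Gap policy: `"pairwise"` (default) excludes sites where
#'   either sequence has a gap.
#' @return p, the proportion of compared sites that differ.
#' @export
#' @examples
#' p_distance("AAAA", "AATT")  # 0.5
p_distance <- function(aligned_a, aligned_b, deletion = c("pairwise")) {
  deletion <- match.arg(deletion)
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned sequences must have equal length")
  }
  a <- split1(aligned_a)
  b <- split1(aligned_b)
  keep <- a != "-" & b != "-"
  if (sum(keep) == 0) stop("no comparable sites (all-gap overlap)")
  mean(a[keep] != b[keep])
}

#' Distance correction for multiple substitutions
#'
#' Converts an observed proportion of differences into an evolutionary
#' distance. `protein_kimura` applies Kimura's correction for amino-acid
#' sequences, `d = -ln(1 - p - 0.2 p^2)`; `nucleotide_k2p` is the Kimura
#' two-parameter nucleotide model from transition (`P`) and transversion
#' (`Q`) proportions, `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`; `p_raw`
#' returns p unchanged.
#'
#' @param p Observed proportion of differing sites (for `nucleotide_k2p`,
#'   the transition proportion `P`).
#' @param model One of `"protein_kimura"`, `"nucleotide_k2p"`, `"p_raw"`.
#' @param Q Transversion proportion (only for `nucleotide_k2p`).
#' @return The corrected distance.
#' @export
#' @examples
#' correct_distance(0.1)  # -log(0.898)
correct_distance <- function(p, model = c("protein_kimura", "nucleotide_k2p",
                                          "p_raw"), Q = NULL) {
  model <- match.arg(model)
  switch(model,
    p_raw = p,
    protein_kimura = {
      arg <- 1 - p - 0.2 * p^2
      if (any(arg <= 0)) stop("saturation: distance undefined (1 - p - 0.2 p^2 <= 0)")
      -log(arg)
    },
    nucleotide_k2p = {
      if (is.null(Q)) stop("nucleotide_k2p needs the transversion proportion `Q`")
      a1 <- 1 - 2 * p - Q
      a2 <- 1 - 2 * Q
      if (any(a1 <= 0) || any(a2 <= 0)) {
        stop("saturation: distance undefined under the K2P model")
      }
      -0.5 * log(a1) - 0.25 * log(a2)
    })
}

#' Distance matrix from a set of aligned sequences
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences, or a character matrix (rows = taxa).
#' @param model Passed to [correct_distance()].
#' @return A symmetric labelled distance matrix.
#' @export
dist_from_alignment <- function(alignment, model = "protein_kimura") {
  m <- alignment_as_matrix(alignment)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p <- p_distance(paste0c(m[i, ]), paste0c(m[j, ]))
      d[i, j] <- d[j, i] <- correct_distance(p, model)
    }
  }
  d
}

alignment_as_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    if (is.null(rownames(alignment))) {
      rownames(alignment) <- paste0("t", seq_len(nrow(alignment)))
    }
    return(alignment)
  }
  if (is.null(names(alignment))) stop("`alignment` must be named")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) stop("aligned sequences must have equal length")
  do.call(rbind, lapply(stats::setNames(alignment, names(alignment)), split1))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor joining: at each step the pair minimizing the
#' Q-criterion is joined, with Saitou-Nei branch lengths. Ties are broken
#' by the lowest (row, column) index pair in the current matrix. Negative
#' branch lengths are clamped to zero with the deficit moved to the sibling
#' branch (the pairwise sum is preserved); the number of clamped branches
#' is recorded in the `negative_clamped` attribute of the returned tree.
#' On an additive distance matrix the tree's path lengths reproduce the
#' input exactly (up to floating-point error).
#'
#' @param d Symmetric numeric matrix with zero diagonal and row/column
#'   labels; at least 3 taxa.
#' @return An unrooted `phylo` tree (class from the \pkg{ape} package).
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("`d` must be a square matrix")
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(abs(d - t(d)) > 1e-8)) stop("`d` must be symmetric")
  if (any(!is.finite(d))) stop("`d` must be finite")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  nodes <- as.list(labels) # growing newick fragments
  n_clamped <- 0L
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0; n_clamped <<- n_clamped + 1L }
    if (lj < 0) { li <- li + lj; lj <- 0; n_clamped <<- n_clamped + 1L }
    c(max(li, 0), max(lj, 0))
  }
  while (length(nodes) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    best_i <- best_j <- NA_integer_
    best_q <- Inf
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (q[i, j] < best_q - 1e-12) {
          best_q <- q[i, j]
          best_i <- i
          best_j <- j
        }
      }
    }
    i <- best_i; j <- best_j
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    ln <- clamp_pair(li, lj)
    new_node <- sprintf("(%s:%.12g,%s:%.12g)", nodes[[i]], ln[1],
                        nodes[[j]], ln[2])
    others <- setdiff(seq_len(n), c(i, j))
    d_new <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d <- d[others, others, drop = FALSE]
    d <- rbind(cbind(d, d_new), c(d_new, 0))
    nodes <- c(nodes[others], new_node)
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (v1 < 0) { n_clamped <- n_clamped + 1L; v1 <- 0 }
  if (v2 < 0) { n_clamped <- n_clamped + 1L; v2 <- 0 }
  if (v3 < 0) { n_clamped <- n_clamped + 1L; v3 <- 0 }
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", nodes[[1]], v1,
                 nodes[[2]], v2, nodes[[3]], v3)
  tree <- ape::read.tree(text = txt)
  attr(tree, "negative_clamped") <- n_clamped
  tree
}

#' Bootstrap neighbor-joining tree from an alignment
#'
#' Builds the neighbor-joining tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds a tree per
#' replicate, and reports the fraction of replicates supporting each
#' internal bipartition of the full tree. Deterministic given `seed`.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences, or a character matrix (rows = taxa).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param model Distance model (see [correct_distance()]).
#' @return An unrooted `phylo` tree with node labels giving bootstrap
#'   support fractions (root label empty).
#' @export
bootstrap_support <- function(alignment, n_reps, seed, model = "protein_kimura") {
  if (n_reps < 1) stop("`n_reps` must be at least 1")
  m <- alignment_as_matrix(alignment)
  if (ncol(m) < 2) stop("alignment must have at least 2 columns")
  build <- function(mat) neighbor_joining(dist_from_alignment(mat, model))
  tree <- build(m)
  counts <- with_local_seed(seed, {
    ape::boot.phylo(tree, m, build, B = n_reps, quiet = TRUE,
                    rooted = FALSE)
  })
  support <- counts / n_reps
  tree$node.label <- c("", format(support[-1], trim = TRUE))
  attr(tree, "support") <- support
  tree
}

#' Terminal sister pairs (cherries) of a tree
#'
#' Returns every pair of leaves that share an internal node. For a 3-taxon
#' unrooted tree every pair is trivially a cherry, so none is reported and
#' a warning is raised.
#'
#' @param tree A `phylo` tree.
#' @return Data.frame with columns `leaf_a`, `leaf_b`.
#' @export
terminal_pairs <- function(tree) {
  n_tip <- length(tree$tip.label)
  empty <- data.frame(leaf_a = character(0), leaf_b = character(0),
                      stringsAsFactors = FALSE)
  if (n_tip <= 3) {
    warning("tree with <= 3 taxa: every pair is a cherry; reporting none")
    return(empty)
  }
  out <- list()
  internal <- unique(tree$edge[, 1])
  for (node in internal) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    tips <- children[children <= n_tip]
    if (length(tips) == 2) {
      pair <- sort(tree$tip.label[tips])
      out[[length(out) + 1L]] <- data.frame(leaf_a = pair[1], leaf_b = pair[2],
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}
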