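#' Expression-profile processing
#'
#' Log2 transformation with state tracking, quantile normalization,
#' differential-expression classification by the log2-ratio-plus-paired-test
#' rule, Pearson correlation of ortholog/paralog pairs, and hierarchical
#' clustering of profiles for heatmap ordering.
#'
#' @name expression_profiles
NULL

expr_scale <- function(mat) {
  s <- attr(mat, "scale")
  if (is.null(s)) "raw" else s
}

#' Log2-transform a raw intensity matrix
#'
#' Elementwise log2 with a double-transform guard: a matrix whose `scale`
#' attribute is already `"log2"` is rejected. Nonpositive values are an
#' error unless a positive `floor` is configured, in which case values
#' below the floor are raised to it first.
#'
#' @param mat Numeric matrix (genes x samples) of raw intensities.
#' @param floor Optional positive floor applied before the transform.
#' @return The log2 matrix, with `scale` attribute `"log2"`.
#' @export
log2_transform <- function(mat, floor = NULL) {
  if (expr_scale(mat) == "log2") {
    stop("matrix is already on the log2 scale")
  }
  if (!is.null(floor)) {
    stopifnot_scalar_number(floor, "floor", lower = .Machine$double.xmin)
    mat[mat < floor] <- floor
  }
  if (any(mat <= 0)) {
    stop("nonpositive intensities; set `floor` to clip them first")
  }
  out <- log2(mat)
  attr(out, "scale") <- "log2"
  out
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to the common reference distribution: the
#' cross-column mean of sorted values. Ties within a column receive the
#' mean of their tied reference quantiles. The computation is delegated to
#' `limma::normalizeQuantiles`.
#'
#' @param mat Numeric matrix (genes x samples), at least 2 columns.
#' @return The normalized matrix (attributes preserved).
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
quantile_normalize <- function(mat) {
  if (ncol(mat) < 2) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  attr(out, "scale") <- expr_scale(mat)
  out
}

#' Classify differential expression per gene and contrast
#'
#' For every treated condition in the design, computes per-gene paired
#' log2 ratios (treated minus mock over the stated mock partners), a
#' two-sided paired t-test, multiplicity adjustment across genes within the
#' contrast, and the up/down/unchanged call: `up` iff the mean log2 ratio
#' exceeds `lfc` and the adjusted p-value is at most `alpha`; `down`
#' symmetric; `unchanged` otherwise.
#'
#' @param mat Log2-scale matrix (genes x samples).
#' @param design Data.frame with columns `sample_id`, `condition`,
#'   `replicate`, `mock_partner` (the paired mock `sample_id`, `NA` for
#'   mocks themselves).
#' @param lfc Absolute log2-ratio threshold (default 0.5).
#' @param alpha Adjusted significance threshold (default 0.05).
#' @param method Multiplicity adjustment: `"BH"` (default) or
#'   `"bonferroni"`.
#' @return Data.frame: `gene`, `contrast`, `log2_ratio`, `p`, `q`, `call`.
#'   Genes with fewer than 2 complete pairs in a contrast are skipped with
#'   a warning.
#' @export
de_classify <- function(mat, design, lfc = 0.5, alpha = 0.05,
                        method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  conditions <- setdiff(unique(design$condition), "mock")
  out <- list()
  for (cond in conditions) {
    treated <- design[design$condition == cond, , drop = FALSE]
    if (any(is.na(treated$mock_partner))) {
      stop(sprintf("condition '%s' has samples without a mock partner", cond))
    }
    if (nrow(treated) < 2) {
      warning(sprintf("contrast '%s' skipped: fewer than 2 replicate pairs", cond))
      next
    }
    t_mat <- mat[, treated$sample_id, drop = FALSE]
    m_mat <- mat[, treated$mock_partner, drop = FALSE]
    diffs <- t_mat - m_mat
    log2_ratio <- rowMeans(diffs)
    p <- apply(diffs, 1, function(x) {
      if (stats::sd(x) == 0) {
        # constant differences: degenerate t-test; exact zero diff -> p = 1
        if (all(x == 0)) 1 else 0
      } else {
        stats::t.test(x)$p.value
      }
    })
    q <- stats::p.adjust(p, method = method)
    call <- ifelse(log2_ratio > lfc & q <= alpha, "up",
                   ifelse(log2_ratio < -lfc & q <= alpha, "down", "unchanged"))
    out[[cond]] <- data.frame(gene = rownames(mat), contrast = cond,
                              log2_ratio = log2_ratio, p = p, q = q,
                              call = call, stringsAsFactors = FALSE,
                              row.names = NULL)
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(0), contrast = character(0),
                      log2_ratio = numeric(0), p = numeric(0), q = numeric(0),
                      call = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation with validation
#'
#' Standard product-moment correlation, with explicit errors for the
#' degenerate inputs (fewer than 3 points, zero variance) that would
#' otherwise yield `NA` silently.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return r in \[-1, 1\].
#' @export
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 2, 4))
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' Pearson correlation of ortholog/paralog pairs
#'
#' Computes r for each gene pair over the ordered vector of shared
#' conditions. The two matrices may be the same object (paralog or isoform
#' pairs within one species).
#'
#' @param mat_a,mat_b Expression matrices (genes x samples); column names
#'   are condition/sample identifiers.
#' @param pairs Data.frame with columns `gene_a` (row of `mat_a`) and
#'   `gene_b` (row of `mat_b`).
#' @param shared_conditions Character vector of column names present in
#'   both matrices; defaults to the intersection of their column names.
#' @return Data.frame: `gene_a`, `gene_b`, `n_points`, `r`.
#' @export
pair_correlations <- function(mat_a, mat_b = mat_a, pairs,
                              shared_conditions = intersect(colnames(mat_a),
                                                            colnames(mat_b))) {
  if (length(shared_conditions) < 3) stop("need at least 3 shared conditions")
  if (!all(shared_conditions %in% colnames(mat_a)) ||
      !all(shared_conditions %in% colnames(mat_b))) {
    stop("both matrices must cover all shared conditions")
  }
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    ga <- pairs$gene_a[k]
    gb <- pairs$gene_b[k]
    if (!ga %in% rownames(mat_a)) stop(sprintf("gene '%s' absent from matrix A", ga))
    if (!gb %in% rownames(mat_b)) stop(sprintf("gene '%s' absent from matrix B", gb))
    x <- mat_a[ga, shared_conditions]
    y <- mat_b[gb, shared_conditions]
    data.frame(gene_a = ga, gene_b = gb, n_points = length(shared_conditions),
               r = pearson_r(x, y), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of genes with a correlation-based
#' dissimilarity (`1 - Pearson r` by default) and configurable linkage.
#' Genes with constant profiles (undefined correlation) are excluded with
#' a warning. The agglomeration of `stats::hclust` is deterministic.
#'
#' @param mat Expression matrix (genes x samples), at least 2 genes.
#' @param metric `"one_minus_pearson"` (default) or `"euclidean"`.
#' @param linkage Linkage method for `stats::hclust` (default
#'   `"average"`).
#' @return A list: `hclust` (the tree), `order` (leaf gene ids in
#'   dendrogram order), `newick` (serialized dendrogram), `excluded`
#'   (constant-profile genes).
#' @export
hierarchical_cluster <- function(mat, metric = c("one_minus_pearson",
                                                 "euclidean"),
                                 linkage = "average") {
  metric <- match.arg(metric)
  excluded <- character(0)
  if (metric == "one_minus_pearson") {
    sds <- apply(mat, 1, stats::sd)
    if (any(sds == 0)) {
      excluded <- rownames(mat)[sds == 0]
      warning(sprintf("%d constant-profile gene(s) excluded from clustering",
                      length(excluded)))
      mat <- mat[sds > 0, , drop = FALSE]
    }
  }
  if (nrow(mat) < 2) stop("need at least 2 non-constant genes")
  d <- switch(metric,
              one_minus_pearson = stats::as.dist(1 - stats::cor(t(mat))),
              euclidean = stats::dist(mat))
  hc <- stats::hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, order = hc$labels[hc$order],
       newick = ape::write.tree(phy), excluded = excluded)
}
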