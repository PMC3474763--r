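#' Synthetic expression matrices with known structure
#'
#' Generates log2-scale expression matrices in one of two layouts:
#' unstructured "profile point" columns (emulating a panel of treatment
#' time points over which ortholog-pair correlations are computed) or a
#' paired mock/treatment design for differential-expression testing.
#' Pairwise correlations are planted by the shared-factor construction
#' `x = s`, `y = rho * s + sqrt(1 - rho^2) * e` with `s`, `e` independent
#' standard normal across samples, so the sample correlation converges to
#' the target as the number of samples grows, and equals the target
#' exactly when `|rho| = 1`. Differential effects are planted as additive
#' log2 shifts on the treated-condition mean.
#'
#' @name simulate_expression
NULL

#' Specification for a synthetic expression data set
#'
#' Two layouts are supported. With `treatments = character(0)` (default)
#' the matrix has `n_samples` profile-point columns and `pair_targets`
#' may plant pairwise correlations. With non-empty `treatments` the matrix
#' has one mock and one sample per treatment for each of `n_reps`
#' replicate pairs, and `de_effects` may plant log2 shifts; `pair_targets`
#' are only valid in the profile layout (planted effects would distort
#' planted correlations).
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of profile-point columns (profile layout).
#' @param pair_targets Data.frame (`gene_i`, `gene_j`, `target_r`) of
#'   planted correlations; gene indices (integers) or ids; `|target_r| <= 1`.
#' @param de_effects Data.frame (`gene`, `contrast`, `log2_shift`) of
#'   planted treatment effects.
#' @param treatments Character vector of treated condition names.
#' @param n_reps Replicate pairs per contrast (>= 2 when `de_effects` are
#'   planted).
#' @param noise_sd Replicate noise standard deviation on the log2 scale
#'   (default 0.1, typical of well-replicated array data).
#' @param profile_sd Biological spread of each gene across profile points
#'   (default 1).
#' @param baseline_mean Mean log2 baseline intensity (default 8).
#' @param seed Integer seed.
#' @return An `expression_sim_spec` list.
#' @export
expression_sim_spec <- function(n_genes, n_samples = 39L, pair_targets = NULL,
                                de_effects = NULL, treatments = character(0),
                                n_reps = 3L, noise_sd = 0.1, profile_sd = 1,
                                baseline_mean = 8, seed = 1L) {
  stopifnot_scalar_number(n_genes, "n_genes", lower = 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 1e-12)
  if (!is.null(pair_targets)) {
    if (any(abs(pair_targets$target_r) > 1)) stop("|target_r| must be <= 1")
    if (length(treatments) > 0) {
      stop("pair_targets are only supported in the profile layout")
    }
  }
  if (!is.null(de_effects)) {
    if (length(treatments) == 0) stop("de_effects need a treatment layout")
    if (!all(de_effects$contrast %in% treatments)) {
      stop("de_effects reference unknown treatments")
    }
    if (n_reps < 2) stop("need at least 2 replicate pairs for the paired test")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 pair_targets = pair_targets, de_effects = de_effects,
                 treatments = treatments, n_reps = as.integer(n_reps),
                 noise_sd = noise_sd, profile_sd = profile_sd,
                 baseline_mean = baseline_mean, seed = as.integer(seed)),
            class = "expression_sim_spec")
}

#' Generate a synthetic expression matrix, design and ground truth
#'
#' @param spec An [expression_sim_spec()].
#' @return A list: `matrix` (genes x samples, log2 scale), `design`
#'   (data.frame `sample_id`, `condition`, `replicate`, `mock_partner`)
#'   and `ledger` (the planted `pair_targets` / `de_effects`).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  with_local_seed(spec$seed, {
    gene_ids <- sprintf("GENE%04d", seq_len(spec$n_genes))
    if (length(spec$treatments) == 0) {
      n_col <- spec$n_samples
      sample_ids <- sprintf("point%02d", seq_len(n_col))
      design <- data.frame(sample_id = sample_ids, condition = "point",
                           replicate = seq_len(n_col),
                           mock_partner = NA_character_,
                           stringsAsFactors = FALSE)
    } else {
      n_col <- (1L + length(spec$treatments)) * spec$n_reps
      conds <- c("mock", spec$treatments)
      design <- do.call(rbind, lapply(seq_len(spec$n_reps), function(r) {
        data.frame(sample_id = sprintf("%s_r%02d", conds, r),
                   condition = conds, replicate = r,
                   mock_partner = c(NA_character_,
                                    rep(sprintf("mock_r%02d", r),
                                        length(spec$treatments))),
                   stringsAsFactors = FALSE)
      }))
      sample_ids <- design$sample_id
    }
    baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean, 1)
    spread <- if (length(spec$treatments) == 0) spec$profile_sd else spec$noise_sd
    mat <- baseline +
      matrix(stats::rnorm(spec$n_genes * n_col, 0, spread),
             nrow = spec$n_genes, ncol = n_col)
    dimnames(mat) <- list(gene_ids, sample_ids)
    if (!is.null(spec$pair_targets)) {
      resolve <- function(g) {
        if (is.numeric(g)) gene_ids[g] else as.character(g)
      }
      for (k in seq_len(nrow(spec$pair_targets))) {
        gi <- resolve(spec$pair_targets$gene_i[k])
        gj <- resolve(spec$pair_targets$gene_j[k])
        rho <- spec$pair_targets$target_r[k]
        s <- stats::rnorm(n_col)
        e <- stats::rnorm(n_col)
        mat[gi, ] <- baseline[match(gi, gene_ids)] + spec$profile_sd * s
        mat[gj, ] <- baseline[match(gj, gene_ids)] +
          spec$profile_sd * (rho * s + sqrt(max(0, 1 - rho^2)) * e)
      }
    }
    if (!is.null(spec$de_effects)) {
      for (k in seq_len(nrow(spec$de_effects))) {
        g <- spec$de_effects$gene[k]
        gid <- if (is.numeric(g)) gene_ids[g] else as.character(g)
        cols <- design$sample_id[design$condition == spec$de_effects$contrast[k]]
        mat[gid, cols] <- mat[gid, cols] + spec$de_effects$log2_shift[k]
      }
    }
    attr(mat, "scale") <- "log2"
    list(matrix = mat, design = design,
         ledger = list(pair_targets = spec$pair_targets,
                       de_effects = spec$de_effects))
  })
}
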