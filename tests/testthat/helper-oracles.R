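# Independent oracles used by the tests. These are deliberately naive
# implementations, kept separate from the package code paths they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Gotoh affine-gap global alignment, score only.
# Gap of length L costs gap_open + L * gap_ext (Biostrings convention).
gotoh_score <- function(a, b, submat, gap_open, gap_ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in b (residue of a vs -)
  Y <- matrix(NEG, n + 1, m + 1) # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + i * gap_ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + j * gap_ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext,
                             Y[i, j + 1] - gap_open - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext,
                             X[i + 1, j] - gap_open - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Linear-gap Needleman-Wunsch enumerating every optimal alignment and
# returning the set of (coverage, identity) pairs over co-optimal tracebacks.
nw_all_optimal_stats <- function(a, b, match = 2, mismatch = -1, gap = 1,
                                 max_paths = 50000) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n) * gap
  S[1, ] <- -(0:m) * gap
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      S[i + 1, j + 1] <- max(S[i, j] + s, S[i, j + 1] - gap, S[i + 1, j] - gap)
    }
  }
  stats <- new.env()
  count <- 0L
  walk <- function(i, j, aligned, identical) {
    if (count >= max_paths) return()
    if (i == 0 && j == 0) {
      count <<- count + 1L
      key <- paste(aligned, identical)
      assign(key, c(aligned = aligned, identical = identical), envir = stats)
      return()
    }
    if (i > 0 && j > 0) {
      s <- if (av[i] == bv[j]) match else mismatch
      if (S[i + 1, j + 1] == S[i, j] + s) {
        walk(i - 1, j - 1, aligned + 1L, identical + (av[i] == bv[j]))
      }
    }
    if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - gap) walk(i - 1, j, aligned, identical)
    if (j > 0 && S[i + 1, j + 1] == S[i + 1, j] - gap) walk(i, j - 1, aligned, identical)
  }
  walk(n, m, 0L, 0L)
  sets <- unique(do.call(rbind, as.list(stats)))
  list(score = S[n + 1, m + 1],
       coverage = 100 * sets[, "aligned"] / max(n, m),
       identity = ifelse(sets[, "aligned"] > 0,
                         100 * sets[, "identical"] / sets[, "aligned"], NA),
       n_paths = count)
}

# Brute-force average-linkage agglomeration returning the cophenetic matrix.
naive_average_cophenetic <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  coph <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best_d - 1e-12) {
          best_d <- avg
          best <- c(i, j)
        }
      }
    }
    for (x in clusters[[best[1]]]) {
      for (y in clusters[[best[2]]]) {
        coph[x, y] <- coph[y, x] <- best_d
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Identity substitution matrix over the 20 residues (linear-gap suite).
identity_submat <- function(match = 2, mismatch = -1) {
  m <- matrix(mismatch, 20, 20, dimnames = list(AA20, AA20))
  diag(m) <- match
  m
}
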