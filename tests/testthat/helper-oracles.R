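# Independent oracles, kept deliberately naive: they are slow,
# literal implementations used only to check the package's fast paths.

# Benjamini-Hochberg step-up by the textbook definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j), mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * p[o[j]] / j)
    q_sorted[i] <- min(1, best)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Gotoh local alignment, match +2 / mismatch -1, gap of length L
# costs 3 + L (so opening move costs 4, each extension 1 more).
sw_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) return(0)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in x (horizontal)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in y (vertical)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - 4, E[i, j - 1L] - 1)
      F[i, j] <- max(H[i - 1L, j] - 4, F[i - 1L, j] - 1)
      s <- if (x[i - 1L] == y[j - 1L]) 2 else -1
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Exhaustive reciprocal-best-hit selection over a score matrix,
# written as explicit nested argmax loops.
rbh_oracle <- function(protA, protB, min_score = 40, min_ratio = 0.3) {
  m <- score_matrix(protA, protB)
  out <- data.frame(focal_id = character(0), other_id = character(0),
                    score = numeric(0), stringsAsFactors = FALSE)
  for (a in rownames(m)) {
    ra <- m[a, ]
    tops_a <- sort(colnames(m)[ra == max(ra)])
    b <- tops_a[1L]
    rb <- m[, b]
    tops_b <- sort(rownames(m)[rb == max(rb)])
    if (tops_b[1L] != a) next
    sc <- m[a, b]
    shorter <- min(nchar(protA[[a]]), nchar(protB[[b]]))
    if (sc < min_score || sc < min_ratio * 2 * shorter) next
    out <- rbind(out, data.frame(focal_id = a, other_id = b,
                                 score = sc, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# small annotation builder for hand-traced layouts
toy_annotation <- function(roles, scaffold = "s1", gap = 500L,
                           len = 1200L, genome_id = "toy",
                           ids = NULL) {
  n <- length(roles)
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(n))
  starts <- 1L + (seq_len(n) - 1L) * (len + gap)
  genome_annotation(data.frame(
    gene_id = ids, scaffold = scaffold,
    start = starts, end = starts + len - 1L,
    strand = "+", role = roles, stringsAsFactors = FALSE),
    genome_id = genome_id)
}

# DE table with a given qualification pattern (TRUE rows upregulated
# at every timepoint, FALSE rows null)
toy_de <- function(gene_ids, qual, timepoints = 1:3) {
  do.call(rbind, lapply(timepoints, function(t)
    data.frame(gene_id = gene_ids, timepoint = t,
               log2fc = ifelse(qual, 6, 0),
               p_value = ifelse(qual, 1e-8, 0.9),
               q_value = ifelse(qual, 1e-6, 0.95),
               mean_control = 5,
               mean_treatment = ifelse(qual, 320, 5),
               stringsAsFactors = FALSE)))
}
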