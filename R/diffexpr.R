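PHI_FLOOR <- 1e-8

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median across genes of the ratio of its
#' count to the per-gene geometric mean over samples (genes with a
#' zero anywhere are excluded from the reference), rescaled so the
#' factors have geometric mean 1. With \code{pseudo_reference = TRUE}
#' the per-gene reference is the geometric mean over the positive
#' counts only, which tolerates matrices where no gene is expressed in
#' every sample.
#'
#' @param counts Count matrix (genes x samples) or a
#'   [counts_matrix()].
#' @param pseudo_reference Fall back to a positive-counts reference.
#' @return Positive numeric vector, one factor per sample, geometric
#'   mean 1.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  if (inherits(counts, "counts_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L) return(stats::setNames(1, colnames(counts)))
  lc <- log(counts)
  if (pseudo_reference) {
    lc[!is.finite(lc)] <- NA
    ref <- rowMeans(lc, na.rm = TRUE)
    use <- is.finite(ref) & rowSums(is.finite(lc)) > 0
  } else {
    ref <- rowMeans(lc)
    use <- is.finite(ref)
    if (!any(use))
      stop("no gene has nonzero counts in every sample; ",
           "retry with pseudo_reference = TRUE")
  }
  f <- apply(lc[use, , drop = FALSE] - ref[use], 2,
             stats::median, na.rm = TRUE)
  if (any(!is.finite(f)))
    stop("size factor undefined for sample(s): ",
         paste(colnames(counts)[!is.finite(f)], collapse = ", "))
  f <- exp(f - mean(f))
  stats::setNames(f, colnames(counts))
}

#' Method-of-moments NB dispersion for one gene
#'
#' On normalized counts, each group with at least two samples and a
#' positive mean contributes \code{(s^2 - m) / m^2}; the estimate is
#' their average, clamped below at \code{floor}. Constant or
#' underdispersed counts therefore clamp to the floor.
#'
#' @param gene_counts Numeric vector of raw counts for one gene.
#' @param groups Factor/vector of group labels, same length.
#' @param factors Size factors (default 1).
#' @param floor Lower clamp (default 1e-8).
#' @return Single non-negative dispersion estimate with attribute
#'   \code{method = "moments"}.
#' @export
moments_dispersion <- function(gene_counts, groups,
                               factors = rep(1, length(gene_counts)),
                               floor = PHI_FLOOR) {
  stopifnot(length(gene_counts) == length(groups),
            length(factors) == length(gene_counts))
  y <- gene_counts / factors
  phis <- c()
  for (g in unique(groups)) {
    yg <- y[groups == g]
    if (length(yg) < 2L) next
    m <- mean(yg)
    if (m <= 0) next
    phis <- c(phis, (stats::var(yg) - m) / m^2)
  }
  est <- if (length(phis) == 0L) floor else max(floor, mean(phis))
  structure(est, method = "moments")
}

#' Exact conditional NB test for a two-group comparison
#'
#' Conditions on the total (normalized) count across both groups and
#' enumerates all splits of that total between the group sums, whose
#' conditional distribution under H0 (equal means, shared dispersion)
#' is the product of the two group-sum NB densities. The two-sided
#' p-value is the probability of all outcomes no more likely than the
#' observed one. A sum of n iid NB(mu, phi) draws is NB(n mu, phi/n),
#' which gives the group-sum densities in closed form.
#'
#' @param gene_counts Raw counts for one gene across both groups.
#' @param groups Two-level factor/vector of group labels.
#' @param phi Shared NB dispersion (e.g. from
#'   [moments_dispersion()]).
#' @param factors Size factors; counts are normalized and group sums
#'   rounded to the nearest integer before conditioning.
#' @return Two-sided p-value; 1 by convention when the total is zero.
#' @export
nb_exact_test <- function(gene_counts, groups, phi,
                          factors = rep(1, length(gene_counts))) {
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required")
  ga <- groups == lev[1L]
  if (sum(ga) < 2L || sum(!ga) < 2L)
    stop("each group needs >= 2 replicates")
  phi <- max(as.numeric(phi), PHI_FLOOR)
  y <- gene_counts / factors
  sa <- round(sum(y[ga])); sb <- round(sum(y[!ga]))
  tot <- sa + sb
  if (tot == 0) return(1)
  na <- sum(ga); nb <- sum(!ga)
  mu_hat <- tot / (na + nb)
  s <- 0:tot
  lp <- stats::dnbinom(s, size = na / phi, mu = na * mu_hat, log = TRUE) +
    stats::dnbinom(tot - s, size = nb / phi, mu = nb * mu_hat, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[sa + 1L] * (1 + 1e-10)]))
}

#' Log2 fold change with a pseudocount
#'
#' \code{log2((mean_treatment + c) / (mean_control + c))}. The
#' pseudocount keeps genes with near-zero control expression (the
#' typical cluster gene before induction) off infinity.
#'
#' @param mean_control,mean_treatment Non-negative normalized means.
#' @param pseudocount Positive stabilizer (default 0.5).
#' @return Numeric log2 fold change (vectorized).
#' @export
log2_fold_change <- function(mean_control, mean_treatment,
                             pseudocount = 0.5) {
  stopifnot(pseudocount > 0, all(mean_control >= 0),
            all(mean_treatment >= 0))
  log2((mean_treatment + pseudocount) / (mean_control + pseudocount))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via \code{stats::p.adjust}); used as the
#' q-value throughout the pipeline.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted values, clipped at 1, monotone in p.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Reads per kilobase per million mapped reads
#'
#' \code{count / ((gene_length_bp / 1000) * (total_mapped / 1e6))}.
#' Linear in the count, inversely proportional to gene length and
#' sequencing depth.
#'
#' @param count Read count(s).
#' @param gene_length_bp Gene length(s) in bp (>= 1).
#' @param total_mapped Total mapped reads in the sample (>= 1).
#' @return Non-negative RPKM value(s).
#' @export
rpkm <- function(count, gene_length_bp, total_mapped) {
  stopifnot(all(gene_length_bp >= 1), all(total_mapped >= 1),
            all(count >= 0))
  count / ((gene_length_bp / 1000) * (total_mapped / 1e6))
}

#' Per-timepoint two-group NB differential expression
#'
#' At each timepoint with both conditions present (>= 2 replicates
#' each), the treatment replicates are compared with the control
#' replicates: median-of-ratios normalization, NB dispersion by the
#' method of moments, the exact conditional NB test per gene,
#' Benjamini-Hochberg adjustment within the timepoint, and a log2
#' fold change on normalized means. Per-sample RPKM is computed on
#' the full matrix (total mapped reads = column sums). "Upregulated"
#' flags combine the two-sided q-value with a directional filter
#' (\code{q < alpha} and \code{log2fc > 0}).
#'
#' @param cm A [counts_matrix()].
#' @param ann Optional [genome_annotation()] supplying gene lengths
#'   for RPKM; genes missing from it get NA RPKM.
#' @param alpha Significance thresholds for the flags (defaults 0.01,
#'   0.001, 0.05).
#' @param dispersion \code{"common"} pools the moments estimator
#'   across all genes at the timepoint (stable for 3 vs 3 designs);
#'   \code{"tagwise"} uses the per-gene estimate.
#' @param pseudocount Pseudocount for the fold change.
#' @return A \code{de_result}: list with \code{table} (gene_id,
#'   timepoint, log2fc, p_value, q_value, mean_control,
#'   mean_treatment, one \code{up_*} flag column per alpha),
#'   \code{rpkm} (genes x samples, or NULL without \code{ann}),
#'   \code{alpha}, and \code{params}.
#' @export
run_timecourse_de <- function(cm, ann = NULL,
                              alpha = c(0.01, 0.001, 0.05),
                              dispersion = c("common", "tagwise"),
                              pseudocount = 0.5) {
  stopifnot(inherits(cm, "counts_matrix"))
  dispersion <- match.arg(dispersion)
  counts <- cm$counts; meta <- cm$meta
  genes <- rownames(counts)
  out <- list()
  for (t in sort(unique(meta$timepoint))) {
    sel <- meta$timepoint == t
    cond <- meta$condition[sel]
    if (length(unique(cond)) < 2L || min(table(cond)) < 2L) {
      warning(sprintf("timepoint %d lacks two conditions with >= 2 replicates; skipped", t))
      next
    }
    sub <- counts[, sel, drop = FALSE]
    sf <- tryCatch(size_factors(sub),
                   error = function(e) size_factors(sub,
                                                    pseudo_reference = TRUE))
    y <- sweep(sub, 2, sf, "/")
    is_trt <- cond == "treatment"
    m_ctl <- rowMeans(y[, !is_trt, drop = FALSE])
    m_trt <- rowMeans(y[, is_trt, drop = FALSE])
    if (dispersion == "common") {
      num <- 0; den <- 0
      for (g in c(FALSE, TRUE)) {
        yg <- y[, is_trt == g, drop = FALSE]
        m <- rowMeans(yg)
        v <- apply(yg, 1, stats::var)
        num <- num + sum(v - m)
        den <- den + sum(m^2)
      }
      phi_common <- if (den > 0) max(PHI_FLOOR, num / den) else PHI_FLOOR
      phis <- rep(phi_common, length(genes))
    } else {
      phis <- vapply(seq_along(genes), function(i)
        as.numeric(moments_dispersion(sub[i, ], cond, sf)), numeric(1))
    }
    p <- vapply(seq_along(genes), function(i)
      nb_exact_test(sub[i, ], cond, phis[i], sf), numeric(1))
    q <- bh_adjust(p)
    lfc <- log2_fold_change(m_ctl, m_trt, pseudocount)
    tab <- data.frame(gene_id = genes, timepoint = t, log2fc = lfc,
                      p_value = p, q_value = q,
                      mean_control = m_ctl, mean_treatment = m_trt,
                      stringsAsFactors = FALSE, row.names = NULL)
    for (a in alpha)
      tab[[sprintf("up_%g", a)]] <- q < a & lfc > 0
    out[[length(out) + 1L]] <- tab
  }
  if (length(out) == 0L) stop("no testable timepoint in the design")
  table <- do.call(rbind, out)
  rp <- NULL
  if (!is.null(ann)) {
    len <- ann$length_bp[match(genes, ann$gene_id)]
    depth <- colSums(counts)
    rp <- counts
    storage.mode(rp) <- "double"
    for (j in seq_len(ncol(rp)))
      rp[, j] <- ifelse(is.na(len), NA_real_,
                        rpkm(counts[, j], pmax(len, 1L), depth[j]))
  }
  structure(list(table = table, rpkm = rp, alpha = alpha,
                 params = list(dispersion = dispersion,
                               pseudocount = pseudocount,
                               adjustment = "BH within timepoint")),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d genes x %d timepoints (%s dispersion)\n",
              length(unique(x$table$gene_id)),
              length(unique(x$table$timepoint)),
              x$params$dispersion))
  invisible(x)
}

#' Write a DE result table as TSV
#' @param de A \code{de_result} from [run_timecourse_de()].
#' @param path Output file.
#' @export
write_de_table <- function(de, path) {
  stopifnot(inherits(de, "de_result"))
  utils::write.table(de$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
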