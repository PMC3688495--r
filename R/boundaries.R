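#' Delineate the transcriptionally defined cluster
#'
#' A gene qualifies when it is upregulated (q-value below \code{alpha}
#' and log2 fold change above zero) at no fewer than
#' \code{min_timepoints} timepoints. Starting from the backbone gene,
#' the call extends along the scaffold in both directions while genes
#' qualify, tolerating up to \code{gap_tolerance} consecutive
#' non-qualifying genes (constitutively expressed cluster members can
#' fail the upregulation filter without breaking the run);
#' non-qualifying genes are trimmed from both ends. If the backbone
#' itself does not qualify the call is still emitted, carrying a
#' \code{"backbone_not_significant"} flag. If every gene on the
#' scaffold qualifies the call carries a \code{"saturated"} flag and a
#' warning, signalling a mis-specified threshold.
#'
#' @param ann A [genome_annotation()].
#' @param de A \code{de_result} from [run_timecourse_de()] (or its
#'   \code{table}).
#' @param backbone_id Backbone gene around which to delineate.
#' @param alpha q-value threshold (default 0.001).
#' @param min_timepoints Minimum number of timepoints at which a gene
#'   must be upregulated (default 1, i.e. "at least one timepoint").
#' @param gap_tolerance Consecutive non-qualifying genes bridged
#'   (default 1).
#' @return A [cluster_call()] with \code{method = "expression"}.
#' @export
call_expression_cluster <- function(ann, de, backbone_id,
                                    alpha = 0.001,
                                    min_timepoints = 1L,
                                    gap_tolerance = 1L) {
  stopifnot(inherits(ann, "genome_annotation"),
            alpha > 0, alpha < 1, min_timepoints >= 1,
            gap_tolerance >= 0)
  tab <- if (inherits(de, "de_result")) de$table else as.data.frame(de)
  if (!(backbone_id %in% ann$gene_id))
    stop("backbone gene not in annotation: ", backbone_id)
  if (!(backbone_id %in% tab$gene_id))
    stop("backbone gene absent from DE table: ", backbone_id)

  up <- tab$q_value < alpha & tab$log2fc > 0
  n_up <- tapply(up, tab$gene_id, sum)
  qualifies <- function(gid) {
    k <- n_up[gid]
    !is.na(k) && k >= min_timepoints
  }

  scf <- ann$scaffold[match(backbone_id, ann$gene_id)]
  genes <- as.data.frame(ann)[ann$scaffold == scf, , drop = FALSE]
  rownames(genes) <- NULL
  qual <- vapply(genes$gene_id, qualifies, logical(1))
  i <- match(backbone_id, genes$gene_id)

  extend <- function(dir) {
    last <- i
    streak <- 0L
    k <- i + dir
    while (k >= 1L && k <= nrow(genes)) {
      if (qual[k]) {
        last <- k
        streak <- 0L
      } else {
        streak <- streak + 1L
        if (streak > gap_tolerance) break
      }
      k <- k + dir
    }
    last
  }
  lo <- extend(-1L); hi <- extend(+1L)

  flags <- character(0)
  if (!qual[i]) flags <- c(flags, "backbone_not_significant")
  if (all(qual)) {
    flags <- c(flags, "saturated")
    warning("every gene on scaffold '", scf,
            "' qualifies at alpha = ", alpha,
            "; expression call is saturated")
  }
  idx <- lo:hi
  cluster_call(method = "expression", scaffold = scf,
               gene_ids = genes$gene_id[idx],
               start_bp = min(genes$start[idx]),
               end_bp = max(genes$end[idx]),
               backbone_id = backbone_id, flags = flags)
}

#' Boundary concordance between cluster calls
#'
#' For every unordered pair of calls on the same scaffold: whether the
#' 5' boundary genes match, whether the 3' boundary genes match
#' (compared by gene id), and the Jaccard index of the gene-id sets.
#'
#' @param calls Named list (or plain list) of [cluster_call()]s; names
#'   default to each call's method label.
#' @return A \code{concordance_report}: list with \code{pairs} (one
#'   row per pair: method_a, method_b, five_prime_match,
#'   three_prime_match, jaccard) and \code{calls} (per-method summary:
#'   n_genes, start_bp, end_bp, span_bp).
#' @export
compare_calls <- function(calls) {
  if (inherits(calls, "cluster_call")) stop(">= 2 calls required")
  stopifnot(length(calls) >= 2,
            all(vapply(calls, inherits, logical(1), "cluster_call")))
  if (is.null(names(calls)) || any(!nzchar(names(calls))))
    names(calls) <- vapply(calls, `[[`, character(1), "method")
  scfs <- vapply(calls, `[[`, character(1), "scaffold")
  if (length(unique(scfs)) > 1L)
    stop("calls lie on different scaffolds: ",
         paste(unique(scfs), collapse = ", "))
  nm <- names(calls)
  pairs <- utils::combn(seq_along(calls), 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- calls[[ij[1]]]; b <- calls[[ij[2]]]
    ga <- a$gene_ids; gb <- b$gene_ids
    data.frame(method_a = nm[ij[1]], method_b = nm[ij[2]],
               five_prime_match = ga[1] == gb[1],
               three_prime_match = ga[length(ga)] == gb[length(gb)],
               jaccard = length(intersect(ga, gb)) /
                 length(union(ga, gb)),
               stringsAsFactors = FALSE)
  })
  summary <- data.frame(
    method = nm,
    n_genes = vapply(calls, function(x) length(x$gene_ids), integer(1)),
    start_bp = vapply(calls, `[[`, integer(1), "start_bp"),
    end_bp = vapply(calls, `[[`, integer(1), "end_bp"),
    span_bp = vapply(calls, `[[`, integer(1), "span_bp"),
    five_prime_gene = vapply(calls, function(x) x$gene_ids[1],
                             character(1)),
    three_prime_gene = vapply(calls, function(x)
      x$gene_ids[length(x$gene_ids)], character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(pairs = do.call(rbind, rows), calls = summary),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report\n")
  print.data.frame(x$pairs, digits = 3)
  invisible(x)
}

#' Deterministic concordance fixture
#'
#' A 40-gene scaffold emulating the canonical three-way boundary
#' pattern: the tight predictor (rule_A) calls a compact 10-gene
#' cluster beginning at the backbone NRPS; the permissive predictor
#' (rule_B) calls a 22-gene superset that also sweeps up a 5' block of
#' associated genes excluded by the other two methods; the
#' expression-defined cluster shares its 5' boundary with rule_A (at
#' the backbone) and its 3' boundary with rule_B. The DE table is
#' synthetic and deterministic: genes at scaffold positions 17-30 are
#' strongly upregulated from timepoint 3 onward, everything else is
#' null.
#'
#' @return List with \code{annotation}, \code{de} (a DE table usable
#'   by [call_expression_cluster()]), and \code{backbone_id}.
#' @export
concordance_fixture <- function() {
  roles <- c(rep("housekeeping", 8),                          # 1-8
             "tailoring", "transport", "racemase", "tailoring",
             "regulator", "tailoring",                        # 9-14
             "hypothetical", "housekeeping",                  # 15-16
             "backbone_nrps",                                 # 17
             "cyclophilin", "tailoring", "racemase",
             "aminotransferase", "tailoring", "regulator",
             "transport", "tailoring", "regulator",           # 18-26
             "hypothetical", "hypothetical",                  # 27-28
             "tailoring", "transport",                        # 29-30
             rep("housekeeping", 10))                         # 31-40
  n <- length(roles)
  len <- rep(1200L, n)
  starts <- 1L + (seq_len(n) - 1L) * 1700L
  ann <- genome_annotation(data.frame(
    gene_id = sprintf("FIX%03d", seq_len(n)),
    scaffold = "scaffold_1",
    start = starts, end = starts + len - 1L,
    strand = rep(c("+", "-"), length.out = n),
    role = roles, stringsAsFactors = FALSE), genome_id = "fixture")
  induced <- seq_len(n) %in% 17:30
  de <- do.call(rbind, lapply(1:6, function(t) {
    on <- induced & t >= 3
    data.frame(gene_id = ann$gene_id,
               timepoint = t,
               log2fc = ifelse(on, 8, 0),
               p_value = ifelse(on, 1e-9, 0.8),
               q_value = ifelse(on, 1e-7, 0.95),
               mean_control = 5,
               mean_treatment = ifelse(on, 1280, 5),
               stringsAsFactors = FALSE)
  }))
  list(annotation = ann, de = de, backbone_id = "FIX017")
}
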