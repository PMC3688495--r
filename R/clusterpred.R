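#' Cluster call
#'
#' A contiguous interval of genes attributed to one delineation method.
#'
#' @param method One of \code{"rule_A"}, \code{"rule_B"},
#'   \code{"expression"} (free-form labels are allowed).
#' @param scaffold Scaffold name.
#' @param gene_ids Ordered gene ids, contiguous in annotation order.
#' @param start_bp,end_bp 1-based inclusive genomic extent.
#' @param backbone_id Seeding backbone gene id (must be in
#'   \code{gene_ids}).
#' @param flags Character vector of quality flags (e.g.
#'   \code{"backbone_not_significant"}, \code{"saturated"}).
#' @return A \code{cluster_call} list with derived \code{span_bp}.
#' @export
cluster_call <- function(method, scaffold, gene_ids, start_bp, end_bp,
                         backbone_id, flags = character(0)) {
  stopifnot(length(gene_ids) >= 1, start_bp <= end_bp,
            backbone_id %in% gene_ids)
  structure(list(method = method, scaffold = scaffold,
                 gene_ids = as.character(gene_ids),
                 start_bp = as.integer(start_bp),
                 end_bp = as.integer(end_bp),
                 span_bp = as.integer(end_bp - start_bp + 1L),
                 backbone_id = backbone_id,
                 flags = flags),
            class = "cluster_call")
}

#' @export
print.cluster_call <- function(x, ...) {
  cat(sprintf("cluster_call [%s] %s:%d-%d (%d genes, %d bp, backbone %s)%s\n",
              x$method, x$scaffold, x$start_bp, x$end_bp,
              length(x$gene_ids), x$span_bp, x$backbone_id,
              if (length(x$flags)) paste0(" flags: ",
                                          paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Parameters for rule-based cluster prediction
#'
#' @param sm_roles Roles counted as cluster-associated (default
#'   [sm_roles_default()]).
#' @param max_gap_genes Consecutive non-associated genes tolerated
#'   while extending (>= 0).
#' @param max_gap_bp Largest intergenic gap crossed while extending.
#' @param merge_backbones Merge calls from distinct backbones when they
#'   are within the same gene/bp tolerances.
#' @return A \code{rule_params} list.
#' @export
rule_params <- function(sm_roles = sm_roles_default(),
                        max_gap_genes = 1L,
                        max_gap_bp = 10000L,
                        merge_backbones = TRUE) {
  stopifnot(max_gap_genes >= 0, max_gap_bp >= 0)
  structure(list(sm_roles = sm_roles,
                 max_gap_genes = as.integer(max_gap_genes),
                 max_gap_bp = as.integer(max_gap_bp),
                 merge_backbones = isTRUE(merge_backbones)),
            class = "rule_params")
}

#' The two shipped predictor parameterizations
#'
#' \code{rule_A} is tight (gap tolerance 1 gene / 10 kb) and tends to
#' call a compact cluster; \code{rule_B} is permissive (3 genes /
#' 20 kb) and calls a larger region. They reproduce the qualitative
#' situation of a smaller prediction nested in a larger one from two
#' independent rule-based tools; they are stand-ins, not
#' reimplementations of any published predictor.
#'
#' @return Named list of [rule_params()].
#' @export
rule_presets <- function() {
  list(rule_A = rule_params(max_gap_genes = 1L, max_gap_bp = 10000L),
       rule_B = rule_params(max_gap_genes = 3L, max_gap_bp = 20000L))
}

# extend from seed index i (within one scaffold's gene table) in
# direction dir, returning the last associated index reached
extend_call <- function(genes, assoc, i, dir, params) {
  last <- i
  streak <- 0L
  k <- i + dir
  while (k >= 1L && k <= nrow(genes)) {
    lo <- min(k, k - dir); hi <- max(k, k - dir)
    gap <- genes$start[hi] - genes$end[lo] - 1L
    if (gap > params$max_gap_bp) break
    if (assoc[k]) {
      last <- k
      streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak > params$max_gap_genes) break
    }
    k <- k + dir
  }
  last
}

#' Predict secondary-metabolite clusters around backbone genes
#'
#' One call is seeded at every backbone (NRPS/PKS) gene and extended
#' gene-by-gene in both directions while the next gene's role is
#' cluster-associated, tolerating up to \code{max_gap_genes}
#' consecutive non-associated genes and stopping at any intergenic gap
#' larger than \code{max_gap_bp}. Non-associated genes are trimmed
#' from both ends, so every call starts and ends on a cluster
#' -associated gene. Calls whose gene sets overlap are coalesced;
#' with \code{merge_backbones} calls separated by no more than the
#' gene/bp tolerances are also merged.
#'
#' @param ann A [genome_annotation()].
#' @param params A [rule_params()].
#' @param method Label recorded on the calls (e.g. \code{"rule_A"}).
#' @return List of [cluster_call()]s (empty, with a message, if the
#'   genome has no backbone genes).
#' @export
predict_clusters <- function(ann, params = rule_params(),
                             method = "rule_A") {
  stopifnot(inherits(ann, "genome_annotation"),
            inherits(params, "rule_params"), nrow(ann) > 0)
  calls <- list()
  for (scf in unique(ann$scaffold)) {
    genes <- as.data.frame(ann)[ann$scaffold == scf, , drop = FALSE]
    rownames(genes) <- NULL
    assoc <- genes$role %in% params$sm_roles
    seeds <- which(genes$role %in% backbone_roles())
    if (length(seeds) == 0L) next
    ranges <- lapply(seeds, function(i) {
      c(lo = extend_call(genes, assoc, i, -1L, params),
        hi = extend_call(genes, assoc, i, +1L, params),
        seed = i)
    })
    ranges <- ranges[order(vapply(ranges, `[[`, numeric(1), "lo"))]
    merged <- list(ranges[[1L]])
    for (r in ranges[-1L]) {
      cur <- merged[[length(merged)]]
      overlap <- r[["lo"]] <= cur[["hi"]]
      near <- FALSE
      if (!overlap && params$merge_backbones) {
        between <- r[["lo"]] - cur[["hi"]] - 1L
        gap_bp <- genes$start[r[["lo"]]] - genes$end[cur[["hi"]]] - 1L
        near <- between <= params$max_gap_genes &&
          gap_bp <= params$max_gap_bp
      }
      if (overlap || near) {
        cur[["hi"]] <- max(cur[["hi"]], r[["hi"]])
        merged[[length(merged)]] <- cur
      } else merged[[length(merged) + 1L]] <- r
    }
    for (r in merged) {
      idx <- r[["lo"]]:r[["hi"]]
      calls[[length(calls) + 1L]] <- cluster_call(
        method = method, scaffold = scf,
        gene_ids = genes$gene_id[idx],
        start_bp = min(genes$start[idx]),
        end_bp = max(genes$end[idx]),
        backbone_id = genes$gene_id[r[["seed"]]])
    }
  }
  if (length(calls) == 0L)
    message("no backbone genes found; no clusters predicted")
  calls
}

#' Export cluster calls to BED
#'
#' Internal 1-based inclusive coordinates are converted to BED's
#' 0-based half-open convention.
#'
#' @param calls List of [cluster_call()]s.
#' @param path Output BED file.
#' @return \code{path}, invisibly.
#' @export
calls_to_bed <- function(calls, path) {
  if (inherits(calls, "cluster_call")) calls <- list(calls)
  rows <- vapply(calls, function(x)
    sprintf("%s\t%d\t%d\t%s\t0\t.", x$scaffold, x$start_bp - 1L,
            x$end_bp, x$method), character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Export cluster calls to JSON
#' @inheritParams calls_to_bed
#' @export
calls_to_json <- function(calls, path) {
  if (inherits(calls, "cluster_call")) calls <- list(calls)
  jsonlite::write_json(lapply(calls, unclass), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
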