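# fixed scoring scheme used for all protein comparisons:
# match +2, mismatch -1, affine gaps costing 3 + L for a gap of length L
align_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters <- Biostrings::AA_ALPHABET
      mm <- matrix(-1, length(letters), length(letters),
                   dimnames = list(letters, letters))
      diag(mm) <- 2
      m <<- mm
    }
    m
  }
})

#' Smith-Waterman local alignment score
#'
#' Local alignment with match +2, mismatch -1 and affine gap penalties
#' (a gap of length L costs 3 + L). The score is symmetric in its
#' arguments and floored at 0; an empty sequence scores 0. A perfect
#' self-alignment therefore scores twice the sequence length.
#'
#' @param a,b Uppercase amino-acid strings.
#' @return Non-negative alignment score.
#' @export
local_align_score <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = align_submat(),
    gapOpening = 3, gapExtension = 1, scoreOnly = TRUE)
  max(0, s)
}

# vectorized: scores of many patterns against one subject
local_align_scores <- function(patterns, subject) {
  if (nchar(subject) == 0L) return(rep(0, length(patterns)))
  ok <- nchar(patterns) > 0L
  out <- numeric(length(patterns))
  if (any(ok)) {
    s <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(patterns[ok]),
      Biostrings::AAString(subject),
      type = "local", substitutionMatrix = align_submat(),
      gapOpening = 3, gapExtension = 1, scoreOnly = TRUE)
    out[ok] <- pmax(0, s)
  }
  out
}

self_align_score <- function(seq) 2 * nchar(seq)

#' All-vs-all local alignment score matrix
#'
#' @param protA,protB Named character vectors of protein sequences.
#' @return Matrix of scores, rows = A, columns = B.
#' @export
score_matrix <- function(protA, protB) {
  m <- matrix(0, nrow = length(protA), ncol = length(protB),
              dimnames = list(names(protA), names(protB)))
  for (j in seq_along(protB))
    m[, j] <- local_align_scores(protA, protB[[j]])
  m
}

#' Reciprocal-best-hit ortholog map
#'
#' A pair (a, b) is reported as orthologous when b is a's unique best
#' hit, a is b's unique best hit, the score reaches \code{min_score},
#' and the score is at least \code{min_ratio} times the self-score of
#' the shorter sequence. Tied best hits are broken toward the
#' lexicographically smallest gene id and reported via a message.
#'
#' @param protA,protB Named character vectors (focal and comparator
#'   proteomes).
#' @param min_score Absolute score floor (default 40).
#' @param min_ratio Fraction of the shorter sequence's self-score that
#'   must be reached (default 0.3).
#' @return An \code{ortholog_map}: data.frame (focal_id, other_id,
#'   score), each gene in at most one pair.
#' @export
rbh_map <- function(protA, protB, min_score = 40, min_ratio = 0.3) {
  empty <- data.frame(focal_id = character(0), other_id = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (length(protA) == 0L || length(protB) == 0L)
    return(structure(empty, class = c("ortholog_map", "data.frame")))
  m <- score_matrix(protA, protB)
  best_of <- function(scores, ids) {
    top <- max(scores)
    hits <- ids[scores == top]
    if (length(hits) > 1L) {
      hits <- sort(hits)
      # ties among hits below the score floor can never become pairs;
      # only log ties that could have mattered
      if (top >= min_score)
        message("tied best hit broken lexicographically: ",
                paste(hits, collapse = " / "))
    }
    hits[1L]
  }
  bestA <- vapply(seq_len(nrow(m)), function(i)
    best_of(m[i, ], colnames(m)), character(1))
  bestB <- vapply(seq_len(ncol(m)), function(j)
    best_of(m[, j], rownames(m)), character(1))
  names(bestA) <- rownames(m); names(bestB) <- colnames(m)
  rows <- list()
  for (a in names(bestA)) {
    b <- bestA[[a]]
    if (bestB[[b]] != a) next
    sc <- m[a, b]
    shorter <- min(nchar(protA[[a]]), nchar(protB[[b]]))
    if (sc < min_score || sc < min_ratio * 2 * shorter) next
    rows[[length(rows) + 1L]] <- data.frame(
      focal_id = a, other_id = b, score = sc,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  structure(out, class = c("ortholog_map", "data.frame"))
}

# longest increasing subsequence length (O(n^2); n <= a few dozen)
lis_length <- function(x) {
  n <- length(x)
  if (n == 0L) return(0L)
  best <- rep(1L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L))
    if (x[j] < x[i]) best[i] <- max(best[i], best[j] + 1L)
  max(best)
}

#' Flank-synteny and ortholog-dispersal report for one comparator
#'
#' Measures, for the \code{flank_n} genes on each side of the cluster
#' call: the fraction with orthologs in the comparator, the
#' conservation of their order (longest increasing subsequence of
#' comparator positions over flank orthologs found), the intervening
#' gap between the innermost mapped 5'-flank and 3'-flank orthologs in
#' the comparator (NA with a \code{different_scaffolds} flag when they
#' do not share a scaffold, as after a rearrangement), and how many
#' cluster-gene orthologs fall inside versus outside that flank span
#' (outside = dispersed).
#'
#' @param focal_ann Focal [genome_annotation()].
#' @param cluster A [cluster_call()] on the focal annotation.
#' @param ortho An \code{ortholog_map} from [rbh_map()] (focal vs this
#'   comparator).
#' @param other_ann Comparator [genome_annotation()].
#' @param flank_n Flanking genes per side (default 10).
#' @return A \code{synteny_report} list; \code{origin_label} is
#'   \code{"unresolved"} until [classify_origin()] is applied.
#' @export
flank_synteny_report <- function(focal_ann, cluster, ortho, other_ann,
                                 flank_n = 10L) {
  stopifnot(inherits(focal_ann, "genome_annotation"),
            inherits(cluster, "cluster_call"),
            inherits(other_ann, "genome_annotation"), flank_n >= 1)
  first_id <- cluster$gene_ids[1L]
  last_id <- cluster$gene_ids[length(cluster$gene_ids)]
  f5 <- neighbor_window(focal_ann, first_id, flank_n)$upstream
  f3 <- neighbor_window(focal_ann, last_id, flank_n)$downstream

  map_to <- function(ids) {
    o <- ortho$other_id[match(ids, ortho$focal_id)]
    stats::setNames(o, ids)
  }
  o5 <- map_to(f5$gene_id); o3 <- map_to(f3$gene_id)
  flank5_conserved <- if (nrow(f5) > 0) mean(!is.na(o5)) else NA_real_
  flank3_conserved <- if (nrow(f3) > 0) mean(!is.na(o3)) else NA_real_
  found <- c(o5[!is.na(o5)], o3[!is.na(o3)])

  oth <- as.data.frame(other_ann)
  pos_global <- function(ids) match(ids, oth$gene_id)
  order_conserved <- if (length(found) > 1L)
    lis_length(pos_global(found)) / length(found)
  else if (length(found) == 1L) 1 else NA_real_

  flags <- character(0)
  gap <- NA_integer_
  inner5 <- rev(o5[!is.na(o5)])[1L]   # closest mapped 5' flank gene
  inner3 <- o3[!is.na(o3)][1L]        # closest mapped 3' flank gene
  span_scf <- NA_character_
  span_lo <- span_hi <- NA_integer_
  if (length(found) == 0L) {
    flags <- c(flags, "no_flank_orthologs")
  } else if (is.na(inner5) || is.na(inner3)) {
    flags <- c(flags, "one_sided_flank")
  } else {
    r5 <- oth[match(inner5, oth$gene_id), ]
    r3 <- oth[match(inner3, oth$gene_id), ]
    if (r5$scaffold != r3$scaffold) {
      flags <- c(flags, "different_scaffolds")
    } else {
      a <- if (r5$start <= r3$start) r5 else r3
      b <- if (r5$start <= r3$start) r3 else r5
      gap <- intergenic_gap(a, b)
      span_scf <- a$scaffold
      span_lo <- a$end; span_hi <- b$start
    }
  }

  cl_o <- map_to(cluster$gene_ids)
  cl_found <- cl_o[!is.na(cl_o)]
  inside <- 0L
  if (length(cl_found) > 0 && !is.na(span_scf)) {
    rows <- oth[match(cl_found, oth$gene_id), ]
    inside <- sum(rows$scaffold == span_scf &
                    rows$start > span_lo & rows$end < span_hi)
  }
  structure(list(
    genome_id = genome_id(other_ann),
    cluster_size = length(cluster$gene_ids),
    flank5_conserved = flank5_conserved,
    flank3_conserved = flank3_conserved,
    flank_conserved = mean(c(!is.na(o5), !is.na(o3))),
    order_conserved = order_conserved,
    intervening_gap_bp = gap,
    cluster_orthologs_total = length(cl_found),
    cluster_orthologs_inside_gap = as.integer(inside),
    cluster_orthologs_dispersed = length(cl_found) - as.integer(inside),
    origin_label = "unresolved",
    flags = flags), class = "synteny_report")
}

#' @export
print.synteny_report <- function(x, ...) {
  cat(sprintf(
    "synteny_report [%s]: flanks %.2f/%.2f (order %.2f), gap %s bp, cluster orthologs %d (%d inside, %d dispersed) -> %s\n",
    x$genome_id, x$flank5_conserved, x$flank3_conserved,
    x$order_conserved,
    ifelse(is.na(x$intervening_gap_bp), "NA",
           format(x$intervening_gap_bp)),
    x$cluster_orthologs_total, x$cluster_orthologs_inside_gap,
    x$cluster_orthologs_dispersed, x$origin_label))
  invisible(x)
}

#' Thresholds for origin classification
#'
#' @param cluster_frac_hi Cluster-ortholog fraction at or above which
#'   the cluster is considered present in the comparator (default
#'   0.8).
#' @param cluster_frac_lo Fraction at or below which it is considered
#'   absent (default 0.3).
#' @param flank_frac_hi Flank conservation at or above which flanks
#'   count as syntenic (default 0.7).
#' @param flank_frac_lo Flank conservation below which flanks count as
#'   non-syntenic (default 0.5).
#' @param gap_max Largest flank-to-flank intervening gap (bp)
#'   compatible with simple cluster absence (default 5000; absent
#'   clusters leave conserved flanks nearly adjacent).
#' @return Named list of thresholds.
#' @export
origin_thresholds <- function(cluster_frac_hi = 0.8,
                              cluster_frac_lo = 0.3,
                              flank_frac_hi = 0.7,
                              flank_frac_lo = 0.5,
                              gap_max = 5000L) {
  list(cluster_frac_hi = cluster_frac_hi,
       cluster_frac_lo = cluster_frac_lo,
       flank_frac_hi = flank_frac_hi,
       flank_frac_lo = flank_frac_lo,
       gap_max = as.integer(gap_max))
}

#' Classify the evolutionary origin signal of a comparator
#'
#' Decision rules, evaluated in order on a [flank_synteny_report()]:
#' \describe{
#'   \item{conserved_cluster}{cluster-ortholog fraction at least
#'     \code{cluster_frac_hi} with at least half of the orthologs
#'     inside the flank span;}
#'   \item{candidate_transfer}{cluster-ortholog fraction at least
#'     \code{cluster_frac_hi} but flank conservation below
#'     \code{flank_frac_lo} (the cluster travels without its
#'     neighborhood);}
#'   \item{lineage_specific}{flanks conserved (at least
#'     \code{flank_frac_hi}), cluster-ortholog fraction at most
#'     \code{cluster_frac_lo}, and an intervening gap no larger than
#'     \code{gap_max};}
#'   \item{rearranged}{flanks conserved but the gap undefined or above
#'     \code{gap_max}, with no cluster orthologs inside;}
#'   \item{unresolved}{anything else.}
#' }
#'
#' @param report A \code{synteny_report}.
#' @param thresholds See [origin_thresholds()].
#' @return The report with \code{origin_label} set.
#' @export
classify_origin <- function(report, thresholds = origin_thresholds()) {
  stopifnot(inherits(report, "synteny_report"))
  th <- thresholds
  frac <- report$cluster_orthologs_total / report$cluster_size
  fc <- report$flank_conserved
  gap <- report$intervening_gap_bp
  label <-
    if (!is.na(frac) && frac >= th$cluster_frac_hi &&
        report$cluster_orthologs_inside_gap >=
          report$cluster_orthologs_total / 2 &&
        report$cluster_orthologs_total > 0)
      "conserved_cluster"
    else if (!is.na(frac) && frac >= th$cluster_frac_hi &&
             !is.na(fc) && fc < th$flank_frac_lo)
      "candidate_transfer"
    else if (!is.na(fc) && fc >= th$flank_frac_hi &&
             frac <= th$cluster_frac_lo &&
             !is.na(gap) && gap <= th$gap_max)
      "lineage_specific"
    else if (!is.na(fc) && fc >= th$flank_frac_hi &&
             (is.na(gap) || gap > th$gap_max) &&
             report$cluster_orthologs_inside_gap == 0L)
      "rearranged"
    else "unresolved"
  report$origin_label <- label
  report
}

#' Scan a genome panel for co-located cluster homolog blocks
#'
#' For each panel genome, every cluster protein is searched against
#' the genome's proteome; a homolog is a hit scoring at least
#' \code{min_ratio} of the shorter sequence's self-score (and
#' \code{min_score}). A window of \code{window_genes} consecutive
#' genes slides along each scaffold; the co-located fraction is the
#' largest fraction of cluster genes with a homolog inside one
#' window. A cluster counts as detected when that fraction reaches
#' \code{min_fraction} and the window holds homologs of both backbone
#' classes (NRPS and PKS).
#'
#' @param cluster_proteins Named character vector of cluster protein
#'   sequences.
#' @param cluster_roles Named character vector of roles for the same
#'   genes (names matching \code{cluster_proteins}).
#' @param panel Named list; each element a list with
#'   \code{annotation} and \code{proteome}.
#' @param window_genes Window width in genes (default 2x cluster
#'   size).
#' @param min_fraction Detection threshold on the co-located fraction
#'   (default 0.5).
#' @param min_score,min_ratio Homolog score thresholds (as in
#'   [rbh_map()]).
#' @return data.frame, one row per panel genome: genome_id,
#'   homolog_fraction, colocated_fraction, detected.
#' @export
homolog_cluster_scan <- function(cluster_proteins, cluster_roles,
                                 panel,
                                 window_genes = NULL,
                                 min_fraction = 0.5,
                                 min_score = 40, min_ratio = 0.3) {
  stopifnot(length(cluster_proteins) >= 2,
            setequal(names(cluster_proteins), names(cluster_roles)))
  if (is.null(window_genes))
    window_genes <- 2L * length(cluster_proteins)
  if (window_genes < 2L) stop("window_genes must be >= 2")
  ids <- names(cluster_proteins)
  backbone <- list(
    nrps = ids[cluster_roles[ids] == "backbone_nrps"],
    pks = ids[cluster_roles[ids] == "backbone_pks"])
  rows <- lapply(names(panel), function(gid) {
    g <- panel[[gid]]
    ann <- as.data.frame(g$annotation)
    m <- score_matrix(cluster_proteins, g$proteome)
    thr <- pmax(min_score,
                min_ratio * 2 * pmin(nchar(cluster_proteins),
                                     matrix(nchar(g$proteome),
                                            nrow = length(ids),
                                            ncol = length(g$proteome),
                                            byrow = TRUE)))
    hit <- m >= thr
    has_homolog <- rowSums(hit) > 0
    best_frac <- 0
    best_detected <- FALSE
    for (scf in unique(ann$scaffold)) {
      gi <- which(ann$scaffold == scf)
      ord_ids <- ann$gene_id[gi]
      hits_here <- hit[, match(ord_ids, colnames(hit)), drop = FALSE]
      n <- length(gi)
      for (s in seq_len(max(1L, n - window_genes + 1L))) {
        w <- s:min(n, s + window_genes - 1L)
        in_w <- rowSums(hits_here[, w, drop = FALSE]) > 0
        frac <- mean(in_w)
        if (frac > best_frac) best_frac <- frac
        both <- any(in_w[backbone$nrps]) && any(in_w[backbone$pks])
        if (frac >= min_fraction && isTRUE(both)) best_detected <- TRUE
      }
    }
    data.frame(genome_id = gid,
               homolog_fraction = mean(has_homolog),
               colocated_fraction = best_frac,
               detected = best_detected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write synteny outputs
#'
#' @param reports List of \code{synteny_report}s.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_synteny_table <- function(reports, path) {
  if (inherits(reports, "synteny_report")) reports <- list(reports)
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(genome_id = r$genome_id,
               flank5_conserved = r$flank5_conserved,
               flank3_conserved = r$flank3_conserved,
               order_conserved = r$order_conserved,
               intervening_gap_bp = r$intervening_gap_bp,
               cluster_orthologs_total = r$cluster_orthologs_total,
               cluster_orthologs_inside_gap = r$cluster_orthologs_inside_gap,
               cluster_orthologs_dispersed = r$cluster_orthologs_dispersed,
               origin_label = r$origin_label,
               flags = paste(r$flags, collapse = ","),
               stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_synteny_table
#' @param ortho An \code{ortholog_map}.
#' @export
write_ortholog_pairs <- function(ortho, path) {
  utils::write.table(as.data.frame(ortho), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
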