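#' Gene role vocabulary
#'
#' Functional roles recognized for genes in and around a
#' secondary-metabolite biosynthetic gene cluster (BGC). The vocabulary
#' is open on input: unknown role strings are mapped to
#' \code{"hypothetical"} with a warning, because real clusters contain
#' genes annotated only as hypothetical proteins.
#'
#' @return Character vector of recognized role names.
#' @export
gene_roles <- function() {
  c("backbone_nrps", "backbone_pks", "tailoring", "regulator",
    "transport", "racemase", "aminotransferase", "cyclophilin",
    "hypothetical", "housekeeping")
}

#' Roles counted as cluster-associated by the rule-based predictors
#'
#' Everything except \code{housekeeping} and \code{hypothetical}:
#' backbone synthetases, tailoring enzymes (P450s, dehydrogenases and
#' the like), pathway-specific regulators, transporters, the racemase,
#' the aminotransferase and the cluster cyclophilin.
#'
#' @return Character vector, a subset of [gene_roles()].
#' @export
sm_roles_default <- function() {
  setdiff(gene_roles(), c("housekeeping", "hypothetical"))
}

backbone_roles <- function() c("backbone_nrps", "backbone_pks")

normalize_roles <- function(role) {
  role <- as.character(role)
  role[is.na(role) | role == ""] <- "housekeeping"
  bad <- !(role %in% gene_roles())
  if (any(bad)) {
    warning(sprintf("unknown role value(s) %s mapped to 'hypothetical'",
                    paste(sQuote(unique(role[bad])), collapse = ", ")),
            call. = FALSE)
    role[bad] <- "hypothetical"
  }
  role
}

#' Construct a genome annotation
#'
#' An ordered table of gene models on scaffolds. Coordinates follow the
#' GFF3 convention: 1-based, inclusive at both ends, always on the
#' forward axis regardless of strand. Strand never affects gene order
#' or intergenic gaps; genes are treated positionally.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{scaffold},
#'   \code{start}, \code{end}, \code{strand} (\code{"+"}/\code{"-"}) and
#'   \code{role} (see [gene_roles()]; missing column means all
#'   \code{"housekeeping"}).
#' @param genome_id Single string identifying the genome.
#' @return A \code{genome_annotation}: a data.frame sorted by
#'   (scaffold, start) with a derived \code{length_bp} column and a
#'   \code{genome_id} attribute.
#' @export
genome_annotation <- function(genes, genome_id = "genome") {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "scaffold", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0)
    stop("missing annotation column(s): ", paste(miss, collapse = ", "))
  if (!("role" %in% names(genes))) genes$role <- "housekeeping"
  genes <- genes[, c(need, "role")]
  genes$gene_id  <- as.character(genes$gene_id)
  genes$scaffold <- as.character(genes$scaffold)
  genes$start    <- as.integer(genes$start)
  genes$end      <- as.integer(genes$end)
  genes$strand   <- as.character(genes$strand)
  genes$role     <- normalize_roles(genes$role)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  if (any(genes$start > genes$end))
    stop("gene(s) with start > end: ",
         paste(genes$gene_id[genes$start > genes$end], collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  genes <- genes[order(genes$scaffold, genes$start, genes$end,
                       genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  genes$length_bp <- genes$end - genes$start + 1L
  structure(genes,
            genome_id = genome_id,
            class = c("genome_annotation", "data.frame"))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation '%s': %d genes on %d scaffold(s)\n",
              attr(x, "genome_id"), nrow(x),
              length(unique(x$scaffold))))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Genome identifier of an annotation
#' @param ann A [genome_annotation()].
#' @return Single string.
#' @export
genome_id <- function(ann) attr(ann, "genome_id")

#' Read gene models from a GFF3 file
#'
#' Features of type \code{gene} are read with \pkg{rtracklayer}; the
#' gene identifier comes from the \code{ID} attribute and the
#' functional role from the attribute named by \code{role_attr}
#' (default \code{"role"}); genes lacking it are treated as
#' \code{housekeeping}.
#'
#' @param path GFF3 file.
#' @param genome_id Genome identifier stored on the result; defaults to
#'   the file name without extension.
#' @param role_attr Attribute key carrying the role.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, genome_id = NULL, role_attr = "role") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stop(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated fields, found %d",
                 bad, path, nf[nf != 9L][1L]))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) stop("no gene features in ", path)
  md <- S4Vectors::mcols(gr)
  role <- if (role_attr %in% names(md)) as.character(md[[role_attr]])
          else rep("housekeeping", length(gr))
  ids <- as.character(md$ID)
  if (any(is.na(ids)) || any(!nzchar(ids)))
    stop("gene feature without ID attribute in ", path)
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  genome_annotation(data.frame(
    gene_id  = ids,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start    = GenomicRanges::start(gr),
    end      = GenomicRanges::end(gr),
    strand   = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                      "-", "+"),
    role     = role,
    stringsAsFactors = FALSE
  ), genome_id = genome_id)
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_annotation()]: IDs, coordinates, strand and role
#' survive a write/read round trip.
#'
#' @param ann A [genome_annotation()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  gr <- GenomicRanges::GRanges(
    seqnames = ann$scaffold,
    ranges   = IRanges::IRanges(start = ann$start, end = ann$end),
    strand   = ann$strand)
  S4Vectors::mcols(gr)$type   <- "gene"
  S4Vectors::mcols(gr)$source <- "bgcdelim"
  S4Vectors::mcols(gr)$ID     <- ann$gene_id
  S4Vectors::mcols(gr)$role   <- ann$role
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Intergenic gap between two genes
#'
#' Number of base pairs strictly between two gene bodies on the same
#' scaffold: \code{max(0, start(b) - end(a) - 1)}. Adjacent or
#' overlapping genes have gap 0. This is the "intervening sequence"
#' convention used throughout the synteny analysis.
#'
#' @param a,b Single annotation rows (data.frame or list with
#'   \code{scaffold}, \code{start}, \code{end}); \code{a} must not
#'   start after \code{b}.
#' @return Integer gap in bp.
#' @export
intergenic_gap <- function(a, b) {
  if (as.character(a$scaffold) != as.character(b$scaffold))
    stop("intergenic gap undefined across scaffolds ('",
         a$scaffold, "' vs '", b$scaffold, "')")
  if (a$start > b$start)
    stop("'a' must not start after 'b'")
  max(0L, as.integer(b$start) - as.integer(a$end) - 1L)
}

#' Flanking genes of a focal gene
#'
#' Up to \code{n} genes on each side of \code{gene_id} on its own
#' scaffold, in annotation order, truncated at scaffold ends.
#'
#' @param ann A [genome_annotation()].
#' @param gene_id Focal gene.
#' @param n Maximum genes per side (>= 0).
#' @return List with data.frames \code{upstream} (5', annotation order)
#'   and \code{downstream} (3').
#' @export
neighbor_window <- function(ann, gene_id, n) {
  stopifnot(inherits(ann, "genome_annotation"), n >= 0)
  i <- match(gene_id, ann$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", gene_id)
  scf <- ann$scaffold[i]
  idx <- which(ann$scaffold == scf)
  pos <- match(i, idx)
  up   <- idx[seq_len(pos - 1L)]
  up   <- utils::tail(up, n)
  down <- idx[pos + seq_len(length(idx) - pos)]
  down <- utils::head(down, n)
  list(upstream   = as.data.frame(ann)[up, , drop = FALSE],
       downstream = as.data.frame(ann)[down, , drop = FALSE])
}

#' Construct a counts container
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param meta data.frame with columns \code{sample_id},
#'   \code{condition} (\code{"control"}/\code{"treatment"}),
#'   \code{timepoint} (integer index), \code{replicate}; one row per
#'   column of \code{counts}, \code{(condition, timepoint, replicate)}
#'   unique.
#' @return A \code{counts_matrix} (list with \code{counts},
#'   \code{meta}).
#' @export
counts_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count for gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"
  meta <- as.data.frame(meta)
  need <- c("sample_id", "condition", "timepoint", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0)
    stop("missing metadata column(s): ", paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$condition <- as.character(meta$condition)
  meta$timepoint <- as.integer(meta$timepoint)
  meta$replicate <- as.integer(meta$replicate)
  if (!all(meta$condition %in% c("control", "treatment")))
    stop("condition must be 'control' or 'treatment'")
  if (anyDuplicated(meta[, c("condition", "timepoint", "replicate")]))
    stop("(condition, timepoint, replicate) must be unique")
  if (!setequal(colnames(counts), meta$sample_id))
    stop("sample ids in counts and metadata differ: ",
         paste(union(setdiff(colnames(counts), meta$sample_id),
                     setdiff(meta$sample_id, colnames(counts))),
               collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("counts_matrix: %d genes x %d samples (%d timepoints, conditions: %s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$timepoint)),
              paste(sort(unique(x$meta$condition)), collapse = "/")))
  invisible(x)
}

#' Read a counts matrix and its sample metadata
#'
#' @param path Tab-separated counts file: first column \code{gene_id},
#'   remaining columns one per sample, header row of sample ids.
#' @param meta data.frame of sample metadata (see [counts_matrix()]) or
#'   path to a tab-separated metadata file with those columns.
#' @return A [counts_matrix()]. Row and column order of the file are
#'   preserved.
#' @export
read_counts <- function(path, meta) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (is.character(meta)) meta <- read_sample_meta(meta)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("counts file needs gene_id plus >=1 sample")
  gene_ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cell in ", path)
  rownames(m) <- gene_ids
  counts_matrix(m, meta)
}

#' @rdname read_counts
#' @param cm A [counts_matrix()] to write.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "counts_matrix"))
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#' @param path Tab-separated file with columns \code{sample_id},
#'   \code{condition}, \code{timepoint}, \code{replicate}.
#' @return data.frame of sample metadata.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_sample_meta
#' @param meta Metadata data.frame to write.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a proteome as FASTA
#'
#' Proteomes are named character vectors of uppercase amino-acid
#' sequences; names are gene ids matching the annotation.
#'
#' @param path FASTA file.
#' @return Named character vector of protein sequences.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("proteome file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  if (any(!nzchar(seqs))) stop("empty protein sequence in ", path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate protein id in ", path)
  seqs
}

#' @rdname read_proteome
#' @param proteome Named character vector of sequences to write.
#' @export
write_proteome <- function(proteome, path) {
  stopifnot(is.character(proteome), !is.null(names(proteome)))
  aa <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
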