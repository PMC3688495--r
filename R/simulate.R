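AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# one RNG sub-stream per artifact, derived from the base seed and a fixed
# label so adding an output never perturbs earlier ones
derive_seed <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults emulate the expression regime of a cyclosporin-type NRPS
#' cluster induced in production medium: accessory genes (PKS, P450,
#' racemase, aminotransferase, dehydrogenase) with very low constitutive
#' expression and ~9 log2-fold induction, backbone synthetases in the
#' 5--9 log2-fold class, and a cyclophilin-like gene with a high
#' constitutive baseline and a 3.18 log2-fold increase. Induction is a
#' step function switching on at timepoint \code{induction_start}
#' (default 3, the mid-series onset) in the treatment condition only.
#'
#' @param seed Integer base seed; every artifact derives its own RNG
#'   sub-stream from it.
#' @param n_timepoints,n_replicates Time-course layout (defaults 6 and
#'   3, i.e. 3 vs 3 at each of six timepoints).
#' @param baseline_means Named positive vector of control-condition NB
#'   means per expression class (\code{backbone}, \code{accessory},
#'   \code{cyclophilin}, \code{housekeeping}).
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param library_size_factors Optional positive vector, one per sample
#'   (2 * n_timepoints * n_replicates); default all 1.
#' @param induced_lfc Named vector of log2 fold changes applied to
#'   cluster genes in treatment at t >= induction_start.
#' @param induction_start Timepoint index at which induction begins.
#' @param cluster_size Number of genes in the planted cluster (>= 2).
#' @param flank_size Conserved housekeeping genes on each side of the
#'   cluster (default 10).
#' @param n_background Housekeeping genes on a second scaffold (genome
#'   background; also hosts dispersed homolog copies in comparators).
#' @param n_constitutive Number of non-backbone cluster genes given a
#'   high constitutive baseline and no induction (emulating
#'   constitutively expressed cluster members); default 0.
#' @param constitutive_baseline Control mean for those genes.
#' @param protein_length_range Min/max simulated protein length (aa).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       n_timepoints = 6L,
                       n_replicates = 3L,
                       baseline_means = c(backbone = 5, accessory = 5,
                                          cyclophilin = 200,
                                          housekeeping = 100),
                       dispersion = 0.1,
                       library_size_factors = NULL,
                       induced_lfc = c(accessory = 9, backbone = 5,
                                       cyclophilin = 3.18),
                       induction_start = 3L,
                       cluster_size = 12L,
                       flank_size = 10L,
                       n_background = 15L,
                       n_constitutive = 0L,
                       constitutive_baseline = 150,
                       protein_length_range = c(80L, 160L)) {
  stopifnot(n_timepoints >= 2, n_replicates >= 2, dispersion > 0,
            induction_start >= 1, induction_start <= n_timepoints,
            all(baseline_means > 0), constitutive_baseline > 0,
            cluster_size >= 2, flank_size >= 0, n_background >= 0,
            n_constitutive >= 0, n_constitutive <= cluster_size - 2,
            length(protein_length_range) == 2,
            protein_length_range[1] >= 10)
  need <- c("backbone", "accessory", "cyclophilin", "housekeeping")
  stopifnot(all(need %in% names(baseline_means)))
  stopifnot(all(c("accessory", "backbone", "cyclophilin") %in%
                  names(induced_lfc)))
  n_samples <- 2L * n_timepoints * n_replicates
  if (is.null(library_size_factors))
    library_size_factors <- rep(1, n_samples)
  stopifnot(length(library_size_factors) == n_samples,
            all(library_size_factors > 0))
  structure(list(seed = as.integer(seed),
                 n_timepoints = as.integer(n_timepoints),
                 n_replicates = as.integer(n_replicates),
                 baseline_means = baseline_means,
                 dispersion = dispersion,
                 library_size_factors = library_size_factors,
                 induced_lfc = induced_lfc,
                 induction_start = as.integer(induction_start),
                 cluster_size = as.integer(cluster_size),
                 flank_size = as.integer(flank_size),
                 n_background = as.integer(n_background),
                 n_constitutive = as.integer(n_constitutive),
                 constitutive_baseline = constitutive_baseline,
                 protein_length_range = as.integer(protein_length_range)),
            class = "sim_config")
}

#' Comparator genome scenario
#'
#' @param label One of \code{"lineage_specific"} (syntenic flanks, no
#'   cluster at the locus, a few cluster homologs dispersed elsewhere,
#'   a small flank-to-flank gap), \code{"conserved_cluster"} (cluster
#'   orthologs in order between syntenic flanks), \code{"inversion"}
#'   (3' flank block inverted with inserted sequence at the junction,
#'   no cluster orthologs) or \code{"hgt_candidate"} (full cluster
#'   ortholog block with non-syntenic flanks).
#' @param genome_id Identifier for the comparator (defaults to label).
#' @param intervening_gap_bp Planted flank-to-flank gap for
#'   \code{lineage_specific} (default 3000, below the 5 kb
#'   classification threshold).
#' @param divergence Per-site substitution probability applied to
#'   ortholog protein sequences (default 0.1).
#' @param n_dispersed Cluster genes given dispersed homolog copies in
#'   \code{lineage_specific} comparators.
#' @param extra_insert_bp Sequence inserted at the rearranged junction
#'   for \code{inversion} (default 480000, emulating a large
#'   inversion-borne insertion).
#' @return A \code{scenario_spec} list with derived consistency flags.
#' @export
scenario_spec <- function(label = c("lineage_specific", "conserved_cluster",
                                    "inversion", "hgt_candidate"),
                          genome_id = NULL,
                          intervening_gap_bp = 3000L,
                          divergence = 0.1,
                          n_dispersed = 2L,
                          extra_insert_bp = NULL) {
  label <- match.arg(label)
  if (intervening_gap_bp < 0) stop("intervening_gap_bp must be >= 0")
  stopifnot(divergence >= 0, divergence <= 1, n_dispersed >= 0)
  if (is.null(extra_insert_bp))
    extra_insert_bp <- if (label == "inversion") 480000L else 0L
  if (is.null(genome_id)) genome_id <- label
  structure(list(label = label,
                 genome_id = genome_id,
                 cluster_present = label %in% c("conserved_cluster",
                                                "hgt_candidate"),
                 flanks_syntenic = label != "hgt_candidate",
                 inversion_applied = label == "inversion",
                 intervening_gap_bp = as.integer(intervening_gap_bp),
                 divergence = divergence,
                 n_dispersed = as.integer(n_dispersed),
                 extra_insert_bp = as.integer(extra_insert_bp)),
            class = "scenario_spec")
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

#' Mutate a protein sequence
#'
#' Substitutes each site independently with probability
#' \code{divergence}, always to a residue different from the original;
#' length is preserved. Uses the current RNG state.
#'
#' @param seq Uppercase amino-acid string.
#' @param divergence Per-site substitution probability in [0, 1].
#' @return Mutated sequence.
#' @export
mutate_protein <- function(seq, divergence) {
  stopifnot(divergence >= 0, divergence <= 1)
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < divergence
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(a) {
      sample(setdiff(AA20, a), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(ch, collapse = "")
}

# cluster role layout: backbone NRPS at the 5' end (the expression
# boundary starts at the backbone), then the accessory vocabulary
cluster_role_layout <- function(cluster_size) {
  acc <- c("cyclophilin", "backbone_pks", "racemase", "tailoring",
           "aminotransferase", "tailoring", "regulator", "tailoring",
           "transport", "regulator", "tailoring")
  roles <- c("backbone_nrps",
             rep(acc, length.out = cluster_size - 1L))
  # keep exactly one cyclophilin and one PKS however large the cluster
  dup <- duplicated(roles) & roles %in% c("cyclophilin", "backbone_pks")
  roles[dup] <- "tailoring"
  roles
}

lfc_class_of <- function(roles) {
  ifelse(roles %in% c("backbone_nrps", "backbone_pks"), "backbone",
         ifelse(roles == "cyclophilin", "cyclophilin", "accessory"))
}

# lay genes along a scaffold; lengths in bp, returns start/end vectors
lay_genes <- function(lengths_bp, gaps_bp, offset = 1L) {
  n <- length(lengths_bp)
  start <- integer(n); end <- integer(n)
  pos <- as.integer(offset)
  for (i in seq_len(n)) {
    start[i] <- pos
    end[i] <- pos + lengths_bp[i] - 1L
    pos <- end[i] + gaps_bp[i] + 1L
  }
  list(start = start, end = end)
}

build_gene_table <- function(ids, scaffold, roles, prot_len, gaps,
                             offset = 1L, strands = NULL) {
  lens <- 3L * prot_len + 3L
  xy <- lay_genes(lens, gaps, offset)
  if (is.null(strands))
    strands <- sample(c("+", "-"), length(ids), replace = TRUE)
  data.frame(gene_id = ids, scaffold = scaffold,
             start = xy$start, end = xy$end,
             strand = strands, role = roles,
             stringsAsFactors = FALSE)
}

#' Simulate a focal genome and comparator genomes
#'
#' Builds a focal genome whose first scaffold carries
#' \code{flank_size} conserved housekeeping genes, a planted contiguous
#' cluster (one backbone NRPS at its 5' end plus accessory roles), and
#' \code{flank_size} more housekeeping genes; a second scaffold holds
#' background housekeeping genes. Each comparator realizes its
#' [scenario_spec()]: ortholog proteins are mutated copies of the focal
#' proteins, everything else is unrelated random sequence.
#'
#' @param cfg A [sim_config()].
#' @param scenarios List of [scenario_spec()] (or a single one).
#' @return List with \code{focal} (list of \code{annotation},
#'   \code{proteome}), \code{comparators} (named list of
#'   \code{annotation}, \code{proteome}, \code{scenario}), and
#'   \code{truth} (planted boundaries, ortholog pairs, gaps,
#'   expression classes).
#' @export
simulate_scenario <- function(cfg, scenarios = list()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  if (!all(vapply(scenarios, inherits, logical(1), "scenario_spec")))
    stop("scenarios must be scenario_spec objects")
  gids <- vapply(scenarios, `[[`, character(1), "genome_id")
  if (anyDuplicated(gids)) stop("duplicate comparator genome_id")

  set.seed(derive_seed(cfg$seed, "focal"))
  k  <- cfg$cluster_size
  fl <- cfg$flank_size
  nb <- cfg$n_background
  plr <- cfg$protein_length_range

  roles1 <- c(rep("housekeeping", fl), cluster_role_layout(k),
              rep("housekeeping", fl))
  n1 <- length(roles1)
  ids1 <- sprintf("FG%04d", seq_len(n1))
  len1 <- sample(plr[1]:plr[2], n1, replace = TRUE)
  gap1 <- sample(200:1500, n1, replace = TRUE)
  tab1 <- build_gene_table(ids1, "scaffold_1", roles1, len1, gap1)

  ids2 <- sprintf("FG%04d", n1 + seq_len(nb))
  len2 <- sample(plr[1]:plr[2], max(nb, 1L), replace = TRUE)[seq_len(nb)]
  gap2 <- sample(200:1500, max(nb, 1L), replace = TRUE)[seq_len(nb)]
  tab2 <- if (nb > 0)
    build_gene_table(ids2, "scaffold_2", rep("housekeeping", nb),
                     len2, gap2)
  else tab1[0, ]

  tab <- rbind(tab1, tab2)
  prot_len <- c(len1, len2)
  proteome <- vapply(prot_len, random_protein, character(1))
  names(proteome) <- tab$gene_id
  focal_ann <- genome_annotation(tab, genome_id = "focal")

  cl_idx <- fl + seq_len(k)
  cluster_ids <- ids1[cl_idx]
  cluster_roles <- roles1[cl_idx]
  classes <- lfc_class_of(cluster_roles)
  names(classes) <- cluster_ids
  if (cfg$n_constitutive > 0) {
    eligible <- which(!(cluster_roles %in%
                          c("backbone_nrps", "backbone_pks", "cyclophilin")))
    # spread constitutive genes out so they are never adjacent
    pick <- eligible[round(seq(1, length(eligible),
                               length.out = cfg$n_constitutive))]
    classes[pick] <- "constitutive"
  }

  truth <- list(
    focal = list(
      genome_id    = "focal",
      cluster_ids  = cluster_ids,
      backbone_id  = cluster_ids[1L],
      cluster_start_bp = min(tab1$start[cl_idx]),
      cluster_end_bp   = max(tab1$end[cl_idx]),
      flank5_ids   = ids1[seq_len(fl)],
      flank3_ids   = ids1[fl + k + seq_len(fl)],
      gene_classes = classes
    ),
    comparators = list()
  )

  comparators <- list()
  for (sc in scenarios) {
    set.seed(derive_seed(cfg$seed, paste0("comparator:", sc$genome_id)))
    comp <- build_comparator(cfg, sc, focal_ann, proteome, truth$focal)
    comparators[[sc$genome_id]] <- comp$genome
    truth$comparators[[sc$genome_id]] <- comp$truth
  }

  structure(list(focal = list(annotation = focal_ann,
                              proteome  = proteome),
                 comparators = comparators,
                 truth = truth),
            class = "bgc_simulation")
}

# realize one comparator genome for a scenario
build_comparator <- function(cfg, sc, focal_ann, focal_prot, ft) {
  plr <- cfg$protein_length_range
  gid <- sc$genome_id
  next_id <- local({ i <- 0L; function() { i <<- i + 1L
    sprintf("%s_g%03d", gid, i) } })

  blocks <- list()   # each: ids, roles, prot, focal (orthology), gaps
  new_block <- function(focal_ids = NULL, n_novel = 0L, reverse = FALSE) {
    if (!is.null(focal_ids)) {
      if (reverse) focal_ids <- rev(focal_ids)
      ids <- vapply(focal_ids, function(x) next_id(), character(1),
                    USE.NAMES = FALSE)
      prot <- vapply(focal_prot[focal_ids], mutate_protein,
                     character(1), divergence = sc$divergence,
                     USE.NAMES = FALSE)
      roles <- focal_ann$role[match(focal_ids, focal_ann$gene_id)]
      list(ids = ids, roles = roles, prot = prot, focal = focal_ids)
    } else {
      ids <- vapply(seq_len(n_novel), function(x) next_id(),
                    character(1))
      prot <- vapply(sample(plr[1]:plr[2], n_novel, replace = TRUE),
                     random_protein, character(1))
      list(ids = ids, roles = rep("housekeeping", n_novel),
           prot = prot, focal = rep(NA_character_, n_novel))
    }
  }

  if (sc$flanks_syntenic) {
    blocks$f5 <- new_block(ft$flank5_ids)
    if (sc$label == "conserved_cluster")
      blocks$cl <- new_block(ft$cluster_ids)
    if (sc$label == "inversion" && sc$extra_insert_bp > 0)
      blocks$ins <- new_block(n_novel = 3L)
    blocks$f3 <- new_block(ft$flank3_ids,
                           reverse = sc$inversion_applied)
  } else {
    blocks$f5 <- new_block(n_novel = cfg$flank_size)
    blocks$cl <- new_block(ft$cluster_ids)
    blocks$f3 <- new_block(n_novel = cfg$flank_size)
  }

  ids   <- unlist(lapply(blocks, `[[`, "ids"),  use.names = FALSE)
  roles <- unlist(lapply(blocks, `[[`, "roles"), use.names = FALSE)
  prot  <- unlist(lapply(blocks, `[[`, "prot"), use.names = FALSE)
  fsrc  <- unlist(lapply(blocks, `[[`, "focal"), use.names = FALSE)
  n <- length(ids)
  gaps <- sample(200:1500, n, replace = TRUE)

  # plant the controlled junction gap after the innermost 5'-flank gene
  j5 <- length(blocks$f5$ids)           # innermost 5' flank position
  planted_gap <- NA_integer_
  if (sc$label == "lineage_specific") {
    gaps[j5] <- sc$intervening_gap_bp
    planted_gap <- sc$intervening_gap_bp
  } else if (sc$label == "inversion") {
    # insert sits between the 5' flank and the novel genes at the
    # junction; the measured flank-to-flank gap also spans those genes
    gaps[j5] <- sc$extra_insert_bp
  }
  prot_len <- nchar(prot)
  tab1 <- build_gene_table(ids, "scaffold_1", roles, prot_len, gaps)

  # background scaffold; lineage-specific comparators scatter a few
  # cluster-gene homologs among the background genes
  disp_src <- character(0)
  if (sc$label == "lineage_specific" && sc$n_dispersed > 0) {
    disp_src <- ft$cluster_ids[-1L]     # never the backbone
    disp_src <- disp_src[round(seq(1, length(disp_src),
                                   length.out = min(sc$n_dispersed,
                                                    length(disp_src))))]
  }
  nb <- cfg$n_background
  ids2 <- character(0); prot2 <- character(0)
  fsrc2 <- character(0)
  if (nb + length(disp_src) > 0) {
    slots <- nb + length(disp_src)
    disp_at <- if (length(disp_src) > 0)
      round(seq(2, slots - 1, length.out = length(disp_src)))
    else integer(0)
    di <- 0L
    for (s in seq_len(slots)) {
      if (s %in% disp_at) {
        di <- di + 1L
        src <- disp_src[di]
        ids2  <- c(ids2, next_id())
        prot2 <- c(prot2, mutate_protein(focal_prot[[src]],
                                         sc$divergence))
        fsrc2 <- c(fsrc2, src)
      } else {
        ids2  <- c(ids2, next_id())
        prot2 <- c(prot2, random_protein(sample(plr[1]:plr[2], 1L)))
        fsrc2 <- c(fsrc2, NA_character_)
      }
    }
    tab2 <- build_gene_table(ids2, "scaffold_2",
                             rep("housekeeping", slots), nchar(prot2),
                             sample(200:1500, slots, replace = TRUE))
  } else tab2 <- tab1[0, ]

  tab <- rbind(tab1, tab2)
  proteome <- c(prot, prot2)
  names(proteome) <- tab$gene_id
  ann <- genome_annotation(tab, genome_id = gid)

  pairs <- data.frame(focal_id = c(fsrc, fsrc2),
                      other_id = c(ids, ids2),
                      stringsAsFactors = FALSE)
  pairs <- pairs[!is.na(pairs$focal_id), , drop = FALSE]
  rownames(pairs) <- NULL

  list(genome = list(annotation = ann, proteome = proteome,
                     scenario = sc),
       truth = list(label = sc$label,
                    ortholog_pairs = pairs,
                    planted_gap_bp = planted_gap,
                    dispersed_focal_ids = disp_src))
}

#' Simulate NB time-course counts for a genome
#'
#' Counts are drawn as \code{NB(mean = s_j * mu_g(condition, t),
#' size = 1/phi)} so that variance = mu + phi mu^2. Cluster genes in
#' the treatment condition at \code{t >= induction_start} have mean
#' \code{mu0 * 2^lfc} for their expression class; all other cells sit
#' at the class baseline. Housekeeping genes are never induced.
#'
#' @param cfg A [sim_config()].
#' @param ann The focal [genome_annotation()].
#' @param truth Truth record from [simulate_scenario()] (its
#'   \code{$truth} element), identifying cluster genes and classes.
#' @return A [counts_matrix()].
#' @export
simulate_counts <- function(cfg, ann, truth) {
  stopifnot(inherits(cfg, "sim_config"),
            inherits(ann, "genome_annotation"))
  ft <- if (!is.null(truth$focal)) truth$focal else truth
  classes <- ft$gene_classes
  stopifnot(all(names(classes) %in% ann$gene_id))

  set.seed(derive_seed(cfg$seed, "counts"))
  T <- cfg$n_timepoints; R <- cfg$n_replicates
  meta <- expand.grid(replicate = seq_len(R), timepoint = seq_len(T),
                      condition = c("control", "treatment"),
                      stringsAsFactors = FALSE)
  meta <- meta[, c("condition", "timepoint", "replicate")]
  meta$sample_id <- sprintf("%s_t%d_r%d",
                            ifelse(meta$condition == "control", "ctl", "trt"),
                            meta$timepoint, meta$replicate)
  sf <- cfg$library_size_factors

  base_of <- function(gene_id) {
    cls <- classes[gene_id]
    if (is.na(cls)) return(unname(cfg$baseline_means["housekeeping"]))
    if (cls == "constitutive") return(cfg$constitutive_baseline)
    unname(cfg$baseline_means[cls])
  }
  lfc_of <- function(gene_id) {
    cls <- classes[gene_id]
    if (is.na(cls) || cls == "constitutive") return(0)
    unname(cfg$induced_lfc[cls])
  }

  genes <- ann$gene_id
  mu0 <- vapply(genes, base_of, numeric(1))
  lfc <- vapply(genes, lfc_of, numeric(1))
  induced_col <- meta$condition == "treatment" &
    meta$timepoint >= cfg$induction_start

  counts <- matrix(0L, nrow = length(genes), ncol = nrow(meta),
                   dimnames = list(genes, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    mu <- mu0 * (if (induced_col[j]) 2^lfc else 1) * sf[j]
    counts[, j] <- stats::rnbinom(length(genes), mu = mu,
                                  size = 1 / cfg$dispersion)
  }
  counts_matrix(counts, meta[, c("sample_id", "condition",
                                 "timepoint", "replicate")])
}

#' Write a simulation to disk
#'
#' Writes GFF3 + FASTA for the focal genome and every comparator, the
#' counts and sample-metadata TSVs, and a truth JSON (planted
#' boundaries, ortholog pairs, gaps).
#'
#' @param sim Result of [simulate_scenario()].
#' @param cm Optional [counts_matrix()] from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, cm = NULL, dir) {
  stopifnot(inherits(sim, "bgc_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotation(sim$focal$annotation, file.path(dir, "focal.gff3"))
  write_proteome(sim$focal$proteome, file.path(dir, "focal.faa"))
  for (gid in names(sim$comparators)) {
    g <- sim$comparators[[gid]]
    write_annotation(g$annotation, file.path(dir, paste0(gid, ".gff3")))
    write_proteome(g$proteome, file.path(dir, paste0(gid, ".faa")))
  }
  if (!is.null(cm)) {
    write_counts(cm, file.path(dir, "counts.tsv"))
    write_sample_meta(cm$meta, file.path(dir, "samples.tsv"))
  }
  truth <- sim$truth
  truth$focal$gene_classes <- as.list(truth$focal$gene_classes)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
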