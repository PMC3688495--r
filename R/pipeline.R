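#' Pipeline configuration
#'
#' In synthetic mode the inputs are generated by [simulate_scenario()]
#' and [simulate_counts()]; in file mode they are read from the given
#' paths (all checked before any stage runs).
#'
#' @param mode \code{"synthetic"} or \code{"files"}.
#' @param sim A [sim_config()] (synthetic mode).
#' @param scenarios List of [scenario_spec()]s (synthetic mode);
#'   default: one of each scripted scenario.
#' @param annotation_path,proteome_path,counts_path,meta_path File-mode
#'   inputs for the focal genome.
#' @param comparators File mode: named list, each element a list with
#'   \code{annotation_path} and \code{proteome_path}.
#' @param backbone_id File mode: backbone gene id to delineate around
#'   (synthetic mode takes it from the truth record).
#' @param presets Rule-based predictor parameterizations
#'   ([rule_presets()]).
#' @param alpha Significance thresholds for DE flags.
#' @param boundary List: \code{alpha}, \code{min_timepoints},
#'   \code{gap_tolerance} for [call_expression_cluster()].
#' @param synteny List: \code{flank_n}, \code{min_score},
#'   \code{min_ratio}, \code{thresholds} ([origin_thresholds()]).
#' @param seed Integer seed recorded in every output (synthetic mode
#'   overrides the sim config's seed with this one).
#' @return A \code{pipeline_config}.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            sim = sim_config(),
                            scenarios = NULL,
                            annotation_path = NULL,
                            proteome_path = NULL,
                            counts_path = NULL,
                            meta_path = NULL,
                            comparators = list(),
                            backbone_id = NULL,
                            presets = rule_presets(),
                            alpha = c(0.01, 0.001, 0.05),
                            boundary = list(alpha = 0.001,
                                            min_timepoints = 1L,
                                            gap_tolerance = 1L),
                            synteny = list(flank_n = 10L,
                                           min_score = 40,
                                           min_ratio = 0.3,
                                           thresholds = origin_thresholds()),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    sim$seed <- as.integer(seed)
    if (is.null(scenarios))
      scenarios <- list(scenario_spec("lineage_specific"),
                        scenario_spec("conserved_cluster"),
                        scenario_spec("inversion"))
  } else {
    paths <- c(annotation = annotation_path, proteome = proteome_path,
               counts = counts_path, meta = meta_path)
    miss <- setdiff(c("annotation", "proteome", "counts", "meta"),
                    names(paths))
    if (length(miss) > 0)
      stop("file mode requires path(s): ",
           paste(paste0(miss, "_path"), collapse = ", "))
    for (nm in names(paths))
      if (!file.exists(paths[[nm]]))
        stop("input file for '", nm, "' not found: ", paths[[nm]])
    for (gid in names(comparators))
      for (p in unlist(comparators[[gid]]))
        if (!file.exists(p))
          stop("comparator '", gid, "' file not found: ", p)
    if (is.null(backbone_id))
      stop("file mode requires backbone_id")
  }
  structure(list(mode = mode, sim = sim, scenarios = scenarios,
                 annotation_path = annotation_path,
                 proteome_path = proteome_path,
                 counts_path = counts_path, meta_path = meta_path,
                 comparators = comparators, backbone_id = backbone_id,
                 presets = presets, alpha = alpha, boundary = boundary,
                 synteny = synteny, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  log[[length(log) + 1L]] <- list(stage = name, rows = if (is.data.frame(res))
    nrow(res) else length(res))
  list(res = res, log = log)
}

#' Run the full delineation pipeline
#'
#' Simulates (or reads) the inputs, predicts clusters with both rule
#' presets, runs the per-timepoint NB differential expression,
#' delineates the expression cluster, reports three-way boundary
#' concordance, and for each comparator genome computes the RBH
#' ortholog map, the flank-synteny report and the origin
#' classification.
#'
#' @param cfg A [pipeline_config()].
#' @return A \code{bgc_report} bundle: config hash and seed, cluster
#'   calls, DE summary, concordance, per-comparator synteny reports,
#'   and the stage log. In synthetic mode it also carries the truth
#'   record.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- list()
  truth <- NULL
  if (cfg$mode == "synthetic") {
    sim <- simulate_scenario(cfg$sim, cfg$scenarios)
    ann <- sim$focal$annotation
    prot <- sim$focal$proteome
    comps <- sim$comparators
    truth <- sim$truth
    backbone_id <- truth$focal$backbone_id
    cm <- simulate_counts(cfg$sim, ann, truth)
    log[[length(log) + 1L]] <- list(stage = "simulate",
                                    rows = nrow(ann))
  } else {
    ann <- read_annotation(cfg$annotation_path)
    prot <- read_proteome(cfg$proteome_path)
    cm <- read_counts(cfg$counts_path, cfg$meta_path)
    comps <- lapply(cfg$comparators, function(x)
      list(annotation = read_annotation(x$annotation_path),
           proteome = read_proteome(x$proteome_path)))
    backbone_id <- cfg$backbone_id
    log[[length(log) + 1L]] <- list(stage = "read_inputs",
                                    rows = nrow(ann))
  }

  calls <- list()
  for (nm in names(cfg$presets)) {
    st <- run_stage(paste0("predict_", nm), log,
                    predict_clusters(ann, cfg$presets[[nm]], method = nm))
    log <- st$log
    found <- st$res
    # keep the call containing the focal backbone
    keep <- Filter(function(x) backbone_id %in% x$gene_ids, found)
    if (length(keep) == 0L)
      stop(sprintf("stage 'predict_%s' failed: no call contains backbone %s",
                   nm, backbone_id), call. = FALSE)
    calls[[nm]] <- keep[[1L]]
  }

  st <- run_stage("diffexpr", log,
                  run_timecourse_de(cm, ann, alpha = cfg$alpha))
  log <- st$log; de <- st$res

  st <- run_stage("delineate", log,
                  call_expression_cluster(ann, de, backbone_id,
                                          alpha = cfg$boundary$alpha,
                                          min_timepoints = cfg$boundary$min_timepoints,
                                          gap_tolerance = cfg$boundary$gap_tolerance))
  log <- st$log; calls$expression <- st$res

  st <- run_stage("concordance", log, compare_calls(calls))
  log <- st$log; conc <- st$res

  syn <- list(); orthos <- list()
  for (gid in names(comps)) {
    g <- comps[[gid]]
    st <- run_stage(paste0("rbh_", gid), log,
                    rbh_map(prot, g$proteome,
                            min_score = cfg$synteny$min_score,
                            min_ratio = cfg$synteny$min_ratio))
    log <- st$log; orthos[[gid]] <- st$res
    st <- run_stage(paste0("synteny_", gid), log, {
      r <- flank_synteny_report(ann, calls$expression, orthos[[gid]],
                                g$annotation,
                                flank_n = cfg$synteny$flank_n)
      classify_origin(r, cfg$synteny$thresholds)
    })
    log <- st$log; syn[[gid]] <- st$res
  }

  cfg_hash <- digest::digest(cfg, algo = "sha256")
  structure(list(
    provenance = list(package = "bgcdelim",
                      version = as.character(utils::packageVersion("bgcdelim")),
                      seed = cfg$seed, config_hash = cfg_hash,
                      schema = "bgc_report/1"),
    calls = calls,
    concordance = conc,
    de = de,
    synteny = syn,
    ortholog_maps = orthos,
    truth = truth,
    stages = log), class = "bgc_report")
}

#' @export
print.bgc_report <- function(x, ...) {
  cat(sprintf("bgc_report (seed %d, %d stages)\n",
              x$provenance$seed, length(x$stages)))
  for (nm in names(x$calls)) print(x$calls[[nm]])
  for (nm in names(x$synteny)) print(x$synteny[[nm]])
  invisible(x)
}

report_to_list <- function(bundle) {
  list(
    provenance = bundle$provenance,
    calls = lapply(bundle$calls, unclass),
    concordance = list(pairs = bundle$concordance$pairs,
                       calls = bundle$concordance$calls),
    de = list(alpha = bundle$de$alpha, params = bundle$de$params,
              n_tests = nrow(bundle$de$table)),
    synteny = lapply(bundle$synteny, unclass),
    stages = bundle$stages)
}

#' Write a consolidated report bundle
#'
#' Writes \code{report.json} (schema-versioned, with a provenance
#' block carrying the config hash, seed and package version), the DE
#' table and per-comparator synteny summary as TSV, ortholog pairs as
#' two-column TSV, and all cluster calls as BED. Output is
#' deterministic: re-serializing the same bundle yields identical
#' bytes.
#'
#' @param bundle A \code{bgc_report} from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "bgc_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(bundle),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  write_de_table(bundle$de, file.path(dir, "de_results.tsv"))
  if (length(bundle$synteny) > 0)
    write_synteny_table(bundle$synteny,
                        file.path(dir, "synteny_summary.tsv"))
  for (gid in names(bundle$ortholog_maps))
    write_ortholog_pairs(bundle$ortholog_maps[[gid]],
                         file.path(dir, paste0("orthologs_", gid,
                                               ".tsv")))
  calls_to_bed(unname(bundle$calls), file.path(dir, "cluster_calls.bed"))
  invisible(dir)
}
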