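test_that("local alignment scores follow the fixed scheme", {
  s <- "ACDEFGHIKL"
  expect_equal(local_align_score(s, s), 20)
  expect_equal(local_align_score("AAAA", "CCCC"), 0)
  expect_equal(local_align_score("ACDEFG", "ACDFG"), sw_oracle("ACDEFG", "ACDFG"))
  expect_equal(local_align_score("", "ACD"), 0)
  expect_equal(local_align_score("ACD", ""), 0)
  set.seed(51)
  for (i in 1:150) {
    a <- random_aa(sample(1:60, 1))
    b <- random_aa(sample(1:60, 1))
    expect_equal(local_align_score(a, b), sw_oracle(a, b))
    expect_equal(local_align_score(a, b), local_align_score(b, a))
  }
})

test_that("reciprocal best hits match the exhaustive oracle", {
  set.seed(61)
  protA <- vapply(rep(60, 10), random_aa, character(1))
  names(protA) <- sprintf("a%02d", 1:10)
  expect_equal(as.data.frame(rbh_map(protA, protA))$other_id,
               names(protA))

  empty <- rbh_map(protA, character(0))
  expect_equal(nrow(empty), 0L)

  for (s in 1:5) {
    set.seed(70 + s)
    protA <- vapply(sample(40:80, 20, replace = TRUE), random_aa,
                    character(1))
    names(protA) <- sprintf("a%02d", 1:20)
    protB <- c(vapply(protA[1:12], mutate_protein, character(1),
                      divergence = 0.1),
               vapply(sample(40:80, 8, replace = TRUE), random_aa,
                      character(1)))
    names(protB) <- sprintf("b%02d", 1:20)
    got <- suppressMessages(as.data.frame(rbh_map(protA, protB)))
    want <- suppressMessages(rbh_oracle(protA, protB))
    expect_equal(got, want)
    # each gene in at most one pair
    expect_false(anyDuplicated(got$focal_id) > 0)
    expect_false(anyDuplicated(got$other_id) > 0)
  }
})

test_that("an identical comparator yields perfect synteny and containment", {
  cfg <- sim_config(seed = 41)
  sim <- simulate_scenario(cfg, list(scenario_spec("conserved_cluster",
                                                   divergence = 0)))
  cl_idx <- match(sim$truth$focal$cluster_ids,
                  sim$focal$annotation$gene_id)
  ann <- sim$focal$annotation
  call <- cluster_call("expression", "scaffold_1",
                       sim$truth$focal$cluster_ids,
                       min(ann$start[cl_idx]), max(ann$end[cl_idx]),
                       sim$truth$focal$backbone_id)
  cmp <- sim$comparators$conserved_cluster
  om <- suppressMessages(rbh_map(sim$focal$proteome, cmp$proteome))
  rep <- flank_synteny_report(ann, call, om, cmp$annotation)
  expect_equal(rep$flank5_conserved, 1)
  expect_equal(rep$flank3_conserved, 1)
  expect_equal(rep$order_conserved, 1)
  expect_equal(rep$cluster_orthologs_inside_gap, 12L)
  expect_equal(rep$cluster_orthologs_dispersed, 0L)
  expect_equal(classify_origin(rep)$origin_label, "conserved_cluster")
})

test_that("the planted intervening gap is recovered exactly", {
  cfg <- sim_config(seed = 42)
  sim <- simulate_scenario(cfg, list(scenario_spec("lineage_specific",
                                                   intervening_gap_bp = 3000)))
  ann <- sim$focal$annotation
  cl_idx <- match(sim$truth$focal$cluster_ids, ann$gene_id)
  call <- cluster_call("expression", "scaffold_1",
                       sim$truth$focal$cluster_ids,
                       min(ann$start[cl_idx]), max(ann$end[cl_idx]),
                       sim$truth$focal$backbone_id)
  cmp <- sim$comparators$lineage_specific
  om <- suppressMessages(rbh_map(sim$focal$proteome, cmp$proteome))
  rep <- flank_synteny_report(ann, call, om, cmp$annotation)
  expect_equal(rep$intervening_gap_bp, 3000L)
  expect_equal(rep$cluster_orthologs_inside_gap, 0L)
  expect_gt(rep$cluster_orthologs_dispersed, 0L)
  expect_equal(classify_origin(rep)$origin_label, "lineage_specific")
})

test_that("an inverted flank lowers order conservation and reads as rearranged", {
  # six-gene toy: flanks f1 f2 | cluster c1 | flanks g1 g2; the
  # comparator inverts the 3' flank and inserts 20 kb at the junction
  focal <- toy_annotation(c("housekeeping", "housekeeping",
                            "backbone_nrps", "housekeeping",
                            "housekeeping"),
                          ids = c("f1", "f2", "c1", "g1", "g2"))
  comp <- genome_annotation(data.frame(
    gene_id = c("F1", "F2", "G2", "G1"),
    scaffold = "s1",
    start = c(1L, 2001L, 24001L, 26001L),
    end = c(1000L, 3000L, 25000L, 27000L),
    strand = "+", role = "housekeeping"), genome_id = "toycmp")
  om <- structure(data.frame(
    focal_id = c("f1", "f2", "g1", "g2"),
    other_id = c("F1", "F2", "G1", "G2"),
    score = 100, stringsAsFactors = FALSE),
    class = c("ortholog_map", "data.frame"))
  call <- cluster_call("expression", "s1", "c1",
                       focal$start[focal$gene_id == "c1"],
                       focal$end[focal$gene_id == "c1"], "c1")
  rep <- flank_synteny_report(focal, call, om, comp, flank_n = 2)
  expect_equal(rep$flank5_conserved, 1)
  expect_equal(rep$flank3_conserved, 1)
  expect_lt(rep$order_conserved, 1)
  # innermost mapped flank orthologs are F2 (end 3000) and G1
  # (start 26001): gap spans the insert plus the displaced G2
  expect_equal(rep$intervening_gap_bp, 26001L - 3000L - 1L)
  expect_equal(classify_origin(rep)$origin_label, "rearranged")
})

test_that("origin rules order and thresholds are honored", {
  base <- structure(list(genome_id = "x", cluster_size = 10L,
                         flank5_conserved = 1, flank3_conserved = 1,
                         flank_conserved = 1, order_conserved = 1,
                         intervening_gap_bp = 3000L,
                         cluster_orthologs_total = 1L,
                         cluster_orthologs_inside_gap = 0L,
                         cluster_orthologs_dispersed = 1L,
                         origin_label = "unresolved",
                         flags = character(0)),
                    class = "synteny_report")
  expect_equal(classify_origin(base)$origin_label, "lineage_specific")

  over <- base; over$intervening_gap_bp <- 8000L
  expect_equal(classify_origin(over)$origin_label, "rearranged")

  hgt <- base
  hgt$flank_conserved <- 0.2
  hgt$flank5_conserved <- 0.2; hgt$flank3_conserved <- 0.2
  hgt$cluster_orthologs_total <- 9L
  hgt$cluster_orthologs_dispersed <- 9L
  hgt$intervening_gap_bp <- NA_integer_
  expect_equal(classify_origin(hgt)$origin_label, "candidate_transfer")

  cons <- base
  cons$cluster_orthologs_total <- 9L
  cons$cluster_orthologs_inside_gap <- 9L
  cons$cluster_orthologs_dispersed <- 0L
  expect_equal(classify_origin(cons)$origin_label, "conserved_cluster")

  odd <- base; odd$flank_conserved <- 0.6
  expect_equal(classify_origin(odd)$origin_label, "unresolved")

  # thresholds are configuration, not constants
  strict <- classify_origin(base, origin_thresholds(gap_max = 2000))
  expect_equal(strict$origin_label, "rearranged")
})

test_that("the homolog scan detects co-located blocks and not dispersed ones", {
  cfg <- sim_config(seed = 55)
  sim <- simulate_scenario(cfg, list(scenario_spec("lineage_specific")))
  ft <- sim$truth$focal
  ann <- sim$focal$annotation
  cl_prot <- sim$focal$proteome[ft$cluster_ids]
  cl_roles <- structure(ann$role[match(ft$cluster_ids, ann$gene_id)],
                        names = ft$cluster_ids)

  panel <- list(
    self = list(annotation = ann, proteome = sim$focal$proteome),
    lineage = sim$comparators$lineage_specific)
  res <- homolog_cluster_scan(cl_prot, cl_roles, panel)
  self_row <- res[res$genome_id == "self", ]
  expect_equal(self_row$colocated_fraction, 1)
  expect_true(self_row$detected)
  lin_row <- res[res$genome_id == "lineage", ]
  expect_lt(lin_row$colocated_fraction, 0.5)
  expect_false(lin_row$detected)

  # homologs scattered one per scaffold cannot co-locate
  scat_ann <- genome_annotation(data.frame(
    gene_id = sprintf("sc%02d", seq_along(cl_prot)),
    scaffold = sprintf("scf%02d", seq_along(cl_prot)),
    start = 1L, end = 3L * nchar(cl_prot) + 2L,
    strand = "+", role = "housekeeping"), genome_id = "scattered")
  scat_prot <- stats::setNames(as.character(cl_prot), scat_ann$gene_id)
  res2 <- homolog_cluster_scan(cl_prot, cl_roles,
                               list(scattered = list(
                                 annotation = scat_ann,
                                 proteome = scat_prot)))
  expect_equal(res2$homolog_fraction, 1)
  expect_equal(res2$colocated_fraction, 1 / length(cl_prot))
  expect_false(res2$detected)
})

test_that("simulated scenarios round-trip to their planted origin labels", {
  for (s in 1:3) {
    cfg <- sim_config(seed = 200 + s)
    sim <- simulate_scenario(cfg, list(
      scenario_spec("lineage_specific"),
      scenario_spec("conserved_cluster"),
      scenario_spec("inversion")))
    ann <- sim$focal$annotation
    cl_idx <- match(sim$truth$focal$cluster_ids, ann$gene_id)
    call <- cluster_call("expression", "scaffold_1",
                         sim$truth$focal$cluster_ids,
                         min(ann$start[cl_idx]), max(ann$end[cl_idx]),
                         sim$truth$focal$backbone_id)
    want <- c(lineage_specific = "lineage_specific",
              conserved_cluster = "conserved_cluster",
              inversion = "rearranged")
    for (gid in names(sim$comparators)) {
      g <- sim$comparators[[gid]]
      om <- suppressMessages(rbh_map(sim$focal$proteome, g$proteome))
      rep <- classify_origin(
        flank_synteny_report(ann, call, om, g$annotation))
      expect_equal(rep$origin_label, unname(want[gid]),
                   info = sprintf("seed %d scenario %s", 200 + s, gid))
    }
  }
})
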