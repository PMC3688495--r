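test_that("identical configuration reproduces identical artifacts", {
  cfg <- sim_config(seed = 5)
  scs <- list(scenario_spec("lineage_specific"),
              scenario_spec("conserved_cluster"))
  s1 <- simulate_scenario(cfg, scs)
  s2 <- simulate_scenario(cfg, scs)
  expect_identical(s1, s2)
  c1 <- simulate_counts(cfg, s1$focal$annotation, s1$truth)
  c2 <- simulate_counts(cfg, s2$focal$annotation, s2$truth)
  expect_identical(c1, c2)
})

test_that("planted layout matches the configuration", {
  cfg <- sim_config(seed = 3, cluster_size = 12, flank_size = 10)
  sim <- simulate_scenario(cfg, list(scenario_spec("lineage_specific",
                                                   intervening_gap_bp = 3000)))
  ann <- sim$focal$annotation
  ft <- sim$truth$focal
  expect_length(ft$cluster_ids, 12L)
  expect_length(ft$flank5_ids, 10L)
  roles <- ann$role[match(ft$cluster_ids, ann$gene_id)]
  expect_equal(sum(roles == "backbone_nrps"), 1L)
  expect_equal(roles[1], "backbone_nrps")
  expect_true("cyclophilin" %in% roles)
  # cluster is contiguous on its scaffold
  idx <- match(ft$cluster_ids, ann$gene_id)
  expect_equal(idx, idx[1]:(idx[1] + 11L))

  # lineage-specific comparator: flank orthologs in order, planted gap
  cmp <- sim$comparators$lineage_specific
  tr <- sim$truth$comparators$lineage_specific
  expect_equal(tr$planted_gap_bp, 3000L)
  inner5 <- tr$ortholog_pairs$other_id[
    tr$ortholog_pairs$focal_id == ft$flank5_ids[10]]
  inner3 <- tr$ortholog_pairs$other_id[
    tr$ortholog_pairs$focal_id == ft$flank3_ids[1]]
  oth <- as.data.frame(cmp$annotation)
  r5 <- oth[oth$gene_id == inner5, ]; r3 <- oth[oth$gene_id == inner3, ]
  expect_equal(r3$start - r5$end - 1L, 3000L)
  # no cluster gene orthologs at the locus; dispersed copies elsewhere
  expect_true(all(tr$dispersed_focal_ids %in% ft$cluster_ids))

  # conserved comparator holds every cluster ortholog in focal order
  sim2 <- simulate_scenario(cfg, list(scenario_spec("conserved_cluster")))
  tr2 <- sim2$truth$comparators$conserved_cluster
  pairs <- tr2$ortholog_pairs
  cl <- pairs[pairs$focal_id %in% ft$cluster_ids, ]
  expect_equal(cl$focal_id, ft$cluster_ids)
  oth2 <- as.data.frame(sim2$comparators$conserved_cluster$annotation)
  pos <- match(cl$other_id, oth2$gene_id)
  expect_equal(pos, sort(pos))
})

test_that("count generator matches the NB mean-dispersion parameterization", {
  # one class, many genes: moments over >= 1e4 draws within 5%
  cfg <- sim_config(seed = 11, cluster_size = 2, flank_size = 0,
                    n_background = 600, n_timepoints = 2,
                    n_replicates = 5, dispersion = 0.1,
                    induction_start = 2)
  sim <- simulate_scenario(cfg, list())
  cm <- simulate_counts(cfg, sim$focal$annotation, sim$truth)
  hk <- setdiff(rownames(cm$counts), sim$truth$focal$cluster_ids)
  draws <- as.vector(cm$counts[hk, ])   # 600 genes x 20 samples
  mu <- 100; phi <- 0.1
  expect_length(draws, 12000L)
  expect_lt(abs(mean(draws) - mu) / mu, 0.05)
  expect_lt(abs(var(draws) - (mu + phi * mu^2)) / (mu + phi * mu^2), 0.05)

  # Poisson limit: variance/mean ratio near 1 as dispersion vanishes
  cfg0 <- sim_config(seed = 12, cluster_size = 2, flank_size = 0,
                     n_background = 600, n_timepoints = 2,
                     n_replicates = 5, dispersion = 1e-8,
                     induction_start = 2)
  sim0 <- simulate_scenario(cfg0, list())
  cm0 <- simulate_counts(cfg0, sim0$focal$annotation, sim0$truth)
  d0 <- as.vector(cm0$counts[setdiff(rownames(cm0$counts),
                                     sim0$truth$focal$cluster_ids), ])
  expect_lt(abs(var(d0) / mean(d0) - 1), 0.05)
})

test_that("expression classes land at their configured baselines and fold changes", {
  cfg <- sim_config(seed = 21, n_timepoints = 4, n_replicates = 25,
                    induction_start = 2)
  sim <- simulate_scenario(cfg, list())
  cm <- simulate_counts(cfg, sim$focal$annotation, sim$truth)
  ft <- sim$truth$focal
  cyc <- names(ft$gene_classes)[ft$gene_classes == "cyclophilin"]
  acc <- names(ft$gene_classes)[ft$gene_classes == "accessory"]
  ctl <- cm$meta$condition == "control"
  ind <- cm$meta$condition == "treatment" & cm$meta$timepoint >= 2

  # high constitutive cyclophilin baseline vs near-zero accessory baseline
  expect_gt(mean(cm$counts[cyc, ctl]), 20 * mean(cm$counts[acc, ctl]))
  # realized log2 ratios near the configured class effects
  expect_lt(abs(log2(mean(cm$counts[cyc, ind]) /
                       mean(cm$counts[cyc, ctl])) - 3.18), 0.25)
  expect_lt(abs(log2(mean(cm$counts[acc[1], ind]) /
                       mean(cm$counts[acc[1], ctl])) - 9), 0.6)
})

test_that("protein mutation follows the per-site substitution model", {
  set.seed(9)
  s <- random_aa(1000)
  expect_identical(mutate_protein(s, 0), s)
  m1 <- mutate_protein(s, 1)
  expect_equal(nchar(m1), 1000L)
  expect_true(all(strsplit(m1, "")[[1]] != strsplit(s, "")[[1]]))
  ham <- sum(strsplit(mutate_protein(s, 0.1), "")[[1]] !=
               strsplit(s, "")[[1]])
  expect_gte(ham, qbinom(0.005, 1000, 0.1))
  expect_lte(ham, qbinom(0.995, 1000, 0.1))
})

test_that("planted ortholog pairs stay close to the configured divergence", {
  cfg <- sim_config(seed = 8)
  div <- 0.1
  sim <- simulate_scenario(cfg, list(scenario_spec("conserved_cluster",
                                                   divergence = div)))
  tr <- sim$truth$comparators$conserved_cluster
  fp <- sim$focal$proteome
  cp <- sim$comparators$conserved_cluster$proteome
  for (i in seq_len(nrow(tr$ortholog_pairs))) {
    a <- strsplit(fp[[tr$ortholog_pairs$focal_id[i]]], "")[[1]]
    b <- strsplit(cp[[tr$ortholog_pairs$other_id[i]]], "")[[1]]
    ident <- mean(a == b)
    sigma <- sqrt(div * (1 - div) / length(a))
    expect_gte(ident, 1 - div - 3 * sigma)
  }
})

test_that("simulation artifacts survive a disk round trip", {
  cfg <- sim_config(seed = 4, n_background = 5)
  sim <- simulate_scenario(cfg, list(scenario_spec("lineage_specific")))
  cm <- simulate_counts(cfg, sim$focal$annotation, sim$truth)
  dir <- tempfile("simout")
  write_simulation(sim, cm, dir)
  ann <- read_annotation(file.path(dir, "focal.gff3"), genome_id = "focal")
  expect_equal(as.data.frame(ann), as.data.frame(sim$focal$annotation))
  expect_equal(read_proteome(file.path(dir, "focal.faa")),
               sim$focal$proteome)
  cm2 <- read_counts(file.path(dir, "counts.tsv"),
                     file.path(dir, "samples.tsv"))
  expect_equal(cm2$counts, cm$counts)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(truth$focal$cluster_ids),
               sim$truth$focal$cluster_ids)
})
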