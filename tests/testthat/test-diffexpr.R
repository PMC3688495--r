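test_that("size factors follow the median-of-ratios contract", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(m2) <- c("a", "b", "c")
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  single <- matrix(5, 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(size_factors(single)), 1)

  # geometric mean 1 on arbitrary matrices
  set.seed(2)
  m3 <- matrix(rpois(60, 50) + 1L, 10, 6,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expect_equal(exp(mean(log(size_factors(m3)))), 1)

  # no universally expressed gene: error advising the fallback flag
  m4 <- rbind(a = c(0L, 5L), b = c(5L, 0L))
  colnames(m4) <- c("s1", "s2")
  expect_error(size_factors(m4), "pseudo_reference")
  expect_length(size_factors(m4, pseudo_reference = TRUE), 2L)
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  set.seed(31)
  m <- matrix(rnbinom(600, mu = 80, size = 5) + 1L, 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))   # both on the geometric-mean-1 scale
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("moments dispersion clamps degenerate genes and is consistent", {
  grp <- rep(c("a", "b"), each = 3)
  expect_equal(as.numeric(moments_dispersion(rep(7, 6), grp)), 1e-8)
  expect_equal(as.numeric(moments_dispersion(rep(0, 6), grp)), 1e-8)

  set.seed(4)
  y <- rnbinom(10000, mu = 100, size = 1 / 0.2)
  est <- as.numeric(moments_dispersion(y, rep("a", length(y))))
  expect_lt(abs(est - 0.2) / 0.2, 0.1)
})

test_that("the exact NB test behaves at its boundary cases", {
  grp <- rep(c("a", "b"), each = 3)
  expect_equal(nb_exact_test(rep(0, 6), grp, 0.1), 1)
  expect_lt(nb_exact_test(c(0, 0, 0, 500, 480, 510), grp, 1e-4), 1e-6)

  # symmetric under group relabeling and replicate permutation
  set.seed(6)
  y <- rnbinom(6, mu = 50, size = 10)
  p1 <- nb_exact_test(y, grp, 0.1)
  p2 <- nb_exact_test(y, rev(grp), 0.1)
  expect_equal(p1, p2)
  perm <- c(sample(1:3), sample(4:6))
  expect_equal(nb_exact_test(y[perm], grp, 0.1), p1)
})

test_that("the exact NB test is calibrated under the null", {
  set.seed(19)
  grp <- rep(c("a", "b"), each = 3)
  p <- vapply(seq_len(3000), function(i)
    nb_exact_test(rnbinom(6, mu = 100, size = 10), grp, 0.1),
    numeric(1))
  expect_gte(mean(p < 0.05), 0.035)
  expect_lte(mean(p < 0.05), 0.065)
})

test_that("log2 fold change handles zeros through the pseudocount", {
  expect_equal(log2_fold_change(10, 10), 0)
  expect_equal(log2_fold_change(10, 80, pseudocount = 1e-9), 3,
               tolerance = 1e-6)
  expect_equal(log2_fold_change(0, 0), 0)
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_lt(max(abs(q - bh_oracle(p))), 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("RPKM has the closed form and its scaling laws", {
  expect_identical(rpkm(10, 1000, 1e6), 10)
  expect_identical(rpkm(0, 1000, 1e6), 0)
  expect_identical(rpkm(500, 2000, 5e6), 50)
  expect_equal(rpkm(20, 1000, 1e6), 2 * rpkm(10, 1000, 1e6))
  expect_equal(rpkm(10, 2000, 1e6), rpkm(10, 1000, 1e6) / 2)
  expect_equal(rpkm(10, 1000, 2e6), rpkm(10, 1000, 1e6) / 2)
})

test_that("the time-course driver flags planted genes and only those", {
  cfg <- sim_config(seed = 13)
  sim <- simulate_scenario(cfg, list())
  cm <- simulate_counts(cfg, sim$focal$annotation, sim$truth)
  de <- run_timecourse_de(cm, sim$focal$annotation)
  cl <- sim$truth$focal$cluster_ids
  tab <- de$table
  late <- tab[tab$timepoint >= 3, ]
  # every cluster gene upregulated at q < 0.001 at every induced timepoint
  expect_true(all(late$up_0.001[late$gene_id %in% cl]))
  # RPKM present for all genes, non-negative
  expect_equal(dim(de$rpkm), dim(cm$counts))
  expect_true(all(de$rpkm >= 0))
})

test_that("identical count columns across conditions give zero fold change", {
  m <- matrix(rep(c(10L, 50L, 200L), 4), nrow = 3,
              dimnames = list(c("a", "b", "c"),
                              c("c1", "c2", "t1", "t2")))
  meta <- data.frame(sample_id = colnames(m),
                     condition = c("control", "control",
                                   "treatment", "treatment"),
                     timepoint = 1L, replicate = c(1L, 2L, 1L, 2L))
  de <- run_timecourse_de(counts_matrix(m, meta))
  expect_equal(de$table$log2fc, rep(0, 3))
  expect_true(all(de$table$q_value > 0.5))
})

test_that("null data produce almost no discoveries at strict thresholds", {
  flagged <- 0L
  for (s in 1:5) {
    cfg <- sim_config(seed = 100 + s,
                      induced_lfc = c(accessory = 0, backbone = 0,
                                      cyclophilin = 0))
    sim <- simulate_scenario(cfg, list())
    cm <- simulate_counts(cfg, sim$focal$annotation, sim$truth)
    de <- run_timecourse_de(cm)
    flagged <- flagged + sum(de$table$q_value < 0.001)
  }
  # expected BH discoveries under the global null: ~alpha per timepoint
  expect_lte(flagged, 2L)
})

test_that("a timepoint missing one condition is skipped with a warning", {
  set.seed(23)
  m <- matrix(rpois(40, 50), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  meta <- data.frame(
    sample_id = paste0("s", 1:10),
    condition = c(rep(c("control", "treatment"), each = 2),
                  rep(c("control", "treatment"), each = 3)),
    timepoint = c(rep(1L, 4), rep(2L, 6)),
    replicate = c(1:2, 1:2, 1:3, 1:3))
  meta$condition[3:4] <- "control"   # timepoint 1 loses treatment
  meta$replicate[3:4] <- 3:4
  cm <- counts_matrix(m, meta)
  expect_warning(de <- run_timecourse_de(cm), "skipped")
  expect_equal(unique(de$table$timepoint), 2L)
})
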