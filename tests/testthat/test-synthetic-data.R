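test_that("same seed gives bit-identical output, different seed differs", {
  cfg <- simulation_config(n_genes = 120, seed = 3)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(simulation_config(n_genes = 120, seed = 4))
  expect_false(identical(s1$matrix, s3$matrix))
})

test_that("the design emulates the five-strain, two-timepoint duplicate study", {
  sim <- simulate_experiment(simulation_config(n_genes = 50, seed = 1))
  expect_identical(dim(sim$matrix), c(50L, 20L))
  expect_identical(nrow(sim$design), 20L)
  expect_setequal(unique(sim$design$strain_role),
                  c("WT", "ASYM_A", "ASYM_B", "DOUBLE", "SET1D"))
  expect_true("ACT1" %in% rownames(sim$matrix))
  # reference gene constant across all samples
  expect_identical(unname(sim$matrix["ACT1", ]), rep(1024, 20))
})

test_that("noise-free planted modes reproduce their defining identities", {
  cfg <- simulation_config(n_genes = 300, sigma = 0, seed = 8)
  sim <- simulate_experiment(cfg)
  fc <- average_fc(compute_fc(sim$matrix, sim$design))
  tr <- sim$truth

  coop <- tr$gene_id[tr$mode == "COOPERATIVE"]
  expect_gt(length(coop), 0)
  # observed FCs in ASYM_A, ASYM_B and DOUBLE are exactly equal
  expect_identical(fc$fc$ASYM_A[coop, ], fc$fc$DOUBLE[coop, ])
  expect_identical(fc$fc$ASYM_B[coop, ], fc$fc$DOUBLE[coop, ])

  red <- tr$gene_id[tr$mode == "REDUNDANT"]
  expect_identical(fc$fc$ASYM_A[red, ], fc$fc$WT[red, ])

  ind <- tr$gene_id[tr$mode == "INDEPENDENT"]
  expect_equal(fc$fca[ind, "ASYM_A"],
               0.5 * fc$fca[ind, "WT"] + 0.5 * fc$fca[ind, "DOUBLE"],
               tolerance = 1e-9)

  # every responsive gene is between the endpoints in both strains (Mid = 1)
  resp <- tr$gene_id[tr$mode != "NULL"]
  mid_a <- mid_statistic(fc$fca[resp, "ASYM_A"], fc$fca[resp, "WT"],
                         fc$fca[resp, "DOUBLE"])
  mid_b <- mid_statistic(fc$fca[resp, "ASYM_B"], fc$fca[resp, "WT"],
                         fc$fca[resp, "DOUBLE"])
  expect_true(all(mid_a <= 1 + 1e-9 & mid_b <= 1 + 1e-9))

  # recovered FCa match the planted truth closely
  expect_equal(unname(fc$fca[tr$gene_id, "WT"]), tr$fc_wt, tolerance = 1e-6)
  expect_equal(unname(fc$fca[tr$gene_id, "DOUBLE"]), tr$fc_double,
               tolerance = 1e-6)
})

test_that("an exact midpoint gene yields asymmetric FC exactly 1", {
  # sigma = 0, planted WT FC = 2, DOUBLE FC = 0: engineered directly
  m <- rbind(ACT1 = rep(100, 4),
             g1 = c(16, 64, 16, 32))
  colnames(m) <- c("A_T0", "A_T1", "B_T0", "B_T1")
  d <- sample_design(data.frame(
    sample_id = colnames(m),
    strain_role = c("WT", "WT", "ASYM_A", "ASYM_A"),
    timepoint = c("T0", "T1", "T0", "T1"),
    replicate = 1L))
  fc <- compute_fc(m, d)
  expect_identical(fc$fc$WT["g1", 1], 2)
  expect_identical(fc$fc$ASYM_A["g1", 1], 1)
})

test_that("planted mode proportions are recovered across seeds", {
  counts <- c(COOPERATIVE = 0, INDEPENDENT = 0, REDUNDANT = 0, "NULL" = 0)
  for (s in 1:6) {
    tr <- simulate_experiment(simulation_config(n_genes = 500, seed = s))$truth
    tab <- table(tr$mode)
    counts[names(tab)] <- counts[names(tab)] + tab
  }
  n_resp <- sum(counts[c("COOPERATIVE", "INDEPENDENT", "REDUNDANT")])
  total <- sum(counts)
  # binomial sampling error at ~1200 responsive draws is well inside 0.04
  expect_lt(abs(n_resp / total - 0.4), 0.04)
  expect_lt(abs(counts[["COOPERATIVE"]] / n_resp - 0.10), 0.04)
  expect_lt(abs(counts[["INDEPENDENT"]] / n_resp - 0.50), 0.05)
  expect_lt(abs(counts[["REDUNDANT"]] / n_resp - 0.40), 0.05)
})

test_that("truth_cluster maps planted modes to expected clusters", {
  tr <- data.frame(gene_id = c("a", "b", "c", "d"),
                   mode = c("COOPERATIVE", "INDEPENDENT", "REDUNDANT", "NULL"))
  expect_identical(unname(truth_cluster(tr)), c("I", "II", "III", "NONE"))
  expect_identical(names(truth_cluster(tr)), tr$gene_id)
})

test_that("zero_fraction plants zero-RPKM genes that the filter excludes", {
  sim <- simulate_experiment(simulation_config(n_genes = 200,
                                               zero_fraction = 0.1, seed = 6))
  fc <- compute_fc(sim$matrix, sim$design)
  expect_gt(nrow(fc$exclusions), 0)
  expect_true(all(fc$exclusions$reason == "ZERO_RPKM"))
})

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(n_genes = 1), "n_genes")
  expect_error(simulation_config(mode_proportions = c(COOPERATIVE = 0.5,
                                                      INDEPENDENT = 0.5,
                                                      REDUNDANT = 0.5)),
               "sum to 1")
  expect_error(simulation_config(sigma = -0.1), "sigma")
  expect_error(simulation_config(lambda = 1), "lambda")
})
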