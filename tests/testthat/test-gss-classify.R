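test_that("Mid statistic: betweenness indicator with degenerate endpoints", {
  expect_identical(mid_statistic(1, 2, 0), 1)
  expect_equal(mid_statistic(3, 2, 0), 2)   # (1 + 3) / 2
  expect_identical(mid_statistic(2, 2, 0), 1)  # boundary: equals an endpoint
  expect_equal(mid_statistic(c(1, 3, 2), c(2, 2, 2), c(0, 0, 0)), c(1, 2, 1))
  expect_warning(out <- mid_statistic(1, 2, 2), "coincide")
  expect_true(is.na(out))
})

test_that("Mid >= 1 always, and = 1 exactly iff between (property)", {
  set.seed(31)
  n <- 20000
  w <- runif(n, -5, 5); d <- runif(n, -5, 5)
  keep <- abs(w - d) > 1e-6
  w <- w[keep]; d <- d[keep]
  a <- runif(length(w), -6, 6)
  mid <- mid_statistic(a, w, d)
  between <- a >= pmin(w, d) & a <= pmax(w, d)
  expect_true(all(mid >= 1 - 1e-12))
  expect_identical(mid <= 1 + 1e-9, between)
})

test_that("GSS: midpoint zero, skew examples, extended-real endpoints", {
  expect_identical(gss_score(1, 2, 0), 0)
  expect_equal(gss_score(1.5, 2, 0), log2(3))
  expect_equal(gss_score(0.5, 2, 0), -log2(3))
  expect_identical(gss_score(2, 2, 0), Inf)    # at the WT endpoint
  expect_identical(gss_score(0, 2, 0), -Inf)   # at the DOUBLE endpoint
})

test_that("GSS antisymmetry and monotonicity along the interval", {
  set.seed(32)
  n <- 5000
  w <- runif(n, -4, 4)
  d <- w + runif(n, 0.5, 3) * sample(c(-1, 1), n, replace = TRUE)
  t0 <- runif(n, 0.05, 0.95)
  a <- w + t0 * (d - w)
  refl <- (w + d) - a
  expect_equal(gss_score(refl, w, d), -gss_score(a, w, d), tolerance = 1e-12)

  # strictly increasing toward the WT endpoint
  w0 <- 2; d0 <- -1
  ts <- seq(0.95, 0.05, by = -0.05)    # from DOUBLE side toward WT side
  g <- gss_score(w0 + ts * (d0 - w0), w0, d0)
  expect_true(all(diff(g) > 0))
})

test_that("MID subset needs betweenness in both asymmetric strains", {
  fcl <- list(
    WT = rbind(both = c(2, 2), one = c(2, 2), out = c(2, 2)),
    ASYM_A = rbind(both = c(1, 1), one = c(1, 1), out = c(3, 3)),
    ASYM_B = rbind(both = c(0.5, 0.5), one = c(3, 3), out = c(3, 3)),
    DOUBLE = rbind(both = c(0, 0.1), one = c(0, 0.1), out = c(0, 0.1)))
  for (s in names(fcl)) colnames(fcl[[s]]) <- c("rep1", "rep2")
  fc <- average_fc(make_fc_table(fcl))
  resp <- data.frame(gene_id = c("both", "one", "out"), p_value = 0.001)
  expect_identical(build_mid_set(fc, resp), "both")
  # a gene outside the responsive set is never in MID
  resp2 <- data.frame(gene_id = c("one", "out"), p_value = 0.001)
  expect_identical(build_mid_set(fc, resp2), character())
})

test_that("five-archetype fixture classifies as the brute-force oracle says", {
  # one clear midpoint gene, one WT-like, one DOUBLE-like, one noisy
  # midpoint, one borderline intermediate
  fcl <- list(
    WT     = rbind(midg = c(2.00, 2.05), wtlike = c(2.00, 2.05),
                   dblike = c(2.00, 2.05), noisy = c(2.00, 2.05),
                   border = c(2.00, 2.05)),
    ASYM_A = rbind(midg = c(1.00, 1.05), wtlike = c(1.98, 2.07),
                   dblike = c(0.03, 0.08), noisy = c(1.9, 0.1),
                   border = c(1.35, 1.40)),
    ASYM_B = rbind(midg = c(0.98, 1.03), wtlike = c(2.01, 2.04),
                   dblike = c(0.02, 0.06), noisy = c(0.2, 1.8),
                   border = c(0.60, 0.65)),
    DOUBLE = rbind(midg = c(0.00, 0.05), wtlike = c(0.00, 0.05),
                   dblike = c(0.00, 0.05), noisy = c(0.00, 0.05),
                   border = c(0.00, 0.05)))
  for (s in names(fcl)) colnames(fcl[[s]]) <- c("rep1", "rep2")
  got <- package_classify_all(fcl)
  want <- oracle_classify_all(fcl)
  expect_identical(got$labels, want$labels)
  expect_identical(got$labels[["midg"]], "II")
  expect_identical(got$labels[["wtlike"]], "III")
  expect_identical(got$labels[["dblike"]], "I")
  expect_equal(got$gss_max, want$gss_max)
  expect_equal(got$gss_min, want$gss_min)
})

test_that("clusters are disjoint subsets of MID and swap-invariant", {
  fcl <- random_fc_fixture(80, seed = 77)
  fc <- average_fc(make_fc_table(fcl))
  resp <- screen_responsive(fc)
  mid <- build_mid_set(fc, resp)
  cls <- classify_clusters(fc, mid)
  expect_setequal(cls$gene_id, mid)
  expect_true(all(mid %in% resp$gene_id))
  for (cl in c("I", "II", "III"))
    expect_true(all(cls$gene_id[cls$cluster == cl] %in% mid))
  # finite GSS of Cluster II members lies within the bounds
  ii <- cls$cluster == "II"
  pool <- c(cls$gss_a[ii], cls$gss_b[ii])
  pool <- pool[is.finite(pool)]
  expect_true(all(pool <= attr(cls, "gss_max") + 1e-12))
  expect_true(all(pool >= attr(cls, "gss_min") - 1e-12))

  # relabeling the two asymmetric strains leaves cluster labels unchanged
  fcl_sw <- fcl
  fcl_sw$ASYM_A <- fcl$ASYM_B
  fcl_sw$ASYM_B <- fcl$ASYM_A
  fc_sw <- average_fc(make_fc_table(fcl_sw))
  cls_sw <- classify_clusters(fc_sw, build_mid_set(fc_sw, screen_responsive(fc_sw)))
  expect_identical(stats::setNames(cls$cluster, cls$gene_id),
                   stats::setNames(cls_sw$cluster, cls_sw$gene_id))
})

test_that("degenerate classification inputs warn instead of failing", {
  expect_warning(cls <- classify_clusters(
    average_fc(make_fc_table(random_fc_fixture(10, seed = 1))),
    character()), "empty")
  expect_identical(nrow(cls), 0L)

  # MID genes none of which reach Cluster II -> bounds undefined
  fcl <- list(
    WT = rbind(g1 = c(2, 2.05)), ASYM_A = rbind(g1 = c(1.97, 2.08)),
    ASYM_B = rbind(g1 = c(1.96, 2.02)), DOUBLE = rbind(g1 = c(0, 0.05)))
  for (s in names(fcl)) colnames(fcl[[s]]) <- c("rep1", "rep2")
  fc <- average_fc(make_fc_table(fcl))
  expect_warning(cls2 <- classify_clusters(fc, "g1"), "bounds undefined")
  expect_identical(cls2$cluster, "UNASSIGNED")
  expect_true(is.na(attr(cls2, "gss_max")))
})
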