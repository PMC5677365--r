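# Fixture builders and independent oracles shared across the test files.
# The oracle code paths deliberately use plain loops and the closed-form
# df = 2 t tail so they share no code with the package implementation.

# closed-form two-sided p for the pooled t-test; df = 2 uses the algebraic
# tail P(T2 > t) = 0.5 * (1 - t / sqrt(2 + t^2))
oracle_t_p <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  df <- length(x) + length(y) - 2
  sp2 <- (sum((x - mx)^2) + sum((y - my)^2)) / df
  if (sp2 == 0) return(if (mx == my) 1 else 0)
  tt <- abs(mx - my) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  if (df == 2) 1 - tt / sqrt(2 + tt^2) else 2 * stats::pt(-tt, df)
}

# build an fc_table directly from per-strain genes x replicates FC matrices
make_fc_table <- function(fcl, reference_gene = "ACT1") {
  genes <- rownames(fcl[[1]])
  structure(list(fc = fcl, fca = NULL,
                 exclusions = data.frame(gene_id = character(),
                                         reason = character(),
                                         stringsAsFactors = FALSE),
                 genes = genes, strains = names(fcl),
                 reference_gene = reference_gene),
            class = "fc_table")
}

# literal, loop-based transcription of the published set definitions:
# DH (responsive screen), MID (betweenness in both asymmetric strains),
# Cluster II, GSS bounds, Cluster III, Cluster I. Returns per-gene labels
# over ALL genes ("NONE" outside MID).
oracle_classify_all <- function(fcl, alpha = 0.05) {
  genes <- rownames(fcl$WT)
  fca <- lapply(fcl, rowMeans)
  lab <- stats::setNames(rep("NONE", length(genes)), genes)

  dh <- genes[vapply(genes, function(g)
    oracle_t_p(fcl$WT[g, ], fcl$DOUBLE[g, ]) < alpha, logical(1))]

  mid <- character()
  for (g in dh) {
    w <- fca$WT[[g]]; d <- fca$DOUBLE[[g]]
    if (w == d) next
    between <- function(a) a >= min(w, d) && a <= max(w, d)
    if (between(fca$ASYM_A[[g]]) && between(fca$ASYM_B[[g]]))
      mid <- c(mid, g)
  }
  lab[mid] <- "UNASSIGNED"

  gss1 <- function(a, w, d) log2(abs(a - d) / abs(a - w))
  p_wt_a <- p_dbl_a <- p_wt_b <- p_dbl_b <- stats::setNames(
    numeric(length(mid)), mid)
  for (g in mid) {
    p_wt_a[g] <- oracle_t_p(fcl$ASYM_A[g, ], fcl$WT[g, ])
    p_dbl_a[g] <- oracle_t_p(fcl$ASYM_A[g, ], fcl$DOUBLE[g, ])
    p_wt_b[g] <- oracle_t_p(fcl$ASYM_B[g, ], fcl$WT[g, ])
    p_dbl_b[g] <- oracle_t_p(fcl$ASYM_B[g, ], fcl$DOUBLE[g, ])
  }

  ii <- mid[p_wt_a[mid] < alpha & p_dbl_a[mid] < alpha &
              p_wt_b[mid] < alpha & p_dbl_b[mid] < alpha]
  lab[ii] <- "II"

  gss_a <- vapply(mid, function(g)
    gss1(fca$ASYM_A[[g]], fca$WT[[g]], fca$DOUBLE[[g]]), numeric(1))
  gss_b <- vapply(mid, function(g)
    gss1(fca$ASYM_B[[g]], fca$WT[[g]], fca$DOUBLE[[g]]), numeric(1))

  if (length(ii) > 0) {
    pool <- c(gss_a[ii], gss_b[ii])
    pool <- pool[is.finite(pool)]
    gmax <- max(pool); gmin <- min(pool)
    for (g in setdiff(mid, ii)) {
      if (p_wt_a[g] >= alpha && p_dbl_a[g] < alpha && gss_a[g] > gmax &&
          p_wt_b[g] >= alpha && p_dbl_b[g] < alpha && gss_b[g] > gmax)
        lab[g] <- "III"
    }
    for (g in setdiff(mid, c(ii, names(lab)[lab == "III"]))) {
      if (p_wt_a[g] < alpha && p_dbl_a[g] >= alpha && gss_a[g] < gmin &&
          p_wt_b[g] < alpha && p_dbl_b[g] >= alpha && gss_b[g] < gmin)
        lab[g] <- "I"
    }
  } else {
    gmax <- gmin <- NA_real_
  }
  list(labels = lab, dh = dh, mid = mid, gss_max = gmax, gss_min = gmin)
}

# random replicate-FC fixture over the four strains of the genotype series;
# genes drawn from archetypes that exercise every branch of the classifier
random_fc_fixture <- function(n_genes, seed) {
  set.seed(seed)
  arch <- sample(c("null", "coop", "indep", "redund", "outside", "wild"),
                 n_genes, replace = TRUE,
                 prob = c(0.15, 0.15, 0.25, 0.2, 0.1, 0.15))
  genes <- sprintf("g%03d", seq_len(n_genes))
  sd <- 0.08
  strains <- c("WT", "ASYM_A", "ASYM_B", "DOUBLE")
  fcl <- lapply(strains, function(s)
    matrix(NA_real_, n_genes, 2, dimnames = list(genes, c("rep1", "rep2"))))
  names(fcl) <- strains
  for (i in seq_len(n_genes)) {
    base <- rnorm(1); eff <- runif(1, 0.8, 3) * sample(c(-1, 1), 1)
    w <- base; d <- base + eff
    a <- switch(arch[i],
                null = {d <- w; w},
                coop = d,
                indep = w + runif(1, 0.25, 0.75) * (d - w),
                redund = w,
                outside = w - sign(eff) * runif(1, 0.3, 1),
                wild = w + runif(1, -2, 3) * (d - w))
    fcl$WT[i, ] <- rnorm(2, w, sd)
    fcl$DOUBLE[i, ] <- rnorm(2, d, sd)
    fcl$ASYM_A[i, ] <- rnorm(2, a, sd)
    fcl$ASYM_B[i, ] <- rnorm(2, a, sd)
  }
  fcl
}

# classification labels over all genes from the package's own pipeline
package_classify_all <- function(fcl, alpha = 0.05) {
  fc <- average_fc(make_fc_table(fcl))
  resp <- screen_responsive(fc, alpha = alpha)
  mid <- build_mid_set(fc, resp)
  cls <- suppressWarnings(classify_clusters(fc, mid, alpha = alpha))
  lab <- stats::setNames(rep("NONE", length(fc$genes)), fc$genes)
  lab[cls$gene_id] <- cls$cluster
  list(labels = lab, dh = resp$gene_id, mid = mid,
       gss_max = attr(cls, "gss_max"), gss_min = attr(cls, "gss_min"))
}

# tiny 4-gene expression fixture used by the IO and fold-change tests
tiny_matrix <- function() {
  m <- rbind(ACT1 = c(100, 100, 100, 100),
             g1 = c(50, 200, 50, 200),
             g2 = c(10, 10, 10, 10),
             g3 = c(80, 20, 80, 20))
  colnames(m) <- c("WT_T0_r1", "WT_T1_r1", "WT_T0_r2", "WT_T1_r2")
  m
}

tiny_design <- function() {
  sample_design(data.frame(
    sample_id = c("WT_T0_r1", "WT_T1_r1", "WT_T0_r2", "WT_T1_r2"),
    strain_role = "WT",
    timepoint = c("T0", "T1", "T0", "T1"),
    replicate = c(1, 1, 2, 2)))
}
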