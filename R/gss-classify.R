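#' Mid betweenness statistic
#'
#' `Mid = (|FCa_asym - FCa_WT| + |FCa_asym - FCa_DOUBLE|) / |FCa_WT - FCa_DOUBLE|`.
#' By the triangle inequality Mid is always >= 1, and equals 1 exactly when
#' the asymmetric strain's average fold-change lies in the closed interval
#' between the wild-type and double-mutant values. If asymmetric
#' modification drives a gene, its single-tail response is expected to fall
#' between the two symmetric extremes, so Mid = 1 is the gate into the MID
#' subset.
#'
#' @param fca_asym,fca_wt,fca_double Average log2 fold-changes (vectorized).
#' @param eps Endpoints closer than `eps` are degenerate: the value is `NA`
#'   and a warning is raised (the gene is skipped).
#' @return Numeric vector of Mid values (>= 1, or `NA` where degenerate).
#' @export
mid_statistic <- function(fca_asym, fca_wt, fca_double, eps = 1e-12) {
  denom <- abs(fca_wt - fca_double)
  out <- (abs(fca_asym - fca_wt) + abs(fca_asym - fca_double)) / denom
  # inside the closed interval the statistic is identically 1; evaluating the
  # betweenness branch directly keeps that exact instead of 1 +/- 1 ulp
  between <- fca_asym >= pmin(fca_wt, fca_double) &
    fca_asym <= pmax(fca_wt, fca_double)
  out[which(between)] <- 1
  deg <- is.finite(denom) & denom < eps
  if (any(deg, na.rm = TRUE)) {
    warning(sum(deg, na.rm = TRUE),
            " gene(s) skipped: WT and DOUBLE fold-changes coincide",
            call. = FALSE)
    out[deg] <- NA_real_
  }
  out
}

#' Gene Skewness Score (GSS)
#'
#' `GSS = log2(|FCa_asym - FCa_DOUBLE| / |FCa_asym - FCa_WT|)`, defined for
#' genes whose asymmetric response lies between the two symmetric extremes
#' (Mid = 1). GSS = 0 at the exact midpoint; larger values mean the
#' asymmetric strain's response is skewed toward the wild type (redundant
#' behaviour), smaller (more negative) values mean skew toward the double
#' mutant (cooperative behaviour). On the extended reals, GSS is `+Inf`
#' when the asymmetric value coincides with the wild-type endpoint and
#' `-Inf` when it coincides with the double-mutant endpoint.
#'
#' @param fca_asym,fca_wt,fca_double Average log2 fold-changes (vectorized).
#' @return Numeric vector of GSS values (possibly `+/-Inf`).
#' @export
gss_score <- function(fca_asym, fca_wt, fca_double) {
  num <- abs(fca_asym - fca_double)
  den <- abs(fca_asym - fca_wt)
  out <- log2(num / den)
  # resolve 0/0 explicitly (asym equal to both endpoints is degenerate)
  out[num == 0 & den == 0] <- NaN
  out
}

#' Build the MID subset
#'
#' Responsive genes whose asymmetric response falls between the wild-type
#' and double-mutant responses in BOTH single-tail mutants
#' (`Mid <= 1 + tol` for each).
#'
#' @param fc An `fc_table` with `fca` filled (see [average_fc()]) containing
#'   strains `WT`, `DOUBLE`, `ASYM_A`, `ASYM_B`.
#' @param responsive A `responsive_set` from [screen_responsive()].
#' @param tol Betweenness tolerance on Mid (default `1e-9`).
#' @return Character vector of MID gene identifiers (in matrix order).
#' @export
build_mid_set <- function(fc, responsive, tol = 1e-9) {
  stopifnot(inherits(fc, "fc_table"))
  if (is.null(fc$fca))
    stop("run average_fc() before build_mid_set()", call. = FALSE)
  for (s in c("WT", "DOUBLE", "ASYM_A", "ASYM_B"))
    if (!s %in% colnames(fc$fca))
      stop("design error: strain role '", s, "' required", call. = FALSE)
  genes <- intersect(fc$genes, responsive$gene_id)
  if (length(genes) == 0L) return(character())
  fca <- fc$fca[genes, , drop = FALSE]
  mid_a <- mid_statistic(fca[, "ASYM_A"], fca[, "WT"], fca[, "DOUBLE"])
  mid_b <- mid_statistic(fca[, "ASYM_B"], fca[, "WT"], fca[, "DOUBLE"])
  keep <- !is.na(mid_a) & !is.na(mid_b) & mid_a <= 1 + tol & mid_b <= 1 + tol
  genes[keep]
}

#' Classify MID genes into cooperative, independent and redundant clusters
#'
#' Four-stage classification of the MID subset by pooled Student t-tests of
#' each asymmetric strain's replicate fold-changes against the wild-type and
#' double-mutant replicates (significance level `alpha`), applied to BOTH
#' asymmetric strains:
#'
#' * **Cluster II (independent):** each asymmetric strain differs
#'   significantly from both WT and DOUBLE. The extreme finite GSS values
#'   over Cluster II define `gss_max` and `gss_min`.
#' * **Cluster III (redundant):** remaining genes where each asymmetric
#'   strain does not differ from WT, differs from DOUBLE, and has
#'   `GSS > gss_max`.
#' * **Cluster I (cooperative):** remaining genes where each asymmetric
#'   strain differs from WT, does not differ from DOUBLE, and has
#'   `GSS < gss_min`.
#' * Everything else stays `UNASSIGNED`.
#'
#' Endpoint-coincident genes carry infinite GSS and participate in the
#' bound comparisons (`+Inf` can satisfy Cluster III, `-Inf` Cluster I).
#'
#' @param fc An `fc_table` with `fca` filled.
#' @param mid_set Character vector from [build_mid_set()].
#' @param alpha Significance level for the four endpoint tests
#'   (default 0.05).
#' @param bounds `"pooled"` (default) takes `gss_max`/`gss_min` over the
#'   finite GSS values of both asymmetric strains of Cluster II members;
#'   `"per_strain"` keeps separate bounds per asymmetric strain.
#' @param strains `"both"` (default) requires every condition of each
#'   cluster in both asymmetric strains; `"either"` is an exploratory mode
#'   requiring it in at least one.
#' @return A `gene_classification` data frame (one row per MID gene) with
#'   columns `gene_id`, `fca_wt`, `fca_asym_a`, `fca_asym_b`, `fca_double`,
#'   `mid_a`, `mid_b`, `gss_a`, `gss_b`, `p_wt_a`, `p_dbl_a`, `p_wt_b`,
#'   `p_dbl_b`, `cluster`, and attributes `gss_max`, `gss_min`, `alpha`.
#' @export
classify_clusters <- function(fc, mid_set, alpha = 0.05,
                              bounds = c("pooled", "per_strain"),
                              strains = c("both", "either")) {
  stopifnot(inherits(fc, "fc_table"))
  bounds <- match.arg(bounds)
  strains <- match.arg(strains)
  if (is.null(fc$fca))
    stop("run average_fc() before classify_clusters()", call. = FALSE)
  empty <- data.frame(gene_id = character(), fca_wt = numeric(),
                      fca_asym_a = numeric(), fca_asym_b = numeric(),
                      fca_double = numeric(), mid_a = numeric(),
                      mid_b = numeric(), gss_a = numeric(), gss_b = numeric(),
                      p_wt_a = numeric(), p_dbl_a = numeric(),
                      p_wt_b = numeric(), p_dbl_b = numeric(),
                      cluster = character(), stringsAsFactors = FALSE)
  if (length(mid_set) == 0L) {
    warning("MID set is empty; nothing to classify", call. = FALSE)
    attr(empty, "gss_max") <- NA_real_
    attr(empty, "gss_min") <- NA_real_
    attr(empty, "alpha") <- alpha
    class(empty) <- c("gene_classification", "data.frame")
    return(empty)
  }
  genes <- intersect(fc$genes, mid_set)
  fca <- fc$fca[genes, , drop = FALSE]
  W <- fc$fc[["WT"]][genes, , drop = FALSE]
  D <- fc$fc[["DOUBLE"]][genes, , drop = FALSE]
  A <- fc$fc[["ASYM_A"]][genes, , drop = FALSE]
  B <- fc$fc[["ASYM_B"]][genes, , drop = FALSE]

  res <- data.frame(
    gene_id = genes,
    fca_wt = fca[, "WT"], fca_asym_a = fca[, "ASYM_A"],
    fca_asym_b = fca[, "ASYM_B"], fca_double = fca[, "DOUBLE"],
    mid_a = mid_statistic(fca[, "ASYM_A"], fca[, "WT"], fca[, "DOUBLE"]),
    mid_b = mid_statistic(fca[, "ASYM_B"], fca[, "WT"], fca[, "DOUBLE"]),
    gss_a = gss_score(fca[, "ASYM_A"], fca[, "WT"], fca[, "DOUBLE"]),
    gss_b = gss_score(fca[, "ASYM_B"], fca[, "WT"], fca[, "DOUBLE"]),
    p_wt_a = .t_rows(A, W), p_dbl_a = .t_rows(A, D),
    p_wt_b = .t_rows(B, W), p_dbl_b = .t_rows(B, D),
    cluster = "UNASSIGNED",
    stringsAsFactors = FALSE, row.names = NULL)

  comb <- if (strains == "both") `&` else `|`

  sig_wt_a <- res$p_wt_a < alpha; sig_dbl_a <- res$p_dbl_a < alpha
  sig_wt_b <- res$p_wt_b < alpha; sig_dbl_b <- res$p_dbl_b < alpha

  ii <- comb(sig_wt_a & sig_dbl_a, sig_wt_b & sig_dbl_b)
  res$cluster[ii] <- "II"

  fin <- function(x) x[is.finite(x)]
  if (!any(ii)) {
    warning("classification bounds undefined: Cluster II is empty; ",
            "Clusters I and III left UNASSIGNED", call. = FALSE)
    gss_max <- gss_min <- NA_real_
    gss_max_a <- gss_min_a <- gss_max_b <- gss_min_b <- NA_real_
  } else if (bounds == "pooled") {
    pool <- fin(c(res$gss_a[ii], res$gss_b[ii]))
    gss_max <- gss_max_a <- gss_max_b <- max(pool)
    gss_min <- gss_min_a <- gss_min_b <- min(pool)
  } else {
    gss_max_a <- max(fin(res$gss_a[ii])); gss_min_a <- min(fin(res$gss_a[ii]))
    gss_max_b <- max(fin(res$gss_b[ii])); gss_min_b <- min(fin(res$gss_b[ii]))
    gss_max <- max(gss_max_a, gss_max_b); gss_min <- min(gss_min_a, gss_min_b)
  }

  if (any(ii)) {
    iii <- !ii & comb(!sig_wt_a & sig_dbl_a & res$gss_a > gss_max_a,
                      !sig_wt_b & sig_dbl_b & res$gss_b > gss_max_b)
    res$cluster[iii] <- "III"
    i1 <- !ii & !iii & comb(sig_wt_a & !sig_dbl_a & res$gss_a < gss_min_a,
                            sig_wt_b & !sig_dbl_b & res$gss_b < gss_min_b)
    res$cluster[i1] <- "I"
  }

  attr(res, "gss_max") <- gss_max
  attr(res, "gss_min") <- gss_min
  attr(res, "alpha") <- alpha
  attr(res, "bounds") <- bounds
  class(res) <- c("gene_classification", "data.frame")
  res
}

#' @export
print.gene_classification <- function(x, ...) {
  tab <- table(factor(x$cluster, levels = c("I", "II", "III", "UNASSIGNED")))
  cat("gene_classification:", nrow(x), "MID genes\n")
  cat(sprintf("  I (cooperative): %d  II (independent): %d  III (redundant): %d  unassigned: %d\n",
              tab["I"], tab["II"], tab["III"], tab["UNASSIGNED"]))
  cat(sprintf("  gss_min = %.4g, gss_max = %.4g (alpha = %g)\n",
              attr(x, "gss_min"), attr(x, "gss_max"), attr(x, "alpha")))
  invisible(x)
}
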