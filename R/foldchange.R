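#' Two-sample Student t-test with pooled variance
#'
#' Two-sided pooled-variance t-test, the test used throughout the screening
#' and classification stages (typically with two replicate fold-changes per
#' group). When the pooled variance is exactly zero the test is degenerate
#' and the p-value is 1 if the group means are equal and 0 otherwise, which
#' keeps the screens well-defined in the noise-free limit.
#'
#' @param a,b Numeric vectors, each with at least two finite values.
#' @return Two-sided p-value in `[0, 1]`.
#' @examples
#' student_t_two_sample(c(1, 2), c(3, 4))  # ~0.1056
#' @export
student_t_two_sample <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two values", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite values in t-test input", call. = FALSE)
  .t_pooled_p(mean(a), stats::var(a), length(a),
              mean(b), stats::var(b), length(b))
}

# vectorized pooled-variance two-sided p; degenerate pooled variance gives
# p = 1 for equal means and p = 0 otherwise
.t_pooled_p <- function(m1, v1, n1, m2, v2, n2) {
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs((m1 - m2) / se), df)
  deg <- sp2 == 0
  if (any(deg)) p[deg] <- ifelse(m1[deg] == m2[deg], 1, 0)
  p
}

# pooled t p-values between two genes-x-replicates matrices, row by row
.t_rows <- function(A, B) {
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1L)
  v2 <- rowSums((B - m2)^2) / (n2 - 1L)
  .t_pooled_p(m1, v1, n1, m2, v2, n2)
}

#' Compute reference-normalized log2 fold-changes
#'
#' For each gene, strain role and replicate, computes
#' `FC = log2((RPKM_T1 / ref_T1) / (RPKM_T0 / ref_T0))`, the glucose
#' starvation induction level normalized to the reference gene within each
#' sample. Genes with zero RPKM in any used sample are excluded (reason
#' `ZERO_RPKM`) unless a pseudocount is supplied.
#'
#' @param matrix Expression matrix (genes x samples, RPKM).
#' @param design A [sample_design()]; only non-`OTHER` strains with a `T1`
#'   sample enter the fold-change analysis.
#' @param pseudocount Optional nonnegative number added to every RPKM before
#'   ratios are formed (default `NULL`: zeros lead to exclusion instead).
#' @return An object of class `fc_table`: a list with elements `fc` (named
#'   list per strain role of genes x replicates FC matrices, `NA` for
#'   excluded genes), `fca` (filled by [average_fc()]), `exclusions` (data
#'   frame `gene_id`, `reason`), `genes`, `strains`, and `reference_gene`.
#' @export
compute_fc <- function(matrix, design, pseudocount = NULL) {
  matrix <- expression_matrix(matrix)
  if (!inherits(design, "sample_design"))
    design <- sample_design(design)
  ref <- attr(design, "reference_gene")

  d <- design[design$strain_role != "OTHER", , drop = FALSE]
  strains <- unique(d$strain_role[d$timepoint == "T1"])
  if (length(strains) == 0L)
    stop("design error: no strain has a T1 sample", call. = FALSE)
  d <- d[d$strain_role %in% strains, , drop = FALSE]

  missing <- setdiff(d$sample_id, colnames(matrix))
  if (length(missing) > 0L)
    stop("design sample(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!ref %in% rownames(matrix))
    stop("reference gene '", ref, "' absent from matrix", call. = FALSE)

  vals <- matrix[, d$sample_id, drop = FALSE]
  if (!is.null(pseudocount)) {
    if (!is.numeric(pseudocount) || pseudocount < 0)
      stop("pseudocount must be a nonnegative number", call. = FALSE)
    vals <- vals + pseudocount
  }
  if (any(vals[ref, ] == 0))
    stop("reference gene '", ref, "' has zero RPKM in a used sample",
         call. = FALSE)

  genes <- rownames(vals)
  zero <- apply(vals == 0, 1L, any)
  excl <- data.frame(gene_id = genes[zero],
                     reason = rep("ZERO_RPKM", sum(zero)),
                     stringsAsFactors = FALSE)

  fc <- list()
  for (s in strains) {
    reps <- sort(unique(d$replicate[d$strain_role == s]))
    m <- base::matrix(NA_real_, nrow = length(genes), ncol = length(reps),
                      dimnames = list(genes, paste0("rep", reps)))
    for (k in seq_along(reps)) {
      s1 <- d$sample_id[d$strain_role == s & d$timepoint == "T1" &
                          d$replicate == reps[k]]
      s0 <- d$sample_id[d$strain_role == s & d$timepoint == "T0" &
                          d$replicate == reps[k]]
      if (length(s1) != 1L || length(s0) != 1L)
        stop(sprintf("design error: strain %s replicate %d is not paired",
                     s, reps[k]), call. = FALSE)
      m[, k] <- log2((vals[, s1] / vals[ref, s1]) / (vals[, s0] / vals[ref, s0]))
    }
    m[zero, ] <- NA_real_
    fc[[s]] <- m
  }

  structure(list(fc = fc, fca = NULL, exclusions = excl, genes = genes,
                 strains = strains, reference_gene = ref),
            class = "fc_table")
}

#' @export
print.fc_table <- function(x, ...) {
  cat("fc_table:", length(x$genes), "genes,",
      length(x$strains), "strains (", paste(x$strains, collapse = ", "), ")\n")
  cat("  excluded:", nrow(x$exclusions), "genes\n")
  cat("  FCa:", if (is.null(x$fca)) "not yet averaged" else "filled", "\n")
  invisible(x)
}

#' Exclude genes with inconsistent replicate fold-changes
#'
#' The study excludes genes whose fold-change disagrees between the two
#' independent experiments. With a single FC value per replicate the default
#' criterion is the spread of the replicate FC values: a gene is excluded
#' (reason `REPLICATE_DISAGREEMENT`) when `max(FC) - min(FC)` exceeds
#' `threshold` in any strain role.
#'
#' @param fc An `fc_table` from [compute_fc()].
#' @param method `"absolute_difference"` (default) or `"none"`.
#' @param threshold Exclusion threshold in log2 units (default 1.0);
#'   `Inf` excludes nothing.
#' @return The `fc_table` with additional exclusions and the excluded genes'
#'   FC values set to `NA`.
#' @export
replicate_filter <- function(fc, method = c("absolute_difference", "none"),
                             threshold = 1.0) {
  stopifnot(inherits(fc, "fc_table"))
  method <- match.arg(method)
  if (method == "none") return(fc)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("threshold must be a single nonnegative number", call. = FALSE)
  spread <- rep(0, length(fc$genes))
  for (s in fc$strains) {
    m <- fc$fc[[s]]
    spread <- pmax(spread,
                   apply(m, 1L, max) - apply(m, 1L, min), na.rm = TRUE)
  }
  already <- fc$genes %in% fc$exclusions$gene_id
  bad <- !already & !is.na(spread) & spread > threshold
  if (any(bad)) {
    fc$exclusions <- rbind(fc$exclusions,
                           data.frame(gene_id = fc$genes[bad],
                                      reason = "REPLICATE_DISAGREEMENT",
                                      stringsAsFactors = FALSE))
    for (s in fc$strains) fc$fc[[s]][bad, ] <- NA_real_
    if (!is.null(fc$fca)) fc$fca[bad, ] <- NA_real_
  }
  fc
}

#' Average replicate fold-changes to FCa
#'
#' Fills the per-(gene, strain) average fold-change `FCa`, the arithmetic
#' mean of that gene's replicate FC values. Excluded genes carry `NA`.
#'
#' @param fc An `fc_table`.
#' @return The `fc_table` with `fca` filled (genes x strains matrix).
#' @export
average_fc <- function(fc) {
  stopifnot(inherits(fc, "fc_table"))
  fca <- base::matrix(NA_real_, nrow = length(fc$genes),
                      ncol = length(fc$strains),
                      dimnames = list(fc$genes, fc$strains))
  for (s in fc$strains) fca[, s] <- rowMeans(fc$fc[[s]])
  fc$fca <- fca
  fc
}

#' Screen modification-responsive genes (set DH)
#'
#' A gene is responsive when its replicate fold-changes differ significantly
#' between the wild-type and double-mutant strains (pooled Student t-test,
#' `p < alpha`). Excluded genes never enter the set.
#'
#' @param fc An `fc_table` containing `WT` and `DOUBLE` strains with at
#'   least two replicates each.
#' @param alpha Significance level (default 0.05).
#' @return A `responsive_set` data frame with columns `gene_id`, `p_value`
#'   (one row per member), with `alpha` attached as an attribute.
#' @export
screen_responsive <- function(fc, alpha = 0.05) {
  stopifnot(inherits(fc, "fc_table"))
  for (s in c("WT", "DOUBLE"))
    if (!s %in% fc$strains)
      stop("design error: strain role '", s, "' required for the screen",
           call. = FALSE)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be in [0, 1]", call. = FALSE)
  W <- fc$fc[["WT"]]; D <- fc$fc[["DOUBLE"]]
  if (ncol(W) < 2L || ncol(D) < 2L)
    stop("the screen needs >= 2 replicates for WT and DOUBLE", call. = FALSE)
  ok <- stats::complete.cases(W) & stats::complete.cases(D)
  p <- rep(NA_real_, length(fc$genes))
  p[ok] <- .t_rows(W[ok, , drop = FALSE], D[ok, , drop = FALSE])
  member <- ok & p < alpha
  out <- data.frame(gene_id = fc$genes[member], p_value = p[member],
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("responsive_set", "data.frame")
  out
}
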