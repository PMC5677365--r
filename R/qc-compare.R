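#' Steady-state two-strain expression comparison
#'
#' Global similarity of two strains' expression profiles at one timepoint:
#' per gene, the mean RPKM across replicates is computed per strain and
#' transformed as `log10(mean + 1)`; the report carries the Pearson
#' correlation of the transformed pairs, the slope of the least-squares fit
#' through the origin (`beta = sum(xy) / sum(x^2)`), and the uncentered
#' R-squared `1 - sum((y - beta*x)^2) / sum(y^2)` appropriate for a
#' no-intercept fit.
#'
#' @param matrix Expression matrix.
#' @param design A [sample_design()].
#' @param strain_a,strain_b Strain roles to compare (`strain_a` on x).
#' @param timepoint Timepoint at which to compare (default `"T0"`).
#' @return A `qc_report` list: `pearson_r`, `origin_slope`,
#'   `r_squared_uncentered`, `n_genes_compared`, `strain_a`, `strain_b`,
#'   `timepoint`.
#' @export
steady_state_comparison <- function(matrix, design, strain_a, strain_b,
                                    timepoint = "T0") {
  matrix <- expression_matrix(matrix)
  sa <- design$sample_id[design$strain_role == strain_a &
                           design$timepoint == timepoint]
  sb <- design$sample_id[design$strain_role == strain_b &
                           design$timepoint == timepoint]
  if (length(sa) < 1L || length(sb) < 1L)
    stop("each strain needs >= 1 sample at ", timepoint, call. = FALSE)
  miss <- setdiff(c(sa, sb), colnames(matrix))
  if (length(miss) > 0L)
    stop("design sample(s) absent from matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  x <- log10(rowMeans(matrix[, sa, drop = FALSE]) + 1)
  y <- log10(rowMeans(matrix[, sb, drop = FALSE]) + 1)
  if (length(x) < 3L)
    stop("insufficient data: fewer than 3 genes to compare", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("insufficient variance in transformed expression values",
         call. = FALSE)
  beta <- sum(x * y) / sum(x^2)
  structure(list(pearson_r = stats::cor(x, y),
                 origin_slope = beta,
                 r_squared_uncentered = 1 - sum((y - beta * x)^2) / sum(y^2),
                 n_genes_compared = length(x),
                 strain_a = strain_a, strain_b = strain_b,
                 timepoint = timepoint),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("steady-state comparison %s vs %s at %s (%d genes)\n",
              x$strain_a, x$strain_b, x$timepoint, x$n_genes_compared))
  cat(sprintf("  Pearson r = %.4f, origin slope = %.4f, uncentered R^2 = %.4f\n",
              x$pearson_r, x$origin_slope, x$r_squared_uncentered))
  invisible(x)
}

#' Differential-expression filter between two strains
#'
#' A gene is differentially expressed when its mean expression changes at
#' least `fold`-fold between the strains and a pooled Student t-test on
#' `log2(RPKM + pseudocount)` across replicates gives `p <= p_cut`. The
#' p-value here comes from a per-gene replicate t-test (the method is
#' recorded in the result), not from a count-model DE caller.
#'
#' @param matrix Expression matrix.
#' @param design A [sample_design()].
#' @param strain_a,strain_b Strain roles to compare; direction is the sign
#'   of `strain_b` relative to `strain_a`.
#' @param fold Fold-change threshold, >= 1 (default 2).
#' @param p_cut p-value cutoff (default 0.001).
#' @param pseudocount Added to RPKM before the log2 transform (default 0.5).
#' @param timepoint Timepoint at which to compare (default `"T0"`).
#' @return List with `de_up`, `de_down` (gene vectors, up = higher in
#'   `strain_b`), `table` (per-gene `log2_ratio`, `p_value`, `de`), and
#'   `method`.
#' @export
de_filter <- function(matrix, design, strain_a, strain_b, fold = 2,
                      p_cut = 0.001, pseudocount = 0.5, timepoint = "T0") {
  matrix <- expression_matrix(matrix)
  if (fold < 1) stop("fold must be >= 1", call. = FALSE)
  sa <- design$sample_id[design$strain_role == strain_a &
                           design$timepoint == timepoint]
  sb <- design$sample_id[design$strain_role == strain_b &
                           design$timepoint == timepoint]
  if (length(sa) < 2L || length(sb) < 2L)
    stop("each strain needs >= 2 replicates for the t-test", call. = FALSE)
  la <- log2(matrix[, sa, drop = FALSE] + pseudocount)
  lb <- log2(matrix[, sb, drop = FALSE] + pseudocount)
  ratio <- log2(rowMeans(matrix[, sb, drop = FALSE]) + pseudocount) -
    log2(rowMeans(matrix[, sa, drop = FALSE]) + pseudocount)
  p <- .t_rows(lb, la)
  de <- abs(ratio) >= log2(fold) & p <= p_cut
  genes <- rownames(matrix)
  list(de_up = genes[de & ratio > 0],
       de_down = genes[de & ratio < 0],
       table = data.frame(gene_id = genes, log2_ratio = ratio, p_value = p,
                          de = de, stringsAsFactors = FALSE, row.names = NULL),
       method = sprintf(
         "pooled Student t-test on log2(RPKM + %g); |log2 ratio| >= log2(%g), p <= %g",
         pseudocount, fold, p_cut))
}
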