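#' Genes significantly altered by SET1 deletion
#'
#' A gene is set1-responsive when its replicate fold-changes under
#' starvation differ significantly between the SET1 deletion strain and the
#' wild type (pooled Student t-test, `p < alpha`). These genes validate
#' that single-tail K-to-R effects act through methylation rather than the
#' mutation itself.
#'
#' @param fc An `fc_table` containing `SET1D` and `WT` strains with at
#'   least two replicates each.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of gene identifiers (in matrix order).
#' @export
set1_responsive_genes <- function(fc, alpha = 0.05) {
  stopifnot(inherits(fc, "fc_table"))
  for (s in c("SET1D", "WT"))
    if (!s %in% fc$strains)
      stop("design error: strain role '", s, "' required", call. = FALSE)
  S <- fc$fc[["SET1D"]]; W <- fc$fc[["WT"]]
  if (ncol(S) < 2L || ncol(W) < 2L)
    stop("need >= 2 replicates for SET1D and WT", call. = FALSE)
  ok <- stats::complete.cases(S) & stats::complete.cases(W)
  p <- rep(NA_real_, length(fc$genes))
  p[ok] <- .t_rows(S[ok, , drop = FALSE], W[ok, , drop = FALSE])
  fc$genes[ok & p < alpha]
}

#' Intersect the regulatory clusters with a gene set
#'
#' Computes the overlap of Clusters I, II and III with a second gene set
#' (typically the set1-responsive genes), mirroring a three-way Venn
#' analysis.
#'
#' @param classification A `gene_classification` from [classify_clusters()].
#' @param set1 Character vector of gene identifiers.
#' @return An `overlap_result` list: `set1_responsive`, `intersections`
#'   (named list of sorted gene vectors for I, II, III) and `sizes`.
#' @export
intersect_clusters <- function(classification, set1) {
  stopifnot(inherits(classification, "gene_classification"))
  set1 <- unique(as.character(set1))
  inter <- lapply(c(I = "I", II = "II", III = "III"), function(cl)
    sort(intersect(classification$gene_id[classification$cluster == cl], set1)))
  structure(list(set1_responsive = sort(set1),
                 intersections = inter,
                 sizes = vapply(inter, length, integer(1))),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap with set1-responsive genes (n =",
      length(x$set1_responsive), "):\n")
  cat(sprintf("  I: %d  II: %d  III: %d\n",
              x$sizes[["I"]], x$sizes[["II"]], x$sizes[["III"]]))
  invisible(x)
}

#' Count pathway memberships of a gene set
#'
#' Tallies how many genes of a set belong to each pathway of a
#' gene-to-pathway map; a gene belonging to several pathways counts toward
#' each, and genes with no mapping are tallied as unmapped. No enrichment
#' statistic is computed, only membership counts.
#'
#' @param genes Character vector of gene identifiers.
#' @param map Named list from [read_pathway_map()].
#' @return List with `counts` (data frame `pathway`, `count`, sorted by
#'   decreasing count then label), `n_unmapped`, and `n_genes`.
#' @export
pathway_counts <- function(genes, map) {
  genes <- unique(as.character(genes))
  labels <- unlist(lapply(genes, function(g) map[[g]]), use.names = FALSE)
  mapped <- vapply(genes, function(g) length(map[[g]]) > 0L, logical(1))
  if (length(labels) == 0L) {
    counts <- data.frame(pathway = character(), count = integer(),
                         stringsAsFactors = FALSE)
  } else {
    tab <- table(labels)
    counts <- data.frame(pathway = names(tab), count = as.integer(tab),
                         stringsAsFactors = FALSE)
    counts <- counts[order(-counts$count, counts$pathway), , drop = FALSE]
    rownames(counts) <- NULL
  }
  list(counts = counts,
       n_unmapped = sum(!mapped),
       n_genes = length(genes))
}
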