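#' Run the full classification pipeline and write result tables
#'
#' Orchestrates the whole analysis on one expression matrix:
#' fold-change computation, replicate-consistency filter, averaging,
#' responsive-gene screen, MID betweenness filter, cluster classification,
#' and (when the design contains them) the set1-deletion overlap, pathway
#' counts and the steady-state QC comparison. All result tables are written
#' as TSV/JSON under `out_dir` together with a run log recording every
#' parameter.
#'
#' @param matrix Expression matrix (genes x samples, RPKM).
#' @param design A [sample_design()].
#' @param out_dir Output directory (created if absent).
#' @param pathway_map Optional named list from [read_pathway_map()].
#' @param alpha Significance level for all screens (default 0.05).
#' @param mid_tol Betweenness tolerance on Mid (default `1e-9`).
#' @param replicate_method,replicate_threshold Replicate-consistency filter
#'   settings (see [replicate_filter()]).
#' @param pseudocount Optional pseudocount for [compute_fc()].
#' @param gss_bounds `"pooled"` or `"per_strain"` (see [classify_clusters()]).
#' @param qc_strains Length-2 character vector of strain roles for the
#'   steady-state QC comparison at T0, or `NULL` to skip (default
#'   `c("WT", "DOUBLE")`).
#' @return Invisibly, a list with the `fc_table`, `responsive` set,
#'   `mid_set`, `classification`, `overlap` (or `NULL`), `pathways` (or
#'   `NULL`), `qc` (or `NULL`) and `summary`.
#' @export
run_pipeline <- function(matrix, design, out_dir,
                         pathway_map = NULL, alpha = 0.05, mid_tol = 1e-9,
                         replicate_method = "absolute_difference",
                         replicate_threshold = 1.0,
                         pseudocount = NULL,
                         gss_bounds = "pooled",
                         qc_strains = c("WT", "DOUBLE")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    paste0(...))
    writeLines(line, log_con)
    message(line)
  }

  logmsg("sistergss ", as.character(utils::packageVersion("sistergss")),
         " pipeline start")
  logmsg(sprintf(
    "parameters: alpha=%g mid_tol=%g replicate_method=%s replicate_threshold=%g pseudocount=%s gss_bounds=%s",
    alpha, mid_tol, replicate_method, replicate_threshold,
    if (is.null(pseudocount)) "none" else format(pseudocount), gss_bounds))

  report <- validate_inputs(matrix, design)
  fatal <- report$type %in% c("missing_sample", "reference_missing",
                              "reference_zero")
  if (any(fatal))
    stop("input validation failed:\n  ",
         paste(report$message[fatal], collapse = "\n  "), call. = FALSE)
  for (m in report$message) logmsg("validation: ", m)

  fc <- compute_fc(matrix, design, pseudocount = pseudocount)
  fc <- replicate_filter(fc, method = replicate_method,
                         threshold = replicate_threshold)
  fc <- average_fc(fc)
  logmsg(sprintf("fold-changes: %d genes, %d excluded (%d ZERO_RPKM, %d REPLICATE_DISAGREEMENT)",
                 length(fc$genes), nrow(fc$exclusions),
                 sum(fc$exclusions$reason == "ZERO_RPKM"),
                 sum(fc$exclusions$reason == "REPLICATE_DISAGREEMENT")))

  responsive <- screen_responsive(fc, alpha = alpha)
  logmsg(sprintf("responsive screen: %d genes at p < %g", nrow(responsive),
                 alpha))
  mid_set <- build_mid_set(fc, responsive, tol = mid_tol)
  logmsg(sprintf("MID subset: %d genes between WT and DOUBLE in both asymmetric strains",
                 length(mid_set)))
  classification <- classify_clusters(fc, mid_set, alpha = alpha,
                                      bounds = gss_bounds)
  tab <- table(factor(classification$cluster,
                      levels = c("I", "II", "III", "UNASSIGNED")))
  logmsg(sprintf("clusters: I=%d II=%d III=%d unassigned=%d (gss_min=%.4g gss_max=%.4g)",
                 tab["I"], tab["II"], tab["III"], tab["UNASSIGNED"],
                 attr(classification, "gss_min"),
                 attr(classification, "gss_max")))

  overlap <- NULL
  pathways <- NULL
  if ("SET1D" %in% fc$strains) {
    set1 <- set1_responsive_genes(fc, alpha = alpha)
    overlap <- intersect_clusters(classification, set1)
    logmsg(sprintf("set1 overlap: |set1|=%d I=%d II=%d III=%d",
                   length(set1), overlap$sizes[["I"]],
                   overlap$sizes[["II"]], overlap$sizes[["III"]]))
    if (!is.null(pathway_map)) {
      pathways <- lapply(overlap$intersections, pathway_counts,
                         map = pathway_map)
      for (nm in names(pathways))
        logmsg(sprintf("pathways %s/set1: %d mapped labels, %d unmapped genes",
                       nm, nrow(pathways[[nm]]$counts),
                       pathways[[nm]]$n_unmapped))
    }
  } else {
    logmsg("no SET1D strain in design; overlap stage skipped")
  }

  qc <- NULL
  if (!is.null(qc_strains)) {
    qc <- steady_state_comparison(matrix, design, qc_strains[1L],
                                  qc_strains[2L], timepoint = "T0")
    logmsg(sprintf("QC %s vs %s: r=%.4f slope=%.4f R2=%.4f",
                   qc$strain_a, qc$strain_b, qc$pearson_r, qc$origin_slope,
                   qc$r_squared_uncentered))
  }

  .write_fc_tsv(fc, file.path(out_dir, "foldchange.tsv"))
  .write_classification_tsv(classification,
                            file.path(out_dir, "classification.tsv"))
  utils::write.table(
    data.frame(gene_id = responsive$gene_id, p_value = responsive$p_value),
    file.path(out_dir, "responsive.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(overlap)) {
    ov <- do.call(rbind, lapply(names(overlap$intersections), function(cl) {
      g <- overlap$intersections[[cl]]
      if (length(g) == 0L) return(NULL)
      data.frame(cluster = cl, gene_id = g, stringsAsFactors = FALSE)
    }))
    if (is.null(ov))
      ov <- data.frame(cluster = character(), gene_id = character())
    utils::write.table(ov, file.path(out_dir, "overlap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(pathways)) {
    pw <- do.call(rbind, lapply(names(pathways), function(nm) {
      ct <- pathways[[nm]]$counts
      if (nrow(ct) == 0L) return(NULL)
      data.frame(set_name = paste0(nm, "_set1"), pathway = ct$pathway,
                 count = ct$count, stringsAsFactors = FALSE)
    }))
    if (is.null(pw))
      pw <- data.frame(set_name = character(), pathway = character(),
                       count = integer())
    utils::write.table(pw, file.path(out_dir, "pathway_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(qc))
    jsonlite::write_json(list(pearson_r = qc$pearson_r,
                              origin_slope = qc$origin_slope,
                              r_squared = qc$r_squared_uncentered,
                              n_genes = qc$n_genes_compared,
                              strain_a = qc$strain_a,
                              strain_b = qc$strain_b),
                         file.path(out_dir, "qc.json"),
                         auto_unbox = TRUE, digits = NA)

  summary <- list(
    n_genes = length(fc$genes),
    n_excluded = nrow(fc$exclusions),
    n_responsive = nrow(responsive),
    n_mid = length(mid_set),
    n_cluster_I = as.integer(tab["I"]),
    n_cluster_II = as.integer(tab["II"]),
    n_cluster_III = as.integer(tab["III"]),
    n_unassigned = as.integer(tab["UNASSIGNED"]),
    gss_max = attr(classification, "gss_max"),
    gss_min = attr(classification, "gss_min"),
    alpha = alpha, mid_tol = mid_tol,
    replicate_method = replicate_method,
    replicate_threshold = replicate_threshold)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logmsg("pipeline done; results in ", out_dir)

  invisible(list(fc = fc, responsive = responsive, mid_set = mid_set,
                 classification = classification, overlap = overlap,
                 pathways = pathways, qc = qc, summary = summary))
}

# long-format fold-change table with exclusion flags
.write_fc_tsv <- function(fc, path) {
  rows <- lapply(fc$strains, function(s) {
    m <- fc$fc[[s]]
    data.frame(gene_id = rownames(m), strain_role = s,
               fc_rep1 = m[, 1L],
               fc_rep2 = if (ncol(m) >= 2L) m[, 2L] else NA_real_,
               fca = if (is.null(fc$fca)) NA_real_ else fc$fca[, s],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  idx <- match(out$gene_id, fc$exclusions$gene_id)
  out$excluded <- !is.na(idx)
  out$reason <- ifelse(out$excluded, fc$exclusions$reason[idx], "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_classification_tsv <- function(classification, path) {
  out <- as.data.frame(classification)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
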