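#' Validate a gene-by-sample expression matrix
#'
#' Checks the invariants every downstream step relies on: a numeric matrix of
#' finite, nonnegative RPKM values with unique gene identifiers as row names
#' and unique sample identifiers as column names.
#'
#' @param values Numeric matrix of RPKM values with gene identifiers as row
#'   names and sample identifiers as column names.
#' @return The validated matrix, unchanged.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("expression matrix must carry gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, ]
    stop(sprintf("invalid RPKM value %s at gene '%s', sample '%s' (must be finite and >= 0)",
                 format(values[i[1L], i[2L]]), genes[i[1L]], samples[i[2L]]),
         call. = FALSE)
  }
  values
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a UTF-8, tab-separated file whose first column holds gene
#' identifiers and whose header row holds sample identifiers. Lines starting
#' with `#` are ignored. Gene identifiers are opaque, case-sensitive strings.
#'
#' @param path Path to a tab-separated expression table.
#' @return A validated numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("expression matrix file needs a gene column and at least one sample column: ",
         path, call. = FALSE)
  # a header whose sample fields all parse as numbers is almost surely data
  hdr <- colnames(raw)[-1L]
  if (all(!is.na(suppressWarnings(as.numeric(hdr)))))
    stop("expression matrix file appears to lack a header row of sample identifiers: ",
         path, call. = FALSE)
  genes <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, ]
    stop(sprintf("non-numeric cell '%s' at gene '%s', sample '%s' in %s",
                 body[i[1L], i[2L]], genes[i[1L]], hdr[i[2L]], path),
         call. = FALSE)
  }
  dimnames(num) <- list(genes, hdr)
  expression_matrix(num)
}

#' Write an expression matrix to TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces every double exactly.
#'
#' @param x Expression matrix as from [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  x <- expression_matrix(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x))
  writeLines(paste(rownames(x), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Strain roles recognised by the pipeline
#' @keywords internal
.known_roles <- c("WT", "ASYM_A", "ASYM_B", "DOUBLE", "SET1D", "OTHER")

#' Construct a sample design
#'
#' A sample design maps each sample to a strain role (`WT` for the
#' heterodimer-only parent strain, `ASYM_A`/`ASYM_B` for the two single-tail
#' K-to-R mutants, `DOUBLE` for the double-tail mutant, `SET1D` for the
#' methyltransferase deletion), a timepoint (`T0` before and `T1` after
#' glucose starvation) and a replicate number, and carries the reference gene
#' used for fold-change normalization.
#'
#' @param data Data frame with columns `sample_id`, `strain_role`,
#'   `timepoint`, `replicate`.
#' @param reference_gene Gene identifier used for normalization
#'   (default `"ACT1"`).
#' @return A `sample_design` data frame with the reference gene attached as
#'   an attribute.
#' @export
sample_design <- function(data, reference_gene = "ACT1") {
  need <- c("sample_id", "strain_role", "timepoint", "replicate")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L)
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.character(reference_gene) || length(reference_gene) != 1L ||
      !nzchar(reference_gene))
    stop("reference_gene must be a single non-empty string", call. = FALSE)
  d <- data.frame(sample_id = as.character(data$sample_id),
                  strain_role = as.character(data$strain_role),
                  timepoint = as.character(data$timepoint),
                  replicate = as.integer(data$replicate),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample identifiers in sample sheet: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(unique(d$strain_role), .known_roles)
  if (length(unknown) > 0L) {
    warning("unknown strain role(s) mapped to OTHER: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    d$strain_role[d$strain_role %in% unknown] <- "OTHER"
  }
  if (!all(d$timepoint %in% c("T0", "T1")))
    stop("timepoint must be 'T0' or 'T1'", call. = FALSE)
  if (anyNA(d$replicate) || any(d$replicate < 1L))
    stop("replicate must be a positive integer", call. = FALSE)
  used <- d[d$strain_role != "OTHER", , drop = FALSE]
  key <- paste(used$strain_role, used$timepoint, used$replicate, sep = "|")
  if (anyDuplicated(key))
    stop("design error: duplicate (strain_role, timepoint, replicate): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  # strains with a starved (T1) sample must pair every replicate across timepoints
  for (role in setdiff(unique(used$strain_role), "OTHER")) {
    sub <- used[used$strain_role == role, , drop = FALSE]
    if (!any(sub$timepoint == "T1")) next
    reps <- unique(sub$replicate)
    for (r in reps) {
      have <- sub$timepoint[sub$replicate == r]
      if (!all(c("T0", "T1") %in% have))
        stop(sprintf("pairing error: strain %s replicate %d lacks a %s sample",
                     role, r, setdiff(c("T0", "T1"), have)[1L]), call. = FALSE)
    }
  }
  attr(d, "reference_gene") <- reference_gene
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Read a sample sheet from TSV
#'
#' @inheritParams sample_design
#' @param path Path to a tab-separated sample sheet with columns
#'   `sample_id`, `strain_role`, `timepoint`, `replicate`.
#' @return A validated [sample_design()].
#' @export
read_sample_sheet <- function(path, reference_gene = "ACT1") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  sample_design(raw, reference_gene = reference_gene)
}

#' Read a gene-to-pathway membership map from TSV
#'
#' One row per membership: `gene_id<TAB>pathway_label`. A gene may appear on
#' several rows; genes absent from the file are treated as unmapped.
#'
#' @param path Path to the two-column membership table.
#' @return Named list mapping each gene identifier to a character vector of
#'   pathway labels.
#' @export
read_pathway_map <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("pathway map needs columns gene_id and pathway_label: ", path,
         call. = FALSE)
  genes <- raw[[1L]]
  labels <- raw[[2L]]
  if (any(!nzchar(labels)))
    stop("empty pathway label in ", path, call. = FALSE)
  lapply(split(labels, genes), unique)
}

#' Cross-check an expression matrix against a sample design
#'
#' Report-only consistency check run before the fold-change stage. Findings
#' cover design samples absent from the matrix, a missing or zero-valued
#' reference gene, and genes with zero RPKM in any used sample (these will be
#' excluded from fold-change analysis, which requires that at least one read
#' was mapped in every sample used).
#'
#' @param matrix Expression matrix.
#' @param design A [sample_design()].
#' @return Data frame with columns `type`, `item`, `message`; zero rows when
#'   everything is consistent. Neither argument is modified.
#' @export
validate_inputs <- function(matrix, design) {
  matrix <- expression_matrix(matrix)
  findings <- list()
  add <- function(type, item, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      type = type, item = item, message = message, stringsAsFactors = FALSE)

  used <- design$sample_id[design$strain_role != "OTHER"]
  missing <- setdiff(used, colnames(matrix))
  for (s in missing)
    add("missing_sample", s, sprintf("design sample '%s' absent from matrix", s))
  present <- intersect(used, colnames(matrix))

  ref <- attr(design, "reference_gene")
  if (!ref %in% rownames(matrix)) {
    add("reference_missing", ref,
        sprintf("reference gene '%s' absent from matrix", ref))
  } else if (length(present) > 0L) {
    zero <- present[matrix[ref, present] == 0]
    for (s in zero)
      add("reference_zero", s,
          sprintf("reference gene '%s' has zero RPKM in sample '%s'", ref, s))
  }

  if (length(present) > 0L) {
    nz <- rownames(matrix)[apply(matrix[, present, drop = FALSE] == 0, 1L, any)]
    for (g in setdiff(nz, ref))
      add("zero_rpkm", g,
          sprintf("gene '%s' has zero RPKM in a used sample; it will be excluded", g))
  }

  if (length(findings) == 0L)
    return(data.frame(type = character(), item = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}
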