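#' Configuration for the synthetic experiment generator
#'
#' Defaults emulate the study design: ~6000 yeast genes, five strains
#' (WT, ASYM_A, ASYM_B, DOUBLE, SET1D), two timepoints (before/after
#' glucose starvation), two replicates, an ACT1 reference gene, roughly
#' 2500 modification-responsive genes (fraction 0.4) split among
#' cooperative / independent / redundant regulatory modes.
#'
#' @param n_genes Total genes including the reference gene (default 6000).
#' @param fraction_responsive Fraction of non-reference genes given a
#'   planted WT-vs-DOUBLE effect (default 0.4).
#' @param mode_proportions Named proportions of `COOPERATIVE`,
#'   `INDEPENDENT`, `REDUNDANT` within responsive genes (must sum to 1;
#'   default 0.10/0.50/0.40).
#' @param baseline_log2_mean,baseline_log2_sd Log2 baseline expression
#'   distribution (default mean 6, sd 2, i.e. typical RPKM ~ 64).
#' @param effect_range Range of `|FCa_WT - FCa_DOUBLE|` in log2 units,
#'   drawn uniformly with random sign (default `c(1, 3)`).
#' @param sigma Standard deviation of the replicate-level fold-change noise
#'   in log2 units (default 0.1); per-sample log2 noise is `sigma/sqrt(2)`
#'   at each timepoint so replicate FC values scatter with sd `sigma`.
#' @param lambda Mixing coefficient of the independent mode, strictly in
#'   (0, 1): true asymmetric FC is `lambda * FC_WT + (1 - lambda) * FC_DOUBLE`
#'   (default 0.5).
#' @param set1_overlap Fraction of responsive genes for which the SET1
#'   deletion phenocopies the double mutant (default 1).
#' @param zero_fraction Fraction of non-reference genes forced to zero RPKM
#'   in one random sample, to exercise the exclusion rule (default 0).
#' @param reference_gene Reference gene identifier (default `"ACT1"`).
#' @param reference_level Constant RPKM of the reference gene (default 1024).
#' @param seed Integer random seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 6000,
                              fraction_responsive = 0.4,
                              mode_proportions = c(COOPERATIVE = 0.10,
                                                   INDEPENDENT = 0.50,
                                                   REDUNDANT = 0.40),
                              baseline_log2_mean = 6,
                              baseline_log2_sd = 2,
                              effect_range = c(1, 3),
                              sigma = 0.1,
                              lambda = 0.5,
                              set1_overlap = 1,
                              zero_fraction = 0,
                              reference_gene = "ACT1",
                              reference_level = 1024,
                              seed = 1L) {
  if (n_genes < 2L) stop("n_genes must be >= 2 (reference gene included)",
                         call. = FALSE)
  if (fraction_responsive < 0 || fraction_responsive > 1)
    stop("fraction_responsive must be in [0, 1]", call. = FALSE)
  need <- c("COOPERATIVE", "INDEPENDENT", "REDUNDANT")
  if (!all(need %in% names(mode_proportions)) ||
      any(mode_proportions < 0) ||
      abs(sum(mode_proportions[need]) - 1) > 1e-8)
    stop("mode_proportions must be nonnegative, named ",
         paste(need, collapse = "/"), " and sum to 1", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (lambda <= 0 || lambda >= 1)
    stop("lambda must be strictly in (0, 1)", call. = FALSE)
  if (set1_overlap < 0 || set1_overlap > 1)
    stop("set1_overlap must be in [0, 1]", call. = FALSE)
  if (zero_fraction < 0 || zero_fraction > 1)
    stop("zero_fraction must be in [0, 1]", call. = FALSE)
  if (length(effect_range) != 2L || any(effect_range < 0) ||
      effect_range[1] > effect_range[2])
    stop("effect_range must be c(lo, hi) with 0 <= lo <= hi", call. = FALSE)
  if (reference_level <= 0)
    stop("reference_level must be positive", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 fraction_responsive = fraction_responsive,
                 mode_proportions = mode_proportions[need],
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 effect_range = effect_range, sigma = sigma,
                 lambda = lambda, set1_overlap = set1_overlap,
                 zero_fraction = zero_fraction,
                 reference_gene = reference_gene,
                 reference_level = reference_level,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate the five-strain, two-timepoint starvation experiment
#'
#' Generates an RPKM expression matrix (5 strains x 2 timepoints x 2
#' replicates = 20 samples), the matching sample design, and a ground-truth
#' table of planted regulatory modes. Per gene and strain, the T1 RPKM is
#' generated so that the reference-normalized log2 ratio to T0 equals the
#' planted fold-change plus Gaussian noise with sd `sigma`; the reference
#' gene is constant (zero planted fold-change, no noise). The same seed
#' yields bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return List with elements `matrix` (expression matrix), `design`
#'   ([sample_design()]) and `truth` (`truth_table` data frame with columns
#'   `gene_id`, `mode`, `fc_wt`, `fc_asym_a`, `fc_asym_b`, `fc_double`,
#'   `fc_set1d`).
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_other <- config$n_genes - 1L
  genes <- c(config$reference_gene,
             sprintf("YSG%04d", seq_len(n_other)))

  mode <- rep("NULL", n_other)
  n_resp <- round(config$fraction_responsive * n_other)
  resp_idx <- sample.int(n_other, n_resp)
  mode[resp_idx] <- sample(names(config$mode_proportions), n_resp,
                           replace = TRUE, prob = config$mode_proportions)

  base_fc <- stats::rnorm(n_other, 0, 1)   # shared starvation response
  effect <- numeric(n_other)
  effect[resp_idx] <- stats::runif(n_resp, config$effect_range[1],
                                   config$effect_range[2]) *
    sample(c(-1, 1), n_resp, replace = TRUE)

  fc_wt <- base_fc
  fc_double <- base_fc + effect
  fc_asym <- ifelse(mode == "COOPERATIVE", fc_double,
             ifelse(mode == "REDUNDANT", fc_wt,
             ifelse(mode == "INDEPENDENT",
                    config$lambda * fc_wt + (1 - config$lambda) * fc_double,
                    fc_wt)))
  set1_mimic <- rep(FALSE, n_other)
  set1_mimic[resp_idx] <- stats::runif(n_resp) < config$set1_overlap
  fc_set1d <- ifelse(set1_mimic, fc_double, fc_wt)

  truth <- data.frame(gene_id = genes[-1L], mode = mode,
                      fc_wt = fc_wt, fc_asym_a = fc_asym, fc_asym_b = fc_asym,
                      fc_double = fc_double, fc_set1d = fc_set1d,
                      stringsAsFactors = FALSE)
  class(truth) <- c("truth_table", "data.frame")

  strains <- c("WT", "ASYM_A", "ASYM_B", "DOUBLE", "SET1D")
  fc_by_strain <- cbind(WT = fc_wt, ASYM_A = fc_asym, ASYM_B = fc_asym,
                        DOUBLE = fc_double, SET1D = fc_set1d)

  reps <- 1:2
  design <- expand.grid(replicate = reps, timepoint = c("T0", "T1"),
                        strain_role = strains, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  design <- design[, c("strain_role", "timepoint", "replicate")]
  design$sample_id <- sprintf("%s_%s_r%d", design$strain_role,
                              design$timepoint, design$replicate)

  baseline <- stats::rnorm(n_other, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  sd_sample <- config$sigma / sqrt(2)
  mat <- base::matrix(0, nrow = config$n_genes, ncol = nrow(design),
                      dimnames = list(genes, design$sample_id))
  mat[1L, ] <- config$reference_level
  for (j in seq_len(nrow(design))) {
    shift <- if (design$timepoint[j] == "T1")
      fc_by_strain[, design$strain_role[j]] else 0
    noise <- if (sd_sample > 0) stats::rnorm(n_other, 0, sd_sample) else 0
    mat[-1L, j] <- 2^(baseline + shift + noise)
  }

  if (config$zero_fraction > 0) {
    n_zero <- round(config$zero_fraction * n_other)
    zi <- sample.int(n_other, n_zero)
    zj <- sample.int(nrow(design), n_zero, replace = TRUE)
    mat[cbind(zi + 1L, zj)] <- 0
  }

  list(matrix = expression_matrix(mat),
       design = sample_design(design[, c("sample_id", "strain_role",
                                         "timepoint", "replicate")],
                              reference_gene = config$reference_gene),
       truth = truth)
}

#' Expected cluster of each planted regulatory mode
#'
#' Oracle for parameter-recovery tests: a planted `COOPERATIVE` gene should
#' land in Cluster I, `INDEPENDENT` in II, `REDUNDANT` in III, and `NULL`
#' genes in no cluster.
#'
#' @param truth A `truth_table` from [simulate_experiment()].
#' @return Named character vector mapping each gene to
#'   `"I"`, `"II"`, `"III"` or `"NONE"`.
#' @export
truth_cluster <- function(truth) {
  stopifnot(is.data.frame(truth), all(c("gene_id", "mode") %in% names(truth)))
  map <- c(COOPERATIVE = "I", INDEPENDENT = "II", REDUNDANT = "III",
           "NULL" = "NONE")
  stats::setNames(unname(map[truth$mode]), truth$gene_id)
}
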