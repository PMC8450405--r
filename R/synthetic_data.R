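#' Default baseline expression means for simulation
#'
#' A frozen per-gene baseline of log2 TPM means covering every KB gene plus
#' the proteoglycan core-protein genes used in planted-change studies
#' (VCAN, DCN). Most baselines were drawn once from Uniform(0, 8) on the
#' log2 scale and frozen for test stability; the genes whose fold changes
#' are the usual study targets (CHST3, CHST15, VCAN, DCN, DSE) are pinned
#' at realistic tissue abundances (16-256 TPM), because the +1 pseudocount
#' in the fold-change statistic makes changes on genes below ~10 TPM
#' unrecoverable regardless of cohort size (see the methods vignette).
#'
#' @return Named numeric vector of log2 TPM means.
#' @export
default_baseline <- function() {
  path <- system.file("extdata", "baseline_log2_tpm.tsv", package = "gagmap",
                      mustWork = TRUE)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  setNames(tab$log2_tpm_mean, tab$gene)
}

#' The 37 reference tissues and their planted expression archetypes
#'
#' Tissue panel emulating a consensus human tissue atlas. Twenty tissues
#' (cerebral cortex, reproductive and glandular tissues, lymphoid organs,
#' skin, lung, ...) form the HIGH_GAG archetype with elevated expression of
#' GAG biosynthesis genes, mirroring the high-expression tissue cluster
#' seen in atlas profiling; the remaining seventeen (liver, pancreas,
#' muscle, digestive tract, ...) are LOW_GAG.
#'
#' @return Named character vector: tissue -> `"HIGH_GAG"` or `"LOW_GAG"`.
#' @export
default_tissue_archetypes <- function() {
  high <- c("cerebral cortex", "thyroid gland", "placenta", "testis",
            "ovary", "endometrium", "smooth muscle", "cervix/uterine",
            "prostate", "fallopian tube", "seminal vesicle", "adrenal gland",
            "parathyroid gland", "spleen", "lymph node", "skin", "lung",
            "urinary bladder", "appendix", "gallbladder")
  low <- c("tonsil", "liver", "skeletal muscle", "pancreas",
           "salivary gland", "heart muscle", "duodenum", "small intestine",
           "colon", "rectum", "kidney", "stomach", "esophagus",
           "adipose tissue", "bone marrow", "breast", "thymus")
  setNames(c(rep("HIGH_GAG", length(high)), rep("LOW_GAG", length(low))),
           c(high, low))
}

#' Configure a tissue-panel simulation
#'
#' @param archetypes Named character vector mapping tissue names to
#'   `"HIGH_GAG"`/`"LOW_GAG"`; default [default_tissue_archetypes()]
#'   (37 tissues).
#' @param delta Archetype effect: log2 TPM added to GAG biosynthesis
#'   (reaction) genes in HIGH_GAG tissues. Default 3 (an 8-fold shift).
#' @param noise_sd Standard deviation of log2-scale Gaussian noise
#'   (log-normal noise on TPM). Default 0.3.
#' @param baseline Named log2 TPM means; default [default_baseline()].
#' @param seed Integer RNG seed; fixed seed implies identical output.
#' @return A validated config list of class `gag_sim_config`.
#' @export
tissue_sim_config <- function(archetypes = default_tissue_archetypes(),
                              delta = 3, noise_sd = 0.3,
                              baseline = default_baseline(), seed = 1L) {
  if (is.null(names(archetypes)) || any(names(archetypes) == ""))
    stop("archetypes must be named by tissue")
  if (!all(archetypes %in% c("HIGH_GAG", "LOW_GAG")))
    stop("archetypes must be 'HIGH_GAG' or 'LOW_GAG'")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(kind = "tissues", archetypes = archetypes, delta = delta,
                 noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed)),
            class = "gag_sim_config")
}

#' Configure a tumor/normal cohort simulation
#'
#' @param n_tumor,n_normal Cohort sizes. Default 100 per arm, a desk-scale
#'   stand-in for the thousand-sample public cohorts the pipeline targets.
#' @param planted_fc Named numeric vector of true multiplicative fold
#'   changes applied to the tumor arm (values > 0); genes not listed are
#'   unchanged. Genes outside the KB (e.g. proteoglycan core proteins) are
#'   allowed and added to the simulated matrix.
#' @param noise_sd Log2-scale noise sd. Default 0.5.
#' @param baseline Named log2 TPM means; default [default_baseline()].
#'   Every planted gene must have a baseline entry.
#' @param seed Integer RNG seed.
#' @return A validated config list of class `gag_sim_config`.
#' @export
cohort_sim_config <- function(n_tumor = 100L, n_normal = 100L,
                              planted_fc = numeric(0), noise_sd = 0.5,
                              baseline = default_baseline(), seed = 1L) {
  if (n_tumor < 1L || n_normal < 1L) stop("cohort sizes must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(planted_fc) > 0L) {
    if (is.null(names(planted_fc)) || any(names(planted_fc) == ""))
      stop("planted_fc must be named by gene symbol")
    if (any(planted_fc <= 0)) stop("planted_fc values must be > 0")
    missing_base <- setdiff(names(planted_fc), names(baseline))
    if (length(missing_base) > 0L)
      stop("planted genes lack a baseline mean: ",
           paste(missing_base, collapse = ", "))
  }
  structure(list(kind = "cohorts", n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal), planted_fc = planted_fc,
                 noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed)),
            class = "gag_sim_config")
}

# Run fn with a locally seeded RNG, restoring the caller's RNG state.
with_sim_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate a tissue-panel expression matrix with two planted archetypes
#'
#' Draws one TPM column per tissue: log2 TPM = baseline + archetype offset
#' + Gaussian noise, exponentiated to the TPM scale (log-normal expression
#' noise, the standard bulk RNA-seq noise model on relative abundances).
#' HIGH_GAG tissues receive `delta` extra log2 units on every GAG
#' biosynthesis (reaction) gene; auxiliary genes are unaffected, so the
#' archetype signal lives where pathway profiling looks for it. Columns are
#' never renormalized, so planted effects are exactly recoverable in
#' expectation.
#'
#' @param config A `gag_sim_config` from [tissue_sim_config()].
#' @param kb A `gag_kb`; default packaged KB (defines the gene list).
#' @return List with `matrix` (a `gag_expr`, genes x tissues) and `truth`
#'   (list with `archetype_assignment`).
#' @export
simulate_tissues <- function(config = tissue_sim_config(), kb = load_kb()) {
  stopifnot(inherits(config, "gag_sim_config"))
  if (config$kind != "tissues") stop("config is not a tissue simulation")
  genes <- kb_genes(kb)
  missing_base <- setdiff(genes, names(config$baseline))
  if (length(missing_base) > 0L)
    stop("baseline lacks KB genes: ", paste(missing_base, collapse = ", "))
  reaction_genes <- kb_genes(kb, include_auxiliary = FALSE)
  tissues <- names(config$archetypes)
  base <- config$baseline[genes]
  with_sim_seed(config$seed, function() {
    log2tpm <- sapply(tissues, function(t) {
      offset <- ifelse(genes %in% reaction_genes &
                         config$archetypes[[t]] == "HIGH_GAG",
                       config$delta, 0)
      base + offset + rnorm(length(genes), 0, config$noise_sd)
    })
    rownames(log2tpm) <- genes
    m <- expression_matrix(2^log2tpm)
    list(matrix = m,
         truth = list(archetype_assignment = config$archetypes))
  })
}

#' Simulate tumor and normal cohorts with planted fold changes
#'
#' The normal arm draws TPM = 2^(baseline + noise); the tumor arm
#' multiplies the TPM scale of each planted gene by its fold change
#' (equivalently adds log2 fc to the gene's mean) before noise. Because the
#' median of a log-normal equals its scale, the planted fold change is
#' exactly the ratio of true medians, making it recoverable by the
#' median-based fold-change estimator without bias.
#'
#' @param config A `gag_sim_config` from [cohort_sim_config()].
#' @param kb A `gag_kb`; default packaged KB.
#' @param up,down Thresholds used to record each gene's expected direction
#'   in the truth table; defaults 1.5 and 1/1.5.
#' @return List with `tumor` and `normal` (`gag_expr` matrices whose
#'   samples are labeled `"tumor"`/`"normal"`) and `truth` (list with
#'   `planted_fc` and `expected_direction`, the classification of the true
#'   fold change under the thresholds).
#' @export
simulate_cohorts <- function(config = cohort_sim_config(), kb = load_kb(),
                             up = 1.5, down = 1 / up) {
  stopifnot(inherits(config, "gag_sim_config"))
  if (config$kind != "cohorts") stop("config is not a cohort simulation")
  genes <- unique(c(kb_genes(kb), names(config$planted_fc)))
  missing_base <- setdiff(genes, names(config$baseline))
  if (length(missing_base) > 0L)
    stop("baseline lacks genes: ", paste(missing_base, collapse = ", "))
  base <- config$baseline[genes]
  fc <- setNames(rep(1, length(genes)), genes)
  fc[names(config$planted_fc)] <- config$planted_fc
  with_sim_seed(config$seed, function() {
    draw <- function(n, means, prefix) {
      log2tpm <- sapply(seq_len(n), function(i)
        means + rnorm(length(means), 0, config$noise_sd))
      dimnames(log2tpm) <- list(genes, paste0(prefix, "_", seq_len(n)))
      groups <- setNames(rep(prefix, n), colnames(log2tpm))
      expression_matrix(2^log2tpm, sample_groups = groups)
    }
    normal <- draw(config$n_normal, base, "normal")
    tumor <- draw(config$n_tumor, base + log2(fc), "tumor")
    list(tumor = tumor, normal = normal,
         truth = list(
           planted_fc = config$planted_fc,
           expected_direction = classify_direction(fc, up = up, down = down)
         ))
  })
}
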