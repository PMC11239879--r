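#' Parameters for the synthetic BioID2 LFQ experiment generator
#'
#' Describes a simulated proximity-labeling LFQ experiment with the study
#' layout: 2 constructs (cilia-BioID2, whole-cell BioID2 control) x 2
#' genotypes (WT, KO) x `n_reps` technical replicates. Protein baselines are
#' log-normal; a spiked subset changes in the cilia-BioID2 KO samples only
#' (a genuine ciliary effect), a contaminant subset changes in the KO
#' samples of both constructs (a whole-cell effect that the control
#' contrast should catch); low-intensity values drop out to 0 with a
#' logistic intensity-dependent probability.
#'
#' @param n_proteins number of proteins.
#' @param n_reps technical replicates per (construct, genotype) group.
#' @param baseline_log2_mean,baseline_log2_sd mean and sd of per-protein
#'   baseline log2 intensities.
#' @param rep_noise_sd replicate noise sd in log2 units.
#' @param n_spiked number of spiked proteins.
#' @param spike_log2fc log2 fold change applied to spiked proteins in
#'   cilia-BioID2 KO samples only (negative = depleted from the cilium).
#' @param n_contaminants number of contaminant proteins.
#' @param contaminant_log2fc log2 fold change applied to contaminants in the
#'   KO samples of both constructs.
#' @param dropout_slope,dropout_midpoint parameters of the dropout law
#'   `P(zero) = plogis(dropout_slope * (dropout_midpoint - log2 intensity))`;
#'   a slope of 0 disables dropout.
#' @param seed integer seed.
#' @return an object of class `synth_proteomics_params`.
#' @seealso [generate_lfq_experiment()]
#' @export
synth_proteomics_params <- function(n_proteins = 2000L,
                                    n_reps = 6L,
                                    baseline_log2_mean = 25,
                                    baseline_log2_sd = 2,
                                    rep_noise_sd = 0.5,
                                    n_spiked = 100L,
                                    spike_log2fc = -2,
                                    n_contaminants = 100L,
                                    contaminant_log2fc = -2,
                                    dropout_slope = 1,
                                    dropout_midpoint = 21,
                                    seed = 1L) {
  p <- list(n_proteins = as.integer(n_proteins), n_reps = as.integer(n_reps),
            baseline_log2_mean = baseline_log2_mean,
            baseline_log2_sd = baseline_log2_sd,
            rep_noise_sd = rep_noise_sd,
            n_spiked = as.integer(n_spiked), spike_log2fc = spike_log2fc,
            n_contaminants = as.integer(n_contaminants),
            contaminant_log2fc = contaminant_log2fc,
            dropout_slope = dropout_slope,
            dropout_midpoint = dropout_midpoint,
            seed = as.integer(seed))
  if (p$n_reps < 2L) stopf("`n_reps` must be >= 2 (t-test undefined below)")
  if (p$n_spiked + p$n_contaminants > p$n_proteins)
    stopf("n_spiked + n_contaminants must not exceed n_proteins")
  if (p$baseline_log2_sd < 0 || p$rep_noise_sd < 0)
    stopf("standard deviations must be >= 0")
  if (p$dropout_slope < 0) stopf("`dropout_slope` must be >= 0")
  class(p) <- "synth_proteomics_params"
  p
}

#' Simulate a BioID2 LFQ experiment with known ground truth
#'
#' Draws the 2 x 2 x `n_reps` sample intensity matrix described by
#' `params`, applies intensity-dependent dropout, and returns the matrix
#' together with the protein class labels and true per-contrast log2 fold
#' changes. Deterministic given `params` (per-protein sub-streams are
#' derived from the seed, so adding proteins does not reshuffle earlier
#' ones).
#'
#' @param params a [synth_proteomics_params()] object.
#' @return list with `matrix` (an [lfq_matrix()]) and `truth` (data.frame
#'   with columns `protein`, `class` in `null|spiked|contaminant`,
#'   `true_lfc_cilia`, `true_lfc_control`).
#' @examples
#' sim <- generate_lfq_experiment(synth_proteomics_params(n_proteins = 50L,
#'                                                        seed = 3L))
#' table(sim$truth$class)
#' @export
generate_lfq_experiment <- function(params) {
  stopifnot(inherits(params, "synth_proteomics_params"))
  p <- params
  grid <- expand.grid(replicate = seq_len(p$n_reps),
                      genotype = c("WT", "KO"),
                      construct = c("cilia-BioID2", "BioID2"),
                      stringsAsFactors = FALSE)
  design <- data.frame(
    sample = sprintf("%s_%s_r%d",
                     ifelse(grid$construct == "cilia-BioID2",
                            "ciliaBioID2", "BioID2"),
                     grid$genotype, grid$replicate),
    construct = grid$construct, genotype = grid$genotype,
    replicate = grid$replicate)
  ids <- sprintf("P%05d", seq_len(p$n_proteins))
  cls <- rep("null", p$n_proteins)
  if (p$n_spiked > 0L) cls[seq_len(p$n_spiked)] <- "spiked"
  if (p$n_contaminants > 0L)
    cls[p$n_spiked + seq_len(p$n_contaminants)] <- "contaminant"

  seeds <- derive_seeds(p$seed, p$n_proteins)
  n_samp <- nrow(design)
  is_ko <- design$genotype == "KO"
  is_cilia <- design$construct == "cilia-BioID2"
  m <- matrix(0, p$n_proteins, n_samp,
              dimnames = list(ids, design$sample))
  for (i in seq_len(p$n_proteins)) {
    set.seed(seeds[i])
    base <- rnorm(1, p$baseline_log2_mean, p$baseline_log2_sd)
    eff <- numeric(n_samp)
    if (cls[i] == "spiked") eff[is_ko & is_cilia] <- p$spike_log2fc
    if (cls[i] == "contaminant") eff[is_ko] <- p$contaminant_log2fc
    l2 <- base + eff + rnorm(n_samp, 0, p$rep_noise_sd)
    v <- 2^l2
    if (p$dropout_slope > 0) {
      pz <- plogis(p$dropout_slope * (p$dropout_midpoint - l2))
      v[runif(n_samp) < pz] <- 0
    }
    m[i, ] <- v
  }
  truth <- data.frame(
    protein = ids, class = cls,
    true_lfc_cilia = ifelse(cls == "spiked", p$spike_log2fc,
                            ifelse(cls == "contaminant",
                                   p$contaminant_log2fc, 0)),
    true_lfc_control = ifelse(cls == "contaminant", p$contaminant_log2fc, 0))
  list(matrix = lfq_matrix(m, design), truth = truth)
}
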