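#' Imputation parameters for missing LFQ values
#'
#' Missing (zero) LFQ values are replaced, per protein and per
#' (construct, genotype) group, by draws from a downshifted normal
#' distribution in log2 space, but only when zeros occupy fewer than half
#' of the group's replicates. Two readings of the downshift are provided:
#'
#' * `perseus_sd` (default): mean = mean(log2 nonzero) - `downshift` *
#'   sd(log2 nonzero), sd = `width_factor` * sd(log2 nonzero) - the
#'   Perseus-style convention where the downshift is expressed in standard
#'   deviations.
#' * `literal_mean`: mean = mean(log2 nonzero) / `downshift`, sd =
#'   `width_factor` * mean(log2 nonzero) - a literal scaling of the mean,
#'   provided for sensitivity analysis.
#'
#' @param downshift dimensionless downshift (default 1.8).
#' @param width_factor dimensionless width factor (default 0.5).
#' @param mode `"perseus_sd"` or `"literal_mean"`.
#' @param seed integer seed making the draws reproducible.
#' @return an object of class `imputation_params`.
#' @export
imputation_params <- function(downshift = 1.8, width_factor = 0.5,
                              mode = c("perseus_sd", "literal_mean"),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (!is.finite(downshift) || downshift <= 0) stopf("`downshift` must be > 0")
  if (!is.finite(width_factor) || width_factor < 0)
    stopf("`width_factor` must be >= 0")
  structure(list(downshift = downshift, width_factor = width_factor,
                 mode = mode, seed = as.integer(seed)),
            class = "imputation_params")
}

#' Impute missing LFQ values from a downshifted normal distribution
#'
#' Operates per protein per (construct, genotype) group in log2 space. A
#' zero cell is eligible when zeros occupy fewer than half of the group's
#' replicates while the remaining replicates are nonzero; groups with at
#' least half zeros are left untouched (their zeros are treated as genuine
#' absence and handled downstream by the median/pseudovalue path). Nonzero
#' entries are never modified. Deterministic under `params$seed`.
#'
#' @param mat an [lfq_matrix()].
#' @param params an [imputation_params()].
#' @return an [lfq_matrix()] with eligible zeros replaced.
#' @export
impute_missing <- function(mat, params = imputation_params()) {
  stopifnot(inherits(mat, "lfq_matrix"), inherits(params, "imputation_params"))
  m <- mat$intensities
  groups <- split(seq_len(ncol(m)),
                  paste(mat$design$construct, mat$design$genotype))
  set.seed(params$seed)
  for (gi in seq_along(groups)) {
    cols <- groups[[gi]]
    sub <- m[, cols, drop = FALSE]
    nz <- rowSums(sub == 0)
    eligible <- which(nz > 0 & nz < length(cols) / 2)
    for (i in eligible) {
      vals <- sub[i, ]
      lv <- log2(vals[vals > 0])
      if (length(lv) < 2L) {
        warnf("protein %s: only one nonzero value in a group; sd undefined, zeros left untouched",
              rownames(m)[i])
        next
      }
      if (params$mode == "perseus_sd") {
        mu <- mean(lv) - params$downshift * sd(lv)
        sg <- params$width_factor * sd(lv)
      } else {
        mu <- mean(lv) / params$downshift
        sg <- params$width_factor * mean(lv)
      }
      z <- which(vals == 0)
      m[i, cols[z]] <- 2^rnorm(length(z), mu, sg)
    }
  }
  lfq_matrix(m, mat$design)
}

#' Per-protein log2 KO/WT ratio of group medians, with pseudovalues
#'
#' For one construct, computes `log2(median KO / median WT)` per protein
#' over that construct's samples (medians taken after imputation, zeros
#' included). When exactly one group median is zero the ratio is infinite
#' and is replaced by a pseudovalue placed two units beyond the observed
#' finite-ratio range: `+Inf` becomes `max(finite) + 2`, `-Inf` becomes
#' `min(finite) - 2`. Proteins with both medians zero are dropped from the
#' contrast (ratio `NA`, `ratio_type = "dropped"`).
#'
#' @param mat an [lfq_matrix()] (imputation already applied).
#' @param contrast `"cilia-BioID2"` or `"BioID2"`.
#' @return data.frame with columns `protein`, `log2_ratio`, `ratio_type`
#'   (`finite`, `pseudo_high`, `pseudo_low`, `dropped`).
#' @export
group_log2_ratio <- function(mat, contrast = c("cilia-BioID2", "BioID2")) {
  contrast <- match.arg(contrast)
  m <- mat$intensities
  ko <- group_columns(mat, contrast, "KO")
  wt <- group_columns(mat, contrast, "WT")
  med_ko <- apply(m[, ko, drop = FALSE], 1L, median)
  med_wt <- apply(m[, wt, drop = FALSE], 1L, median)
  ratio <- ifelse(med_ko == 0 & med_wt == 0, NA_real_,
                  ifelse(med_wt == 0, Inf,
                         ifelse(med_ko == 0, -Inf, log2(med_ko / med_wt))))
  type <- ifelse(is.na(ratio), "dropped",
                 ifelse(ratio == Inf, "pseudo_high",
                        ifelse(ratio == -Inf, "pseudo_low", "finite")))
  fin <- ratio[is.finite(ratio)]
  if (any(is.infinite(ratio)) && length(fin) == 0L)
    stopf("all ratios are infinite in the %s contrast; no finite reference for pseudovalues",
          contrast)
  ratio[ratio == Inf] <- max(fin) + 2
  ratio[ratio == -Inf] <- min(fin) - 2
  n_drop <- sum(type == "dropped")
  if (n_drop > 0L)
    message(n_drop, " protein(s) dropped from the ", contrast,
            " contrast (both group medians zero)")
  data.frame(protein = rownames(m), log2_ratio = ratio, ratio_type = type,
             row.names = NULL)
}

## two-sample equal-variance Student's t on log2 of nonzero intensities;
## handles the zero-variance degeneracies t.test() refuses
student_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- if (na > 1L) var(a) else NA_real_
  vb <- if (nb > 1L) var(b) else NA_real_
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  if (sp2 == 0) return(if (mean(a) == mean(b)) 1 else 0)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(tt), na + nb - 2)
}

#' Per-protein Student's t-test with Benjamini-Hochberg correction
#'
#' Two-sided, two-sample, equal-variance Student's t-test comparing KO vs
#' WT log2 intensities of one construct, zeros excluded as "not
#' quantified". Proteins with fewer than two quantified values in either
#' group get `t_p = NA` and are non-significant by default. BH correction
#' is applied across all tested proteins of the contrast.
#'
#' @param mat an [lfq_matrix()] (imputation already applied).
#' @param contrast `"cilia-BioID2"` or `"BioID2"`.
#' @return data.frame with columns `protein`, `t_p`, `q`.
#' @export
ttest_bh <- function(mat, contrast = c("cilia-BioID2", "BioID2")) {
  contrast <- match.arg(contrast)
  m <- mat$intensities
  ko <- group_columns(mat, contrast, "KO")
  wt <- group_columns(mat, contrast, "WT")
  t_p <- vapply(seq_len(nrow(m)), function(i) {
    a <- m[i, ko]; a <- log2(a[a > 0])
    b <- m[i, wt]; b <- log2(b[b > 0])
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    student_t_p(a, b)
  }, 0)
  n_untested <- sum(is.na(t_p))
  if (n_untested > 0L)
    message(n_untested, " protein(s) with < 2 quantified values per group: ",
            "t-test undefined, non-significant by default")
  q <- rep(NA_real_, length(t_p))
  tested <- !is.na(t_p)
  q[tested] <- p.adjust(t_p[tested], method = "BH")
  data.frame(protein = rownames(m), t_p = t_p, q = q, row.names = NULL)
}

#' Significance A outlier test for log2 ratios
#'
#' Robust outlier p-value for each ratio, derived from the ratio
#' distribution's 15.87th, 50th and 84.13th percentiles (r-1, r0, r1): for
#' r > r0 the robust z-score is `(r - r0) / (r1 - r0)`, for r < r0 it is
#' `(r0 - r) / (r0 - r-1)`, and `p = erfc(z / sqrt(2)) / 2` - the estimated
#' tail probability of a ratio at least that extreme in the observed
#' direction. This is the convention of the Perseus-style analysis the
#' pipeline reproduces; note that under a symmetric null it yields
#' `P(p <= alpha) = 2 * alpha` because both tails are scored. Set
#' `two_sided = TRUE` to double (and cap at 1) the p-values if calibrated
#' two-sided probabilities are wanted instead. Pseudovalue-substituted
#' ratios participate like any other ratio.
#'
#' @param log2_ratios numeric vector of finite log2 ratios (NAs allowed and
#'   returned as NA).
#' @param min_n minimum number of finite ratios needed to estimate the
#'   percentiles (default 20).
#' @param two_sided logical; double the directional tail probability.
#' @return numeric vector of Significance A p-values, parallel to the
#'   input.
#' @export
significance_a <- function(log2_ratios, min_n = 20L, two_sided = FALSE) {
  r <- log2_ratios
  fin <- r[is.finite(r)]
  if (length(fin) < min_n)
    stopf("need at least %d finite ratios to estimate the percentiles", min_n)
  qs <- quantile(fin, c(0.1587, 0.5, 0.8413), names = FALSE, type = 7)
  rm1 <- qs[1L]; r0 <- qs[2L]; r1 <- qs[3L]
  if (!(r1 > r0) || !(r0 > rm1))
    stopf("degenerate ratio distribution: percentiles coincide")
  z <- ifelse(r >= r0, (r - r0) / (r1 - r0), (r0 - r) / (r0 - rm1))
  p <- pnorm(z, lower.tail = FALSE)  # = erfc(z / sqrt(2)) / 2
  if (two_sided) p <- pmin(1, 2 * p)
  p[!is.finite(r)] <- NA_real_
  p
}

#' Flag proteins significant in the whole-cell control contrast
#'
#' A protein is flagged when, in the BioID2 control contrast, it would earn
#' any significance tier (BH q <= alpha or Significance A p <= alpha).
#' Flagged proteins are excluded from tier assignment in the ciliary
#' contrast, restricting the analysis to changes specific to the cilium.
#' Proteins absent from the control contrast (dropped there) are not
#' flagged and are retained, with a message.
#'
#' @param cilia_results data.frame for the cilia-BioID2 contrast containing
#'   at least a `protein` column.
#' @param control_results data.frame for the BioID2 contrast with columns
#'   `protein`, `q`, `sigA_p` (and optionally `ratio_type`).
#' @param alpha significance boundary (default 0.05, inclusive).
#' @return logical vector parallel to `cilia_results$protein`.
#' @export
control_filter <- function(cilia_results, control_results, alpha = 0.05) {
  idx <- match(cilia_results$protein, control_results$protein)
  qc <- control_results$q[idx]
  sc <- control_results$sigA_p[idx]
  dropped <- if (!is.null(control_results$ratio_type))
    control_results$ratio_type[idx] == "dropped" else is.na(qc) & is.na(sc)
  absent <- is.na(idx) | (dropped %in% TRUE)
  if (any(absent))
    message(sum(absent), " protein(s) absent from the control contrast: ",
            "not flagged, retained")
  flag <- (!is.na(qc) & qc <= alpha) | (!is.na(sc) & sc <= alpha)
  flag[absent] <- FALSE
  flag
}

#' Assign significance tiers and direction
#'
#' Tier 1: BH q <= alpha and Significance A p <= alpha; Tier 2: only
#' Significance A; Tier 3: only q; NS otherwise; `excluded` when the
#' protein is flagged in the whole-cell control contrast (the tier
#' boundaries are inclusive). Direction is the sign of the log2 ratio for
#' tiered proteins: `depleted` (< 0) or `enriched` (> 0).
#'
#' @param rows data.frame with columns `protein`, `log2_ratio`, `t_p`, `q`,
#'   `sigA_p`, `control_significant` (and optionally `ratio_type`).
#' @param alpha tier boundary (default 0.05).
#' @return the input data.frame with `tier` and `direction` columns added.
#' @export
assign_tiers <- function(rows, alpha = 0.05) {
  q_sig <- !is.na(rows$q) & rows$q <= alpha
  a_sig <- !is.na(rows$sigA_p) & rows$sigA_p <= alpha
  tier <- ifelse(q_sig & a_sig, "Tier1",
                 ifelse(a_sig, "Tier2", ifelse(q_sig, "Tier3", "NS")))
  tier[rows$control_significant %in% TRUE] <- "excluded"
  if (!is.null(rows$ratio_type)) tier[rows$ratio_type == "dropped"] <- NA
  direction <- ifelse(tier %in% c("Tier1", "Tier2", "Tier3"),
                      ifelse(rows$log2_ratio < 0, "depleted",
                             ifelse(rows$log2_ratio > 0, "enriched", "none")),
                      "none")
  rows$tier <- tier
  rows$direction <- direction
  rows
}

## differential results for one contrast: ratio + t/BH + Significance A
contrast_results <- function(mat, contrast, sigA_min_n, sigA_two_sided) {
  rr <- group_log2_ratio(mat, contrast)
  tt <- ttest_bh(mat, contrast)
  stopifnot(identical(rr$protein, tt$protein))
  out <- cbind(rr, tt[, c("t_p", "q")])
  out$sigA_p <- significance_a(out$log2_ratio, min_n = sigA_min_n,
                               two_sided = sigA_two_sided)
  out
}

#' Run the full LFQ differential pipeline
#'
#' Imputation, per-contrast median log2 ratios with pseudovalues, per-
#' protein Student's t-test with BH correction, Significance A, control
#' filtering and tier assignment, for both the cilia-BioID2 and the
#' whole-cell BioID2 contrasts. Fully reproducible under
#' `impute_params$seed`.
#'
#' The pipeline scores outliers with the calibrated two-sided Significance
#' A p-value (`sigA_two_sided = TRUE`), verified by Monte Carlo to satisfy
#' `P(p <= alpha) = alpha` on null ratios, so the tier boundaries and the
#' control filter operate at their nominal levels; set it to `FALSE` for
#' the raw directional Perseus statistic.
#'
#' @param mat an [lfq_matrix()] covering both constructs.
#' @param impute_params an [imputation_params()].
#' @param alpha tier boundary (default 0.05, inclusive).
#' @param sigA_min_n,sigA_two_sided passed to [significance_a()].
#' @return an object of class `lfq_diff`: `table` (the cilia-BioID2
#'   per-protein table with `log2_ratio`, `t_p`, `q`, `sigA_p`,
#'   `control_significant`, `tier`, `direction` and `neg_log10_p` for
#'   volcano plotting), `control` (the BioID2 contrast table) and
#'   `tier_counts`.
#' @export
run_diff_pipeline <- function(mat, impute_params = imputation_params(),
                              alpha = 0.05, sigA_min_n = 20L,
                              sigA_two_sided = TRUE) {
  imp <- impute_missing(mat, impute_params)
  cil <- contrast_results(imp, "cilia-BioID2", sigA_min_n, sigA_two_sided)
  ctl <- contrast_results(imp, "BioID2", sigA_min_n, sigA_two_sided)
  cil$control_significant <- control_filter(cil, ctl, alpha)
  cil <- assign_tiers(cil, alpha)
  cil$neg_log10_p <- -log10(cil$t_p)
  ctl$control_significant <- FALSE
  ctl <- assign_tiers(ctl, alpha)
  counts <- table(factor(cil$tier,
                         levels = c("Tier1", "Tier2", "Tier3", "NS",
                                    "excluded")))
  structure(list(table = cil, control = ctl, tier_counts = counts,
                 alpha = alpha, impute_params = impute_params),
            class = "lfq_diff")
}

#' @export
print.lfq_diff <- function(x, ...) {
  cat("<lfq_diff> cilia-BioID2 KO/WT differential results\n")
  print(x$tier_counts)
  t1 <- x$table[x$table$tier %in% "Tier1", ]
  cat(sprintf("Tier1: %d depleted, %d enriched\n",
              sum(t1$direction == "depleted"),
              sum(t1$direction == "enriched")))
  invisible(x)
}

#' Write differential results as TSV plus a JSON run manifest
#'
#' @param diff an `lfq_diff` object.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_diff_results <- function(diff, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "diff_cilia.tsv")
  write.table(diff$table, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  tsv_ctl <- file.path(dir, "diff_control.tsv")
  write.table(diff$control, tsv_ctl, sep = "\t", row.names = FALSE,
              quote = FALSE)
  manifest <- file.path(dir, "diff_manifest.json")
  jsonlite::write_json(list(alpha = diff$alpha,
                            impute = unclass(diff$impute_params),
                            tier_counts = as.list(diff$tier_counts),
                            package_version =
                              as.character(packageVersion("ciliomics"))),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(cilia = tsv, control = tsv_ctl, manifest = manifest))
}
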