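#' Normalize grouped measurements to the control group mean
#'
#' Divides every value by the mean of the control group, so the control
#' group's mean maps exactly to 1 (the convention used for relative MFI
#' reporting against WT cells or control mice).
#'
#' @param data data.frame with columns `group`, `value` (long format).
#' @param control label of the control group.
#' @return the data.frame with `value` rescaled.
#' @export
normalize_to_control <- function(data, control) {
  if (!all(c("group", "value") %in% names(data)))
    stopf("`data` needs columns `group` and `value`")
  cv <- data$value[data$group == control]
  if (length(cv) == 0L) stopf("control group '%s' is empty", control)
  cm <- mean(cv)
  if (!is.finite(cm) || cm <= 0)
    stopf("control mean is not positive (%.4g); background correction produced no usable control signal", cm)
  data$value <- data$value / cm
  data
}

#' D'Agostino K-squared omnibus normality test
#'
#' Combines the transformed skewness z (D'Agostino 1970) and kurtosis z
#' (Anscombe-Glynn 1983) into K2 = Z1^2 + Z2^2, referred to a chi-squared
#' distribution with 2 degrees of freedom. Requires n >= 9.
#'
#' @param x numeric vector.
#' @return list with `statistic` (K2), `z_skew`, `z_kurt` and `p.value`.
#' @export
dagostino_k2 <- function(x) {
  n <- length(x)
  if (n < 9L) stopf("D'Agostino's K-squared test needs n >= 9")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2
  ## skewness component
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  ## kurtosis component
  Eg2 <- 3 * (n - 1) / (n + 1)
  Vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (g2 - Eg2) / sqrt(Vg2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xs * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Z1^2 + Z2^2
  list(statistic = K2, z_skew = Z1, z_kurt = Z2,
       p.value = pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Dunn's pairwise post hoc test after Kruskal-Wallis
#'
#' Rank-sum z statistics on the pooled ranks with the tie correction, two-
#' sided p-values, Bonferroni-adjusted across all pairwise comparisons.
#'
#' @param data data.frame with columns `group`, `value`.
#' @return data.frame with one row per pair: `group1`, `group2`, `z`, `p`,
#'   `p_adj`.
#' @export
dunn_test <- function(data) {
  g <- factor(data$group)
  r <- rank(data$value)
  N <- length(r)
  ties <- table(data$value)
  tiecorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se <- sqrt((N * (N + 1) / 12 - tiecorr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p <- 2 * pnorm(-abs(z))
    data.frame(group1 = a, group2 = b, z = z, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * m)
  out
}

## normality verdict for one group: Shapiro-Wilk for small n, D'Agostino
## K-squared otherwise
normality_test <- function(x, small_n = 8L) {
  if (length(x) < small_n || length(x) > 5000L) {
    if (length(x) < small_n) {
      t <- shapiro.test(x)
      return(list(test = "shapiro", p = t$p.value))
    }
    t <- dagostino_k2(x)
    return(list(test = "dagostino", p = t$p.value))
  }
  t <- dagostino_k2(x)
  list(test = "dagostino", p = t$p.value)
}

#' Group comparison with the normality-driven decision tree
#'
#' Each group is tested for Gaussian normality (Shapiro-Wilk for n < 8,
#' D'Agostino K-squared otherwise, at `normality_alpha`). If every group
#' passes: two groups are compared by the two-tailed unpaired Student's
#' t-test, more than two by one-way ANOVA followed by Tukey pairwise
#' comparisons. If any group fails: two groups are compared by the
#' Mann-Whitney test, more than two by Kruskal-Wallis followed by Dunn's
#' pairwise comparisons (Bonferroni-adjusted). All tests are two-sided.
#'
#' @param data data.frame with columns `group`, `value`; at least two
#'   groups, every group with n >= 3.
#' @param normality_alpha alpha for the normality tests (default 0.05).
#' @return an object of class `test_report`: `normality` (per-group test
#'   and p), `branch` (one of `t`, `anova_tukey`, `mann_whitney`,
#'   `kruskal_dunn`), `omnibus_p` (for >2 groups), and `comparisons` (per
#'   pair: p, adjusted p where applicable, significance stars).
#' @export
compare_groups <- function(data, normality_alpha = 0.05) {
  if (!all(c("group", "value") %in% names(data)))
    stopf("`data` needs columns `group` and `value`")
  data$group <- as.character(data$group)
  ns <- table(data$group)
  if (length(ns) < 2L) stopf("need at least two groups")
  if (any(ns < 3L))
    stopf("every group needs n >= 3 (got %s)",
          paste(sprintf("%s: %d", names(ns), ns), collapse = ", "))
  groups <- split(data$value, data$group)
  norm <- lapply(groups, normality_test)
  normality <- data.frame(group = names(groups),
                          test = vapply(norm, `[[`, "", "test"),
                          p = vapply(norm, `[[`, 0, "p"),
                          row.names = NULL)
  ## a group with zero variance cannot be normal; shapiro/K2 are undefined
  degenerate <- vapply(groups, function(x) var(x) == 0, NA)
  normality$p[degenerate] <- 0
  all_normal <- all(normality$p >= normality_alpha)
  two <- length(groups) == 2L
  omnibus_p <- NA_real_
  if (all_normal && two) {
    branch <- "t"
    p <- t.test(groups[[1L]], groups[[2L]], var.equal = TRUE)$p.value
    comparisons <- data.frame(group1 = names(groups)[1L],
                              group2 = names(groups)[2L], p = p,
                              p_adj = p)
  } else if (all_normal) {
    branch <- "anova_tukey"
    fit <- aov(value ~ group, data = data)
    omnibus_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    tk <- TukeyHSD(fit)$group
    pair <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    comparisons <- data.frame(group1 = pair[, 2L], group2 = pair[, 1L],
                              p = tk[, "p adj"], p_adj = tk[, "p adj"],
                              row.names = NULL)
  } else if (two) {
    branch <- "mann_whitney"
    p <- wilcox.test(groups[[1L]], groups[[2L]], exact = FALSE,
                     correct = TRUE)$p.value
    if (is.nan(p)) p <- 1  # every observation tied: identical distributions
    comparisons <- data.frame(group1 = names(groups)[1L],
                              group2 = names(groups)[2L], p = p, p_adj = p)
  } else {
    branch <- "kruskal_dunn"
    omnibus_p <- kruskal.test(value ~ group, data = data)$p.value
    comparisons <- dunn_test(data)
    comparisons <- comparisons[, c("group1", "group2", "p", "p_adj")]
  }
  comparisons$stars <- p_stars(comparisons$p_adj)
  structure(list(normality = normality, branch = branch,
                 omnibus_p = omnibus_p, comparisons = comparisons),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> branch: %s\n", x$branch))
  if (!is.na(x$omnibus_p))
    cat(sprintf("  omnibus p = %.4g\n", x$omnibus_p))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Write a JSON run manifest
#'
#' Records the invocation (arguments, configuration and its MD5 hash, seed,
#' package version, stage timings) next to the outputs of a run, so any
#' result file can be traced back to the exact inputs that produced it.
#'
#' @param path output JSON path (its directory must be writable).
#' @param args named list/vector of command-line arguments or call
#'   parameters.
#' @param config configuration object (serialized into the manifest).
#' @param seed integer seed consumed by the run's stochastic stages.
#' @param timings optional named numeric vector of stage timings (seconds).
#' @return invisibly, the manifest as a list.
#' @export
run_manifest <- function(path, args = list(), config = list(), seed = NA,
                         timings = NULL) {
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stopf("output directory '%s' is not writable", dir)
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf)
  manifest <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   args = as.list(args),
                   config = config,
                   config_md5 = unname(tools::md5sum(tf)),
                   seed = seed,
                   package = "ciliomics",
                   package_version =
                     as.character(packageVersion("ciliomics")),
                   r_version = R.version.string,
                   timings_sec = as.list(timings %||% list()))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
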