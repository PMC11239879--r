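#' Label-free quantification matrix with experimental design
#'
#' Couples a protein x sample intensity matrix (raw LFQ intensities, with 0
#' meaning "not quantified") to a sample design giving each sample's
#' construct (`"cilia-BioID2"` biotin-ligase fusion targeted to the cilium,
#' or the whole-cell `"BioID2"` control), genotype (`"WT"` or `"KO"`) and
#' replicate index.
#'
#' @param intensities numeric matrix, rows = proteins (rownames required),
#'   columns = samples (colnames required), values >= 0 and finite.
#' @param design data.frame with columns `sample`, `construct`, `genotype`,
#'   `replicate`; `sample` must match the matrix column names.
#' @return an object of class `lfq_matrix`.
#' @export
lfq_matrix <- function(intensities, design) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stopf("`intensities` needs protein rownames and sample colnames")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stopf("intensities must be finite and >= 0 (0 = not quantified)")
  need <- c("sample", "construct", "genotype", "replicate")
  if (!all(need %in% names(design)))
    stopf("design needs columns: %s", paste(need, collapse = ", "))
  design <- design[match(colnames(intensities), design$sample), ]
  if (any(is.na(design$sample)))
    stopf("every matrix column must appear in the design")
  if (!all(design$construct %in% c("cilia-BioID2", "BioID2")))
    stopf("construct must be 'cilia-BioID2' or 'BioID2'")
  if (!all(design$genotype %in% c("WT", "KO")))
    stopf("genotype must be 'WT' or 'KO'")
  tab <- table(design$construct, design$genotype)
  if (any(tab < 2L))
    stopf("each (construct, genotype) group needs >= 2 samples")
  structure(list(intensities = intensities, design = design),
            class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf("<lfq_matrix> %d proteins x %d samples\n",
              nrow(x$intensities), ncol(x$intensities)))
  print(table(x$design$construct, x$design$genotype))
  invisible(x)
}

group_columns <- function(mat, construct, genotype) {
  which(mat$design$construct == construct & mat$design$genotype == genotype)
}

#' Write / read an LFQ matrix as TSV
#'
#' The matrix TSV has a `protein` column followed by one column per sample;
#' the design TSV has columns `sample`, `construct`, `genotype`,
#' `replicate`.
#'
#' @param mat an [lfq_matrix()].
#' @param matrix_path,design_path output/input TSV paths.
#' @return `write_lfq_tsv`: invisibly, the paths; `read_lfq_tsv`: an
#'   [lfq_matrix()].
#' @export
write_lfq_tsv <- function(mat, matrix_path, design_path) {
  df <- data.frame(protein = rownames(mat$intensities), mat$intensities,
                   check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(mat$design, design_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(matrix = matrix_path, design = design_path))
}

#' @rdname write_lfq_tsv
#' @param lfq_prefix optional column-name prefix stripped from the matrix
#'   header before matching against the design (e.g. `"LFQ intensity "` for
#'   MaxQuant-style `proteinGroups` exports).
#' @export
read_lfq_tsv <- function(matrix_path, design_path, lfq_prefix = NULL) {
  df <- read.delim(matrix_path, check.names = FALSE)
  if (!"protein" %in% names(df))
    stopf("matrix TSV must have a `protein` column")
  m <- as.matrix(df[, setdiff(names(df), "protein"), drop = FALSE])
  rownames(m) <- df$protein
  if (!is.null(lfq_prefix))
    colnames(m) <- sub(paste0("^", lfq_prefix), "", colnames(m))
  design <- read.delim(design_path)
  lfq_matrix(m, design)
}
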