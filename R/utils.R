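`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Physical arc length of a polyline of voxel coordinates
#'
#' Sums the anisotropy-scaled Euclidean lengths of consecutive segments of a
#' polyline given as an n x 3 matrix of (z, y, x) voxel coordinates.
#'
#' @param path numeric matrix, one row per vertex, columns (z, y, x).
#' @param spacing numeric length-3, micrometres per voxel along (z, y, x).
#' @return arc length in micrometres (0 for a single vertex).
#' @export
polyline_length <- function(path, spacing) {
  path <- as.matrix(path)
  if (nrow(path) < 2L) return(0)
  d <- sweep(diff(path), 2L, spacing, `*`)
  sum(sqrt(rowSums(d^2)))
}

## Otsu's threshold on a numeric vector (256-bin histogram between the
## observed min and max). Returns the bin-edge threshold that maximises
## between-class variance; foreground is `value > threshold`.
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (!(rng[2] > rng[1])) return(NA_real_)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE),
                           nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  mu1 <- cumsum(h * mids) / pmax(w1, 1)
  mu2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  bcv <- w1 * w2 * (mu1 - mu2)^2
  bcv[w1 == 0 | w2 == 0] <- -Inf
  br[which.max(bcv) + 1L]
}

## voxel (z, y, x) 1-based matrix -> 0-based linear index for C++ kernels
voxel_linear_index <- function(vox, dims) {
  vox <- matrix(as.integer(vox), ncol = 3L)
  (vox[, 1L] - 1L) + as.integer(dims[1L]) * (vox[, 2L] - 1L) +
    as.integer(dims[1L]) * as.integer(dims[2L]) * (vox[, 3L] - 1L)
}

## inverse of voxel_linear_index
linear_voxel_index <- function(idx, dims) {
  nz <- as.integer(dims[1L]); ny <- as.integer(dims[2L])
  z <- idx %% nz
  y <- (idx %/% nz) %% ny
  x <- idx %/% (nz * ny)
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

## derive k reproducible sub-seeds (< 2^31) from one base seed
derive_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  as.integer(floor(runif(k) * 2147483646)) + 1L
}

## significance stars used on all reported p-values
#' Map p-values to significance stars
#'
#' Fixed mapping: `ns` for p >= 0.05, `*` < 0.05, `**` < 0.01,
#' `***` < 0.001, `****` < 0.0001.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star labels.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}
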