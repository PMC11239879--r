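#' Parameters for the synthetic polarized-epithelium image generator
#'
#' Describes a simulated spinning-disk confocal field of a ciliated
#' epithelial monolayer: ellipsoidal nuclei resting near the basal side,
#' at most one curved, apically growing primary cilium per ciliated cell,
#' a base-enriched target channel, anisotropic Gaussian PSF blur, a flat
#' background with a linear gradient, and Poisson + Gaussian camera noise.
#'
#' Defaults describe an 88 x 88 micrometre field with 50 cells, 70%
#' ciliation, 4 +/- 1 micrometre cilia of 0.25 micrometre radius, and
#' realistic spinning-disk voxel anisotropy (0.4 micrometre z step, 0.2
#' micrometre pixel pitch, diffraction-limited PSF).
#'
#' @param volume_shape integer length-3, voxels along (z, y, x).
#' @param voxel_spacing numeric length-3, micrometres per voxel (z, y, x).
#' @param n_nuclei number of cells to place.
#' @param ciliation_prob probability in `[0, 1]` that a cell carries a cilium.
#' @param nucleus_radii numeric length-3, mean ellipsoid semi-axes in
#'   micrometres (z, y, x).
#' @param nucleus_radius_jitter fractional standard deviation applied to the
#'   semi-axes per cell.
#' @param nucleus_amplitude nucleus-channel signal amplitude (camera units).
#' @param cilium_length_dist numeric length-3 `(mean, sd, min)` of the cilium
#'   length distribution in micrometres (normal, truncated below at `min`).
#' @param cilium_curvature maximum bend of the cilium axis, radians per
#'   micrometre of arc length.
#' @param cilium_radius radius of the painted cilium tube in micrometres
#'   (axoneme plus antibody staining).
#' @param marker_amplitude cilia-marker channel amplitude.
#' @param target_base_amplitude,target_body_amplitude target-channel
#'   amplitude painted on the proximal (base) segment and on the rest of the
#'   cilium.
#' @param base_truth_extent arc length in micrometres of the base-enriched
#'   segment, measured from the cilium start.
#' @param background_level constant background (camera units).
#' @param background_gradient background increase across the x span of the
#'   volume (camera units per full span).
#' @param psf_sigma numeric length-3 Gaussian PSF sigma in micrometres
#'   (z, y, x); 0 disables blur along that axis.
#' @param read_noise_sd standard deviation of additive Gaussian read noise.
#' @param poisson_noise logical; apply Poisson noise to the expected counts.
#' @param min_center_separation minimum in-plane distance between nucleus
#'   centers in micrometres; default just above one mean in-plane diameter.
#' @param seed integer seed; the generator is fully deterministic given the
#'   parameters and this seed.
#' @return an object of class `synth_imaging_params`.
#' @seealso [generate_cell_field()]
#' @export
synth_imaging_params <- function(volume_shape = c(32L, 440L, 440L),
                                 voxel_spacing = c(0.4, 0.2, 0.2),
                                 n_nuclei = 50L,
                                 ciliation_prob = 0.7,
                                 nucleus_radii = c(2.2, 3.4, 3.4),
                                 nucleus_radius_jitter = 0.08,
                                 nucleus_amplitude = 400,
                                 cilium_length_dist = c(mean = 4, sd = 1, min = 1.5),
                                 cilium_curvature = 0.35,
                                 cilium_radius = 0.25,
                                 marker_amplitude = 1500,
                                 target_base_amplitude = 800,
                                 target_body_amplitude = 200,
                                 base_truth_extent = 1.0,
                                 background_level = 100,
                                 background_gradient = 50,
                                 psf_sigma = c(0.3, 0.11, 0.11),
                                 read_noise_sd = 10,
                                 poisson_noise = TRUE,
                                 min_center_separation = NULL,
                                 seed = 1L) {
  p <- list(volume_shape = as.integer(volume_shape),
            voxel_spacing = as.numeric(voxel_spacing),
            n_nuclei = as.integer(n_nuclei),
            ciliation_prob = ciliation_prob,
            nucleus_radii = as.numeric(nucleus_radii),
            nucleus_radius_jitter = nucleus_radius_jitter,
            nucleus_amplitude = nucleus_amplitude,
            cilium_length_dist = as.numeric(cilium_length_dist),
            cilium_curvature = cilium_curvature,
            cilium_radius = cilium_radius,
            marker_amplitude = marker_amplitude,
            target_base_amplitude = target_base_amplitude,
            target_body_amplitude = target_body_amplitude,
            base_truth_extent = base_truth_extent,
            background_level = background_level,
            background_gradient = background_gradient,
            psf_sigma = as.numeric(psf_sigma),
            read_noise_sd = read_noise_sd,
            poisson_noise = isTRUE(poisson_noise),
            min_center_separation = min_center_separation %||%
              (2.4 * max(nucleus_radii[2:3])),
            seed = as.integer(seed))
  amps <- c(p$nucleus_amplitude, p$marker_amplitude, p$target_base_amplitude,
            p$target_body_amplitude, p$background_level, p$read_noise_sd,
            p$nucleus_radii, p$cilium_length_dist[1:2], p$psf_sigma,
            p$base_truth_extent, p$cilium_curvature, p$cilium_radius)
  if (any(!is.finite(amps)) || any(amps < 0))
    stopf("amplitudes, radii, lengths and sigmas must be finite and >= 0")
  if (length(p$volume_shape) != 3L || any(p$volume_shape < 1L))
    stopf("`volume_shape` must be 3 positive voxel counts")
  if (any(p$voxel_spacing <= 0)) stopf("`voxel_spacing` must be positive")
  if (p$ciliation_prob < 0 || p$ciliation_prob > 1)
    stopf("`ciliation_prob` must lie in [0, 1]")
  if (p$n_nuclei < 0L) stopf("`n_nuclei` must be >= 0")
  if (p$cilium_length_dist[3] <= 0) stopf("minimum cilium length must be > 0")
  class(p) <- "synth_imaging_params"
  p
}

## Rodrigues rotation of v about unit axis k by angle a
rotate_about <- function(v, k, a) {
  v * cos(a) + pracma_cross(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

fill_ellipsoid_voxels <- function(center_um, radii_um, dims, spacing) {
  lo <- pmax(1L, floor((center_um - radii_um) / spacing) + 1L)
  hi <- pmin(dims, ceiling((center_um + radii_um) / spacing) + 1L)
  zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
  dz2 <- (((zs - 1) * spacing[1] - center_um[1]) / radii_um[1])^2
  dy2 <- (((ys - 1) * spacing[2] - center_um[2]) / radii_um[2])^2
  dx2 <- (((xs - 1) * spacing[3] - center_um[3]) / radii_um[3])^2
  inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(z = zs[idx[, 1]], y = ys[idx[, 2]], x = xs[idx[, 3]])
}

## grow one cilium as a bounded-curvature random walk in physical space,
## starting at `start_um` with unit direction `dir`, step = in-plane pitch
grow_cilium_path <- function(start_um, dir, length_um, curvature, spacing,
                             span_um) {
  step <- min(spacing[2:3])
  n_steps <- max(1L, round(length_um / step))
  max_bend <- curvature * step
  pts <- matrix(0, n_steps + 1L, 3L)
  margin <- spacing  # keep one voxel inside the border
  pos <- pmin(pmax(start_um, margin), span_um - margin)
  pts[1L, ] <- pos
  for (i in seq_len(n_steps)) {
    if (max_bend > 0) {
      ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      t1 <- pracma_cross(dir, ref); t1 <- t1 / sqrt(sum(t1^2))
      phi <- runif(1, 0, 2 * pi)
      axis <- t1 * cos(phi) + pracma_cross(dir, t1) * sin(phi)
      dir <- rotate_about(dir, axis / sqrt(sum(axis^2)), runif(1, 0, max_bend))
      dir <- dir / sqrt(sum(dir^2))
    }
    nxt <- pos + dir * step
    for (ax in 1:3) {  # steer back inside near the volume border
      if (nxt[ax] < margin[ax] || nxt[ax] > span_um[ax] - margin[ax]) {
        dir[ax] <- -dir[ax]
        nxt <- pos + dir * step
      }
    }
    pos <- pmin(pmax(nxt, margin), span_um - margin)
    pts[i + 1L, ] <- pos
  }
  pts
}

## voxels within `radius` (physical) of any path vertex, each tagged with
## the smallest arc length among the vertices that reach it
tube_voxels <- function(path_vox, arc, radius, spacing, dims) {
  hw <- floor(radius / spacing)
  offs <- as.matrix(expand.grid(z = -hw[1]:hw[1], y = -hw[2]:hw[2],
                                x = -hw[3]:hw[3]))
  offs <- offs[rowSums(sweep(offs, 2L, spacing, `*`)^2) <= radius^2, ,
               drop = FALSE]
  k <- nrow(offs)
  n <- nrow(path_vox)
  vox <- path_vox[rep(seq_len(n), each = k), , drop = FALSE] +
    offs[rep(seq_len(k), n), , drop = FALSE]
  va <- rep(arc, each = k)
  ok <- vox[, 1L] >= 1L & vox[, 1L] <= dims[1L] &
    vox[, 2L] >= 1L & vox[, 2L] <= dims[2L] &
    vox[, 3L] >= 1L & vox[, 3L] <= dims[3L]
  vox <- vox[ok, , drop = FALSE]
  va <- va[ok]
  ord <- order(va)  # keep the smallest arc per voxel
  vox <- vox[ord, , drop = FALSE]
  va <- va[ord]
  key <- voxel_linear_index(vox, dims)
  first <- !duplicated(key)
  list(voxels = vox[first, , drop = FALSE], arc = va[first])
}

#' Simulate a 3D field of ciliated epithelial cells with ground truth
#'
#' Paints ellipsoidal nuclei (nucleus channel) and, per ciliated cell, one
#' bounded-curvature cilium growing outward from the nucleus surface away
#' from its centroid: a thin tube of `cilium_radius` around the axis
#' polyline, painted into the cilia-marker channel, plus a target channel
#' carrying `target_base_amplitude` on tube voxels within
#' `base_truth_extent` arc length of the cilium start and
#' `target_body_amplitude` beyond. The clean
#' signal is then blurred with the anisotropic PSF, a constant + linear
#' gradient background is added, Poisson noise is applied to the expected
#' counts (if enabled) followed by Gaussian read noise. Ground truth is
#' recorded before blur and noise. Randomness is consumed from per-cell
#' sub-streams derived from `params$seed`, so increasing `n_nuclei` does not
#' reshuffle earlier cells.
#'
#' @param params a [synth_imaging_params()] object.
#' @return list with elements `stack` (an [image_stack()] with channels
#'   `dapi`, `marker`, `target`) and `truth` (class `imaging_truth`: a
#'   per-cell data frame plus voxel-level nucleus, cilium-axis polyline,
#'   cilium-tube and base-segment coordinate sets; the true length is the
#'   arc length of the axis polyline under the voxel spacing).
#' @examples
#' p <- synth_imaging_params(volume_shape = c(16L, 64L, 64L), n_nuclei = 2L,
#'                           seed = 7L)
#' sim <- generate_cell_field(p)
#' sim$truth$cells[, c("cell", "has_cilium", "cilium_length_um")]
#' @export
generate_cell_field <- function(params) {
  stopifnot(inherits(params, "synth_imaging_params"))
  p <- params
  dims <- p$volume_shape
  sp <- p$voxel_spacing
  span <- (dims - 1L) * sp
  rmax <- p$nucleus_radii * (1 + 3 * p$nucleus_radius_jitter)
  l_max <- max(p$cilium_length_dist[3],
               p$cilium_length_dist[1] + 3 * p$cilium_length_dist[2])
  if (p$n_nuclei > 0L &&
      (span[1] < 2 * rmax[1] + 2 * sp[1] ||
       span[2] < 2 * rmax[2] + 2 * sp[2] ||
       span[3] < 2 * rmax[3] + 2 * sp[3] ||
       max(span) < l_max))
    stopf(paste("volume too small to contain a nucleus plus a maximum-length",
                "cilium; enlarge `volume_shape` or shrink the geometry"))

  seeds <- derive_seeds(p$seed, p$n_nuclei + 1L)
  noise_seed <- seeds[1L]
  cell_seeds <- seeds[-1L]

  ch_nuc <- array(0, dims)
  ch_marker <- array(0, dims)
  ch_target <- array(0, dims)

  centers <- matrix(NA_real_, p$n_nuclei, 3L)
  cells <- data.frame()
  nucleus_voxels <- list()
  cilium_paths <- list()
  cilium_voxels <- list()
  base_truth <- list()

  for (i in seq_len(p$n_nuclei)) {
    set.seed(cell_seeds[i])
    radii <- p$nucleus_radii *
      pmax(0.5, 1 + rnorm(3, 0, p$nucleus_radius_jitter))
    placed <- FALSE
    for (try in seq_len(2000L)) {
      cz <- radii[1] + sp[1] + runif(1, 0, 0.5)
      cy <- runif(1, radii[2] + sp[2], span[2] - radii[2] - sp[2])
      cx <- runif(1, radii[3] + sp[3], span[3] - radii[3] - sp[3])
      if (i == 1L) { placed <- TRUE; break }
      prev <- centers[seq_len(i - 1L), , drop = FALSE]
      d2 <- (prev[, 2] - cy)^2 + (prev[, 3] - cx)^2
      if (min(d2) >= p$min_center_separation^2) { placed <- TRUE; break }
    }
    if (!placed)
      stopf("could not place nucleus %d with the requested separation; the volume is too crowded", i)
    centers[i, ] <- c(cz, cy, cx)
    nvox <- fill_ellipsoid_voxels(c(cz, cy, cx), radii, dims, sp)
    ch_nuc[nvox] <- pmax(ch_nuc[nvox], p$nucleus_amplitude)
    nucleus_voxels[[i]] <- nvox

    has_cilium <- runif(1) < p$ciliation_prob
    path_vox <- NULL; base_vox <- NULL; bt_vox <- NULL; tube_vox <- NULL
    clen <- NA_real_
    if (has_cilium) {
      L <- max(p$cilium_length_dist[3],
               rnorm(1, p$cilium_length_dist[1], p$cilium_length_dist[2]))
      theta <- runif(1, 0, 35 * pi / 180)  # apical tilt from +z
      phi <- runif(1, 0, 2 * pi)
      u <- c(cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
      tscale <- 1 / sqrt(sum((u / radii)^2))
      start <- c(cz, cy, cx) + u * tscale
      pts <- grow_cilium_path(start, u, L, p$cilium_curvature, sp, span)
      vox <- cbind(z = round(pts[, 1] / sp[1]) + 1L,
                   y = round(pts[, 2] / sp[2]) + 1L,
                   x = round(pts[, 3] / sp[3]) + 1L)
      keep <- c(TRUE, rowSums(abs(diff(vox))) > 0)
      path_vox <- vox[keep, , drop = FALSE]
      ## true length = arc length of the continuous axis; the voxelized
      ## polyline inflates it by the lattice zigzag factor
      clen <- polyline_length(pts, c(1, 1, 1))
      base_vox <- path_vox[1L, ]
      arc <- c(0, cumsum(sqrt(rowSums(sweep(diff(path_vox), 2, sp, `*`)^2))))
      ## thin tube around the axis: every voxel within cilium_radius of a
      ## path vertex, each voxel tagged with the smallest arc length of a
      ## vertex painting it
      tube <- tube_voxels(path_vox, arc, p$cilium_radius, sp, dims)
      tube_vox <- tube$voxels
      in_base <- tube$arc <= p$base_truth_extent
      bt_vox <- tube_vox[in_base, , drop = FALSE]
      ch_marker[tube_vox] <- pmax(ch_marker[tube_vox], p$marker_amplitude)
      if (nrow(bt_vox))
        ch_target[bt_vox] <- pmax(ch_target[bt_vox], p$target_base_amplitude)
      body_vox <- tube_vox[!in_base, , drop = FALSE]
      if (nrow(body_vox))
        ch_target[body_vox] <- pmax(ch_target[body_vox],
                                    p$target_body_amplitude)
    }
    cilium_paths[[i]] <- path_vox
    cilium_voxels[[i]] <- tube_vox
    base_truth[[i]] <- bt_vox
    cells <- rbind(cells, data.frame(
      cell = i,
      centroid_z = cz / sp[1] + 1, centroid_y = cy / sp[2] + 1,
      centroid_x = cx / sp[3] + 1,
      n_nucleus_voxels = nrow(nvox),
      has_cilium = has_cilium,
      cilium_length_um = clen,
      base_z = if (has_cilium) base_vox[1] else NA_integer_,
      base_y = if (has_cilium) base_vox[2] else NA_integer_,
      base_x = if (has_cilium) base_vox[3] else NA_integer_,
      marker_amplitude = p$marker_amplitude,
      target_base_amplitude = p$target_base_amplitude,
      target_body_amplitude = p$target_body_amplitude))
  }

  blur_vox <- p$psf_sigma / sp
  apply_optics <- function(arr) {
    if (any(blur_vox > 0))
      arr <- array(cpp_sep_gauss_blur(as.numeric(arr), dims, blur_vox), dims)
    bg <- p$background_level + p$background_gradient *
      (if (dims[3] > 1L) (seq_len(dims[3]) - 1) / (dims[3] - 1) else 0)
    arr + rep(bg, each = dims[1] * dims[2])
  }
  ch_nuc <- apply_optics(ch_nuc)
  ch_marker <- apply_optics(ch_marker)
  ch_target <- apply_optics(ch_target)

  set.seed(noise_seed)
  apply_noise <- function(arr) {
    if (p$poisson_noise) arr <- array(rpois(length(arr), arr), dims)
    if (p$read_noise_sd > 0) arr <- arr + rnorm(length(arr), 0, p$read_noise_sd)
    pmax(arr, 0)
  }
  ch_nuc <- apply_noise(ch_nuc)
  ch_marker <- apply_noise(ch_marker)
  ch_target <- apply_noise(ch_target)

  stack <- image_stack(list(dapi = ch_nuc, marker = ch_marker,
                            target = ch_target),
                       spacing = sp,
                       roles = c(dapi = "nucleus", marker = "cilia_marker",
                                 target = "target"))
  truth <- structure(list(cells = cells, nucleus_voxels = nucleus_voxels,
                          cilium_paths = cilium_paths,
                          cilium_voxels = cilium_voxels,
                          base_truth_voxels = base_truth, params = p),
                     class = "imaging_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.imaging_truth <- function(x, ...) {
  cat(sprintf("<imaging_truth> %d cell(s), %d ciliated\n",
              nrow(x$cells), sum(x$cells$has_cilium)))
  invisible(x)
}

#' Write a simulated imaging dataset to disk
#'
#' Writes the stack as 16-bit multi-page TIFF (+ JSON sidecar with voxel
#' spacing), the per-cell ground-truth table as CSV, and the voxel-level
#' ground truth (paths, nucleus and base-segment voxel sets) as JSON.
#'
#' @param sim result of [generate_cell_field()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_image_dataset <- function(sim, dir, prefix = "field") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tif <- file.path(dir, paste0(prefix, ".tif"))
  write_image_stack(sim$stack, tif)
  cells_csv <- file.path(dir, paste0(prefix, "_cells.csv"))
  write.table(sim$truth$cells, cells_csv, sep = ",", row.names = FALSE,
              quote = FALSE)
  gt <- list(cells = sim$truth$cells,
             cilium_paths = lapply(sim$truth$cilium_paths, function(m)
               if (is.null(m)) NULL else unname(as.matrix(m))),
             cilium_voxels = lapply(sim$truth$cilium_voxels, function(m)
               if (is.null(m)) NULL else unname(as.matrix(m))),
             base_truth_voxels = lapply(sim$truth$base_truth_voxels,
               function(m) if (is.null(m)) NULL else unname(as.matrix(m))))
  gt_json <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(gt, gt_json, auto_unbox = TRUE, digits = NA)
  invisible(c(tif = tif, cells = cells_csv, truth = gt_json))
}
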