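#' Configuration for automated cilium quantification
#'
#' Tuning parameters of the five-step quantification: (1) nucleus
#' segmentation, (2) cilium segmentation and nucleus assignment, (3) base
#' detection, (4) geodesic base-region partition, (5) background-corrected
#' intensity measurement. All physical scales are in micrometres; intensity
#' offsets are in raw camera units.
#'
#' @param nucleus_sigma Gaussian smoothing sigma for the nucleus channel.
#' @param nucleus_background_radius scale of the grayscale-opening
#'   background estimate subtracted before thresholding the nucleus channel
#'   (a rolling-ball analogue; must exceed the nucleus radius).
#' @param nucleus_threshold `"otsu"` for a global Otsu threshold on the
#'   smoothed, background-subtracted channel, or a numeric manual override.
#' @param min_nucleus_volume smallest retained nucleus object, cubic
#'   micrometres.
#' @param cilia_sigma Gaussian smoothing sigma for the cilia-marker channel.
#' @param local_threshold_window edge length of the local-mean window used
#'   to threshold the cilia channel.
#' @param local_threshold_offset intensity a voxel must exceed its local
#'   mean by to count as cilium foreground.
#' @param min_cilium_volume smallest retained cilium candidate, cubic
#'   micrometres.
#' @param base_max_geodesic maximum geodesic distance from the base voxel
#'   defining the base region (user-defined base extent).
#' @param median_filter_radius radius of the 3D median filter whose output
#'   is subtracted from each target channel as the background estimate
#'   (must exceed the cilium width).
#' @param median_downsample integer in-plane subsampling factor for the
#'   median background estimate (1 = exact). The background varies on the
#'   scale of the filter radius, so estimating the median on a subsampled
#'   grid and re-expanding it changes the estimate negligibly while being
#'   `median_downsample^4` times faster.
#' @param association_rule how candidate cilia are assigned to nuclei;
#'   currently `"xy_overlap_dilated"`: overlap of the cilium's XY projection
#'   with the `assoc_dilation`-dilated XY projection of a nucleus, ties
#'   broken by largest overlap then nearest centroid.
#' @param assoc_dilation XY dilation of the nucleus projection used by the
#'   association rule.
#' @param intensity_weighted_centroid logical; use the intensity-weighted
#'   nucleus center of mass for base detection instead of the binary
#'   centroid.
#' @return an object of class `quant_config`.
#' @export
quant_config <- function(nucleus_sigma = 0.5,
                         nucleus_background_radius = 10,
                         nucleus_threshold = "otsu",
                         min_nucleus_volume = 20,
                         cilia_sigma = 0.15,
                         local_threshold_window = 2,
                         local_threshold_offset = 300,
                         min_cilium_volume = 0.05,
                         base_max_geodesic = 1.0,
                         median_filter_radius = 2,
                         median_downsample = 2L,
                         association_rule = "xy_overlap_dilated",
                         assoc_dilation = 2,
                         intensity_weighted_centroid = FALSE) {
  cfg <- list(nucleus_sigma = nucleus_sigma,
              nucleus_background_radius = nucleus_background_radius,
              nucleus_threshold = nucleus_threshold,
              min_nucleus_volume = min_nucleus_volume,
              cilia_sigma = cilia_sigma,
              local_threshold_window = local_threshold_window,
              local_threshold_offset = local_threshold_offset,
              min_cilium_volume = min_cilium_volume,
              base_max_geodesic = base_max_geodesic,
              median_filter_radius = median_filter_radius,
              median_downsample = as.integer(median_downsample),
              association_rule = association_rule,
              assoc_dilation = assoc_dilation,
              intensity_weighted_centroid = isTRUE(intensity_weighted_centroid))
  scales <- c(cfg$nucleus_sigma, cfg$nucleus_background_radius,
              cfg$min_nucleus_volume, cfg$cilia_sigma,
              cfg$local_threshold_window, cfg$min_cilium_volume,
              cfg$median_filter_radius, cfg$assoc_dilation)
  if (any(!is.finite(scales)) || any(scales <= 0))
    stopf("all physical scales in quant_config must be > 0")
  if (!is.finite(cfg$base_max_geodesic) || cfg$base_max_geodesic <= 0)
    stopf("`base_max_geodesic` must be > 0")
  if (cfg$median_downsample < 1L)
    stopf("`median_downsample` must be >= 1")
  if (!identical(cfg$association_rule, "xy_overlap_dilated"))
    stopf("unknown association_rule '%s'", cfg$association_rule)
  class(cfg) <- "quant_config"
  cfg
}

## build a label_volume object from an integer label array
label_volume <- function(labels, spacing) {
  dims <- dim(labels)
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    tab <- data.frame(label = integer(), n_voxels = integer(),
                      volume_um3 = numeric(), centroid_z = numeric(),
                      centroid_y = numeric(), centroid_x = numeric())
  } else {
    labs <- labels[idx]
    vox <- linear_voxel_index(idx - 1L, dims)
    cnt <- tabulate(labs)
    keep <- which(cnt > 0L)
    cz <- rowsum(as.numeric(vox[, 1L]), labs)[, 1L] / cnt[keep]
    cy <- rowsum(as.numeric(vox[, 2L]), labs)[, 1L] / cnt[keep]
    cx <- rowsum(as.numeric(vox[, 3L]), labs)[, 1L] / cnt[keep]
    tab <- data.frame(label = keep, n_voxels = cnt[keep],
                      volume_um3 = cnt[keep] * prod(spacing),
                      centroid_z = cz, centroid_y = cy, centroid_x = cx)
  }
  structure(list(labels = labels, table = tab, spacing = spacing),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %d object(s) in %s volume\n", nrow(x$table),
              paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

## drop labels below a voxel-count threshold and relabel contiguously 1..K
filter_relabel <- function(labels, min_voxels) {
  cnt <- tabulate(labels[labels > 0L])
  keep <- which(cnt >= min_voxels)
  map <- integer(length(cnt))
  map[keep] <- seq_along(keep)
  out <- labels
  pos <- labels > 0L
  out[pos] <- map[labels[pos]]
  out
}

label_voxels <- function(lv, label) {
  idx <- which(lv$labels == label)
  linear_voxel_index(idx - 1L, dim(lv$labels))
}

#' Segment nuclei in the nucleus channel
#'
#' Gaussian smoothing (anisotropy-aware), background subtraction by
#' grayscale box opening at `nucleus_background_radius`, one global
#' threshold over the whole volume (Otsu by default, manual override via
#' `nucleus_threshold`), 26-connected component labelling and removal of
#' objects smaller than `min_nucleus_volume`.
#'
#' @param stack an [image_stack()] with a `nucleus` channel.
#' @param cfg a [quant_config()].
#' @return a `label_volume`: integer label array plus an object table
#'   (label, voxel count, volume, centroid). A blank (constant) channel
#'   yields 0 objects with a warning.
#' @export
segment_nuclei <- function(stack, cfg) {
  stopifnot(inherits(stack, "image_stack"), inherits(cfg, "quant_config"))
  ch <- stack_channel(stack, "nucleus")
  dims <- dim(ch)
  sp <- stack$spacing
  if (diff(range(ch)) == 0) {
    warnf("nucleus channel is constant; no nuclei segmented")
    return(label_volume(array(0L, dims), sp))
  }
  sm <- array(cpp_sep_gauss_blur(as.numeric(ch), dims, cfg$nucleus_sigma / sp),
              dims)
  half <- pmax(1L, as.integer(round(cfg$nucleus_background_radius / sp)))
  bg <- cpp_box_extremum(cpp_box_extremum(as.numeric(sm), dims, half, FALSE),
                         dims, half, TRUE)
  bgsub <- pmax(sm - array(bg, dims), 0)
  thr <- if (identical(cfg$nucleus_threshold, "otsu"))
    otsu_threshold(as.numeric(bgsub)) else as.numeric(cfg$nucleus_threshold)
  if (!is.finite(thr)) {
    warnf("degenerate nucleus channel after background subtraction")
    return(label_volume(array(0L, dims), sp))
  }
  mask <- bgsub > thr
  lab <- array(cpp_label26(as.integer(mask), dims), dims)
  lab <- filter_relabel(lab, ceiling(cfg$min_nucleus_volume / prod(sp)))
  label_volume(lab, sp)
}

#' Segment primary cilia and assign each to a nucleus
#'
#' Smooths the cilia-marker channel, applies a local-mean threshold
#' (window `local_threshold_window`, a voxel is foreground when it exceeds
#' its local mean by `local_threshold_offset`), labels 26-connected
#' candidates, removes those below `min_cilium_volume`, assigns each
#' candidate to a nucleus by the association rule, and keeps per nucleus
#' only the candidate with the highest mean smoothed marker intensity (the
#' brightest object). Unassigned candidates are discarded.
#'
#' @param stack an [image_stack()] with a `cilia_marker` channel.
#' @param nuclei the `label_volume` from [segment_nuclei()].
#' @param cfg a [quant_config()].
#' @return list with `cilia` (a `label_volume` of retained cilia, relabeled
#'   1..K) and `association` (integer vector, `association[k]` = nucleus
#'   label of cilium k; empty when there are no nuclei or no candidates).
#' @export
segment_cilia <- function(stack, nuclei, cfg) {
  stopifnot(inherits(stack, "image_stack"), inherits(nuclei, "label_volume"),
            inherits(cfg, "quant_config"))
  ch <- stack_channel(stack, "cilia_marker")
  dims <- dim(ch)
  sp <- stack$spacing
  empty <- list(cilia = label_volume(array(0L, dims), sp),
                association = integer())
  if (nrow(nuclei$table) == 0L) {
    message("no cells: nucleus segmentation is empty")
    return(empty)
  }
  sm <- array(cpp_sep_gauss_blur(as.numeric(ch), dims, cfg$cilia_sigma / sp),
              dims)
  half <- pmax(1L, as.integer(round(cfg$local_threshold_window / 2 / sp)))
  locmean <- array(cpp_box_mean(as.numeric(sm), dims, half), dims)
  mask <- sm > locmean + cfg$local_threshold_offset
  lab <- array(cpp_label26(as.integer(mask), dims), dims)
  lab <- filter_relabel(lab, ceiling(cfg$min_cilium_volume / prod(sp)))
  n_cand <- max(lab)
  if (n_cand == 0L) return(empty)

  idx <- which(lab > 0L)
  labs <- lab[idx]
  vox <- linear_voxel_index(idx - 1L, dims)
  mean_int <- rowsum(sm[idx], labs)[, 1L] / tabulate(labs)

  ## XY projection of the nucleus labels. Nuclei sit side by side in the
  ## monolayer, so their XY projections are essentially disjoint; where
  ## they do overlap the mid-plane (most representative) label wins.
  proj <- matrix(0L, dims[2L], dims[3L])
  zs <- order(abs(seq_len(dims[1L]) - (dims[1L] + 1) / 2))
  for (z in rev(zs)) {  # mid-plane written last, i.e. with priority
    sl <- matrix(nuclei$labels[z, , ], dims[2L], dims[3L])
    hit <- sl > 0L
    proj[hit] <- sl[hit]
  }
  near <- cpp_nearest_label2d(proj, sp[2L], sp[3L], cfg$assoc_dilation)

  ntab <- nuclei$table
  assoc <- integer(n_cand)
  for (k in seq_len(n_cand)) {
    v <- vox[labs == k, , drop = FALSE]
    cpix <- unique(v[, 2L] + (v[, 3L] - 1L) * dims[2L])
    hit <- near$label[cpix]
    hit <- hit[hit > 0L & is.finite(near$dist[cpix])]
    if (length(hit) == 0L) next
    ov <- sort(table(hit), decreasing = TRUE)
    best <- as.integer(names(ov))[as.integer(ov) == max(ov)]
    if (length(best) > 1L) {  # tie: nearest 3D centroid (physical)
      cc <- colMeans(v)
      nd <- vapply(best, function(nl) {
        r <- ntab[ntab$label == nl, ]
        sum(((cc - c(r$centroid_z, r$centroid_y, r$centroid_x)) * sp)^2)
      }, 0)
      best <- best[which.min(nd)]
    }
    assoc[k] <- best[1L]
  }

  ## per nucleus, keep only the brightest assigned candidate
  retained <- integer(0)
  for (nl in unique(assoc[assoc > 0L])) {
    cand <- which(assoc == nl)
    retained <- c(retained, cand[which.max(mean_int[cand])])
  }
  retained <- sort(retained)
  if (length(retained) == 0L) return(empty)
  map <- integer(n_cand)
  map[retained] <- seq_along(retained)
  out <- lab
  pos <- lab > 0L
  out[pos] <- map[lab[pos]]
  list(cilia = label_volume(out, sp),
       association = setNames(assoc[retained], seq_along(retained)))
}

#' Locate the ciliary base voxel
#'
#' The base is the cilium voxel closest (anisotropy-scaled Euclidean
#' distance) to the nucleus center of mass, reflecting outward growth of
#' the cilium from the cell body. Exact distance ties are broken by
#' lexicographic (z, y, x) order.
#'
#' @param cilium_voxels integer matrix (n x 3) of 1-based (z, y, x) voxel
#'   coordinates; must be non-empty.
#' @param nucleus_centroid numeric length-3 centroid in voxel coordinates.
#' @param spacing micrometres per voxel (z, y, x).
#' @return the base voxel as a length-3 integer vector (z, y, x).
#' @export
find_base <- function(cilium_voxels, nucleus_centroid, spacing) {
  vox <- matrix(as.integer(as.matrix(cilium_voxels)), ncol = 3L)
  if (nrow(vox) == 0L) stopf("`cilium_voxels` must be non-empty")
  d2 <- rowSums((sweep(vox, 2L, as.numeric(nucleus_centroid)) *
                   rep(spacing, each = nrow(vox)))^2)
  ord <- order(d2, vox[, 1L], vox[, 2L], vox[, 3L])
  setNames(vox[ord[1L], ], c("z", "y", "x"))
}

#' Partition a cilium into base region and body by geodesic distance
#'
#' Computes geodesic distances from the base voxel inside the cilium mask
#' only (26-connected steps weighted by physical step length). The base
#' region is the set of voxels with distance `<= max_geodesic` (inclusive);
#' the body is the remainder. Fragments disconnected from the base are
#' assigned to the body and flagged.
#'
#' @param cilium_voxels integer matrix (n x 3) of voxel coordinates.
#' @param base_voxel length-3 (z, y, x) voxel; must be in `cilium_voxels`.
#' @param max_geodesic maximum geodesic distance (micrometres) of the base
#'   region; must be > 0.
#' @param spacing micrometres per voxel (z, y, x).
#' @return list with `base_region_voxels`, `body_voxels`,
#'   `has_unreachable` (TRUE when disconnected fragments exist) and
#'   `geodesic` (per-voxel distances, parallel to `cilium_voxels`).
#' @export
base_region <- function(cilium_voxels, base_voxel, max_geodesic, spacing) {
  if (!is.finite(max_geodesic) || max_geodesic <= 0)
    stopf("`max_geodesic` must be > 0")
  vox <- matrix(as.integer(as.matrix(cilium_voxels)), ncol = 3L)
  if (nrow(vox) == 0L) stopf("`cilium_voxels` must be non-empty")
  base_voxel <- as.integer(base_voxel)
  if (!any(vox[, 1L] == base_voxel[1L] & vox[, 2L] == base_voxel[2L] &
             vox[, 3L] == base_voxel[3L]))
    stopf("`base_voxel` must be one of `cilium_voxels`")
  lo <- pmin(apply(vox, 2L, min), base_voxel)
  loc <- sweep(vox, 2L, lo) + 1L
  basec <- base_voxel - lo + 1L
  d <- apply(loc, 2L, max)
  mask <- array(0L, d)
  mask[loc] <- 1L
  dist <- cpp_geodesic26(as.integer(mask), d,
                         voxel_linear_index(matrix(basec, 1L), d),
                         as.numeric(spacing))
  dv <- array(dist, d)[loc]
  in_base <- is.finite(dv) & dv <= max_geodesic
  list(base_region_voxels = vox[in_base, , drop = FALSE],
       body_voxels = vox[!in_base, , drop = FALSE],
       has_unreachable = any(!is.finite(dv)),
       geodesic = dv)
}

#' Measure cilium length
#'
#' Length of the cilium's centerline: the maximal anisotropy-weighted
#' geodesic distance between any two voxels of the mask (its geodesic
#' diameter), found by a double Dijkstra sweep. Because segmented cilia are
#' quasi-one-dimensional filaments, the mask's geodesic diameter coincides
#' with the skeleton path length. Disconnected fragments are measured
#' separately and the largest diameter is reported; a single voxel has
#' length 0.
#'
#' @param cilium_voxels integer matrix (n x 3) of voxel coordinates.
#' @param spacing micrometres per voxel (z, y, x).
#' @return length in micrometres.
#' @export
measure_length <- function(cilium_voxels, spacing) {
  vox <- matrix(as.integer(as.matrix(cilium_voxels)), ncol = 3L)
  if (nrow(vox) == 0L) stopf("`cilium_voxels` must be non-empty")
  if (nrow(vox) == 1L) return(0)
  lo <- apply(vox, 2L, min)
  loc <- sweep(vox, 2L, lo) + 1L
  d <- apply(loc, 2L, max)
  mask <- array(0L, d)
  mask[loc] <- 1L
  comp <- array(cpp_label26(as.integer(mask), d), d)
  best <- 0
  for (k in seq_len(max(comp))) {
    cidx <- which(comp == k)
    if (length(cidx) < 2L) next
    sweep1 <- cpp_geodesic26(as.integer(mask), d, cidx[1L] - 1L,
                             as.numeric(spacing))[cidx]
    e1 <- cidx[which.max(sweep1)]
    sweep2 <- cpp_geodesic26(as.integer(mask), d, e1 - 1L,
                             as.numeric(spacing))[cidx]
    best <- max(best, max(sweep2))
  }
  best
}

## region means of a corrected channel
region_means <- function(corrected, base_vox, body_vox) {
  whole <- rbind(base_vox, body_vox)
  c(mfi_whole = mean(corrected[whole]),
    mfi_base = if (nrow(base_vox)) mean(corrected[base_vox]) else NA_real_,
    mfi_body = if (nrow(body_vox)) mean(corrected[body_vox]) else NA_real_)
}

## median-filter background correction of one channel; the median is
## computed on an in-plane subsampled grid (factor `downsample`) and
## re-expanded by nearest neighbour
median_correct <- function(arr, radius, spacing, downsample = 1L,
                           nbins = 2048L) {
  dims <- dim(arr)
  ds <- max(1L, as.integer(downsample))
  if (ds == 1L) {
    half <- pmax(0L, as.integer(round(radius / spacing)))
    bg <- cpp_median_box(as.numeric(arr), dims, half, nbins)
    return(arr - array(bg, dims))
  }
  ys <- seq(1L, dims[2L], by = ds)
  xs <- seq(1L, dims[3L], by = ds)
  sub <- arr[, ys, xs, drop = FALSE]
  sp_sub <- spacing * c(1, ds, ds)
  half <- pmax(0L, as.integer(round(radius / sp_sub)))
  bgs <- array(cpp_median_box(as.numeric(sub), dim(sub), half, nbins),
               dim(sub))
  bg <- bgs[, ceiling(seq_len(dims[2L]) / ds),
            ceiling(seq_len(dims[3L]) / ds), drop = FALSE]
  arr - bg
}

#' Background-corrected mean intensities of a cilium
#'
#' For each target channel the 3D median-filtered image (radius
#' `median_filter_radius`) is subtracted as the background estimate;
#' negative corrected values are retained so that noise averages out. The
#' mean corrected intensity is then reported over the whole cilium, its
#' base region and its body. An empty body yields `NA` (undefined), not 0.
#'
#' @param stack an [image_stack()].
#' @param record list with elements `base_region_voxels` and `body_voxels`
#'   (as returned by [base_region()]).
#' @param cfg a [quant_config()].
#' @return named list, one numeric vector `(mfi_whole, mfi_base, mfi_body)`
#'   per target channel.
#' @export
measure_intensities <- function(stack, record, cfg) {
  out <- list()
  for (nm in stack_target_names(stack)) {
    corr <- median_correct(stack$channels[[nm]], cfg$median_filter_radius,
                           stack$spacing, cfg$median_downsample)
    out[[nm]] <- region_means(corr, record$base_region_voxels,
                              record$body_voxels)
  }
  out
}

#' Ciliation frequency of an image
#'
#' Fraction of segmented nuclei that have a retained associated cilium.
#' With zero nuclei the frequency is undefined (`NA`), not 0.
#'
#' @param nuclei `label_volume` from [segment_nuclei()].
#' @param association association vector from [segment_cilia()].
#' @return a fraction in `[0, 1]`, or `NA` for an empty image.
#' @export
ciliation_frequency <- function(nuclei, association) {
  n <- nrow(nuclei$table)
  if (n == 0L) return(NA_real_)
  length(unique(association[association > 0L])) / n
}

#' Run the full automated cilium quantification
#'
#' Executes the five stages in order: nucleus segmentation, cilium
#' segmentation + nucleus assignment, base detection, geodesic base-region
#' partition, and background-corrected intensity measurement; finally
#' computes cilium length and the image-level ciliation frequency. The
#' pipeline involves no randomness and is fully deterministic.
#'
#' @param stack an [image_stack()].
#' @param cfg a [quant_config()].
#' @return an object of class `cilia_quant`: `table` (one row per retained
#'   cilium: labels, base voxel, length, per-target `mfi_whole/base/body`),
#'   `records` (full per-cilium voxel sets and partitions), `nuclei`,
#'   `cilia`, `association` and `summary` (nucleus count, cilium count,
#'   ciliation frequency).
#' @export
run_quantification <- function(stack, cfg = quant_config()) {
  nuclei <- segment_nuclei(stack, cfg)
  seg <- segment_cilia(stack, nuclei, cfg)
  targets <- stack_target_names(stack)
  corrected <- lapply(targets, function(nm)
    median_correct(stack$channels[[nm]], cfg$median_filter_radius,
                   stack$spacing, cfg$median_downsample))
  names(corrected) <- targets

  nchan <- stack_channel(stack, "nucleus")
  records <- list()
  rows <- list()
  for (k in seq_len(nrow(seg$cilia$table))) {
    nl <- seg$association[[as.character(k)]]
    vox <- label_voxels(seg$cilia, k)
    nrow_tab <- nuclei$table[nuclei$table$label == nl, ]
    centroid <- c(nrow_tab$centroid_z, nrow_tab$centroid_y,
                  nrow_tab$centroid_x)
    if (cfg$intensity_weighted_centroid) {
      nv <- label_voxels(nuclei, nl)
      w <- nchan[nv]
      centroid <- colSums(nv * w) / sum(w)
    }
    base <- find_base(vox, centroid, stack$spacing)
    part <- base_region(vox, base, cfg$base_max_geodesic, stack$spacing)
    len <- measure_length(vox, stack$spacing)
    mfis <- lapply(corrected, function(corr)
      region_means(corr, part$base_region_voxels, part$body_voxels))
    rec <- list(cilium_label = k, nucleus_label = nl, base_voxel = base,
                cilium_voxels = vox,
                base_region_voxels = part$base_region_voxels,
                body_voxels = part$body_voxels,
                has_unreachable = part$has_unreachable,
                length_um = len, mfi = mfis)
    records[[k]] <- rec
    row <- data.frame(cilium_label = k, nucleus_label = nl,
                      base_z = base[1L], base_y = base[2L], base_x = base[3L],
                      n_voxels = nrow(vox),
                      n_base_voxels = nrow(part$base_region_voxels),
                      n_body_voxels = nrow(part$body_voxels),
                      length_um = len)
    for (nm in targets) {
      row[[paste0(nm, "_mfi_whole")]] <- mfis[[nm]][["mfi_whole"]]
      row[[paste0(nm, "_mfi_base")]] <- mfis[[nm]][["mfi_base"]]
      row[[paste0(nm, "_mfi_body")]] <- mfis[[nm]][["mfi_body"]]
    }
    rows[[k]] <- row
  }
  table <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(table) <- NULL
  structure(list(table = table, records = records, nuclei = nuclei,
                 cilia = seg$cilia, association = seg$association,
                 summary = list(n_nuclei = nrow(nuclei$table),
                                n_cilia = nrow(seg$cilia$table),
                                ciliation_frequency =
                                  ciliation_frequency(nuclei,
                                                      seg$association))),
            class = "cilia_quant")
}

#' @export
print.cilia_quant <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cilia_quant> %d nuclei, %d cilia (ciliation %.3f)\n",
              s$n_nuclei, s$n_cilia, s$ciliation_frequency))
  invisible(x)
}

#' Write quantification results as CSV
#'
#' @param result a `cilia_quant` object.
#' @param dir output directory.
#' @param prefix file-name prefix (typically the image id).
#' @return invisibly, the paths written.
#' @export
write_quantification <- function(result, dir, prefix = "image") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  per_cilium <- file.path(dir, paste0(prefix, "_cilia.csv"))
  tab <- result$table
  if (nrow(tab)) tab <- cbind(image = prefix, tab)
  write.table(tab, per_cilium, sep = ",", row.names = FALSE, quote = FALSE)
  summary_csv <- file.path(dir, paste0(prefix, "_summary.csv"))
  s <- result$summary
  write.table(data.frame(image = prefix, n_nuclei = s$n_nuclei,
                         n_cilia = s$n_cilia,
                         ciliation_frequency = s$ciliation_frequency),
              summary_csv, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(c(cilia = per_cilium, summary = summary_csv))
}
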