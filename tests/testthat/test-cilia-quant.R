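spacing_default <- c(0.4, 0.2, 0.2)

test_that("find_base matches an exhaustive distance scan on random blobs", {
  for (s in 1:25) {
    vox <- random_blob(40L, seed = s)
    set.seed(s + 100)
    centroid <- runif(3, 1, 12)
    base <- find_base(vox, centroid, spacing_default)
    d2 <- rowSums((sweep(vox, 2L, centroid) *
                     rep(spacing_default, each = nrow(vox)))^2)
    expect_equal(min(d2),
                 sum(((base - centroid) * spacing_default)^2),
                 tolerance = 1e-12)
  }
})

test_that("find_base breaks exact ties lexicographically by (z, y, x)", {
  vox <- rbind(c(2L, 1L, 1L), c(1L, 2L, 1L))  # equidistant from centroid
  base <- find_base(vox, c(1, 1, 1), c(1, 1, 1))
  expect_equal(unname(base), c(1L, 2L, 1L))
  expect_error(find_base(vox[0, , drop = FALSE], c(1, 1, 1), c(1, 1, 1)),
               "non-empty")
})

test_that("base_region reproduces the Dijkstra oracle on random masks", {
  for (s in 1:20) {
    vox <- random_blob(35L, seed = s + 50)
    base <- vox[1L, ]
    maxg <- 0.6
    part <- base_region(vox, base, maxg, spacing_default)
    oracle <- r_dijkstra_oracle(vox, base, spacing_default)
    in_base <- is.finite(oracle) & oracle <= maxg
    expect_equal(part$geodesic, oracle, tolerance = 1e-9)
    expect_identical(nrow(part$base_region_voxels), sum(in_base))
    ## partition invariant
    expect_identical(nrow(part$base_region_voxels) + nrow(part$body_voxels),
                     nrow(vox))
  }
})

test_that("base_region handles lines, saturation and disconnected fragments", {
  line <- cbind(z = rep(1L, 30L), y = 1:30, x = rep(1L, 30L))
  sp <- c(0.3, 0.1, 0.1)
  part <- base_region(line, c(1L, 1L, 1L), 1.0, sp)
  ## distances 0.0 .. 1.0 inclusive -> 11 voxels
  expect_identical(nrow(part$base_region_voxels), 11L)
  sat <- base_region(line, c(1L, 1L, 1L), 10, sp)
  expect_identical(nrow(sat$body_voxels), 0L)
  frag <- rbind(line, cbind(z = rep(1L, 3L), y = 40:42, x = rep(1L, 3L)))
  pf <- base_region(frag, c(1L, 1L, 1L), 1.0, sp)
  expect_true(pf$has_unreachable)
  ## the unreachable fragment lands in the body
  expect_identical(nrow(pf$body_voxels), 19L + 3L)
  expect_error(base_region(line, c(1L, 1L, 1L), 0, sp), "max_geodesic")
  expect_error(base_region(line, c(5L, 5L, 5L), 1, sp), "base_voxel")
})

test_that("measure_length handles degenerate and collinear cases and scales with spacing", {
  expect_equal(measure_length(cbind(1L, 1L, 1L), spacing_default), 0)
  line <- cbind(z = rep(1L, 30L), y = 1:30, x = rep(1L, 30L))
  expect_equal(measure_length(line, c(0.3, 0.1, 0.1)), 2.9,
               tolerance = 1e-12)
  for (s in 1:5) {
    vox <- random_blob(30L, seed = s + 200)
    l1 <- measure_length(vox, spacing_default)
    l3 <- measure_length(vox, 3 * spacing_default)
    expect_equal(l3, 3 * l1, tolerance = 1e-9)
  }
})

test_that("segment_nuclei finds well-separated nuclei and honours filters", {
  p <- small_field_params(seed = 21L)
  sim <- generate_cell_field(p)
  cfg <- quant_config()
  nuc <- segment_nuclei(sim$stack, cfg)
  expect_equal(nrow(nuc$table), nrow(sim$truth$cells))
  ## centroids within 1 um of ground truth (greedy nearest matching)
  got <- as.matrix(nuc$table[, c("centroid_z", "centroid_y", "centroid_x")])
  want <- as.matrix(sim$truth$cells[, c("centroid_z", "centroid_y",
                                        "centroid_x")])
  for (i in seq_len(nrow(want))) {
    d <- sqrt(colSums((t(got) - want[i, ])^2 * 1))  # voxel units
    dum <- sqrt(rowSums((sweep(got, 2L, want[i, ]) *
                           rep(p$voxel_spacing, each = nrow(got)))^2))
    expect_lt(min(dum), 1)
  }
  ## a volume filter larger than any nucleus removes everything
  big <- quant_config(min_nucleus_volume = 1e5)
  expect_identical(nrow(segment_nuclei(sim$stack, big)$table), 0L)
})

test_that("a constant nucleus channel yields zero objects with a warning", {
  ch <- array(7, c(6L, 20L, 20L))
  stk <- image_stack(list(n = ch, m = ch, t = ch), c(0.4, 0.2, 0.2),
                     c(n = "nucleus", m = "cilia_marker", t = "target"))
  expect_warning(nuc <- segment_nuclei(stk, quant_config()), "constant")
  expect_identical(nrow(nuc$table), 0L)
  seg <- expect_message(segment_cilia(stk, nuc, quant_config()), "no cells")
  expect_identical(length(seg$association), 0L)
})

test_that("per nucleus only the brightest candidate cilium is retained", {
  dims <- c(10L, 40L, 40L)
  sp <- c(0.4, 0.2, 0.2)
  nchan <- array(0, dims)
  nvox <- as.matrix(expand.grid(z = 2:5, y = 14:26, x = 14:26))
  nchan[nvox] <- 400
  marker <- array(0, dims)
  marker[cbind(7L, 10:20, 18L)] <- 200   # candidate A, brighter
  marker[cbind(7L, 10:20, 24L)] <- 150   # candidate B, dimmer
  stk <- image_stack(list(n = nchan, m = marker, t = array(0, dims)), sp,
                     c(n = "nucleus", m = "cilia_marker", t = "target"))
  cfg <- quant_config(local_threshold_offset = 50, min_cilium_volume = 0.02,
                      nucleus_sigma = 0.3, min_nucleus_volume = 5)
  nuc <- segment_nuclei(stk, cfg)
  expect_identical(nrow(nuc$table), 1L)
  seg <- segment_cilia(stk, nuc, cfg)
  expect_identical(nrow(seg$cilia$table), 1L)
  kept <- which(seg$cilia$labels == 1L, arr.ind = TRUE)
  ## the retained object is the brighter one (x = 18)
  expect_true(all(kept[, 3] < 22))
})

test_that("cilium records satisfy the partition and weighted-mean identities", {
  p <- small_field_params(seed = 31L)
  sim <- generate_cell_field(p)
  res <- run_quantification(sim$stack, quant_config())
  expect_gt(length(res$records), 0L)
  for (r in res$records) {
    both <- rbind(r$base_region_voxels, r$body_voxels)
    expect_identical(nrow(both), nrow(r$cilium_voxels))
    key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
    expect_identical(key(both), key(r$cilium_voxels))
    expect_identical(
      length(intersect(key(r$base_region_voxels), key(r$body_voxels))), 0L)
    ## base voxel inside the base region
    expect_true(paste(r$base_voxel[1], r$base_voxel[2], r$base_voxel[3]) %in%
                  key(r$base_region_voxels))
    for (m in r$mfi) {
      nb <- nrow(r$base_region_voxels); nc <- nrow(r$body_voxels)
      if (nb > 0 && nc > 0)
        expect_equal(m[["mfi_whole"]],
                     (m[["mfi_base"]] * nb + m[["mfi_body"]] * nc) / (nb + nc),
                     tolerance = 1e-6)
    }
  }
})

test_that("ciliation frequency counts nuclei with a retained cilium", {
  labels <- array(0L, c(2L, 12L, 12L))
  for (k in 1:10) labels[1L, k, k] <- k
  lv <- ciliomics:::label_volume(labels, c(0.4, 0.2, 0.2))
  expect_equal(ciliation_frequency(lv, setNames(1:7, 1:7)), 0.7)
  expect_equal(ciliation_frequency(lv, integer()), 0)
  empty <- ciliomics:::label_volume(array(0L, c(2L, 4L, 4L)), c(0.4, 0.2, 0.2))
  expect_true(is.na(ciliation_frequency(empty, integer())))
})

test_that("a constant target channel yields near-zero corrected MFIs", {
  p <- small_field_params(seed = 41L)
  sim <- generate_cell_field(p)
  sim$stack$channels$target <- array(250, dim(sim$stack$channels$target))
  res <- run_quantification(sim$stack, quant_config())
  expect_gt(nrow(res$table), 0L)
  expect_true(all(abs(res$table$target_mfi_whole) < 1e-6))
})

test_that("measured whole-cilium MFI tracks the painted amplitude without blur", {
  ## median radius >> cilium width, no blur, no noise: the corrected MFI
  ## over the cilium region recovers the painted amplitude within 10%
  amps <- c(300, 500, 800)
  cfg <- quant_config()
  meas <- vapply(seq_along(amps), function(i) {
    p <- small_field_params(psf_sigma = c(0, 0, 0), poisson_noise = FALSE,
                            read_noise_sd = 0,
                            target_base_amplitude = amps[i],
                            target_body_amplitude = amps[i], seed = 51L)
    sim <- generate_cell_field(p)
    vals <- vapply(which(sim$truth$cells$has_cilium), function(ci) {
      tube <- sim$truth$cilium_voxels[[ci]]
      part <- base_region(tube, tube[1L, ], cfg$base_max_geodesic,
                          p$voxel_spacing)
      measure_intensities(sim$stack, part, cfg)$target[["mfi_whole"]]
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(abs(meas - amps) / amps < 0.1))
  ## linearity: regression slope of measured on painted amplitude
  fit <- coef(lm(meas ~ amps))
  expect_gt(fit[["amps"]], 0.8)
  expect_lt(fit[["amps"]], 1.2)
})

test_that("quantification is deterministic", {
  p <- small_field_params(seed = 61L)
  sim <- generate_cell_field(p)
  a <- run_quantification(sim$stack, quant_config())
  b <- run_quantification(sim$stack, quant_config())
  expect_identical(a$table, b$table)
  expect_identical(a$summary, b$summary)
})
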