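#' Multi-channel 3D image stack
#'
#' Container for a multi-channel 3D fluorescence volume. Each channel is a
#' numeric array with dim = c(nz, ny, nx); all channels share one shape and
#' one physical voxel spacing. Channel roles name the biological content
#' (one `"nucleus"` channel, one `"cilia_marker"` channel, and one or more
#' `"target"` channels), which is how downstream operators find their input.
#'
#' @param channels named list of numeric 3D arrays, identical dims.
#' @param spacing numeric length-3, micrometres per voxel along (z, y, x).
#' @param roles named character vector mapping channel name to one of
#'   `"nucleus"`, `"cilia_marker"`, `"target"`.
#' @return an object of class `image_stack`.
#' @examples
#' ch <- array(0, c(4, 8, 8))
#' stk <- image_stack(list(dapi = ch, actub = ch, poi = ch),
#'                    spacing = c(0.3, 0.2, 0.2),
#'                    roles = c(dapi = "nucleus", actub = "cilia_marker",
#'                              poi = "target"))
#' dim(stk$channels$dapi)
#' @export
image_stack <- function(channels, spacing, roles) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stopf("`channels` must be a named list of 3D arrays")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stopf("every channel must be a 3D array")
  if (length(unique(dims)) != 1L)
    stopf("all channels must share the same shape")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be 3 strictly positive micrometre steps (z, y, x)")
  roles <- roles[names(channels)]
  if (any(is.na(roles)) ||
      !all(roles %in% c("nucleus", "cilia_marker", "target")))
    stopf("`roles` must assign nucleus/cilia_marker/target to every channel")
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (any(!is.finite(v)))
      stopf("channel '%s' contains non-finite intensities", nm)
  }
  structure(list(channels = channels, spacing = spacing, roles = roles),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<image_stack> %d x %d x %d voxels (z,y,x), %d channel(s)\n",
              d[1], d[2], d[3], length(x$channels)))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g um\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  for (nm in names(x$channels))
    cat(sprintf("  %-12s %s\n", nm, x$roles[[nm]]))
  invisible(x)
}

stack_dims <- function(stack) dim(stack$channels[[1L]])

stack_channel <- function(stack, role) {
  nm <- names(stack$roles)[stack$roles == role]
  if (length(nm) == 0L) stopf("stack has no '%s' channel", role)
  stack$channels[[nm[1L]]]
}

stack_target_names <- function(stack) names(stack$roles)[stack$roles == "target"]

#' Write an image stack as multi-page TIFF plus a JSON sidecar
#'
#' Pages are ordered channel-major then z (C1 z1..zn, C2 z1..zn, ...).
#' Intensities are stored as 16-bit integers; the sidecar records voxel
#' spacing, channel names/roles and the page layout so the stack round-trips
#' through [read_image_stack()].
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar is written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  d <- stack_dims(stack)
  pages <- list()
  for (nm in names(stack$channels)) {
    ch <- pmin(pmax(stack$channels[[nm]], 0), 65535) / 65535
    for (z in seq_len(d[1L]))
      pages[[length(pages) + 1L]] <- matrix(ch[z, , ], d[2L], d[3L])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(spacing_um = stack$spacing, shape_zyx = as.integer(d),
               channels = names(stack$channels),
               roles = as.list(stack$roles), intensity_scale = 65535,
               page_order = "channel_major_then_z")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path with a `<path>.json` sidecar.
#' @param spacing optional numeric length-3 (z, y, x) micrometre spacing; if
#'   supplied it overrides the sidecar value (a mismatch is reported with a
#'   message, mirroring a command-line `--spacing` flag winning over file
#'   metadata).
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, spacing = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape_zyx)
  scale <- meta$intensity_scale %||% 65535
  chs <- list()
  i <- 0L
  for (nm in meta$channels) {
    arr <- array(0, d)
    for (z in seq_len(d[1L])) {
      i <- i + 1L
      arr[z, , ] <- pages[[i]] * scale
    }
    chs[[nm]] <- arr
  }
  sp <- as.numeric(meta$spacing_um)
  if (!is.null(spacing)) {
    if (max(abs(sp - spacing)) > 1e-9)
      message("supplied --spacing overrides file metadata (",
              paste(signif(sp, 4), collapse = "x"), " -> ",
              paste(signif(spacing, 4), collapse = "x"), ")")
    sp <- as.numeric(spacing)
  }
  image_stack(chs, sp, unlist(meta$roles))
}
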