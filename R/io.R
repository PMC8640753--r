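# ---- volume TIFF + YAML sidecar ------------------------------------------

scale_to_unit <- function(a, bits) {
  if (bits == 16) {
    if (any(a < 0 | a > 65535 | a != round(a), na.rm = TRUE))
      stop("16-bit output requires integer intensities in [0, 65535]")
    list(data = a / 65535, lo = 0, hi = 65535)
  } else {
    lo <- min(a, na.rm = TRUE); hi <- max(a, na.rm = TRUE)
    if (!is.finite(lo)) { lo <- 0; hi <- 1 }
    if (hi == lo) hi <- lo + 1
    list(data = (a - lo) / (hi - lo), lo = lo, hi = hi)
  }
}

#' Write a multi-channel volume as per-channel TIFF plus a YAML sidecar
#'
#' One multi-page TIFF per channel (z slices as pages) and a
#' `<prefix>.yaml` sidecar holding voxel size, origin, time point, channel
#' names and the intensity scaling. 16-bit integer volumes round-trip
#' bit-identically; float volumes are stored as normalized 32-bit float.
#'
#' @param vol A [volume_image()].
#' @param prefix Output path prefix (no extension).
#' @param bits 16 (integer data) or 32 (float).
#' @return Invisibly, the sidecar path.
#' @export
write_volume <- function(vol, prefix, bits = 32L) {
  stopifnot(inherits(vol, "volume_image"), bits %in% c(16L, 32L))
  meta <- list(format = "rhizolight-volume-1",
               voxel_size_um = as.numeric(vol$voxel_size_um),
               origin_um = as.numeric(vol$origin_um),
               timepoint_h = if (is.finite(vol$timepoint_h)) vol$timepoint_h else NULL,
               bits = as.integer(bits), channels = list())
  for (ch in names(vol$channels)) {
    a <- vol$channels[[ch]]
    a[is.na(a)] <- 0
    sc <- scale_to_unit(a, bits)
    pages <- lapply(seq_len(dim(a)[1]), function(z) sc$data[z, , ])
    f <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, f, bits.per.sample = bits)
    meta$channels[[ch]] <- list(file = basename(f), lo = sc$lo, hi = sc$hi)
  }
  side <- paste0(prefix, ".yaml")
  yaml::write_yaml(meta, side)
  invisible(side)
}

#' Read a volume written by [write_volume()]
#'
#' @param prefix Path prefix or the sidecar path itself.
#' @return A [volume_image()].
#' @export
read_volume <- function(prefix) {
  side <- if (grepl("\\.ya?ml$", prefix)) prefix else paste0(prefix, ".yaml")
  if (!file.exists(side))
    stop("missing sidecar metadata: ", side)
  meta <- yaml::read_yaml(side)
  if (is.null(meta$voxel_size_um))
    stop("metadata error: voxel size missing from ", side)
  dirn <- dirname(side)
  channels <- list()
  for (ch in names(meta$channels)) {
    e <- meta$channels[[ch]]
    pages <- tiff::readTIFF(file.path(dirn, e$file), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(length(pages), dim(pages[[1]]))
    a <- array(0, d)
    for (z in seq_len(d[1])) a[z, , ] <- pages[[z]]
    channels[[ch]] <- e$lo + a * (e$hi - e$lo)
  }
  volume_image(channels, voxel_size_um = unlist(meta$voxel_size_um),
               origin_um = unlist(meta$origin_um) %||% c(0, 0, 0),
               timepoint_h = meta$timepoint_h %||% NA_real_)
}

# ---- tiles + manifest -----------------------------------------------------

#' Write rendered tiles and a YAML scan manifest
#'
#' @param tiles List of [tile_stack()] objects.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_tiles <- function(tiles, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (t in tiles) {
    tt <- if (is.finite(t$timepoint_h)) sprintf("_t%03d", round(t$timepoint_h)) else ""
    f <- sprintf("tile_%d_%d_%s%s.tif", t$tile_index[1], t$tile_index[2], t$channel, tt)
    a <- t$frames
    sc <- scale_to_unit(a, 32L)
    pages <- lapply(seq_len(dim(a)[1]), function(k) sc$data[k, , ])
    tiff::writeTIFF(pages, file.path(dir, f), bits.per.sample = 32L)
    entries[[length(entries) + 1L]] <- list(
      file = f, channel = t$channel, tile_index = as.integer(t$tile_index),
      origin_um = as.numeric(t$origin_um), lo = sc$lo, hi = sc$hi,
      timepoint_h = if (is.finite(t$timepoint_h)) t$timepoint_h else NULL)
  }
  man <- list(format = "rhizolight-tiles-1", units = "um",
              scan_angle_deg = tiles[[1]]$scan_angle_deg,
              slice_step_um = tiles[[1]]$slice_step_um,
              pixel_size_um = tiles[[1]]$pixel_size_um,
              seed = seed, tiles = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Read tiles from a YAML scan manifest
#' @param manifest Manifest path.
#' @return List of [tile_stack()] objects.
#' @export
read_tiles <- function(manifest) {
  man <- yaml::read_yaml(manifest)
  if (is.null(man$scan_angle_deg)) stop("metadata error: scan angle missing")
  dirn <- dirname(manifest)
  lapply(man$tiles, function(e) {
    pages <- tiff::readTIFF(file.path(dirn, e$file), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(length(pages), dim(pages[[1]]))
    a <- array(0, d)
    for (k in seq_len(d[1])) a[k, , ] <- pages[[k]]
    tile_stack(e$lo + a * (e$hi - e$lo), channel = e$channel,
               tile_index = unlist(e$tile_index), origin_um = unlist(e$origin_um),
               scan_angle_deg = man$scan_angle_deg, slice_step_um = man$slice_step_um,
               pixel_size_um = man$pixel_size_um,
               timepoint_h = e$timepoint_h %||% NA_real_)
  })
}

# ---- tabular outputs ------------------------------------------------------

#' Write a data frame as CSV with a YAML metadata header
#'
#' Metadata lines are prefixed with `#` so the file stays plain CSV.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Named list of metadata values.
#' @export
write_table_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    hdr <- strsplit(yaml::as.yaml(meta), "\n")[[1]]
    writeLines(paste0("# ", hdr), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#' @param path File path.
#' @return Data frame with attribute `"meta"`.
#' @export
read_table_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^# ", lines)
  df <- utils::read.csv(text = paste(lines[!hdr], collapse = "\n"))
  if (any(hdr))
    attr(df, "meta") <- yaml::yaml.load(paste(sub("^# ", "", lines[hdr]), collapse = "\n"))
  df
}
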