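# ---- distance maps --------------------------------------------------------

#' Euclidean distance from the root surface (um)
#'
#' Exact anisotropy-aware Euclidean distance transform: 0 on root voxels,
#' distance to the nearest root voxel centre elsewhere.
#'
#' @param root Logical root mask.
#' @param voxel_size_um Voxel size, scalar or (z, y, x).
#' @return Numeric array of distances (um).
#' @export
distance_from_root <- function(root, voxel_size_um) {
  if (!any(root)) stop("empty root mask")
  d <- dim(root)
  out <- cpp_edt(root, d, rep_len(as.numeric(voxel_size_um), 3))
  dim(out) <- d
  out
}

#' Root centerline, tip, and distance-from-tip map
#'
#' The centerline is the longest geodesic path through the root mask
#' (Dijkstra with 26-neighbour physical step lengths, lightly smoothed): the
#' tip is the voxel geodesically farthest from the base end, and each voxel
#' of the volume is assigned the arc length (from the tip) of its nearest
#' centerline node.
#'
#' @param root Logical root mask (one connected component).
#' @param voxel_size_um Voxel size.
#' @param base_um Optional physical point (z, y, x um) marking the base end;
#'   default is the root voxel with smallest y (top of the chamber).
#' @param origin_um Grid origin.
#' @return List with `centerline_um` (nodes, tip first), `arclength_um`,
#'   `tip_um`, `length_um`, `from_tip_um` (map), `centerline_dist_um` (map).
#' @export
centerline_and_tip <- function(root, voxel_size_um, base_um = NULL,
                               origin_um = c(0, 0, 0)) {
  d <- dim(root)
  vs <- rep_len(as.numeric(voxel_size_um), 3)
  idx <- which(root)
  if (!length(idx)) stop("empty root mask")
  coord <- arrayInd(idx, d)
  if (is.null(base_um)) {
    b <- idx[which.min(coord[, 2])]
  } else {
    pos <- sweep(sweep(coord - 1, 2, vs, "*"), 2, origin_um, "+")
    b <- idx[which.min(colSums((t(pos) - base_um)^2))]
  }
  geo <- cpp_geodesic(root, d, vs, as.integer(b - 1L))
  gd <- geo$dist
  gd[!is.finite(gd)] <- NA
  tip <- which.max(gd)
  if (is.na(gd[tip]) || gd[tip] <= 0)
    stop("degenerate root mask: no geodesic path; review threshold and seeds")
  path <- tip
  p <- geo$pred[tip]
  while (p > 0) {
    path <- c(path, p)
    p <- geo$pred[p]
  }
  if (length(path) < 3)
    stop("degenerate root mask: skeleton too short; review threshold and seeds")
  nodes <- sweep(sweep(arrayInd(path, d) - 1, 2, vs, "*"), 2, origin_um, "+")
  # light smoothing tames the 26-connectivity zigzag before arc-length measure
  if (nrow(nodes) >= 5) {
    sm <- nodes
    for (a in 1:3) sm[, a] <- stats::filter(nodes[, a], rep(1 / 5, 5), sides = 2)
    keep <- !is.na(sm[, 1])
    sm[!keep, ] <- nodes[!keep, ]
    nodes <- sm
  }
  seg <- sqrt(rowSums((nodes[-1, , drop = FALSE] - nodes[-nrow(nodes), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))  # measured from the tip (path starts at tip)
  nn <- cpp_nearest_node(nodes, arc, d, vs, as.numeric(origin_um))
  ft <- nn$arclength; dim(ft) <- d
  cd <- nn$dist; dim(cd) <- d
  list(centerline_um = nodes, arclength_um = arc, tip_um = nodes[1, ],
       length_um = arc[length(arc)], from_tip_um = ft, centerline_dist_um = cd)
}

# ---- calibration ----------------------------------------------------------

#' Fit the fluorescence-to-cell-density calibration
#'
#' Two regressions, following the suspension calibration protocol (12
#' dilutions spanning OD600 1.2e-3 to 3.0): ordinary least squares
#' `intensity = a * OD + b`, and a through-origin fit `CFU = c * OD`.
#'
#' @param standards Data frame with columns `intensity`, `od600`.
#' @param cfu_points Data frame with columns `od600`, `cfu`.
#' @return An object of class `calibration_model` with slopes `a`, offset
#'   `b`, `c` (CFU/mL per OD) and the two r-squared values.
#' @export
fit_calibration <- function(standards, cfu_points) {
  stopifnot(nrow(standards) >= 3, nrow(cfu_points) >= 3)
  if (max(standards$od600) / min(standards$od600) < 10)
    stop("calibration error: OD values must span at least one decade")
  if (stats::var(standards$intensity) == 0)
    stop("calibration error: non-positive intensity-vs-OD slope (constant intensity)")
  f1 <- stats::lm(intensity ~ od600, data = standards)
  a <- unname(stats::coef(f1)[2]); b <- unname(stats::coef(f1)[1])
  if (!is.finite(a) || a <= 0)
    stop("calibration error: non-positive intensity-vs-OD slope")
  f2 <- stats::lm(cfu ~ 0 + od600, data = cfu_points)
  cc <- unname(stats::coef(f2)[1])
  if (!is.finite(cc) || cc <= 0)
    stop("calibration error: non-positive CFU-vs-OD slope")
  r2 <- function(f) suppressWarnings(summary(f)$r.squared)  # exact fits warn
  structure(list(intensity_per_od = a, intensity_offset = b, cfu_per_od = cc,
                 r2_intensity_od = r2(f1), r2_od_cfu = r2(f2)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> I = %.4g * OD + %.4g (r2 %.4f); CFU = %.4g * OD (r2 %.4f)\n",
              x$intensity_per_od, x$intensity_offset, x$r2_intensity_od,
              x$cfu_per_od, x$r2_od_cfu))
  invisible(x)
}

#' Convert GFP intensity to bacterial cell density
#'
#' `density = c * (intensity - b) / a`, clipped at zero.
#'
#' @param gfp A [volume_image()] GFP channel or array.
#' @param calib A [fit_calibration()] model.
#' @return Density array (CFU/mL); attribute `"clipped"` counts negatives.
#' @export
intensity_to_density <- function(gfp, calib) {
  a <- if (inherits(gfp, "volume_image")) vol_channel(gfp, "gfp") else gfp
  dens <- calib$cfu_per_od * (a - calib$intensity_offset) / calib$intensity_per_od
  nneg <- sum(dens < 0, na.rm = TRUE)
  dens <- pmax(dens, 0)
  attr(dens, "clipped") <- nneg
  dens
}

# ---- pixel classification -------------------------------------------------

#' Classify soil voxels into analysis groups
#'
#' Groups (Rk) partition the analyzed soil volume by position perpendicular
#' to the root (`by_root_distance`, `rhizosphere_bulk`: rhizosphere is
#' distance < 0.2 mm), along the root (`by_tip_distance`, `tip_base`: base is
#' more than 2 mm from the tip), or pore size (`by_pore_size`). Radial
#' schemes are restricted to a 3 mm-diameter cylinder around the root
#' centerline. Binning is half-open `[lo, hi)`; boundary values fall upward.
#'
#' @param scheme One of `"by_root_distance"`, `"by_tip_distance"`,
#'   `"by_pore_size"`, `"rhizosphere_bulk"`, `"tip_base"`.
#' @param soil_mask Logical mask of analyzed soil (pore) voxels.
#' @param root_dist_um,tip_dist_um,pore_size_um Maps as required by the
#'   scheme.
#' @param centerline_dist_um Distance-to-centerline map for the radial
#'   cylinder restriction.
#' @param bin_edges Increasing bin edges (um); defaults per scheme.
#' @param analysis_radius_um Radius of the centerline cylinder (default
#'   1500 um, i.e. 3 mm diameter).
#' @return An object of class `pixel_groups`: integer `group` array (NA
#'   outside the analyzed region), `labels`, `bin_edges`, `scheme`.
#' @export
classify_pixels <- function(scheme, soil_mask, root_dist_um = NULL,
                            tip_dist_um = NULL, pore_size_um = NULL,
                            centerline_dist_um = NULL, bin_edges = NULL,
                            analysis_radius_um = 1500) {
  scheme <- match.arg(scheme, c("by_root_distance", "by_tip_distance",
                                "by_pore_size", "rhizosphere_bulk", "tip_base"))
  d <- dim(soil_mask)
  need <- function(x, nm) {
    if (is.null(x)) stop("scheme ", scheme, " requires ", nm)
    if (!identical(dim(x), d)) stop("map grids differ for ", nm)
    x
  }
  radial <- scheme %in% c("by_root_distance", "rhizosphere_bulk")
  vals <- switch(scheme,
    by_root_distance = , rhizosphere_bulk = need(root_dist_um, "root_dist_um"),
    by_tip_distance = , tip_base = need(tip_dist_um, "tip_dist_um"),
    by_pore_size = need(pore_size_um, "pore_size_um"))
  edges <- bin_edges %||% switch(scheme,
    by_root_distance = seq(0, 3000, by = 100),
    rhizosphere_bulk = c(0, 200, Inf),
    by_tip_distance = seq(0, ceiling(max(vals[soil_mask]) / 500) * 500, by = 500),
    tip_base = c(0, 2000, Inf),
    by_pore_size = c(seq(0, 1000, by = 100), Inf))
  if (is.unsorted(edges, strictly = TRUE)) stop("parameter error: bin edges must be increasing")
  analyzed <- soil_mask
  if (radial) {
    cd <- need(centerline_dist_um, "centerline_dist_um")
    analyzed <- analyzed & cd <= analysis_radius_um
  }
  if (scheme == "by_root_distance") analyzed <- analyzed & vals < edges[length(edges)]
  g <- array(NA_integer_, d)
  gi <- findInterval(vals[analyzed], edges)
  gi[gi < 1 | gi >= length(edges)] <- NA_integer_
  g[analyzed] <- gi
  labels <- switch(scheme,
    rhizosphere_bulk = c("rhizosphere", "bulk"),
    tip_base = c("tip", "base"),
    paste0("[", utils::head(edges, -1), ",", utils::tail(edges, -1), ")"))
  structure(list(scheme = scheme, group = g, labels = labels, bin_edges = edges,
                 n_groups = length(edges) - 1L),
            class = "pixel_groups")
}

# ---- indicators -----------------------------------------------------------

#' Bacterial colonization indicators per group and time point
#'
#' For each pixel group Rk at time t, the cell density D is the mean density
#' over the group's soil voxels (CFU/mL), optionally expressed per unit
#' volume of root; the normalized density D/<D> divides by the mean over the
#' scheme's groups at that time; and the mobility indicator is the temporal
#' variance of the normalized density after discarding the first
#' `discard_first` time points (5, allowing sufficient mature-root soil).
#'
#' @param density_list List of density arrays (CFU/mL), one per time point.
#' @param groups A [classify_pixels()] result, or a list of them (one per
#'   time point when groups follow the growing root).
#' @param times_h Time points (h).
#' @param root_volume_mm3 Optional numeric vector of segmented root volumes;
#'   when given, D is divided by it (per unit volume of root).
#' @param discard_first Time points discarded before the variance (default 5).
#' @param normalize_over `"groups"` (default: spatial mean at fixed time) or
#'   `"time"` (temporal mean per group).
#' @return Data frame with one row per (time, group): columns `timepoint_h`,
#'   `scheme`, `group_id`, `group_label`, `D`, `D_norm`, `variance`,
#'   `voxel_count`.
#' @export
compute_indicators <- function(density_list, groups, times_h,
                               root_volume_mm3 = NULL, discard_first = 5L,
                               normalize_over = c("groups", "time")) {
  normalize_over <- match.arg(normalize_over)
  nt <- length(times_h)
  stopifnot(length(density_list) == nt)
  glist <- if (inherits(groups, "pixel_groups")) rep(list(groups), nt) else groups
  stopifnot(length(glist) == nt)
  ng <- glist[[1]]$n_groups
  scheme <- glist[[1]]$scheme
  D <- matrix(NA_real_, ng, nt)
  cnt <- matrix(0L, ng, nt)
  for (ti in seq_len(nt)) {
    g <- glist[[ti]]$group
    dens <- density_list[[ti]]
    ok <- !is.na(g)
    sums <- tapply(dens[ok], g[ok], sum)
    ns <- tapply(dens[ok], g[ok], length)
    ids <- as.integer(names(sums))
    D[ids, ti] <- sums / ns
    cnt[ids, ti] <- as.integer(ns)
    if (!is.null(root_volume_mm3)) D[, ti] <- D[, ti] / root_volume_mm3[ti]
  }
  Dn <- if (normalize_over == "groups") {
    sweep(D, 2, colMeans(D, na.rm = TRUE), "/")
  } else {
    sweep(D, 1, rowMeans(D, na.rm = TRUE), "/")
  }
  keep <- if (nt > discard_first) (discard_first + 1L):nt else seq_len(nt)
  v <- apply(Dn[, keep, drop = FALSE], 1, stats::var, na.rm = TRUE)
  out <- data.frame(
    timepoint_h = rep(times_h, each = ng),
    scheme = scheme,
    group_id = rep(seq_len(ng), nt),
    group_label = rep(glist[[1]]$labels, nt),
    D = as.vector(D),
    D_norm = as.vector(Dn),
    variance = rep(v, nt),
    voxel_count = as.vector(cnt))
  class(out) <- c("indicator_table", "data.frame")
  out
}

#' Small-pore/large-pore density ratio from an indicator table
#'
#' Voxel-weighted mean cell density in pores below the threshold divided by
#' the mean in larger pores, averaged over time points; recovers the
#' generator's pore-occupancy bias on phantoms.
#'
#' @param indicators An [compute_indicators()] table for the `by_pore_size`
#'   scheme (other schemes are filtered out).
#' @param threshold_um Pore-size split (default 400 um).
#' @return Ratio of mean densities (small / large pores).
#' @export
pore_bias_ratio <- function(indicators, threshold_um = 400) {
  df <- indicators[indicators$scheme == "by_pore_size", ]
  stopifnot(nrow(df) > 0)
  lo <- as.numeric(sub("\\[", "", sapply(strsplit(df$group_label, ","), `[`, 1)))
  small <- lo < threshold_um
  wm <- function(sel) {
    s <- df[sel & !is.na(df$D) & df$voxel_count > 0, ]
    sum(s$D * s$voxel_count) / sum(s$voxel_count)
  }
  wm(small) / wm(!small)
}

# ---- kinematics and time series -------------------------------------------

#' Colonization kinematics diagram (distance-from-tip x time)
#'
#' Mean bacterial density per along-root bin and time point. Hotspots fixed
#' in the laboratory frame appear as diagonal stripes: their distance from
#' the advancing tip grows at the elongation rate. Companion profiles give
#' the along-root mean and the along-root temporal variance of the density.
#'
#' @param density_list List of density arrays, one per time point.
#' @param from_tip_list List of distance-from-tip maps (um).
#' @param soil_masks Logical mask or list of masks of analyzed voxels.
#' @param times_h Strictly increasing time points (h).
#' @param bin_um Along-root bin width (um).
#' @param max_dist_um Largest distance binned (default: data maximum).
#' @param discard_first Time points excluded from the variance profile.
#' @return Object of class `kinematics_diagram`: `matrix` (bin x time),
#'   `bin_edges_um`, `times_h`, `mean_profile`, `var_profile`.
#' @export
kinematics_diagram <- function(density_list, from_tip_list, soil_masks, times_h,
                               bin_um = 500, max_dist_um = NULL, discard_first = 5L) {
  if (is.unsorted(times_h, strictly = TRUE))
    stop("times must be strictly increasing")
  nt <- length(times_h)
  if (!is.list(soil_masks)) soil_masks <- rep(list(soil_masks), nt)
  md <- max_dist_um %||% max(vapply(seq_len(nt), function(i)
    max(from_tip_list[[i]][soil_masks[[i]]]), 0))
  edges <- seq(0, ceiling(md / bin_um) * bin_um, by = bin_um)
  nb <- length(edges) - 1L
  M <- matrix(NA_real_, nb, nt)
  for (ti in seq_len(nt)) {
    m <- soil_masks[[ti]]
    b <- findInterval(from_tip_list[[ti]][m], edges)
    b[b < 1 | b > nb] <- NA
    dv <- density_list[[ti]][m]
    ok <- !is.na(b)
    s <- tapply(dv[ok], b[ok], mean)
    M[as.integer(names(s)), ti] <- s
  }
  keep <- if (nt > discard_first) (discard_first + 1L):nt else seq_len(nt)
  structure(list(matrix = M, bin_edges_um = edges, times_h = times_h,
                 mean_profile = rowMeans(M, na.rm = TRUE),
                 var_profile = apply(M[, keep, drop = FALSE], 1, stats::var, na.rm = TRUE)),
            class = "kinematics_diagram")
}

#' Slope of the dominant stripe in a kinematics diagram (um/h)
#'
#' Tracks the densest along-root bin over time and fits a line to its centre
#' position; for a laboratory-frame-fixed hotspot next to an elongating root
#' the slope equals the elongation rate.
#'
#' @param kin A [kinematics_diagram()].
#' @return Slope in um/h.
#' @export
stripe_slope <- function(kin) {
  ctr <- (utils::head(kin$bin_edges_um, -1) + utils::tail(kin$bin_edges_um, -1)) / 2
  pos <- apply(kin$matrix, 2, function(col)
    if (all(is.na(col))) NA_real_ else ctr[which.max(col)])
  ok <- is.finite(pos)
  unname(stats::coef(stats::lm(pos[ok] ~ kin$times_h[ok]))[2])
}

#' Rhizosphere, bulk-soil and whole-soil density time series
#'
#' Mean cell density within 0.2 mm of the root surface (rhizosphere), beyond
#' it (bulk soil), and over all analyzed soil, with plateau-tolerant peak
#' detection per curve.
#'
#' @param density_list List of density arrays per time point.
#' @param root_dist_list List of distance-from-root maps (um).
#' @param soil_masks Logical mask or list of masks.
#' @param times_h Time points (h).
#' @param cutoff_um Rhizosphere cutoff (default 200 um).
#' @param peak_tol Plateau tolerance for [peak_time()].
#' @return List with data frame `series` (columns `timepoint_h`,
#'   `rhizosphere`, `bulk`, `total`, `n_rhizosphere`, `n_bulk`) and `peaks_h`.
#' @export
timeseries_summary <- function(density_list, root_dist_list, soil_masks, times_h,
                               cutoff_um = 200, peak_tol = 0.01) {
  nt <- length(times_h)
  if (!is.list(soil_masks)) soil_masks <- rep(list(soil_masks), nt)
  rows <- lapply(seq_len(nt), function(ti) {
    m <- soil_masks[[ti]]
    rd <- root_dist_list[[ti]]
    dv <- density_list[[ti]]
    rh <- m & rd < cutoff_um & rd > 0
    bk <- m & rd >= cutoff_um
    data.frame(timepoint_h = times_h[ti],
               rhizosphere = mean(dv[rh]), bulk = mean(dv[bk]),
               total = mean(dv[m & rd > 0]),
               n_rhizosphere = sum(rh), n_bulk = sum(bk))
  })
  series <- do.call(rbind, rows)
  peaks <- c(rhizosphere = peak_time(series$rhizosphere, times_h, peak_tol),
             bulk = peak_time(series$bulk, times_h, peak_tol),
             total = peak_time(series$total, times_h, peak_tol))
  list(series = series, peaks_h = peaks)
}
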