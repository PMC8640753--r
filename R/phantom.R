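#' Random sequential sphere packing of transparent-soil particles
#'
#' Generates non-overlapping spherical particles with diameters drawn
#' uniformly from `size_range_um` (0.25-1.25 mm, the grain sizes of the
#' fractured Nafion substrate), inserted largest-first by random sequential
#' addition until the target porosity is reached. When the remaining solid
#' deficit is smaller than the current candidate, the candidate diameter is
#' resampled below the deficit so the achieved porosity lands within one
#' minimum-particle volume of the target.
#'
#' @param chamber A [chamber_geometry()].
#' @param size_range_um Particle diameter range (min, max) in um.
#' @param target_porosity Target pore fraction in (0, 1]; 1 returns an empty
#'   packing.
#' @param seed Integer seed; packings are deterministic given the seed.
#' @param max_attempts Placement attempts per particle before the porosity is
#'   declared unreachable.
#' @return An object of class `particle_packing` with fields `centers_um`
#'   (n x 3, axis order z,y,x), `radii_um`, `porosity`, `chamber`.
#' @export
make_particle_packing <- function(chamber, size_range_um = c(250, 1250),
                                  target_porosity = 0.6, seed = 1L,
                                  max_attempts = 400L) {
  stopifnot(size_range_um[1] > 0, size_range_um[1] < size_range_um[2])
  if (target_porosity <= 0 || target_porosity > 1)
    stop("target_porosity must be in (0, 1]")
  ext <- chamber_extent_um(chamber)
  V <- prod(ext)
  out <- new.env()
  out$centers <- matrix(numeric(0), 0, 3)
  out$radii <- numeric(0)
  if (target_porosity == 1) {
    return(structure(list(centers_um = out$centers, radii_um = out$radii,
                          porosity = 1, target_porosity = 1,
                          size_range_um = size_range_um, chamber = chamber, seed = seed),
                     class = "particle_packing"))
  }
  target_solid <- (1 - target_porosity) * V
  vol_min <- 4 / 3 * pi * (size_range_um[1] / 2)^3
  if (size_range_um[2] > min(ext))
    stop("largest particle does not fit in the chamber")
  with_seed(seed, {
    # coarse occupancy grid for overlap queries
    cell <- size_range_um[2]
    gn <- pmax(1L, as.integer(ceiling(ext / cell)))
    grid <- vector("list", prod(gn))
    cell_of <- function(p) {
      ij <- pmin(gn - 1L, pmax(0L, as.integer(floor(p / cell))))
      1L + ij[1] + gn[1] * (ij[2] + gn[2] * ij[3])
    }
    solid <- 0
    dmax <- size_range_um[2]
    batch <- sort(stats::runif(4096, size_range_um[1], size_range_um[2]), decreasing = TRUE)
    bi <- 0L
    repeat {
      deficit <- target_solid - solid
      if (deficit < vol_min / 2) break
      bi <- bi + 1L
      if (bi > length(batch)) {
        batch <- sort(stats::runif(4096, size_range_um[1], size_range_um[2]), decreasing = TRUE)
        bi <- 1L
      }
      d <- batch[bi]
      # keep the packing on target: shrink candidates that overshoot
      d_fit <- 2 * (3 * deficit / (4 * pi))^(1 / 3)
      if (4 / 3 * pi * (d / 2)^3 > deficit) d <- max(size_range_um[1], min(d, d_fit))
      placed <- FALSE
      repeat {
        r <- d / 2
        for (a in seq_len(max_attempts)) {
          p <- stats::runif(3, min = r, max = ext - r)
          ok <- TRUE
          ij <- as.integer(floor(p / cell))
          for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
            q <- ij + c(dz, dy, dx)
            if (any(q < 0) || any(q >= gn)) next
            ci <- 1L + q[1] + gn[1] * (q[2] + gn[2] * q[3])
            for (k in grid[[ci]]) {
              if (sum((out$centers[k, ] - p)^2) < (out$radii[k] + r)^2) { ok <- FALSE; break }
            }
            if (!ok) break
          }
          if (ok) {
            out$centers <- rbind(out$centers, p)
            out$radii <- c(out$radii, r)
            ci <- cell_of(p)
            grid[[ci]] <- c(grid[[ci]], length(out$radii))
            solid <- solid + 4 / 3 * pi * r^3
            placed <- TRUE
            break
          }
        }
        if (placed) break
        # a crowded bed rejects large grains first: retry with a smaller one
        if (d > size_range_um[1] * 1.001) {
          d <- max(size_range_um[1], 0.8 * d)
        } else break
      }
      if (!placed) {
        achieved <- 1 - solid / V
        stop(sprintf(
          "target porosity %.3f unreachable by random sequential addition; achieved %.3f",
          target_porosity, achieved))
      }
    }
  })
  rownames(out$centers) <- NULL
  structure(list(centers_um = out$centers, radii_um = out$radii,
                 porosity = 1 - sum(4 / 3 * pi * out$radii^3) / V,
                 target_porosity = target_porosity,
                 size_range_um = size_range_um, chamber = chamber, seed = seed),
            class = "particle_packing")
}

#' @export
print.particle_packing <- function(x, ...) {
  cat(sprintf("<particle_packing> %d particles, diameters %g-%g um, porosity %.4f\n",
              length(x$radii_um), x$size_range_um[1], x$size_range_um[2], x$porosity))
  invisible(x)
}

#' Rasterize a particle packing onto a voxel grid
#' @param packing A [make_particle_packing()] result.
#' @param voxel_size_um Isotropic voxel size (um).
#' @param dims Grid dimensions (z, y, x); default covers the chamber.
#' @param origin_um Position of voxel (1,1,1).
#' @return Logical array, TRUE inside particles.
#' @export
rasterize_packing <- function(packing, voxel_size_um, dims = NULL, origin_um = c(0, 0, 0)) {
  ext <- chamber_extent_um(packing$chamber)
  dims <- dims %||% pmax(1L, as.integer(round(ext / voxel_size_um)))
  m <- cpp_paint_spheres(packing$centers_um, packing$radii_um, as.integer(dims),
                         rep_len(voxel_size_um, 3), as.numeric(origin_um))
  dim(m) <- dims
  m
}

#' Straight seedling root elongating at a constant rate
#'
#' The root is modelled as a tube of constant radius along a straight
#' centerline; the seedling starts at ~2 mm length and the centerline arc
#' length grows as `initial_length_um + elongation_rate_um_h * timepoint_h`.
#' Roots reaching the chamber boundary are truncated with a warning flag.
#'
#' @param base_um Root base (z, y, x) in um.
#' @param direction Growth direction vector (z, y, x); normalized internally.
#' @param radius_um Root radius in um.
#' @param elongation_rate_um_h Elongation rate (um/h).
#' @param timepoint_h Hours post inoculation (>= 0).
#' @param initial_length_um Root length at t = 0 (um).
#' @param chamber Optional [chamber_geometry()] used for truncation.
#' @param node_step_um Centerline node spacing (um).
#' @return An object of class `root_model`.
#' @export
grow_root <- function(base_um, direction = c(0, 1, 0), radius_um = 250,
                      elongation_rate_um_h = 250, timepoint_h = 0,
                      initial_length_um = 2000, chamber = NULL, node_step_um = 100) {
  stopifnot(timepoint_h >= 0, elongation_rate_um_h >= 0, radius_um > 0)
  dir <- direction / sqrt(sum(direction^2))
  L <- initial_length_um + elongation_rate_um_h * timepoint_h
  truncated <- FALSE
  if (!is.null(chamber)) {
    ext <- chamber_extent_um(chamber)
    # largest arc length keeping the tube inside the chamber walls
    smax <- L
    for (a in 1:3) {
      if (dir[a] > 1e-12) smax <- min(smax, (ext[a] - radius_um - base_um[a]) / dir[a])
      if (dir[a] < -1e-12) smax <- min(smax, (radius_um - base_um[a]) / dir[a])
    }
    if (smax < L) {
      warning(sprintf("root truncated at chamber boundary (%.0f of %.0f um)", smax, L))
      L <- max(smax, 0)
      truncated <- TRUE
    }
  }
  s <- unique(c(seq(0, L, by = node_step_um), L))
  nodes <- cbind(base_um[1] + s * dir[1], base_um[2] + s * dir[2], base_um[3] + s * dir[3])
  structure(list(centerline_um = nodes, radius_profile_um = rep(radius_um, nrow(nodes)),
                 tip_um = nodes[nrow(nodes), ], elongation_rate_um_h = elongation_rate_um_h,
                 timepoint_h = timepoint_h, length_um = L, truncated = truncated),
            class = "root_model")
}

#' Arc length of a root centerline (um)
#' @param root A `root_model`.
#' @export
root_length <- function(root) {
  n <- root$centerline_um
  if (nrow(n) < 2) return(0)
  sum(sqrt(rowSums((n[-1, , drop = FALSE] - n[-nrow(n), , drop = FALSE])^2)))
}

#' Rasterize a root model onto a voxel grid
#' @inheritParams rasterize_packing
#' @param root A `root_model`.
#' @param dims Grid dimensions (z, y, x).
#' @return Logical array, TRUE inside the root.
#' @export
rasterize_root <- function(root, voxel_size_um, dims, origin_um = c(0, 0, 0)) {
  m <- cpp_paint_tube(root$centerline_um, root$radius_profile_um, as.integer(dims),
                      rep_len(voxel_size_um, 3), as.numeric(origin_um))
  dim(m) <- dims
  m
}

#' Specification of the synthetic bacterial density field
#'
#' Encodes the study conditions of the colonization experiment: a pulsatile
#' hotspot schedule (~4 h apart, maintained ~2 h), preferential occupancy of
#' pores below 400 um (3x weighting), accumulation near the root surface, and
#' temporal envelopes placing the bulk-soil density peak at 26 h and the
#' rhizosphere peak at 32 h post inoculation.
#'
#' @param source_point_um Optional inoculation point (z, y, x um); hotspot
#'   placement is biased towards it when given.
#' @param hotspot_period_h,hotspot_duration_h Pulse schedule: hotspots are
#'   active when `(t %% period) < duration`. Period must exceed duration.
#' @param pore_bias_threshold_um,pore_bias_strength Pores thinner than the
#'   threshold carry `pore_bias_strength` times the density (>= 1).
#' @param root_accumulation_scale_um Exponential decay length of the
#'   near-root accumulation term.
#' @param background_density Bulk background density (CFU/mL).
#' @param root_accumulation_density Amplitude of the near-root term (CFU/mL).
#' @param hotspot_density,hotspot_radius_um,n_hotspots Gaussian hotspot
#'   amplitude (CFU/mL), radius (um) and count.
#' @param hotspot_min_sep_um Minimum separation between hotspot centres.
#' @param bulk_peak_h,bulk_sd_h Gaussian temporal envelope of the background
#'   term (NA disables the envelope).
#' @param rhizosphere_peak_h,rhizosphere_sd_h Temporal envelope of the
#'   near-root term.
#' @param phase_jitter_h Per-hotspot phase jitter (0 = synchronized pulses).
#' @return An object of class `bacteria_field_spec`.
#' @export
bacteria_field_spec <- function(source_point_um = NULL,
                                hotspot_period_h = 4, hotspot_duration_h = 2,
                                pore_bias_threshold_um = 400, pore_bias_strength = 3,
                                root_accumulation_scale_um = 300,
                                background_density = 5e6,
                                root_accumulation_density = 2e7,
                                hotspot_density = 4e7, hotspot_radius_um = 300,
                                n_hotspots = 6L, hotspot_min_sep_um = 1500,
                                bulk_peak_h = 26, bulk_sd_h = 6,
                                rhizosphere_peak_h = 32, rhizosphere_sd_h = 5,
                                phase_jitter_h = 0) {
  stopifnot(hotspot_period_h > hotspot_duration_h, hotspot_duration_h > 0,
            pore_bias_strength >= 1, background_density >= 0,
            root_accumulation_density >= 0, hotspot_density >= 0)
  structure(as.list(environment()), class = "bacteria_field_spec")
}

#' Whether hotspots are active at a time point
#'
#' The pulse schedule is `(t %% period) < duration` (phase jitter shifts t
#' per hotspot when enabled).
#'
#' @param spec A [bacteria_field_spec()].
#' @param timepoint_h Time in hours.
#' @param phase_h Optional per-hotspot phase shift.
#' @return Logical.
#' @export
hotspot_active <- function(spec, timepoint_h, phase_h = 0) {
  ((timepoint_h + phase_h) %% spec$hotspot_period_h) < spec$hotspot_duration_h
}

temporal_envelope <- function(t, peak_h, sd_h) {
  if (is.null(peak_h) || is.na(peak_h)) return(1)
  exp(-(t - peak_h)^2 / (2 * sd_h^2))
}

#' Seeded hotspot centre placement in the pore space
#'
#' Rejection-sampled pore voxels with a minimum pairwise separation
#' (Poisson-disc style); when a source point is given, candidates are
#' accepted with probability decaying with distance from it.
#'
#' @param spec A [bacteria_field_spec()].
#' @param pore_size_um Pore-size map (um, 0 outside pores).
#' @param voxel_size_um Voxel size.
#' @param seed Integer seed.
#' @param origin_um Grid origin.
#' @return Matrix of hotspot centres (n x 3, um).
#' @export
hotspot_positions <- function(spec, pore_size_um, voxel_size_um, seed,
                              origin_um = c(0, 0, 0)) {
  n <- spec$n_hotspots
  if (n < 1) return(matrix(numeric(0), 0, 3))
  d <- dim(pore_size_um)
  vs <- rep_len(voxel_size_um, 3)
  idx <- which(pore_size_um > 0)
  if (!length(idx)) stop("no pore voxels available for hotspot placement")
  with_seed(derive_seed(seed, 1L), {
    pts <- matrix(numeric(0), 0, 3)
    tries <- 0L
    while (nrow(pts) < n && tries < 20000L) {
      tries <- tries + 1L
      i <- idx[sample.int(length(idx), 1L)]
      z <- (i - 1) %% d[1]
      y <- ((i - 1) %/% d[1]) %% d[2]
      x <- (i - 1) %/% (d[1] * d[2])
      p <- origin_um + c(z, y, x) * vs
      if (!is.null(spec$source_point_um)) {
        dd <- sqrt(sum((p - spec$source_point_um)^2))
        if (stats::runif(1) > exp(-dd / (10 * spec$hotspot_min_sep_um))) next
      }
      if (nrow(pts) && min(sqrt(rowSums(sweep(pts, 2, p)^2))) < spec$hotspot_min_sep_um) next
      pts <- rbind(pts, p)
    }
    pts
  })
}

#' Synthetic bacterial cell density field (CFU/mL per voxel)
#'
#' Sum of a (temporally enveloped) background, a near-root accumulation term
#' decaying exponentially with distance from the root surface, and Gaussian
#' hotspot pulses active on the `(t %% period) < duration` schedule; voxels
#' in pores below the bias threshold are weighted by the bias strength, and
#' the field is zero outside the pore space.
#'
#' @param spec A [bacteria_field_spec()].
#' @param root_mask Logical root raster (same grid as `pore_size_um`).
#' @param pore_size_um Pore-size map (um; 0 outside pores).
#' @param voxel_size_um Voxel size (um).
#' @param timepoint_h Hours post inoculation.
#' @param seed Seed for hotspot placement (ignored when `hotspots` given).
#' @param hotspots Optional precomputed hotspot centres (n x 3 um).
#' @param origin_um Grid origin.
#' @return Numeric array of densities (CFU/mL), zero outside pores.
#' @export
bacteria_density_field <- function(spec, root_mask, pore_size_um, voxel_size_um,
                                   timepoint_h, seed = 1L, hotspots = NULL,
                                   origin_um = c(0, 0, 0)) {
  if (!identical(dim(root_mask), dim(pore_size_um)))
    stop("grid mismatch: root raster and pore-size map have different shapes")
  d <- dim(pore_size_um)
  vs <- rep_len(voxel_size_um, 3)
  pore <- pore_size_um > 0 & !root_mask
  field <- array(spec$background_density *
                   temporal_envelope(timepoint_h, spec$bulk_peak_h, spec$bulk_sd_h), d)
  if (spec$root_accumulation_density > 0 && any(root_mask)) {
    dr <- cpp_edt(root_mask, d, vs)
    field <- field + spec$root_accumulation_density *
      temporal_envelope(timepoint_h, spec$rhizosphere_peak_h, spec$rhizosphere_sd_h) *
      exp(-dr / spec$root_accumulation_scale_um)
  }
  if (spec$n_hotspots > 0 && spec$hotspot_density > 0) {
    hs <- hotspots %||% hotspot_positions(spec, pore_size_um, vs, seed, origin_um)
    if (nrow(hs)) {
      phases <- if (spec$phase_jitter_h > 0)
        with_seed(derive_seed(seed, 2L),
                  stats::runif(nrow(hs), -spec$phase_jitter_h, spec$phase_jitter_h))
      else rep(0, nrow(hs))
      sg <- spec$hotspot_radius_um
      # hotspot activity tracks the overall colonization envelope
      henv <- temporal_envelope(timepoint_h, spec$bulk_peak_h, spec$bulk_sd_h)
      for (i in seq_len(nrow(hs))) {
        if (!hotspot_active(spec, timepoint_h, phases[i])) next
        ctr <- hs[i, ]
        r3 <- 3 * sg
        lo <- pmax(1L, as.integer(floor((ctr - r3 - origin_um) / vs)) + 1L)
        hi <- pmin(d, as.integer(ceiling((ctr + r3 - origin_um) / vs)) + 1L)
        if (any(lo > hi)) next
        zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
        qz <- (origin_um[1] + (zi - 1) * vs[1] - ctr[1])^2
        qy <- (origin_um[2] + (yi - 1) * vs[2] - ctr[2])^2
        qx <- (origin_um[3] + (xi - 1) * vs[3] - ctr[3])^2
        blob <- spec$hotspot_density * henv *
          exp(-outer(outer(qz, qy, "+"), qx, "+") / (2 * sg^2))
        field[zi, yi, xi] <- field[zi, yi, xi] + blob
      }
    }
  }
  bias <- pore & pore_size_um < spec$pore_bias_threshold_um
  field[bias] <- field[bias] * spec$pore_bias_strength
  field[!pore] <- 0
  pmax(field, 0)
}
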