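# Generators for every pipeline input, each emitting its ground truth so the
# downstream measurement code always has an oracle. All generators are pure
# functions of their spec and seed.

#' Fourier contour specification
#'
#' Parameterises a near-circular cross-section as the polar curve
#' `r(theta) = base_radius + sum_k a_k cos(k theta + phi_k)`. Requiring the
#' base radius to exceed the total harmonic amplitude guarantees a
#' star-shaped, positive-radius contour — matching the near-circular leg
#' assumption while allowing controlled asphericity for the hip case.
#'
#' @param base_radius mm.
#' @param harmonics data.frame with columns `k` (integer harmonic),
#'   `amplitude` (mm), `phase` (rad); may be empty.
#' @param center length-2 (x, y) in mm.
#' @param n_vertices number of sampled vertices.
#' @param seed integer recorded in the spec (generation is deterministic).
#' @return object of class `contour_spec`.
#' @export
contour_spec <- function(base_radius, harmonics = NULL, center = c(0, 0),
                         n_vertices = 720, seed = 0L) {
  assert_scalar_num(base_radius, "base_radius", 0, strict_lower = TRUE)
  if (is.null(harmonics))
    harmonics <- data.frame(k = integer(), amplitude = numeric(),
                            phase = numeric())
  if (!all(c("k", "amplitude", "phase") %in% names(harmonics)))
    stopf("`harmonics` needs columns k, amplitude, phase")
  if (sum(abs(harmonics$amplitude)) >= base_radius)
    stopf("invalid spec: total harmonic amplitude %.3g >= base radius %.3g",
          sum(abs(harmonics$amplitude)), base_radius)
  if (n_vertices < 8L) stopf("`n_vertices` must be >= 8")
  structure(list(base_radius = base_radius, harmonics = harmonics,
                 center = as.numeric(center), n_vertices = as.integer(n_vertices),
                 seed = as.integer(seed)),
            class = "contour_spec")
}

contour_radius_at <- function(spec, theta) {
  r <- rep(spec$base_radius, length(theta))
  h <- spec$harmonics
  for (i in seq_len(nrow(h)))
    r <- r + h$amplitude[i] * cos(h$k[i] * theta + h$phase[i])
  r
}

#' Sample a contour from its spec
#'
#' @param spec a [contour_spec()].
#' @return `n_vertices x 2` (x, y) matrix in mm, counter-clockwise, with the
#'   generating polar radii attached as attribute `true_radii` and the
#'   sampling angles as `true_angles`.
#' @export
make_contour <- function(spec) {
  if (!inherits(spec, "contour_spec")) stopf("`spec` must be a contour_spec")
  theta <- 2 * pi * (seq_len(spec$n_vertices) - 1L) / spec$n_vertices
  r <- contour_radius_at(spec, theta)
  d <- ray_direction(theta)
  pts <- cbind(x = spec$center[1L] + r * d[, 1L],
               y = spec$center[2L] + r * d[, 2L])
  attr(pts, "true_angles") <- theta
  attr(pts, "true_radii") <- r
  pts
}

#' Apply a known radial deformation field to a contour
#'
#' Moves each vertex radially inward (toward the contour's vertex centroid)
#' by `field(theta)` mm, where theta is the vertex angle about the centroid.
#' The applied per-vertex offsets are attached as ground truth.
#'
#' @param points ordered (x, y) contour, mm.
#' @param field a function `theta (rad) -> mm`, or a single number for a
#'   uniform field. Positive values compress (move inward).
#' @return deformed contour with attributes `true_angles` and
#'   `true_deformation`.
#' @export
deform_contour <- function(points, field) {
  points <- as_points(points)
  if (is.numeric(field) && length(field) == 1L) {
    f0 <- field; field <- function(theta) rep(f0, length(theta))
  }
  if (!is.function(field)) stopf("`field` must be a function or scalar")
  ctr <- contour_centroid(points)
  theta <- point_angle(points, ctr)
  r <- sqrt(rowSums(sweep(points, 2L, ctr)^2))
  off <- field(theta)
  r_new <- r - off
  if (any(r_new <= 0))
    stopf("invalid field: deformation exceeds contour radius")
  d <- ray_direction(theta)
  out <- cbind(x = ctr[1L] + r_new * d[, 1L], y = ctr[2L] + r_new * d[, 2L])
  attr(out, "true_angles") <- theta
  attr(out, "true_deformation") <- off
  out
}

#' Rasterise a contour as a marker-coloured polyline
#'
#' Draws the closed contour as an approximately 1 px polyline in the marker
#' colour on a black background — the synthetic stand-in for the
#' CAD-exported section images. [extract_contour()] inverts it up to
#' rasterisation error (<= 1 px).
#'
#' @param points ordered (x, y) contour, mm.
#' @param image_size raster side length in px (square image).
#' @param pixel_scale mm per px.
#' @param marker_color length-3 RGB in 0-255 (default yellow 255,255,0).
#' @return `image_size x image_size x 3` array in `[0, 1]`.
#' @export
render_contour <- function(points, image_size = 512, pixel_scale = 0.5,
                           marker_color = c(255, 255, 0)) {
  points <- as_points(points)
  H <- W <- as.integer(image_size)
  extent <- image_size * pixel_scale
  if (any(points < pixel_scale) || any(points > extent - pixel_scale))
    stopf("invalid spec: contour does not fit inside the raster")
  closed <- rbind(points, points[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  # sample each edge at ~0.35 px spacing so the rasterised line is connected
  step <- 0.35 * pixel_scale
  t_all <- lapply(seq_len(nrow(points)), function(i) {
    n <- max(2L, ceiling(seg[i] / step) + 1L)
    tt <- seq(0, 1, length.out = n)
    cbind(closed[i, 1L] + tt * (closed[i + 1L, 1L] - closed[i, 1L]),
          closed[i, 2L] + tt * (closed[i + 1L, 2L] - closed[i, 2L]))
  })
  sm <- do.call(rbind, t_all)
  col <- pmin(W, pmax(1L, as.integer(ceiling(sm[, 1L] / pixel_scale))))
  row <- pmin(H, pmax(1L, as.integer(ceiling((extent - sm[, 2L]) / pixel_scale))))
  img <- array(0, dim = c(H, W, 3L))
  idx <- unique((col - 1L) * H + row)
  for (ch in 1:3) {
    plane <- matrix(0, H, W)
    plane[idx] <- marker_color[ch] / 255
    img[, , ch] <- plane
  }
  img
}

#' Loft stacked contours into a watertight limb mesh
#'
#' Builds a triangle mesh by lofting per-height contour specs (all sampled
#' with the same vertex count) and fan-capping the ends; optionally
#' replicates the limb at lateral offsets to emulate a two-leg scan.
#' Slicing the loft between levels recovers the linear interpolation of the
#' generating contours.
#'
#' @param levels list of `list(z = <mm>, spec = <contour_spec>)`, z strictly
#'   increasing.
#' @param limb_offsets list of length-2 (dx, dy) offsets, one limb each;
#'   default a single centred limb.
#' @return a [triangle_mesh()].
#' @export
make_limb_mesh <- function(levels, limb_offsets = list(c(0, 0))) {
  if (length(levels) < 2L) stopf("need >= 2 z-levels")
  zs <- vapply(levels, function(l) l$z, numeric(1))
  if (any(diff(zs) <= 0)) stopf("invalid spec: z-levels must strictly increase")
  n <- levels[[1L]]$spec$n_vertices
  for (l in levels)
    if (l$spec$n_vertices != n)
      stopf("all levels must share n_vertices")
  rings <- lapply(levels, function(l) make_contour(l$spec))
  all_v <- NULL; all_f <- NULL
  for (off in limb_offsets) {
    base <- if (is.null(all_v)) 0L else nrow(all_v)
    verts <- do.call(rbind, lapply(seq_along(rings), function(i)
      cbind(rings[[i]][, 1L] + off[1L], rings[[i]][, 2L] + off[2L], zs[i])))
    nl <- length(rings)
    faces <- vector("list", nl - 1L)
    for (i in seq_len(nl - 1L)) {
      a <- (i - 1L) * n + seq_len(n)
      b <- (i - 1L) * n + c(seq_len(n)[-1L], 1L)
      c2 <- i * n + c(seq_len(n)[-1L], 1L)
      d <- i * n + seq_len(n)
      faces[[i]] <- rbind(cbind(a, b, c2), cbind(a, c2, d))
    }
    faces <- do.call(rbind, faces)
    # end caps: fan to the ring centroid
    bot_c <- nrow(verts) + 1L
    top_c <- nrow(verts) + 2L
    verts <- rbind(verts,
                   c(colMeans(rings[[1L]]) + off, zs[1L]),
                   c(colMeans(rings[[nl]]) + off, zs[nl]))
    bot <- seq_len(n); top <- (nl - 1L) * n + seq_len(n)
    faces <- rbind(faces,
                   cbind(bot[c(seq_len(n)[-1L], 1L)], bot, bot_c),
                   cbind(top, top[c(seq_len(n)[-1L], 1L)], top_c))
    all_v <- rbind(all_v, verts)
    all_f <- rbind(all_f, faces + base)
  }
  triangle_mesh(all_v, all_f)
}

#' Synthetic stress-strain record with a known generating modulus
#'
#' Engineering-strain grid on `[0, max_strain]`; stress `E * strain` and
#' transverse strain `-v * strain`, each perturbed by multiplicative
#' Gaussian noise of relative standard deviation `noise_sd` (the measured
#' fabrics are linear to Pearson r ~ 0.99, which ~1% noise reproduces).
#'
#' @param E generating modulus, Pa (shear modulus when
#'   `direction = "shear"`).
#' @param v generating Poisson's ratio (ignored for shear).
#' @param noise_sd relative noise standard deviation (default 0.01).
#' @param n number of points (default 50).
#' @param seed RNG seed.
#' @param direction `"x"`, `"y"` or `"shear"`.
#' @param max_strain top of the strain grid (default 0.5).
#' @return a [stress_strain_record()].
#' @export
make_stress_strain <- function(E, v = 0, noise_sd = 0.01, n = 50, seed = 1L,
                               direction = "x", max_strain = 0.5) {
  assert_scalar_num(E, "E", 0, strict_lower = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  strain <- seq(0, max_strain, length.out = n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  stress <- E * strain * (1 + stats::rnorm(n, sd = noise_sd))
  tv <- if (direction == "shear") NULL
        else -v * strain * (1 + stats::rnorm(n, sd = noise_sd))
  stress_strain_record(direction, stress, strain, transverse_strain = tv,
                       label = sprintf("synthetic-%s-E%.3g", direction, E))
}

# preserve the caller's RNG stream around seeded generation
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Synthetic vibration recording
#'
#' Sinusoidal vertical position `amplitude * sin(2 pi f t + phase)` sampled
#' at `frame_rate`. The default phase of pi/2 starts the recording on a
#' peak, so that the degenerate 2-samples-per-cycle case (60 Hz filmed at
#' 120 fps) lands the frames on the extremes and the peak-to-peak
#' displacement `2 * amplitude` is observable.
#'
#' @param amplitude mm.
#' @param frequency Hz; `0` produces a constant (degenerate) sequence.
#' @param frame_rate frames per second (default 120).
#' @param n_cycles number of forcing cycles recorded (default 5).
#' @param phase phase offset in rad (default `pi/2`).
#' @return a [vibration_sequence()].
#' @export
make_vibration <- function(amplitude, frequency = 60, frame_rate = 120,
                           n_cycles = 5, phase = pi / 2) {
  assert_scalar_num(amplitude, "amplitude", 0)
  duration <- if (frequency > 0) n_cycles / frequency else n_cycles
  times <- seq(0, duration, by = 1 / frame_rate)
  pos <- amplitude * sin(2 * pi * frequency * times + phase)
  vibration_sequence(times, pos, frame_rate)
}

#' Default six-section synthetic limb
#'
#' Radii are the sample garment circumferences divided by 2 pi, inflated by
#' 10% so every section has positive garment stretch; each section carries a
#' mild 2nd/3rd-harmonic asphericity (larger on the hip sections).
#'
#' @param sample legging sample id 1-5 (default 4).
#' @param inflate relative limb-over-garment circumference excess
#'   (default 0.10).
#' @return data.frame with one row per section: `section`, `limb_radius_mm`,
#'   `garment_circumference_mm`, `section_height_mm`.
#' @export
default_limb <- function(sample = 4, inflate = 0.10) {
  sec <- legging_sections()
  sec <- sec[sec$sample == sample, ]
  data.frame(section = sec$section,
             limb_radius_mm = (1 + inflate) * sec$circumference_mm / (2 * pi),
             garment_circumference_mm = sec$circumference_mm,
             section_height_mm = sec$section_height_mm)
}

#' Write a complete synthetic fixture tree
#'
#' Generates and writes everything a pipeline run needs: per-section,
#' per-side (left/right) control and garment contour images (PNG), their
#' ground-truth deformation CSVs, a control limb mesh (ASCII STL),
#' stress-strain CSVs for the chosen fabric sample, a vibration CSV, and a
#' manifest JSON tying them together. The right side carries a slightly
#' different harmonic phase and 3% less deformation, emulating the mild
#' left/right asymmetry of a real body.
#'
#' @param dir output directory (created if missing).
#' @param seed global seed governing all stochastic generators.
#' @param sample legging sample id 1-5 used for geometry and fabric truth.
#' @param image_size raster side in px.
#' @param pixel_scale mm per px (default 0.7 so the hip sections fit a
#'   512 px raster).
#' @param deformation_mm uniform ground-truth deformation per section, mm;
#'   recycled over the six sections.
#' @return the manifest, invisibly.
#' @export
synth_fixtures <- function(dir, seed = 1L, sample = 4, image_size = 512,
                           pixel_scale = 0.7,
                           deformation_mm = c(3, 2.8, 2.5, 2.2, 1.8, 1.5)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  limb <- default_limb(sample)
  deformation_mm <- rep_len(deformation_mm, nrow(limb))
  fab <- legging_fabrics()
  fab <- fab[fab$sample == sample, ]
  extent <- image_size * pixel_scale
  center <- c(extent / 2, extent / 2)
  manifest <- list(seed = seed, sample = sample, image_size = image_size,
                   pixel_scale = pixel_scale, sections = list())
  for (i in seq_len(nrow(limb))) {
    R <- limb$limb_radius_mm[i]
    if (R * 1.06 > extent / 2 - 2 * pixel_scale)
      stopf("section %d radius %.1f mm does not fit a %.0f mm raster; increase image_size or pixel_scale",
            limb$section[i], R, extent)
    entry <- list(
      section = limb$section[i], limb_radius_mm = R,
      garment_circumference_mm = limb$garment_circumference_mm[i],
      section_height_mm = limb$section_height_mm[i],
      sides = list())
    for (side in c("left", "right")) {
      phase0 <- if (side == "left") 0.4 else 0.7
      defo <- deformation_mm[i] * if (side == "left") 1 else 0.97
      spec <- contour_spec(R, data.frame(k = c(2, 3),
                                         amplitude = c(0.04 * R, 0.015 * R),
                                         phase = c(phase0, phase0 + 0.7)),
                           center = center, seed = seed)
      ctrl <- make_contour(spec)
      garm <- deform_contour(ctrl, defo)
      stem <- sprintf("section%d_%s", limb$section[i], side)
      png::writePNG(render_contour(ctrl, image_size, pixel_scale),
                    file.path(dir, paste0(stem, "_control.png")))
      png::writePNG(render_contour(garm, image_size, pixel_scale),
                    file.path(dir, paste0(stem, "_garment.png")))
      utils::write.csv(
        data.frame(angle_rad = attr(garm, "true_angles"),
                   deformation_mm = attr(garm, "true_deformation")),
        file.path(dir, paste0(stem, "_truth.csv")), row.names = FALSE)
      entry$sides[[side]] <- list(
        deformation_mm = defo,
        control_image = paste0(stem, "_control.png"),
        garment_image = paste0(stem, "_garment.png"),
        truth = paste0(stem, "_truth.csv"))
    }
    manifest$sections[[i]] <- entry
  }
  # limb mesh from the six control sections (z = stacked section heights)
  zs <- cumsum(c(0, limb$section_height_mm))
  levels <- lapply(seq_len(nrow(limb) + 1L), function(i) {
    j <- min(i, nrow(limb))
    list(z = zs[i], spec = contour_spec(limb$limb_radius_mm[j],
                                        n_vertices = 180, seed = seed))
  })
  mesh_path <- file.path(dir, "limb_control.stl")
  write_stl_ascii(make_limb_mesh(levels), mesh_path)
  manifest$mesh <- basename(mesh_path)
  # fabric stress-strain records at the sample's measured constants
  ss <- rbind(
    ss_frame(make_stress_strain(fab$Ex_pa, fab$vxy, seed = seed, direction = "x")),
    ss_frame(make_stress_strain(fab$Ey_pa, fab$vxy, seed = seed + 1L, direction = "y")),
    ss_frame(make_stress_strain(fab$Gxy_pa, seed = seed + 2L, direction = "shear")))
  ss_path <- file.path(dir, "stress_strain.csv")
  utils::write.csv(ss, ss_path, row.names = FALSE)
  manifest$stress_strain <- basename(ss_path)
  manifest$fabric_truth <- as.list(fab)
  # vibration recording (matched to the scan protocol)
  vib <- make_vibration(amplitude = 4.71)
  vib_path <- file.path(dir, "vibration.csv")
  utils::write.csv(data.frame(time_s = vib$times, position_mm = vib$vertical_position),
                   vib_path, row.names = FALSE)
  manifest$vibration <- basename(vib_path)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

ss_frame <- function(rec) {
  data.frame(direction = rec$direction, stress_pa = rec$stress,
             strain = rec$strain,
             transverse_strain = if (is.null(rec$transverse_strain)) NA
                                 else rec$transverse_strain)
}
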