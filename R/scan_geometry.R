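# Measurement side of the package: cross-section contours, centroid-anchored
# radial profiles, with/without-garment differencing, mesh slicing, and
# extreme-frame selection for the vibration protocol.
#
# Coordinate conventions (section plane, viewed from above):
#   x = subject's left -> right (lateral axis), y = posterior -> anterior;
#   angle 0 points anterior (+y) and increases counter-clockwise, so the ray
#   direction at angle theta is (-sin(theta), cos(theta)).

ray_direction <- function(theta) cbind(-sin(theta), cos(theta))

# angle of points about an origin under the same convention, in [0, 2*pi)
point_angle <- function(xy, origin) {
  wrap_angle(atan2(-(xy[, 1] - origin[1]), xy[, 2] - origin[2]))
}

#' Default marker-colour predicate (robust yellow)
#'
#' The section contour is rendered in yellow; the default rule
#' `R >= 200 & G >= 200 & B <= 100` (8-bit channels) tolerates
#' anti-aliasing, while `marker_predicate(1)` reproduces the permissive
#' "any non-black channel >= threshold on R and G, B below" variant.
#'
#' @param threshold minimal 8-bit level demanded of the red and green
#'   channels (default 200); blue must stay at or below `255 - threshold`
#'   capped at 100.
#' @return function `(r, g, b) -> logical`, channels in 0-255.
#' @export
marker_predicate <- function(threshold = 200) {
  bmax <- min(100, 255 - threshold)
  function(r, g, b) r >= threshold & g >= threshold & b <= bmax
}

# 8-connected components of a logical matrix; returns integer label matrix
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  labels <- matrix(0L, H, W)
  todo <- which(mask)
  lab <- 0L
  dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  for (seed in todo) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- seed
    while (length(frontier)) {
      r <- (frontier - 1L) %% H + 1L
      c <- (frontier - 1L) %/% H + 1L
      rr <- rep(r, times = 8L) + rep(dr, each = length(r))
      cc <- rep(c, times = 8L) + rep(dc, each = length(c))
      ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
      nb <- unique((cc[ok] - 1L) * H + rr[ok])
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      frontier <- nb
    }
  }
  labels
}

#' Extract the marked contour from a section image
#'
#' Finds all pixels satisfying the marker-colour predicate, keeps the
#' largest 8-connected component (ties broken by topmost-then-leftmost
#' component centroid, with a message), takes its boundary pixels (those
#' with a 4-neighbour outside the component or on the image edge) and
#' returns them ordered counter-clockwise about the component centroid,
#' converted to mm with the origin at the image's lower-left corner (y up).
#'
#' @param image numeric array `H x W x 3`, channels in `[0, 1]` as returned
#'   by [png::readPNG()], or in 0-255.
#' @param marker predicate `(r, g, b) -> logical` on 8-bit channel values;
#'   default [marker_predicate()].
#' @param pixel_scale mm per pixel.
#' @return two-column matrix of (x, y) in mm, counter-clockwise.
#' @export
extract_contour <- function(image, marker = marker_predicate(),
                            pixel_scale = 1) {
  if (length(dim(image)) != 3L || dim(image)[3L] < 3L)
    stopf("`image` must be an H x W x 3 array")
  assert_scalar_num(pixel_scale, "pixel_scale", 0, strict_lower = TRUE)
  scale8 <- if (max(image) <= 1) 255 else 1
  mask <- marker(image[, , 1L] * scale8, image[, , 2L] * scale8,
                 image[, , 3L] * scale8)
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) stopf("empty contour: no marker pixels in image")
  labels <- label_components(mask)
  areas <- tabulate(labels[labels > 0L])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    # tie: topmost (smallest row), then leftmost (smallest column) centroid
    cent <- t(vapply(best, function(l) {
      i <- which(labels == l)
      c(mean((i - 1L) %% nrow(mask) + 1L), mean((i - 1L) %/% nrow(mask) + 1L))
    }, numeric(2)))
    best <- best[order(cent[, 1L], cent[, 2L])]
    message(sprintf("extract_contour: %d equal-area components; keeping topmost-leftmost",
                    length(best)))
  }
  comp <- labels == best[1L]
  H <- nrow(comp); W <- ncol(comp)
  # boundary: component pixels with a 4-neighbour outside the component
  pad <- function(m, r, c) {
    out <- matrix(FALSE, H, W)
    rs <- max(1, 1 + r):min(H, H + r); rd <- rs - r
    cs <- max(1, 1 + c):min(W, W + c); cd <- cs - c
    out[rd, cd] <- m[rs, cs]
    out
  }
  interior <- pad(comp, -1, 0) & pad(comp, 1, 0) & pad(comp, 0, -1) & pad(comp, 0, 1)
  boundary <- comp & !interior
  idx <- which(boundary)
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  xy <- cbind(x = (c - 0.5) * pixel_scale, y = (H - r + 0.5) * pixel_scale)
  ctr <- colMeans(xy)
  ord <- order(point_angle(xy, ctr))
  xy[ord, , drop = FALSE]
}

#' Vertex centroid of a contour
#'
#' Arithmetic mean of the vertex coordinates. This is deliberately the
#' vertex centroid, not the area centroid: anchored on a contour resampled
#' to uniform arc length it is invariant under rigid displacement of the
#' section, which is what cancels motion between scans.
#'
#' @param points two-column matrix of (x, y) in mm, >= 1 row.
#' @return numeric length-2 vector (x, y) in mm.
#' @export
contour_centroid <- function(points) {
  points <- as_points(points)
  if (nrow(points) < 1L) stopf("invalid input: empty point list")
  colMeans(points)
}

as_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stopf("`points` must be a two-column (x, y) matrix")
  storage.mode(points) <- "double"
  points
}

#' Resample a closed contour to uniform arc length
#'
#' Linear interpolation along the closed polyline at `n` equally spaced
#' arc-length positions. Applied before centroid computation so that vertex
#' density (which varies with mesh tessellation and rasterisation) does not
#' bias the vertex centroid.
#'
#' @param points two-column (x, y) matrix, treated as a closed polygon.
#' @param n number of output vertices (default 720).
#' @return `n x 2` matrix.
#' @export
resample_contour <- function(points, n = 720) {
  points <- as_points(points)
  if (nrow(points) < 3L) stopf("need >= 3 vertices to resample")
  closed <- rbind(points, points[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stopf("degenerate contour: zero perimeter")
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  x <- stats::approx(s, closed[, 1L], xout = target)$y
  y <- stats::approx(s, closed[, 2L], xout = target)$y
  cbind(x = x, y = y)
}

# even-odd point-in-polygon test
point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  xi <- poly[, 1L]; yi <- poly[, 2L]
  xj <- poly[j, 1L]; yj <- poly[j, 2L]
  cross <- ((yi > p[2L]) != (yj > p[2L])) &
    (p[1L] < (xj - xi) * (p[2L] - yi) / (yj - yi) + xi)
  sum(cross) %% 2L == 1L
}

#' Centroid-anchored radial profile of a contour
#'
#' For each of `n_angles` uniformly spaced directions from the centroid,
#' returns the distance to the first crossing of the contour along that ray
#' (exact ray/segment intersection, linear along contour edges). Requires
#' the centroid to lie inside the polygon; contours that a ray crosses more
#' than once (non-star-shaped, e.g. strongly curved hip sections) use the
#' first outward crossing and raise a single warning.
#'
#' @param points two-column (x, y) contour, ordered, treated as closed.
#' @param centroid length-2 anchor point; default [contour_centroid()].
#' @param n_angles number of rays (default 360).
#' @return list with `angles` (radians in `[0, 2 pi)`, 0 = anterior,
#'   counter-clockwise) and `radii` (mm).
#' @export
radial_profile <- function(points, centroid = NULL, n_angles = 360) {
  points <- as_points(points)
  if (nrow(points) < 8L) stopf("contour needs >= 8 points")
  if (is.null(centroid)) centroid <- contour_centroid(points)
  if (!point_in_polygon(centroid, points))
    stopf("non-star-shaped section: centroid lies outside the contour")
  angles <- 2 * pi * (seq_len(n_angles) - 1L) / n_angles
  p1 <- points
  p2 <- points[c(seq_len(nrow(points))[-1L], 1L), , drop = FALSE]
  ex <- p2[, 1L] - p1[, 1L]; ey <- p2[, 2L] - p1[, 2L]
  wx <- p1[, 1L] - centroid[1L]; wy <- p1[, 2L] - centroid[2L]
  vert_ang <- point_angle(points, centroid)
  vert_rad <- sqrt(wx^2 + wy^2)
  eps <- 1e-12
  multi <- FALSE
  radii <- vapply(angles, function(th) {
    d <- c(-sin(th), cos(th))
    det <- ex * d[2L] - d[1L] * ey
    ok <- abs(det) > eps
    t <- (ex * wy - wx * ey) / det
    s <- (d[1L] * wy - wx * d[2L]) / det
    hit <- ok & s >= 0 & s < 1 & t > eps
    if (!any(hit)) {
      # grazing ray: fall back to the vertex nearest in angle
      i <- which.min(pmin(abs(vert_ang - th), 2 * pi - abs(vert_ang - th)))
      return(vert_rad[i])
    }
    tt <- t[hit]
    # crossings more than 5% of the radius apart indicate a genuine fold;
    # tighter clusters are rasterisation jitter on pixel-derived contours
    if (length(tt) > 1L && diff(range(tt)) > 0.05 * min(tt)) multi <<- TRUE
    min(tt)
  }, numeric(1))
  if (multi)
    warnf("non-star-shaped contour: some rays cross the boundary more than once; using first crossing")
  list(angles = angles, radii = radii)
}

#' Cross-section profile of one body section under one wear condition
#'
#' Bundles an ordered contour with its (resampled-)vertex centroid and
#' radial profile. The contour is resampled to uniform arc length
#' (`n_resample` vertices) before the centroid is computed.
#'
#' @param points ordered (x, y) contour in mm.
#' @param section_id integer 1-6.
#' @param side `"left"`, `"right"` or `"hip"`.
#' @param condition wear condition label, e.g. `"control"` or `"legging_4"`.
#' @param n_angles angular resolution of the radial profile.
#' @param n_resample arc-length resampling density (default 720).
#' @param pixel_scale mm/px provenance tag for image-derived contours.
#' @return object of class `cross_section_profile`.
#' @export
cross_section_profile <- function(points, section_id = 1L,
                                  side = c("left", "right", "hip"),
                                  condition = "control", n_angles = 360,
                                  n_resample = 720, pixel_scale = NA_real_) {
  side <- match.arg(side)
  points <- resample_contour(as_points(points), n_resample)
  ctr <- contour_centroid(points)
  prof <- radial_profile(points, ctr, n_angles)
  if (any(prof$radii <= 0)) stopf("invalid contour: non-positive radius")
  structure(list(section_id = as.integer(section_id), side = side,
                 condition = condition, points = points, centroid = ctr,
                 angles = prof$angles, radii = prof$radii,
                 pixel_scale = pixel_scale),
            class = "cross_section_profile")
}

#' @export
print.cross_section_profile <- function(x, ...) {
  cat(sprintf("<cross_section_profile> section %d (%s, %s): %d angles, mean radius %.2f mm\n",
              x$section_id, x$side, x$condition, length(x$angles),
              mean(x$radii)))
  invisible(x)
}

quadrant_of <- function(angles) {
  deg <- (angles * 180 / pi) %% 360
  out <- rep("medial", length(deg))
  out[deg < 45 | deg >= 315] <- "anterior"
  out[deg >= 45 & deg < 135] <- "lateral"
  out[deg >= 135 & deg < 225] <- "posterior"
  factor(out, levels = c("anterior", "lateral", "posterior", "medial"))
}

#' Per-angle tissue deformation between two wear conditions
#'
#' Differences the radial profiles of a control ("thong only") and a
#' garment-condition scan of the same section: deformation(theta) =
#' control radius - garment radius. Each profile is anchored at its own
#' centroid, which is what cancels rigid displacement between the two scans.
#' Negative values (tissue bulge beyond the control contour) are retained.
#'
#' @param control,garment [cross_section_profile()]s with identical
#'   `section_id`, `side` and angle grid.
#' @return object of class `deformation_profile` with `per_angle`
#'   deformation (mm), overall `mean` and `max`, and `quadrants` (mean per
#'   anterior/lateral/posterior/medial quadrant).
#' @export
deformation_profile <- function(control, garment) {
  for (p in list(control, garment))
    if (!inherits(p, "cross_section_profile"))
      stopf("inputs must be cross_section_profile objects")
  if (control$section_id != garment$section_id || control$side != garment$side)
    stopf("invalid pairing: section/side mismatch (%d/%s vs %d/%s)",
          control$section_id, control$side, garment$section_id, garment$side)
  if (length(control$angles) != length(garment$angles) ||
      max(abs(control$angles - garment$angles)) > 1e-12)
    stopf("invalid pairing: angle grids differ")
  d <- control$radii - garment$radii
  q <- c(tapply(d, quadrant_of(control$angles), mean))
  structure(list(section_id = control$section_id, side = control$side,
                 condition = garment$condition, angles = control$angles,
                 per_angle = d, mean = mean(d), max = max(d),
                 quadrants = q),
            class = "deformation_profile")
}

#' @export
print.deformation_profile <- function(x, ...) {
  cat(sprintf("<deformation_profile> section %d (%s, %s): mean %.3f mm, max %.3f mm\n",
              x$section_id, x$side, x$condition, x$mean, x$max))
  invisible(x)
}

# --- mesh handling -----------------------------------------------------------

#' Triangle mesh container
#'
#' @param vertices `N x 3` numeric matrix (x, y, z) in mm.
#' @param faces `M x 3` integer matrix of 1-based vertex indices.
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stopf("vertices must be N x 3 and faces M x 3")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stopf("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, z in [%.2f, %.2f] mm\n",
              nrow(x$vertices), nrow(x$faces),
              min(x$vertices[, 3L]), max(x$vertices[, 3L])))
  invisible(x)
}

#' Slice a triangle mesh with a horizontal plane
#'
#' Intersects the plane `z = const` with every triangle, chains the
#' resulting segments into closed loops and returns them as ordered (x, y)
#' polygons sorted by descending enclosed area. When exactly two substantial
#' loops are found (a two-leg scan) they carry a `side` attribute: the loop
#' whose centroid has the smaller x is labelled `"right"` (scanner faces the
#' subject; set `flip_sides = TRUE` for the opposite convention). An open
#' chain (cracked mesh) is closed between its endpoints with a warning.
#'
#' @param mesh a [triangle_mesh()] (STL units assumed mm).
#' @param z slice height, mm.
#' @param flip_sides flip the left/right labelling convention.
#' @return list of ordered two-column (x, y) polygons (possibly empty).
#' @export
slice_mesh <- function(mesh, z, flip_sides = FALSE) {
  if (!inherits(mesh, "triangle_mesh")) stopf("`mesh` must be a triangle_mesh")
  assert_scalar_num(z, "z")
  V <- mesh$vertices
  # nudge the plane off any vertex to avoid degenerate point intersections
  zs <- V[, 3L]
  if (any(abs(zs - z) < 1e-9)) z <- z + 1e-7 * max(1, diff(range(zs)))
  h <- zs - z
  F1 <- mesh$faces[, 1L]; F2 <- mesh$faces[, 2L]; F3 <- mesh$faces[, 3L]
  s1 <- h[F1] > 0; s2 <- h[F2] > 0; s3 <- h[F3] > 0
  crossing <- !(s1 == s2 & s2 == s3)
  if (!any(crossing)) return(list())
  fc <- cbind(F1, F2, F3)[crossing, , drop = FALSE]
  edge_cut <- function(i, j) {
    hi <- h[i]; hj <- h[j]
    t <- hi / (hi - hj)
    cbind(V[i, 1L] + t * (V[j, 1L] - V[i, 1L]),
          V[i, 2L] + t * (V[j, 2L] - V[i, 2L]))
  }
  segs <- vector("list", nrow(fc))
  for (k in seq_len(nrow(fc))) {
    tri <- fc[k, ]
    hh <- h[tri]
    pos <- tri[hh > 0]; neg <- tri[hh <= 0]
    lone <- if (length(pos) == 1L) pos else neg
    pair <- setdiff(tri, lone)
    segs[[k]] <- rbind(edge_cut(lone, pair[1L]), edge_cut(lone, pair[2L]))
  }
  loops <- chain_segments(segs)
  areas <- vapply(loops, polygon_area, numeric(1))
  loops <- loops[order(abs(areas), decreasing = TRUE)]
  areas <- abs(sort(abs(areas), decreasing = TRUE))
  if (length(loops) >= 2L && areas[2L] > 0.25 * areas[1L]) {
    cx <- vapply(loops[1:2], function(p) mean(p[, 1L]), numeric(1))
    right_first <- cx[1L] < cx[2L]
    if (flip_sides) right_first <- !right_first
    attr(loops[[1L]], "side") <- if (right_first) "right" else "left"
    attr(loops[[2L]], "side") <- if (right_first) "left" else "right"
  }
  loops
}

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(seq_len(n)[-1L], 1L)
  sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]) / 2
}

# chain unordered segments (list of 2 x 2 point matrices) into closed loops
chain_segments <- function(segs) {
  if (length(segs) == 0L) return(list())
  ends <- do.call(rbind, segs)  # 2k rows; rows 2i-1, 2i belong to segment i
  key <- paste(round(ends[, 1L], 6), round(ends[, 2L], 6))
  lookup <- split(seq_len(nrow(ends)), key)
  used <- logical(length(segs))
  other_end <- function(row) if (row %% 2L == 0L) row - 1L else row + 1L
  seg_of <- function(row) (row + 1L) %/% 2L
  loops <- list()
  for (start in seq_along(segs)) {
    if (used[start]) next
    used[start] <- TRUE
    pts <- list(ends[2L * start - 1L, ])
    cur_row <- 2L * start
    start_key <- key[2L * start - 1L]
    repeat {
      pts[[length(pts) + 1L]] <- ends[cur_row, ]
      k <- key[cur_row]
      cand <- lookup[[k]]
      cand <- cand[!used[seg_of(cand)]]
      if (length(cand) == 0L) {
        if (k != start_key)
          warnf("slice_mesh: open intersection chain; closing between endpoints")
        break
      }
      nxt <- cand[1L]
      used[seg_of(nxt)] <- TRUE
      cur_row <- other_end(nxt)
    }
    poly <- do.call(rbind, pts)
    # drop the duplicated closing vertex if present
    if (nrow(poly) > 1L && sum(abs(poly[1L, ] - poly[nrow(poly), ])) < 1e-9)
      poly <- poly[-nrow(poly), , drop = FALSE]
    colnames(poly) <- c("x", "y")
    if (nrow(poly) >= 3L) loops[[length(loops) + 1L]] <- poly
  }
  loops
}

# --- STL I/O -----------------------------------------------------------------

#' Read an STL mesh (binary or ASCII)
#'
#' Units are assumed mm unless `scale` says otherwise. Vertices are not
#' welded; faces index the raw triangle soup (sufficient for slicing).
#'
#' @param path STL file path.
#' @param scale multiplicative unit conversion applied to coordinates.
#' @return a [triangle_mesh()].
#' @export
read_stl <- function(path, scale = 1) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  size <- file.info(path)$size
  close(con)
  is_binary <- length(ntri) == 1L && !is.na(ntri) &&
    size == 84 + 50 * as.numeric(ntri)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84L)
    raw <- readBin(con, "raw", 50L * ntri)
    m <- matrix(raw, nrow = 50L)
    flt <- readBin(as.vector(m[1:48, ]), "numeric", size = 4L,
                   n = 12L * ntri, endian = "little")
    flt <- matrix(flt, nrow = 12L)  # nx ny nz v1 v2 v3 per column
    verts <- matrix(as.vector(flt[4:12, ]), ncol = 3L, byrow = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stopf("%s: not a parsable STL file", path)
    nums <- strsplit(trimws(vl), "\\s+")
    verts <- t(vapply(nums, function(p) as.numeric(p[2:4]), numeric(3)))
  }
  verts <- verts * scale
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, faces)
}

#' Write a mesh as ASCII STL
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl_ascii <- function(mesh, path) {
  if (!inherits(mesh, "triangle_mesh")) stopf("`mesh` must be a triangle_mesh")
  V <- mesh$vertices; F <- mesh$faces
  p1 <- V[F[, 1L], , drop = FALSE]
  p2 <- V[F[, 2L], , drop = FALSE]
  p3 <- V[F[, 3L], , drop = FALSE]
  n <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) - (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
             (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) - (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
             (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) - (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1L], m[, 2L], m[, 3L])
  txt <- c("solid limbdeform",
           as.vector(rbind(paste("facet normal", fmt(n)),
                           "outer loop",
                           paste("vertex", fmt(p1)),
                           paste("vertex", fmt(p2)),
                           paste("vertex", fmt(p3)),
                           "endloop", "endfacet")),
           "endsolid limbdeform")
  writeLines(txt, path)
  invisible(path)
}

# --- vibration frames --------------------------------------------------------

#' Vibration frame sequence
#'
#' @param times frame times in s, uniformly sampled.
#' @param vertical_position vertical marker position per frame, mm.
#' @param frame_rate sampling rate, Hz.
#' @return object of class `vibration_sequence`.
#' @export
vibration_sequence <- function(times, vertical_position, frame_rate) {
  times <- as.numeric(times); vertical_position <- as.numeric(vertical_position)
  if (length(times) != length(vertical_position) || length(times) < 2L)
    stopf("times and vertical_position must have equal length >= 2")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  structure(list(times = times, vertical_position = vertical_position,
                 frame_rate = frame_rate),
            class = "vibration_sequence")
}

#' Select the extreme frames of a vibration recording
#'
#' Returns the first-occurring global maximum and minimum of the vertical
#' position, the displacement between them, and the time interval. A
#' constant sequence yields zero displacement with a degenerate-cycle
#' warning.
#'
#' @param seq a [vibration_sequence()].
#' @return list `index_high`, `index_low` (1-based), `displacement` (mm),
#'   `interval` (s).
#' @export
select_extreme_frames <- function(seq) {
  if (!inherits(seq, "vibration_sequence"))
    stopf("`seq` must be a vibration_sequence")
  p <- seq$vertical_position
  hi <- which.max(p); lo <- which.min(p)
  disp <- p[hi] - p[lo]
  if (disp == 0) warnf("degenerate cycle: constant vertical position")
  list(index_high = hi, index_low = lo, displacement = disp,
       interval = abs(seq$times[hi] - seq$times[lo]))
}
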