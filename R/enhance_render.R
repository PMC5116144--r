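#' Interpolation level to grid-densification factor
#'
#' Levels densify each axis by a fixed factor: none = 1, low = 2,
#' medium = 4, high = 8. The output node count per axis is
#' `(n - 1) * factor + 1`, so original nodes stay on the refined grid.
#'
#' @param level `"none"`, `"low"`, `"medium"` or `"high"`.
#' @return integer factor.
#' @export
interp_factor <- function(level = c("none", "low", "medium", "high")) {
  level <- match.arg(level)
  c(none = 1L, low = 2L, medium = 4L, high = 8L)[[level]]
}

refine_axis <- function(coords, factor) {
  n <- length(coords)
  if (n == 1L || factor == 1L) return(coords)
  seq(coords[1L], coords[n], length.out = (n - 1L) * factor + 1L)
}

#' Upsample a map by bilinear interpolation
#'
#' Creates new data points within the range of the original grid by bilinear
#' interpolation, increasing displayed image resolution without inventing
#' values outside the local data range (every interpolated value is a convex
#' combination of its four surrounding nodes). Original node values are
#' preserved exactly at their coordinates. Missing cells are treated as 0
#' (background) for interpolation.
#'
#' @param map an [elemental_map()].
#' @param level interpolation level (see [interp_factor()]).
#' @return an `elemental_map` on the refined grid.
#' @export
interpolate_map <- function(map, level = c("none", "low", "medium", "high")) {
  level <- match.arg(level)
  factor <- interp_factor(level)
  if (factor == 1L) return(map)
  z <- map$values
  z[is.na(z)] <- 0
  nx <- length(map$x_coords)
  ny <- length(map$y_coords)
  new_x <- refine_axis(map$x_coords, factor)
  new_y <- refine_axis(map$y_coords, factor)
  if (nx == 1L && ny == 1L) {
    warning("1x1 map cannot be interpolated; returning unchanged",
            call. = FALSE)
    return(map)
  }
  if (nx == 1L || ny == 1L) {
    warning("map is a single ", if (ny == 1L) "row" else "column",
            "; interpolating along the single valid axis only", call. = FALSE)
    if (ny == 1L) {
      vals <- matrix(stats::approx(map$x_coords, z[1L, ], xout = new_x)$y,
                     nrow = 1L)
      return(elemental_map(vals, new_x, map$y_coords, map$isotope,
                           map$normalized, map$standard))
    }
    vals <- matrix(stats::approx(map$y_coords, z[, 1L], xout = new_y)$y,
                   ncol = 1L)
    return(elemental_map(vals, map$x_coords, new_y, map$isotope,
                         map$normalized, map$standard))
  }
  grid <- pracma::meshgrid(new_x, new_y)
  vals <- pracma::interp2(map$x_coords, map$y_coords, z,
                          grid$X, grid$Y, method = "linear")
  vals <- matrix(vals, nrow = length(new_y), ncol = length(new_x))
  # guard against ulp-level rounding: convexity bounds hold exactly, and the
  # original nodes (which lie on the refined grid by construction) keep
  # their exact values and coordinates
  vals <- pmin(pmax(vals, min(z)), max(z))
  xi <- (seq_len(nx) - 1L) * factor + 1L
  yi <- (seq_len(ny) - 1L) * factor + 1L
  vals[yi, xi] <- z
  new_x[xi] <- map$x_coords
  new_y[yi] <- map$y_coords
  elemental_map(vals, new_x, new_y, map$isotope, map$normalized,
                map$standard)
}

#' Colour-map specification
#'
#' @param palette a palette name accepted by [grDevices::hcl.colors()]
#'   (default `"viridis"`, a perceptually ordered multi-hue gradient).
#' @param range_mode `"data"` (span the displayed map's own min/max) or
#'   `"custom"` (fixed `v_min`/`v_max`; values outside are clipped to the
#'   end colours — useful to make maps of different elements directly
#'   comparable).
#' @param v_min,v_max range bounds when `range_mode = "custom"`;
#'   `v_min < v_max` required.
#' @param n_colors number of gradient steps.
#' @return an object of class `colormap_spec`.
#' @export
colormap_spec <- function(palette = "viridis",
                          range_mode = c("data", "custom"),
                          v_min = NULL, v_max = NULL, n_colors = 256L) {
  range_mode <- match.arg(range_mode)
  if (range_mode == "custom") {
    if (is.null(v_min) || is.null(v_max) || !(v_min < v_max)) {
      stop("custom range requires v_min < v_max", call. = FALSE)
    }
  }
  structure(list(palette = palette, range_mode = range_mode,
                 v_min = v_min, v_max = v_max,
                 n_colors = as.integer(n_colors)),
            class = "colormap_spec")
}

# Resolve the value range a map is displayed over. A constant map in data
# mode gets the degenerate-range fix [v, v + 1] so the affine mapping is
# defined (the constant then renders as the palette minimum).
resolve_range <- function(values, spec) {
  if (spec$range_mode == "custom") return(c(spec$v_min, spec$v_max))
  finite <- values[is.finite(values)]
  if (length(finite) == 0L) return(c(0, 1))
  r <- range(finite)
  if (r[1L] == r[2L]) r[2L] <- r[1L] + 1
  r
}

#' Map values to colours
#'
#' Affine, order-preserving mapping of map values onto a colour gradient
#' over the resolved range. Values outside a custom range are clipped to the
#' end colours; missing cells take the minimum colour.
#'
#' @param map an [elemental_map()] or numeric matrix.
#' @param spec a [colormap_spec()].
#' @return an `nrow x ncol x 3` array of RGB values in `[0, 1]`.
#' @export
apply_colormap <- function(map, spec = colormap_spec()) {
  values <- if (inherits(map, "elemental_map")) map$values else as.matrix(map)
  if (length(values) == 0L) stop("map is empty", call. = FALSE)
  rng <- resolve_range(values, spec)
  pal <- grDevices::hcl.colors(spec$n_colors, spec$palette)
  idx <- (values - rng[1L]) / (rng[2L] - rng[1L])
  idx[!is.finite(idx)] <- 0
  idx <- pmin(pmax(idx, 0), 1)
  cols <- grDevices::col2rgb(pal[1L + round(idx * (spec$n_colors - 1L))]) / 255
  out <- array(0, dim = c(nrow(values), ncol(values), 3L))
  out[, , 1L] <- cols[1L, ]
  out[, , 2L] <- cols[2L, ]
  out[, , 3L] <- cols[3L, ]
  out
}

#' Rendering specification
#'
#' All options controlling image export: colour map, interpolation level,
#' 2D heat map versus 3D intensity surface (the surface height shows signal
#' intensity only, not sample topology), pixel size, rotation in 90-degree
#' steps, decoration toggles and 3D camera angles.
#'
#' @param colormap a [colormap_spec()].
#' @param interpolation interpolation level (see [interp_factor()]).
#' @param mode `"2d"` or `"3d"`.
#' @param width_px,height_px output size in pixels (>= 16).
#' @param rotation 0, 90, 180 or 270 degrees.
#' @param show_axes,show_colorbar,show_ticks decoration toggles.
#' @param camera_azimuth,camera_elevation 3D viewing angles in degrees.
#' @return an object of class `render_spec`.
#' @export
render_spec <- function(colormap = colormap_spec(),
                        interpolation = "none",
                        mode = c("2d", "3d"),
                        width_px = 800L, height_px = 600L,
                        rotation = 0L,
                        show_axes = TRUE, show_colorbar = TRUE,
                        show_ticks = TRUE,
                        camera_azimuth = 45, camera_elevation = 30) {
  mode <- match.arg(mode)
  interpolation <- match.arg(interpolation,
                             c("none", "low", "medium", "high"))
  if (width_px < 16L || height_px < 16L) {
    stop("image size must be at least 16 x 16 pixels", call. = FALSE)
  }
  if (!rotation %in% c(0L, 90L, 180L, 270L)) {
    stop("rotation must be one of 0, 90, 180, 270 degrees", call. = FALSE)
  }
  structure(list(colormap = colormap, interpolation = interpolation,
                 mode = mode, width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 rotation = as.integer(rotation),
                 show_axes = isTRUE(show_axes),
                 show_colorbar = isTRUE(show_colorbar),
                 show_ticks = isTRUE(show_ticks),
                 camera_azimuth = camera_azimuth,
                 camera_elevation = camera_elevation),
            class = "render_spec")
}

# Rotate a map counter-clockwise in 90-degree steps, axes following.
rotate_map <- function(map, rotation) {
  k <- (rotation %/% 90L) %% 4L
  if (k == 0L) return(map)
  v <- map$values; x <- map$x_coords; y <- map$y_coords
  for (i in seq_len(k)) {
    v <- t(v)[rev(seq_len(ncol(v))), , drop = FALSE]  # ccw quarter turn
    tmp <- x; x <- y; y <- tmp
  }
  elemental_map(v, x, y, map$isotope, map$normalized, map$standard)
}

#' Render a map to a PNG image
#'
#' Applies the spec's interpolation and rotation, then draws either a 2D
#' colour-mapped heat map or a 3D intensity surface and writes it as PNG at
#' the requested pixel size. Axes are labelled in micrometres. When all
#' decorations are disabled in 2D mode, the raster fills the image exactly
#' (each matrix cell maps to an equal pixel block).
#'
#' @param map an [elemental_map()].
#' @param spec a [render_spec()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_image <- function(map, spec = render_spec(), path) {
  stopifnot(inherits(map, "elemental_map"), inherits(spec, "render_spec"))
  map <- interpolate_map(map, spec$interpolation)
  map <- rotate_map(map, spec$rotation)
  bare <- !spec$show_axes && !spec$show_colorbar && !spec$show_ticks
  if (spec$mode == "2d" && bare) {
    # decoration-free export: write the scaled raster directly
    rgb <- apply_colormap(map, spec$colormap)
    png::writePNG(scale_raster(rgb, spec$width_px, spec$height_px), path)
    return(invisible(path))
  }
  grDevices::png(path, width = spec$width_px, height = spec$height_px,
                 type = "cairo")
  on.exit(grDevices::dev.off())
  rng <- resolve_range(map$values, spec$colormap)
  pal <- grDevices::hcl.colors(spec$colormap$n_colors, spec$colormap$palette)
  # panels placed as device fractions so small pixel sizes cannot overflow
  left <- if (spec$show_axes) 0.14 else 0.02
  bottom <- if (spec$show_axes) 0.14 else 0.02
  right <- if (spec$show_colorbar) 0.80 else 0.97
  graphics::par(plt = c(left, right, bottom, 0.97), xpd = FALSE)
  z <- map$values
  z[is.na(z)] <- rng[1L]
  z <- pmin(pmax(z, rng[1L]), rng[2L])
  if (spec$mode == "2d") {
    graphics::image(map$x_coords, map$y_coords, t(z),
                    zlim = rng, col = pal, useRaster = TRUE,
                    axes = FALSE, xlab = "", ylab = "", asp = NA)
    if (spec$show_axes) {
      graphics::title(xlab = "x (µm)", ylab = "y (µm)")
      graphics::axis(1L, lwd.ticks = if (spec$show_ticks) 1 else 0)
      graphics::axis(2L, lwd.ticks = if (spec$show_ticks) 1 else 0)
      graphics::box()
    }
  } else {
    zt <- t(z)  # persp wants z[x, y]
    nxz <- nrow(zt); nyz <- ncol(zt)
    facet <- (zt[-1L, -1L] + zt[-nxz, -1L] + zt[-1L, -nyz] +
              zt[-nxz, -nyz]) / 4
    fi <- (facet - rng[1L]) / (rng[2L] - rng[1L])
    fi <- pmin(pmax(fi, 0), 1)
    fcol <- pal[1L + round(fi * (spec$colormap$n_colors - 1L))]
    graphics::persp(map$x_coords, map$y_coords, zt, zlim = rng,
                    col = fcol, border = NA,
                    theta = spec$camera_azimuth, phi = spec$camera_elevation,
                    axes = spec$show_axes, box = spec$show_axes,
                    ticktype = if (spec$show_ticks) "detailed" else "simple",
                    xlab = "x (um)", ylab = "y (um)", zlab = "ratio",
                    expand = 0.6)
  }
  if (spec$show_colorbar) {
    graphics::par(new = TRUE, plt = c(0.85, 0.89, bottom, 0.97))
    breaks <- seq(rng[1L], rng[2L], length.out = spec$colormap$n_colors + 1L)
    graphics::image(1L, breaks[-1L],
                    matrix(seq_len(spec$colormap$n_colors), nrow = 1L),
                    col = pal, axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4L)
    graphics::box()
  }
  invisible(path)
}

# Nearest-neighbour scaling of an RGB array to the requested pixel size,
# flipped so row 1 (y = 0) sits at the image bottom.
scale_raster <- function(rgb, width_px, height_px) {
  nr <- dim(rgb)[1L]; nc <- dim(rgb)[2L]
  ri <- pmin(nr, 1L + floor(seq(0, nr, length.out = height_px + 1L)[-1L] - 1e-9))
  ci <- pmin(nc, 1L + floor(seq(0, nc, length.out = width_px + 1L)[-1L] - 1e-9))
  rgb[rev(ri), ci, , drop = FALSE]
}

#' Export every isotope of a dataset
#'
#' Writes one PNG image and/or one CSV matrix per isotope with a shared
#' render specification and CSV dialect. Files are named
#' `<canonical isotope>.png` / `<canonical isotope>.csv`.
#'
#' @param dataset an `elemental_dataset`.
#' @param out_dir output directory (created if needed).
#' @param spec a [render_spec()] used for all images.
#' @param dialect a [csv_dialect()] used for all CSVs.
#' @param formats subset of `c("png", "csv")`; must be nonempty.
#' @param overwrite overwrite existing files? Collisions error otherwise.
#' @return character vector of written paths, invisibly.
#' @export
export_maps <- function(dataset, out_dir, spec = render_spec(),
                        dialect = csv_dialect("excel"),
                        formats = c("png", "csv"), overwrite = FALSE) {
  stopifnot(inherits(dataset, "elemental_dataset"))
  formats <- intersect(formats, c("png", "csv"))
  if (length(formats) == 0L) {
    stop("no export format selected; choose 'png', 'csv' or both",
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  targets <- unlist(lapply(names(dataset$maps), function(iso) {
    file.path(out_dir, paste0(iso, ".", formats))
  }))
  existing <- targets[file.exists(targets)]
  if (length(existing) > 0L && !overwrite) {
    stop("output files already exist (use overwrite): ",
         paste(basename(existing), collapse = ", "), call. = FALSE)
  }
  written <- character(0)
  for (iso in names(dataset$maps)) {
    m <- dataset$maps[[iso]]
    if ("png" %in% formats) {
      p <- file.path(out_dir, paste0(iso, ".png"))
      render_image(m, spec, p)
      written <- c(written, p)
    }
    if ("csv" %in% formats) {
      p <- file.path(out_dir, paste0(iso, ".csv"))
      write_map_csv(m, p, dialect)
      written <- c(written, p)
    }
  }
  invisible(written)
}
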