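#' Parametric description of the double-layer device cross-section
#'
#' Builds a validated specification of the chip geometry in the x-z plane
#' (x horizontal, normal to the gel channel; z vertical from the device
#' floor; origin at the center of the gel channel). The device is a PDMS
#' slab on a glass coverslip: a central gel channel flanked by two media
#' channels sits on the floor, two gas channels run above them at height
#' `H_g`, and a gas-impermeable polycarbonate film spans the device at
#' height `H_f` to shield the channels from atmospheric oxygen.
#'
#' All lengths are in meters. Defaults reproduce the published design:
#' 35 mm device width, 4 mm height, 1300 um gel channel, 500 um media
#' channels, 1000 um gas channels separated by 1300 um (so they do not
#' overlap the gel channel), all channels 150 um high, gas channels at
#' `H_g` = 0.5 mm, film at `H_f` = 1 mm, film thickness 0.5 mm.
#'
#' @param device_width Lateral extent of the modeled slab (m).
#' @param device_height Total slab thickness H (m).
#' @param gel_width Width of the central gel channel (m).
#' @param media_width Width of each flanking media channel (m).
#' @param gas_width Width of each gas channel (m).
#' @param gas_separation Inner-edge to inner-edge distance between the two
#'   gas channels (m).
#' @param channel_height Height of all channels (m).
#' @param H_g Height of the bottom of the gas channels above the floor (m).
#' @param H_f Height of the bottom of the PC film above the floor (m).
#' @param film_thickness Thickness of the PC film (m).
#' @return An object of class `device_spec`.
#' @examples
#' spec <- device_spec()
#' spec
#' @export
device_spec <- function(device_width = 35e-3,
                        device_height = 4e-3,
                        gel_width = 1300e-6,
                        media_width = 500e-6,
                        gas_width = 1000e-6,
                        gas_separation = 1300e-6,
                        channel_height = 150e-6,
                        H_g = 0.5e-3,
                        H_f = 1e-3,
                        film_thickness = 0.5e-3) {
  spec <- structure(
    list(
      device_width = device_width, device_height = device_height,
      gel_width = gel_width, media_width = media_width,
      gas_width = gas_width, gas_separation = gas_separation,
      channel_height = channel_height,
      H_g = H_g, H_f = H_f, film_thickness = film_thickness
    ),
    class = "device_spec"
  )
  validate_device_spec(spec)
  spec
}

validate_device_spec <- function(spec) {
  lens <- unlist(spec)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all device_spec lengths must be finite and > 0")
  }
  if (spec$H_f < spec$H_g + spec$channel_height) {
    stop("geometry conflict: PC film (H_f = ", spec$H_f * 1e3,
         " mm) intersects the gas channels (top at ",
         (spec$H_g + spec$channel_height) * 1e3,
         " mm); requires H_f >= H_g + channel_height")
  }
  if (spec$H_f + spec$film_thickness > spec$device_height) {
    stop("geometry conflict: PC film extends above the device ",
         "(H_f + film_thickness > device_height)")
  }
  if (spec$H_g < spec$channel_height) {
    stop("geometry conflict: gas channels (bottom at H_g = ", spec$H_g * 1e3,
         " mm) intersect the media/gel layer (top at ",
         spec$channel_height * 1e3, " mm)")
  }
  aq_half <- spec$gel_width / 2 + spec$media_width
  if (spec$gas_separation / 2 + spec$gas_width > spec$device_width / 2 ||
      aq_half > spec$device_width / 2) {
    stop("geometry conflict: channels extend beyond the device width")
  }
  if (spec$gas_separation < spec$gel_width) {
    warning("gas channels overlap the gel channel footprint ",
            "(gas_separation < gel_width); the design rule keeps them apart ",
            "for unobstructed imaging of the gel")
  }
  invisible(spec)
}

#' @export
print.device_spec <- function(x, ...) {
  mm <- function(v) formatC(v * 1e3, format = "fg")
  cat("Double-layer microfluidic device cross-section (x-z plane)\n")
  cat(sprintf("  slab: %s x %s mm (width x height)\n",
              mm(x$device_width), mm(x$device_height)))
  cat(sprintf("  gel %s mm | media 2 x %s mm | channels %s mm high\n",
              mm(x$gel_width), mm(x$media_width), mm(x$channel_height)))
  cat(sprintf("  gas channels: 2 x %s mm wide, %s mm apart, bottom at H_g = %s mm\n",
              mm(x$gas_width), mm(x$gas_separation), mm(x$H_g)))
  cat(sprintf("  PC film: %s mm thick at H_f = %s mm\n",
              mm(x$film_thickness), mm(x$H_f)))
  invisible(x)
}

subdivide <- function(breaks, h, min_cells = 1L) {
  breaks <- sort(unique(breaks))
  edges <- breaks[1]
  for (i in seq_len(length(breaks) - 1L)) {
    span <- breaks[i + 1L] - breaks[i]
    n <- max(min_cells, ceiling(span / h - 1e-9))
    edges <- c(edges, breaks[i] + span * seq_len(n) / n)
  }
  edges
}

#' Discretize the device cross-section into a material-labeled grid
#'
#' Builds a rectilinear grid over the x-z cross-section whose edges are
#' aligned with every material interface (channel walls, film faces), so no
#' grid cell straddles two materials. Each interface-to-interface span is
#' subdivided uniformly at (or finer than) the requested resolution, and the
#' PC film is always resolved by at least two cell layers. Cells are
#' classified by their centers: the aqueous layer (gel flanked by media,
#' treated as one contiguous water-like region since the PDMS posts between
#' them are discrete in y and the modeled slice passes between posts)
#' occupies `z` in `[0, channel_height]`; the gas channels occupy
#' `[H_g, H_g + channel_height]` at `|x|` in
#' `[gas_separation/2, gas_separation/2 + gas_width]`; the film spans the
#' full lateral extent at `[H_f, H_f + film_thickness]`; everything else is
#' PDMS. The `z = 0` floor is the glass coverslip, modeled as a zero-flux
#' boundary.
#'
#' @param spec A [device_spec()].
#' @param resolution Length-2 numeric, target cell size `(dx, dz)` in
#'   meters. Default 25 um in both directions, which resolves the 150 um
#'   channels with 6 cells and the 500 um film with 20 layers.
#' @param materials Property table, by default [default_materials()].
#' @return An object of class `material_grid`: list with `x_edges`,
#'   `z_edges`, cell centers `xc`, `zc`, dimensions `nx`, `nz`, an
#'   `nz x nx` character matrix `material`, matching matrices `D`, `S`, `k`,
#'   and the originating `spec`.
#' @examples
#' g <- build_cross_section(device_spec(), resolution = c(100e-6, 100e-6))
#' table(g$material)
#' @export
build_cross_section <- function(spec, resolution = c(25e-6, 25e-6),
                                materials = default_materials()) {
  validate_device_spec(spec)
  if (length(resolution) == 1L) resolution <- rep(resolution, 2L)
  stopifnot(length(resolution) == 2L, all(resolution > 0))
  dx <- resolution[1]; dz <- resolution[2]

  aq_half <- spec$gel_width / 2 + spec$media_width
  gas_in <- spec$gas_separation / 2
  gas_out <- gas_in + spec$gas_width
  half_w <- spec$device_width / 2

  x_breaks <- c(-half_w, -gas_out, -gas_in, -aq_half, -spec$gel_width / 2,
                spec$gel_width / 2, aq_half, gas_in, gas_out, half_w)
  z_breaks <- c(0, spec$channel_height, spec$H_g,
                spec$H_g + spec$channel_height, spec$H_f,
                spec$H_f + spec$film_thickness, spec$device_height)

  x_edges <- subdivide(x_breaks, dx)
  # film resolved by >= 2 layers regardless of resolution
  z_edges <- sort(unique(c(
    subdivide(z_breaks, dz),
    subdivide(c(spec$H_f, spec$H_f + spec$film_thickness),
              spec$film_thickness / 2)
  )))

  xc <- (x_edges[-1] + x_edges[-length(x_edges)]) / 2
  zc <- (z_edges[-1] + z_edges[-length(z_edges)]) / 2
  nx <- length(xc); nz <- length(zc)

  X <- matrix(xc, nz, nx, byrow = TRUE)
  Z <- matrix(zc, nz, nx)

  mat <- matrix("PDMS", nz, nx)
  mat[Z < spec$channel_height & abs(X) < aq_half] <- "medium"
  mat[Z < spec$channel_height & abs(X) < spec$gel_width / 2] <- "gel"
  mat[Z > spec$H_g & Z < spec$H_g + spec$channel_height &
        abs(X) > gas_in & abs(X) < gas_out] <- "gas"
  mat[Z > spec$H_f & Z < spec$H_f + spec$film_thickness] <- "PC_film"

  props <- materials[match(mat, materials$name), ]
  D <- matrix(props$D, nz, nx)
  S <- matrix(props$S, nz, nx)

  structure(
    list(x_edges = x_edges, z_edges = z_edges, xc = xc, zc = zc,
         nx = nx, nz = nz, material = mat, D = D, S = S, k = D * S,
         spec = spec),
    class = "material_grid"
  )
}

#' Assemble a material grid from explicit edges and labels
#'
#' Low-level constructor for custom domains (for example one-dimensional
#' composite-slab columns used to check the solver against the
#' series-resistance closed form).
#'
#' @param x_edges,z_edges Strictly increasing coordinate vectors (m).
#' @param material `nz x nx` character matrix of material names.
#' @param materials Property table, by default [default_materials()].
#' @return A `material_grid`.
#' @export
material_grid <- function(x_edges, z_edges, material,
                          materials = default_materials()) {
  stopifnot(all(diff(x_edges) > 0), all(diff(z_edges) > 0))
  nx <- length(x_edges) - 1L
  nz <- length(z_edges) - 1L
  material <- matrix(as.character(material), nz, nx)
  if (!all(material %in% materials$name)) {
    stop("unknown material label in grid")
  }
  props <- materials[match(material, materials$name), ]
  D <- matrix(props$D, nz, nx)
  S <- matrix(props$S, nz, nx)
  structure(
    list(x_edges = x_edges, z_edges = z_edges,
         xc = (x_edges[-1] + x_edges[-nx - 1L]) / 2,
         zc = (z_edges[-1] + z_edges[-nz - 1L]) / 2,
         nx = nx, nz = nz, material = material, D = D, S = S, k = D * S,
         spec = NULL),
    class = "material_grid"
  )
}

#' @export
print.material_grid <- function(x, ...) {
  cat(sprintf("material_grid: %d x %d cells (%d x-edges, %d z-edges)\n",
              x$nx, x$nz, length(x$x_edges), length(x$z_edges)))
  print(table(x$material))
  invisible(x)
}

#' Area occupied by each material in a grid
#'
#' Cross-sectional area per material (m^2, per unit depth in y). Used to
#' check that discretized region areas match the analytic areas implied by
#' the device spec.
#'
#' @param grid A `material_grid`.
#' @return Named numeric vector of areas.
#' @export
region_areas <- function(grid) {
  dxv <- diff(grid$x_edges)
  dzv <- diff(grid$z_edges)
  area <- outer(dzv, dxv)
  tapply(as.vector(area), as.vector(grid$material), sum)
}

#' Generate a family of device specs sweeping the gas-channel height
#'
#' One spec per `H_g` value with the film tied to the gas channels by
#' `H_f = 2 H_g` (the coupling used in the published design sweep); all
#' other fields keep their defaults.
#'
#' @param H_g_values Gas-channel heights (m). The studied range is
#'   0.25-1.5 mm; values outside it are rejected unless `override = TRUE`.
#' @param override Allow values outside the studied range.
#' @param ... Passed to [device_spec()] to change other fields.
#' @return List of `device_spec` objects.
#' @examples
#' sweep_geometries(c(0.25, 0.5, 1.0, 1.5) * 1e-3)
#' @export
sweep_geometries <- function(H_g_values, override = FALSE, ...) {
  if (length(H_g_values) == 0L) return(list())
  if (!override && any(H_g_values < 0.25e-3 - 1e-12 | H_g_values > 1.5e-3 + 1e-12)) {
    stop("H_g values outside the studied range [0.25, 1.5] mm; ",
         "set override = TRUE to sweep them anyway")
  }
  lapply(H_g_values, function(hg) device_spec(H_g = hg, H_f = 2 * hg, ...))
}

#' Write / read a device spec as a YAML config
#'
#' Lengths are serialized in millimeters under a `device:` block so configs
#' are human-editable.
#'
#' @param spec A `device_spec`.
#' @param path File path.
#' @return `read_device_config` returns a `device_spec`;
#'   `write_device_config` returns `path` invisibly.
#' @export
write_device_config <- function(spec, path) {
  vals <- lapply(unclass(spec), function(v) v * 1e3)
  yaml::write_yaml(list(device = vals, units = "mm"), path)
  invisible(path)
}

#' @rdname write_device_config
#' @export
read_device_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$device)) stop("config has no 'device' block")
  scale <- switch(if (is.null(cfg$units)) "mm" else cfg$units,
                  mm = 1e-3, um = 1e-6, m = 1,
                  stop("unknown units: ", cfg$units))
  do.call(device_spec, lapply(cfg$device, function(v) v * scale))
}

#' Export the material map as a delimited table
#'
#' Long-format table (x, z, material) for inspection or plotting.
#'
#' @param grid A `material_grid`.
#' @param path Optional file path; if given, written as TSV.
#' @return Data frame (invisibly if written to file).
#' @export
material_table <- function(grid, path = NULL) {
  df <- data.frame(
    x = rep(grid$xc, each = grid$nz),
    z = rep(grid$zc, grid$nx),
    material = as.vector(grid$material)
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
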