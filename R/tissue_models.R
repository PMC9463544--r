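#' Layered tissue model
#'
#' An ordered stack of laterally infinite slabs below the probe. The surface
#' plane is z = 0 with the external medium (air) above; depth increases into
#' the tissue. Layer intervals are half-open `[top, bottom)`, so a position
#' exactly on an interface belongs to the lower layer.
#'
#' @param layers List of layers from [layer()], surface downward. Only the
#'   last layer may be infinite.
#' @return An `ewdrs_layered_model`.
#' @export
layered_model <- function(layers) {
  stopifnot(length(layers) >= 1L, all(vapply(layers, inherits, TRUE, "ewdrs_layer")))
  th <- vapply(layers, function(l) l$thickness_mm, 0)
  if (any(!is.finite(th[-length(th)])))
    stop_ewdrs("only the terminal layer may be infinite", "ewdrs_parameter")
  structure(list(layers = layers,
                 interfaces_mm = cumsum(th)),
            class = "ewdrs_layered_model")
}

#' @rdname layered_model
#' @param material An [optical_properties()] record.
#' @param thickness_mm Layer thickness (mm, `> 0`; `Inf` for a terminal
#'   semi-infinite layer).
#' @export
layer <- function(material, thickness_mm = Inf) {
  stopifnot(is_optical_properties(material))
  if (!(thickness_mm > 0))
    stop_ewdrs("layer thickness must be positive", "ewdrs_parameter")
  structure(list(material = material, thickness_mm = thickness_mm),
            class = "ewdrs_layer")
}

#' @export
print.ewdrs_layered_model <- function(x, ...) {
  cat(sprintf("<layered model> %d layer(s):\n", length(x$layers)))
  for (l in x$layers)
    cat(sprintf("  %s, %s mm\n", l$material$name,
                if (is.finite(l$thickness_mm)) format(l$thickness_mm) else "semi-infinite"))
  invisible(x)
}

#' Semi-infinite homogeneous model
#'
#' @param material An [optical_properties()] record.
#' @return A one-layer [layered_model()] of infinite thickness.
#' @export
build_homogeneous <- function(material) layered_model(list(layer(material, Inf)))

#' Two-layer model (finite cover over a thick base)
#'
#' Mirrors the phantom study geometry: a nerve-mimicking cover of 1 to 3 mm
#' over a 40-mm muscle-mimicking base, below which photons exit and are
#' booked as transmitted.
#'
#' @param top_material,bottom_material [optical_properties()] records.
#' @param top_thickness_mm Cover thickness (mm, `> 0`).
#' @param bottom_thickness_mm Base thickness (mm, default 40).
#' @return A two-layer [layered_model()].
#' @export
build_two_layer <- function(top_material, top_thickness_mm,
                            bottom_material, bottom_thickness_mm = 40) {
  if (!(top_thickness_mm > 0) || !(bottom_thickness_mm > 0))
    stop_ewdrs("layer thicknesses must be positive", "ewdrs_parameter")
  layered_model(list(layer(top_material, top_thickness_mm),
                     layer(bottom_material, bottom_thickness_mm)))
}

#' Voxelized tissue model
#'
#' A 3-D integer material-index grid with uniform cubic voxels. The grid is
#' centered laterally on the probe axis (x, y in
#' `[-nx*h/2, nx*h/2)`) with z from the surface (0) downward. Lateral
#' lookups beyond the grid clamp to the edge material; the bottom face
#' transmits.
#'
#' @param grid 3-D integer array of 1-based material indices (dims nx, ny, nz).
#' @param voxel_mm Voxel edge length (mm, `> 0`).
#' @param materials List of [optical_properties()], indexed by the grid
#'   values. All must share one refractive index (internal interfaces carry
#'   no Fresnel step).
#' @return An `ewdrs_voxel_model`.
#' @export
voxel_model <- function(grid, voxel_mm, materials) {
  stopifnot(is.array(grid), length(dim(grid)) == 3L, voxel_mm > 0,
            all(vapply(materials, is_optical_properties, TRUE)))
  idx <- range(grid)
  if (idx[1L] < 1L || idx[2L] > length(materials))
    stop_ewdrs("every voxel index needs a material table entry", "ewdrs_parameter")
  ns <- vapply(materials, function(m) m$n, 0)
  if (diff(range(ns)) > 0)
    stop_ewdrs("voxel-model materials must share one refractive index",
               "ewdrs_parameter")
  structure(list(grid = grid, voxel_mm = voxel_mm, materials = materials),
            class = "ewdrs_voxel_model")
}

#' @export
print.ewdrs_voxel_model <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voxel model> %dx%dx%d voxels of %g mm (%g x %g x %g mm), %d material(s)\n",
              d[1L], d[2L], d[3L], x$voxel_mm,
              d[1L] * x$voxel_mm, d[2L] * x$voxel_mm, d[3L] * x$voxel_mm,
              length(x$materials)))
  invisible(x)
}

#' Default nerve-plexus geometry
#'
#' Three parallel trunk cylinders (2-mm diameter, 3 mm apart, long axis along
#' y) joined by two 1-mm crossing branches along x, all confined to a 2-mm
#' thick slab. The published scenario states only the slab thickness and the
#' cover depths, so these dimensions are explicitly non-canonical defaults
#' and fully configurable.
#'
#' @param n_trunks,trunk_diameter_mm,trunk_spacing_mm,branch_diameter_mm,thickness_mm
#'   Geometry parameters (mm).
#' @return A `plexus_spec` list.
#' @export
plexus_spec <- function(n_trunks = 3, trunk_diameter_mm = 2,
                        trunk_spacing_mm = 3, branch_diameter_mm = 1,
                        thickness_mm = 2) {
  stopifnot(n_trunks >= 1, trunk_diameter_mm > 0, branch_diameter_mm > 0,
            thickness_mm >= trunk_diameter_mm)
  list(n_trunks = n_trunks, trunk_diameter_mm = trunk_diameter_mm,
       trunk_spacing_mm = trunk_spacing_mm,
       branch_diameter_mm = branch_diameter_mm, thickness_mm = thickness_mm)
}

# Geometric membership predicate for the plexus network. Positions in mm,
# cover = depth of the slab top. Vectorized over x, y, z.
plexus_contains <- function(spec, x, y, z, cover_thickness_mm) {
  z0 <- cover_thickness_mm + spec$thickness_mm / 2  # slab mid-depth
  rt <- spec$trunk_diameter_mm / 2
  rb <- spec$branch_diameter_mm / 2
  offs <- (seq_len(spec$n_trunks) - (spec$n_trunks + 1) / 2) * spec$trunk_spacing_mm
  inside <- rep(FALSE, length(x))
  for (xc in offs)                       # trunks along y
    inside <- inside | ((x - xc)^2 + (z - z0)^2 <= rt^2)
  for (yc in c(-1, 1) * spec$trunk_spacing_mm)  # two crossing branches along x
    inside <- inside | ((y - yc)^2 + (z - z0)^2 <= rb^2)
  inside & z >= cover_thickness_mm & z < cover_thickness_mm + spec$thickness_mm
}

#' Voxelized nerve-plexus-under-muscle model
#'
#' A 2-mm thick network of nerve cylinders sits under a muscle cover of the
#' given thickness; everything else (laterally and below) is muscle.
#'
#' @param cover_thickness_mm Muscle cover above the plexus (mm, `>= 0`;
#'   the published scenario uses 0.2, 0.5, 1 and 2).
#' @param nerve_material,muscle_material [optical_properties()] records.
#' @param spec Plexus geometry from [plexus_spec()].
#' @param voxel_mm Voxel edge (default 0.1 mm, resolving the 0.2-mm thinnest
#'   cover).
#' @param lateral_mm,depth_mm Grid extent (defaults 20 x 20 mm laterally,
#'   12 mm deep).
#' @return An [voxel_model()] where index 1 = muscle, 2 = nerve.
#' @export
build_plexus <- function(cover_thickness_mm, nerve_material, muscle_material,
                         spec = plexus_spec(), voxel_mm = 0.1,
                         lateral_mm = 20, depth_mm = 12) {
  stopifnot(cover_thickness_mm >= 0)
  thinnest <- min(spec$branch_diameter_mm,
                  if (cover_thickness_mm > 0) cover_thickness_mm else Inf)
  if (voxel_mm > thinnest / 2)
    stop_ewdrs("voxel size must be at most half the thinnest feature",
               "ewdrs_resolution")
  nx <- ny <- as.integer(round(lateral_mm / voxel_mm))
  nz <- as.integer(round(depth_mm / voxel_mm))
  xs <- (seq_len(nx) - 0.5) * voxel_mm - lateral_mm / 2
  zs <- (seq_len(nz) - 0.5) * voxel_mm
  grid <- array(1L, dim = c(nx, ny, nz))
  # only the slab of z-planes containing the plexus needs the predicate
  zi <- which(zs >= cover_thickness_mm - voxel_mm &
              zs <= cover_thickness_mm + spec$thickness_mm + voxel_mm)
  xy <- expand.grid(x = xs, y = xs)
  for (k in zi) {
    nerve <- plexus_contains(spec, xy$x, xy$y, zs[k], cover_thickness_mm)
    grid[, , k][nerve] <- 2L
  }
  voxel_model(grid, voxel_mm, list(muscle_material, nerve_material))
}

#' Voxelize a layered model
#'
#' Renders a [layered_model()] onto a uniform voxel grid (material at each
#' voxel center), for cross-representation checks and heterogeneous editing.
#'
#' @param model A layered model.
#' @param voxel_mm Voxel edge (mm).
#' @param lateral_mm,depth_mm Grid extent (mm).
#' @return An [voxel_model()].
#' @export
voxelize <- function(model, voxel_mm, lateral_mm = 20, depth_mm = 12) {
  stopifnot(inherits(model, "ewdrs_layered_model"))
  nx <- ny <- as.integer(round(lateral_mm / voxel_mm))
  nz <- as.integer(round(depth_mm / voxel_mm))
  zs <- (seq_len(nz) - 0.5) * voxel_mm
  iface <- model$interfaces_mm
  lay <- findInterval(zs, c(0, iface), left.open = FALSE)  # half-open [top, bottom)
  lay[lay > length(model$layers)] <- length(model$layers)
  grid <- array(rep(as.integer(lay), each = nx * ny), dim = c(nx, ny, nz))
  voxel_model(grid, voxel_mm, lapply(model$layers, function(l) l$material))
}

#' External-medium sentinel
#'
#' Returned by [material_at()] for positions above the tissue surface.
#' @return An `ewdrs_external_medium` sentinel.
#' @export
external_medium <- function() structure(list(n = 1.0), class = "ewdrs_external_medium")

#' Look up the material at a position
#'
#' Layered models use half-open depth intervals `[top, bottom)`; voxel
#' models use floor indexing with lateral clamping to the edge material.
#' Positions above the surface return the [external_medium()] sentinel.
#'
#' @param model A layered or voxel model.
#' @param position Numeric `c(x, y, z)` in mm (z is depth; only z matters
#'   for layered models).
#' @return An [optical_properties()] record or the external-medium sentinel.
#' @export
material_at <- function(model, position) {
  stopifnot(is.numeric(position), length(position) == 3L, all(is.finite(position)))
  z <- position[3L]
  if (z < 0) return(external_medium())
  if (inherits(model, "ewdrs_layered_model")) {
    i <- findInterval(z, c(0, model$interfaces_mm), left.open = FALSE)
    if (i > length(model$layers)) return(external_medium())  # below finite stack
    return(model$layers[[i]]$material)
  }
  if (inherits(model, "ewdrs_voxel_model")) {
    d <- dim(model$grid)
    h <- model$voxel_mm
    ix <- min(max(floor((position[1L] + d[1L] * h / 2) / h) + 1, 1), d[1L])
    iy <- min(max(floor((position[2L] + d[2L] * h / 2) / h) + 1, 1), d[2L])
    iz <- floor(z / h) + 1
    if (iz > d[3L]) return(external_medium())
    return(model$materials[[model$grid[ix, iy, iz]]])
  }
  stop_ewdrs("not a tissue model", "ewdrs_parameter")
}
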