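# Voxelized ex vivo vertebral-body phantom and applicator/probe placement.
#
# Coordinate convention: x = latero-lateral (shaft axis), +y = ventral
# (radiation direction), z = craniocaudal. The world origin sits at the
# center of the applicator's active zone for the default pose; voxel i
# (1-based) is centered at origin_corner + (i - 1/2) * spacing.

#' Geometric specification of the vertebral-body phantom
#'
#' Bounding dimensions of a single vertebral body of a ~45 kg pig with its
#' cortical shell, dorsal spinal canal and cranial/caudal intervertebral
#' disks, embedded in a surrounding medium (air for the ex vivo bench
#' setup). The cross-sectional shape is an ellipse (width x depth) by
#' default, with a rectangular-box option.
#'
#' @param body_width Latero-lateral extent (m), default 0.025.
#' @param body_depth Dorsoventral extent (m), default 0.020.
#' @param body_height Craniocaudal extent (m), default 0.025.
#' @param cortical_thickness Cortical shell thickness (m), default 0.002.
#' @param canal_diameter Spinal canal diameter (m), default 0.010.
#' @param disk_thickness Thickness of each intervertebral disk (m),
#'   default 0.0075.
#' @param domain_size Encompassing domain (m), `c(x, y, z)`, default
#'   `c(0.08, 0.04, 0.04)`.
#' @param surround Tissue-class label of the surrounding medium, default
#'   `"air"`.
#' @param shape `"ellipse"` (default) or `"box"` cross-section.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_width = 0.025, body_depth = 0.020,
                         body_height = 0.025, cortical_thickness = 0.002,
                         canal_diameter = 0.010, disk_thickness = 0.0075,
                         domain_size = c(0.08, 0.04, 0.04),
                         surround = "air", shape = c("ellipse", "box")) {
  shape <- match.arg(shape)
  stopifnot(body_width > 0, body_depth > 0, body_height > 0,
            cortical_thickness >= 0, canal_diameter > 0, disk_thickness > 0,
            length(domain_size) == 3L, all(domain_size > 0))
  if (2 * cortical_thickness >= min(body_width, body_depth))
    stop("cortical shell too thick: 2*cortical_thickness must be < min(body_width, body_depth)")
  structure(list(body_width = body_width, body_depth = body_depth,
                 body_height = body_height,
                 cortical_thickness = cortical_thickness,
                 canal_diameter = canal_diameter,
                 disk_thickness = disk_thickness,
                 domain_size = domain_size, surround = surround,
                 shape = shape),
            class = "phantom_spec")
}

# Dorsoventral offset of the body center that puts the default shaft axis
# (back surface 2 mm ventral of the canal) through y = 0.
.body_center_y <- function(spec, back_to_canal_gap = 0.002,
                           shaft_radius = 1.055e-3) {
  spec$body_depth / 2 - back_to_canal_gap - shaft_radius
}

#' Pose of the directional applicator
#'
#' The shaft is a cylinder of radius `shaft_radius` starting at
#' `tip_position` and extending `shaft_length` along `axis_direction`
#' (from tip toward the proximal end). Microwave power is radiated
#' preferentially along `radiation_direction`, perpendicular to the shaft.
#' The active (radiating) zone is centered `active_center_offset` behind
#' the tip. A 14-gauge shaft has outer diameter 2.11 mm (standard gauge
#' table), i.e. radius 1.055 mm.
#'
#' @param tip_position Tip coordinates (m), default `c(-0.0105, 0, 0)`
#'   (abutting the inner far-lateral cortex of the default phantom).
#' @param axis_direction Unit vector along the shaft, default `c(1, 0, 0)`.
#' @param radiation_direction Unit vector of preferential radiation,
#'   perpendicular to the axis; default `c(0, 1, 0)` (ventral).
#' @param shaft_radius Shaft radius (m), default 1.055e-3.
#' @param shaft_length Modeled distal shaft length (m), default 0.06.
#' @param active_length Extent of the radiating zone along the shaft (m),
#'   default 0.010.
#' @param active_center_offset Distance from the tip back along the axis to
#'   the center of the active zone (m), default 0.0105 (centers the zone in
#'   the default body).
#' @param back_to_canal_gap Design gap between the back shaft surface and
#'   the canal boundary (m), default 0.002.
#' @return An object of class `applicator_pose`.
#' @export
applicator_pose <- function(tip_position = c(-0.0105, 0, 0),
                            axis_direction = c(1, 0, 0),
                            radiation_direction = c(0, 1, 0),
                            shaft_radius = 1.055e-3, shaft_length = 0.06,
                            active_length = 0.010,
                            active_center_offset = 0.0105,
                            back_to_canal_gap = 0.002) {
  axis_direction <- axis_direction / sqrt(sum(axis_direction^2))
  radiation_direction <- radiation_direction / sqrt(sum(radiation_direction^2))
  if (abs(sum(axis_direction * radiation_direction)) >= 1e-9)
    stop("radiation_direction must be perpendicular to axis_direction")
  stopifnot(shaft_radius > 0, shaft_length > 0, active_length > 0,
            back_to_canal_gap >= 0)
  structure(list(tip_position = tip_position,
                 axis_direction = axis_direction,
                 radiation_direction = radiation_direction,
                 shaft_radius = shaft_radius, shaft_length = shaft_length,
                 active_length = active_length,
                 active_center_offset = active_center_offset,
                 back_to_canal_gap = back_to_canal_gap),
            class = "applicator_pose")
}

#' Default applicator pose for a phantom specification
#'
#' Entry through the lateral cortical wall, shaft along the latero-lateral
#' axis with the tip abutting (not penetrating) the far cortex, radiating
#' ventrally, back surface `back_to_canal_gap` from the canal boundary.
#'
#' @param spec A [phantom_spec()].
#' @param ... Overrides passed to [applicator_pose()].
#' @return An [applicator_pose()].
#' @export
default_applicator_pose <- function(spec, ...) {
  tip_x <- -(spec$body_width / 2 - spec$cortical_thickness)
  applicator_pose(tip_position = c(tip_x, 0, 0),
                  active_center_offset = -tip_x, ...)
}

#' Center of the applicator's active zone
#'
#' @param pose An [applicator_pose()].
#' @return Numeric length-3 position (m).
#' @export
active_zone_center <- function(pose) {
  pose$tip_position + pose$active_center_offset * pose$axis_direction
}

#' Voxel-center coordinate vectors of a label grid
#'
#' @param grid A `label_grid`.
#' @return List of numeric vectors `x`, `y`, `z` (m).
#' @export
voxel_coords <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$dim[1]) - 0.5) * grid$spacing,
       y = grid$origin[2] + (seq_len(grid$dim[2]) - 0.5) * grid$spacing,
       z = grid$origin[3] + (seq_len(grid$dim[3]) - 0.5) * grid$spacing)
}

#' Build the voxelized phantom
#'
#' Rasterizes the phantom onto a uniform Cartesian grid: cancellous core,
#' cortical shell (including craniocaudal end shells), dorsal spinal-canal
#' cylinder labeled `"spinal cord"` running craniocaudally through the
#' body+disk extent, cartilage disks cranial and caudal, and surrounding
#' medium. Labeling is by voxel-center membership, hence deterministic.
#'
#' @param spec A [phantom_spec()].
#' @param spacing Uniform voxel edge length (m), default 1e-3. Must resolve
#'   the cortical shell: `spacing <= cortical_thickness / 2` (unless the
#'   shell is degenerate, `cortical_thickness = 0`).
#' @return An object of class `label_grid`: `origin` (lower domain corner,
#'   m), `spacing`, `dim` (voxel counts), `labels` (integer 3D array),
#'   `classes` (label for each integer code), `applicator_mask` (logical 3D
#'   array, all `FALSE` until [place_applicator()]).
#' @export
build_phantom <- function(spec, spacing = 1e-3) {
  stopifnot(inherits(spec, "phantom_spec"), spacing > 0)
  if (spec$cortical_thickness > 0 && spacing > spec$cortical_thickness / 2)
    stop(sprintf(paste0("spacing %g m too coarse to resolve the %g m cortical ",
                        "shell; need spacing <= cortical_thickness/2"),
                 spacing, spec$cortical_thickness))
  dm <- round(spec$domain_size / spacing)
  origin <- -spec$domain_size / 2
  xs <- origin[1] + (seq_len(dm[1]) - 0.5) * spacing
  ys <- origin[2] + (seq_len(dm[2]) - 0.5) * spacing
  zs <- origin[3] + (seq_len(dm[3]) - 0.5) * spacing

  yB <- .body_center_y(spec)
  a <- spec$body_width / 2
  b <- spec$body_depth / 2
  h2 <- spec$body_height / 2
  t <- spec$cortical_thickness
  rc <- spec$canal_diameter / 2
  y_canal <- yB - b - rc   # canal tangent to the dorsal body surface

  X <- array(rep(xs, times = dm[2] * dm[3]), dim = dm)
  Y <- array(rep(rep(ys, each = dm[1]), times = dm[3]), dim = dm)
  Z <- array(rep(zs, each = dm[1] * dm[2]), dim = dm)

  inside_xy <- if (spec$shape == "ellipse") {
    (X / a)^2 + ((Y - yB) / b)^2 <= 1
  } else {
    abs(X) <= a & abs(Y - yB) <= b
  }
  inner_xy <- if (t <= 0) inside_xy else if (spec$shape == "ellipse") {
    (X / (a - t))^2 + ((Y - yB) / (b - t))^2 <= 1
  } else {
    abs(X) <= a - t & abs(Y - yB) <= b - t
  }
  in_body_z <- abs(Z) <= h2
  in_core_z <- abs(Z) <= h2 - t
  cancellous <- inner_xy & (if (t <= 0) in_body_z else in_core_z)
  cortical <- inside_xy & in_body_z & !cancellous
  if (t <= 0) cortical[] <- FALSE
  disks <- inside_xy & abs(Z) > h2 & abs(Z) <= h2 + spec$disk_thickness
  canal <- (X^2 + (Y - y_canal)^2 <= rc^2) &
    abs(Z) <= h2 + spec$disk_thickness

  classes <- c(spec$surround, "cortical bone", "cancellous bone",
               "cartilage", "spinal cord", "applicator")
  labels <- array(1L, dim = dm)
  labels[disks] <- 4L
  labels[cortical] <- 2L
  labels[cancellous] <- 3L
  labels[canal & labels == 1L] <- 5L   # bone/cartilage take precedence

  structure(list(origin = origin, spacing = spacing, dim = dm,
                 labels = labels, classes = classes,
                 applicator_mask = array(FALSE, dim = dm),
                 body_center = c(0, yB, 0), canal_center_y = y_canal,
                 spec = spec),
            class = "label_grid")
}

#' Per-class voxel volumes of a label grid
#'
#' @param grid A `label_grid`.
#' @return Named numeric vector of volumes (m^3) per tissue class.
#' @export
class_volumes <- function(grid) {
  counts <- tabulate(grid$labels, nbins = length(grid$classes))
  stats::setNames(counts * grid$spacing^3, grid$classes)
}

#' Carve the applicator shaft into a phantom
#'
#' Voxels whose centers lie within `shaft_radius` of the shaft segment are
#' relabeled `"applicator"`; `applicator_mask` marks the shaft surface
#' voxels (those with at least one face neighbor outside the shaft), on
#' which the solver imposes the fixed cooled-shaft temperature. Placement
#' is rejected if the shaft would intersect the spinal canal.
#'
#' @param grid A `label_grid` from [build_phantom()].
#' @param pose An [applicator_pose()].
#' @return The modified `label_grid`, with the pose stored as `grid$pose`.
#' @export
place_applicator <- function(grid, pose) {
  stopifnot(inherits(grid, "label_grid"), inherits(pose, "applicator_pose"))
  co <- voxel_coords(grid)
  dm <- grid$dim
  X <- array(rep(co$x, times = dm[2] * dm[3]), dim = dm)
  Y <- array(rep(rep(co$y, each = dm[1]), times = dm[3]), dim = dm)
  Z <- array(rep(co$z, each = dm[1] * dm[2]), dim = dm)
  p0 <- pose$tip_position; ax <- pose$axis_direction
  sx <- (X - p0[1]) * ax[1] + (Y - p0[2]) * ax[2] + (Z - p0[3]) * ax[3]
  s <- pmin(pmax(sx, 0), pose$shaft_length)
  d2 <- (X - p0[1] - s * ax[1])^2 + (Y - p0[2] - s * ax[2])^2 +
    (Z - p0[3] - s * ax[3])^2
  in_shaft <- d2 <= pose$shaft_radius^2 & sx >= 0 & sx <= pose$shaft_length
  if (!any(in_shaft))
    stop("applicator shaft lies entirely outside the grid domain")
  if (any(grid$labels[in_shaft] == match("spinal cord", grid$classes)))
    stop("applicator shaft intersects the spinal canal; placement rejected")
  labels <- grid$labels
  app_code <- match("applicator", grid$classes)
  labels[in_shaft] <- app_code

  # surface voxels: shaft voxels with a face neighbor outside the shaft
  is_app <- labels == app_code
  pad <- function(arr, shift, dimn) {
    out <- array(FALSE, dim = dim(arr))
    n <- dim(arr)[dimn]
    idx_to <- idx_from <- list(TRUE, TRUE, TRUE)
    idx_to[[dimn]] <- if (shift > 0) 2:n else 1:(n - 1)
    idx_from[[dimn]] <- if (shift > 0) 1:(n - 1) else 2:n
    out <- do.call(`[<-`, c(list(out), idx_to,
                            list(do.call(`[`, c(list(arr), idx_from)))))
    out
  }
  has_out_neighbor <- array(FALSE, dim = dm)
  for (dimn in 1:3) for (shift in c(-1, 1)) {
    nb <- pad(!is_app, shift, dimn)
    # voxels on the domain boundary also count as surface
    edge <- array(FALSE, dim = dm)
    idx <- list(TRUE, TRUE, TRUE)
    idx[[dimn]] <- if (shift > 0) 1L else dm[dimn]
    edge <- do.call(`[<-`, c(list(edge), idx, list(TRUE)))
    has_out_neighbor <- has_out_neighbor | nb | edge
  }
  mask <- is_app & has_out_neighbor
  grid$labels <- labels
  grid$applicator_mask <- mask
  grid$pose <- pose
  grid
}

#' Shortest gap between the shaft back surface and the canal boundary
#'
#' @param grid A `label_grid` with an applicator placed.
#' @param pose The [applicator_pose()] used.
#' @return Gap in m (axis-to-canal-center distance minus both radii).
#' @export
shaft_canal_gap <- function(grid, pose) {
  # both the shaft axis and the canal run through the central z plane;
  # distance in the x = const plane from axis point to canal center
  axis_y <- pose$tip_position[2]
  axis_z <- pose$tip_position[3]
  d <- sqrt((axis_y - grid$canal_center_y)^2 + axis_z^2)
  d - grid$spec$canal_diameter / 2 - pose$shaft_radius
}

#' Virtual temperature probe
#'
#' @param name Channel label, e.g. `"T1"`.
#' @param position Probe position (m).
#' @param nominal_distance Nominal radial distance from the applicator
#'   shaft axis (m), signed convention-free (magnitude).
#' @return An object of class `probe_spec`.
#' @export
probe_spec <- function(name, position, nominal_distance) {
  stopifnot(length(position) == 3L, nominal_distance >= 0)
  structure(list(name = name, position = position,
                 nominal_distance = nominal_distance), class = "probe_spec")
}

#' Default thermometry probes for a pose
#'
#' T1 sits 9.5 mm from the shaft axis along the radiation direction
#' (forward), in the cross-sectional plane of maximum heating (the active
#' zone center). T2 sits 2.5 mm along the opposite (backward) direction —
#' the simulation convention; `T2_histology` is the alternate backward
#' probe at the histology-derived 2.4 mm. Distances are measured from the
#' shaft axis (configurable convention; the surface-referenced alternative
#' adds the shaft radius).
#'
#' @param pose An [applicator_pose()].
#' @param t1_distance Forward probe distance (m), default 9.5e-3.
#' @param t2_distance Backward probe distance (m), default 2.5e-3.
#' @param t2_histology_distance Alternate backward distance (m), default
#'   2.4e-3.
#' @return Named list of [probe_spec()]s: `T1`, `T2`, `T2_histology`.
#' @export
default_probes <- function(pose, t1_distance = 9.5e-3, t2_distance = 2.5e-3,
                           t2_histology_distance = 2.4e-3) {
  ac <- active_zone_center(pose)
  rd <- pose$radiation_direction
  list(T1 = probe_spec("T1", ac + t1_distance * rd, t1_distance),
       T2 = probe_spec("T2", ac - t2_distance * rd, t2_distance),
       T2_histology = probe_spec("T2_histology",
                                 ac - t2_histology_distance * rd,
                                 t2_histology_distance))
}
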