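#' Construct a 4D flow dataset
#'
#' Bundles a time-resolved three-component velocity field and the matching
#' signal-magnitude image on a regular voxel grid. Velocities are stored
#' internally in m/s; world coordinates follow the VTK image-data convention
#' `world = origin + index * spacing` with 0-based voxel indices and velocity
#' components expressed along the world (x, y, z) axes.
#'
#' @param velocity 5-D numeric array indexed `(phase, z, y, x, component)`,
#'   components ordered (x, y, z).
#' @param magnitude 4-D numeric array `(phase, z, y, x)` in arbitrary units.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @param origin world position of voxel (0,0,0) in mm.
#' @param cycle_duration RR interval in seconds; phase k (0-based) is at time
#'   `k * cycle_duration / n_phases`.
#' @param velocity_units units of the supplied `velocity` values, `"m/s"` or
#'   `"cm/s"`; values are converted to m/s on construction.
#' @param venc optional velocity-encoding limit in cm/s (metadata only).
#' @return An object of class `flow_dataset`.
#' @export
flow_dataset <- function(velocity, magnitude, spacing, origin = c(0, 0, 0),
                         cycle_duration = NULL, velocity_units = "m/s",
                         venc = NULL) {
  check(length(dim(velocity)) == 5L && dim(velocity)[5] == 3L,
        "velocity must be a 5-D array (phase, z, y, x, component=3)")
  check(length(dim(magnitude)) == 4L, "magnitude must be a 4-D array (phase, z, y, x)")
  check(all(dim(velocity)[1:4] == dim(magnitude)),
        "velocity and magnitude grids differ: %s vs %s",
        paste(dim(velocity)[1:4], collapse = "x"),
        paste(dim(magnitude), collapse = "x"))
  check(length(spacing) == 3L && all(spacing > 0), "spacing must be 3 positive values (mm)")
  check(all(is.finite(velocity)), "velocity contains non-finite values")
  check(velocity_units %in% c("m/s", "cm/s"), "velocity_units must be 'm/s' or 'cm/s'")
  if (velocity_units == "cm/s") velocity <- velocity / 100
  if (is.null(cycle_duration)) {
    warning("cycle_duration not supplied; defaulting to 1.0 s")
    cycle_duration <- 1.0
  }
  check(cycle_duration > 0, "cycle_duration must be positive")
  structure(list(
    velocity = velocity, magnitude = magnitude,
    spacing = as.numeric(spacing), origin = as.numeric(origin),
    n_phases = dim(velocity)[1], cycle_duration = cycle_duration,
    venc = venc
  ), class = "flow_dataset")
}

#' @export
print.flow_dataset <- function(x, ...) {
  d <- dim(x$velocity)
  cat(sprintf("flow_dataset: %d phases, grid %dx%dx%d (z,y,x), spacing %s mm, RR %.3g s\n",
              x$n_phases, d[2], d[3], d[4],
              paste(signif(x$spacing, 4), collapse = "x"), x$cycle_duration))
  cat(sprintf("  peak speed %.3g m/s%s\n", sqrt(max(rowSums(
    matrix(x$velocity, ncol = 3)^2))),
    if (is.null(x$venc)) "" else sprintf(", VENC %.4g cm/s", x$venc)))
  invisible(x)
}

#' Phase times of a flow dataset
#'
#' @param ds a `flow_dataset`.
#' @return numeric vector of length `n_phases`, seconds; phase k (0-based) at
#'   `k * cycle_duration / n_phases`.
#' @export
phase_times <- function(ds) {
  (seq_len(ds$n_phases) - 1) * ds$cycle_duration / ds$n_phases
}

#' Construct a labeled segmentation mask
#'
#' @param labels 3-D integer array `(z, y, x)` of non-negative label values.
#' @param label_map named integer vector mapping structure names to label
#'   values, e.g. `c(LA = 1, LV = 2, AscAorta = 3)`.
#' @param spacing,origin grid geometry in mm, shared with the flow dataset the
#'   mask is applied to.
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(labels, label_map = c(LA = 1L), spacing, origin = c(0, 0, 0)) {
  check(length(dim(labels)) == 3L, "labels must be a 3-D array (z, y, x)")
  check(all(labels >= 0) && all(labels == round(labels)), "labels must be non-negative integers")
  check(length(spacing) == 3L && all(spacing > 0), "spacing must be 3 positive values (mm)")
  for (nm in names(label_map))
    if (!any(labels == label_map[[nm]]))
      warning(sprintf("declared label '%s' (=%d) has no voxels", nm, label_map[[nm]]))
  structure(list(labels = labels, label_map = label_map,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "mask3d")
}

# Binary (logical) array of a named label; errors on unknown labels.
label_array <- function(mask, label) {
  check(label %in% names(mask$label_map), "unknown label '%s' (known: %s)",
        label, paste(names(mask$label_map), collapse = ", "))
  mask$labels == mask$label_map[[label]]
}

# Grid congruence between a dataset and a mask.
check_congruent <- function(ds, mask) {
  check(all(dim(ds$velocity)[2:4] == dim(mask$labels)),
        "dataset grid %s and mask grid %s are not congruent",
        paste(dim(ds$velocity)[2:4], collapse = "x"),
        paste(dim(mask$labels), collapse = "x"))
  check(all(abs(ds$spacing - mask$spacing) < 1e-9), "dataset and mask spacing differ")
}

#' Zero all velocities outside a labeled region
#'
#' Velocities at voxels outside the named label are set exactly to zero at all
#' phases; in-mask velocities and the magnitude image are untouched. The
#' operation is idempotent.
#'
#' @param ds a `flow_dataset`.
#' @param mask a `mask3d` on the same grid.
#' @param label structure name in `mask$label_map` (default `"LA"`).
#' @return the masked `flow_dataset`.
#' @export
apply_mask <- function(ds, mask, label = "LA") {
  check_congruent(ds, mask)
  inmask <- label_array(mask, label)
  if (!any(inmask)) warning(sprintf("label '%s' region is empty; all velocities zeroed", label))
  keep <- aperm(array(inmask, c(dim(inmask), ds$n_phases, 3L)), c(4, 1, 2, 3, 5))
  ds$velocity <- ds$velocity * keep
  ds
}

#' Construct a named sample sphere
#'
#' Sample spheres locate the four pulmonary veins and the mitral valve; they
#' seed the dominant-flow-direction estimate and the vessel cross-sections.
#'
#' @param name one of `"RS"`, `"RI"`, `"LS"`, `"LI"`, `"MV"`.
#' @param center world coordinates (x, y, z) in mm.
#' @param radius sphere radius in mm, positive.
#' @return An object of class `sphere_seed`.
#' @export
sphere_seed <- function(name, center, radius) {
  check(name %in% c("RS", "RI", "LS", "LI", "MV"),
        "seed name must be one of RS, RI, LS, LI, MV")
  check(length(center) == 3L && all(is.finite(center)), "center must be (x, y, z) in mm")
  check(is.finite(radius) && radius > 0, "radius must be positive")
  structure(list(name = name, center = as.numeric(center), radius = radius),
            class = "sphere_seed")
}

#' Read and write sphere-seed files
#'
#' Seeds are stored as a JSON array of `{name, center_mm, radius_mm}` objects.
#'
#' @param path file path.
#' @return `read_seeds` returns a named list of `sphere_seed` objects.
#' @export
read_seeds <- function(path) {
  check(file.exists(path), "seeds file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  seeds <- lapply(raw, function(s) sphere_seed(s$name, unlist(s$center_mm), s$radius_mm))
  names(seeds) <- vapply(seeds, `[[`, "", "name")
  seeds
}

#' @rdname read_seeds
#' @param seeds named list of `sphere_seed` objects.
#' @export
write_seeds <- function(seeds, path) {
  jsonlite::write_json(lapply(unname(seeds), function(s)
    list(name = s$name, center_mm = s$center, radius_mm = s$radius)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a sampled time series over one cardiac cycle
#'
#' @param name series name (e.g. `"KE"`, `"flow_RS"`).
#' @param times sample times in seconds, strictly increasing.
#' @param values sampled values, finite.
#' @param units unit string (`"ml/s"`, `"mJ"`, `"mW"`, `"1/s"`, ...).
#' @return An object of class `flow_ts`.
#' @export
flow_ts <- function(name, times, values, units = "") {
  check(length(times) == length(values), "times and values lengths differ")
  check(all(diff(times) > 0), "times must be strictly increasing")
  check(all(is.finite(times)), "times must be finite")
  structure(list(name = name, times = as.numeric(times),
                 values = as.numeric(values), units = units),
            class = "flow_ts")
}

#' @export
print.flow_ts <- function(x, ...) {
  cat(sprintf("flow_ts '%s' [%s]: %d samples over %.3g s, range [%.4g, %.4g]\n",
              x$name, x$units, length(x$times), max(x$times) - min(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.flow_ts <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values, units = x$units, name = x$name)
}

#' Upsample the spatial axes of a scalar field by cubic interpolation
#'
#' Each spatial axis of a `(phase, z, y, x)` field is resampled to `factor`
#' times as many voxel centers by separable cubic-spline interpolation; the
#' time axis is untouched. Output voxel centers tile the same physical extent
#' at spacing `h / factor`. Affine fields are reproduced exactly.
#'
#' @param field 4-D array `(phase, z, y, x)` (a 3-D `(z, y, x)` array is also
#'   accepted and treated as a single phase).
#' @param factor integer upsampling factor, >= 1.
#' @return array with spatial dimensions multiplied by `factor`.
#' @export
upsample_scalar <- function(field, factor) {
  check(is.numeric(factor) && factor >= 1 && factor == round(factor),
        "factor must be an integer >= 1")
  factor <- as.integer(factor)
  squeeze <- FALSE
  if (length(dim(field)) == 3L) {
    field <- array(field, c(1L, dim(field)))
    squeeze <- TRUE
  }
  check(length(dim(field)) == 4L, "field must be (phase, z, y, x)")
  if (factor > 1L) {
    for (ax in 2:4) field <- upsample_axis(field, ax, factor)
  }
  if (squeeze) field <- array(field, dim(field)[2:4])
  field
}

# Cubic-spline resampling of one axis of a 4-D array. New voxel centers in old
# index coordinates: u_j = (j + 0.5)/factor - 0.5, j = 0..factor*n-1, i.e. the
# refined grid covers the same extent with spacing h/factor.
upsample_axis <- function(a, axis, factor) {
  n <- dim(a)[axis]
  uout <- (seq_len(factor * n) - 0.5) / factor - 0.5
  perm <- c(setdiff(seq_len(4L), axis), axis)        # move target axis last
  ap <- aperm(a, perm)
  m <- matrix(ap, ncol = n)
  out <- matrix(0, nrow(m), length(uout))
  u <- 0:(n - 1)
  for (i in seq_len(nrow(m)))
    out[i, ] <- spline(u, m[i, ], xout = uout, method = "fmm")$y
  newdim <- dim(ap); newdim[4] <- length(uout)
  aperm(array(out, newdim), order(perm))
}
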