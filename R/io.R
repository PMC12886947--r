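# Readers and writers. NIfTI goes through RNifti; VTK XML image data (.vti),
# legacy VTK meshes/polylines and STL are written directly (ASCII) since the
# consumers are generic VTK viewers.

#' Save a flow dataset as per-component NIfTI volumes
#'
#' Writes `<basename>_velx/vely/velz.nii.gz` (m/s), `<basename>_mag.nii.gz`,
#' and `<basename>_meta.json` (spacing, origin, timing, VENC) to `dir`.
#'
#' @param ds a `flow_dataset`.
#' @param dir output directory (created if missing).
#' @param basename file stem, default `"flow"`.
#' @return the directory, invisibly.
#' @export
save_flowdataset <- function(ds, dir, basename = "flow") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  comp <- c("velx", "vely", "velz")
  for (c in 1:3) {
    a <- aperm(ds$velocity[, , , , c, drop = FALSE][, , , , 1], c(4, 3, 2, 1)) # -> (x,y,z,t)
    img <- RNifti::asNifti(a, pixdim = c(ds$spacing, ds$cycle_duration / ds$n_phases))
    RNifti::writeNifti(img, file.path(dir, sprintf("%s_%s.nii.gz", basename, comp[c])))
  }
  m <- aperm(ds$magnitude, c(4, 3, 2, 1))
  RNifti::writeNifti(RNifti::asNifti(m, pixdim = c(ds$spacing, ds$cycle_duration / ds$n_phases)),
                     file.path(dir, sprintf("%s_mag.nii.gz", basename)))
  jsonlite::write_json(list(spacing_mm = ds$spacing, origin_mm = ds$origin,
                            n_phases = ds$n_phases, cycle_duration_s = ds$cycle_duration,
                            venc_cms = ds$venc, velocity_units = "m/s"),
                       file.path(dir, sprintf("%s_meta.json", basename)),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a flow dataset from NIfTI files
#'
#' Reads three per-component velocity volumes plus a magnitude volume, each a
#' 4-D NIfTI ordered `(x, y, z, t)`, and normalizes to the internal
#' `(phase, z, y, x, component)` layout in m/s.
#'
#' @param velocity_paths character vector of 3 file paths (x, y, z components).
#' @param magnitude_path magnitude file path.
#' @param units units of the stored velocity values, `"m/s"` or `"cm/s"`.
#' @param cycle_duration RR interval in seconds; if `NULL`, taken from
#'   `meta_path`, else from the NIfTI time step; a hard error if none is
#'   available.
#' @param meta_path optional JSON metadata file written by
#'   [save_flowdataset()]; supplies spacing/origin/timing/VENC defaults.
#' @param venc optional VENC metadata, cm/s.
#' @return a `flow_dataset`.
#' @export
load_flowdataset <- function(velocity_paths, magnitude_path, units = "m/s",
                             cycle_duration = NULL, meta_path = NULL, venc = NULL) {
  check(length(velocity_paths) == 3L, "need exactly 3 velocity component files")
  for (p in c(velocity_paths, magnitude_path))
    check(file.exists(p), "file not found: %s", p)
  imgs <- lapply(velocity_paths, RNifti::readNifti)
  dims <- lapply(imgs, dim)
  for (i in 2:3)
    check(identical(dims[[i]], dims[[1]]),
          "velocity component shape mismatch: %s has %s, expected %s (from %s)",
          velocity_paths[i], paste(dims[[i]], collapse = "x"),
          paste(dims[[1]], collapse = "x"), velocity_paths[1])
  mag <- RNifti::readNifti(magnitude_path)
  check(identical(dim(mag), dims[[1]]),
        "magnitude shape mismatch: %s has %s, expected %s",
        magnitude_path, paste(dim(mag), collapse = "x"),
        paste(dims[[1]], collapse = "x"))
  d <- dims[[1]]
  if (length(d) == 3L) d <- c(d, 1L)
  to_internal <- function(a) aperm(array(a, d), c(4, 3, 2, 1))  # (x,y,z,t)->(t,z,y,x)
  vel <- array(0, c(d[4], d[3], d[2], d[1], 3L))
  for (c in 1:3) vel[, , , , c] <- to_internal(imgs[[c]])
  hdr <- RNifti::niftiHeader(imgs[[1]])
  spacing <- hdr$pixdim[2:4]
  origin <- c(0, 0, 0)
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    spacing <- meta$spacing_mm
    origin <- meta$origin_mm
    if (is.null(cycle_duration)) cycle_duration <- meta$cycle_duration_s
    if (is.null(venc) && !is.null(meta$venc_cms)) venc <- meta$venc_cms
  }
  if (is.null(cycle_duration)) {
    dt <- if (length(hdr$pixdim) >= 5) hdr$pixdim[5] else 0
    check(is.finite(dt) && dt > 0,
          "no cardiac timing available: supply cycle_duration or a metadata file")
    cycle_duration <- dt * d[4]
  }
  flow_dataset(vel, to_internal(mag), spacing = spacing, origin = origin,
               cycle_duration = cycle_duration, velocity_units = units, venc = venc)
}

#' Write scalar/vector voxel fields as VTK XML image data (.vti)
#'
#' @param fields named list of arrays on the `(z, y, x)` grid: 3-D arrays are
#'   written as scalars, 4-D `(z, y, x, 3)` arrays as vectors.
#' @param spacing,origin grid geometry, mm.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vti <- function(fields, spacing, origin, path) {
  d <- NULL
  for (f in fields) {
    dd <- dim(f)[1:3]
    if (is.null(d)) d <- dd else check(all(d == dd), "fields have differing grids")
  }
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">')
  w('  <ImageData WholeExtent="0 %d 0 %d 0 %d" Origin="%.9g %.9g %.9g" Spacing="%.9g %.9g %.9g">',
    nx - 1, ny - 1, nz - 1, origin[1], origin[2], origin[3],
    spacing[1], spacing[2], spacing[3])
  w('    <Piece Extent="0 %d 0 %d 0 %d">', nx - 1, ny - 1, nz - 1)
  w('      <PointData>')
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (length(dim(f)) == 3L) {
      vals <- as.vector(aperm(f, c(3, 2, 1)))  # x fastest
      ncomp <- 1L
    } else {
      vals <- as.vector(t(matrix(aperm(f, c(3, 2, 1, 4)), ncol = 3)))
      ncomp <- 3L
    }
    w('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
      nm, ncomp)
    writeLines(paste(format(vals, digits = 17, trim = TRUE, scientific = TRUE),
                     collapse = " "), con)
    w('        </DataArray>')
  }
  w('      </PointData>')
  w('      <CellData/>')
  w('    </Piece>')
  w('  </ImageData>')
  w('</VTKFile>')
  invisible(path)
}

#' Read a VTK XML image-data file written by [write_vti()]
#'
#' Supports ASCII Float64 point-data arrays only.
#'
#' @param path .vti file path.
#' @return list with `fields` (named arrays, `(z, y, x)[, 3]`), `spacing`,
#'   `origin`.
#' @export
read_vti <- function(path) {
  doc <- xml2::read_xml(path)
  img <- xml2::xml_find_first(doc, ".//ImageData")
  ext <- as.integer(strsplit(xml2::xml_attr(img, "WholeExtent"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(xml2::xml_attr(img, "Origin"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(xml2::xml_attr(img, "Spacing"), "\\s+")[[1]])
  nx <- ext[2] + 1L; ny <- ext[4] + 1L; nz <- ext[6] + 1L
  arrays <- xml2::xml_find_all(doc, ".//PointData/DataArray")
  fields <- list()
  for (a in arrays) {
    nm <- xml2::xml_attr(a, "Name")
    ncomp <- as.integer(xml2::xml_attr(a, "NumberOfComponents"))
    vals <- as.numeric(strsplit(trimws(xml2::xml_text(a)), "\\s+")[[1]])
    if (ncomp == 1L) {
      fields[[nm]] <- aperm(array(vals, c(nx, ny, nz)), c(3, 2, 1))
    } else {
      m <- matrix(vals, ncol = ncomp, byrow = TRUE)
      f <- array(0, c(nz, ny, nx, ncomp))
      for (c in seq_len(ncomp))
        f[, , , c] <- aperm(array(m[, c], c(nx, ny, nz)), c(3, 2, 1))
      fields[[nm]] <- f
    }
  }
  list(fields = fields, spacing = spacing, origin = origin)
}

#' Write a triangular surface mesh as ASCII STL
#'
#' @param mesh a `surface_mesh` (see [mask_to_surface_mesh()]).
#' @param path output path.
#' @param name solid name embedded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "surface") {
  v <- mesh$vertices; f <- mesh$faces
  p0 <- v[f[, 1], , drop = FALSE]
  p1 <- v[f[, 2], , drop = FALSE]
  p2 <- v[f[, 3], , drop = FALSE]
  n <- cross3(p1 - p0, p2 - p0)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  body <- sprintf(paste0(
    "facet normal %.9g %.9g %.9g\n outer loop\n",
    "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
    " endloop\nendfacet"),
    n[, 1], n[, 2], n[, 3],
    p0[, 1], p0[, 2], p0[, 3], p1[, 1], p1[, 2], p1[, 3], p2[, 1], p2[, 2], p2[, 3])
  writeLines(body, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Write a tetrahedral mesh as legacy ASCII VTK unstructured grid
#'
#' @param mesh a `tet_mesh` (see [mask_to_volume_mesh()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vtk_tets <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tetrahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  nt <- nrow(mesh$tets)
  writeLines(sprintf("CELLS %d %d", nt, 5L * nt), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("10", nt), con)
  invisible(path)
}

#' Write pathlines as legacy ASCII VTK polydata with a speed scalar
#'
#' @param paths a `pathline_set` (see [advect()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pathlines_vtk <- function(paths, path) {
  pts <- do.call(rbind, lapply(paths$particles, `[[`, "positions"))
  speeds <- unlist(lapply(paths$particles, `[[`, "speed"))
  lens <- vapply(paths$particles, function(p) nrow(p$positions), 0L)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "pathlines", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(pts))), con)
  writeLines(sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3]), con)
  keep <- lens >= 2L
  offs <- cumsum(c(0L, lens))[seq_along(lens)]
  writeLines(sprintf("LINES %d %d", sum(keep), sum(lens[keep] + 1L)), con)
  for (i in which(keep))
    writeLines(paste(c(lens[i], offs[i] + seq_len(lens[i]) - 1L), collapse = " "), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(pts)), "SCALARS speed double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.9g", speeds), con)
  invisible(path)
}

# Cross product of row-matched 3-vectors (n x 3 matrices).
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
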