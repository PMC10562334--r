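#' Segment the nasal air space by Hounsfield-unit thresholding
#'
#' Marks every voxel whose HU value lies in the closed window
#' \[`lo`, `hi`\] as air. The default window -1000 to -430 HU is the standard
#' air-space window for cone-beam CT of the nasal cavities.
#'
#' @param vol an `hu_volume`.
#' @param lo,hi inclusive window bounds (HU).
#' @return an `airway_mask`: logical 3-D mask plus spacing, origin and a
#'   provenance record of the processing applied.
#' @export
threshold_airway <- function(vol, lo = -1000, hi = -430) {
  stopifnot(inherits(vol, "hu_volume"))
  if (lo >= hi) stopf("lower threshold must be below upper threshold")
  m <- vol$values >= lo & vol$values <= hi
  if (!any(m)) stopf("no air voxels found in window [%g, %g] HU", lo, hi)
  airway_mask(m, vol$spacing, vol$origin,
              provenance = list(threshold = c(lo = lo, hi = hi)))
}

airway_mask <- function(mask, spacing, origin = c(0, 0, 0),
                        provenance = list()) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  structure(list(mask = mask, spacing = spacing, origin = origin,
                 provenance = provenance),
            class = "airway_mask")
}

#' @export
print.airway_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("airway mask: %d x %d x %d voxels at %.3g mm, %d air voxels (%.2f cm3)\n",
              d[1], d[2], d[3], x$spacing, sum(x$mask),
              sum(x$mask) * (x$spacing / 10)^3))
  invisible(x)
}

# y coordinate (mm) -> voxel slice index
y_to_slice <- function(mask, y_mm) {
  j <- round((y_mm - mask$origin[2]) / mask$spacing + 0.5)
  min(max(j, 1L), dim(mask$mask)[2])
}

#' Remove isolated air regions that carry no airflow
#'
#' Labels 6-connected components of the mask and keeps only those that
#' intersect both the nostril plane and the nasopharynx plane (the default
#' "spanning" rule): sinus pockets and reconstruction artefacts cannot carry
#' flow and are excluded. Components smaller than `min_size` voxels are
#' dropped first regardless of connectivity.
#'
#' @param mask an `airway_mask`.
#' @param nostril_y,nasopharynx_y positions of the nostril and nasopharynx
#'   planes (mm along y).
#' @param keep `"spanning"` (default) keeps inlet-to-outlet components;
#'   `"largest"` keeps the single largest component.
#' @param min_size artefact threshold (voxels).
#' @return the cleaned `airway_mask`; the number of voxels removed is logged
#'   in the provenance record.
#' @export
remove_isolated_regions <- function(mask, nostril_y, nasopharynx_y,
                                    keep = c("spanning", "largest"),
                                    min_size = 10) {
  stopifnot(inherits(mask, "airway_mask"))
  keep <- match.arg(keep)
  if (!any(mask$mask)) stopf("empty airway mask")
  lab <- .cc_label6(as.vector(mask$mask), dim(mask$mask))
  nlab <- attr(lab, "n")
  lab <- array(lab, dim = dim(mask$mask))
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  ok <- sizes >= min_size
  if (keep == "largest") {
    sel <- which.max(sizes * ok)
  } else {
    jin <- y_to_slice(mask, nostril_y + mask$spacing / 2)
    jout <- y_to_slice(mask, nasopharynx_y - mask$spacing / 2)
    lab_in <- unique(as.vector(lab[, jin, ]))
    lab_out <- unique(as.vector(lab[, jout, ]))
    sel <- intersect(setdiff(lab_in, 0L), setdiff(lab_out, 0L))
    sel <- sel[ok[sel]]
    if (length(sel) == 0)
      stopf("no air component connects the nostril plane to the nasopharynx (occluded airway)")
  }
  newmask <- array(lab %in% sel, dim = dim(mask$mask))
  removed <- sum(mask$mask) - sum(newmask)
  prov <- mask$provenance
  prov$isolated_removed <- list(voxels = removed,
                                components_kept = length(sel),
                                components_total = nlab, rule = keep)
  airway_mask(newmask, mask$spacing, mask$origin, prov)
}

#' Crop the airway to the nostril-nasopharynx domain and extend the outlet
#'
#' Restricts the mask to the slab between the nostril and nasopharynx planes
#' and appends a straight outlet duct of length `extension_mm` whose
#' cross-section is the airway cross-section at the nasopharynx plane. The
#' extension gives the flow solver a downstream buffer; it is excluded from
#' anatomical surface metrics.
#'
#' @param mask an `airway_mask`.
#' @param nostril_y,nasopharynx_y plane positions (mm); nostril must be
#'   anterior of the nasopharynx.
#' @param extension_mm length of the extruded outlet duct (mm).
#' @return the cropped/extended `airway_mask`, with the nasopharynx plane
#'   position stored in its provenance.
#' @export
crop_domain <- function(mask, nostril_y, nasopharynx_y, extension_mm = 50) {
  stopifnot(inherits(mask, "airway_mask"))
  if (nostril_y >= nasopharynx_y)
    stopf("nostril plane must be anterior of the nasopharynx plane")
  if (extension_mm < 0) stopf("extension must be non-negative")
  s <- mask$spacing
  j0 <- y_to_slice(mask, nostril_y + s / 2)
  j1 <- y_to_slice(mask, nasopharynx_y - s / 2)
  core <- mask$mask[, j0:j1, , drop = FALSE]
  next_ <- round(extension_mm / s)
  if (next_ > 0) {
    dc <- dim(core)
    cs <- core[, dc[2], ]                       # nasopharynx cross-section
    ext <- aperm(array(cs, dim = c(dc[1], dc[3], next_)), c(1, 3, 2))
    out <- array(FALSE, c(dc[1], dc[2] + next_, dc[3]))
    out[, seq_len(dc[2]), ] <- core
    out[, dc[2] + seq_len(next_), ] <- ext
    core <- out
  }
  prov <- mask$provenance
  prov$crop <- list(nostril_y = nostril_y, nasopharynx_y = nasopharynx_y,
                    extension_mm = extension_mm)
  origin <- mask$origin
  origin[2] <- nostril_y
  out <- airway_mask(core, s, origin, prov)
  attr(out, "nasopharynx_mm") <- nasopharynx_y
  out
}

#' Measure airway volume
#'
#' Voxel-counting volumetry, optionally restricted to a band along the
#' posterior axis and/or a z range.
#'
#' @param mask an `airway_mask`.
#' @param y_range optional `c(lo, hi)` band in mm (voxel centres inside the
#'   closed interval are counted).
#' @param z_range optional `c(lo, hi)` range in mm.
#' @return volume in cm^3.
#' @export
measure_volume <- function(mask, y_range = NULL, z_range = NULL) {
  stopifnot(inherits(mask, "airway_mask"))
  m <- mask$mask
  d <- dim(m)
  if (!is.null(y_range)) {
    yc <- mask$origin[2] + (seq_len(d[2]) - 0.5) * mask$spacing
    keep <- yc >= y_range[1] & yc <= y_range[2]
    m <- m[, keep, , drop = FALSE]
  }
  if (!is.null(z_range)) {
    zc <- mask$origin[3] + (seq_len(dim(m)[3]) - 0.5) * mask$spacing
    keep <- zc >= z_range[1] & zc <= z_range[2]
    m <- m[, , keep, drop = FALSE]
  }
  sum(m) * (mask$spacing / 10)^3
}

#' Extract a closed triangulated surface of the airway
#'
#' Builds the blocky isosurface of the binary mask: every boundary voxel face
#' becomes two triangles with outward orientation, and vertices are welded on
#' the voxel-corner lattice, so the surface is watertight (every edge is
#' shared by exactly two triangles) whenever the mask is non-empty. Faces on
#' the grid boundary are capped.
#'
#' @param mask an `airway_mask`.
#' @return a `surface_mesh`: list with `vertices` (n x 3, mm), `triangles`
#'   (m x 3, 1-based), per-triangle `area` (mm^2) and outward `normal`.
#' @export
extract_surface <- function(mask) {
  stopifnot(inherits(mask, "airway_mask"))
  m <- mask$mask
  if (!any(m)) stopf("cannot extract a surface from an empty mask")
  d <- dim(m)
  s <- mask$spacing
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m

  # boundary faces in each direction: cell true, neighbour false
  idx <- which(pad, arr.ind = TRUE)  # padded coords
  vsub <- function(i, j, k) pad[cbind(i, j, k)]
  faces <- list()
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  for (nd in seq_along(dirs)) {
    dv <- dirs[[nd]]
    nb <- !vsub(idx[, 1] + dv[1], idx[, 2] + dv[2], idx[, 3] + dv[3])
    if (any(nb)) faces[[nd]] <- cbind(idx[nb, , drop = FALSE], nd)
  }
  faces <- do.call(rbind, faces)
  # voxel (unpadded, 0-based) lower corner
  cx <- faces[, 1] - 2L; cy <- faces[, 2] - 2L; cz <- faces[, 3] - 2L
  ndir <- faces[, 4]

  # corner offsets of each face quad, ordered CCW seen from outside
  quad_offsets <- list(
    `1` = rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1)),  # +x
    `2` = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0)),  # -x
    `3` = rbind(c(0, 1, 0), c(0, 1, 1), c(1, 1, 1), c(1, 1, 0)),  # +y
    `4` = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1)),  # -y
    `5` = rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),  # +z
    `6` = rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0))   # -z
  )
  nfaces <- length(ndir)
  corner_id <- matrix(0L, nfaces, 4)
  L <- c(d[1] + 1L, d[2] + 1L, d[3] + 1L)  # corner lattice dims
  for (q in 1:4) {
    offs <- t(vapply(ndir, function(nd) quad_offsets[[nd]][q, ],
                     numeric(3)))
    gx <- cx + offs[, 1]; gy <- cy + offs[, 2]; gz <- cz + offs[, 3]
    corner_id[, q] <- 1L + gx + L[1] * (gy + L[2] * gz)
  }
  used <- sort(unique(as.vector(corner_id)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  tri <- rbind(cbind(remap[corner_id[, 1]], remap[corner_id[, 2]],
                     remap[corner_id[, 3]]),
               cbind(remap[corner_id[, 1]], remap[corner_id[, 3]],
                     remap[corner_id[, 4]]))
  u0 <- used - 1L
  gx <- u0 %% L[1]; gy <- (u0 %/% L[1]) %% L[2]; gz <- u0 %/% (L[1] * L[2])
  verts <- cbind(gx, gy, gz) * s +
    matrix(mask$origin, length(used), 3, byrow = TRUE)
  normals <- t(vapply(c(ndir, ndir), function(nd) dirs[[nd]], numeric(3)))
  structure(list(vertices = verts, triangles = tri,
                 area = rep(s^2 / 2, nrow(tri)), normal = normals,
                 spacing = s),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface mesh: %d vertices, %d triangles, area %.2f mm2\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$area)))
  invisible(x)
}

#' Write / read STL surface files
#'
#' Supports binary (default) and ASCII Standard Tessellation Language.
#' Binary STL stores float32 vertices; a write-read round trip preserves the
#' triangle count exactly and coordinates to float32 precision.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param binary write binary STL (TRUE) or ASCII (FALSE).
#' @return `write_stl` returns `path` invisibly; `read_stl` returns a
#'   `surface_mesh` (triangle soup: vertices are not re-welded).
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; tr <- mesh$triangles; nm <- mesh$normal
  nt <- nrow(tr)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nt), con, size = 4, endian = "little")
    for (t in seq_len(nt)) {
      writeBin(as.numeric(nm[t, ]), con, size = 4, endian = "little")
      writeBin(as.numeric(t(v[tr[t, ], ])), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid airway", con)
    for (t in seq_len(nt)) {
      writeLines(sprintf("  facet normal %g %g %g", nm[t, 1], nm[t, 2],
                         nm[t, 3]), con)
      writeLines("    outer loop", con)
      for (q in 1:3)
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           v[tr[t, q], 1], v[tr[t, q], 2], v[tr[t, q], 3]),
                   con)
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid airway", con)
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80)
  probe <- rawToChar(header[1:5])
  close(con)
  if (identical(tolower(probe), "solid")) {
    # could still be binary with a 'solid' header; check facet keyword
    txt <- readLines(path, n = 3, warn = FALSE)
    if (any(grepl("facet", txt))) return(read_stl_ascii(path))
  }
  read_stl_binary(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  verts <- matrix(0, nt * 3, 3)
  normals <- matrix(0, nt, 3)
  for (t in seq_len(nt)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "integer", 1, size = 2, endian = "little")
    normals[t, ] <- rec[1:3]
    verts[(3 * t - 2):(3 * t), ] <- matrix(rec[4:12], 3, byrow = TRUE)
  }
  tri <- matrix(seq_len(nt * 3), nt, 3, byrow = TRUE)
  structure(list(vertices = verts, triangles = tri,
                 area = tri_areas(verts, tri), normal = normals),
            class = "surface_mesh")
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  nt <- nrow(verts) / 3
  tri <- matrix(seq_len(nt * 3), nt, 3, byrow = TRUE)
  nl <- grep("^\\s*facet normal", txt, value = TRUE)
  normals <- do.call(rbind, lapply(strsplit(trimws(nl), "\\s+"),
                                   function(x) as.numeric(x[3:5])))
  structure(list(vertices = verts, triangles = tri,
                 area = tri_areas(verts, tri), normal = normals),
            class = "surface_mesh")
}

tri_areas <- function(v, tr) {
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}
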