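# Synthetic voxel head models. Coordinates: x (probe axis, mm), y (lateral,
# mm), z (depth, mm); the outer medium sits above the z = 0 plane. Voxel
# centers at ((i-1) + 0.5) * voxel_mm along each axis, 0-based indices in the
# stored provenance. Labels: 0 outer, 1 scalp, 2 skull, 3 CSF, 4 GM, 5 WM,
# 6 sinus.

HEAD_LABELS <- c(outer = 0L, scalp = 1L, skull = 2L, csf = 3L, gm = 4L,
                 wm = 5L, sinus = 6L)

#' Build a synthetic layered voxel head model
#'
#' Generates a labeled voxel volume standing in for an MRI-segmented head:
#' stacked scalp / skull / CSF / gray-matter shells over white matter, either
#' flat or spherically curved, with optional smooth random undulation of the
#' layer interfaces and an optional ellipsoidal sinus pocket inside the skull.
#' The defaults (scalp 5, skull 7, CSF 2, GM 4 mm) put the first white-matter
#' depth at 18 mm, inside the 16--20 mm band typical of segmented adult
#' foreheads.
#'
#' @param layer_thicknesses_mm named numeric: `scalp`, `skull`, `csf`, `gm`
#'   thicknesses in mm; everything deeper is white matter.
#' @param curvature_radius_mm radius of the outer scalp sphere in mm, or `Inf`
#'   for a flat slab.
#' @param dims_vox integer triplet, voxels along (x, y, z).
#' @param voxel_mm voxel edge in mm (default 0.93).
#' @param undulation_mm amplitude of smooth random interface undulation (mm);
#'   0 disables it.
#' @param sinus optional `list(center_mm = c(x, y, z), semiaxes_mm = c(a, b, c))`
#'   ellipsoid; voxels inside it that would be skull become sinus.
#' @param seed integer seed controlling the undulation field.
#' @return object of class `voxel_head_model`.
#' @export
build_synthetic_head <- function(layer_thicknesses_mm = c(scalp = 5, skull = 7,
                                                          csf = 2, gm = 4),
                                 curvature_radius_mm = Inf,
                                 dims_vox = c(88L, 56L, 56L),
                                 voxel_mm = 0.93,
                                 undulation_mm = 0,
                                 sinus = NULL,
                                 seed = 1L) {
  stopifnot(all(layer_thicknesses_mm > 0), length(dims_vox) == 3,
            all(dims_vox >= 4), voxel_mm > 0)
  th <- layer_thicknesses_mm[c("scalp", "skull", "csf", "gm")]
  if (anyNA(th)) stop("layer_thicknesses_mm must name scalp, skull, csf, gm")
  nx <- dims_vox[1]; ny <- dims_vox[2]; nz <- dims_vox[3]
  xc <- (seq_len(nx) - 0.5) * voxel_mm
  yc <- (seq_len(ny) - 0.5) * voxel_mm
  zc <- (seq_len(nz) - 0.5) * voxel_mm

  surface <- if (is.finite(curvature_radius_mm)) {
    list(type = "sphere",
         center_mm = c(nx * voxel_mm / 2, ny * voxel_mm / 2,
                       curvature_radius_mm),
         radius_mm = curvature_radius_mm)
  } else {
    list(type = "flat")
  }

  # depth below the (possibly curved) outer surface for every voxel center
  if (surface$type == "flat") {
    depth <- array(rep(zc, each = nx * ny), dim = c(nx, ny, nz))
  } else {
    cx <- surface$center_mm[1]; cy <- surface$center_mm[2]
    R <- surface$radius_mm
    r_lat2 <- outer((xc - cx)^2, (yc - cy)^2, "+")
    depth <- array(NA_real_, dim = c(nx, ny, nz))
    for (k in seq_len(nz)) {
      # distance from sphere center; depth = R - |p - C|, C above at z = R
      depth[, , k] <- R - sqrt(r_lat2 + (R - zc[k])^2)
    }
  }

  # smooth random undulation shared by all interfaces (rigid shift of the
  # layer stack, preserving thicknesses and anatomical order)
  if (undulation_mm > 0) {
    set.seed(seed)
    lx <- nx * voxel_mm; ly <- ny * voxel_mm
    nmodes <- 4L
    amp <- stats::rnorm(nmodes); amp <- amp / sqrt(sum(amp^2)) * undulation_mm
    fx <- stats::runif(nmodes, 0.5, 1.5) * 2 * pi / lx
    fy <- stats::runif(nmodes, 0.5, 1.5) * 2 * pi / ly
    ph <- stats::runif(nmodes, 0, 2 * pi)
    und <- matrix(0, nx, ny)
    for (m in seq_len(nmodes)) {
      und <- und + amp[m] * outer(sin(fx[m] * xc + ph[m]), cos(fy[m] * yc))
    }
    depth <- sweep(depth, c(1, 2), und, "+")
  }

  edges <- cumsum(th)
  labels <- array(HEAD_LABELS[["outer"]], dim = c(nx, ny, nz))
  labels[depth > 0] <- HEAD_LABELS[["scalp"]]
  labels[depth > edges[1]] <- HEAD_LABELS[["skull"]]
  labels[depth > edges[2]] <- HEAD_LABELS[["csf"]]
  labels[depth > edges[3]] <- HEAD_LABELS[["gm"]]
  labels[depth > edges[4]] <- HEAD_LABELS[["wm"]]
  storage.mode(labels) <- "integer"

  if (!is.null(sinus)) {
    stopifnot(length(sinus$center_mm) == 3, length(sinus$semiaxes_mm) == 3,
              all(sinus$semiaxes_mm > 0))
    u2 <- outer(((xc - sinus$center_mm[1]) / sinus$semiaxes_mm[1])^2,
                ((yc - sinus$center_mm[2]) / sinus$semiaxes_mm[2])^2, "+")
    for (k in seq_len(nz)) {
      inside <- u2 + ((zc[k] - sinus$center_mm[3]) / sinus$semiaxes_mm[3])^2 <= 1
      slab <- labels[, , k]
      slab[inside & slab == HEAD_LABELS[["skull"]]] <- HEAD_LABELS[["sinus"]]
      labels[, , k] <- slab
    }
  }

  model <- structure(list(
    labels = labels,
    voxel_mm = voxel_mm,
    surface = surface,
    label_map = HEAD_LABELS,
    layers_mm = th,
    provenance = list(seed = seed, undulation_mm = undulation_mm,
                      sinus = sinus, generator = "build_synthetic_head",
                      histogram = table(labels))
  ), class = "voxel_head_model")
  model
}

#' @export
print.voxel_head_model <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Voxel head model: %d x %d x %d voxels, %.2f mm edge (%s surface)\n",
              d[1], d[2], d[3], x$voxel_mm,
              x$surface$type))
  counts <- table(factor(x$labels, levels = x$label_map,
                         labels = names(x$label_map)))
  cat("  labels:", paste(names(counts), counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Depth of the first white-matter voxel under a surface point
#'
#' @param model a [build_synthetic_head()] model.
#' @param at_mm lateral (x, y) position in mm; defaults to the volume center.
#' @return depth in mm from the outer surface to the first WM voxel center.
#' @export
wm_depth_mm <- function(model, at_mm = NULL) {
  d <- dim(model$labels)
  if (is.null(at_mm)) at_mm <- c(d[1], d[2]) * model$voxel_mm / 2
  i <- pmin(pmax(ceiling(at_mm / model$voxel_mm), 1), d[1:2])
  col <- model$labels[i[1], i[2], ]
  k_wm <- which(col == HEAD_LABELS[["wm"]])[1]
  k_surf <- which(col != HEAD_LABELS[["outer"]])[1]
  if (is.na(k_wm) || is.na(k_surf)) return(NA_real_)
  (k_wm - k_surf) * model$voxel_mm
}

#' Check the anatomical layer ordering invariant
#'
#' Scans random columns of the label volume: along increasing depth, the
#' compressed label sequence must follow scalp, skull, CSF, GM, WM with sinus
#' allowed only adjacent to skull.
#'
#' @param model a head model.
#' @param n_columns number of random columns to scan.
#' @param seed RNG seed for the column sample.
#' @return `TRUE` (invisibly) or an error describing the first bad column.
#' @export
check_anatomical_order <- function(model, n_columns = 100, seed = 1) {
  set.seed(seed)
  d <- dim(model$labels)
  rank <- c(`1` = 1, `2` = 2, `6` = 2, `3` = 3, `4` = 4, `5` = 5)
  for (t in seq_len(n_columns)) {
    i <- sample(d[1], 1); j <- sample(d[2], 1)
    col <- model$labels[i, j, ]
    col <- col[col != 0]
    if (!length(col)) next
    r <- rank[as.character(col)]
    r <- r[c(TRUE, diff(r) != 0)]
    if (any(diff(r) <= 0)) {
      stop(sprintf("column (%d, %d) violates anatomical ordering", i, j))
    }
  }
  invisible(TRUE)
}

# ---- probe placement --------------------------------------------------------

#' Place a source-detector probe on the scalp surface
#'
#' Lays one source fiber bundle and a row of detector fibers along the scalp
#' surface at the requested source-detector separations. On a flat model the
#' detectors are collinear with the source along +x; on a spherical model they
#' follow the great-circle geodesic through the anchor, so the arc length (not
#' the chord) equals the requested separation.
#'
#' @param model a [build_synthetic_head()] model.
#' @param sds_cm source-detector separations in cm, increasing; defaults to
#'   the six-fiber layout 0.8, 1.5, 2.12, 3, 3.35, 4.5 cm.
#' @param anchor_mm lateral (x, y) anchor of the source in mm; defaults to a
#'   margin of 15 mm from the -x face, centered in y.
#' @param source list: `radius_mm` (active bundle radius, default 2.1) and
#'   `na` (launch numerical aperture, default 0.39).
#' @param detector list: `radius_mm` (fiber core radius, default 0.2) and
#'   `na` (acceptance numerical aperture, default 0.12).
#' @param n_fiber refractive index of the fibers and outer medium (1.457).
#' @return object of class `probe_layout`: source description plus a detector
#'   tibble (id, sds_cm, position, outward normal).
#' @export
place_probe <- function(model,
                        sds_cm = c(0.8, 1.5, 2.12, 3, 3.35, 4.5),
                        anchor_mm = NULL,
                        source = list(radius_mm = 2.1, na = 0.39),
                        detector = list(radius_mm = 0.2, na = 0.12),
                        n_fiber = 1.457) {
  stopifnot(all(sds_cm >= 0), !is.unsorted(sds_cm))
  d <- dim(model$labels)
  ext_mm <- d * model$voxel_mm
  if (is.null(anchor_mm)) anchor_mm <- c(15, ext_mm[2] / 2)

  surf_point <- function(lat_mm) {
    if (model$surface$type == "flat") {
      list(pos = c(lat_mm, 0), normal = c(0, 0, -1))
    } else {
      # arc-length parameterization along the great circle in the y = const
      # plane through the anchor; phi measured from the anchor's radius
      C <- model$surface$center_mm; R <- model$surface$radius_mm
      v0 <- c(anchor_mm[1] - C[1], anchor_mm[2] - C[2])
      z0 <- -sqrt(max(R^2 - sum(v0^2), 0))          # anchor below center
      u <- c(v0, z0) / R                            # unit radial at anchor
      tx <- c(1, 0, 0); tx <- tx - sum(tx * u) * u  # tangent toward +x
      tx <- tx / sqrt(sum(tx^2))
      phi <- (lat_mm[1] - anchor_mm[1]) / R
      un <- u * cos(phi) + tx * sin(phi)
      list(pos = C + R * un, normal = un)
    }
  }

  anchor <- surf_point(anchor_mm)
  max_x <- anchor_mm[1] + max(sds_cm) * 10
  if (max_x > ext_mm[1] - 2 * model$voxel_mm) {
    feasible <- (ext_mm[1] - 2 * model$voxel_mm - anchor_mm[1]) / 10
    stop(sprintf("probe span exceeds model extent; max feasible SDS ~ %.2f cm",
                 feasible), call. = FALSE)
  }

  dets <- purrr::map_dfr(seq_along(sds_cm), function(i) {
    p <- surf_point(c(anchor_mm[1] + sds_cm[i] * 10, anchor_mm[2]))
    tibble::tibble(id = i, sds_cm = sds_cm[i],
                   x_mm = p$pos[1], y_mm = p$pos[2],
                   z_mm = if (length(p$pos) == 3) p$pos[3] else 0,
                   nx = p$normal[1], ny = p$normal[2], nz = p$normal[3],
                   radius_mm = detector$radius_mm, na = detector$na)
  })

  structure(list(
    source = list(pos_mm = c(anchor$pos[1:2],
                             if (length(anchor$pos) == 3) anchor$pos[3] else 0),
                  normal = anchor$normal,
                  radius_mm = source$radius_mm, na = source$na),
    detectors = dets,
    n_fiber = n_fiber,
    surface = model$surface
  ), class = "probe_layout")
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("Probe: source at (%.1f, %.1f, %.2f) mm, bundle r=%.1f mm, NA=%.2f\n",
              x$source$pos_mm[1], x$source$pos_mm[2], x$source$pos_mm[3],
              x$source$radius_mm, x$source$na))
  print(x$detectors)
  invisible(x)
}

# ---- I/O ---------------------------------------------------------------------

#' Write / read a head model as NIfTI + JSON sidecar
#'
#' The label volume goes into a NIfTI file (integer datatype, voxel size in
#' the header); everything else (surface description, label map, layers,
#' provenance) into a JSON sidecar at `<prefix>.json`.
#'
#' @param model a head model.
#' @param prefix output path prefix (writes `<prefix>.nii.gz`, `<prefix>.json`).
#' @return `prefix` (write) or the model (read).
#' @export
write_head_model <- function(model, prefix) {
  img <- RNifti::asNifti(model$labels,
                         pixdim = rep(model$voxel_mm, 3), datatype = "int16")
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  meta <- list(voxel_mm = model$voxel_mm, surface = model$surface,
               label_map = as.list(model$label_map),
               layers_mm = as.list(model$layers_mm),
               provenance = model$provenance[setdiff(names(model$provenance),
                                                     "histogram")])
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_head_model
#' @export
read_head_model <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  labels <- array(as.integer(img), dim = dim(img))
  surface <- meta$surface
  if (!is.null(surface$center_mm)) surface$center_mm <- as.numeric(surface$center_mm)
  structure(list(
    labels = labels,
    voxel_mm = meta$voxel_mm,
    surface = surface,
    label_map = unlist(meta$label_map),
    layers_mm = unlist(meta$layers_mm),
    provenance = c(meta$provenance, list(histogram = table(labels)))
  ), class = "voxel_head_model")
}
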