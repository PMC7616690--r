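# Volume I/O, retina flattening, ROI construction and standardization.
#
# Axis convention: (axial row, lateral column, B-scan index), 0-based row
# arithmetic, half-open crop windows. Layer surfaces (ILM, BM) are per-A-scan
# axial heights in micrometres on the en-face (lateral x B-scan) grid; BM
# lies below (deeper than) the ILM, so bm >= ilm everywhere.

#' OCT volume container
#'
#' @param voxels 3D numeric array (height x width x n_bscans).
#' @param spacing Numeric length-3: (axial, lateral, inter-B-scan) voxel
#'   spacing in micrometres; strictly positive.
#' @param eye_id Opaque eye identifier.
#' @param visit_time Months since baseline (non-negative).
#' @param provenance Optional named list carried through I/O.
#' @return An `oct_volume` object.
#' @export
oct_volume <- function(voxels, spacing = c(3.4, 11.7, 60),
                       eye_id = "eye", visit_time = 0,
                       provenance = list()) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array, got ", length(dim(voxels)),
         " dimensions")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  if (visit_time < 0) stop("visit_time must be non-negative")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 eye_id = as.character(eye_id),
                 visit_time = as.numeric(visit_time),
                 provenance = provenance),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  cat("<oct_volume> ", paste(dim(x$voxels), collapse = "x"),
      " | spacing (um): ", paste(signif(x$spacing, 4), collapse = ", "),
      " | eye ", x$eye_id, " @ ", x$visit_time, " months\n", sep = "")
  invisible(x)
}

#' Retinal layer surfaces (ILM and BM)
#'
#' @param ilm,bm Numeric matrices (width x n_bscans) of axial heights in
#'   micrometres. Must be finite with `bm >= ilm` everywhere.
#' @return A `layer_surfaces` object.
#' @export
layer_surfaces <- function(ilm, bm) {
  if (!all(is.finite(ilm)) || !all(is.finite(bm)))
    stop("surfaces must be finite everywhere")
  if (!identical(dim(ilm), dim(bm)))
    stop("ilm and bm must share the en-face grid")
  if (any(bm < ilm))
    stop("bm must lie at or below ilm (bm >= ilm in axial depth)")
  structure(list(ilm = ilm, bm = bm), class = "layer_surfaces")
}

# Deterministic micrometre -> voxel-row rounding (half away from zero).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

check_surface_grid <- function(surfaces, volume) {
  dv <- dim(volume$voxels)
  if (!identical(as.integer(dim(surfaces$ilm)), as.integer(dv[2:3])))
    stop("surface grid (", paste(dim(surfaces$ilm), collapse = "x"),
         ") does not match the volume's en-face grid (",
         paste(dv[2:3], collapse = "x"), ")")
  invisible(TRUE)
}

#' Flatten the retina so that BM lies on a plane
#'
#' Each A-scan is shifted axially by an integer offset so that the
#' Bruch's-membrane row lands on a common target row. Voxels shifted out of
#' range are filled with `fill`.
#'
#' @param volume An [oct_volume()].
#' @param surfaces [layer_surfaces()] on the volume's en-face grid.
#' @param target_row Target 0-based BM row. Default places BM such that the
#'   169 um choroid margin ends at the bottom row.
#' @param fill Fill value for out-of-range voxels (default -1, the
#'   background value on the standardized intensity scale).
#' @return The flattened [oct_volume()].
#' @export
flatten_volume <- function(volume, surfaces, target_row = NULL, fill = -1) {
  stopifnot(inherits(volume, "oct_volume"), inherits(surfaces, "layer_surfaces"))
  check_surface_grid(surfaces, volume)
  v <- volume$voxels
  H <- dim(v)[1L]
  sp <- volume$spacing[1L]
  if (is.null(target_row))
    target_row <- H - 1L - round_half_away(169 / sp)
  bm_row <- round_half_away(surfaces$bm / sp)
  offset <- target_row - bm_row        # (W x D) integer shifts
  out <- array(fill, dim(v))
  for (d in seq_len(dim(v)[3L])) {
    for (w in seq_len(dim(v)[2L])) {
      o <- offset[w, d]
      src <- seq_len(H) - o            # new[r] = old[r - o] (1-based)
      keep <- src >= 1L & src <= H
      out[which(keep), w, d] <- v[src[keep], w, d]
    }
  }
  res <- volume
  res$voxels <- out
  res$provenance$flattened <- TRUE
  res$provenance$bm_target_row <- target_row
  res
}

#' Shift layer surfaces consistently with [flatten_volume()]
#'
#' @inheritParams flatten_volume
#' @return Shifted [layer_surfaces()].
#' @export
flatten_surfaces <- function(surfaces, volume, target_row = NULL) {
  sp <- volume$spacing[1L]
  H <- dim(volume$voxels)[1L]
  if (is.null(target_row))
    target_row <- H - 1L - round_half_away(169 / sp)
  bm_row <- round_half_away(surfaces$bm / sp)
  offset_um <- (target_row - bm_row) * sp
  layer_surfaces(surfaces$ilm + offset_um, surfaces$bm + offset_um)
}

#' Build the retinal region-of-interest mask
#'
#' The mask is 1 for axial rows between `margin_above` micrometres above the
#' ILM and `margin_below` micrometres below the BM (26 and 169 by default,
#' the latter including the choroid), per A-scan, clamped to the volume.
#'
#' @param surfaces [layer_surfaces()].
#' @param volume Matching [oct_volume()].
#' @param margin_above,margin_below Margins in micrometres.
#' @return An `roi_mask` object wrapping a binary array shaped like the
#'   volume.
#' @export
build_roi_mask <- function(surfaces, volume,
                           margin_above = 26, margin_below = 169) {
  stopifnot(inherits(volume, "oct_volume"), inherits(surfaces, "layer_surfaces"))
  check_surface_grid(surfaces, volume)
  sp <- volume$spacing[1L]
  if (!is.finite(sp) || sp <= 0) stop("axial spacing must be positive")
  H <- dim(volume$voxels)[1L]
  ilm_row <- round_half_away(surfaces$ilm / sp)
  bm_row <- round_half_away(surfaces$bm / sp)
  up <- round_half_away(margin_above / sp)
  down <- round_half_away(margin_below / sp)
  lo <- pmax(ilm_row - up, 0)
  hi <- pmin(bm_row + down, H - 1)
  m <- array(0, dim(volume$voxels))
  for (d in seq_len(dim(m)[3L]))
    for (w in seq_len(dim(m)[2L])) {
      if (hi[w, d] >= lo[w, d])
        m[(lo[w, d]:hi[w, d]) + 1L, w, d] <- 1
    }
  structure(list(mask = m), class = "roi_mask")
}

#' Standardize a volume to the network input space
#'
#' Crops the central `crop_mm` x `crop_mm` en-face region (computed from the
#' lateral and inter-B-scan spacing), resizes to `target_shape` (trilinear
#' for intensities; nearest-neighbour for the mask so it stays binary), and
#' linearly rescales the intensity min-max range to [-1, 1].
#'
#' @param volume A flattened [oct_volume()].
#' @param roi Matching `roi_mask`.
#' @param target_shape Output shape, default c(192, 192, 32).
#' @param crop_mm En-face crop size in millimetres (default 3).
#' @return List with elements `volume` and `roi`.
#' @export
standardize_volume <- function(volume, roi, target_shape = c(192L, 192L, 32L),
                               crop_mm = 3) {
  stopifnot(inherits(volume, "oct_volume"), inherits(roi, "roi_mask"))
  v <- volume$voxels
  m <- roi$mask
  dm <- dim(v)
  n_w <- round_half_away(crop_mm * 1000 / volume$spacing[2L])
  n_d <- round_half_away(crop_mm * 1000 / volume$spacing[3L])
  if (n_w > dm[2L] || n_d > dm[3L])
    stop("field of view smaller than ", crop_mm, "x", crop_mm, " mm^2")
  w0 <- (dm[2L] - n_w) %/% 2L
  d0 <- (dm[3L] - n_d) %/% 2L
  wi <- w0 + seq_len(n_w)
  di <- d0 + seq_len(n_d)
  v <- v[, wi, di, drop = FALSE]
  m <- m[, wi, di, drop = FALSE]
  # trilinear resize (intensities)
  x <- array(v, c(1L, dim(v)))
  vz <- trilinear_resize_fw_cpp(x, dim(x), as.integer(target_shape))
  vz <- array(vz, target_shape)
  # nearest-neighbour resize (mask)
  mz <- nearest_resize_3d(m, target_shape)
  rng <- range(vz)
  if (diff(rng) == 0) {
    warning("constant-intensity volume: rescale maps everything to -1")
    vz[] <- -1
  } else {
    vz <- 2 * (vz - rng[1L]) / diff(rng) - 1
  }
  res <- volume
  res$voxels <- vz
  res$provenance$standardized <- TRUE
  list(volume = res, roi = structure(list(mask = mz), class = "roi_mask"))
}

nearest_resize_3d <- function(x, target) {
  dm <- dim(x)
  idx <- function(n_in, n_out) {
    i <- floor(((seq_len(n_out) - 0.5) * n_in) / n_out) + 1L
    pmin(pmax(i, 1L), n_in)
  }
  x[idx(dm[1L], target[1L]), idx(dm[2L], target[2L]), idx(dm[3L], target[3L]),
    drop = FALSE]
}

# --- I/O ---------------------------------------------------------------------

#' Read / write OCT volumes as NIfTI with a JSON sidecar
#'
#' Voxels round-trip bit-exactly (double precision); spacing and visit
#' metadata travel in a JSON sidecar next to the NIfTI file. A missing
#' sidecar or missing spacing falls back to defaults and is flagged in the
#' returned volume's `provenance$spacing_defaulted`.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("corrupt or unreadable NIfTI at ",
                                           path, ": ", conditionMessage(e)))
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))  # strip NIfTI attributes
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume at ", path, ", got ",
         length(dim(arr)), "D data")
  side <- sidecar_path(path)
  prov <- list(source = path)
  spacing <- NULL; eye_id <- "eye"; visit_time <- 0
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    spacing <- meta$spacing_um
    eye_id <- meta$eye_id %||% eye_id
    visit_time <- meta$visit_time_months %||% visit_time
    prov <- c(prov, meta[setdiff(names(meta),
                                 c("spacing_um", "eye_id",
                                   "visit_time_months"))])
  }
  if (is.null(spacing)) {
    pd <- attr(img, "pixdim")
    if (!is.null(pd) && length(pd) >= 3 && all(pd[1:3] > 0)) {
      spacing <- pd[1:3] * 1000  # NIfTI mm -> um
    } else {
      spacing <- c(3.4, 11.7, 60)
      prov$spacing_defaulted <- TRUE
    }
  }
  oct_volume(arr, spacing = spacing, eye_id = eye_id,
             visit_time = visit_time, provenance = prov)
}

#' @rdname read_volume
#' @param volume An [oct_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(structure(volume$voxels,
                                   pixdim = volume$spacing / 1000),  # um->mm
                         datatype = "double")
  RNifti::writeNifti(img, path)
  meta <- c(list(spacing_um = volume$spacing, eye_id = volume$eye_id,
                 visit_time_months = volume$visit_time),
            volume$provenance[setdiff(names(volume$provenance), "source")])
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

# --- visit tables ------------------------------------------------------------

#' Read / write per-eye visit tables
#'
#' CSV columns: `eye_id`, `visit_time_months`, `path`, `t_minus_months`,
#' `t_plus_months` (empty when censored). Invariants are validated:
#' non-negative visit times, and `t_minus < t_plus` when both are present.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_visit_table <- function(path) {
  if (!file.exists(path)) stop("no such visit table: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(eye_id = "character"))
  df <- tibble::as_tibble(df)
  required <- c("eye_id", "visit_time_months", "path")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("visit table lacks columns: ", paste(missing, collapse = ", "))
  for (cl in c("t_minus_months", "t_plus_months"))
    if (!cl %in% names(df)) df[[cl]] <- NA_real_
  validate_visit_table(df)
  df
}

validate_visit_table <- function(df) {
  if (any(df$visit_time_months < 0, na.rm = TRUE))
    stop("visit_time_months must be non-negative")
  both <- is.finite(df$t_minus_months) & is.finite(df$t_plus_months)
  bad <- both & !(df$t_minus_months < df$t_plus_months)
  if (any(bad))
    stop("t_minus_months must be strictly below t_plus_months (",
         sum(bad), " offending rows)")
  invisible(df)
}

#' @rdname read_visit_table
#' @param visits A visit tibble.
#' @export
write_visit_table <- function(visits, path) {
  validate_visit_table(visits)
  utils::write.csv(visits, path, row.names = FALSE, na = "")
  invisible(path)
}
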