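# Volume I/O, orientation and landmark-driven cubic VOI extraction.
#
# Axis convention (fixed for the whole package):
#   axis 1 of the array (dim[1]) = proximal -> distal slice order,
#   axis 2 = image vertical,
#   axis 3 = image horizontal, anterior at low index.
# Coordinates are 0-based voxel indices (z, y, x) = (axis1, axis2, axis3),
# matching the landmark-file convention.

#' Construct a voxel volume
#'
#' A `voxel_volume` holds a 3-D grid of intensities (or a binary mask),
#' its isotropic voxel spacing in micrometres, and a side flag.
#'
#' @param data 3-D array (numeric, integer or logical).
#' @param spacing isotropic voxel edge length in micrometres (> 0).
#' @param side `"left"`, `"right"` or `NA`.
#' @param binary logical; if `TRUE` the data must contain exactly two values.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, side = NA_character_, binary = is.logical(data)) {
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  if (any(dim(data) < 2L)) stop("all three dimensions must be >= 2")
  if (!is.numeric(spacing) || length(spacing) != 1L || is.na(spacing) || spacing <= 0)
    stop("spacing must be a single positive number (micrometres)")
  if (!is.na(side) && !side %in% c("left", "right"))
    stop("side must be 'left', 'right' or NA")
  if (isTRUE(binary)) {
    u <- unique(as.vector(data))
    if (length(u) > 2L)
      stop("binary volume must contain exactly two values, found ", length(u))
  }
  structure(list(data = data, spacing = spacing, side = side, binary = isTRUE(binary)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s, spacing %g um, side %s%s\n",
              paste(dim(x$data), collapse = " x "), x$spacing,
              ifelse(is.na(x$side), "?", x$side),
              if (x$binary) ", binary" else ""))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' Read an image stack as a voxel volume
#'
#' Supported inputs: a multi-page TIFF file, a directory of numbered
#' single-slice TIFF files (slice order taken from the number embedded in
#' each file name; gaps in the numbering are an error), or a JSON header of
#' the raw dialect written by [write_volume()].  Slices are assembled in
#' ascending proximodistal order along axis 1.
#'
#' @param path file or directory path.
#' @param spacing_override voxel spacing in micrometres; overrides (or, for
#'   plain TIFF without calibration metadata, supplies) the stored spacing.
#' @param side optional side flag (`"left"`/`"right"`).
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, spacing_override = NULL, side = NA_character_) {
  if (dir.exists(path)) return(read_slice_dir(path, spacing_override, side))
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return(read_tiff_stack(path, spacing_override, side))
  if (ext == "json") return(read_raw_json(path, spacing_override, side))
  if (ext %in% c("dcm", "dicom", "ima"))
    stop("DICOM input is not supported by this build; convert the series to ",
         "a TIFF stack or the raw+JSON dialect")
  stop("unrecognised volume format: ", path)
}

read_tiff_stack <- function(path, spacing_override, side) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  spacing <- spacing_override
  if (is.null(spacing) || is.na(spacing))
    stop("TIFF carries no spacing calibration; pass spacing_override (um)")
  arr <- simplify2array(lapply(pages, function(p) round(p * 65535)))
  # pages arrive as (y, x, slice); reorder to (slice, y, x)
  arr <- aperm(arr, c(3L, 1L, 2L))
  voxel_volume(arr, spacing, side, binary = FALSE)
}

read_slice_dir <- function(path, spacing_override, side) {
  files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE)
  if (!length(files)) stop("no TIFF slices found in ", path)
  nums <- suppressWarnings(as.integer(sub("^.*?(\\d+)\\.[Tt][Ii][Ff][Ff]?$", "\\1", files)))
  if (anyNA(nums)) stop("slice file names must embed a slice number: ",
                        paste(files[is.na(nums)], collapse = ", "))
  o <- order(nums)
  files <- files[o]; nums <- nums[o]
  expected <- seq(nums[1L], nums[length(nums)])
  missing <- setdiff(expected, nums)
  if (length(missing))
    stop("missing slice index(es): ", paste(missing, collapse = ", "))
  slices <- lapply(file.path(path, files), function(f) round(tiff::readTIFF(f) * 65535))
  arr <- aperm(simplify2array(slices), c(3L, 1L, 2L))
  if (is.null(spacing_override))
    stop("slice directories carry no spacing calibration; pass spacing_override (um)")
  voxel_volume(arr, spacing_override, side, binary = FALSE)
}

read_raw_json <- function(path, spacing_override, side) {
  hdr <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("shape", "spacing_um", "dtype", "data_file")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("raw header missing field(s): ", paste(miss, collapse = ", "))
  if (length(hdr$spacing_um) > 1L && length(unique(hdr$spacing_um)) > 1L)
    stop("anisotropic spacing in header; cubic voxels are required")
  sz <- switch(hdr$dtype, uint8 = 1L, uint16 = 2L,
               stop("unsupported dtype: ", hdr$dtype))
  datafile <- file.path(dirname(path), hdr$data_file)
  nvox <- prod(hdr$shape)
  raw <- readBin(datafile, "integer", n = nvox, size = sz, signed = FALSE,
                 endian = "little")
  if (length(raw) != nvox) stop("raw data truncated: expected ", nvox,
                                " voxels, got ", length(raw))
  arr <- array(raw, dim = hdr$shape)
  spacing <- if (!is.null(spacing_override)) spacing_override else unique(hdr$spacing_um)
  sd_side <- if (!is.na(side)) side else if (!is.null(hdr$side)) hdr$side else NA_character_
  voxel_volume(arr, spacing, sd_side, binary = FALSE)
}

#' Write a voxel volume
#'
#' Writes either a multi-page TIFF (16-bit; carries no spacing metadata, so
#' reading it back needs `spacing_override`) or the raw uint16 + JSON header
#' dialect (self-describing), chosen from the file extension
#' (`.tif`/`.tiff` vs `.json`).  Round-trips through [read_volume()] are
#' bit-exact for integer data in 0..65535.
#'
#' @param vol a [voxel_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  ext <- tolower(tools::file_ext(path))
  dat <- vol$data
  storage.mode(dat) <- "integer"
  if (any(dat < 0L | dat > 65535L)) stop("intensities must lie in 0..65535")
  if (ext %in% c("tif", "tiff")) {
    # plain TIFF carries no calibration metadata; spacing must be supplied
    # again on read (the raw+JSON dialect is the calibrated format)
    pages <- lapply(seq_len(dim(dat)[1L]), function(i) dat[i, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else if (ext == "json") {
    datafile <- sub("\\.json$", ".raw", path)
    writeBin(as.integer(as.vector(dat)), datafile, size = 2L, endian = "little")
    jsonlite::write_json(list(shape = dim(dat), spacing_um = vol$spacing,
                              dtype = "uint16", axes = "z-proximodistal,y,x-anterior-low",
                              side = vol$side, data_file = basename(datafile)),
                         path, auto_unbox = TRUE, digits = NA)
  } else stop("unrecognised output format: ", path)
  invisible(path)
}

#' Mirror a left-side bone to right-side orientation
#'
#' Reverses the horizontal image axis so that left bones become comparable
#' with right bones.  Double mirroring is a silent bug, so volumes already
#' flagged `right` are rejected.
#'
#' @param vol a [voxel_volume()] with `side == "left"`.
#' @param axis array axis to reverse (default 3, the horizontal image axis).
#' @return The mirrored volume, with `side` set to `"right"`.
#' @export
mirror_left_bone <- function(vol, axis = 3L) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (is.na(vol$side)) stop("volume has no side flag; refusing to mirror")
  if (vol$side == "right") stop("volume is already right-sided; mirroring again would double-mirror")
  d <- dim(vol$data)
  idx <- lapply(seq_along(d), function(a) if (a == axis) rev(seq_len(d[a])) else seq_len(d[a]))
  vol$data <- do.call(`[`, c(list(vol$data), idx, list(drop = FALSE)))
  vol$side <- "right"
  vol
}

# ---------------------------------------------------------------------------
# Landmarks

.landmark_sets <- list(
  humeral_head = c("proximal_most", "distal_most", "anterolateral_corner",
                   "medial_most", "posterior_most"),
  humeral_trochlea = c("proximal_most", "distal_most", "anterolateral_corner",
                       "anteromedial_corner", "posterior_most"),
  femoral_head = c("proximal_most", "distal_most", "anterior_border",
                   "medial_border", "posterior_border", "lateral_concavity"),
  femoral_lateral_condyle = c("proximal_most", "distal_most", "anterior_patellar",
                              "posterior_articular", "medial_notch", "lateral_most")
)

#' Required landmark names per articular structure
#' @param structure one of `"humeral_head"`, `"humeral_trochlea"`,
#'   `"femoral_head"`, `"femoral_lateral_condyle"`.
#' @return Character vector of required landmark names.
#' @export
required_landmarks <- function(structure) {
  if (!structure %in% names(.landmark_sets))
    stop("unknown structure: ", structure)
  .landmark_sets[[structure]]
}

#' Construct (and validate) an anatomical landmark set
#'
#' @param structure articular structure name (see [required_landmarks()]).
#' @param landmarks named list of 0-based voxel coordinates `c(z, y, x)`.
#' @param vol_dim optional volume dimensions; when given, coordinates are
#'   checked to lie inside the volume.
#' @return An object of class `anatomical_landmarks`.
#' @export
anatomical_landmarks <- function(structure, landmarks, vol_dim = NULL) {
  req <- required_landmarks(structure)
  miss <- setdiff(req, names(landmarks))
  if (length(miss))
    stop("missing landmark(s) for ", structure, ": ", paste(miss, collapse = ", "))
  for (nm in names(landmarks)) {
    p <- landmarks[[nm]]
    if (length(p) != 3L || anyNA(p)) stop("landmark '", nm, "' must be c(z, y, x)")
    if (!is.null(vol_dim) && (any(p < 0) || any(p > vol_dim - 1L)))
      stop("landmark '", nm, "' lies outside the volume")
  }
  structure(list(structure = structure, landmarks = landmarks),
            class = "anatomical_landmarks")
}

#' Read a landmark file (JSON)
#'
#' Expected keys: `structure`, optional `side`, and `landmarks` mapping each
#' landmark name to a `[z, y, x]` voxel coordinate.
#'
#' @param path JSON file path.
#' @param vol_dim optional volume dimensions for bounds checking.
#' @return An [anatomical_landmarks()] object.
#' @export
read_landmarks <- function(path, vol_dim = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$structure) || is.null(j$landmarks))
    stop("landmark file must contain 'structure' and 'landmarks'")
  lm <- lapply(j$landmarks, as.numeric)
  anatomical_landmarks(j$structure, lm, vol_dim)
}

round_half_down <- function(x) ceiling(x - 0.5)

#' Locate the centre of a cubic VOI from landmarks
#'
#' The slice index is the midpoint of the proximal-most and distal-most
#' landmark slices; the in-slice position is the midpoint of the bounding box
#' of the structure's in-slice landmarks.  Midpoints falling on .5 are
#' rounded down (fixed for determinism).
#'
#' @param landmarks an [anatomical_landmarks()] object.
#' @return Integer voxel coordinate `c(z, y, x)`, 0-based.
#' @export
locate_voi_centre <- function(landmarks) {
  stopifnot(inherits(landmarks, "anatomical_landmarks"))
  lm <- landmarks$landmarks
  zp <- lm[["proximal_most"]][1L]
  zd <- lm[["distal_most"]][1L]
  if (zp == zd) stop("proximal-most and distal-most landmarks collapse to a single slice")
  zc <- round_half_down((zp + zd) / 2)
  inplane <- do.call(rbind, lapply(lm, function(p) p[2:3]))
  yc <- round_half_down((min(inplane[, 1L]) + max(inplane[, 1L])) / 2)
  xc <- round_half_down((min(inplane[, 2L]) + max(inplane[, 2L])) / 2)
  c(z = zc, y = yc, x = xc)
}

#' Extract a cubic VOI centred on a voxel
#'
#' When a trabecular-compartment mask is given, the cube is grown
#' symmetrically around the centre to the largest odd edge that stays
#' entirely inside the mask ("as big as possible without including cortical
#' bone"); otherwise a fixed odd edge is used.  Edges below 16 voxels mark
#' the VOI as unusable and raise an error.
#'
#' @param vol parent [voxel_volume()].
#' @param centre 0-based voxel coordinate `c(z, y, x)`.
#' @param mask optional binary [voxel_volume()] (or logical array) marking
#'   the trabecular compartment.
#' @param edge optional fixed cube edge in voxels (odd).
#' @param min_edge minimum usable edge (default 16 voxels).
#' @return List with elements `voi` (the cropped [voxel_volume()]) and
#'   `selection` (centre, edge, provenance).
#' @export
extract_cubic_voi <- function(vol, centre, mask = NULL, edge = NULL, min_edge = 16L) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$data)
  centre <- as.integer(round(centre))
  if (any(centre < 0L) || any(centre > d - 1L)) stop("centre lies outside the volume")
  if (is.null(mask) && is.null(edge)) stop("either mask or edge must be given")

  mdat <- NULL
  if (!is.null(mask)) {
    mdat <- if (inherits(mask, "voxel_volume")) mask$data else mask
    if (!identical(dim(mdat), d)) stop("mask dimensions do not match the volume")
    mdat <- mdat != 0
    if (!mdat[centre[1L] + 1L, centre[2L] + 1L, centre[3L] + 1L])
      stop("centre does not lie inside the trabecular mask")
  }

  if (is.null(edge)) {
    # symmetric growth: half-edge h gives edge 2h+1; stop at the first shell
    # that protrudes from the mask or the volume
    hmax <- min(c(centre, d - 1L - centre))
    h <- 0L
    while (h < hmax) {
      hn <- h + 1L
      zr <- (centre[1L] - hn):(centre[1L] + hn) + 1L
      yr <- (centre[2L] - hn):(centre[2L] + hn) + 1L
      xr <- (centre[3L] - hn):(centre[3L] + hn) + 1L
      block <- mdat[zr, yr, xr]
      if (any(!block)) break
      h <- hn
    }
    edge <- 2L * h + 1L
  } else {
    edge <- as.integer(edge)
    if (edge %% 2L == 0L) stop("edge must be odd (cube is centred on a voxel)")
    h <- (edge - 1L) %/% 2L
    if (any(centre - h < 0L) || any(centre + h > d - 1L))
      stop("cube of edge ", edge, " does not fit inside the volume at this centre")
    if (!is.null(mdat)) {
      zr <- (centre[1L] - h):(centre[1L] + h) + 1L
      yr <- (centre[2L] - h):(centre[2L] + h) + 1L
      xr <- (centre[3L] - h):(centre[3L] + h) + 1L
      if (any(!mdat[zr, yr, xr])) stop("fixed-edge cube protrudes from the mask")
    }
  }
  if (edge < min_edge)
    stop("VOI unusable: largest centred cube has edge ", edge, " < ", min_edge,
         " voxels (too few trabeculae)")

  h <- (edge - 1L) %/% 2L
  sub <- vol$data[(centre[1L] - h):(centre[1L] + h) + 1L,
                  (centre[2L] - h):(centre[2L] + h) + 1L,
                  (centre[3L] - h):(centre[3L] + h) + 1L, drop = FALSE]
  voi <- voxel_volume(sub, vol$spacing, vol$side, binary = vol$binary)
  list(voi = voi,
       selection = structure(list(centre = centre, edge = edge,
                                  provenance = sprintf("centre=%s edge=%d",
                                                       paste(centre, collapse = ","), edge)),
                             class = "voi_selection"))
}
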