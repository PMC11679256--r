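#' Labeled segmentation volume
#'
#' Container for a 3D integer label grid plus the 4x4 affine mapping 0-based
#' voxel indices (homogeneous coordinate 1) to RAS mm. Label 0 is background.
#'
#' @param labels 3D integer array of non-negative label codes.
#' @param affine 4x4 numeric matrix; its 3x3 block must be invertible.
#' @return Object of class `labeled_volume` with fields `labels`, `affine`
#'   and `voxel_volume` (mm^3, `abs(det)` of the 3x3 block).
#' @export
new_labeled_volume <- function(labels, affine) {
  stopifnot(length(dim(labels)) == 3, is.matrix(affine),
            all(dim(affine) == c(4, 4)))
  if (!is.integer(labels)) {
    if (max(abs(labels - round(labels))) > 1e-6)
      stop("labels must be integer-valued")
    labels <- array(as.integer(round(labels)), dim = dim(labels))
  }
  if (any(labels < 0)) stop("labels must be non-negative")
  d <- det(affine[1:3, 1:3])
  if (abs(d) < 1e-12) stop("singular affine")
  structure(list(labels = labels, affine = affine, voxel_volume = abs(d)),
            class = "labeled_volume")
}

#' @exportS3Method print labeled_volume
print.labeled_volume <- function(x, ...) {
  fg <- sum(x$labels != 0L)
  cat("Labeled volume:", paste(dim(x$labels), collapse = " x "),
      sprintf("voxels (%.3g mm^3 each), %d foreground, %d labels\n",
              x$voxel_volume, fg, length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Read a labeled volume from NIfTI
#'
#' Values must be integer within a tolerance of 1e-6; the affine (sform/qform
#' as resolved by RNifti) must be invertible. Round-trips losslessly with
#' [write_labeled_volume()].
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A `labeled_volume`.
#' @export
read_labeled_volume <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4, 4))
  new_labeled_volume(array(as.vector(img), dim = dim(img)), affine)
}

#' Write a labeled volume to NIfTI
#'
#' @param volume A `labeled_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_labeled_volume <- function(volume, path) {
  stopifnot(inherits(volume, "labeled_volume"))
  img <- RNifti::asNifti(volume$labels)
  aff <- structure(volume$affine, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  dtype <- if (max(volume$labels) > 32767L) "int32" else "int16"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Parse a FreeSurfer-style aseg.stats file
#'
#' Accepts the `aseg.stats` dialect: `#`-prefixed header lines followed by a
#' whitespace-delimited table whose first five columns are Index, SegId,
#' NVoxels, Volume_mm3 and StructName (further columns are ignored).
#'
#' @param path Path to the stats file.
#' @return data.frame with columns `seg_id`, `n_voxels`, `volume_mm3`,
#'   `struct_name` - one row per table row.
#' @export
parse_aseg_stats <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(rows) == 0) stop("empty file (no table rows): ", path)
  parts <- strsplit(trimws(rows), "\\s+")
  parse_row <- function(p) {
    if (length(p) < 5) stop("malformed aseg.stats row: ", paste(p, collapse = " "))
    seg <- suppressWarnings(as.integer(p[2]))
    nv <- suppressWarnings(as.numeric(p[3]))
    vol <- suppressWarnings(as.numeric(p[4]))
    if (is.na(seg) || is.na(nv) || is.na(vol))
      stop("malformed aseg.stats row (non-numeric field): ",
           paste(p, collapse = " "))
    data.frame(seg_id = seg, n_voxels = nv, volume_mm3 = vol,
               struct_name = p[5], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(parts, parse_row))
  if (any(out$n_voxels < 0) || any(out$volume_mm3 < 0))
    stop("malformed aseg.stats row: negative count or volume")
  out
}

#' Write a synthetic aseg.stats summary for a labeled volume
#'
#' Fixture writer: voxel counts and volumes (`n * voxel_volume`) for every
#' registry label present in the volume, in the `aseg.stats` text dialect.
#'
#' @param volume A `labeled_volume`.
#' @param path Output path.
#' @param registry A [structure_registry()].
#' @return `path`, invisibly.
#' @export
write_aseg_stats <- function(volume, path, registry = structure_registry()) {
  lab <- volume$labels
  hdr <- c("# Title Segmentation Statistics (synthetic)",
           "# ColHeaders Index SegId NVoxels Volume_mm3 StructName")
  rows <- character(); i <- 0
  for (nm in names(registry)) {
    for (code in registry[[nm]]) {
      n <- sum(lab == code)
      if (n == 0) next
      i <- i + 1
      rows <- c(rows, sprintf("%3d %4d %8d %12.1f %s",
                              i, code, n, n * volume$voxel_volume, nm))
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Quality-control a cohort manifest
#'
#' Applies the study's exclusion logic: a subject is excluded when its
#' segmentation product is missing, empty (zero bytes, a stats table with no
#' rows, or a label volume with no foreground voxels) or lacks a registry
#' structure. Pure bookkeeping: the decision is made from the per-subject
#' `artifacts` table, which either is supplied directly or is built by
#' [qc_scan_dir()].
#'
#' @param manifest data.frame with at least `subject_id` (unique).
#' @param artifacts data.frame with columns `subject_id`, `file_exists`
#'   (logical), `file_empty` (logical) and `missing_structures` (character;
#'   comma-separated names or `""`).
#' @return A list with `reports` (subject_id, status `pass`/`excluded`,
#'   reasons) and `retained` (the manifest rows that pass, original order).
#' @export
qc_cohort <- function(manifest, artifacts) {
  if (anyDuplicated(manifest$subject_id))
    stop("manifest rows must be unique by subject_id")
  a <- artifacts[match(manifest$subject_id, artifacts$subject_id), ]
  reasons <- vapply(seq_len(nrow(manifest)), function(i) {
    r <- character()
    if (is.na(a$file_exists[i]) || !a$file_exists[i]) r <- c(r, "missing file")
    else {
      if (isTRUE(a$file_empty[i])) r <- c(r, "empty file")
      ms <- a$missing_structures[i]
      if (!is.na(ms) && nzchar(ms))
        r <- c(r, paste("missing structure:", ms))
    }
    paste(r, collapse = "; ")
  }, character(1))
  status <- ifelse(nzchar(reasons), "excluded", "pass")
  reports <- data.frame(subject_id = manifest$subject_id, status = status,
                        reasons = reasons, stringsAsFactors = FALSE)
  list(reports = reports, retained = manifest[status == "pass", , drop = FALSE])
}

#' Scan a data directory and build the QC artifact table
#'
#' Looks for `<subject_id>.nii` / `.nii.gz` under `dir`, checks emptiness
#' (no foreground voxels) and registry completeness, then delegates to
#' [qc_cohort()]. Unknown label codes found in a volume are ignored with a
#' warning.
#'
#' @param manifest data.frame with `subject_id`.
#' @param dir Directory containing per-subject volumes.
#' @param registry A [structure_registry()].
#' @return As [qc_cohort()].
#' @export
qc_scan_dir <- function(manifest, dir, registry = structure_registry()) {
  known <- unlist(registry, use.names = FALSE)
  rows <- lapply(manifest$subject_id, function(sid) {
    cand <- file.path(dir, paste0(sid, c(".nii.gz", ".nii")))
    path <- cand[file.exists(cand)][1]
    if (is.na(path))
      return(data.frame(subject_id = sid, file_exists = FALSE,
                        file_empty = NA, missing_structures = NA_character_))
    v <- read_labeled_volume(path)
    present <- setdiff(unique(as.vector(v$labels)), 0L)
    unknown <- setdiff(present, known)
    if (length(unknown))
      warning("subject ", sid, ": ignoring unknown label codes ",
              paste(unknown, collapse = ", "))
    missing <- names(registry)[!vapply(registry, function(codes)
      any(codes %in% present), logical(1))]
    data.frame(subject_id = sid, file_exists = TRUE,
               file_empty = length(present) == 0,
               missing_structures = paste(missing, collapse = ","),
               stringsAsFactors = FALSE)
  })
  qc_cohort(manifest, do.call(rbind, rows))
}
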