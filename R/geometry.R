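#' Map a voxel index to RAS coordinates
#'
#' Applies the volume's affine to a 0-based voxel-center index with
#' homogeneous coordinate 1.
#'
#' @param volume A `labeled_volume`.
#' @param index Length-3 integer voxel index, 0-based.
#' @return Length-3 numeric RAS position (mm).
#' @export
voxel_to_ras <- function(volume, index) {
  stopifnot(length(index) == 3)
  if (any(index < 0) || any(index > dim(volume$labels) - 1L))
    stop("index out of bounds")
  as.vector(volume$affine %*% c(index, 1))[1:3]
}

#' Minkowski distance between two points
#'
#' `(sum |a_i - b_i|^p)^(1/p)`; `p = 2` is the Euclidean distance and
#' `p = 1` the Manhattan distance.
#'
#' @param a,b Numeric vectors of equal length.
#' @param p Order, `>= 1`.
#' @return Non-negative distance (mm when inputs are in mm).
#' @export
minkowski_distance <- function(a, b, p = 2) {
  if (p < 1) stop("p must be >= 1")
  stopifnot(length(a) == length(b))
  if (is.infinite(p)) return(max(abs(a - b)))
  sum(abs(a - b)^p)^(1 / p)
}

#' @rdname minkowski_distance
#' @export
euclidean_distance <- function(a, b) minkowski_distance(a, b, 2)

#' Cosine distance between two vectors
#'
#' `1 - (a . b) / (||a|| ||b||)`: orientation only, invariant to positive
#' rescaling of either argument. Ranges from 0 (identical direction) to 2
#' (diametrically opposed); the result is clamped to `[0, 2]` against
#' rounding, and exactly equal or exactly antipodal inputs return the exact
#' endpoint.
#'
#' @param a,b Numeric vectors of equal length, neither with zero norm.
#' @return Unitless distance in `[0, 2]`.
#' @export
cosine_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine distance undefined for zero-norm input")
  if (all(a == b)) return(0)
  if (all(a == -b)) return(2)
  d <- 1 - sum(a * b) / (na * nb)
  min(max(d, 0), 2)
}

#' Measure one structure in a labeled volume
#'
#' Pools the voxels carrying any of the structure's label codes (merged
#' labels form a single point cloud), converts their 0-based indices to RAS
#' voxel-center coordinates, and returns the unweighted centroid together
#' with the voxel-count volume.
#'
#' @param volume A `labeled_volume`.
#' @param name Structure name.
#' @param registry A [structure_registry()].
#' @return List with `name`, `n_voxels`, `volume_mm3` and `centroid`
#'   (length-3 RAS mm).
#' @export
measure_structure <- function(volume, name, registry = structure_registry()) {
  if (!name %in% names(registry)) stop("structure not in registry: ", name)
  codes <- registry[[name]]
  hit <- which(array(volume$labels %in% codes, dim = dim(volume$labels)),
               arr.ind = TRUE)
  if (nrow(hit) == 0)
    stop("missing structure: ", name, " (0 voxels)")
  idx0 <- hit - 1  # 0-based voxel indices
  ras <- idx0 %*% t(volume$affine[1:3, 1:3]) +
    matrix(volume$affine[1:3, 4], nrow(idx0), 3, byrow = TRUE)
  list(name = name, n_voxels = nrow(hit),
       volume_mm3 = nrow(hit) * volume$voxel_volume,
       centroid = colMeans(ras))
}

#' Extract the per-subject feature vector
#'
#' For every non-reference structure: volume normalized by the subject's
#' (bilateral) thalamus volume, the Euclidean distance between the structure
#' centroid and the thalamus centroid, and the cosine distance between the
#' two centroids taken as position vectors from `origin` (default the native
#' RAS origin; the cosine metric is origin-dependent and the origin is
#' therefore configurable).
#'
#' @param volume A `labeled_volume` containing all registry structures.
#' @param registry A [structure_registry()].
#' @param demographics List or one-row data.frame with `subject_id`, `group`,
#'   `sex` (M = 0, F = 1) and `age`.
#' @param origin Length-3 RAS origin for the cosine position vectors.
#' @return One-row data.frame: `subject_id`, `group`, then the feature
#'   columns of [feature_column_names()].
#' @export
extract_subject_features <- function(volume, registry = structure_registry(),
                                     demographics, origin = c(0, 0, 0)) {
  ref <- attr(registry, "reference")
  geo <- lapply(names(registry), function(nm)
    measure_structure(volume, nm, registry))
  names(geo) <- names(registry)
  tvol <- geo[[ref]]$volume_mm3
  if (tvol == 0) stop("reference (thalamus) volume is zero")
  tctr <- geo[[ref]]$centroid - origin
  out <- list()
  out[[paste0(ref, "_vol")]] <- tvol
  for (nm in non_reference_structures(registry)) {
    g <- geo[[nm]]
    ctr <- g$centroid - origin
    out[[paste0(nm, "_normvol")]] <- g$volume_mm3 / tvol
    out[[paste0(nm, "_euclid")]] <- euclidean_distance(g$centroid,
                                                       geo[[ref]]$centroid)
    out[[paste0(nm, "_cosine")]] <- cosine_distance(ctr, tctr)
  }
  out$Sex <- demographics$sex
  out$Age <- demographics$age
  data.frame(subject_id = demographics$subject_id,
             group = demographics$group,
             out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Assemble the cohort feature table
#'
#' Binds per-subject feature rows into the fixed-order feature table:
#' `subject_id`, `group`, then 57 feature columns for the default registry
#' (thalamus volume, three features per remaining structure, sex, age).
#'
#' @param rows List of one-row data.frames from [extract_subject_features()],
#'   or a data.frame already containing all feature columns.
#' @param registry A [structure_registry()].
#' @return data.frame with `nrow = n subjects` and exactly
#'   `length(feature_column_names(registry))` feature columns plus
#'   `subject_id` and `group`.
#' @export
assemble_feature_table <- function(rows, registry = structure_registry()) {
  if (is.data.frame(rows)) rows <- list(rows)
  if (length(rows) == 0) stop("empty cohort: no subjects to assemble")
  cols <- feature_column_names(registry)
  tab <- do.call(rbind, lapply(rows, function(r) {
    missing <- setdiff(cols, names(r))
    if (length(missing))
      stop("inconsistent feature sets: missing ",
           paste(missing, collapse = ", "))
    r[, c("subject_id", "group", cols), drop = FALSE]
  }))
  if (anyNA(tab[, cols])) stop("feature table contains missing values")
  rownames(tab) <- NULL
  tab
}
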