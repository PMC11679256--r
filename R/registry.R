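#' Subcortical structure registry
#'
#' The fixed set of 19 deep brain structures used throughout the pipeline,
#' mapped to their FreeSurfer `aseg` label codes. Bilateral thalamus
#' (labels 10 + 49) and each cerebellar hemisphere (cortex + white matter,
#' 7 + 8 and 46 + 47) are merged structures: their label codes are pooled
#' into a single voxel cloud before any measurement. The thalamus is the
#' designated reference structure for volume normalization and for both
#' centroid distance metrics.
#'
#' @param reference Name of the reference structure. Must be present in the
#'   registry. Default `"Thalamus"`.
#' @return An object of class `structure_registry`: a named list of integer
#'   label-code vectors, ordered, with attribute `reference`.
#' @examples
#' reg <- structure_registry()
#' length(reg)               # 19
#' reg[["Thalamus"]]         # c(10, 49)
#' attr(reg, "reference")
#' @export
structure_registry <- function(reference = "Thalamus") {
  reg <- list(
    "Thalamus"          = c(10L, 49L),
    "Left-Hippocampus"  = 17L,
    "Right-Hippocampus" = 53L,
    "Left-Amygdala"     = 18L,
    "Right-Amygdala"    = 54L,
    "Left-Caudate"      = 11L,
    "Right-Caudate"     = 50L,
    "Left-Putamen"      = 12L,
    "Right-Putamen"     = 51L,
    "Left-Pallidum"     = 13L,
    "Right-Pallidum"    = 52L,
    "Left-Accumbens"    = 26L,
    "Right-Accumbens"   = 58L,
    "Left-VentralDC"    = 28L,
    "Right-VentralDC"   = 60L,
    "4th-Ventricle"     = 15L,
    "Left-Cerebellum"   = c(7L, 8L),
    "Right-Cerebellum"  = c(46L, 47L),
    "CSF"               = 24L
  )
  codes <- unlist(reg, use.names = FALSE)
  if (anyDuplicated(codes))
    stop("label sets must be pairwise disjoint")
  if (!reference %in% names(reg))
    stop("reference structure '", reference, "' not in registry")
  structure(reg, reference = reference, class = "structure_registry")
}

#' @exportS3Method print structure_registry
print.structure_registry <- function(x, ...) {
  cat("Structure registry:", length(x), "structures; reference:",
      attr(x, "reference"), "\n")
  for (nm in names(x))
    cat(sprintf("  %-18s labels %s\n", nm, paste(x[[nm]], collapse = "+")))
  invisible(x)
}

# Non-reference structures in registry order (feature column order).
non_reference_structures <- function(registry) {
  setdiff(names(registry), attr(registry, "reference"))
}

#' Feature column names of the assembled table
#'
#' Deterministic order: raw thalamus volume, then for each non-reference
#' structure (registry order) its thalamus-normalized volume, Euclidean
#' distance and cosine distance, then `Sex` and `Age` - 57 columns in total
#' for the default registry.
#'
#' @param registry A [structure_registry()].
#' @return Character vector of feature column names.
#' @export
feature_column_names <- function(registry = structure_registry()) {
  others <- non_reference_structures(registry)
  c(paste0(attr(registry, "reference"), "_vol"),
    as.vector(t(outer(others, c("_normvol", "_euclid", "_cosine"), paste0))),
    "Sex", "Age")
}
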