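#' Cohort generator configuration
#'
#' Describes a synthetic three-group cohort with the statistical structure the
#' downstream analysis assumes. Two generators consume it:
#' [generate_phantom_cohort()] (labeled 3D volumes, slow) and
#' [generate_feature_cohort()] (parametric feature tables, fast).
#'
#' @param n_per_group Subjects per group (default 56, the study size).
#' @param groups Ordered group names; default
#'   `c("CONTROL", "PRODROMAL", "PARKINSON")`.
#' @param voxel_size Isotropic voxel edge in mm (default 1).
#' @param template_scale Global scale applied to the canonical template
#'   (centers and radii) and the phantom grid; `< 1` gives reduced grids for
#'   fast tests. Distances scale linearly, volumes cubically; volume ratios
#'   are preserved.
#' @param jitter_sd Per-subject, per-structure centroid jitter (mm at
#'   template scale 1, normal sd); scales with `template_scale` so reduced
#'   phantoms keep the same relative variability.
#' @param volume_cv Per-subject, per-structure volume coefficient of variation
#'   (multiplicative normal noise on volume).
#' @param effects Phantom-mode effect list: each element a list/row with
#'   `structure`, `group`, `volume_scale` (default 1) and `centroid_shift`
#'   (3-vector mm, default 0). See [effect_spec()].
#' @param feature_effects Fast-mode effect table: data.frame with columns
#'   `column` (feature column name), `group`, `d` (standardized mean shift in
#'   within-group sd units). `NULL` = null cohort;
#'   [default_feature_effects()] encodes the group pattern the pipeline is
#'   designed to detect.
#' @param age_mean,age_sd Per-group age model (years), recycled to the number
#'   of groups. Ages are truncated to `[40, 90]`.
#' @param female_prop Per-group female proportion.
#' @param updrs3 Also generate a per-group UPDRS3 motor score column
#'   (truncated at 0; not part of the 57 ML features).
#' @param updrs3_mean,updrs3_sd Per-group UPDRS3 model.
#' @param registry A [structure_registry()].
#' @param seed Integer seed; every draw the generators make derives from it.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_per_group = 56,
                          groups = c("CONTROL", "PRODROMAL", "PARKINSON"),
                          voxel_size = 1,
                          template_scale = 1.25,
                          jitter_sd = 0.6,
                          volume_cv = 0.05,
                          effects = NULL,
                          feature_effects = NULL,
                          age_mean = c(61.5, 66.3, 61.8),
                          age_sd = c(11.5, 6.2, 11.0),
                          female_prop = c(0.321, 0.250, 0.429),
                          updrs3 = FALSE,
                          updrs3_mean = c(0.79, 4.86, 23.89),
                          updrs3_sd = c(1.67, 5.91, 11.47),
                          registry = structure_registry(),
                          seed = 1L) {
  stopifnot(length(groups) >= 2, !anyDuplicated(groups))
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (volume_cv < 0) stop("volume_cv must be >= 0")
  if (voxel_size <= 0 || template_scale <= 0)
    stop("voxel_size and template_scale must be positive")
  g <- length(groups)
  cfg <- list(
    n_per_group = as.integer(n_per_group), groups = groups,
    voxel_size = voxel_size, template_scale = template_scale,
    jitter_sd = jitter_sd, volume_cv = volume_cv,
    effects = validate_effects(effects, groups, registry),
    feature_effects = validate_feature_effects(feature_effects, groups, registry),
    age_mean = rep_len(age_mean, g), age_sd = rep_len(age_sd, g),
    female_prop = rep_len(female_prop, g),
    updrs3 = isTRUE(updrs3),
    updrs3_mean = rep_len(updrs3_mean, g), updrs3_sd = rep_len(updrs3_sd, g),
    registry = registry, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Phantom-mode effect specification
#'
#' A group-level intervention on one structure: a multiplicative volume change
#' and/or a centroid displacement, applied to every subject of the group.
#' Volume scaling is applied to the ellipsoid radii as `volume_scale^(1/3)`
#' per axis so the expected measured volume scales exactly by `volume_scale`.
#'
#' @param structure Structure name (must exist in the registry).
#' @param group Group name the effect applies to.
#' @param volume_scale Positive multiplier; 1 = no effect.
#' @param centroid_shift Length-3 displacement in RAS mm.
#' @return A list usable in the `effects` argument of [cohort_config()].
#' @export
effect_spec <- function(structure, group, volume_scale = 1,
                        centroid_shift = c(0, 0, 0)) {
  if (volume_scale <= 0) stop("volume_scale must be > 0")
  stopifnot(length(centroid_shift) == 3)
  list(structure = structure, group = group,
       volume_scale = volume_scale, centroid_shift = as.numeric(centroid_shift))
}

validate_effects <- function(effects, groups, registry) {
  if (is.null(effects)) return(list())
  if (!is.null(effects$structure)) effects <- list(effects)  # single spec
  for (e in effects) {
    if (!e$structure %in% names(registry))
      stop("effect references unknown structure: ", e$structure)
    if (!e$group %in% groups)
      stop("effect references unknown group: ", e$group)
    if (e$volume_scale <= 0) stop("volume_scale must be > 0")
  }
  effects
}

validate_feature_effects <- function(fe, groups, registry) {
  if (is.null(fe)) return(NULL)
  stopifnot(is.data.frame(fe), all(c("column", "group", "d") %in% names(fe)))
  cols <- feature_column_names(registry)
  bad <- setdiff(fe$column, cols)
  if (length(bad))
    stop("feature effect references unknown feature column: ",
         paste(bad, collapse = ", "))
  if (!all(fe$group %in% groups)) stop("feature effect references unknown group")
  fe
}

# Canonical phantom template: one axis-aligned ellipsoid per label code, at
# atlas-plausible RAS offsets. Radii give volumes whose ratios (to the
# bilateral thalamus) and whose thalamus-referenced centroid distances sit in
# the ranges the interpretable rule thresholds imply (left amygdala normvol
# ~0.11, hippocampus ~31 mm, right cerebellum ~58 mm). Absolute volumes are
# uniformly shrunk relative to adult anatomy so that structures stay disjoint
# under default jitter; only relative magnitudes carry meaning downstream.
phantom_template <- function(scale = 1) {
  t <- read.table(header = TRUE, text = "
structure label cx cy cz rx ry rz
Thalamus 10 -11 -19 8 8.4 11.6 9.4
Thalamus 49 11 -19 8 8.4 11.6 9.4
Left-Hippocampus 17 -26 -35 -8 9.6 6.8 8.0
Right-Hippocampus 53 26 -35 -8 9.6 6.8 8.0
Left-Amygdala 18 -25 -3 -16 6.4 5.2 5.7
Right-Amygdala 54 25 -3 -16 6.4 5.2 5.7
Left-Caudate 11 -13 8 12 5.6 12.0 6.4
Right-Caudate 50 13 8 12 5.6 12.0 6.4
Left-Putamen 12 -30 -2 3 6.4 11.6 8.2
Right-Putamen 51 30 -2 3 6.4 11.6 8.2
Left-Pallidum 13 -17 -3 1 5.2 6.8 5.8
Right-Pallidum 52 17 -3 1 5.2 6.8 5.8
Left-Accumbens 26 -9 12 -7 6.4 7.2 5.0
Right-Accumbens 58 9 12 -7 6.4 7.2 5.0
Left-VentralDC 28 -11 -13 -15 7.2 9.0 7.2
Right-VentralDC 60 11 -13 -15 7.2 9.0 7.2
4th-Ventricle 15 0 -45 -25 4.8 8.4 5.4
Left-Cerebellum 7 -24 -56 -36 12.8 11.2 9.6
Left-Cerebellum 8 -11 -42 -28 4.8 5.6 4.4
Right-Cerebellum 46 24 -56 -36 12.8 11.2 9.6
Right-Cerebellum 47 11 -42 -28 4.8 5.6 4.4
CSF 24 0 8 2 4.4 7.2 5.8
")
  t[c("cx", "cy", "cz")] <- t[c("cx", "cy", "cz")] * scale
  # packing factor: shrinks all radii uniformly so neighbouring structures
  # stay disjoint under default jitter and moderate volume effects; volume
  # ratios and centroid distances are unaffected
  t[c("rx", "ry", "rz")] <- t[c("rx", "ry", "rz")] * 0.8 * scale
  t
}

# Grid and affine sized to contain the (scaled) template with margin.
phantom_grid <- function(scale = 1, voxel_size = 1, margin = 6) {
  tpl <- phantom_template(scale)
  lo <- c(min(tpl$cx - tpl$rx), min(tpl$cy - tpl$ry), min(tpl$cz - tpl$rz)) -
    margin * scale
  lo <- floor(lo)  # integer-mm origin: exactly representable in NIfTI float32
  hi <- c(max(tpl$cx + tpl$rx), max(tpl$cy + tpl$ry), max(tpl$cz + tpl$rz)) +
    margin * scale
  shape <- as.integer(ceiling((hi - lo) / voxel_size)) + 1L
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- lo
  list(shape = shape, affine = affine)
}

# Draw per-subject structure geometry (true centers/radii per label) for one
# subject. Jitter is one displacement per *structure* (merged labels move
# together, preserving their relative layout); volume noise is likewise per
# structure.
draw_subject_geometry <- function(cfg, group) {
  tpl <- phantom_template(cfg$template_scale)
  structs <- unique(tpl$structure)
  jit <- matrix(stats::rnorm(3 * length(structs), 0,
                             cfg$jitter_sd * cfg$template_scale),
                ncol = 3, dimnames = list(structs, NULL))
  vmul <- stats::rnorm(length(structs), 1, cfg$volume_cv)
  vmul <- pmax(vmul, 0.2)
  names(vmul) <- structs
  scale3 <- rep(1, length(structs)); names(scale3) <- structs
  shift <- matrix(0, length(structs), 3, dimnames = list(structs, NULL))
  for (e in cfg$effects) {
    if (e$group == group) {
      scale3[e$structure] <- scale3[e$structure] * e$volume_scale
      shift[e$structure, ] <- shift[e$structure, ] + e$centroid_shift
    }
  }
  mult <- (vmul * scale3)^(1 / 3)
  tpl$cx <- tpl$cx + jit[tpl$structure, 1] + shift[tpl$structure, 1]
  tpl$cy <- tpl$cy + jit[tpl$structure, 2] + shift[tpl$structure, 2]
  tpl$cz <- tpl$cz + jit[tpl$structure, 3] + shift[tpl$structure, 3]
  tpl$rx <- tpl$rx * mult[tpl$structure]
  tpl$ry <- tpl$ry * mult[tpl$structure]
  tpl$rz <- tpl$rz * mult[tpl$structure]
  tpl
}

# Rasterize one subject's ellipsoids onto an integer grid. Errors if two
# labels claim the same voxel (structure collision) or an ellipsoid leaves
# the grid.
rasterize_subject <- function(geom, shape, affine, voxel_size) {
  labels <- array(0L, dim = shape)
  origin <- affine[1:3, 4]
  for (i in seq_len(nrow(geom))) {
    g <- geom[i, ]
    ctr <- c(g$cx, g$cy, g$cz); rad <- c(g$rx, g$ry, g$rz)
    # voxel-center index range covering the bounding box (0-based)
    lo <- floor((ctr - rad - origin) / voxel_size)
    hi <- ceiling((ctr + rad - origin) / voxel_size)
    if (any(lo < 0) || any(hi > shape - 1L))
      stop("grid too small to contain structure ", g$structure)
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    xs <- (origin[1] + ix * voxel_size - ctr[1]) / rad[1]
    ys <- (origin[2] + iy * voxel_size - ctr[2]) / rad[2]
    zs <- (origin[3] + iz * voxel_size - ctr[3]) / rad[3]
    d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
    inside <- which(d2 <= 1, arr.ind = TRUE)
    if (nrow(inside) == 0) next
    idx <- cbind(ix[inside[, 1]], iy[inside[, 2]], iz[inside[, 3]]) + 1L
    if (any(labels[idx] != 0L))
      stop("structure collision while rasterizing ", g$structure,
           " (label ", g$label, ")")
    labels[idx] <- as.integer(g$label)
  }
  labels
}

draw_demographics <- function(cfg, gi) {
  age <- stats::rnorm(1, cfg$age_mean[gi], cfg$age_sd[gi])
  age <- min(max(age, 40), 90)
  sex <- stats::rbinom(1, 1, cfg$female_prop[gi])  # F = 1, M = 0
  list(age = age, sex = sex)
}

# True (analytic) per-structure volume and centroid for one subject geometry.
true_geometry <- function(geom) {
  vol <- 4 / 3 * pi * geom$rx * geom$ry * geom$rz
  agg <- lapply(split(seq_len(nrow(geom)), geom$structure), function(idx) {
    w <- vol[idx] / sum(vol[idx])
    c(volume = sum(vol[idx]),
      cx = sum(w * geom$cx[idx]), cy = sum(w * geom$cy[idx]),
      cz = sum(w * geom$cz[idx]))
  })
  out <- do.call(rbind, agg)
  data.frame(structure = rownames(out), out, row.names = NULL)
}

#' Generate a labeled-phantom cohort
#'
#' Slow-mode generator: writes one labeled NIfTI volume per subject, in which
#' every registry structure is a voxelized ellipsoid (merged labels are
#' separate ellipsoids pooled under one structure), plus a subject manifest
#' and analytic ground truth. Deterministic under the config seed. The
#' rasterizer verifies that no two labels claim the same voxel and errors on
#' collision.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if missing). If `NULL`, volumes are
#'   returned in memory instead of written.
#' @param write_stats Also write a FreeSurfer-style `aseg.stats` summary per
#'   subject (synthetic fixture; voxel counts and volumes from the rasterized
#'   grid).
#' @return A list with `manifest` (subject_id, group, sex, age, path),
#'   `ground_truth` (per subject and structure: true volume mm^3 and true
#'   centroid RAS mm), `grid` (shape + affine), and - when `dir` is `NULL` -
#'   `volumes`, a named list of `labeled_volume` objects.
#' @export
generate_phantom_cohort <- function(config, dir = NULL, write_stats = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  grid <- phantom_grid(config$template_scale, config$voxel_size)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list(); gt <- list(); vols <- list()
  k <- 0
  for (gi in seq_along(config$groups)) {
    for (s in seq_len(config$n_per_group)) {
      k <- k + 1
      sid <- sprintf("sub-%03d", k)
      geom <- draw_subject_geometry(config, config$groups[gi])
      demo <- draw_demographics(config, gi)
      labels <- rasterize_subject(geom, grid$shape, grid$affine,
                                  config$voxel_size)
      vol <- new_labeled_volume(labels, grid$affine)
      path <- NA_character_
      if (!is.null(dir)) {
        path <- file.path(dir, paste0(sid, ".nii.gz"))
        write_labeled_volume(vol, path)
        if (write_stats)
          write_aseg_stats(vol, file.path(dir, paste0(sid, "_aseg.stats")),
                           registry = config$registry)
      } else {
        vols[[sid]] <- vol
      }
      tg <- true_geometry(geom)
      tg$subject_id <- sid
      gt[[k]] <- tg
      manifest[[k]] <- data.frame(
        subject_id = sid, group = config$groups[gi],
        sex = demo$sex, age = demo$age, path = path,
        stringsAsFactors = FALSE)
    }
  }
  out <- list(manifest = do.call(rbind, manifest),
              ground_truth = do.call(rbind, gt),
              grid = grid)
  if (is.null(dir)) out$volumes <- vols
  out
}

#' Default fast-mode group effects
#'
#' Standardized mean shifts encoding the qualitative group pattern the
#' pipeline is designed to detect: early bilateral-onset atrophy of the left
#' amygdala, putamen and accumbens (both patient groups vs controls),
#' PD-weighted reduction of left caudate and ventral diencephalon volumes,
#' shortened left-hippocampus and right-caudate distances in both patient
#' groups, lengthened right pallidum/putamen distances, and
#' prodromal-weighted reorientation (cosine) of the left caudate, putamen and
#' pallidum. The PD/PR asymmetry of the cosine effects is what makes the
#' PD-vs-PR task learnable while remaining the hardest of the three.
#'
#' @return data.frame with columns `column`, `group`, `d`.
#' @export
default_feature_effects <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
column group d
Left-Amygdala_normvol PARKINSON -0.75
Left-Amygdala_normvol PRODROMAL -0.75
Left-Putamen_normvol PARKINSON -0.75
Left-Putamen_normvol PRODROMAL -0.80
Left-Accumbens_normvol PARKINSON -0.85
Left-Accumbens_normvol PRODROMAL -0.85
Right-Putamen_normvol PARKINSON -0.50
Right-Putamen_normvol PRODROMAL -0.65
Left-Caudate_normvol PARKINSON -0.60
Left-Caudate_normvol PRODROMAL -0.40
Left-VentralDC_normvol PARKINSON -0.75
Left-VentralDC_normvol PRODROMAL -0.48
Left-Hippocampus_euclid PARKINSON -0.60
Left-Hippocampus_euclid PRODROMAL -0.57
Right-Caudate_euclid PARKINSON -0.62
Right-Caudate_euclid PRODROMAL -0.58
Right-Putamen_euclid PARKINSON 0.67
Right-Putamen_euclid PRODROMAL 0.40
Right-Pallidum_euclid PARKINSON 0.90
Right-Pallidum_euclid PRODROMAL 0.70
Left-VentralDC_euclid PARKINSON -0.45
Left-VentralDC_euclid PRODROMAL -0.77
Left-Cerebellum_euclid PARKINSON -0.62
Left-Cerebellum_euclid PRODROMAL -0.30
CSF_euclid PRODROMAL 0.57
Left-Hippocampus_cosine PARKINSON -0.58
Left-Hippocampus_cosine PRODROMAL -0.62
Left-Caudate_cosine PARKINSON -0.12
Left-Caudate_cosine PRODROMAL -0.80
Left-Putamen_cosine PARKINSON -0.22
Left-Putamen_cosine PRODROMAL -0.90
Left-Pallidum_cosine PARKINSON -0.16
Left-Pallidum_cosine PRODROMAL -0.78
")
}

# Baseline feature means/sds for fast mode, derived from the canonical
# template so both generator modes describe the same population. Volumes get
# CV-proportional noise (normvol inherits the thalamus contribution);
# distances get jitter-propagated noise.
feature_population <- function(cfg) {
  tpl <- phantom_template(cfg$template_scale)
  tg <- true_geometry(tpl)
  ref <- attr(cfg$registry, "reference")
  refrow <- tg[tg$structure == ref, ]
  refc <- c(refrow$cx, refrow$cy, refrow$cz)
  cols <- feature_column_names(cfg$registry)
  mu <- stats::setNames(numeric(length(cols)), cols)
  sd <- mu
  mu[paste0(ref, "_vol")] <- refrow$volume
  sd[paste0(ref, "_vol")] <- refrow$volume * cfg$volume_cv
  # distance noise from centroid jitter of both endpoints
  djit <- sqrt(2) * cfg$jitter_sd * cfg$template_scale
  for (s in non_reference_structures(cfg$registry)) {
    row <- tg[tg$structure == s, ]
    ctr <- c(row$cx, row$cy, row$cz)
    nv <- row$volume / refrow$volume
    mu[paste0(s, "_normvol")] <- nv
    sd[paste0(s, "_normvol")] <- nv * cfg$volume_cv * sqrt(2)
    eu <- euclidean_distance(ctr, refc)
    mu[paste0(s, "_euclid")] <- eu
    sd[paste0(s, "_euclid")] <- max(djit, 1e-6)
    co <- cosine_distance(ctr, refc)
    mu[paste0(s, "_cosine")] <- co
    # angular noise: jitter relative to the norm of the two position vectors
    sd[paste0(s, "_cosine")] <-
      max(djit / sqrt(sum(ctr^2) * sum(refc^2))^0.5, 1e-6) * 0.5
  }
  list(mu = mu, sd = sd)
}

#' Generate a parametric feature cohort (fast mode)
#'
#' Draws the assembled feature table directly from a multivariate parametric
#' model whose baseline means derive from the same canonical template as the
#' phantom generator. Features are independent normals; group effects enter
#' as standardized mean shifts (`d` units of the feature's within-group sd)
#' in designated columns. Demographics follow the config's per-group models.
#'
#' @param config A [cohort_config()]; its `feature_effects` (if any) define
#'   the group structure.
#' @return A list with `features` (the assembled feature table: subject_id,
#'   group, then 57 feature columns for the default registry) and
#'   `ground_truth` (the per-group population means actually used).
#' @export
generate_feature_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  pop <- feature_population(config)
  cols <- feature_column_names(config$registry)
  n <- config$n_per_group * length(config$groups)
  group <- rep(config$groups, each = config$n_per_group)
  numcols <- setdiff(cols, c("Sex", "Age"))
  x <- matrix(stats::rnorm(n * length(numcols)), n, length(numcols),
              dimnames = list(NULL, numcols))
  mumat <- matrix(pop$mu[numcols], n, length(numcols), byrow = TRUE,
                  dimnames = list(NULL, numcols))
  if (!is.null(config$feature_effects)) {
    fe <- config$feature_effects
    for (i in seq_len(nrow(fe))) {
      sel <- group == fe$group[i]
      mumat[sel, fe$column[i]] <- mumat[sel, fe$column[i]] +
        fe$d[i] * pop$sd[fe$column[i]]
    }
  }
  x <- mumat + x * matrix(pop$sd[numcols], n, length(numcols), byrow = TRUE)
  # volumes and distances are positive quantities
  x <- pmax(x, 1e-8)
  gi <- match(group, config$groups)
  age <- pmin(pmax(stats::rnorm(n, config$age_mean[gi], config$age_sd[gi]),
                   40), 90)
  sex <- stats::rbinom(n, 1, config$female_prop[gi])
  features <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = group, x, Sex = sex, Age = age,
    check.names = FALSE, stringsAsFactors = FALSE)
  if (config$updrs3)
    features$UPDRS3 <- pmax(stats::rnorm(n, config$updrs3_mean[gi],
                                         config$updrs3_sd[gi]), 0)
  gt <- data.frame(group = rep(config$groups, each = length(numcols)),
                   column = rep(numcols, length(config$groups)))
  gt$mean <- mapply(function(g, cc) {
    m <- pop$mu[cc]
    if (!is.null(config$feature_effects)) {
      fe <- config$feature_effects
      hit <- fe$group == g & fe$column == cc
      if (any(hit)) m <- m + sum(fe$d[hit]) * pop$sd[cc]
    }
    m
  }, gt$group, gt$column)
  list(features = features, ground_truth = gt)
}
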