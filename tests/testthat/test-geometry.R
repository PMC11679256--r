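test_that("voxel-to-RAS mapping equals the explicit affine product", {
  arr <- array(1L, c(6, 7, 8))
  # identity
  v <- new_labeled_volume(arr, diag(4))
  expect_equal(voxel_to_ras(v, c(2, 3, 4)), c(2, 3, 4))
  # pure translation
  aff <- diag(4); aff[1:3, 4] <- c(-5, 2, 7)
  v <- new_labeled_volume(arr, aff)
  expect_equal(voxel_to_ras(v, c(0, 0, 0)), c(-5, 2, 7))
  # random affine vs matrix-vector oracle
  set.seed(4)
  for (i in 1:10) {
    A <- diag(4)
    A[1:3, 1:3] <- matrix(rnorm(9), 3) + diag(3) * 2
    A[1:3, 4] <- rnorm(3, sd = 10)
    v <- new_labeled_volume(arr, A)
    idx <- c(sample(0:5, 1), sample(0:6, 1), sample(0:7, 1))
    expect_equal(voxel_to_ras(v, idx), (A %*% c(idx, 1))[1:3])
  }
  expect_error(voxel_to_ras(v, c(6, 0, 0)), "out of bounds")
})

test_that("structure measurement handles single voxels and symmetric pairs", {
  arr <- array(0L, c(6, 6, 6))
  arr[3, 4, 5] <- 1L  # 0-based index (2,3,4)
  v <- new_labeled_volume(arr, diag(4))
  m <- measure_structure(v, "S", single_registry("S"))
  expect_equal(m$centroid, c(2, 3, 4), ignore_attr = TRUE)
  expect_equal(m$volume_mm3, 1)

  arr2 <- array(0L, c(6, 6, 6))
  arr2[1, 1, 1] <- 1L; arr2[5, 1, 1] <- 1L  # 0-based (0,0,0), (4,0,0)
  v2 <- new_labeled_volume(arr2, diag(4))
  m2 <- measure_structure(v2, "S", single_registry("S"))
  expect_equal(m2$centroid, c(2, 0, 0), ignore_attr = TRUE)
  expect_error(measure_structure(v2, "T", single_registry("T", 7L)),
               "missing structure")
})

test_that("merged labels are pooled into one centroid cloud", {
  arr <- array(0L, c(9, 5, 5))
  arr[1, 1, 1] <- 10L       # 0-based (0,0,0)
  arr[9, 1, 1] <- 49L       # 0-based (8,0,0)
  v <- new_labeled_volume(arr, diag(4))
  m <- measure_structure(v, "Thalamus", structure_registry())
  expect_equal(m$n_voxels, 2)
  expect_equal(m$centroid, c(4, 0, 0), ignore_attr = TRUE)
})

test_that("Minkowski distance matches hand values and is a metric", {
  expect_equal(minkowski_distance(c(0, 0, 0), c(3, 4, 0), 2), 5)
  expect_equal(minkowski_distance(c(0, 0, 0), c(3, 4, 0), 1), 7)
  expect_equal(minkowski_distance(c(1, 2, 3), c(1, 2, 3), 7), 0)
  expect_equal(euclidean_distance(c(0, 0, 0), c(3, 4, 0)),
               minkowski_distance(c(0, 0, 0), c(3, 4, 0), 2))
  expect_error(minkowski_distance(c(0, 0), c(1, 1), 0.5), "p must be >= 1")
  set.seed(9)
  for (i in 1:50) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3)
    p <- sample(c(1, 1.5, 2, 3), 1)
    expect_equal(minkowski_distance(a, b, p), minkowski_distance(b, a, p))
    expect_gte(minkowski_distance(a, b, p) + minkowski_distance(b, c, p),
               minkowski_distance(a, c, p) - 1e-12)
    expect_gte(minkowski_distance(a, b, p), 0)
  }
})

test_that("cosine distance spans [0, 2] with exact endpoints", {
  v <- c(0.3, -1.7, 2.2)
  expect_identical(cosine_distance(v, v), 0)
  expect_identical(cosine_distance(v, -v), 2)
  expect_equal(cosine_distance(c(1, 0, 0), c(0, 1, 0)), 1)
  expect_error(cosine_distance(c(0, 0, 0), v), "zero-norm")
  set.seed(10)
  for (i in 1:100) {
    a <- rnorm(3); b <- rnorm(3)
    d <- cosine_distance(a, b)
    expect_gte(d, 0); expect_lte(d, 2)
    # invariance to positive rescaling: orientation only
    expect_equal(cosine_distance(3.7 * a, b), d)
    expect_equal(cosine_distance(a, 0.002 * b), d)
  }
})

test_that("subject features normalize by thalamus and use both metrics", {
  cfg <- cohort_config(n_per_group = 2, groups = c("CONTROL", "PARKINSON"),
                       template_scale = 0.6, seed = 6)
  ph <- generate_phantom_cohort(cfg)
  v <- ph$volumes[[1]]
  demo <- list(subject_id = "sub-001", group = "CONTROL", sex = 0, age = 60)
  f <- extract_subject_features(v, demographics = demo)
  expect_equal(ncol(f) - 2, 57)
  reg <- structure_registry()
  thal <- measure_structure(v, "Thalamus", reg)
  expect_equal(f$Thalamus_vol, thal$volume_mm3)
  for (nm in c("Left-Hippocampus", "CSF")) {
    m <- measure_structure(v, nm, reg)
    expect_equal(f[[paste0(nm, "_normvol")]], m$volume_mm3 / thal$volume_mm3)
    expect_equal(f[[paste0(nm, "_euclid")]],
                 euclidean_distance(m$centroid, thal$centroid))
    expect_equal(f[[paste0(nm, "_cosine")]],
                 cosine_distance(m$centroid, thal$centroid))
  }
})

test_that("normvol is scale-invariant, distances scale, translation hits cosine only", {
  cfg <- cohort_config(n_per_group = 2, groups = c("CONTROL", "PARKINSON"),
                       template_scale = 0.6, seed = 13)
  ph <- generate_phantom_cohort(cfg)
  v <- ph$volumes[[1]]
  demo <- list(subject_id = "s", group = "CONTROL", sex = 1, age = 55)
  f0 <- extract_subject_features(v, demographics = demo)

  s <- 2.5  # uniform spatial scaling of the whole phantom
  vs <- v; vs$affine[1:3, ] <- vs$affine[1:3, ] * s
  vs <- new_labeled_volume(vs$labels, vs$affine)
  fs <- extract_subject_features(vs, demographics = demo)
  nv <- grep("_normvol$", names(f0), value = TRUE)
  eu <- grep("_euclid$", names(f0), value = TRUE)
  co <- grep("_cosine$", names(f0), value = TRUE)
  expect_equal(unlist(fs[nv]), unlist(f0[nv]))
  expect_equal(unlist(fs[eu]), s * unlist(f0[eu]))
  expect_equal(unlist(fs[co]), unlist(f0[co]))

  vt <- v; vt$affine[1:3, 4] <- vt$affine[1:3, 4] + c(40, -25, 60)
  vt <- new_labeled_volume(vt$labels, vt$affine)
  ft <- extract_subject_features(vt, demographics = demo)
  expect_equal(unlist(ft[eu]), unlist(f0[eu]))
  expect_equal(unlist(ft[nv]), unlist(f0[nv]))
  # cosine is origin-dependent: translation changes it
  expect_gt(max(abs(unlist(ft[co]) - unlist(f0[co]))), 1e-3)
})

test_that("feature assembly enforces width, completeness and order", {
  fc <- generate_feature_cohort(cohort_config(seed = 17))
  tab <- assemble_feature_table(fc$features)
  expect_equal(nrow(tab), 168)
  expect_equal(ncol(tab) - 2, 57)
  expect_identical(names(tab), c("subject_id", "group",
                                 feature_column_names()))
  expect_false(anyNA(tab))
  expect_error(assemble_feature_table(list()), "empty cohort")
  broken <- fc$features[, -5]
  expect_error(assemble_feature_table(broken), "inconsistent|missing")
})
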