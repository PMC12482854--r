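test_that("region means match uniform uptake and flag absent labels", {
  labs <- tiny_labels()
  pet <- uniform_pet(labs, c(`1` = 2.0, `2` = 1.0, `3` = 1.5))
  st <- region_stats(pet, labs)
  expect_equal(st$mean[st$id == 1], 2.0)
  expect_equal(st$voxels[st$id == 1], sum(labs$labels == 1L))
  # label 4 is in the dictionary but absent from the volume
  expect_equal(st$voxels[st$id == 4], 0L)
  expect_true(is.na(st$mean[st$id == 4]))
})

test_that("vectorized region statistics equal the brute-force oracle", {
  set.seed(41)
  dict <- label_dictionary(data.frame(id = 1:9, name = paste("s", 1:9),
                                      tissue = rep(c("GM", "WM", "CSF"), 3)))
  for (rep in 1:20) {
    sp <- phantom_space(c(20L, 20L, 20L), 2)
    lab <- array(sample(0:9, 8000, replace = TRUE), c(20, 20, 20))
    labs <- label_volume(lab, sp$affine, dict)
    up <- array(rnorm(8000, 1.5, 1), c(20, 20, 20))  # includes negatives
    up[sample(8000, 40)] <- NaN
    pet <- image_volume(up, sp$affine)
    st <- region_stats(pet, labs)
    oracle <- brute_region_stats(pet, labs)
    expect_equal(st$mean, unname(oracle[, "mean"]), tolerance = 1e-12)
    expect_identical(st$voxels, as.integer(oracle[, "voxels"]))
    expect_identical(st$valid_voxels, as.integer(oracle[, "valid"]))
  }
})

test_that("region_stats rejects mismatched grids", {
  labs <- tiny_labels()
  pet_small <- image_volume(array(1, c(8, 8, 8)), labs$affine)
  expect_error(region_stats(pet_small, labs), "grid mismatch")
  aff2 <- labs$affine; aff2[1, 4] <- aff2[1, 4] + 1
  pet_off <- image_volume(array(1, dim(labs$labels)), aff2)
  expect_error(region_stats(pet_off, labs), "grid mismatch")
})

test_that("reference uptake is the pooled-voxel (volume-weighted) mean", {
  # construct stats where reference labels have means 1.0 / 3.0 with
  # valid-voxel counts 100 / 300 -> pooled mean (100*1 + 300*3)/400 = 2.5
  dict <- label_dictionary(data.frame(id = 1:2, name = c("a", "b"),
                                      tissue = "GM"))
  sp <- phantom_space(c(10L, 10L, 10L), 1)
  lab <- array(0L, c(10, 10, 10))
  lab[1:100] <- 1L; lab[101:400] <- 2L
  labs <- label_volume(lab, sp$affine, dict)
  up <- array(0, c(10, 10, 10)); up[1:100] <- 1.0; up[101:400] <- 3.0
  st <- region_stats(image_volume(up, sp$affine), labs)
  expect_equal(reference_uptake(st, composite_mask("ref", c(1, 2))), 2.5)
  expect_equal(reference_uptake(st, composite_mask("one", 1)), 1.0)
})

test_that("empty reference or empty mask raise errors", {
  labs <- tiny_labels()
  st <- region_stats(uniform_pet(labs, c(`1` = 1, `2` = 2, `3` = 1)), labs)
  expect_error(reference_uptake(st, composite_mask("absent", 4)), "no voxels")
  expect_error(composite_suvr(st, composite_mask("absent", 4),
                              composite_mask("ref", 1)), "no voxels")
  expect_error(composite_mask("empty", integer(0)), "empty")
  expect_error(composite_mask("bad", 99, tiny_dictionary()),
               "absent from dictionary")
})

test_that("SUVr table covers exactly the GM labels present, reference at 1", {
  labs <- make_label_phantom(phantom_spec(seed = 3), full_dictionary)
  pet <- make_pet_phantom(labs, phantom_uptake_map(full_dictionary, "amyloid",
                                                   masks = full_masks))
  st <- region_stats(pet, labs)
  ref <- full_masks$whole_cerebellum
  tab <- suvr_table(st, ref)
  expect_identical(nrow(tab), 122L)
  expect_identical(length(attr(tab, "missing_ids")), 0L)
  # the reference structures normalize to SUVr 1
  cereb_gm <- intersect(tab$id, ref$structure_ids)
  expect_equal(tab$suvr[tab$id %in% cereb_gm],
               rep(1, length(cereb_gm)), tolerance = 1e-9)
  # self-normalization of the composite reference
  expect_equal(composite_suvr(st, ref, ref), 1, tolerance = 1e-9)
})

test_that("suvr_table errors on a non-positive reference", {
  labs <- tiny_labels()
  st <- region_stats(uniform_pet(labs, c(`1` = 1, `2` = 2, `3` = 0)), labs)
  expect_error(suvr_table(st, composite_mask("ref", 3)), "positive")
})

test_that("composite SUVr pools voxels across mask structures", {
  # two mask regions with means 1.2 / 1.8 and equal counts, reference 1.0
  dict <- label_dictionary(data.frame(id = 1:3, name = c("a", "b", "r"),
                                      tissue = "GM"))
  sp <- phantom_space(c(12L, 12L, 12L), 1)
  lab <- array(0L, c(12, 12, 12))
  lab[1:200] <- 1L; lab[201:400] <- 2L; lab[401:600] <- 3L
  up <- array(0, c(12, 12, 12))
  up[1:200] <- 1.2; up[201:400] <- 1.8; up[401:600] <- 1.0
  st <- region_stats(image_volume(up, sp$affine),
                     label_volume(lab, sp$affine, dict))
  expect_equal(composite_suvr(st, composite_mask("m", c(1, 2)),
                              composite_mask("ref", 3)), 1.5)
})

test_that("discriminative selection finds the separating structures", {
  set.seed(13)
  make_tab <- function(suvr) {
    structure(data.frame(id = 1:6, name = paste("s", 1:6), tissue = "GM",
                         mean = suvr, voxels = 100, volume_mm3 = 800,
                         suvr = suvr),
              class = c("suvr_table", "data.frame"))
  }
  # labels 1 and 2 separate with d ~ 3; the rest are pure noise
  ga <- lapply(1:12, function(i) make_tab(c(rnorm(2, 1.0, 0.1), rnorm(4, 1, 0.1))))
  gb <- lapply(1:12, function(i) make_tab(c(rnorm(2, 1.6, 0.1), rnorm(4, 1, 0.1))))
  sel <- select_discriminative_structures(ga, gb, top_k = 2)
  expect_setequal(sel$mask$structure_ids, c(1L, 2L))
  expect_false(sel$unstable)
  sel_auc <- select_discriminative_structures(ga, gb, criterion = "auc",
                                              top_k = 2)
  expect_setequal(sel_auc$mask$structure_ids, c(1L, 2L))
  # identical groups: criteria collapse and the ranking is flagged unstable
  sel0 <- select_discriminative_structures(ga, ga, top_k = 2)
  expect_true(all(sel0$ranking$criterion < 1e-8))
  expect_true(sel0$unstable)
  expect_error(select_discriminative_structures(ga[1], gb, top_k = 2),
               "at least 2")
})

test_that("volume table computes native and ICV-normalized volumes", {
  # 1000 voxels at 1 mm^3 against ICV 1.5e6 -> fraction 1000/1.5e6
  dict <- label_dictionary(data.frame(id = 1L, name = "s", tissue = "GM"))
  sp <- phantom_space(c(20L, 20L, 20L), 1)
  lab <- array(0L, c(20, 20, 20)); lab[1:1000] <- 1L
  vt <- volume_table(label_volume(lab, sp$affine, dict), icv = 1.5e6)
  expect_equal(vt$native_mm3, 1000)
  expect_equal(vt$icv_fraction, 1000 / 1.5e6, tolerance = 1e-12)
  # empty label -> zero volume
  lab0 <- array(0L, c(20, 20, 20))
  vt0 <- volume_table(label_volume(lab0, sp$affine, dict), icv = 1.5e6)
  expect_equal(vt0$native_mm3, 0)
  expect_error(volume_table(label_volume(lab, sp$affine, dict), icv = 0),
               "positive")
})

test_that("iterative region-based PVC recovers blurred two-region means", {
  # two large regions, uptake 1.0 / 3.0, blurred at 6 mm FWHM
  dict <- label_dictionary(data.frame(id = 1:2, name = c("low", "high"),
                                      tissue = "GM"))
  sp <- phantom_space(c(40L, 40L, 40L), 2)
  lab <- array(0L, c(40, 40, 40))
  lab[9:32, 9:32, 9:20] <- 1L
  lab[9:32, 9:32, 21:32] <- 2L
  labs <- label_volume(lab, sp$affine, dict)
  truth <- c(1, 3)
  pet0 <- uniform_pet(labs, c(`1` = 1, `2` = 3))
  blurred <- image_volume(gaussian_blur(pet0$data, 6, c(2, 2, 2)), sp$affine)
  mean_err <- function(img) {
    st <- region_stats(img, labs)
    abs(st$mean - truth)
  }
  err_by_iter <- sapply(0:5, function(k) {
    img <- if (k == 0) blurred else pvc_region_based(blurred, labs, 6, k)
    max(mean_err(img))
  })
  # strict improvement over the first iterations, and within 2% after 5
  expect_true(all(diff(err_by_iter[1:4]) < 0))
  expect_lt(err_by_iter[6] / 3, 0.02)
  expect_lt(max(abs(region_stats(pvc_region_based(blurred, labs, 6, 5),
                                 labs)$mean - truth) / truth), 0.02)
})

test_that("PVC is the identity in the vanishing-PSF limit and validates input", {
  labs <- tiny_labels()
  pet <- uniform_pet(labs, c(`1` = 1, `2` = 3, `3` = 2))
  out <- pvc_region_based(pet, labs, psf_fwhm = 1e-6, iterations = 3)
  expect_equal(out$data, pet$data, tolerance = 1e-12)
  expect_error(pvc_region_based(pet, labs, psf_fwhm = 0), "positive")
  expect_error(pvc_region_based(pet, labs, psf_fwhm = 6, iterations = 0),
               ">= 1")
})

test_that("PVC approximately conserves total uptake within the brain", {
  # uptake support lies well inside the labelled volume (a zero-uptake rim
  # region catches all spill), so no activity leaves the mask when blurring
  dict <- label_dictionary(data.frame(id = 1:3, name = c("a", "b", "rim"),
                                      tissue = "GM"))
  sp <- phantom_space(c(32L, 32L, 32L), 2)
  lab <- array(3L, c(32, 32, 32))
  lab[9:24, 9:24, 9:16] <- 1L
  lab[9:24, 9:24, 17:24] <- 2L
  labs <- label_volume(lab, sp$affine, dict)
  pet0 <- uniform_pet(labs, c(`1` = 1, `2` = 3, `3` = 0))
  blurred <- image_volume(gaussian_blur(pet0$data, 5, c(2, 2, 2)), sp$affine)
  totals <- vapply(1:4, function(k)
    sum(pvc_region_based(blurred, labs, 5, k)$data), numeric(1))
  # the mask total stays close to the true total at every iteration, and
  # after the first corrective pass successive changes are below 1%
  expect_true(all(abs(totals - sum(pet0$data)) / sum(pet0$data) < 0.02))
  expect_true(all(abs(diff(totals[-1])) / totals[c(-1, -4)] < 0.01))
})
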