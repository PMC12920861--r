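test_that("COCO keypoint round trip preserves records exactly", {
  ds <- tiny_dataset()
  dir <- file.path(tempdir(), "coco_rt")
  unlink(dir, recursive = TRUE)
  write_coco_dataset(ds$records[1:4], dir)
  back <- load_dataset(dir, file.path(dir, "annotations.json"))
  expect_length(back, 4)
  for (i in 1:4) {
    expect_equal(as.matrix(back[[i]]$triplet), as.matrix(ds$records[[i]]$triplet))
    expect_equal(back[[i]]$patient_id, ds$records[[i]]$patient_id)
    expect_equal(back[[i]]$oncologic, ds$records[[i]]$oncologic)
    expect_equal(back[[i]]$modality, ds$records[[i]]$modality)
  }
  unlink(dir, recursive = TRUE)
})

test_that("invalid COCO inputs give descriptive errors", {
  ds <- tiny_dataset()
  dir <- file.path(tempdir(), "coco_bad")
  unlink(dir, recursive = TRUE)
  write_coco_dataset(ds$records[1:2], dir)
  ann <- file.path(dir, "annotations.json")
  coco <- jsonlite::read_json(ann)
  # absent keypoint (visibility 0) rejected with the frame id in the message
  coco2 <- coco
  coco2$annotations[[1]]$keypoints[[3]] <- 0
  bad1 <- file.path(dir, "v0.json")
  jsonlite::write_json(coco2, bad1, auto_unbox = TRUE, digits = NA)
  fid <- sub("\\.png$", "", coco$images[[1]]$file_name)
  expect_error(load_dataset(dir, bad1), fid)
  expect_length(load_dataset(dir, bad1, allow_absent = TRUE), 2)
  # image listed but missing on disk: error names the file
  coco3 <- coco
  coco3$images[[2]]$file_name <- "nonexistent_frame.png"
  bad2 <- file.path(dir, "missing.json")
  jsonlite::write_json(coco3, bad2, auto_unbox = TRUE, digits = NA)
  expect_error(load_dataset(dir, bad2), "nonexistent_frame")
  # wrong keypoint count
  coco4 <- coco
  coco4$annotations[[1]]$keypoints <- coco4$annotations[[1]]$keypoints[1:6]
  bad3 <- file.path(dir, "short.json")
  jsonlite::write_json(coco4, bad3, auto_unbox = TRUE, digits = NA)
  expect_error(load_dataset(dir, bad3), "3 keypoints")
  unlink(dir, recursive = TRUE)
})

test_that("preprocessing rescales coordinates and removes channel means", {
  rec <- list(image = array(runif(480 * 640 * 3), dim = c(480, 640, 3)),
              triplet = vf_triplet(c(320, 240), c(0, 0), c(100, 120)))
  pp <- preprocess_frame(rec, 224)
  expect_equal(dim(pp$image), c(224, 224, 3))
  expect_equal(unname(pp$triplet$LV), c(112, 112))
  expect_equal(unname(pp$triplet$RV), c(0, 0))
  expect_lt(max(abs(apply(pp$image, 3, mean))), 1e-6)
  # idempotent on an already 224x224 zero-mean frame
  pp2 <- preprocess_frame(pp, 224)
  expect_equal(pp2$image, pp$image, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(as.matrix(pp2$triplet), as.matrix(pp$triplet))
})

test_that("augmentation transforms are involutive, seeded and label-correct", {
  ds <- tiny_dataset()
  img <- ds$records[[1]]$image
  tri <- ds$records[[1]]$triplet
  # flips with probability 1 and zero rotation applied twice = identity
  set.seed(1)
  a1 <- augment_frame(img, tri, rotation_range = 0, prob = 1, color = FALSE)
  a2 <- augment_frame(a1$image, a1$triplet, rotation_range = 0, prob = 1,
                      color = FALSE)
  expect_equal(a2$image, img, ignore_attr = TRUE)
  expect_equal(as.matrix(a2$triplet), as.matrix(tri))
  # one horizontal flip swaps the LV/RV labels
  expect_equal(unname(a1$triplet$LV["y"]),
               unname(dim(img)[1] - 1 - tri$RV[["y"]]))
  # a keypoint at the image center is fixed under flips and rotation
  H <- dim(img)[1]; W <- dim(img)[2]
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  tric <- vf_triplet(LV = ctr + c(10, 4), RV = ctr + c(-9, 5), A = ctr)
  set.seed(2)
  ac <- augment_frame(img, tric, rotation_range = 30, prob = 1, color = FALSE)
  expect_equal(unname(ac$triplet$A), ctr, tolerance = 1e-9)
  # determinism under a fixed seed
  set.seed(33)
  b1 <- augment_frame(img, tri)
  set.seed(33)
  b2 <- augment_frame(img, tri)
  expect_identical(b1$image, b2$image)
  expect_equal(as.matrix(b1$triplet), as.matrix(b2$triplet))
})

test_that("augmenting image and keypoints stays heatmap-consistent", {
  set.seed(77)
  for (i in 1:12) {
    tri <- random_triplet(96, 96, margin = 12)
    hm <- encode_heatmaps(tri, 96, 96, sigma = 8)
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    aug <- augment_frame(hm, tri, color = FALSE, swap_channels_on_hflip = TRUE)
    dec <- decode_heatmaps(aug$image)
    expect_lt(max(abs(as.matrix(dec)[, 1:2] - as.matrix(aug$triplet)[, 1:2])),
              1 + 1e-9)
  }
})

test_that("patient folds are balanced, grouped and reproducible", {
  ds <- tiny_dataset()
  # 5 patients, k = 5: each fold tests exactly one patient
  pid <- vapply(ds$records, function(r) r$patient_id, character(1))
  five <- ds$records[pid %in% unique(pid)[1:5]]
  f5 <- make_patient_folds(five, k = 5, seed = 3)
  for (f in f5) expect_length(f$test_patients, 1)
  # many patients: test group sizes differ by at most one
  many <- lapply(seq_len(124), function(i)
    list(patient_id = sprintf("P%03d", i), frame_id = sprintf("f%03d", i)))
  fm <- make_patient_folds(many, k = 5, seed = 9)
  sizes <- vapply(fm, function(f) length(f$test_patients), integer(1))
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sum(sizes), 124)
  # reproducibility
  fa <- make_patient_folds(ds$records, k = 3, seed = 42)
  fb <- make_patient_folds(ds$records, k = 3, seed = 42)
  expect_identical(fa, fb)
  expect_error(make_patient_folds(five, k = 9), "exceeds")
})

test_that("fold exports cover every frame exactly once per fold", {
  ds <- tiny_dataset()
  folds <- make_patient_folds(ds$records, k = 4, seed = 7)
  path <- tempfile(fileext = ".csv")
  export_folds_csv(folds, ds$records, path)
  tab <- read.csv(path)
  n <- length(ds$records)
  for (f in 0:3) {
    d <- tab[tab$fold == f, ]
    expect_equal(nrow(d), n)
    expect_setequal(d$frame_id,
                    vapply(ds$records, function(r) r$frame_id, character(1)))
  }
  unlink(path)
})
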