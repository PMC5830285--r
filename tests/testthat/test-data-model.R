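test_that("multitask_dataset validates shapes, finiteness and blocks", {
  X <- matrix(1:6, 3, 2)
  Y <- matrix(1:3, 3, 1)
  ds <- multitask_dataset(X, Y)
  expect_equal(ds$m, 3L)
  expect_equal(ds$p, 2L)
  expect_equal(ds$n_tasks, 1L)

  expect_error(multitask_dataset(X, matrix(1:4, 4, 1)), "shape error")
  Xbad <- X; Xbad[1, 1] <- NA
  expect_error(multitask_dataset(Xbad, Y), "non-finite")
  expect_error(
    multitask_dataset(X, Y, modality_blocks = list(a = 1L)),
    "partition"
  )
  ds2 <- multitask_dataset(X, Y, modality_blocks = list(a = 1L, b = 2L))
  expect_named(ds2$modality_blocks, c("a", "b"))
})

test_that("load_dataset reads tables and reports parse errors by cell", {
  fx <- tempfile(fileext = ".csv")
  fy <- tempfile(fileext = ".csv")
  write.csv(data.frame(f1 = c(1, 2, 3), f2 = c(4, 5, 6)), fx,
            row.names = FALSE)
  write.csv(data.frame(score = c(7, 8, 9)), fy, row.names = FALSE)
  ds <- load_dataset(fx, fy)
  expect_equal(ds$m, 3L)
  expect_equal(ds$p, 2L)
  expect_equal(ds$n_tasks, 1L)

  fy4 <- tempfile(fileext = ".csv")
  write.csv(data.frame(score = c(7, 8, 9, 10)), fy4, row.names = FALSE)
  expect_error(load_dataset(fx, fy4), "shape error")

  fbad <- tempfile(fileext = ".csv")
  writeLines(c("f1,f2", "1,2", "NA,4"), fbad)
  expect_error(load_dataset(fbad, fy), "row 2.*column 'f1'")
})

test_that("load_dataset accepts a JSON modality map", {
  fx <- tempfile(fileext = ".csv")
  fy <- tempfile(fileext = ".csv")
  write.csv(data.frame(f1 = 1:3, f2 = 4:6, f3 = 7:9), fx, row.names = FALSE)
  write.csv(data.frame(score = c(1, 0, 1)), fy, row.names = FALSE)
  fmap <- tempfile(fileext = ".json")
  jsonlite::write_json(list(mri = c("f1", "f2"), pet = "f3"), fmap)
  ds <- load_dataset(fx, fy, modality_map = fmap)
  expect_equal(ds$modality_blocks, list(mri = c(1L, 2L), pet = 3L))
})

test_that("zscore centers and scales with the sample-sd convention", {
  ds <- multitask_dataset(matrix(c(1, 2, 3), 3, 1), matrix(c(1, 0, 2), 3, 1))
  zs <- zscore(ds)
  expect_equal(as.vector(zs$dataset$X), c(-1, 0, 1))
  expect_equal(mean(zs$dataset$X), 0)
  expect_equal(sd(zs$dataset$X), 1)
  # idempotence on an already standardized column
  zs2 <- zscore(zs$dataset)
  expect_equal(zs2$dataset$X, zs$dataset$X, tolerance = 1e-12)
})

test_that("zscore drops constant columns with a warning", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  ds <- multitask_dataset(X, matrix(c(1, 0, 2), 3, 1))
  expect_warning(zs <- zscore(ds), "zero-variance.*b")
  expect_equal(zs$dataset$p, 1L)
  expect_equal(zs$scaler$feature_names, "a")
})

test_that("zscore uses training statistics only (no leakage)", {
  set.seed(4)
  ds <- make_toy_ds(m = 30)
  train <- 1:20
  zs <- zscore(ds, fit_index = train)
  Xz <- zs$dataset$X
  expect_equal(colMeans(Xz[train, ]), rep(0, ds$p),
               ignore_attr = TRUE, tolerance = 1e-12)
  # held-out rows are transformed with training statistics, so their means
  # do not vanish in general
  expect_gt(max(abs(colMeans(Xz[-train, ]))), 1e-3)
  expect_equal(apply_scaler(zs$scaler, ds$X), Xz, tolerance = 1e-12)
})

test_that("scaler serializes to JSON and back", {
  ds <- make_toy_ds(m = 15)
  zs <- zscore(ds)
  js <- scaler_to_json(zs$scaler)
  back <- scaler_from_json(js)
  expect_equal(unname(back$center), unname(zs$scaler$center),
               tolerance = 1e-12)
  expect_equal(unname(back$scale), unname(zs$scaler$scale), tolerance = 1e-12)
  expect_equal(apply_scaler(back, ds$X), apply_scaler(zs$scaler, ds$X),
               tolerance = 1e-12)
})

test_that("make_folds partitions samples deterministically", {
  plan <- make_folds(20, outer = 10, inner = 5, seed = 3)
  sizes <- vapply(plan$outer_folds, function(f) length(f$test), 0L)
  expect_equal(sizes, rep(2L, 10))
  tests <- sort(unlist(lapply(plan$outer_folds, `[[`, "test")))
  expect_equal(tests, 1:20)  # union covers all samples, pairwise disjoint
  for (f in plan$outer_folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), 1:20)
  }
  plan2 <- make_folds(20, outer = 10, inner = 5, seed = 3)
  expect_identical(plan, plan2)
  plan3 <- make_folds(20, outer = 10, inner = 5, seed = 4)
  expect_false(identical(plan$outer_folds, plan3$outer_folds))
  expect_error(make_folds(5, outer = 10), "configuration error")
})

test_that("inner folds partition each outer training set", {
  plan <- make_folds(47, outer = 5, inner = 3, seed = 9)
  for (o in seq_along(plan$outer_folds)) {
    tr <- plan$outer_folds[[o]]$train
    inner <- plan$inner_folds[[o]]
    expect_length(inner, 3L)
    inner_tests <- sort(unlist(lapply(inner, `[[`, "test")))
    expect_equal(inner_tests, sort(tr))
    for (f in inner) {
      expect_length(intersect(f$train, f$test), 0)
      expect_setequal(c(f$train, f$test), tr)
    }
  }
})
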