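test_that("synthetic_spec validates its contract", {
  expect_error(synthetic_spec(p = 5, s = 10), "s must not exceed p")
  expect_error(synthetic_spec(noise_sd = -1), "nonnegative")
  expect_error(synthetic_spec(mode = "kernel-nonlinear"), "kernel_source")
  expect_error(synthetic_spec(mode = "multimodal"), "block_sizes")
  expect_error(synthetic_spec(p = 10, mode = "multimodal",
                              block_sizes = c(4, 4)), "sum to p")
})

test_that("generators are deterministic and leave the caller RNG alone", {
  sp <- synthetic_spec(m = 40, p = 8, n_tasks = 3, s = 3, snr = 5, seed = 45)
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  g1 <- gen_linear(sp)
  after <- rnorm(1)
  expect_equal(before, after)  # generator did not consume caller RNG draws
  g2 <- gen_linear(sp)
  expect_equal(g1$dataset$X, g2$dataset$X)
  expect_equal(g1$dataset$Y, g2$dataset$Y)
  expect_equal(g1$theta, g2$theta)

  spk <- synthetic_spec(m = 30, p = 5, n_tasks = 2, s = 2, noise_sd = 0.3,
                        mode = "kernel-nonlinear",
                        kernel_source = kernel_spec("gaussian", 1),
                        seed = 46)
  expect_equal(gen_kernel_nonlinear(spk)$dataset$Y,
               gen_kernel_nonlinear(spk)$dataset$Y)

  spm <- synthetic_spec(m = 30, p = 8, n_tasks = 2, s = 4,
                        mode = "multimodal", block_sizes = c(5, 3),
                        seed = 47)
  m1 <- gen_multimodal(spm)
  expect_equal(m1$dataset$Y, gen_multimodal(spm)$dataset$Y)
  expect_named(m1$dataset$modality_blocks, c("modality_1", "modality_2"))
})

test_that("gen_linear has s shared-support rows and the implied SNR", {
  sp <- synthetic_spec(m = 400, p = 30, n_tasks = 4, s = 5, snr = 10,
                       seed = 48)
  sim <- gen_linear(sp)
  expect_length(sim$support, 5)
  active <- which(rowSums(abs(sim$theta)) > 0)
  expect_equal(sort(active), sim$support)
  # every task uses the same rows and coefficient magnitudes in [0.5, 1.5]
  for (t in 1:4) {
    expect_setequal(which(sim$theta[, t] != 0), sim$support)
  }
  mags <- abs(sim$theta[sim$support, ])
  expect_true(all(mags >= 0.5 & mags <= 1.5))
  # empirical variance-ratio SNR within 20 percent at this sample size
  signal <- sim$dataset$X %*% sim$theta
  noise <- sim$dataset$Y - signal
  snr_emp <- apply(signal, 2, var) / apply(noise, 2, var)
  expect_true(all(abs(snr_emp - 10) / 10 < 0.2))
})

test_that("kernel-nonlinear data is fit by the true kernel, not linearly", {
  spk <- synthetic_spec(m = 80, p = 6, n_tasks = 2, s = 2, noise_sd = 0,
                        mode = "kernel-nonlinear",
                        kernel_source = kernel_spec("gaussian", 1),
                        seed = 49)
  sim <- gen_kernel_nonlinear(spk)
  ds <- sim$dataset
  # noiseless data + the source kernel at small ridge: near-interpolation
  K <- gram_matrix(kernel_spec("gaussian", 1), ds$X)
  for (t in 1:2) {
    yhat <- ref_krr(K, ds$Y[, t], lam = 1e8)
    expect_lt(sqrt(mean((ds$Y[, t] - yhat)^2)), 1e-3)
  }
  # while a linear model leaves substantial training residual
  theta_ls <- solve(crossprod(ds$X), crossprod(ds$X, ds$Y))
  lin_res <- ds$Y - ds$X %*% theta_ls
  expect_gt(sqrt(mean(lin_res^2)), 0.1)
})

test_that("multimodal blocks each carry signal; zero extra block is inert", {
  spm <- synthetic_spec(m = 200, p = 20, n_tasks = 3, s = 4,
                        mode = "multimodal", block_sizes = c(12, 8),
                        snr = 5, seed = 50)
  sim <- gen_multimodal(spm)
  th <- sim$theta
  b1 <- sim$blocks[[1]]; b2 <- sim$blocks[[2]]
  expect_gt(sum(abs(th[b1, ])), 0)
  expect_gt(sum(abs(th[b2, ])), 0)
  # the two blocks carry equal signal variance per task
  v1 <- colSums(th[b1, ]^2)
  v2 <- colSums(th[b2, ]^2)
  expect_equal(v1, v2, tolerance = 1e-10)
  expect_equal(v1 + v2, rep(1, 3), tolerance = 1e-10)
})

test_that("write_simulation round-trips through load_dataset", {
  sp <- synthetic_spec(m = 20, p = 4, n_tasks = 2, s = 2, noise_sd = 0.5,
                       seed = 51)
  sim <- gen_linear(sp)
  prefix <- file.path(tempdir(), "simtest")
  paths <- write_simulation(sim, prefix)
  expect_true(all(file.exists(paths)))
  ds <- load_dataset(paths["features"], paths["targets"])
  expect_equal(unname(ds$X), unname(sim$dataset$X), tolerance = 1e-12)
  expect_equal(unname(ds$Y), unname(sim$dataset$Y), tolerance = 1e-12)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(sort(truth$support), sim$support)
  unlink(paths)
})
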