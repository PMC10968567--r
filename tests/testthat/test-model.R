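test_that("zero projections give uniform attention and mean-valued Z", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, seed = 1)
  params$wg[] <- 0; params$wf[] <- 0; params$bg[] <- 0; params$bf[] <- 0
  frame <- matrix(stats::rnorm(81), 9, 9)
  sa <- spatial_attention(frame, params)
  expect_equal(sa$attention, matrix(1 / 81, 81, 81))
  expect_equal(sa$Z, matrix(mean(frame), 9, 9))
})

test_that("attention rows always normalize; constant frames are fixed points", {
  cfg <- tiny_model_cfg()
  set.seed(2)
  for (i in 1:20) {
    params <- init_params(cfg, seed = i)
    frame <- matrix(stats::rnorm(81, sd = 2), 9, 9)
    sa <- spatial_attention(frame, params)
    expect_equal(rowSums(sa$attention), rep(1, 81), tolerance = 1e-6)
    expect_true(all(sa$attention >= 0))
  }
  const <- matrix(4.2, 9, 9)
  sa <- spatial_attention(const, init_params(cfg, seed = 3))
  expect_equal(sa$Z, const, tolerance = 1e-12)
  expect_error(spatial_attention(matrix(c(NA, rep(1, 80)), 9, 9),
                                 init_params(cfg, seed = 3)), "finite")
})

test_that("frame importance weights behave like a softmax over frames", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, seed = 4)
  single <- matrix(stats::rnorm(81), 81, 1)
  expect_equal(frame_importance(single, params), 1.0)
  same <- matrix(rep(stats::rnorm(81), 5), 81, 5)
  expect_equal(frame_importance(same, params), rep(0.2, 5),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:50) {
    Z <- matrix(stats::rnorm(81 * 4), 81, 4)
    a <- frame_importance(Z, params)
    expect_equal(sum(a), 1, tolerance = 1e-6)
    expect_true(all(a >= 0))
  }
  expect_error(frame_importance(matrix(0, 81, 0), params), "empty")
})

test_that("the steady-state map is the alpha-weighted frame combination", {
  set.seed(6)
  Z <- matrix(stats::rnorm(81 * 4), 81, 4)
  onehot <- c(0, 0, 1, 0)
  expect_equal(compute_ssam(Z, onehot), matrix(Z[, 3], 9, 9))
  expect_equal(compute_ssam(Z, rep(0.25, 4)), matrix(rowMeans(Z), 9, 9))
  # linearity against a direct summation oracle
  a <- c(0.1, 0.2, 0.3, 0.4)
  direct <- matrix(0, 9, 9)
  for (t in 1:4) direct <- direct + a[t] * matrix(3 * Z[, t], 9, 9)
  expect_equal(compute_ssam(3 * Z, a), direct, tolerance = 1e-12)
  expect_error(compute_ssam(Z, c(0.5, 0.5)), "alpha")
})

test_that("the CNN encoder preserves spatial size and respects zero inputs", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, seed = 7)
  out <- cnn_encode(matrix(stats::rnorm(81), 9, 9), "beta", params)
  expect_equal(dim(out), c(9, 9, cfg$cnn_filters[3]))
  zp <- params
  for (b in names(zp$conv)) {
    zp$conv[[b]]$c1[] <- 0; zp$conv[[b]]$c2[] <- 0; zp$conv[[b]]$c3[] <- 0
  }
  expect_equal(cnn_encode(matrix(0, 9, 9), "theta", zp),
               array(0, c(9, 9, cfg$cnn_filters[3])))
  expect_error(cnn_encode(matrix(0, 9, 9), "delta", params), "unknown band")
})

test_that("bands stay isolated until the ECA stage", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, seed = 8)
  tp <- rand_topo(T_n = 3, seed = 9)
  tp2 <- tp
  tp2$maps$theta <- tp$maps$theta + 0.5
  f1 <- ssam_forward(tp, params, cfg)
  f2 <- ssam_forward(tp2, params, cfg)
  for (b in c("alpha", "beta", "gamma")) {
    expect_identical(f1$ssam[[b]]$S, f2$ssam[[b]]$S)
    expect_identical(f1$ssam[[b]]$alpha, f2$ssam[[b]]$alpha)
  }
  expect_false(identical(f1$ssam$theta$S, f2$ssam$theta$S))
})

test_that("ECA kernel size follows the adaptive formula with odd rounding", {
  expect_identical(eca_kernel_size(32, 2, 1), 3L)
  expect_identical(eca_kernel_size(128, 2, 1), 5L)  # raw 4, tie rounds up
  expect_identical(eca_kernel_size(2, 2, 1), 1L)
  expect_error(eca_kernel_size(0), ">= 1")
})

test_that("ECA gates are sigmoidal and symmetric under symmetric input", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, seed = 10)
  f3 <- cfg$cnn_filters[3]
  enc <- lapply(ssam:::band_names(), function(b) {
    array(stats::rnorm(81 * f3), c(9, 9, f3))
  })
  names(enc) <- ssam:::band_names()
  eca <- eca_attend(enc, params)
  expect_true(all(eca$gates > 0 & eca$gates < 1))
  # constant input across channels + zero-sum kernel -> equal gates
  pz <- params
  if (length(pz$we) > 1) pz$we <- pz$we - mean(pz$we) else pz$we[] <- 0
  const <- lapply(enc, function(a) array(1, dim(a)))
  g2 <- eca_attend(const, pz)$gates
  # away from the boundary the zero-padding is invisible for constant input
  inner <- 2:(f3 - 1)
  expect_true(all(abs(g2[, inner] - g2[1, inner][1]) < 1e-12))
  expect_error(eca_attend(enc[c("theta", "alpha")], params), "missing band")
})

test_that("classification is a proper softmax with shift invariance", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, seed = 11)
  x <- stats::rnorm(ncol(params$Wd))
  expect_equal(classify_features(x, params), c(0.5, 0.5))  # Wd starts at 0
  set.seed(12)
  params2 <- params
  params2$Wd <- matrix(stats::rnorm(length(params$Wd), sd = 0.01),
                       nrow(params$Wd))
  for (i in 1:20) {
    p <- classify_features(stats::rnorm(ncol(params$Wd)), params2)
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
  params3 <- params2
  params3$bd <- params2$bd + 7
  expect_equal(classify_features(x, params3), classify_features(x, params2),
               tolerance = 1e-12)
  expect_error(classify_features(x[-1], params2), "does not match")
})

test_that("the loss combines clamped NLL with an L2 weight penalty", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, seed = 13)
  expect_equal(model_loss(c(1, 0), 0L, params, 0), 0)
  expect_equal(model_loss(c(0.5, 0.5), 1L, params, 0), log(2))
  expect_warning(l <- model_loss(c(0, 1), 0L, params, 0), "clamped")
  expect_equal(l, -log(1e-12))
  # all-ones weights: penalty = lambda * (number of weight entries)
  v <- rep(1, length(flatten_params(params)))
  ones <- unflatten_params(v, params)
  n_weights <- sum(ssam:::l2_mask(params))
  expect_equal(model_loss(c(1, 0), 0L, ones, 0.01), 0.01 * n_weights)
})

test_that("forward output is deterministic and batch-order invariant", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, seed = 14)
  tp <- rand_topo(T_n = 4, seed = 15)
  f1 <- ssam_forward(tp, params, cfg)
  f2 <- ssam_forward(tp, params, cfg)
  expect_identical(f1$probs, f2$probs)
  expect_equal(sum(f1$probs), 1, tolerance = 1e-6)
  expect_true(all(f1$probs >= 0))
  # no cross-trial coupling in the batched C++ path
  tpB <- rand_topo(T_n = 5, seed = 16)
  pAB <- predict_probs(list(tp, tpB), params, cfg)
  pBA <- predict_probs(list(tpB, tp), params, cfg)
  expect_equal(pAB, pBA[2:1, ], tolerance = 1e-12)
})

test_that("vectorized attention stages match the nested-loop oracle on toy grids", {
  cfg <- tiny_model_cfg(grid_size = 3)
  set.seed(17)
  for (draw in 1:10) {
    params <- init_params(cfg, seed = draw)
    T_n <- sample(1:3, 1)
    X <- matrix(stats::rnorm(9 * T_n, 1, 1), 9, T_n)
    orc <- oracle_ssam(X, params)
    Z <- vapply(seq_len(T_n), function(t) {
      as.vector(spatial_attention(matrix(X[, t], 3, 3), params)$Z)
    }, numeric(9))
    Z <- matrix(Z, 9, T_n)
    alpha <- frame_importance(Z, params)
    S <- compute_ssam(Z, alpha)
    expect_lt(max(abs(Z - orc$Z)), 1e-6)
    expect_lt(max(abs(alpha - orc$alpha)), 1e-6)
    expect_lt(max(abs(as.vector(S) - orc$S)), 1e-6)
  }
})

test_that("the C++ training kernel reproduces the R forward pass", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, seed = 18)
  v <- flatten_params(params)
  set.seed(19)
  params <- unflatten_params(v + stats::rnorm(length(v), sd = 0.05), params)
  tp <- rand_topo(T_n = 3, seed = 20)
  fw <- ssam_forward(tp, params, cfg)
  out <- ssam:::ssam_batch_cpp(ssam:::as_cpp_trials(list(tp)), 1L,
                               unclass(params), ssam:::cpp_cfg(cfg, params),
                               NULL, FALSE)
  expect_equal(as.vector(out$probs), fw$probs, tolerance = 1e-10)
  expect_equal(out$nll[1], -log(fw$probs[2]), tolerance = 1e-10)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, seed = 21)
  v <- flatten_params(params)
  set.seed(22)
  v <- v + stats::rnorm(length(v), sd = 0.05)
  params <- unflatten_params(v, params)
  tp <- rand_topo(T_n = 2, seed = 23)
  lam <- cfg$l2_lambda
  out <- ssam:::ssam_batch_cpp(ssam:::as_cpp_trials(list(tp)), 1L,
                               unclass(params), ssam:::cpp_cfg(cfg, params),
                               NULL, TRUE)
  gvec <- unlist(out$grads, use.names = FALSE) +
    2 * lam * v * ssam:::l2_mask(params)
  loss_at <- function(vv) {
    pp <- unflatten_params(vv, params)
    model_loss(ssam_forward(tp, pp, cfg)$probs, 1L, pp, lam)
  }
  set.seed(24)
  idx <- sample(length(v), 10)
  h <- 1e-5
  for (i in idx) {
    vp <- v; vp[i] <- vp[i] + h
    vm <- v; vm[i] <- vm[i] - h
    fd <- (loss_at(vp) - loss_at(vm)) / (2 * h)
    denom <- max(abs(fd), abs(gvec[i]))
    if (denom > 1e-6) {
      expect_lt(abs(fd - gvec[i]) / denom, 1e-4)
    } else {
      expect_lt(abs(fd - gvec[i]), 1e-8)
    }
  }
})

test_that("checkpoints round-trip and refuse foreign versions", {
  cfg <- tiny_model_cfg()
  params <- init_params(cfg, seed = 25)
  path <- file.path(tempdir(), "ckpt.rds")
  save_checkpoint(params, path)
  back <- load_checkpoint(path)
  expect_equal(unclass(back), unclass(params))
  expect_equal(attr(back, "config"), cfg)
  saveRDS(list(format_version = 99L, params = unclass(params)), path)
  expect_error(load_checkpoint(path), "version")
})
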