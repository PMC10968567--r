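# helper: fabricate a minimal ssam_forward with known column masses/gates
fake_output <- function(colmass_list, gates = NULL) {
  ssam <- lapply(colmass_list, function(m) list(colmass = m, S = m,
                                                alpha = 1))
  structure(list(probs = c(0.5, 0.5), ssam = ssam, gates = gates),
            class = "ssam_forward")
}

test_that("attention topomap thresholds behave at the extremes", {
  layout <- grid_layout()
  occ <- ssam:::occupied_indices(layout)
  m <- matrix(0, 9, 9)
  m[occ] <- seq(0.1, 1, length.out = 32)
  out <- fake_output(stats::setNames(replicate(4, m, simplify = FALSE),
                                     ssam:::band_names()))
  tm0 <- attention_topomap(list(out), threshold = 0)
  expect_equal(sum(tm0$mask), 32)
  tm1 <- attention_topomap(list(out), threshold = 1)
  expect_equal(sum(tm1$mask), 1)
  expect_equal(tm1$ranking$channel[1],
               montage_channels()[which.max(m[occ][match(occ, occ)])])
  # thresholding is idempotent: same threshold twice, same mask
  tm0b <- attention_topomap(list(out), threshold = 0)
  expect_identical(tm0$mask, tm0b$mask)
  expect_error(attention_topomap(list()), "empty")
})

test_that("attention topomap ranking tracks the column masses", {
  layout <- grid_layout()
  occ <- ssam:::occupied_indices(layout)
  m <- matrix(0, 9, 9)
  m[occ] <- stats::runif(32)
  top_chan <- montage_channels()[which.max(m[occ])]
  out <- fake_output(stats::setNames(replicate(4, m, simplify = FALSE),
                                     ssam:::band_names()))
  tm <- attention_topomap(list(out), threshold = 0.5)
  expect_equal(tm$ranking$channel[1], top_chan)
  expect_true(all(diff(tm$ranking$importance) <= 0))
  expect_true(all(tm$map[-occ] == 0))
})

test_that("band contribution shares form a simplex and detect symmetry", {
  gates_eq <- matrix(0.7, 4, 8, dimnames = list(ssam:::band_names(), NULL))
  out <- fake_output(stats::setNames(replicate(4, matrix(1, 9, 9),
                                               simplify = FALSE),
                                     ssam:::band_names()), gates = gates_eq)
  shares <- band_contributions(list(out, out))
  expect_equal(unname(shares), rep(0.25, 4), tolerance = 1e-9)
  expect_equal(sum(shares), 1, tolerance = 1e-9)
  gates2 <- gates_eq
  gates2["gamma", ] <- 0.9
  out2 <- fake_output(out$ssam |> lapply(`[[`, "colmass") |>
                        stats::setNames(ssam:::band_names()), gates = gates2)
  shares2 <- band_contributions(list(out2))
  expect_equal(names(which.max(shares2)), "gamma")
  out_ng <- out
  out_ng$gates <- NULL
  expect_error(band_contributions(list(out_ng)), "gates")
})

test_that("frame-to-map correlation honors exactness, location invariance and nulls", {
  layout <- grid_layout()
  occ <- ssam:::occupied_indices(layout)
  smap <- matrix(0, 9, 9)
  smap[occ] <- stats::rnorm(32)
  maps <- stats::setNames(replicate(4, smap, simplify = FALSE),
                          ssam:::band_names())
  tp <- rand_topo(T_n = 2, seed = 50)
  for (b in ssam:::band_names()) {
    tp$maps[[b]][, , 1] <- smap            # identical frame
    tp$maps[[b]][, , 2] <- smap + 5        # shifted frame (occupied cells)
  }
  res <- temporal_state_correlation(tp, maps, threshold = 0.6)
  for (b in ssam:::band_names()) {
    expect_equal(res$raw[[b]][1, 1], 1.0, tolerance = 1e-10)
    expect_equal(res$raw[[b]][2, 1], 1.0, tolerance = 1e-10)
  }
  # independent noise frames: signed correlations center on zero and |r|
  # sits at the 32-dimensional null level E|r| = sqrt(2/(31*pi)) ~ 0.14
  set.seed(51)
  tpn <- rand_topo(T_n = 400, seed = 52)
  resn <- temporal_state_correlation(tpn, maps, threshold = 0.6)
  expect_lt(abs(mean(resn$raw$alpha[, 1])), 0.05)
  expect_lt(mean(abs(resn$raw$alpha[, 1])), 0.2)
  # thresholded copy zeroes sub-threshold values, raw retained
  expect_true(all(resn$thresholded$alpha[resn$raw$alpha < 0.6 &
                                           !is.na(resn$raw$alpha)] == 0))
  # zero-variance frame recorded as missing
  tpz <- rand_topo(T_n = 1, seed = 53)
  tpz$maps$theta[, , 1] <- map_to_grid(rep(2, 32))
  resz <- temporal_state_correlation(tpz, maps)
  expect_true(is.na(resz$raw$theta[1, 1]))
})

test_that("connectivity matrices are symmetric with exact self- and twin-correlation", {
  set.seed(54)
  de <- list(de = list(alpha = matrix(stats::rnorm(32 * 30), 32, 30)),
             channel_names = montage_channels(), window_s = 1)
  class(de) <- "de_sequence"
  de$de$alpha[2, ] <- de$de$alpha[1, ]          # duplicated channel pair
  res <- electrode_connectivity(list(de), n_perm = 50, seed = 55)
  r <- res$r$alpha
  expect_equal(diag(r), rep(1, 32), ignore_attr = TRUE)
  expect_equal(r[1, 2], 1)
  expect_lt(max(abs(r - t(r)), na.rm = TRUE), 1e-12)
  expect_true(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))
  p <- res$p$alpha
  expect_true(all(p[!is.na(p)] > 0 & p[!is.na(p)] <= 1))
  # constant channel recorded as missing
  de2 <- de
  de2$de$alpha[5, ] <- 3
  res2 <- electrode_connectivity(list(de2), n_perm = 20, seed = 56)
  expect_true(all(is.na(res2$r$alpha[5, -5])))
})

test_that("circular-shift null keeps the connectivity false-positive rate near alpha", {
  set.seed(57)
  rates <- replicate(6, {
    de <- list(de = list(alpha = matrix(stats::rnorm(32 * 250), 32, 250)),
               channel_names = montage_channels(), window_s = 1)
    class(de) <- "de_sequence"
    res <- electrode_connectivity(list(de), n_perm = 400,
                                  seed = sample.int(1e6, 1))
    p <- res$p$alpha[upper.tri(res$p$alpha)]
    mean(p < 0.05)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.025)
})

test_that("edge lists respect the thresholds", {
  set.seed(58)
  de <- list(de = list(alpha = matrix(stats::rnorm(32 * 40), 32, 40)),
             channel_names = montage_channels(), window_s = 1)
  class(de) <- "de_sequence"
  de$de$alpha[2, ] <- de$de$alpha[1, ] + stats::rnorm(40, sd = 0.01)
  res <- electrode_connectivity(list(de), n_perm = 100, seed = 59)
  edges <- connectivity_edges(res, r_threshold = 0.9)
  expect_true(all(abs(edges$r) >= 0.9))
  expect_true(any(edges$electrode_a == "FP1" & edges$electrode_b == "FPZ"))
})

test_that("significance screen is calibrated under the null and powered when planted", {
  set.seed(60)
  # null: identical class distributions on synthetic DE summaries
  feats <- array(stats::rnorm(60 * 32 * 4), c(60, 32, 4),
                 dimnames = list(NULL, montage_channels(),
                                 ssam:::band_names()))
  labels <- rep(c(0L, 1L), 30)
  tab <- significance_screen(feats, labels, n_perm = 2000, seed = 61)
  expect_equal(nrow(tab), 128)
  expect_true(all(tab$p > 0 & tab$p <= 1))
  expect_equal(mean(tab$significant), 0.05, tolerance = 0.05)
  expect_true("p_bh" %in% names(tab))
  # planted shift at FP1/alpha
  feats2 <- feats
  feats2[labels == 1, "FP1", "alpha"] <-
    feats2[labels == 1, "FP1", "alpha"] + 2
  tab2 <- significance_screen(feats2, labels, n_perm = 2000, seed = 62)
  cell <- tab2[tab2$electrode == "FP1" & tab2$band == "alpha", ]
  expect_true(cell$significant)
  # alpha_level 0 -> nothing flagged
  tab3 <- significance_screen(feats, labels, alpha_level = 0,
                              n_perm = 500, seed = 63)
  expect_false(any(tab3$significant))
  expect_error(significance_screen(feats[1:8, , ], labels[1:8][c(1:4, 1:4)] * 0,
                                   n_perm = 100), "both classes")
})

test_that("permutation p-values are stable in the number of permutations", {
  set.seed(64)
  feats <- array(stats::rnorm(40 * 32 * 4), c(40, 32, 4),
                 dimnames = list(NULL, montage_channels(),
                                 ssam:::band_names()))
  labels <- rep(c(0L, 1L), 20)
  p1 <- significance_screen(feats, labels, n_perm = 2000, seed = 65)$p
  p2 <- significance_screen(feats, labels, n_perm = 8000, seed = 66)$p
  # differences bounded by a few Monte Carlo standard errors
  se <- sqrt(p1 * (1 - p1) / 2000)
  expect_true(all(abs(p1 - p2) < 5 * pmax(se, 0.01)))
})
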