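# Mixture model: initialisation moments, EM fixed points and monotonicity,
# bias-field recovery, outlier map, split-and-merge component recovery.

test_that("initialisation reproduces atlas-weighted moments exactly", {
  ph <- cached_phantom("clean0", small_spec(seed = 1, target_lesion_ml = 0))
  atlas <- make_pseudo_atlas(ph$tissue_labels, ph$voxel_mm, smoothing_mm = 0)
  imgs <- list(t1 = ph$t1_noiseless, flair = ph$flair_noiseless)
  Y <- masked_matrix(imgs, ph$head_mask)
  A <- masked_matrix(atlas, ph$head_mask)
  model <- init_model(Y, A, classes = c("GM", "WM", "CSF", "nonbrain"))
  tm <- ph$spec$tissue_means
  get_mean <- function(cl) {
    k <- which(vapply(model$components, `[[`, "", "class") == cl &
               vapply(model$components, `[[`, "", "part") == "inlier")
    model$components[[k]]$mean
  }
  expect_equal(unname(get_mean("WM")), unname(tm["WM", ]))
  expect_equal(unname(get_mean("CSF")), unname(tm["CSF", ]))
  expect_equal(unname(get_mean("nonbrain")), unname(tm["nonbrain", ]))
})

test_that("a uniform two-class atlas on one modality yields the global mean twice", {
  set.seed(3)
  Y <- matrix(stats::rnorm(500, 50, 4), ncol = 1)
  A <- matrix(0.5, 500, 2)
  model <- init_model(Y, A, classes = c("a", "b"))
  mus <- vapply(model$components[c(1, 3)], function(cp) cp$mean, 0)
  expect_equal(mus, rep(mean(Y), 2))
})

test_that("a class with zero atlas mass is reported by name", {
  Y <- matrix(stats::rnorm(100), ncol = 1)
  A <- cbind(rep(1, 100), rep(0, 100))
  expect_error(init_model(Y, A, classes = c("GM", "WM")), "WM")
})

test_that("single class, single component EM lands on the sample moments", {
  set.seed(9)
  Y <- cbind(stats::rnorm(2000, 100, 5), stats::rnorm(2000, 50, 3))
  colnames(Y) <- c("t1", "flair")
  A <- matrix(1, 2000, 1)
  model <- init_model(Y, A, classes = "WM", outlier_fraction = 0)
  fit <- fit_em(model, Y, A, tol = 1e-12, max_iter = 50)
  cp <- fit$model$components[[1]]
  mu_hat <- colMeans(Y)
  S_hat <- crossprod(sweep(Y, 2, mu_hat)) / nrow(Y)   # biased form
  expect_equal(unname(cp$mean), unname(mu_hat), tolerance = 1e-10)
  expect_equal(unname(cp$cov), unname(S_hat), tolerance = 1e-10)
})

test_that("infinite tolerance stops after one EM iteration", {
  set.seed(10)
  Y <- matrix(stats::rnorm(300, 10, 2), ncol = 1)
  A <- matrix(1, 300, 1)
  fit <- fit_em(init_model(Y, A, classes = "WM"), Y, A, tol = Inf)
  expect_equal(fit$n_iterations, 1L)
})

test_that("EM recovers well-separated class means and is monotone", {
  means <- rbind(c(100, 100), c(150, 100), c(100, 150), c(150, 150))
  dat <- make_class_data(2500, means, sds = rep(5, 4), seed = 21)
  model <- init_model(dat$Y, dat$A)
  fit <- fit_em(model, dat$Y, dat$A, tol = 1e-7, max_iter = 80)
  for (c in 1:4) {
    k <- which(vapply(fit$model$components, `[[`, "", "class") ==
                 fit$model$classes[c] &
               vapply(fit$model$components, `[[`, "", "part") == "inlier")
    err <- abs(fit$model$components[[k]]$mean - means[c, ]) / means[c, ]
    expect_lt(max(err), 0.02)
  }
  expect_true(all(diff(fit$ll_trace) >= -1e-8 * abs(fit$ll_trace[-1])))
})

test_that("responsibilities are a per-voxel partition of unity", {
  dat <- make_class_data(400, rbind(c(10, 10), c(30, 30)), sds = c(2, 2),
                         seed = 5)
  fit <- fit_em(init_model(dat$Y, dat$A[, 1:2]), dat$Y, dat$A[, 1:2],
                tol = 1e-6, max_iter = 30)
  expect_lt(max(abs(rowSums(fit$responsibilities) - 1)), 1e-6)
})

test_that("component relabelling changes neither likelihood nor outlier map", {
  dat <- make_class_data(400, rbind(c(10, 10), c(30, 30)), sds = c(2, 2),
                         seed = 6)
  fit <- fit_em(init_model(dat$Y, dat$A), dat$Y, dat$A, tol = 1e-6,
                max_iter = 30)
  perm_model <- fit$model
  perm_model$components <- rev(perm_model$components)
  fit2 <- fit_em(perm_model, dat$Y, dat$A, tol = Inf)  # single E-step view
  expect_equal(fit2$ll_trace[1], fit$log_likelihood, tolerance = 1e-6)
  s1 <- initial_outlier_map(fit, dat$Y, dat$A)
  f_perm <- fit; f_perm$model <- perm_model
  s2 <- initial_outlier_map(f_perm, dat$Y, dat$A)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("the initial outlier map is the squared Mahalanobis distance", {
  # closed form: 1 modality, mean 100, variance 25, intensity 110 -> 4
  Y <- matrix(c(100, 110), ncol = 1)
  A <- matrix(1, 2, 1)
  model <- init_model(Y, A, classes = "WM")
  model$components[[1]]$mean <- 100
  model$components[[1]]$cov <- matrix(25)
  fit <- structure(list(model = model), class = "model_fit")
  s <- initial_outlier_map(fit, Y, A)
  expect_equal(s, c(0, 4))
})

test_that("the outlier map equals a per-voxel quadratic-form oracle", {
  dat <- make_class_data(300, rbind(c(10, 10), c(30, 30)), sds = c(2, 3),
                         seed = 8)
  fit <- fit_em(init_model(dat$Y, dat$A), dat$Y, dat$A, tol = 1e-6,
                max_iter = 30)
  s <- initial_outlier_map(fit, dat$Y, dat$A)
  cls <- vapply(fit$model$components, `[[`, "", "class")
  parts <- vapply(fit$model$components, `[[`, "", "part")
  oracle <- vapply(seq_len(nrow(dat$Y)), function(v) {
    ci <- which.max(dat$A[v, ])
    ks <- which(cls == fit$model$classes[ci] & parts == "inlier")
    min(vapply(ks, function(k) {
      cp <- fit$model$components[[k]]
      d <- dat$Y[v, ] - cp$mean
      as.numeric(t(d) %*% solve(cp$cov) %*% d)
    }, 0))
  }, 0)
  expect_equal(s, oracle, tolerance = 1e-8)
})

test_that("an unbiased image yields a zero fitted bias field", {
  # deep GM shares the GM intensity here so every class is constant and the
  # responsibility-weighted prediction is exact
  tm <- default_tissue_means()
  tm["deepGM", ] <- tm["GM", ]
  ph <- generate_phantom(small_spec(seed = 1, target_lesion_ml = 0,
                                    tissue_means = tm))
  atlas <- make_pseudo_atlas(ph$tissue_labels, ph$voxel_mm, smoothing_mm = 0)
  imgs <- list(t1 = ph$t1_noiseless, flair = ph$flair_noiseless)
  Y <- masked_matrix(imgs, ph$head_mask)
  A <- masked_matrix(atlas, ph$head_mask)
  model <- init_model(Y, A)
  R <- matrix(0, nrow(Y), length(model$components))
  cls <- vapply(model$components, `[[`, "", "class")
  parts <- vapply(model$components, `[[`, "", "part")
  for (ci in seq_len(ncol(A)))
    R[, which(cls == model$classes[ci] & parts == "inlier")] <- A[, ci]
  for (ord in 0:2) {
    bias <- estimate_bias_field(imgs, R, model, ph$head_mask, order = ord)
    expect_lt(max(abs(bias$fields$t1[ph$head_mask])), 1e-6)
    expect_lt(max(abs(bias$fields$flair[ph$head_mask])), 1e-6)
  }
})

test_that("a planted low-order bias field is recovered", {
  tm <- default_tissue_means()
  tm["deepGM", ] <- tm["GM", ]
  ph <- generate_phantom(small_spec(seed = 31, target_lesion_ml = 0,
                                    bias_amplitude = 0, noise_sd = 0,
                                    tissue_means = tm))
  set.seed(77)
  degraded <- apply_bias_and_noise(
    list(t1 = ph$t1_noiseless, flair = ph$flair_noiseless),
    ph$brain_mask, ph$voxel_mm, bias_amplitude = 0.25, noise_sd = 0)
  atlas <- make_pseudo_atlas(ph$tissue_labels, ph$voxel_mm, smoothing_mm = 0)
  Y <- masked_matrix(degraded$images, ph$head_mask)
  A <- masked_matrix(atlas, ph$head_mask)
  model <- init_model(Y, A)
  fit <- fit_em(model, Y, A, tol = 1e-5, max_iter = 40)
  bias <- estimate_bias_field(degraded$images, fit$responsibilities,
                              fit$model, ph$head_mask, order = 3)
  planted <- log(degraded$bias$flair[ph$brain_mask])
  fitted <- bias$fields$flair[ph$brain_mask]
  expect_gt(stats::cor(planted, fitted), 0.95)
})

test_that("order-0 bias is the single mean residual", {
  set.seed(12)
  arr <- array(exp(stats::rnorm(4^3, 0.2, 0.05)) * 100, c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  Y <- masked_matrix(list(m = arr), mask)
  model <- init_model(Y, matrix(1, 64, 1), classes = "WM",
                      outlier_fraction = 0)
  R <- matrix(1, 64, 1)
  bias <- estimate_bias_field(list(m = arr), R, model, mask, order = 0)
  resid <- log(Y[, 1]) - log(model$components[[1]]$mean[1])
  expect_equal(unique(round(bias$fields$m[mask], 10)),
               round(mean(resid), 10))
})

test_that("split-and-merge keeps one component for truly Gaussian classes", {
  for (s in 1:5) {
    set.seed(100 + s)
    Y <- cbind(stats::rnorm(1500, 100, 5), stats::rnorm(1500, 80, 5))
    colnames(Y) <- c("t1", "flair")
    A <- matrix(1, 1500, 1)
    fit <- fit_em(init_model(Y, A, classes = "WM", outlier_fraction = 0),
                  Y, A, tol = 1e-6, max_iter = 40)
    out <- split_merge_search(fit, Y, A, max_components_per_class = 3)
    n_inlier <- sum(vapply(out$model$components, `[[`, "", "part") == "inlier")
    expect_equal(n_inlier, 1L)
  }
})

test_that("split-and-merge discovers a well-separated two-component class", {
  hits <- 0L
  for (s in 1:5) {
    set.seed(200 + s)
    Y <- rbind(cbind(stats::rnorm(1200, 100, 4), stats::rnorm(1200, 80, 4)),
               cbind(stats::rnorm(1200, 130, 4), stats::rnorm(1200, 110, 4)))
    colnames(Y) <- c("t1", "flair")
    A <- matrix(1, 2400, 1)
    fit <- fit_em(init_model(Y, A, classes = "WM", outlier_fraction = 0),
                  Y, A, tol = 1e-6, max_iter = 40)
    out <- split_merge_search(fit, Y, A, max_components_per_class = 3)
    n_inlier <- sum(vapply(out$model$components, `[[`, "", "part") == "inlier")
    hits <- hits + (n_inlier == 2L)
  }
  expect_gte(hits, 4L)
})

test_that("a component cap of one returns the input structure unchanged", {
  set.seed(13)
  Y <- matrix(stats::rnorm(400, 10, 1), ncol = 1)
  A <- matrix(1, 400, 1)
  fit <- fit_em(init_model(Y, A, classes = "WM"), Y, A, tol = 1e-6,
                max_iter = 20)
  out <- split_merge_search(fit, Y, A, max_components_per_class = 1)
  expect_identical(out$model, fit$model)
})

test_that("fitted means agree with an independent mixture implementation", {
  # cross-check against mclust on a one-class two-component problem
  set.seed(55)
  Y <- rbind(cbind(stats::rnorm(800, 100, 4), stats::rnorm(800, 80, 4)),
             cbind(stats::rnorm(800, 130, 4), stats::rnorm(800, 110, 4)))
  colnames(Y) <- c("t1", "flair")
  A <- matrix(1, 1600, 1)
  fit <- fit_em(init_model(Y, A, classes = "WM", outlier_fraction = 0),
                Y, A, tol = 1e-7, max_iter = 60)
  fit <- split_merge_search(fit, Y, A, max_components_per_class = 2)
  ours <- t(vapply(fit$model$components[
    vapply(fit$model$components, `[[`, "", "part") == "inlier"],
    `[[`, numeric(2), "mean"))
  ours <- ours[order(ours[, 1]), , drop = FALSE]
  suppressMessages(library(mclust))
  mc <- Mclust(Y, G = 2, modelNames = "VVV", verbose = FALSE)
  theirs <- t(mc$parameters$mean)[order(mc$parameters$mean[1, ]), ]
  expect_equal(unname(ours), unname(theirs), tolerance = 0.05)
})
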