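# Lesion extraction: outlierness, connectivity classification, two-threshold
# candidate selection with rescue, false-positive rules, volume integration.

# a small converged fit with a deliberate hyperintense cluster
make_lesion_fit <- function(seed = 1, n = 800, n_out = 60) {
  set.seed(seed)
  Y <- rbind(cbind(stats::rnorm(n, 140, 5), stats::rnorm(n, 100, 5)),
             cbind(stats::rnorm(n_out, 100, 5), stats::rnorm(n_out, 160, 5)))
  colnames(Y) <- c("t1", "flair")
  A <- matrix(1, nrow(Y), 1)
  model <- init_model(Y, A, classes = "WM")
  fit <- fit_em(model, Y, A, tol = 1e-6, max_iter = 60)
  list(fit = fit, Y = Y, A = A, n = n, n_out = n_out)
}

test_that("outlierness is zero at the WM mean and for hypointense outliers", {
  d <- make_lesion_fit()
  s <- compute_outlierness(d$fit, d$Y)
  expect_true(all(is.finite(s)) && all(s >= 0))
  # typical WM voxels are inlier-dominated -> score 0
  expect_true(mean(s[seq_len(d$n)] == 0) > 0.95)
  # the hyperintense cluster scores high
  expect_true(mean(s[d$n + seq_len(d$n_out)] > 8) > 0.9)
  # a synthetic hypointense outlier (FLAIR below the WM mean) is excluded
  Y2 <- rbind(d$Y, c(60, 40))
  A2 <- rbind(d$A, 1)
  fit2 <- d$fit
  fit2$responsibilities <- rbind(
    fit2$responsibilities,
    c(0, 1)[match(comp_parts(fit2$model), c("inlier", "outlier"))])
  s2 <- compute_outlierness(fit2, Y2)
  expect_equal(s2[length(s2)], 0)
})

test_that("outlierness equals a brute-force quadratic form where candidate", {
  d <- make_lesion_fit(seed = 2)
  s <- compute_outlierness(d$fit, d$Y)
  model <- d$fit$model
  ks <- which(vapply(model$components, `[[`, "", "class") == "WM" &
              vapply(model$components, `[[`, "", "part") == "inlier")
  wm_flair <- sum(vapply(model$components[ks], function(cp)
    cp$weight * cp$mean[2], 0)) /
    sum(vapply(model$components[ks], `[[`, 0, "weight"))
  parts <- vapply(model$components, `[[`, "", "part")
  r_out <- rowSums(d$fit$responsibilities[, parts == "outlier", drop = FALSE])
  oracle <- vapply(seq_len(nrow(d$Y)), function(v) {
    if (r_out[v] <= 0.5 || d$Y[v, 2] <= wm_flair) return(0)
    min(vapply(ks, function(k) {
      cp <- model$components[[k]]
      dd <- d$Y[v, ] - cp$mean
      as.numeric(t(dd) %*% solve(cp$cov) %*% dd)
    }, 0))
  }, 0)
  expect_equal(s, oracle, tolerance = 1e-8)
})

test_that("18-then-6 classification distinguishes edge and corner adjacency", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE      # edge-adjacent pair
  cc <- classify_components(m)
  expect_equal(max(cc$label18), 1L)
  expect_equal(max(cc$label6), 2L)
  expect_equal(cc$parent18, c(1L, 1L))

  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE    # corner-adjacent pair
  cc2 <- classify_components(m2)
  expect_equal(max(cc2$label18), 2L)

  m3 <- array(FALSE, c(4, 4, 4))
  m3[1, 1, 1] <- TRUE; m3[2, 1, 1] <- TRUE    # face-adjacent pair
  cc3 <- classify_components(m3)
  expect_equal(max(cc3$label18), 1L)
  expect_equal(max(cc3$label6), 1L)
})

test_that("component labelling matches a flood-fill oracle", {
  set.seed(77)
  for (conn in c(6, 18, 26)) {
    m <- array(stats::runif(20^3) < 0.2, c(20, 20, 20))
    expect_true(same_partition(label_components(m, conn),
                               oracle_components(m, conn)))
  }
})

test_that("candidate selection respects threshold and connectivity", {
  s <- array(0, c(8, 8, 8))
  expect_equal(nrow(select_candidates(s + 0.0, T = 5)$table), 0)
  s[2, 2, 2] <- 6; s[3, 2, 2] <- 7            # face-adjacent pair
  s[6, 2, 2] <- 9                             # two voxels away
  cand <- select_candidates(s, T = 5)
  expect_equal(nrow(cand$table), 2)
  expect_error(select_candidates(s, T = 0), "T must be > 0")
})

test_that("primary candidates grow monotonically as T decreases", {
  set.seed(5)
  s <- array(stats::rexp(12^3, 1 / 4), c(12, 12, 12))
  masks <- lapply(c(10, 8, 6, 4), function(T) select_candidates(s, T)$mask)
  for (i in 1:3)
    expect_true(all(masks[[i]] <= masks[[i + 1]]))
})

test_that("clusters under 60 voxels are rescued at two-thirds threshold", {
  T <- 9
  s <- array(0, c(10, 10, 30))
  s[2:4, 2:4, 2:4] <- T + 1                       # primary block
  s[2, 2, 10 + (1:20)] <- T * 0.75                # 20-voxel line, sub-T
  cand <- select_candidates(s, T)
  expect_equal(sum(cand$mask), 27)
  resc <- rescue_small_clusters(s, cand, T)
  expect_equal(sum(resc$mask), 47)
  expect_true(all(resc$table$pass[resc$table$size == 20] == "rescued"))
  # primary candidates never change
  expect_true(all(resc$mask[cand$mask]))
})

test_that("the 59/60 voxel rescue boundary is strict", {
  T <- 9
  base <- array(0, c(80, 6, 6))
  base[1:3, 1:3, 1:3] <- T + 1                    # a primary cluster
  s59 <- base; s59[10 + (1:59), 2, 2] <- T * 0.7
  s60 <- base; s60[10 + (1:60), 2, 2] <- T * 0.7
  r59 <- rescue_small_clusters(s59, select_candidates(s59, T), T)
  r60 <- rescue_small_clusters(s60, select_candidates(s60, T), T)
  expect_equal(sum(r59$rescued_mask), 59)
  expect_equal(sum(r60$rescued_mask), 0)
  # clusters entirely below 2T/3 are never rescued
  slow <- base; slow[10 + (1:10), 2, 2] <- T * 0.5
  rlow <- rescue_small_clusters(slow, select_candidates(slow, T), T)
  expect_equal(sum(rlow$rescued_mask), 0)
})

test_that("rescued components never intersect primary components", {
  set.seed(9)
  for (i in 1:5) {
    s <- array(stats::rexp(12^3, 1 / 3), c(12, 12, 12))
    T <- 8
    cand <- select_candidates(s, T)
    resc <- rescue_small_clusters(s, cand, T)
    expect_equal(sum(resc$rescued_mask & cand$mask), 0)
    tab <- resc$table
    expect_true(all(tab$size[tab$pass == "rescued"] < 60))
  }
})

test_that("two-pass selection equals a brute-force set construction", {
  set.seed(31)
  s <- array(stats::rexp(10^3, 1 / 3), c(10, 10, 10))
  T <- 7
  resc <- rescue_small_clusters(s, select_candidates(s, T), T)
  # oracle: primary voxels, plus low-threshold components (18-conn groups
  # refined by 6-conn) that are small and primary-free
  primary <- s >= T
  low <- s >= 2 * T / 3
  lab6 <- oracle_components(low, 6)
  add <- array(FALSE, dim(s))
  for (l in seq_len(max(lab6))) {
    vox <- lab6 == l
    if (sum(vox) < 60 && !any(primary[vox])) add <- add | vox
  }
  expect_identical(resc$mask, primary | add)
})

test_that("false-positive rules remove extracranial, CSF and dark clusters", {
  d <- make_lesion_fit(seed = 3)
  dm <- c(12, 12, 12)
  mask <- array(FALSE, dm)
  mask[which(array(seq_len(prod(dm)), dm) <= nrow(d$Y))] <- TRUE
  # three synthetic candidate clusters in distinct corners
  score <- array(0, dm)
  score[2:3, 2:3, 2:3] <- 50       # inside brain, hyperintense -> keep
  score[9:10, 2:3, 2:3] <- 50      # outside the brain mask -> drop
  score[2:3, 9:10, 2:3] <- 50      # in CSF -> drop
  cand <- select_candidates(score, T = 6)
  brain <- array(TRUE, dm); brain[8:12, , ] <- FALSE
  csf <- array(0, dm); csf[, 8:12, ] <- 1
  flair <- array(150, dm)          # every cluster hyperintense on FLAIR
  lesion <- correct_false_positives(cand, d$fit, flair, mask,
                                    brain_mask = brain, csf_prior = csf,
                                    supratentorial = array(TRUE, dm))
  tab <- lesion$table
  expect_equal(sort(unique(tab$removed_by)), sort(c("", "csf", "outside_brain")))
  # dark cluster test: FLAIR at CSF level
  flair2 <- array(30, dm)
  lesion2 <- correct_false_positives(cand, d$fit, flair2, mask,
                                     brain_mask = brain, csf_prior = csf,
                                     supratentorial = array(TRUE, dm))
  expect_true(all(lesion2$prob == 0))
  expect_error(correct_false_positives(cand, d$fit, flair, mask,
                                       brain_mask = NULL, csf_prior = csf,
                                       supratentorial = array(TRUE, dm)),
               "brain_mask")
})

test_that("volume integration is exact arithmetic", {
  m <- array(0, c(10, 10, 10))
  m[seq_len(100)] <- 1
  expect_equal(integrate_volume(m, c(1, 1, 5)), 0.5)
  p <- array(0, c(5, 5, 5))
  p[1:2] <- 0.5
  expect_equal(integrate_volume(p, c(1, 1, 1)), 0.001)
  expect_equal(integrate_volume(array(0, c(3, 3, 3)), c(2, 2, 2)), 0)
})

test_that("a planted deep lesion survives the full extraction chain", {
  ph <- cached_phantom("p1", small_spec(seed = 1))
  atlas <- make_pseudo_atlas(ph$tissue_labels, ph$voxel_mm, 2)
  seg <- segment_wmh(ph$t1, ph$flair, atlas, mask = ph$head_mask,
                     brain_mask = ph$brain_mask, voxel_mm = ph$voxel_mm,
                     max_components_per_class = 2)
  expect_gt(dice(seg$lesion_mask, ph$truth_lesions), 0.7)
  truth_ml <- integrate_volume(ph$truth_lesions * 1, ph$voxel_mm)
  expect_lt(abs(seg$volume_ml - truth_ml) / truth_ml, 0.25)
})
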