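## Inlier/outlier multivariate Gaussian mixture over tissue classes with
## atlas priors, additive (log-domain) polynomial bias correction and
## split-and-merge model selection.
##
## The model for a voxel v with intensities y_v is
##   p(y_v) = sum_c a_vc sum_{j in c} pi_cj N(y_v; mu_cj, Sigma_cj)
## where a_vc are per-voxel atlas class priors and each class c carries one
## or more inlier components plus one broad outlier component. Candidate
## lesions live in the outlier part of the white-matter class.

MODEL_CLASSES <- c("GM", "WM", "CSF", "nonbrain")

new_component <- function(class, part, weight, mean, cov) {
  list(class = class, part = part, weight = weight,
       mean = as.numeric(mean), cov = as.matrix(cov))
}

## conditional regularisation: only touch covariances that are numerically
## degenerate, so exact EM monotonicity is preserved in the regular case
regularise_cov <- function(cov, warn = TRUE) {
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  floor_ev <- max(1e-6 * sum(abs(diag(cov))) / nrow(cov), 1e-8)
  if (min(ev) <= 1e-10 * max(1, mean(abs(diag(cov))))) {
    if (warn) warning("singular covariance regularised with eps*I")
    ## lift the spectrum so the smallest eigenvalue reaches the floor
    cov <- cov + diag(floor_ev - min(min(ev), 0), nrow(cov))
  }
  cov
}

mvn_logdensity <- function(Y, mean, cov) {
  M <- ncol(Y)
  ch <- chol(cov)
  P <- chol2inv(ch)
  Xc <- sweep(Y, 2, mean)
  q <- rowSums((Xc %*% P) * Xc)
  -0.5 * (M * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

sq_mahalanobis <- function(Y, mean, cov) {
  Xc <- sweep(Y, 2, mean)
  P <- chol2inv(chol(cov))
  rowSums((Xc %*% P) * Xc)
}

#' Extract masked voxel intensities as a matrix
#'
#' @param images Named list of 3-D intensity arrays (modalities).
#' @param mask Logical 3-D array.
#' @return Numeric matrix, one row per mask voxel, one column per modality.
#' @export
masked_matrix <- function(images, mask) {
  idx <- which(mask != 0)
  if (!length(idx)) stop("mask is empty")
  out <- vapply(images, function(im) im[idx], numeric(length(idx)))
  colnames(out) <- names(images)
  out
}

atlas_matrix <- function(atlas, mask) {
  A <- masked_matrix(atlas, mask)
  A / rowSums(A)
}

#' Initialise the tissue mixture from atlas-weighted moments
#'
#' One inlier component per class with mean/covariance equal to the
#' atlas-weighted sample moments, plus one broad outlier component per class
#' (covariance `kappa` times the inlier covariance) holding a small initial
#' weight.
#'
#' @param Y Voxel-by-modality intensity matrix (see [masked_matrix()]).
#' @param A Voxel-by-class atlas prior matrix (rows sum to 1).
#' @param classes Class names (columns of `A`).
#' @param outlier_fraction Initial within-class outlier weight.
#' @param kappa Outlier covariance inflation factor.
#' @return Object of class `tissue_model`.
#' @export
init_model <- function(Y, A, classes = colnames(A),
                       outlier_fraction = 0.01, kappa = 10) {
  if (is.null(classes)) classes <- MODEL_CLASSES[seq_len(ncol(A))]
  if (abs(max(rowSums(A)) - 1) > 1e-6 || abs(min(rowSums(A)) - 1) > 1e-6)
    stop("atlas rows must sum to 1")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  comps <- list()
  for (ci in seq_along(classes)) {
    w <- A[, ci]
    sw <- sum(w)
    if (sw <= 0)
      stop(sprintf("class '%s' has zero total atlas mass", classes[ci]))
    mu <- colSums(w * Y) / sw
    Xc <- sweep(Y, 2, mu)
    S <- crossprod(Xc * sqrt(w)) / sw
    S <- regularise_cov(S, warn = FALSE)
    comps[[length(comps) + 1L]] <-
      new_component(classes[ci], "inlier", 1 - outlier_fraction, mu, S)
    if (outlier_fraction > 0)
      comps[[length(comps) + 1L]] <-
        new_component(classes[ci], "outlier", outlier_fraction, mu, kappa * S)
  }
  structure(list(components = comps, classes = classes,
                 n_modalities = ncol(Y), modalities = colnames(Y)),
            class = "tissue_model")
}

#' Trim atypical voxels out of the initial inlier moments
#'
#' The raw atlas-weighted moments include any lesions sitting inside a
#' class's atlas support, inflating the inlier covariance enough that a
#' heavy lesion load can be absorbed as normal tissue. Iterated trimmed
#' re-estimation (an MCD-style fixed point) recomputes each inlier's mean
#' and covariance using only the voxels within the `quantile` chi-square
#' ball of the current estimate until the mean stabilises, converging onto
#' the dominant (normal-tissue) mode of the class; outlier covariances are
#' re-inflated from the tightened inlier ones.
#'
#' @param model A `tissue_model` fresh from [init_model()].
#' @param Y,A Intensity and atlas matrices.
#' @param quantile Chi-square trimming probability (default 0.9).
#' @param kappa Outlier covariance inflation factor.
#' @param max_iter Trimming iteration cap.
#' @return The model with tightened inlier moments.
#' @export
robustify_model <- function(model, Y, A, quantile = 0.9, kappa = 10,
                            max_iter = 25L) {
  M <- model$n_modalities
  thr <- stats::qchisq(quantile, df = M)
  cls <- comp_classes(model)
  parts <- comp_parts(model)
  for (ci in seq_along(model$classes)) {
    k_in <- which(cls == model$classes[ci] & parts == "inlier")[1]
    cp <- model$components[[k_in]]
    mu <- cp$mean
    S <- cp$cov
    for (it in seq_len(max_iter)) {
      d2 <- sq_mahalanobis(Y, mu, S)
      w <- A[, ci] * (d2 <= thr)
      sw <- sum(w)
      if (sw <= M + 1) break
      mu_new <- colSums(w * Y) / sw
      Xc <- sweep(Y, 2, mu_new)
      S <- regularise_cov(crossprod(Xc * sqrt(w)) / sw, warn = FALSE)
      delta <- sqrt(sum((mu_new - mu)^2))
      mu <- mu_new
      if (delta < 1e-3 * sqrt(sum(mu^2))) break
    }
    model$components[[k_in]]$mean <- mu
    model$components[[k_in]]$cov <- S
    k_out <- which(cls == model$classes[ci] & parts == "outlier")
    if (length(k_out))
      model$components[[k_out[1]]]$cov <- kappa * S
  }
  model
}

comp_classes <- function(model) vapply(model$components, `[[`, "", "class")
comp_parts <- function(model) vapply(model$components, `[[`, "", "part")
comp_weights <- function(model) vapply(model$components, `[[`, 0, "weight")

#' @export
print.tissue_model <- function(x, ...) {
  cls <- comp_classes(x)
  cat(sprintf("Tissue mixture model: %d components over classes %s\n",
              length(x$components), paste(x$classes, collapse = ", ")))
  for (c in x$classes) {
    k <- sum(cls == c)
    cat(sprintf("  %-8s %d component(s)\n", c, k))
  }
  invisible(x)
}

## E-step: responsibilities and log-likelihood under atlas priors
e_step <- function(model, Y, A) {
  K <- length(model$components)
  V <- nrow(Y)
  cls <- comp_classes(model)
  logW <- matrix(-Inf, V, K)
  for (k in seq_len(K)) {
    cp <- model$components[[k]]
    ci <- match(cp$class, model$classes)
    pa <- A[, ci]
    pos <- pa > 0
    if (!any(pos)) next
    logW[pos, k] <- log(pa[pos]) + log(cp$weight) +
      mvn_logdensity(Y[pos, , drop = FALSE], cp$mean, cp$cov)
  }
  mx <- as.numeric(do.call(pmax, c(asplit(logW, 2), list(na.rm = TRUE))))
  ll_v <- mx + log(rowSums(exp(logW - mx)))
  R <- exp(logW - ll_v)
  list(R = R, ll = sum(ll_v))
}

## M-step: within-class weights, means and (biased) covariances
m_step <- function(model, Y, R) {
  cls <- comp_classes(model)
  nk <- colSums(R)
  for (c in unique(cls)) {
    sel <- which(cls == c)
    tot <- sum(nk[sel])
    for (k in sel) {
      cp <- model$components[[k]]
      if (nk[k] < ncol(Y) + 1e-6) {       # starved component: keep params
        cp$weight <- max(nk[k] / tot, 1e-8)
        model$components[[k]] <- cp
        next
      }
      cp$weight <- nk[k] / tot
      mu <- colSums(R[, k] * Y) / nk[k]
      Xc <- sweep(Y, 2, mu)
      S <- crossprod(Xc * sqrt(R[, k])) / nk[k]
      cp$mean <- mu
      cp$cov <- regularise_cov(S)
      model$components[[k]] <- cp
    }
    ## renormalise weights within the class
    w <- vapply(model$components[sel], `[[`, 0, "weight")
    for (i in seq_along(sel))
      model$components[[sel[i]]]$weight <- w[i] / sum(w)
  }
  model
}

#' Fit the mixture by expectation-maximisation
#'
#' Alternates responsibilities (atlas prior x within-class weight x Gaussian
#' density, normalised per voxel) with closed-form weight/mean/covariance
#' updates. Stops when the relative log-likelihood change drops below `tol`
#' or after `max_iter` iterations. The log-likelihood sequence is
#' non-decreasing at fixed model structure.
#'
#' @param model A `tissue_model` (see [init_model()]).
#' @param Y Voxel-by-modality intensity matrix.
#' @param A Voxel-by-class atlas prior matrix.
#' @param tol Relative log-likelihood convergence tolerance (> 0, may be Inf).
#' @param max_iter Maximum EM iterations.
#' @return Object of class `model_fit`: list with `model`,
#'   `responsibilities`, `log_likelihood`, `ll_trace`, `n_iterations`,
#'   `criterion` (BIC on the masked voxels).
#' @export
fit_em <- function(model, Y, A, tol = 1e-5, max_iter = 100) {
  if (!(tol > 0)) stop("tol must be > 0")
  if (any(!is.finite(Y))) stop("non-finite intensities in Y")
  ll_trace <- numeric(0)
  ll_prev <- NA_real_
  R <- NULL
  it <- 0L
  repeat {
    es <- e_step(model, Y, A)
    R <- es$R
    ll_trace <- c(ll_trace, es$ll)
    if (!is.na(ll_prev)) {
      rel <- abs(es$ll - ll_prev) / max(abs(ll_prev), 1)
      if (rel < tol || it >= max_iter) break
    }
    ll_prev <- es$ll
    model <- m_step(model, Y, R)
    it <- it + 1L
    if (it >= max_iter) {            # final E-step to sync R with params
      es <- e_step(model, Y, A)
      R <- es$R
      ll_trace <- c(ll_trace, es$ll)
      break
    }
  }
  structure(list(model = model, responsibilities = R,
                 log_likelihood = ll_trace[length(ll_trace)],
                 ll_trace = ll_trace,
                 n_iterations = it,
                 criterion = model_bic(model,
                                       ll_trace[length(ll_trace)], nrow(Y))),
            class = "model_fit")
}

## BIC = -2 ll + p log V with p = K(M + M(M+1)/2) + sum_c (K_c - 1)
model_bic <- function(model, ll, V) {
  M <- model$n_modalities
  K <- length(model$components)
  cls <- comp_classes(model)
  p <- K * (M + M * (M + 1) / 2) + sum(table(cls) - 1)
  -2 * ll + p * log(V)
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Mixture fit: %d components, %d EM iterations, logL = %.2f, BIC = %.2f\n",
              length(x$model$components), x$n_iterations,
              x$log_likelihood, x$criterion))
  invisible(x)
}

#' Polynomial basis over 3-D coordinates
#'
#' All monomials x^i y^j z^k with i + j + k <= order, intercept first.
#'
#' @param coords n-by-3 matrix of (preferably normalised) coordinates.
#' @param order Maximum total degree (>= 0).
#' @return n-by-p basis matrix.
#' @export
polynomial_basis <- function(coords, order) {
  if (order < 0) stop("order must be >= 0")
  coords <- as.matrix(coords)
  pows <- expand.grid(i = 0:order, j = 0:order, k = 0:order)
  pows <- pows[rowSums(pows) <= order, , drop = FALSE]
  pows <- pows[order(rowSums(pows), pows$i, pows$j, pows$k), , drop = FALSE]
  X <- matrix(1, nrow(coords), nrow(pows))
  for (r in seq_len(nrow(pows)))
    X[, r] <- coords[, 1]^pows$i[r] * coords[, 2]^pows$j[r] * coords[, 3]^pows$k[r]
  X
}

#' Estimate a polynomial bias field from model residuals
#'
#' Intensities are log-transformed so the multiplicative scanner bias becomes
#' additive; the per-voxel residual is log intensity minus the log of the
#' responsibility-weighted predicted class mean, fitted per modality by least
#' squares on a polynomial basis over normalised voxel coordinates. Because
#' each fitted class mean already absorbs the average bias over that class's
#' (spatially clustered) voxels, per-class nuisance intercepts are included
#' in the regression and excluded from the returned field.
#'
#' @param images Named list of intensity arrays.
#' @param responsibilities Voxel-by-component matrix from a fit.
#' @param model The fitted `tissue_model`.
#' @param mask Logical array defining the fitting domain.
#' @param order Polynomial order (0-4).
#' @return Object of class `bias_field`: list of per-modality log-domain
#'   field arrays (`fields`), coefficients, order, mask.
#' @export
estimate_bias_field <- function(images, responsibilities, model, mask,
                                order = 3L) {
  if (order < 0 || order > 4) stop("order must be in 0..4")
  idx <- which(mask != 0)
  dm <- dim(mask)
  co <- arrayInd(idx, dm)
  coords <- sweep(sweep(co, 2, (dm + 1) / 2), 2, dm / 2, "/")
  X <- polynomial_basis(coords, order)
  if (length(idx) < ncol(X))
    stop(sprintf("mask has %d voxels but the basis needs at least %d",
                 length(idx), ncol(X)))
  means <- t(vapply(model$components, `[[`, numeric(model$n_modalities), "mean"))
  ## dominant tissue class per voxel -> nuisance intercept columns
  cls <- comp_classes(model)
  cls_resp <- vapply(model$classes, function(c)
    rowSums(responsibilities[, cls == c, drop = FALSE]), numeric(length(idx)))
  vox_class <- max.col(cls_resp, ties.method = "first")
  D <- NULL
  present <- sort(unique(vox_class))
  if (length(present) > 1)
    D <- vapply(present[-1], function(c) as.numeric(vox_class == c),
                numeric(length(idx)))
  fields <- list()
  coefs <- list()
  for (nm in names(images)) {
    y <- pmax(images[[nm]][idx], 1e-6)
    mcol <- match(nm, names(images))
    mu <- pmax(as.vector(responsibilities %*% means[, mcol]), 1e-6)
    r <- log(y) - log(mu)
    beta <- stats::lm.fit(cbind(X, D), r)$coefficients
    beta[is.na(beta)] <- 0
    f <- array(0, dm)
    f[idx] <- as.vector(X %*% beta[seq_len(ncol(X))])
    fields[[nm]] <- f
    coefs[[nm]] <- beta[seq_len(ncol(X))]
  }
  structure(list(fields = fields, coefficients = coefs, order = order,
                 mask = mask), class = "bias_field")
}

#' Remove an estimated bias field from images
#'
#' Correction happens in the log domain: corrected = exp(log(image) - field)
#' inside the field's mask; voxels outside are untouched.
#'
#' @param images Named list of intensity arrays.
#' @param bias A `bias_field` from [estimate_bias_field()].
#' @return List of corrected arrays.
#' @export
correct_bias <- function(images, bias) {
  idx <- which(bias$mask != 0)
  out <- images
  for (nm in names(images)) {
    v <- images[[nm]]
    v[idx] <- exp(log(pmax(v[idx], 1e-6)) - bias$fields[[nm]][idx])
    out[[nm]] <- v
  }
  out
}

#' Initial outlier map from the one-component-per-class fit
#'
#' Per-voxel score: minimum squared Mahalanobis distance to the inlier
#' components of the voxel's maximum-prior class. Computed after convergence
#' of the initial model and used to seed the per-class outlier weights.
#'
#' @param fit A `model_fit`.
#' @param Y Voxel-by-modality intensity matrix.
#' @param A Voxel-by-class atlas prior matrix.
#' @return Numeric score vector (one per row of `Y`), all >= 0.
#' @export
initial_outlier_map <- function(fit, Y, A) {
  model <- fit$model
  cls_of_voxel <- max.col(A, ties.method = "first")
  score <- rep(Inf, nrow(Y))
  cls <- comp_classes(model)
  parts <- comp_parts(model)
  for (ci in seq_along(model$classes)) {
    sel <- which(cls_of_voxel == ci)
    if (!length(sel)) next
    for (k in which(cls == model$classes[ci] & parts == "inlier")) {
      cp <- model$components[[k]]
      d2 <- sq_mahalanobis(Y[sel, , drop = FALSE], cp$mean, cp$cov)
      score[sel] <- pmin(score[sel], d2)
    }
  }
  score[!is.finite(score)] <- 0
  score
}

#' Re-seed outlier components from an initial outlier map
#'
#' Voxels whose score exceeds the chi-square quantile (df = number of
#' modalities) are flagged as atypical; each class's outlier component is
#' re-initialised from the flagged voxels of that class (weight, mean,
#' covariance), sharpening sensitivity before the final fit.
#'
#' @param fit A `model_fit` with one inlier component per class.
#' @param Y,A Intensity and atlas matrices.
#' @param score Outlier map from [initial_outlier_map()].
#' @param quantile Chi-square probability cut (default 0.95).
#' @return Updated `tissue_model`.
#' @export
boost_outliers <- function(fit, Y, A, score, quantile = 0.95) {
  model <- fit$model
  M <- model$n_modalities
  thr <- stats::qchisq(quantile, df = M)
  flagged <- score > thr
  cls_of_voxel <- max.col(A, ties.method = "first")
  cls <- comp_classes(model)
  parts <- comp_parts(model)
  for (ci in seq_along(model$classes)) {
    k_out <- which(cls == model$classes[ci] & parts == "outlier")[1]
    k_in <- which(cls == model$classes[ci] & parts == "inlier")[1]
    sel <- which(cls_of_voxel == ci & flagged)
    frac <- length(sel) / max(sum(cls_of_voxel == ci), 1)
    w <- min(max(frac, 0.005), 0.5)
    model$components[[k_out]]$weight <- w
    model$components[[k_in]]$weight <- 1 - w
    if (length(sel) >= 2 * M + 2) {
      Ys <- Y[sel, , drop = FALSE]
      mu <- colMeans(Ys)
      S <- crossprod(sweep(Ys, 2, mu)) / nrow(Ys)
      model$components[[k_out]]$mean <- mu
      model$components[[k_out]]$cov <- regularise_cov(S, warn = FALSE)
    }
  }
  model
}

## weighted KS statistic of squared Mahalanobis distances against the
## chi-square reference: a non-Gaussianity score for one component
component_gaussianity <- function(cp, Y, r, M) {
  keep <- r > 1e-4
  if (sum(keep) < 8) return(0)
  d2 <- sq_mahalanobis(Y[keep, , drop = FALSE], cp$mean, cp$cov)
  w <- r[keep]
  o <- order(d2)
  emp <- cumsum(w[o]) / sum(w)
  theo <- stats::pchisq(d2[o], df = M)
  max(abs(emp - theo))
}

sym_kl_gauss <- function(c1, c2) {
  P1 <- chol2inv(chol(c1$cov)); P2 <- chol2inv(chol(c2$cov))
  dm <- c1$mean - c2$mean
  M <- length(dm)
  0.5 * (sum(diag(P2 %*% c1$cov)) + sum(diag(P1 %*% c2$cov)) - 2 * M +
         as.numeric(t(dm) %*% (P1 + P2) %*% dm)) / 2
}

split_component <- function(model, k, Y = NULL, R = NULL) {
  cp <- model$components[[k]]
  ## split direction: principal axis of the whole class's responsibility-
  ## weighted scatter (atypical voxels parked in the outlier part must be
  ## able to pull a new inlier component towards them)
  dir_cov <- cp$cov
  if (!is.null(Y) && !is.null(R)) {
    cls <- comp_classes(model)
    sel <- which(cls == cp$class)
    w <- rowSums(R[, sel, drop = FALSE])
    sw <- sum(w)
    if (sw > ncol(Y) + 1) {
      mu_c <- colSums(w * Y) / sw
      Xc <- sweep(Y, 2, mu_c)
      dir_cov <- crossprod(Xc * sqrt(w)) / sw
    }
  }
  eg <- eigen(dir_cov, symmetric = TRUE)
  v <- eg$vectors[, 1]
  lam <- eg$values[1]
  shift <- 0.8 * sqrt(lam) * v
  S <- cp$cov - 0.5 * min(lam, eigen(cp$cov, symmetric = TRUE,
                                     only.values = TRUE)$values[1]) *
    tcrossprod(v)
  S <- regularise_cov(S, warn = FALSE)
  c1 <- new_component(cp$class, "inlier", cp$weight / 2, cp$mean + shift, S)
  c2 <- new_component(cp$class, "inlier", cp$weight / 2, cp$mean - shift, S)
  model$components[[k]] <- c1
  model$components[[length(model$components) + 1L]] <- c2
  model
}

merge_components <- function(model, k1, k2) {
  a <- model$components[[k1]]; b <- model$components[[k2]]
  w <- a$weight + b$weight
  wa <- a$weight / w; wb <- b$weight / w
  mu <- wa * a$mean + wb * b$mean
  da <- a$mean - mu; db <- b$mean - mu
  S <- wa * (a$cov + tcrossprod(da)) + wb * (b$cov + tcrossprod(db))
  model$components[[k1]] <- new_component(a$class, "inlier", w, mu,
                                          regularise_cov(S, warn = FALSE))
  model$components[[k2]] <- NULL
  model
}

## inlier components model normal tissue: a WM inlier brighter on FLAIR
## than the brightest GM inlier would swallow lesions into the normal part
## of the model, so such split outcomes are vetoed
split_outcome_admissible <- function(model) {
  if (is.null(model$modalities)) return(TRUE)
  fcol <- match("flair", model$modalities)
  if (is.na(fcol)) return(TRUE)
  cls <- comp_classes(model)
  parts <- comp_parts(model)
  gm <- which(cls == "GM" & parts == "inlier")
  wm <- which(cls == "WM" & parts == "inlier")
  if (!length(gm) || !length(wm)) return(TRUE)
  gm_ref <- max(vapply(model$components[gm],
                       function(cp) cp$mean[fcol], 0))
  all(vapply(model$components[wm],
             function(cp) cp$mean[fcol], 0) <= gm_ref)
}

#' Split-and-merge search over the number of inlier components
#'
#' Iteratively proposes splitting the inlier component whose responsibility-
#' weighted squared Mahalanobis distances deviate most from the chi-square
#' reference (worst within-component Gaussianity), and merging the most
#' similar same-class inlier pair (symmetric KL divergence). A proposal is
#' kept only if the BIC improves after a short EM refit and the refitted
#' model keeps every WM inlier no brighter on FLAIR than the brightest GM
#' inlier (inliers represent normal tissue; hyperintense clusters belong to
#' the outlier part). The search stops when no proposal improves or the
#' per-class component cap is reached.
#'
#' @param fit A converged `model_fit`.
#' @param Y,A Intensity and atlas matrices.
#' @param max_components_per_class Cap on inlier components per class.
#' @param refit_iter EM iterations used to evaluate each proposal.
#' @param max_sweeps Maximum accepted-proposal rounds.
#' @return A refitted `model_fit` (identical structure if nothing improved).
#' @export
split_merge_search <- function(fit, Y, A, max_components_per_class = 3L,
                               refit_iter = 15L, max_sweeps = 8L) {
  if (max_components_per_class < 1) stop("max_components_per_class must be >= 1")
  best <- fit
  if (max_components_per_class == 1L) return(best)
  M <- best$model$n_modalities
  for (sweep_i in seq_len(max_sweeps)) {
    improved <- FALSE
    model <- best$model
    cls <- comp_classes(model)
    parts <- comp_parts(model)
    inl <- which(parts == "inlier")
    n_per_class <- table(cls[inl])

    ## split proposals, worst Gaussianity first
    splittable <- inl[n_per_class[cls[inl]] < max_components_per_class]
    if (length(splittable)) {
      gs <- vapply(splittable, function(k)
        component_gaussianity(model$components[[k]], Y,
                              best$responsibilities[, k], M), 0)
      for (k_split in splittable[order(gs, decreasing = TRUE)]) {
        cand <- fit_em(split_component(model, k_split, Y,
                                       best$responsibilities), Y, A,
                       tol = 1e-4, max_iter = refit_iter)
        if (!split_outcome_admissible(cand$model)) next
        if (cand$criterion < best$criterion - 1e-6) {
          best <- cand
          improved <- TRUE
          break
        }
      }
      if (improved) next
    }

    ## merge proposal
    pairs <- NULL
    for (c in unique(cls[inl])) {
      ks <- inl[cls[inl] == c]
      if (length(ks) >= 2)
        pairs <- rbind(pairs, t(utils::combn(ks, 2)))
    }
    if (!is.null(pairs)) {
      kl <- apply(pairs, 1, function(p)
        sym_kl_gauss(model$components[[p[1]]], model$components[[p[2]]]))
      p <- pairs[which.min(kl), ]
      cand <- fit_em(merge_components(model, p[1], p[2]), Y, A,
                     tol = 1e-4, max_iter = refit_iter)
      if (cand$criterion < best$criterion - 1e-6) {
        best <- cand
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  best
}
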