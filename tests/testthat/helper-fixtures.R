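# Shared fixtures and independent oracles built in code.

# compact phantom for unit tests (default grid is reserved for the
# end-to-end suite)
small_spec <- function(seed = 1, target_lesion_ml = 2, ...) {
  phantom_spec(grid_shape = c(40L, 44L, 40L), target_lesion_ml = target_lesion_ml,
               seed = seed, ...)
}

.phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(key, spec) {
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(spec)
  .phantom_cache[[key]]
}

# independent flood-fill connected-components oracle: explicit queue BFS
# with literal neighbourhood enumeration (no shared code with the package)
oracle_components <- function(mask, connectivity) {
  dm <- dim(mask)
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    nz <- sum(c(dx, dy, dz) != 0)
    keep <- (connectivity == 6 && nz == 1) ||
            (connectivity == 18 && nz >= 1 && nz <= 2) ||
            (connectivity == 26 && nz >= 1)
    if (keep) offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  lab <- array(0L, dm)
  nextlab <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, dm)
      for (o in offs) {
        p <- co + o
        if (any(p < 1) || any(p > dm)) next
        if (mask[p[1], p[2], p[3]] != 0 && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- nextlab
          queue <- c(queue, p[1] + (p[2] - 1) * dm[1] + (p[3] - 1) * dm[1] * dm[2])
        }
      }
    }
  }
  lab
}

# two labelings define the same partition iff the label pairing is 1:1
same_partition <- function(a, b) {
  ia <- a[a != 0 | b != 0]; ib <- b[a != 0 | b != 0]
  if (any((ia == 0) != (ib == 0))) return(FALSE)
  pairs <- unique(cbind(ia, ib))
  !any(duplicated(pairs[, 1])) && !any(duplicated(pairs[, 2]))
}

# random blobby binary mask for evaluation-property tests
random_mask <- function(dm, p = 0.15) {
  array(stats::runif(prod(dm)) < p, dm)
}

# ICC(A,1) oracle through a from-scratch two-way ANOVA via stats::aov
oracle_icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  MSR <- tab["subject   ", "Mean Sq"]
  if (is.na(MSR)) MSR <- tab[grep("subject", rownames(tab)), "Mean Sq"]
  MSC <- tab[grep("rater", rownames(tab)), "Mean Sq"]
  MSE <- tab[grep("Residuals", rownames(tab)), "Mean Sq"]
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

make_class_data <- function(n_per_class, means, sds, seed = 1,
                            prior_correct = 0.85) {
  # two-modality Gaussian draws per class plus a mildly informative atlas
  set.seed(seed)
  C <- nrow(means)
  Y <- NULL; lab <- integer(0)
  for (c in seq_len(C)) {
    Y <- rbind(Y, cbind(stats::rnorm(n_per_class, means[c, 1], sds[c]),
                        stats::rnorm(n_per_class, means[c, 2], sds[c])))
    lab <- c(lab, rep(c, n_per_class))
  }
  A <- matrix((1 - prior_correct) / (C - 1), nrow(Y), C)
  A[cbind(seq_along(lab), lab)] <- prior_correct
  colnames(Y) <- c("t1", "flair")
  list(Y = Y, A = A, lab = lab)
}
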