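# Blockwise profiled Gaussian log-likelihood for the twin mixed model.
#
# The marginal covariance is block-diagonal by twin pair, and in a balanced
# design most pairs share the same within-block sharing pattern of the five
# random effects. Blocks are therefore grouped by pattern: each unique block
# covariance is factorised once per likelihood evaluation, and the GLS
# accumulators (X' S^-1 X, X' S^-1 y, y' S^-1 y, log|S|) are computed with
# stacked-matrix products over all pairs of a pattern at once.

# Precompute the pattern decomposition for a fixed (groups, X, y) triple.
# Rows of X / elements of y must align with rows of `groups`.
build_block_patterns <- function(groups, X, y) {
  eff <- c("H", "M", "E", "W", "V")
  idx_by_pair <- split(seq_len(nrow(groups)), groups$pair)
  # pattern signature: block size + each effect's labels relabelled in order
  # of first occurrence within the block
  sig <- vapply(idx_by_pair, function(idx) {
    paste(length(idx),
          paste(vapply(eff, function(e) {
            lab <- groups[[e]][idx]
            paste(match(lab, unique(lab)), collapse = "")
          }, character(1)), collapse = "|"),
          sep = "@")
  }, character(1))
  patterns <- lapply(split(idx_by_pair, sig), function(pair_list) {
    m <- length(pair_list[[1]])
    G <- length(pair_list)
    rows <- unlist(pair_list, use.names = FALSE)
    idx1 <- pair_list[[1]]
    share <- lapply(eff, function(e) {
      lab <- groups[[e]][idx1]
      outer(lab, lab, "==") * 1
    })
    names(share) <- eff
    Xstk <- X[rows, , drop = FALSE]
    p <- ncol(X)
    list(m = m, G = G, p = p, share = share,
         Xstk = Xstk,
         Xperm = matrix(array(Xstk, c(m, G, p)), m, G * p),
         ystk = y[rows],
         yperm = matrix(y[rows], m, G))
  })
  list(patterns = patterns, n = nrow(groups), p = ncol(X))
}

# Profiled log-likelihood at variance vector v = (H, M, E, W, V, eps).
# Returns list(loglik, beta); -Inf on a numerically singular covariance.
profile_loglik <- function(bp, v) {
  p <- bp$p
  XtAX <- matrix(0, p, p)
  XtAy <- numeric(p)
  ytAy <- 0
  logdet <- 0
  for (pt in bp$patterns) {
    S <- diag(v[6], pt$m)
    for (i in 1:5) S <- S + v[i] * pt$share[[i]]
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) return(list(loglik = -Inf, beta = rep(NA_real_, p)))
    logdet <- logdet + pt$G * 2 * sum(log(diag(R)))
    A <- chol2inv(R)
    AX <- A %*% pt$Xperm                         # m x (G*p)
    AXstk <- matrix(array(AX, c(pt$m, pt$G, p)), pt$m * pt$G, p)
    Ay <- A %*% pt$yperm                         # m x G
    Aystk <- as.vector(Ay)
    XtAX <- XtAX + crossprod(pt$Xstk, AXstk)
    XtAy <- XtAy + crossprod(pt$Xstk, Aystk)
    ytAy <- ytAy + sum(pt$ystk * Aystk)
  }
  ch <- tryCatch(chol(XtAX), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf, beta = rep(NA_real_, p)))
  beta <- backsolve(ch, forwardsolve(t(ch), XtAy))
  quad <- ytAy - sum(XtAy * beta)
  ll <- -0.5 * (bp$n * log(2 * pi) + logdet + quad)
  list(loglik = ll, beta = as.vector(beta))
}

# Fixed-effect design matrix: one mean per plate (model 1), plus one
# plate-specific slope on the centered well index (model 2).
fixed_design_matrix <- function(groups, model_form) {
  plate <- factor(groups$plate)
  X <- vapply(levels(plate), function(l) as.numeric(plate == l),
              numeric(length(plate)))
  colnames(X) <- paste0("plate", levels(plate))
  if (model_form == 2) {
    cw <- centered_well(groups$plate, groups$well)
    D <- X * cw
    colnames(D) <- paste0("drift", levels(plate))
    X <- cbind(X, D)
  }
  X
}
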