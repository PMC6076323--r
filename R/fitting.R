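#' Eigendecomposition of a covariance kernel for sampling
#'
#' Each kernel effect `u ~ N(0, sigma2 K)` is reparameterized through the
#' eigendecomposition `K = U diag(d) U'` as `u = U diag(sqrt(d)) delta` with
#' `delta ~ N(0, sigma2 I)`. Because the columns of `U` are orthonormal over
#' the full record set, the Gibbs full conditional of `delta` is diagonal.
#' Eigenvalues below `tol * max(d)` are truncated; diagonal kernels (such as
#' the naive line-by-environment kernel on a complete layout, which is the
#' identity) are detected and kept in trivial form.
#'
#' Kernels that decouple into connected components (for instance the
#' genomic-by-environment kernel, which is block-diagonal by environment)
#' are decomposed block by block, which avoids factorizing the full
#' records-by-records matrix and keeps the per-iteration matrix-vector
#' products small.
#'
#' @param K Symmetric PSD matrix.
#' @param tol Relative truncation tolerance.
#' @param max_blocks Use the blockwise decomposition when the kernel splits
#'   into between 2 and `max_blocks` connected components; beyond that the
#'   per-block bookkeeping outweighs the saving and a dense decomposition
#'   is used.
#' @return A list describing the decomposition: `type` is `"diag"` (fields
#'   `d`, `idx`), `"dense"` (fields `U`, `d`) or `"block"` (field `blocks`,
#'   a list of per-component `idx`, `U`, `d`).
#' @export
kernel_eigen <- function(K, tol = 1e-8, max_blocks = 64) {
  n <- nrow(K)
  off <- K
  diag(off) <- 0
  if (max(abs(off)) == 0) {
    d <- diag(K)
    keep <- d > tol * max(d)
    return(list(type = "diag", d = d[keep], idx = which(keep)))
  }
  comp <- .connected_components(K != 0)
  ncomp <- max(comp)
  if (ncomp >= 2 && ncomp <= max_blocks) {
    blocks <- lapply(seq_len(ncomp), function(b) {
      idx <- which(comp == b)
      sub <- K[idx, idx, drop = FALSE]
      eig <- eigen(sub, symmetric = TRUE)
      if (min(eig$values) < -1e-8 * length(idx) * max(abs(eig$values))) {
        abort("Kernel is not positive semidefinite.")
      }
      keep <- eig$values > tol * max(eig$values)
      list(idx = idx, U = eig$vectors[, keep, drop = FALSE],
           d = eig$values[keep])
    })
    return(list(type = "block", blocks = blocks))
  }
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * n * max(abs(eig$values))) {
    abort("Kernel is not positive semidefinite.")
  }
  keep <- eig$values > tol * max(eig$values)
  list(type = "dense", U = eig$vectors[, keep, drop = FALSE],
       d = eig$values[keep])
}

# connected components of a symmetric logical adjacency matrix
.connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

.prepare_kernels <- function(kernels, n, eigens = NULL) {
  stopifnot(length(kernels) >= 1)
  for (k in kernels) {
    if (!inherits(k, "kernel_term")) abort("Kernels must be kernel_term objects.")
    if (nrow(k$K) != n) abort("Kernel dimension does not match the records.")
  }
  if (is.null(eigens)) {
    eigens <- lapply(kernels, function(k) kernel_eigen(k$K))
  }
  eigens
}

#' Fit a multi-kernel Gaussian model by Gibbs sampling
#'
#' Bayesian linear mixed model `y = mu 1 + sum_k u_k + e` with
#' `u_k ~ N(0, sigma2_k K_k)` and iid residuals. Each kernel effect is
#' sampled in its eigenbasis, variance components from scaled-inverse-
#' chi-square full conditionals (df `df0`, scale set so the prior mode
#' assigns a fraction `R2` of the response variance to the kernels, split
#' equally), and `mu` from its normal full conditional under a flat prior.
#' Records outside `train` are treated as missing responses and imputed from
#' the current model draw each iteration (data augmentation), so held-out
#' records are predicted from their kernel covariance with the training
#' records; their predicted value is the posterior mean of the genetic
#' component `mu + sum_k u_k`.
#'
#' @param y Numeric response over all records (values at non-train positions
#'   are ignored and may be `NA`).
#' @param kernels Named list of `kernel_term` objects from [build_kernels()].
#' @param train Logical vector marking training records (default all).
#' @param niter,burnin,thin MCMC settings.
#' @param df0,R2 Prior degrees of freedom and prior proportion of variance
#'   attributed to the kernels.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param eigens Optional pre-computed [kernel_eigen()] list (cacheable
#'   across train/test partitions since it does not depend on the mask).
#' @return An object of class `gibbs_fit`: list with `mu_hat`, `var_hat`
#'   (named posterior-mean variances incl. `sigma2_e`), `effects_hat` (list
#'   of posterior-mean effect vectors), `yhat` (posterior-mean genetic value
#'   per record), `settings` and `n_train`.
#' @export
fit_gibbs <- function(y, kernels, train = rep(TRUE, length(y)),
                      niter = 12000, burnin = 2000, thin = 5,
                      df0 = 5, R2 = 0.5, seed = 1L, eigens = NULL) {
  n <- length(y)
  stopifnot(length(train) == n, is.logical(train))
  if (sum(train) < 2) abort("Need at least 2 training records.")
  if (burnin >= niter) abort("`burnin` must be smaller than `niter`.")
  eigens <- .prepare_kernels(kernels, n, eigens)
  nk <- length(kernels)
  knames <- vapply(kernels, `[[`, character(1), "name")
  vcnames <- vapply(kernels, `[[`, character(1), "vc")

  y_train <- y[train]
  vy <- var(y_train)
  if (!is.finite(vy) || vy <= 0) vy <- 1e-6
  # scaled-inv-chisq scale with prior mode R2*vy/nk per kernel
  s0_k <- (R2 * vy / nk) * (df0 + 2) / df0
  s0_e <- ((1 - R2) * vy) * (df0 + 2) / df0

  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    y_aug <- y
    y_aug[!train] <- mean(y_train)
    mu <- mean(y_train)
    sig2 <- rep(R2 * vy / nk, nk)
    sig2_e <- (1 - R2) * vy
    u <- lapply(seq_len(nk), function(k) numeric(n))

    n_keep <- length(seq(burnin + thin, niter, by = thin))
    if (n_keep < 1) abort("MCMC settings leave no post-burn-in samples.")
    acc_mu <- 0; acc_sig2 <- numeric(nk); acc_sig2e <- 0
    acc_u <- lapply(seq_len(nk), function(k) numeric(n))
    acc_yhat <- numeric(n)

    for (it in seq_len(niter)) {
      usum <- Reduce(`+`, u)
      # intercept
      mu <- rnorm(1, mean(y_aug - usum), sqrt(sig2_e / n))
      # kernel effects in their eigenbases
      for (k in seq_len(nk)) {
        e_k <- y_aug - mu - (usum - u[[k]])
        ek <- eigens[[k]]
        ssq <- 0
        rank_k <- 0L
        if (ek$type == "diag") {
          d <- ek$d
          r <- e_k[ek$idx]
          cvar <- 1 / (d / sig2_e + 1 / sig2[k])
          dl <- rnorm(length(d), cvar * sqrt(d) * r / sig2_e, sqrt(cvar))
          unew <- numeric(n)
          unew[ek$idx] <- sqrt(d) * dl
          ssq <- sum(dl^2)
          rank_k <- length(dl)
        } else if (ek$type == "dense") {
          d <- ek$d
          r <- crossprod(ek$U, e_k)[, 1]
          cvar <- 1 / (d / sig2_e + 1 / sig2[k])
          dl <- rnorm(length(d), cvar * sqrt(d) * r / sig2_e, sqrt(cvar))
          unew <- as.vector(ek$U %*% (sqrt(d) * dl))
          ssq <- sum(dl^2)
          rank_k <- length(dl)
        } else {
          unew <- numeric(n)
          for (blk in ek$blocks) {
            d <- blk$d
            r <- crossprod(blk$U, e_k[blk$idx])[, 1]
            cvar <- 1 / (d / sig2_e + 1 / sig2[k])
            dl <- rnorm(length(d), cvar * sqrt(d) * r / sig2_e, sqrt(cvar))
            unew[blk$idx] <- unew[blk$idx] +
              as.vector(blk$U %*% (sqrt(d) * dl))
            ssq <- ssq + sum(dl^2)
            rank_k <- rank_k + length(dl)
          }
        }
        usum <- usum - u[[k]] + unew
        u[[k]] <- unew
        # kernel variance
        sig2[k] <- (ssq + df0 * s0_k) / rchisq(1, df = df0 + rank_k)
      }
      # residual variance over all (observed + augmented) records
      res <- y_aug - mu - usum
      sig2_e <- (sum(res^2) + df0 * s0_e) / rchisq(1, df = df0 + n)
      # re-impute held-out responses from the current draw
      if (any(!train)) {
        ghat <- mu + usum
        y_aug[!train] <- ghat[!train] +
          rnorm(sum(!train), 0, sqrt(sig2_e))
      }
      if (it > burnin && (it - burnin) %% thin == 0) {
        acc_mu <- acc_mu + mu
        acc_sig2 <- acc_sig2 + sig2
        acc_sig2e <- acc_sig2e + sig2_e
        for (k in seq_len(nk)) acc_u[[k]] <- acc_u[[k]] + u[[k]]
        acc_yhat <- acc_yhat + mu + usum
      }
    }

    var_hat <- c(setNames(acc_sig2 / n_keep, vcnames),
                 sigma2_e = acc_sig2e / n_keep)
    structure(
      list(
        mu_hat = acc_mu / n_keep,
        var_hat = var_hat,
        effects_hat = setNames(lapply(acc_u, `/`, n_keep), knames),
        yhat = acc_yhat / n_keep,
        n_train = sum(train),
        settings = list(niter = niter, burnin = burnin, thin = thin,
                        df0 = df0, R2 = R2, seed = as.integer(seed))
      ),
      class = "gibbs_fit"
    )
  })
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat(sprintf(
    "<gibbs_fit> %d records (%d train); mu_hat = %.4g\n",
    length(x$yhat), x$n_train, x$mu_hat
  ))
  cat("  posterior-mean variances:\n")
  print(round(x$var_hat, 4))
  invisible(x)
}

#' @describeIn fit_gibbs Tidy the posterior-mean variance components.
#' @param x A `gibbs_fit`.
#' @param ... Unused.
#' @export
tidy.gibbs_fit <- function(x, ...) {
  tibble(
    component = names(x$var_hat),
    estimate = unname(x$var_hat)
  )
}

#' @describeIn fit_gibbs One-row model-level summary.
#' @export
glance.gibbs_fit <- function(x, ...) {
  tibble(
    mu_hat = x$mu_hat,
    sigma2_e = unname(x$var_hat[["sigma2_e"]]),
    n_records = length(x$yhat),
    n_train = x$n_train,
    niter = x$settings$niter,
    burnin = x$settings$burnin,
    thin = x$settings$thin
  )
}

#' Closed-form BLUP at known variance components
#'
#' Mixed-model oracle for the same model family as [fit_gibbs()]: with
#' known kernel variances, `V = sum_k sigma2_k K_k[train, train] +
#' sigma2_e I`, the generalized-least-squares mean
#' `mu = (1' V^-1 1)^-1 1' V^-1 y`, and the prediction for any record r is
#' `mu + sum_k sigma2_k K_k[r, train] V^-1 (y_train - mu)`.
#'
#' @param y Numeric response over all records.
#' @param kernels Named list of `kernel_term` objects.
#' @param variances Named numeric vector of kernel variances; matched to
#'   kernels by variance symbol (`sigma2_E`, ...) or by kernel name.
#' @param var_e Residual variance (> 0).
#' @param train Logical training mask.
#' @return Numeric vector of predictions for every record.
#' @export
blup_known_variance <- function(y, kernels, variances, var_e,
                                train = rep(TRUE, length(y))) {
  n <- length(y)
  stopifnot(length(train) == n)
  if (var_e <= 0) abort("`var_e` must be positive.")
  .prepare_kernels(kernels, n, eigens = list())  # structural checks only
  sig2 <- vapply(kernels, function(k) {
    if (k$vc %in% names(variances)) return(as.numeric(variances[[k$vc]]))
    if (k$name %in% names(variances)) return(as.numeric(variances[[k$name]]))
    abort(paste0("No variance supplied for kernel ", k$name))
  }, numeric(1))
  if (any(sig2 < 0)) abort("Kernel variances must be non-negative.")
  tr <- which(train)
  Ksum_tt <- Reduce(`+`, lapply(seq_along(kernels), function(k) {
    sig2[k] * kernels[[k]]$K[tr, tr, drop = FALSE]
  }))
  V <- Ksum_tt + diag(var_e, length(tr))
  Vi <- solve(V)
  one <- rep(1, length(tr))
  mu <- as.numeric((one %*% Vi %*% y[tr]) / (one %*% Vi %*% one))
  w <- Vi %*% (y[tr] - mu)
  C_all <- Reduce(`+`, lapply(seq_along(kernels), function(k) {
    sig2[k] * kernels[[k]]$K[, tr, drop = FALSE]
  }))
  as.vector(mu + C_all %*% w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
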