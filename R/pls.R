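#' Bootstrap cross-validation settings for PLS component selection
#'
#' Component counts are chosen by repeated bootstrap resampling of the
#' training rows: each repetition fits on a with-replacement sample and
#' scores all component counts on the out-of-bag rows; the count minimising
#' the mean out-of-bag RMSE wins, with ties broken toward fewer components.
#'
#' @param n_bootstrap Number of bootstrap repetitions (default 25).
#' @param component_cap Maximum number of latent components considered
#'   (20 for interval models, 40 for the wide-spectrum model).
#' @param seed Optional integer seed for the resampling.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_bootstrap = 25, component_cap = 20, seed = NULL) {
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1")
  structure(
    list(
      n_bootstrap = as.integer(n_bootstrap),
      component_cap = as.integer(component_cap),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "cv_config"
  )
}

# Single-response SIMPLS. X is n x p, y length n. Returns weights W (p x A),
# y-loadings q (A), and the centering/scaling vectors; the fit at A
# components nests every smaller fit, so submodels come for free.
simpls_fit <- function(X, y, ncomp, center = TRUE, scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n != length(y)) stop("shape error: rows(X) must equal length(y)")
  xm <- if (center) colMeans(X) else rep(0, p)
  xs <- rep(1, p)
  if (scale) {
    xs <- apply(X, 2, stats::sd)
    xs[xs < 1e-12] <- 1
  }
  Xc <- sweep(sweep(X, 2, xm, "-"), 2, xs, "/")
  ym <- if (center) mean(y) else 0
  yc <- y - ym
  A <- max(0L, min(ncomp, p, n - 1L))
  if (stats::sd(y) < 1e-12) A <- 0L
  if (A > 0 && max(colSums(Xc^2)) < 1e-20) {
    stop("degenerate input: all spectra columns have zero variance")
  }
  W <- matrix(0, p, A)
  V <- matrix(0, p, A)
  qv <- numeric(A)
  a <- 0L
  if (A > 0) {
    S <- crossprod(Xc, yc) # p x 1
    s0 <- sqrt(sum(S^2))
    for (k in seq_len(A)) {
      r <- S
      if (sqrt(sum(r^2)) < 1e-10 * max(s0, 1e-300)) break
      t <- Xc %*% r
      tn <- sqrt(sum(t^2))
      if (tn < 1e-12) break
      t <- t / tn
      r <- r / tn
      pl <- crossprod(Xc, t)
      qk <- sum(yc * t)
      v <- pl
      if (k > 1) {
        Vk <- V[, seq_len(k - 1), drop = FALSE]
        v <- v - Vk %*% crossprod(Vk, pl)
      }
      vn <- sqrt(sum(v^2))
      if (vn < 1e-12) break
      v <- v / vn
      S <- S - v %*% crossprod(v, S)
      W[, k] <- r
      V[, k] <- v
      qv[k] <- qk
      a <- k
    }
  }
  structure(
    list(
      W = W[, seq_len(a), drop = FALSE],
      q = qv[seq_len(a)],
      xmean = xm, xscale = xs, ymean = ym,
      max_ncomp = a, ncomp = a,
      center = center, scale = scale,
      wavelengths = suppressWarnings(as.numeric(colnames(X)))
    ),
    class = "pls_fit"
  )
}

#' Predict from a fitted PLS model
#'
#' @param object A `pls_fit` from [fit_pls()].
#' @param newdata Matrix (or data frame) with the same columns the model
#'   was trained on.
#' @param ncomp Number of components to use (default: the cross-validated
#'   choice stored in the model).
#' @param cumulative If `TRUE`, return an `n x ncomp` matrix of predictions
#'   for every component count `1..ncomp` (used by the bootstrap CV).
#' @param ... Unused.
#' @return Numeric vector of predicted ages (days), or a matrix if
#'   `cumulative = TRUE`.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$ncomp,
                            cumulative = FALSE, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$xmean)) {
    stop(
      "shape error: model expects ", length(object$xmean),
      " columns, got ", ncol(X)
    )
  }
  ncomp <- min(ncomp, object$max_ncomp)
  Xc <- sweep(sweep(X, 2, object$xmean, "-"), 2, object$xscale, "/")
  if (ncomp == 0L) {
    out <- rep(object$ymean, nrow(X))
    if (cumulative) out <- matrix(out, nrow(X), 1)
    return(out)
  }
  Tn <- Xc %*% object$W[, seq_len(ncomp), drop = FALSE]
  contrib <- sweep(Tn, 2, object$q[seq_len(ncomp)], "*")
  if (cumulative) {
    # row-wise cumulative sums over components via an upper-triangular mask
    U <- upper.tri(diag(ncomp), diag = TRUE) * 1
    object$ymean + contrib %*% U
  } else {
    as.numeric(object$ymean + rowSums(contrib))
  }
}

# Mean out-of-bag RMSE for component counts 0..cap; NA where a repetition
# could not reach that count.
boot_cv_rmse <- function(X, y, cap, n_bootstrap, center = TRUE,
                         scale = FALSE) {
  n <- nrow(X)
  res <- matrix(NA_real_, n_bootstrap, cap + 1)
  for (r in seq_len(n_bootstrap)) {
    ib <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(ib))
    if (length(oob) == 0) next
    fit <- simpls_fit(X[ib, , drop = FALSE], y[ib], ncomp = cap,
                      center = center, scale = scale)
    res[r, 1] <- sqrt(mean((y[oob] - fit$ymean)^2))
    if (fit$max_ncomp > 0) {
      P <- predict(fit, X[oob, , drop = FALSE], ncomp = fit$max_ncomp,
                   cumulative = TRUE)
      err <- sweep(-P, 1, y[oob], "+")
      res[r, 1 + seq_len(fit$max_ncomp)] <- sqrt(colMeans(err^2))
    }
  }
  colMeans(res, na.rm = TRUE)
}

#' Fit a PLS regression of age on spectra with bootstrap-CV component choice
#'
#' Single-response PLS (SIMPLS algorithm, mean-centred columns, no variance
#' scaling by default — the convention of classical NIR chemometrics). The
#' number of latent components is selected by out-of-bag RMSE over
#' bootstrap repetitions ([cv_config()]), capped at `cv$component_cap`;
#' a constant response yields an intercept-only model with 0 components.
#'
#' @param X Spectra sub-matrix (rows = mosquitoes, columns = wavelengths).
#' @param y True ages (days), one per row of `X`.
#' @param cv A [cv_config()].
#' @param center,scale Column centering/unit-variance scaling flags.
#' @return A `pls_fit` with the selected `ncomp` and the CV curve in
#'   `$cv_rmse` (index 1 = 0 components).
#' @export
fit_pls <- function(X, y, cv = cv_config(), center = TRUE, scale = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("shape error: rows(X) must equal length(y)")
  if (nrow(X) < 3) stop("size error: need at least 3 training rows")
  if (stats::sd(y) < 1e-12) {
    fit <- simpls_fit(X, y, ncomp = 0, center = center, scale = scale)
    fit$cv_rmse <- 0
    return(fit)
  }
  cap <- min(cv$component_cap, ncol(X), nrow(X) - 1L)
  run <- function() boot_cv_rmse(X, y, cap, cv$n_bootstrap, center, scale)
  cv_rmse <- if (is.null(cv$seed)) run() else withr::with_seed(cv$seed, run())
  best <- which.min(cv_rmse) - 1L # ties resolve toward fewer components
  fit <- simpls_fit(X, y, ncomp = cap, center = center, scale = scale)
  fit$ncomp <- min(best, fit$max_ncomp)
  fit$cv_rmse <- cv_rmse
  fit
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf(
    "<pls_fit> %d wavelength columns, %d/%d components (cap %s)\n",
    length(x$xmean), x$ncomp, x$max_ncomp,
    if (is.null(x$cv_rmse)) "-" else length(x$cv_rmse) - 1
  ))
  invisible(x)
}

#' @method tidy pls_fit
#' @export
tidy.pls_fit <- function(x, ...) {
  tibble::tibble(
    ncomp = seq_along(x$cv_rmse) - 1L,
    cv_rmse = x$cv_rmse,
    selected = (seq_along(x$cv_rmse) - 1L) == x$ncomp
  )
}
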