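#' Phylogenetic generalized least squares under Brownian motion
#'
#' Fits y ~ x by GLS with the Brownian-motion covariance implied by the
#' tree (shared-path lengths, `ape::vcv`). Estimation whitens both sides by
#' the Cholesky factor of the covariance and solves ordinary least squares
#' in the whitened space; on a star tree with equal branch lengths this
#' reduces exactly to OLS. The coefficient of determination and its F-test
#' are computed against the GLS intercept-only model.
#'
#' @param x,y named numeric vectors; names must match the tree tip labels
#' @param tree `ape::phylo` with positive branch lengths
#' @return object of class `pgls_fit`: slope, intercept, r2_adj, p_value
#'   (F-statistic), sigma2, n, model = "BM"
#' @export
pgls_fit <- function(x, y, tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (is.null(names(x)) || is.null(names(y))) {
    stop("x and y must be named by tree tip labels")
  }
  bad <- c(setdiff(tips, names(x)), setdiff(names(x), tips),
           setdiff(tips, names(y)), setdiff(names(y), tips))
  if (length(bad)) {
    stop("tip/sample mismatch: ", paste(unique(bad), collapse = ", "))
  }
  if (any(tree$edge.length <= 0)) stop("tree has non-positive branch lengths")
  x <- x[tips]; y <- y[tips]
  n <- length(tips)
  C <- ape::vcv(tree)
  U <- chol(C)                       # C = t(U) %*% U
  wh <- function(m) forwardsolve(t(U), m)
  Xw <- wh(cbind(1, x))
  colnames(Xw) <- c("intercept", "slope")
  yw <- wh(y)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  fit0 <- stats::lm.fit(wh(matrix(1, n, 1)), yw)
  rss0 <- sum(fit0$residuals^2)
  r2 <- 1 - rss / rss0
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  Fstat <- if (rss > 0) (rss0 - rss) / (rss / (n - 2)) else Inf
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  structure(list(
    slope = unname(fit$coefficients["slope"]),
    intercept = unname(fit$coefficients["intercept"]),
    r2_adj = r2_adj,
    p_value = p,
    sigma2 = rss / (n - 2),
    n = n,
    model = "BM"
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "<pgls_fit BM> n = %d; slope = %.4g, intercept = %.4g; adj R2 = %.4f; p(F) = %.3g\n",
    x$n, x$slope, x$intercept, x$r2_adj, x$p_value))
  invisible(x)
}
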