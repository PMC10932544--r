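#' Brownian-motion covariance matrix of a tree
#'
#' Under Brownian trait evolution, the covariance of two taxa is the branch
#' length shared by their root-to-tip paths; the diagonal holds the
#' root-to-tip distances.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @return A symmetric covariance matrix with taxa labels as dimnames.
#' @export
brownian_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  # the tree is taken as rooted at its basal node; star phylogenies
  # (basal polytomies) are legitimate and give diagonal covariance
  ape::vcv.phylo(tree)
}

#' Phylogenetic generalized least squares regression
#'
#' Fits `y ~ x` by generalized least squares with residual covariance
#' proportional to a Brownian-motion phylogenetic covariance matrix
#' ("phylogenetic inertia" correction). The slope is tested with a
#' two-sided t-test on `n - 2` degrees of freedom. With `V` proportional to
#' the identity (star phylogeny) the fit reduces exactly to ordinary least
#' squares, and the fit is invariant to uniform rescaling of `V`.
#'
#' @param y,x Numeric trait vectors. If named, names must match the
#'   row names of `vcv` (values are reordered to match).
#' @param vcv Covariance matrix from [brownian_vcv()].
#' @return An object of class `pgls_fit`: list with `slope`, `intercept`,
#'   `slope_se`, `t_statistic`, `p_value`, `n_taxa`, `df`.
#' @export
pgls_fit <- function(y, x, vcv) {
  stopifnot(is.matrix(vcv), nrow(vcv) == ncol(vcv))
  n <- nrow(vcv)
  if (length(y) != n || length(x) != n)
    stop("trait vectors and covariance matrix sizes differ")
  if (n < 3L) stop("need at least 3 taxa")
  taxa <- rownames(vcv)
  if (!is.null(taxa) && !is.null(names(y))) {
    if (!setequal(names(y), taxa)) stop("taxa of y do not match vcv")
    y <- y[taxa]
  }
  if (!is.null(taxa) && !is.null(names(x))) {
    if (!setequal(names(x), taxa)) stop("taxa of x do not match vcv")
    x <- x[taxa]
  }
  L <- tryCatch(chol(vcv), error = function(e)
    stop("covariance matrix is not positive definite (singular V?)"))
  # whiten: solve t(L) %*% z = v
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, cbind(1, x), transpose = TRUE)
  fit <- stats::lm.fit(wX, wy)
  beta <- unname(fit$coefficients)
  rss <- sum(fit$residuals^2)
  df <- n - 2L
  sigma2 <- rss / df
  XtX_inv <- chol2inv(chol(crossprod(wX)))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tstat <- beta[2L] / se[2L]
  out <- list(slope = beta[2L],
              intercept = beta[1L],
              slope_se = unname(se[2L]),
              t_statistic = unname(tstat),
              p_value = 2 * pt(abs(tstat), df, lower.tail = FALSE),
              n_taxa = n, df = df)
  class(out) <- "pgls_fit"
  out
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "PGLS fit (%d taxa): slope = %.4g (se %.3g), t = %.3g, p = %.3g\n",
    x$n_taxa, x$slope, x$slope_se, x$t_statistic, x$p_value))
  invisible(x)
}

#' PGLS over a trait table
#'
#' Convenience wrapper: fits [pgls_fit()] for a response and one or more
#' predictors taken from a per-species trait table, optionally
#' log10-transforming variables first (Ne proxies such as longevity and
#' body length are conventionally analysed on log scale).
#'
#' @param traits Data.frame with a `species` column matching the tree's tip
#'   labels.
#' @param tree A rooted [ape::phylo].
#' @param y Name of the response column.
#' @param x Character vector of predictor column names (one fit each).
#' @param log_y,log_x Log10-transform the response / predictors.
#' @return A data.frame with one row per predictor: `y`, `x`, `slope`,
#'   `slope_se`, `t_statistic`, `p_value`, `n_taxa`.
#' @export
pgls_traits <- function(traits, tree, y, x, log_y = FALSE, log_x = FALSE) {
  stopifnot(all(c("species", y, x) %in% names(traits)))
  missing_sp <- setdiff(tree$tip.label, traits$species)
  if (length(missing_sp))
    stop("species missing from trait table: ",
         paste(missing_sp, collapse = ", "))
  V <- brownian_vcv(tree)
  tr <- traits[match(rownames(V), traits$species), , drop = FALSE]
  yy <- tr[[y]]
  if (log_y) yy <- log10(yy)
  names(yy) <- tr$species
  rows <- lapply(x, function(xc) {
    xx <- tr[[xc]]
    if (log_x) xx <- log10(xx)
    names(xx) <- tr$species
    f <- pgls_fit(yy, xx, V)
    data.frame(y = y, x = xc, slope = f$slope, slope_se = f$slope_se,
               t_statistic = f$t_statistic, p_value = f$p_value,
               n_taxa = f$n_taxa, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
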