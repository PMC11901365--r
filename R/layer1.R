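# Layer 1: rbf kernel PCA to two components, then a rotated-ellipse capture
# region built from the clinical reference cloud. Containment is analytic
# (rotate/translate + canonical inequality); the 100-vertex polygon variant
# is retained only as a test oracle and TSV export.

#' Kernel PCA configuration
#'
#' @param kernel `"rbf"` (default), `"cosine"` or `"poly"`.
#' @param gamma kernel coefficient; default 500 (the rbf value used for
#'   language-model encodings). For `"poly"`, degree 3 and coef0 1 are fixed.
#' @param n_components number of components (2 for the gate).
#' @return a `kpca_config`.
#' @export
kpca_config <- function(kernel = c("rbf", "cosine", "poly"), gamma = 500,
                        n_components = 2L) {
  kernel <- match.arg(kernel)
  stopifnot(gamma > 0, n_components >= 1)
  structure(list(kernel = kernel, gamma = gamma,
                 n_components = as.integer(n_components)),
            class = "kpca_config")
}

kernel_matrix <- function(X, Y, config) {
  switch(config$kernel,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
      exp(-config$gamma * pmax(d2, 0))
    },
    cosine = {
      nx <- sqrt(rowSums(X^2)); ny <- sqrt(rowSums(Y^2))
      tcrossprod(X, Y) / outer(pmax(nx, 1e-300), pmax(ny, 1e-300))
    },
    poly = (config$gamma * tcrossprod(X, Y) + 1)^3)
}

#' Fit kernel PCA
#'
#' Eigendecomposition of the double-centered kernel matrix. Training
#' projections are the top eigenvectors scaled by the square root of their
#' eigenvalues, with the sign convention that each component's
#' largest-magnitude loading is positive.
#'
#' @param X numeric matrix (>= 3 rows, finite).
#' @param config a [kpca_config()].
#' @return a `kpca_model` with `projections` (n x n_components), eigenvalues
#'   `lambda`, and what [kpca_project()] needs for out-of-sample points.
#' @export
fit_kpca <- function(X, config = kpca_config()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 3, all(is.finite(X)))
  n <- nrow(X)
  K <- kernel_matrix(X, X, config)
  rm_ <- rowMeans(K); am <- mean(K)
  Kc <- K - matrix(rm_, n, n) - matrix(rm_, n, n, byrow = TRUE) + am
  eig <- eigen(Kc, symmetric = TRUE)
  lam <- eig$values[seq_len(config$n_components)]
  if (any(lam < 1e-12 * max(eig$values[1], 1e-300)) || eig$values[1] <= 0)
    ab_stop("ab_degenerate_kernel", sprintf(
      "centered kernel has rank < %d", config$n_components))
  V <- eig$vectors[, seq_len(config$n_components), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(config = config, X = X, col_means = rm_, all_mean = am,
                 lambda = lam,
                 alphas = sweep(V, 2, sqrt(lam), "/"),
                 projections = sweep(V, 2, sqrt(lam), "*")),
            class = "kpca_model")
}

#' Project new points with a fitted kernel PCA model
#'
#' Kernel-centred projection; projecting the training rows reproduces the
#' stored training projections.
#'
#' @param model a `kpca_model`.
#' @param X_new matrix with the training feature dimension (0 rows allowed).
#' @return matrix (nrow(X_new) x n_components).
#' @export
kpca_project <- function(model, X_new) {
  stopifnot(inherits(model, "kpca_model"))
  X_new <- as.matrix(X_new)
  if (nrow(X_new) == 0L)
    return(matrix(numeric(0), 0, model$config$n_components))
  if (ncol(X_new) != ncol(model$X))
    ab_stop("ab_dimension_mismatch", sprintf(
      "new data has %d features, model was fit on %d", ncol(X_new), ncol(model$X)))
  Kn <- kernel_matrix(X_new, model$X, model$config)
  Kc <- Kn - matrix(model$col_means, nrow(Kn), ncol(Kn), byrow = TRUE) -
    rowMeans(Kn) + model$all_mean
  Kc %*% model$alphas
}

# Ellipse gate ------------------------------------------------------------

#' Construct a rotated ellipse from its major-axis endpoints
#'
#' Major radius a = |p2 - p1| / 2, minor radius b = h / 2, rotation
#' theta = atan2(dy, dx), centre = midpoint of the endpoints.
#'
#' @param p1,p2 numeric length-2 points (the major-axis extremes).
#' @param h minor-axis height (> 0).
#' @return an `ellipse_spec`: `a`, `b`, `theta`, `center`, `p1`, `p2`, `h`.
#' @export
make_ellipse <- function(p1, p2, h) {
  stopifnot(length(p1) == 2, length(p2) == 2)
  if (isTRUE(all.equal(p1, p2, tolerance = 0)) || all(p1 == p2))
    ab_stop("ab_degenerate_ellipse", "major-axis endpoints coincide")
  if (!is.numeric(h) || h <= 0)
    ab_stop("ab_degenerate_ellipse", "minor height h must be > 0")
  d <- p2 - p1
  structure(list(a = sqrt(sum(d^2)) / 2, b = h / 2,
                 theta = atan2(d[2], d[1]),
                 center = (p1 + p2) / 2, p1 = p1, p2 = p2, h = h),
            class = "ellipse_spec")
}

#' Point-in-ellipse containment (boundary counts as inside)
#'
#' @param e an `ellipse_spec`.
#' @param p length-2 point or an n x 2 matrix.
#' @return logical vector.
#' @export
point_in_ellipse <- function(e, p) {
  stopifnot(inherits(e, "ellipse_spec"))
  p <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  x <- p[, 1] - e$center[1]; y <- p[, 2] - e$center[2]
  ct <- cos(e$theta); st <- sin(e$theta)
  xr <- ct * x + st * y
  yr <- -st * x + ct * y
  (xr / e$a)^2 + (yr / e$b)^2 <= 1 + 1e-9
}

#' Parametric polygon approximation of an ellipse
#'
#' 100 equally spaced parameter values by default; used for TSV export and as
#' the independent containment oracle in the test suite.
#'
#' @param e an `ellipse_spec`.
#' @param n vertex count.
#' @return n x 2 matrix of vertices.
#' @export
ellipse_polygon <- function(e, n = 100L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ct <- cos(e$theta); st <- sin(e$theta)
  x0 <- e$a * cos(t); y0 <- e$b * sin(t)
  cbind(e$center[1] + ct * x0 - st * y0,
        e$center[2] + st * x0 + ct * y0)
}

#' Build the Layer-1 ellipse from reference (clinical) projections
#'
#' The major axis is the projection component with the greater reference
#' range. For numeric Z, the endpoints are the two reference points whose
#' major-axis coordinates are closest to mean +/- Z*sd, and the minor height
#' is 2*Z*sd of the minor coordinate. For `z = "all"`, the endpoints are the
#' extreme reference points and the minor height is grown to the smallest
#' value capturing every reference point (matching the published definition
#' of the "All" threshold: every reference antibody captured).
#'
#' For numeric Z two endpoint conventions are available: `"nearest"` (the
#' published rule -- the actual reference points nearest mean +/- Z*sd, which
#' tilts the ellipse and makes gates at different Z only approximately
#' nested) and `"moment"` (idealised points on the major component axis at
#' exactly mean +/- Z*sd, for which gates are exactly nested in Z).
#'
#' @param points_2d n x 2 matrix of reference projections (n >= 3).
#' @param z positive number or `"all"`.
#' @param endpoints `"nearest"` (default) or `"moment"`.
#' @return an `ellipse_spec` (with attributes `z` and `major_axis`).
#' @export
ellipse_from_reference <- function(points_2d, z = "all",
                                   endpoints = c("nearest", "moment")) {
  endpoints <- match.arg(endpoints)
  points_2d <- as.matrix(points_2d)
  if (nrow(points_2d) < 3)
    ab_stop("ab_insufficient_reference", "need >= 3 reference points")
  rng <- apply(points_2d, 2, function(v) diff(range(v)))
  maj <- which.max(rng); mnr <- if (maj == 1L) 2L else 1L
  mc <- points_2d[, maj]
  if (identical(z, "all")) {
    p1 <- points_2d[which.min(mc), ]; p2 <- points_2d[which.max(mc), ]
    if (all(p1 == p2))
      ab_stop("ab_degenerate_ellipse", "reference points are coincident")
    ctr <- (p1 + p2) / 2; d <- p2 - p1
    a <- sqrt(sum(d^2)) / 2; th <- atan2(d[2], d[1])
    xr <- cos(th) * (points_2d[, 1] - ctr[1]) + sin(th) * (points_2d[, 2] - ctr[2])
    yr <- -sin(th) * (points_2d[, 1] - ctr[1]) + cos(th) * (points_2d[, 2] - ctr[2])
    # guarded expansion: any point past the endpoint span would need b = Inf
    amax <- max(abs(xr))
    if (amax >= a) a <- amax * (1 + 1e-6)
    den <- sqrt(pmax(1 - (xr / a)^2, 1e-300))
    breq <- max(ifelse(abs(yr) < 1e-12, 0, abs(yr) / den))
    if (breq <= 0)
      ab_stop("ab_degenerate_ellipse", "reference points are collinear")
    e <- make_ellipse(p1, p2, h = 2 * breq * (1 + 1e-9))
    e$a <- a  # expanded major radius, if any point fell outside the span
  } else {
    stopifnot(is.numeric(z), z >= 0)
    mu <- mean(mc); s <- stats::sd(mc)
    if (endpoints == "nearest") {
      p1 <- points_2d[which.min(abs(mc - (mu - z * s))), ]
      p2 <- points_2d[which.min(abs(mc - (mu + z * s))), ]
    } else {
      mu2 <- mean(points_2d[, mnr])
      p1 <- p2 <- c(NA_real_, NA_real_)
      p1[maj] <- mu - z * s; p2[maj] <- mu + z * s
      p1[mnr] <- p2[mnr] <- mu2
    }
    if (all(p1 == p2))
      ab_stop("ab_degenerate_ellipse",
              "Z too small: major-axis endpoints coincide")
    e <- make_ellipse(p1, p2, h = 2 * z * stats::sd(points_2d[, mnr]))
  }
  attr(e, "z") <- z
  attr(e, "major_axis") <- maj
  e
}

#' Per-group ellipse capture percentages
#'
#' @param e an `ellipse_spec`.
#' @param points n x 2 matrix.
#' @param groups factor/character of length n.
#' @return named numeric vector of percentages (0-100).
#' @export
capture_rates <- function(e, points, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || length(groups) == 0)
    ab_stop("ab_empty_group", "every group must be non-empty")
  inside <- point_in_ellipse(e, as.matrix(points))
  100 * vapply(split(inside, groups), mean, numeric(1))
}

#' Layer-1 selection: ids whose projections fall inside the gate
#'
#' @param ids character vector.
#' @param projections matching n x 2 matrix.
#' @param e an `ellipse_spec`.
#' @return retained ids (character).
#' @export
layer1_select <- function(ids, projections, e) {
  projections <- as.matrix(projections)
  stopifnot(length(ids) == nrow(projections))
  if (!length(ids)) return(character(0))
  ids[point_in_ellipse(e, projections)]
}
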