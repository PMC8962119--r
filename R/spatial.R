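# Spatial diagnostics and residual correlation structures.

#' Moran's I spatial autocorrelation test
#'
#' Global Moran's I with row-standardized weights.  The default weights are
#' inverse Euclidean distance; `knn` gives binary k-nearest-neighbour
#' weights.  The p-value uses the normal approximation under the
#' randomization assumption; a permutation p-value is computed when
#' `n_perm > 0`.
#'
#' @param values numeric vector (e.g. DBH), length n >= 4.
#' @param coords n x 2 matrix or data.frame of planar coordinates.
#' @param weight_scheme `"inverse_distance"` or `"knn"`.
#' @param k neighbours for the knn scheme.
#' @param n_perm number of permutations (0 = analytic only).
#' @param seed seed for the permutation test.
#' @param alternative `"greater"` (clustering, default), `"less"` or
#'   `"two.sided"`.
#' @return list of class `moran_result`: `I`, `expected` (= -1/(n-1)),
#'   `variance`, `z`, `p_value`, `p_perm` (or `NA`), `weight_scheme`.
#' @export
morans_i <- function(values, coords,
                     weight_scheme = c("inverse_distance", "knn"),
                     k = 8L, n_perm = 0L, seed = 1L,
                     alternative = c("greater", "less", "two.sided")) {
  weight_scheme <- match.arg(weight_scheme)
  alternative <- match.arg(alternative)
  coords <- as.matrix(coords)
  n <- length(values)
  stopifnot(n >= 4L, nrow(coords) == n)
  if (stats::sd(values) == 0) stop("values are constant: Moran's I undefined")
  D <- as.matrix(stats::dist(coords))
  if (weight_scheme == "inverse_distance") {
    if (any(D[upper.tri(D)] == 0))
      stop("coincident points: jitter coordinates or use the knn scheme")
    W <- 1 / D
    diag(W) <- 0
  } else {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[2:(k + 1L)]
      W[i, nb] <- 1
    }
  }
  W <- W / rowSums(W)
  z <- values - mean(values)
  s0 <- sum(W)
  I <- (n / s0) * sum(W * outer(z, z)) / sum(z^2)
  EI <- -1 / (n - 1)
  # randomization variance (Cliff & Ord)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * s0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - EI^2
  zs <- (I - EI) / sqrt(VI)
  p <- switch(alternative,
              greater = stats::pnorm(zs, lower.tail = FALSE),
              less = stats::pnorm(zs),
              two.sided = 2 * stats::pnorm(abs(zs), lower.tail = FALSE))
  p_perm <- NA_real_
  if (n_perm > 0) {
    Iperm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      zp <- z[sample.int(n)]
      (n / s0) * sum(W * outer(zp, zp)) / sum(zp^2)
    }, numeric(1)))
    p_perm <- switch(alternative,
                     greater = (1 + sum(Iperm >= I)) / (n_perm + 1),
                     less = (1 + sum(Iperm <= I)) / (n_perm + 1),
                     two.sided = (1 + sum(abs(Iperm - EI) >= abs(I - EI))) /
                       (n_perm + 1))
  }
  structure(list(I = I, expected = EI, variance = VI, z = zs, p_value = p,
                 p_perm = p_perm, weight_scheme = weight_scheme, n = n,
                 alternative = alternative),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf(
    "Moran's I = %.4f (expected %.4f), z = %.2f, p = %.3g [%s, %s]\n",
    x$I, x$expected, x$z, x$p_value, x$weight_scheme, x$alternative))
  if (!is.na(x$p_perm)) cat(sprintf("permutation p = %.3g\n", x$p_perm))
  invisible(x)
}

#' Rasterize irregular tree coordinates onto a grid
#'
#' Affine map of the coordinate bounding box onto an `nrows` x `ncols`
#' grid with truncation to integer cells (0-based, row-major; rows follow
#' y, columns follow x).  When two trees land in the same cell the later
#' tree (in id order) is moved to the nearest free cell by Chebyshev
#' distance, scanning each ring in row-major order — deterministic and
#' injective.
#'
#' @param records data.frame with columns `id`, `x`, `y`.
#' @param nrows,ncols grid dimensions; `nrows * ncols` must be >= n.
#' @return data.frame of class `grid_assignment` with columns id, row, col
#'   and attributes `nrows`, `ncols`, `n_nudged`.
#' @export
rasterize <- function(records, nrows, ncols) {
  n <- nrow(records)
  if (nrows * ncols < n) stop("more trees than grid cells")
  rx <- range(records$x); ry <- range(records$y)
  if (diff(rx) == 0 || diff(ry) == 0)
    stop("degenerate coordinate bounding box")
  col0 <- pmin(floor((records$x - rx[1]) / diff(rx) * ncols), ncols - 1L)
  row0 <- pmin(floor((records$y - ry[1]) / diff(ry) * nrows), nrows - 1L)
  occupied <- matrix(FALSE, nrows, ncols)
  row <- integer(n); col <- integer(n)
  nudged <- 0L
  for (i in seq_len(n)) {
    r <- row0[i]; cc <- col0[i]
    if (!occupied[r + 1L, cc + 1L]) {
      row[i] <- r; col[i] <- cc
    } else {
      nudged <- nudged + 1L
      found <- FALSE
      for (rad in seq_len(max(nrows, ncols))) {
        # ring at Chebyshev distance rad, row-major scan
        rr <- max(0L, r - rad):min(nrows - 1L, r + rad)
        for (r2 in rr) {
          ccs <- max(0L, cc - rad):min(ncols - 1L, cc + rad)
          if (abs(r2 - r) < rad)         # only the ring edges
            ccs <- ccs[abs(ccs - cc) == rad]
          for (c2 in ccs) {
            if (!occupied[r2 + 1L, c2 + 1L]) {
              row[i] <- r2; col[i] <- c2; found <- TRUE; break
            }
          }
          if (found) break
        }
        if (found) break
      }
      if (!found) stop("no free cell found (grid too small)")
    }
    occupied[row[i] + 1L, col[i] + 1L] <- TRUE
  }
  out <- data.frame(id = records$id, row = row, col = col)
  attr(out, "nrows") <- nrows
  attr(out, "ncols") <- ncols
  attr(out, "n_nudged") <- nudged
  class(out) <- c("grid_assignment", "data.frame")
  out
}

#' Define a residual spatial correlation structure
#'
#' Distance-based kinds (`exponential`, `gaussian`, `spherical`, `linear`,
#' `rational`) take a range `r > 0` and operate on raw coordinates.  `ar1`
#' takes a single `rho` and operates on the row-major cell sequence of a
#' grid; `ar1xar1` takes `rho_row`, `rho_col` and is the separable
#' row-by-column product.
#'
#' @param kind one of `"exponential"`, `"gaussian"`, `"spherical"`,
#'   `"linear"`, `"rational"`, `"ar1"`, `"ar1xar1"`, or `"none"`.
#' @param r range parameter (distance kinds).
#' @param rho,rho_row,rho_col autoregression parameters in (-1, 1).
#' @return list of class `spatial_structure`.
#' @export
spatial_structure <- function(kind, r = NULL, rho = NULL,
                              rho_row = NULL, rho_col = NULL) {
  kind <- match.arg(kind, c("exponential", "gaussian", "spherical",
                            "linear", "rational", "ar1", "ar1xar1", "none"))
  if (kind %in% c("exponential", "gaussian", "spherical", "linear",
                  "rational")) {
    if (!is.null(r) && r <= 0) stop("range r must be positive")
  } else if (kind == "ar1") {
    if (!is.null(rho) && abs(rho) >= 1) stop("|rho| must be < 1")
  } else if (kind == "ar1xar1") {
    for (p in c(rho_row, rho_col))
      if (!is.null(p) && abs(p) >= 1) stop("|rho| must be < 1")
  }
  structure(list(kind = kind, r = r, rho = rho,
                 rho_row = rho_row, rho_col = rho_col),
            class = "spatial_structure")
}

#' Correlation at a given separation
#'
#' @param structure a [spatial_structure()].
#' @param separation Euclidean distance (distance kinds), integer lag
#'   (`ar1`), or two-column matrix / length-2 vector of `(drow, dcol)` lags
#'   (`ar1xar1`).
#' @export
correlation <- function(structure, separation) {
  kind <- structure$kind
  if (kind == "ar1xar1") {
    sep <- if (is.matrix(separation)) separation else
      matrix(separation, ncol = 2L)
    return(structure$rho_row^abs(sep[, 1L]) *
             structure$rho_col^abs(sep[, 2L]))
  }
  if (kind == "ar1") return(structure$rho^abs(separation))
  d <- separation
  if (any(d < 0)) stop("negative distance")
  r <- structure$r
  switch(kind,
         exponential = exp(-d / r),
         gaussian = exp(-(d / r)^2),
         spherical = ifelse(d < r, 1 - 1.5 * (d / r) + 0.5 * (d / r)^3, 0),
         linear = ifelse(d < r, 1 - d / r, 0),
         rational = 1 - (d / r)^2 / (1 + (d / r)^2),
         none = as.numeric(d == 0),
         stop("unsupported kind"))
}

#' Correlation matrix over observed trees
#'
#' For distance-based structures the matrix is built from pairwise
#' Euclidean distances between coordinates.  For `ar1` it uses the
#' row-major cell index of an injective grid assignment as a 1-D position;
#' for `ar1xar1` the entry for trees in cells `(r1,c1)`, `(r2,c2)` is
#' `rho_row^|r1-r2| * rho_col^|c1-c2|` — the observed-cell submatrix of the
#' full Kronecker product, which is never materialized.
#'
#' @param structure a [spatial_structure()].
#' @param grid a `grid_assignment` (required for ar1 kinds).
#' @param coords data.frame/matrix with x, y (distance kinds).
#' @param ids optional id subset/order; default order of `grid`/`coords`.
#' @return dense correlation matrix with unit diagonal.
#' @export
build_correlation_matrix <- function(structure, grid = NULL, coords = NULL,
                                     ids = NULL) {
  kind <- structure$kind
  if (kind %in% c("ar1", "ar1xar1")) {
    if (is.null(grid)) stop(kind, " needs a grid assignment")
    if (anyDuplicated(grid$row * attr(grid, "ncols") + grid$col))
      stop("grid assignment is not injective")
    if (!is.null(ids)) grid <- grid[match(ids, grid$id), , drop = FALSE]
    if (kind == "ar1xar1") {
      R <- outer(grid$row, grid$row,
                 function(a, b) structure$rho_row^abs(a - b)) *
        outer(grid$col, grid$col,
              function(a, b) structure$rho_col^abs(a - b))
    } else {
      pos <- grid$row * attr(grid, "ncols") + grid$col
      R <- outer(pos, pos, function(a, b) structure$rho^abs(a - b))
    }
    dimnames(R) <- list(grid$id, grid$id)
    return(R)
  }
  if (kind == "none") {
    n <- if (!is.null(ids)) length(ids) else nrow(coords)
    return(diag(n))
  }
  if (is.null(coords)) stop(kind, " needs coordinates")
  cc <- as.data.frame(coords)
  if (!is.null(ids)) cc <- cc[match(ids, cc$id), , drop = FALSE]
  D <- as.matrix(stats::dist(cbind(cc$x, cc$y)))
  R <- correlation(structure, D)
  dim(R) <- dim(D)
  diag(R) <- 1
  if (!is.null(cc$id)) dimnames(R) <- list(cc$id, cc$id)
  R
}
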