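# Moran's I, rasterization, correlation structures

test_that("Moran expectation, checkerboard sign, and field detection", {
  # expected I is -1/(n-1) for any input
  set.seed(71)
  v <- rnorm(30)
  xy <- cbind(runif(30), runif(30))
  m <- morans_i(v, xy)
  expect_equal(m$expected, -1 / 29)

  # perfect checkerboard -> strong negative autocorrelation
  g <- expand.grid(x = 1:6, y = 1:6)
  chk <- (-1)^(g$x + g$y)
  mc <- morans_i(chk, g, weight_scheme = "knn", k = 4)
  expect_lt(mc$I, mc$expected)

  # a strong AR1xAR1 field is detected (z > 0, permutation p small)
  Lr <- orchardgt:::ar1_chol(12, 0.9)
  set.seed(72)
  f <- Lr %*% matrix(rnorm(144), 12, 12) %*% t(Lr)
  gg <- expand.grid(row = 1:12, col = 1:12)
  mf <- morans_i(f[cbind(gg$row, gg$col)], cbind(gg$col, gg$row),
                 n_perm = 199, seed = 73)
  expect_gt(mf$z, 0)
  expect_lt(mf$p_perm, 0.01)
  expect_lt(mf$p_value, 0.01)
})

test_that("Moran errors on degenerate inputs", {
  xy <- cbind(1:5, 1:5)
  expect_error(morans_i(rep(1, 5), xy), "constant")
  xy2 <- rbind(c(0, 0), c(0, 0), c(1, 1), c(2, 2))
  expect_error(morans_i(rnorm(4), xy2), "oincident")
})

test_that("permutation and normal-approximation p agree on null fields", {
  set.seed(74)
  diffs <- replicate(5, {
    v <- rnorm(100)
    xy <- cbind(runif(100, 0, 50), runif(100, 0, 50))
    m <- morans_i(v, xy, n_perm = 399, seed = 75)
    abs(m$p_value - m$p_perm)
  })
  expect_lt(max(diffs), 0.05)
})

test_that("rasterization is injective with deterministic collision rule", {
  # corners of the unit square, 2x2 grid: no collisions
  rec <- data.frame(id = letters[1:4], x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  g <- rasterize(rec, 2, 2)
  expect_equal(nrow(unique(g[, c("row", "col")])), 4L)
  expect_equal(attr(g, "n_nudged"), 0L)

  # coincident pair: second tree moved to an adjacent free cell
  rec2 <- data.frame(id = c("a", "b", "z"), x = c(5, 5, 9), y = c(5, 5, 9))
  g2 <- rasterize(rec2, 10, 10)
  expect_equal(nrow(unique(g2[, c("row", "col")])), 3L)
  expect_equal(max(abs(g2$row[2] - g2$row[1]), abs(g2$col[2] - g2$col[1])),
               1L)

  expect_error(rasterize(rec, 1, 2), "more trees than")

  # jittered synthetic positions: injective, mostly unnudged
  set.seed(76)
  n <- 188
  cells <- sample.int(450 * 450, n)
  row <- (cells - 1) %/% 450; col <- (cells - 1) %% 450
  rec3 <- data.frame(id = sprintf("t%03d", 1:n),
                     x = col + 0.5 + runif(n, -0.3, 0.3),
                     y = row + 0.5 + runif(n, -0.3, 0.3))
  # pin the bounding box so the affine map is the identity on cells
  rec3 <- rbind(rec3, data.frame(id = c("lo", "hi"),
                                 x = c(0, 450), y = c(0, 450)))
  g3 <- rasterize(rec3, 450, 450)
  expect_equal(anyDuplicated(g3[, c("row", "col")]), 0L)
  match_rate <- mean(g3$row[1:n] == row & g3$col[1:n] == col)
  expect_gte(match_rate, 0.95)
})

test_that("correlation kinds: closed forms, bounds, monotonicity", {
  kinds <- c("exponential", "gaussian", "spherical", "linear", "rational")
  d <- seq(0, 30, by = 0.5)
  for (k in kinds) {
    st <- spatial_structure(k, r = 10)
    v <- correlation(st, d)
    expect_equal(v[1], 1, label = k)
    expect_true(all(v <= 1 & v >= -1), label = k)
    expect_true(all(diff(v) <= 1e-12), label = k)  # non-increasing
    expect_error(correlation(st, -1), "negative")
  }
  expect_equal(correlation(spatial_structure("spherical", r = 10), 10), 0)
  expect_equal(correlation(spatial_structure("linear", r = 10), 10), 0)
  expect_equal(correlation(spatial_structure("rational", r = 10), 10), 0.5)
  expect_equal(correlation(spatial_structure("ar1", rho = 0.5), 3), 0.125)
  st2 <- spatial_structure("ar1xar1", rho_row = 0.5, rho_col = 0.4)
  expect_equal(correlation(st2, c(2, 3)), 0.25 * 0.064)
  expect_equal(correlation(st2, c(0, 0)), 1)
  expect_error(spatial_structure("ar1", rho = 1.2), "rho")
})

test_that("observed submatrix equals the explicit Kronecker product", {
  # full grids up to 5x5, random rho pairs
  set.seed(77)
  for (rep in 1:4) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    rr <- runif(1, -0.8, 0.9); rc <- runif(1, -0.8, 0.9)
    gg <- expand.grid(col = 0:(nc - 1), row = 0:(nr - 1))  # row-major order
    gg <- gg[order(gg$row, gg$col), ]
    grid <- data.frame(id = sprintf("c%02d", seq_len(nr * nc)),
                       row = gg$row, col = gg$col)
    attr(grid, "nrows") <- nr; attr(grid, "ncols") <- nc
    class(grid) <- c("grid_assignment", "data.frame")
    st <- spatial_structure("ar1xar1", rho_row = rr, rho_col = rc)
    R <- build_correlation_matrix(st, grid = grid)
    Ar <- outer(0:(nr - 1), 0:(nr - 1), function(a, b) rr^abs(a - b))
    Ac <- outer(0:(nc - 1), 0:(nc - 1), function(a, b) rc^abs(a - b))
    expect_equal(unname(R), kronecker(Ar, Ac), tolerance = 1e-12)

    # extraction commutes: random observed subset
    keep <- sort(sample(nr * nc, min(6, nr * nc)))
    Rsub <- build_correlation_matrix(st, grid = grid[keep, ])
    expect_equal(unname(Rsub), kronecker(Ar, Ac)[keep, keep],
                 tolerance = 1e-12)
  }
})

test_that("ar1xar1 submatrices are positive definite at high rho", {
  set.seed(78)
  cells <- sample.int(20 * 20, 30)
  grid <- data.frame(id = sprintf("t%02d", 1:30),
                     row = (cells - 1) %/% 20, col = (cells - 1) %% 20)
  attr(grid, "nrows") <- 20; attr(grid, "ncols") <- 20
  class(grid) <- c("grid_assignment", "data.frame")
  st <- spatial_structure("ar1xar1", rho_row = 0.9, rho_col = 0.9)
  R <- build_correlation_matrix(st, grid = grid)
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(unname(diag(R)), rep(1, 30))

  st0 <- spatial_structure("ar1xar1", rho_row = 0, rho_col = 0)
  expect_equal(unname(build_correlation_matrix(st0, grid = grid)), diag(30))

  # non-injective grid errors
  grid2 <- grid; grid2$row[2] <- grid2$row[1]; grid2$col[2] <- grid2$col[1]
  expect_error(build_correlation_matrix(st, grid = grid2), "injective")
})
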