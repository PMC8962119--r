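# REML/BLUP against dense independent oracles, AICc, model comparison

# small simulated dataset shared across blocks
make_small <- function(seed = 101, n_dams = 4, fam = 2, grid = c(4, 4),
                       truth = default_truth()) {
  af <- simulate_allele_frequencies(n_loci = 3, seed = seed)
  orch <- simulate_orchard(af, n_mothers = n_dams, family_sizes = fam,
                           seed = seed + 1)
  sim <- simulate_phenotypes(orch$pedigree, truth, grid_dims = grid,
                             seed = seed + 2)
  sim
}

test_that("reml_loglik equals the error-contrast oracle (n <= 12)", {
  sim <- make_small()
  y <- sim$records$dbh
  n <- length(y)
  X <- matrix(1, n, 1)
  G <- sim$A[sim$records$id, sim$records$id]
  st <- spatial_structure("ar1xar1", rho_row = 0.6, rho_col = 0.7)
  R <- build_correlation_matrix(st, grid = sim$grid, ids = sim$records$id)
  params_grid <- list(
    list(sigma2_A = 5, sigma2_xi = 8, sigma2_eta = 3,
         rho_row = 0.6, rho_col = 0.7),
    list(sigma2_A = 1, sigma2_xi = 0.5, sigma2_eta = 10,
         rho_row = -0.3, rho_col = 0.2),
    list(sigma2_A = 9.086, sigma2_xi = 12.478, sigma2_eta = 4.885,
         rho_row = 0.8, rho_col = 0.8))
  spec <- model_spec("ar1xar1")
  for (pp in params_grid) {
    stp <- spatial_structure("ar1xar1", rho_row = pp$rho_row,
                             rho_col = pp$rho_col)
    Rp <- build_correlation_matrix(stp, grid = sim$grid,
                                   ids = sim$records$id)
    V <- pp$sigma2_A * G + pp$sigma2_xi * Rp + pp$sigma2_eta * diag(n)
    expect_equal(reml_loglik(pp, spec, sim$records, sim$A, sim$grid),
                 as.numeric(oracle_reml_contrasts(y, X, V)),
                 tolerance = 1e-8)
  }
})

test_that("degenerate REML reduces to the i.i.d. closed form", {
  set.seed(103)
  y <- rnorm(15, 20, 3)
  data <- data.frame(id = sprintf("i%02d", 1:15), dbh = y,
                     x = runif(15), y = runif(15))
  A <- diag(15); dimnames(A) <- list(data$id, data$id)
  spec <- model_spec("none")
  # at sigma2_A = 0 the model is i.i.d.; profile likelihood over sigma2_eta
  # is maximized at the n-1 sample variance
  s2 <- seq(0.5, 3, by = 0.01) * var(y)
  ll <- vapply(s2, function(s)
    reml_loglik(list(sigma2_A = 1e-12, sigma2_eta = s), spec, data, A),
    numeric(1))
  expect_equal(s2[which.max(ll)], var(y), tolerance = 0.02 * var(y))
})

test_that("blup matches Henderson's mixed-model equations", {
  sim <- make_small(seed = 104, n_dams = 4, fam = 3, grid = c(4, 4))
  fit <- fit_spatial_model(model_spec("ar1xar1"), sim$records, A = sim$A,
                           grid = sim$grid, seed = 105)
  est <- fit$estimates
  n <- nrow(sim$records)
  ids_all <- rownames(sim$A)
  Z <- matrix(0, n, length(ids_all),
              dimnames = list(sim$records$id, ids_all))
  Z[cbind(seq_len(n), match(sim$records$id, ids_all))] <- 1
  st <- spatial_structure("ar1xar1", rho_row = est$rho_row,
                          rho_col = est$rho_col)
  Rs <- build_correlation_matrix(st, grid = sim$grid, ids = sim$records$id)
  R_full <- est$sigma2_xi * Rs + est$sigma2_eta * diag(n)
  mme <- oracle_blup_mme(sim$records$dbh, matrix(1, n, 1), Z, sim$A,
                         est$sigma2_A, R_full)
  expect_equal(fit$blup[ids_all], mme$u[ids_all], tolerance = 1e-6)
  expect_equal(fit$intercept, unname(mme$b), tolerance = 1e-6)
  # non-phenotyped mothers received predictions through A
  mothers <- setdiff(ids_all, sim$records$id)
  expect_true(all(is.finite(fit$blup[mothers])))
  expect_true(any(fit$blup[mothers] != 0))
})

test_that("aicc arithmetic, limit and penalty ordering", {
  expect_equal(aicc(-100, 3, 188), 200 + 6 + 24 / 184)
  expect_equal(aicc(-50, 4, 1e8), 100 + 8, tolerance = 1e-5)
  expect_lt(aicc(-10, 2, 100), aicc(-10, 5, 100))
  expect_error(aicc(-10, 9, 10), "undefined")
})

test_that("heritability follows the full-denominator convention", {
  expect_equal(heritability(c(sigma2_A = 3, sigma2_xi = 0, sigma2_eta = 6)),
               1 / 3)
  expect_equal(heritability(c(sigma2_A = 0, sigma2_xi = 2, sigma2_eta = 1)),
               0)
  expect_error(heritability(c(sigma2_A = 0, sigma2_xi = 0, sigma2_eta = 0)),
               "zero")
})

test_that("fits are deterministic and nested models are consistent", {
  sim <- make_small(seed = 106, n_dams = 10, fam = 3, grid = c(8, 8),
                    truth = default_truth(sigma2_xi = 0.001))
  f1 <- fit_spatial_model(model_spec("ar1xar1"), sim$records, A = sim$A,
                          grid = sim$grid, seed = 107)
  f2 <- fit_spatial_model(model_spec("ar1xar1"), sim$records, A = sim$A,
                          grid = sim$grid, seed = 107)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$blup, f2$blup)

  f0 <- fit_spatial_model(model_spec("none"), sim$records, A = sim$A,
                          seed = 107)
  # truth has (almost) no spatial variance: fitted sigma2_xi small and the
  # spatial fit cannot fall below the nested animal-only optimum
  expect_lt(f1$estimates$sigma2_xi,
            0.2 * (f1$estimates$sigma2_A + f1$estimates$sigma2_eta))
  expect_gte(f1$loglik, f0$loglik - 1e-6)
})

test_that("likelihood is monotone under nesting for every structure", {
  sim <- make_small(seed = 108, n_dams = 12, fam = 3, grid = c(9, 9))
  f0 <- fit_spatial_model(model_spec("none"), sim$records, A = sim$A,
                          seed = 109)
  for (kind in c("exponential", "gaussian", "spherical", "linear",
                 "rational", "ar1", "ar1xar1")) {
    f <- fit_spatial_model(model_spec(kind), sim$records, A = sim$A,
                           grid = sim$grid, seed = 109)
    expect_gte(f$loglik, f0$loglik - 1e-6)
  }
})

test_that("model comparison ranks the generating structure first", {
  sim <- make_small(seed = 110, n_dams = 25, fam = 4, grid = c(11, 11),
                    truth = default_truth(sigma2_xi = 20,
                                          rho_row = 0.85, rho_col = 0.85))
  cmp <- compare_models(sim$records, sim$A, sim$grid,
                        structures = c("none", "exponential", "ar1xar1"),
                        seed = 111)
  expect_s3_class(cmp, "model_comparison")
  expect_equal(cmp$model[1], "animal+ar1xar1")
  expect_equal(cmp$rank, seq_len(nrow(cmp)))
  expect_true(all(diff(cmp$aicc) >= 0))

  # single spec -> one row, rank 1
  one <- compare_models(sim$records, sim$A, sim$grid,
                        structures = "none", seed = 111)
  expect_equal(nrow(one), 1L)
  expect_equal(one$rank, 1L)
})

test_that("blup accuracy grows with heritability; ranking is deterministic", {
  cors <- vapply(c(0.1, 0.3, 0.6), function(h2) {
    tot <- 26.449
    tr <- default_truth(sigma2_A = h2 * tot, sigma2_xi = 0,
                        sigma2_eta = (1 - h2) * tot)
    sim <- make_small(seed = 112, n_dams = 20, fam = 4, grid = c(10, 10),
                      truth = tr)
    fit <- fit_spatial_model(model_spec("none"), sim$records, A = sim$A,
                             seed = 113)
    cor(fit$blup[sim$records$id], sim$true_u[sim$records$id])
  }, numeric(1))
  expect_true(all(cors > 0))
  expect_true(all(diff(cors) > 0))

  ebv <- c(a = 2, b = 5, c = -1)
  sel <- rank_selection(ebv, 2, "forward")
  expect_equal(sel$id, c("b", "a"))
  expect_error(rank_selection(ebv, 4), "exceeds")
  ties <- c(z = 1, y = 1, x = 1)
  expect_equal(rank_selection(ties, 3)$id, c("x", "y", "z"))
})

test_that("the family-effect variant fits and ranks dams", {
  sim <- make_small(seed = 114, n_dams = 15, fam = 4, grid = c(8, 8))
  fit <- fit_spatial_model(model_spec("ar1xar1", genetic = "family"),
                           sim$records, grid = sim$grid, seed = 115)
  expect_true(fit$converged)
  dams <- unique(na.omit(sim$records$dam))
  expect_true(all(dams %in% names(fit$blup)))
  # family variance is about a quarter of the additive variance: it should
  # come out well below the generating sigma2_A + residual scale
  expect_gte(fit$estimates$sigma2_A, 0)
  expect_lt(fit$estimates$sigma2_A, var(sim$records$dbh))
})

test_that("bundled fixtures read cleanly", {
  f <- system.file("extdata", "synthetic_orchard_genalex.csv",
                   package = "orchardgt")
  tab <- read_genotype_table(f, "genalex_csv")
  expect_equal(length(tab$ids), 25L)
  expect_equal(length(tab$loci), 7L)
  p <- read.csv(system.file("extdata", "larix_microsat_primers.csv",
                            package = "orchardgt"))
  expect_equal(nrow(p), 14L)
  expect_equal(length(unique(p$marker)), 7L)
})
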