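# Seeded simulation experiments used to validate parameter recovery.

#' Variance-component recovery experiment
#'
#' Repeatedly simulates a balanced maternal half-sib orchard (dams x
#' offspring per dam) with phenotypes generated from the additive-genetic +
#' separable AR1 x AR1 field + nugget model, refits the animal + AR1 x AR1
#' model by REML on each replicate, and collects the estimates.  Used to
#' check that the fitting machinery recovers the generating variance
#' components.
#'
#' @param n_rep number of replicates (default 50).
#' @param n_dams,family_size pedigree design (default 60 x 5 = 300 trees).
#' @param grid_dims grid for placement and the AR1 terms (default 30 x 30).
#' @param truth generating parameters, see [default_truth()].
#' @param seed root seed; every replicate derives its own seeds from it.
#' @param n_loci loci simulated for the genotype side (default 7).
#' @param quiet suppress per-replicate progress.
#' @return data.frame with one row per replicate: the REML estimates,
#'   their standard errors, log-likelihood and convergence flag; the
#'   generating truth is attached as attribute `truth`.
#' @export
recovery_experiment <- function(n_rep = 50L, n_dams = 60L, family_size = 5L,
                                grid_dims = c(30L, 30L),
                                truth = default_truth(), seed = 1L,
                                n_loci = 7L, quiet = TRUE) {
  seeds <- matrix(split_seed(seed, 4L * n_rep), ncol = 4L)
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    af <- simulate_allele_frequencies(n_loci = n_loci, seed = seeds[r, 1L])
    orch <- simulate_orchard(af, n_mothers = n_dams,
                             family_sizes = family_size,
                             seed = seeds[r, 2L])
    sim <- simulate_phenotypes(orch$pedigree, truth, grid_dims = grid_dims,
                               seed = seeds[r, 3L])
    fit <- fit_spatial_model(model_spec("ar1xar1"), sim$records, A = sim$A,
                             grid = sim$grid, seed = seeds[r, 4L])
    est <- fit$estimates
    rows[[r]] <- data.frame(
      rep = r,
      sigma2_A = est$sigma2_A, sigma2_xi = est$sigma2_xi,
      sigma2_eta = est$sigma2_eta,
      rho_row = est$rho_row, rho_col = est$rho_col,
      se_sigma2_A = unname(fit$se["sigma2_A"]),
      se_sigma2_xi = unname(fit$se["sigma2_xi"]),
      se_sigma2_eta = unname(fit$se["sigma2_eta"]),
      h2 = fit$h2, loglik = fit$loglik, converged = fit$converged)
    if (!quiet)
      message(sprintf("rep %d/%d: s2A %.2f s2xi %.2f s2eta %.2f",
                      r, n_rep, est$sigma2_A, est$sigma2_xi,
                      est$sigma2_eta))
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- truth
  out
}
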