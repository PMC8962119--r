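# REML fitting of the individual-tree (animal) mixed model with spatially
# correlated residuals:
#
#   y = Xb + Zu + xi + eta
#
# u  ~ N(0, sigma2_A * A)      additive genetic effects (pedigree)
# xi ~ N(0, sigma2_xi * R)     spatially structured residual
# eta~ N(0, sigma2_eta * I)    independent residual (nugget)
#
# Variance components are estimated by restricted maximum likelihood with
# the fixed effects profiled out; optimization runs in transformed space
# (log variances, scaled-logit correlations) from several seeded starts.
# Everything is dense: the target problems have a few hundred trees.

RHO_BOUND <- 0.999

# restricted log-likelihood of y ~ N(Xb, V), b profiled out.
# Includes all constants (Patterson-Thompson form with log|X'X|), so it
# matches the error-contrast definition exactly.
reml_ll_dense <- function(y, X, V) {
  n <- length(y)
  p <- qr(X)$rank
  L <- chol_jitter(V)
  Vinv_y <- backsolve(L, forwardsolve(t(L), y))
  Vinv_X <- backsolve(L, forwardsolve(t(L), X))
  XtViX <- crossprod(X, Vinv_X)
  XtViy <- crossprod(X, Vinv_y)
  bhat <- solve(XtViX, XtViy)
  r <- y - X %*% bhat
  Vinv_r <- backsolve(L, forwardsolve(t(L), r))
  quad <- sum(r * Vinv_r)
  logdetV <- 2 * sum(log(diag(L)))
  logdetXtViX <- determinant(XtViX, logarithm = TRUE)$modulus
  logdetXtX <- determinant(crossprod(X), logarithm = TRUE)$modulus
  as.numeric(-0.5 * ((n - p) * log(2 * pi) - logdetXtX +
                       logdetV + logdetXtViX + quad))
}

# number of free covariance parameters per structure kind
n_struct_pars <- function(kind) {
  switch(kind, none = 0L, ar1xar1 = 2L, ar1 = 1L, 1L)
}

# build the structured correlation matrix from free parameters
struct_R <- function(kind, pars, env) {
  switch(kind,
         none = NULL,
         ar1xar1 = env$rho_r_pow(pars[1L]) * env$rho_c_pow(pars[2L]),
         ar1 = env$pos_pow(pars[1L]),
         env$dist_R(pars[1L]))
}

#' Specify an animal / spatial mixed model
#'
#' @param structure a [spatial_structure()] (or its kind as a string) for
#'   the spatially dependent residual; `"none"` gives the plain animal
#'   model (no xi term).
#' @param genetic `"animal"` (individual effect with pedigree covariance)
#'   or `"family"` (i.i.d. dam effect; offspring with unknown dams get
#'   their own level).
#' @param response name of the phenotype column (default `"dbh"`).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(structure = "none", genetic = c("animal", "family"),
                       response = "dbh") {
  if (is.character(structure)) structure <- spatial_structure(structure)
  genetic <- match.arg(genetic)
  structure(list(structure = structure, genetic = genetic,
                 response = response), class = "model_spec")
}

# genetic covariance G = Z A Z' among phenotyped individuals, plus the
# full-to-observed map used for BLUP
genetic_cov <- function(spec, data, A) {
  if (spec$genetic == "animal") {
    if (is.null(A)) stop("animal model needs a relationship matrix A")
    miss <- setdiff(data$id, rownames(A))
    if (length(miss)) stop("phenotyped ids missing from A: ",
                           paste(utils::head(miss, 3), collapse = ","))
    G <- A[data$id, data$id, drop = FALSE]
    AZ <- A[, data$id, drop = FALSE]   # A %*% t(Z)
    list(G = G, AZ = AZ, u_ids = rownames(A))
  } else {
    dam <- data$dam
    dam[is.na(dam)] <- paste0(".self.", data$id[is.na(dam)])
    lev <- unique(dam)
    Z <- outer(dam, lev, "==") * 1
    list(G = tcrossprod(Z), AZ = t(Z), u_ids = lev)
  }
}

#' Restricted log-likelihood at given parameter values
#'
#' Evaluates the REML log-likelihood of the model defined by `spec` at the
#' supplied variance components and structure parameters.  Used directly by
#' the optimizer in [fit_spatial_model()]; exposed for diagnostics and for
#' oracle testing.
#'
#' @param params named list/vector: `sigma2_A`, `sigma2_eta`, and (when the
#'   spec has a spatial term) `sigma2_xi` plus `rho_row`/`rho_col`, `rho`,
#'   or `r`.
#' @param spec a [model_spec()].
#' @param data data.frame with `id`, the response column, `x`, `y`, and
#'   `dam` for the family model.
#' @param A relationship matrix over pedigree ids (animal model).
#' @param grid `grid_assignment` (ar1 kinds).
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(params, spec, data, A = NULL, grid = NULL) {
  params <- as.list(params)
  y <- data[[spec$response]]
  X <- matrix(1, length(y), 1L)
  gc <- genetic_cov(spec, data, A)
  kind <- spec$structure$kind
  V <- params$sigma2_A * gc$G + params$sigma2_eta * diag(length(y))
  if (kind != "none") {
    st <- spec$structure
    st$rho_row <- params$rho_row %||% st$rho_row
    st$rho_col <- params$rho_col %||% st$rho_col
    st$rho <- params$rho %||% st$rho
    st$r <- params$r %||% st$r
    R <- build_correlation_matrix(st, grid = grid, coords = data,
                                  ids = data$id)
    V <- V + params$sigma2_xi * R
  }
  reml_ll_dense(y, X, V)
}

#' Fit the spatial animal model by REML
#'
#' Maximizes the restricted likelihood over the variance components (log
#' scale) and structure parameters (correlations on a scaled logit in
#' (-0.999, 0.999); ranges on log scale), from `n_starts` seeded starting
#' points, keeping the best.  Standard errors come from the observed
#' information (numerical Hessian on the natural scale).  Breeding values
#' are the BLUPs `u_hat = sigma2_A * A Z' V^-1 (y - X b_hat)` for every
#' pedigree member, including non-phenotyped mothers.
#'
#' @param spec a [model_spec()].
#' @param data data.frame with `id`, the response, `x`, `y` (and `dam` for
#'   the family model).
#' @param A relationship matrix (animal model).
#' @param grid `grid_assignment` for ar1 kinds.
#' @param n_starts number of seeded multistarts (>= 3 recommended).
#' @param seed integer seed for the starts.
#' @param reltol convergence tolerance on the log-likelihood.
#' @return object of class `orchard_fit`: estimates, SEs, log-likelihood,
#'   `k`, AICc, heritability, breeding values, convergence info.
#' @export
fit_spatial_model <- function(spec, data, A = NULL, grid = NULL,
                              n_starts = 3L, seed = 1L, reltol = 1e-10) {
  y <- data[[spec$response]]
  n <- length(y)
  X <- matrix(1, n, 1L)
  gc <- genetic_cov(spec, data, A)
  kind <- spec$structure$kind
  ns <- n_struct_pars(kind)
  Ident <- diag(n)

  # precomputations for fast R(theta)
  env <- new.env(parent = emptyenv())
  if (kind == "ar1xar1") {
    g <- grid[match(data$id, grid$id), ]
    if (anyNA(g$row)) stop("grid assignment missing some phenotyped ids")
    Dr <- abs(outer(g$row, g$row, "-"))
    Dc <- abs(outer(g$col, g$col, "-"))
    env$rho_r_pow <- function(rho) rho^Dr
    env$rho_c_pow <- function(rho) rho^Dc
  } else if (kind == "ar1") {
    g <- grid[match(data$id, grid$id), ]
    pos <- g$row * attr(grid, "ncols") + g$col
    Dp <- abs(outer(pos, pos, "-"))
    env$pos_pow <- function(rho) rho^Dp
  } else if (kind != "none") {
    D <- as.matrix(stats::dist(cbind(data$x, data$y)))
    st0 <- spec$structure
    env$dist_R <- function(r) {
      st0$r <- r
      R <- correlation(st0, D)
      diag(R) <- 1
      R
    }
    env$dmax <- max(D)
  }

  has_xi <- kind != "none"
  # theta layout: log s2A, log s2eta, [log s2xi, struct pars (transformed)]
  to_nat <- function(theta) {
    out <- list(sigma2_A = exp(theta[1L]), sigma2_eta = exp(theta[2L]))
    if (has_xi) {
      out$sigma2_xi <- exp(theta[3L])
      sp <- theta[3L + seq_len(ns)]
      if (kind == "ar1xar1") {
        out$rho_row <- RHO_BOUND * tanh(sp[1L])
        out$rho_col <- RHO_BOUND * tanh(sp[2L])
      } else if (kind == "ar1") {
        out$rho <- RHO_BOUND * tanh(sp[1L])
      } else {
        out$r <- exp(sp[1L])
      }
    }
    out
  }
  Vof <- function(nat) {
    V <- nat$sigma2_A * gc$G + nat$sigma2_eta * Ident
    if (has_xi) {
      sp <- switch(kind,
                   ar1xar1 = c(nat$rho_row, nat$rho_col),
                   ar1 = nat$rho,
                   nat$r)
      V <- V + nat$sigma2_xi * struct_R(kind, sp, env)
    }
    V
  }
  negll <- function(theta) {
    nat <- to_nat(theta)
    V <- Vof(nat)
    ll <- tryCatch(reml_ll_dense(y, X, V), error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  vy <- stats::var(y)
  starts <- list()
  base_props <- list(c(1, 1, 1) / 3, c(0.6, 0.2, 0.2), c(0.1, 0.6, 0.3))
  base_rho <- c(0.5, 0.8, 0.2)
  child <- split_seed(seed, n_starts)
  for (s in seq_len(n_starts)) {
    pr <- base_props[[(s - 1L) %% 3L + 1L]]
    jit <- with_seed(child[s], stats::runif(3 + ns, 0.9, 1.1))
    th <- c(log(vy * pr[1] * jit[1]), log(vy * pr[3] * jit[2]))
    if (has_xi) {
      th <- c(th, log(vy * pr[2] * jit[3]))
      rr <- base_rho[(s - 1L) %% 3L + 1L]
      th <- c(th, switch(kind,
                         ar1xar1 = rep(atanh(rr / RHO_BOUND), 2L),
                         ar1 = atanh(rr / RHO_BOUND),
                         log(env$dmax * rr / 2)) * jit[3 + seq_len(ns)])
    } else {
      th <- c(log(vy * (pr[1] + pr[2]) * jit[1]), log(vy * pr[3] * jit[2]))
    }
    starts[[s]] <- th
  }

  best <- NULL
  opt_log <- list()
  for (s in seq_along(starts)) {
    o <- stats::optim(starts[[s]], negll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = reltol))
    opt_log[[s]] <- c(value = o$value, convergence = o$convergence)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$value >= 1e10)
    stop("all optimizer starts failed; trace: ",
         paste(vapply(opt_log, function(z) format(z[["value"]]),
                      character(1)), collapse = ", "))
  nat <- to_nat(best$par)
  ll <- -best$value

  # parameter count for AICc: fixed effects + variances + structure pars
  k <- 1L + 2L + (if (has_xi) 1L + ns else 0L)
  aicc_val <- aicc(ll, k, n)

  # SEs: numerical observed information on the natural scale
  nat_vec <- unlist(nat)
  ll_nat <- function(v) {
    natl <- as.list(v)
    names(natl) <- names(nat_vec)
    V <- tryCatch(Vof(natl), error = function(e) NULL)
    if (is.null(V)) return(NA_real_)
    tryCatch(reml_ll_dense(y, X, V), error = function(e) NA_real_)
  }
  H <- num_hessian(ll_nat, nat_vec)
  se <- rep(NA_real_, length(nat_vec))
  names(se) <- names(nat_vec)
  ih <- tryCatch(solve(-H), error = function(e) NULL)
  if (!is.null(ih)) {
    dg <- diag(ih)
    se[dg > 0] <- sqrt(dg[dg > 0])
  }

  # GLS fixed effects and BLUP breeding values on the full pedigree
  V <- Vof(nat)
  L <- chol_jitter(V)
  Vi_y <- backsolve(L, forwardsolve(t(L), y))
  Vi_X <- backsolve(L, forwardsolve(t(L), X))
  bhat <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
  r <- y - X %*% bhat
  Vi_r <- backsolve(L, forwardsolve(t(L), r))
  u <- as.numeric(nat$sigma2_A * (gc$AZ %*% Vi_r))
  names(u) <- gc$u_ids

  h2 <- heritability_components(nat$sigma2_A,
                                if (has_xi) nat$sigma2_xi else 0,
                                nat$sigma2_eta)
  structure(list(spec = spec, estimates = nat, se = se,
                 intercept = as.numeric(bhat), loglik = ll, k = k, n = n,
                 aicc = aicc_val, h2 = h2, blup = u,
                 converged = best$convergence == 0,
                 opt = list(par = best$par, starts = length(starts),
                            trace = opt_log),
                 data_ids = data$id),
            class = "orchard_fit")
}

#' @export
print.orchard_fit <- function(x, ...) {
  cat("animal model fit:", x$spec$genetic, "+",
      x$spec$structure$kind, "\n")
  est <- unlist(x$estimates)
  for (nm in names(est))
    cat(sprintf("  %-10s %10.4f  (SE %s)\n", nm, est[[nm]],
                ifelse(is.na(x$se[nm]), "NA", sprintf("%.4f", x$se[nm]))))
  cat(sprintf("  logLik %.3f  k %d  AICc %.2f  h2 %.3f  %s\n",
              x$loglik, x$k, x$aicc, x$h2,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

# central-difference Hessian
num_hessian <- function(f, x, rel_h = 1e-4) {
  p <- length(x)
  h <- pmax(abs(x), 1e-3) * rel_h
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xm <- x
        xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpm <- x; xmp <- x; xmm <- x
        xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Second-order Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik maximized (restricted) log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

heritability_components <- function(sigma2_A, sigma2_xi, sigma2_eta) {
  tot <- sigma2_A + sigma2_xi + sigma2_eta
  if (tot <= 0) stop("all variance components are zero")
  sigma2_A / tot
}

#' Narrow-sense heritability from a fit
#'
#' `h2 = sigma2_A / (sigma2_A + sigma2_xi + sigma2_eta)`: the spatially
#' structured residual variance counts in the phenotypic denominator.
#'
#' @param x an `orchard_fit`, or a named vector/list of variance
#'   components (`sigma2_A`, optionally `sigma2_xi`, `sigma2_eta`).
#' @export
heritability <- function(x) {
  if (inherits(x, "orchard_fit")) {
    if (!x$converged) warning("fit did not converge; h2 may be unreliable")
    return(x$h2)
  }
  x <- as.list(x)
  heritability_components(x$sigma2_A, x$sigma2_xi %||% 0, x$sigma2_eta)
}

#' BLUP breeding values from a converged fit
#'
#' `u_hat = sigma2_A A Z' V^-1 (y - X b_hat)`, reported for every pedigree
#' member; non-phenotyped mothers get predictions through the relationship
#' matrix.  The values are stored on the fit; this accessor returns them as
#' a ranked data.frame.
#'
#' @param fit an `orchard_fit`.
#' @param ids optional subset of ids.
#' @return data.frame id, ebv, rank (descending ebv, ties by id).
#' @export
blup <- function(fit, ids = NULL) {
  u <- fit$blup
  if (!is.null(ids)) u <- u[ids]
  ord <- order(-u, names(u))
  data.frame(id = names(u)[ord], ebv = unname(u[ord]),
             rank = seq_along(u))
}

#' Rank individuals for selection on breeding value
#'
#' @param ebv named numeric vector of breeding values.
#' @param top_n how many to select.
#' @param mode `"forward"` (offspring) or `"backward"` (mothers) — label
#'   only; ranking is identical.
#' @return data.frame id, ebv, rank for the selected individuals
#'   (descending ebv, ties broken by id).
#' @export
rank_selection <- function(ebv, top_n, mode = c("forward", "backward")) {
  mode <- match.arg(mode)
  if (top_n > length(ebv)) stop("top_n exceeds population size")
  ord <- order(-ebv, names(ebv))
  sel <- ord[seq_len(top_n)]
  data.frame(id = names(ebv)[sel], ebv = unname(ebv[sel]),
             rank = seq_len(top_n), mode = mode)
}

#' Fit and rank candidate residual structures by AICc
#'
#' Fits the plain animal model and the animal model plus each requested
#' spatial structure, returning a ranking by AICc (ascending).  Failed fits
#' are kept as rows flagged `failed`.
#'
#' @param data phenotype data.frame (`id`, response, `x`, `y`).
#' @param A relationship matrix.
#' @param grid `grid_assignment` (needed for ar1 kinds).
#' @param structures character vector of structure kinds to try.
#' @param genetic `"animal"` or `"family"`.
#' @param response response column name.
#' @param n_starts,seed passed to [fit_spatial_model()].
#' @return data.frame of class `model_comparison` with columns model,
#'   intercept, k, loglik, aicc, h2, converged, rank; attribute `fits`
#'   holds the fit objects.
#' @export
compare_models <- function(data, A, grid = NULL,
                           structures = c("none", "exponential", "gaussian",
                                          "spherical", "linear", "rational",
                                          "ar1", "ar1xar1"),
                           genetic = "animal", response = "dbh",
                           n_starts = 3L, seed = 1L) {
  fits <- list()
  rows <- list()
  for (kind in structures) {
    spec <- model_spec(kind, genetic = genetic, response = response)
    f <- tryCatch(fit_spatial_model(spec, data, A = A, grid = grid,
                                    n_starts = n_starts, seed = seed),
                  error = function(e) e)
    nm <- if (kind == "none") "animal" else paste0("animal+", kind)
    fits[[nm]] <- f
    if (inherits(f, "error")) {
      rows[[nm]] <- data.frame(model = nm, intercept = NA_real_,
                               k = NA_integer_, loglik = NA_real_,
                               aicc = NA_real_, h2 = NA_real_,
                               converged = FALSE, failed = TRUE)
    } else {
      rows[[nm]] <- data.frame(model = nm, intercept = f$intercept,
                               k = f$k, loglik = f$loglik, aicc = f$aicc,
                               h2 = f$h2, converged = f$converged,
                               failed = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$failed, out$aicc), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("model_comparison", "data.frame")
  out
}
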