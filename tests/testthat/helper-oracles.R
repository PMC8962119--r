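# Independent oracle implementations used to cross-check the package.
# These deliberately take different computational routes from the code
# under test (error contrasts instead of profiled GLS, mixed-model
# equations instead of the covariance form, enumeration / gene dropping
# instead of closed forms).

# REML log-likelihood via orthonormal error contrasts K (K'X = 0, K'K = I)
oracle_reml_contrasts <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  K <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  M <- crossprod(K, V %*% K)
  ky <- crossprod(K, y)
  -0.5 * ((n - p) * log(2 * pi) +
            determinant(M, logarithm = TRUE)$modulus +
            sum(ky * solve(M, ky)))
}

# BLUP via Henderson's mixed-model equations.  R_full is the full residual
# covariance (spatial + nugget); G_full = sigma2_A * A over all pedigree
# members; Z maps observations to pedigree members.
oracle_blup_mme <- function(y, X, Z, A, sigma2_A, R_full) {
  Ri <- solve(R_full)
  Gi <- solve(sigma2_A * A)
  lhs <- rbind(cbind(crossprod(X, Ri %*% X), crossprod(X, Ri %*% Z)),
               cbind(crossprod(Z, Ri %*% X), crossprod(Z, Ri %*% Z) + Gi))
  rhs <- rbind(crossprod(X, Ri %*% y), crossprod(Z, Ri %*% y))
  sol <- solve(lhs, rhs)
  list(b = sol[seq_len(ncol(X)), , drop = TRUE],
       u = sol[-seq_len(ncol(X)), , drop = TRUE])
}

# Additive relationship by gene dropping: founders get unique allele
# labels, each descendant inherits one random allele per parent (unknown
# parent -> fresh founder alleles).  A_ij is estimated as twice the
# kinship: the average probability that random alleles from i and j are
# identical by descent, plus the self term on the diagonal.
oracle_gene_drop <- function(ped, n_rep = 1e5, seed = 1) {
  set.seed(seed)
  ids <- ped$id
  n <- length(ids)
  di <- match(ped$dam, ids)
  si <- match(ped$sire, ids)
  # allele label matrices: n_rep x n
  al1 <- matrix(0L, n_rep, n)
  al2 <- matrix(0L, n_rep, n)
  counter <- 0L
  fresh <- function() {
    counter <<- counter + 1L
    rep(counter, n_rep) * 0L + seq_len(n_rep) + (counter - 1L) * n_rep
  }
  # pedigree must be ordered parents-first for this loop
  for (i in seq_len(n)) {
    if (is.na(di[i])) {
      al1[, i] <- fresh()
    } else {
      pick <- stats::runif(n_rep) < 0.5
      al1[, i] <- ifelse(pick, al1[, di[i]], al2[, di[i]])
    }
    if (is.na(si[i])) {
      al2[, i] <- fresh()
    } else {
      pick <- stats::runif(n_rep) < 0.5
      al2[, i] <- ifelse(pick, al1[, si[i]], al2[, si[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
        (al2[, i] == al1[, j]) + (al2[, i] == al2[, j])
      if (i == j) {
        # 2 * kinship(i,i) = 1 + P(two alleles of i IBD)
        A[i, i] <- 1 + mean(al1[, i] == al2[, i])
      } else {
        A[i, j] <- A[j, i] <- mean(ibd) / 2
      }
    }
  }
  A
}

# all unordered genotypes at a locus with allele codes `codes`
all_genotypes <- function(codes) {
  g <- expand.grid(a = codes, b = codes)
  g <- g[g$a <= g$b, ]
  as.matrix(g)
}

hwe_g <- function(g, p) {
  pa <- p[as.character(g[1])] * p[as.character(g[2])]
  unname(if (g[1] == g[2]) pa else 2 * pa)
}

# exhaustive-sum oracle for the error-model transition probability:
# P(obs_o | obs_m) = sum over true genotype pairs of
#   P(tm | obs_m) P(obs_o | to) T(to | tm)
oracle_transition <- function(obs_o, obs_m, p, e) {
  codes <- as.integer(names(p))
  G <- all_genotypes(codes)
  p_obs_given_true <- function(obs, true) {
    (1 - e) * (obs[1] == true[1] && obs[2] == true[2]) + e * hwe_g(obs, p)
  }
  trans <- function(off, dam) {
    m1 <- 0.5 * (dam[1] == off[1]) + 0.5 * (dam[2] == off[1])
    if (off[1] == off[2]) return(m1 * unname(p[as.character(off[1])]))
    m2 <- 0.5 * (dam[1] == off[2]) + 0.5 * (dam[2] == off[2])
    m1 * unname(p[as.character(off[2])]) +
      m2 * unname(p[as.character(off[1])])
  }
  num <- 0; den <- 0
  for (i in seq_len(nrow(G))) {
    tm <- G[i, ]
    w <- p_obs_given_true(obs_m, tm) * hwe_g(tm, p)
    den <- den + w
    inner <- 0
    for (j in seq_len(nrow(G))) {
      to <- G[j, ]
      inner <- inner + trans(to, tm) * p_obs_given_true(obs_o, to)
    }
    num <- num + w * inner
  }
  unname(num / den)
}

# enumeration oracle for single-locus first-parent non-exclusion: the
# probability, over an HWE offspring and an independent HWE candidate,
# that the candidate carries a transmissible allele of the offspring
oracle_ne1p_enum <- function(p) {
  codes <- as.integer(names(p))
  G <- all_genotypes(codes)
  tot <- 0
  for (i in seq_len(nrow(G))) {
    off <- G[i, ]
    for (j in seq_len(nrow(G))) {
      cand <- G[j, ]
      compatible <- any(cand %in% off)
      if (compatible) tot <- tot + hwe_g(off, p) * hwe_g(cand, p)
    }
  }
  tot
}

# small synthetic fixture: 3 groups, deterministic genotypes
tiny_table <- function() {
  a1 <- rbind(m1 = c(101L, 101L), m2 = c(101L, 102L), o1 = c(101L, 0L))
  a2 <- rbind(m1 = c(101L, 102L), m2 = c(102L, 102L), o2 = c(102L, 0L))
  rownames(a2) <- rownames(a1)
  colnames(a1) <- colnames(a2) <- c("LA", "LB")
  genotype_table(a1, a2, c(m1 = "PT", m2 = "PT", o1 = "HC"))
}
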