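# Likelihood-based maternity assignment with a genotyping-error model and
# simulated Delta confidence thresholds.
#
# Error model: with probability e the recorded genotype of an individual at
# a locus is replaced by a random Hardy-Weinberg genotype; with probability
# 1-e it is the true genotype.  Marginalizing the per-locus maternity
# likelihood ratio over true genotypes collapses to a closed form:
#
#   P(obs offspring | obs dam)   = (1-e)^2 T(o|m) + e(2-e) H(o)
#   P(obs offspring | unrelated) = H(o)
#
# where T(o|m) is the Mendelian transmission probability (maternal allele
# from m, paternal allele from the population) and H(o) the HWE genotype
# frequency of the observed offspring genotype.  The closed form is checked
# against an exhaustive sum over true genotype pairs in the test-suite.

#' Parentage analysis configuration
#'
#' @param error_rate probability that a recorded genotype is a random HWE
#'   genotype rather than the true one (default 0.01).
#' @param n_sim number of simulated offspring used to calibrate the Delta
#'   confidence thresholds (default 10000).
#' @param confidence_levels named vector `c(strict = 0.95, relaxed = 0.80)`.
#' @param prop_candidates_sampled fraction of true mothers present in the
#'   candidate list (default 1: a closed, fully genotyped orchard).
#' @param prop_loci_typed fraction of loci typed per individual in the
#'   simulation; `NA` means estimate it from the data.
#' @param seed integer seed for threshold simulation.
#' @return list of class `parentage_config`.
#' @export
parentage_config <- function(error_rate = 0.01, n_sim = 10000,
                             confidence_levels = c(strict = 0.95,
                                                   relaxed = 0.80),
                             prop_candidates_sampled = 1.0,
                             prop_loci_typed = NA_real_,
                             seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 0.5,
            all(confidence_levels > 0), all(confidence_levels < 1),
            confidence_levels[["strict"]] > confidence_levels[["relaxed"]],
            prop_candidates_sampled > 0, prop_candidates_sampled <= 1)
  structure(list(error_rate = error_rate, n_sim = as.integer(n_sim),
                 confidence_levels = confidence_levels,
                 prop_candidates_sampled = prop_candidates_sampled,
                 prop_loci_typed = prop_loci_typed,
                 seed = as.integer(seed)),
            class = "parentage_config")
}

# HWE genotype frequency of an observed unordered call (c(a, b))
hwe_prob <- function(call, p) {
  pa <- p[[as.character(call[1L])]]
  pb <- p[[as.character(call[2L])]]
  if (is.null(pa) || is.null(pb))
    stop("allele absent from frequency table: ",
         call[1L], "/", call[2L])
  if (call[1L] == call[2L]) pa * pa else 2 * pa * pb
}

# Mendelian transmission probability T(offspring call | dam call), paternal
# allele drawn from population frequencies p
mendel_trans <- function(off, dam, p) {
  m1 <- 0.5 * (dam[1L] == off[1L]) + 0.5 * (dam[2L] == off[1L])
  if (off[1L] == off[2L]) return(m1 * p[[as.character(off[1L])]])
  m2 <- 0.5 * (dam[1L] == off[2L]) + 0.5 * (dam[2L] == off[2L])
  m1 * p[[as.character(off[2L])]] + m2 * p[[as.character(off[1L])]]
}

#' Maternity transition probability under the genotyping-error model
#'
#' Probability of the observed offspring genotype given the observed
#' genotype of a candidate dam, marginalized over true genotypes under the
#' replacement error model, with the paternal allele drawn from the
#' population allele frequencies.
#'
#' @param offspring_call,parent_call length-2 integer vectors of allele
#'   codes (non-missing).
#' @param p named numeric vector of allele frequencies at the locus.
#' @param error_rate per-genotype mistyping probability.
#' @export
transition_probability <- function(offspring_call, parent_call, p,
                                   error_rate = 0) {
  if (any(offspring_call <= 0L) || any(parent_call <= 0L))
    stop("calls must be non-missing")
  if (!all(as.character(offspring_call) %in% names(p)))
    stop("allele absent from frequency table: ",
         paste(offspring_call, collapse = "/"))
  tr <- mendel_trans(offspring_call, parent_call, p)
  h <- hwe_prob(offspring_call, p)
  (1 - error_rate)^2 * tr + error_rate * (2 - error_rate) * h
}

#' LOD score for one offspring-candidate pair
#'
#' Sum over shared typed loci of
#' `ln P(offspring | candidate is dam) / P(offspring | unrelated)`.
#' With `error_rate = 0`, a Mendelian-incompatible locus yields `-Inf`
#' (exclusion); incompatible loci are also counted as mismatches.
#'
#' @param offspring_id,candidate_id individual ids in `tab`.
#' @param tab a [genotype_table()].
#' @param af `allele_freqs` for the reference population.
#' @param error_rate per-genotype mistyping probability.
#' @return list with `lod` (total), `n_mismatch`, `n_loci` (shared typed
#'   loci), `per_locus` (named vector).
#' @export
lod_score <- function(offspring_id, candidate_id, tab, af, error_rate = 0) {
  io <- match(offspring_id, tab$ids)
  ic <- match(candidate_id, tab$ids)
  if (is.na(io) || is.na(ic)) stop("unknown individual id")
  per <- numeric(0)
  mism <- 0L
  for (l in tab$loci) {
    off <- c(tab$a1[io, l], tab$a2[io, l])
    dam <- c(tab$a1[ic, l], tab$a2[ic, l])
    if (off[1L] == 0L || dam[1L] == 0L) next
    p <- af$freqs[[l]]
    tr <- mendel_trans(off, dam, p)
    if (tr == 0) mism <- mism + 1L
    num <- (1 - error_rate)^2 * tr +
      error_rate * (2 - error_rate) * hwe_prob(off, p)
    per[l] <- if (num == 0) -Inf else log(num / hwe_prob(off, p))
  }
  if (length(per) == 0L)
    stop("no shared typed loci between ", offspring_id, " and ", candidate_id)
  list(lod = sum(per), n_mismatch = mism, n_loci = length(per),
       per_locus = per)
}

#' Delta statistic from a vector of candidate LOD scores
#'
#' Difference between the best and second-best LOD when at least two
#' candidates have positive LOD; the best LOD itself when it is the only
#' positive one; 0 when no candidate has positive LOD.
#'
#' @param lods numeric vector of LOD scores (any order).
#' @export
delta_statistic <- function(lods) {
  if (length(lods) == 0L) stop("need at least one LOD")
  s <- sort(lods, decreasing = TRUE)
  if (s[1L] <= 0) return(0)
  pos <- sum(s > 0)
  if (pos == 1L) s[1L] else s[1L] - s[2L]
}

# --- vectorized LOD machinery -------------------------------------------
# For one locus, LOD contributions of every candidate (rows) against every
# offspring (cols).  ca1/ca2: candidate alleles; oa1/oa2: offspring alleles
# (0 = missing).  Returns list(lod, mismatch) matrices; missing cells are 0
# lod / 0 mismatch (locus skipped).
locus_lod_matrix <- function(ca1, ca2, oa1, oa2, p, error_rate) {
  idx <- function(a) {
    out <- rep(NA_real_, length(a))
    typed <- a > 0L
    out[typed] <- p[as.character(a[typed])]
    out
  }
  po1 <- idx(oa1); po2 <- idx(oa2)
  homo <- oa1 == oa2
  hwe <- ifelse(homo, po1 * po1, 2 * po1 * po2)
  # match indicators: candidate allele == offspring allele k
  m1 <- 0.5 * (outer(ca1, oa1, "==") + outer(ca2, oa1, "=="))
  tr <- matrix(0, length(ca1), length(oa1))
  hN <- matrix(rep(homo, each = length(ca1)), nrow = length(ca1))
  p1N <- matrix(rep(po1, each = length(ca1)), nrow = length(ca1))
  p2N <- matrix(rep(po2, each = length(ca1)), nrow = length(ca1))
  m2 <- 0.5 * (outer(ca1, oa2, "==") + outer(ca2, oa2, "=="))
  tr <- ifelse(hN, m1 * p1N, m1 * p2N + m2 * p1N)
  hweN <- matrix(rep(hwe, each = length(ca1)), nrow = length(ca1))
  num <- (1 - error_rate)^2 * tr + error_rate * (2 - error_rate) * hweN
  lod <- ifelse(num == 0, -Inf, log(num / hweN))
  mism <- (tr == 0) * 1L
  # missing in candidate or offspring: zero contribution
  cmiss <- ca1 == 0L
  omiss <- oa1 == 0L
  lod[cmiss, ] <- 0
  mism[cmiss, ] <- 0L
  lod[, omiss] <- 0
  mism[, omiss] <- 0L
  list(lod = lod, mismatch = mism,
       shared = outer(!cmiss, !omiss, "&") * 1L)
}

# total LOD / mismatch / shared-locus-count matrices (candidates x offspring)
lod_matrices <- function(tab, candidate_ids, offspring_ids, af, error_rate) {
  ic <- match(candidate_ids, tab$ids)
  io <- match(offspring_ids, tab$ids)
  if (anyNA(ic) || anyNA(io)) stop("unknown individual id")
  lod <- matrix(0, length(ic), length(io),
                dimnames = list(candidate_ids, offspring_ids))
  mism <- lod
  shared <- lod
  for (l in tab$loci) {
    res <- locus_lod_matrix(tab$a1[ic, l], tab$a2[ic, l],
                            tab$a1[io, l], tab$a2[io, l],
                            af$freqs[[l]], error_rate)
    lod <- lod + res$lod
    mism <- mism + res$mismatch
    shared <- shared + res$shared
  }
  list(lod = lod, mismatch = mism, shared = shared)
}

#' Simulate critical Delta thresholds
#'
#' Calibrates the Delta statistic by Monte-Carlo simulation: offspring are
#' generated from random HWE mothers with pollen from the population,
#' genotyping errors are injected at `config$error_rate`, loci are masked
#' at `config$prop_loci_typed`, and the true mother is present among the
#' candidates with probability `config$prop_candidates_sampled`.  For each
#' confidence level c the critical value is the smallest simulated Delta
#' such that the proportion of correct assignments among simulated trials
#' with Delta at or above it is at least c.
#'
#' @param af `allele_freqs` of the reference population.
#' @param n_candidates number of candidate mothers offered per offspring.
#' @param config a [parentage_config()].
#' @return object of class `delta_thresholds`: list with `critical` (named
#'   numeric per confidence level), `deltas`, `correct` (the simulated
#'   draws, retained for audit) and `success_rate`.
#' @export
simulate_critical_delta <- function(af, n_candidates, config) {
  stopifnot(n_candidates >= 1)
  if (config$n_sim < 100) stop("n_sim < 100 gives unstable thresholds")
  plt <- config$prop_loci_typed
  if (is.na(plt)) plt <- 1.0
  e <- config$error_rate
  loci <- names(af$freqs)
  sim <- with_seed(config$seed, {
    n <- config$n_sim
    deltas <- numeric(n)
    correct <- logical(n)
    chunk <- max(1L, min(n, as.integer(2e6 / n_candidates)))
    done <- 0L
    while (done < n) {
      m <- min(chunk, n - done)
      present <- stats::runif(m) <= config$prop_candidates_sampled
      lod <- matrix(0, n_candidates, m)
      for (j in seq_along(loci)) {
        p <- af$freqs[[loci[j]]]
        codes <- as.integer(names(p))
        draw <- function(k) codes[sample.int(length(p), k, replace = TRUE,
                                             prob = p)]
        # candidates (rows) per simulated offspring (cols)
        g1 <- matrix(draw(n_candidates * m), n_candidates, m)
        g2 <- matrix(draw(n_candidates * m), n_candidates, m)
        # true dam: candidate 1 when present, else an off-list dam
        d1 <- ifelse(present, g1[1L, ], draw(m))
        d2 <- ifelse(present, g2[1L, ], draw(m))
        mat <- ifelse(stats::runif(m) < 0.5, d1, d2)
        pat <- draw(m)
        o1 <- pmin(mat, pat); o2 <- pmax(mat, pat)
        if (e > 0) {
          # offspring mistyping: replace with a random HWE genotype
          repl <- stats::runif(m) < e
          if (any(repl)) {
            r1 <- draw(sum(repl)); r2 <- draw(sum(repl))
            o1[repl] <- pmin(r1, r2); o2[repl] <- pmax(r1, r2)
          }
          # candidate mistyping
          replc <- matrix(stats::runif(n_candidates * m) < e,
                          n_candidates, m)
          if (any(replc)) {
            k <- sum(replc)
            r1 <- draw(k); r2 <- draw(k)
            g1[replc] <- pmin(r1, r2); g2[replc] <- pmax(r1, r2)
          }
        }
        typed <- if (plt < 1) stats::runif(m) <= plt else rep(TRUE, m)
        # vectorized per-locus LOD, candidates x sims with recycling by row
        O1 <- matrix(o1, n_candidates, m, byrow = TRUE)
        O2 <- matrix(o2, n_candidates, m, byrow = TRUE)
        m1 <- 0.5 * ((g1 == O1) + (g2 == O1))
        m2 <- 0.5 * ((g1 == O2) + (g2 == O2))
        po1 <- p[as.character(o1)]; po2 <- p[as.character(o2)]
        homo <- o1 == o2
        hwe <- ifelse(homo, po1 * po1, 2 * po1 * po2)
        trw <- sweep(m1, 2L, ifelse(homo, po1, po2), "*") +
          sweep(ifelse(matrix(homo, n_candidates, m, byrow = TRUE), 0, m2),
                2L, po1, "*")
        num <- (1 - e)^2 * trw +
          e * (2 - e) * matrix(hwe, n_candidates, m, byrow = TRUE)
        ll <- log(sweep(num, 2L, hwe, "/"))
        ll[, !typed] <- 0
        lod <- lod + ll
      }
      for (s in seq_len(m)) {
        deltas[done + s] <- delta_statistic(lod[, s])
        correct[done + s] <- present[s] && which.max(lod[, s]) == 1L
      }
      done <- done + m
    }
    list(deltas = deltas, correct = correct)
  })
  ord <- order(sim$deltas, decreasing = TRUE)
  d_sorted <- sim$deltas[ord]
  c_sorted <- sim$correct[ord]
  rate <- cumsum(c_sorted) / seq_along(c_sorted)
  # smallest threshold: the largest index whose top-set still meets cl.
  # The top-sets nest across levels, so strict >= relaxed automatically.
  critical <- vapply(config$confidence_levels, function(cl) {
    ok <- which(rate >= cl)
    if (length(ok) == 0L) Inf else d_sorted[max(ok)]
  }, numeric(1))
  structure(list(critical = critical,
                 deltas = sim$deltas, correct = sim$correct,
                 success_rate = mean(sim$correct),
                 config = config, n_candidates = n_candidates),
            class = "delta_thresholds")
}

#' @export
print.delta_thresholds <- function(x, ...) {
  cat("simulated Delta thresholds (", length(x$deltas), " offspring, ",
      x$n_candidates, " candidates):\n", sep = "")
  for (nm in names(x$critical))
    cat(sprintf("  %s (%.0f%%): Delta* = %.4f\n", nm,
                100 * x$config$confidence_levels[[nm]], x$critical[[nm]]))
  cat(sprintf("  overall simulated success rate: %.3f\n", x$success_rate))
  invisible(x)
}

#' Assign offspring to candidate mothers
#'
#' Computes the LOD of every candidate for every offspring, assigns each
#' offspring its maximum-LOD candidate (ties broken by lexicographic
#' candidate id, flagged in the result), computes the Delta statistic and
#' grades it against simulated thresholds into strict / relaxed / low
#' confidence tiers.
#'
#' @param tab a [genotype_table()] containing both groups.
#' @param offspring_group,candidate_group group labels.
#' @param config a [parentage_config()].
#' @param thresholds optional precomputed [simulate_critical_delta()]
#'   result; computed from `config` when `NULL`.
#' @param af optional `allele_freqs`; defaults to frequencies over the
#'   whole table.
#' @return list of class `parentage_result` with `results` (data.frame:
#'   offspring, candidate, lod, delta, mismatches, shared_loci, tier, tie),
#'   `pedigree` (data.frame id, dam, sire; dam `NA` below relaxed
#'   confidence), `thresholds`.
#' @export
assign_maternity <- function(tab, offspring_group, candidate_group,
                             config = parentage_config(),
                             thresholds = NULL, af = NULL) {
  off_ids <- tab$ids[tab$groups %in% offspring_group]
  cand_ids <- tab$ids[tab$groups %in% candidate_group]
  if (length(off_ids) == 0L || length(cand_ids) == 0L)
    stop("offspring and candidate groups must be nonempty")
  af <- af %||% allele_frequencies(tab)
  if (is.null(thresholds)) {
    cfg <- config
    if (is.na(cfg$prop_loci_typed))
      cfg$prop_loci_typed <- mean(tab$a1[match(off_ids, tab$ids), ,
                                         drop = FALSE] > 0L)
    thresholds <- simulate_critical_delta(af, length(cand_ids), cfg)
  }
  mats <- lod_matrices(tab, cand_ids, off_ids, af, config$error_rate)
  ord_cand <- order(cand_ids)  # lexicographic tie-break
  res <- lapply(seq_along(off_ids), function(k) {
    shared <- mats$shared[, k]
    if (all(shared == 0))
      return(data.frame(offspring = off_ids[k], candidate = NA_character_,
                        lod = NA_real_, delta = NA_real_,
                        mismatches = NA_integer_, shared_loci = 0L,
                        tier = "unassigned", tie = FALSE,
                        reason = "no typed loci"))
    lods <- mats$lod[, k]
    mx <- max(lods)
    best_set <- which(lods == mx)
    best <- best_set[order(cand_ids[best_set])][1L]
    d <- delta_statistic(lods)
    tier <- if (d >= thresholds$critical[["strict"]]) "strict"
    else if (d >= thresholds$critical[["relaxed"]]) "relaxed"
    else "low"
    data.frame(offspring = off_ids[k], candidate = cand_ids[best],
               lod = mx, delta = d,
               mismatches = as.integer(mats$mismatch[best, k]),
               shared_loci = as.integer(max(shared)),
               tier = tier, tie = length(best_set) > 1L,
               reason = "")
  })
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  assigned <- !is.na(results$candidate) & results$tier %in%
    c("strict", "relaxed")
  ped <- data.frame(id = results$offspring,
                    dam = ifelse(assigned, results$candidate, NA_character_),
                    sire = NA_character_)
  structure(list(results = results, pedigree = ped,
                 thresholds = thresholds,
                 offspring_group = paste(offspring_group, collapse = "+"),
                 candidate_group = paste(candidate_group, collapse = "+")),
            class = "parentage_result")
}

#' @export
print.parentage_result <- function(x, ...) {
  cat("maternity assignment:", nrow(x$results), "offspring (",
      x$offspring_group, ") vs candidates (", x$candidate_group, ")\n")
  print(tier_summary(x))
  invisible(x)
}

#' Tier summary of a parentage result
#'
#' Counts and percentages of offspring per confidence tier, in the shape of
#' a maternity-analysis confidence table.
#'
#' @param x a `parentage_result` (or its `results` data.frame).
#' @return data.frame with columns tier, n, percent.
#' @export
tier_summary <- function(x) {
  res <- if (inherits(x, "parentage_result")) x$results else x
  lv <- c("strict", "relaxed", "low", "unassigned")
  n <- vapply(lv, function(t) sum(res$tier == t), integer(1))
  keep <- n > 0 | lv %in% c("strict", "relaxed", "low")
  out <- data.frame(tier = lv[keep], n = n[keep],
                    percent = round(100 * n[keep] / nrow(res)))
  rbind(out, data.frame(tier = "total", n = nrow(res), percent = 100L))
}

#' Assignment rate as a printed percentage
#'
#' Share of offspring assigned (at or above a tier), rounded to whole
#' percent as reported in confidence tables.
#'
#' @param n_assigned,n_total counts.
#' @export
assignment_rate <- function(n_assigned, n_total) {
  stopifnot(n_total > 0, n_assigned >= 0, n_assigned <= n_total)
  round(100 * n_assigned / n_total)
}

#' Write / read a pedigree CSV (id,dam,sire; literal NA for unknown)
#' @param ped data.frame with id, dam, sire.
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(ped[, c("id", "dam", "sire")], path, row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", na.strings = "NA")
}
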