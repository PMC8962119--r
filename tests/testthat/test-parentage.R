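# maternity likelihoods, Delta statistic, simulated confidence, assignment

test_that("transition probability matches the exhaustive error-model sum", {
  set.seed(51)
  for (rep in 1:6) {
    k <- sample(3:5, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    names(p) <- 100 + seq_len(k)
    codes <- as.integer(names(p))
    e <- sample(c(0, 0.01, 0.1), 1)
    off <- sort(sample(codes, 2, replace = TRUE))
    dam <- sort(sample(codes, 2, replace = TRUE))
    expect_equal(transition_probability(off, dam, p, e),
                 oracle_transition(off, dam, p, e), tolerance = 1e-12)
  }
  # Mendelian limits at e = 0
  p <- c("1" = 0.6, "2" = 0.4)
  expect_equal(transition_probability(c(1, 2), c(1, 1), p, 0), 0.4)
  expect_equal(transition_probability(c(2, 2), c(1, 1), p, 0), 0)
  expect_error(transition_probability(c(1, 3), c(1, 1), p, 0), "absent")
})

test_that("lod_score sums per-locus ratios; exclusion gives -Inf", {
  af <- simulate_allele_frequencies(n_loci = 3, seed = 52)
  orch <- simulate_orchard(af, n_mothers = 6, n_offspring = 4, seed = 53)
  tab <- orch$table
  afreq <- allele_frequencies(tab)
  # against per-locus oracle built from transition_probability
  off <- orch$pedigree$id[7L]
  dam <- orch$pedigree$dam[7L]
  ls <- lod_score(off, dam, tab, afreq, 0.01)
  manual <- 0
  io <- match(off, tab$ids); ic <- match(dam, tab$ids)
  for (l in tab$loci) {
    oc <- c(tab$a1[io, l], tab$a2[io, l])
    dc <- c(tab$a1[ic, l], tab$a2[ic, l])
    p <- afreq$freqs[[l]]
    h <- if (oc[1] == oc[2]) p[as.character(oc[1])]^2 else
      2 * p[as.character(oc[1])] * p[as.character(oc[2])]
    manual <- manual + log(transition_probability(oc, dc, p, 0.01) / h)
  }
  expect_equal(ls$lod, unname(manual), tolerance = 1e-12)
  expect_equal(ls$n_mismatch, 0L)  # true dam, e = 0 in the generator

  # monomorphic-only sharing -> LOD 0
  a1 <- rbind(o = 101L, c = 101L); a2 <- rbind(o = 101L, c = 101L)
  colnames(a1) <- colnames(a2) <- "L1"
  mono <- genotype_table(a1, a2, c("HC", "PT"))
  afm <- allele_frequencies(mono)
  expect_equal(lod_score("o", "c", mono, afm, 0)$lod, 0)

  # e = 0 with an incompatible locus -> -Inf and a counted mismatch
  a1 <- rbind(o = 101L, c = 102L); a2 <- rbind(o = 101L, c = 102L)
  colnames(a1) <- colnames(a2) <- "L1"
  bad <- genotype_table(a1, a2, c("HC", "PT"))
  afb <- list(freqs = list(L1 = c("101" = 0.5, "102" = 0.5)))
  ls <- lod_score("o", "c", bad, afb, 0)
  expect_identical(ls$lod, -Inf)
  expect_gte(ls$n_mismatch, 1L)
})

test_that("delta statistic follows the three-branch convention", {
  expect_equal(delta_statistic(c(5, 2, 1)), 3)
  expect_equal(delta_statistic(c(4.2, -1, -3)), 4.2)
  expect_equal(delta_statistic(c(-0.5, -2)), 0)
  expect_equal(delta_statistic(7), 7)
})

test_that("LOD is invariant to allele relabeling", {
  af <- simulate_allele_frequencies(n_loci = 4, seed = 54)
  orch <- simulate_orchard(af, n_mothers = 8, n_offspring = 6, seed = 55)
  tab <- orch$table
  afreq <- allele_frequencies(tab)
  l1 <- lod_score(orch$pedigree$id[9L], "M001", tab, afreq, 0.01)$lod
  # relabel: shift every allele code by 500
  tab2 <- tab
  tab2$a1 <- tab$a1 + 500L * (tab$a1 > 0L)
  tab2$a2 <- tab$a2 + 500L * (tab$a2 > 0L)
  af2 <- allele_frequencies(tab2)
  l2 <- lod_score(orch$pedigree$id[9L], "M001", tab2, af2, 0.01)$lod
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("simulated thresholds are deterministic and ordered", {
  af <- simulate_allele_frequencies(seed = 56)
  cfg <- parentage_config(n_sim = 500, seed = 57)
  thr1 <- simulate_critical_delta(af, 30, cfg)
  thr2 <- simulate_critical_delta(af, 30, cfg)
  expect_identical(thr1$critical, thr2$critical)
  expect_identical(thr1$deltas, thr2$deltas)
  expect_gte(thr1$critical[["strict"]], thr1$critical[["relaxed"]])
  expect_gte(thr1$critical[["relaxed"]], 0)
  expect_error(simulate_critical_delta(af, 30,
                                       parentage_config(n_sim = 50)),
               "n_sim")
})

test_that("many highly informative loci make assignment near-certain", {
  # e = 0, all mothers sampled: success rate grows with loci towards 1,
  # and with 20 loci x 10 equifrequent alleles virtually every simulated
  # assignment clears the strict threshold (the threshold stops binding)
  mk <- function(nl) {
    freqs <- lapply(seq_len(nl), function(i)
      stats::setNames(rep(0.1, 10), 100 + 1:10))
    names(freqs) <- sprintf("L%02d", seq_len(nl))
    structure(list(freqs = freqs), class = "allele_freqs")
  }
  cfg <- parentage_config(error_rate = 0, n_sim = 400, seed = 58)
  thr3 <- simulate_critical_delta(mk(3), 20, cfg)
  thr20 <- simulate_critical_delta(mk(20), 20, cfg)
  expect_gt(thr20$success_rate, thr3$success_rate)
  expect_gt(thr20$success_rate, 0.99)
  expect_gte(mean(thr20$deltas >= thr20$critical[["strict"]]), 0.99)
})

test_that("assignment recovers true mothers and breaks ties lexically", {
  af <- simulate_allele_frequencies(n_loci = 10, allele_range = c(8, 14),
                                    seed = 59)
  orch <- simulate_orchard(af, n_mothers = 25, n_offspring = 40,
                           error_rate = 0, seed = 60)
  cfg <- parentage_config(error_rate = 1e-4, n_sim = 400, seed = 61)
  pr <- assign_maternity(orch$table, "HC", "PT", cfg)
  truth <- orch$pedigree$dam[match(pr$results$offspring, orch$pedigree$id)]
  expect_true(mean(pr$results$candidate == truth) > 0.9)
  # e = 0 in the generator: no true mother is Mendelian-excluded
  afreq <- allele_frequencies(orch$table)
  mm <- vapply(which(!is.na(orch$pedigree$dam)), function(i) {
    lod_score(orch$pedigree$id[i], orch$pedigree$dam[i],
              orch$table, afreq, 0)$n_mismatch
  }, integer(1))
  expect_true(all(mm == 0L))

  # clone candidates tie -> lexicographically first, flagged
  tab <- orch$table
  clone_src <- "M003"
  i <- match(clone_src, tab$ids)
  a1 <- rbind(tab$a1, M000x = tab$a1[i, ])
  a2 <- rbind(tab$a2, M000x = tab$a2[i, ])
  tabc <- genotype_table(a1, a2, c(tab$groups, M000x = "PT"))
  prc <- assign_maternity(tabc, "HC", "PT", cfg,
                          thresholds = pr$thresholds)
  was_m3 <- pr$results$candidate == clone_src
  expect_true(all(prc$results$tie[was_m3]))
  expect_true(all(prc$results$candidate[was_m3] == "M000x"))
})

test_that("genotyping errors raise exclusion rates monotonically", {
  af <- simulate_allele_frequencies(seed = 62)
  rates <- vapply(c(0, 0.05, 0.2), function(e) {
    orch <- simulate_orchard(af, n_mothers = 20, n_offspring = 120,
                             error_rate = e, seed = 63)
    afreq <- allele_frequencies(orch$table)
    off <- which(!is.na(orch$pedigree$dam))
    mean(vapply(off, function(i) {
      lod_score(orch$pedigree$id[i], orch$pedigree$dam[i],
                orch$table, afreq, 0)$n_mismatch > 0L
    }, logical(1)))
  }, numeric(1))
  expect_equal(rates[1], 0)
  expect_true(all(diff(rates) > 0))
})

test_that("unassignable offspring are reported with a reason", {
  af <- simulate_allele_frequencies(n_loci = 2, seed = 64)
  orch <- simulate_orchard(af, n_mothers = 4, n_offspring = 3, seed = 65)
  tab <- orch$table
  oid <- orch$pedigree$id[5L]
  i <- match(oid, tab$ids)
  tab$a1[i, ] <- 0L; tab$a2[i, ] <- 0L
  cfg <- parentage_config(n_sim = 200, seed = 66)
  pr <- assign_maternity(tab, "HC", "PT", cfg)
  row <- pr$results[pr$results$offspring == oid, ]
  expect_equal(row$tier, "unassigned")
  expect_match(row$reason, "no typed loci")
  expect_true(is.na(pr$pedigree$dam[pr$pedigree$id == oid]))
})
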