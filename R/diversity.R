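# Per-locus diversity and marker-informativeness statistics.

#' Effective number of alleles
#' @param p numeric vector of allele frequencies at one locus.
#' @return `1 / sum(p^2)`.
#' @export
effective_alleles <- function(p) {
  check_freqs(p)
  1 / sum(p^2)
}

#' Expected heterozygosity (gene diversity)
#'
#' The uncorrected form `1 - sum(p^2)` (GenAlEx default), which satisfies
#' the identity `H_E = 1 - 1/N_E`.  Set `unbiased = TRUE` for Nei's
#' small-sample correction `2N/(2N-1) * (1 - sum(p^2))`.
#'
#' @param p allele frequency vector.
#' @param n number of typed individuals (needed only when `unbiased`).
#' @param unbiased apply the `2N/(2N-1)` correction (default off).
#' @export
expected_het <- function(p, n = NULL, unbiased = FALSE) {
  check_freqs(p)
  he <- 1 - sum(p^2)
  if (unbiased) {
    if (is.null(n)) stop("unbiased H_E needs the sample size n")
    he <- he * (2 * n) / (2 * n - 1)
  }
  he
}

#' Polymorphic information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p allele frequency vector at one locus.
#' @export
pic <- function(p) {
  check_freqs(p)
  s2 <- sum(p^2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(p^4))
}

check_freqs <- function(p) {
  if (!is.numeric(p) || length(p) < 1L || any(p <= 0))
    stop("frequencies must be positive")
  if (abs(sum(p) - 1) > 1e-8)
    stop("frequencies must sum to 1 (got ", format(sum(p)), ")")
  invisible(p)
}

#' Per-group, per-locus diversity summary
#'
#' Computes, for each locus of one group, the number of alleles `N_A`, the
#' effective number of alleles `N_E = 1/sum(p^2)`, the observed
#' heterozygosity `H_O` (fraction of typed individuals with two different
#' alleles), the expected heterozygosity `H_E = 1 - sum(p^2)` and the
#' fixation index `F = 1 - H_O/H_E` (negative values mean heterozygote
#' excess; `NA` at a monomorphic locus).  The across-locus mean and
#' standard error (sd over sqrt(number of loci)) are attached.
#'
#' @param tab a [genotype_table()].
#' @param group group label(s); `NULL` uses all individuals.
#' @param unbiased use the small-sample corrected `H_E` (default off; the
#'   `H_E = 1 - 1/N_E` identity then no longer holds).
#' @return data.frame of class `diversity_summary` with one row per locus
#'   and attributes `mean` and `se` (named numeric vectors over the five
#'   statistics) plus `group`.
#' @export
diversity_summary <- function(tab, group = NULL, unbiased = FALSE) {
  sub <- subset_group(tab, group)
  af <- allele_frequencies(sub)
  st <- lapply(sub$loci, function(l) {
    p <- af$freqs[[l]]
    typed <- sub$a1[, l] > 0L
    ho <- mean(sub$a1[typed, l] != sub$a2[typed, l])
    he <- expected_het(p, n = af$n_typed[[l]], unbiased = unbiased)
    data.frame(locus = l,
               n = af$n_typed[[l]],
               N_A = length(p),
               N_E = effective_alleles(p),
               H_O = ho,
               H_E = he,
               F = if (he > 0) 1 - ho / he else NA_real_)
  })
  out <- do.call(rbind, st)
  rownames(out) <- NULL
  stats <- c("N_A", "N_E", "H_O", "H_E", "F")
  L <- nrow(out)
  attr(out, "mean") <- vapply(stats, function(s) mean(out[[s]], na.rm = TRUE),
                              numeric(1))
  attr(out, "se") <- vapply(stats, function(s)
    stats::sd(out[[s]], na.rm = TRUE) / sqrt(L), numeric(1))
  attr(out, "group") <- if (is.null(group)) "all" else
    paste(group, collapse = "+")
  class(out) <- c("diversity_summary", "data.frame")
  out
}

#' @export
print.diversity_summary <- function(x, digits = 3, ...) {
  cat("diversity summary, group:", attr(x, "group"), "\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  m <- attr(x, "mean"); s <- attr(x, "se")
  cat("mean (SE): ",
      paste(sprintf("%s %.3f (%.3f)", names(m), m, s), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Diversity table across groups
#'
#' Convenience wrapper producing one [diversity_summary()] per group plus an
#' overall row set, in the shape of a per-population microsatellite
#' diversity report.
#'
#' @param tab a [genotype_table()].
#' @param groups group labels (default: all groups present, in order of
#'   first appearance).
#' @return long data.frame with columns group, locus, n, N_A, N_E, H_O,
#'   H_E, F; per-group mean/SE rows carry locus = "Total".
#' @export
diversity_table <- function(tab, groups = NULL) {
  groups <- groups %||% unique(unname(tab$groups))
  blocks <- lapply(c(as.list(groups), list(groups)), function(g) {
    ds <- diversity_summary(tab, g)
    m <- attr(ds, "mean"); s <- attr(ds, "se")
    tot <- data.frame(locus = "Total", n = NA_integer_,
                      N_A = m[["N_A"]], N_E = m[["N_E"]], H_O = m[["H_O"]],
                      H_E = m[["H_E"]], F = m[["F"]])
    se <- data.frame(locus = "SE", n = NA_integer_,
                     N_A = s[["N_A"]], N_E = s[["N_E"]], H_O = s[["H_O"]],
                     H_E = s[["H_E"]], F = s[["F"]])
    cbind(group = if (length(g) > 1L) "Overall" else g,
          rbind(as.data.frame(ds), tot, se))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Marker informativeness: PIC and non-exclusion probabilities
#'
#' For each locus, computes the polymorphic information content and two
#' non-exclusion probabilities under Hardy-Weinberg equilibrium:
#' `NE_1P`, the probability that a random non-mother cannot be excluded as
#' the mother of a random offspring when the other parent is unknown
#' (first-parent non-exclusion, complement of the Jamieson & Taylor
#' one-parent exclusion polynomial
#' `E1 = 1 - 4a2 + 2a2^2 + 4a3 - 3a4` with `ak = sum(p^k)`), and `NE_I`,
#' the probability that two random individuals share a genotype
#' (`NE_I = sum(p^4) + sum_{i<j} (2 p_i p_j)^2 = 2 a2^2 - a4`).
#' Multi-locus values are products across loci (independent loci).
#'
#' @param af an `allele_freqs` object (or a bare list of frequency vectors).
#' @return data.frame of class `locus_informativeness` with columns locus,
#'   PIC, NE_1P, NE_I; attributes `combined_NE_1P`, `combined_NE_I` and
#'   `mean_PIC`.
#' @export
non_exclusion <- function(af) {
  freqs <- if (inherits(af, "allele_freqs")) af$freqs else af
  if (length(freqs) < 1L) stop("need at least one locus")
  rows <- lapply(names(freqs), function(l) {
    p <- freqs[[l]]
    check_freqs(p)
    a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
    e1 <- 1 - 4 * a2 + 2 * a2^2 + 4 * a3 - 3 * a4
    data.frame(locus = l, PIC = pic(p),
               NE_1P = 1 - e1,
               NE_I = 2 * a2^2 - a4)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "combined_NE_1P") <- prod(out$NE_1P)
  attr(out, "combined_NE_I") <- prod(out$NE_I)
  attr(out, "mean_PIC") <- mean(out$PIC)
  class(out) <- c("locus_informativeness", "data.frame")
  out
}

#' @export
print.locus_informativeness <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  cat(sprintf("mean PIC %.3f; combined NE_1P %.3g; combined NE_I %.3g\n",
              attr(x, "mean_PIC"), attr(x, "combined_NE_1P"),
              attr(x, "combined_NE_I")))
  invisible(x)
}
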