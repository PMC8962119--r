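# Genotype data model and I/O for codominant (microsatellite) markers.
#
# A genotype table stores, for every individual and locus, an unordered pair
# of integer allele codes (typically fragment sizes).  Code 0 is reserved
# for missing: a call is either two positive codes or missing at both.

#' Construct a genotype table
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   codes of each call; 0 in both marks a missing call.  Row names are
#'   individual ids, column names are locus names.
#' @param groups character vector of group labels (e.g. `"PT"`, `"HC"`,
#'   `"HS"`), one per individual, named by id or in row order.
#' @return an object of class `genotype_table` with fields `ids`, `groups`,
#'   `loci`, `a1`, `a2`.
#' @export
genotype_table <- function(a1, a2, groups) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices must have identical dimensions")
  ids <- rownames(a1)
  loci <- colnames(a1)
  if (is.null(ids) || is.null(loci))
    stop("allele matrices need row names (ids) and column names (loci)")
  if (anyDuplicated(ids)) stop("duplicate individual id: ",
                               ids[duplicated(ids)][1L])
  if (anyDuplicated(loci)) stop("duplicate locus name: ",
                                loci[duplicated(loci)][1L])
  if (!is.null(names(groups))) groups <- groups[ids]
  groups <- as.character(groups)
  if (length(groups) != length(ids))
    stop("groups must have one label per individual")
  names(groups) <- ids
  bad <- (a1 > 0L) != (a2 > 0L)
  if (any(bad, na.rm = TRUE))
    stop("half-missing call (one allele 0) at individual ",
         ids[which(rowSums(bad) > 0)[1L]])
  if (any(a1 < 0L) || any(a2 < 0L)) stop("negative allele codes not allowed")
  structure(list(ids = ids, groups = groups, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d loci\n",
              length(x$ids), length(x$loci)))
  tg <- table(x$groups)
  cat("groups:", paste(sprintf("%s (%d)", names(tg), tg), collapse = ", "),
      "\n")
  miss <- mean(x$a1 == 0L)
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

# subset a table to one group (or all individuals when group is NULL)
subset_group <- function(tab, group = NULL) {
  if (is.null(group)) return(tab)
  keep <- tab$groups %in% group
  if (!any(keep)) stop("no individuals in group ", paste(group, collapse = "/"))
  genotype_table(tab$a1[keep, , drop = FALSE], tab$a2[keep, , drop = FALSE],
                 tab$groups[keep])
}

#' Read a genotype table
#'
#' Two dialects are supported.  `genalex_csv` is the GenAlEx codominant
#' layout: line 1 `n_loci,n_individuals,n_groups,size1,size2,...`; line 2
#' `title,,,group1,group2,...`; line 3 the column header
#' `id,group,locus1,,locus2,,...`; then one row per individual with two
#' columns per locus.  `long_csv` has columns
#' `id,group,locus,allele1,allele2`.  Allele code 0 means missing.
#'
#' @param path file path.
#' @param dialect `"genalex_csv"` or `"long_csv"`.
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path, dialect = c("genalex_csv", "long_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "long_csv") read_long_csv(path) else read_genalex_csv(path)
}

read_long_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "locus", "allele1", "allele2")
  if (!all(need %in% names(d)))
    stop("long_csv needs columns ", paste(need, collapse = ","))
  ids <- unique(d$id)
  loci <- unique(d$locus)
  key <- paste(d$id, d$locus)
  if (anyDuplicated(key))
    stop("duplicate (id, locus) row at line ",
         which(duplicated(key))[1L] + 1L)
  a1 <- matrix(0L, length(ids), length(loci), dimnames = list(ids, loci))
  a2 <- a1
  a1[cbind(match(d$id, ids), match(d$locus, loci))] <- as.integer(d$allele1)
  a2[cbind(match(d$id, ids), match(d$locus, loci))] <- as.integer(d$allele2)
  groups <- d$group[match(ids, d$id)]
  genotype_table(a1, a2, groups)
}

read_genalex_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("genalex_csv: file too short")
  hd <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  n_loci <- as.integer(hd[1L]); n_ind <- as.integer(hd[2L])
  n_grp <- as.integer(hd[3L])
  if (is.na(n_loci) || is.na(n_ind))
    stop("genalex_csv: malformed header at line 1")
  grp_sizes <- as.integer(hd[3L + seq_len(n_grp)])
  l2 <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  grp_names <- l2[3L + seq_len(n_grp)]
  colh <- strsplit(lines[3L], ",", fixed = TRUE)[[1L]]
  loci <- colh[seq(3L, by = 2L, length.out = n_loci)]
  if (anyNA(loci) || any(loci == ""))
    stop("genalex_csv: malformed locus header at line 3")
  rows <- lines[3L + seq_len(n_ind)]
  a1 <- matrix(0L, n_ind, n_loci)
  a2 <- a1
  ids <- character(n_ind); grp <- character(n_ind)
  for (i in seq_len(n_ind)) {
    f <- strsplit(rows[i], ",", fixed = TRUE)[[1L]]
    if (length(f) < 2L + 2L * n_loci)
      stop("genalex_csv: row with wrong allele count at line ", i + 3L)
    ids[i] <- f[1L]; grp[i] <- f[2L]
    al <- suppressWarnings(as.integer(f[2L + seq_len(2L * n_loci)]))
    if (anyNA(al))
      stop("genalex_csv: non-integer allele code at line ", i + 3L)
    a1[i, ] <- al[seq(1L, by = 2L, length.out = n_loci)]
    a2[i, ] <- al[seq(2L, by = 2L, length.out = n_loci)]
  }
  if (anyDuplicated(ids))
    stop("genalex_csv: duplicated id at line ",
         which(duplicated(ids))[1L] + 3L)
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  tab <- genotype_table(a1, a2, grp)
  attr(tab, "genalex_title") <- l2[1L]
  attr(tab, "genalex_group_order") <- grp_names
  if (!is.na(n_grp) && length(grp_sizes) == n_grp &&
      !identical(unname(grp_sizes),
                 unname(as.integer(table(grp)[grp_names]))))
    warning("genalex_csv: header group sizes disagree with data rows")
  tab
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]; writing then reading a canonical file
#' is lossless.
#'
#' @param tab a [genotype_table()].
#' @param path output file path.
#' @param dialect `"genalex_csv"` or `"long_csv"`.
#' @param title title cell for the genalex header.
#' @export
write_genotype_table <- function(tab, path,
                                 dialect = c("genalex_csv", "long_csv"),
                                 title = "orchardgt export") {
  dialect <- match.arg(dialect)
  if (dialect == "long_csv") {
    d <- data.frame(
      id = rep(tab$ids, times = length(tab$loci)),
      group = rep(unname(tab$groups), times = length(tab$loci)),
      locus = rep(tab$loci, each = length(tab$ids)),
      allele1 = as.vector(tab$a1),
      allele2 = as.vector(tab$a2))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  grp_names <- attr(tab, "genalex_group_order") %||% unique(unname(tab$groups))
  sizes <- as.integer(table(tab$groups)[grp_names])
  n_loci <- length(tab$loci)
  l1 <- paste(c(n_loci, length(tab$ids), length(grp_names), sizes),
              collapse = ",")
  ttl <- gsub(",", ";", attr(tab, "genalex_title") %||% title, fixed = TRUE)
  l2 <- paste(c(ttl, "", "", grp_names), collapse = ",")
  lcols <- as.vector(rbind(tab$loci, ""))
  l3 <- paste(c("id", "group", lcols), collapse = ",")
  body <- vapply(seq_along(tab$ids), function(i) {
    al <- as.vector(rbind(tab$a1[i, ], tab$a2[i, ]))
    paste(c(tab$ids[i], unname(tab$groups[i]), al), collapse = ",")
  }, character(1))
  writeLines(c(l1, l2, l3, body), path)
  invisible(path)
}

#' Allele frequencies per locus
#'
#' Each non-missing call contributes two allele observations; missing calls
#' are dropped locus by locus (per-locus deletion).
#'
#' @param tab a [genotype_table()].
#' @param group optional group label(s) to restrict to.
#' @return object of class `allele_freqs`: a list with `freqs` (per locus, a
#'   named numeric vector of frequencies summing to 1) and `n_typed` (per
#'   locus, the number of individuals with a non-missing call).
#' @export
allele_frequencies <- function(tab, group = NULL) {
  tab <- subset_group(tab, group)
  freqs <- vector("list", length(tab$loci))
  names(freqs) <- tab$loci
  n_typed <- integer(length(tab$loci))
  names(n_typed) <- tab$loci
  for (l in tab$loci) {
    typed <- tab$a1[, l] > 0L
    n_typed[l] <- sum(typed)
    if (n_typed[l] == 0L)
      stop("locus ", l, " has no typed individuals")
    cnt <- table(c(tab$a1[typed, l], tab$a2[typed, l]))
    p <- as.numeric(cnt) / sum(cnt)
    names(p) <- names(cnt)
    freqs[[l]] <- p
  }
  structure(list(freqs = freqs, n_typed = n_typed), class = "allele_freqs")
}
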