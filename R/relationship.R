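# Additive (numerator) relationship matrix from a pedigree.

#' Additive relationship matrix by the tabular method
#'
#' Founders are assumed unrelated and non-inbred; unknown parents (NA) are
#' treated as distinct unrelated founders, so maternal half-sibs with
#' unknown sires get the expected relationship 0.25 and dam-offspring pairs
#' 0.5.  Individuals are sorted so parents precede offspring; a cyclic
#' pedigree is an error.
#'
#' @param ped data.frame with columns `id`, `dam`, `sire` (character; `NA`
#'   for unknown).  Parents not listed as individuals are added as
#'   founders.
#' @return symmetric relationship matrix with ids as dimnames (includes
#'   any added founder parents).
#' @export
build_A <- function(ped) {
  ped$id <- as.character(ped$id)
  ped$dam <- as.character(ped$dam)
  ped$sire <- as.character(ped$sire)
  if (anyDuplicated(ped$id)) stop("duplicated id in pedigree")
  parents <- setdiff(stats::na.omit(c(ped$dam, ped$sire)), ped$id)
  if (length(parents))
    ped <- rbind(data.frame(id = parents, dam = NA_character_,
                            sire = NA_character_), ped)
  n <- nrow(ped)
  # topological sort: repeatedly emit individuals whose parents are placed
  placed <- logical(n)
  order_idx <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(ped$dam) | ped$dam %in% ped$id[placed]) &
      (is.na(ped$sire) | ped$sire %in% ped$id[placed])
    if (!any(ready)) break
    order_idx <- c(order_idx, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) stop("cyclic pedigree (or parent listed after use): ",
                         paste(ped$id[!placed], collapse = ","))
  ped <- ped[order_idx, ]
  ids <- ped$id
  di <- match(ped$dam, ids)
  si <- match(ped$sire, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    d <- di[i]; s <- si[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (is.na(d)) 0 else A[j, d]) +
                      (if (is.na(s)) 0 else A[j, s]))
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + 0.5 * (if (is.na(d) || is.na(s)) 0 else A[d, s])
  }
  A
}
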