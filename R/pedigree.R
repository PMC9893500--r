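#' Validate and topologically sort a pedigree
#'
#' A pedigree is a data.frame with columns `animal`, `sire`, `dam`
#' (character or integer IDs; unknown parents coded `NA`, `"0"` or `0`).
#' The result lists every animal (parents that lack their own row are added
#' as founders), ordered so that parents precede offspring; a cycle (an
#' animal that is its own ancestor) is a fatal error reporting the
#' offending chain.
#'
#' @param ped Data.frame with `animal`, `sire`, `dam`.
#' @return Data.frame `animal`, `sire`, `dam` (character, `NA` = unknown),
#'   topologically sorted, with attribute `founders`.
#' @export
sort_pedigree <- function(ped) {
  ped <- as.data.frame(ped)
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA")] <- NA_character_
    x
  }
  an <- norm(ped$animal); si <- norm(ped$sire); da <- norm(ped$dam)
  if (anyNA(an)) stop("animal IDs must be known")
  if (anyDuplicated(an)) stop("duplicated animal IDs in pedigree")
  parents <- setdiff(stats::na.omit(c(si, da)), an)
  an2 <- c(parents, an)
  si2 <- c(rep(NA_character_, length(parents)), si)
  da2 <- c(rep(NA_character_, length(parents)), da)
  n <- length(an2)
  idx <- setNames(seq_len(n), an2)
  sire_i <- ifelse(is.na(si2), 0L, idx[si2])
  dam_i <- ifelse(is.na(da2), 0L, idx[da2])
  # Kahn topological sort; leftovers indicate a cycle
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_i[i], dam_i[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    bad <- an2[setdiff(seq_len(n), ord)]
    stop("pedigree contains a cycle involving: ",
         paste(head(bad, 10), collapse = " -> "))
  }
  out <- data.frame(animal = an2[ord], sire = si2[ord], dam = da2[ord],
                    stringsAsFactors = FALSE)
  attr(out, "founders") <- out$animal[is.na(out$sire) & is.na(out$dam)]
  out
}

#' Read a 3-column pedigree file
#'
#' Whitespace- or comma-delimited text with columns animal, sire, dam
#' (header optional); 0 or NA marks an unknown parent.
#'
#' @param path File path.
#' @return Sorted pedigree (see [sort_pedigree()]).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("animal", first, ignore.case = TRUE)
  tab <- read.table(path, sep = sep, header = header,
                    stringsAsFactors = FALSE)
  if (!header) names(tab)[1:3] <- c("animal", "sire", "dam")
  sort_pedigree(tab[, 1:3])
}

#' Additive (numerator) relationship matrix from a pedigree
#'
#' Tabular method on the topologically sorted pedigree:
#' a_ii = 1 + 0.5 a(sire_i, dam_i), a_ij = 0.5 (a(j, sire_i) + a(j, dam_i))
#' for j earlier than i, with unknown parents contributing 0. The diagonal
#' is 1 plus the animal's inbreeding coefficient.
#'
#' @param ped Pedigree data.frame (sorted or not; [sort_pedigree()] is
#'   applied).
#' @return Symmetric matrix with dimnames = animal IDs, ordered
#'   parents-before-offspring.
#' @export
additive_relationship_matrix <- function(ped) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      aj <- 0.5 * ((if (si > 0) A[j, si] else 0) +
                   (if (di > 0) A[j, di] else 0))
      A[j, i] <- aj
      A[i, j] <- aj
    }
    A[i, i] <- 1 + if (si > 0 && di > 0) 0.5 * A[si, di] else 0
  }
  A
}

#' Inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding accounted for via the diagonal of A
#' (computed by the tabular method). Returned dense; the pedigree sizes
#' this package targets (hundreds of animals) do not need sparse storage.
#'
#' @param ped Pedigree data.frame.
#' @return Inverse of [additive_relationship_matrix()] with matching
#'   dimnames.
#' @export
ainverse <- function(ped) {
  ped <- sort_pedigree(ped)
  A <- additive_relationship_matrix(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  Ai <- matrix(0, n, n, dimnames = dimnames(A))
  F_ <- diag(A) - 1
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    Fs <- if (si > 0) F_[si] else -1
    Fd <- if (di > 0) F_[di] else -1
    # Mendelian sampling variance
    m <- 1 - 0.25 * (1 + Fs) - 0.25 * (1 + Fd)
    w <- 1 / m
    Ai[i, i] <- Ai[i, i] + w
    for (p in c(si, di)) {
      if (p > 0) {
        Ai[i, p] <- Ai[i, p] - w / 2
        Ai[p, i] <- Ai[p, i] - w / 2
      }
    }
    for (p in c(si, di)) for (q in c(si, di)) {
      if (p > 0 && q > 0) Ai[p, q] <- Ai[p, q] + w / 4
    }
  }
  Ai
}
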