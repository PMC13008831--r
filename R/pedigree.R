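#' Pedigree validation and additive-relationship algebra
#'
#' A pedigree is a plain `data.frame` with columns `id`, `sire`, `dam`
#' (character; `NA` = unknown parent), `sex` (`"F"`/`"M"`) and `generation`
#' (free-form label, e.g. `"P"`, `"F1"`, `"F2"`). [validate_and_sort()] checks
#' the structural invariants and returns the records topologically ordered so
#' that every parent precedes its offspring; all downstream algebra
#' ([inbreeding()], [amatrix()], [ainverse()]) requires that ordering and will
#' call it when given an unsorted frame.
#'
#' @name pedigree
NULL

#' Validate a pedigree and sort parents before offspring
#'
#' Checks id uniqueness, self-parenthood, presence of named parents, sex
#' consistency of parental roles (an id used as a sire must be recorded as
#' male, a dam as female) and acyclicity, then returns the same records in a
#' topological order.
#'
#' @param records data.frame with columns `id`, `sire`, `dam`, `sex`,
#'   `generation`. Empty strings in `sire`/`dam` are treated as unknown.
#' @return The validated records, reordered, with class
#'   `c("pedigree", "data.frame")`.
#' @examples
#' ped <- data.frame(id = c("o", "s", "d"), sire = c("s", NA, NA),
#'                   dam = c("d", NA, NA), sex = c("F", "M", "F"),
#'                   generation = c("F1", "P", "P"))
#' validate_and_sort(ped)$id
#' @export
validate_and_sort <- function(records) {
  req <- c("id", "sire", "dam", "sex", "generation")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))
  ped <- as.data.frame(records)[, req]
  for (col in c("id", "sire", "dam", "sex", "generation"))
    ped[[col]] <- as.character(ped[[col]])
  ped$sire[!is.na(ped$sire) & ped$sire == ""] <- NA_character_
  ped$dam[!is.na(ped$dam) & ped$dam == ""] <- NA_character_

  if (anyDuplicated(ped$id))
    stop("duplicated pedigree id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  if (any(bad <- !is.na(ped$sire) & ped$sire == ped$id) ||
      any(bad2 <- !is.na(ped$dam) & ped$dam == ped$id))
    stop("self-parent: individual listed as its own sire or dam: ",
         paste(ped$id[(!is.na(ped$sire) & ped$sire == ped$id) |
                        (!is.na(ped$dam) & ped$dam == ped$id)], collapse = ", "))
  if (!all(ped$sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M'")

  known <- ped$id
  orphan <- setdiff(c(ped$sire, ped$dam), c(known, NA))
  if (length(orphan))
    stop("parent label(s) absent from pedigree: ", paste(orphan, collapse = ", "))

  sex_of <- stats::setNames(ped$sex, ped$id)
  bad_sire <- unique(stats::na.omit(ped$sire[sex_of[ped$sire] == "F"]))
  bad_dam <- unique(stats::na.omit(ped$dam[sex_of[ped$dam] == "M"]))
  if (length(bad_sire) || length(bad_dam))
    stop("sex inconsistent with parental role: ",
         paste(c(bad_sire, bad_dam), collapse = ", "))

  # Kahn's algorithm on the parent -> offspring DAG
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n)
    stop("cycle detected in pedigree involving: ",
         paste(ped$id[indeg > 0L], collapse = ", "))
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' @keywords internal
.ped_indices <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- validate_and_sort(ped)
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  list(ped = ped,
       sire = ifelse(is.na(ped$sire), 0L, unname(idx[ped$sire])),
       dam = ifelse(is.na(ped$dam), 0L, unname(idx[ped$dam])))
}

#' Inbreeding coefficients
#'
#' Computes each individual's inbreeding coefficient F as the kinship between
#' its parents, by the Meuwissen-Luo ancestor-tracing recursion (exact,
#' O(n x pedigree depth)). Founders and individuals with at least one unknown
#' parent get F = 0 (unknown parents are unrelated non-inbred founders).
#'
#' @param ped pedigree (see [validate_and_sort()]).
#' @return Named numeric vector of F, in pedigree order.
#' @export
inbreeding <- function(ped) {
  pp <- .ped_indices(ped)
  ped <- pp$ped; si <- pp$sire; di <- pp$dam
  n <- nrow(ped)
  FF <- numeric(n)
  # D[j] = within-family (Mendelian) variance scale for j, needs parents' F only
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    D[i] <- if (s > 0L && d > 0L) 0.5 - 0.25 * (FF[s] + FF[d])
    else if (s > 0L) 0.75 - 0.25 * FF[s]
    else if (d > 0L) 0.75 - 0.25 * FF[d]
    else 1
    if (s == 0L || d == 0L) { FF[i] <- 0; next }
    # trace ancestors of i: A_ii = sum_j L_ij^2 D_j, F_i = A_ii - 1
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      if (si[j] > 0L) L[si[j]] <- L[si[j]] + 0.5 * L[j]
      if (di[j] > 0L) L[di[j]] <- L[di[j]] + 0.5 * L[j]
      aii <- aii + L[j]^2 * D[j]
    }
    FF[i] <- aii - 1
    # D[i] computed above used parents' F (indices < i), unaffected by FF[i]
  }
  stats::setNames(FF, ped$id)
}

#' Additive genetic relationship matrix A
#'
#' Recursive tabular method: `A[i,j] = (A[j,sire_i] + A[j,dam_i]) / 2` for
#' j preceding i and `A[i,i] = 1 + F_i` with `F_i = A[sire_i, dam_i] / 2`.
#' Dense; intended for pedigrees up to a few thousand individuals. For the
#' mixed-model equations use [ainverse()], which never forms A.
#'
#' @param ped pedigree.
#' @return Dense symmetric matrix with individual labels as dimnames.
#' @export
amatrix <- function(ped) {
  pp <- .ped_indices(ped)
  ped <- pp$ped; si <- pp$sire; di <- pp$dam
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    prev <- seq_len(i - 1L)
    row <- numeric(i - 1L)
    if (s > 0L) row <- row + A[prev, s]
    if (d > 0L) row <- row + A[prev, d]
    row <- row / 2
    A[prev, i] <- row
    A[i, prev] <- row
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding corrections: A-inverse is assembled
#' directly from parent links and the Mendelian sampling variances
#' `d_i = 1/2 - (F_s + F_d)/4` (adjusted when a parent is unknown), without
#' ever forming the dense A.
#'
#' @param ped pedigree.
#' @return Sparse symmetric matrix (`Matrix::dsCMatrix`) with labels.
#' @export
ainverse <- function(ped) {
  pp <- .ped_indices(ped)
  ped <- pp$ped; si <- pp$sire; di <- pp$dam
  n <- nrow(ped)
  FF <- inbreeding(ped)
  dinv <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dd <- if (s > 0L && d > 0L) 0.5 - 0.25 * (FF[s] + FF[d])
    else if (s > 0L) 0.75 - 0.25 * FF[s]
    else if (d > 0L) 0.75 - 0.25 * FF[d]
    else 1
    dinv[i] <- 1 / dd
  }
  bi <- dinv
  i_self <- seq_len(n)
  ii <- i_self; jj <- i_self; xx <- bi
  hs <- si > 0L; hd <- di > 0L
  # sire terms
  ii <- c(ii, si[hs], i_self[hs], si[hs])
  jj <- c(jj, i_self[hs], si[hs], si[hs])
  xx <- c(xx, -bi[hs] / 2, -bi[hs] / 2, bi[hs] / 4)
  # dam terms
  ii <- c(ii, di[hd], i_self[hd], di[hd])
  jj <- c(jj, i_self[hd], di[hd], di[hd])
  xx <- c(xx, -bi[hd] / 2, -bi[hd] / 2, bi[hd] / 4)
  # sire-dam cross terms
  hb <- hs & hd
  ii <- c(ii, si[hb], di[hb])
  jj <- c(jj, di[hb], si[hb])
  xx <- c(xx, bi[hb] / 4, bi[hb] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  methods::as(Matrix::forceSymmetric(Ainv), "symmetricMatrix")
}

#' Read / write the pedigree CSV
#'
#' Columns `id,sire,dam,sex,generation`; empty string encodes an unknown
#' parent; header mandatory; UTF-8.
#'
#' @param path file path.
#' @return [read_pedigree()] returns a validated, sorted pedigree.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = "", fileEncoding = "UTF-8")
  validate_and_sort(df)
}

#' @rdname read_pedigree
#' @param ped pedigree to write.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
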