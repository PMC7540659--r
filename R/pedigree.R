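#' Build the numerator relationship matrix from a pedigree
#'
#' Computes the additive (numerator) relationship matrix \eqn{A} by the
#' tabular (recursive) method with inbreeding.  \eqn{A} is the
#' pedigree-expected additive genetic covariance kernel used as the
#' covariance of breeding values in every mixed model of this package:
#' \eqn{a_{ij} = \frac{1}{2}(a_{j,s(i)} + a_{j,d(i)})} for \eqn{j < i} and
#' \eqn{a_{ii} = 1 + \frac{1}{2} a_{s(i),d(i)}}, where \eqn{s(i)} and
#' \eqn{d(i)} are the sire and dam of animal \eqn{i}.  Unknown parents
#' contribute nothing (founder assumption).
#'
#' @param ped a pedigree as returned by [read_pedigree()], or any data frame
#'   with columns `animal`, `sire`, `dam` (character; `NA` = unknown parent).
#'   Parents must precede offspring; use [read_pedigree()] to sort and
#'   validate an arbitrary pedigree.
#' @return an object of class `relmat`: a list with elements
#'   \describe{
#'     \item{ids}{character vector of animal ids, in pedigree order}
#'     \item{A}{dense symmetric numerator relationship matrix}
#'     \item{F}{per-animal inbreeding coefficients, `diag(A) - 1`}
#'   }
#' @seealso [subset_relmat()] to extract/reorder a principal submatrix.
#' @export
build_A <- function(ped) {
  ped <- as.data.frame(ped)
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  ids <- as.character(ped$animal)
  if (anyDuplicated(ids) > 0L)
    stop("duplicated animal ids in pedigree")
  n <- length(ids)
  idx <- seq_len(n)
  names(idx) <- ids
  si <- match(as.character(ped$sire), ids)
  di <- match(as.character(ped$dam), ids)
  # a referenced parent must already be defined (topological order)
  bad <- which(!is.na(si) & si >= idx | !is.na(di) & di >= idx)
  if (length(bad))
    stop("pedigree not topologically ordered (offspring before parent); ",
         "run read_pedigree() first: row ", bad[1L])
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[j, s]
      if (!is.na(d)) row <- row + 0.5 * A[j, d]
      A[j, i] <- A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  structure(list(ids = ids, A = A, F = diag(A) - 1), class = "relmat")
}

#' Principal submatrix of a relationship matrix
#'
#' @param R a `relmat` from [build_A()]
#' @param ids animal ids to keep, in the requested output order
#' @return a `relmat` restricted (and permuted) to `ids`
#' @export
subset_relmat <- function(R, ids) {
  stopifnot(inherits(R, "relmat"))
  ids <- as.character(ids)
  miss <- setdiff(ids, R$ids)
  if (length(miss))
    stop("unknown animal id(s): ", paste(utils::head(miss, 5L), collapse = ", "))
  k <- match(ids, R$ids)
  structure(list(ids = ids, A = R$A[k, k, drop = FALSE], F = R$F[k]),
            class = "relmat")
}

#' @export
print.relmat <- function(x, ...) {
  cat("Numerator relationship matrix:", length(x$ids), "animals; mean F =",
      format(mean(x$F), digits = 4), "\n")
  invisible(x)
}
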