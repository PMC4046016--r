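#' Joint entropy of 1-4 alignment columns
#'
#' Plug-in Shannon entropy, in bits, of the empirical joint distribution of
#' the named columns: H = -sum p log2 p with 0 log 0 = 0. Gaps count as an
#' ordinary 21st symbol.
#'
#' @param aln An [encoded_alignment()].
#' @param columns 1 to 4 distinct column indices (1-based).
#' @return Entropy in bits (non-negative scalar).
#' @export
joint_entropy <- function(aln, columns) {
  stopifnot(inherits(aln, "encoded_alignment"))
  columns <- as.integer(columns)
  if (length(columns) < 1L || length(columns) > 4L)
    stop("argument error: 1 to 4 columns required")
  if (anyDuplicated(columns))
    stop("argument error: columns must be distinct")
  if (any(columns < 1L) || any(columns > ncol(aln$matrix)))
    stop("argument error: column index out of range")
  cpp_joint_entropy(aln$matrix, columns, length(aln$alphabet))
}

#' Pairwise mutual information between two columns
#'
#' I(Xi;Xj) = H(Xi) + H(Xj) - H(Xi,Xj), in bits.
#'
#' @inheritParams joint_entropy
#' @param i,j Distinct column indices.
#' @return MI in bits.
#' @export
mi_2d <- function(aln, i, j) {
  if (i == j) stop("argument error: i and j must differ")
  joint_entropy(aln, i) + joint_entropy(aln, j) - joint_entropy(aln, c(i, j))
}

#' Conditional mutual information given one column
#'
#' I(Xi;Xj|Xk) computed from four joint entropies:
#' H(Xi,Xk) - H(Xi,Xk,Xj) - H(Xk) + H(Xk,Xj). Equals I(Xi;Xj) minus the
#' three-way interaction information I(Xi;Xj;Xk), and equals the
#' probability-weighted average of the per-stratum MI over the values of Xk.
#'
#' @inheritParams joint_entropy
#' @param i,j,k Pairwise distinct column indices.
#' @return Conditional MI in bits.
#' @export
cond_mi_given_one <- function(aln, i, j, k) {
  if (anyDuplicated(c(i, j, k)))
    stop("argument error: i, j, k must be pairwise distinct")
  joint_entropy(aln, c(i, k)) - joint_entropy(aln, c(i, k, j)) -
    joint_entropy(aln, k) + joint_entropy(aln, c(k, j))
}

#' Conditional mutual information given two columns
#'
#' I(Xi;Xj|Xk,Xl) in its four-entropy form:
#' -H(Xk,Xl) + H(Xi,Xk,Xl) + H(Xj,Xk,Xl) - H(Xi,Xj,Xk,Xl).
#'
#' @inheritParams joint_entropy
#' @param i,j,k,l Pairwise distinct column indices.
#' @return Conditional MI in bits.
#' @export
cond_mi_given_two <- function(aln, i, j, k, l) {
  if (anyDuplicated(c(i, j, k, l)))
    stop("argument error: i, j, k, l must be pairwise distinct")
  -joint_entropy(aln, c(k, l)) + joint_entropy(aln, c(i, k, l)) +
    joint_entropy(aln, c(j, k, l)) - joint_entropy(aln, c(i, j, k, l))
}

#' Interaction information of three columns
#'
#' I(Xi;Xj;Xk) from the seven-entropy inclusion-exclusion expansion; may be
#' negative (synergy).
#'
#' @inheritParams joint_entropy
#' @param i,j,k Pairwise distinct column indices.
#' @return Interaction information in bits.
#' @export
interaction_information_3 <- function(aln, i, j, k) {
  if (anyDuplicated(c(i, j, k)))
    stop("argument error: i, j, k must be pairwise distinct")
  joint_entropy(aln, i) + joint_entropy(aln, j) + joint_entropy(aln, k) -
    joint_entropy(aln, c(i, j)) - joint_entropy(aln, c(i, k)) -
    joint_entropy(aln, c(j, k)) + joint_entropy(aln, c(i, j, k))
}

#' Interaction information of four columns
#'
#' Fifteen-entropy inclusion-exclusion expansion of the four-way
#' interaction information.
#'
#' @inheritParams joint_entropy
#' @param i,j,k,l Pairwise distinct column indices.
#' @return Interaction information in bits.
#' @export
interaction_information_4 <- function(aln, i, j, k, l) {
  if (anyDuplicated(c(i, j, k, l)))
    stop("argument error: indices must be pairwise distinct")
  one <- sum(vapply(c(i, j, k, l), function(a) joint_entropy(aln, a), 0))
  prs <- combn(c(i, j, k, l), 2L)
  two <- sum(vapply(seq_len(ncol(prs)),
                    function(a) joint_entropy(aln, prs[, a]), 0))
  trp <- combn(c(i, j, k, l), 3L)
  three <- sum(vapply(seq_len(ncol(trp)),
                      function(a) joint_entropy(aln, trp[, a]), 0))
  one - two + three - joint_entropy(aln, c(i, j, k, l))
}

#' Build the pairwise (2D) mutual information map
#'
#' @param aln An [encoded_alignment()].
#' @return A [covariation_map()] with method \code{"2D_MI"}.
#' @export
build_map_2d <- function(aln) {
  stopifnot(inherits(aln, "encoded_alignment"))
  if (ncol(aln$matrix) < 2L) stop("input error: need L >= 2")
  covariation_map(cpp_map_2d(aln$matrix, length(aln$alphabet)),
                  method = "2D_MI")
}

#' Build the 3D mutual information map
#'
#' For each pair (i, j) the conditional MI I(Xi;Xj|Xk) is averaged over
#' every third column k not in the pair. Averaging over all third columns
#' removes indirect (ternary) coupling transmitted through any single other
#' residue.
#'
#' @param aln An [encoded_alignment()].
#' @return A [covariation_map()] with method \code{"3D_MI"}.
#' @export
build_map_3d <- function(aln) {
  stopifnot(inherits(aln, "encoded_alignment"))
  if (ncol(aln$matrix) < 3L) stop("input error: need L >= 3")
  covariation_map(cpp_map_3d(aln$matrix, length(aln$alphabet)),
                  method = "3D_MI")
}

#' Build the 4D mutual information map
#'
#' For each pair (i, j) the conditional MI I(Xi;Xj|Xk,Xl) is first averaged
#' over all fourth columns l for a given third column k, then over all
#' third columns k, removing quaternary indirect coupling. By default both
#' conditioning columns are drawn from outside the pair (l not in
#' \{i, j, k\}); the alternative reading that lets l range over the pair
#' members only adds zero-valued terms, i.e. rescales every score by
#' (L-3)/(L-1) and leaves all rankings unchanged.
#'
#' @param aln An [encoded_alignment()].
#' @param x4_set \code{"exclude_pair"} (default) or \code{"include_pair"}.
#' @return A [covariation_map()] with method \code{"4D_MI"}.
#' @export
build_map_4d <- function(aln, x4_set = c("exclude_pair", "include_pair")) {
  stopifnot(inherits(aln, "encoded_alignment"))
  x4_set <- match.arg(x4_set)
  L <- ncol(aln$matrix)
  if (L < 4L) stop("input error: need L >= 4")
  scores <- cpp_map_4d(aln$matrix, length(aln$alphabet))
  if (x4_set == "include_pair")
    scores <- scores * (L - 3) / (L - 1)
  covariation_map(scores, method = "4D_MI")
}

#' Build a covariation map by method name
#'
#' @param aln An [encoded_alignment()].
#' @param method \code{"2d"}, \code{"3d"} or \code{"4d"}.
#' @param ... Passed to the specific builder.
#' @return A [covariation_map()].
#' @export
build_map <- function(aln, method = c("2d", "3d", "4d"), ...) {
  switch(match.arg(method),
         "2d" = build_map_2d(aln),
         "3d" = build_map_3d(aln),
         "4d" = build_map_4d(aln, ...))
}
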