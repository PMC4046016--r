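#' Build a contact map from a PDB structure
#'
#' Residue centroids are the unweighted mean of the heavy-atom coordinates
#' of the whole residue (side chain included). Two alignment columns are in
#' contact when the centroids of their mapped residues lie closer than the
#' cutoff. Columns without a mapped residue, or mapped to residues missing
#' from the coordinates, get the sentinel \code{NA}.
#'
#' @param pdb PDB file path.
#' @param chain Chain identifier.
#' @param colmap A \code{colstruct_map} from [map_columns_to_structure()].
#' @param cutoff Contact cutoff in Angstrom (default 8).
#' @param mode Centroid definition: \code{"heavy"} (all heavy atoms,
#'   default) or \code{"CB"} (beta carbon; CA for glycine).
#' @return A \code{contact_map}: list with \code{distances} and
#'   \code{contacts} (L x L matrices) and \code{cutoff}.
#' @export
contact_map_from_pdb <- function(pdb, chain, colmap, cutoff = 8,
                                 mode = c("heavy", "CB")) {
  mode <- match.arg(mode)
  L <- attr(colmap, "L")
  cent <- residue_centroids(read_pdb(pdb)$atoms, chain, mode)
  idx <- match(colmap$residue, cent$resseq)
  if (anyNA(idx))
    warning(sum(is.na(idx)),
            " mapped residue(s) missing from coordinates; set to NA")
  xyz <- matrix(NA_real_, nrow = L, ncol = 3L)
  xyz[colmap$column, ] <- as.matrix(cent[idx, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  dimnames(d) <- NULL
  diag(d) <- NA_real_
  contact_map(d, cutoff)
}

#' Construct a contact map from a distance matrix
#'
#' @param distances Symmetric L x L centroid distance matrix in Angstrom
#'   (NA for unmapped columns; diagonal NA).
#' @param cutoff Contact cutoff in Angstrom.
#' @return A \code{contact_map}.
#' @export
contact_map <- function(distances, cutoff = 8) {
  distances <- as.matrix(distances)
  stopifnot(nrow(distances) == ncol(distances))
  diag(distances) <- NA_real_
  structure(list(distances = distances,
                 contacts = distances < cutoff,
                 cutoff = cutoff),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: L = %d, cutoff = %g A, %d contacts\n",
              nrow(x$distances), x$cutoff,
              sum(x$contacts[upper.tri(x$contacts)], na.rm = TRUE)))
  invisible(x)
}

# all eligible (i < j) pairs of a map under a sequence-separation filter:
# strict keeps |j - i| > min_sep, non-strict |j - i| >= min_sep
eligible_pairs <- function(L, min_sep = 0L, strict = TRUE) {
  ij <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  sep <- ij[, 2L] - ij[, 1L]
  keep <- if (strict) sep > min_sep else sep >= min_sep
  ij[keep, , drop = FALSE]
}

#' Top-scoring residue pairs under a sequence-separation filter
#'
#' Returns the n highest-scoring unordered pairs with |j - i| > min_sep
#' (strict, i.e. at least \code{min_sep} intervening positions). Ties are
#' broken by (i, j) lexicographic order, so the ranking is deterministic.
#'
#' @param map A [covariation_map()].
#' @param n Number of pairs to keep (the contact-prediction budget,
#'   typically L).
#' @param min_sep Minimum sequence separation (see \code{strict}).
#' @param strict If TRUE (default) require |j - i| > min_sep; if FALSE
#'   require |j - i| >= min_sep.
#' @return A \code{ranked_pairs} data.frame (i, j, score) in descending
#'   score order, with attributes \code{n}, \code{min_sep}, \code{strict}
#'   and \code{L}.
#' @export
top_pairs <- function(map, n, min_sep = 0L, strict = TRUE) {
  stopifnot(inherits(map, "covariation_map"), n >= 1L)
  L <- map_size(map)
  ij <- eligible_pairs(L, min_sep, strict)
  sc <- map$scores[ij]
  ok <- !is.na(sc)
  ij <- ij[ok, , drop = FALSE]
  sc <- sc[ok]
  if (nrow(ij) < n)
    warning("only ", nrow(ij), " eligible pairs (requested ", n, ")")
  ord <- order(-sc, ij[, 1L], ij[, 2L])
  take <- head(ord, n)
  out <- data.frame(i = ij[take, 1L], j = ij[take, 2L], score = sc[take])
  attr(out, "n") <- as.integer(n)
  attr(out, "min_sep") <- as.integer(min_sep)
  attr(out, "strict") <- strict
  attr(out, "L") <- L
  class(out) <- c("ranked_pairs", "data.frame")
  out
}

#' Cumulative true-contact curve over a ranked pair list
#'
#' curve[k] = 100 x (true contacts among the first k ranked pairs) /
#' (total contact pairs passing the same sequence-separation filter).
#' Columns unmapped to the structure are excluded from both numerator and
#' denominator.
#'
#' @param ranked A \code{ranked_pairs} list from [top_pairs()].
#' @param contacts A \code{contact_map} of the same L.
#' @return Numeric vector (percent), one value per ranked pair, with
#'   attribute \code{total_contacts}.
#' @export
tp_curve <- function(ranked, contacts) {
  stopifnot(inherits(ranked, "ranked_pairs"), inherits(contacts, "contact_map"))
  L <- nrow(contacts$distances)
  ij <- eligible_pairs(L, attr(ranked, "min_sep"), attr(ranked, "strict"))
  total <- sum(contacts$contacts[ij], na.rm = TRUE)
  if (total == 0L)
    stop("input error: no contact pairs pass the separation filter")
  hit <- contacts$contacts[cbind(ranked$i, ranked$j)]
  hit[is.na(hit)] <- FALSE
  curve <- 100 * cumsum(hit) / total
  attr(curve, "total_contacts") <- total
  curve
}

pair_keys <- function(ranked, L) (ranked$i - 1L) * L + ranked$j

#' Percentage of top pairs shared by two ranked lists
#'
#' @param a,b \code{ranked_pairs} built with the same n and filter.
#' @return 100 x |pairs(a) intersect pairs(b)| / n.
#' @export
overlap_percentage <- function(a, b) {
  stopifnot(inherits(a, "ranked_pairs"), inherits(b, "ranked_pairs"))
  if (!identical(attr(a, "n"), attr(b, "n")) ||
      !identical(attr(a, "min_sep"), attr(b, "min_sep")))
    stop("argument error: lists built with different n or min_sep")
  L <- max(attr(a, "L"), attr(b, "L"))
  100 * length(intersect(pair_keys(a, L), pair_keys(b, L))) / attr(a, "n")
}

#' Method-overlap matrix for a set of covariation maps
#'
#' Pairwise [overlap_percentage()] of the top-n pair sets of every map,
#' as a symmetric method x method percent matrix (diagonal 100). When
#' \code{maps} is a list of per-family map lists, per-family matrices are
#' averaged entrywise.
#'
#' @param maps Named list of [covariation_map()]s, or a list of such lists
#'   (one per protein family).
#' @param n Pairs per list (typically L).
#' @param min_sep Sequence-separation filter passed to [top_pairs()].
#' @param strict Filter strictness, see [top_pairs()].
#' @return Numeric matrix of percentages with method dimnames.
#' @export
overlap_matrix <- function(maps, n, min_sep = 0L, strict = TRUE) {
  stopifnot(length(maps) >= 1L)
  if (inherits(maps[[1]], "covariation_map")) {
    families <- list(maps)
  } else {
    families <- maps
  }
  per_family <- lapply(families, function(fam) {
    ranked <- lapply(fam, top_pairs, n = n, min_sep = min_sep,
                     strict = strict)
    m <- length(ranked)
    out <- matrix(100, m, m)
    if (m > 1L)
      for (a in seq_len(m - 1L))
        for (b in seq(a + 1L, m))
          out[a, b] <- out[b, a] <- overlap_percentage(ranked[[a]],
                                                       ranked[[b]])
    out
  })
  avg <- Reduce(`+`, per_family) / length(per_family)
  methods <- names(families[[1]])
  if (is.null(methods))
    methods <- vapply(families[[1]], function(m) m$method, "")
  dimnames(avg) <- list(methods, methods)
  avg
}
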