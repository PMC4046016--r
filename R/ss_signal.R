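#' Secondary-structure elements in alignment-column coordinates
#'
#' Converts the HELIX/SHEET records of a PDB header into alignment-column
#' intervals via the column-structure map. Residues at either end of an
#' element that do not map to an alignment column are truncated away;
#' elements shorter than 2 mapped columns are dropped.
#'
#' @param pdb PDB file path.
#' @param colmap A \code{colstruct_map} from [map_columns_to_structure()].
#' @return An \code{ss_annotation} data.frame: type ("helix"/"strand"),
#'   start, end (alignment columns, 1-based).
#' @export
ss_from_pdb_header <- function(pdb, colmap) {
  ss <- read_pdb(pdb)$ss
  ss <- ss[ss$chain == attr(colmap, "chain"), , drop = FALSE]
  if (nrow(ss) == 0L)
    warning("no HELIX/SHEET records for chain ", attr(colmap, "chain"))
  rows <- lapply(seq_len(nrow(ss)), function(r) {
    resids <- seq(ss$start[r], ss$end[r])
    cols <- residue_to_column(colmap, resids)
    cols <- cols[!is.na(cols)]
    if (length(cols) < 2L) return(NULL)
    data.frame(type = ss$type[r], start = min(cols), end = max(cols))
  })
  out <- do.call(rbind, c(rows, list(data.frame(type = character(),
                                                start = integer(),
                                                end = integer()))))
  class(out) <- c("ss_annotation", "data.frame")
  out
}

#' Distance-dependent covariation signal within one element
#'
#' For an element of length n spanning columns start..end, builds the
#' (n-1) x (n-1) staggered score matrix whose r-th row holds the scores
#' C[r, r+1], C[r, r+2], ..., C[r, n] (all other cells 0), and returns for
#' every sequence distance d = 1..n-1 the mean of the non-zero entries of
#' column d. Distances where all entries are zero (or NA) are reported as
#' missing.
#'
#' @param map A [covariation_map()].
#' @param element One row of an \code{ss_annotation} (or any list with
#'   \code{start} and \code{end} columns).
#' @return data.frame: distance, score (NA when missing), n_values.
#' @export
distance_signal <- function(map, element) {
  stopifnot(inherits(map, "covariation_map"))
  start <- as.integer(element$start)
  end <- as.integer(element$end)
  n <- end - start + 1L
  if (n < 2L) stop("input error: element must span at least 2 columns")
  cols <- seq(start, end)
  sub <- map$scores[cols, cols, drop = FALSE]
  out <- data.frame(distance = seq_len(n - 1L), score = NA_real_,
                    n_values = 0L)
  for (d in seq_len(n - 1L)) {
    vals <- sub[cbind(seq_len(n - d), seq_len(n - d) + d)]
    vals <- vals[!is.na(vals) & vals != 0]
    out$n_values[d] <- length(vals)
    if (length(vals)) out$score[d] <- mean(vals)
  }
  out
}

# min-max rescale of the off-diagonal scores to [0, 1]
normalize_map <- function(map, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  s <- map$scores
  v <- offdiag_values(s)
  out <- if (method == "minmax") {
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0) s * 0 else (s - rng[1]) / diff(rng)
  } else {
    (s - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
  }
  diag(out) <- NA_real_
  covariation_map(out, method = map$method,
                  corrections = map$corrections)
}

#' Aggregate distance signal over elements and families
#'
#' Each family's map is min-max normalized to [0, 1] over its off-diagonal
#' entries so score scales are commensurable, then [distance_signal()] is
#' computed for every element of the requested type and averaged per
#' sequence distance across all elements of all families (missing
#' distances ignored).
#'
#' @param maps List of per-family [covariation_map()]s.
#' @param annotations List of per-family \code{ss_annotation}s (matched to
#'   \code{maps}).
#' @param type \code{"helix"} or \code{"strand"}.
#' @param normalize Normalization applied per map before averaging.
#' @return data.frame: distance, score, n_elements.
#' @export
aggregate_signal <- function(maps, annotations, type = c("helix", "strand"),
                             normalize = c("minmax", "zscore")) {
  type <- match.arg(type)
  stopifnot(length(maps) == length(annotations))
  signals <- list()
  for (f in seq_along(maps)) {
    nm <- normalize_map(maps[[f]], match.arg(normalize))
    ann <- annotations[[f]]
    ann <- ann[ann$type == type, , drop = FALSE]
    for (r in seq_len(nrow(ann)))
      signals[[length(signals) + 1L]] <- distance_signal(nm, ann[r, ])
  }
  if (length(signals) == 0L)
    stop("input error: no elements of type '", type, "'")
  all_d <- sort(unique(unlist(lapply(signals, `[[`, "distance"))))
  out <- data.frame(distance = all_d, score = NA_real_, n_elements = 0L)
  for (q in seq_along(all_d)) {
    vals <- unlist(lapply(signals, function(s) {
      v <- s$score[s$distance == all_d[q]]
      v[!is.na(v)]
    }))
    out$n_elements[q] <- length(vals)
    if (length(vals)) out$score[q] <- mean(vals)
  }
  out
}
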