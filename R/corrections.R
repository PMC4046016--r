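#' Average product correction (APC)
#'
#' Subtracts from every off-diagonal score the product of its row means
#' divided by the grand mean: out[i,j] = s[i,j] - mean_i * mean_j /
#' mean_all, where mean_i is the mean off-diagonal score of row i. This is
#' the standard correction for the entropic and phylogenetic bias of MI
#' statistics; it leaves the diagonal sentinel untouched.
#'
#' @param map A [covariation_map()].
#' @return Corrected map with \code{"APC"} appended to its corrections.
#' @export
apc_correct <- function(map) {
  stopifnot(inherits(map, "covariation_map"))
  s <- map$scores
  if (nrow(s) < 3L) stop("input error: APC needs L >= 3")
  mean_all <- mean(offdiag_values(s), na.rm = TRUE)
  if (!is.finite(mean_all) || mean_all == 0) {
    warning("degenerate all-zero map: APC skipped")
    return(map)
  }
  row_means <- rowMeans(s, na.rm = TRUE)
  out <- s - outer(row_means, row_means) / mean_all
  diag(out) <- NA_real_
  covariation_map(out, method = map$method,
                  corrections = c(map$corrections, "APC"))
}

#' ZPX2 correction (double z-score product)
#'
#' Each score is standardized twice, against the off-diagonal statistics of
#' its row and of its column: z_i(j) = (s[i,j] - mu_i) / sigma_i and
#' z_j(i) likewise. The corrected score is the product z_i(j) * z_j(i),
#' with the sign forced negative when both z-scores are negative so that
#' "below both row means" reads as anticovariation. Rows with zero variance
#' contribute zero z-scores (with a warning).
#'
#' @param map A [covariation_map()].
#' @return Corrected map with \code{"ZPX2"} appended to its corrections.
#' @export
zpx2_correct <- function(map) {
  stopifnot(inherits(map, "covariation_map"))
  s <- map$scores
  mu <- rowMeans(s, na.rm = TRUE)
  sigma <- apply(s, 1L, sd, na.rm = TRUE)  # sample sd over row off-diagonals
  if (any(!is.finite(sigma) | sigma == 0)) {
    warning("zero-variance row(s): their z-scores set to 0")
    sigma[!is.finite(sigma) | sigma == 0] <- Inf
  }
  z <- (s - mu) / sigma                     # z[i, j] = z_i(j)
  out <- z * t(z)
  both_neg <- (z < 0) & (t(z) < 0)
  out[which(both_neg)] <- -out[which(both_neg)]
  diag(out) <- NA_real_
  covariation_map(out, method = map$method,
                  corrections = c(map$corrections, "ZPX2"))
}

#' Standard correction pipeline: APC then ZPX2
#'
#' Applies APC unless the map's correction history already records it, then
#' ZPX2 — the post-processing applied uniformly to every covariation map
#' before structural evaluation (external maps from methods that carry
#' their own APC skip straight to ZPX2).
#'
#' @param map A [covariation_map()].
#' @return Map with corrections ending in \code{c("APC", "ZPX2")}.
#' @export
standard_pipeline <- function(map) {
  stopifnot(inherits(map, "covariation_map"))
  if (!"APC" %in% map$corrections)
    map <- apc_correct(map)
  zpx2_correct(map)
}
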