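#' Construct a covariation map
#'
#' A symmetric L x L score matrix with a method tag and an append-only
#' record of the corrections applied to it. Diagonal entries carry the
#' sentinel \code{NA} (not 0) so self-scores never enter row statistics.
#'
#' @param scores Symmetric numeric matrix.
#' @param method One of \code{"2D_MI"}, \code{"3D_MI"}, \code{"4D_MI"},
#'   \code{"external"}, or any method label for externally computed maps.
#' @param corrections Character vector of corrections already applied.
#' @return An object of class \code{covariation_map}.
#' @export
covariation_map <- function(scores, method = "external",
                            corrections = character()) {
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores))
    stop("covariation map must be square")
  probe <- scores
  diag(probe) <- 0
  if (!isTRUE(all.equal(probe, t(probe), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("covariation map must be symmetric")
  diag(scores) <- NA_real_
  dimnames(scores) <- NULL
  if (anyDuplicated(corrections))
    stop("corrections list must be duplicate-free")
  structure(list(scores = scores, method = method,
                 corrections = as.character(corrections)),
            class = "covariation_map")
}

#' @export
print.covariation_map <- function(x, ...) {
  cat(sprintf("covariation_map: %s, L = %d, corrections: %s\n",
              x$method, nrow(x$scores),
              if (length(x$corrections)) paste(x$corrections, collapse = " -> ")
              else "none"))
  invisible(x)
}

#' @export
dim.covariation_map <- function(x) dim(x$scores)

map_size <- function(map) nrow(map$scores)

offdiag_values <- function(scores) scores[row(scores) != col(scores)]

#' Write a covariation map as TSV
#'
#' Full L x L matrix preceded by a single `#` header line recording the
#' method and correction history, so the file can be read back as an
#' external map without losing provenance.
#'
#' @param map A \code{covariation_map}.
#' @param path Output path (written atomically).
#' @return Invisibly, \code{path}.
#' @export
write_map <- function(map, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tsv")
  header <- sprintf("# mdmi method=%s corrections=%s L=%d",
                    map$method,
                    if (length(map$corrections))
                      paste(map$corrections, collapse = ",") else "none",
                    map_size(map))
  writeLines(header, tmp)
  suppressWarnings(write.table(map$scores, tmp, append = TRUE, sep = "\t",
                               row.names = FALSE, col.names = FALSE))
  file.rename(tmp, path)
  invisible(path)
}

#' Read a covariation map from a plain numeric matrix file
#'
#' Accepts the TSV written by [write_map()] (whose `#` header restores the
#' method and corrections) or any whitespace/comma-separated square numeric
#' matrix exported by third-party covariation tools.
#'
#' @param path File path.
#' @param method Method label used when the file carries no mdmi header.
#' @param corrections Corrections assumed already applied when the file
#'   carries no mdmi header (e.g. `"APC"` for plmDCA/GREMLIN exports).
#' @return A \code{covariation_map}.
#' @export
read_map <- function(path, method = "external", corrections = character()) {
  if (!file.exists(path))
    stop("input error: file not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "# mdmi")) {
    fields <- regmatches(first, gregexpr("[a-zA-Z0-9_]+=[^ ]+", first))[[1]]
    kv <- strsplit(fields, "=", fixed = TRUE)
    vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    method <- vals[["method"]]
    corrections <- if (identical(vals[["corrections"]], "none")) character()
                   else strsplit(vals[["corrections"]], ",")[[1]]
  }
  m <- as.matrix(read.table(path, comment.char = "#",
                            sep = "", header = FALSE))
  if (nrow(m) != ncol(m))
    stop("input error: matrix in ", path, " is not square")
  dimnames(m) <- NULL
  covariation_map(m, method = method, corrections = corrections)
}
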