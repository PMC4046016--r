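# Minimal fixed-width PDB reader: coordinates of the first model plus the
# HELIX/SHEET header records. Only what the structural evaluation needs —
# no mmCIF, no multi-model ensembles, altloc A only.

pdb_field <- function(lines, from, to) substr(lines, from, to)

#' Read coordinates and secondary-structure records from a PDB file
#'
#' Parses ATOM records of the first model (altloc blank or "A") and the
#' HELIX/SHEET header records. Hydrogens and deuteriums are dropped.
#'
#' @param path PDB file path.
#' @return List with \code{atoms} (data.frame: name, resname, chain,
#'   resseq, x, y, z) and \code{ss} (data.frame: type, chain, start, end in
#'   residue numbers).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path))
    stop("input error: file not found: ", path)
  lines <- readLines(path)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  coord_lines <- if (length(endmdl)) lines[seq_len(endmdl[1] - 1L)] else lines

  at <- coord_lines[startsWith(coord_lines, "ATOM")]
  if (length(at)) {
    altloc <- pdb_field(at, 17, 17)
    at <- at[altloc %in% c(" ", "", "A")]
  }
  name <- trimws(pdb_field(at, 13, 16))
  element <- trimws(pdb_field(at, 77, 78))
  # infer element from the atom name when the element field is absent
  guess <- toupper(substr(gsub("[0-9']", "", name), 1, 1))
  element <- ifelse(element == "", guess, toupper(element))
  keep <- !(element %in% c("H", "D"))
  atoms <- data.frame(
    name = name[keep],
    resname = trimws(pdb_field(at, 18, 20))[keep],
    chain = pdb_field(at, 22, 22)[keep],
    resseq = as.integer(pdb_field(at, 23, 26))[keep],
    x = as.numeric(pdb_field(at, 31, 38))[keep],
    y = as.numeric(pdb_field(at, 39, 46))[keep],
    z = as.numeric(pdb_field(at, 47, 54))[keep])

  hx <- lines[startsWith(lines, "HELIX")]
  sh <- lines[startsWith(lines, "SHEET")]
  ss <- rbind(
    if (length(hx)) data.frame(
      type = "helix",
      chain = pdb_field(hx, 20, 20),
      start = as.integer(pdb_field(hx, 22, 25)),
      end = as.integer(pdb_field(hx, 34, 37))),
    if (length(sh)) data.frame(
      type = "strand",
      chain = pdb_field(sh, 22, 22),
      start = as.integer(pdb_field(sh, 23, 26)),
      end = as.integer(pdb_field(sh, 34, 37))))
  if (is.null(ss))
    ss <- data.frame(type = character(), chain = character(),
                     start = integer(), end = integer())
  list(atoms = atoms, ss = ss)
}

# per-residue centroids for one chain: unweighted mean of heavy-atom
# coordinates (side chain included); optionally CB only (CA for GLY)
residue_centroids <- function(atoms, chain, mode = c("heavy", "CB")) {
  mode <- match.arg(mode)
  a <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L)
    stop("input error: chain '", chain, "' not found in structure")
  if (mode == "CB") {
    cb <- a[a$name == "CB" | (a$name == "CA" & a$resname == "GLY"), ,
            drop = FALSE]
    cb <- cb[!duplicated(cb$resseq), , drop = FALSE]
    a <- cb
  }
  xs <- tapply(a$x, a$resseq, mean)
  ys <- tapply(a$y, a$resseq, mean)
  zs <- tapply(a$z, a$resseq, mean)
  data.frame(resseq = as.integer(names(xs)),
             x = as.numeric(xs), y = as.numeric(ys), z = as.numeric(zs))
}
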