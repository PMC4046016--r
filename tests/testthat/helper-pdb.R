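# Synthetic toy PDB fixture, built in code (plain text, strict fixed-width
# columns). Chain A: 8 two-atom ALA residues 10..17 whose centroids sit on
# the x axis at 0, 3, 6, ..., 21 A (atoms offset +/-1 A about the
# centroid), plus a hydrogen and an altloc-B atom that parsers must skip.
# Chain C: two single-atom residues at (0,0,0) and (3,4,0), 5 A apart.
# Header: two helices (11-15, 16-17) and two strands (10-11 and the
# degenerate single-residue 17-17). An ENDMDL followed by a garbage second
# model checks first-model-only reading.

atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                      element, altloc = " ") {
  sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", name), altloc, resname, chain, resseq,
          " ", x, y, z, 1, 0, element)
}

helix_line <- function(ser, chain, start, end) {
  sprintf("HELIX  %3d %3s ALA %1s %4d  ALA %1s %4d  1%30s%6d",
          ser, sprintf("H%d", ser), chain, start, chain, end, "",
          end - start + 1)
}

sheet_line <- function(ser, chain, start, end) {
  sprintf("SHEET  %3d %3s 1 ALA %1s%4d  ALA %1s%4d  0",
          ser, sprintf("S%d", ser), chain, start, chain, end)
}

write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "HEADER    TOY STRUCTURE",
    helix_line(1, "A", 11, 15),
    helix_line(2, "A", 16, 17),
    sheet_line(1, "A", 10, 11),
    sheet_line(2, "A", 17, 17))
  serial <- 0L
  nxt <- function() { serial <<- serial + 1L; serial }
  for (r in 0:7) {
    lines <- c(lines,
      atom_line(nxt(), "CA", "ALA", "A", 10L + r, 3 * r - 1, 0, 0, "C"),
      atom_line(nxt(), "CB", "ALA", "A", 10L + r, 3 * r + 1, 0, 0, "C"))
  }
  lines <- c(lines,
    # must be ignored: hydrogen, altloc B
    atom_line(nxt(), "HA", "ALA", "A", 10L, 500, 0, 0, "H"),
    atom_line(nxt(), "CG", "ALA", "A", 11L, 500, 0, 0, "C", altloc = "B"),
    # chain C: 3-4-5 triangle pair
    atom_line(nxt(), "CA", "GLY", "C", 1L, 0, 0, 0, "C"),
    atom_line(nxt(), "CA", "GLY", "C", 2L, 3, 4, 0, "C"),
    "ENDMDL",
    atom_line(nxt(), "CA", "ALA", "A", 10L, 999, 999, 999, "C"),
    "END")
  writeLines(lines, path)
  path
}

# alignment whose row 1 maps 1:1 onto chain A residues 10..17 (L = 8)
toy_aln_for_pdb <- function(seed = 42) {
  set.seed(seed)
  mat <- matrix(sample.int(20L, 4 * 8, replace = TRUE), 4, 8)
  encoded_alignment(mat)
}

toy_colmap <- function(aln = toy_aln_for_pdb()) {
  map_columns_to_structure(aln, 1L, 10:17, chain = "A")
}
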