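# Shared fixtures, built in code at test time.

# Minimal PDB text: one CA pseudo-atom per residue at the given coordinates.
pdb_lines <- function(xyz, resno = seq_len(nrow(xyz)), chain = "A",
                      record = "ATOM  ") {
  vapply(seq_len(nrow(xyz)), function(i) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            trimws(record), i, " CA", " ", "GLY", chain, resno[i], " ",
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, "C")
  }, character(1))
}

# A structure model built directly (exact coordinates, no PDB 3-decimal
# rounding) for numerical invariance checks.
model_from_xyz <- function(xyz, resno = seq_len(nrow(xyz)), chain = "A") {
  atoms <- data.frame(chain = chain, resno = resno, resid = "GLY",
                      elety = "CA", element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occupancy = 1, stringsAsFactors = FALSE)
  structure(list(atoms = atoms,
                 residues = unique(atoms[, c("chain", "resno", "resid")])),
            class = "structure_model")
}

random_rotation <- function() {
  qr_out <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
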