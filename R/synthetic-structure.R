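#' Synthetic protein structure with planted triad shell geometry
#'
#' Emits a toy single-chain structure (one C-alpha pseudo-atom per residue)
#' in which residues 1-3 form the designated catalytic triad and every
#' remaining residue is planted at a controlled minimal distance from the
#' triad so that each distance shell contains exactly the requested number
#' of residues. Planted residues lie along random directions in the octant
#' opposite the two non-origin triad atoms, which guarantees the nearest
#' triad atom is the one at the origin and makes the planted distance the
#' true minimal distance.
#'
#' @param n_residues total residue count; must equal
#'   `3 + sum(shell_counts)`
#' @param shell_counts named integer vector with (a subset of) names
#'   `first`, `second`, `third`, `beyond`: residues to plant in each band
#'   (&lt;4, 4-8, 8-12, &gt;=12 Angstrom)
#' @param seed integer seed for the random directions and distances
#' @return list of class `toy_structure`: `pdb` (character vector of PDB
#'   lines), `residues` (data frame `resno`, `planted_distance`, `shell`),
#'   `triad` (data frame `chain`, `resno`)
#' @examples
#' ts <- toy_structure(10, c(second = 5, beyond = 2), seed = 1)
#' @export
toy_structure <- function(n_residues, shell_counts, seed = 1) {
  bands <- list(first = c(1.0, 3.8), second = c(4.2, 7.8),
                third = c(8.2, 11.8), beyond = c(12.5, 19.5))
  bad <- setdiff(names(shell_counts), names(bands))
  if (length(bad)) stop("unknown shell name(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  shell_counts <- shell_counts[shell_counts > 0]
  n_plant <- sum(shell_counts)
  if (n_residues != 3 + n_plant) {
    stop(sprintf(paste0("infeasible geometry: n_residues (%d) must equal ",
                        "3 triad residues + sum(shell_counts) (%d)"),
                 n_residues, 3 + n_plant), call. = FALSE)
  }

  withr::with_seed(seed, {
    # triad: origin atom plus two neighbours along +x / +y
    xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0))
    res <- data.frame(resno = integer(0), planted_distance = numeric(0),
                      shell = character(0), stringsAsFactors = FALSE)
    resno <- 4L
    for (sh in names(shell_counts)) {
      for (i in seq_len(shell_counts[[sh]])) {
        d <- stats::runif(1, bands[[sh]][1], bands[[sh]][2])
        u <- -abs(stats::rnorm(3))
        u <- u / sqrt(sum(u^2))
        xyz <- rbind(xyz, d * u)
        res <- rbind(res, data.frame(resno = resno, planted_distance = d,
                                     shell = sh, stringsAsFactors = FALSE))
        resno <- resno + 1L
      }
    }
    pdb <- c(
      "HEADER    SYNTHETIC TOY STRUCTURE",
      "REMARK    Synthetic fixture with planted triad shell geometry",
      vapply(seq_len(nrow(xyz)), function(i) {
        sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                i, " CA", " ", "GLY", "A", i, " ",
                xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, "C")
      }, character(1)),
      "END")
    structure(list(pdb = pdb, residues = res,
                   triad = data.frame(chain = "A", resno = 1:3,
                                      stringsAsFactors = FALSE)),
              class = "toy_structure")
  })
}

#' Write a toy structure (or raw PDB lines) to a PDB file
#'
#' @param x a `toy_structure` or a character vector of PDB lines
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_pdb <- function(x, path) {
  lines <- if (inherits(x, "toy_structure")) x$pdb else as.character(x)
  writeLines(lines, path)
  invisible(path)
}
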