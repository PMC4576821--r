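#' Parse a PDB structure into a structure model
#'
#' Thin wrapper around [bio3d::read.pdb()] with the validation this
#' pipeline needs: the input must contain ATOM records (HETATM-only files
#' are rejected), malformed coordinate fields are reported with their line
#' number, heteroatoms and waters are excluded by default, and where
#' alternate locations exist only the highest-occupancy copy of each atom
#' is kept.
#'
#' @param x path to a PDB file, or a character vector of PDB lines
#' @param keep_hetatm keep HETATM records (default FALSE)
#' @return object of class `structure_model`: list with `atoms` (data
#'   frame `chain`, `resno`, `resid`, `elety`, `element`, `x`, `y`, `z`,
#'   `occupancy`) and `residues` (data frame `chain`, `resno`, `resid`);
#'   raw SITE header records, if any, are attached as attribute `"site"`.
#' @export
parse_structure <- function(x, keep_hetatm = FALSE) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(x), "\n", fixed = TRUE))
  }
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "ATOM ")
  is_het <- startsWith(lines, "HETATM")
  if (!any(is_atom)) {
    stop(if (any(is_het)) "no ATOM records (HETATM only)" else
      "no ATOM records found", call. = FALSE)
  }
  for (i in which(is_atom | is_het)) {
    coords <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                            substr(lines[i], 39, 46),
                                            substr(lines[i], 47, 54))))
    if (any(is.na(coords)) || any(!is.finite(coords))) {
      stop(sprintf("malformed coordinates at line %d: %s", i,
                   trimws(lines[i])), call. = FALSE)
    }
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- pdb$atom
  keep <- at$type == "ATOM" | (keep_hetatm & at$type == "HETATM")
  keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no usable ATOM records after filtering",
                          call. = FALSE)
  # altloc: keep the highest-occupancy copy of each atom
  at$occ <- ifelse(is.na(at$o), 1, at$o)
  at <- at[order(at$chain, at$resno, at$elety, -at$occ), , drop = FALSE]
  dup <- duplicated(at[, c("chain", "resno", "insert", "elety")])
  at <- at[!dup, , drop = FALSE]
  at <- at[order(at$chain, at$resno, at$eleno), , drop = FALSE]

  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety,
                      element = toupper(trimws(ifelse(is.na(at$elesy) |
                                                        at$elesy == "",
                                                      substr(trimws(at$elety), 1, 1),
                                                      at$elesy))),
                      x = at$x, y = at$y, z = at$z, occupancy = at$occ,
                      stringsAsFactors = FALSE)
  residues <- unique(atoms[, c("chain", "resno", "resid")])
  rownames(atoms) <- rownames(residues) <- NULL
  structure(list(atoms = atoms, residues = residues),
            site = lines[startsWith(lines, "SITE")],
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d residues, %d atoms, chains %s\n",
              nrow(x$residues), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Define the catalytic triad
#'
#' @param x residue specification: a character vector like
#'   `c("A:46", "A:81", "A:151")`, or a data frame with columns `chain`
#'   and `resno`
#' @param model optional [parse_structure()] model; when given, membership
#'   is checked and missing residues raise an error. When `x` is `NULL`
#'   the triad is extracted from the model's PDB SITE records (first site),
#'   and an error is raised if there are none.
#' @return data frame of class `triad_definition` with columns `chain`,
#'   `resno`
#' @export
triad_definition <- function(x = NULL, model = NULL) {
  if (is.null(x)) {
    if (is.null(model)) stop("need either residues or a model with SITE records",
                             call. = FALSE)
    site <- attr(model, "site")
    if (is.null(site) || length(site) == 0) {
      stop("no triad given and the PDB header has no SITE records; ",
           "specify the triad explicitly", call. = FALSE)
    }
    m <- gregexpr("[A-Z]{3} +[A-Za-z0-9] +-?[0-9]+", site)
    hits <- unlist(regmatches(site, m))
    if (length(hits) == 0) stop("could not parse SITE records", call. = FALSE)
    parts <- strsplit(hits, " +")
    td <- unique(data.frame(chain = vapply(parts, `[`, character(1), 2),
                            resno = as.integer(vapply(parts, `[`,
                                                      character(1), 3)),
                            stringsAsFactors = FALSE))
  } else if (is.character(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      stop("triad strings must look like \"A:151\"", call. = FALSE)
    }
    td <- data.frame(chain = vapply(parts, `[`, character(1), 1),
                     resno = as.integer(vapply(parts, `[`, character(1), 2)),
                     stringsAsFactors = FALSE)
  } else if (is.data.frame(x) && all(c("chain", "resno") %in% names(x))) {
    td <- data.frame(chain = as.character(x$chain),
                     resno = as.integer(x$resno), stringsAsFactors = FALSE)
  } else {
    stop("cannot interpret triad specification", call. = FALSE)
  }
  if (nrow(td) == 0) stop("triad must be non-empty", call. = FALSE)
  if (!is.null(model)) {
    key <- paste(model$residues$chain, model$residues$resno)
    missing <- !(paste(td$chain, td$resno) %in% key)
    if (any(missing)) {
      stop("triad residue(s) absent from structure: ",
           paste(td$chain[missing], td$resno[missing], sep = ":",
                 collapse = ", "), call. = FALSE)
    }
  }
  class(td) <- c("triad_definition", "data.frame")
  td
}

heavy_atoms <- function(model, chain, resno) {
  a <- model$atoms
  a[a$chain == chain & a$resno == resno & a$element != "H", , drop = FALSE]
}

#' Minimal heavy-atom distance from a residue to the catalytic triad
#'
#' Minimum Euclidean distance between any non-hydrogen atom of the query
#' residue and any non-hydrogen atom of any triad residue. A triad residue
#' queried against its own triad returns 0.
#'
#' @param model a [parse_structure()] model
#' @param position residue number of the query residue
#' @param triad a [triad_definition()]
#' @param chain chain of the query residue (default: first chain in the
#'   model)
#' @return distance in Angstrom
#' @export
min_distance_to_triad <- function(model, position, triad,
                                  chain = model$atoms$chain[1]) {
  qa <- heavy_atoms(model, chain, position)
  if (nrow(qa) == 0) {
    stop("residue ", chain, ":", position, " absent from structure",
         call. = FALSE)
  }
  ta <- do.call(rbind, lapply(seq_len(nrow(triad)), function(i) {
    heavy_atoms(model, triad$chain[i], triad$resno[i])
  }))
  if (is.null(ta) || nrow(ta) == 0) {
    stop("triad residues absent from structure", call. = FALSE)
  }
  q <- as.matrix(qa[, c("x", "y", "z")])
  tm <- as.matrix(ta[, c("x", "y", "z")])
  d2 <- outer(rowSums(q^2), rowSums(tm^2), "+") - 2 * q %*% t(tm)
  sqrt(max(min(d2), 0))
}

#' Assign a triad distance to a shell
#'
#' Half-open bands: first `[0, 4)`, second `[4, 8)`, third `[8, 12)`,
#' beyond `[12, Inf)` Angstrom, so every distance maps to exactly one
#' shell.
#'
#' @param d distance(s) in Angstrom, >= 0
#' @param breaks the three inner shell boundaries (default `c(4, 8, 12)`)
#' @return character vector in `{"first","second","third","beyond"}`
#' @examples
#' assign_shell(c(0, 4, 5.6, 12))
#' @export
assign_shell <- function(d, breaks = c(4, 8, 12)) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances must be finite and >= 0", call. = FALSE)
  }
  as.character(cut(d, c(0, breaks, Inf), right = FALSE,
                   labels = c("first", "second", "third", "beyond")))
}

#' Shell assignment table for all residues of a chain
#'
#' @inheritParams min_distance_to_triad
#' @param positions residue numbers to classify (default: every residue of
#'   `chain`)
#' @return data frame `position`, `min_distance_A`, `shell`
#' @export
shell_table <- function(model, triad, chain = model$atoms$chain[1],
                        positions = NULL) {
  if (is.null(positions)) {
    positions <- model$residues$resno[model$residues$chain == chain]
  }
  d <- vapply(positions, function(p) {
    min_distance_to_triad(model, p, triad, chain = chain)
  }, numeric(1))
  data.frame(position = positions, min_distance_A = d,
             shell = assign_shell(d), stringsAsFactors = FALSE)
}

#' Permutation test for shell enrichment of mutations
#'
#' Tests whether the observed number of mutated positions in a target
#' shell exceeds what uniform random placement over the eligible positions
#' would give. The null draws `n_mutations` distinct positions uniformly
#' from `eligible_positions`; the p-value is the upper-tail fraction of
#' permutations with a target-shell count at least as large as observed,
#' with the (1 + x)/(1 + n) correction. Truncation mutations are excluded
#' (only point mutations are placeable residues).
#'
#' @inheritParams min_distance_to_triad
#' @param mutations data frame with columns `position` and (optionally)
#'   `kind`; rows with `kind == "truncation"` are dropped
#' @param target_shell shell to test (default `"second"`)
#' @param eligible_positions residue numbers forming the null universe;
#'   default: all residues of `chain` except triad members. Must contain
#'   every mutated position.
#' @param n_permutations Monte-Carlo permutations (default 10000)
#' @param seed integer seed
#' @return object of class `enrichment_result`: list with
#'   `observed_count`, `n_mutations`, `shell_sizes`, `p_value`,
#'   `n_permutations`, `seed`, `target_shell`, `null_model`
#' @export
shell_enrichment <- function(model, triad, mutations, target_shell = "second",
                             chain = model$atoms$chain[1],
                             eligible_positions = NULL,
                             n_permutations = 10000, seed = 1) {
  if (!is.null(mutations$kind)) {
    mutations <- mutations[mutations$kind != "truncation", , drop = FALSE]
  }
  positions <- unique(as.integer(mutations$position))
  if (is.null(eligible_positions)) {
    eligible_positions <- setdiff(
      model$residues$resno[model$residues$chain == chain],
      triad$resno[triad$chain == chain])
  }
  eligible_positions <- unique(as.integer(eligible_positions))
  if (!all(positions %in% eligible_positions)) {
    stop("mutated position(s) not in the eligible set: ",
         paste(setdiff(positions, eligible_positions), collapse = ", "),
         call. = FALSE)
  }
  m <- length(positions)
  N <- length(eligible_positions)
  if (m > N) stop("more mutations than eligible positions", call. = FALSE)

  st <- shell_table(model, triad, chain = chain,
                    positions = eligible_positions)
  in_shell <- st$shell == target_shell
  observed <- sum(positions %in% st$position[in_shell])

  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      sum(in_shell[sample.int(N, m)]) >= observed
    }, logical(1)))
  })
  structure(list(observed_count = observed, n_mutations = m,
                 shell_sizes = table(st$shell),
                 p_value = (1 + exceed) / (1 + n_permutations),
                 n_permutations = n_permutations, seed = seed,
                 target_shell = target_shell,
                 null_model = paste("uniform placement of distinct mutated",
                                    "positions over the eligible set",
                                    "(chain residues minus triad)")),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("shell enrichment: %d/%d mutations in the %s shell; ",
                     "p = %.4g (%d permutations, seed %d)\n"),
              x$observed_count, x$n_mutations, x$target_shell, x$p_value,
              x$n_permutations, x$seed))
  invisible(x)
}
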