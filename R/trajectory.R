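#' Fold change between two rate constants
#'
#' Orientation-normalised ratio `max(a, b) / min(a, b)`, reported to two
#' significant figures, so that 7e3 vs 3e3 min^-1 M^-1 reads as 2.3-fold
#' regardless of argument order.
#'
#' @param a,b positive rate constants (same units)
#' @return fold difference (>= 1), two significant figures
#' @examples
#' fold_change(7e3, 3e3)  # 2.3
#' @export
fold_change <- function(a, b) {
  if (any(!is.finite(c(a, b))) || any(c(a, b) <= 0)) {
    stop("rate constants must be positive and finite", call. = FALSE)
  }
  signif(max(a, b) / min(a, b), 2)
}

#' Trade-off report for a nucleophile-revertant trajectory
#'
#' Measures how neutral the accumulated mutations are in the original
#' (cysteine) background: the per-round fold deviation of the cysteine
#' constant from its reference-round value, the maximum deviation, a
#' neutrality call against a fold threshold (default fourfold), and the
#' twin ratio — the fold difference between the two nucleophile
#' backgrounds at the final round.
#'
#' @param table a trajectory table (data frame with columns `round`,
#'   `cys_constant` and, for the twin ratio, `ser_constant`); missing
#'   constants are reported as gaps (`NA`), not errors
#' @param reference_round round used as the trade-off reference (default 0,
#'   the unevolved parent)
#' @param threshold neutrality threshold in fold (default 4)
#' @return list of class `tradeoff_report`: `per_round` (data frame
#'   `round`, `ratio`), `max_deviation`, `neutral`, `twin_ratio`,
#'   `reference_round`, `threshold`
#' @export
tradeoff_report <- function(table, reference_round = 0, threshold = 4) {
  if (!all(c("round", "cys_constant") %in% names(table))) {
    stop("table needs columns round and cys_constant", call. = FALSE)
  }
  ref_row <- table[table$round == reference_round, , drop = FALSE]
  if (nrow(ref_row) != 1 || is.na(ref_row$cys_constant)) {
    stop("reference round ", reference_round,
         " absent or lacking a cysteine constant", call. = FALSE)
  }
  ref <- ref_row$cys_constant
  ratio <- vapply(table$cys_constant, function(k) {
    if (is.na(k)) NA_real_ else fold_change(k, ref)
  }, numeric(1))
  per_round <- data.frame(round = table$round, ratio = ratio)
  max_dev <- if (all(is.na(ratio))) NA_real_ else max(ratio, na.rm = TRUE)

  last <- table[nrow(table), , drop = FALSE]
  twin <- if (!is.null(table$ser_constant) &&
              !is.na(last$ser_constant) && !is.na(last$cys_constant)) {
    fold_change(last$ser_constant, last$cys_constant)
  } else {
    NA_real_
  }
  structure(list(per_round = per_round, max_deviation = max_dev,
                 neutral = !is.na(max_dev) && max_dev <= threshold,
                 twin_ratio = twin, reference_round = reference_round,
                 threshold = threshold),
            class = "tradeoff_report")
}

#' @export
print.tradeoff_report <- function(x, ...) {
  cat(sprintf(paste0("tradeoff_report: max deviation %.3g-fold from round ",
                     "%s (threshold %g) -> %s\n"),
              x$max_deviation, x$reference_round, x$threshold,
              if (isTRUE(x$neutral)) "neutral" else "NOT neutral"))
  if (!is.na(x$twin_ratio)) {
    cat(sprintf("  endpoint twin ratio: %.3g-fold between backgrounds\n",
                x$twin_ratio))
  }
  invisible(x)
}

#' Percent identity between two protein sequences
#'
#' Identity = matching positions / alignment length x 100. For the
#' in-scope case (point mutants and truncations of a known parent)
#' positions map directly, so the default method compares position by
#' position from the N terminus and counts the unaligned C-terminal
#' overhang of the longer sequence as mismatch. `method = "global"` uses a
#' Needleman-Wunsch alignment ([Biostrings::pairwiseAlignment()]) with the
#' same overhang-as-mismatch convention, for sequence pairs that are not
#' simple mutants of one another.
#'
#' @param seq_a,seq_b protein sequences (non-empty character strings)
#' @param method `"direct"` (positional, default) or `"global"`
#' @return percent identity in `[0, 100]`
#' @examples
#' percent_identity("ACDEF", "ACDEF")   # 100
#' percent_identity("ACDEFGHIKL", "ACDEFGHIK")  # 90: overhang is mismatch
#' @export
percent_identity <- function(seq_a, seq_b, method = c("direct", "global")) {
  method <- match.arg(method)
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  if (method == "direct") {
    a <- strsplit(seq_a, "")[[1]]
    b <- strsplit(seq_b, "")[[1]]
    L <- max(length(a), length(b))
    n <- min(length(a), length(b))
    matches <- sum(a[seq_len(n)] == b[seq_len(n)])
    100 * matches / L
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    100 * sum(pat == sub & pat != "-") / length(pat)
  }
}

#' Apply a mutation list to a parent sequence
#'
#' Point mutations replace single residues after checking that the
#' recorded `from_aa` matches the parent (guarding against off-by-one
#' numbering); a `truncation` removes the residue at `position` and
#' everything C-terminal of it. Truncations are applied after all point
#' mutations.
#'
#' @param parent_seq protein sequence (character string)
#' @param mutations data frame with columns `position`, `from_aa`,
#'   `to_aa`, and optionally `kind` (`"point"` assumed when absent)
#' @return the mutated sequence
#' @examples
#' apply_mutations("AACAA", data.frame(position = 3, from_aa = "C",
#'                                     to_aa = "S", kind = "point"))
#' @export
apply_mutations <- function(parent_seq, mutations) {
  s <- strsplit(parent_seq, "")[[1]]
  if (is.null(mutations) || nrow(mutations) == 0) return(parent_seq)
  kind <- if (is.null(mutations$kind)) rep("point", nrow(mutations)) else
    mutations$kind
  pts <- mutations[kind == "point", , drop = FALSE]
  trs <- mutations[kind == "truncation", , drop = FALSE]
  for (i in seq_len(nrow(pts))) {
    pos <- as.integer(pts$position[i])
    if (pos < 1 || pos > length(s)) {
      stop("position ", pos, " outside sequence (length ", length(s), ")",
           call. = FALSE)
    }
    if (s[pos] != pts$from_aa[i]) {
      stop(sprintf("from_aa mismatch at position %d: expected %s, parent has %s",
                   pos, pts$from_aa[i], s[pos]), call. = FALSE)
    }
    if (pts$from_aa[i] == pts$to_aa[i]) {
      stop("point mutation at position ", pos, " must change the residue",
           call. = FALSE)
    }
    s[pos] <- pts$to_aa[i]
  }
  if (nrow(trs) > 0) {
    cut_at <- min(as.integer(trs$position))
    if (cut_at < 1 || cut_at > length(s)) {
      stop("truncation position ", cut_at, " outside sequence", call. = FALSE)
    }
    s <- s[seq_len(cut_at - 1L)]
  }
  paste(s, collapse = "")
}

#' Count point and total mutations in a mutation table
#'
#' Bookkeeping that distinguishes point substitutions from
#' truncation/frameshift events: both counters are reported.
#'
#' @param mutations data frame with a `kind` column
#' @return named vector `c(point = ..., truncation = ..., total = ...)`
#' @export
count_mutations <- function(mutations) {
  kind <- if (is.null(mutations$kind)) rep("point", nrow(mutations)) else
    mutations$kind
  c(point = sum(kind == "point"),
    truncation = sum(kind == "truncation"),
    total = length(kind))
}
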