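#' Read progress-curve traces from CSV
#'
#' The trace dialect has columns `variant_id, replicate, time_min, signal`
#' (header required, UTF-8); one [progress_curve()] is built per
#' (variant, replicate) pair.
#'
#' @param path CSV file path
#' @param conditions [assay_conditions()] applied to every trace
#' @return named list of `progress_curve` objects
#' @export
read_traces <- function(path, conditions = assay_conditions()) {
  if (!file.exists(path)) stop("traces file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "replicate", "time_min", "signal")
  if (!all(need %in% names(df))) {
    stop("traces CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(df[, c("variant_id", "replicate")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$variant_id == keys$variant_id[i] &
                df$replicate == keys$replicate[i], , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    progress_curve(sub$time_min, sub$signal, conditions,
                   variant_id = keys$variant_id[i],
                   replicate = keys$replicate[i])
  })
  names(out) <- paste(keys$variant_id, keys$replicate, sep = "/")
  out
}

#' Write progress-curve traces to CSV
#'
#' @param traces a `progress_curve` or list of them
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "progress_curve")) traces <- list(traces)
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(variant_id = attr(tr, "variant_id"),
               replicate = attr(tr, "replicate"),
               time_min = tr$time, signal = tr$signal,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mutation list from CSV
#'
#' Expected columns: `position, from_aa, to_aa, round, kind` (`kind`
#' defaults to `"point"` when the column is absent).
#'
#' @param path CSV file path
#' @return mutation data frame
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) stop("mutations file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "from_aa", "to_aa")
  if (!all(need %in% names(df))) {
    stop("mutations CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$kind)) df$kind <- "point"
  if (is.null(df$round)) df$round <- NA_character_
  df$position <- as.integer(df$position)
  df
}

#' Read a trajectory table from CSV
#'
#' Long-format dialect: `round, background (ser|cys), phase (1|2|mono),
#' k2, annotation`, with `k2` in min^-1 M^-1. Converted to the wide
#' per-round table used by [tradeoff_report()]: the slow-phase (phase 2)
#' constant represents biphasic serine variants and the monophasic
#' constant represents cysteine revertants, matching how the two
#' backgrounds are compared across rounds.
#'
#' @param path CSV file path
#' @param ser_phase which phase carries the serine-background activity
#'   measure (default `"2"`)
#' @return data frame with columns `round`, `ser_constant`, `cys_constant`
#' @export
read_trajectory <- function(path, ser_phase = "2") {
  if (!file.exists(path)) stop("trajectory file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("round", "background", "phase", "k2")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rounds <- sort(unique(df$round))
  pick <- function(r, bg, ph) {
    hit <- df$k2[df$round == r & df$background == bg & df$phase %in% ph]
    if (length(hit)) hit[1] else NA_real_
  }
  data.frame(
    round = rounds,
    ser_constant = vapply(rounds, pick, numeric(1), bg = "ser",
                          ph = c(ser_phase, "mono")),
    cys_constant = vapply(rounds, pick, numeric(1), bg = "cys",
                          ph = c("mono", "1", "2")))
}

#' Write a wide trajectory table to the long CSV dialect
#'
#' @param table data frame with columns `round`, `ser_constant`,
#'   `cys_constant`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(table, path) {
  long <- rbind(
    data.frame(round = table$round, background = "ser", phase = "2",
               k2 = table$ser_constant, annotation = ""),
    data.frame(round = table$round, background = "cys", phase = "mono",
               k2 = table$cys_constant, annotation = ""))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write phase fits to JSON
#'
#' One record per fitted trace with all fit fields, the seed and the
#' package version.
#'
#' @param fits named list of `phase_fit` objects (or [select_model()]
#'   results)
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_fits_json <- function(fits, path) {
  recs <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    extra <- NULL
    if (!inherits(f, "phase_fit") && !is.null(f$model)) {
      extra <- list(F = f$F, p_value = f$p_value, alpha = f$alpha,
                    aicc_mono = f$aicc_mono, aicc_bi = f$aicc_bi)
      f <- if (f$model == "biphasic") f$fit_bi else f$fit_mono
    }
    c(list(trace = nm), unclass(f), extra,
      list(package_version = as.character(utils::packageVersion("nucleoperm"))))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Validate pipeline input files
#'
#' Report-only checks of CSV dialects, FASTA alphabet and PDB
#' parseability; problems are returned as rows, never thrown.
#'
#' @param paths character vector of file paths
#' @param formats matching vector of formats, each one of `"trace_csv"`,
#'   `"mutations_csv"`, `"trajectory_csv"`, `"fasta"`, `"pdb"`
#' @return data frame `file, format, level (ok|warning|error), message,
#'   row` (row is `NA` where not applicable); attribute `"valid"` is TRUE
#'   when no error rows exist
#' @export
validate_inputs <- function(paths, formats) {
  stopifnot(length(paths) == length(formats))
  issue <- function(file, format, level, message, row = NA_integer_) {
    data.frame(file = file, format = format, level = level,
               message = message, row = row, stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_along(paths)) {
    p <- paths[i]
    fmt <- formats[i]
    if (!file.exists(p)) {
      out[[length(out) + 1]] <- issue(p, fmt, "error", "file not found")
      next
    }
    res <- switch(fmt,
      trace_csv = validate_trace_csv(p),
      mutations_csv = validate_mutations_csv(p),
      trajectory_csv = tryCatch({
        read_trajectory(p); NULL
      }, error = function(e) issue(p, fmt, "error", conditionMessage(e))),
      fasta = validate_fasta(p),
      pdb = tryCatch({
        parse_structure(p); NULL
      }, error = function(e) issue(p, fmt, "error", conditionMessage(e))),
      issue(p, fmt, "error", paste("unknown format", fmt)))
    if (is.null(res) || nrow(res) == 0) {
      res <- issue(p, fmt, "ok", "ok")
    } else {
      res$file <- p
      res$format <- fmt
    }
    out[[length(out) + 1]] <- res
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  attr(rep, "valid") <- !any(rep$level == "error")
  rep
}

validate_trace_csv <- function(p) {
  df <- tryCatch(utils::read.csv(p, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df)) {
    return(data.frame(file = p, format = "trace_csv", level = "error",
                      message = "unreadable CSV", row = NA_integer_))
  }
  need <- c("variant_id", "replicate", "time_min", "signal")
  miss <- setdiff(need, names(df))
  rows <- list()
  if (length(miss)) {
    rows[[1]] <- data.frame(file = p, format = "trace_csv", level = "error",
                            message = paste("missing columns:",
                                            paste(miss, collapse = ", ")),
                            row = NA_integer_)
    return(do.call(rbind, rows))
  }
  if (!is.numeric(df$time_min) || !is.numeric(df$signal)) {
    rows[[length(rows) + 1]] <-
      data.frame(file = p, format = "trace_csv", level = "error",
                 message = "time_min and signal must be numeric",
                 row = NA_integer_)
  } else {
    keys <- unique(df[, c("variant_id", "replicate")])
    for (i in seq_len(nrow(keys))) {
      idx <- which(df$variant_id == keys$variant_id[i] &
                     df$replicate == keys$replicate[i])
      bad <- idx[which(diff(df$time_min[idx]) <= 0) + 1L]
      for (b in bad) {
        rows[[length(rows) + 1]] <-
          data.frame(file = p, format = "trace_csv", level = "error",
                     message = sprintf("non-monotone time for %s/%s",
                                       keys$variant_id[i], keys$replicate[i]),
                     row = b + 1L)  # +1 for the header line
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

validate_mutations_csv <- function(p) {
  df <- tryCatch(read_mutations(p), error = function(e) e)
  if (inherits(df, "error")) {
    return(data.frame(file = p, format = "mutations_csv", level = "error",
                      message = conditionMessage(df), row = NA_integer_))
  }
  rows <- list()
  bad_pos <- which(is.na(df$position) | df$position < 1)
  for (b in bad_pos) {
    rows[[length(rows) + 1]] <-
      data.frame(file = p, format = "mutations_csv", level = "error",
                 message = "position must be >= 1", row = b + 1L)
  }
  same <- which(df$kind == "point" & df$from_aa == df$to_aa)
  for (b in same) {
    rows[[length(rows) + 1]] <-
      data.frame(file = p, format = "mutations_csv", level = "error",
                 message = "point mutation with from_aa == to_aa",
                 row = b + 1L)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

validate_fasta <- function(p) {
  seqs <- tryCatch(Biostrings::readBStringSet(p), error = function(e) e)
  if (inherits(seqs, "error")) {
    return(data.frame(file = p, format = "fasta", level = "error",
                      message = conditionMessage(seqs), row = NA_integer_))
  }
  legal <- c(Biostrings::AA_ALPHABET, "*")
  rows <- list()
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(toupper(as.character(seqs[[i]])), "")[[1]])
    bad <- setdiff(chars, legal)
    if (length(bad)) {
      rows[[length(rows) + 1]] <-
        data.frame(file = p, format = "fasta", level = "error",
                   message = sprintf("illegal character(s) %s in record %s",
                                     paste(bad, collapse = ""),
                                     names(seqs)[i]),
                   row = NA_integer_)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}
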