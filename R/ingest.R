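#' @name ingest
#' @title Parsing per-read methylation caller output
#'
#' @description
#' Nanopore methylation callers emit per-read, per-site (or per-site-group)
#' calls in slightly different tabular dialects. These parsers normalise them
#' into a common record with five fields: `sample_id`, `chromosome`, 1-based
#' `position` of the CpG cytosine, `statistic` (a natural-log likelihood ratio,
#' positive meaning evidence for methylation) and `read_id`.
#'
#' nanopolish and f5c share a dialect in which one row may cover several
#' nearby CpG motifs (`num_motifs` > 1) with a single shared log-likelihood
#' ratio; such rows are split into one record per motif using the CpG offsets
#' found in the reported `sequence` context. Megalodon reports natural-log
#' probabilities for the modified and canonical base; the record statistic is
#' their difference, so the sigmoid transform of the statistic recovers the
#' modified-base probability exactly.
NULL

.nanopolish_required <- c("chromosome", "strand", "start", "end", "read_name",
                          "log_lik_ratio", "num_motifs", "sequence")
.megalodon_required <- c("read_id", "chrm", "strand", "pos",
                         "mod_log_prob", "can_log_prob")

.empty_records <- function() {
  data.table(sample_id = character(), chromosome = character(),
             position = integer(), statistic = numeric(),
             read_id = character())
}

.check_header <- function(cols, required, caller) {
  missing <- setdiff(required, cols)
  if (length(missing) > 0L) {
    stop(sprintf("%s input is missing required column(s): %s",
                 caller, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Split a grouped nanopolish/f5c call into single-CpG records
#'
#' nanopolish and f5c group calls over CpG motifs closer than ~10 bp into one
#' row covering `num_motifs` motifs. The reported `start` is the 0-based
#' position of the first motif's cytosine, and the `sequence` field contains
#' the local context with every grouped motif. This function places each motif
#' at a 1-based single-nucleotide position: the first motif at `start + 1`,
#' subsequent motifs offset by the spacing between successive `"CG"`
#' occurrences in `sequence`. Every motif inherits the full group
#' log-likelihood ratio unchanged.
#'
#' @param start 0-based position of the first CpG cytosine, as reported.
#' @param sequence local sequence context containing the grouped motifs.
#' @param num_motifs number of CpG motifs covered by the call.
#' @param log_lik_ratio natural-log likelihood ratio shared by the group.
#'
#' @return A `data.frame` with columns `position` (1-based) and `statistic`,
#'   one row per motif.
#'
#' @examples
#' split_grouped_call(1000, "AACGTTACGTT", 2, 2.5)
#' @export
split_grouped_call <- function(start, sequence, num_motifs, log_lik_ratio) {
  offs <- gregexpr("CG", sequence, fixed = TRUE)[[1L]]
  if (identical(c(offs), -1L)) offs <- integer()
  if (length(offs) != num_motifs) {
    stop(sprintf(
      "grouped call at start %d is inconsistent: num_motifs = %d but sequence %s contains %d CG motif(s)",
      as.integer(start), as.integer(num_motifs), sequence, length(offs)),
      call. = FALSE)
  }
  pos <- as.integer(start) + 1L + (as.integer(offs) - as.integer(offs[1L]))
  data.frame(position = pos, statistic = rep(log_lik_ratio, length(pos)))
}

# Vectorised grouped-call expansion over a parsed block. Rows whose sequence
# does not contain num_motifs CG occurrences are flagged rather than expanded.
.expand_nanopolish <- function(chrom, start0, read, llr, nmotif, seqs) {
  single <- nmotif == 1L
  out <- vector("list", 2L)
  bad <- rep(FALSE, length(start0))
  if (any(single)) {
    out[[1L]] <- data.table(
      chromosome = chrom[single],
      position = start0[single] + 1L,
      statistic = llr[single],
      read_id = read[single])
    # single-motif rows must still contain exactly one CG
    ncg <- vapply(gregexpr("CG", seqs[single], fixed = TRUE),
                  function(m) if (identical(c(m), -1L)) 0L else length(m),
                  integer(1L))
    bad1 <- ncg != 1L
    if (any(bad1)) {
      out[[1L]] <- out[[1L]][!bad1]
      bad[which(single)[bad1]] <- TRUE
    }
  }
  multi <- which(!single)
  if (length(multi) > 0L) {
    offs <- gregexpr("CG", seqs[multi], fixed = TRUE)
    ncg <- vapply(offs, function(m) if (identical(c(m), -1L)) 0L else length(m),
                  integer(1L))
    ok <- ncg == nmotif[multi]
    bad[multi[!ok]] <- TRUE
    mi <- multi[ok]
    if (length(mi) > 0L) {
      offs <- offs[ok]
      reps <- nmotif[mi]
      delta <- unlist(lapply(offs, function(o) as.integer(o) - as.integer(o[1L])),
                      use.names = FALSE)
      out[[2L]] <- data.table(
        chromosome = rep(chrom[mi], reps),
        position = rep(start0[mi] + 1L, reps) + delta,
        statistic = rep(llr[mi], reps),
        read_id = rep(read[mi], reps))
    }
  }
  list(records = rbindlist(out), bad = bad)
}

#' Parse nanopolish / f5c methylation-call output
#'
#' Reads the tab-separated per-read methylation call table written by
#' `nanopolish call-methylation` or `f5c call-methylation` (the two share
#' column names and are treated identically) and converts it into single-CpG
#' methylation records. Grouped multi-motif calls are split with
#' [split_grouped_call()]; each row therefore yields exactly `num_motifs`
#' records, all carrying the row's log-likelihood ratio.
#'
#' The file is processed in blocks of `block_size` lines so that peak memory
#' use is bounded by the block size, not the file size. When `callback` is
#' supplied, each block of records is handed to it and not accumulated, which
#' allows conversion of inputs of arbitrary size (see [build_store()]).
#'
#' @param file path to the caller output (TSV with a header row).
#' @param sample_id sample name attached to every record from this file.
#' @param strict if `TRUE`, malformed lines abort with the offending line
#'   number; if `FALSE` (default) they are skipped and counted.
#' @param block_size number of lines read per block.
#' @param callback optional `function(records)` invoked once per block.
#'
#' @return A `data.table` of records with columns `sample_id`, `chromosome`,
#'   `position`, `statistic`, `read_id`, carrying attributes `skipped`
#'   (malformed line count) and `calls` (input rows parsed). With a
#'   `callback`, an invisible summary list instead.
#'
#' @seealso [parse_megalodon()], [parse_f5c()]
#' @export
parse_nanopolish <- function(file, sample_id, strict = FALSE,
                             block_size = 50000L, callback = NULL) {
  stopifnot(is.character(sample_id), nchar(sample_id) > 0L)
  con <- file(file, open = "r")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  if (length(header) == 0L) {
    stop("empty input: no header line found", call. = FALSE)
  }
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  .check_header(cols, .nanopolish_required, "nanopolish/f5c")
  idx <- match(.nanopolish_required, cols)
  names(idx) <- .nanopolish_required
  nfield <- length(cols)

  skipped <- 0L
  ncalls <- 0L
  lineno <- 1L
  acc <- list()
  repeat {
    lines <- readLines(con, n = block_size)
    if (length(lines) == 0L) break
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(parts) == nfield
    if (strict && !all(ok)) {
      stop(sprintf("malformed line %d: expected %d fields, found %d",
                   lineno + which(!ok)[1L], nfield,
                   lengths(parts)[!ok][1L]), call. = FALSE)
    }
    m <- matrix(unlist(parts[ok], use.names = FALSE), ncol = nfield,
                byrow = TRUE)
    llr <- suppressWarnings(as.numeric(m[, idx["log_lik_ratio"]]))
    nmotif <- suppressWarnings(as.integer(m[, idx["num_motifs"]]))
    start0 <- suppressWarnings(as.integer(m[, idx["start"]]))
    num_ok <- is.finite(llr) & !is.na(nmotif) & nmotif >= 1L &
      !is.na(start0) & start0 >= 0L
    if (strict && !all(num_ok)) {
      stop(sprintf("non-numeric or invalid value on line %d",
                   lineno + which(ok)[which(!num_ok)[1L]]), call. = FALSE)
    }
    exp <- .expand_nanopolish(
      chrom = m[num_ok, idx["chromosome"]],
      start0 = start0[num_ok],
      read = m[num_ok, idx["read_name"]],
      llr = llr[num_ok],
      nmotif = nmotif[num_ok],
      seqs = m[num_ok, idx["sequence"]])
    if (strict && any(exp$bad)) {
      stop(sprintf(
        "grouped call on line %d: CG count in sequence does not match num_motifs",
        lineno + which(ok)[which(num_ok)[which(exp$bad)[1L]]]), call. = FALSE)
    }
    skipped <- skipped + sum(!ok) + sum(!num_ok) + sum(exp$bad)
    ncalls <- ncalls + sum(num_ok) - sum(exp$bad)
    rec <- exp$records
    if (nrow(rec) > 0L) {
      rec[, sample_id := sample_id]
      data.table::setcolorder(rec, c("sample_id", "chromosome", "position",
                                     "statistic", "read_id"))
      if (is.null(callback)) acc[[length(acc) + 1L]] <- rec else callback(rec)
    }
    lineno <- lineno + length(lines)
  }
  if (!is.null(callback)) {
    return(invisible(list(calls = ncalls, skipped = skipped)))
  }
  out <- if (length(acc) > 0L) rbindlist(acc) else .empty_records()
  data.table::setattr(out, "skipped", skipped)
  data.table::setattr(out, "calls", ncalls)
  out[]
}

#' @rdname parse_nanopolish
#' @details `parse_f5c()` is an alias for [parse_nanopolish()]: f5c writes the
#'   same columns and is parsed identically.
#' @export
parse_f5c <- parse_nanopolish

#' Parse Megalodon per-read modified-base output
#'
#' Reads Megalodon's per-read modified-base text output (columns are matched
#' by header name, since their order varies across Megalodon versions). The
#' record statistic is `mod_log_prob - can_log_prob`, the natural-log odds of
#' modification, so `plogis(statistic)` recovers
#' `exp(mod_log_prob) / (exp(mod_log_prob) + exp(can_log_prob))`. The reported
#' 0-based `pos` becomes a 1-based `position`.
#'
#' @inheritParams parse_nanopolish
#' @param collapse_strand if `TRUE`, calls on the minus strand are shifted by
#'   -1 bp to the forward-strand cytosine so both strands of a CpG stack on
#'   one position. Off by default, preserving the caller's coordinates.
#'
#' @return As [parse_nanopolish()].
#' @export
parse_megalodon <- function(file, sample_id, strict = FALSE,
                            collapse_strand = FALSE,
                            block_size = 50000L, callback = NULL) {
  stopifnot(is.character(sample_id), nchar(sample_id) > 0L)
  con <- file(file, open = "r")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  if (length(header) == 0L) {
    stop("empty input: no header line found", call. = FALSE)
  }
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  .check_header(cols, .megalodon_required, "megalodon")
  idx <- match(.megalodon_required, cols)
  names(idx) <- .megalodon_required
  nfield <- length(cols)

  skipped <- 0L
  ncalls <- 0L
  lineno <- 1L
  acc <- list()
  repeat {
    lines <- readLines(con, n = block_size)
    if (length(lines) == 0L) break
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(parts) == nfield
    if (strict && !all(ok)) {
      stop(sprintf("malformed line %d: expected %d fields, found %d",
                   lineno + which(!ok)[1L], nfield,
                   lengths(parts)[!ok][1L]), call. = FALSE)
    }
    m <- matrix(unlist(parts[ok], use.names = FALSE), ncol = nfield,
                byrow = TRUE)
    mod <- suppressWarnings(as.numeric(m[, idx["mod_log_prob"]]))
    can <- suppressWarnings(as.numeric(m[, idx["can_log_prob"]]))
    pos0 <- suppressWarnings(as.integer(m[, idx["pos"]]))
    num_ok <- is.finite(mod) & is.finite(can) & !is.na(pos0) & pos0 >= 0L
    if (strict && !all(num_ok)) {
      stop(sprintf("non-numeric or invalid value on line %d",
                   lineno + which(ok)[which(!num_ok)[1L]]), call. = FALSE)
    }
    skipped <- skipped + sum(!ok) + sum(!num_ok)
    ncalls <- ncalls + sum(num_ok)
    position <- pos0[num_ok] + 1L
    if (collapse_strand) {
      minus <- m[num_ok, idx["strand"]] == "-"
      position[minus] <- pmax(position[minus] - 1L, 1L)
    }
    rec <- data.table(
      sample_id = sample_id,
      chromosome = m[num_ok, idx["chrm"]],
      position = position,
      statistic = mod[num_ok] - can[num_ok],
      read_id = m[num_ok, idx["read_id"]])
    if (nrow(rec) > 0L) {
      if (is.null(callback)) acc[[length(acc) + 1L]] <- rec else callback(rec)
    }
    lineno <- lineno + length(lines)
  }
  if (!is.null(callback)) {
    return(invisible(list(calls = ncalls, skipped = skipped)))
  }
  out <- if (length(acc) > 0L) rbindlist(acc) else .empty_records()
  data.table::setattr(out, "skipped", skipped)
  data.table::setattr(out, "calls", ncalls)
  out[]
}
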