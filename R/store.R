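#' @name store
#' @title The bgzip/tabix methylation store
#'
#' @description
#' Methylation records are persisted as a 5-column tab-separated file
#' (`sample_id`, `chromosome`, `position`, `statistic`, `read_id`), sorted by
#' chromosome (lexicographic byte order) then position, block-compressed with
#' bgzip and indexed with tabix. bgzip compresses rows into independently
#' decompressible blocks and tabix records the genomic range held by each
#' block, so a region query decompresses only the blocks it needs — whole
#' chromosomes of per-read calls never have to be loaded into memory.
#'
#' A small sidecar TSV (`<store>.samples.tsv`) maps each `sample_id` to an
#' experimental group label (e.g. a haplotype); the indexed data file itself
#' stays minimal.
NULL

.store_colnames <- c("sample_id", "chromosome", "position", "statistic",
                     "read_id")

.sort_key <- function(chrom, pos) sprintf("%s\t%012d", chrom, pos)

.format_records <- function(dt) {
  paste(dt$sample_id, dt$chromosome, dt$position,
        sprintf("%.6g", dt$statistic), dt$read_id, sep = "\t")
}

.parse_store_lines <- function(lines) {
  if (length(lines) == 0L) return(.empty_records())
  dt <- fread(text = lines, sep = "\t", header = FALSE,
              col.names = .store_colnames,
              colClasses = list(character = c(1L, 2L, 5L),
                                integer = 3L, numeric = 4L))
  dt
}

#' Build a sorted, indexed methylation store
#'
#' Sorts methylation records by (chromosome, position), writes them as a
#' 5-column TSV, block-compresses the file with bgzip and builds a tabix
#' index (sequence column 2, begin/end column 3, 1-based coordinates).
#'
#' `records` may be a data.frame of records or a generator
#' `function()` returning successive record blocks (`NULL` when exhausted),
#' e.g. built from a parser callback; blocks are sorted and spilled to
#' temporary chunk files of at most `chunk_size` rows which are then merged,
#' so memory use is bounded regardless of input size.
#'
#' @param records data.frame with columns `sample_id`, `chromosome`,
#'   `position`, `statistic`, `read_id`, or a generator function as above.
#' @param out_path output path; `.bgz` is appended if no gz-like extension is
#'   present.
#' @param samples optional sample sheet: data.frame with columns `sample_id`
#'   and `group`. Defaults to one group per sample.
#' @param chunk_size maximum rows held in memory while sorting.
#'
#' @return A `methy_store` handle (see [open_store()]).
#' @export
build_store <- function(records, out_path, samples = NULL,
                        chunk_size = 1000000L) {
  pull <- if (is.function(records)) {
    records
  } else {
    done <- FALSE
    dt0 <- as.data.table(records)
    function() {
      if (done) return(NULL)
      done <<- TRUE
      dt0
    }
  }

  tmpdir <- tempfile("store_chunks_")
  dir.create(tmpdir)
  on.exit(unlink(tmpdir, recursive = TRUE), add = TRUE)

  chunk_files <- character()
  buf <- list()
  nbuf <- 0L
  seen_samples <- character()

  flush_chunk <- function() {
    if (nbuf == 0L) return(invisible())
    dt <- rbindlist(buf)
    setorderv(dt, c("chromosome", "position"))  # data.table: C-locale radix
    f <- file.path(tmpdir, sprintf("chunk_%05d.tsv", length(chunk_files)))
    writeLines(.format_records(dt), f)
    chunk_files <<- c(chunk_files, f)
    buf <<- list()
    nbuf <<- 0L
  }

  repeat {
    block <- pull()
    if (is.null(block)) break
    block <- as.data.table(block)
    if (nrow(block) == 0L) next
    if (!all(.store_colnames %in% names(block))) {
      stop("records must have columns: ",
           paste(.store_colnames, collapse = ", "), call. = FALSE)
    }
    if (any(block$position < 1L)) {
      stop("records with position < 1 are not allowed", call. = FALSE)
    }
    seen_samples <- union(seen_samples, unique(block$sample_id))
    # split oversize blocks so chunks respect chunk_size
    off <- 0L
    while (off < nrow(block)) {
      take <- min(chunk_size - nbuf, nrow(block) - off)
      buf[[length(buf) + 1L]] <- block[(off + 1L):(off + take)]
      nbuf <- nbuf + take
      off <- off + take
      if (nbuf >= chunk_size) flush_chunk()
    }
  }
  flush_chunk()

  plain <- tempfile(fileext = ".tsv")
  on.exit(unlink(plain), add = TRUE)
  if (length(chunk_files) == 0L) {
    file.create(plain)
  } else if (length(chunk_files) == 1L) {
    file.copy(chunk_files[1L], plain, overwrite = TRUE)
  } else {
    .merge_sorted_chunks(chunk_files, plain, buffer_rows = max(
      1000L, chunk_size %/% length(chunk_files)))
  }

  if (!grepl("\\.(bgz|gz)$", out_path)) out_path <- paste0(out_path, ".bgz")
  if (file.exists(out_path)) unlink(out_path)
  Rsamtools::bgzip(plain, dest = out_path, overwrite = TRUE)
  index_path <- Rsamtools::indexTabix(out_path, seq = 2L, start = 3L,
                                      end = 3L, skip = 0L,
                                      zeroBased = FALSE)

  if (is.null(samples)) {
    samples <- data.frame(sample_id = sort(seen_samples),
                          group = sort(seen_samples))
  }
  samples <- as.data.frame(samples)[, c("sample_id", "group")]
  if (anyDuplicated(samples$sample_id)) {
    stop("sample sheet has duplicated sample_id values", call. = FALSE)
  }
  write.table(samples, paste0(out_path, ".samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  open_store(out_path)
}

# k-way merge of sorted chunk files under a per-file row budget. Rows are
# emitted only up to the smallest maximum key currently buffered among
# non-exhausted files, which guarantees global order with bounded memory.
.merge_sorted_chunks <- function(chunk_files, out_file, buffer_rows) {
  # chunks were sorted in C collation (data.table radix); pin comparisons here
  old_collate <- Sys.getlocale("LC_COLLATE")
  Sys.setlocale("LC_COLLATE", "C")
  on.exit(Sys.setlocale("LC_COLLATE", old_collate), add = TRUE)
  cons <- lapply(chunk_files, function(f) file(f, open = "r"))
  on.exit(lapply(cons, close))
  bufs <- vector("list", length(cons))
  eof <- rep(FALSE, length(cons))
  out_con <- file(out_file, open = "w")
  on.exit(close(out_con), add = TRUE)

  refill <- function(i) {
    lines <- readLines(cons[[i]], n = buffer_rows)
    if (length(lines) == 0L) {
      eof[i] <<- TRUE
      return(invisible())
    }
    dt <- .parse_store_lines(lines)
    dt[, key_ := .sort_key(chromosome, position)]
    bufs[[i]] <<- if (is.null(bufs[[i]])) dt else rbind(bufs[[i]], dt)
  }
  for (i in seq_along(cons)) refill(i)

  repeat {
    active <- which(vapply(bufs, function(b) !is.null(b) && nrow(b) > 0L,
                           logical(1L)))
    if (length(active) == 0L) break
    # frontier: rows beyond a non-exhausted file's buffered max may still
    # arrive, so only emit keys <= the min of those maxima
    open_files <- active[!eof[active]]
    cut <- if (length(open_files) == 0L) NULL else {
      min(vapply(open_files, function(i) max(bufs[[i]]$key_), character(1L)))
    }
    pieces <- list()
    for (i in active) {
      take <- if (is.null(cut)) rep(TRUE, nrow(bufs[[i]])) else
        bufs[[i]]$key_ <= cut
      if (any(take)) {
        pieces[[length(pieces) + 1L]] <- bufs[[i]][take]
        bufs[[i]] <- bufs[[i]][!take]
      }
      if (nrow(bufs[[i]]) == 0L && !eof[i]) refill(i)
    }
    emit <- rbindlist(pieces)
    setorderv(emit, "key_")
    writeLines(.format_records(emit), out_con)
  }
  invisible(out_file)
}

#' Open an existing methylation store
#'
#' @param path path to the bgzip data file produced by [build_store()].
#' @return A `methy_store` object: a handle holding the data path, index
#'   path and the sample sheet.
#' @export
open_store <- function(path) {
  if (!file.exists(path)) stop("store file not found: ", path, call. = FALSE)
  index_path <- paste0(path, ".tbi")
  if (!file.exists(index_path)) {
    stop("tabix index not found: ", index_path, call. = FALSE)
  }
  sheet_path <- paste0(path, ".samples.tsv")
  samples <- if (file.exists(sheet_path)) {
    setDT(read.table(sheet_path, sep = "\t", header = TRUE,
                     colClasses = "character"))
  } else {
    data.table(sample_id = character(), group = character())
  }
  structure(list(data_path = path, index_path = index_path,
                 samples = samples),
            class = "methy_store")
}

#' @export
print.methy_store <- function(x, ...) {
  cat("methylation store:", x$data_path, "\n")
  cat("  index:  ", x$index_path, "\n")
  chroms <- tryCatch(
    Rsamtools::seqnamesTabix(Rsamtools::TabixFile(x$data_path)),
    error = function(e) character())
  cat("  chromosomes:", paste(chroms, collapse = ", "), "\n")
  cat("  samples:\n")
  print(x$samples)
  invisible(x)
}

#' Query methylation records in a genomic region
#'
#' Extracts the records with the given chromosome and
#' `start <= position <= end` (1-based, fully closed) from the store. Only the
#' bgzip blocks overlapping the query are decompressed.
#'
#' @param store a `methy_store`.
#' @param chromosome chromosome name.
#' @param start,end 1-based inclusive query bounds.
#'
#' @return A `data.table` of records in file order. A chromosome absent from
#'   the index yields an empty result with a warning.
#' @export
query_region <- function(store, chromosome, start, end) {
  stopifnot(inherits(store, "methy_store"), start <= end)
  tf <- Rsamtools::TabixFile(store$data_path)
  known <- Rsamtools::seqnamesTabix(tf)
  if (!chromosome %in% known) {
    warning("chromosome not present in store index: ", chromosome,
            call. = FALSE)
    return(.empty_records())
  }
  gr <- GenomicRanges::GRanges(chromosome,
                               IRanges::IRanges(max(1L, start), end))
  lines <- Rsamtools::scanTabix(tf, param = gr)[[1L]]
  .parse_store_lines(lines)
}

#' Query methylation records around a named feature
#'
#' Resolves `name` against a feature table (or gene annotation) and delegates
#' to [query_region()] over the feature span extended by `flank` bp on both
#' sides, clipped at position 1.
#'
#' @param store a `methy_store`.
#' @param features a feature table (see [feature_set()]) or an
#'   `exon_annotation` from [read_annotation()].
#' @param name feature id / gene symbol; must resolve to exactly one feature.
#' @param flank bp added on each side of the feature.
#'
#' @return A `data.table` of records.
#' @export
query_genes <- function(store, features, name, flank = 0L) {
  loc <- .resolve_feature(features, name)
  query_region(store, loc$chromosome,
               max(1L, loc$start - flank), loc$end + flank)
}

#' Read every record in a store, in blocks
#'
#' Streams the full store file through `callback(records)` in blocks, or
#' returns all records when no callback is given. Used by exporters so that
#' genome-wide summaries never hold the full per-read data in memory.
#'
#' @inheritParams query_region
#' @param block_size lines per block.
#' @param callback optional `function(records)` per block.
#' @return All records as a `data.table`, or (with a callback) an invisible
#'   count of records streamed.
#' @export
read_store <- function(store, block_size = 200000L, callback = NULL) {
  stopifnot(inherits(store, "methy_store"))
  con <- gzfile(store$data_path, open = "r")
  on.exit(close(con))
  acc <- list()
  n <- 0L
  repeat {
    lines <- readLines(con, n = block_size)
    if (length(lines) == 0L) break
    dt <- .parse_store_lines(lines)
    n <- n + nrow(dt)
    if (is.null(callback)) acc[[length(acc) + 1L]] <- dt else callback(dt)
  }
  if (!is.null(callback)) return(invisible(n))
  if (length(acc) == 0L) .empty_records() else rbindlist(acc)
}
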