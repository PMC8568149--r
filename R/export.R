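#' @name export
#' @title Site-level count matrices and DMR-tool export formats
#'
#' @description
#' Differential-methylation tools (bsseq, DSS, edgeR) work from per-site
#' methylated/unmethylated call counts rather than per-read log-likelihood
#' ratios. [count_sites()] binarises each record by the sign of its statistic
#' (with an optional ambiguity dead-zone) and tallies counts per site and
#' sample; [write_dmr_tables()] emits the three tools' input layouts, and
#' [log_methy_ratio()] forms the moderated log2 methylated/unmethylated ratio
#' matrix used for sample embeddings.
NULL

.new_site_counts <- function(sites, samples, me, un, discarded = 0L,
                             total = NULL) {
  rn <- if (nrow(sites) > 0L) paste0(sites$chromosome, ":",
                                     sites$position) else character()
  dimnames(me) <- dimnames(un) <- list(rn, samples)
  structure(list(sites = sites, samples = samples,
                 methylated = me, unmethylated = un,
                 discarded = discarded,
                 total_records = if (is.null(total)) sum(me) + sum(un) +
                   discarded else total),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf("site_counts: %d sites x %d samples (%d calls, %d discarded)\n",
              nrow(x$sites), length(x$samples),
              sum(x$methylated) + sum(x$unmethylated), x$discarded))
  invisible(x)
}

#' Tally methylated/unmethylated calls per site and sample
#'
#' Each record is called methylated if `statistic > call_threshold`,
#' unmethylated if `statistic < -call_threshold`, and discarded when
#' `|statistic| <= call_threshold`. With the default threshold of 0 only
#' exact zeros are discarded; a threshold of 2 reproduces the common
#' nanopolish practice of dropping ambiguous calls.
#'
#' @param x a `methy_store` or a data.frame of methylation records.
#' @param call_threshold ambiguity dead-zone on the log-likelihood ratio.
#' @param samples optional sample sheet fixing sample order; defaults to the
#'   store's sheet (or sorted sample ids for a plain record table).
#'
#' @return A `site_counts` object: the sorted unique site table, the sample
#'   order, and integer `methylated` / `unmethylated` matrices (sites x
#'   samples), with the discarded-call count attached.
#' @export
count_sites <- function(x, call_threshold = 0, samples = NULL) {
  stopifnot(call_threshold >= 0)
  tallies <- list()
  discarded <- 0L
  total <- 0L
  tally_block <- function(dt) {
    total <<- total + nrow(dt)
    me <- dt$statistic > call_threshold
    un <- dt$statistic < -call_threshold
    discarded <<- discarded + sum(!me & !un)
    kept <- dt[me | un]
    kept[, state := fifelse(statistic > call_threshold, 1L, 0L)]
    t <- kept[, .(me = sum(state), un = sum(1L - state)),
              by = .(sample_id, chromosome, position)]
    tallies[[length(tallies) + 1L]] <<- t
  }
  if (inherits(x, "methy_store")) {
    if (is.null(samples)) samples <- x$samples
    read_store(x, callback = tally_block)
  } else {
    tally_block(as.data.table(x))
  }
  if (length(tallies) == 0L || sum(vapply(tallies, nrow, 0L)) == 0L) {
    sites <- data.table(chromosome = character(), position = integer())
    ids <- if (!is.null(samples)) samples$sample_id else character()
    return(.new_site_counts(sites, ids,
                            matrix(0L, 0L, length(ids)),
                            matrix(0L, 0L, length(ids)),
                            discarded, total))
  }
  tally <- rbindlist(tallies)[, .(me = sum(me), un = sum(un)),
                              by = .(sample_id, chromosome, position)]
  sample_ids <- if (!is.null(samples)) samples$sample_id else
    sort(unique(tally$sample_id))
  sites <- unique(tally[, .(chromosome, position)])
  setorderv(sites, c("chromosome", "position"))
  si <- sites[, key_ := paste0(chromosome, ":", position)]$key_
  row <- match(paste0(tally$chromosome, ":", tally$position), si)
  col <- match(tally$sample_id, sample_ids)
  me <- un <- matrix(0L, nrow(sites), length(sample_ids))
  me[cbind(row, col)] <- tally$me
  un[cbind(row, col)] <- tally$un
  sites[, key_ := NULL]
  .new_site_counts(sites, sample_ids, me, un, discarded, total)
}

#' Write count tables in DMR-tool input layouts
#'
#' * `dss`: one TSV per sample with columns `chr`, `pos`, `N` (coverage =
#'   methylated + unmethylated) and `X` (methylated), the input of
#'   `DSS::makeBSseqData`.
#' * `edger`: one wide TSV with the site coordinates followed by paired
#'   columns `Me_<sample>` / `Un_<sample>` in sample-sheet order, as used by
#'   the edgeR bisulfite workflow.
#' * `bsseq`: a coordinate TSV plus `methylation` and `coverage` matrix TSVs,
#'   the components of a `BSseq` object.
#'
#' @param counts a `site_counts` object.
#' @param flavor `"dss"`, `"edger"` or `"bsseq"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dmr_tables <- function(counts, flavor = c("dss", "edger", "bsseq"),
                             dir) {
  stopifnot(inherits(counts, "site_counts"))
  if (nrow(counts$sites) == 0L) stop("empty count matrix", call. = FALSE)
  flavor <- match.arg(flavor)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sites <- counts$sites
  paths <- character()
  if (flavor == "dss") {
    for (s in counts$samples) {
      d <- data.frame(chr = sites$chromosome, pos = sites$position,
                      N = counts$methylated[, s] + counts$unmethylated[, s],
                      X = counts$methylated[, s])
      p <- file.path(dir, paste0(s, ".dss.tsv"))
      write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  } else if (flavor == "edger") {
    wide <- data.frame(chr = sites$chromosome, pos = sites$position)
    for (s in counts$samples) {
      wide[[paste0("Me_", s)]] <- counts$methylated[, s]
      wide[[paste0("Un_", s)]] <- counts$unmethylated[, s]
    }
    p <- file.path(dir, "edger_counts.tsv")
    write.table(wide, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- p
  } else {
    cp <- file.path(dir, "sites.tsv")
    write.table(data.frame(chr = sites$chromosome, pos = sites$position),
                cp, sep = "\t", quote = FALSE, row.names = FALSE)
    mp <- file.path(dir, "methylation.tsv")
    write.table(as.data.frame(counts$methylated), mp, sep = "\t",
                quote = FALSE, row.names = FALSE)
    vp <- file.path(dir, "coverage.tsv")
    write.table(as.data.frame(counts$methylated + counts$unmethylated), vp,
                sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(cp, mp, vp)
  }
  invisible(paths)
}

#' Re-assemble a count matrix from DSS-style per-sample files
#'
#' Inverse of `write_dmr_tables(..., flavor = "dss")`: reads each sample's
#' `(chr, pos, N, X)` table and rebuilds the `site_counts` object
#' (methylated = X, unmethylated = N - X) over the union of sites.
#'
#' @param files named character vector of per-sample file paths; names are
#'   the sample ids (defaults to file names stripped of `.dss.tsv`).
#' @return A `site_counts` object.
#' @export
read_dss_tables <- function(files) {
  if (is.null(names(files)) || any(names(files) == "")) {
    names(files) <- sub("\\.dss\\.tsv$", "", basename(files))
  }
  recs <- rbindlist(lapply(names(files), function(s) {
    d <- fread(files[[s]])
    data.table(sample_id = s, chromosome = as.character(d$chr),
               position = as.integer(d$pos), me = as.integer(d$X),
               un = as.integer(d$N - d$X))
  }))
  sites <- unique(recs[, .(chromosome, position)])
  setorderv(sites, c("chromosome", "position"))
  si <- paste0(sites$chromosome, ":", sites$position)
  row <- match(paste0(recs$chromosome, ":", recs$position), si)
  col <- match(recs$sample_id, names(files))
  me <- un <- matrix(0L, nrow(sites), length(files))
  me[cbind(row, col)] <- recs$me
  un[cbind(row, col)] <- recs$un
  .new_site_counts(sites, names(files), me, un)
}

#' Log-methylation-ratio matrix
#'
#' Converts site counts into the matrix of moderated log ratios
#' `log2((Me + prior) / (Un + prior))` used to represent sample methylation
#' profiles for MDS/PCA. The pseudocount (`prior_count`, default 2, the
#' convention of the edgeR count-ratio workflows) keeps every entry finite;
#' sites whose total coverage across all samples falls below `min_coverage`
#' are dropped so all-pseudocount rows cannot dominate variance-based site
#' selection.
#'
#' @param counts a `site_counts` object.
#' @param prior_count pseudocount added to both counts; must be > 0.
#' @param min_coverage minimum total coverage (across samples) to keep a site.
#'
#' @return A numeric sites x samples matrix with rownames `chrom:pos`,
#'   carrying the site table and pseudocount as attributes.
#' @export
log_methy_ratio <- function(counts, prior_count = 2, min_coverage = 1L) {
  stopifnot(inherits(counts, "site_counts"))
  if (prior_count <= 0) stop("prior_count must be > 0", call. = FALSE)
  keep <- rowSums(counts$methylated + counts$unmethylated) >= min_coverage
  me <- counts$methylated[keep, , drop = FALSE]
  un <- counts$unmethylated[keep, , drop = FALSE]
  m <- log2((me + prior_count) / (un + prior_count))
  attr(m, "prior_count") <- prior_count
  attr(m, "sites") <- counts$sites[keep]
  m
}
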