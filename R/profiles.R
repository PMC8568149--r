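#' @name profiles
#' @title Methylation probability profiles
#'
#' @description
#' The plotting layers all work on methylation probabilities obtained from
#' the stored log-likelihood ratios by the sigmoid transform. This module
#' holds the numerical steps behind the figures: per-site mean probabilities
#' (computed before smoothing so loess never sees millions of raw calls),
#' mapping of genomic positions onto a relative feature axis with fixed-width
#' flanks, binned means along that axis (giving uniform point density, which
#' keeps local smoothers well behaved at the body/flank boundary), the
#' equal-feature-weight aggregate, lowess smoothing, and pooled per-region
#' summaries for box plots.
NULL

#' Sigmoid and logit transforms
#'
#' `sigmoid(x)` maps a log-likelihood ratio to a methylation probability,
#' `1 / (1 + exp(-x))`; `logit()` is its inverse on (0, 1). Both are thin
#' wrappers over the exact distribution-function forms in `stats`.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(2)      # 0.8807971
#' logit(sigmoid(1.7))
#' @export
sigmoid <- function(x) plogis(x)

#' @rdname sigmoid
#' @export
logit <- function(x) qlogis(x)

.grouping_column <- function(records, group_by = c("sample", "group"),
                             samples = NULL) {
  group_by <- match.arg(group_by)
  if (group_by == "sample") return(records$sample_id)
  if (is.null(samples)) {
    stop("group_by = \"group\" needs a sample sheet", call. = FALSE)
  }
  samples <- as.data.table(samples)
  g <- samples$group[match(records$sample_id, samples$sample_id)]
  if (anyNA(g)) {
    stop("records contain sample ids absent from the sample sheet: ",
         paste(unique(records$sample_id[is.na(g)]), collapse = ", "),
         call. = FALSE)
  }
  g
}

#' Per-site mean methylation probability
#'
#' For each site and grouping level (sample or experimental group), the
#' unweighted mean of `sigmoid(statistic)` over all reads covering the site.
#' Taking these means before smoothing reduces tens of reads per site to one
#' point, which is what makes loess over genomic windows tractable; note the
#' mean confounds biological and technical signal — two reads confidently
#' called 0.99 and 0.01 average to 0.5, exactly like two ambiguous calls.
#'
#' @param records a data.frame of methylation records.
#' @param group_by `"sample"` or `"group"`.
#' @param samples sample sheet (required for `group_by = "group"`).
#'
#' @return A `data.table` with columns `chromosome`, `position`, `group`,
#'   `mean_prob`, `n_reads`.
#' @export
per_site_means <- function(records, group_by = c("sample", "group"),
                           samples = NULL) {
  dt <- as.data.table(records)
  if (nrow(dt) == 0L) {
    return(data.table(chromosome = character(), position = integer(),
                      group = character(), mean_prob = numeric(),
                      n_reads = integer()))
  }
  dt <- copy(dt)
  dt[, group := .grouping_column(dt, group_by, samples)]
  out <- dt[, .(mean_prob = mean(sigmoid(statistic)), n_reads = .N),
            by = .(chromosome, position, group)]
  setorderv(out, c("chromosome", "position", "group"))
  out[]
}

#' Map genomic positions onto the relative feature axis
#'
#' Positions inside the feature body map linearly onto `[0, 1]`; positions in
#' the upstream flank map onto `[-f, 0)` and the downstream flank onto
#' `(1, 1 + f]`, where `f` (`flank_fraction`, default 1/3) is the fixed width
#' the flanks occupy on the display axis regardless of the feature's length.
#' Within a flank the mapping is linear in actual bp offset / `flank`.
#' Minus-strand features are mirrored so that 0 is always the feature's 5'
#' end and the upstream flank is always on the left.
#'
#' @param position genomic position(s), 1-based.
#' @param start,end feature body, 1-based closed.
#' @param strand `"+"`, `"-"` or `"."` (treated as `"+"`).
#' @param flank flank width in bp.
#' @param flank_fraction display width of each flank on the relative axis.
#'
#' @return Numeric vector of relative coordinates in `[-f, 1 + f]`.
#' @export
relative_position <- function(position, start, end, strand = "+",
                              flank = 2000L, flank_fraction = 1 / 3) {
  stopifnot(end >= start, flank >= 0, flank_fraction > 0)
  if (any(position < start - flank | position > end + flank)) {
    stop("position outside the flanked feature window", call. = FALSE)
  }
  w <- end - start
  x <- numeric(length(position))
  body <- position >= start & position <= end
  x[body] <- if (w == 0L) 0 else (position[body] - start) / w
  up <- position < start
  x[up] <- -flank_fraction * (start - position[up]) / flank
  dn <- position > end
  x[dn] <- 1 + flank_fraction * (position[dn] - end) / flank
  if (identical(strand, "-")) x <- 1 - x
  x
}

#' Binned means along an axis
#'
#' Partitions `xlim` into `n_bins` equal-width half-open bins (the last bin
#' closed on the right) and returns the unweighted mean of `y` per non-empty
#' bin. Used to equalise point density along the relative feature axis before
#' smoothing; empty bins are omitted, never interpolated.
#'
#' @param x numeric positions, all within `xlim`.
#' @param y values to average.
#' @param n_bins number of bins (>= 1).
#' @param xlim domain to partition; defaults to `range(x)`.
#'
#' @return A `data.table` with columns `bin` (index), `x` (bin midpoint),
#'   `y` (bin mean) and `n` (points in bin).
#' @export
binned_means <- function(x, y, n_bins, xlim = range(x)) {
  stopifnot(n_bins >= 1L, length(x) == length(y))
  lo <- xlim[1L]
  hi <- xlim[2L]
  if (any(x < lo | x > hi)) stop("x values outside xlim", call. = FALSE)
  w <- (hi - lo) / n_bins
  idx <- if (w == 0) rep(1L, length(x)) else
    pmin(as.integer(floor((x - lo) / w)) + 1L, n_bins)
  out <- data.table(bin = idx, y = y)[, .(y = mean(y), n = .N), by = bin]
  out[, x := lo + (bin - 0.5) * w]
  setorderv(out, "bin")
  out[, .(bin, x, y, n)]
}

#' Aggregate methylation profile over a feature class
#'
#' Builds the metagene-style aggregate curve: per-site mean probabilities are
#' mapped onto the relative axis of each overlapping feature and binned
#' within that feature; the aggregate is then the per-bin unweighted mean
#' across features that have data in the bin. Averaging feature curves rather
#' than pooled reads gives every feature equal weight, so the aggregate is
#' not biased towards features with higher coverage.
#'
#' @param x a `methy_store` or a data.frame of methylation records.
#' @param features a feature table (see [feature_set()]).
#' @param flank flank width in bp queried around each feature.
#' @param n_bins bins along the relative axis.
#' @param group_by,samples see [per_site_means()].
#' @param flank_fraction display width of each flank (see
#'   [relative_position()]).
#'
#' @return A `profile_curve` `data.table`: `group`, `bin`, `x`, `y`
#'   (aggregate probability), `n_features` (features contributing to the
#'   bin), with attribute `kind = "aggregate"`.
#' @export
aggregate_features <- function(x, features, flank = 2000L, n_bins = 100L,
                               group_by = c("group", "sample"),
                               samples = NULL, flank_fraction = 1 / 3) {
  group_by <- match.arg(group_by)
  features <- as.data.table(features)
  if (inherits(x, "methy_store") && is.null(samples)) samples <- x$samples
  per_feature <- list()
  for (i in seq_len(nrow(features))) {
    ft <- features[i]
    recs <- if (inherits(x, "methy_store")) {
      query_region(x, ft$chromosome, max(1L, ft$start - flank),
                   ft$end + flank)
    } else {
      dt <- as.data.table(x)
      dt[chromosome == ft$chromosome & position >= ft$start - flank &
           position <= ft$end + flank]
    }
    if (nrow(recs) == 0L) next
    sm <- per_site_means(recs, group_by, samples)
    sm[, rel := relative_position(position, ft$start, ft$end, ft$strand,
                                  flank, flank_fraction)]
    bm <- sm[, binned_means(rel, mean_prob, n_bins,
                            xlim = c(-flank_fraction, 1 + flank_fraction)),
             by = group]
    bm[, feature_id := ft$feature_id]
    per_feature[[length(per_feature) + 1L]] <- bm
  }
  if (length(per_feature) == 0L) {
    stop("no methylation records overlap any feature", call. = FALSE)
  }
  all_bins <- rbindlist(per_feature)
  out <- all_bins[, .(y = mean(y), n_features = .N), by = .(group, bin, x)]
  setorderv(out, c("group", "bin"))
  data.table::setattr(out, "kind", "aggregate")
  out[]
}

#' Lowess-smoothed probability curve
#'
#' Degree-1 locally weighted regression (tricube kernel, no robustness
#' iterations) evaluated at the input positions, with the output clamped to
#' `[0, 1]`. Inputs with fewer than 5 points are returned unsmoothed with
#' attribute `smoothed = FALSE` — too few points for a stable local fit.
#'
#' @param x positions.
#' @param y probabilities.
#' @param span fraction of points used for each local fit.
#'
#' @return A `data.table` with columns `x` (sorted) and `y` (smoothed,
#'   clamped), attribute `smoothed`.
#' @export
smooth_curve <- function(x, y, span = 0.3) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) {
    ord <- order(x)
    out <- data.table(x = as.numeric(x[ord]), y = pmin(pmax(y[ord], 0), 1))
    data.table::setattr(out, "smoothed", FALSE)
    return(out[])
  }
  fit <- lowess(x, y, f = span, iter = 0L)
  out <- data.table(x = fit$x, y = pmin(pmax(fit$y, 0), 1))
  data.table::setattr(out, "smoothed", TRUE)
  out[]
}

#' Pooled per-site probabilities by region class
#'
#' For each region class (e.g. promoter / non-promoter) and grouping level,
#' pools the per-site mean probabilities of the sites falling inside that
#' class's regions — the distributions behind the region box plots. Sites in
#' no region are assigned to `complement` when one is named, and dropped
#' otherwise.
#'
#' @param x a `methy_store` or a data.frame of methylation records.
#' @param regions a feature table with a `class_label` column; regions of one
#'   class must not overlap each other.
#' @param group_by,samples see [per_site_means()].
#' @param complement optional class name for sites covered by no region.
#'
#' @return A `data.table` with columns `class_label`, `group`, `chromosome`,
#'   `position`, `mean_prob`.
#' @export
region_summary <- function(x, regions, group_by = c("group", "sample"),
                           samples = NULL, complement = NULL) {
  group_by <- match.arg(group_by)
  regions <- as.data.table(regions)
  if (!"class_label" %in% names(regions)) {
    stop("regions need a class_label column", call. = FALSE)
  }
  if (inherits(x, "methy_store")) {
    if (is.null(samples)) samples <- x$samples
    recs <- read_store(x)
  } else {
    recs <- as.data.table(x)
  }
  sm <- per_site_means(recs, group_by, samples)
  site_gr <- GenomicRanges::GRanges(sm$chromosome,
                                    IRanges::IRanges(sm$position,
                                                     sm$position))
  out <- list()
  for (cl in unique(regions$class_label)) {
    rg <- regions[class_label == cl]
    gr <- GenomicRanges::GRanges(rg$chromosome,
                                 IRanges::IRanges(rg$start, rg$end))
    red <- GenomicRanges::reduce(gr)
    if (sum(GenomicRanges::width(red)) < sum(GenomicRanges::width(gr))) {
      stop("regions overlap within class: ", cl, call. = FALSE)
    }
    hit <- IRanges::overlapsAny(site_gr, gr)
    if (any(hit)) {
      d <- sm[hit, .(group, chromosome, position, mean_prob)]
      d[, class_label := cl]
      out[[length(out) + 1L]] <- d
    }
  }
  if (!is.null(complement)) {
    all_gr <- GenomicRanges::GRanges(regions$chromosome,
                                     IRanges::IRanges(regions$start,
                                                      regions$end))
    miss <- !IRanges::overlapsAny(site_gr, all_gr)
    if (any(miss)) {
      d <- sm[miss, .(group, chromosome, position, mean_prob)]
      d[, class_label := complement]
      out[[length(out) + 1L]] <- d
    }
  }
  if (length(out) == 0L) {
    return(data.table(class_label = character(), group = character(),
                      chromosome = character(), position = integer(),
                      mean_prob = numeric()))
  }
  res <- rbindlist(out)
  data.table::setcolorder(res, c("class_label", "group", "chromosome",
                                 "position", "mean_prob"))
  res[]
}
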