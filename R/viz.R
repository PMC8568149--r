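#' @name viz
#' @title Methylation figures
#'
#' @description
#' ggplot2 renderings of the four figure families: per-read spaghetti plots
#' (thin smoothed per-read lines with a thick per-group trend, CpG-site tick
#' marks, exon track and DMR shading), per-read heatmaps with lane-packed
#' reads, aggregate feature profiles on the relative axis, embedding
#' scatters, and region-class box plots. All functions return ggplot objects
#' so they can be composed and saved with the usual tooling.
NULL

.records_with_groups <- function(store, chromosome, start, end,
                                 samples = NULL) {
  recs <- query_region(store, chromosome, start, end)
  if (nrow(recs) == 0L) {
    stop(sprintf("no methylation records in %s:%d-%d", chromosome,
                 as.integer(start), as.integer(end)), call. = FALSE)
  }
  if (is.null(samples)) samples <- store$samples
  recs <- copy(recs)
  recs[, group := .grouping_column(recs, "group", samples)]
  # groups with no records are dropped; warn so panels are not silently absent
  absent <- setdiff(unique(samples$group), unique(recs$group))
  if (length(absent) > 0L) {
    warning("no records in region for group(s): ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  recs[, group := factor(group, levels = unique(samples$group))]
  recs
}

#' Assign reads to non-overlapping display lanes
#'
#' Greedy first-fit interval packing: reads are taken in ascending span
#' start (ties by `read_id`) and each is placed in the lowest lane whose
#' current end is strictly less than the read's start. On interval graphs
#' first-fit by start is optimal, so the number of lanes equals the maximum
#' overlap depth.
#'
#' @param starts,ends integer span bounds (closed intervals).
#' @param read_id optional ids used to break start ties deterministically.
#' @return Integer lane indices (1-based) in input order.
#' @export
pack_reads <- function(starts, ends, read_id = NULL) {
  n <- length(starts)
  stopifnot(length(ends) == n, all(ends >= starts))
  if (n == 0L) return(integer())
  if (is.null(read_id)) read_id <- as.character(seq_len(n))
  ord <- order(starts, read_id)
  lane_end <- numeric()
  lanes <- integer(n)
  for (i in ord) {
    free <- which(lane_end < starts[i])
    if (length(free) == 0L) {
      lane_end <- c(lane_end, ends[i])
      lanes[i] <- length(lane_end)
    } else {
      lanes[i] <- free[1L]
      lane_end[free[1L]] <- ends[i]
    }
  }
  lanes
}

.dmr_shading <- function(dmrs, chrom, wstart, wend, top_n) {
  if (is.null(dmrs) || nrow(dmrs) == 0L) return(NULL)
  d <- as.data.table(dmrs)
  setorderv(d, "rank_stat", order = -1L)
  d <- head(d, top_n)
  d <- d[d$chromosome == chrom & d$start <= wend & d$end >= wstart]
  if (nrow(d) == 0L) return(NULL)
  d
}

.exon_track <- function(annotation, chrom, wstart, wend) {
  if (is.null(annotation)) return(NULL)
  ex <- annotation$exons
  ex <- ex[ex$chromosome == chrom & ex$start <= wend & ex$end >= wstart]
  if (nrow(ex) == 0L) return(NULL)
  ex
}

#' Spaghetti plot of per-read methylation in a region
#'
#' Draws each read's sigmoid-transformed calls as a thin line (smoothed along
#' the read when it carries at least 5 sites), a thick per-group trend built
#' from per-site means followed by lowess smoothing, tick marks at every
#' distinct CpG site in the window, merged exons below the x-axis, and light
#' grey shading over the `top_n` highest-ranked DMRs that overlap the
#' window.
#'
#' @param store a `methy_store`.
#' @param chromosome,start,end window to plot (1-based closed).
#' @param samples optional sample sheet overriding the store's.
#' @param annotation optional `exon_annotation` for the exon track.
#' @param dmrs optional DMR table with columns `chromosome`, `start`, `end`,
#'   `rank_stat` (larger = more differential).
#' @param top_n number of top-ranked DMRs eligible for shading.
#' @param span lowess span for the group trend.
#' @param read_span lowess span for individual reads.
#' @return A ggplot object.
#' @export
plot_spaghetti <- function(store, chromosome, start, end, samples = NULL,
                           annotation = NULL, dmrs = NULL, top_n = 500L,
                           span = 0.2, read_span = 0.6) {
  recs <- .records_with_groups(store, chromosome, start, end, samples)
  recs[, prob := sigmoid(statistic)]
  read_lines <- recs[, {
    s <- smooth_curve(position, prob, span = read_span)
    .(position = s$x, prob = s$y)
  }, by = .(group, read_id)]
  trend <- per_site_means(recs, "group",
                          if (is.null(samples)) store$samples else samples)
  trend_lines <- trend[, {
    s <- smooth_curve(position, mean_prob, span = span)
    .(position = s$x, prob = s$y)
  }, by = group]
  ticks <- sort(unique(recs$position))

  p <- ggplot2::ggplot()
  shade <- .dmr_shading(dmrs, chromosome, start, end, top_n)
  if (!is.null(shade)) {
    p <- p + ggplot2::annotate("rect", xmin = pmax(shade$start, start),
                               xmax = pmin(shade$end, end),
                               ymin = -Inf, ymax = Inf,
                               fill = "grey80", alpha = 0.6)
  }
  p <- p +
    ggplot2::geom_line(
      data = read_lines,
      ggplot2::aes(position, prob, group = interaction(group, read_id),
                   colour = group),
      linewidth = 0.25, alpha = 0.35) +
    ggplot2::geom_line(
      data = trend_lines,
      ggplot2::aes(position, prob, colour = group),
      linewidth = 1.2) +
    ggplot2::annotate("segment", x = ticks, xend = ticks,
                      y = -0.02, yend = 0, linewidth = 0.2)
  ex <- .exon_track(annotation, chromosome, start, end)
  if (!is.null(ex)) {
    p <- p + ggplot2::annotate("rect", xmin = pmax(ex$start, start),
                               xmax = pmin(ex$end, end),
                               ymin = -0.1, ymax = -0.05, fill = "grey30")
  }
  p + ggplot2::coord_cartesian(xlim = c(start, end),
                               ylim = c(-0.1, 1), expand = FALSE) +
    ggplot2::labs(x = sprintf("%s position (bp)", chromosome),
                  y = "methylation probability", colour = "group") +
    ggplot2::theme_minimal()
}

#' Per-read methylation heatmap of a region
#'
#' One row per read, packed into lanes within each group panel so spans never
#' overlap; one cell per called site, coloured by methylation probability on
#' a fixed diverging scale anchored at 0.5 (a log-likelihood ratio of 0). No
#' smoothing is applied. Cell width defaults to a fixed fraction of the
#' window so sparse CpG sites stay visible; set `cell_width` to a bp value
#' for bp-proportional cells.
#'
#' @inheritParams plot_spaghetti
#' @param cell_width cell width in bp; default `(end - start) / 150`.
#' @return A ggplot object.
#' @export
plot_heatmap <- function(store, chromosome, start, end, samples = NULL,
                         cell_width = NULL) {
  recs <- .records_with_groups(store, chromosome, start, end, samples)
  recs[, prob := sigmoid(statistic)]
  spans <- recs[, .(start = min(position), end = max(position)),
                by = .(group, read_id)]
  spans[, lane := pack_reads(start, end, read_id), by = group]
  recs <- merge(recs, spans[, .(group, read_id, lane)],
                by = c("group", "read_id"))
  if (is.null(cell_width)) cell_width <- max(1, (end - start) / 150)
  ggplot2::ggplot(recs,
                  ggplot2::aes(position, lane, fill = prob)) +
    ggplot2::geom_tile(width = cell_width, height = 0.85) +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "#ffffbf",
                                  high = "#a50026", midpoint = 0.5,
                                  limits = c(0, 1),
                                  name = "P(methylated)") +
    ggplot2::facet_grid(group ~ ., scales = "free_y", space = "free_y") +
    ggplot2::coord_cartesian(xlim = c(start, end)) +
    ggplot2::labs(x = sprintf("%s position (bp)", chromosome), y = "read") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot aggregate feature profiles
#'
#' Renders the curves from [aggregate_features()]: one smoothed line per
#' group over the relative feature axis, with vertical guides at 0 and 1
#' marking the feature start and end.
#'
#' @param curves a `profile_curve` table from [aggregate_features()].
#' @param span lowess span applied per group.
#' @return A ggplot object.
#' @export
plot_aggregate <- function(curves, span = 0.3) {
  curves <- as.data.table(curves)
  stopifnot(nrow(curves) > 0L)
  smoothed <- curves[, {
    s <- smooth_curve(x, y, span = span)
    .(x = s$x, y = s$y)
  }, by = group]
  ggplot2::ggplot(smoothed, ggplot2::aes(x, y, colour = group)) +
    ggplot2::geom_vline(xintercept = c(0, 1), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "relative position", y = "methylation probability",
                  colour = "group") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot a sample embedding
#'
#' Scatter of the first two embedding dimensions, coloured by group and
#' labelled by sample. PCA axes carry the percentage of variance explained.
#'
#' @param embedding a `methy_embedding`.
#' @param groups optional vector (or sample sheet) of group labels per
#'   sample.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, groups = NULL) {
  stopifnot(inherits(embedding, "methy_embedding"))
  co <- embedding$coordinates
  d <- data.table(sample_id = rownames(co), dim1 = co[, 1L],
                  dim2 = co[, 2L])
  if (is.data.frame(groups)) {
    d[, group := groups$group[match(sample_id, groups$sample_id)]]
  } else if (!is.null(groups)) {
    d[, group := rep_len(groups, nrow(d))]
  } else {
    d[, group := "all"]
  }
  axis_name <- function(i) {
    if (embedding$method == "PCA") {
      sprintf("PC-%d (%.1f%% var)", i, 100 * embedding$explained[i])
    } else {
      sprintf("MDS-%d", i)
    }
  }
  ggplot2::ggplot(d, ggplot2::aes(dim1, dim2, colour = group,
                                  label = sample_id)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1, show.legend = FALSE) +
    ggplot2::labs(x = axis_name(1L), y = axis_name(2L), colour = "group") +
    ggplot2::theme_minimal()
}

#' Box plot of per-site methylation by region class
#'
#' Renders the pooled per-site distributions from [region_summary()] as box
#' plots, one box per (region class, group).
#'
#' @param summary output of [region_summary()].
#' @return A ggplot object.
#' @export
plot_region_summary <- function(summary) {
  summary <- as.data.table(summary)
  stopifnot(nrow(summary) > 0L)
  ggplot2::ggplot(summary,
                  ggplot2::aes(class_label, mean_prob, fill = group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "region class", y = "per-site mean probability",
                  fill = "group") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
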