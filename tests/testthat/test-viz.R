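small_plot_store <- function() {
  pos <- seq(1000L, 2000L, by = 100L)
  recs <- rbindlist(list(
    make_records("s1", "chr1", pos, statistic = logit(0.9),
                 read_id = "read_a"),
    make_records("s1", "chr1", pos + 40L, statistic = logit(0.1),
                 read_id = "read_b"),
    make_records("s2", "chr1", pos, statistic = logit(0.8),
                 read_id = "read_c")))
  temp_store(recs, samples = data.frame(sample_id = c("s1", "s2"),
                                        group = c("mat", "pat")))
}

test_that("GTF exons are merged per gene and looked up by symbol", {
  ann <- read_annotation(write_gtf_fixture())
  g1 <- ann$exons[ann$exons$gene_id == "g1", ]
  expect_equal(nrow(g1), 1L)  # [100,200] + [150,300] merge to [100,300]
  expect_equal(c(g1$start, g1$end), c(100L, 300L))
  g2 <- ann$genes[ann$genes$gene_id == "g2", ]
  expect_equal(g2$strand, "-")
  loc <- methtrace:::.resolve_feature(ann, "GeneC")
  expect_equal(loc$chromosome, "chr2")
  expect_equal(c(loc$start, loc$end), c(1000L, 1400L))
})

test_that("annotation without exon features is a format error", {
  f <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "x", "gene", 1, 10, ".", "+", ".",
                   'gene_id "g";', sep = "\t"), f)
  expect_error(read_annotation(f), "exon")
})

test_that("read packing is first-fit and uses one lane per clique member", {
  # pairwise disjoint reads all land in lane 1
  expect_equal(pack_reads(c(1, 10, 20), c(5, 15, 25)), c(1L, 1L, 1L))
  # k mutually overlapping reads need k lanes
  expect_equal(sort(pack_reads(c(1, 2, 3, 4), c(100, 100, 100, 100))),
               1:4)
  # adjacent closed intervals (end == next start) still conflict
  expect_equal(pack_reads(c(1, 5), c(5, 9)), c(1L, 2L))
  expect_equal(pack_reads(c(1, 6), c(5, 9)), c(1L, 1L))
})

test_that("lane count equals the sweep-line maximum overlap depth", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    starts <- sample.int(500L, n, replace = TRUE)
    ends <- starts + sample.int(80L, n, replace = TRUE)
    lanes <- pack_reads(starts, ends)
    expect_equal(max(lanes), max_overlap_depth(starts, ends))
    # no two reads in a lane overlap
    for (l in unique(lanes)) {
      idx <- which(lanes == l)
      if (length(idx) > 1L) {
        o <- order(starts[idx])
        expect_true(all(starts[idx][o][-1] > head(ends[idx][o], -1)))
      }
    }
  }
})

test_that("spaghetti plots carry reads, trends, ticks and DMR shading", {
  st <- small_plot_store()
  dmrs <- data.frame(chromosome = "chr1", start = c(1200L, 9000L),
                     end = c(1500L, 9500L), rank_stat = c(5, 10))
  p <- plot_spaghetti(st, "chr1", 1000, 2100, dmrs = dmrs)
  expect_s3_class(p, "ggplot")
  b <- ggplot2::ggplot_build(p)
  # tick marks: one per distinct site position in the window
  recs <- query_region(st, "chr1", 1000, 2100)
  n_sites <- length(unique(recs$position))
  seg <- b$data[[which(vapply(p$layers, function(l)
    inherits(l$geom, "GeomSegment"), logical(1)))]]
  expect_equal(nrow(seg), n_sites)
  # the in-window DMR is shaded, the outside one is not
  rect_layers <- which(vapply(p$layers, function(l)
    inherits(l$geom, "GeomRect"), logical(1)))
  rect <- b$data[[rect_layers[1]]]
  expect_equal(nrow(rect), 1L)
  expect_equal(c(rect$xmin, rect$xmax), c(1200, 1500))
})

test_that("DMRs outside the window or rank cut-off draw no shading", {
  st <- small_plot_store()
  outside <- data.frame(chromosome = "chr1", start = 9000L, end = 9500L,
                        rank_stat = 1)
  p <- plot_spaghetti(st, "chr1", 1000, 2100, dmrs = outside)
  has_rect <- any(vapply(p$layers, function(l)
    inherits(l$geom, "GeomRect"), logical(1)))
  expect_false(has_rect)
  # rank cut: only the top_n DMRs are eligible
  two <- data.frame(chromosome = "chr1", start = c(1100L, 1600L),
                    end = c(1300L, 1800L), rank_stat = c(1, 2))
  p2 <- plot_spaghetti(st, "chr1", 1000, 2100, dmrs = two, top_n = 1L)
  b2 <- ggplot2::ggplot_build(p2)
  rect2 <- b2$data[[which(vapply(p2$layers, function(l)
    inherits(l$geom, "GeomRect"), logical(1)))[1]]]
  expect_equal(nrow(rect2), 1L)
  expect_equal(rect2$xmin, 1600)
})

test_that("heatmaps draw one cell per called site at a fixed midpoint scale", {
  st <- small_plot_store()
  p <- plot_heatmap(st, "chr1", 1000, 2100)
  b <- ggplot2::ggplot_build(p)
  recs <- query_region(st, "chr1", 1000, 2100)
  expect_equal(nrow(b$data[[1]]), nrow(recs))  # one tile per call
  # colour scale anchored at p = 0.5 with limits [0, 1]
  fill <- p$scales$get_scales("fill")
  expect_equal(fill$limits, c(0, 1))
  mid_col <- fill$palette(0.5)
  expect_equal(toupper(mid_col), "#FFFFBF")
})

test_that("region plots error informatively on empty windows", {
  st <- small_plot_store()
  expect_error(plot_spaghetti(st, "chr1", 5000, 6000), "no methylation")
  expect_error(plot_heatmap(st, "chr1", 5000, 6000), "no methylation")
})

test_that("groups without records are dropped with a warning, not a crash", {
  st <- small_plot_store()
  # only s1 (mat) covers 1040..1040 + 40 offsets; pat has no record there
  expect_warning(p <- plot_heatmap(st, "chr1", 1035, 1045), "pat")
  expect_s3_class(p, "ggplot")
})

test_that("aggregate and embedding plots render their inputs", {
  recs <- make_records(position = seq(1000L, 3000L, 100L),
                       statistic = logit(0.7),
                       read_id = sprintf("r%02d", 1:21))
  ft <- feature_set("chr1", 1000L, 3000L, "+", "f1")
  sheet <- data.frame(sample_id = "s1", group = "g1")
  curves <- aggregate_features(recs, ft, flank = 500L, n_bins = 20L,
                               samples = sheet)
  p <- plot_aggregate(curves)
  expect_s3_class(p, "ggplot")
  b <- ggplot2::ggplot_build(p)
  vl <- b$data[[which(vapply(p$layers, function(l)
    inherits(l$geom, "GeomVline"), logical(1)))]]
  expect_equal(sort(vl$xintercept), c(0, 1))

  pm <- planar_matrix()
  emb <- pca_embedding(pm$m)
  pe <- plot_embedding(emb, groups = c("a", "a", "b", "b"))
  expect_s3_class(pe, "ggplot")
  be <- ggplot2::ggplot_build(pe)
  expect_equal(nrow(be$data[[1]]), 4L)  # one point per sample
  expect_match(pe$labels$x, "PC-1 \\(\\d+\\.\\d% var\\)")
})

test_that("plot construction is deterministic across repeated calls", {
  st <- small_plot_store()
  b1 <- ggplot2::ggplot_build(plot_spaghetti(st, "chr1", 1000, 2100))
  b2 <- ggplot2::ggplot_build(plot_spaghetti(st, "chr1", 1000, 2100))
  expect_equal(b1$data, b2$data)
})

test_that("region-class box plots show one box per class and group", {
  recs <- make_records(position = seq(100L, 1000L, 100L),
                       statistic = logit(seq(0.1, 0.9, length.out = 10)),
                       read_id = sprintf("r%02d", 1:10))
  sheet <- data.frame(sample_id = "s1", group = "g1")
  rs <- region_summary(
    recs, data.frame(chromosome = "chr1", start = 1L, end = 500L,
                     class_label = "promoter"),
    samples = sheet, complement = "other")
  p <- plot_region_summary(rs)
  expect_s3_class(p, "ggplot")
  b <- ggplot2::ggplot_build(p)
  expect_equal(nrow(b$data[[1]]), 2L)
})
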