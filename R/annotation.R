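#' @name annotation
#' @title Feature tables and gene annotation
#'
#' @description
#' Aggregate profiles and region summaries work from a plain feature table
#' (chromosome, 1-based closed start/end, strand, feature id, class label).
#' Tables can be built directly with [feature_set()], read from BED (0-based
#' half-open, converted on import), or derived from a GTF/GFF gene annotation
#' read with [read_annotation()], which also supplies the merged exon
#' intervals drawn under region plots and the symbol lookup behind
#' [query_genes()].
NULL

#' Build a feature table
#'
#' @param chromosome,start,end vectors describing the features; coordinates
#'   are 1-based, closed.
#' @param strand `"+"`, `"-"` or `"."` per feature (`"."` is treated as
#'   `"+"` wherever orientation matters).
#' @param feature_id unique feature identifiers.
#' @param class_label optional class grouping (e.g. "promoter").
#'
#' @return A `data.table` with the columns above.
#' @export
feature_set <- function(chromosome, start, end, strand = ".",
                        feature_id = NULL, class_label = "feature") {
  n <- length(chromosome)
  if (is.null(feature_id)) feature_id <- sprintf("feature_%d", seq_len(n))
  ft <- data.table(chromosome = as.character(chromosome),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   feature_id = as.character(feature_id),
                   class_label = rep_len(as.character(class_label), n))
  if (any(ft$end < ft$start)) stop("feature end < start", call. = FALSE)
  if (anyDuplicated(ft$feature_id)) {
    stop("feature_id values must be unique", call. = FALSE)
  }
  if (!all(ft$strand %in% c("+", "-", "."))) {
    stop("strand must be one of +, -, .", call. = FALSE)
  }
  ft[]
}

#' Read features from a BED file
#'
#' BED coordinates (0-based, half-open) are converted to the package's
#' 1-based closed convention. Name and strand columns are used when present.
#'
#' @param file path to a BED file.
#' @param class_label class assigned to all features.
#' @return A feature table as from [feature_set()].
#' @export
read_bed <- function(file, class_label = "feature") {
  gr <- rtracklayer::import(file, format = "BED")
  nm <- if (!is.null(gr$name) && !anyNA(gr$name) &&
            !anyDuplicated(gr$name)) gr$name else NULL
  feature_set(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr), GenomicRanges::end(gr),
              as.character(GenomicRanges::strand(gr)),
              feature_id = nm, class_label = class_label)
}

#' Read gene/exon annotation from GTF or GFF
#'
#' Collects `exon` features per gene, merges overlapping exons, and indexes
#' genes by symbol (`gene_name`, falling back to `gene_id`). The result feeds
#' the exon tracks of the region plots and gene-symbol queries.
#'
#' @param file path to a GTF/GFF file.
#' @return An `exon_annotation` object: `$genes` (one row per gene:
#'   `gene_id`, `symbol`, `chromosome`, `strand`, `start`, `end`) and
#'   `$exons` (merged exon intervals per gene).
#' @export
read_annotation <- function(file) {
  gr <- rtracklayer::import(file)
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) {
    stop("annotation contains no exon features", call. = FALSE)
  }
  gene_id <- as.character(gr$gene_id)
  if (all(is.na(gene_id))) {
    stop("exon features carry no gene_id attribute", call. = FALSE)
  }
  symbol <- if (!is.null(gr$gene_name)) as.character(gr$gene_name) else
    gene_id
  symbol[is.na(symbol)] <- gene_id[is.na(symbol)]
  ex <- data.table(gene_id = gene_id, symbol = symbol,
                   chromosome = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr))
  # merge overlapping exons within each gene
  merged <- ex[, {
    r <- IRanges::reduce(IRanges::IRanges(start, end))
    .(start = IRanges::start(r), end = IRanges::end(r))
  }, by = .(gene_id, symbol, chromosome, strand)]
  setorderv(merged, c("gene_id", "start"))
  genes <- merged[, .(start = min(start), end = max(end)),
                  by = .(gene_id, symbol, chromosome, strand)]
  structure(list(genes = genes, exons = merged), class = "exon_annotation")
}

#' @export
print.exon_annotation <- function(x, ...) {
  cat(sprintf("exon_annotation: %d genes, %d merged exons\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Convert gene annotation to a feature table
#'
#' @param annotation an `exon_annotation`.
#' @param class_label class assigned to all genes.
#' @return A feature table of gene spans (see [feature_set()]).
#' @export
genes_as_features <- function(annotation, class_label = "gene") {
  stopifnot(inherits(annotation, "exon_annotation"))
  g <- annotation$genes
  feature_set(g$chromosome, g$start, g$end, g$strand,
              feature_id = g$symbol, class_label = class_label)
}

# Resolve a symbol/feature id to one (chromosome, start, end, strand).
.resolve_feature <- function(features, name) {
  if (inherits(features, "exon_annotation")) {
    tab <- features$genes
    hits <- which(tab$symbol == name | tab$gene_id == name)
    ids <- tab$symbol
  } else {
    tab <- as.data.table(features)
    hits <- which(tab$feature_id == name)
    ids <- tab$feature_id
  }
  if (length(hits) == 0L) {
    near <- unique(agrep(name, ids, value = TRUE, max.distance = 0.3))
    stop("unknown feature: ", name,
         if (length(near) > 0L) paste0(" (near matches: ",
                                       paste(head(near, 5L), collapse = ", "),
                                       ")") else "",
         call. = FALSE)
  }
  if (length(hits) > 1L) {
    stop("ambiguous feature name: ", name, " matches ", length(hits),
         " features", call. = FALSE)
  }
  as.list(tab[hits, c("chromosome", "start", "end", "strand"), with = FALSE])
}
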