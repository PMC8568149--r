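library(data.table)

# --- caller-format text fixtures, built in code -----------------------------

nanopolish_header <- paste(
  c("chromosome", "strand", "start", "end", "read_name", "log_lik_ratio",
    "log_lik_methylated", "log_lik_unmethylated", "num_calling_strands",
    "num_motifs", "sequence"),
  collapse = "\t")

nanopolish_line <- function(chrom = "chr1", strand = "+", start = 1000,
                            end = start, read = "read1", llr = 2.5,
                            num_motifs = 1, sequence = "AAACGAAA") {
  paste(chrom, strand, start, end, read, llr, llr, 0, 1, num_motifs,
        sequence, sep = "\t")
}

write_nanopolish_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(nanopolish_header, lines), f)
  f
}

megalodon_header <- paste(
  c("read_id", "chrm", "strand", "pos", "mod_log_prob", "can_log_prob",
    "mod_base"),
  collapse = "\t")

megalodon_line <- function(read = "read1", chrom = "chr1", strand = "+",
                           pos = 100, mod = log(0.9), can = log(0.1)) {
  paste(read, chrom, strand, pos, mod, can, "m", sep = "\t")
}

write_megalodon_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(megalodon_header, lines), f)
  f
}

# --- record / store builders ------------------------------------------------

make_records <- function(sample_id = "s1", chromosome = "chr1",
                         position = 100L, statistic = 1,
                         read_id = "r1") {
  data.table(sample_id = sample_id, chromosome = chromosome,
             position = as.integer(position), statistic = statistic,
             read_id = read_id)
}

temp_store <- function(records, samples = NULL, chunk_size = 1000000L) {
  build_store(records, tempfile(fileext = ".tsv"), samples = samples,
              chunk_size = chunk_size)
}

# canonical representation for multiset comparison of record tables
record_multiset <- function(dt) {
  sort(paste(dt$sample_id, dt$chromosome, dt$position,
             sprintf("%.6g", dt$statistic), dt$read_id, sep = "|"))
}

# linear-scan oracle over an uncompressed copy of the store
scan_oracle <- function(store, chromosome, start, end) {
  all <- read_store(store)
  keep <- all$chromosome == chromosome & all$position >= start &
    all$position <= end
  all[which(keep)]
}

# two-group landscape under the study conditions used throughout the tests
two_group_landscape <- function(delta = 0.4, coverage = 50,
                                chrom_len = 20000L, spacing = 100L) {
  methyl_landscape(
    chromosome_lengths = c(chrT = chrom_len),
    cpg_spacing = spacing,
    groups = c("grpA", "grpB"),
    background_mu = c(0.5 + delta / 2, 0.5 - delta / 2),
    coverage = coverage)
}

# simulate a 3 + 3 two-group record table (no file round trip)
simulate_two_group_records <- function(seed, delta = 0.4, coverage = 50) {
  ls_ <- two_group_landscape(delta, coverage)
  groups <- rep(c("grpA", "grpB"), each = 3)
  ids <- paste0(rep(c("A", "B"), each = 3), 1:3)
  recs <- rbindlist(lapply(seq_along(ids), function(i) {
    simulate_reads(ls_, ids[i], groups[i], seed = seed * 101L + i)$records
  }))
  list(records = recs,
       samples = data.frame(sample_id = ids, group = groups))
}

# minimal 3-gene GTF fixture
write_gtf_fixture <- function() {
  f <- tempfile(fileext = ".gtf")
  attrs <- function(id, name) {
    sprintf('gene_id "%s"; gene_name "%s";', id, name)
  }
  rows <- c(
    paste("chr1", "test", "exon", 100, 200, ".", "+", ".",
          attrs("g1", "GeneA"), sep = "\t"),
    paste("chr1", "test", "exon", 150, 300, ".", "+", ".",
          attrs("g1", "GeneA"), sep = "\t"),
    paste("chr1", "test", "exon", 500, 600, ".", "-", ".",
          attrs("g2", "GeneB"), sep = "\t"),
    paste("chr2", "test", "exon", 1000, 1100, ".", "+", ".",
          attrs("g3", "GeneC"), sep = "\t"),
    paste("chr2", "test", "exon", 1300, 1400, ".", "+", ".",
          attrs("g3", "GeneC"), sep = "\t"))
  writeLines(rows, f)
  f
}

# 4 samples constructed as exact 2-D points, lifted into 6 "sites" so that
# the RMS site-difference distance equals the planar Euclidean distance
planar_matrix <- function() {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4), c(3, 4))
  lift <- matrix(0, nrow = 6, ncol = 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  lift[1, ] <- pts[, 1]
  lift[2, ] <- pts[, 2]
  list(m = lift * sqrt(6), pts = pts)
}

# sweep-line oracle: maximum overlap depth of closed intervals
max_overlap_depth <- function(starts, ends) {
  max(vapply(seq_along(starts), function(i) {
    sum(starts <= starts[i] & ends >= starts[i])
  }, integer(1L)))
}
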