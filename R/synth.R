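#' @name synth
#' @title Synthetic nanopore methylation data with known ground truth
#'
#' @description
#' A seeded generator of caller-format methylation calls over a declared
#' methylation landscape, so every part of the package can be exercised and
#' validated without any external dataset. The landscape fixes CpG positions
#' and a per-group methylation level surface (a background level overlaid
#' with regions such as TSS dips or group-specific DMRs); reads are placed
#' uniformly with lognormal lengths, each (read, site) pair draws a single
#' methylated/unmethylated state from the local level — so per-read
#' trajectories are molecule-consistent — and the emitted log-likelihood
#' ratio is Normal(+m, s) for methylated and Normal(-m, s) for unmethylated
#' states. With the defaults (m = 4, s = 1.5) most calls are confident while
#' a realistic tail lands near probability 0.5.
NULL

#' Declare a methylation landscape
#'
#' @param chromosome_lengths named integer vector of chromosome lengths.
#' @param cpg_spacing regular spacing (bp) between CpG sites; sites are
#'   placed deterministically at `cpg_spacing / 2, 3 cpg_spacing / 2, ...`.
#' @param groups experimental group labels.
#' @param background_mu methylation level per group outside any region
#'   (recycled over groups).
#' @param regions optional data.frame with columns `chromosome`, `start`,
#'   `end`, `group`, `mu` overriding the background for one group within an
#'   interval; later rows win where regions overlap.
#' @param coverage mean read coverage per chromosome.
#' @param read_length_median,read_length_sdlog lognormal read length model.
#' @param llr_mean,llr_sd the two-component call model: methylated states
#'   emit `Normal(llr_mean, llr_sd)`, unmethylated `Normal(-llr_mean,
#'   llr_sd)`.
#' @param grouped_fraction fraction of nanopolish-dialect calls grouped into
#'   two-motif calls (where adjacent sites on a read allow it).
#'
#' @return A `methyl_landscape` object.
#' @export
methyl_landscape <- function(chromosome_lengths = c(chrS = 60000L),
                             cpg_spacing = 100L,
                             groups = c("grpA", "grpB"),
                             background_mu = 0.7,
                             regions = NULL,
                             coverage = 20,
                             read_length_median = 3000,
                             read_length_sdlog = 0.35,
                             llr_mean = 4, llr_sd = 1.5,
                             grouped_fraction = 0.1) {
  stopifnot(!is.null(names(chromosome_lengths)),
            all(chromosome_lengths > 0L),
            all(background_mu >= 0 & background_mu <= 1),
            grouped_fraction >= 0, grouped_fraction <= 1)
  background_mu <- rep_len(background_mu, length(groups))
  names(background_mu) <- groups
  if (!is.null(regions)) {
    regions <- as.data.table(regions)
    stopifnot(all(c("chromosome", "start", "end", "group", "mu") %in%
                    names(regions)))
    if (any(regions$mu < 0 | regions$mu > 1)) {
      stop("region mu outside [0, 1]", call. = FALSE)
    }
    bad <- !regions$chromosome %in% names(chromosome_lengths) |
      regions$start < 1L |
      regions$end > chromosome_lengths[regions$chromosome]
    if (any(bad)) stop("region outside chromosome bounds", call. = FALSE)
  }
  cpg <- lapply(chromosome_lengths, function(len) {
    as.integer(seq(max(1L, cpg_spacing %/% 2L), len, by = cpg_spacing))
  })
  structure(list(chromosome_lengths = chromosome_lengths,
                 cpg_positions = cpg, groups = groups,
                 background_mu = background_mu, regions = regions,
                 coverage = coverage,
                 read_length_median = read_length_median,
                 read_length_sdlog = read_length_sdlog,
                 llr_mean = llr_mean, llr_sd = llr_sd,
                 grouped_fraction = grouped_fraction),
            class = "methyl_landscape")
}

#' True per-site methylation levels of a landscape
#'
#' @param landscape a `methyl_landscape`.
#' @return A `data.table` with columns `chromosome`, `position`, `group`,
#'   `mu`.
#' @export
landscape_truth <- function(landscape) {
  stopifnot(inherits(landscape, "methyl_landscape"))
  out <- rbindlist(lapply(names(landscape$cpg_positions), function(chrom) {
    pos <- landscape$cpg_positions[[chrom]]
    rbindlist(lapply(landscape$groups, function(g) {
      mu <- rep(landscape$background_mu[[g]], length(pos))
      rg <- landscape$regions
      if (!is.null(rg)) {
        rg <- rg[rg$chromosome == chrom & rg$group == g]
        for (i in seq_len(nrow(rg))) {
          mu[pos >= rg$start[i] & pos <= rg$end[i]] <- rg$mu[i]
        }
      }
      data.table(chromosome = chrom, position = pos, group = g, mu = mu)
    }))
  }))
  setorderv(out, c("chromosome", "position", "group"))
  out[]
}

# One state + llr per call unit; grouped nanopolish calls share both.
.simulate_units <- function(landscape, group, seed) {
  set.seed(seed)
  truth <- landscape_truth(landscape)
  units <- list()
  for (chrom in names(landscape$chromosome_lengths)) {
    len <- landscape$chromosome_lengths[[chrom]]
    cpg <- landscape$cpg_positions[[chrom]]
    sel <- truth$chromosome == chrom & truth$group == group
    mu <- truth$mu[sel]
    mean_len <- landscape$read_length_median *
      exp(landscape$read_length_sdlog^2 / 2)
    n_reads <- max(1L, as.integer(round(landscape$coverage * len /
                                          mean_len)))
    rstart <- sample.int(len, n_reads, replace = TRUE)
    rlen <- pmax(50, rlnorm(n_reads, log(landscape$read_length_median),
                            landscape$read_length_sdlog))
    rend <- pmin(len, as.integer(rstart + rlen - 1))
    i1 <- findInterval(rstart - 1L, cpg) + 1L
    i2 <- findInterval(rend, cpg)
    nsites <- pmax(0L, i2 - i1 + 1L)
    keep <- nsites > 0L
    if (!any(keep)) next
    idx <- sequence(nsites[keep], from = i1[keep])
    read_no <- rep(which(keep), nsites[keep])
    dt <- data.table(
      chromosome = chrom,
      read_id = sprintf("%s_read_%06d", chrom, read_no),
      site_index = idx,
      position = cpg[idx],
      mu = mu[idx])
    # pair adjacent sites within a read into grouped units
    dt[, unit := seq_len(.N)]
    if (landscape$grouped_fraction > 0) {
      first_of_pair <- dt[, {
        cand <- seq_len(.N - 1L)
        cand <- cand[cand %% 2L == 1L]  # non-overlapping pairs
        take <- cand[runif(length(cand)) < landscape$grouped_fraction]
        flag <- rep(FALSE, .N)
        flag[take] <- TRUE
        .(flag = flag)
      }, by = read_id]$flag
      second <- c(FALSE, head(first_of_pair, -1L))
      dt[second, unit := unit - 1L]
    }
    units[[length(units) + 1L]] <- dt
  }
  all <- rbindlist(units)
  # one Bernoulli state and one LLR per unit, shared by its sites
  heads <- all[, .(mu = mu[1L]), by = .(read_id, unit)]
  heads[, state := rbinom(.N, 1L, mu)]
  # round once so emitted text files and in-memory records agree exactly
  heads[, statistic := round(rnorm(.N, fifelse(state == 1L,
                                               landscape$llr_mean,
                                               -landscape$llr_mean),
                                   landscape$llr_sd), 4L)]
  merge(all, heads[, .(read_id, unit, state, statistic)],
        by = c("read_id", "unit"), sort = FALSE)
}

#' Simulate caller-format methylation calls for one sample
#'
#' Draws reads and per-site calls from the landscape for the given group and
#' returns them as methylation records, optionally also writing
#' nanopolish-dialect and Megalodon-dialect TSVs plus the ground-truth table
#' to `dir`. Grouped nanopolish calls cover two adjacent CpGs with one
#' shared log-likelihood ratio and a sequence context whose CG offsets match
#' the genomic spacing. Output is deterministic given `seed`.
#'
#' @param landscape a `methyl_landscape`.
#' @param sample_id sample name for the emitted records/files.
#' @param group which landscape group this sample belongs to.
#' @param seed integer RNG seed.
#' @param dir optional output directory for caller-format files.
#'
#' @return A list with `records` (a `data.table` of methylation records),
#'   `truth` (per-site `mu` for the sample's group), and — when `dir` is
#'   given — `nanopolish_file`, `megalodon_file`, `truth_file`.
#' @export
simulate_reads <- function(landscape, sample_id, group, seed, dir = NULL) {
  stopifnot(inherits(landscape, "methyl_landscape"),
            group %in% landscape$groups)
  units <- .simulate_units(landscape, group, seed)
  records <- units[, .(sample_id = sample_id, chromosome, position,
                       statistic, read_id)]
  setorderv(records, c("chromosome", "position", "read_id"))
  truth <- landscape_truth(landscape)
  keep_rows <- truth$group == group  # evaluated outside [ to dodge masking
  truth <- truth[keep_rows]
  out <- list(records = records, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$nanopolish_file <- file.path(dir,
                                     paste0(sample_id, ".nanopolish.tsv"))
    .write_nanopolish(units, out$nanopolish_file)
    out$megalodon_file <- file.path(dir, paste0(sample_id, ".megalodon.tsv"))
    .write_megalodon(units, out$megalodon_file)
    out$truth_file <- file.path(dir, paste0(sample_id, ".truth.tsv"))
    write.table(truth, out$truth_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  out
}

.context_sequence <- function(gaps) {
  # CG occurrences at offsets 3 and 3 + gap within an A-padded context
  vapply(gaps, function(g) {
    if (is.na(g)) "AACGAAA" else
      paste0("AA", "CG", strrep("A", max(0L, g - 2L)), "CG", "AA")
  }, character(1L))
}

.write_nanopolish <- function(units, path) {
  calls <- units[, .(
    chromosome = chromosome[1L],
    start = position[1L] - 1L,
    end = position[.N] - 1L,
    num_motifs = .N,
    gap = if (.N > 1L) position[2L] - position[1L] else NA_integer_,
    log_lik_ratio = statistic[1L]
  ), by = .(read_id, unit)]
  setorderv(calls, c("read_id", "unit"))
  d <- data.frame(
    chromosome = calls$chromosome,
    strand = "+",
    start = calls$start,
    end = calls$end,
    read_name = calls$read_id,
    log_lik_ratio = sprintf("%.4f", calls$log_lik_ratio),
    log_lik_methylated = sprintf("%.4f", pmin(calls$log_lik_ratio, 0)),
    log_lik_unmethylated = sprintf("%.4f", pmin(-calls$log_lik_ratio, 0)),
    num_calling_strands = 1L,
    num_motifs = calls$num_motifs,
    sequence = .context_sequence(calls$gap))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_megalodon <- function(units, path) {
  p <- sigmoid(units$statistic)
  d <- data.frame(
    read_id = units$read_id,
    chrm = units$chromosome,
    strand = "+",
    pos = units$position - 1L,
    mod_log_prob = sprintf("%.6f", log(p)),
    can_log_prob = sprintf("%.6f", log1p(-p)),
    mod_base = "m")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
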