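#' Tumor/normal log-R-ratio copy-number track
#'
#' The copy-number signal is computed in four steps: (1) select SNP sites
#' that are homozygous (normal VAF <= 0.05 or >= 0.95) or heterozygous
#' (0.4-0.6) in the matched normal; (2) adjust normal and tumor depths for
#' local GC content; (3) compute the per-site log2 ratio of library-size
#' normalised tumor to normal depth; (4) take the median over a 1-Mb moving
#' window centred at each site as its representative LRR.
#'
#' @name cnv_lrr
NULL

#' Select SNP sites by normal-sample zygosity
#'
#' A site enters the copy-number computation only when its normal VAF is
#' consistent with a clean homozygous or heterozygous genotype; intermediate
#' VAFs (mapping artefacts, subclonal contamination) are excluded.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `normal_vaf`,
#'   `normal_depth`, `tumor_depth` and either `gc_fraction` or enough context
#'   to compute it.
#' @param hom_low,hom_high homozygous bands: VAF <= `hom_low` or >= `hom_high`.
#' @param het_low,het_high heterozygous band, inclusive on both ends.
#' @return the input with a `zygosity` factor (`homozygous`, `heterozygous`,
#'   `excluded`); rows marked `excluded` are dropped by downstream steps.
#' @examples
#' s <- data.frame(chrom = "chr1", pos = 1:3,
#'                 normal_vaf = c(0.50, 0.97, 0.20),
#'                 normal_depth = 100, tumor_depth = 100, gc_fraction = 0.4)
#' select_snp_sites(s)$zygosity
#' @export
select_snp_sites <- function(sites, hom_low = 0.05, hom_high = 0.95,
                             het_low = 0.4, het_high = 0.6) {
  stopifnot(is.data.frame(sites), !is.null(sites$normal_vaf),
            !any(is.na(sites$normal_vaf)))
  v <- sites$normal_vaf
  zyg <- rep("excluded", length(v))
  zyg[v <= hom_low | v >= hom_high] <- "homozygous"
  zyg[v >= het_low & v <= het_high] <- "heterozygous"
  sites$zygosity <- factor(zyg, levels = c("homozygous", "heterozygous", "excluded"))
  sites
}

#' GC-content depth adjustment
#'
#' Sequencing depth covaries with local GC content. Within each sample
#' independently, sites are binned by `gc_fraction` (default 1% bins) and
#' each site's depth is rescaled by (global median depth) / (median depth of
#' its bin). Median scaling is robust to copy-number outliers and exactly
#' reproducible, unlike a loess fit. A GC-unbiased track is left unchanged up
#' to bin granularity; bins whose median depth is 0 yield adjusted depth 0
#' and are flagged.
#'
#' @param sites selected sites (zygosity not `excluded`) with `normal_depth`,
#'   `tumor_depth` and `gc_fraction` columns.
#' @param bin_width GC-fraction bin width.
#' @return the input data.frame with `normal_adj` and `tumor_adj` columns and
#'   attribute `zero_gc_bins` (count of zero-median bins encountered).
#' @export
gc_adjust_depths <- function(sites, bin_width = 0.01) {
  stopifnot(is.data.frame(sites), bin_width > 0,
            !is.null(sites$gc_fraction),
            all(sites$gc_fraction >= 0 & sites$gc_fraction <= 1))
  if (!is.null(sites$zygosity)) {
    sites <- sites[sites$zygosity != "excluded", , drop = FALSE]
  }
  if (nrow(sites) == 0) stop("no sites left after zygosity selection")
  bin <- floor(sites$gc_fraction / bin_width)
  zero_bins <- 0L
  adjust_one <- function(depth) {
    if (all(depth == 0)) stop("all-zero depths: cannot GC-adjust")
    gmed <- stats::median(depth)
    bmed <- tapply(depth, bin, stats::median)
    fac <- gmed / bmed[as.character(bin)]
    zero <- !is.finite(fac)
    zero_bins <<- zero_bins + sum(zero)
    fac[zero] <- 0
    as.numeric(depth * fac)
  }
  sites$normal_adj <- adjust_one(sites$normal_depth)
  sites$tumor_adj <- adjust_one(sites$tumor_depth)
  attr(sites, "zero_gc_bins") <- zero_bins
  sites
}

#' Per-site log-R ratio
#'
#' LRR_i = log2( (t_i / T) / (n_i / N) ) with t_i, n_i the GC-adjusted tumor
#' and normal depths and T, N their totals over all evaluated sites
#' (library-size normalisation; `normalizer = "median"` uses the medians
#' instead). The track is invariant to rescaling either sample's depths by a
#' constant. Sites with zero adjusted depth in either sample are dropped, not
#' propagated as infinities; the dropped count is recorded.
#'
#' @param sites output of [gc_adjust_depths()].
#' @param normalizer `"sum"` (default) or `"median"`.
#' @return the evaluated sites with an `lrr` column; attribute
#'   `n_dropped_zero_depth` counts excluded sites.
#' @export
compute_lrr <- function(sites, normalizer = c("sum", "median")) {
  normalizer <- match.arg(normalizer)
  stopifnot(is.data.frame(sites),
            !is.null(sites$normal_adj), !is.null(sites$tumor_adj))
  ok <- sites$normal_adj > 0 & sites$tumor_adj > 0
  dropped <- sum(!ok)
  sites <- sites[ok, , drop = FALSE]
  if (nrow(sites) == 0) stop("no sites with positive adjusted depth")
  norm <- switch(normalizer, sum = base::sum, median = stats::median)
  Tn <- norm(sites$tumor_adj)
  Nn <- norm(sites$normal_adj)
  sites$lrr <- log2((sites$tumor_adj / Tn) / (sites$normal_adj / Nn))
  attr(sites, "n_dropped_zero_depth") <- dropped
  sites
}

#' Moving-window representative LRR
#'
#' For each site the representative LRR is the median of per-site LRR over
#' all sites on the same chromosome within `window_bp / 2` of it (a closed
#' 1-Mb window by default). Windows never span chromosomes, and the median is
#' reported only where at least `min_sites` sites fall in the window; the
#' median of an even count is the mean of the two central values.
#'
#' @param sites output of [compute_lrr()]; positions must be sorted within
#'   each chromosome.
#' @param window_bp full window width in bp.
#' @param min_sites minimum sites per window for a defined median.
#' @return the input with an `lrr_windowed` column (`NA` where undefined).
#' @export
windowed_lrr <- function(sites, window_bp = 1e6, min_sites = 10) {
  stopifnot(is.data.frame(sites), !is.null(sites$lrr), window_bp > 0)
  half <- window_bp / 2
  out <- rep(NA_real_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    if (is.unsorted(pos)) stop("positions unsorted within chromosome ", ch)
    lrr <- sites$lrr[idx]
    # two-pointer sweep over the sorted positions
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    for (k in seq_along(idx)) {
      if (hi[k] - lo[k] + 1L >= min_sites) {
        out[idx[k]] <- stats::median(lrr[lo[k]:hi[k]])
      }
    }
  }
  sites$lrr_windowed <- out
  sites
}

#' Full LRR pipeline
#'
#' Runs site selection, GC adjustment, per-site LRR and the moving-window
#' median in sequence.
#'
#' @inheritParams select_snp_sites
#' @inheritParams gc_adjust_depths
#' @inheritParams compute_lrr
#' @inheritParams windowed_lrr
#' @return data.frame with `lrr` and `lrr_windowed` columns.
#' @examples
#' sim <- sim_depth_tracks(sim_config(seed = 1, n_sites = 2000))
#' track <- lrr_pipeline(sim$sites)
#' summary(track$lrr_windowed)
#' @export
lrr_pipeline <- function(sites, hom_low = 0.05, hom_high = 0.95,
                         het_low = 0.4, het_high = 0.6, bin_width = 0.01,
                         normalizer = "sum", window_bp = 1e6, min_sites = 10) {
  sites <- select_snp_sites(sites, hom_low, hom_high, het_low, het_high)
  sites <- gc_adjust_depths(sites, bin_width)
  sites <- compute_lrr(sites, normalizer)
  windowed_lrr(sites, window_bp, min_sites)
}

#' GC fraction around positions from a FASTA reference
#'
#' Computes the G+C fraction of the window flanking each position (default
#' 50 bp each side, i.e. a 101-bp centred window), for site tables that do
#' not already carry a `gc_fraction` column. Windows are truncated at
#' sequence ends; ambiguous bases are excluded from the denominator.
#'
#' @param fasta path to a reference FASTA whose sequence names include the
#'   site chromosomes.
#' @param chrom,pos site coordinates (1-based).
#' @param flank bases on each side of the position.
#' @return numeric vector of GC fractions in \[0, 1\].
#' @export
gc_fraction_from_fasta <- function(fasta, chrom, pos, flank = 50) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("gc_fraction_from_fasta() requires the Biostrings package")
  }
  ref <- Biostrings::readDNAStringSet(fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  stopifnot(all(chrom %in% names(ref)), all(pos >= 1))
  vapply(seq_along(pos), function(i) {
    seqlen <- Biostrings::width(ref[chrom[i]])
    win <- Biostrings::subseq(ref[[chrom[i]]],
                              start = max(1, pos[i] - flank),
                              end = min(seqlen, pos[i] + flank))
    counts <- Biostrings::alphabetFrequency(win)
    acgt <- sum(counts[c("A", "C", "G", "T")])
    if (acgt == 0) return(NA_real_)
    sum(counts[c("G", "C")]) / acgt
  }, numeric(1))
}

#' Read a SNP-site table / write an LRR track
#'
#' The site TSV carries `chrom, pos, normal_vaf, normal_depth, tumor_depth,
#' gc_fraction` with 1-based positions.
#'
#' @param path file path.
#' @export
read_snp_sites_tsv <- function(path) {
  sites <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "normal_vaf", "normal_depth", "tumor_depth",
            "gc_fraction")
  missing <- setdiff(need, names(sites))
  if (length(missing) > 0) {
    stop("site table lacks columns: ", paste(missing, collapse = ", "))
  }
  stopifnot(all(sites$normal_depth >= 0), all(sites$tumor_depth >= 0),
            all(sites$gc_fraction >= 0 & sites$gc_fraction <= 1))
  sites
}

#' @rdname read_snp_sites_tsv
#' @param track output of [lrr_pipeline()] or [windowed_lrr()].
#' @export
write_lrr_track <- function(track, path) {
  keep <- intersect(c("chrom", "pos", "lrr", "lrr_windowed"), names(track))
  utils::write.table(track[, keep], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(track)
}
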