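#' Single-cell TCR clonotype analysis
#'
#' Per-cell contig evidence is resolved to beta-chain clonotypes under the
#' retention and UMI-ambiguity rules, cells are QC-filtered on mitochondrial
#' content and detected genes, and the resulting repertoires are summarised
#' by Pielou evenness, interlesion dominance and exhausted-clone enrichment.
#'
#' Clonotype identity is the TRB (V gene, J gene, CDR3 nucleotide) triple:
#' cells lacking a TCR alpha chain are kept while cells lacking a beta chain
#' are dropped, so the beta chain defines identity and alpha is annotation.
#'
#' @name tcr_clonotypes
NULL

#' Single-cell QC on cell metadata
#'
#' Cells with mitochondrial content above 10% are removed as dying cells;
#' cells with fewer than 200 or more than 4,000 detected genes are removed
#' as empty droplets and doublets respectively. The exclusions are strict,
#' so boundary cells (exactly 10% mitochondrial, exactly 200 or 4,000 genes)
#' are retained.
#'
#' @param cells data.frame with columns `barcode`, `sample`, `mito_fraction`,
#'   `n_genes` (and optionally `cluster`).
#' @param max_mito,min_genes,max_genes QC thresholds.
#' @return list with `retained` and `filtered` data.frames.
#' @export
qc_cells <- function(cells, max_mito = 0.10, min_genes = 200, max_genes = 4000) {
  stopifnot(is.data.frame(cells),
            all(c("barcode", "mito_fraction", "n_genes") %in% names(cells)),
            all(cells$mito_fraction >= 0 & cells$mito_fraction <= 1),
            all(cells$n_genes >= 0))
  ok <- cells$mito_fraction <= max_mito &
    cells$n_genes >= min_genes & cells$n_genes <= max_genes
  list(retained = cells[ok, , drop = FALSE],
       filtered = cells[!ok, , drop = FALSE])
}

#' Resolve per-cell clonotypes from contig evidence
#'
#' Candidate clonotypes of a cell are its distinct TRB
#' (v_gene, j_gene, cdr3_nt) triples, ranked by total UMI support. Cells
#' with no TRB contig are dropped. When a cell has two or more candidates,
#' the top one is taken unless the runner-up has more than half the top's
#' UMIs — then the cell is labelled ambiguous; a tie for the top rank is
#' ambiguous too. The best-supported TRA triple, if any, is attached as
#' annotation.
#'
#' @param contigs data.frame with columns `barcode`, `chain` (`"TRA"`/
#'   `"TRB"`), `v_gene`, `j_gene`, `cdr3_nt` and `umis` (positive integers).
#' @return data.frame with one row per barcode: `barcode`, `status`
#'   (`resolved`, `ambiguous`, `dropped_no_trb`), `clonotype` (TRB key,
#'   `NA` unless resolved), `trb_umis`, and `tra_key` annotation.
#' @examples
#' contigs <- data.frame(
#'   barcode = c("c1", "c1", "c2"),
#'   chain = c("TRB", "TRA", "TRA"),
#'   v_gene = c("TRBV9", "TRAV1", "TRAV2"), j_gene = "J1",
#'   cdr3_nt = c("TGTGCC", "TGCATC", "TGCAAA"), umis = c(7L, 3L, 2L))
#' resolve_cell_clonotypes(contigs)
#' @export
resolve_cell_clonotypes <- function(contigs) {
  stopifnot(is.data.frame(contigs),
            all(c("barcode", "chain", "v_gene", "j_gene", "cdr3_nt", "umis")
                %in% names(contigs)),
            all(contigs$umis >= 1),
            all(contigs$chain %in% c("TRA", "TRB")))
  key <- paste(contigs$v_gene, contigs$j_gene, contigs$cdr3_nt, sep = "_")
  barcodes <- unique(contigs$barcode)
  # top and runner-up candidate per barcode, UMIs pooled over identical
  # (V, J, CDR3nt) triples; ties broken lexicographically for determinism
  top_two <- function(idx) {
    if (length(idx) == 0) {
      return(data.frame(barcode = character(), key = character(),
                        umis = integer(), second_umis = integer()))
    }
    agg <- rowsum(contigs$umis[idx],
                  paste(contigs$barcode[idx], key[idx], sep = "\r"))
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    df <- data.frame(barcode = vapply(parts, `[`, "", 1),
                     key = vapply(parts, `[`, "", 2),
                     umis = as.integer(agg))
    df <- df[order(df$barcode, -df$umis, df$key), ]
    first <- !duplicated(df$barcode)
    top <- df[first, , drop = FALSE]
    rest <- df[!first, , drop = FALSE]
    second <- rest[!duplicated(rest$barcode), , drop = FALSE]
    top$second_umis <- second$umis[match(top$barcode, second$barcode)]
    top
  }
  trb <- top_two(which(contigs$chain == "TRB"))
  tra <- top_two(which(contigs$chain == "TRA"))
  m <- match(barcodes, trb$barcode)
  ambiguous <- !is.na(m) & !is.na(trb$second_umis[m]) &
    trb$second_umis[m] > trb$umis[m] / 2  # covers exact top-rank ties
  status <- ifelse(is.na(m), "dropped_no_trb",
                   ifelse(ambiguous, "ambiguous", "resolved"))
  out <- data.frame(barcode = barcodes, status = status,
                    clonotype = ifelse(status == "resolved", trb$key[m],
                                       NA_character_),
                    trb_umis = trb$umis[m],
                    tra_key = tra$key[match(barcodes, tra$barcode)])
  rownames(out) <- NULL
  out
}

#' Pielou's evenness
#'
#' J = H' / ln(S), where H' is the Shannon entropy of clone frequencies and
#' S the number of clones with positive counts. J is 1 for a perfectly even
#' repertoire and approaches 0 when a single clone dominates; it is
#' invariant to rescaling the counts.
#'
#' @param counts non-negative clone-size vector; zeros are dropped before S
#'   is computed. At least two positive clones are required (ln S > 0).
#' @return evenness in (0, 1].
#' @examples
#' pielou_evenness(c(10, 10, 10, 10))  # 1
#' pielou_evenness(c(97, 1, 1, 1))     # 0.1387...
#' @export
pielou_evenness <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  counts <- counts[counts > 0]
  S <- length(counts)
  if (S < 2) stop("evenness undefined for fewer than 2 clones (ln S = 0)")
  p <- counts / sum(counts)
  -sum(p * log(p)) / log(S)
}

#' Clonotype table across samples
#'
#' Joins resolved clonotypes to QC-passed cell metadata and tabulates
#' per-sample cell counts and within-sample frequencies per clonotype,
#' together with the fraction of each clonotype's cells carrying the
#' exhausted cluster label.
#'
#' @param resolved output of [resolve_cell_clonotypes()].
#' @param cells QC-passed cell metadata with `barcode`, `sample` and
#'   `cluster` columns.
#' @param exhausted_label cluster label counting as exhausted.
#' @return data.frame with one row per (clonotype) and columns `clonotype`,
#'   per-sample counts `n_<sample>`, frequencies `freq_<sample>` (each
#'   sample's frequencies sum to 1) and `exhausted_fraction`.
#' @export
clonotype_table <- function(resolved, cells, exhausted_label = "exhausted_cd8") {
  stopifnot(all(c("barcode", "sample") %in% names(cells)))
  res <- resolved[resolved$status == "resolved", c("barcode", "clonotype")]
  merged <- merge(res, cells, by = "barcode")
  if (nrow(merged) == 0) stop("no resolved, QC-passed cells")
  samples <- sort(unique(merged$sample))
  tab <- table(merged$clonotype, factor(merged$sample, levels = samples))
  out <- data.frame(clonotype = rownames(tab), stringsAsFactors = FALSE)
  for (s in samples) {
    out[[paste0("n_", s)]] <- as.integer(tab[, s])
    out[[paste0("freq_", s)]] <- as.numeric(tab[, s] / max(1, sum(tab[, s])))
  }
  if (!is.null(merged$cluster)) {
    exh <- tapply(merged$cluster == exhausted_label, merged$clonotype, mean)
    out$exhausted_fraction <- as.numeric(exh[out$clonotype])
  }
  rownames(out) <- NULL
  out
}

#' Classify interlesion clonotype dominance
#'
#' A merged clonotype is A-dominant when its frequency in sample A is at
#' least `ratio_threshold` times its frequency in B (and symmetrically for
#' B-dominant); otherwise it is equivalent. A clonotype observed in only one
#' sample is dominant there provided it has at least `min_cells` cells;
#' clonotypes below `min_cells` in both samples are excluded. The rule is
#' antisymmetric: swapping the samples swaps the dominant labels and fixes
#' the equivalent class.
#'
#' @param freq_a,freq_b per-clonotype within-sample frequencies.
#' @param n_a,n_b per-clonotype cell counts (for the `min_cells` rule).
#' @param ratio_threshold dominance frequency ratio.
#' @param min_cells minimum cells in at least one sample.
#' @return factor with levels `A_dominant`, `equivalent`, `B_dominant`;
#'   `NA` for excluded clonotypes.
#' @examples
#' classify_dominance(freq_a = 0.04, freq_b = 0.01, n_a = 8, n_b = 2)
#' @export
classify_dominance <- function(freq_a, freq_b, n_a, n_b,
                               ratio_threshold = 2.0, min_cells = 2) {
  stopifnot(length(freq_a) == length(freq_b), ratio_threshold >= 1)
  lab <- rep(NA_character_, length(freq_a))
  eligible <- n_a >= min_cells | n_b >= min_cells
  a_dom <- eligible & freq_a >= ratio_threshold * freq_b & freq_a > 0
  b_dom <- eligible & freq_b >= ratio_threshold * freq_a & freq_b > 0
  both <- a_dom & b_dom  # only possible when one side is 0-frequency noise
  lab[eligible] <- "equivalent"
  lab[a_dom & !both] <- "A_dominant"
  lab[b_dom & !both] <- "B_dominant"
  factor(lab, levels = c("A_dominant", "equivalent", "B_dominant"))
}

#' Exact Fisher test for a 2x2 table
#'
#' Two-sided exact test on a 2x2 contingency table: conditioning on the
#' margins, the p-value is the sum of hypergeometric probabilities of all
#' tables whose probability does not exceed that of the observed table
#' (within relative tolerance 1e-7, guarding ties against floating-point
#' noise). Probabilities are computed in log space to avoid overflow.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `p_value`, `odds_ratio` (sample odds ratio ad/bc) and
#'   the input `table`.
#' @examples
#' fisher_exact(matrix(c(9, 4, 24, 46), nrow = 2))
#' @export
fisher_exact <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2),
            all(table >= 0), all(table == round(table)))
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  m <- a + b        # row 1 total
  n <- c_ + d       # row 2 total
  k <- a + c_       # column 1 total
  or <- (a * d) / (b * c_)
  if (m == 0 || n == 0 || k == 0 || b + d == 0) {
    return(list(p_value = 1, odds_ratio = or, table = table))
  }
  support <- max(0, k - n):min(k, m)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  obs <- stats::dhyper(a, m, n, k, log = TRUE)
  p <- sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
  list(p_value = min(1, p), odds_ratio = or, table = table)
}

#' Exhausted-clonotype enrichment between dominance classes
#'
#' Tests whether exhausted clonotypes are over-represented among A-dominant
#' relative to B-dominant clonotypes: rows of the 2x2 table are the two
#' dominant classes (equivalent clonotypes excluded), columns exhausted vs
#' not, compared with [fisher_exact()]. A clonotype is flagged exhausted
#' when more than `exhausted_fraction_threshold` of its cells lie in the
#' exhausted cluster.
#'
#' @param dominance factor from [classify_dominance()].
#' @param exhausted_fraction per-clonotype fraction of cells in the
#'   exhausted cluster.
#' @param exhausted_fraction_threshold majority threshold for the flag.
#' @return list with the 2x2 `table` (rows `A_dominant`, `B_dominant`;
#'   columns `exhausted`, `not_exhausted`), `odds_ratio` and `p_value`.
#' @export
exhausted_enrichment <- function(dominance, exhausted_fraction,
                                 exhausted_fraction_threshold = 0.5) {
  stopifnot(length(dominance) == length(exhausted_fraction))
  keep <- !is.na(dominance) & dominance != "equivalent"
  dom <- droplevels(factor(dominance[keep],
                           levels = c("A_dominant", "B_dominant")))
  exh <- factor(ifelse(exhausted_fraction[keep] > exhausted_fraction_threshold,
                       "exhausted", "not_exhausted"),
                levels = c("exhausted", "not_exhausted"))
  tab <- table(factor(dominance[keep], levels = c("A_dominant", "B_dominant")),
               exh)
  tab <- matrix(as.integer(tab), nrow = 2,
                dimnames = list(c("A_dominant", "B_dominant"),
                                c("exhausted", "not_exhausted")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin in enrichment table; p = 1")
    return(list(table = tab, odds_ratio = NaN, p_value = 1))
  }
  ft <- fisher_exact(tab)
  list(table = tab, odds_ratio = ft$odds_ratio, p_value = ft$p_value)
}

#' Rule-based cluster annotation from marker genes
#'
#' A transparent surrogate for manual cluster annotation: a gene is "high"
#' in a cluster when its mean expression there exceeds the across-cluster
#' median for that gene, and "low" otherwise. A cluster receives the first
#' label whose required markers are all high and whose excluded markers are
#' all low; unmatched clusters are `unassigned`. Rules referencing genes
#' absent from the matrix are skipped with a warning.
#'
#' @param cluster_means genes x clusters numeric matrix of mean expression.
#' @param rules list of rules, each `list(label=, required=, excluded=)`;
#'   `tcell_marker_rules()` supplies the default T-cell panel.
#' @return named character vector of labels, one per cluster.
#' @export
annotate_clusters <- function(cluster_means, rules = tcell_marker_rules()) {
  stopifnot(is.matrix(cluster_means), ncol(cluster_means) >= 2)
  med <- apply(cluster_means, 1, stats::median)
  high <- sweep(cluster_means, 1, med, ">")
  labels <- stats::setNames(rep("unassigned", ncol(cluster_means)),
                            colnames(cluster_means))
  usable <- vapply(rules, function(rule) {
    ok <- all(c(rule$required, rule$excluded) %in% rownames(cluster_means))
    if (!ok) warning("rule '", rule$label, "' references absent genes; skipped")
    ok
  }, logical(1))
  rules <- rules[usable]
  for (cl in seq_len(ncol(cluster_means))) {
    for (rule in rules) {
      if (all(high[rule$required, cl]) &&
          (length(rule$excluded) == 0 || all(!high[rule$excluded, cl]))) {
        labels[cl] <- rule$label
        break
      }
    }
  }
  labels
}

#' Default T-cell marker rule table
#'
#' The nine archetype labels used for tumor-infiltrating T-cell clusters,
#' each defined by required (and, where needed, excluded) marker genes:
#' exhausted CD8+ (CD8A, PDCD1, HAVCR2), regulatory (CD4, FOXP3), follicular
#' helper (CD4, CD200, CXCL13), cytotoxic CD4+ (CD4, GZMA, lacking CD8A),
#' activated/memory CD4+ (CD4, CD69), naive CD4+ (CD4, CCR7), activated
#' CD8+ (CD8A, CD69), memory CD8+ (CD8A, EOMES), naive CD8+ (CD8A, CCR7).
#' More specific rules are listed first so that they win over the generic
#' activation rules.
#'
#' @return list of rules for [annotate_clusters()].
#' @export
tcell_marker_rules <- function() {
  list(
    list(label = "exhausted_cd8", required = c("CD8A", "PDCD1", "HAVCR2"),
         excluded = "CD4"),
    list(label = "treg", required = c("CD4", "FOXP3"), excluded = character()),
    list(label = "tfh", required = c("CD4", "CD200", "CXCL13"),
         excluded = character()),
    list(label = "cytotoxic_cd4", required = c("CD4", "GZMA"),
         excluded = "CD8A"),
    list(label = "activated_memory_cd4", required = c("CD4", "CD69"),
         excluded = "CD8A"),
    list(label = "naive_cd4", required = c("CD4", "CCR7"), excluded = "CD8A"),
    list(label = "activated_cd8", required = c("CD8A", "CD69"),
         excluded = "CD4"),
    list(label = "memory_cd8", required = c("CD8A", "EOMES"), excluded = "CD4"),
    list(label = "naive_cd8", required = c("CD8A", "CCR7"), excluded = "CD4")
  )
}

#' Read 10x-style contig annotations / cell metadata
#'
#' `read_contigs_csv()` accepts the `filtered_contig_annotations.csv`
#' dialect (columns `barcode, chain, v_gene, j_gene, cdr3, cdr3_nt, umis`);
#' `read_cell_metadata_csv()` expects `barcode, sample, mito_fraction,
#' n_genes, cluster`.
#'
#' @param path file path.
#' @export
read_contigs_csv <- function(path) {
  contigs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("barcode", "chain", "v_gene", "j_gene", "cdr3_nt", "umis")
  missing <- setdiff(need, names(contigs))
  if (length(missing) > 0) {
    stop("contig table lacks columns: ", paste(missing, collapse = ", "))
  }
  contigs
}

#' @rdname read_contigs_csv
#' @export
read_cell_metadata_csv <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("barcode", "sample", "mito_fraction", "n_genes")
  missing <- setdiff(need, names(cells))
  if (length(missing) > 0) {
    stop("cell metadata lacks columns: ", paste(missing, collapse = ", "))
  }
  cells
}
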