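test_that("cell QC keeps boundary cells and drops strict violations", {
  cells <- data.frame(barcode = sprintf("c%d", 1:5), sample = "LN1",
                      mito_fraction = c(0.10, 0.11, 0.05, 0.05, 0.05),
                      n_genes = c(200, 300, 199, 4000, 4001))
  qc <- qc_cells(cells)
  expect_setequal(qc$retained$barcode, c("c1", "c4"))
  expect_setequal(qc$filtered$barcode, c("c2", "c3", "c5"))
})

test_that("clonotype resolution applies the beta-retention and UMI rules", {
  contig <- function(bc, chain, v, umis, cdr3 = paste0("TGT", v)) {
    data.frame(barcode = bc, chain = chain, v_gene = v, j_gene = "J1",
               cdr3_nt = cdr3, umis = umis)
  }
  contigs <- rbind(
    contig("paired", "TRB", "V1", 7), contig("paired", "TRA", "AV1", 3),
    contig("alpha_only", "TRA", "AV2", 5),
    contig("amb", "TRB", "V2", 10), contig("amb", "TRB", "V3", 6),
    contig("kept_half", "TRB", "V4", 10), contig("kept_half", "TRB", "V5", 5),
    contig("tie", "TRB", "V6", 4), contig("tie", "TRB", "V7", 4))
  res <- resolve_cell_clonotypes(contigs)
  get <- function(bc) res[res$barcode == bc, ]
  expect_equal(get("paired")$status, "resolved")
  expect_match(get("paired")$clonotype, "^V1")
  expect_false(is.na(get("paired")$tra_key))
  expect_equal(get("alpha_only")$status, "dropped_no_trb")
  # second UMIs 6 > 10/2: ambiguous
  expect_equal(get("amb")$status, "ambiguous")
  # second UMIs exactly half (5 of 10): top kept
  expect_equal(get("kept_half")$status, "resolved")
  expect_match(get("kept_half")$clonotype, "^V4")
  # tie at the top rank: ambiguous
  expect_equal(get("tie")$status, "ambiguous")
})

test_that("split contigs of the same clonotype are pooled by UMIs", {
  contigs <- data.frame(barcode = "c1", chain = "TRB",
                        v_gene = c("V1", "V1", "V2"), j_gene = "J1",
                        cdr3_nt = c("TGTA", "TGTA", "TGTC"),
                        umis = c(3, 3, 4))
  # V1 pools to 6 UMIs, V2 has 4 > 3: ambiguous
  expect_equal(resolve_cell_clonotypes(contigs)$status, "ambiguous")
})

test_that("Pielou evenness matches direct formula and its invariances", {
  expect_equal(pielou_evenness(c(10, 10, 10, 10)), 1)
  p <- c(97, 1, 1, 1) / 100
  expect_equal(pielou_evenness(c(97, 1, 1, 1)), -sum(p * log(p)) / log(4),
               tolerance = 1e-12)
  expect_equal(round(pielou_evenness(c(97, 1, 1, 1)), 4), 0.121)
  expect_identical(pielou_evenness(c(5, 5)), pielou_evenness(c(500, 500)))
  expect_error(pielou_evenness(c(5)), "fewer than 2")
  expect_error(pielou_evenness(c(5, 0)), "fewer than 2")
  set.seed(17)
  for (i in 1:100) {
    x <- rgamma(sample(2:30, 1), 2)
    j <- pielou_evenness(x)
    expect_true(j > 0 && j <= 1)
    expect_equal(j, pielou_evenness(x * runif(1, 0.1, 50)))
  }
  # J = 1 iff uniform
  expect_lt(pielou_evenness(c(10, 10, 11)), 1)
})

test_that("evenness agrees with an independent diversity implementation", {
  skip_if_not_installed("vegan")
  set.seed(23)
  x <- rpois(40, 20) + 1
  expect_equal(pielou_evenness(x),
               as.numeric(vegan::diversity(x) / log(length(x))))
})

test_that("dominance classification is antisymmetric and honours min_cells", {
  expect_equal(as.character(classify_dominance(0.04, 0.01, 8, 2)), "A_dominant")
  expect_equal(as.character(classify_dominance(0.02, 0.02, 4, 4)), "equivalent")
  expect_equal(as.character(classify_dominance(0.01, 0.04, 2, 8)), "B_dominant")
  # present in one sample only, enough cells: dominant there
  expect_equal(as.character(classify_dominance(0.03, 0, 5, 0)), "A_dominant")
  # too few cells everywhere: excluded
  expect_true(is.na(classify_dominance(0.001, 0, 1, 0)))
  set.seed(29)
  fa <- runif(50); fb <- runif(50)
  na_ <- sample(0:20, 50, TRUE); nb <- sample(0:20, 50, TRUE)
  fwd <- classify_dominance(fa, fb, na_, nb)
  rev <- classify_dominance(fb, fa, nb, na_)
  swap <- c(A_dominant = "B_dominant", equivalent = "equivalent",
            B_dominant = "A_dominant")
  expect_identical(as.character(rev),
                   unname(swap[as.character(fwd)]))
})

test_that("fisher_exact matches enumeration and known closed forms", {
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-12)
  # the lesion-enrichment table: odds ratio (9*46)/(24*4)
  ft <- fisher_exact(matrix(c(9, 4, 24, 46), 2))
  expect_equal(ft$odds_ratio, 4.3125)
  expect_lt(ft$p_value, 0.05)
  # transpose invariance
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(sample(0:15, 4, TRUE), 2)
    expect_equal(fisher_exact(m)$p_value, fisher_exact(t(m))$p_value,
                 tolerance = 1e-12)
  }
  # empty margins give p = 1
  expect_equal(fisher_exact(matrix(c(0, 0, 7, 9), 2))$p_value, 1)
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  set.seed(37)
  for (i in 1:50) {
    m <- matrix(sample(0:40, 4, TRUE), 2)
    expect_equal(fisher_exact(m)$p_value, stats::fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("enrichment builds the dominant-by-exhausted table correctly", {
  dom <- factor(rep(c("A_dominant", "B_dominant", "equivalent"),
                    c(33, 50, 10)),
                levels = c("A_dominant", "equivalent", "B_dominant"))
  exh_frac <- c(rep(1, 9), rep(0, 24), rep(1, 4), rep(0, 46), rep(1, 10))
  enr <- exhausted_enrichment(dom, exh_frac)
  expect_equal(unname(enr$table), matrix(c(9, 4, 24, 46), 2))
  expect_equal(enr$odds_ratio, 4.3125)
  expect_lt(enr$p_value, 0.05)
  # empty margin warns and returns p = 1
  dom2 <- factor(c("A_dominant", "B_dominant"),
                 levels = c("A_dominant", "equivalent", "B_dominant"))
  expect_warning(e2 <- exhausted_enrichment(dom2, c(0, 0)), "empty margin")
  expect_equal(e2$p_value, 1)
})

test_that("marker rules recover planted cluster archetypes", {
  rules <- tcell_marker_rules()
  genes <- unique(unlist(lapply(rules, function(r) c(r$required, r$excluded))))
  # one cluster per archetype, expressing exactly its required markers high
  mat <- matrix(0, nrow = length(genes), ncol = length(rules) + 1,
                dimnames = list(genes,
                                c(vapply(rules, `[[`, "", "label"), "none")))
  for (i in seq_along(rules)) mat[rules[[i]]$required, i] <- 10
  labels <- annotate_clusters(mat, rules)
  expect_identical(unname(labels[seq_along(rules)]),
                   vapply(rules, `[[`, "", "label"))
  expect_equal(unname(labels[["none"]]), "unassigned")
})

test_that("clusters at the median and absent genes are handled", {
  # everything at the median: nothing is "high", no rule matches
  genes <- c("CD8A", "PDCD1", "HAVCR2", "CD4", "FOXP3", "CD200", "CXCL13",
             "GZMA", "CD69", "CCR7", "EOMES")
  mat <- matrix(5, nrow = length(genes), ncol = 3,
                dimnames = list(genes, NULL))
  expect_true(all(annotate_clusters(mat) == "unassigned"))
  # a rule naming an absent gene is skipped with a warning
  small <- matrix(c(1, 9), nrow = 1, ncol = 2, dimnames = list("CD8A", NULL))
  expect_warning(labels <- annotate_clusters(
    small, rules = list(list(label = "x", required = "NOT_A_GENE",
                             excluded = character()))),
    "absent genes")
  expect_true(all(labels == "unassigned"))
})

test_that("clonotype table frequencies sum to one per sample", {
  sim <- sim_clonotype_tables(sim_config(seed = 41, n_clonotypes = 40,
                                         n_cells_per_sample = 400))
  qc <- qc_cells(sim$cells)
  res <- resolve_cell_clonotypes(sim$contigs)
  tab <- clonotype_table(res, qc$retained)
  expect_equal(sum(tab$freq_LN1), 1)
  expect_equal(sum(tab$freq_LN2), 1)
  expect_true(all(tab$exhausted_fraction >= 0 & tab$exhausted_fraction <= 1))
})

test_that("resolution conserves cells across outcome bins", {
  sim <- sim_clonotype_tables(sim_config(seed = 43, n_clonotypes = 50,
                                         n_cells_per_sample = 500))
  qc <- qc_cells(sim$cells)
  res <- resolve_cell_clonotypes(sim$contigs)
  res_qc <- res[res$barcode %in% qc$retained$barcode, ]
  n_bins <- nrow(qc$filtered) + sum(res_qc$status == "dropped_no_trb") +
    sum(res_qc$status == "ambiguous") + sum(res_qc$status == "resolved")
  expect_equal(n_bins, nrow(sim$cells))
})
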