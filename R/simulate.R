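#' Seeded synthetic-data generators
#'
#' Every input the pipeline consumes can be generated with known ground
#' truth: paired-lesion mutation tables with shared trunk and private branch
#' mutations plus filter-violating decoys, GC-biased depth tracks with
#' planted copy-number segments, skewed clonotype repertoires with planted
#' dominance and exhaustion structure, and patient cohorts whose lesion
#' trajectories encode known response groups linked to survival. All draws
#' are governed by the configuration seed; each generator emits a truth
#' table alongside its observables.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Collects the knobs of all generators with the defaults used throughout
#' the package's tests: exome-like depth 100x, trunk-heavy paired lesions,
#' a truncated power-law repertoire, and a 503-patient cohort split across
#' four cancer types.
#'
#' @param seed integer seed governing every draw.
#' @param n_trunk,n_private_a,n_private_b mutation counts shared / private.
#' @param decoys_per_criterion planted filter-violating calls per criterion.
#' @param depth_mean mean sequencing depth (reads).
#' @param n_sites SNP sites for the depth-track generator.
#' @param gc_bias_slope multiplicative depth bias per unit GC fraction
#'   (depth factor = 1 + slope * (gc - 0.5); 0 disables the bias).
#' @param cnv_segments data.frame `chrom, start, end, copy_number`
#'   (non-overlapping; copy number in 0..4) or `NULL` for a flat genome.
#' @param n_clonotypes,n_cells_per_sample repertoire size per lesion.
#' @param clone_freq_alpha power-law exponent for clone sizes (0 = even
#'   base frequencies; larger = more skewed).
#' @param dominance_ratio interlesion frequency multiplier planted on the
#'   dominant thirds of the repertoire (1 = no planted dominance).
#' @param exhausted_enrichment_or target odds ratio for exhausted
#'   membership between A- and B-dominant clonotypes.
#' @param ambiguous_rate,no_trb_rate,qc_fail_rate planted per-cell rates.
#' @param cohort_sizes named integer vector of patients per cancer type.
#' @param group_proportions length-3 proportions (nonmixed responder,
#'   mixed, nonmixed nonresponder), summing to 1.
#' @param hazard_scale named vector of exponential mean survival (days) per
#'   group; the mixed group sits between the nonmixed groups.
#' @param censor_scale mean of the independent exponential censoring time.
#' @param exact_group_counts optional named integer vector (same names as
#'   `group_proportions`); when given, exactly these many patients per group
#'   are planted (in a seeded shuffle) instead of multinomial draws.
#' @param exact_local_therapy_count optional integer; when given, exactly
#'   this many mixed responders carry the local-therapy flag.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_trunk = 50L, n_private_a = 25L, n_private_b = 15L,
                       decoys_per_criterion = 5L,
                       depth_mean = 100,
                       n_sites = 6000L,
                       gc_bias_slope = 0.8,
                       cnv_segments = NULL,
                       n_clonotypes = 150L, n_cells_per_sample = 1500L,
                       clone_freq_alpha = 1.2, dominance_ratio = 4,
                       exhausted_enrichment_or = 4,
                       ambiguous_rate = 0.05, no_trb_rate = 0.05,
                       qc_fail_rate = 0.05,
                       cohort_sizes = c(melanoma = 150L, NSCLC = 200L,
                                        gastric = 80L, head_and_neck = 73L),
                       group_proportions = c(nonmixed_responder = 0.35,
                                             mixed_responder = 0.14,
                                             nonmixed_nonresponder = 0.51),
                       hazard_scale = c(nonmixed_responder = 900,
                                        mixed_responder = 450,
                                        nonmixed_nonresponder = 200),
                       censor_scale = 1500,
                       exact_group_counts = NULL,
                       exact_local_therapy_count = NULL) {
  stopifnot(seed == round(seed), depth_mean > 0, n_sites > 0,
            abs(sum(group_proportions) - 1) < 1e-8)
  if (!is.null(cnv_segments)) {
    stopifnot(is.data.frame(cnv_segments),
              all(c("chrom", "start", "end", "copy_number")
                  %in% names(cnv_segments)),
              all(cnv_segments$copy_number %in% 0:4))
    for (ch in unique(cnv_segments$chrom)) {
      seg <- cnv_segments[cnv_segments$chrom == ch, ]
      seg <- seg[order(seg$start), ]
      if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
        stop("overlapping copy-number segments on ", ch)
      }
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate paired-lesion somatic mutation calls
#'
#' Trunk mutations appear in both lesions, private mutations in one. Clean
#' calls are drawn to pass every filter criterion (depth ~ Poisson around
#' `depth_mean` with a floor above the read cutoff, VAF ~ 0.2-0.6, alternate
#' reads split Binomial(0.5) across strands with both strands guaranteed,
#' no germline support, absent from population databases). For each
#' exclusion criterion, `decoys_per_criterion` calls violating exactly that
#' criterion are planted per lesion. Roughly 75% of clean calls are
#' annotated nonsynonymous.
#'
#' @param config a [sim_config()].
#' @return list with `lesion_a`, `lesion_b` (candidate-variant data.frames)
#'   and `truth` (per-mutation origin, planted decoy labels and planted
#'   nonsynonymous counts).
#' @export
sim_lesion_pair_mutations <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_all <- config$n_trunk + config$n_private_a + config$n_private_b
  origin <- rep(c("trunk", "private_a", "private_b"),
                c(config$n_trunk, config$n_private_a, config$n_private_b))
  bases <- c("A", "C", "G", "T")
  pos <- sort(sample.int(5e7, n_all))
  ref <- sample(bases, n_all, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  consequence <- sample(c("nonsynonymous", "synonymous", "other"), n_all,
                        replace = TRUE, prob = c(0.75, 0.2, 0.05))

  clean_call <- function(i) {
    depth <- max(25L, stats::rpois(1, config$depth_mean))
    vaf <- stats::runif(1, 0.2, 0.6)
    alt_n <- max(2L, stats::rbinom(1, depth, vaf))
    alt_fwd <- stats::rbinom(1, alt_n, 0.5)
    if (alt_fwd == 0) alt_fwd <- 1L
    if (alt_fwd == alt_n) alt_fwd <- alt_n - 1L
    ref_n <- depth - alt_n
    ref_fwd <- stats::rbinom(1, ref_n, 0.5)
    data.frame(chrom = "chr1", pos = pos[i], ref = ref[i], alt = alt[i],
               tumor_alt_fwd = alt_fwd, tumor_alt_rev = alt_n - alt_fwd,
               tumor_ref_fwd = ref_fwd, tumor_ref_rev = ref_n - ref_fwd,
               normal_alt = sample(0:2, 1), normal_total = 40L,
               in_population_db = FALSE, consequence = consequence[i])
  }
  decoy_call <- function(criterion, p) {
    call <- clean_call_at(p)
    switch(criterion,
           total_reads = {
             call$tumor_alt_fwd <- 3L; call$tumor_alt_rev <- 3L
             call$tumor_ref_fwd <- 5L; call$tumor_ref_rev <- 5L  # depth 16
           },
           low_vaf = {
             call$tumor_alt_fwd <- 1L; call$tumor_alt_rev <- 1L
             call$tumor_ref_fwd <- 49L; call$tumor_ref_rev <- 49L  # VAF 0.02
           },
           germline_support = call$normal_alt <- 5L,
           single_strand = {
             call$tumor_alt_rev <- 0L
             call$tumor_alt_fwd <- max(call$tumor_alt_fwd, 10L)
           },
           population_db = call$in_population_db <- TRUE)
    call
  }
  clean_call_at <- function(p) {
    call <- clean_call(1L)
    call$pos <- p
    call
  }

  criteria_labels <- c("total_reads", "low_vaf", "germline_support",
                       "single_strand", "population_db")
  build_lesion <- function(keep_origin) {
    idx <- which(origin %in% keep_origin)
    calls <- do.call(rbind, lapply(idx, clean_call))
    truth_rows <- data.frame(pos = calls$pos, origin = origin[idx],
                             planted_decoy = NA_character_,
                             consequence = calls$consequence)
    if (config$decoys_per_criterion > 0) {
      dpos <- sample(setdiff(seq(5e7 + 1, 6e7), pos),
                     config$decoys_per_criterion * length(criteria_labels))
      d <- 0L
      for (cr in criteria_labels) {
        for (j in seq_len(config$decoys_per_criterion)) {
          d <- d + 1L
          calls <- rbind(calls, decoy_call(cr, dpos[d]))
          truth_rows <- rbind(truth_rows,
                              data.frame(pos = dpos[d], origin = "decoy",
                                         planted_decoy = cr,
                                         consequence = calls$consequence[nrow(calls)]))
        }
      }
    }
    ord <- order(calls$pos)
    list(calls = calls[ord, ], truth = truth_rows[ord, ])
  }
  a <- build_lesion(c("trunk", "private_a"))
  b <- build_lesion(c("trunk", "private_b"))
  truth <- list(
    lesion_a = a$truth, lesion_b = b$truth,
    n_trunk = config$n_trunk,
    n_private_a = config$n_private_a, n_private_b = config$n_private_b,
    nonsyn_a = sum(a$truth$origin != "decoy" &
                     a$truth$consequence == "nonsynonymous"),
    nonsyn_b = sum(b$truth$origin != "decoy" &
                     b$truth$consequence == "nonsynonymous"))
  list(lesion_a = a$calls, lesion_b = b$calls, truth = truth)
}

#' Simulate tumor/normal depth tracks with planted copy-number segments
#'
#' Sites are scattered over two chromosomes; each site gets a GC fraction
#' (Beta-distributed around 0.45) and a multiplicative GC depth effect
#' shared by tumor and normal. Normal depth is Poisson around `depth_mean`
#' times the GC effect; tumor depth is additionally scaled by copy_number/2
#' inside planted segments (diploid elsewhere, purity 1). Normal VAFs are
#' drawn from a homozygous/heterozygous/intermediate mixture so that site
#' selection has work to do.
#'
#' @param config a [sim_config()]; set `config$cnv_segments` to plant
#'   segments.
#' @return list with `sites` (SNP-site data.frame) and `truth` (per-site
#'   planted copy number and the segment table).
#' @export
sim_depth_tracks <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_sites
  chrom <- sort(rep_len(c("chr1", "chr2"), n))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(idx) {
    sort(sample.int(6e7, length(idx)))
  }), use.names = FALSE)
  gc <- stats::rbeta(n, 18, 22)  # centred near 0.45, exome-like spread
  gc_effect <- pmax(0.1, 1 + config$gc_bias_slope * (gc - 0.5))
  cn <- rep(2L, n)
  if (!is.null(config$cnv_segments)) {
    for (i in seq_len(nrow(config$cnv_segments))) {
      seg <- config$cnv_segments[i, ]
      inside <- chrom == seg$chrom & pos >= seg$start & pos <= seg$end
      cn[inside] <- as.integer(seg$copy_number)
    }
  }
  normal_depth <- stats::rpois(n, config$depth_mean * gc_effect)
  tumor_depth <- stats::rpois(n, config$depth_mean * gc_effect * cn / 2)
  normal_vaf <- numeric(n)
  zyg_class <- sample(c("hom_ref", "het", "hom_alt", "noise"), n,
                      replace = TRUE, prob = c(0.35, 0.35, 0.2, 0.1))
  normal_vaf[zyg_class == "hom_ref"] <- stats::runif(sum(zyg_class == "hom_ref"), 0, 0.03)
  normal_vaf[zyg_class == "het"] <- stats::runif(sum(zyg_class == "het"), 0.45, 0.55)
  normal_vaf[zyg_class == "hom_alt"] <- stats::runif(sum(zyg_class == "hom_alt"), 0.97, 1)
  normal_vaf[zyg_class == "noise"] <- stats::runif(sum(zyg_class == "noise"), 0.1, 0.35)
  sites <- data.frame(chrom = chrom, pos = pos, normal_vaf = normal_vaf,
                      normal_depth = normal_depth, tumor_depth = tumor_depth,
                      gc_fraction = gc)
  list(sites = sites,
       truth = list(copy_number = cn, segments = config$cnv_segments,
                    selected = zyg_class != "noise"))
}

# sample clone frequencies from a truncated power law p_k ~ k^(-alpha)
power_law_freqs <- function(n_clonotypes, alpha) {
  w <- seq_len(n_clonotypes)^(-alpha)
  w / sum(w)
}

#' Simulate paired-lesion single-cell TCR tables
#'
#' Clonotype base frequencies follow a truncated power law; per-lesion
#' frequencies are perturbed so that a planted third of clonotypes is
#' A-dominant, a third B-dominant and a third equivalent (frequency ratios
#' 4x vs 1x, safely beyond the 2x dominance threshold). Exhausted-cluster
#' membership is assigned per clonotype so that the odds of being exhausted
#' among A-dominant clonotypes exceed those among B-dominant clonotypes by
#' `exhausted_enrichment_or` in expectation. Cells are emitted as 10x-style
#' contig rows (TRB always for clean cells, TRA for ~85%) plus a metadata
#' table; planted fractions of cells are made ambiguous (second TRB with
#' more than half the top UMIs), beta-less (TRA only) or QC-failing.
#'
#' @param config a [sim_config()].
#' @return list with `contigs`, `cells` and `truth` (planted per-clonotype
#'   dominance and exhaustion, per-cell planted status and rates).
#' @export
sim_clonotype_tables <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  K <- config$n_clonotypes
  base <- power_law_freqs(K, config$clone_freq_alpha)
  planted_dom <- rep(c("A_dominant", "equivalent", "B_dominant"),
                     length.out = K)
  if (config$dominance_ratio == 1) planted_dom <- rep("equivalent", K)
  r <- config$dominance_ratio
  wa <- base * ifelse(planted_dom == "A_dominant", r,
                      ifelse(planted_dom == "B_dominant", 1, (1 + r) / 2))
  wb <- base * ifelse(planted_dom == "B_dominant", r,
                      ifelse(planted_dom == "A_dominant", 1, (1 + r) / 2))
  # exhaustion odds differ between the dominant classes by the target OR
  p_b <- 0.12
  odds_b <- p_b / (1 - p_b)
  odds_a <- odds_b * config$exhausted_enrichment_or
  p_a <- odds_a / (1 + odds_a)
  p_exh <- ifelse(planted_dom == "A_dominant", p_a,
                  ifelse(planted_dom == "B_dominant", p_b, (p_a + p_b) / 2))
  exhausted <- stats::rbinom(K, 1, p_exh) == 1

  nt <- c("A", "C", "G", "T")
  clono <- data.frame(
    id = seq_len(K),
    v_gene = paste0("TRBV", sample(1:30, K, replace = TRUE)),
    j_gene = paste0("TRBJ", sample(1:2, K, replace = TRUE), "-",
                    sample(1:7, K, replace = TRUE)),
    cdr3_nt = vapply(seq_len(K), function(i) {
      paste(sample(nt, 39, replace = TRUE), collapse = "")
    }, character(1)),
    planted_dominance = planted_dom,
    planted_exhausted = exhausted)
  tra_v <- paste0("TRAV", sample(1:40, K, replace = TRUE))
  tra_cdr3 <- vapply(seq_len(K), function(i) {
    paste(sample(nt, 36, replace = TRUE), collapse = "")
  }, character(1))

  clusters <- c("exhausted_cd8", "naive_cd4", "naive_cd8", "treg",
                "activated_cd8", "memory_cd8")
  make_sample <- function(sample_id, w) {
    n <- config$n_cells_per_sample
    clone_of <- sample.int(K, n, replace = TRUE, prob = w)
    status <- sample(c("clean", "ambiguous", "no_trb", "qc_fail"), n,
                     replace = TRUE,
                     prob = c(1 - config$ambiguous_rate - config$no_trb_rate -
                                config$qc_fail_rate,
                              config$ambiguous_rate, config$no_trb_rate,
                              config$qc_fail_rate))
    barcode <- sprintf("%s_cell%04d", sample_id, seq_len(n))
    mito <- stats::runif(n, 0, 0.08)
    genes <- sample(500:3500, n, replace = TRUE)
    qc_mode <- sample(c("mito", "low_genes", "high_genes"),
                      n, replace = TRUE)
    mito[status == "qc_fail" & qc_mode == "mito"] <-
      stats::runif(sum(status == "qc_fail" & qc_mode == "mito"), 0.15, 0.6)
    genes[status == "qc_fail" & qc_mode == "low_genes"] <-
      sample(10:150, sum(status == "qc_fail" & qc_mode == "low_genes"),
             replace = TRUE)
    genes[status == "qc_fail" & qc_mode == "high_genes"] <-
      sample(4500:8000, sum(status == "qc_fail" & qc_mode == "high_genes"),
             replace = TRUE)
    cluster <- ifelse(exhausted[clone_of],
                      "exhausted_cd8",
                      sample(clusters[-1], n, replace = TRUE))
    top <- sample(4:12, n, replace = TRUE)
    has_trb <- status != "no_trb"
    k <- clone_of
    trb <- data.frame(barcode = barcode[has_trb], chain = "TRB",
                      v_gene = clono$v_gene[k[has_trb]],
                      j_gene = clono$j_gene[k[has_trb]],
                      cdr3_nt = clono$cdr3_nt[k[has_trb]],
                      umis = top[has_trb])
    amb <- which(status == "ambiguous")
    trb2 <- if (length(amb) > 0) {
      k2 <- ifelse(k[amb] == K, 1L, k[amb] + 1L)
      data.frame(barcode = barcode[amb], chain = "TRB",
                 v_gene = clono$v_gene[k2], j_gene = clono$j_gene[k2],
                 cdr3_nt = clono$cdr3_nt[k2],
                 umis = floor(top[amb] / 2) + 1L)  # strictly > half
    } else NULL
    has_tra <- status == "no_trb" | stats::runif(n) < 0.85
    tra <- data.frame(barcode = barcode[has_tra], chain = "TRA",
                      v_gene = tra_v[k[has_tra]], j_gene = "TRAJ1",
                      cdr3_nt = tra_cdr3[k[has_tra]],
                      umis = sample(1:6, sum(has_tra), replace = TRUE))
    list(contigs = rbind(trb, trb2, tra),
         cells = data.frame(barcode = barcode, sample = sample_id,
                            mito_fraction = mito, n_genes = genes,
                            cluster = cluster),
         truth_cells = data.frame(barcode = barcode, sample = sample_id,
                                  clonotype_id = clone_of,
                                  planted_status = status))
  }
  a <- make_sample("LN1", wa)
  b <- make_sample("LN2", wb)
  list(contigs = rbind(a$contigs, b$contigs),
       cells = rbind(a$cells, b$cells),
       truth = list(clonotypes = clono,
                    cells = rbind(a$truth_cells, b$truth_cells),
                    rates = c(ambiguous = config$ambiguous_rate,
                              no_trb = config$no_trb_rate,
                              qc_fail = config$qc_fail_rate)))
}

#' Simulate a patient cohort with known response groups
#'
#' Each patient receives a planted response group (multinomial over
#' `group_proportions`) and 2-4 lesions whose diameter trajectories exceed
#' the classification thresholds by a margin: regressing lesions shrink
#' 40-70%, progressing lesions grow 30-80%, nonmixed nonresponders may also
#' acquire a new lesion. Survival times are exponential with group-specific
#' means (mixed responders intermediate) under independent exponential
#' censoring; OS is PFS plus an exponential post-progression time.
#'
#' @param config a [sim_config()].
#' @return list with `lesions`, `patients` and `truth` (planted group per
#'   patient).
#' @export
sim_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  groups <- names(config$group_proportions)
  n_total <- sum(config$cohort_sizes)
  planted <- if (!is.null(config$exact_group_counts)) {
    stopifnot(sum(config$exact_group_counts) == n_total)
    sample(rep(names(config$exact_group_counts), config$exact_group_counts))
  } else {
    sample(groups, n_total, replace = TRUE, prob = config$group_proportions)
  }
  rows_l <- list(); rows_p <- list()
  pid <- 0L
  for (ct in names(config$cohort_sizes)) {
    for (i in seq_len(config$cohort_sizes[[ct]])) {
      pid <- pid + 1L
      id <- sprintf("P%04d", pid)
      g <- planted[pid]
      n_les <- sample(2:4, 1)
      kinds <- switch(g,
        nonmixed_responder = rep("regress", n_les),
        nonmixed_nonresponder = {
          k <- rep("progress", n_les)
          if (stats::runif(1) < 0.3) k[n_les] <- "new"
          k
        },
        mixed_responder = {
          k <- c("regress", if (stats::runif(1) < 0.3) "new" else "progress")
          if (n_les > 2) {
            k <- c(k, sample(c("regress", "progress"), n_les - 2,
                             replace = TRUE))
          }
          k
        })
      scan_times <- c(60, 120, 180)
      for (j in seq_len(n_les)) {
        d0 <- stats::runif(1, 10, 40)
        kind <- kinds[j]
        if (kind == "new") {
          t_new <- sample(scan_times[-1], 1)
          rows_l[[length(rows_l) + 1L]] <- data.frame(
            patient = id, lesion = paste0("L", j),
            time_days = t_new, diameter_mm = stats::runif(1, 6, 15),
            is_new = TRUE)
          next
        }
        final <- switch(kind,
                        regress = 1 - stats::runif(1, 0.40, 0.70),
                        progress = 1 + stats::runif(1, 0.30, 0.80))
        frac <- c(0, (final - 1) * scan_times / max(scan_times) + 1)[-1]
        traj <- data.frame(
          patient = id, lesion = paste0("L", j),
          time_days = c(0, scan_times),
          diameter_mm = round(d0 * c(1, frac), 1),
          is_new = FALSE)
        rows_l[[length(rows_l) + 1L]] <- traj
      }
      scale <- config$hazard_scale[[g]]
      pfs_true <- stats::rexp(1, 1 / scale)
      os_true <- pfs_true + stats::rexp(1, 1 / (scale * 0.8))
      cens <- stats::rexp(1, 1 / config$censor_scale)
      rows_p[[length(rows_p) + 1L]] <- data.frame(
        patient = id, cancer_type = ct,
        pfs_days = round(min(pfs_true, cens), 1),
        pfs_event = as.integer(pfs_true <= cens),
        os_days = round(min(os_true, cens), 1),
        os_event = as.integer(os_true <= cens),
        local_therapy = g == "mixed_responder" & stats::runif(1) < 0.19,
        planted_group = g)
    }
  }
  patients <- do.call(rbind, rows_p)
  if (!is.null(config$exact_local_therapy_count)) {
    mixed_idx <- which(patients$planted_group == "mixed_responder")
    stopifnot(config$exact_local_therapy_count <= length(mixed_idx))
    patients$local_therapy <- FALSE
    patients$local_therapy[sample(mixed_idx,
                                  config$exact_local_therapy_count)] <- TRUE
  }
  truth <- patients[, c("patient", "planted_group")]
  patients$planted_group <- NULL
  list(lesions = do.call(rbind, rows_l), patients = patients, truth = truth)
}

#' Write simulated inputs to their on-disk dialects
#'
#' Emits the exact file formats the package readers accept, so end-to-end
#' tests need no adapters: mutation TSVs, a SNP-site TSV, contig and cell
#' CSVs, or cohort CSVs, depending on which generator output is passed.
#'
#' @param sim output of one of the `sim_*` generators.
#' @param dir destination directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(obj, file, writer) {
    p <- file.path(dir, file)
    writer(obj, p)
    paths[[length(paths) + 1L]] <<- p
  }
  tsv <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  csv <- function(x, p) utils::write.csv(x, p, quote = FALSE,
                                         row.names = FALSE)
  if (!is.null(sim$lesion_a)) {
    emit(sim$lesion_a, "lesion_a.tsv", tsv)
    emit(sim$lesion_b, "lesion_b.tsv", tsv)
  }
  if (!is.null(sim$sites)) emit(sim$sites, "sites.tsv", tsv)
  if (!is.null(sim$contigs)) {
    emit(sim$contigs, "contigs.csv", csv)
    emit(sim$cells, "cells.csv", csv)
  }
  if (!is.null(sim$lesions)) {
    emit(sim$lesions, "lesions.csv", csv)
    emit(sim$patients, "patients.csv", csv)
  }
  invisible(unlist(paths))
}
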