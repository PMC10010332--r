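#' Mutant 9-mer neoantigen candidates and interlesion overlap
#'
#' Nonsynonymous mutations are expanded into every 9-residue peptide window
#' covering the mutated position; candidates are filtered against an MHC
#' class I binding table at the strong-binder threshold (%Rank <= 0.5) and
#' partitioned into lesion-private and shared sets.
#'
#' @name neoantigen_overlap
NULL

#' Enumerate mutant 9-mer peptides
#'
#' Every length-9 window of the mutated protein that covers the substituted
#' position is a candidate: windows start at `max(1, p - 8)` through
#' `min(p, L - 8)`, giving 9 peptides at interior positions and as few as 1
#' at the termini.
#'
#' @param protein_seq amino-acid string (single-letter code).
#' @param p 1-based position of the substituted residue.
#' @param alt_aa mutant residue (single letter); substituted into the
#'   sequence before windowing.
#' @param ref_aa optional reference residue; when given it must differ from
#'   `alt_aa` and match `substr(protein_seq, p, p)`.
#' @return data.frame with columns `peptide`, `start` (1-based window start
#'   in the protein) and `mut_offset` (1-based position of the mutant residue
#'   within the peptide). Proteins shorter than 9 residues yield zero rows
#'   with a warning.
#' @examples
#' enumerate_mutant_9mers(strrep("A", 100), p = 50, alt_aa = "V")  # 9 windows
#' enumerate_mutant_9mers(strrep("A", 100), p = 1, alt_aa = "V")   # 1 window
#' @export
enumerate_mutant_9mers <- function(protein_seq, p, alt_aa, ref_aa = NULL) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1,
            nchar(alt_aa) == 1, alt_aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  L <- nchar(protein_seq)
  if (p < 1 || p > L) stop("mutated position outside protein (p = ", p, ", L = ", L, ")")
  if (!is.null(ref_aa)) {
    if (ref_aa == alt_aa) stop("ref_aa equals alt_aa: not a substitution")
    if (substr(protein_seq, p, p) != ref_aa) {
      stop("ref_aa does not match the protein sequence at position ", p)
    }
  }
  if (L < 9) {
    warning("protein shorter than 9 residues: no 9-mer windows")
    return(data.frame(peptide = character(), start = integer(),
                      mut_offset = integer()))
  }
  mutated <- protein_seq
  substr(mutated, p, p) <- alt_aa
  starts <- seq.int(max(1L, p - 8L), min(p, L - 8L))
  data.frame(peptide = substring(mutated, starts, starts + 8L),
             start = starts,
             mut_offset = p - starts + 1L)
}

#' Filter strong MHC binders
#'
#' Retains candidates at or below the %Rank threshold (the strong-binder
#' convention; the boundary is inclusive) and collapses duplicate
#' (peptide, allele) pairs to the minimal rank.
#'
#' @param candidates data.frame with columns `peptide`, `mhc_allele`,
#'   `percent_rank` (plus any carry-through columns).
#' @param rank_threshold retain `percent_rank <= rank_threshold`.
#' @return deduplicated data.frame of strong binders.
#' @export
filter_strong_binders <- function(candidates, rank_threshold = 0.5) {
  stopifnot(is.data.frame(candidates),
            all(c("peptide", "mhc_allele", "percent_rank") %in% names(candidates)))
  if (any(is.na(candidates$percent_rank)) || any(candidates$percent_rank < 0)) {
    stop("percent_rank must be non-negative and present")
  }
  keep <- candidates[candidates$percent_rank <= rank_threshold, , drop = FALSE]
  if (nrow(keep) == 0) return(keep)
  keep <- keep[order(keep$percent_rank), , drop = FALSE]
  dup <- duplicated(keep[, c("peptide", "mhc_allele")])
  out <- keep[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-set Venn partition
#'
#' @param set_a,set_b character vectors of keys (duplicates ignored).
#' @return list of class `"venn_partition"` with `only_a`, `shared`,
#'   `only_b` (sorted unique keys) and `counts` (named integer vector).
#' @examples
#' venn_partition(c("x", "y"), c("y", "z"))$counts
#' @export
venn_partition <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  out <- list(only_a = sort(setdiff(a, b)),
              shared = sort(intersect(a, b)),
              only_b = sort(setdiff(b, a)))
  out$counts <- c(only_a = length(out$only_a), shared = length(out$shared),
                  only_b = length(out$only_b))
  structure(out, class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition: only A =", x$counts[["only_a"]],
      "| shared =", x$counts[["shared"]],
      "| only B =", x$counts[["only_b"]], "\n")
  invisible(x)
}

mutation_key <- function(mutations) {
  paste(mutations$chrom, mutations$pos, mutations$ref, mutations$alt, sep = ":")
}

#' Per-lesion neoantigen burden and overlap
#'
#' Composes 9-mer enumeration, binding-table lookup and strong-binder
#' filtering for two lesions, then partitions neoantigens between them. A
#' neoantigen is identified by its (peptide, MHC allele) pair — distinct
#' mutations can produce identical peptides — and is "shared" when that pair
#' passes the threshold in both lesions. Counts deduplicated by source
#' mutation are also reported. Peptides absent from the binding table are
#' excluded from counts and listed in the coverage report.
#'
#' @param mutations_a,mutations_b per-lesion mutation data.frames with
#'   columns `chrom, pos, ref, alt, protein_id, protein_pos, ref_aa, alt_aa`.
#' @param proteins named character vector of protein sequences (names =
#'   `protein_id`).
#' @param binding data.frame with `peptide, mhc_allele, percent_rank` for
#'   every enumerated peptide/allele pair.
#' @param rank_threshold strong-binder %Rank cutoff.
#' @return list with per-lesion strong-binder tables (`lesion_a`,
#'   `lesion_b`), `venn_peptide` ((peptide, allele) keys), `venn_mutation`
#'   (source-mutation keys of strong binders), per-lesion counts and
#'   `missing_from_binding` (peptides with no prediction).
#' @export
neoantigen_burden_by_lesion <- function(mutations_a, mutations_b, proteins,
                                        binding, rank_threshold = 0.5) {
  expand <- function(mutations) {
    if (nrow(mutations) == 0) {
      return(data.frame(peptide = character(), mutation = character()))
    }
    rows <- lapply(seq_len(nrow(mutations)), function(i) {
      m <- mutations[i, ]
      seqs <- proteins[[m$protein_id]]
      if (is.null(seqs)) stop("protein not found: ", m$protein_id)
      w <- enumerate_mutant_9mers(seqs, m$protein_pos, m$alt_aa, m$ref_aa)
      if (nrow(w) == 0) return(NULL)
      data.frame(peptide = w$peptide, mutation = mutation_key(m))
    })
    do.call(rbind, rows)
  }
  score <- function(peps) {
    hit <- merge(peps, binding, by = "peptide")
    strong <- filter_strong_binders(hit, rank_threshold)
    list(strong = strong,
         missing = sort(setdiff(unique(peps$peptide), unique(binding$peptide))))
  }
  pa <- expand(mutations_a); pb <- expand(mutations_b)
  sa <- score(pa); sb <- score(pb)
  pep_key <- function(s) {
    if (nrow(s) == 0) character() else paste(s$peptide, s$mhc_allele, sep = "|")
  }
  list(lesion_a = sa$strong,
       lesion_b = sb$strong,
       counts = c(lesion_a = length(unique(pep_key(sa$strong))),
                  lesion_b = length(unique(pep_key(sb$strong)))),
       venn_peptide = venn_partition(pep_key(sa$strong), pep_key(sb$strong)),
       venn_mutation = venn_partition(unique(sa$strong$mutation),
                                      unique(sb$strong$mutation)),
       missing_from_binding = sort(unique(c(sa$missing, sb$missing))))
}

#' Deterministic stub binding predictor
#'
#' Assigns each (peptide, allele) pair a reproducible pseudo %Rank derived
#' from a hash of the pair, uniform on (0, `max_rank`). This is a stand-in
#' for an external MHC binding predictor so that the enumeration/filter/
#' partition machinery can be exercised end-to-end without one; the ranks
#' carry no biology.
#'
#' @param peptides character vector.
#' @param alleles character vector (recycled against peptides).
#' @param max_rank upper end of the pseudo-rank scale.
#' @return data.frame `peptide, mhc_allele, percent_rank`.
#' @export
stub_binding_table <- function(peptides, alleles = "HLA-A*02:01",
                               max_rank = 100) {
  grid <- expand.grid(peptide = unique(peptides),
                      mhc_allele = unique(alleles),
                      stringsAsFactors = FALSE)
  hash1 <- function(s) {
    # deterministic polynomial hash onto (0, 1); no RNG involvement
    vapply(strsplit(s, ""), function(ch) {
      h <- 7
      for (x in utf8ToInt(paste(ch, collapse = ""))) h <- (h * 131 + x) %% 1e9
      (h + 0.5) / 1e9
    }, numeric(1))
  }
  grid$percent_rank <- max_rank * hash1(paste(grid$peptide, grid$mhc_allele))
  grid
}
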