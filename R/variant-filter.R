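#' Somatic variant consensus filtering
#'
#' Candidate somatic mutations are screened with the exclusion criteria used
#' for tumor/normal whole-exome data: low total depth, low tumor variant
#' allele frequency, mutant support in the germline control, single-strand
#' support, and presence in population databases of normal genomes. A call is
#' rejected if \emph{any} enabled criterion fires; all failing criteria are
#' recorded for every call so that per-criterion tallies do not depend on
#' evaluation order.
#'
#' @name variant_filter
NULL

#' Filter criteria presets
#'
#' `filter_criteria()` builds the threshold set used by
#' [apply_somatic_filters()]. Two presets are provided: `"human"` enables all
#' five criteria (total reads < 20, tumor VAF < 0.05, germline mutant reads
#' > 2, single-strand support, population-database membership); `"mouse"`
#' drops the germline-support and population-database criteria, as cell-line
#' data have no matched germline database.
#'
#' All inequalities are strict as stated: a call with exactly 20 total reads,
#' VAF exactly 0.05 or exactly 2 germline mutant reads is retained.
#'
#' @param preset `"human"` or `"mouse"`.
#' @param min_total_reads reject when tumor total reads are below this.
#' @param min_vaf reject when tumor VAF is below this fraction.
#' @param max_germline_alt_reads reject when the normal sample has more than
#'   this many mutant reads; `NA` disables the criterion (mouse preset).
#' @param require_both_strands reject calls whose alternate reads sit on one
#'   strand only.
#' @param exclude_population_db reject calls flagged as present in a
#'   population database of normal genomes.
#' @return a list of class `"filter_criteria"`.
#' @examples
#' filter_criteria("human")
#' filter_criteria("mouse")
#' @export
filter_criteria <- function(preset = c("human", "mouse"),
                            min_total_reads = 20,
                            min_vaf = 0.05,
                            max_germline_alt_reads = NULL,
                            require_both_strands = TRUE,
                            exclude_population_db = NULL) {
  preset <- match.arg(preset)
  if (is.null(max_germline_alt_reads)) {
    max_germline_alt_reads <- if (preset == "human") 2L else NA_integer_
  }
  if (is.null(exclude_population_db)) {
    exclude_population_db <- preset == "human"
  }
  stopifnot(min_total_reads >= 0, min_vaf >= 0,
            is.na(max_germline_alt_reads) || max_germline_alt_reads >= 0)
  structure(list(preset = preset,
                 min_total_reads = min_total_reads,
                 min_vaf = min_vaf,
                 max_germline_alt_reads = max_germline_alt_reads,
                 require_both_strands = isTRUE(require_both_strands),
                 exclude_population_db = isTRUE(exclude_population_db)),
            class = "filter_criteria")
}

# Column contract for a candidate-variant table; consequence is optional for
# filtering but required by count_nonsynonymous().
.variant_cols <- c("chrom", "pos", "ref", "alt",
                   "tumor_alt_fwd", "tumor_alt_rev",
                   "tumor_ref_fwd", "tumor_ref_rev",
                   "normal_alt", "normal_total", "in_population_db")

validate_variant_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  missing <- setdiff(.variant_cols, names(calls))
  if (length(missing) > 0) {
    stop("variant table lacks columns: ", paste(missing, collapse = ", "))
  }
  counts <- c("tumor_alt_fwd", "tumor_alt_rev", "tumor_ref_fwd",
              "tumor_ref_rev", "normal_alt", "normal_total")
  for (cl in counts) {
    v <- calls[[cl]]
    if (any(is.na(v)) || any(v < 0)) stop("negative or missing counts in ", cl)
  }
  if (any(calls$normal_alt > calls$normal_total)) {
    stop("normal_alt exceeds normal_total")
  }
  if (any(calls$pos < 1)) stop("positions must be 1-based (pos >= 1)")
  if (any(calls$ref == calls$alt)) stop("ref and alt alleles must differ")
  if (any(grepl(",", calls$alt, fixed = TRUE))) {
    stop("multi-allelic rows detected; split to one alt allele per row")
  }
  invisible(calls)
}

#' Tumor variant allele frequency
#'
#' VAF = alternate-supporting reads / total reads in the tumor sample, with
#' strand-resolved counts summed first.
#'
#' @param calls data.frame with the per-strand count columns
#'   `tumor_alt_fwd`, `tumor_alt_rev`, `tumor_ref_fwd`, `tumor_ref_rev`.
#' @return numeric vector of fractions in \[0, 1\].
#' @examples
#' tumor_vaf(data.frame(tumor_alt_fwd = 5, tumor_alt_rev = 5,
#'                      tumor_ref_fwd = 45, tumor_ref_rev = 45))  # 0.10
#' @export
tumor_vaf <- function(calls) {
  alt <- calls$tumor_alt_fwd + calls$tumor_alt_rev
  tot <- alt + calls$tumor_ref_fwd + calls$tumor_ref_rev
  if (any(tot == 0)) {
    stop("zero tumor depth: VAF undefined (such calls also fail the total-read criterion)")
  }
  alt / tot
}

#' Apply somatic-mutation exclusion criteria
#'
#' Evaluates every enabled criterion for every call (no short-circuit) and
#' rejects a call when at least one fires. Criterion labels:
#' `total_reads`, `low_vaf`, `germline_support`, `single_strand`,
#' `population_db`.
#'
#' @param calls candidate-variant data.frame (see [validate_variant_calls()]
#'   for the column contract).
#' @param criteria a [filter_criteria()] object.
#' @return a list of class `"filter_report"` with elements `retained`
#'   (data.frame), `rejected` (data.frame with a `failed_criteria` list
#'   column), `tally` (named integer vector over criterion labels) and
#'   `criteria`.
#' @examples
#' calls <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "T",
#'                     tumor_alt_fwd = 5, tumor_alt_rev = 5,
#'                     tumor_ref_fwd = 45, tumor_ref_rev = 45,
#'                     normal_alt = 0, normal_total = 40,
#'                     in_population_db = FALSE)
#' apply_somatic_filters(calls, filter_criteria("human"))$tally
#' @export
apply_somatic_filters <- function(calls, criteria = filter_criteria("human")) {
  stopifnot(inherits(criteria, "filter_criteria"))
  labels <- c("total_reads", "low_vaf", "germline_support",
              "single_strand", "population_db")
  if (nrow(calls) == 0) {
    return(structure(list(retained = calls,
                          rejected = cbind(calls[0, , drop = FALSE],
                                           failed_criteria = I(list())),
                          tally = stats::setNames(integer(length(labels)), labels),
                          criteria = criteria),
                     class = "filter_report"))
  }
  validate_variant_calls(calls)

  alt <- calls$tumor_alt_fwd + calls$tumor_alt_rev
  tot <- alt + calls$tumor_ref_fwd + calls$tumor_ref_rev
  vaf <- ifelse(tot > 0, alt / tot, 0)

  fails <- cbind(
    total_reads      = tot < criteria$min_total_reads,
    low_vaf          = vaf < criteria$min_vaf,
    germline_support = if (is.na(criteria$max_germline_alt_reads)) {
      rep(FALSE, nrow(calls))
    } else {
      calls$normal_alt > criteria$max_germline_alt_reads
    },
    single_strand    = if (criteria$require_both_strands) {
      # the mutation present on only one strand: either ALT strand count is 0
      calls$tumor_alt_fwd == 0 | calls$tumor_alt_rev == 0
    } else rep(FALSE, nrow(calls)),
    population_db    = if (criteria$exclude_population_db) {
      as.logical(calls$in_population_db)
    } else rep(FALSE, nrow(calls))
  )

  any_fail <- rowSums(fails) > 0
  rejected <- calls[any_fail, , drop = FALSE]
  rejected$failed_criteria <- lapply(which(any_fail), function(i) {
    labels[fails[i, ]]
  })
  structure(list(retained = calls[!any_fail, , drop = FALSE],
                 rejected = rejected,
                 tally = stats::setNames(colSums(fails), labels),
                 criteria = criteria),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Somatic filter report (", x$criteria$preset, " preset)\n", sep = "")
  cat("  retained:", nrow(x$retained), " rejected:", nrow(x$rejected), "\n")
  cat("  failures per criterion:\n")
  for (nm in names(x$tally)) cat(sprintf("    %-17s %d\n", nm, x$tally[[nm]]))
  invisible(x)
}

#' Count retained nonsynonymous mutations
#'
#' The nonsynonymous count of the retained set is the TMB surrogate used for
#' interlesion Venn comparisons.
#'
#' @param report a `"filter_report"` from [apply_somatic_filters()].
#' @return integer count.
#' @export
count_nonsynonymous <- function(report) {
  stopifnot(inherits(report, "filter_report"))
  cons <- report$retained$consequence
  if (nrow(report$retained) == 0) return(0L)
  if (is.null(cons) || any(is.na(cons))) {
    stop("consequence annotation missing on retained calls")
  }
  sum(cons == "nonsynonymous")
}

#' Read and write candidate-variant tables
#'
#' The TSV dialect carries one alternate allele per row with the columns
#' `chrom, pos, ref, alt, tumor_alt_fwd, tumor_alt_rev, tumor_ref_fwd,
#' tumor_ref_rev, normal_alt, normal_total, in_population_db[, consequence]`.
#' Positions are 1-based (VCF convention).
#'
#' @param path file path.
#' @return `read_variant_tsv()` returns a validated data.frame.
#' @export
read_variant_tsv <- function(path) {
  calls <- utils::read.delim(path, stringsAsFactors = FALSE)
  calls$in_population_db <- as.logical(calls$in_population_db)
  validate_variant_calls(calls)
  calls
}

#' @rdname read_variant_tsv
#' @param report a `"filter_report"`.
#' @param tsv_path destination for the retained calls (TSV); `NULL` to skip.
#' @param json_path destination for the criterion tally (JSON); `NULL` to skip.
#' @export
write_filter_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "filter_report"))
  if (!is.null(tsv_path)) {
    utils::write.table(report$retained, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(preset = report$criteria$preset,
                              retained = nrow(report$retained),
                              rejected = nrow(report$rejected),
                              tally = as.list(report$tally)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
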