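#' Fold enrichment of vector-genome reads
#'
#' Ratio of the observed number of reads mapping to the integrated vector
#' genome to the number expected by chance at the same sequencing depth
#' without enrichment:
#' \deqn{\mathrm{fold} = \frac{\mathrm{observed}}{(a b)\,(c d)/e}}
#' where `a` is the number of input genomes, `b` the vector copy number per
#' genome, `c` the total number of sequenced reads, `d` the average read size
#' in bases and `e` the total input bases contributed by the input genomes.
#' The expectation counts reads rather than bases because a junction read
#' carries a fixed amount of vector sequence however long its host portion
#' is.
#'
#' @param observed number of reads mapped onto the integrated vector genome.
#' @param a number of input genomes.
#' @param b vector copy number (copies per genome).
#' @param c total number of sequenced reads.
#' @param d average read size (bases).
#' @param e total input bases based on input genomes.
#' @return dimensionless enrichment ratio.
#' @examples
#' fold_enrichment(observed = 1, a = 1000, b = 2, c = 100, d = 10000,
#'                 e = 6.4e12)   # 3200
#' @export
fold_enrichment <- function(observed, a, b, c, d, e) {
  vals <- c(a = a, b = b, c = c, d = d, e = e)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("a, b, c, d, e must all be strictly positive and finite")
  if (!is.finite(observed) || observed < 0)
    stop("observed must be >= 0")
  if (e < a) stop("e must be at least a (>=1 base per input genome)")
  expected <- (a * b) * (c * d) / e
  observed / expected
}

#' Total input bases from input genomes
#'
#' Convenience helper for the common case where the total input bases `e`
#' are not measured directly: `e = a * genome_size`.
#'
#' @param a number of input genomes.
#' @param genome_size haploid genome size in bases.
#' @export
input_bases <- function(a, genome_size) a * genome_size

#' Summarise a pipeline run
#'
#' One row mirroring the per-sample run table: input reads, filter-bucket
#' diagnostics, reads mapped onto the vector genome, junction calls, unique
#' integration sites, VCN and fold enrichment.  Raw counts are never rounded.
#' Bucket conservation (buckets partition the input reads) is asserted.
#'
#' @param result an `is_result` from [detect_sites()].
#' @param sample sample label.
#' @param vcn vector copy number (input; measured externally).
#' @param enrichment optional named list with `a`, `d`, `e` (and optionally
#'   `c`, default the input read count) for [fold_enrichment()]; `b` defaults
#'   to `vcn`.  When absent, fold enrichment is reported as NA.
#' @return one-row `data.frame`.
#' @export
summarize_run <- function(result, sample = "sample", vcn = NA_real_,
                          enrichment = NULL) {
  if (!inherits(result, "is_result"))
    stop("missing stage artifact: detect_sites() result required")
  counts <- result$counts
  if (sum(counts) != result$n_input)
    stop("bucket conservation violated: buckets sum to ", sum(counts),
         " but input had ", result$n_input, " reads")
  fe <- NA_real_
  if (!is.null(enrichment) && result$n_input > 0L) {
    need <- setdiff(c("a", "d", "e"), names(enrichment))
    if (length(need) > 0L)
      stop("enrichment inputs missing: ", paste(need, collapse = ", "))
    fe <- fold_enrichment(observed = result$lv_mapped,
                          a = enrichment$a,
                          b = enrichment$b %||% vcn,
                          c = enrichment$c %||% result$n_input,
                          d = enrichment$d, e = enrichment$e)
  }
  data.frame(sample = sample,
             input_reads = result$n_input,
             dropped_quality = counts[["dropped_quality"]],
             dropped_size = counts[["dropped_size"]],
             lv_mapped = result$lv_mapped,
             episome = counts[["episome"]],
             no_structure = counts[["no_structure"]],
             ambiguous = counts[["ambiguous"]],
             junction_calls = counts[["member_of_site"]],
             n_sites = nrow(result$sites),
             n_bidirectional = sum(result$sites$bidirectional),
             vcn = vcn,
             fold_enrichment = fe,
             stringsAsFactors = FALSE)
}
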