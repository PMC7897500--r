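#' Build a minimizer index over a reference
#'
#' Indexes canonical (w,k)-minimizers of every sequence, the usual long-read
#' seeding scheme.  Defaults (k = 15, w = 10) match the regime production
#' long-read mappers use for genomic DNA.
#'
#' @param reference a [Biostrings::DNAStringSet], named character vector, or
#'   path to a FASTA file.
#' @param k k-mer size (4..26).
#' @param w minimizer window (number of consecutive k-mer starts).
#' @return object of class `"minimizer_index"`.
#' @export
build_index <- function(reference, k = 15L, w = 10L) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (methods::is(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
  } else {
    seqs <- reference
  }
  if (length(seqs) == 0L) stop("reference is empty")
  nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
  if (is.null(names(seqs))) names(seqs) <- nm
  ptr <- .mz_index_build(unname(seqs), nm, as.integer(k), as.integer(w))
  structure(list(ptr = ptr, names = nm,
                 lengths = stats::setNames(nchar(seqs), nm),
                 k = as.integer(k), w = as.integer(w)),
            class = "minimizer_index")
}

#' @export
print.minimizer_index <- function(x, ...) {
  st <- .mz_index_stats(x$ptr)
  cat(sprintf("minimizer_index: %d target(s), k=%d w=%d, %s minimizer positions\n",
              length(x$names), x$k, x$w,
              format(st$n_positions, big.mark = ",")))
  invisible(x)
}

#' Index summary statistics
#' @param index a [build_index()] result.
#' @return list with `n_distinct_kmers`, `n_positions`, `k`, `w`.
#' @export
index_stats <- function(index) .mz_index_stats(index$ptr)

#' Selected minimizers of an index (for inspection and testing)
#' @param index a [build_index()] result.
#' @return `data.frame` with `target`, `pos` (0-based), `strand`, `hash`,
#'   `n_hits`.
#' @export
index_minimizers <- function(index) {
  df <- .mz_index_minimizers(index$ptr)
  df$target <- index$names[df$target]
  df[order(df$target, df$pos), , drop = FALSE]
}

#' Canonical hashed k-mer table of a sequence (testing hook)
#'
#' Exposes the hash primitive so an exhaustive sliding-window oracle can
#' verify minimizer selection independently of the C++ window scan.
#'
#' @param sequence DNA string.
#' @param k k-mer size.
#' @return `data.frame` with `pos` (0-based), `hash` (NA where the k-mer is
#'   invalid or strand-symmetric), `strand`.
#' @export
kmer_hashes <- function(sequence, k = 15L) {
  .mz_kmer_table(as.character(sequence), as.integer(k))
}

#' Align one read against a minimizer index
#'
#' Seed-and-chain alignment: minimizer anchors are chained colinearly per
#' (target, strand), chains are refined to base level by piecewise banded
#' dynamic programming (linear gap penalties) with x-drop end extension, and
#' the resulting spans are returned best-first.  Identity is
#' `matches / block_length` where the block length counts aligned columns
#' including gaps.
#'
#' @param read DNA string (or [Biostrings::DNAString]).
#' @param index a [build_index()] result.
#' @param min_chain_anchors minimum chained anchors for a reportable span.
#' @param min_identity minimum identity of a reportable span.
#' @param max_chains maximum chains refined per (target, strand).
#' @param band banded-DP half width.
#' @param xdrop extension stops when the score drops this far below the best.
#' @param max_gap maximum anchor-to-anchor gap within a chain (bp).
#' @param max_occ seeds occurring more often than this are skipped.
#' @param query_id id recorded in the output.
#' @return span `data.frame` (see [read_alignments()] for columns), sorted by
#'   score descending with deterministic tie-breaking (lowest target
#'   coordinate, then target name).  Zero rows if unalignable.
#' @export
align_read <- function(read, index, min_chain_anchors = 4L,
                       min_identity = 0.8, max_chains = 8L, band = 50L,
                       xdrop = 50L, max_gap = 5000L, max_occ = 200L,
                       query_id = "query") {
  stopifnot(inherits(index, "minimizer_index"))
  read <- toupper(as.character(read))
  df <- .mz_align(index$ptr, read, as.integer(min_chain_anchors),
                  min_identity, as.integer(max_chains), as.integer(band),
                  as.integer(xdrop), as.integer(max_gap), as.integer(max_occ))
  n <- nrow(df)
  out <- data.frame(
    query_id = rep(query_id, n), query_length = rep(nchar(read), n),
    query_start = df$query_start, query_end = df$query_end,
    strand = as.character(df$strand), target_name = index$names[df$target],
    target_length = unname(index$lengths[df$target]),
    target_start = df$target_start, target_end = df$target_end,
    matches = df$matches, block_length = df$block_length,
    score = as.numeric(df$score), is_primary = seq_len(n) == 1L,
    stringsAsFactors = FALSE)
  out
}

#' Two-phase read triage: vector first, then host
#'
#' Phase 1 aligns each read to the provirus construct.  Only reads with a
#' vector (LV) span proceed to phase 2, where the portion of the read outside
#' the LV span (minus a small overlap allowance for the target-site
#' duplication) is aligned to the host genome; reads without an LV span are
#' never host-aligned, mirroring the vector-first gate of the protocol.  Host
#' uniqueness is decided by a best/second-best score ratio rather than a
#' mapper-specific MAPQ, because the construct and host may both contain
#' repeats (e.g. the two LTR copies).
#'
#' @param reads [Biostrings::QualityScaledDNAStringSet], `DNAStringSet`, or
#'   named character vector.
#' @param construct_index minimizer index of the provirus construct.
#' @param host_index minimizer index of the host genome.
#' @param uniqueness_ratio best host score must be at least this multiple of
#'   the runner-up for `unique_host = TRUE`.
#' @param min_host_anchor minimum host-aligned query length (bp).
#' @param tsd_max largest target-site duplication allowed to overlap the LV
#'   span on the read.
#' @param lv_alignments,host_alignments optional precomputed span tables from
#'   [read_alignments()] (external PAF/SAM); when supplied the internal
#'   aligner is bypassed for that phase.  Host spans are still gated on the
#'   presence of an LV span.
#' @param ... passed to [align_read()].
#' @return list of per-read `triage_result` records, each a list with
#'   `read_id`, `read_length`, `lv_spans`, `host_spans`, `lv_best`,
#'   `host_best`, `unique_host`, `classification` in
#'   `{junction_candidate, vector_only, host_only, unmapped, ambiguous}`.
#' @export
triage_reads <- function(reads, construct_index, host_index,
                         uniqueness_ratio = 1.2, min_host_anchor = 200L,
                         tsd_max = 7L, lv_alignments = NULL,
                         host_alignments = NULL, ...) {
  seqs <- as.character(reads)
  ids <- names(seqs) %||% paste0("read", seq_along(seqs))
  lv_ext <- if (!is.null(lv_alignments)) split(lv_alignments, lv_alignments$query_id)
  host_ext <- if (!is.null(host_alignments)) split(host_alignments, host_alignments$query_id)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    rd <- seqs[[i]]
    id <- ids[[i]]
    lv <- if (!is.null(lv_ext)) {
      sp <- lv_ext[[id]] %||% empty_spans()
      sp[order(-sp$score, sp$target_start, sp$target_name), , drop = FALSE]
    } else {
      align_read(rd, construct_index, query_id = id, ...)
    }
    rec <- list(read_id = id, read_length = nchar(rd), lv_spans = lv,
                host_spans = empty_spans(), lv_best = NULL, host_best = NULL,
                unique_host = NA, classification = "host_only")
    if (nrow(lv) > 0L) {
      rec$lv_best <- lv[1L, , drop = FALSE]
      # Mask: align only the read portion beyond the LV span.  The vector
      # target ends at the terminus so the LV span cannot overrun the
      # junction; masking exactly at its read-side end keeps the host span
      # from creeping back over the vector portion on coincidental matches.
      mask_from <- rec$lv_best$query_end
      host <- if (!is.null(host_ext)) {
        sp <- host_ext[[id]] %||% empty_spans()
        sp <- sp[sp$query_start >= mask_from, , drop = FALSE]
        sp[order(-sp$score, sp$target_start, sp$target_name), , drop = FALSE]
      } else if (nchar(rd) - mask_from >= host_index$k) {
        sub <- substr(rd, mask_from + 1L, nchar(rd))
        sp <- align_read(sub, host_index, query_id = id, ...)
        sp$query_start <- sp$query_start + mask_from
        sp$query_end <- sp$query_end + mask_from
        sp$query_length <- nchar(rd)
        sp
      } else empty_spans()
      rec$host_spans <- host
      ok <- host[host$query_end - host$query_start >= min_host_anchor, ,
                 drop = FALSE]
      if (nrow(ok) > 0L) {
        rec$host_best <- ok[1L, , drop = FALSE]
        rec$unique_host <- nrow(ok) == 1L ||
          ok$score[1L] >= uniqueness_ratio * ok$score[2L]
        rec$classification <- if (rec$unique_host) "junction_candidate"
                              else "ambiguous"
      } else {
        rec$unique_host <- FALSE
        rec$classification <- "vector_only"
      }
    }
    class(rec) <- "triage_result"
    out[[i]] <- rec
  }
  out
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("triage_result %s (%d bp): %s, %d LV span(s), %d host span(s)\n",
              x$read_id, x$read_length, x$classification, nrow(x$lv_spans),
              nrow(x$host_spans)))
  invisible(x)
}
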