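#' Read basecalled long reads from FASTQ
#'
#' Thin wrapper around [Biostrings::readQualityScaledDNAStringSet()] with
#' Phred+33 qualities.  Returns the field-standard container so downstream
#' filters can work on widths and quality matrices directly.
#'
#' @param path FASTQ file (uncompressed or gzip).
#' @return A [Biostrings::QualityScaledDNAStringSet]; zero-length for an
#'   empty file.
#' @export
read_fastq <- function(path) {
  info <- file.info(path)
  if (is.na(info$size)) stop("no such file: ", path)
  if (info$size == 0L)
    return(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character())))
  # validate record shape first: the Biostrings reader is lenient about
  # sequence/quality length mismatches, which must be a hard error
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", length(lines), " non-empty lines")
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqlen <- nchar(lines[seq(2L, length(lines), by = 4L)])
  quallen <- nchar(lines[seq(4L, length(lines), by = 4L)])
  bad <- which(seqlen != quallen)
  if (length(bad) > 0L)
    stop("sequence/quality length mismatch for record ",
         sub("^@", "", ids[bad[1L]]))
  suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path,
                                              quality.scoring = "phred"))
}

#' Write long reads to FASTQ (Phred+33)
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' Mean Phred quality per read
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @return numeric vector of per-read mean Phred scores (NaN for empty reads).
#' @export
mean_quality <- function(reads) {
  if (length(reads) == 0L) return(numeric(0))
  q <- methods::as(Biostrings::quality(reads), "IntegerList")
  vapply(q, function(x) mean(as.numeric(x)), numeric(1))
}

empty_spans <- function() {
  data.frame(query_id = character(), query_length = integer(),
             query_start = integer(), query_end = integer(),
             strand = character(), target_name = character(),
             target_length = integer(), target_start = integer(),
             target_end = integer(), matches = integer(),
             block_length = integer(), score = numeric(),
             is_primary = logical(), stringsAsFactors = FALSE)
}

#' Import alignments from PAF or a SAM subset
#'
#' Normalises external long-read alignments to the internal `AlignmentSpan`
#' table: 0-based half-open query and target intervals, strand flag, match
#' and block-length counts.  The SAM dialect is deliberately narrow: flags
#' 0/16/256/2048 (with 0x1/0x4 handled), CIGAR operations M/I/D/S/H/=/X.
#' Anything else raises an explicit "unsupported" error rather than being
#' skipped silently.
#'
#' @param path alignment file.
#' @param dialect `"paf"` or `"sam"`.
#' @return `data.frame` with columns `query_id`, `query_length`,
#'   `query_start`, `query_end`, `strand`, `target_name`, `target_length`,
#'   `target_start`, `target_end`, `matches`, `block_length`, `score`,
#'   `is_primary`.
#' @export
read_alignments <- function(path, dialect = c("paf", "sam")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "paf") parse_paf(lines) else parse_sam(lines)
}

parse_paf <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_spans())
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L)
      stop("unparseable PAF line ", i, ": expected >=12 fields, got ",
           length(f))
    num <- suppressWarnings(as.integer(f[c(2:4, 7:12)]))
    if (anyNA(num) || !f[5L] %in% c("+", "-"))
      stop("unparseable PAF line ", i)
    tp <- grep("^tp:A:", f, value = TRUE)
    is_primary <- if (length(tp) > 0L) substring(tp[1L], 6L, 6L) == "P" else TRUE
    rows[[i]] <- data.frame(
      query_id = f[1L], query_length = num[1L], query_start = num[2L],
      query_end = num[3L], strand = f[5L], target_name = f[6L],
      target_length = num[4L], target_start = num[5L], target_end = num[6L],
      matches = num[7L], block_length = num[8L], score = as.numeric(num[7L]),
      is_primary = is_primary, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  validate_spans(out)
  out
}

#' Walk a CIGAR string into query/target interval lengths
#' @noRd
cigar_walk <- function(cigar, line = NA) {
  ops <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1L]]
  if (length(ops) == 0L || sum(nchar(ops)) != nchar(cigar))
    stop("unparseable CIGAR", if (!is.na(line)) paste0(" at line ", line))
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  bad <- setdiff(unique(op), c("M", "I", "D", "S", "H", "=", "X"))
  if (length(bad) > 0L)
    stop("unsupported CIGAR operation '", bad[1L], "'",
         if (!is.na(line)) paste0(" at line ", line))
  lead_clip <- 0L
  i <- 1L
  while (i <= length(op) && op[i] %in% c("S", "H")) {
    lead_clip <- lead_clip + n[i]; i <- i + 1L
  }
  aligned <- op %in% c("M", "=", "X")
  qlen_aln <- sum(n[aligned | op == "I"])
  tlen_aln <- sum(n[aligned | op == "D"])
  block <- sum(n[aligned | op == "I" | op == "D"])
  matches <- sum(n[op == "="])
  if (!any(op == "=")) matches <- sum(n[op == "M"])  # M: matches unknown, upper bound
  total_q <- sum(n[op %in% c("M", "=", "X", "I", "S", "H")])
  list(lead_clip = lead_clip, query_aligned = qlen_aln,
       target_aligned = tlen_aln, block = block, matches = matches,
       query_length = total_q)
}

parse_sam <- function(lines) {
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  tlens <- local({
    sq <- lines[startsWith(lines, "@SQ")]
    if (length(sq) == 0L) return(integer(0))
    nm <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    stats::setNames(ln, nm)
  })
  if (length(body) == 0L) return(empty_spans())
  rows <- list()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) stop("unparseable SAM line ", i)
    flag <- suppressWarnings(as.integer(f[2L]))
    if (is.na(flag)) stop("unparseable SAM line ", i)
    known <- bitwOr(bitwOr(16L, 256L), bitwOr(2048L, 4L))
    if (bitwAnd(flag, bitwNot(known)) != 0L)
      stop("unsupported SAM flag ", flag, " at line ", i,
           ": only 0/4/16/256/2048 combinations are handled")
    if (bitwAnd(flag, 4L) != 0L) next  # unmapped
    cw <- cigar_walk(f[6L], line = i)
    strand <- if (bitwAnd(flag, 16L) != 0L) "-" else "+"
    qlen <- cw$query_length
    qs <- cw$lead_clip
    qe <- qs + cw$query_aligned
    if (strand == "-") {  # SAM clips are on the reverse-complemented read
      qs2 <- qlen - qe; qe <- qlen - qs; qs <- qs2
    }
    ts <- suppressWarnings(as.integer(f[4L])) - 1L  # SAM POS is 1-based
    if (is.na(ts) || ts < 0L) stop("unparseable SAM line ", i)
    nm <- f[3L]
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = f[1L], query_length = qlen, query_start = qs,
      query_end = qe, strand = strand, target_name = nm,
      target_length = if (nm %in% names(tlens)) tlens[[nm]] else NA_integer_,
      target_start = ts, target_end = ts + cw$target_aligned,
      matches = cw$matches, block_length = cw$block,
      score = as.numeric(cw$matches),
      is_primary = bitwAnd(flag, bitwOr(256L, 2048L)) == 0L,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_spans())
  out <- do.call(rbind, rows)
  validate_spans(out)
  out
}

validate_spans <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  stopifnot(all(x$query_end > x$query_start),
            all(x$target_end > x$target_start),
            all(x$matches <= x$block_length))
  invisible(x)
}

#' Write integration sites to BED6 or TSV
#'
#' BED output is 0-based half-open with 1-bp features at the junction
#' coordinate, `name` = site id, `score` = supporting read count, and the
#' provirus strand in column 6.  TSV output carries all site fields
#' (including TSD estimate and any annotation columns) and round-trips
#' losslessly through [read_sites()].
#'
#' @param sites site `data.frame` as produced by [cluster_calls()] (possibly
#'   annotated).
#' @param path output file.
#' @param format `"bed"` or `"tsv"`.
#' @export
write_sites <- function(sites, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    if (nrow(sites) == 0L) {
      writeLines(character(0), path)
      return(invisible(path))
    }
    bed <- data.frame(chrom = sites$chromosome, start = sites$position,
                      end = sites$position + 1L, name = sites$is_id,
                      score = sites$support, strand = sites$strand,
                      stringsAsFactors = FALSE)
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    flat <- sites
    for (cl in names(flat))
      if (is.list(flat[[cl]]))
        flat[[cl]] <- vapply(flat[[cl]], paste, character(1), collapse = ",")
    write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  }
  invisible(path)
}

#' @rdname write_sites
#' @param list_columns names of columns to re-split on "," into list columns
#'   (e.g. `member_reads`).
#' @export
read_sites <- function(path, list_columns = c("member_reads", "genes")) {
  out <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = NA)
  for (cl in intersect(list_columns, names(out)))
    out[[cl]] <- strsplit(as.character(out[[cl]]), ",", fixed = TRUE)
  out
}

#' Load a gene model from GFF3 or BED12
#'
#' Builds the internal gene-model object (gene bodies plus exon intervals)
#' from a GFF3 file with `gene`/`exon` features or a BED12 file whose blocks
#' encode exons.  Import is delegated to [rtracklayer::import()].
#'
#' @param path gene model file; format inferred from extension unless given.
#' @param format `"gff3"` or `"bed12"` (default: by extension).
#' @param chrom_lengths named vector of chromosome lengths; required when the
#'   file carries none.
#' @return A `gene_model` object; see [gene_model()].
#' @export
read_gene_model <- function(path, format = NULL,
                            chrom_lengths = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "bed12"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    genes <- gr[gr$type == "gene"]
    names(genes) <- genes$ID %||% genes$Name
    exons <- gr[gr$type == "exon"]
    gene_of_exon <- as.character(unlist(exons$Parent))
    exons$gene <- gene_of_exon
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    genes <- GenomicRanges::granges(gr)
    names(genes) <- gr$name
    bl <- gr$blocks
    exons <- unlist(IRanges::shift(bl, GenomicRanges::start(gr) - 1L))
    exons <- GenomicRanges::GRanges(
      rep(GenomeInfoDb::seqnames(gr), lengths(bl)), exons,
      strand = rep(GenomicRanges::strand(gr), lengths(bl)))
    exons$gene <- rep(gr$name, lengths(bl))
  }
  sl <- GenomeInfoDb::seqlengths(genes)
  if (length(sl) == 0L || all(is.na(sl))) {
    # fall back to sequence-region pragmas, then to the caller
    prag <- grep("^##sequence-region", readLines(path, n = 500L),
                 value = TRUE)
    if (length(prag) > 0L) {
      f <- strsplit(prag, "[ \t]+")
      sl <- stats::setNames(vapply(f, function(x) as.integer(x[4L]),
                                   integer(1)),
                            vapply(f, `[[`, character(1), 2L))
    } else if (!is.null(chrom_lengths)) {
      sl <- chrom_lengths
    } else {
      stop("gene model carries no chromosome lengths; supply chrom_lengths")
    }
  }
  gene_model(genes, exons, sl)
}

#' Construct a gene model object
#'
#' @param genes [GenomicRanges::GRanges] of gene bodies, named by gene id.
#' @param exons [GenomicRanges::GRanges] of exons with an mcols column `gene`.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return list with class `"gene_model"`.
#' @export
gene_model <- function(genes, exons, chrom_lengths) {
  stopifnot(methods::is(genes, "GRanges"), methods::is(exons, "GRanges"))
  if (length(genes) > 0L && is.null(names(genes)))
    stop("genes must be named by gene id")
  structure(list(genes = genes, exons = exons,
                 chrom_lengths = chrom_lengths),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d genes, %d exons, %d chromosome(s)\n",
              length(x$genes), length(x$exons), length(x$chrom_lengths)))
  invisible(x)
}

#' Write a gene model to GFF3
#'
#' @param gm a [gene_model()].
#' @param path output GFF3 path.
#' @export
write_gene_model <- function(gm, path) {
  genes <- gm$genes
  exons <- gm$exons
  if (length(genes) > 0L) {
    genes$type <- "gene"
    genes$ID <- names(genes)
    S4Vectors::mcols(genes) <- S4Vectors::mcols(genes)[c("type", "ID")]
  }
  if (length(exons) > 0L) {
    exons$type <- "exon"
    exons$Parent <- exons$gene
    exons$ID <- paste0(exons$gene, ":exon", seq_along(exons))
    S4Vectors::mcols(exons) <- S4Vectors::mcols(exons)[c("type", "Parent", "ID")]
  }
  prag <- sprintf("##sequence-region %s 1 %d", names(gm$chrom_lengths),
                  as.integer(gm$chrom_lengths))
  all <- c(genes, exons)
  if (length(all) == 0L) {
    writeLines(c("##gff-version 3", prag), path)
    return(invisible(path))
  }
  GenomeInfoDb::seqlevels(all) <- names(gm$chrom_lengths)
  GenomeInfoDb::seqlengths(all) <- unname(gm$chrom_lengths)
  rtracklayer::export(all, path, format = "gff3")
  # rtracklayer does not emit sequence-region pragmas; add them so the
  # chromosome universe survives the round trip
  lines <- readLines(path)
  writeLines(c(lines[1L], prag, lines[-1L]), path)
  invisible(path)
}
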