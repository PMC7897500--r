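# Shared fixture builders.  Everything is generated in code at test time;
# no binary fixtures on disk.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small construct + compliant guide panel, cheap to align against
small_construct <- function(seed = 42L) {
  synthetic_construct(length = 4000L, ltr_length = 300L, seed = seed,
                      cut_window = c(550L, 1100L))
}

# small simulation world: 4 kb construct, short chromosomes, ~4 kb reads
small_params <- function(...) {
  defaults <- list(n_chromosomes = 2L, chrom_length = 150000L, n_genes = 6L,
                   n_integrations = 3L, tsd_length = 6L,
                   read_length_mean = 4000, read_length_sd = 500,
                   reads_per_end = 2L, outward_bias = 1, error_rate = 0,
                   background_fraction = 0.2, circle_fraction = 0.1,
                   seed = 7L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

small_run <- function(...) {
  p <- small_params(...)
  simulate_run(p, construct = small_construct(seed = p$seed + 101L))
}

# hand-built guide table (no PAM realism needed for geometry tests)
fake_guides <- function(cuts_left, cuts_right, total_length,
                        strand_left = "-", strand_right = "+") {
  rows <- list()
  for (i in seq_along(cuts_left))
    rows[[length(rows) + 1L]] <- guide_site(strrep("A", 20), strand_left,
                                            pam_position = max(0L, cuts_left[i] - 6L),
                                            cut_position = cuts_left[i],
                                            arm = "left",
                                            name = paste0("L", i))
  for (i in seq_along(cuts_right))
    rows[[length(rows) + 1L]] <- guide_site(strrep("A", 20), strand_right,
                                            pam_position = cuts_right[i] + 3L,
                                            cut_position = cuts_right[i],
                                            arm = "right",
                                            name = paste0("R", i))
  do.call(rbind, rows)
}

# toy gene model built directly in memory
toy_gene_model <- function() {
  sl <- c(chr1 = 200000L, chr2 = 200000L)
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(10001, 50001, 20001),
                     end = c(30000, 130000, 40000)))
  names(genes) <- c("geneA", "geneB", "geneC")
  exons <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(10001, 25001, 50001, 20001),
                     end = c(12000, 30000, 52000, 22000)))
  exons$gene <- c("geneA", "geneA", "geneB", "geneC")
  gene_model(genes, exons, sl)
}

make_reads <- function(seqs, quals) {
  # quals: integer Phred per read (recycled across bases)
  q <- Biostrings::PhredQuality(vapply(seq_along(seqs), function(i)
    strrep(intToUtf8(quals[[i]] + 33L), nchar(seqs[[i]])), character(1)))
  dna <- Biostrings::DNAStringSet(seqs)
  if (length(dna) > 0L && (is.null(names(dna)) || any(names(dna) == "")))
    names(dna) <- paste0("r", seq_along(dna))
  Biostrings::QualityScaledDNAStringSet(dna, q)
}
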