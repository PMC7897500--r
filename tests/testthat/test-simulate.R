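test_that("make_host is deterministic and writes byte-identical FASTA", {
  p <- small_params()
  h1 <- make_host(p)
  h2 <- make_host(p)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(h1$genome, f1)
  Biostrings::writeXStringSet(h2$genome, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("make_host places the requested genes within bounds", {
  p <- sim_params(n_chromosomes = 3L, chrom_length = 1000000L, n_genes = 30L,
                  seed = 4L)
  h <- make_host(p)
  # independent re-parse through the GFF3 writer/reader round trip
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_model(h$genes, f)
  gm <- read_gene_model(f)
  expect_equal(length(gm$genes), 30L)
  expect_true(all(GenomicRanges::start(gm$genes) >= 1L))
  expect_true(all(GenomicRanges::end(gm$genes) <= 1000000L))
  expect_equal(length(gm$exons), 30L * p$exons_per_gene)
  # genes do not overlap
  expect_equal(sum(GenomicRanges::countOverlaps(gm$genes, gm$genes)),
               length(gm$genes))
  # zero genes -> empty model
  h0 <- make_host(small_params(n_genes = 0L))
  expect_equal(length(h0$genes$genes), 0L)
  f0 <- withr::local_tempfile(fileext = ".gff3")
  write_gene_model(h0$genes, f0)
  expect_equal(length(read_gene_model(
    f0, chrom_lengths = h0$genes$chrom_lengths)$genes), 0L)
})

test_that("gene_density_weights skew gene placement", {
  p <- small_params(n_genes = 12L, gene_density_weights = c(5, 1))
  h <- make_host(p)
  counts <- table(factor(as.character(
    GenomeInfoDb::seqnames(h$genes$genes)), levels = c("chr1", "chr2")))
  expect_gt(counts[["chr1"]], counts[["chr2"]])
})

test_that("plant_integrations duplicates the target-site motif", {
  con <- small_construct()
  for (tsd in c(0L, 6L)) {
    p <- small_params(n_integrations = 2L, tsd_length = tsd)
    host <- make_host(p)
    pl <- plant_integrations(host, con, p)
    expect_equal(nrow(pl$truth), 2L)
    for (i in seq_len(nrow(pl$truth))) {
      tr <- pl$truth[i, ]
      M <- as.character(pl$genome[[tr$chromosome]])
      H <- as.character(host$genome[[tr$chromosome]])
      vs <- pl$vstart[i]
      # direct string inspection: vector body, flanking duplication, host
      vexp <- if (tr$strand == "+") con$sequence else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(con$sequence)))
      expect_identical(substr(M, vs + 1L, vs + con$length), vexp)
      if (tsd > 0L) {
        motif <- substr(H, tr$position + 1L, tr$position + tsd)
        expect_identical(substr(M, vs - tsd + 1L, vs), motif)
        expect_identical(substr(M, vs + con$length + 1L,
                                vs + con$length + tsd), motif)
      } else {
        # tsd = 0: provirus ends abut host with no duplicated bases
        expect_identical(substr(M, vs - 9L, vs),
                         substr(H, tr$position - 9L, tr$position))
        expect_identical(substr(M, vs + con$length + 1L,
                                vs + con$length + 10L),
                         substr(H, tr$position + 1L, tr$position + 10L))
      }
    }
  }
})

test_that("plant_integrations rejects infeasible requests", {
  con <- small_construct()
  p <- small_params(n_integrations = 1000L)
  host <- make_host(p)
  expect_error(plant_integrations(host, con, p), "too large")
})

test_that("error-free outward reads are exact substrings of the planted locus", {
  run <- small_run(n_integrations = 1L, reads_per_end = 1L,
                   background_fraction = 0, circle_fraction = 0, seed = 31L)
  prov <- run$reads$provenance
  M <- run$planted$genome[[run$truth$chromosome[1L]]]
  for (i in seq_along(run$reads$reads)) {
    rd <- Biostrings::DNAString(as.character(run$reads$reads[[i]]))
    fwd <- Biostrings::matchPattern(rd, M)
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(rd), M)
    expect_gt(length(fwd) + length(rev), 0L)
  }
})

test_that("reads begin exactly at the chosen guide cut site", {
  run <- small_run(n_integrations = 1L, reads_per_end = 2L,
                   background_fraction = 0, circle_fraction = 0, seed = 32L)
  prov <- run$reads$provenance
  con <- run$construct
  arms <- arm_specs(con)
  for (i in seq_along(run$reads$reads)) {
    rd <- as.character(run$reads$reads[[i]])
    id <- names(run$reads$reads)[i]
    g <- arms[arms$name == prov$cut_used[prov$read_id == id], ]
    first20 <- substr(rd, 1L, 20L)
    expected <- if (g$arm == "left") {
      # outward toward the left terminus: read starts with the reverse
      # complement of the 20 vector bases left of the cut
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(con$sequence, g$cut_position - 19L, g$cut_position))))
    } else {
      substr(con$sequence, g$cut_position + 1L, g$cut_position + 20L)
    }
    expect_identical(first20, expected)
  }
})

test_that("background reads contain no 30-mer of the construct", {
  run <- small_run(seed = 33L, background_fraction = 0.4)
  con30 <- substring(run$construct$sequence,
                     1:(nchar(run$construct$sequence) - 29L),
                     30:nchar(run$construct$sequence))
  con30 <- c(con30, vapply(con30, revcomp <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    character(1)))
  bg_ids <- run$reads$provenance$read_id[
    run$reads$provenance$class == "background"]
  expect_gt(length(bg_ids), 0L)
  for (id in head(bg_ids, 3L)) {
    rd <- as.character(run$reads$reads[[which(names(run$reads$reads) == id)]])
    rd30 <- substring(rd, 1:(nchar(rd) - 29L), 30:nchar(rd))
    expect_equal(length(intersect(rd30, con30)), 0L)
  }
})

test_that("provenance partitions reads and matches the requested fractions", {
  run <- small_run(n_integrations = 4L, reads_per_end = 3L,
                   background_fraction = 0.3, circle_fraction = 0.1,
                   seed = 34L)
  prov <- run$reads$provenance
  expect_equal(sort(prov$read_id), sort(names(run$reads$reads)))
  expect_equal(anyDuplicated(prov$read_id), 0L)
  n_j <- sum(prov$class %in% c("junction_left", "junction_right"))
  expect_equal(n_j, 4L * 2L * 3L)
  total <- nrow(prov)
  expect_equal(sum(prov$class == "background") / total, 0.3, tolerance = 0.15)
  expect_equal(sum(prov$class == "circle") / total, 0.1, tolerance = 0.3)
})

test_that("reads carry the quality implied by the error rate", {
  run <- small_run(seed = 35L, error_rate = 0.1, n_integrations = 1L,
                   reads_per_end = 1L, background_fraction = 0,
                   circle_fraction = 0)
  expect_equal(unique(round(mean_quality(run$reads$reads))), 10)
  run0 <- small_run(seed = 35L, n_integrations = 1L, reads_per_end = 1L,
                    background_fraction = 0, circle_fraction = 0)
  expect_equal(unique(mean_quality(run0$reads$reads)), 40)
})

test_that("minus-strand integrations carry the reverse-complemented vector", {
  con <- small_construct()
  p <- small_params(n_integrations = 6L, seed = 36L)
  host <- make_host(p)
  pl <- plant_integrations(host, con, p)
  minus <- which(pl$truth$strand == "-")
  expect_gt(length(minus), 0L)
  i <- minus[1L]
  M <- as.character(pl$genome[[pl$truth$chromosome[i]]])
  expect_identical(substr(M, pl$vstart[i] + 1L, pl$vstart[i] + con$length),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(con$sequence))))
})
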