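fake_sites <- function(chrom, pos) {
  n <- length(pos)
  s <- data.frame(is_id = sprintf("IS_%04d", seq_len(n)), chromosome = chrom,
                  position = as.integer(pos), strand = "+",
                  support = 1L, bidirectional = FALSE,
                  tsd_estimate = NA_integer_, stringsAsFactors = FALSE)
  s$member_reads <- as.list(sprintf("r%d", seq_len(n)))
  s
}

test_that("classify_sites matches a brute-force interval-containment oracle", {
  gm <- toy_gene_model()
  set.seed(20)
  sites <- fake_sites(sample(c("chr1", "chr2"), 20L, replace = TRUE),
                      sample.int(200000L, 20L) - 1L)
  ann <- classify_sites(sites, gm)
  # oracle: direct interval checks on the fixture's known coordinates
  for (i in seq_len(nrow(sites))) {
    pos1 <- sites$position[i] + 1L
    ch <- sites$chromosome[i]
    in_exon <- any(ch == as.character(GenomeInfoDb::seqnames(gm$exons)) &
                     pos1 >= GenomicRanges::start(gm$exons) &
                     pos1 <= GenomicRanges::end(gm$exons))
    in_gene <- any(ch == as.character(GenomeInfoDb::seqnames(gm$genes)) &
                     pos1 >= GenomicRanges::start(gm$genes) &
                     pos1 <= GenomicRanges::end(gm$genes))
    want <- if (in_exon) "exon" else if (in_gene) "intron" else "intergenic"
    expect_equal(ann$category[i], want, info = paste("site", i))
    expect_equal(is.na(ann$gene[i]), want == "intergenic")
  }
  fr <- category_fractions(ann)
  expect_equal(sum(fr), 1)
})

test_that("classification edge cases", {
  gm <- toy_gene_model()
  # exon boundary is exonic; one base past the gene end is intergenic
  ann <- classify_sites(fake_sites("chr1", c(10000L, 11999L, 30000L)), gm)
  expect_equal(ann$category, c("exon", "exon", "intergenic"))
  # unknown chromosome errors
  expect_error(classify_sites(fake_sites("chrZ", 5L), gm),
               "unknown chromosome")
  # empty gene model: everything intergenic, nearest gene absent
  empty <- gene_model(GenomicRanges::GRanges(),
                      GenomicRanges::GRanges(gene = character(0)),
                      c(chr1 = 200000L))
  ann0 <- classify_sites(fake_sites("chr1", c(10L, 55L)), empty)
  expect_true(all(ann0$category == "intergenic"))
  expect_true(all(is.na(ann0$nearest_gene)))
})

test_that("nearest_gene distance and tie-breaking", {
  gm <- toy_gene_model()
  # inside geneA -> distance 0
  ng <- nearest_gene(fake_sites("chr1", 15000L), gm)
  expect_equal(ng$gene, "geneA")
  expect_equal(ng$distance, 0L)
  # 500 bp downstream of geneC (only gene on chr2) -> +500
  ng2 <- nearest_gene(fake_sites("chr2", 40499L), gm)
  expect_equal(ng2$gene, "geneC")
  expect_equal(ng2$distance, 500L)
  # upstream gives a negative distance
  ng3 <- nearest_gene(fake_sites("chr2", 19500L), gm)
  expect_equal(ng3$distance, -500L)
  # exact equidistance prefers the gene with the smaller start
  g2 <- GenomicRanges::GRanges(c("chr1", "chr1"),
                               IRanges::IRanges(start = c(100L, 400L),
                                                end = c(200L, 500L)))
  names(g2) <- c("gLeft", "gRight")
  gm_tie <- gene_model(g2, GenomicRanges::GRanges(gene = character(0)),
                       c(chr1 = 1000L))
  tie <- fake_sites("chr1", 299L)   # 1-based 300: 100 bp from both genes
  expect_equal(nearest_gene(tie, gm_tie)$gene, "gLeft")
  expect_equal(nearest_gene(tie, gm_tie)$distance, 100L)
})

test_that("find_mis equals a brute-force group-by", {
  gm <- toy_gene_model()
  # geneB spans 50001..130000 (~80 kb): two sites > 60 kb apart in one gene
  sites <- fake_sites("chr1", c(52000L, 125000L, 15000L, 26000L, 140000L))
  ann <- classify_sites(sites, gm)
  mis <- find_mis(ann)
  # oracle group-by
  pairs <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i)
    if (length(ann$genes[[i]])) data.frame(gene = ann$genes[[i]],
                                           id = ann$is_id[i])))
  want <- table(unique(pairs)$gene)
  want <- want[want >= 2L]
  expect_equal(sort(mis$gene), sort(names(want)))
  expect_equal(mis$n_sites[match(names(want), mis$gene)],
               as.integer(want))
  expect_true("geneB" %in% mis$gene)
  expect_equal(mis$n_sites[mis$gene == "geneB"], 2L)
  expect_gte(diff(range(mis$positions[mis$gene == "geneB"][[1L]])), 60000L)
  # all genes hit once -> empty
  ann1 <- classify_sites(fake_sites("chr1", c(15000L, 52000L)), gm)
  expect_equal(nrow(find_mis(ann1)), 0L)
})

test_that("gene_overlap set arithmetic and conventions", {
  both <- gene_overlap(c("A", "B", "C"), c("C", "D"))
  expect_equal(both$shared, "C")
  expect_equal(both$shared_fraction, 1 / 4)
  expect_equal(both$only_a, c("A", "B"))
  expect_equal(both$only_b, "D")
  expect_equal(gene_overlap(c("A", "B", "C"), c("C", "D"),
                            method = "min")$shared_fraction, 1 / 2)
  expect_equal(gene_overlap(c("X", "Y"), c("X", "Y"))$shared_fraction, 1)
  expect_equal(gene_overlap(c("A"), c("B"))$shared_fraction, 0)
  expect_warning(res <- gene_overlap(character(0), character(0)),
                 "empty")
  expect_equal(res$shared_fraction, 0)
})

test_that("chrom_distribution regression and degenerate inputs", {
  gm <- toy_gene_model()
  # IS counts exactly proportional to gene density -> R^2 = 1
  sl <- c(chr1 = 1e6, chr2 = 2e6, chr3 = 1e6, chr4 = 5e5)
  genes <- GenomicRanges::GRanges(
    rep(c("chr1", "chr2", "chr3", "chr4"), times = c(10L, 8L, 2L, 4L)),
    IRanges::IRanges(start = seq_len(24L) * 100L, width = 10L))
  names(genes) <- paste0("g", 1:24)
  gmx <- gene_model(genes, GenomicRanges::GRanges(gene = character(0)), sl)
  mksites <- function(counts) {
    do.call(rbind, lapply(seq_along(counts), function(ci)
      if (counts[ci] > 0L)
        fake_sites(names(sl)[ci], seq_len(counts[ci]) * 1000L)))
  }
  # site count per chromosome = 2 * gene count  =>  identical densities
  s <- mksites(c(20L, 16L, 4L, 8L))
  cd <- chrom_distribution(s, gmx)
  expect_equal(cd$r_squared, 1.0, tolerance = 1e-12)
  # hand-built table: R^2 equals the closed-form squared Pearson correlation
  s2 <- mksites(c(12L, 30L, 3L, 2L))
  cd2 <- chrom_distribution(s2, gmx)
  x <- cd2$table$gene_density
  y <- cd2$table$site_density
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cd2$r_squared, r^2, tolerance = 1e-12)
  expect_true(cd2$r_squared >= 0 && cd2$r_squared <= 1)
  # constant gene density -> fit undefined, reported NA (no crash)
  flat_genes <- GenomicRanges::GRanges(
    rep(c("chr1", "chr3"), each = 2L),
    IRanges::IRanges(start = c(1, 2, 1, 2) * 100L, width = 10L))
  names(flat_genes) <- paste0("h", 1:4)
  gmflat <- gene_model(flat_genes,
                       GenomicRanges::GRanges(gene = character(0)),
                       sl[c("chr1", "chr3")])
  cd3 <- chrom_distribution(mksites(c(5L, 9L)), gmflat)
  expect_true(is.na(cd3$r_squared))
  # fewer than two chromosomes is an error
  gm1 <- gene_model(genes, GenomicRanges::GRanges(gene = character(0)),
                    sl["chr1"])
  expect_error(chrom_distribution(s, gm1), "at least 2")
  # exclusion removes a chromosome from the universe
  cd4 <- chrom_distribution(s, gmx, exclude = "chr4")
  expect_equal(nrow(cd4$table), 3L)
})

test_that("bin_windows respects half-open boundaries and conserves counts", {
  sl <- c(chr1 = 150000L)
  s <- fake_sites("chr1", c(49999L, 50000L))
  w <- bin_windows(s, sl, window = 50000L)
  expect_equal(w$Value, c(1L, 1L, 0L))
  expect_equal(w$Start, c(0L, 50000L, 100000L))
  expect_equal(w$End, c(50000L, 100000L, 150000L))
  # single site -> exactly one nonzero window
  w1 <- bin_windows(fake_sites("chr1", 123L), sl, window = 50000L)
  expect_equal(sum(w1$Value > 0L), 1L)
  # conservation on 1000 random sites, several window sizes
  set.seed(8)
  s2 <- fake_sites("chr1", sample.int(150000L, 1000L, replace = TRUE) - 1L)
  for (win in c(1000L, 50000L, 64000L))
    expect_equal(sum(bin_windows(s2, sl, window = win)$Value), 1000L)
  expect_error(bin_windows(s, sl, window = 0L), "window")
})
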