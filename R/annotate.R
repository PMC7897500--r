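sites_as_granges <- function(sites, chrom_lengths = NULL) {
  GenomicRanges::GRanges(sites$chromosome,
                         IRanges::IRanges(sites$position + 1L, width = 1L))
}

#' Classify integration sites against a gene model
#'
#' A site is `exon` if its junction coordinate falls in any exon of any gene,
#' else `intron` if it falls in any gene body ("transcriptional unit", TSS to
#' transcription end), else `intergenic`; precedence exon > intron.  A site
#' inside overlapping gene bodies is classified once but attributed to every
#' overlapping gene (column `genes`), because gene-level analyses (multiple
#' integration sites, cross-sample overlap) are membership analyses.
#' Intergenic sites get the nearest gene and a signed distance (positive =
#' rightward of the gene end).
#'
#' @param sites site `data.frame` from [cluster_calls()] (0-based
#'   `position`).
#' @param gene_model a [gene_model()].
#' @return `sites` with added columns `category`, `gene` (NA for
#'   intergenic), `genes` (list column, all overlapping genes),
#'   `nearest_gene`, `nearest_distance`.
#' @export
classify_sites <- function(sites, gene_model) {
  stopifnot(inherits(gene_model, "gene_model"))
  out <- sites
  n <- nrow(sites)
  out$category <- rep(NA_character_, n)
  out$gene <- rep(NA_character_, n)
  out$genes <- vector("list", n)
  out$nearest_gene <- rep(NA_character_, n)
  out$nearest_distance <- rep(NA_integer_, n)
  if (n == 0L) return(out)
  unknown <- setdiff(unique(sites$chromosome), names(gene_model$chrom_lengths))
  if (length(unknown) > 0L)
    stop("unknown chromosome: ", unknown[1L])
  gr <- sites_as_granges(sites)
  genes <- gene_model$genes
  exons <- gene_model$exons
  ov_gene <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
  ov_exon <- GenomicRanges::findOverlaps(gr, exons, ignore.strand = TRUE)
  in_exon <- unique(S4Vectors::queryHits(ov_exon))
  in_gene <- unique(S4Vectors::queryHits(ov_gene))
  for (i in seq_len(n)) {
    hit_genes <- names(genes)[S4Vectors::subjectHits(ov_gene)[
      S4Vectors::queryHits(ov_gene) == i]]
    hit_genes <- sort(unique(hit_genes))
    out$genes[[i]] <- hit_genes
    if (i %in% in_exon) {
      out$category[i] <- "exon"
      ex_genes <- exons$gene[S4Vectors::subjectHits(ov_exon)[
        S4Vectors::queryHits(ov_exon) == i]]
      out$gene[i] <- sort(ex_genes)[1L]
    } else if (i %in% in_gene) {
      out$category[i] <- "intron"
      # tie rule: smaller gene start, then name
      cand <- genes[hit_genes]
      ordc <- order(GenomicRanges::start(cand), names(cand))
      out$gene[i] <- names(cand)[ordc[1L]]
    } else {
      out$category[i] <- "intergenic"
    }
    ng <- nearest_gene(sites[i, , drop = FALSE], gene_model)
    out$nearest_gene[i] <- ng$gene
    out$nearest_distance[i] <- ng$distance
  }
  out
}

#' Category fractions of an annotated site set
#'
#' @param annotated output of [classify_sites()].
#' @return named numeric vector over `exon`, `intron`, `intergenic` summing
#'   to 1 (all zero for an empty set).
#' @export
category_fractions <- function(annotated) {
  cats <- c("exon", "intron", "intergenic")
  if (nrow(annotated) == 0L)
    return(stats::setNames(rep(0, 3L), cats))
  tab <- table(factor(annotated$category, levels = cats))
  as.numeric(tab) / nrow(annotated) -> fr
  stats::setNames(fr, cats)
}

#' Nearest gene to a site
#'
#' Distance 0 if the site lies inside a gene body.  Ties are broken by the
#' smaller gene start, then lexicographic gene name.  The returned distance
#' is signed: positive when the site lies rightward of the gene end, negative
#' when leftward of the gene start.
#'
#' @param site one-row site `data.frame` (0-based `position`).
#' @param gene_model a [gene_model()].
#' @return list with `gene` (NA if the chromosome has no genes) and
#'   `distance`.
#' @export
nearest_gene <- function(site, gene_model) {
  genes <- gene_model$genes
  onchr <- genes[GenomeInfoDb::seqnames(genes) == site$chromosome[1L]]
  if (length(onchr) == 0L)
    return(list(gene = NA_character_, distance = NA_integer_))
  pos1 <- site$position[1L] + 1L  # 1-based
  st <- GenomicRanges::start(onchr)
  en <- GenomicRanges::end(onchr)
  dist <- ifelse(pos1 < st, pos1 - st,          # negative: left of gene
                 ifelse(pos1 > en, pos1 - en,   # positive: right of gene
                        0L))
  o <- order(abs(dist), st, names(onchr))
  list(gene = names(onchr)[o[1L]], distance = as.integer(dist[o[1L]]))
}

#' Genes hit by multiple integration sites (MIS)
#'
#' Reports every gene whose body contains two or more distinct integration
#' sites, regardless of their separation, using the full per-site gene
#' attribution (`genes` column).
#'
#' @param annotated output of [classify_sites()].
#' @return `data.frame` with `gene`, `n_sites`, `positions` (list column),
#'   sorted by `n_sites` descending (ties: gene name).
#' @export
find_mis <- function(annotated) {
  empty <- data.frame(gene = character(), n_sites = integer(),
                      stringsAsFactors = FALSE)
  empty$positions <- list()
  if (nrow(annotated) == 0L) return(empty)
  pairs <- do.call(rbind, lapply(seq_len(nrow(annotated)), function(i) {
    g <- annotated$genes[[i]]
    if (length(g) == 0L) return(NULL)
    data.frame(gene = g, is_id = annotated$is_id[i],
               position = annotated$position[i], stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) return(empty)
  counts <- tapply(pairs$is_id, pairs$gene, function(x) length(unique(x)))
  hit <- names(counts)[counts >= 2L]
  if (length(hit) == 0L) return(empty)
  out <- data.frame(gene = hit, n_sites = as.integer(counts[hit]),
                    stringsAsFactors = FALSE)
  out$positions <- lapply(hit, function(g)
    sort(unique(pairs$position[pairs$gene == g])))
  out <- out[order(-out$n_sites, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-level overlap between two samples
#'
#' Compares the sets of genes hit by integration sites in two samples
#' (intergenic sites excluded upstream).  The shared fraction is Jaccard
#' (`|A intersect B| / |A union B|`) by default; the alternative
#' `"min"` convention divides by the smaller set size.
#'
#' @param genes_a,genes_b character vectors of gene names (duplicates
#'   ignored).
#' @param method `"jaccard"` or `"min"`.
#' @return list: `shared` (sorted character vector), `shared_fraction`,
#'   `only_a`, `only_b`.
#' @export
gene_overlap <- function(genes_a, genes_b, method = c("jaccard", "min")) {
  method <- match.arg(method)
  a <- unique(genes_a[!is.na(genes_a)])
  b <- unique(genes_b[!is.na(genes_b)])
  shared <- sort(intersect(a, b))
  denom <- if (method == "jaccard") length(union(a, b))
           else min(length(a), length(b))
  if (denom == 0L) {
    warning("both gene sets are empty; shared fraction reported as 0")
    frac <- 0
  } else {
    frac <- length(shared) / denom
  }
  list(shared = shared, shared_fraction = frac,
       only_a = sort(setdiff(a, b)), only_b = sort(setdiff(b, a)))
}

#' Chromosome-normalised site distribution vs gene density
#'
#' For each chromosome, computes the integration-site count and gene count
#' normalised to chromosome length, then fits ordinary least squares of site
#' density on gene density and reports the fit R^2 (the squared Pearson
#' correlation).
#'
#' @param sites site `data.frame`.
#' @param gene_model a [gene_model()]; its `chrom_lengths` define the
#'   chromosome universe.
#' @param exclude chromosomes to drop (e.g. `"chrY"` for female-origin
#'   samples).
#' @return list: `table` (`data.frame` with `chromosome`, `length`,
#'   `n_sites`, `n_genes`, `site_density`, `gene_density`), `slope`,
#'   `intercept`, `r_squared` (NA when the fit is degenerate).
#' @export
chrom_distribution <- function(sites, gene_model, exclude = character()) {
  sl <- gene_model$chrom_lengths
  sl <- sl[!names(sl) %in% exclude]
  if (length(sl) < 2L) stop("need at least 2 chromosomes for a fit")
  genes <- gene_model$genes
  tab <- data.frame(
    chromosome = names(sl), length = as.numeric(sl),
    n_sites = vapply(names(sl), function(ch)
      sum(sites$chromosome == ch), integer(1)),
    n_genes = vapply(names(sl), function(ch)
      sum(as.character(GenomeInfoDb::seqnames(genes)) == ch), integer(1)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab$site_density <- tab$n_sites / tab$length
  tab$gene_density <- tab$n_genes / tab$length
  if (stats::var(tab$gene_density) == 0 || stats::var(tab$site_density) == 0) {
    return(list(table = tab, slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_))
  }
  # a perfect fit is legitimate here (proportional synthetic counts)
  fit <- suppressWarnings(lm(site_density ~ gene_density, data = tab))
  list(table = tab, slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Bin sites into fixed-width genome windows
#'
#' Windows are `[i*w, (i+1)*w)` per chromosome (0-based half-open); the
#' output covers every window of every chromosome, ideogram-ready
#' (`Chr`, `Start`, `End`, `Value`).  Total counts are conserved.
#'
#' @param sites site `data.frame` (0-based `position`).
#' @param chrom_lengths named vector of chromosome lengths, or a
#'   [gene_model()].
#' @param window window width (bp), default 50 kb.
#' @return `data.frame` with columns `Chr`, `Start`, `End`, `Value`.
#' @export
bin_windows <- function(sites, chrom_lengths, window = 50000L) {
  if (inherits(chrom_lengths, "gene_model"))
    chrom_lengths <- chrom_lengths$chrom_lengths
  if (window <= 0L) stop("window must be > 0")
  out <- list()
  for (ch in names(chrom_lengths)) {
    n_win <- ceiling(chrom_lengths[[ch]] / window)
    starts <- (seq_len(n_win) - 1L) * window
    ends <- pmin(starts + window, chrom_lengths[[ch]])
    v <- integer(n_win)
    pos <- sites$position[sites$chromosome == ch]
    if (length(pos) > 0L) {
      wi <- pos %/% window + 1L
      tb <- table(wi)
      v[as.integer(names(tb))] <- as.integer(tb)
    }
    out[[ch]] <- data.frame(Chr = ch, Start = starts, End = ends, Value = v,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
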