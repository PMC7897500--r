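#' Simulation parameters
#'
#' Bundles the knobs of the ground-truth simulator.  Defaults encode the
#' stated experimental regime: ~12 kb mean read length, a 5-6 bp target-site
#' duplication (default 6), and a strong but imperfect outward-sequencing
#' bias (the non-A-tailed end is suppressed, not eliminated).
#'
#' @param n_chromosomes number of host chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param n_genes total genes placed across the genome.
#' @param exons_per_gene exons per gene.
#' @param n_integrations number of provirus integrations planted.
#' @param vcn vector copy number (copies/cell), used only for enrichment
#'   bookkeeping.
#' @param tsd_length target-site duplication length in bp (0..7; integrase
#'   biology gives 5-6).
#' @param read_length_mean,read_length_sd truncated-normal read length model.
#' @param reads_per_end junction reads emitted per planted site per vector
#'   end.
#' @param outward_bias probability a junction read leaves the cut toward the
#'   served terminus (wrong-direction reads stay inside the vector).
#' @param error_rate per-base substitution+indel probability.
#' @param background_fraction fraction of emitted reads drawn from host only.
#' @param circle_fraction fraction of vector-only episomal (LTR-circle) reads.
#' @param gene_density_weights optional per-chromosome weights for gene
#'   placement (default uniform); use a skewed vector to test the
#'   gene-density correlation.
#' @param seed integer seed; every simulator stage derives from it.
#' @return list with class `"sim_params"`.
#' @export
sim_params <- function(n_chromosomes = 3L, chrom_length = 1e6, n_genes = 30L,
                       exons_per_gene = 4L, n_integrations = 50L, vcn = 2,
                       tsd_length = 6L, read_length_mean = 12000,
                       read_length_sd = 2000, reads_per_end = 3L,
                       outward_bias = 0.9, error_rate = 0,
                       background_fraction = 0.3, circle_fraction = 0.1,
                       gene_density_weights = NULL, seed = 1L) {
  p <- list(n_chromosomes = as.integer(n_chromosomes),
            chrom_length = as.integer(chrom_length),
            n_genes = as.integer(n_genes),
            exons_per_gene = as.integer(exons_per_gene),
            n_integrations = as.integer(n_integrations), vcn = vcn,
            tsd_length = as.integer(tsd_length),
            read_length_mean = read_length_mean,
            read_length_sd = read_length_sd,
            reads_per_end = as.integer(reads_per_end),
            outward_bias = outward_bias, error_rate = error_rate,
            background_fraction = background_fraction,
            circle_fraction = circle_fraction,
            gene_density_weights = gene_density_weights,
            seed = as.integer(seed))
  probs <- c(p$outward_bias, p$error_rate, p$background_fraction,
             p$circle_fraction)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0,1]")
  if (p$background_fraction + p$circle_fraction >= 1)
    stop("background_fraction + circle_fraction must be < 1")
  if (p$tsd_length < 0L) stop("tsd_length must be >= 0")
  structure(p, class = "sim_params")
}

#' Build a synthetic provirus construct with a valid guide panel
#'
#' Generates a random vector genome with a duplicated terminal repeat (an
#' LTR-like copy of the first `ltr_length` bases at the right end, so the
#' construct genuinely multi-maps) and selects a design-rule-compliant guide
#' panel from the PAM scan: two minus-strand guides serving the left arm and
#' two plus-strand guides serving the right arm, each cut 650-1400 bp from
#' its terminus (outside the LTR) with >= 50 bp within-arm spacing.
#'
#' @param length construct length (bp).
#' @param ltr_length length of the duplicated terminal repeat (bp).
#' @param seed RNG seed.
#' @param guides_per_arm guides chosen per arm.
#' @param cut_window distance window (from the served terminus) for cuts.
#' @param min_pair_spacing within-arm cut spacing (bp).
#' @return a [provirus_construct()] that passes [validate_guide_set()].
#' @export
synthetic_construct <- function(length = 9000L, ltr_length = 600L, seed = 42L,
                                guides_per_arm = 2L,
                                cut_window = c(650L, 1400L),
                                min_pair_spacing = 50L) {
  length <- as.integer(length)
  with_seed(seed, {
    s <- random_dna(length)
    # duplicated terminal repeat (SIN-LTR-like layout)
    substr(s, length - ltr_length + 1L, length) <- substr(s, 1L, ltr_length)
    cand <- scan_pam_sites(s)
    pick <- function(cand, n) {
      chosen <- integer(0)
      for (i in seq_len(nrow(cand))) {
        if (length(chosen) == n) break
        if (all(abs(cand$cut_position[chosen] - cand$cut_position[i]) >=
                min_pair_spacing))
          chosen <- c(chosen, i)
      }
      if (length(chosen) < n)
        stop("could not find ", n, " spaced guide candidates")
      cand[chosen, , drop = FALSE]
    }
    left <- pick(cand[cand$strand == "-" &
                        cand$cut_position >= cut_window[1L] &
                        cand$cut_position <= cut_window[2L], , drop = FALSE],
                 guides_per_arm)
    right <- pick(cand[cand$strand == "+" &
                         cand$cut_position >= length - cut_window[2L] &
                         cand$cut_position <= length - cut_window[1L], ,
                       drop = FALSE],
                  guides_per_arm)
    g <- rbind(
      cbind(left, arm = "left",
            name = paste0("L", seq_len(nrow(left)))),
      cbind(right, arm = "right",
            name = paste0("R", seq_len(nrow(right)))))
    g <- g[, c("name", "protospacer", "strand", "pam_position",
               "cut_position", "arm")]
    rownames(g) <- NULL
    provirus_construct("synthetic_vector", s, g)
  })
}

#' Generate a random host genome with a gene model
#'
#' Chromosomes are i.i.d. random DNA; genes are non-overlapping intervals
#' with a fixed exon count, evenly spaced exons, and optional per-chromosome
#' density weights.  Deterministic for a fixed seed.
#'
#' @param params a [sim_params()].
#' @param seed override for `params$seed`.
#' @return list with class `"sim_host"`: `genome`
#'   ([Biostrings::DNAStringSet]) and `genes` (a [gene_model()]).
#' @export
make_host <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(seed, {
    nm <- paste0("chr", seq_len(params$n_chromosomes))
    genome <- Biostrings::DNAStringSet(
      vapply(nm, function(x) random_dna(params$chrom_length), character(1)))
    names(genome) <- nm
    w <- params$gene_density_weights %||% rep(1, params$n_chromosomes)
    if (length(w) != params$n_chromosomes)
      stop("gene_density_weights must have one weight per chromosome")
    n_per <- as.integer(round(params$n_genes * w / sum(w)))
    # distribute rounding remainder deterministically
    while (sum(n_per) < params$n_genes)
      n_per[which.max(w)] <- n_per[which.max(w)] + 1L
    while (sum(n_per) > params$n_genes)
      n_per[which.max(n_per)] <- n_per[which.max(n_per)] - 1L
    # gene sizes adapt to crowding so dense chromosomes remain packable
    upper <- min(20000L,
                 params$chrom_length %/% max(1L, 2L * max(n_per, 1L)))
    if (upper < 200L)
      stop("infeasible packing: genes exceed chromosome length")
    gene_len_range <- c(max(200L, upper %/% 4L), upper)
    glist <- list(); elist <- list(); gid <- 0L
    for (ci in seq_len(params$n_chromosomes)) {
      starts <- integer(0); ends <- integer(0)
      tries <- 0L
      while (length(starts) < n_per[ci]) {
        len <- sample(gene_len_range[1L]:gene_len_range[2L], 1L)
        st <- sample.int(params$chrom_length - len, 1L)  # 1-based start
        if (all(st > ends + 1L | st + len < starts - 1L)) {
          starts <- c(starts, st); ends <- c(ends, st + len - 1L)
        }
        tries <- tries + 1L
        if (tries > 100L * n_per[ci] + 100L)
          stop("infeasible packing: could not place genes")
      }
      if (n_per[ci] == 0L) next
      ord <- order(starts)
      for (j in ord) {
        gid <- gid + 1L
        gname <- sprintf("gene%03d", gid)
        glist[[gid]] <- data.frame(chrom = nm[ci], start = starts[j],
                                   end = ends[j], name = gname,
                                   stringsAsFactors = FALSE)
        # exons_per_gene exons in the odd slots of 2E-1 equal chunks
        E <- params$exons_per_gene
        if (E > 0L) {
          glen <- ends[j] - starts[j] + 1L
          bounds <- round(seq(0L, glen, length.out = 2L * E))
          es <- starts[j] + bounds[seq(1L, 2L * E - 1L, by = 2L)]
          ee <- starts[j] + bounds[seq(2L, 2L * E, by = 2L)] - 1L
          elist[[gid]] <- data.frame(chrom = nm[ci], start = es, end = ee,
                                     gene = gname, stringsAsFactors = FALSE)
        }
      }
    }
    sl <- stats::setNames(rep(params$chrom_length, params$n_chromosomes), nm)
    if (gid == 0L) {
      genes <- GenomicRanges::GRanges(seqlengths = sl)
      exons <- GenomicRanges::GRanges(seqlengths = sl)
      exons$gene <- character(0)
    } else {
      gdf <- do.call(rbind, glist)
      genes <- GenomicRanges::GRanges(gdf$chrom,
                                      IRanges::IRanges(gdf$start, gdf$end),
                                      seqlengths = sl)
      names(genes) <- gdf$name
      edf <- do.call(rbind, elist)
      exons <- GenomicRanges::GRanges(edf$chrom,
                                      IRanges::IRanges(edf$start, edf$end),
                                      seqlengths = sl)
      exons$gene <- edf$gene
    }
    structure(list(genome = genome, genes = gene_model(genes, exons, sl)),
              class = "sim_host")
  })
}

#' Plant provirus integrations with target-site duplications
#'
#' At each sampled host position `p` (0-based, the first base of the
#' duplicated motif), the `tsd_length`-bp host motif starting at `p` is
#' duplicated to flank the inserted provirus, whose strand is random:
#' `modified = host[0, p+tsd) + provirus(strand) + host[p, L)`.
#' Positions are sampled uniformly, excluding `read_length_mean` from each
#' chromosome end and enforcing a minimum separation so planted sites do not
#' interleave within single reads.
#'
#' @param host a [make_host()] result.
#' @param construct a [provirus_construct()].
#' @param params a [sim_params()].
#' @param seed RNG seed (default derived from `params$seed`).
#' @param min_separation minimum distance between planted sites (bp).
#' @return list with class `"sim_planted"`: `genome` (modified
#'   [Biostrings::DNAStringSet]), `truth` (`data.frame` with `is_id`,
#'   `chromosome`, `position`, `strand`, `tsd`), `construct`, and internal
#'   vector offsets used by [emit_reads()].
#' @export
plant_integrations <- function(host, construct, params,
                               seed = params$seed + 1L,
                               min_separation = 30000L) {
  stopifnot(inherits(host, "sim_host"),
            inherits(construct, "provirus_construct"))
  with_seed(seed, {
    margin <- as.integer(params$read_length_mean)
    nm <- names(host$genome)
    lens <- Biostrings::width(host$genome)
    usable <- pmax(0L, lens - 2L * margin)
    if (sum(usable %/% min_separation) < params$n_integrations)
      stop("n_integrations too large for genome (after end exclusion)")
    chrom <- character(params$n_integrations)
    pos <- integer(params$n_integrations)
    placed <- 0L; tries <- 0L
    while (placed < params$n_integrations) {
      tries <- tries + 1L
      if (tries > 1000L * params$n_integrations)
        stop("n_integrations too large for genome (packing failed)")
      ci <- sample.int(length(nm), 1L, prob = usable)
      p <- margin + sample.int(usable[ci], 1L) - 1L
      same <- which(chrom[seq_len(placed)] == nm[ci])
      if (any(abs(pos[same] - p) < min_separation)) next
      placed <- placed + 1L
      chrom[placed] <- nm[ci]; pos[placed] <- p
    }
    strand <- sample(c("+", "-"), params$n_integrations, replace = TRUE)
    truth <- data.frame(is_id = sprintf("IS%03d", seq_len(params$n_integrations)),
                        chromosome = chrom, position = pos, strand = strand,
                        tsd = params$tsd_length, stringsAsFactors = FALSE)
    truth <- truth[order(match(truth$chromosome, nm), truth$position), ]
    truth$is_id <- sprintf("IS%03d", seq_len(nrow(truth)))
    rownames(truth) <- NULL
    vseq_plus <- construct$sequence
    vseq_minus <- revcomp_chr(vseq_plus)
    lv <- construct$length
    tsd <- params$tsd_length
    genome_chr <- as.character(host$genome)
    out_genome <- genome_chr
    vstart <- integer(nrow(truth))  # 0-based offset of vector base in modified chr
    for (ci in seq_along(nm)) {
      idx <- which(truth$chromosome == nm[ci])
      if (length(idx) == 0L) next
      h <- genome_chr[[ci]]
      pieces <- character(0)
      prev <- 0L  # 0-based consumed-up-to on original
      shift <- 0L
      for (j in idx) {
        p <- truth$position[j]
        pieces <- c(pieces, substr(h, prev + 1L, p + tsd))
        vstart[j] <- p + tsd + shift
        pieces <- c(pieces,
                    if (truth$strand[j] == "+") vseq_plus else vseq_minus)
        shift <- shift + tsd + lv
        prev <- p
      }
      pieces <- c(pieces, substr(h, prev + 1L, nchar(h)))
      out_genome[[ci]] <- paste(pieces, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(out_genome)
    names(genome) <- nm
    structure(list(genome = genome, truth = truth, vstart = vstart,
                   construct = construct, host = host),
              class = "sim_planted")
  })
}

# draw truncated-normal read lengths (>= floor)
draw_lengths <- function(n, mean, sd, floor = 200L) {
  len <- round(rnorm(n, mean, sd))
  while (any(len < floor)) len[len < floor] <- round(rnorm(sum(len < floor),
                                                           mean, sd))
  as.integer(len)
}

# apply substitution/insertion/deletion errors at a total per-base rate
mutate_seq <- function(s, rate) {
  n <- nchar(s)
  if (n == 0L || rate <= 0) return(s)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(s)
  pos <- sort(sample.int(n, k))
  type <- sample(c("sub", "ins", "del"), k, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  ins_after <- character(n)
  keep <- rep(TRUE, n)
  for (i in seq_len(k)) {
    p <- pos[i]
    if (type[i] == "sub") {
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    } else if (type[i] == "del") {
      keep[p] <- FALSE
    } else {
      ins_after[p] <- sample(bases, 1L)
    }
  }
  paste0(paste0(ch[keep], ins_after[keep], collapse = ""), collapse = "")
}

#' Emit Cas9-cut directional reads with ground-truth provenance
#'
#' Junction reads start exactly at a randomly chosen guide cut site of the
#' appropriate arm and proceed outward through the vector terminus into host
#' sequence (with probability `outward_bias`; otherwise inward, terminating
#' at the opposite arm's cut and never reaching host).  Background reads are
#' host-only substrings; circle reads cross a terminus-to-terminus episomal
#' junction and contain no host sequence.  Per-base errors are applied at
#' `error_rate` and the constant Phred quality is derived from it
#' (`Q = -10 log10(p)`, capped at 40).
#'
#' @param planted a [plant_integrations()] result.
#' @param params a [sim_params()].
#' @param seed RNG seed (default derived from `params$seed`).
#' @return list with class `"sim_reads"`: `reads`
#'   ([Biostrings::QualityScaledDNAStringSet]) and `provenance`
#'   (`data.frame`: `read_id`, `class` in
#'   `{junction_left, junction_right, background, circle}`, `is_id`,
#'   `inward`, `cut_used`).
#' @export
emit_reads <- function(planted, params, seed = params$seed + 2L) {
  stopifnot(inherits(planted, "sim_planted"), inherits(params, "sim_params"))
  with_seed(seed, {
    con <- planted$construct
    arms <- arm_specs(con)
    lv <- con$length
    vv <- paste0(con$sequence, con$sequence)
    genome <- as.character(planted$genome)
    truth <- planted$truth
    n_j <- nrow(truth) * 2L * params$reads_per_end
    other <- params$background_fraction + params$circle_fraction
    n_total <- if (other > 0) ceiling(n_j / (1 - other)) else n_j
    n_bg <- round(n_total * params$background_fraction)
    n_circ <- round(n_total * params$circle_fraction)
    seqs <- character(0); prov <- list()
    add <- function(seq, class, is_id = NA_character_, inward = FALSE,
                    cut = NA_character_) {
      seqs[[length(seqs) + 1L]] <<- seq
      prov[[length(prov) + 1L]] <<- data.frame(
        read_id = NA_character_, class = class, is_id = is_id,
        inward = inward, cut_used = cut, stringsAsFactors = FALSE)
    }
    left_cuts <- arms[arms$arm == "left", , drop = FALSE]
    right_cuts <- arms[arms$arm == "right", , drop = FALSE]
    max_left_cut <- max(left_cuts$cut_position)
    min_right_cut <- min(right_cuts$cut_position)
    for (si in seq_len(nrow(truth))) {
      chr_seq <- genome[[truth$chromosome[si]]]
      vs <- planted$vstart[si]          # vector base 0 offset in modified chr
      strand <- truth$strand[si]
      for (end in c("left", "right")) {
        pool <- if (end == "left") left_cuts else right_cuts
        for (r in seq_len(params$reads_per_end)) {
          gi <- sample.int(nrow(pool), 1L)
          cut <- pool$cut_position[gi]
          alen <- pool$arm_length[gi]
          len <- draw_lengths(1L, params$read_length_mean,
                              params$read_length_sd)
          outward <- runif(1L) < params$outward_bias
          if (!outward) {
            # wrong-direction read: stays inside the vector
            if (end == "left") {
              seq <- substr(con$sequence, cut + 1L,
                            min(cut + len, min_right_cut))
            } else {
              y <- max(max_left_cut, cut - len)
              seq <- revcomp_chr(substr(con$sequence, y + 1L, cut))
            }
            add(seq, paste0("junction_", end), truth$is_id[si], TRUE,
                pool$name[gi])
            next
          }
          hostlen <- max(0L, len - alen)
          # vector orientation in the modified chromosome decides geometry
          eff_end <- if (strand == "+") end else
            if (end == "left") "right" else "left"
          eff_cut <- if (strand == "+") cut else lv - cut
          if (eff_end == "left") {
            a <- max(0L, vs - hostlen)
            seq <- revcomp_chr(substr(chr_seq, a + 1L, vs + eff_cut))
          } else {
            b <- min(nchar(chr_seq), vs + lv + hostlen)
            seq <- substr(chr_seq, vs + eff_cut + 1L, b)
          }
          add(seq, paste0("junction_", end), truth$is_id[si], FALSE,
              pool$name[gi])
        }
      }
    }
    host_genome <- as.character(planted$host$genome)  # pristine host only
    for (i in seq_len(n_bg)) {
      len <- min(draw_lengths(1L, params$read_length_mean,
                              params$read_length_sd),
                 min(nchar(host_genome)) - 1L)
      ci <- sample.int(length(host_genome), 1L)
      st <- sample.int(nchar(host_genome[[ci]]) - len, 1L)
      seq <- substr(host_genome[[ci]], st, st + len - 1L)
      if (runif(1L) < 0.5) seq <- revcomp_chr(seq)
      add(seq, "background")
    }
    for (i in seq_len(n_circ)) {
      pool <- rbind(left_cuts, right_cuts)
      gi <- sample.int(nrow(pool), 1L)
      cut <- pool$cut_position[gi]
      len <- draw_lengths(1L, params$read_length_mean, params$read_length_sd)
      if (pool$arm[gi] == "left") {
        len <- min(len, lv + cut)
        seq <- revcomp_chr(substr(vv, lv + cut - len + 1L, lv + cut))
      } else {
        len <- min(len, 2L * lv - cut)
        seq <- substr(vv, cut + 1L, cut + len)
      }
      add(seq, "circle", cut = pool$name[gi])
    }
    prov <- do.call(rbind, prov)
    ord <- sample.int(nrow(prov))  # shuffle so read order carries no signal
    seqs <- seqs[ord]; prov <- prov[ord, , drop = FALSE]
    prov$read_id <- sprintf("read%05d", seq_len(nrow(prov)))
    rownames(prov) <- NULL
    if (params$error_rate > 0)
      seqs <- vapply(seqs, mutate_seq, character(1),
                     rate = params$error_rate, USE.NAMES = FALSE)
    q <- if (params$error_rate <= 0) 40L else
      min(40L, max(2L, as.integer(round(-10 * log10(params$error_rate)))))
    qual <- Biostrings::PhredQuality(
      vapply(nchar(seqs), function(n) strrep(intToUtf8(q + 33L), n),
             character(1)))
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- prov$read_id
    reads <- Biostrings::QualityScaledDNAStringSet(dna, qual)
    structure(list(reads = reads, provenance = prov, quality = q),
              class = "sim_reads")
  })
}

#' Run the full simulator
#'
#' Convenience wrapper: build (or accept) a construct, generate a host with
#' gene model, plant integrations, emit reads.
#'
#' @param params a [sim_params()].
#' @param construct optional [provirus_construct()]; default
#'   [synthetic_construct()] seeded from `params$seed`.
#' @return list with class `"sim_run"`: `construct`, `host`, `planted`,
#'   `reads` (the [emit_reads()] result), `truth`.
#' @export
simulate_run <- function(params, construct = NULL) {
  if (is.null(construct))
    construct <- synthetic_construct(seed = params$seed + 101L)
  host <- make_host(params)
  planted <- plant_integrations(host, construct, params)
  rd <- emit_reads(planted, params)
  structure(list(construct = construct, host = host, planted = planted,
                 reads = rd, truth = planted$truth),
            class = "sim_run")
}

#' Write simulator outputs to standard files
#'
#' @param run a [simulate_run()] result.
#' @param dir output directory (created if needed).
#' @return named vector of file paths (genome FASTA, genes GFF3, reads FASTQ,
#'   truth and provenance TSV, construct FASTA + guide TSV).
#' @export
write_sim_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "host_genome.fasta"),
             genes = file.path(dir, "host_genes.gff3"),
             reads = file.path(dir, "reads.fastq"),
             truth = file.path(dir, "truth_sites.tsv"),
             provenance = file.path(dir, "truth_reads.tsv"),
             construct = file.path(dir, "construct.fasta"),
             guides = file.path(dir, "construct_guides.tsv"))
  Biostrings::writeXStringSet(run$host$genome, paths[["genome"]])
  write_gene_model(run$host$genes, paths[["genes"]])
  write_fastq(run$reads$reads, paths[["reads"]])
  write.table(run$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(run$reads$provenance, paths[["provenance"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_construct(run$construct, paths[["construct"]], paths[["guides"]])
  paths
}
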