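#' Describe a guide (gRNA) target on the provirus construct
#'
#' A guide is stored by its 20-nt protospacer, strand, PAM coordinate and
#' blunt cut coordinate on the construct, plus the vector end ("arm") the
#' guide serves.  All coordinates are 0-based; `cut_position` is the index of
#' the first base of the right-hand fragment produced by the cut (i.e. the
#' cut falls between `cut_position - 1` and `cut_position`).  For SpCas9 the
#' blunt cut lies 3 bp on the protospacer (5') side of the NGG PAM.
#'
#' @param protospacer 20-nt DNA string (construct plus-strand sequence for
#'   `strand = "+"`, reverse complement otherwise).
#' @param strand `"+"` or `"-"`: strand of the construct carrying the
#'   protospacer/PAM.
#' @param pam_position 0-based coordinate of the first PAM base on the
#'   construct plus strand.
#' @param cut_position 0-based blunt-cut coordinate.
#' @param arm `"left"` or `"right"`: which vector terminus this guide serves.
#' @param name optional guide label.
#' @return A one-row `data.frame` with class `"guide_site"` columns.
#' @export
guide_site <- function(protospacer, strand, pam_position, cut_position,
                       arm, name = NA_character_) {
  stopifnot(is.character(protospacer), length(protospacer) == 1L)
  if (nchar(protospacer) != 20L)
    stop("protospacer must be exactly 20 nt, got ", nchar(protospacer))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!arm %in% c("left", "right")) stop("arm must be 'left' or 'right'")
  data.frame(name = as.character(name), protospacer = protospacer,
             strand = strand, pam_position = as.integer(pam_position),
             cut_position = as.integer(cut_position), arm = arm,
             stringsAsFactors = FALSE)
}

#' Provirus construct with annotated guide cut sites
#'
#' The construct is the integrated (proviral) form of the vector genome and
#' is the coordinate frame for guide cut positions and arm lengths.  The left
#' terminus is coordinate 0 and the right terminus is `length` (0-based
#' half-open).
#'
#' @param name construct label.
#' @param sequence DNA string or [Biostrings::DNAString]; alphabet restricted
#'   to A, C, G, T, N.
#' @param guides `data.frame` of guides as produced by [guide_site()] (rows
#'   may be concatenated with `rbind`), or `NULL`.
#' @return An object of class `"provirus_construct"`: a list with elements
#'   `name`, `sequence` (character), `length`, `guides`.
#' @examples
#' pc <- provirus_construct("toy", strrep("ACGT", 300))
#' pc$length
#' @export
provirus_construct <- function(name, sequence, guides = NULL) {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty input")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence alphabet must be within {A,C,G,T,N}")
  if (is.null(guides)) {
    guides <- guide_site("A", "+", 0L, 0L, "left")[0L, ]
  }
  len <- nchar(sequence)
  if (nrow(guides) > 0L &&
      any(guides$cut_position < 0L | guides$cut_position > len))
    stop("guide cut positions must lie in [0, construct length]")
  structure(list(name = name, sequence = sequence, length = len,
                 guides = guides),
            class = "provirus_construct")
}

#' @export
print.provirus_construct <- function(x, ...) {
  cat(sprintf("provirus_construct '%s': %d bp, %d guide(s)\n",
              x$name, x$length, nrow(x$guides)))
  if (nrow(x$guides) > 0L) print(x$guides)
  invisible(x)
}

#' Scan a sequence for SpCas9 PAM sites
#'
#' Enumerates every NGG (plus strand) and CCN (minus strand) PAM whose 20-nt
#' protospacer lies fully inside the sequence and returns one candidate guide
#' per PAM.  The blunt cut is placed 3 bp on the 5' (protospacer) side of the
#' PAM, strand-aware.  Protospacers containing N are rejected.
#'
#' @param sequence DNA string (uppercase ACGTN) or a `provirus_construct`.
#' @return `data.frame` with columns `protospacer`, `strand`, `pam_position`,
#'   `cut_position`, sorted by `cut_position` (ties: plus strand first).
#' @examples
#' scan_pam_sites("ATATATATAT")     # no PAM -> zero rows
#' @export
scan_pam_sites <- function(sequence) {
  if (inherits(sequence, "provirus_construct")) sequence <- sequence$sequence
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || nchar(sequence) == 0L) stop("empty input")
  if (grepl("[^ACGTN]", sequence)) stop("sequence must be uppercase ACGTN")
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  res <- list()
  # plus strand: PAM = N G G at [p, p+3); protospacer [p-20, p); cut p-3
  if (n >= 23L) {
    gg <- which(chars[-c(1L, n)] == "G" & chars[-(1:2)] == "G") # pos of N (1-based)
    for (p1 in gg) {                    # p1 = 1-based PAM start
      p <- p1 - 1L                      # 0-based
      if (p < 20L || p + 3L > n) next
      proto <- substr(sequence, p1 - 20L, p1 - 1L)
      if (grepl("N", proto, fixed = TRUE)) next
      res[[length(res) + 1L]] <- data.frame(
        protospacer = proto, strand = "+", pam_position = p,
        cut_position = p - 3L, stringsAsFactors = FALSE)
    }
    # minus strand: CCN at [p, p+3); protospacer occupies [p+3, p+23) on the
    # plus strand (reverse-complemented); cut between p+5 and p+6 -> p+6
    cc <- which(chars[-c(n - 1L, n)] == "C" & chars[-c(1L, n)] == "C")
    for (p1 in cc) {
      p <- p1 - 1L
      if (p + 23L > n) next
      plus_proto <- substr(sequence, p1 + 3L, p1 + 22L)
      if (grepl("N", plus_proto, fixed = TRUE)) next
      res[[length(res) + 1L]] <- data.frame(
        protospacer = revcomp_chr(plus_proto), strand = "-",
        pam_position = p, cut_position = p + 6L, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(protospacer = character(), strand = character(),
                      pam_position = integer(), cut_position = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$cut_position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate an enrichment guide panel against the design rules
#'
#' Checks the rules a Cas9 enrichment panel must obey for outward sequencing
#' across the vector termini:
#' \describe{
#'   \item{R1}{at least two guides per arm (cleavage redundancy);}
#'   \item{R2}{each cut at least `min_junction_distance` from the terminus it
#'     serves, so enough vector sequence remains for confident mapping;}
#'   \item{R3}{guides within an arm separated by at least `min_pair_spacing`
#'     (steric hindrance);}
#'   \item{R4}{orientation: SpCas9 stays bound to the fragment 5' of the PAM,
#'     so only the PAM-containing fragment is A-tailed and sequenced.  That
#'     fragment must be the one carrying the served terminus, i.e. left-arm
#'     guides lie on the minus strand and right-arm guides on the plus
#'     strand;}
#'   \item{R5}{left-arm and right-arm guides on opposite strands.}
#' }
#'
#' @param construct a [provirus_construct()] with at least one guide.
#' @param min_junction_distance minimum cut-to-terminus distance (bp).
#' @param min_pair_spacing minimum within-arm cut spacing (bp).
#' @return `data.frame` with columns `rule`, `guide`, `message`; zero rows
#'   means the panel is valid.
#' @export
validate_guide_set <- function(construct, min_junction_distance = 500L,
                               min_pair_spacing = 50L) {
  stopifnot(inherits(construct, "provirus_construct"))
  g <- construct$guides
  if (nrow(g) == 0L) stop("construct has no guides")
  if (any(g$cut_position < 0L | g$cut_position > construct$length))
    stop("guide coordinates outside construct")
  v <- list()
  viol <- function(rule, guide, msg) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, guide = guide,
                                       message = msg,
                                       stringsAsFactors = FALSE)
  }
  gname <- ifelse(is.na(g$name), paste0("guide", seq_len(nrow(g))), g$name)
  for (arm in c("left", "right")) {
    idx <- which(g$arm == arm)
    if (length(idx) < 2L)
      viol("R1", NA_character_,
           sprintf("arm '%s' has %d guide(s); >=2 required for cleavage redundancy",
                   arm, length(idx)))
    if (length(idx) >= 2L) {
      cuts <- sort(g$cut_position[idx])
      if (any(diff(cuts) < min_pair_spacing))
        viol("R3", NA_character_,
             sprintf("arm '%s' guide cuts closer than min_pair_spacing = %d bp",
                     arm, min_pair_spacing))
    }
  }
  for (i in seq_len(nrow(g))) {
    dist <- if (g$arm[i] == "left") g$cut_position[i] else
      construct$length - g$cut_position[i]
    if (dist < min_junction_distance)
      viol("R2", gname[i],
           sprintf("cut %d bp from %s terminus; minimum %d bp required",
                   dist, g$arm[i], min_junction_distance))
    # R4: PAM-side fragment must contain the served terminus.  For a plus
    # strand guide the PAM is right of the cut (right fragment); for a minus
    # strand guide it is left of the cut.
    pam_side <- if (g$strand[i] == "+") "right" else "left"
    if (pam_side != g$arm[i])
      viol("R4", gname[i],
           sprintf("PAM faces the construct interior: %s-arm guide must be on the '%s' strand so the A-tailed (PAM-side) fragment carries the served terminus",
                   g$arm[i], if (g$arm[i] == "left") "-" else "+"))
  }
  left_strands <- unique(g$strand[g$arm == "left"])
  right_strands <- unique(g$strand[g$arm == "right"])
  if (length(left_strands) == 1L && length(right_strands) == 1L &&
      left_strands == right_strands)
    viol("R5", NA_character_,
         "left-arm and right-arm guides must lie on opposite strands")
  if (length(v) == 0L)
    return(data.frame(rule = character(), guide = character(),
                      message = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

#' Arm specifications for a guide panel
#'
#' One row per guide: the distance from the cut to the vector terminus it
#' serves (the "arm length") and the outward sequencing direction.  The
#' minimum arm length over the panel sets the pre-alignment size-selection
#' threshold used by [size_select()].
#'
#' @param construct a [provirus_construct()] with guides.
#' @return `data.frame` with columns `name`, `arm`, `cut_position`,
#'   `arm_length`, `outward_direction`.
#' @export
arm_specs <- function(construct) {
  stopifnot(inherits(construct, "provirus_construct"))
  g <- construct$guides
  if (nrow(g) == 0L) stop("construct has no guides")
  arm_length <- ifelse(g$arm == "left", g$cut_position,
                       construct$length - g$cut_position)
  if (any(arm_length <= 0L)) stop("arm_length must be strictly positive")
  data.frame(name = g$name, arm = g$arm, cut_position = g$cut_position,
             arm_length = as.integer(arm_length),
             outward_direction = ifelse(g$arm == "left",
                                        "toward_left_terminus",
                                        "toward_right_terminus"),
             stringsAsFactors = FALSE)
}

#' Count exact and 1-mismatch protospacer occurrences in a host genome
#'
#' Optional off-target screen: counts occurrences of each guide's
#' protospacer+PAM-free 20-mer (both strands) at Hamming distance 0 and 1 in
#' the host genome.  No cutoff is asserted; the counts are returned for the
#' designer to judge.
#'
#' @param construct a [provirus_construct()] with guides.
#' @param host_genome [Biostrings::DNAStringSet] (or named character vector).
#' @return `data.frame` with columns `name`, `exact`, `one_mismatch`.
#' @export
offtarget_counts <- function(construct, host_genome) {
  g <- construct$guides
  if (!methods::is(host_genome, "DNAStringSet"))
    host_genome <- Biostrings::DNAStringSet(host_genome)
  exact <- integer(nrow(g)); one <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    pat <- Biostrings::DNAString(g$protospacer[i])
    for (strand_pat in list(pat, Biostrings::reverseComplement(pat))) {
      h0 <- Biostrings::vcountPattern(strand_pat, host_genome, max.mismatch = 0)
      h1 <- Biostrings::vcountPattern(strand_pat, host_genome, max.mismatch = 1)
      exact[i] <- exact[i] + sum(h0)
      one[i] <- one[i] + sum(h1 - h0)
    }
  }
  data.frame(name = g$name, exact = exact, one_mismatch = one,
             stringsAsFactors = FALSE)
}

#' Read and write a construct (FASTA plus guide TSV sidecar)
#'
#' The construct sequence travels as single-record FASTA; guides travel in a
#' plain TSV sidecar with columns `name`, `protospacer`, `strand`,
#' `pam_position`, `cut_position`, `arm`.
#'
#' @param fasta path to the construct FASTA.
#' @param guides_tsv path to the guide sidecar TSV (optional on read).
#' @return `read_construct()` returns a [provirus_construct()].
#' @export
read_construct <- function(fasta, guides_tsv = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) stop("construct FASTA must contain one record")
  guides <- NULL
  if (!is.null(guides_tsv)) {
    guides <- read.table(guides_tsv, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(name = "character"))
  }
  provirus_construct(names(seqs)[1L], as.character(seqs[[1L]]), guides)
}

#' @rdname read_construct
#' @param construct a [provirus_construct()].
#' @export
write_construct <- function(construct, fasta, guides_tsv = NULL) {
  seqs <- Biostrings::DNAStringSet(construct$sequence)
  names(seqs) <- construct$name
  Biostrings::writeXStringSet(seqs, fasta)
  if (!is.null(guides_tsv))
    write.table(construct$guides, guides_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(fasta = fasta, guides_tsv = guides_tsv))
}
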