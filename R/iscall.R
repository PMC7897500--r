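#' Mean-quality read filter
#'
#' Keeps reads whose mean Phred quality is strictly greater than
#' `min_mean_q` (the basecaller convention "quality cut-off of >9" is an
#' exclusive boundary: a read at exactly the cut-off is dropped).
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param min_mean_q exclusive mean-quality threshold.
#' @return list: `passed` (subset of `reads`), `dropped` (count),
#'   `dropped_ids`.
#' @export
quality_filter <- function(reads, min_mean_q = 9) {
  mq <- mean_quality(reads)
  keep <- mq > min_mean_q
  list(passed = reads[keep], dropped = sum(!keep),
       dropped_ids = names(reads)[!keep])
}

#' Pre-alignment size selection
#'
#' A junction read must contain the whole vector arm (cut site to terminus)
#' plus enough host sequence to map.  The cheapest sound pre-alignment filter
#' keeps reads of length at least `min(arm_length) + min_host_anchor`; the
#' per-arm requirement (the LV span must actually reach the terminus) is
#' enforced later by [call_junction()].
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param arm_specs output of [arm_specs()].
#' @param min_host_anchor minimum host sequence required beyond the arm (bp).
#' @return list: `passed`, `dropped`, `dropped_ids`, `threshold`.
#' @export
size_select <- function(reads, arm_specs, min_host_anchor = 200L) {
  if (is.null(arm_specs) || nrow(arm_specs) == 0L)
    stop("empty arm_specs")
  threshold <- min(arm_specs$arm_length) + min_host_anchor
  keep <- Biostrings::width(reads) >= threshold
  list(passed = reads[keep], dropped = sum(!keep),
       dropped_ids = names(reads)[!keep], threshold = threshold)
}

empty_calls <- function() {
  data.frame(read_id = character(), chromosome = character(),
             position = integer(), host_strand = character(),
             host_side = character(), vector_end = character(),
             vector_strand_in_host = character(), cut_site_used = character(),
             stringsAsFactors = FALSE)
}

#' Call a host junction from a triaged read
#'
#' Requires the read structure of the protocol: an LV span that starts within
#' `cut_slack` of a known guide cut site and extends to within `end_slack` of
#' the served vector terminus, followed on the read (gap at most `max_gap`,
#' overlap at most `tsd_max`) by the host span.  The reported `position` is
#' the 0-based host coordinate of the first host base adjacent to the vector:
#' for a plus-strand host span the host lies 3' (right) of the vector and the
#' position is the span's `target_start`; for a minus-strand host span the
#' host lies 5' (left) and the position is the span's `target_end`.  With a
#' TSD of `t` bp the right-side and left-side positions of one integration
#' differ by exactly `t` (both fall on the duplicated motif), which is what
#' [cluster_calls()] and [estimate_tsd()] exploit.
#'
#' @param tr a `triage_result` (classification must be
#'   `"junction_candidate"`).
#' @param construct the [provirus_construct()].
#' @param arm_specs output of [arm_specs()].
#' @param end_slack tolerance (bp) for the LV span reaching the terminus.
#' @param cut_slack tolerance (bp) for matching a guide cut site.
#' @param max_gap largest read-side gap between LV and host spans (bp).
#' @param tsd_max largest read-side overlap between LV and host spans (bp).
#' @return one-row junction-call `data.frame`; on structural failure a
#'   zero-row `data.frame` carrying the failure in attribute `"reason"`.
#' @export
call_junction <- function(tr, construct, arm_specs, end_slack = 50L,
                          cut_slack = 50L, max_gap = 20L, tsd_max = 7L) {
  fail <- function(reason) {
    out <- empty_calls()
    attr(out, "reason") <- reason
    return(out)
  }
  if (!identical(tr$classification, "junction_candidate"))
    return(fail(paste0("not_junction_candidate:", tr$classification)))
  lv <- tr$lv_best
  host <- tr$host_best
  lvlen <- construct$length
  if (lv$strand == "+") {
    exit_coord <- lv$target_end
    cut_coord <- lv$target_start
    vector_end <- if (exit_coord >= lvlen - end_slack) "right_terminus" else NA
  } else {
    exit_coord <- lv$target_start
    cut_coord <- lv$target_end
    vector_end <- if (exit_coord <= end_slack) "left_terminus" else NA
  }
  if (is.na(vector_end)) return(fail("short_arm"))
  arm <- if (vector_end == "left_terminus") "left" else "right"
  cand <- arm_specs[arm_specs$arm == arm, , drop = FALSE]
  if (nrow(cand) == 0L) return(fail("no_guides_for_arm"))
  d <- abs(cand$cut_position - cut_coord)
  if (min(d) > cut_slack) return(fail("no_cut_match"))
  cut_used <- cand$name[which.min(d)]
  gap <- host$query_start - lv$query_end
  if (gap > max_gap) return(fail("host_gap"))
  if (gap < -tsd_max) return(fail("host_overlap"))
  # The vector target ends exactly at the terminus, so the LV span cannot
  # overrun the junction: its read-side end q* marks the junction crossing
  # exactly at error 0, and phase-2 masking starts the host span at or after
  # q*.  Any residual read-side gap (sequencing errors at the junction) is
  # extrapolated as diagonal.
  qstar <- lv$query_end
  offset <- host$query_start - qstar
  if (host$strand == "+") {
    host_side <- "right"; position <- host$target_start - offset
  } else {
    host_side <- "left"; position <- host$target_end + offset
  }
  vstrand <- if ((vector_end == "left_terminus") == (host_side == "left"))
    "+" else "-"
  data.frame(read_id = tr$read_id, chromosome = host$target_name,
             position = as.integer(position), host_strand = host$strand,
             host_side = host_side, vector_end = vector_end,
             vector_strand_in_host = vstrand, cut_site_used = cut_used,
             stringsAsFactors = FALSE)
}

#' Flag episomal (LTR-circle) reads
#'
#' A read is episomal when it continues past a vector terminus into sequence
#' that aligns back to the construct (the circle junction of a 1-LTR/2-LTR
#' circle), or when it is vector-only: it crosses a terminus but no unique
#' host anchor follows.  Vector-only reads whose tail beyond the terminus is
#' shorter than `min_host_anchor` are excluded conservatively with a distinct
#' reason (`"ends_at_terminus"`).
#'
#' @param tr a `triage_result` with at least one LV span.
#' @param construct the [provirus_construct()].
#' @param min_host_anchor minimum judgeable tail length (bp).
#' @param end_slack terminus tolerance (bp).
#' @param max_gap largest read-side gap between consecutive LV spans at a
#'   circle junction (bp).
#' @return logical flag with attribute `"reason"`.
#' @export
detect_episome <- function(tr, construct, min_host_anchor = 200L,
                           end_slack = 50L, max_gap = 50L) {
  res <- function(flag, reason) {
    attr(flag, "reason") <- reason
    flag
  }
  lv <- tr$lv_spans
  if (nrow(lv) == 0L) return(res(FALSE, "no_lv_span"))
  lvlen <- construct$length
  at_terminus_exit <- function(sp) {
    if (sp$strand == "+") sp$target_end >= lvlen - end_slack
    else sp$target_start <= end_slack
  }
  at_terminus_entry <- function(sp) {
    if (sp$strand == "+") sp$target_start <= end_slack
    else sp$target_end >= lvlen - end_slack
  }
  if (nrow(lv) >= 2L) {
    byq <- lv[order(lv$query_start), , drop = FALSE]
    for (i in seq_len(nrow(byq) - 1L)) {
      for (j in (i + 1L):nrow(byq)) {
        a <- byq[i, , drop = FALSE]
        b <- byq[j, , drop = FALSE]
        gap <- b$query_start - a$query_end
        if (gap >= -end_slack && gap <= max_gap &&
            at_terminus_exit(a) && at_terminus_entry(b))
          return(res(TRUE, "vector_circle_junction"))
      }
    }
  }
  if (identical(tr$classification, "vector_only")) {
    best <- tr$lv_best
    if (at_terminus_exit(best)) {
      tail_len <- tr$read_length - best$query_end
      if (tail_len < min_host_anchor)
        return(res(TRUE, "ends_at_terminus"))
      return(res(TRUE, "no_host_anchor"))
    }
    return(res(FALSE, "inward_vector_read"))
  }
  res(FALSE, "host_junction_present")
}

#' Call junctions for a list of triaged reads
#'
#' Applies [detect_episome()] then [call_junction()] to every triage result
#' and keeps a per-read decision log.
#'
#' @param triage list of `triage_result` records from [triage_reads()].
#' @param construct the [provirus_construct()].
#' @param arm_specs output of [arm_specs()].
#' @param ... passed to [call_junction()].
#' @return list: `calls` (junction-call `data.frame`), `log` (`data.frame`
#'   with `read_id`, `bucket`, `reason`).
#' @export
call_junctions <- function(triage, construct, arm_specs, ...) {
  calls <- list(); log <- list()
  note <- function(id, bucket, reason) {
    log[[length(log) + 1L]] <<- data.frame(read_id = id, bucket = bucket,
                                           reason = reason,
                                           stringsAsFactors = FALSE)
  }
  for (tr in triage) {
    epi <- detect_episome(tr, construct)
    if (isTRUE(epi)) {
      note(tr$read_id, "episome", attr(epi, "reason"))
      next
    }
    if (identical(tr$classification, "ambiguous")) {
      note(tr$read_id, "ambiguous", "multi_mapping_host")
      next
    }
    if (!identical(tr$classification, "junction_candidate")) {
      note(tr$read_id, "no_structure",
           if (nrow(tr$lv_spans) == 0L) "no_lv_alignment"
           else attr(epi, "reason"))
      next
    }
    jc <- call_junction(tr, construct, arm_specs, ...)
    if (nrow(jc) == 0L) {
      note(tr$read_id, "no_structure", attr(jc, "reason"))
    } else {
      calls[[length(calls) + 1L]] <- jc
      note(tr$read_id, "junction_call", jc$cut_site_used)
    }
  }
  list(calls = if (length(calls)) do.call(rbind, calls) else empty_calls(),
       log = if (length(log)) do.call(rbind, log) else
         data.frame(read_id = character(), bucket = character(),
                    reason = character(), stringsAsFactors = FALSE))
}

#' Cluster junction calls into unique integration sites
#'
#' Single-linkage clustering per chromosome: calls on the same host side
#' merge when within `merge_window` bp; calls on opposite host sides merge
#' when their coordinates are consistent with a target-site duplication of
#' 0..`tsd_max` bp (the left-side position exceeds the right-side position by
#' the TSD, because both junctions fall on the duplicated motif).  Each
#' cluster becomes one site whose representative `position` is the minimum
#' member coordinate (the 5'-most copy of the duplicated motif), flagged
#' `bidirectional` when both vector ends are represented.
#'
#' @param calls junction-call `data.frame` from [call_junctions()].
#' @param merge_window same-side merge distance (bp).
#' @param tsd_max largest duplication considered (bp).
#' @return site `data.frame`: `is_id`, `chromosome`, `position`, `strand`,
#'   `support`, `bidirectional`, `tsd_estimate`, `member_reads` (list
#'   column).  The input calls, with a `site` column added, are attached as
#'   attribute `"calls"`.
#' @export
cluster_calls <- function(calls, merge_window = 10L, tsd_max = 7L) {
  empty_sites <- data.frame(is_id = character(), chromosome = character(),
                            position = integer(), strand = character(),
                            support = integer(), bidirectional = logical(),
                            tsd_estimate = integer(),
                            stringsAsFactors = FALSE)
  empty_sites$member_reads <- list()
  if (is.null(calls) || nrow(calls) == 0L) {
    attr(empty_sites, "calls") <- calls
    return(empty_sites)
  }
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- min(ri, rj) # keep min as root
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (chr in unique(calls$chromosome)) {
    idx <- which(calls$chromosome == chr)
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        i <- idx[a]; j <- idx[b]
        same_side <- calls$host_side[i] == calls$host_side[j]
        if (same_side) {
          if (abs(calls$position[i] - calls$position[j]) <= merge_window)
            union_(i, j)
        } else {
          left_pos <- if (calls$host_side[i] == "left") calls$position[i]
                      else calls$position[j]
          right_pos <- if (calls$host_side[i] == "left") calls$position[j]
                       else calls$position[i]
          d <- left_pos - right_pos
          if (d >= 0L && d <= tsd_max) union_(i, j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  ord <- order(vapply(groups, function(g) min(calls$position[g]), integer(1)))
  groups <- groups[ord]
  # order clusters genome-wide: chromosome then position
  chr_of <- vapply(groups, function(g) calls$chromosome[g[1L]], character(1))
  pos_of <- vapply(groups, function(g) min(calls$position[g]), integer(1))
  groups <- groups[order(chr_of, pos_of)]
  sites <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    members <- calls[g, , drop = FALSE]
    strand_tab <- table(members$vector_strand_in_host)
    bidir <- length(unique(members$vector_end)) == 2L
    sites[[k]] <- data.frame(
      is_id = sprintf("IS_%04d", k),
      chromosome = members$chromosome[1L],
      position = min(members$position),
      strand = names(strand_tab)[which.max(strand_tab)],
      support = nrow(members),
      bidirectional = bidir,
      tsd_estimate = if (bidir) estimate_tsd(members, tsd_max = tsd_max)
                     else NA_integer_,
      stringsAsFactors = FALSE)
    sites[[k]]$member_reads <- list(members$read_id)
  }
  out <- do.call(rbind, sites)
  rownames(out) <- NULL
  calls$site <- rep(NA_character_, n)
  for (k in seq_along(groups)) calls$site[groups[[k]]] <- out$is_id[k]
  attr(out, "calls") <- calls
  out
}

#' Estimate the target-site duplication of a bidirectional site
#'
#' The integrase duplicates `t` bp of host sequence around the insertion, so
#' the left-side junction coordinate exceeds the right-side coordinate by
#' exactly `t`.  The estimate is the difference of the per-side medians,
#' clipped to `[0, tsd_max]`; it is only defined when both vector ends are
#' observed.
#'
#' @param members junction calls belonging to one site (the rows of the
#'   `"calls"` attribute of [cluster_calls()] output for one `site`).
#' @param tsd_max clip ceiling (bp).
#' @return integer TSD estimate, or `NA` if the site is not bidirectional.
#' @export
estimate_tsd <- function(members, tsd_max = 7L) {
  if (length(unique(members$vector_end)) < 2L) return(NA_integer_)
  left <- members$position[members$host_side == "left"]
  right <- members$position[members$host_side == "right"]
  if (length(left) == 0L || length(right) == 0L) return(NA_integer_)
  est <- round(median(left) - median(right))
  as.integer(max(0L, min(tsd_max, est)))
}

#' Run the full junction-calling pipeline
#'
#' Quality filter, size selection, two-phase triage, episome elimination,
#' junction calling and clustering, with a per-read decision log whose
#' buckets partition the input reads exactly
#' (`dropped_quality`, `dropped_size`, `episome`, `no_structure`,
#' `ambiguous`, `member_of_site`).
#'
#' @param reads [Biostrings::QualityScaledDNAStringSet].
#' @param construct a [provirus_construct()] with a guide panel.
#' @param host host genome: a `minimizer_index`, `DNAStringSet`, named
#'   character vector or FASTA path.
#' @param min_mean_q exclusive mean-quality cut-off.
#' @param min_host_anchor minimum host anchor (bp).
#' @param merge_window,tsd_max clustering parameters; see [cluster_calls()].
#' @param k,w minimizer parameters for internally built indexes.
#' @param lv_alignments,host_alignments optional external alignments; see
#'   [triage_reads()].
#' @param ... passed to [call_junction()].
#' @return list with class `"is_result"`: `sites`, `calls`, `log`, `counts`
#'   (named bucket counts), `n_input`, `lv_mapped` (reads with an LV span).
#' @export
detect_sites <- function(reads, construct, host, min_mean_q = 9,
                         min_host_anchor = 200L, merge_window = 10L,
                         tsd_max = 7L, k = 15L, w = 10L,
                         lv_alignments = NULL, host_alignments = NULL, ...) {
  arms <- arm_specs(construct)
  qf <- quality_filter(reads, min_mean_q)
  ss <- size_select(qf$passed, arms, min_host_anchor)
  cidx <- build_index(stats::setNames(construct$sequence, construct$name),
                      k = k, w = w)
  hidx <- if (inherits(host, "minimizer_index")) host
          else build_index(host, k = k, w = w)
  triage <- triage_reads(ss$passed, cidx, hidx,
                         min_host_anchor = min_host_anchor,
                         tsd_max = tsd_max,
                         lv_alignments = lv_alignments,
                         host_alignments = host_alignments)
  cj <- call_junctions(triage, construct, arms, tsd_max = tsd_max, ...)
  sites <- cluster_calls(cj$calls, merge_window = merge_window,
                         tsd_max = tsd_max)
  log <- rbind(
    if (length(qf$dropped_ids))
      data.frame(read_id = qf$dropped_ids, bucket = "dropped_quality",
                 reason = paste0("mean_q<=", min_mean_q),
                 stringsAsFactors = FALSE),
    if (length(ss$dropped_ids))
      data.frame(read_id = ss$dropped_ids, bucket = "dropped_size",
                 reason = paste0("length<", ss$threshold),
                 stringsAsFactors = FALSE),
    cj$log)
  log$bucket[log$bucket == "junction_call"] <- "member_of_site"
  buckets <- c("dropped_quality", "dropped_size", "episome", "no_structure",
               "ambiguous", "member_of_site")
  counts <- vapply(buckets, function(b) sum(log$bucket == b), integer(1))
  lv_mapped <- sum(vapply(triage, function(tr) nrow(tr$lv_spans) > 0L,
                          logical(1)))
  structure(list(sites = sites, calls = attr(sites, "calls"), log = log,
                 counts = counts, n_input = length(reads),
                 lv_mapped = lv_mapped),
            class = "is_result")
}

#' @export
print.is_result <- function(x, ...) {
  cat(sprintf("is_result: %d input reads -> %d junction calls -> %d site(s)\n",
              x$n_input, sum(x$counts["member_of_site"]), nrow(x$sites)))
  print(x$counts)
  invisible(x)
}
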