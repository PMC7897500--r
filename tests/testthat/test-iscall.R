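test_that("quality_filter applies a strict > boundary", {
  r <- make_reads(c(hi = strrep("ACGT", 25L),       # Q40
                    atcut = strrep("ACGT", 25L),    # Q9 exactly -> dropped
                    lo = strrep("ACGT", 25L)),      # Q5
                  c(40L, 9L, 5L))
  qf <- quality_filter(r, min_mean_q = 9)
  expect_equal(names(qf$passed), "hi")
  expect_equal(qf$dropped, 2L)
  expect_true("atcut" %in% qf$dropped_ids)
})

test_that("quality_filter matches a hand tally on mixed means", {
  # per-read constant qualities straddling the cut-off
  quals <- c(8L, 9L, 10L, 12L, 40L)
  r <- make_reads(stats::setNames(replicate(5L, strrep("AC", 30L)),
                                  paste0("m", 1:5)), quals)
  qf <- quality_filter(r, min_mean_q = 9)
  expect_equal(sum(quals > 9), length(qf$passed))
  expect_equal(qf$dropped, sum(quals <= 9))
})

test_that("size_select threshold is min arm length plus host anchor", {
  arms <- data.frame(name = c("a", "b", "c", "d"),
                     arm = c("left", "left", "right", "right"),
                     cut_position = c(700L, 950L, 100L, 100L),
                     arm_length = c(700L, 950L, 800L, 600L),
                     outward_direction = "x", stringsAsFactors = FALSE)
  r <- make_reads(c(short = rand_dna(799L, seed = 1L),
                    exact = rand_dna(800L),
                    tiny = rand_dna(400L)), c(40L, 40L, 40L))
  ss <- size_select(r, arms, min_host_anchor = 200L)
  expect_equal(ss$threshold, 800L)
  expect_equal(names(ss$passed), "exact")
  expect_true(all(c("short", "tiny") %in% ss$dropped_ids))
  expect_error(size_select(r, arms[0L, ]), "empty arm_specs")
})

test_that("junction calls land on the simulated truth, both strands", {
  run <- small_run(n_integrations = 4L, reads_per_end = 2L, seed = 41L)
  res <- detect_sites(run$reads$reads, run$construct, run$host$genome)
  expect_equal(nrow(res$sites), nrow(run$truth))
  for (i in seq_len(nrow(run$truth))) {
    tr <- run$truth[i, ]
    hit <- res$sites[res$sites$chromosome == tr$chromosome &
                       res$sites$position == tr$position, ]
    expect_equal(nrow(hit), 1L, info = tr$is_id)
    expect_equal(hit$strand, tr$strand, info = tr$is_id)
    expect_true(hit$bidirectional)
    expect_equal(hit$tsd_estimate, tr$tsd)
  }
  # per-call positions: right-side calls at p, left-side at p + tsd
  calls <- res$calls
  for (i in seq_len(nrow(calls))) {
    tr <- run$truth[run$truth$chromosome == calls$chromosome[i] &
                      abs(run$truth$position - calls$position[i]) <= 7L, ]
    expect_equal(nrow(tr), 1L)
    expected <- if (calls$host_side[i] == "right") tr$position else
      tr$position + tr$tsd
    expect_equal(calls$position[i], expected)
    expect_equal(calls$vector_strand_in_host[i], tr$strand)
  }
})

test_that("inward reads fail junction structure with reason short_arm", {
  run <- small_run(n_integrations = 1L, reads_per_end = 4L,
                   outward_bias = 0, background_fraction = 0,
                   circle_fraction = 0, seed = 42L)
  expect_true(all(run$reads$provenance$inward))
  res <- detect_sites(run$reads$reads, run$construct, run$host$genome)
  expect_equal(nrow(res$sites), 0L)
  expect_true(all(res$log$bucket %in% c("no_structure", "dropped_size")))
  surviving <- res$log[res$log$bucket == "no_structure", ]
  expect_true(all(surviving$reason %in%
                    c("inward_vector_read", "no_lv_alignment", "short_arm")))
})

test_that("episomal circle reads are detected and eliminated", {
  run <- small_run(n_integrations = 2L, reads_per_end = 1L,
                   background_fraction = 0, circle_fraction = 0.5, seed = 43L)
  prov <- run$reads$provenance
  expect_gt(sum(prov$class == "circle"), 0L)
  res <- detect_sites(run$reads$reads, run$construct, run$host$genome)
  lg <- merge(res$log, prov, by = "read_id")
  expect_true(all(lg$bucket[lg$class == "circle"] == "episome"))
  # genuine junction reads are never flagged episomal here
  expect_true(all(lg$bucket[lg$class %in% c("junction_left",
                                            "junction_right")] ==
                    "member_of_site"))
})

test_that("a vector-only read ending at the terminus is excluded conservatively", {
  con <- small_construct()
  arms <- arm_specs(con)
  cut <- arms$cut_position[arms$arm == "left"][1L]
  rd <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(con$sequence, 1L, cut))))   # exactly cut -> terminus, no host
  cidx <- build_index(stats::setNames(con$sequence, "vec"))
  hidx <- build_index(c(chr1 = rand_dna(30000L, seed = 44L)))
  tr <- triage_reads(stats::setNames(rd, "v1"), cidx, hidx)[[1L]]
  flag <- detect_episome(tr, con)
  expect_true(flag)
  expect_equal(attr(flag, "reason"), "ends_at_terminus")
})

test_that("cluster_calls merges by window and duplication geometry", {
  mk <- function(pos, side, end, read) {
    data.frame(read_id = read, chromosome = "chr1", position = pos,
               host_strand = "+", host_side = side, vector_end = end,
               vector_strand_in_host = "+", cut_site_used = "L1",
               stringsAsFactors = FALSE)
  }
  # same-side calls at 100, 103, 500 with window 10 -> two sites {2,1}
  calls <- rbind(mk(100L, "right", "right_terminus", "r1"),
                 mk(103L, "right", "right_terminus", "r2"),
                 mk(500L, "right", "right_terminus", "r3"))
  s <- cluster_calls(calls, merge_window = 10L)
  expect_equal(nrow(s), 2L)
  expect_equal(sort(s$support), c(1L, 2L))
  expect_false(any(s$bidirectional))
  expect_true(all(is.na(s$tsd_estimate)))
  # opposite ends offset by the 6-bp duplication -> one bidirectional site
  calls2 <- rbind(mk(100L, "right", "right_terminus", "r1"),
                  mk(106L, "left", "left_terminus", "r2"))
  s2 <- cluster_calls(calls2)
  expect_equal(nrow(s2), 1L)
  expect_true(s2$bidirectional)
  expect_equal(s2$position, 100L)
  expect_equal(s2$tsd_estimate, 6L)
  expect_equal(s2$support, 2L)
  # offset beyond tsd_max does not merge
  calls3 <- rbind(mk(100L, "right", "right_terminus", "r1"),
                  mk(109L, "left", "left_terminus", "r2"))
  expect_equal(nrow(cluster_calls(calls3, tsd_max = 7L)), 2L)
  # single call -> one unidirectional site of support 1
  s4 <- cluster_calls(mk(42L, "left", "left_terminus", "r1"))
  expect_equal(s4$support, 1L)
  expect_false(s4$bidirectional)
})

test_that("estimate_tsd recovers the simulated duplication exactly at error 0", {
  for (tsd in c(0L, 5L, 6L)) {
    run <- small_run(n_integrations = 2L, reads_per_end = 2L,
                     tsd_length = tsd, background_fraction = 0,
                     circle_fraction = 0, seed = 45L + tsd)
    res <- detect_sites(run$reads$reads, run$construct, run$host$genome)
    bidir <- res$sites[res$sites$bidirectional, ]
    expect_equal(nrow(bidir), 2L, info = paste("tsd", tsd))
    expect_true(all(bidir$tsd_estimate == tsd), info = paste("tsd", tsd))
  }
})

test_that("every read lands in exactly one decision bucket", {
  run <- small_run(n_integrations = 3L, reads_per_end = 2L,
                   error_rate = 0.08, outward_bias = 0.8, seed = 47L)
  res <- detect_sites(run$reads$reads, run$construct, run$host$genome)
  expect_equal(sum(res$counts), length(run$reads$reads))
  expect_equal(anyDuplicated(res$log$read_id), 0L)
  expect_equal(sort(res$log$read_id), sort(names(run$reads$reads)))
  # sum of site supports equals surviving junction calls
  expect_equal(sum(res$sites$support), nrow(res$calls))
  expect_equal(sum(res$sites$support), res$counts[["member_of_site"]])
})

test_that("detect_sites handles an empty read set", {
  r <- make_reads(character(0), integer(0))
  run <- small_run(n_integrations = 1L, reads_per_end = 1L, seed = 48L)
  res <- detect_sites(r, run$construct, run$host$genome)
  expect_equal(res$n_input, 0L)
  expect_equal(nrow(res$sites), 0L)
  expect_equal(sum(res$counts), 0L)
})
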