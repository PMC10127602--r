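toy_track <- function(counts, N, ...) {
  read_start_track(counts, N = N, replicon_id = "rep1", length = 1000, ...)
}

test_that("RRS is reads-per-million per position and orientation", {
  tr <- toy_track(data.frame(pos = 5, strand = "+", count = 10), N = 10)
  expect_equal(compute_rrs(tr)$counts$rrs, 1e6)
  tr2 <- toy_track(data.frame(pos = c(1, 2), strand = c("+", "-"),
                              count = c(3, 1)), N = 4)
  expect_equal(sort(compute_rrs(tr2)$counts$rrs), c(250000, 750000))
  # doubling counts and N leaves every RRS unchanged
  tr3 <- toy_track(data.frame(pos = c(1, 2), strand = c("+", "-"),
                              count = c(6, 2)), N = 8)
  expect_equal(compute_rrs(tr3)$counts$rrs, compute_rrs(tr2)$counts$rrs)
  expect_error(read_start_track(data.frame(pos = 1, strand = "+", count = 5),
                                N = 2), "exceeds")
})

test_that("total RRS is one million when the sparse map covers all reads", {
  for (s in 1:5) {
    tr <- random_full_track(n_pos = 200, seed = s)
    expect_equal(sum(compute_rrs(tr)$counts$rrs), 1e6, tolerance = 1e-9)
  }
})

test_that("cutoff filtering keeps the >= boundary and matches brute force", {
  tr <- toy_track(data.frame(pos = c(10, 20, 30), strand = "+",
                             count = c(5, 4, 60)), N = 1e6)
  rrs <- compute_rrs(tr)
  cand <- candidate_positions(rrs, cutoff = 5)
  expect_setequal(cand$pos, c(10, 30))   # rrs 5 kept, 4 dropped
  expect_equal(nrow(candidate_positions(rrs, cutoff = 100)), 0L)
  # exhaustive oracle over a dense 1 kb representation
  set.seed(77)
  sim <- gen_read_starts(1000, data.frame(pos = c(100, 700),
                                          strand = c("+", "-"),
                                          strength = c(50, 12)),
                         background_rate = 0.02, N = 1e6, n_replicates = 1,
                         seed = 77)
  tr2 <- sim[[1]][[1]]
  got <- candidate_positions(compute_rrs(tr2), 5)
  want <- brute_candidates(tr2, 5)
  expect_equal(got[order(got$strand, got$pos), c("pos", "strand", "rrs")],
               want[, c("pos", "strand", "rrs")],
               ignore_attr = TRUE)
})

test_that("clustering groups candidates within the cluster value", {
  cand <- data.frame(pos = c(100, 103, 120), strand = "+",
                     count = c(5, 9, 7), rrs = c(5, 9, 7))
  cl <- cluster_candidates(cand, cluster_value = 5)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$span_min, c(100, 120))
  expect_equal(cl$span_max, c(103, 120))
  expect_equal(cl$position, c(103, 120))  # max-RRS representative
  # equal-RRS tie on the minus strand resolves to the 5'-most (largest) pos
  tie <- data.frame(pos = c(100, 104), strand = "-", count = c(5, 5),
                    rrs = c(8, 8))
  expect_equal(cluster_candidates(tie, 5)$position, 104)
  tie_plus <- data.frame(pos = c(100, 104), strand = "+", count = c(5, 5),
                         rrs = c(8, 8))
  expect_equal(cluster_candidates(tie_plus, 5)$position, 100)
})

test_that("single-linkage clustering equals the transitive-closure oracle", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:25, 1)
    cand <- data.frame(pos = sample.int(300, n),
                       strand = sample(c("+", "-"), n, replace = TRUE),
                       count = 1L)
    cand <- cand[!duplicated(cand[c("pos", "strand")]), ]
    cand$rrs <- runif(nrow(cand), 5, 50)
    cv <- sample(1:10, 1)
    got <- cluster_candidates(cand, cv)
    want <- brute_cluster_partition(cand, cv)
    expect_equal(nrow(got), length(want))
    got_sets <- lapply(seq_len(nrow(got)), function(j) {
      sort(cand$pos[cand$strand == got$strand[j] &
                      cand$pos >= got$span_min[j] &
                      cand$pos <= got$span_max[j]])
    })
    want_sets <- lapply(want, `[[`, "pos")
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(want_sets, paste, collapse = ","))
  }
})

test_that("replicate matching keeps only TSSs present in all replicates", {
  cl <- function(pos, rrs, strand = "+") {
    data.frame(strand = strand, position = pos, span_min = pos,
               span_max = pos, rrs = rrs, n_candidates = 1L)
  }
  # near-identical positions across three replicates merge into one call
  calls <- reproducible_tss(list(cl(74141, 100), cl(74143, 140), cl(74145, 90)))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$position, 74143)
  expect_equal(calls$mean_rrs, mean(c(100, 140, 90)))
  expect_equal(calls$label, "TSS_74143+4")  # span 74141..74145
  # a peak in only 2 of 3 replicates is excluded
  two_of_three <- reproducible_tss(list(cl(500, 50), cl(500, 60),
                                        cl(9000, 55)))
  expect_equal(nrow(two_of_three), 0L)
  # ... but kept when require_all is off
  any_rep <- reproducible_tss(list(cl(500, 50), cl(500, 60), cl(9000, 55)),
                              require_all = FALSE)
  expect_equal(sort(any_rep$position), c(500, 9000))
  # opposite strands never match
  opp <- reproducible_tss(list(cl(500, 50), cl(500, 60, strand = "-")))
  expect_equal(nrow(opp), 0L)
})

test_that("scores and pass flags follow the control and floor rules", {
  calls <- reproducible_tss(list(
    data.frame(strand = "+", position = c(100, 600), span_min = c(100, 600),
               span_max = c(100, 600), rrs = c(60069, 9.9),
               n_candidates = 1L)))
  no_ctrl <- score_tss(calls)
  expect_equal(no_ctrl$score, c(60069, 9.9))
  expect_equal(no_ctrl$passed, c(TRUE, FALSE))   # score_min 10 boundary
  with_ctrl <- score_tss(calls, control = c(232, 0))
  expect_equal(with_ctrl$score[1], 60069 / 232, tolerance = 1e-9)
  expect_equal(with_ctrl$score[2], 9.9)  # floor of 1 guards the division
})

test_that("condition fold changes reproduce the metal-stress contrast", {
  up <- condition_fold_change(measured_value(60069, 10166, 3),
                              measured_value(232, 42, 3))
  expect_equal(up$fold_rounded, 259)
  expect_true(up$significant)
  edta <- condition_fold_change(measured_value(236, 43, 3),
                                measured_value(232, 42, 3))
  expect_equal(edta$fold, 236 / 232, tolerance = 1e-9)
  expect_equal(edta$fold_rounded, 1.02)
  expect_false(edta$significant)
  same <- condition_fold_change(measured_value(100, 5, 3),
                                measured_value(100, 5, 3))
  expect_equal(same$fold, 1)
})

test_that("calls are invariant to replicate order and replicon labels", {
  specs <- data.frame(pos = c(1000, 4000, 7000), strand = c("+", "-", "+"),
                      strength = c(100, 60, 40))
  sim <- gen_read_starts(8000, specs, background_rate = 0.05, N = 1e6,
                         n_replicates = 3, seed = 12)
  tracks <- sim[[1]]
  calls <- call_tss(tracks)
  perm <- call_tss(tracks[c(3, 1, 2)])
  expect_equal(calls$position, perm$position)
  expect_equal(calls$mean_rrs, perm$mean_rrs)
  relab <- lapply(tracks, function(tr) { tr$replicon_id <- "other"; tr })
  expect_equal(call_tss(relab)$position, calls$position)
})

test_that("reads on one strand never contribute to calls on the other", {
  specs <- data.frame(pos = c(2000, 2000), strand = c("+", "-"),
                      strength = c(500, 0))
  sim <- gen_read_starts(4000, specs, background_rate = 0, N = 1e6,
                         n_replicates = 3, seed = 4)
  calls <- call_tss(sim[[1]])
  expect_true(all(calls$strand == "+"))
  expect_equal(calls$position, 2000)
})

test_that("promoter windows are orientation-aware and involutive", {
  genome <- gen_genome(1000, seed = 8)
  fwd <- extract_promoter(genome, 300, "+")
  expect_equal(fwd$window, c(10, 410))
  expect_equal(length(fwd$sequence), 401L)
  expect_equal(as.character(fwd$sequence),
               as.character(genome[[1]][10:410]))
  rev <- extract_promoter(genome, 300, "-")
  expect_equal(rev$window, c(190, 590))
  expect_equal(length(rev$sequence), 401L)
  # reverse-complementing twice restores the reference-strand window
  expect_equal(as.character(Biostrings::reverseComplement(rev$sequence)),
               as.character(genome[[1]][190:590]))
  expect_warning(extract_promoter(genome, 100, "+"), "truncated")
  wrapped <- extract_promoter(genome, 100, "+", circular = TRUE)
  expect_equal(length(wrapped$sequence), 401L)
})

test_that("a motif planted upstream of a TSS lands at a fixed window offset", {
  motif <- "TTGACATATAATGCTAGC"
  tss_pos <- 600
  genome <- gen_genome(1200, data.frame(motif = motif, at = tss_pos - 35),
                       seed = 21)
  win <- extract_promoter(genome, tss_pos, "+")
  # window starts at tss - 290, so the motif begins at offset 290 - 35 + 1
  expect_equal(as.character(Biostrings::subseq(win$sequence, 256,
                                               256 + nchar(motif) - 1)),
               motif)
})

test_that("track files round-trip in both dialects and feed the caller", {
  specs <- data.frame(pos = 500, strand = "-", strength = 80)
  tr <- gen_read_starts(1000, specs, background_rate = 0.1, N = 1e6,
                        n_replicates = 1, seed = 3)[[1]][[1]]
  for (fmt in c("tsv", "bed")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_read_starts(tr, f, format = fmt)
    back <- read_read_starts(f, format = fmt, replicon_length = 1000)
    expect_equal(back$N, tr$N)
    expect_equal(back$counts$pos, tr$counts$pos)
    expect_equal(back$counts$count, tr$counts$count)
  }
  # explicit N overrides the header
  f <- tempfile()
  write_read_starts(tr, f)
  expect_equal(read_read_starts(f, N = 2e6)$N, 2e6)
  # calls + promoters can be written out
  calls <- score_tss(reproducible_tss(list(cluster_candidates(
    candidate_positions(compute_rrs(tr), 5), 5))))
  fc <- tempfile(fileext = ".tsv")
  write_tss_calls(calls, fc)
  expect_true(file.exists(fc))
  genome <- gen_genome(1000, seed = 2)
  fp <- tempfile(fileext = ".fasta")
  write_promoters(genome, calls, fp, circular = TRUE)
  seqs <- Biostrings::readDNAStringSet(fp)
  expect_equal(length(seqs), nrow(calls))
  expect_equal(unique(Biostrings::width(seqs)), 401L)
})
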