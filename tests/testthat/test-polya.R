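# 2P-Seq: positional signal, peak clustering, 3'-end assignment, APA calls,
# and 3'-end refinement.

test_that("positional signal accumulates counts and preserves totals", {
  empty <- tag_set(data.frame(chrom = character(), position = integer(),
                              strand = character(), count = integer()), 10)
  expect_equal(nrow(position_signal(empty)), 0L)
  ts <- tag_set(data.frame(chrom = "c", position = c(100L, 100L, 101L),
                           strand = "+", count = c(3L, 2L, 1L)), 100)
  sig <- position_signal(ts)
  expect_equal(sig$count[sig$position == 100], 5L)
  set.seed(41)
  df <- data.frame(chrom = sample(c("c1", "c2"), 500, TRUE),
                   position = sample(1:300, 500, TRUE),
                   strand = sample(c("+", "-"), 500, TRUE), count = 1L)
  sig <- position_signal(tag_set(df, 1e4))
  expect_equal(sum(sig$count), 500L)
  brute <- aggregate(count ~ chrom + position + strand, df, sum)
  m <- merge(sig, brute, by = c("chrom", "position", "strand"))
  expect_equal(m$count.x, m$count.y)
})

test_that("peak clustering is single-linkage with the documented tie rule", {
  sig <- data.frame(chrom = "c", strand = "+",
                    position = c(1000L, 1003L, 2100L), count = c(5L, 7L, 6L))
  pk <- call_peaks(sig, bandwidth = 24, min_peak_count = 1)
  expect_equal(pk$mode, c(1003L, 2100L))
  expect_equal(pk$signal, c(12L, 6L))
  # sub-threshold clusters are dropped but their signal is accounted for
  pk2 <- call_peaks(data.frame(chrom = "c", strand = "+", position = 500L,
                               count = 1L), 24, min_peak_count = 2)
  expect_equal(nrow(pk2), 0L)
  expect_equal(attr(pk2, "dropped_signal"), 1L)
  # tie in one cluster resolves to the most 3' position per strand
  tie <- data.frame(chrom = "c", strand = "+", position = c(10L, 20L),
                    count = c(4L, 4L))
  expect_equal(call_peaks(tie, 24, 1)$mode, 20L)
  tie$strand <- "-"
  expect_equal(call_peaks(tie, 24, 1)$mode, 10L)
})

test_that("clustering matches a brute-force oracle with signal conservation", {
  set.seed(42)
  for (rep in 1:20) {
    pos <- sort(sample(1:5000, 60))
    cnt <- sample(1:8, 60, TRUE)
    sig <- data.frame(chrom = "c", strand = "+", position = pos, count = cnt)
    bw <- sample(c(5, 24, 50), 1)
    floor <- sample(1:10, 1)
    pk <- call_peaks(sig, bw, floor)
    oc <- oracle_clusters(pos, bw)
    osum <- vapply(oc, function(p) sum(cnt[pos %in% p]), numeric(1))
    expect_equal(pk$signal, as.integer(osum[osum >= floor]))
    expect_equal(sum(pk$signal) + attr(pk, "dropped_signal"), sum(cnt))
  }
})

test_that("assignment respects the 1000-nt window boundary exactly", {
  tm <- transcript_models(data.frame(
    transcript_id = "t1", gene_id = "g1", chrom = "c",
    start = 1000L, end = 2000L, strand = "+"))
  mk_peak <- function(mode) data.frame(chrom = "c", strand = "+",
                                       mode = mode, span_start = mode,
                                       span_end = mode + 1L, signal = 10L)
  # annotated 3' base is 1999; modes 999 and 1001 nt downstream
  in_win <- assign_sites(mk_peak(1999L + 999L), tm)
  out_win <- assign_sites(mk_peak(1999L + 1001L), tm)
  at_win <- assign_sites(mk_peak(1999L + 1000L), tm)
  expect_equal(in_win$transcript_id, "t1")
  expect_equal(in_win$distance_to_3prime, 999L)
  expect_true(is.na(out_win$transcript_id))
  expect_equal(at_win$distance_to_3prime, 1000L)
  # fuzzed inputs never violate the window invariant
  set.seed(43)
  fuzz <- do.call(rbind, lapply(sample(-3000:3000, 200), function(d)
    mk_peak(1999L + d)))
  got <- assign_sites(fuzz, tm)
  expect_true(all(abs(got$distance_to_3prime) <= 1000, na.rm = TRUE))
  expect_equal(is.na(got$transcript_id), abs(fuzz$mode - 1999L) > 1000)
})

test_that("nearest same-strand transcript wins with lexicographic ties", {
  tm <- transcript_models(data.frame(
    transcript_id = c("b", "a"), gene_id = c("b", "a"), chrom = "c",
    start = c(1000L, 3000L), end = c(2000L, 4000L), strand = "+"))
  pk <- data.frame(chrom = "c", strand = "+", mode = 2999L,
                   span_start = 2999L, span_end = 3000L, signal = 5L)
  # 3' ends at 1999 and 3999: equidistant (1000 nt each) -> 'a'
  expect_equal(assign_sites(pk, tm)$transcript_id, "a")
  pk$strand <- "-"
  expect_true(is.na(assign_sites(pk, tm)$transcript_id))
})

test_that("APA detection requires two well-separated peaks per locus", {
  base <- data.frame(chrom = "c", strand = "+", span_start = 0L,
                     span_end = 1L, signal = 50L, transcript_id = "t1",
                     gene_id = "g1", distance_to_3prime = 0L)
  one <- transform(base, mode = 5000L)
  expect_equal(nrow(detect_apa(one)), 0L)
  two <- rbind(transform(base, mode = 5000L),
               transform(base, mode = 6000L, signal = 25L))
  apa <- detect_apa(two)
  expect_equal(nrow(apa), 2L)
  expect_equal(unique(apa$min_separation), 1000L)
  expect_equal(apa$signal_fraction, c(50, 25) / 75)
  # closer peaks merge into the stronger one first
  three <- rbind(two, transform(base, mode = 6050L, signal = 5L))
  apa3 <- detect_apa(three, apa_min_separation = 100)
  expect_equal(sort(apa3$mode), c(5000L, 6000L))
})

test_that("3'-end refinement moves the terminal exon to the peak mode", {
  tm <- transcript_models(data.frame(
    transcript_id = c("t1", "t1"), gene_id = "g1", chrom = "c",
    start = c(1000L, 1500L), end = c(1200L, 2000L), strand = "+"))
  same <- refine_three_prime(tm, "t1", 1999L)
  expect_equal(as.data.frame(same), as.data.frame(tm))
  ext <- refine_three_prime(tm, "t1", 2199L)
  expect_equal(tx_summary(ext)$three_prime, 2199L)
  expect_equal(tx_summary(ext)$exonic_length,
               tx_summary(tm)$exonic_length + 200L)
  expect_error(refine_three_prime(tm, "t1", 1400L), "terminal exon")
  # extension must not cross a same-strand annotated neighbour
  guard <- transcript_models(data.frame(
    transcript_id = "n1", gene_id = "n1", chrom = "c",
    start = 2100L, end = 2500L, strand = "+"))
  expect_error(refine_three_prime(tm, "t1", 2199L, annotation = guard),
               "cross")
  # minus strand: 3' end is the leftmost base
  tmm <- transcript_models(data.frame(
    transcript_id = "t2", gene_id = "g2", chrom = "c",
    start = 1000L, end = 2000L, strand = "-"))
  expect_equal(tx_summary(refine_three_prime(tmm, "t2", 800L))$three_prime,
               800L)
})

test_that("planted poly(A) sites and APA loci are recovered on synthetic data", {
  sim <- default_sim()
  peaks <- call_peaks(position_signal(sim$tags))
  assigned <- assign_sites(peaks, sim$assembled)
  truth <- sim$truth$polya
  hit <- vapply(seq_len(nrow(truth)), function(i)
    any(!is.na(assigned$transcript_id) &
          assigned$transcript_id == truth$transcript_id[i] &
          abs(assigned$mode - truth$site[i]) <= 10), logical(1))
  expect_gte(mean(hit), 0.9)
  apa <- detect_apa(assigned)
  truth_apa_gene <- sub("\\.1$", "", sim$truth$apa_loci)
  expect_setequal(unique(apa$locus_id), truth_apa_gene)
  refined <- refine_all(sim$assembled, assigned, annotation = sim$reference)
  # every revised 3' end lands on a recovered peak mode near a planted site
  expect_true(all(vapply(seq_len(nrow(refined$revised)), function(i) {
    tid <- refined$revised$transcript_id[i]
    any(truth$transcript_id == tid &
          abs(truth$site - refined$revised$new_three_prime[i]) <= 10)
  }, logical(1))))
})
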