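# Degradome target calling: penalty-scored alignment, cleavage prediction,
# peak categories, permutation p-values, and composed target calls.

test_that("perfect complement scores penalty 0 at the canonical register", {
  set.seed(51)
  mir <- rand_dna(21)
  tx <- paste0(rand_dna(100), revcomp(mir), rand_dna(100))
  al <- align_mirna(mir, tx)
  expect_equal(al$penalty[1], 0)
  expect_equal(al$site_start[1], 101L)
  expect_equal(al$cleavage_site[1], 101L + 21L - 10L)
})

test_that("a single core mismatch adds a doubled penalty", {
  set.seed(52)
  mir <- rand_dna(21)
  site <- revcomp(mir)
  # mutate the transcript base paired with miRNA position 12 into a mismatch
  loc <- 21 - 12 + 1
  t_old <- substr(site, loc, loc)
  m12 <- substr(mir, 12, 12)
  forbidden <- c(c(A = "T", C = "G", G = "C", T = "A")[[m12]],
                 if (m12 == "G") "T", if (m12 == "T") "G")
  substr(site, loc, loc) <- setdiff(c("A", "C", "G", "T"), c(forbidden, t_old))[1]
  tx <- paste0(rand_dna(50), site, rand_dna(50))
  al <- align_mirna(mir, tx)
  expect_equal(al$penalty[1], 2.0)
})

test_that("miRNA length bounds and alphabet are enforced", {
  expect_error(align_mirna(rand_dna(18), rand_dna(100)), "19-24")
  expect_error(align_mirna(rand_dna(25), rand_dna(100)), "19-24")
  expect_error(align_mirna(paste0(rand_dna(20), "N"), rand_dna(100)),
               "alphabet")
})

test_that("best penalty equals the exhaustive brute-force oracle", {
  set.seed(53)
  for (rep in 1:50) {
    L <- sample(19:24, 1)
    mir <- rand_dna(L)
    tx <- if (rep %% 3 == 0)
      paste0(rand_dna(40), revcomp(mir), rand_dna(40)) else rand_dna(120)
    got <- align_mirna(mir, tx, max_penalty = Inf)
    expect_equal(min(got$penalty), oracle_best_penalty(mir, tx),
                 info = sprintf("rep %d", rep))
  }
})

test_that("adding a mismatch never decreases the penalty", {
  set.seed(54)
  mir <- rand_dna(21)
  tx <- paste0(rand_dna(60), revcomp(mir), rand_dna(60))
  base_pen <- min(align_mirna(mir, tx, max_penalty = Inf)$penalty)
  for (pos in c(1, 5, 9, 14, 21)) {
    m2 <- mir
    cur <- substr(m2, pos, pos)
    substr(m2, pos, pos) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    expect_gte(min(align_mirna(m2, tx, max_penalty = Inf)$penalty), base_pen)
  }
})

test_that("cleavage is opposite miRNA position 10 and shifts with the site", {
  set.seed(55)
  mir <- rand_dna(21)
  tx1 <- paste0(rand_dna(100), revcomp(mir), rand_dna(30))
  tx2 <- paste0(rand_dna(107), revcomp(mir), rand_dna(30))
  a1 <- align_mirna(mir, tx1)[1, ]
  a2 <- align_mirna(mir, tx2)[1, ]
  expect_equal(predict_cleavage(a1), 112L)
  expect_equal(predict_cleavage(a2), 119L)
  a1$cleavage_site <- NA_integer_
  expect_error(predict_cleavage(a1), "bulge")
})

test_that("category assignment matches the rule-table oracle", {
  expect_equal(categorize(data.frame(position = 7L, count = 1L), 7L), 4L)
  uniq <- data.frame(position = c(3L, 7L, 9L), count = c(2L, 50L, 3L))
  expect_equal(categorize(uniq, 7L), 0L)
  expect_true(is.na(categorize(uniq, 5L)))
  set.seed(56)
  for (rep in 1:200) {
    npos <- sample(1:12, 1)
    prof <- data.frame(position = sample(1:30, npos),
                       count = sample(1:10, npos, TRUE))
    site <- sample(1:30, 1)
    cbp <- setNames(prof$count, prof$position)
    expect_equal(categorize(prof, site), oracle_category(cbp, site),
                 info = sprintf("rep %d", rep))
  }
})

test_that("permutation p-values are deterministic with the documented floor", {
  set.seed(57)
  mir <- rand_dna(21)
  tx <- paste0(rand_dna(80), revcomp(mir), rand_dna(80))
  site <- 81L + 21L - 10L
  prof <- data.frame(position = c(site, 10L, 40L), count = c(30L, 2L, 1L))
  expect_error(target_pvalue(mir, tx, prof, n_permutations = 10), ">= 19")
  p1 <- target_pvalue(mir, tx, prof, n_permutations = 99, seed = 5)
  p2 <- target_pvalue(mir, tx, prof, n_permutations = 99, seed = 5)
  expect_equal(p1$p_value, p2$p_value)
  expect_equal(p1$observed, c(0, 0))
  expect_equal(p1$p_value, 1 / 100)  # no shuffle ties the perfect site
})

test_that("dinucleotide shuffles preserve dinucleotide composition", {
  set.seed(58)
  dinucs <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    sort(paste0(ch[-length(ch)], ch[-1]))
  }
  for (rep in 1:20) {
    s <- rand_dna(21)
    sh <- lncstar:::.dinuc_shuffle(s)
    expect_equal(dinucs(sh), dinucs(s))
    expect_equal(nchar(sh), 21L)
  }
})

test_that("planted targets are called and decoys are not", {
  sim <- default_sim()
  coding <- unique(sim$assembled$transcript_id[sim$assembled$biotype == "coding"])
  calls <- call_targets(sim$mirnas, sim$tx_seqs[coding], sim$degradome,
                        n_permutations = 100, seed = 1)
  truth <- sim$truth$targets
  found <- paste(calls$mirna_id, calls$transcript_id) %in%
    paste(truth$mirna_id, truth$transcript_id)
  expect_gte(sum(found) / nrow(truth), 0.9)
  expect_false(any(calls$mirna_id %in% sim$truth$mirna_decoys))
  m <- merge(calls, truth, by = c("mirna_id", "transcript_id"))
  expect_equal(m$penalty.x, m$penalty.y)
  expect_equal(m$cleavage_site.x, m$cleavage_site.y)
  # the planted 60% cleavage fraction is reflected in percent-of-reads
  expect_true(all(abs(m$pct_reads_on_site - 60) < 10))
})

test_that("prediction without degradome respects the penalty threshold", {
  set.seed(59)
  mir <- rand_dna(21)
  hit <- paste0(rand_dna(20), revcomp(mir), rand_dna(20))
  txs <- c(hit = hit, null = rand_dna(61))
  got <- predict_only(c(m1 = mir), txs, max_penalty = 0)
  expect_equal(nrow(got), 1L)
  expect_equal(got$transcript_id, "hit")
  got0 <- predict_only(c(m1 = mir), txs["null"], max_penalty = 0)
  expect_equal(nrow(got0), 0L)
})
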