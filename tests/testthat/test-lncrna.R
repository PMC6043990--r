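# lncRNA discovery: novelty selection, filters, coding potential,
# dual-reference classification, locus merging and context labels.

simple_tm <- function(df) transcript_models(df)

test_that("novelty selection removes same-strand exonic overlap only", {
  ref <- simple_tm(data.frame(
    transcript_id = "r1", gene_id = "rg1", chrom = "c",
    start = 1000L, end = 2000L, strand = "+"))
  asm <- simple_tm(data.frame(
    transcript_id = c("sense1", "sense2", "anti1", "anti2", "int1", "int2"),
    gene_id = c("a1", "a2", "a3", "a4", "a5", "a6"), chrom = "c",
    start = c(1000L, 1500L, 1200L, 1900L, 5000L, 8000L),
    end = c(2000L, 2600L, 1400L, 2300L, 5600L, 8700L),
    strand = c("+", "+", "-", "-", "+", "-")))
  kept <- select_novel(asm, ref)
  expect_setequal(unique(kept$transcript_id), c("anti1", "anti2", "int1", "int2"))
})

test_that("candidate filters match brute-force predicates", {
  set.seed(31)
  lens <- sample(c(150L, 250L, 600L), 10, TRUE)
  tm <- simple_tm(data.frame(
    transcript_id = sprintf("t%02d", 1:10), gene_id = sprintf("g%02d", 1:10),
    chrom = "c", start = seq(0, 9000, 1000), end = seq(0, 9000, 1000) + lens,
    strand = "+"))
  expr <- matrix(runif(20, 0, 3), 10, 2,
                 dimnames = list(sprintf("t%02d", 1:10), c("s1", "s2")))
  got <- unique(filter_candidates(tm, expr, 200, 1.0)$transcript_id)
  want <- rownames(expr)[lens >= 200 & apply(expr, 1, max) > 1.0]
  expect_setequal(got, want)
  expect_error(filter_candidates(tm, expr[1:5, ], 200, 1.0), "missing")
})

test_that("longest ORF equals brute-force enumeration", {
  expect_equal(coding_potential(c(x = "CCCCCCAAACCCGGG"),
                                c(p = "MKL"))$longest_orf_nt, 0)
  set.seed(32)
  for (rep in 1:20) {
    s <- rand_dna(400)
    got <- coding_potential(setNames(s, "q"), c(p = "MKLMKLMKL"))
    expect_equal(got$longest_orf_nt, oracle_longest_orf(s))
    expect_equal(got$orf_coverage, oracle_longest_orf(s) / 400)
  }
})

test_that("a transcript that is a reference peptide's exact CDS scores as coding", {
  set.seed(33)
  codons <- setdiff(as.vector(outer(as.vector(outer(
    c("A","C","G","T"), c("A","C","G","T"), paste0)),
    c("A","C","G","T"), paste0)), c("TAA","TAG","TGA"))
  cds <- paste0("ATG", paste(sample(codons, 80, TRUE), collapse = ""), "TAA")
  pep <- sub("\\*$", "", as.character(Biostrings::translate(
    Biostrings::DNAString(cds))))
  rep <- coding_potential(c(q = cds), setNames(pep, "ref"))
  expect_equal(rep$homology_score, 1)
  expect_equal(rep$orf_coverage, 1)
  expect_equal(rep$verdict, "coding")
})

test_that("dual-reference classification follows the RLC/RHC rule table", {
  set.seed(34)
  codons <- setdiff(as.vector(outer(as.vector(outer(
    c("A","C","G","T"), c("A","C","G","T"), paste0)),
    c("A","C","G","T"), paste0)), c("TAA","TAG","TGA"))
  mk_cds <- function(n) paste0("ATG", paste(sample(codons, n, TRUE),
                                            collapse = ""), "TGA")
  pep_of <- function(cds) sub("\\*$", "", as.character(
    Biostrings::translate(Biostrings::DNAString(cds))))
  conserved <- mk_cds(90)   # in both references
  internal <- mk_cds(65)    # only in the full reference
  ref_full <- c(cons = pep_of(conserved), int = pep_of(internal))
  ref_excl <- ref_full["cons"]
  seqs <- c(rlc = rand_dna(500), rhc = internal, disc = conserved)
  got <- dual_reference_classify(seqs, ref_full, ref_excl)
  expect_equal(setNames(got$class, got$transcript_id),
               c(rlc = "RLC", rhc = "RHC", disc = "discarded"))
  expect_error(dual_reference_classify(seqs, ref_full["cons"], ref_full),
               "subset|absent")
})

test_that("locus merging is single-linkage and context uses any member", {
  ref <- simple_tm(data.frame(
    transcript_id = "r1", gene_id = "rg1", chrom = "c",
    start = 900L, end = 1100L, strand = "-"))
  lnc <- simple_tm(data.frame(
    transcript_id = c("a", "b", "c"), gene_id = c("ga", "gb", "gc"),
    chrom = "c", start = c(1000L, 1250L, 5000L),
    end = c(1300L, 1600L, 5400L), strand = "+"))
  cls <- data.frame(transcript_id = c("a", "b", "c"),
                    class = c("RLC", "RLC", "RHC"))
  res <- classify_context_and_merge(lnc, ref, cls)
  expect_equal(nrow(res$loci), 2L)
  merged <- res$loci[res$loci$n_transcripts == 2, ]
  expect_equal(merged$context, "cis-NAT")  # via member 'a' only
  expect_equal(res$loci$context[res$loci$n_transcripts == 1], "intergenic")
  expect_equal(res$loci$locus_id, c("cG0001", "cG0002"))
  expect_equal(unname(res$assignments[c("a", "b", "c")]),
               c("cG0001", "cG0001", "cG0002"))
})

test_that("the discovery pipeline recovers planted loci and is idempotent", {
  sim <- default_sim()
  disc <- default_discovery()
  truth <- sim$truth$loci
  # every locus carries exactly one context and one coding class
  expect_true(all(disc$loci$context %in% c("intergenic", "cis-NAT")))
  expect_true(all(disc$loci$coding_class %in% c("RLC", "RHC")))
  # planted-truth recovery by coordinates
  key <- function(d) paste(d$chrom, d$strand, d$start, d$end)
  expect_setequal(key(disc$loci), key(truth))
  # rerunning the filters on the surviving transcripts changes nothing
  expr <- fpkm(sim$counts, sim$lengths, sim$depths)
  again <- filter_candidates(select_novel(disc$transcripts, sim$reference),
                             expr)
  expect_setequal(unique(again$transcript_id),
                  unique(disc$transcripts$transcript_id))
})
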