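# Stepwise lncRNA discovery: novelty filtering against the reference
# annotation, length/expression filters, a self-contained coding-potential
# scorer run against two protein references (full and taxon-excluded), and
# genomic-context classification (intergenic vs cis-NAT).

#' Select assembled transcripts absent from the reference annotation
#'
#' Removes every assembled transcript with at least 1 bp of same-strand
#' exonic overlap with a reference transcript. Antisense and intergenic
#' transcripts are retained.
#'
#' @param assembled,reference `transcript_models` on the same genome.
#' @return `transcript_models` of the retained (novel) transcripts.
#' @export
select_novel <- function(assembled, reference) {
  ga <- tx_granges(assembled)
  gr <- tx_granges(reference)
  hits <- GenomicRanges::findOverlaps(ga, gr, ignore.strand = FALSE,
                                      minoverlap = 1L)
  bad <- unique(ga$transcript_id[S4Vectors::queryHits(hits)])
  keep <- !(assembled$transcript_id %in% bad)
  out <- assembled[keep, , drop = FALSE]
  class(out) <- class(assembled)
  out
}

#' Apply length and expression filters to lncRNA candidates
#'
#' Keeps transcripts with exonic length at least `min_length` nt and
#' expression above `min_fpkm` in at least one sample. The outcome is
#' independent of candidate order.
#'
#' @param candidates `transcript_models`.
#' @param expr expression matrix (FPKM) with one row per candidate
#'   transcript id.
#' @param min_length minimum exonic length in nt (default 200, the
#'   conventional lncRNA floor).
#' @param min_fpkm expression floor; a candidate must exceed it in >= 1
#'   sample (default 1.0).
#' @return filtered `transcript_models`.
#' @export
filter_candidates <- function(candidates, expr, min_length = 200,
                              min_fpkm = 1.0) {
  info <- tx_summary(candidates)
  miss <- setdiff(info$transcript_id, rownames(expr))
  if (length(miss))
    stop("candidate(s) missing from expression matrix: ",
         paste(miss, collapse = ", "))
  max_expr <- apply(expr[info$transcript_id, , drop = FALSE], 1L, max)
  keep_ids <- info$transcript_id[info$exonic_length >= min_length &
                                   max_expr > min_fpkm]
  out <- candidates[candidates$transcript_id %in% keep_ids, , drop = FALSE]
  class(out) <- class(candidates)
  out
}

# -- coding potential -------------------------------------------------------

# Longest ORF (ATG..stop, stop required, length in nt including the stop
# codon) over the three forward frames.
.longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  for (f in 1:3) {
    if (n - f + 1L < 6L) next
    starts <- seq.int(f, n - 2L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(atg) || !length(stp)) next
    # first in-frame stop at or after each ATG
    idx <- findInterval(atg - 1L, stp) + 1L
    ok <- idx <= length(stp)
    if (!any(ok)) next
    len <- (stp[idx[ok]] - atg[ok] + 1L) * 3L
    best <- max(best, max(len))
  }
  best
}

.translate_frames <- function(seq) {
  dna <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(dna)
  out <- character(0L)
  for (s in list(dna, rc)) {
    n <- length(s)
    for (f in 1:3) {
      m <- n - f + 1L
      m <- m - (m %% 3L)
      if (m < 3L) next
      aa <- Biostrings::translate(Biostrings::subseq(s, f, f + m - 1L),
                                  if.fuzzy.codon = "X", no.init.codon = TRUE)
      out <- c(out, as.character(aa))
    }
  }
  out
}

.kmer_set <- function(aa, k = 4L) {
  if (nchar(aa) < k) return(character(0L))
  km <- substring(aa, seq_len(nchar(aa) - k + 1L), seq_len(nchar(aa) - k + 1L) + k - 1L)
  unique(km[!grepl("[*X]", km)])
}

#' Score coding potential of transcripts against a protein reference
#'
#' A deterministic composite scorer standing in for SVM-based classifiers:
#' the longest ATG..stop open reading frame over the three forward frames,
#' its coverage of the transcript, and a peptide-homology term defined as the
#' best shared 4-mer fraction between any 6-frame translation of the
#' transcript and any reference peptide (|shared 4-mers| / |query-frame
#' 4-mers|). The composite score is
#' `w1 * min(longest_orf_nt / 300, 1) + w2 * orf_coverage + w3 * homology`
#' and a transcript is called coding when the composite reaches `cutoff`
#' (ties are called coding, the conservative choice for lncRNA discovery).
#'
#' @param seqs named character vector of transcript sequences (ACGTN).
#' @param protein_reference named character vector of reference peptides.
#' @param weights numeric length-3: ORF-length, ORF-coverage and homology
#'   weights (default `c(0.3, 0.2, 0.5)`).
#' @param cutoff composite score at or above which the verdict is `coding`
#'   (default 0.5).
#' @return data.frame: `transcript_id`, `longest_orf_nt`, `orf_coverage`,
#'   `homology_score`, `composite_score`, `verdict`.
#' @export
coding_potential <- function(seqs, protein_reference,
                             weights = c(0.3, 0.2, 0.5), cutoff = 0.5) {
  if (!length(protein_reference)) stop("protein reference must be non-empty")
  if (any(nchar(seqs) < 1L)) stop("empty transcript sequence")
  if (any(grepl("[^ACGTN]", seqs)))
    stop("transcript alphabet outside ACGTN")
  ref_kmers <- lapply(protein_reference, .kmer_set)
  rows <- lapply(seq_along(seqs), function(j) {
    s <- seqs[[j]]
    orf <- .longest_orf(s)
    cov <- orf / nchar(s)
    hom <- 0
    for (aa in .translate_frames(s)) {
      q <- .kmer_set(aa)
      if (!length(q)) next
      for (r in ref_kmers) {
        if (!length(r)) next
        sc <- length(intersect(q, r)) / length(q)
        if (sc > hom) hom <- sc
      }
      if (hom >= 1) break
    }
    comp <- weights[1L] * min(orf / 300, 1) + weights[2L] * cov +
      weights[3L] * hom
    data.frame(transcript_id = names(seqs)[j] %||% as.character(j),
               longest_orf_nt = orf, orf_coverage = cov,
               homology_score = hom, composite_score = comp,
               verdict = if (comp >= cutoff) "coding" else "noncoding",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dual-reference coding classification (RLC / RHC / discarded)
#'
#' Candidates are scored against the full protein reference and against a
#' taxon-excluded subset of it. A transcript noncoding under the full
#' reference is relatively low-coding (`RLC`); one coding under the full
#' reference but noncoding once taxon-internal peptides are excluded is
#' rescued as relatively high-coding (`RHC`); one coding under both is
#' discarded from the lncRNA set.
#'
#' @param seqs named character vector of candidate transcript sequences.
#' @param ref_full full peptide reference.
#' @param ref_taxon_excluded peptide reference with the focal taxon's entries
#'   removed (must be a subset of `ref_full`).
#' @param ... passed to [coding_potential()].
#' @return data.frame: `transcript_id`, `class` in `{RLC, RHC, discarded}`,
#'   plus the two composite scores.
#' @export
dual_reference_classify <- function(seqs, ref_full, ref_taxon_excluded, ...) {
  extra <- setdiff(ref_taxon_excluded, ref_full)
  if (length(extra))
    stop("taxon-excluded reference contains peptides absent from the full reference")
  full <- coding_potential(seqs, ref_full, ...)
  excl <- coding_potential(seqs, ref_taxon_excluded, ...)
  cls <- ifelse(full$verdict == "noncoding", "RLC",
                ifelse(excl$verdict == "noncoding", "RHC", "discarded"))
  data.frame(transcript_id = full$transcript_id, class = cls,
             composite_full = full$composite_score,
             composite_excluded = excl$composite_score,
             stringsAsFactors = FALSE)
}

# connected components of transcripts linked by same-strand exonic overlap
.overlap_components <- function(tm) {
  g <- tx_granges(tm)
  hits <- GenomicRanges::findOverlaps(g, g, ignore.strand = FALSE,
                                      minoverlap = 1L)
  ids <- unique(tm$transcript_id)
  # union-find on integer parents
  parent <- seq_along(ids)
  root <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  qi <- match(g$transcript_id[S4Vectors::queryHits(hits)], ids)
  si <- match(g$transcript_id[S4Vectors::subjectHits(hits)], ids)
  for (k in seq_along(qi)) {
    a <- root(qi[k]); b <- root(si[k])
    if (a != b) parent[a] <- b
  }
  setNames(vapply(seq_along(ids), root, integer(1L)), ids)
}

#' Merge lncRNA transcripts into loci and classify genomic context
#'
#' Transcripts are merged into loci by single-linkage same-strand exonic
#' overlap. A locus is `cis-NAT` when any member has at least `overlap_min`
#' bp of opposite-strand exonic overlap with an annotated transcript, else
#' `intergenic`. Locus identifiers follow the pattern `<chrom>Gnnnn`,
#' assigned per chromosome in coordinate order. The locus coding class is
#' `RLC` when any member is RLC, else `RHC`.
#'
#' @param lnc `transcript_models` of transcripts that passed all filters.
#' @param reference annotated `transcript_models`.
#' @param classes data.frame from [dual_reference_classify()] covering every
#'   member (rows with class `discarded` must already be removed).
#' @param overlap_min minimum opposite-strand exonic overlap in bp for the
#'   cis-NAT call (default 1).
#' @return list with `loci` (data.frame: locus_id, chrom, strand, start, end,
#'   context, coding_class, n_transcripts, n_exons, single_exon,
#'   transcript_ids), `assignments` (transcript_id -> locus_id) and
#'   `single_exon_fraction`.
#' @export
classify_context_and_merge <- function(lnc, reference, classes,
                                       overlap_min = 1L) {
  if (!nrow(lnc))
    return(list(loci = data.frame(), assignments = character(0L),
                single_exon_fraction = NA_real_))
  comp <- .overlap_components(lnc)
  info <- tx_summary(lnc)
  cls <- setNames(classes$class, classes$transcript_id)
  if (anyNA(cls[info$transcript_id]))
    stop("coding class missing for some transcripts")
  # opposite-strand exonic overlap of each transcript with the reference
  g <- tx_granges(lnc)
  gref <- tx_granges(reference)
  hits <- GenomicRanges::findOverlaps(g, gref, ignore.strand = TRUE)
  opp <- as.character(GenomicRanges::strand(g))[S4Vectors::queryHits(hits)] !=
    as.character(GenomicRanges::strand(gref))[S4Vectors::subjectHits(hits)]
  ov_w <- GenomicRanges::width(GenomicRanges::pintersect(
    g[S4Vectors::queryHits(hits)], gref[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE))
  opp_bp <- tapply(ov_w[opp], g$transcript_id[S4Vectors::queryHits(hits)][opp], sum)
  tx_opp <- setNames(rep(0L, nrow(info)), info$transcript_id)
  tx_opp[names(opp_bp)] <- as.integer(opp_bp)
  loci <- lapply(split(info$transcript_id, comp[info$transcript_id]), function(members) {
    e <- info[info$transcript_id %in% members, , drop = FALSE]
    data.frame(
      chrom = e$chrom[1L], strand = e$strand[1L],
      start = min(e$tx_start), end = max(e$tx_end),
      context = if (any(tx_opp[members] >= overlap_min)) "cis-NAT" else "intergenic",
      coding_class = if (any(cls[members] == "RLC")) "RLC" else "RHC",
      n_transcripts = length(members),
      n_exons = max(e$n_exons),
      single_exon = all(e$n_exons == 1L),
      transcript_ids = paste(sort(members), collapse = ","),
      stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, loci)
  loci <- loci[order(loci$chrom, loci$start, loci$end), , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(loci)), loci$chrom, FUN = seq_along)
  loci$locus_id <- sprintf("%sG%04d", loci$chrom, idx)
  loci <- loci[, c("locus_id", setdiff(names(loci), "locus_id"))]
  rownames(loci) <- NULL
  assign <- setNames(rep(loci$locus_id, loci$n_transcripts), character(0L))
  assign <- unlist(lapply(seq_len(nrow(loci)), function(i)
    setNames(rep(loci$locus_id[i], loci$n_transcripts[i]),
             strsplit(loci$transcript_ids[i], ",", fixed = TRUE)[[1L]])))
  list(loci = loci, assignments = assign,
       single_exon_fraction = mean(loci$single_exon))
}

#' Run the full lncRNA discovery pipeline
#'
#' Chains novelty selection, length/expression filtering, dual-reference
#' coding classification, and locus merging/context classification.
#'
#' @param assembled,reference `transcript_models`.
#' @param genome named chromosome sequences.
#' @param expr FPKM matrix over assembled transcript ids.
#' @param ref_full,ref_taxon_excluded peptide references.
#' @param min_length,min_fpkm,overlap_min filter parameters.
#' @param ... passed to [coding_potential()].
#' @return list with `loci`, `assignments`, `single_exon_fraction`,
#'   `classes`, and `transcripts` (the surviving `transcript_models`).
#' @export
discover_lncrna <- function(assembled, reference, genome, expr,
                            ref_full, ref_taxon_excluded,
                            min_length = 200, min_fpkm = 1.0,
                            overlap_min = 1L, ...) {
  novel <- select_novel(assembled, reference)
  filt <- filter_candidates(novel, expr, min_length, min_fpkm)
  if (!nrow(filt))
    return(list(loci = data.frame(), assignments = character(0L),
                single_exon_fraction = NA_real_, classes = data.frame(),
                transcripts = filt))
  seqs <- tx_sequences(filt, genome)
  cls <- dual_reference_classify(seqs, ref_full, ref_taxon_excluded, ...)
  keep <- cls$class != "discarded"
  kept_ids <- cls$transcript_id[keep]
  lnc <- filt[filt$transcript_id %in% kept_ids, , drop = FALSE]
  class(lnc) <- class(filt)
  merged <- classify_context_and_merge(lnc, reference, cls[keep, , drop = FALSE],
                                       overlap_min)
  c(merged, list(classes = cls, transcripts = lnc))
}
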