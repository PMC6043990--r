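# cis-natural antisense transcript (cis-NAT) pairs: identification,
# expression-relationship classification, and correlation-based attribution
# of overlapping small-RNA signal to the sense or antisense transcript.

#' Find cis-NAT pairs between coding transcripts and other transcripts
#'
#' Reports every (sense, antisense) pair of a coding transcript and any
#' opposite-strand transcript with at least 1 bp of exonic overlap, with the
#' total exonic overlap in bp.
#'
#' @param coding `transcript_models` of annotated coding transcripts (the
#'   sense partners).
#' @param others `transcript_models` searched for antisense partners
#'   (annotated NATs and/or novel lncRNAs).
#' @return data.frame: `sense_id`, `antisense_id`, `chrom`, `sense_strand`,
#'   `overlap_bp`.
#' @export
find_pairs <- function(coding, others) {
  gs <- tx_granges(coding)
  go <- tx_granges(others)
  hits <- GenomicRanges::findOverlaps(gs, go, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(sense_id = character(), antisense_id = character(),
                      chrom = character(), sense_strand = character(),
                      overlap_bp = integer()))
  qs <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  opp <- as.character(GenomicRanges::strand(gs))[qs] !=
    as.character(GenomicRanges::strand(go))[sh]
  qs <- qs[opp]; sh <- sh[opp]
  if (!length(qs))
    return(data.frame(sense_id = character(), antisense_id = character(),
                      chrom = character(), sense_strand = character(),
                      overlap_bp = integer()))
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    gs[qs], go[sh], ignore.strand = TRUE))
  key <- paste(gs$transcript_id[qs], go$transcript_id[sh], sep = "\r")
  agg <- tapply(w, key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  sense <- vapply(parts, `[`, character(1L), 1L)
  anti <- vapply(parts, `[`, character(1L), 2L)
  info <- tx_summary(coding)
  out <- data.frame(
    sense_id = sense, antisense_id = anti,
    chrom = info$chrom[match(sense, info$transcript_id)],
    sense_strand = info$strand[match(sense, info$transcript_id)],
    overlap_bp = as.integer(agg), stringsAsFactors = FALSE)
  out <- out[out$sense_id != out$antisense_id, , drop = FALSE]
  out <- out[order(out$sense_id, out$antisense_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the expression relationship of a NAT pair
#'
#' Deterministic truth table over the partners' DE directions, structurally
#' identical to tissue concordance but over the (sense, antisense) pair:
#' both changed in the same direction -> `concordant`; in opposite
#' directions -> `discordant`; exactly one changed -> `sense-only` /
#' `antisense-only`; neither -> `none`.
#'
#' @param sense_dir,antisense_dir direction vectors in
#'   `{"up", "down", "unchanged"}`.
#' @return character vector of relationship labels.
#' @export
pair_pattern <- function(sense_dir, antisense_dir) {
  lab <- concordance_label(sense_dir, antisense_dir)
  map <- c("concordant-up" = "concordant", "concordant-down" = "concordant",
           "discordant" = "discordant", "root-only" = "sense-only",
           "shoot-only" = "antisense-only", "none" = "none")
  unname(map[lab])
}

#' Attribute overlap-region small-RNA signal to the sense or antisense strand
#'
#' Small-RNA totals from the pair's overlap region are RP40M-normalised per
#' strand and correlated with the strand-matched partner's expression across
#' samples: the sense correlation pairs the small-RNA totals on the sense
#' transcript's strand with the sense partner's FPKM, and likewise for the
#' antisense partner. The verdict is the partner with the larger correlation
#' only when that correlation reaches `r_min` and the margin over the other
#' reaches `delta`; otherwise `ambiguous` (the outcome that also represents
#' a double-stranded origin).
#'
#' @param plus_counts,minus_counts per-sample raw small-RNA counts on the
#'   `+` and `-` genomic strand of the overlap region (same sample order).
#' @param depths per-sample small-RNA library depths.
#' @param sense_fpkm,antisense_fpkm per-sample expression of the partners.
#' @param sense_strand genomic strand of the sense transcript (`"+"`/`"-"`).
#' @param r_min minimum winning correlation (default 0.7).
#' @param delta minimum correlation margin (default 0.2).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list: `r_sense`, `r_antisense`, `verdict` in
#'   `{sense-derived, antisense-derived, ambiguous}`.
#' @export
attribute_smallrna <- function(plus_counts, minus_counts, depths,
                               sense_fpkm, antisense_fpkm, sense_strand,
                               r_min = 0.7, delta = 0.2,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(plus_counts)
  if (n < 3L) stop("at least 3 samples are required for attribution")
  stopifnot(length(minus_counts) == n, length(sense_fpkm) == n,
            length(antisense_fpkm) == n)
  if (length(depths) == 1L) depths <- rep(depths, n)
  stopifnot(length(depths) == n, sense_strand %in% c("+", "-"))
  plus_n <- plus_counts * 4e7 / depths
  minus_n <- minus_counts * 4e7 / depths
  sense_sr <- if (sense_strand == "+") plus_n else minus_n
  anti_sr <- if (sense_strand == "+") minus_n else plus_n
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    cor(x, y, method = method)
  }
  r_sense <- safe_cor(sense_sr, sense_fpkm)
  r_anti <- safe_cor(anti_sr, antisense_fpkm)
  verdict <- "ambiguous"
  if (max(r_sense, r_anti) >= r_min && abs(r_sense - r_anti) >= delta)
    verdict <- if (r_sense > r_anti) "sense-derived" else "antisense-derived"
  list(r_sense = r_sense, r_antisense = r_anti, verdict = verdict)
}
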