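# 2P-Seq 3'-end analysis: per-position 5'-tag signal, single-linkage peak
# clustering, candidate poly(A)-site assignment within 1 kb of transcript
# 3' ends, alternative-polyadenylation calls, and 3'-end model refinement.

#' Per-position 5'-tag signal
#'
#' Sums tag counts per exact (chrom, strand, position); the total tag count
#' is preserved.
#'
#' @param ts a `tag_set`.
#' @return data.frame: chrom, strand, position, count, sorted by position
#'   within chrom/strand.
#' @export
position_signal <- function(ts) {
  stopifnot(inherits(ts, "tag_set"))
  t <- ts$tags  # tag_set already collapses duplicates
  t[order(t$chrom, t$strand, t$position), c("chrom", "strand", "position", "count")]
}

#' Cluster positional tag signal into poly(A)-site peaks
#'
#' Positions on one chrom/strand are single-linkage clustered: consecutive
#' positions with a gap of at most `bandwidth` nt join one cluster. Clusters
#' whose summed signal falls below `min_peak_count` are dropped (the dropped
#' signal is reported for conservation checks). The peak mode is the position
#' of maximal count; ties resolve to the most 3' position on the strand.
#'
#' @param signal data.frame from [position_signal()].
#' @param bandwidth maximum within-cluster gap in nt (default 24).
#' @param min_peak_count minimum summed tag count per retained peak
#'   (default 5).
#' @return data.frame of peaks (chrom, strand, mode, span_start, span_end
#'   half-open, signal), sorted and disjoint, with attribute
#'   `dropped_signal`.
#' @export
call_peaks <- function(signal, bandwidth = 24L, min_peak_count = 5L) {
  stopifnot(bandwidth >= 1L)
  if (!nrow(signal)) {
    out <- data.frame(chrom = character(), strand = character(),
                      mode = integer(), span_start = integer(),
                      span_end = integer(), signal = integer())
    attr(out, "dropped_signal") <- 0L
    return(out)
  }
  dropped <- 0L
  res <- list()
  for (key in split(seq_len(nrow(signal)),
                    paste(signal$chrom, signal$strand))) {
    s <- signal[key, , drop = FALSE]
    s <- s[order(s$position), , drop = FALSE]
    cl <- cumsum(c(1L, diff(s$position) > bandwidth))
    for (grp in split(seq_len(nrow(s)), cl)) {
      g <- s[grp, , drop = FALSE]
      tot <- sum(g$count)
      if (tot < min_peak_count) { dropped <- dropped + tot; next }
      mx <- which(g$count == max(g$count))
      mode <- if (g$strand[1L] == "+") max(g$position[mx]) else min(g$position[mx])
      res[[length(res) + 1L]] <- data.frame(
        chrom = g$chrom[1L], strand = g$strand[1L], mode = mode,
        span_start = min(g$position), span_end = max(g$position) + 1L,
        signal = tot, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), strand = character(), mode = integer(),
               span_start = integer(), span_end = integer(), signal = integer())
  out <- out[order(out$chrom, out$strand, out$span_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_signal") <- dropped
  out
}

#' Assign peaks to transcript 3' ends within a distance window
#'
#' Each peak is assigned to the same-strand transcript whose annotated 3'
#' end is nearest to the peak mode, provided the absolute signed distance is
#' at most `window` nt (distance is measured along the strand: positive =
#' downstream of the annotated 3' end). Ties go to the lexicographically
#' smallest transcript id. Unassigned peaks are retained with `NA`
#' assignment.
#'
#' @param peaks data.frame from [call_peaks()].
#' @param tm `transcript_models` supplying annotated 3' ends.
#' @param window maximum |distance| in nt (default 1000).
#' @return `peaks` with columns `transcript_id`, `gene_id`,
#'   `distance_to_3prime` appended.
#' @export
assign_sites <- function(peaks, tm, window = 1000L) {
  info <- tx_summary(tm)
  peaks$transcript_id <- NA_character_
  peaks$gene_id <- NA_character_
  peaks$distance_to_3prime <- NA_integer_
  for (i in seq_len(nrow(peaks))) {
    cand <- info[info$chrom == peaks$chrom[i] & info$strand == peaks$strand[i], ,
                 drop = FALSE]
    if (!nrow(cand)) next
    d <- if (peaks$strand[i] == "+") peaks$mode[i] - cand$three_prime else
      cand$three_prime - peaks$mode[i]
    ok <- abs(d) <= window
    if (!any(ok)) next
    cand <- cand[ok, , drop = FALSE]; d <- d[ok]
    best <- order(abs(d), cand$transcript_id)[1L]
    peaks$transcript_id[i] <- cand$transcript_id[best]
    peaks$gene_id[i] <- cand$gene_id[best]
    peaks$distance_to_3prime[i] <- d[best]
  }
  peaks
}

#' Detect alternative polyadenylation from assigned peaks
#'
#' Peaks are grouped by locus (gene id of the assigned transcript). Within a
#' locus, peaks closer than `apa_min_separation` nt are merged into the
#' stronger peak first (greedy, by descending signal); a locus retaining two
#' or more well-separated peaks yields one APA call.
#'
#' @param assigned data.frame from [assign_sites()].
#' @param apa_min_separation minimum pairwise mode separation in nt
#'   (default 100).
#' @return data.frame with one row per retained site of each APA locus:
#'   `locus_id`, `mode`, `signal`, `signal_fraction`, `n_sites`,
#'   `min_separation`.
#' @export
detect_apa <- function(assigned, apa_min_separation = 100L) {
  a <- assigned[!is.na(assigned$gene_id), , drop = FALSE]
  out <- list()
  for (locus in unique(a$gene_id)) {
    p <- a[a$gene_id == locus, , drop = FALSE]
    if (nrow(p) < 2L) next
    p <- p[order(-p$signal, p$mode), , drop = FALSE]
    kept <- integer(0L)
    for (i in seq_len(nrow(p))) {
      if (all(abs(p$mode[i] - p$mode[kept]) >= apa_min_separation))
        kept <- c(kept, i)
    }
    if (length(kept) < 2L) next
    k <- p[kept, , drop = FALSE]
    k <- k[order(k$mode), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      locus_id = locus, mode = k$mode, signal = k$signal,
      signal_fraction = k$signal / sum(k$signal), n_sites = nrow(k),
      min_separation = min(diff(k$mode)), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(locus_id = character(), mode = integer(),
                      signal = integer(), signal_fraction = numeric(),
                      n_sites = integer(), min_separation = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Refine a transcript 3' end to an assigned poly(A) peak
#'
#' Moves the strand-aware 3' boundary of the terminal exon to the peak mode.
#' The revision must leave the terminal exon non-empty and must not extend
#' into an exon of another same-strand annotated transcript.
#'
#' @param tm `transcript_models` containing the transcript.
#' @param transcript_id transcript to revise.
#' @param mode 0-based coordinate of the peak mode (new 3'-terminal base).
#' @param annotation optional `transcript_models` used as the extension
#'   guard.
#' @return revised `transcript_models`.
#' @export
refine_three_prime <- function(tm, transcript_id, mode, annotation = NULL) {
  rows <- which(tm$transcript_id == transcript_id)
  if (!length(rows)) stop("unknown transcript: ", transcript_id)
  e <- tm[rows, , drop = FALSE]
  strand <- e$strand[1L]
  if (strand == "+") {
    term <- rows[which.max(tm$start[rows])]
    new_end <- mode + 1L
    if (new_end <= tm$start[term])
      stop("3' revision of ", transcript_id,
           " would empty its terminal exon")
    old <- tm$end[term]
    if (!is.null(annotation) && new_end > old)
      .check_extension(annotation, e$chrom[1L], strand, old, new_end,
                       e$gene_id[1L], transcript_id)
    tm$end[term] <- new_end
  } else {
    term <- rows[which.min(tm$start[rows])]
    new_start <- mode
    if (new_start >= tm$end[term])
      stop("3' revision of ", transcript_id,
           " would empty its terminal exon")
    old <- tm$start[term]
    if (!is.null(annotation) && new_start < old)
      .check_extension(annotation, e$chrom[1L], strand, new_start, old,
                       e$gene_id[1L], transcript_id)
    tm$start[term] <- new_start
  }
  transcript_models(as.data.frame(tm))
}

.check_extension <- function(annotation, chrom, strand, lo, hi, gene_id,
                             transcript_id) {
  other <- annotation[annotation$chrom == chrom & annotation$strand == strand &
                        annotation$gene_id != gene_id, , drop = FALSE]
  clash <- other$start < hi & other$end > lo
  if (any(clash))
    stop("3' extension of ", transcript_id,
         " would cross same-strand transcript ",
         other$transcript_id[which(clash)[1L]])
}

#' Batch 3'-end refinement from assigned peaks
#'
#' For every transcript with at least one assigned peak, revises the 3' end
#' to the mode of its strongest assigned peak. Transcripts whose revision
#' fails the guards are left unchanged with a warning.
#'
#' @param tm `transcript_models`.
#' @param assigned data.frame from [assign_sites()].
#' @param annotation optional guard annotation for [refine_three_prime()].
#' @return list: `models` (revised `transcript_models`) and `revised`
#'   (data.frame transcript_id, old_three_prime, new_three_prime).
#' @export
refine_all <- function(tm, assigned, annotation = NULL) {
  a <- assigned[!is.na(assigned$transcript_id), , drop = FALSE]
  rev_log <- list()
  for (tid in unique(a$transcript_id)) {
    p <- a[a$transcript_id == tid, , drop = FALSE]
    mode <- p$mode[which.max(p$signal)]
    old <- tx_summary(tm[tm$transcript_id == tid, , drop = FALSE])$three_prime
    if (mode == old) next
    res <- tryCatch(refine_three_prime(tm, tid, mode, annotation),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping 3' revision of ", tid, ": ", conditionMessage(res))
      next
    }
    tm <- res
    rev_log[[length(rev_log) + 1L]] <- data.frame(
      transcript_id = tid, old_three_prime = old, new_three_prime = mode,
      stringsAsFactors = FALSE)
  }
  list(models = tm,
       revised = if (length(rev_log)) do.call(rbind, rev_log) else
         data.frame(transcript_id = character(), old_three_prime = integer(),
                    new_three_prime = integer()))
}
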