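#' @importFrom stats rnorm rlnorm rnbinom rpois runif setNames aggregate cor median
#' @importFrom utils read.table write.table head tail
NULL

# ---------------------------------------------------------------------------
# Internal coordinate convention: 0-based half-open [start, end), BED-like.
# GTF/GFF3 are converted at the IO boundary (1-based inclusive <-> internal).
# ---------------------------------------------------------------------------

#' Construct a set of transcript models from an exon table
#'
#' The canonical container for transcript models is a data frame of exons with
#' one row per exon and internal 0-based half-open coordinates. Exons of one
#' transcript must lie on a single chromosome and strand, be pairwise disjoint,
#' and are stored sorted by start.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start` (0-based inclusive), `end` (0-based exclusive), `strand`
#'   (`"+"`/`"-"`), and optionally `biotype` (`coding`, `noncoding`, `unknown`).
#' @return A `transcript_models` object (a validated, sorted data.frame).
#' @export
transcript_models <- function(exons) {
  need <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stop("exon table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(exons$biotype)) exons$biotype <- "unknown"
  exons <- exons[, c(need, "biotype")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(is.na(exons$start)) || any(is.na(exons$end)))
    stop("exon coordinates must be integral")
  if (any(exons$start < 0L) || any(exons$start >= exons$end))
    stop("exon intervals must satisfy 0 <= start < end")
  if (!all(exons$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  for (tid in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tid, , drop = FALSE]
    if (length(unique(e$chrom)) != 1L || length(unique(e$strand)) != 1L)
      stop("transcript ", tid, " mixes chromosomes or strands")
    if (length(unique(e$gene_id)) != 1L)
      stop("transcript ", tid, " has inconsistent gene_id")
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
      stop("transcript ", tid, " has overlapping exons")
  }
  class(exons) <- c("transcript_models", "data.frame")
  exons
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("transcript_models: %d transcripts, %d exons, %d genes\n",
              length(unique(x$transcript_id)), nrow(x),
              length(unique(x$gene_id))))
  invisible(x)
}

#' Per-transcript summary of a transcript-model set
#'
#' @param tm a `transcript_models` object.
#' @return data.frame with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `tx_start`, `tx_end` (0-based half-open span),
#'   `exonic_length`, `n_exons`, `three_prime` (0-based coordinate of the
#'   strand-aware 3'-terminal base: last base on `+`, first base on `-`),
#'   and `biotype`.
#' @export
tx_summary <- function(tm) {
  sp <- split(seq_len(nrow(tm)), tm$transcript_id)
  out <- do.call(rbind, lapply(sp, function(i) {
    e <- tm[i, , drop = FALSE]
    data.frame(
      transcript_id = e$transcript_id[1L], gene_id = e$gene_id[1L],
      chrom = e$chrom[1L], strand = e$strand[1L],
      tx_start = min(e$start), tx_end = max(e$end),
      exonic_length = sum(e$end - e$start), n_exons = nrow(e),
      three_prime = if (e$strand[1L] == "+") max(e$end) - 1L else min(e$start),
      biotype = e$biotype[1L], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Convert transcript models to an exon-level GRanges
#'
#' @param tm a `transcript_models` object.
#' @return `GRanges` (1-based) with `transcript_id` and `gene_id` metadata.
#' @export
tx_granges <- function(tm) {
  GenomicRanges::GRanges(
    seqnames = tm$chrom,
    ranges = IRanges::IRanges(start = tm$start + 1L, end = tm$end),
    strand = tm$strand,
    transcript_id = tm$transcript_id, gene_id = tm$gene_id)
}

#' Extract spliced transcript sequences from a genome
#'
#' Exon sequences are concatenated 5' to 3' on the transcript strand
#' (reverse-complemented for `-`-strand models).
#'
#' @param tm a `transcript_models` object.
#' @param genome named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @return named character vector of transcript sequences.
#' @export
tx_sequences <- function(tm, genome) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  chr_seq <- as.character(genome)
  sp <- split(seq_len(nrow(tm)), tm$transcript_id)
  out <- vapply(sp, function(i) {
    e <- tm[i, , drop = FALSE]
    s <- paste(substring(chr_seq[[e$chrom[1L]]], e$start + 1L, e$end),
               collapse = "")
    if (e$strand[1L] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1L))
  out
}

.guess_gff_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("gff", "gff3")) "gff3" else "gtf"
}

#' Read transcript models from a GTF/GFF3 annotation
#'
#' Exon features are grouped into transcripts; 1-based inclusive file
#' coordinates are converted to the internal 0-based half-open convention.
#' Exons lacking a transcript identifier, or on an undetermined (`.`) strand,
#' are skipped with a warning. Both quoted (GTF) and unquoted (RAP-DB style)
#' attribute values are tolerated via the underlying parser.
#'
#' @param path GTF or GFF3 file.
#' @param format `"auto"` (by extension), `"gtf"`, or `"gff3"`.
#' @return a `transcript_models` object.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_gff_format(path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1L))
  if (any(nf < 8L))
    stop(sprintf("malformed %s record at line %d of %s (expected >= 8 tab-separated fields)",
                 toupper(format), body[which(nf < 8L)[1L]], path))
  gr <- rtracklayer::import(path, format = format)
  gr <- gr[!is.na(gr$type) & tolower(as.character(gr$type)) == "exon"]
  if (!length(gr)) stop("no exon features found in ", path)
  mc <- S4Vectors::mcols(gr)
  tid <- if ("transcript_id" %in% names(mc)) {
    as.character(mc$transcript_id)
  } else if ("Parent" %in% names(mc)) {
    vapply(as.list(mc$Parent), function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, character(1L))
  } else rep(NA_character_, length(gr))
  gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else tid
  gid[is.na(gid)] <- tid[is.na(gid)]
  bio <- if ("biotype" %in% names(mc)) as.character(mc$biotype) else
    rep("unknown", length(gr))
  bio[is.na(bio)] <- "unknown"
  drop <- is.na(tid) | !nzchar(tid)
  if (any(drop))
    warning(sum(drop), " exon record(s) without a transcript id skipped")
  no_strand <- as.character(GenomicRanges::strand(gr)) == "*"
  if (any(no_strand & !drop))
    warning(sum(no_strand & !drop), " unstranded exon record(s) skipped")
  keep <- !drop & !no_strand
  gr <- gr[keep]
  transcript_models(data.frame(
    transcript_id = tid[keep], gene_id = gid[keep],
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = bio[keep], stringsAsFactors = FALSE))
}

#' Write transcript models as GTF
#'
#' Emits one `exon` feature per exon, 1-based inclusive, with `gene_id`,
#' `transcript_id` and `biotype` attributes. `read_annotation()` round-trips
#' the output.
#'
#' @param tm a `transcript_models` object.
#' @param path output GTF path.
#' @param source value for the GTF source column.
#' @param extra_attrs optional named character vector of per-transcript
#'   attributes (names are transcript ids) appended to that transcript's rows.
#' @export
write_annotation <- function(tm, path, source = "lncstar", extra_attrs = NULL) {
  ord <- order(tm$chrom, tm$transcript_id, tm$start)
  tm2 <- tm[ord, , drop = FALSE]
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; biotype "%s";',
                   tm2$gene_id, tm2$transcript_id, tm2$biotype)
  if (!is.null(extra_attrs)) {
    extra <- extra_attrs[tm2$transcript_id]
    extra[is.na(extra)] <- ""
    attrs <- paste0(attrs, ifelse(nzchar(extra), paste0(" ", extra), ""))
  }
  lines <- paste(tm2$chrom, source, "exon", tm2$start + 1L, tm2$end, ".",
                 tm2$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Tag sets (5'-end positions of sequenced tags)
# ---------------------------------------------------------------------------

#' Construct a tag set
#'
#' A tag set is a multiset of 5'-end tag positions with counts, plus the
#' total aligned library depth used for per-million style normalisation.
#'
#' @param tags data.frame with columns `chrom`, `position` (0-based 5'-end
#'   coordinate), `strand`, `count` (positive integer). Duplicate
#'   (chrom, position, strand) records are collapsed by summing counts.
#' @param library_depth total aligned reads in the library; must be at least
#'   the sum of counts.
#' @return a `tag_set` object.
#' @export
tag_set <- function(tags, library_depth) {
  need <- c("chrom", "position", "strand", "count")
  miss <- setdiff(need, names(tags))
  if (length(miss)) stop("tag table missing columns: ", paste(miss, collapse = ", "))
  tags <- tags[, need]
  tags$position <- as.integer(tags$position)
  tags$count <- as.integer(tags$count)
  if (any(tags$count < 1L)) stop("tag counts must be >= 1")
  if (!all(tags$strand %in% c("+", "-"))) stop("tag strand must be '+' or '-'")
  if (nrow(tags)) {
    tags <- aggregate(count ~ chrom + position + strand, data = tags, FUN = sum)
    tags <- tags[order(tags$chrom, tags$strand, tags$position), , drop = FALSE]
  }
  rownames(tags) <- NULL
  if (sum(tags$count) > library_depth)
    stop("library_depth (", library_depth, ") is smaller than total tag count (",
         sum(tags$count), ")")
  structure(list(tags = tags, library_depth = library_depth), class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("tag_set: %d positions, %d tags, depth %g\n",
              nrow(x$tags), sum(x$tags$count), x$library_depth))
  invisible(x)
}

#' Read 5'-end tag positions from a BED6 file
#'
#' The biological 5' end of each tag is taken strand-aware: BED `start` for
#' `+`-strand records and BED `end - 1` for `-`-strand records. The score
#' column is used as the tag count (scores below 1 are treated as count 1).
#'
#' @param path BED6 file.
#' @param depth total aligned library depth.
#' @return a `tag_set`.
#' @export
read_tags <- function(path, depth) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 6L) stop("BED6 expected (6 columns) in ", path)
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  score <- suppressWarnings(as.numeric(df$score))
  count <- ifelse(is.na(score) | score < 1, 1L, as.integer(round(score)))
  pos <- ifelse(df$strand == "+", df$start, df$end - 1L)
  tag_set(data.frame(chrom = df$chrom, position = pos, strand = df$strand,
                     count = count, stringsAsFactors = FALSE),
          library_depth = depth)
}

#' Write a tag set as BED6
#'
#' Each position becomes a 1-bp record whose score carries the tag count;
#' `read_tags()` round-trips the output.
#'
#' @param ts a `tag_set`.
#' @param path output path.
#' @export
write_tags <- function(ts, path) {
  t <- ts$tags
  lines <- paste(t$chrom, t$position, t$position + 1L, ".", t$count, t$strand,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA
# ---------------------------------------------------------------------------

#' Read a FASTA file of DNA/RNA sequences
#'
#' Sequences are upper-cased and `U` is normalised to `T`; the alphabet is
#' restricted to `ACGTN`. Duplicate identifiers are an error.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  seqs <- chartr("u", "T", chartr("U", "T", toupper(as.character(ss))))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence(s) with characters outside ACGTUN: ",
         paste(head(ids[bad], 3L), collapse = ", "))
  setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector (DNA alphabet).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# TSV matrices
# ---------------------------------------------------------------------------

#' Read a feature-by-sample matrix from TSV
#'
#' First column must be `feature_id`; remaining columns are sample keys
#' formatted `tissue_condition_timepoint` (e.g. `root_-N_7d`). Any missing
#' cell is a validation error.
#'
#' @param path TSV file.
#' @return numeric matrix with feature rownames.
#' @export
read_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (names(df)[1L] != "feature_id") stop("first column must be 'feature_id'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyNA(m)) stop("matrix contains missing cells")
  if (any(m < 0)) stop("matrix contains negative values")
  rownames(m) <- df$feature_id
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param m matrix with feature rownames and sample colnames.
#' @param path output path.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse sample keys of the form tissue_condition_timepoint
#'
#' @param keys character vector, e.g. `"root_-N_7d"`.
#' @return data.frame with `tissue`, `condition`, `timepoint` (integer days).
#' @export
parse_sample_key <- function(keys) {
  parts <- strsplit(keys, "_", fixed = TRUE)
  bad <- vapply(parts, length, integer(1L)) != 3L
  if (any(bad)) stop("malformed sample key(s): ", paste(keys[bad], collapse = ", "))
  data.frame(
    key = keys,
    tissue = vapply(parts, `[`, character(1L), 1L),
    condition = vapply(parts, `[`, character(1L), 2L),
    timepoint = as.integer(sub("d$", "", vapply(parts, `[`, character(1L), 3L))),
    stringsAsFactors = FALSE)
}
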