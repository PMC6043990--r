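# End-to-end orchestration over an on-disk input bundle: lncRNA discovery ->
# 2P-Seq poly(A)/APA -> expression profiling -> degradome targets -> cis-NAT
# small-RNA attribution, with a resolved-config echo, per-stage counts, and
# a machine-readable summary.

.cfg_error <- function(msg) stop(structure(
  class = c("lncstar_config_error", "error", "condition"),
  list(message = msg, call = NULL)))
.input_error <- function(msg) stop(structure(
  class = c("lncstar_input_error", "error", "condition"),
  list(message = msg, call = NULL)))

#' Pipeline configuration
#'
#' All thresholds of the individual stages, with their documented defaults.
#' Unknown keys are rejected.
#'
#' @param seed RNG seed used for every stochastic step (permutation nulls).
#' @param stages character vector of enabled stages, a subset of
#'   `c("lncrna", "polya", "expr", "degradome", "natpair")`.
#' @param min_length,min_fpkm,overlap_min lncRNA discovery thresholds.
#' @param cp_weights,cp_cutoff coding-potential scorer parameters.
#' @param bandwidth,min_peak_count,window,apa_min_separation 2P-Seq
#'   parameters.
#' @param pseudocount,min_expr_floor expression parameters.
#' @param max_penalty,max_category,alpha,n_permutations degradome parameters.
#' @param r_min,delta small-RNA attribution thresholds.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("lncrna", "polya", "expr",
                                       "degradome", "natpair"),
                            min_length = 200, min_fpkm = 1.0,
                            overlap_min = 1L,
                            cp_weights = c(0.3, 0.2, 0.5), cp_cutoff = 0.5,
                            bandwidth = 24L, min_peak_count = 5L,
                            window = 1000L, apa_min_separation = 100L,
                            pseudocount = 0.1, min_expr_floor = 1.0,
                            max_penalty = 5.0, max_category = 4L,
                            alpha = 0.05, n_permutations = 100L,
                            r_min = 0.7, delta = 0.2) {
  cfg <- as.list(environment())
  known <- c("lncrna", "polya", "expr", "degradome", "natpair")
  if (length(setdiff(stages, known)))
    .cfg_error(paste("unknown stage(s):",
                     paste(setdiff(stages, known), collapse = ", ")))
  class(cfg) <- "pipeline_config"
  cfg
}

.read_two_col <- function(path, what) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  setNames(df[[2L]], df[[1L]])
}

#' Run the integrated pipeline on an input bundle
#'
#' Reads a directory laid out as written by [write_bundle()] and executes
#' the enabled stages in dependency order, writing all stage outputs, a
#' resolved-config echo (`config.json`) and a summary (`summary.json`)
#' under `out_dir`. Identical inputs, config and seed give byte-identical
#' outputs.
#'
#' @param in_dir input bundle directory.
#' @param out_dir output directory (created; existing stage outputs are
#'   overwritten).
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(in_dir, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("genome.fa", "reference.gtf", "assembled.gtf", "counts.tsv",
            "lengths.tsv", "depths.tsv")
  stage_need <- list(
    lncrna = c("proteins_full.fa", "proteins_excl.fa"),
    polya = "tags_2pseq.bed",
    degradome = c("mirnas.fa", "degradome.bed"),
    natpair = "smallrna_nat.tsv")
  for (st in config$stages)
    need <- c(need, stage_need[[st]])
  miss <- need[!file.exists(file.path(in_dir, need))]
  if (length(miss))
    .input_error(paste("missing input file(s):", paste(miss, collapse = ", ")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  op <- function(f) file.path(out_dir, f)
  log_lines <- character(0L)
  say <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", "lncstar", sprintf(fmt, ...))
    log_lines <<- c(log_lines, msg)
  }
  summary <- list(seed = config$seed, stages = as.list(config$stages))

  genome <- read_fasta(file.path(in_dir, "genome.fa"))
  reference <- read_annotation(file.path(in_dir, "reference.gtf"))
  assembled <- read_annotation(file.path(in_dir, "assembled.gtf"))
  counts <- read_matrix(file.path(in_dir, "counts.tsv"))
  lengths <- .read_two_col(file.path(in_dir, "lengths.tsv"))
  depths <- .read_two_col(file.path(in_dir, "depths.tsv"))
  expr <- fpkm(counts, lengths, depths)
  write_matrix(round(expr, 6), op("fpkm.tsv"))
  skey <- parse_sample_key(colnames(counts))
  say("inputs: %d reference / %d assembled transcripts, %d x %d counts",
      length(unique(reference$transcript_id)),
      length(unique(assembled$transcript_id)), nrow(counts), ncol(counts))

  lnc <- NULL
  if ("lncrna" %in% config$stages) {
    ref_full <- .aa_fasta(file.path(in_dir, "proteins_full.fa"))
    ref_excl <- .aa_fasta(file.path(in_dir, "proteins_excl.fa"))
    lnc <- discover_lncrna(assembled, reference, genome, expr,
                           ref_full, ref_excl,
                           min_length = config$min_length,
                           min_fpkm = config$min_fpkm,
                           overlap_min = config$overlap_min,
                           weights = config$cp_weights,
                           cutoff = config$cp_cutoff)
    write.table(lnc$loci, op("lncrna_loci.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_annotation(lnc$transcripts, op("lncrna.gtf"))
    summary$lncrna <- list(
      n_loci = nrow(lnc$loci),
      n_intergenic = sum(lnc$loci$context == "intergenic"),
      n_cis_nat = sum(lnc$loci$context == "cis-NAT"),
      n_rlc = sum(lnc$loci$coding_class == "RLC"),
      n_rhc = sum(lnc$loci$coding_class == "RHC"),
      single_exon_fraction = lnc$single_exon_fraction)
    say("lncrna: %d loci (%d intergenic / %d cis-NAT; %d RLC / %d RHC)",
        summary$lncrna$n_loci, summary$lncrna$n_intergenic,
        summary$lncrna$n_cis_nat, summary$lncrna$n_rlc, summary$lncrna$n_rhc)
  }

  if ("polya" %in% config$stages) {
    n_tag_lines <- length(readLines(file.path(in_dir, "tags_2pseq.bed")))
    tags <- read_tags(file.path(in_dir, "tags_2pseq.bed"),
                      depth = .bed_total(file.path(in_dir, "tags_2pseq.bed")))
    sig <- position_signal(tags)
    peaks <- call_peaks(sig, bandwidth = config$bandwidth,
                        min_peak_count = config$min_peak_count)
    assigned <- assign_sites(peaks, assembled, window = config$window)
    apa <- detect_apa(assigned, apa_min_separation = config$apa_min_separation)
    refined <- refine_all(assembled, assigned, annotation = reference)
    write.table(assigned, op("polya_peaks.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(apa, op("apa_calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_annotation(refined$models, op("refined.gtf"))
    summary$polya <- list(
      n_peaks = nrow(peaks), n_assigned = sum(!is.na(assigned$transcript_id)),
      n_apa_loci = length(unique(apa$locus_id)),
      n_revised = nrow(refined$revised))
    say("polya: %d peaks, %d assigned, %d APA loci (%d tag records)",
        nrow(peaks), summary$polya$n_assigned, summary$polya$n_apa_loci,
        n_tag_lines)
  }

  if ("expr" %in% config$stages) {
    de_all <- list(); conc_all <- list(); resp <- list()
    tissues <- unique(skey$tissue)
    cond <- unique(skey$condition)[1L]
    tps <- sort(setdiff(unique(skey$timepoint), 0L))
    for (ti in tissues) {
      de <- call_de(expr, starvation_contrasts(ti, cond, tps),
                    min_expr_floor = config$min_expr_floor,
                    pseudocount = config$pseudocount)
      de_all[[ti]] <- de
      resp[[ti]] <- de$responsive
    }
    if (all(c("root", "shoot") %in% tissues)) {
      for (tp in tps) {
        cname_r <- sprintf("root_%s_%dd_vs_0d", cond, tp)
        cr <- de_all$root$calls[de_all$root$calls$contrast == cname_r, ]
        cs <- de_all$shoot$calls[
          de_all$shoot$calls$contrast == sprintf("shoot_%s_%dd_vs_0d", cond, tp), ]
        feats <- sort(union(cr$feature, cs$feature))
        rd <- setNames(rep("unchanged", length(feats)), feats)
        sd_ <- rd
        rd[cr$feature] <- cr$direction
        sd_[cs$feature] <- cs$direction
        conc_all[[as.character(tp)]] <- data.frame(
          feature = feats, timepoint = tp, root_direction = unname(rd),
          shoot_direction = unname(sd_),
          label = concordance_label(unname(rd), unname(sd_)),
          stringsAsFactors = FALSE)
      }
    }
    de_tab <- do.call(rbind, lapply(de_all, `[[`, "calls"))
    rownames(de_tab) <- NULL
    write.table(de_tab, op("de_calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (length(conc_all)) {
      conc_tab <- do.call(rbind, conc_all)
      rownames(conc_tab) <- NULL
      write.table(conc_tab, op("concordance.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    responsive <- sort(unique(unlist(resp)))
    writeLines(responsive, op("responsive_features.txt"))
    summary$expr <- list(n_responsive = length(responsive),
                         n_de_calls = sum(de_tab$direction != "unchanged"))
    say("expr: %d responsive features, %d directional calls",
        summary$expr$n_responsive, summary$expr$n_de_calls)
  }

  if ("degradome" %in% config$stages) {
    mirnas <- read_fasta(file.path(in_dir, "mirnas.fa"))
    deg <- read_tags(file.path(in_dir, "degradome.bed"),
                     depth = .bed_total(file.path(in_dir, "degradome.bed")))
    tx_seqs <- tx_sequences(assembled, genome)
    coding_ids <- unique(assembled$transcript_id[assembled$biotype == "coding"])
    targets <- call_targets(mirnas, tx_seqs[coding_ids], deg,
                            max_penalty = config$max_penalty,
                            max_category = config$max_category,
                            alpha = config$alpha,
                            n_permutations = config$n_permutations,
                            seed = config$seed)
    write.table(targets, op("targets.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    summary$degradome <- list(n_calls = nrow(targets),
                              n_mirnas = length(unique(targets$mirna_id)))
    say("degradome: %d target calls from %d miRNAs",
        nrow(targets), summary$degradome$n_mirnas)
  }

  if ("natpair" %in% config$stages) {
    lnc_tx <- if (!is.null(lnc)) lnc$transcripts else {
      nc <- assembled[assembled$biotype != "coding", , drop = FALSE]
      class(nc) <- class(assembled); nc
    }
    pairs <- find_pairs(reference, lnc_tx)
    sr <- read.table(file.path(in_dir, "smallrna_nat.tsv"), sep = "\t",
                     header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE)
    att_rows <- list()
    for (i in seq_len(nrow(pairs))) {
      pid <- paste0(pairs$sense_id[i], "|", pairs$antisense_id[i])
      block <- sr[sr$pair_id == pid, , drop = FALSE]
      if (nrow(block) != 2L) next
      scols <- setdiff(names(block), c("pair_id", "strand"))
      plus <- as.numeric(block[block$strand == "+", scols])
      minus <- as.numeric(block[block$strand == "-", scols])
      if (!all(c(pairs$sense_id[i], pairs$antisense_id[i]) %in% rownames(expr)))
        next
      att <- attribute_smallrna(plus, minus, depths[scols],
                                as.numeric(expr[pairs$sense_id[i], scols]),
                                as.numeric(expr[pairs$antisense_id[i], scols]),
                                pairs$sense_strand[i],
                                r_min = config$r_min, delta = config$delta)
      att_rows[[length(att_rows) + 1L]] <- data.frame(
        pairs[i, ], r_sense = att$r_sense, r_antisense = att$r_antisense,
        verdict = att$verdict, stringsAsFactors = FALSE)
    }
    att_tab <- if (length(att_rows)) do.call(rbind, att_rows) else
      cbind(pairs[0, ], r_sense = numeric(0), r_antisense = numeric(0),
            verdict = character(0))
    write.table(pairs, op("nat_pairs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(att_tab, op("nat_attribution.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$natpair <- list(n_pairs = nrow(pairs),
                            n_attributed = sum(att_tab$verdict != "ambiguous"))
    say("natpair: %d pairs, %d attributed", nrow(pairs),
        summary$natpair$n_attributed)
  }

  cfg_out <- config
  class(cfg_out) <- NULL
  jsonlite::write_json(cfg_out, op("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(summary, op("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, op("run.log"))
  invisible(summary)
}

.bed_total <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  sum(pmax(1, suppressWarnings(as.numeric(df[[5L]]))), na.rm = TRUE)
}

# peptide FASTA reader (amino-acid alphabet; no U->T normalisation)
.aa_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  setNames(toupper(as.character(ss)), ids)
}
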