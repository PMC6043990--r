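# Seeded synthetic-data generator: a toy genome with coding genes, antisense
# (cis-NAT) and intergenic noncoding loci, a two-tissue x five-timepoint
# count design with planted fold changes, 2P-Seq tag clusters at planted
# poly(A) sites (including dual-site APA loci), miRNA families with planted
# down-regulation, and degradome tag peaks at planted cleavage sites. All
# planted truth is returned (and written) alongside the data.

.ACGT <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")
.SENSE_CODONS <- local({
  all <- as.vector(outer(as.vector(outer(.ACGT, .ACGT, paste0)), .ACGT, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

.rand_dna <- function(n) paste(sample(.ACGT, n, replace = TRUE), collapse = "")

.revcomp <- function(s)
  paste(rev(.COMP[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")

# random CDS of n_aa amino acids (ATG + sense codons + stop), returned with
# its peptide
.rand_cds <- function(n_aa) {
  body <- paste(sample(.SENSE_CODONS, n_aa - 1L, replace = TRUE), collapse = "")
  cds <- paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L))
  pep <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                            no.init.codon = TRUE))
  pep <- sub("\\*$", "", pep)
  list(cds = cds, peptide = pep)
}

#' Simulation configuration
#'
#' Defaults describe a compact but complete world: a 500 kb chromosome with
#' 60 coding genes, 15 intergenic and 15 antisense noncoding loci (8
#' two-exon, giving a ~73% single-exon fraction), 4 dual-poly(A)-site loci,
#' 8 miRNAs of which 6 have planted degradome-supported targets, a 2 tissue
#' x 5 timepoint (0/1/3/5/7 d) negative-binomial count design with planted
#' log2 effects of 1.5-3, 2P-Seq tag jitter of 5 nt over a 0.2 tags/kb
#' background, and 60% of a target's degradome tags at the true cleavage
#' site.
#'
#' @param seed integer RNG seed.
#' @param n_coding_genes,n_intergenic_nc,n_antisense_nc,n_apa_loci,n_mirnas,n_true_targets,n_rhc locus/feature counts.
#' @param chrom_length chromosome length in bp.
#' @param tissues,timepoints,condition sample design.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline of expected
#'   counts.
#' @param dispersion negative-binomial size (Inf = Poisson).
#' @param de_fraction fraction of features with planted effects.
#' @param lfc_range planted |log2 fold change| range (min must be >= 1).
#' @param tag_jitter_sd 2P-Seq tag jitter (nt, Gaussian, integer-rounded).
#' @param background_tag_rate uniform background 2P-Seq tags per kb and
#'   strand.
#' @param apa_separation distance between dual poly(A) sites (nt).
#' @param polya_tags_per_site tags drawn around each planted site.
#' @param cleavage_fraction fraction of a target's degradome tags placed
#'   exactly at the planted cleavage site.
#' @param sample_depth sequencing depth per RNA-seq sample.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 42L, n_coding_genes = 60L,
                       n_intergenic_nc = 15L, n_antisense_nc = 15L,
                       n_apa_loci = 4L, n_mirnas = 8L, n_true_targets = 6L,
                       n_rhc = 7L, chrom_length = 500000L,
                       tissues = c("root", "shoot"),
                       timepoints = c(0L, 1L, 3L, 5L, 7L), condition = "-N",
                       baseline_meanlog = log(200), baseline_sdlog = 0.5,
                       dispersion = 80, de_fraction = 0.3,
                       lfc_range = c(1.5, 3), tag_jitter_sd = 5,
                       background_tag_rate = 0.2, apa_separation = 300L,
                       polya_tags_per_site = 200L, cleavage_fraction = 0.6,
                       sample_depth = 2e7) {
  cfg <- as.list(environment())
  counts <- c(n_coding_genes, n_intergenic_nc, n_antisense_nc, n_apa_loci,
              n_mirnas, n_true_targets, n_rhc)
  if (any(counts < 0L)) stop("locus counts must be >= 0")
  if (lfc_range[1L] < 1)
    stop("lfc_range minimum must be >= 1 so planted effects exceed the 2-fold call threshold")
  if (cleavage_fraction <= 0 || cleavage_fraction > 1)
    stop("cleavage_fraction must be in (0, 1]")
  if (n_true_targets > n_mirnas) stop("n_true_targets exceeds n_mirnas")
  if (n_apa_loci > n_intergenic_nc) stop("n_apa_loci exceeds n_intergenic_nc")
  if (n_coding_genes < n_true_targets + n_antisense_nc)
    stop("need n_coding_genes >= n_true_targets + n_antisense_nc")
  class(cfg) <- "sim_config"
  cfg
}

# mutate miRNA position `pos` into a mismatch (or G:U wobble) against the
# given site; the site is read 5'->3' and miRNA position i pairs site
# position L - i + 1.
.plant_mutation <- function(mirna, site, pos, kind) {
  L <- nchar(mirna)
  t <- substr(site, L - pos + 1L, L - pos + 1L)
  if (kind == "wobble") {
    new <- if (t == "T") "G" else if (t == "G") "T" else
      stop("wobble requires a T or G transcript base at the planted position")
  } else {
    forbid <- c(.COMP[[t]], if (t == "T") "G", if (t == "G") "T")
    new <- sample(setdiff(.ACGT, c(forbid, substr(mirna, pos, pos))), 1L)
  }
  substr(mirna, pos, pos) <- new
  mirna
}

# mismatch/wobble recipes realising the prescribed penalties exactly
# (positions chosen away from the 9-11 cleavage register)
.penalty_recipes <- list(
  `0` = list(),
  `1.5` = list(c(1L, "mismatch"), c(16L, "wobble")),
  `3` = list(c(5L, "mismatch"), c(1L, "mismatch")),
  `5` = list(c(5L, "mismatch"), c(13L, "mismatch"), c(1L, "mismatch")))

#' Generate the complete synthetic bundle with planted truth
#'
#' Deterministic given the config seed. When `out_dir` is supplied the
#' bundle is also written to disk in the formats the IO layer reads (FASTA,
#' GTF, BED6, TSV), together with truth tables.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return a list with the genome, reference/assembled transcript models,
#'   count matrices, tag sets, sequences, and a `truth` list of planted
#'   ground-truth tables.
#' @export
simulate_nstarve <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom <- "Chr01"
  n_cod <- config$n_coding_genes
  n_int <- config$n_intergenic_nc
  n_anti <- config$n_antisense_nc
  n_slots <- n_cod + n_int
  slot_w <- config$chrom_length %/% n_slots
  if (slot_w < 4000L)
    stop("chromosome too short for the requested locus counts")
  genome <- .rand_dna(config$chrom_length)

  exon_rows <- list()
  paint_jobs <- list()
  add_exons <- function(tid, gid, starts, ends, strand, biotype) {
    exon_rows[[length(exon_rows) + 1L]] <<- data.frame(
      transcript_id = tid, gene_id = gid, chrom = chrom, start = starts,
      end = ends, strand = strand, biotype = biotype,
      stringsAsFactors = FALSE)
  }
  paint <- function(starts, ends, strand, txseq) {
    gs <- if (strand == "+") txseq else .revcomp(txseq)
    off <- 0L
    for (k in seq_along(starts)) {
      w <- ends[k] - starts[k]
      substr(genome, starts[k] + 1L, ends[k]) <<-
        substr(gs, off + 1L, off + w)
      off <- off + w
    }
  }

  # --- coding genes -------------------------------------------------------
  coding_pep <- character(n_cod)
  target_sites <- list()
  mirna_ids <- sprintf("mir%03d", seq_len(config$n_mirnas))
  target_pen <- rep(c(0, 1.5, 3, 5), length.out = config$n_true_targets)
  mirnas <- setNames(character(config$n_mirnas), mirna_ids)
  coding_ids <- sprintf("CG%03d", seq_len(n_cod))
  for (i in seq_len(n_cod)) {
    n_aa <- sample(80:200, 1L)
    cds <- .rand_cds(n_aa)
    coding_pep[i] <- cds$peptide
    utr5 <- .rand_dna(50L)
    utr3 <- .rand_dna(150L)
    txseq <- paste0(utr5, cds$cds, utr3)
    if (i <= config$n_true_targets) {
      # plant a 21-nt miRNA complementary site in the 3' UTR
      site <- .rand_dna(21L)
      # guarantee wobble-capable bases where the recipes need them
      substr(site, 21L - 16L + 1L, 21L - 16L + 1L) <- "T"
      off <- nchar(utr5) + nchar(cds$cds) + 30L  # 1-based site start
      substr(txseq, off, off + 20L) <- site
      mir <- .revcomp(site)
      for (mut in .penalty_recipes[[as.character(target_pen[i])]])
        mir <- .plant_mutation(mir, site, as.integer(mut[1L]), mut[2L])
      mirnas[i] <- mir
      target_sites[[length(target_sites) + 1L]] <- data.frame(
        mirna_id = mirna_ids[i], transcript_id = paste0(coding_ids[i], ".1"),
        site_start = off, site_end = off + 20L, penalty = target_pen[i],
        cleavage_site = off + 21L - 10L, stringsAsFactors = FALSE)
    }
    strand <- if (i %% 2L == 0L) "-" else "+"
    cut <- 50L + nchar(cds$cds) %/% 2L   # split inside the CDS
    g0 <- (i - 1L) * slot_w + 500L
    w1 <- cut; w2 <- nchar(txseq) - cut
    starts <- c(g0, g0 + w1 + 200L)
    ends <- c(g0 + w1, g0 + w1 + 200L + w2)
    if (strand == "-") {  # keep exon order genomic; transcript reads right->left
      w <- c(w2, w1)
      starts <- c(g0, g0 + w[1L] + 200L)
      ends <- c(g0 + w[1L], g0 + w[1L] + 200L + w[2L])
    }
    add_exons(paste0(coding_ids[i], ".1"), coding_ids[i], starts, ends,
              strand, "coding")
    paint(starts, ends, strand, txseq)
  }
  for (i in seq_len(config$n_mirnas - config$n_true_targets))
    mirnas[config$n_true_targets + i] <- .rand_dna(21L)

  # --- noncoding loci -----------------------------------------------------
  rhc_pep <- character(0L)
  nc_truth <- list()
  novel_count <- 0L
  n_rhc_int <- min(config$n_rhc, 3L)
  n_rhc_anti <- config$n_rhc - n_rhc_int
  add_noncoding <- function(starts, ends, strand, txseq, context, cls) {
    novel_count <<- novel_count + 1L
    tid <- sprintf("NOVEL%03d.1", novel_count)
    gid <- sprintf("NOVEL%03d", novel_count)
    add_exons(tid, gid, starts, ends, strand, "unknown")
    paint(starts, ends, strand, txseq)
    nc_truth[[length(nc_truth) + 1L]] <<- data.frame(
      transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
      start = min(starts), end = max(ends), context = context,
      coding_class = cls, n_exons = length(starts),
      stringsAsFactors = FALSE)
    tid
  }
  # intergenic: slots after the coding genes; 8 two-exon RLC, then single-exon
  # RLC, then single-exon RHC (exact short CDS of a taxon-internal peptide)
  n_int_two <- min(8L, max(0L, n_int - n_rhc_int))
  for (j in seq_len(n_int)) {
    g0 <- (n_cod + j - 1L) * slot_w + 500L
    strand <- if (j %% 2L == 0L) "-" else "+"
    if (j <= n_int_two) {
      txseq <- .rand_dna(600L)
      starts <- c(g0, g0 + 300L + 150L)
      ends <- c(g0 + 300L, g0 + 300L + 150L + 300L)
      add_noncoding(starts, ends, strand, txseq, "intergenic", "RLC")
    } else if (j <= n_int - n_rhc_int) {
      txseq <- .rand_dna(600L)
      add_noncoding(g0, g0 + 600L, strand, txseq, "intergenic", "RLC")
    } else {
      cds <- .rand_cds(66L)
      rhc_pep <- c(rhc_pep, cds$peptide)
      txseq <- cds$cds  # 201 nt: the exact CDS of a short internal peptide
      add_noncoding(g0, g0 + nchar(txseq), strand, txseq, "intergenic", "RHC")
    }
  }
  # antisense: hosted on the last n_anti coding genes (disjoint from the
  # degradome-target genes); overlap the terminal 100 nt of the host 3' UTR
  # and extend beyond the gene
  anti_hosts <- (n_cod - n_anti + 1L):n_cod
  nat_truth <- list()
  for (j in seq_along(anti_hosts)) {
    i <- anti_hosts[j]
    host_rows <- which(vapply(exon_rows, function(e)
      e$gene_id[1L] == coding_ids[i], logical(1L)))
    he <- exon_rows[[host_rows[1L]]]
    hstrand <- he$strand[1L]
    strand <- if (hstrand == "+") "-" else "+"
    is_rhc <- j > n_anti - n_rhc_anti
    txseq <- if (is_rhc) {
      cds <- .rand_cds(66L)
      rhc_pep <- c(rhc_pep, cds$peptide)
      cds$cds
    } else .rand_dna(500L)
    w <- nchar(txseq)
    if (hstrand == "+") {
      g_end <- max(he$end)
      starts <- g_end - 100L; ends <- starts + w
    } else {
      g_start <- min(he$start)
      ends <- g_start + 100L; starts <- ends - w
    }
    tid <- add_noncoding(starts, ends, strand, txseq, "cis-NAT",
                         if (is_rhc) "RHC" else "RLC")
    nat_truth[[j]] <- data.frame(
      sense_id = paste0(coding_ids[i], ".1"), antisense_id = tid,
      sense_strand = hstrand,
      generating = if (j %% 2L == 1L) "sense" else "antisense",
      stringsAsFactors = FALSE)
  }
  nc_truth <- do.call(rbind, nc_truth)
  nat_truth <- do.call(rbind, nat_truth)

  exons <- do.call(rbind, exon_rows)
  reference <- transcript_models(exons[exons$biotype == "coding", , drop = FALSE])
  assembled <- transcript_models(exons)
  genome_set <- setNames(genome, chrom)
  tx_seqs <- tx_sequences(assembled, genome_set)

  # --- expression counts --------------------------------------------------
  info <- tx_summary(assembled)
  features <- info$transcript_id
  lengths <- setNames(info$exonic_length, features)
  samples <- as.vector(outer(config$tissues, config$timepoints,
                             function(ti, tp) sprintf("%s_%s_%dd", ti,
                                                      config$condition, tp)))
  samples <- sort(samples)
  skey <- parse_sample_key(samples)
  baseline <- setNames(rlnorm(length(features), config$baseline_meanlog,
                              config$baseline_sdlog), features)
  de_feat <- sample(features, round(config$de_fraction * length(features)))
  # NAT partners are always planted DE so their profiles vary across samples
  de_feat <- union(de_feat, c(nat_truth$sense_id, nat_truth$antisense_id))
  lfc <- matrix(0, nrow = length(features), ncol = length(config$tissues),
                dimnames = list(features, config$tissues))
  for (ti in config$tissues)
    lfc[de_feat, ti] <- sample(c(-1, 1), length(de_feat), replace = TRUE) *
      runif(length(de_feat), config$lfc_range[1L], config$lfc_range[2L])
  mu <- matrix(0, length(features), length(samples),
               dimnames = list(features, samples))
  for (s in seq_along(samples)) {
    eff <- if (skey$timepoint[s] > 0L) 2^lfc[, skey$tissue[s]] else 1
    mu[, s] <- baseline * eff
  }
  draw <- function(mu_vec) {
    if (is.infinite(config$dispersion)) rpois(length(mu_vec), mu_vec)
    else rnbinom(length(mu_vec), size = config$dispersion, mu = mu_vec)
  }
  counts <- matrix(0L, length(features), length(samples),
                   dimnames = list(features, samples))
  for (s in seq_along(samples)) counts[, s] <- draw(mu[, s])
  depths <- setNames(rep(config$sample_depth, length(samples)), samples)

  # --- 2P-Seq tags --------------------------------------------------------
  polya_truth <- list()
  tag_pos <- integer(0L); tag_strand <- character(0L)
  apa_tx <- nc_truth$transcript_id[nc_truth$context == "intergenic" &
                                     nc_truth$n_exons == 1L &
                                     nc_truth$coding_class == "RLC"]
  apa_tx <- head(apa_tx, config$n_apa_loci)
  for (k in seq_len(nrow(nc_truth))) {
    tid <- nc_truth$transcript_id[k]
    tinfo <- info[info$transcript_id == tid, ]
    sites <- tinfo$three_prime
    if (tid %in% apa_tx) {
      sites <- c(sites, if (tinfo$strand == "+")
        sites - config$apa_separation else sites + config$apa_separation)
    }
    n_site_tags <- c(config$polya_tags_per_site,
                     round(config$polya_tags_per_site * 0.6))
    for (si in seq_along(sites)) {
      n <- n_site_tags[si]
      tag_pos <- c(tag_pos, sites[si] +
                     as.integer(round(rnorm(n, 0, config$tag_jitter_sd))))
      tag_strand <- c(tag_strand, rep(tinfo$strand, n))
      polya_truth[[length(polya_truth) + 1L]] <- data.frame(
        transcript_id = tid, site = sites[si], proximal = si > 1L,
        n_tags = n, stringsAsFactors = FALSE)
    }
  }
  n_bg <- round(config$background_tag_rate * config$chrom_length / 1000)
  for (st in c("+", "-")) {
    tag_pos <- c(tag_pos, sample.int(config$chrom_length, n_bg) - 1L)
    tag_strand <- c(tag_strand, rep(st, n_bg))
  }
  tag_pos <- pmax(0L, pmin(config$chrom_length - 1L, tag_pos))
  tags_df <- data.frame(chrom = chrom, position = tag_pos,
                        strand = tag_strand, count = 1L,
                        stringsAsFactors = FALSE)
  tags <- tag_set(tags_df, library_depth = nrow(tags_df))
  polya_truth <- do.call(rbind, polya_truth)

  # --- degradome tags (transcript coordinates) ----------------------------
  target_truth <- if (length(target_sites)) do.call(rbind, target_sites) else
    data.frame(mirna_id = character(), transcript_id = character(),
               site_start = integer(), site_end = integer(),
               penalty = numeric(), cleavage_site = integer())
  deg_rows <- list()
  for (k in seq_len(nrow(target_truth))) {
    tid <- target_truth$transcript_id[k]
    len <- lengths[[tid]]
    total <- 50L
    at_site <- round(config$cleavage_fraction * total)
    other <- sample(setdiff(seq_len(len), target_truth$cleavage_site[k]),
                    total - at_site, replace = TRUE)
    deg_rows[[length(deg_rows) + 1L]] <- data.frame(
      chrom = tid,
      position = c(rep(target_truth$cleavage_site[k], at_site), other) - 1L,
      strand = "+", count = 1L, stringsAsFactors = FALSE)
  }
  # low-level background on a few non-target coding transcripts
  bg_tx <- setdiff(paste0(coding_ids, ".1"), target_truth$transcript_id)
  for (tid in head(bg_tx, 4L)) {
    deg_rows[[length(deg_rows) + 1L]] <- data.frame(
      chrom = tid, position = sample.int(lengths[[tid]], 10L) - 1L,
      strand = "+", count = 1L, stringsAsFactors = FALSE)
  }
  deg_df <- do.call(rbind, deg_rows)
  degradome <- tag_set(deg_df, library_depth = sum(deg_df$count))

  # --- small RNAs ---------------------------------------------------------
  # miRNA counts: true miRNAs are monotonically down-regulated with time
  mir_lfc <- setNames(rep(0, config$n_mirnas), mirna_ids)
  mir_lfc[seq_len(config$n_true_targets)] <-
    -runif(config$n_true_targets, config$lfc_range[1L], config$lfc_range[2L])
  tp_rank <- match(skey$timepoint, sort(unique(skey$timepoint))) - 1L
  mir_mu <- outer(setNames(rlnorm(config$n_mirnas, log(500), 0.3), mirna_ids),
                  rep(1, length(samples)))
  colnames(mir_mu) <- samples
  for (s in seq_along(samples))
    mir_mu[, s] <- mir_mu[, s] *
      2^(mir_lfc * tp_rank[s] / max(tp_rank))
  mir_counts <- matrix(0L, config$n_mirnas, length(samples),
                       dimnames = list(mirna_ids, samples))
  for (s in seq_along(samples)) mir_counts[, s] <- draw(mir_mu[, s])
  # NAT-overlap small RNAs: signal on the generating partner's strand tracks
  # that partner's expression; the other strand carries flat background
  nat_sr <- list()
  for (k in seq_len(nrow(nat_truth))) {
    gen_sense <- nat_truth$generating[k] == "sense"
    gen_id <- if (gen_sense) nat_truth$sense_id[k] else nat_truth$antisense_id[k]
    gen_strand <- if (gen_sense) nat_truth$sense_strand[k] else
      setdiff(c("+", "-"), nat_truth$sense_strand[k])
    for (st in c("+", "-")) {
      mu_s <- if (st == gen_strand) 0.3 * mu[gen_id, ] else rep(2, length(samples))
      nat_sr[[length(nat_sr) + 1L]] <- data.frame(
        pair_id = paste0(nat_truth$sense_id[k], "|", nat_truth$antisense_id[k]),
        strand = st, t(draw(mu_s)), check.names = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  nat_sr <- do.call(rbind, nat_sr)
  names(nat_sr)[-(1:2)] <- samples

  truth <- list(loci = nc_truth, polya = polya_truth,
                de = data.frame(feature = rep(rownames(lfc), ncol(lfc)),
                                tissue = rep(colnames(lfc), each = nrow(lfc)),
                                lfc = as.vector(lfc))[as.vector(lfc) != 0, ],
                targets = target_truth,
                mirna_decoys = if (config$n_mirnas > config$n_true_targets)
                  mirna_ids[(config$n_true_targets + 1L):config$n_mirnas]
                else character(0L),
                nat_pairs = nat_truth, apa_loci = apa_tx)
  proteins_full <- setNames(c(coding_pep, rhc_pep),
                            c(coding_ids, sprintf("ORYPEP%02d", seq_along(rhc_pep))))
  proteins_excl <- proteins_full[coding_ids]
  out <- list(config = config, genome = genome_set, reference = reference,
              assembled = assembled, tx_seqs = tx_seqs, counts = counts,
              depths = depths, lengths = lengths, tags = tags,
              degradome = degradome, mirnas = mirnas,
              proteins_full = proteins_full, proteins_excl = proteins_excl,
              mirna_counts = mir_counts, nat_smallrna = nat_sr,
              truth = truth)
  if (!is.null(out_dir)) write_bundle(out, out_dir)
  out
}

#' Write a simulated bundle to disk
#'
#' Emits the formats the IO layer reads: genome FASTA, reference/assembled
#' GTF, 2P-Seq and degradome BED6, count/length TSVs, peptide FASTAs, and
#' truth tables.
#'
#' @param sim result of [simulate_nstarve()].
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_fasta(sim$genome, p("genome.fa"))
  write_annotation(sim$reference, p("reference.gtf"))
  write_annotation(sim$assembled, p("assembled.gtf"))
  write_matrix(sim$counts, p("counts.tsv"))
  write.table(data.frame(feature_id = names(sim$lengths),
                         length = unname(sim$lengths)),
              p("lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(sim$depths),
                         depth = unname(sim$depths)),
              p("depths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_tags(sim$tags, p("tags_2pseq.bed"))
  write_tags(sim$degradome, p("degradome.bed"))
  write_fasta(sim$mirnas, p("mirnas.fa"))
  write_fasta(sim$proteins_full, p("proteins_full.fa"))
  write_fasta(sim$proteins_excl, p("proteins_excl.fa"))
  write_matrix(sim$mirna_counts, p("smallrna_mirna_counts.tsv"))
  write.table(sim$nat_smallrna, p("smallrna_nat.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in c("loci", "polya", "de", "targets", "nat_pairs"))
    write.table(sim$truth[[nm]], p(paste0("truth_", nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  writeLines(c(paste("apa_locus", sim$truth$apa_loci, sep = "\t"),
               paste("decoy_mirna", sim$truth$mirna_decoys, sep = "\t")),
             p("truth_misc.tsv"))
  invisible(out_dir)
}

#' Simulate NAT pairs with a known small-RNA generating strand
#'
#' A focused simulator for validating strand attribution: each pair gets
#' independent log-normal expression profiles for the sense and antisense
#' partner over the sample design, and small-RNA counts on the generating
#' partner's strand proportional to that partner's expression under
#' log-normal noise, with flat background on the other strand.
#'
#' @param n_pairs number of pairs.
#' @param n_samples samples per pair (default 10: 2 tissues x 5 timepoints).
#' @param noise_sd log-scale multiplicative noise on the small-RNA signal
#'   (default 0.2).
#' @param depth small-RNA library depth.
#' @param seed RNG seed.
#' @return data.frame with one row per pair: truth and inputs suitable for
#'   [attribute_smallrna()], plus the attribution verdict and correlations.
#' @export
simulate_nat_attribution <- function(n_pairs = 100L, n_samples = 10L,
                                     noise_sd = 0.2, depth = 2e7,
                                     seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(n_pairs), function(k) {
    sense_strand <- sample(c("+", "-"), 1L)
    gen_sense <- runif(1) < 0.5
    sense_fpkm <- rlnorm(n_samples, log(20), 1)
    anti_fpkm <- rlnorm(n_samples, log(5), 1)
    gen_fpkm <- if (gen_sense) sense_fpkm else anti_fpkm
    gen_counts <- round(gen_fpkm * 50 * exp(rnorm(n_samples, 0, noise_sd)))
    bg_counts <- rpois(n_samples, 3)
    gen_strand <- if (gen_sense) sense_strand else setdiff(c("+", "-"), sense_strand)
    plus <- if (gen_strand == "+") gen_counts else bg_counts
    minus <- if (gen_strand == "-") gen_counts else bg_counts
    att <- attribute_smallrna(plus, minus, depth, sense_fpkm, anti_fpkm,
                              sense_strand)
    data.frame(pair = k, truth = if (gen_sense) "sense-derived" else
      "antisense-derived", verdict = att$verdict,
      r_sense = att$r_sense, r_antisense = att$r_antisense,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
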