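# Expression normalisation (FPKM / RP40M), fold changes, >= 2-fold DE calls,
# tissue concordance, and cross-condition set intersections.

#' FPKM normalisation
#'
#' FPKM(f, s) = count(f, s) / (exonic length of f in kb * depth of s in
#' millions): fragments per kilobase of exon per million mapped fragments.
#'
#' @param counts non-negative count matrix (features x samples).
#' @param lengths named vector of exonic lengths in nt covering every row.
#' @param depths named (or positionally matched) vector of per-sample total
#'   mapped fragments.
#' @return FPKM matrix with attributes `unit`, `depths`, `lengths`.
#' @export
fpkm <- function(counts, lengths, depths) {
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("missing exonic length for feature(s): ", paste(head(miss, 5L), collapse = ", "))
  lens <- lengths[rownames(counts)]
  if (any(lens <= 0)) stop("exonic lengths must be > 0")
  depths <- .match_depths(counts, depths)
  if (any(depths <= 0)) stop("depths must be > 0")
  m <- counts / (outer(lens / 1e3, depths / 1e6))
  structure(m, unit = "FPKM", depths = depths, lengths = lens)
}

#' RP40M normalisation for small-RNA counts
#'
#' RP40M(f, s) = count(f, s) * 4e7 / depth(s): reads per 40 million sequenced
#' reads, the conventional unit for small-RNA libraries.
#'
#' @param counts count matrix.
#' @param depths per-sample sequencing depths.
#' @return RP40M matrix with attributes `unit` and `depths`.
#' @export
rp40m <- function(counts, depths) {
  depths <- .match_depths(counts, depths)
  if (any(depths <= 0)) stop("depths must be > 0")
  m <- sweep(counts, 2L, 4e7 / depths, `*`)
  structure(m, unit = "RP40M", depths = depths)
}

.match_depths <- function(counts, depths) {
  if (!is.null(names(depths))) {
    miss <- setdiff(colnames(counts), names(depths))
    if (length(miss)) stop("missing depth for sample(s): ", paste(miss, collapse = ", "))
    depths <- depths[colnames(counts)]
  } else if (length(depths) == 1L) {
    depths <- rep(depths, ncol(counts))
  }
  if (length(depths) != ncol(counts)) stop("depths do not match samples")
  unname(depths)
}

#' Per-feature log2 fold change for one contrast
#'
#' log2((a + pseudocount) / (b + pseudocount)), antisymmetric under swapping
#' the contrast.
#'
#' @param expr expression matrix (any unit).
#' @param sample_a,sample_b column names of the contrast (a over b).
#' @param pseudocount stabilising offset in expression units (default 0.1).
#' @return named numeric vector of log2 ratios.
#' @export
log2fc <- function(expr, sample_a, sample_b, pseudocount = 0.1) {
  if (!all(c(sample_a, sample_b) %in% colnames(expr)))
    stop("contrast samples not found in expression matrix")
  lfc <- log2((expr[, sample_a] + pseudocount) / (expr[, sample_b] + pseudocount))
  setNames(as.numeric(lfc), rownames(expr))
}

.direction <- function(lfc) {
  ifelse(lfc >= 1, "up", ifelse(lfc <= -1, "down", "unchanged"))
}

#' Call >= 2-fold differential expression over a set of contrasts
#'
#' A feature is called `up` (`down`) in a contrast when |log2 fold change|
#' >= 1 and the larger of the two expression values reaches `min_expr_floor`;
#' otherwise `unchanged`. The responsive set is the union of features changed
#' in at least one contrast.
#'
#' @param expr expression matrix (FPKM or RP40M).
#' @param contrasts data.frame with columns `name`, `sample_a`, `sample_b`.
#' @param min_expr_floor expression floor (default 1.0).
#' @param pseudocount passed to [log2fc()].
#' @return list with `calls` (long data.frame: feature, contrast, log2fc,
#'   direction) and `responsive` (character vector of feature ids).
#' @export
call_de <- function(expr, contrasts, min_expr_floor = 1.0, pseudocount = 0.1) {
  stopifnot(all(c("name", "sample_a", "sample_b") %in% names(contrasts)))
  calls <- do.call(rbind, lapply(seq_len(nrow(contrasts)), function(i) {
    a <- contrasts$sample_a[i]; b <- contrasts$sample_b[i]
    lfc <- log2fc(expr, a, b, pseudocount)
    expressed <- pmax(expr[, a], expr[, b]) >= min_expr_floor
    dir <- .direction(lfc)
    dir[!expressed] <- "unchanged"
    data.frame(feature = rownames(expr), contrast = contrasts$name[i],
               log2fc = as.numeric(lfc), direction = dir,
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  responsive <- sort(unique(calls$feature[calls$direction != "unchanged"]))
  list(calls = calls, responsive = responsive)
}

#' Classify tissue concordance of a (root, shoot) direction pair
#'
#' Deterministic truth table on the per-tissue DE directions at one contrast:
#' (up, up) -> `concordant-up`; (down, down) -> `concordant-down`;
#' (up, down) or (down, up) -> `discordant`; exactly one changed ->
#' `root-only` / `shoot-only`; neither -> `none`.
#'
#' @param root_dir,shoot_dir character vectors in
#'   `{"up", "down", "unchanged"}`, aligned by feature.
#' @return character vector of concordance labels.
#' @export
concordance_label <- function(root_dir, shoot_dir) {
  stopifnot(length(root_dir) == length(shoot_dir))
  ok <- c("up", "down", "unchanged")
  if (!all(root_dir %in% ok) || !all(shoot_dir %in% ok))
    stop("directions must be 'up', 'down' or 'unchanged'")
  out <- rep("none", length(root_dir))
  out[root_dir == "up" & shoot_dir == "up"] <- "concordant-up"
  out[root_dir == "down" & shoot_dir == "down"] <- "concordant-down"
  opp <- (root_dir == "up" & shoot_dir == "down") |
    (root_dir == "down" & shoot_dir == "up")
  out[opp] <- "discordant"
  ronly <- root_dir != "unchanged" & shoot_dir == "unchanged"
  sonly <- root_dir == "unchanged" & shoot_dir != "unchanged"
  out[ronly] <- "root-only"
  out[sonly] <- "shoot-only"
  out
}

#' Tissue concordance of DE calls between root and shoot
#'
#' @param root_calls,shoot_calls `calls` data.frames from [call_de()] for the
#'   matching contrast in each tissue.
#' @param contrast contrast name present in both call sets.
#' @return data.frame: feature, contrast, root_direction, shoot_direction,
#'   label.
#' @export
concordance <- function(root_calls, shoot_calls, contrast) {
  r <- root_calls[root_calls$contrast == contrast, ]
  s <- shoot_calls[shoot_calls$contrast == contrast, ]
  feats <- sort(union(r$feature, s$feature))
  rd <- setNames(rep("unchanged", length(feats)), feats)
  sd <- rd
  rd[r$feature] <- r$direction
  sd[s$feature] <- s$direction
  data.frame(feature = feats, contrast = contrast,
             root_direction = unname(rd), shoot_direction = unname(sd),
             label = concordance_label(unname(rd), unname(sd)),
             stringsAsFactors = FALSE)
}

#' Venn-region counts for responsive-feature sets across conditions
#'
#' Exact set algebra over 1-3 named feature sets: returns the per-feature
#' membership table and the count of every Venn region (each region keyed by
#' the sets a feature belongs to, e.g. `"A&B"`).
#'
#' @param sets named list of character vectors.
#' @return list with `membership` (logical data.frame, one column per set)
#'   and `regions` (named integer vector of exclusive region sizes, plus
#'   pairwise/overall intersection sizes in `intersections`).
#' @export
intersect_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  univ <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  member <- matrix(member, nrow = length(univ),
                   dimnames = list(univ, names(sets)))
  pattern <- apply(member, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  all_patterns <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&", simplify = TRUE)))
  regions <- setNames(integer(length(all_patterns)), all_patterns)
  tb <- table(pattern)
  regions[names(tb)] <- as.integer(tb)
  inters <- setNames(vapply(all_patterns, function(p) {
    ids <- strsplit(p, "&", fixed = TRUE)[[1L]]
    length(Reduce(intersect, sets[ids]))
  }, integer(1L)), all_patterns)
  list(membership = as.data.frame(member), regions = regions,
       intersections = inters)
}

#' Default N-starvation contrast table
#'
#' Each non-zero timepoint versus day 0 within one tissue, for sample keys of
#' the form `tissue_condition_timepoint`.
#'
#' @param tissue tissue name (e.g. `"root"`).
#' @param condition condition label (default `"-N"`).
#' @param timepoints non-zero timepoints in days.
#' @return contrast data.frame for [call_de()].
#' @export
starvation_contrasts <- function(tissue, condition = "-N",
                                 timepoints = c(1, 3, 5, 7)) {
  data.frame(
    name = sprintf("%s_%s_%dd_vs_0d", tissue, condition, timepoints),
    sample_a = sprintf("%s_%s_%dd", tissue, condition, timepoints),
    sample_b = sprintf("%s_%s_0d", tissue, condition),
    stringsAsFactors = FALSE)
}
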