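# Degradome-supported miRNA target calling: penalty-scored miRNA:transcript
# alignment (plant-style complementarity scoring), cleavage-site prediction
# opposite miRNA positions 10-11, degradome peak categorisation, RPM /
# percent-of-reads statistics, and dinucleotide-shuffle permutation p-values.

.BASES <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# pairing penalty lookup: rows = miRNA base, cols = transcript base.
# match (Watson-Crick) 0, G:U wobble 0.5, mismatch 1.
.pen_lookup <- local({
  m <- matrix(1, 4L, 4L, dimnames = list(names(.BASES), names(.BASES)))
  m["A", "T"] <- 0; m["T", "A"] <- 0; m["G", "C"] <- 0; m["C", "G"] <- 0
  m["G", "T"] <- 0.5; m["T", "G"] <- 0.5
  m
})

.encode <- function(seq) {
  v <- .BASES[strsplit(seq, "", fixed = TRUE)[[1L]]]
  if (anyNA(v)) stop("sequence alphabet outside ACGT (after U->T normalisation)")
  unname(v)
}

# position weight: penalties doubled at miRNA positions 2-13 (5'-core)
.pos_weight <- function(L) ifelse(seq_len(L) >= 2L & seq_len(L) <= 13L, 2, 1)

#' Align a miRNA against a transcript with penalty scoring
#'
#' Scans every ungapped register and every single-bulge (1-2 nt, in either
#' strand) placement of the reverse-complemented miRNA along the transcript.
#' Position penalties: Watson-Crick match 0, G:U wobble 0.5, mismatch 1.0,
#' each bulged nucleotide 1.0; all penalties are doubled at miRNA positions
#' 2-13 counted from the miRNA 5' end (a bulged transcript nucleotide takes
#' the position of the next miRNA nucleotide toward the 3' end). Sites are
#' reported when the total penalty is at most `max_penalty`, sorted by
#' penalty then coordinate. The predicted cleavage site is the transcript
#' nucleotide paired with miRNA position 10 (`NA` when a miRNA bulge covers
#' position 10).
#'
#' @param mirna_seq miRNA sequence, 5' to 3', 19-24 nt (U tolerated).
#' @param transcript_seq transcript sequence, 5' to 3'.
#' @param max_penalty maximum reported penalty (default 5.0).
#' @param max_bulge maximum bulge size in nt (default 2; 0 disables bulges).
#' @return data.frame: `site_start`, `site_end` (1-based inclusive transcript
#'   coordinates), `penalty`, `cleavage_site`, `bulge` (`"none"`,
#'   `"transcript"`, `"mirna"`), `bulge_len`.
#' @export
align_mirna <- function(mirna_seq, transcript_seq, max_penalty = 5.0,
                        max_bulge = 2L) {
  mirna_seq <- chartr("Uu", "Tt", mirna_seq)
  mirna_seq <- toupper(mirna_seq)
  transcript_seq <- toupper(chartr("Uu", "Tt", transcript_seq))
  L <- nchar(mirna_seq)
  if (L < 19L || L > 24L)
    stop("miRNA length must be 19-24 nt, got ", L)
  m <- .encode(mirna_seq)
  t <- .encode(transcript_seq)
  n <- length(t)
  empty <- data.frame(site_start = integer(), site_end = integer(),
                      penalty = numeric(), cleavage_site = integer(),
                      bulge = character(), bulge_len = integer())
  if (n < L) return(empty)
  w <- .pos_weight(L)
  bp <- function(j) if (j >= 2L && j <= 13L) 2 else 1  # per-bulged-nt penalty
  # penmat[i, p]: weighted penalty of pairing miRNA position i with
  # transcript position p, padded 2 columns each side (pad value 0: padded
  # entries only ever cancel in the bulge decompositions below).
  pad <- 2L
  penmat <- matrix(0, nrow = L, ncol = n + 2L * pad)
  for (i in seq_len(L))
    penmat[i, pad + seq_len(n)] <- w[i] * .pen_lookup[m[i], t]
  # register grid (ungapped): s = 1 .. n - L + 1, extended by pad each side.
  # U[i, s] = penmat[i, s + L - i]; P = column-wise cumulative sums over i.
  s_grid <- (1L - pad):(n - L + 1L + pad)
  U <- matrix(0, nrow = L, ncol = length(s_grid))
  for (i in seq_len(L))
    U[i, ] <- penmat[i, pad + s_grid + L - i]
  P <- apply(U, 2L, cumsum)
  if (L == 1L) P <- matrix(P, nrow = 1L)
  gidx <- function(s) s + pad  # register -> column of P
  Ttot <- P[L, ]
  out <- list()
  add <- function(s, site_len, pen, cleav, bulge, blen) {
    keep <- pen <= max_penalty + 1e-9
    if (!any(keep)) return()
    out[[length(out) + 1L]] <<- data.frame(
      site_start = s[keep], site_end = s[keep] + site_len - 1L,
      penalty = pen[keep], cleavage_site = cleav[keep],
      bulge = bulge, bulge_len = blen, stringsAsFactors = FALSE)
  }
  # ungapped
  s <- seq_len(n - L + 1L)
  add(s, L, Ttot[gidx(s)], s + L - 10L, "none", 0L)
  if (max_bulge >= 1L) {
    for (b in seq_len(max_bulge)) {
      # transcript bulge of b nt between miRNA positions k and k+1
      if (n >= L + b) {
        s <- seq_len(n - L - b + 1L)
        for (k in seq_len(L - 1L)) {
          pen <- Ttot[gidx(s)] + P[k, gidx(s + b)] - P[k, gidx(s)] +
            b * bp(k + 1L)
          cleav <- if (k >= 10L) s + L + b - 10L else s + L - 10L
          add(s, L + b, pen, cleav, "transcript", b)
        }
      }
      # miRNA bulge: positions k+1 .. k+b unpaired (internal)
      if (L - b >= 2L && n >= L - b) {
        s <- seq_len(n - (L - b) + 1L)
        for (k in seq_len(L - b - 1L)) {
          bulge_pen <- sum(vapply((k + 1L):(k + b), bp, numeric(1L)))
          pen <- P[k, gidx(s - b)] + Ttot[gidx(s)] - P[k + b, gidx(s)] +
            bulge_pen
          cleav <- if (k >= 10L) s + L - b - 10L
          else if (k + b < 10L) s + L - 10L
          else rep(NA_integer_, length(s))
          add(s, L - b, pen, cleav, "mirna", b)
        }
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  # one row per distinct site interval: keep the minimum-penalty explanation
  # (ungapped preferred on ties)
  res <- res[order(res$penalty, res$bulge != "none", res$site_start), ,
             drop = FALSE]
  res <- res[!duplicated(res[, c("site_start", "site_end")]), , drop = FALSE]
  res <- res[order(res$penalty, res$site_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predicted cleavage position of an alignment
#'
#' The transcript nucleotide paired with miRNA nucleotide 10 (counted from
#' the miRNA 5' end), reported 1-based from the transcript 5' end. An
#' alignment whose bulge covers miRNA position 10 is rejected.
#'
#' @param alignment one row of an [align_mirna()] result.
#' @return integer transcript position.
#' @export
predict_cleavage <- function(alignment) {
  if (nrow(alignment) != 1L) stop("expected a single alignment row")
  if (is.na(alignment$cleavage_site))
    stop("alignment bulged at miRNA position 10: no cleavage prediction")
  alignment$cleavage_site
}

#' Categorise a degradome peak at a predicted cleavage site
#'
#' CleaveLand-style categories on raw per-position counts: no reads at the
#' site -> no call (`NA`); exactly 1 read -> category 4; more than 1 read but
#' at most the transcript median of positive positions -> 3; above the median
#' but below the maximum -> 2; equal to a non-unique maximum -> 1; the unique
#' maximum -> 0.
#'
#' @param profile data.frame with columns `position` (1-based transcript nt)
#'   and `count` for one transcript.
#' @param site 1-based transcript position.
#' @return integer category 0-4, or `NA` when no reads support the site.
#' @export
categorize <- function(profile, site) {
  if (!nrow(profile)) return(NA_integer_)
  cnt <- profile$count[match(site, profile$position)]
  if (is.na(cnt) || cnt == 0L) return(NA_integer_)
  if (cnt == 1L) return(4L)
  pos <- profile$count[profile$count > 0L]
  mx <- max(pos)
  if (cnt == mx) {
    if (sum(pos == mx) > 1L) return(1L) else return(0L)
  }
  if (cnt > median(pos)) return(2L)
  3L
}

# Altschul-Erickson dinucleotide shuffle: permutes a sequence uniformly
# among those with identical dinucleotide composition (and first/last base).
.dinuc_shuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 3L) return(seq)
  verts <- unique(ch)
  edges <- lapply(setNames(verts, verts), function(v) ch[which(ch[-n] == v) + 1L])
  last <- ch[n]
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last || !length(edges[[v]])) NA_character_
      else sample(edges[[v]], 1L)
    }, character(1L))
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(last_edge[[v]])) next
      seen <- character(0L); cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur); cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  lists <- lapply(setNames(verts, verts), function(v) {
    e <- edges[[v]]
    if (v != last && !is.na(last_edge[[v]])) {
      drop <- match(last_edge[[v]], e)
      e <- e[-drop]
    }
    e <- if (length(e) > 1L) sample(e) else e
    if (v != last && !is.na(last_edge[[v]])) e <- c(e, last_edge[[v]])
    e
  })
  res <- character(n)
  res[1L] <- ch[1L]
  ptr <- setNames(rep(1L, length(verts)), verts)
  for (i in 2:n) {
    v <- res[i - 1L]
    res[i] <- lists[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
  }
  paste(res, collapse = "")
}

# best (category, penalty) statistic of a miRNA on one transcript profile;
# returns c(category, penalty) with category 5 standing for "no degradome
# support" so that every supported call beats it.
.best_statistic <- function(mirna_seq, transcript_seq, profile,
                            max_penalty = 5.0) {
  al <- align_mirna(mirna_seq, transcript_seq, max_penalty)
  al <- al[!is.na(al$cleavage_site), , drop = FALSE]
  if (!nrow(al)) return(c(Inf, Inf))
  cats <- vapply(al$cleavage_site, function(p) {
    cc <- categorize(profile, p)
    if (is.na(cc)) 5L else cc
  }, integer(1L))
  best <- order(cats, al$penalty)[1L]
  c(cats[best], al$penalty[best])
}

#' Permutation p-value for a degradome-supported target call
#'
#' The null is formed by `n_permutations` dinucleotide-shuffled variants of
#' the miRNA; the test statistic is the (category, penalty) pair of the best
#' call on the same transcript (lexicographic, smaller better). p = (1 +
#' number of null statistics at least as good as observed) /
#' (1 + n_permutations); deterministic given `seed`.
#'
#' @param mirna_seq,transcript_seq sequences as in [align_mirna()].
#' @param profile degradome profile data.frame (`position`, `count`).
#' @param n_permutations number of shuffles (>= 19; default 100).
#' @param seed RNG seed.
#' @param max_penalty alignment penalty ceiling (default 5.0).
#' @return list: `p_value`, `observed` (category, penalty).
#' @export
target_pvalue <- function(mirna_seq, transcript_seq, profile,
                          n_permutations = 100L, seed = 1L,
                          max_penalty = 5.0) {
  if (n_permutations < 19L) stop("n_permutations must be >= 19")
  obs <- .best_statistic(mirna_seq, transcript_seq, profile, max_penalty)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  better <- 0L
  mirna_seq <- toupper(chartr("Uu", "Tt", mirna_seq))
  for (i in seq_len(n_permutations)) {
    sh <- .dinuc_shuffle(mirna_seq)
    st <- .best_statistic(sh, transcript_seq, profile, max_penalty)
    if (st[1L] < obs[1L] || (st[1L] == obs[1L] && st[2L] <= obs[2L]))
      better <- better + 1L
  }
  list(p_value = (1 + better) / (1 + n_permutations), observed = obs)
}

#' Build per-transcript degradome profiles from a tag set
#'
#' Degradome tags are expected in transcript coordinates (`chrom` = the
#' transcript id, 0-based tag positions); profile positions are reported
#' 1-based from the transcript 5' end.
#'
#' @param ts `tag_set` of degradome 5'-end tags.
#' @return named list of data.frames (`position`, `count`), plus the library
#'   depth as attribute `depth`.
#' @export
degradome_profiles <- function(ts) {
  t <- ts$tags
  sp <- split(t, t$chrom)
  out <- lapply(sp, function(d)
    data.frame(position = d$position + 1L, count = d$count))
  attr(out, "depth") <- ts$library_depth
  out
}

#' Call degradome-supported miRNA targets
#'
#' Composes alignment, cleavage prediction, peak categorisation and the
#' permutation p-value for every miRNA x transcript pair, retaining calls
#' with penalty at most `max_penalty`, category at most `max_category`, and
#' p at most `alpha`.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param degradome `tag_set` in transcript coordinates.
#' @param max_penalty penalty ceiling (default 5.0).
#' @param max_category maximum accepted category (default 4).
#' @param alpha p-value threshold (default 0.05).
#' @param n_permutations,seed permutation-null parameters.
#' @return data.frame shaped like a degradome target table: `mirna_id`,
#'   `transcript_id`, `category`, `penalty`, `cleavage_site`, `cleaved_rpm`,
#'   `pct_reads_on_site`, `p_value`.
#' @export
call_targets <- function(mirnas, transcripts, degradome, max_penalty = 5.0,
                         max_category = 4L, alpha = 0.05,
                         n_permutations = 100L, seed = 1L) {
  profs <- degradome_profiles(degradome)
  depth <- attr(profs, "depth")
  rows <- list()
  for (mi in names(mirnas)) {
    for (tx in names(transcripts)) {
      prof <- profs[[tx]]
      if (is.null(prof) || !nrow(prof)) next
      al <- align_mirna(mirnas[[mi]], transcripts[[tx]], max_penalty)
      al <- al[!is.na(al$cleavage_site), , drop = FALSE]
      if (!nrow(al)) next
      cats <- vapply(al$cleavage_site, categorize, integer(1L),
                     profile = prof)
      supported <- which(!is.na(cats))
      if (!length(supported)) next
      best <- supported[order(cats[supported], al$penalty[supported])][1L]
      if (cats[best] > max_category) next
      pv <- target_pvalue(mirnas[[mi]], transcripts[[tx]], prof,
                          n_permutations = n_permutations,
                          seed = seed + match(mi, names(mirnas)),
                          max_penalty = max_penalty)
      if (pv$p_value > alpha) next
      site <- al$cleavage_site[best]
      cnt <- prof$count[match(site, prof$position)]
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mi, transcript_id = tx, category = cats[best],
        penalty = al$penalty[best], cleavage_site = site,
        cleaved_rpm = cnt * 1e6 / depth,
        pct_reads_on_site = 100 * cnt / sum(prof$count),
        p_value = pv$p_value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      category = integer(), penalty = numeric(),
                      cleavage_site = integer(), cleaved_rpm = numeric(),
                      pct_reads_on_site = numeric(), p_value = numeric()))
  res <- do.call(rbind, rows)
  res[order(res$p_value, res$penalty, res$mirna_id), , drop = FALSE]
}

#' Alignment-only target prediction (no degradome evidence)
#'
#' @param mirnas,transcripts named sequence vectors.
#' @param max_penalty penalty ceiling (default 5.0).
#' @return data.frame of all alignments with `mirna_id`, `transcript_id`
#'   prepended.
#' @export
predict_only <- function(mirnas, transcripts, max_penalty = 5.0) {
  rows <- list()
  for (mi in names(mirnas)) {
    for (tx in names(transcripts)) {
      al <- align_mirna(mirnas[[mi]], transcripts[[tx]], max_penalty)
      if (!nrow(al)) next
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(mirna_id = mi, transcript_id = tx,
                   stringsAsFactors = FALSE), al)
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      penalty = numeric(), cleavage_site = integer(),
                      bulge = character(), bulge_len = integer()))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
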