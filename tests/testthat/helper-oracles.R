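# Independent brute-force oracles used to cross-check the implementation,
# plus a cached default simulation shared across test files.

.cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.cache$sim)) .cache$sim <- simulate_nstarve(sim_config(seed = 42L))
  .cache$sim
}

default_discovery <- function() {
  if (is.null(.cache$disc)) {
    sim <- default_sim()
    expr <- fpkm(sim$counts, sim$lengths, sim$depths)
    .cache$disc <- discover_lncrna(sim$assembled, sim$reference, sim$genome,
                                   expr, sim$proteins_full, sim$proteins_excl)
  }
  .cache$disc
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

# --- ORF oracle: enumerate every ATG and scan codon-by-codon to the first
# in-frame stop over the three forward frames -------------------------------
oracle_longest_orf <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  best <- 0L
  for (f in 1:3) {
    i <- f
    while (i + 2L <= n) {
      if (paste(ch[i:(i + 2L)], collapse = "") == "ATG") {
        j <- i
        while (j + 2L <= n) {
          cod <- paste(ch[j:(j + 2L)], collapse = "")
          if (cod %in% c("TAA", "TAG", "TGA")) {
            best <- max(best, j + 3L - i)
            break
          }
          j <- j + 3L
        }
      }
      i <- i + 3L
    }
  }
  best
}

# --- miRNA alignment oracle: explicit enumeration of every register and
# single-bulge placement, scored by walking the alignment ------------------
oracle_pair_pen <- function(m, t) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (t == comp[[m]]) return(0)
  if ((m == "G" && t == "T") || (m == "T" && t == "G")) return(0.5)
  1
}

oracle_weight <- function(i) if (i >= 2 && i <= 13) 2 else 1

# score one explicit configuration; site is the transcript substring,
# walked from its 3' end (miRNA position 1 pairs the site's last base)
oracle_score <- function(mir, site, type = "none", k = 0L, b = 0L) {
  mc <- strsplit(mir, "", fixed = TRUE)[[1L]]
  sc <- strsplit(site, "", fixed = TRUE)[[1L]]
  L <- length(mc)
  idx <- length(sc)
  pen <- 0
  for (i in seq_len(L)) {
    if (type == "mirna" && i > k && i <= k + b) {
      pen <- pen + oracle_weight(i)  # unpaired miRNA nt
      next
    }
    pen <- pen + oracle_weight(i) * oracle_pair_pen(mc[i], sc[idx])
    idx <- idx - 1L
    if (type == "transcript" && i == k) {
      pen <- pen + b * oracle_weight(k + 1L)  # bulged transcript nts
      idx <- idx - b
    }
  }
  pen
}

oracle_best_penalty <- function(mir, transcript, max_bulge = 2L) {
  L <- nchar(mir)
  n <- nchar(transcript)
  best <- Inf
  for (s in seq_len(max(0L, n - L + 1L)))
    best <- min(best, oracle_score(mir, substr(transcript, s, s + L - 1L)))
  for (b in seq_len(max_bulge)) {
    if (n >= L + b) {
      for (k in 1:(L - 1L)) for (s in seq_len(n - L - b + 1L))
        best <- min(best, oracle_score(mir, substr(transcript, s, s + L + b - 1L),
                                       "transcript", k, b))
    }
    if (L - b >= 2L && n >= L - b && L - b - 1L >= 1L) {
      for (k in 1:(L - b - 1L)) for (s in seq_len(n - (L - b) + 1L))
        best <- min(best, oracle_score(mir, substr(transcript, s, s + L - b - 1L),
                                       "mirna", k, b))
    }
  }
  best
}

# --- degradome category oracle: direct restatement of the rule table ------
oracle_category <- function(counts_by_pos, site) {
  cnt <- counts_by_pos[as.character(site)]
  if (is.na(cnt) || cnt == 0) return(NA_integer_)
  if (cnt == 1) return(4L)
  pos <- counts_by_pos[counts_by_pos > 0]
  if (cnt == max(pos)) {
    if (sum(pos == max(pos)) > 1) 1L else 0L
  } else if (cnt > stats::median(pos)) 2L else 3L
}

# --- single-linkage clustering oracle -------------------------------------
oracle_clusters <- function(positions, bandwidth) {
  positions <- sort(positions)
  out <- list(positions[1L])
  for (p in positions[-1L]) {
    last <- out[[length(out)]]
    if (p - last[length(last)] <= bandwidth)
      out[[length(out)]] <- c(last, p)
    else out[[length(out) + 1L]] <- p
  }
  out
}
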