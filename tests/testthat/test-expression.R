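# Normalisation, fold changes, DE calls, concordance, set intersections.

test_that("FPKM matches its closed form and brute force", {
  counts <- matrix(c(10, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  m <- fpkm(counts, c(a = 1000, b = 500), c(s1 = 1e6))
  expect_equal(m["a", "s1"], 10)
  expect_equal(m["b", "s1"], 0)
  set.seed(21)
  cm <- matrix(rpois(120, 50), 20, 6,
               dimnames = list(paste0("f", 1:20), paste0("s", 1:6)))
  lens <- setNames(sample(200:3000, 20), rownames(cm))
  deps <- setNames(runif(6, 1e6, 5e7), colnames(cm))
  got <- fpkm(cm, lens, deps)
  for (i in 1:20) for (j in 1:6)
    expect_equal(got[i, j],
                 cm[i, j] / ((lens[i] / 1000) * (deps[j] / 1e6)),
                 ignore_attr = TRUE)
  # conservation: sum_f FPKM * len_kb * depth_M recovers the column sums
  recon <- colSums(got * (lens / 1000)) * (deps / 1e6)
  expect_equal(unname(recon), unname(colSums(cm)))
})

test_that("RP40M matches its closed form and is depth-scale invariant", {
  counts <- matrix(100, 1, 1, dimnames = list("m1", "s1"))
  expect_equal(rp40m(counts, 2e7)[1, 1], 200)
  set.seed(22)
  cm <- matrix(rpois(40, 30), 10, 4,
               dimnames = list(paste0("m", 1:10), paste0("s", 1:4)))
  deps <- setNames(runif(4, 5e6, 4e7), colnames(cm))
  got <- rp40m(cm, deps)
  for (i in 1:10) for (j in 1:4)
    expect_equal(got[i, j], cm[i, j] * 4e7 / deps[j], ignore_attr = TRUE)
  expect_equal(unclass(rp40m(cm * 3, deps * 3)), unclass(got),
               ignore_attr = TRUE)
})

test_that("log2 fold change is antisymmetric and hits its closed form", {
  m <- matrix(c(4, 8, 1, 2), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(unname(log2fc(m, "x", "x", 0.1)), c(0, 0))
  expect_equal(unname(log2fc(m, "x", "y", 0)), c(2, 2))
  set.seed(23)
  for (rep in 1:100) {
    mm <- matrix(runif(2, 0, 50), 1, 2, dimnames = list("f", c("a", "b")))
    expect_equal(log2fc(mm, "a", "b", 0.1), -log2fc(mm, "b", "a", 0.1))
  }
})

test_that("DE calls apply the 2-fold threshold and the expression floor", {
  m <- matrix(c(1.7, 0.8, 10, 0.9, 0.08, 10), 3, 2,
              dimnames = list(c("near", "low", "flat"), c("a", "b")))
  ct <- data.frame(name = "a_vs_b", sample_a = "a", sample_b = "b")
  de <- call_de(m, ct, min_expr_floor = 1, pseudocount = 0)
  dirs <- setNames(de$calls$direction, de$calls$feature)
  expect_equal(unname(dirs["near"]), "unchanged")  # log2fc ~ 0.93
  expect_equal(unname(dirs["low"]), "unchanged")   # below floor despite 10x
  expect_equal(unname(dirs["flat"]), "unchanged")
  # antisymmetry: swapping the contrast swaps up and down
  set.seed(24)
  mm <- matrix(runif(60, 0, 30), 30, 2,
               dimnames = list(paste0("f", 1:30), c("a", "b")))
  fwd <- call_de(mm, ct, min_expr_floor = 0)$calls$direction
  rev <- call_de(mm, data.frame(name = "a_vs_b", sample_a = "b",
                                sample_b = "a"), min_expr_floor = 0)$calls$direction
  expect_equal(fwd == "up", rev == "down")
  expect_equal(fwd == "down", rev == "up")
})

test_that("planted DE effects are recovered with high sensitivity and low FPR", {
  sim <- default_sim()
  expr <- fpkm(sim$counts, sim$lengths, sim$depths)
  truth <- sim$truth$de
  hits <- character(0)
  for (ti in c("root", "shoot")) {
    de <- call_de(expr, starvation_contrasts(ti))
    hits <- union(hits, de$responsive)
  }
  de_feats <- unique(truth$feature)
  null_feats <- setdiff(rownames(expr), de_feats)
  expect_gte(mean(de_feats %in% hits), 0.9)
  expect_lte(mean(null_feats %in% hits), 0.05)
})

test_that("concordance labels enumerate the full direction grid", {
  dirs <- c("up", "down", "unchanged")
  grid <- expand.grid(root = dirs, shoot = dirs, stringsAsFactors = FALSE)
  got <- concordance_label(grid$root, grid$shoot)
  expected <- apply(grid, 1, function(r) {
    if (r[1] == "up" && r[2] == "up") "concordant-up"
    else if (r[1] == "down" && r[2] == "down") "concordant-down"
    else if (r[1] != "unchanged" && r[2] != "unchanged") "discordant"
    else if (r[1] != "unchanged") "root-only"
    else if (r[2] != "unchanged") "shoot-only"
    else "none"
  })
  expect_equal(got, unname(expected))
  expect_equal(concordance_label("down", "up"), "discordant")
})

test_that("Venn region counts equal brute-force set algebra", {
  expect_equal(unname(intersect_sets(list(A = "x", B = "y"))$regions),
               c(1L, 1L, 0L))
  s <- list(A = letters, B = letters)
  expect_equal(intersect_sets(s)$intersections[["A&B"]], 26L)
  set.seed(25)
  univ <- sprintf("g%04d", 1:2000)
  sets <- list(A = sample(univ, 200), B = sample(univ, 200),
               C = sample(univ, 200))
  got <- intersect_sets(sets)
  u <- unique(unlist(sets))
  for (p in names(got$regions)) {
    inn <- strsplit(p, "&", fixed = TRUE)[[1]]
    out <- setdiff(names(sets), inn)
    brute <- sum(vapply(u, function(x)
      all(vapply(inn, function(s1) x %in% sets[[s1]], logical(1))) &&
        !any(vapply(out, function(s0) x %in% sets[[s0]], logical(1))),
      logical(1)))
    expect_equal(unname(got$regions[p]), brute)
  }
})
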