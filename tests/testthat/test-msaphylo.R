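# Progressive alignment, column filtering, NJ with oracle, bootstrap,
# cluster extraction.

test_that("identical sequences align gap-free; prefixes gap terminally", {
  msa <- progressive_align(c(a = "MCHKKW", b = "MCHKKW"))
  expect_equal(msa$aligned, c("MCHKKW", "MCHKKW"))

  msa2 <- progressive_align(c(a = "MCHKKWDD", b = "MCHKKW"))
  expect_equal(msa2$aligned[1], "MCHKKWDD")
  expect_equal(msa2$aligned[2], "MCHKKW--")

  one <- progressive_align(c(solo = "MCH"))
  expect_equal(one$aligned, "MCH")
})

test_that("de-gapping aligned rows always reproduces the inputs", {
  set.seed(61)
  seqs <- setNames(vapply(1:6, function(i) random_protein(80 + i),
                          character(1)), paste0("s", 1:6))
  msa <- progressive_align(seqs)
  expect_equal(degap(msa), seqs)
  flt <- filter_columns(msa, min_coverage = 0.5)
  # filtered rows de-gap to subsequences of the originals
  expect_true(all(nchar(degap(flt)) <= nchar(seqs)))
})

test_that("no-indel paralogs align with fully correct column homology", {
  # sequences of equal length with no indels: every column must pair
  # positionally homologous residues, i.e. the alignment stays gap-free
  sim <- simulate_codon_msa(n_seq = 8, n_codons = 120,
                            omega_classes = data.frame(omega = 0.3,
                                                       fraction = 1),
                            divergence = 0.15, seed = 6)
  prots <- vapply(sim$cds, translate_cds, character(1))
  msa <- progressive_align(prots)
  expect_true(all(nchar(msa$aligned) == nchar(prots[1])))
  expect_false(any(grepl("-", msa$aligned, fixed = TRUE)))
})

test_that("filter_columns keeps the 95% coverage boundary exactly", {
  rows <- setNames(rep("AC", 20), paste0("r", 1:20))
  rows[1] <- "-C"                       # col 1 coverage 0.95 -> kept
  msa1 <- filter_columns(rows, 0.95)
  expect_equal(attr(msa1, "kept_columns"), c(1L, 2L))
  rows[2] <- "-C"                       # col 1 coverage 0.90 -> dropped
  msa2 <- filter_columns(rows, 0.95)
  expect_equal(attr(msa2, "kept_columns"), 2L)
  expect_error(filter_columns(setNames(c("-", "-"), c("a", "b"))), "empty")
})

test_that("coordinate lift-over round-trips for kept columns", {
  msa <- c(a = "MC-HW", b = "MCK-W", c = "MCKHW")
  flt <- filter_columns(msa, min_coverage = 0.9)
  kept <- attr(flt, "kept_columns")
  m0 <- do.call(rbind, strsplit(msa, ""))
  m1 <- do.call(rbind, strsplit(.subset2(flt, "aligned"), ""))
  expect_equal(m0[, kept], m1, ignore_attr = TRUE)
})

test_that("three taxa give the closed-form star lengths", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 3)
  # closed form: la = (dab + dac - dbc)/2, etc.
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens[c("a", "b", "c")]), c(0, 2, 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), "degenerate")
})

test_that("NJ recovers the generating topology of additive matrices", {
  for (seed in 1:50) {
    n <- 4 + (seed %% 3)
    case <- random_additive_case(n, seed)
    got <- neighbor_joining(case$d)
    expect_true(same_topology(got, case$tree), info = paste("seed", seed))
    # oracle cross-check: exhaustive least-squares topology scoring
    if (seed <= 10) {
      expect_true(same_topology(oracle_best_topology(case$d), case$tree),
                  info = paste("oracle seed", seed))
    }
  }
})

test_that("negative NJ branch lengths are clamped and logged", {
  d <- matrix(c(0, 1, 6, 6, 1, 0, 6, 6, 6, 6, 0, 1, 6, 6, 1, 0) / 2, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 5.8  # near-violating quartet
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "negative_length_deficit"), 0)
})

test_that("bootstrap gives full support to clearly separated clans", {
  sim1 <- simulate_codon_msa(4, 150, data.frame(omega = 1, fraction = 1),
                             divergence = 0.1, seed = 8)
  sim2 <- simulate_codon_msa(4, 150, data.frame(omega = 1, fraction = 1),
                             divergence = 0.1, seed = 9)
  rows <- c(setNames(vapply(sim1$cds, translate_cds, character(1)),
                     paste0("x", 1:4)),
            setNames(vapply(sim2$cds, translate_cds, character(1)),
                     paste0("y", 1:4)))
  msa <- progressive_align(rows)
  tr <- bootstrap_support(msa, B = 100, seed = 5)
  support <- suppressWarnings(as.numeric(tr$node.label))
  # the central x|y split must be (nearly) universally supported
  expect_gte(max(support, na.rm = TRUE), 95)
  tr2 <- bootstrap_support(msa, B = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("an alignment of identical sequences collapses to a star at 100", {
  msa <- setNames(rep("MCHKW", 4), paste0("s", 1:4))
  tr <- bootstrap_support(msa, B = 10, seed = 1)
  expect_equal(tr$node.label, "100")
  expect_equal(ape::Ntip(tr), 4)
})

test_that("cluster extraction respects n_clusters and labels by size", {
  # caterpillar with one long central edge
  tr <- ape::read.tree(
    text = "((a:0.1,b:0.1):2.0,((c:0.1,d:0.1):0.1,e:0.1):2.0);")
  cl <- extract_clusters(tr, 2)
  expect_equal(sort(unique(cl$cluster)), c("C1", "C2"))
  expect_equal(sort(cl$id[cl$cluster == "C1"]), c("c", "d", "e"))
  expect_equal(sort(cl$id[cl$cluster == "C2"]), c("a", "b"))

  all_in_one <- extract_clusters(tr, 1)
  expect_equal(unique(all_in_one$cluster), "C1")
  expect_error(extract_clusters(tr, 50), "config")
})

test_that("simulated subfamilies are recovered as clusters", {
  # five deeply separated radiations
  rows <- unlist(lapply(1:5, function(g) {
    sim <- simulate_codon_msa(4, 130, data.frame(omega = 0.5, fraction = 1),
                              divergence = 0.12, seed = 100 + g)
    setNames(vapply(sim$cds, translate_cds, character(1)),
             paste0("g", g, "_", 1:4))
  }))
  msa <- progressive_align(rows)
  tr <- build_tree(msa, min_coverage = 0.5)
  cl <- extract_clusters(tr, 5)
  truth <- sub("_.*", "", cl$id)
  got <- cl$cluster
  keep <- !is.na(got)
  # adjusted Rand index against the generating subfamily labels
  ari <- mclust_ari(truth[keep], got[keep])
  expect_gte(ari, 0.9)
})

test_that("bootstrap supports are invariant to leaf input order", {
  set.seed(71)
  base <- random_protein(100)
  seqs <- setNames(vapply(1:5, function(i) {
    ch <- strsplit(base, "")[[1]]
    idx <- sample(100, 12)
    ch[idx] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      12, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1)), paste0("s", 1:5))
  msa <- progressive_align(seqs)
  rows <- setNames(msa$aligned, msa$id)
  t1 <- bootstrap_support(rows, B = 50, seed = 3)
  t2 <- bootstrap_support(rows[c(3, 1, 5, 2, 4)], B = 50, seed = 3)
  # same bipartition supports regardless of row order
  s1 <- sort(suppressWarnings(as.numeric(t1$node.label)))
  s2 <- sort(suppressWarnings(as.numeric(t2$node.label)))
  expect_equal(s1, s2)
})
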