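# Local alignment, proteome screening, profile scan, cross-reactivity and
# peptide mapping.

test_that("self-alignment gives identity 1 over the full length", {
  al <- smith_waterman(c(q = "HEAGAWGHEE"), c(s = "HEAGAWGHEE"))
  expect_equal(al$identity, 1)
  expect_equal(al$alignment_length, 10L)
  expect_equal(al$matches, 10L)
  expect_gt(al$score, 0)
})

test_that("non-homologous sequences yield an empty alignment of score 0", {
  al <- smith_waterman(c(q = "AAAA"), c(s = "CCCC"))
  expect_equal(al$score, 0)
  expect_equal(al$alignment_length, 0L)
  expect_equal(nrow(al$aligned_pairs[[1]]), 0)
  expect_error(smith_waterman(c(q = ""), c(s = "MCH")), "empty")
})

test_that("smith_waterman matches brute-force enumeration on short pairs", {
  mat <- blosum62()
  set.seed(101)
  n_checked <- 0
  for (case in 1:100) {
    q <- random_protein(sample(3:8, 1))
    s <- random_protein(sample(3:8, 1))
    got <- smith_waterman(setNames(q, "q"), setNames(s, "s"))
    exp <- oracle_local_align(q, s, mat)
    expect_equal(got$score, exp$score, info = paste(q, s))
    expect_equal(got$identity, exp$identity, info = paste(q, s))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 100)
})

test_that("identity is symmetric under the stated tie-breaking", {
  set.seed(55)
  for (case in 1:20) {
    a <- setNames(random_protein(30), "a")
    b <- setNames(random_protein(30), "b")
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
})

test_that("screening references against themselves finds each as top match", {
  set.seed(9)
  refs <- setNames(vapply(1:3, function(i) random_protein(120),
                          character(1)), c("r1", "r2", "r3"))
  sc <- screen_proteome(refs, refs, min_score = 100)
  expect_true(all(sc$is_family))
  expect_equal(sc$identity, rep(1, 3))
  expect_true(all(sc$is_top_match))
  expect_equal(sc$best_reference, sc$protein_id)
})

test_that("screen output is invariant to proteome input order", {
  set.seed(10)
  refs <- setNames(list(random_protein(100))[[1]], "ref")
  prot <- setNames(vapply(1:6, function(i) random_protein(100),
                          character(1)), paste0("p", 1:6))
  a <- screen_proteome(prot, c(ref = refs), min_score = 20)
  b <- screen_proteome(prot[sample(6)], c(ref = refs), min_score = 20)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("family recovery on simulation is near-perfect; spacers never hit", {
  sim <- simulate_family(small_sim_params())
  refs <- sim_references(sim)
  tr <- sim$truth
  for (sp in names(sim$species)[1:2]) {
    d <- sim$species[[sp]]
    sc <- screen_proteome(d$proteins, refs, min_score = 100)
    truth_fam <- paste0(tr$gene_id[tr$species == sp & tr$family_member],
                        ".t1")
    called <- sc$protein_id[sc$is_family]
    expect_gte(mean(truth_fam %in% called), 0.95)
    expect_gte(mean(called %in% truth_fam), 0.95)
    # spacer genes are non-homologous by construction (identity < 0.20
    # after the local alignment is forced over >= 50 columns)
    spacers <- sc[!sc$protein_id %in% truth_fam, ]
    expect_true(all(!spacers$is_family))
  }
})

test_that("decoy calibration yields a threshold separating family scores", {
  sim <- simulate_family(small_sim_params())
  refs <- sim_references(sim)
  d <- sim$species[[1]]
  thr <- calibrate_score_threshold(refs, d$proteins, n_shuffles = 200)
  fam_score <- smith_waterman(setNames(refs[1], "r"),
                              setNames(refs[2], "s"))$score
  expect_gt(fam_score, thr)
})

test_that("profile built from identical rows scores its source maximally", {
  set.seed(21)
  seqs <- setNames(rep(random_protein(60), 2), c("a", "b"))
  prof <- build_profile(seqs)
  prot <- c(setNames(seqs[1], "true"),
            setNames(vapply(1:5, function(i) random_protein(60),
                            character(1)), paste0("decoy", 1:5)))
  hits <- profile_scan(prof, prot)
  expect_equal(hits$protein_id[which.max(hits$score)], "true")
})

test_that("infinite pseudocount weight drives scores to the background", {
  set.seed(22)
  seqs <- setNames(c(random_protein(40), random_protein(40)), c("a", "b"))
  prof <- build_profile(seqs, pseudocount_weight = 1e9)
  expect_lt(max(abs(prof$scores)), 1e-6)
})

test_that("profile scan confirms most alignment-screen hits on simulation", {
  sim <- simulate_family(small_sim_params())
  refs <- sim_references(sim)
  msa <- progressive_align(refs)
  prof <- build_profile(msa)
  d <- sim$species[[1]]
  sc <- screen_proteome(d$proteins, refs, min_score = 100)
  # threshold: halfway between the best spacer score and the references'
  # own self-scan scores
  ref_scores <- profile_scan(prof, refs)$score
  scan <- profile_scan(prof, d$proteins,
                       score_threshold = min(ref_scores) * 0.5)
  agree <- compare_hit_sets(sc, scan)
  screen_pos <- agree$protein_id[agree$in_screen]
  expect_gte(mean(screen_pos %in% agree$protein_id[agree$in_scan]), 0.95)
})

test_that("all-gap profile columns are dropped with a warning", {
  msa <- c(a = "MC-H", b = "MC-H")
  expect_warning(prof <- build_profile(msa), "all-gap")
  expect_equal(nrow(prof$scores), 3)
})

test_that("cross-reactivity needs 35% identity over at least 80 residues", {
  set.seed(31)
  p <- random_protein(100)
  res <- predict_cross_reactivity(c(a = p), c(b = p))
  expect_true(res$cross_reactive)
  expect_equal(res$identity, 1)
  expect_equal(res$alignment_length, 100L)

  # identical 79-residue core flanked by unrelated tails: alignment is one
  # column short of the 80-residue requirement
  core <- random_protein(79)
  a <- paste0(strrep("W", 12), core)
  b <- paste0(core, strrep("P", 12))
  res <- predict_cross_reactivity(c(a = a), c(b = b))
  expect_equal(res$alignment_length, 79L)
  expect_false(res$cross_reactive)

  # short sequences are not evaluable rather than negative
  res <- predict_cross_reactivity(c(a = random_protein(60)),
                                  c(b = random_protein(100)))
  expect_true(is.na(res$cross_reactive))
  expect_equal(res$status, "not_evaluable")
})

test_that("cross-reactivity is false just below the identity threshold", {
  # 200-column gap-free alignment at identity 0.34 < 0.35: matches are W/W
  # (+11), mismatches I/L (+2), so every column scores positively and the
  # optimal local alignment spans the full length without trimming
  match_pos <- round(seq(2, 199, length.out = 68))
  achars <- rep("I", 200); bchars <- rep("L", 200)
  achars[match_pos] <- "W"; bchars[match_pos] <- "W"
  a <- paste(achars, collapse = ""); b <- paste(bchars, collapse = "")
  al <- smith_waterman(c(a = a), c(b = b))
  expect_equal(al$alignment_length, 200L)
  expect_equal(al$identity, 0.34)
  res <- predict_cross_reactivity(c(a = a), c(b = b))
  expect_false(res$cross_reactive)
})

test_that("peptides map exactly with I/L equivalence", {
  prot <- c(p1 = "MKKAAILVNDEGHWWK", p2 = "MNNNNNNNNNNNNNNN")
  hit <- map_peptides(c(ep = substr(prot[["p1"]], 5, 12)), prot)
  expect_equal(hit$unique_to, "p1")
  # I <-> L substitution still matches
  pep_il <- chartr("IL", "LI", substr(prot[["p1"]], 5, 12))
  hit <- map_peptides(c(ep = pep_il), prot)
  expect_equal(hit$unique_to, "p1")
  # a peptide found in both proteins is not unique
  both <- map_peptides(c(ep = "NNNNNN"),
                       c(p1 = "AAANNNNNNBBB", p2 = "CCCNNNNNNDDD"))
  expect_equal(both$n_matches, 2)
  expect_true(is.na(both$unique_to))
})

test_that("tryptic peptides of a dominant gene are mostly unique to it", {
  sim <- simulate_family(small_sim_params())
  tr <- sim$truth
  sp <- names(sim$species)[1]
  d <- sim$species[[sp]]
  fam <- paste0(tr$gene_id[tr$species == sp & tr$family_member], ".t1")
  dom <- fam[1]
  prot <- d$proteins[fam]
  set.seed(77)
  starts <- sample(nchar(prot[[dom]]) - 9, 20)
  peps <- setNames(substring(prot[[dom]], starts, starts + 8),
                   paste0("pep", seq_along(starts)))
  res <- map_peptides(peps, prot)
  expect_gte(mean(res$unique_to == dom, na.rm = TRUE), 0.9)
})
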