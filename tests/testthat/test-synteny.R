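# Array classification boundaries, family summary arithmetic, decay
# detection.

# small hand-built annotation: family genes f*, spacers s*
toy_genes <- function(layout, scaffold = "sc1", start0 = 1000, gap = 100) {
  n <- length(layout)
  starts <- start0 + (seq_len(n) - 1) * 1000
  tibble::tibble(
    gene_id = layout, scaffold_id = scaffold,
    start = starts, end = starts + 500,
    strand = rep(c("+", "-"), length.out = n),
    cds_segments = lapply(starts, function(s) cbind(start = s, end = s + 500)),
    protein_id = paste0(layout, ".t1"), translatable = TRUE)
}

test_that("zero spacers make a TAG, up to nine make a PAG", {
  g <- toy_genes(c("s1", "f1", "f2", "s2"))
  cls <- classify_arrays(g, c("f1", "f2"))
  expect_equal(unique(cls$arrayed_class), "TAG")
  expect_equal(length(unique(cls$array_id)), 1)

  g9 <- toy_genes(c("f1", paste0("s", 1:9), "f2"))
  cls9 <- classify_arrays(g9, c("f1", "f2"))
  expect_equal(unique(cls9$arrayed_class), "PAG")

  g10 <- toy_genes(c("f1", paste0("s", 1:10), "f2"))
  cls10 <- classify_arrays(g10, c("f1", "f2"))
  expect_equal(unique(cls10$arrayed_class), "singleton")
  expect_true(all(is.na(cls10$array_id)))
})

test_that("a mixed-gap run is a PAG and genes on other scaffolds split", {
  g <- dplyr::bind_rows(
    toy_genes(c("f1", "f2", "s1", "f3")),           # gaps 0 and 1 -> PAG
    toy_genes(c("s9", "f4"), scaffold = "sc2"))
  cls <- classify_arrays(g, c("f1", "f2", "f3", "f4"))
  expect_equal(cls$arrayed_class, c("PAG", "PAG", "PAG", "singleton"))
  arr <- attr(cls, "arrays")
  expect_equal(arr$gap_spacers[[1]], c(0L, 1L))
})

test_that("every family gene lands in exactly one class", {
  sim <- simulate_family(small_sim_params(seed = 19))
  tr <- sim$truth
  for (sp in names(sim$species)) {
    fam <- tr$gene_id[tr$species == sp & tr$family_member]
    cls <- classify_arrays(sim$species[[sp]]$genes, fam)
    expect_setequal(cls$gene_id, fam)
    expect_equal(nrow(cls), length(fam))
    expect_true(all(cls$arrayed_class %in% c("TAG", "PAG", "singleton")))
  }
  expect_error(classify_arrays(sim$species[[1]]$genes, "nonexistent_gene"),
               "missing annotation")
})

test_that("classification is invariant to coordinate shifts and strand flips", {
  g <- toy_genes(c("s1", "f1", "f2", "s2", "s3", "f3"))
  base <- classify_arrays(g, c("f1", "f2", "f3"))
  g2 <- g
  g2$start <- g2$start + 7777
  g2$end <- g2$end + 7777
  g2$strand <- ifelse(g2$strand == "+", "-", "+")
  moved <- classify_arrays(g2, c("f1", "f2", "f3"))
  expect_equal(base$arrayed_class, moved$arrayed_class)
  expect_equal(base$array_id, moved$array_id)
})

test_that("summary table reproduces printed per-species totals", {
  # per-species totals as printed for the six mite species
  species <- c("Dpte", "Dfar", "Povi", "Ssca", "Btro", "Tput")
  totals <- c(29, 25, 22, 20, 52, 66)
  arrayed <- c(18, 13, 10, 12, 34, 20)
  active <- c(24, 22, 20, 14, 44, 45)
  rows <- do.call(dplyr::bind_rows, lapply(seq_along(species), function(i) {
    tibble::tibble(
      species = species[i],
      gene_id = sprintf("%s_%03d", species[i], seq_len(totals[i])),
      arrayed = seq_len(totals[i]) <= arrayed[i],
      active = seq_len(totals[i]) <= active[i])
  }))
  tab <- summarize_family(rows)
  expect_equal(tab$total[tab$species == "Total"], 214)
  expect_equal(tab$arrayed[tab$species == "Total"], 107)
  expect_equal(tab$active[tab$species == "Total"], 169)
  expect_equal(tab$species, c(species, "Total"))
  # totals equal the sum of their rows
  expect_equal(sum(tab$total[tab$species != "Total"]),
               tab$total[tab$species == "Total"])
})

test_that("empty input summarizes to an all-zero table", {
  tab <- summarize_family(tibble::tibble(species = character(0),
                                         gene_id = character(0),
                                         arrayed = logical(0),
                                         active = logical(0)))
  expect_equal(tab$total, 0L)
})

test_that("no decay events are reported when every species is present", {
  sim <- simulate_family(small_sim_params(seed = 41, dup_prob = 0))
  tr <- sim$truth
  clusters <- tr |>
    dplyr::filter(.data$family_member) |>
    dplyr::transmute(cluster_id = .data$origin, species = .data$species,
                     gene_id = .data$gene_id)
  genes_by_sp <- lapply(sim$species, `[[`, "genes")
  prot_by_sp <- lapply(sim$species, function(d) {
    setNames(unname(d$proteins), sub("\\.t1$", "", names(d$proteins)))
  })
  ev <- detect_gene_decay(clusters, genes_by_sp, prot_by_sp,
                          names(sim$species))
  expect_equal(nrow(ev), 0)
})

test_that("simulated decay is recovered as anchored events", {
  sim <- simulate_family(small_sim_params(seed = 22, dup_prob = 0,
                                          decay_prob = 0.08))
  tr <- sim$truth
  fam <- tr[tr$family_member, ]
  clusters <- fam |>
    dplyr::transmute(cluster_id = .data$origin, species = .data$species,
                     gene_id = .data$gene_id)
  genes_by_sp <- lapply(sim$species, `[[`, "genes")
  prot_by_sp <- lapply(sim$species, function(d) {
    setNames(unname(d$proteins), sub("\\.t1$", "", names(d$proteins)))
  })
  ev <- detect_gene_decay(clusters, genes_by_sp, prot_by_sp,
                          names(sim$species))
  # truth: all (origin, species) decay pairs
  truth_pairs <- unique(dplyr::bind_rows(lapply(seq_len(nrow(fam)),
    function(i) {
      sp <- fam$decayed_in[[i]]
      if (length(sp) == 0) return(NULL)
      tibble::tibble(cluster_id = fam$origin[i], missing_species = sp)
    })))
  expect_gt(nrow(truth_pairs), 0)
  got <- ev[ev$confidence == "anchored", c("cluster_id", "missing_species")]
  # every truth decay with surviving flanks must be reported as anchored
  found <- dplyr::inner_join(truth_pairs, got,
                             by = c("cluster_id", "missing_species"))
  expect_equal(nrow(found), nrow(truth_pairs))
  # no event may name a species that actually carries the gene
  for (i in seq_len(nrow(ev))) {
    expect_false(any(fam$origin == ev$cluster_id[i] &
                     fam$species == ev$missing_species[i]))
  }
})

test_that("a missing species without conserved flanks is unanchored", {
  sim <- simulate_family(small_sim_params(seed = 22, dup_prob = 0,
                                          decay_prob = 0.08))
  tr <- sim$truth
  fam <- tr[tr$family_member, ]
  dec <- NULL
  for (i in seq_len(nrow(fam))) {
    if (length(fam$decayed_in[[i]]) > 0) {
      dec <- list(origin = fam$origin[i], sp = fam$decayed_in[[i]][1])
      break
    }
  }
  skip_if(is.null(dec), "no decay event in this run")
  clusters <- fam |>
    dplyr::filter(.data$origin == dec$origin) |>
    dplyr::transmute(cluster_id = .data$origin, species = .data$species,
                     gene_id = .data$gene_id)
  genes_by_sp <- lapply(sim$species, `[[`, "genes")
  prot_by_sp <- lapply(sim$species, function(d) {
    setNames(unname(d$proteins), sub("\\.t1$", "", names(d$proteins)))
  })
  # cripple the missing species' annotation down to a single unrelated gene
  # so no orthologous flanks remain
  genes_by_sp[[dec$sp]] <- genes_by_sp[[dec$sp]][1, ]
  prot_by_sp[[dec$sp]] <- prot_by_sp[[dec$sp]][
    genes_by_sp[[dec$sp]]$gene_id]
  ev <- detect_gene_decay(clusters, genes_by_sp, prot_by_sp,
                          names(sim$species))
  row <- ev[ev$missing_species == dec$sp, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$confidence, "unanchored")
})

test_that("arrays export to BED with half-open coordinates", {
  g <- toy_genes(c("f1", "f2", "s1"))
  cls <- classify_arrays(g, c("f1", "f2"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_arrays_bed(attr(cls, "arrays"), g, f)
  bed <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(as.integer(bed[2]), min(g$start[1:2]) - 1L)
  expect_equal(as.integer(bed[3]), max(g$end[1:2]))
})
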