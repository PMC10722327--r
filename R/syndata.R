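# Synthetic multi-species genome, read-set and ELISA simulator with recorded
# ground truth. The generator emulates the evolutionary regime of a tandemly
# expanding papain-like protease family: codon substitution with per-site
# omega classes, tandem/proximal duplication, catalytic-triad knockouts,
# lineage-specific whole-gene decay with conserved flanking anchors, one
# dominantly expressed paralog per species, and control-vs-sensitized ELISA
# optical densities.

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

#' Simulation parameters
#'
#' Bundles every knob of the synthetic-data generator with defaults that
#' emulate a six-species astigmatic-mite-like study design: a species tree
#' with two house-dust-mite-like sister taxa, two parasitic-mite-like taxa
#' and two deeper storage-mite-like taxa; an ancestral family expanded by
#' tandem duplication; mostly purifying per-site selection with a small
#' positively selected fraction; occasional triad knockouts and
#' lineage-specific gene loss.
#'
#' @param species_tree Newick string with branch lengths in expected proposed
#'   substitutions per codon site.
#' @param n_scaffolds Scaffolds per species genome.
#' @param ancestral_family_size Family copies in the ancestral genome.
#' @param gene_length_codons Codons per ancestral family gene.
#' @param init_divergence Burn-in divergence separating ancestral paralogs.
#' @param dup_prob Per-branch tandem-duplication probability per family gene.
#' @param spacer_count_dist Probability vector over 0, 1, 2, ... spacer genes
#'   inserted between a duplicate and its source.
#' @param omega_classes Data frame with columns `omega` and `fraction`
#'   (fractions summing to 1) describing per-site dN/dS classes.
#' @param triad_knockout_prob Per-gene (per species) probability of a
#'   catalytic-site point mutation or codon deletion.
#' @param knockout_deletion_prob Probability a knockout is a deletion rather
#'   than a point mutation.
#' @param decay_prob Per-branch probability of whole-gene loss per family
#'   gene.
#' @param n_spacer_genes Unrelated background genes per scaffold.
#' @param dominant_ratio Mean TPM-weight ratio of the dominant paralog over
#'   background paralogs.
#' @param read_length,depth Read simulation defaults (bases; reads/sample).
#' @param elisa List: `n_controls`, `n_subjects`, `control_mean`,
#'   `control_sd`, `subject_effect_dist` (function of n returning effects),
#'   `n_replicates`.
#' @param seed Integer seed; a fixed seed yields byte-identical outputs.
#' @return A list of class `cpfam_syn_params`.
#' @export
syn_params <- function(
    species_tree = paste0("((((Dpte:0.10,Dfar:0.10):0.06,",
                          "(Povi:0.12,Ssca:0.12):0.06):0.05,",
                          "(Btro:0.18,Tput:0.18):0.05):0.01);"),
    n_scaffolds = 3,
    ancestral_family_size = 10,
    gene_length_codons = 220,
    init_divergence = 0.12,
    dup_prob = 0.3,
    spacer_count_dist = c(0.60, 0.14, 0.08, 0.05, 0.04, 0.03, 0.02,
                          0.02, 0.01, 0.01),
    omega_classes = data.frame(omega = c(0.1, 0.5, 1, 5),
                               fraction = c(0.55, 0.25, 0.15, 0.05)),
    triad_knockout_prob = 0.2,
    knockout_deletion_prob = 0.3,
    decay_prob = 0,
    n_spacer_genes = 45,
    dominant_ratio = 10,
    read_length = 75,
    depth = 20000,
    elisa = list(n_controls = 8, n_subjects = 15, control_mean = 0.06,
                 control_sd = 0.015,
                 subject_effect_dist = function(n) stats::rgamma(n, 0.8, 6),
                 n_replicates = 2),
    seed = 1) {
  p <- list(species_tree = species_tree, n_scaffolds = n_scaffolds,
            ancestral_family_size = ancestral_family_size,
            gene_length_codons = gene_length_codons,
            init_divergence = init_divergence, dup_prob = dup_prob,
            spacer_count_dist = spacer_count_dist / sum(spacer_count_dist),
            omega_classes = omega_classes,
            triad_knockout_prob = triad_knockout_prob,
            knockout_deletion_prob = knockout_deletion_prob,
            decay_prob = decay_prob, n_spacer_genes = n_spacer_genes,
            dominant_ratio = dominant_ratio, read_length = read_length,
            depth = depth, elisa = elisa, seed = seed)
  stopifnot(dup_prob >= 0, dup_prob <= 1, decay_prob >= 0, decay_prob <= 1,
            triad_knockout_prob >= 0, triad_knockout_prob <= 1,
            all(omega_classes$omega >= 0),
            abs(sum(omega_classes$fraction) - 1) < 1e-8,
            elisa$control_sd >= 0)
  class(p) <- "cpfam_syn_params"
  p
}

.random_codons <- function(n) {
  sample(SENSE_CODONS, n, replace = TRUE)
}

#' Evolve a codon sequence under omega-scaled substitution
#'
#' Single-nucleotide changes are proposed per codon site at rate
#' `divergence * max(1, omega)` (expected proposals per site); a proposal to
#' a stop codon is always rejected, a synonymous proposal is accepted with
#' probability `min(1, 1/omega)` and a nonsynonymous proposal with
#' probability `min(1, omega)`. For `omega <= 1` this is plain
#' omega-filtered acceptance at the branch rate; for `omega > 1` it keeps
#' the synonymous substitution rate at the branch rate while multiplying
#' the nonsynonymous rate by omega, the standard codon-model semantics of
#' dN/dS. Sites flagged invariant receive no proposals.
#'
#' @param codons Character vector of sense codons.
#' @param divergence Expected proposed substitutions per codon site (for a
#'   neutral site).
#' @param omega Per-site omega (recycled if scalar).
#' @param invariant Logical per-site mask of frozen sites (default none).
#' @return The evolved codon vector, with proposal/acceptance counters in
#'   attribute `stats` (`proposed`, `proposed_nonsyn`, `accepted_nonsyn`,
#'   `accepted_syn`).
#' @export
evolve_codons <- function(codons, divergence, omega,
                          invariant = rep(FALSE, length(codons))) {
  L <- length(codons)
  omega <- rep_len(omega, L)
  k <- rpois(L, divergence * pmax(1, omega))
  k[invariant] <- 0L
  stats <- c(proposed = 0L, proposed_nonsyn = 0L, accepted_nonsyn = 0L,
             accepted_syn = 0L)
  bases <- c("A", "C", "G", "T")
  for (site in which(k > 0L)) {
    cur <- codons[[site]]
    for (e in seq_len(k[[site]])) {
      pos <- sample.int(3L, 1L)
      old_b <- substr(cur, pos, pos)
      new_b <- sample(setdiff(bases, old_b), 1L)
      cand <- cur
      substr(cand, pos, pos) <- new_b
      stats[["proposed"]] <- stats[["proposed"]] + 1L
      aa_old <- GENETIC_CODE_TABLE[[cur]]
      aa_new <- GENETIC_CODE_TABLE[[cand]]
      if (aa_new == "*") next
      if (aa_new == aa_old) {
        if (runif(1) <= min(1, 1 / max(omega[[site]], 1e-12))) {
          cur <- cand
          stats[["accepted_syn"]] <- stats[["accepted_syn"]] + 1L
        }
      } else {
        stats[["proposed_nonsyn"]] <- stats[["proposed_nonsyn"]] + 1L
        if (runif(1) <= min(1, omega[[site]])) {
          cur <- cand
          stats[["accepted_nonsyn"]] <- stats[["accepted_nonsyn"]] + 1L
        }
      }
    }
    codons[[site]] <- cur
  }
  attr(codons, "stats") <- stats
  codons
}

.draw_site_omegas <- function(n, omega_classes) {
  idx <- sample.int(nrow(omega_classes), n, replace = TRUE,
                    prob = omega_classes$fraction)
  omega_classes$omega[idx]
}

#' Simulate a codon alignment with per-site omega truth
#'
#' Independent tip lineages radiate from one random ancestral codon sequence
#' (a star phylogeny), each evolved with [evolve_codons()] under per-site
#' omega classes. Because there are no indels the emitted rows are a codon
#' alignment by construction.
#'
#' @param n_seq Number of tip sequences.
#' @param n_codons Codons per sequence.
#' @param omega_classes Data frame `omega`/`fraction` of per-site classes.
#' @param divergence Expected proposed substitutions per site per tip.
#' @param seed Integer seed.
#' @return List with `cds` (named character vector of codon rows) and
#'   `site_omega` (numeric truth per codon site).
#' @export
simulate_codon_msa <- function(n_seq = 16, n_codons = 300,
                               omega_classes = data.frame(
                                 omega = c(1, 5), fraction = c(0.7, 0.3)),
                               divergence = 0.5, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  anc <- .random_codons(n_codons)
  site_omega <- .draw_site_omegas(n_codons, omega_classes)
  rows <- vapply(seq_len(n_seq), function(i) {
    paste(evolve_codons(anc, divergence, site_omega), collapse = "")
  }, character(1))
  names(rows) <- sprintf("s%02d", seq_len(n_seq))
  list(cds = rows, site_omega = site_omega)
}

# ---- full family simulator -------------------------------------------------

#' Simulate multi-species genomes with a tandemly expanding gene family
#'
#' Evolves an ancestral genome down the species tree of `params`. On every
#' branch each gene's codons substitute under omega-filtered proposals, each
#' family gene may duplicate in tandem (the copy lands downstream of its
#' source separated by a draw from `spacer_count_dist` fresh spacer genes)
#' and may decay (whole-gene loss with flanking genes retained). At the tips,
#' catalytic-triad knockouts (point mutation or codon deletion at one triad
#' site) are applied per gene, one family paralog per species is marked
#' dominantly expressed, and genomes are laid out on scaffolds with 1-based
#' coordinates and random strands.
#'
#' @param params A [syn_params()] object.
#' @param out_dir If non-`NULL`, per-species `*_proteins.faa`, `*_cds.fna`,
#'   `*.gff3`, a `truth.tsv` and a `params.txt` echo are written there.
#' @return List of class `cpfam_simulation`: `species` (named list with
#'   `genes` gene-model tibble, `proteins`, `cds`, `scaffolds` named
#'   character vectors), `truth` (one row per emitted gene: `gene_id`,
#'   `species`, `family_member`, `origin`, `array_id`, `arrayed_class`,
#'   `active`, `triad_fate`, `expr_tier`, `decayed_in` list column,
#'   `site_omega` list column), `triad` (the triad codon indices and expected
#'   residues), and `params`.
#' @export
simulate_family <- function(params = syn_params(), out_dir = NULL) {
  stopifnot(inherits(params, "cpfam_syn_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  tree <- ape::read.tree(text = params$species_tree)
  if (is.null(tree)) stop("config error: species_tree is not valid newick")
  species <- tree$tip.label
  ntip <- length(species)

  L <- params$gene_length_codons
  triad_pos <- sort(unique(pmax(2L, round(L * c(0.25, 0.62, 0.82)))))
  triad_res <- c("C", "H", "N")
  triad_codons <- c("TGC", "CAC", "AAC")

  founder <- .random_codons(L)
  founder[triad_pos] <- triad_codons
  # catalytic sites sit in conserved motifs; freezing the flanking codons
  # (glycine, distinct from C/H/N) keeps a knockout deletion positionally
  # identifiable in the alignment instead of sliding within a repeat
  flank_pos <- setdiff(unique(c(triad_pos - 1L, triad_pos + 1L)), triad_pos)
  flank_pos <- flank_pos[flank_pos >= 1L & flank_pos <= L]
  founder[flank_pos] <- "GGA"
  site_omega <- .draw_site_omegas(L, params$omega_classes)
  site_omega[c(triad_pos, flank_pos)] <- 0
  invariant <- rep(FALSE, L)
  invariant[c(triad_pos, flank_pos)] <- TRUE

  env <- new.env(parent = emptyenv())
  env$uid <- 0L
  new_uid <- function() { env$uid <- env$uid + 1L; env$uid }
  env$decay <- list()  # list of (origin, node)

  new_spacer <- function(tag) {
    len <- sample(120:260, 1L)
    list(uid = new_uid(), origin = paste0("sp_", tag, "_", new_uid()),
         family = FALSE, seq = .random_codons(len))
  }
  # ancestral genome: family genes spread across scaffolds, separated by
  # >= 10 spacers so every ancestral copy starts as a singleton
  fam_origin <- sprintf("fam%02d", seq_len(params$ancestral_family_size))
  fam_scaf <- rep_len(seq_len(params$n_scaffolds),
                      params$ancestral_family_size)
  genome <- vector("list", params$n_scaffolds)
  for (sc in seq_len(params$n_scaffolds)) {
    fams <- which(fam_scaf == sc)
    n_gaps <- length(fams) + 1L
    per_gap <- max(ceiling(params$n_spacer_genes / n_gaps), 11L)
    scaf <- list()
    for (fi in seq_along(fams)) {
      scaf <- c(scaf, replicate(per_gap, new_spacer(sc), simplify = FALSE))
      g <- list(uid = new_uid(), origin = fam_origin[fams[fi]], family = TRUE,
                seq = evolve_codons(founder, params$init_divergence,
                                    site_omega, invariant))
      attr(g$seq, "stats") <- NULL
      scaf <- c(scaf, list(g))
    }
    scaf <- c(scaf, replicate(per_gap, new_spacer(sc), simplify = FALSE))
    genome[[sc]] <- scaf
  }

  # preorder branch traversal
  root <- ntip + 1L
  genomes_at <- list()
  genomes_at[[root]] <- genome
  edge_order <- order(tree$edge[, 1])  # parents before children from root
  # ensure true preorder: repeatedly process edges whose parent is resolved
  edges <- tree$edge[edge_order, , drop = FALSE]
  lens <- tree$edge.length[edge_order]
  done <- rep(FALSE, nrow(edges))
  while (!all(done)) {
    for (e in which(!done)) {
      par <- edges[e, 1]; child <- edges[e, 2]
      if (length(genomes_at) < par || is.null(genomes_at[[par]])) next
      genomes_at[[child]] <- .evolve_branch(genomes_at[[par]], lens[e],
                                            child, site_omega, invariant,
                                            params, env, new_uid, new_spacer)
      done[e] <- TRUE
    }
  }

  # map decay events to affected tip species
  desc_tips <- function(node) {
    if (node <= ntip) return(species[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  decay_map <- list()
  for (ev in env$decay) {
    decay_map[[ev$origin]] <- sort(unique(c(decay_map[[ev$origin]],
                                            desc_tips(ev$node))))
  }

  out_species <- list()
  truth_rows <- list()
  for (ti in seq_len(ntip)) {
    sp <- species[ti]
    fin <- .finalize_tip(genomes_at[[ti]], sp, params, triad_pos, triad_res,
                         site_omega, decay_map)
    out_species[[sp]] <- fin$data
    truth_rows[[sp]] <- fin$truth
  }
  truth <- dplyr::bind_rows(truth_rows)

  sim <- structure(list(species = out_species, truth = truth,
                        triad = list(positions = triad_pos,
                                     residues = triad_res),
                        params = params),
                   class = "cpfam_simulation")
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

.evolve_branch <- function(genome, len, child_node, site_omega, invariant,
                           params, env, new_uid, new_spacer) {
  for (sc in seq_along(genome)) {
    scaf <- genome[[sc]]
    # substitution
    for (gi in seq_along(scaf)) {
      g <- scaf[[gi]]
      if (g$family) {
        g$seq <- evolve_codons(g$seq, len, site_omega, invariant)
      } else {
        g$seq <- evolve_codons(g$seq, len, 1)
      }
      attr(g$seq, "stats") <- NULL
      scaf[[gi]] <- g
    }
    # tandem duplication (iterate over the pre-duplication members)
    fam_idx <- which(vapply(scaf, `[[`, TRUE, "family"))
    offset <- 0L
    for (gi in fam_idx) {
      if (runif(1) >= params$dup_prob) next
      pos <- gi + offset
      src <- scaf[[pos]]
      k <- sample(seq_along(params$spacer_count_dist), 1L,
                  prob = params$spacer_count_dist) - 1L
      uid <- new_uid()
      insert <- c(replicate(k, new_spacer(sc), simplify = FALSE),
                  # a duplicate founds its own locus lineage so that decay
                  # and orthology are tracked per locus, not per ancestor
                  list(list(uid = uid,
                            origin = paste0(src$origin, ".d", uid),
                            family = TRUE, seq = src$seq)))
      scaf <- append(scaf, insert, after = pos)
      offset <- offset + k + 1L
    }
    # decay
    if (params$decay_prob > 0) {
      fam_idx <- which(vapply(scaf, `[[`, TRUE, "family"))
      drop <- fam_idx[runif(length(fam_idx)) < params$decay_prob]
      for (gi in drop) {
        env$decay[[length(env$decay) + 1L]] <-
          list(origin = scaf[[gi]]$origin, node = child_node)
      }
      if (length(drop)) scaf <- scaf[-drop]
    }
    genome[[sc]] <- scaf
  }
  genome
}

.finalize_tip <- function(genome, sp, params, triad_pos, triad_res,
                          site_omega, decay_map) {
  # triad knockouts, ids, coordinates, strands, emission
  idx <- 0L
  gene_rows <- list()
  scaffolds <- character(0)
  truth <- list()
  fam_ids <- character(0)
  for (sc in seq_along(genome)) {
    scaf_id <- sprintf("%s_scaf%02d", sp, sc)
    pos <- 200L
    dna_parts <- list(paste(sample(c("A", "C", "G", "T"), 200L,
                                   replace = TRUE), collapse = ""))
    scaf <- genome[[sc]]
    for (gi in seq_along(scaf)) {
      g <- scaf[[gi]]
      idx <- idx + 1L
      gene_id <- sprintf("%s_%03d", sp, idx)
      fate <- "intact"
      active <- g$family
      seq <- g$seq
      if (g$family && runif(1) < params$triad_knockout_prob) {
        site <- sample.int(3L, 1L)
        if (runif(1) < params$knockout_deletion_prob) {
          seq <- seq[-triad_pos[site]]
          fate <- "deleted"
        } else {
          aa_bad <- triad_res[site]
          alt <- SENSE_CODONS[GENETIC_CODE_TABLE[SENSE_CODONS] != aa_bad]
          seq[triad_pos[site]] <- sample(alt, 1L)
          fate <- "mutated"
        }
        active <- FALSE
      }
      cds <- paste(seq, collapse = "")
      strand <- sample(c("+", "-"), 1L)
      glen <- nchar(cds)
      start <- pos + 1L
      end <- pos + glen
      dna_parts <- c(dna_parts,
                     list(if (strand == "+") cds else reverse_complement(cds)),
                     list(paste(sample(c("A", "C", "G", "T"), 300L,
                                       replace = TRUE), collapse = "")))
      pos <- end + 300L
      gene_rows[[length(gene_rows) + 1L]] <- tibble(
        gene_id = gene_id, scaffold_id = scaf_id, start = start, end = end,
        strand = strand,
        cds_segments = list(cbind(start = start, end = end)),
        protein_id = paste0(gene_id, ".t1"), translatable = TRUE)
      truth[[length(truth) + 1L]] <- tibble(
        gene_id = gene_id, species = sp, family_member = g$family,
        origin = g$origin, scaffold_id = scaf_id, scaffold_rank = gi,
        active = if (g$family) active else NA,
        triad_fate = if (g$family) fate else NA_character_,
        cds = cds,
        decayed_in = list(if (g$family) decay_map[[g$origin]] %||%
                            character(0) else character(0)),
        site_omega = list(if (g$family) site_omega else numeric(0)))
      if (g$family) fam_ids <- c(fam_ids, gene_id)
    }
    scaffolds[[scaf_id]] <- paste(unlist(dna_parts), collapse = "")
  }
  genes <- dplyr::bind_rows(gene_rows)
  tr <- dplyr::bind_rows(truth)

  # definitional recount of array labels from the emitted layout
  tr$array_id <- NA_character_
  tr$arrayed_class <- ifelse(tr$family_member, "singleton", NA_character_)
  arr_n <- 0L
  for (scaf_id in unique(tr$scaffold_id)) {
    rows <- which(tr$scaffold_id == scaf_id)
    fam <- rows[tr$family_member[rows]]
    if (length(fam) < 2L) next
    ranks <- tr$scaffold_rank[fam]
    gaps <- diff(ranks) - 1L
    run_start <- 1L
    runs <- list()
    for (i in seq_along(gaps)) {
      if (gaps[i] > 9L) { runs <- c(runs, list(run_start:i)); run_start <- i + 1L }
    }
    runs <- c(runs, list(run_start:length(fam)))
    for (r in runs) {
      if (length(r) < 2L) next
      arr_n <- arr_n + 1L
      members <- fam[r]
      g <- gaps[r[-length(r)]]
      tr$array_id[members] <- sprintf("%s_A%02d", sp, arr_n)
      tr$arrayed_class[members] <- if (all(g == 0L)) "TAG" else "PAG"
    }
  }
  # dominant paralog
  tr$expr_tier <- ifelse(tr$family_member, "background", NA_character_)
  if (length(fam_ids) > 0) {
    dom <- sample(fam_ids, 1L)
    tr$expr_tier[tr$gene_id == dom] <- "dominant"
  }
  proteins <- setNames(vapply(tr$cds, function(s) translate_cds(s, "+"),
                              character(1)), paste0(tr$gene_id, ".t1"))
  cds <- setNames(tr$cds, paste0(tr$gene_id, ".t1"))
  tr$scaffold_rank <- NULL
  list(data = list(genes = genes, proteins = proteins, cds = cds,
                   scaffolds = scaffolds),
       truth = tr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulation to disk (FASTA/GFF3/TSV)
#'
#' @param sim A `cpfam_simulation`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$species)) {
    d <- sim$species[[sp]]
    write_fasta(tibble(id = names(d$proteins), description = "",
                       residues = unname(d$proteins)),
                file.path(out_dir, paste0(sp, "_proteins.faa")))
    write_fasta(tibble(id = names(d$cds), description = "",
                       residues = unname(d$cds)),
                file.path(out_dir, paste0(sp, "_cds.fna")))
    write_gff3(d$genes, file.path(out_dir, paste0(sp, ".gff3")))
  }
  truth <- sim$truth
  truth$decayed_in <- vapply(truth$decayed_in, paste, "", collapse = ",")
  truth$site_omega <- vapply(truth$site_omega, paste, "", collapse = ",")
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  echo <- utils::capture.output(utils::str(sim$params, give.attr = FALSE))
  writeLines(echo, file.path(out_dir, "params.txt"))
  invisible(out_dir)
}

#' Simulate an expression read set
#'
#' Reads are drawn from transcripts with probability proportional to tier
#' weight times transcript length, with uniform start positions and a fixed
#' quality string.
#'
#' @param transcripts Named character vector of transcript (CDS) sequences.
#' @param tiers Named character vector (`"dominant"`/`"background"`) aligned
#'   with `transcripts`.
#' @param depth Number of reads.
#' @param read_length Read length in bases; must not exceed the shortest
#'   transcript.
#' @param dominant_ratio Tier weight of a dominant transcript (default 10).
#' @param seed Integer seed.
#' @param out_fastq Optional path; if given, reads are also written as FASTQ.
#' @return Tibble `read_id`, `transcript_id` (truth), `seq`.
#' @export
simulate_reads <- function(transcripts, tiers, depth = 20000,
                           read_length = 75, dominant_ratio = 10, seed = 1,
                           out_fastq = NULL) {
  stopifnot(length(transcripts) >= 1, !is.null(names(transcripts)))
  tiers <- tiers[names(transcripts)]
  if (anyNA(tiers)) stop("config error: every transcript needs a tier")
  if (read_length > min(nchar(transcripts))) {
    stop("config error: read_length exceeds the shortest transcript")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  w <- ifelse(tiers == "dominant", dominant_ratio, 1) * nchar(transcripts)
  pick <- sample(names(transcripts), depth, replace = TRUE, prob = w)
  starts <- vapply(pick, function(t) {
    sample.int(nchar(transcripts[[t]]) - read_length + 1L, 1L)
  }, integer(1))
  reads <- tibble(
    read_id = sprintf("read%06d", seq_len(depth)),
    transcript_id = pick,
    seq = substring(transcripts[pick], starts, starts + read_length - 1L))
  if (!is.null(out_fastq)) write_fastq(reads, out_fastq)
  reads
}

#' Write reads as FASTQ (fixed quality)
#' @param reads Tibble with `read_id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  writeLines(rbind(paste0("@", reads$read_id), reads$seq, "+", qual), path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path Path to an uncompressed FASTQ file.
#' @return Tibble `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path)
  ids <- sub("^@", "", lines[seq(1, length(lines), 4)])
  tibble(read_id = sub("\\s.*$", "", ids),
         seq = lines[seq(2, length(lines), 4)])
}

#' Simulate an ELISA plate table
#'
#' Control optical densities are Normal(`control_mean`, `control_sd`)
#' truncated at 0; each sensitized subject's readings add a per-subject
#' effect drawn from `subject_effect_dist` to fresh control-like baselines.
#'
#' @param elisa Parameter list, see [syn_params()].
#' @param seed Integer seed.
#' @return Tibble `subject`, `group` (`control`/`sensitized`), `replicate`,
#'   `od`.
#' @export
simulate_elisa <- function(elisa = syn_params()$elisa, seed = 1) {
  stopifnot(elisa$control_sd >= 0, elisa$n_replicates >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(elisa$n_controls)) {
    od <- pmax(rnorm(elisa$n_replicates, elisa$control_mean,
                     elisa$control_sd), 0)
    rows[[length(rows) + 1L]] <- tibble(
      subject = sprintf("C%02d", i), group = "control",
      replicate = seq_len(elisa$n_replicates), od = od)
  }
  effects <- elisa$subject_effect_dist(elisa$n_subjects)
  for (i in seq_len(elisa$n_subjects)) {
    base <- pmax(rnorm(elisa$n_replicates, elisa$control_mean,
                       elisa$control_sd), 0)
    rows[[length(rows) + 1L]] <- tibble(
      subject = sprintf("S%02d", i), group = "sensitized",
      replicate = seq_len(elisa$n_replicates),
      od = pmax(base + effects[i], 0))
  }
  dplyr::bind_rows(rows)
}
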