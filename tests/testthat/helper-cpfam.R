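# Independent oracles used by the unit and acceptance tests. These are
# deliberately written against different machinery than the package code
# paths they check.

# ---- brute-force local alignment oracle ------------------------------------
# Enumerates every non-empty increasing matching between query and subject
# positions (all local alignments with affine gaps, grouped by their matched
# pairs), scores each with gap cost gap_open + k * gap_extend per gap run,
# and applies the tie chain: max score, min subject end, min query end, min
# alignment length, max matches.
oracle_local_align <- function(q, s, mat, gap_open = 11, gap_extend = 1) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  qi <- match(qc, rownames(mat)); si <- match(sc, colnames(mat))
  best <- list(score = 0, send = Inf, qend = Inf, alen = Inf, matches = 0,
               identity = 0)
  gapcost <- function(d) sum(ifelse(d > 0, gap_open + d * gap_extend, 0))
  for (k in seq_len(min(m, n))) {
    A <- utils::combn(m, k)
    B <- utils::combn(n, k)
    for (ai in seq_len(ncol(A))) {
      a <- A[, ai]
      gq <- if (k > 1) gapcost(diff(a) - 1) else 0
      sub_rows <- qi[a]
      for (bi in seq_len(ncol(B))) {
        b <- B[, bi]
        sc_pairs <- sum(mat[cbind(sub_rows, si[b])])
        gs <- if (k > 1) gapcost(diff(b) - 1) else 0
        score <- sc_pairs - gq - gs
        if (score <= 0) next
        alen <- k + sum(pmax(diff(a) - 1, 0)) + sum(pmax(diff(b) - 1, 0))
        matches <- sum(qc[a] == sc[b])
        cand <- list(score = score, send = b[k], qend = a[k], alen = alen,
                     matches = matches, identity = matches / alen)
        if (cand$score > best$score + 1e-9 ||
            (abs(cand$score - best$score) <= 1e-9 &&
             (cand$send < best$send ||
              (cand$send == best$send && cand$qend < best$qend) ||
              (cand$send == best$send && cand$qend == best$qend &&
               cand$alen < best$alen) ||
              (cand$send == best$send && cand$qend == best$qend &&
               cand$alen == best$alen && cand$matches > best$matches)))) {
          best <- cand
        }
      }
    }
  }
  best
}

# ---- exhaustive-topology least-squares oracle ------------------------------
# Scores every unrooted topology on the given taxa by ordinary least squares
# against the distance matrix and returns the best tree.
oracle_best_topology <- function(d) {
  taxa <- rownames(d)
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE,
                              tip.label = taxa)
  ss <- vapply(trees, function(tr) {
    X <- oracle_design_matrix(tr)
    dv <- oracle_pair_dists(d, tr)
    fit <- stats::lm.fit(X, dv)
    sum(fit$residuals^2)
  }, numeric(1))
  trees[[which.min(ss)]]
}

oracle_design_matrix <- function(tr) {
  ntip <- length(tr$tip.label)
  pairs <- utils::combn(ntip, 2)
  X <- matrix(0, ncol(pairs), nrow(tr$edge))
  for (p in seq_len(ncol(pairs))) {
    path <- oracle_tip_path(tr, pairs[1, p], pairs[2, p])
    X[p, path] <- 1
  }
  X
}

oracle_tip_path <- function(tr, i, j) {
  # edge indices on the path between tips i and j
  np <- ape::nodepath(tr, i, j)
  steps <- cbind(np[-length(np)], np[-1])
  vapply(seq_len(nrow(steps)), function(r) {
    w <- which((tr$edge[, 1] == steps[r, 1] & tr$edge[, 2] == steps[r, 2]) |
               (tr$edge[, 1] == steps[r, 2] & tr$edge[, 2] == steps[r, 1]))
    w[1]
  }, integer(1))
}

oracle_pair_dists <- function(d, tr) {
  ntip <- length(tr$tip.label)
  pairs <- utils::combn(ntip, 2)
  vapply(seq_len(ncol(pairs)), function(p) {
    d[tr$tip.label[pairs[1, p]], tr$tip.label[pairs[2, p]]]
  }, numeric(1))
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

random_additive_case <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_taxa, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.15, 1)
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

# ---- independent pathway-enumeration oracle (Nei-Gojobori) -----------------
# Uses seqinr for translation and its own permutation enumeration.
oracle_pair_pathways <- function(c1, c2) {
  tr <- function(cd) seqinr::translate(strsplit(cd, "")[[1]])
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(n_obs = 0, s_obs = 0))
  orders <- oracle_perms(pos)
  n_tot <- 0; s_tot <- 0; valid <- 0
  for (o in seq_len(nrow(orders))) {
    cur <- c1; n <- 0; s <- 0; ok <- TRUE
    for (p in orders[o, ]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (tr(nxt) == "*") { ok <- FALSE; break }
      if (tr(nxt) == tr(cur)) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { n_tot <- n_tot + n; s_tot <- s_tot + s; valid <- valid + 1 }
  }
  if (valid == 0) return(c(n_obs = length(pos), s_obs = 0))
  c(n_obs = n_tot / valid, s_obs = s_tot / valid)
}

oracle_perms <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- oracle_perms(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

# ---- misc fixtures ---------------------------------------------------------
random_protein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                  "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

small_sim_params <- function(seed = 7, ...) {
  syn_params(
    species_tree = "((A:0.08,B:0.08):0.05,(C:0.10,D:0.10):0.05);",
    n_scaffolds = 2, ancestral_family_size = 4, gene_length_codons = 150,
    n_spacer_genes = 24, seed = seed, ...)
}

sim_references <- function(sim) {
  tr <- sim$truth
  refs <- vapply(names(sim$species), function(sp) {
    fid <- tr$gene_id[tr$species == sp & tr$family_member][1]
    sim$species[[sp]]$proteins[[paste0(fid, ".t1")]]
  }, character(1))
  setNames(refs, paste0("ref_", names(sim$species)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mclust_ari <- function(a, b) mclust::adjustedRandIndex(a, b)
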