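# Progressive multiple alignment, distance phylogeny with bootstrap, and
# phylogenetic cluster extraction.

.as_msa_rows <- function(x) {
  rows <- if (is.data.frame(x)) {
    col <- if ("aligned" %in% names(x)) "aligned" else "residues"
    setNames(x[[col]], x$id)
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    x
  }
  if (length(unique(nchar(rows))) > 1L) {
    stop("MSA rows are not of equal length")
  }
  rows
}

new_msa <- function(ids, rows) {
  out <- tibble(id = ids, aligned = unname(rows))
  class(out) <- c("cpfam_msa", class(out))
  out
}

#' Remove gaps from MSA rows
#' @param msa MSA tibble or named character vector.
#' @return Named character vector of ungapped sequences.
#' @export
degap <- function(msa) {
  rows <- .as_msa_rows(msa)
  setNames(gsub("-", "", rows, fixed = TRUE), names(rows))
}

# column-frequency matrix (L x 20) of a set of gapped rows; gaps carry zero
# mass so a gap-heavy column scores weakly in profile merging
.profile_freq <- function(rows) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  t(apply(m, 2, function(col) {
    as.numeric(table(factor(col, levels = aa))) / length(col)
  }))
}

.merge_profiles <- function(rows1, rows2, sub20, gap_open, gap_extend) {
  f1 <- .profile_freq(rows1)
  f2 <- .profile_freq(rows2)
  S <- f1 %*% sub20 %*% t(f2)
  path <- cpp_global_affine(S, gap_open, gap_extend)
  build <- function(rows, col) {
    chars <- strsplit(rows, "", fixed = TRUE)
    vapply(chars, function(ch) {
      paste(ifelse(path[, col] == 0L, "-", ch[pmax(path[, col], 1L)]),
            collapse = "")
    }, character(1))
  }
  c(build(rows1, 1L), build(rows2, 2L))
}

#' Progressive multiple sequence alignment
#'
#' Pairwise identity distances (`d = 1 - identity` from local alignments)
#' feed a neighbor-joining guide tree; profiles are merged bottom-up by
#' sum-of-pairs dynamic programming under the same substitution matrix and
#' affine gap penalties as [smith_waterman()]. Deterministic for a fixed
#' input order.
#'
#' @param records A `read_fasta()` tibble or named character vector of
#'   protein sequences (>= 1).
#' @param substitution_matrix Default [blosum62()].
#' @param gap_open,gap_extend Affine gap penalties (defaults 11 and 1).
#' @return An MSA tibble (`id`, `aligned`) of class `cpfam_msa`, rows in the
#'   input order. Removing gaps from row i reproduces input sequence i.
#' @export
progressive_align <- function(records, substitution_matrix = blosum62(),
                              gap_open = 11, gap_extend = 1) {
  seqs <- .as_named_seqs(records)
  n <- length(seqs)
  stopifnot(n >= 1)
  if (n == 1L) return(new_msa(names(seqs), seqs))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sub20 <- substitution_matrix[aa, aa]
  if (n == 2L) {
    rows <- .merge_profiles(seqs[1], seqs[2], sub20, gap_open, gap_extend)
    return(new_msa(names(seqs), rows))
  }
  # guide tree on identity distances
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- smith_waterman(seqs[i], seqs[j], substitution_matrix,
                           gap_open, gap_extend)
      d[i, j] <- d[j, i] <- 1 - al$identity
    }
  }
  guide <- ape::nj(stats::as.dist(d))
  node_prof <- vector("list", guide$Nnode + n)
  for (i in seq_len(n)) node_prof[[i]] <- setNames(seqs[i], names(seqs)[i])
  # postorder merge of children at each internal node
  children <- split(guide$edge[, 2], guide$edge[, 1])
  visit <- function(node) {
    if (node <= n) return(node_prof[[node]])
    kids <- children[[as.character(node)]]
    prof <- NULL
    for (k in kids) {
      p <- visit(k)
      prof <- if (is.null(prof)) p
      else .merge_profiles(prof, p, sub20, gap_open, gap_extend)
    }
    node_prof[[node]] <<- prof
    prof
  }
  rows <- visit(n + 1L)
  rows <- rows[names(seqs)]
  new_msa(names(seqs), rows)
}

#' Filter MSA columns by coverage
#'
#' Keeps columns whose non-gap fraction is at least `min_coverage`. The
#' retained column indices are attached as attribute `kept_columns` for
#' coordinate lift-over.
#'
#' @param msa MSA tibble or named character vector.
#' @param min_coverage Minimum non-gap fraction per column (default 0.95).
#' @return Filtered MSA tibble with attribute `kept_columns`.
#' @export
filter_columns <- function(msa, min_coverage = 0.95) {
  rows <- .as_msa_rows(msa)
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  cov <- colMeans(m != "-")
  keep <- which(cov >= min_coverage)
  if (length(keep) == 0L) {
    stop("empty alignment: no column reaches coverage ", min_coverage)
  }
  out <- new_msa(names(rows),
                 apply(m[, keep, drop = FALSE], 1, paste, collapse = ""))
  attr(out, "kept_columns") <- keep
  out
}

#' Pairwise distances from an MSA
#'
#' Per-pair mismatch fraction p over columns where both rows are ungapped,
#' optionally Poisson-corrected (`d = -ln(1 - p)`). p is clamped at 0.95 so
#' corrected distances stay finite; pairs with no shared ungapped column get
#' the maximal distance.
#'
#' @param msa MSA tibble or named character vector.
#' @param correction `"poisson"` (default) or `"p"` for raw p-distance.
#' @return A symmetric distance matrix with row/column names.
#' @export
msa_distance <- function(msa, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  rows <- .as_msa_rows(msa)
  n <- length(rows)
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  p_cap <- 0.95
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      p <- if (!any(ok)) p_cap else min(mean(m[i, ok] != m[j, ok]), p_cap)
      d[i, j] <- d[j, i] <- if (correction == "poisson") -log(1 - p) else p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero with the total deficit recorded in attribute
#' `negative_length_deficit`.
#'
#' @param distance_matrix Symmetric numeric matrix (or `dist`) with zero
#'   diagonal; at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) < 3L) stop("degenerate tree: need at least 3 taxa")
  stopifnot(isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
            all(is.finite(d)), all(diag(d) == 0))
  tr <- ape::nj(stats::as.dist(d))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "negative_length_deficit") <- deficit
  tr
}

#' Build a tree from an MSA (coverage filter + corrected distances + NJ)
#'
#' @param msa MSA tibble or named character vector.
#' @param min_coverage Column coverage threshold (default 0.95).
#' @param correction Distance correction, see [msa_distance()].
#' @return An unrooted `phylo` tree.
#' @export
build_tree <- function(msa, min_coverage = 0.95, correction = "poisson") {
  flt <- filter_columns(msa, min_coverage)
  neighbor_joining(msa_distance(flt, correction))
}

#' Bootstrap support for an MSA-derived tree
#'
#' `B` column resamples (with replacement) of the alignment; the support of
#' each internal edge is the percentage of replicate trees containing the
#' same bipartition, written into `node.label`. An alignment of identical
#' sequences collapses to a star tree whose single internal node is assigned
#' support 100 by convention.
#'
#' @param msa MSA tibble or named character vector.
#' @param tree_builder Function mapping a character matrix (taxa x columns)
#'   to a `phylo`; the default rebuilds with [build_tree()] machinery without
#'   the coverage filter (resampling already respects it upstream).
#' @param B Number of replicates (default 100).
#' @param seed Integer seed.
#' @return The tree from the full alignment with `node.label` supports
#'   (percentages in \eqn{[0, 100]}).
#' @export
bootstrap_support <- function(msa, tree_builder = NULL, B = 100, seed = 1) {
  rows <- .as_msa_rows(msa)
  if (length(unique(rows)) == 1L) {
    txt <- paste0("(", paste(names(rows), collapse = ","), ");")
    tr <- ape::read.tree(text = txt)
    tr$node.label <- "100"
    tr$edge.length <- rep(0, nrow(tr$edge))
    return(tr)
  }
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- names(rows)
  if (is.null(tree_builder)) {
    tree_builder <- function(mat) {
      msa_i <- setNames(apply(mat, 1, paste, collapse = ""), rownames(mat))
      neighbor_joining(msa_distance(msa_i))
    }
  }
  phy <- tree_builder(m)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- ape::boot.phylo(phy, m, tree_builder, B = B, quiet = TRUE,
                            rooted = FALSE)
  support <- round(100 * counts / B)
  support[1] <- NA  # root of the unrooted representation
  phy$node.label <- as.character(support)
  phy
}

#' Extract clade clusters by removing the longest internal edges
#'
#' The tree is midpoint-rooted (display convention only); the
#' `n_clusters - 1` longest internal edges are removed and the resulting
#' leaf groups of size >= 2 become clusters labelled `C1`, `C2`, ... in
#' decreasing size. Singleton leaves are reported as outliers.
#'
#' @param tree A `phylo` with branch lengths.
#' @param n_clusters Number of partitions to aim for (default 5).
#' @return Tibble `id`, `cluster` (`NA` for outliers); outlier ids also in
#'   attribute `outliers`.
#' @export
extract_clusters <- function(tree, n_clusters = 5) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ntip <- length(tree$tip.label)
  if (n_clusters == 1L) {
    out <- tibble(id = tree$tip.label, cluster = "C1")
    attr(out, "outliers") <- character(0)
    return(out)
  }
  rooted <- phangorn::midpoint(tree)
  edge <- rooted$edge
  len <- rooted$edge.length
  internal <- which(edge[, 2] > ntip)
  if (n_clusters > length(internal) + 1L) {
    stop("config error: n_clusters exceeds internal edge count + 1")
  }
  cut <- internal[order(-len[internal], internal)][seq_len(n_clusters - 1L)]
  # connected components of the remaining edges
  keep <- setdiff(seq_len(nrow(edge)), cut)
  nn <- max(edge)
  parent <- seq_len(nn)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in keep) {
    a <- find(edge[e, 1]); b <- find(edge[e, 2])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(ntip), function(i) find(i), integer(1))
  groups <- split(rooted$tip.label[seq_len(ntip)], comp)
  sizes <- lengths(groups)
  big <- groups[sizes >= 2]
  ord <- order(-lengths(big), vapply(big, function(g) sort(g)[1], ""))
  big <- big[ord]
  labels <- setNames(rep(NA_character_, ntip), rooted$tip.label)
  for (k in seq_along(big)) labels[big[[k]]] <- paste0("C", k)
  out <- tibble(id = tree$tip.label,
                cluster = unname(labels[tree$tip.label]))
  attr(out, "outliers") <- tree$tip.label[is.na(out$cluster)]
  out
}
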