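# Homology search: local alignment, decoy-calibrated screening, PSSM profile
# scan, cross-reactivity prediction and MS-peptide mapping.

.cpfam_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix (25 x 25, including B/J/Z/X and `*`), as
#' distributed with Biostrings.
#'
#' @return A numeric matrix with amino-acid dimnames.
#' @export
blosum62 <- function() {
  if (is.null(.cpfam_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .cpfam_env$blosum62 <- e$BLOSUM62
  }
  .cpfam_env$blosum62
}

.encode_protein <- function(seq, mat, id = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, rownames(mat))
  if (anyNA(idx)) {
    stop("alphabet error: '", id, "' has residue(s) not in the ",
         "substitution matrix: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

#' Optimal local alignment with affine gaps (Smith-Waterman)
#'
#' Affine gap cost: a gap of length k costs `gap_open + k * gap_extend`
#' (BLAST convention). Ties between co-optimal alignments are broken by the
#' earliest subject end, then the earliest query end, then the shortest
#' alignment. Identity is `matches / alignment_length` with the alignment
#' length counting gap columns (BLAST convention).
#'
#' @param query,subject Protein strings, or length-1 named character vectors
#'   (names become `query_id`/`subject_id`).
#' @param substitution_matrix Scoring matrix; default [blosum62()].
#' @param gap_open,gap_extend Positive gap penalties; defaults 11 and 1.
#' @return A one-row tibble: `query_id`, `subject_id`, `score`, `matches`,
#'   `alignment_length`, `identity`, `qstart`, `qend`, `sstart`, `send`, and
#'   `aligned_pairs` (list column of two-column matrices of 1-based aligned
#'   positions). A pair with no positive-scoring cell yields score 0 and an
#'   empty alignment.
#' @export
smith_waterman <- function(query, subject, substitution_matrix = blosum62(),
                           gap_open = 11, gap_extend = 1) {
  stopifnot(gap_open >= gap_extend, gap_extend > 0)
  qid <- if (!is.null(names(query))) names(query)[1] else "query"
  sid <- if (!is.null(names(subject))) names(subject)[1] else "subject"
  q <- unname(query[[1]]); s <- unname(subject[[1]])
  if (nchar(q) == 0L || nchar(s) == 0L) {
    stop("empty input: both sequences must be non-empty")
  }
  qi <- .encode_protein(q, substitution_matrix, qid)
  si <- .encode_protein(s, substitution_matrix, sid)
  res <- cpp_sw_align(qi, si, substitution_matrix, gap_open, gap_extend)
  pairs <- res$pairs
  matches <- if (nrow(pairs) == 0L) 0L else {
    qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
    sum(qc[pairs[, 1]] == sc[pairs[, 2]])
  }
  alen <- res$align_len
  tibble(
    query_id = qid, subject_id = sid, score = res$score,
    matches = as.integer(matches), alignment_length = as.integer(alen),
    identity = if (alen > 0) matches / alen else 0,
    qstart = if (nrow(pairs)) pairs[1, 1] else NA_integer_,
    qend = if (nrow(pairs)) pairs[nrow(pairs), 1] else NA_integer_,
    sstart = if (nrow(pairs)) pairs[1, 2] else NA_integer_,
    send = if (nrow(pairs)) pairs[nrow(pairs), 2] else NA_integer_,
    aligned_pairs = list(pairs)
  )
}

#' Calibrate a raw-score acceptance threshold on shuffled decoys
#'
#' Replaces an E-value cutoff with a deterministic raw-score threshold: decoy
#' sequences are residue-shuffles of the supplied pool, each aligned to a
#' randomly chosen reference, and the threshold is an upper quantile of the
#' decoy score distribution.
#'
#' @param references Named character vector of reference proteins.
#' @param decoy_pool Named character vector of sequences to shuffle (typically
#'   the proteome under study).
#' @param n_shuffles Number of decoy alignments (default 1000).
#' @param probs Quantile of the decoy scores (default 0.999).
#' @param seed Integer seed for reproducibility.
#' @return The score threshold (numeric scalar).
#' @export
calibrate_score_threshold <- function(references, decoy_pool,
                                      n_shuffles = 1000, probs = 0.999,
                                      seed = 1) {
  stopifnot(length(references) >= 1, length(decoy_pool) >= 1)
  mat <- blosum62()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  scores <- vapply(seq_len(n_shuffles), function(i) {
    src <- decoy_pool[[sample.int(length(decoy_pool), 1)]]
    dec <- paste(sample(strsplit(src, "")[[1]]), collapse = "")
    ref <- references[sample.int(length(references), 1)]
    smith_waterman(c(decoy = dec), ref, mat)$score
  }, numeric(1))
  unname(quantile(scores, probs, type = 7))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Screen a proteome for family members against reference allergens
#'
#' Aligns every protein to every reference with [smith_waterman()] and keeps
#' proteins whose best alignment reaches `min_identity` and `min_score`. The
#' top-scoring protein for each reference is flagged the putative group 1
#' allergen of that proteome.
#'
#' @param proteome A tibble from [read_fasta()] (columns `id`, `residues`) or
#'   a named character vector.
#' @param references Named character vector (or `read_fasta()` tibble) of
#'   reference allergen proteins.
#' @param min_identity Minimum identity of the best alignment (default 0.30).
#' @param min_score Minimum raw score; if `NULL`, calibrated with
#'   [calibrate_score_threshold()] on the proteome itself.
#' @param ... Passed to [smith_waterman()].
#' @return A tibble with one row per (protein, best reference): `protein_id`,
#'   `best_reference`, `score`, `identity`, `alignment_length`, `is_family`,
#'   `is_top_match`, `near_threshold` (identity within 0.02 of the cutoff,
#'   logged for audit). Row order follows the sorted protein ids, so results
#'   are invariant to input order.
#' @export
screen_proteome <- function(proteome, references, min_identity = 0.30,
                            min_score = NULL, ...) {
  prot <- .as_named_seqs(proteome)
  refs <- .as_named_seqs(references)
  stopifnot(length(refs) >= 1)
  if (is.null(min_score)) {
    min_score <- calibrate_score_threshold(refs, prot)
  }
  prot <- prot[order(names(prot))]
  rows <- lapply(names(prot), function(pid) {
    hits <- dplyr::bind_rows(lapply(names(refs), function(rid) {
      smith_waterman(setNames(prot[pid], pid), setNames(refs[rid], rid), ...)
    }))
    best <- hits[order(-hits$score, hits$subject_id), ][1, ]
    tibble(protein_id = pid, best_reference = best$subject_id,
           score = best$score, identity = best$identity,
           alignment_length = best$alignment_length)
  })
  out <- dplyr::bind_rows(rows)
  out$is_family <- out$identity >= min_identity & out$score >= min_score
  # top match per reference among family hits
  out$is_top_match <- FALSE
  fam <- out[out$is_family, ]
  if (nrow(fam) > 0) {
    top <- fam |>
      dplyr::group_by(.data$best_reference) |>
      dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    out$is_top_match <- out$protein_id %in% top$protein_id & out$is_family
  }
  out$near_threshold <- abs(out$identity - min_identity) < 0.02
  attr(out, "min_score") <- min_score
  attr(out, "min_identity") <- min_identity
  class(out) <- c("cpfam_screen", class(out))
  out
}

.as_named_seqs <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "residues") %in% names(x)))
    setNames(x$residues, x$id)
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    x
  }
}

#' Build a position-specific scoring model from a reference alignment
#'
#' Per-column log-odds scores from pseudocount-smoothed residue frequencies
#' against a background distribution. Columns that are gap in the majority of
#' rows are removed; an all-gap column is dropped with a warning.
#'
#' @param reference_msa An MSA tibble (see [progressive_align()]) or named
#'   character vector of equal-length gapped rows; at least 2 rows.
#' @param pseudocount_weight Positive pseudocount mass (default 1).
#' @param background Named amino-acid frequency vector summing to 1; default
#'   the uniform distribution over the 20 standard residues.
#' @return An object of class `cpfam_profile`: list with `scores` (L x 20
#'   log2-odds matrix), `background`, `pseudocount_weight`, `kept_columns`.
#' @export
build_profile <- function(reference_msa, pseudocount_weight = 1,
                          background = NULL) {
  rows <- .as_msa_rows(reference_msa)
  stopifnot(length(rows) >= 2, pseudocount_weight > 0)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), aa)
  stopifnot(abs(sum(background) - 1) < 1e-8)
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  gap_frac <- colMeans(m == "-")
  if (any(gap_frac == 1)) {
    warning("dropping ", sum(gap_frac == 1), " all-gap column(s)")
  }
  keep <- which(gap_frac <= 0.5)
  m <- m[, keep, drop = FALSE]
  w <- pseudocount_weight
  scores <- t(apply(m, 2, function(col) {
    col <- col[col != "-"]
    cnt <- table(factor(col, levels = aa))
    f <- (as.numeric(cnt) / max(length(col), 1) + w * background[aa]) / (1 + w)
    log2(f / background[aa])
  }))
  colnames(scores) <- aa
  structure(list(scores = scores, background = background,
                 pseudocount_weight = w, kept_columns = keep),
            class = "cpfam_profile")
}

#' Scan a proteome with a position-specific scoring model
#'
#' Each protein is scored by the best ungapped placement of the profile along
#' the sequence (sliding window equal to the profile length; proteins shorter
#' than the profile are scored at their best offset within it). Residues
#' outside the 20-letter alphabet score 0.
#'
#' @param profile A `cpfam_profile` from [build_profile()].
#' @param proteome Named character vector or `read_fasta()` tibble.
#' @param score_threshold Keep proteins scoring at least this; `NULL` keeps
#'   all, with scores reported.
#' @return Tibble `protein_id`, `score`, `offset` (1-based start of the best
#'   window in the protein), `hit`.
#' @export
profile_scan <- function(profile, proteome, score_threshold = NULL) {
  stopifnot(inherits(profile, "cpfam_profile"))
  prot <- .as_named_seqs(proteome)
  S <- profile$scores
  L <- nrow(S)
  aa <- colnames(S)
  res <- lapply(names(prot), function(pid) {
    chars <- strsplit(prot[[pid]], "")[[1]]
    n <- length(chars)
    idx <- match(chars, aa)
    if (n >= L) {
      offs <- seq_len(n - L + 1L)
      sc <- vapply(offs, function(o) {
        j <- idx[o:(o + L - 1L)]
        ok <- !is.na(j)
        sum(S[cbind(which(ok), j[ok])])
      }, numeric(1))
    } else {
      # slide the (shorter) protein within the profile
      offs <- seq_len(L - n + 1L)
      sc <- vapply(offs, function(o) {
        ok <- !is.na(idx)
        sum(S[cbind(o + which(ok) - 1L, idx[ok])])
      }, numeric(1))
    }
    best <- which.max(sc)
    tibble(protein_id = pid, score = sc[best], offset = as.integer(best))
  })
  out <- dplyr::bind_rows(res)
  out$hit <- if (is.null(score_threshold)) TRUE else out$score >= score_threshold
  out
}

#' Cross-validate alignment screening against a profile scan
#'
#' @param screen_hits Result of [screen_proteome()].
#' @param scan_hits Result of [profile_scan()].
#' @return Tibble `protein_id`, `in_screen`, `in_scan`, `agreement`.
#' @export
compare_hit_sets <- function(screen_hits, scan_hits) {
  ids <- sort(union(screen_hits$protein_id, scan_hits$protein_id))
  tibble(
    protein_id = ids,
    in_screen = ids %in% screen_hits$protein_id[screen_hits$is_family],
    in_scan = ids %in% scan_hits$protein_id[scan_hits$hit]
  ) |>
    dplyr::mutate(agreement = .data$in_screen == .data$in_scan)
}

#' Predict allergen cross-reactivity from sequence identity
#'
#' Two proteins are flagged potentially cross-reactive when they share at
#' least `min_identity` sequence identity over a local alignment of at least
#' `min_length` amino acids (the WHO/FAO 35%/80-residue rule). Sequences
#' shorter than `min_length` give a `not_evaluable` status rather than a
#' negative call.
#'
#' @param a,b Protein strings (optionally named).
#' @param min_identity Identity threshold (default 0.35).
#' @param min_length Minimum alignment length in residues (default 80).
#' @param ... Passed to [smith_waterman()].
#' @return One-row tibble: `id_a`, `id_b`, `identity`, `alignment_length`,
#'   `cross_reactive` (logical, `NA` when not evaluable), `status`.
#' @export
predict_cross_reactivity <- function(a, b, min_identity = 0.35,
                                     min_length = 80, ...) {
  ida <- if (!is.null(names(a))) names(a)[1] else "a"
  idb <- if (!is.null(names(b))) names(b)[1] else "b"
  if (nchar(a[[1]]) < min_length || nchar(b[[1]]) < min_length) {
    return(tibble(id_a = ida, id_b = idb, identity = NA_real_,
                  alignment_length = NA_integer_, cross_reactive = NA,
                  status = "not_evaluable"))
  }
  al <- smith_waterman(a, b, ...)
  tibble(id_a = ida, id_b = idb, identity = al$identity,
         alignment_length = al$alignment_length,
         cross_reactive = al$identity >= min_identity &
           al$alignment_length >= min_length,
         status = "evaluated")
}

#' Map MS peptides onto a protein set
#'
#' Exact substring matching with isoleucine and leucine treated as
#' equivalent (they are isobaric in MS). A peptide is "unique to" a protein
#' when it matches exactly one protein in the set.
#'
#' @param peptides Character vector of peptide strings (length >= 6), named
#'   or unnamed (unnamed peptides are labelled `pep1`, `pep2`, ...).
#' @param proteins Named character vector or `read_fasta()` tibble.
#' @return Tibble `peptide_id`, `peptide`, `n_matches`, `protein_ids`
#'   (list column), `unique_to` (`NA` unless exactly one match).
#' @export
map_peptides <- function(peptides, proteins) {
  prot <- .as_named_seqs(proteins)
  if (is.null(names(peptides))) {
    names(peptides) <- paste0("pep", seq_along(peptides))
  }
  stopifnot(all(nchar(peptides) >= 6))
  prot_il <- chartr("I", "L", prot)
  rows <- lapply(names(peptides), function(pid) {
    pat <- chartr("I", "L", peptides[[pid]])
    hit <- names(prot)[grepl(pat, prot_il, fixed = TRUE)]
    tibble(peptide_id = pid, peptide = unname(peptides[[pid]]),
           n_matches = length(hit), protein_ids = list(hit),
           unique_to = if (length(hit) == 1L) hit else NA_character_)
  })
  dplyr::bind_rows(rows)
}
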