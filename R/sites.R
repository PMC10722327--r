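# Catalytic-triad mapping, linear-epitope mapping and protein-to-codon MSA
# threading.

#' Define a catalytic-triad specification
#'
#' Positions are 1-based residue indices in the (ungapped) reference
#' sequence, in C-H-N order; they are lifted through the alignment at
#' mapping time. Positions are supplied rather than hard-coded because
#' triad numbering depends on whether preprotein or mature-chain coordinates
#' are used.
#'
#' @param reference_id MSA row id of the reference sequence.
#' @param positions Strictly increasing integer triple.
#' @param expected_residues Expected residues at the three sites (default
#'   `c("C", "H", "N")`).
#' @return A list of class `cpfam_triad_spec`.
#' @export
triad_spec <- function(reference_id, positions,
                       expected_residues = c("C", "H", "N")) {
  stopifnot(length(positions) == 3, all(diff(positions) > 0),
            length(expected_residues) == 3)
  structure(list(reference_id = reference_id,
                 positions = as.integer(positions),
                 expected_residues = expected_residues),
            class = "cpfam_triad_spec")
}

# lift ungapped residue positions of one row to MSA column indices
.lift_positions <- function(row, positions) {
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  residue_idx <- cumsum(chars != "-")
  vapply(positions, function(p) {
    w <- which(residue_idx == p & chars != "-")
    if (length(w) == 0L) stop("position ", p, " beyond the reference row")
    w[1]
  }, integer(1))
}

#' Map catalytic triads through an alignment and call activity
#'
#' The triad positions of the reference are lifted to alignment columns;
#' each row's residue at each triad column is classified `conserved`
#' (equals the expected residue), `mutated` (any other residue, including
#' conservative replacements) or `deleted` (gap). A gene is active iff all
#' three sites are conserved.
#'
#' @param msa MSA tibble or named character vector containing the reference
#'   row.
#' @param spec A [triad_spec()].
#' @return Tibble of class `cpfam_triad`: `gene_id`, `site_c`, `site_h`,
#'   `site_n` (states), `residues` (observed triple as a string), `active`.
#' @export
map_triad <- function(msa, spec) {
  stopifnot(inherits(spec, "cpfam_triad_spec"))
  rows <- .as_msa_rows(msa)
  if (!spec$reference_id %in% names(rows)) {
    stop("bad spec: reference '", spec$reference_id, "' is not an MSA row")
  }
  cols <- .lift_positions(rows[[spec$reference_id]], spec$positions)
  ref_res <- substring(rows[[spec$reference_id]], cols, cols)
  if (!all(ref_res == spec$expected_residues)) {
    stop("bad spec: reference residues (", paste(ref_res, collapse = ""),
         ") do not match expected (",
         paste(spec$expected_residues, collapse = ""), ")")
  }
  state <- function(obs, exp) {
    dplyr::case_when(obs == exp ~ "conserved",
                     obs == "-" ~ "deleted",
                     TRUE ~ paste0("mutated(", obs, ")"))
  }
  obs <- t(vapply(rows, function(r) substring(r, cols, cols), character(3)))
  out <- tibble(
    gene_id = names(rows),
    site_c = state(obs[, 1], spec$expected_residues[1]),
    site_h = state(obs[, 2], spec$expected_residues[2]),
    site_n = state(obs[, 3], spec$expected_residues[3]),
    residues = paste0(obs[, 1], obs[, 2], obs[, 3]))
  out$active <- out$site_c == "conserved" & out$site_h == "conserved" &
    out$site_n == "conserved"
  class(out) <- c("cpfam_triad", class(out))
  out
}

#' Map linear epitopes through an alignment
#'
#' Each epitope is located in its source row by exact substring match, its
#' columns are lifted through the MSA, and every other row is scored by the
#' identity fraction over those columns (a gap counts as a mismatch).
#' Classes: `conserved` at identity 1, `partial` at or above
#' `partial_threshold`, else `divergent`.
#'
#' @param msa MSA tibble or named character vector.
#' @param epitopes Tibble with columns `epitope_id`, `source_id` (an MSA row
#'   id), `peptide`.
#' @param partial_threshold Identity at or above which an epitope is called
#'   partially conserved (default 0.5).
#' @return Tibble `epitope_id`, `source_id`, `homolog_id`, `identity`,
#'   `class`, `ref_start`, `ref_end` (epitope span in ungapped source
#'   coordinates).
#' @export
map_epitopes <- function(msa, epitopes, partial_threshold = 0.5) {
  rows <- .as_msa_rows(msa)
  out <- list()
  for (i in seq_len(nrow(epitopes))) {
    ep <- epitopes[i, ]
    if (!ep$source_id %in% names(rows)) {
      stop("epitope source '", ep$source_id, "' is not an MSA row")
    }
    src_ungapped <- gsub("-", "", rows[[ep$source_id]], fixed = TRUE)
    loc <- regexpr(ep$peptide, src_ungapped, fixed = TRUE)
    if (loc == -1L) {
      stop("epitope location error: '", ep$epitope_id,
           "' not found in source row '", ep$source_id, "'")
    }
    span <- seq(loc, loc + nchar(ep$peptide) - 1L)
    cols <- .lift_positions(rows[[ep$source_id]], span)
    src_res <- substring(rows[[ep$source_id]], cols, cols)
    for (hid in setdiff(names(rows), ep$source_id)) {
      res <- substring(rows[[hid]], cols, cols)
      ident <- mean(res == src_res)
      cls <- if (ident == 1) "conserved"
      else if (ident >= partial_threshold) "partial"
      else "divergent"
      out[[length(out) + 1L]] <- tibble(
        epitope_id = ep$epitope_id, source_id = ep$source_id,
        homolog_id = hid, identity = ident, class = cls,
        ref_start = as.integer(loc),
        ref_end = as.integer(loc + nchar(ep$peptide) - 1L))
    }
  }
  dplyr::bind_rows(out)
}

#' Thread a protein alignment onto coding sequences
#'
#' Each residue in the protein MSA is replaced by its codon and each gap by
#' `"---"`, producing a codon alignment three times the protein alignment
#' length. The translation of every CDS must match its ungapped protein row
#' exactly.
#'
#' @param protein_msa MSA tibble or named character vector.
#' @param cds_by_id Named character vector of coding sequences (same ids as
#'   the MSA rows; a terminal stop codon is permitted and trimmed).
#' @return Codon MSA as a named character vector (class preserved as a
#'   `cpfam_msa` tibble).
#' @export
thread_codons <- function(protein_msa, cds_by_id) {
  rows <- .as_msa_rows(protein_msa)
  out <- vapply(names(rows), function(id) {
    if (!id %in% names(cds_by_id)) {
      stop("threading error: no CDS for row '", id, "'")
    }
    cds <- cds_by_id[[id]]
    prot <- gsub("-", "", rows[[id]], fixed = TRUE)
    tr <- translate_cds(cds, "+")
    if (tr != prot) {
      diff_at <- which(strsplit(tr, "")[[1]] != strsplit(prot, "")[[1]])[1]
      stop("threading error: translation of '", id,
           "' mismatches the MSA row at residue ",
           ifelse(is.na(diff_at), nchar(tr), diff_at))
    }
    codons <- substring(cds, seq(1, nchar(prot) * 3, 3),
                        seq(3, nchar(prot) * 3, 3))
    chars <- strsplit(rows[[id]], "", fixed = TRUE)[[1]]
    ci <- cumsum(chars != "-")
    paste(ifelse(chars == "-", "---", codons[ci]), collapse = "")
  }, character(1))
  new_msa(names(rows), out)
}
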