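# Sequence and annotation input/output.
#
# All coordinates are GFF3-style 1-based inclusive throughout the package; any
# half-open conversion (e.g. BED export) is performed locally at the writer.

PROTEIN_CHARS <- "ACDEFGHIKLMNPQRSTVWYBJZXUO*"
DNA_CHARS <- "ACGTUNRYSWKMBDHV"

#' Read a FASTA file into a tibble of sequence records
#'
#' One row per record. Header lines are split at the first whitespace into
#' `id` and `description`; residues are concatenated across wrapped lines and
#' upper-cased. The alphabet of each record is validated against IUPAC codes.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"auto"` (default), `"protein"` or `"dna"`. With `"auto"`
#'   a record is called DNA when every residue is an IUPAC nucleotide code,
#'   protein otherwise.
#' @return A tibble with columns `id`, `description`, `residues`, `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("auto", "protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("failed to parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty input: no records in FASTA '", path, "'")
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- unname(toupper(as.character(set)))
  if (any(!nzchar(residues))) {
    stop("empty sequence for record: ",
         paste(id[!nzchar(residues)], collapse = ", "))
  }
  rec_alpha <- vapply(seq_along(residues), function(i) {
    .check_alphabet(residues[[i]], id[[i]], alphabet)
  }, character(1))
  tibble(id = id, description = description, residues = residues,
         alphabet = rec_alpha)
}

.check_alphabet <- function(seq, id, alphabet) {
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  is_dna <- all(chars %in% strsplit(DNA_CHARS, "")[[1]])
  # IUPAC ambiguity codes are a subset of the amino-acid alphabet, so
  # auto-detection only calls DNA on unambiguous nucleotides
  is_plain_dna <- all(chars %in% c("A", "C", "G", "T", "U", "N"))
  is_prot <- all(chars %in% strsplit(PROTEIN_CHARS, "")[[1]])
  if (alphabet == "dna") {
    if (!is_dna) stop("alphabet error: record '", id,
                      "' contains non-nucleotide characters")
    return("dna")
  }
  if (alphabet == "protein") {
    if (!is_prot) stop("alphabet error: record '", id,
                       "' contains non-amino-acid characters")
    return("protein")
  }
  if (is_plain_dna) "dna"
  else if (is_prot) "protein"
  else stop("alphabet error: record '", id, "' contains illegal characters")
}

#' Write sequence records to FASTA with 60-column wrapping
#'
#' @param records A tibble as returned by [read_fasta()], or any data frame
#'   with `id`, `residues` and optionally `description` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  nm <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(setNames(records$residues, nm))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA` and `CDS` features linked through `ID`/`Parent`
#' attributes into one row per gene. When a gene carries several transcripts
#' the one with the longest total CDS is taken as the representative. CDS
#' segments are sorted by start; coordinates stay 1-based inclusive.
#'
#' Genes whose total CDS length is not divisible by 3 are kept but flagged
#' `translatable = FALSE` with a warning, mirroring manual-curation practice.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `scaffold_id`, `start`, `end`,
#'   `strand`, `cds_segments` (list of two-column matrices), `protein_id`,
#'   `translatable`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty input: no features in GFF3 '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) != 9L
  if (any(bad)) stop("malformed GFF3 line(s) at ", which(bad)[1])
  feat <- tibble(
    scaffold_id = vapply(fields, `[[`, "", 1L),
    type = vapply(fields, `[[`, "", 3L),
    start = as.integer(vapply(fields, `[[`, "", 4L)),
    end = as.integer(vapply(fields, `[[`, "", 5L)),
    strand = vapply(fields, `[[`, "", 7L),
    attr = vapply(fields, `[[`, "", 9L)
  )
  feat$id <- .gff_attr(feat$attr, "ID")
  feat$parent <- .gff_attr(feat$attr, "Parent")
  feat$protein_id <- .gff_attr(feat$attr, "protein_id")

  genes <- feat[feat$type == "gene", ]
  mrnas <- feat[feat$type == "mRNA", ]
  cdss <- feat[feat$type == "CDS", ]
  if (nrow(genes) == 0L) stop("no gene features in GFF3 '", path, "'")

  # resolve each CDS to a gene, directly or through its mRNA
  mrna_gene <- setNames(mrnas$parent, mrnas$id)
  cds_tx <- cdss$parent
  cds_gene <- ifelse(cds_tx %in% genes$id, cds_tx,
                     unname(mrna_gene[cds_tx]))
  if (anyNA(cds_gene) || any(!cds_gene %in% genes$id)) {
    orphan <- cdss$parent[is.na(cds_gene) | !cds_gene %in% genes$id][1]
    stop("orphan feature: CDS with unresolvable parent '", orphan, "'")
  }
  cdss$gene <- cds_gene

  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gc <- cdss[cdss$gene == g$id, , drop = FALSE]
    if (nrow(gc) == 0L) return(NULL)
    # representative transcript = longest total CDS
    by_tx <- split(gc, gc$parent)
    lens <- vapply(by_tx, function(t) sum(t$end - t$start + 1L), integer(1))
    best <- by_tx[[order(-lens, names(by_tx))[1]]]
    best <- best[order(best$start), , drop = FALSE]
    seg <- cbind(start = best$start, end = best$end)
    prot <- best$protein_id[!is.na(best$protein_id)][1]
    if (is.na(prot)) prot <- best$parent[1]
    total <- sum(seg[, "end"] - seg[, "start"] + 1L)
    ok <- total %% 3L == 0L
    if (!ok) warning("CDS length of gene '", g$id,
                     "' not divisible by 3; flagged not-translatable")
    tibble(gene_id = g$id, scaffold_id = g$scaffold_id,
           start = g$start, end = g$end, strand = g$strand,
           cds_segments = list(seg), protein_id = prot, translatable = ok)
  })
  dplyr::bind_rows(out)
}

.gff_attr <- function(attr, key) {
  m <- regmatches(attr, regexpr(paste0("(^|;)", key, "=[^;]*"), attr))
  has <- grepl(paste0("(^|;)", key, "="), attr)
  out <- rep(NA_character_, length(attr))
  out[has] <- sub(paste0("^;?", key, "="), "", m)
  out
}

#' Write gene models to GFF3
#'
#' Emits the `##gff-version 3` pragma followed by gene/mRNA/CDS rows for each
#' gene model, in input order. The mRNA ID is the gene's `protein_id` so that
#' round-tripping through [read_gff3()] is exact.
#'
#' @param genes A gene-model tibble as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    seg <- g$cds_segments[[1]]
    lines <- c(
      paste(g$scaffold_id, "cpfam", "gene", g$start, g$end, ".", g$strand,
            ".", paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$scaffold_id, "cpfam", "mRNA", g$start, g$end, ".", g$strand,
            ".", paste0("ID=", g$protein_id, ";Parent=", g$gene_id),
            sep = "\t"),
      paste(g$scaffold_id, "cpfam", "CDS", seg[, "start"], seg[, "end"],
            ".", g$strand, "0",
            paste0("ID=", g$protein_id, ".cds;Parent=", g$protein_id),
            sep = "\t")
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Reverse-complement a DNA sequence
#'
#' @param seq A DNA string (IUPAC codes allowed).
#' @return The reverse complement string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a coding sequence under the standard genetic code
#'
#' Minus-strand sequences are reverse-complemented before translation. An
#' internal stop codon is an error reporting the codon index; a terminal stop
#' is trimmed.
#'
#' @param seq A CDS string; length must be divisible by 3.
#' @param strand `"+"` or `"-"`.
#' @return The protein string.
#' @export
translate_cds <- function(seq, strand = "+") {
  if (nchar(seq) == 0L) stop("empty input: zero-length CDS")
  if (nchar(seq) %% 3L != 0L) {
    stop("CDS length ", nchar(seq), " not divisible by 3")
  }
  if (strand == "-") seq <- reverse_complement(seq)
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  aa <- unname(GENETIC_CODE_TABLE[codons])
  if (anyNA(aa)) {
    aa[is.na(aa)] <- "X"  # ambiguous nucleotide codes
  }
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  stops <- which(aa == "*")
  if (length(stops) > 0L) {
    stop("premature stop codon at codon index ", stops[1])
  }
  paste(aa, collapse = "")
}

# standard genetic code, named by codon
GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

#' Extract and translate the representative protein of each gene model
#'
#' Splices `cds_segments` out of the scaffold sequence (reverse-complementing
#' minus-strand genes) and translates. Genes flagged not-translatable are
#' skipped.
#'
#' @param genes Gene-model tibble from [read_gff3()].
#' @param scaffolds Named character vector of scaffold DNA sequences.
#' @return A tibble `id` (protein_id), `gene_id`, `cds`, `residues`.
#' @export
extract_proteins <- function(genes, scaffolds) {
  genes <- genes[genes$translatable, , drop = FALSE]
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    sc <- scaffolds[[g$scaffold_id]]
    if (is.null(sc)) stop("scaffold '", g$scaffold_id, "' not supplied")
    seg <- g$cds_segments[[1]]
    cds <- paste(substring(sc, seg[, "start"], seg[, "end"]), collapse = "")
    prot <- translate_cds(cds, g$strand)
    if (g$strand == "-") cds <- reverse_complement(cds)
    tibble(id = g$protein_id, gene_id = g$gene_id, cds = cds, residues = prot)
  })
  dplyr::bind_rows(rows)
}
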