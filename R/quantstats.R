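# Transcript quantification (k-mer unique assignment + TPM) and ELISA
# seropositivity statistics.

#' Assign reads to transcripts by unique k-mer ownership
#'
#' A read is assigned to a transcript iff every one of its k-mers occurs in
#' that transcript and in no other; reads touching k-mers shared between
#' transcripts are `ambiguous`, reads containing k-mers absent from every
#' transcript (or split across transcripts) are `unmatched`. A deliberately
#' conservative surrogate for quasi-mapping quantifiers.
#'
#' @param reads Tibble with `read_id` and `seq` (e.g. from
#'   [simulate_reads()] or [read_fastq()]), or a FASTQ path.
#' @param transcripts Named character vector of transcript sequences.
#' @param k K-mer size (default 31); must not exceed the read length.
#' @return Tibble `read_id`, `transcript_id` (`NA` unless assigned),
#'   `status` (`assigned`/`ambiguous`/`unmatched`).
#' @export
assign_reads <- function(reads, transcripts, k = 31) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(length(transcripts) >= 1, !is.null(names(transcripts)))
  if (any(nchar(reads$seq) < k)) {
    stop("config error: k exceeds the length of some reads")
  }
  # k-mer ownership table: transcript index, or 0 when shared
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) character(0) else unique(substring(s, 1:(n - k + 1), k:n))
  }
  tx_kmers <- lapply(transcripts, kmers_of)
  all_k <- unlist(tx_kmers, use.names = FALSE)
  owner_idx <- rep.int(seq_along(transcripts), lengths(tx_kmers))
  dup <- duplicated(all_k) | duplicated(all_k, fromLast = TRUE)
  owner_idx[dup] <- 0L
  first <- !duplicated(all_k)
  kmer_owner <- owner_idx[first]
  names(kmer_owner) <- all_k[first]

  res <- lapply(seq_len(nrow(reads)), function(i) {
    km <- kmers_of(reads$seq[i])
    own <- kmer_owner[km]
    if (anyNA(own)) return(c(NA_integer_, 1L))      # unmatched
    u <- unique(own)
    if (any(u == 0L) || length(u) > 1L) return(c(NA_integer_, 2L))  # ambiguous
    c(u, 3L)
  })
  code <- vapply(res, `[[`, integer(1), 2L)
  idx <- vapply(res, `[[`, integer(1), 1L)
  tibble(read_id = reads$read_id,
         transcript_id = ifelse(is.na(idx), NA_character_,
                                names(transcripts)[idx]),
         status = c("unmatched", "ambiguous", "assigned")[code])
}

#' Count assigned reads per transcript
#'
#' @param assignments Tibble from [assign_reads()].
#' @param transcripts Named character vector (defines the output rows; zero
#'   counts are kept).
#' @return Tibble `transcript_id`, `count`, with attribute `unassigned`
#'   (tibble of `status`, `n` for ambiguous/unmatched reads).
#' @export
count_reads <- function(assignments, transcripts) {
  tab <- table(factor(assignments$transcript_id,
                      levels = names(transcripts)))
  out <- tibble(transcript_id = names(transcripts),
                count = as.integer(tab))
  un <- assignments |>
    dplyr::filter(.data$status != "assigned") |>
    dplyr::count(.data$status, name = "n")
  attr(out, "unassigned") <- un
  out
}

#' Effective transcript length for TPM
#'
#' `max(length - read_length + 1, 1)`, the number of possible read start
#' positions.
#'
#' @param lengths Transcript lengths (bases).
#' @param read_length Read length (bases).
#' @return Effective lengths.
#' @export
effective_length <- function(lengths, read_length) {
  pmax(lengths - read_length + 1, 1)
}

#' Transcripts-per-million from counts and effective lengths
#'
#' `tpm_i = 1e6 (c_i / l_i) / sum_j (c_j / l_j)`; TPM sums to 1e6 within a
#' sample whenever any count is positive. An all-zero count vector returns
#' all-zero TPM with a warning.
#'
#' @param counts Tibble with `transcript_id`, `count` (e.g. from
#'   [count_reads()]) or a numeric vector.
#' @param effective_lengths Positive lengths aligned with `counts`.
#' @return Tibble `transcript_id`, `count`, `effective_length`, `tpm`.
#' @export
compute_tpm <- function(counts, effective_lengths) {
  if (is.data.frame(counts)) {
    ids <- counts$transcript_id
    cnt <- counts$count
  } else {
    ids <- names(counts) %||% paste0("t", seq_along(counts))
    cnt <- unname(counts)
  }
  stopifnot(length(effective_lengths) == length(cnt),
            all(effective_lengths > 0))
  if (any(cnt < 0)) stop("input error: negative count")
  rate <- cnt / effective_lengths
  denom <- sum(rate)
  tpm <- if (denom == 0) {
    warning("all counts are zero; TPM set to zero")
    rep(0, length(cnt))
  } else 1e6 * rate / denom
  tibble(transcript_id = ids, count = cnt,
         effective_length = effective_lengths, tpm = tpm)
}

#' Compare expression of a focal gene against all others
#'
#' One-way ANOVA with genes as groups and samples as replicates, followed by
#' focal-vs-each-other two-sample Student's t tests with Bonferroni
#' correction (a deterministic surrogate for Dunnett's test; the output
#' names it). Genes with zero variance and equal means are reported as not
#' significant rather than erroring.
#'
#' @param tpm_table Tibble with `gene_id`, `sample`, `tpm` (>= 2 samples per
#'   gene).
#' @param focal_gene Gene id compared against every other gene.
#' @param sig_level Corrected significance threshold flagged in the output
#'   (default 0.001).
#' @return Tibble of class `cpfam_expr`: one row per non-focal gene with
#'   `gene_id`, `mean_tpm`, `t_stat`, `p_raw`, `p_adj`, `significant`;
#'   attributes `anova` (F, p), `focal_gene`, `focal_mean`, `method`.
#' @export
compare_expression <- function(tpm_table, focal_gene, sig_level = 0.001) {
  stopifnot(all(c("gene_id", "sample", "tpm") %in% names(tpm_table)),
            focal_gene %in% tpm_table$gene_id)
  n_samples <- tpm_table |>
    dplyr::count(.data$gene_id) |>
    dplyr::pull(.data$n)
  if (any(n_samples < 2)) stop("need >= 2 samples per gene")
  fit <- stats::aov(tpm ~ gene_id, data = tpm_table)
  an <- summary(fit)[[1]]
  focal_vals <- tpm_table$tpm[tpm_table$gene_id == focal_gene]
  others <- setdiff(unique(tpm_table$gene_id), focal_gene)
  rows <- lapply(others, function(g) {
    v <- tpm_table$tpm[tpm_table$gene_id == g]
    tt <- tryCatch(stats::t.test(focal_vals, v, var.equal = TRUE),
                   error = function(e) NULL)
    tibble(gene_id = g, mean_tpm = mean(v),
           t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
           p_raw = if (is.null(tt)) 1 else tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "bonferroni")
  out$significant <- out$p_adj < sig_level
  attr(out, "anova") <- c(F = an$`F value`[1], p = an$`Pr(>F)`[1])
  attr(out, "focal_gene") <- focal_gene
  attr(out, "focal_mean") <- mean(focal_vals)
  attr(out, "method") <-
    "one-way ANOVA + Bonferroni-corrected t comparisons (Dunnett surrogate)"
  class(out) <- c("cpfam_expr", class(out))
  out
}

#' Seropositivity cutoff from control optical densities
#'
#' Mean plus two sample standard deviations (n - 1 denominator) of the
#' control ODs.
#'
#' @param control_ods Numeric vector of control OD readings (>= 2).
#' @return The cutoff (numeric scalar).
#' @export
elisa_cutoff <- function(control_ods) {
  if (length(control_ods) < 2L) {
    stop("insufficient controls: need >= 2 control ODs")
  }
  mean(control_ods) + 2 * sd(control_ods)
}

#' Per-subject ELISA calls and positivity statistics
#'
#' Each sensitized subject's replicate ODs are tested against all control
#' readings by a two-sided two-sample Student's t test; positivity is mean
#' OD above the control mean + 2 SD cutoff, and high binding is mean OD
#' above `high_threshold`. Subjects with a single replicate get a cutoff
#' call but no t test (warning).
#'
#' @param elisa_table Tibble `subject`, `group` (`control`/`sensitized`),
#'   `replicate`, `od` (see [simulate_elisa()]).
#' @param high_threshold High-binder mean-OD threshold (default 0.2).
#' @param alpha Significance level for the per-subject t test (default
#'   0.05).
#' @return Tibble of class `cpfam_elisa`: one row per sensitized subject
#'   with `subject`, `mean_od`, `p_value`, `significant`, `positive`,
#'   `high_binder`; attributes `cutoff`, `positive_rate`,
#'   `high_binder_rate` (percentages), `n_controls`, `n_sensitized`.
#' @export
elisa_calls <- function(elisa_table, high_threshold = 0.2, alpha = 0.05) {
  stopifnot(all(c("subject", "group", "od") %in% names(elisa_table)))
  ctrl <- elisa_table$od[elisa_table$group == "control"]
  if (length(ctrl) < 2L) stop("insufficient controls: need >= 2 control ODs")
  cutoff <- elisa_cutoff(ctrl)
  sens <- elisa_table[elisa_table$group == "sensitized", ]
  subjects <- unique(sens$subject)
  rows <- lapply(subjects, function(s) {
    od <- sens$od[sens$subject == s]
    p <- NA_real_
    if (length(od) >= 2L) {
      tt <- tryCatch(stats::t.test(od, ctrl, var.equal = TRUE),
                     error = function(e) NULL)
      p <- if (is.null(tt)) 1 else tt$p.value
    } else {
      warning("subject '", s, "' has a single replicate; t test skipped")
    }
    tibble(subject = s, mean_od = mean(od), p_value = p,
           significant = !is.na(p) & p < alpha,
           positive = mean(od) > cutoff,
           high_binder = mean(od) > high_threshold)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "cutoff") <- cutoff
  attr(out, "positive_rate") <- 100 * sum(out$positive) / nrow(out)
  attr(out, "high_binder_rate") <- 100 * sum(out$high_binder) / nrow(out)
  attr(out, "n_controls") <- length(unique(
    elisa_table$subject[elisa_table$group == "control"]))
  attr(out, "n_sensitized") <- length(subjects)
  class(out) <- c("cpfam_elisa", class(out))
  out
}
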