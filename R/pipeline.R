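# End-to-end orchestration: search -> synteny -> phylogeny -> triad/epitope
# -> selection -> expression -> ELISA -> summary. Each stage is an exported
# function of its own; run_pipeline() wires them together over a config.

#' Pipeline configuration
#'
#' All thresholds of the analysis in one validated list.
#'
#' @param min_identity Family-membership identity threshold (default 0.30).
#' @param min_score Raw alignment score threshold; `NULL` calibrates on
#'   shuffled decoys per proteome.
#' @param max_spacers Maximum spacer genes within an array (default 9).
#' @param coverage MSA column coverage for tree building (default 0.95).
#' @param alpha Site-selection significance level (default 0.05).
#' @param cross_identity,cross_length Cross-reactivity rule (defaults 0.35
#'   identity over >= 80 residues).
#' @param high_od ELISA high-binder mean OD threshold (default 0.2).
#' @param bootstrap_B Bootstrap replicates when requested (default 100).
#' @param n_clusters Clade clusters to extract (default 5).
#' @param seed Integer seed used by every stochastic step.
#' @return A list of class `cpfam_config`.
#' @export
pipeline_config <- function(min_identity = 0.30, min_score = NULL,
                            max_spacers = 9, coverage = 0.95, alpha = 0.05,
                            cross_identity = 0.35, cross_length = 80,
                            high_od = 0.2, bootstrap_B = 100, n_clusters = 5,
                            seed = 1) {
  cfg <- list(min_identity = min_identity, min_score = min_score,
              max_spacers = max_spacers, coverage = coverage, alpha = alpha,
              cross_identity = cross_identity, cross_length = cross_length,
              high_od = high_od, bootstrap_B = bootstrap_B,
              n_clusters = n_clusters, seed = seed)
  stopifnot(min_identity >= 0, min_identity <= 1, max_spacers >= 0,
            coverage > 0, coverage <= 1, alpha > 0, alpha < 1,
            cross_identity >= 0, cross_identity <= 1, n_clusters >= 1)
  class(cfg) <- "cpfam_config"
  cfg
}

#' Run the comparative family analysis end to end
#'
#' Stage order: homology search per species, array classification,
#' multi-species alignment and tree with clade clusters, catalytic-triad
#' calls, per-cluster site selection, expression ranking, ELISA statistics,
#' and a cross-species summary table. Stages whose inputs are `NULL` are
#' skipped. Deterministic for a fixed config and inputs.
#'
#' @param species_data Named list (one entry per species) of lists with
#'   `genes` (gene-model tibble), `proteins` and `cds` (named character
#'   vectors keyed by protein id), e.g. `simulate_family()$species`.
#' @param references Named character vector of reference allergen proteins.
#' @param config A [pipeline_config()].
#' @param triad Optional [triad_spec()] whose `reference_id` is a protein in
#'   the analysis (triad stage skipped when `NULL`).
#' @param epitopes Optional epitope tibble for [map_epitopes()].
#' @param expression Optional named list of per-sample read tibbles plus
#'   `transcripts` (named character vector) and `read_length`.
#' @param elisa_table Optional ELISA tibble for [elisa_calls()].
#' @return A list of class `cpfam_report`: `family` (per-species per-gene
#'   calls), `screen`, `arrays`, `msa`, `tree`, `clusters`, `triad`,
#'   `epitopes`, `selection` (per cluster), `expression`, `elisa`,
#'   `summary`, `config`.
#' @export
run_pipeline <- function(species_data, references, config = pipeline_config(),
                         triad = NULL, epitopes = NULL, expression = NULL,
                         elisa_table = NULL) {
  stopifnot(inherits(config, "cpfam_config"))
  if (length(species_data) == 0L) {
    return(structure(list(family = tibble(), summary = summarize_family(
      tibble(species = character(0), gene_id = character(0),
             arrayed = logical(0), active = logical(0))),
      config = config), class = "cpfam_report"))
  }
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[cpfam] %-10s %.1fs", name,
                                          as.numeric(Sys.time() - t0,
                                                     units = "secs")))
  # -- search ---------------------------------------------------------------
  screens <- list(); fam_by_sp <- list()
  for (sp in names(species_data)) {
    d <- species_data[[sp]]
    sc <- screen_proteome(d$proteins, references,
                          min_identity = config$min_identity,
                          min_score = config$min_score)
    screens[[sp]] <- sc
    hit_prot <- sc$protein_id[sc$is_family]
    fam_by_sp[[sp]] <- d$genes$gene_id[match(hit_prot, d$genes$protein_id)]
  }
  stage("search")
  # -- synteny --------------------------------------------------------------
  arrays <- list()
  for (sp in names(species_data)) {
    arrays[[sp]] <- classify_arrays(species_data[[sp]]$genes,
                                    fam_by_sp[[sp]],
                                    max_spacers = config$max_spacers)
  }
  stage("synteny")
  # -- alignment / phylogeny ------------------------------------------------
  fam_prot <- unlist(lapply(names(species_data), function(sp) {
    d <- species_data[[sp]]
    pid <- d$genes$protein_id[match(fam_by_sp[[sp]], d$genes$gene_id)]
    setNames(d$proteins[pid], pid)
  }))
  msa <- NULL; tree <- NULL; clusters <- NULL
  if (length(fam_prot) >= 3L) {
    msa <- progressive_align(fam_prot)
    tree <- build_tree(msa, min_coverage = config$coverage)
    n_cl <- min(config$n_clusters, length(fam_prot) - 1L)
    clusters <- extract_clusters(tree, n_cl)
  }
  stage("phylo")
  # -- triad / epitopes -----------------------------------------------------
  triad_calls <- if (!is.null(triad) && !is.null(msa)) map_triad(msa, triad)
  epitope_map <- if (!is.null(epitopes) && !is.null(msa)) {
    map_epitopes(msa, epitopes)
  }
  stage("triad")
  # -- selection per cluster ------------------------------------------------
  selection <- NULL
  if (!is.null(clusters) && !is.null(msa)) {
    cds_all <- unlist(unname(lapply(species_data, `[[`, "cds")))
    rows <- .as_msa_rows(msa)
    selection <- list()
    for (cl in sort(unique(stats::na.omit(clusters$cluster)))) {
      ids <- clusters$id[!is.na(clusters$cluster) & clusters$cluster == cl]
      if (length(ids) < 3L) next
      sub_msa <- new_msa(ids, rows[ids])
      codon <- thread_codons(sub_msa, cds_all[ids])
      cnt <- count_site_substitutions(codon)
      selection[[cl]] <- site_selection_test(cnt, alpha = config$alpha)
    }
  }
  stage("selection")
  # -- expression -----------------------------------------------------------
  expr <- NULL
  if (!is.null(expression)) {
    tx <- expression$transcripts
    el <- effective_length(nchar(tx), expression$read_length)
    tpm_tab <- dplyr::bind_rows(lapply(names(expression$samples), function(s) {
      asg <- assign_reads(expression$samples[[s]], tx)
      cnt <- count_reads(asg, tx)
      tp <- compute_tpm(cnt, el)
      tibble(gene_id = tp$transcript_id, sample = s, tpm = tp$tpm)
    }))
    focal <- tpm_tab |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(m = mean(.data$tpm)) |>
      dplyr::slice_max(.data$m, n = 1, with_ties = FALSE) |>
      dplyr::pull(.data$gene_id)
    expr <- compare_expression(tpm_tab, focal)
  }
  stage("express")
  # -- elisa ----------------------------------------------------------------
  elisa <- if (!is.null(elisa_table)) {
    elisa_calls(elisa_table, high_threshold = config$high_od)
  }
  stage("elisa")
  # -- summary --------------------------------------------------------------
  fam_rows <- dplyr::bind_rows(lapply(names(species_data), function(sp) {
    arr <- arrays[[sp]]
    d <- species_data[[sp]]
    pid <- d$genes$protein_id[match(arr$gene_id, d$genes$gene_id)]
    act <- if (!is.null(triad_calls)) {
      triad_calls$active[match(pid, triad_calls$gene_id)]
    } else NA
    tibble(species = sp, gene_id = arr$gene_id, protein_id = pid,
           arrayed = arr$arrayed_class %in% c("TAG", "PAG"),
           arrayed_class = arr$arrayed_class, active = act)
  }))
  summary_tab <- summarize_family(fam_rows)
  stage("summary")
  structure(list(family = fam_rows, screen = screens, arrays = arrays,
                 msa = msa, tree = tree, clusters = clusters,
                 triad = triad_calls, epitopes = epitope_map,
                 selection = selection, expression = expr, elisa = elisa,
                 summary = summary_tab, config = config),
            class = "cpfam_report")
}

#' @export
print.cpfam_report <- function(x, ...) {
  cat("cpfam run report\n")
  print(x$summary)
  if (!is.null(x$clusters)) {
    cl <- table(x$clusters$cluster, useNA = "ifany")
    cat("clusters:", paste(names(cl), cl, sep = "=", collapse = " "), "\n")
  }
  if (!is.null(x$elisa)) {
    cat(sprintf("ELISA: positive rate %.1f%%, high binders %.1f%%\n",
                attr(x$elisa, "positive_rate"),
                attr(x$elisa, "high_binder_rate")))
  }
  invisible(x)
}
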