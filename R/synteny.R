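# Gene order, tandem/proximal array classification and synteny-anchored
# gene-decay detection.

#' Order genes along scaffolds
#'
#' Gene order on a scaffold is by start coordinate regardless of strand;
#' ties are resolved by end coordinate, then gene id.
#'
#' @param genes A gene-model tibble (see [read_gff3()]).
#' @return Tibble `scaffold_id`, `gene_id`, `start`, `end`, `rank` (1-based
#'   position within its scaffold).
#' @export
scaffold_orders <- function(genes) {
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in input")
  genes |>
    dplyr::select("scaffold_id", "gene_id", "start", "end") |>
    dplyr::arrange(.data$scaffold_id, .data$start, .data$end,
                   .data$gene_id) |>
    dplyr::group_by(.data$scaffold_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Classify tandemly and proximally arrayed genes
#'
#' Family genes on one scaffold are grouped into maximal runs in which
#' consecutive members are separated by at most `max_spacers` non-family
#' ("spacer") genes. A run of two or more members is a tandem array (TAG)
#' when every gap is zero, otherwise a proximal array (PAG); remaining family
#' genes are singletons. Every family gene lands in exactly one of the three
#' classes.
#'
#' @param genes Gene-model tibble covering the whole annotation (family and
#'   non-family genes).
#' @param family_ids Character vector of family gene ids.
#' @param max_spacers Maximum spacer genes between consecutive array members
#'   (default 9, i.e. "fewer than 10").
#' @return Tibble of class `cpfam_arrays`, one row per family gene:
#'   `gene_id`, `scaffold_id`, `array_id` (`NA` for singletons),
#'   `arrayed_class` (`"TAG"`, `"PAG"`, `"singleton"`). Attribute `arrays`
#'   holds one row per array with `gap_spacers` list column.
#' @export
classify_arrays <- function(genes, family_ids, max_spacers = 9) {
  ord <- scaffold_orders(genes)
  missing <- setdiff(family_ids, ord$gene_id)
  if (length(missing) > 0) {
    stop("missing annotation: family gene(s) absent from all scaffolds: ",
         paste(missing, collapse = ", "))
  }
  ord$is_family <- ord$gene_id %in% family_ids
  per_gene <- list()
  arrays <- list()
  arr_n <- 0L
  for (sc in unique(ord$scaffold_id)) {
    so <- ord[ord$scaffold_id == sc, ]
    fam <- so[so$is_family, ]
    if (nrow(fam) == 0L) next
    gaps <- if (nrow(fam) > 1L) diff(fam$rank) - 1L else integer(0)
    brk <- c(0L, which(gaps > max_spacers), nrow(fam))
    for (b in seq_len(length(brk) - 1L)) {
      members <- (brk[b] + 1L):brk[b + 1L]
      ids <- fam$gene_id[members]
      if (length(ids) < 2L) {
        per_gene[[length(per_gene) + 1L]] <- tibble(
          gene_id = ids, scaffold_id = sc, array_id = NA_character_,
          arrayed_class = "singleton")
        next
      }
      arr_n <- arr_n + 1L
      aid <- sprintf("array%03d", arr_n)
      g <- gaps[members[-length(members)]]
      cls <- if (all(g == 0L)) "TAG" else "PAG"
      per_gene[[length(per_gene) + 1L]] <- tibble(
        gene_id = ids, scaffold_id = sc, array_id = aid, arrayed_class = cls)
      arrays[[length(arrays) + 1L]] <- tibble(
        array_id = aid, scaffold_id = sc, n_members = length(ids),
        classification = cls, member_gene_ids = list(ids),
        gap_spacers = list(as.integer(g)))
    }
  }
  out <- dplyr::bind_rows(per_gene)
  # report in family_ids order for stable downstream joins
  out <- out[match(family_ids, out$gene_id), ]
  attr(out, "arrays") <- dplyr::bind_rows(arrays)
  class(out) <- c("cpfam_arrays", class(out))
  out
}

#' Summarize a gene family across species
#'
#' Per-species totals of family members, arrayed (TAG or PAG) members and
#' active members, with a grand-total row. Column order follows the input
#' species order.
#'
#' @param per_species Tibble with columns `species`, `gene_id`, `arrayed`
#'   (logical or an `arrayed_class` string), `active` (logical).
#' @return Tibble `species`, `total`, `arrayed`, `active` with a final
#'   `"Total"` row.
#' @export
summarize_family <- function(per_species) {
  if (nrow(per_species) == 0L) {
    return(tibble(species = "Total", total = 0L, arrayed = 0L, active = 0L))
  }
  arrayed <- per_species$arrayed
  if (is.character(arrayed)) arrayed <- arrayed %in% c("TAG", "PAG")
  active <- as.logical(per_species$active)
  df <- tibble(species = per_species$species, arrayed = arrayed,
               active = active)
  df$species <- factor(df$species, levels = unique(df$species))
  per <- df |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(total = dplyr::n(),
                     arrayed = sum(.data$arrayed, na.rm = TRUE),
                     active = sum(.data$active, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(species = as.character(.data$species))
  dplyr::bind_rows(per, tibble(species = "Total",
                               total = sum(per$total),
                               arrayed = sum(per$arrayed),
                               active = sum(per$active)))
}

#' Detect lineage-specific gene decay from synteny anchors
#'
#' For every ortholog cluster (at most one member per species) and every
#' species lacking a member, the cluster's neighborhood in a reference
#' species (up to `window` genes on each side) is searched for flanking
#' genes with a reciprocal-best-identity ortholog in the missing species.
#' An event is `anchored` when at least one flank on each side has a
#' conserved ortholog and the two anchors lie on one scaffold within a
#' window-sized gene span, `unanchored` otherwise.
#'
#' @param ortholog_clusters Tibble `cluster_id`, `species`, `gene_id`
#'   (phylogeny-derived; clusters with two members in one species are
#'   skipped with a warning).
#' @param genes_by_species Named list of gene-model tibbles.
#' @param proteomes Named list of named character vectors (protein
#'   sequences, keyed by gene id).
#' @param species_list Character vector of all species under study.
#' @param window Neighborhood size in genes (default 10).
#' @param min_identity Reciprocal-best anchor identity threshold
#'   (default 0.5).
#' @return Tibble `cluster_id`, `missing_species`, `reference_species`,
#'   `left_anchor`, `right_anchor`, `confidence`
#'   (`"anchored"`/`"unanchored"`).
#' @export
detect_gene_decay <- function(ortholog_clusters, genes_by_species, proteomes,
                              species_list, window = 10, min_identity = 0.5) {
  events <- list()
  orders <- lapply(genes_by_species, scaffold_orders)
  for (cl in unique(ortholog_clusters$cluster_id)) {
    sub <- ortholog_clusters[ortholog_clusters$cluster_id == cl, ]
    if (anyDuplicated(sub$species)) {
      warning("cluster '", cl, "' is not single-copy in some species; skipped")
      next
    }
    absent <- setdiff(species_list, sub$species)
    if (length(absent) == 0L) next
    ref_sp <- species_list[species_list %in% sub$species][1]
    ref_gene <- sub$gene_id[sub$species == ref_sp]
    ord <- orders[[ref_sp]]
    row <- ord[ord$gene_id == ref_gene, ]
    if (nrow(row) == 0L) next
    so <- ord[ord$scaffold_id == row$scaffold_id, ]
    r <- row$rank
    left <- so$gene_id[so$rank >= r - window & so$rank < r]
    right <- so$gene_id[so$rank > r & so$rank <= r + window]
    for (miss in absent) {
      la <- .find_anchor(rev(left), ref_sp, miss, proteomes, min_identity)
      ra <- .find_anchor(right, ref_sp, miss, proteomes, min_identity)
      conf <- "unanchored"
      if (!is.na(la$ortholog) && !is.na(ra$ortholog)) {
        mo <- orders[[miss]]
        ga <- mo[mo$gene_id == la$ortholog, ]
        gb <- mo[mo$gene_id == ra$ortholog, ]
        if (nrow(ga) == 1L && nrow(gb) == 1L &&
            ga$scaffold_id == gb$scaffold_id &&
            abs(ga$rank - gb$rank) <= window + 1L) {
          conf <- "anchored"
        }
      }
      events[[length(events) + 1L]] <- tibble(
        cluster_id = cl, missing_species = miss,
        reference_species = ref_sp,
        left_anchor = la$ortholog, right_anchor = ra$ortholog,
        confidence = conf)
    }
  }
  if (length(events) == 0L) {
    return(tibble(cluster_id = character(0), missing_species = character(0),
                  reference_species = character(0),
                  left_anchor = character(0), right_anchor = character(0),
                  confidence = character(0)))
  }
  dplyr::bind_rows(events)
}

# best reciprocal-identity ortholog of any of `flank_ids` (supplied
# nearest-flank-first) in species `miss`. Identity here is the local
# alignment's match count over the shorter protein length: a plain local
# identity rewards short spurious segments between unrelated proteins,
# whereas orthologs align near end to end.
.anchor_identity <- function(a, b) {
  al <- smith_waterman(a, b)
  al$matches / min(nchar(a[[1]]), nchar(b[[1]]))
}

.find_anchor <- function(flank_ids, ref_sp, miss, proteomes, min_identity) {
  ref_prot <- proteomes[[ref_sp]]
  mis_prot <- proteomes[[miss]]
  for (fid in flank_ids) {
    fseq <- ref_prot[[fid]]
    if (is.null(fseq)) next
    hits <- vapply(names(mis_prot), function(mid) {
      .anchor_identity(setNames(fseq, fid), setNames(mis_prot[[mid]], mid))
    }, numeric(1))
    best <- names(which.max(hits))
    if (hits[[best]] < min_identity) next
    # reciprocal check
    back <- vapply(names(ref_prot), function(rid) {
      .anchor_identity(setNames(mis_prot[[best]], best),
                       setNames(ref_prot[[rid]], rid))
    }, numeric(1))
    if (names(which.max(back)) == fid) {
      return(list(flank = fid, ortholog = best, identity = hits[[best]]))
    }
  }
  list(flank = NA_character_, ortholog = NA_character_, identity = NA_real_)
}

#' Export arrays as BED intervals
#'
#' BED is 0-based half-open; the conversion happens only here.
#'
#' @param arrays The `arrays` attribute of a [classify_arrays()] result.
#' @param genes Gene-model tibble with coordinates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arrays_bed <- function(arrays, genes, path) {
  lines <- vapply(seq_len(nrow(arrays)), function(i) {
    ids <- arrays$member_gene_ids[[i]]
    g <- genes[genes$gene_id %in% ids, ]
    paste(arrays$scaffold_id[i], min(g$start) - 1L, max(g$end),
          arrays$array_id[i], sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
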