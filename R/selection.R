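# Per-site synonymous/nonsynonymous counting (Nei-Gojobori pathway
# enumeration) and a counting-based exact site-selection test. This is a
# deliberate desk-scale surrogate for likelihood site models (FEL/MEME);
# output metadata names it.

# ---- codon bookkeeping -----------------------------------------------------

# Nei-Gojobori synonymous site count of one codon: at each position, the
# fraction of single-nucleotide changes that are synonymous. Changes to
# stop codons are excluded from the possible-change count (stop codons are
# outside the sense-codon state space, as in codon-model software); each
# position still contributes one full site.
.ng_sites_one <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- GENETIC_CODE_TABLE[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      cand <- codon
      substr(cand, pos, pos) <- b
      aa2 <- GENETIC_CODE_TABLE[[cand]]
      if (aa2 == "*") next
      valid <- valid + 1L
      if (aa2 == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(s_sites = s, n_sites = 3 - s)
}

# pathway-averaged substitution counts between two sense codons: enumerate
# all orders of the differing positions, drop pathways through stop codons,
# average synonymous/nonsynonymous step counts over the remaining pathways.
.ng_pair_one <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(n_obs = 0, s_obs = 0))
  perms <- switch(d, list(1L), list(1:2, 2:1),
                  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  tot_n <- 0; tot_s <- 0; valid <- 0L
  for (p in perms) {
    cur <- c1
    n <- 0; s <- 0; ok <- TRUE
    for (step in pos[p]) {
      nxt <- cur
      substr(nxt, step, step) <- substr(c2, step, step)
      if (GENETIC_CODE_TABLE[[nxt]] == "*") { ok <- FALSE; break }
      if (GENETIC_CODE_TABLE[[nxt]] == GENETIC_CODE_TABLE[[cur]]) s <- s + 1
      else n <- n + 1
      cur <- nxt
    }
    if (ok) { tot_n <- tot_n + n; tot_s <- tot_s + s; valid <- valid + 1L }
  }
  if (valid == 0L) {
    # no stop-free pathway; fall back to counting every step, averaging over
    # all orders (degenerate corner, flagged large nonsynonymous load)
    return(c(n_obs = d, s_obs = 0))
  }
  c(n_obs = tot_n / valid, s_obs = tot_s / valid)
}

.ng_tables <- function() {
  if (is.null(.cpfam_env$ng_sites)) {
    sites <- t(vapply(SENSE_CODONS, .ng_sites_one, numeric(2)))
    .cpfam_env$ng_sites <- sites
    .cpfam_env$ng_pairs <- new.env(parent = emptyenv())
  }
  invisible(NULL)
}

.ng_pair_cached <- function(c1, c2) {
  key <- if (c1 <= c2) paste0(c1, c2) else paste0(c2, c1)
  hit <- .cpfam_env$ng_pairs[[key]]
  if (is.null(hit)) {
    hit <- .ng_pair_one(if (c1 <= c2) c1 else c2, if (c1 <= c2) c2 else c1)
    .cpfam_env$ng_pairs[[key]] <- hit
  }
  hit
}

# per-pathway (nonsyn, syn) step counts of every stop-free minimal pathway
# between two codons (symmetric), for sampled-pathway counting
.ng_pair_options <- function(c1, c2) {
  key <- paste0("opt", if (c1 <= c2) paste0(c1, c2) else paste0(c2, c1))
  hit <- .cpfam_env$ng_pairs[[key]]
  if (!is.null(hit)) return(hit)
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  opts <- if (d == 0L) matrix(c(0, 0), 1) else {
    perms <- switch(d, list(1L), list(1:2, 2:1),
                    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
    rows <- list()
    for (p in perms) {
      cur <- c1
      n <- 0; s <- 0; ok <- TRUE
      for (step in pos[p]) {
        nxt <- cur
        substr(nxt, step, step) <- substr(c2, step, step)
        if (GENETIC_CODE_TABLE[[nxt]] == "*") { ok <- FALSE; break }
        if (GENETIC_CODE_TABLE[[nxt]] == GENETIC_CODE_TABLE[[cur]]) {
          s <- s + 1
        } else n <- n + 1
        cur <- nxt
      }
      if (ok) rows[[length(rows) + 1L]] <- c(n, s)
    }
    if (length(rows) == 0L) matrix(c(d, 0), 1)
    else do.call(rbind, rows)
  }
  .cpfam_env$ng_pairs[[key]] <- opts
  opts
}

#' Pathway-averaged substitution counts for a codon pair
#'
#' Nei-Gojobori counting: synonymous and nonsynonymous differences averaged
#' over all minimal mutational pathways between the two codons (pathways
#' through stop codons excluded), together with the codons' degeneracy-based
#' site counts averaged over the pair.
#'
#' @param codon1,codon2 Sense codons (strings of length 3).
#' @return Named numeric: `n_obs`, `s_obs`, `n_sites`, `s_sites`.
#' @export
codon_pair_counts <- function(codon1, codon2) {
  .ng_tables()
  for (cd in c(codon1, codon2)) {
    if (!cd %in% SENSE_CODONS) stop("not a sense codon: ", cd)
  }
  obs <- .ng_pair_cached(codon1, codon2)
  st <- (.cpfam_env$ng_sites[codon1, ] + .cpfam_env$ng_sites[codon2, ]) / 2
  c(obs, n_sites = unname(st["n_sites"]), s_sites = unname(st["s_sites"]))
}

#' Per-column substitution counts of a codon alignment
#'
#' Two counting bases are offered. `"ancestral"` (the default for three or
#' more rows) reconstructs each column's ancestral codon as the plurality
#' codon (ties by lexicographic order) and accumulates pathway-averaged
#' synonymous/nonsynonymous differences of every other row against it, a
#' star-parsimony event count in which each substitution is counted about
#' once. `"pairwise"` accumulates pathway counts over every unordered row
#' pair, the classical Nei-Gojobori pairwise scheme (the column
#' `event_divisor` then records `n_rows - 1`, the factor by which a single
#' substitution is multiplied in pair sums on a star phylogeny, so
#' downstream tests can de-duplicate). Results are invariant to row order.
#'
#' @param codon_msa Codon MSA (named character vector or `cpfam_msa` tibble;
#'   row lengths divisible by 3, gaps as `"---"`).
#' @param method `"ancestral"` (default) or `"pairwise"`. With fewer than 3
#'   ungapped rows the two coincide.
#' @param pathway `"average"` (default) averages synonymous/nonsynonymous
#'   steps over all stop-free minimal pathways per comparison, the classical
#'   Nei-Gojobori counts; `"sample"` resolves each comparison by one
#'   uniformly drawn stop-free pathway, giving integer counts with
#'   event-level dispersion (appropriate when the counts feed a binomial
#'   test; uses the R random number generator, so seed for
#'   reproducibility and note the result then depends on row order).
#' @return Tibble `codon_column`, `n_obs`, `s_obs`, `n_sites`, `s_sites`,
#'   `n_rows_ungapped`, `n_pairs`, `event_divisor`.
#' @export
count_site_substitutions <- function(codon_msa,
                                     method = c("ancestral", "pairwise"),
                                     pathway = c("average", "sample")) {
  method <- match.arg(method)
  pathway <- match.arg(pathway)
  .ng_tables()
  pair_obs <- if (pathway == "average") {
    function(c1, c2) .ng_pair_cached(c1, c2)
  } else {
    function(c1, c2) {
      opts <- .ng_pair_options(c1, c2)
      pick <- opts[sample.int(nrow(opts), 1L), ]
      c(n_obs = pick[[1]], s_obs = pick[[2]])
    }
  }
  rows <- .as_msa_rows(codon_msa)
  len <- unique(nchar(rows))
  stopifnot(length(len) == 1, len %% 3 == 0)
  n_col <- len / 3
  codons <- do.call(rbind, lapply(rows, function(r) {
    substring(r, seq(1, len, 3), seq(3, len, 3))
  }))
  # validate codons
  for (i in seq_len(nrow(codons))) {
    for (j in seq_len(n_col)) {
      cd <- codons[i, j]
      if (grepl("-", cd, fixed = TRUE)) next
      if (!cd %in% SENSE_CODONS) {
        if (GENETIC_CODE_TABLE[cd] %in% "*") {
          stop("in-frame stop codon in row '", names(rows)[i],
               "' at codon column ", j)
        }
        stop("invalid codon '", cd, "' in row '", names(rows)[i],
             "' at codon column ", j)
      }
    }
  }
  out <- lapply(seq_len(n_col), function(j) {
    col <- codons[, j]
    ok <- which(!grepl("-", col, fixed = TRUE))
    n_obs <- s_obs <- n_sites <- s_sites <- 0
    n_pairs <- 0L
    divisor <- 1
    use_pairwise <- method == "pairwise" || length(ok) < 3L
    if (length(ok) >= 2L && use_pairwise) {
      for (a in seq_len(length(ok) - 1L)) {
        for (b in (a + 1L):length(ok)) {
          cc <- pair_obs(col[ok[a]], col[ok[b]])
          n_obs <- n_obs + cc[["n_obs"]]
          s_obs <- s_obs + cc[["s_obs"]]
          st <- (.cpfam_env$ng_sites[col[ok[a]], ] +
                   .cpfam_env$ng_sites[col[ok[b]], ]) / 2
          n_sites <- n_sites + st[["n_sites"]]
          s_sites <- s_sites + st[["s_sites"]]
          n_pairs <- n_pairs + 1L
        }
      }
      divisor <- length(ok) - 1L
    } else if (length(ok) >= 3L) {
      tab <- table(col[ok])
      anc <- names(tab)[order(-tab, names(tab))][1]
      for (cd in col[ok]) {
        if (cd == anc) next
        cc <- pair_obs(cd, anc)
        n_obs <- n_obs + cc[["n_obs"]]
        s_obs <- s_obs + cc[["s_obs"]]
      }
      st <- .cpfam_env$ng_sites[col[ok], , drop = FALSE]
      n_sites <- mean(st[, "n_sites"]); s_sites <- mean(st[, "s_sites"])
      n_pairs <- length(ok) - 1L
    } else if (length(ok) == 1L) {
      st <- .cpfam_env$ng_sites[col[ok], ]
      n_sites <- st[["n_sites"]]; s_sites <- st[["s_sites"]]
    }
    tibble(codon_column = j, n_obs = n_obs, s_obs = s_obs,
           n_sites = n_sites, s_sites = s_sites,
           n_rows_ungapped = length(ok), n_pairs = n_pairs,
           event_divisor = divisor)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "count_method") <- method
  res
}

#' Binomial site-selection test on substitution event counts
#'
#' Per codon column, the observed nonsynonymous difference count is compared
#' with the neutral expectation `n_sites / (n_sites + s_sites)` by a
#' two-sided binomial test on the rounded event counts (pairwise totals are
#' first de-duplicated by the counts' `event_divisor`; with two rows this is
#' the identity). The default p-value uses the mid-p correction, the
#' standard remedy for the conservativeness of discrete exact tails;
#' `p_method = "exact"` gives the plain exact test. A column is tested only
#' when it has at least `min_rows` ungapped rows and a non-zero (rounded)
#' difference count. Classes: `positive` when p < alpha with the observed
#' nonsynonymous fraction above expectation, `negative` below, otherwise
#' `neutral`/`untested`.
#'
#' @param counts Tibble from [count_site_substitutions()] (columns `n_obs`,
#'   `s_obs`, `n_sites`, `s_sites`, optionally `n_rows_ungapped` and
#'   `event_divisor`).
#' @param alpha Significance level (default 0.05).
#' @param min_rows Minimum ungapped rows per tested column (default 3; use 2
#'   for pairwise alignments).
#' @param p_method `"midp"` (default) or `"exact"`.
#' @return Tibble of class `cpfam_selection`: the count columns plus
#'   `omega`, `p_value`, `class`. Attribute `method` records the surrogate
#'   test used.
#' @export
site_selection_test <- function(counts, alpha = 0.05, min_rows = 3,
                                p_method = c("midp", "exact")) {
  p_method <- match.arg(p_method)
  r <- if ("n_rows_ungapped" %in% names(counts)) counts$n_rows_ungapped
  else rep(2L, nrow(counts))
  divisor <- if ("event_divisor" %in% names(counts)) counts$event_divisor
  else pmax(r - 1L, 1L)
  out <- counts
  out$omega <- NA_real_
  out$p_value <- NA_real_
  out$class <- "untested"
  for (i in seq_len(nrow(counts))) {
    n_obs <- counts$n_obs[i]; s_obs <- counts$s_obs[i]
    n_sites <- counts$n_sites[i]; s_sites <- counts$s_sites[i]
    if (n_obs + s_obs > 0 && n_sites > 0 && s_sites > 0) {
      pn <- n_obs / n_sites; ps <- s_obs / s_sites
      out$omega[i] <- if (ps > 0) pn / ps else Inf
    }
    if (r[i] < min_rows) next
    k <- round(n_obs / divisor[i])
    n <- round((n_obs + s_obs) / divisor[i])
    if (n == 0) next
    k <- min(k, n)
    p_exp <- n_sites / (n_sites + s_sites)
    pv <- .binom_p(k, n, p_exp, p_method)
    out$p_value[i] <- pv
    out$class[i] <- if (pv >= alpha) "neutral"
    else if (k / n > p_exp) "positive" else "negative"
  }
  attr(out, "method") <- paste0(
    "Nei-Gojobori pathway counting + two-sided ", p_method,
    " binomial test (FEL/MEME surrogate)")
  attr(out, "alpha") <- alpha
  class(out) <- c("cpfam_selection", class(out))
  out
}

# two-sided binomial p-value; "midp" halves the probability of the observed
# outcome in each tail (doubled smaller tail, capped at 1)
.binom_p <- function(k, n, p, method) {
  if (method == "exact") return(stats::binom.test(k, n, p)$p.value)
  lo <- stats::pbinom(k, n, p) - 0.5 * stats::dbinom(k, n, p)
  hi <- stats::pbinom(k - 1, n, p, lower.tail = FALSE) -
    0.5 * stats::dbinom(k, n, p)
  min(1, 2 * min(lo, hi))
}

#' Gene-level dN/dS summary with Jukes-Cantor correction
#'
#' Aggregates per-column counts to per-comparison proportions (`pN`, `pS`),
#' applies the Jukes-Cantor multiple-hit correction
#' `d = -3/4 log(1 - 4 p / 3)` and reports their ratio. Pairwise counts are
#' averaged per pair; ancestral counts per derived row.
#'
#' @param counts Tibble from [count_site_substitutions()].
#' @return One-row tibble `pn`, `ps`, `dn`, `ds`, `dnds`.
#' @export
summarize_dnds <- function(counts) {
  method <- attr(counts, "count_method") %||% "pairwise"
  np <- pmax(counts$n_pairs, 1L)
  obs_n <- sum(counts$n_obs / np)
  obs_s <- sum(counts$s_obs / np)
  if (method == "pairwise") {
    sites_n <- sum(counts$n_sites / np)
    sites_s <- sum(counts$s_sites / np)
  } else {
    sites_n <- sum(counts$n_sites)
    sites_s <- sum(counts$s_sites)
  }
  pn <- obs_n / sites_n
  ps <- obs_s / sites_s
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dn <- jc(pn); ds <- jc(ps)
  tibble(pn = pn, ps = ps, dn = dn, ds = ds,
         dnds = if (!is.na(ds) && ds > 0) dn / ds else NA_real_)
}
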