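# broom-style tidiers for the package's result objects.

#' Tidy ELISA calls
#' @param x A `cpfam_elisa` from [elisa_calls()].
#' @param ... Unused.
#' @return The per-subject tibble without the class decoration.
#' @export
tidy.cpfam_elisa <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cpfam_elisa")
  attributes(out)[c("cutoff", "positive_rate", "high_binder_rate",
                    "n_controls", "n_sensitized")] <- NULL
  out
}

#' One-row ELISA summary
#' @param x A `cpfam_elisa`.
#' @param ... Unused.
#' @return Tibble `cutoff`, `n_controls`, `n_sensitized`, `n_positive`,
#'   `positive_rate`, `n_high_binder`, `high_binder_rate`.
#' @export
glance.cpfam_elisa <- function(x, ...) {
  tibble(cutoff = attr(x, "cutoff"),
         n_controls = attr(x, "n_controls"),
         n_sensitized = attr(x, "n_sensitized"),
         n_positive = sum(x$positive),
         positive_rate = attr(x, "positive_rate"),
         n_high_binder = sum(x$high_binder),
         high_binder_rate = attr(x, "high_binder_rate"))
}

#' Tidy per-site selection results
#' @param x A `cpfam_selection` from [site_selection_test()].
#' @param ... Unused.
#' @return The per-column tibble.
#' @export
tidy.cpfam_selection <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cpfam_selection")
  attributes(out)[c("method", "alpha")] <- NULL
  out
}

#' One-row selection summary
#' @param x A `cpfam_selection`.
#' @param ... Unused.
#' @return Tibble `n_sites`, `n_positive`, `n_negative`, `n_neutral`,
#'   `n_untested`, `dnds` (gene-level Jukes-Cantor-corrected ratio),
#'   `method`.
#' @export
glance.cpfam_selection <- function(x, ...) {
  g <- summarize_dnds(x)
  tibble(n_sites = nrow(x),
         n_positive = sum(x$class == "positive"),
         n_negative = sum(x$class == "negative"),
         n_neutral = sum(x$class == "neutral"),
         n_untested = sum(x$class == "untested"),
         dnds = g$dnds,
         method = attr(x, "method"))
}

#' Tidy array classifications
#' @param x A `cpfam_arrays` from [classify_arrays()].
#' @param ... Unused.
#' @return The per-gene tibble.
#' @export
tidy.cpfam_arrays <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cpfam_arrays")
  attr(out, "arrays") <- NULL
  out
}

#' One-row array summary
#' @param x A `cpfam_arrays`.
#' @param ... Unused.
#' @return Tibble `n_family`, `n_tag`, `n_pag`, `n_singleton`, `n_arrays`.
#' @export
glance.cpfam_arrays <- function(x, ...) {
  arr <- attr(x, "arrays")
  tibble(n_family = nrow(x),
         n_tag = sum(x$arrayed_class == "TAG"),
         n_pag = sum(x$arrayed_class == "PAG"),
         n_singleton = sum(x$arrayed_class == "singleton"),
         n_arrays = if (is.null(arr)) 0L else nrow(arr))
}

#' Tidy an expression comparison
#' @param x A `cpfam_expr` from [compare_expression()].
#' @param ... Unused.
#' @return The per-gene tibble.
#' @export
tidy.cpfam_expr <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cpfam_expr")
  attributes(out)[c("anova", "focal_gene", "focal_mean", "method")] <- NULL
  out
}

#' One-row expression-comparison summary
#' @param x A `cpfam_expr`.
#' @param ... Unused.
#' @return Tibble `focal_gene`, `focal_mean`, `anova_f`, `anova_p`,
#'   `n_significant`, `method`.
#' @export
glance.cpfam_expr <- function(x, ...) {
  an <- attr(x, "anova")
  tibble(focal_gene = attr(x, "focal_gene"),
         focal_mean = attr(x, "focal_mean"),
         anova_f = unname(an["F"]), anova_p = unname(an["p"]),
         n_significant = sum(x$significant),
         method = attr(x, "method"))
}
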