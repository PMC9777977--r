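#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per (animal, tissue, gene) first; then,
#' per animal and tissue, dCt = Ct_target - Ct_reference; ddCt subtracts the
#' mean dCt of the calibrator tissue; fold change = 2^-ddCt per animal,
#' summarised as mean +/- SEM over animals. Amplification efficiency is fixed
#' at 2 (doubling per cycle), as the method's name implies. Adding a constant
#' to every Ct of both genes, or to the reference gene alone, leaves fold
#' ratios between tissues unchanged.
#'
#' When no calibrator is given, the tissue with the highest mean dCt (lowest
#' expression) is used, so reported folds are >= 1-ish; the choice only
#' rescales all folds by a common factor.
#'
#' @param ct Ct tibble (`animal`, `tissue`, `gene`, `replicate`, `ct`), as
#'   from [read_ct_tsv()] or [simulate_ct()].
#' @param target Target gene symbol.
#' @param reference Reference (housekeeping) gene symbol, default `"GAPDH"`.
#' @param calibrator Calibrator tissue; default picks the lowest-expression
#'   tissue.
#' @param replicate_summary `"mean"` (default) or `"median"` across technical
#'   replicates.
#' @return An object of class `rel_expr`: list with `summary` (per-tissue
#'   tibble `tissue`, `n`, `dct_mean`, `ddct`, `fold`, `fold_sem`),
#'   `per_animal` (per animal-tissue folds), `target`, `reference`,
#'   `calibrator`.
#' @export
relative_expression <- function(ct, target, reference = "GAPDH", calibrator = NULL,
                                replicate_summary = c("mean", "median")) {
  replicate_summary <- match.arg(replicate_summary)
  ct <- validate_ct(ct)
  if (!target %in% ct$gene) abort(paste0("Target gene not in Ct table: ", target))
  if (!reference %in% ct$gene) abort(paste0("Reference gene not in Ct table: ", reference))
  agg <- if (replicate_summary == "mean") mean else stats::median

  per_cell <- ct %>%
    filter(.data$gene %in% c(target, reference)) %>%
    group_by(.data$animal, .data$tissue, .data$gene) %>%
    summarise(ct = agg(.data$ct), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")

  no_ref <- is.na(per_cell[[reference]]) | is.na(per_cell[[target]])
  if (any(no_ref)) {
    warn(paste0(sum(no_ref), " animal-tissue cell(s) lack the target or reference ",
                "gene and were dropped"))
    per_cell <- per_cell[!no_ref, ]
  }
  per_cell$dct <- per_cell[[target]] - per_cell[[reference]]

  tissue_dct <- per_cell %>%
    group_by(.data$tissue) %>%
    summarise(dct_mean = mean(.data$dct), .groups = "drop")
  if (is.null(calibrator)) {
    calibrator <- tissue_dct$tissue[which.max(tissue_dct$dct_mean)]
  } else if (!calibrator %in% tissue_dct$tissue) {
    abort(paste0("Calibrator tissue not present: ", calibrator))
  }
  cal_dct <- tissue_dct$dct_mean[tissue_dct$tissue == calibrator]

  per_animal <- per_cell %>%
    mutate(ddct = .data$dct - cal_dct, fold = 2^(-.data$ddct)) %>%
    select("animal", "tissue", "dct", "ddct", "fold")

  summary_tbl <- per_animal %>%
    group_by(.data$tissue) %>%
    summarise(n = dplyr::n(), dct_mean = mean(.data$dct),
              ddct = mean(.data$ddct),
              fold_sem = ifelse(dplyr::n() > 1, sd(.data$fold) / sqrt(dplyr::n()), 0),
              fold = mean(.data$fold),
              .groups = "drop") %>%
    dplyr::relocate("fold", .before = "fold_sem") %>%
    arrange(dplyr::desc(.data$fold))

  structure(list(summary = summary_tbl, per_animal = per_animal,
                 target = target, reference = reference, calibrator = calibrator),
            class = "rel_expr")
}

#' @export
print.rel_expr <- function(x, ...) {
  cat("<rel_expr> ", x$target, " normalised to ", x$reference,
      ", calibrator tissue: ", x$calibrator, "\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}

#' @rdname relative_expression
#' @param x A `rel_expr` object.
#' @param ... Unused.
#' @export
tidy.rel_expr <- function(x, ...) x$summary

#' @rdname relative_expression
#' @export
glance.rel_expr <- function(x, ...) {
  tibble(target = x$target, reference = x$reference, calibrator = x$calibrator,
         n_tissues = nrow(x$summary), n_animals = length(unique(x$per_animal$animal)))
}

#' One-way tissue comparison of relative expression
#'
#' One-way ANOVA on the per-animal fold changes across tissues, followed by
#' pairwise comparisons rendered as a compact letter display (tissues sharing
#' no letter differ at `alpha`).
#'
#' @param r A `rel_expr` object.
#' @param alpha Significance level (default 0.05).
#' @return Tibble of per-tissue rows (`tissue`, `n`, `mean` fold, `letters`)
#'   with the ANOVA F statistic and p-value in attributes `"anova_f"` and
#'   `"anova_p"`.
#' @export
tissue_comparison <- function(r, alpha = 0.05) {
  stopifnot(inherits(r, "rel_expr"))
  d <- r$per_animal
  n_per <- table(d$tissue)
  if (length(n_per) < 2) abort("Need at least 2 tissues")
  if (any(n_per < 2)) abort("Need at least 2 animals per tissue for a within-tissue variance")
  fit <- aov(fold ~ tissue, data = d)
  s <- summary(fit)[[1]]
  lets <- pairwise_letters(as.data.frame(d), group = "tissue", value = "fold",
                           alpha = alpha)
  out <- rename(lets, tissue = "group")
  attr(out, "anova_f") <- s[["F value"]][1]
  attr(out, "anova_p") <- s[["Pr(>F)"]][1]
  out
}

#' Bar chart of relative expression with significance letters
#'
#' @param object A `rel_expr` object.
#' @param alpha Significance level for the letters (default 0.05).
#' @param ... Unused.
#' @return A ggplot: per-tissue mean fold +/- SEM, letters above the bars.
#' @export
autoplot.rel_expr <- function(object, alpha = 0.05, ...) {
  s <- object$summary
  lets <- tryCatch(tissue_comparison(object, alpha)[, c("tissue", "letters")],
                   error = function(e) tibble(tissue = s$tissue, letters = ""))
  d <- left_join(s, lets, by = "tissue")
  d$tissue <- factor(d$tissue, levels = d$tissue[order(-d$fold)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tissue, y = .data$fold)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fold - .data$fold_sem,
                                        ymax = .data$fold + .data$fold_sem),
                           width = 0.3) +
    ggplot2::geom_text(ggplot2::aes(y = .data$fold + .data$fold_sem,
                                    label = .data$letters), vjust = -0.5) +
    ggplot2::labs(x = NULL, y = paste0("Relative ", object$target, " expression (2^-ddCt)")) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
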