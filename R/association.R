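#' Fixed-effects litter-size model
#'
#' Fits the study's linear model Y = mu + parity + genotype + parity:genotype
#' + e by ordinary least squares (litter size treated as a continuous
#' response, as in the source analysis, even though observed values are
#' almost always 1 or 2) and reports Type III F tests computed with
#' sum-to-zero contrasts. Parity-by-genotype cells with no data make some
#' interaction columns unestimable; those columns are dropped from the design
#' (with a message) and each term's F test compares the retained columns
#' against the model without that term's columns, which coincides with the
#' standard Type III test on complete designs.
#'
#' @param assoc Association table from [join_genotypes_phenotypes()]:
#'   columns `genotype`, `parity`, `litter_size`.
#' @param interaction Include the parity-by-genotype interaction (default TRUE).
#' @return An object of class `litter_fit`: list with the underlying `lm` fit,
#'   the ANOVA table (tibble `term`, `sumsq`, `df`, `meansq`, `statistic`,
#'   `p.value`), residual df/variance, and the input data.
#' @export
fit_litter_model <- function(assoc, interaction = TRUE) {
  req <- c("genotype", "parity", "litter_size")
  if (!all(req %in% names(assoc))) {
    abort(paste0("Association table needs columns: ", paste(req, collapse = ", ")))
  }
  d <- tibble(
    genotype = factor(assoc$genotype),
    parity = factor(assoc$parity),
    litter_size = as.numeric(assoc$litter_size)
  )
  if (nlevels(d$genotype) < 2) {
    abort("Only one genotype level present; use genotype_means() instead")
  }
  terms <- c("parity", "genotype", if (interaction && nlevels(d$parity) > 1) "parity:genotype")
  form <- stats::reformulate(terms, response = "litter_size")
  contr <- list(genotype = "contr.sum", parity = "contr.sum")
  fit <- lm(form, data = d, contrasts = contr[vapply(
    c("parity", "genotype"), function(v) nlevels(d[[v]]) > 1, logical(1))])

  beta <- stats::coef(fit)
  aliased <- names(beta)[is.na(beta)]
  if (length(aliased) > 0) {
    inform(paste0("Dropping ", length(aliased),
                  " unestimable interaction column(s): ",
                  paste(aliased, collapse = ", ")))
  }
  anova_tbl <- type3_anova(fit, d)
  structure(list(
    fit = fit,
    anova = anova_tbl,
    df_residual = fit$df.residual,
    sigma2 = sum(stats::residuals(fit)^2) / fit$df.residual,
    dropped = aliased,
    data = d
  ), class = "litter_fit")
}

# Type III sums of squares via estimable-column model comparison.
# With a full-rank design and sum-to-zero contrasts this equals the classical
# Type III table (cross-checked against car::Anova in the test suite); with
# empty cells the unestimable columns are removed first.
type3_anova <- function(fit, d) {
  X <- stats::model.matrix(fit)
  asgn <- attr(X, "assign")
  beta <- stats::coef(fit)
  keep <- !is.na(beta)
  X <- X[, keep, drop = FALSE]
  asgn <- asgn[keep]
  y <- stats::model.response(stats::model.frame(fit))
  labels <- attr(stats::terms(fit), "term.labels")

  rss <- function(M) {
    f <- stats::lm.fit(M, y)
    sum(f$residuals^2)
  }
  rss_full <- rss(X)
  df_res <- nrow(X) - qr(X)$rank
  ms_res <- rss_full / df_res

  rows <- purrr::map_dfr(seq_along(labels), function(i) {
    cols <- asgn == i
    if (!any(cols)) {
      return(tibble(term = labels[i], sumsq = NA_real_, df = 0L,
                    meansq = NA_real_, statistic = NA_real_, p.value = NA_real_))
    }
    X_red <- X[, !cols, drop = FALSE]
    df_term <- qr(X)$rank - qr(X_red)$rank
    ss <- max(rss(X_red) - rss_full, 0)
    # degenerate data (e.g. every litter size identical): F = 0, p = 1
    f_stat <- if (ms_res <= 1e-12) {
      if (ss <= 1e-12) 0 else Inf
    } else (ss / df_term) / ms_res
    tibble(term = labels[i], sumsq = ss, df = as.integer(df_term),
           meansq = ss / df_term, statistic = f_stat,
           p.value = pf(f_stat, df_term, df_res, lower.tail = FALSE))
  })
  bind_rows(rows, tibble(term = "Residuals", sumsq = rss_full,
                         df = as.integer(df_res), meansq = ms_res,
                         statistic = NA_real_, p.value = NA_real_))
}

#' @export
print.litter_fit <- function(x, ...) {
  cat("<litter_fit> n =", nrow(x$data), "\n")
  print(x$anova, ...)
  invisible(x)
}

#' @rdname fit_litter_model
#' @param x A `litter_fit`.
#' @param ... Unused.
#' @export
tidy.litter_fit <- function(x, ...) x$anova

#' @rdname fit_litter_model
#' @export
glance.litter_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         df.residual = x$df_residual, nobs = nrow(x$data),
         n_dropped_columns = length(x$dropped))
}

#' Compact letter display from pairwise comparisons
#'
#' All pairwise two-sided t tests between groups, by default on a pooled
#' (residual) variance with the combined residual degrees of freedom - the
#' same comparisons an LSD procedure makes after a one-way fit. Letters are
#' then built by insert-and-absorb on the groups sorted by descending mean:
#' groups that differ at `alpha` share no letter; groups sharing any letter
#' are not significantly different. The display is a function of the pairwise
#' p-value matrix only.
#'
#' @param values Data frame with columns named by `group` and `value`, or a
#'   list of numeric vectors named by group.
#' @param group,value Column names when `values` is a data frame.
#' @param alpha Significance level (default 0.05).
#' @param var Variance handling: `"pooled"` (default) or `"welch"`. Welch
#'   falls back to pooled with a warning when any group has fewer than 2
#'   observations.
#' @param sigma2,df_residual Optional externally fitted residual variance and
#'   df (e.g. from a [fit_litter_model()] fit) to use for the pooled tests.
#' @return Tibble with columns `group`, `n`, `mean`, `letters`, ordered by
#'   descending mean (ties by input order); the highest mean is lettered "a".
#' @export
pairwise_letters <- function(values, group = "group", value = "value",
                             alpha = 0.05, var = c("pooled", "welch"),
                             sigma2 = NULL, df_residual = NULL) {
  var <- match.arg(var)
  if (is.data.frame(values)) {
    groups <- split(values[[value]], factor(values[[group]], levels = unique(values[[group]])))
  } else {
    groups <- values
  }
  groups <- lapply(groups, as.numeric)
  k <- length(groups)
  if (k < 2) abort("Need at least 2 groups")
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 1)) abort("Every group needs at least one observation")
  means <- vapply(groups, mean, numeric(1))

  if (var == "welch" && any(ns < 2)) {
    warn("Welch tests need n >= 2 per group; falling back to pooled variance")
    var <- "pooled"
  }
  if (var == "pooled" && is.null(sigma2)) {
    df_residual <- sum(ns) - k
    if (df_residual <= 0) abort("No residual degrees of freedom for pooled variance")
    sigma2 <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) / df_residual
  }

  p_mat <- matrix(1, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (var == "pooled") {
        se <- sqrt(sigma2 * (1 / ns[i] + 1 / ns[j]))
        df <- df_residual
      } else {
        vi <- var(groups[[i]]) / ns[i]
        vj <- var(groups[[j]]) / ns[j]
        se <- sqrt(vi + vj)
        df <- (vi + vj)^2 / (vi^2 / (ns[i] - 1) + vj^2 / (ns[j] - 1))
      }
      p <- if (se == 0) as.numeric(means[i] == means[j]) else
        2 * pt(abs(means[i] - means[j]) / se, df, lower.tail = FALSE)
      p_mat[i, j] <- p_mat[j, i] <- p
    }
  }

  ord <- order(-means)
  letters_by_group <- cld_insert_absorb(p_mat[ord, ord, drop = FALSE] < alpha)
  out <- tibble(group = names(groups)[ord], n = ns[ord], mean = means[ord],
                letters = letters_by_group)
  out
}

# Insert-and-absorb compact letter display. `sig` is a logical matrix over
# groups already sorted by descending mean; TRUE = significantly different.
cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))  # letter columns: membership vectors
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          cols[[ci]] <- a
          cols[[length(cols) + 1]] <- b
        }
      }
      # absorb: drop any column whose membership is a subset of another's
      keys <- vapply(cols, function(x) paste(as.integer(x), collapse = ""), character(1))
      drop <- duplicated(keys)
      for (ci in seq_along(cols)) {
        if (drop[ci]) next
        for (cj in seq_along(cols)) {
          if (ci == cj || drop[cj]) next
          proper_subset <- all(!cols[[ci]] | cols[[cj]]) && any(cols[[cj]] & !cols[[ci]])
          if (proper_subset) {
            drop[ci] <- TRUE
            break
          }
        }
      }
      cols <- cols[!drop]
    }
  }
  # order letter columns by first member so "a" is the top-mean group's letter
  firsts <- vapply(cols, function(x) which(x)[1], integer(1))
  cols <- cols[order(firsts)]
  vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, function(x) x[i], logical(1)))], collapse = "")
  }, character(1))
}

#' Per-genotype litter-size means with significance letters
#'
#' The publication-style association table: per-genotype sample size, mean
#' litter size, dispersion (both SD and SEM are carried; `dispersion` names
#' which one the `display` column shows) and compact significance letters
#' from [pairwise_letters()]. Genotype classes present in the locus annotation
#' but absent from the data are reported as n = 0 with zero mean, matching
#' report convention.
#'
#' @param assoc Association table (`genotype`, `litter_size`, optionally
#'   `parity`).
#' @param alpha Significance level for the letters (default 0.05).
#' @param dispersion Which dispersion the `display` column shows: `"sd"`
#'   (default; matches the published table) or `"sem"`.
#' @param all_genotypes Optional character vector of the full genotype-class
#'   universe (e.g. c("CC","CT","TT")) so empty classes get zero rows.
#' @param use_model_variance Use the residual variance of the full
#'   parity-adjusted model for the pairwise tests (default TRUE when a
#'   `parity` column is present and the model is estimable).
#' @return Tibble with columns `genotype`, `n`, `mean`, `sd`, `sem`,
#'   `letters`, `display`.
#' @export
genotype_means <- function(assoc, alpha = 0.05, dispersion = c("sd", "sem"),
                           all_genotypes = NULL, use_model_variance = TRUE) {
  dispersion <- match.arg(dispersion)
  if (nrow(assoc) == 0) abort("Empty association table")
  stats_tbl <- assoc %>%
    group_by(genotype = as.character(.data$genotype)) %>%
    summarise(n = dplyr::n(), mean = mean(.data$litter_size),
              sd = ifelse(dplyr::n() > 1, sd(.data$litter_size), 0),
              .groups = "drop") %>%
    mutate(sem = ifelse(.data$n > 0, .data$sd / sqrt(.data$n), 0))

  sigma2 <- NULL; df_res <- NULL
  if (use_model_variance && "parity" %in% names(assoc) &&
      length(unique(assoc$genotype)) > 1) {
    fit <- tryCatch(suppressMessages(fit_litter_model(assoc)), error = function(e) NULL)
    if (!is.null(fit) && fit$df_residual > 0) {
      sigma2 <- fit$sigma2
      df_res <- fit$df_residual
    }
  }
  if (length(unique(assoc$genotype)) > 1) {
    lets <- pairwise_letters(as.data.frame(assoc), group = "genotype",
                             value = "litter_size", alpha = alpha,
                             sigma2 = sigma2, df_residual = df_res)
    stats_tbl <- left_join(stats_tbl, lets[, c("group", "letters")],
                           by = c(genotype = "group"))
  } else {
    stats_tbl$letters <- "a"
  }
  if (!is.null(all_genotypes)) {
    absent <- setdiff(all_genotypes, stats_tbl$genotype)
    if (length(absent) > 0) {
      stats_tbl <- bind_rows(stats_tbl,
                             tibble(genotype = absent, n = 0L, mean = 0, sd = 0,
                                    sem = 0, letters = ""))
    }
    stats_tbl <- stats_tbl[match(all_genotypes, stats_tbl$genotype), ]
  } else {
    stats_tbl <- arrange(stats_tbl, dplyr::desc(.data$n))
  }
  stats_tbl %>%
    mutate(display = sprintf("%.2f ± %.2f", round_half_up(.data$mean, 2),
                             round_half_up(.data[[dispersion]], 2)))
}
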