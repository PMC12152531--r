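## Canonicalise the sample input: either a named list of numeric vectors or
## a long data frame with columns sample_label (or sample) and score.
as_sample_scores <- function(samples) {
  if (is.data.frame(samples)) {
    lab_col <- intersect(c("sample_label", "sample"), names(samples))[1]
    if (is.na(lab_col) || !"score" %in% names(samples)) {
      stop("data-frame input needs columns 'sample_label' (or 'sample') and 'score'",
           call. = FALSE)
    }
    samples <- split(samples$score, factor(samples[[lab_col]],
                                           levels = unique(samples[[lab_col]])))
  }
  if (!is.list(samples) || is.null(names(samples)) ||
      any(!nzchar(names(samples)))) {
    stop("samples must be a named list of score vectors", call. = FALSE)
  }
  if (anyDuplicated(names(samples))) {
    stop("duplicate sample labels: ",
         paste(unique(names(samples)[duplicated(names(samples))]),
               collapse = ", "), call. = FALSE)
  }
  for (lab in names(samples)) {
    x <- samples[[lab]]
    if (!is.numeric(x) || length(x) < 1L) {
      stop("sample '", lab, "' must contain at least one numeric score",
           call. = FALSE)
    }
    if (any(!is.finite(x))) {
      stop("sample '", lab, "' contains non-finite scores", call. = FALSE)
    }
  }
  lapply(samples, as.numeric)
}

#' Normality gate: choose the parametric or non-parametric route
#'
#' Applies the Shapiro-Wilk test to each sample's score distribution. The
#' parametric route (one-way ANOVA, Tukey HSD) is taken only when every
#' sample is compatible with normality (all Shapiro-Wilk p-values at or
#' above `alpha`); otherwise the non-parametric route (Kruskal-Wallis,
#' Mann-Whitney U) is used. Samples with fewer than 3 observations, or
#' with zero variance, cannot be tested and force the non-parametric
#' route; their gate p-value is reported as `NA`.
#'
#' @param samples Named list of numeric score vectors, or a long data frame
#'   with columns `sample_label` and `score`.
#' @param alpha Gate significance level in (0, 1); default 0.05.
#'
#' @return A list with `route` (`"parametric"` or `"nonparametric"`) and
#'   `normality_p`, a named vector of per-sample Shapiro-Wilk p-values.
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  samples <- as_sample_scores(samples)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  p <- vapply(samples, function(x) {
    if (length(x) < 3L || length(x) > 5000L) return(NA_real_)
    if (stats::var(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  route <- if (length(p) > 0 && all(!is.na(p)) && all(p >= alpha)) {
    "parametric"
  } else {
    "nonparametric"
  }
  list(route = route, normality_p = p)
}

#' Omnibus test across all samples
#'
#' One-way ANOVA on the parametric route, the (tie-corrected)
#' Kruskal-Wallis H test on the non-parametric route. A significant
#' omnibus result gates the pairwise post hoc comparisons.
#'
#' @inheritParams normality_gate
#' @param route `"parametric"` or `"nonparametric"` (normally supplied by
#'   [normality_gate()]).
#'
#' @return A list with `name`, `statistic` (F or H) and `p`.
#' @export
omnibus_test <- function(samples, route = c("nonparametric", "parametric")) {
  samples <- as_sample_scores(samples)
  route <- match.arg(route)
  if (length(samples) < 2L) {
    stop("omnibus test needs at least 2 samples", call. = FALSE)
  }
  values <- unlist(samples, use.names = FALSE)
  group <- factor(rep(names(samples), lengths(samples)),
                  levels = names(samples))
  if (stats::var(values) == 0) {
    stop("degenerate input: all observations identical across all groups",
         call. = FALSE)
  }
  if (route == "parametric") {
    fit <- stats::aov(values ~ group)
    tab <- summary(fit)[[1]]
    list(name = "one-way ANOVA", statistic = tab[["F value"]][1],
         p = tab[["Pr(>F)"]][1], fit = fit)
  } else {
    kw <- stats::kruskal.test(values, group)
    list(name = "Kruskal-Wallis H", statistic = unname(kw$statistic),
         p = kw$p.value, fit = NULL)
  }
}

## Mann-Whitney U, two-sided. Exact enumeration for small tie-free samples,
## normal approximation with continuity and tie correction otherwise.
mann_whitney_p <- function(x, y) {
  exact <- length(x) <= 20L && length(y) <= 20L &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
}

#' Post hoc pairwise comparisons
#'
#' On the non-parametric route: two-sided Mann-Whitney U tests with
#' Bonferroni correction. On the parametric route: Tukey's honest
#' significant difference over all pairs, or pooled-variance t tests with
#' Bonferroni correction in reference mode. When `reference` is given,
#' only the k-1 pairs involving the reference group are tested and the
#' Bonferroni multiplier shrinks accordingly; otherwise all k(k-1)/2 pairs
#' are tested.
#'
#' @inheritParams omnibus_test
#' @param reference Optional label of the reference sample; all comparisons
#'   then involve this group.
#'
#' @return A tibble with columns `label_a`, `label_b`, `raw_p`,
#'   `adjusted_p`, `stars`, plus the attribute `m_comparisons`.
#' @export
posthoc_pairwise <- function(samples, route = c("nonparametric", "parametric"),
                             reference = NULL) {
  samples <- as_sample_scores(samples)
  route <- match.arg(route)
  labs <- names(samples)
  k <- length(labs)
  if (k < 2L) stop("post hoc needs at least 2 samples", call. = FALSE)
  if (!is.null(reference) && !reference %in% labs) {
    stop("reference label '", reference, "' is not among the samples",
         call. = FALSE)
  }

  if (is.null(reference)) {
    pairs <- utils::combn(labs, 2)
    pairs <- tibble::tibble(label_a = pairs[1, ], label_b = pairs[2, ])
  } else {
    others <- setdiff(labs, reference)
    pairs <- tibble::tibble(label_a = others, label_b = reference)
  }
  m <- nrow(pairs)

  raw_p <- mapply(function(a, b) {
    if (route == "parametric") {
      stats::t.test(samples[[a]], samples[[b]], var.equal = TRUE)$p.value
    } else {
      mann_whitney_p(samples[[a]], samples[[b]])
    }
  }, pairs$label_a, pairs$label_b)

  if (route == "parametric" && is.null(reference)) {
    ## Tukey family-wise adjustment across all pairs
    values <- unlist(samples, use.names = FALSE)
    group <- factor(rep(labs, lengths(samples)), levels = labs)
    tk <- stats::TukeyHSD(stats::aov(values ~ group))$group
    key_fwd <- paste(pairs$label_b, pairs$label_a, sep = "-")
    key_rev <- paste(pairs$label_a, pairs$label_b, sep = "-")
    idx <- ifelse(key_fwd %in% rownames(tk), key_fwd, key_rev)
    adj <- tk[idx, "p adj"]
    ## family-wise p can fall below the raw pairwise-t p only through
    ## numerical noise; clamp to preserve adjusted >= raw
    adjusted_p <- pmin(1, pmax(unname(adj), raw_p))
  } else {
    adjusted_p <- pmin(1, m * raw_p)
  }

  out <- tibble::tibble(
    label_a = pairs$label_a, label_b = pairs$label_b,
    raw_p = unname(raw_p), adjusted_p = adjusted_p,
    stars = significance_label(adjusted_p)
  )
  attr(out, "m_comparisons") <- m
  out
}

#' Asterisk notation for adjusted p-values
#'
#' Standard significance labels with strict boundaries: `***` for
#' p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise
#' (so p = 0.05 exactly is `ns`).
#'
#' @param adjusted_p Numeric vector of p-values in \[0, 1\].
#' @param thresholds Decreasing significance boundaries.
#' @return Character vector of labels.
#' @examples
#' significance_label(c(0.0005, 0.02, 0.05))  # "***" "*" "ns"
#' @export
significance_label <- function(adjusted_p, thresholds = c(0.05, 0.01, 0.001)) {
  if (any(!is.finite(adjusted_p)) || any(adjusted_p < 0) || any(adjusted_p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(adjusted_p < thresholds[3], "***",
    ifelse(adjusted_p < thresholds[2], "**",
      ifelse(adjusted_p < thresholds[1], "*", "ns")))
}

#' Two-step gated comparison of binding-score distributions
#'
#' The full comparison used for Figure-style sample contrasts: a
#' Shapiro-Wilk normality gate selects the parametric or non-parametric
#' route; an omnibus test (one-way ANOVA or Kruskal-Wallis H) checks for
#' any overall difference; and only when the omnibus p-value falls below
#' `alpha` are post hoc pairwise comparisons run (Tukey HSD or
#' Mann-Whitney U with Bonferroni correction), optionally restricted to
#' pairs involving a reference group with the correction multiplier
#' reduced to k-1.
#'
#' All statistics are computed on the complete data; the 1.5 x IQR outlier
#' rule used by the violin plots is display-only and never reaches this
#' function.
#'
#' @inheritParams posthoc_pairwise
#' @param alpha Omnibus gate level for running post hoc tests.
#' @param gate_alpha Significance level of the Shapiro-Wilk normality gate.
#' @param force_posthoc Run the pairwise comparisons even when the omnibus
#'   test is not significant; the result is then flagged (`posthoc_forced`)
#'   and should be treated as exploratory.
#'
#' @return An object of class `binding_comparison`: route, per-sample
#'   normality p-values, omnibus name/statistic/p, the pairwise table with
#'   significance labels, the reference label, the Bonferroni multiplier
#'   `m_comparisons`, and the flags `posthoc_run` / `posthoc_forced`.
#' @export
compare_samples <- function(samples, reference = NULL, alpha = 0.05,
                            gate_alpha = 0.05, force_posthoc = FALSE) {
  samples <- as_sample_scores(samples)
  if (length(samples) < 2L) {
    stop("comparison needs at least 2 samples", call. = FALSE)
  }
  gate <- normality_gate(samples, alpha = gate_alpha)
  omni <- omnibus_test(samples, route = gate$route)

  run_posthoc <- omni$p < alpha
  forced <- FALSE
  pairwise <- NULL
  m <- NA_integer_
  if (run_posthoc || force_posthoc) {
    forced <- !run_posthoc && force_posthoc
    pairwise <- posthoc_pairwise(samples, route = gate$route,
                                 reference = reference)
    m <- attr(pairwise, "m_comparisons")
  }

  structure(
    list(
      route = gate$route,
      normality_p = gate$normality_p,
      omnibus_name = omni$name,
      omnibus_stat = omni$statistic,
      omnibus_p = omni$p,
      pairwise = pairwise,
      reference = reference,
      m_comparisons = m,
      posthoc_run = run_posthoc || force_posthoc,
      posthoc_forced = forced,
      alpha = alpha,
      n_per_sample = lengths(samples)
    ),
    class = "binding_comparison"
  )
}

#' @export
print.binding_comparison <- function(x, ...) {
  cat(sprintf("Binding-score comparison (%s route)\n", x$route))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(x$n_per_sample),
                            x$n_per_sample), collapse = ", ")))
  cat(sprintf("  omnibus %s: statistic = %.4g, p = %.3g\n",
              x$omnibus_name, x$omnibus_stat, x$omnibus_p))
  if (!is.null(x$pairwise)) {
    if (x$posthoc_forced) cat("  post hoc (FORCED, omnibus not significant):\n")
    else cat(sprintf("  post hoc (m = %d comparisons):\n", x$m_comparisons))
    df <- as.data.frame(x$pairwise)
    df$raw_p <- signif(df$raw_p, 3)
    df$adjusted_p <- signif(df$adjusted_p, 3)
    print(df, row.names = FALSE)
  } else {
    cat("  post hoc: not run (omnibus p >= alpha)\n")
  }
  invisible(x)
}

#' Write a comparison report
#'
#' Serialises a [compare_samples()] result to JSON (full object) and,
#' when post hoc tests ran, a flat TSV of the pairwise rows.
#'
#' @param comparison A `binding_comparison` object.
#' @param json_path Output path for the JSON report.
#' @param tsv_path Optional output path for the pairwise TSV.
#' @return `json_path`, invisibly.
#' @export
write_comparison <- function(comparison, json_path, tsv_path = NULL) {
  stopifnot(inherits(comparison, "binding_comparison"))
  out <- unclass(comparison)
  out$normality_p <- as.list(out$normality_p)
  out$n_per_sample <- as.list(out$n_per_sample)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(tsv_path) && !is.null(comparison$pairwise)) {
    readr::write_tsv(comparison$pairwise, tsv_path)
  }
  invisible(json_path)
}
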