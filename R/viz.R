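#' Display specification for score distribution plots
#'
#' @param outlier_rule `"iqr"` to hide values beyond 1.5 x IQR from the
#'   quartiles (display only — statistics always use complete data), or
#'   `"all"` to draw every point.
#' @param order Optional sample display order (a permutation of the
#'   available labels).
#' @param annotate Draw significance labels for comparisons against the
#'   reference group when a comparison is supplied.
#' @return A `plot_spec` list.
#' @export
plot_spec <- function(outlier_rule = c("iqr", "all"), order = NULL,
                      annotate = TRUE) {
  structure(list(outlier_rule = match.arg(outlier_rule), order = order,
                 annotate = isTRUE(annotate)),
            class = "plot_spec")
}

#' Flag display outliers by the 1.5 x IQR rule
#'
#' Marks values below Q1 - 1.5 x IQR or above Q3 + 1.5 x IQR. Used only
#' to declutter plots; flagged values never leave any statistic.
#'
#' @param x Numeric vector.
#' @return Logical vector, `TRUE` for outliers.
#' @export
flag_display_outliers <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr
}

#' Violin plot of binding-score distributions
#'
#' One violin per sample drawn from a kernel density estimate of the
#' displayed values, overlaid individual measurements, a bold line at the
#' sample mean and thinner lines at the quartiles. With the IQR display
#' rule active, points beyond 1.5 x IQR from the quartiles are omitted
#' from the drawing (the supplied comparison and any statistic remain
#' computed on complete data). When a [compare_samples()] result with a
#' reference group is supplied, its significance labels are drawn above
#' each compared sample.
#'
#' A JSON sidecar (`<out>.meta.json`) records the display rule, the KDE
#' bandwidths (Silverman's rule-of-thumb, per sample) and the number of
#' points excluded per sample.
#'
#' @inheritParams normality_gate
#' @param comparison Optional `binding_comparison` for annotations.
#' @param spec A [plot_spec()].
#' @param out Output figure path; format from the extension (`.png`,
#'   `.svg`, `.pdf`).
#' @return The ggplot object, invisibly.
#' @export
violin_plot <- function(samples, comparison = NULL, spec = plot_spec(),
                        out = NULL) {
  samples <- as_sample_scores(samples)
  stopifnot(inherits(spec, "plot_spec"))
  labs <- names(samples)
  if (!is.null(spec$order)) {
    if (!setequal(spec$order, labs)) {
      stop("spec$order must be a permutation of the sample labels",
           call. = FALSE)
    }
    labs <- spec$order
  }

  df <- tibble::tibble(
    sample = factor(rep(names(samples), lengths(samples)), levels = labs),
    score = unlist(samples, use.names = FALSE))
  hidden <- rep(FALSE, nrow(df))
  if (spec$outlier_rule == "iqr") {
    for (g in levels(df$sample)) {
      idx <- which(df$sample == g)
      hidden[idx] <- flag_display_outliers(df$score[idx])
    }
  }
  df$hidden <- hidden
  shown <- df[!df$hidden, ]

  stat_df <- dplyr::summarise(
    dplyr::group_by(shown, .data$sample),
    mean = mean(.data$score),
    q1 = stats::quantile(.data$score, 0.25),
    q3 = stats::quantile(.data$score, 0.75),
    .groups = "drop")

  p <- ggplot2::ggplot(shown, ggplot2::aes(x = .data$sample, y = .data$score)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40",
                         trim = TRUE, scale = "width") +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 0.6,
                         alpha = 0.5) +
    ggplot2::geom_errorbar(
      data = stat_df,
      ggplot2::aes(x = .data$sample, ymin = .data$mean, ymax = .data$mean),
      inherit.aes = FALSE, width = 0.55, linewidth = 1.1) +
    ggplot2::geom_errorbar(
      data = stat_df,
      ggplot2::aes(x = .data$sample, ymin = .data$q1, ymax = .data$q1),
      inherit.aes = FALSE, width = 0.4, linewidth = 0.4) +
    ggplot2::geom_errorbar(
      data = stat_df,
      ggplot2::aes(x = .data$sample, ymin = .data$q3, ymax = .data$q3),
      inherit.aes = FALSE, width = 0.4, linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "binding score (particles / nm)") +
    ggplot2::coord_cartesian(ylim = c(0, NA)) +
    ggplot2::theme_classic()

  if (spec$annotate && !is.null(comparison) &&
      !is.null(comparison$pairwise) && !is.null(comparison$reference)) {
    ann <- comparison$pairwise
    other <- ifelse(ann$label_a == comparison$reference,
                    ann$label_b, ann$label_a)
    ypos <- max(shown$score) * 1.08
    ann_df <- tibble::tibble(
      sample = factor(other, levels = labs),
      score = ypos, label = ann$stars)
    p <- p + ggplot2::geom_text(data = ann_df,
                                ggplot2::aes(label = .data$label),
                                size = 4)
  }

  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 7, height = 4.5, dpi = 150)
    bw <- vapply(split(shown$score, shown$sample),
                 function(v) if (length(v) >= 2 && stats::var(v) > 0)
                   stats::bw.nrd0(v) else NA_real_,
                 numeric(1))
    excluded <- vapply(split(df$hidden, df$sample), sum, numeric(1))
    jsonlite::write_json(
      list(outlier_rule = spec$outlier_rule,
           kde_bandwidth = as.list(bw),
           excluded_points = as.list(excluded),
           order = labs),
      paste0(out, ".meta.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(p)
}

## 100-gon approximation of a circle, for particle halos
circle_path <- function(cx, cy, radius, id) {
  th <- seq(0, 2 * pi, length.out = 101)
  tibble::tibble(x = cx + radius * cos(th), y = cy + radius * sin(th),
                 id = id)
}

#' Annotated-micrograph overlay plot
#'
#' Draws the annotation geometry the way binding is decided: each fibril
#' as a band of width `d` (the fibril's physical footprint around its
#' annotated axis) and each particle as a circle of radius `r + a` (the
#' particle plus the reach of the antibody complex). A particle's circle
#' overlaps a fibril's band exactly when their centre-to-axis distance is
#' at most `r + a + d/2` — the plot is a visual restatement of the
#' binding threshold. Bound particles are drawn in red, unbound in grey.
#'
#' @param annotations An [annotation_set()].
#' @param assignments Output of [assign_particles()] on the same set.
#' @param params The [binding_params()] used for the assignment.
#' @param out Optional output figure path (`.png`, `.svg`, `.pdf`).
#' @return The ggplot object, invisibly.
#' @export
overlay_plot <- function(annotations, assignments, params, out = NULL) {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(params, "binding_params"))
  fib <- annotations$fibrils
  par <- dplyr::left_join(annotations$particles, assignments,
                          by = "particle_id")

  ## fibril band polygons: rectangle of half-width d/2 around the axis
  half <- params$d / 2
  bands <- do.call(rbind, lapply(seq_len(nrow(fib)), function(i) {
    ux <- (fib$x2[i] - fib$x1[i]) / fib$length[i]
    uy <- (fib$y2[i] - fib$y1[i]) / fib$length[i]
    nx <- -uy; ny <- ux
    tibble::tibble(
      x = c(fib$x1[i] + nx * half, fib$x2[i] + nx * half,
            fib$x2[i] - nx * half, fib$x1[i] - nx * half),
      y = c(fib$y1[i] + ny * half, fib$y2[i] + ny * half,
            fib$y2[i] - ny * half, fib$y1[i] - ny * half),
      id = fib$fibril_id[i])
  }))

  halo_r <- params$r + params$a
  circles <- if (nrow(par) > 0) {
    do.call(rbind, lapply(seq_len(nrow(par)), function(i) {
      cp <- circle_path(par$x[i], par$y[i], halo_r, par$particle_id[i])
      cp$status <- par$status[i]
      cp
    }))
  } else {
    tibble::tibble(x = numeric(0), y = numeric(0), id = character(0),
                   status = character(0))
  }

  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = bands,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id),
      fill = "#38a73866", colour = "#2d7a2d", linewidth = 0.2)
  if (nrow(circles) > 0) {
    p <- p + ggplot2::geom_path(
      data = circles,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                   colour = .data$status),
      linewidth = 0.4) +
      ggplot2::scale_colour_manual(
        values = c(bound = "red", unbound = "grey50"))
  }
  if (nrow(par) > 0) {
    p <- p + ggplot2::geom_point(
      data = par, ggplot2::aes(x = .data$x, y = .data$y), size = 0.5)
  }
  p <- p +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = annotations$meta$micrograph_id) +
    ggplot2::scale_y_reverse() +   # image convention: origin top-left
    ggplot2::theme_minimal()

  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 6, height = 6, dpi = 150)
  }
  invisible(p)
}
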