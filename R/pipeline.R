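## Machine-readable run manifest: parameters, package version and input
## hashes, so any published score table or report is traceable to its
## inputs. No timestamps — repeated runs with the same inputs must produce
## byte-identical output trees.
write_manifest <- function(path, command, params, inputs = character(0),
                           extra = list()) {
  hashes <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else list()
  jsonlite::write_json(
    c(list(command = command,
           package = "fibrilgold",
           version = as.character(utils::packageVersion("fibrilgold")),
           parameters = unclass(params),
           input_md5 = hashes),
      extra),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Score one annotated micrograph from files
#'
#' The full scoring path: read the annotation tables, optionally apply the
#' crowding filter, assign particles under the binding threshold, compute
#' per-fibril scores, and write the score CSV plus a run manifest
#' (`<out>.manifest.json`) and a short log of the counts.
#'
#' @param particles_file,fibrils_file Annotation CSV paths.
#' @param out Output score CSV path.
#' @param params A [binding_params()] object.
#' @param meta A [micrograph_meta()]; defaults to an id derived from the
#'   fibrils file name.
#' @param units,swap_xy,sample_label Passed to [read_annotations()].
#' @param min_separation When > 0, run [crowding_filter()] with this
#'   separation before assignment (default 0 = off; curated annotations
#'   are normally already selected for accessibility).
#' @param quiet Suppress the console log.
#' @return The score tibble, invisibly.
#' @export
run_score <- function(particles_file, fibrils_file, out,
                      params = binding_params(),
                      meta = NULL, units = "nm", swap_xy = FALSE,
                      sample_label = "", min_separation = 0,
                      quiet = FALSE) {
  if (is.null(meta)) {
    meta <- micrograph_meta(tools::file_path_sans_ext(basename(fibrils_file)))
  }
  ann <- read_annotations(particles_file, fibrils_file, meta,
                          units = units, swap_xy = swap_xy,
                          sample_label = sample_label)
  n_before <- nrow(ann$fibrils)
  if (min_separation > 0) {
    ann$fibrils <- crowding_filter(ann$fibrils, min_separation)
  }
  assignments <- assign_particles(ann, params)
  scores <- score_fibrils(assignments, ann)
  write_scores(scores, out)
  write_manifest(paste0(out, ".manifest.json"), "score", params,
                 inputs = c(particles_file, fibrils_file),
                 extra = list(min_separation = min_separation,
                              fibrils_in = n_before,
                              fibrils_scored = nrow(ann$fibrils)))
  if (!quiet) {
    message(sprintf(
      "[%s] threshold %.2f nm: %d/%d particles bound, %d fibrils scored%s",
      meta$micrograph_id, params$threshold,
      sum(assignments$status == "bound"), nrow(assignments),
      nrow(ann$fibrils),
      if (min_separation > 0)
        sprintf(" (%d dropped by crowding filter)", n_before - nrow(ann$fibrils))
      else ""))
  }
  invisible(scores)
}

#' Compare score files across samples
#'
#' Reads two or more score CSVs (as written by [run_score()] or
#' [write_scores()]), pools fibril scores by sample label, runs the gated
#' [compare_samples()] analysis, writes the JSON/TSV report and renders
#' the violin figure.
#'
#' @param score_files Character vector of score CSV paths (>= 2 distinct
#'   sample labels across them).
#' @param out_prefix Output prefix: writes `<prefix>.json`,
#'   `<prefix>.tsv` and `<prefix>.png`.
#' @param reference,alpha,gate_alpha,force_posthoc Passed to
#'   [compare_samples()].
#' @param outlier_rule Display rule for the figure (see [plot_spec()]).
#' @param quiet Suppress the console log.
#' @return The `binding_comparison`, invisibly.
#' @export
run_compare <- function(score_files, out_prefix, reference = NULL,
                        alpha = 0.05, gate_alpha = 0.05,
                        force_posthoc = FALSE, outlier_rule = "iqr",
                        quiet = FALSE) {
  tabs <- lapply(score_files, read_scores)
  all_scores <- dplyr::bind_rows(tabs)
  labels <- unique(all_scores$sample_label)
  if (length(labels) < 2L) {
    stop("need score files covering at least 2 distinct sample labels, got: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  samples <- split(all_scores$score,
                   factor(all_scores$sample_label, levels = labels))
  cmp <- compare_samples(samples, reference = reference, alpha = alpha,
                         gate_alpha = gate_alpha,
                         force_posthoc = force_posthoc)
  write_comparison(cmp, paste0(out_prefix, ".json"),
                   paste0(out_prefix, ".tsv"))
  violin_plot(samples, comparison = cmp,
              spec = plot_spec(outlier_rule = outlier_rule,
                               order = labels),
              out = paste0(out_prefix, ".png"))
  write_manifest(paste0(out_prefix, ".manifest.json"), "compare",
                 list(reference = reference, alpha = alpha,
                      gate_alpha = gate_alpha),
                 inputs = score_files)
  if (!quiet) {
    message(sprintf("route %s; omnibus %s p = %.3g; report at %s.json",
                    cmp$route, cmp$omnibus_name, cmp$omnibus_p, out_prefix))
  }
  invisible(cmp)
}

#' Simulate an annotated micrograph field to files
#'
#' Front-end for [generate_sample()]: writes the particles and fibrils
#' CSVs in the dialect [read_annotations()] reads, plus a ground-truth
#' CSV (`particle_id`, `label`, `source_fibril_id`) and a manifest, and
#' prints the closed-form [expected_score()] for the configuration.
#'
#' @param config A [synthetic_config()].
#' @param params A [binding_params()] object.
#' @param out_dir Output directory (created if needed).
#' @param sample_label,micrograph_id Labels for the generated set.
#' @param quiet Suppress the console log.
#' @return Invisibly, the list from [generate_sample()] plus the file
#'   paths.
#' @export
run_simulate <- function(config, params = binding_params(),
                         out_dir = ".", sample_label = "synthetic",
                         micrograph_id = "sim-0001", quiet = FALSE) {
  sim <- generate_sample(config, params, sample_label = sample_label,
                         micrograph_id = micrograph_id)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(out_dir, micrograph_id)
  paths <- list(particles = paste0(stem, "_particles.csv"),
                fibrils = paste0(stem, "_fibrils.csv"),
                truth = paste0(stem, "_truth.csv"))
  ann <- sim$annotations
  readr::write_csv(
    tibble::tibble(micrograph_id = micrograph_id,
                   particle_id = ann$particles$particle_id,
                   x = ann$particles$x, y = ann$particles$y),
    paths$particles)
  readr::write_csv(
    tibble::tibble(micrograph_id = micrograph_id,
                   fibril_id = ann$fibrils$fibril_id,
                   x1 = ann$fibrils$x1, y1 = ann$fibrils$y1,
                   x2 = ann$fibrils$x2, y2 = ann$fibrils$y2),
    paths$fibrils)
  readr::write_csv(sim$truth$particle_labels, paths$truth)
  es <- expected_score(config, params)
  write_manifest(paste0(stem, ".manifest.json"), "simulate", params,
                 extra = list(config = unclass(config),
                              expected_score = es))
  if (!quiet) {
    message(sprintf(
      "simulated %d fibrils, %d particles (seed %d); expected score %.5g /nm",
      nrow(ann$fibrils), nrow(ann$particles), config$seed, es))
  }
  invisible(c(sim, list(paths = paths, expected_score = es)))
}
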