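#' Micrograph metadata
#'
#' Describes one electron micrograph: its identifier, the pixel size used to
#' convert annotation coordinates to physical units, and the field extent.
#'
#' @param micrograph_id Character identifier.
#' @param pixel_size Pixel size in nm per pixel (required when annotations
#'   are in pixel units); must be positive.
#' @param field_width,field_height Field extent in nm (optional; must be
#'   positive when given).
#'
#' @return A `micrograph_meta` list.
#' @export
micrograph_meta <- function(micrograph_id, pixel_size = NULL,
                            field_width = NULL, field_height = NULL) {
  stopifnot(is.character(micrograph_id), length(micrograph_id) == 1L)
  for (v in list(pixel_size = pixel_size, field_width = field_width,
                 field_height = field_height)) NULL
  chk_pos <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)) {
      stop(nm, " must be a positive number", call. = FALSE)
    }
  }
  chk_pos(pixel_size, "pixel_size")
  chk_pos(field_width, "field_width")
  chk_pos(field_height, "field_height")
  structure(
    list(micrograph_id = micrograph_id, pixel_size = pixel_size,
         field_width = field_width, field_height = field_height),
    class = "micrograph_meta"
  )
}

#' Build a validated annotation set
#'
#' An annotation set holds one micrograph's particle centres and fibril
#' segments, all in nm. Fibril lengths are derived (Euclidean distance
#' between endpoints); zero-length fibrils and duplicate identifiers are
#' rejected.
#'
#' @param meta A [micrograph_meta()] object.
#' @param particles Data frame with columns `particle_id`, `x`, `y` (nm).
#' @param fibrils Data frame with columns `fibril_id`, `x1`, `y1`, `x2`,
#'   `y2` (nm).
#' @param sample_label Sample (group) label, e.g. a mouse-model name.
#'
#' @return An object of class `annotation_set` with elements `meta`,
#'   `particles` (tibble), `fibrils` (tibble, with derived `length` in nm)
#'   and `sample_label`.
#' @export
annotation_set <- function(meta, particles, fibrils, sample_label = "") {
  stopifnot(inherits(meta, "micrograph_meta"))
  particles <- tibble::as_tibble(particles)
  fibrils <- tibble::as_tibble(fibrils)

  for (col in c("particle_id", "x", "y")) {
    if (!col %in% names(particles)) {
      stop("particles: missing column '", col, "'", call. = FALSE)
    }
  }
  for (col in c("fibril_id", "x1", "y1", "x2", "y2")) {
    if (!col %in% names(fibrils)) {
      stop("fibrils: missing column '", col, "'", call. = FALSE)
    }
  }
  if (nrow(particles) > 0 && !all(is.finite(particles$x) & is.finite(particles$y))) {
    stop("particle coordinates must be finite", call. = FALSE)
  }
  coords <- c(fibrils$x1, fibrils$y1, fibrils$x2, fibrils$y2)
  if (nrow(fibrils) > 0 && !all(is.finite(coords))) {
    stop("fibril coordinates must be finite", call. = FALSE)
  }
  if (anyDuplicated(particles$particle_id)) {
    stop("duplicate particle_id: ",
         paste(unique(particles$particle_id[duplicated(particles$particle_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(fibrils$fibril_id)) {
    stop("duplicate fibril_id: ",
         paste(unique(fibrils$fibril_id[duplicated(fibrils$fibril_id)]),
               collapse = ", "), call. = FALSE)
  }
  len <- sqrt((fibrils$x2 - fibrils$x1)^2 + (fibrils$y2 - fibrils$y1)^2)
  if (any(len == 0)) {
    stop("zero-length fibril(s) at row(s): ",
         paste(which(len == 0), collapse = ", "),
         " (start and end points coincide)", call. = FALSE)
  }
  fibrils$length <- len
  structure(
    list(meta = meta, particles = particles, fibrils = fibrils,
         sample_label = sample_label),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "Annotation set '%s' (sample '%s'): %d particles, %d fibrils\n",
    x$meta$micrograph_id, x$sample_label,
    nrow(x$particles), nrow(x$fibrils)))
  if (nrow(x$fibrils) > 0) {
    cat(sprintf("  fibril length: %.0f-%.0f nm (median %.0f)\n",
                min(x$fibrils$length), max(x$fibrils$length),
                stats::median(x$fibrils$length)))
  }
  invisible(x)
}

## Read a CSV strictly: header required, all requested columns present,
## numeric columns validated cell by cell so errors can name the row.
read_annotation_csv <- function(path, required, numeric_cols, kind) {
  if (!file.exists(path)) {
    stop(kind, " file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(kind, " file ", basename(path), ": missing column(s) ",
         paste(sprintf("'%s'", missing), collapse = ", "), call. = FALSE)
  }
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) & nzchar(df[[col]]))
    bad <- union(bad, which(is.na(df[[col]]) | !nzchar(df[[col]])))
    if (length(bad) > 0) {
      stop(kind, " file ", basename(path), ": non-numeric value in column '",
           col, "' at data row(s) ", paste(sort(bad), collapse = ", "),
           call. = FALSE)
    }
    df[[col]] <- vals
  }
  tibble::as_tibble(df)
}

#' Read particle and fibril annotation tables
#'
#' Reads the two CSV tables exported from an annotation tool (one row per
#' gold particle with its centre coordinates; one row per fibril with its
#' start and end coordinates), validates them, converts pixel coordinates
#' to nm when required, and returns a validated [annotation_set()].
#'
#' The expected dialect is comma-separated UTF-8 with a header row and "."
#' as the decimal mark. Particles need columns `x`, `y`; fibrils need
#' `x1`, `y1`, `x2`, `y2`. `micrograph_id` and the id columns are optional:
#' absent ids are auto-generated (`p0001`, `f0001`, ...) in row order.
#' Point-annotation tools frequently export coordinates in (row, column)
#' order; set `swap_xy = TRUE` to interpret the x column as the row (y)
#' direction and vice versa. Internally x is the column direction, y the
#' row direction, origin at the image's top-left.
#'
#' @param particles_file,fibrils_file Paths to the CSV tables.
#' @param meta A [micrograph_meta()] object; its `pixel_size` is required
#'   when `units = "pixel"`.
#' @param units Unit of the coordinates in the files: `"nm"` (default) or
#'   `"pixel"` (converted to nm at load using `meta$pixel_size`).
#' @param swap_xy Logical; swap the interpretation of the coordinate axes
#'   for (row, col)-ordered exports. Applies to both tables.
#' @param sample_label Sample label attached to the annotation set.
#'
#' @return An [annotation_set()].
#' @export
read_annotations <- function(particles_file, fibrils_file, meta,
                             units = c("nm", "pixel"),
                             swap_xy = FALSE, sample_label = "") {
  units <- match.arg(units)
  stopifnot(inherits(meta, "micrograph_meta"))
  if (units == "pixel" && is.null(meta$pixel_size)) {
    stop("units = 'pixel' requires meta$pixel_size", call. = FALSE)
  }

  particles <- read_annotation_csv(particles_file, required = c("x", "y"),
                                   numeric_cols = c("x", "y"),
                                   kind = "particles")
  fibrils <- read_annotation_csv(fibrils_file,
                                 required = c("x1", "y1", "x2", "y2"),
                                 numeric_cols = c("x1", "y1", "x2", "y2"),
                                 kind = "fibrils")

  if (!"particle_id" %in% names(particles) ||
      all(!nzchar(particles$particle_id %||% ""))) {
    particles$particle_id <- sprintf("p%04d", seq_len(nrow(particles)))
  }
  if (!"fibril_id" %in% names(fibrils) ||
      all(!nzchar(fibrils$fibril_id %||% ""))) {
    fibrils$fibril_id <- sprintf("f%04d", seq_len(nrow(fibrils)))
  }

  if (swap_xy) {
    particles[c("x", "y")] <- particles[c("y", "x")]
    fibrils[c("x1", "y1", "x2", "y2")] <- fibrils[c("y1", "x1", "y2", "x2")]
  }
  if (units == "pixel") {
    s <- meta$pixel_size
    particles$x <- particles$x * s
    particles$y <- particles$y * s
    for (col in c("x1", "y1", "x2", "y2")) fibrils[[col]] <- fibrils[[col]] * s
  }

  annotation_set(meta,
                 particles[, c("particle_id", "x", "y")],
                 fibrils[, c("fibril_id", "x1", "y1", "x2", "y2")],
                 sample_label = sample_label)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write and read per-fibril binding score tables
#'
#' Scores are written as plain CSV with one row per fibril and columns
#' `sample_label`, `micrograph_id`, `fibril_id`, `length_nm`,
#' `bound_count`, `score`. Numeric values round-trip exactly through
#' write/read.
#'
#' @param scores A score table from [score_fibrils()] (may have zero rows;
#'   a header-only file is then written).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  need <- c("sample_label", "micrograph_id", "fibril_id",
            "length_nm", "bound_count", "score")
  if ("length" %in% names(scores) && !"length_nm" %in% names(scores)) {
    scores <- dplyr::rename(scores, length_nm = "length")
  }
  missing <- setdiff(need, names(scores))
  if (length(missing) > 0) {
    stop("score table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(scores[, need], path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_label = readr::col_character(),
                    micrograph_id = readr::col_character(),
                    fibril_id = readr::col_character(),
                    length_nm = readr::col_double(),
                    bound_count = readr::col_integer(),
                    score = readr::col_double()))
}

#' Read a pipeline configuration file
#'
#' Reads physical and statistical parameters from YAML (`.yaml`/`.yml`) or
#' JSON (`.json`). Recognised fields: `r_nm`, `a_nm`, `d_nm`,
#' `pixel_size_nm`, `units`, `reference_sample`, `alpha`, `gate_alpha`,
#' `min_separation_nm`, `seed`. Missing physical parameters fall back to
#' the [binding_params()] defaults.
#'
#' @param path Path to the configuration file.
#' @return A list with a `params` element ([binding_params()]) plus the
#'   remaining fields.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be YAML or JSON, got .", ext, call. = FALSE)
  )
  list(
    params = binding_params(
      r = raw$r_nm %||% 5, a = raw$a_nm %||% 30, d = raw$d_nm %||% 17),
    pixel_size_nm = raw$pixel_size_nm,
    units = raw$units %||% "nm",
    reference_sample = raw$reference_sample,
    alpha = raw$alpha %||% 0.05,
    gate_alpha = raw$gate_alpha %||% 0.05,
    min_separation_nm = raw$min_separation_nm,
    seed = raw$seed
  )
}
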