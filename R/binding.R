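#' Classify particles as bound and assign each to its closest fibril
#'
#' Computes the distance from every particle centre to every fibril segment
#' in the annotation set. A particle is bound when its minimum distance over
#' all fibrils is less than or equal to the binding threshold
#' (\eqn{r + a + d/2}); a bound particle is assigned to the fibril achieving
#' that minimum, so each particle contributes to at most one fibril. Exact
#' distance ties are broken in favour of the fibril that appears first in
#' the annotation file.
#'
#' Distances are computed in double precision and compared to the threshold
#' without rounding; the boundary is inclusive (a particle at exactly the
#' threshold distance is bound).
#'
#' @param annotations An [annotation_set()].
#' @param params A [binding_params()] object.
#'
#' @return A tibble with one row per particle: `particle_id`, `status`
#'   (`"bound"` or `"unbound"`), `fibril_id` (`NA` when unbound),
#'   `distance` (nm, to the assigned fibril, or the minimum over all
#'   fibrils when unbound; `NA` when the set has no fibrils).
#' @export
assign_particles <- function(annotations, params) {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(params, "binding_params"))
  particles <- annotations$particles
  fibrils <- annotations$fibrils
  n <- nrow(particles)

  if (n == 0L) {
    return(tibble::tibble(particle_id = character(0),
                          status = character(0),
                          fibril_id = character(0),
                          distance = numeric(0)))
  }
  if (nrow(fibrils) == 0L) {
    return(tibble::tibble(particle_id = particles$particle_id,
                          status = "unbound",
                          fibril_id = NA_character_,
                          distance = NA_real_))
  }

  D <- particle_fibril_distances(particles, fibrils)
  j <- max.col(-D, ties.method = "first")
  dmin <- D[cbind(seq_len(n), j)]
  bound <- dmin <= params$threshold

  tibble::tibble(
    particle_id = particles$particle_id,
    status = ifelse(bound, "bound", "unbound"),
    fibril_id = ifelse(bound, fibrils$fibril_id[j], NA_character_),
    distance = dmin
  )
}

#' Per-fibril binding scores
#'
#' For every fibril in the annotation set (including those with no bound
#' particles) counts the bound particles assigned to it and divides by the
#' fibril length, giving the binding score in particles per nm — the unit
#' of statistical analysis downstream.
#'
#' @param assignments Output of [assign_particles()] on the same set.
#' @param annotations The [annotation_set()] the assignments came from.
#'
#' @return A tibble with one row per fibril: `sample_label`,
#'   `micrograph_id`, `fibril_id`, `length_nm`, `bound_count`, `score`.
#' @export
score_fibrils <- function(assignments, annotations) {
  stopifnot(inherits(annotations, "annotation_set"))
  fibrils <- annotations$fibrils
  bound <- assignments[assignments$status == "bound", ]
  unknown <- setdiff(bound$fibril_id, fibrils$fibril_id)
  if (length(unknown) > 0) {
    stop("assignments reference unknown fibril_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(bound$fibril_id, levels = fibrils$fibril_id))
  tibble::tibble(
    sample_label = annotations$sample_label,
    micrograph_id = annotations$meta$micrograph_id,
    fibril_id = fibrils$fibril_id,
    length_nm = fibrils$length,
    bound_count = as.integer(counts),
    score = as.integer(counts) / fibrils$length
  )
}

#' Drop sterically crowded fibrils
#'
#' Retains only fibrils that are sufficiently separated from every other
#' retained fibril, mirroring the curation step that excludes fibrils made
#' inaccessible to antibodies by neighbouring fibrils. Retention is greedy
#' in file order: a fibril is dropped when its segment-to-segment distance
#' to any already-retained fibril is below `min_separation`.
#'
#' This filter is off by default in the pipeline: manually curated
#' annotations are normally already selected for accessibility. It matters
#' for exhaustive annotations and for synthetic fields. A natural setting
#' when enabled is the binding threshold itself, since a particle lying
#' between two fibrils closer than the threshold is ambiguous by
#' construction.
#'
#' @param fibrils Fibril tibble (columns `fibril_id`, `x1`, `y1`, `x2`,
#'   `y2`, optionally `length`).
#' @param min_separation Minimum allowed segment-to-segment distance in nm;
#'   `0` returns the input unchanged.
#'
#' @return The retained subset of `fibrils`, in the original order.
#' @export
crowding_filter <- function(fibrils, min_separation) {
  stopifnot(is.numeric(min_separation), min_separation >= 0)
  if (min_separation == 0 || nrow(fibrils) <= 1L) return(fibrils)
  keep <- logical(nrow(fibrils))
  keep[1] <- TRUE
  for (i in seq_len(nrow(fibrils))[-1]) {
    retained <- fibrils[keep, ]
    d <- seg_to_segs_distance(fibrils$x1[i], fibrils$y1[i],
                              fibrils$x2[i], fibrils$y2[i], retained)
    keep[i] <- all(d >= min_separation)
  }
  fibrils[keep, ]
}
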