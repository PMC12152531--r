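#' Configuration for the synthetic annotation generator
#'
#' Describes one simulated micrograph field: its extent, the number of
#' fibrils and their length distribution, the true (planted) binding rate
#' along fibrils, the uniform background particle density, and the minimum
#' fibril separation. The defaults emulate the study conditions the
#' pipeline targets: fields of well-separated straight fibrils a few
#' hundred nm long, a strongly-binding sample at about 0.02 bound
#' particles per nm of fibril, and a sparse non-specific background.
#'
#' Fibril lengths are drawn from a normal distribution truncated below at
#' `length_min`; the floor (default 50 nm) reflects that shorter filaments
#' are not resolvable as segments at typical magnification, and keeps the
#' per-length score well defined and stable.
#'
#' @param field_width,field_height Field extent in nm.
#' @param n_fibrils Number of fibrils to place.
#' @param length_mean,length_sd,length_min Fibril length distribution
#'   parameters in nm (normal truncated at `length_min`).
#' @param lambda_bound True rate of planted bound particles per nm of
#'   fibril length (>= 0).
#' @param background_density Uniform background particle density per nm^2
#'   (>= 0).
#' @param min_separation Minimum segment-to-segment distance between
#'   placed fibrils in nm; `NULL` resolves to twice the binding threshold
#'   at generation time, which makes every particle's assignment
#'   unambiguous. Use `0` to disable.
#' @param max_attempts Placement attempts per fibril before giving up.
#' @param seed Integer seed; generation is deterministic given the seed.
#'
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(field_width = 8000, field_height = 8000,
                             n_fibrils = 150,
                             length_mean = 400, length_sd = 150,
                             length_min = 50,
                             lambda_bound = 0.02,
                             background_density = 1e-5,
                             min_separation = NULL,
                             max_attempts = 5000,
                             seed = 1L) {
  stopifnot(field_width > 0, field_height > 0, n_fibrils >= 0,
            length_mean > 0, length_sd >= 0, length_min > 0,
            lambda_bound >= 0, background_density >= 0,
            is.null(min_separation) || min_separation >= 0,
            max_attempts >= 1)
  structure(
    list(field_width = field_width, field_height = field_height,
         n_fibrils = n_fibrils, length_mean = length_mean,
         length_sd = length_sd, length_min = length_min,
         lambda_bound = lambda_bound,
         background_density = background_density,
         min_separation = min_separation,
         max_attempts = max_attempts, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

rtrunc_norm <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(max(mean, lower), n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw > lower
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic annotation set with known ground truth
#'
#' Places `n_fibrils` straight fibrils with uniform random centre and
#' orientation inside the field (re-drawn until the minimum separation is
#' honoured, up to an attempt cap), with lengths from the truncated
#' normal. For each fibril a Poisson(`lambda_bound` x length) number of
#' planted bound particles is placed uniformly along the fibril axis with
#' a perpendicular offset drawn uniformly from \[0, threshold\] on a random
#' side — so every planted particle is bound by construction. A
#' Poisson(`background_density` x area) number of background particles is
#' scattered uniformly over the field.
#'
#' Fibrils are kept at least one binding threshold away from the field
#' border, so the full binding neighbourhood (a stadium of half-width
#' `threshold` around the segment) lies inside the field and the
#' closed-form [expected_score()] applies without edge corrections.
#'
#' @param config A [synthetic_config()].
#' @param params A [binding_params()] object (sets the threshold used for
#'   offsets, the default separation and the border margin).
#' @param sample_label,micrograph_id Labels attached to the generated set.
#'
#' @return A list with `annotations` (an [annotation_set()]) and `truth`
#'   (a `synthetic_truth` list: per-particle labels with source fibril,
#'   per-fibril planted counts, and the config used).
#' @export
generate_sample <- function(config, params, sample_label = "synthetic",
                            micrograph_id = "sim-0001") {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(params, "binding_params"))
  thr <- params$threshold
  sep <- config$min_separation %||% (2 * thr)
  W <- config$field_width
  H <- config$field_height
  margin <- thr
  if (W <= 2 * margin || H <= 2 * margin) {
    stop("field too small for the border margin of one threshold",
         call. = FALSE)
  }

  ## isolate this generator from the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  ## sequential fibril placement with rejection
  fx1 <- fy1 <- fx2 <- fy2 <- numeric(config$n_fibrils)
  for (i in seq_len(config$n_fibrils)) {
    ok <- FALSE
    placed <- list(x1 = fx1[seq_len(i - 1)], y1 = fy1[seq_len(i - 1)],
                   x2 = fx2[seq_len(i - 1)], y2 = fy2[seq_len(i - 1)])
    for (attempt in seq_len(config$max_attempts)) {
      L <- rtrunc_norm(1, config$length_mean, config$length_sd,
                       config$length_min)
      theta <- stats::runif(1, 0, pi)
      cx <- stats::runif(1, margin, W - margin)
      cy <- stats::runif(1, margin, H - margin)
      ux <- cos(theta); uy <- sin(theta)
      x1 <- cx - ux * L / 2; y1 <- cy - uy * L / 2
      x2 <- cx + ux * L / 2; y2 <- cy + uy * L / 2
      if (x1 < margin || x1 > W - margin || y1 < margin || y1 > H - margin ||
          x2 < margin || x2 > W - margin || y2 < margin || y2 > H - margin) {
        next
      }
      if (sep > 0 && i > 1L) {
        d <- seg_to_segs_distance(x1, y1, x2, y2, placed)
        if (any(d < sep)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not place fibril ", i, " after ", config$max_attempts,
           " attempts while honouring min_separation = ", sep,
           " nm; lower n_fibrils, min_separation or fibril length, or ",
           "enlarge the field", call. = FALSE)
    }
    fx1[i] <- x1; fy1[i] <- y1; fx2[i] <- x2; fy2[i] <- y2
  }
  fibrils <- tibble::tibble(
    fibril_id = sprintf("f%04d", seq_len(config$n_fibrils)),
    x1 = fx1, y1 = fy1, x2 = fx2, y2 = fy2)
  flen <- sqrt((fx2 - fx1)^2 + (fy2 - fy1)^2)

  ## planted bound particles, Poisson(lambda * length) per fibril
  n_planted <- if (config$n_fibrils > 0) {
    stats::rpois(config$n_fibrils, config$lambda_bound * flen)
  } else integer(0)
  src <- rep(seq_len(config$n_fibrils), n_planted)
  if (length(src) > 0) {
    t_along <- stats::runif(length(src)) * flen[src]
    offset <- stats::runif(length(src), 0, thr)
    side <- sample(c(-1, 1), length(src), replace = TRUE)
    ux <- (fx2 - fx1)[src] / flen[src]
    uy <- (fy2 - fy1)[src] / flen[src]
    px <- fx1[src] + ux * t_along - side * uy * offset
    py <- fy1[src] + uy * t_along + side * ux * offset
  } else {
    px <- py <- numeric(0)
  }

  ## uniform background over the whole field
  n_bg <- stats::rpois(1, config$background_density * W * H)
  bx <- stats::runif(n_bg, 0, W)
  by <- stats::runif(n_bg, 0, H)

  particles <- tibble::tibble(
    particle_id = sprintf("p%05d", seq_len(length(px) + n_bg)),
    x = c(px, bx), y = c(py, by))

  truth <- structure(
    list(
      particle_labels = tibble::tibble(
        particle_id = particles$particle_id,
        label = c(rep("planted_bound", length(px)),
                  rep("background", n_bg)),
        source_fibril_id = c(fibrils$fibril_id[src],
                             rep(NA_character_, n_bg))),
      fibril_truth = tibble::tibble(
        fibril_id = fibrils$fibril_id,
        length_nm = flen,
        planted_count = as.integer(n_planted)),
      config = config
    ),
    class = "synthetic_truth"
  )

  meta <- micrograph_meta(micrograph_id, pixel_size = 1,
                          field_width = W, field_height = H)
  list(
    annotations = annotation_set(meta, particles, fibrils,
                                 sample_label = sample_label),
    truth = truth
  )
}

#' Closed-form expected binding score of a synthetic sample
#'
#' In the isolated-fibril regime (`min_separation >= 2 * threshold`, so no
#' particle can lie within the threshold of two fibrils) the expected
#' per-fibril binding score decomposes into the planted rate plus the
#' background captured by the fibril's binding neighbourhood — a stadium
#' of half-width `threshold` with area \eqn{2 t L + \pi t^2}:
#' \deqn{E[score] = \lambda + 2 \rho t + \rho \pi t^2 E[1/L]}
#' where \eqn{\lambda} is `lambda_bound`, \eqn{\rho} the background
#' density, \eqn{t} the threshold and the end-cap term carries the mean
#' inverse fibril length, evaluated by numerical integration over the
#' truncated normal length distribution (using \eqn{1/E[L]} instead
#' biases the end-cap term low by Jensen's inequality).
#'
#' @param config A [synthetic_config()].
#' @param params A [binding_params()] object.
#' @return Expected mean fibril score in particles per nm.
#' @export
expected_score <- function(config, params) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(params, "binding_params"))
  t <- params$threshold
  rho <- config$background_density
  mean_inv_len <- if (config$length_sd == 0) {
    1 / max(config$length_mean, config$length_min)
  } else {
    z <- stats::pnorm(config$length_min, config$length_mean,
                      config$length_sd, lower.tail = FALSE)
    stats::integrate(
      function(l) (1 / l) *
        stats::dnorm(l, config$length_mean, config$length_sd) / z,
      lower = config$length_min, upper = Inf)$value
  }
  config$lambda_bound + rho * 2 * t + rho * pi * t^2 * mean_inv_len
}
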