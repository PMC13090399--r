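# Parametric synthetic cranial-patch generator.
#
# The template is an analytic open spherical-cap patch (the "squama") with a
# Gaussian ridge along its anterior-inferior margin (the "supraorbital"
# bulge) and a posterior shear controlling how receding the squama is.
# Because the surface is analytic, two templates built at the same resolution
# share exact vertex correspondence by parameter value — the ground-truth
# oracle used by the registration tests.

# fixed template geometry (mm / radians)
.tpl <- list(R = 60,            # base radius: bregma-ophryon arc ~ 90 mm
             alpha_max = 1.45,  # elevation span (rad), open at the top
             theta_max = 1.10,  # half-breadth azimuth span (rad)
             ridge_width = 0.145,   # Gaussian ridge width in alpha (rad)
             shear_max = 0.6)       # posterior shear at inclination = 1

#' Shape parameters of the synthetic cranial patch
#'
#' @param squama_inclination dimensionless in \[0, 1\]: 0 = vertical squama,
#'   1 = fully receding (sheared posteriorly).
#' @param brow_prominence mm, amplitude of the anterior supraorbital ridge
#'   bulge (>= 0).
#' @param squama_breadth dimensionless lateral aspect factor (> 0).
#' @param size_scale dimensionless global scale (> 0).
#' @return An object of class `shape_params`.
#' @export
shape_params <- function(squama_inclination = 0.4, brow_prominence = 2,
                         squama_breadth = 1, size_scale = 1) {
  if (brow_prominence < 0) dm_stop("brow_prominence must be >= 0")
  if (size_scale <= 0) dm_stop("size_scale must be > 0")
  if (squama_breadth <= 0) dm_stop("squama_breadth must be > 0")
  structure(list(squama_inclination = squama_inclination,
                 brow_prominence = brow_prominence,
                 squama_breadth = squama_breadth,
                 size_scale = size_scale),
            class = "shape_params")
}

# analytic surface map: (alpha, theta) -> 3D point, vectorized
template_surface <- function(alpha, theta, params) {
  g <- .tpl
  ca <- cos(alpha); sa <- sin(alpha)
  # radial unit direction of the underlying sphere point
  ux <- ca * sin(theta); uy <- ca * cos(theta); uz <- sa
  r <- g$R + params$brow_prominence * exp(-(alpha / g$ridge_width)^2)
  x <- params$squama_breadth * r * ux
  y <- r * uy
  z <- r * uz
  # receding squama: push the top posteriorly (negative y = posterior)
  y <- y - params$squama_inclination * g$shear_max * z
  cbind(x, y, z) * params$size_scale
}

#' Elevation band affected by the synthetic brow ridge
#'
#' Vertices with parametric elevation `alpha <= 3 * ridge_width` — where the
#' Gaussian ridge carries > 99.98% of its mass. Used by tests that check the
#' brow displacement is confined to this band.
#' @param mesh a template mesh produced by [make_template()].
#' @return Logical vector over vertices.
#' @export
ridge_band <- function(mesh) {
  attr(mesh, "alpha") <= 3 * .tpl$ridge_width
}

#' Build the parametric template mesh and its landmarks
#'
#' Constructs an open, single-layered triangular patch of approximately
#' `resolution` vertices from the analytic surface, and places the six
#' canonical registration landmarks at fixed parametric positions (apex
#' midline = bregma, anterior midline above the ridge = ophryon, lateral
#' ridge ends = frontotemporale L/R, lateral posterior margin = stephanion
#' L/R). Deterministic for fixed inputs; two calls at the same resolution
#' yield vertex-wise corresponding meshes.
#'
#' @param params a [shape_params].
#' @param resolution target vertex count (>= 50).
#' @param specimen_id identifier for the outputs.
#' @return A list with elements `mesh` ([tri_mesh], with per-vertex
#'   parametric coordinates attached as attributes `alpha`/`theta`) and
#'   `landmarks` ([landmark_set]).
#' @export
make_template <- function(params, resolution = 2000, specimen_id = "template") {
  if (resolution < 50) dm_stop("resolution must be >= 50")
  g <- .tpl
  # grid dimensions: columns/rows proportional to the patch aspect
  aspect <- (2 * g$theta_max * params$squama_breadth) / g$alpha_max
  n_v <- max(5L, round(sqrt(resolution * aspect)))
  n_u <- max(5L, round(resolution / n_v))
  alpha <- seq(0, g$alpha_max, length.out = n_u)
  theta <- seq(-g$theta_max, g$theta_max, length.out = n_v)
  gr <- expand.grid(theta = theta, alpha = alpha) # theta fastest: row-major rows
  v <- template_surface(gr$alpha, gr$theta, params)
  # two triangles per grid quad
  idx <- function(i, j) (i - 1L) * n_v + j  # i over alpha rows, j over theta cols
  i <- rep(seq_len(n_u - 1L), each = n_v - 1L)
  j <- rep(seq_len(n_v - 1L), times = n_u - 1L)
  f <- rbind(cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j)),
             cbind(idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j)))
  mesh <- tri_mesh(v, f, specimen_id)
  attr(mesh, "alpha") <- gr$alpha
  attr(mesh, "theta") <- gr$theta
  lm_par <- rbind(bregma            = c(g$alpha_max, 0),
                  ophryon           = c(0.35 * g$alpha_max, 0),
                  frontotemporale_L = c(0.05 * g$alpha_max, -g$theta_max),
                  frontotemporale_R = c(0.05 * g$alpha_max, g$theta_max),
                  stephanion_L      = c(0.75 * g$alpha_max, -g$theta_max),
                  stephanion_R      = c(0.75 * g$alpha_max, g$theta_max))
  pts <- template_surface(lm_par[, 1], lm_par[, 2], params)
  rownames(pts) <- rownames(lm_par)
  list(mesh = mesh, landmarks = landmark_set(pts, specimen_id))
}

#' Population specification for the synthetic sample generator
#'
#' @param groups list of group definitions, each a list with `label`
#'   (character), `mean` (a [shape_params]), `sd` (named list/vector of
#'   per-parameter SDs; `size_scale` SD acts on the log scale), and `n`
#'   (specimens, >= 1).
#' @param allometric_slope change in `squama_inclination` per unit log
#'   `size_scale` (the injected static-allometry coupling; 0 = none).
#' @param landmark_noise_sd mm, isotropic Gaussian landmark placement noise.
#'   Default 0.5 mm, inside the 0.19-3.08 mm observer-error range reported
#'   for real cranial landmarking.
#' @param vertex_jitter_sd mm, per-vertex isotropic jitter emulating scan
#'   noise. Default 0.05 mm.
#' @param mesh_resolution target vertex count per specimen (default 2000).
#' @param resolution_jitter relative spread of per-specimen resolution
#'   (default 0.1, i.e. +/-10%), so targets genuinely lack vertex
#'   correspondence with the reference; set 0 for ground-truth-corresponding
#'   meshes.
#' @param seed integer RNG seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(groups, allometric_slope = 0,
                            landmark_noise_sd = 0.5, vertex_jitter_sd = 0.05,
                            mesh_resolution = 2000, resolution_jitter = 0.1,
                            seed = 1L) {
  for (gdef in groups) {
    if (is.null(gdef$label) || is.null(gdef$mean) || is.null(gdef$sd) ||
          is.null(gdef$n))
      dm_stop("each group needs label, mean, sd and n")
    if (gdef$n < 1) dm_stop("group n must be >= 1")
    if (any(unlist(gdef$sd) < 0)) dm_stop("group SDs must be >= 0")
  }
  if (landmark_noise_sd < 0 || vertex_jitter_sd < 0 || resolution_jitter < 0)
    dm_stop("noise SDs must be >= 0")
  structure(list(groups = groups, allometric_slope = allometric_slope,
                 landmark_noise_sd = landmark_noise_sd,
                 vertex_jitter_sd = vertex_jitter_sd,
                 mesh_resolution = mesh_resolution,
                 resolution_jitter = resolution_jitter,
                 seed = as.integer(seed)),
            class = "population_spec")
}

sd_of <- function(sdlist, name) {
  v <- sdlist[[name]]
  if (is.null(v)) 0 else as.numeric(v)
}

#' Draw a synthetic specimen sample
#'
#' Per specimen: draws shape parameters from its group distribution
#' (`size_scale` log-normally), couples `squama_inclination` to the drawn log
#' size through `allometric_slope`, builds the template at a per-specimen
#' resolution, adds vertex jitter and landmark placement noise. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec a [population_spec].
#' @return A list with `meshes` (list of [tri_mesh]), `landmarks` (list of
#'   [landmark_set]) and `study` (data.frame: specimen_id, group, period,
#'   abbrev, surface_area_cm2, log_size and the drawn true parameters).
#' @export
sample_population <- function(spec) {
  with_seed(spec$seed, {
    meshes <- list(); lms <- list(); rows <- list()
    s_idx <- 0L
    for (gdef in spec$groups) {
      mu <- gdef$mean
      for (i in seq_len(gdef$n)) {
        s_idx <- s_idx + 1L
        id <- sprintf("%s_%02d", gdef$label, i)
        log_size <- rnorm(1, log(mu$size_scale), sd_of(gdef$sd, "size_scale"))
        incl <- rnorm(1, mu$squama_inclination,
                      sd_of(gdef$sd, "squama_inclination")) +
          spec$allometric_slope * (log_size - log(mu$size_scale))
        brow <- max(0, rnorm(1, mu$brow_prominence,
                             sd_of(gdef$sd, "brow_prominence")))
        breadth <- max(0.2, rnorm(1, mu$squama_breadth,
                                  sd_of(gdef$sd, "squama_breadth")))
        pars <- shape_params(squama_inclination = incl, brow_prominence = brow,
                             squama_breadth = breadth,
                             size_scale = exp(log_size))
        res <- round(spec$mesh_resolution *
                       (1 + runif(1, -spec$resolution_jitter,
                                  spec$resolution_jitter)))
        tpl <- make_template(pars, resolution = res, specimen_id = id)
        mesh <- tpl$mesh
        if (spec$vertex_jitter_sd > 0)
          mesh$vertices <- mesh$vertices +
            matrix(rnorm(length(mesh$vertices), 0, spec$vertex_jitter_sd),
                   ncol = 3)
        lm <- tpl$landmarks
        if (spec$landmark_noise_sd > 0)
          lm$points <- lm$points +
            matrix(rnorm(length(lm$points), 0, spec$landmark_noise_sd),
                   ncol = 3)
        meshes[[s_idx]] <- mesh
        lms[[s_idx]] <- lm
        rows[[s_idx]] <- data.frame(
          specimen_id = id, group = gdef$label,
          period = if (is.null(gdef$period)) gdef$label else gdef$period,
          abbrev = sprintf("%s%d", substr(gdef$label, 1, 2), i),
          surface_area_cm2 = surface_area(mesh),
          log_size = log_size,
          squama_inclination = incl, brow_prominence = brow,
          squama_breadth = breadth, size_scale = exp(log_size),
          stringsAsFactors = FALSE)
      }
    }
    study <- do.call(rbind, rows)
    rownames(study) <- NULL
    list(meshes = meshes, landmarks = lms, study = study)
  })
}

#' Perturb a landmark set with isotropic Gaussian noise
#'
#' Emulates repeated landmark digitization sessions: `n_repeats` noisy copies
#' tagged with synthetic observer/session ids. At `sd = 1` mm the expected
#' per-landmark displacement is `sqrt(8/pi) = 1.5958` mm (the mean of a 3D
#' Gaussian radial norm).
#'
#' @param lms a [landmark_set].
#' @param sd mm (>= 0).
#' @param n_repeats number of noisy copies.
#' @param seed integer RNG seed.
#' @param n_observers repeats are split round-robin across this many
#'   synthetic observers (default 1).
#' @return List of [landmark_set] objects.
#' @export
perturb_landmarks <- function(lms, sd, n_repeats, seed = 1L, n_observers = 1L) {
  if (sd < 0) dm_stop("sd must be >= 0")
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(i) {
      out <- lms
      out$points <- lms$points +
        matrix(rnorm(length(lms$points), 0, sd), ncol = 3)
      out$observer_id <- sprintf("obs%d", ((i - 1L) %% n_observers) + 1L)
      out$session_id <- sprintf("s%03d", i)
      out
    })
  })
}
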