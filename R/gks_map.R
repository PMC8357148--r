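#' Parameters of the iterative gKs ("ACh") map generator
#'
#' The spatial gKs field over the E lattice is produced by a discrete
#' diffusion-release-decay process: each iteration applies a 5-point
#' Laplacian (diffusion of the modulator), subtracts a constant release
#' term at the chosen hotspot sites (ACh release lowers gKs) and relaxes
#' the field back towards the unmodulated ceiling (modulator decay), then
#' hard-clamps to `[gks_min, gks_max]`. The iteration is frozen at a chosen
#' step; only the frozen map enters the network simulation, so (D, B,
#' R_amp) parameterize a family of profiles whose operative descriptor is
#' the effective hotspot radius at the 0.6 mS/cm^2 contour.
#'
#' @param D diffusion coefficient (lattice^2 per step)
#' @param B decay rate towards `gks_max` (1/step)
#' @param R_amp release magnitude at source sites (gKs units per step)
#' @param gks_min,gks_max clamp bounds (mS/cm^2)
#' @param step_cap maximum number of iterations during calibration
#' @return object of class `gks_map_params`
#' @export
gks_map_params <- function(D = 0.2, B = 0.04, R_amp = 25,
                           gks_min = 0.2, gks_max = 1.5, step_cap = 20000L) {
  stopifnot(D >= 0, B >= 0, R_amp >= 0, gks_min <= gks_max, step_cap > 0)
  structure(list(D = D, B = B, R_amp = R_amp, gks_min = gks_min,
                 gks_max = gks_max, step_cap = as.integer(step_cap)),
            class = "gks_map_params")
}

# periodic shifts of a matrix by one cell in each direction
.shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 + dr) %% nr) + 1, ((seq_len(nc) - 1 + dc) %% nc) + 1]
}

#' One step of the diffusion-release-decay iteration
#'
#' `next = cur + D * Laplacian(cur) - R + B * (gks_max - cur)`, followed by
#' a hard clamp to `[gks_min, gks_max]`. `R` equals `R_amp` at release
#' sites and 0 elsewhere; the Laplacian uses periodic boundaries and unit
#' lattice spacing.
#'
#' @param field numeric matrix (E-lattice gKs values, rows = x, cols = y)
#' @param sites integer matrix of release-site coordinates (columns x, y,
#'   0-based), or NULL
#' @param params [gks_map_params()]
#' @param clamp apply the bound clamp (disable to inspect the raw update)
#' @return updated matrix
#' @export
gks_iterate_step <- function(field, sites = NULL, params = gks_map_params(),
                             clamp = TRUE) {
  if (!all(is.finite(field))) stop("field must be finite")
  lap <- .shift(field, 1, 0) + .shift(field, -1, 0) +
         .shift(field, 0, 1) + .shift(field, 0, -1) - 4 * field
  R <- matrix(0, nrow(field), ncol(field))
  if (!is.null(sites) && nrow(sites) > 0)
    R[cbind(sites[, 1] + 1L, sites[, 2] + 1L)] <- params$R_amp
  nxt <- field + params$D * lap - R + params$B * (params$gks_max - field)
  if (any(!is.finite(nxt)))
    stop("gKs iteration diverged (non-finite values); check D, B, R_amp")
  if (clamp) nxt <- pmin(pmax(nxt, params$gks_min), params$gks_max)
  nxt
}

#' Effective radius of a gKs hotspot
#'
#' Area-equivalent radius of the sub-threshold region: `r = sqrt(count /
#' pi)` where `count` is the number of E cells with gKs below `threshold`
#' (the 0.6 mS/cm^2 contour drawn in the map figures).
#'
#' @param E_values E-lattice gKs matrix or `gks_map` object
#' @param threshold contour level (mS/cm^2)
#' @return effective radius (lattice units)
#' @export
hotspot_radius <- function(E_values, threshold = 0.6) {
  if (inherits(E_values, "gks_map")) E_values <- E_values$E_values
  count <- sum(E_values < threshold)
  if (count == 0) stop("no hotspot: no cells below the threshold")
  sqrt(count / pi)
}

#' Assign I-cell gKs values by 2x2 block averaging
#'
#' Each I cell receives the arithmetic mean of the 4 E cells in the 2x2
#' block centered on it. `override_zero` sets all I values to 0 instead
#' (the no-I-cell-M-current variant).
#'
#' @param E_values E-lattice gKs matrix (L_E x L_E)
#' @param override_zero force all I-cell gKs to 0
#' @return L_I x L_I matrix of I-cell gKs values
#' @export
assign_I_gks <- function(E_values, override_zero = FALSE) {
  L <- nrow(E_values)
  stopifnot(L %% 2 == 0, ncol(E_values) == L)
  LI <- L %/% 2
  if (override_zero) return(matrix(0, LI, LI))
  odd <- seq(1, L, by = 2)
  (E_values[odd, odd] + E_values[odd + 1, odd] +
   E_values[odd, odd + 1] + E_values[odd + 1, odd + 1]) / 4
}

#' Draw random hotspot site coordinates
#'
#' Uniform positions on the E lattice; sites may coincide or be adjacent,
#' in which case the resulting hotspots overlap and coalesce.
#'
#' @param n number of sites
#' @param seed integer RNG seed
#' @param geom [lattice_geometry()]
#' @return integer matrix with columns `x`, `y` (0-based)
#' @export
random_sites <- function(n, seed = 1L, geom = lattice_geometry()) {
  stopifnot(n >= 0)
  set.seed(seed)
  cbind(x = sample.int(geom$L_E, n, replace = TRUE) - 1L,
        y = sample.int(geom$L_E, n, replace = TRUE) - 1L)
}

# freeze step at which an isolated site first reaches the target radius
.calibrate_freeze_step <- function(target_radius, params, geom,
                                   threshold = 0.6) {
  L <- geom$L_E
  field <- matrix(params$gks_max, L, L)
  site <- matrix(c(L %/% 2, L %/% 2), 1)
  for (step in seq_len(params$step_cap)) {
    field <- gks_iterate_step(field, site, params, clamp = FALSE)
    count <- sum(field < threshold)
    if (count > 0 && sqrt(count / pi) >= target_radius) return(step)
  }
  stop("target radius ", target_radius,
       " not reached within step cap ", params$step_cap)
}

#' Generate a frozen heterogeneous gKs map
#'
#' Starts from the uniform field at `gks_max`, iterates the
#' diffusion-release-decay process with constant release at `sites`, and
#' freezes at the step where an isolated single site first reaches
#' `target_radius` at the 0.6 mS/cm^2 contour (calibrated on a one-site
#' reference run, so maps with different site lists but the same target
#' radius are frozen at the same step). The frozen field is clamped to
#' `[gks_min, gks_max]` and I-cell values are assigned by 2x2 block
#' averaging. Deterministic given `sites` and `params`.
#'
#' @param sites integer matrix of 0-based site coordinates (columns x, y),
#'   or `NULL`/empty for the homogeneous control at `gks_max`
#' @param target_radius effective hotspot radius (lattice units)
#' @param params [gks_map_params()]
#' @param geom [lattice_geometry()]
#' @param n_steps freeze step; overrides the radius calibration if given
#' @param I_gks_zero set all I-cell gKs to 0 (no M-current in I population)
#' @return object of class `gks_map` with `E_values` (L_E x L_E),
#'   `I_values` (L_I x L_I) and `provenance`
#' @export
generate_gks_map <- function(sites, target_radius = NULL,
                             params = gks_map_params(),
                             geom = lattice_geometry(),
                             n_steps = NULL, I_gks_zero = FALSE) {
  L <- geom$L_E
  field <- matrix(params$gks_max, L, L)
  if (is.null(sites) || NROW(sites) == 0) {
    n_steps <- 0L
  } else {
    sites <- matrix(as.integer(sites), ncol = 2)
    if (any(sites < 0 | sites >= L)) stop("sites outside the E lattice")
    if (is.null(n_steps)) {
      if (is.null(target_radius))
        stop("give either target_radius or n_steps")
      n_steps <- .calibrate_freeze_step(target_radius, params, geom)
    }
    # the iteration runs unclamped (it is linear, so multi-site maps are
    # superpositions of single-site bowls); the paper's bounds are imposed
    # on the frozen mapping
    for (i in seq_len(n_steps))
      field <- gks_iterate_step(field, sites, params, clamp = FALSE)
    field <- pmin(pmax(field, params$gks_min), params$gks_max)
  }
  structure(list(E_values = field,
                 I_values = assign_I_gks(field, override_zero = I_gks_zero),
                 provenance = list(params = params, sites = sites,
                                   n_steps = n_steps,
                                   target_radius = target_radius,
                                   I_gks_zero = I_gks_zero)),
            class = "gks_map")
}

#' Homogeneous gKs map
#'
#' Control map with every E and I cell at the same gKs value.
#'
#' @param value gKs (mS/cm^2)
#' @param geom [lattice_geometry()]
#' @param I_gks_zero set all I-cell gKs to 0
#' @return `gks_map` object
#' @export
uniform_gks_map <- function(value = 1.5, geom = lattice_geometry(),
                            I_gks_zero = FALSE) {
  field <- matrix(value, geom$L_E, geom$L_E)
  structure(list(E_values = field,
                 I_values = assign_I_gks(field, override_zero = I_gks_zero),
                 provenance = list(uniform = value, I_gks_zero = I_gks_zero)),
            class = "gks_map")
}

#' @export
print.gks_map <- function(x, ...) {
  cat("gKs map:", nrow(x$E_values), "x", ncol(x$E_values),
      "E lattice; range", sprintf("[%.3f, %.3f] mS/cm^2\n",
      min(x$E_values), max(x$E_values)))
  invisible(x)
}

#' Write a gKs map as a delimited numeric grid
#'
#' The E grid and I grid are written as tab-separated blocks with
#' `#`-prefixed header lines recording the provenance.
#'
#' @param map `gks_map`
#' @param path output file
#' @export
write_gks_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pv <- map$provenance
  hdr <- if (!is.null(pv$uniform)) sprintf("uniform=%g", pv$uniform) else
    sprintf("n_sites=%d n_steps=%d", NROW(pv$sites), pv$n_steps)
  writeLines(c(paste("# achnet gKs map", hdr), "# E block then I block"), con)
  utils::write.table(map$E_values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(map$I_values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# flatten map values into the per-ID gKs vector (E IDs then I IDs);
# matrices are indexed [x+1, y+1] and the ID index is y + x*L, so the ID
# order runs y fastest within x, i.e. the row-major flatten
.gks_vector <- function(map) {
  c(as.vector(t(map$E_values)), as.vector(t(map$I_values)))
}
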