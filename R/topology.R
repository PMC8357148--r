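#' Lattice geometry of the E-I network
#'
#' 400 excitatory cells on an `L_E x L_E` lattice and 100 inhibitory cells
#' on an `L_I x L_I` lattice with `L_E = 2 L_I`, so that every I cell sits
#' at the center of a 2x2 block of E cells. The unit of length is the
#' minimal inter-cell distance on the E lattice; both lattices are periodic
#' in both dimensions.
#'
#' @param L_E side of the excitatory lattice (cells)
#' @param L_I side of the inhibitory lattice (cells)
#' @return object of class `lattice_geometry`
#' @export
lattice_geometry <- function(L_E = 20L, L_I = 10L) {
  L_E <- as.integer(L_E); L_I <- as.integer(L_I)
  stopifnot(L_E >= 2, L_I >= 1, L_E == 2L * L_I)
  structure(list(L_E = L_E, L_I = L_I, n_E = L_E^2, n_I = L_I^2),
            class = "lattice_geometry")
}

#' Synaptic parameters
#'
#' Class strengths of the four synapse types (E-E, E-I, I-I, I-E),
#' exponential decay time constants and reversal potentials. Excitatory and
#' inhibitory decay constants are separate so the inhibitory timescale can
#' be scanned while holding the product `w_inh * tau_inh` constant.
#'
#' @param wEE,wEI,wII,wIE synaptic strengths (mS/cm^2); `wEI` is E onto I,
#'   `wIE` is I onto E
#' @param tau_exc,tau_inh synaptic decay constants (ms)
#' @param E_exc,E_inh reversal potentials (mV)
#' @return object of class `synapse_params`
#' @export
synapse_params <- function(wEE = 0.01, wEI = 0.05, wII = 0.04, wIE = 0.04,
                           tau_exc = 3.0, tau_inh = 3.0,
                           E_exc = 0, E_inh = -75) {
  stopifnot(wEE >= 0, wEI >= 0, wII >= 0, wIE >= 0, tau_exc > 0, tau_inh > 0)
  structure(list(wEE = wEE, wEI = wEI, wII = wII, wIE = wIE,
                 tau_exc = tau_exc, tau_inh = tau_inh,
                 E_exc = E_exc, E_inh = E_inh),
            class = "synapse_params")
}

#' Map lattice coordinates to raster cell IDs
#'
#' Cells are indexed column-major: internal 0-based index `y + x * L`.
#' Emitted IDs are 1-based, with E cells occupying 1..n_E and I cells
#' n_E+1 .. n_E+n_I (1..400 and 401..500 for the default geometry).
#'
#' @param x,y 0-based lattice coordinates (vectorized)
#' @param kind `"E"` or `"I"`
#' @param geom [lattice_geometry()]
#' @return integer cell IDs
#' @export
cell_id <- function(x, y, kind = c("E", "I"), geom = lattice_geometry()) {
  kind <- match.arg(kind)
  L <- if (kind == "E") geom$L_E else geom$L_I
  if (any(x < 0 | x >= L | y < 0 | y >= L))
    stop("coordinates out of range for the ", kind, " lattice")
  idx <- as.integer(y + x * L)
  if (kind == "E") idx + 1L else geom$n_E + idx + 1L
}

#' Euclidean distance under periodic (minimum-image) boundary conditions
#'
#' @param p,q coordinate pairs or n x 2 matrices
#' @param L lattice side (wrap period)
#' @return numeric distances (lattice units)
#' @export
periodic_distance <- function(p, q, L) {
  p <- matrix(p, ncol = 2); q <- matrix(q, ncol = 2)
  d <- (p[rep_len(seq_len(nrow(p)), max(nrow(p), nrow(q))), , drop = FALSE] -
        q[rep_len(seq_len(nrow(q)), max(nrow(p), nrow(q))), , drop = FALSE])
  d <- (d + L / 2) %% L - L / 2
  sqrt(rowSums(d^2))
}

# minimum-image wrap of coordinate offsets
.wrap <- function(d, L) (d + L / 2) %% L - L / 2

# rank candidate offsets by (squared distance, |angle to +x axis|); a final
# target-ID tie-break is applied by the stable order of the candidates
.rank_offsets <- function(dx, dy) {
  d2 <- dx^2 + dy^2
  ang <- abs(atan2(dy, dx))
  order(d2, ang)
}

#' Build the default local-excitation / global-inhibition topology
#'
#' Every E cell sends synapses to its 40 nearest E cells and its 10 nearest
#' I cells under the periodic metric (I cells sit at their 2x2 block
#' centers). Every I cell sends synapses to all E cells and to all other I
#' cells (autapses excluded). Ties at the neighborhood boundary are broken
#' by (distance, |angle to +x axis|, target ID), which is deterministic.
#'
#' @param geom [lattice_geometry()]
#' @param syn [synapse_params()]
#' @return object of class `network_topology`: list with `geom`, `syn`,
#'   `kind` (per-ID "E"/"I"), `positions` (per-ID coordinates in E-lattice
#'   units) and `edges` (data.frame `src`, `tgt`, `w` with 1-based IDs)
#' @export
build_topology <- function(geom = lattice_geometry(), syn = synapse_params()) {
  LE <- geom$L_E; LI <- geom$L_I
  nE <- geom$n_E; nI <- geom$n_I
  ex <- rep(0:(LE - 1), each = LE)   # ID order: index = y + x*L
  ey <- rep(0:(LE - 1), times = LE)
  ix <- rep(0:(LI - 1), each = LI)
  iy <- rep(0:(LI - 1), times = LI)
  posE <- cbind(x = ex, y = ey)
  posI <- cbind(x = 2 * ix + 0.5, y = 2 * iy + 0.5)

  # E -> E: the 40-nearest offset stencil is translation invariant
  odx <- rep(0:(LE - 1), times = LE); ody <- rep(0:(LE - 1), each = LE)
  wdx <- .wrap(odx, LE); wdy <- .wrap(ody, LE)
  keep <- !(odx == 0 & ody == 0)
  ord <- .rank_offsets(wdx[keep], wdy[keep])
  sel <- cbind(odx[keep][ord], ody[keep][ord])[seq_len(min(40L, nE - 1L)), , drop = FALSE]
  ee_src <- rep(seq_len(nE), each = nrow(sel))
  tx <- (rep(ex, each = nrow(sel)) + sel[, 1]) %% LE
  ty <- (rep(ey, each = nrow(sel)) + sel[, 2]) %% LE
  ee_tgt <- ty + tx * LE + 1L

  # E -> I: 10 nearest I cells; relative geometry depends on E parity, so
  # rank per source (cheap: 400 x 100 distances)
  ei_src <- integer(0); ei_tgt <- integer(0)
  kI <- min(10L, nI)
  ei_src <- rep(seq_len(nE), each = kI)
  ei_tgt <- integer(nE * kI)
  for (s in seq_len(nE)) {
    ddx <- .wrap(posI[, 1] - ex[s], LE)
    ddy <- .wrap(posI[, 2] - ey[s], LE)
    ord <- .rank_offsets(ddx, ddy)
    ei_tgt[((s - 1) * kI + 1):(s * kI)] <- nE + ord[seq_len(kI)]
  }

  # I -> E (all) and I -> I (all but self)
  ie_src <- rep(nE + seq_len(nI), each = nE)
  ie_tgt <- rep(seq_len(nE), times = nI)
  ii <- expand.grid(src = nE + seq_len(nI), tgt = nE + seq_len(nI))
  ii <- ii[ii$src != ii$tgt, ]

  edges <- data.frame(
    src = c(ee_src, ei_src, ie_src, ii$src),
    tgt = c(ee_tgt, ei_tgt, ie_tgt, ii$tgt),
    w = c(rep(syn$wEE, length(ee_src)), rep(syn$wEI, length(ei_src)),
          rep(syn$wIE, length(ie_src)), rep(syn$wII, nrow(ii))))
  edges <- edges[order(edges$src, edges$tgt), ]
  rownames(edges) <- NULL

  structure(list(geom = geom, syn = syn,
                 kind = c(rep("E", nE), rep("I", nI)),
                 positions = rbind(posE, posI),
                 edges = edges),
            class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat("E-I network topology:", sum(x$kind == "E"), "E +", sum(x$kind == "I"),
      "I cells,", nrow(x$edges), "directed synapses\n")
  invisible(x)
}

#' Randomly rewire excitatory-to-excitatory connections
#'
#' Each E-E edge is independently rewired with probability `p` to a
#' uniformly chosen E cell anywhere in the network, avoiding self-loops and
#' duplicate targets; the E-E out-degree is preserved and all other edges
#' are untouched. `p = 0` leaves the topology unchanged; `p = 1` gives a
#' fully random excitatory subnetwork (small-world-style rewiring).
#'
#' @param topo [build_topology()] result
#' @param p rewiring probability in `[0, 1]`
#' @param seed integer RNG seed
#' @return rewired `network_topology`
#' @export
rewire_ee <- function(topo, p, seed = 1L) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0) return(topo)
  set.seed(seed)
  eIDs <- which(topo$kind == "E")
  ed <- topo$edges
  ee_rows <- which(ed$src %in% eIDs & ed$tgt %in% eIDs)
  by_src <- split(ee_rows, ed$src[ee_rows])
  for (s_chr in names(by_src)) {
    s <- as.integer(s_chr)
    rows <- by_src[[s_chr]]
    flip <- stats::runif(length(rows)) < p
    if (!any(flip)) next
    kept <- ed$tgt[rows[!flip]]
    cand <- setdiff(eIDs, c(s, kept))
    ed$tgt[rows[flip]] <- sample(cand, sum(flip))
  }
  topo$edges <- ed
  topo
}

#' Sparsify inhibitory connectivity
#'
#' Keeps each I-sourced edge (I-E and I-I) independently with probability
#' `density` and re-weights the kept inhibitory synapses to `w_inh`,
#' emulating sparse random inhibitory connectivity with compensating
#' strength. E-sourced edges are untouched.
#'
#' @param topo [build_topology()] result
#' @param density kept-edge fraction in `(0, 1]`
#' @param w_inh strength of the kept inhibitory synapses (mS/cm^2)
#' @param seed integer RNG seed
#' @return modified `network_topology`
#' @export
sparsify_inhibition <- function(topo, density, w_inh, seed = 1L) {
  stopifnot(density > 0, density <= 1)
  set.seed(seed)
  iIDs <- which(topo$kind == "I")
  ed <- topo$edges
  is_inh <- ed$src %in% iIDs
  keep <- !is_inh | (stats::runif(nrow(ed)) < density)
  ed$w[is_inh] <- w_inh
  topo$edges <- ed[keep, ]
  rownames(topo$edges) <- NULL
  topo
}

#' Write / read a topology edge list as delimited text
#'
#' Tab-separated columns `src`, `tgt`, `w`; geometry recorded in `#`-prefixed
#' header lines.
#'
#' @param topo `network_topology`
#' @param path output file
#' @export
write_topology <- function(topo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# achnet topology L_E=%d L_I=%d", topo$geom$L_E,
                     topo$geom$L_I), con)
  writeLines("src\ttgt\tw", con)
  utils::write.table(topo$edges, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
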