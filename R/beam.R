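# Brain electrical activity mapping: per-channel fourth-order cumulative
# energy, min-max normalization, inverse-distance-weighted scalp
# interpolation, and activation breadth/depth metrics.

#' Fourth-order cumulative energy per channel
#'
#' `E_c = sum_s x[c, s]^4` over the window — the energy statistic behind the
#' activation maps. For a unit-variance Gaussian channel `E/N` approaches 3
#' (the fourth moment of the standard normal).
#'
#' @param epoch a channels x samples matrix (one trial), or an `epoch_set`
#'   with a `trial` index.
#' @param trial trial index when `epoch` is an `epoch_set`.
#' @return numeric vector of per-channel energies.
#' @export
fourth_order_energy <- function(epoch, trial = 1L) {
  if (inherits(epoch, "epoch_set")) {
    if (dim(epoch$data)[1] == 0) stop("empty epoch set")
    epoch <- epoch$data[trial, , , drop = TRUE]
  }
  epoch <- as.matrix(epoch)
  if (ncol(epoch) == 0 || nrow(epoch) == 0) stop("empty epoch")
  rowSums(epoch^4)
}

#' Min-max normalize a channel-energy vector
#'
#' Scales energies to `[0, 1]` across channels; a constant vector maps to
#' all 0.5 by convention. Monotone, so channel ranks are preserved, and
#' invariant to overall epoch scaling.
#'
#' @param energies per-channel energy vector (length >= 2).
#' @return normalized vector in `[0, 1]`.
#' @export
normalize_map <- function(energies) {
  if (length(energies) < 2) stop("need at least two channels")
  rng <- range(energies)
  if (rng[1] == rng[2]) return(rep(0.5, length(energies)))
  (energies - rng[1]) / (rng[2] - rng[1])
}

#' Interpolate a channel map onto the scalp grid
#'
#' Inverse-distance-weighted interpolation (power 2) of the 19 normalized
#' channel values over a `grid_size` x `grid_size` raster of the unit disc.
#' Values at electrode pixels equal the inputs exactly, and IDW is a convex
#' combination, so the grid never extrapolates beyond the input range.
#' Pixels outside the unit disc are `NA` (masked).
#'
#' @param normalized one value per montage channel.
#' @param montage a [make_montage()] montage.
#' @param grid_size raster resolution per side (default 64).
#' @return a `beamap`: list with `channel_energy`, `montage`, `grid`
#'   (matrix with `NA` outside the scalp) and `grid_size`.
#' @export
interpolate_topomap <- function(normalized, montage = make_montage(),
                                grid_size = 64) {
  if (length(normalized) != length(montage$labels))
    stop("one value per montage channel is required")
  g <- seq(-1, 1, length.out = grid_size)
  px <- rep(g, times = grid_size)
  py <- rep(g, each = grid_size)
  inside <- px^2 + py^2 <= 1
  vals <- rep(NA_real_, grid_size^2)
  pos <- montage$positions
  d2 <- outer(px[inside], pos[, 1], `-`)^2 +
        outer(py[inside], pos[, 2], `-`)^2
  w <- 1 / pmax(d2, 1e-12)
  vals[inside] <- (w %*% normalized) / rowSums(w)
  # exact at electrode pixels (d2 ~ 0 dominates, but pin them explicitly)
  hit <- d2 < 1e-12
  if (any(hit)) {
    ij <- which(hit, arr.ind = TRUE)
    vi <- which(inside)[ij[, 1]]
    vals[vi] <- normalized[ij[, 2]]
  }
  structure(list(channel_energy = normalized, montage = montage,
                 grid = matrix(vals, grid_size, grid_size),
                 grid_size = as.integer(grid_size)),
            class = "beamap")
}

#' @export
print.beamap <- function(x, ...) {
  cat(sprintf("<beamap: %d channels on a %dx%d grid>\n",
              length(x$channel_energy), x$grid_size, x$grid_size))
  invisible(x)
}

#' Build the activation map of one trial
#'
#' Convenience wrapper: fourth-order energy, min-max normalization, scalp
#' interpolation.
#'
#' @param epochs an `epoch_set`.
#' @param trial trial index.
#' @param montage montage; defaults to the packaged 19-channel montage.
#' @param grid_size raster resolution.
#' @return a `beamap`.
#' @export
trial_beamap <- function(epochs, trial = 1L, montage = make_montage(),
                         grid_size = 64) {
  e <- fourth_order_energy(epochs, trial)
  interpolate_topomap(normalize_map(e), montage, grid_size)
}

# Breadth/depth of a single map: fraction of unmasked pixels above the
# threshold, and the mean of those pixels (0 if none).
beam_breadth_depth <- function(map, threshold = 0.6) {
  v <- map$grid[!is.na(map$grid)]
  above <- v > threshold
  c(breadth = mean(above),
    depth = if (any(above)) mean(v[above]) else 0)
}

#' Topographic map of event-related desynchronization
#'
#' The field-standard ERD topography: for every channel, the fractional
#' band-power decrease of the motor-imagery window relative to the same
#' trials' rest (baseline) window, interpolated over the scalp. Per-sample
#' fourth-order energies are averaged across trials in each window; since
#' the fourth-order energy of a band-limited signal scales with its power
#' squared, the power ratio is the square root of the energy ratio, and
#' `ERD_c = max(0, 1 - sqrt(Emi_c / Erest_c))`. Values are natural fractions
#' in `[0, 1]` (0.3 = 30% power suppression), so no min-max rescaling is
#' applied; a channel with no rhythm shows ~0 rather than spuriously high
#' "activation". Breadth/depth of such maps are conventionally read at a
#' 10% suppression threshold.
#'
#' @param mi_epochs an `epoch_set` of motor-imagery windows.
#' @param rest_epochs an `epoch_set` of rest windows from the same trials.
#' @param trials trial indices to average over (default all).
#' @param montage montage; defaults to the packaged one.
#' @param grid_size raster resolution.
#' @return a `beamap` whose `channel_energy` holds the per-channel ERD
#'   fractions.
#' @export
erd_topomap <- function(mi_epochs, rest_epochs, trials = NULL,
                        montage = make_montage(), grid_size = 64) {
  stopifnot(inherits(mi_epochs, "epoch_set"),
            inherits(rest_epochs, "epoch_set"))
  trials <- trials %||% seq_len(dim(mi_epochs$data)[1])
  nsm <- dim(mi_epochs$data)[3]
  nsr <- dim(rest_epochs$data)[3]
  e_mi <- rowMeans(vapply(trials, function(t)
    fourth_order_energy(mi_epochs, t) / nsm,
    numeric(dim(mi_epochs$data)[2])))
  e_rest <- rowMeans(vapply(trials, function(t)
    fourth_order_energy(rest_epochs, t) / nsr,
    numeric(dim(rest_epochs$data)[2])))
  erd <- pmax(0, 1 - sqrt(e_mi / pmax(e_rest, .Machine$double.eps)))
  interpolate_topomap(erd, montage, grid_size)
}

#' Activation breadth/depth change between two maps
#'
#' Breadth is the fraction of scalp pixels above `threshold`; depth is the
#' mean value of those pixels. The changes are `post - pre`, quantifying how
#' much the activated region expanded and intensified.
#'
#' @param pre,post `beamap`s on the same montage and grid.
#' @param threshold activation threshold on the normalized scale
#'   (default 0.6).
#' @return list with `breadth_change`, `depth_change` and the per-map
#'   `pre`/`post` breadth-depth pairs.
#' @export
activation_metrics <- function(pre, post, threshold = 0.6) {
  stopifnot(inherits(pre, "beamap"), inherits(post, "beamap"))
  if (pre$grid_size != post$grid_size ||
      !identical(pre$montage$labels, post$montage$labels))
    stop("maps must share the montage and grid size")
  a <- beam_breadth_depth(pre, threshold)
  b <- beam_breadth_depth(post, threshold)
  list(breadth_change = unname(b["breadth"] - a["breadth"]),
       depth_change = unname(b["depth"] - a["depth"]),
       pre = a, post = b)
}

#' Export a map grid as a plain-text matrix
#'
#' @param map a `beamap`.
#' @param path output path (tab-separated; masked pixels written as `NA`).
#' @export
write_beamap <- function(map, path) {
  write.table(map$grid, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
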