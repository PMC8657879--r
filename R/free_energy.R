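GAS_CONSTANT_KCAL <- 8.314462618 / 4184  # kcal mol^-1 K^-1

#' Thermal energy in kcal/mol
#'
#' kT per mole (i.e. RT) expressed in kcal mol^-1; 300 K gives 0.596.
#'
#' @param temperature Absolute temperature in kelvin (> 0).
#' @return kT in kcal mol^-1.
#' @export
#' @examples
#' thermal_energy(300)
thermal_energy <- function(temperature) {
  if (!is.numeric(temperature) || any(temperature <= 0)) {
    stop("temperature must be positive (kelvin)")
  }
  GAS_CONSTANT_KCAL * temperature
}

#' Potential of mean force from collective-variable samples
#'
#' Histograms one or two CV time series, normalises to a probability over
#' occupied bins, and converts to a free-energy surface
#' `F = -kT ln(p / pmax)` whose minimum over occupied bins is exactly 0.
#' Empty bins are masked (infinite free energy), never imputed.
#'
#' @param x Numeric samples of the first CV.
#' @param y Optional samples of a second CV (same length) for a 2D surface.
#' @param bins Number of bins per axis (>= 2), or a length-2 vector for
#'   (x, y).
#' @param kT Thermal energy in kcal mol^-1 (see [thermal_energy()]).
#' @param range_x,range_y Optional axis limits; default to the data range,
#'   widened infinitesimally so the maximum falls inside the last bin.
#' @return An object of class `pmf_grid`: `edges_x`, `edges_y` (NULL in
#'   1D), `counts`, `p`, `F` (masked bins `NA`), `mask` (TRUE = empty),
#'   `kT`.
#' @export
build_pmf <- function(x, y = NULL, bins = 50L, kT = thermal_energy(300),
                      range_x = NULL, range_y = NULL) {
  if (length(x) == 0L) stop("empty series")
  if (!is.null(y) && length(y) != length(x)) {
    stop("x and y series must have equal length")
  }
  if (kT <= 0) stop("kT must be positive")
  bins <- rep(as.integer(bins), length.out = 2L)
  if (any(bins < 2L)) stop("need at least 2 bins per axis")
  mk_edges <- function(v, rng, nb) {
    if (is.null(rng)) rng <- range(v)
    if (diff(rng) == 0) {
      stop("all samples identical; binning impossible without an explicit range")
    }
    seq(rng[1L], rng[2L], length.out = nb + 1L)
  }
  bin_of <- function(v, edges) {
    i <- findInterval(v, edges, rightmost.closed = TRUE)
    if (any(i < 1L | i > length(edges) - 1L)) {
      stop("samples outside the requested range")
    }
    i
  }
  edges_x <- mk_edges(x, range_x, bins[1L])
  ix <- bin_of(x, edges_x)
  if (is.null(y)) {
    counts <- tabulate(ix, nbins = bins[1L])
    counts <- matrix(counts, ncol = 1L)
    edges_y <- NULL
  } else {
    edges_y <- mk_edges(y, range_y, bins[2L])
    iy <- bin_of(y, edges_y)
    counts <- matrix(0L, bins[1L], bins[2L])
    for (k in seq_along(ix)) {
      counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
    }
  }
  p <- counts / sum(counts)
  mask <- counts == 0L
  FF <- matrix(NA_real_, nrow(p), ncol(p))
  FF[!mask] <- -kT * log(p[!mask] / max(p))
  structure(list(edges_x = edges_x, edges_y = edges_y, counts = counts,
                 p = p, F = FF, mask = mask, kT = kT),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat("<pmf_grid>", nrow(x$F), "x", ncol(x$F), "bins,",
      sum(!x$mask), "occupied, kT =", round(x$kT, 4), "kcal/mol, max F =",
      round(max(x$F, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Bin centres of a PMF grid axis
#'
#' @param grid A `pmf_grid`.
#' @param axis `"x"` or `"y"`.
#' @return Numeric vector of bin midpoints.
#' @export
bin_centers <- function(grid, axis = c("x", "y")) {
  axis <- match.arg(axis)
  e <- if (axis == "x") grid$edges_x else grid$edges_y
  if (is.null(e)) stop("grid has no ", axis, " axis")
  (e[-1L] + e[-length(e)]) / 2
}

#' Minimum-energy path across a PMF grid
#'
#' Finds, among all 8-connected paths between two occupied bins that avoid
#' masked (empty) bins, a path minimising the maximum free energy
#' encountered (the minimax criterion, the natural barrier definition on a
#' discretised surface).  Ties are broken towards fewer steps, then
#' lexicographically by bin index.  The barrier is the peak free energy on
#' the path above the starting bin.
#'
#' @param grid A `pmf_grid` from [build_pmf()].
#' @param start,end Bin indices, each a length-2 integer vector (row,
#'   column); for 1D grids the column is 1.
#' @return An object of class `mep_path`: `path` (n x 2 matrix of bin
#'   indices), `F` (free energy along the path), `barrier` (kcal mol^-1).
#' @export
minimum_energy_path <- function(grid, start, end) {
  stopifnot(inherits(grid, "pmf_grid"))
  nr <- nrow(grid$F); nc <- ncol(grid$F)
  start <- as.integer(rep(start, length.out = 2L))
  end <- as.integer(rep(end, length.out = 2L))
  at <- function(idx) (idx[2L] - 1L) * nr + idx[1L]
  if (start[1L] < 1L || start[1L] > nr || start[2L] < 1L || start[2L] > nc ||
      end[1L] < 1L || end[1L] > nr || end[2L] < 1L || end[2L] > nc) {
    stop("start/end outside the grid")
  }
  if (grid$mask[start[1L], start[2L]] || grid$mask[end[1L], end[2L]]) {
    stop("start and end must be occupied bins")
  }
  s <- at(start); e <- at(end)
  if (s == e) {
    return(structure(list(path = matrix(start, 1L, 2L),
                          F = grid$F[start[1L], start[2L]], barrier = 0),
                     class = "mep_path"))
  }
  FF <- as.vector(grid$F)
  n <- nr * nc
  # Dijkstra-style label setting on (max-F, #steps) lexicographic cost
  best_max <- rep(Inf, n)
  best_len <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  best_max[s] <- FF[s]
  best_len[s] <- 0
  repeat {
    open <- which(!done & is.finite(best_max))
    if (length(open) == 0L) stop("no unmasked path between start and end")
    u <- open[order(best_max[open], best_len[open], open)][1L]
    if (u == e) break
    done[u] <- TRUE
    ui <- ((u - 1L) %% nr) + 1L
    uj <- ((u - 1L) %/% nr) + 1L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      vi <- ui + di; vj <- uj + dj
      if (vi < 1L || vi > nr || vj < 1L || vj > nc) next
      if (grid$mask[vi, vj]) next
      v <- (vj - 1L) * nr + vi
      if (done[v]) next
      cand_max <- max(best_max[u], FF[v])
      cand_len <- best_len[u] + 1
      if (cand_max < best_max[v] ||
          (cand_max == best_max[v] && cand_len < best_len[v]) ||
          (cand_max == best_max[v] && cand_len == best_len[v] &&
             (is.na(prev[v]) || u < prev[v]))) {
        best_max[v] <- cand_max
        best_len[v] <- cand_len
        prev[v] <- u
      }
    }
  }
  nodes <- e
  while (nodes[1L] != s) nodes <- c(prev[nodes[1L]], nodes)
  path <- cbind(((nodes - 1L) %% nr) + 1L, ((nodes - 1L) %/% nr) + 1L)
  colnames(path) <- c("i", "j")
  fpath <- FF[nodes]
  structure(list(path = path, F = fpath,
                 barrier = max(fpath) - fpath[1L]),
            class = "mep_path")
}

#' @export
print.mep_path <- function(x, ...) {
  cat("<mep_path>", nrow(x$path), "bins, barrier =",
      round(x$barrier, 4), "kcal/mol\n")
  invisible(x)
}

#' Write a PMF grid as CSV
#'
#' Rows indexed by x-bin centre, columns by y-bin centre; masked bins are
#' empty fields.
#'
#' @param grid A `pmf_grid`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_pmf_csv <- function(grid, path) {
  m <- grid$F
  cx <- bin_centers(grid, "x")
  header <- if (is.null(grid$edges_y)) c("x", "F")
            else c("x", bin_centers(grid, "y"))
  df <- data.frame(x = cx, m, check.names = FALSE)
  colnames(df) <- header
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
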