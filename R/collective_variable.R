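#' Characteristic folding-degree statistics per secondary-structure category
#'
#' Reference means and sample standard deviations of the residue folding
#' degree (and of the phi/psi angles) for the nine DSSP 4 secondary-structure
#' categories, as estimated from a large survey of folded structures.  The H
#' row (alpha helix, RCS 7.273 +/- 0.421) supplies the default switching
#' parameters of the helicality collective variable.
#'
#' @return A data frame with columns `category`, `phi_mean`, `phi_sd`,
#'   `psi_mean`, `psi_sd`, `rcs_mean`, `rcs_sd`, `count`.
#' @export
#' @examples
#' ss_reference_stats()
ss_reference_stats <- function() {
  data.frame(
    category = c("H", "G", "I", "E", "B", "T", "S", "P", "C"),
    phi_mean = c(-64.70, -66.05, -79.15, -110.89, -96.98, -39.33, -69.26,
                 -72.33, -82.97),
    phi_sd   = c(11.84, 34.16, 25.74, 42.62, 49.29, 70.25, 73.32, 13.05,
                 55.81),
    psi_mean = c(-39.56, -15.55, -41.63, 122.38, 122.90, 6.23, 44.16,
                 144.79, 97.00),
    psi_sd   = c(11.39, 29.33, 20.41, 58.10, 67.45, 51.49, 97.63, 13.85,
                 83.52),
    rcs_mean = c(7.273, 7.523, 6.516, 2.730, 2.976, 6.923, 4.850, 3.660,
                 3.835),
    rcs_sd   = c(0.421, 0.840, 0.999, 0.966, 0.898, 1.223, 2.166, 0.498,
                 1.574),
    count    = c(412071L, 51822L, 7086L, 282196L, 15416L, 151631L, 113536L,
                 24764L, 218948L),
    stringsAsFactors = FALSE
  )
}

#' Switching-function parameters
#'
#' Parameters of the rational switching function that maps a residue
#' folding degree onto \[0, 1\]: a reference value, a tolerance, and even
#' exponents m < n.  The defaults are the alpha-helix (H category) mean and
#' standard deviation, which make the resulting collective variable a
#' helical-content measure.
#'
#' @param ref Reference folding degree (dimensionless).
#' @param tol Tolerance (> 0).
#' @param m,n Positive even integer exponents with m < n.
#' @return An object of class `switching_params`.
#' @export
switching_params <- function(ref = 7.273, tol = 0.421, m = 2L, n = 4L) {
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0")
  m <- as.integer(m); n <- as.integer(n)
  if (m <= 0L || n <= 0L || m %% 2L != 0L || n %% 2L != 0L || m >= n) {
    stop("exponents must be positive even integers with m < n")
  }
  structure(list(ref = ref, tol = tol, m = m, n = n),
            class = "switching_params")
}

#' @export
print.switching_params <- function(x, ...) {
  cat(sprintf("<switching_params> ref = %g, tol = %g, m = %d, n = %d\n",
              x$ref, x$tol, x$m, x$n))
  invisible(x)
}

#' Relative residue folding degree
#'
#' The switching function `(1 - x^m) / (1 - x^n)` of the scaled deviation
#' `x = (rcs - ref) / tol`, extended continuously with the value m/n at
#' |x| = 1.  For the default exponents m = 2, n = 4 this simplifies exactly
#' to `1 / (1 + x^2)`: a bounded, symmetric score on (0, 1] that equals 1
#' when the residue matches the reference folding degree and 0.5 one
#' tolerance away.
#'
#' @param rcs Residue folding degree value(s).
#' @param params A [switching_params] object.
#' @return Numeric vector of relative folding degrees.
#' @export
#' @examples
#' rcs_rel(7.273)  # at the reference: 1
#' rcs_rel(6.516)  # ideal pi-helix residue under the helical reference
rcs_rel <- function(rcs, params = switching_params()) {
  stopifnot(inherits(params, "switching_params"))
  x <- (rcs - params$ref) / params$tol
  if (params$m == 2L && params$n == 4L) {
    return(1 / (1 + x^2))   # exact simplification, no removable singularity
  }
  out <- (1 - x^params$m) / (1 - x^params$n)
  at_one <- abs(abs(x) - 1) < 1e-12
  out[at_one] <- params$m / params$n
  out
}

#' Segment definition
#'
#' A segment is a consecutive run of residues, identified by chain and an
#' inclusive residue-number interval.
#'
#' @param name Segment label.
#' @param start,end First and last residue number (inclusive), start <= end.
#' @param chain Chain identifier.
#' @return An object of class `segment_definition`.
#' @export
segment_definition <- function(name, start, end, chain = "A") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("segment needs start <= end")
  }
  structure(list(name = name, chain = chain, start = start, end = end),
            class = "segment_definition")
}

#' @export
print.segment_definition <- function(x, ...) {
  cat(sprintf("<segment> %s: chain %s, residues %d-%d\n",
              x$name, x$chain, x$start, x$end))
  invisible(x)
}

segment_rows <- function(profile, segment) {
  rows <- which(profile$chain == segment$chain &
                  profile$resno >= segment$start &
                  profile$resno <= segment$end)
  if (length(rows) == 0L) {
    stop("segment ", segment$name, " (", segment$chain, ":", segment$start,
         "-", segment$end, ") matches no residues in the profile")
  }
  rows
}

#' Per-residue reference parameters for a segment
#'
#' Builds one (reference, tolerance) pair per residue of a segment, in one
#' of four modes:
#' \describe{
#'   \item{helicality}{the alpha-helix preset: reference 7.273, tolerance
#'     0.421 for every residue (no reference structure needed).}
#'   \item{segment_mean}{one shared reference, the mean folding degree of
#'     the segment in a reference structure's profile.}
#'   \item{per_residue}{each residue's own folding degree in the reference
#'     profile.}
#'   \item{category}{the characteristic folding degree of each residue's
#'     secondary-structure category (see [ss_reference_stats()]); requires
#'     per-residue labels.}
#' }
#' For arbitrary references the tolerance is a free choice; 1.0 gives
#' well-separated free-energy basins in practice and is the default.  In
#' category mode the category's own standard deviation may be used instead
#' via `tol = "sd"`.
#'
#' @param mode Reference mode, see above.
#' @param segment A [segment_definition].
#' @param reference_profile A `folding_profile` of the reference structure
#'   (required except in helicality mode).
#' @param labels Per-residue label data frame (`chain`, `resno`, `label`)
#'   for category mode, e.g. from [parse_labels()].
#' @param tol Numeric tolerance shared by all residues, or `"sd"` in
#'   category mode for the per-category standard deviation.
#' @param m,n Switching exponents.
#' @return A data frame of class `segment_reference` with one row per
#'   residue: `resno`, `ref`, `tol`, plus attributes `segment`, `m`, `n`.
#' @export
make_reference <- function(mode = c("helicality", "segment_mean",
                                    "per_residue", "category"),
                           segment, reference_profile = NULL, labels = NULL,
                           tol = 1.0, m = 2L, n = 4L) {
  mode <- match.arg(mode)
  stopifnot(inherits(segment, "segment_definition"))
  resno <- segment$start:segment$end
  if (mode == "helicality") {
    ref <- rep(7.273, length(resno))
    tol_v <- rep(if (identical(tol, 1.0)) 0.421 else tol, length(resno))
  } else if (mode == "category") {
    if (is.null(labels)) stop("category mode requires per-residue labels")
    tab <- ss_reference_stats()
    lab <- labels$label[match(resno, labels$resno)]
    if (anyNA(lab)) stop("missing secondary-structure label for residue(s) ",
                         paste(resno[is.na(lab)], collapse = ", "))
    row <- match(lab, tab$category)
    if (anyNA(row)) stop("unknown secondary-structure category: ",
                         paste(unique(lab[is.na(row)]), collapse = ", "))
    ref <- tab$rcs_mean[row]
    tol_v <- if (identical(tol, "sd")) tab$rcs_sd[row]
             else rep(as.numeric(tol), length(resno))
  } else {
    if (is.null(reference_profile)) {
      stop(mode, " mode requires a reference profile")
    }
    rows <- segment_rows(reference_profile, segment)
    rcs <- reference_profile$rcs[rows]
    if (anyNA(rcs)) {
      stop("undefined reference folding degree for residue(s) ",
           paste(reference_profile$resno[rows][is.na(rcs)], collapse = ", "))
    }
    resno <- reference_profile$resno[rows]
    ref <- if (mode == "segment_mean") rep(mean(rcs), length(rcs)) else rcs
    tol_v <- rep(as.numeric(tol), length(resno))
  }
  out <- data.frame(resno = resno, ref = ref, tol = tol_v)
  class(out) <- c("segment_reference", "data.frame")
  attr(out, "segment") <- segment
  attr(out, "m") <- as.integer(m)
  attr(out, "n") <- as.integer(n)
  out
}

#' Relative segment folding degree
#'
#' The mean of the relative residue folding degrees over a segment: a
#' similarity score in (0, 1] between the segment's current backbone
#' conformation and the reference conformation encoded by the per-residue
#' switching parameters.
#'
#' @param profile A `folding_profile` for one structure/frame.
#' @param reference A `segment_reference` from [make_reference()], or a
#'   [segment_definition] (then `params` supplies shared switching
#'   parameters).
#' @param params A [switching_params] used when `reference` is a bare
#'   segment definition.
#' @return A single numeric value.
#' @export
scs_rel <- function(profile, reference, params = switching_params()) {
  if (inherits(reference, "segment_definition")) {
    reference <- make_reference("helicality", reference)
    reference$ref <- params$ref
    reference$tol <- params$tol
    attr(reference, "m") <- params$m
    attr(reference, "n") <- params$n
  }
  stopifnot(inherits(reference, "segment_reference"))
  seg <- attr(reference, "segment")
  rows <- which(profile$chain == seg$chain &
                  profile$resno %in% reference$resno)
  if (length(rows) != nrow(reference)) {
    stop("segment ", seg$name, " not fully resolvable in the profile")
  }
  rcs <- profile$rcs[rows][match(reference$resno, profile$resno[rows])]
  if (anyNA(rcs)) {
    stop("undefined folding degree inside segment ", seg$name,
         " (residues ", paste(reference$resno[is.na(rcs)], collapse = ", "),
         "); segments must not span stretch termini")
  }
  vals <- vapply(seq_along(rcs), function(i) {
    rcs_rel(rcs[i], switching_params(reference$ref[i], reference$tol[i],
                                     attr(reference, "m"),
                                     attr(reference, "n")))
  }, numeric(1))
  mean(vals)
}

#' Relative folding degrees of ideal secondary-structure motifs
#'
#' An ideal motif is a segment whose residues all sit exactly at the
#' characteristic folding degree of one secondary-structure category.  This
#' evaluates the switching function at each category mean; under the
#' default alpha-helix reference the H motif scores exactly 1 and all other
#' categories strictly less, which is what makes the collective variable a
#' helical-content measure.
#'
#' @param params A [switching_params]; the default is the helical reference.
#' @param digits Rounding for the `scs_display` column (full precision is
#'   kept in `scs`).
#' @return Data frame with columns `category`, `rcs_mean`, `scs`,
#'   `scs_display`.
#' @export
#' @examples
#' ideal_motif_table()
ideal_motif_table <- function(params = switching_params(), digits = 2L) {
  tab <- ss_reference_stats()
  scs <- rcs_rel(tab$rcs_mean, params)
  data.frame(category = tab$category, rcs_mean = tab$rcs_mean, scs = scs,
             scs_display = round(scs, digits), stringsAsFactors = FALSE)
}

#' Collective-variable time series over a trajectory
#'
#' Evaluates the relative segment folding degree of one or more segments
#' for every frame of a trajectory (a multi-model PDB file or a list of
#' [backbone_chain] objects), using the block folding-degree method.
#' Frames in which a segment contains an undefined residue folding degree
#' (e.g. a chain break inside the segment) are flagged with `NA` rather
#' than silently averaged over the remaining residues.
#'
#' @param trajectory Path to a multi-model PDB file, or a list of
#'   `backbone_chain` objects (one per frame).
#' @param references A `segment_reference`, or a named list of them (one
#'   per segment).
#' @return A data frame of class `cv_series` with columns `frame`,
#'   `segment`, `scs`, `flagged`.
#' @export
cv_timeseries <- function(trajectory, references) {
  if (inherits(references, "segment_reference")) {
    references <- list(references)
  }
  names(references) <- vapply(references, function(r)
    attr(r, "segment")$name, character(1))
  frames <- if (is.character(trajectory)) {
    parse_trajectory(trajectory)
  } else {
    lapply(trajectory, function(ch)
      if (inherits(ch, "backbone_chain")) list(ch) else ch)
  }
  res <- list()
  for (f in seq_along(frames)) {
    profs <- lapply(frames[[f]], rcs_profile, method = "block")
    prof <- do.call(rbind, profs)
    class(prof) <- c("folding_profile", "data.frame")
    for (rn in names(references)) {
      val <- tryCatch(scs_rel(prof, references[[rn]]),
                      error = function(e) NA_real_)
      res[[length(res) + 1L]] <- data.frame(
        frame = f, segment = rn, scs = val, flagged = is.na(val))
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("cv_series", "data.frame")
  out
}

#' Write a collective-variable series as TSV
#'
#' @param series A `cv_series` from [cv_timeseries()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_cv_tsv <- function(series, path) {
  write.table(series, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
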