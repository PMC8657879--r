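#' Internal-coordinate specification of a backbone
#'
#' Per-residue backbone torsions plus standard peptide stereochemistry
#' (bond lengths N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; bond angles
#' N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7 degrees).  `phi[1]` and the
#' last residue's `psi`/`omega` are never used by the builder.
#'
#' @param phi,psi,omega Numeric vectors of equal length (degrees).
#' @param b_nca,b_cac,b_cn Bond lengths in Angstrom.
#' @param a_ncac,a_cacn,a_cnca Bond angles in degrees.
#' @return A data frame of class `internal_coords` with the geometry
#'   constants as attributes.
#' @export
internal_coords <- function(phi, psi, omega = rep(180, length(phi)),
                            b_nca = 1.458, b_cac = 1.525, b_cn = 1.329,
                            a_ncac = 111.2, a_cacn = 116.2, a_cnca = 121.7) {
  n <- length(phi)
  stopifnot(length(psi) == n, length(omega) == n)
  if (any(c(b_nca, b_cac, b_cn) <= 0)) stop("bond lengths must be positive")
  if (any(c(a_ncac, a_cacn, a_cnca) <= 0) ||
      any(c(a_ncac, a_cacn, a_cnca) >= 180)) {
    stop("bond angles must lie strictly between 0 and 180 degrees")
  }
  out <- data.frame(phi = phi, psi = psi, omega = omega)
  class(out) <- c("internal_coords", "data.frame")
  attr(out, "geometry") <- c(b_nca = b_nca, b_cac = b_cac, b_cn = b_cn,
                             a_ncac = a_ncac, a_cacn = a_cacn,
                             a_cnca = a_cnca)
  out
}

#' Ideal alpha-helix internal coordinates
#'
#' @param n Number of residues.
#' @param phi,psi Helical torsions in degrees (defaults: textbook
#'   right-handed alpha helix).
#' @return An [internal_coords] specification.
#' @export
ideal_helix_spec <- function(n, phi = -57, psi = -47) {
  internal_coords(rep(phi, n), rep(psi, n), rep(180, n))
}

# NeRF placement: atom D bonded to C with length r, angle theta at C
# (B-C-D) and torsion chi about B-C (A-B-C-D)
place_atom <- function(a, b, cc, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  d2 <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  bc <- cc - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nv <- cross3(ab, bc)
  nv <- nv / sqrt(sum(nv^2))
  m2 <- cross3(nv, bc)
  cc + d2[1L] * bc + d2[2L] * m2 + d2[3L] * nv
}

#' Build backbone coordinates from internal coordinates
#'
#' Deterministic sequential (NeRF-style) atom placement: the first three
#' atoms (N1, CA1, C1) are laid down canonically in the xy-plane at the
#' origin, and every further backbone atom is placed from the previous
#' three using the prescribed bond length, bond angle and torsion.
#' [compute_dihedrals()] on the result recovers the prescribed phi/psi/
#' omega to numerical precision, which makes this the round-trip oracle
#' for the dihedral machinery.
#'
#' @param spec An [internal_coords] specification with >= 2 residues.
#' @param chain_id Chain label for the resulting chain.
#' @return A [backbone_chain].
#' @export
#' @examples
#' ch <- build_backbone(ideal_helix_spec(5))
#' compute_dihedrals(ch)
build_backbone <- function(spec, chain_id = "A") {
  stopifnot(inherits(spec, "internal_coords"))
  n <- nrow(spec)
  if (n < 2L) stop("need at least 2 residues")
  g <- attr(spec, "geometry")
  N <- CA <- CC <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g[["b_nca"]], 0, 0)
  ang <- (180 - g[["a_ncac"]]) * pi / 180
  CC[1L, ] <- CA[1L, ] + g[["b_cac"]] * c(cos(ang), sin(ang), 0)
  for (k in seq_len(n - 1L)) {
    N[k + 1L, ] <- place_atom(N[k, ], CA[k, ], CC[k, ], g[["b_cn"]],
                              g[["a_cacn"]], spec$psi[k])
    CA[k + 1L, ] <- place_atom(CA[k, ], CC[k, ], N[k + 1L, ], g[["b_nca"]],
                               g[["a_cnca"]], spec$omega[k])
    CC[k + 1L, ] <- place_atom(CC[k, ], N[k + 1L, ], CA[k + 1L, ],
                               g[["b_cac"]], g[["a_ncac"]],
                               spec$phi[k + 1L])
  }
  backbone_chain(chain_id = chain_id, resno = seq_len(n),
                 resname = rep("ALA", n), n_xyz = N, ca_xyz = CA, c_xyz = CC)
}

#' Random dihedral ensembles
#'
#' Draws `n_sets` independent dihedral configurations for an `n_res`
#' residue stretch: phi and psi uniform on (-180, 180], omega jittered
#' around the planar trans value 180.  Deterministic for a fixed seed.
#'
#' @param n_res Residues per configuration (>= 3).
#' @param n_sets Number of configurations.
#' @param seed Integer seed.
#' @param omega_jitter Half-width (degrees) of the uniform omega jitter.
#' @return A list of [internal_coords] specifications.
#' @export
random_dihedrals <- function(n_res, n_sets = 1L, seed = 1L,
                             omega_jitter = 10) {
  if (n_res < 3L) stop("need at least 3 residues")
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    internal_coords(
      phi = runif(n_res, -180, 180),
      psi = runif(n_res, -180, 180),
      omega = wrap_angle(180 + runif(n_res, -omega_jitter, omega_jitter)))
  })
}

# wrap degrees onto (-180, 180]
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Two-state switching dihedral trajectory
#'
#' Simulates a Markov two-state ("folded"/"unfolded") process and emits
#' one dihedral configuration per frame: within each state the backbone
#' torsions are Gaussian around the state's mean angles and wrapped onto
#' (-180, 180].  This emulates the conformational switching an MD
#' trajectory of a small folder shows in a segment collective variable,
#' without any of the correlated, anharmonic structure of real dynamics.
#'
#' @param n_frames Number of frames.
#' @param state_a,state_b Lists with elements `phi`, `psi` (mean angles,
#'   degrees), optional `sd` (angular noise, degrees; default 8) and
#'   `omega` (default 180).
#' @param switch_prob Per-frame probability of switching state (scalar, or
#'   length 2 for a->b and b->a).
#' @param n_res Residues per frame.
#' @param seed Integer seed.
#' @return A list of class `two_state_trajectory`: `states` (integer
#'   vector, 1 = A, 2 = B), `specs` (list of [internal_coords]), and the
#'   generator settings.
#' @export
two_state_cv_trajectory <- function(n_frames, state_a, state_b,
                                    switch_prob = 0.05, n_res = 12L,
                                    seed = 1L) {
  p <- rep(switch_prob, length.out = 2L)
  if (any(p < 0) || any(p > 1)) stop("switch probabilities must be in [0,1]")
  set.seed(seed)
  st <- list(state_a, state_b)
  for (i in 1:2) {
    if (is.null(st[[i]]$sd)) st[[i]]$sd <- 8
    if (is.null(st[[i]]$omega)) st[[i]]$omega <- 180
  }
  states <- integer(n_frames)
  states[1L] <- 1L
  if (n_frames > 1L) {
    u <- runif(n_frames - 1L)
    for (f in 2:n_frames) {
      cur <- states[f - 1L]
      states[f] <- if (u[f - 1L] < p[cur]) 3L - cur else cur
    }
  }
  specs <- lapply(seq_len(n_frames), function(f) {
    s <- st[[states[f]]]
    internal_coords(
      phi = wrap_angle(rnorm(n_res, s$phi, s$sd)),
      psi = wrap_angle(rnorm(n_res, s$psi, s$sd)),
      omega = wrap_angle(rnorm(n_res, s$omega, s$sd / 2)))
  })
  structure(list(states = states, specs = specs, switch_prob = p,
                 state_a = st[[1L]], state_b = st[[2L]], seed = seed),
            class = "two_state_trajectory")
}

#' Write backbone chains as a (multi-model) PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame when a list of chains is given, so
#' the output doubles as a trajectory readable by [parse_structure()] and
#' [cv_timeseries()].
#'
#' @param x A [backbone_chain] or a list of them (one per model/frame).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_backbone_pdb <- function(x, path) {
  frames <- if (inherits(x, "backbone_chain")) list(x) else x
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  fmt <- "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f"
  for (f in seq_along(frames)) {
    ch <- frames[[f]]
    stopifnot(inherits(ch, "backbone_chain"))
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    for (r in seq_along(ch$resno)) {
      for (atom in c("N", "CA", "C")) {
        xyz <- switch(atom, N = ch$n_xyz[r, ], CA = ch$ca_xyz[r, ],
                      C = ch$c_xyz[r, ])
        if (anyNA(xyz)) next
        serial <- serial + 1L
        writeLines(sprintf(fmt, serial, atom, ch$resname[r], ch$chain_id,
                           ch$resno[r], xyz[1L], xyz[2L], xyz[3L], 1, 0),
                   con)
      }
    }
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Build and write a trajectory fixture
#'
#' Convenience wrapper: turns the dihedral specs of a
#' [two_state_cv_trajectory()] (or any list of [internal_coords]) into
#' backbone chains and writes them as a multi-model PDB.
#'
#' @param specs A `two_state_trajectory` or list of `internal_coords`.
#' @param path Output PDB path.
#' @return Invisibly, the path.
#' @export
write_trajectory_pdb <- function(specs, path) {
  if (inherits(specs, "two_state_trajectory")) specs <- specs$specs
  write_backbone_pdb(lapply(specs, build_backbone), path)
}
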