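#' Parse a PDB structure into backbone chains
#'
#' Reads a (possibly multi-model) PDB file and extracts, for every protein
#' chain of the selected model, the backbone N/CA/C coordinates needed for
#' dihedral-angle and folding-degree calculations.  Only `ATOM` records are
#' considered (waters, ligands and other `HETATM` entries are skipped);
#' alternate locations are resolved by highest occupancy with ties broken in
#' favour of altloc `"A"`, and residues are ordered by residue number and
#' insertion code.
#'
#' @param path Path to a PDB-format file.
#' @param model 1-based model index; multi-model files double as
#'   trajectories, with one model per frame.
#' @return A list of [backbone_chain] objects, one per chain.
#' @seealso [compute_dihedrals()], [rcs_profile()], [n_models()]
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' ch <- build_backbone(ideal_helix_spec(5))
#' write_backbone_pdb(ch, pdb)
#' parse_structure(pdb)[[1]]
parse_structure <- function(path, model = 1L) {
  parse_trajectory(path, models = model)[[1L]]
}

#' Parse every model of a multi-model PDB in one pass
#'
#' Reads the file once, resolves the atom-to-residue topology once, and
#' returns per-model backbone chains -- far cheaper than calling
#' [parse_structure()] per frame on long trajectories.
#'
#' @param path Path to a PDB-format file.
#' @param models Integer vector of 1-based model indices, or `NULL` for
#'   all models.
#' @return A list with one element per requested model, each a list of
#'   [backbone_chain] objects.
#' @export
parse_trajectory <- function(path, models = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  nm <- nrow(pdb$xyz)
  if (is.null(models)) models <- seq_len(nm)
  models <- as.integer(models)
  if (any(models < 1L)) stop("'model' must be >= 1")
  if (any(models > nm)) {
    stop("model ", max(models), " requested but file has only ", nm,
         " model(s)")
  }
  atoms <- pdb$atom
  keep <- which(atoms$type == "ATOM" & atoms$elety %in% c("N", "CA", "C"))
  if (length(keep) == 0L) stop("no protein backbone atoms found in ", path)
  atoms <- atoms[keep, , drop = FALSE]
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$o[is.na(atoms$o)] <- 1

  # topology: per chain, per residue (ordered by resseq, icode), the row
  # index of each backbone atom after altloc resolution
  topo <- list()
  for (ch in unique(atoms$chain)) {
    sel <- which(atoms$chain == ch)
    a <- atoms[sel, , drop = FALSE]
    rid <- paste(a$resno, a$insert, sep = "\r")
    uid <- unique(rid[order(a$resno, a$insert)])
    n <- length(uid)
    idx <- matrix(NA_integer_, n, 3L,
                  dimnames = list(NULL, c("N", "CA", "C")))
    for (r in seq_len(n)) {
      for (name in c("N", "CA", "C")) {
        i <- which(rid == uid[r] & a$elety == name)
        if (length(i) == 0L) next
        if (length(i) > 1L) {
          # altloc conflict: highest occupancy, ties towards altloc "A"
          i <- i[order(-a$o[i], a$alt[i])][1L]
        }
        idx[r, name] <- sel[i]
      }
    }
    first <- sel[match(uid, rid)]
    topo[[length(topo) + 1L]] <- list(
      chain_id = ch, resno = atoms$resno[first],
      resname = atoms$resid[first], idx = idx)
  }

  lapply(models, function(m) {
    coords <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)[keep, ,
                                                            drop = FALSE]
    lapply(topo, function(tp) {
      pick <- function(col) {
        out <- matrix(NA_real_, nrow(tp$idx), 3L)
        ok <- !is.na(tp$idx[, col])
        out[ok, ] <- coords[tp$idx[ok, col], , drop = FALSE]
        out
      }
      backbone_chain(chain_id = tp$chain_id, resno = tp$resno,
                     resname = tp$resname, n_xyz = pick("N"),
                     ca_xyz = pick("CA"), c_xyz = pick("C"))
    })
  })
}

#' Number of models in a PDB file
#'
#' @param path Path to a PDB-format file.
#' @return Integer model count (1 for single-model files).
#' @export
n_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  nrow(pdb$xyz)
}

#' Backbone chain container
#'
#' Ordered backbone (N, CA, C) coordinates for one protein chain.  Residues
#' missing any of the three backbone atoms are flagged incomplete and never
#' contribute dihedral angles.
#'
#' @param chain_id Chain identifier.
#' @param resno Integer residue numbers, ordered.
#' @param resname Three-letter residue names.
#' @param n_xyz,ca_xyz,c_xyz Numeric n-by-3 coordinate matrices in Angstrom;
#'   rows of `NA` mark missing atoms.
#' @return An object of class `backbone_chain`.
#' @export
backbone_chain <- function(chain_id, resno, resname, n_xyz, ca_xyz, c_xyz) {
  n <- length(resno)
  stopifnot(length(resname) == n, nrow(n_xyz) == n,
            nrow(ca_xyz) == n, nrow(c_xyz) == n)
  complete <- !apply(is.na(n_xyz), 1L, any) &
    !apply(is.na(ca_xyz), 1L, any) & !apply(is.na(c_xyz), 1L, any)
  structure(list(chain_id = chain_id, resno = as.integer(resno),
                 resname = resname, n_xyz = n_xyz, ca_xyz = ca_xyz,
                 c_xyz = c_xyz, complete = complete),
            class = "backbone_chain")
}

#' @export
print.backbone_chain <- function(x, ...) {
  cat("<backbone_chain> chain", x$chain_id, "-", length(x$resno),
      "residues (", sum(x$complete), "complete )\n")
  invisible(x)
}

#' @export
length.backbone_chain <- function(x) length(x$resno)

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Torsion angle of four points
#'
#' Dihedral about the p2-p3 axis, IUPAC sign convention, reported in degrees
#' on (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# maximum C(i)-N(i+1) distance still treated as a peptide bond (Angstrom);
# generously above the ~1.33 A ideal so only real gaps split a chain
PEPTIDE_BOND_CUTOFF <- 2.5

#' Backbone dihedral angles of a chain
#'
#' Computes phi, psi and the flanking omega angles for every residue:
#' `psi_k` from (N_k, CA_k, C_k, N_k+1), `omega_k` from
#' (CA_k, C_k, N_k+1, CA_k+1) and `phi_k` from (C_k-1, N_k, CA_k, C_k).
#' Consecutive residues whose C-N distance exceeds 2.5 Angstrom (or with
#' incomplete backbones) start a new contiguous stretch; no dihedral is
#' evaluated across a break, so phi is undefined at the start of a stretch
#' and psi/omega at its end.
#'
#' @param chain A [backbone_chain].
#' @return A data frame of class `dihedral_table` with one row per residue:
#'   `k` (1-based index in the chain), `resno`, `resname`, `stretch`
#'   (contiguous-stretch id), and `phi`, `psi`, `omega_prev`, `omega_next`
#'   in degrees on (-180, 180] with `NA` for undefined angles.
#' @export
compute_dihedrals <- function(chain) {
  stopifnot(inherits(chain, "backbone_chain"))
  n <- length(chain$resno)
  if (n < 2L) stop("chain too short: need at least 2 residues")
  if (sum(chain$complete) < 2L) {
    stop("chain has fewer than 2 residues with complete backbones")
  }
  # bonded[i]: residue i is peptide-bonded to residue i+1
  bonded <- logical(max(n - 1L, 0L))
  for (i in seq_len(n - 1L)) {
    if (chain$complete[i] && chain$complete[i + 1L]) {
      d <- sqrt(sum((chain$c_xyz[i, ] - chain$n_xyz[i + 1L, ])^2))
      bonded[i] <- d <= PEPTIDE_BOND_CUTOFF
    }
  }
  stretch <- cumsum(c(TRUE, !bonded))
  phi <- psi <- omg <- rep(NA_real_, n)   # omg[k] = omega between k and k+1
  for (i in seq_len(n - 1L)) {
    if (!bonded[i]) next
    psi[i] <- torsion_angle(chain$n_xyz[i, ], chain$ca_xyz[i, ],
                            chain$c_xyz[i, ], chain$n_xyz[i + 1L, ])
    omg[i] <- torsion_angle(chain$ca_xyz[i, ], chain$c_xyz[i, ],
                            chain$n_xyz[i + 1L, ], chain$ca_xyz[i + 1L, ])
    phi[i + 1L] <- torsion_angle(chain$c_xyz[i, ], chain$n_xyz[i + 1L, ],
                                 chain$ca_xyz[i + 1L, ], chain$c_xyz[i + 1L, ])
  }
  omega_prev <- c(NA_real_, omg[-n])
  out <- data.frame(k = seq_len(n), resno = chain$resno,
                    resname = chain$resname, stretch = stretch,
                    phi = phi, psi = psi,
                    omega_prev = omega_prev, omega_next = omg,
                    stringsAsFactors = FALSE)
  class(out) <- c("dihedral_table", "data.frame")
  attr(out, "chain_id") <- chain$chain_id
  out
}

#' Write a dihedral table to TSV
#'
#' @param dihedrals A `dihedral_table` (see [compute_dihedrals()]).
#' @param path Output file path.
#' @param chain_id Chain label for the first column.
#' @return Invisibly, the path.
#' @export
write_dihedral_table <- function(dihedrals, path,
                                 chain_id = attr(dihedrals, "chain_id")) {
  if (is.null(chain_id)) chain_id <- "A"
  df <- data.frame(chain = chain_id, resnum = dihedrals$resno,
                   resname = dihedrals$resname,
                   phi = dihedrals$phi, psi = dihedrals$psi,
                   omega_prev = dihedrals$omega_prev,
                   omega_next = dihedrals$omega_next)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
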