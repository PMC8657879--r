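# shared fixture builders (everything synthetic, generated at test time)

helix_chain <- function(n = 10, phi = -57, psi = -47) {
  build_backbone(internal_coords(rep(phi, n), rep(psi, n), rep(180, n)))
}

# interior block RCS of an infinite-like stretch at constant angles
constant_angle_rcs <- function(phi, psi, n = 15) {
  sp <- internal_coords(rep(phi, n), rep(psi, n), rep(180, n))
  rcs_local(sp)$rcs[ceiling(n / 2)]
}

# a folding profile assembled directly (for ss_stats / CV tests)
fake_profile <- function(resno, rcs, chain = "A") {
  out <- data.frame(chain = chain, resno = resno,
                    resname = rep("ALA", length(resno)), rcs = rcs,
                    stringsAsFactors = FALSE)
  class(out) <- c("folding_profile", "data.frame")
  out
}

# hand-written PDB exercising altloc occupancy rules and HETATM exclusion:
# residue 2 CA has altloc A (occ 0.4) and B (occ 0.6) at different x
altloc_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
    "ATOM      3  C   ALA A   1       2.009   1.421   0.000  1.00  0.00",
    "ATOM      4  N   ALA A   2       3.332   1.536   0.000  1.00  0.00",
    "ATOM      5  CA AALA A   2       4.100   2.700   0.000  0.40  0.00",
    "ATOM      6  CA BALA A   2       4.200   2.700   0.000  0.60  0.00",
    "ATOM      7  C   ALA A   2       5.500   2.500   0.500  1.00  0.00",
    "HETATM    8  O   HOH A 101       9.000   9.000   9.000  1.00  0.00",
    "END")
}

dssp_fixture_lines <- function(labels, resno = seq_along(labels),
                               chain = "A") {
  hdr <- paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O",
                "    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA")
  rows <- vapply(seq_along(labels), function(i)
    sprintf("%5d%5d %1s %1s  %1s", i, resno[i], chain, "A", labels[i]),
    character(1))
  c("==== Secondary Structure Definition ====", hdr, rows)
}

stride_fixture_lines <- function(labels, resno = seq_along(labels),
                                 chain = "A") {
  vapply(seq_along(labels), function(i)
    sprintf("ASG  ALA %s %4d %4d    %1s    SomeName   -60.00    -45.00     100.0",
            chain, resno[i], i, labels[i]), character(1))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

write_labels_tsv <- function(labels, resno = seq_along(labels),
                             chain = "A") {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chain\tresnum\tlabel",
               paste(chain, resno, labels, sep = "\t")), f)
  f
}

# exhaustive minimax-barrier oracle on small grids (8-connectivity)
brute_force_barrier <- function(FF, mask, start, end) {
  nr <- nrow(FF); nc <- ncol(FF)
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  recurse <- function(i, j, cur_max) {
    if (cur_max >= best && !(i == end[1] && j == end[2])) {
      if (cur_max > best) return(invisible())
    }
    if (i == end[1] && j == end[2]) {
      best <<- min(best, cur_max)
      return(invisible())
    }
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ni <- i + di; nj <- j + dj
      if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
      if (mask[ni, nj] || visited[ni, nj]) next
      visited[ni, nj] <<- TRUE
      recurse(ni, nj, max(cur_max, FF[ni, nj]))
      visited[ni, nj] <<- FALSE
    }
  }
  visited[start[1], start[2]] <- TRUE
  recurse(start[1], start[2], FF[start[1], start[2]])
  best - FF[start[1], start[2]]
}

manual_pmf_grid <- function(FF, kT = 1) {
  FF <- as.matrix(FF)
  mask <- is.na(FF)
  p <- exp(-FF / kT)
  p[mask] <- 0
  p <- p / sum(p)
  structure(list(edges_x = seq(0, 1, length.out = nrow(FF) + 1L),
                 edges_y = if (ncol(FF) > 1L)
                   seq(0, 1, length.out = ncol(FF) + 1L) else NULL,
                 counts = (!mask) * 1L, p = p, F = FF, mask = mask,
                 kT = kT),
            class = "pmf_grid")
}
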