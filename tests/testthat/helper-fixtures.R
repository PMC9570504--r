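# Shared fixture builders: simple gating models, synthetic traces, and toy
# PDB structures (written as text at test time).

# gating model with no voltage dependence (a = 0): open probability 1/2
flat_model <- function(k0 = 5, gamma_main = 200, gamma_res = 0,
                       p_fullclose = 1) {
  gating_model(v0_pos = 40, a_pos = 0, k0 = k0, gamma_main = gamma_main,
               gamma_res = gamma_res, p_fullclose = p_fullclose,
               label = "flat")
}

# trace holding a given sample vector (defaults: no baseline segment)
make_trace <- function(samples, fs = 10000, vj = 40, t_on = 0) {
  gj_trace(vj = vj, samples = samples, sampling_rate = fs, t_on = t_on,
           metadata = list(construct = "test", seed = 0, n_channels = 1))
}

# square wave alternating lo/hi, starting at lo, `cycles` full periods
square_trace <- function(lo = 0, hi = 8, half_period_s = 0.1, cycles = 10,
                         fs = 10000, vj = 40) {
  half <- round(half_period_s * fs)
  make_trace(rep(rep(c(lo, hi), cycles), each = half), fs = fs, vj = vj)
}

# --- toy PDB machinery -----------------------------------------------------

pdb_atom_line <- function(serial, atom, resid, chain, resno, x, y, z,
                          occ = 1, elem = substr(atom, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, atom, " ", resid, chain, resno, " ", x, y, z, occ, 0, elem)
}

write_toy_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  # atoms: data.frame(atom, resid, chain, resno, x, y, z[, occ][, altloc])
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    ln <- pdb_atom_line(i, a$atom, a$resid, a$chain, a$resno, a$x, a$y, a$z,
                        occ = if ("occ" %in% names(atoms)) a$occ else 1)
    if ("altloc" %in% names(atoms) && nzchar(a$altloc))
      substr(ln, 17, 17) <- a$altloc
    lines[i] <- ln
  }
  writeLines(c(lines, "END"), path)
  path
}

# a cloud of CA-like carbon atoms on separate residues, two chains
random_toy_structure <- function(n_atoms, seed, spread = 12) {
  set.seed(seed)
  elements <- c("C", "N", "O", "S")
  data.frame(atom = paste0(sample(elements, n_atoms, replace = TRUE), "X"),
             resid = "GLY",
             chain = rep(c("A", "B"), length.out = n_atoms),
             resno = seq_len(n_atoms),
             x = runif(n_atoms, 0, spread),
             y = runif(n_atoms, 0, spread),
             z = runif(n_atoms, 0, spread),
             stringsAsFactors = FALSE)
}

# Brute-force all-pairs clash oracle: O(n^2) distances, bond graph by the
# same distance rule, BFS exclusion of pairs within two bonds.
brute_force_clash <- function(structure, sel_a, sel_b, tolerance = 0.4,
                              cutoff = 5) {
  radius <- function(e) {
    r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)[e]
    ifelse(is.na(r), 1.70, r)
  }
  ia <- which(paste(structure$chain, structure$resno) %in%
                do.call(paste, parse_selection(sel_a)))
  ib <- which(paste(structure$chain, structure$resno) %in%
                do.call(paste, parse_selection(sel_b)))
  xyz <- as.matrix(structure[c("x", "y", "z")])
  nall <- nrow(structure)
  dmat <- as.matrix(dist(xyz))
  bond <- dmat <= ifelse(outer(structure$element == "S",
                               structure$element == "S", "|"), 2.1, 1.85) &
    dmat > 0
  within2 <- bond | (bond %*% bond > 0)
  rows <- list()
  for (i in ia) for (j in ib) {
    if (i == j) next
    d <- dmat[i, j]
    if (d > cutoff) next
    if (within2[i, j]) next
    a <- min(i, j); b <- max(i, j)
    rsum <- radius(structure$element[a]) + radius(structure$element[b])
    rows[[paste(a, b)]] <- data.frame(
      a = a, b = b, distance = d, radii_sum = rsum,
      classification = if (d < rsum - tolerance) "clash"
      else if (d < rsum + 0.5) "contact" else "none")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[order(out$a, out$b), ]
  rownames(out) <- NULL
  out
}
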