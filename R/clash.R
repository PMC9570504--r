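# Van der Waals steric clash screening between residue selections in PDB
# coordinate files, for the connexin amino-terminal / TM2 packing interface.

vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
default_radius <- 1.70
contact_margin <- 0.5

#' Read heavy-atom records from a PDB file
#'
#' Parses ATOM/HETATM records (via `bio3d::read.pdb`) into a flat atom
#' table.  Waters are skipped, hydrogens dropped, and where alternate
#' locations exist only the highest-occupancy copy of each atom is kept.
#' Truncated ATOM records are rejected with an error naming the line;
#' elements without a tabulated van der Waals radius trigger a warning and
#' get a default 1.70 A radius downstream.
#'
#' @param path PDB-format file.
#' @return Data frame of class `"gj_structure"`: `chain`, `resno`, `resid`,
#'   `atom` (atom name), `element`, `x`, `y`, `z` (A).
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in '", path, "'")
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad))
    stop(sprintf("line %d: truncated ATOM/HETATM record (needs coordinates)",
                 bad[1]))
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  guess <- toupper(substr(trimws(at$elety), 1, 1))
  elem[!nzchar(elem)] <- guess[!nzchar(elem)]
  at$element <- elem
  at <- at[at$element != "H", , drop = FALSE]
  if (nrow(at) == 0) stop("no heavy atoms after filtering")
  unknown <- setdiff(unique(at$element), names(vdw_radii))
  if (length(unknown))
    warning("element(s) without tabulated radius, using default 1.70 A: ",
            paste(unknown, collapse = ", "))
  # alternate locations: keep the highest-occupancy copy of each atom
  occ <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  keep <- !duplicated(key[order(-occ)])[order(order(-occ))]
  at <- at[keep, , drop = FALSE]
  structure(data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                       atom = trimws(at$elety), element = at$element,
                       x = at$x, y = at$y, z = at$z,
                       stringsAsFactors = FALSE),
            class = c("gj_structure", "data.frame"))
}

#' @export
print.gj_structure <- function(x, ...) {
  cat(sprintf("Structure: %d heavy atoms, %d residues, chains %s\n",
              nrow(x), length(unique(paste(x$chain, x$resno))),
              paste(sort(unique(x$chain)), collapse = "")))
  invisible(x)
}

#' Parse a residue selection
#'
#' Selections use `CHAIN:RESNUM` or `CHAIN:FIRST-LAST` syntax (e.g.
#' `"A:4-17"`), possibly several strings.  Data frames with `chain` and
#' `resno` columns pass through.
#'
#' @param sel Character vector of selections or a data frame.
#' @return Data frame with columns `chain` and `resno`.
#' @export
parse_selection <- function(sel) {
  if (is.data.frame(sel)) {
    stopifnot(all(c("chain", "resno") %in% names(sel)))
    return(sel[c("chain", "resno")])
  }
  out <- lapply(sel, function(s) {
    m <- regmatches(s, regexec("^([A-Za-z0-9]):(-?[0-9]+)(?:-(-?[0-9]+))?$", s))[[1]]
    if (length(m) == 0)
      stop("cannot parse selection '", s, "' (expected CHAIN:RESNUM[-RESNUM])")
    lo <- as.integer(m[3])
    hi <- if (nzchar(m[4])) as.integer(m[4]) else lo
    data.frame(chain = m[2], resno = lo:hi, stringsAsFactors = FALSE)
  })
  unique(do.call(rbind, out))
}

atom_radius <- function(element) {
  r <- vdw_radii[element]
  r[is.na(r)] <- default_radius
  unname(r)
}

select_atoms <- function(structure, sel) {
  sel <- parse_selection(sel)
  which(paste(structure$chain, structure$resno) %in%
          paste(sel$chain, sel$resno))
}

# Cell-list neighbour search: all (i in a, j in b) atom index pairs within
# `cutoff`, cost proportional to the number of nearby pairs.
grid_pairs <- function(structure, ia, ib, cutoff) {
  xyz <- as.matrix(structure[c("x", "y", "z")])
  cell <- function(idx) floor(xyz[idx, , drop = FALSE] / cutoff)
  ca <- cell(ia); cb <- cell(ib)
  keyb <- paste(cb[, 1], cb[, 2], cb[, 3])
  bmap <- split(seq_along(ib), keyb)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  for (k in seq_along(ia)) {
    keys <- paste(ca[k, 1] + off[, 1], ca[k, 2] + off[, 2], ca[k, 3] + off[, 3])
    cand <- unlist(bmap[keys], use.names = FALSE)
    if (length(cand) == 0) next
    jj <- ib[cand]
    d <- sqrt(colSums((t(xyz[jj, , drop = FALSE]) - xyz[ia[k], ])^2))
    sel <- d <= cutoff & jj != ia[k]
    out_i <- c(out_i, rep(ia[k], sum(sel)))
    out_j <- c(out_j, jj[sel])
    out_d <- c(out_d, d[sel])
  }
  list(i = out_i, j = out_j, d = out_d)
}

# Heavy-atom covalent bonds by distance (< 1.85 A, 2.1 A when sulfur is
# involved); returns for each atom the set of atoms within 2 bonds.
bonded_within2 <- function(structure, idx) {
  pr <- grid_pairs(structure, idx, idx, 2.1)
  bond <- pr$d <= ifelse(structure$element[pr$i] == "S" |
                           structure$element[pr$j] == "S", 2.1, 1.85)
  adj <- split(pr$j[bond], pr$i[bond])
  near2 <- lapply(adj, function(nb)
    unique(c(nb, unlist(adj[as.character(nb)], use.names = FALSE))))
  near2
}

classify_overlap <- function(d, rsum, tolerance) {
  ifelse(d < rsum - tolerance, "clash",
         ifelse(d < rsum + contact_margin, "contact", "none"))
}

#' Scan for van der Waals clashes between two selections
#'
#' Evaluates every inter-selection heavy-atom pair within 5 A (cell-list
#' neighbour search) against the van der Waals criterion: a pair clashes
#' when its distance is below the radii sum minus `tolerance`, is a contact
#' when below the radii sum plus 0.5 A, and is otherwise reported as
#' `"none"`.  Radii: C 1.70, N 1.55, O 1.52, S 1.80 A (default 1.70 A
#' elsewhere).  Atom pairs separated by two covalent bonds or fewer
#' (distance-inferred bonding) are excluded, as are self pairs.
#'
#' @param structure A `"gj_structure"` from [read_structure()].
#' @param selection_a,selection_b Residue selections (see
#'   [parse_selection()]).
#' @param tolerance Allowed overlap (A) before a pair counts as a clash.
#' @return Data frame of class `"gj_clash_report"`, one row per evaluated
#'   pair (canonical atom order, sorted): atom descriptors, `distance`,
#'   `radii_sum`, `overlap` (`radii_sum - distance - tolerance`) and
#'   `classification`.
#' @export
clash_scan <- function(structure, selection_a, selection_b, tolerance = 0.4) {
  stopifnot(inherits(structure, "gj_structure"))
  if (tolerance < 0) stop("'tolerance' must be >= 0")
  ia <- select_atoms(structure, selection_a)
  ib <- select_atoms(structure, selection_b)
  if (length(ia) == 0 || length(ib) == 0)
    stop("empty selection: no atoms matched")
  pr <- grid_pairs(structure, ia, ib, 5)
  if (length(pr$i)) {
    # bond graph over the whole structure: two selection atoms can be
    # covalently linked through atoms outside either selection
    excl <- bonded_within2(structure, seq_len(nrow(structure)))
    is_excluded <- mapply(function(i, j) j %in% excl[[as.character(i)]],
                          pr$i, pr$j)
    keep <- !is_excluded
    pr <- list(i = pr$i[keep], j = pr$j[keep], d = pr$d[keep])
  }
  # canonicalize pair order and drop duplicates (overlapping selections)
  a <- pmin(pr$i, pr$j); b <- pmax(pr$i, pr$j)
  dup <- duplicated(paste(a, b))
  a <- a[!dup]; b <- b[!dup]; d <- pr$d[!dup]
  rsum <- atom_radius(structure$element[a]) + atom_radius(structure$element[b])
  out <- data.frame(
    chain_a = structure$chain[a], resno_a = structure$resno[a],
    resid_a = structure$resid[a], atom_a = structure$atom[a],
    chain_b = structure$chain[b], resno_b = structure$resno[b],
    resid_b = structure$resid[b], atom_b = structure$atom[b],
    distance = d, radii_sum = rsum,
    overlap = rsum - d - tolerance,
    classification = classify_overlap(d, rsum, tolerance),
    stringsAsFactors = FALSE)
  out <- out[order(out$chain_a, out$resno_a, out$atom_a,
                   out$chain_b, out$resno_b, out$atom_b), ]
  rownames(out) <- NULL
  class(out) <- c("gj_clash_report", "data.frame")
  attr(out, "tolerance") <- tolerance
  out
}

#' @export
print.gj_clash_report <- function(x, ...) {
  cat(sprintf("Clash report: %d pairs within 5 A, %d clash, %d contact (tolerance %.2g A)\n",
              nrow(x), sum(x$classification == "clash"),
              sum(x$classification == "contact"), attr(x, "tolerance")))
  if (nrow(x)) print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Amino-terminal / TM2 interface contact profile
#'
#' For every subunit (chain), lists each amino-terminal residue x TM2
#' residue pair with the minimal heavy-atom distance and its van der Waals
#' classification, both within the subunit and against the adjacent chain
#' (chains taken in sorted order, cyclically, as in a hexamer).  Residues
#' absent from the model (e.g. an unmodeled NT) are reported as missing
#' rather than failing.
#'
#' @param structure A `"gj_structure"`.
#' @param nt_range Amino-terminal residue numbers (default 4:17).
#' @param tm2_range TM2 residue numbers (default 85:95).
#' @param tolerance Clash tolerance (A).
#' @return Data frame: `chain_nt`, `chain_tm2`, `relation`
#'   (`"intra"`/`"inter"`), `nt_res`, `tm2_res`, `min_dist`,
#'   `classification`, `missing`.
#' @export
interface_profile <- function(structure, nt_range = 4:17, tm2_range = 85:95,
                              tolerance = 0.4) {
  stopifnot(inherits(structure, "gj_structure"))
  chains <- sort(unique(structure$chain))
  combos <- data.frame(chain_nt = chains, chain_tm2 = chains,
                       relation = "intra", stringsAsFactors = FALSE)
  if (length(chains) > 1) {
    nxt <- chains[c(seq_along(chains)[-1], 1)]
    combos <- rbind(combos,
                    data.frame(chain_nt = chains, chain_tm2 = nxt,
                               relation = "inter", stringsAsFactors = FALSE))
  }
  rows <- list()
  for (ci in seq_len(nrow(combos))) {
    cn <- combos$chain_nt[ci]; ct <- combos$chain_tm2[ci]
    for (r1 in nt_range) for (r2 in tm2_range) {
      i1 <- which(structure$chain == cn & structure$resno == r1)
      i2 <- which(structure$chain == ct & structure$resno == r2)
      if (length(i1) == 0 || length(i2) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          chain_nt = cn, chain_tm2 = ct, relation = combos$relation[ci],
          nt_res = r1, tm2_res = r2, min_dist = NA_real_,
          classification = NA_character_, missing = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      xyz1 <- as.matrix(structure[i1, c("x", "y", "z")])
      xyz2 <- as.matrix(structure[i2, c("x", "y", "z")])
      d2 <- outer(rowSums(xyz1^2), rowSums(xyz2^2), "+") -
        2 * xyz1 %*% t(xyz2)
      k <- arrayInd(which.min(d2), dim(d2))
      dmin <- sqrt(max(d2[k], 0))
      rsum <- atom_radius(structure$element[i1[k[1]]]) +
        atom_radius(structure$element[i2[k[2]]])
      rows[[length(rows) + 1]] <- data.frame(
        chain_nt = cn, chain_tm2 = ct, relation = combos$relation[ci],
        nt_res = r1, tm2_res = r2, min_dist = dmin,
        classification = classify_overlap(dmin, rsum, tolerance),
        missing = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
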