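#' Write a scaffold to a PDB file
#'
#' Emits standard ATOM records (backbone N, CA, C, O; residues written as
#' GLY placeholders since the scaffold is sequence-agnostic), chain IDs in
#' construction order, occupancy 1.00 and B-factor 0.00.
#'
#' @param scaffold A `scaffold`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_pdb <- function(scaffold, path) {
  validate_scaffold(scaffold)
  at <- scaffold$atoms
  ord <- order(match(at$chain, scaffold$chains$chain), at$resno,
               match(at$atom, c("N", "CA", "C", "O")))
  at <- at[ord, ]
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$resno, chain = at$chain,
                   resid = rep("GLY", nrow(at)), elety = at$atom,
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}

#' Read a scaffold back from a PDB file
#'
#' Parses ATOM records, groups them into chains and residues, and rebuilds
#' a `scaffold`: strand directions are recomputed from the CA end-to-end
#' vectors and sheet membership from single-linkage clustering of chain
#' centroids (chains closer than `sheet_cut` belong to one sheet).
#'
#' @param path PDB file path.
#' @param sheet_cut Centroid-distance cutoff separating sheets (A).
#' @return A `scaffold`.
#' @export
read_pdb <- function(path, sheet_cut = 8.0) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  atom_idx <- grep("^ATOM  |^HETATM", lines)
  if (length(atom_idx) == 0) abort("no ATOM records found")
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(sprintf("malformed ATOM record at line %d: too short", i))
    }
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords))))) {
      abort(sprintf("malformed ATOM record at line %d: non-numeric coordinates", i))
    }
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  a <- a[a$type %in% c("ATOM", "HETATM"), ]
  keep <- a$elety %in% c("N", "CA", "C", "O")
  a <- a[keep, ]
  if (nrow(a) == 0) abort("no backbone atoms (N, CA, C, O) in file")
  if (any(is.na(a$chain))) a$chain[is.na(a$chain)] <- "A"
  atoms <- tibble(chain = a$chain, resno = a$resno, atom = a$elety,
                  x = a$x, y = a$y, z = a$z)
  chains_ids <- unique(atoms$chain)
  # every residue needs a CA
  for (id in chains_ids) {
    sub <- atoms[atoms$chain == id, ]
    for (r in unique(sub$resno)) {
      if (!"CA" %in% sub$atom[sub$resno == r]) {
        abort(sprintf("chain %s residue %d is missing its CA atom", id, r))
      }
    }
  }
  nres <- vapply(chains_ids,
                 function(id) length(unique(atoms$resno[atoms$chain == id])),
                 integer(1))
  if (length(unique(nres)) != 1) abort("chains differ in residue count")

  cent <- t(vapply(chains_ids, function(id) {
    m <- atoms[atoms$chain == id & atoms$atom == "CA", c("x", "y", "z")]
    colMeans(as.matrix(m))
  }, numeric(3)))
  if (length(chains_ids) > 1) {
    hc <- stats::hclust(stats::dist(cent), method = "single")
    sheet <- stats::cutree(hc, h = sheet_cut)
    # renumber sheets in order of first appearance
    sheet <- as.integer(factor(sheet, levels = unique(sheet)))
  } else {
    sheet <- 1L
  }
  dirs <- t(vapply(chains_ids, function(id) {
    m <- atoms[atoms$chain == id & atoms$atom == "CA", ]
    m <- m[order(m$resno), c("x", "y", "z")]
    v <- as.numeric(m[nrow(m), ] - m[1, ])
    if (sum(v^2) == 0) c(1, 0, 0) else v / sqrt(sum(v^2))
  }, numeric(3)))

  chains <- tibble(chain = chains_ids, sheet_id = sheet,
                   dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
                   capped_n = FALSE, capped_c = FALSE)
  # infer spacings from the geometry itself
  sc <- structure(
    list(atoms = atoms, chains = chains,
         class_id = NA_integer_, n_residues = unname(nres[1]),
         d_strand = NA_real_, d_sheet = NA_real_),
    class = "scaffold")
  sc$d_strand <- measure_d_strand(sc)
  sc$d_sheet <- measure_d_sheet(sc)
  # classify by orientation pattern where recognizable
  ds <- as.matrix(chains[, c("dx", "dy", "dz")])
  insheet <- c()
  for (s in unique(sheet)) {
    idx <- which(sheet == s)
    if (length(idx) >= 2) {
      dots <- tcrossprod(ds[idx, , drop = FALSE])
      insheet <- c(insheet, dots[upper.tri(dots)])
    }
  }
  if (length(insheet) > 0) {
    if (all(insheet > 0)) sc$class_id <- 1L
    else if (all(diff(sign(ds[order(cent[, 2]), 1])) != 0)) sc$class_id <- 8L
  }
  sc
}
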