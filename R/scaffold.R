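#' Build an idealized two-layer cross-beta spine scaffold
#'
#' Constructs the fixed backbone geometry used for sequence design: two
#' stacked beta-sheets, each with `n_strands_per_sheet` extended 7-mer
#' strands. Class 1 has parallel strands within each sheet and
#' antiparallel strands between the two sheets; Class 8 has antiparallel
#' strands within each sheet (used as a comparison fixture).
#'
#' The geometry is an idealized extended strand (rise 3.4 A per residue
#' along x, strands stacked along y at `d_strand`, sheets stacked along z
#' at `d_sheet`) with the carbonyl oxygen extended toward the hydrogen
#' bonding partner strand, so that the standard backbone H-bond ladders of
#' parallel and antiparallel beta-sheets are realized by the N...O
#' distances.
#'
#' @param class_id 1 or 8 (cross-beta symmetry class).
#' @param n_strands_per_sheet Number of strands in each of the two sheets.
#' @param n_residues Residues per strand (default 7).
#' @param d_strand In-sheet strand spacing, Angstrom (default 5.5).
#' @param d_sheet Inter-sheet spacing, Angstrom (default 12).
#' @return A `scaffold` object: list with `atoms` (tibble: chain, resno,
#'   atom, x, y, z), `chains` (tibble: chain, sheet_id, dx, dy, dz,
#'   capped_n, capped_c), and scalars `class_id`, `n_residues`,
#'   `d_strand`, `d_sheet`.
#' @export
#' @examples
#' sc <- build_cross_beta_scaffold(1, 4, 7)
#' sc
build_cross_beta_scaffold <- function(class_id = 1, n_strands_per_sheet = 4,
                                      n_residues = 7, d_strand = 5.5,
                                      d_sheet = 12.0) {
  if (!class_id %in% c(1, 8)) {
    abort(paste0("unsupported cross-beta class: ", class_id,
                 " (supported: 1, 8)"))
  }
  stopifnot(n_strands_per_sheet >= 1, n_residues >= 1,
            d_strand > 0, d_sheet > 0)

  n_chains <- 2L * n_strands_per_sheet
  ids <- .chain_ids(n_chains)

  atoms <- vector("list", n_chains)
  chains <- vector("list", n_chains)
  k <- 0L
  for (sheet in 1:2) {
    for (s in seq_len(n_strands_per_sheet)) {
      k <- k + 1L
      # strand direction: Class 1 -> all parallel within a sheet, sheet 2
      # reversed; Class 8 -> alternating within each sheet
      reversed <- if (class_id == 1) sheet == 2 else (s %% 2 == 0)
      tpl <- .strand_template(n_residues, reversed)
      tpl$y <- tpl$y + (s - 1) * d_strand
      tpl$z <- tpl$z + (sheet - 1) * d_sheet
      tpl$chain <- ids[k]
      atoms[[k]] <- tpl
      dirx <- if (reversed) -1 else 1
      chains[[k]] <- tibble(chain = ids[k], sheet_id = sheet,
                            dx = dirx, dy = 0, dz = 0,
                            capped_n = FALSE, capped_c = FALSE)
    }
  }

  sc <- structure(
    list(atoms = bind_rows(atoms)[, c("chain", "resno", "atom", "x", "y", "z")],
         chains = bind_rows(chains),
         class_id = class_id, n_residues = n_residues,
         d_strand = d_strand, d_sheet = d_sheet),
    class = "scaffold")
  validate_scaffold(sc)
  sc
}

# Extended-strand backbone template (N, CA, C, O per residue), centered on
# x so that a 180-degree rotation about z leaves the strand's footprint in
# place. Carbonyl O extends +y (toward the next strand); CA carries an
# alternating +-0.6 A pleat in z.
.strand_template <- function(n_residues, reversed = FALSE, rise = 3.4) {
  i <- seq_len(n_residues)
  xN <- (i - 1) * rise
  xCA <- xN + 1.15
  xC <- xN + 2.3
  pleat <- 0.6 * (-1)^i
  atoms <- tibble(
    resno = rep(i, each = 4L),
    atom = rep(c("N", "CA", "C", "O"), n_residues),
    x = as.vector(rbind(xN, xCA, xC, xC)),
    y = rep(c(0, 0, 0, 1.23), n_residues),
    z = as.vector(rbind(0, pleat, 0, 0))
  )
  xc <- (max(xC) + min(xN)) / 2
  atoms$x <- atoms$x - xc
  if (reversed) {
    # rotate 180 degrees about the z axis through the strand center
    atoms$x <- -atoms$x
    atoms$y <- -atoms$y
    # renumber so residue 1 is still at the N terminus of the chain walk
  }
  atoms
}

.chain_ids <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n > length(pool)) abort("too many chains for single-character IDs")
  pool[seq_len(n)]
}

#' Validate scaffold invariants
#'
#' Checks finite coordinates, equal chain lengths, the strand-direction
#' sign pattern of the declared class, and the realized in-sheet spacing.
#'
#' @param scaffold A `scaffold`.
#' @return Invisibly `TRUE`; aborts with a message on violation.
#' @export
validate_scaffold <- function(scaffold) {
  at <- scaffold$atoms
  if (!all(is.finite(c(at$x, at$y, at$z)))) abort("non-finite coordinates")
  nres <- tapply(at$resno, at$chain, function(r) length(unique(r)))
  if (length(unique(nres)) != 1) abort("chains differ in residue count")
  ch <- scaffold$chains
  dirs <- as.matrix(ch[, c("dx", "dy", "dz")])
  if (is.na(scaffold$class_id)) return(invisible(TRUE))
  for (s in unique(ch$sheet_id)) {
    idx <- which(ch$sheet_id == s)
    if (length(idx) >= 2) {
      dots <- tcrossprod(dirs[idx, , drop = FALSE])
      off <- dots[upper.tri(dots)]
      if (scaffold$class_id == 1 && any(off <= 0))
        abort("Class-1 scaffold has non-parallel strands within a sheet")
      if (scaffold$class_id == 8) {
        # adjacent strands must be antiparallel
        for (j in seq_len(length(idx) - 1)) {
          if (sum(dirs[idx[j], ] * dirs[idx[j + 1], ]) >= 0)
            abort("Class-8 scaffold has non-antiparallel adjacent strands")
        }
      }
    }
  }
  if (scaffold$class_id == 1 && length(unique(ch$sheet_id)) == 2) {
    d1 <- dirs[match(1, ch$sheet_id), ]
    d2 <- dirs[match(2, ch$sheet_id), ]
    if (sum(d1 * d2) >= 0) abort("Class-1 sheets are not mutually antiparallel")
  }
  ds <- measure_d_strand(scaffold)
  if (is.finite(ds) && is.finite(scaffold$d_strand) &&
      abs(ds - scaffold$d_strand) > 0.1)
    abort(sprintf("realized d_strand %.3f deviates from requested %.3f",
                  ds, scaffold$d_strand))
  invisible(TRUE)
}

#' @export
print.scaffold <- function(x, ...) {
  cat("<scaffold> class", x$class_id, "-", nrow(x$chains), "chains x",
      x$n_residues, "residues; d_strand", x$d_strand, "A, d_sheet",
      x$d_sheet, "A\n")
  capped <- x$chains$capped_n[1] || x$chains$capped_c[1]
  if (capped) cat("  termini capped (N-acetyl / C-amide)\n")
  invisible(x)
}

#' Scaffold atom table
#'
#' @param scaffold A `scaffold`.
#' @return The atom tibble (chain, resno, atom, x, y, z).
#' @export
scaffold_atoms <- function(scaffold) scaffold$atoms

.chain_ca <- function(scaffold, chain) {
  at <- scaffold$atoms
  sel <- at$atom == "CA" & at$chain == chain
  m <- as.matrix(at[sel, c("x", "y", "z")])
  m[order(at$resno[sel]), , drop = FALSE]
}

#' Measured in-sheet strand spacing
#'
#' Mean over all adjacent in-sheet strand pairs of the mean nearest
#' CA-to-CA distance, an independent check that the construction realized
#' the requested `d_strand`.
#'
#' @param scaffold A `scaffold`.
#' @return Spacing in Angstrom (NaN for single-strand sheets).
#' @export
measure_d_strand <- function(scaffold) {
  ch <- scaffold$chains
  vals <- c()
  for (s in unique(ch$sheet_id)) {
    ids <- ch$chain[ch$sheet_id == s]
    if (length(ids) < 2) next
    cas <- lapply(ids, function(id) .chain_ca(scaffold, id))
    cent <- t(vapply(cas, colMeans, numeric(3)))
    # order strands along the stacking direction within the sheet
    ax <- prcomp(cent)$rotation[, 1]
    ord <- order(cent %*% ax)
    for (j in seq_len(length(ids) - 1)) {
      a <- cas[[ord[j]]]; b <- cas[[ord[j + 1]]]
      dmat <- sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b))
      vals <- c(vals, mean(apply(dmat, 1, min)))
    }
  }
  if (length(vals) == 0) return(NaN)
  mean(vals)
}

#' Measured inter-sheet spacing
#'
#' Distance between the mean planes of the two sheets (projection of the
#' centroid difference onto the common sheet normal estimated by SVD).
#'
#' @param scaffold A `scaffold`.
#' @return Spacing in Angstrom (NaN if fewer than two sheets).
#' @export
measure_d_sheet <- function(scaffold) {
  ch <- scaffold$chains
  sheets <- unique(ch$sheet_id)
  if (length(sheets) < 2) return(NaN)
  pts <- lapply(sheets[1:2], function(s) {
    ids <- ch$chain[ch$sheet_id == s]
    do.call(rbind, lapply(ids, function(id) .chain_ca(scaffold, id)))
  })
  all_pts <- rbind(pts[[1]], pts[[2]])
  # sheet normal: direction of largest variation of the sheet labels
  c1 <- colMeans(pts[[1]]); c2 <- colMeans(pts[[2]])
  centered1 <- sweep(pts[[1]], 2, c1)
  centered2 <- sweep(pts[[2]], 2, c2)
  # normal of each sheet plane = least-variance direction
  n1 <- svd(centered1)$v[, 3]
  n2 <- svd(centered2)$v[, 3]
  if (sum(n1 * n2) < 0) n2 <- -n2
  nrm <- (n1 + n2) / sqrt(sum((n1 + n2)^2))
  abs(sum((c2 - c1) * nrm))
}

#' Replicate a scaffold unit under a symmetry transform
#'
#' Appends `n_copies` transformed copies of the unit, the transform being
#' applied cumulatively (copy k carries the transform applied k times).
#' Copies inherit the sheet assignment of their source chain, which is the
#' intended use for translational replication that extends the sheets.
#'
#' @param unit A `scaffold`.
#' @param rotation 3x3 orthonormal matrix (default identity).
#' @param translation Length-3 numeric, Angstrom.
#' @param n_copies Total number of copies including the original
#'   (`n_copies = 1` with identity transform returns the unit unchanged).
#' @return A `scaffold` with `n_copies * n_chains` chains.
#' @export
replicate_unit <- function(unit, rotation = diag(3), translation = c(0, 0, 0),
                           n_copies = 1) {
  stopifnot(n_copies >= 1)
  if (abs(abs(det(rotation)) - 1) > 1e-8)
    abort("rotation must be orthonormal (|det| = 1)")
  n0 <- nrow(unit$chains)
  ids <- .chain_ids(n0 * n_copies)
  atoms <- vector("list", n_copies)
  chains <- vector("list", n_copies)
  xyz0 <- as.matrix(unit$atoms[, c("x", "y", "z")])
  dir0 <- as.matrix(unit$chains[, c("dx", "dy", "dz")])
  xyz <- xyz0; dirm <- dir0
  for (k in seq_len(n_copies)) {
    a <- unit$atoms
    a[, c("x", "y", "z")] <- as.data.frame(xyz)
    a$chain <- ids[(k - 1) * n0 + match(a$chain, unit$chains$chain)]
    atoms[[k]] <- a
    cc <- unit$chains
    cc$chain <- ids[(k - 1) * n0 + seq_len(n0)]
    cc[, c("dx", "dy", "dz")] <- as.data.frame(dirm)
    chains[[k]] <- cc
    xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
    dirm <- dirm %*% t(rotation)
  }
  out <- unit
  out$atoms <- bind_rows(atoms)
  out$chains <- bind_rows(chains)
  # steric-clash check between distinct copies
  if (n_copies > 1) {
    coords <- lapply(atoms, function(a) as.matrix(a[, c("x", "y", "z")]))
    for (i in seq_len(n_copies - 1)) {
      for (j in (i + 1):n_copies) {
        d2 <- outer(rowSums(coords[[i]]^2), rowSums(coords[[j]]^2), "+") -
          2 * tcrossprod(coords[[i]], coords[[j]])
        if (min(d2) < 1.0^2) {
          abort(sprintf(
            "steric clash between copies %d and %d (min distance %.2f A < 1.0 A)",
            i, j, sqrt(max(min(d2), 0))))
        }
      }
    }
  }
  validate_scaffold(out)
  out
}

#' Cap scaffold termini
#'
#' Flags the N-termini as acetylated and/or the C-termini as amidated.
#' Capping neutralizes the terminal charges, which the scoring module uses
#' when evaluating charged residues at the termini. Idempotent.
#'
#' @param scaffold A `scaffold`.
#' @param n_cap,c_cap Logical flags.
#' @return The scaffold with updated cap flags.
#' @export
cap_termini <- function(scaffold, n_cap = TRUE, c_cap = TRUE) {
  scaffold$chains$capped_n <- scaffold$chains$capped_n | n_cap
  scaffold$chains$capped_c <- scaffold$chains$capped_c | c_cap
  scaffold
}
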