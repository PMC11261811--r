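# shared fixtures for the test suite (built in code, no stored data)

# two single-residue strands 5.5 A apart in one sheet: exactly one CA-CA
# contact pair under the 6.5 A cutoff
toy_two_chain_scaffold <- function() {
  at <- tibble::tibble(
    chain = rep(c("A", "B"), each = 4),
    resno = 1L,
    atom = rep(c("N", "CA", "C", "O"), 2),
    x = c(0, 1.15, 2.3, 2.3, 0, 1.15, 2.3, 2.3),
    y = c(0, 0, 0, 1.23, 5.5, 5.5, 5.5, 6.73),
    z = 0
  )
  ch <- tibble::tibble(chain = c("A", "B"), sheet_id = 1L,
                       dx = 1, dy = 0, dz = 0,
                       capped_n = FALSE, capped_c = FALSE)
  structure(list(atoms = at, chains = ch, class_id = 1L, n_residues = 1L,
                 d_strand = 5.5, d_sheet = 12), class = "scaffold")
}

# a potential with a single nonzero entry
single_entry_potential <- function(aa1 = "G", aa2 = "G", value = -1,
                                   e_hbond = 0) {
  p <- null_potential(e_hbond = e_hbond)
  p$e[aa1, aa2] <- value
  p$e[aa2, aa1] <- value
  p
}

# sheet of parallel strands with the last `n_reversed` strands
# antiparallel, in the scaffold frame layout
mixed_sheet_frame <- function(n_parallel, n_reversed, n_res = 7,
                              d_strand = 5.5) {
  n <- n_parallel + n_reversed
  ids <- LETTERS[seq_len(n)]
  rows <- lapply(seq_len(n), function(k) {
    tpl <- crossbeta:::.strand_template(n_res, reversed = k > n_parallel)
    tpl$y <- tpl$y + (k - 1) * d_strand
    tpl$chain <- ids[k]
    tpl
  })
  dplyr::bind_rows(rows)[, c("chain", "resno", "atom", "x", "y", "z")]
}

# apply a rigid rotation + translation to a scaffold (atoms and strand
# directions)
transform_scaffold <- function(sc, rot, trans) {
  xyz <- as.matrix(sc$atoms[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, trans, "+")
  sc$atoms[, c("x", "y", "z")] <- as.data.frame(xyz)
  dirs <- as.matrix(sc$chains[, c("dx", "dy", "dz")]) %*% t(rot)
  sc$chains[, c("dx", "dy", "dz")] <- as.data.frame(dirs)
  sc
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# direct access to the event-driven core for two-body and oracle checks
run_core <- function(pos, vel, mass, sigma, wellr, eps, bonds = NULL,
                     box = 200, kT = 0, ghost_rate = 0, t_end = 20,
                     frame_interval = NULL, max_log = 1000, chain = NULL) {
  n <- nrow(pos)
  if (is.null(chain)) chain <- seq_len(n) - 1L
  crossbeta:::.dmd_run(
    pos = pos, vel = vel, mass = mass,
    type = rep(0L, n), chain = as.integer(chain),
    sigma_tbl = matrix(sigma, 1, 1), wellr_tbl = matrix(wellr, 1, 1),
    eps_tbl = matrix(eps, 1, 1), inter_only_tbl = matrix(FALSE, 1, 1),
    bonds = if (is.null(bonds)) matrix(numeric(0), ncol = 4) else bonds,
    excl_pairs = matrix(numeric(0), ncol = 2),
    box = box, pbc = TRUE, kT = kT, ghost_rate = ghost_rate,
    t_end = t_end, frame_interval = frame_interval %||% t_end,
    max_events = 1e6, max_log = max_log, max_ghost_log = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

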