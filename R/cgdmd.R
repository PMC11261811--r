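#' Coarse-grained model parameters
#'
#' Loads the four-bead-per-residue model: shared backbone beads (NH, CA,
#' CO) and one side-chain sphere per residue with residue-specific
#' diameter, mass and CA-R bond length (shipped as a plain-text table).
#' Side-chain pair well depths are derived from the residue contact
#' potential (attractive entries only, scaled by `eps_scale`); backbone
#' hydrogen bonding is a square well between NH and CO beads of different
#' chains. Sequence recognition is side-chain driven: in-register
#' stacking wells of identical residues are the deep "zipper" (2-3.5
#' kcal/mol), while the H-bond well is moderate (default 1.0 kcal/mol)
#' and narrow (outer distance 4.2 A against a 3.65 A contact), which
#' acts as a registry filter: sheared or reversed backbone pairings sit
#' near the outer well edge and detach, while in-register ladders hold.
#' At 296-310 K (kT = 0.59-0.62 kcal/mol) in-register parallel ladders
#' are stable while mismatched contacts exchange - the fibrillization
#' window of the shipped parameter set.
#'
#' @param bead_file TSV with columns aa, sc_diameter, sc_mass, ca_r_bond;
#'   `NULL` loads the shipped table.
#' @param pair_file Contact-potential TSV for side-chain well depths;
#'   `NULL` loads the shipped table.
#' @param eps_hb Backbone H-bond well depth, kcal/mol.
#' @param hb_range NH-CO well outer distance, Angstrom.
#' @param well_factor Side-chain well outer distance as a multiple of the
#'   contact diameter.
#' @param eps_scale kcal/mol per score unit for side-chain depths.
#' @param bond_tol Half-width of bond windows as a fraction of the
#'   nominal length.
#' @return A `cg_params` list.
#' @export
cg_model_params <- function(bead_file = NULL, pair_file = NULL,
                            eps_hb = 1.0, hb_range = 4.2,
                            well_factor = 1.5, eps_scale = 1.0,
                            bond_tol = 0.02375) {
  if (is.null(bead_file)) {
    bead_file <- system.file("extdata", "cg_beads.tsv",
                             package = "crossbeta", mustWork = TRUE)
  }
  beads <- utils::read.delim(bead_file)
  stopifnot(all(c("aa", "sc_diameter", "sc_mass", "ca_r_bond") %in% names(beads)))
  pot <- contact_potential(pair_file)
  depth <- pmax(-pot$e, 0) * eps_scale
  structure(list(
    backbone = tibble(bead = c("NH", "CA", "CO"),
                      diameter = c(3.3, 3.7, 4.0),
                      mass = c(15.015, 13.019, 28.010)),
    sidechain = as_tibble(beads),
    sc_depth = depth,
    eps_hb = eps_hb, hb_range = hb_range,
    well_factor = well_factor, bond_tol = bond_tol),
    class = "cg_params")
}

#' Purely repulsive variant of a parameter set
#'
#' Zeroes every square-well attraction (H-bond and side chain), leaving
#' hard cores and bonds; used as a no-aggregation control.
#'
#' @param params A `cg_params`.
#' @return Modified `cg_params`.
#' @export
repulsive_params <- function(params = cg_model_params()) {
  params$eps_hb <- 0
  params$sc_depth[] <- 0
  params
}

#' Peptide concentration of n chains in a cubic box
#'
#' `n / (N_A * L^3)` expressed in mM.
#'
#' @param n_peptides Number of chains.
#' @param box_edge Box edge length, Angstrom.
#' @return Concentration in mM.
#' @export
#' @examples
#' concentration(48, 200)  # ~10 mM
concentration <- function(n_peptides, box_edge) {
  stopifnot(n_peptides > 0, box_edge > 0)
  litres <- (box_edge * 1e-9 / 10)^3 * 1e3  # A^3 -> dm^3
  (n_peptides / .NA_const) / litres * 1e3   # mol/L -> mM
}

# ideal linear-backbone template for one CG chain: bead tibble with
# columns resno, atom, x, y, z, type, mass (types indexed into the
# interaction tables built by .cg_tables)
.cg_template <- function(sequence, params) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  rise <- 3.4
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    x0 <- (i - 1) * rise
    sc <- params$sidechain[params$sidechain$aa == aa[i], ]
    if (nrow(sc) == 0) abort(paste0("no CG parameters for residue ", aa[i]))
    side <- ifelse(i %% 2 == 0, 1, -1)
    rows[[i]] <- tibble(
      resno = i,
      atom = c("NH", "CA", "CO", "R"),
      x = c(x0, x0 + 1.15, x0 + 2.3, x0 + 1.15),
      y = 0,
      z = c(0, 0, 0, side * sc$ca_r_bond),
      aa = aa[i]
    )
  }
  bind_rows(rows)
}

# bond + pseudobond list for one chain, nominal lengths measured on the
# template so the initial state satisfies every window exactly
.cg_bonds <- function(template, tol) {
  idx <- function(resno, atom) {
    which(template$resno == resno & template$atom == atom)
  }
  n <- max(template$resno)
  spec <- list()
  add <- function(i, j) spec[[length(spec) + 1]] <<- c(i, j)
  for (r in seq_len(n)) {
    add(idx(r, "NH"), idx(r, "CA"))
    add(idx(r, "CA"), idx(r, "CO"))
    add(idx(r, "NH"), idx(r, "CO"))   # angle pseudo-bond
    add(idx(r, "CA"), idx(r, "R"))
    add(idx(r, "NH"), idx(r, "R"))    # side-chain placement pseudo-bonds
    add(idx(r, "CO"), idx(r, "R"))
    if (r < n) {
      add(idx(r, "CO"), idx(r + 1, "NH"))
      add(idx(r, "CA"), idx(r + 1, "NH"))  # backbone geometry pseudo-bonds
      add(idx(r, "CO"), idx(r + 1, "CA"))
      add(idx(r, "CA"), idx(r + 1, "CA"))
    }
    if (r < n - 1) {
      add(idx(r, "CA"), idx(r + 2, "CA"))  # extension bias
    }
  }
  m <- do.call(rbind, spec)
  xyz <- as.matrix(template[, c("x", "y", "z")])
  len <- sqrt(rowSums((xyz[m[, 1], , drop = FALSE] -
                         xyz[m[, 2], , drop = FALSE])^2))
  cbind(i = m[, 1], j = m[, 2],
        rmin = len * (1 - tol), rmax = len * (1 + tol))
}

# interaction tables: type 1 = NH, 2 = CA, 3 = CO, 3+k = side chain of
# the k-th residue of the 20-residue alphabet
.cg_tables <- function(params) {
  aa <- params$sidechain$aa
  diam <- c(params$backbone$diameter, params$sidechain$sc_diameter)
  mass <- c(params$backbone$mass, params$sidechain$sc_mass)
  nt <- length(diam)
  sigma <- outer(diam, diam, function(a, b) (a + b) / 2)
  wellr <- matrix(0, nt, nt)
  eps <- matrix(0, nt, nt)
  inter_only <- matrix(TRUE, nt, nt)
  # backbone H-bond: NH (type 1) with CO (type 3), inter-chain only
  if (params$eps_hb > 0) {
    wellr[1, 3] <- wellr[3, 1] <- params$hb_range
    eps[1, 3] <- eps[3, 1] <- params$eps_hb
  }
  # side-chain square wells
  sc_idx <- 3 + seq_along(aa)
  for (a in seq_along(aa)) {
    for (b in seq_along(aa)) {
      d <- params$sc_depth[aa[a], aa[b]]
      if (d > 0) {
        wellr[sc_idx[a], sc_idx[b]] <- params$well_factor *
          sigma[sc_idx[a], sc_idx[b]]
        eps[sc_idx[a], sc_idx[b]] <- d
      }
    }
  }
  list(aa = aa, sigma = sigma, wellr = wellr, eps = eps,
       inter_only = inter_only, mass = mass)
}

.bead_type <- function(template, aa_order) {
  ifelse(template$atom == "NH", 1L,
         ifelse(template$atom == "CA", 2L,
                ifelse(template$atom == "CO", 3L,
                       3L + match(template$aa, aa_order))))
}

#' Build a multi-chain coarse-grained peptide system
#'
#' Places `n_peptides` copies of the CG chain at random non-overlapping
#' positions and orientations in a cubic periodic box and draws
#' Maxwell-Boltzmann velocities at temperature `T` with zero net
#' momentum.
#'
#' @param sequence Peptide sequence.
#' @param n_peptides Number of chains.
#' @param box_edge Box edge, Angstrom.
#' @param temperature Temperature, K.
#' @param params A [cg_model_params()].
#' @param seed Optional integer seed.
#' @param max_tries Placement attempts per chain before giving up.
#' @return A `cg_system` list: beads tibble (chain, resno, atom, aa, type,
#'   mass, x, y, z, vx, vy, vz), bonds matrix, interaction tables, box
#'   edge, temperature.
#' @export
build_cg_system <- function(sequence, n_peptides, box_edge, temperature = 310,
                            params = cg_model_params(), seed = NULL,
                            max_tries = 2000) {
  if (!is.null(seed)) set.seed(seed)
  tpl <- .cg_template(sequence, params)
  tab <- .cg_tables(params)
  tpl$type <- .bead_type(tpl, tab$aa)
  tpl$mass <- tab$mass[tpl$type]
  bonds1 <- .cg_bonds(tpl, params$bond_tol)
  nb <- nrow(tpl)
  xyz0 <- as.matrix(tpl[, c("x", "y", "z")])
  xyz0 <- sweep(xyz0, 2, colMeans(xyz0))
  maxdiam <- max(tab$sigma)

  placed <- list()
  for (k in seq_len(n_peptides)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      rot <- .random_rotation()
      shift <- runif(3, 0, box_edge)
      cand <- sweep(xyz0 %*% t(rot), 2, shift, "+")
      ok <- TRUE
      for (prev in placed) {
        dx <- abs(outer(cand[, 1], prev[, 1], "-"))
        dy <- abs(outer(cand[, 2], prev[, 2], "-"))
        dz <- abs(outer(cand[, 3], prev[, 3], "-"))
        dx <- pmin(dx, box_edge - dx)
        dy <- pmin(dy, box_edge - dy)
        dz <- pmin(dz, box_edge - dz)
        if (min(dx^2 + dy^2 + dz^2) < maxdiam^2) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) {
      abort(sprintf(
        "could not place chain %d without overlap after %d tries; use a larger box",
        k, max_tries))
    }
    placed[[k]] <- cand
  }

  beads <- purrr::map_dfr(seq_len(n_peptides), function(k) {
    b <- tpl
    b$chain <- .chain_ids(n_peptides)[k]
    b[, c("x", "y", "z")] <- as.data.frame(placed[[k]])
    b
  })
  kT <- .kB * temperature
  vel <- matrix(rnorm(nrow(beads) * 3), ncol = 3) *
    sqrt(kT / beads$mass)
  # remove net momentum
  ptot <- colSums(vel * beads$mass)
  vel <- sweep(vel, 2, ptot / sum(beads$mass))
  beads$vx <- vel[, 1]; beads$vy <- vel[, 2]; beads$vz <- vel[, 3]

  bonds <- do.call(rbind, lapply(seq_len(n_peptides), function(k) {
    b <- bonds1
    b[, 1:2] <- b[, 1:2] + (k - 1) * nb
    b
  }))
  # full exclusions: same-chain bead pairs closer than two residues apart
  # that are not bond-window pairs (their template distances are shorter
  # than the hard cores)
  excl <- do.call(rbind, lapply(seq_len(n_peptides), function(k) {
    off <- (k - 1) * nb
    pairs <- list()
    for (i in seq_len(nb - 1)) {
      for (j in (i + 1):nb) {
        if (abs(tpl$resno[i] - tpl$resno[j]) <= 1) {
          pairs[[length(pairs) + 1]] <- c(i + off, j + off)
        }
      }
    }
    do.call(rbind, pairs)
  }))
  bond_keys <- paste(bonds[, 1], bonds[, 2])
  excl <- excl[!(paste(excl[, 1], excl[, 2]) %in% bond_keys), , drop = FALSE]

  structure(list(
    beads = beads[, c("chain", "resno", "atom", "aa", "type", "mass",
                      "x", "y", "z", "vx", "vy", "vz")],
    bonds = bonds, exclusions = excl, tables = tab,
    box_edge = box_edge, temperature = temperature,
    sequence = sequence, n_peptides = n_peptides, params = params),
    class = "cg_system")
}

.random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' @export
print.cg_system <- function(x, ...) {
  cat("<cg_system>", x$n_peptides, "x", x$sequence, "-",
      nrow(x$beads), "beads in", x$box_edge, "A box at",
      x$temperature, "K (", round(concentration(x$n_peptides, x$box_edge), 2),
      "mM )\n")
  invisible(x)
}

#' Kinetic temperature of a CG system
#'
#' From the velocity variance: `T = sum(m v^2) / (3 N kB)`.
#'
#' @param system A `cg_system` (or a trajectory's final system).
#' @return Temperature in K.
#' @export
measure_temperature <- function(system) {
  b <- system$beads
  if (nrow(b) < 2) abort("need at least 2 beads")
  ke2 <- sum(b$mass * (b$vx^2 + b$vy^2 + b$vz^2))
  ke2 / (3 * nrow(b) * .kB)
}

#' Run event-driven dynamics on a CG system
#'
#' Beads move ballistically between events: elastic hard-core collisions,
#' square-well captures and escapes (energy-conserving with well-depth
#' bookkeeping), hard reflections at bond-window walls, and - when the
#' thermostat is on - Andersen ghost collisions that redraw one bead's
#' velocity from the Maxwell-Boltzmann distribution at the set
#' temperature.
#'
#' @param system A [build_cg_system()] result.
#' @param t_end End time, reduced units (1 unit ~ 48.9 fs).
#' @param thermostat_rate Ghost-collision rate per bead per time unit
#'   (0 disables the thermostat).
#' @param frame_interval Snapshot interval, reduced time.
#' @param seed Optional integer seed.
#' @param max_events Safety cap on processed events.
#' @param event_log Number of events to record (for diagnostics/oracles).
#' @param ghost_log Number of thermostat velocity draws to record.
#' @return A `cg_trajectory`: list with `frames` (tibbles in the standard
#'   frame layout, box attribute set), `times`, `energy` (tibble: time,
#'   kinetic, potential), `final` (the system with updated coordinates),
#'   `n_events`, `energy_drift`, `events`, `ghost_draws`.
#' @export
run_dmd <- function(system, t_end, thermostat_rate = 0.1,
                    frame_interval = NULL, seed = NULL,
                    max_events = 5e7, event_log = 0, ghost_log = 0) {
  stopifnot(inherits(system, "cg_system"), t_end > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(frame_interval)) frame_interval <- t_end / 10
  b <- system$beads
  kT <- .kB * system$temperature
  res <- .dmd_run(
    pos = as.matrix(b[, c("x", "y", "z")]),
    vel = as.matrix(b[, c("vx", "vy", "vz")]),
    mass = b$mass, type = b$type - 1L,
    chain = as.integer(factor(b$chain, levels = unique(b$chain))) - 1L,
    sigma_tbl = system$tables$sigma,
    wellr_tbl = system$tables$wellr,
    eps_tbl = system$tables$eps,
    inter_only_tbl = system$tables$inter_only,
    bonds = cbind(system$bonds[, 1] - 1, system$bonds[, 2] - 1,
                  system$bonds[, 3], system$bonds[, 4]),
    excl_pairs = if (nrow(system$exclusions) > 0) {
      cbind(system$exclusions[, 1] - 1, system$exclusions[, 2] - 1)
    } else matrix(numeric(0), ncol = 2),
    box = system$box_edge, pbc = TRUE, kT = kT,
    ghost_rate = thermostat_rate, t_end = t_end,
    frame_interval = frame_interval, max_events = max_events,
    max_log = event_log, max_ghost_log = ghost_log)

  frames <- lapply(res$frames, function(m) {
    f <- b[, c("chain", "resno", "atom", "aa")]
    f$x <- m[, 1]; f$y <- m[, 2]; f$z <- m[, 3]
    attr(f, "box") <- system$box_edge
    f
  })
  final <- system
  final$beads$x <- res$pos[, 1]; final$beads$y <- res$pos[, 2]
  final$beads$z <- res$pos[, 3]
  final$beads$vx <- res$vel[, 1]; final$beads$vy <- res$vel[, 2]
  final$beads$vz <- res$vel[, 3]
  structure(list(
    frames = frames, times = res$times,
    energy = tibble(time = res$times, kinetic = res$kinetic,
                    potential = res$potential),
    final = final, n_events = res$n_events,
    energy_drift = res$energy_drift,
    events = as_tibble(res$events), ghost_draws = res$ghost_draws,
    t_end = t_end, seed = seed),
    class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory>", length(x$frames), "frames to t =", x$t_end,
      "(", format(x$n_events, big.mark = ","), "events )\n")
  invisible(x)
}
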