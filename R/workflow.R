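#' Configuration for one design round
#'
#' Bundles everything one round of the design loop needs: the scaffold,
#' the hydration cases and aggregation weights to search, the design
#' length, and the simulation screen (temperatures, chain count, box,
#' durations). Defaults are desk-scale; the full-scale study conditions
#' (10000 design steps, 48 chains in a 200 A box) are set by passing the
#' corresponding values.
#'
#' @param scaffold A `scaffold` (default: Class-1, 4 strands per sheet,
#'   7-mers).
#' @param cases List of [case_spec()]s to search.
#' @param lambdas Aggregation weights to search.
#' @param design_steps Monte Carlo steps per search.
#' @param temperatures Screening temperatures, K.
#' @param n_chains Chains per aggregation simulation.
#' @param box_edge Simulation box edge, Angstrom.
#' @param screen_t,extend_t Reduced durations of the preliminary screen
#'   and the extended run at the best temperature.
#' @param thermostat_rate Andersen ghost-collision rate per bead per
#'   reduced time unit; the aggregation screens use a low rate so that
#'   chain diffusion is not suppressed.
#' @param params CG parameter set for the simulations.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `round_config` list.
#' @export
round_config <- function(scaffold = build_cross_beta_scaffold(),
                         cases = list(case_spec(1), case_spec(2)),
                         lambdas = c(2.0, 3.0),
                         design_steps = 1000,
                         temperatures = c(296, 303, 310),
                         n_chains = 12, box_edge = 50,
                         screen_t = 3000, extend_t = 12000,
                         thermostat_rate = 0.02,
                         params = cg_model_params(), seed = 1) {
  stopifnot(length(cases) >= 1, length(lambdas) >= 1,
            length(temperatures) >= 1)
  structure(list(scaffold = scaffold, cases = cases, lambdas = lambdas,
                 design_steps = design_steps, temperatures = temperatures,
                 n_chains = n_chains, box_edge = box_edge,
                 screen_t = screen_t, extend_t = extend_t,
                 thermostat_rate = thermostat_rate,
                 params = params, seed = seed),
            class = "round_config")
}

.classify_candidate <- function(beta, parallel) {
  if (is.na(beta) || beta < 20) return("low fibril content")
  if (!is.na(parallel) && parallel >= 50) return("predominantly parallel")
  "<50% parallel"
}

#' Screen one sequence across temperatures by CG aggregation
#'
#' Runs the preliminary screen at each temperature, picks the temperature
#' with the highest final beta-sheet content, re-runs there for the
#' extended duration, and returns the final-frame metrics.
#'
#' @param sequence Peptide sequence.
#' @param config A [round_config()].
#' @param seed Integer seed.
#' @param criterion H-bond criterion for the metrics.
#' @return One-row tibble: sequence, best_t, beta_content,
#'   parallel_fraction, n_layers, largest_aggregate, classification.
#' @export
screen_sequence <- function(sequence, config, seed = 1,
                            criterion = hbond_criterion()) {
  finals <- purrr::map(seq_along(config$temperatures), function(ti) {
    tK <- config$temperatures[ti]
    sys <- build_cg_system(sequence, config$n_chains, config$box_edge,
                           temperature = tK, params = config$params,
                           seed = seed + 101 * ti)
    tr <- run_dmd(sys, t_end = config$screen_t,
                  thermostat_rate = config$thermostat_rate,
                  frame_interval = config$screen_t / 4,
                  seed = seed + 101 * ti + 1)
    f <- tr$frames[[length(tr$frames)]]
    frame_metrics(f, criterion, time = config$screen_t) |>
      mutate(temperature = tK)
  }) |> bind_rows()
  best_i <- which.max(tidyr::replace_na(finals$beta_content, 0))
  tK <- finals$temperature[best_i]
  sys <- build_cg_system(sequence, config$n_chains, config$box_edge,
                         temperature = tK, params = config$params,
                         seed = seed + 7)
  tr <- run_dmd(sys, t_end = config$extend_t,
                thermostat_rate = config$thermostat_rate,
                frame_interval = config$extend_t / 8,
                seed = seed + 8)
  f <- tr$frames[[length(tr$frames)]]
  m <- frame_metrics(f, criterion, time = config$extend_t)
  tibble(sequence = sequence, best_t = tK,
         beta_content = m$beta_content,
         parallel_fraction = m$parallel_fraction,
         n_layers = m$n_layers, largest_aggregate = m$largest_aggregate,
         classification = .classify_candidate(m$beta_content,
                                              m$parallel_fraction))
}

#' Run one full design round
#'
#' For every (hydration case, lambda) combination: Monte Carlo sequence
#' design on the fixed scaffold, selection of the best-scoring sequence,
#' aggregation screening across the configured temperatures, an extended
#' run at the most fibrillization-prone temperature, and classification
#' of the final structure ("predominantly parallel" at parallel fraction
#' >= 50%, "low fibril content" below 20% beta content).
#'
#' @param config A [round_config()].
#' @param simulate Set `FALSE` to skip the CG simulations (design-only
#'   report).
#' @return A `round_report`: list with `candidates` tibble (case, lambda,
#'   sequence, gamma, dg_binding, lambda_times_p, and when simulated the
#'   screen columns), the config, and the design runs.
#' @export
run_round <- function(config = round_config(), simulate = TRUE) {
  combos <- tidyr::expand_grid(case_i = seq_along(config$cases),
                               lambda = config$lambdas)
  designs <- list()
  rows <- purrr::pmap(combos, function(case_i, lambda) {
    sub_seed <- config$seed + 1000 * case_i + round(100 * lambda)
    dr <- run_design(config$scaffold, case = config$cases[[case_i]],
                     lambda = lambda, n_steps = config$design_steps,
                     seed = sub_seed)
    designs[[length(designs) + 1]] <<- dr
    best <- dr$best[1, ]
    row <- tibble(case = case_i, lambda = lambda,
                  sequence = best$sequence, gamma = best$gamma,
                  dg_binding = best$dg_binding,
                  lambda_times_p = best$lambda_times_p)
    if (simulate) {
      scr <- tryCatch(
        screen_sequence(best$sequence, config, seed = sub_seed),
        error = function(e) {
          tibble(sequence = best$sequence, best_t = NA_real_,
                 beta_content = NA_real_, parallel_fraction = NA_real_,
                 n_layers = NA_integer_, largest_aggregate = NA_integer_,
                 classification = paste0("failed: ", conditionMessage(e)))
        })
      row <- dplyr::bind_cols(row, scr[, setdiff(names(scr), "sequence")])
    }
    row
  })
  candidates <- bind_rows(rows) |> arrange(.data$gamma)
  structure(list(candidates = candidates, config = config,
                 designs = designs),
            class = "round_report")
}

#' @export
print.round_report <- function(x, ...) {
  cat("<round_report>", nrow(x$candidates), "candidates\n")
  print(as.data.frame(x$candidates))
  invisible(x)
}

#' @export
tidy.round_report <- function(x, ...) x$candidates

#' Build the next-round scaffold from a round's best candidate
#'
#' Takes the best-scoring candidate classified as predominantly parallel,
#' and drapes it (as the reference sequence) on an extended, capped
#' Class-1 scaffold of 16 chains (8 strands per sheet), the refined
#' starting geometry for a second round of design.
#'
#' @param report A `round_report` whose candidates were simulated.
#' @param n_strands_per_sheet Strands per sheet of the refined scaffold.
#' @return A capped `scaffold` with attribute `reference_sequence`.
#' @export
refine_scaffold <- function(report, n_strands_per_sheet = 8) {
  cand <- report$candidates
  if (!"classification" %in% names(cand)) {
    abort("report has no simulation classifications")
  }
  ok <- cand[cand$classification == "predominantly parallel", ]
  if (nrow(ok) == 0) abort("no predominantly-parallel candidate to refine from")
  best <- ok[which.min(ok$gamma), ]
  nres <- nchar(best$sequence)
  sc <- build_cross_beta_scaffold(1, n_strands_per_sheet, nres,
                                  report$config$scaffold$d_strand,
                                  report$config$scaffold$d_sheet)
  sc <- cap_termini(sc, TRUE, TRUE)
  attr(sc, "reference_sequence") <- best$sequence
  sc
}

#' Write the package's standard fixture bundle
#'
#' Writes, under `dir`: the eight designed sequences with their scores
#' (`pp_peptides.csv`), ideal Class-1 and Class-8 scaffolds (PDB),
#' synthetic coil / fibril / mixed frames (CSV in the standard frame
#' layout) and synthetic parallel/antiparallel amide-I spectra (CSV).
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the stochastic fixtures.
#' @return Invisibly, a named list of the written paths.
#' @export
make_fixtures <- function(dir = tempfile("fixtures"), seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  paths <- list()
  pp <- pp_peptides()
  paths$peptides <- file.path(dir, "pp_peptides.csv")
  utils::write.csv(pp, paths$peptides, row.names = FALSE)

  sc1 <- build_cross_beta_scaffold(1, 4, 7)
  sc8 <- build_cross_beta_scaffold(8, 4, 7)
  paths$class1 <- file.path(dir, "class1_scaffold.pdb")
  paths$class8 <- file.path(dir, "class8_scaffold.pdb")
  write_pdb(sc1, paths$class1)
  write_pdb(sc8, paths$class8)

  fib <- scaffold_atoms(sc1)
  coil <- coil_frame(8, 7, spacing = 50, seed = seed + 1)
  mixed <- dplyr::bind_rows(
    scaffold_atoms(build_cross_beta_scaffold(1, 2, 7)),
    dplyr::mutate(coil_frame(4, 7, spacing = 60, seed = seed + 2),
                  chain = chartr("ABCD", "EFGH", .data$chain),
                  x = .data$x + 150))
  paths$fibril_frame <- file.path(dir, "frame_fibril.csv")
  paths$coil_frame <- file.path(dir, "frame_coil.csv")
  paths$mixed_frame <- file.path(dir, "frame_mixed.csv")
  utils::write.csv(fib, paths$fibril_frame, row.names = FALSE)
  utils::write.csv(coil, paths$coil_frame, row.names = FALSE)
  utils::write.csv(mixed, paths$mixed_frame, row.names = FALSE)

  spec_dir <- file.path(dir, "spectra")
  dir.create(spec_dir, showWarnings = FALSE)
  for (motif in c("parallel", "antiparallel")) {
    sp <- preset_spectrum(motif, noise_sd = 0.005, seed = seed + 3)
    p <- file.path(spec_dir, paste0(motif, ".csv"))
    utils::write.csv(as.data.frame(sp), p, row.names = FALSE)
    paths[[paste0("spectrum_", motif)]] <- p
  }
  invisible(paths)
}

#' Synthetic random-coil frame
#'
#' Chains built as random walks with a 3.8 A step, placed on a sparse
#' grid so they form no aggregate; a dispersed-coil fixture for the
#' fibril metrics.
#'
#' @param n_chains,n_residues Chain count and length.
#' @param spacing Grid spacing between chain origins, Angstrom.
#' @param seed Seed.
#' @return A frame tibble (atoms N, CA, C, O per residue).
#' @export
coil_frame <- function(n_chains, n_residues, spacing = 50, seed = 1) {
  set.seed(seed)
  ids <- .chain_ids(n_chains)
  rows <- purrr::map(seq_len(n_chains), function(k) {
    origin <- c((k - 1) %% 4, ((k - 1) %/% 4) %% 4, (k - 1) %/% 16) * spacing
    ca <- matrix(0, n_residues, 3)
    ca[1, ] <- origin
    for (r in 2:n_residues) {
      st <- rnorm(3)
      ca[r, ] <- ca[r - 1, ] + 3.8 * st / sqrt(sum(st^2))
    }
    purrr::map_dfr(seq_len(n_residues), function(r) {
      tibble(chain = ids[k], resno = r,
             atom = c("N", "CA", "C", "O"),
             x = ca[r, 1] + c(-1.2, 0, 1.2, 1.2) + rnorm(4, 0, 0.2),
             y = ca[r, 2] + rnorm(4, 0, 0.4),
             z = ca[r, 3] + rnorm(4, 0, 0.4))
    })
  })
  bind_rows(rows)
}
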