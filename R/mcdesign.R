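#' Random sequence under a hydration-case constraint
#'
#' Draws each class slot uniformly from its class members, then shuffles
#' the positions, so composition equals the case by construction.
#'
#' @param case A [case_spec()].
#' @param length Sequence length; must equal the sum of the case counts.
#' @return A sequence string.
#' @export
random_sequence <- function(case, length = 7) {
  if (sum(case) != length) {
    abort(sprintf("case counts sum to %d, not the requested length %d",
                  sum(case), length))
  }
  tab <- residue_classes()
  pools <- split(tab$aa, tab$class)
  draws <- c(
    sample(pools$hydrophobic, case[["n_hydrophobic"]], replace = TRUE),
    sample(pools$polar, case[["n_polar"]], replace = TRUE),
    sample(pools$charged, case[["n_charged"]], replace = TRUE),
    sample(pools$other, case[["n_other"]], replace = TRUE)
  )
  paste(sample(draws), collapse = "")
}

#' Residue-mutation move
#'
#' Picks one position at random and replaces its residue by a uniformly
#' drawn member of the same residue class (possibly the same residue, so
#' the within-class draw stays unbiased). Applied to all chains at once
#' since one sequence is shared across the assembly.
#'
#' @param sequence Current sequence.
#' @return List with `sequence` (new) and `position`.
#' @export
propose_mutation <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  pos <- sample.int(length(aa), 1)
  tab <- residue_classes()
  pool <- tab$aa[tab$class == classify_residue(aa[pos])]
  aa[pos] <- sample(pool, 1)
  list(sequence = paste(aa, collapse = ""), position = pos)
}

#' Residue-exchange move
#'
#' Swaps two randomly chosen positions regardless of residue type; the
#' residue multiset (hence the composition) is unchanged.
#'
#' @param sequence Current sequence (length >= 2).
#' @return List with `sequence` and `positions` (the swapped pair).
#' @export
propose_exchange <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) < 2) abort("exchange needs a sequence of length >= 2")
  pos <- sample.int(length(aa), 2)
  aa[pos] <- aa[rev(pos)]
  list(sequence = paste(aa, collapse = ""), positions = pos)
}

#' Metropolis acceptance on a score difference
#'
#' Accepts with probability `min(1, exp(-delta_gamma / seq_temperature))`.
#'
#' @param delta_gamma Score change of the proposed move.
#' @param seq_temperature Dimensionless Metropolis scale (> 0).
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
metropolis_accept <- function(delta_gamma, seq_temperature = 1.0) {
  if (seq_temperature <= 0) abort("seq_temperature must be > 0")
  if (!is.finite(delta_gamma)) abort("delta_gamma must be finite")
  if (delta_gamma <= 0) return(TRUE)
  runif(1) < exp(-delta_gamma / seq_temperature)
}

#' Monte Carlo sequence design on a fixed scaffold
#'
#' Starts from a random sequence satisfying the hydration case, then
#' performs `n_steps` trial moves (mutation or exchange, 50/50) with
#' Metropolis acceptance on the combined score. The scaffold geometry is
#' fixed, so contacts are precomputed once and each step costs a table
#' lookup sum.
#'
#' @param scaffold A `scaffold`.
#' @param case A [case_spec()] (default Case 1).
#' @param lambda Aggregation-propensity weight (the design rounds use 2.0
#'   and 3.0).
#' @param n_steps Number of evolution steps (default 10000).
#' @param seq_temperature Metropolis scale for sequence moves.
#' @param potential,scale Energy tables.
#' @param top_k How many best sequences to report.
#' @param seed Optional integer seed for full reproducibility.
#' @return A `design_run` object: list with `trace` (tibble: step,
#'   sequence, gamma, dg_binding, lambda_times_p, move, accepted),
#'   `best` (top-k tibble), and the configuration.
#' @export
run_design <- function(scaffold, case = case_spec(1), lambda = 2.0,
                       n_steps = 10000, seq_temperature = 1.0,
                       potential = contact_potential(),
                       scale = aggregation_scale(),
                       top_k = 4, seed = NULL) {
  stopifnot(n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  ctx <- scoring_context(scaffold, potential)
  score1 <- function(s) {
    dg <- binding_free_energy(scaffold, s, potential, context = ctx)
    lp <- lambda * aggregation_propensity(s, scale)
    c(gamma = gamma_score(dg, lp), dg = dg, lp = lp)
  }
  cur <- random_sequence(case, scaffold$n_residues)
  cur_s <- score1(cur)

  step <- integer(n_steps); seqs <- character(n_steps)
  gam <- numeric(n_steps); dgv <- numeric(n_steps); lpv <- numeric(n_steps)
  move <- character(n_steps); acc <- logical(n_steps)
  for (i in seq_len(n_steps)) {
    use_mut <- scaffold$n_residues < 2 || runif(1) < 0.5
    prop <- if (use_mut) propose_mutation(cur) else propose_exchange(cur)
    new_s <- score1(prop$sequence)
    a <- metropolis_accept(new_s[["gamma"]] - cur_s[["gamma"]], seq_temperature)
    if (a) {
      cur <- prop$sequence
      cur_s <- new_s
    }
    step[i] <- i; seqs[i] <- cur
    gam[i] <- cur_s[["gamma"]]; dgv[i] <- cur_s[["dg"]]; lpv[i] <- cur_s[["lp"]]
    move[i] <- if (use_mut) "mutation" else "exchange"
    acc[i] <- a
  }
  trace <- tibble(step = step, sequence = seqs, gamma = gam,
                  dg_binding = dgv, lambda_times_p = lpv,
                  move = move, accepted = acc)
  best <- trace |>
    group_by(.data$sequence) |>
    summarise(gamma = .data$gamma[1], dg_binding = .data$dg_binding[1],
              lambda_times_p = .data$lambda_times_p[1],
              first_step = min(.data$step), .groups = "drop") |>
    arrange(.data$gamma, .data$first_step) |>
    utils::head(top_k)
  structure(list(trace = trace, best = best, case = case, lambda = lambda,
                 seq_temperature = seq_temperature, n_steps = n_steps,
                 seed = seed),
            class = "design_run")
}

#' @export
print.design_run <- function(x, ...) {
  cat("<design_run>", x$n_steps, "steps, lambda =", x$lambda,
      ", acceptance =", round(mean(x$trace$accepted), 3), "\n")
  cat("best sequences:\n")
  print(as.data.frame(x$best))
  invisible(x)
}

#' @export
tidy.design_run <- function(x, ...) x$trace

#' @export
glance.design_run <- function(x, ...) {
  tibble(
    n_steps = x$n_steps,
    lambda = x$lambda,
    acceptance_rate = mean(x$trace$accepted),
    best_sequence = x$best$sequence[1],
    best_gamma = x$best$gamma[1]
  )
}

#' @export
autoplot.design_run <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$step, y = .data$gamma)) +
    geom_line(colour = "grey40") +
    geom_line(aes(y = cummin(.data$gamma)), colour = "firebrick") +
    labs(x = "evolution step", y = "score (gamma)",
         title = "score profile over sequence evolution") +
    theme_minimal()
}
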