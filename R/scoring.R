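#' Residue-pair contact potential
#'
#' Loads a symmetric 20x20 residue-pair contact energy table (score
#' units) together with the contact cutoff and the per-backbone-H-bond
#' energy. The shipped default blends a hydrophobicity/beta-propensity
#' mixing rule with like-residue stacking bonuses and charge rules; it is
#' a residue-level stand-in with the same interface as an atomistic
#' binding free energy, and its absolute values carry no kcal/mol claim.
#'
#' @param file Path to a TSV with header row/column naming the residues;
#'   `NULL` loads the shipped default.
#' @param cutoff Side-chain centroid contact cutoff, Angstrom.
#' @param e_hbond Energy per backbone H-bond of the test chain.
#' @param e_term Scale of the terminal-charge interaction applied when
#'   termini are uncapped.
#' @return A `contact_potential` object.
#' @export
contact_potential <- function(file = NULL, cutoff = 6.5, e_hbond = -0.5,
                              e_term = 0.5) {
  if (is.null(file)) {
    file <- system.file("extdata", "contact_potential.tsv",
                        package = "crossbeta", mustWork = TRUE)
  }
  tab <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    abort("contact potential table must be symmetric")
  }
  if (any(!is.finite(m))) abort("contact potential entries must be finite")
  structure(list(e = m, cutoff = cutoff, e_hbond = e_hbond, e_term = e_term),
            class = "contact_potential")
}

#' Null (all-zero) contact potential
#'
#' @inheritParams contact_potential
#' @return A `contact_potential` with all pair energies zero.
#' @export
null_potential <- function(cutoff = 6.5, e_hbond = 0, e_term = 0) {
  aa <- residue_classes()$aa
  m <- matrix(0, 20, 20, dimnames = list(aa, aa))
  structure(list(e = m, cutoff = cutoff, e_hbond = e_hbond, e_term = e_term),
            class = "contact_potential")
}

#' Per-residue intrinsic aggregation propensity scale
#'
#' @param file Two-column TSV (`aa`, `value`); `NULL` loads the shipped
#'   hydrophobicity/beta-propensity blend.
#' @return Named numeric vector of 20 values.
#' @export
aggregation_scale <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "aggregation_scale.tsv",
                        package = "crossbeta", mustWork = TRUE)
  }
  tab <- utils::read.delim(file)
  v <- setNames(tab$value, tab$aa)
  if (length(v) != 20 || any(!is.finite(v))) {
    abort("aggregation scale must have 20 finite entries")
  }
  v
}

#' Intrinsic aggregation propensity of a sequence
#'
#' Additive per-residue sum under the configured scale.
#'
#' @param sequence Peptide sequence.
#' @param scale Named numeric scale from [aggregation_scale()].
#' @return Dimensionless propensity.
#' @export
aggregation_propensity <- function(sequence, scale = aggregation_scale()) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(scale))
  if (length(bad) > 0) abort(paste0("invalid residue(s): ",
                                    paste(unique(bad), collapse = ", ")))
  sum(scale[aa])
}

# geometric context for scoring a sequence on a fixed scaffold: the
# residue-residue contact list of the designated test chain (the chain
# with the most neighbours) and its backbone H-bond count. Side-chain
# centroids are proxied by CA positions on backbone-only scaffolds.
scoring_context <- function(scaffold, potential = contact_potential()) {
  at <- scaffold$atoms
  ids <- scaffold$chains$chain
  cas <- lapply(ids, function(id) .chain_ca(scaffold, id))
  names(cas) <- ids
  # choose the test chain: most residue contacts with other chains
  contact_count <- setNames(integer(length(ids)), ids)
  pair_list <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      a <- cas[[i]]; b <- cas[[j]]
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      hit <- which(d2 <= potential$cutoff^2, arr.ind = TRUE)
      contact_count[i] <- contact_count[i] + nrow(hit)
      pair_list[[paste(i, j)]] <- hit
    }
  }
  test <- which.max(contact_count)
  contacts <- NULL
  for (j in seq_along(ids)) {
    if (j == test) next
    hit <- pair_list[[paste(test, j)]]
    if (length(hit) > 0) contacts <- rbind(contacts, hit)
  }
  hb <- backbone_hbonds(at, hbond_criterion())
  test_id <- ids[test]
  n_hb <- sum(hb$donor_chain == test_id | hb$acceptor_chain == test_id)
  list(
    contacts = contacts,  # matrix: test-chain residue, partner residue
    n_hbonds = n_hb,
    n_residues = scaffold$n_residues,
    capped_n = scaffold$chains$capped_n[test],
    capped_c = scaffold$chains$capped_c[test]
  )
}

.res_charge <- function(aa) {
  ifelse(aa %in% c("K", "R"), 1, ifelse(aa %in% c("D", "E"), -1, 0))
}

#' Binding free energy of a sequence draped on a scaffold
#'
#' Sums the pair contact energies between the designated test chain (the
#' chain with the most neighbours) and its neighbouring chains for all
#' residue pairs within the contact cutoff, adds the constant backbone
#' H-bond term per H-bond of the test chain, and - when termini are
#' uncapped - the terminal-charge interactions of the free N(+)/C(-)
#' termini with charged contact partners.
#'
#' @param scaffold A `scaffold` (one sequence is draped on every chain).
#' @param sequence Peptide sequence of length `scaffold$n_residues`.
#' @param potential A [contact_potential()].
#' @param context Optional precomputed [scoring_context] (for repeated
#'   evaluation during design).
#' @return Energy in score units.
#' @export
binding_free_energy <- function(scaffold, sequence,
                                potential = contact_potential(),
                                context = NULL) {
  aa <- strsplit(sequence, "")[[1]]
  if (!is.null(scaffold) && length(aa) != scaffold$n_residues) {
    abort(sprintf("sequence length %d does not match scaffold residues %d",
                  length(aa), scaffold$n_residues))
  }
  if (is.null(context)) context <- scoring_context(scaffold, potential)
  if (is.null(context$contacts) || nrow(context$contacts) == 0) {
    pair_e <- 0
    term_e <- 0
  } else {
    ci <- context$contacts[, 1]
    cj <- context$contacts[, 2]
    pair_e <- sum(potential$e[cbind(aa[ci], aa[cj])])
    # terminal charges when uncapped: +1 at residue 1 (N-term), -1 at the
    # C-terminal residue, interacting with charged contact partners
    q <- .res_charge(aa)
    qn <- if (context$capped_n) 0 else 1
    qc <- if (context$capped_c) 0 else -1
    n_res <- context$n_residues
    term_e <- potential$e_term *
      (qn * sum(q[cj][ci == 1]) + qc * sum(q[cj][ci == n_res]) +
         qn * sum(q[ci][cj == 1]) + qc * sum(q[ci][cj == n_res]))
  }
  pair_e + term_e + potential$e_hbond * context$n_hbonds
}

#' Combined design score
#'
#' The design objective: binding free energy minus the weighted intrinsic
#' aggregation propensity, `gamma = dg_binding - lambda * p_aggregation`.
#' Lower is better.
#'
#' @param dg_binding Binding free energy (score units).
#' @param lambda_times_p The product `lambda * p_aggregation`.
#' @return `dg_binding - lambda_times_p`.
#' @export
#' @examples
#' gamma_score(-27.23, 3.70)   # -30.93
#' gamma_score(-12.37, -0.18)  # -12.19
gamma_score <- function(dg_binding, lambda_times_p) {
  if (!all(is.finite(c(dg_binding, lambda_times_p)))) {
    abort("gamma_score requires finite inputs")
  }
  dg_binding - lambda_times_p
}

#' Full score breakdown for a sequence on a scaffold
#'
#' @inheritParams binding_free_energy
#' @param scale Aggregation scale.
#' @param lambda Weighting factor of the aggregation term.
#' @return One-row tibble: sequence, gamma, dg_binding, lambda,
#'   p_aggregation, lambda_times_p.
#' @export
score_sequence <- function(scaffold, sequence,
                           potential = contact_potential(),
                           scale = aggregation_scale(), lambda = 2.0,
                           context = NULL) {
  dg <- binding_free_energy(scaffold, sequence, potential, context)
  p <- aggregation_propensity(sequence, scale)
  lp <- lambda * p
  tibble(sequence = sequence, gamma = gamma_score(dg, lp), dg_binding = dg,
         lambda = lambda, p_aggregation = p, lambda_times_p = lp)
}
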