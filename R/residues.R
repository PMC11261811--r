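#' Four-class typing of the twenty natural amino acids
#'
#' The design algorithm constrains sequence composition in terms of four
#' residue classes: hydrophobic (Leu, Val, Ile, Ala, Met, Phe, Tyr, Trp,
#' Gly), polar (Ser, Thr, His, Asn, Gln), charged (Arg, Lys, Asp, Glu) and
#' other (Cys, Pro).
#'
#' @return A tibble with columns `aa` (one-letter code) and `class`
#'   (one of `"hydrophobic"`, `"polar"`, `"charged"`, `"other"`).
#' @export
#' @examples
#' residue_classes()
residue_classes <- function() {
  tibble(
    aa = c("L", "V", "I", "A", "M", "F", "Y", "W", "G",
           "S", "T", "H", "N", "Q",
           "R", "K", "D", "E",
           "C", "P"),
    class = rep(c("hydrophobic", "polar", "charged", "other"),
                times = c(9L, 5L, 4L, 2L))
  )
}

.class_lookup <- function() {
  tab <- residue_classes()
  setNames(tab$class, tab$aa)
}

#' Classify a residue into its hydration class
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @return Character vector of classes.
#' @export
#' @examples
#' classify_residue(c("L", "P", "D"))
classify_residue <- function(aa) {
  lut <- .class_lookup()
  bad <- setdiff(aa, names(lut))
  if (length(bad) > 0) {
    abort(paste0("unknown amino-acid code(s): ", paste(unique(bad), collapse = ", ")))
  }
  unname(lut[aa])
}

#' Residue-class composition of a sequence
#'
#' Counts the hydrophobic, polar, charged and other residues of a peptide
#' sequence; the counts are what a hydration-case constraint fixes during
#' design.
#'
#' @param sequence A single peptide sequence (one-letter codes).
#' @return A tibble with one row and columns `n_hydrophobic`, `n_polar`,
#'   `n_charged`, `n_other`.
#' @export
#' @examples
#' composition("GDIKIVV")
composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  aa <- strsplit(sequence, "")[[1]]
  cls <- if (length(aa) > 0) classify_residue(aa) else character()
  tibble(
    n_hydrophobic = sum(cls == "hydrophobic"),
    n_polar       = sum(cls == "polar"),
    n_charged     = sum(cls == "charged"),
    n_other       = sum(cls == "other")
  )
}

#' Hydration-case composition constraint
#'
#' A case specification fixes how many residues of each class a designed
#' peptide contains. The two cases used for the 7-mer designs are
#' `case_spec(1)` (5 hydrophobic, 0 polar, 2 charged, 0 other) and
#' `case_spec(2)` (5 hydrophobic, 2 polar, 0 charged, 0 other).
#'
#' @param case Either `1` or `2` for the preset cases, or omit and give
#'   explicit counts.
#' @param n_hydrophobic,n_polar,n_charged,n_other Explicit class counts.
#' @return A `case_spec` object (named integer vector).
#' @export
#' @examples
#' case_spec(1)
#' case_spec(n_hydrophobic = 7, n_polar = 0, n_charged = 0, n_other = 0)
case_spec <- function(case = NULL, n_hydrophobic = 0, n_polar = 0,
                      n_charged = 0, n_other = 0) {
  if (!is.null(case)) {
    if (case == 1) {
      n_hydrophobic <- 5; n_polar <- 0; n_charged <- 2; n_other <- 0
    } else if (case == 2) {
      n_hydrophobic <- 5; n_polar <- 2; n_charged <- 0; n_other <- 0
    } else {
      abort("preset `case` must be 1 or 2")
    }
  }
  counts <- c(n_hydrophobic = as.integer(n_hydrophobic),
              n_polar = as.integer(n_polar),
              n_charged = as.integer(n_charged),
              n_other = as.integer(n_other))
  if (any(counts < 0)) abort("case counts must be non-negative")
  structure(counts, class = "case_spec")
}

#' @export
print.case_spec <- function(x, ...) {
  cat("<case_spec> hydrophobic:", x[["n_hydrophobic"]],
      " polar:", x[["n_polar"]],
      " charged:", x[["n_charged"]],
      " other:", x[["n_other"]], "\n")
  invisible(x)
}

#' Does a sequence satisfy a hydration case?
#'
#' @param sequence Peptide sequence.
#' @param case A [case_spec()].
#' @return `TRUE` or `FALSE`.
#' @export
satisfies_case <- function(sequence, case) {
  cmp <- composition(sequence)
  all(c(cmp$n_hydrophobic, cmp$n_polar, cmp$n_charged, cmp$n_other) ==
        c(case[["n_hydrophobic"]], case[["n_polar"]],
          case[["n_charged"]], case[["n_other"]]))
}

#' The eight designed 7-mer peptides
#'
#' The two design rounds produced eight 7-mer candidates (PP1-PP8) with
#' their design scores: the combined score `gamma`, its binding
#' free-energy component `dg_binding` and the weighted aggregation
#' propensity `lambda_p` (all in score units), together with the hydration
#' case each was designed under and the fibril classification observed in
#' coarse-grained aggregation simulations.
#'
#' @return A tibble with columns `peptide`, `case`, `sequence`, `gamma`,
#'   `dg_binding`, `lambda_p`, `round`, `dmd_summary`.
#' @export
#' @examples
#' pp_peptides()
pp_peptides <- function() {
  tibble(
    peptide = paste0("PP", 1:8),
    case = c(1L, 2L, 1L, 1L, 1L, 1L, 2L, 2L),
    sequence = c("GDIKIVV", "GNIVTFV", "GAIDWVK", "GGIDWKI",
                 "ADKVMFV", "GDFVKFV", "GNYTMFI", "ANMTVFV"),
    gamma = c(-12.19, -17.25, -8.28, -6.55, -23.50, -26.61, -30.93, -30.15),
    dg_binding = c(-12.37, -12.39, -9.29, -6.45, -23.68, -25.96, -27.23, -26.99),
    lambda_p = c(-0.18, 4.85, -1.01, 0.10, -0.17, 0.64, 3.70, 3.16),
    round = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
    dmd_summary = c(
      "Two-layer fibril, ~77% parallel beta-sheet content",
      "Two-layer fibril, ~100% parallel beta-sheet content",
      "Multi-layer fibril, ~100% parallel beta-sheet content",
      "Two-layer fibril, ~46% parallel beta-sheet content",
      "Multilayer fibril, ~87% parallel beta-sheet content",
      "Low fibril content",
      "Two-layer fibrils, ~91% parallel beta-sheet content",
      "Two-layer fibril, ~47% parallel beta-sheet content"
    )
  )
}
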