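# Generates the shipped parameter tables under inst/extdata/.
# Run from the package root: Rscript data-raw/make_tables.R
#
# The residue-level contact potential and aggregation scale are the
# package's own defaults: a hydrophobicity / beta-propensity blend with
# like-residue stacking and charge rules. They are score-unit tables, not
# a reproduction of any published atomistic force field.

aa <- c("A","R","N","D","C","Q","E","G","H","I",
        "L","K","M","F","P","S","T","W","Y","V")

# Kyte-Doolittle hydropathy
kd <- c(A=1.8, R=-4.5, N=-3.5, D=-3.5, C=2.5, Q=-3.5, E=-3.5, G=-0.4,
        H=-3.2, I=4.5, L=3.8, K=-3.9, M=1.9, F=2.8, P=-1.6, S=-0.8,
        T=-0.7, W=-0.9, Y=-1.3, V=4.2)
# Chou-Fasman beta-sheet propensity
pb <- c(A=0.83, R=0.93, N=0.89, D=0.54, C=1.19, Q=1.10, E=0.37, G=0.75,
        H=0.87, I=1.60, L=1.30, K=0.74, M=1.05, F=1.38, P=0.55, S=0.75,
        T=1.19, W=1.37, Y=1.47, V=1.70)

# intrinsic aggregation propensity: additive per-residue scale
p_agg <- round(0.1 * kd + 0.5 * (pb - 1), 3)
write.table(data.frame(aa = aa, value = p_agg[aa]),
            "inst/extdata/aggregation_scale.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# contact potential: pairwise residue interaction energies (score units).
# In-register stacking of identical residues (hydrophobic ladders, polar
# Asn/Gln-type ladders, aromatic stacking) dominates; generic
# hydrophobic mixing is kept weak so that out-of-register or reversed
# strand arrangements bind much more loosely.
hydrophobic <- c("L","V","I","A","M","F","Y","W","G")
polar <- c("S","T","H","N","Q")
pos <- c("R","K"); neg <- c("D","E")
aromatic <- c("F","Y","W")
stick <- pmax(p_agg + 0.3, 0)

e <- matrix(0, 20, 20, dimnames = list(aa, aa))
for (a in aa) for (b in aa) {
  v <- -0.5 * sqrt(stick[a] * stick[b])
  if (a %in% aromatic && b %in% aromatic) v <- v - 0.3
  if (a == b && (a %in% hydrophobic || a %in% polar)) v <- v - 1.5 - stick[a]
  if ((a %in% pos && b %in% neg) || (a %in% neg && b %in% pos)) v <- v - 0.6
  if ((a %in% pos && b %in% pos) || (a %in% neg && b %in% neg)) v <- v + 1.0
  e[a, b] <- round(v, 3)
}
stopifnot(isSymmetric(e))
write.table(cbind(data.frame(aa = aa), as.data.frame(e)),
            "inst/extdata/contact_potential.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# coarse-grained bead parameters: per-residue side-chain sphere diameter
# (A), mass (amu) and CA-R bond length (A). Backbone beads NH/CA/CO are
# shared. Side-chain diameters and bond lengths are physically reasonable
# placeholder values (flagged); masses are residue mass minus the 56.04
# amu backbone.
sc_diam <- c(A=3.1, R=4.7, N=3.9, D=3.8, C=3.6, Q=4.2, E=4.1, G=2.0,
             H=4.4, I=4.4, L=4.4, K=4.4, M=4.4, F=4.7, P=3.7, S=3.3,
             T=3.7, W=5.1, Y=4.8, V=4.0)
sc_mass <- c(A=15.03, R=100.14, N=58.06, D=59.04, C=47.10, Q=72.09,
             E=73.07, G=1.01, H=81.10, I=57.11, L=57.11, K=72.13,
             M=75.15, F=91.13, P=41.07, S=31.03, T=45.06, W=130.17,
             Y=107.13, V=43.09)
ca_r <- c(A=1.5, R=4.1, N=2.5, D=2.5, C=2.1, Q=3.0, E=3.0, G=1.1,
          H=3.1, I=2.3, L=2.6, K=3.5, M=3.0, F=3.4, P=1.9, S=1.9,
          T=1.9, W=3.9, Y=3.9, V=2.0)
write.table(data.frame(aa = aa, sc_diameter = sc_diam[aa],
                       sc_mass = sc_mass[aa], ca_r_bond = ca_r[aa]),
            "inst/extdata/cg_beads.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
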