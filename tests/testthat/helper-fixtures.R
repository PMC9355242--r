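# Shared fixtures, all built in code.

# Minimal hand-written PDB text: three atoms with exactly known fields.
minimal_pdb_text <- function() {
  paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END", sep = "\n")
}

# Two-model PDB (NMR-style); model 2 has shifted coordinates.
two_model_pdb_text <- function() {
  paste(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       9.000   9.000   9.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       9.000   9.000  10.458  1.00  0.00           C",
    "ENDMDL",
    "END", sep = "\n")
}

# PDB with alternate locations: CA has B (occ 0.7) after A (occ 0.3),
# CB has equal-occupancy tie (first should win).
altloc_pdb_text <- function() {
  paste(
    "ATOM      1  N   LEU A   5       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA ALEU A   5       1.000   0.000   0.000  0.30  0.00           C",
    "ATOM      3  CA BLEU A   5       2.000   0.000   0.000  0.70  0.00           C",
    "ATOM      4  CB ALEU A   5       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  CB BLEU A   5       4.000   0.000   0.000  0.50  0.00           C",
    "HETATM    6  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END", sep = "\n")
}

# A leucine-bearing helix: poly-Ala helix with one residue renamed LEU and
# given a fake side chain beyond CB, to exercise substitute_to_cys pruning.
leu_structure <- function() {
  s <- make_toy_structure("exposed-helix")
  a <- s$atoms
  a$resname[a$resno == 8] <- "LEU"
  cb <- as.numeric(a[a$resno == 8 & a$name == "CB", c("x", "y", "z")])
  extra <- data.frame(
    serial = max(a$serial) + 1:3,
    name = c("CG", "CD1", "CD2"), resname = "LEU", chain = "A", resno = 8,
    x = cb[1] + c(0.8, 1.6, 1.6), y = cb[2] + c(1.2, 2.0, 0.4),
    z = cb[3] + c(0.4, 0.8, 1.6), element = "C", occ = 1,
    stringsAsFactors = FALSE)
  spin_structure(rbind(a, extra), id = "toy-leu-helix")
}

# Ensemble with exactly one conformer whose paramagnetic center is at `mid`.
fake_single_conformer_ensemble <- function(mid, site = list(chain = "A", resno = 1)) {
  conf <- matrix(rep(mid, each = 2), 2, 3)
  rownames(conf) <- c("N1", "O1")
  structure(list(site = site, conformers = list(conf),
                 midpoints = matrix(mid, 1, 3), n_requested = 1L,
                 n_attempted = 1L, seed = 0L, clash_tol = 2.5),
            class = "rotamer_ensemble")
}

# Independent Simpson-rule oracle for the dipolar kernel x-integral.
kernel_quadrature <- function(r_nm, t_us, n_nodes = 20001) {
  x <- seq(0, 1, length.out = n_nodes)
  w <- 2 * pi * 52.04 / r_nm^3
  fx <- cos((3 * x^2 - 1) * w * t_us)
  h <- x[2] - x[1]
  idx <- seq_len(n_nodes)
  coef <- ifelse(idx %% 2 == 0, 4, 2)
  coef[c(1, n_nodes)] <- 1
  sum(coef * fx) * h / 3
}
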