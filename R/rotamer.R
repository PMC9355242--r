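# label_ensemble: accessible-volume modeling of the MTSL/R1 nitroxide side
# chain. Conformers are built by attaching an idealized R1 template at CB,
# drawing the five linker dihedrals uniformly and rejecting sterically clashing
# conformers (mtsslWizard-style accessible volume, not an energy-weighted
# rotamer library). The paramagnetic center is the N-O bond midpoint.

#' Internal-coordinate template of the R1 (MTSL-cysteine) side chain
#'
#' Each row places one atom from three previously placed reference atoms via
#' bond length (Angstrom), bond angle and dihedral (degrees). Dihedral entries
#' `chi1` ... `chi5` are the five sampled rotations; numeric entries are rigid.
#' Ring geometry is an idealized, near-planar
#' 2,2,5,5-tetramethyl-pyrroline-1-oxyl fragment with standard bond lengths.
#'
#' @return data.frame with columns `atom`, `ref1`, `ref2`, `ref3`, `bond`,
#'   `angle`, `dihedral`.
#' @export
r1_template_geometry <- function() {
  data.frame(
    atom     = c("SG",  "SD",  "CE",  "C3",  "C2",   "C4",     "N1",  "C5",  "O1",  "C2A", "C2B", "C5A", "C5B"),
    ref1     = c("N",   "CA",  "CB",  "SG",  "SD",   "SD",     "CE",  "C3",  "C3",  "CE",  "CE",  "C2",  "C2"),
    ref2     = c("CA",  "CB",  "SG",  "SD",  "CE",   "CE",     "C3",  "C2",  "C2",  "C3",  "C3",  "N1",  "N1"),
    ref3     = c("CB",  "SG",  "SD",  "CE",  "C3",   "C3",     "C2",  "N1",  "N1",  "C2",  "C2",  "C5",  "C5"),
    bond     = c(1.81,  2.04,  1.81,  1.50,  1.51,   1.33,     1.48,  1.48,  1.28,  1.52,  1.52,  1.52,  1.52),
    angle    = c(114.0, 104.0, 104.0, 114.0, 126.0,  126.0,    101.0, 112.0, 123.0, 111.0, 111.0, 111.0, 111.0),
    dihedral = c("chi1", "chi2", "chi3", "chi4", "chi5", "chi5+180", "180", "0", "180", "60", "-60", "120", "-120"),
    stringsAsFactors = FALSE)
}

# Build one R1 conformer from backbone anchors and five dihedrals (degrees).
# Returns a 13 x 3 coordinate matrix with rownames = template atom names.
build_r1_conformer <- function(n_xyz, ca_xyz, cb_xyz, chi) {
  tmpl <- r1_template_geometry()
  pos <- list(N = n_xyz, CA = ca_xyz, CB = cb_xyz)
  for (i in seq_len(nrow(tmpl))) {
    dh <- tmpl$dihedral[i]
    val <- switch(dh,
      "chi1" = chi[1], "chi2" = chi[2], "chi3" = chi[3],
      "chi4" = chi[4], "chi5" = chi[5], "chi5+180" = chi[5] + 180,
      as.numeric(dh))
    pos[[tmpl$atom[i]]] <- place_atom(pos[[tmpl$ref1[i]]], pos[[tmpl$ref2[i]]],
                                      pos[[tmpl$ref3[i]]], tmpl$bond[i],
                                      tmpl$angle[i], val)
  }
  m <- do.call(rbind, pos[tmpl$atom])
  rownames(m) <- tmpl$atom
  m
}

# Evaluate code with a temporarily seeded RNG, restoring global state after.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate an accessible-volume ensemble of MTSL label conformers
#'
#' Attaches the idealized R1 template at the CB of the labeling site (the
#' residue is substituted to Cys first if needed), samples the five side-chain
#' dihedrals uniformly on \[0, 360) degrees and keeps conformers whose heavy
#' atoms stay at least `clash_tol` Angstrom away from every protein heavy atom
#' outside the labeled residue. Sampling is a fixed-length draw per attempt
#' from a seeded stream, so for a given seed the accepted conformers of a
#' smaller request are a prefix of a larger one.
#'
#' @param structure a [spin_structure()].
#' @param site labeling site, `"chain:resno"` (e.g. `"A:195"`).
#' @param n number of conformers requested (default 200, the conventional
#'   ensemble size for MTSL distance prediction).
#' @param seed integer seed; the ensemble is a pure function of
#'   (structure, site, n, seed).
#' @param clash_tol steric rejection threshold in Angstrom (default 2.5,
#'   loose-tolerance accessible-volume regime).
#' @param attempt_budget maximum number of sampled conformers, as a multiple of
#'   `n` (default 50).
#' @return object of class `rotamer_ensemble`: fields `site`, `conformers`
#'   (list of 13 x 3 coordinate matrices), `midpoints` (n x 3 matrix of N-O
#'   bond midpoints, the paramagnetic-center positions), `n_requested`,
#'   `n_attempted`, `seed`.
#' @export
generate_ensemble <- function(structure, site, n = 200, seed = 1,
                              clash_tol = 2.5, attempt_budget = 50) {
  stopifnot(n >= 1)
  s <- parse_address(site)
  res <- residue_atoms(structure, s$chain, s$resno)
  if (nrow(res) == 0L)
    stop("labeling site ", s$chain, ":", s$resno, " not found in '", structure$id, "'")
  if (!identical(res$resname[1], "CYS"))
    structure <- substitute_to_cys(structure, s$chain, s$resno)
  anchors <- lapply(c("N", "CA", "CB"), function(nm) atom_xyz(structure, s$chain, s$resno, nm))
  names(anchors) <- c("N", "CA", "CB")
  cb <- anchors$CB

  env <- heavy_atoms(structure)
  env <- env[!(env$chain == s$chain & env$resno == s$resno), , drop = FALSE]
  env_xyz <- as.matrix(env[, c("x", "y", "z")])
  if (nrow(env_xyz)) {
    reach <- 10.5 + clash_tol  # maximal template extension from CB plus tolerance
    near <- rowSums(sweep(env_xyz, 2, cb)^2) <= reach^2
    env_xyz <- env_xyz[near, , drop = FALSE]
  }

  budget <- attempt_budget * n
  conformers <- vector("list", n)
  midpoints <- matrix(NA_real_, n, 3)
  accepted <- 0L
  attempted <- 0L
  with_local_seed(seed, {
    while (accepted < n && attempted < budget) {
      chi <- stats::runif(5, 0, 360)
      attempted <- attempted + 1L
      conf <- build_r1_conformer(anchors$N, anchors$CA, anchors$CB, chi)
      if (nrow(env_xyz)) {
        if (min(cross_dist(conf, env_xyz)) < clash_tol) next
      }
      accepted <- accepted + 1L
      conformers[[accepted]] <- conf
      midpoints[accepted, ] <- (conf["N1", ] + conf["O1", ]) / 2
    }
  })
  if (accepted == 0L)
    stop("site ", s$chain, ":", s$resno, " appears buried: no clash-free label ",
         "conformer in ", budget, " attempts (clash_tol = ", clash_tol, " A)")
  structure(list(
    site = list(chain = s$chain, resno = s$resno),
    conformers = conformers[seq_len(accepted)],
    midpoints = midpoints[seq_len(accepted), , drop = FALSE],
    n_requested = as.integer(n), n_attempted = attempted, seed = seed,
    clash_tol = clash_tol), class = "rotamer_ensemble")
}

#' @export
print.rotamer_ensemble <- function(x, ...) {
  cat("<rotamer_ensemble> site ", x$site$chain, ":", x$site$resno, "\n", sep = "")
  cat("  conformers: ", length(x$conformers), " / ", x$n_requested,
      " requested (", x$n_attempted, " attempted, seed ", x$seed, ")\n", sep = "")
  mp <- mean_label_position(x)
  cat("  mean paramagnetic center: (", paste(round(mp, 2), collapse = ", "), ") A\n", sep = "")
  invisible(x)
}

#' Mean paramagnetic-center position of an ensemble
#'
#' Unweighted mean of the N-O bond midpoints over all accepted conformers —
#' the "average position of the paramagnetic center" used for label-to-nucleus
#' distance prediction.
#'
#' @param ensemble a [generate_ensemble()] result.
#' @return numeric 3-vector (Angstrom).
#' @export
mean_label_position <- function(ensemble) {
  if (!length(ensemble$conformers)) stop("empty ensemble")
  colMeans(ensemble$midpoints)
}

#' Distances from the mean label position to selected atoms
#'
#' @param ensemble a [generate_ensemble()] result.
#' @param structure the [spin_structure()] holding the target nuclei.
#' @param atom_selector `"RESNAME:ATOM"` pattern, e.g. `"ILE:CD1"` for
#'   isoleucine delta-1 carbons; either side may be `"*"`.
#' @return data.frame with columns `chain`, `resno`, `resname`, `name`,
#'   `residue_id` (e.g. `"I114"`), `distance_A`, sorted by residue number.
#' @export
label_to_atom_distances <- function(ensemble, structure, atom_selector = "ILE:CD1") {
  parts <- strsplit(atom_selector, ":")[[1]]
  if (length(parts) != 2L) stop("atom_selector must be 'RESNAME:ATOMNAME'")
  a <- structure$atoms
  sel <- (parts[1] == "*" | a$resname == parts[1]) &
         (parts[2] == "*" | a$name == parts[2])
  if (!any(sel)) stop("selector '", atom_selector, "' matches no atom in '",
                      structure$id, "'")
  a <- a[sel, , drop = FALSE]
  mp <- mean_label_position(ensemble)
  d <- sqrt(rowSums(sweep(as.matrix(a[, c("x", "y", "z")]), 2, mp)^2))
  out <- data.frame(chain = a$chain, resno = a$resno, resname = a$resname,
                    name = a$name,
                    residue_id = paste0(substr(a$resname, 1, 1), a$resno),
                    distance_A = d, stringsAsFactors = FALSE)
  out[order(out$resno), , drop = FALSE]
}

#' Inter-label distance distribution of two ensembles
#'
#' Normalized, Gaussian-smoothed histogram of all pairwise paramagnetic-center
#' distances between the conformers of two ensembles — the structure-based
#' prediction compared against DEER-derived distributions.
#'
#' @param ens_a,ens_b [generate_ensemble()] results.
#' @param r_grid uniform distance grid in nm (default 1-10 nm, 0.02 nm step).
#' @param smooth_sd Gaussian kernel width in nm (default 0.05).
#' @return a [distance_distribution()].
#' @export
interlabel_distribution <- function(ens_a, ens_b,
                                    r_grid = seq(1, 10, by = 0.02),
                                    smooth_sd = 0.05) {
  d <- as.vector(cross_dist(ens_a$midpoints, ens_b$midpoints)) / 10  # A -> nm
  if (min(d) < min(r_grid) || max(d) > max(r_grid))
    stop(sprintf(
      "r_grid [%.2f, %.2f] nm does not span the observed distances [%.2f, %.2f] nm",
      min(r_grid), max(r_grid), min(d), max(d)))
  dr <- mean(diff(r_grid))
  idx <- pmin(pmax(round((d - r_grid[1]) / dr) + 1L, 1L), length(r_grid))
  counts <- tabulate(idx, nbins = length(r_grid))
  half <- ceiling(5 * smooth_sd / dr)
  kern <- stats::dnorm(seq(-half, half) * dr, sd = smooth_sd)
  sm <- stats::filter(c(rep(0, half), counts, rep(0, half)), kern, sides = 2)
  sm <- as.numeric(sm[(half + 1):(half + length(counts))])
  sm[is.na(sm)] <- 0
  distance_distribution(r_grid, sm,
    metadata = list(smooth_sd_nm = smooth_sd, n_pairs = length(d),
                    site_a = paste0(ens_a$site$chain, ":", ens_a$site$resno),
                    site_b = paste0(ens_b$site$chain, ":", ens_b$site$resno)))
}
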