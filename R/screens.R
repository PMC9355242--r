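# screens: structure-based interpretation utilities — disulfide Cys-pair
# feasibility in the resting (crystal) conformation, and native-MS
# peptide-bound-fraction arithmetic with decoy correction.

#' Assess disulfide feasibility of an engineered Cys pair
#'
#' Computes the CB-CB distance between two residues and compares it to a
#' standard disulfide engineering criterion (default 5.5 A). Pairs that
#' crosslink in vivo despite being infeasible in the resting structure report
#' conformational changes that transiently bring the sites together.
#'
#' @param structure a [spin_structure()].
#' @param a,b residue addresses `"chain:resno"`.
#' @param threshold feasibility cutoff on the CB-CB distance in A
#'   (default 5.5).
#' @return list of class `cys_pair_assessment` with `pair`, `cb_distance`,
#'   `feasible_resting`, `interpretation`.
#' @export
assess_cys_pair <- function(structure, a, b, threshold = 5.5) {
  pa <- parse_address(a); pb <- parse_address(b)
  for (p in list(pa, pb)) {
    res <- residue_atoms(structure, p$chain, p$resno)
    if (nrow(res) == 0L) stop("residue ", p$chain, ":", p$resno, " not found")
    if (!"CB" %in% res$name)
      stop("residue ", p$chain, ":", p$resno,
           " has no CB atom (glycine?); cannot assess a Cys pair there")
  }
  d <- atom_distance(structure,
                     paste(pa$chain, pa$resno, "CB", sep = ":"),
                     paste(pb$chain, pb$resno, "CB", sep = ":"))
  feas <- d <= threshold
  structure(list(
    pair = c(paste0(pa$chain, ":", pa$resno), paste0(pb$chain, ":", pb$resno)),
    cb_distance = d, threshold = threshold, feasible_resting = feas,
    interpretation = if (feas) "feasible"
                     else "requires-conformational-change"),
    class = "cys_pair_assessment")
}

#' @export
print.cys_pair_assessment <- function(x, ...) {
  cat("<cys_pair_assessment> ", x$pair[1], " + ", x$pair[2], "\n", sep = "")
  cat(sprintf("  CB-CB: %.2f A (threshold %.2f A) -> %s\n",
              x$cb_distance, x$threshold, x$interpretation))
  invisible(x)
}

#' Peptide-bound fraction from native-MS peak intensities
#'
#' bound_fraction = sum of intensities of species with >= 1 peptide bound over
#' the total; the bound fraction measured on a decoy protein is subtracted to
#' correct for non-specific binding (reported both raw and clipped at 0).
#'
#' @param intensities named numeric vector of per-species intensities; names
#'   are the number of bound peptides (`"0"`, `"1"`, `"2"`, ...). An unnamed
#'   vector is taken as 0, 1, 2, ... bound.
#' @param decoy_fraction bound fraction of the decoy protein (default 0).
#' @return list of class `binding_summary` with `intensities`,
#'   `bound_fraction`, `decoy_corrected_fraction` (clipped at 0) and
#'   `decoy_corrected_raw`.
#' @export
bound_fraction <- function(intensities, decoy_fraction = 0) {
  if (any(intensities < 0)) stop("intensities must be non-negative")
  tot <- sum(intensities)
  if (tot <= 0) stop("all species intensities are zero")
  k <- if (is.null(names(intensities))) seq_along(intensities) - 1L
       else as.integer(names(intensities))
  bf <- sum(intensities[k >= 1]) / tot
  raw <- bf - decoy_fraction
  structure(list(intensities = intensities, bound_fraction = bf,
                 decoy_corrected_fraction = max(0, raw),
                 decoy_corrected_raw = raw),
            class = "binding_summary")
}

#' @export
print.binding_summary <- function(x, ...) {
  cat(sprintf("<binding_summary> bound %.3f; decoy-corrected %.3f (raw %.3f)\n",
              x$bound_fraction, x$decoy_corrected_fraction, x$decoy_corrected_raw))
  invisible(x)
}

#' Reported in vivo disulfide-crosslinking outcomes for FhaC Cys pairs
#'
#' Experimental input data (not computed output): outcomes of in vivo
#' spontaneous S-S bond formation between engineered Cys pairs combining
#' extracellular-loop sites with periplasmic sites in FhaC, used to interpret
#' structure-based feasibility calls. Outcome levels: `"yes"`, `"weak"`,
#' `"no"`.
#'
#' @return data.frame with columns `periplasmic_site`, `surface_site`,
#'   `crosslink`.
#' @export
fhac_crosslink_outcomes <- function() {
  path <- system.file("extdata", "fhac_cys_crosslinks.csv", package = "spinsight")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
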