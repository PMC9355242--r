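# pre_nmr: paramagnetic relaxation enhancement intensity-ratio analysis.
# Ratios of para-/diamagnetic peak intensities with noise-propagated errors,
# normalization to the maximum observed ratio (the PRE-unaffected reference),
# one-sided z-score attenuation tests and classification against
# structure-predicted label distances. Only relative attenuation is analyzed;
# no quantitative distances are extracted from ratios.

#' Construct a peak-intensity table
#'
#' @param residue_id character, e.g. `"I114"`; overlapped peaks may carry a
#'   merged id such as `"I252+I420"`.
#' @param intensity positive peak intensities (arbitrary units).
#' @param noise_rms positive root-mean-square spectral noise, same units.
#' @param condition `"para"` or `"dia"`.
#' @param sample free-form sample label.
#' @return data.frame of class `intensity_table`.
#' @export
intensity_table <- function(residue_id, intensity, noise_rms,
                            condition = c("para", "dia"), sample = "") {
  condition <- match.arg(condition)
  if (any(intensity <= 0)) stop("intensities must be positive")
  if (any(noise_rms <= 0)) stop("noise_rms must be positive")
  if (anyDuplicated(residue_id)) stop("duplicate residue ids")
  out <- data.frame(residue_id = as.character(residue_id),
                    intensity = intensity, noise_rms = noise_rms,
                    stringsAsFactors = FALSE)
  attr(out, "condition") <- condition
  attr(out, "sample") <- sample
  class(out) <- c("intensity_table", "data.frame")
  out
}

#' Para/dia intensity ratios with propagated errors
#'
#' ratio = I_para / I_dia; sigma = ratio * sqrt((noise_p / I_p)^2 +
#' (noise_d / I_d)^2), i.e. first-order propagation of the spectral noise.
#' Residues present in only one table are dropped and reported via the
#' `"mismatched"` attribute.
#'
#' @param para,dia [intensity_table()]s (or data.frames with columns
#'   `residue_id`, `intensity`, `noise_rms`).
#' @return data.frame of class `pre_ratio_table` with columns `residue_id`,
#'   `ratio`, `sigma` (and, after [normalize_to_max()], `norm_ratio`,
#'   `norm_sigma`).
#' @export
compute_ratios <- function(para, dia) {
  common <- intersect(para$residue_id, dia$residue_id)
  if (!length(common)) stop("para and dia tables share no residue ids")
  mism <- union(setdiff(para$residue_id, common), setdiff(dia$residue_id, common))
  p <- para[match(common, para$residue_id), ]
  d <- dia[match(common, dia$residue_id), ]
  ratio <- p$intensity / d$intensity
  sigma <- ratio * sqrt((p$noise_rms / p$intensity)^2 + (d$noise_rms / d$intensity)^2)
  out <- data.frame(residue_id = common, ratio = ratio, sigma = sigma,
                    stringsAsFactors = FALSE)
  attr(out, "mismatched") <- mism
  class(out) <- c("pre_ratio_table", "data.frame")
  out
}

#' Normalize PRE ratios to the maximum observed ratio
#'
#' Divides all ratios and their errors by the largest ratio in the table. The
#' residue carrying that maximum (in practice one of the residues furthest
#' from the paramagnetic center) becomes the reference with norm_ratio = 1.
#' Idempotent.
#'
#' @param table a [compute_ratios()] result.
#' @return the table with `norm_ratio`, `norm_sigma` columns and a
#'   `"reference_residue"` attribute.
#' @export
normalize_to_max <- function(table) {
  if (!nrow(table)) stop("empty ratio table")
  i <- which.max(table$ratio)
  ref <- table$ratio[i]
  table$norm_ratio <- table$ratio / ref
  table$norm_sigma <- table$sigma / ref
  attr(table, "reference_residue") <- table$residue_id[i]
  table
}

#' z-score test for significant PRE attenuation
#'
#' Compares a residue's normalized ratio against the error-weighted mean of a
#' set of reference residues (typically those far from the label). Ratio
#' errors are taken as normally distributed;
#' z = (ref_mean - ratio) / sqrt(sigma_ref^2 + sigma^2) and the default
#' one-sided p = 1 - Phi(z) tests for attenuation (lower ratio).
#'
#' @param table a normalized [pre_ratio_table][compute_ratios()]; raw ratios
#'   are used when `norm_ratio` is absent (the z statistic is identical, since
#'   normalization rescales ratios and errors by a common factor).
#' @param residue residue id to test.
#' @param references character vector of reference residue ids (must not
#'   include `residue`).
#' @param two_sided use a two-sided p-value (default `FALSE`).
#' @return list with `z`, `p`, `significant_05`, `significant_01`,
#'   `ref_mean`, `ref_sigma`.
#' @export
compare_attenuation <- function(table, residue, references, two_sided = FALSE) {
  if (residue %in% references)
    stop("residue '", residue, "' cannot be one of its own references")
  have <- c(residue, references) %in% table$residue_id
  if (!all(have))
    stop("residues not in table: ",
         paste(c(residue, references)[!have], collapse = ", "))
  rcol <- if ("norm_ratio" %in% names(table)) "norm_ratio" else "ratio"
  scol <- if ("norm_sigma" %in% names(table)) "norm_sigma" else "sigma"
  ri <- match(residue, table$residue_id)
  ref <- match(references, table$residue_id)
  w <- 1 / table[[scol]][ref]^2
  ref_mean <- sum(w * table[[rcol]][ref]) / sum(w)
  ref_sigma <- sqrt(1 / sum(w))
  z <- (ref_mean - table[[rcol]][ri]) / sqrt(ref_sigma^2 + table[[scol]][ri]^2)
  p <- if (two_sided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(-z)
  list(z = z, p = p, significant_05 = p < 0.05, significant_01 = p < 0.01,
       ref_mean = ref_mean, ref_sigma = ref_sigma)
}

#' Classify observed PRE attenuation against structure-predicted distances
#'
#' A residue is *expected* attenuated when its predicted distance from the
#' mean paramagnetic-center position is within the PRE detection radius
#' (default 25 A; PRE effects reach about 25-30 A), and *observed* attenuated
#' when its normalized ratio falls below `attenuation_threshold`. Discordant
#' residues — attenuated far from the label, or untouched close to it — are
#' the candidates for transient conformers. Merged ids (`"I252+I420"`) use the
#' minimum distance of their components.
#'
#' @param table a normalized [pre_ratio_table][compute_ratios()].
#' @param distances data.frame with columns `residue_id`, `distance_A` (e.g.
#'   from [label_to_atom_distances()]), or a named numeric vector.
#' @param attenuation_threshold normalized-ratio cutoff separating attenuated
#'   from unaffected (default 0.7).
#' @param detection_radius PRE detection radius in A (default 25).
#' @return data.frame with columns `residue_id`, `distance_A`, `norm_ratio`,
#'   `expected`, `observed`, `concordant`.
#' @export
classify_against_structure <- function(table, distances,
                                       attenuation_threshold = 0.7,
                                       detection_radius = 25) {
  if (!"norm_ratio" %in% names(table)) table <- normalize_to_max(table)
  if (is.numeric(distances))
    distances <- data.frame(residue_id = names(distances), distance_A = unname(distances))
  dist_of <- function(id) {
    parts <- strsplit(id, "+", fixed = TRUE)[[1]]
    d <- distances$distance_A[match(parts, distances$residue_id)]
    if (anyNA(d)) NA_real_ else min(d)
  }
  d <- vapply(table$residue_id, dist_of, 0)
  if (anyNA(d))
    stop("no predicted distance for residues: ",
         paste(table$residue_id[is.na(d)], collapse = ", "))
  expected <- ifelse(d <= detection_radius, "attenuated", "unaffected")
  observed <- ifelse(table$norm_ratio < attenuation_threshold, "attenuated", "unaffected")
  data.frame(residue_id = table$residue_id, distance_A = unname(d),
             norm_ratio = table$norm_ratio,
             expected = expected, observed = observed,
             concordant = expected == observed,
             stringsAsFactors = FALSE)
}
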