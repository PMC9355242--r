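# synthetic_data: seeded generators that produce inputs with the statistical
# structure each analysis stage assumes, so the whole pipeline is testable
# without downloads. Every generator is a pure function of its arguments and
# seed.

# --- toy structures ---------------------------------------------------------

# Ideal poly-Ala alpha helix (phi = -57, psi = -47, omega = 180) with
# N, CA, C, O, CB per residue. Returns the atom data.frame in local coords.
build_helix_atoms <- function(n_res, chain = "A", start_resno = 1) {
  stopifnot(n_res >= 2)
  N <- list(); CA <- list(); C <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(1.458, 0, 0)
  C[[1]] <- place_atom(c(0, 1, 0), N[[1]], CA[[1]], 1.525, 111.2, 57.0)
  phi <- -57; psi <- -47
  for (i in 2:n_res) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]], 1.329, 116.2, psi)
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]], 1.458, 121.7, 180)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]], 1.525, 111.2, phi)
  }
  rows <- list()
  serial <- 0L
  add <- function(resno, name, xyz, element) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, resname = "ALA", chain = chain,
      resno = resno, x = xyz[1], y = xyz[2], z = xyz[3],
      element = element, occ = 1, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_res)) {
    resno <- start_resno + i - 1L
    add(resno, "N", N[[i]], "N")
    add(resno, "CA", CA[[i]], "C")
    add(resno, "C", C[[i]], "C")
    o_ref <- if (i < n_res) N[[i + 1]] else place_atom(N[[i]], CA[[i]], C[[i]], 1.329, 116.2, psi)
    o <- place_atom(CA[[i]], o_ref, C[[i]], 1.231, 122.0, 180)
    add(resno, "O", o, "O")
    cb_ref <- if (i > 1) C[[i - 1]] else place_atom(CA[[i]], N[[i]], C[[i]], 1.329, 116.2, 100)
    cb <- place_atom(cb_ref, N[[i]], CA[[i]], 1.53, 110.5, phi - 122.6)
    add(resno, "CB", cb, "C")
  }
  do.call(rbind, rows)
}

# Rotate atoms about z so the site's CA->CB vector projects onto +y, then
# translate the site CB to `cb_target`.
orient_helix <- function(atoms, site_resno, cb_target = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ca <- xyz[atoms$resno == site_resno & atoms$name == "CA", ]
  cb <- xyz[atoms$resno == site_resno & atoms$name == "CB", ]
  v <- cb - ca
  ang <- atan2(v[1], v[2])  # rotate so x-component -> 0, y > 0
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  xyz <- xyz %*% t(R)
  cb2 <- xyz[atoms$resno == site_resno & atoms$name == "CB", ]
  xyz <- sweep(xyz, 2, cb2 - cb_target)
  atoms[, c("x", "y", "z")] <- xyz
  atoms
}

# Deterministic quasi-uniform points on a sphere (Fibonacci lattice).
fibonacci_sphere <- function(n, radius, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + radius * sin(phi) * cos(theta),
        center[2] + radius * sin(phi) * sin(theta),
        center[3] + radius * cos(phi))
}

#' Generate a toy structure with known geometry
#'
#' Three kinds of idealized poly-Ala scaffolds for testing the labeling and
#' screening stages:
#' * `"exposed-helix"`: a single isolated 16-residue helix; the label site
#'   (`"A:8"`) is fully solvent exposed.
#' * `"two-site-scaffold"`: two parallel 9-residue helices whose middle-residue
#'   CB atoms sit exactly `separation_A` apart along x, with the label arms
#'   oriented perpendicular to the separation axis; label sites `"A:5"` and
#'   `"B:105"`. A reporter ILE CD1 pseudo-atom (`"R:500"`) is placed 10 A from
#'   the first site's CB along +y.
#' * `"buried-cage"`: a 5-residue helix whose site (`"C:3"`) CB is enclosed in
#'   two concentric shells of pseudo-atoms (radii 3.5 and 6 A), so every label
#'   conformer clashes.
#'
#' @param kind scaffold type.
#' @param seed accepted for interface uniformity; the scaffolds are fully
#'   deterministic.
#' @param separation_A CB-CB distance of the two-site scaffold (default 45).
#' @return a [spin_structure()]; attribute `"sites"` lists the designated
#'   label sites.
#' @export
make_toy_structure <- function(kind = c("exposed-helix", "two-site-scaffold",
                                        "buried-cage"),
                               seed = 1, separation_A = 45) {
  kind <- match.arg(kind)
  if (kind == "exposed-helix") {
    atoms <- build_helix_atoms(16, chain = "A")
    s <- spin_structure(atoms, id = "toy-exposed-helix")
    attr(s, "sites") <- "A:8"
    return(s)
  }
  if (kind == "two-site-scaffold") {
    a <- orient_helix(build_helix_atoms(9, chain = "A", start_resno = 1), 5,
                      cb_target = c(0, 0, 0))
    b <- orient_helix(build_helix_atoms(9, chain = "B", start_resno = 101), 105,
                      cb_target = c(separation_A, 0, 0))
    b$chain <- "B"
    b$serial <- b$serial + max(a$serial)
    rep_atom <- data.frame(serial = max(b$serial) + 1L, name = "CD1",
                           resname = "ILE", chain = "R", resno = 500,
                           x = 0, y = 10, z = 0, element = "C", occ = 1,
                           stringsAsFactors = FALSE)
    s <- spin_structure(rbind(a, b, rep_atom), id = "toy-two-site-scaffold")
    attr(s, "sites") <- c("A:5", "B:105")
    attr(s, "separation_A") <- separation_A
    return(s)
  }
  # buried cage
  atoms <- build_helix_atoms(5, chain = "C")
  cb <- as.numeric(atoms[atoms$resno == 3 & atoms$name == "CB", c("x", "y", "z")])
  shells <- rbind(fibonacci_sphere(100, 3.5, cb), fibonacci_sphere(260, 6, cb))
  cage <- data.frame(serial = max(atoms$serial) + seq_len(nrow(shells)),
                     name = "C", resname = "CAG", chain = "X",
                     resno = 900 + seq_len(nrow(shells)),
                     x = shells[, 1], y = shells[, 2], z = shells[, 3],
                     element = "C", occ = 1, stringsAsFactors = FALSE)
  s <- spin_structure(rbind(atoms, cage), id = "toy-buried-cage")
  attr(s, "sites") <- "C:3"
  s
}

# --- DEER -------------------------------------------------------------------

#' Synthetic DEER dataset from a multi-Gaussian distance distribution
#'
#' @param components list of `c(mean_nm, sd_nm, weight)` triples; weights must
#'   sum to 1.
#' @param k,lambda,d background parameters (see [background_model()]).
#' @param t_max dipolar evolution time in us.
#' @param n_points points on the time axis.
#' @param noise_sd Gaussian noise level of the normalized trace.
#' @param seed integer seed.
#' @param r_grid distance grid for the true distribution (nm).
#' @return list with `trace` (a [dipolar_trace()]) and `truth` (true
#'   [distance_distribution()], component table, background parameters).
#' @export
make_deer_dataset <- function(components = list(c(4.5, 0.3, 1)),
                              k = 0.2, lambda = 0.3, d = 3,
                              t_max = 3.2, n_points = 320, noise_sd = 0.02,
                              seed = 1, r_grid = seq(1, 10, by = 0.02)) {
  comp <- do.call(rbind, components)
  if (abs(sum(comp[, 3]) - 1) > 1e-9) stop("component weights must sum to 1")
  p <- numeric(length(r_grid))
  for (i in seq_len(nrow(comp)))
    p <- p + comp[i, 3] * stats::dnorm(r_grid, comp[i, 1], comp[i, 2])
  P <- distance_distribution(r_grid, p,
                             metadata = list(components = comp))
  bg <- background_model(k = k, lambda = lambda, d = d)
  t_grid <- seq(0, t_max, length.out = n_points)
  trace <- simulate_trace(P, bg, t_grid, noise_sd = noise_sd, seed = seed)
  list(trace = trace,
       truth = list(P = P, components = comp, k = k, lambda = lambda, d = d,
                    noise_sd = noise_sd, seed = seed))
}

# --- PRE --------------------------------------------------------------------

#' Synthetic paired para/diamagnetic intensity tables
#'
#' Forward model: I_para / I_dia = exp(-Gamma2) with Gamma2 =
#' `tau_factor` * r^-6 (r in A) — the simplest Solomon-Bloembergen-consistent
#' attenuation, used only to generate data. By default `tau_factor` is
#' calibrated so that the ratio at `half_ratio_A` (25 A) equals 0.5. The para
#' and dia tables carry distinct global scale factors, emulating different
#' amounts of protein in the two samples, so raw ratios do not normalize
#' to 1. True ratios are floored at `ratio_floor` (detection limit for fully
#' bleached peaks).
#'
#' @param true_distances named numeric vector, residue id -> label distance
#'   in A.
#' @param tau_factor attenuation scale (A^6); default calibrated from
#'   `half_ratio_A`.
#' @param half_ratio_A distance at which the true ratio is 0.5 (default 25).
#' @param scale_para,scale_dia global intensity scales of the two tables.
#' @param noise_rms additive Gaussian noise on intensities (0 allowed; the
#'   recorded per-row noise is floored at a tiny positive value so error
#'   propagation stays defined).
#' @param base_intensity unattenuated peak intensity.
#' @param ratio_floor lower bound on true ratios (default 1e-3).
#' @param detection_radius radius used for the truth-table expected class
#'   (default 25 A).
#' @param seed integer seed.
#' @return list with `para`, `dia` ([intensity_table()]s) and `truth`
#'   (data.frame: residue_id, distance_A, true_ratio, true_norm_ratio,
#'   expected).
#' @export
make_pre_dataset <- function(true_distances,
                             tau_factor = NULL, half_ratio_A = 25,
                             scale_para = 1, scale_dia = 1,
                             noise_rms = 0, base_intensity = 1000,
                             ratio_floor = 1e-3, detection_radius = 25,
                             seed = 1) {
  if (any(true_distances <= 0)) stop("distances must be positive")
  if (is.null(tau_factor)) tau_factor <- log(2) * half_ratio_A^6
  r <- true_distances
  ids <- names(r)
  if (is.null(ids)) ids <- paste0("I", seq_along(r))
  ratio <- pmax(exp(-tau_factor / r^6), ratio_floor)
  noise_rec <- max(noise_rms, 1e-6 * base_intensity * min(scale_para, scale_dia))
  vals <- with_local_seed(seed, {
    eps_p <- stats::rnorm(length(r), 0, 1)
    eps_d <- stats::rnorm(length(r), 0, 1)
    list(
      para = pmax(scale_para * base_intensity * ratio + noise_rms * eps_p,
                  noise_rec / 10),
      dia = pmax(scale_dia * base_intensity + noise_rms * eps_d, noise_rec / 10))
  })
  truth <- data.frame(
    residue_id = ids, distance_A = unname(r), true_ratio = unname(ratio),
    true_norm_ratio = unname(ratio / max(ratio)),
    expected = ifelse(r <= detection_radius, "attenuated", "unaffected"),
    stringsAsFactors = FALSE)
  list(
    para = intensity_table(ids, vals$para, rep(noise_rec, length(r)),
                           condition = "para", sample = "synthetic-para"),
    dia = intensity_table(ids, vals$dia, rep(noise_rec, length(r)),
                          condition = "dia", sample = "synthetic-dia"),
    truth = truth)
}

# --- dispersion -------------------------------------------------------------

#' Synthetic spin-lock decay series
#'
#' Decays are generated from R1rho(nu1) = R1 cos^2(theta) +
#' R2,eff(nu1) sin^2(theta) with R2,eff = r20 (flat) or
#' r20 + phi kex / (kex^2 + (2 pi nu1)^2) when `exchange = TRUE`.
#' Defaults use the 1.2-10 kHz spin-lock ladder and the 2.5-80 ms duration
#' ladder typical of methyl R1rho experiments on large membrane proteins.
#'
#' @param r20 exchange-free transverse rate, per s.
#' @param phi exchange amplitude, s^-2; @param kex exchange rate, s^-1.
#' @param r1 longitudinal rate, per s.
#' @param nu1_khz spin-lock fields in kHz; warns outside (0.1, 100) kHz.
#' @param durations_ms spin-lock durations in ms (>= 3).
#' @param noise fractional intensity noise.
#' @param seed integer seed.
#' @param exchange include the exchange contribution?
#' @param offset_khz resonance offset (0 = on resonance).
#' @param residue_id label for the series.
#' @return list of class `spin_lock_series` with `points`, `r1`, `r1_sigma`,
#'   `residue_id`, `truth`.
#' @export
make_dispersion_dataset <- function(r20 = 20, phi = 5e5, kex = 1e4, r1 = 1,
                                    nu1_khz = c(1.2, 2, 3.5, 5, 7.5, 10),
                                    durations_ms = c(2.5, 10, 25, 50, 80),
                                    noise = 0.02, seed = 1, exchange = TRUE,
                                    offset_khz = 0, residue_id = "I1") {
  if (length(durations_ms) < 3L) stop("need >= 3 spin-lock durations")
  if (any(nu1_khz <= 0.1) || any(nu1_khz >= 100))
    warning("spin-lock fields outside the plausible 0.1-100 kHz range")
  theta <- ifelse(offset_khz == 0, pi / 2, atan(nu1_khz / offset_khz))
  omega1 <- 2 * pi * nu1_khz * 1000
  r2eff <- r20 + if (exchange) phi * kex / (kex^2 + omega1^2) else 0 * omega1
  r1rho <- r1 * cos(theta)^2 + r2eff * sin(theta)^2
  i0 <- 1000
  points <- with_local_seed(seed, {
    lapply(seq_along(nu1_khz), function(i) {
      mu <- i0 * exp(-r1rho[i] * durations_ms / 1000)
      I <- pmax(mu * (1 + stats::rnorm(length(mu), 0, noise)), i0 * 1e-6)
      list(nu1_khz = nu1_khz[i], offset_khz = offset_khz,
           durations_ms = durations_ms, intensities = I)
    })
  })
  structure(list(residue_id = residue_id, points = points,
                 r1 = r1, r1_sigma = 0.05 * r1,
                 truth = list(r20 = r20, phi = if (exchange) phi else 0,
                              kex = kex, r2eff = r2eff, exchange = exchange,
                              noise = noise, seed = seed)),
            class = "spin_lock_series")
}
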