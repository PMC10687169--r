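# Seeded synthetic-data generators. Every generator emits the same containers
# the analysis stages consume (structure_model, itc series, melt curves), so
# each stage has a download-free oracle. All pseudo-randomness in the package
# lives here; the analysis modules are deterministic.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  force(expr)
}

# idealized ring templates in the z = 0 plane, centroid at the origin
ring_template <- function(ring_type) {
  if (ring_type %in% c("PHE", "TYR")) {
    r <- 1.39  # benzene C-C bond length gives a circumradius of 1.39 A
    ang <- seq(0, 300, by = 60) * pi / 180
    names_ <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    data.frame(name = names_, element = "C",
               x = r * cos(ang), y = r * sin(ang), z = 0,
               stringsAsFactors = FALSE)
  } else if (ring_type == "HIS") {
    r <- 1.17  # imidazole circumradius (approx)
    ang <- seq(90, 90 + 288, by = 72) * pi / 180
    names_ <- c("CG", "ND1", "CE1", "NE2", "CD2")
    data.frame(name = names_,
               element = c("C", "N", "C", "N", "C"),
               x = r * cos(ang), y = r * sin(ang), z = 0,
               stringsAsFactors = FALSE)
  } else stop("unsupported ring type for the generator: ", ring_type)
}

rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, 3,
         byrow = TRUE)
}

ring_atoms_df <- function(tmpl, chain, resno, resid, rot = diag(3),
                          shift = c(0, 0, 0)) {
  xyz <- as.matrix(tmpl[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  data.frame(eleno = NA_integer_, name = tmpl$name, alt = "",
             resid = resid, chain = chain, resno = resno,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             o = 1, b = 0, element = tmpl$element, het = FALSE,
             stringsAsFactors = FALSE)
}

finish_model <- function(id, atoms, ...) {
  atoms$eleno <- seq_len(nrow(atoms))
  structure_model(id = id, atoms = atoms, ...)
}

#' Build an idealized aromatic ring pair at prescribed geometry
#'
#' Two idealized rings, placed so that \code{\link{pair_geometry}} on the
#' result recovers exactly the requested centroid distance and inter-plane
#' angle: ring A lies in the z = 0 plane at the origin; ring B is rotated by
#' \code{gamma} about the x axis and its centroid displaced by \code{r_cen}
#' along z. The rings sit on different chains (A and B) so the contact is
#' flagged intermolecular.
#'
#' @param r_cen centroid-centroid distance (Angstrom), > 0.
#' @param gamma inter-plane angle in degrees, in [0, 90].
#' @param ring_type_a,ring_type_b residue types ("PHE", "TYR" or "HIS").
#' @return a \code{\link{structure_model}} with two single-ring residues.
#' @export
make_ring_pair <- function(r_cen, gamma, ring_type_a = "PHE",
                           ring_type_b = "PHE") {
  if (r_cen <= 0) stop("r_cen must be positive")
  if (gamma < 0 || gamma > 90) stop("gamma must lie in [0, 90] degrees")
  a <- ring_atoms_df(ring_template(ring_type_a), "A", 1L, ring_type_a)
  b <- ring_atoms_df(ring_template(ring_type_b), "B", 1L, ring_type_b,
                     rot = rot_x(gamma), shift = c(0, 0, r_cen))
  finish_model(sprintf("ring_pair_r%.3f_g%.3f", r_cen, gamma), rbind(a, b))
}

tetrahedral_dirs <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1),
                           4, 3, byrow = TRUE) / sqrt(3)

#' Build an idealized tetrahedral metal site
#'
#' A single zinc atom with donors placed along tetrahedral directions at
#' \code{bond_length}: pattern "C" donors are cysteine SG sulfurs, "H" donors
#' histidine NE2 nitrogens, "X" donors water oxygens. Running
#' \code{\link{find_metal_sites}} + \code{\link{coordination_pattern}} on the
#' result recovers the input pattern (for bond lengths within the cutoff).
#'
#' @param pattern pattern string such as "C2H2", "C4" or "C3X1"; at most 4
#'   donors total.
#' @param bond_length metal-donor distance (Angstrom, default 2.3).
#' @param chain chain id (default "A").
#' @param resno_start first donor residue number (default 1).
#' @param origin zinc position (default the origin).
#' @return a \code{\link{structure_model}}.
#' @export
make_zinc_site <- function(pattern, bond_length = 2.3, chain = "A",
                           resno_start = 1L, origin = c(0, 0, 0)) {
  m <- gregexpr("([CHX])([0-9]+)", pattern)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(pattern))
    stop("unparseable coordination pattern: ", pattern)
  toks <- regmatches(pattern, gregexpr("([CHX])([0-9]+)", pattern))[[1]]
  classes <- character()
  for (t in toks) {
    cls <- substr(t, 1, 1)
    cnt <- as.integer(substr(t, 2, nchar(t)))
    classes <- c(classes, rep(cls, cnt))
  }
  if (length(classes) > 4)
    stop("tetrahedral generator supports at most 4 donors")
  rows <- list(data.frame(
    eleno = NA_integer_, name = "ZN", alt = "", resid = "ZN", chain = chain,
    resno = resno_start + 100L, x = origin[1], y = origin[2], z = origin[3],
    o = 1, b = 0, element = "Zn", het = TRUE, stringsAsFactors = FALSE))
  for (i in seq_along(classes)) {
    pos <- origin + bond_length * tetrahedral_dirs[i, ]
    info <- switch(classes[i],
                   C = list(resid = "CYS", name = "SG", element = "S",
                            het = FALSE),
                   H = list(resid = "HIS", name = "NE2", element = "N",
                            het = FALSE),
                   X = list(resid = "HOH", name = "O", element = "O",
                            het = TRUE))
    rows[[length(rows) + 1]] <- data.frame(
      eleno = NA_integer_, name = info$name, alt = "", resid = info$resid,
      chain = chain, resno = resno_start + i - 1L,
      x = pos[1], y = pos[2], z = pos[3], o = 1, b = 0,
      element = info$element, het = info$het, stringsAsFactors = FALSE)
  }
  finish_model(paste0("zinc_site_", pattern), do.call(rbind, rows))
}

#' Synthetic UBR-box-like zinc architecture
#'
#' Builds a synthetic multi-chain model emulating the zinc organisation of a
#' subfamily-2 UBR box: per chain, one canonical C2H2 site (Zn1) plus a
#' bi-zinc cluster (Zn2, Zn3) in which seven distinct cysteines coordinate
#' the two zincs through one bridging thiolate. This is a geometric stand-in
#' constructed by the package, not deposited coordinates.
#'
#' @param n_chains number of protein chains (default 3).
#' @param bond_length metal-donor distance (default 2.3 A).
#' @return a \code{\link{structure_model}} with \code{3 * n_chains} zincs.
#' @export
make_ubr_zinc_model <- function(n_chains = 3, bond_length = 2.3) {
  chains <- LETTERS[seq_len(n_chains)]
  all_rows <- list()
  add_atom <- function(chain, resno, resid, name, element, het, pos) {
    all_rows[[length(all_rows) + 1]] <<- data.frame(
      eleno = NA_integer_, name = name, alt = "", resid = resid,
      chain = chain, resno = as.integer(resno), x = pos[1], y = pos[2],
      z = pos[3], o = 1, b = 0, element = element, het = het,
      stringsAsFactors = FALSE)
  }
  for (ci in seq_along(chains)) {
    ch <- chains[ci]
    off <- c(0, 0, 50 * (ci - 1))
    # Zn1: canonical C2H2
    zn1 <- off
    add_atom(ch, 201, "ZN", "ZN", "Zn", TRUE, zn1)
    for (i in 1:2)
      add_atom(ch, i, "CYS", "SG", "S", FALSE,
               zn1 + bond_length * tetrahedral_dirs[i, ])
    for (i in 3:4)
      add_atom(ch, i, "HIS", "NE2", "N", FALSE,
               zn1 + bond_length * tetrahedral_dirs[i, ])
    # Zn2/Zn3 cluster: 4.0 A apart, bridged by one cysteine thiolate at the
    # midpoint (2.0 A from each zinc), plus three terminal cysteines each
    zn2 <- off + c(12, 0, 0)
    zn3 <- off + c(16, 0, 0)
    add_atom(ch, 202, "ZN", "ZN", "Zn", TRUE, zn2)
    add_atom(ch, 203, "ZN", "ZN", "Zn", TRUE, zn3)
    add_atom(ch, 10, "CYS", "SG", "S", FALSE, (zn2 + zn3) / 2)
    for (i in 1:3)
      add_atom(ch, 10 + i, "CYS", "SG", "S", FALSE,
               zn2 + bond_length * tetrahedral_dirs[i, ] * c(-1, 1, 1))
    for (i in 1:3)
      add_atom(ch, 13 + i, "CYS", "SG", "S", FALSE,
               zn3 + bond_length * tetrahedral_dirs[i, ])
  }
  finish_model("synthetic_ubr_zinc", do.call(rbind, all_rows))
}

#' Simulate a single-site ITC titration
#'
#' Model heats from \code{\link{itc_heats}} plus Gaussian noise, reproducible
#' per seed. Noise standard deviation per injection is
#' \code{noise_sd + noise_prop * |model heat|}, supporting both constant
#' (i.i.d.) and proportional noise.
#'
#' @param n,kd,dh ground-truth stoichiometry, dissociation constant (mol/L)
#'   and enthalpy (cal/mol).
#' @param protocol an \code{\link{itc_protocol}}.
#' @param noise_sd constant noise component (ucal, default 0), >= 0.
#' @param noise_prop proportional noise component (fraction of each model
#'   heat's magnitude, default 0), >= 0.
#' @param baseline constant per-injection offset (ucal, default 0).
#' @param seed integer seed, or NULL for the current RNG stream.
#' @return list of class \code{titration_series}: \code{protocol},
#'   \code{heats}, \code{truth}.
#' @export
simulate_itc <- function(n, kd, dh, protocol, noise_sd = 0, noise_prop = 0,
                         baseline = 0, seed = NULL) {
  if (noise_sd < 0 || noise_prop < 0) stop("noise levels must be >= 0")
  model <- itc_heats(n, kd, dh, protocol, baseline)
  sds <- noise_sd + noise_prop * abs(model)
  heats <- with_seed(seed, model + stats::rnorm(length(model), sd = sds))
  structure(list(protocol = protocol, heats = heats,
                 truth = list(n = n, kd = kd, dh = dh, baseline = baseline,
                              noise_sd = noise_sd, noise_prop = noise_prop,
                              seed = seed)),
            class = "titration_series")
}

#' Simulate a thermal-shift melt curve
#'
#' Boltzmann sigmoid over a temperature grid (default 25-95 C in 0.2 C
#' steps, the assay's scan protocol) plus i.i.d. Gaussian noise.
#'
#' @param tm ground-truth melting temperature (deg C).
#' @param low,high plateaus (default 0 and 1).
#' @param slope transition width (deg C, default 1.5).
#' @param noise_sd Gaussian noise sd in signal units (default 0), >= 0.
#' @param seed integer seed or NULL.
#' @param t_min,t_max,t_step temperature grid (deg C).
#' @return list of class \code{melt_curve}: \code{temperature},
#'   \code{signal}, \code{truth}.
#' @export
simulate_melt <- function(tm, low = 0, high = 1, slope = 1.5, noise_sd = 0,
                          seed = NULL, t_min = 25, t_max = 95, t_step = 0.2) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  temperature <- seq(t_min, t_max, by = t_step)
  model <- boltzmann_sigmoid(temperature, tm, low, high, slope)
  signal <- with_seed(seed,
                      model + stats::rnorm(length(model), sd = noise_sd))
  structure(list(temperature = temperature, signal = signal,
                 truth = list(tm = tm, low = low, high = high, slope = slope,
                              noise_sd = noise_sd, seed = seed)),
            class = "melt_curve")
}

#' Write a titration series as CSV
#'
#' Columns \code{injection}, \code{heat} (ucal); the protocol travels
#' separately (see \code{\link{fit_thermo}}).
#'
#' @param series a \code{titration_series} (or list with \code{heats}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  utils::write.csv(data.frame(injection = seq_along(series$heats),
                              heat = series$heats),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a melt curve as CSV
#'
#' Columns \code{temperature} (deg C), \code{signal}.
#'
#' @param curve a \code{melt_curve} (or list with \code{temperature},
#'   \code{signal}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_melt_csv <- function(curve, path) {
  utils::write.csv(data.frame(temperature = curve$temperature,
                              signal = curve$signal),
                   path, row.names = FALSE)
  invisible(path)
}
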