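# Aromatic ring definitions: atom names per residue type. TRP contributes two
# independent rings (pyrrole + benzene); fused-centroid treatment is not used.
RING_ATOMS <- list(
  PHE = list(six_membered = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(six_membered = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(five_membered = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(five_membered = c("CG", "CD1", "NE1", "CE2", "CD2"),
             six_membered = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

#' Least-squares plane through a point set
#'
#' Fits the plane minimizing the sum of squared perpendicular distances; the
#' normal is the smallest principal axis of the centered coordinates
#' (singular vector of the smallest singular value). The normal's sign is
#' fixed deterministically: its first component of magnitude > 1e-8 is made
#' positive (the inter-plane angle gamma uses acute folding, so the sign
#' never affects reported geometry).
#'
#' @param points n x 3 numeric matrix, n >= 3.
#' @return list with \code{centroid} (length 3), \code{normal} (unit length
#'   3-vector) and \code{rms} (root-mean-square perpendicular deviation,
#'   Angstrom).
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("plane fit needs at least 3 points")
  centroid <- unname(colMeans(points))
  centered <- sweep(points, 2, centroid)
  sv <- svd(centered)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear) points: plane undefined")
  normal <- unname(sv$v[, 3])
  lead <- which(abs(normal) > 1e-8)[1]
  if (normal[lead] < 0) normal <- -normal
  rms <- sqrt(mean((centered %*% normal)^2))
  list(centroid = centroid, normal = normal, rms = rms)
}

#' Aromatic rings of a residue
#'
#' Builds \code{aromatic_ring} descriptors (centroid, unit plane normal,
#' planarity RMS) for PHE/TYR (one six-membered ring), HIS (one five-membered
#' ring) and TRP (two rings). A ring with any member atom missing is skipped
#' with a warning rather than an error.
#'
#' @param res_atoms data.frame of atom records of a single residue.
#' @return list of \code{aromatic_ring} objects (possibly empty).
#' @export
ring_descriptor <- function(res_atoms) {
  resid <- toupper(res_atoms$resid[1])
  defs <- RING_ATOMS[[resid]]
  if (is.null(defs)) return(list())
  rings <- list()
  for (label in names(defs)) {
    wanted <- defs[[label]]
    idx <- match(wanted, res_atoms$name)
    if (anyNA(idx)) {
      warning(sprintf("%s %s%s: ring atom(s) %s missing; ring skipped",
                      resid, res_atoms$chain[1], res_atoms$resno[1],
                      paste(wanted[is.na(idx)], collapse = ",")),
              call. = FALSE)
      next
    }
    pl <- fit_plane(atom_xyz(res_atoms[idx, ]))
    rings[[length(rings) + 1]] <- structure(
      list(chain = res_atoms$chain[1], resno = res_atoms$resno[1],
           resid = resid, ring_label = label, atom_names = wanted,
           centroid = pl$centroid, normal = pl$normal,
           planarity_rms = pl$rms,
           is_symmetry_copy = isTRUE(res_atoms$is_symmetry_copy[1]),
           sym_op = res_atoms$sym_op[1] %||% ""),
      class = "aromatic_ring")
  }
  rings
}

#' All aromatic rings in a selection
#'
#' @param model a \code{\link{structure_model}}.
#' @param selection optional atom data.frame (e.g. from
#'   \code{\link{select_atoms}}); defaults to all atoms.
#' @return list of \code{aromatic_ring} objects in deterministic
#'   (chain, residue) order.
#' @export
find_rings <- function(model, selection = NULL) {
  a <- selection %||% model$atoms
  a <- a[toupper(a$resid) %in% names(RING_ATOMS), , drop = FALSE]
  if (!nrow(a)) return(list())
  key <- paste(a$chain, a$resno, a$resid, sep = "\r")
  out <- list()
  for (k in unique(key[order(a$chain, a$resno)]))
    out <- c(out, ring_descriptor(a[key == k, , drop = FALSE]))
  out
}

ring_id <- function(r) paste0(r$chain, "/", r$resid, r$resno, "/", r$ring_label)

#' Centroid distance and inter-plane angle of a ring pair
#'
#' R_cen is the Euclidean distance between ring centroids; gamma is the angle
#' between the two plane normals folded into [0, 90] degrees (acute
#' convention, so normal sign is irrelevant).
#'
#' @param ring_a,ring_b \code{aromatic_ring} objects.
#' @return list with \code{r_cen} (Angstrom) and \code{gamma} (degrees).
#' @export
pair_geometry <- function(ring_a, ring_b) {
  r_cen <- sqrt(sum((ring_a$centroid - ring_b$centroid)^2))
  cosg <- abs(sum(ring_a$normal * ring_b$normal))
  gamma <- acos(min(1, max(-1, cosg))) * 180 / pi
  list(r_cen = r_cen, gamma = gamma)
}

#' Default pi-pi classification thresholds
#'
#' Detection window on R_cen and left-closed gamma bands:
#' parallel [0, 30), intermediate [30, 50), T-shaped [50, 90].
#'
#' @return list with \code{r_cen_min}, \code{r_cen_max}, \code{gamma_parallel}
#'   and \code{gamma_tshaped} (band boundaries, degrees).
#' @export
pi_pi_thresholds <- function() {
  list(r_cen_min = 3.0, r_cen_max = 7.0,
       gamma_parallel = 30, gamma_tshaped = 50)
}

#' Classify a pi-pi contact
#'
#' Returns "none" when R_cen falls outside the detection window, otherwise
#' the conformational class from left-closed gamma bands:
#' \code{[0, gamma_parallel)} parallel,
#' \code{[gamma_parallel, gamma_tshaped)} intermediate,
#' \code{[gamma_tshaped, 90]} T-shaped.
#'
#' @param r_cen centroid distance (Angstrom).
#' @param gamma inter-plane angle (degrees, in [0, 90]).
#' @param thresholds see \code{\link{pi_pi_thresholds}}.
#' @return one of "parallel", "intermediate", "t_shaped", "none".
#' @export
classify_pi_pi <- function(r_cen, gamma, thresholds = pi_pi_thresholds()) {
  th <- thresholds
  if (!(th$r_cen_min < th$r_cen_max) ||
      !(0 <= th$gamma_parallel && th$gamma_parallel < th$gamma_tshaped &&
        th$gamma_tshaped <= 90))
    stop("non-monotone pi-pi thresholds")
  if (is.na(r_cen) || is.na(gamma)) return("none")
  if (r_cen < th$r_cen_min || r_cen > th$r_cen_max) return("none")
  if (gamma < th$gamma_parallel) "parallel"
  else if (gamma < th$gamma_tshaped) "intermediate"
  else "t_shaped"
}

#' Find pi-pi stacking contacts
#'
#' Enumerates all aromatic ring pairs (excluding pairs within the same
#' residue instance) whose centroid distance falls in the detection window,
#' classifies each by gamma, and returns them sorted by R_cen. A contact is
#' flagged intermolecular when the two rings belong to different chains or
#' either ring sits on a symmetry copy.
#'
#' @param model a \code{\link{structure_model}} (optionally symmetry-expanded).
#' @param selection optional atom data.frame restricting the ring search.
#' @param thresholds see \code{\link{pi_pi_thresholds}}.
#' @return data.frame with one row per contact: ring identifiers, r_cen,
#'   gamma, conformation, intermolecular flag and symmetry-operator labels.
#' @export
find_pi_pi_contacts <- function(model, selection = NULL,
                                thresholds = pi_pi_thresholds()) {
  rings <- find_rings(model, selection)
  empty <- data.frame(ring_a = character(), ring_b = character(),
                      r_cen = numeric(), gamma = numeric(),
                      conformation = character(), intermolecular = logical(),
                      sym_op_a = character(), sym_op_b = character(),
                      stringsAsFactors = FALSE)
  if (length(rings) < 2) return(empty)
  rows <- list()
  for (i in seq_len(length(rings) - 1)) {
    for (j in seq(i + 1, length(rings))) {
      ra <- rings[[i]]; rb <- rings[[j]]
      same_res <- ra$chain == rb$chain && ra$resno == rb$resno &&
        ra$resid == rb$resid
      if (same_res) next
      g <- pair_geometry(ra, rb)
      cls <- classify_pi_pi(g$r_cen, g$gamma, thresholds)
      if (cls == "none") next
      rows[[length(rows) + 1]] <- data.frame(
        ring_a = ring_id(ra), ring_b = ring_id(rb),
        r_cen = g$r_cen, gamma = g$gamma, conformation = cls,
        intermolecular = ra$chain != rb$chain ||
          ra$is_symmetry_copy || rb$is_symmetry_copy,
        sym_op_a = ra$sym_op, sym_op_b = rb$sym_op,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$r_cen, out$ring_a, out$ring_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find pi-cation contacts
#'
#' Tests cationic side-chain centers (Lys NZ; Arg guanidinium, taken as the
#' mean of NE/CZ/NH1/NH2) against every aromatic ring. A contact is reported
#' when the cation-to-centroid distance is at most \code{max_distance} and
#' the angle between the centroid-to-cation vector and the ring normal
#' (folded acute) is at most \code{max_offset}.
#'
#' @param model a \code{\link{structure_model}}.
#' @param selection optional atom data.frame restricting the search.
#' @param max_distance cutoff on cation-centroid distance (default 6.0 A).
#' @param max_offset cutoff on the offset angle in degrees (default 90 =
#'   no angular filter).
#' @return data.frame: ring id, cation residue id, distance, offset_angle.
#' @export
find_pi_cation_contacts <- function(model, selection = NULL,
                                    max_distance = 6.0, max_offset = 90) {
  a <- selection %||% model$atoms
  rings <- find_rings(model, selection)
  cations <- cation_centers(a)
  empty <- data.frame(ring = character(), cation = character(),
                      distance = numeric(), offset_angle = numeric(),
                      intermolecular = logical(), stringsAsFactors = FALSE)
  if (!length(rings) || !nrow(cations)) return(empty)
  rows <- list()
  for (r in rings) {
    for (k in seq_len(nrow(cations))) {
      same_res <- r$chain == cations$chain[k] && r$resno == cations$resno[k]
      if (same_res) next
      v <- c(cations$x[k], cations$y[k], cations$z[k]) - r$centroid
      d <- sqrt(sum(v^2))
      if (d > max_distance || d == 0) next
      cosang <- abs(sum(v / d * r$normal))
      ang <- acos(min(1, max(-1, cosang))) * 180 / pi
      if (ang > max_offset) next
      rows[[length(rows) + 1]] <- data.frame(
        ring = ring_id(r),
        cation = paste0(cations$chain[k], "/", cations$resid[k],
                        cations$resno[k], "/", cations$group[k]),
        distance = d, offset_angle = ang,
        intermolecular = r$chain != cations$chain[k],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$distance, out$ring, out$cation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

cation_centers <- function(atoms) {
  out <- list()
  lys <- atoms[toupper(atoms$resid) == "LYS" & atoms$name == "NZ", ,
               drop = FALSE]
  if (nrow(lys))
    out[[length(out) + 1]] <- data.frame(
      chain = lys$chain, resno = lys$resno, resid = "LYS", group = "NZ",
      x = lys$x, y = lys$y, z = lys$z, stringsAsFactors = FALSE)
  arg <- atoms[toupper(atoms$resid) == "ARG" &
                 atoms$name %in% c("NE", "CZ", "NH1", "NH2"), , drop = FALSE]
  if (nrow(arg)) {
    key <- paste(arg$chain, arg$resno, sep = "\r")
    for (k in unique(key)) {
      g <- arg[key == k, , drop = FALSE]
      if (nrow(g) < 3) next  # incomplete guanidinium
      out[[length(out) + 1]] <- data.frame(
        chain = g$chain[1], resno = g$resno[1], resid = "ARG",
        group = "guanidinium", x = mean(g$x), y = mean(g$y), z = mean(g$z),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), group = character(), x = numeric(),
                      y = numeric(), z = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chain, res$resno, res$group), , drop = FALSE]
}
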