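#' Kabsch rigid-body superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets (moving set b onto reference a), via SVD of the
#' covariance matrix with the determinant sign correction that excludes
#' reflections.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates (n >= 3).
#' @return object of class \code{superposition} with \code{rotation} (3x3,
#'   det +1), \code{translation} (length 3), \code{rmsd} (Angstrom),
#'   \code{n_pairs}, and \code{transformed} (coords_b after superposition).
#'   The transform maps b onto a: \code{t(R %*% t(b)) + translation}.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (nrow(A) != nrow(B)) stop("coordinate sets must have equal length")
  if (nrow(A) < 3) stop("superposition needs at least 3 point pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("rank-deficient (collinear) coordinates: rotation ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - A0)^2)))
  translation <- ca - as.numeric(R %*% cb)
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 n_pairs = nrow(A),
                 transformed = sweep(moved, 2, ca, "+")),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d pairs, rmsd %.4f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V", MSE = "M")

# Calpha trace of one chain: one-letter sequence + coordinates + residue ids
chain_ca_trace <- function(model, chain = NULL) {
  a <- model$atoms
  a <- a[!a$is_symmetry_copy & a$name == "CA" &
           toupper(a$resid) %in% names(AA3TO1), , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (!nrow(a)) stop("no Calpha atoms found")
  if (is.null(chain)) a <- a[a$chain == a$chain[1], , drop = FALSE]
  a <- a[order(a$resno), , drop = FALSE]
  list(seq = unname(AA3TO1[toupper(a$resid)]), xyz = atom_xyz(a),
       resno = a$resno, chain = a$chain[1])
}

#' Superpose two structures on sequence-paired Calpha atoms
#'
#' Residues are paired by global (Needleman-Wunsch, BLOSUM62, affine gaps)
#' alignment of the chain sequences; matched Calpha pairs are then superposed
#' with \code{\link{kabsch_superpose}}. Optional iterative trimming drops
#' pairs deviating by more than \code{trim_cap} Angstrom after superposition
#' and repeats to convergence (the rejection-cycle behaviour of common
#' structure-alignment tools); the default is no trimming, which is fully
#' deterministic.
#'
#' @param model_a,model_b \code{\link{structure_model}} objects.
#' @param chain_a,chain_b chain to use from each model (default: first chain).
#' @param trim enable iterative outlier rejection (default FALSE).
#' @param trim_cap deviation cap in Angstrom for trimming (default 2.0).
#' @return \code{superposition} object with an added \code{pairing}
#'   data.frame (residue numbers paired) and \code{n_trimmed}.
#' @export
align_structures <- function(model_a, model_b, chain_a = NULL, chain_b = NULL,
                             trim = FALSE, trim_cap = 2.0) {
  ta <- chain_ca_trace(model_a, chain_a)
  tb <- chain_ca_trace(model_b, chain_b)
  al <- nw_align(paste(ta$seq, collapse = ""), paste(tb$seq, collapse = ""))
  ia <- 0L; ib <- 0L
  pa <- integer(); pb <- integer()
  for (k in seq_along(al$aln_a)) {
    ca <- al$aln_a[k]; cb <- al$aln_b[k]
    if (ca != "-") ia <- ia + 1L
    if (cb != "-") ib <- ib + 1L
    if (ca != "-" && cb != "-") { pa <- c(pa, ia); pb <- c(pb, ib) }
  }
  if (length(pa) < 3) stop("fewer than 3 alignable residues")
  keep <- seq_along(pa)
  repeat {
    sup <- kabsch_superpose(ta$xyz[pa[keep], , drop = FALSE],
                            tb$xyz[pb[keep], , drop = FALSE])
    if (!trim) break
    dev <- sqrt(rowSums((sup$transformed -
                           ta$xyz[pa[keep], , drop = FALSE])^2))
    drop <- dev > trim_cap
    if (!any(drop) || sum(!drop) < 3) break
    keep <- keep[!drop]
  }
  sup$pairing <- data.frame(resno_a = ta$resno[pa[keep]],
                            resno_b = tb$resno[pb[keep]])
  sup$n_trimmed <- length(pa) - length(keep)
  sup
}
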