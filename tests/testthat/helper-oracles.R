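# Shared builders and independent oracles for the test suite. Oracles are
# deliberately written with different algorithms/code paths than the package.

# --- PDB text fixture builder ------------------------------------------------

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz,
                          occ = 1, b = 0, element = substr(name, 1, 1),
                          record = "ATOM", alt = " ") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resid, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, b, toupper(element))
}

minimal_pdb_text <- function() {
  paste(c(
    pdb_atom_line(1, "N", "GLY", "A", 1, c(0, 0, 0), element = "N"),
    pdb_atom_line(2, "CA", "GLY", "A", 1, c(1.45, 0, 0)),
    pdb_atom_line(3, "C", "GLY", "A", 1, c(2.0, 1.3, 0)),
    "END"), collapse = "\n")
}

# --- rigid motions -----------------------------------------------------------

random_rotation <- function() {
  repeat {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    if (abs(det(q) - 1) < 1e-9) return(q)
  }
}

transform_model <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

# --- Kabsch oracle: coarse rotation grid + Nelder-Mead refinement ------------

euler_rot <- function(ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

brute_force_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  obj <- function(ang) sqrt(mean(rowSums((B0 %*% t(euler_rot(ang)) - A0)^2)))
  grid <- seq(0, 2 * pi, length.out = 9)[-9]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a1 in grid) for (a2 in seq(0, pi, length.out = 5)) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best) { best <- v; best_ang <- c(a1, a2, a3) }
  }
  opt <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# --- exhaustive global-alignment oracle (tiny sequences, affine gaps) --------

# enumerates every global alignment of a and b as paths of moves
# (match / gap-in-b / gap-in-a) and scores with BLOSUM62 + affine penalties
enumerate_alignment_score <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  bl <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, score + bl[ca[i], cb[j]], "M")
    if (i <= length(ca))
      rec(i + 1, j,
          score - gap_ext - if (prev == "X") 0 else gap_open, "X")
    if (j <= length(cb))
      rec(i, j + 1,
          score - gap_ext - if (prev == "Y") 0 else gap_open, "Y")
  }
  rec(1, 1, 0, "M")
  best
}

# --- structure helpers -------------------------------------------------------

# synthetic Calpha-trace protein: smooth seeded random walk, 3.8 A steps
make_ca_model <- function(sequence, seed = 1, id = "ca_model") {
  aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  chars <- strsplit(sequence, "")[[1]]
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * length(chars)), ncol = 3)
  dirs <- dirs + 2  # bias so the walk extends instead of folding back
  dirs <- dirs / sqrt(rowSums(dirs^2))
  xyz <- apply(dirs * 3.8, 2, cumsum)
  atoms <- data.frame(
    eleno = seq_along(chars), name = "CA", alt = "",
    resid = unname(aa1to3[chars]), chain = "A",
    resno = seq_along(chars), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = 0, element = "C", het = FALSE, stringsAsFactors = FALSE)
  structure_model(id, atoms)
}

# complete TRP side-chain ring system in the z = 0 plane (both rings planar,
# shared CD2-CE2 edge); chemically idealized, good enough for ring detection
make_trp_atoms <- function(chain = "A", resno = 1) {
  r5 <- 1.17
  ang <- seq(90, 90 + 288, by = 72) * pi / 180
  pent <- cbind(r5 * cos(ang), r5 * sin(ang), 0)
  rownames(pent) <- c("CG", "CD1", "NE1", "CE2", "CD2")
  e1 <- pent["CD2", ]; e2 <- pent["CE2", ]
  mid <- (e1 + e2) / 2
  s <- sqrt(sum((e1 - e2)^2))
  out_dir <- mid / sqrt(sum(mid^2)) * -1  # away from pentagon centre (origin)
  centre6 <- mid - out_dir * 0  # placed below
  # regular hexagon with edge e1-e2: centre at distance s*sqrt(3)/2 from mid
  perp <- c(-(e2 - e1)[2], (e2 - e1)[1], 0); perp <- perp / sqrt(sum(perp^2))
  if (sum(perp * mid) > 0) perp <- -perp  # point away from the pentagon
  c6 <- mid + perp * s * sqrt(3) / 2
  hexa <- t(sapply(0:5, function(k) {
    v <- e1 - c6
    th <- k * pi / 3
    Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                 byrow = TRUE)
    c6 + as.numeric(Rz %*% v)
  }))
  # order hexagon vertices starting at CD2 (= e1) going around
  nm6 <- c("CD2", "CZ3", "CH2", "CZ2", "CE2", "CE3")
  # identify which rotation lands on e2 to name correctly: find vertex == e2
  i_e2 <- which(apply(hexa, 1, function(p) sum((p - e2)^2)) < 1e-9)
  nm6 <- rep(NA_character_, 6)
  nm6[1] <- "CD2"; nm6[i_e2] <- "CE2"
  rest <- setdiff(1:6, c(1, i_e2))
  nm6[rest] <- c("CE3", "CZ3", "CH2", "CZ2")[seq_along(rest)]
  keep <- !nm6 %in% c("CD2", "CE2")
  pos <- rbind(pent, hexa[keep, , drop = FALSE])
  nms <- c(rownames(pent), nm6[keep])
  data.frame(eleno = seq_along(nms), name = nms, alt = "", resid = "TRP",
             chain = chain, resno = resno,
             x = pos[, 1], y = pos[, 2], z = pos[, 3], o = 1, b = 0,
             element = ifelse(startsWith(nms, "N"), "N", "C"), het = FALSE,
             stringsAsFactors = FALSE)
}

ubr_fixture_path <- function() {
  system.file("extdata", "synthetic_ubr_boxes.fasta", package = "degronstruct")
}
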