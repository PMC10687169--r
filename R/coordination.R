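# Donor classification for coordination patterns: cysteine sulfur -> "C",
# histidine ring nitrogen -> "H", anything else (incl. water O) -> "X".
donor_class <- function(resid, name) {
  resid <- toupper(resid)
  ifelse(resid == "CYS" & name == "SG", "C",
         ifelse(resid == "HIS" & name %in% c("ND1", "NE2"), "H", "X"))
}

#' Find metal coordination sites
#'
#' One site per metal atom; donors are N/O/S atoms (protein or solvent, but
#' never another metal) within \code{cutoff}, sorted by distance. The default
#' 3.0 A cutoff comfortably includes first-shell Zn-S (~2.3 A) and Zn-N/O
#' (~2.1 A) bonds while excluding the second shell.
#'
#' @param model a \code{\link{structure_model}}.
#' @param metals character vector of metal element symbols (default "Zn").
#' @param cutoff coordination distance cutoff in Angstrom (default 3.0).
#' @param include_copies search symmetry-copy atoms too (default FALSE).
#' @return list of \code{metal_site} objects, ordered by (chain, resno) of
#'   the metal atom.
#' @export
find_metal_sites <- function(model, metals = "Zn", cutoff = 3.0,
                             include_copies = FALSE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  a <- model$atoms
  if (!include_copies) a <- a[!a$is_symmetry_copy, , drop = FALSE]
  met <- a[toupper(a$element) %in% toupper(metals), , drop = FALSE]
  met <- met[order(met$chain, met$resno, met$name), , drop = FALSE]
  if (!nrow(met)) return(list())
  don_pool <- a[toupper(a$element) %in% c("N", "O", "S"), , drop = FALSE]
  lapply(seq_len(nrow(met)), function(i) {
    m <- met[i, ]
    d <- sqrt((don_pool$x - m$x)^2 + (don_pool$y - m$y)^2 +
              (don_pool$z - m$z)^2)
    keep <- which(d <= cutoff)
    keep <- keep[order(d[keep], don_pool$chain[keep], don_pool$resno[keep],
                       don_pool$name[keep])]
    donors <- don_pool[keep, , drop = FALSE]
    donors$distance <- d[keep]
    structure(list(metal = m, donors = donors,
                   pattern = pattern_string(donors)),
              class = "metal_site")
  })
}

pattern_string <- function(donors) {
  if (!nrow(donors)) return("C0H0")
  cls <- donor_class(donors$resid, donors$name)
  # count unique coordinating residues per class
  key <- paste(donors$chain, donors$resno, donors$resid, cls, sep = "\r")
  cls_u <- cls[!duplicated(key)]
  n_c <- sum(cls_u == "C"); n_h <- sum(cls_u == "H"); n_x <- sum(cls_u == "X")
  out <- ""
  if (n_c > 0) out <- paste0(out, "C", n_c)
  if (n_h > 0) out <- paste0(out, "H", n_h)
  if (n_x > 0) out <- paste0(out, "X", n_x)
  if (out == "") "C0H0" else out
}

#' Coordination pattern of a metal site
#'
#' Canonical residue-class count string: "C{n}" for coordinating cysteines
#' (via SG), "H{m}" for histidines (via ND1/NE2), "X{k}" for any other donor
#' residue (waters included), classes in C, H, X order and zero counts
#' omitted. A donor-less site yields "C0H0" with a warning.
#'
#' @param site a \code{metal_site} from \code{\link{find_metal_sites}}.
#' @return pattern string.
#' @export
coordination_pattern <- function(site) {
  stopifnot(inherits(site, "metal_site"))
  if (!nrow(site$donors)) {
    warning("metal site has no donors within cutoff", call. = FALSE)
    return("C0H0")
  }
  pattern_string(site$donors)
}

#' @export
print.metal_site <- function(x, ...) {
  cat(sprintf("metal_site %s %s%s: %d donors, pattern %s\n",
              x$metal$element, x$metal$chain, x$metal$resno,
              nrow(x$donors), x$pattern))
  if (nrow(x$donors))
    print(x$donors[, c("chain", "resno", "resid", "name", "distance")],
          row.names = FALSE)
  invisible(x)
}

#' Find hydrogen bonds between two selections
#'
#' Heavy-atom criterion: N/O/S atom pairs, one from each selection, within
#' \code{max_distance} (default 3.5 A). Pairs within the same residue and
#' pairs closer than 1.8 A (covalent range) are excluded. Without hydrogens
#' no donor/acceptor assignment or angle term is attempted; each contact is
#' reported once as a geometric bond.
#'
#' @param model a \code{\link{structure_model}} (used only when a selection is
#'   NULL, in which case all atoms are taken).
#' @param selection_a,selection_b atom data.frames (e.g. from
#'   \code{\link{select_atoms}}).
#' @param max_distance heavy-atom distance cutoff (default 3.5 A).
#' @return data.frame, one row per bond, sorted by distance.
#' @export
find_hbonds <- function(model = NULL, selection_a, selection_b,
                        max_distance = 3.5) {
  polar <- function(s) s[toupper(s$element) %in% c("N", "O", "S"), ,
                         drop = FALSE]
  A <- polar(selection_a); B <- polar(selection_b)
  empty <- data.frame(atom_a = character(), atom_b = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(A) || !nrow(B)) return(empty)
  rows <- list()
  for (i in seq_len(nrow(A))) {
    d <- sqrt((B$x - A$x[i])^2 + (B$y - A$y[i])^2 + (B$z - A$z[i])^2)
    same_res <- B$chain == A$chain[i] & B$resno == A$resno[i] &
      B$resid == A$resid[i]
    hit <- which(d <= max_distance & d >= 1.8 & !same_res)
    for (j in hit)
      rows[[length(rows) + 1]] <- data.frame(
        atom_a = paste0(A$chain[i], "/", A$resid[i], A$resno[i], "/", A$name[i]),
        atom_b = paste0(B$chain[j], "/", B$resid[j], B$resno[j], "/", B$name[j]),
        distance = d[j], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(pmin(out$atom_a, out$atom_b),
                               pmax(out$atom_a, out$atom_b))), , drop = FALSE]
  out <- out[order(out$distance, out$atom_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count waters near an anchor selection
#'
#' Unique water oxygen atoms within \code{cutoff} of any anchor atom.
#'
#' @param model a \code{\link{structure_model}} including solvent.
#' @param anchor atom data.frame (e.g. a side chain from
#'   \code{\link{select_atoms}}).
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @return list with \code{count} and \code{waters} (atom data.frame).
#' @export
waters_near <- function(model, anchor, cutoff = 4.0) {
  w <- model$atoms[is_water_name(model$atoms$resid) &
                     toupper(model$atoms$element) == "O", , drop = FALSE]
  if (!nrow(w) || !nrow(anchor))
    return(list(count = 0L, waters = w[0, , drop = FALSE]))
  keep <- logical(nrow(w))
  for (i in seq_len(nrow(anchor))) {
    d2 <- (w$x - anchor$x[i])^2 + (w$y - anchor$y[i])^2 +
      (w$z - anchor$z[i])^2
    keep <- keep | d2 <= cutoff^2
  }
  out <- w[keep, , drop = FALSE]
  out <- out[order(out$chain, out$resno, out$name), , drop = FALSE]
  list(count = nrow(out), waters = out)
}
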