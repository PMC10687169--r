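ATOM_COLS <- c("eleno", "name", "alt", "resid", "chain", "resno",
               "x", "y", "z", "o", "b", "element", "het",
               "is_symmetry_copy", "sym_op")

#' Construct a structure model
#'
#' Container for a macromolecular structure: an atom table plus (optionally)
#' the crystallographic unit cell, space group and symmetry operators.
#' Symmetry operators are stored as Cartesian 3x4 matrices (rotation |
#' translation in Angstrom), the convention of PDB REMARK 290 SMTRY records.
#'
#' @param id structure identifier.
#' @param atoms data.frame with columns \code{eleno, name, alt, resid, chain,
#'   resno, x, y, z, o, b, element, het}; the bookkeeping columns
#'   \code{is_symmetry_copy} and \code{sym_op} are added when missing.
#' @param unit_cell numeric length-6 vector \code{(a, b, c, alpha, beta,
#'   gamma)}, lengths in Angstrom and angles in degrees, or NULL.
#' @param space_group Hermann-Mauguin symbol, or NULL.
#' @param sym_ops list of 3x4 Cartesian operator matrices, or NULL.
#' @return An object of class \code{structure_model}.
#' @export
structure_model <- function(id, atoms, unit_cell = NULL, space_group = NULL,
                            sym_ops = NULL) {
  stopifnot(is.data.frame(atoms))
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$is_symmetry_copy)) atoms$is_symmetry_copy <- FALSE
  if (is.null(atoms$sym_op)) atoms$sym_op <- ""
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("non-finite atom coordinates in model '", id, "'")
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE))
    stop("occupancies outside [0, 1]")
  if (!is.null(unit_cell)) {
    unit_cell <- as.numeric(unit_cell)
    if (length(unit_cell) != 6 || any(unit_cell[1:3] <= 0))
      stop("unit_cell must be 6 numbers with positive lengths")
    names(unit_cell) <- c("a", "b", "c", "alpha", "beta", "gamma")
  }
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, unit_cell = unit_cell,
                 space_group = space_group, sym_ops = sym_ops),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model '", x$id, "': ", nrow(a), " atoms, ",
      length(unique(a$chain[!a$is_symmetry_copy])), " chains",
      if (any(a$is_symmetry_copy))
        paste0(" (+", sum(a$is_symmetry_copy), " symmetry-copy atoms)"),
      "\n", sep = "")
  if (!is.null(x$unit_cell))
    cat("  cell: ", paste(signif(x$unit_cell, 6), collapse = " "),
        "  [", x$space_group %||% "?", "], ",
        length(x$sym_ops %||% list()), " symmetry ops\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

is_water_name <- function(resid) toupper(resid) %in% WATER_NAMES

#' Read a macromolecular structure
#'
#' Parses a PDB or mmCIF file into a \code{\link{structure_model}}. Atom
#' records are read with bio3d; the unit cell, space group and symmetry
#' operators (PDB \code{CRYST1} / \code{REMARK 290 SMTRY}, mmCIF
#' \code{_cell.*} / \code{_symmetry*} categories) are extracted from the file
#' text. Alternate locations are collapsed to a single conformer per atom:
#' the highest-occupancy altloc wins, ties resolved in favour of altloc "A"
#' (alphabetical order).
#'
#' @param source path to a structure file, or a character scalar containing
#'   the file text itself (detected by embedded newlines).
#' @param format "pdb", "mmcif", or "auto" (default: guess from the file name
#'   extension, falling back to content sniffing).
#' @return A \code{\link{structure_model}}.
#' @export
parse_structure <- function(source, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (length(source) != 1 || !is.character(source))
    stop("source must be a single path or text string")
  if (grepl("\n", source)) {
    path <- tempfile(fileext = if (format == "mmcif") ".cif" else ".pdb")
    writeLines(strsplit(source, "\n")[[1]], path)
    on.exit(unlink(path))
  } else {
    path <- source
    if (!file.exists(path)) stop("no such structure file: ", path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif"
              else if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)) "pdb"
              else {
                head_txt <- readLines(path, n = 50, warn = FALSE)
                if (any(grepl("^(data_|_atom_site)", head_txt))) "mmcif" else "pdb"
              }
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(lines)))
    stop("empty structure file: ", path)

  raw <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- raw$atom
  if (!nrow(at)) stop("no atom records in ", path)
  atoms <- data.frame(
    eleno = as.integer(at$eleno),
    name = trimws(at$elety),
    alt = ifelse(is.na(at$alt) | at$alt == "" , "", trimws(at$alt)),
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", trimws(at$chain)),
    resno = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    element = guess_element(at$elesy, at$elety),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  atoms <- collapse_altlocs(atoms)

  meta <- if (format == "pdb") read_pdb_symmetry(lines) else read_cif_symmetry(lines)
  structure_model(id = sub("\\.[^.]+$", "", basename(path)), atoms = atoms,
                  unit_cell = meta$unit_cell, space_group = meta$space_group,
                  sym_ops = meta$sym_ops)
}

guess_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  bad <- is.na(el) | el == ""
  if (any(bad)) {
    nm <- gsub("[^A-Za-z]", "", trimws(elety[bad]))
    two <- toupper(substr(nm, 1, 2))
    el[bad] <- ifelse(two %in% c("ZN", "FE", "MG", "MN", "CA", "NA", "CL",
                                 "CU", "NI", "CO", "BR"),
                      two, toupper(substr(nm, 1, 1)))
  }
  # normalise e.g. "Zn" vs "ZN"
  paste0(substr(el, 1, 1), tolower(substr(el, 2, 10)))
}

# Keep one conformer per atom: highest occupancy, ties to the alphabetically
# first altloc (so 'A' beats 'B' at equal occupancy).
collapse_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$o, ifelse(atoms$alt == "", "A", atoms$alt))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$eleno), , drop = FALSE]
}

read_pdb_symmetry <- function(lines) {
  out <- list(unit_cell = NULL, space_group = NULL, sym_ops = NULL)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    cr <- cr[1]
    cell <- suppressWarnings(as.numeric(c(
      substr(cr, 7, 15), substr(cr, 16, 24), substr(cr, 25, 33),
      substr(cr, 34, 40), substr(cr, 41, 47), substr(cr, 48, 54))))
    if (all(is.finite(cell)) && all(cell[1:3] > 0)) {
      out$unit_cell <- cell
      out$space_group <- trimws(substr(cr, 56, 66))
    }
  }
  sm <- grep("^REMARK 290 +SMTRY", lines, value = TRUE)
  if (length(sm)) {
    fields <- lapply(sm, function(l) {
      toks <- strsplit(trimws(sub("^REMARK 290", "", l)), " +")[[1]]
      # SMTRYr  opno  m1 m2 m3 t
      list(row = as.integer(substr(toks[1], 6, 6)), op = as.integer(toks[2]),
           vals = as.numeric(toks[3:6]))
    })
    ops <- list()
    for (f in fields) {
      if (is.na(f$op) || is.na(f$row)) next
      if (length(ops) < f$op) ops[[f$op]] <- matrix(0, 3, 4)
      ops[[f$op]][f$row, ] <- f$vals
    }
    if (length(ops)) out$sym_ops <- ops
  }
  out
}

read_cif_symmetry <- function(lines) {
  out <- list(unit_cell = NULL, space_group = NULL, sym_ops = NULL)
  grab <- function(tag) {
    hit <- grep(paste0("^", tag, "[[:space:]]"), lines, value = TRUE)
    if (!length(hit)) return(NA)
    val <- trimws(sub(paste0("^", tag), "", hit[1]))
    gsub("^['\"]|['\"]$", "", val)
  }
  cell <- suppressWarnings(as.numeric(c(
    grab("_cell\\.length_a"), grab("_cell\\.length_b"), grab("_cell\\.length_c"),
    grab("_cell\\.angle_alpha"), grab("_cell\\.angle_beta"),
    grab("_cell\\.angle_gamma"))))
  if (all(is.finite(cell)) && all(cell[1:3] > 0)) out$unit_cell <- cell
  sg <- grab("_symmetry\\.space_group_name_H-M")
  if (is.na(sg)) sg <- grab("_symmetry_space_group_name_H-M")
  if (!is.na(sg)) out$space_group <- sg

  # explicit operator loops (fractional xyz strings), when present
  opl <- grep("^[12][0-9]* +['\"]?[-+xyzXYZ0-9/, ]+['\"]?$", lines, value = TRUE)
  idx <- grep("_symmetry_equiv\\.?(_)?pos_as_xyz|_space_group_symop\\.?operation_xyz",
              lines)
  if (length(idx) && !is.null(out$unit_cell)) {
    xyz <- character()
    for (i in seq(idx[1] + 1, length(lines))) {
      l <- trimws(lines[i])
      if (l == "" || startsWith(l, "_") || startsWith(l, "loop_") ||
          startsWith(l, "#")) break
      m <- regmatches(l, regexpr("['\"][^'\"]+['\"]|[-+0-9/xyzXYZ,. ]+$", l))
      if (length(m)) xyz <- c(xyz, gsub("['\"]", "", m))
    }
    xyz <- trimws(xyz)
    xyz <- xyz[grepl("[xyzXYZ]", xyz)]
    if (length(xyz)) {
      O <- orthogonalization_matrix(out$unit_cell)
      Oinv <- solve(O)
      out$sym_ops <- lapply(xyz, function(s) {
        fr <- parse_symop_xyz(s)
        cbind(O %*% fr[, 1:3] %*% Oinv, O %*% fr[, 4])
      })
    }
  }
  out
}

#' Parse a fractional symmetry-operator string
#'
#' Converts an xyz-style operator such as \code{"-x,y+1/2,-z+1/2"} into a
#' fractional 3x4 matrix (rotation | translation).
#'
#' @param s operator string, comma-separated components in x, y, z.
#' @return 3x4 numeric matrix in fractional coordinates.
#' @export
parse_symop_xyz <- function(s) {
  comps <- strsplit(gsub(" ", "", tolower(s)), ",")[[1]]
  if (length(comps) != 3) stop("malformed symmetry operator: ", s)
  m <- matrix(0, 3, 4)
  for (i in 1:3) {
    expr <- comps[i]
    # tokenize signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (t in terms) {
      sign <- if (startsWith(t, "-")) -1 else 1
      body <- sub("^[+-]", "", t)
      if (body %in% c("x", "y", "z")) {
        m[i, match(body, c("x", "y", "z"))] <- sign
      } else if (grepl("/", body)) {
        fr <- as.numeric(strsplit(body, "/")[[1]])
        m[i, 4] <- m[i, 4] + sign * fr[1] / fr[2]
      } else {
        v <- suppressWarnings(as.numeric(body))
        if (is.na(v)) stop("malformed symmetry operator term: ", t)
        m[i, 4] <- m[i, 4] + sign * v
      }
    }
  }
  m
}

#' Cell orthogonalization matrix
#'
#' Matrix O mapping fractional to Cartesian coordinates for a unit cell
#' (a along x, b in the xy plane; the PDB convention).
#'
#' @param cell numeric length-6: a, b, c (Angstrom), alpha, beta, gamma (deg).
#' @return 3x3 numeric matrix.
#' @export
orthogonalization_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
            2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, cc * v / sin(ga)), 3, 3, byrow = TRUE)
}

#' Write a structure model as PDB
#'
#' Emits CRYST1 and REMARK 290 SMTRY records when the model carries a unit
#' cell / symmetry operators, then the atom records (via bio3d). Symmetry-copy
#' atoms are skipped unless \code{include_copies = TRUE}.
#'
#' @param model a \code{\link{structure_model}}.
#' @param path output file path.
#' @param include_copies write symmetry-copy atoms too (default FALSE).
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(model, path, include_copies = FALSE) {
  a <- model$atoms
  if (!include_copies) a <- a[!a$is_symmetry_copy, , drop = FALSE]
  chains <- a$chain
  if (any(nchar(chains) > 1)) {
    map <- stats::setNames(
      c(LETTERS, letters, 0:9)[seq_along(unique(chains))], unique(chains))
    chains <- unname(map[chains])
  }
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   eleno = seq_len(nrow(a)), elety = a$name,
                   resid = a$resid, chain = chains, resno = a$resno,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   o = a$o, b = a$b, elesy = toupper(a$element))
  body <- readLines(tmp, warn = FALSE)
  unlink(tmp)
  hdr <- character()
  if (!is.null(model$unit_cell)) {
    cl <- model$unit_cell
    hdr <- c(hdr, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                          cl[1], cl[2], cl[3], cl[4], cl[5], cl[6],
                          model$space_group %||% "P 1"))
  }
  if (!is.null(model$sym_ops)) {
    for (k in seq_along(model$sym_ops)) {
      op <- model$sym_ops[[k]]
      for (r in 1:3)
        hdr <- c(hdr, sprintf(
          "REMARK 290   SMTRY%d %3d%10.6f%10.6f%10.6f%15.5f",
          r, k, op[r, 1], op[r, 2], op[r, 3], op[r, 4]))
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate crystallographic symmetry mates
#'
#' Augments a model with symmetry- and lattice-translated copies of its atoms
#' that come within \code{radius} of the asymmetric unit. Copies are flagged
#' \code{is_symmetry_copy}, labelled by operator index and lattice shift
#' (e.g. \code{"op2[0,1,0]"}), and given distinct chain labels
#' (\code{"A:op2[0,1,0]"}) so downstream contact searches treat them as
#' separate molecules. Original atoms are left untouched.
#'
#' @param model a \code{\link{structure_model}} with unit cell and symmetry
#'   operators.
#' @param radius contact search radius in Angstrom (default 5.0).
#' @param max_shift lattice translation search range in each direction
#'   (default 1, i.e. shifts in \{-1, 0, 1\}^3).
#' @return The augmented \code{\link{structure_model}}.
#' @export
expand_symmetry <- function(model, radius = 5.0, max_shift = 1L) {
  if (is.null(model$unit_cell) || is.null(model$sym_ops))
    stop("model '", model$id, "' has no unit cell / symmetry operators; ",
         "run the contact search without symmetry expansion")
  orig <- model$atoms[!model$atoms$is_symmetry_copy, , drop = FALSE]
  X <- as.matrix(orig[, c("x", "y", "z")])
  O <- orthogonalization_matrix(model$unit_cell)
  shifts <- as.matrix(expand.grid(na = -max_shift:max_shift,
                                  nb = -max_shift:max_shift,
                                  nc = -max_shift:max_shift))
  copies <- list()
  for (k in seq_along(model$sym_ops)) {
    op <- model$sym_ops[[k]]
    Xk <- X %*% t(op[, 1:3])
    Xk <- sweep(Xk, 2, op[, 4], "+")
    for (s in seq_len(nrow(shifts))) {
      nvec <- shifts[s, ]
      identity_copy <- all(nvec == 0) &&
        max(abs(op[, 1:3] - diag(3))) < 1e-9 && max(abs(op[, 4])) < 1e-9
      if (identity_copy) next
      tvec <- as.numeric(O %*% nvec)
      Xs <- sweep(Xk, 2, tvec, "+")
      if (min_intermodel_distance(Xs, X, radius) > radius) next
      cp <- orig
      cp$x <- Xs[, 1]; cp$y <- Xs[, 2]; cp$z <- Xs[, 3]
      lab <- sprintf("op%d[%d,%d,%d]", k, nvec[1], nvec[2], nvec[3])
      cp$is_symmetry_copy <- TRUE
      cp$sym_op <- lab
      cp$chain <- paste0(cp$chain, ":", lab)
      copies[[length(copies) + 1]] <- cp
    }
  }
  if (length(copies)) {
    all_atoms <- rbind(model$atoms, do.call(rbind, copies))
    all_atoms$eleno <- seq_len(nrow(all_atoms))
    model$atoms <- all_atoms
  }
  model
}

# minimum distance between two coordinate sets, with a bounding-box shortcut;
# returns Inf early when the boxes are separated by more than `radius`
min_intermodel_distance <- function(A, B, radius) {
  gap <- pmax(apply(B, 2, min) - apply(A, 2, max),
              apply(A, 2, min) - apply(B, 2, max), 0)
  if (sqrt(sum(gap^2)) > radius) return(Inf)
  min_d2 <- Inf
  step <- max(1L, floor(2e6 / nrow(B)))
  for (i in seq(1, nrow(A), by = step)) {
    ii <- i:min(i + step - 1, nrow(A))
    d2 <- outer(rowSums(A[ii, , drop = FALSE]^2), rowSums(B^2), "+") -
      2 * A[ii, , drop = FALSE] %*% t(B)
    min_d2 <- min(min_d2, d2)
  }
  sqrt(max(min_d2, 0))
}

#' Select atoms from a model
#'
#' Returns matching atoms as a data.frame in deterministic
#' (chain, residue number, atom name) order. Filters combine with AND; a
#' custom \code{selector} predicate (function taking the atom data.frame and
#' returning a logical vector) may be supplied instead of, or on top of, the
#' convenience filters.
#'
#' @param model a \code{\link{structure_model}}.
#' @param selector optional predicate \code{function(atoms) -> logical}.
#' @param chain,resno,resid,name,element optional filter values (vectors).
#' @param water TRUE to keep only waters, FALSE to drop them, NULL to ignore.
#' @param include_copies include symmetry-copy atoms (default TRUE).
#' @return data.frame of atom records (possibly 0 rows).
#' @export
select_atoms <- function(model, selector = NULL, chain = NULL, resno = NULL,
                         resid = NULL, name = NULL, element = NULL,
                         water = NULL, include_copies = TRUE) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!include_copies) keep <- keep & !a$is_symmetry_copy
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resid)) keep <- keep & toupper(a$resid) %in% toupper(resid)
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element))
    keep <- keep & toupper(a$element) %in% toupper(element)
  if (!is.null(water)) keep <- keep & (is_water_name(a$resid) == water)
  if (!is.null(selector)) keep <- keep & selector(a)
  out <- a[keep, , drop = FALSE]
  out[order(out$chain, out$resno, out$name), , drop = FALSE]
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
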