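# In-package Needleman-Wunsch/Gotoh core with BLOSUM62 (matrix taken from
# Biostrings data) and affine gaps (open 10, extend 0.5). Kept dependency-light
# so the same core drives pairwise alignment, residue pairing for structural
# superposition, and progressive multiple alignment.

.aln_env <- new.env(parent = emptyenv())

get_blosum62 <- function() {
  if (is.null(.aln_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .aln_env$BLOSUM62 <- e$BLOSUM62
  }
  .aln_env$BLOSUM62
}

blosum_lookup <- function(chars) {
  m <- get_blosum62()
  ch <- toupper(chars)
  ch[!ch %in% rownames(m)] <- "X"
  ch
}

# column-vs-column sum-of-pairs score between two profiles (character
# matrices, gap = "-"); mean over non-gap sequence pairs, 0 if none.
profile_col_scores <- function(profA, profB) {
  m <- get_blosum62()
  La <- ncol(profA); Lb <- ncol(profB)
  S <- matrix(0, La, Lb)
  for (i in seq_len(La)) {
    ca <- profA[, i]; ca <- ca[ca != "-"]
    if (!length(ca)) next
    ca <- blosum_lookup(ca)
    for (j in seq_len(Lb)) {
      cb <- profB[, j]; cb <- cb[cb != "-"]
      if (!length(cb)) next
      cb <- blosum_lookup(cb)
      S[i, j] <- mean(m[ca, cb, drop = FALSE])
    }
  }
  S
}

# Gotoh global alignment of two profiles; returns the merged gap pattern as
# an alignment path (list of column indices, 0 = gap).
profile_nw <- function(profA, profB, gap_open = 10, gap_ext = 0.5) {
  La <- ncol(profA); Lb <- ncol(profB)
  S <- profile_col_scores(profA, profB)
  NEG <- -1e18
  M <- matrix(NEG, La + 1, Lb + 1)
  Ix <- matrix(NEG, La + 1, Lb + 1)  # gap in B (A column vs gap)
  Iy <- matrix(NEG, La + 1, Lb + 1)  # gap in A
  # a gap of length L costs gap_open + L * gap_ext (EMBOSS convention)
  M[1, 1] <- 0
  open1 <- gap_open + gap_ext
  for (i in 2:(La + 1)) Ix[i, 1] <- -gap_open - (i - 1) * gap_ext
  for (j in 2:(Lb + 1)) Iy[1, j] <- -gap_open - (j - 1) * gap_ext
  for (i in 2:(La + 1)) {
    for (j in 2:(Lb + 1)) {
      M[i, j] <- S[i - 1, j - 1] +
        max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      Ix[i, j] <- max(M[i - 1, j] - open1, Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - open1, Iy[i, j - 1] - gap_ext)
    }
  }
  # traceback (prefer M, then Ix, then Iy for determinism)
  i <- La + 1; j <- Lb + 1
  state <- which.max(c(M[i, j], Ix[i, j], Iy[i, j]))
  score <- c(M[i, j], Ix[i, j], Iy[i, j])[state]
  path_a <- integer(); path_b <- integer()
  while (i > 1 || j > 1) {
    if (state == 1) {
      path_a <- c(i - 1, path_a); path_b <- c(j - 1, path_b)
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      target <- M[i, j] - S[i - 1, j - 1]
      state <- which(abs(prev - target) < 1e-9)[1]
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      path_a <- c(i - 1, path_a); path_b <- c(0, path_b)
      state <- if (abs(M[i - 1, j] - open1 - Ix[i, j]) < 1e-9) 1 else 2
      i <- i - 1
    } else {
      path_a <- c(0, path_a); path_b <- c(j - 1, path_b)
      state <- if (abs(M[i, j - 1] - open1 - Iy[i, j]) < 1e-9) 1 else 3
      j <- j - 1
    }
    if (i == 1 && state == 2) state <- 3
    if (j == 1 && state == 3 && i > 1) state <- 2
  }
  list(path_a = path_a, path_b = path_b, score = score)
}

#' Pairwise global sequence alignment
#'
#' Needleman-Wunsch with affine gaps (Gotoh), BLOSUM62 scoring, gap open 10
#' and gap extension 0.5; a gap of length L costs open + L * ext (the
#' EMBOSS/Biostrings convention).
#'
#' @param seq_a,seq_b amino-acid sequences (character scalars).
#' @param gap_open,gap_ext affine gap penalties (positive).
#' @return list with \code{aln_a}, \code{aln_b} (aligned character vectors,
#'   gap = "-"), \code{score}, and \code{identity} (fraction of identical
#'   aligned positions over alignment length).
#' @export
nw_align <- function(seq_a, seq_b, gap_open = 10, gap_ext = 0.5) {
  ca <- strsplit(toupper(seq_a), "")[[1]]
  cb <- strsplit(toupper(seq_b), "")[[1]]
  if (!length(ca) || !length(cb)) stop("empty sequence")
  if (any(!grepl("[A-Z]", c(ca, cb))))
    stop("invalid (non-letter) residue in sequence")
  pa <- matrix(ca, 1); pb <- matrix(cb, 1)
  res <- profile_nw(pa, pb, gap_open, gap_ext)
  aln_a <- ifelse(res$path_a == 0, "-", ca[pmax(res$path_a, 1)])
  aln_b <- ifelse(res$path_b == 0, "-", cb[pmax(res$path_b, 1)])
  ident <- mean(aln_a == aln_b & aln_a != "-")
  list(aln_a = aln_a, aln_b = aln_b, score = res$score, identity = ident)
}

#' Progressive multiple sequence alignment
#'
#' Progressive alignment over a UPGMA guide tree: all-pairs global alignment
#' gives pairwise identities; average-linkage clustering on (1 - identity)
#' fixes the merge order; profiles are merged by sum-of-pairs
#' Needleman-Wunsch. Deterministic for fixed input.
#'
#' @param sequences named character vector of amino-acid sequences, an
#'   \code{AAStringSet}, or the path to a FASTA file.
#' @return character matrix (sequences x columns, gap = "-") with sequence
#'   ids as rownames; columns are 1-based alignment positions.
#' @export
progressive_align <- function(sequences) {
  seqs <- as_named_sequences(sequences)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  ids <- names(seqs)
  profiles <- lapply(seqs, function(s) {
    m <- matrix(strsplit(toupper(s), "")[[1]], 1)
    m
  })
  for (k in seq_len(n)) rownames(profiles[[k]]) <- ids[k]
  if (n == 2) {
    merged <- merge_profiles(profiles[[1]], profiles[[2]])
    return(merged[ids, , drop = FALSE])
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    al <- nw_align(seqs[i], seqs[j])
    D[i, j] <- D[j, i] <- 1 - al$identity
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  nodes <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    pick <- function(x) if (x < 0) profiles[[-x]] else nodes[[x]]
    nodes[[s]] <- merge_profiles(pick(hc$merge[s, 1]), pick(hc$merge[s, 2]))
  }
  nodes[[n - 1]][ids, , drop = FALSE]
}

merge_profiles <- function(pa, pb) {
  res <- profile_nw(pa, pb)
  ncol_out <- length(res$path_a)
  out <- matrix("-", nrow(pa) + nrow(pb), ncol_out,
                dimnames = list(c(rownames(pa), rownames(pb)), NULL))
  sel_a <- res$path_a > 0
  out[seq_len(nrow(pa)), sel_a] <- pa[, res$path_a[sel_a], drop = FALSE]
  sel_b <- res$path_b > 0
  out[nrow(pa) + seq_len(nrow(pb)), sel_b] <-
    pb[, res$path_b[sel_b], drop = FALSE]
  out
}

as_named_sequences <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences)) {
    ss <- Biostrings::readAAStringSet(sequences)
    seqs <- as.character(ss)
    names(seqs) <- sub(" .*", "", names(ss))
    return(seqs)
  }
  if (methods::is(sequences, "XStringSet")) {
    seqs <- as.character(sequences)
    names(seqs) <- sub(" .*", "", names(sequences))
    return(seqs)
  }
  if (!is.character(sequences) || is.null(names(sequences)))
    stop("sequences must be a named character vector, AAStringSet, or FASTA path")
  bad <- !nzchar(sequences)
  if (any(bad)) stop("empty sequence: ", paste(names(sequences)[bad],
                                               collapse = ", "))
  sequences
}

#' Classify UBR-box sequences into subfamilies by the Zn2-coordinating column
#'
#' Reads the alignment column holding the anchor residue (a position in the
#' ungapped reference sequence, e.g. the Zn2-coordinating cysteine of UBR4)
#' and calls each sequence: histidine in that column -> subfamily 1
#' (UBR1-like), cysteine -> subfamily 2 (UBR4-like), anything else (including
#' a gap) -> unclassified.
#'
#' @param alignment character matrix from \code{\link{progressive_align}}.
#' @param anchor_id rownames entry of the reference sequence.
#' @param anchor_pos 1-based position in the ungapped reference sequence.
#' @return data.frame with \code{id}, \code{zn2_column_residue},
#'   \code{subfamily} ("1", "2", or "unclassified") and the alignment
#'   \code{column} used.
#' @export
classify_subfamily <- function(alignment, anchor_id, anchor_pos) {
  if (!anchor_id %in% rownames(alignment))
    stop("anchor id '", anchor_id, "' not in alignment")
  ref <- alignment[anchor_id, ]
  ungapped <- cumsum(ref != "-")
  col <- match(anchor_pos, ungapped)
  if (is.na(col) || ref[col] == "-")
    stop("anchor position ", anchor_pos, " is gapped/absent in reference")
  res <- toupper(alignment[, col])
  data.frame(id = rownames(alignment),
             zn2_column_residue = res,
             subfamily = ifelse(res == "H", "1",
                                ifelse(res == "C", "2", "unclassified")),
             column = col,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an alignment as FASTA
#'
#' @param alignment character matrix (sequences x columns).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta_alignment <- function(alignment, path) {
  lines <- character()
  for (id in rownames(alignment))
    lines <- c(lines, paste0(">", id),
               paste(alignment[id, ], collapse = ""))
  writeLines(lines, path)
  invisible(path)
}
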