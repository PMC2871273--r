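# PDB and FASTA input/output. File parsing is delegated to bio3d; this layer
# enforces the package's structure invariants (single chain, contiguous
# 1-based numbering, complete N/CA/C/O backbone per residue).

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
             GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
             MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
             TYR = "Y", VAL = "V", MSE = "M")
.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
             E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
             M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
             Y = "TYR", V = "VAL", X = "UNK")

#' Read a backbone structure from a PDB file
#'
#' Keeps a single chain (the first one by default), drops altloc records other
#' than blank/`A`, and renumbers residues contiguously from 1; the original
#' author numbering is preserved in `meta$orig_resno`. Every residue must carry
#' the four backbone atoms N, CA, C and O.
#'
#' @param path PDB file.
#' @param chain chain identifier to keep; `NULL` keeps the first chain found.
#' @return a `fold_structure`.
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path, call. = FALSE)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[is.na(at$chain) | at$chain == chain, , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  key <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  resno_order <- unique(key)
  n <- length(resno_order)
  xyz <- array(NA_real_, dim = c(n, 4L, 3L))
  seq1 <- character(n)
  for (i in seq_len(n)) {
    rows <- at[key == resno_order[i], , drop = FALSE]
    for (j in seq_len(4L)) {
      nm <- c("N", "CA", "C", "O")[j]
      hit <- which(rows$elety == nm)
      if (!length(hit))
        stop(sprintf("residue %s (chain %s) is missing backbone atom %s",
                     trimws(resno_order[i]), chain, nm), call. = FALSE)
      xyz[i, j, ] <- as.numeric(rows[hit[1L], c("x", "y", "z")])
    }
    seq1[i] <- .aa3to1[rows$resid[1L]] %||% NA_character_
    if (is.na(seq1[i])) seq1[i] <- "X"
  }
  fold_structure(seq1, xyz, chain_id = chain,
                 meta = list(source = path,
                             orig_resno = as.integer(sub(" .*$", "", resno_order))))
}

#' Write a backbone structure to a PDB file
#'
#' Fixed-width ATOM records with residues numbered 1..n on a single chain;
#' coordinates are written at the format's three-decimal precision, so
#' write-then-read round-trips coordinates to 1e-3 Angstrom.
#'
#' @param s a `fold_structure`.
#' @param path output file.
#' @export
write_pdb <- function(s, path) {
  n <- n_residues(s)
  elety <- rep(c("N", "CA", "C", "O"), n)
  resno <- rep(seq_len(n), each = 4L)
  resid <- rep(unname(.aa1to3[s$sequence]), each = 4L)
  resid[is.na(resid)] <- "UNK"
  xyz <- as.numeric(t(matrix(aperm(s$xyz, c(2L, 1L, 3L)), ncol = 3L)))
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = rep(s$chain_id, length(elety)))
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
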