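#' Parse a PDB-format coordinate file into a structure model
#'
#' Reads ATOM records and returns a single-chain, single-model structure:
#' the first MODEL of a multi-model (e.g. NMR) file, the requested chain (or
#' the first chain encountered), with alternate locations resolved by highest
#' occupancy (ties prefer altLoc 'A', then blank). HETATM records and
#' hydrogens are ignored.
#'
#' @param pdb_text PDB file content: a single string or a character vector of
#'   lines. Use [read_structure()] to go straight from a file path.
#' @param chain Optional chain identifier. Default: first chain encountered.
#' @return An object of class `structure_model`: a list with `atoms` (data
#'   frame: name, element, residue serial, residue type, x/y/z in Angstrom),
#'   `residues` (ordered data frame with 1-based `serial`), `chain`, and
#'   `sequence` (one-letter amino-acid string).
#' @export
parse_structure <- function(pdb_text, chain = NULL) {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE))
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text
  if (!any(startsWith(lines, "ATOM  ")))
    stop("no ATOM records found in PDB input", call. = FALSE)

  # keep the first MODEL only
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1] - 1L)]

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records found in PDB input", call. = FALSE)

  chains <- unique(at$chain)
  chains[is.na(chains)] <- " "
  at$chain[is.na(at$chain)] <- " "
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains)
    stop(sprintf("chain '%s' not present; available chains: %s",
                 chain, paste(chains, collapse = ", ")), call. = FALSE)
  at <- at[at$chain == chain, , drop = FALSE]

  # element symbol: prefer PDB column, else first letter of the atom name
  elem <- toupper(trimws(if ("elesy" %in% names(at)) at$elesy else ""))
  fallback <- toupper(substr(gsub("[0-9]", "", trimws(at$elety)), 1, 1))
  elem[is.na(elem) | elem == ""] <- fallback[is.na(elem) | elem == ""]
  at$element <- elem
  at <- at[at$element != "H", , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy atoms in selected chain", call. = FALSE)

  # altLoc: per (residue, atom name) keep the highest-occupancy record;
  # ties prefer altLoc 'A', then blank
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  rkey <- paste(at$resno, at$insert, sep = "_")
  akey <- paste(rkey, at$elety, sep = "|")
  pref <- ifelse(at$alt == "A", 2L, ifelse(at$alt == "", 1L, 0L))
  keep <- unlist(lapply(split(seq_len(nrow(at)), akey), function(idx) {
    idx[order(-at$o[idx], -pref[idx])][1]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  rkey <- paste(at$resno, at$insert, sep = "_")

  if (!all(is.finite(at$x)) || !all(is.finite(at$y)) || !all(is.finite(at$z)))
    stop("non-finite coordinates in ATOM records", call. = FALSE)

  serial_of <- stats::setNames(seq_along(unique(rkey)), unique(rkey))
  at$residue <- unname(serial_of[rkey])

  first <- !duplicated(rkey)
  residues <- data.frame(
    serial = at$residue[first],
    resno = at$resno[first],
    insert = at$insert[first],
    resid = at$resid[first],
    aa = suppressWarnings(bio3d::aa321(at$resid[first])),
    stringsAsFactors = FALSE)
  residues$aa[is.na(residues$aa)] <- "X"

  out <- list(
    atoms = data.frame(name = trimws(at$elety), element = at$element,
                       residue = at$residue, resid = at$resid,
                       x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE),
    residues = residues,
    chain = chain,
    sequence = paste(residues$aa, collapse = ""))
  class(out) <- "structure_model"
  out
}

#' @rdname parse_structure
#' @param path Path to a PDB file.
#' @export
read_structure <- function(path, chain = NULL) {
  parse_structure(readLines(path, warn = FALSE), chain = chain)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> chain %s: %d residues, %d heavy atoms\n",
              x$chain, nrow(x$residues), nrow(x$atoms)))
  cat("sequence:", x$sequence, "\n")
  invisible(x)
}
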