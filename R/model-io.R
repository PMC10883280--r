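# Reading and writing of predicted models, native references and score files.
#
# A structure_model keeps atoms as a plain data frame in file order; per-residue
# pLDDT is recovered from the B-factor column, which is where the upstream
# prediction engine stores it.

NUCLEIC_RESIDUES <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT", "DI", "I", "N")

#' Read a predicted or native structure model
#'
#' Parses a PDB file (or mmCIF, intended for native reference structures) into
#' a `structure_model`. HETATM records, hydrogens and nucleic-acid chains are
#' excluded; for alternate locations the highest-occupancy conformer of each
#' residue is kept (ties broken by file order). For predicted models the
#' per-residue pLDDT is read from the B-factor field; within a residue the
#' B-factors are expected to be identical, otherwise their mean is taken with
#' a warning.
#'
#' @param path Path to a PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param predicted Logical; `TRUE` for models produced by the prediction
#'   engine (B-factors are validated as pLDDT in \[0, 100\]).
#' @param model_id Identifier stored on the model; defaults to the file name.
#' @param rank Optional integer rank of the model within its prediction run.
#' @return An object of class `structure_model`: a list with `model_id`,
#'   `predicted`, `rank`, `atoms` (data frame with columns `chain`, `resno`,
#'   `icode`, `resname`, `atom_name`, `element`, `x`, `y`, `z`, `occupancy`,
#'   `b`) and `plddt` (one row per residue, file order).
#' @export
read_model <- function(path, predicted = FALSE, model_id = basename(path),
                       rank = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  parsed <- tryCatch(
    if (is_cif) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("could not parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)

  nuc <- unique(at$chain[at$resid %in% NUCLEIC_RESIDUES])
  if (length(nuc)) {
    warning("skipping nucleic-acid chain(s): ", paste(nuc, collapse = ", "))
    at <- at[!(at$chain %in% nuc), , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no protein atoms left in ", path)

  elem <- at$elesy
  missing_elem <- is.na(elem) | elem == ""
  if (any(missing_elem)) elem[missing_elem] <- guess_element(at$elety[missing_elem])
  at <- at[!(toupper(elem) %in% c("H", "D")), , drop = FALSE]
  elem <- elem[!(toupper(elem) %in% c("H", "D"))]

  icode <- ifelse(is.na(at$insert), "", at$insert)
  occ <- ifelse(is.na(at$o), 1, at$o)
  alt <- ifelse(is.na(at$alt), "", at$alt)

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, icode = icode, resname = at$resid,
    atom_name = at$elety, element = toupper(elem),
    x = at$x, y = at$y, z = at$z, occupancy = occ, b = at$b, alt = alt,
    stringsAsFactors = FALSE
  )
  atoms <- resolve_altloc(atoms)
  atoms$alt <- NULL

  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)

  model <- new_structure_model(atoms, model_id = model_id,
                               predicted = predicted, rank = rank)
  if (predicted) {
    bad <- model$plddt$plddt < 0 | model$plddt$plddt > 100
    if (any(bad))
      stop("predicted model has B-factors outside [0, 100]; ",
           "not a valid pLDDT field (", sum(bad), " residue(s))")
  }
  model
}

# Keep, per residue, the alternate-location conformer with the highest
# occupancy (first in file order on ties), plus all atoms without altloc.
resolve_altloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[atoms$alt != ""])) {
    idx <- which(key == k & atoms$alt != "")
    alts <- atoms$alt[idx]
    occ_by_alt <- vapply(unique(alts), function(a)
      max(atoms$occupancy[idx[alts == a]]), numeric(1))
    best <- unique(alts)[which.max(occ_by_alt)]  # which.max = first on ties
    keep[idx[alts != best]] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", atom_name)
  ifelse(nchar(nm) > 0, substr(nm, 1, 1), "X")
}

new_structure_model <- function(atoms, model_id, predicted = FALSE,
                                rank = NA_integer_) {
  stopifnot(nrow(atoms) > 0)
  rk <- residue_key(atoms)
  uk <- !duplicated(rk)
  res <- atoms[uk, c("chain", "resno", "icode", "resname")]
  rownames(res) <- NULL
  res$plddt <- vapply(split(atoms$b, factor(rk, levels = rk[uk])), function(b) {
    if (diff(range(b)) > 1e-6)
      warning("B-factors differ within a residue; using their mean")
    mean(b)
  }, numeric(1))
  structure(
    list(model_id = model_id, predicted = predicted, rank = rank,
         atoms = atoms, plddt = res),
    class = "structure_model"
  )
}

residue_key <- function(df) paste(df$chain, df$resno, df$icode, sep = "\r")

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model '", x$model_id, "'",
      if (x$predicted) " (predicted)" else "", "\n", sep = "")
  for (ch in unique(x$atoms$chain)) {
    res <- x$plddt[x$plddt$chain == ch, ]
    cat(sprintf("  chain %s: %d residues (%d-%d), %d atoms", ch, nrow(res),
                min(res$resno), max(res$resno), sum(x$atoms$chain == ch)))
    if (x$predicted)
      cat(sprintf(", mean pLDDT %.1f", mean(res$plddt)))
    cat("\n")
  }
  invisible(x)
}

#' Chain identifiers of a structure model
#' @param model A `structure_model`.
#' @return Character vector of chain ids in file order.
#' @export
model_chains <- function(model) unique(model$atoms$chain)

#' Write a structure model to PDB
#'
#' Residue keys, coordinates (to PDB precision) and B-factors round-trip
#' through [read_model()].
#'
#' @param model A `structure_model`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  a <- model$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resname,
                   chain = a$chain,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   elety = a$atom_name, o = a$occupancy, b = a$b,
                   elesy = a$element)
  invisible(path)
}

#' Read a score bundle for one predicted model
#'
#' Consumes the JSON score schema
#' `{"iptm": x, "ptm": x, "model_confidence": x?, "rank": n?, "pae": [[..]]?,
#' "pae_residues": [["chain", number, "icode"], ...]?}`.
#' When `model_confidence` is absent it is computed as
#' `0.8 * ipTM + 0.2 * pTM` (see [model_confidence()]).
#'
#' @param path Path to the score JSON file.
#' @return An object of class `score_bundle`: list with `iptm`, `ptm`,
#'   `model_confidence`, `rank`, `pae` (numeric matrix or `NULL`) and
#'   `pae_residues` (data frame or `NULL`).
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  iptm <- js$iptm; ptm <- js$ptm; mc <- js$model_confidence
  if (is.null(mc) && (is.null(iptm) || is.null(ptm)))
    stop("score file must contain model_confidence or both iptm and ptm")
  if (!is.null(iptm) && (iptm < 0 || iptm > 1)) stop("iptm outside [0, 1]")
  if (!is.null(ptm) && (ptm < 0 || ptm > 1)) stop("ptm outside [0, 1]")
  if (is.null(mc)) {
    mc <- model_confidence(iptm, ptm)
  } else if (!is.null(iptm) && !is.null(ptm) &&
             abs(mc - model_confidence(iptm, ptm)) > 1e-6) {
    warning("stored model_confidence differs from 0.8*ipTM + 0.2*pTM")
  }
  pae <- js$pae
  if (!is.null(pae)) {
    pae <- as.matrix(pae)
    if (nrow(pae) != ncol(pae)) stop("PAE matrix is not square")
    if (any(pae < 0)) stop("PAE values must be >= 0")
  }
  pres <- js$pae_residues
  if (!is.null(pres)) {
    pres <- as.data.frame(pres, stringsAsFactors = FALSE)
    names(pres) <- c("chain", "resno", "icode")[seq_len(ncol(pres))]
    if (is.null(pres$icode)) pres$icode <- ""
    pres$resno <- as.integer(pres$resno)
    if (!is.null(pae) && nrow(pres) != nrow(pae))
      stop("pae_residues length does not match PAE dimension")
  }
  structure(
    list(iptm = if (is.null(iptm)) NA_real_ else iptm,
         ptm = if (is.null(ptm)) NA_real_ else ptm,
         model_confidence = mc,
         rank = if (is.null(js$rank)) NA_integer_ else as.integer(js$rank),
         pae = pae, pae_residues = pres),
    class = "score_bundle"
  )
}

#' @export
print.score_bundle <- function(x, ...) {
  cat(sprintf("score_bundle: ipTM %.3f, pTM %.3f, model confidence %.3f",
              x$iptm, x$ptm, x$model_confidence))
  if (!is.na(x$rank)) cat(", rank", x$rank)
  if (!is.null(x$pae)) cat(sprintf(", PAE %dx%d", nrow(x$pae), ncol(x$pae)))
  cat("\n")
  invisible(x)
}

# Map a score bundle's PAE matrix onto a model's residues; defaults to model
# residue file order when the bundle carries no explicit residue index.
pae_index_for_model <- function(model, scores) {
  if (is.null(scores$pae)) stop("score bundle has no PAE matrix")
  n <- nrow(model$plddt)
  if (nrow(scores$pae) != n)
    stop("PAE dimension (", nrow(scores$pae),
         ") does not match model residue count (", n, ")")
  if (is.null(scores$pae_residues)) {
    idx <- seq_len(n)
    names(idx) <- residue_key(model$plddt)
  } else {
    idx <- seq_len(n)
    names(idx) <- residue_key(scores$pae_residues)
    if (!all(residue_key(model$plddt) %in% names(idx)))
      stop("pae_residues does not cover all model residues")
  }
  idx
}
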