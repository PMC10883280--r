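# Evaluation of predicted models against native reference structures:
# domain-frame superposition, all-atom motif RMSD with accuracy categories,
# DockQ and top-model ensemble similarity.

#' Chain mapping between a model and its native reference
#'
#' @param model_chain,native_chain Chain id pairs.
#' @param role `"domain"` or `"motif"` for each pair.
#' @param residue_offset Integer added to model residue numbers to obtain
#'   native residue numbers.
#' @return A `chain_mapping` data frame.
#' @export
chain_mapping <- function(model_chain, native_chain, role,
                          residue_offset = 0L) {
  stopifnot(length(model_chain) == length(native_chain),
            length(role) == length(model_chain),
            all(role %in% c("domain", "motif")))
  out <- data.frame(model_chain = model_chain, native_chain = native_chain,
                    role = role,
                    residue_offset = rep_len(as.integer(residue_offset),
                                             length(model_chain)),
                    stringsAsFactors = FALSE)
  class(out) <- c("chain_mapping", class(out))
  out
}

#' Read a chain-mapping TSV
#'
#' Columns: `model_chain`, `native_chain`, `role` (domain/motif),
#' `residue_offset`.
#' @param path TSV path.
#' @return A `chain_mapping`.
#' @export
read_chain_mapping <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  chain_mapping(df$model_chain, df$native_chain, df$role,
                if (is.null(df$residue_offset)) 0L else df$residue_offset)
}

# Match atoms of mapped residues between model and native by (native residue
# number, insertion code, atom name); restrict to the given roles.
matched_atoms <- function(model, native, mapping, roles) {
  rows <- mapping[mapping$role %in% roles, , drop = FALSE]
  if (nrow(rows) == 0L) stop("mapping has no chain with role ",
                             paste(roles, collapse = "/"))
  mlist <- list(); nlist <- list()
  for (r in seq_len(nrow(rows))) {
    ma <- model$atoms[model$atoms$chain == rows$model_chain[r], , drop = FALSE]
    na <- native$atoms[native$atoms$chain == rows$native_chain[r], , drop = FALSE]
    if (nrow(ma) == 0L || nrow(na) == 0L)
      stop("mapped chain absent from model or native")
    mkey <- paste(ma$resno + rows$residue_offset[r], ma$icode, ma$atom_name)
    nkey <- paste(na$resno, na$icode, na$atom_name)
    hit <- match(mkey, nkey)
    mlist[[r]] <- ma[!is.na(hit), , drop = FALSE]
    nlist[[r]] <- na[hit[!is.na(hit)], , drop = FALSE]
  }
  m <- do.call(rbind, mlist); n <- do.call(rbind, nlist)
  n_model <- sum(vapply(rows$model_chain,
                        function(ch) sum(model$atoms$chain == ch), numeric(1)))
  list(model = m, native = n, n_unmatched = n_model - nrow(m))
}

coords <- function(df) as.matrix(df[, c("x", "y", "z")])

# Kabsch algorithm: rotation + translation minimizing RMSD of p onto q.
kabsch <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  h <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = rot, translation = as.numeric(cq - rot %*% cp))
}

apply_transform <- function(xyz, tr) {
  sweep(xyz %*% t(tr$rotation), 2, tr$translation, "+")
}

#' Superpose a model on the native domain chain
#'
#' Optimal least-squares (Kabsch) rigid superposition over all heavy atoms
#' shared by mapped domain residues, matched by residue mapping and atom
#' name, with no outlier rejection. The transform is applied to the whole
#' model.
#'
#' @param model,native `structure_model`s.
#' @param mapping A [chain_mapping()].
#' @return Object of class `superposition`: list with `rotation`,
#'   `translation`, `domain_rmsd`, `n_atoms`, `n_unmatched` and
#'   `model_transformed` (the whole model in the native frame).
#' @export
superpose_on_domain <- function(model, native, mapping) {
  mt <- matched_atoms(model, native, mapping, "domain")
  if (nrow(mt$model) < 3L)
    stop("fewer than 3 matched domain atoms; cannot superpose")
  tr <- kabsch(coords(mt$model), coords(mt$native))
  moved <- apply_transform(coords(mt$model), tr)
  rmsd <- sqrt(mean(rowSums((moved - coords(mt$native))^2)))

  model_t <- model
  model_t$atoms[, c("x", "y", "z")] <- apply_transform(coords(model$atoms), tr)
  structure(
    list(rotation = tr$rotation, translation = tr$translation,
         domain_rmsd = rmsd, n_atoms = nrow(mt$model),
         n_unmatched = mt$n_unmatched, model_transformed = model_t),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition on %d domain atoms: RMSD %.3f A\n",
              x$n_atoms, x$domain_rmsd))
  invisible(x)
}

#' Motif RMSD accuracy category
#'
#' `<= 2` correct_sidechain, `(2, 5]` correct_backbone, `(5, 15]`
#' correct_pocket, `> 15` wrong_pocket (upper bounds inclusive).
#'
#' @param rmsd Non-negative RMSD in Angstrom.
#' @return Factor level among the four categories.
#' @export
rmsd_category <- function(rmsd) {
  stopifnot(all(rmsd >= 0))
  cut(rmsd, breaks = c(-Inf, 2, 5, 15, Inf),
      labels = c("correct_sidechain", "correct_backbone", "correct_pocket",
                 "wrong_pocket"))
}

#' All-atom motif RMSD in the domain-superposed frame
#'
#' RMSD over all shared heavy atoms of mapped motif residues after the domain
#' superposition, matched strictly by atom identifiers, with no refinement or
#' outlier rejection. Atoms present on only one side are dropped with a
#' warning and counted. A model is deemed accurate when the motif RMSD is
#' at most 5 A.
#'
#' @inheritParams superpose_on_domain
#' @param superposition Optional precomputed [superpose_on_domain()] result.
#' @return Object of class `motif_rmsd`: list with `rmsd`, `n_atoms`,
#'   `n_unmatched`, `category` and `accurate`.
#' @export
motif_all_atom_rmsd <- function(model, native, mapping, superposition = NULL) {
  if (is.null(superposition))
    superposition <- superpose_on_domain(model, native, mapping)
  mt <- matched_atoms(superposition$model_transformed, native, mapping, "motif")
  if (nrow(mt$model) == 0L) stop("no shared motif atoms between model and native")
  if (mt$n_unmatched > 0L)
    warning(mt$n_unmatched, " motif atom(s) without a counterpart were dropped")
  rmsd <- sqrt(mean(rowSums((coords(mt$model) - coords(mt$native))^2)))
  structure(
    list(rmsd = rmsd, n_atoms = nrow(mt$model), n_unmatched = mt$n_unmatched,
         category = as.character(rmsd_category(rmsd)), accurate = rmsd <= 5),
    class = "motif_rmsd"
  )
}

#' @export
print.motif_rmsd <- function(x, ...) {
  cat(sprintf("motif RMSD %.3f A over %d atoms: %s (%saccurate)\n", x$rmsd,
              x$n_atoms, x$category, if (x$accurate) "" else "not "))
  invisible(x)
}

# DockQ scaling constants from the published definition.
DOCKQ_D1 <- 8.5   # ligand RMSD scaling (A)
DOCKQ_D2 <- 1.5   # interface RMSD scaling (A)

dockq_quality <- function(dockq) {
  cut(dockq, breaks = c(-Inf, 0.23, 0.49, 0.80, Inf), right = FALSE,
      labels = c("incorrect", "acceptable", "medium", "high"))
}

backbone_rows <- function(df) df[df$atom_name %in% c("N", "CA", "C", "O"), ,
                                 drop = FALSE]

residue_pairs_in_contact <- function(model, chain_a, chain_b, cutoff) {
  rep <- find_interface(model, c(chain_a, chain_b), cutoff)
  paste(rep$contacts$key_a, rep$contacts$key_b, sep = "\n")
}

#' DockQ of a model against its native reference
#'
#' Components per the published DockQ definition: `fnat` (fraction of native
#' cross-chain residue contacts, 5 A heavy-atom, preserved in the model),
#' `irms` (backbone RMSD over the native 10 A interface residues after
#' superposing on those atoms) and `lrms` (motif/ligand backbone RMSD after
#' superposing on the domain/receptor backbone). The combined score is the
#' mean of `fnat` and the two scaled RMSD terms `1 / (1 + (rms/d)^2)` with
#' d = 1.5 A (irms) and 8.5 A (lrms). Quality classes: `< 0.23` incorrect,
#' `[0.23, 0.49)` acceptable, `[0.49, 0.80)` medium, `>= 0.80` high.
#'
#' @inheritParams superpose_on_domain
#' @return Object of class `dockq_result`: list with `fnat`, `irms`, `lrms`,
#'   `dockq` and `quality`.
#' @export
compute_dockq <- function(model, native, mapping) {
  dom <- mapping[mapping$role == "domain", , drop = FALSE][1, ]
  mot <- mapping[mapping$role == "motif", , drop = FALSE][1, ]

  # fnat: native contacts at 5 A, looked up in the model under the mapping
  nat_pairs <- residue_pairs_in_contact(native, dom$native_chain,
                                        mot$native_chain, 5)
  if (length(nat_pairs) == 0L) stop("native structure has no interface contacts")
  mod_rep <- find_interface(model, c(dom$model_chain, mot$model_chain), 5)
  remap <- function(keys, offset, from, to) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    vapply(parts, function(p)
      paste(to, as.integer(p[2]) + offset, if (length(p) > 2) p[3] else "",
            sep = "\r"), character(1))
  }
  mod_pairs <- paste(
    remap(mod_rep$contacts$key_a, dom$residue_offset, dom$model_chain,
          dom$native_chain),
    remap(mod_rep$contacts$key_b, mot$residue_offset, mot$model_chain,
          mot$native_chain),
    sep = "\n")
  fnat <- mean(nat_pairs %in% mod_pairs)

  # irms: backbone of native interface residues at 10 A
  rep10 <- find_interface(native, c(dom$native_chain, mot$native_chain), 10)
  ikeys <- c(residue_key(rep10$residues[[1]]), residue_key(rep10$residues[[2]]))
  mt <- matched_atoms(model, native, mapping, c("domain", "motif"))
  bb <- mt$native$atom_name %in% c("N", "CA", "C", "O")
  ifc <- residue_key(mt$native) %in% ikeys & bb
  if (sum(ifc) < 3L) stop("fewer than 3 shared interface backbone atoms")
  tr <- kabsch(coords(mt$model[ifc, ]), coords(mt$native[ifc, ]))
  irms <- sqrt(mean(rowSums(
    (apply_transform(coords(mt$model[ifc, ]), tr) - coords(mt$native[ifc, ]))^2)))

  # lrms: superpose on receptor (domain) backbone, RMSD of ligand backbone
  rec <- mt$native$chain == dom$native_chain & bb
  lig <- mt$native$chain == mot$native_chain & bb
  if (sum(rec) < 3L || sum(lig) == 0L)
    stop("insufficient backbone atoms for ligand RMSD")
  tr2 <- kabsch(coords(mt$model[rec, ]), coords(mt$native[rec, ]))
  lrms <- sqrt(mean(rowSums(
    (apply_transform(coords(mt$model[lig, ]), tr2) - coords(mt$native[lig, ]))^2)))

  dockq <- (fnat + 1 / (1 + (irms / DOCKQ_D2)^2) +
              1 / (1 + (lrms / DOCKQ_D1)^2)) / 3
  structure(
    list(fnat = fnat, irms = irms, lrms = lrms, dockq = dockq,
         quality = as.character(dockq_quality(dockq))),
    class = "dockq_result"
  )
}

#' @export
print.dockq_result <- function(x, ...) {
  cat(sprintf("DockQ %.3f (%s): fnat %.3f, iRMS %.2f A, LRMS %.2f A\n",
              x$dockq, x$quality, x$fnat, x$irms, x$lrms))
  invisible(x)
}

#' Mean pairwise DockQ among the top-ranked models
#'
#' Similarity of the top (up to five) models of one prediction run, ranked by
#' model confidence: DockQ is computed for every pair, with the higher-ranked
#' model taking the reference role, and averaged.
#'
#' @param models List of 2-5 `structure_model`s ordered by decreasing model
#'   confidence (rank 1 first). All models share chain ids and numbering.
#' @param domain_chain,motif_chain Chain roles within the shared numbering.
#' @return Mean DockQ over all pairs.
#' @export
mean_pairwise_dockq <- function(models, domain_chain, motif_chain) {
  n <- length(models)
  if (n < 2L) stop("at least two ranked models are required")
  if (n > 5L) stop("at most the top five models are considered")
  map <- chain_mapping(c(domain_chain, motif_chain),
                       c(domain_chain, motif_chain),
                       c("domain", "motif"))
  vals <- c()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    vals <- c(vals, compute_dockq(models[[j]], models[[i]], map)$dockq)
  mean(vals)
}

#' Log2 fold change of motif RMSD upon fragment extension
#'
#' `log2(rmsd_minimal / rmsd_extended)`; positive values mean the extension
#' improved the prediction.
#'
#' @param rmsd_minimal,rmsd_extended Positive motif RMSDs (A) of the minimal
#'   and extended fragment predictions.
#' @return Log2 fold change.
#' @export
extension_fold_change <- function(rmsd_minimal, rmsd_extended) {
  if (any(c(rmsd_minimal, rmsd_extended) <= 0))
    stop("RMSD values must be positive")
  log2(rmsd_minimal / rmsd_extended)
}
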