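# Interface detection and per-model confidence metrics.
#
# An interface residue has at least one heavy atom strictly closer than the
# cutoff (default 5 A) to any heavy atom of the partner chain. All cutoffs in
# this module are strict ("less than").

#' Detect the interface between two chains
#'
#' @param model A `structure_model` (heavy atoms only, guaranteed by
#'   [read_model()]).
#' @param chain_pair Character vector of two chain ids. Defaults to the only
#'   two chains of the model; models with more chains require an explicit
#'   pair.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (strict `<`).
#' @return An object of class `interface_report`: list with `chains`,
#'   `cutoff`, `residues` (named list of per-chain residue data frames),
#'   `residue_contacts`, `atom_contacts` and `contacts` (data frame of
#'   cross-chain residue pairs with their minimal heavy-atom distance and
#'   atom-contact count).
#' @export
find_interface <- function(model, chain_pair = NULL, cutoff = 5) {
  chain_pair <- resolve_chain_pair(model, chain_pair)
  a <- model$atoms[model$atoms$chain == chain_pair[1], , drop = FALSE]
  b <- model$atoms[model$atoms$chain == chain_pair[2], , drop = FALSE]

  d <- cross_distances(as.matrix(a[, c("x", "y", "z")]),
                       as.matrix(b[, c("x", "y", "z")]))
  hit <- d < cutoff
  atom_contacts <- sum(hit)

  if (atom_contacts == 0L) {
    contacts <- data.frame(key_a = character(), key_b = character(),
                           min_distance = numeric(),
                           n_atom_contacts = integer(),
                           stringsAsFactors = FALSE)
  } else {
    ij <- which(hit, arr.ind = TRUE)
    ka <- residue_key(a)[ij[, 1]]
    kb <- residue_key(b)[ij[, 2]]
    pair <- paste(ka, kb, sep = "\n")
    contacts <- data.frame(
      key_a = ka[!duplicated(pair)], key_b = kb[!duplicated(pair)],
      min_distance = as.numeric(tapply(d[hit], pair, min)[unique(pair)]),
      n_atom_contacts = as.integer(table(pair)[unique(pair)]),
      stringsAsFactors = FALSE
    )
  }

  res_of <- function(df, keys) {
    r <- df[!duplicated(residue_key(df)), c("chain", "resno", "icode", "resname")]
    out <- r[residue_key(r) %in% keys, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  residues <- list(res_of(a, unique(contacts$key_a)),
                   res_of(b, unique(contacts$key_b)))
  names(residues) <- chain_pair

  structure(
    list(chains = chain_pair, cutoff = cutoff, residues = residues,
         residue_contacts = nrow(contacts), atom_contacts = atom_contacts,
         contacts = contacts),
    class = "interface_report"
  )
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(
    "interface %s:%s (< %g A): %d | %d interface residues, %d residue and %d atom contacts\n",
    x$chains[1], x$chains[2], x$cutoff, nrow(x$residues[[1]]),
    nrow(x$residues[[2]]), x$residue_contacts, x$atom_contacts))
  invisible(x)
}

resolve_chain_pair <- function(model, chain_pair) {
  chains <- model_chains(model)
  if (is.null(chain_pair)) {
    if (length(chains) != 2L)
      stop("model has ", length(chains),
           " chains; name a chain pair explicitly")
    chain_pair <- chains
  }
  if (length(chain_pair) != 2L || !all(chain_pair %in% chains))
    stop("chain pair must name two chains present in the model")
  chain_pair
}

# Full cross Euclidean distance matrix between two coordinate matrices.
cross_distances <- function(p, q) {
  d2 <- outer(rowSums(p^2), rowSums(q^2), "+") - 2 * tcrossprod(p, q)
  sqrt(pmax(d2, 0))
}

plddt_of_keys <- function(model, keys) {
  p <- model$plddt
  p$plddt[match(keys, residue_key(p))]
}

#' Mean pLDDT over one chain's interface residues
#'
#' For DMI models this is the "motif chain interface pLDDT" (when applied to
#' the motif chain) or "domain chain interface pLDDT" (domain chain).
#'
#' @param report An `interface_report` from [find_interface()].
#' @param model The `structure_model` the report was computed on.
#' @param chain_id Chain whose interface residues are averaged.
#' @return Arithmetic mean pLDDT, or `NA` (with a warning) when the chain has
#'   no interface residues.
#' @export
chain_interface_plddt <- function(report, model, chain_id) {
  if (!chain_id %in% report$chains) stop("chain ", chain_id, " not in report")
  res <- report$residues[[chain_id]]
  if (nrow(res) == 0L) {
    warning("chain ", chain_id, " has no interface residues; pLDDT undefined")
    return(NA_real_)
  }
  mean(plddt_of_keys(model, residue_key(res)))
}

#' Mean pLDDT pooled over both chains' interface residues
#'
#' @inheritParams chain_interface_plddt
#' @return Pooled mean pLDDT over all interface residues of both chains, or
#'   `NA` (with a warning) for an empty interface.
#' @export
average_interface_plddt <- function(report, model) {
  keys <- c(residue_key(report$residues[[1]]), residue_key(report$residues[[2]]))
  if (length(keys) == 0L) {
    warning("empty interface; average interface pLDDT undefined")
    return(NA_real_)
  }
  mean(plddt_of_keys(model, keys))
}

#' Weighted model confidence from ipTM and pTM
#'
#' `model confidence = 0.8 * ipTM + 0.2 * pTM`, the ranking score of the
#' multimer prediction engine.
#'
#' @param iptm Interface predicted TM-score in \[0, 1\].
#' @param ptm Global predicted TM-score in \[0, 1\].
#' @return The weighted combination, in \[0, 1\].
#' @export
model_confidence <- function(iptm, ptm) {
  if (any(!is.finite(c(iptm, ptm))) || any(c(iptm, ptm) < 0) ||
      any(c(iptm, ptm) > 1))
    stop("iptm and ptm must lie in [0, 1]")
  0.8 * iptm + 0.2 * ptm
}

#' Default pDockQ sigmoid constants
#'
#' Constants of the fitted sigmoid `L / (1 + exp(-k (x - x0))) + b` from the
#' reference pDockQ implementation.
#' @export
PDOCKQ_CONSTANTS <- c(L = 0.724, k = 0.052, x0 = 152.611, b = 0.018)

#' pDockQ score of a two-chain model
#'
#' Interface contacts are pairs of C-beta atoms (C-alpha for glycine) from
#' different chains strictly within `cutoff` (8 A). With `x` = (mean pLDDT of
#' the contacting residues) times the natural log of the number of contact
#' pairs, the score is the sigmoid `L / (1 + exp(-k (x - x0))) + b`. Zero
#' contacts give `x = 0` (baseline score).
#'
#' @inheritParams find_interface
#' @param cutoff C-beta distance cutoff in Angstrom (strict `<`).
#' @param constants Named vector with elements `L`, `k`, `x0`, `b`.
#' @return pDockQ score in `(b, L + b)`.
#' @export
pdockq <- function(model, chain_pair = NULL, cutoff = 8,
                   constants = PDOCKQ_CONSTANTS) {
  chain_pair <- resolve_chain_pair(model, chain_pair)
  cb <- function(ch) {
    at <- model$atoms[model$atoms$chain == ch, , drop = FALSE]
    sel <- ifelse(at$resname == "GLY", at$atom_name == "CA",
                  at$atom_name == "CB")
    at[sel, , drop = FALSE]
  }
  a <- cb(chain_pair[1]); b <- cb(chain_pair[2])
  n_contacts <- 0L
  keys <- character()
  if (nrow(a) && nrow(b)) {
    d <- cross_distances(as.matrix(a[, c("x", "y", "z")]),
                         as.matrix(b[, c("x", "y", "z")]))
    hit <- d < cutoff
    n_contacts <- sum(hit)
    if (n_contacts > 0L) {
      ij <- which(hit, arr.ind = TRUE)
      keys <- unique(c(residue_key(a)[ij[, 1]], residue_key(b)[ij[, 2]]))
    }
  }
  x <- if (n_contacts == 0L) 0
       else mean(plddt_of_keys(model, keys)) * log(n_contacts)
  unname(constants["L"] /
           (1 + exp(-constants["k"] * (x - constants["x0"]))) + constants["b"])
}

#' Median interface predicted aligned error (iPAE)
#'
#' Residue pairs across the chain pair are in contact when their minimal
#' heavy-atom distance is strictly below `cutoff` (3.5 A); the iPAE is the
#' median of the PAE values of those pairs, pooling both matrix directions
#' (i, j) and (j, i).
#'
#' @inheritParams find_interface
#' @param scores A `score_bundle` carrying a PAE matrix aligned to the model.
#' @param cutoff Contact distance cutoff in Angstrom (strict `<`).
#' @return Median PAE at the interface, or `NA` (with a warning) when no
#'   residue pair is within the cutoff.
#' @export
ipae <- function(model, scores, chain_pair = NULL, cutoff = 3.5) {
  chain_pair <- resolve_chain_pair(model, chain_pair)
  idx <- pae_index_for_model(model, scores)
  rep35 <- find_interface(model, chain_pair, cutoff = cutoff)
  if (rep35$residue_contacts == 0L) {
    warning("no residue pair within ", cutoff, " A; iPAE undefined")
    return(NA_real_)
  }
  i <- idx[rep35$contacts$key_a]
  j <- idx[rep35$contacts$key_b]
  stats::median(c(scores$pae[cbind(i, j)], scores$pae[cbind(j, i)]))
}

#' Confidence call for one model
#'
#' Disordered-ordered (motif-domain) fragment pairs are called confident when
#' the disordered-chain interface pLDDT is at least `motif_plddt` (70).
#' Ordered-ordered pairs require the average interface pLDDT to be at least
#' `avg_plddt` (default 70; 75 is the ROC-derived DDI alternative) and, when
#' `require_model_confidence` is set, a model confidence of at least
#' `min_model_confidence` (0.7).
#'
#' @param report An `interface_report`.
#' @param model The `structure_model`.
#' @param pair_kind `"disordered-ordered"` or `"ordered-ordered"`.
#' @param disordered_chain Chain id of the disordered fragment (required for
#'   disordered-ordered pairs).
#' @param model_conf Model confidence value (needed only when
#'   `require_model_confidence = TRUE`).
#' @param motif_plddt,avg_plddt,min_model_confidence Inclusive thresholds.
#' @param require_model_confidence Apply the optional model-confidence filter
#'   to ordered-ordered pairs.
#' @return Logical flag; undefined metrics give `FALSE` with a warning.
#' @export
classify_confident <- function(report, model,
                               pair_kind = c("disordered-ordered",
                                             "ordered-ordered"),
                               disordered_chain = NULL, model_conf = NA_real_,
                               motif_plddt = 70, avg_plddt = 70,
                               min_model_confidence = 0.7,
                               require_model_confidence = FALSE) {
  pair_kind <- match.arg(pair_kind)
  if (pair_kind == "disordered-ordered") {
    if (is.null(disordered_chain))
      stop("disordered_chain must name the disordered fragment's chain")
    v <- withCallingHandlers(
      chain_interface_plddt(report, model, disordered_chain),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.na(v)) {
      warning("interface pLDDT undefined; model not confident")
      return(FALSE)
    }
    return(v >= motif_plddt)
  }
  v <- withCallingHandlers(average_interface_plddt(report, model),
                           warning = function(w) invokeRestart("muffleWarning"))
  if (is.na(v)) {
    warning("average interface pLDDT undefined; model not confident")
    return(FALSE)
  }
  ok <- v >= avg_plddt
  if (require_model_confidence) {
    if (is.na(model_conf)) {
      warning("model confidence undefined; model not confident")
      return(FALSE)
    }
    ok <- ok && model_conf >= min_model_confidence
  }
  ok
}

#' All interface metrics for one model
#'
#' Convenience wrapper combining [find_interface()] with every per-model
#' confidence metric.
#'
#' @inheritParams find_interface
#' @param scores Optional `score_bundle` (enables model confidence and iPAE).
#' @return The `interface_report` augmented with `chain_plddt` (named vector),
#'   `average_plddt`, `pdockq`, `model_confidence` and `ipae`.
#' @export
score_interface <- function(model, scores = NULL, chain_pair = NULL,
                            cutoff = 5) {
  chain_pair <- resolve_chain_pair(model, chain_pair)
  rep <- find_interface(model, chain_pair, cutoff)
  quiet <- function(expr) withCallingHandlers(
    expr, warning = function(w) invokeRestart("muffleWarning"))
  rep$chain_plddt <- vapply(
    chain_pair, function(ch) quiet(chain_interface_plddt(rep, model, ch)),
    numeric(1))
  rep$average_plddt <- quiet(average_interface_plddt(rep, model))
  rep$pdockq <- pdockq(model, chain_pair)
  rep$model_confidence <- if (is.null(scores)) NA_real_
                          else scores$model_confidence
  rep$ipae <- if (!is.null(scores) && !is.null(scores$pae))
    quiet(ipae(model, scores, chain_pair)) else NA_real_
  rep
}
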