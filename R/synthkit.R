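# Synthetic fixtures: rigid two-chain complexes with controlled motif
# displacement and prescribed pLDDT/PAE, Gaussian benchmark score sets, and
# noisy hyperbolic titrations. Everything is deterministic under a fixed
# seed; structures are written through the package's own model writer so the
# full IO path is exercised.

#' Specification of a synthetic two-chain complex
#'
#' Describes a rigid poly-alanine-like domain trace (chain A) with one
#' pocket-facing side-chain atom per residue and a shorter motif chain
#' (chain B) docked against it. The "model" copy displaces the motif chain
#' rigidly by `displacement` in the domain frame, so downstream evaluation
#' must recover `norm(displacement)` as the motif RMSD.
#'
#' @param domain_length,motif_length Residue counts of the two chains.
#' @param displacement Numeric 3-vector applied to every motif atom in the
#'   model copy (Angstrom).
#' @param domain_plddt,motif_plddt Per-residue pLDDT written to the model's
#'   B-factors (scalars are recycled).
#' @param pae Constant predicted-aligned-error value (Angstrom) for the
#'   score bundle's PAE matrix.
#' @param iptm,ptm Scores for the bundle.
#' @param seed Integer seed fixing any randomness.
#' @return A `synthetic_complex_spec` list.
#' @export
synthetic_complex_spec <- function(domain_length = 30, motif_length = 8,
                                   displacement = c(0, 0, 0),
                                   domain_plddt = 90, motif_plddt = 80,
                                   pae = 5, iptm = 0.85, ptm = 0.80,
                                   seed = 1L) {
  stopifnot(domain_length >= 3, motif_length >= 1,
            length(displacement) == 3, all(is.finite(displacement)))
  structure(
    list(domain_length = as.integer(domain_length),
         motif_length = as.integer(motif_length),
         displacement = as.numeric(displacement),
         domain_plddt = rep_len(domain_plddt, domain_length),
         motif_plddt = rep_len(motif_plddt, motif_length),
         pae = pae, iptm = iptm, ptm = ptm, seed = as.integer(seed)),
    class = "synthetic_complex_spec"
  )
}

# Backbone + one pocket-facing CB per residue along a straight trace.
synthetic_chain <- function(chain, n, y0, cb_toward, x0 = 0, z0 = 0,
                            plddt = rep(70, n)) {
  rows <- list()
  offs <- list(N = c(-1.45, 0.60, 0.00), CA = c(0, 0, 0),
               C = c(1.51, 0.60, 0.00), O = c(1.60, 1.70, 0.40),
               CB = c(0.00, cb_toward * 1.40, 0.40))
  for (i in seq_len(n)) {
    ca <- c(x0 + 3.8 * (i - 1), y0, z0)
    for (nm in names(offs)) {
      p <- ca + offs[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = i, icode = "", resname = "ALA",
        atom_name = nm, element = substr(nm, 1, 1),
        x = p[1], y = p[2], z = p[3], occupancy = 1, b = plddt[i],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

build_complex_atoms <- function(spec, displaced) {
  dom <- synthetic_chain("A", spec$domain_length, y0 = 0, cb_toward = -1,
                         plddt = spec$domain_plddt)
  x0 <- 3.8 * floor((spec$domain_length - spec$motif_length) / 2)
  mot <- synthetic_chain("B", spec$motif_length, y0 = -4.7, cb_toward = +1,
                         x0 = x0, z0 = 0.6, plddt = spec$motif_plddt)
  if (displaced) {
    mot$x <- mot$x + spec$displacement[1]
    mot$y <- mot$y + spec$displacement[2]
    mot$z <- mot$z + spec$displacement[3]
  }
  atoms <- rbind(dom, mot)
  d <- cross_distances(coords(dom), coords(mot))
  if (min(d) < 0.5)
    stop("synthetic displacement produces overlapping atoms (< 0.5 A)")
  atoms
}

#' Generate a native/model synthetic complex pair with scores
#'
#' Writes a native reference PDB, a predicted-model PDB whose motif chain is
#' rigidly displaced by `spec$displacement` and whose B-factors carry the
#' prescribed pLDDT profile, and a score-bundle JSON (ipTM/pTM, rank, and a
#' constant PAE matrix over all residues). Output is byte-deterministic
#' given the spec.
#'
#' @param spec A [synthetic_complex_spec()].
#' @param dir Output directory (created if needed).
#' @param basename File-name stem.
#' @return List with paths `native`, `model`, `scores` and the in-memory
#'   `structure_model`s (`native_model`, `model_model`).
#' @export
make_complex_pair <- function(spec, dir = tempdir(), basename = "synthetic") {
  stopifnot(inherits(spec, "synthetic_complex_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  native_atoms <- build_complex_atoms(spec, displaced = FALSE)
  model_atoms <- build_complex_atoms(spec, displaced = TRUE)
  native_atoms$b <- 50  # crystallographic-style placeholder B-factors
  native <- new_structure_model(native_atoms,
                                model_id = paste0(basename, "_native"))
  model <- new_structure_model(model_atoms,
                               model_id = paste0(basename, "_model"),
                               predicted = TRUE, rank = 1L)

  native_path <- file.path(dir, paste0(basename, "_native.pdb"))
  model_path <- file.path(dir, paste0(basename, "_model.pdb"))
  scores_path <- file.path(dir, paste0(basename, "_scores.json"))
  write_model(native, native_path)
  write_model(model, model_path)

  n <- spec$domain_length + spec$motif_length
  res <- model$plddt
  scores <- list(
    iptm = spec$iptm, ptm = spec$ptm, rank = 1L,
    pae = matrix(spec$pae, n, n),
    pae_residues = unname(lapply(seq_len(n), function(i)
      list(res$chain[i], res$resno[i], res$icode[i]))))
  writeLines(jsonlite::toJSON(scores, auto_unbox = TRUE, digits = NA),
             scores_path)

  list(native = native_path, model = model_path, scores = scores_path,
       native_model = native, model_model = model)
}

#' Generate a synthetic benchmark score set
#'
#' Gaussian score draws for a positive and a random class, emulating the
#' separable (or overlapping) metric distributions of a benchmark.
#'
#' @param n_pos,n_neg Number of positive and random scores.
#' @param pos_mean,neg_mean Class means (defaults emulate an interface-pLDDT
#'   style metric separating positives around 75 from randoms around 55).
#' @param sd Common standard deviation.
#' @param seed Integer seed.
#' @return Data frame with columns `value` and `label`.
#' @export
make_benchmark_scores <- function(n_pos, n_neg, pos_mean = 75, neg_mean = 55,
                                  sd = 10, seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  set.seed(seed)
  data.frame(
    value = c(stats::rnorm(n_pos, pos_mean, sd),
              stats::rnorm(n_neg, neg_mean, sd)),
    label = rep(c("positive", "random"), c(n_pos, n_neg)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic BRET titration
#'
#' Points on the 1:1 hyperbolic saturation curve with seeded Gaussian noise.
#'
#' @param bretmax,bret50 True curve parameters.
#' @param ad_grid Acceptor/donor ratios (defaults span ~2 orders of
#'   magnitude, as in a donor-saturation transfection series).
#' @param noise_sd Gaussian noise standard deviation on the BRET scale.
#' @param seed Integer seed.
#' @return Data frame with columns `ad_ratio` and `cbret`.
#' @export
make_titration <- function(bretmax = 1, bret50 = 2,
                           ad_grid = c(0.25, 0.5, 1, 2, 4, 8, 16),
                           noise_sd = 0.02, seed = 1L) {
  stopifnot(all(ad_grid > 0))
  set.seed(seed)
  data.frame(
    ad_ratio = ad_grid,
    cbret = bretmax * ad_grid / (bret50 + ad_grid) +
      stats::rnorm(length(ad_grid), 0, noise_sd))
}
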