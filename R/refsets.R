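# Positive and random benchmark reference sets: key positions of motif
# regular expressions, maximal-Miyata-distance mutagenesis, cognate-avoiding
# shuffles, and pairwise sequence identity.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Side-chain polarity and volume (Grantham 1974), the two physico-chemical
# properties underlying the Miyata amino-acid distance.
AA_POLARITY <- c(A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5,
                 E = 12.3, G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3,
                 M = 5.7, F = 5.2, P = 8.0, S = 9.2, T = 8.6, W = 5.4,
                 Y = 6.2, V = 5.9)
AA_VOLUME <- c(A = 31, R = 124, N = 56, D = 54, C = 55, Q = 85, E = 83,
               G = 3, H = 96, I = 111, L = 111, K = 119, M = 105, F = 132,
               P = 32.5, S = 32, T = 61, W = 170, Y = 136, V = 84)

#' Miyata amino-acid distance matrix
#'
#' Physico-chemical distance between the 20 standard amino acids: the
#' Euclidean distance over polarity and side-chain volume differences, each
#' normalized by the standard deviation of the pairwise differences across
#' all amino-acid pairs. Used to pick maximally disruptive substitutions.
#'
#' @return Symmetric 20x20 matrix with zero diagonal, one-letter row and
#'   column names.
#' @export
miyata_matrix <- function() {
  dp <- abs(outer(AA_POLARITY[AA1], AA_POLARITY[AA1], "-"))
  dv <- abs(outer(AA_VOLUME[AA1], AA_VOLUME[AA1], "-"))
  sd_p <- stats::sd(dp[upper.tri(dp)])
  sd_v <- stats::sd(dv[upper.tri(dv)])
  m <- sqrt((dp / sd_p)^2 + (dv / sd_v)^2)
  dimnames(m) <- list(AA1, AA1)
  m
}

#' Key (defined) positions of a motif instance
#'
#' The defined positions of a motif are those whose element in the motif
#' class regular expression is not a wildcard: fixed letters, character
#' classes and alternations all count as defined. Operationally, a position
#' is defined iff some amino-acid substitution at that position breaks the
#' anchored match of the sequence against the regex.
#'
#' @param regex Motif class regular expression (un-anchored; anchoring is
#'   added internally).
#' @param motif_sequence Motif instance matching `regex`.
#' @return Integer vector of 1-based defined positions.
#' @export
key_positions <- function(regex, motif_sequence) {
  pat <- paste0("^(?:", regex, ")$")
  if (!grepl(pat, motif_sequence, perl = TRUE))
    stop("motif sequence does not match the class regular expression")
  chars <- strsplit(motif_sequence, "")[[1]]
  defined <- vapply(seq_along(chars), function(i) {
    for (aa in AA1) {
      if (aa == chars[i]) next
      probe <- chars; probe[i] <- aa
      if (!grepl(pat, paste(probe, collapse = ""), perl = TRUE)) return(TRUE)
    }
    FALSE
  }, logical(1))
  which(defined)
}

#' Mutate key motif residues to maximal Miyata distance
#'
#' Substitutes `k` key residues by the amino acid at the largest Miyata
#' distance from the original residue (ties broken alphabetically). The
#' default policy mutates the first `k` key positions left to right;
#' `positions` overrides the choice.
#'
#' @param motif_sequence Motif instance sequence.
#' @param key_positions Integer vector of defined positions (see
#'   [key_positions()]).
#' @param k Number of residues to mutate (1 or 2).
#' @param positions Optional explicit positions (subset of `key_positions`)
#'   of length `k`.
#' @param matrix Miyata distance matrix (defaults to [miyata_matrix()]).
#' @return Mutant sequence differing from the input at exactly `k` positions.
#' @export
miyata_mutate <- function(motif_sequence, key_positions, k = 1,
                          positions = NULL, matrix = miyata_matrix()) {
  if (!k %in% c(1L, 2L)) stop("k must be 1 or 2")
  if (length(key_positions) < k)
    stop("fewer than k key positions available")
  if (is.null(positions)) positions <- sort(key_positions)[seq_len(k)]
  if (length(positions) != k || !all(positions %in% key_positions))
    stop("positions must be k of the key positions")
  chars <- strsplit(motif_sequence, "")[[1]]
  for (i in positions) {
    aa <- chars[i]
    if (!aa %in% AA1) stop("non-standard residue '", aa, "' at position ", i)
    row <- matrix[aa, ]
    best <- sort(names(row)[row == max(row)])[1]  # alphabetical tie-break
    chars[i] <- best
  }
  paste(chars, collapse = "")
}

#' Read motif class definitions from TSV
#'
#' Columns: `class_id`, `regex`, `cognate_domain_types` (semicolon-separated)
#' and optionally `motif_probability` (carried from the motif resource, never
#' computed here).
#'
#' @param path TSV path.
#' @return Data frame with `cognate_domain_types` as a list column.
#' @export
read_motif_classes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class_id", "regex", "cognate_domain_types") %in% names(df)))
  for (re in df$regex)
    tryCatch(grepl(re, "", perl = TRUE),
             error = function(e) stop("regex does not compile: ", re))
  df$cognate_domain_types <- strsplit(df$cognate_domain_types, ";")
  df
}

#' Shuffle domain-motif pairings avoiding cognate domain types
#'
#' Builds a random reference set by permuting the domain assignments of
#' positive instances such that no motif ends up paired with a domain whose
#' type belongs to the cognate set of the motif's class — including via any
#' other class sharing a domain type, and including the identity pairing.
#' Rejection-resamples seeded permutations until valid.
#'
#' @param instances Data frame of positive instances with at least columns
#'   `class_id`, `motif_protein`, `motif_sequence`, `domain_protein`,
#'   `domain_sequence`.
#' @param classes Data frame from [read_motif_classes()] (or with columns
#'   `class_id` and list column `cognate_domain_types`).
#' @param seed Integer seed; fixed seed gives identical output.
#' @param max_attempts Attempt limit for rejection sampling.
#' @return `instances` with the domain columns permuted, a `domain_from`
#'   column recording the source instance, and provenance label
#'   `"shuffled"`.
#' @export
shuffle_pairs <- function(instances, classes, seed = 1L,
                          max_attempts = 10000L) {
  n <- nrow(instances)
  if (n < 2L) stop("at least two instances are required")
  cog <- classes$cognate_domain_types
  names(cog) <- classes$class_id
  icog <- cog[instances$class_id]
  # domain of instance j carries the domain types of its own class
  forbidden <- function(i, j)
    length(intersect(icog[[i]], icog[[j]])) > 0L
  conflict <- outer(seq_len(n), seq_len(n), Vectorize(forbidden))

  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    perm <- sample.int(n)
    if (!any(conflict[cbind(seq_len(n), perm)])) {
      dom_cols <- intersect(c("domain_protein", "domain_span",
                              "domain_sequence"), names(instances))
      out <- instances
      out[dom_cols] <- instances[perm, dom_cols]
      out$domain_from <- instances$class_id[perm]
      out$provenance <- "shuffled"
      return(out)
    }
  }
  stop("no valid shuffled pairing found in ", max_attempts, " attempts; ",
       "cognate-conflict pairs: ", sum(conflict), " of ", n^2)
}

#' Pairwise sequence identity from a gap-penalty-free global alignment
#'
#' Global alignment scoring matches 1 and mismatches 0 with zero gap
#' penalties; the identity is the optimal number of matches divided by the
#' length of the longer sequence.
#'
#' @param seq_a,seq_b Non-empty amino-acid sequences.
#' @return Identity fraction in (0, 1\].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    stop("sequences must be non-empty")
  letters <- unique(strsplit(paste0(seq_a, seq_b), "")[[1]])
  m <- diag(1, length(letters))
  dimnames(m) <- list(letters, letters)
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = m,
    gapOpening = 0, gapExtension = 0)
  Biostrings::score(aln) / max(nchar(seq_a), nchar(seq_b))
}
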