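# Region annotation, sliding-window fragment design, fragment pairing, and
# the motif/domain extension schedules. All coordinates are 1-based inclusive
# residue positions.

#' Construct a region annotation
#'
#' Ordered spans must not overlap each other; a disordered span may overlap an
#' ordered span (a low-pLDDT loop inside a domain is annotated disordered in
#' addition to being part of the ordered region). The union of spans must
#' cover the whole sequence.
#'
#' @param protein_id Protein identifier.
#' @param length Sequence length.
#' @param spans Data frame with columns `start`, `end`, `label`
#'   (`"ordered"`/`"disordered"`).
#' @param source `"manual"` or `"suggested"`. Manual annotations always
#'   override suggestions.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(protein_id, length, spans,
                              source = c("manual", "suggested")) {
  source <- match.arg(source)
  spans <- as.data.frame(spans)
  stopifnot(all(c("start", "end", "label") %in% names(spans)),
            all(spans$label %in% c("ordered", "disordered")))
  spans$start <- as.integer(spans$start); spans$end <- as.integer(spans$end)
  if (any(spans$start < 1) || any(spans$end > length) ||
      any(spans$start > spans$end))
    stop("spans must satisfy 1 <= start <= end <= length")
  ord <- spans[spans$label == "ordered", , drop = FALSE]
  if (nrow(ord) > 1L) {
    ord <- ord[order(ord$start), ]
    if (any(ord$start[-1] <= ord$end[-nrow(ord)]))
      stop("ordered spans must not overlap each other")
  }
  covered <- rep(FALSE, length)
  for (i in seq_len(nrow(spans))) covered[spans$start[i]:spans$end[i]] <- TRUE
  if (!all(covered)) stop("spans do not cover the full sequence")
  structure(list(protein_id = protein_id, length = as.integer(length),
                 spans = spans[order(spans$start, spans$end), ,
                               drop = FALSE],
                 source = source),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("region_annotation '%s' (%d aa, %s):\n", x$protein_id,
              x$length, x$source))
  for (i in seq_len(nrow(x$spans)))
    cat(sprintf("  %4d-%4d %s\n", x$spans$start[i], x$spans$end[i],
                x$spans$label[i]))
  invisible(x)
}

#' Read region annotations from TSV
#'
#' Columns: `protein_id`, `start`, `end`, `label`, `source`.
#' @param path TSV path.
#' @param lengths Named integer vector of protein lengths; defaults to the
#'   maximal annotated end per protein.
#' @return Named list of `region_annotation`s.
#' @export
read_region_annotations <- function(path, lengths = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$protein_id), function(d) {
    len <- if (!is.null(lengths)) lengths[[d$protein_id[1]]] else max(d$end)
    region_annotation(d$protein_id[1], len, d[, c("start", "end", "label")],
                      source = if (all(d$source == "suggested")) "suggested"
                               else "manual")
  })
  out
}

#' Suggest ordered/disordered spans from a pLDDT profile
#'
#' Convenience helper proposing spans for human review: runs of smoothed
#' pLDDT at or above `cutoff` are labelled ordered, the rest disordered, and
#' runs shorter than the smoothing window are merged into their surroundings.
#' Boundary suggestions are deliberately conservative input for manual
#' curation, which always takes precedence.
#'
#' @param per_residue_plddt Numeric vector of per-residue pLDDT.
#' @param smoothing_window Centered running-mean window (residues).
#' @param cutoff pLDDT threshold for "ordered".
#' @param protein_id Identifier for the returned annotation.
#' @return A `region_annotation` with `source = "suggested"`.
#' @export
suggest_regions <- function(per_residue_plddt, smoothing_window = 5,
                            cutoff = 70, protein_id = "protein") {
  p <- per_residue_plddt
  if (length(p) == 0L) stop("pLDDT profile is empty")
  n <- length(p)
  half <- floor(smoothing_window / 2)
  sm <- vapply(seq_len(n), function(i)
    mean(p[max(1, i - half):min(n, i + half)]), numeric(1))
  lab <- ifelse(sm >= cutoff, "ordered", "disordered")

  # merge runs shorter than the window into their flanks
  repeat {
    r <- rle(lab)
    short <- which(r$lengths < smoothing_window)
    short <- short[short > 1 & short < length(r$lengths)]
    if (length(short) == 0L) break
    i <- short[1]
    r$values[i] <- r$values[i - 1]
    lab <- inverse.rle(r)
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  region_annotation(protein_id, n,
                    data.frame(start = starts, end = ends, label = r$values),
                    source = "suggested")
}

#' Sliding-window fragments of a region span
#'
#' For each window size `s`, primary windows tile the span from its start
#' with step `s`, and an offset series starts at `start + s/2` (overlapping
#' the primary series by half a window). A window that would extend past the
#' span end is replaced by one terminal window anchored at the span end
#' (dropped if it duplicates an existing window). The whole unfragmented span
#' is always included; spans shorter than `s` yield only the whole-span
#' fragment for that size.
#'
#' @param span Integer vector `c(start, end)`, 1-based inclusive.
#' @param sizes Positive even window sizes (default 10, 20, 30 residues).
#' @return Data frame with columns `start`, `end`, `window_size`
#'   (`NA` for the whole-region fragment), de-duplicated and sorted by
#'   `(start, end)`.
#' @export
fragment_region <- function(span, sizes = c(10, 20, 30)) {
  start <- as.integer(span[1]); end <- as.integer(span[2])
  stopifnot(start >= 1, end >= start)
  if (any(sizes < 1)) stop("sizes must be positive")
  if (any(sizes %% 2 != 0)) stop("sizes must be even (half-window step)")
  len <- end - start + 1L

  rows <- list(data.frame(start = start, end = end, window_size = NA_integer_))
  for (s in sizes) {
    if (len < s) next
    series <- function(first) {
      st <- seq(first, end, by = s)
      en <- st + s - 1L
      over <- en > end
      if (any(over)) {  # anchored terminal window
        st <- c(st[!over], end - s + 1L)
        en <- c(en[!over], end)
      }
      data.frame(start = st, end = en, window_size = s)
    }
    rows[[length(rows) + 1L]] <- series(start)
    if (start + s / 2 <= end)
      rows[[length(rows) + 1L]] <- series(as.integer(start + s / 2))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("start", "end", "window_size")]), ]
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  out
}

#' Enumerate fragment pairs for prediction jobs
#'
#' Pairs the disordered units (whole disordered spans plus their sliding
#' window fragments) of each protein with the ordered regions of its partner,
#' and pairs the ordered regions of both proteins with each other.
#'
#' @param annotation_a,annotation_b `region_annotation`s for the two proteins
#'   of one PPI.
#' @param fragments_a,fragments_b Optional data frames of fragments of the
#'   disordered spans (as from [fragment_region()], with a `protein span`
#'   column pair `start`/`end`); the whole disordered spans are always
#'   included even when no fragments are supplied.
#' @return Data frame with one row per pair: `pair_id`, `protein_a`,
#'   `start_a`, `end_a`, `label_a`, `protein_b`, `start_b`, `end_b`,
#'   `label_b`, `pair_kind`.
#' @export
pair_fragments <- function(annotation_a, annotation_b,
                           fragments_a = NULL, fragments_b = NULL) {
  units <- function(ann, frags) {
    sp <- ann$spans
    ordered <- sp[sp$label == "ordered", c("start", "end"), drop = FALSE]
    dis <- sp[sp$label == "disordered", c("start", "end"), drop = FALSE]
    if (!is.null(frags) && nrow(frags))
      dis <- rbind(dis, frags[, c("start", "end"), drop = FALSE])
    dis <- dis[!duplicated(dis), , drop = FALSE]
    list(ordered = ordered, disordered = dis)
  }
  ua <- units(annotation_a, fragments_a)
  ub <- units(annotation_b, fragments_b)
  if (nrow(ua$ordered) == 0L)
    warning("protein ", annotation_a$protein_id, " has no ordered region")
  if (nrow(ub$ordered) == 0L)
    warning("protein ", annotation_b$protein_id, " has no ordered region")

  cross <- function(xa, xb, la, lb, kind) {
    if (nrow(xa) == 0L || nrow(xb) == 0L) return(NULL)
    g <- expand.grid(i = seq_len(nrow(xa)), j = seq_len(nrow(xb)))
    data.frame(protein_a = annotation_a$protein_id,
               start_a = xa$start[g$i], end_a = xa$end[g$i], label_a = la,
               protein_b = annotation_b$protein_id,
               start_b = xb$start[g$j], end_b = xb$end[g$j], label_b = lb,
               pair_kind = kind, stringsAsFactors = FALSE)
  }
  out <- rbind(
    cross(ua$disordered, ub$ordered, "disordered", "ordered",
          "disordered-ordered"),
    cross(ua$ordered, ub$disordered, "ordered", "disordered",
          "disordered-ordered"),
    cross(ua$ordered, ub$ordered, "ordered", "ordered", "ordered-ordered")
  )
  if (is.null(out)) return(data.frame(
    pair_id = character(), protein_a = character(), start_a = integer(),
    end_a = integer(), label_a = character(), protein_b = character(),
    start_b = integer(), end_b = integer(), label_b = character(),
    pair_kind = character(), stringsAsFactors = FALSE))
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(pair_id = sprintf("pair_%03d", seq_len(nrow(out))), out)
  out
}

clip_span <- function(start, end, protein_length) {
  c(max(1L, as.integer(start)), min(as.integer(protein_length),
                                    as.integer(end)))
}

# A span is "terminal" when it touches a protein end; it is then extended on
# the opposite side only.
pad_span <- function(span, pad, protein_length) {
  at_n <- span[1] == 1L
  at_c <- span[2] == protein_length
  clip_span(span[1] - if (at_c && !at_n) pad else if (at_n) 0L else pad,
            span[2] + if (at_n && !at_c) pad else if (at_c) 0L else pad,
            protein_length)
}

nearest_neighbors <- function(span, neighbor_domains) {
  if (is.null(neighbor_domains) || nrow(neighbor_domains) == 0L)
    return(list(n = NULL, c = NULL))
  nd <- as.data.frame(neighbor_domains)
  n_side <- nd[nd$end < span[1], , drop = FALSE]
  c_side <- nd[nd$start > span[2], , drop = FALSE]
  list(n = if (nrow(n_side)) n_side[which.max(n_side$end), ] else NULL,
       c = if (nrow(c_side)) c_side[which.min(c_side$start), ] else NULL)
}

#' Motif extension schedule
#'
#' With `n` the motif length, levels 1-4 pad the minimal motif span
#' cumulatively by `n`, `2n`, `4n` and `6n` residues on each side (levels 3
#' and 4 each add another `2n`); level 5 extends the minimal span to include
#' the nearest neighboring domain on each side; level 6 is the full-length
#' sequence. Motifs at a protein terminus are extended on the opposite side
#' only; all spans are clipped to the protein.
#'
#' @param motif_span Integer `c(start, end)` of the minimal annotated motif.
#' @param level Extension level, 1-6.
#' @param neighbor_domains Optional data frame of domain spans
#'   (`start`, `end`) used by level 5.
#' @param protein_length Protein length.
#' @return Integer `c(start, end)` of the extended span.
#' @export
extend_motif <- function(motif_span, level, neighbor_domains = NULL,
                         protein_length) {
  span <- clip_span(motif_span[1], motif_span[2], protein_length)
  if (!level %in% 1:6) stop("motif extension level must be 1..6")
  n <- span[2] - span[1] + 1L
  if (level <= 4) {
    pad <- c(1L, 2L, 4L, 6L)[level] * n
    return(pad_span(span, pad, protein_length))
  }
  if (level == 5L) {
    nb <- nearest_neighbors(span, neighbor_domains)
    lo <- if (!is.null(nb$n)) min(span[1], nb$n$start) else span[1]
    hi <- if (!is.null(nb$c)) max(span[2], nb$c$end) else span[2]
    return(clip_span(lo, hi, protein_length))
  }
  c(1L, as.integer(protein_length))
}

#' Domain extension schedule
#'
#' Level 1 extends the domain through its flanking disordered regions up to
#' (but excluding) the neighboring domain boundaries; level 2 includes the
#' nearest neighboring domains; level 3 is the full-length sequence. Domains
#' at a protein terminus are extended on the opposite side only.
#'
#' @param domain_span Integer `c(start, end)` of the minimal binding domain.
#' @param level Extension level, 1-3.
#' @param neighbor_domains Optional data frame of other domain spans.
#' @param protein_length Protein length.
#' @return Integer `c(start, end)` of the extended span.
#' @export
extend_domain <- function(domain_span, level, neighbor_domains = NULL,
                          protein_length) {
  span <- clip_span(domain_span[1], domain_span[2], protein_length)
  if (!level %in% 1:3) stop("domain extension level must be 1..3")
  if (level == 3L) return(c(1L, as.integer(protein_length)))
  nb <- nearest_neighbors(span, neighbor_domains)
  at_n <- span[1] == 1L; at_c <- span[2] == protein_length
  if (level == 1L) {
    lo <- if (is.null(nb$n)) 1L else nb$n$end + 1L
    hi <- if (is.null(nb$c)) as.integer(protein_length) else nb$c$start - 1L
  } else {
    lo <- if (is.null(nb$n)) 1L else as.integer(nb$n$start)
    hi <- if (is.null(nb$c)) as.integer(protein_length)
          else as.integer(nb$c$end)
  }
  if (at_n && !at_c) lo <- span[1]
  if (at_c && !at_n) hi <- span[2]
  clip_span(min(lo, span[1]), max(hi, span[2]), protein_length)
}

#' Exclusion rule for minimal extension steps
#'
#' An extension step that adds fewer than 20 residues on the N side and fewer
#' than 20 on the C side of the previous step is dropped from analysis.
#'
#' @param previous_span,new_span Integer spans, `new_span` containing
#'   `previous_span`.
#' @return `TRUE` to keep the step, `FALSE` to drop it.
#' @export
minimal_extension_filter <- function(previous_span, new_span) {
  if (new_span[1] > previous_span[1] || new_span[2] < previous_span[2])
    stop("new_span must contain previous_span")
  added_n <- previous_span[1] - new_span[1]
  added_c <- new_span[2] - previous_span[2]
  !(added_n < 20 && added_c < 20)
}

#' Write a fragment-pair manifest TSV
#'
#' @param pairs Data frame from [pair_fragments()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pair_manifest <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
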