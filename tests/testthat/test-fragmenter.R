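# Region suggestion, sliding-window tiling, fragment pairing and the
# extension schedules.

test_that("suggest_regions labels constant and step pLDDT profiles", {
  a <- suggest_regions(rep(90, 80), smoothing_window = 5, cutoff = 70)
  expect_equal(nrow(a$spans), 1L)
  expect_equal(unname(unlist(a$spans[1, c("start", "end")])), c(1L, 80L))
  expect_equal(a$spans$label, "ordered")
  expect_equal(a$source, "suggested")

  b <- suggest_regions(rep(40, 80), smoothing_window = 5, cutoff = 70)
  expect_equal(b$spans$label, "disordered")

  step <- suggest_regions(c(rep(90, 50), rep(40, 50)), smoothing_window = 1,
                          cutoff = 70)
  expect_equal(step$spans$start, c(1L, 51L))
  expect_equal(step$spans$end, c(50L, 100L))
  expect_equal(step$spans$label, c("ordered", "disordered"))
})

test_that("fragment_region reproduces the hand-enumerated tiling", {
  fr <- fragment_region(c(1, 40), 10)
  win <- fr[!is.na(fr$window_size), c("start", "end")]
  expect_equal(
    win,
    data.frame(start = c(1L, 6L, 11L, 16L, 21L, 26L, 31L),
               end = c(10L, 15L, 20L, 25L, 30L, 35L, 40L)),
    ignore_attr = TRUE)
  expect_true(any(is.na(fr$window_size) & fr$start == 1 & fr$end == 40))

  # region shorter than the window: only the whole-region fragment
  short <- fragment_region(c(1, 10), 20)
  expect_equal(nrow(short), 1L)
  expect_true(is.na(short$window_size))
  expect_equal(c(short$start, short$end), c(1L, 10L))

  # terminal anchored window
  fr25 <- fragment_region(c(1, 25), 10)
  expect_true(any(fr25$start == 16 & fr25$end == 25))
  covered <- rep(FALSE, 25)
  w <- fr25[!is.na(fr25$window_size), ]
  for (i in seq_len(nrow(w))) covered[w$start[i]:w$end[i]] <- TRUE
  expect_true(all(covered))

  expect_error(fragment_region(c(1, 40), 9), "even")
})

test_that("tiling coverage and exact half-window overlaps hold generally", {
  set.seed(42)
  for (rep in 1:20) {
    start <- sample(1:200, 1)
    len <- sample(10:120, 1)
    span <- c(start, start + len - 1)
    sizes <- sample(c(10, 20, 30), sample(1:3, 1))
    fr <- fragment_region(span, sizes)
    expect_true(any(is.na(fr$window_size)))
    for (s in sizes[sizes <= len]) {
      w <- fr[!is.na(fr$window_size) & fr$window_size == s, ]
      covered <- rep(FALSE, len)
      for (i in seq_len(nrow(w)))
        covered[(w$start[i]:w$end[i]) - start + 1] <- TRUE
      expect_true(all(covered))
      # merged primary+offset series: consecutive windows overlap by s/2,
      # except where the terminal window was anchored at the span end
      w <- w[order(w$start), ]
      if (nrow(w) > 2) {
        steps <- diff(w$start[-nrow(w)])
        expect_true(all(steps == s / 2))
      }
      expect_true(all(w$end - w$start + 1 == s))
    }
  }
})

test_that("pair_fragments matches the combinatorial count", {
  ann_a <- region_annotation("A", 100, data.frame(
    start = c(1, 61), end = c(60, 100), label = c("ordered", "disordered")))
  ann_b <- region_annotation("B", 50,
                             data.frame(start = 1, end = 50, label = "ordered"))
  fr <- fragment_region(c(61, 100), 10)  # 7 windows + whole region
  pairs <- pair_fragments(ann_a, ann_b, fragments_a = fr)
  expect_equal(sum(pairs$pair_kind == "disordered-ordered"), 8L)
  expect_equal(sum(pairs$pair_kind == "ordered-ordered"), 1L)
  expect_equal(nrow(pairs), 9L)

  # both fully ordered: exactly one ordered-ordered pair
  oa <- region_annotation("A", 30, data.frame(start = 1, end = 30,
                                              label = "ordered"))
  ob <- region_annotation("B", 40, data.frame(start = 1, end = 40,
                                              label = "ordered"))
  expect_equal(nrow(pair_fragments(oa, ob)), 1L)

  # closed-form product for random synthetic annotations
  set.seed(7)
  for (rep in 1:10) {
    n_ord_a <- sample(0:3, 1); n_dis_a <- sample(0:2, 1)
    n_ord_b <- sample(1:3, 1); n_dis_b <- sample(0:2, 1)
    mk <- function(id, n_ord, n_dis) {
      n <- n_ord + n_dis
      if (n == 0) return(NULL)
      len <- 10 * n
      lab <- sample(rep(c("ordered", "disordered"), c(n_ord, n_dis)))
      region_annotation(id, len, data.frame(
        start = seq(1, by = 10, length.out = n),
        end = seq(10, by = 10, length.out = n), label = lab))
    }
    aa <- mk("A", n_ord_a, n_dis_a); bb <- mk("B", n_ord_b, n_dis_b)
    if (is.null(aa) || is.null(bb)) next
    pairs <- suppressWarnings(pair_fragments(aa, bb))
    expected <- n_dis_a * n_ord_b + n_ord_a * n_dis_b + n_ord_a * n_ord_b
    expect_equal(if (is.null(pairs)) 0L else nrow(pairs), expected)
  }
})

test_that("motif extension levels follow the cumulative pad schedule", {
  len <- 500
  expect_equal(extend_motif(c(100, 109), 1, protein_length = len), c(90L, 119L))
  expect_equal(extend_motif(c(100, 109), 2, protein_length = len), c(80L, 129L))
  expect_equal(extend_motif(c(100, 109), 3, protein_length = len), c(60L, 149L))
  expect_equal(extend_motif(c(100, 109), 4, protein_length = len), c(40L, 169L))
  expect_equal(extend_motif(c(100, 109), 6, protein_length = len), c(1L, 500L))
  # N-terminal motif extends on the C side only
  expect_equal(extend_motif(c(1, 8), 1, protein_length = len), c(1L, 16L))
  # level 5 reaches the neighboring domains
  nb <- data.frame(start = c(20, 200), end = c(60, 260))
  expect_equal(extend_motif(c(100, 109), 5, nb, len), c(20L, 260L))
  expect_error(extend_motif(c(100, 109), 7, protein_length = len), "1\\.\\.6")
})

test_that("domain extension stops at, then includes, neighboring domains", {
  nb <- data.frame(start = 200, end = 300)
  expect_equal(extend_domain(c(50, 150), 1, nb, 400), c(1L, 199L))
  expect_equal(extend_domain(c(50, 150), 2, nb, 400), c(1L, 300L))
  expect_equal(extend_domain(c(50, 150), 3, nb, 400), c(1L, 400L))
  # no neighbors: nothing to stop at
  expect_equal(extend_domain(c(1, 100), 1, NULL, 400), c(1L, 400L))
  expect_error(extend_domain(c(50, 150), 4, nb, 400), "1\\.\\.3")
})

test_that("extension schedules are monotone within each arm", {
  set.seed(11)
  for (rep in 1:15) {
    len <- sample(200:600, 1)
    st <- sample(20:(len - 30), 1)
    span <- c(st, st + sample(5:15, 1))
    prev <- extend_motif(span, 1, protein_length = len)
    for (lv in 2:4) {
      cur <- extend_motif(span, lv, protein_length = len)
      expect_true(cur[1] <= prev[1] && cur[2] >= prev[2])
      prev <- cur
    }
    full <- extend_motif(span, 6, protein_length = len)
    expect_true(full[1] <= prev[1] && full[2] >= prev[2])
    nb <- data.frame(start = min(len - 10, st + 40),
                     end = min(len, st + 80))
    l5 <- extend_motif(span, 5, nb, len)
    expect_true(all(l5 == pmin(pmax(l5, 1), len)))
    expect_true(l5[1] <= span[1] && l5[2] >= span[2])
    expect_true(full[1] <= l5[1] && full[2] >= l5[2])

    dspan <- c(st, st + 25)
    d1 <- extend_domain(dspan, 1, nb, len)
    d2 <- extend_domain(dspan, 2, nb, len)
    d3 <- extend_domain(dspan, 3, nb, len)
    expect_true(d2[1] <= d1[1] && d2[2] >= d1[2])
    expect_true(d3[1] <= d2[1] && d3[2] >= d2[2])
  }
})

test_that("minimal extension steps (<20 residues both sides) are dropped", {
  expect_true(minimal_extension_filter(c(80, 129), c(60, 149)))
  expect_false(minimal_extension_filter(c(80, 129), c(70, 139)))
  expect_false(minimal_extension_filter(c(80, 129), c(80, 129)))
  # 20+ on one side only is enough to keep
  expect_true(minimal_extension_filter(c(80, 129), c(80, 160)))
  expect_error(minimal_extension_filter(c(80, 129), c(90, 129)), "contain")
})

test_that("region annotations validate spans and allow disordered loops", {
  expect_error(region_annotation("P", 100, data.frame(
    start = c(1, 40), end = c(50, 100),
    label = c("ordered", "ordered"))), "overlap")
  # disordered loop inside an ordered region is allowed
  ann <- region_annotation("P", 100, data.frame(
    start = c(1, 30, 81), end = c(80, 45, 100),
    label = c("ordered", "disordered", "disordered")))
  expect_s3_class(ann, "region_annotation")
  expect_error(region_annotation("P", 100, data.frame(
    start = 1, end = 50, label = "ordered")), "cover")
})
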