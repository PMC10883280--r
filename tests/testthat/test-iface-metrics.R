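# Interface detection (strict 5 A heavy-atom rule) and the per-model
# confidence metrics: interface pLDDT variants, model confidence, pDockQ,
# iPAE and the confidence call.

two_atom_model <- function(separation, b = c(80, 60)) {
  toy_model(chain = c("A", "B"), resno = c(1, 1), atom_name = c("CA", "CA"),
            xyz = rbind(c(0, 0, 0), c(separation, 0, 0)), b = b)
}

test_that("interface membership uses a strict < 5 A heavy-atom rule", {
  near <- find_interface(two_atom_model(4.99))
  expect_equal(near$residue_contacts, 1L)
  expect_equal(near$atom_contacts, 1L)
  expect_equal(nrow(near$residues$A), 1L)
  expect_equal(nrow(near$residues$B), 1L)

  at_cutoff <- find_interface(two_atom_model(5.00))
  expect_equal(at_cutoff$residue_contacts, 0L)
  expect_equal(at_cutoff$atom_contacts, 0L)

  far <- find_interface(two_atom_model(12))
  expect_equal(nrow(far$residues$A) + nrow(far$residues$B), 0L)
})

test_that("interface sets and contact counts match a brute-force scan", {
  set.seed(3)
  for (rep in 1:8) {
    n_a <- sample(20:100, 1); n_b <- sample(20:100, 1)
    xa <- matrix(rnorm(n_a * 3, sd = 6), ncol = 3)
    xb <- sweep(matrix(rnorm(n_b * 3, sd = 6), ncol = 3), 2,
                c(4, 0, 0), "+")
    m <- toy_model(
      chain = rep(c("A", "B"), c(n_a, n_b)),
      resno = c(rep(seq_len(ceiling(n_a / 3)), each = 3)[1:n_a],
                rep(seq_len(ceiling(n_b / 3)), each = 3)[1:n_b]),
      atom_name = rep(c("N", "CA", "C"), length.out = n_a + n_b),
      xyz = rbind(xa, xb))
    fast <- find_interface(m, c("A", "B"))
    slow <- brute_interface(m, c("A", "B"))
    expect_equal(fast$atom_contacts, slow$atom_contacts)
    expect_equal(fast$residue_contacts, slow$residue_contacts)
    expect_setequal(paste(fast$residues$A$chain, fast$residues$A$resno,
                          fast$residues$A$icode), slow$res_a)
    expect_setequal(paste(fast$residues$B$chain, fast$residues$B$resno,
                          fast$residues$B$icode), slow$res_b)
    # symmetry of the chain pair
    rev <- find_interface(m, c("B", "A"))
    expect_equal(rev$atom_contacts, fast$atom_contacts)
    expect_equal(rev$residue_contacts, fast$residue_contacts)
    expect_equal(rev$residues$A, fast$residues$A)
  }
})

test_that("chain and pooled interface pLDDT are plain arithmetic means", {
  m <- toy_model(chain = c("A", "A", "B", "B", "B"),
                 resno = c(1, 2, 1, 2, 3),
                 atom_name = "CA",
                 xyz = rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0),
                             c(2, 3, 0), c(4, 3, 0)),
                 b = c(80, 60, 90, 70, 80))
  rep <- find_interface(m)
  expect_equal(chain_interface_plddt(rep, m, "A"), 70)
  # pooled mean over both chains
  expect_equal(average_interface_plddt(rep, m),
               mean(c(80, 60, 90, 70, 80)))
  # weighted-mean bound
  avg <- average_interface_plddt(rep, m)
  ca <- chain_interface_plddt(rep, m, "A")
  cb <- chain_interface_plddt(rep, m, "B")
  expect_true(avg >= min(ca, cb) && avg <= max(ca, cb))

  single <- find_interface(two_atom_model(3, b = c(91.3, 50)))
  expect_equal(chain_interface_plddt(single, m = two_atom_model(3, c(91.3, 50)),
                                     "A"), 91.3)
  empty <- find_interface(two_atom_model(50))
  expect_warning(v <- chain_interface_plddt(empty, two_atom_model(50), "A"),
                 "undefined")
  expect_true(is.na(v))
  expect_warning(v2 <- average_interface_plddt(empty, two_atom_model(50)),
                 "undefined")
  expect_true(is.na(v2))
})

test_that("model confidence is the exact 0.8/0.2 weighted sum", {
  expect_identical(model_confidence(1.0, 0.0), 0.8)
  expect_identical(model_confidence(0.0, 1.0), 0.2)
  expect_equal(model_confidence(0.9, 0.5), 0.82)
  expect_error(model_confidence(1.1, 0.5), "\\[0, 1\\]")
  expect_error(model_confidence(0.5, -0.1), "\\[0, 1\\]")
})

test_that("pDockQ behaves as a bounded monotone sigmoid of pLDDT", {
  spec0 <- synthetic_complex_spec(domain_length = 10, motif_length = 4)
  pair <- make_complex_pair(spec0, dir = tempfile())
  m <- pair$model_model

  # zero contacts: separate the chains far beyond 8 A
  far <- m
  sel <- far$atoms$chain == "B"
  far$atoms$y[sel] <- far$atoms$y[sel] - 100
  k <- fragscore::PDOCKQ_CONSTANTS
  expect_equal(pdockq(far),
               unname(k["L"] / (1 + exp(k["k"] * k["x0"])) + k["b"]),
               tolerance = 1e-12)
  expect_equal(pdockq(far), 0.0183, tolerance = 5e-3)

  # raising every pLDDT never decreases the score
  lo <- make_complex_pair(synthetic_complex_spec(
    domain_length = 10, motif_length = 4, domain_plddt = 50,
    motif_plddt = 50), dir = tempfile())$model_model
  hi <- make_complex_pair(synthetic_complex_spec(
    domain_length = 10, motif_length = 4, domain_plddt = 90,
    motif_plddt = 90), dir = tempfile())$model_model
  expect_gte(pdockq(hi), pdockq(lo))

  # bounds
  for (mm in list(far, lo, hi, m)) {
    v <- pdockq(mm)
    expect_gt(v, unname(k["b"]))
    expect_lt(v, unname(k["L"] + k["b"]))
  }
})

test_that("iPAE is the median PAE over 3.5 A contacts, pooling directions", {
  spec <- synthetic_complex_spec(domain_length = 10, motif_length = 4,
                                 pae = 10)
  pair <- make_complex_pair(spec, dir = tempfile())
  m <- pair$model_model
  s <- read_scores(pair$scores)
  rep35 <- find_interface(m, cutoff = 3.5)
  expect_gt(rep35$residue_contacts, 0)
  expect_equal(ipae(m, s), 10)

  # asymmetric PAE: median pools (i,j) and (j,i)
  s2 <- s
  n <- nrow(s2$pae)
  contacts <- rep35$contacts
  idx <- fragscore:::pae_index_for_model(m, s2)
  s2$pae[] <- 0
  i <- idx[contacts$key_a]; j <- idx[contacts$key_b]
  s2$pae[cbind(i, j)] <- 4
  s2$pae[cbind(j, i)] <- 6
  expect_equal(ipae(m, s2), 5.0)

  # symmetrization of a symmetric matrix changes nothing
  s3 <- s
  s3$pae <- (s$pae + t(s$pae)) / 2
  expect_equal(ipae(m, s3), ipae(m, s))

  # no contact within 3.5 A: undefined
  far <- m
  far$atoms$y[far$atoms$chain == "B"] <-
    far$atoms$y[far$atoms$chain == "B"] - 100
  expect_warning(v <- ipae(far, s), "undefined")
  expect_true(is.na(v))
})

test_that("confidence calls apply the inclusive pLDDT and score cutoffs", {
  mk <- function(motif_plddt) {
    pair <- make_complex_pair(synthetic_complex_spec(
      domain_length = 10, motif_length = 4, motif_plddt = motif_plddt),
      dir = tempfile())
    pair$model_model
  }
  m70 <- mk(70); rep70 <- find_interface(m70)
  expect_true(classify_confident(rep70, m70, "disordered-ordered",
                                 disordered_chain = "B"))
  m699 <- mk(69.9); rep699 <- find_interface(m699)
  expect_false(classify_confident(rep699, m699, "disordered-ordered",
                                  disordered_chain = "B"))

  # ordered-ordered with the optional strict model-confidence filter
  m80 <- mk(80); rep80 <- find_interface(m80)
  expect_true(classify_confident(rep80, m80, "ordered-ordered",
                                 model_conf = 0.75,
                                 require_model_confidence = TRUE))
  expect_false(classify_confident(rep80, m80, "ordered-ordered",
                                  model_conf = 0.6,
                                  require_model_confidence = TRUE))
  # DDI alternative cutoff of 75 on the average interface pLDDT
  avg <- average_interface_plddt(rep70, m70)
  expect_equal(classify_confident(rep70, m70, "ordered-ordered",
                                  avg_plddt = 75), avg >= 75)
  # undefined metric: not confident, with a warning
  far <- two_atom_model(50)
  repf <- find_interface(far)
  expect_warning(
    flag <- classify_confident(repf, far, "disordered-ordered",
                               disordered_chain = "B"),
    "not confident")
  expect_false(flag)
})

test_that("metrics demand a resolvable chain pair", {
  m <- two_atom_model(3)
  expect_error(find_interface(m, c("A", "C")), "present")
  three <- toy_model(chain = c("A", "B", "C"), resno = 1,
                     atom_name = "CA",
                     xyz = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)))
  expect_error(find_interface(three), "name a chain pair")
  expect_equal(find_interface(three, c("A", "C"))$residue_contacts, 1L)
})
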