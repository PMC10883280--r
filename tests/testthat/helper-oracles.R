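# Independent brute-force oracles and tiny fixture builders used across the
# test files. The oracles deliberately share no code with the implementation
# paths they check.

# Minimal hand-built structure model: one atom per row.
toy_model <- function(chain, resno, atom_name, xyz, b = 70,
                      resname = "ALA", occupancy = 1, predicted = FALSE,
                      model_id = "toy") {
  atoms <- data.frame(
    chain = chain, resno = resno, icode = "", resname = resname,
    atom_name = atom_name, element = substr(atom_name, 1, 1),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = occupancy, b = b, stringsAsFactors = FALSE)
  fragscore:::new_structure_model(atoms, model_id = model_id,
                                  predicted = predicted)
}

# Brute-force all-pairs interface scan (double loop, no vectorization).
brute_interface <- function(model, chains, cutoff = 5) {
  at <- model$atoms
  a <- at[at$chain == chains[1], ]
  b <- at[at$chain == chains[2], ]
  res_a <- character(); res_b <- character()
  rr <- character(); atom_contacts <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                (a$z[i] - b$z[j])^2)
    if (d < cutoff) {
      atom_contacts <- atom_contacts + 1L
      ka <- paste(a$chain[i], a$resno[i], a$icode[i])
      kb <- paste(b$chain[j], b$resno[j], b$icode[j])
      res_a <- union(res_a, ka); res_b <- union(res_b, kb)
      rr <- union(rr, paste(ka, kb, sep = " / "))
    }
  }
  list(res_a = res_a, res_b = res_b,
       residue_contacts = length(rr), atom_contacts = atom_contacts)
}

# Random rigid transform (rotation from QR of a Gaussian matrix).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_model <- function(model, rot, shift = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(rot)
  model$atoms$x <- xyz[, 1] + shift[1]
  model$atoms$y <- xyz[, 2] + shift[2]
  model$atoms$z <- xyz[, 3] + shift[3]
  model
}

euler_rotation <- function(ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

# Numeric minimization over rotations (multi-start BFGS on Euler angles);
# independent oracle for the least-squares superposition RMSD.
numeric_min_rmsd <- function(p, q, n_starts = 20) {
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  obj <- function(ang) {
    r <- euler_rotation(ang)
    sqrt(mean(rowSums((pc %*% t(r) - qc)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    start <- runif(3, -pi, pi)
    fit <- tryCatch(
      optim(start, obj, method = "BFGS",
            control = list(reltol = 1e-15, maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(fit)) best <- min(best, fit$value)
  }
  best
}

# Concordant-pair (Mann-Whitney) AUROC by brute force.
brute_auroc <- function(values, labels) {
  pos <- values[labels == "positive"]; neg <- values[labels == "random"]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Miyata distance recomputed by explicit loops from the polarity/volume
# formula (independent of the vectorized implementation).
brute_miyata <- function(a, b) {
  p <- fragscore:::AA_POLARITY; v <- fragscore:::AA_VOLUME
  aa <- fragscore:::AA1
  dp <- c(); dv <- c()
  for (i in seq_along(aa)) for (j in seq_along(aa)) if (i < j) {
    dp <- c(dp, abs(p[aa[i]] - p[aa[j]]))
    dv <- c(dv, abs(v[aa[i]] - v[aa[j]]))
  }
  sqrt((abs(p[a] - p[b]) / sd(dp))^2 + (abs(v[a] - v[b]) / sd(dv))^2)
}
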