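# BRET plate analysis: bleedthrough/background correction, interaction
# detection calls, and donor-saturation titration fits of the 1:1 hyperbolic
# model BRET = (A/D) * BRETmax / (BRET50 + A/D).

#' Raw BRET ratio from luminescence readings
#'
#' Long-wavelength over short-wavelength luminescence (acceptor over donor
#' emission window). The window assignment is configurable since different
#' instruments/protocols may swap filter naming.
#'
#' @param long_wl_lum,short_wl_lum Luminescence readings (a.u.).
#' @return BRET ratio.
#' @export
raw_bret <- function(long_wl_lum, short_wl_lum) {
  if (any(short_wl_lum == 0))
    stop("zero short-wavelength luminescence; BRET ratio undefined")
  long_wl_lum / short_wl_lum
}

#' Corrected BRET (cBRET)
#'
#' Subtracts the maximal BRET of the two single-tag control pairs
#' (donor-only, acceptor-only) from the test-pair BRET, correcting for donor
#' bleedthrough, unspecific tag binding and background. May be negative.
#'
#' @param test_bret BRET ratio of the test pair.
#' @param control_a_bret,control_b_bret BRET ratios of the control pairs.
#' @return Corrected BRET.
#' @export
corrected_bret <- function(test_bret, control_a_bret, control_b_bret) {
  test_bret - pmax(control_a_bret, control_b_bret)
}

#' Interaction detection call
#'
#' A protein pair is called detected when, at the configured transfection
#' ratio, the corrected BRET, the acceptor-expression fluorescence and the
#' donor-expression total luminescence all meet their thresholds
#' (inclusive): cBRET >= 0.05, fluorescence >= 500 units, total
#' luminescence >= 50,000 units by default.
#'
#' @param cbret Corrected BRET at the detection transfection ratio.
#' @param fluorescence Fluorescence reading (acceptor expression, a.u.).
#' @param total_luminescence Total luminescence (donor expression, a.u.).
#' @param thresholds Named list with `cbret`, `fluorescence`,
#'   `luminescence`.
#' @return Logical detection flag.
#' @export
detect_interaction <- function(cbret, fluorescence, total_luminescence,
                               thresholds = list(cbret = 0.05,
                                                 fluorescence = 500,
                                                 luminescence = 50000)) {
  cbret >= thresholds$cbret &
    fluorescence >= thresholds$fluorescence &
    total_luminescence >= thresholds$luminescence
}

#' Acceptor/donor expression ratio
#'
#' Background-corrected fluorescence over background-corrected total
#' luminescence, optionally normalized for fluorescence gain settings via a
#' fluorescein-control factor.
#'
#' @param fluorescence,total_luminescence Test readings (a.u.).
#' @param background_fluor,background_lum Same-plate empty-vector background
#'   readings.
#' @param gain_norm Gain normalization factor (1 when all wells share one
#'   gain).
#' @return Ratio, `0` (with a warning) when the corrected fluorescence is
#'   zero, or `NA` (with a warning) when the corrected luminescence is not
#'   positive.
#' @export
acceptor_donor_ratio <- function(fluorescence, total_luminescence,
                                 background_fluor = 0, background_lum = 0,
                                 gain_norm = 1) {
  lum <- total_luminescence - background_lum
  if (any(lum <= 0)) {
    warning("corrected luminescence <= 0; point(s) excluded")
    lum[lum <= 0] <- NA_real_
  }
  fl <- fluorescence - background_fluor
  if (any(fl == 0, na.rm = TRUE))
    warning("corrected fluorescence is zero; point flagged")
  gain_norm * fl / lum
}

#' Fit a donor-saturation titration curve
#'
#' Least-squares fit of the 1:1 binding model
#' `BRET = (A/D) * BRETmax / (BRET50 + A/D)` to corrected-BRET measurements
#' over a range of acceptor/donor expression ratios. Standard errors are the
#' square roots of the diagonal of the fractional covariance matrix
#' `(J'J)^-1` multiplied by the residual variance. A runs test on the
#' residual signs flags systematic lack of fit (e.g. non-saturating or
#' non-1:1 binding trajectories) via `reliable = FALSE` while still
#' reporting the fit.
#'
#' @param ad_ratio Acceptor/donor expression ratios (> 0), or a data frame
#'   with columns `ad_ratio` and `cbret`.
#' @param cbret Corrected BRET values (ignored when `ad_ratio` is a data
#'   frame).
#' @return Object of class `bret_fit` with coefficients `bretmax`, `bret50`,
#'   their standard errors, `residual_variance`, `converged` and `reliable`.
#' @export
fit_titration <- function(ad_ratio, cbret = NULL) {
  if (is.data.frame(ad_ratio)) {
    cbret <- ad_ratio$cbret
    ad_ratio <- ad_ratio$ad_ratio
  }
  keep <- is.finite(ad_ratio) & is.finite(cbret)
  ad <- ad_ratio[keep]; y <- cbret[keep]
  if (length(ad) < 2L) stop("at least two titration points are required")
  if (any(ad <= 0)) stop("ad_ratio must be positive")

  start <- list(bretmax = max(y), bret50 = stats::median(ad))
  if (start$bretmax <= 0) start$bretmax <- 0.1
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ bretmax * ad / (bret50 + ad), start = start,
                      data = data.frame(ad = ad, y = y),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    out <- list(bretmax = NA_real_, bret50 = NA_real_,
                se_bretmax = NA_real_, se_bret50 = NA_real_,
                residual_variance = NA_real_, converged = FALSE,
                reliable = FALSE, n = length(ad),
                data = data.frame(ad_ratio = ad, cbret = y))
    return(structure(out, class = "bret_fit"))
  }

  cf <- stats::coef(fit)
  bmax <- unname(cf["bretmax"]); b50 <- unname(cf["bret50"])
  res <- y - bmax * ad / (b50 + ad)
  dof <- max(length(ad) - 2L, 1L)
  s2 <- sum(res^2) / dof
  # analytic Jacobian of the hyperbolic model
  jac <- cbind(bretmax = ad / (b50 + ad),
               bret50 = -bmax * ad / (b50 + ad)^2)
  cov_frac <- tryCatch(solve(crossprod(jac)), error = function(e) NULL)
  if (is.null(cov_frac)) {
    se <- c(NA_real_, NA_real_)
  } else {
    se <- sqrt(pmax(diag(cov_frac * s2), 0))
  }
  converged <- is.finite(bmax) && is.finite(b50) && bmax > 0 && b50 > 0
  structure(
    list(bretmax = bmax, bret50 = b50,
         se_bretmax = se[1], se_bret50 = se[2],
         residual_variance = s2, converged = converged,
         reliable = converged && residual_runs_ok(ad, res),
         n = length(ad),
         data = data.frame(ad_ratio = ad, cbret = y)),
    class = "bret_fit"
  )
}

# Wald-Wolfowitz runs test on residual signs (normal approximation); FALSE
# signals systematic deviation from the 1:1 model.
residual_runs_ok <- function(ad, res, alpha = 0.05) {
  s <- sign(res[order(ad)])
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 < 2 || n2 < 2 || n1 + n2 < 8) return(TRUE)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / (n1 + n2) + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
    ((n1 + n2)^2 * (n1 + n2 - 1))
  p <- 2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
  p >= alpha
}

#' @export
print.bret_fit <- function(x, ...) {
  if (!x$converged) {
    cat("bret_fit: not converged (", x$n, " points)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("bret_fit (%d points): BRETmax %.4f (SE %.4f), BRET50 %.4f (SE %.4f)\n",
              x$n, x$bretmax, x$se_bretmax, x$bret50, x$se_bret50))
  if (!x$reliable)
    cat("  warning: residual pattern suggests lack of fit (non-1:1 binding?)\n")
  invisible(x)
}

#' @export
coef.bret_fit <- function(object, ...) {
  c(bretmax = object$bretmax, bret50 = object$bret50)
}

#' @export
summary.bret_fit <- function(object, ...) {
  tab <- data.frame(
    estimate = c(object$bretmax, object$bret50),
    std_error = c(object$se_bretmax, object$se_bret50),
    row.names = c("bretmax", "bret50"))
  out <- list(coefficients = tab, residual_variance = object$residual_variance,
              converged = object$converged, reliable = object$reliable,
              n = object$n)
  class(out) <- "summary.bret_fit"
  out
}

#' @export
print.summary.bret_fit <- function(x, ...) {
  cat("BRET titration fit (", x$n, " points)\n", sep = "")
  print(x$coefficients)
  cat(sprintf("residual variance %.3g; converged: %s; reliable: %s\n",
              x$residual_variance, x$converged, x$reliable))
  invisible(x)
}

#' @export
predict.bret_fit <- function(object, newdata = NULL, ...) {
  ad <- if (is.null(newdata)) object$data$ad_ratio
        else if (is.data.frame(newdata)) newdata$ad_ratio else newdata
  object$bretmax * ad / (object$bret50 + ad)
}

#' @export
residuals.bret_fit <- function(object, ...) {
  object$data$cbret - predict(object)
}

#' @export
plot.bret_fit <- function(x, ...) {
  graphics::plot(x$data$ad_ratio, x$data$cbret, log = "x",
                 xlab = "acceptor/donor ratio", ylab = "corrected BRET", ...)
  if (x$converged) {
    grid <- exp(seq(log(min(x$data$ad_ratio)), log(max(x$data$ad_ratio)),
                    length.out = 100))
    graphics::lines(grid, predict(x, grid))
  }
  invisible(x)
}

#' Read a BRET plate CSV
#'
#' Columns: `pair_id`, `construct_role` (`test`, `control_donor_only`,
#' `control_acceptor_only`, `background`), `donor_ng`, `acceptor_ng`,
#' `fluorescence`, `total_lum`, `short_wl_lum`, `long_wl_lum`, `replicate`.
#'
#' @param path CSV path.
#' @return Data frame of well measurements.
#' @export
read_bret_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "construct_role", "donor_ng", "acceptor_ng",
            "fluorescence", "total_lum", "short_wl_lum", "long_wl_lum")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate file lacks column(s): ",
                         paste(miss, collapse = ", "))
  num <- c("donor_ng", "acceptor_ng", "fluorescence", "total_lum",
           "short_wl_lum", "long_wl_lum")
  if (any(as.matrix(df[num]) < 0, na.rm = TRUE))
    stop("negative readings in plate file")
  df
}

#' Analyse a BRET plate: cBRET per test well and detection calls
#'
#' For every test well of each pair, computes the raw BRET ratio, subtracts
#' the maximal BRET of the pair's two single-tag control wells at matched
#' DNA amounts (falling back to the controls' plate-wide maximum) and calls
#' detection at the configured transfection ratio.
#'
#' @param plate Data frame from [read_bret_plate()].
#' @param detect_donor_ng,detect_acceptor_ng Transfection amounts (ng)
#'   defining the detection condition; per-pair overrides via a named list
#'   `overrides` of `c(donor_ng, acceptor_ng)`.
#' @param overrides Optional named list of per-pair transfection ratios.
#' @param thresholds Passed to [detect_interaction()].
#' @return Data frame with one row per test well (`pair_id`, `donor_ng`,
#'   `acceptor_ng`, `cbret`, `fluorescence`, `total_lum`, `at_detection`,
#'   `detected`).
#' @export
analyze_bret_plate <- function(plate, detect_donor_ng = 2,
                               detect_acceptor_ng = 50, overrides = list(),
                               thresholds = list(cbret = 0.05,
                                                 fluorescence = 500,
                                                 luminescence = 50000)) {
  out <- list()
  for (pid in unique(plate$pair_id)) {
    p <- plate[plate$pair_id == pid, , drop = FALSE]
    tests <- p[p$construct_role == "test", , drop = FALSE]
    ctrl <- p[p$construct_role %in% c("control_donor_only",
                                      "control_acceptor_only"), ,
              drop = FALSE]
    if (nrow(tests) == 0L) next
    cond <- overrides[[pid]]
    dng <- if (is.null(cond)) detect_donor_ng else cond[1]
    ang <- if (is.null(cond)) detect_acceptor_ng else cond[2]
    for (i in seq_len(nrow(tests))) {
      w <- tests[i, ]
      tb <- raw_bret(w$long_wl_lum, w$short_wl_lum)
      ctrl_bret <- function(role) {
        c1 <- ctrl[ctrl$construct_role == role, , drop = FALSE]
        if (nrow(c1) == 0L) return(0)
        m <- c1[c1$donor_ng == w$donor_ng & c1$acceptor_ng == w$acceptor_ng, ,
                drop = FALSE]
        if (nrow(m) == 0L) m <- c1
        max(raw_bret(m$long_wl_lum, m$short_wl_lum))
      }
      cb <- corrected_bret(tb, ctrl_bret("control_donor_only"),
                           ctrl_bret("control_acceptor_only"))
      at_det <- w$donor_ng == dng && w$acceptor_ng == ang
      out[[length(out) + 1L]] <- data.frame(
        pair_id = pid, donor_ng = w$donor_ng, acceptor_ng = w$acceptor_ng,
        cbret = cb, fluorescence = w$fluorescence, total_lum = w$total_lum,
        at_detection = at_det,
        detected = at_det && detect_interaction(cb, w$fluorescence,
                                                w$total_lum, thresholds),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
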