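#' Continuous c(s) distribution fit
#'
#' Models observed sedimentation scans as a superposition of Lamm-equation
#' solutions, `a(r,t) = integral c(s) chi(s, D(s), r, t) ds`, with one shared
#' frictional ratio linking s to D(s) (see [diffusion_coefficient()]). The
#' distribution c(s) is recovered by non-negative least squares with
#' second-difference Tikhonov regularization. With `f_ratio = "fit"` the
#' frictional ratio is optimized by a golden-section scan over `[1.0, 2.5]`
#' minimizing the fit rmsd.
#'
#' @param data a `sedimentation_dataset` (from [lamm_simulate()],
#'   [simulate_auc()] or [read_scans()]); must contain at least two scans
#'   covering a sedimenting boundary.
#' @param s_grid grid of sedimentation coefficients in Svedberg (default 100
#'   points, 1-15 S, linear).
#' @param f_ratio frictional ratio f/f0, or `"fit"`.
#' @param lambda Tikhonov regularization weight on the second differences of
#'   c(s). The default is calibrated so that the residual rmsd of a fit at
#'   the package's reference noise level (sigma = 0.005) is of the order of
#'   that noise.
#' @param buffer a [hydro_params()]; defaults to the dataset's.
#' @param vbar partial specific volume, mL/g.
#' @param ncell_kernel radial cells for the Lamm kernels; `NULL` uses the
#'   data's own (uniform) grid so no interpolation is needed.
#' @param thin keep every `thin`-th radius when building the least-squares
#'   system (speed knob; 1 = all).
#' @param f_tol convergence tolerance of the golden-section f/f0 scan.
#' @return a `cs_fit` model object with components `s_grid`, `c`
#'   (concentration density per S, >= 0), `f_ratio`, `lambda`, `fit_rmsd`,
#'   `fitted`, `residuals`, `data`. Methods: `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `plot`.
#' @export
fit_cs <- function(data, s_grid = seq(1, 15, length.out = 100),
                   f_ratio = 1.2, lambda = 0.05, buffer = NULL,
                   vbar = NULL, ncell_kernel = NULL, thin = 1, f_tol = 0.01) {
  stopifnot(inherits(data, "sedimentation_dataset"))
  buffer <- buffer %||% data$buffer
  if (is.null(buffer)) stop("no hydro_params: pass buffer=")
  vbar <- vbar %||% buffer$vbar
  if (length(data$times) < 2) stop("need at least two scans (single-scan datasets rejected)")
  if (all(abs(data$scans) < .Machine$double.eps)) stop("all-zero scan data")
  if (any(diff(s_grid) <= 0)) stop("s_grid must be strictly increasing")

  if (identical(f_ratio, "fit")) {
    # coarse golden-section scan, then a final full-resolution solve
    coarse_s <- s_grid[seq(1, length(s_grid), by = 2)]
    coarse_thin <- max(thin, 2)
    obj <- function(fr) cs_solve(data, coarse_s, fr, lambda, buffer, vbar,
                                 ncell_kernel, coarse_thin)$fit_rmsd
    fr_best <- golden_section(obj, 1.0, 2.5, tol = f_tol)
    fit <- cs_solve(data, s_grid, fr_best, lambda, buffer, vbar,
                    ncell_kernel, thin)
    fit$f_ratio_fitted <- TRUE
    return(fit)
  }
  if (f_ratio < 1) stop("f_ratio < 1 is unphysical")
  fit <- cs_solve(data, s_grid, f_ratio, lambda, buffer, vbar,
                  ncell_kernel, thin)
  fit$f_ratio_fitted <- FALSE
  fit
}

# build the kernel matrix and solve the regularized NNLS problem
cs_solve <- function(data, s_grid, f_ratio, lambda, buffer, vbar,
                     ncell_kernel, thin) {
  radii <- data$radii
  h <- stats::median(diff(radii))
  uniform <- max(abs(diff(radii) - h)) < 1e-6 * h
  rm <- radii[1] - h / 2; rb <- radii[length(radii)] + h / 2
  ncell <- if (!is.null(ncell_kernel)) ncell_kernel
           else if (uniform) length(radii) else 300L
  K <- length(s_grid)
  ds <- mean(diff(s_grid))
  D <- diffusion_coefficient(s_grid, f_ratio, buffer, vbar)
  keep <- seq(1, length(radii), by = thin)
  nobs <- length(data$times) * length(keep)
  A <- matrix(0, nobs, K)
  vmax <- max(s_grid) * .S_unit * buffer$omega2 * rb
  dt <- max(1, min(30, ((rb - rm) / ncell) / vmax))
  for (k in seq_len(K)) {
    chi <- .lamm_core(as.integer(ncell), rm, rb, s_grid[k] * .S_unit, D[k],
                      buffer$omega2, data$times, dt, 1.0)
    if (ncell != length(radii)) {
      rk <- rm + (seq_len(ncell) - 0.5) * (rb - rm) / ncell
      chi <- t(apply(chi, 1, function(row)
        approx(rk, row, xout = radii, rule = 2)$y))
    }
    A[, k] <- as.numeric(t(chi[, keep, drop = FALSE])) * ds
  }
  b <- as.numeric(t(data$scans[, keep, drop = FALSE]))
  # second-difference Tikhonov rows, scaled to the data block
  D2 <- diff(diag(K), differences = 2)
  scale <- sqrt(lambda) * sqrt(nobs / nrow(D2)) * mean(abs(A))
  Aaug <- rbind(A, scale * D2)
  baug <- c(b, rep(0, nrow(D2)))
  sol <- pracma::lsqnonneg(Aaug, baug)
  cvec <- pmax(0, sol$x)
  fitted_b <- A %*% cvec
  resid <- b - fitted_b
  structure(list(s_grid = s_grid, c = as.numeric(cvec), f_ratio = f_ratio,
                 lambda = lambda, fit_rmsd = sqrt(mean(resid^2)),
                 fitted = fitted_b, residuals = as.numeric(resid),
                 times = data$times, radii = radii[keep], thin = thin,
                 data = data, buffer = buffer, vbar = vbar),
            class = "cs_fit")
}

golden_section <- function(f, lo, hi, tol = 0.01) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else { a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  (a + b) / 2
}

#' @export
print.cs_fit <- function(x, ...) {
  cat(sprintf("<cs_fit> %d-point s grid %.2f-%.2f S, f/f0 = %.3f%s, rmsd %.4g\n",
              length(x$s_grid), min(x$s_grid), max(x$s_grid), x$f_ratio,
              if (isTRUE(x$f_ratio_fitted)) " (fitted)" else "", x$fit_rmsd))
  pk <- peaks_to_species(x)
  if (nrow(pk)) {
    cat("  peaks:\n")
    print(data.frame(s = round(pk$s_obs, 2), s20w = round(pk$s_20w, 2),
                     M_kDa = round(pk$M / 1000, 1),
                     loading = signif(pk$loading, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.cs_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual rmsd %.5f over %d observations, lambda = %g\n",
              object$fit_rmsd, length(object$residuals), object$lambda))
  invisible(object)
}

#' @export
coef.cs_fit <- function(object, ...) setNames(object$c, format(object$s_grid))

#' @export
fitted.cs_fit <- function(object, ...) object$fitted

#' @export
residuals.cs_fit <- function(object, ...) object$residuals

#' @export
plot.cs_fit <- function(x, ...) {
  plot(x$s_grid, x$c, type = "l", xlab = "s (S)",
       ylab = "c(s) (signal / S)", ...)
  invisible(x)
}

#' Species estimates from a fitted c(s) distribution
#'
#' Local maxima of c(s) above a relative threshold become species: per peak,
#' the weighted-centroid s over the peak's support, its s20,w, diffusion
#' coefficient and Svedberg molecular weight (via [svedberg_mass()] at the
#' fit's frictional ratio), and the loading (integral of c(s) over the
#' support). With `monomer_mass` given, species whose mass is within 15% of
#' k times the monomer mass are labelled `"(ab)k"`.
#'
#' @param fit a `cs_fit`.
#' @param buffer,vbar override the fit's solution parameters.
#' @param rel_threshold peak threshold relative to max(c) (default 0.05).
#' @param monomer_mass optional monomer molar mass in Da for oligomer labels.
#' @return data frame of species: `s_obs`, `s_20w`, `D`, `M`, `loading`,
#'   and `label` when `monomer_mass` is given. Empty (with a warning) when
#'   no peak exceeds the threshold.
#' @export
peaks_to_species <- function(fit, buffer = NULL, vbar = NULL,
                             rel_threshold = 0.05, monomer_mass = NULL) {
  stopifnot(inherits(fit, "cs_fit"))
  buffer <- buffer %||% fit$buffer
  vbar <- vbar %||% fit$vbar
  cvec <- fit$c; s <- fit$s_grid
  K <- length(cvec)
  thr <- rel_threshold * max(cvec)
  empty <- data.frame(s_obs = numeric(0), s_20w = numeric(0), D = numeric(0),
                      M = numeric(0), loading = numeric(0))
  if (max(cvec) <= 0) { warning("flat zero distribution: no peaks"); return(empty) }
  cpad <- c(-Inf, cvec, -Inf)
  is_peak <- vapply(seq_len(K), function(i)
    cvec[i] > thr && cpad[i] <= cvec[i] && cvec[i] >= cpad[i + 2], logical(1))
  peaks <- which(is_peak)
  # collapse plateaus
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 1)]
  if (!length(peaks)) { warning("no peaks above threshold"); return(empty) }
  ds <- mean(diff(s))
  rows <- lapply(peaks, function(p) {
    lo <- p; while (lo > 1 && cvec[lo - 1] > thr && cvec[lo - 1] <= cvec[lo]) lo <- lo - 1
    hi <- p; while (hi < K && cvec[hi + 1] > thr && cvec[hi + 1] <= cvec[hi]) hi <- hi + 1
    sup <- lo:hi
    s_hat <- sum(cvec[sup] * s[sup]) / sum(cvec[sup])
    est <- svedberg_mass(s_hat, fit$f_ratio, buffer, vbar,
                         loading = sum(cvec[sup]) * ds)
    est
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(monomer_mass)) {
    k <- pmax(1, round(out$M / monomer_mass))
    ok <- abs(out$M - k * monomer_mass) / (k * monomer_mass) <= 0.15
    out$label <- ifelse(ok, paste0("(ab)", k), NA_character_)
  }
  out
}
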