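#' Cyclic B-spline basis and difference penalty
#'
#' Evaluates a periodic cubic B-spline basis on clock times by the standard
#' knot-wrapping construction (evenly spaced knots over one period; the
#' basis functions that spill over the period boundary are folded back), and
#' builds the cyclic difference penalty on the spline coefficients.
#'
#' @param hours Evaluation points, hours (reduced modulo `period`).
#' @param n_basis Number of basis functions.
#' @param period Period in hours (default 24).
#' @return `cyclic_bspline_basis()`: a `length(hours) x n_basis` design
#'   matrix; rows sum to 1 (partition of unity).
#' @export
cyclic_bspline_basis <- function(hours, n_basis = 24L, period = 24) {
  stopifnot(n_basis >= 4L)
  h <- period / n_basis
  knots <- seq(-4 * h, period + 4 * h, by = h)
  B <- splines::splineDesign(knots, hours %% period, ord = 4,
                             outer.ok = TRUE)
  # fold the wrap-around columns: column j and j + n_basis represent the
  # same periodic basis function
  extra <- ncol(B) - n_basis
  for (j in seq_len(extra)) B[, j] <- B[, j] + B[, j + n_basis]
  B[, seq_len(n_basis), drop = FALSE]
}

#' @rdname cyclic_bspline_basis
#' @param order Difference order of the penalty (default 2).
#' @param cyclic Wrap differences across the period boundary?
#' @return `diff_penalty()`: the `n_basis x n_basis` penalty matrix `D'D`;
#'   cyclic second differences have a one-dimensional null space (constants).
#' @export
diff_penalty <- function(n_basis, order = 2L, cyclic = TRUE) {
  if (cyclic) {
    D <- diag(n_basis)
    for (k in seq_len(order)) {
      D <- D[c(2:n_basis, 1), , drop = FALSE] - D
    }
  } else {
    D <- diff(diag(n_basis), differences = order)
  }
  crossprod(D)
}

#' Basis specification for coefficient curves
#'
#' @param n_basis Basis dimension per coefficient curve (default 24).
#' @param degree Spline degree (cubic; fixed at 3).
#' @param penalty_order Difference-penalty order (default 2).
#' @param cyclic Periodic basis over `[0, 24)` h? Curves then wrap
#'   continuously across midnight (default `TRUE`).
#' @return A `hrv_basis_spec` list.
#' @export
basis_spec <- function(n_basis = 24L, degree = 3L, penalty_order = 2L,
                       cyclic = TRUE) {
  if (n_basis < penalty_order + 2)
    stop_config("n_basis", "must be at least penalty_order + 2")
  if (degree != 3L) stop_config("degree", "only cubic (3) is supported")
  structure(list(n_basis = as.integer(n_basis), degree = 3L,
                 penalty_order = as.integer(penalty_order),
                 cyclic = isTRUE(cyclic)), class = "hrv_basis_spec")
}

#' Build the functional design from profiles and covariates
#'
#' Joins subject profiles to the covariate table and assembles the scalar
#' design: the target indicator (MCI status, or one domain's impairment
#' flag), age and education centered at the sample mean, a female indicator,
#' and ethnicity dummies against non-Hispanic White. The secondary model
#' adds depression, diabetes, and hypertension flags.
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param covariates Covariate tibble (`subject_id`, `age`, `sex`,
#'   `ethnicity`, `education`, the target column, and for the secondary
#'   model `depression`, `diabetes`, `hypertension`).
#' @param model `"primary"` (7 coefficient curves including the intercept)
#'   or `"secondary"` (10).
#' @param target Name of the 0/1 covariate of interest (default `"mci"`).
#' @return A `hrv_fosr_design`: observations (`subject_id`, `bin`, `y`),
#'   scalar design matrix `x` (subjects x terms, intercept first), and the
#'   grid size.
#' @export
build_design <- function(profiles, covariates, model = c("primary", "secondary"),
                         target = "mci") {
  model <- match.arg(model)
  ids <- unique(profiles$subject_id)
  unmatched <- setdiff(ids, covariates$subject_id)
  if (length(unmatched) > 0)
    stop("profiles contain subjects missing from the covariate table: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  cov <- covariates[match(ids, covariates$subject_id), ]
  if (!target %in% names(cov))
    stop("target covariate '", target, "' not in covariate table",
         call. = FALSE)
  x <- cbind(
    intercept = 1,
    target = as.numeric(cov[[target]]),
    age_c = cov$age - mean(cov$age),
    female = as.integer(cov$sex == "female"),
    black = as.integer(cov$ethnicity == "nh_black"),
    other = as.integer(cov$ethnicity == "other"),
    education_c = cov$education - mean(cov$education))
  colnames(x)[2] <- target
  if (model == "secondary") {
    x <- cbind(x, depression = as.numeric(cov$depression),
               diabetes = as.numeric(cov$diabetes),
               hypertension = as.numeric(cov$hypertension))
  }
  rownames(x) <- ids
  qx <- qr(x)
  if (qx$rank < ncol(x))
    stop("collinear covariate columns: ",
         paste(colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]], collapse = ", "),
         call. = FALSE)
  obs <- profiles[!is.na(profiles$y), c("subject_id", "bin", "y")]
  counts <- table(obs$subject_id)
  if (any(!ids %in% names(counts)))
    stop("subjects with no observed bins: ",
         paste(setdiff(ids, names(counts)), collapse = ", "), call. = FALSE)
  structure(list(obs = obs, x = x, ids = ids, model = model, target = target,
                 grid = N_BINS), class = "hrv_fosr_design")
}

# eigen-reparametrization of one curve's basis: fixed (penalty null space)
# and scaled penalized columns, so every penalized coefficient carries an
# i.i.d. N(0, phi/lambda) prior in the mixed-model representation
reparam_basis <- function(C, P) {
  eg <- eigen(P, symmetric = TRUE)
  tol <- max(eg$values) * 1e-9
  null_idx <- which(eg$values < tol)
  range_idx <- which(eg$values >= tol)
  list(
    Cf = C %*% eg$vectors[, null_idx, drop = FALSE],
    Cz = C %*% eg$vectors[, range_idx, drop = FALSE] %*%
      diag(1 / sqrt(eg$values[range_idx]), length(range_idx)),
    n_fixed = length(null_idx))
}

#' Fit the function-on-scalar additive mixed model
#'
#' Fits `Y_i(t) = beta_0(t) + sum_k beta_k(t) x_ik + b_i + eps_i(t)` on the
#' 288-bin grid. Each coefficient curve is expanded in a penalized cyclic
#' B-spline basis; penalties are handled through their mixed-model
#' representation (penalized basis coefficients as i.i.d. Gaussian random
#' effects with variance `sigma_eps^2 / lambda_k`), the subject intercept as
#' a further i.i.d. Gaussian component. Smoothing parameters and variance
#' components maximize the restricted likelihood, profiled over the error
#' variance and optimized by `nlminb` on the log scale. The fit uses the
#' observed (subject, bin) pairs only, so missing bins need no imputation,
#' and is deterministic (no random initialization).
#'
#' @param design A [build_design()] result.
#' @param basis A [basis_spec()].
#' @param lambda Optional named numeric vector fixing the smoothing
#'   parameters (one per curve plus `subject`) instead of REML selection.
#' @param control List: `maxit` (default 200), `reltol` (1e-10), `rho_start`
#'   (initial log smoothing parameters).
#' @return A `hrv_fosr_fit` with coefficient curve matrix
#'   `coefficients` (288 x K), pointwise `se`, smoothing parameters
#'   `lambda`, variance components `sigma_b`/`sigma_eps`, effective dof per
#'   curve `edf`, the REML criterion value, fitted values and residuals, and
#'   convergence info.
#' @export
fosr_fit <- function(design, basis = basis_spec(), lambda = NULL,
                     control = list()) {
  stopifnot(inherits(design, "hrv_fosr_design"))
  maxit <- control$maxit %||% 200L
  reltol <- control$reltol %||% 1e-10

  X <- design$x
  K <- ncol(X)
  terms <- colnames(X)
  obs <- design$obs
  n <- nrow(obs)
  y <- obs$y
  subj <- match(obs$subject_id, design$ids)
  n_subj <- length(design$ids)

  C <- cyclic_basis_for(basis)
  P <- diff_penalty(basis$n_basis, basis$penalty_order, basis$cyclic)
  rp <- reparam_basis(C, P)
  Cf_obs <- rp$Cf[obs$bin + 1L, , drop = FALSE]
  Cz_obs <- rp$Cz[obs$bin + 1L, , drop = FALSE]
  n_f <- rp$n_fixed                 # unpenalized columns per curve
  n_z <- ncol(rp$Cz)                # penalized columns per curve

  # model matrix: per-curve fixed parts, per-curve penalized parts, subjects
  Xr <- X[subj, , drop = FALSE]
  Mf <- do.call(cbind, lapply(seq_len(K), function(k) Cf_obs * Xr[, k]))
  Mz <- do.call(cbind, lapply(seq_len(K), function(k) Cz_obs * Xr[, k]))
  Zb <- matrix(0, n, n_subj)
  Zb[cbind(seq_len(n), subj)] <- 1
  M <- cbind(Mf, Mz, Zb)
  p_f <- K * n_f
  p <- ncol(M)
  if (n < p_f + 2)
    stop("too few observations for the penalized design", call. = FALSE)

  G <- crossprod(M)
  g <- crossprod(M, y)
  yty <- sum(y * y)
  pen_index <- c(rep(seq_len(K), each = n_z), rep(K + 1L, n_subj))

  reml_obj <- function(rho) {
    lam <- exp(rho)[pen_index]
    A <- G
    diag(A)[(p_f + 1):p] <- diag(G)[(p_f + 1):p] + lam
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    beta <- backsolve(R, forwardsolve(t(R), g))
    Q <- max(yty - sum(beta * g), 1e-300)
    (n - p_f) * log(Q) + 2 * sum(log(diag(R))) - sum(log(lam))
  }

  if (is.null(lambda)) {
    rho0 <- control$rho_start %||% rep(log(10), K + 1L)
    opt <- nlminb(rho0, reml_obj, lower = -20, upper = 30,
                  control = list(iter.max = maxit, eval.max = 10 * maxit,
                                 rel.tol = reltol))
    if (opt$iterations >= maxit)
      stop("REML optimization failed to converge within ", maxit,
           " iterations (last criterion ", signif(opt$objective, 8), ")",
           call. = FALSE)
    rho <- opt$par
    convergence <- list(code = opt$convergence, message = opt$message,
                        iterations = opt$iterations)
  } else {
    stopifnot(length(lambda) == K + 1L, all(lambda > 0))
    rho <- log(unname(lambda))
    opt <- list(objective = reml_obj(rho))
    convergence <- list(code = 0L, message = "fixed lambda", iterations = 0L)
  }

  lam_full <- exp(rho)[pen_index]
  A <- G
  diag(A)[(p_f + 1):p] <- diag(G)[(p_f + 1):p] + lam_full
  R <- chol(A)
  beta <- drop(backsolve(R, forwardsolve(t(R), g)))
  Q <- yty - sum(beta * g)
  phi <- Q / (n - p_f)
  Ainv <- chol2inv(R)

  lambda_hat <- stats::setNames(exp(rho), c(terms, "subject"))
  sigma_eps <- sqrt(phi)
  sigma_b <- sqrt(phi / lambda_hat[["subject"]])

  # back out curves, pointwise SEs, and effective dof on the full grid
  Bfull <- cbind(rp$Cf, rp$Cz)      # 288 x (n_f + n_z)
  coef_mat <- se_mat <- matrix(NA_real_, N_BINS, K,
                               dimnames = list(NULL, terms))
  edf <- stats::setNames(numeric(K + 1L), c(terms, "subject"))
  H <- Ainv %*% G                   # influence of each coefficient
  for (k in seq_len(K)) {
    idx <- c((k - 1L) * n_f + seq_len(n_f),
             p_f + (k - 1L) * n_z + seq_len(n_z))
    coef_mat[, k] <- drop(Bfull %*% beta[idx])
    Vk <- phi * Ainv[idx, idx, drop = FALSE]
    se_mat[, k] <- sqrt(pmax(rowSums((Bfull %*% Vk) * Bfull), 0))
    edf[k] <- sum(diag(H)[idx])
  }
  b_idx <- (p_f + K * n_z) + seq_len(n_subj)
  edf[K + 1L] <- sum(diag(H)[b_idx])
  b_hat <- stats::setNames(beta[b_idx], design$ids)

  fitted <- drop(M %*% beta)
  structure(list(
    coefficients = coef_mat, se = se_mat, lambda = lambda_hat,
    sigma_b = sigma_b, sigma_eps = sigma_eps, edf = edf,
    reml = opt$objective, n_obs = n, phi = phi,
    subject_intercepts = b_hat, fitted = fitted, residuals = y - fitted,
    design = design, basis = basis, convergence = convergence,
    grid_hours = bin_to_hour(0:287)), class = "hrv_fosr_fit")
}

cyclic_basis_for <- function(basis) {
  hours <- bin_to_hour(0:287)
  if (basis$cyclic) {
    cyclic_bspline_basis(hours, basis$n_basis)
  } else {
    knots <- seq(0, 24, length.out = basis$n_basis - 2)
    splines::splineDesign(c(rep(0, 3), knots, rep(24, 3)), hours, ord = 4)
  }
}

#' @export
print.hrv_fosr_fit <- function(x, ...) {
  cat("Function-on-scalar additive mixed model fit\n")
  cat(sprintf("  observations: %d  subjects: %d  curves: %d (%s)\n",
              x$n_obs, length(x$subject_intercepts),
              ncol(x$coefficients), x$design$model))
  cat(sprintf("  sigma_b = %.3f  sigma_eps = %.3f (residual, profile scale)\n",
              x$sigma_b, x$sigma_eps))
  cat("  effective dof per curve:\n")
  print(round(x$edf, 2))
  invisible(x)
}

#' @export
coef.hrv_fosr_fit <- function(object, ...) object$coefficients

#' Pointwise confidence bands for coefficient curves
#'
#' Normal-theory pointwise intervals `beta_k(t) +/- z * SE_k(t)` on the
#' 288-bin grid, using the penalized-fit posterior covariance (shading-style
#' bands; no simultaneous adjustment).
#'
#' @param fit A [fosr_fit()] result.
#' @param level Coverage level in (0, 1).
#' @param coefficient Optional curve name(s); default all.
#' @return Tidy tibble: `coefficient`, `bin`, `hour`, `estimate`, `se`,
#'   `lower`, `upper`.
#' @export
pointwise_ci <- function(fit, level = 0.95, coefficient = NULL) {
  stopifnot(inherits(fit, "hrv_fosr_fit"))
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  terms <- coefficient %||% colnames(fit$coefficients)
  stopifnot(all(terms %in% colnames(fit$coefficients)))
  z <- qnorm(1 - (1 - level) / 2)
  out <- lapply(terms, function(k) {
    tibble::tibble(coefficient = k, bin = 0:287, hour = fit$grid_hours,
                   estimate = fit$coefficients[, k], se = fit$se[, k],
                   lower = fit$coefficients[, k] - z * fit$se[, k],
                   upper = fit$coefficients[, k] + z * fit$se[, k])
  })
  dplyr::bind_rows(out)
}

#' Clock windows where a coefficient's CI excludes zero
#'
#' Maximal runs of consecutive bins whose pointwise interval lies entirely
#' above or entirely below zero, merged across the midnight wrap, reported
#' as clock intervals.
#'
#' @inheritParams pointwise_ci
#' @param coefficient Single curve name.
#' @return Tibble: `start_hour`, `end_hour` (end exclusive; an interval that
#'   wraps midnight has `end_hour < start_hour`), `start_clock`,
#'   `end_clock`, `sign` ("below"/"above"), `n_bins`.
#' @export
significance_windows <- function(fit, coefficient, level = 0.95) {
  ci <- pointwise_ci(fit, level, coefficient)
  state <- integer(N_BINS)           # -1 below zero, +1 above, 0 neither
  state[ci$upper < 0] <- -1L
  state[ci$lower > 0] <- 1L
  if (all(state == 0L))
    return(tibble::tibble(start_hour = numeric(), end_hour = numeric(),
                          start_clock = character(), end_clock = character(),
                          sign = character(), n_bins = integer()))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0L
  win <- data.frame(start = starts[keep], end = ends[keep],
                    value = runs$values[keep])
  # merge across the midnight wrap
  if (nrow(win) > 1 && win$start[1] == 1L && win$end[nrow(win)] == N_BINS &&
      win$value[1] == win$value[nrow(win)]) {
    win$start[1] <- win$start[nrow(win)]
    win <- win[-nrow(win), , drop = FALSE]
  }
  n_bins <- ifelse(win$end >= win$start, win$end - win$start + 1L,
                   N_BINS - win$start + 1L + win$end)
  start_hour <- bin_to_hour(win$start - 1L)
  end_hour <- (bin_to_hour(win$end - 1L) + 5 / 60) %% 24
  tibble::tibble(
    start_hour = start_hour, end_hour = end_hour,
    start_clock = format_clock(start_hour),
    end_clock = format_clock(ifelse(end_hour == 0, 24, end_hour)),
    sign = ifelse(win$value < 0, "below", "above"),
    n_bins = as.integer(n_bins))
}

#' Standardized effect size (Cohen's d)
#'
#' Divides a group difference by a reference SD — here the sample SD of
#' person-level mean Ln(HF-HRV).
#'
#' @param difference Group difference (ln ms^2).
#' @param sd_ref Reference SD (must be positive).
#' @return `difference / sd_ref`.
#' @export
#' @examples
#' cohens_d(0.6, 0.8)  # 0.75
cohens_d <- function(difference, sd_ref) {
  if (!is.numeric(sd_ref) || any(sd_ref <= 0))
    stop("sd_ref must be positive", call. = FALSE)
  difference / sd_ref
}
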