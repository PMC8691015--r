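#' Cell-indexed observer measurements
#'
#' Validates the long-format input shared by the variability estimators: one
#' value per (structure, patient, observer).
#'
#' @param data data frame with columns `structure`, `patient`, `observer`,
#'   `value`.
#' @return The validated data frame (factors coerced to character).
#' @export
cell_values <- function(data) {
  need <- c("structure", "patient", "observer", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))
  data$structure <- as.character(data$structure)
  data$patient <- as.character(data$patient)
  data$observer <- as.character(data$observer)
  data$value <- as.double(data$value)
  key <- paste(data$structure, data$patient, data$observer)
  if (anyDuplicated(key))
    stop("duplicate (structure, patient, observer) cells")
  data
}

new_estimate <- function(structure, metric, estimate, lower, upper, kind,
                         n, flag = NA_character_) {
  data.frame(structure = structure, metric = metric, estimate = estimate,
             lower = lower, upper = upper, interval = kind, n = n,
             flag = flag, stringsAsFactors = FALSE)
}

#' Coefficient of variation from a log-normal model
#'
#' Fits, per structure, the log-normal measurement model
#' `log(value) = cell mean + error`, where the cells index all
#' (structure, patient) combinations and the error is Gaussian with a
#' structure-specific variance `sigma^2`. The interobserver CV follows as
#' `sqrt(exp(sigma^2) - 1)`. With the cell means profiled out, the residual
#' sum of squares is sufficient for `sigma^2`; under a conjugate
#' inverse-gamma prior `IG(a, b)` the posterior is
#' `IG(a + df / 2, b + SS / 2)`, from which the point estimate (posterior
#' median) and the equal-tailed 95% credible interval are taken.
#'
#' @param data a [cell_values()] data frame; values must be positive.
#' @param level credible level (default 0.95).
#' @param prior_a,prior_b inverse-gamma prior parameters (weakly
#'   informative default 0.001).
#' @return Data frame with one row per structure: `estimate`, `lower`,
#'   `upper` (CV as a fraction), `interval = "credible"`, `n`, `flag`.
#' @export
lognormal_cv <- function(data, level = 0.95, prior_a = 0.001,
                         prior_b = 0.001) {
  data <- cell_values(data)
  if (any(data$value <= 0))
    stop("log-normal CV requires strictly positive values")
  alpha <- (1 - level) / 2
  out <- lapply(split(data, data$structure), function(d) {
    cell <- paste(d$patient)
    sizes <- table(cell)
    if (any(sizes < 2)) {
      warning(sprintf("%s: dropping %d singleton cell(s)", d$structure[1],
                      sum(sizes < 2)))
      d <- d[cell %in% names(sizes)[sizes >= 2], ]
      cell <- paste(d$patient)
    }
    if (length(unique(cell)) < 2 || nrow(d) < 4)
      return(new_estimate(d$structure[1], "cv", NA, NA, NA, "credible",
                          nrow(d), "not_calculated"))
    ly <- log(d$value)
    cm <- ave(ly, cell)
    ss <- sum((ly - cm)^2)
    df <- nrow(d) - length(unique(cell))
    a <- prior_a + df / 2
    b <- prior_b + ss / 2
    # sigma^2 ~ IG(a, b) <=> 1 / sigma^2 ~ Gamma(a, rate = b)
    s2q <- function(p) b / qgamma(1 - p, shape = a)
    cv <- function(s2) sqrt(exp(s2) - 1)
    new_estimate(d$structure[1], "cv", cv(s2q(0.5)), cv(s2q(alpha)),
                 cv(s2q(1 - alpha)), "credible", nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# negative log-likelihood and gradient of the cell-mean beta model:
# theta = (eta_1..eta_C, log phi); mu_c = plogis(eta_c); y ~ Beta(mu phi,
# (1 - mu) phi) within cell c
beta_nll <- function(theta, y, cell_idx, n_cells) {
  mu <- plogis(theta[seq_len(n_cells)])[cell_idx]
  phi <- exp(theta[n_cells + 1])
  -sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

beta_nll_grad <- function(theta, y, cell_idx, n_cells) {
  eta <- theta[seq_len(n_cells)]
  mu_c <- plogis(eta)
  mu <- mu_c[cell_idx]
  phi <- exp(theta[n_cells + 1])
  ystar <- log(y) - log1p(-y)
  dl_dmu <- phi * (ystar - digamma(mu * phi) + digamma((1 - mu) * phi))
  g_eta <- -vapply(seq_len(n_cells), function(c)
    sum(dl_dmu[cell_idx == c]) * mu_c[c] * (1 - mu_c[c]), numeric(1))
  dl_dphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                 (1 - mu) * digamma((1 - mu) * phi) +
                 mu * log(y) + (1 - mu) * log1p(-y))
  c(g_eta, -dl_dphi * phi)
}

# interobserver SD implied by a beta model: structure-level mean mu and
# precision phi give Var(y) = mu (1 - mu) / (1 + phi)
beta_sd_value <- function(mu, phi) sqrt(mu * (1 - mu) / (1 + phi))

fit_beta_cells <- function(y, cell_idx, n_cells) {
  # moment-based starting values
  mu0 <- vapply(seq_len(n_cells), function(c) mean(y[cell_idx == c]),
                numeric(1))
  mu0 <- pmin(pmax(mu0, 1e-4), 1 - 1e-4)
  v0 <- vapply(seq_len(n_cells), function(c) var(y[cell_idx == c]),
               numeric(1))
  with_var <- is.finite(v0) & v0 > 0
  phi0 <- if (any(with_var)) {
    stats::median(mu0[with_var] * (1 - mu0[with_var]) / v0[with_var] - 1)
  } else 50
  phi0 <- min(max(phi0, 1), 1e4)
  fit <- optim(c(qlogis(mu0), log(phi0)), beta_nll, gr = beta_nll_grad,
               y = y, cell_idx = cell_idx, n_cells = n_cells,
               method = "BFGS", control = list(maxit = 500))
  list(mu = plogis(fit$par[seq_len(n_cells)]),
       phi = exp(fit$par[n_cells + 1]), convergence = fit$convergence)
}

#' Standard deviation of a proportion from a beta regression
#'
#' Fits, per structure, a beta regression with logit-linked cell means (cells
#' indexing all structure-patient combinations) and a structure-specific
#' precision `phi`, by maximum likelihood. The interobserver SD is
#' `sqrt(mu * (1 - mu) / (1 + phi))` evaluated at the structure-level mean
#' `mu` (the average of the cell means). The 95% interval is a seeded
#' parametric bootstrap. Structures whose values are all 0 or all 1 (e.g.
#' a structure never reaching the dose threshold) are flagged
#' `"not_calculated"`.
#'
#' Values exactly at 0 or 1 are compressed to the open interval by the usual
#' `(y * (n - 1) + 0.5) / n` transformation before fitting.
#'
#' @param data a [cell_values()] data frame of fractions in `[0, 1]`.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param level interval level.
#' @return Data frame with one row per structure; estimates on the fraction
#'   scale.
#' @export
beta_sd <- function(data, B = 1000, seed = 1, level = 0.95) {
  data <- cell_values(data)
  if (any(data$value < 0 | data$value > 1))
    stop("beta SD requires values in [0, 1]")
  alpha <- (1 - level) / 2
  out <- lapply(split(data, data$structure), function(d) {
    if (all(d$value == 0) || all(d$value == 1))
      return(new_estimate(d$structure[1], "sd", NA, NA, NA, "bootstrap",
                          nrow(d), "not_calculated"))
    n <- nrow(d)
    y <- (d$value * (n - 1) + 0.5) / n
    cells <- unique(d$patient)
    cell_idx <- match(d$patient, cells)
    n_cells <- length(cells)
    # ML underestimates the within-cell dispersion when one mean per cell is
    # profiled out; rescale the implied variance by n / (n - C) (REML-style
    # degrees-of-freedom correction) before converting to a precision
    adjust <- function(f) {
      f$phi <- max((1 + f$phi) * (n - n_cells) / n - 1, 1e-8)
      f
    }
    fit <- adjust(fit_beta_cells(y, cell_idx, n_cells))
    sd_of <- function(f) beta_sd_value(mean(f$mu), f$phi)
    est <- sd_of(fit)
    set.seed(seed)
    boot <- vapply(seq_len(B), function(i) {
      yb <- rbeta(n, fit$mu[cell_idx] * fit$phi,
                  (1 - fit$mu[cell_idx]) * fit$phi)
      yb <- pmin(pmax(yb, 1e-12), 1 - 1e-12)
      sd_of(adjust(fit_beta_cells(yb, cell_idx, n_cells)))
    }, numeric(1))
    ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE)
    new_estimate(d$structure[1], "sd", est, ci[1], ci[2], "bootstrap", n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater intraclass
#' correlation from the two-way ANOVA decomposition:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)` with `n` patients
#' and `k` observers. The 95% interval is the standard F-based confidence
#' interval (McGraw & Wong). Mild imbalance (up to 10% missing cells) is
#' handled through the sequential ANOVA with the other factor entered first;
#' more missingness is an error (no imputation).
#'
#' @param data a [cell_values()] data frame (single or multiple structures).
#' @param level confidence level.
#' @return Data frame with one row per structure; `interval = "confidence"`.
#' @export
icc2 <- function(data, level = 0.95) {
  data <- cell_values(data)
  alpha <- 1 - level
  out <- lapply(split(data, data$structure), function(d) {
    pats <- unique(d$patient)
    obs <- unique(d$observer)
    n <- length(pats)
    k <- length(obs)
    if (n < 2 || k < 2)
      stop(d$structure[1], ": ICC needs >= 2 patients and >= 2 observers")
    n_missing <- n * k - nrow(d)
    if (n_missing > 0.1 * n * k)
      stop(d$structure[1], sprintf(
        ": %d of %d cells missing (> 10%%); no imputation", n_missing, n * k))
    if (var(d$value) == 0)
      return(new_estimate(d$structure[1], "icc", NA, NA, NA, "confidence",
                          nrow(d), "not_calculated"))
    p <- factor(d$patient, levels = pats)
    o <- factor(d$observer, levels = obs)
    ms <- anova(lm(d$value ~ o + p))
    msr <- ms["p", "Mean Sq"]
    mse <- ms["Residuals", "Mean Sq"]
    msc <- anova(lm(d$value ~ p + o))["o", "Mean Sq"]
    r <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    # F-based interval (McGraw & Wong 1996, case 2, single rater)
    a <- k * r / (n * (1 - r))
    b <- 1 + k * r * (n - 1) / (n * (1 - r))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    # tiny designs (n = 2) make qf emit qbeta accuracy warnings about far
    # decimals of an interval endpoint that is weakly determined anyway
    v <- min(max(v, 1e-3), 1e6)
    fl <- suppressWarnings(qf(1 - alpha / 2, n - 1, v))
    fu <- suppressWarnings(qf(1 - alpha / 2, v, n - 1))
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    new_estimate(d$structure[1], "icc", r, lo, hi, "confidence", nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Structure-specific variability table
#'
#' Combines the four per-structure variability estimates into one report:
#' CV (log-normal model) for structure volume, DMEAN and D2CC; SD (beta
#' model) for V5GY; and ICC(2,1) for all four quantities. CVs are reported in
#' percent, the V5GY SD in percentage points.
#'
#' @param volumes,dmean,d2cc [cell_values()] data frames of positive values.
#' @param v5gy a [cell_values()] data frame of fractions in `[0, 1]`.
#' @param B bootstrap replicates for the beta SD interval.
#' @param seed seed for the bootstrap.
#' @return Data frame of class `variability_table`, one row per structure,
#'   with `<metric>`, `<metric>_lo`, `<metric>_hi` columns for `cv_volume`,
#'   `cv_dmean`, `cv_d2cc`, `sd_v5gy`, `icc_volume`, `icc_dmean`,
#'   `icc_d2cc`, `icc_v5gy`, plus a `flags` column naming metrics that were
#'   not calculated.
#' @export
variability_report <- function(volumes, dmean, d2cc, v5gy, B = 1000,
                               seed = 1) {
  parts <- list(
    cv_volume = transform_est(lognormal_cv(volumes), 100),
    cv_dmean = transform_est(lognormal_cv(dmean), 100),
    cv_d2cc = transform_est(lognormal_cv(d2cc), 100),
    sd_v5gy = transform_est(beta_sd(v5gy, B = B, seed = seed), 100),
    icc_volume = transform_est(icc2(volumes), 1),
    icc_dmean = transform_est(icc2(dmean), 1),
    icc_d2cc = transform_est(icc2(d2cc), 1),
    icc_v5gy = transform_est(icc2(v5gy), 1))
  structs <- unique(unlist(lapply(parts, function(p) p$structure)))
  structs <- c(intersect(atlas_structures(), structs),
               setdiff(structs, atlas_structures()))
  out <- data.frame(structure = structs, stringsAsFactors = FALSE)
  flags <- rep("", length(structs))
  for (nm in names(parts)) {
    p <- parts[[nm]]
    i <- match(structs, p$structure)
    out[[nm]] <- p$estimate[i]
    out[[paste0(nm, "_lo")]] <- p$lower[i]
    out[[paste0(nm, "_hi")]] <- p$upper[i]
    flagged <- !is.na(p$flag[i])
    flags[flagged] <- paste(flags[flagged],
                            paste0(nm, ":", p$flag[i][flagged]))
  }
  out$flags <- trimws(flags)
  class(out) <- c("variability_table", "data.frame")
  out
}

transform_est <- function(est, scale) {
  est$estimate <- est$estimate * scale
  est$lower <- est$lower * scale
  est$upper <- est$upper * scale
  est
}
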