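#' Assay curve containers
#'
#' Constructors for the four experimental readouts the campaign analyses:
#' thermal-shift melt curves, coupled-assay kinetic traces (NADH
#' fluorescence decay), cellular/enzymatic dose-response tables and
#' integrated ITC isotherms. Units are normalised package-wide: degrees
#' Celsius, seconds, nanomolar, kcal/mol.
#'
#' @param temperature Ascending temperature grid (degrees C), >= 20 points.
#' @param fluorescence Fluorescence values (arbitrary units).
#' @param label Curve label (`"apo"` or a compound id).
#' @return `melt_curve()` returns a `MeltCurve`.
#' @name assay-containers
#' @export
melt_curve <- function(temperature, fluorescence, label = "apo") {
  stopifnot(length(temperature) == length(fluorescence),
            length(temperature) >= 20L,
            all(diff(temperature) > 0), all(is.finite(fluorescence)))
  structure(list(temperature = temperature, fluorescence = fluorescence,
                 label = label), class = "MeltCurve")
}

#' @rdname assay-containers
#' @param time Strictly increasing time grid (seconds), >= 10 points.
#' @param condition Condition label (compound id + concentration, or
#'   `"drug_free"`).
#' @export
kinetic_trace <- function(time, fluorescence, condition = "drug_free") {
  stopifnot(length(time) == length(fluorescence), length(time) >= 10L,
            all(diff(time) > 0), all(is.finite(fluorescence)))
  structure(list(time = time, fluorescence = fluorescence,
                 condition = condition), class = "KineticTrace")
}

#' @rdname assay-containers
#' @param concentrations Concentrations (nM, > 0); >= 4 distinct values.
#' @param responses Responses (% of control), finite.
#' @param replicate Optional replicate ids.
#' @export
dose_response <- function(concentrations, responses, replicate = NULL) {
  stopifnot(length(concentrations) == length(responses),
            all(concentrations > 0), all(is.finite(responses)),
            length(unique(concentrations)) >= 4L)
  structure(list(concentrations = concentrations, responses = responses,
                 replicate = replicate %||% rep(1L, length(responses))),
            class = "DoseResponse")
}

#' @rdname assay-containers
#' @param heats Integrated injection heats (kcal/mol of injectant).
#' @param injection_volumes Injection volumes (microlitre), recycled.
#' @param cell_concentration Analyte concentration in the cell (micromolar).
#' @param syringe_concentration Titrant concentration in the syringe
#'   (micromolar). In the campaign's reverse titrations the protein is the
#'   titrant and the compound the cell analyte.
#' @param cell_volume Cell volume (microlitre).
#' @param temperature_c Temperature (degrees C).
#' @export
itc_isotherm <- function(heats, injection_volumes = 2.5,
                         cell_concentration, syringe_concentration,
                         cell_volume = 200, temperature_c = 25) {
  stopifnot(length(heats) >= 10L, all(is.finite(heats)),
            cell_concentration > 0, syringe_concentration > 0)
  v <- rep_len(injection_volumes, length(heats))
  f <- cumprod(1 - v / cell_volume)
  m <- cell_concentration * f
  x <- syringe_concentration * (1 - f)
  structure(
    list(heats = heats, injection_volumes = v,
         cell_concentration = cell_concentration,
         syringe_concentration = syringe_concentration,
         cell_volume = cell_volume, temperature_c = temperature_c,
         molar_ratios = x / m),
    class = "ItcIsotherm"
  )
}

# ---- thermal shift --------------------------------------------------------

#' Melting temperature from a thermal-shift melt curve
#'
#' Fits a Boltzmann sigmoid
#' \eqn{F(T) = b + (t - b) / (1 + \exp((T_m - T)/s))} and reports the
#' inflection \eqn{T_m}. If the sigmoid fit does not converge, the argmax
#' of the smoothed first derivative dF/dT is used as a fallback.
#'
#' @param curve A `MeltCurve` with a sigmoidal rise.
#' @return Tm in degrees C, with attribute `diagnostics` (method,
#'   coefficients, residual norm).
#' @export
melting_temperature <- function(curve) {
  stopifnot(inherits(curve, "MeltCurve"))
  Tg <- curve$temperature
  Fv <- curve$fluorescence
  rng <- diff(range(Fv))
  if (rng <= 0 || rng < 1e-8 * max(abs(Fv), 1)) {
    stop_no_transition("melt curve is flat: no unfolding transition")
  }
  dT <- diff(Tg); dF <- diff(Fv)
  deriv <- dF / dT
  sm <- stats::filter(deriv, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- deriv[is.na(sm)]
  if (max(sm) <= 0) {
    stop_no_transition("melt curve has no rising transition")
  }
  tm0 <- Tg[which.max(sm)]
  start <- list(bottom = min(Fv), top = max(Fv), tm = tm0,
                slope = diff(range(Tg)) / 20)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      Fv ~ bottom + (top - bottom) / (1 + exp((tm - Tg) / slope)),
      start = start,
      lower = c(bottom = -Inf, top = -Inf, tm = min(Tg), slope = 1e-3),
      upper = c(bottom = Inf, top = Inf, tm = max(Tg), slope = diff(range(Tg))),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    if (co[["top"]] - co[["bottom"]] > 0.05 * rng) {
      tm <- co[["tm"]]
      attr(tm, "diagnostics") <- list(
        method = "boltzmann", coefficients = co,
        residual_norm = sqrt(sum(stats::resid(fit)^2))
      )
      return(tm)
    }
  }
  tm <- tm0
  attr(tm, "diagnostics") <- list(method = "derivative_argmax",
                                  coefficients = NULL, residual_norm = NA_real_)
  tm
}

#' Thermal shift
#'
#' Signed difference between the melting temperature of the protein in the
#' presence of a compound (holo) and alone (apo). Destabilisation gives a
#' negative shift.
#'
#' @param holo,apo Melting temperatures (degrees C).
#' @return Delta Tm (degrees C).
#' @export
delta_tm <- function(holo, apo) {
  stopifnot(is.finite(holo), is.finite(apo))
  as.numeric(holo) - as.numeric(apo)
}

# ---- enzymatic kinetics ---------------------------------------------------

#' Velocity from the linear range of a kinetic trace
#'
#' Scans all contiguous windows covering at least `min_fraction` of the
#' points, keeps those whose linear fit reaches the R-squared threshold,
#' and reports the slope of the window maximising R-squared (ties: longest
#' window, then earliest start). For the decaying NADH signal the slope is
#' negative; the magnitude is returned, the signed slope is in the
#' attributes. A constant trace is accepted as the degenerate zero-velocity
#' case and flagged.
#'
#' @param trace A `KineticTrace`.
#' @param r2_threshold Minimum R-squared for a window (default 0.99).
#' @param min_fraction Minimum window size as a fraction of the points.
#' @return Velocity magnitude (a.u./s) with attributes `slope`, `window`
#'   (index range), `r_squared`, `degenerate`.
#' @export
linear_range_velocity <- function(trace, r2_threshold = 0.99, min_fraction = 0.3) {
  stopifnot(inherits(trace, "KineticTrace"))
  x <- trace$time; y <- trace$fluorescence
  n <- length(x)
  wmin <- max(3L, ceiling(min_fraction * n))
  # O(1) window statistics from cumulative sums
  cx <- cumsum(x); cy <- cumsum(y); cxx <- cumsum(x^2)
  cyy <- cumsum(y^2); cxy <- cumsum(x * y)
  seg <- function(cs, i, j) cs[j] - if (i > 1) cs[i - 1] else 0
  best <- NULL
  for (w in seq(n, wmin)) {
    for (i in seq_len(n - w + 1L)) {
      j <- i + w - 1L
      sx <- seg(cx, i, j); sy <- seg(cy, i, j)
      sxx <- seg(cxx, i, j); syy <- seg(cyy, i, j); sxy <- seg(cxy, i, j)
      ssx <- sxx - sx^2 / w
      ssy <- syy - sy^2 / w
      sxy0 <- sxy - sx * sy / w
      if (ssy <= .Machine$double.eps * max(abs(syy), 1)) {
        cand <- list(slope = 0, r2 = 1, i = i, j = j, degenerate = TRUE)
      } else {
        slope <- sxy0 / ssx
        r2 <- sxy0^2 / (ssx * ssy)
        cand <- list(slope = slope, r2 = r2, i = i, j = j, degenerate = FALSE)
      }
      if (cand$r2 < r2_threshold) next
      cand$len <- w
      better <- is.null(best) ||
        cand$r2 > best$r2 + 1e-12 ||
        (abs(cand$r2 - best$r2) <= 1e-12 &&
           (cand$len > best$len ||
              (cand$len == best$len && cand$i < best$i)))
      if (better) best <- cand
    }
  }
  if (is.null(best)) {
    stop_nonlinear_trace(sprintf(
      "no window of >= %d points reaches R^2 >= %g", wmin, r2_threshold))
  }
  out <- abs(best$slope)
  attr(out, "slope") <- best$slope
  attr(out, "window") <- c(best$i, best$j)
  attr(out, "r_squared") <- best$r2
  attr(out, "degenerate") <- best$degenerate
  out
}

#' Activity normalised to the drug-free control
#'
#' Ratio of velocities; above 1 indicates activation, below 1 inhibition
#' (the activator-to-inhibitor switch of the campaign is read in this
#' ratio).
#'
#' @param v_compound,v_control Velocities (a.u./s).
#' @return Ratio.
#' @export
normalized_activity <- function(v_compound, v_control) {
  stopifnot(is.finite(v_compound), is.finite(v_control), v_control != 0)
  as.numeric(v_compound) / as.numeric(v_control)
}

# ---- dose-response --------------------------------------------------------

#' Four-parameter logistic IC50 with a technical censoring floor
#'
#' Least-squares fit of
#' \eqn{y = bottom + (top - bottom)/(1 + (c/IC_{50})^{h})} with free Hill
#' slope; top and bottom are constrained to \[0, 120\]% unless overridden.
#' An enzymatic IC50 cannot be resolved below the enzyme concentration of
#' the assay, so when `floor` is given and the fitted IC50 falls below it,
#' the result is censored and reported as `"< floor"`.
#'
#' @param dr A `DoseResponse` (concentrations in nM, responses in % of
#'   control spanning at least 40% of the dynamic range).
#' @param floor Technical floor in nM, or `NULL` for no censoring.
#' @param bounds Constraint for top/bottom (default `c(0, 120)`).
#' @return An `InhibitionResult`: list with `ic50` (nM; the floor when
#'   censored), `fitted_ic50`, `censored`, `floor`, `reported`,
#'   `hill_slope`, `top`, `bottom`, `residual_norm`.
#' @export
fit_ic50 <- function(dr, floor = NULL, bounds = c(0, 120)) {
  stopifnot(inherits(dr, "DoseResponse"))
  conc <- dr$concentrations
  resp <- dr$responses
  if (diff(range(resp)) < 40) {
    stop_fit(sprintf("responses span %.1f%% of the dynamic range (need >= 40%%)",
                     diff(range(resp))),
             diagnostics = list(span = diff(range(resp))))
  }
  lc <- log10(conc)
  obj <- function(p) {
    p[2] + (p[1] - p[2]) / (1 + 10^((lc - p[3]) * p[4])) - resp
  }
  half <- (max(resp) + min(resp)) / 2
  lic50_starts <- unique(c(lc[which.min(abs(resp - half))], stats::median(lc)))
  lower <- c(bounds[1], bounds[1], min(lc) - 3, 0.2)
  upper <- c(bounds[2], bounds[2], max(lc) + 3, 5)
  best <- NULL
  for (l0 in lic50_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(max(resp), min(resp), l0, 1), fn = obj,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) {
    stop_fit("4PL fit did not converge",
             diagnostics = list(lic50_starts = lic50_starts))
  }
  co <- best$fit$par
  fitted_ic50 <- 10^co[3]
  censored <- !is.null(floor) && fitted_ic50 < floor
  structure(
    list(ic50 = if (censored) floor else fitted_ic50,
         fitted_ic50 = fitted_ic50,
         censored = censored,
         floor = floor,
         reported = if (censored) sprintf("< %g nM", floor)
                    else sprintf("%.4g nM", fitted_ic50),
         hill_slope = co[4],
         top = co[1], bottom = co[2],
         residual_norm = sqrt(best$ssr)),
    class = "InhibitionResult"
  )
}

#' @export
print.InhibitionResult <- function(x, ...) {
  cat(sprintf("<InhibitionResult> IC50 %s (hill %.2f%s)\n", x$reported,
              x$hill_slope, if (x$censored) ", censored at technical floor" else ""))
  invisible(x)
}

# ---- isothermal titration calorimetry -------------------------------------

# Per-injection heats (kcal/mol injectant) of an independent-sites
# isotherm. sites: data.frame(n, kd_nm, dh). The cell analyte carries the
# sites and is diluted by each injection; the titrant accumulates.
.itc_forward <- function(sites, iso) {
  v <- iso$injection_volumes
  V0 <- iso$cell_volume
  f <- cumprod(1 - v / V0)
  M <- iso$cell_concentration * f                # cell analyte (uM)
  X <- iso$syringe_concentration * (1 - f)       # cumulative titrant (uM)
  ka <- 1000 / sites$kd_nm                       # 1/uM
  Qtot <- function(i) {
    if (X[i] <= 0) return(0)
    free_rhs <- function(L) {
      L + M[i] * sum(sites$n * ka * L / (1 + ka * L)) - X[i]
    }
    L <- stats::uniroot(free_rhs, c(0, X[i]), tol = 1e-12)$root
    # kcal per litre * cell volume; concentrations uM, volume ul -> nmol;
    # dh kcal/mol -> heat in 1e-12 kcal units; the per-mole normalisation
    # below divides the scale out again.
    V0 * M[i] * sum(sites$n * sites$dh * ka * L / (1 + ka * L))
  }
  Q <- vapply(seq_along(v), Qtot, numeric(1))
  Qprev <- c(0, Q[-length(Q)])
  dq <- Q - Qprev + (v / V0) * (Q + Qprev) / 2   # displaced-volume term
  inj_moles <- iso$syringe_concentration * v
  dq / inj_moles
}

#' Fit an independent-sites binding model to an ITC isotherm
#'
#' Nonlinear least squares on the independent-sites isotherm equations,
#' with the cell/syringe roles taken from the isotherm record (the
#' campaign's titrations are reverse: protein in the syringe, compound in
#' the cell). The two-site model serves biphasic thermograms; fitting it
#' to monophasic data converges but is flagged when the two dissociation
#' constants are statistically indistinguishable.
#'
#' @param iso An `ItcIsotherm`.
#' @param model `"one_site"` or `"two_site"`.
#' @return An `ItcFit`: list with `sites` (data.frame `n`, `kd_nm`, `dh`
#'   \[kcal/mol\]), `residual_norm`, `model`, `indistinguishable`
#'   (two-site flag).
#' @export
itc_fit <- function(iso, model = c("one_site", "two_site")) {
  stopifnot(inherits(iso, "ItcIsotherm"))
  model <- match.arg(model)
  y <- iso$heats
  if (max(abs(y)) < 1e-6) {
    stop_no_binding_signal("all injection heats are zero: no binding signal")
  }
  dh_guess <- y[which.max(abs(y[1:3]))]
  n_par <- if (model == "one_site") 3L else 6L

  obj <- function(p) {
    sites <- .par_to_sites(p, model)
    pred <- tryCatch(.itc_forward(sites, iso), error = function(e) NULL)
    if (is.null(pred) || anyNA(pred)) return(rep(1e6, length(y)))
    pred - y
  }

  # deterministic multi-start over plausible stoichiometries and Kd decades
  starts <- .itc_starts(model, dh_guess)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = obj,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) stop_fit("ITC fit did not converge")
  fit <- best$fit
  sites <- .par_to_sites(fit$par, model)
  # order sites tight-first for a stable report
  sites <- sites[order(sites$kd_nm), , drop = FALSE]
  rownames(sites) <- NULL

  indist <- FALSE
  if (model == "two_site") {
    se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, n_par))
    lkd <- fit$par[c(2, 5)]
    lse <- se[c(2, 5)]
    if (all(is.finite(lse))) {
      lo <- lkd - 1.96 * lse; hi <- lkd + 1.96 * lse
      indist <- max(lo) <= min(hi)               # 95% CIs overlap
    } else {
      indist <- abs(diff(lkd)) < 0.3             # within a factor ~2
    }
  }
  structure(
    list(sites = sites, residual_norm = sqrt(best$ssr), model = model,
         indistinguishable = indist),
    class = "ItcFit"
  )
}

.par_to_sites <- function(p, model) {
  if (model == "one_site") {
    data.frame(n = p[1], kd_nm = 10^p[2], dh = p[3])
  } else {
    data.frame(n = c(p[1], p[4]), kd_nm = 10^c(p[2], p[5]), dh = c(p[3], p[6]))
  }
}

.itc_starts <- function(model, dh_guess) {
  if (model == "one_site") {
    grid <- expand.grid(n = c(0.5, 1, 2), lkd = c(1, 2, 3, 4))
    lapply(seq_len(nrow(grid)), function(i) {
      c(grid$n[i], grid$lkd[i], dh_guess)
    })
  } else {
    grid <- expand.grid(lkd1 = c(1, 2, 3), lkd2 = c(3, 4, 5))
    grid <- grid[grid$lkd2 > grid$lkd1, , drop = FALSE]
    lapply(seq_len(nrow(grid)), function(i) {
      c(1, grid$lkd1[i], dh_guess, 1, grid$lkd2[i], dh_guess / 2)
    })
  }
}

#' @export
print.ItcFit <- function(x, ...) {
  cat(sprintf("<ItcFit> %s (residual norm %.3g%s)\n", x$model, x$residual_norm,
              if (isTRUE(x$indistinguishable)) ", sites indistinguishable" else ""))
  for (i in seq_len(nrow(x$sites))) {
    cat(sprintf("  site %d: n = %.2f, Kd = %.3g nM, dH = %.2f kcal/mol\n",
                i, x$sites$n[i], x$sites$kd_nm[i], x$sites$dh[i]))
  }
  invisible(x)
}
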