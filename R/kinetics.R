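# Ping-pong bi-bi kinetics: rate law, nonlinear fitting (full and
# no-saturation reduced forms), specificity constants and AATase/TATase
# classification.
#
# Units: kcat s^-1, Km in mM, concentrations of substrates in mM,
# enzyme concentration in M (any unit, carried through), rate in
# s^-1 x [E] units. Specificity constants kcat/Km are reported in
# M^-1 s^-1, hence the factor 1000 when dividing s^-1 by mM.

#' Rate-law parameters for the ping-pong bi-bi mechanism
#'
#' @param kcat turnover number, s^-1.
#' @param Km_AA Michaelis constant of the varied amino acid, mM.
#' @param Km_cosub Michaelis constant of the co-substrate
#'   (2-oxoglutarate), mM.
#' @return list of class `rate_law_params`.
#' @export
rate_law_params <- function(kcat, Km_AA, Km_cosub) {
  vals <- c(kcat = kcat, Km_AA = Km_AA, Km_cosub = Km_cosub)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_input("rate-law parameters must be finite and > 0, got %s",
                paste(sprintf("%s=%g", names(vals), vals), collapse = ", "))
  }
  structure(list(kcat = kcat, Km_AA = Km_AA, Km_cosub = Km_cosub),
            class = "rate_law_params")
}

#' Ping-pong bi-bi initial rate
#'
#' `v = [E] kcat A B / (Km_AA B + Km_cosub A + A B)` with `A` the amino
#' acid and `B` the co-substrate concentration (mM). The mechanism has no
#' ternary complex, hence no `Km_AA Km_cosub` term in the denominator.
#'
#' @param params a [rate_law_params()] object.
#' @param conc_AA amino-acid concentration, mM (vectorised).
#' @param conc_cosub co-substrate concentration, mM (vectorised).
#' @param conc_E enzyme concentration.
#' @return initial rate(s), in s^-1 times the units of `conc_E`.
#' @export
pingpong_rate <- function(params, conc_AA, conc_cosub, conc_E) {
  stopifnot(inherits(params, "rate_law_params"))
  if (any(conc_AA < 0) || any(conc_cosub < 0)) {
    abort_input("concentrations must be >= 0")
  }
  A <- conc_AA
  B <- conc_cosub
  denom <- params$Km_AA * B + params$Km_cosub * A + A * B
  out <- conc_E * params$kcat * A * B / denom
  out[denom == 0] <- 0
  out
}

#' First-order (no-saturation) rate
#'
#' The limit of the ping-pong law when `[AA] << Km_AA` at saturating
#' co-substrate: `v = [E] (kcat/Km) [AA]`, used when saturating amino-acid
#' concentrations cannot be attained.
#'
#' @param kcat_over_Km specificity constant, M^-1 s^-1.
#' @param conc_AA amino-acid concentration, mM.
#' @param conc_E enzyme concentration.
#' @return initial rate(s).
#' @export
reduced_rate <- function(kcat_over_Km, conc_AA, conc_E) {
  if (any(conc_AA < 0)) abort_input("concentrations must be >= 0")
  conc_E * kcat_over_Km * conc_AA * 1e-3
}

# Hanes linearisation A/v' = A/Vapp + Km_app/Vapp on the rows with the
# other substrate closest to saturation; returns c(V, Km) or NULL.
hanes_start <- function(A, vprime) {
  ok <- A > 0 & vprime > 0
  if (sum(ok) < 2L) return(NULL)
  fit <- try(stats::lm(I(A[ok] / vprime[ok]) ~ A[ok]), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  sl <- unname(stats::coef(fit)[2])
  ic <- unname(stats::coef(fit)[1])
  if (!is.finite(sl) || sl <= 0 || !is.finite(ic) || ic <= 0) return(NULL)
  c(V = 1 / sl, Km = ic / sl)
}

#' Fit ping-pong bi-bi kinetics for one enzyme/substrate pair
#'
#' In `"full"` mode all three parameters of the rate law are fitted by
#' least squares (Levenberg-Marquardt, Hanes-linearisation starting
#' values). In `"reduced"` mode only the specificity constant kcat/Km is
#' estimated, as the slope of the origin-constrained regression of rate
#' on `[E][AA]` (the first-order law). In `"auto"` mode the full model is
#' tried first and the fit is demoted to reduced when no saturation is
#' seen: the fitted Km_AA exceeds the largest tested concentration (or
#' `ns_bound`, the highest attainable assay concentration, 40 mM by
#' default), its standard error is unbounded, or the fit fails.
#'
#' @param data a [new_kinetic_dataset()].
#' @param enzyme,substrate row selectors.
#' @param model `"auto"`, `"full"` or `"reduced"`.
#' @param ns_bound highest attainable amino-acid concentration, mM.
#' @param weighting `"none"` (default) or `"relative"` (1/rate^2).
#' @param tol relative convergence tolerance.
#' @param maxit maximum iterations.
#' @return list of class `kinetic_fit`: `params` (full model only),
#'   `std_errors`, `saturated` (named logical for AA and co-substrate),
#'   `specificity_constant` (M^-1 s^-1) with `specificity_se`,
#'   `model_used`, residual summary and design size.
#' @export
fit_pingpong <- function(data, enzyme, substrate,
                         model = c("auto", "full", "reduced"),
                         ns_bound = 40, weighting = c("none", "relative"),
                         tol = 1e-10, maxit = 500L) {
  stopifnot(inherits(data, "kinetic_dataset"))
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  rows <- data[data$enzyme == enzyme & data$substrate == substrate, ,
               drop = FALSE]
  if (nrow(rows) == 0L) {
    abort_input("no rows for enzyme '%s', substrate '%s'", enzyme, substrate)
  }
  A <- rows$conc_aa_mM
  B <- rows$conc_cosub_mM
  E <- rows$conc_e
  v <- rows$rate
  w <- if (weighting == "relative") 1 / pmax(v, .Machine$double.eps)^2
       else rep(1, length(v))

  fit_reduced <- function() {
    if (length(unique(A[A > 0])) < 3L) {
      abort_input("reduced fit needs >= 3 distinct [AA] values (got %d)",
                  length(unique(A[A > 0])))
    }
    z <- E * A * 1e-3
    slope <- sum(w * z * v) / sum(w * z^2)
    resid <- v - slope * z
    dof <- length(v) - 1L
    se <- sqrt(sum(w * resid^2) / dof / sum(w * z^2))
    structure(list(
      enzyme = enzyme, substrate = substrate, model_used = "reduced",
      params = NULL,
      std_errors = c(kcat_over_Km = se),
      saturated = c(AA = FALSE, cosub = NA),
      specificity_constant = slope, specificity_se = se,
      n = length(v), rss = sum(resid^2),
      sigma = sqrt(sum(resid^2) / dof)), class = "kinetic_fit")
  }

  fit_full <- function() {
    if (nrow(rows) < 5L || length(unique(A)) < 3L || length(unique(B)) < 2L) {
      abort_input(
        "full fit needs >= 5 design points spanning both substrates")
    }
    vp <- v / E
    topB <- B >= 0.8 * max(B)
    topA <- A >= 0.8 * max(A)
    hA <- hanes_start(A[topB], vp[topB])
    hB <- hanes_start(B[topA], vp[topA])
    kcat0 <- max(c(hA["V"], hB["V"], 1.2 * max(vp)), na.rm = TRUE)
    KmA0 <- if (!is.null(hA)) unname(hA["Km"]) else stats::median(A[A > 0])
    KmB0 <- if (!is.null(hB)) unname(hB["Km"]) else stats::median(B[B > 0])
    df <- data.frame(A = A, B = B, E = E, v = v)
    fit <- try(minpack.lm::nlsLM(
      v ~ E * kcat * A * B / (KmA * B + KmB * A + A * B),
      data = df,
      start = list(kcat = kcat0, KmA = max(KmA0, 1e-6),
                   KmB = max(KmB0, 1e-6)),
      lower = c(1e-12, 1e-12, 1e-12),
      weights = w,
      control = minpack.lm::nls.lm.control(
        ftol = tol, ptol = tol, maxiter = min(as.integer(maxit), 1024L))),
      silent = TRUE)
    if (inherits(fit, "try-error")) {
      abort_fit("full ping-pong fit failed for %s/%s: %s", enzyme, substrate,
                attr(fit, "condition")$message %||% "unknown")
    }
    est <- stats::coef(fit)
    sm <- summary(fit)
    se <- sm$coefficients[, "Std. Error"]
    vc <- try(stats::vcov(fit), silent = TRUE)
    kcat <- est[["kcat"]]; KmA <- est[["KmA"]]; KmB <- est[["KmB"]]
    spec <- 1000 * kcat / KmA
    spec_se <- if (!inherits(vc, "try-error")) {
      g <- c(1000 / KmA, -1000 * kcat / KmA^2, 0)
      sqrt(drop(t(g) %*% vc %*% g))
    } else NA_real_
    sat_AA <- is.finite(se[["KmA"]]) && KmA <= min(max(A), ns_bound)
    sat_B <- is.finite(se[["KmB"]]) && KmB <= min(max(B), ns_bound)
    structure(list(
      enzyme = enzyme, substrate = substrate, model_used = "full",
      params = rate_law_params(kcat, KmA, KmB),
      std_errors = c(kcat = se[["kcat"]], Km_AA = se[["KmA"]],
                     Km_cosub = se[["KmB"]]),
      saturated = c(AA = sat_AA, cosub = sat_B),
      specificity_constant = spec, specificity_se = spec_se,
      n = length(v), rss = sum(stats::residuals(fit)^2),
      sigma = sm$sigma), class = "kinetic_fit")
  }

  if (model == "reduced") return(fit_reduced())
  if (model == "full") return(fit_full())
  # auto: demote to the reduced first-order fit when saturation of the
  # varied amino acid is not reached
  full <- try(fit_full(), silent = TRUE)
  if (inherits(full, "try-error") || !isTRUE(full$saturated[["AA"]])) {
    return(fit_reduced())
  }
  full
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (x$model_used == "full") {
    cat(sprintf(
      "%s / %s (full): kcat = %.3g (%.2g) s-1, Km_AA = %.3g (%.2g) mM, Km_cosub = %.3g (%.2g) mM\n",
      x$enzyme, x$substrate, x$params$kcat, x$std_errors[["kcat"]],
      x$params$Km_AA, x$std_errors[["Km_AA"]],
      x$params$Km_cosub, x$std_errors[["Km_cosub"]]))
  } else {
    cat(sprintf("%s / %s (reduced, no saturation):\n", x$enzyme, x$substrate))
  }
  cat(sprintf("  kcat/Km = %.3g M-1 s-1 (se %.2g), n = %d\n",
              x$specificity_constant, x$specificity_se, x$n))
  invisible(x)
}

#' Specificity ratio and AATase/TATase call from two constants
#'
#' The substrate preference of a subfamily Ia aminotransferase is the
#' ratio of specificity constants kcat/Km for the aspartate reaction over
#' the aromatic (phenylalanine) reaction: `> 1` is an AATase, `< 1` a
#' TATase; a ratio equal to 1 at the reported 2-significant-figure
#' precision is ambiguous.
#'
#' @param kcat_km_asp,kcat_km_aromatic specificity constants, M^-1 s^-1.
#' @return list of class `specificity_call`: `ratio`, `rounded_ratio`
#'   (2 significant figures) and `label`.
#' @export
specificity_call <- function(kcat_km_asp, kcat_km_aromatic) {
  if (!is.finite(kcat_km_asp) || !is.finite(kcat_km_aromatic) ||
      kcat_km_asp <= 0 || kcat_km_aromatic <= 0) {
    abort_input("specificity constants must be finite and > 0")
  }
  ratio <- kcat_km_asp / kcat_km_aromatic
  rounded <- signif(ratio, 2)
  # the ambiguous zone is symmetric in ratio <-> 1/ratio so the call is
  # antisymmetric under swapping the two reactions
  ambiguous <- rounded == 1 || signif(1 / ratio, 2) == 1
  label <- if (ambiguous) "ambiguous" else if (ratio > 1) "AATase" else "TATase"
  structure(list(ratio = ratio, rounded_ratio = rounded, label = label),
            class = "specificity_call")
}

#' Specificity ratio from two kinetic fits
#'
#' @param fit_asp fit for the aspartate reaction.
#' @param fit_aromatic fit for the aromatic (Phe) reaction.
#' @return a [specificity_call()].
#' @export
specificity_ratio <- function(fit_asp, fit_aromatic) {
  stopifnot(inherits(fit_asp, "kinetic_fit"),
            inherits(fit_aromatic, "kinetic_fit"))
  specificity_call(fit_asp$specificity_constant,
                   fit_aromatic$specificity_constant)
}

#' @export
print.specificity_call <- function(x, ...) {
  cat(sprintf("kcat/Km ratio (Asp : aromatic) = %.3g -> %g : %s\n",
              x$ratio, x$rounded_ratio, x$label))
  invisible(x)
}

#' Summarise fits as a kinetic-constants table
#'
#' One row per enzyme: fitted constants for the aspartate and aromatic
#' reactions (`NS` semantics: reduced-model rows carry only kcat/Km) plus
#' the specificity ratio and class label, rounded to 2 significant
#' figures as conventionally reported.
#'
#' @param fits named list: for each enzyme, a list with elements `asp`
#'   and `aromatic`, each a `kinetic_fit`.
#' @return data.frame, one row per enzyme.
#' @export
kinetics_summary <- function(fits) {
  rows <- lapply(names(fits), function(enz) {
    fa <- fits[[enz]]$asp
    fr <- fits[[enz]]$aromatic
    call <- specificity_ratio(fa, fr)
    grab <- function(f, what) {
      if (f$model_used == "full") signif(f$params[[what]], 3) else NA_real_
    }
    data.frame(
      enzyme = enz,
      Km_asp_mM = grab(fa, "Km_AA"), kcat_asp = grab(fa, "kcat"),
      kcat_Km_asp = signif(fa$specificity_constant, 2),
      sat_asp = isTRUE(fa$saturated[["AA"]]),
      Km_aro_mM = grab(fr, "Km_AA"), kcat_aro = grab(fr, "kcat"),
      kcat_Km_aro = signif(fr$specificity_constant, 2),
      sat_aro = isTRUE(fr$saturated[["AA"]]),
      ratio = call$rounded_ratio, label = call$label,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
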