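#' Photosynthetic pigment contents from absorbance readings
#'
#' Implements the acetone/ethanol-extract equations exactly as used for
#' spectrophotometric pigment assays:
#' \deqn{Chl_a = (12.72 OD_{663} - 2.69 OD_{645}) V N / W}
#' \deqn{Chl_b = (22.88 OD_{645} - 4.68 OD_{663}) V N / W}
#' \deqn{Chls = Chl_a + Chl_b}
#' \deqn{Car = [OD_{470} (V/W) - 3.27 Chl_a - 104 Chl_b] / 198}
#' The carotenoid equation is implemented verbatim in that form (note its
#' 104 coefficient and the absence of the dilution factor N), which
#' differs from the common Lichtenthaler formulation; set
#' \code{variant = "lichtenthaler"} to use
#' \eqn{Car = [1000 OD_{470} V N / W - 1.82 Chl_a - 85.02 Chl_b]/198}
#' for comparison.  Negative pigment values are returned unclamped and
#' raised as a warning - silent clamping would hide bad inputs.
#'
#' @param od663,od645,od470 absorbances (unitless, >= 0); vectorized.
#' @param V extract volume, ml (> 0; default 30).
#' @param N dilution factor (>= 1; default 1).
#' @param W fresh weight, g (> 0; default 1).
#' @param variant carotenoid formula variant; \code{"published"} (default)
#'   or \code{"lichtenthaler"}.
#' @return data.frame with columns \code{chlA}, \code{chlB}, \code{chls},
#'   \code{car} (mg per g fresh weight, as the formulas dictate).
#' @export
pigmentsFromAbsorbance <- function(od663, od645, od470, V = 30, N = 1,
                                   W = 1,
                                   variant = c("published",
                                               "lichtenthaler")) {
  variant <- match.arg(variant)
  if (any(V <= 0)) .stopf("extract volume V must be positive")
  if (any(W <= 0)) .stopf("fresh weight W must be positive")
  if (any(N < 1)) .stopf("dilution factor N must be >= 1")
  if (any(c(od663, od645, od470) < 0)) .stopf("absorbances must be >= 0")
  chlA <- (12.72 * od663 - 2.69 * od645) * V * N / W
  chlB <- (22.88 * od645 - 4.68 * od663) * V * N / W
  chls <- chlA + chlB
  car <- if (variant == "published")
    (od470 * (V / W) - 3.27 * chlA - 104 * chlB) / 198
  else
    (1000 * od470 * V * N / W - 1.82 * chlA - 85.02 * chlB) / 198
  out <- data.frame(chlA = chlA, chlB = chlB, chls = chls, car = car)
  if (any(out < 0))
    warning("negative pigment content computed; check the readings",
            call. = FALSE)
  out
}

.checkTrace <- function(t) {
  need <- c("fo", "fm", "fs", "fmP", "foP", "tau", "pm", "p0", "abs940",
            "abs650", "refAbs940", "refAbs650")
  miss <- setdiff(need, names(t))
  if (length(miss)) .stopf("trace is missing '%s'", miss[1])
  chk <- function(cond, what) if (any(!cond)) .stopf("invalid trace: %s",
                                                     what)
  chk(t$fo > 0, "Fo must be > 0")
  chk(t$fm >= t$fo, "Fm must be >= Fo")
  chk(t$fs > 0, "Fs must be > 0")
  chk(t$fmP >= t$fs, "Fm' must be >= Fs")
  chk(t$foP > 0, "Fo' must be > 0")
  chk(t$fmP > t$foP, "Fm' must be > Fo'")
  chk(t$tau > 0, "tau must be > 0")
  chk(t$abs940 > 0 & t$abs650 > 0 & t$refAbs940 > 0 & t$refAbs650 > 0,
      "absorbances must be > 0")
}

#' Chlorophyll-fluorescence and absorbance-derived parameters
#'
#' Computes the seven standard parameters from a raw fluorescence /
#' absorbance trace, each exactly per its defining formula:
#' relative chlorophyll content
#' \eqn{k \log_{10}[(Abs_{940} \cdot refAbs_{650})/(Abs_{650} \cdot
#' refAbs_{940})]}; maximum PSII quantum efficiency
#' \eqn{F_v/F_m = (F_m - F_o)/F_m}; PSII operating efficiency
#' \eqn{\Phi_{II} = (F_m' - F_s)/F_m'}; fraction of open PSII centers
#' \eqn{qL = [(F_m' - F_s)/(F_m' - F_o')] (F_o'/F_s)}; quantum yield of
#' regulated non-photochemical quenching
#' \eqn{\Phi_{NPQ} = 1 - (F_m' - F_s)/F_m' - F_s/F_m}; thylakoid proton
#' conductivity \eqn{gH^+ = 1/\tau}; and the active PSI fraction
#' \eqn{P_M/P_0}.  Note the algebraic identity
#' \eqn{\Phi_{II} + \Phi_{NPQ} + F_s/F_m = 1}.
#'
#' @param trace list or data.frame with fields \code{fo}, \code{fm},
#'   \code{fs}, \code{fmP}, \code{foP}, \code{tau}, \code{pm}, \code{p0},
#'   \code{abs940}, \code{abs650}, \code{refAbs940}, \code{refAbs650};
#'   vectorized over rows.
#' @param k instrument constant for relative chlorophyll (default 1; the
#'   device calibration constant is accepted as given, not interpreted).
#' @return data.frame with columns \code{relChl}, \code{fvFm},
#'   \code{phi2}, \code{qL}, \code{phiNPQ}, \code{gHplus},
#'   \code{psiActive}.
#' @export
fluorescenceParams <- function(trace, k = 1) {
  t <- as.list(trace)
  .checkTrace(t)
  phi2 <- (t$fmP - t$fs) / t$fmP
  data.frame(
    relChl = k * log10((t$abs940 * t$refAbs650) /
                         (t$abs650 * t$refAbs940)),
    fvFm = (t$fm - t$fo) / t$fm,
    phi2 = phi2,
    qL = ((t$fmP - t$fs) / (t$fmP - t$foP)) * (t$foP / t$fs),
    phiNPQ = 1 - phi2 - t$fs / t$fm,
    gHplus = 1 / t$tau,
    psiActive = t$pm / t$p0)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct(target) - Ct(reference); ddCt is the mean dCt
#' of the treatment sample minus the mean dCt of the control sample, and
#' the fold change is 2^-ddCt.  The spread is propagated from the
#' replicate standard deviations of dCt
#' (se = sqrt(var_t/n_t + var_c/n_c)) and reported as the fold-change
#' interval 2^-(ddCt +/- se).
#'
#' @param ctTargetTreat,ctRefTreat numeric replicate Ct vectors for the
#'   target and reference gene in the treatment sample (paired by
#'   replicate).
#' @param ctTargetCtrl,ctRefCtrl the same for the control sample.
#' @return list with \code{foldChange}, \code{ddCt}, \code{se},
#'   \code{foldLow}, \code{foldHigh}.
#' @export
ddctRelativeExpression <- function(ctTargetTreat, ctRefTreat,
                                   ctTargetCtrl, ctRefCtrl) {
  if (!length(ctTargetTreat) || !length(ctTargetCtrl))
    .stopf("at least one replicate per condition is required")
  if (length(ctTargetTreat) != length(ctRefTreat) ||
      length(ctTargetCtrl) != length(ctRefCtrl))
    .stopf("target and reference replicates must be paired")
  if (any(c(ctTargetTreat, ctRefTreat, ctTargetCtrl, ctRefCtrl) <= 0))
    .stopf("Ct values must be positive")
  dT <- ctTargetTreat - ctRefTreat
  dC <- ctTargetCtrl - ctRefCtrl
  ddCt <- mean(dT) - mean(dC)
  vT <- if (length(dT) > 1) stats::var(dT) else 0
  vC <- if (length(dC) > 1) stats::var(dC) else 0
  se <- sqrt(vT / length(dT) + vC / length(dC))
  list(foldChange = 2^(-ddCt), ddCt = ddCt, se = se,
       foldLow = 2^(-(ddCt + se)), foldHigh = 2^(-(ddCt - se)))
}
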