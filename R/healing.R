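# Mechano-regulated tissue differentiation in the fracture callus.
#
# The biophysical stimulus S = eps_dev/a + wf/b selects the tissue
# phenotype an element forms: fibrous tissue at high S, cartilage,
# immature bone, then mature (woven) bone at low S, and osteoclastic
# resorption below S = 0.01.  Fuzzy zones of total width 10% of each
# threshold crossfade adjacent memberships linearly so phenotype changes
# are gradual.  Cell populations (normalized densities) differentiate
# down a potency hierarchy MSC -> fibroblast -> chondrocyte -> immature ->
# mature bone cell; tissues are produced by their cells and replace
# lower-priority tissues proportionally.  Element stiffness follows a
# rule of mixtures over tissue volume fractions, smoothed by a trailing
# 10-day time average.

#' Mechano-regulation parameter set
#'
#' Defaults: strain normalizer a = 0.0375, fluid-velocity normalizer
#' b = 3 um/s, phenotype thresholds S = 0.01 / 0.2667 / 1 / 3, fuzzy-zone
#' width 10% of each threshold, calibrated differentiation rates
#' Ff = 0.02, Fc = 0.3, Fib = 0.15, Fmb = 0.15 per day and production
#' rates Qf = 0.12, Qc = 0.2, Qib = 0.1, Qmb = 0.1 per day, maximum
#' per-increment volume-fraction change 0.05 and a 10-day smoothing
#' window.
#'
#' @param ... overrides for any default listed above.
#' @return object of class `mechano_reg_params`.
#' @export
mechano_reg_params <- function(...) {
  p <- list(
    a = 0.0375, b = 3,
    thresholds = c(resorb = 0.01, mature = 0.2667, immature = 1, fibrous = 3),
    fuzzy_fraction = 0.10,
    F_f = 0.02, F_c = 0.3, F_ib = 0.15, F_mb = 0.15,
    Q_f = 0.12, Q_c = 0.2, Q_ib = 0.1, Q_mb = 0.1,
    dm_max = 0.05, window = 10,
    E_gran = 0.3,
    bone_fraction_union = 0.5,
    tissue_moduli = list(f = c(0.2, 5), c = c(5, 500), ib = c(500, 1000),
                         mb = c(2000, 6000))
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stopf("unknown mechano-regulation parameter '%s'", unknown[1L])
  p[names(dots)] <- dots
  if (any(diff(p$thresholds) <= 0)) stopf("'thresholds' must be strictly increasing")
  if (p$fuzzy_fraction <= 0 || p$fuzzy_fraction >= 1) {
    stopf("'fuzzy_fraction' must lie in (0, 1)")
  }
  rates <- c(p$F_f, p$F_c, p$F_ib, p$F_mb, p$Q_f, p$Q_c, p$Q_ib, p$Q_mb)
  if (any(rates <= 0)) stopf("differentiation/production rates must be positive")
  class(p) <- "mechano_reg_params"
  p
}

#' Biophysical stimulus of the biphasic mechano-regulation theory
#'
#' `S = eps_dev / a + wf / b`.
#'
#' @param eps_dev octahedral deviatoric strain (>= 0, vectorized).
#' @param wf_mag interstitial fluid-velocity magnitude, um/s (>= 0).
#' @param params a [mechano_reg_params()].
#' @return dimensionless stimulus S.
#' @export
biophysical_stimulus <- function(eps_dev, wf_mag, params = mechano_reg_params()) {
  if (any(eps_dev < 0) || any(wf_mag < 0)) {
    stopf("stimulus inputs must be non-negative")
  }
  eps_dev / params$a + wf_mag / params$b
}

#' Fuzzy tissue memberships from the stimulus
#'
#' Outside a fuzzy zone the band containing S has membership 1; inside a
#' zone of total width `fuzzy_fraction * threshold`, centered on the
#' threshold, the two adjacent memberships crossfade linearly and sum
#' to 1.  Bands (low to high S): resorption, mature bone, immature bone,
#' cartilage, fibrous tissue.
#'
#' @param S stimulus (vectorized, >= 0).
#' @param params a [mechano_reg_params()].
#' @return matrix with columns TM_f, TM_c, TM_ib, TM_mb, TM_resorb.
#' @export
tissue_membership <- function(S, params = mechano_reg_params()) {
  if (any(S < 0)) stopf("'S' must be non-negative")
  thr <- params$thresholds           # resorb < mature < immature < fibrous
  # bands from below each threshold upward:
  # [0, t1): resorb | (t1, t2): mb | (t2, t3): ib | (t3, t4): c | > t4: f
  upper_share <- function(S, t) {
    w <- params$fuzzy_fraction * t
    clamp((S - (t - w / 2)) / w, 0, 1)
  }
  u1 <- upper_share(S, thr[[1]])
  u2 <- upper_share(S, thr[[2]])
  u3 <- upper_share(S, thr[[3]])
  u4 <- upper_share(S, thr[[4]])
  TM_resorb <- 1 - u1
  TM_mb <- u1 - u2
  TM_ib <- u2 - u3
  TM_c <- u3 - u4
  TM_f <- u4
  cbind(f = TM_f, c = TM_c, ib = TM_ib, mb = TM_mb, resorb = TM_resorb)
}

#' Initialize the per-element healing state
#'
#' At t = 0 the callus is pure granulation tissue without any
#' differentiated cells or tissues.
#'
#' @param n number of callus elements.
#' @param params a [mechano_reg_params()].
#' @return object of class `tissue_state`: matrix of cell densities and
#'   tissue fractions plus modulus history bookkeeping.
#' @export
tissue_state <- function(n, params = mechano_reg_params()) {
  st <- list(
    cells = matrix(0, n, 4, dimnames = list(NULL, c("f", "c", "ib", "mb"))),
    frac = matrix(0, n, 4, dimnames = list(NULL, c("f", "c", "ib", "mb"))),
    E_raw = rep(params$E_gran, n),
    E_smoothed = rep(params$E_gran, n),
    hist_t = numeric(0),       # increment end times
    hist_dt = numeric(0),      # increment lengths
    hist_E = matrix(numeric(0), nrow = 0, ncol = n)
  )
  class(st) <- "tissue_state"
  st
}

#' Granulation-tissue closure fraction
#' @param frac matrix of tissue fractions (f, c, ib, mb).
#' @return m_gran = 1 - sum of differentiated fractions.
#' @export
granulation_fraction <- function(frac) {
  1 - rowSums(frac)
}

#' Cell-density time derivatives
#'
#' Logistic differentiation down the potency hierarchy: each phenotype is
#' produced from all higher-potency populations when its membership is
#' active, saturating as its own density approaches 1.
#'
#' @param cells matrix (f, c, ib, mb) of normalized cell densities.
#' @param cm MSC concentration per element (from diffusion).
#' @param TM membership matrix from [tissue_membership()].
#' @param params a [mechano_reg_params()].
#' @return matrix of d(c)/dt, per day.
#' @export
cell_density_rates <- function(cells, cm, TM, params = mechano_reg_params()) {
  cf <- cells[, "f"]; cc <- cells[, "c"]; cib <- cells[, "ib"]; cmb <- cells[, "mb"]
  gf <- params$F_f * TM[, "f"] * (1 - cf)
  gc <- params$F_c * TM[, "c"] * (1 - cc)
  gib <- params$F_ib * TM[, "ib"] * (1 - cib)
  gmb <- params$F_mb * TM[, "mb"] * (1 - cmb)
  dcf <- gf * cm - gc * cf - gib * cf - gmb * cf
  dcc <- gc * (cm + cf) - gib * cc - gmb * cc
  dcib <- gib * (cm + cf + cc) - gmb * cib
  dcmb <- gmb * (cm + cf + cc + cib)
  cbind(f = dcf, c = dcc, ib = dcib, mb = dcmb)
}

#' Tissue volume-fraction time derivatives
#'
#' Production saturates against the fractions of equal or higher priority;
#' replacement removes lower-priority tissue in proportion to its share of
#' the differentiated total m_tot.  In the resorption band, bone fractions
#' are removed at their production rate scaled by TM_resorb and return to
#' granulation tissue through the closure.
#'
#' @param frac matrix of tissue fractions (f, c, ib, mb).
#' @param cells matrix of cell densities.
#' @param TM membership matrix.
#' @param params a [mechano_reg_params()].
#' @return matrix of d(m)/dt, per day.
#' @export
tissue_fraction_rates <- function(frac, cells, TM, params = mechano_reg_params()) {
  mf <- frac[, "f"]; mc <- frac[, "c"]; mib <- frac[, "ib"]; mmb <- frac[, "mb"]
  mtot <- pmax(mf + mc + mib + mmb, 1e-9)
  rep_mb <- TM[, "mb"] * params$Q_mb * cells[, "mb"]
  rep_ib <- TM[, "ib"] * params$Q_ib * cells[, "ib"]
  rep_c <- TM[, "c"] * params$Q_c * cells[, "c"]
  dmmb <- params$Q_mb * TM[, "mb"] * (1 - mmb) * cells[, "mb"]
  dmib <- params$Q_ib * TM[, "ib"] * (1 - mib - mmb) * cells[, "ib"] -
    rep_mb * mib / mtot
  dmc <- params$Q_c * TM[, "c"] * (1 - mc - mib - mmb) * cells[, "c"] -
    (rep_mb + rep_ib) * mc / mtot
  dmf <- params$Q_f * TM[, "f"] * (1 - mf - mc - mib - mmb) * cells[, "f"] -
    (rep_mb + rep_ib + rep_c) * mf / mtot
  # osteoclastic removal of unloaded bone
  dmib <- dmib - params$Q_ib * TM[, "resorb"] * mib
  dmmb <- dmmb - params$Q_mb * TM[, "resorb"] * mmb
  cbind(f = dmf, c = dmc, ib = dmib, mb = dmmb)
}

#' Healing time-control scale factor
#'
#' Keeps the accepted per-increment tissue-fraction change below dm_max:
#' factor = dm_max / max_dm when the attempted change exceeds dm_max,
#' else 1.
#'
#' @param max_dm largest attempted per-increment |dm| (>= 0).
#' @param params a [mechano_reg_params()].
#' @return scale factor in (0, 1].
#' @export
healing_time_scale <- function(max_dm, params = mechano_reg_params()) {
  if (max_dm < 0) stopf("'max_dm' must be non-negative")
  if (max_dm > params$dm_max) params$dm_max / max_dm else 1
}

#' Rule-of-mixtures elastic modulus
#'
#' Volume-fraction-weighted sum of constituent moduli; each range-valued
#' tissue modulus is interpolated within its tabulated range by the
#' matching cell density (maturation), granulation tissue uses the fixed
#' early-callus modulus E_gran.
#'
#' @param frac,cells tissue fractions and cell densities.
#' @param params a [mechano_reg_params()].
#' @return E_raw per element, MPa.
#' @export
mixture_modulus <- function(frac, cells, params = mechano_reg_params()) {
  tm <- params$tissue_moduli
  lerp <- function(rng, c) rng[1] + (rng[2] - rng[1]) * c
  E_f <- lerp(tm$f, cells[, "f"])
  E_c <- lerp(tm$c, cells[, "c"])
  E_ib <- lerp(tm$ib, cells[, "ib"])
  E_mb <- lerp(tm$mb, cells[, "mb"])
  unname(granulation_fraction(frac) * params$E_gran +
    frac[, "f"] * E_f + frac[, "c"] * E_c +
    frac[, "ib"] * E_ib + frac[, "mb"] * E_mb)
}

#' Trailing time-averaged modulus
#'
#' dt-weighted average of the raw modulus over the trailing `window` days
#' (over the available history when less time has elapsed).
#'
#' @param hist_t increment end times (days, increasing).
#' @param hist_dt increment lengths.
#' @param hist_E matrix of E_raw snapshots (rows = increments).
#' @param t_now current time.
#' @param window averaging window, days.
#' @return vector of smoothed moduli.
#' @export
smoothed_modulus <- function(hist_t, hist_dt, hist_E, t_now, window = 10) {
  if (!length(hist_t)) stopf("empty modulus history buffer")
  t0 <- t_now - window
  # overlap of each increment [t_i - dt_i, t_i] with [t0, t_now]
  lo <- pmax(hist_t - hist_dt, t0)
  w <- pmax(hist_t - lo, 0)
  if (sum(w) <= 0) w[length(w)] <- 1
  as.numeric(crossprod(w, hist_E) / sum(w))
}

# Mixture poroelastic side-properties for healing callus elements.
# Permeability is mixed on a log scale (values span decades), Poisson
# ratio and porosity arithmetically.
callus_mixture_properties <- function(frac, table = default_material_table()) {
  rows <- match(c("granulation", "fibrous", "cartilage", "immature", "mature"),
                table$tissue)
  perm <- log10(table$permeability[rows] * PERM_M4NS_TO_MM4NS)
  nu <- table$nu[rows]
  Kf <- table$Kf[rows]
  mg <- granulation_fraction(frac)
  W <- cbind(mg, frac[, "f"], frac[, "c"], frac[, "ib"], frac[, "mb"])
  list(permeability = 10^(W %*% perm), nu = as.numeric(W %*% nu),
       porosity = rep(0.8, nrow(frac)), Kf = as.numeric(W %*% Kf))
}
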