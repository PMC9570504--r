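# Published Boltzmann and unitary-conductance parameters for lens connexin
# GJs (wild-type Cx46/Cx50 and their amino-terminal point variants), used as
# simulator presets.  v0 are absolute values; one variant (Cx46 L10I) showed
# no consistent gating on the negative polarity, so its negative-polarity
# Boltzmann parameters are unavailable and the positive-polarity values are
# mirrored when a full kinetic model is requested.
#
# Cx46 A14V has two published slope conductances (158 pS in the unitary
# conductance analysis, 94 pS in the figure summarizing slopes); both are
# shipped, as "Cx46_A14V" and "Cx46_A14V_alt", without adjudication.
#
# The kinetic time scale is invented (the Boltzmann law constrains only the
# rate ratio).  It is parameterized as beta60, the closing rate at
# |Vj| = 60 mV, from which k0 = beta60 / exp(a_pos * (60 - v0_pos) / 2):
# anchoring the mid-protocol closing rate rather than k0 itself keeps the
# kinetics usable across constructs whose gating sensitivities differ by
# 2-3x.  beta60_single was chosen once so the simulated open dwell ordering
# is qualitatively right (wild-type Cx46 longest, its variants clearly
# shorter, the Cx50 family intermediate and similar to its variants); the
# macro regime uses a common beta60 = 1.25 /s, slow enough that the 15 ms
# peak-measurement window sees little gating relaxation even at
# |Vj| = 100 mV.
preset_table <- function() {
  tab <- read.table(header = TRUE, text = "
name           gmin_pos v0_pos a_pos gmin_neg v0_neg a_neg gamma beta60_single neg_na
Cx46               0.24   39.1  0.09     0.23   38.6  0.11   192           1.2  FALSE
Cx46_L10I          0.22   56.1  0.06     0.22   56.1  0.06   188           3.0   TRUE
Cx46_N13E          0.17   33.6  0.16     0.17   32.9  0.15    93           3.0  FALSE
Cx46_A14V          0.24   35.1  0.19     0.15   37.1  0.14   158           3.0  FALSE
Cx46_A14V_alt      0.24   35.1  0.19     0.15   37.1  0.14    94           3.0  FALSE
Cx46_Q15N          0.27   37.3  0.06     0.25   32.3  0.09   187           3.0  FALSE
Cx50               0.20   41.5  0.07     0.25   43.6  0.07   220           2.0  FALSE
Cx50_I10L          0.22   33.0  0.11     0.22   33.7  0.17   204           2.0  FALSE
Cx50_E13N          0.16   33.2  0.10     0.29   30.0  0.10   193           2.0  FALSE
Cx50_V14A          0.23   45.4  0.13     0.23   37.8  0.14   234           2.0  FALSE
Cx50_N15Q          0.23   37.1  0.08     0.18   30.6  0.09   162           2.0  FALSE
")
  tab$name <- as.character(tab$name)
  tab
}

#' Published gating parameter presets
#'
#' @return A data frame with one row per construct: Boltzmann residual
#'   conductance `gmin`, half-deactivation voltage `v0` (mV, absolute) and
#'   sensitivity `a` (1/mV) for each transjunctional-voltage polarity, the
#'   slope unitary conductance `gamma` (pS), and the single-channel-regime
#'   closing rate at 60 mV, `beta60_single` (1/s).  `neg_na` marks the
#'   construct whose negative-polarity gating could not be characterized
#'   (values mirrored from the positive polarity).
#' @export
gj_presets <- function() preset_table()

#' Build a gating model from a published preset
#'
#' Populates a [gating_model()] from the parameter table in [gj_presets()].
#' The residual unitary conductance is `gmin * gamma_main` (positive-polarity
#' `gmin`), so the simulated stationary normalized conductance floor matches
#' the published Boltzmann `Gmin`.
#'
#' The `regime` selects kinetic defaults (see [gj_presets()] for the
#' parameterization): `"macro"` anchors the closing rate at 60 mV to a slow
#' common 1.25 1/s and routes all closures through the residual state
#' (`p_fullclose = 0`), so the lumped stationary conductance follows the
#' Boltzmann law exactly; `"single"` anchors it at the per-construct
#' `beta60_single` and uses `p_fullclose = 0.8`, so analyzed stretches
#' reliably visit the fully closed (zero-current) level while residual
#' sojourns still occur.
#'
#' @param name Construct name, see `gj_presets()$name`.
#' @param regime `"macro"` or `"single"`.
#' @param ... Overrides passed on to [gating_model()] (e.g. `k0`,
#'   `p_fullclose`).
#' @return A `"gj_gating_model"`.
#' @export
gj_preset <- function(name, regime = c("macro", "single"), ...) {
  regime <- match.arg(regime)
  tab <- preset_table()
  i <- match(name, tab$name)
  if (is.na(i))
    stop("unknown preset '", name, "'; see gj_presets()$name", call. = FALSE)
  row <- tab[i, ]
  beta60 <- if (regime == "macro") 1.25 else row$beta60_single
  args <- list(v0_pos = row$v0_pos, v0_neg = row$v0_neg,
               a_pos = row$a_pos, a_neg = row$a_neg,
               k0 = beta60 / exp(row$a_pos * (60 - row$v0_pos) / 2),
               gamma_main = row$gamma,
               gamma_res = row$gmin_pos * row$gamma,
               p_fullclose = if (regime == "macro") 0 else 0.8,
               label = row$name)
  args[names(list(...))] <- list(...)
  do.call(gating_model, args)
}
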