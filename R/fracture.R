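#' Per-cycle fracture probabilities and post-fracture mortality ratios
#'
#' Holds, for each main health state and strategy arm, the per-cycle
#' probabilities of an incident vertebral fracture (VF) and non-vertebral
#' fracture (non-VF), plus the standardized mortality ratios (SMR) applied
#' during the fracture cycle. States:
#' * `S` — starting state, T-score recovered to (-2.5, -2.0\];
#' * `D` — T-score decreased back below -2.5;
#' * `I_mid` — T-score increase state in (-2.5, -2.0\] (reached from D);
#' * `I_high` — T-score increase state above -2.0 (reached from S).
#'
#' The `treated` arm holds the probabilities under continued therapy; the
#' `discontinued` arm holds the (higher) probabilities after all therapy
#' stops. Defaults are the published per-cycle values. Alternatively the
#' discontinued arm can be derived from the treated one via risk ratios
#' (`rr_vf`, `rr_nvf`).
#'
#' @param p_vf 4 x 2 matrix (rows `S,D,I_mid,I_high`; columns
#'   `treated,discontinued`) of per-cycle vertebral-fracture probabilities.
#' @param p_nvf same shape, non-vertebral fracture probabilities.
#' @param smr_vf named vector of SMRs after vertebral fracture by sex.
#' @param smr_nvf named vector of SMRs after non-vertebral fracture by sex.
#' @param rr_vf,rr_nvf optional per-state risk ratios; when supplied (and the
#'   corresponding matrix has only a `treated` column) the discontinued
#'   column is `treated * rr`.
#' @return object of class `fracture_model`.
#' @export
fracture_model <- function(p_vf = default_p_vf(),
                           p_nvf = default_p_nvf(),
                           smr_vf = c(female = 2.99, male = 4.56),
                           smr_nvf = c(female = 3.29, male = 5.02),
                           rr_vf = NULL, rr_nvf = NULL) {
  expand <- function(p, rr) {
    if (!is.null(rr)) {
      stopifnot(ncol(p) == 1)
      p <- cbind(treated = p[, 1], discontinued = pmin(1, p[, 1] * rr))
    }
    p
  }
  p_vf <- expand(as.matrix(p_vf), rr_vf)
  p_nvf <- expand(as.matrix(p_nvf), rr_nvf)
  states <- c("S", "D", "I_mid", "I_high")
  arms <- c("treated", "discontinued")
  for (p in list(p_vf, p_nvf)) {
    if (!identical(rownames(p), states) || !identical(colnames(p), arms))
      stop("fracture probability matrices need rows S,D,I_mid,I_high and ",
           "columns treated,discontinued")
    if (any(p < 0 | p > 1)) stop("fracture probabilities must lie in [0, 1]")
  }
  if (any(p_vf + p_nvf > 1))
    stop("p_vf + p_nvf must not exceed 1 for any state/arm")
  if (any(p_vf[, "discontinued"] < p_vf[, "treated"]) ||
      any(p_nvf[, "discontinued"] < p_nvf[, "treated"]))
    stop("discontinued-arm fracture probabilities must be >= treated-arm")
  if (any(c(smr_vf, smr_nvf) < 0)) stop("SMRs must be nonnegative")
  structure(list(p_vf = p_vf, p_nvf = p_nvf,
                 smr_vf = smr_vf, smr_nvf = smr_nvf),
            class = "fracture_model")
}

#' @rdname fracture_model
#' @export
default_p_vf <- function() {
  matrix(c(0.004, 0.006, 0.004, 0.002,
           0.013, 0.019, 0.013, 0.007),
         ncol = 2, dimnames = list(c("S", "D", "I_mid", "I_high"),
                                   c("treated", "discontinued")))
}

#' @rdname fracture_model
#' @export
default_p_nvf <- function() {
  matrix(c(0.013, 0.015, 0.013, 0.009,
           0.016, 0.018, 0.016, 0.011),
         ncol = 2, dimnames = list(c("S", "D", "I_mid", "I_high"),
                                   c("treated", "discontinued")))
}

#' Excess deaths attributable to a fracture during its cycle
#'
#' Patients with an incident fracture die during the fracture cycle with
#' probability `min(1, q_cycle * smr)` instead of the background `q_cycle`.
#' The fracture-related component is the excess:
#' `incidence * (min(1, q_cycle * smr) - q_cycle)`. Background deaths among
#' fractured patients remain background, keeping all-cause mortality
#' consistent with the life table.
#'
#' @param incidence incident-fracture cohort mass (per patient).
#' @param q_cycle per-cycle background death probability.
#' @param smr standardized mortality ratio (>= 0).
#' @return excess death mass; never negative when `smr >= 1`.
#' @export
fracture_related_death <- function(incidence, q_cycle, smr) {
  stopifnot(smr >= 0, q_cycle >= 0, q_cycle <= 1)
  incidence * (pmin(1, q_cycle * smr) - q_cycle)
}
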