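#' Harmonize exposure and outcome summary statistics
#'
#' Joins the two GWAS tables on rsid and aligns every instrument to the
#' exposure effect allele. Outcome records whose alleles are swapped
#' (directly or as strand complements) have their beta negated; palindromic
#' SNPs (A/T or C/G) are dropped because their orientation cannot be
#' resolved without frequencies; records whose alleles cannot be matched
#' are dropped as mismatches. The action taken is recorded per instrument.
#'
#' @param exposure,outcome GWAS record data.frames (see
#'   [read_gwas_table()]).
#' @return A data.frame of class `instrument_set` with columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `action` (kept / sign-flipped /
#'   dropped-palindromic / dropped-mismatch); dropped rows are retained in
#'   the table but excluded by the estimators.
#' @export
harmonize <- function(exposure, outcome) {
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0L)
    stop("no shared rsids between exposure and outcome")
  ex <- exposure[match(shared, exposure$rsid), ]
  ou <- outcome[match(shared, outcome$rsid), ]
  comp <- function(a) chartr("ACGT", "TGCA", a)
  palindromic <- ex$effect_allele == comp(ex$other_allele)
  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  same_strand <- ou$effect_allele == comp(ex$effect_allele) &
    ou$other_allele == comp(ex$other_allele)
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  swapped_strand <- ou$effect_allele == comp(ex$other_allele) &
    ou$other_allele == comp(ex$effect_allele)
  action <- rep("dropped-mismatch", length(shared))
  action[same | same_strand] <- "kept"
  action[(swapped | swapped_strand) & !(same | same_strand)] <- "sign-flipped"
  action[palindromic] <- "dropped-palindromic"
  beta_out <- ifelse(action == "sign-flipped", -ou$beta, ou$beta)
  out <- data.frame(rsid = shared,
                    effect_allele = ex$effect_allele,
                    other_allele = ex$other_allele,
                    beta_exposure = ex$beta, se_exposure = ex$se,
                    beta_outcome = beta_out, se_outcome = ou$se,
                    action = action, stringsAsFactors = FALSE)
  if (!any(action %in% c("kept", "sign-flipped")))
    stop("no instruments left after harmonization")
  structure(out, class = c("instrument_set", "data.frame"))
}

retained_instruments <- function(instr) {
  instr[instr$action %in% c("kept", "sign-flipped"), , drop = FALSE]
}

mr_estimate_row <- function(method, estimate, se, p, n) {
  data.frame(method = method, estimate = estimate, se = se, p = p,
             n_instruments = n, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect IVW: the causal effect is the weighted slope through the
#' origin of outcome effects on exposure effects, with weights
#' `w_j = se_outcome_j^-2`: `estimate = sum(w bX bY) / sum(w bX^2)` and
#' `se = (sum(w bX^2))^-1/2`, with a normal two-sided p-value. With
#' `random_effects = TRUE` the standard error is inflated by the residual
#' scale when it exceeds 1 (multiplicative random effects).
#'
#' @param instr An `instrument_set` from [harmonize()], or any data.frame
#'   with `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`.
#' @param random_effects Use multiplicative random-effects scaling
#'   (default FALSE).
#' @return A one-row `MrEstimate` data.frame: `method`, `estimate`, `se`,
#'   `p`, `n_instruments`.
#' @export
mr_ivw <- function(instr, random_effects = FALSE) {
  d <- if (inherits(instr, "instrument_set")) retained_instruments(instr)
       else instr
  n <- nrow(d)
  if (n < 2L) stop("IVW requires at least 2 instruments")
  w <- d$se_outcome^-2
  est <- sum(w * d$beta_exposure * d$beta_outcome) /
    sum(w * d$beta_exposure^2)
  se <- sqrt(1 / sum(w * d$beta_exposure^2))
  if (random_effects) {
    sigma <- sqrt(sum(w * (d$beta_outcome - est * d$beta_exposure)^2) /
                    (n - 1))
    se <- se * max(1, sigma)
  }
  mr_estimate_row("IVW", est, se, 2 * stats::pnorm(-abs(est / se)), n)
}

#' MR-Egger regression and pleiotropy test
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' intercept, weights `se_outcome^-2`, after orienting all exposure effects
#' non-negative (the MR-Egger sign convention). The slope estimates the
#' causal effect allowing directional pleiotropy; the intercept's
#' deviation from zero (t test, n - 2 df) is the pleiotropy test.
#'
#' @param instr An `instrument_set` (or compatible data.frame).
#' @return A two-row `MrEstimate` data.frame: `Egger-slope` and
#'   `Egger-intercept`.
#' @export
mr_egger <- function(instr) {
  d <- if (inherits(instr, "instrument_set")) retained_instruments(instr)
       else instr
  n <- nrow(d)
  if (n < 3L) stop("MR-Egger requires at least 3 instruments")
  flip <- sign(d$beta_exposure)
  flip[flip == 0] <- 1
  bx <- d$beta_exposure * flip
  by <- d$beta_outcome * flip
  fit <- stats::lm(by ~ bx, weights = d$se_outcome^-2)
  sm <- summary(fit)$coefficients
  rbind(
    mr_estimate_row("Egger-slope", sm["bx", 1L], sm["bx", 2L],
                    2 * stats::pt(-abs(sm["bx", 3L]), n - 2L), n),
    mr_estimate_row("Egger-intercept", sm["(Intercept)", 1L],
                    sm["(Intercept)", 2L],
                    2 * stats::pt(-abs(sm["(Intercept)", 3L]), n - 2L), n))
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Refits the IVW estimator with each instrument excluded in turn and flags
#' exclusions that change the estimate's sign or move it outside the
#' full-set 95% confidence interval — the signature of a single
#' high-leverage instrument.
#'
#' @param instr An `instrument_set` (or compatible data.frame) with at
#'   least 3 retained instruments.
#' @param random_effects Passed to [mr_ivw()].
#' @return A data.frame with one row per excluded instrument: `excluded`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `flagged`; the full-set
#'   estimate is attached as attribute `full`.
#' @export
leave_one_out <- function(instr, random_effects = FALSE) {
  d <- if (inherits(instr, "instrument_set")) retained_instruments(instr)
       else instr
  n <- nrow(d)
  if (n < 3L) stop("leave-one-out requires at least 3 instruments")
  full <- mr_ivw(d, random_effects)
  ci <- full$estimate + c(-1, 1) * stats::qnorm(0.975) * full$se
  rows <- lapply(seq_len(n), function(i) {
    fit <- mr_ivw(d[-i, , drop = FALSE], random_effects)
    data.frame(excluded = d$rsid[i], estimate = fit$estimate, se = fit$se,
               ci_low = fit$estimate - stats::qnorm(0.975) * fit$se,
               ci_high = fit$estimate + stats::qnorm(0.975) * fit$se,
               flagged = sign(fit$estimate) != sign(full$estimate) ||
                 fit$estimate < ci[1] || fit$estimate > ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

#' Full two-sample MR analysis
#'
#' Harmonizes the two summary-statistics tables and runs IVW, MR-Egger
#' (slope and pleiotropy intercept) and the leave-one-out sensitivity
#' analysis.
#'
#' @param exposure,outcome GWAS record data.frames.
#' @param random_effects Passed to [mr_ivw()].
#' @return A list with `instruments` (the harmonized `instrument_set`),
#'   `estimates` (stacked `MrEstimate` rows) and `loo`.
#' @export
mr_analysis <- function(exposure, outcome, random_effects = FALSE) {
  instr <- harmonize(exposure, outcome)
  estimates <- rbind(mr_ivw(instr, random_effects), mr_egger(instr))
  list(instruments = instr, estimates = estimates,
       loo = leave_one_out(instr, random_effects))
}
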