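#' Fit a single-site binding isotherm
#'
#' Least-squares fit of the fraction bound f = P / (K_D + P) to a protein
#' titration (the standard EMSA densitometry model); a Hill variant
#' f = P^n / (K_D^n + P^n) is available behind `hill = TRUE`. The standard
#' error comes from the fit covariance. A titration that never reaches 30%
#' bound yields a warning: K_D is then poorly constrained.
#'
#' @param isotherm a [BindingIsotherm-class], or a numeric vector of
#'   concentrations (molar) with `fractionBound` supplied.
#' @param fractionBound fraction bound per point when `isotherm` is a
#'   plain vector.
#' @param hill if TRUE, fit a Hill coefficient as well.
#' @return The [BindingIsotherm-class] with `fittedKd` and `stderr` filled
#'   in; the Hill coefficient, when fitted, is reported in the
#'   `hill_n` attribute.
#' @examples
#' iso <- simulateIsotherm(63e-9, c(1, 2, 4, 8, 16, 32, 64) * 1e-8,
#'                         noiseSd = 0)
#' fittedKd(fitKd(iso))
#' @export
fitKd <- function(isotherm, fractionBound = NULL, hill = FALSE) {
  if (!is(isotherm, "BindingIsotherm"))
    isotherm <- bindingIsotherm(isotherm, fractionBound)
  P <- isotherm@concentrations
  f <- isotherm@fractionBound
  if (length(P) < 4L) stop("at least 4 titration points are required")
  if (max(P) / min(P) < 10)
    warning("concentrations span less than one decade; fit may be poor")
  if (max(f) < 0.3)
    warning("titration does not approach saturation (max fraction bound ",
            round(max(f), 2), "); K_D confidence interval will be wide")
  start_k <- P[which.min(abs(f - 0.5))]
  fit <- if (hill)
    minpack.lm::nlsLM(f ~ P^n / (K^n + P^n),
                      start = list(K = start_k, n = 1),
                      lower = c(K = min(P) / 1e3, n = 0.1),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  else
    minpack.lm::nlsLM(f ~ P / (K + P), start = list(K = start_k),
                      lower = c(K = min(P) / 1e3),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- summary(fit)$coefficients
  isotherm@fittedKd <- unname(co["K", "Estimate"])
  isotherm@stderr <- unname(co["K", "Std. Error"])
  if (hill) attr(isotherm, "hill_n") <- unname(co["n", "Estimate"])
  validObject(isotherm)
  isotherm
}

#' @describeIn fitKd fitted dissociation constant (molar).
#' @export
fittedKd <- function(isotherm) {
  if (!length(isotherm@fittedKd)) stop("isotherm has not been fitted")
  isotherm@fittedKd
}

#' @describeIn fitKd standard error of the fitted K_D (molar).
#' @export
kdStderr <- function(isotherm) {
  if (!length(isotherm@stderr)) stop("isotherm has not been fitted")
  isotherm@stderr
}

#' Relative expression by the 2^-ddCt method
#'
#' Per biological replicate, dCt = Cq(target) - Cq(reference); ddCt is the
#' mean dCt of the mutant minus the mean dCt of wild type; the fold ratio is
#' 2^-ddCt. Because the reference is subtracted within each replicate, any
#' constant Cq offset of a replicate (input-amount variation) cancels
#' exactly. The standard deviation of the fold is delta-method propagated
#' from the between-replicate variance of dCt, and significance is a
#' two-sided Welch t-test on the dCt values.
#'
#' @param cq data.frame with columns `gene_id`, `strain` ("WT"/"mutant"),
#'   `biorep`, `cq` (technical replicates, if present, are averaged per
#'   biorep).
#' @param targetGene gene to quantify.
#' @param refGene reference gene (default "tbp"); must be measured in every
#'   (strain, biorep).
#' @return list with `fold` (mutant/WT expression ratio), `sd`, `p_value`,
#'   `ddct` and the per-strain dCt vectors.
#' @export
ddct <- function(cq, targetGene, refGene = "tbp") {
  stopifnot(all(c("gene_id", "strain", "biorep", "cq") %in% names(cq)))
  dct_for <- function(strain) {
    sub <- cq[cq$strain == strain, ]
    reps <- unique(sub$biorep)
    vapply(reps, function(b) {
      ref <- sub$cq[sub$biorep == b & sub$gene_id == refGene]
      tgt <- sub$cq[sub$biorep == b & sub$gene_id == targetGene]
      if (!length(ref))
        stop("reference gene '", refGene, "' missing in strain ", strain,
             ", biorep ", b)
      if (!length(tgt))
        stop("target gene '", targetGene, "' missing in strain ", strain,
             ", biorep ", b)
      mean(tgt) - mean(ref)
    }, numeric(1))
  }
  dct_wt <- dct_for("WT")
  dct_mut <- dct_for("mutant")
  if (length(dct_wt) < 2L || length(dct_mut) < 2L)
    stop("at least 2 biological replicates per strain are required")
  dd <- mean(dct_mut) - mean(dct_wt)
  fold <- 2^(-dd)
  se_dd <- sqrt(var(dct_mut) / length(dct_mut) +
                  var(dct_wt) / length(dct_wt))
  # noise-free data (both dCt vectors constant) defeats the t statistic;
  # identical means then carry no evidence of change
  p <- tryCatch(t.test(dct_mut, dct_wt)$p.value,
                error = function(e)
                  if (abs(dd) < 1e-9) 1 else NA_real_)
  list(fold = fold, sd = fold * log(2) * se_dd, p_value = p,
       ddct = dd, dct_wt = dct_wt, dct_mutant = dct_mut)
}
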