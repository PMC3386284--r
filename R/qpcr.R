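# ChIP-qPCR arithmetic: standard-curve efficiency and 2^-ddCp enrichment.

#' Primer efficiency from a qPCR standard curve
#'
#' Fits the least-squares line Cp ~ log10(input ng) over a dilution series
#' and reports the per-cycle amplification factor
#' \code{efficiency = 10^(-1/slope)} (2.0 = perfect doubling, reached at the
#' canonical slope of -3.3219 cycles per decade). Requires at least three
#' distinct concentrations; a non-negative slope (no amplification with
#' dilution) is an error.
#'
#' @param input_ng template mass per reaction in ng, or a data.frame with
#'   columns \code{input_ng} and \code{cp}.
#' @param cp crossing-point values (same length), ignored when a data.frame
#'   is given.
#' @return object of class \code{standard_curve}: list with \code{slope},
#'   \code{intercept}, \code{efficiency}, \code{r_squared},
#'   \code{residuals} and the input \code{points}.
#' @export
standard_curve_efficiency <- function(input_ng, cp = NULL) {
  if (is.data.frame(input_ng)) {
    cp <- input_ng$cp
    input_ng <- input_ng$input_ng
  }
  if (length(input_ng) != length(cp)) .stopf("input_ng and cp lengths differ")
  if (any(input_ng <= 0)) .stopf("input_ng must be positive")
  if (any(cp <= 0)) .stopf("Cp values must be positive")
  if (length(unique(input_ng)) < 3L)
    .stopf("standard curve needs at least 3 distinct concentrations")
  lx <- log10(input_ng)
  fit <- lm(cp ~ lx)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0) .stopf("non-amplifying standard curve (slope >= 0)")
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1L]),
    efficiency = 10^(-1 / slope),
    r_squared = 1 - sum(fit$residuals^2) / sum((cp - mean(cp))^2),
    residuals = unname(fit$residuals),
    points = data.frame(log10_ng = lx, cp = cp)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: slope %.4f, efficiency %.3f (R^2 %.4f)\n",
              x$slope, x$efficiency, x$r_squared))
  invisible(x)
}

#' Relative ChIP enrichment by the 2^-ddCp method
#'
#' Computes \code{dCp_target = Cp(ChIP, target) - Cp(input, target)} and the
#' same for a negative-control primer site, then
#' \code{fold = 2^-(dCp_target - dCp_negative)}. Replicate Cp values are
#' averaged before the differences, and the replicate standard deviations are
#' propagated to \code{sd_ddcp} for error bars. Swapping the ChIP and input
#' templates inverts the fold exactly.
#'
#' @param cp_chip_target,cp_input_target,cp_chip_negative,cp_input_negative
#'   numeric vectors of Cp replicates (length >= 1) for the target and
#'   negative primer sites in the ChIP and input templates.
#' @return list with \code{fold}, \code{ddcp}, \code{delta_cp_target},
#'   \code{delta_cp_negative} and \code{sd_ddcp}.
#' @export
ddcp_fold_enrichment <- function(cp_chip_target, cp_input_target,
                                 cp_chip_negative, cp_input_negative) {
  vals <- list(cp_chip_target, cp_input_target,
               cp_chip_negative, cp_input_negative)
  if (any(vapply(vals, function(v) any(v <= 0), logical(1))))
    .stopf("Cp values must be positive")
  m <- vapply(vals, mean, numeric(1))
  d_target <- m[1L] - m[2L]
  d_neg <- m[3L] - m[4L]
  ddcp <- d_target - d_neg
  # variance of each replicate mean, summed through the differences
  v <- vapply(vals, function(x)
    if (length(x) > 1L) var(x) / length(x) else 0, numeric(1))
  list(fold = 2^(-ddcp), ddcp = ddcp,
       delta_cp_target = d_target, delta_cp_negative = d_neg,
       sd_ddcp = sqrt(sum(v)))
}
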