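#' Root-mean-square error between two series
#'
#' @param a,b numeric series of equal length (>= 1).
#' @return `sqrt(mean((a - b)^2))`.
#' @examples
#' rmse(c(1, 2, 3), c(2, 3, 4))   # 1
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("rmse: series lengths differ")
  if (length(a) < 1L) stop("rmse: empty series")
  sqrt(mean((a - b)^2))
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation. Constant series have no defined
#' correlation and raise an error; callers that need a fallback (the
#' calibration objective) substitute the worst case themselves.
#'
#' @param a,b numeric series, length >= 2, both non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("pearson: series lengths differ")
  if (length(a) < 2L) stop("pearson: need at least 2 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("pearson: correlation undefined for a constant series")
  stats::cor(a, b)
}

#' Categorize a correlation coefficient
#'
#' Bands: `rho <= 0.35` weak, `0.35 < rho <= 0.67` moderate,
#' `0.67 < rho <= 0.9` strong, `rho > 0.9` excellent. Negative
#' correlations fall in the lowest (weak) band.
#'
#' @param rho correlation in `[-1, 1]`.
#' @return One of `"weak"`, `"moderate"`, `"strong"`, `"excellent"`.
#' @examples
#' categorize_rho(0.95)   # "excellent"
#' categorize_rho(0.35)   # "weak" (boundary inclusive)
#' @export
categorize_rho <- function(rho) {
  if (!is.finite(rho) || rho < -1 || rho > 1)
    stop("categorize_rho: rho must lie in [-1, 1]")
  if (rho <= 0.35) "weak"
  else if (rho <= 0.67) "moderate"
  else if (rho <= 0.9) "strong"
  else "excellent"
}

#' Load RMSE as a percentage of the mean experimental load
#'
#' @param rmse_load load RMSE, N.
#' @param mean_experimental_load mean experimentally obtained load, N (> 0).
#' @return Percentage, `100 * rmse / mean`.
#' @examples
#' load_error_percent(45, 90)   # 50
#' @export
load_error_percent <- function(rmse_load, mean_experimental_load) {
  if (mean_experimental_load <= 0)
    stop("load_error_percent: mean experimental load must be > 0")
  100 * rmse_load / mean_experimental_load
}

#' Compare simulated and reference traces channel by channel
#'
#' Builds a per-channel comparison table: RMSE, Pearson rho and its
#' category, and for load channels the RMSE as a percentage of the mean
#' reference force.
#'
#' @param sim,ref data frames on the same cycle grid sharing the channels.
#' @param channels channels to compare (default: the six DOFs plus the
#'   ankle and quadriceps loads, intersected with what is present).
#' @return Data frame with columns `channel, rmse, rho, rho_category,
#'   load_error_pct`.
#' @export
compare_traces <- function(sim, ref,
                           channels = c("FE", "VV", "IE", "AP", "ML", "IS",
                                        "F_ankle", "F_quad")) {
  channels <- intersect(channels, intersect(names(sim), names(ref)))
  if (nrow(sim) != nrow(ref))
    stop("compare_traces: traces are not on the same cycle grid")
  rows <- lapply(channels, function(ch) {
    e <- rmse(sim[[ch]], ref[[ch]])
    rho <- tryCatch(pearson(sim[[ch]], ref[[ch]]), error = function(e) NA_real_)
    data.frame(channel = ch, rmse = e, rho = rho,
               rho_category = if (is.na(rho)) NA_character_ else categorize_rho(rho),
               load_error_pct = if (ch %in% c("F_ankle", "F_quad"))
                 load_error_percent(e, mean(ref[[ch]])) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
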