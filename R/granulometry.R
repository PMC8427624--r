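#' Sieve-stack granulometry
#'
#' A sieve stack is the raw granulometric measurement for one plot: the mass
#' retained on each sieve of a descending aperture series, plus the mass
#' collected in the pan below the finest sieve. The default aperture series is
#' the six-sieve geological stack (2, 1, 0.5, 0.25, 0.125, 0.063 mm) used to
#' process 100 g of dried plot sediment. All derived metrics are invariant to
#' the total mass, so subsample size is not enforced.
#'
#' @param retained numeric vector of masses (g) retained on each sieve, in the
#'   same order as `apertures`.
#' @param apertures sieve openings in mm, strictly descending.
#' @param pan mass (g) passing the finest sieve.
#' @return an object of class `sieve_stack`.
#' @export
#' @examples
#' s <- sieve_stack(c(5, 10, 40, 30, 10, 4), pan = 1)
#' grain_metrics(s)
sieve_stack <- function(retained,
                        apertures = c(2, 1, 0.5, 0.25, 0.125, 0.063),
                        pan = 0) {
  if (length(retained) != length(apertures))
    stop_invalid("`retained` must have one mass per aperture")
  if (any(!is.finite(c(retained, pan, apertures))))
    stop_invalid("sieve masses and apertures must be finite")
  if (any(retained < 0) || pan < 0)
    stop_invalid("negative sieve mass")
  if (any(diff(apertures) >= 0))
    stop_invalid("apertures must be strictly descending")
  if (sum(retained) + pan <= 0)
    stop_invalid("total sieve mass must be positive")
  structure(list(apertures = as.numeric(apertures),
                 retained = as.numeric(retained),
                 pan = as.numeric(pan)),
            class = "sieve_stack")
}

# Lower bound assigned to the pan fraction (mm) and the multiplier giving the
# upper bound of the coarsest fraction. A fraction retained on the a-mm sieve
# spans [a, next coarser bound).
PAN_LOWER_MM <- 0.001
COARSE_UPPER_FACTOR <- 2

#' Cumulative grain-size curve
#'
#' Converts a sieve stack into a cumulative distribution of percent finer by
#' mass against diameter. The curve is evaluated at the fraction boundaries:
#' the pan fraction is bounded below at 0.001 mm and the coarsest fraction is
#' bounded above at twice the largest aperture.
#'
#' @param stack a [sieve_stack()].
#' @return an object of class `grain_curve`: a data frame with columns
#'   `diameter` (mm, increasing) and `pct_finer` (0 at the lower bound of the
#'   finest fraction, 100 at the upper bound of the coarsest).
#' @export
cumulative_curve <- function(stack) {
  if (!inherits(stack, "sieve_stack")) stack <- do.call(sieve_stack, as.list(stack))
  ap <- stack$apertures
  # masses ordered fine -> coarse: pan, then sieves from finest to coarsest
  masses <- c(stack$pan, rev(stack$retained))
  total <- sum(masses)
  bounds <- c(PAN_LOWER_MM, rev(ap), ap[1] * COARSE_UPPER_FACTOR)
  pct <- c(0, cumsum(masses)) / total * 100
  structure(data.frame(diameter = bounds, pct_finer = pct),
            class = c("grain_curve", "data.frame"))
}

#' Percentile diameter from a cumulative grain-size curve
#'
#' Reads the diameter at which the cumulative percent finer by mass equals
#' `x`. Interpolation is log-linear on the phi scale within each fraction
#' (standard sedimentological practice); linear-in-mm interpolation is
#' available via `method = "mm"`. Percentiles falling in the extreme
#' (pan or coarsest) fractions are interpolated within their nominal bounds
#' and a warning is issued, since those bounds are conventions rather than
#' measurements.
#'
#' @param curve a [cumulative_curve()] result.
#' @param x percent in (0, 100).
#' @param method interpolation scale, `"phi"` (default) or `"mm"`.
#' @return diameter in mm.
#' @export
percentile_diameter <- function(curve, x, method = c("phi", "mm")) {
  method <- match.arg(method)
  if (!inherits(curve, "grain_curve")) stop_invalid("`curve` must be a grain_curve")
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 100))
    stop_invalid("percentile x must lie strictly inside (0, 100)")
  pct <- curve$pct_finer
  d <- curve$diameter
  k <- length(pct)
  if (any(x < pct[2]) || any(x > pct[k - 1]))
    warning("percentile falls in an extreme (pan or coarsest) fraction; ",
            "value interpolated within nominal bounds", call. = FALSE)
  # drop empty leading/trailing fractions so percentiles stay bracketed by
  # the innermost boundaries carrying mass
  first <- max(which(pct == 0))
  last <- min(which(pct == 100))
  pct <- pct[first:last]; d <- d[first:last]
  scale_fun <- if (method == "phi") function(z) -log2(z) else identity
  unscale <- if (method == "phi") function(z) 2^(-z) else identity
  vapply(x, function(xx) {
    # approx with ties = mean places a percentile inside a zero-mass fraction
    # at the midpoint (on the interpolation scale) of the flat segment
    unscale(approx(pct, scale_fun(d), xout = xx, ties = mean)$y)
  }, numeric(1))
}

#' Substrate metrics from a sieve stack
#'
#' Computes the Table-style substrate variables: the 16th/50th/84th percentile
#' diameters, mean particle size `D_mean = (D16 + D50 + D84)/3`, the sorting
#' index `So = (phi84 - phi16)/2`, and bed roughness `ks = 2 * D50`.
#'
#' The phi percentiles follow the phi-distribution convention: phi increases
#' as diameter decreases, so the 84th phi percentile lies in the *finer* tail,
#' `phi84 = -log2(D16)` and `phi16 = -log2(D84)`. With this convention
#' `So >= 0` always. The alternative reading (`phi84 = phi(D84)`) would flip
#' the sign; the convention used here is the one under which the sorting index
#' is a nonnegative spread measure.
#'
#' @param stack a [sieve_stack()], or anything [cumulative_curve()] accepts.
#' @param method interpolation scale passed to [percentile_diameter()].
#' @return a one-row data frame with columns `D16`, `D50`, `D84`, `phi16`,
#'   `phi84`, `D_mean`, `So`, `ks`.
#' @export
grain_metrics <- function(stack, method = c("phi", "mm")) {
  method <- match.arg(method)
  curve <- if (inherits(stack, "grain_curve")) stack else cumulative_curve(stack)
  p <- percentile_diameter(curve, c(16, 50, 84), method = method)
  D16 <- p[1]; D50 <- p[2]; D84 <- p[3]
  phi16 <- -log2(D84)  # coarse tail: 16th percentile of the phi distribution
  phi84 <- -log2(D16)  # fine tail
  data.frame(D16 = D16, D50 = D50, D84 = D84,
             phi16 = phi16, phi84 = phi84,
             D_mean = (D16 + D50 + D84) / 3,
             So = (phi84 - phi16) / 2,
             ks = 2 * D50)
}

#' Verbal sorting class for a sorting index
#'
#' Maps the sorting index to the Folk and Ward verbal scale. The field
#' anchors are So = 0.1 "very well sorted" and So = 0.9 "moderately sorted".
#'
#' @param So sorting index, nonnegative.
#' @return character vector of sorting classes.
#' @export
classify_sorting <- function(So) {
  if (any(!is.finite(So)) || any(So < 0)) stop_invalid("So must be nonnegative")
  cut(So,
      breaks = c(-Inf, 0.35, 0.50, 0.71, 1.00, 2.00, 4.00, Inf),
      labels = c("very well sorted", "well sorted", "moderately well sorted",
                 "moderately sorted", "poorly sorted", "very poorly sorted",
                 "extremely poorly sorted"),
      right = FALSE) |> as.character()
}

#' Substrate metrics for a table of plots
#'
#' Applies [grain_metrics()] to wide-format sieve columns. The header
#' contract is one column per aperture named `sieve_<aperture>` (mm, `.`
#' allowed) plus `pan`.
#'
#' @param plots data frame with sieve columns.
#' @param apertures aperture series matching the `sieve_*` columns.
#' @return `plots` with columns `D16`, `D50`, `D84`, `D_mean`, `So`, `ks`
#'   appended.
#' @export
grain_table <- function(plots, apertures = c(2, 1, 0.5, 0.25, 0.125, 0.063)) {
  cols <- paste0("sieve_", apertures)
  missing_cols <- setdiff(c(cols, "pan"), names(plots))
  if (length(missing_cols))
    stop_invalid("missing sieve columns: ", paste(missing_cols, collapse = ", "))
  gm <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    s <- sieve_stack(as.numeric(plots[i, cols]), apertures, pan = plots$pan[i])
    grain_metrics(s)
  }))
  cbind(plots, gm[, c("D16", "D50", "D84", "D_mean", "So", "ks")])
}
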