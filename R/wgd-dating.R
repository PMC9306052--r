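#' Ks distribution configuration
#'
#' @param ks_min,ks_max retained Ks range. The lower bound excludes
#'   near-zero values from allelic variation or assembly artifacts
#'   (recent species-specific peaks can sit at Ks 0.02--0.03, so lower
#'   it when those are the target); the upper bound excludes the
#'   saturated tail.
#' @param bandwidth_rule "silverman" (rule-of-thumb) or "fixed".
#' @param fixed_bandwidth bandwidth when rule is "fixed".
#' @param min_pairs minimum surviving values required before a density
#'   is estimated.
#' @return A named list of class \code{"DistributionConfig"}.
#' @export
distributionConfig <- function(ks_min = 0.005, ks_max = 2.0,
                               bandwidth_rule = c("silverman", "fixed"),
                               fixed_bandwidth = NULL,
                               min_pairs = 50L) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  stopifnot(ks_min >= 0, ks_min < ks_max)
  if (bandwidth_rule == "fixed" &&
      (is.null(fixed_bandwidth) || fixed_bandwidth <= 0))
    stop("fixed bandwidth rule requires fixed_bandwidth > 0")
  structure(list(ks_min = ks_min, ks_max = ks_max,
                 bandwidth_rule = bandwidth_rule,
                 fixed_bandwidth = fixed_bandwidth,
                 min_pairs = as.integer(min_pairs)),
            class = "DistributionConfig")
}

#' Filter Ks values for distribution analysis
#'
#' Drops undefined (NA, saturated) values and values outside
#' \code{[ks_min, ks_max]}; reports how many were dropped per reason.
#'
#' @param ks numeric vector of Ks values (NA = saturated/undefined).
#' @param config a [distributionConfig()].
#' @return list(values, n_input, n_na, n_out_of_range).
#' @export
collectKsValues <- function(ks, config = distributionConfig()) {
  n_input <- length(ks)
  n_na <- sum(is.na(ks))
  v <- ks[!is.na(ks)]
  in_range <- v >= config$ks_min & v <= config$ks_max
  n_oor <- sum(!in_range)
  v <- v[in_range]
  if (length(v) < config$min_pairs)
    stop("only ", length(v), " usable Ks values; need at least ",
         config$min_pairs)
  list(values = v, n_input = n_input, n_na = n_na,
       n_out_of_range = n_oor)
}

#' KsPeakSet: modes of a Ks distribution with dated ages
#'
#' @slot peaks data.frame (mode_ks, density, n_pairs_in_window,
#'   confidence), modes ascending.
#' @slot lambdaRate substitution rate (substitutions/site/year).
#' @slot agesMya ages of the modes, \eqn{T = Ks / (2 \lambda)}, Mya.
#' @slot bandwidth the kernel bandwidth used.
#' @slot nValues number of Ks values in the density.
#' @export
setClass("KsPeakSet",
  representation(peaks = "data.frame", lambdaRate = "numeric",
                 agesMya = "numeric", bandwidth = "numeric",
                 nValues = "integer"),
  validity = function(object) {
    p <- object@peaks
    if (nrow(p) > 1L && is.unsorted(p$mode_ks, strictly = TRUE))
      return("modes must be sorted ascending")
    if (object@lambdaRate <= 0) return("lambdaRate must be positive")
    if (length(object@agesMya) != nrow(p))
      return("one age per mode required")
    expect <- p$mode_ks / (2 * object@lambdaRate) / 1e6
    if (nrow(p) && any(abs(expect - object@agesMya) > 1e-9))
      return("agesMya inconsistent with mode_ks / (2 lambda)")
    TRUE
  })

setMethod("show", "KsPeakSet", function(object) {
  cat("KsPeakSet:", nrow(object@peaks), "mode(s) from",
      object@nValues, "pairs (lambda =", object@lambdaRate, ")\n")
  if (nrow(object@peaks)) {
    df <- object@peaks
    df$age_mya <- round(object@agesMya, 2)
    print(df)
  }
})

#' @describeIn KsPeakSet-class mode table accessor
#' @param x a KsPeakSet
#' @export
peaks <- function(x) x@peaks

#' @describeIn KsPeakSet-class ages (Mya) accessor
#' @export
agesMya <- function(x) x@agesMya

#' Convert a Ks mode to an event age
#'
#' \eqn{T = Ks / (2\lambda)}, reported in Mya. The default rate is the
#' average grass synonymous substitution rate 6.5e-9
#' substitutions/site/year.
#'
#' @param mode_ks Ks value(s), >= 0.
#' @param lambda_rate substitution rate per site per year, > 0.
#' @return Age(s) in Mya.
#' @examples
#' dateEvent(0.27)  # ~20.8 Mya
#' @export
dateEvent <- function(mode_ks, lambda_rate = 6.5e-9) {
  if (any(lambda_rate <= 0)) stop("lambda_rate must be positive")
  if (any(mode_ks < 0)) stop("mode_ks must be non-negative")
  mode_ks / (2 * lambda_rate) / 1e6
}

#' Detect modes of a Ks (or 4DTv) distribution
#'
#' Gaussian kernel density on a 512-point grid over
#' \code{[ks_min, ks_max]}; modes are strict local maxima whose density
#' reaches at least 5\% of the global maximum; adjacent modes closer
#' than one bandwidth are merged to the higher one. A mode is flagged
#' low-confidence when its density is below twice the mean grid
#' density (a flat, uninformative distribution).
#'
#' @param values numeric Ks values (already filtered; see
#'   [collectKsValues()]).
#' @param config a [distributionConfig()].
#' @param lambda_rate substitution rate used to date the modes.
#' @param prominence minimum density relative to the global maximum.
#' @return A [KsPeakSet-class].
#' @export
detectKsPeaks <- function(values, config = distributionConfig(),
                          lambda_rate = 6.5e-9, prominence = 0.05) {
  if (length(values) < config$min_pairs)
    stop("need at least ", config$min_pairs, " values")
  bw <- if (config$bandwidth_rule == "fixed") config$fixed_bandwidth
        else stats::bw.nrd0(values)
  d <- stats::density(values, bw = bw, n = 512L,
                      from = config$ks_min, to = config$ks_max)
  y <- d$y; x <- d$x
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] > y[3:n], FALSE)
  cand <- which(is_max & y >= prominence * max(y))
  # merge modes closer than one bandwidth, keep the higher
  cand <- cand[order(-y[cand])]
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(x[i] - x[keep]) >= bw)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  modes <- x[keep]
  dens <- y[keep]
  n_window <- vapply(modes, function(m)
    sum(values >= m - bw & values <= m + bw), integer(1))
  conf <- ifelse(dens >= 2 * mean(y), "ok", "low")
  pk <- data.frame(mode_ks = modes, density = dens,
                   n_pairs_in_window = n_window, confidence = conf,
                   stringsAsFactors = FALSE)
  methods::new("KsPeakSet", peaks = pk, lambdaRate = lambda_rate,
               agesMya = dateEvent(modes, lambda_rate),
               bandwidth = bw, nValues = length(values))
}

#' Tabulate WGD and divergence candidate events
#'
#' Combines peak sets from several comparisons into one event table.
#' Modes from within-genome (paralog) comparisons are labelled
#' "WGD-candidate", modes from between-genome (ortholog) comparisons
#' "divergence-candidate".
#'
#' @param peaksets named list of [KsPeakSet-class] objects; names are
#'   comparison labels.
#' @param within logical vector (same length) marking within-genome
#'   comparisons.
#' @return data.frame (comparison, type, mode_ks, density, n_pairs,
#'   age_mya, confidence).
#' @export
summarizeWgd <- function(peaksets, within) {
  stopifnot(length(peaksets) >= 1L, length(within) == length(peaksets))
  rows <- lapply(seq_along(peaksets), function(i) {
    ps <- peaksets[[i]]
    p <- peaks(ps)
    if (nrow(p) == 0L) return(NULL)
    data.frame(comparison = names(peaksets)[i],
               type = if (within[i]) "WGD-candidate"
                      else "divergence-candidate",
               mode_ks = p$mode_ks, density = p$density,
               n_pairs = p$n_pairs_in_window,
               age_mya = agesMya(ps), confidence = p$confidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(comparison = character(0), type = character(0),
                      mode_ks = numeric(0), density = numeric(0),
                      n_pairs = integer(0), age_mya = numeric(0),
                      confidence = character(0))
  rownames(out) <- NULL
  out
}
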