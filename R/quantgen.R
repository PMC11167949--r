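#' One-locus population mean under additivity and dominance
#'
#' For a biallelic locus with additive effect `a`, dominance deviation `d`
#' and frequency `p` of the increasing allele (q = 1 - p), the population
#' mean deviation from the homozygote midpoint is
#' \deqn{\mu = a (p - q) + 2 p q d.}
#' The screen's frequency cutoff comes from asking when this mean exceeds
#' zero, i.e. when the population average is pulled above the midpoint.
#'
#' @param p frequency of the increasing allele, in \[0, 1\].
#' @param a additive effect (default 1; the cutoff depends only on `d/a`).
#' @param d dominance deviation.
#' @return The population mean \eqn{\mu}.
#' @export
population_mean <- function(p, a = 1, d = 0) {
  stopifnot(all(p >= 0 & p <= 1))
  a * (p - (1 - p)) + 2 * p * (1 - p) * d
}

#' Allele-frequency cutoff implied by the population-mean model
#'
#' Returns the smallest frequency p* in \[0, 1\] at which the population
#' mean crosses zero, i.e. the root of a(2p - 1) + 2p(1 - p)d = 0. With no
#' dominance (d = 0) this is exactly 0.5; with complete dominance (d = a)
#' it is 1 - sqrt(2)/2, about 0.2929 (commonly quoted as 0.30). The screen
#' uses the conservative d = 0 value, 0.50, as its default threshold.
#'
#' @param d_over_a dominance-to-additive ratio d/a, in \[0, 1\].
#' @return The cutoff frequency p*.
#' @export
threshold_frequency <- function(d_over_a) {
  stopifnot(length(d_over_a) == 1L, d_over_a >= 0)
  d <- d_over_a
  if (d == 0) return(0.5)
  # -2d p^2 + (2 + 2d) p - 1 = 0; the smaller root lies in [0, 0.5]
  disc <- (1 + d)^2 - 2 * d
  root <- ((1 + d) - sqrt(disc)) / (2 * d)
  if (root < 0 || root > 1) stop("no root in [0, 1] for d/a = ", d_over_a)
  root
}
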