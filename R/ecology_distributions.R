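# Probability distributions over the 16 canonical ecologies.

#' Validate an ecology distribution
#'
#' An ecology distribution is a probability vector of length 16 aligned to
#' the canonical ecology indices (see [enumerate_ecologies()]).
#'
#' @param probs Numeric vector of length 16.
#' @return The validated (unnamed) probability vector.
#' @export
as_ecology_distribution <- function(probs) {
  if (!is.numeric(probs) || length(probs) != 16L || anyNA(probs)) {
    stop("an ecology distribution must be 16 probabilities", call. = FALSE)
  }
  if (any(probs < 0)) {
    stop("ecology probabilities must be non-negative", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("ecology probabilities must sum to 1 (tolerance 1e-12)",
         call. = FALSE)
  }
  unname(as.numeric(probs))
}

#' Uniform ecology distribution
#'
#' Every one of the 16 ecologies has probability 1/16 = 0.0625.
#'
#' @return Probability vector of length 16.
#' @export
uniform_distribution <- function() {
  rep(1 / 16, 16L)
}

#' Poisson-weighted ecology distribution
#'
#' Weights ecology index `j` by the Poisson probability mass at `j - 1`
#' (mean `mu`), truncated to the 16 indices and renormalized. Larger means
#' shift mass toward the metabolite-rich end of the canonical ordering,
#' in particular toward ecologies 14 and 16 -- the only two permissive for a
#' HIS-up monoculture.
#'
#' @param mu Positive Poisson mean.
#' @return Probability vector of length 16.
#' @export
poisson_distribution <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0) {
    stop("`mu` must be a single positive number", call. = FALSE)
  }
  p <- dpois(0:15, mu)
  as_ecology_distribution(p / sum(p))
}

#' Metabolic-feedback ecology distribution
#'
#' Models strains shaping their own niche: the metabolites secreted during
#' the previous cycle bias the next cycle's ecologies. Each metabolite is
#' present independently with probability equal to the global frequency of
#' the strain that overproduces it (optionally rescaled as
#' `min(1, 4 * frequency)`), and the 16 ecology probabilities are the
#' resulting product-Bernoulli masses.
#'
#' A pool fixed for one strain therefore generates only ecologies containing
#' that strain's own product -- ecologies in which the strain itself starves,
#' the self-defeating skew that drives collapse under late feedback.
#'
#' @param strain_freqs Per-strain frequency 4-vector (non-negative, sums
#'   to 1 within 1e-9), strain order ADE, TRP, HIS, LYS.
#' @param scaling `"identity"` (presence probability = producer frequency)
#'   or `"4x"` (`min(1, 4 * frequency)`).
#' @return Probability vector of length 16.
#' @export
feedback_distribution <- function(strain_freqs, scaling = c("identity", "4x")) {
  scaling <- match.arg(scaling)
  if (!is.numeric(strain_freqs) || length(strain_freqs) != 4L ||
      anyNA(strain_freqs) || any(strain_freqs < 0)) {
    stop("`strain_freqs` must be 4 non-negative frequencies", call. = FALSE)
  }
  if (abs(sum(strain_freqs) - 1) > 1e-9) {
    stop("`strain_freqs` must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  p_m <- unname(as.numeric(strain_freqs)) # P(metabolite m present)
  if (scaling == "4x") p_m <- pmin(1, 4 * p_m)
  eco <- enumerate_ecologies()
  pres <- as.matrix(eco[, METABOLITES])
  probs <- apply(pres, 1L, function(b) prod(ifelse(b == 1L, p_m, 1 - p_m)))
  as_ecology_distribution(probs)
}

#' Restrict an ecology distribution (keystone experiment)
#'
#' Removes all ecologies containing a banned metabolite and renormalizes the
#' remaining 8. With tryptophan banned, no ecology supplies TRP, so the
#' TRP overproducer becomes an essential (keystone) community member.
#'
#' @param dist Ecology distribution (length-16 probability vector).
#' @param banned One of `metabolites()`.
#' @return Probability vector of length 16 with zero mass on every ecology
#'   containing `banned`.
#' @export
restrict_distribution <- function(dist, banned) {
  dist <- as_ecology_distribution(dist)
  banned <- match.arg(banned, METABOLITES)
  eco <- enumerate_ecologies()
  dist[eco[[banned]] == 1L] <- 0
  tot <- sum(dist)
  if (tot <= 0) {
    stop("no probability mass remains after banning ", banned, call. = FALSE)
  }
  dist / tot
}
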