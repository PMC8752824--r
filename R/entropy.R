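#' Inclusion fractions of a stride-1 tiling
#'
#' For a region of `L` units tiled by all `L - n + 1` contiguous windows of
#' length `n`, the inclusion fraction `P_i` is the fraction of windows that
#' contain unit `i`. Units near the region edges are covered by fewer
#' windows, giving the closed form
#' `P_i = min(i, n, L - i + 1, L - n + 1) / (L - n + 1)`.
#'
#' Note that the `P_i` are per-unit coverage fractions, not a probability
#' distribution: they sum to `n`, not 1.
#'
#' @param L Region length in units (positive integer).
#' @param n Window (sub-segment) length, `1 <= n <= L`.
#' @return Numeric vector of length `L`.
#' @examples
#' inclusion_fractions(11, 3)
#' @export
inclusion_fractions <- function(L, n) {
  L <- check_count(L, "L", min = 1L)
  n <- check_count(n, "n", min = 1L)
  if (n > L) abort(sprintf("invalid sub-segment length: n = %d exceeds L = %d.", n, L))
  i <- seq_len(L)
  pmin(i, n, L - i + 1L, L - n + 1L) / (L - n + 1L)
}

#' Information entropy of a sub-segmentation experiment
#'
#' Scores a design that tests all `L - n + 1` contiguous length-`n` windows
#' of an `L`-unit region by the entropy of its per-unit inclusion fractions,
#' `-sum_i P_i log2 P_i` (with `1 * log2(1) = 0`). High entropy means the
#' windows discriminate well between units; `n = L` (a single window) gives
#' zero information.
#'
#' @inheritParams inclusion_fractions
#' @return Entropy in bits (nonnegative scalar).
#' @examples
#' segmentation_entropy(11, 3)
#' @export
segmentation_entropy <- function(L, n) {
  p <- inclusion_fractions(L, n)
  terms <- ifelse(p == 1, 0, -p * log2(p))
  sum(terms)
}

#' Entropy profile of a region
#'
#' Evaluates the segmentation entropy for every sub-segment length
#' `n = 1..L`, together with the number of constructs each design needs and
#' its inclusion fractions.
#'
#' @param L Region length in units.
#' @return A tibble of class `entropy_profile` with columns `n`,
#'   `n_constructs`, `entropy_bits` and list-column `inclusion_fractions`.
#' @examples
#' entropy_profile(11)
#' @export
entropy_profile <- function(L) {
  L <- check_count(L, "L", min = 1L)
  n <- seq_len(L)
  prof <- tibble(
    n = n,
    n_constructs = L - n + 1L,
    inclusion_fractions = lapply(n, function(k) inclusion_fractions(L, k)),
    entropy_bits = vapply(n, function(k) segmentation_entropy(L, k), numeric(1))
  )
  structure(prof, region_length = L,
            class = c("entropy_profile", class(prof)))
}

#' Entropy-maximising sub-segment length
#'
#' Ties are broken towards the larger `n`: longer sub-segments keep repeats
#' in a more native-like structural context, so when two lengths carry equal
#' information the longer one is preferred.
#'
#' @param profile An [entropy_profile()].
#' @return The argmax `n` (single integer).
#' @export
max_entropy_length <- function(profile) {
  stopifnot(inherits(profile, "entropy_profile"))
  e <- profile$entropy_bits
  best <- max(e)
  # relative epsilon guards against float noise in the tie comparison
  candidates <- profile$n[e >= best - 1e-9 * max(1, abs(best))]
  max(candidates)
}

#' Admissible sub-segment lengths under an entropy tolerance
#'
#' Returns every `n` whose entropy is at least `tolerance` times the
#' maximal entropy over the profile, in ascending order. The comparison uses
#' a relative epsilon of 1e-9 so lengths sitting exactly on the threshold
#' are not excluded by float rounding.
#'
#' @param profile An [entropy_profile()].
#' @param tolerance Fraction of the maximal entropy in `(0, 1]`; default 0.9.
#' @return Integer vector of admissible lengths, ascending.
#' @examples
#' admissible_lengths(entropy_profile(11))  # 2 3 4 5
#' admissible_lengths(entropy_profile(12))  # 3 4 5
#' @export
admissible_lengths <- function(profile, tolerance = 0.9) {
  stopifnot(inherits(profile, "entropy_profile"))
  if (!is.numeric(tolerance) || length(tolerance) != 1L ||
      tolerance <= 0 || tolerance > 1) {
    abort("`tolerance` must be a single number in (0, 1].")
  }
  e <- profile$entropy_bits
  threshold <- tolerance * max(e)
  sort(profile$n[e >= threshold - 1e-9 * max(1, abs(threshold))])
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("Entropy profile for a %d-unit region (argmax n = %d)\n",
              attr(x, "region_length"), max_entropy_length(x)))
  NextMethod()
}
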