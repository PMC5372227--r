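#' Method parameters
#'
#' Bundles every tunable parameter of the tag-generation, convolution,
#' gap-estimation and assembly stages. Defaults are the values used for
#' top-down protein data.
#'
#' @param k Tag length (residues). A k-tag is read off k + 1 peaks.
#' @param epsilon Peak-difference mass tolerance epsilon (Da); spectrum-graph
#'   edges and tag gluing compare at `2 * epsilon`.
#' @param gmax Maximum acceptable gap mass (Da). Binned differences above
#'   this are never candidates.
#' @param bmin Minimum multiplicity a binned difference needs to become a
#'   candidate gap estimate.
#' @param amin Minimum number of amino acids of each fragment that the tags
#'   supporting an estimate must cover; the support check derives
#'   `m* = amin - k + 1` from it.
#' @param eps_abs_ppm Relative tolerance (ppm) for comparing mass offsets
#'   during the embedding overlap check.
#' @param h Scaling exponent: offset differences are multiplied by `10^h`
#'   and rounded to integers before histogramming.
#' @param water_loss Logical; eliminate water-loss peaks during
#'   preprocessing.
#' @param reflect Logical; add precursor-reflected peaks during
#'   preprocessing.
#' @param same_spectrum_only Logical; restrict tag convolution to pairs of
#'   tags from the same spectrum (the top-down default). Lifting the
#'   restriction reproduces the bottom-up behaviour used for position
#'   validation experiments.
#'
#' @return A list with class `"stitch_params"`.
#' @examples
#' stitch_params()
#' stitch_params(bmin = 10)
#' @export
stitch_params <- function(k = 4L,
                          epsilon = 0.004,
                          gmax = 3000,
                          bmin = 20L,
                          amin = 6L,
                          eps_abs_ppm = 10,
                          h = 4L,
                          water_loss = TRUE,
                          reflect = TRUE,
                          same_spectrum_only = TRUE) {
  k <- as.integer(k); bmin <- as.integer(bmin)
  amin <- as.integer(amin); h <- as.integer(h)
  stopifnot(
    k >= 1L, epsilon > 0, gmax > 0, bmin >= 1L,
    amin >= k, eps_abs_ppm > 0, h >= 0L,
    is.logical(water_loss), is.logical(reflect),
    is.logical(same_spectrum_only)
  )
  structure(
    list(
      k = k, epsilon = epsilon, gmax = gmax, bmin = bmin, amin = amin,
      eps_abs_ppm = eps_abs_ppm, h = h, water_loss = water_loss,
      reflect = reflect, same_spectrum_only = same_spectrum_only
    ),
    class = "stitch_params"
  )
}

#' @export
print.stitch_params <- function(x, ...) {
  cat("<stitch_params>\n")
  cat(sprintf("  k = %d, epsilon = %g Da, h = %d\n", x$k, x$epsilon, x$h))
  cat(sprintf("  gmax = %g Da, bmin = %d, amin = %d (m* = %d)\n",
              x$gmax, x$bmin, x$amin, x$amin - x$k + 1L))
  cat(sprintf("  eps_abs = %g ppm\n", x$eps_abs_ppm))
  cat(sprintf("  preprocessing: water_loss = %s, reflect = %s\n",
              x$water_loss, x$reflect))
  cat(sprintf("  same_spectrum_only = %s\n", x$same_spectrum_only))
  invisible(x)
}

# round half away from zero; R's round() rounds half to even
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Percent coverage
#'
#' Share of a protein's residues covered by reconstructed fragments,
#' reported as a percentage rounded to one decimal, e.g. 63 of 76 residues
#' is 82.9.
#'
#' @param covered Number of covered residues.
#' @param total Protein length in residues.
#' @return Percentage (one decimal).
#' @examples
#' coverage_percent(63, 76)
#' @export
coverage_percent <- function(covered, total) {
  stopifnot(total > 0, covered >= 0, covered <= total)
  round(100 * covered / total, 1)
}
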