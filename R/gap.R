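#' Scale and bin offset differences
#'
#' Each raw offset difference `d` is scaled by `10^h` and rounded to the
#' nearest integer (the scaled difference), and independently rounded to
#' the nearest integer dalton (the binned difference). Multiplicities
#' aggregate by exact equality of the rounded values; rounding is
#' half-away-from-zero. Negative differences are allowed at this stage —
#' filtering to `[0, Gmax]` happens in [select_candidate()].
#'
#' @param conv A contribution tibble from [string_convolution()] or
#'   [tag_convolution()].
#' @param h Scaling exponent (>= 0).
#' @return The contribution tibble with added integer columns `scaled` and
#'   `binned`, classed `binned_differences` (attribute `h` records the
#'   exponent). Row counts, and hence total multiplicity, are unchanged.
#' @export
bin_differences <- function(conv, h = 4L) {
  stopifnot(h >= 0L)
  conv$scaled <- round_half_away(conv$difference * 10^h)
  conv$binned <- round_half_away(conv$difference)
  attr(conv, "h") <- as.integer(h)
  class(conv) <- c("binned_differences", class(conv))
  conv
}

#' Binned multiplicities of a difference histogram
#'
#' @param hist A [bin_differences()] result.
#' @return A tibble `binned`, `multiplicity`, sorted by bin.
#' @export
bin_multiplicities <- function(hist) {
  dplyr::count(tibble::as_tibble(hist), .data$binned,
               name = "multiplicity") |>
    dplyr::arrange(.data$binned)
}

#' Score of a binned difference
#'
#' `Score(db) = mu(db) + mu(db - 1) + mu(db + 1)`, with absent bins
#' counting zero. Aggregating the two neighbouring 1 Da bins absorbs the
#' well-known plus/minus 1 Da monoisotopic-assignment errors of
#' deconvoluted masses.
#'
#' @param hist A [bin_differences()] result.
#' @param db Integer bin value(s).
#' @return Integer score(s).
#' @export
score_bin <- function(hist, db) {
  mu <- bin_multiplicities(hist)
  look <- function(b) {
    i <- match(b, mu$binned)
    ifelse(is.na(i), 0L, mu$multiplicity[i])
  }
  look(db) + look(db - 1) + look(db + 1)
}

#' Select a candidate gap estimate from a binned histogram
#'
#' Restricts to non-negative bins not exceeding `Gmax` with multiplicity at
#' least `Bmin`; among those with the maximal multiplicity, picks the one
#' with the highest score (ties: smallest bin); within the winning bin,
#' picks the scaled difference with the highest multiplicity (ties:
#' smallest scaled value) and reports `d_hat = scaled / 10^h`.
#'
#' @param hist A [bin_differences()] result.
#' @param params A [stitch_params()] object.
#' @return A one-row tibble `d_hat`, `d_hat_b`, `multiplicity`, `score`,
#'   or `NULL` if no bin survives the filters.
#' @export
select_candidate <- function(hist, params = stitch_params()) {
  mu <- bin_multiplicities(hist)
  ok <- mu[mu$binned >= 0 & mu$binned <= params$gmax &
             mu$multiplicity >= params$bmin, ]
  if (nrow(ok) == 0L) return(NULL)
  bmax <- max(ok$multiplicity)
  cand <- ok[ok$multiplicity == bmax, ]
  cand$score <- score_bin(hist, cand$binned)
  cand <- cand[order(-cand$score, cand$binned), ]
  db <- cand$binned[1L]
  in_bin <- hist[hist$binned == db, ]
  sc <- dplyr::count(tibble::as_tibble(in_bin), .data$scaled, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$scaled)
  tibble::tibble(
    d_hat = sc$scaled[1L] / 10^attr(hist, "h"),
    d_hat_b = db,
    multiplicity = bmax,
    score = cand$score[1L]
  )
}

# distinct supporting k-mer windows per string among the contributions to
# one bin
support_counts <- function(hist, db) {
  in_bin <- hist[hist$binned == db, ]
  c(n1 = length(unique(in_bin$win1)), n2 = length(unique(in_bin$win2)))
}

#' Coverage-based support check of a candidate estimate
#'
#' A candidate bin is accepted only if the tag windows supporting it cover
#' enough of both strings. With `m* = Amin - k + 1`, the estimate is
#' accepted when at least `m*` distinct supporting windows are observed for
#' each string, or `m* + 1` for one and `m* - 1` for the other. Failing
#' that, if both counts are at least `m* - 1` and a neighbouring bin
#' (`db - 1` or `db + 1`) occurred with at least `m* - 1` and `m*`
#' supporting windows for the two strings (in either assignment), the
#' estimate is still accepted — again a concession to plus/minus 1 Da
#' deconvolution errors. Support is counted as distinct k-mer start
#' positions per string: a window counts once however many spectra echo it.
#'
#' @param hist A [bin_differences()] result carrying window provenance
#'   (i.e. produced from [string_convolution()]).
#' @param db The candidate binned difference.
#' @param params A [stitch_params()] object.
#' @return A list: `accepted`, `n1`, `n2` (support counts for the candidate
#'   bin), `m_star`, `via_neighbor`.
#' @export
support_check <- function(hist, db, params = stitch_params()) {
  m_star <- params$amin - params$k + 1L
  n <- support_counts(hist, db)
  n1 <- n[["n1"]]; n2 <- n[["n2"]]
  direct <- (n1 >= m_star && n2 >= m_star) ||
    (n1 >= m_star + 1L && n2 >= m_star - 1L) ||
    (n2 >= m_star + 1L && n1 >= m_star - 1L)
  via_neighbor <- FALSE
  accepted <- direct
  if (!accepted && n1 >= m_star - 1L && n2 >= m_star - 1L) {
    bins <- unique(hist$binned)
    for (nb in c(db - 1, db + 1)) {
      if (!nb %in% bins) next
      m <- support_counts(hist, nb)
      if ((m[["n1"]] >= m_star - 1L && m[["n2"]] >= m_star) ||
          (m[["n1"]] >= m_star && m[["n2"]] >= m_star - 1L)) {
        via_neighbor <- TRUE
        accepted <- TRUE
        break
      }
    }
  }
  list(accepted = accepted, n1 = n1, n2 = n2, m_star = m_star,
       via_neighbor = via_neighbor)
}

#' Estimate the gap mass between two sequence fragments
#'
#' Tests the hypothesis that `s1` and `s2` are disjoint fragments of one
#' protein, with `s1` first, and if accepted reports the estimated
#' monoisotopic mass of the subsequence separating them: string
#' convolution, scaling/binning, candidate selection and the coverage
#' support check, in that order. A single candidate bin is examined; if it
#' fails support, the hypothesis is rejected.
#'
#' @param tags A tag tibble.
#' @param s1,s2 Amino-acid strings (length >= `k`).
#' @param params A [stitch_params()] object.
#' @return A one-row tibble of class `gap_estimate` with columns `s1`,
#'   `s2`, `estimate` (Da), `binned`, `multiplicity`, `score`, `support1`,
#'   `support2`, `via_neighbor`, `n_contrib`; the binned histogram of
#'   candidate bins is attached as attribute `"bins"` for auditing.
#'   `NULL` when the hypothesis is rejected.
#' @examples
#' \donttest{
#' prot <- simulate_protein(120, seed = 7)
#' sp <- simulate_spectra(prot, sim_config(n_spectra = 40, seed = 7))
#' tags <- generate_tags(sp$spectra)
#' estimate_gap(tags, substr(prot, 10, 25), substr(prot, 32, 47))
#' }
#' @export
estimate_gap <- function(tags, s1, s2, params = stitch_params()) {
  conv <- string_convolution(tags, s1, s2, params)
  if (nrow(conv) == 0L) return(NULL)
  hist <- bin_differences(conv, h = params$h)
  cand <- select_candidate(hist, params)
  if (is.null(cand)) return(NULL)
  sup <- support_check(hist, cand$d_hat_b, params)
  if (!sup$accepted) return(NULL)
  out <- tibble::tibble(
    s1 = s1, s2 = s2,
    estimate = cand$d_hat, binned = cand$d_hat_b,
    multiplicity = cand$multiplicity, score = cand$score,
    support1 = sup$n1, support2 = sup$n2,
    via_neighbor = sup$via_neighbor,
    n_contrib = nrow(conv)
  )
  attr(out, "bins") <- bin_multiplicities(hist)
  class(out) <- c("gap_estimate", class(out))
  out
}

#' Write a gap-estimation audit report
#'
#' Serializes a [estimate_gap()] result — inputs, candidate bins with
#' multiplicities, the accepted estimate and its support counts — as JSON.
#'
#' @param est A `gap_estimate`.
#' @param path Output file; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
gap_report <- function(est, path = NULL) {
  stopifnot(inherits(est, "gap_estimate"))
  payload <- list(
    s1 = est$s1, s2 = est$s2,
    estimate = est$estimate, binned = est$binned,
    multiplicity = est$multiplicity, score = est$score,
    support = c(est$support1, est$support2),
    via_neighbor = est$via_neighbor,
    n_contributions = est$n_contrib,
    bins = attr(est, "bins")
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
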