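empty_conv <- function() {
  tibble::tibble(
    difference = numeric(0), win1 = integer(0), win2 = integer(0),
    orientation = character(0), spectrum_id1 = character(0),
    spectrum_id2 = character(0)
  )
}

#' Tag convolution of two k-mers
#'
#' Considers all pairs `(t1, t2)` of tags with sequences `w1` and `w2` and
#' records the offset difference `o(t2) - o(t1)` of each pair. In the
#' top-down default only tags from the same spectrum pair up; offsets of
#' different spectra are not on a common scale there. Differences are kept
#' exact (raw); grouping into a histogram is deferred to
#' [bin_differences()].
#'
#' @param tags A tag tibble (`spectrum_id`, `sequence`, `offset`).
#' @param w1,w2 k-mers (equal length).
#' @param same_spectrum_only Restrict to pairs from one spectrum.
#' @return A contribution tibble, one row per contributing tag pair, with
#'   columns `difference`, `spectrum_id1`, `spectrum_id2`. Summarize with
#'   [tally_differences()].
#' @export
tag_convolution <- function(tags, w1, w2, same_spectrum_only = TRUE) {
  stopifnot(nchar(w1) == nchar(w2))
  t1 <- tags[tags$sequence == w1, ]
  t2 <- tags[tags$sequence == w2, ]
  if (nrow(t1) == 0L || nrow(t2) == 0L) {
    return(empty_conv()[, c("difference", "spectrum_id1", "spectrum_id2")])
  }
  a <- tibble::tibble(spectrum_id1 = t1$spectrum_id, offset1 = t1$offset)
  b <- tibble::tibble(spectrum_id2 = t2$spectrum_id, offset2 = t2$offset)
  pairs <- if (same_spectrum_only) {
    dplyr::inner_join(a, b, by = c(spectrum_id1 = "spectrum_id2"),
                      relationship = "many-to-many") |>
      dplyr::mutate(spectrum_id2 = .data$spectrum_id1)
  } else {
    dplyr::cross_join(a, b)
  }
  tibble::tibble(
    difference = pairs$offset2 - pairs$offset1,
    spectrum_id1 = pairs$spectrum_id1,
    spectrum_id2 = pairs$spectrum_id2
  )
}

#' Shift a set of offset differences
#'
#' Adds `delta` to every raw difference, preserving multiplicities (rows).
#'
#' @param conv A contribution tibble (or any tibble with a `difference`
#'   column).
#' @param delta Shift (Da).
#' @return The shifted tibble.
#' @export
shift_differences <- function(conv, delta) {
  conv$difference <- conv$difference + delta
  conv
}

#' Tally raw differences into multiplicities
#'
#' @param conv A contribution tibble.
#' @return A tibble with columns `difference` and `multiplicity`, grouping
#'   exactly-equal raw differences, sorted by difference.
#' @export
tally_differences <- function(conv) {
  conv |>
    dplyr::count(.data$difference, name = "multiplicity") |>
    dplyr::arrange(.data$difference)
}

#' Dump tallied offset differences as TSV
#'
#' Writes the (difference, multiplicity) table of a contribution tibble for
#' inspection or external plotting.
#'
#' @param conv A contribution tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_differences <- function(conv, path) {
  utils::write.table(tally_differences(conv), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

kmer_windows <- function(s, k) {
  n <- nchar(s)
  if (n < k) {
    return(tibble::tibble(win = integer(0), kmer = character(0)))
  }
  starts <- seq_len(n - k + 1L)
  tibble::tibble(
    win = starts,
    kmer = vapply(starts, function(i) substr(s, i, i + k - 1L),
                  character(1L))
  )
}

# one directed half of the string convolution: tag pairs matching k-mers of
# sa and sb, each shifted by -Mass(sa from the k-mer on) - Mass(sb before
# the k-mer)
conv_half <- function(tags, sa, sb, k, same_spectrum_only) {
  ka <- kmer_windows(sa, k)
  kb <- kmer_windows(sb, k)
  ka$shift_a <- -vapply(ka$win, function(i) {
    sequence_mass(substr(sa, i, nchar(sa)))
  }, numeric(1L))
  kb$shift_b <- -vapply(kb$win, function(j) {
    sequence_mass(substr(sb, 1L, j - 1L))
  }, numeric(1L))
  a <- dplyr::inner_join(tags, ka, by = c(sequence = "kmer"),
                         relationship = "many-to-many")
  b <- dplyr::inner_join(tags, kb, by = c(sequence = "kmer"),
                         relationship = "many-to-many")
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty_conv())
  a <- tibble::tibble(spectrum_id1 = a$spectrum_id, offset1 = a$offset,
                      wina = a$win, shift_a = a$shift_a)
  b <- tibble::tibble(spectrum_id2 = b$spectrum_id, offset2 = b$offset,
                      winb = b$win, shift_b = b$shift_b)
  pairs <- if (same_spectrum_only) {
    dplyr::inner_join(a, b, by = c(spectrum_id1 = "spectrum_id2"),
                      relationship = "many-to-many") |>
      dplyr::mutate(spectrum_id2 = .data$spectrum_id1)
  } else {
    dplyr::cross_join(a, b)
  }
  tibble::tibble(
    difference = pairs$offset2 - pairs$offset1 + pairs$shift_a +
      pairs$shift_b,
    win1 = pairs$wina, win2 = pairs$winb,
    orientation = NA_character_,
    spectrum_id1 = pairs$spectrum_id1, spectrum_id2 = pairs$spectrum_id2
  )
}

#' String convolution of two sequence fragments
#'
#' Generalizes tag convolution from k-mers to whole strings. Every pair of
#' k-mer windows, one from `s1` and one from `s2`, contributes its tag
#' convolution shifted by minus the mass of `s1` from the window on and
#' minus the mass of `s2` before the window, so that a tag pair bridging
#' two genuine fragments of one protein contributes the mass of the
#' subsequence separating them. The analogous contributions for the
#' reversed pair (`reverse(s2)`, `reverse(s1)`) — which arise from the
#' suffix-type (reflected) ion series — are accumulated as well and merged.
#' The result is symmetric: `string_convolution(tags, s1, s2)` equals
#' `string_convolution(tags, reverse(s2), reverse(s1))` as a multiset.
#'
#' @param tags A tag tibble.
#' @param s1,s2 Amino-acid strings, each of length >= `k`.
#' @param params A [stitch_params()] object.
#' @return A contribution tibble with one row per contributing tag pair:
#'   `difference` (Da), `win1`/`win2` (k-mer start positions in `s1`/`s2`),
#'   `orientation` (`"fwd"` or `"rev"`), `spectrum_id1`, `spectrum_id2`.
#'   Total multiplicity of a difference = its number of rows.
#' @export
string_convolution <- function(tags, s1, s2, params = stitch_params()) {
  k <- params$k
  stopifnot(nchar(s1) >= k, nchar(s2) >= k)
  fwd <- conv_half(tags, s1, s2, k, params$same_spectrum_only)
  fwd$orientation <- rep("fwd", nrow(fwd))
  rev <- conv_half(tags, reverse_sequence(s2), reverse_sequence(s1), k,
                   params$same_spectrum_only)
  # map window positions in the reversed strings back onto s1/s2
  if (nrow(rev) > 0L) {
    f <- nchar(s2); e <- nchar(s1)
    rev <- tibble::tibble(
      difference = rev$difference,
      win1 = e - rev$win2 - k + 2L,
      win2 = f - rev$win1 - k + 2L,
      orientation = "rev",
      spectrum_id1 = rev$spectrum_id1, spectrum_id2 = rev$spectrum_id2
    )
  } else {
    rev$orientation <- character(0)
  }
  out <- dplyr::bind_rows(fwd, rev)
  attr(out, "s1") <- s1
  attr(out, "s2") <- s2
  out
}

#' Validate one position of a de novo sequence
#'
#' Computes the string convolution of the prefix before position `i` and
#' the suffix after it, and reports the dominant binned difference together
#' with its margin over the runner-up. For a correct sequence the dominant
#' difference matches the mass of the residue at `i`; the caller judges
#' whether the margin is convincing (the procedure reports, it does not
#' decide).
#'
#' @param tags A tag tibble. For bottom-up style data pass params with
#'   `same_spectrum_only = FALSE`.
#' @param s Candidate amino-acid sequence.
#' @param i Position to check, with `k < i <= nchar(s) - k`.
#' @param params A [stitch_params()] object.
#' @return A one-row tibble: `top` (representative raw difference of the
#'   dominant bin, Da), `binned`, `multiplicity`, `margin` (ratio of top to
#'   runner-up binned multiplicity, `Inf` if there is no runner-up), and
#'   `residue_mass` of `s[i]` for reference. `NULL` when the convolution is
#'   empty.
#' @export
validate_position <- function(tags, s, i, params = stitch_params()) {
  n <- nchar(s)
  k <- params$k
  if (!(i > k && i <= n - k)) {
    stop("position i must satisfy k < i <= nchar(s) - k", call. = FALSE)
  }
  conv <- string_convolution(tags, substr(s, 1L, i - 1L),
                             substr(s, i + 1L, n), params)
  if (nrow(conv) == 0L) return(NULL)
  hist <- bin_differences(conv, h = params$h)
  bins <- dplyr::count(hist, .data$binned, name = "multiplicity") |>
    dplyr::arrange(dplyr::desc(.data$multiplicity), .data$binned)
  top_bin <- bins$binned[1L]
  in_bin <- hist[hist$binned == top_bin, ]
  sc <- dplyr::count(in_bin, .data$scaled, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$scaled)
  tibble::tibble(
    top = sc$scaled[1L] / 10^params$h,
    binned = top_bin,
    multiplicity = bins$multiplicity[1L],
    margin = if (nrow(bins) > 1L) {
      bins$multiplicity[1L] / bins$multiplicity[2L]
    } else {
      Inf
    },
    residue_mass = residue_mass(substr(s, i, i))
  )
}
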