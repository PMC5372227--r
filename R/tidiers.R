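#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gapped path
#'
#' @param x A `gapped_path`.
#' @param ... Unused.
#' @return The segment table as a plain tibble: one row per fragment or
#'   gap, with orientation flags, mass offsets, gap estimates, scores and
#'   support counts.
#' @method tidy gapped_path
#' @export
tidy.gapped_path <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "gapped_path")
  out
}

#' Summarize a gapped path
#'
#' @param x A `gapped_path`.
#' @param ... Unused.
#' @return A one-row tibble: fragment and gap counts, total fragment
#'   residues, summed gap mass and total path mass (Da).
#' @method glance gapped_path
#' @export
glance.gapped_path <- function(x, ...) {
  fr <- x[x$type == "fragment", ]
  tibble::tibble(
    n_fragments = nrow(fr),
    n_gaps = sum(x$type == "gap"),
    n_residues = sum(nchar(fr$sequence)),
    gap_mass = sum(x$gap[x$type == "gap"]),
    total_mass = path_mass(x),
    sources = paste(fr$source, collapse = "+")
  )
}

#' Tidy an assembly
#'
#' @param x A `gap_assembly`.
#' @param ... Unused.
#' @return All paths' segment tables stacked, with a `path` index column.
#' @method tidy gap_assembly
#' @export
tidy.gap_assembly <- function(x, ...) {
  dplyr::bind_rows(lapply(x, tidy), .id = "path") |>
    dplyr::mutate(path = as.integer(.data$path))
}

#' Summarize an assembly
#'
#' @param x A `gap_assembly`.
#' @param ... Unused.
#' @return One row per gapped path (see [glance.gapped_path()]).
#' @method glance gap_assembly
#' @export
glance.gap_assembly <- function(x, ...) {
  dplyr::bind_rows(lapply(x, glance), .id = "path") |>
    dplyr::mutate(path = as.integer(.data$path))
}

#' Plot a binned difference histogram
#'
#' Bar chart of binned-difference multiplicities, the quantity from which
#' candidate gap estimates are selected.
#'
#' @param object A [bin_differences()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot binned_differences
#' @export
autoplot.binned_differences <- function(object, ...) {
  mu <- bin_multiplicities(object)
  ggplot2::ggplot(mu, ggplot2::aes(x = .data$binned,
                                   y = .data$multiplicity)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "binned offset difference (Da)", y = "multiplicity")
}

#' Plot a gapped path
#'
#' Draws fragments as boxes on the mass-offset axis and gaps as labeled
#' dashed connectors.
#'
#' @param object A `gapped_path`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gapped_path
#' @export
autoplot.gapped_path <- function(object, ...) {
  fr <- tidy(object) |>
    dplyr::filter(.data$type == "fragment") |>
    dplyr::mutate(
      xend = .data$offset +
        sequence_mass(oriented_sequence(.data$sequence, .data$orientation))
    )
  gp <- tidy(object) |> dplyr::filter(.data$type == "gap")
  p <- ggplot2::ggplot(fr) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$offset, xmax = .data$xend,
                                    ymin = 0.4, ymax = 0.6),
                       fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(x = (.data$offset + .data$xend) / 2,
                                    y = 0.7, label = .data$source),
                       size = 3) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(0, 1)) +
    ggplot2::labs(x = "mass offset (Da)")
  if (nrow(gp) > 0L) {
    seg <- tibble::tibble(
      x = fr$xend[-nrow(fr)], xend = fr$offset[-1L],
      label = sprintf("%.2f", gp$gap)
    )
    p <- p +
      ggplot2::geom_segment(
        data = seg,
        ggplot2::aes(x = .data$x, xend = .data$xend, y = 0.5, yend = 0.5),
        linetype = "dashed"
      ) +
      ggplot2::geom_text(
        data = seg,
        ggplot2::aes(x = (.data$x + .data$xend) / 2, y = 0.35,
                     label = .data$label),
        size = 3
      )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
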