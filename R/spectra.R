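#' Build a peak-list tibble
#'
#' Constructs the flat tibble representation of one or more deconvoluted
#' spectra used throughout the package: one row per neutral monoisotopic
#' fragment-mass peak.
#'
#' @param spectrum_id Spectrum identifier (recycled).
#' @param precursor_mass Neutral monoisotopic precursor mass (Da, recycled).
#' @param mass Numeric vector of neutral peak masses (Da), > 0.
#' @param intensity Numeric vector of abundances (arbitrary units), >= 0.
#' @param activation Fragmentation label (e.g. "CID", "HCD", "ETD");
#'   informational only.
#' @param reflected Logical; marks peaks created by precursor reflection.
#' @return A tibble with columns `spectrum_id`, `precursor_mass`,
#'   `activation`, `mass`, `intensity`, `reflected`, sorted by
#'   (`spectrum_id`, `mass`).
#' @examples
#' spectrum_tbl("s1", 1000, mass = c(300, 700), intensity = c(10, 20))
#' @export
spectrum_tbl <- function(spectrum_id, precursor_mass, mass, intensity = 1,
                         activation = NA_character_, reflected = FALSE) {
  stopifnot(all(mass > 0), all(intensity >= 0))
  tibble::tibble(
    spectrum_id = as.character(spectrum_id),
    precursor_mass = as.numeric(precursor_mass),
    activation = as.character(activation),
    mass = as.numeric(mass),
    intensity = as.numeric(intensity),
    reflected = as.logical(reflected)
  ) |>
    dplyr::arrange(.data$spectrum_id, .data$mass)
}

#' Read deconvoluted spectra in msalign format
#'
#' Parses the text format emitted by common top-down deconvolution tools:
#' `BEGIN IONS` / `END IONS` blocks with `KEY=VALUE` headers (`ID`, `SCANS`,
#' `ACTIVATION`, `PRECURSOR_MASS`, ...) followed by one
#' `mass<TAB>intensity<TAB>charge` line per peak. The charge column, if
#' present, is ignored: masses are already neutral. Blocks without a
#' precursor mass are skipped with a warning.
#'
#' @param path Path to an msalign file.
#' @return A peak tibble as produced by [spectrum_tbl()]; zero rows for an
#'   empty file.
#' @export
read_msalign <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed msalign file: unbalanced BEGIN IONS/END IONS",
         call. = FALSE)
  }
  skipped <- 0L
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    lineno <- (starts[b] + 1L):(ends[b] - 1L)
    is_header <- grepl("=", block, fixed = TRUE)
    headers <- block[is_header]
    keys <- sub("=.*$", "", headers)
    vals <- sub("^[^=]*=", "", headers)
    id <- if ("ID" %in% keys) vals[match("ID", keys)] else as.character(b)
    activation <- if ("ACTIVATION" %in% keys) {
      vals[match("ACTIVATION", keys)]
    } else {
      NA_character_
    }
    if (!"PRECURSOR_MASS" %in% keys) {
      skipped <- skipped + 1L
      next
    }
    prec <- suppressWarnings(as.numeric(vals[match("PRECURSOR_MASS", keys)]))
    if (is.na(prec)) {
      skipped <- skipped + 1L
      next
    }
    peak_lines <- block[!is_header & nzchar(trimws(block))]
    peak_nos <- lineno[!is_header & nzchar(trimws(block))]
    if (length(peak_lines) == 0L) {
      out[[b]] <- spectrum_tbl(id, prec, numeric(0), numeric(0), activation)
      next
    }
    fields <- strsplit(trimws(peak_lines), "[ \t]+")
    mass <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
    intensity <- suppressWarnings(
      as.numeric(vapply(fields, function(f) {
        if (length(f) >= 2L) f[2L] else "1"
      }, ""))
    )
    if (anyNA(mass)) {
      stop("unparsable peak line at line ", peak_nos[which(is.na(mass))[1L]],
           " of ", path, call. = FALSE)
    }
    intensity[is.na(intensity)] <- 1
    out[[b]] <- spectrum_tbl(id, prec, mass, intensity, activation)
  }
  if (skipped > 0L) {
    warning(skipped, " spectrum block(s) without a precursor mass skipped",
            call. = FALSE)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- spectrum_tbl(character(0), numeric(0), numeric(0), numeric(0))
  }
  message(sprintf("read %d spectra (%d skipped) from %s",
                  length(starts) - skipped, skipped, path))
  res
}

#' Read a plain two-column peak list
#'
#' A minimal alternative to [read_msalign()] for `mass<TAB>intensity` text
#' files holding a single spectrum; the precursor mass must be supplied.
#'
#' @param path Path to a whitespace-separated `mass intensity` file.
#' @param precursor_mass Neutral precursor mass (Da).
#' @param spectrum_id Identifier for the spectrum.
#' @return A peak tibble.
#' @export
read_peaks_tsv <- function(path, precursor_mass, spectrum_id = "1") {
  x <- utils::read.table(path, header = FALSE,
                         col.names = c("mass", "intensity"))
  spectrum_tbl(spectrum_id, precursor_mass, x$mass, x$intensity)
}

#' Write spectra in msalign format
#'
#' @param spectra A peak tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msalign <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in unique(spectra$spectrum_id)) {
    s <- spectra[spectra$spectrum_id == id, ]
    writeLines(c(
      "BEGIN IONS",
      paste0("ID=", id),
      if (!is.na(s$activation[1L])) paste0("ACTIVATION=", s$activation[1L]),
      sprintf("PRECURSOR_MASS=%.6f", s$precursor_mass[1L]),
      sprintf("%.6f\t%.2f\t1", s$mass, s$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Eliminate water-loss peaks
#'
#' Removes every peak `p` for which the same spectrum contains a parent peak
#' `q` exactly one water above it (within `tol`) with intensity at least
#' that of `p`. The intensity condition keeps the rule from deleting real
#' signal: a putative loss that is more intense than its putative parent is
#' left alone.
#'
#' @param spectra A peak tibble.
#' @param tol Mass tolerance (Da) on the water offset; defaults to 8 mDa
#'   (2 * epsilon at the default epsilon).
#' @return The peak tibble with water-loss peaks removed.
#' @export
remove_water_loss <- function(spectra, tol = 0.008) {
  stopifnot(tol > 0)
  if (nrow(spectra) == 0L) return(spectra)
  drop_one <- function(s) {
    n <- nrow(s)
    if (n < 2L) return(s)
    s <- s[order(s$mass), ]
    m <- s$mass
    lo <- findInterval(m + water_mass - tol, m)
    hi <- findInterval(m + water_mass + tol, m)
    keep <- rep(TRUE, n)
    for (i in which(hi > lo)) {
      cand <- (lo[i] + 1L):hi[i]
      if (any(s$intensity[cand] >= s$intensity[i])) keep[i] <- FALSE
    }
    s[keep, ]
  }
  parts <- split(spectra, spectra$spectrum_id)
  dplyr::bind_rows(lapply(parts, drop_one))
}

#' Reflect peaks about the precursor mass
#'
#' For every peak `p` adds a reflected copy at `precursor_mass - mass(p)`
#' with the same intensity, so that prefix- and suffix-type fragment series
#' reinforce each other. No ion-type constant is applied: any constant
#' common to a tag pair cancels in the offset differences consumed
#' downstream. Reflected peaks with non-positive mass are discarded, and
#' peaks closer than 1e-5 Da are merged keeping the maximum intensity.
#'
#' @param spectra A peak tibble with known precursor masses.
#' @return The augmented peak tibble; added peaks carry `reflected = TRUE`.
#' @export
reflect_peaks <- function(spectra) {
  if (nrow(spectra) == 0L) return(spectra)
  if (anyNA(spectra$precursor_mass)) {
    stop("reflect_peaks: precursor mass missing", call. = FALSE)
  }
  refl_one <- function(s) {
    if (nrow(s) == 0L) return(s)
    r <- s
    r$mass <- s$precursor_mass - s$mass
    r$reflected <- TRUE
    r <- r[r$mass > 0, ]
    all <- dplyr::bind_rows(s, r)
    all <- all[order(all$mass), ]
    # merge runs of near-identical masses (self-reflections, double passes),
    # keeping the most intense member; a merge with a real peak clears the
    # reflected flag
    repeat {
      close <- which(diff(all$mass) <= 1e-5)
      if (length(close) == 0L) break
      # process non-overlapping pairs only; loop again if runs were longer
      close <- close[c(TRUE, diff(close) > 1L)]
      a <- close; b <- close + 1L
      win_b <- all$intensity[b] > all$intensity[a]
      keep_idx <- ifelse(win_b, b, a)
      drop_idx <- ifelse(win_b, a, b)
      all$reflected[keep_idx] <- all$reflected[a] & all$reflected[b]
      all <- all[-drop_idx, ]
    }
    all
  }
  parts <- split(spectra, spectra$spectrum_id)
  dplyr::bind_rows(lapply(parts, refl_one))
}

#' Preprocess deconvoluted spectra
#'
#' Applies water-loss elimination followed by peak reflection, each
#' switchable through the parameter object. Losses are removed before
#' reflection so that loss artifacts are not duplicated into the reflected
#' series.
#'
#' @param spectra A peak tibble.
#' @param params A [stitch_params()] object.
#' @return The preprocessed peak tibble.
#' @export
preprocess_spectra <- function(spectra, params = stitch_params()) {
  if (params$water_loss) {
    spectra <- remove_water_loss(spectra, tol = 2 * params$epsilon)
  }
  if (params$reflect) spectra <- reflect_peaks(spectra)
  spectra
}
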