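#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe
#' the reference simulation used throughout the package: a 300-residue
#' protein interrogated by 200 top-down spectra whose fragment series cover
#' a contiguous window of 50-100% of the sequence, 80% cleavage-site
#' coverage, 1 mDa Gaussian mass error (well below the 4 mDa matching
#' tolerance), no 1 Da deconvolution errors, and four 16-residue fragment
#' strings separated by gaps of 5, 8 and 11 residues.
#'
#' @param protein_length Protein length (residues).
#' @param n_spectra Number of simulated MS/MS spectra.
#' @param coverage Probability that a cleavage site yields a fragment peak.
#' @param window_frac Two numbers: each spectrum's window length is drawn
#'   uniformly between these fractions of the protein length.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model.
#' @param mass_error_sd Gaussian peak mass error (Da); keep well below
#'   `epsilon`.
#' @param p_da_error Per-peak probability of an exact plus/minus 1 Da
#'   monoisotopic-assignment error (random sign), emulating deconvolution
#'   artifacts.
#' @param fragment_lengths Lengths (residues) of the fragment strings to
#'   cut from the protein.
#' @param gap_lengths Lengths (residues) of the subsequences separating
#'   consecutive fragments; one fewer than `fragment_lengths`.
#' @param flip_prob Probability that a fragment string is emitted reversed.
#' @param seed Integer seed fixing all downstream randomness.
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(protein_length = 300L,
                       n_spectra = 200L,
                       coverage = 0.8,
                       window_frac = c(0.5, 1),
                       intensity_meanlog = log(1e4),
                       intensity_sdlog = 1,
                       mass_error_sd = 0.001,
                       p_da_error = 0,
                       fragment_lengths = c(16L, 16L, 16L, 16L),
                       gap_lengths = c(5L, 8L, 11L),
                       flip_prob = 0,
                       seed = 1L) {
  stopifnot(
    protein_length >= 1L, n_spectra >= 0L,
    coverage >= 0, coverage <= 1,
    length(window_frac) == 2L, window_frac[1L] <= window_frac[2L],
    window_frac[1L] > 0, window_frac[2L] <= 1,
    mass_error_sd >= 0, p_da_error >= 0, p_da_error <= 1,
    length(gap_lengths) == length(fragment_lengths) - 1L,
    flip_prob >= 0, flip_prob <= 1
  )
  structure(
    list(
      protein_length = as.integer(protein_length),
      n_spectra = as.integer(n_spectra), coverage = coverage,
      window_frac = window_frac, intensity_meanlog = intensity_meanlog,
      intensity_sdlog = intensity_sdlog, mass_error_sd = mass_error_sd,
      p_da_error = p_da_error,
      fragment_lengths = as.integer(fragment_lengths),
      gap_lengths = as.integer(gap_lengths), flip_prob = flip_prob,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a random protein sequence
#'
#' Uniform over the 20 standard residues; deterministic per seed.
#'
#' @param length Number of residues.
#' @param seed Integer seed.
#' @return A single amino-acid string.
#' @export
simulate_protein <- function(length, seed = 1L) {
  stopifnot(length >= 1L)
  set.seed(seed)
  paste(sample(names(.residue_mass_table)[names(.residue_mass_table) != "I"],
               length, replace = TRUE), collapse = "")
}

#' Simulate deconvoluted top-down spectra
#'
#' Each spectrum covers a contiguous window of the protein; its peaks are
#' the cumulative residue-mass sums from the window start (a prefix-type
#' neutral fragment series; the complementary suffix series is produced by
#' peak reflection during preprocessing), with each cleavage site emitted
#' with probability `coverage`, Gaussian mass error, and an optional exact
#' plus/minus 1 Da shift per peak. The precursor mass is the window mass
#' plus water. Peaks carry no ion-type constant: offset differences cancel
#' any constant common to a tag pair, and this keeps ground truth exact.
#'
#' @param protein Amino-acid string.
#' @param config A [sim_config()].
#' @return A list: `spectra` (peak tibble) and `truth` (tibble with one row
#'   per spectrum: `spectrum_id`, `window_start`, `window_end`).
#' @export
simulate_spectra <- function(protein, config = sim_config()) {
  set.seed(config$seed + 1L)
  n <- nchar(protein)
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  rmass <- residue_mass(res)
  wmin <- max(2L, floor(config$window_frac[1L] * n))
  wmax <- max(wmin, floor(config$window_frac[2L] * n))
  out <- vector("list", config$n_spectra)
  truth <- vector("list", config$n_spectra)
  for (i in seq_len(config$n_spectra)) {
    w <- sample(wmin:wmax, 1L)
    start <- sample(seq_len(n - w + 1L), 1L)
    end <- start + w - 1L
    masses <- cumsum(rmass[start:end])
    window_mass <- masses[w]
    sites <- seq_len(w - 1L) # cleavage after each residue but the last
    keep <- sites[stats::runif(length(sites)) < config$coverage]
    id <- sprintf("sim%04d", i)
    truth[[i]] <- tibble::tibble(spectrum_id = id, window_start = start,
                                 window_end = end)
    if (length(keep) == 0L) {
      out[[i]] <- NULL
      next
    }
    mz <- masses[keep] +
      stats::rnorm(length(keep), sd = config$mass_error_sd)
    if (config$p_da_error > 0) {
      hit <- stats::runif(length(mz)) < config$p_da_error
      mz[hit] <- mz[hit] + sample(c(-1, 1), sum(hit), replace = TRUE)
    }
    out[[i]] <- spectrum_tbl(
      id,
      precursor_mass = window_mass + water_mass +
        stats::rnorm(1L, sd = config$mass_error_sd),
      mass = mz,
      intensity = stats::rlnorm(length(mz), config$intensity_meanlog,
                                config$intensity_sdlog),
      activation = "HCD"
    )
  }
  spectra <- dplyr::bind_rows(out)
  if (nrow(spectra) == 0L) {
    spectra <- spectrum_tbl(character(0), numeric(0), numeric(0),
                            numeric(0))
  }
  list(spectra = spectra, truth = dplyr::bind_rows(truth))
}

#' Cut fragment strings from a protein with known gaps
#'
#' Cuts non-overlapping substrings separated by the configured gap lengths,
#' optionally reversing each with probability `flip_prob`, and records the
#' ground truth: positions, orientations, and the true separating masses
#' (the residue-mass sums of the separating subsequences).
#'
#' @param protein Amino-acid string.
#' @param config A [sim_config()].
#' @return A list: `strings` (named character vector, names are input ids),
#'   `fragments` (tibble `id`, `start`, `end`, `orientation`, `sequence`),
#'   and `gaps` (tibble `after` (fragment index), `gap_seq`, `gap_mass`).
#' @export
simulate_fragment_strings <- function(protein, config = sim_config()) {
  set.seed(config$seed + 2L)
  n <- nchar(protein)
  fl <- config$fragment_lengths
  gl <- config$gap_lengths
  need <- sum(fl) + sum(gl)
  if (need > n) {
    stop("fragments plus gaps (", need, " residues) exceed protein length (",
         n, ")", call. = FALSE)
  }
  lead <- if (n - need > 0L) sample(0:(n - need), 1L) else 0L
  starts <- integer(length(fl))
  pos <- lead + 1L
  frs <- vector("list", length(fl))
  gaps <- vector("list", length(gl))
  for (i in seq_along(fl)) {
    starts[i] <- pos
    seq_i <- substr(protein, pos, pos + fl[i] - 1L)
    flip <- stats::runif(1L) < config$flip_prob
    frs[[i]] <- tibble::tibble(
      id = sprintf("F%02d", i), start = pos, end = pos + fl[i] - 1L,
      orientation = if (flip) "rev" else "fwd",
      sequence = if (flip) reverse_sequence(seq_i) else seq_i
    )
    pos <- pos + fl[i]
    if (i <= length(gl)) {
      gseq <- substr(protein, pos, pos + gl[i] - 1L)
      gaps[[i]] <- tibble::tibble(after = i, gap_seq = gseq,
                                  gap_mass = sequence_mass(gseq))
      pos <- pos + gl[i]
    }
  }
  fragments <- dplyr::bind_rows(frs)
  strings <- stats::setNames(fragments$sequence, fragments$id)
  list(strings = strings, fragments = fragments,
       gaps = dplyr::bind_rows(gaps))
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the spectra (msalign), the fragment strings (FASTA) and the
#' ground truth (JSON) of one simulation, exercising the same file formats
#' the command-line interface consumes.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @return Invisibly, a list with the paths written and the simulated
#'   objects.
#' @export
write_fixture <- function(dir, config = sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  protein <- simulate_protein(config$protein_length, config$seed)
  sim <- simulate_spectra(protein, config)
  frs <- simulate_fragment_strings(protein, config)
  msalign <- file.path(dir, "spectra.msalign")
  fasta <- file.path(dir, "fragments.fasta")
  truth <- file.path(dir, "truth.json")
  write_msalign(sim$spectra, msalign)
  writeLines(as.vector(rbind(paste0(">", names(frs$strings)),
                             unname(frs$strings))), fasta)
  jsonlite::write_json(
    list(protein = protein, fragments = frs$fragments, gaps = frs$gaps,
         windows = sim$truth),
    truth, auto_unbox = TRUE, digits = NA
  )
  invisible(list(msalign = msalign, fasta = fasta, truth = truth,
                 protein = protein, spectra = sim$spectra,
                 fragments = frs$fragments, gaps = frs$gaps,
                 strings = frs$strings))
}

#' Read fragment strings from FASTA or plain text
#'
#' @param path A FASTA file (headers become ids) or a one-sequence-per-line
#'   text file.
#' @return A named character vector of fragment strings.
#' @export
read_fragment_strings <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(character(0), NULL))
  if (startsWith(lines[1L], ">")) {
    hdr <- grepl("^>", lines)
    ids <- sub("^>\\s*", "", lines[hdr])
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, collapse = "",
                   FUN.VALUE = character(1L))
    return(stats::setNames(toupper(unname(seqs)), ids))
  }
  stats::setNames(toupper(lines), sprintf("S%03d", seq_along(lines)))
}
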