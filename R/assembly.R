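frag_row <- function(sequence, source, orientation = "fwd") {
  tibble::tibble(
    type = "fragment", sequence = sequence, orientation = orientation,
    source = source, offset = 0, gap = NA_real_, gap_binned = NA_real_,
    score = NA_integer_, support1 = NA_integer_, support2 = NA_integer_
  )
}

gap_row <- function(gap, gap_binned = round_half_away(gap),
                    score = NA_integer_, support1 = NA_integer_,
                    support2 = NA_integer_) {
  tibble::tibble(
    type = "gap", sequence = NA_character_, orientation = NA_character_,
    source = NA_character_, offset = NA_real_, gap = gap,
    gap_binned = gap_binned, score = as.integer(score),
    support1 = as.integer(support1), support2 = as.integer(support2)
  )
}

est_gap_row <- function(est) {
  gap_row(est$estimate, est$binned, est$score, est$support1, est$support2)
}

#' Create a single-fragment gapped path
#'
#' A gapped path is an alternation of sequence fragments (with orientation
#' flags and mass offsets relative to the path origin) and gaps annotated
#' with estimated masses. Paths are initialized from single input strings
#' and grown by [join_pair()] / [assemble_fragments()].
#'
#' @param sequence The fragment's amino-acid string, as supplied.
#' @param source Identifier of the input string (provenance).
#' @return A `gapped_path` (a segment tibble).
#' @export
gapped_path <- function(sequence, source = sequence) {
  as_gapped_path(frag_row(sequence, source))
}

as_gapped_path <- function(segments) {
  segments <- recompute_offsets(segments)
  class(segments) <- unique(c("gapped_path", class(segments)))
  segments
}

# fragment offsets: previous fragment offset + its (oriented) mass + the
# intervening gap estimate
recompute_offsets <- function(segments) {
  off <- 0
  for (i in seq_len(nrow(segments))) {
    if (segments$type[i] == "fragment") {
      segments$offset[i] <- off
      off <- off + sequence_mass(oriented_sequence(segments$sequence[i],
                                                   segments$orientation[i]))
    } else {
      off <- off + segments$gap[i]
    }
  }
  segments
}

oriented_sequence <- function(sequence, orientation) {
  ifelse(orientation == "rev", reverse_sequence(sequence), sequence)
}

#' Reverse a gapped path
#'
#' Segment order is reversed, every fragment's orientation flag is flipped,
#' gap annotations are kept, and offsets are recomputed from the new
#' origin.
#'
#' @param path A `gapped_path`.
#' @return The reversed `gapped_path`.
#' @export
reverse_path <- function(path) {
  segments <- path[rev(seq_len(nrow(path))), ]
  is_frag <- segments$type == "fragment"
  segments$orientation[is_frag] <-
    ifelse(segments$orientation[is_frag] == "fwd", "rev", "fwd")
  as_gapped_path(segments)
}

path_fragments <- function(path) path[path$type == "fragment", ]

# total mass of a path: oriented fragment masses plus gap estimates
path_mass <- function(path) {
  fr <- path_fragments(path)
  sum(sequence_mass(oriented_sequence(fr$sequence, fr$orientation))) +
    sum(path$gap[path$type == "gap"])
}

#' Try appending one gapped path to another
#'
#' Runs [estimate_gap()] on the last fragment of `g1` (as oriented in the
#' path) and the first fragment of `g2`; on acceptance returns
#' `g1 + gap + g2` with offsets recomputed, otherwise `NULL`.
#'
#' @param g1,g2 `gapped_path` objects.
#' @param tags A tag tibble.
#' @param params A [stitch_params()] object.
#' @return The merged `gapped_path`, or `NULL`.
#' @export
try_append <- function(g1, g2, tags, params = stitch_params()) {
  f1 <- path_fragments(g1)
  f2 <- path_fragments(g2)
  s1last <- oriented_sequence(f1$sequence[nrow(f1)],
                              f1$orientation[nrow(f1)])
  s2first <- oriented_sequence(f2$sequence[1L], f2$orientation[1L])
  if (nchar(s1last) < params$k || nchar(s2first) < params$k) return(NULL)
  est <- estimate_gap(tags, s1last, s2first, params)
  if (is.null(est)) return(NULL)
  as_gapped_path(dplyr::bind_rows(tibble::as_tibble(g1), est_gap_row(est),
                                  tibble::as_tibble(g2)))
}

#' Try embedding one gapped path into a gap of another
#'
#' Examines the gaps of `host` in order. A gap qualifies when its estimate
#' can accommodate the total mass of `guest` (within the ppm tolerance);
#' then the fragment immediately preceding the gap and the first fragment
#' of `guest` are tested with [estimate_gap()]. On acceptance the end
#' offset of the placed `guest` is compared against the start offset of the
#' fragment after the gap, at a relative tolerance of `eps_abs_ppm` parts
#' per million of the larger offset (offsets measured from the host
#' origin); if the guest does not overlap it, the guest is spliced in, the
#' original gap being split into the estimated leading gap and an
#' arithmetic trailing remainder (clamped at zero when within tolerance).
#' The first qualifying gap wins.
#'
#' @param host,guest `gapped_path` objects.
#' @param tags A tag tibble.
#' @param params A [stitch_params()] object.
#' @return The merged `gapped_path`, or `NULL`.
#' @export
try_embed <- function(host, guest, tags, params = stitch_params()) {
  gap_idx <- which(host$type == "gap")
  if (length(gap_idx) == 0L) return(NULL)
  guest_mass <- path_mass(guest)
  f2 <- path_fragments(guest)
  s2first <- oriented_sequence(f2$sequence[1L], f2$orientation[1L])
  if (nchar(s2first) < params$k) return(NULL)
  ppm <- params$eps_abs_ppm * 1e-6
  for (gi in gap_idx) {
    g <- host$gap[gi]
    if (g < guest_mass - ppm * max(g, guest_mass)) next
    sprime <- host[gi - 1L, ]
    s1 <- oriented_sequence(sprime$sequence, sprime$orientation)
    if (nchar(s1) < params$k) next
    est <- estimate_gap(tags, s1, s2first, params)
    if (is.null(est)) next
    # overlap check against the fragment after the gap, in host offsets
    o_end <- sprime$offset + sequence_mass(s1) + est$estimate + guest_mass
    o_start <- host$offset[gi + 1L]
    tol <- ppm * max(o_end, o_start)
    trailing <- g - est$estimate - guest_mass
    if (trailing < -tol) next
    merged <- dplyr::bind_rows(
      tibble::as_tibble(host[seq_len(gi - 1L), ]),
      est_gap_row(est),
      tibble::as_tibble(guest),
      gap_row(max(trailing, 0)),
      tibble::as_tibble(host[(gi + 1L):nrow(host), ])
    )
    return(as_gapped_path(merged))
  }
  NULL
}

#' Try joining two gapped paths in all four orientations
#'
#' Examines, in order, the pairs `(g1, g2)`, `(g1, rev g2)`, `(rev g1, g2)`
#' and `(rev g1, rev g2)`; for each, tries appending the second to the
#' first, then embedding the second into a gap of the first, then embedding
#' the first into a gap of the second. The first success is returned and
#' the remaining combinations are not considered.
#'
#' @param g1,g2 `gapped_path` objects.
#' @param tags A tag tibble.
#' @param params A [stitch_params()] object.
#' @return The merged `gapped_path`, or `NULL` after all four fail.
#' @export
join_pair <- function(g1, g2, tags, params = stitch_params()) {
  combos <- list(
    list(g1, g2),
    list(g1, reverse_path(g2)),
    list(reverse_path(g1), g2),
    list(reverse_path(g1), reverse_path(g2))
  )
  for (cb in combos) {
    m <- try_append(cb[[1L]], cb[[2L]], tags, params)
    if (is.null(m)) m <- try_embed(cb[[1L]], cb[[2L]], tags, params)
    if (is.null(m)) m <- try_embed(cb[[2L]], cb[[1L]], tags, params)
    if (!is.null(m)) return(m)
  }
  NULL
}

#' Assemble fragment strings into gapped paths
#'
#' Initializes one single-fragment path per input string, then repeatedly
#' scans path pairs in deterministic order (ascending index, inner index
#' ascending), merging on the first success via [join_pair()] and
#' restarting the scan; stops when a full scan yields no merge. Strings
#' shorter than `k` cannot carry tags and are passed through unmerged with
#' a warning.
#'
#' @param strings Character vector of fragment strings (or a data frame
#'   with columns `id` and `sequence`).
#' @param tags A tag tibble.
#' @param params A [stitch_params()] object.
#' @return A `gap_assembly`: list of `gapped_path` objects.
#' @export
assemble_fragments <- function(strings, tags, params = stitch_params()) {
  if (is.data.frame(strings)) {
    ids <- as.character(strings$id)
    seqs <- as.character(strings$sequence)
  } else {
    seqs <- as.character(strings)
    ids <- if (!is.null(names(strings))) names(strings) else
      sprintf("S%03d", seq_along(strings))
  }
  stopifnot(length(seqs) > 0L, !anyDuplicated(ids))
  short <- nchar(seqs) < params$k
  if (any(short)) {
    warning(sum(short), " input string(s) shorter than k passed through ",
            "unmerged", call. = FALSE)
  }
  paths <- purrr::map2(seqs, ids, gapped_path)
  mergeable <- !short
  repeat {
    merged_any <- FALSE
    n <- length(paths)
    if (n < 2L) break
    for (i in seq_len(n - 1L)) {
      if (!mergeable[i]) next
      for (j in (i + 1L):n) {
        if (!mergeable[j]) next
        m <- join_pair(paths[[i]], paths[[j]], tags, params)
        if (!is.null(m)) {
          paths[[i]] <- m
          paths[[j]] <- NULL
          mergeable <- mergeable[-j]
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }
  structure(paths, class = "gap_assembly", params = params)
}

#' Render a gapped path as text
#'
#' @param path A `gapped_path`.
#' @return A string such as `"SGATF -[1583.842]-> KEST"`; fragments used in
#'   reversed orientation are wrapped as `rev(...)`.
#' @export
path_string <- function(path) {
  parts <- character(nrow(path))
  for (i in seq_len(nrow(path))) {
    parts[i] <- if (path$type[i] == "fragment") {
      if (path$orientation[i] == "rev") {
        paste0("rev(", path$sequence[i], ")")
      } else {
        path$sequence[i]
      }
    } else {
      sprintf("-[%.4f]->", path$gap[i])
    }
  }
  paste(parts, collapse = " ")
}

#' @export
print.gapped_path <- function(x, ...) {
  cat("<gapped_path> ", path_string(x), "\n", sep = "")
  cat(sprintf("  %d fragment(s), %d gap(s), total mass %.4f Da\n",
              sum(x$type == "fragment"), sum(x$type == "gap"),
              path_mass(x)))
  invisible(x)
}

#' @export
print.gap_assembly <- function(x, ...) {
  cat("<gap_assembly> ", length(x), " gapped path(s)\n", sep = "")
  for (p in x) cat("  ", path_string(p), "\n", sep = "")
  invisible(x)
}

#' Write an assembly as JSON
#'
#' Serializes every path with its fragments, orientations, offsets, gap
#' estimates, scores, support counts and input-string provenance.
#'
#' @param assembly A `gap_assembly`.
#' @param path Output file; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
write_assembly <- function(assembly, path = NULL) {
  payload <- lapply(assembly, function(p) tibble::as_tibble(p))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
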