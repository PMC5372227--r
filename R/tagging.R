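#' Build a spectrum graph
#'
#' One vertex per peak, scored by peak intensity; a directed edge from a
#' lower-mass peak `u` to a higher-mass peak `w` labeled with residue `r`
#' whenever `mass(w) - mass(u)` matches the monoisotopic mass of `r` within
#' `2 * epsilon`. Isoleucine/leucine edges carry the single canonical label
#' `"L"`. The graph is acyclic by construction (edges increase in mass).
#'
#' @param peaks A tibble with columns `mass` and `intensity` for a single
#'   spectrum (extra columns ignored).
#' @param epsilon Mass tolerance epsilon (Da); edges compare at
#'   `2 * epsilon`.
#' @return A `spectrum_graph`: list with `peaks` (tibble, sorted by mass)
#'   and `edges` (tibble with columns `from`, `to`, `residue`, vertex
#'   indices into `peaks`).
#' @examples
#' g <- spectrum_graph(tibble::tibble(mass = c(100, 157.02146),
#'                                    intensity = c(1, 1)))
#' g$edges
#' @export
spectrum_graph <- function(peaks, epsilon = 0.004) {
  stopifnot(epsilon > 0)
  peaks <- peaks[order(peaks$mass), ]
  m <- peaks$mass
  n <- length(m)
  tab <- .residue_mass_table[names(.residue_mass_table) != "I"]
  edge_list <- vector("list", length(tab))
  tol <- 2 * epsilon
  for (j in seq_along(tab)) {
    lo <- findInterval(m + tab[j] - tol, m)
    hi <- findInterval(m + tab[j] + tol, m)
    cnt <- pmax(hi - lo, 0L)
    if (sum(cnt) == 0L) next
    from <- rep(seq_len(n), cnt)
    to <- sequence(cnt) + rep(lo, cnt)
    edge_list[[j]] <- list(from = from, to = to,
                           residue = rep(names(tab)[j], length(from)))
  }
  edge_list <- edge_list[!vapply(edge_list, is.null, logical(1L))]
  from <- c(integer(0),
            unlist(lapply(edge_list, `[[`, "from"), use.names = FALSE))
  to <- c(integer(0),
          unlist(lapply(edge_list, `[[`, "to"), use.names = FALSE))
  residue <- c(character(0),
               unlist(lapply(edge_list, `[[`, "residue"), use.names = FALSE))
  keep <- which(to > from)
  o <- keep[order(from[keep], to[keep])]
  edges <- tibble::new_tibble(
    list(from = as.integer(from[o]), to = as.integer(to[o]),
         residue = residue[o]),
    nrow = length(o)
  )
  structure(list(peaks = peaks, edges = edges), class = "spectrum_graph")
}

#' Extract the optimal path from each connected component
#'
#' Components are taken direction-blind (weak connectivity); within each,
#' the directed path maximizing the sum of vertex intensity scores is found
#' by exact dynamic programming over the mass-ordered DAG. Ties are broken
#' by the smaller starting-peak mass, then lexicographically by the edge
#' label string. Single-vertex components yield edge-less paths, which
#' downstream tag derivation discards.
#'
#' @param graph A [spectrum_graph()].
#' @return A list of paths; each path is a list with `peak_idx` (vertex
#'   indices), `masses`, `labels` (character vector of edge residues) and
#'   `score`.
#' @export
optimal_paths <- function(graph) {
  pk <- graph$peaks
  ed <- graph$edges
  n <- nrow(pk)
  if (n == 0L) return(list())
  if (nrow(ed) == 0L) {
    comp <- seq_len(n)
  } else {
    g <- igraph::graph_from_edgelist(as.matrix(ed[, c("from", "to")]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  score <- pk$intensity
  m <- pk$mass
  # DP state per vertex: best path ending there
  best_score <- score
  best_start <- m
  best_label <- character(n)
  parent <- rep(NA_integer_, n)
  if (nrow(ed) > 0L) {
    in_edges <- split(seq_len(nrow(ed)), ed$to)
    for (v in seq_len(n)) {
      ein <- in_edges[[as.character(v)]]
      if (is.null(ein)) next
      for (e in ein) {
        u <- ed$from[e]
        cs <- best_score[u] + score[v]
        cl <- paste0(best_label[u], ed$residue[e])
        better <-
          cs > best_score[v] ||
          (cs == best_score[v] && (best_start[u] < best_start[v] ||
            (best_start[u] == best_start[v] && cl < best_label[v])))
        if (better) {
          best_score[v] <- cs
          best_start[v] <- best_start[u]
          best_label[v] <- cl
          parent[v] <- u
        }
      }
    }
  }
  out <- list()
  for (cid in unique(comp)) {
    vs <- which(comp == cid)
    o <- order(-best_score[vs], best_start[vs], best_label[vs])
    end <- vs[o[1L]]
    idx <- end
    while (!is.na(parent[idx[1L]])) idx <- c(parent[idx[1L]], idx)
    out[[length(out) + 1L]] <- list(
      peak_idx = idx,
      masses = m[idx],
      labels = if (nchar(best_label[end]) == 0L) character(0) else
        strsplit(best_label[end], "", fixed = TRUE)[[1L]],
      score = best_score[end]
    )
  }
  out
}

#' Derive all k-tags from a path
#'
#' Every window of `k` consecutive edges of a labeled spectrum-graph path
#' yields one tag: its sequence is the concatenated residue labels and its
#' offset is the mass of the window's first peak. Paths shorter than `k`
#' edges yield none.
#'
#' @param path A path as returned by [optimal_paths()].
#' @param k Tag length.
#' @return A tibble with columns `sequence` and `offset` (possibly empty).
#' @export
path_tags <- function(path, k = 4L) {
  e <- length(path$labels)
  if (e < k) {
    return(tibble::new_tibble(list(sequence = character(0),
                                   offset = numeric(0)), nrow = 0L))
  }
  starts <- seq_len(e - k + 1L)
  lbl <- paste(path$labels, collapse = "")
  tibble::new_tibble(
    list(sequence = substring(lbl, starts, starts + k - 1L),
         offset = path$masses[starts]),
    nrow = length(starts)
  )
}

#' Generate k-tags from deconvoluted spectra
#'
#' Runs the full tag pipeline per spectrum: preprocessing (water-loss
#' elimination, peak reflection), spectrum-graph construction, optimal-path
#' extraction per connected component, and k-tag derivation from every
#' path of at least `k` edges.
#'
#' @param spectra A peak tibble (see [spectrum_tbl()], [read_msalign()]).
#' @param params A [stitch_params()] object supplying `k`, `epsilon` and
#'   the preprocessing switches.
#' @return A tag tibble with columns `spectrum_id`, `sequence`, `offset`.
#' @examples
#' # prefix fragment series of ...SGATF with an N-terminal offset of 500 Da
#' sp <- spectrum_tbl("s1", 1000,
#'   mass = 500 + cumsum(c(0, residue_mass(c("S", "G", "A", "T", "F")))),
#'   intensity = 1)
#' generate_tags(sp, stitch_params(reflect = FALSE)) # SGAT@500, GATF@587
#' @export
generate_tags <- function(spectra, params = stitch_params()) {
  empty <- tibble::tibble(spectrum_id = character(0),
                          sequence = character(0), offset = numeric(0))
  if (nrow(spectra) == 0L) return(empty)
  spectra <- preprocess_spectra(spectra, params)
  parts <- split(spectra, spectra$spectrum_id)
  out <- lapply(names(parts), function(id) {
    g <- spectrum_graph(parts[[id]], epsilon = params$epsilon)
    tags <- dplyr::bind_rows(lapply(optimal_paths(g), path_tags,
                                    k = params$k))
    if (nrow(tags) == 0L) return(NULL)
    tibble::new_tibble(
      list(spectrum_id = rep(id, nrow(tags)), sequence = tags$sequence,
           offset = tags$offset),
      nrow = nrow(tags)
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) empty else res
}

#' Write / read a tag table as TSV
#'
#' @param tags A tag tibble (`spectrum_id`, `sequence`, `offset`).
#' @param path File path.
#' @return `write_tags` returns `path` invisibly; `read_tags` returns the
#'   tag tibble.
#' @export
write_tags <- function(tags, path) {
  utils::write.table(tags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tags
#' @export
read_tags <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "character", "numeric"))
  tibble::as_tibble(x)
}

#' Glue consistent tags into a de novo string
#'
#' Two k-tags whose sequences overlap by `k - 1` and whose offsets differ
#' by the mass of the first tag's leading residue (within `2 * epsilon`)
#' are merged into a `(k + 1)`-length string carrying the smallest
#' contributing offset. Longer chains are glued associatively, one tag at
#' a time in offset order.
#'
#' @param tags A tibble with columns `sequence` and `offset` (two or more
#'   rows; all sequences the same length).
#' @param params A [stitch_params()] object (uses `epsilon`).
#' @return A one-row tibble with columns `sequence` and `offset`, or `NULL`
#'   when the tags are inconsistent.
#' @examples
#' glue_tags(tibble::tibble(sequence = c("SGAT", "GATF"),
#'                          offset = c(500, 500 + residue_mass("S"))))
#' @export
glue_tags <- function(tags, params = stitch_params()) {
  stopifnot(nrow(tags) >= 2L)
  k <- nchar(tags$sequence[1L])
  stopifnot(all(nchar(tags$sequence) == k))
  tags <- tags[order(tags$offset), ]
  cur_seq <- tags$sequence[1L]
  cur_off <- tags$offset[1L]
  tol <- 2 * params$epsilon
  for (i in 2L:nrow(tags)) {
    s2 <- tags$sequence[i]
    len <- nchar(cur_seq)
    head_len <- len - (k - 1L)
    if (substr(cur_seq, head_len + 1L, len) != substr(s2, 1L, k - 1L)) {
      return(NULL)
    }
    expected <- cur_off + sequence_mass(substr(cur_seq, 1L, head_len))
    if (abs(tags$offset[i] - expected) > tol) return(NULL)
    cur_seq <- paste0(cur_seq, substr(s2, k, k))
    cur_off <- min(cur_off, tags$offset[i])
  }
  tibble::tibble(sequence = cur_seq, offset = cur_off)
}
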