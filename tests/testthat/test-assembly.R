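check_offsets <- function(path) {
  off <- 0
  for (i in seq_len(nrow(path))) {
    if (path$type[i] == "fragment") {
      expect_equal(path$offset[i], off)
      off <- off + sequence_mass(
        if (path$orientation[i] == "rev") {
          reverse_sequence(path$sequence[i])
        } else {
          path$sequence[i]
        })
    } else {
      off <- off + path$gap[i]
    }
  }
  # alternation: starts and ends with a fragment, no two adjacent gaps
  expect_equal(path$type[1], "fragment")
  expect_equal(path$type[nrow(path)], "fragment")
  expect_false(any(path$type[-1] == "gap" &
                     path$type[-nrow(path)] == "gap"))
}

test_that("try_append joins in-order fragments with the true gap", {
  scn <- small_scene(51, protein_length = 150L, n_spectra = 60L)
  g1 <- gapped_path(scn$strings[[1]], "F01")
  g2 <- gapped_path(scn$strings[[2]], "F02")
  merged <- try_append(g1, g2, scn$tags)
  expect_s3_class(merged, "gapped_path")
  expect_equal(sum(merged$type == "gap"), 1L)
  expect_equal(merged$gap[merged$type == "gap"], scn$gaps$gap_mass[1],
               tolerance = 0.05 / scn$gaps$gap_mass[1])
  check_offsets(merged)

  # unrelated proteins do not append
  other <- small_scene(52, protein_length = 150L, n_spectra = 40L)
  expect_null(try_append(g1, gapped_path(other$strings[[1]], "X"),
                         scn$tags))
})

test_that("try_embed places a fragment inside a large gap", {
  scn <- small_scene(53, protein_length = 160L, n_spectra = 70L,
                     fragment_lengths = c(14L, 10L, 14L),
                     gap_lengths = c(5L, 5L))
  a <- gapped_path(scn$strings[[1]], "A")
  b <- gapped_path(scn$strings[[2]], "B")
  cc <- gapped_path(scn$strings[[3]], "C")
  # A ... C with a gap wide enough to hold B plus both flanking gaps
  host <- try_append(a, cc, scn$tags)
  expect_false(is.null(host))
  big_gap <- host$gap[host$type == "gap"]
  true_mid <- scn$gaps$gap_mass[1] + sequence_mass(scn$strings[[2]]) +
    scn$gaps$gap_mass[2]
  expect_equal(big_gap, true_mid, tolerance = 0.1 / true_mid)

  merged <- try_embed(host, b, scn$tags)
  expect_false(is.null(merged))
  expect_equal(sum(merged$type == "fragment"), 3L)
  gaps <- merged$gap[merged$type == "gap"]
  expect_equal(length(gaps), 2L)
  expect_lt(max(abs(gaps - scn$gaps$gap_mass)), 0.05)
  check_offsets(merged)

  # a guest heavier than every gap cannot be embedded
  heavy <- gapped_path(paste0(scn$strings[[2]],
                              "WWWWWWWWWWWWWWWWWWWWWWWW"), "H")
  expect_null(try_embed(host, heavy, scn$tags))
})

test_that("try_embed rejects a guest that would overlap the next fragment", {
  scn <- small_scene(54, protein_length = 160L, n_spectra = 70L,
                     fragment_lengths = c(14L, 10L, 14L),
                     gap_lengths = c(5L, 5L))
  a <- gapped_path(scn$strings[[1]], "A")
  cc <- gapped_path(scn$strings[[3]], "C")
  host <- try_append(a, cc, scn$tags)
  expect_false(is.null(host))
  # extend the middle fragment into the territory of C: it still follows A
  # in the protein, but no longer fits the gap
  fr <- scn$fragments
  long_mid <- substr(scn$protein, fr$start[2], fr$start[3])
  expect_null(try_embed(host, gapped_path(long_mid, "B+"), scn$tags))
})

test_that("join_pair tries the four orientation combinations in order", {
  scn <- anchored_scene(71)
  f1 <- scn$fragments[1]
  f2 <- scn$fragments[2]
  g1 <- gapped_path(f1, "F01")

  # reversed second path merges through the (g1, rev g2) combination
  g2r <- gapped_path(reverse_sequence(f2), "F02r")
  merged <- join_pair(g1, g2r, scn$tags)
  expect_false(is.null(merged))
  fr <- merged[merged$type == "fragment", ]
  expect_equal(fr$orientation, c("fwd", "rev"))
  expect_lt(abs(merged$gap[merged$type == "gap"] - scn$gap_masses[1]),
            0.05)
  check_offsets(merged)

  # reversed first path merges through the (rev g1, g2) combination
  g1r <- gapped_path(reverse_sequence(f1), "F01r")
  merged2 <- join_pair(g1r, gapped_path(f2, "F02"), scn$tags)
  expect_false(is.null(merged2))
  expect_lt(abs(merged2$gap[merged2$type == "gap"] - scn$gap_masses[1]),
            0.05)

  # both reversed: the (rev g1, rev g2) combination restores protein order
  merged3 <- join_pair(g1r, g2r, scn$tags)
  expect_false(is.null(merged3))
  expect_lt(abs(merged3$gap[merged3$type == "gap"] - scn$gap_masses[1]),
            0.05)

  # unrelated paths fail on all four combinations
  other <- small_scene(56, protein_length = 150L, n_spectra = 40L)
  expect_null(join_pair(g1, gapped_path(other$strings[[1]], "X"),
                        scn$tags))
})

test_that("join_pair short-circuits after the first success", {
  calls <- 0L
  local_mocked_bindings(
    try_append = function(g1, g2, tags, params) {
      calls <<- calls + 1L
      try_append_result
    }
  )
  try_append_result <- gapped_path("SGATF", "ok")
  out <- join_pair(gapped_path("AAAA", "a"), gapped_path("CCCC", "b"),
                   tags = NULL)
  expect_equal(calls, 1L)
  expect_identical(out$source[1], "ok")
})

test_that("assemble_fragments reconstructs one path with true gaps", {
  scn <- small_scene(57, protein_length = 150L, n_spectra = 60L)
  asm <- assemble_fragments(scn$strings, scn$tags)
  expect_s3_class(asm, "gap_assembly")
  expect_equal(length(asm), 1L)
  path <- asm[[1]]
  expect_equal(sum(path$type == "fragment"), 3L)
  gaps <- path$gap[path$type == "gap"]
  expect_lt(max(abs(gaps - scn$gaps$gap_mass)), 0.05)
  check_offsets(path)

  # single input string is a fixed point
  one <- assemble_fragments(scn$strings[1], scn$tags)
  expect_equal(length(one), 1L)
  expect_equal(one[[1]]$sequence, unname(scn$strings[1]))

  # determinism: identical inputs give identical output
  asm2 <- assemble_fragments(scn$strings, scn$tags)
  expect_equal(tidy(asm), tidy(asm2))
})

test_that("assembly merges flipped fragments via orientation search", {
  scn <- anchored_scene(72)
  strings <- stats::setNames(reverse_sequence(scn$fragments),
                             c("F01", "F02", "F03"))
  asm <- assemble_fragments(strings, scn$tags)
  expect_equal(length(asm), 1L)
  gaps <- asm[[1]]$gap[asm[[1]]$type == "gap"]
  # a fully reversed scene may assemble in reverse order: gaps match the
  # truth as a set
  expect_lt(max(abs(sort(gaps) - sort(scn$gap_masses))), 0.05)
})

test_that("fragments are conserved across assembly and paths never mix proteins", {
  scnA <- small_scene(59, protein_length = 150L, n_spectra = 50L,
                      fragment_lengths = c(12L, 12L), gap_lengths = 6L)
  scnB <- small_scene(60, protein_length = 150L, n_spectra = 50L,
                      fragment_lengths = c(12L, 12L), gap_lengths = 6L)
  tags <- dplyr::bind_rows(
    scnA$tags, dplyr::mutate(scnB$tags,
                             spectrum_id = paste0("B", spectrum_id)))
  strings <- c(A1 = scnA$strings[[1]], A2 = scnA$strings[[2]],
               B1 = scnB$strings[[1]], B2 = scnB$strings[[2]])
  asm <- assemble_fragments(strings, tags)
  sources <- lapply(asm, function(p) p$source[p$type == "fragment"])
  # conservation: every input appears exactly once over all paths
  expect_setequal(unlist(sources), names(strings))
  expect_equal(length(unlist(sources)), length(strings))
  # no path mixes the two proteins
  for (s in sources) {
    expect_equal(length(unique(substr(s, 1, 1))), 1L)
  }
})

test_that("short strings pass through unmerged with a warning", {
  scn <- small_scene(61, protein_length = 120L, n_spectra = 30L)
  expect_warning(
    asm <- assemble_fragments(c(scn$strings[1], tiny = "AG"), scn$tags),
    "shorter than k")
  expect_equal(length(asm), 2L)
})

test_that("gapped paths render, tidy, glance and plot", {
  scn <- small_scene(62, protein_length = 150L, n_spectra = 60L)
  asm <- assemble_fragments(scn$strings, scn$tags)
  p <- asm[[1]]
  expect_match(path_string(p), "-\\[")
  td <- tidy(p)
  expect_false(inherits(td, "gapped_path"))
  expect_equal(nrow(td), nrow(p))
  gl <- glance(p)
  expect_equal(gl$n_fragments, 3L)
  expect_equal(gl$n_gaps, 2L)
  expect_equal(gl$total_mass,
               sum(sequence_mass(scn$strings)) + sum(gl$gap_mass))
  ta <- tidy(asm)
  expect_equal(unique(ta$path), 1L)
  expect_s3_class(autoplot(p), "ggplot")
  h <- bin_differences(string_convolution(scn$tags, scn$strings[[1]],
                                          scn$strings[[2]]))
  expect_s3_class(autoplot(h), "ggplot")
  expect_output(print(p), "gapped_path")
  expect_output(print(asm), "gap_assembly")
  js <- jsonlite::fromJSON(write_assembly(asm))
  expect_equal(length(js), 1L)
})
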