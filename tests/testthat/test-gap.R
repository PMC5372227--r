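test_that("bin_differences scales and rounds half away from zero", {
  h <- bin_differences(make_conv(129.042593), h = 4L)
  expect_equal(h$scaled, 1290426)
  expect_equal(h$binned, 129)

  # rounding collision: nearby raw values share one scaled value
  h2 <- bin_differences(make_conv(c(rep(129.04259, 2), rep(129.04261, 3))))
  mu <- dplyr::count(tibble::as_tibble(h2), scaled)
  expect_equal(mu$scaled, 1290426)
  expect_equal(mu$n, 5L)

  h3 <- bin_differences(make_conv(c(-0.4, 0.6)))
  expect_equal(h3$binned, c(0, 1))
})

test_that("binning conserves total multiplicity", {
  set.seed(9)
  for (rep in 1:10) {
    conv <- make_conv(runif(sample(5:60, 1), -50, 2000))
    h <- bin_differences(conv)
    expect_equal(nrow(h), nrow(conv))
    expect_equal(sum(bin_multiplicities(h)$multiplicity), nrow(conv))
    sc <- dplyr::count(tibble::as_tibble(h), scaled)
    expect_equal(sum(sc$n), nrow(conv))
    # each scaled difference maps to exactly one binned difference
    map <- unique(tibble::as_tibble(h)[, c("scaled", "binned")])
    expect_equal(anyDuplicated(map$scaled), 0L)
  }
})

test_that("score_bin sums the bin with its 1 Da neighbors", {
  h <- bin_differences(make_conv(c(rep(1583, 25), rep(1582, 10))))
  expect_equal(score_bin(h, 1583), 35L)
  expect_equal(score_bin(h, 1581), 10L)
  h2 <- bin_differences(make_conv(rep(500, 20)))
  expect_equal(score_bin(h2, 500), 20L)
  expect_equal(score_bin(h2, 100), 0L)
})

test_that("select_candidate applies Gmax, Bmin, bmax and tie rules", {
  params <- stitch_params()
  expect_null(select_candidate(bin_differences(make_conv(numeric(0))),
                               params))

  # only bins at the maximal multiplicity enter scoring: 501 (30) wins even
  # though 500 + 700 both carry 25
  conv <- make_conv(c(rep(500.2, 25), rep(700.0, 25), rep(501.2, 30)))
  cand <- select_candidate(bin_differences(conv), params)
  expect_equal(cand$d_hat_b, 501)
  expect_equal(cand$multiplicity, 30)
  expect_equal(cand$score, 55) # 30 + 25 from bin 500

  # equal multiplicity and equal score: the smaller bin wins
  conv2 <- make_conv(c(rep(800.1, 25), rep(900.1, 25)))
  expect_equal(select_candidate(bin_differences(conv2), params)$d_hat_b,
               800)

  # bins beyond Gmax or below zero are never candidates
  conv3 <- make_conv(c(rep(3400.5, 30), rep(-5.2, 30)))
  expect_null(select_candidate(bin_differences(conv3), params))

  # within the winning bin, the scaled value of highest multiplicity wins
  conv4 <- make_conv(c(rep(650.0001, 12), rep(650.0002, 18)))
  expect_equal(select_candidate(bin_differences(conv4), params)$d_hat,
               650.0002)
})

test_that("select_candidate output respects its invariants", {
  set.seed(13)
  params <- stitch_params()
  for (rep in 1:10) {
    conv <- make_conv(runif(300, -100, 3500))
    h <- bin_differences(conv)
    cand <- select_candidate(h, stitch_params(bmin = 2))
    if (is.null(cand)) next
    expect_gte(cand$d_hat_b, 0)
    expect_lte(cand$d_hat_b, params$gmax)
    expect_gte(cand$score, cand$multiplicity)
  }
})

test_that("support_check implements m* and the neighbor-bin fallback", {
  params <- stitch_params() # amin 6, k 4 -> m* = 3
  mk <- function(n1, n2, extra = NULL) {
    conv <- make_conv(rep(1000.1, max(n1, n2) * 2),
                      win1 = rep_len(seq_len(n1), max(n1, n2) * 2),
                      win2 = rep_len(seq_len(n2), max(n1, n2) * 2))
    if (!is.null(extra)) conv <- dplyr::bind_rows(conv, extra)
    bin_differences(conv)
  }
  chk <- function(...) support_check(..., params = params)

  s <- chk(mk(3, 3), 1000)
  expect_equal(s$m_star, 3L)
  expect_true(s$accepted)
  expect_equal(c(s$n1, s$n2), c(3L, 3L))

  expect_true(chk(mk(4, 2), 1000)$accepted)   # m*+1 / m*-1
  expect_true(chk(mk(2, 4), 1000)$accepted)   # symmetric reading
  expect_false(chk(mk(2, 2), 1000)$accepted)  # no qualifying neighbor

  # neighbor bin at db + 1 supported by (2, 3) rescues a (2, 2) candidate
  neighbor <- make_conv(rep(1001.1, 6),
                        win1 = rep_len(1:2, 6), win2 = rep_len(1:3, 6))
  s2 <- chk(mk(2, 2, extra = neighbor), 1000)
  expect_true(s2$accepted)
  expect_true(s2$via_neighbor)

  expect_false(chk(mk(1, 3), 1000)$accepted) # below m* - 1 on one side
})

test_that("estimate_gap recovers true separating masses on clean data", {
  scn <- small_scene(41, protein_length = 150L, n_spectra = 60L,
                     mass_error_sd = 0.0005)
  est <- estimate_gap(scn$tags, scn$strings[[1]], scn$strings[[2]])
  expect_s3_class(est, "gap_estimate")
  expect_equal(est$estimate, scn$gaps$gap_mass[1], tolerance = 0.01 /
                 scn$gaps$gap_mass[1])
  expect_gte(est$multiplicity, stitch_params()$bmin)
  expect_gte(est$support1, 3)

  # adjacent fragments: the estimate is nearly zero
  scn0 <- small_scene(42, protein_length = 120L, n_spectra = 60L,
                      fragment_lengths = c(12L, 12L),
                      gap_lengths = 0L)
  est0 <- estimate_gap(scn0$tags, scn0$strings[[1]], scn0$strings[[2]])
  expect_false(is.null(est0))
  expect_lt(abs(est0$estimate), 0.01)

  # fragments of two different proteins never get an estimate
  scnA <- small_scene(43, protein_length = 120L, n_spectra = 40L)
  scnB <- small_scene(44, protein_length = 120L, n_spectra = 40L)
  tags <- dplyr::bind_rows(
    scnA$tags,
    dplyr::mutate(scnB$tags,
                  spectrum_id = paste0("B", spectrum_id)))
  expect_null(estimate_gap(tags, scnA$strings[[1]], scnB$strings[[1]]))
})

test_that("raising Bmin never converts a reject into an accept", {
  scn <- small_scene(45, protein_length = 120L, n_spectra = 30L,
                     coverage = 0.7, mass_error_sd = 0.001)
  accepted <- vapply(c(5L, 10L, 20L, 40L, 80L, 1000L), function(bmin) {
    !is.null(estimate_gap(scn$tags, scn$strings[[1]], scn$strings[[2]],
                          stitch_params(bmin = bmin)))
  }, logical(1))
  # monotone non-increasing acceptance along increasing Bmin
  expect_true(all(diff(as.integer(accepted)) <= 0))
  expect_false(accepted[length(accepted)]) # absurd Bmin must reject
})

test_that("1 Da-shifted tag pairs are aggregated by the score", {
  # clean prefix series of s1 ... gap ... s2, duplicated across spectra;
  # in half of them every peak beyond the gap is +1 Da (a monoisotopic
  # mis-assignment), so cross-gap pairs land in bin db + 1
  prot <- paste0("ARNDCEQGHKMFPSTWYVAR", "KHG", "DEFGHKMNPQRSTVWYACDE")
  s1 <- substr(prot, 1, 20)
  s2 <- substr(prot, 24, 43)
  gap_true <- sequence_mass("KHG")
  res <- strsplit(prot, "")[[1]]
  masses <- cumsum(residue_mass(res))
  sp <- lapply(1:30, function(i) {
    m <- masses
    if (i <= 15) m[24:length(m)] <- m[24:length(m)] + 1
    spectrum_tbl(sprintf("p%02d", i), masses[length(masses)] + water_mass,
                 m[-length(m)], intensity = 1)
  })
  tags <- generate_tags(dplyr::bind_rows(sp),
                        stitch_params(reflect = FALSE))
  conv <- string_convolution(tags, s1, s2)
  h <- bin_differences(conv)
  mu <- bin_multiplicities(h)
  db <- round(gap_true)
  expect_true(all(c(db, db + 1) %in% mu$binned))
  cand <- select_candidate(h, stitch_params())
  expect_equal(cand$d_hat_b, db)
  expect_equal(cand$score,
               sum(mu$multiplicity[mu$binned %in% c(db, db + 1)]))
  est <- estimate_gap(tags, s1, s2)
  expect_false(is.null(est))
  expect_lte(abs(est$binned - gap_true), 1)
})

test_that("gap_report serializes an auditable record", {
  scn <- small_scene(46, protein_length = 120L, n_spectra = 40L)
  est <- estimate_gap(scn$tags, scn$strings[[1]], scn$strings[[2]])
  js <- jsonlite::fromJSON(gap_report(est))
  expect_equal(js$estimate, est$estimate)
  expect_equal(js$support, c(est$support1, est$support2))
  expect_true(is.data.frame(js$bins))
})
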