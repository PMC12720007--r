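test_that("motif_spec pairs the hexamer with its reverse complement", {
  m <- motif_spec()
  expect_equal(m$forward, "TTAGGG")
  expect_equal(m$reverse, "CCCTAA")
  expect_equal(m$unit_length, 6)
  expect_error(motif_spec(""), "non-empty")
})

test_that("exact scanning finds all offsets, case-insensitively", {
  expect_equal(scan_motif("TTAGGGTTAGGG", "TTAGGG"), c(0L, 6L))
  expect_equal(scan_motif("", "TTAGGG"), integer(0))
  expect_equal(scan_motif("ttagggTTAGGG", "TTAGGG"), c(0L, 6L))
  expect_equal(scan_motif("TTANGG", "TTAGGG"), integer(0))  # N never matches
  expect_error(scan_motif("ACGT", ""), "non-empty")
  # soft-mask mode: lowercase bases become unmatchable
  expect_equal(scan_motif("ttagggTTAGGG", "TTAGGG", respect_softmask = TRUE),
               6L)
})

test_that("scanner agrees with a naive sliding window on random sequences", {
  set.seed(21)
  for (i in 1:10000) {
    s <- random_seq(60, with_n = i %% 5 == 0)
    expect_identical(scan_motif(s, "TTAGGG"), naive_scan(s, "TTAGGG"))
  }
  for (i in 1:100) {
    s <- random_seq(2000)
    expect_identical(scan_motif(s, "TTAGGG"), naive_scan(s, "TTAGGG"))
    expect_identical(scan_motif(s, "CCCTAA"), naive_scan(s, "CCCTAA"))
  }
  # a self-overlapping motif must report overlapping occurrences
  expect_equal(scan_motif("AAAA", "AA"), c(0L, 1L, 2L))
})

test_that("repeat counting sums planted forward and reverse units", {
  expect_equal(unname(count_repeats("TTAGGGCCCTAA")), c(1L, 1L))
  expect_equal(unname(count_repeats("ACGTACGT")), c(0L, 0L))
  set.seed(22)
  # plant 7 forward and 3 reverse units at non-adjacent, spaced positions in
  # a background the naive oracle certifies free of spurious occurrences
  pos <- seq(10, by = 70, length.out = 10)
  units <- c(rep("TTAGGG", 7), rep("CCCTAA", 3))
  repeat {
    v <- strsplit(clean_background(800), "")[[1]]
    for (k in seq_along(pos))
      v[(pos[k] + 1):(pos[k] + 6)] <- strsplit(units[k], "")[[1]]
    planted <- paste(v, collapse = "")
    if (length(naive_scan(planted, "TTAGGG")) == 7 &&
        length(naive_scan(planted, "CCCTAA")) == 3) break
  }
  cnt <- count_repeats(planted)
  expect_equal(unname(cnt), c(7L, 3L))
})

test_that("tandem runs are maximal, strand-pure and zero-gap", {
  r4 <- tandem_runs(strrep("TTAGGG", 4))
  expect_equal(nrow(r4), 1)
  expect_equal(r4$units, 4)
  r32 <- tandem_runs(paste0(strrep("TTAGGG", 3), "A", strrep("TTAGGG", 2)))
  expect_equal(r32$units, c(3, 2))
  expect_equal(max(r32$units), 3)
  junction <- tandem_runs("TTAGGGCCCTAA")
  expect_equal(nrow(junction), 2)
  expect_equal(junction$units, c(1, 1))
  expect_setequal(junction$motif, c("TTAGGG", "CCCTAA"))
})

test_that("every occurrence belongs to exactly one run (conservation)", {
  set.seed(23)
  for (i in 1:150) {
    n_units <- sample(0:8, 1)
    parts <- character(0)
    for (u in seq_len(n_units)) {
      parts <- c(parts,
                 strrep(sample(c("TTAGGG", "CCCTAA"), 1), sample(1:5, 1)),
                 if (runif(1) < 0.7) random_seq(sample(1:20, 1)))
    }
    s <- paste(c(random_seq(30), parts, random_seq(30)), collapse = "")
    tr <- tandem_runs(s)
    expect_equal(sum(tr$units), sum(unname(count_repeats(s))))
    # run lengths per motif match the naive grouping oracle
    expect_identical(sort(tr$units[tr$motif == "TTAGGG"]),
                     sort(naive_runs(s, "TTAGGG")))
    expect_identical(sort(tr$units[tr$motif == "CCCTAA"]),
                     sort(naive_runs(s, "CCCTAA")))
  }
})

test_that("peak typing follows the five-class definitions", {
  expect_equal(classify_peak(integer(0)), "I")
  expect_equal(classify_peak(1L), "II")
  expect_equal(classify_peak(c(3, 3, 3)), "III")
  expect_equal(classify_peak(c(4, 3)), "IV")
  expect_equal(classify_peak(c(5, 4, 1)), "V")
  expect_equal(classify_peak(4L), "IV")        # boundary: one run of exactly 4
  expect_equal(classify_peak(c(2, 1)), "III")
  expect_error(classify_peak(c(2, 2), total = 5), "inconsistent")
  expect_error(classify_peak(c(0, 1)), "positive")
})

test_that("peak profiling recovers planted arrays from a FASTA genome", {
  set.seed(24)
  # 6-unit forward array planted at offset 1000; the naive oracle certifies
  # that planting created no spurious junction occurrences
  repeat {
    v <- strsplit(clean_background(3000), "")[[1]]
    v[1001:1036] <- strsplit(strrep("TTAGGG", 6), "")[[1]]
    s <- paste(v, collapse = "")
    if (identical(naive_scan(s, "TTAGGG"), seq(1000L, 1030L, by = 6L)) &&
        !length(naive_scan(s, "CCCTAA"))) break
  }
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrS some description", s), fa)
  peaks <- peak_set(data.frame(
    chrom = "chrS",
    start = c(900, 100, 1024),
    end = c(1200, 400, 1300),
    name = c("on_array", "background", "straddle")))
  pr <- profile_peaks(peaks, fa)
  expect_equal(pr$total[pr$peak_name == "on_array"], 6)
  expect_equal(pr$longest_tandem[pr$peak_name == "on_array"], 6)
  expect_equal(pr$peak_type[pr$peak_name == "on_array"], "IV")
  expect_equal(pr$peak_type[pr$peak_name == "background"], "I")
  # straddling peak covers only units 5 and 6 of the array
  expect_equal(pr$total[pr$peak_name == "straddle"], 2)
  expect_equal(pr$peak_type[pr$peak_name == "straddle"], "III")
  bad_chrom <- peak_set(data.frame(chrom = "chrZ", start = 0, end = 10))
  expect_error(profile_peaks(bad_chrom, fa), "chrZ")
  oob <- peak_set(data.frame(chrom = "chrS", start = 0, end = 99999,
                             name = "oob"))
  expect_error(profile_peaks(oob, fa), "out of bounds")
})

test_that("profiling is reverse-complement symmetric", {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  set.seed(25)
  for (i in 1:20) {
    s <- paste0(random_seq(100), strrep("TTAGGG", sample(1:6, 1)),
                random_seq(50), strrep("CCCTAA", sample(1:6, 1)),
                random_seq(100))
    ps <- peak_set(data.frame(chrom = "c", start = 0, end = nchar(s),
                              name = "p"))
    fwd <- profile_peaks(ps, c(c = s))
    rev <- profile_peaks(ps, c(c = revcomp(s)))
    expect_equal(fwd$count_fwd, rev$count_rev)
    expect_equal(fwd$count_rev, rev$count_fwd)
    expect_equal(fwd$longest_tandem, rev$longest_tandem)
    expect_equal(fwd$peak_type, rev$peak_type)
  }
})

test_that("tandem filter partition coincides with the type IV/V classes", {
  set.seed(26)
  runs <- lapply(1:300, function(i) sample(1:6, sample(0:4, 1), replace = TRUE))
  prof <- data.frame(
    peak_name = sprintf("p%03d", 1:300),
    total = vapply(runs, sum, 1),
    longest_tandem = vapply(runs, function(r) if (length(r)) max(r) else 0, 1),
    peak_type = vapply(runs, classify_peak, ""),
    stringsAsFactors = FALSE)
  split4 <- filter_min_tandem(prof, 4)
  expect_setequal(split4$passing$peak_name,
                  prof$peak_name[prof$peak_type %in% c("IV", "V")])
  expect_setequal(split4$failing$peak_name,
                  prof$peak_name[prof$peak_type %in% c("I", "II", "III")])
  # boundary: longest run exactly at the threshold passes
  bprof <- data.frame(peak_name = c("x", "y"), total = c(4, 3),
                      longest_tandem = c(4, 3), stringsAsFactors = FALSE)
  bsplit <- filter_min_tandem(bprof, 4)
  expect_equal(bsplit$passing$peak_name, "x")
  expect_equal(bsplit$failing$peak_name, "y")
})

test_that("soft-masked arrays are skipped only when asked", {
  s <- paste0("ACGTACGT", tolower(strrep("TTAGGG", 5)), "ACGTACGT")
  ps <- peak_set(data.frame(chrom = "c", start = 0, end = nchar(s),
                            name = "p"))
  default <- profile_peaks(ps, c(c = s))
  masked <- profile_peaks(ps, c(c = s), respect_softmask = TRUE)
  expect_equal(default$total, 5)
  expect_equal(masked$total, 0)
  expect_equal(masked$peak_type, "I")
})
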