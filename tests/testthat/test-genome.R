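test_that("multi-record FASTA produces independent per-chromosome tracks", {
  seqs <- c(chrA = random_seq(600, 1), chrB = random_seq(800, 2))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  tracks <- scan_genome(f)
  expect_equal(sort(unique(tracks$chrom)), c("chrA", "chrB"))
  expect_equal(nrow(tracks), 1400L)
  # per-chromosome normalization, and identity with a single-molecule run
  for (nm in names(seqs)) {
    tr <- tracks[tracks$chrom == nm, ]
    expect_equal(mean(tr$density[tr$defined]), 1, tolerance = 1e-9)
    solo <- plectoneme_density(seqs[[nm]])
    expect_equal(tr$w_tot, solo$w_tot, tolerance = 1e-12)
  }
})

test_that("chunked evaluation is independent of the chunk size", {
  sq <- c(g = random_seq(9000, 13))
  whole <- scan_genome(sq, chunk_size = 20000L)
  chunked <- scan_genome(sq, chunk_size = 1234L)
  expect_equal(chunked$w_tot, whole$w_tot, tolerance = 1e-9)
  # circular chromosome, chunked, against the direct circular run
  circ_whole <- scan_genome(sq, circular = TRUE, chunk_size = 20000L)
  circ_chunk <- scan_genome(sq, circular = TRUE, chunk_size = 2500L)
  expect_equal(circ_chunk$w_tot, circ_whole$w_tot, tolerance = 1e-9)
  expect_true(all(circ_whole$defined))
})

test_that("rotating a circular genome rotates its track exactly", {
  sq <- random_seq(2000, 21)
  k <- 611L
  rot <- paste0(substr(sq, k + 1, 2000), substr(sq, 1, k))
  t1 <- scan_genome(c(g = sq), circular = TRUE)
  t2 <- scan_genome(c(g = rot), circular = TRUE)
  expect_equal(t2$w_tot, t1$w_tot[c((k + 1):2000, 1:k)], tolerance = 1e-9)
})

test_that("meta-profile of a single plus-strand site is the smoothed local window", {
  tracks <- scan_genome(c(g = random_seq(2000, 3)))
  tss <- tibble::tibble(chrom = "g", position = 1000L, strand = "+",
                        name = "t1")
  mp <- tss_metaprofile(tracks, tss, halfwidth = 200L, smooth_window = 1L)
  expect_equal(mp$mean_raw, tracks$density[800:1200], tolerance = 1e-12)
  expect_equal(mp$mean_density, mp$mean_raw, tolerance = 1e-12)
  expect_equal(attr(mp, "n_sites"), 1L)
})

test_that("a site listed on both strands yields a mirror-symmetric meta-profile", {
  tracks <- scan_genome(c(g = random_seq(2000, 30)))
  tss <- tibble::tibble(chrom = "g", position = c(1000L, 1000L),
                        strand = c("+", "-"), name = c("a", "b"))
  mp <- tss_metaprofile(tracks, tss, halfwidth = 150L)
  expect_equal(mp$mean_raw, rev(mp$mean_raw), tolerance = 1e-12)
})

test_that("planted upstream curvature is recovered at the planted offset", {
  curved <- make_fixture("phased_tract", length = 75, period = 10.5)
  n_sites <- 12L
  spacing <- 1000L
  backbone <- make_fixture("flat_random", length = n_sites * spacing + 1000L,
                           seed = 55)
  ch <- strsplit(backbone, "")[[1]]
  tss_pos <- integer(n_sites)
  for (j in seq_len(n_sites)) {
    tss_pos[j] <- 500L + (j - 1L) * spacing
    at <- tss_pos[j] - 100L - 37L  # insert centered ~100 bp upstream
    ch[at:(at + 74L)] <- strsplit(curved, "")[[1]]
  }
  tracks <- scan_genome(c(g = paste(ch, collapse = "")))
  tss <- tibble::tibble(chrom = "g", position = tss_pos, strand = "+",
                        name = paste0("s", seq_len(n_sites)))
  mp <- tss_metaprofile(tracks, tss, halfwidth = 300L)
  expect_lt(abs(mp$offset[which.max(mp$mean_density)] + 100L), 40L)
})

test_that("random TSS in a homopolymer genome average to a flat profile", {
  tracks <- scan_genome(c(g = strrep("A", 3000)))
  set.seed(6)
  tss <- tibble::tibble(chrom = "g",
                        position = sample(300:2700, 15),
                        strand = sample(c("+", "-"), 15, replace = TRUE),
                        name = NA_character_)
  mp <- tss_metaprofile(tracks, tss, halfwidth = 100L)
  expect_lt(max(abs(mp$mean_density - 1)), 1e-9)
})

test_that("out-of-bounds or unsupported TSS are dropped with a message", {
  tracks <- scan_genome(c(g = random_seq(1000, 2)))
  tss <- tibble::tibble(chrom = c("g", "g", "nope"),
                        position = c(500L, 40L, 500L),
                        strand = "+", name = c("ok", "edge", "missing"))
  expect_message(mp <- tss_metaprofile(tracks, tss, halfwidth = 100L),
                 "2 TSS site")
  expect_equal(attr(mp, "n_sites"), 1L)
  expect_error(tss_metaprofile(tracks, tss[0, ]), "empty")
})

test_that("bedGraph round trip preserves values and skips masked ends", {
  prof <- plectoneme_density(random_seq(400, 14))
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(prof, f, chrom = "chr1")
  bg <- read_bedgraph(f)
  expect_equal(nrow(bg), sum(prof$defined))
  expect_equal(min(bg$position), 66L)  # no records for the masked 65 bp ends
  expect_equal(bg$value, prof$density[prof$defined], tolerance = 1e-9)
  # 0-based half-open starts
  first <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_equal(as.integer(first[2]), 65L)
  expect_equal(as.integer(first[3]), 66L)
})

test_that("TSS reader accepts 4-column TSV and BED6, with line-numbered errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "chr1\t100\t+\tgeneA", "chr1\t250\t-\tgeneB"), f)
  tab <- read_tss_table(f)
  expect_equal(tab$position, c(100L, 250L))
  expect_equal(tab$strand, c("+", "-"))

  b <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t100\tgeneA\t0\t+", "chr1\t249\t300\tgeneB\t0\t-"), b)
  bed <- read_tss_table(b)
  expect_equal(bed$position, c(100L, 300L))
  expect_equal(bed$strand, c("+", "-"))

  m <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t+\tok", "chr1\toops"), m)
  expect_error(read_tss_table(m), "line 2")
})

test_that("track TSV round trip supports the meta-profile pipeline", {
  tracks <- scan_genome(c(g = random_seq(600, 50)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_track_tsv(tracks, f)
  back <- read_track_tsv(f)
  expect_equal(back$density, tracks$density, tolerance = 1e-9)
  tss <- tibble::tibble(chrom = "g", position = 300L, strand = "+", name = NA)
  mp <- tss_metaprofile(back, tss, halfwidth = 100L)
  expect_equal(attr(mp, "n_sites"), 1L)
})
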