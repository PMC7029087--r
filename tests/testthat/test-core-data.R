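test_that("csv genotype dialect parses metadata, missing codes, and round-trips", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,location,species,LocAa,LocAb,LocBa,LocBb",
               "s1,CMU,fabalis,120,140,100,100",
               "s2,CMU,obtusata,140,140,NA,NA"), p)
  d <- read_genotypes(p, "csv")
  expect_equal(d$loci, c("LocA", "LocB"))
  expect_equal(unname(d$a1["s1", ]), c("120", "100"))
  expect_true(is.na(d$a1["s2", "LocB"]) && is.na(d$a2["s2", "LocB"]))
  expect_equal(sum(is.na(d$a1)), 1)

  # round-trip a simulated 50 x 11 dataset bit-identically
  set.seed(42)
  fr <- simulate_parental_frequencies(sim_config(seed = 42))
  sim <- simulate_class("F", 50, fr)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(sim, p2)
  back <- read_genotypes(p2, "csv")
  expect_identical(back$a1, sim$a1)
  expect_identical(back$a2, sim$a2)
  expect_identical(back$meta, sim$meta)
})

test_that("genepop dialect decodes 3-digit allele pairs and flags malformed rows", {
  p <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("title", "LocA", "LocB", "Pop",
               "ind1 , 120140 000000",
               "ind2 , 100100 110112"), p)
  d <- read_genotypes(p, "genepop")
  # unordered pair {120, 140}, stored in canonical order
  expect_equal(unname(c(d$a1[1, 1], d$a2[1, 1])), c("120", "140"))
  expect_true(is.na(d$a1[1, 2]))
  expect_equal(unname(c(d$a1[2, 2], d$a2[2, 2])), c("110", "112"))
  # no samples silently dropped
  expect_equal(n_samples(d), 2L)

  bad <- withr::local_tempfile()
  writeLines(c("title", "LocA", "LocB", "Pop", "ind1 , 12014 100100"), bad)
  expect_error(read_genotypes(bad, "genepop"), "ind1.*LocA")
  bad2 <- withr::local_tempfile()
  writeLines(c("title", "LocA", "LocB", "Pop", "ind1 , 120140"), bad2)
  expect_error(read_genotypes(bad2, "genepop"), "expected 2 loci")

  # genepop round-trip through write_genotypes
  p3 <- withr::local_tempfile()
  write_genotypes(d, p3, "genepop")
  back <- read_genotypes(p3, "genepop")
  expect_identical(back$a1, `rownames<-`(d$a1, rownames(back$a1)))
})

test_that("unordered allele pairs are stored canonically", {
  d1 <- microsat_dataset(rbind("140"), rbind("120"), "L1",
                         data.frame(sample_id = "x"))
  d2 <- microsat_dataset(rbind("120"), rbind("140"), "L1",
                         data.frame(sample_id = "x"))
  expect_identical(d1$a1, d2$a1)
  expect_identical(d1$a2, d2$a2)
})

test_that("fasta reader preserves order, uppercases, and accepts empty files", {
  p <- withr::local_tempfile(fileext = ".fa")
  s <- paste(rep("acgt", 569 / 4 + 1), collapse = "")
  s <- substr(s, 1, 569)
  writeLines(c(">b_sample extra header", s, ">a_sample", toupper(s),
               ">c_sample", s), p)
  a <- read_fasta(p)
  expect_equal(length(a), 3L)
  expect_equal(alignment_width(a), 569L)
  expect_equal(a$ids, c("b_sample", "a_sample", "c_sample"))
  expect_equal(a$seqs[1], toupper(s))

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  e <- read_fasta(empty)
  expect_equal(length(e), 0L)

  ragged <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">y", "ACG"), ragged)
  expect_error(read_fasta(ragged), "ragged")

  # round-trip
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(a, p2)
  expect_identical(read_fasta(p2), a)
})

test_that("tps reader applies SCALE, maps ids, and enforces the landmark count", {
  p <- withr::local_tempfile(fileext = ".tps")
  coords <- cbind(1:28, 28:1)
  block <- c("LM=28", apply(coords, 1, paste, collapse = " "))
  writeLines(c(block, "IMAGE=shell_001.jpg", "SCALE=0.01",
               block, "ID=snailB",
               block), p)
  lm <- read_tps(p)
  expect_equal(dim(lm$coords), c(3, 28, 2))
  expect_equal(lm$coords[1, , ], coords * 0.01)       # SCALE applied
  expect_equal(lm$coords[3, , ], coords * 1)          # no SCALE
  expect_equal(lm$ids, c("shell_001", "snailB", "cfg_3"))

  bad <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=27", apply(coords[1:27, ], 1, paste, collapse = " ")), bad)
  expect_error(read_tps(bad), "LM=27")

  # round-trip
  p2 <- withr::local_tempfile(fileext = ".tps")
  write_tps(lm, p2)
  back <- read_tps(p2)
  expect_equal(back$coords, lm$coords, tolerance = 1e-9)
  expect_equal(back$ids, lm$ids)
})

test_that("slider specification covers exactly the semilandmarks", {
  lm <- landmark_set(matrix(rnorm(56), 28, 2))
  expect_equal(sort(lm$sliders[, 2]), 5:28)
  expect_error(landmark_set(matrix(rnorm(56), 28, 2),
                            sliders = cbind(4, 5, 6)),
               "cover exactly")
})

test_that("genital measurements are validated", {
  df <- data.frame(sample_id = "m1", filament_length = 2,
                   total_penis_length = 5, gland_row_length = 1.5,
                   n_rows = 3, n_glands = 12, penis_width = 1.2,
                   tip_width = 0.5)
  expect_s3_class(genital_measurements(df), "genital_measurements")
  bad <- df; bad$filament_length <- 6
  expect_error(genital_measurements(bad), "filament")
  expect_error(genital_measurements(df[-2]), "missing columns")
})
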