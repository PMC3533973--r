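test_that("slash dialect parses pairs, homozygotes and missing cells", {
  txt <- paste("id,PVCAG-2397/8,PVCAG-2517/8",
               "K4,161/189,213/234",
               "K4-01,161,",
               "K4-02,0,213/213", sep = "\n")
  p <- read_genotype_table(text = txt, dialect = "slash")
  expect_equal(locus_genotype(p, "K4", "PVCAG-2397/8"), c("161", "189"))
  # single value scored as a one-band homozygote
  expect_equal(locus_genotype(p, "K4-01", "PVCAG-2397/8"), c("161", "161"))
  # blank and "0" cells are missing
  expect_length(locus_genotype(p, "K4-01", "PVCAG-2517/8"), 0)
  expect_length(locus_genotype(p, "K4-02", "PVCAG-2397/8"), 0)
})

test_that("two_col dialect treats a half-filled locus as missing, with a warning", {
  txt <- paste("id\tLocAa\tLocAb",
               "S1\t161\t189",
               "S2\t161\t", sep = "\n")
  expect_warning(p <- read_genotype_table(text = txt, dialect = "two_col"),
                 "single filled cell")
  expect_equal(locus_genotype(p, "S1", "LocA"), c("161", "189"))
  expect_length(locus_genotype(p, "S2", "LocA"), 0)
})

test_that("structural errors are reported by name", {
  dup <- "id,L1\nA,1/2\nA,3/4"
  expect_error(read_genotype_table(text = dup, dialect = "slash"),
               "duplicated individual id: A")
  odd <- "id\tL1a\tL1b\tL2a\nA\t1\t2\t3"
  expect_error(read_genotype_table(text = odd, dialect = "two_col"),
               "L2a")
  bad_pair <- "id\tL1a\tL2b\nA\t1\t2"
  expect_error(read_genotype_table(text = bad_pair, dialect = "two_col"),
               "unknown column structure")
})

test_that("every parsed genotype has zero or two allele copies", {
  txt <- paste("id,L1,L2", "A,100/102,", "B,100,104/106", "C,,102", sep = "\n")
  p <- read_genotype_table(text = txt, dialect = "slash")
  for (i in p$individuals$id) {
    for (m in p$markers$id) {
      expect_true(length(locus_genotype(p, i, m)) %in% c(0L, 2L))
    }
  }
})

test_that("write/read round-trips randomized panels in both dialects", {
  for (seed in c(1, 2, 3)) {
    p <- random_panel(seed)
    for (dialect in c("two_col", "slash")) {
      q <- read_genotype_table(text = write_genotype_table(p, dialect),
                               dialect = dialect)
      expect_true(panels_equal(p, q),
                  info = sprintf("seed %d dialect %s", seed, dialect))
    }
  }
})

test_that("writer conventions: header-only empty panel, x/x homozygote, blank missing", {
  empty <- genotype_panel(data.frame(id = character(0)),
                          data.frame(id = c("L1", "L2")),
                          matrix(NA_character_, 0, 2), matrix(NA_character_, 0, 2))
  expect_equal(write_genotype_table(empty, "slash"), "id\tL1\tL2\n")
  p <- genotype_panel(data.frame(id = c("A", "B")), data.frame(id = "L1"),
                      matrix(c("161", NA), 2, 1), matrix(c("161", NA), 2, 1))
  lines <- strsplit(write_genotype_table(p, "slash"), "\n")[[1]]
  expect_equal(lines[2], "A\t161/161")
  expect_equal(lines[3], "B\t")
})

test_that("marker table reader reproduces the packaged 48-marker duplex panel", {
  m <- read_marker_table(table2_path())
  expect_equal(nrow(m), 48L)
  expect_equal(length(unique(m$duplex_set)), 24L)
  row <- m[m$id == "PVAAG-3163/4", ]
  expect_equal(row$size_min_bp, 211)
  expect_equal(row$size_max_bp, 293)
  expect_equal(row$pic, 0.925)
  expect_equal(row$linkage_group, "5b")
  expect_equal(row$n_alleles, 19)
  expect_equal(m[m$id == "SWW-387", ]$pic, 0.622)
})

test_that("marker table reader flags malformed size ranges with the row number", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("ssr_id\tsize_range", "M1\t156-195", "M2\t211to293"), tmp)
  expect_error(read_marker_table(tmp), "row 2")
  writeLines(c("ssr_id\tsize_range\tpic", "M1\t156-195\t1.2"), tmp)
  expect_error(read_marker_table(tmp), "pic")
})

test_that("allele sizes outside a marker's declared range warn but do not fail", {
  markers <- data.frame(id = "L1", size_min_bp = 100, size_max_bp = 120)
  expect_warning(
    genotype_panel(data.frame(id = "A"), markers,
                   matrix("150", 1, 1), matrix("100", 1, 1)),
    "outside declared marker range")
})

test_that("band letter codes follow the maternal a/b, size-descending c,d,... scheme", {
  # maternal heterozygote: upper band a, lower band b
  enc <- encode_band_letters(c(189, 161), list(p1 = c(189, 161)))
  expect_equal(enc$mother, "ab")
  expect_equal(unname(enc$progeny["p1"]), "ab")
  # single non-maternal band is the largest and gets "c"
  enc <- encode_band_letters(c(189, 161), list(p1 = c(200, 161)))
  expect_equal(unname(enc$progeny["p1"]), "cb")
  # non-maternal sizes lettered jointly across progeny, in decreasing size
  enc <- encode_band_letters(c(189, 161),
                             list(p1 = c(210, 140), p2 = c(195, 161)))
  expect_equal(enc$letters[["210"]], "c")
  expect_equal(enc$letters[["195"]], "d")
  expect_equal(enc$letters[["140"]], "e")
  expect_equal(unname(enc$progeny), c("ce", "db"))
  # maternal homozygote is "aa"
  expect_equal(encode_band_letters(c(161, 161), list())$mother, "aa")
})

test_that("letter assignment is invariant to progeny order and shares letters for equal sizes", {
  prog <- list(a = c(210, 140), b = c(195, 161), c = c(210, 161))
  enc1 <- encode_band_letters(c(189, 161), prog)
  enc2 <- encode_band_letters(c(189, 161), rev(prog))
  expect_identical(enc1$letters, enc2$letters)
  expect_identical(enc1$progeny[names(prog)], enc2$progeny[names(prog)])
  # 210 appears in two progeny but gets a single letter
  expect_equal(sum(enc1$letters == "c"), 1L)
})
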