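test_that("haplotype tables round-trip through TSV files", {
  reps <- matrix(c(14L, 15L, 13L, 12L, 14L, 13L), nrow = 2, byrow = TRUE)
  colnames(reps) <- default_loci()[1:3]
  tab <- haplotype_table(c("a1", "a2"), c("Lebanon", "Syria"),
                         c("J1", "J2"), reps)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_table(tab, path)
  back <- read_haplotype_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_identical(attr(back, "loci"), attr(tab, "loci"))
  # byte-stable on rewrite
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("an empty (header-only) haplotype file round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("sample_id", "population", "haplogroup",
                     default_loci()), collapse = "\t"), path)
  tab <- read_haplotype_table(path)
  expect_equal(nrow(tab), 0L)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_table(tab, path2)
  expect_equal(nrow(read_haplotype_table(path2)), 0L)
})

test_that("missing repeats are flagged and excluded from denominators", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpopulation\thaplogroup\tDYS392\tDYS438",
               "a\tX\tJ\t10\t12",
               "b\tX\tJ\t?\t13",
               "c\tX\tJ\t12\t14"), path)
  tab <- read_haplotype_table(path)
  expect_true(is.na(loci_matrix(tab)["b", "DYS392"]))
  v <- str_variance(tab)
  # DYS392: var(10, 12) = 2 (n-1 denominator over the 2 observed values);
  # DYS438: var(12, 13, 14) = 1
  expect_equal(v$mean_variance, mean(c(2, 1)))
})

test_that("validation rejects corrupted tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpopulation\thaplogroup\tDYS392",
               "a\tX\tJ\tten"), path)
  expect_error(read_haplotype_table(path), "malformed")
  writeLines(c("sample_id\tpopulation\thaplogroup\tDYS392",
               "a\tX\tJ\t10", "a\tX\tJ\t11"), path)
  expect_error(read_haplotype_table(path), "duplicate")
  writeLines(c("sample_id\tpopulation\thaplogroup\tDYS392",
               "a\tX\tJ\t99"), path)
  expect_error(read_haplotype_table(path), "out of range")
  writeLines(c("sample_id\tpopulation\thaplogroup\tDYS392",
               "a\tX\tJ\t10"), path)
  expect_error(read_haplotype_table(path, locus_spec = c("DYS392", "DYS19")),
               "locus")
})

test_that("pooling files map populations uniquely to the regional scheme", {
  path <- withr::local_tempfile(fileext = ".tsv")
  pops <- c("Saudi Arabia", "Yemen", "Armenia", "Georgia", "Iran", "Cyprus",
            "Jordan", "Lebanon", "Egypt", "Libya", "Ethiopia")
  regions <- c("Arabia", "Yemen", "Armenia+Turkey", "Caucasus", "Mesopotamia",
               "Cyprus", "Southern Levant", "Northern Levant", "Egypt",
               "North Africa", "Ethiopia")
  writeLines(c("population\tregion", paste(pops, regions, sep = "\t")), path)
  pool <- read_pooling(path)
  expect_equal(nrow(pool), 11L)
  expect_setequal(unique(pool$region), regions)
  expect_equal(region_of(pool, "Lebanon"), "Northern Levant")
  # singleton pooling
  expect_equal(nrow(population_pooling("Lebanon", "Levant")), 1L)
  # duplicated population is rejected
  writeLines(c("population\tregion", "Lebanon\tA", "Lebanon\tB"), path)
  expect_error(read_pooling(path), "more than one region")
})

test_that("distance matrices survive PHYLIP round trips at high precision", {
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m[1, 2] <- m[2, 1] <- 0.123456789
  m[1, 3] <- m[3, 1] <- 2.5
  m[2, 3] <- m[3, 2] <- 1e-4
  D <- dist_matrix(m)
  path <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(D, path)
  back <- read_distance_matrix(path)
  expect_equal(unclass(back), unclass(D), tolerance = 1e-9)
  expect_equal(back["a", "b"], 0.123456789, tolerance = 1e-10)
  # 1x1 matrix
  one <- dist_matrix(matrix(0, 1, 1, dimnames = list("x", "x")))
  write_distance_matrix(one, path)
  b1 <- read_distance_matrix(path)
  expect_equal(rownames(b1), "x")
  expect_equal(unname(b1[1, 1]), 0)
  # asymmetric input is rejected
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(dist_matrix(bad), "symmetric")
})

test_that("haplogroup trees resolve labels and reject cycles", {
  tr <- haplogroup_tree(c("J", "J1", "J2", "J1e", "J2a"),
                        c(NA, "J", "J", "J1", "J2"))
  expect_equal(haplogroup_at_depth(tr, c("J1e", "J2a", "J"), 1),
               c("J1", "J2", "J"))
  expect_error(haplogroup_tree(c("A", "B"), c("B", "A")), "root")
  expect_error(haplogroup_at_depth(tr, "E1b1b1", 1), "not in tree")
})
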