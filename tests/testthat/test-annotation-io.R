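test_that("Prokka TSV reader parses rows, EC cells and empty files", {
  path <- write_prokka_fixture(c(
    "g_001\tCDS\t900\t\t3.8.1.5\t\thaloalkane dehalogenase",
    "g_002\tCDS\t1200\t\t\t\thypothetical protein",
    "g_003\ttRNA\t75\t\t\t\ttRNA-Ala",
    "g_004\tCDS\t800\t\t3.8.1.5 1.14.19.9\t\tbifunctional protein",
    "g_005\tCDS\t650\t\t2.5.1.18\t\tglutathione transferase"
  ))
  tab <- read_prokka_tsv(path, "sA", "metagenome", 5e6)
  expect_s3_class(tab, "annotation_table")
  expect_equal(nrow(tab$features), 5L)
  expect_equal(tab$features$locus_tag, sprintf("g_%03d", 1:5))
  expect_equal(sum(lengths(tab$features$ec_numbers) > 0), 3L)
  # whitespace-separated multi-EC cell
  expect_setequal(tab$features$ec_numbers[[4]], c("3.8.1.5", "1.14.19.9"))
  # comma-separated variant parses identically
  path2 <- write_prokka_fixture("g_001\tCDS\t800\t\t3.8.1.5,1.14.19.9\t\tp")
  expect_setequal(read_prokka_tsv(path2, "s", "mag", 1e6)$
                    features$ec_numbers[[1]],
                  c("3.8.1.5", "1.14.19.9"))

  empty <- write_prokka_fixture(character(0))
  expect_equal(nrow(read_prokka_tsv(empty, "s", "metagenome", 1e6)$features),
               0L)
})

test_that("Prokka TSV reader rejects malformed tables", {
  no_col <- tempfile(fileext = ".tsv")
  writeLines(c("locus_tag\tftype\tlength_bp", "g1\tCDS\t100"), no_col)
  expect_error(read_prokka_tsv(no_col, "s", "mag", 1e6), "EC_number")

  dup <- write_prokka_fixture(c("g1\tCDS\t100\t\t\t\tp",
                                "g1\tCDS\t200\t\t\t\tp"))
  expect_error(read_prokka_tsv(dup, "s", "mag", 1e6), "duplicate locus_tag")

  neg <- write_prokka_fixture(c("g1\tCDS\t100\t\t\t\tp",
                                "g2\tCDS\t0\t\t\t\tp"))
  expect_error(read_prokka_tsv(neg, "s", "mag", 1e6), "row.*2")

  expect_error(read_prokka_tsv(write_prokka_fixture("g1\tCDS\t10\t\t\t\tp"),
                               "s", "mag", 0), "size_bp")
})

test_that("GFF3 reader parses attributes and flags bad intervals", {
  gff <- tempfile(fileext = ".gff")
  writeLines(c(
    "##gff-version 3",
    paste("c1", "x", "CDS", "1", "900", ".", "+", "0",
          "ID=g_001;locus_tag=g_001;eC_number=3.8.1.5;product=haloalkane dehalogenase",
          sep = "\t")
  ), gff)
  tab <- read_gff3(gff, "s", "mag", 2e6)
  expect_equal(nrow(tab$features), 1L)
  expect_equal(tab$features$ec_numbers[[1]], "3.8.1.5")
  expect_equal(tab$features$length_bp, 900)

  bad <- tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3",
               paste("c1", "x", "CDS", "900", "1", ".", "+", "0",
                     "ID=g1", sep = "\t")), bad)
  expect_error(read_gff3(bad, "s", "mag", 2e6), "start > end")

  noid <- tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3",
               paste("c1", "x", "CDS", "1", "9", ".", "+", "0",
                     "product=orphan", sep = "\t")), noid)
  expect_error(read_gff3(noid, "s", "mag", 2e6), "locus_tag nor an ID")
})

test_that("TSV and GFF3 exports of the same annotation read identically", {
  set.seed(11)
  spec <- random_exact_spec(11, the_catalog)
  bundle <- simulate_bundle(spec, the_catalog)
  dir <- tempfile()
  write_bundle(bundle, dir)
  for (sid in names(bundle$tables)) {
    size <- bundle$tables[[sid]]$size_bp
    a <- read_prokka_tsv(file.path(dir, "annotations", paste0(sid, ".tsv")),
                         sid, "metagenome", size)
    b <- read_gff3(file.path(dir, "annotations", paste0(sid, ".gff")),
                   sid, "metagenome", size)
    expect_equal(a$features$locus_tag, b$features$locus_tag)
    expect_equal(a$features$ftype, b$features$ftype)
    expect_equal(a$features$ec_numbers, b$features$ec_numbers)
    expect_equal(a$features$product, b$features$product)
  }
})

test_that("MAG metadata reader enforces ranges and GTDB shape", {
  path <- tempfile(fileext = ".tsv")
  write.table(rbind(
    mag_row("m1", completeness = 92.4, contamination = 1.1,
            gtdb = "d__Bacteria;p__Proteobacteria;c__;o__;f__;g__;s__"),
    mag_row("m2", completeness = 55, contamination = 8,
            gtdb = "unclassified")
  ), path, sep = "\t", quote = FALSE, row.names = FALSE)
  mags <- read_mag_metadata(path)
  expect_equal(nrow(mags), 2L)
  ranks <- parse_gtdb(mags$gtdb_classification[1])
  expect_equal(ranks$phylum, "Proteobacteria")
  expect_equal(sum(!nzchar(as.character(ranks[1, ])), na.rm = TRUE), 5L)

  bad <- tempfile(fileext = ".tsv")
  write.table(mag_row("m9", completeness = 104), bad, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_mag_metadata(bad), "completeness")

  badg <- tempfile(fileext = ".tsv")
  write.table(mag_row("mg", gtdb = "d__Bacteria;p__Proteobacteria"), badg,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mag_metadata(badg), "mg")
})

test_that("tree reader reports unmatched leaves and parse failures", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("(A,(B,C));", nwk)
  mags3 <- do.call(rbind, lapply(c("A", "B", "C"), mag_row))
  tr <- read_tree(nwk, mags3)
  expect_equal(sort(tr$leaves), c("A", "B", "C"))
  expect_length(tr$unmatched_leaves, 0)

  tr2 <- read_tree(nwk, mags3[1:2, ])
  expect_equal(tr2$unmatched_leaves, "C")
  expect_length(tr2$missing_mags, 0)

  broken <- tempfile(fileext = ".nwk")
  writeLines("(A,(B,C)", broken)
  expect_error(read_tree(broken), "Newick")
})

test_that("result tables round-trip losslessly, digit grouping strips", {
  df <- data.frame(sample_id = "s", key = c("a", "b"), level = "function",
                   n_genes = c(3L, 7L),
                   density = c(3 / 3.2, 7 / 3.2),
                   density_display = round(c(3 / 3.2, 7 / 3.2), 2),
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_result_tsv(df, path)
  back <- read_result_tsv(path)
  expect_identical(back$density, df$density)  # bit-exact via %.17g
  expect_equal(back$density_display, df$density_display)

  expect_equal(strip_digit_grouping("784.246.579"), 784246579)
  expect_equal(strip_digit_grouping("435,330,334"), 435330334)
  expect_error(strip_digit_grouping("12.3a"), "grouping")
})
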