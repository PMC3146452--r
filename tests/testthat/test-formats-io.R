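test_that("promoter FASTA reading validates, normalizes and round-trips", {
  fa <- withr::local_tempfile(fileext = ".fa")
  seq1 <- paste(rep("ACGT", 500), collapse = "")
  writeLines(c(">p1 mirna=mir-1 strand=-", seq1, ">p2", "acgtacgtnn"), fa)
  prom <- read_promoter_fasta(fa)
  expect_equal(nrow(prom), 2L)
  expect_equal(nchar(prom$sequence[1]), 2000L)
  expect_equal(prom$mirna_id[1], "mir-1")
  expect_equal(prom$strand, c("-", "+"))
  # lowercase input is uppercased
  expect_equal(prom$sequence[2], "ACGTACGTNN")

  out <- withr::local_tempfile(fileext = ".fa")
  write_promoter_fasta(prom, out)
  again <- read_promoter_fasta(out)
  expect_equal(again, prom)

  expect_error(read_promoter_fasta(fa, expected_length = 2000), "p2")
  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1", "ACGTX"), bad)
  expect_error(read_promoter_fasta(bad), "p1.*offset 4")
  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1", "ACGT", ">p1", "ACGT"), dup)
  expect_error(read_promoter_fasta(dup), "duplicate")
})

test_that("pseudocount normalization matches the closed form", {
  # first position has counts (4,0,0,0): with pc=0 the frequencies are
  # (1,0,0,0); with pc=1 they are (5/8,1/8,1/8,1/8)
  counts <- rbind(c(4, 0, 0, 0), c(1, 1, 1, 1), c(0, 2, 2, 0), c(8, 0, 0, 0))
  m0 <- motif_matrix("m", counts, pseudocount = 0)
  expect_equal(unname(m0$freq[1, ]), c(1, 0, 0, 0))
  m1 <- motif_matrix("m", counts, pseudocount = 1)
  expect_equal(unname(m1$freq[1, ]), c(5, 1, 1, 1) / 8)
  expect_equal(unname(rowSums(m1$freq)), rep(1, 4), tolerance = 1e-12)
  expect_error(motif_matrix("m", rbind(counts, c(0, 0, 0, 0)),
                            pseudocount = 0), "zero total count")
})

test_that("JASPAR PFM parsing matches a hand-parsed fixture", {
  pfm <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(
    ">M001 TFA",
    "A [ 4 0 0 2 ]",
    "C [ 0 4 0 1 ]",
    "G [ 0 0 4 1 ]",
    "T [ 0 0 0 0 ]",
    ">M002 TFB",
    "1 2 3 4 5",
    "0 0 0 0 0",
    "1 1 1 1 1",
    "2 1 0 1 2",
    ">M003",
    "9 0 0 0 0 9",
    "0 9 0 0 9 0",
    "0 0 9 9 0 0",
    "0 0 0 0 0 0"), pfm)
  lib <- read_motif_library(pfm, "jaspar_pfm", pseudocount = 0.5)
  expect_length(lib, 3L)
  expect_equal(vapply(lib, `[[`, integer(1), "width"),
               c(M001 = 4L, M002 = 5L, M003 = 6L))
  expect_equal(lib$M001$tf_name, "TFA")
  expect_equal(lib$M003$tf_name, "M003")  # defaults to motif_id
  # hand-parsed: position 3 of M001 has counts A=0,C=0,G=4,T=0
  expect_equal(unname(lib$M001$counts[3, ]), c(0, 0, 4, 0))
  expect_equal(unname(lib$M002$counts[, 1]), c(1, 2, 3, 4, 5))
  expect_equal(unname(rowSums(lib$M003$freq)), rep(1, 6), tolerance = 1e-12)
})

test_that("minimal TRANSFAC dialect parses and errors carry line numbers", {
  tf <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(
    "ID MAT1",
    "BF factor one",
    "P0  A  C  G  T",
    "01  4  0  0  0  A",
    "02  0  4  0  0  C",
    "03  1  1  1  1  N",
    "04  0  0  0  4  T",
    "//",
    "ID MAT2",
    "PO  A  C  G  T",
    "01  1  2  3  4",
    "02  4  3  2  1",
    "03  1  1  1  1",
    "04  2  2  2  2",
    "//"), tf)
  lib <- read_motif_library(tf, "transfac_dialect", pseudocount = 0)
  expect_equal(names(lib), c("MAT1", "MAT2"))
  expect_equal(lib$MAT1$tf_name, "factor one")
  expect_equal(unname(lib$MAT1$counts[2, ]), c(0, 4, 0, 0))
  expect_equal(unname(lib$MAT2$counts[1, ]), c(1, 2, 3, 4))

  bad <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("ID X", "01 1 2 zz 4", "//"), bad)
  expect_error(read_motif_library(bad, "transfac_dialect"), "line 2")
  unterminated <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("ID X", "01 1 2 3 4"), unterminated)
  expect_error(read_motif_library(unterminated, "transfac_dialect"),
               "unterminated")
})

test_that("conservation wiggle IO masks uncovered bases and round-trips", {
  prom <- make_promoters(c(paste(rep("A", 2000), collapse = ""),
                           paste(rep("C", 50), collapse = "")),
                         ids = c("p1", "p2"))
  wig <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=p1 start=1 step=1",
               formatC(rep(1, 2000), format = "f"),
               "fixedStep chrom=p2 start=1 step=1",
               formatC(seq(0, 1, length.out = 30), format = "f", digits = 6)),
             wig)
  tracks <- read_conservation_wig(wig, prom)
  expect_equal(tracks$p1, rep(1, 2000))
  expect_equal(sum(is.na(tracks$p2)), 20L)  # positions 31-50 missing
  expect_equal(tracks$p2[1:30], seq(0, 1, length.out = 30), tolerance = 1e-5)

  out <- withr::local_tempfile(fileext = ".wig")
  write_conservation_wig(tracks, out)
  again <- read_conservation_wig(out, prom)
  expect_equal(again$p1, tracks$p1, tolerance = 1e-6)
  expect_equal(again$p2, tracks$p2, tolerance = 1e-6)

  bad <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=p2 start=1 step=1", "0.5", "1.5"), bad)
  expect_error(read_conservation_wig(bad, prom), "outside \\[0,1\\]")
  long <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=p2 start=45 step=1",
               rep("0.5", 10)), long)
  expect_error(read_conservation_wig(long, prom), "extends")
})

test_that("Ct, presence and locus tables validate and round-trip", {
  vals <- matrix(c(18, 18.5, 30, 31, 25, 24, 26, 27), nrow = 2, byrow = TRUE,
                 dimnames = list(c("hsa-let-7a", "miR-x"),
                                 c("monocyte.D1", "monocyte.D2",
                                   "iDC.D1", "iDC.D2")))
  ct <- ct_matrix(vals[, 1:4], c("monocyte", "monocyte", "iDC", "iDC"),
                  c("D1", "D2", "D1", "D2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(ct, path)
  again <- read_ct_table(path)
  expect_equal(again$values, ct$values)
  expect_equal(again$samples, ct$samples)

  small <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tmonocyte.D1\tmonocyte.D2\tiDC.D1\tiDC.D2",
               "hsa-let-7a\t18\t18\t18\t18",
               "a\t20\t21\t22\t23", "b\t30\t31\t32\t33", "c\t25\t25\t25\t25"),
             small)
  m <- read_ct_table(small)
  expect_equal(dim(m$values), c(4L, 4L))
  badct <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\tmonocyte.D1", "hsa-let-7a\toops"), badct)
  expect_error(read_ct_table(badct), "non-numeric")

  pres <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf\tcall", "TFA\tPresent", "TFB\tMARGINAL", "TFC\tabsent"),
             pres)
  pt <- read_presence_table(pres)
  expect_equal(pt$call, c("present", "marginal", "absent"))
  badp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf\tcall", "TFA\tmaybe"), badp)
  expect_error(read_presence_table(badp), "unknown presence")

  # annotation shape: more promoters than miRNAs is legitimate
  loc <- withr::local_tempfile(fileext = ".tsv")
  mir <- sprintf("mir_%02d", c(1:27, 1:4))
  prm <- sprintf("prom_%02d", 1:31)
  writeLines(c("mirna_id\tpromoter_id", paste(mir, prm, sep = "\t")), loc)
  lt <- read_locus_table(loc)
  expect_equal(length(unique(lt$promoter_id)), 31L)
  expect_equal(length(unique(lt$mirna_id)), 27L)
})

test_that("hit files use half-open intervals and round-trip", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_hits(data.frame(), path)
  expect_equal(readLines(path), paste(c("promoter_id", "start", "end",
                                        "motif_id", "instance_score",
                                        "strand", "conservation_score"),
                                      collapse = "\t"))
  hits <- data.frame(promoter_id = c("p2", "p1"), start = c(10L, 3L),
                     width = c(8L, 5L), motif_id = "M1",
                     instance_score = c(7.25, 6.5), strand = c("+", "-"),
                     conservation_score = c(0.9, NA),
                     stringsAsFactors = FALSE)
  write_hits(hits, path)
  back <- read_hits(path)
  expect_equal(back$start, c(3L, 10L))      # stable sort by promoter, start
  expect_equal(back$end, c(8L, 18L))        # end = start + width, half-open
  expect_equal(back$width, c(5L, 8L))
  expect_equal(back$conservation_score, c(NA, 0.9))
})
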