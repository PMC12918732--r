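## HMMER3 profile, FASTA, tblout, taxonomy and Newick readers/writers.

minimal_hmm_text <- function(nc_line = "NC    25.00 25.00;") {
  u <- paste(rep(sprintf("%.5f", log(20)), 20), collapse = "  ")  # uniform
  tr <- paste(sprintf("%.5f", -log(c(0.95, 0.02, 0.03, 0.9, 0.1, 0.9, 0.1))),
              collapse = "  ")
  trM <- paste(c(sprintf("%.5f", -log(c(0.98, 0.02))), "*",
                 sprintf("%.5f", -log(c(0.9, 0.1))), "0.00000", "*"),
               collapse = "  ")
  peaked <- function(letter) {
    p <- rep((1 - 0.9) / 19, 20); p[match(letter, amino_alphabet())] <- 0.9
    paste(sprintf("%.5f", -log(p)), collapse = "  ")
  }
  c("HMMER3/f [toy]", "NAME  mini", "ACC   MINI001", "LENG  2", "ALPH  amino",
    nc_line,
    "HMM  A C D E F G H I K L M N P Q R S T V W Y",
    "     m->m m->i m->d i->m i->i d->m d->d",
    paste("  COMPO", u), paste("   ", u), paste("   ", tr),
    paste("  1", peaked("A"), "1 A - - -"), paste("   ", u), paste("   ", tr),
    paste("  2", peaked("C"), "2 C - - -"), paste("   ", u), paste("   ", trM),
    "//")
}

test_that("a minimal hand-written profile parses with normalised rows and NC cutoff", {
  f <- withr::local_tempfile(fileext = ".hmm")
  writeLines(minimal_hmm_text(), f)
  hmm <- parse_hmmer3(f)[[1]]
  expect_equal(hmm$M, 2L)
  expect_equal(hmm$name, "mini")
  expect_equal(hmm$acc, "MINI001")
  expect_true(all(abs(rowSums(hmm$match) - 1) < 1e-4))
  expect_true(all(abs(rowSums(hmm$insert) - 1) < 1e-4))
  expect_equal(hmm$cutoffs$NC, c(25, 25))
  expect_equal(hmm_consensus(hmm), "AC")
})

test_that("write/parse round trips preserve probabilities within 1e-6 and map cutoffs", {
  h <- make_hmm("ACDEFGHIKLMN", seed = 11, name = "rt")
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(h, f)
  h2 <- parse_hmmer3(f)[[1]]
  expect_lt(max(abs(h$match - h2$match)), 1e-6)
  expect_lt(max(abs(h$insert - h2$insert)), 1e-6)
  expect_lt(max(abs(h$trans - h2$trans)), 1e-6)
  expect_lt(max(abs(h$background - h2$background)), 1e-6)
  expect_equal(h2$cutoffs$NC, round(h$cutoffs$NC, 2))
  expect_equal(names(h2$cutoffs), c("GA", "TC", "NC"))
  expect_equal(h2$stats$viterbi, round(h$stats$viterbi, 5))

  ## no cutoffs -> no GA/TC/NC lines; NC only -> exactly one cutoff line
  h$cutoffs <- NULL
  write_hmmer3(h, f)
  expect_false(any(grepl("^(GA|TC|NC)\\b", readLines(f))))
  expect_null(parse_hmmer3(f)[[1]]$cutoffs)
  h$cutoffs <- list(NC = c(12.5, 12.5))
  write_hmmer3(h, f)
  expect_equal(sum(grepl("^(GA|TC|NC)\\b", readLines(f))), 1L)

  ## multi-record files round trip too
  write_hmmer3(make_hmm("ACD", seed = 1, name = "a", calibrate = FALSE), f)
  write_hmmer3(make_hmm("DEF", seed = 2, name = "b", calibrate = FALSE), f, append = TRUE)
  expect_equal(vapply(parse_hmmer3(f), `[[`, character(1), "name"), c("a", "b"))
})

test_that("malformed profile files raise named parse errors with line numbers", {
  f <- withr::local_tempfile(fileext = ".hmm")
  writeLines(sub("ALPH  amino", "ALPH  DNA", minimal_hmm_text()), f)
  expect_error(parse_hmmer3(f), class = "acetoscan_parse_error")
  writeLines(sub("^HMMER3/f.*", "HMMER2.0", minimal_hmm_text()), f)
  expect_error(parse_hmmer3(f), "HMMER3", class = "acetoscan_parse_error")
  txt <- minimal_hmm_text()
  txt[10] <- paste(txt[10], "0.5")  # node-0 insert row with 21 values
  writeLines(txt, f)
  err <- tryCatch(parse_hmmer3(f), error = function(e) e)
  expect_s3_class(err, "acetoscan_parse_error")
  expect_match(conditionMessage(err), "line 10")
})

test_that("a profile built by an external HMMER binary parses and validates", {
  hmmbuild <- Sys.which("hmmbuild")
  msa <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "s1 ACDEFGHIKLMNPQRSTVWY",
               "s2 ACDEFGHIKLMNPQRSTVWY",
               "s3 ACDEYGHIKLMNPQRSTVWY", "//"), msa)
  out <- withr::local_tempfile(fileext = ".hmm")
  system2(hmmbuild, c("--amino", shQuote(out), shQuote(msa)),
          stdout = FALSE, stderr = FALSE)
  hmm <- parse_hmmer3(out)[[1]]
  expect_equal(hmm$M, 20L)
  expect_true(all(abs(rowSums(hmm$match) - 1) < 1e-4))
  expect_false(is.null(hmm$stats$viterbi))
  ## and our rewritten copy parses back identically
  f2 <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(hmm, f2)
  hmm2 <- parse_hmmer3(f2)[[1]]
  expect_lt(max(abs(hmm$match - hmm2$match)), 1e-6)
})

test_that("FASTA proteomes load uppercased with unique ids and a clean alphabet", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1 some description", "acdefg", ">p2", "MKLV"), f)
  prot <- read_fasta(f, "G1")
  expect_equal(prot$protein_id, c("p1", "p2"))
  expect_equal(prot$seq, c("ACDEFG", "MKLV"))
  expect_equal(prot$genome_id, c("G1", "G1"))

  writeLines(c(">p1", "ACDE", ">p1", "MKLV"), f)
  expect_error(read_fasta(f, "G1"), "duplicate", class = "acetoscan_parse_error")
  writeLines(c(">p1", "ACDEO"), f)  # O is not a standard residue
  expect_error(read_fasta(f, "G1"), "illegal", class = "acetoscan_parse_error")
  writeLines(c(">p1", "ACDXE"), f)  # but ambiguous X is fine
  expect_equal(read_fasta(f, "G1")$seq, "ACDXE")
  writeLines(character(0), f)
  expect_error(read_fasta(f, "G1"), class = "acetoscan_parse_error")
})

test_that("tblout tables parse, skipping comments and catching bad numbers", {
  f <- withr::local_tempfile(fileext = ".tbl")
  cmt <- rep("# comment line", 5)
  row <- function(t, q, e, b)
    paste(t, "-", q, "-", e, b, "0.1 1 1 0 0 0 1 1 -", sep = "  ")
  writeLines(c(cmt, row("prot1", "hmmA", "1.2e-45", "150.2"),
               row("prot2", "hmmA", "0.5", "10.0"),
               row("prot1", "hmmB", "3e-7", "55.5"), cmt), f)
  hits <- parse_tblout(f)
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$e_value[1], 1.2e-45)
  expect_equal(hits$bit_score[3], 55.5)
  expect_equal(hits$hmm_name, c("hmmA", "hmmA", "hmmB"))

  writeLines(cmt, f)
  expect_equal(nrow(parse_tblout(f)), 0L)
  writeLines(row("p", "h", "abc", "1.0"), f)
  expect_error(parse_tblout(f), "non-numeric", class = "acetoscan_parse_error")
})

test_that("GTDB taxonomy strings split into validated ranks", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste0("G1\td__Archaea;p__Halobacteriota;c__Methanosarcinia;",
                      "o__X;f__Y;g__Methanosarcina;s__Z"),
               paste0("RS_GCF_1\td__Archaea;p__Halobacteriota;c__Methanosarcinia;",
                      "o__X;f__Y;g__Methanothrix;s__")), f)
  tax <- parse_gtdb_taxonomy(f)
  expect_equal(tax$genus, c("Methanosarcina", "Methanothrix"))
  expect_equal(tax$species[2], "")          # empty species stored, no error
  expect_equal(tax$genome_id[2], "GCF_1")   # RS_ prefix stripped

  writeLines("G1\td__A;p__B;c__C;o__D;f__E;g__F", f)  # 6 ranks
  expect_error(parse_gtdb_taxonomy(f), "7 ranks", class = "acetoscan_parse_error")
  writeLines("G1\td__A;c__B;p__C;o__D;f__E;g__F;s__G", f)  # swapped prefixes
  expect_error(parse_gtdb_taxonomy(f), "prefix", class = "acetoscan_parse_error")
})

test_that("Newick trees read, write and round trip; imbalance is caught", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A,(B,C));", f)
  tr <- read_newick(f)
  expect_setequal(tr$tip.label, c("A", "B", "C"))

  tr20 <- withr::with_seed(7, ape::rtree(20))
  write_newick(tr20, f)
  expect_setequal(read_newick(f)$tip.label, tr20$tip.label)

  writeLines("(A,(B,C);", f)
  expect_error(read_newick(f), "unbalanced", class = "acetoscan_parse_error")
})
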