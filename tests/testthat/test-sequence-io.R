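writeTempFasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

test_that("FASTA import normalizes, rejects and reports", {
  fa <- writeTempFasta(list(x = "acgtacgt", y = "ACGN", z = "ACGU", ok = "ACGUACGUA"))
  seqs <- readFastaSequences(fa, minLength = 5)
  expect_setequal(names(seqs), c("x", "ok"))
  expect_identical(as.character(seqs[["x"]]), "ACGUACGU")
  rej <- S4Vectors::metadata(seqs)$rejected
  expect_identical(rej$reason[rej$id == "y"], "invalid_alphabet")
  expect_identical(rej$reason[rej$id == "z"], "too_short")
})

test_that("FASTA import errors on duplicates and empty results", {
  fa <- writeTempFasta(list(a = "ACGUA"))
  lines <- readLines(fa)
  writeLines(c(lines, lines), fa)
  expect_error(readFastaSequences(fa), "duplicate")
  fa2 <- writeTempFasta(list(a = "NNNNN"))
  expect_error(readFastaSequences(fa2), "no sequences remain")
})

test_that("FASTA round-trip preserves ids and residues", {
  set.seed(42)
  seqs <- vapply(1:8, function(i)
    paste(sample(c("A", "C", "G", "U"), sample(5:40, 1), TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("s", 1:8)
  x <- Biostrings::RNAStringSet(seqs)
  path <- withr::local_tempfile(fileext = ".fa")
  writeFastaSequences(x, path)
  y <- readFastaSequences(path)
  expect_identical(as.character(y), as.character(x))
})

test_that("label import matches ids, warns on orphans, errors on conflicts", {
  fa <- writeTempFasta(list(x = "ACGUA", y = "ACGUA", z = "ACGUA"))
  seqs <- readFastaSequences(fa)
  lab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("x\tnucleus", "y\tcytoplasm", "z\tnucleus"), lab)
  ds <- readLabels(lab, seqs)
  expect_identical(classSet(ds), c("cytoplasm", "nucleus"))
  expect_identical(as.integer(classCounts(ds)), c(1L, 2L))

  writeLines(c("x\tnucleus", "y\tcytoplasm", "z\tnucleus", "q\texosome"), lab)
  expect_warning(ds2 <- readLabels(lab, seqs), "unknown sequence id")
  expect_identical(length(ds2), 3L)

  writeLines(c("x\tnucleus", "x\texosome", "y\tcytoplasm", "z\tnucleus"), lab)
  expect_error(readLabels(lab, seqs), "conflicting")
})

test_that("minimum class size filter keeps the boundary and is idempotent", {
  seqs <- setNames(rep("ACGUACGUA", 21), paste0("s", 1:21))
  labels <- setNames(c(rep("A", 12), rep("B", 9)), names(seqs))
  ds <- labelledSequenceSet(seqs, labels)
  f <- filterMinClassSize(ds, 10)
  expect_identical(classSet(f), "A")
  expect_identical(length(f), 12L)
  # boundary: exactly 10 is retained
  ds10 <- labelledSequenceSet(seqs[1:10], setNames(rep("A", 10), names(seqs)[1:10]))
  expect_identical(length(filterMinClassSize(ds10, 10)), 10L)
  # idempotent
  f2 <- filterMinClassSize(f, 10)
  expect_identical(names(sequences(f2)), names(sequences(f)))
  # everything below threshold -> error
  small <- labelledSequenceSet(seqs[1:5],
    setNames(c(rep("A", 3), rep("B", 2)), names(seqs)[1:5]))
  expect_error(filterMinClassSize(small, 10), "no classes remain")
})

test_that("redundancy filter collapses duplicates and keeps dissimilar sequences", {
  x <- Biostrings::RNAStringSet(c(a = "ACGUACGUACGU", b = "ACGUACGUACGU"))
  expect_identical(length(greedyRedundancyFilter(x)), 1L)
  y <- Biostrings::RNAStringSet(c(a = "AAAAAAAAAA", b = "CCCCCCCCCC"))
  expect_identical(length(greedyRedundancyFilter(y, 0.8)), 2L)
})

test_that("redundancy filter matches a brute-force greedy clustering", {
  wordSim <- function(short, long, w = 5L) {
    kms <- function(s) unique(substring(s, 1:(nchar(s) - w + 1), w:nchar(s)))
    a <- kms(short)
    sum(a %in% kms(long)) / length(a)
  }
  bruteCluster <- function(seqs, thr) {
    ord <- order(-nchar(seqs))
    reps <- integer(0)
    assign <- integer(length(seqs))
    for (i in ord) {
      hit <- 0L
      for (r in seq_along(reps)) {
        if (wordSim(seqs[i], seqs[reps[r]]) >= thr) { hit <- r; break }
      }
      if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
      assign[i] <- hit
    }
    assign
  }
  set.seed(7)
  for (rep in 1:5) {
    base <- paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = "")
    seqs <- vapply(1:8, function(i) {
      if (i %% 2 == 0) paste0(base, paste(sample(c("A", "C", "G", "U"), sample(0:6, 1), TRUE), collapse = ""))
      else paste(sample(c("A", "C", "G", "U"), sample(15:35, 1), TRUE), collapse = "")
    }, character(1))
    names(seqs) <- paste0("s", seq_along(seqs))
    out <- greedyRedundancyFilter(Biostrings::RNAStringSet(seqs), 0.8)
    got <- S4Vectors::metadata(out)$clusters[names(seqs)]
    expect_identical(unname(got), bruteCluster(seqs, 0.8))
  }
})

test_that("redundancy filter output size is non-increasing in the threshold", {
  set.seed(11)
  base <- paste(sample(c("A", "C", "G", "U"), 40, TRUE), collapse = "")
  seqs <- vapply(1:12, function(i) {
    mut <- sample(40, sample(0:12, 1))
    b <- strsplit(base, "")[[1]]
    b[mut] <- sample(c("A", "C", "G", "U"), length(mut), TRUE)
    paste(b, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:12)
  x <- Biostrings::RNAStringSet(seqs)
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9, 1.0),
                  function(thr) length(greedyRedundancyFilter(x, thr)), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("RNAfold output parsing validates structure and energy", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">a", "GGGAAACCC", "(((...))) ( -1.20)"), path)
  rec <- readRnafoldOutput(path)
  expect_identical(rec$structure, "(((...)))")
  expect_equal(rec$mfe, -1.2)
  expect_identical(rec$sequence, "GGGAAACCC")

  writeLines(c(">a", "GGGAAACCC", "(((...)) ( -1.2)"), path)
  expect_error(readRnafoldOutput(path), "unbalanced|length")
  writeLines(c(">a", "GGGAAACCC", "(((...) ( -1.2)"), path)
  expect_error(readRnafoldOutput(path), "length")
  writeLines(c(">a", "GGGAAACCC", "(((...))) (xyz)"), path)
  expect_error(readRnafoldOutput(path), "parse")
})
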