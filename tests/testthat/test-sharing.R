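test_that("conservation symbols follow the strong/weak group scheme", {
  expect_equal(conservationString(c("CASS", "CASS")), "****")
  expect_equal(conservationString(c("I", "V")), ":")   # within MILV
  expect_equal(conservationString(c("C", "S")), ".")   # within CSA only
  expect_equal(conservationString(c("A", "K")), " ")
  expect_error(conservationString("CASS"), "two")
  expect_error(conservationString(c("CASS", "CAS")), "unequal")
})

test_that("a 14-column set shows the expected symbol pattern", {
  seqs <- c("CASSAAAACAAIAF",
            "CASSKKKKSKKVKF")
  sym <- conservationString(seqs)
  expect_equal(nchar(sym), 14L)
  expect_equal(sym, "****    .  : *")
  counts <- table(strsplit(sym, "")[[1]])
  expect_equal(unname(counts[["*"]]), 5L)
  expect_equal(unname(counts[[":"]]), 1L)
  expect_equal(unname(counts[["."]]), 1L)
})

test_that("removing a divergent sequence never loses full conservation", {
  set.seed(120)
  for (i in 1:20) {
    seqs <- replicate(4, randomPeptide(10))
    starCount <- function(s) sum(strsplit(conservationString(s), "")[[1]] == "*")
    full <- starCount(seqs)
    expect_gte(starCount(seqs[-1]), full)
  }
})

test_that("shared clones are found by exact productive aa match", {
  shared <- "TGTGCCAGCAGTTTT"                    # CASSF in both samples
  coh <- CDR3Cohort(list(
    CDR3Repertoire("a", c(shared, "TGTGCCTGGTTT"), group = "ARDS"),
    CDR3Repertoire("b", c(shared, "TGTGGCTGGTTT"), group = "non_ARDS"),
    CDR3Repertoire("c", "TGTAAATGGTTT", group = "non_ARDS")))
  rep <- sharedClones(coh)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$sequence, "CASSF")
  expect_equal(rep$samples, "a,b")
  expect_equal(rep$sharing, "between_group")
  expect_equal(attr(rep, "n_between_group"), 1L)

  # symmetric in sample order and idempotent
  rev <- sharedClones(CDR3Cohort(rev(as.list(repertoires(coh)))))
  expect_equal(rev$sequence, rep$sequence)
  expect_equal(rev$samples, rep$samples)

  # a nonproductive copy does not create sharing
  stopCopy <- CDR3Cohort(list(
    CDR3Repertoire("a", shared),
    CDR3Repertoire("b", "TGTTAAAGCAGTTTT")))   # stop codon variant
  expect_equal(nrow(sharedClones(stopCopy)), 0L)
})

test_that("nt-level sharing distinguishes convergent recombination", {
  # two distinct nt junctions encoding the same peptide
  coh <- CDR3Cohort(list(
    CDR3Repertoire("a", "TGTGCCAGCAGTTTT"),    # CASSF
    CDR3Repertoire("b", "TGCGCCAGCAGTTTC")))   # CASSF, different codons
  expect_equal(nrow(sharedClones(coh, level = "aa")), 1L)
  expect_equal(nrow(sharedClones(coh, level = "nt")), 0L)
})

test_that("alignment blocks end with the symbol line", {
  block <- alignmentBlock(c("CASSF", "CASTF"), c("x", "y"))
  expect_length(block, 3L)
  expect_match(block[3], "\\*\\*\\*.\\*")
})
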