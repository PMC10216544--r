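## Independent oracles used across the suite. Each reimplements the checked
## quantity from first principles, sharing no code with the package.

## hand-written standard codon table (independent of Biostrings)
ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracleTranslate <- function(nt) {
  k <- nchar(nt) %/% 3L
  if (k == 0L) return("")
  codons <- substring(nt, 3L * seq_len(k) - 2L, 3L * seq_len(k))
  paste(ORACLE_CODONS[codons], collapse = "")
}

randomJunction <- function(len_nt) {
  sense <- names(ORACLE_CODONS)[ORACLE_CODONS != "*"]
  paste0(sample(c("TGT", "TGC"), 1),
         paste(sample(sense, len_nt %/% 3L - 2L, replace = TRUE),
               collapse = ""),
         sample(c("TTT", "TTC"), 1))
}

randomPeptide <- function(len) {
  aa <- setdiff(unique(unname(ORACLE_CODONS)), "*")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

## net charge re-expanded from the Henderson-Hasselbalch terms
oracleNetCharge <- function(aa, pH, pka = cdr3profiler::defaultPkaTable()) {
  res <- strsplit(aa, "")[[1]]
  q <- 1 / (1 + 10^(pH - pka[["N_terminus"]])) -
    1 / (1 + 10^(pka[["C_terminus"]] - pH))
  for (r in res) {
    if (r %in% c("K", "R", "H")) q <- q + 1 / (1 + 10^(pH - pka[[r]]))
    if (r %in% c("D", "E", "C", "Y")) q <- q - 1 / (1 + 10^(pka[[r]] - pH))
  }
  q
}

## fine-grid root scan of the net-charge curve (step 2e-4 pH)
oracleGridPI <- function(aa, pka = cdr3profiler::defaultPkaTable()) {
  grid <- seq(0, 14, by = 2e-4)
  q <- oracleNetCharge(aa, grid, pka)
  i <- max(which(q > 0))
  (grid[i] + grid[i + 1]) / 2
}

## brute-force Dunn pairwise rank statistic: midranks computed by counting,
## tie correction and z expanded directly
oracleDunnPair <- function(xa, xb) {
  x <- c(xa, xb)
  N <- length(x)
  midrank <- vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2,
                    numeric(1))
  Ra <- mean(midrank[seq_along(xa)])
  Rb <- mean(midrank[length(xa) + seq_along(xb)])
  tie <- table(x)
  Tcorr <- sum(tie^3 - tie) / (12 * (N - 1))
  se <- sqrt((N * (N + 1) / 12 - Tcorr) *
               (1 / length(xa) + 1 / length(xb)))
  z <- (Ra - Rb) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

## brute-force Dunn over all pairs, ranking the pooled observations
oracleDunnAll <- function(obsList) {
  labs <- names(obsList)
  x <- unlist(obsList, use.names = FALSE)
  g <- rep(labs, lengths(obsList))
  N <- length(x)
  midrank <- vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2,
                    numeric(1))
  tie <- table(x)
  Tcorr <- sum(tie^3 - tie) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - Tcorr
  pairs <- combn(labs, 2)
  do.call(rbind, apply(pairs, 2, function(ab) {
    a <- ab[1]; b <- ab[2]
    z <- (mean(midrank[g == a]) - mean(midrank[g == b])) /
      sqrt(s2 * (1 / sum(g == a) + 1 / sum(g == b)))
    data.frame(sample_a = a, sample_b = b, z = z, p = 2 * pnorm(-abs(z)))
  }))
}

## independent summation over the packaged weight file for a whole peptide
oracleImmunoScore <- function(aa, weightFile = system.file(
    "extdata", "immunogenicity_model_default.tsv",
    package = "cdr3profiler")) {
  tab <- read.delim(weightFile, header = FALSE, comment.char = "#",
                    col.names = c("type", "key", "weight"))
  enr <- setNames(tab$weight[tab$type == "residue"],
                  tab$key[tab$type == "residue"])
  imp <- numeric(9)
  imp[as.integer(tab$key[tab$type == "position"])] <-
    tab$weight[tab$type == "position"]
  res <- strsplit(aa, "")[[1]]
  L <- length(res)
  total <- 0
  for (i in seq_len(L)) {
    w <- if (i <= 2 || i == L) 0 else if (i <= 8) imp[i] else imp[5]
    total <- total + w * enr[[res[i]]]
  }
  total
}

## small two-clone repertoire used in several files
tinyRepertoire <- function(sampleId = "s1", group = "unlabeled") {
  cdr3profiler::CDR3Repertoire(
    sampleId,
    c("TGTGCCAGCAGTTTT", "TGTGCCTGGTTT"),   # CASSF, CAWF
    templates = c(3L, 1L), group = group)
}

refCountsFile <- function(name) {
  system.file("extdata", name, package = "cdr3profiler")
}
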