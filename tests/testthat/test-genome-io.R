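test_that("FASTA round trips preserve sequence, id and circularity", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">g1 circular=true", "ACGT"), tf)
  g <- read_fasta(tf)
  expect_length(g, 1)
  expect_equal(g$g1$sequence, "ACGT")
  expect_true(g$g1$circular)

  # lowercase and ambiguity codes are accepted and uppercased
  writeLines(c(">g1", "acgtn", ">g2 circular=true", "TTAA"), tf)
  g <- read_fasta(tf)
  expect_equal(g$g1$sequence, "ACGTN")
  expect_false(g$g1$circular)

  # write -> read is the identity
  tf2 <- tempfile(fileext = ".fasta")
  write_fasta(g, tf2)
  g2 <- read_fasta(tf2)
  expect_equal(lapply(g2, `[[`, "sequence"), lapply(g, `[[`, "sequence"))
  expect_equal(lapply(g2, `[[`, "circular"), lapply(g, `[[`, "circular"))

  # duplicate ids are an error
  writeLines(c(">dup", "ACGT", ">dup", "GGCC"), tf)
  expect_error(read_fasta(tf), "duplicate")
})

test_that("non-IUPAC characters are rejected with record and offset", {
  expect_error(new_genome("bad", "ACGU"), "offset 4")
  expect_error(new_genome("bad", "ACGU"), "bad")
  expect_error(new_genome("empty", ""), "length")
})

test_that("TSV feature tables round trip through 1-based coordinates", {
  fx <- tiny_genome()
  tf <- tempfile(fileext = ".tsv")
  write_features(fx$features, tf)
  back <- read_features(tf, "tsv", genomes = list(tiny = fx$genome))
  strip <- function(x) {
    x <- as.data.frame(x)
    attr(x, "source") <- NULL
    class(x) <- "data.frame"
    rownames(x) <- NULL
    x
  }
  expect_equal(strip(back), strip(fx$features))

  # on-disk coordinates really are 1-based inclusive
  raw <- utils::read.delim(tf)
  expect_equal(raw$start[raw$locus_tag == "G_A"], 41)
  expect_equal(raw$end[raw$locus_tag == "G_A"], 70)

  # pseudo flag round trips
  f2 <- fx$features
  f2$pseudo[2] <- TRUE
  write_features(f2, tf)
  expect_true(read_features(tf, "tsv")$pseudo[2])
})

test_that("GFF3 parsing converts coordinates and keeps pseudo flags", {
  tf <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("tiny", "test", "CDS", "1", "9", ".", "+", "0",
          "ID=c1;locus_tag=L1;gene=bioA;product=x", sep = "\t"),
    paste("tiny", "test", "CDS", "20", "31", ".", "-", "0",
          "ID=c2;locus_tag=L2;pseudo=true", sep = "\t"),
    paste("tiny", "test", "rRNA", "40", "45", ".", "+", ".",
          "ID=r1;locus_tag=R1", sep = "\t")), tf)
  fs <- read_features(tf, "gff3")
  l1 <- fs[fs$locus_tag == "L1", ]
  expect_equal(c(l1$start, l1$end), c(0L, 9L))  # 1..9 -> (0, 9)
  expect_equal(fs$gene[fs$locus_tag == "L1"], "bioA")
  expect_true(fs$pseudo[fs$locus_tag == "L2"])
  expect_equal(fs$type[fs$locus_tag == "R1"], "rRNA")
})

test_that("the fallback GFF3 text parser agrees on the same file", {
  tf <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("tiny", "t", "CDS", "1", "9", ".", "+", "0",
          "ID=c1;locus_tag=L1;gene=bioA", sep = "\t"),
    paste("tiny", "t", "CDS", "20", "31", ".", "-", "0",
          "ID=c2;locus_tag=L2;pseudo=true", sep = "\t")), tf)
  g <- endosym:::.parse_gff3_text(tf)
  expect_equal(g$start, c(1L, 20L))
  expect_equal(g$gene, c("bioA", NA))
  expect_equal(g$pseudo, c(NA, "true"))
  expect_equal(g$locus_tag, c("L1", "L2"))
})

test_that("GenBank complement(join()) features extract correctly", {
  tf <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       gbx       60 bp    DNA     circular BCT 01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(join(1..6,10..15))",
    "                     /locus_tag=\"J_1\"",
    "                     /gene=\"bioA\"",
    "     CDS             20..37",
    "                     /locus_tag=\"J_2\"",
    "                     /pseudo",
    "ORIGIN", "//"), tf)
  fs <- read_features(tf, "genbank")
  g <- new_genome("gbx", paste(rep("ACGTTA", 10), collapse = ""),
                  circular = TRUE)
  # hand-built oracle: revcomp of seq[1..6] + seq[10..15]
  oracle <- revcomp_chr(paste0(substr(g$sequence, 1, 6),
                               substr(g$sequence, 10, 15)))
  expect_equal(extract_cds(g, fs[fs$locus_tag == "J_1", ]), oracle)
  expect_true(fs$pseudo[fs$locus_tag == "J_2"][1])
})

test_that("features beyond the genome end wrap on circular, error on linear", {
  tf <- tempfile(fileext = ".tsv")
  df <- data.frame(genome_id = "g", locus_tag = "W_1", start = 55,
                   end = 66, strand = "+", gene = NA, product = NA,
                   pseudo = "false")
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  circ <- new_genome("g", paste(rep("ACGTTA", 10), collapse = ""),
                     circular = TRUE)
  fs <- read_features(tf, "tsv", genomes = list(g = circ))
  w <- fs[fs$locus_tag == "W_1", ]
  expect_equal(nrow(w), 2)           # normalised to two segments
  expect_equal(w$end[1], 60L)
  expect_equal(c(w$start[2], w$end[2]), c(0L, 6L))
  # extraction equals the doubled-sequence oracle
  doubled <- paste0(circ$sequence, circ$sequence)
  expect_equal(extract_cds(circ, w), substr(doubled, 55, 66))

  lin <- new_genome("g", circ$sequence, circular = FALSE)
  expect_error(read_features(tf, "tsv", genomes = list(g = lin)),
               "exceeds linear genome")
})

test_that("extract_cds handles strand and reports wrong references", {
  fx <- tiny_genome()
  expect_equal(extract_cds(fx$genome, fx$features[1, ]), fx$gene_seqs$G_A)
  # minus strand gives back the coding sequence
  expect_equal(extract_cds(fx$genome,
                           fx$features[fx$features$locus_tag == "G_C", ]),
               fx$gene_seqs$G_C)
  other <- new_genome("other", "ACGT")
  expect_error(extract_cds(other, fx$features[1, ]), "reference")
})

test_that("translation reports internal stops and handles edge cases", {
  r <- translate_cds("ATGAAATAA")
  expect_equal(r$protein, "MK")
  expect_equal(nrow(r$internal_stops), 0)

  r <- translate_cds("ATGTGAAAATAA")
  expect_equal(r$protein, "M*K")
  expect_equal(r$internal_stops$codon_index, 1L)
  expect_equal(r$internal_stops$codon, "TGA")

  expect_error(translate_cds("ATGAA"), "remainder 2")
  # ambiguity codes translate to X
  expect_equal(translate_cds("ATGNNATAA")$protein, "MX")
})
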