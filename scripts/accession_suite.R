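#!/usr/bin/env Rscript
# Re-analysis of the deposited endosymbiont genomes (BioProjects
# PRJNA1100464 and PRJNA1100466, 16S accession OQ099687.1) with the same
# package functions the synthetic acceptance surface exercises.  This
# suite needs the deposited data and therefore network access (or a local
# copy); it is not part of the offline test suite.
#
# Expected layout under --data-dir (obtained e.g. with the NCBI `datasets`
# tool or from the BioProject FTP):
#   mirabilia_cw.fasta        mirabilia_cw.gff        (165,642 bp genome)
#   karelsulcia_plfr.fasta    karelsulcia_plch.fasta
#   vidania_plfr.fasta        vidania_plch.fasta
#   purcelliella_plfr.fasta   purcelliella_plch.fasta
#   mirabilia_cw_16s.fasta    cnervosus_16s.fasta     purcelliella_16s.fasta
#
# Usage: Rscript scripts/accession_suite.R --data-dir DIR [--out PATH]
#
# Reported quantities (published values in parentheses):
#   split candidates on the Mirabilia genome (87) and its stop-usage
#   table (group 1: 80/7/13, internal: 55/9/36 for TAA/TAG/TGA);
#   SNP counts for the Karelsulcia (2) and Vidania (68) pairs;
#   16S identities C. nervosus vs Mirabilia (96) and vs Purcelliella (84);
#   Mirabilia genome length (165,642 bp) and GC (18.4).

suppressMessages(library(endosym))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(`data-dir` = NULL, out = "results/accession_suite.json")
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[[i]])
  opt[[key]] <- args[[i + 1L]]
  i <- i + 2L
}
if (is.null(opt$`data-dir`)) {
  stop("--data-dir is required (directory with the deposited genomes)")
}
dd <- function(f) {
  p <- file.path(opt$`data-dir`, f)
  if (!file.exists(p)) stop("missing file: ", p)
  p
}
results <- list()
record <- function(name, value, n) {
  results[[name]] <<- list(value = value, n = n)
  message(sprintf("%-34s %s", name, format(value)))
}

mir <- read_fasta(dd("mirabilia_cw.fasta"), circular_default = TRUE)[[1]]
feats <- read_features(dd("mirabilia_cw.gff"), "gff3",
                       genomes = stats::setNames(list(mir), mir$id))
cands <- find_split_candidates(mir, feats)
record("mirabilia_split_candidates", nrow(cands), nrow(feats))
su <- stop_usage(mir, feats, cands)
for (grp in unique(su$group)) {
  for (cc in c("TAA", "TAG", "TGA")) {
    record(sprintf("%s_%s_pct", sub("_.*", "", grp), tolower(cc)),
           su$percent[su$group == grp & su$codon == cc],
           sum(su$count[su$group == grp]))
  }
}
st <- genome_stats(mir, feats)
record("mirabilia_length_bp", st$length, 1)
record("mirabilia_gc_pct", st$gc_percent, st$length)

for (pair in list(c("karelsulcia", 2), c("vidania", 68),
                  c("purcelliella", 122))) {
  a <- read_fasta(dd(sprintf("%s_plfr.fasta", pair[1])),
                  circular_default = TRUE)[[1]]
  b <- read_fasta(dd(sprintf("%s_plch.fasta", pair[1])),
                  circular_default = TRUE)[[1]]
  snp <- count_snps(a, b)
  record(sprintf("%s_pair_snps", pair[1]), snp$n_substitutions,
         nchar(a$sequence))
}

cn <- read_fasta(dd("cnervosus_16s.fasta"))[[1]]
mir16 <- read_fasta(dd("mirabilia_cw_16s.fasta"))[[1]]
pur16 <- read_fasta(dd("purcelliella_16s.fasta"))[[1]]
record("identity_16s_cnervosus_mirabilia",
       identity_16s(cn$sequence, mir16$sequence)$identity_rounded, 1)
record("identity_16s_cnervosus_purcelliella",
       identity_16s(cn$sequence, pur16$sequence)$identity_rounded, 1)

dir.create(dirname(opt$out), showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(results, opt$out, auto_unbox = TRUE, digits = NA)
message("wrote ", opt$out)
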