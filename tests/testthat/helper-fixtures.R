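# Shared fixture builders.  All fixtures are constructed in code; no
# binary data is read from disk.

# A tiny hand-built genome whose CDS coordinates are known exactly.
# Layout (0-based half-open):
#   [40, 70)  +  geneA  10 codons: ATG + 8 codons + TAA
#   [110,140) +  geneB  10 codons
#   [180,210) -  geneC  10 codons (reverse strand)
tiny_genome <- function(circular = TRUE) {
  spacer <- function(n) paste(rep("T", n), collapse = "")
  geneA <- "ATGAAAGAATTTATTCTTAAAAATCCATAA"
  geneB <- "ATGGAACATATTAAAACTGTTTGTTGGTAA"
  geneC_fwd <- "ATGTTTAATAAACCAGAAATTGATCGTTAA"
  seq <- paste0(spacer(40), geneA, spacer(40), geneB, spacer(40),
                revcomp_chr(geneC_fwd), spacer(40))
  genome <- new_genome("tiny", seq, circular = circular)
  features <- new_feature_set(data.frame(
    genome_id = "tiny",
    locus_tag = c("G_A", "G_B", "G_C"),
    segment = 1L,
    start = c(40L, 110L, 180L),
    end = c(70L, 140L, 210L),
    strand = c("+", "+", "-"),
    type = "CDS",
    gene = c("bioB", NA, "ribD"),
    product = NA_character_,
    pseudo = FALSE,
    stringsAsFactors = FALSE
  ))
  list(genome = genome, features = features,
       gene_seqs = list(G_A = geneA, G_B = geneB, G_C = geneC_fwd))
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Independent translation oracle: Biostrings with the bacterial code,
# fuzzy codons forced to X.
oracle_translate <- function(cds) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(cds),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE,
    if.fuzzy.codon = "X"))
}

# Small default simulation shared by several tests.
small_sim <- function(seed = 11, n_split = 0) {
  simulate_genome(simulation_config(
    seed = seed, genome_length = 40000, gc_target = 0.22, n_genes = 40,
    mean_gene_length = 200, n_split_genes = n_split))
}

# A minimal two-pathway catalog used in unit tests.
mini_catalog <- function() {
  new_catalog(list(
    list(pathway_id = "p1", display_name = "P1", class = "EAA",
         steps = list("g1", c("g2", "g2alt"), "g3")),
    list(pathway_id = "p2", display_name = "P2", class = "B-vitamin",
         steps = list("h1", "h2"))
  ), synonym_map = c(g2syn = "g2alt"))
}

presence_from_list <- function(lst, catalog) {
  vocab <- endosym:::catalog_symbols(catalog)
  m <- matrix("absent", nrow = length(lst), ncol = length(vocab),
              dimnames = list(names(lst), vocab))
  for (g in names(lst)) {
    for (s in lst[[g]]) m[g, s] <- "present"
  }
  structure(m, class = c("presence_matrix", class(m)))
}
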