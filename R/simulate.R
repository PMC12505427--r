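# Synthetic endosymbiont genomes with tracked ground truth.
#
# The generator emulates the genomes this toolkit targets: small (130-500
# kb), circular, extremely AT-rich molecules densely packed with
# single-exon CDS, optionally carrying genes split in two halves by a
# single in-frame internal stop codon, near-identical genome pairs
# differing by a known number of substitutions, and 16S pairs diverged to
# a target identity.  Every planted artefact is recorded so the analysis
# modules can be scored against exact truth.

# Internal stop codons observed in the split genes of the reduced
# Gammaproteobacteria symbiont analysed here (TAA/TAG/TGA).
DEFAULT_SPLIT_STOP_DIST <- c(TAA = 0.55, TAG = 0.09, TGA = 0.36)
# Terminal stop usage of intact genes in the same genome.
DEFAULT_TERMINAL_STOP_DIST <- c(TAA = 0.80, TAG = 0.07, TGA = 0.13)

# Intergenic spacers are kept longer than the split-detection gap
# threshold so that adjacent *unrelated* genes can never mimic a split
# pair; see the methods vignette.
MIN_INTERGENIC <- 31L

#' Simulation configuration
#'
#' Validated parameter bundle for \code{\link{simulate_genome}}.
#'
#' @param seed RNG seed (all randomness in the generator flows from it)
#' @param genome_length target genome size in nt (realised exactly)
#' @param gc_target GC fraction in (0, 1); endosymbionts here sit at
#'   0.18-0.27
#' @param n_genes number of CDS to place
#' @param mean_gene_length mean coding length in codons (excluding the
#'   terminal stop)
#' @param intergenic_mean mean intergenic spacer length in nt (spacers are
#'   floored at 31 nt; see Details)
#' @param n_split_genes number of genes to split by planting one internal
#'   stop codon
#' @param split_stop_distribution probabilities over c(TAA, TAG, TGA) used
#'   when planting internal stops
#' @param terminal_stop_distribution probabilities over c(TAA, TAG, TGA)
#'   for terminal stops of generated genes
#' @param pathway_assignment named list: pathway id -> character vector of
#'   gene symbols to attach to generated CDS
#' @param n_snps_pair substitutions to plant when deriving a paired genome
#' @param target_16s_identity identity target for a simulated 16S pair
#' @return object of class \code{sim_config}
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 150000L,
                              gc_target = 0.20,
                              n_genes = 150L,
                              mean_gene_length = 300L,
                              intergenic_mean = 90L,
                              n_split_genes = 0L,
                              split_stop_distribution = DEFAULT_SPLIT_STOP_DIST,
                              terminal_stop_distribution = DEFAULT_TERMINAL_STOP_DIST,
                              pathway_assignment = list(),
                              n_snps_pair = 0L,
                              target_16s_identity = 1.0) {
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              gc_target = gc_target,
              n_genes = as.integer(n_genes),
              mean_gene_length = as.integer(mean_gene_length),
              intergenic_mean = as.integer(intergenic_mean),
              n_split_genes = as.integer(n_split_genes),
              split_stop_distribution = .norm_stop_dist(split_stop_distribution),
              terminal_stop_distribution = .norm_stop_dist(terminal_stop_distribution),
              pathway_assignment = pathway_assignment,
              n_snps_pair = as.integer(n_snps_pair),
              target_16s_identity = target_16s_identity)
  if (cfg$gc_target <= 0 || cfg$gc_target >= 1) {
    stop("gc_target must be in (0, 1)")
  }
  if (cfg$n_split_genes > cfg$n_genes) {
    stop("n_split_genes cannot exceed n_genes")
  }
  if (cfg$target_16s_identity <= 0 || cfg$target_16s_identity > 1) {
    stop("target_16s_identity must be in (0, 1]")
  }
  # Feasibility check before any generation: expected coding plus minimal
  # spacers must fit the requested genome length.
  min_needed <- cfg$n_genes * (3L * cfg$mean_gene_length + 6L) +
    cfg$n_genes * MIN_INTERGENIC
  if (min_needed > cfg$genome_length) {
    stop(sprintf(paste0("infeasible packing: %d genes of ~%d codons need ",
                        "about %d nt but genome_length is %d"),
                 cfg$n_genes, cfg$mean_gene_length, min_needed,
                 cfg$genome_length))
  }
  structure(cfg, class = "sim_config")
}

.norm_stop_dist <- function(p) {
  if (is.null(names(p))) names(p) <- STOP_CODONS
  if (!setequal(names(p), STOP_CODONS)) {
    stop("stop distribution must be named over TAA, TAG, TGA")
  }
  p <- p[STOP_CODONS]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("stop distribution must be non-negative and sum to 1")
  }
  p / sum(p)
}

# iid bases with the genome's AT bias
.sample_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# A stop-free run of `n_codons` codons sampled position-independently with
# the target nucleotide weights; stop codons are resampled.
.sample_codons <- function(n_codons, gc) {
  if (n_codons == 0) return(character(0))
  codons <- split_codons(paste(.sample_bases(3L * n_codons, gc),
                               collapse = ""))
  repeat {
    bad <- which(codons %in% STOP_CODONS)
    if (!length(bad)) break
    repl <- split_codons(paste(.sample_bases(3L * length(bad), gc),
                               collapse = ""))
    codons[bad] <- repl
  }
  codons
}

#' Simulate an annotated endosymbiont genome
#'
#' Generates a circular, AT-rich genome packed with ATG-initiated,
#' stop-terminated, internally stop-free CDS separated by intergenic
#' spacers, realising \code{genome_length} exactly and GC within two
#' percentage points of \code{gc_target}.  Gene symbols listed in
#' \code{pathway_assignment} are attached to randomly chosen CDS.  When
#' \code{n_split_genes > 0} the corresponding number of genes is split via
#' \code{\link{plant_split_genes}} within the same seeded stream.
#'
#' The result is byte-deterministic given the config (including its seed).
#'
#' @param config a \code{\link{simulation_config}}
#' @return list with elements \code{genome} (\code{nuc_genome}),
#'   \code{features} (\code{feature_set}) and \code{truth} (split records,
#'   SNP positions, planted gene symbols, achieved GC)
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    sim <- .simulate_genome_core(config)
    if (config$n_split_genes > 0) {
      sim <- .plant_split_core(sim$genome, sim$features, sim$truth,
                               config$n_split_genes,
                               config$split_stop_distribution)
    }
    sim
  })
}

.simulate_genome_core <- function(cfg) {
  n <- cfg$n_genes
  gc <- cfg$gc_target
  # coding codons per gene (excluding ATG? included; excluding stop)
  lens <- 60L + stats::rpois(n, max(0L, cfg$mean_gene_length - 60L))
  gene_nt <- 3L * lens + 3L  # plus terminal stop
  avail <- cfg$genome_length - sum(gene_nt)
  extra <- avail - n * MIN_INTERGENIC
  if (extra < 0) {
    stop("infeasible packing: sampled gene lengths exceed genome_length")
  }
  raw <- stats::rpois(n, max(1L, cfg$intergenic_mean - MIN_INTERGENIC)) + 1
  gaps <- MIN_INTERGENIC +
    as.integer(stats::rmultinom(1, extra, prob = raw))

  strands <- sample(c("+", "-"), n, replace = TRUE)
  term_stops <- sample(STOP_CODONS, n, replace = TRUE,
                       prob = cfg$terminal_stop_distribution)

  symbols <- unlist(lapply(names(cfg$pathway_assignment), function(p) {
    stats::setNames(cfg$pathway_assignment[[p]],
                    rep(p, length(cfg$pathway_assignment[[p]])))
  }))
  if (length(symbols) > n) {
    stop("more pathway gene symbols than genes to carry them")
  }
  sym_idx <- if (length(symbols)) sort(sample.int(n, length(symbols)))
             else integer(0)
  gene_of <- rep(NA_character_, n)
  pathway_of <- rep(NA_character_, n)
  gene_of[sym_idx] <- unname(symbols)
  pathway_of[sym_idx] <- names(symbols)

  pieces <- character(2L * n)
  rows <- vector("list", n)
  pos <- 0L
  for (i in seq_len(n)) {
    gseq <- paste0("ATG",
                   paste(.sample_codons(lens[i] - 1L, gc), collapse = ""),
                   term_stops[i])
    pieces[2L * i - 1L] <- paste(.sample_bases(gaps[i], gc), collapse = "")
    pos <- pos + gaps[i]
    placed <- if (strands[i] == "+") gseq else revcomp(gseq)
    pieces[2L * i] <- placed
    rows[[i]] <- data.frame(
      genome_id = "sim", locus_tag = sprintf("SIM_%04d", i), segment = 1L,
      start = pos, end = pos + nchar(gseq), strand = strands[i],
      type = "CDS", gene = gene_of[i],
      product = if (is.na(gene_of[i])) "hypothetical protein"
                else paste(gene_of[i], "biosynthesis protein"),
      pseudo = FALSE, stringsAsFactors = FALSE
    )
    pos <- pos + nchar(gseq)
  }
  seq <- paste(pieces, collapse = "")
  stopifnot(nchar(seq) == cfg$genome_length)
  genome <- new_genome("sim", seq, circular = TRUE,
                       description = "synthetic endosymbiont genome")
  achieved <- gc_content(seq)
  if (abs(achieved - gc) > 0.02) {
    stop(sprintf("achieved GC %.3f deviates from target %.3f by > 0.02",
                 achieved, gc))
  }
  features <- new_feature_set(do.call(rbind, rows), source = "simulated")
  truth <- list(
    split_records = data.frame(locus_tag = character(0),
                               first_locus_tag = character(0),
                               second_locus_tag = character(0),
                               internal_stop_codon = character(0),
                               internal_stop_codon_index = integer(0),
                               stringsAsFactors = FALSE),
    snp_positions = integer(0),
    planted_genes = stats::na.omit(data.frame(
      symbol = gene_of, pathway = pathway_of,
      locus_tag = sprintf("SIM_%04d", seq_len(n)),
      stringsAsFactors = FALSE)),
    achieved_gc = achieved
  )
  list(genome = genome, features = features, truth = truth)
}

#' Plant split genes
#'
#' Rewrites one mid-gene codon of each chosen CDS into a stop codon drawn
#' from \code{stop_dist} and replaces the gene's annotation by two CDS
#' halves (the first ending at the planted stop, the second starting at
#' the next codon), mirroring what an annotation pipeline reports for such
#' genes.  No frame shift is introduced: exactly one codon changes.
#'
#' @param genome a \code{nuc_genome}
#' @param features the matching \code{feature_set}
#' @param n number of genes to split; must not exceed the number of
#'   intact single-segment CDS of at least 60 codons
#' @param stop_dist probabilities over c(TAA, TAG, TGA)
#' @param seed RNG seed
#' @param truth optional existing truth record to extend
#' @return list(genome, features, truth) with
#'   \code{truth$split_records} describing every planted split
#' @export
plant_split_genes <- function(genome, features, n,
                              stop_dist = DEFAULT_SPLIT_STOP_DIST,
                              seed = 1L, truth = NULL) {
  with_seed(seed, .plant_split_core(genome, features, truth, n,
                                    .norm_stop_dist(stop_dist)))
}

.plant_split_core <- function(genome, features, truth, n, stop_dist) {
  min_half <- 15L  # codons per half, comfortably above detection defaults
  df <- as.data.frame(features)
  seg1 <- df[df$segment == 1L, , drop = FALSE]
  multi <- df$locus_tag[df$segment > 1L]
  cod_len <- (seg1$end - seg1$start) %/% 3L
  eligible <- which(seg1$type == "CDS" & !seg1$pseudo &
                    !(seg1$locus_tag %in% multi) & cod_len >= 60L)
  if (n > length(eligible)) {
    stop(sprintf("cannot plant %d split genes: only %d intact CDS of >= 60 codons",
                 n, length(eligible)))
  }
  if (n == 0) {
    return(list(genome = genome, features = features,
                truth = truth %||% list(split_records = NULL)))
  }
  chosen <- sort(sample(eligible, n))
  seq <- genome$sequence
  records <- vector("list", n)
  new_rows <- list()
  drop_tags <- character(n)
  for (j in seq_along(chosen)) {
    row <- seg1[chosen[j], , drop = FALSE]
    L_cod <- (row$end - row$start) %/% 3L
    k <- sample(seq.int(min_half, L_cod - 2L - min_half), 1L)
    stop_codon <- sample(STOP_CODONS, 1L, prob = stop_dist)
    if (row$strand == "+") {
      at <- row$start + 3L * k  # 0-based genomic offset of codon start
      substr(seq, at + 1L, at + 3L) <- stop_codon
      cut <- row$start + 3L * (k + 1L)
      first <- row; second <- row
      first$end <- cut
      second$start <- cut
    } else {
      at <- row$end - 3L * (k + 1L)
      substr(seq, at + 1L, at + 3L) <- revcomp(stop_codon)
      cut <- row$end - 3L * (k + 1L)
      first <- row; second <- row
      first$start <- cut     # coding-first half is genomic-rightmost
      second$end <- cut
    }
    first$locus_tag <- paste0(row$locus_tag, "_1")
    second$locus_tag <- paste0(row$locus_tag, "_2")
    drop_tags[j] <- row$locus_tag
    new_rows[[2L * j - 1L]] <- first
    new_rows[[2L * j]] <- second
    records[[j]] <- data.frame(
      locus_tag = row$locus_tag,
      first_locus_tag = first$locus_tag,
      second_locus_tag = second$locus_tag,
      internal_stop_codon = stop_codon,
      internal_stop_codon_index = k,
      stringsAsFactors = FALSE
    )
  }
  out <- df[!(df$locus_tag %in% drop_tags), , drop = FALSE]
  out <- rbind(out, do.call(rbind, new_rows))
  out <- out[order(out$start, out$locus_tag, out$segment), , drop = FALSE]
  rownames(out) <- NULL
  truth <- truth %||% list()
  truth$split_records <- rbind(truth$split_records,
                               do.call(rbind, records))
  list(genome = new_genome(genome$id, seq, genome$circular,
                           genome$description),
       features = new_feature_set(out, source = attr(features, "source")),
       truth = truth)
}

#' Derive a paired genome by planting substitutions
#'
#' Plants exactly \code{n_snps} substitutions at distinct positions (no
#' indels).  With \code{avoid_stop_creation} (requires \code{features}),
#' substitutions that would create or destroy a stop codon inside an
#' annotated CDS are re-drawn, so downstream split-gene and SNP analyses
#' see the planted truth and nothing else.
#'
#' @param genome a \code{nuc_genome}
#' @param n_snps number of substitutions
#' @param seed RNG seed
#' @param features optional \code{feature_set} used for the stop-codon
#'   guard
#' @param avoid_stop_creation re-draw substitutions that flip stop status
#'   inside a CDS
#' @param max_draws bound on total redraw attempts
#' @return list(genome, snp_positions) with 1-based positions on the input
#' @export
mutate_pair <- function(genome, n_snps, seed = 1L, features = NULL,
                        avoid_stop_creation = !is.null(features),
                        max_draws = 200L * max(1L, n_snps)) {
  L <- nchar(genome$sequence)
  if (n_snps > L) stop("n_snps exceeds genome length")
  if (avoid_stop_creation && is.null(features)) {
    stop("avoid_stop_creation requires 'features'")
  }
  with_seed(seed, {
    seq <- genome$sequence
    taken <- integer(0)
    draws <- 0L
    while (length(taken) < n_snps) {
      if (draws >= max_draws) {
        stop(sprintf("could not place %d substitutions (placed %d) under the stop-codon guard",
                     n_snps, length(taken)))
      }
      draws <- draws + 1L
      pos <- sample.int(L, 1L)
      if (pos %in% taken) next
      old <- substr(seq, pos, pos)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      if (avoid_stop_creation &&
          .flips_stop_status(seq, pos, new, features)) next
      substr(seq, pos, pos) <- new
      taken <- c(taken, pos)
    }
    list(genome = new_genome(genome$id, seq, genome$circular,
                             genome$description),
         snp_positions = sort(taken))
  })
}

# Would substituting `new` at 1-based `pos` change stop-codon status of the
# codon covering that position in any single-segment CDS?
.flips_stop_status <- function(seq, pos, new, features) {
  df <- as.data.frame(features)
  df <- df[df$type == "CDS" & df$segment == 1L, , drop = FALSE]
  p0 <- pos - 1L  # 0-based
  hit <- which(df$start <= p0 & p0 < df$end)
  for (i in hit) {
    if (df$strand[i] == "+") {
      k <- (p0 - df$start[i]) %/% 3L
      at <- df$start[i] + 3L * k
    } else {
      k <- (df$end[i] - 1L - p0) %/% 3L
      at <- df$end[i] - 3L * (k + 1L)
    }
    codon_old <- substr(seq, at + 1L, at + 3L)
    codon_new <- codon_old
    substr(codon_new, pos - at, pos - at) <- new
    if (df$strand[i] == "-") {
      codon_old <- revcomp(codon_old)
      codon_new <- revcomp(codon_new)
    }
    if ((codon_old %in% STOP_CODONS) != (codon_new %in% STOP_CODONS)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Simulate a 16S rRNA gene pair at a target identity
#'
#' Substitution-only divergence: the second sequence differs from the
#' first at exactly \code{round(length * (1 - target_identity))} positions,
#' so the realised identity equals the target to within half a percentage
#' point at typical 16S length (1500 nt).
#'
#' @param length sequence length in nt
#' @param target_identity fraction in (0, 1]
#' @param seed RNG seed
#' @param gc GC content of the backbone sequence (rRNA genes are not
#'   AT-extreme; default 0.53)
#' @return list(seq1, seq2, n_substitutions)
#' @export
simulate_16s_pair <- function(length = 1500L, target_identity, seed = 1L,
                              gc = 0.53) {
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must be in (0, 1]")
  }
  with_seed(seed, {
    s1 <- paste(.sample_bases(length, gc), collapse = "")
    n_mut <- as.integer(round(length * (1 - target_identity)))
    s2 <- s1
    if (n_mut > 0) {
      pos <- sample.int(length, n_mut)
      for (p in pos) {
        substr(s2, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(s1, p, p)), 1L)
      }
    }
    list(seq1 = s1, seq2 = s2, n_substitutions = n_mut)
  })
}

#' Simulate a consortium of genomes
#'
#' Drives \code{\link{simulate_genome}} for several genomes from one
#' config (a YAML file or an equivalent list): top-level \code{seed} plus a
#' \code{genomes} map of per-genome overrides (\code{genome_length},
#' \code{gc_target}, \code{n_genes}, \code{n_split_genes},
#' \code{pathway_assignment}, ...).  Per-genome seeds are derived
#' deterministically from the top-level seed.
#'
#' @param config path to a YAML file or a list
#' @return named list of simulations (genome, features, truth), one per
#'   configured genome
#' @export
simulate_consortium <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed0 <- as.integer(config$seed %||% 1L)
  gens <- config$genomes
  if (is.null(gens) || !length(gens)) stop("config has no 'genomes' entry")
  out <- list()
  for (i in seq_along(gens)) {
    nm <- names(gens)[i] %||% sprintf("genome%d", i)
    spec <- gens[[i]]
    args <- spec[intersect(names(spec),
                           names(formals(simulation_config)))]
    args$seed <- as.integer(spec$seed %||% ((seed0 * 131L + i) %% .Machine$integer.max))
    cfg <- do.call(simulation_config, args)
    sim <- simulate_genome(cfg)
    sim$genome$id <- nm
    sim$features$genome_id <- nm
    # per-genome locus-tag prefix so consortium-wide tables stay unique
    relabel <- function(x) sub("^SIM", toupper(nm), x)
    sim$features$locus_tag <- relabel(sim$features$locus_tag)
    if (nrow(sim$truth$planted_genes)) {
      sim$truth$planted_genes$genome_id <- nm
      sim$truth$planted_genes$locus_tag <-
        relabel(sim$truth$planted_genes$locus_tag)
    }
    if (NROW(sim$truth$split_records)) {
      for (col in c("locus_tag", "first_locus_tag", "second_locus_tag")) {
        sim$truth$split_records[[col]] <-
          relabel(sim$truth$split_records[[col]])
      }
    }
    out[[nm]] <- sim
  }
  out
}

#' Write a simulation to disk
#'
#' Emits \code{<id>.fasta}, \code{<id>_features.tsv} and
#' \code{<id>_truth.json} under \code{dir}.
#'
#' @param sim a simulation (genome, features, truth)
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sim$genome$id
  paths <- c(
    fasta = file.path(dir, paste0(id, ".fasta")),
    features = file.path(dir, paste0(id, "_features.tsv")),
    truth = file.path(dir, paste0(id, "_truth.json"))
  )
  write_fasta(sim$genome, paths[["fasta"]])
  write_features(sim$features, paths[["features"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}
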