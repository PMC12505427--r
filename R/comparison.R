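# Pairwise genome and marker comparisons.
#
# Circular genomes are deposited at arbitrary start coordinates, so
# whole-genome comparisons first normalise rotation via shared unique
# k-mer anchors.  SNP counting is column-wise after rotation for
# equal-length pairs and anchor-segmented for pairs with indels.  ANI is
# an OrthoANI-style reciprocal-best-fragment mean computed fully
# in-process: fragments are placed by unique k-mer seeding and aligned
# against a bounded window.

.kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1L), k:L)
}

# positions (1-based) of k-mers occurring exactly once in seq
.unique_kmer_index <- function(seq, k) {
  km <- .kmers(seq, k)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  list(kmer = km[!dup], pos = which(!dup))
}

#' Rotation offset between two circular genomes
#'
#' Finds the rotation of \code{b} that best aligns it with \code{a}, as
#' the modal difference of positions of k-mers unique within each genome
#' (the offset supported by the longest collinear anchor set under pure
#' rotation).  Ties break towards the smallest offset.
#'
#' @param a,b circular \code{nuc_genome}s of comparable length (length
#'   difference below 10\%)
#' @param anchor_k k-mer size for anchors
#' @return 0-based offset: rotating \code{b} left by this amount (see
#'   \code{\link{rotate_genome}}) superimposes it on \code{a}
#' @export
rotate_align <- function(a, b, anchor_k = 17L) {
  if (!isTRUE(a$circular) || !isTRUE(b$circular)) {
    stop("rotate_align requires two circular genomes")
  }
  La <- nchar(a$sequence); Lb <- nchar(b$sequence)
  if (abs(La - Lb) / max(La, Lb) >= 0.10) {
    stop("genomes differ in length by >= 10%; not a comparable pair")
  }
  ia <- .unique_kmer_index(a$sequence, anchor_k)
  ib <- .unique_kmer_index(b$sequence, anchor_k)
  m <- match(ia$kmer, ib$kmer)
  hit <- !is.na(m)
  if (!any(hit)) {
    stop("no shared unique ", anchor_k,
         "-mers between genomes; try linear alignment instead")
  }
  offsets <- (ib$pos[m[hit]] - ia$pos[hit]) %% Lb
  tab <- table(offsets)
  best <- as.integer(names(tab)[tab == max(tab)])
  min(best)
}

#' Rotate a circular genome
#'
#' @param genome a circular \code{nuc_genome}
#' @param offset 0-based left rotation in nt
#' @return the rotated genome
#' @export
rotate_genome <- function(genome, offset) {
  L <- nchar(genome$sequence)
  offset <- ((offset %% L) + L) %% L
  if (offset == 0) return(genome)
  seq <- paste0(substr(genome$sequence, offset + 1L, L),
                substr(genome$sequence, 1L, offset))
  new_genome(genome$id, seq, genome$circular, genome$description)
}

#' Count SNPs between two near-identical genomes
#'
#' For circular inputs the rotation of \code{b} is normalised first.
#' Equal-length pairs are compared column-wise: substitutions are columns
#' where both bases are unambiguous and differ; columns involving an
#' ambiguity code are tallied separately, not as substitutions.
#' Unequal-length pairs (up to 10\% difference) are segmented along a
#' collinear chain of shared unique k-mer anchors and each inter-anchor
#' segment is globally aligned; gap runs count as indel events.
#'
#' @param a,b \code{nuc_genome}s
#' @param anchor_k anchor k-mer size
#' @return list of class \code{snp_report}: \code{n_substitutions},
#'   \code{positions} (1-based, on the rotated frame of \code{a}),
#'   \code{n_indel_events}, \code{n_ambiguous_columns},
#'   \code{rotation_offset}
#' @export
count_snps <- function(a, b, anchor_k = 17L) {
  La <- nchar(a$sequence); Lb <- nchar(b$sequence)
  if (abs(La - Lb) / max(La, Lb) >= 0.10) {
    stop("genomes differ in length by >= 10%; not a closed pair")
  }
  off <- 0L
  if (isTRUE(a$circular) && isTRUE(b$circular) &&
      a$sequence != b$sequence) {
    off <- rotate_align(a, b, anchor_k)
    b <- rotate_genome(b, off)
  }
  if (La == Lb) {
    xa <- strsplit(a$sequence, "")[[1]]
    xb <- strsplit(b$sequence, "")[[1]]
    plain <- c("A", "C", "G", "T")
    differs <- xa != xb
    unamb <- xa %in% plain & xb %in% plain
    pos <- which(differs & unamb)
    rep <- list(n_substitutions = length(pos), positions = pos,
                n_indel_events = 0L,
                n_ambiguous_columns = sum(differs & !unamb),
                rotation_offset = off)
  } else {
    rep <- .count_snps_segmented(a$sequence, b$sequence, anchor_k)
    rep$rotation_offset <- off
  }
  structure(rep, class = "snp_report")
}

# Anchor-chain segmentation for pairs with indels.
.count_snps_segmented <- function(sa, sb, k) {
  ia <- .unique_kmer_index(sa, k)
  ib <- .unique_kmer_index(sb, k)
  m <- match(ia$kmer, ib$kmer)
  hit <- which(!is.na(m))
  if (!length(hit)) stop("no shared anchors; genomes too divergent")
  pa <- ia$pos[hit]; pb <- ib$pos[m[hit]]
  o <- order(pa)
  pa <- pa[o]; pb <- pb[o]
  # thin to ~1 anchor per 200 nt, then keep the longest collinear chain
  keep <- c(TRUE, diff(pa) >= 200L)
  pa <- pa[keep]; pb <- pb[keep]
  lis <- .longest_increasing(pb)
  pa <- pa[lis]; pb <- pb[lis]

  n_sub <- 0L; n_indel <- 0L; n_amb <- 0L; positions <- integer(0)
  starts_a <- c(1L, pa + k); ends_a <- c(pa - 1L, nchar(sa))
  starts_b <- c(1L, pb + k); ends_b <- c(pb - 1L, nchar(sb))
  for (i in seq_along(starts_a)) {
    seg_a <- if (starts_a[i] <= ends_a[i])
      substr(sa, starts_a[i], ends_a[i]) else ""
    seg_b <- if (starts_b[i] <= ends_b[i])
      substr(sb, starts_b[i], ends_b[i]) else ""
    if (!nchar(seg_a) && !nchar(seg_b)) next
    if (nchar(seg_a) == nchar(seg_b)) {
      xa <- strsplit(seg_a, "")[[1]]; xb <- strsplit(seg_b, "")[[1]]
      plain <- c("A", "C", "G", "T")
      differs <- xa != xb
      unamb <- xa %in% plain & xb %in% plain
      n_sub <- n_sub + sum(differs & unamb)
      n_amb <- n_amb + sum(differs & !unamb)
      positions <- c(positions, starts_a[i] - 1L + which(differs & unamb))
    } else if (!nchar(seg_a) || !nchar(seg_b)) {
      n_indel <- n_indel + 1L
    } else {
      aln <- Biostrings::pairwiseAlignment(seg_a, seg_b, type = "global")
      mt <- Biostrings::mismatchTable(aln)
      if (nrow(mt)) {
        plain <- c("A", "C", "G", "T")
        is_amb <- !(as.character(mt$PatternSubstring) %in% plain) |
                  !(as.character(mt$SubjectSubstring) %in% plain)
        n_sub <- n_sub + sum(!is_amb)
        n_amb <- n_amb + sum(is_amb)
        positions <- c(positions,
                       starts_a[i] - 1L + mt$PatternStart[!is_amb])
      }
      n_indel <- n_indel +
        length(Biostrings::indel(aln)@insertion[[1]]) +
        length(Biostrings::indel(aln)@deletion[[1]])
    }
  }
  list(n_substitutions = n_sub, positions = sort(positions),
       n_indel_events = n_indel, n_ambiguous_columns = n_amb)
}

.longest_increasing <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  tails <- integer(0)      # indices of smallest tail per length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (x[tails[mid]] < x[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(length(tails))
  cur <- tails[length(tails)]
  for (j in rev(seq_along(tails))) {
    out[j] <- cur
    cur <- prev[cur]
  }
  out
}

#' 16S rRNA percent identity
#'
#' Global alignment with free terminal gaps (overlap alignment); identity
#' is matches over aligned columns, internal gap columns included in the
#' denominator and terminal overhangs excluded.  The orientation of
#' \code{y} is auto-detected (the strand with the higher score is used).
#'
#' @param x,y near-complete 16S sequences (character strings); a warning
#'   is issued below 1200 nt
#' @return list of class \code{identity_result}: \code{matches},
#'   \code{aligned_columns}, \code{identity_percent},
#'   \code{identity_rounded} (half away from zero)
#' @export
identity_16s <- function(x, y) {
  x <- toupper(x); y <- toupper(y)
  if (min(nchar(x), nchar(y)) < 1200) {
    warning("sequence shorter than 1200 nt; identity computed anyway")
  }
  score_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = FALSE)
  aln_f <- Biostrings::pairwiseAlignment(
    x, y, type = "overlap", substitutionMatrix = score_mat,
    gapOpening = 4, gapExtension = 2)
  aln_r <- Biostrings::pairwiseAlignment(
    x, revcomp(y), type = "overlap", substitutionMatrix = score_mat,
    gapOpening = 4, gapExtension = 2)
  aln <- if (Biostrings::score(aln_r) > Biostrings::score(aln_f))
    aln_r else aln_f
  matches <- Biostrings::nmatch(aln)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  pct <- 100 * matches / cols
  structure(list(matches = matches, aligned_columns = cols,
                 identity_percent = pct,
                 identity_rounded = as.integer(round_half_up(pct))),
            class = "identity_result")
}

#' Average nucleotide identity (OrthoANI-style)
#'
#' Each genome is chopped into non-overlapping fragments of
#' \code{fragment_length}; every fragment is placed in the other genome by
#' unique k-mer seeding and aligned against a bounded window
#' (global on the fragment, local in the window).  Reciprocal best
#' fragment pairs with coverage at least \code{min_coverage} contribute
#' the mean of their two directional identities; ANI is the mean over
#' contributing pairs.
#'
#' @param a,b \code{nuc_genome}s, each at least 5 fragments long
#' @param fragment_length fragment size in nt
#' @param min_coverage minimum aligned fraction of a fragment
#' @param anchor_k seeding k-mer size
#' @return list of class \code{ani_result}: \code{ani_percent} (NA when
#'   no fragment pair qualifies), \code{n_fragment_pairs},
#'   \code{fragment_length}
#' @export
ani <- function(a, b, fragment_length = 1020L, min_coverage = 0.7,
                anchor_k = 15L) {
  La <- nchar(a$sequence); Lb <- nchar(b$sequence)
  na <- La %/% fragment_length; nb <- Lb %/% fragment_length
  if (na < 5L || nb < 5L) {
    stop("each genome must contain at least 5 fragments of ",
         fragment_length, " nt")
  }
  map_a <- .map_fragments(a$sequence, b$sequence, fragment_length,
                          anchor_k)
  map_b <- .map_fragments(b$sequence, a$sequence, fragment_length,
                          anchor_k)
  idents <- numeric(0)
  for (i in seq_len(na)) {
    j <- map_a$frag_hit[i]
    if (is.na(j) || j < 1L || j > nb) next
    if (is.na(map_b$frag_hit[j]) || map_b$frag_hit[j] != i) next
    if (map_a$coverage[i] < min_coverage ||
        map_b$coverage[j] < min_coverage) next
    idents <- c(idents, (map_a$identity[i] + map_b$identity[j]) / 2)
  }
  if (!length(idents)) {
    warning("no qualifying reciprocal fragment pairs; ANI undefined")
    return(structure(list(ani_percent = NA_real_, n_fragment_pairs = 0L,
                          fragment_length = fragment_length),
                     class = "ani_result"))
  }
  structure(list(ani_percent = 100 * mean(idents),
                 n_fragment_pairs = length(idents),
                 fragment_length = fragment_length),
            class = "ani_result")
}

# Place every fragment of `qry` in `ref` by unique-k-mer seeding; returns
# per-fragment identity, coverage and the index of the ref fragment the
# best placement falls in.
.map_fragments <- function(qry, ref, flen, k) {
  nf <- nchar(qry) %/% flen
  idx <- .unique_kmer_index(ref, k)
  # one vectorised lookup of every seed of every fragment
  seed_at <- seq(1L, flen - k + 1L, by = 64L)
  ns <- length(seed_at)
  all_at <- rep((seq_len(nf) - 1L) * flen, each = ns) + seed_at
  all_seeds <- substring(qry, all_at, all_at + k - 1L)
  seed_pos <- idx$pos[match(all_seeds, idx$kmer)]
  # offset of the implied fragment start in ref, per seed
  frag_start <- seed_pos - rep(seed_at, nf) + 1L
  identity <- rep(NA_real_, nf)
  coverage <- rep(NA_real_, nf)
  frag_hit <- rep(NA_integer_, nf)
  margin <- 60L
  for (i in seq_len(nf)) {
    frag <- substr(qry, (i - 1L) * flen + 1L, i * flen)
    hits <- frag_start[((i - 1L) * ns + 1L):(i * ns)]
    hits <- hits[!is.na(hits)]
    if (!length(hits)) next
    tab <- table(hits)
    start <- min(as.integer(names(tab)[tab == max(tab)]))
    w_start <- max(1L, start - margin)
    w_end <- min(nchar(ref), start + flen - 1L + margin)
    window <- substr(ref, w_start, w_end)
    aln <- Biostrings::pairwiseAlignment(frag, window,
                                         type = "global-local")
    pat <- as.character(Biostrings::pattern(aln))
    sub <- as.character(Biostrings::subject(aln))
    cols <- nchar(pat)
    matches <- Biostrings::nmatch(aln)
    sub_gaps <- lengths(regmatches(sub, gregexpr("-", sub, fixed = TRUE)))
    identity[i] <- matches / cols
    coverage[i] <- (flen - sub_gaps) / flen
    frag_hit[i] <- ((start - 1L + flen %/% 2L) %/% flen) + 1L
  }
  list(identity = identity, coverage = coverage, frag_hit = frag_hit)
}

#' Reciprocal-best-hit orthologue sharing
#'
#' Local protein alignment (BLOSUM62) between all members of two
#' proteomes; pairs that are each other's best hit are reported as shared
#' orthologues.  Ties break towards the lexicographically smallest
#' locus_tag.
#'
#' @param proteome_a,proteome_b named character vectors of protein
#'   sequences (names are locus_tags)
#' @return list of class \code{rbh_result}: \code{pairs} (data.frame a,
#'   b, score), \code{n_shared}, \code{unique_a}, \code{unique_b}
#' @export
rbh_orthologues <- function(proteome_a, proteome_b) {
  if (!length(proteome_a) || !length(proteome_b)) {
    stop("empty proteome")
  }
  clean <- function(p) gsub("*", "X", toupper(p), fixed = TRUE)
  pa <- clean(proteome_a); pb <- clean(proteome_b)
  # order names so that which.max resolves ties lexicographically
  pa <- pa[order(names(pa))]; pb <- pb[order(names(pb))]
  set_b <- Biostrings::AAStringSet(pb)
  scores <- matrix(NA_real_, nrow = length(pb), ncol = length(pa),
                   dimnames = list(names(pb), names(pa)))
  for (i in seq_along(pa)) {
    scores[, i] <- Biostrings::pairwiseAlignment(
      set_b, pa[[i]], type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  }
  best_for_a <- apply(scores, 2, which.max)
  best_for_b <- apply(scores, 1, which.max)
  recip <- which(best_for_b[best_for_a] == seq_along(pa))
  pairs <- data.frame(
    a = names(pa)[recip],
    b = names(pb)[best_for_a[recip]],
    score = scores[cbind(best_for_a[recip], recip)],
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, n_shared = nrow(pairs),
                 unique_a = setdiff(names(pa), pairs$a),
                 unique_b = setdiff(names(pb), pairs$b)),
            class = "rbh_result")
}

#' Translate all CDS of a genome into a proteome
#'
#' Internal stop codons (split genes) are kept as \code{*} in the
#' returned proteins; terminal stops are dropped.
#'
#' @param genome a \code{nuc_genome}
#' @param features a \code{feature_set}
#' @param skip_partial drop CDS whose length is not divisible by 3
#' @return named character vector (locus_tag -> protein)
#' @export
proteome_from_features <- function(genome, features, skip_partial = TRUE) {
  df <- as.data.frame(features)
  tags <- unique(df$locus_tag[df$type == "CDS"])
  out <- character(0)
  for (tag in tags) {
    seq <- extract_cds(genome, feature_rows(features, tag))
    if (nchar(seq) %% 3L != 0L) {
      if (skip_partial) next
      stop("CDS length not divisible by 3: ", tag)
    }
    out[[tag]] <- translate_cds(seq)$protein
  }
  out
}

#' Genome summary statistics
#'
#' @param genome a \code{nuc_genome}
#' @param features a \code{feature_set} (optional; feature counts are NA
#'   without it)
#' @return one-row data.frame of class \code{genome_stats}: length,
#'   gc_percent (1 decimal, half away from zero), n_genes, n_cds,
#'   n_pseudo, n_rrna, n_trna
#' @export
genome_stats <- function(genome, features = NULL) {
  n_genes <- n_cds <- n_pseudo <- n_rrna <- n_trna <- NA_integer_
  if (!is.null(features)) {
    df <- as.data.frame(features)
    per_tag <- df[!duplicated(df$locus_tag), , drop = FALSE]
    n_cds <- sum(per_tag$type == "CDS" & !per_tag$pseudo)
    n_pseudo <- sum(per_tag$pseudo)
    n_rrna <- sum(per_tag$type == "rRNA")
    n_trna <- sum(per_tag$type == "tRNA")
    n_genes <- nrow(per_tag[per_tag$type != "gene", , drop = FALSE])
  }
  structure(data.frame(
    genome_id = genome$id,
    length = nchar(genome$sequence),
    gc_percent = round_half_up(100 * gc_content(genome$sequence), 1),
    n_genes = n_genes, n_cds = n_cds, n_pseudo = n_pseudo,
    n_rrna = n_rrna, n_trna = n_trna,
    stringsAsFactors = FALSE),
    class = c("genome_stats", "data.frame"))
}
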