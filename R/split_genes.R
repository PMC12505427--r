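# Detection of genes split in two by a single in-frame internal stop
# codon, merged re-annotation, and the three-group stop-codon usage
# statistic.
#
# Annotation pipelines report such genes as two adjacent CDS.  A
# neighbouring same-strand pair (A, B) qualifies as a split candidate when
# merging the full span from A's coding start to B's coding end stays in
# frame and its translation contains exactly one internal stop, located
# between A's annotated stop and B's first codon.  Homology evidence (the
# original manual route) can be supplied as an override table; the
# geometric criterion is the testable core.

#' Find split-gene candidates
#'
#' @param genome a \code{nuc_genome}
#' @param features a \code{feature_set} for that genome
#' @param max_gap maximum allowed gap (nt) between the two halves in
#'   coding orientation
#' @param min_half_length minimum length of each half in codons
#' @param homology optional data.frame with columns
#'   \code{first_locus_tag}, \code{second_locus_tag}: pairs asserted
#'   homologous, accepted even when the gap exceeds \code{max_gap}
#' @return data.frame of class \code{split_candidates}, one row per merged
#'   gene, with 0-based half-open \code{merged_start}/\code{merged_end}
#'   (end may exceed the genome length for origin-spanning merges on a
#'   circular genome)
#' @export
find_split_candidates <- function(genome, features, max_gap = 30L,
                                  min_half_length = 10L, homology = NULL) {
  df <- as.data.frame(features)
  df <- df[df$type == "CDS", , drop = FALSE]
  cds <- df[df$segment == 1L, , drop = FALSE]
  multi <- unique(df$locus_tag[df$segment > 1L])
  # span of each feature in linearized coordinates (wrapped features
  # extend past the genome end)
  L <- nchar(genome$sequence)
  span <- lapply(seq_len(nrow(cds)), function(i) {
    tag <- cds$locus_tag[i]
    if (tag %in% multi) {
      segs <- df[df$locus_tag == tag, , drop = FALSE]
      segs <- segs[order(segs$segment), , drop = FALSE]
      # two-segment origin wrap: (s..L) + (0..e)
      c(segs$start[1], L + segs$end[nrow(segs)])
    } else {
      c(cds$start[i], cds$end[i])
    }
  })
  cds$span_start <- vapply(span, `[`, 0, 1)
  cds$span_end <- vapply(span, `[`, 0, 2)

  .check_overlaps(cds)

  pairs <- list()
  for (s in c("+", "-")) {
    sub <- cds[cds$strand == s, , drop = FALSE]
    if (nrow(sub) < 2) next
    ord <- order(sub$span_start)
    sub <- sub[if (s == "+") ord else rev(ord), , drop = FALSE]
    for (i in seq_len(nrow(sub) - 1L)) {
      a <- sub[i, ]
      b <- sub[i + 1L, ]
      cand <- .qualify_pair(genome, a, b, s, max_gap, min_half_length)
      if (!is.null(cand)) pairs[[length(pairs) + 1L]] <- cand
    }
    # circular adjacency: last gene in coding order vs first
    if (isTRUE(genome$circular) && nrow(sub) >= 2) {
      cand <- .qualify_pair(genome, sub[nrow(sub), ], sub[1, ], s,
                            max_gap, min_half_length, wrap = TRUE)
      if (!is.null(cand)) pairs[[length(pairs) + 1L]] <- cand
    }
  }

  if (!is.null(homology)) {
    for (i in seq_len(nrow(homology))) {
      a <- cds[cds$locus_tag == homology$first_locus_tag[i], , drop = FALSE]
      b <- cds[cds$locus_tag == homology$second_locus_tag[i], , drop = FALSE]
      if (nrow(a) != 1 || nrow(b) != 1) next
      cand <- .qualify_pair(genome, a, b, a$strand, max_gap = Inf,
                            min_half_length = min_half_length)
      if (!is.null(cand)) pairs[[length(pairs) + 1L]] <- cand
    }
  }

  empty <- data.frame(
    genome_id = character(0), merged_locus_tag = character(0),
    first_locus_tag = character(0), second_locus_tag = character(0),
    strand = character(0), gap_nt = integer(0),
    merged_start = integer(0), merged_end = integer(0),
    internal_stop_codon = character(0), internal_stop_index = integer(0),
    first_len_codons = integer(0), second_len_codons = integer(0),
    gene = character(0), stringsAsFactors = FALSE)
  if (!length(pairs)) {
    return(structure(empty, class = c("split_candidates", "data.frame")))
  }
  out <- do.call(rbind, pairs)
  out <- out[!duplicated(out$merged_locus_tag), , drop = FALSE]
  # greedy matching: left-to-right by merged start, smaller gap first on
  # ties; each CDS participates in at most one candidate
  out <- out[order(out$merged_start, out$gap_nt), , drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    tags <- c(out$first_locus_tag[i], out$second_locus_tag[i])
    if (!any(tags %in% used)) {
      keep[i] <- TRUE
      used <- c(used, tags)
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("split_candidates", "data.frame"))
}

.check_overlaps <- function(cds) {
  for (s in c("+", "-")) {
    sub <- cds[cds$strand == s, , drop = FALSE]
    if (nrow(sub) < 2) next
    sub <- sub[order(sub$span_start), , drop = FALSE]
    bad <- which(sub$span_start[-1] < sub$span_end[-nrow(sub)])
    if (length(bad)) {
      stop("overlapping same-strand CDS features: ",
           paste(sprintf("%s/%s", sub$locus_tag[bad],
                         sub$locus_tag[bad + 1L]), collapse = ", "))
    }
  }
}

# Test whether ordered neighbours (a, b) on strand s merge into a single
# ORF with exactly one internal stop between a's stop and b's first codon.
.qualify_pair <- function(genome, a, b, s, max_gap, min_half_length,
                          wrap = FALSE) {
  L <- nchar(genome$sequence)
  if (s == "+") {
    gap <- (b$span_start + if (wrap) L else 0) - a$span_end
    m_start <- a$span_start
    m_end <- b$span_end + if (wrap) L else 0
  } else {
    gap <- a$span_start - (b$span_end - if (wrap) L else 0)
    m_start <- b$span_start - if (wrap) L else 0
    m_end <- a$span_end
    if (m_start < 0) {  # renormalize to [0, L)
      m_start <- m_start + L
      m_end <- m_end + L
    }
  }
  if (gap < 0 || gap > max_gap) return(NULL)
  len_a <- a$span_end - a$span_start
  len_b <- b$span_end - b$span_start
  merged_len <- len_a + gap + len_b
  if (merged_len %% 3L != 0L) return(NULL)
  if (len_a %/% 3L < min_half_length || len_b %/% 3L < min_half_length) {
    return(NULL)
  }
  seq <- span_extract(genome, m_start, m_end)
  if (s == "-") seq <- revcomp(seq)
  tr <- translate_cds(seq)
  if (nrow(tr$internal_stops) != 1L) return(NULL)
  idx <- tr$internal_stops$codon_index[1]
  # at/after A's annotated stop (A's last codon) and before B's first codon
  first_cod <- len_a %/% 3L
  b_first <- (len_a + gap) %/% 3L
  if (idx < first_cod - 1L || idx >= b_first) return(NULL)
  data.frame(
    genome_id = a$genome_id,
    merged_locus_tag = paste0(a$locus_tag, "_merged"),
    first_locus_tag = a$locus_tag, second_locus_tag = b$locus_tag,
    strand = s, gap_nt = as.integer(gap),
    merged_start = as.integer(m_start), merged_end = as.integer(m_end),
    internal_stop_codon = tr$internal_stops$codon[1],
    internal_stop_index = as.integer(idx),
    first_len_codons = len_a %/% 3L, second_len_codons = len_b %/% 3L,
    gene = if (!is.na(a$gene)) a$gene else b$gene,
    stringsAsFactors = FALSE)
}

#' Merged-gene annotation table
#'
#' One row per merged gene in 1-based inclusive coordinates (an
#' origin-spanning merge on a circular genome keeps end > genome length,
#' i.e. coordinates along the unwrapped path).
#'
#' @param candidates a \code{split_candidates} table
#' @param path optional file; when given the table is written as TSV
#' @return data.frame (invisibly when \code{path} is given)
#' @export
write_merged_annotation <- function(candidates, path = NULL) {
  df <- data.frame(
    merged_locus_tag = candidates$merged_locus_tag,
    genome_id = candidates$genome_id,
    start = candidates$merged_start + 1L,
    end = candidates$merged_end,
    strand = candidates$strand,
    internal_stop_codon = candidates$internal_stop_codon,
    internal_stop_codon_index = candidates$internal_stop_index + 1L,
    first_locus_tag = candidates$first_locus_tag,
    second_locus_tag = candidates$second_locus_tag,
    gene = candidates$gene,
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Stop-codon usage in three gene groups
#'
#' Group 1: terminal stop codons of intact CDS (those not participating in
#' any split candidate); group 2: the internal stop codon of each split
#' candidate; group 3: the terminal stop codon of each candidate's second
#' half.  Frequencies are integer percentages (half away from zero).  CDS
#' whose extracted sequence does not end in a stop codon are excluded from
#' group 1 and counted in the \code{n_excluded} attribute.
#'
#' @param genome a \code{nuc_genome}
#' @param features a \code{feature_set}
#' @param candidates output of \code{\link{find_split_candidates}} on the
#'   same features
#' @param include_pseudo also count CDS flagged pseudo in group 1
#' @return data.frame of class \code{stop_usage} with columns group,
#'   codon, count, percent
#' @export
stop_usage <- function(genome, features, candidates,
                       include_pseudo = FALSE) {
  df <- as.data.frame(features)
  cds_tags <- unique(df$locus_tag[df$type == "CDS"])
  in_cand <- unique(c(candidates$first_locus_tag,
                      candidates$second_locus_tag))
  n_excluded <- 0L

  terminal_of <- function(tag) {
    feat <- feature_rows(features, tag)
    seq <- extract_cds(genome, feat)
    if (nchar(seq) %% 3L != 0L) return(NA_character_)
    last <- substr(seq, nchar(seq) - 2L, nchar(seq))
    if (last %in% STOP_CODONS) last else NA_character_
  }

  g1_tags <- setdiff(cds_tags, in_cand)
  if (!include_pseudo) {
    pseudo_tags <- unique(df$locus_tag[df$pseudo])
    g1_tags <- setdiff(g1_tags, pseudo_tags)
  }
  g1 <- vapply(g1_tags, terminal_of, "")
  n_excluded <- sum(is.na(g1))
  g1 <- g1[!is.na(g1)]

  g2 <- candidates$internal_stop_codon

  g3 <- vapply(candidates$second_locus_tag, terminal_of, "")
  n_excluded <- n_excluded + sum(is.na(g3))
  g3 <- g3[!is.na(g3)]

  tab <- function(group, codons) {
    counts <- vapply(STOP_CODONS, function(cc) sum(codons == cc), 0L)
    pct <- if (sum(counts) > 0) {
      round_half_up(100 * counts / sum(counts))
    } else rep(NA_real_, 3)
    data.frame(group = group, codon = STOP_CODONS, count = counts,
               percent = pct, stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- rbind(tab("group1_intact_terminal", g1),
               tab("group2_internal", g2),
               tab("group3_second_half_terminal", g3))
  structure(out, class = c("stop_usage", "data.frame"),
            n_excluded = n_excluded)
}
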