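# Genome and annotation input/output.
#
# Internal coordinate convention: 0-based half-open intervals, one row per
# segment.  All on-disk formats (FASTA headers aside) use the conventional
# 1-based inclusive coordinates; conversion happens only at the file
# boundary.  A feature spanning the origin of a circular genome is always
# normalised to a two-segment representation.

#' Construct a nucleotide genome
#'
#' @param id genome identifier (unique within a loaded set)
#' @param sequence DNA sequence, IUPAC alphabet; stored uppercased
#' @param circular is the molecule circular?
#' @param description free-text description
#' @return object of class \code{nuc_genome}
#' @export
new_genome <- function(id, sequence, circular = FALSE, description = "") {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1) stop("genome sequence must have length >= 1")
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_DNA, collapse = "")), sequence)
  if (bad > 0) {
    stop(sprintf("record '%s': non-IUPAC character '%s' at offset %d",
                 id, substr(sequence, bad, bad), as.integer(bad)))
  }
  stopifnot_scalar_flag(circular, "circular")
  structure(
    list(id = id, sequence = sequence, circular = circular,
         description = description),
    class = "nuc_genome"
  )
}

#' @export
print.nuc_genome <- function(x, ...) {
  cat(sprintf("<nuc_genome> %s: %s bp, %s, GC %.1f%%\n", x$id,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              100 * gc_content(x$sequence)))
  invisible(x)
}

#' @export
length.nuc_genome <- function(x) nchar(x$sequence)

#' Read genomes from a FASTA file
#'
#' One genome per record.  Circularity is taken from a
#' \code{circular=true} keyword in the record description, falling back to
#' \code{circular_default}.
#'
#' @param path FASTA file
#' @param circular_default circularity for records without the keyword
#' @return named list of \code{nuc_genome} objects
#' @export
read_fasta <- function(path, circular_default = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate genome ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genomes <- lapply(seq_along(set), function(i) {
    desc <- sub("^\\S+\\s*", "", headers[i])
    circ <- if (grepl("circular=true", desc, ignore.case = TRUE)) TRUE
      else if (grepl("circular=false", desc, ignore.case = TRUE)) FALSE
      else circular_default
    new_genome(ids[i], as.character(set[[i]]), circular = circ,
               description = desc)
  })
  stats::setNames(genomes, ids)
}

#' Write genomes to a FASTA file
#'
#' Sequences are wrapped at 80 columns; circular genomes carry a
#' \code{circular=true} keyword in the header so that circularity
#' round-trips through \code{\link{read_fasta}}.
#'
#' @param genomes list of \code{nuc_genome}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "nuc_genome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(set) <- vapply(genomes, function(g) {
    tag <- if (g$circular) "circular=true" else ""
    desc <- trimws(paste(tag, sub("circular=(true|false)\\s*", "",
                                  g$description)))
    trimws(paste(g$id, desc))
  }, "")
  Biostrings::writeXStringSet(set, path, width = 80)
  invisible(path)
}

# ---- feature sets ----------------------------------------------------------

.feature_cols <- c("genome_id", "locus_tag", "segment", "start", "end",
                   "strand", "type", "gene", "product", "pseudo")

#' Construct a feature set
#'
#' A feature set is a data.frame with one row per feature segment, in
#' 0-based half-open internal coordinates.  Multi-segment features (origin
#' wrapping, joined locations) occupy several rows sharing a
#' \code{locus_tag}, in join order.
#'
#' @param df data.frame with columns genome_id, locus_tag, segment, start,
#'   end, strand, type, gene, product, pseudo
#' @param source format dialect the features came from
#' @return object of class \code{feature_set} (a data.frame)
#' @export
new_feature_set <- function(df, source = "memory") {
  missing_cols <- setdiff(.feature_cols, names(df))
  if ("segment" %in% missing_cols) df$segment <- 1L
  if ("type" %in% missing_cols) df$type <- "CDS"
  if ("gene" %in% missing_cols) df$gene <- NA_character_
  if ("product" %in% missing_cols) df$product <- NA_character_
  if ("pseudo" %in% missing_cols) df$pseudo <- FALSE
  missing_cols <- setdiff(.feature_cols, names(df))
  if (length(missing_cols)) {
    stop("feature set is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, .feature_cols]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$segment <- as.integer(df$segment)
  df$pseudo <- as.logical(df$pseudo)
  if (any(df$start >= df$end)) {
    stop("invalid segments (start >= end): ",
         paste(df$locus_tag[df$start >= df$end], collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df$gene <- as.character(df$gene)
  df$product <- as.character(df$product)
  key <- paste(df$genome_id, df$locus_tag, df$segment)
  if (anyDuplicated(key)) {
    stop("duplicate locus_tag/segment rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  structure(df, class = c("feature_set", "data.frame"), source = source)
}

#' Read CDS/RNA annotations
#'
#' Supported dialects: \code{tsv} (plain feature table with header
#' genome_id, locus_tag, start, end, strand, gene, product, pseudo and
#' optional type/segment columns), \code{gff3}, and a restricted
#' \code{genbank} flat-file reader covering CDS, gene, rRNA and tRNA
#' features with \code{join()}/\code{complement()} locations and
#' \code{/pseudo}, \code{/gene}, \code{/product}, \code{/locus_tag}
#' qualifiers.
#'
#' File coordinates are 1-based inclusive and converted to the internal
#' 0-based half-open convention.  A feature running past the end of a
#' circular genome is wrapped into two segments; on a linear genome it is
#' an error.  Supplying \code{genomes} enables these length checks.
#'
#' @param path annotation file
#' @param dialect one of "tsv", "gff3", "genbank"
#' @param genomes optional named list of \code{nuc_genome} for validation
#'   and origin wrapping
#' @return a \code{feature_set}
#' @export
read_features <- function(path, dialect = c("tsv", "gff3", "genbank"),
                          genomes = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- switch(dialect,
    tsv = .read_features_tsv(path),
    gff3 = .read_features_gff3(path),
    genbank = .read_features_genbank(path)
  )
  df <- .wrap_and_validate(df, genomes)
  new_feature_set(df, source = dialect)
}

.read_features_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", ""))
  req <- c("genome_id", "locus_tag", "start", "end", "strand")
  if (!all(req %in% names(df))) {
    stop("TSV feature table must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(df$type)) df$type <- "CDS"
  if (is.null(df$gene)) df$gene <- NA_character_
  if (is.null(df$product)) df$product <- NA_character_
  df$gene <- as.character(df$gene)
  df$product <- as.character(df$product)
  if (is.null(df$pseudo)) df$pseudo <- FALSE
  df$pseudo <- tolower(as.character(df$pseudo)) %in% c("true", "t", "1", "yes")
  if (is.null(df$segment)) {
    df$segment <- stats::ave(seq_len(nrow(df)), df$locus_tag,
                             FUN = seq_along)
  }
  # 1-based inclusive -> 0-based half-open
  df$start <- as.integer(df$start) - 1L
  df$end <- as.integer(df$end)
  df
}

.read_features_gff3 <- function(path) {
  keep_types <- c("CDS", "gene", "rRNA", "tRNA", "pseudogene")
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    g <- as.data.frame(rtracklayer::readGFF(path))
  } else {
    g <- .parse_gff3_text(path)
  }
  g <- g[g$type %in% keep_types, , drop = FALSE]
  if (nrow(g) == 0) stop("no CDS/gene/rRNA/tRNA features in ", path)
  get_attr <- function(nm, default = NA_character_) {
    if (nm %in% names(g)) as.character(g[[nm]]) else rep(default, nrow(g))
  }
  locus <- get_attr("locus_tag")
  id <- get_attr("ID")
  locus <- ifelse(is.na(locus), id, locus)
  pseudo_col <- get_attr("pseudo", "false")
  pseudo <- !is.na(pseudo_col) & tolower(pseudo_col) %in% c("true", "")
  df <- data.frame(
    genome_id = as.character(g$seqid),
    locus_tag = locus,
    start = as.integer(g$start) - 1L,
    end = as.integer(g$end),
    strand = as.character(g$strand),
    type = ifelse(as.character(g$type) == "pseudogene", "gene",
                  as.character(g$type)),
    gene = get_attr("gene"),
    product = get_attr("product"),
    pseudo = pseudo | as.character(g$type) == "pseudogene",
    stringsAsFactors = FALSE
  )
  # multi-row CDS sharing an ID are segments of one feature, in file order
  df$segment <- stats::ave(seq_len(nrow(df)),
                           paste(df$type, df$locus_tag), FUN = seq_along)
  df
}

# Minimal 9-column GFF3 reader used when rtracklayer is unavailable.
.parse_gff3_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- parts[vapply(parts, length, 0L) == 9]
  if (!length(parts)) stop("no GFF3 feature lines in ", path)
  m <- do.call(rbind, parts)
  attrs <- lapply(strsplit(m[, 9], ";", fixed = TRUE), function(kv) {
    kv <- strsplit(kv, "=", fixed = TRUE)
    stats::setNames(
      vapply(kv, function(p) {
        if (length(p) < 2 || is.na(p[2])) "true" else utils::URLdecode(p[2])
      }, ""),
      vapply(kv, `[[`, "", 1))
  })
  pull <- function(nm) vapply(attrs, function(a) a[nm][[1]] %||% NA_character_, "")
  data.frame(seqid = m[, 1], type = m[, 3],
             start = as.integer(m[, 4]), end = as.integer(m[, 5]),
             strand = m[, 7], ID = pull("ID"), locus_tag = pull("locus_tag"),
             gene = pull("gene"), product = pull("product"),
             pseudo = pull("pseudo"), stringsAsFactors = FALSE)
}

.read_features_genbank <- function(path) {
  lines <- readLines(path)
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus_line)) stop("not a GenBank flat file: ", path)
  genome_id <- strsplit(trimws(sub("^LOCUS\\s+", "", locus_line[1])),
                        "\\s+")[[1]][1]
  feat_start <- grep("^FEATURES", lines)
  if (!length(feat_start)) stop("no FEATURES block in ", path)
  feat_end <- grep("^(ORIGIN|CONTIG|//)", lines)
  feat_end <- min(feat_end[feat_end > feat_start[1]], length(lines) + 1L)
  block <- lines[(feat_start[1] + 1L):(feat_end - 1L)]

  # A new feature starts with a key at column 6; continuation lines are
  # indented to column 22.
  is_key <- grepl("^ {5}\\S", block)
  idx <- cumsum(is_key)
  feats <- split(block[idx > 0], idx[idx > 0])
  keep <- c("CDS", "gene", "rRNA", "tRNA")
  rows <- list()
  n_auto <- 0L
  for (fl in feats) {
    key <- sub("^\\s+(\\S+).*$", "\\1", fl[1])
    if (!key %in% keep) next
    text <- paste(trimws(sub("^ {5}\\S+\\s*", "", fl[1])),
                  paste(trimws(fl[-1]), collapse = " "))
    qual_at <- regexpr("/[A-Za-z_]+", text)
    loc_text <- if (qual_at > 0) substr(text, 1, qual_at - 1) else text
    quals <- .parse_genbank_qualifiers(
      if (qual_at > 0) substr(text, qual_at, nchar(text)) else "")
    loc <- .parse_genbank_location(gsub("\\s", "", loc_text))
    n_auto <- n_auto + 1L
    tag <- quals[["locus_tag"]] %||% sprintf("%s_f%04d", key, n_auto)
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = genome_id, locus_tag = tag,
      segment = seq_len(nrow(loc$segments)),
      start = loc$segments$start - 1L, end = loc$segments$end,
      strand = if (loc$complement) "-" else "+",
      type = key, gene = quals[["gene"]] %||% NA_character_,
      product = quals[["product"]] %||% NA_character_,
      pseudo = isTRUE(quals[["pseudo"]] == "true"),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no CDS/gene/rRNA/tRNA features found in ", path)
  do.call(rbind, rows)
}

.parse_genbank_location <- function(loc) {
  complement <- FALSE
  if (startsWith(loc, "complement(")) {
    complement <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (startsWith(loc, "join(")) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  segs <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    nums <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (length(nums) == 1) nums <- c(nums, nums)
    data.frame(start = nums[1], end = nums[2])
  })
  list(segments = do.call(rbind, segs), complement = complement)
}

.parse_genbank_qualifiers <- function(text) {
  if (!nzchar(text)) return(list())
  hits <- gregexpr('/([A-Za-z_]+)(="[^"]*"|=[^/ ]+)?', text)[[1]]
  out <- list()
  for (i in seq_along(hits)) {
    q <- substr(text, hits[i], hits[i] + attr(hits, "match.length")[i] - 1)
    nm <- sub("^/([A-Za-z_]+).*$", "\\1", q)
    val <- if (grepl("=", q, fixed = TRUE)) {
      gsub('^"|"$', "", sub("^/[A-Za-z_]+=", "", q))
    } else "true"  # bare flag qualifier, e.g. /pseudo
    out[[nm]] <- val
  }
  out
}

# Wrap features past the end of a circular genome; error on linear ones.
.wrap_and_validate <- function(df, genomes) {
  if (is.null(genomes)) return(df)
  lens <- vapply(genomes, function(g) nchar(g$sequence), 0L)
  circ <- vapply(genomes, function(g) isTRUE(g$circular), TRUE)
  unknown <- setdiff(unique(df$genome_id), names(lens))
  if (length(unknown)) {
    stop("features reference unknown genome id(s): ",
         paste(unknown, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, , drop = FALSE]
    L <- lens[[row$genome_id]]
    if (row$end > L) {
      if (!circ[[row$genome_id]]) {
        stop(sprintf("feature %s (end %d) exceeds linear genome %s (%d bp)",
                     row$locus_tag, row$end, row$genome_id, L))
      }
      first <- row; first$end <- L
      second <- row
      second$start <- 0L
      second$end <- row$end - L
      second$segment <- row$segment + 1L
      out[[length(out) + 1L]] <- first
      out[[length(out) + 1L]] <- second
    } else {
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  # renumber segments per feature, preserving order
  res$segment <- stats::ave(seq_len(nrow(res)), res$locus_tag,
                            FUN = seq_along)
  res
}

#' Write a feature set to a TSV feature table
#'
#' Coordinates are converted back to 1-based inclusive, so reading the file
#' with \code{read_features(..., dialect = "tsv")} reproduces the input.
#'
#' @param features a \code{feature_set}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
write_features <- function(features, path) {
  df <- as.data.frame(features)
  df$start <- df$start + 1L
  df$pseudo <- ifelse(df$pseudo, "true", "false")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Substring of a genome allowing end > length(genome) on circular molecules
# (the doubled-sequence trick for origin-spanning spans).
span_extract <- function(genome, start0, end0) {
  L <- nchar(genome$sequence)
  if (end0 <= L) return(substr(genome$sequence, start0 + 1L, end0))
  if (!genome$circular) {
    stop("span exceeds linear genome ", genome$id)
  }
  if (end0 - start0 > L) stop("span longer than the genome")
  paste0(substr(genome$sequence, start0 + 1L, L),
         substr(genome$sequence, 1L, end0 - L))
}

#' Extract the coding sequence of a feature
#'
#' Segments are concatenated in join order and the result is
#' reverse-complemented for minus-strand features (the
#' \code{complement(join(...))} semantics).  The returned length equals the
#' sum of segment lengths.
#'
#' @param genome a \code{nuc_genome}
#' @param feature the rows of a \code{feature_set} belonging to one
#'   locus_tag (one or more segments)
#' @return DNA sequence as a character string
#' @export
extract_cds <- function(genome, feature) {
  feature <- as.data.frame(feature)
  if (length(unique(feature$locus_tag)) != 1) {
    stop("extract_cds expects the segments of a single feature")
  }
  if (any(feature$genome_id != genome$id)) {
    stop("feature ", feature$locus_tag[1], " does not reference genome ",
         genome$id)
  }
  feature <- feature[order(feature$segment), , drop = FALSE]
  L <- nchar(genome$sequence)
  if (any(feature$end > L)) {
    stop("segment outside genome ", genome$id, " for ",
         feature$locus_tag[1])
  }
  parts <- vapply(seq_len(nrow(feature)), function(i) {
    substr(genome$sequence, feature$start[i] + 1L, feature$end[i])
  }, "")
  seq <- paste(parts, collapse = "")
  if (feature$strand[1] == "-") seq <- revcomp(seq)
  seq
}

#' All segment rows of one feature
#'
#' @param features a \code{feature_set}
#' @param locus_tag feature identifier
#' @return the matching rows, in segment order
#' @export
feature_rows <- function(features, locus_tag) {
  features[features$locus_tag == locus_tag, , drop = FALSE]
}
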